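# Brute-force reference implementation of the labeled-OTU protocol.
# Written directly from the published criteria and kept independent of the
# package internals: every proportion and every inequality is re-derived
# here from raw counts, with explicit loops and no shared code.
oracle_call_labeled <- function(counts, libraries, design,
                                min_heavy = 0.5, min_diff = 0.3,
                                min_lp = 5) {
  pool <- function(tr, iso, fr) {
    ids <- libraries$library_id[libraries$treatment == tr &
                                  libraries$isotope == iso &
                                  libraries$fraction == fr]
    s <- rep(0, nrow(counts))
    for (id in ids) s <- s + counts[, id]
    s
  }
  out <- list()
  for (i in seq_len(nrow(design))) {
    tr <- design$labeled[i]; ctrl <- design$control[i]
    h13c <- pool(tr, "13C", "H"); l13c <- pool(tr, "13C", "L")
    h12c <- pool(ctrl, "12C", "H")
    h13 <- 100 * h13c / sum(h13c)
    l13 <- 100 * l13c / sum(l13c)
    h12 <- 100 * h12c / sum(h12c)
    res <- data.frame(otu_id = rownames(counts), treatment = tr,
                      c1 = NA, c2 = NA, c3 = NA, c4 = NA,
                      lp = NA_real_, labeled = FALSE)
    for (j in seq_len(nrow(counts))) {
      res$c1[j] <- h13[j] > h12[j]                 # heavy 13C > heavy 12C
      res$c2[j] <- h13[j] > l13[j]                 # heavy > light
      res$c3[j] <- h13[j] >= min_heavy             # >= 0.5 %
      res$c4[j] <- (h13[j] - l13[j]) >= min_diff   # H - L >= 0.3 %
    }
    cand <- which(res$c1 & res$c2 & res$c3 & res$c4)
    denom <- sum(h13[cand])
    for (j in cand) {
      res$lp[j] <- 100 * h13[j] / denom
      res$labeled[j] <- res$lp[j] >= min_lp
    }
    out[[i]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Random small SIP count table (one 13C treatment with its 12C control,
# one library per fraction) with overdispersed counts and guaranteed
# positive library totals.
random_sip_table <- function(seed, max_otus = 10) {
  set.seed(seed)
  n <- sample(2:max_otus, 1)
  libs <- data.frame(
    library_id = c("t13_H", "t13_L", "c12_H", "c12_L"),
    treatment = c("t13", "t13", "c12", "c12"),
    isotope = c("13C", "13C", "12C", "12C"),
    fraction = c("H", "L", "H", "L"),
    replicate = 1L, marker = "16S")
  counts <- matrix(stats::rnbinom(n * 4, mu = 25, size = 0.6), n, 4,
                   dimnames = list(paste0("OTU", seq_len(n)),
                                   libs$library_id))
  for (j in seq_len(4)) if (sum(counts[, j]) == 0)
    counts[sample(n, 1), j] <- 1L
  storage.mode(counts) <- "integer"
  list(counts = counts, libraries = libs,
       design = data.frame(labeled = "t13", control = "c12"))
}

as_experiment <- function(tab) {
  structure(list(counts = tab$counts, libraries = tab$libraries,
                 design = tab$design, truth = NULL),
            class = "sip_experiment")
}
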