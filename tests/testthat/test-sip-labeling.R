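make_exp <- function(counts) {
  libs <- data.frame(
    library_id = c("t13_H", "t13_L", "c12_H", "c12_L"),
    treatment = c("t13", "t13", "c12", "c12"),
    isotope = c("13C", "13C", "12C", "12C"),
    fraction = c("H", "L", "H", "L"),
    replicate = 1L, marker = "16S")
  colnames(counts) <- libs$library_id
  structure(list(counts = counts, libraries = libs,
                 design = data.frame(labeled = "t13", control = "c12"),
                 truth = NULL),
            class = "sip_experiment")
}

test_that("relative abundances pool replicates and sum to 100", {
  x <- gen_sip_otu_tables(truth = synthetic_truth(seed = 3))
  ra <- relative_abundance(x, "13C-CH3Cl", "13C", "H")
  expect_equal(sum(ra), 100, tolerance = 1e-9)
  # pooling: sum replicate counts before dividing
  cols <- x$libraries$library_id[x$libraries$treatment == "13C-CH3Cl" &
                                   x$libraries$fraction == "H"]
  pooled <- rowSums(x$counts[, cols])
  expect_equal(unname(ra), unname(100 * pooled / sum(pooled)))
  # depth invariance of proportions
  x2 <- x
  x2$counts[, cols[1]] <- x2$counts[, cols[1]] * 10L
  cols2 <- x2$libraries$library_id[x2$libraries$treatment == "12C-CH3Cl" &
                                     x2$libraries$fraction == "H"]
  expect_equal(relative_abundance(x, "12C-CH3Cl", "12C", "H"),
               relative_abundance(x2, "12C-CH3Cl", "12C", "H"))
  # empty library is a clean error
  x3 <- x
  x3$counts[, cols] <- 0L
  expect_error(relative_abundance(x3, "13C-CH3Cl", "13C", "H"),
               "empty library")
})

test_that("the four criteria implement strict and inclusive comparisons as worded", {
  thr <- labeling_thresholds()
  # clear positive: heavy 13C at 2 %, control at 0.1 %, light at 0.5 %
  expect_equal(unname(evaluate_criteria(2.0, 0.5, 0.1, thr)[1, ]),
               rep(TRUE, 4))
  # below the 0.5 % abundance floor: criterion 3 fails regardless
  expect_false(evaluate_criteria(0.4, 0.0, 0.0, thr)[1, "c3"])
  # equality fails the strict 'higher than' and the 0.3 % gap
  eq <- evaluate_criteria(1.0, 1.0, 0.5, thr)
  expect_false(eq[1, "c2"]); expect_false(eq[1, "c4"])
  # boundary values are inclusive for criteria 3 and 4
  b <- evaluate_criteria(0.5, 0.2, 0.1, thr)
  expect_true(b[1, "c3"]); expect_true(b[1, "c4"])
})

test_that("labeling proportions renormalize over the candidate set", {
  ra <- c(OTU1 = 4, OTU2 = 1, OTU3 = 10)
  lp <- labeling_proportion(ra, c("OTU1", "OTU2"))
  expect_equal(unname(lp), c(80, 20))
  expect_equal(sum(lp), 100, tolerance = 1e-9)
  expect_equal(unname(labeling_proportion(ra, "OTU3")), 100)
  expect_length(labeling_proportion(ra, character(0)), 0)
  # whole-library denominator variant passes abundances through
  expect_equal(unname(labeling_proportion(ra, c("OTU1", "OTU2"),
                                          denominator = "library")),
               c(4, 1))
})

test_that("the caller recovers planted OTUs and respects the LP floor", {
  truth <- synthetic_truth(true_labeled_otus = c("OTU1", "OTU2", "OTU3"),
                           enrichment_factor = 10, seed = 101)
  x <- gen_sip_otu_tables(n_otus = 20, depth = 1e5, truth = truth)
  res <- call_labeled(x)
  expect_setequal(labeled_otus(res), truth$true_labeled_otus)
  # audit covers every OTU x treatment combination
  expect_equal(nrow(res$audit), 20L)
  expect_true(all(res$audit$labeled == (res$audit$c1 & res$audit$c2 &
                                          res$audit$c3 & res$audit$c4 &
                                          !is.na(res$audit$labeling_proportion) &
                                          res$audit$labeling_proportion >= 5)))
  # LP sums to 100 over candidates
  cand <- !is.na(res$audit$labeling_proportion)
  expect_equal(sum(res$audit$labeling_proportion[cand]), 100,
               tolerance = 1e-9)
})

test_that("no enrichment means no labeled calls", {
  truth <- synthetic_truth(enrichment_factor = 1, seed = 55)
  x <- gen_sip_otu_tables(truth = truth)
  expect_length(labeled_otus(call_labeled(x)), 0)
})

test_that("an OTU absent from the heavy fraction is never labeled", {
  counts <- matrix(c(
    0L, 50L, 40L, 45L,     # absent in H 13C
    500L, 100L, 80L, 90L,  # enriched
    500L, 850L, 880L, 865L), 3, 4, byrow = TRUE,
    dimnames = list(paste0("OTU", 1:3), NULL))
  x <- make_exp(counts)
  res <- call_labeled(x)
  expect_equal(labeled_otus(res), "OTU2")
  expect_false(res$audit$labeled[res$audit$otu_id == "OTU1"])
})

test_that("a high-abundance OTU below 5 % labeling proportion is not called", {
  # OTU2 passes all four abundance criteria but carries under 5 % of the
  # candidate labeling proportion
  counts <- matrix(c(
    9000L, 400L, 350L, 380L,
    110L,   10L,   5L,   8L,
    891L, 9590L, 9645L, 9612L), 3, 4, byrow = TRUE,
    dimnames = list(paste0("OTU", 1:3), NULL))
  x <- make_exp(counts)
  res <- call_labeled(x)
  a <- res$audit
  expect_true(all(a[a$otu_id == "OTU2", c("c1", "c2", "c3", "c4")] == TRUE))
  expect_lt(a$labeling_proportion[a$otu_id == "OTU2"], 5)
  expect_equal(labeled_otus(res), "OTU1")
})

test_that("missing fraction libraries raise an incomplete-design error naming the key", {
  x <- gen_sip_otu_tables(truth = synthetic_truth(seed = 2))
  keep <- x$libraries$fraction != "H" | x$libraries$isotope != "12C"
  x$libraries <- x$libraries[keep, ]
  x$counts <- x$counts[, x$libraries$library_id]
  expect_error(call_labeled(x), "incomplete design.*fraction=H")
})

test_that("calls are invariant to library depth scaling", {
  tab <- random_sip_table(seed = 77)
  x <- as_experiment(tab)
  res1 <- call_labeled(x)
  x2 <- x
  x2$counts[, 2] <- x2$counts[, 2] * 7L
  res2 <- call_labeled(x2)
  expect_identical(res1$audit$labeled, res2$audit$labeled)
})

test_that("raising a heavy-fraction count never un-labels that OTU", {
  for (seed in 1:30) {
    tab <- random_sip_table(seed)
    x <- as_experiment(tab)
    res <- call_labeled(x)
    lab <- res$audit$otu_id[res$audit$labeled]
    if (!length(lab)) next
    otu <- lab[1]
    x2 <- x
    x2$counts[otu, "t13_H"] <- x2$counts[otu, "t13_H"] + 25L
    res2 <- call_labeled(x2)
    expect_true(res2$audit$labeled[res2$audit$otu_id == otu])
  }
})

test_that("caller matches the brute-force oracle on random small tables", {
  for (seed in 1:100) {
    tab <- random_sip_table(seed)
    got <- call_labeled(as_experiment(tab))$audit
    want <- oracle_call_labeled(tab$counts, tab$libraries, tab$design)
    expect_identical(got$labeled, want$labeled, info = paste("seed", seed))
    expect_identical(got[, c("c1", "c2", "c3", "c4")],
                     want[, c("c1", "c2", "c3", "c4")],
                     info = paste("seed", seed))
    expect_equal(got$labeling_proportion, want$lp, tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("family-level summary drops faint unlabeled OTUs from display only", {
  counts <- matrix(c(
    600L,  40L,  35L,  38L,   # labeled, Beijerinckiaceae
    400L,  30L,  25L,  28L,   # labeled, Beijerinckiaceae
    100L, 400L, 420L, 410L,   # unlabeled but abundant
    5L,   100L, 120L, 110L,   # unlabeled, < 0.5 %: hidden
    8895L, 9430L, 9400L, 9414L), 5, 4, byrow = TRUE,
    dimnames = list(paste0("OTU", 1:5), NULL))
  x <- make_exp(counts)
  res <- call_labeled(x)
  taxmap <- data.frame(otu_id = paste0("OTU", 1:4),
                       family = c("Beijerinckiaceae", "Beijerinckiaceae",
                                  "Acidothermaceae", "Streptomycetaceae"))
  disp <- summarize_by_taxon(res, taxmap)
  # the two labeled congeners aggregate into one family row
  lab_row <- disp[disp$labeled & disp$family == "Beijerinckiaceae", ]
  expect_equal(nrow(lab_row), 1L)
  expect_equal(lab_row$relative_abundance,
               sum(res$audit$relab_h13[res$audit$otu_id %in%
                                         c("OTU1", "OTU2")]))
  # abundant unlabeled family shown; the faint one is absent from the
  # display yet present in the audit
  expect_true("Acidothermaceae" %in% disp$family)
  expect_false("Streptomycetaceae" %in% disp$family)
  expect_true("OTU4" %in% res$audit$otu_id)
  # unmapped OTUs fall back to 'unclassified'
  expect_true("unclassified" %in% disp$family)
})

test_that("OTU tables round-trip through TSV and feed the caller unchanged", {
  x <- gen_sip_otu_tables(truth = synthetic_truth(seed = 8))
  paths <- vapply(c("counts", "meta", "design"), function(p)
    withr::local_tempfile(fileext = ".tsv",
                          .local_envir = parent.frame(3)), "")
  write_otu_table(x, paths[1], paths[2], paths[3])
  x2 <- read_otu_table(paths[1], paths[2], paths[3])
  expect_identical(x2$counts, x$counts)
  expect_identical(call_labeled(x2)$audit$labeled,
                   call_labeled(x)$audit$labeled)
})
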