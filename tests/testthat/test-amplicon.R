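rec <- function(seqs, lib = "A", counts = rep(1L, length(seqs)),
                ids = sprintf("s%02d", seq_along(seqs))) {
  data.frame(id = ids, sequence = seqs, library_id = lib, count = counts)
}

test_that("16S length bounds are inclusive at 420 and 460 nt", {
  seqs <- vapply(c(419, 420, 460, 461), function(n) strrep("A", n), "")
  kept <- length_filter(rec(seqs), "16S")
  expect_equal(nchar(kept$sequence), c(420, 460))
  # idempotence
  expect_identical(length_filter(kept, "16S"), kept)
  # empty in, empty out
  expect_equal(nrow(length_filter(rec("AAAA")[0, ], "16S")), 0L)
})

test_that("functional-gene filter keeps reads within 20 nt of the expected length", {
  seqs <- vapply(c(401, 402, 422, 442, 443), function(n) strrep("G", n), "")
  kept <- length_filter(rec(seqs), "cmuA")
  expect_equal(nchar(kept$sequence), c(402, 422, 442))
  kept_mdh <- length_filter(rec(seqs), "mdh")
  expect_equal(nchar(kept_mdh$sequence), c(422, 442, 443))  # 430 +/- 20
})

test_that("global singleton rule removes one-off sequences but keeps shared library singletons", {
  r <- rbind(
    rec("AAAA", lib = "A", ids = "only_in_A"),
    rec("CCCC", lib = "A", ids = "shared_a"),
    rec("CCCC", lib = "B", ids = "shared_b"),
    rec("GGGG", lib = "B", counts = 2L, ids = "doubleton"))
  out <- global_singleton_filter(r)
  expect_false("AAAA" %in% out$sequence)
  expect_equal(sum(out$sequence == "CCCC"), 2L)  # kept in both libraries
  expect_true("GGGG" %in% out$sequence)
  expect_equal(nrow(global_singleton_filter(r[0, ])), 0L)
})

test_that("pairwise identity counts compatible aligned columns", {
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAC"), 1.0)
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTCC"), 0.9)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  # ambiguity codes match any compatible base; inosine matches everything
  expect_equal(pairwise_identity("ACGN", "ACGT"), 1.0)
  expect_equal(pairwise_identity("RYII", "ACGT"), 1.0)
  expect_equal(pairwise_identity("RRRR", "CCCC"), 0.0)
  # unequal lengths: terminal gaps excluded from the identity denominator
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGTAAAA"), 1.0)
})

test_that("preclustering merges within two substitutions, abundance-descending", {
  a <- strrep("ACGT", 10)
  b <- sub("^AC", "TT", a)            # 2 substitutions from a
  d <- sub("^ACG", "TTT", a)          # 3 substitutions from a
  r <- rbind(rec(a, counts = 10L, ids = "abund"),
             rec(b, counts = 3L, ids = "near"),
             rec(d, counts = 2L, ids = "far"))
  out <- precluster(r)
  expect_equal(sort(out$sequence), sort(c(a, d)))
  expect_equal(out$count[out$sequence == a], 13L)
  # identical duplicates dereplicate
  dup <- rbind(rec(a, ids = "x1"), rec(a, ids = "x2"))
  expect_equal(nrow(precluster(dup)), 1L)
  expect_equal(precluster(dup)$count, 2L)
})

test_that("greedy clustering joins by identity cutoff and conserves reads", {
  s1 <- strrep("ACGT", 10)                       # 40 nt
  s2 <- paste0(substr(s1, 1, 32), "TTTTTTTT")    # 85 % identical to s1
  r <- rbind(rec(s1, counts = 5L, ids = "a"), rec(s2, counts = 3L, ids = "b"))
  expect_equal(nrow(greedy_cluster(r, 90)$counts), 2L)
  expect_equal(nrow(greedy_cluster(r, 75)$counts), 1L)
  expect_equal(nrow(greedy_cluster(rec(rep(s1, 3)), 98)$counts), 1L)
  # cutoff 100: one OTU per distinct sequence
  expect_equal(nrow(greedy_cluster(r, 100)$counts), 2L)
  # read-count conservation at every cutoff
  for (co in c(100, 90, 75))
    expect_equal(sum(greedy_cluster(r, co)$counts), sum(r$count))
})

test_that("clustering is invariant to input order", {
  set.seed(42)
  base <- strrep("ACGTGCTA", 10)
  mutate <- function(s, n) {
    pos <- sample(nchar(s), n)
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos],
                      function(x) sample(setdiff(c("A", "C", "G", "T"), x),
                                         1), "")
    paste(ch, collapse = "")
  }
  seqs <- c(base, vapply(c(2, 4, 10, 25, 40), function(n) mutate(base, n),
                         ""))
  r <- rec(seqs, counts = c(9L, 5L, 4L, 3L, 2L, 1L))
  cl1 <- greedy_cluster(r, 95)
  for (perm_seed in 1:5) {
    set.seed(perm_seed)
    cl2 <- greedy_cluster(r[sample(nrow(r)), ], 95)
    expect_identical(cl2$membership[names(cl1$membership)],
                     cl1$membership)
    expect_identical(cl2$representatives, cl1$representatives)
  }
})

test_that("cutoff scan selects the highest stabilized cutoff on a two-cluster fixture", {
  set.seed(7)
  r1 <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
              collapse = "")
  ch <- strsplit(r1, "")[[1]]
  pos <- seq(1, 46, by = 5)  # 10 positions -> 80 % identity
  ch[pos] <- vapply(ch[pos],
                    function(x) setdiff(c("A", "C", "G", "T"), x)[1], "")
  r2 <- paste(ch, collapse = "")
  expect_equal(pairwise_identity(r1, r2), 0.8)
  reads <- gen_amplicon_reads(c(a = r1, b = r2), c(a = 6L, b = 4L), seed = 1)
  scan <- cutoff_scan(reads, cutoffs = c(100, 95, 90, 85, 81))
  expect_true(all(scan$curve$n_otus == 2))   # flat at 2 above 80 %
  expect_equal(scan$selected_cutoff, 100)    # highest cutoff of the flat run
  expect_true(scan$stabilized)
  # at 80 % the two references merge
  expect_equal(nrow(greedy_cluster(reads, 80)$counts), 1L)
})

test_that("cutoff scan flags a never-stabilizing staircase", {
  set.seed(13)
  s1 <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
              collapse = "")
  flip <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos],
                      function(x) setdiff(c("A", "C", "G", "T"), x)[1], "")
    paste(ch, collapse = "")
  }
  s2 <- flip(s1, 1)            # 99 % to s1
  s3 <- flip(s1, 10:13)        # 96 %
  s4 <- flip(s1, 20:27)        # 92 %
  r <- rec(c(s1, s2, s3, s4), counts = c(10L, 5L, 4L, 3L))
  scan <- cutoff_scan(r, cutoffs = c(100, 99, 95, 90), stability_delta = 0)
  expect_equal(scan$curve$n_otus, c(4L, 3L, 2L, 1L))
  expect_false(scan$stabilized)
  expect_equal(scan$selected_cutoff, 90)
  # OTU count is non-increasing as the cutoff drops
  expect_true(all(diff(scan$curve$n_otus) <= 0))
})

test_that("consensus takes the count-weighted majority with centroid tie-break", {
  expect_equal(consensus_sequence("ACGT"), "ACGT")
  expect_equal(consensus_sequence(c("AAAA", "AAAT"), counts = c(3, 1)),
               "AAAA")
  # clear non-centroid majority wins the column
  expect_equal(consensus_sequence(c("AAAA", "AAAT", "AAAT"),
                                  counts = c(1, 1, 1)), "AAAT")
  # tie at the last column resolves to the centroid base
  expect_equal(consensus_sequence(c("AAAA", "AAAT"), counts = c(1, 1)),
               "AAAA")
})

test_that("degenerate primer expansion is the product of per-symbol degeneracies", {
  expect_equal(expand_degenerate("ACGT"), "ACGT")
  expect_setequal(expand_degenerate("RY"), c("AC", "AT", "GC", "GT"))
  # bacterial 341for primer: N (4) x W (2) = 8 concrete sequences
  expect_equal(length(expand_degenerate("CCTACGGGNGGCWGCAG")), 8L)
  expect_equal(length(expand_degenerate("BDHVN")), 3 * 3 * 3 * 3 * 4)
  expect_equal(length(expand_degenerate("AIC")), 4L)  # inosine acts as N
  expect_error(expand_degenerate("ACGX"), "alphabet error")
})

test_that("amplicon records round-trip through FASTA with library tags", {
  r <- rbind(rec(strrep("ACGT", 5), lib = "libA", counts = 3L, ids = "r1"),
             rec(strrep("TTGG", 5), lib = "libB", ids = "r2"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_records(r, path)
  r2 <- read_fasta_records(path)
  expect_equal(r2$sequence, r$sequence)
  expect_equal(r2$library_id, r$library_id)
  expect_equal(r2$count, r$count)
})
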