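## Amplicon read processing: length filters, the global-singleton rule,
## preclustering, greedy centroid OTU clustering and iterative cutoff
## selection. Records are plain data frames with columns id, sequence,
## library_id, count — the simplest structure that round-trips to FASTA.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  ## inosine pairs indiscriminately; treated like N
  I = c("A", "C", "G", "T"))

## logical compatibility lookup, symbols x symbols
.iupac_compat <- local({
  syms <- names(IUPAC_SETS)
  m <- matrix(FALSE, length(syms), length(syms), dimnames = list(syms, syms))
  for (a in syms) for (b in syms)
    m[a, b] <- length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0
  m
})

#' Marker-gene amplicon specification
#'
#' Bundles the expected amplicon length, the length-filter rule and the OTU
#' identity cutoff for a marker gene. Built-in markers: \code{"16S"}
#' (464 bp amplicon, absolute length bounds 420--460 nt, 98\% cutoff; 90\%
#' for family-level analyses), \code{"cmuA"} (chloromethane
#' dehalogenase/methyltransferase, 422 bp, window of 20 nt around the
#' expected length, 90\% cutoff) and \code{"mdh"} (mxaF/xoxF methanol
#' dehydrogenase, 430 bp, 20 nt window, 80\% cutoff).
#'
#' @param name marker name; one of \code{"16S"}, \code{"cmuA"},
#'   \code{"mdh"}, unless all other fields are supplied.
#' @param expected_amplicon_length,otu_identity_cutoff,length_rule,bounds,window
#'   override the built-in values; \code{length_rule} is
#'   \code{"absolute_bounds"} (keep lengths in \code{bounds}) or
#'   \code{"window"} (keep lengths within \code{window} nt of the expected
#'   length).
#' @return object of class \code{"marker_spec"}.
#' @export
marker_spec <- function(name, expected_amplicon_length = NULL,
                        otu_identity_cutoff = NULL, length_rule = NULL,
                        bounds = c(420, 460), window = 20) {
  builtin <- list(
    `16S`  = list(len = 464, cutoff = 98, rule = "absolute_bounds"),
    cmuA   = list(len = 422, cutoff = 90, rule = "window"),
    mdh    = list(len = 430, cutoff = 80, rule = "window"))
  if (name %in% names(builtin)) {
    b <- builtin[[name]]
    expected_amplicon_length <- expected_amplicon_length %||% b$len
    otu_identity_cutoff <- otu_identity_cutoff %||% b$cutoff
    length_rule <- length_rule %||% b$rule
  }
  if (is.null(expected_amplicon_length) || is.null(otu_identity_cutoff) ||
      is.null(length_rule))
    stop("unknown marker '", name, "': supply length, cutoff and rule")
  stopifnot(otu_identity_cutoff > 0, otu_identity_cutoff <= 100)
  structure(list(name = name,
                 expected_amplicon_length = expected_amplicon_length,
                 otu_identity_cutoff = otu_identity_cutoff,
                 length_rule = match.arg(length_rule,
                                         c("absolute_bounds", "window")),
                 bounds = bounds, window = window),
            class = "marker_spec")
}

as_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence", "library_id", "count") %in%
                names(records)))
  records
}

#' Filter reads by length
#'
#' For 16S (absolute-bounds rule) reads shorter than 420 nt or longer than
#' 460 nt are discarded (the boundaries themselves are kept). For
#' functional-gene markers (window rule) reads within 20 nt of the expected
#' amplicon length are kept.
#'
#' @param records record data frame (\code{id}, \code{sequence},
#'   \code{library_id}, \code{count}).
#' @param spec a [marker_spec()] or a marker name.
#' @return the surviving records.
#' @export
length_filter <- function(records, spec) {
  records <- as_records(records)
  if (is.character(spec)) spec <- marker_spec(spec)
  len <- nchar(records$sequence)
  keep <- if (spec$length_rule == "absolute_bounds")
    len >= spec$bounds[1] & len <= spec$bounds[2]
  else
    abs(len - spec$expected_amplicon_length) <= spec$window
  records[keep, , drop = FALSE]
}

#' Remove sequences occurring only once across all libraries
#'
#' A unique sequence whose total count summed over every library is exactly
#' one is considered artefactual and removed. Singletons within an
#' individual library are kept whenever the same sequence occurs anywhere
#' else: once in library A and once in library B means kept in both.
#'
#' @param records record data frame with \code{library_id} set on every
#'   row.
#' @return the surviving records.
#' @export
global_singleton_filter <- function(records) {
  records <- as_records(records)
  if (nrow(records) == 0) return(records)
  total <- tapply(records$count, records$sequence, sum)
  records[total[records$sequence] >= 2, , drop = FALSE]
}

## Number of differences between two sequences: Hamming count over
## IUPAC-incompatible columns at equal length, alignment-based otherwise
## (gaps count as differences).
seq_ndiff <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    return(sum(!.iupac_compat[cbind(ca, cb)]))
  }
  al <- align_overlap(a, b)
  sum(!al$match) + al$overhang
}

## Overlap (ends-free global) alignment via Biostrings; returns per-column
## compatibility over the aligned region plus the total unaligned overhang.
align_overlap <- function(a, b) {
  syms <- names(IUPAC_SETS)
  subst <- matrix(-1, length(syms), length(syms),
                  dimnames = list(syms, syms))
  subst[.iupac_compat] <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "overlap",
    substitutionMatrix = subst, gapOpening = 0, gapExtension = 2)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gap <- pat == "-" | sub == "-"
  match <- !gap
  match[!gap] <- .iupac_compat[cbind(pat[!gap], sub[!gap])]
  used_a <- sum(pat != "-"); used_b <- sum(sub != "-")
  list(match = match,
       overhang = (nchar(a) - used_a) + (nchar(b) - used_b))
}

#' Pairwise nucleotide identity
#'
#' Fraction of identical aligned columns over the alignment length, from a
#' global alignment with terminal gaps excluded (ends-free). IUPAC
#' ambiguity codes (and inosine) match any compatible base. Equal-length
#' sequences are compared column-wise, which coincides with the optimal
#' ends-free alignment under the +1/-1/-2 match/mismatch/gap scoring used
#' here.
#'
#' @param a,b non-empty nucleotide strings.
#' @return identity as a fraction in \code{[0, 1]}.
#' @examples
#' pairwise_identity("ACGTACGTAC", "ACGTACGTCC")  # 0.9
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    return(mean(.iupac_compat[cbind(ca, cb)]))
  }
  al <- align_overlap(a, b)
  if (length(al$match) == 0) return(0)
  mean(al$match)
}

## Dereplicate records to unique sequences with per-library and total
## counts; order abundance-descending with lexicographic id tie-break so
## clustering is invariant to input order.
derep_records <- function(records) {
  key <- records$sequence
  total <- tapply(records$count, key, sum)
  first_id <- tapply(records$id, key, function(x) min(as.character(x)))
  seqs <- names(total)
  ord <- order(-as.numeric(total), as.character(first_id))
  list(sequence = seqs[ord], total = as.numeric(total)[ord],
       rep_id = as.character(first_id)[ord])
}

#' Merge near-identical sequences (preclustering)
#'
#' Greedy abundance-descending merge: each unique sequence within
#' \code{max_diff} substitutions of a more abundant representative is
#' absorbed into it, counts summed per library. Identical duplicates are
#' dereplicated as a side effect.
#'
#' @param records record data frame (ideally length-filtered).
#' @param max_diff maximum nucleotide differences to merge (default 2).
#' @return record data frame of representatives with merged per-library
#'   counts.
#' @export
precluster <- function(records, max_diff = 2) {
  records <- as_records(records)
  if (nrow(records) == 0) return(records)
  d <- derep_records(records)
  n <- length(d$sequence)
  assign_to <- integer(n)  # index of representative for each unique seq
  reps <- integer(0)
  for (i in seq_len(n)) {
    hit <- 0L
    for (r in reps) {
      if (seq_ndiff(d$sequence[i], d$sequence[r]) <= max_diff) {
        hit <- r; break
      }
    }
    if (hit == 0L) { reps <- c(reps, i); assign_to[i] <- i }
    else assign_to[i] <- hit
  }
  rep_seq_of <- d$sequence[assign_to[match(records$sequence, d$sequence)]]
  rep_id_of <- d$rep_id[assign_to[match(records$sequence, d$sequence)]]
  agg <- stats::aggregate(records$count,
                          by = list(sequence = rep_seq_of, id = rep_id_of,
                                    library_id = records$library_id),
                          FUN = sum)
  data.frame(id = agg$id, sequence = agg$sequence,
             library_id = agg$library_id, count = agg$x)
}

#' Greedy centroid OTU clustering at an identity cutoff
#'
#' Unique sequences are visited in order of decreasing total abundance
#' (ties broken lexicographically by record id); each joins the first
#' centroid it matches at \code{>= cutoff} percent identity, otherwise it
#' founds a new OTU. Per-library counts are aggregated per OTU. The
#' ordering makes membership invariant to input permutation.
#'
#' @param records record data frame (preprocessed reads).
#' @param cutoff identity cutoff in percent (98 for 16S, 90 for cmuA, 80
#'   for mdh by convention).
#' @return object of class \code{"otu_clustering"}: \code{counts} (OTU x
#'   library matrix), \code{representatives} (centroid sequences, named by
#'   OTU), \code{membership} (unique sequence -> OTU), \code{cutoff}.
#' @export
greedy_cluster <- function(records, cutoff) {
  records <- as_records(records)
  stopifnot(cutoff > 0, cutoff <= 100)
  if (nrow(records) == 0)
    return(structure(list(counts = matrix(integer(), 0, 0),
                          representatives = character(),
                          membership = character(), cutoff = cutoff),
                     class = "otu_clustering"))
  d <- derep_records(records)
  n <- length(d$sequence)
  otu_of <- integer(n); centroids <- integer(0)
  for (i in seq_len(n)) {
    hit <- 0L
    for (ci in seq_along(centroids)) {
      if (pairwise_identity(d$sequence[i],
                            d$sequence[centroids[ci]]) >= cutoff / 100) {
        hit <- ci; break
      }
    }
    if (hit == 0L) { centroids <- c(centroids, i); hit <- length(centroids) }
    otu_of[i] <- hit
  }
  otu_ids <- paste0("OTU", seq_along(centroids))
  libs <- sort(unique(records$library_id))
  counts <- matrix(0L, length(centroids), length(libs),
                   dimnames = list(otu_ids, libs))
  otu_of_rec <- otu_of[match(records$sequence, d$sequence)]
  for (j in seq_len(nrow(records)))
    counts[otu_of_rec[j], records$library_id[j]] <-
      counts[otu_of_rec[j], records$library_id[j]] + records$count[j]
  membership <- stats::setNames(otu_ids[otu_of], d$sequence)
  structure(list(counts = counts,
                 representatives = stats::setNames(d$sequence[centroids],
                                                   otu_ids),
                 membership = membership, cutoff = cutoff),
            class = "otu_clustering")
}

#' @export
print.otu_clustering <- function(x, ...) {
  cat(sprintf("OTU clustering at %g%% identity: %d OTUs, %d libraries, %d reads\n",
              x$cutoff, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Iterative cutoff selection by OTU-count stabilization
#'
#' Clusters the reads at each cutoff of a descending list and selects the
#' highest cutoff at which the OTU count has stabilized, i.e. the count
#' changes by at most \code{stability_delta} OTUs when moving to the next
#' lower cutoff. If the curve never stabilizes the lowest cutoff is
#' returned flagged \code{stabilized = FALSE}.
#'
#' @param records record data frame.
#' @param cutoffs identity cutoffs in percent; sorted descending
#'   internally; at least 3.
#' @param stability_delta tolerated OTU-count change per step (default 0).
#' @return list with \code{curve} (data frame cutoff / n_otus),
#'   \code{selected_cutoff} and \code{stabilized}.
#' @export
cutoff_scan <- function(records, cutoffs, stability_delta = 0) {
  stopifnot(length(cutoffs) >= 3)
  cutoffs <- sort(unique(cutoffs), decreasing = TRUE)
  n_otus <- vapply(cutoffs,
                   function(co) nrow(greedy_cluster(records, co)$counts),
                   integer(1))
  curve <- data.frame(cutoff = cutoffs, n_otus = n_otus)
  selected <- NA_real_; stabilized <- FALSE
  for (i in seq_len(length(cutoffs) - 1L)) {
    if (abs(n_otus[i] - n_otus[i + 1L]) <= stability_delta) {
      selected <- cutoffs[i]; stabilized <- TRUE; break
    }
  }
  if (!stabilized) selected <- cutoffs[length(cutoffs)]
  list(curve = curve, selected_cutoff = selected, stabilized = stabilized)
}

#' Count-weighted consensus sequence of a cluster
#'
#' Column-wise majority base over the members, weighted by member counts,
#' with members aligned to the centroid (insertions relative to the
#' centroid are dropped; a member's gap columns cast no vote). Ties
#' resolve to the centroid's base.
#'
#' @param sequences cluster member sequences; first element is the
#'   centroid unless \code{centroid} is given.
#' @param counts per-member counts (weights); default all 1.
#' @param centroid centroid sequence; defaults to the highest-count member.
#' @return consensus sequence string.
#' @export
consensus_sequence <- function(sequences, counts = rep(1, length(sequences)),
                               centroid = NULL) {
  stopifnot(length(sequences) >= 1, length(counts) == length(sequences))
  centroid <- centroid %||% sequences[[which.max(counts)]]
  L <- nchar(centroid)
  votes <- matrix(0, nrow = 4L + 1L, ncol = L,
                  dimnames = list(c("A", "C", "G", "T", "other"), NULL))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    if (nchar(s) == L) cols <- strsplit(s, "")[[1]]
    else {
      al <- align_to_centroid(s, centroid)
      cols <- al
    }
    for (p in seq_len(L)) {
      b <- cols[p]
      if (is.na(b) || b == "-") next
      row <- if (b %in% c("A", "C", "G", "T")) b else "other"
      votes[row, p] <- votes[row, p] + counts[i]
    }
  }
  cen <- strsplit(centroid, "")[[1]]
  out <- character(L)
  ## a clear majority wins; any tie resolves to the centroid base
  for (p in seq_len(L)) {
    v <- votes[c("A", "C", "G", "T"), p]
    if (all(v == 0)) { out[p] <- cen[p]; next }
    top <- names(v)[v == max(v)]
    out[p] <- if (length(top) == 1) top else cen[p]
  }
  paste(out, collapse = "")
}

## Map a member's bases onto centroid coordinates via overlap alignment;
## returns a character vector of length nchar(centroid) with NA where the
## member provides no base.
align_to_centroid <- function(member, centroid) {
  syms <- names(IUPAC_SETS)
  subst <- matrix(-1, length(syms), length(syms),
                  dimnames = list(syms, syms))
  subst[.iupac_compat] <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(member), Biostrings::BString(centroid),
    type = "overlap", substitutionMatrix = subst,
    gapOpening = 0, gapExtension = 2)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  L <- nchar(centroid)
  out <- rep(NA_character_, L)
  ## position of the aligned region within the centroid
  start <- Biostrings::start(Biostrings::subject(pa))
  cpos <- start - 1L
  for (k in seq_along(sub)) {
    if (sub[k] != "-") {
      cpos <- cpos + 1L
      if (pat[k] != "-") out[cpos] <- pat[k]
    }
  }
  out
}

#' Expand a degenerate primer into concrete sequences
#'
#' Cartesian expansion of IUPAC degeneracy codes (B, D, H, V, K, M, R, S,
#' W, Y, N); inosine (I) expands like N. The cardinality of the result is
#' the product of per-symbol degeneracies.
#'
#' @param primer IUPAC nucleotide string.
#' @return character vector of all concrete sequences.
#' @examples
#' expand_degenerate("RY")                 # AC, AT, GC, GT
#' length(expand_degenerate("CCTACGGGNGGCWGCAG"))  # 8
#' @export
expand_degenerate <- function(primer) {
  chars <- strsplit(toupper(primer), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad))
    stop("alphabet error: unknown symbol(s) ", paste(bad, collapse = ", "))
  sets <- IUPAC_SETS[chars]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  sort(out)
}

#' Read / write amplicon records as FASTA
#'
#' Library and count travel in the record description as
#' \code{key=value} pairs (\code{library_id=...;count=...}), so a FASTA
#' file round-trips to an identical record data frame.
#'
#' @param records record data frame.
#' @param path file path.
#' @return \code{write_fasta_records} returns \code{path} invisibly;
#'   \code{read_fasta_records} returns a record data frame.
#' @export
write_fasta_records <- function(records, path) {
  records <- as_records(records)
  seqs <- Biostrings::BStringSet(records$sequence)
  names(seqs) <- sprintf("%s library_id=%s;count=%d", records$id,
                         records$library_id, records$count)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' @rdname write_fasta_records
#' @export
read_fasta_records <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  hdr <- names(seqs)
  id <- sub(" .*$", "", hdr)
  lib <- sub(".*library_id=([^;]+).*", "\\1", hdr)
  cnt <- as.integer(sub(".*count=([0-9]+).*", "\\1", hdr))
  data.frame(id = id, sequence = as.character(seqs), library_id = lib,
             count = cnt, row.names = NULL)
}
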