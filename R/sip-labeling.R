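#' Thresholds for calling 13C-labeled OTUs
#'
#' All three thresholds are on the 0--100 percent scale. Defaults follow
#' the established SIP false-positive-minimizing protocol: a candidate OTU
#' must reach 0.5\% relative abundance in the heavy fraction of the
#' 13C treatment, exceed its light-fraction abundance by at least 0.3\%
#' (a margin absorbing per-OTU abundance variance), and carry at least 5\%
#' of the labeling proportion.
#'
#' @param min_heavy_abundance minimum relative abundance (\%) in the heavy
#'   fraction of the 13C treatment (criterion 3).
#' @param min_hl_difference minimum heavy-minus-light abundance difference
#'   (\%) (criterion 4).
#' @param min_labeling_proportion minimum labeling proportion (\%).
#' @return object of class \code{"labeling_thresholds"}.
#' @export
labeling_thresholds <- function(min_heavy_abundance = 0.5,
                                min_hl_difference = 0.3,
                                min_labeling_proportion = 5) {
  stopifnot(min_heavy_abundance >= 0, min_hl_difference >= 0,
            min_labeling_proportion >= 0)
  structure(list(min_heavy_abundance = min_heavy_abundance,
                 min_hl_difference = min_hl_difference,
                 min_labeling_proportion = min_labeling_proportion),
            class = "labeling_thresholds")
}

## Pool replicate libraries matching a (treatment, isotope, fraction) key
## and return per-OTU relative abundances in percent.
pooled_counts <- function(x, treatment, isotope, fraction) {
  sel <- x$libraries$treatment == treatment &
    x$libraries$isotope == isotope & x$libraries$fraction == fraction
  if (!any(sel))
    stop("incomplete design: no library for (treatment=", treatment,
         ", isotope=", isotope, ", fraction=", fraction, ")")
  cols <- x$libraries$library_id[sel]
  rowSums(x$counts[, cols, drop = FALSE])
}

#' Per-OTU relative abundance in one gradient-fraction library
#'
#' Replicate libraries with the same (treatment, isotope, fraction) key are
#' pooled by summing counts before dividing, mirroring the pooling of
#' duplicate microcosm gradient fractions. Abundances are in percent and
#' sum to 100 over OTUs.
#'
#' @param x a \code{sip_experiment} (see [gen_sip_otu_tables()] /
#'   [read_otu_table()]).
#' @param treatment,isotope,fraction library key: treatment name,
#'   \code{"12C"}/\code{"13C"}, \code{"H"}/\code{"L"}.
#' @return named numeric vector of percentages.
#' @export
relative_abundance <- function(x, treatment, isotope, fraction) {
  counts <- pooled_counts(x, treatment, isotope, fraction)
  total <- sum(counts)
  if (total == 0)
    stop("empty library: total count is zero for (", treatment, ", ",
         isotope, ", ", fraction, ")")
  100 * counts / total
}

#' Evaluate the four abundance criteria for 13C labeling
#'
#' Criterion 1: abundance in the heavy fraction of the 13C treatment
#' strictly higher than in the heavy fraction of the paired 12C control.
#' Criterion 2: strictly higher than in the 13C treatment's own light
#' fraction. Criterion 3: heavy-fraction abundance at least
#' \code{min_heavy_abundance}. Criterion 4: heavy-minus-light difference
#' at least \code{min_hl_difference}. Strict versus inclusive comparisons
#' follow the protocol's wording ("higher than" vs "at least").
#' Comparisons are made on exact proportions, never on rounded
#' percentages.
#'
#' @param relab_h13,relab_l13,relab_h12 per-OTU relative abundances (\%)
#'   in the heavy and light fractions of the 13C treatment and the heavy
#'   fraction of the 12C control (equal-length vectors).
#' @param thresholds a [labeling_thresholds()].
#' @return logical matrix with columns \code{c1..c4}.
#' @export
evaluate_criteria <- function(relab_h13, relab_l13, relab_h12,
                              thresholds = labeling_thresholds()) {
  stopifnot(length(relab_h13) == length(relab_l13),
            length(relab_h13) == length(relab_h12))
  cbind(c1 = relab_h13 > relab_h12,
        c2 = relab_h13 > relab_l13,
        c3 = relab_h13 >= thresholds$min_heavy_abundance,
        c4 = relab_h13 - relab_l13 >= thresholds$min_hl_difference)
}

#' Labeling proportion over a candidate set
#'
#' The labeling proportion (LP) of a candidate OTU is its relative
#' frequency among the labeled candidates of one heavy fraction:
#' \code{100 * relab_i / sum(relab_j over candidates)}. LP values sum to
#' 100 over the candidate set. With
#' \code{denominator = "library"} the whole-library abundance (already in
#' percent) is used directly instead.
#'
#' @param relab_h13 named per-OTU relative abundances (\%) in the heavy
#'   fraction of the 13C treatment.
#' @param candidates names of OTUs passing criteria 1--4.
#' @param denominator \code{"candidates"} (default) or \code{"library"}.
#' @return named LP vector over \code{candidates}; empty if no candidates.
#' @export
labeling_proportion <- function(relab_h13, candidates,
                                denominator = c("candidates", "library")) {
  denominator <- match.arg(denominator)
  if (length(candidates) == 0) return(stats::setNames(numeric(0),
                                                      character(0)))
  v <- relab_h13[candidates]
  if (denominator == "candidates") 100 * v / sum(v) else v
}

#' Call 13C-labeled OTUs from heavy/light fraction count tables
#'
#' The full caller: for every 13C treatment and its paired 12C control it
#' computes pooled relative abundances for the four fraction libraries,
#' evaluates the four abundance criteria per OTU, computes labeling
#' proportions over the candidate set, and calls an OTU labeled when all
#' four criteria hold and its labeling proportion reaches the threshold.
#' Every OTU x treatment combination is retained in the audit table,
#' called or not.
#'
#' @param x a \code{sip_experiment}: list with \code{counts} (OTU x
#'   library matrix), \code{libraries} (metadata data frame) and
#'   optionally \code{design}.
#' @param design data frame with columns \code{labeled} and
#'   \code{control} pairing each 13C treatment with its 12C control;
#'   defaults to \code{x$design}.
#' @param thresholds a [labeling_thresholds()].
#' @param lp_denominator passed to [labeling_proportion()].
#' @return object of class \code{"sip_labeling"} whose \code{audit}
#'   component has one row per OTU and treatment: the four abundances,
#'   criteria \code{c1..c4}, \code{labeling_proportion} (\code{NA} for
#'   non-candidates) and the final \code{labeled} call.
#' @examples
#' x <- gen_sip_otu_tables(truth = synthetic_truth(seed = 42))
#' res <- call_labeled(x)
#' labeled_otus(res)
#' @export
call_labeled <- function(x, design = NULL,
                         thresholds = labeling_thresholds(),
                         lp_denominator = c("candidates", "library")) {
  lp_denominator <- match.arg(lp_denominator)
  design <- design %||% x$design
  if (is.null(design))
    stop("incomplete design: no 13C/12C treatment pairing supplied")
  audits <- list()
  for (i in seq_len(nrow(design))) {
    tr <- design$labeled[i]; ctrl <- design$control[i]
    h13 <- relative_abundance(x, tr, "13C", "H")
    l13 <- relative_abundance(x, tr, "13C", "L")
    h12 <- relative_abundance(x, ctrl, "12C", "H")
    l12 <- relative_abundance(x, ctrl, "12C", "L")
    crit <- evaluate_criteria(h13, l13, h12, thresholds)
    candidates <- names(h13)[rowSums(crit) == 4L]
    lp_all <- rep(NA_real_, length(h13))
    names(lp_all) <- names(h13)
    lp <- labeling_proportion(h13, candidates, lp_denominator)
    lp_all[names(lp)] <- lp
    labeled <- rowSums(crit) == 4L & !is.na(lp_all) &
      lp_all >= thresholds$min_labeling_proportion
    audits[[i]] <- data.frame(
      otu_id = names(h13), treatment = tr, control = ctrl,
      relab_h13 = unname(h13), relab_l13 = unname(l13),
      relab_h12 = unname(h12), relab_l12 = unname(l12),
      c1 = unname(crit[, "c1"]), c2 = unname(crit[, "c2"]),
      c3 = unname(crit[, "c3"]), c4 = unname(crit[, "c4"]),
      labeling_proportion = unname(lp_all), labeled = unname(labeled))
  }
  structure(list(audit = do.call(rbind, c(audits, make.row.names = FALSE)),
                 thresholds = thresholds, design = design,
                 lp_denominator = lp_denominator),
            class = "sip_labeling")
}

#' @describeIn call_labeled labeled OTU ids, optionally for one treatment.
#' @param object a \code{sip_labeling} result.
#' @param treatment restrict to one 13C treatment.
#' @export
labeled_otus <- function(object, treatment = NULL) {
  a <- object$audit
  if (!is.null(treatment)) a <- a[a$treatment == treatment, ]
  sort(unique(a$otu_id[a$labeled]))
}

#' @export
print.sip_labeling <- function(x, ...) {
  n_lab <- sum(x$audit$labeled)
  cat(sprintf(
    "13C-labeling calls: %d labeled of %d OTU x treatment combinations\n",
    n_lab, nrow(x$audit)))
  cat(sprintf("  thresholds: heavy >= %g%%, H-L >= %g%%, LP >= %g%% (%s denominator)\n",
              x$thresholds$min_heavy_abundance,
              x$thresholds$min_hl_difference,
              x$thresholds$min_labeling_proportion, x$lp_denominator))
  invisible(x)
}

#' @export
summary.sip_labeling <- function(object, ...) {
  a <- object$audit
  print(object)
  for (tr in unique(a$treatment)) {
    sel <- a$treatment == tr & a$labeled
    cat(sprintf("  %s: %d labeled OTU(s)", tr, sum(sel)))
    if (any(sel)) {
      top <- a[sel, ][order(-a$labeling_proportion[sel]), ]
      cat(": ", paste(sprintf("%s (LP %.1f%%)", top$otu_id,
                              top$labeling_proportion), collapse = ", "))
    }
    cat("\n")
  }
  invisible(object)
}

#' @export
plot.sip_labeling <- function(x, treatment = NULL, ...) {
  a <- x$audit
  treatment <- treatment %||% a$treatment[1]
  a <- a[a$treatment == treatment & a$labeled, ]
  if (nrow(a) == 0) {
    graphics::plot.new(); graphics::title(main = "no labeled OTUs")
    return(invisible(x))
  }
  graphics::barplot(stats::setNames(a$labeling_proportion, a$otu_id),
                    ylab = "labeling proportion (%)", main = treatment, ...)
  invisible(x)
}

#' Aggregate labeling calls to family level
#'
#' Builds the display table behind stacked-bar composition figures:
#' heavy-fraction relative abundances aggregated by family, split into
#' labeled and unlabeled, per 13C treatment. Unlabeled OTUs below
#' \code{display_min} percent relative abundance are dropped from the
#' display (they remain in the audit table of the
#' [call_labeled()] result); labeled OTUs are always shown. OTUs missing
#' from the taxonomy map are reported as "unclassified".
#'
#' @param object a \code{sip_labeling} result.
#' @param taxonomy_map data frame with columns \code{otu_id},
#'   \code{family} and optionally \code{genus}.
#' @param display_min display floor (\%) for unlabeled OTUs.
#' @return data frame with columns \code{treatment}, \code{family},
#'   \code{labeled}, \code{relative_abundance}.
#' @export
summarize_by_taxon <- function(object, taxonomy_map, display_min = 0.5) {
  stopifnot(inherits(object, "sip_labeling"),
            all(c("otu_id", "family") %in% names(taxonomy_map)))
  a <- object$audit
  fam <- taxonomy_map$family[match(a$otu_id, taxonomy_map$otu_id)]
  fam[is.na(fam)] <- "unclassified"
  keep <- a$labeled | a$relab_h13 >= display_min
  d <- data.frame(treatment = a$treatment[keep], family = fam[keep],
                  labeled = a$labeled[keep], relab = a$relab_h13[keep])
  agg <- stats::aggregate(d$relab,
                          by = list(treatment = d$treatment,
                                    family = d$family, labeled = d$labeled),
                          FUN = sum)
  names(agg)[4] <- "relative_abundance"
  agg[order(agg$treatment, -agg$labeled, -agg$relative_abundance), ]
}
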