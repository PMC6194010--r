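#' Diversity summary of an OTU count vector or SIP experiment
#'
#' Observed richness (Sobs: OTUs with positive count), Shannon index
#' (natural log by default) and Simpson diversity expressed as the
#' effective number of phylotypes (inverse Simpson, \eqn{1/\sum p_i^2}),
#' a conservative effective-number measure. The Gini--Simpson variant
#' (\eqn{1 - \sum p_i^2}) is available behind \code{simpson = "gini"}.
#' Index computation is delegated to \pkg{vegan}.
#'
#' @param x numeric count vector (one library) or a \code{sip_experiment},
#'   in which case one summary row per library is returned.
#' @param base logarithm base for Shannon (default natural log).
#' @param simpson \code{"inverse"} (effective number, default) or
#'   \code{"gini"}.
#' @param ... unused.
#' @return data frame with columns \code{sobs}, \code{shannon},
#'   \code{simpson_effective} (or \code{simpson_gini}); for a
#'   \code{sip_experiment}, one row per library plus its metadata key.
#' @examples
#' diversity_summary(c(8, 2))
#' @export
diversity_summary <- function(x, base = exp(1),
                              simpson = c("inverse", "gini"), ...) {
  UseMethod("diversity_summary")
}

#' @export
diversity_summary.default <- function(x, base = exp(1),
                                      simpson = c("inverse", "gini"), ...) {
  simpson <- match.arg(simpson)
  x <- as.numeric(x)
  if (all(x == 0)) stop("empty library: all counts are zero")
  if (any(x < 0)) stop("counts must be non-negative")
  sobs <- sum(x > 0)
  shannon <- as.numeric(vegan::diversity(x, index = "shannon", base = base))
  simp <- as.numeric(vegan::diversity(
    x, index = if (simpson == "inverse") "invsimpson" else "simpson"))
  out <- data.frame(sobs = sobs, shannon = shannon)
  out[[if (simpson == "inverse") "simpson_effective" else "simpson_gini"]] <-
    simp
  out
}

#' @export
diversity_summary.sip_experiment <- function(x, base = exp(1),
                                             simpson = c("inverse", "gini"),
                                             ...) {
  rows <- lapply(seq_len(ncol(x$counts)), function(j)
    cbind(x$libraries[j, c("library_id", "treatment", "fraction")],
          diversity_summary(x$counts[, j], base = base, simpson = simpson)))
  do.call(rbind, c(rows, make.row.names = FALSE))
}
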