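#' Planted ground truth for a synthetic SIP dataset
#'
#' Every simulated dataset travels with the parameters that generated it,
#' so downstream stages can be scored on recovery: the true first-order
#' rate constant, the identities of the planted 13C-labeled OTUs, their
#' heavy-fraction enrichment factor, the true mineralized fraction, and the
#' master seed.
#'
#' @param true_k per-vessel first-order rate constant, 1/h, \code{>= 0}.
#' @param true_labeled_otus character vector of planted labeled OTU ids.
#' @param enrichment_factor multiplicative heavy-fraction enrichment of
#'   labeled OTUs in 13C treatments, \code{>= 1}.
#' @param true_mineralized_fraction fraction of added labeled carbon
#'   released as 13C-CO2, in \code{[0, 1]}.
#' @param seed master integer seed.
#' @return object of class \code{"synthetic_truth"}.
#' @export
synthetic_truth <- function(true_k = 2.35,
                            true_labeled_otus = c("OTU1", "OTU2", "OTU3"),
                            enrichment_factor = 10,
                            true_mineralized_fraction = 0.2,
                            seed = 1L) {
  stopifnot(true_k >= 0,
            enrichment_factor >= 1,
            true_mineralized_fraction >= 0, true_mineralized_fraction <= 1)
  structure(list(true_k = true_k,
                 true_labeled_otus = as.character(true_labeled_otus),
                 enrichment_factor = enrichment_factor,
                 true_mineralized_fraction = true_mineralized_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic truth: k = %g 1/h, %d labeled OTU(s) at enrichment %g, mineralized fraction %g, seed %d\n",
    x$true_k, length(x$true_labeled_otus), x$enrichment_factor,
    x$true_mineralized_fraction, x$seed))
  invisible(x)
}

#' Simulate a first-order decay gas series
#'
#' Values follow \eqn{c_0 e^{-kt}} perturbed by multiplicative lognormal
#' noise (a relative-error model for gas-chromatographic quantification:
#' it keeps values positive and leaves log-linear fitting unbiased in the
#' noise-free limit). \code{noise_sd = 0} gives the exact exponential.
#'
#' @param k rate constant, 1/h, \code{>= 0}.
#' @param c0 initial mixing ratio, \code{> 0}.
#' @param times sampling times in hours, strictly increasing, at least 3.
#' @param noise_sd standard deviation of the lognormal noise on the log
#'   scale (approximately the relative error), \code{>= 0}.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param ... passed to [gas_series()] (unit, vessel_id, treatment, ...).
#' @return a [gas_series()].
#' @examples
#' s <- gen_decay_series(k = 2.35, c0 = 200, times = seq(0, 2, by = 0.25))
#' fit_first_order(s)$k   # exactly 2.35 without noise
#' @export
gen_decay_series <- function(k, c0, times = seq(0, 2, length.out = 12),
                             noise_sd = 0, seed = NULL, ...) {
  stopifnot(k >= 0, c0 > 0, noise_sd >= 0)
  if (length(times) < 3L)
    stop("invalid design: need at least 3 sampling times")
  if (any(diff(times) <= 0))
    stop("invalid design: times must be strictly increasing")
  mu <- c0 * exp(-k * times)
  values <- if (noise_sd > 0)
    with_seed(seed, mu * stats::rlnorm(length(times), 0, noise_sd))
  else mu
  gas_series(times, values, ...)
}

#' Simulate pulse-wise cumulative CO2 and 13C-CO2 accumulation
#'
#' After each amendment pulse a fixed fraction of the carbon added so far
#' has been mineralized, so cumulative 13C-CO2 after pulse p equals
#' \code{mineralized_fraction} times the labeled carbon added through p.
#' Noise is applied multiplicatively to per-pulse increments, which keeps
#' the cumulative series monotone non-decreasing even when noisy.
#'
#' @param schedule a [pulse_schedule()].
#' @param mineralized_fraction fraction of added carbon mineralized, in
#'   \code{[0, 1]}; applied to both isotopologues.
#' @param noise_sd lognormal sd on per-pulse CO2 increments.
#' @param seed integer seed.
#' @return data frame with one row per pulse (plus a pulse-0 row of
#'   zeros): \code{pulse}, \code{added_labeled_mM}, \code{added_total_mM},
#'   \code{co2_13_mM}, \code{co2_total_mM}, all cumulative.
#' @examples
#' s <- amendment_schedules()[["13C-CH3Cl"]]
#' gen_pulsed_co2(s, mineralized_fraction = 10 / 54)  # 10 mM 13C-CO2 at pulse 3
#' @export
gen_pulsed_co2 <- function(schedule, mineralized_fraction, noise_sd = 0,
                           seed = NULL) {
  stopifnot(inherits(schedule, "pulse_schedule"),
            mineralized_fraction >= 0, mineralized_fraction <= 1,
            noise_sd >= 0)
  np <- schedule$n_pulses
  labeled_pp <- cumulative_carbon(schedule, 1, "13C")
  total_pp <- cumulative_carbon(schedule, 1, "both")
  inc13 <- rep(mineralized_fraction * labeled_pp, np)
  inctot <- rep(mineralized_fraction * total_pp, np)
  if (noise_sd > 0) {
    mult <- with_seed(seed, stats::rlnorm(2L * np, 0, noise_sd))
    inc13 <- inc13 * mult[seq_len(np)]
    inctot <- inctot * mult[np + seq_len(np)]
  }
  data.frame(pulse = 0:np,
             added_labeled_mM = labeled_pp * (0:np),
             added_total_mM = total_pp * (0:np),
             co2_13_mM = c(0, cumsum(inc13)),
             co2_total_mM = c(0, cumsum(inctot)))
}

#' Simulate heavy/light fraction OTU count tables with planted labeling
#'
#' Emulates the count-table structure of a DNA-SIP experiment: for every
#' 13C treatment, heavy (H) and light (L) fraction libraries plus the
#' paired 12C-control H and L libraries, in \code{n_replicates} duplicate
#' microcosms. Baseline relative abundances put each planted labeled OTU
#' at \code{base_abundance}; the remaining mass is split over the other
#' OTUs by a seeded lognormal rank-abundance draw. In the H fraction of a
#' 13C treatment the planted OTUs' proportions are multiplied by the
#' truth's \code{enrichment_factor} and renormalized; all other libraries
#' (L fractions, and both fractions of the 12C control) use the baseline.
#' Counts are drawn multinomially at the stated depth per library.
#'
#' @param n_otus total number of OTUs, at least the number planted.
#' @param depth reads per library, \code{> 0}.
#' @param truth a [synthetic_truth()]; its \code{true_labeled_otus} must be
#'   a subset of \code{OTU1..OTUn} and its \code{enrichment_factor >= 1}.
#' @param treatments data frame with columns \code{labeled} and
#'   \code{control} naming each 13C treatment and its paired 12C control.
#' @param n_replicates duplicate microcosms per treatment.
#' @param base_abundance baseline relative abundance of each planted OTU.
#' @param marker marker-gene label stored with each library.
#' @param seed integer seed; defaults to the truth's seed.
#' @return object of class \code{"sip_experiment"}: \code{counts} (OTU x
#'   library integer matrix), \code{libraries} (metadata with columns
#'   library_id, treatment, isotope, fraction, replicate, marker),
#'   \code{design} (the treatment pairing) and \code{truth}.
#' @seealso [call_labeled()], [read_otu_table()]
#' @export
gen_sip_otu_tables <- function(n_otus = 20, depth = 1e5,
                               truth = synthetic_truth(),
                               treatments = data.frame(
                                 labeled = "13C-CH3Cl",
                                 control = "12C-CH3Cl"),
                               n_replicates = 2, base_abundance = 0.05,
                               marker = "16S", seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), depth > 0,
            is.data.frame(treatments),
            all(c("labeled", "control") %in% names(treatments)))
  if (truth$enrichment_factor < 1)
    stop("invalid design: enrichment_factor must be >= 1")
  otu_ids <- paste0("OTU", seq_len(n_otus))
  if (!all(truth$true_labeled_otus %in% otu_ids))
    stop("invalid design: true_labeled_otus must be a subset of ",
         "OTU1..OTU", n_otus)
  n_lab <- length(truth$true_labeled_otus)
  if (n_lab * base_abundance >= 1)
    stop("invalid design: planted abundance mass must be < 1")
  seed <- seed %||% truth$seed
  with_seed(seed, {
    ## baseline community: planted OTUs at base_abundance each, the rest a
    ## lognormal rank-abundance profile over the remaining mass
    is_lab <- otu_ids %in% truth$true_labeled_otus
    w <- stats::rlnorm(n_otus - n_lab, 0, 1)
    base <- numeric(n_otus)
    base[is_lab] <- base_abundance
    base[!is_lab] <- (1 - n_lab * base_abundance) * w / sum(w)
    names(base) <- otu_ids
    heavy13 <- base
    heavy13[is_lab] <- heavy13[is_lab] * truth$enrichment_factor
    heavy13 <- heavy13 / sum(heavy13)

    libs <- list(); cols <- list()
    for (i in seq_len(nrow(treatments))) {
      for (rep_i in seq_len(n_replicates)) {
        spec <- list(
          list(treatments$labeled[i], "13C", "H", heavy13),
          list(treatments$labeled[i], "13C", "L", base),
          list(treatments$control[i], "12C", "H", base),
          list(treatments$control[i], "12C", "L", base))
        for (s in spec) {
          id <- sprintf("%s_%s_r%d", s[[1]], s[[3]], rep_i)
          libs[[id]] <- data.frame(library_id = id, treatment = s[[1]],
                                   isotope = s[[2]], fraction = s[[3]],
                                   replicate = rep_i, marker = marker)
          cols[[id]] <- as.integer(stats::rmultinom(1, depth, s[[4]]))
        }
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- otu_ids
    structure(list(counts = counts,
                   libraries = do.call(rbind, c(libs,
                                                make.row.names = FALSE)),
                   design = treatments, truth = truth),
              class = "sip_experiment")
  })
}

#' @export
print.sip_experiment <- function(x, ...) {
  cat(sprintf("SIP experiment: %d OTUs x %d libraries (%d treatment pair(s))\n",
              nrow(x$counts), ncol(x$counts), nrow(x$design)))
  if (!is.null(x$truth))
    cat(sprintf("  planted labeled OTUs: %s (enrichment %g)\n",
                paste(x$truth$true_labeled_otus, collapse = ", "),
                x$truth$enrichment_factor))
  invisible(x)
}

#' Simulate tagged amplicon reads from reference sequences
#'
#' Emits per-library reads at stated abundances from a set of reference
#' sequences, with optional per-read length jitter (random end-trimming or
#' random-base extension) and a known number of injected global singletons
#' — random sequences that occur exactly once across all libraries, the
#' artefact class the global-singleton filter removes.
#'
#' @param ref_seqs named character vector of reference sequences over
#'   \code{A,C,G,T}.
#' @param abundances integer matrix (references x libraries, dimnames
#'   required) or a named vector for a single library \code{"lib1"}.
#' @param length_jitter maximum nucleotides trimmed or appended per read
#'   (uniform over \code{-length_jitter..length_jitter}).
#' @param global_singleton_count number of one-off artefact sequences to
#'   inject (assigned to random libraries).
#' @param seed integer seed.
#' @return a record data frame with columns \code{id}, \code{sequence},
#'   \code{library_id}, \code{count} (all 1), suitable for the read
#'   filtering and clustering functions.
#' @seealso [length_filter()], [global_singleton_filter()],
#'   [greedy_cluster()]
#' @export
gen_amplicon_reads <- function(ref_seqs, abundances, length_jitter = 0,
                               global_singleton_count = 0, seed = NULL) {
  stopifnot(length(ref_seqs) > 0, all(nchar(ref_seqs) > 0))
  if (!all(grepl("^[ACGT]+$", ref_seqs)))
    stop("reference sequences must be over A,C,G,T")
  if (is.null(dim(abundances))) {
    abundances <- matrix(abundances, ncol = 1,
                         dimnames = list(names(abundances) %||%
                                           names(ref_seqs), "lib1"))
  }
  stopifnot(nrow(abundances) == length(ref_seqs))
  with_seed(seed, {
    rows <- list(); n <- 0L
    for (j in seq_len(ncol(abundances))) {
      lib <- colnames(abundances)[j]
      for (i in seq_len(nrow(abundances))) {
        cnt <- abundances[i, j]
        if (cnt <= 0) next
        for (r in seq_len(cnt)) {
          s <- ref_seqs[[i]]
          if (length_jitter > 0) {
            delta <- sample.int(2L * length_jitter + 1L, 1L) -
              length_jitter - 1L
            if (delta < 0) s <- substr(s, 1L, nchar(s) + delta)
            else if (delta > 0)
              s <- paste0(s, paste(sample(c("A", "C", "G", "T"), delta,
                                          replace = TRUE), collapse = ""))
          }
          n <- n + 1L
          rows[[n]] <- data.frame(id = sprintf("read%05d", n), sequence = s,
                                  library_id = lib, count = 1L)
        }
      }
    }
    if (global_singleton_count > 0) {
      len <- round(stats::median(nchar(ref_seqs)))
      for (g in seq_len(global_singleton_count)) {
        n <- n + 1L
        rows[[n]] <- data.frame(
          id = sprintf("artefact%03d", g),
          sequence = paste(sample(c("A", "C", "G", "T"), len,
                                  replace = TRUE), collapse = ""),
          library_id = sample(colnames(abundances), 1L), count = 1L)
      }
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
}
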