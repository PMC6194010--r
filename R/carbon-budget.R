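#' Pulse-amendment schedule for a microcosm treatment
#'
#' Describes how carbon substrate is added to one treatment: which
#' compounds, which isotopologue of each, how much carbon per pulse (mM in
#' the soil slurry), how many pulses and over how many days.
#'
#' @param treatment_name label for the treatment.
#' @param substrates data frame with columns \code{compound} (one of
#'   \code{"CH3Cl"}, \code{"CH3OH"}), \code{isotope} (\code{"12C"} or
#'   \code{"13C"}) and \code{carbon_per_pulse} (mM, \code{> 0}). May have
#'   zero rows for an unamended control.
#' @param n_pulses number of substrate pulses.
#' @param period_days incubation period covered by the pulses.
#' @return object of class \code{"pulse_schedule"}.
#' @seealso [amendment_schedules()] for the standard eight-treatment design.
#' @export
pulse_schedule <- function(treatment_name, substrates, n_pulses = 5,
                           period_days = 23) {
  stopifnot(is.data.frame(substrates),
            all(c("compound", "isotope", "carbon_per_pulse") %in%
                names(substrates)))
  if (nrow(substrates) > 0) {
    if (!all(substrates$compound %in% c("CH3Cl", "CH3OH")))
      stop("unknown compound in schedule")
    if (!all(substrates$isotope %in% c("12C", "13C")))
      stop("isotope must be '12C' or '13C'")
    if (any(substrates$carbon_per_pulse <= 0))
      stop("carbon_per_pulse must be > 0")
  }
  stopifnot(n_pulses >= 0, period_days > 0)
  structure(list(treatment_name = treatment_name, substrates = substrates,
                 n_pulses = as.integer(n_pulses),
                 period_days = period_days),
            class = "pulse_schedule")
}

#' @export
print.pulse_schedule <- function(x, ...) {
  tot <- if (nrow(x$substrates)) sum(x$substrates$carbon_per_pulse) else 0
  cat(sprintf("Pulse schedule '%s': %g mM C per pulse, %d pulses / %g days\n",
              x$treatment_name, tot, x$n_pulses, x$period_days))
  if (nrow(x$substrates)) print(x$substrates, row.names = FALSE)
  invisible(x)
}

#' The standard eight-treatment amendment design
#'
#' The SIP experiment uses eight duplicate microcosm treatments: four with a
#' 13C-labeled substrate (13C-CH3Cl alone, 13C-CH3Cl plus unlabeled CH3OH,
#' unlabeled CH3Cl plus 13C-CH3OH, 13C-CH3OH alone) and four unlabeled
#' controls mirroring them, plus an unamended control. Single-substrate
#' treatments add 18 mM carbon per pulse and dual-substrate treatments
#' 36 mM (18 + 18), in 5 pulses over 23 days. Amendment volumes (6 mL
#' CH3Cl gas per pulse, 56 mL total gas phase, 1 mL of 216 mM CH3OH stock)
#' are attached as metadata.
#'
#' @return named list of [pulse_schedule()] objects.
#' @export
amendment_schedules <- function() {
  sub <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(compound = m[, 1], isotope = m[, 2],
               carbon_per_pulse = as.numeric(m[, 3]))
  }
  none <- data.frame(compound = character(), isotope = character(),
                     carbon_per_pulse = numeric())
  sched <- list(
    "13C-CH3Cl"         = sub("CH3Cl", "13C", 18),
    "13C-CH3Cl+CH3OH"   = sub("CH3Cl", "13C", 18, "CH3OH", "12C", 18),
    "CH3Cl+13C-CH3OH"   = sub("CH3Cl", "12C", 18, "CH3OH", "13C", 18),
    "13C-CH3OH"         = sub("CH3OH", "13C", 18),
    "12C-CH3Cl"         = sub("CH3Cl", "12C", 18),
    "12C-CH3Cl+CH3OH"   = sub("CH3Cl", "12C", 18, "CH3OH", "12C", 18),
    "12C-CH3OH"         = sub("CH3OH", "12C", 18),
    "unamended"         = none)
  out <- lapply(names(sched), function(nm)
    pulse_schedule(nm, sched[[nm]], n_pulses = 5, period_days = 23))
  names(out) <- names(sched)
  attr(out, "amendment_volumes") <-
    list(ch3cl_gas_mL = 6, gas_phase_mL = 56, ch3oh_stock_mL = 1,
         ch3oh_stock_mM = 216)
  out
}

#' Cumulative carbon added through a given pulse
#'
#' @param schedule a [pulse_schedule()].
#' @param through_pulse pulse index, \code{0 <= through_pulse <= n_pulses};
#'   e.g. DNA harvested after the third pulse has seen
#'   \code{through_pulse = 3}.
#' @param isotope \code{"both"} (default), \code{"13C"} or \code{"12C"}:
#'   restrict the sum to one isotopologue.
#' @return carbon in mM.
#' @examples
#' s <- amendment_schedules()[["13C-CH3Cl"]]
#' cumulative_carbon(s, 3, "13C")   # 54 mM at DNA harvest
#' @export
cumulative_carbon <- function(schedule, through_pulse,
                              isotope = c("both", "13C", "12C")) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  isotope <- match.arg(isotope)
  if (through_pulse < 0 || through_pulse > schedule$n_pulses)
    stop("range error: through_pulse must be in [0, ", schedule$n_pulses, "]")
  s <- schedule$substrates
  if (isotope != "both") s <- s[s$isotope == isotope, , drop = FALSE]
  per_pulse <- if (nrow(s)) sum(s$carbon_per_pulse) else 0
  per_pulse * through_pulse
}

#' Partition labeled carbon into mineralized and assimilated fractions
#'
#' Carbon from a 13C-labeled substrate either leaves the microcosm as
#' 13C-CO2 (mineralized) or stays in biomass (assimilated, computed as the
#' complement). With an optional undetected-loss term (e.g. carbonate
#' precipitation) the assimilated percentage becomes an upper bound and is
#' reported as such.
#'
#' @param co2_13 cumulative 13C-CO2 formed, mM carbon.
#' @param added_labeled labeled carbon added, mM; must be \code{> 0} and
#'   \code{>= co2_13}.
#' @param rounding \code{"none"} (default) or \code{"nearest_10"} for
#'   headline percentages; values are never rounded internally.
#' @param loss_mM optional undetected loss (mM) subtracted from the
#'   assimilated pool.
#' @return object of class \code{"carbon_budget"} with
#'   \code{mineralized_pct} and \code{assimilated_pct} summing to 100
#'   (before any loss term).
#' @examples
#' carbon_budget(10, 54, rounding = "nearest_10")  # 20% mineralized, 80% assimilated
#' @export
carbon_budget <- function(co2_13, added_labeled,
                          rounding = c("none", "nearest_10"),
                          loss_mM = NULL) {
  rounding <- match.arg(rounding)
  stopifnot(added_labeled > 0, co2_13 >= 0)
  if (co2_13 > added_labeled)
    stop("mass-balance violation: 13C-CO2 (", co2_13,
         " mM) exceeds added labeled carbon (", added_labeled, " mM)")
  mineralized <- 100 * co2_13 / added_labeled
  if (rounding == "nearest_10") mineralized <- 10 * round(mineralized / 10)
  assimilated <- 100 - mineralized
  upper_bound <- FALSE
  if (!is.null(loss_mM)) {
    assimilated <- assimilated - 100 * loss_mM / added_labeled
    upper_bound <- TRUE
  }
  structure(list(added_labeled = added_labeled, co2_13 = co2_13,
                 mineralized_pct = mineralized, assimilated_pct = assimilated,
                 assimilated_is_upper_bound = !upper_bound,
                 rounding_rule = rounding),
            class = "carbon_budget")
}

#' @export
print.carbon_budget <- function(x, ...) {
  cat(sprintf(
    "Carbon budget: %g of %g mM labeled C mineralized (%g%%), %g%% assimilated%s\n",
    x$co2_13, x$added_labeled, x$mineralized_pct, x$assimilated_pct,
    if (!x$assimilated_is_upper_bound) " (upper bound after losses)" else ""))
  invisible(x)
}

#' @describeIn carbon_budget return just the mineralized percentage.
#' @export
mineralized_percent <- function(co2_13, added_labeled,
                                rounding = c("none", "nearest_10")) {
  carbon_budget(co2_13, added_labeled, rounding)$mineralized_pct
}

#' CO2 production rate normalized to soil dry mass
#'
#' OLS slope of a cumulative CO2 series against time, divided by dry mass.
#' A cumulative series that decreases by more than \code{tol} times its
#' range triggers a data warning (cumulative production cannot fall).
#'
#' @param time_days sampling times in days.
#' @param co2_mmol cumulative CO2 in mmol.
#' @param dry_mass_g soil dry mass in g, \code{> 0}.
#' @param tol tolerated relative dip before warning.
#' @return rate in mmol per g dry soil per day.
#' @export
co2_production_rate <- function(time_days, co2_mmol, dry_mass_g, tol = 0.02) {
  stopifnot(dry_mass_g > 0, length(time_days) >= 2,
            length(time_days) == length(co2_mmol))
  rng <- diff(range(co2_mmol))
  if (rng > 0 && any(diff(co2_mmol) < -tol * rng))
    warning("cumulative CO2 series decreases beyond noise tolerance")
  slope <- unname(stats::coef(stats::lm(co2_mmol ~ time_days))[2L])
  slope / dry_mass_g
}

#' Gravimetric water content
#'
#' @param wet_mass,dry_mass masses in g, \code{wet_mass >= dry_mass > 0}.
#' @param basis \code{"dry"} (soil-science convention, default):
#'   \code{(wet - dry)/dry}; or \code{"wet"}: \code{(wet - dry)/wet}.
#' @return water content as a fraction.
#' @export
water_content <- function(wet_mass, dry_mass, basis = c("dry", "wet")) {
  basis <- match.arg(basis)
  stopifnot(dry_mass > 0)
  if (wet_mass < dry_mass)
    stop("input error: wet mass below dry mass")
  if (basis == "dry") (wet_mass - dry_mass) / dry_mass
  else (wet_mass - dry_mass) / wet_mass
}
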