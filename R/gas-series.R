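#' Headspace gas time series
#'
#' Container for a timestamped series of headspace mixing ratios (or
#' dissolved concentrations) measured on one vessel — a closed chamber,
#' serum-bottle microcosm or incubation flask. Times must be strictly
#' increasing and values non-negative; the unit applies to the whole series.
#'
#' @param time_h numeric vector of sampling times in hours, strictly
#'   increasing.
#' @param value numeric vector of mixing ratios or concentrations, same
#'   length as \code{time_h}, all \code{>= 0}.
#' @param unit single string, e.g. \code{"ppb"}, \code{"ppm"} or
#'   \code{"mM"}.
#' @param vessel_id identifier of the measured vessel.
#' @param compartment one of \code{"leaf_litter"}, \code{"Of"}, \code{"Ah"},
#'   \code{"B"}, \code{"fresh_leaves"}, \code{"chamber"}, \code{"microcosm"},
#'   or \code{NA}.
#' @param treatment one of \code{"substrate"}, \code{"substrate_plus_KCN"},
#'   \code{"anoxic"}, \code{"unamended"}.
#' @param detection_limit instrument floor in the same unit as
#'   \code{value}; points at or below it are excluded from kinetic fits.
#' @return a data frame of class \code{"gas_series"} with columns
#'   \code{time_h} and \code{value} and the remaining fields as attributes.
#' @seealso [fit_first_order()], [gen_decay_series()]
#' @export
gas_series <- function(time_h, value, unit = "ppm", vessel_id = "vessel1",
                       compartment = NA_character_,
                       treatment = c("substrate", "substrate_plus_KCN",
                                     "anoxic", "unamended"),
                       detection_limit = 0) {
  treatment <- match.arg(treatment)
  compartments <- c("leaf_litter", "Of", "Ah", "B", "fresh_leaves",
                    "chamber", "microcosm")
  if (!is.na(compartment) && !compartment %in% compartments)
    stop("unknown compartment: ", compartment)
  time_h <- as.numeric(time_h); value <- as.numeric(value)
  if (length(time_h) != length(value))
    stop("time_h and value must have equal length")
  if (any(diff(time_h) <= 0))
    stop("times must be strictly increasing")
  if (any(value < 0)) stop("values must be non-negative")
  if (length(unit) != 1L) stop("unit must be a single string")
  out <- data.frame(time_h = time_h, value = value)
  structure(out,
            unit = unit, vessel_id = vessel_id, compartment = compartment,
            treatment = treatment, detection_limit = detection_limit,
            class = c("gas_series", "data.frame"))
}

#' @export
print.gas_series <- function(x, ...) {
  cat(sprintf("Gas time series '%s' (%s, %s): %d points, %s\n",
              attr(x, "vessel_id"),
              ifelse(is.na(attr(x, "compartment")), "?",
                     attr(x, "compartment")),
              attr(x, "treatment"), nrow(x), attr(x, "unit")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write / read a gas series as CSV
#'
#' The on-disk layout has columns \code{time_h}, \code{value}, \code{unit},
#' \code{vessel_id}; series metadata travels in the unit/vessel columns so a
#' file round-trips to an identical object.
#'
#' @param x a \code{gas_series}.
#' @param path file path.
#' @return \code{write_gas_series} returns \code{path} invisibly;
#'   \code{read_gas_series} returns a \code{gas_series}.
#' @export
write_gas_series <- function(x, path) {
  stopifnot(inherits(x, "gas_series"))
  df <- data.frame(time_h = x$time_h, value = x$value,
                   unit = attr(x, "unit"), vessel_id = attr(x, "vessel_id"),
                   compartment = attr(x, "compartment"),
                   treatment = attr(x, "treatment"),
                   detection_limit = attr(x, "detection_limit"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gas_series
#' @export
read_gas_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  gas_series(df$time_h, df$value, unit = df$unit[1],
             vessel_id = df$vessel_id[1],
             compartment = if ("compartment" %in% names(df))
               df$compartment[1] else NA_character_,
             treatment = if ("treatment" %in% names(df))
               df$treatment[1] else "substrate",
             detection_limit = if ("detection_limit" %in% names(df))
               df$detection_limit[1] else 0)
}
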