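#' Fit a first-order consumption rate constant to a gas series
#'
#' Headspace dissipation of a trace gas consumed by first-order kinetics
#' follows \eqn{c(t) = c_0 e^{-kt}}, so \eqn{\ln c} is linear in time with
#' slope \eqn{-k}. The fit is ordinary least squares of \code{log(value)} on
#' \code{time_h} over the points strictly above the detection limit; the
#' rate constant is the negated slope and \eqn{\hat c_0 = e^{intercept}}.
#' Points at or below the detection limit are excluded rather than imputed,
#' avoiding censoring bias from the instrument floor.
#'
#' @param series a [gas_series()].
#' @param detection_limit overrides the series' own detection limit.
#' @return an object of class \code{"kinfit"} with components \code{k}
#'   (h^-1), \code{c0_hat}, \code{r_squared}, \code{n_points_used},
#'   \code{half_life} (h; \code{NA} and flagged when \eqn{k \le 0}), and
#'   \code{degenerate} (\code{TRUE} when the series carries no variance in
#'   \code{log(value)}, e.g. a constant series, in which case
#'   \code{r_squared} is \code{NA}).
#' @examples
#' s <- gas_series(0:3, c(100, 50, 25, 12.5), unit = "ppm")
#' fit <- fit_first_order(s)
#' coef(fit)        # k is log(2): the value halves every hour
#' summary(fit)
#' @seealso [classify_sink()], [gen_decay_series()]
#' @export
fit_first_order <- function(series, detection_limit = NULL) {
  stopifnot(inherits(series, "gas_series"))
  dl <- detection_limit %||% attr(series, "detection_limit")
  keep <- series$value > dl
  t <- series$time_h[keep]; v <- series$value[keep]
  if (length(t) < 3L)
    stop("insufficient data: need >= 3 points above the detection limit, got ",
         length(t))
  if (any(v <= 0))
    stop("data error: non-positive value above the detection limit")
  fit <- stats::lm(log(v) ~ t)
  k <- -unname(stats::coef(fit)[2L])
  c0_hat <- exp(unname(stats::coef(fit)[1L]))
  tss <- sum((log(v) - mean(log(v)))^2)
  degenerate <- tss < .Machine$double.eps * length(v)
  if (degenerate) k <- 0
  r2 <- if (degenerate) NA_real_
  else max(0, min(1, 1 - sum(stats::residuals(fit)^2) / tss))
  structure(list(k = k, c0_hat = c0_hat, r_squared = r2,
                 n_points_used = length(t),
                 half_life = if (k > 0) log(2) / k else NA_real_,
                 degenerate = degenerate,
                 vessel_id = attr(series, "vessel_id"),
                 compartment = attr(series, "compartment"),
                 treatment = attr(series, "treatment"),
                 unit = attr(series, "unit"),
                 lm_fit = fit, time_h = t, value = v),
            class = "kinfit")
}

#' @export
print.kinfit <- function(x, ...) {
  cat(sprintf("First-order fit (%s, %s): k = %.4g 1/h", x$vessel_id,
              x$treatment, x$k))
  if (!is.na(x$half_life)) cat(sprintf(", half-life = %.3g h", x$half_life))
  cat("\n")
  invisible(x)
}

#' @export
summary.kinfit <- function(object, ...) {
  cat("First-order consumption kinetics\n")
  cat(sprintf("  vessel: %s  compartment: %s  treatment: %s\n",
              object$vessel_id,
              ifelse(is.na(object$compartment), "?", object$compartment),
              object$treatment))
  cat(sprintf("  k       = %.6g 1/h\n", object$k))
  cat(sprintf("  c0_hat  = %.6g %s\n", object$c0_hat, object$unit))
  cat(sprintf("  r^2     = %s\n",
              if (is.na(object$r_squared)) "degenerate (constant series)"
              else sprintf("%.4f", object$r_squared)))
  cat(sprintf("  points  = %d\n", object$n_points_used))
  if (!is.na(object$half_life))
    cat(sprintf("  t(1/2)  = %.4g h\n", object$half_life))
  invisible(object)
}

#' @export
coef.kinfit <- function(object, ...) c(k = object$k, c0_hat = object$c0_hat)

#' @export
predict.kinfit <- function(object, time_h = object$time_h, ...) {
  object$c0_hat * exp(-object$k * time_h)
}

#' @export
residuals.kinfit <- function(object, ...) {
  log(object$value) - log(predict(object, object$time_h))
}

#' @export
plot.kinfit <- function(x, ...) {
  graphics::plot(x$time_h, x$value, log = "y", xlab = "time (h)",
                 ylab = sprintf("mixing ratio (%s)", x$unit),
                 main = sprintf("%s: k = %.3g 1/h", x$vessel_id, x$k), ...)
  tt <- seq(min(x$time_h), max(x$time_h), length.out = 100)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Classify sink activity against killed and anoxic controls
#'
#' Decides whether observed substrate dissipation is biological. The call
#' is \emph{biotic} when the substrate-amended rate constant exceeds both a
#' minimum rate and \code{ratio_threshold} times the cyanide-killed control
#' rate; \emph{abiotic} when consumption persists in the killed control; and
#' \emph{none} otherwise. The anoxic control, when given, can veto a biotic
#' call attributed to aerobes only in the sense that its rate is reported
#' alongside; it does not enter the rule.
#'
#' @param fit_substrate,fit_kcn [fit_first_order()] fits from matched
#'   vessels: substrate-amended and KCN-killed (biological process control).
#' @param fit_anoxic optional fit from the anoxic control.
#' @param ratio_threshold substrate rate must exceed this multiple of the
#'   killed-control rate to be called biotic.
#' @param k_min minimum rate constant (1/h) regarded as real consumption.
#' @return list with \code{verdict} (\code{"biotic"}, \code{"abiotic"} or
#'   \code{"none"}) and the rates entering the decision.
#' @export
classify_sink <- function(fit_substrate, fit_kcn, fit_anoxic = NULL,
                          ratio_threshold = 3, k_min = 0.05) {
  stopifnot(inherits(fit_substrate, "kinfit"), inherits(fit_kcn, "kinfit"))
  comp_s <- fit_substrate$compartment; comp_k <- fit_kcn$compartment
  if (!is.na(comp_s) && !is.na(comp_k) && comp_s != comp_k)
    stop("pairing error: fits are from different compartments (",
         comp_s, " vs ", comp_k, ")")
  ks <- fit_substrate$k; kk <- max(fit_kcn$k, 0)
  verdict <-
    if (ks >= k_min && ks > ratio_threshold * kk) "biotic"
    else if (kk >= k_min) "abiotic"
    else "none"
  list(verdict = verdict, k_substrate = ks, k_kcn = fit_kcn$k,
       k_anoxic = if (!is.null(fit_anoxic)) fit_anoxic$k else NA_real_,
       ratio_threshold = ratio_threshold, k_min = k_min)
}

#' Net trace-gas flux from a closed-chamber series
#'
#' Summarizes a closed-chamber headspace series as net consumption (a
#' spiked chamber whose mixing ratio declines), net emission (an unspiked
#' chamber rising above the emission floor), "no net emission" (an unspiked
#' chamber that stays entirely below the floor), or neither. Decline/rise
#' is judged on the OLS slope relative to the series mean, with tolerance
#' \code{slope_tol} (1/h).
#'
#' @param series a [gas_series()]; \code{treatment = "substrate"} marks a
#'   spiked chamber, \code{"unamended"} an unspiked one.
#' @param control_series optional paired series; only checked for unit
#'   consistency.
#' @param emission_floor mixing ratio below which an unspiked chamber is
#'   considered emission-free (default 1, i.e. 1 ppb for a ppb series).
#' @param slope_tol relative slope (1/h) below which the series counts as
#'   flat.
#' @return list with \code{verdict} one of \code{"consumption"},
#'   \code{"emission"}, \code{"no net emission"}, \code{"neither"}, plus the
#'   absolute and relative slope.
#' @export
chamber_net_flux <- function(series, control_series = NULL,
                             emission_floor = 1, slope_tol = 1e-3) {
  stopifnot(inherits(series, "gas_series"))
  if (!is.null(control_series)) {
    stopifnot(inherits(control_series, "gas_series"))
    if (attr(series, "unit") != attr(control_series, "unit"))
      stop("unit error: series in ", attr(series, "unit"),
           " but control in ", attr(control_series, "unit"))
  }
  spiked <- attr(series, "treatment") != "unamended"
  slope <- unname(stats::coef(stats::lm(series$value ~ series$time_h))[2L])
  rel <- if (mean(series$value) > 0) slope / mean(series$value) else 0
  verdict <-
    if (!spiked && all(series$value < emission_floor)) "no net emission"
    else if (spiked && rel < -slope_tol) "consumption"
    else if (!spiked && rel > slope_tol) "emission"
    else "neither"
  list(verdict = verdict, slope = slope, relative_slope = rel,
       unit_per_h = sprintf("%s/h", attr(series, "unit")))
}
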