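## Null-point calibration of basal free cAMP and intracellular pH, and
## conversions between ratio, occupancy and free ligand concentration.

#' Null-point experiment container
#'
#' An intact-cell baseline ratio plus a post-permeabilization titration:
#' the basal free concentration is the external concentration at which
#' permeabilization produces no ratio change.
#'
#' @param r_basal Intact-cell baseline ratio.
#' @param concentration Added analyte values, strictly increasing: cAMP in
#'   nM, or pH units for a pH titration.
#' @param ratio Measured ratio at each titration point (>= 3 points).
#' @param analyte `"cAMP"` or `"pH"`.
#' @return A `nullpoint_experiment` object.
#' @export
nullpoint_experiment <- function(r_basal, concentration, ratio,
                                 analyte = c("cAMP", "pH")) {
  analyte <- match.arg(analyte)
  if (length(concentration) != length(ratio))
    stop_domain("concentration and ratio must have equal length")
  if (length(concentration) < 3) stop_domain("need >= 3 titration points")
  if (any(diff(concentration) <= 0))
    stop_domain("titration values must be strictly increasing")
  structure(list(r_basal = r_basal,
                 titration = data.frame(concentration = concentration,
                                        ratio = ratio),
                 analyte = analyte),
            class = "nullpoint_experiment")
}

#' Null-point calibration by linear regression
#'
#' Regresses the titration ratios on concentration by ordinary least
#' squares and solves `regression(c) = R_basal` for the null point. The
#' underlying ratio-concentration relation is an occupancy isotherm, so
#' the regression is only locally linear: `range` restricts the fit to the
#' titration points whose concentrations fall inside it (use a sub-range
#' bracketing the expected crossing; the full titration is used when
#' `range` is `NULL`).
#'
#' @param exp A [nullpoint_experiment()].
#' @param range Optional length-2 concentration interval selecting the
#'   points entering the regression (>= 2 points required).
#' @return A `nullpoint_cal` fit object with `c_basal` (nM, or pH units
#'   for a pH analyte), regression `slope`, `intercept`, `r_squared`, and
#'   logical `extrapolated` set when the crossing lies outside the
#'   regressed titration span.
#' @export
nullpoint_calibrate <- function(exp, range = NULL) {
  stopifnot(inherits(exp, "nullpoint_experiment"))
  tt <- exp$titration
  if (!is.null(range)) {
    keep <- tt$concentration >= range[1] & tt$concentration <= range[2]
    if (sum(keep) < 2)
      stop_domain("regression range must contain >= 2 titration points")
    tt <- tt[keep, ]
  }
  if (diff(range(tt$ratio)) == 0)
    stop_domain("titration ratios are all equal; no regression possible")
  fit <- lm(ratio ~ concentration, data = tt)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope == 0)
    stop_domain("zero regression slope: the titration never crosses R_basal")
  c_basal <- (exp$r_basal - intercept) / slope
  extrap <- c_basal < min(tt$concentration) || c_basal > max(tt$concentration)
  if (extrap)
    warning("null point lies outside the regressed titration range ",
            "(extrapolation)")
  ## suppressed: lm warns on exactly collinear (noise-free) titrations
  r2 <- suppressWarnings(summary(fit)$r.squared)
  new_fq_fit("nullpoint_cal",
             estimate = list(c_basal = c_basal, slope = slope,
                             intercept = intercept),
             rss = sum(residuals(fit)^2),
             r_squared = r2, extrapolated = extrap, analyte = exp$analyte,
             converged = TRUE, regressed = tt, r_basal = exp$r_basal)
}

#' Intracellular pH by the null-point method
#'
#' Same regression machinery as [nullpoint_calibrate()] applied to a pH
#' buffer titration of permeabilized cells; the crossing with the
#' intact-cell ratio is the intracellular pH.
#'
#' @inheritParams nullpoint_calibrate
#' @return A `nullpoint_cal` object whose `c_basal` slot is the pH_i.
#' @export
pH_nullpoint <- function(exp, range = NULL) {
  if (exp$analyte != "pH") stop_domain("experiment analyte must be 'pH'")
  nullpoint_calibrate(exp, range = range)
}

#' Free ligand concentration from sensor occupancy
#'
#' Inverts the depletion-free isotherm:
#' \eqn{c_{free} = K_D\,\theta / (1 - \theta)}. Used to convert a
#' calibrated occupancy at the null point into a basal free concentration.
#'
#' @param theta Occupancy fraction in `[0, 1)`.
#' @param kd_nM Dissociation constant, nM.
#' @return Free ligand concentration, nM.
#' @export
free_from_occupancy <- function(theta, kd_nM) {
  if (any(theta < 0) || any(theta >= 1))
    stop_domain("theta must be in [0, 1)")
  kd_nM * theta / (1 - theta)
}

#' @export
print.nullpoint_cal <- function(x, ...) {
  lab <- if (x$analyte == "pH") "pH_i" else "basal free concentration (nM)"
  cat("<nullpoint_cal>\n")
  cat(sprintf("  %s: %.4g\n", lab, x$estimate$c_basal))
  cat(sprintf("  regression slope %.4g, intercept %.4g, R^2 %.4f\n",
              x$estimate$slope, x$estimate$intercept, x$r_squared))
  if (isTRUE(x$extrapolated)) cat("  WARNING: extrapolated beyond titration\n")
  invisible(x)
}
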