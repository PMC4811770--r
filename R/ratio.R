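## Ratiometric FRET processing: bleed-through-corrected ratio, baseline
## normalization, drift correction, spectra metrics, acceptor-photobleaching
## quantification.

#' Bleed-through-corrected FRET ratio
#'
#' Computes the donor/acceptor emission ratio corrected for acceptor
#' bleed-through, exactly as used for the dual-emission readout:
#' \deqn{R = (donor - \beta \cdot acceptor) / acceptor.}
#' Samples with non-positive acceptor signal are returned as `NA` (masked,
#' not dropped) with a warning.
#'
#' @param donor Donor-channel (cerulean) intensities, a.u.
#' @param acceptor Acceptor-channel (citrine) intensities, a.u.
#' @param beta Bleed-through coefficient in `[0, 1)`; 0.69 for the
#'   dual-view imaging channels, 0 for spectrofluorometer ratios.
#' @return Ratio values, same length as the inputs.
#' @export
fret_ratio <- function(donor, acceptor, beta = 0.69) {
  if (beta < 0 || beta >= 1) stop_domain("beta must be in [0, 1)")
  if (length(donor) != length(acceptor))
    stop_domain("donor and acceptor must have equal length")
  bad <- !is.na(acceptor) & acceptor <= 0
  r <- (donor - beta * acceptor) / acceptor
  if (any(bad)) {
    r[bad] <- NA_real_
    warning(sum(bad), " sample(s) with non-positive acceptor signal masked")
  }
  r
}

#' Ratio time series container
#'
#' @param times Time points, s.
#' @param donor,acceptor Channel intensities, a.u.
#' @param beta Bleed-through coefficient used for the ratio.
#' @return A `ratio_timeseries` data frame (columns `time_s`, `donor`,
#'   `acceptor`, `R`) with attributes `beta` and `normalized`.
#' @export
ratio_timeseries <- function(times, donor, acceptor, beta = 0.69) {
  stopifnot(length(times) == length(donor), length(donor) == length(acceptor))
  structure(data.frame(time_s = times, donor = donor, acceptor = acceptor,
                       R = fret_ratio(donor, acceptor, beta)),
            beta = beta, normalized = FALSE,
            class = c("ratio_timeseries", "data.frame"))
}

#' Normalize a ratio time series to its pre-stimulus baseline
#'
#' Divides the ratio trace by its mean over the baseline window so the
#' pre-stimulus level is 1 and subsequent changes read directly as
#' fractional increases (e.g. 1.43 = +43%).
#'
#' @param series A `ratio_timeseries` (or data frame with `time_s`, `R`).
#' @param baseline_window Numeric length-2: `[t0, t1]` in s. Must contain
#'   at least 3 samples.
#' @return The series with `R` replaced by `R / mean(R[baseline])` and the
#'   `normalized` attribute set.
#' @export
normalize_to_baseline <- function(series, baseline_window) {
  idx <- series$time_s >= baseline_window[1] & series$time_s <= baseline_window[2]
  if (sum(idx) < 3) stop_domain("baseline window must contain >= 3 samples")
  base <- mean(series$R[idx], na.rm = TRUE)
  if (!is.finite(base) || base == 0) stop_domain("degenerate baseline mean")
  series$R <- series$R / base
  attr(series, "normalized") <- TRUE
  series
}

#' Linear drift correction against a buffer-only control
#'
#' Estimates the instrumental drift as the slope of a buffer-addition
#' control recording (linear regression of ratio on time), subtracts
#' `slope * t` from the sample trace, and renormalizes to the initial
#' ratio.
#'
#' @param series Sample `ratio_timeseries`.
#' @param control Buffer-only control series spanning the post-addition
#'   interval (>= 3 samples).
#' @return Drift-corrected, initially-normalized series; the fitted slope
#'   is attached as attribute `drift_slope` (ratio units / s).
#' @export
drift_correct <- function(series, control) {
  if (nrow(control) < 3) stop_domain("control must have >= 3 samples")
  s <- unname(coef(lm(R ~ time_s, data = control))[2])
  series$R <- series$R - s * series$time_s
  r0 <- series$R[1]
  if (!is.finite(r0) || r0 == 0) stop_domain("degenerate initial ratio")
  series$R <- series$R / r0
  attr(series, "normalized") <- TRUE
  attr(series, "drift_slope") <- s
  series
}

#' Emission spectrum container
#'
#' @param wavelength_nm Strictly increasing wavelength grid, nm.
#' @param intensity Non-negative intensities, a.u.
#' @param excitation_nm Excitation wavelength (430 nm for the donor).
#' @return An `emission_spectrum` data frame.
#' @export
emission_spectrum <- function(wavelength_nm, intensity, excitation_nm = 430) {
  if (any(diff(wavelength_nm) <= 0))
    stop_domain("wavelengths must be strictly increasing")
  if (any(intensity < 0)) stop_domain("intensities must be >= 0")
  structure(data.frame(wavelength_nm = wavelength_nm, intensity = intensity),
            excitation_nm = excitation_nm,
            class = c("emission_spectrum", "data.frame"))
}

#' Donor/acceptor metrics from an emission spectrum
#'
#' Reads the donor (cerulean) and acceptor (citrine) emissions at fixed
#' wavelengths by nearest-grid lookup and returns their ratio; optionally
#' returns the spectrum normalized to the donor emission at 471 nm.
#'
#' @param spec An [emission_spectrum()].
#' @param donor_nm Donor read-out wavelength (471 nm; the emission peak
#'   itself is at 475 nm).
#' @param acceptor_nm Acceptor read-out wavelength (529 nm).
#' @param normalize If `TRUE`, also return the spectrum scaled so the
#'   intensity at `donor_nm` is exactly 1.
#' @return List with `donor`, `acceptor`, `ratio` (donor/acceptor) and,
#'   if requested, `normalized` spectrum.
#' @export
spectrum_metrics <- function(spec, donor_nm = 471, acceptor_nm = 529,
                             normalize = FALSE) {
  wl <- spec$wavelength_nm
  if (min(wl) > donor_nm || max(wl) < acceptor_nm)
    stop_domain("wavelength grid must cover ", donor_nm, " and ",
                acceptor_nm, " nm")
  lookup <- function(target) spec$intensity[which.min(abs(wl - target))]
  d <- lookup(donor_nm); a <- lookup(acceptor_nm)
  out <- list(donor = d, acceptor = a, ratio = d / a)
  if (normalize) {
    if (d == 0) stop_domain("cannot normalize: zero donor intensity")
    out$normalized <- emission_spectrum(wl, spec$intensity / d,
                                        attr(spec, "excitation_nm"))
  }
  out
}

#' Donor dequenching after acceptor photobleaching
#'
#' Percent increase of background-corrected donor emission after the
#' acceptor is bleached; a positive increase demonstrates FRET.
#'
#' @param donor_pre,donor_post Donor intensity before/after bleaching, a.u.
#' @param background Background intensity, a.u. (default 0).
#' @return Percent increase,
#'   `100 * ((post - bg) - (pre - bg)) / (pre - bg)`.
#' @export
photobleach_donor_increase <- function(donor_pre, donor_post, background = 0) {
  if (any(donor_pre <= background))
    stop_domain("donor_pre must exceed background")
  100 * ((donor_post - background) - (donor_pre - background)) /
    (donor_pre - background)
}
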