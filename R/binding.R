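## Equilibrium binding: single-site isotherm with ligand depletion, and
## Hill/EC50 fitting for cellular agonist dose-response curves.

#' Parameters of the single-site depletion binding model
#'
#' Bundles the parameters of the mass-action single-binding-site model used
#' to fit sensor dose-response curves. Because the sensor is used at
#' micromolar concentration while its dissociation constant is tens of
#' nanomolar, free and total ligand differ appreciably and the model works
#' with *total* concentrations (ligand depletion).
#'
#' @param kd_nM Dissociation constant, nM. Must be positive.
#' @param et_uM Total sensor (protein) concentration, µM. Must be positive.
#' @param df_max Maximal FRET-change amplitude at saturation (ratio units).
#' @param df0 Baseline offset (ratio units), default 0.
#' @return An object of class `binding_params` (a named list).
#' @seealso [bound_fraction()], [predict_dose_response()], [fit_binding()]
#' @export
binding_params <- function(kd_nM, et_uM, df_max, df0 = 0) {
  if (!is.finite(kd_nM) || kd_nM <= 0) stop_domain("kd_nM must be > 0")
  if (!is.finite(et_uM) || et_uM <= 0) stop_domain("et_uM must be > 0")
  if (!is.finite(df_max)) stop_domain("df_max must be finite")
  structure(list(kd_nM = kd_nM, et_uM = et_uM, df_max = df_max, df0 = df0),
            class = "binding_params")
}

#' Dose-response curve container
#'
#' @param ligand_total_nM Total ligand concentrations, nM; strictly
#'   increasing and non-negative.
#' @param dF Measured FRET change at each concentration (ratio units).
#' @param ligand_id Label, e.g. `"cAMP"` or `"cGMP"`.
#' @param pH Buffer pH (optional metadata).
#' @return A `dose_response` data frame with attributes `ligand_id`, `pH`.
#' @export
dose_response <- function(ligand_total_nM, dF, ligand_id = "cAMP", pH = NA) {
  if (length(ligand_total_nM) != length(dF))
    stop_domain("ligand_total_nM and dF must have equal length")
  if (any(ligand_total_nM < 0)) stop_domain("concentrations must be >= 0")
  if (any(diff(ligand_total_nM) <= 0))
    stop_domain("concentrations must be strictly increasing")
  structure(data.frame(ligand_total_nM = ligand_total_nM, dF = dF),
            ligand_id = ligand_id, pH = pH,
            class = c("dose_response", "data.frame"))
}

#' Equilibrium occupancy under ligand depletion
#'
#' Fraction of sensor bound at equilibrium for given *total* sensor and
#' ligand concentrations. The bound complex B is the physical root of
#' \deqn{B^2 - (E_T + L_T + K_D)\,B + E_T L_T = 0,}
#' computed in the numerically stable form
#' \eqn{B = 2 E_T L_T / (S + \sqrt{S^2 - 4 E_T L_T})} with
#' \eqn{S = E_T + L_T + K_D}, and the occupancy is \eqn{\theta = B/E_T}.
#' All three concentrations must be in the *same* unit (µM or nM).
#'
#' @param et Total sensor concentration (> 0).
#' @param lt Total ligand concentration(s) (>= 0); vectorized.
#' @param kd Dissociation constant (> 0), same unit as `et` and `lt`.
#' @return Occupancy fraction(s) in `[0, min(1, lt/et)]`.
#' @examples
#' bound_fraction(1, 1, 1)  # (3 - sqrt(5))/2
#' @export
bound_fraction <- function(et, lt, kd) {
  if (any(!is.finite(et)) || any(et <= 0)) stop_domain("et must be > 0")
  if (any(!is.finite(kd)) || any(kd <= 0)) stop_domain("kd must be > 0")
  if (any(!is.finite(lt)) || any(lt < 0)) stop_domain("lt must be >= 0")
  s <- et + lt + kd
  b <- 2 * et * lt / (s + sqrt(s^2 - 4 * et * lt))
  b / et
}

#' Predict a dose-response curve from binding parameters
#'
#' Forward model \eqn{\Delta F(L_T) = \Delta F_0 + \Delta F_{max}\,
#' \theta(E_T, L_T, K_D)} with the depletion isotherm [bound_fraction()].
#'
#' @param params A [binding_params()] object.
#' @param ligand_total_nM Total ligand concentrations, nM.
#' @return Predicted FRET changes (ratio units).
#' @export
predict_dose_response <- function(params, ligand_total_nM) {
  stopifnot(inherits(params, "binding_params"))
  th <- bound_fraction(params$et_uM * 1000, ligand_total_nM, params$kd_nM)
  params$df0 + params$df_max * th
}

#' Fit the depletion binding model to a dose-response curve
#'
#' Unweighted least-squares fit of \eqn{K_D}, \eqn{\Delta F_{max}} and
#' (optionally) the baseline offset, with the total sensor concentration
#' fixed to its known value. K_D is optimized on a log scale for stability;
#' standard errors come from the fit covariance.
#'
#' @param curve A [dose_response()] object (or data frame with columns
#'   `ligand_total_nM`, `dF`).
#' @param et_uM Known total sensor concentration, µM.
#' @param float_df0 If `FALSE`, the baseline offset is fixed at 0 (as after
#'   baseline correction); default floats it.
#' @return A `binding_fit` object: estimates (`kd_nM`, `df_max`, `df0`),
#'   standard errors, residual sum of squares.
#' @export
fit_binding <- function(curve, et_uM, float_df0 = TRUE) {
  lt <- curve$ligand_total_nM
  y <- curve$dF
  if (length(lt) < 4) stop_domain("need at least 4 dose points")
  if (max(y) - min(y) <= .Machine$double.eps * max(1, abs(max(y))))
    stop_domain("degenerate data: response is constant, no binding signal")
  et_nM <- et_uM * 1000

  model <- function(p) {
    df0 <- if (float_df0) p[["df0"]] else 0
    df0 + p[["df_max"]] * bound_fraction(et_nM, lt, exp(p[["log_kd"]]))
  }
  ## crude start: half-max crossing for kd, range for amplitude
  amp0 <- y[which.max(lt)] - y[1]
  kd0 <- max(stats::approx(y, lt, xout = y[1] + amp0 / 2, ties = "ordered")$y,
             min(lt[lt > 0]), na.rm = TRUE)
  start <- c(log_kd = log(kd0), df_max = amp0)
  if (float_df0) start <- c(start, df0 = y[1])
  res <- fq_nlsLM(function(p) y - model(p), start, what = "binding fit")

  kd <- exp(res$par[["log_kd"]])
  se <- fq_lm_se(res)
  se_kd <- kd * se[["log_kd"]]  # delta method for the log-parameterization
  est <- list(kd_nM = kd, df_max = res$par[["df_max"]],
              df0 = if (float_df0) res$par[["df0"]] else 0)
  ses <- list(kd_nM = se_kd, df_max = se[["df_max"]],
              df0 = if (float_df0) se[["df0"]] else 0)
  new_fq_fit("binding_fit", est, ses,
             rss = res$deviance, converged = TRUE, et_uM = et_uM,
             data = data.frame(ligand_total_nM = lt, dF = y),
             fitted = model(res$par))
}

#' @export
predict.binding_fit <- function(object, ligand_total_nM = NULL, ...) {
  if (is.null(ligand_total_nM)) return(object$fitted)
  p <- binding_params(object$estimate$kd_nM, object$et_uM,
                      object$estimate$df_max, object$estimate$df0)
  predict_dose_response(p, ligand_total_nM)
}

#' @export
residuals.binding_fit <- function(object, ...) object$data$dF - object$fitted

#' @export
plot.binding_fit <- function(x, ...) {
  d <- x$data
  plot(d$ligand_total_nM, d$dF, log = "x", xlab = "total ligand (nM)",
       ylab = expression(Delta * F), ...)
  grid <- exp(seq(log(max(min(d$ligand_total_nM), 1e-3)),
                  log(max(d$ligand_total_nM)), length.out = 200))
  lines(grid, predict(x, grid))
  invisible(x)
}

#' Fit a Hill (four-parameter logistic) dose-response model
#'
#' Fits \eqn{y = bottom + (top - bottom) / (1 + (EC_{50}/x)^{n_H})} to an
#' agonist concentration series, as used for cellular dose-response curves
#' where the agonist acts upstream of the sensed second messenger.
#'
#' @param dose_uM Agonist concentrations, µM (> 0; at least 4).
#' @param response Normalized response at each dose.
#' @param n_h_fixed Optional fixed Hill coefficient (e.g. 1); default the
#'   slope is a free parameter.
#' @return A `hill_fit` object with estimates `ec50_uM`, `n_h`, `top`,
#'   `bottom` and their standard errors.
#' @export
fit_hill <- function(dose_uM, response, n_h_fixed = NULL) {
  if (length(dose_uM) < 4) stop_domain("need at least 4 doses")
  if (any(dose_uM <= 0)) stop_domain("doses must be > 0")
  x <- dose_uM; y <- response
  model <- function(p) {
    nh <- if (is.null(n_h_fixed)) exp(p[["log_nh"]]) else n_h_fixed
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + (exp(p[["log_ec50"]]) / x)^nh)
  }
  start <- c(log_ec50 = log(exp(mean(log(range(x))))),
             top = y[which.max(x)], bottom = y[which.min(x)])
  if (is.null(n_h_fixed)) start <- c(start, log_nh = 0)
  res <- fq_nlsLM(function(p) y - model(p), start, what = "Hill fit")
  se <- fq_lm_se(res)
  ec50 <- exp(res$par[["log_ec50"]])
  nh <- if (is.null(n_h_fixed)) exp(res$par[["log_nh"]]) else n_h_fixed
  est <- list(ec50_uM = ec50, n_h = nh,
              top = res$par[["top"]], bottom = res$par[["bottom"]])
  ses <- list(ec50_uM = ec50 * se[["log_ec50"]],
              n_h = if (is.null(n_h_fixed)) nh * se[["log_nh"]] else 0,
              top = se[["top"]], bottom = se[["bottom"]])
  new_fq_fit("hill_fit", est, ses, rss = res$deviance, converged = TRUE,
             n_h_fixed = !is.null(n_h_fixed),
             data = data.frame(dose_uM = x, response = y))
}

#' @export
predict.hill_fit <- function(object, dose_uM = NULL, ...) {
  if (is.null(dose_uM)) dose_uM <- object$data$dose_uM
  e <- object$estimate
  e$bottom + (e$top - e$bottom) / (1 + (e$ec50_uM / dose_uM)^e$n_h)
}
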