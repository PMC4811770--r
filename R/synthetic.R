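## Seeded synthetic-data generators. Each generator draws from the forward
## model of the stage that will consume its output and returns ground truth
## alongside, so every analysis stage has an exact recovery target.

#' Generate a synthetic dose-response curve
#'
#' Forward model [predict_dose_response()] plus additive Gaussian noise.
#'
#' @param true_params A [binding_params()] object (ground truth).
#' @param grid Total ligand concentrations, nM; default 12 points
#'   log-spaced from ~0.1 to ~30 times the K_D.
#' @param noise_sd Gaussian noise SD as a fraction of `df_max` (default 0).
#' @param seed Integer seed.
#' @param ligand_id Label carried in the curve metadata.
#' @return A [dose_response()] with attribute `truth`.
#' @export
gen_dose_response <- function(true_params, grid = NULL, noise_sd = 0,
                              seed = NULL, ligand_id = "cAMP") {
  stopifnot(inherits(true_params, "binding_params"))
  if (is.null(grid))
    grid <- exp(seq(log(0.1 * true_params$kd_nM),
                    log(30 * true_params$kd_nM), length.out = 12))
  mu <- predict_dose_response(true_params, grid)
  y <- mu + with_seed(seed,
                      rnorm(length(mu), 0, noise_sd * abs(true_params$df_max)))
  out <- dose_response(grid, y, ligand_id = ligand_id)
  attr(out, "truth") <- true_params
  out
}

#' Generate a synthetic stopped-flow trace set
#'
#' Traces from [simulate_complex()] mapped through
#' `signal = offset + alpha * [EL]`, with seeded Gaussian noise. The
#' default concentration series is the six-step cAMP series used for the
#' global kinetic fit (0.5, 1, 1.6, 2.5, 5 and 10 µM against 2.5 µM
#' sensor), treated as final in-cuvette values.
#'
#' @param true_params A [kinetic_params()] object (ground truth).
#' @param lt_uM Ligand concentrations, µM.
#' @param et_uM Sensor concentration, µM (default 2.5).
#' @param duration_s Trace duration, s (default 0.5).
#' @param rate_hz Sampling rate, Hz (default 200).
#' @param noise_sd Gaussian noise SD as a fraction of the largest plateau
#'   amplitude (default 0).
#' @param seed Integer seed.
#' @return A [sf_traceset()] with attribute `truth`.
#' @export
gen_stopped_flow <- function(true_params,
                             lt_uM = c(0.5, 1, 1.6, 2.5, 5, 10),
                             et_uM = 2.5, duration_s = 0.5, rate_hz = 200,
                             noise_sd = 0, seed = NULL) {
  stopifnot(inherits(true_params, "kinetic_params"))
  times <- seq(0, duration_s, by = 1 / rate_hz)
  clean <- lapply(lt_uM, function(l)
    true_params$offset + true_params$alpha *
      simulate_complex(true_params, et_uM, l, times))
  plateau <- max(vapply(clean, function(s) abs(tail(s, 1) - s[1]),
                        numeric(1)))
  traces <- with_seed(seed, lapply(seq_along(lt_uM), function(i) {
    list(lt_uM = lt_uM[i], times = times,
         signal = clean[[i]] + rnorm(length(times), 0, noise_sd * plateau))
  }))
  out <- sf_traceset(traces, et_uM, rate_hz)
  attr(out, "truth") <- true_params
  out
}

#' Generate a synthetic null-point experiment
#'
#' Ratios follow the depletion-free isotherm mapped affinely into ratio
#' units: `R(c) = r0 + r_span * c/(c + K_D)`; the intact-cell baseline is
#' the same map evaluated at the true basal concentration.
#'
#' @param true_basal_nM Ground-truth basal free concentration, nM.
#' @param kd_nM Sensor dissociation constant, nM.
#' @param titration_nM Added concentrations, nM (keep within ~3 K_D for
#'   the local-linearity assumption of the readout).
#' @param r0,r_span Affine map from occupancy to ratio units.
#' @param noise_sd Gaussian noise SD on the ratios (absolute, ratio units).
#' @param seed Integer seed.
#' @return A [nullpoint_experiment()] with attribute `truth`.
#' @export
gen_nullpoint <- function(true_basal_nM, kd_nM,
                          titration_nM = seq(0, 200, by = 25),
                          r0 = 0.8, r_span = 0.6, noise_sd = 0,
                          seed = NULL) {
  theta <- titration_nM / (titration_nM + kd_nM)
  ratio <- r0 + r_span * theta +
    with_seed(seed, rnorm(length(theta), 0, noise_sd))
  r_basal <- r0 + r_span * true_basal_nM / (true_basal_nM + kd_nM)
  out <- nullpoint_experiment(r_basal, titration_nM, ratio, analyte = "cAMP")
  attr(out, "truth") <- list(basal_nM = true_basal_nM, kd_nM = kd_nM)
  out
}

#' Generate a synthetic pH null-point experiment
#'
#' Ratio linear in pH over the titration range (the pH readout is locally
#' linear by design), with the intact-cell baseline at the true pH_i.
#'
#' @param true_pH Ground-truth intracellular pH.
#' @param titration_pH pH buffer values (default 5–8 in 0.5 steps).
#' @param slope,intercept Linear ratio-vs-pH map.
#' @param noise_sd Gaussian noise SD on the ratios.
#' @param seed Integer seed.
#' @return A [nullpoint_experiment()] with analyte `"pH"`.
#' @export
gen_pH_nullpoint <- function(true_pH, titration_pH = seq(5, 8, by = 0.5),
                             slope = 0.3, intercept = -0.5, noise_sd = 0,
                             seed = NULL) {
  ratio <- intercept + slope * titration_pH +
    with_seed(seed, rnorm(length(titration_pH), 0, noise_sd))
  r_basal <- intercept + slope * true_pH
  out <- nullpoint_experiment(r_basal, titration_pH, ratio, analyte = "pH")
  attr(out, "truth") <- list(pH = true_pH)
  out
}

## -- flagellum movie ---------------------------------------------------------

#' Default configuration for the synthetic flagellum movie
#'
#' The defaults mirror the dual-view recordings the analysis targets:
#' 1 Hz acquisition, 0.25 µm pixels, a ~60 µm flagellum beating as a
#' traveling wave with the cytoplasmic droplet at 22 µm arc length, a 26%
#' FRET-ratio plateau in the midpiece and 22% in the principal piece, and
#' a faster principal-piece rise (half-rise 60 s vs 120 s).
#'
#' @param ... Overrides for any default field.
#' @return Named list of generator settings.
#' @export
flagellum_movie_config <- function(...) {
  cfg <- list(
    n_rows = 200, n_cols = 600, pixel_size_um = 0.25,
    n_frames = 600, frame_rate_hz = 1,
    flagellum_length_um = 60, droplet_s_um = 22,
    wave_amplitude = 0.5,       # tangent-angle amplitude, rad
    wavelength_um = 35,         # beat wavelength along the arc
    beat_freq_hz = 0.05,        # apparent slow envelope at 1 Hz sampling
    body_intensity = 400,       # acceptor counts at the flagellar core
    droplet_gain = 3,           # droplet brightness multiplier
    droplet_sigma_um = 1.5,
    psf_sigma_px = 1.2,
    beta = 0.69, r0 = 0.5,
    plateau_mp = 0.26, plateau_pp = 0.22,
    x0_mp_s = 120, x0_pp_s = 60, logistic_p = 4,
    read_noise_sd = 2, shot_noise = TRUE,
    acceptor_shift_px = c(0, 0)  # optional mis-registration (drow, dcol)
  )
  modifyList(cfg, list(...))
}

## Analytic centerline at time t: arc-length parameterization through the
## tangent angle, so the ground-truth arc length is exact by construction.
flagellum_curve <- function(cfg, t_s, ds_um = 0.1) {
  s <- seq(0, cfg$flagellum_length_um, by = ds_um)
  phi <- cfg$wave_amplitude *
    sin(2 * pi * (s / cfg$wavelength_um - cfg$beat_freq_hz * t_s))
  px <- cfg$pixel_size_um
  margin_r <- cfg$n_rows / 2
  margin_c <- max(8, (cfg$n_cols * px - cfg$flagellum_length_um) / (2 * px))
  row <- margin_r + cumsum(c(0, sin(phi[-1]) * ds_um)) / px
  col <- margin_c + cumsum(c(0, cos(phi[-1]) * ds_um)) / px
  list(s_um = s, row = row, col = col)
}

## Separable Gaussian blur (matches the rendering PSF).
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- exp(-0.5 * ((-r:r) / sigma)^2); k <- k / sum(k)
  EBImage::filter2(m, outer(k, k), boundary = 0)
}

#' Generate a synthetic dual-view flagellum movie
#'
#' Renders a beating flagellum (Gaussian radial profile, traveling-wave
#' shape) with a bright droplet landmark at fixed arc length. The acceptor
#' channel carries the structural intensity; the donor channel is derived
#' from the local FRET ratio so that
#' `(donor - beta*acceptor)/acceptor = R(s, t)` holds exactly before
#' noise. `R(s, t)` follows region-specific logistic time courses
#' (principal piece faster than midpiece by default). Poisson shot noise
#' and Gaussian read noise emulate an EMCCD camera.
#'
#' @param config From [flagellum_movie_config()].
#' @param seed Integer seed (fixed seed gives identical movies).
#' @return A [dualview_movie()] with droplet annotations and attribute
#'   `truth`: per-frame centerlines, droplet arc position, true region
#'   traces on the frame grid and the true logistic parameters.
#' @export
gen_flagellum_movie <- function(config = flagellum_movie_config(),
                                seed = NULL) {
  cfg <- config
  nt <- cfg$n_frames
  px <- cfg$pixel_size_um
  times <- (seq_len(nt) - 1) / cfg$frame_rate_hz
  logi <- function(t, x0, plateau)
    ifelse(t <= 0, 1, 1 + plateau / (1 + (x0 / t)^cfg$logistic_p))

  donor <- array(0, c(cfg$n_rows, cfg$n_cols, nt))
  acceptor <- array(0, c(cfg$n_rows, cfg$n_cols, nt))
  droplet_xy <- matrix(NA_real_, nt, 2)
  truth_centerlines <- vector("list", nt)

  render <- function(vals, rows, cols) {
    ## bilinear splat of point masses onto the pixel grid
    m <- matrix(0, cfg$n_rows, cfg$n_cols)
    r0 <- floor(rows); c0 <- floor(cols)
    fr <- rows - r0; fc <- cols - c0
    for (dr in 0:1) for (dc in 0:1) {
      w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
      ok <- r0 + dr >= 1 & r0 + dr <= cfg$n_rows &
        c0 + dc >= 1 & c0 + dc <= cfg$n_cols
      if (any(ok)) {
        idx <- cbind(r0[ok] + dr, c0[ok] + dc)
        agg <- rowsum(vals[ok] * w[ok],
                      group = (idx[, 2] - 1) * cfg$n_rows + idx[, 1])
        m[as.integer(rownames(agg))] <- m[as.integer(rownames(agg))] + agg
      }
    }
    gauss_blur(m, cfg$psf_sigma_px)
  }

  ds <- 0.1
  mp_true <- logi(times, cfg$x0_mp_s, cfg$plateau_mp)
  pp_true <- logi(times, cfg$x0_pp_s, cfg$plateau_pp)
  for (k in seq_len(nt)) {
    cur <- flagellum_curve(cfg, times[k], ds_um = ds)
    truth_centerlines[[k]] <- cur
    is_mp <- cur$s_um <= cfg$droplet_s_um
    resp <- ifelse(is_mp, mp_true[k], pp_true[k])
    r_st <- cfg$r0 * resp
    ## structural (acceptor) weight per sample point, droplet bump included
    w <- rep(1, length(cur$s_um))
    w <- w + cfg$droplet_gain *
      exp(-0.5 * ((cur$s_um - cfg$droplet_s_um) / cfg$droplet_sigma_um)^2)
    amp <- cfg$body_intensity * ds / px * w
    acceptor[, , k] <- render(amp, cur$row, cur$col)
    donor[, , k] <- render(amp * (r_st + cfg$beta), cur$row, cur$col)
    di <- which.min(abs(cur$s_um - cfg$droplet_s_um))
    droplet_xy[k, ] <- c(cur$row[di], cur$col[di])
  }

  if (any(cfg$acceptor_shift_px != 0))
    for (k in seq_len(nt))
      acceptor[, , k] <- shift_image(acceptor[, , k],
                                     -cfg$acceptor_shift_px[1],
                                     -cfg$acceptor_shift_px[2])

  with_seed(seed, {
    if (cfg$shot_noise) {
      donor[] <- rpois(length(donor), pmax(donor, 0))
      acceptor[] <- rpois(length(acceptor), pmax(acceptor, 0))
    }
    if (cfg$read_noise_sd > 0) {
      donor[] <- donor + rnorm(length(donor), 0, cfg$read_noise_sd)
      acceptor[] <- acceptor + rnorm(length(acceptor), 0, cfg$read_noise_sd)
    }
  })

  mv <- dualview_movie(donor, acceptor, px, cfg$frame_rate_hz,
                       droplet = droplet_xy)
  attr(mv, "truth") <- list(
    config = cfg,
    centerlines = truth_centerlines,
    arc_length_um = cfg$flagellum_length_um,
    droplet_s_um = cfg$droplet_s_um,
    region_traces = data.frame(time_s = times, midpiece = mp_true,
                               principal_piece = pp_true),
    logistic = list(
      midpiece = list(A1 = 1, A2 = 1 + cfg$plateau_mp, x0_s = cfg$x0_mp_s,
                      p = cfg$logistic_p),
      principal_piece = list(A1 = 1, A2 = 1 + cfg$plateau_pp,
                             x0_s = cfg$x0_pp_s, p = cfg$logistic_p)))
  mv
}
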