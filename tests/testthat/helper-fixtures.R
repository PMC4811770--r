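## Shared fixtures: everything is generated in code at test time.

## small, fast TCSPC setup
fx_grid <- tcspc_grid(256)
fx_irf <- gaussian_irf(fx_grid, center_ns = 1, sigma_ns = 0.1)
fx_delta_irf <- c(1, rep(0, length(fx_grid) - 1))

## smooth random test image for registration tests
fx_smooth_image <- function(n = 64, k = 6, seed = 1) {
  set.seed(seed)
  img <- matrix(0, n, n)
  for (i in seq_len(k)) {
    cx <- runif(1, n * 0.25, n * 0.75)
    cy <- runif(1, n * 0.25, n * 0.75)
    img <- img + outer(seq_len(n), seq_len(n),
                       function(r, c) exp(-((r - cy)^2 + (c - cx)^2) / 18))
  }
  img
}

## down-scaled flagellum movie used across tests: same study conditions,
## smaller frame and shorter recording
fx_movie_config <- function(...) {
  base <- list(n_rows = 80, n_cols = 140, pixel_size_um = 0.5,
               n_frames = 360)
  do.call(flagellum_movie_config, utils::modifyList(base, list(...)))
}

## quiet wrapper: region windows shorter than 20 um raise a contract
## warning on the default geometry (droplet at 22 um)
fx_region_ts <- function(movie, ...) {
  suppressWarnings(region_fret_timeseries(movie, ...))
}
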