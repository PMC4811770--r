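test_that("channel registration recovers known shifts", {
  base <- fx_smooth_image()
  as_stack <- function(m) array(m, c(dim(m), 1))
  ## identical channels
  mv0 <- dualview_movie(as_stack(base), as_stack(base), 0.5)
  r0 <- register_channels(mv0)
  expect_equal(unname(attr(r0, "shifts")[1, ]), c(0, 0))
  ## integer shift recovered exactly
  moved <- fretquant:::shift_image(base, -3, 2)  # content moves (+3, -2)
  mv1 <- dualview_movie(as_stack(base), as_stack(moved), 0.5)
  r1 <- register_channels(mv1)
  expect_equal(unname(attr(r1, "shifts")[1, ]), c(3, -2), tolerance = 1e-6)
  ## and the acceptor is realigned onto the donor grid
  expect_lt(max(abs(r1$acceptor[10:50, 10:50, 1] - base[10:50, 10:50])),
            1e-5)
  ## sub-pixel shift recovered within 0.1 px
  mv2 <- dualview_movie(as_stack(base),
                        as_stack(fretquant:::shift_image(base, -0.4, 0)),
                        0.5)
  r2 <- register_channels(mv2)
  expect_lt(abs(unname(attr(r2, "shifts")[1, "drow"]) - 0.4), 0.1)
  expect_lt(abs(unname(attr(r2, "shifts")[1, "dcol"])), 0.1)
  ## structureless frames are flagged unregistered
  mvn <- dualview_movie(as_stack(matrix(rnorm(64^2), 64)),
                        as_stack(matrix(rnorm(64^2), 64)), 0.5)
  expect_false(attr(register_channels(mvn), "registered")[1])
})

test_that("registration and sampling commute with global translation", {
  cfg <- fx_movie_config(n_frames = 1, shot_noise = FALSE, read_noise_sd = 0)
  mv <- gen_flagellum_movie(cfg)
  cl <- track_centerline(mv$donor[, , 1], 0.5, droplet_hint = mv$droplet[1, ])
  prof <- sample_along(cl, mv$donor[, , 1])
  ## translate both channels by the same integer offset
  shifted <- fretquant:::shift_image(mv$donor[, , 1], -4, -3)
  cl2 <- track_centerline(shifted, 0.5,
                          droplet_hint = mv$droplet[1, ] + c(4, 3))
  prof2 <- sample_along(cl2, shifted)
  n <- min(nrow(prof), nrow(prof2))
  keep <- 5:(n - 5)
  expect_equal(prof2$intensity[keep], prof$intensity[keep],
               tolerance = 0.02)
})

test_that("centerline tracking measures arc length correctly", {
  ## straight 50 px segment at 0.5 um/px spans 24.5 um of arc
  frame <- matrix(0, 40, 80)
  frame[20, 11:60] <- 1
  cl <- track_centerline(frame, 0.5, spline_df = 3)
  expect_equal(max(cl$arc_length_um), 24.5, tolerance = 0.05)
  expect_equal(cl$arc_length_um[1], 0)
  expect_true(all(diff(cl$arc_length_um) > 0))
  ## arc length always >= straight chord
  expect_gte(max(cl$arc_length_um), cl$chord_um - 1e-6)

  ## sine curve: arc length vs numeric quadrature within 2%
  xs <- seq(0, 100, by = 0.05)
  ys <- 5 * sin(2 * pi * xs / 50)
  img <- matrix(0, 60, 120)
  for (i in seq_along(xs)) {
    r <- round(30 + ys[i]); c <- round(10 + xs[i])
    img[(r - 1):(r + 1), c] <- 1  # 3 px wide band
  }
  img <- fretquant:::gauss_blur(img, 0.8)
  cl2 <- track_centerline(img, 0.5, spline_df = 25)
  ## quadrature oracle over the span the tracker actually covered (the
  ## threshold erodes a pixel or two at the very ends)
  x_lo <- min(cl2$points[, 2]) - 10; x_hi <- max(cl2$points[, 2]) - 10
  l_true_px <- integrate(function(x)
    sqrt(1 + (5 * 2 * pi / 50 * cos(2 * pi * x / 50))^2), x_lo, x_hi)$value
  expect_gt(x_hi - x_lo, 90)
  expect_equal(max(cl2$arc_length_um), l_true_px * 0.5, tolerance = 0.02)

  ## blank frame fails loudly
  expect_error(track_centerline(matrix(0, 40, 40), 0.5), "blank")
  ## too-short component fails
  tiny <- matrix(0, 40, 40); tiny[20, 18:23] <- 1
  expect_error(track_centerline(tiny, 0.5), "tracking failure")
})

test_that("arc length is stable under resampling step changes", {
  cfg <- fx_movie_config(n_frames = 1, shot_noise = FALSE, read_noise_sd = 0)
  mv <- gen_flagellum_movie(cfg)
  cl_a <- track_centerline(mv$donor[, , 1], 0.5, step_um = 0.5)
  cl_b <- track_centerline(mv$donor[, , 1], 0.5, step_um = 0.25)
  expect_equal(max(cl_a$arc_length_um), max(cl_b$arc_length_um),
               tolerance = 0.01)
})

test_that("sample_along interpolates bilinearly and masks out-of-bounds", {
  ## uniform image -> constant profile
  cl <- flagellum_centerline(cbind(rep(10.3, 21), seq(5, 25, 1)),
                             seq(0, 10, 0.5), pixel_size_um = 0.5)
  u <- sample_along(cl, matrix(4.2, 30, 30))
  expect_equal(u$intensity, rep(4.2, 21))
  ## linear gradient along x -> linear profile with matching slope
  grad <- matrix(rep(1:30, each = 30), 30, 30)  # value = column index
  g <- sample_along(cl, grad)
  expect_equal(unname(coef(lm(g$intensity ~ g$s_um))[2]), 2,
               tolerance = 1e-9)  # 1 per px = 2 per um at 0.5 um/px
  ## out-of-bounds points propagate as NA, not zero
  cl_oob <- flagellum_centerline(cbind(rep(10, 5), c(28, 29, 30, 31, 32)),
                                 seq(0, 2, 0.5), pixel_size_um = 0.5)
  s <- sample_along(cl_oob, matrix(1, 30, 30))
  expect_true(all(is.na(s$intensity[4:5])))
  expect_true(all(!is.na(s$intensity[1:3])))
})

test_that("region windows respect the droplet offset geometry", {
  cfg <- fx_movie_config(n_frames = 2)
  mv <- gen_flagellum_movie(cfg, seed = 4)
  rk <- fx_region_ts(mv, baseline_frames = 2)
  d_s <- rk$droplet_s_um[1]
  expect_equal(d_s, 22, tolerance = 2)
  expect_equal(rk$windows$midpiece[2], d_s - 5, tolerance = 1e-6)
  expect_equal(rk$windows$principal_piece[1], d_s + 5, tolerance = 1e-6)
  expect_equal(diff(rk$windows$principal_piece), 20, tolerance = 1e-6)
  ## truncated midpiece window raises the shortened-window warning
  expect_warning(region_fret_timeseries(
    dualview_movie(mv$donor[, , 1, drop = FALSE],
                   mv$acceptor[, , 1, drop = FALSE],
                   0.5, droplet = mv$droplet[1, ]),
    baseline_frames = 1), class = "fq_shortened_window")
})

test_that("movie with no FRET change yields flat unit traces", {
  cfg <- fx_movie_config(n_frames = 10, plateau_mp = 0, plateau_pp = 0,
                         shot_noise = FALSE, read_noise_sd = 0)
  mv <- gen_flagellum_movie(cfg)
  rk <- fx_region_ts(mv, baseline_frames = 5)
  expect_equal(rk$midpiece$R, rep(1, 10), tolerance = 1e-3)
  expect_equal(rk$principal_piece$R, rep(1, 10), tolerance = 1e-3)
})

test_that("logistic kinetics: midpoint identity, recovery, degeneracy", {
  t <- seq(0, 360)
  y <- 1.25 + (1 - 1.25) / (1 + (t / 120)^4)
  fit <- fit_logistic_kinetics(t, y)
  expect_equal(fit$estimate$A1, 1, tolerance = 5e-3)
  expect_equal(fit$estimate$A2, 1.25, tolerance = 5e-3)
  expect_equal(fit$estimate$x0_s, 120, tolerance = 5e-3)
  expect_equal(fit$estimate$p, 4, tolerance = 5e-3)
  ## midpoint property of the fitted curve
  expect_equal(predict(fit, fit$estimate$x0_s),
               (fit$estimate$A1 + fit$estimate$A2) / 2, tolerance = 1e-9)
  ## constant trace: degenerate flag, no spurious half-rise time
  flat <- fit_logistic_kinetics(t, rep(1, length(t)))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$estimate$x0_s))
  expect_equal(flat$estimate$A1, flat$estimate$A2)
})

test_that("average_kinetics pools fitted curves per region", {
  t <- seq(0, 360)
  mk_fit <- function(x0) fit_logistic_kinetics(
    t, 1.25 + (1 - 1.25) / (1 + (t / x0)^4))
  f100 <- mk_fit(100); f140 <- mk_fit(140)
  ## identical fits -> SD identically zero
  same <- average_kinetics(list(c1 = list(midpiece = f100,
                                          principal_piece = f100),
                                c2 = list(midpiece = f100,
                                          principal_piece = f100)), t)
  expect_equal(same$midpiece$sd, rep(0, length(t)))
  ## mean curve's half-rise lies between the individual half-rise times
  two <- average_kinetics(list(c1 = list(midpiece = f100,
                                         principal_piece = f100),
                               c2 = list(midpiece = f140,
                                         principal_piece = f140)), t)
  half <- (1 + 1.25) / 2
  t_half <- t[which.min(abs(two$midpiece$mean - half))]
  expect_true(t_half > 100 && t_half < 140)
  expect_error(average_kinetics(list(list(midpiece = f100)), t), "2 cells")
  expect_error(average_kinetics(list(c1 = list(midpiece = f100),
                                     c2 = list(midpiece = f100)), t),
               "principal_piece")
})
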