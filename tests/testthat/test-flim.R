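test_that("weighted mean lifetime: formula, bounds, scale invariance", {
  expect_equal(weighted_mean_lifetime(biexp_params(3, 1, 1, 0)), 3)
  expect_equal(weighted_mean_lifetime(biexp_params(3, 2, 1, 1)), 2.5)
  expect_equal(weighted_mean_lifetime(biexp_params(3, 1.5, 2, 1)), 2.5)
  ## scale invariance in the amplitudes and component bounds
  set.seed(11)
  for (i in 1:20) {
    t1 <- runif(1, 1, 4); t2 <- runif(1, 0.2, 1)
    a1 <- runif(1); a2 <- runif(1)
    wm <- weighted_mean_lifetime(biexp_params(t1, t2, a1, a2))
    expect_equal(wm, weighted_mean_lifetime(biexp_params(t1, t2,
                                                         5 * a1, 5 * a2)))
    expect_true(wm >= min(t1, t2) && wm <= max(t1, t2))
  }
  expect_error(biexp_params(3, 1, 0, 0), "amplitudes")
  expect_error(weighted_mean_lifetime(list(tau1 = 3, tau2 = 1,
                                           a1 = 0, a2 = 0)), "a1")
})

test_that("simulate_tcspc: convolution identity, normalization, determinism", {
  p <- biexp_params(2.5, 2.5, 1, 0)
  d <- simulate_tcspc(p, fx_delta_irf, 1e5, seed = 1, time_ns = fx_grid)
  mu <- attr(d, "expected")
  ## delta IRF, mono-exponential: expectation proportional to exp(-t/tau)
  ref <- exp(-(fx_grid - fx_grid[1]) / 2.5)
  expect_equal(mu / mu[1], ref, tolerance = 1e-9)
  expect_equal(sum(mu), 1e5)
  ## determinism contract
  d2 <- simulate_tcspc(p, fx_delta_irf, 1e5, seed = 1, time_ns = fx_grid)
  expect_identical(d$counts, d2$counts)
  d3 <- simulate_tcspc(p, fx_delta_irf, 1e5, seed = 2, time_ns = fx_grid)
  expect_false(identical(d$counts, d3$counts))
})

test_that("reconvolution fit recovers noiseless and Poisson-noised truth", {
  p <- biexp_params(3.0, 1.2, 500, 500)
  ## noiseless expected histogram: recovery within 0.5% per parameter
  d <- simulate_tcspc(p, fx_irf, 1e6, time_ns = fx_grid, noise = FALSE)
  fit <- fit_decay_reconvolution(d)
  expect_equal(fit$estimate$tau1, 3.0, tolerance = 5e-3)
  expect_equal(fit$estimate$tau2, 1.2, tolerance = 5e-3)
  expect_equal(fit$estimate$a1 / fit$estimate$a2, 1, tolerance = 5e-3)
  expect_true(fit$estimate$tau1 >= fit$estimate$tau2)

  ## seeded Poisson realization at 1e6 counts: tau_wm within 2%
  dn <- simulate_tcspc(p, fx_irf, 1e6, seed = 99, time_ns = fx_grid)
  fitn <- fit_decay_reconvolution(dn)
  expect_equal(fitn$estimate$tau_wm, p$tau_wm, tolerance = 0.02)
  expect_true(fitn$chisq_red > 0.7 && fitn$chisq_red < 1.3)
})

test_that("mono-exponential truth degenerates gracefully via tau_wm", {
  p <- biexp_params(2.4, 2.4, 1, 0)
  d <- simulate_tcspc(p, fx_irf, 5e5, seed = 5, time_ns = fx_grid)
  fit <- fit_decay_reconvolution(d)
  e <- fit$estimate
  expect_true(min(e$a1, e$a2) / (e$a1 + e$a2) < 0.1 ||
                abs(e$tau1 - e$tau2) / e$tau1 < 0.25)
  expect_equal(e$tau_wm, 2.4, tolerance = 0.01)
})

test_that("delta-IRF reconvolution equals a plain bi-exponential fit", {
  p <- biexp_params(3.0, 1.0, 600, 400)
  d <- simulate_tcspc(p, fx_delta_irf, 1e6, time_ns = fx_grid,
                      noise = FALSE)
  fit <- fit_decay_reconvolution(d)
  ## independent plain fit, no convolution machinery
  t0 <- fx_grid - fx_grid[1]
  y <- d$counts
  w <- 1 / sqrt(pmax(y, 1))
  plain <- minpack.lm::nls.lm(
    par = c(lt1 = log(2.5), lt2 = log(0.8), a1 = max(y) / 2,
            a2 = max(y) / 2, bg = 0),
    fn = function(q) (y - (q[["a1"]] * exp(-t0 / exp(q[["lt1"]])) +
                             q[["a2"]] * exp(-t0 / exp(q[["lt2"]])) +
                             q[["bg"]])) * w,
    lower = c(log(0.01), log(0.01), 0, 0, 0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15))
  taus <- sort(exp(plain$par[c("lt1", "lt2")]), decreasing = TRUE)
  expect_equal(fit$estimate$tau1, unname(taus[1]), tolerance = 1e-6)
  expect_equal(fit$estimate$tau2, unname(taus[2]), tolerance = 1e-6)
})

test_that("flim_map masks low-count pixels and maps homogeneous images", {
  grid <- tcspc_grid(128)
  irf <- gaussian_irf(grid, 0.8, 0.1)
  p <- biexp_params(2.8, 1.4, 1, 1)
  base <- attr(simulate_tcspc(p, irf, 400, time_ns = grid, noise = FALSE),
               "expected")
  stack <- array(0, c(7, 7, 128))
  for (i in 1:7) for (j in 1:7) stack[i, j, ] <- base
  ## one pixel just below the count threshold
  stack[3, 4, ] <- base * (19 / sum(base))
  img <- flim_image(stack, irf, grid)
  map <- flim_map(img, min_counts = 20, bin_size = 3)
  expect_true(is.na(map[3, 4]))
  expect_equal(sum(is.na(map)), 1)
  vals <- map[!is.na(map)]
  ## homogeneous decays -> uniform map equal to the single-decay fit
  single <- fit_decay_reconvolution(tcspc_decay(grid, base * 25, irf))
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-3)
  expect_equal(mean(vals), single$estimate$tau_wm, tolerance = 1e-2)
  ## fully masked image errors
  expect_error(flim_map(flim_image(stack * 1e-3, irf, grid),
                        min_counts = 20, bin_size = 3), "threshold")
})

test_that("two-region FLIM image resolves 2.38 vs 2.47 ns without leakage", {
  grid <- tcspc_grid(128)
  irf <- gaussian_irf(grid, 0.8, 0.1)
  ## amplitude fractions chosen so tau_wm hits each regional target
  f_for <- function(wm, t1 = 3, t2 = 1.5) (wm - t2) / (t1 - t2)
  mk <- function(wm, n) {
    f <- f_for(wm)
    attr(simulate_tcspc(biexp_params(3, 1.5, f, 1 - f), irf, n,
                        time_ns = grid, noise = FALSE), "expected")
  }
  nr <- 12; nc <- 16; half <- 8
  stack <- array(0, c(nr, nc, 128))
  for (j in 1:nc) {
    base <- mk(if (j <= half) 2.38 else 2.47, 2000)
    for (i in 1:nr) stack[i, j, ] <- base
  }
  map <- flim_map(flim_image(stack, irf, grid), min_counts = 20,
                  bin_size = 3)
  expect_false(anyNA(map))
  ## interior columns (more than one bin radius from the boundary)
  left <- map[, 1:(half - 1)]
  right <- map[, (half + 2):nc]
  expect_equal(mean(left), 2.38, tolerance = 0.02)
  expect_equal(mean(right), 2.47, tolerance = 0.02)
  expect_lt(max(abs(left - 2.38)), 0.03)
  expect_lt(max(abs(right - 2.47)), 0.03)
})

test_that("pooled-decay fitting variance shrinks with bin size", {
  grid <- tcspc_grid(128)
  irf <- gaussian_irf(grid, 0.8, 0.1)
  p <- biexp_params(2.8, 1.2, 1, 1)
  mu <- attr(simulate_tcspc(p, irf, 500, time_ns = grid, noise = FALSE),
             "expected")
  set.seed(21)
  stack <- array(rpois(15 * 15 * 128, rep(mu, each = 225)),
                 c(15, 15, 128))
  img <- flim_image(stack, irf, grid)
  spread <- vapply(c(1, 5, 15), function(b) {
    m <- flim_map(img, min_counts = 20, bin_size = b)
    sd(m, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
})
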