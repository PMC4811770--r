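test_that("bound_fraction solves the depletion quadratic", {
  ## no ligand, stoichiometric limit
  expect_equal(bound_fraction(1, 0, 5), 0)
  expect_equal(bound_fraction(1, 0.5, 1e-12), 0.5, tolerance = 1e-6)

  ## independent oracle: numeric root of (E - B)(L - B)/B = K
  mass_action_root <- function(et, lt, kd) {
    uniroot(function(b) (et - b) * (lt - b) - kd * b,
            c(1e-15, min(et, lt) - 1e-15), tol = 1e-14)$root
  }
  expect_equal(bound_fraction(1, 1, 1), mass_action_root(1, 1, 1),
               tolerance = 1e-10)
  expect_equal(bound_fraction(1, 1, 1), (3 - sqrt(5)) / 2, tolerance = 1e-12)
  for (et in c(0.1, 1, 2.5)) for (lt in c(0.05, 0.7, 8)) for (kd in c(0.07, 1))
    expect_equal(et * bound_fraction(et, lt, kd),
                 mass_action_root(et, lt, kd), tolerance = 1e-9)

  expect_error(bound_fraction(1, -1, 1), "lt")
  expect_error(bound_fraction(0, 1, 1), "et")
})

test_that("occupancy is monotone and bounded, with the dilute limit", {
  lt <- seq(0, 50, length.out = 200)
  th <- bound_fraction(1, lt, 0.5)
  expect_true(all(diff(th) >= -1e-12))
  expect_true(all(th >= 0 & th <= pmin(1, lt / 1 + 1e-12)))
  ## nonincreasing in K_D
  kd <- seq(0.05, 10, length.out = 50)
  thk <- bound_fraction(1, 2, kd)
  expect_true(all(diff(thk) <= 1e-12))
  ## depletion-free limit when E_T <= K_D / 100
  kd0 <- 1; et <- kd0 / 100
  lt2 <- c(0.1, 0.5, 1, 3, 10)
  expect_equal(bound_fraction(et, lt2, kd0), lt2 / (lt2 + kd0),
               tolerance = 0.01)
})

test_that("predict_dose_response has correct limits and round-trips", {
  p <- binding_params(66, 1, 0.5, 0.1)
  expect_equal(predict_dose_response(p, 0), 0.1)
  expect_equal(predict_dose_response(p, 1e9), 0.6, tolerance = 1e-4)
  ## monotone nondecreasing when df_max > 0
  y <- predict_dose_response(p, seq(0, 2000, by = 10))
  expect_true(all(diff(y) >= -1e-12))
  ## fit then re-predict reproduces the fitted responses
  curve <- gen_dose_response(p)
  fit <- fit_binding(curve, 1)
  expect_equal(predict(fit, curve$ligand_total_nM), curve$dF,
               tolerance = 1e-6)
})

test_that("fit_binding recovers noiseless truth and rejects degenerate data", {
  for (kd in c(66, 504)) {
    truth <- binding_params(kd, 1, 0.45, 0.05)
    curve <- gen_dose_response(truth)
    fit <- fit_binding(curve, 1)
    expect_equal(fit$estimate$kd_nM, kd, tolerance = 1e-3)
    expect_equal(fit$estimate$df_max, 0.45, tolerance = 1e-3)
    expect_equal(fit$estimate$df0, 0.05, tolerance = 1e-3)
    expect_true(all(is.finite(unlist(fit$se))))
    expect_true(fit$rss < 1e-10)
  }
  flat <- dose_response(c(1, 10, 100, 1000), rep(0.2, 4))
  expect_error(fit_binding(flat, 1), "degenerate")
  expect_error(fit_binding(dose_response(c(1, 10, 100), c(0, .1, .2)), 1),
               "4 dose points")
})

test_that("fit_binding is unbiased under 2% noise (seeded replicates)", {
  ## identifiable design: the 1 uM protein condition with a dense 24-point
  ## titration (at 12 points the heavy ligand depletion leaves K_D weakly
  ## identified and the estimate is visibly skewed)
  truth <- binding_params(66, 1, 0.5, 0)
  grid <- exp(seq(log(6.6), log(1980), length.out = 24))
  kds <- vapply(seq_len(200), function(s) {
    curve <- gen_dose_response(truth, grid = grid, noise_sd = 0.02,
                               seed = 1000 + s)
    tryCatch(fit_binding(curve, 1)$estimate$kd_nM, error = function(e) NA)
  }, numeric(1))
  expect_true(mean(is.na(kds)) < 0.05)
  expect_lt(abs(median(kds, na.rm = TRUE) - 66) / 66, 0.05)
})

test_that("fit_hill midpoint, recovery and sign-flip behavior", {
  x <- exp(seq(log(0.3), log(100), length.out = 8))
  hill <- function(x, ec50, nh, top, bottom)
    bottom + (top - bottom) / (1 + (ec50 / x)^nh)

  fit <- fit_hill(x, hill(x, 3.6, 1, 1.43, 1), n_h_fixed = 1)
  expect_equal(fit$estimate$ec50_uM, 3.6, tolerance = 1e-3)
  ## response at EC50 equals mid-plateau
  e <- fit$estimate
  expect_equal(predict(fit, e$ec50_uM), (e$top + e$bottom) / 2,
               tolerance = 1e-8)

  ## free slope
  fit2 <- fit_hill(x, hill(x, 5, 1.7, 2, 1))
  expect_equal(fit2$estimate$ec50_uM, 5, tolerance = 1e-3)
  expect_equal(fit2$estimate$n_h, 1.7, tolerance = 1e-3)

  ## strictly decreasing curve: plateaus flip consistently
  fit3 <- fit_hill(x, hill(x, 3.6, 1, 0.6, 1.4), n_h_fixed = 1)
  expect_lt(fit3$estimate$top, fit3$estimate$bottom)
  expect_equal(fit3$estimate$ec50_uM, 3.6, tolerance = 1e-3)

  expect_error(fit_hill(c(1, 2, 3), c(0, 1, 2)), "4 doses")
})
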