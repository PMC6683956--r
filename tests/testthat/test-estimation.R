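test_that("observed series validate their contract", {
  s <- observed_series(c(0, 120, 240), c(1, 0.8, 0.62), "curcumin")
  expect_s3_class(s, "observed_series")
  expect_error(observed_series(c(0, 120), c(1, 0.8), "curcumin"),
               "at least 3")
  expect_error(observed_series(c(0, 120, 120), c(1, 0.8, 0.7), "curcumin"),
               "strictly increasing")
  expect_error(observed_series(c(0, 1, 2), c(1, 2, 0.5), "curcumin"),
               "1.5")
})

test_that("sse and r_squared match hand arithmetic", {
  obs <- observed_series(c(0, 60, 120), c(1, 0.5, 0.25), "curcumin")
  pred <- c(1, 0.6, 0.2)
  expect_equal(sse(obs, pred), 0.0125)
  expect_equal(sse(obs, obs$value), 0)
  # additivity across series
  expect_equal(sse(list(obs, obs), list(pred, pred)), 0.025)
  expect_equal(r_squared(obs, pred), 1 - 0.0125 / 0.2916667,
               tolerance = 1e-6)
  expect_equal(r_squared(obs, obs$value), 1)
  expect_equal(r_squared(obs, rep(mean(obs$value), 3)), 0)
  expect_error(sse(obs, c(1, 0.5)), "lengths differ")
  const <- observed_series(c(0, 1, 2), c(1, 1, 1), "curcumin")
  expect_error(r_squared(const, c(1, 1, 1)), "zero total sum of squares")
})

test_that("r_squared is invariant to a shared affine rescaling", {
  obs_n <- observed_series(c(0, 60, 120, 180), c(1, 0.7, 0.5, 0.4),
                           "curcumin")
  pred_n <- c(1, 0.72, 0.48, 0.41)
  obs_u <- observed_series(c(0, 60, 120, 180), 135.7 * obs_n$value,
                           "curcumin", scale = "uM")
  expect_equal(r_squared(obs_u, 135.7 * pred_n), r_squared(obs_n, pred_n))
})

test_that("predicted observables are normalized, monotone and deterministic", {
  cfg <- free_curcumin_config()
  expect_equal(predict_observable(cfg, "curcumin", 0), 1)
  p <- predict_observable(cfg, "curcumin", sample_grid)
  expect_equal(p[1], 1)
  expect_true(all(diff(p) < 0))
  expect_identical(p, predict_observable(cfg, "curcumin", sample_grid))
  # inert curcumin stays flat
  p0 <- predict_observable(free_curcumin_config(k_C = 0), "curcumin",
                           sample_grid)
  expect_equal(p0, rep(1, length(sample_grid)))
  expect_error(predict_observable(cfg, "curcumin", 2000), "horizon")
})

test_that("noiseless single-parameter fit recovers the generating constant", {
  truth <- free_curcumin_config(k_C = 200)
  obs <- generate_observed_series(truth, sample_grid, noise_model(sigma = 0))
  fit <- fit_rate_constants(obs, free_curcumin_config(k_C = 0), free = "k_C")
  expect_true(fit$converged)
  expect_equal(coef(fit)[["k_C"]], 200, tolerance = 1e-3)
  expect_gt(fit$r_squared[["curcumin"]], 0.9999)
  # descent: optimum no worse than the initial guess
  expect_lte(fit$sse, fit$sse_initial)
  # full-stiff cross-check of the optimum agrees
  expect_lt(summary(fit)$mode_agreement, 0.005)
})

test_that("a null consumption signal fits k_C to ~0", {
  truth <- free_curcumin_config(k_C = 0)
  obs <- generate_observed_series(truth, sample_grid, noise_model(sigma = 0))
  fit <- fit_rate_constants(obs, free_curcumin_config(k_C = 0), free = "k_C",
                            stiff_check = FALSE)
  expect_lt(coef(fit)[["k_C"]], 1e-3)
})

test_that("joint two-species fit recovers both constants from noiseless data", {
  rel <- generate_release_product_series(noise = noise_model(sigma = 0))
  fit <- fit_rate_constants(rel, release_products_config(k_C = 0, k_CM = 0),
                            free = c("k_C", "k_CM"))
  expect_true(fit$converged)
  expect_equal(coef(fit)[["k_C"]], 75, tolerance = 5e-3)
  expect_equal(coef(fit)[["k_CM"]], 25, tolerance = 5e-3)
  expect_named(fit$r_squared, c("curcumin", "curcumin_monoacrylate"))
})

test_that("hitting the iteration cap reports non-convergence without error", {
  rel <- generate_release_product_series(noise = noise_model(sigma = 0))
  fit <- fit_rate_constants(rel, release_products_config(k_C = 0, k_CM = 0),
                            free = c("k_C", "k_CM"), maxit = 3,
                            stiff_check = FALSE)
  expect_false(fit$converged)
})

test_that("fit methods expose coefficients, predictions and residuals", {
  truth <- free_curcumin_config(k_C = 200)
  obs <- generate_observed_series(truth, sample_grid,
                                  noise_model(sigma = 0.02, seed = 42))
  fit <- fit_rate_constants(obs, free_curcumin_config(k_C = 0), free = "k_C",
                            stiff_check = FALSE)
  expect_named(coef(fit), "k_C")
  expect_length(fitted(fit), length(sample_grid))
  expect_equal(residuals(fit), obs$value - fitted(fit))
  expect_equal(predict(fit), fitted(fit))
  expect_output(print(fit), "k_C")
  expect_output(print(summary(fit)), "R\\^2")
  sims <- simulate(fit, nsim = 2, seed = 7)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]][[1]], "observed_series")
})
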