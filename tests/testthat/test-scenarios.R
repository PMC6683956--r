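test_that("baseline radical level follows the quasi-steady oracle", {
  base <- baseline_trajectory(10, dt = 60)
  qss <- 2 * 1.26e-6 * base$C_A / 4.16e4
  expect_true(all(abs(base$C_R / qss - 1) < 1e-6))
  expect_rel_equal(base$C_R[1], 6.0577e-7, 1e-4)
  # zero AAPH: no radicals at all
  expect_true(all(baseline_trajectory(0, dt = 360)$C_R == 0))
  # linearity in the AAPH level
  b100 <- baseline_trajectory(100, dt = 60)
  expect_true(all(abs(b100$C_R / (10 * base$C_R) - 1) < 1e-3))
})

test_that("scenario specs demand exactly one delivery kind", {
  expect_error(scenario_spec(), "exactly one")
  expect_error(scenario_spec(bolus_uM = 10, rate_uM_min = 0.1), "exactly one")
  expect_error(scenario_spec(bolus_uM = -1), ">= 0")
})

test_that("a zero dose produces an identically zero deviation", {
  for (spec in list(scenario_spec(bolus_uM = 0),
                    scenario_spec(rate_uM_min = 0))) {
    res <- deviation_series(spec, dt = 120)
    expect_equal(res$deviation, rep(0, nrow(res)))
    expect_equal(auc(res), 0)
  }
})

test_that("deviations are non-negative, peak early for boluses, and decay monotonically", {
  res <- deviation_series(scenario_spec(bolus_uM = 225))
  expect_true(all(res$deviation >= -1e-12))
  expect_equal(attr(res, "t_peak"), 0)
  # scavenging only lowers the radical level below baseline
  expect_true(all(res$scenario_C_R <= res$baseline_C_R + 1e-18))
  # monotone return toward baseline once curcumin only decreases
  i_peak <- which.max(res$deviation)
  expect_true(all(diff(res$deviation[i_peak:nrow(res)]) <= 1e-15))
})

test_that("peak deviations match the quasi-steady closed form", {
  # baseline minus suppressed level at t = 0:
  # 2 kA CA (1/k_el - 1/(k_el + k_C*C0))
  closed <- function(C0) 2 * 1.26e-6 * 1e4 *
    (1 / 4.16e4 - 1 / (4.16e4 + 200 * C0))
  for (C0 in c(10, 225)) {
    res <- deviation_series(scenario_spec(bolus_uM = C0))
    expect_rel_equal(attr(res, "peak_deviation"), closed(C0), 1e-6)
  }
})

test_that("deviation AUC obeys the quasi-steady identity consumed/k_el", {
  for (kC in c(200, 2000)) {
    spec <- scenario_spec(bolus_uM = 10, k = rate_constants(k_C = kC))
    res <- deviation_series(spec)
    cfg <- kinetic_config(spec$k, species_state(C_A = 1e4, C_C = 10),
                          mode = "quasi_steady_radical")
    traj <- simulate_kinetics(cfg)
    consumed <- 10 - traj$C_C[nrow(traj)]
    expect_rel_equal(auc(res), analytic_auc_estimate(consumed), 1e-3)
  }
  # full consumption: the closed form dose/k_el is reached
  res_fast <- deviation_series(scenario_spec(bolus_uM = 10,
                                             k = rate_constants(k_C = 2e4)))
  expect_rel_equal(auc(res_fast), analytic_auc_estimate(10), 5e-3)
  expect_rel_equal(analytic_auc_estimate(10), 2.404e-4, 1e-3)
  expect_rel_equal(analytic_auc_estimate(225), 5.409e-3, 1e-3)
  expect_equal(analytic_auc_estimate(0), 0)
})

test_that("refining the deviation grid leaves the AUC essentially unchanged", {
  spec <- scenario_spec(bolus_uM = 225)
  a1 <- auc(deviation_series(spec, dt = 1))
  a01 <- auc(deviation_series(spec, dt = 0.1))
  expect_lt(abs(a1 - a01) / a01, 1e-3)
})

test_that("quasi-steady and full-stiff deviation pipelines agree", {
  spec <- scenario_spec(bolus_uM = 225)
  a_q <- auc(deviation_series(spec, dt = 10))
  a_f <- auc(deviation_series(spec, dt = 10, mode = "full_stiff"))
  expect_rel_equal(a_f, a_q, 5e-3)
})

test_that("the dose comparison table pairs boluses with equivalent release rates", {
  expect_equal(nrow(run_demonstration(numeric(0))), 0)
  doses <- c(10, 25, 75, 100, 150, 225)
  tab <- run_demonstration(doses)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$rate_uM_min, doses / 1440)
  # headline qualitative claim: bolus always deviates more in total
  expect_true(all(tab$bolus_auc >= tab$rate_auc))
  expect_true(all(tab$bolus_peak >= tab$rate_peak))
  # AUC strictly increases with the dose
  expect_true(all(diff(tab$bolus_auc) > 0))
  expect_true(all(diff(tab$rate_auc) > 0))
  # AUC is bounded by total radical production over the window
  produced <- 2 * 1e4 * (1 - exp(-1.26e-6 * 1440))
  expect_true(all(tab$bolus_auc <= 2 * produced))
  # printed-rate override is honoured verbatim
  tab2 <- run_demonstration(c(10, 100), rates_override = c(0.0070, 0.0678))
  expect_equal(tab2$rate_uM_min, c(0.0070, 0.0678))
})

test_that("comparison tables print and export", {
  tab <- run_demonstration(c(10, 225), dt = 10)
  expect_output(print(tab), "bolus AUC")
  path <- withr::local_tempfile(fileext = ".csv")
  write_comparison_csv(tab, path)
  back <- read.csv(path)
  expect_equal(back$bolus_auc, tab$bolus_auc)
})
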