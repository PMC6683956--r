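test_that("rhs reproduces hand-evaluated derivatives", {
  k <- rate_constants()
  # null state: nothing happens
  expect_equal(unname(rhs(species_state(), k)), rep(0, 4))
  # AAPH alone: first-order decay, two radicals per decomposition
  d <- rhs(species_state(C_A = 10000), k)
  expect_equal(d[["C_A"]], -1.26e-2)
  expect_equal(d[["C_R"]], 2.52e-2)
  expect_equal(unname(d[c("C_C", "C_CM")]), c(0, 0))
  # at the quasi-steady radical level, generation balances elimination
  d2 <- rhs(species_state(C_A = 10000, C_R = 2.52e-2 / 4.16e4), k)
  expect_equal(d2[["C_R"]], 0, tolerance = 1e-10)
  expect_error(rhs(species_state(C_A = 1), k, release_rate = -1), ">= 0")
})

test_that("literal-radical compatibility form generates nothing from C_R = 0", {
  k <- rate_constants()
  d <- rhs(species_state(C_A = 10000), k, generation = "literal_radical")
  expect_equal(d[["C_R"]], 0)
  cfg <- kinetic_config(k, species_state(C_A = 10000),
                        generation = "literal_radical")
  traj <- simulate_kinetics(cfg, times = seq(0, 1440, by = 60))
  expect_true(all(traj$C_R == 0))
})

test_that("quasi-steady radical level matches its closed form", {
  k <- rate_constants()
  expect_equal(quasi_steady_radical(species_state(), k), 0)
  expect_equal(quasi_steady_radical(species_state(C_A = 10000), k),
               2.52e-2 / 4.16e4)  # 6.0577e-7 uM
  expect_equal(
    quasi_steady_radical(species_state(C_A = 10000, C_C = 225),
                         rate_constants(k_C = 200)),
    2.52e-2 / (4.16e4 + 200 * 225))  # 2.9099e-7 uM
  expect_error(
    quasi_steady_radical(species_state(C_A = 1),
                         rate_constants(k_el = 0)), "undefined")
})

test_that("an empty system stays identically zero", {
  for (mode in c("full_stiff", "quasi_steady_radical")) {
    traj <- simulate_kinetics(
      kinetic_config(rate_constants(k_C = 200), species_state(), mode = mode),
      times = seq(0, 1440, by = 120))
    expect_true(all(as.matrix(traj[, c("C_A", "C_R", "C_C", "C_CM")]) == 0))
    expect_equal(radical_balance_residual(traj), 0)
  }
})

test_that("AAPH decay matches its closed form and trajectories stay non-negative", {
  for (mode in c("full_stiff", "quasi_steady_radical")) {
    cfg <- kinetic_config(rate_constants(k_C = 200),
                          species_state(C_A = 10000, C_C = 135.7),
                          mode = mode)
    traj <- simulate_kinetics(cfg, times = seq(0, 1440, by = 10))
    expect_equal(traj$C_A, 10000 * exp(-1.26e-6 * traj$time),
                 tolerance = 1e-6)
    expect_equal(traj$C_A[traj$time == 1440], 9981.9, tolerance = 1e-4)
    expect_true(all(traj[, c("C_A", "C_R", "C_C", "C_CM")] >= 0))
    # scavenger and AAPH are non-increasing without dosing
    expect_true(all(diff(traj$C_C) <= 1e-12))
    expect_true(all(diff(traj$C_A) <= 0))
  }
})

test_that("full-stiff radical relaxes to the quasi-steady level and tracks it", {
  cfg <- kinetic_config(rate_constants(), species_state(C_A = 10000))
  traj <- simulate_kinetics(cfg, times = c(seq(0, 1, by = 0.01),
                                           seq(10, 1440, by = 10)))
  t_half <- log(2) / 4.16e4
  after <- traj[traj$time >= 10 * t_half, ]
  qss <- 2 * 1.26e-6 * after$C_A / 4.16e4
  expect_true(all(abs(after$C_R - qss) / qss < 0.005))
})

test_that("full-stiff and quasi-steady modes agree on slow species", {
  mk <- function(mode) simulate_kinetics(
    kinetic_config(rate_constants(k_C = 200, k_CM = 25),
                   species_state(C_A = 10000, C_C = 81.4, C_CM = 54.3),
                   mode = mode),
    times = seq(0, 1440, by = 60))
  fs <- mk("full_stiff"); qs <- mk("quasi_steady_radical")
  # align on the shared output grid; full-stiff adds transient refinement
  i <- match(qs$time, fs$time)
  expect_true(all(abs(fs$C_C[i] - qs$C_C) / qs$C_C < 1e-3))
  expect_true(all(abs(fs$C_CM[i] - qs$C_CM) / qs$C_CM < 1e-3))
  r_fs <- radical_balance_residual(fs)
  r_qs <- radical_balance_residual(qs)
  expect_lt(r_fs, 1e-4)
  expect_lt(r_qs, 1e-4)
  expect_lt(abs(r_fs - r_qs), 1e-4)
})

test_that("with k_C = 0 curcumin is inert under bolus-only dosing", {
  cfg <- kinetic_config(
    rate_constants(k_C = 0), species_state(C_A = 10000),
    dosing = dosing_scheme(boluses = data.frame(
      time = c(0, 600), species = "curcumin", amount = c(50, 25))),
    mode = "quasi_steady_radical")
  traj <- simulate_kinetics(cfg)
  expect_equal(traj$C_C[traj$time == 300], 50)
  expect_equal(traj$C_C[traj$time == 1440], 75)
})

test_that("boluses jump the state and release segments feed it continuously", {
  # inert scavenger isolates the dosing bookkeeping from the kinetics
  cfg <- kinetic_config(
    rate_constants(k_C = 0), species_state(C_A = 10000),
    dosing = dosing_scheme(
      boluses = data.frame(time = 100, species = "curcumin", amount = 30),
      rate_segments = data.frame(t_start = 200, t_end = 400,
                                 species = "curcumin_monoacrylate",
                                 rate = 0.5)),
    mode = "quasi_steady_radical")
  traj <- simulate_kinetics(cfg)
  expect_equal(traj$C_C[traj$time == 99], 0)
  expect_equal(traj$C_C[traj$time == 100], 30)
  expect_equal(traj$C_CM[traj$time == 200], 0)
  expect_equal(traj$C_CM[traj$time == 300], 50, tolerance = 1e-8)
  expect_equal(traj$C_CM[traj$time == 1440], 100, tolerance = 1e-8)
})

test_that("radical balance residual is small for default runs", {
  cfg <- kinetic_config(rate_constants(k_C = 200),
                        species_state(C_A = 10000, C_C = 225))
  traj <- simulate_kinetics(cfg)
  expect_lt(radical_balance_residual(traj), 1e-4)
})

test_that("cumulative consumption tracks the delivered scavenger", {
  cfg <- kinetic_config(rate_constants(k_C = 20000),
                        species_state(C_A = 10000, C_C = 10),
                        mode = "quasi_steady_radical")
  traj <- simulate_kinetics(cfg)
  final <- traj[nrow(traj), ]
  # consumed + remaining = dose
  expect_equal(final$consumed_C + final$C_C, 10, tolerance = 1e-3)
  expect_true(all(diff(traj$consumed_C) >= 0))
})

test_that("quasi-steady mode refuses a nonzero initial radical level", {
  expect_error(simulate_kinetics(kinetic_config(
    rate_constants(), species_state(C_A = 1, C_R = 1),
    mode = "quasi_steady_radical")), "C_R")
})
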