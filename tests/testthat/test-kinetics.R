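test_that("free evolution reduces to mono-exponential decay without exchange", {
  kin <- kinetic_params(kPL = 0)
  cond <- field_conditions(linewidth_fwhm = 0, n_isochromats = 1)
  st <- init_state(cond)
  st[1, 3] <- 1
  out <- evolve_free(st, kin$T1_pyr, kin, NULL, cond)
  expect_equal(out[1, 3], exp(-1), tolerance = 1e-12)
  expect_equal(out[1, 6], 0)
})

test_that("one-way exchange follows its closed form and conserves magnetization", {
  kin <- kinetic_params(kPL = 0.05, T1_pyr = Inf, T1_lac = Inf,
                        T2_pyr = Inf, T2_lac = Inf)
  cond <- field_conditions(linewidth_fwhm = 0, n_isochromats = 1)
  st <- init_state(cond)
  st[1, 3] <- 1
  dt <- 7
  out <- evolve_free(st, dt, kin, NULL, cond)
  expect_equal(out[1, 3], exp(-kin$kPL * dt), tolerance = 1e-12)
  expect_equal(out[1, 3] + out[1, 6], 1, tolerance = 1e-12)
})

test_that("matrix-exponential propagation matches a fine-step forward-Euler oracle", {
  # slow precession regime: forward Euler is only stable/accurate for small
  # frequencies, which is where it can serve as an independent oracle
  set.seed(11)
  for (rep in 1:2) {
    kin <- kinetic_params(kPL = runif(1, 0, 0.1),
                          T1_pyr = runif(1, 20, 40), T1_lac = runif(1, 15, 30),
                          T2_pyr = runif(1, 0.3, 0.7), T2_lac = runif(1, 0.6, 1.4),
                          omega_pyr = runif(1, -1, 1), omega_lac = runif(1, -1, 1))
    cond <- field_conditions(linewidth_fwhm = 0, n_isochromats = 1,
                             b0_offset = runif(1, -0.5, 0.5))
    bol <- bolus_params()
    st <- init_state(cond)
    st[1, ] <- c(0.3, -0.2, 0.5, 0.1, 0.05, 0.2)
    a <- evolve_free(st, 0.05, kin, bol, cond, t0 = -1)  # bolus active
    b <- euler_evolve(st[1, ], 0.05, kin, bol, cond, t0 = -1)
    expect_lt(max(abs(a[1, ] - b)) / max(abs(b)), 1e-6)
  }
})

test_that("magnetization plus delivered bolus input is conserved without relaxation", {
  kin <- kinetic_params(kPL = 0.08, T1_pyr = Inf, T1_lac = Inf,
                        T2_pyr = Inf, T2_lac = Inf)
  cond <- field_conditions(linewidth_fwhm = 0, n_isochromats = 1)
  bol <- bolus_params()
  st <- init_state(cond)
  # propagate far past the end of the bolus: everything injected must sit in
  # the two longitudinal pools
  # piecewise-constant midpoint integration of the gamma inflow is accurate
  # to O(dt^2) ~ 1e-6 at the 10 ms sub-step
  out <- evolve_free(st, 120, kin, bol, cond, t0 = bol$t_arrival)
  expect_equal(out[1, 3] + out[1, 6], 1, tolerance = 1e-5)
  # after the bolus has completed, the sum drifts by < 1e-9 over further steps
  tot0 <- out[1, 3] + out[1, 6]
  out2 <- evolve_free(out, 50, kin, bol, cond, t0 = bol$t_arrival + 120)
  expect_lt(abs(out2[1, 3] + out2[1, 6] - tot0), 1e-9)
})

test_that("RF rotations are exact, spectrally selective, and B1-scaled", {
  cond <- field_conditions(linewidth_fwhm = 0, n_isochromats = 1)
  st <- init_state(cond)
  st[1, 3] <- 1
  st[1, 6] <- 0.5
  expect_identical(apply_rf(st, 0, 0, "pyr", cond), st)

  out <- apply_rf(st, 90, 0, "pyr", cond)
  expect_equal(sqrt(out[1, 1]^2 + out[1, 2]^2), 1, tolerance = 1e-12)
  expect_equal(out[1, 3], 0, tolerance = 1e-12)
  expect_equal(out[1, 4:6], st[1, 4:6])  # lactate untouched

  # b1 scale equivalence: 30 deg at b1 = 1.2 equals 36 deg at b1 = 1
  c12 <- field_conditions(b1_scale = 1.2, linewidth_fwhm = 0,
                          n_isochromats = 1)
  expect_equal(apply_rf(st, 30, 45, "lac", c12),
               apply_rf(st, 36, 45, "lac", cond), tolerance = 1e-12)
  expect_error(apply_rf(st, 30, 0, "water", cond))
})

test_that("spoiled GRE excitation train follows the (cos theta)^n closed form", {
  kin <- kinetic_params(kPL = 0)
  cond <- field_conditions(linewidth_fwhm = 0, n_isochromats = 1)
  theta <- 10
  tr <- 0.0625
  n <- 16
  st <- init_state(cond)
  st[1, 3] <- 1
  for (i in seq_len(n)) {
    st <- apply_rf(st, theta, 0, "pyr", cond)
    st[, 1:2] <- 0  # spoiler
    st <- evolve_free(st, tr, kin, NULL, cond)
  }
  expect_equal(st[1, 3],
               cos(theta * pi / 180)^n * exp(-n * tr / kin$T1_pyr),
               tolerance = 1e-12)
})

test_that("compiled event-driven kernel agrees with the R state operations", {
  kin <- kinetic_params(kPL = 0.03)
  bol <- bolus_params()
  cond <- small_cond()
  for (design in c("mrf_sigmoid", "hybridgre")) {
    sched <- small_schedule(design)
    ref <- simulate_fingerprint_r(sched, kin, bol, cond)
    fp <- simulate_fingerprint(sched, kin, bol, cond)
    expect_lt(max(Mod(fp$signal - ref)), 1e-10)
  }
})

test_that("fingerprints are linear in the bolus and silent without conversion", {
  sched <- small_schedule()
  cond <- small_cond()
  kin <- kinetic_params(kPL = 0.02)
  f1 <- simulate_fingerprint(sched, kin, bolus_params(total_input = 1), cond)
  f2 <- simulate_fingerprint(sched, kin, bolus_params(total_input = 2), cond)
  expect_equal(f2$signal, 2 * f1$signal, tolerance = 1e-12)

  f0 <- simulate_fingerprint(sched, kinetic_params(kPL = 0),
                             bolus_params(), cond)
  expect_true(all(f0$signal[f0$metabolite == "lac"] == 0))
  expect_gt(max(Mod(f0$signal[f0$metabolite == "pyr"])), 0)
})

test_that("fingerprint is continuous in kPL at the dictionary resolution", {
  dict <- get_dict("mrf_sigmoid")
  raw <- dict$entries * dict$raw_norms
  n <- nrow(raw)
  dif <- sqrt(rowSums(Mod(raw[-1, ] - raw[-n, ])^2))
  nrm <- sqrt(rowSums(Mod(raw[-n, ])^2))
  expect_lt(max(dif / nrm), 0.01)
})

test_that("single on-resonance isochromat equals the vanishing-linewidth limit", {
  sched <- small_schedule()
  kin <- kinetic_params(kPL = 0.03)
  bol <- bolus_params()
  a <- simulate_fingerprint(sched, kin, bol,
                            field_conditions(linewidth_fwhm = 0,
                                             n_isochromats = 1))
  b <- simulate_fingerprint(sched, kin, bol,
                            field_conditions(linewidth_fwhm = 1e-9,
                                             n_isochromats = 101))
  expect_equal(a$signal, b$signal, tolerance = 1e-6)
})

test_that("sigmoid excitation delays the pyruvate signal peak relative to constant flips", {
  for (k in c(0.01, 0.02)) {
    i <- which.min(abs(get_dict("mrf_sigmoid")$kpl_grid - k))
    sig <- get_dict("mrf_sigmoid")
    con <- get_dict("mrf_constant")
    peak_sig <- which.max(Mod(sig$entries[i, sig$metabolite == "pyr"]))
    peak_con <- which.max(Mod(con$entries[i, con$metabolite == "pyr"]))
    expect_gt(peak_sig, peak_con)
  }
})

test_that("negative time steps are rejected", {
  cond <- small_cond()
  expect_error(evolve_free(init_state(cond), -1, kinetic_params(),
                           NULL, cond))
})
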