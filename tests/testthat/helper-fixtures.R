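# shared fixtures: full default dictionaries are built once per test run and
# memoised here (dictionary generation is deterministic)

.fixture_env <- new.env(parent = emptyenv())

get_dict <- function(design) {
  key <- paste0("dict_", design)
  if (is.null(.fixture_env[[key]])) {
    spec <- dictionary_spec(build_schedule(design))
    .fixture_env[[key]] <- generate_dictionary(spec)
  }
  .fixture_env[[key]]
}

# small fast schedule for propagator-level tests
small_schedule <- function(design = "mrf_constant") {
  build_schedule(design, total_duration = 13, n_exc = 4, n_cat = 2)
}

small_cond <- function(...) field_conditions(n_isochromats = 5, ...)

# forward-Euler integration of the two-pool Bloch-McConnell system for one
# isochromat; independent oracle for the closed-form propagator
euler_evolve <- function(state6, dt, kin, bolus, cond, t0, h = 1e-6) {
  n <- round(dt / h)
  s <- state6
  t <- t0
  w <- 2 * pi
  fp <- w * (kin$omega_pyr + cond$b0_offset)
  fl <- w * (kin$omega_lac + cond$b0_offset)
  for (i in seq_len(n)) {
    u <- if (is.null(bolus)) 0 else bolus_input_rate(t, bolus)
    d <- c(-s[1] / kin$T2_pyr - kin$kPL * s[1] - fp * s[2],
           -s[2] / kin$T2_pyr - kin$kPL * s[2] + fp * s[1],
           -s[3] / kin$T1_pyr - kin$kPL * s[3] + u,
           -s[4] / kin$T2_lac - fl * s[5] + kin$kPL * s[1],
           -s[5] / kin$T2_lac + fl * s[4] + kin$kPL * s[2],
           -s[6] / kin$T1_lac + kin$kPL * s[3])
    s <- s + h * d
    t <- t + h
  }
  s
}

# reference fingerprint simulation through the exported R-level state
# operations only (independent of the compiled event-driven kernel)
simulate_fingerprint_r <- function(schedule, kin, bolus, cond) {
  state <- init_state(cond)
  targets <- vapply(schedule$blocks, function(b) b$target, "")
  n_pyr <- sum(targets == "pyr")
  out <- complex(length(targets))
  pyr_i <- 0
  lac_i <- 0
  t_cur <- min(0, bolus$t_arrival, schedule$blocks[[1]]$start_time)
  for (b in schedule$blocks) {
    state <- evolve_free(state, b$start_time - t_cur, kin, bolus, cond,
                         t0 = t_cur)
    t <- b$start_time
    fr <- schedule$ref_freqs[[b$target]]
    cols <- if (b$target == "pyr") 1:3 else 4:6
    imaging <- seq(b$n_cat + 1, b$n_cat + b$n_exc)
    acc <- 0 + 0i
    for (k in seq_along(b$flips)) {
      axis <- b$phases[k] + 360 * ((fr * t) %% 1)
      state <- apply_rf(state, b$flips[k], axis, b$target, cond)
      if (k %in% imaging) {
        state <- evolve_free(state, b$te, kin, bolus, cond, t0 = t)
        mp <- mean(complex(real = state[, cols[1]],
                           imaginary = state[, cols[2]]))
        demod <- 2 * pi * ((fr * (t + b$te)) %% 1) + b$phases[k] * pi / 180
        acc <- acc + mp * exp(-1i * demod)
        state <- evolve_free(state, b$tr - b$te, kin, bolus, cond,
                             t0 = t + b$te)
      } else {
        state <- evolve_free(state, b$tr, kin, bolus, cond, t0 = t)
      }
      if (b$mode == "spoiled") state[, cols[1:2]] <- 0
      t <- t + b$tr
    }
    if (b$mode == "balanced") state[, cols[1:2]] <- 0
    if (b$target == "pyr") {
      pyr_i <- pyr_i + 1
      out[pyr_i] <- acc
    } else {
      lac_i <- lac_i + 1
      out[n_pyr + lac_i] <- acc
    }
    t_cur <- t
  }
  out
}
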