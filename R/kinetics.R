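# Closed-form propagation of the one-way two-pool Bloch-McConnell system.
#
# All simulation happens in a single rotating frame at the pyruvate carrier.
# Each pool's transverse magnetization precesses at its own chemical shift
# (plus B0 offset and isochromat offset); spectral selectivity is ideal, so
# an RF pulse rotates only the targeted pool, about an axis that co-rotates
# with that metabolite's reference frequency. Echo samples are demodulated at
# the same reference frequency.

# stable (exp(a*dt)-1)/a, scalar or vector, real or complex
.g_em1 <- function(a, dt) {
  x <- a * dt
  out <- ifelse(abs(x) < 1e-6,
                dt * (1 + x / 2 + x^2 / 6 + x^3 / 24),
                (exp(x) - 1) / a)
  out
}

# stable (exp(a*dt)-exp(b*dt))/(a-b)
.h_diff <- function(a, b, dt) {
  d <- a - b
  small <- abs(d * dt) < 1e-6
  m <- (a + b) / 2
  y <- d * dt / 2
  ifelse(small,
         dt * exp(m * dt) * (1 + y^2 / 6),
         (exp(a * dt) - exp(b * dt)) / d)
}

# stable (g(a)-g(b))/(a-b) with g = .g_em1 (longitudinal bolus gain)
.q_diff <- function(a, b, dt) {
  d <- a - b
  if (abs(d * dt) < 1e-8) {
    m <- (a + b) / 2
    if (abs(m * dt) < 1e-6) {
      dt^2 * (0.5 + m * dt / 3 + (m * dt)^2 / 8)
    } else {
      (dt * exp(m * dt) - .g_em1(m, dt)) / m
    }
  } else {
    (.g_em1(a, dt) - .g_em1(b, dt)) / d
  }
}

#' Zero magnetization state
#'
#' One row per isochromat; columns `Mx_pyr, My_pyr, Mz_pyr, Mx_lac, My_lac,
#' Mz_lac` in units of the total bolus input.
#'
#' @param cond a [field_conditions()] object
#' @return numeric matrix `n_isochromats` x 6
#' @export
init_state <- function(cond = field_conditions()) {
  matrix(0, nrow = cond$n_isochromats, ncol = 6)
}

evolve_piece_r <- function(state, dt, u, kin, cond, offs) {
  tp <- 2 * pi
  P <- complex(real = state[, 1], imaginary = state[, 2])
  L <- complex(real = state[, 4], imaginary = state[, 5])
  Pz <- state[, 3]
  Lz <- state[, 6]

  ap <- complex(real = -1 / kin$T2_pyr - kin$kPL,
                imaginary = tp * (kin$omega_pyr + cond$b0_offset + offs))
  bl <- complex(real = -1 / kin$T2_lac,
                imaginary = tp * (kin$omega_lac + cond$b0_offset + offs))
  Lnew <- exp(bl * dt) * L + kin$kPL * .h_diff(ap, bl, dt) * P
  Pnew <- exp(ap * dt) * P

  a2 <- -1 / kin$T1_pyr - kin$kPL
  b2 <- -1 / kin$T1_lac
  Lznew <- exp(b2 * dt) * Lz + kin$kPL * .h_diff(a2, b2, dt) * Pz +
    u * kin$kPL * .q_diff(a2, b2, dt)
  Pznew <- exp(a2 * dt) * Pz + u * .g_em1(a2, dt)

  state[, 1] <- Re(Pnew); state[, 2] <- Im(Pnew); state[, 3] <- Pznew
  state[, 4] <- Re(Lnew); state[, 5] <- Im(Lnew); state[, 6] <- Lznew
  state
}

# split [t0, t1] into sub-intervals with piecewise-constant bolus rate:
# 10 ms sub-steps while the bolus is active, single steps elsewhere
split_bolus_interval <- function(t0, t1, bolus, max_step = 0.01) {
  if (t1 <= t0 + 1e-15) return(NULL)
  if (is.null(bolus) || bolus$total_input == 0) {
    return(list(dt = t1 - t0, u = 0))
  }
  w0 <- bolus$t_arrival
  w1 <- bolus_end_time(bolus)
  pts <- sort(unique(pmin(pmax(c(w0, w1), t0), t1)))
  pts <- unique(c(t0, pts, t1))
  dt_all <- numeric(0)
  u_all <- numeric(0)
  for (i in seq_len(length(pts) - 1)) {
    a <- pts[i]; b <- pts[i + 1]
    if (b <= a + 1e-15) next
    if (b > w0 && a < w1) {
      n <- ceiling((b - a) / max_step)
      bd <- seq(a, b, length.out = n + 1)
      mid <- (bd[-1] + bd[-(n + 1)]) / 2
      dt_all <- c(dt_all, diff(bd))
      u_all <- c(u_all, bolus_input_rate(mid, bolus))
    } else {
      dt_all <- c(dt_all, b - a)
      u_all <- c(u_all, 0)
    }
  }
  list(dt = dt_all, u = u_all)
}

#' Free evolution of the magnetization state
#'
#' Propagates relaxation, chemical-shift precession, one-way exchange (acting
#' on all three components of each pool) and longitudinal bolus inflow over
#' `dt` seconds, using the exact matrix-exponential solution of the linear
#' system. The gamma bolus is integrated by the closed form of a
#' piecewise-constant-rate approximation on 10 ms sub-steps.
#'
#' @param state magnetization matrix from [init_state()]
#' @param dt interval length, s (>= 0)
#' @param kin a [kinetic_params()] object
#' @param bolus a [bolus_params()] object, or `NULL` for no inflow
#' @param cond a [field_conditions()] object
#' @param t0 absolute start time of the interval, s (bolus timing reference)
#' @return evolved state matrix
#' @export
evolve_free <- function(state, dt, kin, bolus = NULL,
                        cond = field_conditions(), t0 = 0) {
  if (dt < 0) stop("dt must be >= 0")
  if (dt == 0) return(state)
  offs <- isochromat_offsets(cond)
  stopifnot(nrow(state) == length(offs))
  seg <- split_bolus_interval(t0, t0 + dt, bolus)
  for (i in seq_along(seg$dt)) {
    state <- evolve_piece_r(state, seg$dt[i], seg$u[i], kin, cond, offs)
  }
  state
}

#' Instantaneous spectrally selective RF rotation
#'
#' Rotates only the targeted metabolite's magnetization, in every isochromat,
#' by `flip * b1_scale` degrees about the in-plane axis at `phase` degrees
#' (ideal spectral selectivity; the other pool is untouched).
#'
#' @param state magnetization matrix from [init_state()]
#' @param flip nominal flip angle, degrees
#' @param phase RF axis phase, degrees
#' @param target `"pyr"` or `"lac"`
#' @param cond a [field_conditions()] object (supplies `b1_scale`)
#' @return rotated state matrix
#' @export
apply_rf <- function(state, flip, phase, target = c("pyr", "lac"),
                     cond = field_conditions()) {
  target <- match.arg(target)
  th <- flip * cond$b1_scale * pi / 180
  ph <- phase * pi / 180
  ux <- cos(ph); uy <- sin(ph)
  cs <- cos(th); sn <- sin(th)
  R <- matrix(c(cs + (1 - cs) * ux^2, (1 - cs) * ux * uy, sn * uy,
                (1 - cs) * ux * uy, cs + (1 - cs) * uy^2, -sn * ux,
                -sn * uy, sn * ux, cs),
              nrow = 3, byrow = TRUE)
  idx <- if (target == "pyr") 1:3 else 4:6
  state[, idx] <- state[, idx, drop = FALSE] %*% t(R)
  state
}

# --- event compilation -----------------------------------------------------

# Flatten a schedule + bolus into the numeric event table consumed by the
# compiled kernel. Events do not depend on kPL, relaxation, B0/B1 or the
# isochromat set, so one compilation serves a whole dictionary.
compile_events <- function(schedule, bolus) {
  blocks <- schedule$blocks
  ref <- schedule$ref_freqs
  counts <- schedule_sample_counts(schedule)
  n_out <- sum(counts)
  w0 <- bolus$t_arrival
  w1 <- bolus_end_time(bolus)

  rows <- vector("list", 8L * sum(vapply(blocks, function(b)
    length(b$flips), 0L)) + 4L * length(blocks) + 16L)
  ri <- 0L
  add <- function(m) {
    ri <<- ri + 1L
    rows[[ri]] <<- m
  }
  evolve_rows <- function(t0, t1) {
    seg <- split_bolus_interval(t0, t1, bolus)
    if (is.null(seg)) return(NULL)
    cbind(1, seg$dt, seg$u, 0)
  }

  times_pyr <- numeric(counts["pyr"])
  times_lac <- numeric(counts["lac"])
  pyr_i <- 0L; lac_i <- 0L
  t_cur <- min(0, w0, blocks[[1]]$start_time)

  for (b in blocks) {
    gr <- evolve_rows(t_cur, b$start_time)
    if (!is.null(gr)) add(gr)
    t <- b$start_time
    np <- length(b$flips)
    tid <- if (b$target == "pyr") 1 else 2
    fr <- ref[[b$target]]
    if (tid == 1) {
      pyr_i <- pyr_i + 1L
      out_idx <- pyr_i
    } else {
      lac_i <- lac_i + 1L
      out_idx <- counts[["pyr"]] + lac_i
    }
    t_pulse <- t + (seq_len(np) - 1) * b$tr
    # acquired echoes: the imaging excitations (catalyzation /
    # de-catalyzation pulses are preparation only and are not sampled);
    # all echoes of a block accumulate into its single complex sample
    imaging <- seq(b$n_cat + 1, b$n_cat + b$n_exc)
    t_samp <- t_pulse[b$sample_index] + b$te
    if (tid == 1) times_pyr[pyr_i] <- t_samp else times_lac[lac_i] <- t_samp
    axes <- b$phases + 360 * ((fr * t_pulse) %% 1)
    # receiver phase tracks the transmit phase cycling
    demod <- 2 * pi * ((fr * (t_pulse + b$te)) %% 1) + b$phases * pi / 180
    block_end <- t + np * b$tr

    if (t >= w1 || block_end <= w0) {
      # fast path: bolus inactive throughout the block
      is_img <- seq_len(np) %in% imaging
      nr <- 2L * np + 2L * sum(is_img)
      M <- matrix(0, nrow = nr, ncol = 4)
      pos <- cumsum(ifelse(is_img, 4L, 2L))
      p0 <- pos - ifelse(is_img, 4L, 2L)  # row offset before each excitation
      M[p0 + 1L, ] <- cbind(2, tid, b$flips, axes)
      img <- which(is_img)
      M[p0[img] + 2L, ] <- matrix(c(1, b$te, 0, 0), nrow = length(img),
                                  ncol = 4, byrow = TRUE)
      M[p0[img] + 3L, ] <- cbind(3, tid, out_idx, demod[img])
      M[p0[img] + 4L, ] <- matrix(c(1, b$tr - b$te, 0, 0),
                                  nrow = length(img), ncol = 4, byrow = TRUE)
      oth <- which(!is_img)
      if (length(oth)) {
        M[p0[oth] + 2L, ] <- matrix(c(1, b$tr, 0, 0), nrow = length(oth),
                                    ncol = 4, byrow = TRUE)
      }
      if (b$mode == "spoiled") {
        out <- vector("list", np)
        for (k in seq_len(np)) {
          out[[k]] <- rbind(M[(p0[k] + 1):pos[k], , drop = FALSE],
                            c(4, tid, 0, 0))
        }
        M <- do.call(rbind, out)
      }
      add(M)
    } else {
      # slow path: bolus active, sub-step every inter-pulse interval
      for (k in seq_len(np)) {
        add(matrix(c(2, tid, b$flips[k], axes[k]), nrow = 1))
        if (k %in% imaging) {
          er <- evolve_rows(t_pulse[k], t_pulse[k] + b$te)
          if (!is.null(er)) add(er)
          add(matrix(c(3, tid, out_idx, demod[k]), nrow = 1))
          er <- evolve_rows(t_pulse[k] + b$te, t_pulse[k] + b$tr)
          if (!is.null(er)) add(er)
        } else {
          er <- evolve_rows(t_pulse[k], t_pulse[k] + b$tr)
          if (!is.null(er)) add(er)
        }
        if (b$mode == "spoiled") add(matrix(c(4, tid, 0, 0), nrow = 1))
      }
    }
    if (b$mode == "balanced") add(matrix(c(4, tid, 0, 0), nrow = 1))
    t_cur <- block_end
  }

  ev <- do.call(rbind, rows[seq_len(ri)])
  # drop degenerate evolution rows, then index unique interval lengths
  keep <- !(ev[, 1] == 1 & ev[, 2] <= 1e-15)
  ev <- ev[keep, , drop = FALSE]
  sel <- ev[, 1] == 1
  keys <- signif(ev[sel, 2], 12)
  dts <- unique(keys)
  ev[sel, 2] <- match(keys, dts)

  list(events = ev, dts = dts, n_out = n_out,
       times_pyr = times_pyr, times_lac = times_lac, counts = counts)
}

#' Simulate a fingerprint for a schedule and parameter set
#'
#' Steps chronologically through every acquisition block of the schedule,
#' applying catalyzation ramps, phase-alternated bSSFP excitations (or
#' spoiled GRE excitations) and exact free evolution between pulses, and
#' records one complex echo sample per block (the isochromat-mean transverse
#' magnetization of the target metabolite at the designated center-of-k-space
#' excitation, demodulated at that metabolite's reference frequency).
#'
#' The returned signal vector holds all pyruvate samples (in time order)
#' followed by all lactate samples.
#'
#' @param schedule a [build_schedule()] object
#' @param kin a [kinetic_params()] object
#' @param bolus a [bolus_params()] object
#' @param cond a [field_conditions()] object
#' @param events precompiled event table from `compile_events` (internal
#'   speed-up for dictionary generation); leave `NULL` normally
#' @return object of class `fingerprint` with elements `signal` (complex),
#'   `times` (s), `metabolite`, and `meta`
#' @export
simulate_fingerprint <- function(schedule, kin = kinetic_params(),
                                 bolus = bolus_params(),
                                 cond = field_conditions(),
                                 events = NULL) {
  stopifnot(inherits(schedule, "sequence_schedule"))
  if (is.null(events)) events <- compile_events(schedule, bolus)
  offs <- isochromat_offsets(cond)
  sig <- .bm_simulate_cpp(events$events, events$dts,
                          kin$kPL, kin$T1_pyr, kin$T1_lac,
                          kin$T2_pyr, kin$T2_lac,
                          kin$omega_pyr + cond$b0_offset,
                          kin$omega_lac + cond$b0_offset,
                          offs, cond$b1_scale, events$n_out)
  structure(list(signal = sig,
                 times = c(events$times_pyr, events$times_lac),
                 metabolite = rep(c("pyr", "lac"), events$counts),
                 meta = list(design_id = schedule$design_id, kin = kin,
                             bolus = bolus, cond = cond)),
            class = "fingerprint")
}

#' Precompiled fingerprint simulator
#'
#' Returns a closure `function(kPL)` that simulates fingerprints for varying
#' conversion rates with the schedule/bolus event table compiled once. Used
#' by dictionary generation and direct curve fitting, where thousands of
#' forward simulations share the same schedule.
#'
#' @inheritParams simulate_fingerprint
#' @param kin_fixed kinetic parameters whose `kPL` is overridden per call
#' @return function mapping `kPL` (1/s) to a complex signal vector
#' @export
fingerprint_simulator <- function(schedule, kin_fixed = kinetic_params(),
                                  bolus = bolus_params(),
                                  cond = field_conditions()) {
  events <- compile_events(schedule, bolus)
  offs <- isochromat_offsets(cond)
  fp <- kin_fixed$omega_pyr + cond$b0_offset
  fl <- kin_fixed$omega_lac + cond$b0_offset
  function(kPL) {
    .bm_simulate_cpp(events$events, events$dts,
                     kPL, kin_fixed$T1_pyr, kin_fixed$T1_lac,
                     kin_fixed$T2_pyr, kin_fixed$T2_lac,
                     fp, fl, offs, cond$b1_scale, events$n_out)
  }
}

#' @export
print.fingerprint <- function(x, ...) {
  n <- table(x$metabolite)
  cat(sprintf(
    "<fingerprint> %s: %d pyruvate + %d lactate samples over %.1f s\n",
    x$meta$design_id, n[["pyr"]], n[["lac"]], max(x$times)))
  invisible(x)
}

#' Export a fingerprint to CSV
#'
#' Columns `time_s`, `metabolite`, `real`, `imag`.
#'
#' @param fp a `fingerprint`
#' @param path output file
#' @export
write_fingerprint_csv <- function(fp, path) {
  utils::write.csv(
    data.frame(time_s = fp$times, metabolite = fp$metabolite,
               real = Re(fp$signal), imag = Im(fp$signal)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_csv
#' @export
read_fingerprint_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(signal = complex(real = d$real, imaginary = d$imag),
                 times = d$time_s, metabolite = d$metabolite,
                 meta = list()),
            class = "fingerprint")
}
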