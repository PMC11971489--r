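#' Complex noise specification for Monte Carlo evaluation
#'
#' `sigma` is the SD of both the real and the imaginary channel noise, in
#' units of the relaxation-free total bolus signal (the same units as the raw
#' fingerprints, whose total bolus input is 1).
#'
#' @param sigma noise SD per channel (>= 0)
#' @param n_iter Monte Carlo iterations per (kPL, sigma) combination
#' @param seed master seed; every (entry, sigma) combination derives its own
#'   reproducible stream from it
#' @export
noise_spec <- function(sigma, n_iter = 10000, seed = 1) {
  stopifnot(sigma >= 0, n_iter >= 1)
  structure(list(sigma = sigma, n_iter = n_iter, seed = as.integer(seed)),
            class = "noise_spec")
}

# derived stream seed, kept below 2^31; doubles are exact well past this range
stream_seed <- function(seed, entry_index, sigma_index, extra = 0) {
  as.integer((abs(seed) * 100003 + entry_index * 10007 +
                sigma_index * 101 + extra) %% 2147483629 + 1)
}

#' Add reproducible complex Gaussian noise to a signal
#'
#' i.i.d. Gaussian noise of SD `noise$sigma` is added to the real and
#' imaginary parts of every sample. The draw is a pure function of
#' `(noise$seed, draw_index, noise$sigma)`, so individual realizations can be
#' reproduced in any order.
#'
#' @param signal complex vector (un-normalized, total-bolus units)
#' @param noise a [noise_spec()] object
#' @param draw_index index of the realization
#' @return noisy complex vector
#' @export
add_noise <- function(signal, noise, draw_index = 1) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma == 0) return(signal)
  n <- length(signal)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(stream_seed(noise$seed, 0, round(noise$sigma * 1e6), draw_index))
  signal + complex(real = stats::rnorm(n, 0, noise$sigma),
                   imaginary = stats::rnorm(n, 0, noise$sigma))
}

#' Monte Carlo noise-robustness evaluation of dictionary matching
#'
#' For every requested (kPL, sigma) combination, adds `n_iter` independent
#' complex-noise realizations to the raw (amplitude-true) fingerprint of that
#' dictionary entry, template-matches each realization against the full
#' unit-norm dictionary, and summarizes the fitted kPL distribution: mean,
#' SD, percent bias of the mean, coefficient of variation
#' (CV = 100 * SD / mean), and the fraction of individual runs within 1% of
#' truth.
#'
#' Noise streams are derived per (entry, sigma) from the master seed, so any
#' subset of combinations reproduces the same estimates regardless of
#' execution order.
#'
#' @param dict an `mrf_dictionary`
#' @param sigmas noise SD levels (total-bolus-signal units)
#' @param n_iter iterations per combination
#' @param seed master seed
#' @param kpl_subset optional kPL values (matched to nearest grid entries);
#'   default: the full grid
#' @param chunk_size realizations matched per block (memory bound)
#' @param return_estimates also return the raw fitted kPL draws
#' @return object of class `mc_summary`: a data.frame with one row per
#'   (kPL, sigma) and columns `kpl_true`, `sigma`, `n_iter`, `mean_kpl`,
#'   `sd_kpl`, `bias_pct`, `cv_pct`, `frac_runs_lt_1pct`,
#'   `mean_bias_lt_0.1pct`; attribute `design_id`; attribute `estimates`
#'   (list of numeric vectors) if requested
#' @export
run_monte_carlo <- function(dict, sigmas, n_iter = 1000, seed = 1,
                            kpl_subset = NULL, chunk_size = 2000,
                            return_estimates = FALSE) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  if (length(sigmas) == 0) stop("empty sigma list")
  grid <- dict$kpl_grid
  idx <- if (is.null(kpl_subset)) {
    seq_along(grid)
  } else {
    vapply(kpl_subset, function(k) which.min(abs(grid - k)), 0L)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  ent_t <- Conj(t(dict$entries))
  len <- ncol(dict$entries)
  rows <- vector("list", length(idx) * length(sigmas))
  ests <- if (return_estimates) vector("list", length(rows)) else NULL
  r <- 0L
  for (i in idx) {
    raw <- dict$entries[i, ] * dict$raw_norms[i]
    for (si in seq_along(sigmas)) {
      sg <- sigmas[si]
      set.seed(stream_seed(seed, i, si))
      est <- numeric(n_iter)
      done <- 0L
      while (done < n_iter) {
        nb <- min(chunk_size, n_iter - done)
        noisy <- matrix(raw, nrow = nb, ncol = len, byrow = TRUE)
        if (sg > 0) {
          noisy <- noisy +
            complex(real = stats::rnorm(nb * len, 0, sg),
                    imaginary = stats::rnorm(nb * len, 0, sg))
        }
        g <- Mod(noisy %*% ent_t)
        best <- max.col(g, ties.method = "first")
        est[(done + 1):(done + nb)] <- grid[best]
        done <- done + nb
      }
      true <- grid[i]
      m <- mean(est)
      s <- stats::sd(est)
      r <- r + 1L
      rows[[r]] <- data.frame(
        kpl_true = true, sigma = sg, n_iter = n_iter,
        mean_kpl = m, sd_kpl = s,
        bias_pct = if (true > 0) 100 * (m - true) / true else NA_real_,
        cv_pct = if (m > 0) 100 * s / m else NA_real_,
        frac_runs_lt_1pct = if (true > 0) {
          mean(abs(est - true) < 0.01 * true)
        } else {
          mean(est == 0)
        },
        mean_bias_lt_0.1pct = if (true > 0) {
          abs(m - true) / true < 0.001
        } else {
          m == 0
        })
      if (return_estimates) ests[[r]] <- est
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "design_id") <- dict$spec$schedule$design_id
  if (return_estimates) attr(out, "estimates") <- ests
  class(out) <- c("mc_summary", class(out))
  out
}

#' Aggregate Monte Carlo fractions
#'
#' Pools a Monte Carlo summary over its (kPL, sigma) combinations and
#' reports (a) the percentage of all individual runs whose estimate deviates
#' from truth by less than 1%, and (b) the percentage of combinations whose
#' mean estimate deviates from truth by less than 0.1%.
#'
#' @param mc an `mc_summary` from [run_monte_carlo()]
#' @return list with `pct_runs_bias_lt_1`, `pct_points_mean_bias_lt_0.1`
#' @export
mc_fractions <- function(mc) {
  list(pct_runs_bias_lt_1 = 100 * mean(mc$frac_runs_lt_1pct),
       pct_points_mean_bias_lt_0.1 = 100 * mean(mc$mean_bias_lt_0.1pct))
}
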