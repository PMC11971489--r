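#' Kinetic and spectral constants of a fingerprint
#'
#' Bundles the eight per-pool constants of the two-pool pyruvate/lactate
#' exchange model. Defaults are the fixed dictionary values used throughout:
#' frequencies 0 / 392 Hz, T1 30 / 25 s, T2 0.5 / 1 s.
#'
#' @param kPL pyruvate-to-lactate conversion rate, 1/s (>= 0)
#' @param T1_pyr,T1_lac longitudinal relaxation times, s
#' @param T2_pyr,T2_lac transverse relaxation times, s
#' @param omega_pyr,omega_lac chemical-shift frequencies, Hz
#' @return object of class `kinetic_params`
#' @export
kinetic_params <- function(kPL = 0, T1_pyr = 30, T1_lac = 25,
                           T2_pyr = 0.5, T2_lac = 1,
                           omega_pyr = 0, omega_lac = 392) {
  stopifnot(kPL >= 0, T1_pyr > 0, T1_lac > 0, T2_pyr > 0, T2_lac > 0)
  structure(list(kPL = kPL, T1_pyr = T1_pyr, T1_lac = T1_lac,
                 T2_pyr = T2_pyr, T2_lac = T2_lac,
                 omega_pyr = omega_pyr, omega_lac = omega_lac),
            class = "kinetic_params")
}

#' Gamma-variate bolus input
#'
#' The pyruvate inflow is a gamma-variate rate
#' `u(t) = total_input * dgamma(t - t_arrival, shape_alpha, scale = beta)`.
#' The scale `beta` is chosen so that 99% of the input is delivered within
#' `t_duration` seconds of arrival; the gamma shape itself is configurable.
#'
#' @param t_arrival bolus arrival time relative to acquisition start, s
#'   (negative values mean the bolus starts before the first excitation)
#' @param t_duration bolus duration, s; the window after arrival containing
#'   99% of the input
#' @param shape_alpha gamma shape parameter (dimensionless, > 0)
#' @param total_input total delivered longitudinal magnetization; all signals
#'   are expressed in units of this quantity (the relaxation-free total bolus
#'   signal), so it defaults to 1
#' @return object of class `bolus_params`; element `scale` holds the implied
#'   gamma scale parameter, s
#' @export
bolus_params <- function(t_arrival = -4, t_duration = 12,
                         shape_alpha = 2, total_input = 1) {
  stopifnot(t_duration > 0, shape_alpha > 0, total_input >= 0)
  scale <- t_duration / stats::qgamma(0.99, shape = shape_alpha)
  structure(list(t_arrival = t_arrival, t_duration = t_duration,
                 shape_alpha = shape_alpha, total_input = total_input,
                 scale = scale),
            class = "bolus_params")
}

#' Instantaneous bolus input rate
#'
#' @param t time, s (vectorized)
#' @param bolus a [bolus_params()] object
#' @return input rate in magnetization per second; zero before arrival
#' @export
bolus_input_rate <- function(t, bolus) {
  stopifnot(inherits(bolus, "bolus_params"))
  bolus$total_input *
    stats::dgamma(t - bolus$t_arrival, shape = bolus$shape_alpha,
                  scale = bolus$scale)
}

# time after which the remaining bolus mass is < 1e-9 of the total
bolus_end_time <- function(bolus) {
  bolus$t_arrival +
    stats::qgamma(1 - 1e-9, shape = bolus$shape_alpha) * bolus$scale
}

#' Field conditions: B1 scale, B0 offset, intravoxel linewidth
#'
#' The intravoxel off-resonance distribution is modeled by `n_isochromats`
#' frequency offsets placed at equally spaced quantiles of a Lorentzian
#' (default) or Gaussian line of full width at half maximum `linewidth_fwhm`,
#' truncated at +/- 3 FWHM. `n_isochromats` must be odd so that the
#' zero-offset isochromat is always present.
#'
#' @param b1_scale dimensionless multiplier applied to every flip angle
#' @param b0_offset bulk frequency error added to both metabolite
#'   frequencies, Hz
#' @param linewidth_fwhm FWHM of the intravoxel frequency distribution, Hz
#' @param n_isochromats number of isochromats (odd, >= 1)
#' @param lineshape `"lorentzian"` or `"gaussian"`
#' @return object of class `field_conditions`
#' @export
field_conditions <- function(b1_scale = 1, b0_offset = 0,
                             linewidth_fwhm = 5, n_isochromats = 101,
                             lineshape = c("lorentzian", "gaussian")) {
  lineshape <- match.arg(lineshape)
  stopifnot(b1_scale > 0, linewidth_fwhm >= 0, n_isochromats >= 1)
  if (n_isochromats %% 2 == 0)
    stop("n_isochromats must be odd so the zero-offset isochromat exists")
  structure(list(b1_scale = b1_scale, b0_offset = b0_offset,
                 linewidth_fwhm = linewidth_fwhm,
                 n_isochromats = n_isochromats, lineshape = lineshape),
            class = "field_conditions")
}

#' Isochromat frequency offsets implied by the field conditions
#'
#' @param cond a [field_conditions()] object
#' @return numeric vector of length `n_isochromats`, Hz, symmetric about zero
#' @export
isochromat_offsets <- function(cond) {
  stopifnot(inherits(cond, "field_conditions"))
  n <- cond$n_isochromats
  lw <- cond$linewidth_fwhm
  if (lw == 0 || n == 1) return(rep(0, n))
  trunc <- 3 * lw
  p <- (seq_len(n) - 0.5) / n
  if (cond$lineshape == "lorentzian") {
    gam <- lw / 2
    plo <- stats::pcauchy(-trunc, scale = gam)
    phi <- stats::pcauchy(trunc, scale = gam)
    stats::qcauchy(plo + p * (phi - plo), scale = gam)
  } else {
    sdv <- lw / (2 * sqrt(2 * log(2)))
    plo <- stats::pnorm(-trunc, sd = sdv)
    phi <- stats::pnorm(trunc, sd = sdv)
    stats::qnorm(plo + p * (phi - plo), sd = sdv)
  }
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Two-pool kinetic parameters\n")
  cat(sprintf("  kPL = %g 1/s\n", x$kPL))
  cat(sprintf("  pyruvate: T1 = %g s, T2 = %g s, omega = %g Hz\n",
              x$T1_pyr, x$T2_pyr, x$omega_pyr))
  cat(sprintf("  lactate:  T1 = %g s, T2 = %g s, omega = %g Hz\n",
              x$T1_lac, x$T2_lac, x$omega_lac))
  invisible(x)
}

#' @export
print.bolus_params <- function(x, ...) {
  cat(sprintf(
    "Gamma bolus: arrival %g s, duration %g s (shape %g, scale %.4g s)\n",
    x$t_arrival, x$t_duration, x$shape_alpha, x$scale))
  invisible(x)
}

#' @export
print.field_conditions <- function(x, ...) {
  cat(sprintf(
    "Field conditions: B1 x%g, B0 %+g Hz, LW %g Hz (%s, %d isochromats)\n",
    x$b1_scale, x$b0_offset, x$linewidth_fwhm, x$lineshape, x$n_isochromats))
  invisible(x)
}
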