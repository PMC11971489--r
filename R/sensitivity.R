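# default per-parameter test ranges; relaxation/field ranges follow the
# published sweep protocol, bolus timing ranges are symmetric about the
# nominal arrival (-4 s) and duration (12 s)
.sens_ranges <- list(
  T1_pyr = c(20, 40), T1_lac = c(15, 30),
  T2_pyr = c(0.3, 0.7), T2_lac = c(0.6, 1.4),
  b1_scale = c(0.8, 1.2), b0_offset = c(-15, 15),
  linewidth = c(0.2, 9.8),
  bolus_arrival = c(-8, 0), bolus_duration = c(8, 16))

#' Specification of a fixed-parameter sensitivity sweep
#'
#' One nuisance parameter is swept over a test range while simulated
#' (noise-free) signals at a fixed true kPL are matched against the nominal
#' dictionary. All sweeps use `n_test` equally spaced values (default 21);
#' default ranges bracket the nominal dictionary value of each parameter.
#'
#' @param parameter one of `"T1_pyr"`, `"T1_lac"`, `"T2_pyr"`, `"T2_lac"`,
#'   `"bolus_arrival"`, `"bolus_duration"`, `"b1_scale"`, `"b0_offset"`,
#'   `"linewidth"`
#' @param test_min,test_max sweep range (parameter units); defaults per
#'   parameter
#' @param n_test number of equally spaced test values
#' @param kpl_true simulated conversion rate, 1/s
#' @export
sensitivity_spec <- function(parameter, test_min = NULL, test_max = NULL,
                             n_test = 21, kpl_true = 0.02) {
  if (!parameter %in% names(.sens_ranges))
    stop("unknown sensitivity parameter: ", parameter)
  rng <- .sens_ranges[[parameter]]
  if (is.null(test_min)) test_min <- rng[1]
  if (is.null(test_max)) test_max <- rng[2]
  stopifnot(test_min < test_max, n_test >= 2)
  structure(list(parameter = parameter,
                 test_values = seq(test_min, test_max, length.out = n_test),
                 kpl_true = kpl_true),
            class = "sensitivity_spec")
}

perturb_params <- function(parameter, value, kin, bolus, cond) {
  switch(parameter,
    T1_pyr = kin$T1_pyr <- value,
    T1_lac = kin$T1_lac <- value,
    T2_pyr = kin$T2_pyr <- value,
    T2_lac = kin$T2_lac <- value,
    b1_scale = cond$b1_scale <- value,
    b0_offset = cond$b0_offset <- value,
    linewidth = cond$linewidth_fwhm <- value,
    bolus_arrival = bolus <- bolus_params(value, bolus$t_duration,
                                          bolus$shape_alpha,
                                          bolus$total_input),
    bolus_duration = bolus <- bolus_params(bolus$t_arrival, value,
                                           bolus$shape_alpha,
                                           bolus$total_input))
  list(kin = kin, bolus = bolus, cond = cond)
}

#' Run a fixed-parameter sensitivity sweep
#'
#' Simulates noise-free test fingerprints at `spec$kpl_true` with one
#' nuisance parameter perturbed away from its nominal (dictionary) value, and
#' matches each against the unperturbed dictionary. The signed error
#' convention is `fitted - true`.
#'
#' @param spec a [sensitivity_spec()] object
#' @param dict the nominal `mrf_dictionary` (built at the nominal parameter
#'   values)
#' @return object of class `sensitivity_curve`: data.frame with
#'   `test_value`, `fitted_kpl`, `abs_error` (1/s), `rel_error_pct`;
#'   attributes `max_abs_error` and `signed_extreme` (the error of largest
#'   magnitude, keeping its sign)
#' @export
run_sensitivity <- function(spec, dict) {
  stopifnot(inherits(spec, "sensitivity_spec"),
            inherits(dict, "mrf_dictionary"))
  dspec <- dict$spec
  kin0 <- dspec$kin_fixed
  kin0$kPL <- spec$kpl_true
  schedule <- dspec$schedule
  events_nominal <- compile_events(schedule, dspec$bolus)
  bolus_swept <- spec$parameter %in% c("bolus_arrival", "bolus_duration")

  fitted <- vapply(spec$test_values, function(v) {
    p <- perturb_params(spec$parameter, v, kin0, dspec$bolus, dspec$cond)
    ev <- if (bolus_swept) NULL else events_nominal
    fp <- simulate_fingerprint(schedule, p$kin, p$bolus, p$cond, events = ev)
    match_fingerprint(fp$signal, dict)$kpl_hat
  }, 0)

  err <- fitted - spec$kpl_true
  out <- data.frame(test_value = spec$test_values, fitted_kpl = fitted,
                    abs_error = err,
                    rel_error_pct = 100 * err / spec$kpl_true)
  attr(out, "parameter") <- spec$parameter
  attr(out, "max_abs_error") <- max(abs(err))
  attr(out, "signed_extreme") <- err[which.max(abs(err))]
  class(out) <- c("sensitivity_curve", class(out))
  out
}
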