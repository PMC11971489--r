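#' Sigmoid excitation schedule parameters
#'
#' The variable flip angle design ramps the pyruvate excitation from
#' `alpha_min` to `alpha_max` following a logistic curve with midpoint
#' `t_mid` (defaults 5 deg, 80 deg, 20 s).
#'
#' @param alpha_min,alpha_max minimum / maximum flip angle, degrees
#' @param t_mid logistic midpoint, seconds after acquisition start
#' @export
sigmoid_params <- function(alpha_min = 5, alpha_max = 80, t_mid = 20) {
  stopifnot(alpha_max > alpha_min, alpha_min >= 0)
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max, t_mid = t_mid),
            class = "sigmoid_params")
}

#' Sigmoid flip angle at a given time
#'
#' `alpha(t) = alpha_min + (alpha_max - alpha_min) / (1 + exp(t_mid - t))`,
#' evaluated per excitation at its absolute time since acquisition start.
#'
#' @param t elapsed time since acquisition start, s (vectorized)
#' @param p a [sigmoid_params()] object
#' @return flip angle(s), degrees
#' @export
sigmoid_flip <- function(t, p = sigmoid_params()) {
  p$alpha_min + (p$alpha_max - p$alpha_min) / (1 + exp(p$t_mid - t))
}

#' Catalyzation / de-catalyzation ramp
#'
#' Nonlinear preparation ramp easing magnetization into (or out of) the bSSFP
#' steady state. The default profile is `alpha_edge * sin^2(i*pi/(2*n_cat))`,
#' `i = 1..n_cat`, ending exactly at the edge imaging tip angle; the
#' de-catalyzation ramp is its mirror image.
#'
#' @param alpha_edge the first (up) or last (down) imaging tip angle, degrees
#' @param n_cat number of ramp pulses (>= 0)
#' @param direction `"up"` or `"down"`
#' @return numeric vector of `n_cat` flip angles, degrees
#' @export
catalyzation_ramp <- function(alpha_edge, n_cat, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (n_cat < 0) stop("n_cat must be >= 0")
  if (n_cat == 0) return(numeric(0))
  ramp <- alpha_edge * sin(seq_len(n_cat) * pi / (2 * n_cat))^2
  if (direction == "down") rev(ramp) else ramp
}

make_bssfp_block <- function(start_time, target, tr, imaging_flips, n_cat) {
  flips <- c(catalyzation_ramp(imaging_flips[1], n_cat, "up"),
             imaging_flips,
             catalyzation_ramp(imaging_flips[length(imaging_flips)],
                               n_cat, "down"))
  phases <- rep_len(c(0, 180), length(flips))
  list(start_time = start_time, target = target, mode = "balanced",
       tr = tr, te = tr / 2, n_exc = length(imaging_flips), n_cat = n_cat,
       flips = flips, phases = phases,
       sample_index = n_cat + floor(length(imaging_flips) / 2) + 1L)
}

# Multi-slice 2D GRE block: the slice-revisit time `tr` is divided among the
# n_exc slice excitations, all of which drive the (non-spatially-resolved)
# two-pool system; transverse magnetization is spoiled after every readout.
make_gre_block <- function(start_time, target, tr, flip, readout, n_exc) {
  list(start_time = start_time, target = target, mode = "spoiled",
       tr = tr / n_exc, te = readout / 2, n_exc = as.integer(n_exc),
       n_cat = 0L,
       flips = rep(flip, n_exc), phases = rep(0, n_exc),
       sample_index = floor(n_exc / 2) + 1L)
}

#' Build one of the three interleaved experiment designs
#'
#' Constructs the full excitation schedule for one of the three acquisition
#' designs compared by the framework:
#' * `mrf_sigmoid`: pyruvate 3D bSSFP with sigmoid flip schedule
#'   (5 to 80 deg), TR 15.6 ms; lactate bSSFP 60 deg, TR 15.3 ms; interleave
#'   period 4.1 s.
#' * `mrf_constant`: identical, but constant 30 deg pyruvate flips.
#' * `hybridgre`: pyruvate spoiled multi-slice GRE, 10 deg, TR 1 s, 22 ms
#'   readout; lactate bSSFP 60 deg; interleave period 4.6 s.
#'
#' Each period contains a pyruvate block at its start and a lactate block at
#' the half-period offset. All bSSFP blocks alternate RF phase 0/180 deg and
#' are book-ended by `n_cat` sin^2-profile catalyzation/de-catalyzation
#' pulses tied to the first/last imaging tip. One complex sample per block is
#' recorded at the echo of the center imaging excitation.
#'
#' The per-block excitation count follows the through-plane encoding implied
#' by the nominal geometry: a 33.6 cm slab at 21 mm resolution needs 16 kz
#' phase encodes, with the short (~4 ms) readout covering the in-plane
#' k-space in a single shot per excitation, so `n_exc = 16` by default. The
#' recorded complex sample of a block is the coherent sum of all of its
#' acquired imaging echoes (reconstructed image intensity scales with the
#' total collected k-space signal); catalyzation pulses are not acquired.
#'
#' @param design_id one of `"mrf_sigmoid"`, `"mrf_constant"`, `"hybridgre"`
#' @param total_duration nominal acquisition window, s
#' @param n_exc imaging excitations per bSSFP block
#' @param n_cat catalyzation pulses per ramp
#' @param sigmoid a [sigmoid_params()] object (sigmoid design only)
#' @param flip_pyr,flip_lac imaging flip angles, degrees (constant designs)
#' @param tr_pyr,tr_lac repetition times, s
#' @param temporal_resolution interleave period, s (design default if `NULL`)
#' @param readout_gre GRE readout duration, s (echo at half readout)
#' @return object of class `sequence_schedule`
#' @export
build_schedule <- function(design_id = c("mrf_sigmoid", "mrf_constant",
                                         "hybridgre"),
                           total_duration = 60,
                           n_exc = 16, n_cat = 10,
                           sigmoid = sigmoid_params(),
                           flip_pyr = NULL, flip_lac = 60,
                           tr_pyr = NULL, tr_lac = 0.0153,
                           temporal_resolution = NULL,
                           readout_gre = 0.022) {
  design_id <- match.arg(design_id)
  if (is.null(temporal_resolution))
    temporal_resolution <- if (design_id == "hybridgre") 4.6 else 4.1
  if (is.null(tr_pyr))
    tr_pyr <- if (design_id == "hybridgre") 1.0 else 0.0156
  if (is.null(flip_pyr))
    flip_pyr <- switch(design_id, mrf_constant = 30, hybridgre = 10,
                       mrf_sigmoid = NA)

  n_t <- round(total_duration / temporal_resolution)
  stopifnot(n_t >= 1)
  blocks <- vector("list", 2L * n_t)
  for (k in seq_len(n_t) - 1L) {
    t_pyr <- k * temporal_resolution
    t_lac <- t_pyr + temporal_resolution / 2
    if (design_id == "hybridgre") {
      pb <- make_gre_block(t_pyr, "pyr", tr_pyr, flip_pyr, readout_gre,
                           n_exc)
    } else {
      flips <- if (design_id == "mrf_sigmoid") {
        sigmoid_flip(t_pyr + (n_cat + seq_len(n_exc) - 1) * tr_pyr, sigmoid)
      } else {
        rep(flip_pyr, n_exc)
      }
      pb <- make_bssfp_block(t_pyr, "pyr", tr_pyr, flips, n_cat)
    }
    lb <- make_bssfp_block(t_lac, "lac", tr_lac, rep(flip_lac, n_exc), n_cat)
    blocks[[2L * k + 1L]] <- pb
    blocks[[2L * k + 2L]] <- lb
  }

  sched <- structure(
    list(blocks = blocks, design_id = design_id,
         temporal_resolution = temporal_resolution,
         total_duration = total_duration,
         ref_freqs = c(pyr = 0, lac = 392)),
    class = "sequence_schedule")
  validate_schedule(sched)
  sched
}

validate_schedule <- function(sched) {
  bl <- sched$blocks
  ends <- vapply(bl, function(b) b$start_time + length(b$flips) * b$tr, 0)
  starts <- vapply(bl, function(b) b$start_time, 0)
  if (is.unsorted(starts))
    stop("blocks must be ordered by start time")
  if (any(ends[-length(ends)] > starts[-1] + 1e-12))
    stop("acquisition blocks overlap")
  for (b in bl) {
    stopifnot(length(b$flips) == length(b$phases), b$tr > 0,
              b$sample_index >= 1, b$sample_index <= length(b$flips))
  }
  invisible(sched)
}

schedule_sample_counts <- function(sched) {
  targets <- vapply(sched$blocks, function(b) b$target, "")
  c(pyr = sum(targets == "pyr"), lac = sum(targets == "lac"))
}

#' @export
print.sequence_schedule <- function(x, ...) {
  n <- schedule_sample_counts(x)
  cat(sprintf("<sequence_schedule> %s: %d pyruvate + %d lactate blocks,\n",
              x$design_id, n["pyr"], n["lac"]))
  cat(sprintf("  interleave period %g s, nominal duration %g s\n",
              x$temporal_resolution, x$total_duration))
  invisible(x)
}

#' Serialize a schedule to / from a YAML configuration file
#'
#' The full per-block arrays (flip angles, phases, timing) are written so the
#' round trip preserves the schedule to numeric precision.
#'
#' @param sched a `sequence_schedule`
#' @param path file path
#' @return `read_schedule_yaml` returns a `sequence_schedule`
#' @export
write_schedule_yaml <- function(sched, path) {
  obj <- list(design_id = sched$design_id,
              temporal_resolution = sched$temporal_resolution,
              total_duration = sched$total_duration,
              ref_freqs = as.list(sched$ref_freqs),
              blocks = lapply(sched$blocks, function(b) {
                b$flips <- as.list(b$flips)
                b$phases <- as.list(b$phases)
                b
              }))
  writeLines(yaml::as.yaml(obj, precision = 15L), path)
  invisible(path)
}

#' @rdname write_schedule_yaml
#' @export
read_schedule_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  blocks <- lapply(obj$blocks, function(b) {
    b$flips <- as.numeric(unlist(b$flips))
    b$phases <- as.numeric(unlist(b$phases))
    b$sample_index <- as.integer(b$sample_index)
    b
  })
  sched <- structure(
    list(blocks = blocks, design_id = obj$design_id,
         temporal_resolution = obj$temporal_resolution,
         total_duration = obj$total_duration,
         ref_freqs = unlist(obj$ref_freqs)),
    class = "sequence_schedule")
  validate_schedule(sched)
  sched
}
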