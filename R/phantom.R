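# Synthetic dynamic-image generation and voxel-wise kPL analysis.
#
# The phantom stands in for the in vivo interleaved pyruvate/lactate series:
# two ellipsoidal "kidney" ROIs with distinct conversion rates on a zero-rate
# background, every voxel following the same forward model as the dictionary,
# plus i.i.d. complex Gaussian noise per voxel, channel and frame.

#' Specification of the synthetic dynamic phantom
#'
#' @param shape grid dimensions `c(nx, ny, nz)`
#' @param roi_kpl conversion rates of the two ellipsoidal ROIs, 1/s
#' @param sigma complex channel noise SD (total-bolus-signal units)
#' @param seed RNG seed for the noise
#' @param voxel_mm voxel size, mm
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(shape = c(12, 12, 3), roi_kpl = c(0.02, 0.05),
                         sigma = 0.1, seed = 1, voxel_mm = c(2.5, 2.5, 21)) {
  stopifnot(length(shape) == 3, all(shape >= 1), shape[1] >= 8,
            shape[2] >= 8, length(roi_kpl) == 2,
            all(roi_kpl >= 0), sigma >= 0)
  structure(list(shape = shape, roi_kpl = roi_kpl, sigma = sigma,
                 seed = as.integer(seed), voxel_mm = voxel_mm),
            class = "phantom_spec")
}

# two disjoint ellipsoids, mirrored left/right, on all slices
phantom_truth_map <- function(spec) {
  d <- spec$shape
  kpl <- array(0, dim = d)
  roi <- array(0L, dim = d)
  cx <- c(0.3, 0.7) * (d[1] + 1)
  cy <- 0.5 * (d[2] + 1)
  rx <- d[1] / 8
  ry <- d[2] / 4
  for (k in 1:2) {
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
      if (((x - cx[k]) / rx)^2 + ((y - cy) / ry)^2 <= 1) {
        roi[x, y, ] <- k
        kpl[x, y, ] <- spec$roi_kpl[k]
      }
    }
  }
  list(kpl = kpl, roi = roi)
}

#' Generate a synthetic dynamic image series with known kPL map
#'
#' Every voxel's pyruvate/lactate time series is the raw fingerprint at that
#' voxel's true kPL (nuisance parameters constant across the phantom), plus
#' complex Gaussian noise of SD `spec$sigma` added independently per voxel,
#' channel and frame. Deterministic under `spec$seed`.
#'
#' @param spec a [phantom_spec()] object
#' @param schedule,kin,bolus,cond forward model, as in
#'   [simulate_fingerprint()] (`kin$kPL` is taken from the truth map)
#' @return list with `series` (a `dynamic_image_series`: per-metabolite
#'   complex 4D arrays plus timing metadata) and `truth` (list with `kpl`
#'   and `roi` arrays)
#' @export
generate_phantom <- function(spec, schedule, kin = kinetic_params(),
                             bolus = bolus_params(),
                             cond = field_conditions()) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- phantom_truth_map(spec)
  events <- compile_events(schedule, bolus)
  counts <- events$counts
  kpls <- sort(unique(as.vector(truth$kpl)))
  sims <- lapply(kpls, function(k) {
    kin$kPL <- k
    simulate_fingerprint(schedule, kin, bolus, cond, events = events)$signal
  })
  names(sims) <- format(kpls, digits = 12)

  d <- spec$shape
  nv <- prod(d)
  pyr <- array(complex(real = 0, imaginary = 0), c(d, counts[["pyr"]]))
  lac <- array(complex(real = 0, imaginary = 0), c(d, counts[["lac"]]))
  flat_kpl <- as.vector(truth$kpl)
  for (k in seq_along(kpls)) {
    vox <- which(flat_kpl == kpls[k])
    sig <- sims[[k]]
    for (tt in seq_len(counts[["pyr"]])) {
      slice <- tt
      pyr[vox + (slice - 1) * nv] <- sig[tt]
    }
    for (tt in seq_len(counts[["lac"]])) {
      lac[vox + (tt - 1) * nv] <- sig[counts[["pyr"]] + tt]
    }
  }
  if (spec$sigma > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(spec$seed)
    pyr <- pyr + array(complex(real = rnorm(length(pyr), 0, spec$sigma),
                               imaginary = rnorm(length(pyr), 0, spec$sigma)),
                       dim(pyr))
    lac <- lac + array(complex(real = rnorm(length(lac), 0, spec$sigma),
                               imaginary = rnorm(length(lac), 0, spec$sigma)),
                       dim(lac))
  }
  series <- structure(
    list(pyr = pyr, lac = lac,
         times_pyr = events$times_pyr, times_lac = events$times_lac,
         noise_sd = spec$sigma, design_id = schedule$design_id,
         voxel_mm = spec$voxel_mm),
    class = "dynamic_image_series")
  list(series = series, truth = truth)
}

series_dims <- function(series) dim(series$pyr)[1:3]

# voxels x time matrix of one metabolite
series_matrix <- function(series, metabolite = c("pyr", "lac")) {
  metabolite <- match.arg(metabolite)
  a <- series[[metabolite]]
  d <- dim(a)
  matrix(a, nrow = prod(d[1:3]), ncol = d[4])
}

#' Voxel-wise kPL map by template matching
#'
#' Concatenates each masked voxel's pyruvate and lactate series and matches
#' it against the dictionary. Unmasked voxels are `NA`.
#'
#' @param series a `dynamic_image_series`
#' @param dict an `mrf_dictionary` simulated on the same sampling grid
#' @param mask logical array (default: all voxels)
#' @return object of class `param_map`: `kpl` and `score` arrays plus the
#'   `mask` used
#' @export
fit_voxelwise <- function(series, dict, mask = NULL) {
  d <- series_dims(series)
  nt <- dim(series$pyr)[4] + dim(series$lac)[4]
  if (nt != ncol(dict$entries))
    stop("series and dictionary sampling grids do not agree")
  if (max(abs(c(series$times_pyr, series$times_lac) - dict$times)) > 1e-9)
    stop("series and dictionary sampling times do not agree")
  if (is.null(mask)) mask <- array(TRUE, d)
  stopifnot(all(dim(mask) == d))
  sig <- cbind(series_matrix(series, "pyr"), series_matrix(series, "lac"))
  vox <- which(as.vector(mask))
  kpl <- array(NA_real_, d)
  score <- array(NA_real_, d)
  if (length(vox)) {
    res <- match_fingerprints(sig[vox, , drop = FALSE], dict)
    kpl[vox] <- res$kpl_hat
    score[vox] <- res$score
  }
  structure(list(kpl = kpl, score = score, mask = mask),
            class = "param_map")
}

#' SNR-based mask from peak pyruvate signal
#'
#' Keeps voxels whose peak-over-time magnitude divided by the noise SD
#' reaches `threshold` (default 5). The noise SD defaults to the known
#' phantom value; pass `noise_sd` explicitly for external data.
#'
#' @param series a `dynamic_image_series`
#' @param metabolite which metabolite defines the mask
#' @param threshold peak SNR cutoff
#' @param noise_sd per-channel noise SD; defaults to `series$noise_sd`
#' @return logical array
#' @export
snr_mask <- function(series, metabolite = "pyr", threshold = 5,
                     noise_sd = NULL) {
  if (is.null(noise_sd)) noise_sd <- series$noise_sd
  stopifnot(is.numeric(noise_sd), noise_sd > 0)
  m <- series_matrix(series, metabolite)
  peak <- apply(Mod(m), 1, max)
  array(peak / noise_sd >= threshold, series_dims(series))
}

#' AUC images and lactate-to-pyruvate AUC ratio
#'
#' Per voxel, AUC is the sum over time of the signal magnitude. The ratio is
#' `NA` wherever the pyruvate AUC is not positive.
#'
#' @param series a `dynamic_image_series`
#' @return list of arrays `auc_pyr`, `auc_lac`, `ratio`
#' @export
auc_maps <- function(series) {
  d <- series_dims(series)
  ap <- array(rowSums(Mod(series_matrix(series, "pyr"))), d)
  al <- array(rowSums(Mod(series_matrix(series, "lac"))), d)
  ratio <- array(NA_real_, d)
  ok <- ap > 0
  ratio[ok] <- al[ok] / ap[ok]
  list(auc_pyr = ap, auc_lac = al, ratio = ratio)
}

#' Time-to-peak map
#'
#' Per voxel, the time stamp of the maximum signal magnitude; all-zero
#' voxels are `NA`.
#'
#' @param series a `dynamic_image_series`
#' @param metabolite metabolite to analyze
#' @param mask optional logical array
#' @return list with `ttp` array (s) and masked `mean` (s)
#' @export
time_to_peak <- function(series, metabolite = "lac", mask = NULL) {
  d <- series_dims(series)
  if (is.null(mask)) mask <- array(TRUE, d)
  m <- Mod(series_matrix(series, metabolite))
  times <- if (metabolite == "pyr") series$times_pyr else series$times_lac
  if (length(times) < 3) stop("need at least 3 time points")
  ttp <- array(NA_real_, d)
  vox <- which(as.vector(mask))
  for (v in vox) {
    if (any(m[v, ] > 0)) ttp[v] <- times[which.max(m[v, ])]
  }
  list(ttp = ttp, mean = mean(ttp[vox], na.rm = TRUE))
}

#' Dynamic AUC SNR ratio between two experiments
#'
#' Per series, the dynamic AUC SNR is the magnitude of the cumulative
#' complex sum over time divided by the real-channel noise SD. Series `b` is
#' shifted in time (whole frames, nearest) so that its mean lactate
#' time-to-peak matches series `a`, then the voxel-wise ratio `a / b` is
#' averaged over the mask at each common time point.
#'
#' @param series_a,series_b `dynamic_image_series` objects
#' @param mask logical array (e.g. the kidney-SNR intersection)
#' @param noise_sd_a,noise_sd_b per-channel noise SDs (default: stored values)
#' @return data.frame with `time` (series `a` clock, s) and `ratio`
#' @export
dynamic_auc_snr_ratio <- function(series_a, series_b, mask = NULL,
                                  noise_sd_a = NULL, noise_sd_b = NULL) {
  if (is.null(noise_sd_a)) noise_sd_a <- series_a$noise_sd
  if (is.null(noise_sd_b)) noise_sd_b <- series_b$noise_sd
  d <- series_dims(series_a)
  if (is.null(mask)) mask <- array(TRUE, d)
  vox <- which(as.vector(mask))

  dyn_snr <- function(series, sd) {
    m <- series_matrix(series, "pyr")
    cs <- t(apply(m, 1, cumsum))
    Mod(cs) / sd
  }
  snr_a <- dyn_snr(series_a, noise_sd_a)
  snr_b <- dyn_snr(series_b, noise_sd_b)

  mean_curve <- function(series) {
    colMeans(Mod(series_matrix(series, "lac"))[vox, , drop = FALSE])
  }
  ttp_frames <- function(curve) {
    if (all(diff(curve) > 0) || all(diff(curve) < 0))
      stop("lactate time-to-peak undefined: monotone mean signal")
    which.max(curve)
  }
  ia <- ttp_frames(mean_curve(series_a))
  ib <- ttp_frames(mean_curve(series_b))
  ta <- series_a$times_lac[ia]
  tb <- series_b$times_lac[ib]
  dt_b <- mean(diff(series_b$times_pyr))
  shift <- round((tb - ta) / dt_b)  # frames to advance series b

  na <- ncol(snr_a)
  nb <- ncol(snr_b)
  ratio <- rep(NA_real_, na)
  for (tt in seq_len(na)) {
    tb_idx <- tt + shift
    if (tb_idx < 1 || tb_idx > nb) next
    rr <- snr_a[vox, tt] / snr_b[vox, tb_idx]
    ratio[tt] <- mean(rr[is.finite(rr)])
  }
  data.frame(time = series_a$times_pyr, ratio = ratio)
}

#' Voxel-wise agreement between two parameter maps
#'
#' Pearson correlation (with `n - 2` degrees of freedom and p-value),
#' least-squares slope, and Bland-Altman mean difference with
#' mean +/- 1.96 SD limits, over the shared masked voxels.
#'
#' @param map_a,map_b `param_map` objects or numeric arrays
#' @param mask logical array; defaults to voxels finite in both maps
#' @return list with `n`, `r`, `df`, `p_value`, `slope`, `bias`,
#'   `loa_lower`, `loa_upper`, `constant` (TRUE flags a degenerate map with
#'   undefined correlation)
#' @export
compare_maps <- function(map_a, map_b, mask = NULL) {
  a <- if (inherits(map_a, "param_map")) map_a$kpl else map_a
  b <- if (inherits(map_b, "param_map")) map_b$kpl else map_b
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(mask)) mask <- is.finite(a) & is.finite(b)
  v <- which(as.vector(mask) & is.finite(a) & is.finite(b))
  if (length(v) < 3) stop("need at least 3 shared voxels")
  x <- a[v]; y <- b[v]
  diffs <- y - x
  bias <- mean(diffs)
  sdd <- stats::sd(diffs)
  constant <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (constant) {
    r <- NA_real_; p <- NA_real_; slope <- NA_real_
  } else {
    ct <- stats::cor.test(x, y)
    r <- unname(ct$estimate)
    p <- ct$p.value
    slope <- unname(stats::coef(stats::lm(y ~ x))[2])
  }
  list(n = length(v), r = r, df = length(v) - 2L, p_value = p,
       slope = slope, bias = bias,
       loa_lower = bias - 1.96 * sdd, loa_upper = bias + 1.96 * sdd,
       constant = constant)
}

# --- NIfTI input/output ----------------------------------------------------

#' Write / read a dynamic image series as NIfTI volumes
#'
#' Complex data are stored as real/imaginary 4D pairs per metabolite
#' (`<prefix>_<met>_real.nii.gz`, `..._imag.nii.gz`) with a JSON sidecar
#' (`<prefix>_meta.json`) holding time stamps, noise SD and design id.
#'
#' @param series a `dynamic_image_series`
#' @param prefix output path prefix
#' @return `read_series_nifti` returns a `dynamic_image_series`
#' @export
write_series_nifti <- function(series, prefix) {
  for (met in c("pyr", "lac")) {
    RNifti::writeNifti(Re(series[[met]]),
                       paste0(prefix, "_", met, "_real.nii.gz"))
    RNifti::writeNifti(Im(series[[met]]),
                       paste0(prefix, "_", met, "_imag.nii.gz"))
  }
  meta <- list(times_pyr = series$times_pyr, times_lac = series$times_lac,
               noise_sd = series$noise_sd, design_id = series$design_id,
               voxel_mm = series$voxel_mm)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(prefix, "_meta.json"))
  invisible(prefix)
}

#' @rdname write_series_nifti
#' @export
read_series_nifti <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, "_meta.json"))
  rd <- function(met) {
    re <- RNifti::readNifti(paste0(prefix, "_", met, "_real.nii.gz"))
    im <- RNifti::readNifti(paste0(prefix, "_", met, "_imag.nii.gz"))
    array(complex(real = as.vector(re), imaginary = as.vector(im)), dim(re))
  }
  structure(list(pyr = rd("pyr"), lac = rd("lac"),
                 times_pyr = meta$times_pyr, times_lac = meta$times_lac,
                 noise_sd = meta$noise_sd, design_id = meta$design_id,
                 voxel_mm = meta$voxel_mm),
            class = "dynamic_image_series")
}

#' Write a kPL parameter map (and its mask) as NIfTI
#'
#' @param map a `param_map`
#' @param prefix output path prefix
#' @export
write_map_nifti <- function(map, prefix) {
  RNifti::writeNifti(map$kpl, paste0(prefix, "_kpl.nii.gz"))
  RNifti::writeNifti(array(as.integer(map$mask), dim(map$kpl)),
                     paste0(prefix, "_mask.nii.gz"))
  invisible(prefix)
}
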