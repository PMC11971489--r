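#' Specification of a kPL fingerprint dictionary
#'
#' A dictionary holds one fingerprint per conversion-rate value on a uniform
#' grid, with every nuisance parameter fixed. The default grid is
#' 0 to 0.1 1/s in steps of 1e-4 (1001 entries), and the default fixed
#' parameters are the nominal dictionary values of [kinetic_params()],
#' [bolus_params()] and [field_conditions()].
#'
#' @param schedule a [build_schedule()] object
#' @param kpl_min,kpl_max,kpl_res conversion-rate grid, 1/s
#' @param kin_fixed fixed kinetic parameters (the `kPL` field is ignored)
#' @param bolus fixed bolus parameters
#' @param cond fixed field conditions
#' @return object of class `dictionary_spec`
#' @export
dictionary_spec <- function(schedule, kpl_min = 0, kpl_max = 0.1,
                            kpl_res = 1e-4,
                            kin_fixed = kinetic_params(),
                            bolus = bolus_params(),
                            cond = field_conditions()) {
  stopifnot(inherits(schedule, "sequence_schedule"),
            kpl_min <= kpl_max, kpl_res > 0)
  structure(list(schedule = schedule, kpl_min = kpl_min, kpl_max = kpl_max,
                 kpl_res = kpl_res, kin_fixed = kin_fixed, bolus = bolus,
                 cond = cond),
            class = "dictionary_spec")
}

kpl_grid_of <- function(spec) {
  n <- floor((spec$kpl_max - spec$kpl_min) / spec$kpl_res + 1e-9) + 1
  spec$kpl_min + spec$kpl_res * (seq_len(n) - 1)
}

# small polynomial rolling hash of a string, as hex (cache keying only)
str_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% 2147483647
    h2 <- (h2 * 137 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

spec_cache_key <- function(spec) {
  sched <- spec$schedule
  key <- paste(
    sched$design_id, sched$total_duration, sched$temporal_resolution,
    paste(vapply(sched$blocks, function(b)
      paste(format(c(b$start_time, b$tr, b$te, b$sample_index,
                     length(b$flips), sum(b$flips), sum(b$phases)),
                   digits = 15), collapse = ","), ""), collapse = ";"),
    format(c(spec$kpl_min, spec$kpl_max, spec$kpl_res,
             unlist(spec$kin_fixed), unlist(spec$bolus)), digits = 15),
    spec$cond$b1_scale, spec$cond$b0_offset, spec$cond$linewidth_fwhm,
    spec$cond$n_isochromats, spec$cond$lineshape,
    collapse = "|")
  str_hash(paste(key, collapse = "|"))
}

#' Generate (or load from cache) a kPL fingerprint dictionary
#'
#' Simulates one fingerprint per grid value and stores unit-L2-norm complex
#' rows together with the pre-normalization norms, so the matched amplitude
#' can be recovered. Generation is deterministic: the same spec always
#' yields a bit-identical dictionary, which is why entries can be cached on
#' disk keyed by a content hash of the spec (dictionary precomputation is the
#' costly step of the framework; matching is cheap).
#'
#' @param spec a [dictionary_spec()] object
#' @param cache_dir optional directory for the on-disk cache
#' @return object of class `mrf_dictionary` with `kpl_grid`, `entries`
#'   (grid x signal-length complex matrix, unit rows), `raw_norms`, `times`,
#'   `metabolite` and `spec`
#' @export
generate_dictionary <- function(spec, cache_dir = NULL) {
  stopifnot(inherits(spec, "dictionary_spec"))
  grid <- kpl_grid_of(spec)
  if (length(grid) < 1) stop("degenerate kPL grid")
  if (!is.null(cache_dir)) {
    cache_file <- file.path(cache_dir,
                            paste0("hpmrf-dict-", spec_cache_key(spec), ".rds"))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }

  events <- compile_events(spec$schedule, spec$bolus)
  offs <- isochromat_offsets(spec$cond)
  kin <- spec$kin_fixed
  fp <- kin$omega_pyr + spec$cond$b0_offset
  fl <- kin$omega_lac + spec$cond$b0_offset
  entries <- matrix(complex(real = 0, imaginary = 0),
                    nrow = length(grid), ncol = events$n_out)
  for (i in seq_along(grid)) {
    entries[i, ] <- .bm_simulate_cpp(events$events, events$dts, grid[i],
                                     kin$T1_pyr, kin$T1_lac,
                                     kin$T2_pyr, kin$T2_lac,
                                     fp, fl, offs, spec$cond$b1_scale,
                                     events$n_out)
  }
  raw_norms <- sqrt(rowSums(Mod(entries)^2))
  if (any(raw_norms == 0)) stop("zero-norm dictionary entry")
  dict <- structure(
    list(kpl_grid = grid, entries = entries / raw_norms,
         raw_norms = raw_norms,
         times = c(events$times_pyr, events$times_lac),
         metabolite = rep(c("pyr", "lac"), events$counts),
         spec = spec),
    class = "mrf_dictionary")
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(dict, cache_file)
  }
  dict
}

# raw (amplitude-true) fingerprint matrix, entries scaled back by their norms
dictionary_raw <- function(dict, idx = seq_along(dict$kpl_grid)) {
  dict$entries[idx, , drop = FALSE] * dict$raw_norms[idx]
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf(
    "<mrf_dictionary> %s: %d entries, kPL %g..%g 1/s (step %g), %d samples\n",
    x$spec$schedule$design_id, length(x$kpl_grid),
    min(x$kpl_grid), max(x$kpl_grid), x$spec$kpl_res, ncol(x$entries)))
  invisible(x)
}

#' Save / load a dictionary
#'
#' Dictionaries are plain R objects; these helpers serialize them to RDS.
#'
#' @param dict an `mrf_dictionary`
#' @param path file path
#' @export
save_dictionary <- function(dict, path) {
  saveRDS(dict, path)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) readRDS(path)
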