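make_phantom <- function(design, sigma = 0, seed = 1,
                         roi_kpl = c(0.02, 0.05)) {
  generate_phantom(phantom_spec(shape = c(12, 12, 2), roi_kpl = roi_kpl,
                                sigma = sigma, seed = seed),
                   build_schedule(design))
}

test_that("noise-free phantom voxels reproduce the dictionary fingerprints exactly", {
  ph <- make_phantom("mrf_sigmoid", sigma = 0)
  dict <- get_dict("mrf_sigmoid")
  series <- ph$series
  i <- which(ph$truth$kpl == 0.05)[1]
  xyz <- arrayInd(i, dim(ph$truth$kpl))
  vox <- c(series$pyr[xyz[1], xyz[2], xyz[3], ],
           series$lac[xyz[1], xyz[2], xyz[3], ])
  raw <- dict$entries[which(dict$kpl_grid == 0.05), ] *
    dict$raw_norms[which(dict$kpl_grid == 0.05)]
  expect_equal(vox, raw, tolerance = 1e-12)
  # background voxels carry no lactate before noise
  bg <- which(ph$truth$roi == 0)[1]
  xyz <- arrayInd(bg, dim(ph$truth$kpl))
  expect_true(all(series$lac[xyz[1], xyz[2], xyz[3], ] == 0))
})

test_that("phantom noise is reproducible under its seed", {
  a <- make_phantom("mrf_constant", sigma = 0.1, seed = 7)
  b <- make_phantom("mrf_constant", sigma = 0.1, seed = 7)
  d <- make_phantom("mrf_constant", sigma = 0.1, seed = 8)
  expect_identical(a$series$pyr, b$series$pyr)
  expect_false(identical(a$series$pyr, d$series$pyr))
})

test_that("voxel-wise fitting recovers a noise-free kPL map exactly", {
  ph <- make_phantom("mrf_constant", sigma = 0)
  dict <- get_dict("mrf_constant")
  mask <- ph$truth$roi > 0
  map <- fit_voxelwise(ph$series, dict, mask)
  expect_equal(map$kpl[mask], ph$truth$kpl[mask])
  expect_true(all(is.na(map$kpl[!mask])))  # mask-respecting
})

test_that("voxel-wise fitting equals a per-voxel matching loop", {
  ph <- make_phantom("mrf_sigmoid", sigma = 0.15, seed = 3)
  dict <- get_dict("mrf_sigmoid")
  mask <- array(FALSE, dim(ph$truth$kpl))
  mask[4:6, 4:6, 1] <- TRUE
  map <- fit_voxelwise(ph$series, dict, mask)
  for (v in which(mask)) {
    xyz <- arrayInd(v, dim(mask))
    sig <- c(ph$series$pyr[xyz[1], xyz[2], xyz[3], ],
             ph$series$lac[xyz[1], xyz[2], xyz[3], ])
    expect_equal(map$kpl[v], match_fingerprint(sig, dict)$kpl_hat)
  }
})

test_that("voxel-wise median kPL per ROI is recovered within 5% at sigma 0.1", {
  for (design in c("mrf_sigmoid", "mrf_constant", "hybridgre")) {
    ph <- make_phantom(design, sigma = 0.1, seed = 5,
                       roi_kpl = c(0.02, 0.05))
    map <- fit_voxelwise(ph$series, get_dict(design), ph$truth$roi > 0)
    for (k in c(0.02, 0.05)) {
      med <- median(map$kpl[ph$truth$kpl == k])
      expect_lt(abs(med - k) / k, 0.05)
    }
  }
})

test_that("SNR masks shrink with threshold and reject pure noise", {
  ph <- make_phantom("mrf_sigmoid", sigma = 0.1, seed = 2)
  m0 <- snr_mask(ph$series, threshold = 0)
  expect_true(all(m0))
  m5 <- snr_mask(ph$series, threshold = 5)
  m8 <- snr_mask(ph$series, threshold = 8)
  expect_true(all(m8[m5 == FALSE] == FALSE))
  expect_true(all(which(m8) %in% which(m5)))

  # pure complex noise: peak-over-time SNR exceeds 5 essentially never
  set.seed(4)
  d <- c(20, 20, 5)
  nt <- 15
  noise_series <- structure(
    list(pyr = array(complex(real = rnorm(prod(d) * nt, 0, 0.1),
                             imaginary = rnorm(prod(d) * nt, 0, 0.1)),
                     c(d, nt)),
         lac = array(0 + 0i, c(d, nt)),
         times_pyr = seq(0, by = 4.1, length.out = nt),
         times_lac = seq(2.05, by = 4.1, length.out = nt),
         noise_sd = 0.1, design_id = "none", voxel_mm = c(1, 1, 1)),
    class = "dynamic_image_series")
  frac <- mean(snr_mask(noise_series, threshold = 5))
  expect_lt(frac, 0.01)
})

test_that("AUC maps sum magnitudes and their ratio is scale invariant", {
  d <- c(4, 4, 1)
  nt <- 10
  unit <- array(complex(modulus = 1, argument = runif(prod(d) * nt, 0, 2 * pi)),
                c(d, nt))
  ser <- structure(list(pyr = unit, lac = 0.5 * unit,
                        times_pyr = 1:nt, times_lac = 1:nt + 0.5,
                        noise_sd = 0, design_id = "toy",
                        voxel_mm = c(1, 1, 1)),
                   class = "dynamic_image_series")
  maps <- auc_maps(ser)
  expect_equal(maps$auc_pyr, array(10, d))
  expect_equal(maps$ratio, array(0.5, d))

  ser2 <- ser
  ser2$pyr <- 3 * ser$pyr
  ser2$lac <- 3 * ser$lac
  expect_equal(auc_maps(ser2)$ratio, maps$ratio)
})

test_that("lactate/pyruvate AUC ratio grows with the conversion rate", {
  for (design in c("hybridgre", "mrf_sigmoid", "mrf_constant")) {
    ph <- make_phantom(design, sigma = 0)
    ratio <- auc_maps(ph$series)$ratio
    expect_gt(mean(ratio[ph$truth$kpl == 0.05]),
              mean(ratio[ph$truth$kpl == 0.02]))
  }
})

test_that("time-to-peak maps track the signal maximum and frame shifts", {
  d <- c(3, 3, 1)
  nt <- 8
  arr <- array(0 + 0i, c(d, nt))
  arr[, , , 5] <- 1 + 0i
  times <- seq(0, by = 4.1, length.out = nt)
  ser <- structure(list(pyr = arr, lac = arr, times_pyr = times,
                        times_lac = times, noise_sd = 0, design_id = "toy",
                        voxel_mm = c(1, 1, 1)),
                   class = "dynamic_image_series")
  ttp <- time_to_peak(ser, "lac")
  expect_equal(ttp$mean, times[5])

  shifted <- ser
  shifted$lac <- array(0 + 0i, c(d, nt))
  shifted$lac[, , , 6] <- 1 + 0i
  expect_equal(time_to_peak(shifted, "lac")$mean, times[6])
})

test_that("sigmoid excitation delays the phantom pyruvate time to peak", {
  sig <- make_phantom("mrf_sigmoid", sigma = 0)
  con <- make_phantom("mrf_constant", sigma = 0)
  mask <- sig$truth$roi > 0
  expect_gt(time_to_peak(sig$series, "pyr", mask)$mean,
            time_to_peak(con$series, "pyr", mask)$mean)
})

test_that("dynamic AUC SNR ratio is exact for identical and scaled series", {
  ph <- make_phantom("mrf_sigmoid", sigma = 0)
  ser <- ph$series
  ser$noise_sd <- 0.1
  mask <- ph$truth$roi > 0
  r11 <- dynamic_auc_snr_ratio(ser, ser, mask)
  expect_equal(r11$ratio, rep(1, length(r11$ratio)))

  ser2 <- ser
  ser2$pyr <- 2 * ser$pyr
  ser2$lac <- 2 * ser$lac
  r21 <- dynamic_auc_snr_ratio(ser2, ser, mask)
  expect_equal(r21$ratio, rep(2, length(r21$ratio)))
})

test_that("bSSFP pyruvate accumulates SNR over HybridGRE through the acquisition", {
  sig <- make_phantom("mrf_sigmoid", sigma = 0)
  gre <- make_phantom("hybridgre", sigma = 0)
  a <- sig$series; a$noise_sd <- 0.1
  b <- gre$series; b$noise_sd <- 0.1
  mask <- sig$truth$roi > 0
  r <- dynamic_auc_snr_ratio(a, b, mask)
  ok <- which(is.finite(r$ratio))
  expect_gt(r$ratio[max(ok)], r$ratio[min(ok)])  # gain grows with time
  expect_gt(r$ratio[max(ok)], 1)
})

test_that("map comparison reproduces hand-computed Pearson and Bland-Altman results", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  a <- array(x, c(5, 1, 1))
  b <- array(y, c(5, 1, 1))
  cmp <- compare_maps(a, b)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cmp$r, r_hand)
  expect_equal(cmp$df, 3L)
  expect_equal(cmp$bias, mean(y - x))

  same <- compare_maps(a, a)
  expect_equal(same$r, 1)
  expect_equal(same$bias, 0)

  off <- compare_maps(a, a + 0.002)
  expect_equal(off$bias, 0.002)
  expect_equal(off$r, 1)

  cst <- compare_maps(a, array(1, c(5, 1, 1)))
  expect_true(cst$constant)
  expect_true(is.na(cst$r))
})

test_that("Bland-Altman limits cover about 95% of Gaussian differences", {
  set.seed(12)
  n <- 4000
  a <- array(runif(n, 0.01, 0.05), c(n, 1, 1))
  b <- a + array(rnorm(n, 0.001, 0.003), c(n, 1, 1))
  cmp <- compare_maps(a, b)
  d <- as.vector(b - a)
  cover <- mean(d >= cmp$loa_lower & d <= cmp$loa_upper)
  expect_gte(cover, 0.93)
})

test_that("dynamic image series round-trip through NIfTI volumes", {
  ph <- make_phantom("mrf_constant", sigma = 0.05, seed = 9)
  prefix <- file.path(tempdir(), "phantom-series")
  write_series_nifti(ph$series, prefix)
  back <- read_series_nifti(prefix)
  expect_equal(back$pyr, ph$series$pyr, ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_equal(back$times_lac, ph$series$times_lac)
  expect_equal(back$noise_sd, ph$series$noise_sd)
  unlink(paste0(prefix, "*"))
})
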