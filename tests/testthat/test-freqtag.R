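test_that("percent signal change normalizes every voxel's mean to 100", {
  expect_true(all(percent_signal_change(rep(500, 50)) == 100))
  set.seed(1)
  m <- matrix(rnorm(200, 300, 5), 50, 4)
  out <- percent_signal_change(m)
  expect_lt(max(abs(colMeans(out) - 100)), 1e-9)
  # scale invariance
  expect_lt(max(abs(percent_signal_change(2 * m) - out)), 1e-9)
  expect_warning(percent_signal_change(cbind(m[, 1], -m[, 2])),
                 "non-positive")
})

test_that("power spectra satisfy Parseval and put a sinusoid in one bin", {
  n <- 216; TR <- 2.46
  set.seed(2)
  x <- rnorm(n)
  sp <- power_spectrum(x, TR)
  expect_lt(abs(sum(sp$power) - sum(x^2)) / sum(x^2), 1e-6)
  expect_equal(sp$delta_f, 1 / 531.36)
  # sinusoid at an exact bin: all non-DC power in that bin
  k <- 20
  s <- cos(2 * pi * k * (0:(n - 1)) / n)
  sps <- power_spectrum(s, TR)
  expect_gt(sps$power[k + 1] / sum(sps$power[-1]), 1 - 1e-9)
  expect_error(power_spectrum(c(x[-1], NA), TR), "NA")
  expect_error(power_spectrum(x[1:4], TR), "short")
})

test_that("white-noise expected power is flat across bins", {
  set.seed(3)
  acc <- 0
  for (i in 1:200) acc <- acc + power_spectrum(rnorm(128), 1)$power
  pw <- (acc / 200)[2:64]   # skip DC and Nyquist
  fit <- lm(pw ~ seq_along(pw))
  expect_lt(abs(coef(fit)[2]) / mean(pw), 0.002)
})

test_that("SNR spectrum handles flat, delta and edge cases", {
  flat <- snr_spectrum(rep(3, 40))
  expect_true(all(is.na(flat[1:7])) && all(is.na(flat[34:40])))
  expect_true(all(abs(flat[8:33] - 1) < 1e-12))
  delta <- rep(1, 41); delta[21] <- 15
  s <- snr_spectrum(delta)
  expect_equal(s[21], 15)
  # a neighbor's noise band contains the delta, dragging its SNR below 1
  expect_lt(s[22], 1)
  expect_error(snr_spectrum(rep(1, 40), band_bins = 13), "even")
})

test_that("mean white-noise SNR is close to 1", {
  set.seed(4)
  vals <- replicate(200, {
    s <- snr_spectrum(power_spectrum(rnorm(64), 1))
    mean(s$snr, na.rm = TRUE)
  })
  expect_gt(mean(vals), 0.9)
  expect_lt(mean(vals), 1.1)
})

test_that("noise-frequency sets: default 22, single-tag 14, union merges", {
  nf <- noise_frequency_set(c(0.06, 0.08, 0.10))
  expect_length(nf, 22)
  expect_false(any(attr(nf, "bins") %in% round(c(0.06, 0.08, 0.10) * 540)))
  # a single far tag at an exact bin with 7-bin band and no guard: 7 + 7
  one <- noise_frequency_set(0.1, delta_f = 1 / 540, half_band = 7,
                             guard = 0.1)
  expect_length(one, 14)
  # two adjacent tags with overlapping bands give fewer than 28
  two <- noise_frequency_set(c(0.06, 0.065), delta_f = 1 / 540,
                             half_band = 7, guard = 0.1)
  expect_lt(length(two), 28)
  expect_error(noise_frequency_set(0.1, guard = 8), "guard")
})

test_that("tagging p-values match a reference t-test on raw power", {
  # dual route: the vectorized statistic against stats::t.test per voxel
  st <- null_study(n_voxels = 5, seed = 21)
  spectra <- lapply(1:3, function(r)
    swiftag:::.power_matrix(percent_signal_change(
      roi_series(st, "NULLROI", r)), st$TR, detrend = TRUE))
  nf <- noise_frequency_set(c(0.06, 0.08, 0.10),
                            delta_f = 1 / (216 * 2.46))
  res <- tagging_pvalues(spectra, 0.06, nf, log_power = FALSE)
  bins <- res$noise_bins + 1L
  for (v in 1:5) {
    tag <- vapply(spectra, function(s) s$power[res$tag_bin + 1, v],
                  numeric(1))
    noi <- unlist(lapply(spectra, function(s) s$power[bins, v]))
    ref <- t.test(tag, noi, var.equal = TRUE)
    expect_equal(res$p[v], ref$p.value, tolerance = 1e-12)
    expect_equal(res$t[v], unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("tagging statistics detect strong signals and degrade cleanly", {
  set.seed(5)
  onsets <- seq(2, 530, by = 10)
  runs <- lapply(1:3, function(r)
    cbind(simulate_voxel(onsets, amplitude = 3, noise_sd = 0.5,
                         seed = 100 + r),
          simulate_voxel(numeric(0), amplitude = 0, noise_sd = 0.5,
                         seed = 200 + r)))
  res <- suppressWarnings(
    tagging_pvalues(runs, 0.1, swift_noise_freqs, TR = 2.46,
                    series = TRUE))
  expect_lt(res$p[1], 1e-4)
  expect_gt(res$p[2], 0.01)
  # identical constant power everywhere: degenerate, p = 1
  const <- lapply(1:2, function(r)
    list(power = matrix(1, 100, 1), delta_f = 1 / 540))
  expect_warning(pc <- tagging_pvalues(const, 0.1, swift_noise_freqs),
                 "zero variance")
  expect_equal(pc$p, 1)
})

test_that("null-study p-values are uniform and FDR stays controlled", {
  st <- null_study(n_voxels = 1000, seed = 31)
  maps <- suppressWarnings(tagging_analysis(st, tag_freqs = c(f = 0.1)))
  p <- maps$f$p
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_lt(mean(p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
  expect_equal(sum(fdr_bh(p, 0.05)), 0)
})

test_that("Benjamini-Hochberg mask agrees with hand-computed rules", {
  expect_true(all(fdr_bh(rep(0.001, 10), 0.05)))
  expect_equal(fdr_bh(c(0.04, 0.5), 0.05), c(FALSE, FALSE))
  expect_equal(fdr_bh(c(0.01, 0.04, 0.03, 0.005), 0.05),
               c(TRUE, TRUE, TRUE, TRUE))
  expect_length(fdr_bh(numeric(0)), 0)
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
  # shape preserved
  m <- matrix(runif(12), 3, 4)
  expect_equal(dim(fdr_bh(m)), c(3L, 4L))
})

test_that("phase maps recover injected phase and mask noise voxels", {
  n <- 216; TR <- 2.46
  tt <- (0:(n - 1)) * TR
  f0 <- 18 / (n * TR)
  clean <- 100 + cos(2 * pi * f0 * tt + pi / 3)
  pm <- phase_map(cbind(clean), f0, TR, snr_threshold = 2)
  expect_false(is.na(pm$phase[1]))
  expect_lt(abs(pm$phase[1] - pi / 3), 2 * pi / n)
  # pure-noise voxels mostly fall below the SNR threshold
  set.seed(6)
  noise <- matrix(rnorm(n * 200, 100, 1), n, 200)
  pmn <- phase_map(noise, f0, TR, snr_threshold = 2)
  expect_gt(mean(is.na(pmn$phase)), 0.5)
  # threshold 0 disables masking
  pm0 <- phase_map(noise, f0, TR, snr_threshold = 0)
  expect_false(anyNA(pm0$phase))
})

test_that("cycle averages recover the driving response exactly", {
  onsets <- seq(0, 530, by = 10)
  v <- simulate_voxel(onsets, amplitude = 1, noise_sd = 0, TR = 2.5,
                      n_volumes = 216)
  # drop the pre-steady-state onsets so every epoch sees the same tails
  ca <- cycle_average(v, onsets[onsets >= 70], TR = 2.5, window = 10)
  expect_lt(max(ca$sem), 1e-9)
  one <- v[29:33]   # the epoch starting at t = 70 s
  expect_lt(max(abs(ca$mean - one)), 1e-9)
  # constant series: flat average, SEM 0
  cc <- cycle_average(rep(7, 100), c(10, 30, 50), TR = 1, window = 15)
  expect_true(all(cc$mean == 7) && all(cc$sem == 0))
  # window exceeding the inter-onset gap is rejected unless wrapped
  expect_error(cycle_average(v, onsets, TR = 2.5, window = 12.5),
               "exceeds")
  expect_silent(cycle_average(v, onsets, TR = 2.5, window = 12.5,
                              wrap = TRUE))
})
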