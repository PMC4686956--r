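test_that("canonical HRF peaks near 6 s, starts at 0 and scales linearly", {
  h <- canonical_hrf(TR = 2.46, duration = 32)
  expect_gte(h$peak_time, 4.92)
  expect_lte(h$peak_time, 7.38)
  fine <- canonical_hrf(TR = 0.1, duration = 32)
  # unit peak on a fine grid; TR sampling can only undershoot it
  expect_equal(max(fine$samples), 1, tolerance = 1e-4)
  expect_lte(max(h$samples), 1)
  expect_equal(fine$samples[1], 0)
  h2 <- canonical_hrf(TR = 2.46, amplitude = 2)
  expect_equal(h2$samples, 2 * h$samples)
  expect_error(canonical_hrf(TR = 0), "TR")
})

test_that("simulate_voxel reduces to baseline and is seed-deterministic", {
  v <- simulate_voxel(seq(5, 500, by = 10), amplitude = 0, noise_sd = 0)
  expect_true(all(v == 100))
  expect_identical(simulate_voxel(c(5, 15), 1, seed = 42),
                   simulate_voxel(c(5, 15), 1, seed = 42))
  expect_error(simulate_voxel(c(-1), 1), "within the run")
  expect_error(simulate_voxel(c(5), 1, noise_sd = -1), "noise_sd")
})

test_that("periodic onsets produce a spectral peak at the driving rate", {
  v <- simulate_voxel(seq(0, 530, by = 10), amplitude = 1, noise_sd = 0,
                      TR = 2.46, n_volumes = 216)
  sp <- power_spectrum(v - mean(v), TR = 2.46)
  f_peak <- sp$frequency[-1][which.max(sp$power[-1])]
  expect_lt(abs(f_peak - 0.1), sp$delta_f)
})

test_that("generated studies have disjoint masks and full truth coverage", {
  st <- generate_study(seed = 3)
  overlap <- Reduce(`+`, lapply(st$roi_masks, function(m) m * 1))
  expect_lte(max(overlap), 1)
  expect_equal(nrow(st$truth), sum(vapply(st$roi_masks, sum, numeric(1))))
  expect_true(all(is.finite(unlist(lapply(st$runs, range)))))
  # tagged counts follow the requested fractions
  byroi <- tapply(st$truth$tagged, st$truth$roi, mean)
  spec <- roi_spec()
  expect_equal(as.vector(byroi[spec$roi]), spec$fraction,
               tolerance = 1e-12)
  # deterministic given the seed
  st2 <- generate_study(seed = 3)
  expect_identical(st$runs, st2$runs)
  expect_identical(st$truth, st2$truth)
})

test_that("roi_series extracts time-by-voxel matrices aligned with truth", {
  st <- generate_study(spec = roi_spec(names = c("A", "B"),
                                       n_voxels = c(4, 3),
                                       fraction = c(0, 1), amplitude = 2,
                                       category = c(NA, "faces")),
                       n_runs = 2, seed = 5)
  m <- roi_series(st, "B", run = 2)
  expect_equal(dim(m), c(216L, 3L))
  expect_identical(m[, 2], st$runs[[2]][2, 2, 1, ])
  expect_error(roi_series(st, "nope"), "unknown ROI")
})

test_that("NIfTI round trip is lossless and errors are explicit", {
  st <- generate_study(spec = roi_spec(names = c("V1", "FFA"),
                                       n_voxels = 5,
                                       fraction = c(0, 1),
                                       amplitude = c(0, 2),
                                       category = c(NA, "faces")),
                       n_volumes = 20, n_runs = 2, seed = 8)
  d <- tempfile()
  write_study(st, d)
  back <- read_study(d)
  expect_identical(back$runs, st$runs)
  expect_equal(back$TR, st$TR)
  expect_identical(lapply(back$roi_masks, as.logical),
                   lapply(st$roi_masks, as.logical))
  expect_equal(back$truth$tagged, st$truth$tagged)
  # TR is carried in the header's 4th pixdim slot
  img <- RNifti::readNifti(file.path(d, "run_01.nii.gz"))
  expect_equal(RNifti::pixdim(img)[4], 2.46, tolerance = 1e-6)
  file.remove(file.path(d, "mask_FFA.nii.gz"))
  expect_error(read_study(d), "missing mask")
  expect_error(read_study(tempfile()), "missing truth.json")
})
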