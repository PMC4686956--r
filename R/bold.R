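# Synthetic BOLD generator: canonical double-gamma HRF, periodically driven
# voxels at the tagging frequencies, ROI-structured studies with recorded
# ground truth for recovery and calibration tests.

# continuous double-gamma evaluation, unit peak
.hrf_fun <- function(peak_time = 6, undershoot_time = 16, ratio = 6) {
  shape1 <- peak_time + 1
  shape2 <- undershoot_time + 1
  fine <- seq(0, undershoot_time + 16, by = 0.01)
  raw <- function(t) stats::dgamma(t, shape1, 1) -
    stats::dgamma(t, shape2, 1) / ratio
  scale <- max(raw(fine))
  function(t) ifelse(t < 0, 0, raw(pmax(t, 0)) / scale)
}

#' Canonical hemodynamic response kernel
#'
#' Double-gamma difference with a positive peak near `peak_time` seconds and
#' a late undershoot, normalized to unit peak and sampled at TR resolution.
#'
#' @param TR Repetition time in seconds (> 0).
#' @param duration Kernel support in seconds (default 32).
#' @param peak_time Mode of the positive lobe in seconds (default 6).
#' @param undershoot_time Mode of the undershoot lobe (default 16).
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @param amplitude Multiplier applied after unit-peak normalization.
#' @return Object of class `hrf_kernel`: list with `samples`, `times`, `TR`,
#'   `peak_time` (time of the sampled maximum).
#' @export
canonical_hrf <- function(TR, duration = 32, peak_time = 6,
                          undershoot_time = 16, ratio = 6, amplitude = 1) {
  if (TR <= 0) stop("TR must be positive")
  f <- .hrf_fun(peak_time, undershoot_time, ratio)
  times <- seq(0, duration, by = TR)
  samples <- amplitude * f(times)
  structure(list(samples = samples, times = times, TR = TR,
                 peak_time = times[which.max(samples)]),
            class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat("hrf_kernel: TR", x$TR, "s,", length(x$samples),
      "samples, peak at", x$peak_time, "s\n")
  invisible(x)
}

#' Simulate one voxel's BOLD time series
#'
#' Events at `onsets` evoke canonical responses of `amplitude` percent of
#' baseline; white Gaussian noise (optionally AR(1)-correlated) is added:
#' `baseline * (1 + amplitude/100 * sum_onsets hrf(t - onset)) + noise`.
#'
#' @param onsets Event times in seconds (within the run).
#' @param amplitude Response amplitude in percent signal change.
#' @param baseline Baseline intensity (default 100).
#' @param TR Repetition time in seconds.
#' @param n_volumes Number of volumes.
#' @param noise_sd Noise standard deviation in raw intensity units (>= 0).
#' @param seed Optional integer seed.
#' @param ar1 AR(1) coefficient of the noise (default 0: white).
#' @param hrf_params Optional list overriding `peak_time`,
#'   `undershoot_time`, `ratio` of the canonical response.
#' @return Numeric vector of length `n_volumes`.
#' @export
simulate_voxel <- function(onsets, amplitude, baseline = 100, TR = 2.46,
                           n_volumes = 216, noise_sd = 1, seed = NULL,
                           ar1 = 0, hrf_params = list()) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  run_len <- n_volumes * TR
  if (length(onsets) && any(onsets < 0 | onsets >= run_len))
    stop("onsets must lie within the run [0, ", run_len, ")")
  f <- do.call(.hrf_fun, hrf_params)
  times <- (seq_len(n_volumes) - 1) * TR
  resp <- if (length(onsets))
    rowSums(vapply(onsets, function(o) f(times - o), numeric(n_volumes)))
  else numeric(n_volumes)
  gen <- function() {
    eps <- stats::rnorm(n_volumes, 0, noise_sd)
    if (ar1 != 0)
      eps <- as.numeric(stats::filter(eps, ar1, method = "recursive")) *
        sqrt(1 - ar1^2)
    baseline * (1 + amplitude / 100 * resp) + eps
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' ROI specification for a synthetic study
#'
#' Default layout emulating a graded visual hierarchy: early retinotopic
#' areas (V1, V2) contain no frequency-tagged voxels, intermediate areas a
#' growing fraction, and the category-selective ROIs (FFA, PPA, LOC) are
#' fully tagged at their category's frequency — functionally-defined ROIs
#' consist of voxels selected because they respond, so their tagged fraction
#' is 1 by construction.
#'
#' @param names ROI names.
#' @param n_voxels Voxels per ROI.
#' @param fraction Fraction of tagged voxels per ROI, in `[0, 1]`.
#' @param amplitude Percent-signal response amplitude per ROI. Default: 1%
#'   in retinotopic areas, 2% in the category-selective ROIs, the typical
#'   range of category-evoked BOLD responses.
#' @param category Category label per ROI (`NA` = draw per tagged voxel).
#' @return Data frame with one row per ROI.
#' @export
roi_spec <- function(names = c("V1", "V2", "V3", "V4", "FFA", "PPA", "LOC"),
                     n_voxels = 200,
                     fraction = c(0, 0, 0.2, 0.4, 1, 1, 1),
                     amplitude = c(1, 1, 1, 1, 2, 2, 2),
                     category = c(NA, NA, NA, NA, "faces", "scenes",
                                  "objects")) {
  if (any(fraction < 0 | fraction > 1)) stop("fractions must be in [0, 1]")
  data.frame(roi = names,
             n_voxels = rep_len(n_voxels, length(names)),
             fraction = rep_len(fraction, length(names)),
             amplitude = rep_len(amplitude, length(names)),
             category = rep_len(category, length(names)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic frequency-tagged BOLD study
#'
#' Builds an ROI-labelled volume in which a specified fraction of each ROI's
#' voxels responds periodically (canonical response at every semantic onset
#' of its category's tagging frequency, with a random onset phase per voxel)
#' on top of baseline plus noise; the remaining voxels are baseline plus
#' noise only. The full per-voxel ground truth is recorded for recovery and
#' calibration tests and is excluded from analysis inputs.
#'
#' @param spec ROI table from [roi_spec()].
#' @param frequencies Named tagging frequencies in Hz
#'   (default `c(faces = 0.10, scenes = 0.06, objects = 0.08)`).
#' @param TR Repetition time in seconds (default 2.46).
#' @param n_volumes Volumes per run (default 216).
#' @param n_runs Number of runs (default 3).
#' @param noise_sd Noise SD in raw units (baseline is 100).
#' @param baseline Baseline intensity.
#' @param ar1 AR(1) noise coefficient.
#' @param seed Integer seed; the study is fully deterministic given it.
#' @return Object of class `bold_study`: `runs` (list of 4D arrays
#'   x,y,z,t), `roi_masks` (named logical 3D arrays, disjoint), `truth`
#'   (data frame: voxel coordinates, roi, tagged, frequency, amplitude,
#'   phase), `TR`, `n_volumes`, `frequencies`, `seed`, `dim`.
#' @export
generate_study <- function(spec = roi_spec(),
                           frequencies = c(faces = 0.10, scenes = 0.06,
                                           objects = 0.08),
                           TR = 2.46, n_volumes = 216, n_runs = 3,
                           noise_sd = 1, baseline = 100, ar1 = 0,
                           seed = 1) {
  stopifnot(is.data.frame(spec), n_runs >= 1)
  n_rois <- nrow(spec)
  nx <- max(spec$n_voxels)
  dims <- c(nx, n_rois, 1L)
  run_len <- n_volumes * TR
  hrf <- .hrf_fun()
  times <- (seq_len(n_volumes) - 1) * TR

  roi_masks <- lapply(seq_len(n_rois), function(r) {
    m <- array(FALSE, dims)
    m[seq_len(spec$n_voxels[r]), r, 1] <- TRUE
    m
  })
  names(roi_masks) <- spec$roi

  .with_seed(seed, {
    truth <- do.call(rbind, lapply(seq_len(n_rois), function(r) {
      nv <- spec$n_voxels[r]
      tagged <- logical(nv)
      n_tag <- round(spec$fraction[r] * nv)
      if (n_tag > 0) tagged[sample.int(nv, n_tag)] <- TRUE
      cat_r <- spec$category[r]
      cats <- rep(NA_character_, nv)
      cats[tagged] <- if (!is.na(cat_r)) cat_r else
        names(frequencies)[sample.int(length(frequencies), sum(tagged),
                                      replace = TRUE)]
      data.frame(x = seq_len(nv), y = r, z = 1L, roi = spec$roi[r],
                 tagged = tagged, category = cats,
                 frequency = unname(frequencies[cats]),
                 amplitude = ifelse(tagged, spec$amplitude[r], 0),
                 phase = ifelse(tagged,
                                stats::runif(nv) / unname(frequencies[cats]),
                                NA_real_),
                 stringsAsFactors = FALSE)
    }))
    # deterministic expected responses (shared across runs, stimulus-locked)
    resp <- matrix(0, n_volumes, nrow(truth))
    for (v in which(truth$tagged)) {
      onsets <- seq(truth$phase[v], run_len - 1e-9, by = 1 / truth$frequency[v])
      resp[, v] <- rowSums(vapply(onsets, function(o) hrf(times - o),
                                  numeric(n_volumes))) *
        truth$amplitude[v] / 100
    }
    runs <- lapply(seq_len(n_runs), function(rr) {
      eps <- matrix(stats::rnorm(n_volumes * nrow(truth), 0, noise_sd),
                    n_volumes, nrow(truth))
      if (ar1 != 0)
        eps <- apply(eps, 2, function(e)
          as.numeric(stats::filter(e, ar1, method = "recursive")) *
            sqrt(1 - ar1^2))
      series <- baseline * (1 + resp) + eps
      arr <- array(0, c(dims, n_volumes))
      for (v in seq_len(nrow(truth)))
        arr[truth$x[v], truth$y[v], truth$z[v], ] <- series[, v]
      arr
    })
  })
  structure(list(runs = runs, roi_masks = roi_masks, truth = truth,
                 TR = TR, n_volumes = n_volumes, n_runs = n_runs,
                 frequencies = frequencies, noise_sd = noise_sd,
                 baseline = baseline, seed = seed, dim = dims),
            class = "bold_study")
}

#' @export
print.bold_study <- function(x, ...) {
  cat("bold_study:", paste(x$dim, collapse = "x"), "volume,",
      x$n_runs, "runs x", x$n_volumes, "volumes, TR", x$TR, "s\n")
  cat("  ROIs:", paste(names(x$roi_masks), collapse = ", "), "\n")
  cat("  tagged voxels:", sum(x$truth$tagged), "/", nrow(x$truth), "\n")
  invisible(x)
}

#' Extract an ROI's voxel time series from one run
#'
#' @param study A `bold_study`.
#' @param roi ROI name.
#' @param run Run index.
#' @return `n_volumes` x `n_voxels` matrix (time in rows).
#' @export
roi_series <- function(study, roi, run = 1) {
  stopifnot(inherits(study, "bold_study"))
  mask <- study$roi_masks[[roi]]
  if (is.null(mask)) stop("unknown ROI: ", roi)
  arr <- study$runs[[run]]
  idx <- which(mask)
  nvol <- dim(arr)[4]
  m <- matrix(arr, prod(dim(arr)[1:3]), nvol)[idx, , drop = FALSE]
  t(m)
}

#' Write a synthetic study to NIfTI + JSON
#'
#' Each run is written as a double-precision NIfTI volume (`run_01.nii.gz`,
#' ...; TR stored in the 4th pixdim slot), each mask as an integer NIfTI
#' (`mask_<ROI>.nii.gz`), and the ground truth, seed and parameters as
#' `truth.json` (a sidecar that analysis functions never read).
#'
#' @param study A `bold_study`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "bold_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(study$runs)) {
    img <- RNifti::asNifti(study$runs[[r]])
    RNifti::pixdim(img) <- c(1, 1, 1, study$TR)
    RNifti::writeNifti(img, file.path(dir, sprintf("run_%02d.nii.gz", r)),
                       datatype = "double")
  }
  for (nm in names(study$roi_masks)) {
    img <- RNifti::asNifti(array(as.integer(study$roi_masks[[nm]]),
                                 study$dim))
    RNifti::writeNifti(img, file.path(dir, paste0("mask_", nm, ".nii.gz")),
                       datatype = "uint8")
  }
  sidecar <- list(TR = study$TR, n_volumes = study$n_volumes,
                  n_runs = study$n_runs, dim = study$dim,
                  frequencies = as.list(study$frequencies),
                  noise_sd = study$noise_sd, baseline = study$baseline,
                  seed = study$seed, rois = names(study$roi_masks),
                  truth = study$truth)
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing `run_*.nii.gz`, `mask_*.nii.gz`,
#'   `truth.json`.
#' @return A `bold_study` (series round trip is bit-identical).
#' @export
read_study <- function(dir) {
  sidefile <- file.path(dir, "truth.json")
  if (!file.exists(sidefile)) stop("missing truth.json in ", dir)
  side <- jsonlite::read_json(sidefile, simplifyVector = TRUE)
  runs <- lapply(seq_len(side$n_runs), function(r) {
    f <- file.path(dir, sprintf("run_%02d.nii.gz", r))
    if (!file.exists(f)) stop("missing run file: ", f)
    img <- RNifti::readNifti(f)
    arr <- array(as.numeric(img), dim(img))
    tr <- RNifti::pixdim(img)[4]
    if (abs(tr - side$TR) > 1e-6)
      stop("TR mismatch between header (", tr, ") and sidecar (", side$TR,
           ")")
    if (!identical(as.integer(dim(arr)[1:3]), as.integer(side$dim)))
      stop("shape mismatch in ", f)
    arr
  })
  masks <- lapply(side$rois, function(nm) {
    f <- file.path(dir, paste0("mask_", nm, ".nii.gz"))
    if (!file.exists(f)) stop("missing mask file: ", f)
    array(as.numeric(RNifti::readNifti(f)) > 0, side$dim)
  })
  names(masks) <- side$rois
  truth <- as.data.frame(side$truth)
  freqs <- unlist(side$frequencies)
  structure(list(runs = runs, roi_masks = masks, truth = truth,
                 TR = side$TR, n_volumes = side$n_volumes,
                 n_runs = side$n_runs, frequencies = freqs,
                 noise_sd = side$noise_sd, baseline = side$baseline,
                 seed = side$seed, dim = as.integer(side$dim)),
            class = "bold_study")
}
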