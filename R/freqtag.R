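# Frequency-domain analysis of tagged BOLD responses: percent signal change,
# power spectra, spectral SNR, noise-frequency sets, per-voxel tagging
# statistics with FDR control, phase maps and cycle-averaged time courses.

#' Percent signal change normalization
#'
#' Divides each voxel's series by its temporal mean and scales by 100, so
#' every voxel's transformed mean is 100 regardless of raw intensity.
#' Voxels with non-positive temporal mean are flagged: their output is `NA`
#' and a warning is raised.
#'
#' @param series Numeric vector (one voxel), matrix (time in rows, voxels in
#'   columns) or 4D array (x, y, z, t).
#' @return Same shape as the input.
#' @export
percent_signal_change <- function(series) {
  if (is.vector(series)) {
    m <- mean(series)
    if (!is.finite(m) || m <= 0) {
      warning("voxel with non-positive temporal mean excluded")
      return(rep(NA_real_, length(series)))
    }
    return(100 * series / m)
  }
  if (length(dim(series)) == 4) {
    d <- dim(series)
    m <- matrix(series, prod(d[1:3]), d[4])
    out <- t(percent_signal_change(t(m)))
    return(array(out, d))
  }
  mns <- colMeans(series)
  bad <- !is.finite(mns) | mns <= 0
  if (any(bad))
    warning(sum(bad), " voxel(s) with non-positive temporal mean excluded")
  out <- sweep(series, 2, mns, "/") * 100
  out[, bad] <- NA_real_
  out
}

.detrend <- function(x) {
  n <- NROW(x)
  tt <- seq_len(n)
  X <- cbind(1, tt - mean(tt))
  x - X %*% qr.solve(X, x)
}

#' One-sided discrete power spectrum
#'
#' FFT power on the frequency grid `k / (n * TR)`, `k = 0..floor(n/2)`, with
#' interior bins doubled so that the total one-sided power equals the series'
#' total energy (Parseval).
#'
#' @param series Numeric vector, length >= 8, no NAs.
#' @param TR Sampling interval in seconds.
#' @param detrend Remove a linear trend first (default `FALSE`; the study
#'   analysis pipeline detrends the percent-signal-change series before
#'   calling this).
#' @return Object of class `bold_spectrum`: list with `frequency`, `power`,
#'   `delta_f`, `n`, `TR`.
#' @export
power_spectrum <- function(series, TR, detrend = FALSE) {
  if (anyNA(series)) stop("series contains NA")
  n <- length(series)
  if (n < 8) stop("series too short (need >= 8 samples)")
  if (detrend) series <- as.numeric(.detrend(series))
  X <- stats::fft(series)
  half <- floor(n / 2)
  pw <- Mod(X[seq_len(half + 1)])^2 / n
  dbl <- seq(2, half + 1)
  if (n %% 2 == 0) dbl <- dbl[-length(dbl)]   # Nyquist bin not doubled
  pw[dbl] <- 2 * pw[dbl]
  structure(list(frequency = (0:half) / (n * TR), power = pw,
                 delta_f = 1 / (n * TR), n = n, TR = TR),
            class = "bold_spectrum")
}

# power spectra of many voxels at once: series matrix time x voxels
.power_matrix <- function(series, TR, detrend = TRUE) {
  n <- nrow(series)
  if (detrend) series <- .detrend(series)
  X <- stats::mvfft(series)
  half <- floor(n / 2)
  pw <- Mod(X[seq_len(half + 1), , drop = FALSE])^2 / n
  dbl <- seq(2, half + 1)
  if (n %% 2 == 0) dbl <- dbl[-length(dbl)]
  pw[dbl, ] <- 2 * pw[dbl, , drop = FALSE]
  list(frequency = (0:half) / (n * TR), power = pw, delta_f = 1 / (n * TR))
}

#' Spectral signal-to-noise ratio
#'
#' Per-bin power divided by the mean power in the surrounding band (default
#' 14 bins: 7 on each side, the center bin excluded from its own noise
#' estimate). Bins whose band would run off the grid edge are `NA`.
#'
#' @param spectrum A `bold_spectrum` (or a bare numeric power vector).
#' @param band_bins Total surrounding bins (even; default 14).
#' @return Same class as the input with `snr` added (or a numeric vector).
#' @export
snr_spectrum <- function(spectrum, band_bins = 14) {
  pw <- if (inherits(spectrum, "bold_spectrum")) spectrum$power else spectrum
  half <- band_bins / 2
  if (half != round(half)) stop("band_bins must be even")
  nb <- length(pw)
  snr <- rep(NA_real_, nb)
  lo <- half + 1
  hi <- nb - half
  if (hi >= lo) {
    offs <- c(-(half:1), 1:half)
    for (i in lo:hi) snr[i] <- pw[i] / mean(pw[i + offs])
  }
  if (inherits(spectrum, "bold_spectrum")) {
    spectrum$snr <- snr
    spectrum$band_bins <- band_bins
    spectrum
  } else snr
}

#' Noise-frequency set around the tagging frequencies
#'
#' Builds the set of noise bins used as the reference distribution of the
#' per-voxel tagging statistic: all integer frequency bins within
#' `half_band` bins of some tagging frequency but more than `guard` bins
#' away from every tagging frequency (distances measured to the exact,
#' fractional tag position `f / delta_f`). The defaults (`delta_f = 1/540`,
#' `half_band = 7.5`, `guard = 2.5`) reproduce the packaged 22-frequency set
#' for tags at 0.06/0.08/0.10 Hz; see [swift_noise_freqs].
#'
#' @param tag_freqs Tagging frequencies in Hz.
#' @param delta_f Frequency resolution in Hz (default 1/540).
#' @param half_band Band half-width in bins (default 7.5).
#' @param guard Guard half-width in bins (default 2.5; must be < half_band).
#' @return Sorted numeric vector of distinct noise frequencies in Hz, with
#'   the bin indices as attribute `bins`.
#' @export
noise_frequency_set <- function(tag_freqs, delta_f = 1 / 540,
                                half_band = 7.5, guard = 2.5) {
  if (guard >= half_band) stop("guard must be < half_band")
  tb <- tag_freqs / delta_f
  bins <- seq.int(max(1L, floor(min(tb) - half_band)),
                  ceiling(max(tb) + half_band))
  dist <- vapply(bins, function(b) min(abs(b - tb)), numeric(1))
  keep <- dist <= half_band & dist > guard
  bins <- bins[keep]
  if (!length(bins)) stop("empty noise-frequency set; widen half_band")
  structure(sort(unique(bins)) * delta_f, bins = sort(unique(bins)))
}

.nearest_bin <- function(freq, grid_delta, n_bins, warn = TRUE) {
  b <- round(freq / grid_delta)
  if (warn && any(abs(freq / grid_delta - b) > 0.25))
    warning("frequency off-grid by more than delta_f/4: ",
            paste(signif(freq[abs(freq / grid_delta - b) > 0.25], 4),
                  collapse = ", "))
  pmin(pmax(b, 0), n_bins - 1)
}

#' Per-voxel tagging statistics
#'
#' For each voxel, compares the spectral power at the tagging frequency
#' across runs (the signal sample, n = number of runs) with the power at the
#' noise frequencies across runs (the noise sample, n = runs x noise bins)
#' using a two-tailed two-sample t-test. By default the test is applied to
#' log power, which stabilizes the variance of spectral power estimates and
#' keeps the null distribution of p-values uniform; `log_power = FALSE`
#' applies it to raw power.
#'
#' @param spectra List over runs of power matrices (bins x voxels) as
#'   returned internally, or a list over runs of `n_volumes` x `n_voxels`
#'   time-series matrices with `series = TRUE`.
#' @param tag_freq Tagging frequency in Hz.
#' @param noise_freqs Noise frequencies in Hz (e.g. [noise_frequency_set()]
#'   or [swift_noise_freqs]); mapped to nearest grid bins, duplicates
#'   dropped.
#' @param TR Repetition time (needed when `series = TRUE`).
#' @param series Treat `spectra` as raw time-series matrices and compute
#'   percent-signal-change, detrended power spectra first.
#' @param log_power Apply the t-test to log power (default `TRUE`).
#' @return Object of class `voxel_stat_map`: list with `p`, `t` (numeric
#'   vectors per voxel), `df`, `tag_freq`, `tag_bin`, `noise_bins`.
#' @export
tagging_pvalues <- function(spectra, tag_freq, noise_freqs, TR = NULL,
                            series = FALSE, log_power = TRUE) {
  stopifnot(is.list(spectra), length(spectra) >= 1)
  if (series) {
    if (is.null(TR)) stop("TR required when series = TRUE")
    spectra <- lapply(spectra, function(m)
      .power_matrix(percent_signal_change(m), TR, detrend = TRUE))
  }
  if (!is.list(spectra[[1]]))
    stop("spectra must be a list of power lists or series matrices")
  delta_f <- spectra[[1]]$delta_f
  nbins <- nrow(spectra[[1]]$power)
  tag_bin <- .nearest_bin(tag_freq, delta_f, nbins)
  noise_bins <- unique(.nearest_bin(noise_freqs, delta_f, nbins))
  noise_bins <- setdiff(noise_bins, tag_bin)
  n_runs <- length(spectra)
  if (n_runs * length(noise_bins) < 2 || n_runs < 1)
    stop("need >= 2 samples overall for the t-test")
  V <- ncol(spectra[[1]]$power)
  tagm <- do.call(rbind, lapply(spectra, function(s)
    s$power[tag_bin + 1L, ]))                      # n_runs x V
  noim <- do.call(rbind, lapply(spectra, function(s)
    s$power[noise_bins + 1L, , drop = FALSE]))     # (n_runs*K) x V
  if (log_power) {
    tagm <- log(pmax(tagm, .Machine$double.xmin))
    noim <- log(pmax(noim, .Machine$double.xmin))
  }
  n1 <- nrow(tagm)
  n2 <- nrow(noim)
  m1 <- colMeans(tagm)
  m2 <- colMeans(noim)
  ss1 <- colSums(sweep(tagm, 2, m1)^2)
  ss2 <- colSums(sweep(noim, 2, m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / denom
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- denom == 0 | !is.finite(tstat)
  if (any(degen)) {
    warning(sum(degen), " voxel(s) with zero variance in both groups; p = 1")
    p[degen] <- 1
    tstat[degen] <- 0
  }
  structure(list(p = p, t = tstat, df = df, tag_freq = tag_freq,
                 tag_bin = tag_bin, noise_bins = noise_bins,
                 log_power = log_power),
            class = "voxel_stat_map")
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure controlling the false discovery rate at level `q`.
#' `NA` p-values are never rejected.
#'
#' @param pvals Numeric p-values in `[0, 1]` (any shape).
#' @param q FDR level (default 0.05).
#' @return Logical rejection mask, same shape as `pvals`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(logical(0))
  pv <- as.numeric(pvals)
  if (any(pv < 0 | pv > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  mask <- !is.na(pv) & stats::p.adjust(pv, method = "BH") <= q
  if (!is.null(dim(pvals))) dim(mask) <- dim(pvals)
  mask
}

#' Phase map at a stimulation frequency
#'
#' Extracts each voxel's response phase at the bin nearest the stimulation
#' frequency, masking out voxels whose spectral SNR at that bin falls below
#' the amplitude threshold (default >= 2, the criterion used for
#' phase-encoded retinotopic maps).
#'
#' @param series Matrix (time x voxels) or 4D array of raw intensities.
#' @param stim_freq Stimulation frequency in Hz.
#' @param TR Repetition time in seconds.
#' @param snr_threshold Minimum spectral SNR (default 2; 0 disables
#'   masking).
#' @param band_bins SNR band width, see [snr_spectrum()].
#' @return List with `phase` (radians in (-pi, pi], `NA` where masked),
#'   `snr`, `bin`, each per voxel (vectors, or 3D arrays for 4D input).
#' @export
phase_map <- function(series, stim_freq, TR, snr_threshold = 2,
                      band_bins = 14) {
  is4d <- length(dim(series)) == 4
  if (is4d) {
    d <- dim(series)
    series <- t(matrix(series, prod(d[1:3]), d[4]))
  }
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  n <- nrow(series)
  psc <- percent_signal_change(series)
  psc <- .detrend(psc)
  X <- stats::mvfft(psc)
  half <- floor(n / 2)
  bin <- .nearest_bin(stim_freq, 1 / (n * TR), half + 1)
  pw <- Mod(X[seq_len(half + 1), , drop = FALSE])^2 / n
  snr <- apply(pw, 2, function(p) snr_spectrum(p, band_bins)[bin + 1L])
  phase <- Arg(X[bin + 1L, ])
  phase[is.na(snr) | snr < snr_threshold] <- NA_real_
  if (is4d) {
    phase <- array(phase, d[1:3])
    snr <- array(snr, d[1:3])
  }
  list(phase = phase, snr = snr, bin = bin)
}

#' Cycle-averaged BOLD time course
#'
#' Extracts an epoch of length `window` seconds after every semantic onset
#' (onsets whose epoch runs past the series end are dropped), aligns the
#' epochs at time 0 and averages them; values between samples are obtained
#' by linear interpolation, which is exact when onsets fall on the sampling
#' grid. No baseline is subtracted by default (percent-signal-change input
#' hovers around 100).
#'
#' @param series Numeric vector (a voxel's or an ROI-mean time course).
#' @param onsets Semantic-onset times in seconds.
#' @param TR Sampling interval in seconds.
#' @param window Epoch length in seconds; must not exceed the smallest
#'   inter-onset gap unless `wrap = TRUE`.
#' @param wrap Allow the window to exceed the inter-onset gap (epochs then
#'   overlap the next cycle).
#' @param baseline `"none"` (default), `"first"` (subtract each epoch's
#'   first sample) or `"mean"` (subtract each epoch's mean).
#' @return Data frame with columns `time`, `mean`, `sem`, plus attribute
#'   `n_cycles`.
#' @export
cycle_average <- function(series, onsets, TR, window, wrap = FALSE,
                          baseline = c("none", "first", "mean")) {
  baseline <- match.arg(baseline)
  if (length(onsets) < 2) stop("need >= 2 onsets")
  gaps <- diff(sort(onsets))
  if (!wrap && window > min(gaps) + 1e-9)
    stop("window (", window, " s) exceeds the smallest inter-onset gap (",
         min(gaps), " s); set wrap = TRUE to allow overlap")
  n <- length(series)
  times <- (seq_len(n) - 1) * TR
  rel <- seq(0, window, by = TR)
  use <- onsets[onsets + window <= times[n] + 1e-9]
  if (length(use) < 2) stop("fewer than 2 complete cycles in the run")
  ep <- vapply(use, function(o)
    stats::approx(times, series, xout = o + rel)$y, numeric(length(rel)))
  ep <- switch(baseline,
               none = ep,
               first = sweep(ep, 2, ep[1, ]),
               mean = sweep(ep, 2, colMeans(ep)))
  out <- data.frame(time = rel, mean = rowMeans(ep),
                    sem = apply(ep, 1, stats::sd) / sqrt(ncol(ep)))
  attr(out, "n_cycles") <- ncol(ep)
  out
}

#' Frequency-tagging analysis of a synthetic study
#'
#' Convenience pipeline over a [generate_study()] object: percent signal
#' change, linear detrend, per-run power spectra, then [tagging_pvalues()]
#' at each tagging frequency against the study-grid noise set.
#'
#' @param study A `bold_study`.
#' @param tag_freqs Frequencies to test (default the study's).
#' @param noise_freqs Noise frequencies; default is [noise_frequency_set()]
#'   on the study's own frequency grid.
#' @param log_power See [tagging_pvalues()].
#' @return Named list over tagging frequencies of `voxel_stat_map`s whose
#'   `p`/`t` vectors follow the study's `truth` row order.
#' @export
tagging_analysis <- function(study, tag_freqs = NULL, noise_freqs = NULL,
                             log_power = TRUE) {
  stopifnot(inherits(study, "bold_study"))
  if (is.null(tag_freqs)) tag_freqs <- study$frequencies
  delta_f <- 1 / (study$n_volumes * study$TR)
  if (is.null(noise_freqs))
    noise_freqs <- noise_frequency_set(sort(unname(study$frequencies)),
                                       delta_f = delta_f)
  series <- lapply(seq_len(study$n_runs), function(r)
    do.call(cbind, lapply(names(study$roi_masks), function(roi)
      roi_series(study, roi, r))))
  spectra <- lapply(series, function(m)
    .power_matrix(percent_signal_change(m), study$TR, detrend = TRUE))
  maps <- lapply(tag_freqs, function(f)
    tagging_pvalues(spectra, f, noise_freqs, log_power = log_power))
  names(maps) <- if (!is.null(names(tag_freqs))) names(tag_freqs) else
    as.character(tag_freqs)
  maps
}
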