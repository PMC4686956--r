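# Deterministic synthetic images with category-like structure, used by tests
# and documentation in place of downloaded photographs.

.disk <- function(gx, gy, cx, cy, r, soft = 2) {
  d <- sqrt((gx - cx)^2 + (gy - cy)^2)
  stats::plogis((r - d) / soft)
}

#' Deterministic synthetic fixture images
#'
#' Three kinds of category-like images: `"geometric-face"` (oval outline,
#' eyes, mouth: long coherent contours), `"geometric-scene"` (horizon and
#' blocky structures) and `"texture"` (the face image with its Fourier
#' phases randomized, so its amplitude spectrum — hence radially averaged
#' power — matches the face's while all coherent contours are destroyed).
#' Same seed, same image, always.
#'
#' @param kind One of `"geometric-face"`, `"geometric-scene"`, `"texture"`.
#' @param side Image side, a power of two (default 512).
#' @param seed Integer seed.
#' @return `side` x `side` matrix in `[0, 1]`.
#' @export
fixture_images <- function(kind = c("geometric-face", "geometric-scene",
                                    "texture"),
                           side = 512L, seed = 1) {
  kind <- match.arg(kind)
  if (side < 8 || bitwAnd(as.integer(side), as.integer(side) - 1L) != 0L)
    stop("side must be a power of two >= 8")
  s <- side
  gx <- matrix(rep(seq_len(s), s), s, s)
  gy <- t(gx)
  soft <- s / 256
  img <- .with_seed(seed, {
    bg <- matrix(stats::rnorm(s * s, 0, 0.04), s, s)
    if (kind == "geometric-scene") {
      horizon <- 0.55 * s + 0.02 * s * sin(2 * pi * gx[, 1] / s)
      x <- 0.35 + 0.3 * (gy > horizon)
      nb <- 4
      w <- s / 8
      for (b in seq_len(nb)) {
        cx <- (b - 0.5) * s / nb + stats::runif(1, -w / 4, w / 4)
        h <- stats::runif(1, 0.2, 0.45) * s
        x <- x + 0.25 * stats::plogis((w / 2 - abs(gx - cx)) / soft) *
          stats::plogis((0.55 * s - gy) / soft) *
          stats::plogis((gy - (0.55 * s - h)) / soft)
      }
      x + bg
    } else {
      # face used directly or as the spectral donor for the texture
      cx <- s / 2 + stats::runif(1, -s / 50, s / 50)
      cy <- s / 2
      x <- matrix(0.35, s, s)
      oval <- sqrt(((gx - cx) / (0.30 * s))^2 + ((gy - cy) / (0.38 * s))^2)
      x <- x + 0.35 * stats::plogis((1 - oval) / (2 * soft / s * 3)) # head
      x <- x - 0.25 * .disk(gx, gy, cx - 0.12 * s, cy - 0.10 * s,
                            0.045 * s, soft)
      x <- x - 0.25 * .disk(gx, gy, cx + 0.12 * s, cy - 0.10 * s,
                            0.045 * s, soft)
      mouth <- abs(sqrt((gx - cx)^2 + (gy - (cy + 0.08 * s))^2) - 0.14 * s)
      x <- x - 0.2 * stats::plogis((0.02 * s - mouth) / soft) *
        (gy > cy + 0.10 * s)
      x <- x + bg
      if (kind == "texture") {
        # phase scramble: keep |F|, take the phase of a random real field
        Fx <- stats::fft(x)
        Fn <- stats::fft(matrix(stats::rnorm(s * s), s, s))
        x <- Re(stats::fft(Mod(Fx) * Fn / pmax(Mod(Fn), 1e-12),
                           inverse = TRUE)) / (s * s)
      }
      x
    }
  })
  rng <- range(img)
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Radially averaged power spectrum of an image
#'
#' Mean squared Fourier magnitude in integer-radius frequency bins,
#' DC excluded; used to verify that fixtures of different kinds share their
#' low-level spectral content.
#'
#' @param image Square matrix.
#' @param n_bins Number of radial bins (default `side/2`).
#' @return Numeric vector of band powers (normalized to unit sum).
#' @export
radial_spectrum <- function(image, n_bins = nrow(image) / 2) {
  s <- nrow(image)
  P <- Mod(stats::fft(image - mean(image)))^2
  f <- c(0:(s %/% 2), -((s - s %/% 2 - 1):1)) / s
  fr <- sqrt(outer(f[seq_len(s)]^2, f[seq_len(s)]^2, "+"))
  bin <- pmin(1L + as.integer(fr * s), n_bins)
  out <- vapply(seq_len(n_bins), function(b) sum(P[bin == b]), numeric(1))
  out[1] <- out[1] - P[1, 1]   # drop DC
  out / sum(out)
}
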