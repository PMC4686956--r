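# -- Orthonormal wavelet filter banks -----------------------------------------

#' Orthonormal wavelet filters
#'
#' Returns the scaling (low-pass) filter of a compactly supported orthonormal
#' wavelet family. The quadrature mirror high-pass filter is derived as
#' `g[k] = (-1)^k h[L-1-k]`. Orthonormality is what makes the decomposition
#' energy-conserving under periodic extension, a property the scrambling
#' engine relies on.
#'
#' @param family One of `"haar"`, `"d4"` (4-tap Daubechies, the default
#'   elsewhere in the package) or `"d6"` (6-tap Daubechies).
#' @return List with elements `h` (low-pass) and `g` (high-pass), both
#'   unit-norm numeric vectors.
#' @export
wavelet_filters <- function(family = c("d4", "haar", "d6")) {
  family <- match.arg(family)
  h <- switch(family,
    haar = c(1, 1) / sqrt(2),
    d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    d6 = c(0.33267055295095688, 0.80689150931333875, 0.45987750211933132,
           -0.13501102001039084, -0.08544127388224149, 0.03522629188210562)
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g, family = family)
}

# One level of the periodized decimated transform along the first dimension.
# x must have an even number of rows; returns half-height lo and hi bands.
.dwt_cols <- function(x, h, g) {
  n <- nrow(x)
  n2 <- n / 2L
  lo <- matrix(0, n2, ncol(x))
  hi <- matrix(0, n2, ncol(x))
  base <- 2L * (seq_len(n2) - 1L)
  for (k in seq_along(h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    xs <- x[idx, , drop = FALSE]
    lo <- lo + h[k] * xs
    hi <- hi + g[k] * xs
  }
  list(lo = lo, hi = hi)
}

.idwt_cols <- function(lo, hi, h, g) {
  n2 <- nrow(lo)
  n <- 2L * n2
  y <- matrix(0, n, ncol(lo))
  base <- 2L * (seq_len(n2) - 1L)
  for (k in seq_along(h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    y[idx, ] <- y[idx, ] + h[k] * lo + g[k] * hi
  }
  y
}

.dwt2_step <- function(x, f) {
  cb <- .dwt_cols(x, f$h, f$g)                 # along dim 1
  lo <- .dwt_cols(t(cb$lo), f$h, f$g)          # along dim 2
  hi <- .dwt_cols(t(cb$hi), f$h, f$g)
  # band naming: H responds to horizontally oriented structure (high-pass
  # across rows, low-pass across columns), V to vertical, D to diagonal.
  list(LL = t(lo$lo), V = t(lo$hi), H = t(hi$lo), D = t(hi$hi))
}

.idwt2_step <- function(LL, H, V, D, f) {
  lo <- t(.idwt_cols(t(LL), t(V), f$h, f$g))
  hi <- t(.idwt_cols(t(H), t(D), f$h, f$g))
  .idwt_cols(lo, hi, f$h, f$g)
}

# -- Pyramid ------------------------------------------------------------------

#' Multiscale wavelet decomposition of a square grayscale image
#'
#' Decomposes a square image (side a multiple of `2^levels`) into `levels`
#' scales of horizontal/vertical/diagonal detail bands plus a coarsest
#' approximation band, using a periodized orthonormal transform so that
#' coefficient counts per scale are exactly `(side/2^s)^2` per orientation and
#' total coefficient energy equals image energy.
#'
#' @param image Numeric matrix, square, finite values. Typically intensities
#'   in `[0, 1]` (see [as_gray_image()]).
#' @param levels Number of decomposition scales (>= 1).
#' @param family Wavelet family name, see [wavelet_filters()].
#' @return An object of class `wavelet_pyramid`: list with `approx` (matrix),
#'   `detail` (list per scale of matrices `H`, `V`, `D`), `side`, `levels`,
#'   `family`.
#' @seealso [reconstruct()], [orientation_vectors()]
#' @export
decompose <- function(image, levels, family = "d4") {
  image <- as.matrix(image)
  if (nrow(image) != ncol(image))
    stop("image must be square; got ", nrow(image), "x", ncol(image))
  if (!all(is.finite(image))) stop("image contains non-finite values")
  side <- nrow(image)
  if (levels < 1L) stop("levels must be >= 1")
  if (side %% 2L^levels != 0L)
    stop("image side (", side, ") is not divisible by 2^levels (", 2L^levels, ")")
  f <- wavelet_filters(family)
  detail <- vector("list", levels)
  cur <- image
  for (s in seq_len(levels)) {
    b <- .dwt2_step(cur, f)
    detail[[s]] <- list(H = b$H, V = b$V, D = b$D)
    cur <- b$LL
  }
  structure(
    list(approx = cur, detail = detail, side = side, levels = levels,
         family = f$family),
    class = "wavelet_pyramid"
  )
}

#' Reconstruct an image from a wavelet pyramid
#'
#' Exact inverse of [decompose()] (round-trip error is at floating-point
#' level, well below 1e-8).
#'
#' @param pyramid A `wavelet_pyramid`.
#' @return Numeric square matrix of side `pyramid$side`.
#' @export
reconstruct <- function(pyramid) {
  stopifnot(inherits(pyramid, "wavelet_pyramid"))
  f <- wavelet_filters(pyramid$family)
  cur <- pyramid$approx
  for (s in rev(seq_len(pyramid$levels))) {
    d <- pyramid$detail[[s]]
    if (nrow(d$H) != nrow(cur) || nrow(d$V) != nrow(cur) ||
        nrow(d$D) != nrow(cur))
      stop("shape mismatch between scales at scale ", s)
    cur <- .idwt2_step(cur, d$H, d$V, d$D, f)
  }
  cur
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat("wavelet_pyramid:", x$side, "x", x$side, "image,", x$levels,
      "levels, family", x$family, "\n")
  cat("  detail locations:", sum((x$side / 2^seq_len(x$levels))^2), "\n")
  invisible(x)
}

# Number of detail locations (one 3D orientation vector each).
.n_locations <- function(pyramid) {
  sum((pyramid$side / 2^seq_len(pyramid$levels))^2)
}

# Flatten all detail bands into an n x 3 matrix (columns H, V, D), rows in a
# fixed scale-major, column-major-within-band order. Inverse: .set_detail_matrix.
.detail_matrix <- function(pyramid) {
  m <- matrix(0, .n_locations(pyramid), 3)
  colnames(m) <- c("H", "V", "D")
  off <- 0L
  for (s in seq_len(pyramid$levels)) {
    d <- pyramid$detail[[s]]
    k <- length(d$H)
    m[off + seq_len(k), 1] <- as.vector(d$H)
    m[off + seq_len(k), 2] <- as.vector(d$V)
    m[off + seq_len(k), 3] <- as.vector(d$D)
    off <- off + k
  }
  m
}

.set_detail_matrix <- function(pyramid, m) {
  off <- 0L
  for (s in seq_len(pyramid$levels)) {
    sz <- nrow(pyramid$detail[[s]]$H)
    k <- sz * sz
    pyramid$detail[[s]]$H <- matrix(m[off + seq_len(k), 1], sz, sz)
    pyramid$detail[[s]]$V <- matrix(m[off + seq_len(k), 2], sz, sz)
    pyramid$detail[[s]]$D <- matrix(m[off + seq_len(k), 3], sz, sz)
    off <- off + k
  }
  pyramid
}

#' Orientation vectors of a wavelet pyramid
#'
#' At every scale and location the three detail coefficients (H, V, D) form a
#' 3D orientation vector whose Euclidean norm is the coefficient's local
#' contour energy. The SWIFT scrambler moves these vectors along isoenergetic
#' circular paths, so the norm column is the quantity conserved frame to
#' frame.
#'
#' @param pyramid A `wavelet_pyramid`.
#' @return Data frame with columns `scale`, `row`, `col`, `wH`, `wV`, `wD`,
#'   `norm`; one row per (scale, location).
#' @export
orientation_vectors <- function(pyramid) {
  stopifnot(inherits(pyramid, "wavelet_pyramid"))
  m <- .detail_matrix(pyramid)
  key <- do.call(rbind, lapply(seq_len(pyramid$levels), function(s) {
    sz <- pyramid$side / 2^s
    cbind(scale = s,
          row = rep(seq_len(sz), times = sz),
          col = rep(seq_len(sz), each = sz))
  }))
  data.frame(key, wH = m[, 1], wV = m[, 2], wD = m[, 3],
             norm = sqrt(rowSums(m^2)))
}

#' Rebuild a pyramid from orientation vectors and an approximation band
#'
#' Inverse of [orientation_vectors()]: given the vector table (in the order
#' that function emits) and the untouched approximation band, reproduces the
#' pyramid exactly.
#'
#' @param vectors Data frame from [orientation_vectors()] (or any object with
#'   `wH`, `wV`, `wD` columns in the same order), or an n x 3 matrix.
#' @param approx Approximation band matrix.
#' @param side,levels,family Pyramid geometry.
#' @return A `wavelet_pyramid`.
#' @export
pyramid_from_vectors <- function(vectors, approx, side, levels, family = "d4") {
  if (is.data.frame(vectors))
    vectors <- as.matrix(vectors[, c("wH", "wV", "wD")])
  skel <- structure(
    list(approx = approx,
         detail = lapply(seq_len(levels), function(s) {
           sz <- side / 2^s
           z <- matrix(0, sz, sz)
           list(H = z, V = z, D = z)
         }),
         side = side, levels = levels, family = family),
    class = "wavelet_pyramid"
  )
  if (nrow(vectors) != .n_locations(skel))
    stop("vector count (", nrow(vectors), ") does not match pyramid geometry")
  .set_detail_matrix(skel, vectors)
}

#' Total detail energy of a pyramid
#'
#' Sum of squared detail coefficients over all scales and orientations; the
#' quantity SWIFT scrambling holds constant across frames.
#'
#' @param pyramid A `wavelet_pyramid`.
#' @return Scalar.
#' @export
detail_energy <- function(pyramid) sum(.detail_matrix(pyramid)^2)

# -- Image I/O and conditioning -----------------------------------------------

#' Condition an array into a normalized square grayscale image
#'
#' Converts RGB(A) to luminance (Rec. 601 weights), rescales intensities to
#' `[0, 1]`, center-crops to a square and bilinearly resamples to a
#' power-of-two side, ready for [decompose()].
#'
#' @param x Numeric matrix or 3D array (height x width x channels).
#' @param side Target side, a power of two. Default 512, which supports the
#'   9-level decomposition used for stimulus generation.
#' @return `side` x `side` matrix in `[0, 1]`.
#' @export
as_gray_image <- function(x, side = 512L) {
  if (length(dim(x)) == 3L) {
    nc <- dim(x)[3]
    w <- if (nc >= 3) c(0.299, 0.587, 0.114) else rep(1 / nc, nc)
    x <- Reduce(`+`, lapply(seq_len(min(nc, 3L)), function(i) w[i] * x[, , i]))
  }
  x <- as.matrix(x)
  if (bitwAnd(side, side - 1L) != 0L || side < 1L)
    stop("side must be a power of two")
  rng <- range(x)
  x <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0 + 0.5
  # center crop to square
  n <- min(dim(x))
  r0 <- (nrow(x) - n) %/% 2L
  c0 <- (ncol(x) - n) %/% 2L
  x <- x[r0 + seq_len(n), c0 + seq_len(n), drop = FALSE]
  if (n == side) return(x)
  # bilinear resample to side x side
  src <- (seq_len(side) - 0.5) * n / side + 0.5
  i0 <- pmin(pmax(floor(src), 1L), n)
  i1 <- pmin(i0 + 1L, n)
  fr <- src - i0
  rows <- x[i0, , drop = FALSE] * (1 - fr) + x[i1, , drop = FALSE] * fr
  t(t(rows[, i0, drop = FALSE]) * (1 - fr) + t(rows[, i1, drop = FALSE]) * fr)
}

#' Read an image file as a normalized grayscale matrix
#'
#' Supports PNG and TIFF input; see [as_gray_image()] for the conditioning
#' applied.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @param side Target power-of-two side.
#' @return Square numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path, side = 512L) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, " (PNG and TIFF are supported)")
  )
  as_gray_image(x, side = side)
}

#' Write a grayscale matrix to a PNG file
#'
#' @param image Matrix with values in `[0, 1]` (clamped on write).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
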