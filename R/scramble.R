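# SWIFT scrambling: isoenergetic circular paths in (H,V,D) orientation space,
# harmonic temporal schedules, frame rendering and the relative image
# similarity (RIS) measure.

# Evaluate an expression with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so library calls never perturb user randomness.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.row_norms <- function(m) sqrt(rowSums(m^2))

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Vectorized isoenergetic path construction. anchors: n x 3. Returns
# center, u (= anchor - center), w (in-plane normal direction, |w| = |u|).
# For each anchor two additional random vectors of the same norm are drawn;
# the circle through the three equal-norm points lies on their common sphere,
# so every path point conserves the anchor norm.
.make_paths_matrix <- function(anchors) {
  n <- nrow(anchors)
  r <- .row_norms(anchors)
  rand_sphere <- function(k, rr) {
    v <- matrix(stats::rnorm(3 * k), k, 3)
    v / .row_norms(v) * rr
  }
  p2 <- rand_sphere(n, r)
  p3 <- rand_sphere(n, r)
  center <- u <- w <- matrix(0, n, 3)
  live <- r > 0
  # redraw near-degenerate triples (collinear points give no unique circle)
  for (iter in 1:50) {
    a <- p2 - anchors
    b <- p3 - anchors
    nv <- .cross3(a, b)
    bad <- live & (.row_norms(nv) < 1e-8 * pmax(r^2, 1e-300))
    if (!any(bad)) break
    p2[bad, ] <- rand_sphere(sum(bad), r[bad])
    p3[bad, ] <- rand_sphere(sum(bad), r[bad])
  }
  if (any(live)) {
    a <- a[live, , drop = FALSE]
    b <- b[live, , drop = FALSE]
    nv <- nv[live, , drop = FALSE]
    a2 <- rowSums(a^2)
    b2 <- rowSums(b^2)
    denom <- 2 * rowSums(nv^2)
    cen <- anchors[live, , drop = FALSE] +
      (b2 * .cross3(nv, a) + a2 * .cross3(b, nv)) / denom
    uu <- anchors[live, , drop = FALSE] - cen
    nhat <- nv / .row_norms(nv)
    ww <- .cross3(nhat, uu)
    center[live, ] <- cen
    u[live, ] <- uu
    w[live, ] <- ww
  }
  list(center = center, u = u, w = w)
}

#' Isoenergetic circular path through an orientation vector
#'
#' Given an anchor vector in (H,V,D) orientation space, draws two further
#' vectors with random orientations but the same Euclidean norm and returns
#' the unique circle through the three points. Because all three lie on the
#' sphere of radius `|anchor|`, every point of the path has exactly the
#' anchor's norm: moving a wavelet coefficient along it scrambles local
#' contour orientation while conserving local energy. A zero anchor yields
#' the degenerate constant path at the origin.
#'
#' @param anchor Numeric length-3 vector.
#' @param seed Optional integer seed for the two random defining vectors.
#' @return Object of class `circular_path`: list with `anchor`, `center`,
#'   `basis` (2 x 3 matrix of orthonormal in-plane directions), `radius`.
#' @seealso [path_points()]
#' @export
build_isoenergetic_path <- function(anchor, seed = NULL) {
  stopifnot(length(anchor) == 3, all(is.finite(anchor)))
  m <- rbind(as.numeric(anchor))
  g <- if (is.null(seed)) .make_paths_matrix(m) else
    .with_seed(seed, .make_paths_matrix(m))
  radius <- .row_norms(g$u)
  basis <- if (radius > 0) rbind(g$u[1, ] / radius, g$w[1, ] / radius) else
    matrix(0, 2, 3)
  structure(list(anchor = as.numeric(anchor), center = g$center[1, ],
                 basis = basis, radius = radius),
            class = "circular_path")
}

#' Evaluate points on a circular path
#'
#' `path_points(p, 0)` returns the anchor exactly; the path is 2*pi-periodic.
#'
#' @param path A `circular_path`.
#' @param theta Numeric vector of angles (radians).
#' @return `length(theta)` x 3 matrix of points.
#' @export
path_points <- function(path, theta) {
  stopifnot(inherits(path, "circular_path"))
  out <- outer(rep(1, length(theta)), path$center) +
    path$radius * (cos(theta) %o% path$basis[1, ] +
                   sin(theta) %o% path$basis[2, ])
  out[theta == 0, ] <- rep(path$anchor, each = sum(theta == 0))
  out
}

#' Build a SWIFT scrambling schedule for a pyramid
#'
#' Assigns every coefficient location an isoenergetic circular path (one per
#' independent path geometry) and a harmonic multiplier drawn uniformly from
#' `1:n_harmonics`. During a cycle of `frames_per_cycle` frames, location `c`
#' traverses its path with angle `theta_c(t) = 2*pi * h_c * t /
#' frames_per_cycle`, so all locations re-align at their anchors exactly at
#' cycle boundaries — the semantic onsets — and nowhere else when several
#' harmonics are in play. Successive cycles rotate through `n_paths`
#' independently randomized path geometries, so consecutive cycles traverse
#' different scrambled frames while each still anchors at the original.
#'
#' @param pyramid A `wavelet_pyramid` of the image to scramble.
#' @param n_harmonics Number of harmonic modulation frequencies (default 8).
#' @param frames_per_cycle Frames per scrambling cycle (default 200).
#' @param n_paths Number of independent path geometries (default 3).
#' @param seed Integer seed; the whole schedule is a deterministic function
#'   of (pyramid, parameters, seed).
#' @return Object of class `scramble_schedule`.
#' @export
make_schedule <- function(pyramid, n_harmonics = 8, frames_per_cycle = 200,
                          n_paths = 3, seed = 1) {
  stopifnot(inherits(pyramid, "wavelet_pyramid"))
  if (n_harmonics < 1) stop("n_harmonics must be >= 1")
  if (frames_per_cycle < 2) stop("frames_per_cycle must be >= 2")
  if (n_paths < 1) stop("n_paths must be >= 1")
  anchors <- .detail_matrix(pyramid)
  n <- nrow(anchors)
  .with_seed(seed, {
    harmonic <- sample.int(n_harmonics, n, replace = TRUE)
    geoms <- lapply(seq_len(n_paths), function(g) .make_paths_matrix(anchors))
  })
  structure(
    list(anchors = anchors, harmonic = harmonic, geoms = geoms,
         diameters = vapply(geoms, function(g) 2 * .row_norms(g$u),
                            numeric(n)),
         frames_per_cycle = as.integer(frames_per_cycle),
         n_harmonics = as.integer(n_harmonics),
         n_paths = as.integer(n_paths), seed = seed,
         side = pyramid$side, levels = pyramid$levels,
         family = pyramid$family),
    class = "scramble_schedule"
  )
}

#' @export
print.scramble_schedule <- function(x, ...) {
  cat("scramble_schedule:", nrow(x$anchors), "locations,",
      x$n_harmonics, "harmonics,", x$frames_per_cycle, "frames/cycle,",
      x$n_paths, "path geometries, seed", x$seed, "\n")
  invisible(x)
}

.check_schedule_pyramid <- function(pyramid, schedule) {
  if (pyramid$side != schedule$side || pyramid$levels != schedule$levels)
    stop("schedule/pyramid mismatch: schedule built for ", schedule$side,
         "x", schedule$side, " @ ", schedule$levels, " levels")
}

#' Scrambled orientation vectors at a frame index
#'
#' Evaluates every location's path at its frame-`t` angle (0-based frames;
#' frame 0 and every multiple of `frames_per_cycle` are semantic onsets where
#' the anchors are reproduced exactly).
#'
#' @param schedule A `scramble_schedule`.
#' @param t Frame index (0-based integer).
#' @return n x 3 matrix of (H,V,D) coefficients.
#' @export
schedule_coefficients <- function(schedule, t) {
  stopifnot(inherits(schedule, "scramble_schedule"), t >= 0)
  fpc <- schedule$frames_per_cycle
  cyc <- (t %/% fpc) %% schedule$n_paths + 1L
  g <- schedule$geoms[[cyc]]
  # integer phase keeps the exact-anchor case exact
  ph <- (schedule$harmonic * (t %% fpc)) %% fpc
  theta <- 2 * pi * ph / fpc
  out <- g$center + g$u * cos(theta) + g$w * sin(theta)
  at0 <- ph == 0L
  if (any(at0)) out[at0, ] <- schedule$anchors[at0, ]
  out
}

#' Render one SWIFT frame
#'
#' Replaces the pyramid's detail coefficients by their scheduled path
#' positions at frame `t` and reconstructs the image. The approximation band
#' is left untouched (local luminance is preserved) and every orientation
#' vector keeps its anchor norm (global contrast and local spatial frequency
#' are preserved).
#'
#' @param pyramid The reference `wavelet_pyramid`.
#' @param schedule Matching `scramble_schedule`.
#' @param t Frame index (0-based).
#' @param as_image If `FALSE`, return the scrambled pyramid instead of the
#'   reconstructed image.
#' @return Square image matrix (or `wavelet_pyramid`).
#' @export
render_frame <- function(pyramid, schedule, t, as_image = TRUE) {
  .check_schedule_pyramid(pyramid, schedule)
  pf <- .set_detail_matrix(pyramid, schedule_coefficients(schedule, t))
  if (as_image) reconstruct(pf) else pf
}

#' Generate a SWIFT movie
#'
#' End-to-end stimulus generation: decompose the image, build a scrambling
#' schedule and define a movie of `n_cycles * frames_per_cycle` frames whose
#' semantic onsets (full revelations of the original) fall at frames
#' `0, frames_per_cycle, 2*frames_per_cycle, ...` (0-based).
#'
#' Frames are rendered lazily via [movie_frame()]; set `keep_frames = TRUE`
#' to materialize all of them (memory: `side^2 * 8` bytes per frame).
#'
#' @param image Square grayscale matrix (side divisible by `2^levels`).
#' @param levels Wavelet decomposition levels (default 9, requiring side 512).
#' @param n_harmonics,frames_per_cycle,n_paths,seed See [make_schedule()].
#' @param n_cycles Number of scrambling cycles (default 3).
#' @param family Wavelet family.
#' @param keep_frames Materialize the frame list.
#' @return Object of class `swift_movie`: `pyramid`, `schedule`, `n_frames`,
#'   `frames_per_cycle`, `semantic_onset_frames` (0-based), optional
#'   `frames`.
#' @export
generate_movie <- function(image, levels = 9, n_harmonics = 8,
                           frames_per_cycle = 200, n_cycles = 3, n_paths = 3,
                           seed = 1, family = "d4", keep_frames = FALSE) {
  pyr <- decompose(image, levels, family)
  sch <- make_schedule(pyr, n_harmonics = n_harmonics,
                       frames_per_cycle = frames_per_cycle,
                       n_paths = n_paths, seed = seed)
  n_frames <- as.integer(n_cycles * frames_per_cycle)
  mv <- structure(
    list(pyramid = pyr, schedule = sch, n_frames = n_frames,
         frames_per_cycle = as.integer(frames_per_cycle),
         n_cycles = as.integer(n_cycles),
         semantic_onset_frames = as.integer(seq(0, n_cycles - 1) *
                                              frames_per_cycle),
         frames = NULL),
    class = "swift_movie"
  )
  if (keep_frames)
    mv$frames <- lapply(seq(0, n_frames - 1), function(t)
      render_frame(pyr, sch, t))
  mv
}

#' @export
print.swift_movie <- function(x, ...) {
  cat("swift_movie:", x$n_frames, "frames (", x$n_cycles, "cycles x",
      x$frames_per_cycle, "),", x$pyramid$side, "px,",
      "onsets at", paste(x$semantic_onset_frames, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one frame of a SWIFT movie
#'
#' @param movie A `swift_movie`.
#' @param t 0-based frame index in `[0, n_frames - 1]`.
#' @return Square image matrix.
#' @export
movie_frame <- function(movie, t) {
  stopifnot(inherits(movie, "swift_movie"), t >= 0, t < movie$n_frames)
  if (!is.null(movie$frames)) return(movie$frames[[t + 1L]])
  render_frame(movie$pyramid, movie$schedule, t)
}

#' Relative image similarity (RIS)
#'
#' Quantifies how close a scrambled frame is to the original on a 0-100
#' scale. For each coefficient location the (H,V,D) orientation-vector
#' difference between reference and frame is divided by that location's
#' normalizer (its maximal attainable deviation, the path diameter) and
#' clipped at 1; RIS is `100 * mean(1 - |dW|)`. RIS = 100 when the frame
#' equals the reference and 0 when every location sits at its maximal
#' deviation. Locations whose normalizer is zero cannot deviate and
#' contribute perfect similarity.
#'
#' @param reference Reference `wavelet_pyramid`.
#' @param frame_pyramid Frame `wavelet_pyramid` (same geometry).
#' @param normalizer Positive per-location scales (length = number of
#'   locations), e.g. [schedule_normalizer()].
#' @return Scalar in `[0, 100]`.
#' @export
ris <- function(reference, frame_pyramid, normalizer) {
  stopifnot(inherits(reference, "wavelet_pyramid"),
            inherits(frame_pyramid, "wavelet_pyramid"))
  if (reference$side != frame_pyramid$side ||
      reference$levels != frame_pyramid$levels)
    stop("reference/frame pyramid shape mismatch")
  d <- .row_norms(.detail_matrix(frame_pyramid) - .detail_matrix(reference))
  if (length(normalizer) != length(d))
    stop("normalizer length (", length(normalizer),
         ") does not match location count (", length(d), ")")
  dW <- ifelse(normalizer > 0, pmin(1, d / normalizer), 0)
  100 * mean(1 - dW)
}

#' Per-location RIS normalizer of a schedule
#'
#' The maximal orientation-vector deviation attainable on each location's
#' path during a given cycle: the path diameter `2 * radius`.
#'
#' @param schedule A `scramble_schedule`.
#' @param cycle 0-based cycle index (selects the path geometry).
#' @return Numeric vector, one entry per location.
#' @export
schedule_normalizer <- function(schedule, cycle = 0) {
  stopifnot(inherits(schedule, "scramble_schedule"))
  schedule$diameters[, cycle %% schedule$n_paths + 1L]
}

#' RIS time course of a SWIFT movie
#'
#' Computes the RIS of every requested frame against the movie's reference
#' pyramid, in the coefficient domain (no frame reconstruction needed). The
#' curve attains 100 exactly at the semantic onsets; with several harmonics
#' it is U-shaped between onsets with small intermediate peaks at partial
#' phase alignments.
#'
#' @param movie A `swift_movie`.
#' @param frames 0-based frame indices (default all).
#' @return Data frame with columns `frame`, `ris`.
#' @export
ris_curve <- function(movie, frames = NULL) {
  stopifnot(inherits(movie, "swift_movie"))
  if (is.null(frames)) frames <- seq(0, movie$n_frames - 1)
  sch <- movie$schedule
  anchors <- sch$anchors
  vals <- vapply(frames, function(t) {
    d <- .row_norms(schedule_coefficients(sch, t) - anchors)
    nz <- schedule_normalizer(sch, t %/% sch$frames_per_cycle)
    dW <- ifelse(nz > 0, pmin(1, d / nz), 0)
    100 * mean(1 - dW)
  }, numeric(1))
  data.frame(frame = frames, ris = vals)
}

#' Export a SWIFT movie as a PNG frame archive
#'
#' Writes `frame_000000.png`, ... plus a JSON sidecar recording the cycle
#' structure, onsets and seed. Frames can be read back losslessly to 16-bit
#' precision with [read_gray_image()].
#'
#' @param movie A `swift_movie`.
#' @param dir Output directory (created if needed).
#' @param frames 0-based frame indices to write (default all).
#' @return `dir`, invisibly.
#' @export
export_movie <- function(movie, dir, frames = NULL) {
  stopifnot(inherits(movie, "swift_movie"))
  if (is.null(frames)) frames <- seq(0, movie$n_frames - 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in frames)
    write_gray_image(movie_frame(movie, t),
                     file.path(dir, sprintf("frame_%06d.png", t)))
  sidecar <- list(
    n_frames = movie$n_frames, frames_per_cycle = movie$frames_per_cycle,
    n_cycles = movie$n_cycles,
    semantic_onset_frames = movie$semantic_onset_frames,
    seed = movie$schedule$seed, side = movie$pyramid$side,
    levels = movie$pyramid$levels, family = movie$pyramid$family,
    written_frames = frames
  )
  jsonlite::write_json(sidecar, file.path(dir, "movie.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export an RIS curve as CSV
#'
#' @param curve Data frame from [ris_curve()].
#' @param path Output CSV path (columns `frame`, `ris`).
#' @return `path`, invisibly.
#' @export
export_ris_csv <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
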