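# Composite SWIFT runs: alpha blending of independently tagged streams,
# segment concatenation with phase continuity, onset-phase randomization.

#' Specify one SWIFT stream of a composite run
#'
#' A stream is a category's sequence of exemplar images, scrambled with a
#' common schedule seed and revealed at a fixed tagging frequency. Exemplars
#' are switched at segment boundaries (one per segment, recycled) without
#' resetting the scrambling phase, so semantic onsets stay strictly periodic
#' across the whole run.
#'
#' @param images A square grayscale matrix or list of them (exemplars).
#' @param tagging_frequency Semantic revelation rate in Hz (> 0).
#' @param alpha Blend weight in (0, 1].
#' @param levels Wavelet decomposition levels for the scrambler.
#' @param n_harmonics,n_paths See [make_schedule()].
#' @param name Optional stream label (e.g. `"faces"`).
#' @return Object of class `stream_spec`.
#' @export
stream_spec <- function(images, tagging_frequency, alpha = 1, levels = 9,
                        n_harmonics = 8, n_paths = 3, name = NULL) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1, all(vapply(images, is.matrix, logical(1))))
  if (tagging_frequency <= 0) stop("tagging_frequency must be > 0")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  structure(list(images = images, tagging_frequency = tagging_frequency,
                 alpha = alpha, levels = levels, n_harmonics = n_harmonics,
                 n_paths = n_paths, name = name),
            class = "stream_spec")
}

#' Alpha-blend frame sequences
#'
#' Pixelwise weighted sum of equally sized frame sequences; linear and
#' order-independent.
#'
#' @param frame_sets List of frame sequences (each a list of matrices), or a
#'   list of single matrices.
#' @param alphas Positive weights, one per set.
#' @return List of blended frames (or a single matrix if matrices were
#'   given).
#' @export
blend <- function(frame_sets, alphas) {
  single <- all(vapply(frame_sets, is.matrix, logical(1)))
  if (single) frame_sets <- lapply(frame_sets, list)
  if (length(frame_sets) != length(alphas))
    stop("need one alpha per frame set")
  if (any(alphas <= 0)) stop("alphas must be positive")
  nf <- unique(vapply(frame_sets, length, integer(1)))
  if (length(nf) != 1) stop("frame sets have unequal lengths")
  dims <- lapply(frame_sets, function(s) dim(s[[1]]))
  if (length(unique(dims)) != 1) stop("frame sets have unequal frame sizes")
  out <- lapply(seq_len(nf), function(i)
    Reduce(`+`, Map(function(s, a) a * s[[i]], frame_sets, alphas)))
  if (single) out[[1]] else out
}

# smallest fps <= 240 giving integer frames-per-cycle for all frequencies
.suggest_fps <- function(freqs) {
  for (fps in 1:240)
    if (all(abs(fps / freqs - round(fps / freqs)) < 1e-9)) return(fps)
  NA_integer_
}

#' Schedule a composite SWIFT run
#'
#' Lays out a multi-stream run: each stream gets an integer frames-per-cycle
#' (`fps / tagging_frequency`), a random initial cycle phase drawn uniformly
#' from frames 30-100 (out of 200, rescaled proportionally for other cycle
#' lengths) so no semantic onset occurs near the run start, and exemplar
#' switches at segment boundaries that preserve cycle phase. Exemplar changes
#' therefore recur at the low frequency `1/segment_duration`, far below and
#' not harmonically related to the tagging frequencies.
#'
#' Frames are rendered lazily with [composite_frame()]; this function only
#' computes the run's timing structure.
#'
#' @param streams List of [stream_spec()] objects with total alpha <= 1.
#' @param run_duration Run length in seconds (multiple of
#'   `segment_duration`).
#' @param segment_duration Segment length in seconds (default 180).
#' @param fps Common display rate; every stream's `fps / frequency` must be
#'   an integer (default 12, which accommodates 0.06/0.08/0.10 Hz).
#' @param seed Integer seed for phase randomization and stream schedules.
#' @param start_frames Optional integer vector overriding the random initial
#'   phases (validated against the per-stream 30-100/200 range).
#' @return Object of class `composite_run`.
#' @export
schedule_run <- function(streams, run_duration, segment_duration = 180,
                         fps = 12, seed = 1, start_frames = NULL) {
  if (inherits(streams, "stream_spec")) streams <- list(streams)
  stopifnot(length(streams) >= 1,
            all(vapply(streams, inherits, logical(1), "stream_spec")))
  alphas <- vapply(streams, `[[`, numeric(1), "alpha")
  if (sum(alphas) > 1 + 1e-9)
    stop("stream alphas sum to ", sum(alphas), " > 1")
  if (abs(run_duration %% segment_duration) > 1e-9)
    stop("run_duration must be a multiple of segment_duration")
  freqs <- vapply(streams, `[[`, numeric(1), "tagging_frequency")
  fpcs <- fps / freqs
  if (any(abs(fpcs - round(fpcs)) > 1e-9))
    stop("non-integer frames-per-cycle at fps = ", fps,
         " for frequencies ", paste(freqs[abs(fpcs - round(fpcs)) > 1e-9],
                                    collapse = ", "),
         "; suggested fps: ", .suggest_fps(freqs))
  fpcs <- as.integer(round(fpcs))
  n_frames <- as.integer(round(run_duration * fps))
  n_segments <- as.integer(round(run_duration / segment_duration))

  # phase randomization: frames 30..100 out of 200, rescaled per cycle length
  ranges <- lapply(fpcs, function(fpc)
    seq.int(max(1L, as.integer(round(30 * fpc / 200))),
            as.integer(round(100 * fpc / 200))))
  if (is.null(start_frames)) {
    start_frames <- .with_seed(seed, vapply(ranges, function(r)
      r[sample.int(length(r), 1)], integer(1)))
  } else {
    start_frames <- as.integer(start_frames)
    ok <- mapply(function(s, r) s %in% r, start_frames, ranges)
    if (!all(ok))
      stop("start_frames outside the allowed randomization range ",
           "(30-100 out of 200, rescaled): ",
           paste(start_frames[!ok], collapse = ", "))
  }

  onsets <- lapply(seq_along(streams), function(i) {
    f <- seq.int(0L, n_frames - 1L)
    f[(start_frames[i] + f) %% fpcs[i] == 0L] / fps
  })
  names(onsets) <- vapply(seq_along(streams), function(i)
    if (is.null(streams[[i]]$name)) paste0("stream", i) else
      streams[[i]]$name, character(1))

  structure(
    list(streams = streams, fps = fps, n_frames = n_frames,
         duration = run_duration, segment_duration = segment_duration,
         n_segments = n_segments, frames_per_cycle = fpcs,
         start_frames = start_frames, semantic_onsets = onsets,
         segment_boundaries = seq(0, run_duration, by = segment_duration),
         exemplar_recurrence_hz = 1 / segment_duration,
         seed = seed, schedules = new.env(parent = emptyenv())),
    class = "composite_run"
  )
}

#' @export
print.composite_run <- function(x, ...) {
  cat("composite_run:", length(x$streams), "streams,", x$duration, "s at",
      x$fps, "fps (", x$n_frames, "frames ),", x$n_segments, "segments\n")
  for (i in seq_along(x$streams))
    cat(sprintf("  %s: %.3g Hz, alpha %.3g, start frame %d, %d onsets\n",
                names(x$semantic_onsets)[i],
                x$streams[[i]]$tagging_frequency, x$streams[[i]]$alpha,
                x$start_frames[i], length(x$semantic_onsets[[i]])))
  invisible(x)
}

# Cached (pyramid, schedule) per stream x exemplar. The same schedule seed is
# reused across a stream's exemplars so segment switches keep the phase and
# geometry of the scrambling cycle.
.stream_machinery <- function(run, i, exemplar) {
  key <- paste0("s", i, "e", exemplar)
  env <- run$schedules
  if (!is.null(env[[key]])) return(env[[key]])
  st <- run$streams[[i]]
  img <- st$images[[(exemplar - 1L) %% length(st$images) + 1L]]
  pyr <- decompose(img, st$levels)
  sch <- make_schedule(pyr, n_harmonics = st$n_harmonics,
                       frames_per_cycle = run$frames_per_cycle[i],
                       n_paths = st$n_paths, seed = run$seed + 1000L * i)
  env[[key]] <- list(pyramid = pyr, schedule = sch)
  env[[key]]
}

#' Render one frame of a composite run
#'
#' Each stream is rendered at its own cycle phase (`start_frame + f`, carried
#' continuously across segment boundaries) from the exemplar of the current
#' segment, then the streams are alpha blended.
#'
#' @param run A `composite_run`.
#' @param f 0-based frame index.
#' @return Square image matrix.
#' @export
composite_frame <- function(run, f) {
  stopifnot(inherits(run, "composite_run"), f >= 0, f < run$n_frames)
  seg <- as.integer(f %/% (run$segment_duration * run$fps)) + 1L
  frames <- lapply(seq_along(run$streams), function(i) {
    m <- .stream_machinery(run, i, seg)
    render_frame(m$pyramid, m$schedule, run$start_frames[i] + f)
  })
  alphas <- vapply(run$streams, `[[`, numeric(1), "alpha")
  blend(frames, alphas)
}

#' Export a composite run
#'
#' Writes the requested frames plus a JSON sidecar with per-stream onset
#' times, tagging frequencies, alphas, fps and the seed. `format = "png"`
#' writes 8-bit viewable frames; `format = "rds"` writes a lossless frame
#' archive whose round trip is bit-identical.
#'
#' @param run A `composite_run`.
#' @param dir Output directory.
#' @param frames 0-based frame indices (default all; consider a subset for
#'   long runs).
#' @param format `"png"` or `"rds"`.
#' @return `dir`, invisibly.
#' @export
export_run <- function(run, dir, frames = NULL, format = c("png", "rds")) {
  stopifnot(inherits(run, "composite_run"))
  format <- match.arg(format)
  if (run$n_frames < 1) stop("empty run")
  if (is.null(frames)) frames <- seq.int(0L, run$n_frames - 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in frames) {
    img <- composite_frame(run, f)
    if (format == "png")
      write_gray_image(img, file.path(dir, sprintf("frame_%06d.png", f)))
    else
      saveRDS(img, file.path(dir, sprintf("frame_%06d.rds", f)))
  }
  sidecar <- list(
    fps = run$fps, duration = run$duration, n_frames = run$n_frames,
    segment_duration = run$segment_duration,
    segment_boundaries = run$segment_boundaries,
    exemplar_recurrence_hz = run$exemplar_recurrence_hz,
    seed = run$seed, written_frames = frames, format = format,
    streams = lapply(seq_along(run$streams), function(i) list(
      name = names(run$semantic_onsets)[i],
      tagging_frequency = run$streams[[i]]$tagging_frequency,
      alpha = run$streams[[i]]$alpha,
      start_frame = run$start_frames[i],
      frames_per_cycle = run$frames_per_cycle[i],
      semantic_onsets = run$semantic_onsets[[i]]))
  )
  jsonlite::write_json(sidecar, file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
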