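test_that("isoenergetic paths stay on the anchor's sphere and anchor at 0", {
  th <- seq(0, 2 * pi, length.out = 360)
  for (seed in 1:5) {
    anchor <- rnorm(3)
    p <- build_isoenergetic_path(anchor, seed = seed)
    pts <- path_points(p, th)
    r <- sqrt(rowSums(pts^2))
    expect_lt(rel_dev(r, rep(sqrt(sum(anchor^2)), length(r))), 1e-9)
  }
  p <- build_isoenergetic_path(c(1, 0, 0), seed = 1)
  expect_identical(as.numeric(path_points(p, 0)), c(1, 0, 0))
  expect_lt(max(abs(path_points(p, 2 * pi) - path_points(p, 0))), 1e-12)
})

test_that("a zero anchor degenerates to the constant path at the origin", {
  p <- build_isoenergetic_path(c(0, 0, 0), seed = 3)
  expect_equal(p$radius, 0)
  expect_true(all(path_points(p, seq(0, 6, by = 0.5)) == 0))
})

test_that("schedules align all coefficients at cycle boundaries only", {
  x <- rand_image(64, 9)
  pyr <- decompose(x, 3)
  sch <- make_schedule(pyr, n_harmonics = 8, frames_per_cycle = 200,
                       seed = 5)
  expect_true(all(sch$harmonic %in% 1:8))
  # anchors reproduced exactly at multiples of frames_per_cycle
  for (t in c(0, 200, 400))
    expect_equal(unname(schedule_coefficients(sch, t)),
                 unname(sch$anchors))
  # single harmonic: mid-cycle is the antipodal point on every path
  s1 <- make_schedule(pyr, n_harmonics = 1, frames_per_cycle = 200,
                      seed = 5)
  co <- schedule_coefficients(s1, 100)
  d <- sqrt(rowSums((co - s1$anchors)^2))
  expect_lt(max(abs(d - s1$diameters[, 1])), 1e-9)
})

test_that("different seeds give different harmonic assignments", {
  pyr <- decompose(rand_image(64, 1), 3)   # 1344 coefficients
  s7 <- make_schedule(pyr, seed = 7)
  s8 <- make_schedule(pyr, seed = 8)
  expect_gt(sum(s7$harmonic != s8$harmonic), 0)
  # same seed reproduces the schedule exactly
  s7b <- make_schedule(pyr, seed = 7)
  expect_identical(s7$harmonic, s7b$harmonic)
  expect_identical(s7$geoms, s7b$geoms)
})

test_that("schedule parameter validation", {
  pyr <- decompose(rand_image(16, 1), 2)
  expect_error(make_schedule(pyr, n_harmonics = 0), "n_harmonics")
  expect_error(make_schedule(pyr, frames_per_cycle = 1),
               "frames_per_cycle")
})

test_that("rendered frames conserve norms, energy and the luminance band", {
  x <- rand_image(64, 9)
  pyr <- decompose(x, 3)
  sch <- make_schedule(pyr, seed = 5)
  an <- sqrt(rowSums(sch$anchors^2))
  e0 <- detail_energy(pyr)
  for (t in c(0, 37, 100, 150, 199, 261)) {
    pf <- render_frame(pyr, sch, t, as_image = FALSE)
    # per-coefficient norm conservation
    nn <- orientation_vectors(pf)$norm
    expect_lt(rel_dev(nn, an), 1e-9)
    # global detail energy flat
    expect_lt(abs(detail_energy(pf) - e0) / e0, 1e-6)
    # approximation band untouched
    expect_identical(pf$approx, pyr$approx)
  }
  # t = 0 reproduces the original image; one full cycle later is identical
  expect_lt(max(abs(render_frame(pyr, sch, 0) - x)), 1e-6)
  expect_equal(render_frame(pyr, sch, 200), render_frame(pyr, sch, 0))
  # size mismatch between schedule and pyramid is caught
  expect_error(render_frame(decompose(rand_image(32, 1), 3), sch, 0),
               "mismatch")
})

test_that("movies are deterministic and onset frames reveal the original", {
  x <- rand_image(64, 2)
  m1 <- generate_movie(x, levels = 3, n_cycles = 2, seed = 10,
                       keep_frames = TRUE)
  m2 <- generate_movie(x, levels = 3, n_cycles = 2, seed = 10,
                       keep_frames = TRUE)
  expect_identical(m1$frames, m2$frames)
  expect_equal(m1$semantic_onset_frames, c(0L, 200L))
  for (f in m1$semantic_onset_frames)
    expect_lt(max(abs(movie_frame(m1, f) - x)), 1e-6)
})

test_that("RIS boundary values and direct-sum arithmetic", {
  pyr <- decompose(rand_image(64, 3), 3)
  sch <- make_schedule(pyr, seed = 2)
  nz <- schedule_normalizer(sch, 0)
  # identity
  expect_identical(ris(pyr, pyr, nz), 100)
  # every location at maximal deviation: the antipodal point on its path
  g <- sch$geoms[[1]]
  anti <- .set_detail_matrix(pyr, g$center - g$u)
  expect_lt(abs(ris(pyr, anti, nz) - 0), 1e-9)
  # half at anchor, half at maximal deviation
  m <- .detail_matrix(pyr)
  half <- seq_len(nrow(m) / 2)
  mixed <- m
  mixed[half, ] <- (g$center - g$u)[half, ]
  expect_lt(abs(ris(pyr, .set_detail_matrix(pyr, mixed), nz) - 50), 1e-9)
  # shape mismatch
  expect_error(ris(pyr, decompose(rand_image(32, 1), 3), nz), "mismatch")
})

test_that("RIS curve peaks at 100 only at onsets, U-shaped in between", {
  mv <- small_movie(seed = 4)
  rc <- ris_curve(mv)
  on <- rc$frame %in% mv$semantic_onset_frames
  expect_true(all(abs(rc$ris[on] - 100) < 1e-9))
  expect_true(all(rc$ris >= 0 & rc$ris <= 100))
  # strictly below 100 away from onsets, with intermediate local maxima
  mid <- rc$ris[rc$frame %in% 20:180]
  expect_lt(max(mid), 95)
  interior <- mid[2:(length(mid) - 1)]
  n_locmax <- sum(interior > mid[1:(length(mid) - 2)] &
                    interior > mid[3:length(mid)])
  expect_gt(n_locmax, 2)
})

test_that("single-harmonic RIS is symmetric about mid-cycle", {
  mv <- generate_movie(rand_image(64, 2), levels = 3, n_harmonics = 1,
                       frames_per_cycle = 200, n_cycles = 1, seed = 6)
  r <- ris_curve(mv)$ris
  expect_lt(max(abs(r[2:200] - rev(r[2:200]))), 1e-6)
})

test_that("movie export writes frames and a faithful sidecar", {
  mv <- generate_movie(rand_image(32, 5), levels = 2, n_cycles = 1,
                       frames_per_cycle = 10, seed = 3)
  d <- tempfile()
  export_movie(mv, d)
  expect_length(list.files(d, pattern = "frame_.*png"), 10)
  side <- jsonlite::read_json(file.path(d, "movie.json"),
                              simplifyVector = TRUE)
  expect_equal(side$semantic_onset_frames, 0)
  expect_equal(side$frames_per_cycle, 10)
  f <- tempfile(fileext = ".csv")
  export_ris_csv(ris_curve(mv), f)
  expect_equal(nrow(read.csv(f)), 10)
})
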