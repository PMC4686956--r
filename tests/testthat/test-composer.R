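test_that("blend is the pixelwise weighted sum", {
  a <- rand_image(16, 1)
  b <- rand_image(16, 2)
  cc <- rand_image(16, 3)
  expect_identical(blend(list(a), 1), a)
  expect_lt(max(abs(blend(list(a, a), c(0.5, 0.5)) - a)), 1e-12)
  tri <- blend(list(a, b, cc), rep(1 / 3, 3))
  expect_lt(max(abs(tri - (a + b + cc) / 3)), 1e-12)
  # order independence
  expect_lt(max(abs(blend(list(b, a), c(0.3, 0.7)) -
                      blend(list(a, b), c(0.7, 0.3)))), 1e-12)
  expect_error(blend(list(a, rand_image(8, 1)), c(0.5, 0.5)), "sizes")
  expect_error(blend(list(list(a, a), list(b)), c(0.5, 0.5)), "lengths")
})

test_that("run scheduling yields periodic onsets with the correct gaps", {
  img <- rand_image(32, 1)
  st <- stream_spec(img, tagging_frequency = 0.1, alpha = 1, levels = 3)
  run <- schedule_run(list(st), run_duration = 180,
                      segment_duration = 180, fps = 12, seed = 1)
  on <- run$semantic_onsets[[1]]
  expect_length(on, 18)
  expect_true(all(abs(diff(on) - 10) < 1e-9))
  # no onset in the first 1.5 s (phase randomization range)
  expect_gt(min(on), 1.5)
  # start frame within the rescaled 30..100 range (fpc = 120)
  expect_true(run$start_frames[1] %in% 18:60)
})

test_that("segment concatenation recurs at 1/segment_duration", {
  img <- rand_image(32, 1)
  streams <- list(
    stream_spec(list(img, rand_image(32, 2), rand_image(32, 3)), 0.1,
                alpha = 0.5, levels = 3, name = "faces"),
    stream_spec(img, 0.06, alpha = 0.5, levels = 3, name = "scenes"))
  run <- schedule_run(streams, run_duration = 540,
                      segment_duration = 180, fps = 12, seed = 2)
  expect_equal(run$exemplar_recurrence_hz, 1 / 180)
  expect_equal(run$segment_boundaries, c(0, 180, 360, 540))
  expect_equal(run$n_segments, 3)
  # onsets remain strictly periodic across segment boundaries
  for (i in 1:2) {
    on <- run$semantic_onsets[[i]]
    expect_lt(max(abs(diff(on) -
                        1 / streams[[i]]$tagging_frequency)), 1e-9)
  }
})

test_that("scheduling rejects invalid phase, fps and alpha settings", {
  img <- rand_image(32, 1)
  st <- stream_spec(img, 0.1, alpha = 1, levels = 3)
  expect_error(schedule_run(list(st), 180, 180, fps = 12,
                            start_frames = 0), "range")
  slow <- stream_spec(img, 0.06, alpha = 1, levels = 3)
  expect_error(schedule_run(list(slow), 180, 180, fps = 7),
               "suggested fps")
  two <- list(stream_spec(img, 0.1, alpha = 0.7, levels = 3),
              stream_spec(img, 0.06, alpha = 0.7, levels = 3))
  expect_error(schedule_run(two, 180, 180), "alphas sum")
  expect_error(schedule_run(list(st), 170, 180), "multiple")
  expect_error(stream_spec(img, -0.1), "tagging_frequency")
  expect_error(stream_spec(img, 0.1, alpha = 0), "alpha")
})

test_that("composite detail energy decomposes into conserved stream terms", {
  s1 <- stream_spec(rand_image(64, 5), 0.1, alpha = 0.5, levels = 3)
  s2 <- stream_spec(rand_image(64, 6), 0.06, alpha = 0.5, levels = 3)
  run <- schedule_run(list(s1, s2), run_duration = 30,
                      segment_duration = 30, fps = 12, seed = 3)
  m1 <- swiftag:::.stream_machinery(run, 1, 1)
  m2 <- swiftag:::.stream_machinery(run, 2, 1)
  e1 <- detail_energy(m1$pyramid)
  e2 <- detail_energy(m2$pyramid)
  energies <- vapply(seq(0, 300, by = 30), function(f) {
    c1 <- schedule_coefficients(m1$schedule, run$start_frames[1] + f)
    c2 <- schedule_coefficients(m2$schedule, run$start_frames[2] + f)
    # each stream's own detail energy is conserved exactly ...
    expect_lt(abs(sum(c1^2) - e1) / e1, 1e-9)
    expect_lt(abs(sum(c2^2) - e2) / e2, 1e-9)
    eb <- detail_energy(decompose(composite_frame(run, f), 3))
    # ... and the blend's energy is the exact quadratic form, so the only
    # frame-to-frame variation is the bounded stream cross-correlation
    expect_lt(abs(eb - (0.25 * e1 + 0.25 * e2 + 0.5 * sum(c1 * c2))) /
                eb, 1e-9)
    eb
  }, numeric(1))
  cross_bound <- 2 * 0.25 * sqrt(e1 * e2)
  expect_lt(diff(range(energies)), 2 * cross_bound)
})

test_that("run export round-trips frames and records the schedule", {
  st <- stream_spec(rand_image(32, 7), 0.1, alpha = 1, levels = 3)
  run <- schedule_run(list(st), 10, 10, fps = 1, seed = 4)
  d <- tempfile()
  export_run(run, d, frames = 0:9, format = "rds")
  side <- jsonlite::read_json(file.path(d, "run.json"),
                              simplifyVector = TRUE)
  expect_equal(side$fps, 1)
  expect_equal(side$streams$tagging_frequency, 0.1)
  expect_equal(unlist(side$streams$semantic_onsets),
               run$semantic_onsets[[1]])
  back <- readRDS(file.path(d, "frame_000003.rds"))
  expect_identical(back, composite_frame(run, 3))
})
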