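make_trace <- function(t, x = -0.7, y = 0.1, z = 0.3, valid = 1L) {
  position_trace(data.frame(t = t, x = x, y = y, z = z, valid = valid))
}

test_that("traces load, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,z,valid", "0,1,2,3,1", "0.2,1.1,2,3,1", "0.4,1.2,2,3,0"), f)
  tr <- read_trace(f)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$valid, c(1L, 1L, 0L))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f2)
  expect_equal(read_trace(f2), tr)

  fdup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,z", "0,1,2,3", "0,1,2,3"), fdup)
  expect_error(read_trace(fdup), "row 2")
  fe <- withr::local_tempfile(fileext = ".csv")
  writeLines("t,x,y,z", fe)
  expect_error(read_trace(fe), "empty")
})

test_that("event positions are held from the last sample at event start", {
  tr <- make_trace(t = c(0, 1, 2, 3), x = c(-0.7, -0.8, -0.9, -1.0))
  ev <- fix_event(t_start = 2)
  expect_equal(position_at_event_start(tr, ev), c(-0.9, 0.1, 0.3))
  # between samples: hold-last-value, not interpolation
  ev2 <- fix_event(t_start = 2.9)
  expect_equal(position_at_event_start(tr, ev2), c(-0.9, 0.1, 0.3))
  # clock offset shifts the matching
  expect_equal(position_at_event_start(tr, ev2, clock_offset = 0.2),
               c(-1.0, 0.1, 0.3))
  # stale or missing samples give position-unknown
  expect_true(all(is.na(position_at(tr, 20, max_gap = 5))))
  expect_true(all(is.na(position_at(tr, -1))))
  tr_inv <- make_trace(t = 0:3, valid = 0L)
  expect_true(all(is.na(position_at_event_start(tr_inv, ev))))
})

test_that("position lookup is invariant to resampling that keeps held samples", {
  tr_fine <- make_trace(t = seq(0, 10, 0.5), x = -0.7 - seq(0, 10, 0.5) / 20)
  keep <- seq(1, 21, by = 2)  # coarser trace containing the held samples
  tr_coarse <- position_trace(as.data.frame(tr_fine)[keep, ])
  ev <- fix_event(t_start = 6)  # start coincides with a kept sample
  expect_equal(position_at_event_start(tr_fine, ev),
               position_at_event_start(tr_coarse, ev))
})

test_that("event subdivision conserves output and follows the trace", {
  ev <- fix_event(t_start = 0, duration = 7, p_ka = 1.4, k_air_ref = 5.6,
                  event_type = "acquisition")
  tr <- make_trace(t = seq(-1, 8, 0.2), x = -0.7 - pmax(seq(-1, 8, 0.2), 0) / 10)
  sub <- subdivide_event(ev, tr, 7)
  expect_equal(nrow(sub$events), 7L)
  expect_equal(sum(sub$events$p_ka), ev$p_ka, tolerance = 1e-12)
  expect_equal(sum(sub$events$k_air_ref), ev$k_air_ref, tolerance = 1e-12)
  expect_equal(sum(sub$events$duration), ev$duration, tolerance = 1e-12)
  # positions recede monotonically with the scripted trace
  expect_true(all(diff(sub$positions[, 1]) < 0))
  # degenerate split is the static treatment
  one <- subdivide_event(ev, tr, 1)
  expect_equal(one$events$event_id, "e1")
  expect_equal(one$positions[1, ], position_at_event_start(tr, ev))
  # more frames than trace samples falls back with a warning
  tr3 <- make_trace(t = c(0, 3, 6))
  expect_warning(s3 <- subdivide_event(ev, tr3, 25), "fewer trace samples")
  expect_lte(nrow(s3$events), 3L)
  expect_equal(sum(s3$events$p_ka), ev$p_ka, tolerance = 1e-12)
})

test_that("movement fixtures recede monotonically", {
  mv <- generate_movement_event(0.7, 1.5, duration = 7, n_frames = 7)
  expect_equal(nrow(mv$trace), 7L)
  d <- sqrt(mv$trace$x^2)
  expect_true(all(diff(d) > 0))
  expect_equal(range(d), c(0.7, 1.5), tolerance = 1e-12)
  st <- generate_movement_event(0.9, 0.9, n_frames = 5)
  expect_true(all(st$trace$x == -0.9))
})
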