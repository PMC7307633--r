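test_that("the baseline window is the minimum-SD window (exhaustive oracle)", {
  set.seed(101)
  for (rep in 1:5) {
    trace <- 100 + cumsum(rnorm(80, sd = 2))
    trace <- abs(trace) + 10
    d <- delta_f_over_f(trace, window = 6)
    sds <- vapply(seq_len(length(trace) - 5L),
                  function(i) sd(trace[i:(i + 5L)]), 0)
    k <- which.min(sds)
    expect_equal(d$window_start, k)
    expect_equal(d$f0, mean(trace[k:(k + 5L)]), tolerance = 1e-12)
    expect_equal(d$baseline_sd, sds[k] / d$f0, tolerance = 1e-9)
    expect_equal(d$dff, (trace - d$f0) / d$f0, tolerance = 1e-12)
  }
})

test_that("dF/F handles documented plateau and degenerate cases", {
  r <- delta_f_over_f(c(50, 50, 50, 50, 50, 50, 100, 100))
  expect_equal(r$dff[7], 1)
  expect_equal(r$f0, 50)
  expect_equal(r$window_start, 1L)     # earliest window on SD ties

  r2 <- delta_f_over_f(rep(80, 20))
  expect_equal(r2$dff, rep(0, 20))
  expect_equal(r2$baseline_sd, 0)

  expect_error(delta_f_over_f(1:5), "at least 6")
  expect_error(delta_f_over_f(rep(0, 10)), "F0 <= 0")
})

test_that("dF/F is invariant to multiplicative gain", {
  set.seed(7)
  trace <- 100 + rnorm(50)
  a <- delta_f_over_f(trace)
  b <- delta_f_over_f(3.7 * trace)
  expect_equal(b$dff, a$dff, tolerance = 1e-9)
  # the running-moment variance cancels catastrophically, so gain
  # invariance holds only to ~1e-11 relative
  expect_equal(b$baseline_sd, a$baseline_sd, tolerance = 1e-9)
})

test_that("event detection applies width, threshold and edge rules", {
  sd0 <- 0.1
  dff <- rep(0, 40)
  dff[10:12] <- 1          # 3-frame event
  dff[20] <- 1             # 1-frame excursion: too short
  dff[30:31] <- 0.2        # below 2.5 * sd0 = 0.25
  ev <- detect_events(dff, sd0)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset, 10L)
  expect_equal(ev$offset, 12L)
  expect_equal(ev$width, 3L)
  expect_equal(ev$peak_dff, 1)

  # runs touching either edge are excluded
  dff2 <- rep(0, 20); dff2[1:3] <- 1; dff2[18:20] <- 1
  expect_equal(nrow(detect_events(dff2, sd0)), 0L)

  # exactly at threshold does not cross (strict >)
  expect_equal(nrow(detect_events(c(0, 0.25, 0.25, 0), sd0)), 0L)

  expect_warning(detect_events(c(0, 1, 1, 0), 0), "baseline_sd is 0")
  expect_error(detect_events(dff, -1), "baseline_sd")
})

test_that("event curation filters work and default to off", {
  ev <- data.frame(onset = c(1, 5, 8, 30), offset = c(2, 6, 9, 31),
                   width = c(2L, 2L, 2L, 2L), peak_dff = c(0.5, 2, 1, 3))
  expect_equal(filter_events(ev), ev)
  expect_equal(nrow(filter_events(ev, min_peak_dff = 1.5)), 2L)
  out <- filter_events(ev, min_iei_frames = 10)
  expect_equal(out$onset, c(1, 30))
})

test_that("ROI size filtering keeps >= 70 px and unknown sizes", {
  rois <- roi_trace_set(matrix(100, 10, 3), 10,
                        pixel_count = c(69L, 70L, NA))
  out <- filter_rois(rois)
  expect_equal(out$roi_id, c(2L, 3L))
  expect_equal(ncol(out$traces), 2L)
})

test_that("neuropil correction is seeded, local and self-cancelling", {
  ny <- 40; nx <- 40; nt <- 30
  labels <- matrix(0L, ny, nx)
  labels[18:22, 18:22] <- 1L
  common <- 100 + 5 * sin(seq_len(nt) / 3)
  movie <- array(rep(common, each = ny * nx), c(ny, nx, nt))

  a <- neuropil_correct(movie, labels, 1L, radius_px = 10, seed = 1)
  b <- neuropil_correct(movie, labels, 1L, radius_px = 10, seed = 1)
  expect_identical(a$pixels, b$pixels)
  # identical ROI and neuropil dynamics cancel exactly
  expect_equal(a$corrected, rep(0, nt), tolerance = 1e-12)
  # all selected pixels are non-cell and within the radius
  expect_true(all(labels[a$pixels] == 0L))
  rows <- (a$pixels - 1L) %% ny + 1L
  cols <- (a$pixels - 1L) %/% ny + 1L
  expect_true(all((rows - 20)^2 + (cols - 20)^2 <= 10^2))

  expect_error(neuropil_correct(movie, labels, 5L), "no pixels with label")
  labels2 <- matrix(1L, ny, nx)
  expect_error(neuropil_correct(movie, labels2, 1L, radius_px = 5),
               "no eligible neuropil")
})

test_that("global event rate counts events per minute with 5-min inclusion", {
  rate <- 10
  trace <- rep(100, 5 * 60 * rate)
  onsets <- seq(100, by = 290, length.out = 10)
  for (o in onsets) trace[o:(o + 3)] <- 110
  # noise floor so the MAD scale is positive
  set.seed(2)
  trace <- trace + rnorm(length(trace), sd = 0.5)
  r <- global_event_rate(trace = trace, sampling_rate = rate)
  expect_equal(r$status, "ok")
  expect_equal(r$rate_per_min, 2)

  short <- global_event_rate(trace = trace[1:(4 * 60 * rate)],
                             sampling_rate = rate)
  expect_match(short$status, "excluded: < 5 min")
  expect_true(is.na(short$rate_per_min))
  ok <- global_event_rate(trace = trace[1:(4 * 60 * rate)],
                          sampling_rate = rate, allow_short = TRUE)
  expect_equal(ok$status, "ok")
})

test_that("coactive fractions use the detected-ROI denominator, self excluded", {
  n <- 50
  rois <- data.frame(roi_id = 1:n, depth_norm = seq(0, 1, length.out = n))
  # ROI 1 event overlaps events of ROIs 2-5 only
  events <- rbind(
    data.frame(roi_id = 1L, onset = 10L, offset = 12L),
    data.frame(roi_id = 2:5, onset = 12L, offset = 14L),
    data.frame(roi_id = 6:n, onset = 100L + 10L * (6:n),
               offset = 101L + 10L * (6:n)))
  co <- coactivity(events, rois)
  r1 <- co$records[co$records$roi_id == 1L, ]
  expect_equal(r1$mean_coactive_fraction, 4 / 49)
  expect_equal(r1$mean_coactive_fraction_incl, 5 / 50)
  expect_equal(co$n_detected_rois, 50L)

  # full synchrony: every ROI coactive with every other
  sync <- data.frame(roi_id = 1:n, onset = 5L, offset = 7L)
  co2 <- coactivity(sync, rois)
  expect_true(all(co2$records$mean_coactive_fraction == 1))
  expect_true(all(co2$records$mean_coactive_fraction_incl == 1))

  # depth thirds partition at 1/3 and 2/3
  expect_equal(as.character(co$records$third[co$records$depth_norm == 0]),
               "superficial")
  expect_true(all(table(co$records$third) > 0))
  expect_error(coactivity(events[0, ], rois), "no active ROI")
})

test_that("coactivity overlap is symmetric between ROI pairs", {
  rois <- data.frame(roi_id = 1:2, depth_norm = c(0.2, 0.8))
  ev <- data.frame(roi_id = c(1L, 2L), onset = c(10L, 12L),
                   offset = c(12L, 20L))
  co <- coactivity(ev, rois)
  expect_equal(co$records$mean_coactive_fraction, c(1, 1))
})

test_that("ROI trace CSVs round-trip", {
  fov <- gen_ca_fov(ca_fov_spec(n_cells = 4, frames = 120), seed = 3)
  dir <- withr::local_tempdir()
  write_ca_fov(fov, dir)
  rois <- read_roi_traces_csv(file.path(dir, "traces.csv"), 10)
  expect_equal(dim(rois$traces), dim(fov$rois$traces))
  expect_equal(rois$traces, fov$rois$traces, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rois$depth_norm, fov$rois$depth_norm, tolerance = 1e-9)
})
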