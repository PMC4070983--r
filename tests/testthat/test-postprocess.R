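test_that("fiducial drift correction recovers an injected linear drift", {
  cam <- camera_model(background = 5)
  n_frames <- 200
  drift <- tibble::tibble(dx_nm = 1.0 * (seq_len(n_frames) - 1),
                          dy_nm = -0.6 * (seq_len(n_frames) - 1))
  em <- tibble::tibble(emitter_id = 1L, x_nm = 1000, y_nm = 3000)
  # the emitter is on for 60% of the movie only, so it is not mistaken for
  # a fiducial (those persist in > 90% of frames)
  iv <- tibble::tibble(emitter_id = 1L, start_frame = 1L, end_frame = 120L,
                       photon_rate = 600)
  fid <- tibble::tibble(x_nm = 3000, y_nm = 1000)
  st <- render_frames(em, intervals = iv, camera = cam, n_frames = n_frames,
                      roi = c(0, 4000, 0, 4000), drift = drift,
                      fiducials = fid, photon_rate = 600, seed = 301)
  locs <- localize_stack(st, threshold = 20)
  expect_true(any(locs$is_fiducial))
  expect_true(any(!locs$is_fiducial))
  corr <- correct_drift(locs)
  emloc <- dplyr::filter(corr, !.data$is_fiducial)
  rms <- sqrt(mean((emloc$x_nm - mean(emloc$x_nm))^2 +
                     (emloc$y_nm - mean(emloc$y_nm))^2) / 2)
  expect_lt(rms, 1.5 * median(emloc$precision_nm))
  # without correction the emitter smears over ~100 nm
  raw <- dplyr::filter(locs, !.data$is_fiducial)
  expect_gt(sd(raw$x_nm), 3 * median(raw$precision_nm))
})

test_that("zero injected drift produces near-zero corrections", {
  cam <- camera_model(background = 5)
  fid <- tibble::tibble(x_nm = c(1000, 3000), y_nm = c(1000, 3000))
  st <- render_frames(tibble::tibble(emitter_id = integer(0),
                                     x_nm = numeric(0), y_nm = numeric(0)),
                      camera = cam, n_frames = 100, roi = c(0, 4000, 0, 4000),
                      fiducials = fid, photon_rate = 600, seed = 302)
  locs <- localize_stack(st, threshold = 20)
  corr <- correct_drift(locs)
  dr <- attr(corr, "drift")
  fid_prec <- median(locs$precision_nm[locs$is_fiducial])
  expect_lt(max(abs(c(dr$dx_nm, dr$dy_nm))), 2 * fid_prec)
})

test_that("drift correction refuses to run without fiducials", {
  locs <- tibble::tibble(frame = 1:10, x_nm = 1, y_nm = 1, photons = 500,
                         background = 5, sigma_nm = 130, precision_nm = 15,
                         is_fiducial = FALSE)
  expect_error(correct_drift(locs), "fiducial")
})

test_that("blink grouping merges what it should and nothing else", {
  base <- tibble::tibble(photons = 600, background = 0, sigma_nm = 130,
                         precision_nm = 15, is_fiducial = FALSE)
  # T_d = 0: only consecutive frames merge
  locs <- dplyr::bind_cols(
    tibble::tibble(frame = c(1L, 2L, 4L), x_nm = 1000, y_nm = 1000), base)
  m0 <- group_blinks(locs, t_d = 0, r_group = 50, frame_time = 0.05)
  expect_equal(nrow(m0), 2L)
  expect_equal(sort(m0$n_locs), c(1L, 2L))

  # one emitter blinking 5 times with sub-threshold gaps: one molecule
  frames <- c(1, 2, 5, 9, 12, 15, 16)  # 5 on-events, max gap 3 frames
  locs5 <- dplyr::bind_cols(
    tibble::tibble(frame = as.integer(frames), x_nm = 2000, y_nm = 2000), base)
  m5 <- group_blinks(locs5, t_d = 0.2, r_group = 50, frame_time = 0.05)
  expect_equal(nrow(m5), 1L)
  expect_equal(m5$n_events, 5L)
  expect_equal(m5$n_locs, 7L)
  expect_equal(m5$first_frame, 1L)
  expect_equal(m5$last_frame, 16L)

  # two distant emitters never merge regardless of timing
  far <- dplyr::bind_cols(
    tibble::tibble(frame = c(1L, 1L, 2L, 2L),
                   x_nm = c(0, 5000, 0, 5000), y_nm = 0), base[c(1, 1, 1, 1), ])
  expect_equal(nrow(group_blinks(far, t_d = 1, r_group = 50)), 2L)

  expect_error(group_blinks(locs, t_d = -0.1), ">= 0")
})

test_that("grouping conserves localizations and is monotone in T_d", {
  # low localization noise so the grouping radius captures essentially all
  # re-localizations of a molecule (the sparse-count bound assumes this)
  locs <- make_blinky_locs(150, t_off = 0.26, n_frames = 1500,
                           roi_side = 8000, loc_sigma = 5, seed = 303)
  # the last value is >> T_off so that essentially no true dark period
  # exceeds it and the sparse-count bound applies
  tds <- c(0, 0.15, 0.3, 0.6, 3)
  counts <- sapply(tds, function(td) {
    m <- group_blinks(locs, t_d = td, r_group = 54)
    # conservation: every non-fiducial localization lands in one molecule
    expect_equal(sum(m$n_locs), nrow(locs))
    nrow(m)
  })
  expect_true(all(diff(counts) <= 0))
  # with spatially sparse emitters, N(large T_d) <= true emitter count
  expect_lte(counts[length(counts)], length(unique(locs$emitter_id)))
})

test_that("T_off is recovered at a second lifetime setting", {
  locs <- make_blinky_locs(1200, t_off = 0.10, n_frames = 2500,
                           roi_side = 15000, seed = 304)
  est <- estimate_toff(locs)
  expect_lt(abs(est$t_off - 0.10) / 0.10, 0.20)
  expect_gt(est$fit_r, 0.97)
  # curve is a valid non-increasing molecule-count curve
  expect_true(all(diff(est$curve$n_molecules) <= 0))
})

test_that("a blink-free movie gives a degenerate flat curve", {
  locs <- make_blinky_locs(300, t_off = 0.26, n_frames = 1500,
                           roi_side = 10000, seed = 305, bleach_prob = 1)
  expect_error(estimate_toff(locs), "degenerate|does not vary")
})

test_that("PALM rendering conserves counts and resolves close molecules", {
  one <- tibble::tibble(x_nm = 500, y_nm = 500)
  img <- render_palm(one, out_pixel = 10, mode = "histogram",
                     roi = c(0, 1000, 0, 1000))
  expect_equal(sum(img), 1)
  expect_equal(sum(img > 0), 1L)

  two <- tibble::tibble(x_nm = c(450, 550), y_nm = 500, precision_nm = 18)
  g <- render_palm(two, out_pixel = 10, mode = "gaussian",
                   roi = c(0, 1000, 0, 1000))
  expect_equal(sum(g), 2, tolerance = 1e-6)
  # two local maxima along the joining axis at ~100 nm separation
  row <- g[50, ]
  peaks <- which(diff(sign(diff(row))) == -2) + 1
  expect_equal(length(peaks), 2L)
  expect_lt(abs((peaks[2] - peaks[1]) * 10 - 100), 20)
})
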