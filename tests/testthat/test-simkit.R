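test_that("dark periods are exponential with the requested mean lifetime", {
  p <- photophysics_params(activation_rate = 0.01, mean_dark_time = 0.26,
                           bleach_prob = 0.3)
  iv <- sim_photophysics(p, n_emitters = 4000, n_frames = 3000,
                         frame_time = 0.05, seed = 101)
  gaps <- dark_periods(iv)
  expect_gt(length(gaps), 2000)
  se <- sd(gaps) / sqrt(length(gaps))
  # dark gaps are ceiling(X / dt) frames with X ~ Exp(T_off), so the
  # frame-measured mean is dt / (1 - exp(-dt / T_off)) ~ T_off + dt/2;
  # survival probabilities at grid times stay exactly exponential
  expect_lt(abs(mean(gaps) - 0.05 / (1 - exp(-0.05 / 0.26))), 3 * se)
  # survival beyond 6 frames (0.3 s) matches the exponential law:
  # ceiling(X/dt) > k iff X > k*dt
  gap_frames <- round(gaps / 0.05)
  expect_lt(abs(mean(gap_frames > 6) - exp(-0.3 / 0.26)), 0.03)
})

test_that("bleaching after the first on-event suppresses all blinking", {
  p <- photophysics_params(activation_rate = 0.05, bleach_prob = 1)
  iv <- sim_photophysics(p, 200, 500, seed = 102)
  expect_gt(nrow(iv), 0)
  expect_equal(anyDuplicated(iv$emitter_id), 0L)
  expect_length(dark_periods(iv), 0)
})

test_that("zero activation rate yields no on-intervals", {
  p <- photophysics_params(activation_rate = 0)
  iv <- sim_photophysics(p, 100, 100, seed = 103)
  expect_equal(nrow(iv), 0L)
  expect_equal(attr(iv, "n_emitters"), 100L)
})

test_that("on-intervals are disjoint, ordered and inside the movie", {
  p <- photophysics_params(activation_rate = 0.02, mean_on_time = 0.12,
                           bleach_prob = 0.2)
  iv <- sim_photophysics(p, 300, 800, seed = 104)
  expect_true(all(iv$start_frame >= 1 & iv$end_frame <= 800))
  expect_true(all(iv$end_frame >= iv$start_frame))
  by_em <- split(iv, iv$emitter_id)
  gaps_ok <- vapply(by_em, function(d) {
    d <- d[order(d$start_frame), ]
    nrow(d) < 2 || all(d$start_frame[-1] > d$end_frame[-nrow(d)])
  }, logical(1))
  expect_true(all(gaps_ok))
})

test_that("non-positive dark lifetime is rejected", {
  expect_error(photophysics_params(mean_dark_time = 0), "T_off|> 0")
  expect_error(photophysics_params(mean_dark_time = -1), "T_off|> 0")
})

test_that("cluster pattern honours occupancy distribution and fraction", {
  roi <- c(0, 20000, 0, 20000)
  # all monomers
  mono <- sim_cluster_pattern(roi, total_density = 3, clustered_fraction = 0,
                              seed = 105)
  expect_true(all(is.na(mono$cluster_id)))
  expect_true(all(mono$x_nm >= roi[1] & mono$x_nm <= roi[2]))

  # fixed occupancy of exactly 2
  dim2 <- sim_cluster_pattern(roi, total_density = 3, clustered_fraction = 1,
                              occupancy_pmf = c(`2` = 1), seed = 106)
  expect_true(all(table(dim2$cluster_id) == 2))

  # mixed occupancy: empirical mean ~ 2.5 (sample-mean oracle)
  mix <- sim_cluster_pattern(roi, total_density = 8, clustered_fraction = 1,
                             occupancy_pmf = c(`2` = 0.5, `3` = 0.5),
                             seed = 107)
  sizes <- as.integer(table(mix$cluster_id))
  expect_gt(length(sizes), 400)
  expect_lt(abs(mean(sizes) - 2.5), 3 * sd(sizes) / sqrt(length(sizes)))

  # clustered fraction within binomial error
  half <- sim_cluster_pattern(roi, total_density = 5,
                              clustered_fraction = 0.5, seed = 108)
  frac <- mean(!is.na(half$cluster_id))
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(nrow(half)) + 3 / nrow(half))
})

test_that("empty ROI and invalid occupancy are rejected", {
  expect_error(sim_cluster_pattern(c(0, 0, 0, 100), 1), "empty")
  expect_error(sim_cluster_pattern(c(0, 100, 0, 100), 1,
                                   occupancy_pmf = c(`1` = 1)), ">= 2")
  expect_error(sim_cluster_pattern(c(0, 100, 0, 100), 1,
                                   occupancy_pmf = c(`2` = 0.7)), "sum to 1")
})

test_that("rendered frames follow the analytic photon forward model", {
  cam <- camera_model(background = 4)
  # background only
  blank <- render_frames(tibble::tibble(emitter_id = integer(0),
                                        x_nm = numeric(0), y_nm = numeric(0)),
                         camera = cam, n_frames = 30,
                         roi = c(0, 2000, 0, 2000), seed = 109)
  px <- unlist(blank$frames)
  expect_lt(abs(mean(px) - 4), 3 * sqrt(4 / length(px)))
  expect_lt(abs(var(px) - 4) / 4, 0.1)  # Poisson: variance = mean

  # one emitter, zero background: summed counts ~ 600 per frame
  cam0 <- camera_model(background = 0)
  em <- tibble::tibble(emitter_id = 1L, x_nm = 1000, y_nm = 1000)
  st <- render_frames(em, camera = cam0, n_frames = 40,
                      roi = c(0, 2000, 0, 2000), photon_rate = 600,
                      seed = 110)
  totals <- vapply(st$frames, sum, numeric(1))
  expect_lt(abs(mean(totals) - 600), 3 * sqrt(600 / 40))

  # with background: expected total = photons + b * n_pixels
  st2 <- render_frames(em, camera = cam, n_frames = 40,
                       roi = c(0, 2000, 0, 2000), photon_rate = 600,
                       seed = 111)
  npx <- length(st2$frames[[1]])
  expected <- 600 + 4 * npx
  totals2 <- vapply(st2$frames, sum, numeric(1))
  expect_lt(abs(mean(totals2) - expected), 3 * sqrt(expected / 40))
})

test_that("trajectory steps have the Brownian variance, plus noise floor", {
  dt <- 0.05
  # single state, no noise: E[step^2] = 4 D dt
  tr <- sim_trajectories(D = 0.2, n_tracks = 400, mean_track_length = 12,
                         dt = dt, seed = 112)
  st <- track_steps(tr)
  msq <- mean(st$disp_nm^2)
  expect_gt(nrow(st), 3000)
  se <- sd(st$disp_nm^2) / sqrt(nrow(st))
  expect_lt(abs(msq - 4 * 0.2 * 1e6 * dt), 3 * se)

  # localization noise adds 4 sigma^2
  trn <- sim_trajectories(D = 0.1, n_tracks = 400, mean_track_length = 12,
                          dt = dt, loc_noise_sigma = 20, seed = 113)
  stn <- track_steps(trn)
  expect_lt(abs(mean(stn$disp_nm^2) - (4 * 0.1 * 1e6 * dt + 4 * 400)),
            3 * sd(stn$disp_nm^2) / sqrt(nrow(stn)))
})

test_that("identity transition matrix freezes the hidden state", {
  tr <- sim_trajectories(D = c(0.02, 0.44), trans = diag(2), n_tracks = 60,
                         mean_track_length = 15, seed = 114)
  switches <- tr |>
    dplyr::filter(!is.na(state)) |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(k = dplyr::n_distinct(state))
  expect_true(all(switches$k == 1))
})

test_that("invalid transition matrices are rejected", {
  expect_error(sim_trajectories(D = c(0.1, 0.2),
                                trans = matrix(c(0.9, 0.9, 0.2, 0.2), 2)),
               "row-stochastic")
  expect_error(sim_trajectories(D = c(-0.1), trans = diag(1)),
               "non-negative")
})

test_that("generators are reproducible under a fixed seed", {
  a <- sim_cluster_pattern(c(0, 5000, 0, 5000), 10, 0.3, seed = 115)
  b <- sim_cluster_pattern(c(0, 5000, 0, 5000), 10, 0.3, seed = 115)
  expect_identical(a, b)
  p <- photophysics_params(activation_rate = 0.01)
  expect_identical(sim_photophysics(p, 50, 200, seed = 116),
                   sim_photophysics(p, 50, 200, seed = 116))
})
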