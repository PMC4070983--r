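test_that("Mortensen precision has the right limits and scaling", {
  # background-free limit: sigma = s_a * sqrt(16/9) / sqrt(N)
  s <- 130; a <- 125; N <- 600
  sa <- sqrt(s^2 + a^2 / 12)
  expect_equal(estimate_precision(N, 0, s, a), sa * sqrt(16 / 9) / sqrt(N),
               tolerance = 1e-12)
  # doubling N at b = 0 improves precision by sqrt(2)
  expect_equal(estimate_precision(N, 0, s, a) /
                 estimate_precision(2 * N, 0, s, a),
               sqrt(2), tolerance = 1e-12)
  # strictly decreasing in N, increasing in b
  Ns <- c(100, 200, 400, 800, 1600)
  expect_true(all(diff(estimate_precision(Ns, 50, s, a)) < 0))
  bs <- c(0, 10, 50, 100, 200)
  expect_true(all(diff(sapply(bs, function(b)
    estimate_precision(N, b, s, a))) > 0))
  expect_error(estimate_precision(0, 10), "positive")
})

test_that("background inversion reproduces the 18 nm operating point", {
  # numerically invert the precision formula at N = 600; the background
  # that yields 18 nm is ~1.8e2 photons/pixel
  b_star <- invert_precision_background(18, 600)
  expect_gt(b_star, 150)
  expect_lt(b_star, 220)
  expect_equal(estimate_precision(600, b_star), 18, tolerance = 1e-9)
  expect_error(invert_precision_background(1, 600), "unreachable")
})

test_that("candidate detection finds isolated emitters and nothing else", {
  cam <- camera_model(background = 5)
  set.seed(201)
  # blank frame: background only, threshold far above its fluctuations
  blank <- render_frames(tibble::tibble(emitter_id = integer(0),
                                        x_nm = numeric(0), y_nm = numeric(0)),
                         camera = cam, n_frames = 1, roi = c(0, 4000, 0, 4000))
  expect_equal(nrow(detect_candidates(blank$frames[[1]], 50, cam)), 0L)

  # one bright emitter: exactly one candidate within 1 pixel of truth
  em <- tibble::tibble(emitter_id = 1L, x_nm = 1987, y_nm = 2043)
  st <- render_frames(em, camera = cam, n_frames = 1, roi = c(0, 4000, 0, 4000),
                      photon_rate = 600)
  cand <- detect_candidates(st$frames[[1]], 20, cam)
  expect_equal(nrow(cand), 1L)
  expect_lt(abs((cand$col - 0.5) * 125 - 1987), 187.5)
  expect_lt(abs((cand$row - 0.5) * 125 - 2043), 187.5)

  # two emitters 2 um apart: two candidates
  em2 <- tibble::tibble(emitter_id = 1:2, x_nm = c(1000, 3000), y_nm = 2000)
  st2 <- render_frames(em2, camera = cam, n_frames = 1,
                       roi = c(0, 4000, 0, 4000), photon_rate = 600)
  expect_equal(nrow(detect_candidates(st2$frames[[1]], 20, cam)), 2L)
})

test_that("the MLE fitter is accurate in the noise-free limit", {
  cam <- camera_model(background = 2)
  a <- cam$pixel_size
  # analytic expected counts, no Poisson draw: fit should nail the position
  fx <- diff(pnorm(a * (0:11), 5.5 * a, cam$psf_sigma))
  fy <- diff(pnorm(a * (0:11), 5.5 * a, cam$psf_sigma))
  counts <- 600 * outer(fy, fx) + 2
  fit <- fit_spot(counts, cam)
  expect_true(fit$converged)
  expect_lt(abs(fit$x_nm - 5.5 * a), 1)
  expect_lt(abs(fit$y_nm - 5.5 * a), 1)
  expect_lt(abs(fit$photons - 600) / 600, 0.01)
  expect_lt(abs(fit$background - 2), 0.1)
})

test_that("photon estimates are unbiased across brightness levels", {
  cam <- camera_model(background = 10)
  set.seed(202)
  for (N in c(200, 600, 2000)) {
    est <- replicate(60, {
      sp <- render_single_spot(N, 10, cam, offset_px = runif(2, -0.5, 0.5))
      fit_spot(sp$window, cam)$photons
    })
    expect_lt(abs(mean(est) - N), 3 * sd(est) / sqrt(length(est)))
  }
})

test_that("empirical fit error matches the predicted precision", {
  # CRLB-consistency on a (N, b) grid: RMSE within 15% of Mortensen
  set.seed(203)
  for (case in list(c(600, 20), c(1500, 60))) {
    N <- case[1]; b <- case[2]
    cam <- camera_model(background = b)
    err <- replicate(120, {
      sp <- render_single_spot(N, b, cam, offset_px = runif(2, -0.5, 0.5))
      f <- fit_spot(sp$window, cam)
      c(f$x_nm - sp$x, f$y_nm - sp$y)
    })
    rmse <- sqrt(mean(err^2))
    pred <- estimate_precision(N, b)
    expect_lt(abs(rmse - pred) / pred, 0.15)
  }
})

test_that("localize_stack recovers position, photons and flags nothing", {
  cam <- camera_model(background = 5)
  em <- tibble::tibble(emitter_id = 1:2, x_nm = c(900, 3100),
                       y_nm = c(1100, 2900))
  st <- render_frames(em, camera = cam, n_frames = 15,
                      roi = c(0, 4000, 0, 4000), photon_rate = 600,
                      seed = 204)
  locs <- localize_stack(st, threshold = 20)
  expect_gte(nrow(locs), 28)
  expect_setequal(names(locs), c("frame", "x_nm", "y_nm", "photons",
                                 "background", "sigma_nm", "precision_nm",
                                 "is_fiducial"))
  # every localization within 3 precisions of a true emitter
  d1 <- sqrt((locs$x_nm - 900)^2 + (locs$y_nm - 1100)^2)
  d2 <- sqrt((locs$x_nm - 3100)^2 + (locs$y_nm - 2900)^2)
  expect_true(all(pmin(d1, d2) < 60))
  # persistent static emitters are fiducial-flagged by design
  expect_true(all(locs$is_fiducial))
})

test_that("localization filtering is correct, order-preserving, idempotent", {
  locs <- tibble::tibble(frame = 1:5, x_nm = 1:5, y_nm = 1:5,
                         photons = c(100, 300, 600, 800, 50),
                         background = 5, sigma_nm = c(120, 400, 130, 135, 125),
                         precision_nm = c(10, 20, 30, 80, 12),
                         is_fiducial = FALSE)
  expect_equal(nrow(filter_localizations(locs)), 5L)
  f <- filter_localizations(locs, min_photons = 300)
  expect_equal(f$photons, c(300, 600, 800))
  expect_equal(attr(f, "filter_log")[["kept"]], 3L)
  f2 <- filter_localizations(locs, min_photons = 300, max_sigma = 200,
                             max_precision = 50)
  expect_equal(f2$frame, 3L)
  # idempotence
  once <- filter_localizations(locs, 150, 300, 50)
  twice <- filter_localizations(once, 150, 300, 50)
  attr(once, "filter_log") <- attr(twice, "filter_log") <- NULL
  expect_equal(once, twice)
})
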