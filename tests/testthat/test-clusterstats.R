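test_that("Ripley's K equals the brute-force pair-count oracle", {
  roi <- c(0, 1000, 0, 1000)
  r_grid <- seq(20, 240, by = 20)
  set.seed(401)
  for (rep in 1:8) {
    n <- sample(10:25, 1)
    pts <- tibble::tibble(x_nm = runif(n, 0, 1000), y_nm = runif(n, 0, 1000))
    rk <- ripley_k(pts, r_grid, roi)
    expect_equal(rk$curve$K, ripley_bruteforce(pts, r_grid, roi),
                 tolerance = 1e-9)
  }
})

test_that("K is zero below the smallest pair distance and non-decreasing", {
  set.seed(402)
  pts <- tibble::tibble(x_nm = runif(12, 0, 1000), y_nm = runif(12, 0, 1000))
  dmin <- min(dist(cbind(pts$x_nm, pts$y_nm)))
  rk <- ripley_k(pts, c(dmin / 2, seq(50, 250, 50)), c(0, 1000, 0, 1000))
  expect_equal(rk$curve$K[1], 0)
  expect_true(all(diff(rk$curve$K) >= 0))
})

test_that("CSR patterns give H near zero within the envelope", {
  roi <- c(0, 4000, 0, 4000)
  r_grid <- seq(25, 500, by = 25)
  set.seed(403)
  pts <- tibble::tibble(x_nm = runif(1000, 0, 4000),
                        y_nm = runif(1000, 0, 4000))
  rk <- ripley_k(pts, r_grid, roi) |>
    add_csr_envelope(n_sims = 39, seed = 404)
  env <- rk$envelope
  # H(r) is strongly correlated across r, so judge the pattern globally:
  # its maximum must stay below the family-wise CSR bound, and |H| must be
  # tiny relative to the ~30-150 nm peaks clustered patterns produce
  expect_lt(max(rk$curve$H), rk$global_hi)
  expect_lt(mean(abs(rk$curve$H)), 10)
  # the envelope is centred on 0
  expect_true(all(env$lo <= 0 & env$hi >= 0))
})

test_that("envelope width shrinks roughly like 1/sqrt(n)", {
  roi <- c(0, 4000, 0, 4000)
  r_grid <- c(100, 200)
  w <- sapply(c(100, 400), function(n) {
    env <- csr_envelope(n, roi, r_grid, n_sims = 59, seed = 405)
    mean(env$hi - env$lo)
  })
  expect_gt(w[1] / w[2], 1.5)  # expected ~2 for a 4x point-count increase
  # bit-exact reproducibility under a fixed seed
  expect_identical(csr_envelope(50, roi, r_grid, n_sims = 19, seed = 406),
                   csr_envelope(50, roi, r_grid, n_sims = 19, seed = 406))
})

test_that("r_max beyond a quarter window side is refused", {
  pts <- tibble::tibble(x_nm = runif(20, 0, 1000), y_nm = runif(20, 0, 1000))
  expect_error(ripley_k(pts, c(100, 300), c(0, 1000, 0, 1000)), "1/4")
})

test_that("DBSCAN calibration tracks density and the CSR NN law", {
  roi <- c(0, 10000, 0, 10000)
  set.seed(407)
  lo <- tibble::tibble(x_nm = runif(200, 0, 10000),
                       y_nm = runif(200, 0, 10000))
  hi <- tibble::tibble(x_nm = runif(800, 0, 10000),
                       y_nm = runif(800, 0, 10000))
  eps_lo <- calibrate_dbscan(lo, roi, seed = 408)$eps
  eps_hi <- calibrate_dbscan(hi, roi, seed = 408)$eps
  expect_lt(eps_hi, eps_lo)  # denser pattern -> smaller chance distance
  # 50th percentile ~ median CSR nearest-neighbour distance ~ 0.5/sqrt(lambda)
  lambda <- 800 / (10000 * 10000)
  med <- calibrate_dbscan(hi, roi, percentile = 50, seed = 409)$eps
  expect_lt(abs(med - 0.5 / sqrt(lambda)) / (0.5 / sqrt(lambda)), 0.1)
  # seeded reproducibility
  expect_identical(calibrate_dbscan(hi, roi, seed = 410),
                   calibrate_dbscan(hi, roi, seed = 410))
})

test_that("DBSCAN clusters chains and leaves isolated points as noise", {
  # all pairwise distances > eps: everything is noise
  iso <- tibble::tibble(x_nm = c(0, 100, 200, 300), y_nm = c(0, 100, 0, 100))
  rep_iso <- dbscan_clusters(iso, eps = 50)
  expect_equal(rep_iso$n_clusters, 0L)
  expect_true(all(rep_iso$labels == 0))
  expect_equal(rep_iso$clustered_fraction, 0)

  # chain within eps: one cluster of three
  chain <- tibble::tibble(x_nm = c(0, 40, 80), y_nm = 0)
  rep_ch <- dbscan_clusters(chain, eps = 50)
  expect_equal(rep_ch$n_clusters, 1L)
  expect_equal(rep_ch$occupancy$size, 3L)
  expect_equal(rep_ch$mean_occupancy, 3)
  expect_equal(rep_ch$clustered_fraction, 1)
})

test_that("calibrated DBSCAN recovers the generating occupancy", {
  roi <- c(0, 10000, 0, 10000)
  pts <- sim_cluster_pattern(roi, total_density = 2, clustered_fraction = 0.5,
                             occupancy_pmf = c(`2` = 0.6, `3` = 0.4),
                             cluster_sigma = 10, seed = 411)
  # blink-corrected molecule table: one entry per true molecule, blurred by
  # the localization precision
  set.seed(412)
  mols <- dplyr::mutate(pts,
                        x_nm = x_nm + rnorm(dplyr::n(), 0, 18),
                        y_nm = y_nm + rnorm(dplyr::n(), 0, 18))
  cal <- calibrate_dbscan(mols, roi, n_sims = 20, percentile = 1, seed = 413)
  rep <- dbscan_clusters(mols, cal$eps, cal$min_pts)
  expect_lt(abs(rep$mean_occupancy - 2.4), 0.5)
})

test_that("the apparent cluster scale grows with localization error", {
  roi <- c(0, 10000, 0, 10000)
  r_grid <- seq(5, 250, by = 5)
  peaks <- sapply(c(5, 18, 40), function(s) {
    tr <- sim_cluster_pattern(roi, total_density = 3, clustered_fraction = 0.8,
                              occupancy_pmf = c(`4` = 1), cluster_sigma = 1,
                              seed = 414)
    set.seed(415)
    m <- dplyr::mutate(tr, x_nm = x_nm + rnorm(dplyr::n(), 0, s),
                       y_nm = y_nm + rnorm(dplyr::n(), 0, s))
    rk <- ripley_k(m, r_grid, roi) |> add_csr_envelope(n_sims = 39, seed = 416)
    apparent_cluster_size(rk)
  })
  expect_true(all(diff(peaks) > 0))
  # refining the grid moves the peak by at most one original step
  tr <- sim_cluster_pattern(roi, total_density = 3, clustered_fraction = 0.8,
                            occupancy_pmf = c(`4` = 1), cluster_sigma = 1,
                            seed = 414)
  set.seed(415)
  m <- dplyr::mutate(tr, x_nm = x_nm + rnorm(dplyr::n(), 0, 18),
                     y_nm = y_nm + rnorm(dplyr::n(), 0, 18))
  coarse <- ripley_k(m, seq(10, 250, 10), roi) |>
    add_csr_envelope(n_sims = 39, seed = 417)
  fine <- ripley_k(m, seq(5, 250, 5), roi) |>
    add_csr_envelope(n_sims = 39, seed = 417)
  expect_lte(abs(apparent_cluster_size(coarse) - apparent_cluster_size(fine)),
             10)
})

test_that("CSR input yields no significant apparent cluster size", {
  roi <- c(0, 10000, 0, 10000)
  csr <- sim_cluster_pattern(roi, total_density = 3, clustered_fraction = 0,
                             seed = 418)
  rk <- ripley_k(csr, seq(5, 250, 5), roi) |>
    add_csr_envelope(n_sims = 39, seed = 419)
  expect_message(res <- apparent_cluster_size(rk), "CSR|No significant")
  expect_null(res)
})
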