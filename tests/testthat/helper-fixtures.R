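# Shared fixture builders and independent oracles used across test files.

# Brute-force Ripley's K: explicit double loop over ordered pairs, weights
# evaluated per pair. Kept deliberately naive and separate from the
# vectorised implementation it checks.
ripley_bruteforce <- function(pts, r_grid, roi) {
  n <- nrow(pts)
  area <- (roi[2] - roi[1]) * (roi[4] - roi[3])
  K <- numeric(length(r_grid))
  for (g in seq_along(r_grid)) {
    s <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d <- sqrt((pts$x_nm[i] - pts$x_nm[j])^2 +
                    (pts$y_nm[i] - pts$y_nm[j])^2)
        if (d <= r_grid[g]) {
          s <- s + palmkit:::iso_weight(pts$x_nm[i], pts$y_nm[i], d, roi)
        }
      }
    }
    K[g] <- s * area / (n * (n - 1))
  }
  K
}

# Brute-force HMM log-likelihood and posteriors by enumerating every state
# path of one short track.
hmm_enumerate <- function(logB, pi0, trans) {
  T_ <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  pr <- apply(paths, 1, function(s) {
    p <- pi0[s[1]] * exp(logB[1, s[1]])
    if (T_ > 1) for (t in 2:T_) p <- p * trans[s[t - 1], s[t]] * exp(logB[t, s[t]])
    p
  })
  gamma <- sapply(seq_len(K), function(k) {
    sapply(seq_len(T_), function(t) sum(pr[paths[, t] == k]))
  }) / sum(pr)
  list(loglik = log(sum(pr)), gamma = gamma)
}

# Brute-force optimal gated matching by permutation enumeration (n <= 6):
# minimises total cost where matching at distance d costs d (only if
# d <= max_disp) and each unmatched point costs max_disp.
match_bruteforce <- function(x1, y1, x2, y2, max_disp) {
  n1 <- length(x1); n2 <- length(x2)
  d <- sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
  best <- NULL; best_cost <- Inf
  # enumerate all injective partial maps from set 1 to set 2
  assignments <- list(integer(n1))
  for (i in seq_len(n1)) {
    assignments <- unlist(lapply(assignments, function(a) {
      opts <- c(0L, setdiff(seq_len(n2), a[a > 0]))
      lapply(opts, function(o) { a[i] <- o; a })
    }), recursive = FALSE)
  }
  for (a in assignments) {
    if (any(a > 0 & d[cbind(seq_len(n1), pmax(a, 1))] > max_disp)) next
    linked <- sum(a > 0)
    cost <- sum(d[cbind(which(a > 0), a[a > 0])]) +
      max_disp * ((n1 - linked) + (n2 - linked))
    if (cost < best_cost - 1e-12) { best_cost <- cost; best <- a }
  }
  list(assignment = best, cost = best_cost)
}

# Single-frame rendering of isolated spots for fitter tests: returns the
# 11x11 photon-count window and the true position within it.
render_single_spot <- function(photons, background, camera = camera_model(),
                               offset_px = c(0, 0)) {
  a <- camera$pixel_size
  truth <- c(5.5 * a + offset_px[1] * a, 5.5 * a + offset_px[2] * a)
  em <- tibble::tibble(emitter_id = 1L, x_nm = truth[1], y_nm = truth[2])
  st <- render_frames(em, camera = camera, n_frames = 1,
                      roi = c(0, 11 * a, 0, 11 * a), photon_rate = photons)
  list(window = st$frames[[1]], x = truth[1], y = truth[2])
}

fig4c_trans <- function() {
  matrix(c(0.9, 0.05, 0.05,
           0.05, 0.9, 0.05,
           0.05, 0.05, 0.9), 3, 3, byrow = TRUE)
}

# Sparse blinking emitters run through the truth-based localization
# shortcut; the workhorse input for dark-lifetime and grouping tests.
make_blinky_locs <- function(n_emitters, t_off, n_frames = 3000,
                             roi_side = 20000, loc_sigma = 18, seed = 1,
                             activation_rate = 0.002, bleach_prob = 0.5) {
  p <- photophysics_params(activation_rate = activation_rate,
                           mean_dark_time = t_off,
                           bleach_prob = bleach_prob)
  density <- n_emitters / (roi_side / 1000)^2
  em <- sim_cluster_pattern(c(0, roi_side, 0, roi_side), density,
                            clustered_fraction = 0, seed = seed)
  iv <- sim_photophysics(p, nrow(em), n_frames, seed = seed + 1)
  sim_localizations(em, iv, loc_sigma = loc_sigma, seed = seed + 2)
}

# Render-and-fit statistics at the reported per-event photon yield and at
# the background that the precision formula maps to ~18 nm. Cached so the
# photon-yield and precision checks share one simulation.
spot_fit_stats <- local({
  cache <- NULL
  function(n_spots = 500, seed = 42) {
    if (!is.null(cache)) return(cache)
    b_star <- invert_precision_background(18, 600, psf_sigma = 130,
                                          pixel_size = 125)
    cam <- camera_model(background = b_star, psf_sigma = 130,
                        pixel_size = 125)
    set.seed(seed)
    phot <- numeric(n_spots); err <- matrix(0, n_spots, 2)
    for (i in seq_len(n_spots)) {
      sp <- render_single_spot(600, b_star, cam,
                               offset_px = runif(2, -0.5, 0.5))
      f <- fit_spot(sp$window, cam)
      phot[i] <- f$photons
      err[i, ] <- c(f$x_nm - sp$x, f$y_nm - sp$y)
    }
    cache <<- list(photons = phot, errors = err, b_star = b_star,
                   predicted_precision = estimate_precision(600, b_star))
    cache
  }
})
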