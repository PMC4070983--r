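# Synthetic-data engine: photophysics, clustered point patterns, camera
# frames, and state-switching Brownian trajectories. Every generator takes an
# explicit seed and returns tidy tibbles (or a light list object for stacks).

#' Photophysics parameters for a photoactivatable fluorophore
#'
#' Describes PAmCherry1-like single-molecule photophysics on the camera frame
#' grid: each emitter is dark until it stochastically photoactivates, then
#' alternates fluorescent on-periods with reversible dark (blink) periods
#' until it irreversibly bleaches.
#'
#' @param activation_rate Per-frame activation probability (dimensionless).
#' @param mean_on_time Mean fluorescent on-period, seconds.
#' @param mean_dark_time Mean reversible dark-state lifetime `T_off`, seconds.
#'   Dark periods are drawn from an exponential with this mean.
#' @param bleach_prob Probability that an on-event ends in irreversible
#'   photobleaching rather than a reversible dark state.
#' @param photons_per_frame Expected photons emitted per frame while on.
#'
#' @return A `palm_photophysics` list.
#' @export
photophysics_params <- function(activation_rate = 0.002,
                                mean_on_time = 0.05,
                                mean_dark_time = 0.26,
                                bleach_prob = 0.5,
                                photons_per_frame = 600) {
  stop_if_not_scalar(activation_rate, "activation_rate", 0, 1)
  stop_if_not_scalar(mean_on_time, "mean_on_time", lower = 0)
  stop_if_not_scalar(mean_dark_time, "mean_dark_time")
  if (mean_dark_time <= 0) abort("`mean_dark_time` (T_off) must be > 0.")
  stop_if_not_scalar(bleach_prob, "bleach_prob", 0, 1)
  stop_if_not_scalar(photons_per_frame, "photons_per_frame", lower = 0)
  structure(
    list(activation_rate = activation_rate,
         mean_on_time = mean_on_time,
         mean_dark_time = mean_dark_time,
         bleach_prob = bleach_prob,
         photons_per_frame = photons_per_frame),
    class = "palm_photophysics"
  )
}

#' Simulate blinking photophysics time traces
#'
#' Each emitter activates at most once (geometric waiting time with the
#' per-frame activation probability), then alternates on-intervals and dark
#' intervals. On-durations are exponential with mean `mean_on_time`,
#' discretised to whole frames (minimum one frame). Dark durations are drawn
#' as continuous exponentials with mean `mean_dark_time` and rounded up to
#' whole frames, so the probability that a dark period exceeds a grid time
#' `T_d` (a multiple of the frame time) keeps its exact exponential value.
#' After each on-event the emitter bleaches with probability `bleach_prob`.
#'
#' @param params A [photophysics_params()] object.
#' @param n_emitters Number of emitters to simulate.
#' @param n_frames Number of camera frames (>= 1).
#' @param frame_time Frame (exposure) time in seconds.
#' @param seed Optional integer seed.
#'
#' @return A tibble with one row per on-interval: `emitter_id`,
#'   `start_frame`, `end_frame` (inclusive, 1-based), `photon_rate`
#'   (expected photons per frame). Emitters that never activate contribute no
#'   rows; the attribute `n_emitters` records how many were simulated.
#' @export
sim_photophysics <- function(params, n_emitters, n_frames,
                             frame_time = 0.05, seed = NULL) {
  stopifnot(inherits(params, "palm_photophysics"))
  stop_if_not_scalar(n_emitters, "n_emitters", lower = 0)
  stop_if_not_scalar(n_frames, "n_frames", lower = 1)
  stop_if_not_scalar(frame_time, "frame_time")
  if (frame_time <= 0) abort("`frame_time` must be > 0.")

  with_seed(seed, {
    ids <- integer(0); starts <- integer(0); ends <- integer(0)
    for (e in seq_len(n_emitters)) {
      if (params$activation_rate <= 0) next
      t_act <- 1L + rgeom_safe(params$activation_rate)
      frame <- t_act
      while (frame <= n_frames) {
        on_frames <- max(1L, ceiling(rexp(1, 1 / max(params$mean_on_time, 1e-12)) /
                                       frame_time))
        end <- min(n_frames, frame + on_frames - 1L)
        ids <- c(ids, e); starts <- c(starts, frame); ends <- c(ends, end)
        if (end >= n_frames) break
        if (runif(1) < params$bleach_prob) break
        dark_frames <- ceiling(rexp(1, 1 / params$mean_dark_time) / frame_time)
        frame <- end + dark_frames + 1L
      }
    }
    out <- tibble(emitter_id = ids,
                  start_frame = as.integer(starts),
                  end_frame = as.integer(ends),
                  photon_rate = params$photons_per_frame)
    attr(out, "n_emitters") <- as.integer(n_emitters)
    attr(out, "n_frames") <- as.integer(n_frames)
    attr(out, "frame_time") <- frame_time
    attr(out, "params") <- params
    out
  })
}

rgeom_safe <- function(p) {
  if (p >= 1) return(0L)
  stats::rgeom(1, p)
}

#' Dark-period durations implied by a photophysics trace
#'
#' @param intervals Output of [sim_photophysics()].
#' @return Numeric vector of dark-period durations in seconds (gaps between
#'   successive on-intervals of the same emitter).
#' @export
dark_periods <- function(intervals) {
  frame_time <- attr(intervals, "frame_time") %||% 0.05
  gaps <- intervals |>
    dplyr::arrange(.data$emitter_id, .data$start_frame) |>
    dplyr::group_by(.data$emitter_id) |>
    dplyr::mutate(gap = .data$start_frame - dplyr::lag(.data$end_frame) - 1L) |>
    dplyr::ungroup()
  gaps$gap[!is.na(gaps$gap)] * frame_time
}

#' Simulate a clustered membrane point pattern
#'
#' Places `(1 - clustered_fraction)` of the molecules uniformly at random in
#' the ROI (complete spatial randomness) and the remainder in small clusters:
#' cluster centres are themselves CSR, each cluster's occupancy is drawn from
#' `occupancy_pmf`, and members scatter about the centre with an isotropic
#' Gaussian of standard deviation `cluster_sigma`.
#'
#' @param roi Rectangle `c(xmin, xmax, ymin, ymax)` in nm.
#' @param total_density Expected molecule density, molecules per square
#'   micrometre.
#' @param clustered_fraction Fraction of molecules belonging to clusters, in
#'   `[0, 1]`.
#' @param occupancy_pmf Named numeric vector over cluster sizes `>= 2`
#'   (names are sizes, values probabilities summing to 1).
#' @param cluster_sigma Gaussian scatter of members about their centre, nm.
#' @param seed Optional integer seed.
#'
#' @return Tibble: `emitter_id`, `x_nm`, `y_nm`, `cluster_id` (`NA` for
#'   monomers).
#' @export
sim_cluster_pattern <- function(roi, total_density, clustered_fraction = 0,
                                occupancy_pmf = c(`2` = 0.6, `3` = 0.4),
                                cluster_sigma = 10, seed = NULL) {
  check_roi(roi)
  stop_if_not_scalar(total_density, "total_density", lower = 0)
  stop_if_not_scalar(clustered_fraction, "clustered_fraction", 0, 1)
  stop_if_not_scalar(cluster_sigma, "cluster_sigma", lower = 0)
  sizes <- as.integer(names(occupancy_pmf))
  if (length(occupancy_pmf) == 0 || any(is.na(sizes)) || any(sizes < 2)) {
    abort("`occupancy_pmf` must be named by integer cluster sizes >= 2.")
  }
  if (abs(sum(occupancy_pmf) - 1) > 1e-8) {
    abort("`occupancy_pmf` probabilities must sum to 1.")
  }

  with_seed(seed, {
    n_total <- round(total_density * roi_area_nm2(roi) * UM2_PER_NM2)
    n_mono <- round((1 - clustered_fraction) * n_total)
    target_clustered <- n_total - n_mono

    x <- runif(n_mono, roi[1], roi[2])
    y <- runif(n_mono, roi[3], roi[4])
    cl <- rep(NA_integer_, n_mono)

    cid <- 0L
    n_clustered <- 0L
    while (n_clustered < target_clustered) {
      cid <- cid + 1L
      k <- sizes[sample.int(length(sizes), 1, prob = occupancy_pmf)]
      cx <- runif(1, roi[1], roi[2]); cy <- runif(1, roi[3], roi[4])
      x <- c(x, rnorm(k, cx, cluster_sigma))
      y <- c(y, rnorm(k, cy, cluster_sigma))
      cl <- c(cl, rep(cid, k))
      n_clustered <- n_clustered + k
    }
    tibble(emitter_id = seq_along(x), x_nm = x, y_nm = y, cluster_id = cl)
  })
}

#' Camera and optics model
#'
#' @param pixel_size Back-projected pixel size, nm (default 125: a 500 nm
#'   distance spans 4 pixels).
#' @param frame_time Frame time, seconds (default 0.05).
#' @param psf_sigma Gaussian PSF standard deviation, nm.
#' @param background Mean background, photons/pixel/frame.
#' @param read_noise Gaussian read noise, electrons rms.
#' @param offset,gain Camera digitisation: `DN = offset + gain * electrons`.
#'
#' @return A `palm_camera` list.
#' @export
camera_model <- function(pixel_size = 125, frame_time = 0.05, psf_sigma = 130,
                         background = 5, read_noise = 0, offset = 0,
                         gain = 1) {
  stop_if_not_scalar(pixel_size, "pixel_size"); if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  stop_if_not_scalar(frame_time, "frame_time"); if (frame_time <= 0) abort("`frame_time` must be > 0.")
  stop_if_not_scalar(psf_sigma, "psf_sigma"); if (psf_sigma <= 0) abort("`psf_sigma` must be > 0.")
  stop_if_not_scalar(background, "background", lower = 0)
  stop_if_not_scalar(read_noise, "read_noise", lower = 0)
  stop_if_not_scalar(gain, "gain", lower = 1e-9)
  stop_if_not_scalar(offset, "offset")
  structure(
    list(pixel_size = pixel_size, frame_time = frame_time,
         psf_sigma = psf_sigma, background = background,
         read_noise = read_noise, offset = offset, gain = gain),
    class = "palm_camera"
  )
}

# Expected photons deposited by a unit-intensity emitter at (xc, yc) nm into
# pixels [cols x rows]; pixel (r, c) spans ((c-1)a, ca) x ((r-1)a, ra).
pixel_psf_matrix <- function(xc, yc, sigma, a, cols, rows) {
  fx <- diff(stats::pnorm(a * (0:max(cols)), xc, sigma))[cols]
  fy <- diff(stats::pnorm(a * (0:max(rows)), yc, sigma))[rows]
  outer(fy, fx)
}

#' Render synthetic camera frames
#'
#' Forward model for the localization stage: each active emitter contributes
#' a pixel-integrated 2D Gaussian with Poisson photon statistics; a uniform
#' Poisson background is added per pixel; optional fiducial markers are
#' rendered bright in every frame; per-frame stage drift shifts every true
#' position before rendering. Photon counts are digitised through the camera
#' gain/offset with optional Gaussian read noise.
#'
#' @param emitters Tibble with `emitter_id`, `x_nm`, `y_nm` (true positions).
#' @param intervals On-intervals from [sim_photophysics()] (`emitter_id`,
#'   `start_frame`, `end_frame`, `photon_rate`). May be `NULL`, in which case
#'   every emitter is on in every frame at `photon_rate`.
#' @param camera A [camera_model()].
#' @param n_frames Number of frames to render.
#' @param roi Field of view `c(xmin, xmax, ymin, ymax)` nm; the image spans
#'   it with `ceiling(extent / pixel_size)` pixels (origin at `xmin`,
#'   `ymin`, image top-left).
#' @param drift Optional tibble/matrix of per-frame drift (`dx_nm`,
#'   `dy_nm`), `n_frames` rows; applied additively to all true positions.
#' @param fiducials Optional tibble with `x_nm`, `y_nm` of stationary bright
#'   markers.
#' @param photon_rate Photons/frame for always-on rendering and fiducials.
#' @param fiducial_rate Photons/frame per fiducial (default 20 x
#'   `photon_rate`, emulating 100 nm gold particles).
#' @param seed Optional integer seed.
#'
#' @return A `palm_stack`: list with `frames` (list of numeric matrices in
#'   camera units), `camera`, `roi`, `drift`, and the ground truth used.
#' @export
render_frames <- function(emitters, intervals = NULL, camera = camera_model(),
                          n_frames = NULL, roi = NULL, drift = NULL,
                          fiducials = NULL, photon_rate = 600,
                          fiducial_rate = 20 * photon_rate, seed = NULL) {
  stopifnot(inherits(camera, "palm_camera"))
  if (is.null(n_frames)) {
    n_frames <- if (!is.null(intervals)) attr(intervals, "n_frames") else NULL
    if (is.null(n_frames)) abort("`n_frames` is required.")
  }
  if (is.null(roi)) {
    pad <- 6 * camera$psf_sigma
    roi <- c(min(emitters$x_nm) - pad, max(emitters$x_nm) + pad,
             min(emitters$y_nm) - pad, max(emitters$y_nm) + pad)
  }
  check_roi(roi)
  a <- camera$pixel_size
  ncol_px <- max(4L, ceiling((roi[2] - roi[1]) / a))
  nrow_px <- max(4L, ceiling((roi[4] - roi[3]) / a))

  if (is.null(drift)) {
    drift <- tibble(dx_nm = rep(0, n_frames), dy_nm = rep(0, n_frames))
  } else {
    drift <- as_tibble(as.data.frame(drift))
    names(drift)[1:2] <- c("dx_nm", "dy_nm")
    if (nrow(drift) != n_frames) abort("`drift` must have one row per frame.")
  }

  if (is.null(intervals)) {
    intervals <- tibble(emitter_id = emitters$emitter_id,
                        start_frame = 1L, end_frame = as.integer(n_frames),
                        photon_rate = photon_rate)
  }
  emit_xy <- emitters[match(intervals$emitter_id, emitters$emitter_id), ]
  # per-frame active emitter index
  active <- vector("list", n_frames)
  for (i in seq_len(nrow(intervals))) {
    fr <- intervals$start_frame[i]:intervals$end_frame[i]
    fr <- fr[fr >= 1 & fr <= n_frames]
    for (f in fr) active[[f]] <- c(active[[f]], i)
  }

  with_seed(seed, {
    frames <- vector("list", n_frames)
    halfwin <- ceiling(5 * camera$psf_sigma / a)
    for (f in seq_len(n_frames)) {
      mu <- matrix(camera$background, nrow_px, ncol_px)
      add_spot <- function(x, y, rate) {
        # local window in pixel indices
        cpx <- floor(x / a) + 1L
        cpy <- floor(y / a) + 1L
        cols <- max(1L, cpx - halfwin):min(ncol_px, cpx + halfwin)
        rows <- max(1L, cpy - halfwin):min(nrow_px, cpy + halfwin)
        if (!length(cols) || !length(rows)) return()
        mu[rows, cols] <<- mu[rows, cols] +
          rate * pixel_psf_matrix(x, y, camera$psf_sigma, a, cols, rows)
      }
      dx <- drift$dx_nm[f]; dy <- drift$dy_nm[f]
      for (i in active[[f]]) {
        add_spot(emit_xy$x_nm[i] - roi[1] + dx, emit_xy$y_nm[i] - roi[3] + dy,
                 intervals$photon_rate[i])
      }
      if (!is.null(fiducials)) {
        for (i in seq_len(nrow(fiducials))) {
          add_spot(fiducials$x_nm[i] - roi[1] + dx,
                   fiducials$y_nm[i] - roi[3] + dy, fiducial_rate)
        }
      }
      counts <- matrix(rpois(length(mu), mu), nrow_px, ncol_px)
      img <- camera$offset + camera$gain * counts
      if (camera$read_noise > 0) {
        img <- img + camera$gain * matrix(rnorm(length(mu), 0, camera$read_noise),
                                          nrow_px, ncol_px)
      }
      frames[[f]] <- img
    }
    structure(list(frames = frames, camera = camera, roi = roi, drift = drift,
                   emitters = emitters, intervals = intervals,
                   fiducials = fiducials),
              class = "palm_stack")
  })
}

#' @export
print.palm_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<palm_stack> %d frames of %d x %d px (%.0f nm/px)\n",
              length(x$frames), d[1], d[2], x$camera$pixel_size))
  invisible(x)
}

#' Ground-truth localizations without rendering
#'
#' Shortcut through the imaging forward model: emits one localization per
#' on-frame at the emitter's true position plus isotropic Gaussian
#' localization noise. Useful for testing downstream stages at scale without
#' the cost of rendering and refitting frames.
#'
#' @inheritParams render_frames
#' @param loc_sigma Localization noise standard deviation per axis, nm.
#' @param seed Optional integer seed.
#' @return A localization tibble (`frame`, `x_nm`, `y_nm`, `photons`,
#'   `background`, `sigma_nm`, `precision_nm`, `is_fiducial`) with the
#'   generating `emitter_id` retained for truth-based checks.
#' @export
sim_localizations <- function(emitters, intervals, loc_sigma = 18,
                              seed = NULL) {
  stop_if_not_scalar(loc_sigma, "loc_sigma", lower = 0)
  with_seed(seed, {
    idx <- rep(seq_len(nrow(intervals)),
               intervals$end_frame - intervals$start_frame + 1L)
    frames <- unlist(purrr::map2(intervals$start_frame, intervals$end_frame,
                                 seq.int))
    e <- match(intervals$emitter_id[idx], emitters$emitter_id)
    n <- length(idx)
    tibble(
      frame = as.integer(frames),
      x_nm = emitters$x_nm[e] + rnorm(n, 0, loc_sigma),
      y_nm = emitters$y_nm[e] + rnorm(n, 0, loc_sigma),
      photons = intervals$photon_rate[idx],
      background = 0,
      sigma_nm = 130,
      precision_nm = max(loc_sigma, 1e-6),
      is_fiducial = FALSE,
      emitter_id = intervals$emitter_id[idx]
    ) |>
      dplyr::arrange(.data$frame)
  })
}

#' Simulate state-switching Brownian trajectories
#'
#' Hidden diffusion states follow a discrete Markov chain (initial
#' distribution `pi0`, per-frame transition matrix `trans`); conditional on
#' the state, each per-axis displacement is Gaussian with variance
#' `2 * D[state] * dt`. Observed positions add isotropic Gaussian
#' localization noise.
#'
#' @param D Diffusion constants per state, um^2/s (length K).
#' @param trans K x K row-stochastic per-frame transition matrix.
#' @param pi0 Initial state distribution (default stationary-ish uniform).
#' @param n_tracks Number of trajectories.
#' @param mean_track_length Mean track length in frames (geometric, min 2).
#' @param dt Frame interval, seconds.
#' @param loc_noise_sigma Localization noise per axis, nm.
#' @param seed Optional integer seed.
#'
#' @return Tibble: `track_id`, `frame`, `x_nm`, `y_nm`, `state` (true state
#'   generating the step that starts at this row; `NA` on the last row of a
#'   track), `precision_nm`.
#' @export
sim_trajectories <- function(D, trans = diag(length(D)), pi0 = NULL,
                             n_tracks = 100, mean_track_length = 10,
                             dt = 0.05, loc_noise_sigma = 0, seed = NULL) {
  K <- length(D)
  if (any(D < 0)) abort("`D` must be non-negative.")
  trans <- as.matrix(trans)
  if (!all(dim(trans) == K) || any(trans < 0) ||
      any(abs(rowSums(trans) - 1) > 1e-8)) {
    abort("`trans` must be a K x K row-stochastic matrix.")
  }
  if (is.null(pi0)) pi0 <- rep(1 / K, K)
  if (length(pi0) != K || any(pi0 < 0) || abs(sum(pi0) - 1) > 1e-8) {
    abort("`pi0` must be a length-K distribution.")
  }
  stop_if_not_scalar(dt, "dt"); if (dt <= 0) abort("`dt` must be > 0.")
  stop_if_not_scalar(loc_noise_sigma, "loc_noise_sigma", lower = 0)

  step_sd_nm <- sqrt(2 * D * 1e6 * dt)  # per axis, nm
  with_seed(seed, {
    res <- vector("list", n_tracks)
    frame0 <- 1L
    for (tr in seq_len(n_tracks)) {
      len <- 2L
      if (mean_track_length > 2) {
        len <- 2L + stats::rgeom(1, 1 / (mean_track_length - 1))
      }
      s <- integer(len - 1L)
      s[1] <- sample.int(K, 1, prob = pi0)
      if (len > 2L) for (t in 2:(len - 1L)) {
        s[t] <- sample.int(K, 1, prob = trans[s[t - 1L], ])
      }
      x <- cumsum(c(0, rnorm(len - 1L, 0, step_sd_nm[s])))
      y <- cumsum(c(0, rnorm(len - 1L, 0, step_sd_nm[s])))
      if (loc_noise_sigma > 0) {
        x <- x + rnorm(len, 0, loc_noise_sigma)
        y <- y + rnorm(len, 0, loc_noise_sigma)
      }
      res[[tr]] <- tibble(track_id = tr, frame = frame0 + seq_len(len) - 1L,
                          x_nm = x, y_nm = y,
                          state = c(s, NA_integer_),
                          precision_nm = loc_noise_sigma)
      frame0 <- frame0 + len + 2L  # non-overlapping frame ranges
    }
    out <- dplyr::bind_rows(res)
    attr(out, "dt") <- dt
    attr(out, "D") <- D
    attr(out, "trans") <- trans
    out
  })
}
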