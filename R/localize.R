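# Frame-by-frame single-molecule localization: candidate detection, Poisson
# maximum-likelihood fitting of a pixel-integrated Gaussian + uniform
# background, Mortensen precision, filtering, and fiducial flagging.

#' Mortensen localization precision for MLE Gaussian fitting
#'
#' Closed-form lateral precision of the maximum-likelihood position estimate
#' for a pixel-integrated Gaussian PSF on a uniform Poisson background:
#' \deqn{\sigma_{loc}^2 = \frac{s_a^2}{N}\left(\frac{16}{9} +
#'   \frac{8\pi s_a^2 b}{N a^2}\right), \quad s_a^2 = s^2 + a^2/12}
#' with `N` detected photons, `b` background photons per pixel, PSF width
#' `s`, and pixel size `a`.
#'
#' @param N Photon count (> 0); vectorised.
#' @param b Background, photons/pixel/frame.
#' @param psf_sigma PSF standard deviation `s`, nm.
#' @param pixel_size Pixel size `a`, nm.
#' @return Precision in nm.
#' @export
estimate_precision <- function(N, b, psf_sigma = 130, pixel_size = 125) {
  if (any(!is.finite(N)) || any(N <= 0)) abort("`N` must be positive.")
  if (any(b < 0)) abort("`b` must be non-negative.")
  sa2 <- psf_sigma^2 + pixel_size^2 / 12
  sqrt(sa2 / N * (16 / 9 + 8 * pi * sa2 * b / (N * pixel_size^2)))
}

#' Background level that yields a target precision
#'
#' Numerically inverts [estimate_precision()] in `b` at fixed photon count,
#' PSF width and pixel size. The relation is linear in `b`, so the inversion
#' is exact.
#'
#' @param target_precision Desired precision, nm.
#' @inheritParams estimate_precision
#' @return Background in photons/pixel/frame (error if the target is below
#'   the background-free limit).
#' @export
invert_precision_background <- function(target_precision, N,
                                        psf_sigma = 130, pixel_size = 125) {
  stop_if_not_scalar(target_precision, "target_precision", lower = 0)
  sa2 <- psf_sigma^2 + pixel_size^2 / 12
  b <- (target_precision^2 * N / sa2 - 16 / 9) * N * pixel_size^2 /
    (8 * pi * sa2)
  if (b < 0) {
    abort("Target precision is unreachable: below the background-free limit.")
  }
  b
}

gaussian_blur <- function(img, sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-half:half, 0, sigma_px)
  k <- k / sum(k)
  pad <- function(m, n) {
    m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), , drop = FALSE]
  }
  conv_rows <- function(m) {
    p <- pad(m, half)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * p[(i - 1) + seq_len(nrow(m)), ]
    out
  }
  t(conv_rows(t(conv_rows(img))))
}

#' Detect candidate spots in one frame
#'
#' Smooths the frame with a Gaussian matched to the PSF, finds local maxima
#' exceeding the local background by `threshold` (camera units above the
#' image median), and suppresses candidates closer than one fit window to
#' each other (both are discarded: overlapping emitters are not fitted).
#'
#' @param img Numeric matrix (one frame, camera units).
#' @param threshold Peak height above the median of the smoothed image.
#' @param camera A [camera_model()] (for PSF width in pixels).
#' @param window Fit window edge in pixels (default 11).
#' @return Tibble of candidate pixel coordinates `row`, `col` (1-based).
#' @export
detect_candidates <- function(img, threshold, camera = camera_model(),
                              window = 11L) {
  if (any(!is.finite(img))) abort("`img` must be finite.")
  sm <- gaussian_blur(img, camera$psf_sigma / camera$pixel_size)
  bg <- median(sm)
  nr <- nrow(sm); nc <- ncol(sm)
  if (nr < 3 || nc < 3) return(tibble(row = integer(0), col = integer(0)))
  core <- sm[2:(nr - 1), 2:(nc - 1)]
  is_max <- core >= sm[1:(nr - 2), 2:(nc - 1)] &
    core >= sm[3:nr, 2:(nc - 1)] &
    core >= sm[2:(nr - 1), 1:(nc - 2)] &
    core >= sm[2:(nr - 1), 3:nc] &
    core >= sm[1:(nr - 2), 1:(nc - 2)] &
    core >= sm[1:(nr - 2), 3:nc] &
    core >= sm[3:nr, 1:(nc - 2)] &
    core >= sm[3:nr, 3:nc] &
    core - bg > threshold
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0) return(tibble(row = integer(0), col = integer(0)))
  rows <- hits[, 1] + 1L; cols <- hits[, 2] + 1L
  vals <- sm[cbind(rows, cols)]
  ord <- order(vals, decreasing = TRUE)
  rows <- rows[ord]; cols <- cols[ord]
  # discard *both* members of any pair within one window
  n <- length(rows)
  drop <- rep(FALSE, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (max(abs(rows[i] - rows[j]), abs(cols[i] - cols[j])) < window) {
        drop[i] <- TRUE; drop[j] <- TRUE
      }
    }
  }
  tibble(row = rows[!drop], col = cols[!drop]) |> dplyr::arrange(.data$row, .data$col)
}

# Negative Poisson log-likelihood of a pixel-integrated Gaussian + uniform
# background on a window. theta = (x, y, N, b, s) with x, y in nm relative to
# the window origin.
spot_nll <- function(theta, counts, a, fit_sigma, s_fixed) {
  x <- theta[1]; y <- theta[2]; N <- theta[3]; b <- theta[4]
  s <- if (fit_sigma) theta[5] else s_fixed
  nr <- nrow(counts); nc <- ncol(counts)
  fx <- diff(stats::pnorm(a * (0:nc), x, s))
  fy <- diff(stats::pnorm(a * (0:nr), y, s))
  mu <- N * outer(fy, fx) + b
  mu <- pmax(mu, 1e-12)
  sum(mu - counts * log(mu))
}

#' Fit one spot by Poisson maximum likelihood
#'
#' Fits a pixel-integrated 2D Gaussian plus uniform background to a window
#' of photon counts, maximising the Poisson likelihood (L-BFGS-B). Returns
#' the sub-pixel position in nm (window coordinates), photon count,
#' background, fitted PSF width, and the Mortensen precision.
#'
#' @param counts Numeric matrix of photon counts (camera units already
#'   converted: `(DN - offset) / gain`).
#' @param camera A [camera_model()].
#' @param init Optional list with starting values `x`, `y` (nm), `N`, `b`.
#' @param fit_sigma Fit the PSF width (default) or hold it at
#'   `camera$psf_sigma`.
#' @return One-row tibble: `x_nm`, `y_nm`, `photons`, `background`,
#'   `sigma_nm`, `precision_nm`, `converged`.
#' @export
fit_spot <- function(counts, camera = camera_model(), init = NULL,
                     fit_sigma = TRUE) {
  a <- camera$pixel_size
  nr <- nrow(counts); nc <- ncol(counts)
  if (is.null(init)) {
    b0 <- max(median(counts[c(1, nr), ]), 1e-3)
    tot <- sum(counts) - b0 * length(counts)
    N0 <- max(tot, 10)
    w <- pmax(counts - b0, 0)
    if (sum(w) <= 0) w <- counts
    xg <- (seq_len(nc) - 0.5) * a
    yg <- (seq_len(nr) - 0.5) * a
    init <- list(x = sum(colSums(w) * xg) / sum(w),
                 y = sum(rowSums(w) * yg) / sum(w),
                 N = N0, b = b0)
  }
  theta0 <- c(init$x, init$y, init$N, init$b)
  lower <- c(0, 0, 1, 0)
  upper <- c(nc * a, nr * a, Inf, Inf)
  if (fit_sigma) {
    theta0 <- c(theta0, camera$psf_sigma)
    lower <- c(lower, 0.3 * camera$psf_sigma)
    upper <- c(upper, 3 * camera$psf_sigma)
  }
  fit <- tryCatch(
    optim(theta0, spot_nll, counts = counts, a = a, fit_sigma = fit_sigma,
          s_fixed = camera$psf_sigma, method = "L-BFGS-B",
          lower = lower, upper = upper,
          control = list(maxit = 200, factr = 1e7)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble(x_nm = NA_real_, y_nm = NA_real_, photons = NA_real_,
                  background = NA_real_, sigma_nm = NA_real_,
                  precision_nm = NA_real_, converged = FALSE))
  }
  th <- fit$par
  s_hat <- if (fit_sigma) th[5] else camera$psf_sigma
  tibble(
    x_nm = th[1], y_nm = th[2], photons = th[3], background = th[4],
    sigma_nm = s_hat,
    precision_nm = estimate_precision(max(th[3], 1), max(th[4], 0),
                                      s_hat, a),
    converged = fit$convergence == 0
  )
}

#' Localize an entire frame stack
#'
#' Runs [detect_candidates()] and [fit_spot()] on every frame of a rendered
#' or loaded stack and assembles the localization table. Non-converged fits
#' are dropped; fiducials are flagged afterwards with [flag_fiducials()].
#'
#' @param stack A `palm_stack` (see [render_frames()]) or list of matrices.
#' @param camera A [camera_model()]; taken from the stack when available.
#' @param threshold Detection threshold (see [detect_candidates()]).
#' @param window Fit window edge, pixels (odd, default 11).
#' @param fit_sigma Passed to [fit_spot()].
#' @return Localization tibble: `frame`, `x_nm`, `y_nm`, `photons`,
#'   `background`, `sigma_nm`, `precision_nm`, `is_fiducial`.
#' @export
localize_stack <- function(stack, camera = NULL, threshold = 30,
                           window = 11L, fit_sigma = TRUE) {
  frames <- if (inherits(stack, "palm_stack")) stack$frames else stack
  camera <- camera %||%
    (if (inherits(stack, "palm_stack")) stack$camera else camera_model())
  half <- (window - 1L) %/% 2L
  a <- camera$pixel_size
  out <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    img <- frames[[f]]
    photons <- (img - camera$offset) / camera$gain
    cand <- detect_candidates(img, threshold, camera, window)
    if (nrow(cand) == 0) next
    fits <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      r0 <- cand$row[i] - half; r1 <- cand$row[i] + half
      c0 <- cand$col[i] - half; c1 <- cand$col[i] + half
      if (r0 < 1 || c0 < 1 || r1 > nrow(img) || c1 > ncol(img)) next
      win <- photons[r0:r1, c0:c1]
      fit <- fit_spot(win, camera, fit_sigma = fit_sigma)
      # window coordinates -> image coordinates (nm)
      fit$x_nm <- fit$x_nm + (c0 - 1) * a
      fit$y_nm <- fit$y_nm + (r0 - 1) * a
      fits[[i]] <- fit
    }
    fits <- dplyr::bind_rows(fits)
    if (nrow(fits) == 0) next
    fits <- dplyr::filter(fits, .data$converged, !is.na(.data$x_nm))
    if (nrow(fits) == 0) next
    out[[f]] <- dplyr::mutate(fits, frame = f, .before = 1)
  }
  locs <- dplyr::bind_rows(out)
  if (nrow(locs) == 0) {
    return(tibble(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                  photons = numeric(0), background = numeric(0),
                  sigma_nm = numeric(0), precision_nm = numeric(0),
                  is_fiducial = logical(0)))
  }
  locs <- dplyr::select(locs, "frame", "x_nm", "y_nm", "photons",
                        "background", "sigma_nm", "precision_nm")
  locs$is_fiducial <- FALSE
  flag_fiducials(locs, n_frames = length(frames), pixel_size = a)
}

#' Flag fiducial markers in a localization table
#'
#' A localization cluster persisting within a one-pixel radius in more than
#' `min_fraction` of all frames is flagged as a fiducial (stationary bright
#' marker used for drift correction).
#'
#' @param locs Localization tibble.
#' @param n_frames Total number of frames in the movie.
#' @param pixel_size nm per pixel (grouping radius).
#' @param min_fraction Persistence threshold (default 0.9).
#' @return `locs` with `is_fiducial` updated.
#' @export
flag_fiducials <- function(locs, n_frames, pixel_size = 125,
                           min_fraction = 0.9) {
  if (nrow(locs) == 0) return(locs)
  comp <- spatial_components(locs$x_nm, locs$y_nm, pixel_size)
  persist <- tapply(locs$frame, comp, function(f) length(unique(f)))
  fid_comp <- as.integer(names(persist)[persist > min_fraction * n_frames])
  locs$is_fiducial <- comp %in% fid_comp
  locs
}

#' Filter localizations on quality criteria
#'
#' @param locs Localization tibble.
#' @param min_photons Minimum photon count.
#' @param max_sigma Maximum fitted PSF width, nm (`Inf` to disable).
#' @param max_precision Maximum localization precision, nm (`Inf` to
#'   disable).
#' @return The surviving rows, in the original order; the counts removed by
#'   each criterion are attached as attribute `filter_log`.
#' @export
filter_localizations <- function(locs, min_photons = 0, max_sigma = Inf,
                                 max_precision = Inf) {
  stop_if_not_scalar(min_photons, "min_photons", lower = 0)
  if (max_sigma < 0 || max_precision < 0) abort("Thresholds must be >= 0.")
  keep_n <- locs$photons >= min_photons
  keep_s <- locs$sigma_nm <= max_sigma
  keep_p <- locs$precision_nm <= max_precision
  keep <- keep_n & keep_s & keep_p
  out <- locs[keep, , drop = FALSE]
  attr(out, "filter_log") <- c(low_photons = sum(!keep_n),
                               wide_sigma = sum(!keep_s),
                               poor_precision = sum(!keep_p),
                               kept = sum(keep))
  out
}
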