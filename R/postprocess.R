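# Post-processing of localization tables: fiducial drift correction,
# grouping of blink events into molecules, dark-state lifetime estimation
# from the molecule-count vs allowed-dark-period curve, and image rendering.

#' Correct stage drift using fiducial markers
#'
#' Per-frame drift is the mean displacement of all fiducials from their
#' first-frame positions, smoothed with a centred moving average, and is
#' subtracted from every localization. Fiducial rows are retained (still
#' flagged) so downstream stages can drop them explicitly.
#'
#' @param locs Localization tibble with `is_fiducial` set (see
#'   [flag_fiducials()]).
#' @param smoothing_window Moving-average window in frames (default 10).
#' @return `locs` with corrected coordinates; the per-frame drift trace is
#'   attached as attribute `drift` (tibble `frame`, `dx_nm`, `dy_nm`).
#' @export
correct_drift <- function(locs, smoothing_window = 10) {
  fid <- dplyr::filter(locs, .data$is_fiducial)
  if (nrow(fid) == 0) {
    abort(paste("No fiducial localizations present; skip drift correction",
                "or flag fiducials first."))
  }
  frames <- seq(min(locs$frame), max(locs$frame))
  comp <- spatial_components(fid$x_nm, fid$y_nm, 250)
  fid$fid_id <- comp
  ref <- fid |>
    dplyr::group_by(.data$fid_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(dx = .data$x_nm - dplyr::first(.data$x_nm),
                  dy = .data$y_nm - dplyr::first(.data$y_nm)) |>
    dplyr::ungroup()
  per_frame <- ref |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(dx = mean(.data$dx), dy = mean(.data$dy))
  # fill missing frames by interpolation, then smooth
  dx <- approx(per_frame$frame, per_frame$dx, xout = frames, rule = 2)$y
  dy <- approx(per_frame$frame, per_frame$dy, xout = frames, rule = 2)$y
  sm <- function(v) {
    as.numeric(stats::filter(v, rep(1 / smoothing_window, smoothing_window),
                             sides = 2)) |>
      (\(s) ifelse(is.na(s), v, s))()
  }
  drift <- tibble(frame = frames, dx_nm = sm(dx), dy_nm = sm(dy))
  idx <- match(locs$frame, drift$frame)
  out <- locs
  out$x_nm <- locs$x_nm - drift$dx_nm[idx]
  out$y_nm <- locs$y_nm - drift$dy_nm[idx]
  attr(out, "drift") <- drift
  out
}

# Greedy grouping core on one spatial component, frame order, ties by
# distance to the running (precision-weighted) mean position.
group_component <- function(frame, x, y, w, max_gap_frames, r_group) {
  n <- length(frame)
  assign <- integer(n)
  # open molecules: running weighted sums, last frame
  mx <- numeric(0); my <- numeric(0); mw <- numeric(0)
  last <- integer(0); nloc <- integer(0); nev <- integer(0)
  first <- integer(0)
  ord <- order(frame, x, y)
  for (ii in ord) {
    best <- 0L; bestd <- Inf
    if (length(last)) {
      gap <- frame[ii] - last - 1L
      open <- which(gap >= 0L & gap <= max_gap_frames)
      if (length(open)) {
        d <- sqrt((mx[open] / mw[open] - x[ii])^2 +
                    (my[open] / mw[open] - y[ii])^2)
        k <- which.min(d)
        if (d[k] <= r_group) { best <- open[k]; bestd <- d[k] }
      }
    }
    if (best == 0L) {
      mx <- c(mx, w[ii] * x[ii]); my <- c(my, w[ii] * y[ii]); mw <- c(mw, w[ii])
      last <- c(last, frame[ii]); first <- c(first, frame[ii])
      nloc <- c(nloc, 1L); nev <- c(nev, 1L)
      assign[ii] <- length(last)
    } else {
      if (frame[ii] - last[best] > 1L) nev[best] <- nev[best] + 1L
      mx[best] <- mx[best] + w[ii] * x[ii]
      my[best] <- my[best] + w[ii] * y[ii]
      mw[best] <- mw[best] + w[ii]
      last[best] <- frame[ii]
      nloc[best] <- nloc[best] + 1L
      assign[ii] <- best
    }
  }
  list(assign = assign, x = mx / mw, y = my / mw,
       first = first, last = last, n_locs = nloc, n_events = nev)
}

#' Group blink events into molecules
#'
#' Greedy temporal grouping of (drift-corrected) localizations: in frame
#' order, a localization joins an open molecule when it lies within
#' `r_group` of the molecule's running precision-weighted mean position and
#' the dark time since the molecule's last localization is at most `t_d`
#' seconds; otherwise it seeds a new molecule. Each localization is assigned
#' exactly once; ties go to the nearest molecule. With `t_d = 0` only
#' consecutive-frame localizations merge.
#'
#' @param locs Drift-corrected localization tibble (fiducials are excluded
#'   automatically when `is_fiducial` is present).
#' @param t_d Maximum allowed dark period, seconds (>= 0).
#' @param r_group Grouping radius, nm; default `"auto"` = 3x the median
#'   localization precision.
#' @param frame_time Frame time, seconds.
#' @return Molecule tibble: `mol_id`, `x_nm`, `y_nm` (precision-weighted
#'   means), `first_frame`, `last_frame`, `n_locs`, `n_events`,
#'   `total_photons`.
#' @export
group_blinks <- function(locs, t_d = 0.26, r_group = "auto",
                         frame_time = 0.05) {
  if (!is.numeric(t_d) || length(t_d) != 1 || is.na(t_d) || t_d < 0) {
    abort("`t_d` must be a single number >= 0.")
  }
  if ("is_fiducial" %in% names(locs)) {
    locs <- dplyr::filter(locs, !.data$is_fiducial)
  }
  if (nrow(locs) == 0) {
    return(tibble(mol_id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                  first_frame = integer(0), last_frame = integer(0),
                  n_locs = integer(0), n_events = integer(0),
                  total_photons = numeric(0)))
  }
  if (identical(r_group, "auto")) {
    r_group <- 3 * median(locs$precision_nm)
  }
  stop_if_not_scalar(r_group, "r_group", lower = 0)
  max_gap <- floor(t_d / frame_time + 1e-9)

  prec <- locs$precision_nm
  w <- 1 / pmax(prec, 1e-6)^2
  # exact decomposition: points in different components > r_group apart can
  # never share a molecule, so each component is grouped independently
  comp <- spatial_components(locs$x_nm, locs$y_nm, r_group + 1e-9)
  res <- vector("list", max(comp))
  offset <- 0L
  phot <- locs$photons %||% rep(0, nrow(locs))
  for (k in seq_len(max(comp))) {
    idx <- which(comp == k)
    g <- group_component(locs$frame[idx], locs$x_nm[idx], locs$y_nm[idx],
                         w[idx], max_gap, r_group)
    tp <- tapply(phot[idx], g$assign, sum)
    res[[k]] <- tibble(
      mol_id = offset + seq_along(g$x),
      x_nm = g$x, y_nm = g$y,
      first_frame = as.integer(g$first), last_frame = as.integer(g$last),
      n_locs = g$n_locs, n_events = g$n_events,
      total_photons = as.numeric(tp[as.character(seq_along(g$x))])
    )
    offset <- offset + length(g$x)
  }
  dplyr::bind_rows(res)
}

#' Estimate the dark-state lifetime from the molecule-count curve
#'
#' Computes the number of molecules `N(T_d)` obtained from [group_blinks()]
#' at each allowed dark period on `td_grid`, then fits
#' `N(T_d)/N(0) = A * exp(-T_d / T_off) + C` to the first `n_fit_points`
#' grid points by nonlinear least squares. The initial sharp decay of the
#' curve reflects reconnection of true blinks (rate `1/T_off`); the additive
#' offset `C` absorbs the persistent-molecule plateau.
#'
#' @param locs Drift-corrected localization tibble.
#' @param td_grid Ascending grid of allowed dark periods, seconds (default
#'   0 to 1.05 s in 0.15 s steps).
#' @param n_fit_points Number of leading grid points used in the fit
#'   (default 7).
#' @param r_group,frame_time Passed to [group_blinks()].
#' @return A `palm_toff` object: list with `t_off` (s), `ci` (standard
#'   error), `curve` (tibble `t_d`, `n_molecules`, `fraction`), `fit_r`
#'   (correlation of fitted vs observed on the fitted points), `n_fit_points`,
#'   and the fitted `A`, `C`. Supports [tidy()], [glance()], [autoplot()].
#' @export
estimate_toff <- function(locs, td_grid = seq(0, 1.05, by = 0.15),
                          n_fit_points = 7, r_group = "auto",
                          frame_time = 0.05) {
  if (is.unsorted(td_grid, strictly = TRUE)) {
    abort("`td_grid` must be strictly ascending.")
  }
  if (length(td_grid) < n_fit_points) {
    abort("`td_grid` must have at least `n_fit_points` entries.")
  }
  if (identical(r_group, "auto")) {
    r_group <- 3 * median(locs$precision_nm)
  }
  n_td <- vapply(td_grid, function(td) {
    nrow(group_blinks(locs, t_d = td, r_group = r_group,
                      frame_time = frame_time))
  }, numeric(1))
  curve <- tibble(t_d = td_grid, n_molecules = n_td,
                  fraction = n_td / n_td[1])
  fit_pts <- curve[seq_len(n_fit_points), ]
  if (diff(range(fit_pts$fraction)) < 0.02) {
    abort(paste("Molecule count does not vary with T_d (no blinking",
                "detected); the exponential fit is degenerate."))
  }
  start <- list(A = max(fit_pts$fraction) - min(fit_pts$fraction),
                t_off = max(td_grid[2], 0.2),
                C = min(fit_pts$fraction))
  fit <- tryCatch(
    minpack.lm::nlsLM(fraction ~ A * exp(-t_d / t_off) + C,
                      data = fit_pts, start = start,
                      lower = c(0, 1e-4, 0), upper = c(2, 10, 1.5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(sprintf("Exponential fit failed: %s", conditionMessage(e)),
            body = c(i = "The N(T_d) curve is attached to the error."),
            curve = curve)
    }
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit)))[["t_off"]], error = function(e) NA_real_)
  structure(
    list(t_off = unname(est[["t_off"]]), ci = se,
         A = unname(est[["A"]]), C = unname(est[["C"]]),
         curve = curve,
         fit_r = cor(stats::fitted(fit), fit_pts$fraction),
         n_fit_points = n_fit_points, fit = fit),
    class = "palm_toff"
  )
}

#' @export
print.palm_toff <- function(x, ...) {
  cat(sprintf(
    "<palm_toff> T_off = %.3f s (se %.3f); fit R = %.4f on %d points\n",
    x$t_off, x$ci, x$fit_r, x$n_fit_points))
  invisible(x)
}

#' Render a PALM image from molecule positions
#'
#' @param molecules Molecule tibble (from [group_blinks()]) or any tibble
#'   with `x_nm`, `y_nm` (and `precision_nm` for gaussian mode; molecule
#'   tables use the precision-weighted mean position, width defaults to
#'   `default_sigma`).
#' @param out_pixel Output pixel size, nm.
#' @param mode `"histogram"` (counts per bin) or `"gaussian"` (each molecule
#'   a unit-integral Gaussian of width = its precision).
#' @param roi Optional `c(xmin, xmax, ymin, ymax)` nm; defaults to the data
#'   bounding box padded by 3 `default_sigma`.
#' @param default_sigma Rendering width when no per-molecule precision is
#'   available, nm (default 18).
#' @return Numeric matrix (rows = y); pixel size and ROI as attributes.
#' @export
render_palm <- function(molecules, out_pixel = 10,
                        mode = c("histogram", "gaussian"), roi = NULL,
                        default_sigma = 18) {
  mode <- match.arg(mode)
  stop_if_not_scalar(out_pixel, "out_pixel")
  if (out_pixel <= 0) abort("`out_pixel` must be > 0.")
  x <- molecules$x_nm; y <- molecules$y_nm
  if (is.null(roi)) {
    pad <- 3 * default_sigma
    roi <- c(min(x) - pad, max(x) + pad, min(y) - pad, max(y) + pad)
  }
  nc <- max(1L, ceiling((roi[2] - roi[1]) / out_pixel))
  nr <- max(1L, ceiling((roi[4] - roi[3]) / out_pixel))
  img <- matrix(0, nr, nc)
  if (mode == "histogram") {
    cx <- pmin(pmax(floor((x - roi[1]) / out_pixel) + 1L, 1L), nc)
    cy <- pmin(pmax(floor((y - roi[3]) / out_pixel) + 1L, 1L), nr)
    for (i in seq_along(cx)) img[cy[i], cx[i]] <- img[cy[i], cx[i]] + 1
  } else {
    sig <- if ("precision_nm" %in% names(molecules)) {
      molecules$precision_nm
    } else {
      rep(default_sigma, length(x))
    }
    sig <- pmax(sig, out_pixel / 4)
    for (i in seq_along(x)) {
      fx <- diff(stats::pnorm(roi[1] + out_pixel * (0:nc), x[i], sig[i]))
      fy <- diff(stats::pnorm(roi[3] + out_pixel * (0:nr), y[i], sig[i]))
      img <- img + outer(fy, fx)
    }
  }
  attr(img, "pixel_nm") <- out_pixel
  attr(img, "roi") <- roi
  img
}
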