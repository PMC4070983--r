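# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' Tidy a dark-state lifetime fit
#'
#' @param x A `palm_toff` from [estimate_toff()].
#' @param ... Unused.
#' @return The molecule-count curve as a tibble (`t_d`, `n_molecules`,
#'   `fraction`, `fitted`).
#' @exportS3Method generics::tidy
tidy.palm_toff <- function(x, ...) {
  fitted <- x$A * exp(-x$curve$t_d / x$t_off) + x$C
  dplyr::mutate(x$curve, fitted = fitted)
}

#' @rdname tidy.palm_toff
#' @return For `glance()`: a one-row tibble with `t_off`, `se`, `fit_r`,
#'   `n_fit_points`.
#' @exportS3Method generics::glance
glance.palm_toff <- function(x, ...) {
  tibble(t_off = x$t_off, se = x$ci, fit_r = x$fit_r,
         n_fit_points = x$n_fit_points)
}

#' @rdname tidy.palm_toff
#' @param object A `palm_toff`.
#' @exportS3Method ggplot2::autoplot
autoplot.palm_toff <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_d)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$fraction)) +
    ggplot2::geom_line(
      data = d[seq_len(object$n_fit_points), ],
      ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = expression(T[d] ~ "(s)"),
                  y = "N(T_d) / N(0)",
                  title = sprintf("T_off = %.2f s", object$t_off)) +
    ggplot2::theme_minimal()
}

#' Tidy a Ripley's K result
#'
#' @param x A `palm_ripley` from [ripley_k()].
#' @param ... Unused.
#' @return Tibble `r`, `K`, `L`, `H` (+ `lo`, `hi` when an envelope is
#'   attached).
#' @exportS3Method generics::tidy
tidy.palm_ripley <- function(x, ...) {
  out <- x$curve
  if (!is.null(x$envelope)) {
    out <- dplyr::left_join(out, x$envelope, by = "r")
  }
  out
}

#' @rdname tidy.palm_ripley
#' @param object A `palm_ripley`.
#' @exportS3Method ggplot2::autoplot
autoplot.palm_ripley <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$r))
  if (!is.null(object$envelope)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "grey80", alpha = 0.7)
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$H)) +
    ggplot2::labs(x = "r (nm)", y = "H(r) = L(r) - r") +
    ggplot2::theme_minimal()
}

#' Tidy a cluster report
#'
#' @param x A `palm_clusters` from [dbscan_clusters()].
#' @param ... Unused.
#' @return The occupancy histogram tibble (`size`, `n_clusters`).
#' @exportS3Method generics::tidy
tidy.palm_clusters <- function(x, ...) x$occupancy

#' @rdname tidy.palm_clusters
#' @exportS3Method generics::glance
glance.palm_clusters <- function(x, ...) {
  tibble(n_clusters = x$n_clusters, mean_occupancy = x$mean_occupancy,
         clustered_fraction = x$clustered_fraction, eps = x$eps,
         min_pts = x$min_pts)
}

#' @rdname tidy.palm_clusters
#' @param object A `palm_clusters`.
#' @exportS3Method ggplot2::autoplot
autoplot.palm_clusters <- function(object, ...) {
  ggplot2::ggplot(object$occupancy,
                  ggplot2::aes(x = factor(.data$size), y = .data$n_clusters)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Molecules per cluster", y = "Clusters") +
    ggplot2::theme_minimal()
}

#' Tidy a diffusion-state HMM
#'
#' @param x A `palm_hmm` from [fit_hmm()] or [select_model()].
#' @param ... Unused.
#' @return One row per state: `state`, `D`, `occupancy`, `self_transition`.
#' @exportS3Method generics::tidy
tidy.palm_hmm <- function(x, ...) {
  tibble(state = seq_len(x$K), D = x$D, occupancy = x$occupancy,
         self_transition = diag(x$trans))
}

#' @rdname tidy.palm_hmm
#' @exportS3Method generics::glance
glance.palm_hmm <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik, bic = x$bic, n_steps = x$n_steps,
         dt = x$dt)
}

#' @rdname tidy.palm_hmm
#' @param object A `palm_hmm`.
#' @exportS3Method ggplot2::autoplot
autoplot.palm_hmm <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$state),
                                  y = .data$occupancy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("D = %.3g", .data$D)), vjust = -0.4, size = 3) +
    ggplot2::labs(x = "Diffusion state (ascending D, um²/s)",
                  y = "Occupancy") +
    ggplot2::theme_minimal()
}

#' Plot trajectories coloured by track
#'
#' @param trajs Trajectory tibble.
#' @param max_tracks Subsample for readability (default 200).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajs, max_tracks = 200) {
  ids <- unique(trajs$track_id)
  if (length(ids) > max_tracks) {
    trajs <- dplyr::filter(trajs, .data$track_id %in% ids[seq_len(max_tracks)])
  }
  ggplot2::ggplot(trajs, ggplot2::aes(.data$x_nm, .data$y_nm,
                                      group = .data$track_id,
                                      colour = factor(.data$track_id))) +
    ggplot2::geom_path(show.legend = FALSE, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a displacement histogram
#'
#' @param hist Tibble from [displacement_histogram()].
#' @return A ggplot object.
#' @export
plot_displacement_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$mid_nm, y = .data$count)) +
    ggplot2::geom_col(width = hist$bin_hi[1] - hist$bin_lo[1],
                      fill = "steelblue") +
    ggplot2::labs(x = "Displacement per frame (nm)", y = "Steps") +
    ggplot2::theme_minimal()
}

#' Display a rendered PALM image
#'
#' @param img Matrix from [render_palm()].
#' @param trans Intensity transform (default `sqrt` for dynamic range).
#' @return A ggplot object.
#' @export
plot_palm_image <- function(img, trans = sqrt) {
  px <- attr(img, "pixel_nm") %||% 1
  d <- expand.grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  d$v <- trans(as.vector(img))
  ggplot2::ggplot(d, ggplot2::aes(.data$x * px, .data$y * px,
                                  fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_void()
}
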