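# Frame-to-frame trajectory linking with a hard displacement gate, pooled
# displacement statistics, and MSD-based diffusion-constant estimation.

# O(n^3) Hungarian algorithm (Jonker-Volgenant style potentials with
# augmenting paths) for an n x m cost matrix, n <= m; returns for each row
# its assigned column.
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    while (j0 != 0L) {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assignment[p[j + 1]] <- j
  assignment
}

# Optimal gated matching between two point sets: minimises total linked
# displacement; any pairing farther than max_disp is forbidden, and leaving
# a point unmatched costs max_disp (so a feasible link is always preferred
# over leaving both ends unmatched). Returns an integer vector over set 1
# (0 = unmatched).
match_frames <- function(x1, y1, x2, y2, max_disp) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 == 0 || n2 == 0) return(integer(n1))
  BIG <- 1e9
  d <- sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
  sz <- n1 + n2
  cost <- matrix(BIG, sz, sz)
  cost[seq_len(n1), seq_len(n2)] <- ifelse(d <= max_disp, d, BIG)
  for (i in seq_len(n1)) cost[i, n2 + i] <- max_disp
  for (j in seq_len(n2)) cost[n1 + j, j] <- max_disp
  cost[(n1 + 1):sz, (n2 + 1):sz] <- 0
  asg <- hungarian(cost)
  out <- integer(n1)
  for (i in seq_len(n1)) {
    j <- asg[i]
    if (j <= n2 && d[i, j] <= max_disp) out[i] <- j
  }
  out
}

# Greedy gated nearest-neighbour matching (alternative to optimal).
match_frames_greedy <- function(x1, y1, x2, y2, max_disp) {
  n1 <- length(x1); n2 <- length(x2)
  out <- integer(n1)
  if (n1 == 0 || n2 == 0) return(out)
  d <- sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
  d[d > max_disp] <- Inf
  while (any(is.finite(d))) {
    k <- arrayInd(which.min(d), dim(d))
    out[k[1]] <- k[2]
    d[k[1], ] <- Inf
    d[, k[2]] <- Inf
  }
  out
}

#' Linking configuration for single-molecule tracking
#'
#' @param max_disp Hard gate on the distance a molecule may travel between
#'   consecutive frames, nm (default 500 = 4 pixels at 125 nm/px).
#' @param dt Frame interval, seconds (default 0.05).
#' @param method `"optimal"` (minimum-total-displacement bipartite matching)
#'   or `"greedy"` (nearest neighbour first).
#' @return A `palm_linking` list; `max_D` is the diffusion constant whose
#'   mean-squared frame displacement equals the gate,
#'   `max_disp^2 / (4 dt)` in um^2/s.
#' @export
linking_config <- function(max_disp = 500, dt = 0.05,
                           method = c("optimal", "greedy")) {
  stop_if_not_scalar(max_disp, "max_disp"); if (max_disp <= 0) abort("`max_disp` must be > 0.")
  stop_if_not_scalar(dt, "dt"); if (dt <= 0) abort("`dt` must be > 0.")
  structure(
    list(max_disp = max_disp, dt = dt, allow_gaps = FALSE,
         max_D = (max_disp / NM_PER_UM)^2 / (4 * dt),
         method = match.arg(method)),
    class = "palm_linking"
  )
}

#' Link localizations into diffusion trajectories
#'
#' For every pair of consecutive frames, matches localizations by minimum
#' total displacement (optimal bipartite assignment) subject to the hard
#' per-frame gate `max_disp`; unmatched localizations start or terminate
#' tracks. There is no gap closing: a molecule absent for one frame ends its
#' track. Tracks spanning fewer than two frames are discarded.
#'
#' @param locs Localization tibble (drift-corrected, fiducials removed;
#'   rows with `is_fiducial = TRUE` are dropped if the column is present).
#' @param config A [linking_config()].
#' @return Trajectory tibble: `track_id`, `frame`, `x_nm`, `y_nm`,
#'   `precision_nm`; attribute `dt`.
#' @export
link_trajectories <- function(locs, config = linking_config()) {
  stopifnot(inherits(config, "palm_linking"))
  if ("is_fiducial" %in% names(locs)) {
    locs <- dplyr::filter(locs, !.data$is_fiducial)
  }
  if (nrow(locs) == 0) {
    return(tibble(track_id = integer(0), frame = integer(0),
                  x_nm = numeric(0), y_nm = numeric(0),
                  precision_nm = numeric(0)))
  }
  if (!"precision_nm" %in% names(locs)) locs$precision_nm <- NA_real_
  locs <- dplyr::arrange(locs, .data$frame)
  frames <- sort(unique(locs$frame))
  by_frame <- split(seq_len(nrow(locs)), locs$frame)
  track_of <- integer(nrow(locs))
  next_id <- 0L
  # seed tracks in the first frame
  for (i in by_frame[[1]]) { next_id <- next_id + 1L; track_of[i] <- next_id }
  matcher <- if (config$method == "optimal") match_frames else match_frames_greedy
  for (k in seq_along(frames)[-1]) {
    prev <- by_frame[[k - 1]]
    cur <- by_frame[[k]]
    consecutive <- frames[k] == frames[k - 1] + 1L
    if (consecutive) {
      m <- matcher(locs$x_nm[prev], locs$y_nm[prev],
                   locs$x_nm[cur], locs$y_nm[cur], config$max_disp)
      for (i in seq_along(prev)) {
        if (m[i] > 0L) track_of[cur[m[i]]] <- track_of[prev[i]]
      }
    }
    for (i in cur) {
      if (track_of[i] == 0L) { next_id <- next_id + 1L; track_of[i] <- next_id }
    }
  }
  out <- tibble(track_id = track_of, frame = locs$frame,
                x_nm = locs$x_nm, y_nm = locs$y_nm,
                precision_nm = locs$precision_nm) |>
    dplyr::add_count(.data$track_id) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::select(-"n") |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::mutate(track_id = match(.data$track_id, unique(.data$track_id)))
  # hard invariant: no link exceeds the gate
  steps <- track_steps(out)
  if (any(steps$disp_nm > config$max_disp + 1e-9)) {
    abort("Internal error: a link exceeds `max_disp`.")
  }
  attr(out, "dt") <- config$dt
  out
}

#' Per-step displacements of a trajectory table
#'
#' @param trajs Trajectory tibble (`track_id`, `frame`, `x_nm`, `y_nm`).
#' @return Tibble with one row per step: `track_id`, `frame` (of the step's
#'   start), `dx_nm`, `dy_nm`, `disp_nm`.
#' @export
track_steps <- function(trajs) {
  trajs |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(dx_nm = dplyr::lead(.data$x_nm) - .data$x_nm,
                  dy_nm = dplyr::lead(.data$y_nm) - .data$y_nm) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$dx_nm)) |>
    dplyr::mutate(disp_nm = sqrt(.data$dx_nm^2 + .data$dy_nm^2)) |>
    dplyr::select("track_id", "frame", "dx_nm", "dy_nm", "disp_nm")
}

#' Histogram of per-frame displacement magnitudes
#'
#' Pools every per-step displacement over all trajectories; the total count
#' equals the total number of steps, `sum(length - 1)`.
#'
#' @param trajs Trajectory tibble.
#' @param bin_width Bin width, nm.
#' @return Tibble `bin_lo`, `bin_hi`, `mid_nm`, `count`.
#' @export
displacement_histogram <- function(trajs, bin_width = 25) {
  if (nrow(trajs) == 0) abort("Need at least one trajectory.")
  disp <- track_steps(trajs)$disp_nm
  edges <- seq(0, max(disp) + bin_width, by = bin_width)
  cnt <- graphics::hist(disp, breaks = edges, plot = FALSE)$counts
  tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
         mid_nm = (edges[-length(edges)] + edges[-1]) / 2, count = cnt)
}

#' Diffusion constant from the mean squared displacement
#'
#' Pools squared displacements at lags 1..`max_lag` over all trajectories
#' long enough to contribute, fits `MSD(tau) = 4 D tau dt + c` by least
#' squares, and returns `D = slope / 4` with the intercept (which absorbs
#' the static localization-noise floor `4 sigma_loc^2`).
#'
#' @param trajs Trajectory tibble.
#' @param max_lag Maximum lag in frames (default 4).
#' @param dt Frame interval, s; defaults to the table's `dt` attribute.
#' @return List: `D` (um^2/s), `intercept_nm2`, `msd` (tibble `lag`,
#'   `tau_s`, `msd_nm2`, `n`).
#' @export
estimate_D_msd <- function(trajs, max_lag = 4, dt = NULL) {
  dt <- dt %||% attr(trajs, "dt") %||% 0.05
  tr <- split(trajs[c("frame", "x_nm", "y_nm")],
              trajs$track_id)
  rows <- list()
  for (lag in seq_len(max_lag)) {
    sq <- unlist(lapply(tr, function(t) {
      n <- nrow(t)
      if (n < lag + 1) return(numeric(0))
      (t$x_nm[(1 + lag):n] - t$x_nm[1:(n - lag)])^2 +
        (t$y_nm[(1 + lag):n] - t$y_nm[1:(n - lag)])^2
    }))
    rows[[lag]] <- tibble(lag = lag, tau_s = lag * dt,
                          msd_nm2 = mean(sq), n = length(sq))
  }
  msd <- dplyr::bind_rows(rows)
  if (any(msd$n == 0) || nrow(msd) < 2) {
    abort("Trajectories too short for the requested `max_lag`.")
  }
  fit <- stats::lm(msd_nm2 ~ tau_s, data = msd, weights = msd$n)
  slope_nm2_per_s <- coef(fit)[["tau_s"]]
  list(D = slope_nm2_per_s / 4 * UM2_PER_NM2,
       intercept_nm2 = coef(fit)[["(Intercept)"]],
       msd = msd)
}
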