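# Hidden-Markov diffusion-state inference from per-step displacement
# magnitudes: Rayleigh emissions, Baum-Welch EM with multiple seeded
# restarts, BIC model-size selection, and Viterbi state summaries.

#' Rayleigh log-density of a 2D Brownian step magnitude
#'
#' For a molecule diffusing with constant `D` over a frame interval `dt`,
#' observed with static localization noise `loc_sigma` per axis, each
#' displacement component is Gaussian with variance
#' `v = 2 D dt + 2 loc_sigma^2` (nm^2), so the step magnitude `r` is
#' Rayleigh: `log p(r) = log r - log v - r^2 / (2 v)`.
#'
#' @param r Step magnitudes, nm (>= 0); vectorised.
#' @param D Diffusion constant, um^2/s (> 0, or 0 with positive
#'   `loc_sigma`).
#' @param dt Frame interval, s.
#' @param loc_sigma Localization noise per axis, nm (default 0).
#' @return Log-density values.
#' @export
step_loglik <- function(r, D, dt = 0.05, loc_sigma = 0) {
  if (any(r < 0)) abort("`r` must be non-negative.")
  v <- 2 * D * 1e6 * dt + 2 * loc_sigma^2   # nm^2 per axis
  if (any(v <= 0)) abort("Per-axis step variance must be positive.")
  log(pmax(r, 1e-300)) - log(v) - r^2 / (2 * v)
}

# log-emission matrix: one row per step, one column per state
emission_matrix <- function(r, D, dt, loc_sigma) {
  vapply(D, function(d) step_loglik(r, d, dt, loc_sigma),
         numeric(length(r)))
}

steps_by_track <- function(trajs) {
  st <- track_steps(trajs)
  st <- dplyr::arrange(st, .data$track_id, .data$frame)
  list(r = st$disp_nm, lens = as.integer(table(st$track_id)[
    as.character(unique(st$track_id))]))
}

init_D <- function(logr2, K, dt, loc_sigma, jitter = 0) {
  if (K == 1) {
    v <- mean(exp(logr2)) / 2
  } else {
    km <- suppressWarnings(kmeans(logr2, centers = K, nstart = 3))
    v <- sort(exp(as.numeric(km$centers))) / 2
  }
  if (jitter > 0) v <- v * exp(rnorm(K, 0, jitter))
  # v is the per-axis variance 2 D dt + 2 sigma^2 (nm^2)
  D <- (v - 2 * loc_sigma^2) / (2e6 * dt)
  pmax(D, 1e-6)
}

#' Fit a diffusion-state hidden Markov model by EM
#'
#' Baum-Welch over the per-step displacement magnitudes of every trajectory
#' (tracks are independent; sufficient statistics are pooled). State
#' emissions are Rayleigh with per-axis variance `2 D_k dt + 2 loc_sigma^2`;
#' the M-step updates each `D_k` in closed form from the state-weighted mean
#' squared displacement. Fitting restarts `n_restarts` times from seeded
#' k-means initializations on `log r^2` (with multiplicative jitter after
#' the first restart) and returns the best run. The log-likelihood is
#' non-decreasing across EM iterations (asserted).
#'
#' @param trajs Trajectory tibble (see [link_trajectories()] or
#'   [sim_trajectories()]).
#' @param K Number of diffusion states (>= 1).
#' @param dt Frame interval, s.
#' @param loc_sigma Static localization noise per axis, nm (default 0).
#' @param n_restarts EM restarts (default 10).
#' @param seed Optional integer seed.
#' @param max_iter,tol EM stopping rule: at most `max_iter` iterations or
#'   log-likelihood improvement below `tol`.
#' @return A `palm_hmm` object: `K`, `D` (ascending, um^2/s), `trans`,
#'   `pi0`, `occupancy` (stationary distribution of `trans`), `loglik`,
#'   `bic`, `n_steps`, `dt`, `loc_sigma`, `convergence` (per-iteration
#'   log-likelihoods of the winning restart). Supports [tidy()], [glance()].
#' @export
fit_hmm <- function(trajs, K, dt = 0.05, loc_sigma = 0, n_restarts = 10,
                    seed = NULL, max_iter = 500, tol = 1e-8) {
  stop_if_not_scalar(K, "K", lower = 1)
  sb <- steps_by_track(trajs)
  r <- sb$r; lens <- sb$lens
  n <- length(r)
  if (n < 50 * K) {
    abort(sprintf("Need >= %d steps to fit K = %d states (have %d).",
                  50 * K, K, n))
  }
  logr2 <- log(pmax(r, 1e-3)^2)

  with_seed(seed, {
    best <- NULL
    for (rs in seq_len(n_restarts)) {
      D <- init_D(logr2, K, dt, loc_sigma, jitter = if (rs == 1) 0 else 0.3)
      trans <- matrix(0.1 / max(K - 1, 1), K, K); diag(trans) <- if (K > 1) 0.9 else 1
      pi0 <- rep(1 / K, K)
      ll_trace <- numeric(0)
      ok <- TRUE
      for (it in seq_len(max_iter)) {
        fb <- hmm_forward_backward(emission_matrix(r, D, dt, loc_sigma),
                                   lens, pi0, trans)
        ll_trace <- c(ll_trace, fb$loglik)
        g <- fb$gamma
        wsum <- colSums(g)
        if (any(wsum < 1e-8 * n)) { ok <- FALSE; break }  # state collapse
        # M-step
        v <- colSums(g * r^2) / (2 * wsum)   # per-axis variance 2Ddt + 2s^2
        D <- pmax((v - 2 * loc_sigma^2) / (2e6 * dt), 1e-8)
        if (K > 1) {
          trans <- fb$xi_sum / pmax(rowSums(fb$xi_sum), 1e-300)
          pi0 <- fb$gamma1 / sum(fb$gamma1)
        }
        if (it > 1 && ll_trace[it] - ll_trace[it - 1] < tol) break
      }
      if (!ok) next
      if (length(ll_trace) > 1 && any(diff(ll_trace) < -1e-6)) {
        abort("EM log-likelihood decreased; numerical failure.")
      }
      cand <- list(D = D, trans = trans, pi0 = pi0,
                   loglik = ll_trace[length(ll_trace)], trace = ll_trace)
      if (is.null(best) || cand$loglik > best$loglik) best <- cand
    }
    if (is.null(best)) {
      abort("All EM restarts collapsed to an empty state; reduce K.")
    }
    # sort states by ascending D
    ord <- order(best$D)
    D <- best$D[ord]
    trans <- best$trans[ord, ord, drop = FALSE]
    pi0 <- best$pi0[ord]
    k_par <- K + K * (K - 1) + (K - 1)
    structure(
      list(K = as.integer(K), D = D, trans = trans, pi0 = pi0,
           occupancy = stationary_distribution(trans),
           loglik = best$loglik,
           bic = -2 * best$loglik + k_par * log(n),
           n_steps = n, dt = dt, loc_sigma = loc_sigma,
           convergence = best$trace),
      class = "palm_hmm"
    )
  })
}

stationary_distribution <- function(trans) {
  K <- nrow(trans)
  if (K == 1) return(1)
  e <- eigen(t(trans))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- abs(v)
  v / sum(v)
}

#' @export
print.palm_hmm <- function(x, ...) {
  cat(sprintf("<palm_hmm> K = %d states, %d steps, loglik %.1f, BIC %.1f\n",
              x$K, x$n_steps, x$loglik, x$bic))
  cat("  D (um^2/s):", paste(signif(x$D, 3), collapse = ", "), "\n")
  cat("  occupancy: ", paste(signif(x$occupancy, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Select the number of diffusion states by BIC
#'
#' Fits [fit_hmm()] for each `K` in `K_range` and returns the model with the
#' smallest Bayesian information criterion
#' `BIC = -2 loglik + k log(n_steps)` with
#' `k = K + K(K-1) + (K-1)` free parameters (diffusion constants,
#' transition matrix, initial distribution). BIC here plays the role the
#' variational evidence plays in variational-Bayes treatments of the same
#' model.
#'
#' @inheritParams fit_hmm
#' @param K_range Candidate state counts (default 1:5).
#' @return The best `palm_hmm`; all candidates are attached as attribute
#'   `scan` (tibble `K`, `loglik`, `bic`, `fitted`).
#' @export
select_model <- function(trajs, K_range = 1:5, dt = 0.05, loc_sigma = 0,
                         n_restarts = 10, seed = NULL) {
  if (length(K_range) == 0) abort("`K_range` must be non-empty.")
  fits <- list()
  for (i in seq_along(K_range)) {
    sk <- if (is.null(seed)) NULL else seed + i - 1L
    fits[[i]] <- tryCatch(
      fit_hmm(trajs, K_range[i], dt, loc_sigma, n_restarts, seed = sk),
      error = function(e) NULL
    )
  }
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) abort("No candidate model could be fitted.")
  fits <- fits[keep]; Ks <- K_range[keep]
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  best <- fits[[which.min(bics)]]
  attr(best, "scan") <- tibble(
    K = as.integer(Ks),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    bic = bics
  )
  best
}

#' Summarise fitted diffusion states on data
#'
#' Decodes the most likely (Viterbi) state path of every trajectory and
#' reports per-state step occupancy, empirical mean dwell times, and the
#' expected dwell time `dt / (1 - trans_kk)` implied by the transition
#' matrix.
#'
#' @param model A fitted `palm_hmm`.
#' @param trajs Trajectory tibble.
#' @return List: `states` (tibble `track_id`, `frame`, `state` for every
#'   step), `summary` (tibble `state`, `D`, `occupancy`, `n_steps`,
#'   `mean_dwell_s` (empirical), `expected_dwell_s`).
#' @export
summarize_states <- function(model, trajs) {
  stopifnot(inherits(model, "palm_hmm"))
  st <- track_steps(trajs)
  sb <- steps_by_track(trajs)
  path <- hmm_viterbi(emission_matrix(sb$r, model$D, model$dt,
                                      model$loc_sigma),
                      sb$lens, model$pi0, model$trans)
  states <- dplyr::mutate(st[c("track_id", "frame")], state = path)
  # empirical dwells: runs of equal state within a track
  dwell <- states |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(runs = list(rle(.data$state)), .groups = "drop")
  runs <- dplyr::bind_rows(lapply(dwell$runs, function(r) {
    tibble(state = r$values, len = r$lengths)
  }))
  emp <- runs |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(mean_dwell_s = mean(.data$len) * model$dt,
                     .groups = "drop")
  occ <- tabulate(path, nbins = model$K) / length(path)
  summary <- tibble(
    state = seq_len(model$K),
    D = model$D,
    occupancy = occ,
    n_steps = tabulate(path, nbins = model$K),
    expected_dwell_s = model$dt / pmax(1 - diag(model$trans), 1e-12)
  ) |>
    dplyr::left_join(emp, by = "state")
  list(states = states, summary = summary)
}
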