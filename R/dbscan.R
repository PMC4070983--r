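# Simulation-aided DBSCAN: eps calibrated against CSR nearest-neighbour
# distances at the observed density, then density-based clustering with
# occupancy statistics.

#' Calibrate DBSCAN parameters against CSR simulations
#'
#' Fixes `min_pts = 2` (so dimers are detectable) and sets `eps` to a low
#' percentile of the nearest-neighbour distances pooled over CSR simulations
#' at the observed density: a distance this small between molecules rarely
#' arises by chance in a random pattern, so pairs this close are evidence of
#' genuine clustering.
#'
#' @param points Tibble with `x_nm`, `y_nm`.
#' @param roi Window `c(xmin, xmax, ymin, ymax)`, nm.
#' @param n_sims Number of CSR simulations (default 20).
#' @param percentile Percentile of pooled NN distances used for `eps`
#'   (default 1).
#' @param seed Optional integer seed.
#' @return List: `eps` (nm), `min_pts` (= 2).
#' @export
calibrate_dbscan <- function(points, roi, n_sims = 20, percentile = 1,
                             seed = NULL) {
  check_roi(roi)
  n <- nrow(points)
  if (n < 10) abort("Need at least 10 points to calibrate.")
  stop_if_not_scalar(percentile, "percentile", 0, 100)
  with_seed(seed, {
    pooled <- unlist(lapply(seq_len(n_sims), function(s) {
      nn_distances(runif(n, roi[1], roi[2]), runif(n, roi[3], roi[4]))
    }))
    list(eps = unname(quantile(pooled, percentile / 100)), min_pts = 2L)
  })
}

#' Density-based clustering of molecule positions
#'
#' Standard DBSCAN: a point is a core point when at least `min_pts` points
#' (itself included) lie within `eps`; clusters are the connected components
#' of core points under eps-reachability, with border points attached to a
#' neighbouring core's cluster. Points in no cluster are noise
#' (label 0 = monomers/unclustered).
#'
#' @param points Tibble with `x_nm`, `y_nm`.
#' @param eps Neighbourhood radius, nm (> 0).
#' @param min_pts Core-point threshold (default 2).
#' @return A `palm_clusters` object: list with `labels` (0 = noise),
#'   `occupancy` (tibble `size`, `n_clusters`), `mean_occupancy`,
#'   `clustered_fraction`, `n_clusters`, `eps`, `min_pts`.
#' @export
dbscan_clusters <- function(points, eps, min_pts = 2L) {
  stop_if_not_scalar(eps, "eps"); if (eps <= 0) abort("`eps` must be > 0.")
  n <- nrow(points)
  x <- points$x_nm; y <- points$y_nm
  labels <- integer(n)
  if (n > 0) {
    # neighbour lists via cell hashing (cells of side eps)
    cxy <- cbind(floor(x / eps), floor(y / eps))
    key <- paste(cxy[, 1], cxy[, 2], sep = ",")
    cell_of <- split(seq_len(n), key)
    nbrs <- vector("list", n)
    for (i in seq_len(n)) {
      cand <- integer(0)
      for (dx in -1:1) for (dy in -1:1) {
        cand <- c(cand,
                  cell_of[[paste(cxy[i, 1] + dx, cxy[i, 2] + dy, sep = ",")]])
      }
      d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
      nbrs[[i]] <- cand[d2 <= eps^2]  # includes i itself
    }
    core <- vapply(nbrs, length, integer(1)) >= min_pts
    # flood fill over core points; borders join the first claiming cluster
    cl <- 0L
    for (i in which(core)) {
      if (labels[i] != 0L) next
      cl <- cl + 1L
      queue <- i
      labels[i] <- cl
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (q in nbrs[[p]]) {
          if (labels[q] == 0L) {
            labels[q] <- cl
            if (core[q]) queue <- c(queue, q)
          }
        }
      }
    }
  }
  sizes <- if (any(labels > 0)) as.integer(table(labels[labels > 0])) else integer(0)
  occ <- if (length(sizes)) {
    tibble(size = as.integer(names(table(sizes))),
           n_clusters = as.integer(table(sizes)))
  } else tibble(size = integer(0), n_clusters = integer(0))
  structure(
    list(labels = labels,
         occupancy = occ,
         mean_occupancy = if (length(sizes)) mean(sizes) else NA_real_,
         clustered_fraction = if (n) mean(labels > 0) else NA_real_,
         n_clusters = length(sizes),
         eps = eps, min_pts = as.integer(min_pts)),
    class = "palm_clusters"
  )
}

#' @export
print.palm_clusters <- function(x, ...) {
  cat(sprintf(
    "<palm_clusters> %d clusters (eps %.1f nm, min_pts %d); mean occupancy %.2f; clustered fraction %.2f\n",
    x$n_clusters, x$eps, x$min_pts,
    x$mean_occupancy, x$clustered_fraction))
  invisible(x)
}
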