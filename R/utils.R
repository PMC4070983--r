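# Internal helpers: argument checking, units, seeded RNG, spatial hashing.

NM_PER_UM <- 1e3
UM2_PER_NM2 <- 1e-6

stop_if_not_scalar <- function(x, name, lower = -Inf, upper = Inf,
                               allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must not be NULL.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

# Set the RNG state locally so seeded calls do not disturb the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stop_if_not_scalar(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# An ROI is a rectangle in nm: c(xmin, xmax, ymin, ymax).
check_roi <- function(roi) {
  if (!is.numeric(roi) || length(roi) != 4L || any(!is.finite(roi))) {
    abort("`roi` must be numeric c(xmin, xmax, ymin, ymax) in nm.")
  }
  if (roi[2] <= roi[1] || roi[4] <= roi[3]) {
    abort("`roi` is empty: xmax must exceed xmin and ymax must exceed ymin.")
  }
  invisible(roi)
}

roi_area_nm2 <- function(roi) (roi[2] - roi[1]) * (roi[4] - roi[3])

# Connected components of the graph joining points closer than `r`,
# found by hashing points into cells of side r and union-find over the
# 3x3 cell neighbourhood. Exact: any pair within r lies in adjacent cells.
spatial_components <- function(x, y, r) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  if (r <= 0) return(seq_len(n))
  cx <- floor(x / r)
  cy <- floor(y / r)
  key <- paste(cx, cy, sep = ",")
  cell_of <- split(seq_len(n), key)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }

  r2 <- r * r
  for (k in names(cell_of)) {
    idx <- cell_of[[k]]
    ij <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    for (dxy in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
      nb <- cell_of[[paste(ij[1] + dxy[1], ij[2] + dxy[2], sep = ",")]]
      if (is.null(nb)) next
      for (i in idx) {
        d2 <- (x[nb] - x[i])^2 + (y[nb] - y[i])^2
        for (j in nb[d2 <= r2]) if (j != i) union(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Pairwise-distance based k = 1 nearest-neighbour distances, chunked so the
# full n x n matrix is never materialised for large n.
nn_distances <- function(x, y, chunk = 512L) {
  n <- length(x)
  if (n < 2L) return(rep(NA_real_, n))
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}
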