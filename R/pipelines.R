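# Pipeline configuration and the two end-to-end analysis chains: the static
# PALM pipeline (localize -> drift -> blink grouping -> cluster statistics
# -> rendering) and the tracking pipeline (localize -> drift -> link ->
# displacement histogram -> diffusion-state model selection).

default_config <- function() {
  list(
    seed = 1L,
    camera = list(pixel_size = 125, frame_time = 0.05, psf_sigma = 130,
                  background = 5, read_noise = 0, offset = 0, gain = 1),
    detection = list(threshold = 30, window = 11, min_photons = 100,
                     max_sigma = Inf, max_precision = Inf),
    drift = list(smoothing_window = 10),
    grouping = list(t_d = 0.26, r_group = "auto"),
    toff = list(td_max = 1.05, td_step = 0.15, n_fit_points = 7),
    ripley = list(r_max = 200, r_step = 5, n_sims = 99, alpha = 0.05),
    clusters = list(n_sims = 20, percentile = 1),
    render = list(out_pixel = 10, mode = "gaussian"),
    linking = list(max_disp = 500, dt = 0.05, method = "optimal"),
    hmm = list(K_range = 1:4, loc_sigma = 0, n_restarts = 10)
  )
}

merge_config <- function(base, user, path = character()) {
  for (nm in names(user)) {
    if (!nm %in% names(base)) {
      abort(sprintf("Unknown configuration key: %s",
                    paste(c(path, nm), collapse = "$")))
    }
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], c(path, nm))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Pipeline configuration
#'
#' Builds the full parameter set of both analysis pipelines from defaults,
#' overridden by any subset of keys; unknown keys are rejected. The
#' configuration round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param ... Named overrides, e.g. `grouping = list(t_d = 0.3)`.
#' @return A `palm_config` nested list.
#' @export
palm_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(default_config(), user)
  structure(cfg, class = "palm_config")
}

#' @rdname palm_config
#' @param config A `palm_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname palm_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- rapply(raw, function(x) {
    if (identical(x, ".inf")) Inf else x
  }, how = "replace")
  do.call(palm_config, raw)
}

config_camera <- function(config) do.call(camera_model, config$camera)

provenance <- function(config, stage_counts) {
  list(package = "palmkit",
       version = as.character(utils::packageVersion("palmkit")),
       config_hash = rlang::hash(unclass(config)),
       seed = config$seed,
       counts = stage_counts,
       parameters = unclass(config))
}

prepare_locs <- function(locs, config, n_frames) {
  cam <- config_camera(config)
  if (inherits(locs, "palm_stack")) {
    n_frames <- length(locs$frames)
    locs <- localize_stack(locs, cam, threshold = config$detection$threshold,
                           window = config$detection$window)
  }
  locs <- filter_localizations(locs,
                               min_photons = config$detection$min_photons,
                               max_sigma = config$detection$max_sigma,
                               max_precision = config$detection$max_precision)
  if (any(locs$is_fiducial)) {
    locs <- correct_drift(locs, config$drift$smoothing_window)
  }
  locs
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the static PALM pipeline
#'
#' Localize (when given a frame stack) or load localizations, drift-correct
#' on fiducials, group blink events into molecules at the configured allowed
#' dark period, run Ripley's K with a CSR envelope plus
#' simulation-calibrated DBSCAN on the molecule positions, and render the
#' super-resolution image.
#'
#' @param input A `palm_stack` or a localization tibble (or CSV path).
#' @param config A [palm_config()].
#' @param roi Analysis window `c(xmin, xmax, ymin, ymax)` nm; defaults to
#'   the molecule bounding box.
#' @param out_dir Optional directory: writes molecule table, cluster
#'   report, rendered image (CSV matrix) and a JSON provenance record.
#' @return List: `localizations`, `molecules`, `ripley`, `clusters`,
#'   `image`, `provenance`.
#' @export
run_static_pipeline <- function(input, config = palm_config(), roi = NULL,
                                out_dir = NULL) {
  stopifnot(inherits(config, "palm_config"))
  if (is.character(input)) input <- read_localizations(input)
  locs <- run_stage("localize", prepare_locs(input, config, NULL))
  mols <- run_stage("group", group_blinks(
    locs, t_d = config$grouping$t_d, r_group = config$grouping$r_group,
    frame_time = config$camera$frame_time))
  if (is.null(roi)) {
    roi <- c(min(mols$x_nm), max(mols$x_nm), min(mols$y_nm), max(mols$y_nm))
  }
  r_grid <- seq(config$ripley$r_step, config$ripley$r_max,
                by = config$ripley$r_step)
  rip <- run_stage("ripley", {
    ripley_k(mols, r_grid, roi) |>
      add_csr_envelope(n_sims = config$ripley$n_sims,
                       alpha = config$ripley$alpha, seed = config$seed)
  })
  clus <- run_stage("clusters", {
    cal <- calibrate_dbscan(mols, roi, n_sims = config$clusters$n_sims,
                            percentile = config$clusters$percentile,
                            seed = config$seed + 1L)
    dbscan_clusters(mols, cal$eps, cal$min_pts)
  })
  img <- run_stage("render", render_palm(mols, config$render$out_pixel,
                                         config$render$mode))
  prov <- provenance(config, list(localizations = nrow(locs),
                                  molecules = nrow(mols),
                                  clusters = clus$n_clusters))
  res <- list(localizations = locs, molecules = mols, ripley = rip,
              clusters = clus, image = img, provenance = prov)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_molecules(mols, file.path(out_dir, "molecules.csv"))
    readr::write_csv(rip$curve, file.path(out_dir, "ripley.csv"))
    readr::write_csv(clus$occupancy, file.path(out_dir, "occupancy.csv"))
    utils::write.table(img, file.path(out_dir, "palm_image.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Run the single-molecule-tracking pipeline
#'
#' Localize/load, drift-correct, link frame-to-frame localizations into
#' trajectories under the hard displacement gate, pool the per-frame
#' displacement histogram, and select the number of diffusion states by
#' BIC.
#'
#' @inheritParams run_static_pipeline
#' @return List: `localizations`, `trajectories`, `histogram`, `model`,
#'   `provenance`.
#' @export
run_tracking_pipeline <- function(input, config = palm_config(),
                                  out_dir = NULL) {
  stopifnot(inherits(config, "palm_config"))
  if (is.character(input)) input <- read_localizations(input)
  locs <- run_stage("localize", prepare_locs(input, config, NULL))
  lcfg <- linking_config(config$linking$max_disp, config$linking$dt,
                         config$linking$method)
  trajs <- run_stage("link", link_trajectories(locs, lcfg))
  hist <- run_stage("histogram", displacement_histogram(trajs))
  model <- run_stage("hmm", select_model(
    trajs, K_range = config$hmm$K_range, dt = config$linking$dt,
    loc_sigma = config$hmm$loc_sigma, n_restarts = config$hmm$n_restarts,
    seed = config$seed))
  prov <- provenance(config, list(localizations = nrow(locs),
                                  trajectories = length(unique(trajs$track_id)),
                                  selected_K = model$K))
  res <- list(localizations = locs, trajectories = trajs, histogram = hist,
              model = model, provenance = prov)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectories(trajs, file.path(out_dir, "trajectories.csv"))
    readr::write_csv(hist, file.path(out_dir, "displacements.csv"))
    jsonlite::write_json(
      list(K = model$K, D = model$D, trans = model$trans,
           pi0 = model$pi0, occupancy = model$occupancy,
           loglik = model$loglik, bic = model$bic),
      file.path(out_dir, "hmm_model.json"), auto_unbox = TRUE, digits = NA,
      matrix = "rowmajor")
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
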