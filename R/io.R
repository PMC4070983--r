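# File formats: localization/molecule/trajectory CSV tables with a fixed,
# versioned column schema, and multi-page TIFF stacks with a YAML sidecar.

LOC_SCHEMA <- c("frame", "x_nm", "y_nm", "photons", "background",
                "sigma_nm", "precision_nm", "is_fiducial")
MOL_SCHEMA <- c("mol_id", "x_nm", "y_nm", "first_frame", "last_frame",
                "n_locs", "n_events", "total_photons")
TRACK_SCHEMA <- c("track_id", "frame", "x_nm", "y_nm", "precision_nm")

#' Read/write localization, molecule and trajectory tables
#'
#' Plain CSV with a fixed column schema (`frame`, `x_nm`, `y_nm`,
#' `photons`, `background`, `sigma_nm`, `precision_nm`, `is_fiducial` for
#' localizations; analogous fixed schemas for molecules and trajectories).
#' Extra columns are preserved on write and ignored on schema validation.
#'
#' @param x Table to write.
#' @param path File path.
#' @return The tibble (readers) or `path`, invisibly (writers).
#' @name palm_io
NULL

check_schema <- function(x, schema, what) {
  missing <- setdiff(schema, names(x))
  if (length(missing)) {
    abort(sprintf("%s table is missing columns: %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname palm_io
#' @export
write_localizations <- function(x, path) {
  check_schema(x, LOC_SCHEMA, "Localization")
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname palm_io
#' @export
read_localizations <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(x, LOC_SCHEMA, "Localization")
  x
}

#' @rdname palm_io
#' @export
write_molecules <- function(x, path) {
  check_schema(x, MOL_SCHEMA, "Molecule")
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname palm_io
#' @export
read_molecules <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(x, MOL_SCHEMA, "Molecule")
  x
}

#' @rdname palm_io
#' @export
write_trajectories <- function(x, path) {
  check_schema(x, TRACK_SCHEMA, "Trajectory")
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname palm_io
#' @export
read_trajectories <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(x, TRACK_SCHEMA, "Trajectory")
  x
}

#' Write a frame stack as multi-page TIFF with a YAML sidecar
#'
#' Pixel values are stored as 32-bit floats; acquisition metadata (pixel
#' size, frame time, frame count) goes to `<path>.yaml`.
#'
#' @param stack A `palm_stack` (see [render_frames()]).
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "palm_stack"))
  scale <- max(1, max(vapply(stack$frames, max, numeric(1))))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / scale), path,
                  bits.per.sample = 32L)
  meta <- list(pixel_size_nm = stack$camera$pixel_size,
               frame_time_s = stack$camera$frame_time,
               n_frames = length(stack$frames),
               intensity_scale = scale,
               roi_nm = as.numeric(stack$roi))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a frame stack written by [write_stack_tiff()]
#'
#' @param path `.tif` path (expects the `.yaml` sidecar next to it).
#' @return A `palm_stack` (without ground truth).
#' @export
read_stack_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  frames <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(frames, function(f) f * meta$intensity_scale)
  structure(
    list(frames = frames,
         camera = camera_model(pixel_size = meta$pixel_size_nm,
                               frame_time = meta$frame_time_s),
         roi = meta$roi_nm, drift = NULL, emitters = NULL,
         intervals = NULL, fiducials = NULL),
    class = "palm_stack"
  )
}
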