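# Plain-text and TIFF serialization of runs, logs, images and phantoms.

#' Write / read a transient run as CSV
#'
#' Columns: `cycle_index`, `timestamp_s`, one column per isotope.
#'
#' @param run A `transient_run`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `transient_run` (read).
#' @export
write_transient_csv <- function(run, path) {
  utils::write.csv(as.data.frame(run), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transient_csv
#' @param run_kind Run kind recorded on the object read back.
#' @param cycle_time_s Cycle time of the run read back.
#' @export
read_transient_csv <- function(path, run_kind = "image", cycle_time_s = 0.1) {
  new_transient_run(as_tibble(utils::read.csv(path)), run_kind, cycle_time_s)
}

#' Write / read a laser log as CSV
#'
#' Columns: `line_id`, `t_start_s`, `t_end_s`, `x0_um`, `y0_um`, `x1_um`,
#' `y1_um`.
#'
#' @param log Laser-log tibble.
#' @param path CSV path.
#' @export
write_laser_log_csv <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_laser_log_csv
#' @export
read_laser_log_csv <- function(path) as_tibble(utils::read.csv(path))

#' Write an elemental image to per-isotope files
#'
#' One 32-bit float TIFF per isotope (when the tiff package is available)
#' plus a CSV matrix dump; filenames carry the isotope label.
#'
#' @param image An `elemental_image`.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @param tiff Also write TIFFs.
#' @return Tibble of written paths, invisibly.
#' @export
write_elemental_image <- function(image, dir, prefix = "map", tiff = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_dfr(image$data, function(m, k) {
    csv <- file.path(dir, paste0(prefix, "_", k, ".csv"))
    utils::write.table(m, csv, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    tif <- NA_character_
    if (tiff && requireNamespace("tiff", quietly = TRUE)) {
      tif <- file.path(dir, paste0(prefix, "_", k, ".tif"))
      scale <- max(m, 1e-12)
      tiff::writeTIFF(m / scale, tif, bits.per.sample = 32L)
    }
    tibble(isotope = k, csv = csv, tiff = tif)
  })
  invisible(paths)
}

#' Write phantom ground truth
#'
#' The label grid as a 16-bit TIFF (when available) plus CSV, and the
#' particle table as CSV.
#'
#' @param phantom A [build_phantom()] result.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(phantom$label_grid,
                     file.path(dir, paste0(prefix, "_labels.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.csv(as.data.frame(phantom$particle_table),
                   file.path(dir, paste0(prefix, "_particles.csv")),
                   row.names = FALSE)
  if (requireNamespace("tiff", quietly = TRUE)) {
    tiff::writeTIFF(phantom$label_grid / 65535,
                    file.path(dir, paste0(prefix, "_labels.tif")),
                    bits.per.sample = 16L)
  }
  invisible(dir)
}

#' Read a scene configuration from YAML
#'
#' Accepts the fields of [scene_config()] under their argument names.
#'
#' @param path YAML file path.
#' @return A `scene_config`.
#' @export
read_scene_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(scene_config, y)
}
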