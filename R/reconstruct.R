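# Transient run + laser log -> per-isotope pixel matrices, anchored on the
# Au (or C) marker spikes that flag each line's start and end.

#' Detect line-boundary marker spikes
#'
#' Cycles whose marker-channel signal exceeds `blank mean + k * blank sd`
#' (default k = 10) are merged into consecutive spike groups; each group's
#' intensity-weighted center cycle is a boundary estimate. Two spikes per
#' line (start and end) are expected.
#'
#' @param run A `transient_run`.
#' @param marker_isotope Marker channel; Au for imaging runs (carbon is also
#'   monitored and can serve as an alternate marker).
#' @param blank_mean,blank_sd Marker blank statistics; when `NULL` they are
#'   estimated robustly from the channel itself (median and MAD).
#' @param k Threshold multiplier.
#' @return Tibble with `boundary_id`, `cycle` (0-based boundary cycle),
#'   `n_cycles` (spike-group width).
#' @export
detect_line_boundaries <- function(run, marker_isotope = "Au197",
                                   blank_mean = NULL, blank_sd = NULL,
                                   k = 10) {
  if (!marker_isotope %in% names(run)) {
    stop_twp(paste0("marker channel ", marker_isotope, " not present"),
             "twpscan_no_marker")
  }
  x <- run[[marker_isotope]]
  bm <- blank_mean %||% median(x)
  bs <- blank_sd %||% max(mad(x), sqrt(max(bm, 0)), 1e-12)
  thr <- bm + k * bs
  above <- which(x > thr)
  if (length(above) == 0) {
    stop_twp("no marker spikes above threshold (zero-amplitude marker?)",
             "twpscan_no_spikes")
  }
  grp <- cumsum(c(1L, diff(above) > 1L))
  centers <- vapply(split(above, grp), function(idx) {
    w <- x[idx]
    sum((idx - 1L) * w) / sum(w)          # 0-based weighted center
  }, 0)
  widths <- vapply(split(above, grp), length, 0L)
  tibble(boundary_id = seq_along(centers),
         cycle = round(unname(centers)),
         n_cycles = unname(widths))
}

#' Align the laser log with detected boundaries
#'
#' Pairs consecutive boundaries into (start, end) per line, estimates the
#' clock offset between log timestamps and the acquisition clock as the
#' median start-time difference, and assigns each line exactly
#' `pixels_per_line = floor(line_length / pitch)` cycles.
#'
#' @param laser_log Laser-log tibble (see [simulate_raster()]).
#' @param boundaries Result of [detect_line_boundaries()].
#' @param cycle_time_s Cycle time in seconds.
#' @param pitch_um Pixel pitch; defaults to stage speed times cycle time
#'   derived from the log itself.
#' @return A `line_segmentation` tibble: `line_id`, `first_cycle`,
#'   `last_cycle`, `offset_s`.
#' @export
align_log <- function(laser_log, boundaries, cycle_time_s, pitch_um = NULL) {
  n_lines <- nrow(laser_log)
  if (nrow(boundaries) != 2L * n_lines) {
    stop_twp(paste0("detected ", nrow(boundaries), " spike groups but log has ",
                    n_lines, " lines (expected ", 2L * n_lines,
                    "); run and log are desynchronized"),
             "twpscan_desync")
  }
  length_um <- sqrt((laser_log$x1_um - laser_log$x0_um)^2 +
                      (laser_log$y1_um - laser_log$y0_um)^2)
  speed <- length_um / (laser_log$t_end_s - laser_log$t_start_s)
  pitch_um <- pitch_um %||% (speed[1] * cycle_time_s)
  px_per_line <- floor(length_um / pitch_um + 1e-9)
  start_cycles <- boundaries$cycle[seq(1, 2L * n_lines, by = 2L)]
  offsets <- laser_log$t_start_s - start_cycles * cycle_time_s
  if (diff(range(offsets)) > 2 * cycle_time_s) {
    stop_twp("per-line clock offsets spread over more than 2 cycles; clock drift beyond model",
             "twpscan_clock_drift")
  }
  offset <- median(offsets)
  first_cycle <- round((laser_log$t_start_s - offset) / cycle_time_s)
  structure(tibble(line_id = laser_log$line_id,
                   first_cycle = as.integer(first_cycle),
                   last_cycle = as.integer(first_cycle + px_per_line - 1L),
                   offset_s = offsets),
            class = c("line_segmentation", class(tibble())),
            offset_s = offset, pitch_um = pitch_um)
}

#' Build per-isotope pixel matrices
#'
#' Row i of every isotope matrix holds the per-cycle signals of line i in
#' scan order; cycles between lines (washout tail, background) are
#' discarded rather than folded into edge pixels. With `serpentine = TRUE`
#' even lines are flipped to a common orientation.
#'
#' @param run A `transient_run` (typically background-corrected and
#'   normalized).
#' @param segmentation An [align_log()] result.
#' @param isotopes Isotope columns to map (default: all monitored).
#' @param pitch_um Pixel pitch stored on the image; defaults to the
#'   segmentation's.
#' @param serpentine Flip alternate lines.
#' @return An `elemental_image`: list with `data` (named list of matrices),
#'   `pitch_um`, `isotopes`.
#' @export
build_maps <- function(run, segmentation, isotopes = NULL, pitch_um = NULL,
                       serpentine = FALSE) {
  isotopes <- isotopes %||% isotope_columns(run)
  if (max(segmentation$last_cycle) > nrow(run) - 1L) {
    stop_twp("segmentation extends past the end of the run", "twpscan_segment")
  }
  n_px <- unique(segmentation$last_cycle - segmentation$first_cycle + 1L)
  if (length(n_px) != 1L) {
    stop_twp("lines have unequal pixel counts", "twpscan_segment")
  }
  data <- lapply(isotopes, function(k) {
    m <- matrix(NA_real_, nrow(segmentation), n_px)
    for (i in seq_len(nrow(segmentation))) {
      idx <- (segmentation$first_cycle[i]:segmentation$last_cycle[i]) + 1L
      row <- run[[k]][idx]
      if (serpentine && i %% 2L == 0L) row <- rev(row)
      m[i, ] <- row
    }
    m
  })
  new_elemental_image(setNames(data, isotopes),
                      pitch_um %||% attr(segmentation, "pitch_um"))
}

new_elemental_image <- function(data, pitch_um) {
  stopifnot(length(unique(lapply(data, dim))) == 1L)
  structure(list(data = data, pitch_um = pitch_um, isotopes = names(data),
                 normalized = FALSE),
            class = "elemental_image")
}

#' @export
print.elemental_image <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat("<elemental_image>", d[1], "x", d[2], "px @", x$pitch_um, "um;",
      length(x$data), "isotopes:", paste(x$isotopes, collapse = ", "), "\n")
  invisible(x)
}

#' Long-format view of an elemental image
#'
#' @param x An `elemental_image`.
#' @param ... Unused.
#' @return Tibble with `isotope`, `line`, `pixel`, `x_um`, `y_um`, `value`.
#' @export
as_tibble.elemental_image <- function(x, ...) {
  purrr::imap_dfr(x$data, function(m, k) {
    tibble(isotope = k,
           line = rep(seq_len(nrow(m)), times = ncol(m)),
           pixel = rep(seq_len(ncol(m)), each = nrow(m)),
           value = as.vector(m))
  }) %>%
    mutate(x_um = (.data$pixel - 0.5) * x$pitch_um,
           y_um = (.data$line - 0.5) * x$pitch_um)
}

#' Pixel feature matrix of an elemental image
#'
#' Flattens the six marker maps (or any requested isotopes) into a tibble of
#' per-pixel feature rows, the input expected by the classifier.
#'
#' @param image An `elemental_image`.
#' @param isotopes Feature columns, default [marker_isotopes()].
#' @return Tibble with `line`, `pixel` and one column per isotope.
#' @export
image_features <- function(image, isotopes = marker_isotopes()) {
  missing <- setdiff(isotopes, names(image$data))
  if (length(missing) > 0) {
    stop_twp(paste0("missing marker map(s): ", paste(missing, collapse = ", ")),
             "twpscan_missing_map")
  }
  d <- dim(image$data[[1]])
  out <- tibble(line = rep(seq_len(d[1]), times = d[2]),
                pixel = rep(seq_len(d[2]), each = d[1]))
  for (k in isotopes) out[[k]] <- as.vector(image$data[[k]])
  out
}

#' Reconstruct an elemental image from a raw simulated acquisition
#'
#' Convenience chain used throughout the package: background-correct the run
#' against a gas blank, normalize to the bracketing standards, detect the Au
#' line markers, align the log and build the maps.
#'
#' @param sim A `list(run, log)` from [simulate_raster()].
#' @param gas_blank A gas-blank `transient_run`.
#' @param standard_before,standard_after Standard runs (raw; they are
#'   background-corrected against the same blank).
#' @param marker_isotope Marker channel for boundary detection.
#' @return List with `image` (normalized `elemental_image`) and
#'   `record` (normalization record).
#' @export
reconstruct_image <- function(sim, gas_blank, standard_before, standard_after,
                              marker_isotope = "Au197") {
  run <- background_correct(sim$run, gas_blank)
  sb <- background_correct(standard_before, gas_blank)
  sa <- background_correct(standard_after, gas_blank)
  blank_means <- attr(run, "blank_means")
  bm <- 0   # after background correction the marker blank sits at ~0
  bs <- sqrt(max(blank_means[[marker_isotope]], 1))
  bounds <- detect_line_boundaries(run, marker_isotope,
                                   blank_mean = bm, blank_sd = bs)
  dt <- attr(sim$run, "cycle_time_s")
  seg <- align_log(sim$log, bounds, dt)
  img <- build_maps(run, seg)
  norm <- nist_normalize(img, sb, sa)
  list(image = norm$normalized, record = norm$record)
}
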