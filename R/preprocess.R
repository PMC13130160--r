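# Background correction, NIST612 bracketing-standard normalization with the
# 20 percent inter-run drift check, and train/apply feature standardization.

#' Gas-blank background correction
#'
#' Subtracts the per-isotope gas-blank mean from every cycle and clips the
#' result at zero. The subtracted means are recorded in the
#' `"blank_means"` attribute of the returned run.
#'
#' @param run A `transient_run`.
#' @param gas_blank_run A `transient_run` of at least 100 background cycles.
#' @return The corrected run.
#' @export
background_correct <- function(run, gas_blank_run) {
  if (nrow(gas_blank_run) < 100L) {
    stop_twp("gas blank has fewer than 100 cycles; blank estimate unreliable",
             "twpscan_short_blank")
  }
  iso <- isotope_columns(run)
  means <- vapply(iso, function(k) mean(gas_blank_run[[k]]), 0)
  for (k in iso) run[[k]] <- pmax(run[[k]] - means[[k]], 0)
  attr(run, "blank_means") <- means
  attr(run, "background_corrected") <- TRUE
  run
}

#' Normalize signals to bracketing NIST612 standards
#'
#' Per isotope, the sensitivity is the arithmetic mean of the mean signal of
#' the standard analyzed before and after the measurement; signals are
#' divided by it. The relative variation `|before - after| / mean` is
#' recorded and flagged (with a warning, processing continues) when it
#' exceeds 20 percent, the drift level the acquisition protocol treats as
#' acceptable between bracketing standards.
#'
#' @param x A `transient_run` or an `elemental_image` to normalize.
#' @param standard_before,standard_after Background-corrected standard runs.
#' @return List with `normalized` (same type as `x`) and `record`
#'   (a tibble: `isotope`, `sens_before`, `sens_after`, `sensitivity`,
#'   `rel_variation`, `warn_flag`).
#' @export
nist_normalize <- function(x, standard_before, standard_after) {
  iso_std <- isotope_columns(standard_before)
  before <- vapply(iso_std, function(k) mean(standard_before[[k]]), 0)
  after <- vapply(iso_std, function(k) mean(standard_after[[k]]), 0)
  sens <- (before + after) / 2
  if (any(sens <= 0)) {
    stop_twp(paste0("nonpositive sensitivity for ",
                    paste(iso_std[sens <= 0], collapse = ", "),
                    " (dead channel)"), "twpscan_dead_channel")
  }
  rel <- abs(before - after) / sens
  record <- tibble(isotope = iso_std, sens_before = unname(before),
                   sens_after = unname(after), sensitivity = unname(sens),
                   rel_variation = unname(rel),
                   warn_flag = unname(rel) > 0.20)
  if (any(record$warn_flag)) {
    warn(paste0("NIST612 inter-run variation exceeds 20% for: ",
                paste(record$isotope[record$warn_flag], collapse = ", ")))
  }
  if (inherits(x, "elemental_image")) {
    for (k in intersect(names(x$data), iso_std)) {
      x$data[[k]] <- x$data[[k]] / sens[[k]]
    }
    x$normalized <- TRUE
  } else {
    for (k in intersect(isotope_columns(x), iso_std)) {
      x[[k]] <- x[[k]] / sens[[k]]
    }
  }
  list(normalized = x, record = record)
}

#' Fit feature standardization parameters
#'
#' Per-feature center (mean) and scale (sample standard deviation, n-1
#' denominator) computed on training data. Parameters are frozen at fit time
#' and reused unchanged on any later table or image.
#'
#' @param feature_table Data frame whose numeric columns are features.
#' @param features Character vector of feature columns; defaults to all
#'   numeric columns.
#' @return A `standardization_params` tibble (`feature`, `center`, `scale`).
#' @export
fit_standardization <- function(feature_table,
                                features = NULL) {
  features <- features %||%
    names(feature_table)[vapply(feature_table, is.numeric, TRUE)]
  if (nrow(feature_table) < 2L) {
    stop_twp("need at least 2 rows to fit standardization", "twpscan_fit")
  }
  center <- vapply(features, function(f) mean(feature_table[[f]]), 0)
  scale <- vapply(features, function(f) sd(feature_table[[f]]), 0)
  if (any(scale == 0)) {
    stop_twp(paste0("constant feature(s): ",
                    paste(features[scale == 0], collapse = ", ")),
             "twpscan_constant_feature")
  }
  structure(tibble(feature = features, center = unname(center),
                   scale = unname(scale)),
            class = c("standardization_params", class(tibble())))
}

#' Apply frozen standardization parameters
#'
#' @param feature_table Data frame containing the fitted feature columns.
#' @param params A [fit_standardization()] result.
#' @return The table with the fitted columns replaced by
#'   `(x - center) / scale`.
#' @export
apply_standardization <- function(feature_table, params) {
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    if (!f %in% names(feature_table)) {
      stop_twp(paste0("missing feature column: ", f), "twpscan_missing_feature")
    }
    feature_table[[f]] <- (feature_table[[f]] - params$center[i]) / params$scale[i]
  }
  feature_table
}

#' Write a processing-provenance sidecar
#'
#' Appends the normalization record (and any extra metadata) to a JSON
#' sidecar accompanying a reconstructed image.
#'
#' @param path JSON file path.
#' @param record Normalization record tibble from [nist_normalize()].
#' @param extra Optional named list of additional metadata.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, record, extra = list()) {
  payload <- c(list(normalization = record), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
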