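# Bulk fingerprint workflow: per-line averaging, PCA biplots, Ward
# hierarchical clustering and the column-standardized heatmap.

#' Average a bulk run per line
#'
#' One row per line of the log; values are the mean signal over the line's
#' cycles for each isotope. Runs are expected to be preprocessed
#' (background-corrected, normalized) before averaging.
#'
#' @param bulk_run A `transient_run`.
#' @param log Laser-log tibble segmenting the run into lines.
#' @return Tibble with `line_id` and one column per isotope.
#' @export
average_lines <- function(bulk_run, log) {
  iso <- isotope_columns(bulk_run)
  rows <- purrr::map_dfr(seq_len(nrow(log)), function(i) {
    sel <- bulk_run$timestamp_s >= log$t_start_s[i] - 1e-9 &
      bulk_run$timestamp_s < log$t_end_s[i] - 1e-9
    if (!any(sel)) {
      stop_twp(paste0("empty line segment for line ", log$line_id[i]),
               "twpscan_empty_line")
    }
    vals <- vapply(iso, function(k) mean(bulk_run[[k]][sel]), 0)
    dplyr::bind_cols(tibble(line_id = log$line_id[i]), as_tibble(as.list(vals)))
  })
  rows
}

#' Simulate the 13-material bulk fingerprint table
#'
#' Runs the full bulk workflow for every material: simulate the line scans,
#' background-correct against a gas blank, normalize to bracketing NIST612
#' standards, average per line, and keep the six marker elements. This is
#' the synthetic analogue of the bulk reference data behind the PCA and
#' cluster analysis.
#'
#' @param materials Materials to include (default: all 13).
#' @param n_lines Line-scan replicates per material (default 20).
#' @param fingerprints Fingerprint table.
#' @param seed Integer seed.
#' @param drift Sensitivity drift of the closing standard relative to the
#'   opening one (default 5 percent, well inside the 20 percent acceptance).
#' @return Tibble: `material`, `replicate`, then the marker columns.
#' @export
simulate_bulk_table <- function(materials = NULL, n_lines = 20L,
                                fingerprints = default_fingerprints(),
                                seed = 1L, drift = 1.05) {
  materials <- materials %||% fingerprint_materials(fingerprints)
  blank <- simulate_gas_blank(seed = child_seed(seed, 1L))
  std_before <- simulate_standard(drift_factor = 1,
                                  seed = child_seed(seed, 2L))
  std_after <- simulate_standard(drift_factor = drift,
                                 seed = child_seed(seed, 3L))
  sb <- background_correct(std_before, blank)
  sa <- background_correct(std_after, blank)
  purrr::imap_dfr(setNames(materials, materials), function(mat, nm) {
    sim <- simulate_bulk_lines(mat, fingerprints = fingerprints,
                               n_lines = n_lines,
                               seed = child_seed(seed, 10L + match(mat, materials)))
    run <- background_correct(sim$run, blank)
    run <- nist_normalize(run, sb, sa)$normalized
    avg <- average_lines(run, sim$log)
    dplyr::bind_cols(tibble(material = mat, replicate = avg$line_id),
                     avg[marker_isotopes()])
  })
}

feature_matrix <- function(table, features = marker_isotopes()) {
  as.matrix(table[, features, drop = FALSE])
}

#' Principal component analysis of a standardized fingerprint table
#'
#' PCA of the column-standardized marker table; components are ordered by
#' decreasing explained variance and signs are fixed so each component's
#' largest-magnitude loading is positive (for reproducible biplots).
#'
#' @param table Feature table (rows = line replicates) with a `material`
#'   column; marker columns are standardized internally with
#'   [fit_standardization()] unless `standardize = FALSE`.
#' @param n_components Number of components to retain (<= number of
#'   features).
#' @param standardize Standardize columns before decomposition.
#' @return A `twp_pca` object: `scores` (tibble with `material` and PCs),
#'   `loadings` (matrix), `explained` (variance fractions over all
#'   components), `sdev`.
#' @export
fingerprint_pca <- function(table, n_components = 2L, standardize = TRUE) {
  x <- feature_matrix(table)
  if (n_components > ncol(x)) {
    stop_twp("more components than features", "twpscan_pca")
  }
  if (nrow(x) < n_components) {
    stop_twp("fewer rows than components", "twpscan_pca")
  }
  if (standardize) {
    params <- fit_standardization(as.data.frame(x))
    x <- as.matrix(apply_standardization(as.data.frame(x), params))
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  # sign convention: dominant loading of each component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  if ("material" %in% names(table)) {
    scores <- dplyr::bind_cols(tibble(material = table$material), scores)
  }
  structure(list(scores = scores,
                 loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 explained = explained, sdev = pc$sdev),
            class = "twp_pca")
}

#' @export
print.twp_pca <- function(x, ...) {
  cat("<twp_pca>", nrow(x$scores), "scores,",
      ncol(x$loadings), "components;",
      "explained:", paste(sprintf("%.1f%%", 100 * x$explained), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
tidy.twp_pca <- function(x, ...) {
  ld <- as_tibble(x$loadings)
  ld$feature <- rownames(x$loadings)
  tidyr::pivot_longer(ld, -"feature", names_to = "component",
                      values_to = "loading")
}

#' @export
glance.twp_pca <- function(x, ...) {
  tibble(n_components = ncol(x$loadings),
         explained_pc1 = x$explained[1],
         explained_pc2 = x$explained[2])
}

#' Ward hierarchical clustering of a fingerprint table
#'
#' Agglomerative clustering with Euclidean distances and Ward's minimum
#' variance linkage in the Ward.D2 convention (squared-Euclidean
#' Lance-Williams update, merge heights reported on the distance scale).
#'
#' @inheritParams fingerprint_pca
#' @return A `twp_hca` object wrapping the `hclust` fit with material leaf
#'   labels and the merge table.
#' @export
hca_ward <- function(table, standardize = TRUE) {
  x <- feature_matrix(table)
  if (nrow(x) < 2L) stop_twp("need at least 2 rows", "twpscan_hca")
  if (standardize) {
    params <- fit_standardization(as.data.frame(x))
    x <- as.matrix(apply_standardization(as.data.frame(x), params))
  }
  labels <- if ("material" %in% names(table)) {
    paste0(table$material, "_", ave(seq_len(nrow(table)), table$material,
                                    FUN = seq_along))
  } else as.character(seq_len(nrow(x)))
  rownames(x) <- labels
  hc <- hclust(dist(x), method = "ward.D2")
  merges <- tibble(step = seq_len(nrow(hc$merge)),
                   left = hc$merge[, 1], right = hc$merge[, 2],
                   height = hc$height)
  structure(list(hclust = hc, merges = merges, labels = labels,
                 material = if ("material" %in% names(table)) table$material else NULL),
            class = "twp_hca")
}

#' @export
print.twp_hca <- function(x, ...) {
  cat("<twp_hca>", length(x$labels), "leaves,",
      nrow(x$merges), "merges; max height", max(x$merges$height), "\n")
  invisible(x)
}

#' Leaf sets of the two root branches
#'
#' @param hca A [hca_ward()] result.
#' @return List of two character vectors of leaf labels (or materials when
#'   available), the two clusters obtained by cutting at the root.
#' @export
root_split <- function(hca) {
  ct <- cutree(hca$hclust, k = 2L)
  groups <- split(seq_along(ct), ct)
  lapply(groups, function(idx) {
    if (!is.null(hca$material)) unique(hca$material[idx]) else hca$labels[idx]
  })
}

#' Does a material form a pure subcluster?
#'
#' TRUE when some node of the dendrogram contains exactly the replicates of
#' `material` (equivalently, some `cutree` cut isolates them as one
#' cluster).
#'
#' @param hca A [hca_ward()] result built from a table with materials.
#' @param material Material name.
#' @return Logical.
#' @export
is_pure_subcluster <- function(hca, material) {
  stopifnot(!is.null(hca$material))
  target <- which(hca$material == material)
  n <- length(hca$material)
  for (k in seq_len(n)) {
    ct <- cutree(hca$hclust, k = k)
    kt <- ct[target]
    if (length(unique(kt)) == 1L && sum(ct == kt[1]) == length(target)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Export a dendrogram as Newick text
#'
#' @param hca A [hca_ward()] result.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to file).
#' @export
hca_newick <- function(hca, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop_twp("the ape package is required for Newick export", "twpscan_ape")
  }
  phy <- ape::as.phylo(hca$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Column-standardized fingerprint heatmap
#'
#' Column z-scores of the replicate table (identical to
#' [apply_standardization()] with parameters fitted on the same table) plus
#' the material-by-element mean matrix that the heatmap renders.
#'
#' @inheritParams fingerprint_pca
#' @return A `twp_heatmap` object: `z` (replicate-level z-score tibble),
#'   `material_means` (matrix, materials x elements).
#' @export
standardized_heatmap <- function(table) {
  x <- as.data.frame(feature_matrix(table))
  params <- fit_standardization(x)
  z <- as_tibble(apply_standardization(x, params))
  mm <- NULL
  if ("material" %in% names(table)) {
    zz <- z; zz$material <- table$material
    mm_df <- aggregate(. ~ material, data = as.data.frame(zz), FUN = mean)
    mm <- as.matrix(mm_df[, -1, drop = FALSE])
    rownames(mm) <- mm_df$material
  }
  structure(list(z = z, material_means = mm,
                 material = if ("material" %in% names(table)) table$material else NULL),
            class = "twp_heatmap")
}

#' @export
print.twp_heatmap <- function(x, ...) {
  cat("<twp_heatmap>", nrow(x$z), "rows x", ncol(x$z), "elements\n")
  invisible(x)
}
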