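# ggplot2 displays for images, biplots, dendrograms, heatmaps, error
# surfaces and classification overlays.

#' @export
autoplot.elemental_image <- function(object, isotopes = NULL, trans = "sqrt",
                                     ...) {
  isotopes <- isotopes %||% intersect(marker_isotopes(), object$isotopes)
  df <- as_tibble(object) %>% filter(.data$isotope %in% isotopes)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~isotope) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(trans = trans) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  fill = "normalized\nsignal")
}

#' PCA biplot of bulk fingerprints
#'
#' Scores colored by material with loading vectors overlaid on a
#' correlation-biplot scale (loadings scaled by the component standard
#' deviations).
#'
#' @param object A `twp_pca`.
#' @param components Two components to draw.
#' @param loading_scale Extra multiplier applied to the loading arrows.
#' @param ... Unused.
#' @export
autoplot.twp_pca <- function(object, components = c(1L, 2L),
                             loading_scale = 2, ...) {
  pcs <- paste0("PC", components)
  sc <- object$scores
  ld <- as.data.frame(object$loadings[, pcs, drop = FALSE])
  ld$feature <- rownames(object$loadings)
  for (i in seq_along(pcs)) {
    ld[[pcs[i]]] <- ld[[pcs[i]]] * object$sdev[components[i]] * loading_scale
  }
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data[[pcs[1]]], .data[[pcs[2]]]))
  if ("material" %in% names(sc)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$material),
                                 alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p +
    ggplot2::geom_segment(data = ld,
                          ggplot2::aes(x = 0, y = 0, xend = .data[[pcs[1]]],
                                       yend = .data[[pcs[2]]]),
                          arrow = ggplot2::arrow(length = grid::unit(2, "mm")),
                          color = "grey30") +
    ggplot2::geom_text(data = ld,
                       ggplot2::aes(label = .data$feature),
                       nudge_x = 0.15, nudge_y = 0.15, size = 3) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcs[1], 100 * object$explained[components[1]]),
      y = sprintf("%s (%.1f%%)", pcs[2], 100 * object$explained[components[2]]))
}

#' @export
autoplot.twp_hca <- function(object, ...) {
  hc <- object$hclust
  dend <- stats::as.dendrogram(hc)
  dd <- dendrogram_segments(dend)
  ggplot2::ggplot(dd$segments) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend)) +
    ggplot2::geom_text(data = dd$labels,
                       ggplot2::aes(x = .data$x, y = -0.02 * max(dd$segments$y),
                                    label = .data$label),
                       angle = 90, hjust = 1, size = 2) +
    ggplot2::scale_y_continuous("Ward.D2 merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.title.x = ggplot2::element_blank())
}

# flatten a dendrogram into plottable segments (small hand-rolled walker,
# avoids a ggdendro dependency)
dendrogram_segments <- function(dend) {
  segments <- list(); labels <- list()
  walk <- function(node) {
    if (is.leaf(node)) {
      x <- attr(node, "x") %||% 0
      labels[[length(labels) + 1L]] <<-
        tibble(x = x, label = attr(node, "label"))
      return(invisible(NULL))
    }
    h <- attr(node, "height")
    xs <- vapply(seq_along(node), function(i) {
      child <- node[[i]]
      attr(child, "midpoint_x") %||%
        (if (is.leaf(child)) attr(child, "x") else mean(child_span(child)))
    }, 0)
    for (i in seq_along(node)) {
      child <- node[[i]]
      ch <- attr(child, "height") %||% 0
      segments[[length(segments) + 1L]] <<-
        tibble(x = xs[i], y = h, xend = xs[i], yend = ch)
      walk(child)
    }
    segments[[length(segments) + 1L]] <<-
      tibble(x = min(xs), y = h, xend = max(xs), yend = h)
    invisible(NULL)
  }
  # assign leaf x positions in dendrogram order
  counter <- 0L
  assign_x <- function(node) {
    if (is.leaf(node)) {
      counter <<- counter + 1L
      attr(node, "x") <- counter
      return(node)
    }
    for (i in seq_along(node)) node[[i]] <- assign_x(node[[i]])
    node
  }
  dend <- assign_x(dend)
  walk(dend)
  list(segments = dplyr::bind_rows(segments),
       labels = dplyr::bind_rows(labels))
}

child_span <- function(node) {
  if (is.leaf(node)) return(rep(attr(node, "x"), 2L))
  range(unlist(lapply(seq_along(node), function(i) child_span(node[[i]]))))
}

#' @export
autoplot.twp_heatmap <- function(object, ...) {
  stopifnot(!is.null(object$material_means))
  mm <- object$material_means
  df <- as_tibble(mm)
  df$material <- rownames(mm)
  long <- tidyr::pivot_longer(df, -"material", names_to = "element",
                              values_to = "z")
  ggplot2::ggplot(long, ggplot2::aes(.data$element, .data$material,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(fill = "column\nz-score")
}

#' @export
autoplot.rf_opt <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(.data$n_trees, .data$r_value,
                               fill = .data$oob_error)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::annotate("point", x = object$best_n_trees,
                      y = object$best_r_value, shape = 4, color = "red") +
    ggplot2::labs(x = "number of trees", y = "R-value",
                  fill = "averaged\nOOB error")
}

#' Classification overlay plot
#'
#' Classified TWP pixels in a single highlight color over a grayscale
#' background map (the Zn channel by default), the standard way the
#' classification results are displayed over micrographs.
#'
#' @param image Normalized `elemental_image` used as the background.
#' @param mask Logical classification mask.
#' @param background_isotope Background channel.
#' @return A ggplot.
#' @export
plot_classification_overlay <- function(image, mask,
                                        background_isotope = "Zn64") {
  bg <- image$data[[background_isotope]]
  d <- dim(bg)
  df <- tibble(
    x_um = rep((seq_len(d[2]) - 0.5) * image$pitch_um, each = d[1]),
    y_um = rep((seq_len(d[1]) - 0.5) * image$pitch_um, times = d[2]),
    value = as.vector(bg), twp = as.vector(mask))
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_raster(data = df[df$twp, , drop = FALSE],
                         fill = "yellow") +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 trans = "sqrt") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "Zn signal")
}
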