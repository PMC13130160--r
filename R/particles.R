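# Classified masks -> particle records, the geometric detection-limit
# model, control-point registration, and truth-matched detection tables.

#' Label connected particles in a binary mask
#'
#' Connected-component labeling (8- or 4-connectivity) of the TWP mask.
#' Records are sorted by pixel count, largest first. The equivalent
#' circular diameter derives from the pixel area:
#' `2 * sqrt(n_pixels * pitch^2 / pi)`.
#'
#' @param mask Logical matrix.
#' @param pitch_um Pixel pitch (um).
#' @param connectivity 8 (default) or 4.
#' @return Tibble with `particle_id`, `n_pixels`, `centroid_x_um`,
#'   `centroid_y_um`, `eq_diameter_um`, bounding box columns; the label
#'   matrix is attached as attribute `"labels"`.
#' @export
label_particles <- function(mask, pitch_um = 7, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(c(-1L, 0L, 1L), 3L), rep(c(-1L, 0L, 1L), each = 3L))[-5L, ]
  }
  cur <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    labels[start] <- cur
    while (length(stack) > 0) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      si <- (s - 1L) %% nr + 1L; sj <- (s - 1L) %/% nr + 1L
      for (d in seq_len(nrow(nb))) {
        ni <- si + nb[d, 1]; nj <- sj + nb[d, 2]
        if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc &&
            mask[ni, nj] && labels[ni, nj] == 0L) {
          labels[ni, nj] <- cur
          stack <- c(stack, (nj - 1L) * nr + ni)
        }
      }
    }
  }
  if (cur == 0L) {
    out <- tibble(particle_id = integer(), n_pixels = integer(),
                  centroid_x_um = numeric(), centroid_y_um = numeric(),
                  eq_diameter_um = numeric(), bbox_row_min = integer(),
                  bbox_row_max = integer(), bbox_col_min = integer(),
                  bbox_col_max = integer())
    attr(out, "labels") <- labels
    return(out)
  }
  idx <- which(labels > 0L)
  li <- (idx - 1L) %% nr + 1L; lj <- (idx - 1L) %/% nr + 1L
  lab <- labels[idx]
  out <- tibble(
    particle_id = seq_len(cur),
    n_pixels = as.integer(tabulate(lab, cur)),
    centroid_x_um = as.numeric(tapply((lj - 0.5) * pitch_um, lab, mean)),
    centroid_y_um = as.numeric(tapply((li - 0.5) * pitch_um, lab, mean)),
    bbox_row_min = as.integer(tapply(li, lab, min)),
    bbox_row_max = as.integer(tapply(li, lab, max)),
    bbox_col_min = as.integer(tapply(lj, lab, min)),
    bbox_col_max = as.integer(tapply(lj, lab, max)))
  out$eq_diameter_um <- 2 * sqrt(out$n_pixels * pitch_um^2 / pi)
  out <- out[order(-out$n_pixels), c("particle_id", "n_pixels",
                                     "centroid_x_um", "centroid_y_um",
                                     "eq_diameter_um", "bbox_row_min",
                                     "bbox_row_max", "bbox_col_min",
                                     "bbox_col_max")]
  attr(out, "labels") <- labels
  out
}

#' Geometric minimum detectable particle diameter
#'
#' The smallest disk diameter guaranteeing that, for every raster
#' alignment, at least one laser shot is fully contained within the
#' particle. The laser fires quasi-continuously along each scan line (at
#' the imaging settings, one shot every 0.7 um versus a 7 um spot), so the
#' binding constraint is the across-scan line spacing: the disk center lies
#' within `pitch / 2` of some scan line, and a spot centered at the nearest
#' point of that line is fully contained iff
#' `diameter/2 >= spot/2 + pitch/2`. Hence
#' `min diameter = spot + pitch`, which equals twice the spot size at the
#' imaging settings (7 um spot, 7 um pitch): 14 um.
#'
#' @param spot_diameter_um Laser spot diameter (um).
#' @param pitch_um Line spacing / pixel pitch (um).
#' @return Minimum detectable diameter (um).
#' @export
min_detectable_diameter <- function(spot_diameter_um = 7, pitch_um = 7) {
  if (spot_diameter_um <= 0 || pitch_um <= 0) {
    stop_twp("spot diameter and pitch must be positive", "twpscan_geometry")
  }
  spot_diameter_um + pitch_um
}

#' Brute-force raster-offset sweep of the detection-limit geometry
#'
#' For `n_offsets` random raster alignments (line-grid offsets uniform over
#' one pitch cell), tests whether a disk of the given diameter contains at
#' least one fully contained circular spot footprint. Per offset the
#' candidate shot is placed at the closest point of each scan line crossing
#' the disk; containment is tested exactly.
#'
#' @param diameter_um Particle (disk) diameter.
#' @param spot_diameter_um,pitch_um Raster geometry.
#' @param n_offsets Number of random offsets (default 1e4).
#' @param seed Integer seed.
#' @return Fraction of offsets with at least one fully contained shot.
#' @export
containment_sweep <- function(diameter_um, spot_diameter_um = 7, pitch_um = 7,
                              n_offsets = 10000L, seed = 1L) {
  with_seed(seed, {
    off <- runif(n_offsets, 0, pitch_um)
    # distance from disk center (at 0) to the nearest raster line
    kmin <- floor(-off / pitch_um)
    d <- pmin(abs(off + kmin * pitch_um), abs(off + (kmin + 1) * pitch_um))
    reach <- (diameter_um - spot_diameter_um) / 2
    mean(diameter_um >= spot_diameter_um & d <= reach)
  })
}

#' Least-squares affine registration from control points
#'
#' Fits the 6-parameter affine transform mapping moving to fixed
#' coordinates by ordinary least squares over 3 or more non-collinear
#' control-point pairs (4-8 in routine use), the same landmark scheme used
#' to register elemental maps onto reference micrographs.
#'
#' @param control_points Tibble/data frame with columns `moving_x`,
#'   `moving_y`, `fixed_x`, `fixed_y`.
#' @return An `affine_transform`: 2x3 coefficient matrix `A` (columns
#'   intercept, x, y) and `rmse`, the root-mean-square residual distance.
#' @export
estimate_registration <- function(control_points) {
  cp <- control_points
  n <- nrow(cp)
  if (n < 3L) {
    stop_twp("need at least 3 control-point pairs", "twpscan_registration")
  }
  X <- cbind(1, cp$moving_x, cp$moving_y)
  if (qr(X)$rank < 3L) {
    stop_twp("control points are collinear", "twpscan_registration")
  }
  Y <- cbind(cp$fixed_x, cp$fixed_y)
  coefs <- qr.solve(X, Y)                 # 3 x 2
  resid <- Y - X %*% coefs
  rmse <- sqrt(mean(rowSums(resid^2) / 2))
  structure(list(A = t(coefs), rmse = rmse, n_points = n),
            class = "affine_transform")
}

#' Apply an affine transform to coordinates
#'
#' @param transform An [estimate_registration()] result.
#' @param xy Two-column matrix or data frame of (x, y) coordinates.
#' @return Matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, xy) {
  xy <- as.matrix(xy)
  X <- cbind(1, xy[, 1], xy[, 2])
  X %*% t(transform$A)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>", x$n_points, "points, RMSE", signif(x$rmse, 4), "\n")
  print(x$A)
  invisible(x)
}

# number of pixel centers whose spot footprint lies fully inside the truth
# disk, for the actual raster lattice of the phantom
count_interior_pixels <- function(particle_row, pitch_um, spot_um, nr, nc) {
  reach <- particle_row$diameter_um / 2 - spot_um / 2
  if (reach < 0) return(0L)
  ci <- particle_row$centroid_y_um; cj <- particle_row$centroid_x_um
  ii <- ((seq_len(nr) - 0.5) * pitch_um - ci)
  jj <- ((seq_len(nc) - 0.5) * pitch_um - cj)
  sum(outer(ii^2, jj^2, `+`) <= reach^2)
}

#' Mask of fully interior truth pixels
#'
#' Pixels whose circular spot footprint lies entirely inside some truth
#' particle of the requested material; these are the "pure" pixels the
#' classifier is trained on and the basis of the recall figure of merit.
#'
#' @param phantom A [build_phantom()] result.
#' @param spot_um Spot diameter.
#' @param material Material to restrict to (default `"TWP"`).
#' @return Logical matrix.
#' @export
interior_pixel_mask <- function(phantom, spot_um = 7, material = "TWP") {
  nr <- nrow(phantom$label_grid); nc <- ncol(phantom$label_grid)
  pitch <- phantom$pitch_um
  out <- matrix(FALSE, nr, nc)
  pt <- phantom$particle_table
  pt <- pt[pt$material == material, , drop = FALSE]
  for (p in seq_len(nrow(pt))) {
    reach <- pt$diameter_um[p] / 2 - spot_um / 2
    if (reach < 0) next
    d2 <- outer(((seq_len(nr) - 0.5) * pitch - pt$centroid_y_um[p])^2,
                ((seq_len(nc) - 0.5) * pitch - pt$centroid_x_um[p])^2, `+`)
    out <- out | (d2 <= reach^2)
  }
  out
}

#' Truth mask of a phantom
#'
#' @param phantom A [build_phantom()] result.
#' @param material Material (default `"TWP"`).
#' @return Logical matrix, TRUE where the label grid belongs to a particle
#'   of the material.
#' @export
truth_mask <- function(phantom, material = "TWP") {
  ids <- phantom$particle_table$particle_id[
    phantom$particle_table$material == material]
  matrix(phantom$label_grid %in% ids,
         nrow(phantom$label_grid), ncol(phantom$label_grid))
}

#' Match detected particles to ground truth
#'
#' Matches every truth particle to the predicted particle with maximal
#' pixel overlap. A truth particle counts as detected when at least one
#' predicted pixel lies inside it (`min_overlap_px = 1`); the table also
#' reports whether the particle satisfies the geometric detectability
#' criterion (at least one pixel with a fully interior spot footprint).
#'
#' @param particles A [label_particles()] result (with its label matrix
#'   attribute).
#' @param phantom The ground-truth phantom.
#' @param spot_um Spot diameter for the interior-pixel criterion.
#' @param min_overlap_px Minimum overlapping pixels to count as detected.
#' @param material Truth material to evaluate.
#' @return Tibble per truth particle: `truth_id`, `material`,
#'   `diameter_um`, `n_true_pixels`, `n_overlap_pixels`,
#'   `matched_particle_id`, `detected`, `interior_pixels`, `detectable`.
#' @export
evaluate_detection <- function(particles, phantom, spot_um = 7,
                               min_overlap_px = 1L, material = "TWP") {
  labels <- attr(particles, "labels")
  stopifnot(!is.null(labels),
            identical(dim(labels), dim(phantom$label_grid)))
  pt <- phantom$particle_table
  pt <- pt[pt$material == material, , drop = FALSE]
  nr <- nrow(labels); nc <- ncol(labels)
  purrr::map_dfr(seq_len(nrow(pt)), function(p) {
    tid <- pt$particle_id[p]
    inside <- phantom$label_grid == tid
    overl <- labels[inside]
    overl <- overl[overl > 0L]
    if (length(overl) > 0) {
      tab <- tabulate(overl)
      matched <- which.max(tab)
      n_over <- max(tab)
    } else {
      matched <- NA_integer_; n_over <- 0L
    }
    interior <- count_interior_pixels(pt[p, ], phantom$pitch_um, spot_um,
                                      nr, nc)
    tibble(truth_id = tid, material = pt$material[p],
           diameter_um = pt$diameter_um[p],
           n_true_pixels = sum(inside),
           n_overlap_pixels = as.integer(n_over),
           matched_particle_id = matched,
           detected = n_over >= min_overlap_px,
           interior_pixels = as.integer(interior),
           detectable = interior >= 1L)
  })
}
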