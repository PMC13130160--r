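# Phantom scenes: ground-truth material label grids with per-particle
# realized fingerprints. Label 0 = paraffin, 1 = gut tissue, >= 2 = particles.

#' Scene configuration
#'
#' Builds the configuration list consumed by [build_phantom()]. Defaults per
#' scene kind reproduce the study's sample types: `"twp_in_paraffin"` (the
#' classifier training/test scene), `"blank_gut"` (gut tissue with biogenic
#' hotspots and feed-like confounder particles, no TWPs) and `"twp_in_gut"`
#' (TWPs placed inside the gut region alongside confounders).
#'
#' Particle diameters are drawn from a truncated normal with mean 80 and sd
#' 39 um, truncated to 14-355 um, matching the administered TWP size
#' distribution (80 +/- 39 um).
#'
#' @param scene One of `"twp_in_paraffin"`, `"blank_gut"`, `"twp_in_gut"`.
#' @param n_rows,n_cols Grid size in pixels.
#' @param pitch_um Pixel pitch in micrometers (default 7).
#' @param n_particles Number of TWPs.
#' @param n_confounders Number of feed-like confounder particles (gut scenes).
#' @param diameter_mean_um,diameter_sd_um,diameter_range_um TWP diameter
#'   distribution (truncated normal).
#' @param gut_semiaxes Fractions of the grid half-extent spanned by the
#'   elliptical gut region (gut scenes only).
#' @param hotspots Logical; add element-specific biogenic hotspot fields
#'   (Zn, Ti, Pb) to the gut tissue.
#' @return A `scene_config` list.
#' @export
scene_config <- function(scene = c("twp_in_paraffin", "blank_gut", "twp_in_gut"),
                         n_rows = NULL, n_cols = NULL, pitch_um = 7,
                         n_particles = NULL, n_confounders = NULL,
                         diameter_mean_um = 80, diameter_sd_um = 39,
                         diameter_range_um = c(14, 355),
                         gut_semiaxes = c(0.80, 0.64),
                         hotspots = TRUE) {
  scene <- arg_match(scene)
  defaults <- switch(scene,
    twp_in_paraffin = list(n_rows = 150, n_cols = 150, n_particles = 60,
                           n_confounders = 0),
    blank_gut       = list(n_rows = 100, n_cols = 100, n_particles = 0,
                           n_confounders = 6),
    twp_in_gut      = list(n_rows = 120, n_cols = 120, n_particles = 12,
                           n_confounders = 6)
  )
  cfg <- list(
    scene = scene,
    n_rows = n_rows %||% defaults$n_rows,
    n_cols = n_cols %||% defaults$n_cols,
    pitch_um = pitch_um,
    n_particles = n_particles %||% defaults$n_particles,
    n_confounders = n_confounders %||% defaults$n_confounders,
    diameter_mean_um = diameter_mean_um,
    diameter_sd_um = diameter_sd_um,
    diameter_range_um = diameter_range_um,
    confounder_diameter = list(mean = 40, sd = 15, range = c(14, 120)),
    gut_semiaxes = gut_semiaxes,
    hotspots = hotspots,
    # element-specific biogenic hotspot gains relative to gut base levels
    hotspot_gain = c(Zn64 = 25, Ti48 = 6, Pb208 = 5),
    n_hotspots = c(Zn64 = 10, Ti48 = 5, Pb208 = 5)
  )
  structure(cfg, class = "scene_config")
}

rtruncnorm1 <- function(n, mean, sd, range) {
  if (sd <= 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * n, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

# squared distance of every pixel center to a point (in pixel units)
pixel_dist2 <- function(n_rows, n_cols, ci, cj) {
  di <- (seq_len(n_rows) - 0.5) - ci
  dj <- (seq_len(n_cols) - 0.5) - cj
  outer(di^2, dj^2, `+`)
}

#' Build a ground-truth phantom scene
#'
#' Places non-overlapping circular particles uniformly inside the allowed
#' region (the whole grid for paraffin scenes, the gut ellipse for gut
#' scenes), draws each particle's realized multielement levels once from its
#' material fingerprint (Bernoulli marker presence times a lognormal level),
#' and, for gut scenes, lays down a smooth biogenic modulation plus
#' element-specific hotspot fields so that single elements (Zn, Ti, Pb) reach
#' TWP-like signal levels somewhere in the blank tissue.
#'
#' Particles are placed largest-first; placement fails with an error if a
#' particle cannot be placed without overlap within 1000 attempts.
#'
#' @param config A [scene_config()].
#' @param fingerprints Fingerprint table, see [default_fingerprints()].
#' @param seed Integer seed; the phantom is bit-reproducible given
#'   (config, seed).
#' @return A `phantom` object: `label_grid` (integer matrix; 0 paraffin,
#'   1 gut, >= 2 particle ids), `particle_table` (one row per particle with
#'   realized per-isotope levels), `gut_multiplier` (per-isotope tissue
#'   modulation matrices), `pitch_um`, `scene`.
#' @export
build_phantom <- function(config, fingerprints = default_fingerprints(),
                          seed = 1L) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(seed, build_phantom_impl(config, fingerprints))
}

build_phantom_impl <- function(config, fingerprints) {
  nr <- config$n_rows; nc <- config$n_cols; pitch <- config$pitch_um
  label <- matrix(0L, nr, nc)
  in_gut <- config$scene %in% c("blank_gut", "twp_in_gut")

  gut_mask <- NULL
  if (in_gut) {
    ci <- nr / 2; cj <- nc / 2
    ry <- config$gut_semiaxes[2] * nr / 2
    rx <- config$gut_semiaxes[1] * nc / 2
    di <- ((seq_len(nr) - 0.5) - ci) / ry
    dj <- ((seq_len(nc) - 0.5) - cj) / rx
    gut_mask <- outer(di^2, dj^2, `+`) <= 1
    label[gut_mask] <- 1L
  }

  # particle specs: TWPs then confounders, placed largest-first
  spec <- tibble(
    material = c(rep("TWP", config$n_particles),
                 rep("hikari_feed", config$n_confounders)),
    diameter_um = c(
      rtruncnorm1(config$n_particles, config$diameter_mean_um,
                  config$diameter_sd_um, config$diameter_range_um),
      rtruncnorm1(config$n_confounders, config$confounder_diameter$mean,
                  config$confounder_diameter$sd,
                  config$confounder_diameter$range))
  )
  spec <- spec[order(-spec$diameter_um), , drop = FALSE]

  placed <- vector("list", nrow(spec))
  if (nrow(spec) > 0) {
    for (p in seq_len(nrow(spec))) {
      r_px <- spec$diameter_um[p] / 2 / pitch
      ok <- FALSE
      for (attempt in seq_len(1000L)) {
        if (in_gut) {
          ci <- runif(1, 0, nr); cj <- runif(1, 0, nc)
          ii <- pmin(pmax(ceiling(ci), 1L), nr)
          jj <- pmin(pmax(ceiling(cj), 1L), nc)
          if (!gut_mask[ii, jj]) next
        } else {
          ci <- runif(1, r_px, nr - r_px); cj <- runif(1, r_px, nc - r_px)
        }
        clash <- FALSE
        if (p > 1) {
          for (q in seq_len(p - 1L)) {
            pq <- placed[[q]]
            if ((ci - pq$ci)^2 + (cj - pq$cj)^2 <
                (r_px + pq$r_px)^2) { clash <- TRUE; break }
          }
        }
        if (!clash) { placed[[p]] <- list(ci = ci, cj = cj, r_px = r_px); ok <- TRUE; break }
      }
      if (!ok) {
        stop_twp(paste0("could not place particle ", p,
                        " without overlap in 1000 attempts (scene too crowded)"),
                 "twpscan_overcrowded")
      }
    }
  }

  # paint particles and draw realized levels
  iso <- TWP_ISOTOPES
  lev_mat <- matrix(0, nrow(spec), length(iso), dimnames = list(NULL, iso))
  for (p in seq_len(nrow(spec))) {
    pq <- placed[[p]]
    inside <- pixel_dist2(nr, nc, pq$ci, pq$cj) <= pq$r_px^2
    label[inside] <- p + 1L
    lev_mat[p, ] <- draw_realized_levels(fingerprints, spec$material[p])
  }

  particle_table <- tibble(
    particle_id = seq_len(nrow(spec)) + 1L,
    material = spec$material,
    centroid_x_um = vapply(placed, function(p) p$cj * pitch, 0)[seq_len(nrow(spec))],
    centroid_y_um = vapply(placed, function(p) p$ci * pitch, 0)[seq_len(nrow(spec))],
    diameter_um = spec$diameter_um
  )
  if (nrow(spec) == 0) {
    particle_table <- tibble(particle_id = integer(), material = character(),
                             centroid_x_um = numeric(), centroid_y_um = numeric(),
                             diameter_um = numeric())
    lev_mat <- matrix(0, 0, length(iso), dimnames = list(NULL, iso))
  }
  for (k in iso) particle_table[[paste0("level_", k)]] <- lev_mat[, k]

  # biogenic tissue modulation: smooth broad field plus element hotspots
  gut_mult <- NULL
  if (in_gut) {
    gut_mult <- setNames(vector("list", length(iso)), iso)
    base_mod <- matrix(1, nr, nc)
    for (b in seq_len(3L)) {
      bi <- runif(1, 0.2 * nr, 0.8 * nr); bj <- runif(1, 0.2 * nc, 0.8 * nc)
      sig <- runif(1, 0.2, 0.4) * min(nr, nc)
      amp <- runif(1, -0.08, 0.08)
      base_mod <- base_mod + amp * exp(-pixel_dist2(nr, nc, bi, bj) / (2 * sig^2))
    }
    for (k in iso) gut_mult[[k]] <- base_mod
    if (isTRUE(config$hotspots)) {
      # hotspot centers of different elements are kept apart: the biogenic
      # enrichments (Zn-rich epithelium, Ca-rich calcified spots seen on the
      # interfered 48Ti channel, Pb deposits) are distinct tissue structures,
      # so no gut pixel carries a TWP-like multielement co-elevation
      centers <- lapply(names(config$hotspot_gain), function(k) {
        matrix(numeric(0), 0, 2)
      })
      names(centers) <- names(config$hotspot_gain)
      for (k in names(config$hotspot_gain)) {
        h <- matrix(0, nr, nc)
        others <- do.call(rbind, centers[setdiff(names(centers), k)])
        for (s in seq_len(config$n_hotspots[[k]])) {
          placed_ok <- FALSE
          for (try in seq_len(500L)) {
            hi <- runif(1, 0, nr); hj <- runif(1, 0, nc)
            ii <- pmin(pmax(ceiling(hi), 1L), nr)
            jj <- pmin(pmax(ceiling(hj), 1L), nc)
            if (!gut_mask[ii, jj]) next
            if (is.null(others) || nrow(others) == 0 ||
                min((others[, 1] - hi)^2 + (others[, 2] - hj)^2) > 12^2) {
              placed_ok <- TRUE
              break
            }
          }
          if (!placed_ok) next   # skip rather than violate the separation
          centers[[k]] <- rbind(centers[[k]], c(hi, hj))
          sig <- if (k == "Zn64") runif(1, 3, 6) else runif(1, 2, 4)
          h <- h + exp(-pixel_dist2(nr, nc, hi, hj) / (2 * sig^2))
        }
        gut_mult[[k]] <- gut_mult[[k]] * (1 + config$hotspot_gain[[k]] * pmin(h, 1))
      }
    }
  }

  structure(
    list(label_grid = label, particle_table = particle_table,
         gut_multiplier = gut_mult, pitch_um = pitch, scene = config$scene,
         config = config),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>", x$scene, ":", nrow(x$label_grid), "x", ncol(x$label_grid),
      "px @", x$pitch_um, "um;", nrow(x$particle_table), "particles\n")
  invisible(x)
}

# Per-isotope expected ablation level (counts/cycle, before background and
# footprint averaging) at every pixel.
phantom_level_maps <- function(phantom, fingerprints = default_fingerprints()) {
  nr <- nrow(phantom$label_grid); nc <- ncol(phantom$label_grid)
  iso <- TWP_ISOTOPES
  par_lev <- median_levels(fingerprints, "paraffin")
  gut_lev <- median_levels(fingerprints, "gut_tissue")
  out <- setNames(vector("list", length(iso)), iso)
  lab <- phantom$label_grid
  pt <- phantom$particle_table
  for (k in iso) {
    m <- matrix(par_lev[[k]], nr, nc)
    if (any(lab == 1L)) {
      g <- gut_lev[[k]] * phantom$gut_multiplier[[k]]
      m[lab == 1L] <- g[lab == 1L]
    }
    if (nrow(pt) > 0) {
      lv <- pt[[paste0("level_", k)]]
      idx <- lab >= 2L
      m[idx] <- lv[lab[idx] - 1L]
    }
    out[[k]] <- m
  }
  out
}

#' Footprint-averaged expected elemental image of a phantom
#'
#' The per-pixel expected signal seen by the instrument: the material level
#' map averaged over the circular laser-spot footprint centered at each pixel
#' center, plus the per-isotope gas-blank background. When the spot diameter
#' does not exceed the pixel pitch the footprint lies inside its own pixel
#' and the average is the pixel's own level.
#'
#' @param phantom A [build_phantom()] result.
#' @param raster_params A [raster_params()] object.
#' @param fingerprints Fingerprint table.
#' @param background Named per-isotope background rate (counts/cycle);
#'   defaults to [default_noise()]'s background.
#' @return Named list of matrices (one per monitored isotope).
#' @export
phantom_expectation <- function(phantom, raster_params,
                                fingerprints = default_fingerprints(),
                                background = default_noise()$background) {
  levels <- phantom_level_maps(phantom, fingerprints)
  spot <- raster_params$spot_um; pitch <- phantom$pitch_um
  out <- lapply(levels, footprint_average, spot = spot, pitch = pitch)
  for (k in names(out)) out[[k]] <- out[[k]] + (background[[k]] %||% 0)
  out
}

# Area-averaged level over a circular spot footprint centered at each pixel
# center. Sampled on a fixed sub-pixel point grid; exact (identity) whenever
# spot <= pitch because the footprint then stays inside its own pixel.
footprint_average <- function(level_matrix, spot, pitch) {
  if (spot <= pitch) return(level_matrix)
  r <- spot / 2 / pitch                 # footprint radius in pixel units
  step <- 0.25
  off <- seq(-r, r, by = step)
  pts <- expand.grid(di = off, dj = off)
  pts <- pts[pts$di^2 + pts$dj^2 <= r^2, , drop = FALSE]
  nr <- nrow(level_matrix); nc <- ncol(level_matrix)
  acc <- matrix(0, nr, nc)
  for (p in seq_len(nrow(pts))) {
    si <- pmin(pmax(seq_len(nr) + round(pts$di[p]), 1L), nr)
    sj <- pmin(pmax(seq_len(nc) + round(pts$dj[p]), 1L), nc)
    acc <- acc + level_matrix[si, sj, drop = FALSE]
  }
  acc / nrow(pts)
}
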