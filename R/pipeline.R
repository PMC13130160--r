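# End-to-end convenience wrappers: scene -> acquisition -> normalized image,
# and the full train/apply detection workflow.

#' Simulate and reconstruct one scene
#'
#' Builds a phantom, simulates the gas blank, bracketing NIST612 standards
#' and the rastered acquisition, then reconstructs the normalized elemental
#' image through the standard chain (background correction, Au line-marker
#' alignment, NIST normalization).
#'
#' @param config A [scene_config()] (or a scene kind string).
#' @param seed Integer seed; all stochastic steps derive child seeds from
#'   it.
#' @param fingerprints Fingerprint table.
#' @param raster A [raster_params()]; pitch must match the scene.
#' @param noise A [default_noise()] list.
#' @param drift Closing-standard drift relative to the opening standard.
#' @return List with `phantom`, `image` (normalized `elemental_image`),
#'   `record` (normalization record), `sim` (raw run + log).
#' @export
simulate_scene_image <- function(config, seed = 1L,
                                 fingerprints = default_fingerprints(),
                                 raster = raster_params(),
                                 noise = default_noise(), drift = 1.05) {
  if (is.character(config)) config <- scene_config(config)
  phantom <- build_phantom(config, fingerprints, seed = child_seed(seed, 1L))
  blank <- simulate_gas_blank(noise = noise, seed = child_seed(seed, 2L))
  std_b <- simulate_standard(drift_factor = 1, noise = noise,
                             seed = child_seed(seed, 3L))
  std_a <- simulate_standard(drift_factor = drift, noise = noise,
                             seed = child_seed(seed, 4L))
  sim <- simulate_raster(phantom, raster, fingerprints, noise,
                         seed = child_seed(seed, 5L))
  rec <- reconstruct_image(sim, blank, std_b, std_a)
  list(phantom = phantom, image = rec$image, record = rec$record, sim = sim)
}

#' Train the TWP pixel classifier from simulated training scenes
#'
#' The training design of the study: class-1 pixels from a TWP-in-paraffin
#' scene (Zn pixels above `0.75 * P95`), class-2 pixels from a blank-gut
#' scene, 4000 per class, six standardized marker features, then the
#' row-subsampled random forest.
#'
#' @param seed Integer seed driving both scene simulations and the pixel
#'   draws.
#' @param config An [rf_config()].
#' @param n_per_class Training pixels per class.
#' @param fingerprints Fingerprint table.
#' @param noise A [default_noise()] list.
#' @return List with `classifier`, `pixel_set`, `train_twp`
#'   and `train_blank` (each a [simulate_scene_image()] result).
#' @export
train_twp_classifier <- function(seed = 1L, config = rf_config(),
                                 n_per_class = 4000L,
                                 fingerprints = default_fingerprints(),
                                 noise = default_noise()) {
  train_twp <- simulate_scene_image("twp_in_paraffin",
                                    seed = child_seed(seed, 101L),
                                    fingerprints = fingerprints, noise = noise)
  train_blank <- simulate_scene_image("blank_gut",
                                      seed = child_seed(seed, 102L),
                                      fingerprints = fingerprints,
                                      noise = noise)
  pixel_set <- extract_training_pixels(train_twp$image, train_blank$image,
                                       n_per_class = n_per_class,
                                       seed = child_seed(seed, 103L))
  classifier <- fit_forest(pixel_set, config)
  list(classifier = classifier, pixel_set = pixel_set,
       train_twp = train_twp, train_blank = train_blank)
}

#' Detect and size TWPs in an elemental image
#'
#' Classifies every pixel, labels connected components and, when the
#' ground-truth phantom is supplied, appends the truth-matched detection
#' table.
#'
#' @param classifier A trained `twp_classifier`.
#' @param image Normalized `elemental_image`.
#' @param phantom Optional ground-truth phantom.
#' @param connectivity Particle connectivity (default 8).
#' @return List with `mask`, `particles`, and (with truth) `detection`.
#' @export
detect_particles <- function(classifier, image, phantom = NULL,
                             connectivity = 8) {
  mask <- classify_image(classifier, image)
  particles <- label_particles(mask, pitch_um = image$pitch_um,
                               connectivity = connectivity)
  out <- list(mask = mask, particles = particles)
  if (!is.null(phantom)) {
    out$detection <- evaluate_detection(particles, phantom)
  }
  out
}
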