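test_that("connected-component labeling sizes particles correctly", {
  expect_equal(nrow(label_particles(matrix(FALSE, 4, 4))), 0L)
  # one 3x3 block at 7 um pitch: 9 pixels, equivalent diameter 23.68 um
  m <- matrix(FALSE, 8, 8)
  m[3:5, 3:5] <- TRUE
  p <- label_particles(m, pitch_um = 7)
  expect_equal(nrow(p), 1L)
  expect_equal(p$n_pixels, 9L)
  expect_equal(p$eq_diameter_um, 2 * sqrt(9 * 49 / pi))
  expect_equal(p$eq_diameter_um, 23.68, tolerance = 1e-3)
  # centroid at the block center
  expect_equal(p$centroid_x_um, 3.5 * 7)
  expect_equal(p$centroid_y_um, 3.5 * 7)
})

test_that("connectivity semantics distinguish diagonal touches", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(nrow(label_particles(m, connectivity = 8)), 1L)
  expect_equal(nrow(label_particles(m, connectivity = 4)), 2L)
})

test_that("particle pixel counts partition the mask", {
  withr::with_seed(8, m <- matrix(runif(900) > 0.7, 30, 30))
  p <- label_particles(m)
  expect_equal(sum(p$n_pixels), sum(m))
  labels <- attr(p, "labels")
  expect_equal(sum(labels > 0), sum(m))
})

test_that("geometric detection limit is twice the spot size at equal pitch", {
  expect_equal(min_detectable_diameter(7, 7), 14)
  for (s in c(0.5, 3, 7, 21)) {
    expect_equal(min_detectable_diameter(s, s), 2 * s)
  }
  expect_error(min_detectable_diameter(-1, 7), class = "twpscan_geometry")
})

test_that("brute-force offset sweep confirms the closed-form limit", {
  # a 14 um disk always contains a fully interior 7 um shot; 10 um fails
  expect_equal(containment_sweep(14, 7, 7, n_offsets = 10000, seed = 1), 1)
  expect_lt(containment_sweep(10, 7, 7, n_offsets = 10000, seed = 1), 1)
  # closed form vs sweep across random spot/pitch combinations (pitch <= spot)
  withr::with_seed(21, {
    for (i in 1:20) {
      spot <- runif(1, 2, 40)
      pitch <- runif(1, 0.2, 1) * spot
      d <- min_detectable_diameter(spot, pitch)
      expect_equal(containment_sweep(d + 1e-9, spot, pitch,
                                     n_offsets = 2000, seed = i), 1)
      expect_lt(containment_sweep(0.9 * d, spot, pitch,
                                  n_offsets = 2000, seed = i), 1)
    }
  })
})

test_that("affine registration recovers exact and noisy transforms", {
  A <- matrix(c(4, 1.1, 0.12, -2, -0.08, 0.95), 2, 3, byrow = TRUE)
  withr::with_seed(31, {
    mov <- cbind(runif(4, 0, 200), runif(4, 0, 200))
  })
  fixed <- cbind(1, mov) %*% t(A)
  cp <- tibble::tibble(moving_x = mov[, 1], moving_y = mov[, 2],
                       fixed_x = fixed[, 1], fixed_y = fixed[, 2])
  tf <- estimate_registration(cp)
  expect_equal(tf$A, A, tolerance = 1e-9)
  expect_lt(tf$rmse, 1e-9)
  # identity points give the identity transform
  cpi <- tibble::tibble(moving_x = c(0, 10, 3, 7), moving_y = c(0, 2, 9, 5),
                        fixed_x = c(0, 10, 3, 7), fixed_y = c(0, 2, 9, 5))
  ti <- estimate_registration(cpi)
  expect_equal(ti$A, matrix(c(0, 1, 0, 0, 0, 1), 2, 3, byrow = TRUE),
               tolerance = 1e-9)
  got <- apply_transform(tf, mov)
  expect_equal(got, fixed, tolerance = 1e-9, ignore_attr = TRUE)
  # collinear and insufficient points error
  bad <- tibble::tibble(moving_x = c(0, 1, 2, 3), moving_y = c(0, 1, 2, 3),
                        fixed_x = 1:4, fixed_y = 1:4)
  expect_error(estimate_registration(bad), class = "twpscan_registration")
  expect_error(estimate_registration(cpi[1:2, ]),
               class = "twpscan_registration")
})

test_that("registration RMSE scales as sigma * sqrt(1 - p/n)", {
  # 8 points, 16 coordinate observations, 6 parameters per fit
  A <- matrix(c(0, 1, 0, 0, 0, 1), 2, 3, byrow = TRUE)
  sigma <- 2
  rmses <- withr::with_seed(17, vapply(1:400, function(i) {
    mov <- cbind(runif(8, 0, 500), runif(8, 0, 500))
    fixed <- mov + matrix(rnorm(16, 0, sigma), 8, 2)
    cp <- tibble::tibble(moving_x = mov[, 1], moving_y = mov[, 2],
                         fixed_x = fixed[, 1], fixed_y = fixed[, 2])
    estimate_registration(cp)$rmse
  }, 0))
  expect_equal(sqrt(mean(rmses^2)), sigma * sqrt(1 - 6 / 16),
               tolerance = 0.05)
})

test_that("detection evaluation matches by overlap and flags detectability", {
  ph <- build_phantom(small_twp_config(), seed = 9)
  # perfect prediction: the truth mask itself
  tm <- truth_mask(ph)
  p <- label_particles(tm, pitch_um = ph$pitch_um)
  det <- evaluate_detection(p, ph)
  expect_equal(nrow(det), nrow(ph$particle_table))
  expect_true(all(det$detected[det$n_true_pixels > 0]))
  # zero overlap: everything missed
  p0 <- label_particles(matrix(FALSE, nrow(tm), ncol(tm)),
                        pitch_um = ph$pitch_um)
  det0 <- evaluate_detection(p0, ph)
  expect_false(any(det0$detected))
  # geometric criterion consistent with the interior-pixel count
  expect_equal(det$detectable, det$interior_pixels >= 1L)
  # particles well above the limit always carry interior pixels
  expect_true(all(det$interior_pixels[det$diameter_um >= 21] >= 1L))
})

test_that("detection probability is nondecreasing in particle diameter", {
  tr <- default_training()
  diam <- c(7, 10, 14, 21, 35, 80)
  hits <- matrix(0, length(diam), 2, dimnames = list(diam, c("det", "n")))
  for (s in 1:6) {
    for (di in seq_along(diam)) {
      cfg <- scene_config("twp_in_paraffin", n_rows = 60, n_cols = 60,
                          n_particles = 5, diameter_mean_um = diam[di],
                          diameter_sd_um = 0,
                          diameter_range_um = c(diam[di], diam[di]))
      sc <- simulate_scene_image(cfg, seed = 5000 + 37 * s + di)
      mask <- classify_image(tr$classifier, sc$image)
      p <- label_particles(mask, pitch_um = sc$image$pitch_um)
      det <- evaluate_detection(p, sc$phantom)
      hits[di, "det"] <- hits[di, "det"] + sum(det$detected)
      hits[di, "n"] <- hits[di, "n"] + nrow(det)
    }
  }
  prob <- hits[, "det"] / hits[, "n"]
  se <- sqrt(pmax(prob * (1 - prob), 0.01) / hits[, "n"])
  for (i in seq_len(length(diam) - 1)) {
    expect_gte(prob[i + 1], prob[i] - 2 * (se[i] + se[i + 1]))
  }
  # large particles are essentially always found, sub-limit ones rarely
  expect_gt(prob[length(diam)], 0.95)
  expect_lt(prob[1], prob[length(diam)])
})
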