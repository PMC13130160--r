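test_that("two Au spike groups are detected per line", {
  cfg <- scene_config("twp_in_paraffin", n_rows = 10, n_cols = 30,
                      n_particles = 0)
  ph <- build_phantom(cfg, seed = 1)
  sim <- simulate_raster(ph, noise = noise_off(), seed = 1)
  b <- detect_line_boundaries(sim$run, blank_mean = 0, blank_sd = 1)
  expect_equal(nrow(b), 20L)
  # zero-amplitude marker spikes are a degenerate input
  dead <- sim$run
  dead$Au197 <- rep(0, nrow(dead))
  expect_error(detect_line_boundaries(dead, blank_mean = 0, blank_sd = 1),
               class = "twpscan_no_spikes")
})

test_that("boundary estimates land within one cycle of the truth", {
  worst <- 0
  for (s in 1:25) {
    cfg <- scene_config("twp_in_paraffin", n_rows = 8, n_cols = 25,
                        n_particles = 0)
    ph <- build_phantom(cfg, seed = s)
    sim <- simulate_raster(ph, seed = s)          # Poisson noise on
    blank <- simulate_gas_blank(seed = 100 + s)
    run <- background_correct(sim$run, blank)
    b <- detect_line_boundaries(run, blank_mean = 0, blank_sd = 1)
    starts <- b$cycle[seq(1, nrow(b), by = 2)]
    truth <- round(sim$log$t_start_s / attr(sim$run, "cycle_time_s"))
    worst <- max(worst, max(abs(starts - truth)))
  }
  expect_lte(worst, 1)
})

test_that("log alignment recovers injected clock offsets", {
  ph <- build_phantom(small_twp_config(), seed = 2)
  sim <- simulate_raster(ph, noise = noise_off(), seed = 2)
  b <- detect_line_boundaries(sim$run, blank_mean = 0, blank_sd = 1)
  dt <- attr(sim$run, "cycle_time_s")
  seg0 <- align_log(sim$log, b, dt)
  expect_equal(attr(seg0, "offset_s"), 0, tolerance = 1e-9)
  expect_equal(seg0$first_cycle,
               as.integer(round(sim$log$t_start_s / dt)))
  # +0.35 s global shift on the log clock
  shifted <- sim$log
  shifted$t_start_s <- shifted$t_start_s + 0.35
  shifted$t_end_s <- shifted$t_end_s + 0.35
  seg1 <- align_log(shifted, b, dt)
  expect_lt(abs(attr(seg1, "offset_s") - 0.35), dt / 2)
  expect_equal(seg1$first_cycle, seg0$first_cycle)  # same cycles recovered
})

test_that("pixels per line derive from floor(line_length / pitch)", {
  log <- tibble::tibble(line_id = 1, t_start_s = 2, t_end_s = 2 + 5000 / 700,
                        x0_um = 0, y0_um = 0, x1_um = 5000, y1_um = 0)
  b <- tibble::tibble(boundary_id = 1:2, cycle = c(20, 90), n_cycles = 1)
  seg <- align_log(log, b, cycle_time_s = 0.1)
  expect_equal(seg$last_cycle - seg$first_cycle + 1L, 71L)
})

test_that("noise-free simulate then reconstruct matches the phantom exactly", {
  ph <- build_phantom(small_twp_config(), seed = 4)
  nz <- noise_off()
  sim <- simulate_raster(ph, noise = nz, seed = 4)
  blank <- simulate_gas_blank(noise = nz, seed = 5)
  run <- background_correct(sim$run, blank)
  b <- detect_line_boundaries(run, blank_mean = 0, blank_sd = 1)
  seg <- align_log(sim$log, b, attr(sim$run, "cycle_time_s"))
  img <- build_maps(run, seg)
  zero_bg <- setNames(rep(0, 8), monitored_isotopes())
  expected <- phantom_expectation(ph, raster_params(), background = zero_bg)
  for (k in marker_isotopes()) {
    expect_identical(dim(img$data[[k]]), dim(expected[[k]]))
    expect_lt(max(abs(img$data[[k]] - expected[[k]])), 1e-9)
  }
  # map shape contract
  expect_equal(dim(img$data$Zn64), dim(ph$label_grid))
})

test_that("washout-on reconstruction deviates by at most the kernel tail", {
  ph <- build_phantom(small_twp_config(), seed = 4)
  nz <- default_noise(poisson = FALSE, washout = TRUE)
  sim <- simulate_raster(ph, noise = nz, seed = 4)
  blank <- simulate_gas_blank(noise = default_noise(poisson = FALSE), seed = 5)
  run <- background_correct(sim$run, blank)
  b <- detect_line_boundaries(run, blank_mean = 0, blank_sd = 1)
  seg <- align_log(sim$log, b, attr(sim$run, "cycle_time_s"))
  img <- build_maps(run, seg)
  zero_bg <- setNames(rep(0, 8), monitored_isotopes())
  expected <- phantom_expectation(ph, raster_params(), background = zero_bg)
  k <- washout_kernel(nz$washout_tau_s, 0.1)
  tail_mass <- 1 - k[1]
  rng <- diff(range(expected$Zn64))
  expect_lt(max(abs(img$data$Zn64 - expected$Zn64)), rng * tail_mass * 1.01)
})

test_that("single-line runs give a one-row matrix and serpentine flips rows", {
  cfg <- scene_config("twp_in_paraffin", n_rows = 1, n_cols = 15,
                      n_particles = 0)
  ph <- build_phantom(cfg, seed = 1)
  sim <- simulate_raster(ph, noise = noise_off(), seed = 1)
  b <- detect_line_boundaries(sim$run, blank_mean = 0, blank_sd = 1)
  seg <- align_log(sim$log, b, attr(sim$run, "cycle_time_s"))
  img <- build_maps(sim$run, seg)
  expect_equal(dim(img$data$Zn64), c(1L, 15L))
  # serpentine: even rows reversed
  ph2 <- build_phantom(small_twp_config(), seed = 3)
  sim2 <- simulate_raster(ph2, noise = noise_off(), seed = 3)
  b2 <- detect_line_boundaries(sim2$run, blank_mean = 0, blank_sd = 1)
  seg2 <- align_log(sim2$log, b2, attr(sim2$run, "cycle_time_s"))
  uni <- build_maps(sim2$run, seg2)
  ser <- build_maps(sim2$run, seg2, serpentine = TRUE)
  expect_equal(ser$data$Zn64[2, ], rev(uni$data$Zn64[2, ]))
  expect_equal(ser$data$Zn64[1, ], uni$data$Zn64[1, ])
})

test_that("desynchronized runs and out-of-range segments error", {
  ph <- build_phantom(small_twp_config(), seed = 5)
  sim <- simulate_raster(ph, noise = noise_off(), seed = 5)
  b <- detect_line_boundaries(sim$run, blank_mean = 0, blank_sd = 1)
  expect_error(align_log(sim$log[-1, ], b, 0.1), class = "twpscan_desync")
  seg <- align_log(sim$log, b, attr(sim$run, "cycle_time_s"))
  bad <- seg
  bad$last_cycle[nrow(bad)] <- nrow(sim$run) + 10L
  bad$first_cycle[nrow(bad)] <- bad$last_cycle[nrow(bad)] - 39L
  expect_error(build_maps(sim$run, bad), class = "twpscan_segment")
})
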