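test_that("background correction subtracts the blank mean and clips at zero", {
  blank <- simulate_gas_blank(n_cycles = 5000, seed = 1)
  run <- simulate_gas_blank(n_cycles = 5000, seed = 2)
  corrected <- background_correct(run, blank)
  for (k in c("Zn64", "C13")) {
    expect_lt(abs(mean(corrected[[k]])),
              mean(run[[k]]) * 0.2 + 0.5)  # near zero up to clipping bias
    expect_true(all(corrected[[k]] >= 0))
  }
  # explicit clip: blank mean 50, value 30 -> 0
  fake <- run
  fake$C13 <- rep(30, nrow(fake))
  cc <- background_correct(fake, blank)   # blank C13 mean ~50
  expect_true(all(cc$C13 == 0))
  expect_error(background_correct(run, blank[1:50, ]),
               class = "twpscan_short_blank")
})

test_that("corrected line means equal raw means minus blank means", {
  ph <- build_phantom(small_twp_config(), seed = 3)
  sim <- simulate_raster(ph, seed = 3)
  blank <- simulate_gas_blank(n_cycles = 5000, seed = 4)
  corrected <- background_correct(sim$run, blank)
  raw_mean <- mean(sim$run$Zn64)
  blank_mean <- attr(corrected, "blank_means")[["Zn64"]]
  # clipping affects near-zero channels only; Zn is far from zero on particles
  expect_equal(mean(corrected$Zn64), raw_mean - blank_mean, tolerance = 0.05)
})

test_that("NIST normalization arithmetic and drift flag", {
  mk <- function(val) {
    cycles <- tibble::tibble(cycle_index = 0:199, timestamp_s = (0:199) * 0.1)
    for (k in monitored_isotopes()) cycles[[k]] <- rep(val, 200)
    structure(cycles, class = c("transient_run", class(tibble::tibble())),
              run_kind = "standard", cycle_time_s = 0.1)
  }
  sig <- mk(1000)
  out <- nist_normalize(sig, mk(500), mk(500))
  expect_equal(unique(as.numeric(out$normalized$Zn64)), 2)
  expect_false(any(out$record$warn_flag))
  # before 100, after 130: variation |100-130|/115 = 26.1 percent
  expect_warning(out2 <- nist_normalize(sig, mk(100), mk(130)))
  expect_equal(out2$record$rel_variation[1], 30 / 115, tolerance = 1e-12)
  expect_true(all(out2$record$warn_flag))
  # normalizing a standard by itself gives ~1
  self <- nist_normalize(mk(800), mk(800), mk(800))
  expect_equal(unique(as.numeric(self$normalized$Pb208)), 1)
})

test_that("normalization removes inter-run sensitivity drift", {
  # a common detector-gain drift scales sample run, gas blank and standards
  # alike; bracketing-standard normalization must cancel it exactly
  ph <- build_phantom(small_twp_config(), seed = 6)
  nz <- default_noise(poisson = FALSE, washout = FALSE)
  acquire <- function(drift) {
    sim <- simulate_raster(ph, noise = nz, seed = 1)
    blank <- simulate_gas_blank(noise = nz, seed = 1)
    sb <- simulate_standard(drift_factor = 1, noise = nz, seed = 2)
    sa <- simulate_standard(drift_factor = 1, noise = nz, seed = 3)
    for (k in monitored_isotopes()) {
      sim$run[[k]] <- sim$run[[k]] * drift
      blank[[k]] <- blank[[k]] * drift
      sb[[k]] <- sb[[k]] * drift
      sa[[k]] <- sa[[k]] * drift
    }
    run <- background_correct(sim$run, blank)
    nist_normalize(run, background_correct(sb, blank),
                   background_correct(sa, blank))$normalized
  }
  a <- acquire(1.0)
  b <- acquire(1.15)
  expect_equal(as.numeric(a$Zn64), as.numeric(b$Zn64), tolerance = 1e-9)
  expect_gt(max(a$Zn64), 0)
})

test_that("standardization is a frozen z-score transform", {
  df <- tibble::tibble(a = c(1, 3, 5, 9), b = c(2, 2.5, 4, 8))
  p <- fit_standardization(df)
  z <- apply_standardization(df, p)
  expect_equal(colMeans(as.matrix(z)), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(as.matrix(z), 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  # {1, 3}: centered to {-1, +1}, sample-sd (n-1) convention gives sd sqrt(2)
  p2 <- fit_standardization(tibble::tibble(x = c(1, 3)))
  expect_equal(p2$center, 2)
  expect_equal(p2$scale, sqrt(2))
  z2 <- apply_standardization(tibble::tibble(x = c(1, 3)), p2)
  expect_equal(z2$x * p2$scale, c(-1, 1))
  # params are frozen: applying to shifted data is not a fresh z-score
  z3 <- apply_standardization(tibble::tibble(x = c(11, 13)), p2)
  expect_false(isTRUE(all.equal(mean(z3$x), 0)))
  expect_error(fit_standardization(tibble::tibble(x = c(2, 2, 2))),
               class = "twpscan_constant_feature")
})

test_that("provenance sidecar round-trips through JSON", {
  rec <- tibble::tibble(isotope = "Zn64", sens_before = 500, sens_after = 510,
                        sensitivity = 505, rel_variation = 10 / 505,
                        warn_flag = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_provenance(path, rec, extra = list(image = "blank_gut_1"))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$normalization$sensitivity, 505)
  expect_equal(back$image, "blank_gut_1")
})
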