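# Transient-signal simulation: rastered imaging runs, NIST612 standard runs,
# and bulk line-scan runs, all with Poisson counting noise and a laser log.

#' Raster parameters
#'
#' Imaging defaults follow the study's imaging table: 7 um spot, 7 um pixel
#' pitch, 70 um/s stage speed, 100 ms quadrupole cycle, the eight monitored
#' isotopes with their dwell times. The no-bleeding condition
#' `scan_speed * cycle_time == pitch` is enforced: one cycle of signal maps
#' to exactly one pixel.
#'
#' @param spot_um Laser spot diameter (um).
#' @param pitch_um Pixel pitch (um).
#' @param scan_speed_um_s Stage speed (um/s).
#' @param cycle_time_ms Quadrupole cycle time (ms).
#' @param dwell_times_ms Named per-isotope dwell times (ms); their sum must
#'   not exceed the cycle time.
#' @param line_length_um Line length (um); defaults to `pitch * n` set by the
#'   caller (imaging rasters derive it from the phantom).
#' @param n_lines Number of lines (bulk runs).
#' @param repetition_rate_hz,fluence_j_cm2 Laser metadata (not modeled).
#' @return A `raster_params` list.
#' @export
raster_params <- function(spot_um = 7, pitch_um = 7, scan_speed_um_s = 70,
                          cycle_time_ms = 100, dwell_times_ms = TWP_DWELL_MS,
                          line_length_um = NULL, n_lines = NULL,
                          repetition_rate_hz = 100, fluence_j_cm2 = 2.4) {
  if (abs(scan_speed_um_s * cycle_time_ms / 1000 - pitch_um) > 1e-9) {
    stop_twp("no-bleeding condition violated: scan_speed * cycle_time must equal pitch",
             "twpscan_bleeding")
  }
  if (sum(dwell_times_ms) > cycle_time_ms + 1e-9) {
    stop_twp("sum of dwell times exceeds the cycle time", "twpscan_dwell")
  }
  structure(list(spot_um = spot_um, pitch_um = pitch_um,
                 scan_speed_um_s = scan_speed_um_s,
                 cycle_time_ms = cycle_time_ms,
                 dwell_times_ms = dwell_times_ms,
                 line_length_um = line_length_um, n_lines = n_lines,
                 repetition_rate_hz = repetition_rate_hz,
                 fluence_j_cm2 = fluence_j_cm2),
            class = "raster_params")
}

#' Bulk-line raster parameters
#'
#' Bulk fingerprinting defaults: 70 um spot, 700 um/s, 5 mm lines, 20 lines,
#' 100 ms cycles (so 70 um per cycle and roughly 7 s of ablation per line).
#'
#' @inheritParams raster_params
#' @export
bulk_raster_params <- function(spot_um = 70, pitch_um = 70,
                               scan_speed_um_s = 700, cycle_time_ms = 100,
                               line_length_um = 5000, n_lines = 20) {
  raster_params(spot_um = spot_um, pitch_um = pitch_um,
                scan_speed_um_s = scan_speed_um_s,
                cycle_time_ms = cycle_time_ms,
                line_length_um = line_length_um, n_lines = n_lines,
                repetition_rate_hz = 50)
}

#' Default noise and acquisition nuisance configuration
#'
#' Per-isotope gas-blank background rates (counts/cycle), the aerosol washout
#' kernel time constant (chosen so 99 percent of the signal arrives within
#' one 100 ms cycle, matching a washout time below 100 ms), the gold
#' line-marker spike amplitude, and the inter-line gap. `poisson = FALSE`
#' yields noise-free expectations (used by round-trip tests).
#'
#' @param background Named per-isotope background counts/cycle.
#' @param washout Logical, convolve line signals with the washout kernel.
#' @param washout_tau_s Washout time constant (s).
#' @param poisson Logical, apply Poisson counting noise.
#' @param au_spike Expected counts of the Au marker spike injected at each
#'   line start and end.
#' @param gap_cycles Background-only cycles between lines.
#' @param lead_cycles Background-only cycles before the first line.
#' @return A list.
#' @export
default_noise <- function(background = c(C13 = 50, Zn64 = 2, Ti48 = 5,
                                         Mo92 = 0.5, Sb121 = 0.5, Nd142 = 0.3,
                                         Au197 = 1, Pb208 = 0.8),
                          washout = TRUE,
                          washout_tau_s = 0.1 / log(100),
                          poisson = TRUE, au_spike = 5e4,
                          gap_cycles = 10L, lead_cycles = 25L) {
  list(background = background, washout = washout,
       washout_tau_s = washout_tau_s, poisson = poisson,
       au_spike = au_spike, gap_cycles = as.integer(gap_cycles),
       lead_cycles = as.integer(lead_cycles))
}

#' Discretized washout kernel
#'
#' Single-exponential aerosol washout, discretized over cycles, truncated at
#' five time constants and renormalized to sum exactly to one so the
#' convolution conserves total expected counts per line.
#'
#' @param tau_s Time constant (s).
#' @param cycle_time_s Cycle time (s).
#' @return Numeric kernel (first tap = same cycle).
#' @export
washout_kernel <- function(tau_s, cycle_time_s) {
  n <- ceiling(5 * tau_s / cycle_time_s)
  k <- exp(-(0:n) * cycle_time_s / tau_s)
  k / sum(k)
}

# causal convolution of x with kernel k, keeping length(x) + length(k) - 1
convolve_causal <- function(x, k) {
  n <- length(x) + length(k) - 1L
  out <- numeric(n)
  for (j in seq_along(k)) {
    out[(j - 1L) + seq_along(x)] <- out[(j - 1L) + seq_along(x)] + k[j] * x
  }
  out
}

new_transient_run <- function(cycles, run_kind, cycle_time_s) {
  structure(cycles, class = c("transient_run", class(tibble())),
            run_kind = run_kind, cycle_time_s = cycle_time_s)
}

#' Simulate a rastered imaging run over a phantom
#'
#' For each line (grid row) the expected per-cycle signal is the
#' footprint-averaged material level, optionally convolved along the scan
#' direction with the normalized washout kernel, plus the gas-blank
#' background; counts are Poisson-sampled. Au marker spikes are injected at
#' the first and last cycle of every line; cycles between lines (washout
#' tail plus background) are recorded but belong to no pixel. The laser log
#' records the true line timings and stage coordinates.
#'
#' @param phantom A [build_phantom()] result.
#' @param raster A [raster_params()] with pitch equal to the phantom pitch.
#' @param fingerprints Fingerprint table.
#' @param noise A [default_noise()] list.
#' @param seed Integer seed.
#' @return List with `run` (a `transient_run` tibble: `cycle_index`,
#'   `timestamp_s`, one column per isotope) and `log` (laser-log tibble:
#'   `line_id`, `t_start_s`, `t_end_s`, `x0_um`, `y0_um`, `x1_um`, `y1_um`).
#' @export
simulate_raster <- function(phantom, raster = raster_params(),
                            fingerprints = default_fingerprints(),
                            noise = default_noise(), seed = 1L) {
  stopifnot(inherits(phantom, "phantom"))
  if (abs(raster$pitch_um - phantom$pitch_um) > 1e-9) {
    stop_twp("raster pitch does not match phantom pitch", "twpscan_pitch")
  }
  with_seed(seed, simulate_raster_impl(phantom, raster, fingerprints, noise))
}

simulate_raster_impl <- function(phantom, raster, fingerprints, noise) {
  nr <- nrow(phantom$label_grid); nc <- ncol(phantom$label_grid)
  dt <- raster$cycle_time_ms / 1000
  iso <- TWP_ISOTOPES
  levels <- phantom_level_maps(phantom, fingerprints)
  levels <- lapply(levels, footprint_average,
                   spot = raster$spot_um, pitch = raster$pitch_um)
  kern <- if (isTRUE(noise$washout)) {
    washout_kernel(noise$washout_tau_s, dt)
  } else 1
  tail_n <- length(kern) - 1L
  gap <- max(noise$gap_cycles, tail_n)

  per_line <- nc + gap
  total <- noise$lead_cycles + nr * per_line
  expected <- matrix(0, total, length(iso), dimnames = list(NULL, iso))
  line_first <- integer(nr)
  pos <- noise$lead_cycles
  for (i in seq_len(nr)) {
    line_first[i] <- pos                       # 0-based cycle index of pixel 0
    for (k in seq_along(iso)) {
      sig <- convolve_causal(levels[[iso[k]]][i, ], kern)
      idx <- pos + seq_along(sig)              # 1-based rows
      expected[idx, k] <- expected[idx, k] + sig
    }
    # Au spikes mark line start and end cycles
    expected[pos + 1L, "Au197"] <- expected[pos + 1L, "Au197"] + noise$au_spike
    expected[pos + nc, "Au197"] <- expected[pos + nc, "Au197"] + noise$au_spike
    pos <- pos + per_line
  }
  bg <- noise$background[iso]; bg[is.na(bg)] <- 0
  expected <- sweep(expected, 2, bg, `+`)

  counts <- if (isTRUE(noise$poisson)) {
    matrix(rpois(length(expected), expected), nrow(expected),
           dimnames = dimnames(expected))
  } else expected

  cycles <- as_tibble(counts)
  cycles <- dplyr::bind_cols(
    tibble(cycle_index = seq_len(total) - 1L,
           timestamp_s = (seq_len(total) - 1L) * dt),
    cycles)
  run <- new_transient_run(cycles, "image", dt)

  log <- tibble(
    line_id = seq_len(nr),
    t_start_s = line_first * dt,
    t_end_s = (line_first + nc) * dt,
    x0_um = 0, y0_um = (seq_len(nr) - 0.5) * raster$pitch_um,
    x1_um = nc * raster$pitch_um, y1_um = (seq_len(nr) - 0.5) * raster$pitch_um)
  list(run = run, log = log)
}

#' Default NIST612 per-isotope sensitivities
#'
#' Instrument response to the NIST612 glass standard, in counts per cycle;
#' an arbitrary but fixed instrument scale used by the normalization step.
#'
#' @return Named numeric vector.
#' @export
default_sensitivity <- function() {
  c(C13 = 2000, Zn64 = 5000, Ti48 = 8000, Mo92 = 6000, Sb121 = 7000,
    Nd142 = 9000, Au197 = 3000, Pb208 = 10000)
}

#' Simulate a NIST612 standard run
#'
#' Constant-expectation line scan on the glass standard: per isotope the
#' expectation is `sensitivity * drift_factor` plus background, with Poisson
#' noise. Standards bracket every image; inter-run sensitivity drift is what
#' the normalization step measures and flags.
#'
#' @param sensitivity Named per-isotope sensitivity (counts/cycle).
#' @param drift_factor Named or scalar multiplicative drift; `NULL` draws one
#'   factor per isotope uniformly within +/-20 percent.
#' @param n_cycles Number of cycles.
#' @param noise A [default_noise()] list (background and Poisson flag used).
#' @param seed Integer seed.
#' @return A `transient_run` tibble with `run_kind = "standard"`.
#' @export
simulate_standard <- function(sensitivity = default_sensitivity(),
                              drift_factor = 1, n_cycles = 500L,
                              noise = default_noise(), seed = 1L) {
  with_seed(seed, {
    iso <- TWP_ISOTOPES
    if (is.null(drift_factor)) drift_factor <- runif(length(iso), 0.8, 1.2)
    drift <- rep_len(drift_factor, length(iso))
    if (!is.null(names(drift_factor))) drift <- drift_factor[iso]
    bg <- noise$background[iso]; bg[is.na(bg)] <- 0
    expect <- sensitivity[iso] * drift + bg
    counts <- matrix(rep(expect, each = n_cycles), n_cycles,
                     dimnames = list(NULL, iso))
    if (isTRUE(noise$poisson)) {
      counts <- matrix(rpois(length(counts), counts), n_cycles,
                       dimnames = list(NULL, iso))
    }
    dt <- 0.1
    cycles <- dplyr::bind_cols(
      tibble(cycle_index = seq_len(n_cycles) - 1L,
             timestamp_s = (seq_len(n_cycles) - 1L) * dt),
      as_tibble(counts))
    new_transient_run(cycles, "standard", dt)
  })
}

#' Simulate a gas-blank run
#'
#' Background-only cycles (laser off), used for background correction.
#'
#' @inheritParams simulate_standard
#' @return A `transient_run` with `run_kind = "gas_blank"`.
#' @export
simulate_gas_blank <- function(n_cycles = 500L, noise = default_noise(),
                               seed = 1L) {
  with_seed(seed, {
    iso <- TWP_ISOTOPES
    bg <- noise$background[iso]; bg[is.na(bg)] <- 0
    counts <- matrix(rep(bg, each = n_cycles), n_cycles,
                     dimnames = list(NULL, iso))
    if (isTRUE(noise$poisson)) {
      counts <- matrix(rpois(length(counts), counts), n_cycles,
                       dimnames = list(NULL, iso))
    }
    dt <- 0.1
    cycles <- dplyr::bind_cols(
      tibble(cycle_index = seq_len(n_cycles) - 1L,
             timestamp_s = (seq_len(n_cycles) - 1L) * dt),
      as_tibble(counts))
    new_transient_run(cycles, "gas_blank", dt)
  })
}

#' Simulate a bulk line-scan run of one material
#'
#' Twenty parallel 5-mm lines by default. Each line carries a homogeneous
#' expectation drawn once per line from the material fingerprint; for
#' particulate materials (TWPs) the Bernoulli marker-presence draw applies
#' per line segment, reproducing the between-line heterogeneity of a bed of
#' individual particles. Poisson noise throughout; the accompanying log
#' gives the line boundaries.
#'
#' @param material Material name present in `fingerprints`.
#' @param raster A [bulk_raster_params()].
#' @param fingerprints Fingerprint table.
#' @param n_lines Number of lines (defaults to `raster$n_lines`).
#' @param noise A [default_noise()] list.
#' @param seed Integer seed.
#' @return List with `run` (`transient_run`, `run_kind = "bulk"`) and `log`.
#' @export
simulate_bulk_lines <- function(material, raster = bulk_raster_params(),
                                fingerprints = default_fingerprints(),
                                n_lines = NULL, noise = default_noise(),
                                seed = 1L) {
  if (!material %in% fingerprints$material) {
    stop_twp(paste0("unknown material: ", material), "twpscan_unknown_material")
  }
  n_lines <- n_lines %||% raster$n_lines %||% 20L
  with_seed(seed, {
    iso <- TWP_ISOTOPES
    dt <- raster$cycle_time_ms / 1000
    n_px <- floor(raster$line_length_um / raster$pitch_um)
    fp <- fingerprints[fingerprints$material == material, ]
    particulate <- any(fp$particulate)
    gap <- noise$gap_cycles
    total <- noise$lead_cycles + n_lines * (n_px + gap)
    expected <- matrix(0, total, length(iso), dimnames = list(NULL, iso))
    line_first <- integer(n_lines)
    pos <- noise$lead_cycles
    for (i in seq_len(n_lines)) {
      line_first[i] <- pos
      lev <- if (particulate) {
        draw_realized_levels(fingerprints, material)
      } else {
        # homogeneous material: lognormal line-to-line replicate variation
        setNames(rlnorm(nrow(fp), fp$log_mean, fp$log_sd), fp$isotope)[iso]
      }
      expected[pos + seq_len(n_px), ] <-
        matrix(rep(lev, each = n_px), n_px)
      pos <- pos + n_px + gap
    }
    bg <- noise$background[iso]; bg[is.na(bg)] <- 0
    expected <- sweep(expected, 2, bg, `+`)
    counts <- if (isTRUE(noise$poisson)) {
      matrix(rpois(length(expected), expected), nrow(expected),
             dimnames = dimnames(expected))
    } else expected
    cycles <- dplyr::bind_cols(
      tibble(cycle_index = seq_len(total) - 1L,
             timestamp_s = (seq_len(total) - 1L) * dt),
      as_tibble(counts))
    run <- new_transient_run(cycles, "bulk", dt)
    log <- tibble(
      line_id = seq_len(n_lines),
      t_start_s = line_first * dt,
      t_end_s = (line_first + n_px) * dt,
      x0_um = 0, y0_um = (seq_len(n_lines) - 0.5) * raster$pitch_um,
      x1_um = n_px * raster$pitch_um,
      y1_um = (seq_len(n_lines) - 0.5) * raster$pitch_um)
    list(run = run, log = log)
  })
}

#' @export
print.transient_run <- function(x, ...) {
  cat("<transient_run>", attr(x, "run_kind"), ":", nrow(x), "cycles @",
      attr(x, "cycle_time_s"), "s\n")
  NextMethod()
}

isotope_columns <- function(run) intersect(TWP_ISOTOPES, names(run))
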