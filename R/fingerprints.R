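# Material fingerprint registry for the synthetic LA-ICP-MS study.
#
# Levels are median expected detector counts per 100-ms cycle at instrument
# sensitivity (before NIST612 normalization). No certified concentrations
# exist for the marker elements in tire rubber (Zn is reported only at the
# g/kg level, Pb at mg/kg), so the absolute scale is a free simulator
# parameter; what the registry encodes is the qualitative multielement
# ordering of the thirteen bulk materials: TWP dominated by Zn; lake sediment
# by Ti; river sediment by Nd; road dust by Pb and Mo; PET by its Sb
# polycondensation catalyst; gut tissue carrying biogenic Zn/Ti/Pb levels
# that overlap TWPs in single elements; paraffin a near-blank.

#' Default material fingerprints
#'
#' Returns the fingerprint table for the thirteen bulk reference materials of
#' the study: road dust, mussel tissue, lake sediment, river sediment,
#' paraffin, gut tissue, hatched artemia, Hikari feed, PVC, PET, PP, HDPE and
#' tire-wear particles (TWP).
#'
#' Each (material, isotope) pair carries a lognormal expected-signal model:
#' `log_mean` is the log of the median expected counts per cycle, `log_sd`
#' the lognormal spread drawn per particle (imaging) or per line (bulk), and
#' `presence_prob` the probability that an individual particle of the
#' material carries the marker at all. Only TWPs have `presence_prob < 1` for
#' Ti, Mo, Sb, Nd and Pb: individual tire particles from different
#' manufacturers carry different additive packages, so no single marker
#' element is present in every particle. Zn (the vulcanization activator) is
#' always present and comparatively tightly distributed.
#'
#' @return A tibble with columns `material`, `isotope`, `log_mean`,
#'   `log_sd`, `presence_prob` and a per-material logical `particulate`
#'   (particle-presence draws apply per bulk line segment).
#' @export
#' @examples
#' fp <- default_fingerprints()
#' fingerprint_level(fp, "TWP", "Zn64") > fingerprint_level(fp, "paraffin", "Zn64")
default_fingerprints <- function() {
  # median counts/cycle for (Zn, Ti, Mo, Sb, Nd, Pb, C); Au never ablates
  # from the materials themselves (it is the injected line marker).
  lv <- list(
    road_dust      = c(600,  3000, 400,  30,   250, 900,  150),
    mussel_tissue  = c(200,  80,   5,    2,    3,   30,   1800),
    lake_sediment  = c(150,  5000, 80,   12,   500, 350,  100),
    river_sediment = c(150,  4000, 70,   10,   900, 400,  100),
    paraffin       = c(0.5,  0.5,  1e-6, 1e-6, 1e-6, 0.3, 3000),
    gut_tissue     = c(150,  200,  1e-6, 1e-6, 1e-6, 60,  2000),
    artemia        = c(120,  60,   4,    1,    2,   10,   1800),
    hikari_feed    = c(300,  700,  8,    1,    2,   400,  1800),
    PVC            = c(40,   120,  2,    5,    1,   250,  2500),
    PET            = c(10,   20,   2,    2500, 1,   5,    2500),
    PP             = c(8,    30,   1,    1,    0.5, 3,    2500),
    HDPE           = c(10,   25,   1,    1,    0.5, 4,    2500),
    TWP            = c(3000, 700,  100,  80,   70,  400,  800)
  )
  iso <- c("Zn64", "Ti48", "Mo92", "Sb121", "Nd142", "Pb208", "C13")
  # Zn in TWP is narrow (ubiquitous ZnO additive); the optional markers vary
  # strongly between particles. Paraffin is a homogeneous blank.
  sdlog_for <- function(mat, is) {
    if (mat == "paraffin") return(0.05)
    if (mat == "hikari_feed") return(0.05)
    if (mat == "TWP") {
      return(switch(is, Zn64 = 0.05, Ti48 = 0.1, Pb208 = 0.1, 0.35))
    }
    0.25
  }
  presence_for <- function(mat, is) {
    if (mat != "TWP") return(1)
    switch(is,
      Zn64 = 1, Ti48 = 1, Mo92 = 0.5, Sb121 = 0.5, Nd142 = 0.5,
      Pb208 = 1, C13 = 1)
  }
  rows <- purrr::imap(lv, function(v, mat) {
    tibble(
      material = mat,
      isotope = c(iso, "Au197"),
      log_mean = log(c(v, 1e-6)),
      log_sd = c(vapply(iso, function(i) sdlog_for(mat, i), 0), 0.05),
      presence_prob = c(vapply(iso, function(i) presence_for(mat, i), 0), 1),
      particulate = mat == "TWP"
    )
  })
  dplyr::bind_rows(rows)
}

#' Look up a fingerprint's median expected level
#'
#' @param fingerprints Tibble from [default_fingerprints()].
#' @param material Material name.
#' @param isotope Isotope label, e.g. `"Zn64"`.
#' @return Median expected counts per cycle (numeric scalar).
#' @export
fingerprint_level <- function(fingerprints, material, isotope) {
  row <- fingerprints[fingerprints$material == material &
                        fingerprints$isotope == isotope, ]
  if (nrow(row) == 0) {
    stop_twp(paste0("unknown material/isotope: ", material, "/", isotope),
             "twpscan_unknown_material")
  }
  exp(row$log_mean[[1]])
}

fingerprint_materials <- function(fingerprints) unique(fingerprints$material)

# Realized per-particle (or per-line) levels: Bernoulli marker presence,
# then a lognormal level draw. Returns a named vector over all monitored
# isotopes (Au stays at its negligible ablation level).
draw_realized_levels <- function(fingerprints, material) {
  fp <- fingerprints[fingerprints$material == material, ]
  if (nrow(fp) == 0) {
    stop_twp(paste0("unknown material: ", material), "twpscan_unknown_material")
  }
  present <- rbinom(nrow(fp), 1L, fp$presence_prob)
  lev <- present * rlnorm(nrow(fp), meanlog = fp$log_mean, sdlog = fp$log_sd)
  setNames(lev, fp$isotope)[TWP_ISOTOPES]
}

# Median (no-draw) levels as a named vector over monitored isotopes.
median_levels <- function(fingerprints, material) {
  fp <- fingerprints[fingerprints$material == material, ]
  setNames(exp(fp$log_mean), fp$isotope)[TWP_ISOTOPES]
}
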