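# Shared constants and small helpers.

# Monitored isotopes and quadrupole dwell times (ms); the six marker elements
# used as classifier features are Zn, Ti, Mo, Sb, Nd, Pb. Carbon is an
# alignment/tissue channel, gold carries line start/end spikes.
TWP_ISOTOPES <- c("C13", "Zn64", "Ti48", "Mo92", "Sb121", "Nd142", "Au197", "Pb208")
TWP_DWELL_MS <- c(C13 = 10, Zn64 = 10, Ti48 = 10, Mo92 = 14, Sb121 = 14,
                  Nd142 = 14, Au197 = 5, Pb208 = 15)

#' Marker-element isotope panel
#'
#' The six marker isotopes used as classifier features, in the fixed feature
#' order Zn, Ti, Mo, Sb, Nd, Pb.
#'
#' @return Character vector of isotope labels.
#' @export
marker_isotopes <- function() {
  c("Zn64", "Ti48", "Mo92", "Sb121", "Nd142", "Pb208")
}

#' All monitored isotopes
#'
#' The eight isotopes monitored per quadrupole cycle (markers plus the carbon
#' tissue/alignment channel and the gold line-marker channel).
#'
#' @return Character vector of isotope labels.
#' @export
monitored_isotopes <- function() TWP_ISOTOPES

# Run code with a local RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

# Derive a reproducible child seed from a base seed and a stream index,
# kept well inside 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009L + 97L * as.double(index)) %% 2147483587)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_twp <- function(msg, class) {
  abort(msg, class = c(class, "twpscan_error"))
}
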