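#' Isotope-scale conversions for 15N tracer work
#'
#' All internal isotope arithmetic in nitrifyr is carried out on the atom
#' fraction scale (proportion of 15N among total N, in `[0, 1)`), which avoids
#' the percent/per-mil bookkeeping errors that delta notation invites.
#' `delta_to_atom_fraction()` and `atom_fraction_to_delta()` convert between
#' the two scales; they are exact inverses.
#'
#' Delta values are per-mil deviations of the 15N/14N ratio from the
#' atmospheric-N2 reference scale, for which the package adopts
#' R_air = 0.0036765 (15N/14N of air N2).
#'
#' @param d15n Numeric vector of delta-15N values in per mil. Must be
#'   >= -1000 (the physical limit: a pool with no heavy isotope).
#' @param af Numeric vector of atom fractions in `[0, 1)`.
#' @return A numeric vector: atom fractions for `delta_to_atom_fraction()`,
#'   per-mil delta values for `atom_fraction_to_delta()`.
#' @examples
#' delta_to_atom_fraction(0)       # the air standard itself, ~0.003663
#' delta_to_atom_fraction(-1000)   # no 15N at all
#' atom_fraction_to_delta(delta_to_atom_fraction(250))  # round trip -> 250
#' @name isotope-scales
NULL

# 15N/14N ratio of atmospheric N2 (reference scale)
R_AIR <- 0.0036765

#' @rdname isotope-scales
#' @export
delta_to_atom_fraction <- function(d15n) {
  if (any(d15n < -1000, na.rm = TRUE)) {
    rlang::abort("delta-15N below physical limit (-1000 per mil)")
  }
  r <- R_AIR * (d15n / 1000 + 1)
  r / (1 + r)
}

#' @rdname isotope-scales
#' @export
atom_fraction_to_delta <- function(af) {
  if (any(af < 0 | af >= 1, na.rm = TRUE)) {
    rlang::abort("atom fraction must lie in [0, 1)")
  }
  r <- af / (1 - af)
  (r / R_AIR - 1) * 1000
}

#' Labelled fraction of the ammonium substrate pool
#'
#' The labelled fraction alpha of the NH4+ pool in an incubation bottle is the
#' tracer concentration divided by tracer plus ambient NH4+. It scales the
#' transfer of 15N label into the nitrite pool and so divides the rate
#' equation: at fixed isotope enrichment a smaller alpha implies a larger
#' ammonia-oxidation rate.
#'
#' @param spike_15n Added 15N-NH4+ tracer, umol/L (> 0).
#' @param nh4_ambient Ambient NH4+ concentration, umol/L (>= 0).
#' @return Numeric vector of fractions in (0, 1].
#' @examples
#' compute_alpha(0.05, 0)    # all substrate labelled -> 1
#' compute_alpha(0.1, 1.9)   # 0.05
#' @export
compute_alpha <- function(spike_15n, nh4_ambient) {
  if (any(spike_15n <= 0, na.rm = TRUE)) {
    rlang::abort("no tracer added: spike_15n must be > 0")
  }
  if (any(nh4_ambient < 0, na.rm = TRUE)) {
    rlang::abort("nh4_ambient must be >= 0")
  }
  spike_15n / (spike_15n + nh4_ambient)
}

#' Azide-method correction from the N2O scale to the NO2- scale
#'
#' The azide method converts NO2- to N2O for isotope-ratio analysis. Each N2O
#' molecule carries one N atom from the (unenriched) azide and one from the
#' NO2- pool, so an enrichment measured on N2O is half the enrichment of the
#' nitrite it derives from. This correction doubles an atom-fraction excess
#' measured on N2O to recover the NO2- scale; negative inputs (analytical
#' noise) are preserved so that non-detects propagate downstream.
#'
#' @param delta_excess_n2o Atom-fraction excess measured on N2O-derived N
#'   (dimensionless; may be negative from noise, must be >= -1).
#' @return Atom-fraction excess of the NO2- pool (input times two).
#' @export
azide_correction <- function(delta_excess_n2o) {
  if (any(delta_excess_n2o < -1, na.rm = TRUE)) {
    rlang::abort("atom-fraction excess cannot be below -1")
  }
  2 * delta_excess_n2o
}
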