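#' Stated analytical precisions of the measurement chain
#'
#' One-sigma analytical precisions used by the Monte-Carlo uncertainty
#' propagation and by the synthetic generator: delta-15N reproducibility on
#' N2O-derived N (per mil), NH4+ and NO3-+NO2- spectrophotometry (umol/L),
#' and chlorophyll-a triplicate precision (ug/L).
#'
#' @param d15n,nh4,no2,chla One-sigma precisions; defaults are the stated
#'   instrument values (6.8 per mil, 0.2 umol/L, 0.06 umol/L, 0.3 ug/L).
#' @return A named list with elements `d15n`, `nh4`, `no2`, `chla`.
#' @export
analytical_precisions <- function(d15n = 6.8, nh4 = 0.2, no2 = 0.06,
                                  chla = 0.3) {
  stopifnot(d15n >= 0, nh4 >= 0, no2 >= 0, chla >= 0)
  list(d15n = d15n, nh4 = nh4, no2 = no2, chla = chla)
}

#' Design the 15N-NH4+ tracer spike for an incubation
#'
#' Tracer additions target 5% of the ambient NH4+ concentration (estimated
#' from the previous month's measurement), with a floor of 0.05 umol/L when
#' ambient concentrations are too low to scale the addition (i.e. below
#' 1 umol/L, where 5% would fall under the floor).
#'
#' @param nh4_prior Prior ambient NH4+ concentration, umol/L (>= 0).
#' @return Spike concentration, umol/L.
#' @examples
#' design_spike(2.0)  # 0.10
#' design_spike(0)    # floor: 0.05
#' @export
design_spike <- function(nh4_prior) {
  if (any(nh4_prior < 0, na.rm = TRUE)) {
    rlang::abort("nh4_prior must be >= 0")
  }
  pmax(0.05 * nh4_prior, 0.05)
}

#' Flag tracer over-spike
#'
#' Additions above 15% of the ambient NH4+ pool may stimulate ammonia
#' oxidation and bias rates high; such incubations are retained but flagged.
#'
#' @param spike_15n Tracer addition, umol/L.
#' @param nh4_ambient Ambient NH4+ concentration, umol/L.
#' @param threshold Flagging threshold on spike/ambient (default 0.15).
#' @return A tibble with `overspike_ratio` (spike/ambient, `Inf` when ambient
#'   is zero) and logical `overspike_flag`.
#' @export
flag_overspike <- function(spike_15n, nh4_ambient, threshold = 0.15) {
  ratio <- ifelse(nh4_ambient > 0, spike_15n / nh4_ambient, Inf)
  tibble::tibble(
    overspike_ratio = ratio,
    overspike_flag = ratio > threshold
  )
}

# Rate equation on the atom-fraction scale. d_af_n2o is the mean calibrated
# atom-fraction difference (t_f - t_0) measured on N2O-derived N; the factor 2
# is the azide correction back to the NO2- scale. no2_initial in umol/L,
# t_incubation in hours, output nmol/L/day.
ao_rate_raw <- function(d_af_n2o, no2_initial, t_incubation, alpha) {
  no2_nmol <- no2_initial * 1000
  t_days <- t_incubation / 24
  azide_correction(d_af_n2o) * no2_nmol / (t_days * alpha)
}

validate_incubation <- function(no2_initial, t_incubation, spike_15n,
                                nh4_ambient, carrier_no2 = 0) {
  if (any(no2_initial <= 0)) rlang::abort("no2_initial must be > 0")
  if (any(t_incubation <= 0 | t_incubation > 24)) {
    rlang::abort("t_incubation must lie in (0, 24] hours")
  }
  if (any(spike_15n <= 0)) rlang::abort("spike_15n must be > 0")
  if (any(nh4_ambient < 0)) rlang::abort("nh4_ambient must be >= 0")
  if (any(no2_initial < carrier_no2)) {
    rlang::abort("no2_initial cannot be below the added carrier")
  }
  invisible(TRUE)
}

#' Ammonia-oxidation rate from one 15N tracer incubation
#'
#' Computes the AO rate from a single end-point tracer experiment: the
#' duplicate delta-15N measurements of NO2--derived N2O at t0 and at the end
#' of the incubation are calibrated, converted to atom fractions and averaged
#' per time point; the rate is
#'
#' `r = 2 * (n15_f - n15_i) * NO2(i) / (t * alpha)`
#'
#' with `n15` the atom fraction on the N2O measurement scale (the factor 2 is
#' the azide correction), `NO2(i)` the initial nitrite concentration in the
#' bottle immediately after tracer and carrier additions (initial, not final
#' -- nitrite is consumed during some incubations), `t` the incubation time in
#' days, and `alpha` the labelled fraction of the NH4+ pool. A negative raw
#' rate (nitrite 15N depleted relative to background) is reported as a
#' non-detect with `rate = 0`; zero itself is a valid detected rate.
#'
#' The instrument detection limit (~2 nmol N per analyte aliquot) is not
#' enforced computationally; detection is sign-based, mirroring the field
#' protocol.
#'
#' @param d15n_t0,d15n_tf Numeric vectors of raw delta-15N (per mil) of the
#'   duplicate t0 and end-point bottles.
#' @param nh4_ambient Ambient NH4+ in the bottle, umol/L.
#' @param no2_initial Initial NO2- after tracer + carrier, umol/L.
#' @param spike_15n Added 15N-NH4+ tracer, umol/L.
#' @param t_incubation Incubation duration, hours (in (0, 24]).
#' @param calibration Optional [calibrate_delta()] object; `NULL` means the
#'   deltas are already calibrated.
#' @param carrier_no2 Carrier NO2- added, umol/L (validation only).
#' @return A one-row tibble: `rate` (nmol/L/day, >= 0), `detected`,
#'   `raw_rate` (signed), `alpha`, `overspike_ratio`, `overspike_flag`.
#' @examples
#' # enrichment worth 0.00025 atom fraction on the N2O scale over 4 h
#' d0 <- atom_fraction_to_delta(delta_to_atom_fraction(0))
#' df <- atom_fraction_to_delta(delta_to_atom_fraction(0) + 0.00025)
#' ao_rate(d0, df, nh4_ambient = 0.95, no2_initial = 0.3,
#'         spike_15n = 0.05, t_incubation = 4)$rate  # 36 nmol/L/day
#' @export
ao_rate <- function(d15n_t0, d15n_tf, nh4_ambient, no2_initial, spike_15n,
                    t_incubation, calibration = NULL, carrier_no2 = 0) {
  stopifnot(length(d15n_t0) >= 1, length(d15n_tf) >= 1)
  validate_incubation(no2_initial, t_incubation, spike_15n, nh4_ambient,
                      carrier_no2)
  af_t0 <- mean(delta_to_atom_fraction(apply_calibration(d15n_t0, calibration)))
  af_tf <- mean(delta_to_atom_fraction(apply_calibration(d15n_tf, calibration)))
  alpha <- compute_alpha(spike_15n, nh4_ambient)
  raw <- ao_rate_raw(af_tf - af_t0, no2_initial, t_incubation, alpha)
  os <- flag_overspike(spike_15n, nh4_ambient)
  tibble::tibble(
    rate = max(raw, 0),
    detected = raw >= 0,
    raw_rate = raw,
    alpha = alpha,
    overspike_ratio = os$overspike_ratio,
    overspike_flag = os$overspike_flag
  )
}

#' Monte-Carlo uncertainty of an AO rate estimate
#'
#' Propagates the stated analytical precisions through the rate equation by
#' seeded Monte-Carlo: independent Gaussian perturbations of every bottle
#' delta-15N (sigma 6.8 per mil), of ambient NH4+ (sigma 0.2 umol/L,
#' truncated at 0) and of initial NO2- (sigma 0.06 umol/L, truncated just
#' above 0), re-evaluating the raw rate for each draw. The SD of the raw
#' (unclipped) rate is returned; clipping non-detects inside the Monte Carlo
#' would understate the uncertainty.
#'
#' @inheritParams ao_rate
#' @param n_draws Number of Monte-Carlo draws (>= 100).
#' @param seed Integer seed; same seed, same result.
#' @param precisions One-sigma perturbation scales, see
#'   [analytical_precisions()].
#' @return The Monte-Carlo rate SD, nmol/L/day.
#' @export
propagate_rate_sd <- function(d15n_t0, d15n_tf, nh4_ambient, no2_initial,
                              spike_15n, t_incubation, calibration = NULL,
                              n_draws = 1000, seed = 1L,
                              precisions = analytical_precisions()) {
  if (n_draws < 100) rlang::abort("n_draws must be >= 100")
  validate_incubation(no2_initial, t_incubation, spike_15n, nh4_ambient)
  withr::with_seed(seed, {
    draws <- vapply(seq_len(n_draws), function(i) {
      t0 <- pmax(d15n_t0 + stats::rnorm(length(d15n_t0), 0, precisions$d15n),
                 -1000)
      tf <- pmax(d15n_tf + stats::rnorm(length(d15n_tf), 0, precisions$d15n),
                 -1000)
      nh4 <- max(nh4_ambient + stats::rnorm(1, 0, precisions$nh4), 0)
      no2 <- max(no2_initial + stats::rnorm(1, 0, precisions$no2), 1e-6)
      af0 <- mean(delta_to_atom_fraction(apply_calibration(t0, calibration)))
      aff <- mean(delta_to_atom_fraction(apply_calibration(tf, calibration)))
      ao_rate_raw(aff - af0, no2, t_incubation,
                  compute_alpha(spike_15n, nh4))
    }, numeric(1))
    stats::sd(draws)
  })
}

#' Estimate AO rates for a table of tracer incubations
#'
#' The data-frame front end to [ao_rate()]. Input is long format, one row per
#' bottle, with a `bottle_role` column (`"t0"` or `"tf"`) and a `d15n` column
#' holding that bottle's raw delta-15N; bottle rows sharing a `sample_id`
#' form one incubation. Remaining incubation-level columns (concentrations,
#' spike, duration, metadata) must be constant within a `sample_id`.
#'
#' @param incubations A data frame with columns `sample_id`, `bottle_role`,
#'   `d15n`, `nh4_ambient`, `no2_initial`, `spike_15n`, `carrier_no2`,
#'   `t_incubation`, and optionally `date`, `depth_label`, `diel`.
#' @param calibration Optional `delta_calibration` applied to every bottle.
#' @param mc_draws Monte-Carlo draws for the rate SD; 0 skips propagation
#'   (`rate_sd` = `NA`).
#' @param seed Integer seed for the Monte Carlo.
#' @param precisions See [analytical_precisions()].
#' @return A tibble, one row per incubation, with the [ao_rate()] columns
#'   plus `rate_sd` and any metadata columns present.
#' @export
estimate_ao_rates <- function(incubations, calibration = NULL, mc_draws = 0,
                              seed = 1L,
                              precisions = analytical_precisions()) {
  needed <- c("sample_id", "bottle_role", "d15n", "nh4_ambient",
              "no2_initial", "spike_15n", "t_incubation")
  missing_cols <- setdiff(needed, names(incubations))
  if (length(missing_cols) > 0) {
    rlang::abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!all(incubations$bottle_role %in% c("t0", "tf"))) {
    rlang::abort("bottle_role must be 't0' or 'tf'")
  }
  meta_cols <- intersect(c("date", "depth_label", "diel"), names(incubations))
  if (!"carrier_no2" %in% names(incubations)) incubations$carrier_no2 <- 0

  incubations |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_split() |>
    purrr::map(function(g) {
      t0 <- g$d15n[g$bottle_role == "t0"]
      tf <- g$d15n[g$bottle_role == "tf"]
      if (length(t0) == 0 || length(tf) == 0) {
        rlang::abort(paste0("sample ", g$sample_id[1],
                            ": needs at least one t0 and one tf bottle"))
      }
      est <- ao_rate(t0, tf, g$nh4_ambient[1], g$no2_initial[1],
                     g$spike_15n[1], g$t_incubation[1], calibration,
                     g$carrier_no2[1])
      est$rate_sd <- if (mc_draws > 0) {
        propagate_rate_sd(t0, tf, g$nh4_ambient[1], g$no2_initial[1],
                          g$spike_15n[1], g$t_incubation[1], calibration,
                          n_draws = mc_draws, seed = seed,
                          precisions = precisions)
      } else {
        NA_real_
      }
      dplyr::bind_cols(
        tibble::tibble(sample_id = g$sample_id[1]),
        g[1, meta_cols, drop = FALSE],
        est
      )
    }) |>
    purrr::list_rbind()
}
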