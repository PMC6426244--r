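# Gas constant, L atm / (mol K) -- convention used throughout the headspace
# mass balance.
R_GAS <- 0.08206

#' N2O solubility (Weiss and Price 1980)
#'
#' Equilibrium solubility K0 of nitrous oxide in water, mol/(L atm), from the
#' Weiss & Price (1980) fit: `ln K0 = A1 + A2*(100/T) + A3*ln(T/100) +
#' S*(B1 + B2*(T/100) + B3*(T/100)^2)` with T in kelvin and S in practical
#' salinity units. K0 decreases with temperature and with salinity
#' (salting-out); lake work uses S = 0.
#'
#' @param temp Water temperature, degrees C (between -2 and 40).
#' @param salinity Salinity, PSU (default 0, freshwater).
#' @return K0 in mol/(L atm).
#' @examples
#' n2o_solubility(5) > n2o_solubility(25)  # colder water holds more gas
#' @export
n2o_solubility <- function(temp, salinity = 0) {
  if (any(temp < -2 | temp > 40, na.rm = TRUE)) {
    rlang::abort("temperature out of range (-2, 40) degC for the solubility fit")
  }
  tk <- temp + 273.15
  a <- c(-62.7062, 97.3066, 24.1406)
  b <- c(-0.058420, 0.033193, -0.0051313)
  exp(a[1] + a[2] * (100 / tk) + a[3] * log(tk / 100) +
        salinity * (b[1] + b[2] * (tk / 100) + b[3] * (tk / 100)^2))
}

#' Dissolved N2O from a headspace equilibration
#'
#' Back-calculates the in-situ dissolved N2O concentration from a
#' headspace-equilibration measurement. A sealed bottle of volume `v_bottle`
#' is filled with lake water, `v_headspace` of water is replaced with ambient
#' air, and the bottle is shaken to equilibrium. Mass balance over the bottle:
#' N2O initially dissolved in the water (`C_water * V_w`) plus N2O in the
#' introduced air equals, after equilibration, dissolved N2O at solubility
#' equilibrium with the final headspace plus the N2O left in the headspace.
#' Solving for the unknown initial concentration:
#'
#' `C_water = K0(T_eq) * x_hs * P + (x_hs - x_air) * P * V_h / (R * T_eq * V_w)`
#'
#' with partial pressures `x * P` (dry mixing ratios, atm), the headspace
#' treated as ideal gas (R = 0.08206 L atm/mol/K), and `V_w = v_bottle -
#' v_headspace`. All arguments are vectorised.
#'
#' @param x_headspace Headspace N2O dry mixing ratio after equilibration, ppm.
#' @param x_air Ambient air N2O mixing ratio, ppm.
#' @param temp_equil Equilibration temperature, degC.
#' @param pressure Ambient atmospheric pressure, atm.
#' @param v_bottle Bottle volume, L (default 1.12).
#' @param v_headspace Headspace volume, L (default 0.12).
#' @param k0 Optional solubility override, mol/(L atm); default
#'   `n2o_solubility(temp_equil)`.
#' @return Dissolved N2O, nmol/L. An error is raised if the mass balance
#'   yields a negative concentration (nonphysical inputs).
#' @export
headspace_cwater <- function(x_headspace, x_air, temp_equil, pressure = 1,
                             v_bottle = 1.12, v_headspace = 0.12, k0 = NULL) {
  if (any(v_headspace <= 0 | v_headspace >= v_bottle)) {
    rlang::abort("need 0 < v_headspace < v_bottle")
  }
  if (any(x_headspace < 0 | x_air < 0)) {
    rlang::abort("mixing ratios must be >= 0")
  }
  if (is.null(k0)) k0 <- n2o_solubility(temp_equil)
  tk <- temp_equil + 273.15
  vw <- v_bottle - v_headspace
  p_hs <- x_headspace * 1e-6 * pressure
  p_air <- x_air * 1e-6 * pressure
  cw <- k0 * p_hs + (p_hs - p_air) * v_headspace / (R_GAS * tk * vw)
  cw_nmol <- cw * 1e9
  if (any(cw_nmol < 0)) {
    bad <- which(cw_nmol < 0)
    rlang::abort(paste0(
      "negative dissolved N2O solution at record(s) ",
      paste(bad, collapse = ", "),
      ": headspace depleted below what the introduced air can explain"
    ))
  }
  cw_nmol
}

#' Forward mass-balance check of a solved headspace record
#'
#' Re-computes total N2O moles in the bottle before (solved `c_water` plus the
#' introduced air) and after equilibration (dissolved at equilibrium plus
#' final headspace) and returns the relative residual. Zero (to rounding)
#' certifies conservation.
#'
#' @inheritParams headspace_cwater
#' @param c_water Solved dissolved concentration, nmol/L.
#' @return Relative residual |n_before - n_after| / n_after.
#' @export
n2o_balance_residual <- function(c_water, x_headspace, x_air, temp_equil,
                                 pressure = 1, v_bottle = 1.12,
                                 v_headspace = 0.12, k0 = NULL) {
  if (is.null(k0)) k0 <- n2o_solubility(temp_equil)
  tk <- temp_equil + 273.15
  vw <- v_bottle - v_headspace
  p_hs <- x_headspace * 1e-6 * pressure
  p_air <- x_air * 1e-6 * pressure
  n_before <- c_water * 1e-9 * vw + p_air * v_headspace / (R_GAS * tk)
  n_after <- k0 * p_hs * vw + p_hs * v_headspace / (R_GAS * tk)
  abs(n_before - n_after) / n_after
}

#' Dissolved N2O, equilibrium concentration and saturation deviation
#'
#' Processes a chronologically ordered table of headspace-equilibration
#' records into dissolved N2O (`c_water`), the air-equilibrium concentration
#' at in-situ temperature (`c_eq`) and the deviation from saturation
#' `delta_n2o = c_water - c_eq` (positive = supersaturation). Replicate vials
#' of the same `sample_id` are averaged (mixing ratios) before solving.
#'
#' Under ice no exchange with the atmosphere is possible, so all `under_ice`
#' samples of a winter reuse the equilibrium concentration of the first
#' under-ice sample of that winter (consecutive under-ice runs are treated as
#' one winter); these rows carry `winter_ceq_used = TRUE`.
#'
#' The deviation is also reported as a ppm-equivalent mixing-ratio deviation,
#' `delta_n2o_ppm = delta_n2o / (K0(T_insitu) * pressure)` (nmol/L converted
#' to mol/L), for comparison with air mixing ratios.
#'
#' @param headspace A data frame, one row per vial, with columns `sample_id`,
#'   `date`, `x_headspace`, `x_air`, `temp_equil`, `temp_insitu`, `pressure`,
#'   `under_ice`, and optionally `depth_label`, `v_bottle`, `v_headspace`.
#'   Must be sorted by date.
#' @return A tibble, one row per sample, with `c_water`, `c_eq`, `delta_n2o`
#'   (all nmol/L), `delta_n2o_ppm`, and `winter_ceq_used`.
#' @export
n2o_results <- function(headspace) {
  needed <- c("sample_id", "date", "x_headspace", "x_air", "temp_equil",
              "temp_insitu", "pressure", "under_ice")
  missing_cols <- setdiff(needed, names(headspace))
  if (length(missing_cols) > 0) {
    rlang::abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (is.unsorted(headspace$date)) {
    rlang::abort("headspace records must be sorted chronologically")
  }
  if (!"v_bottle" %in% names(headspace)) headspace$v_bottle <- 1.12
  if (!"v_headspace" %in% names(headspace)) headspace$v_headspace <- 0.12
  meta_cols <- intersect("depth_label", names(headspace))

  # average replicate vials on the measurement scale
  samples <- headspace |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      date = .data$date[1],
      dplyr::across(dplyr::all_of(meta_cols), ~ .x[1]),
      dplyr::across(dplyr::all_of(c("x_headspace", "x_air", "temp_equil",
                                    "temp_insitu", "pressure", "v_bottle",
                                    "v_headspace")), mean),
      under_ice = .data$under_ice[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$date)

  k0_insitu <- n2o_solubility(samples$temp_insitu)
  c_water <- headspace_cwater(samples$x_headspace, samples$x_air,
                              samples$temp_equil, samples$pressure,
                              samples$v_bottle, samples$v_headspace)
  c_eq_own <- k0_insitu * samples$x_air * 1e-6 * samples$pressure * 1e9

  # winter convention: each consecutive under-ice run shares the c_eq of its
  # first sample (the first sample of a winter reuses its own, flagged too)
  winter_id <- cumsum(samples$under_ice &
                        !dplyr::lag(samples$under_ice, default = FALSE))
  c_eq <- c_eq_own
  for (w in unique(winter_id[samples$under_ice])) {
    idx <- which(samples$under_ice & winter_id == w)
    c_eq[idx] <- c_eq_own[idx[1]]
  }

  tibble::tibble(
    sample_id = samples$sample_id,
    date = samples$date
  ) |>
    dplyr::bind_cols(samples[, meta_cols, drop = FALSE]) |>
    dplyr::mutate(
      c_water = c_water,
      c_eq = c_eq,
      delta_n2o = c_water - c_eq,
      delta_n2o_ppm = .data$delta_n2o * 1e-9 / (k0_insitu * samples$pressure) * 1e6,
      under_ice = samples$under_ice,
      winter_ceq_used = samples$under_ice
    )
}
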