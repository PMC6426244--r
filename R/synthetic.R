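#' Configuration for the synthetic incubation and lake-year generator
#'
#' Collects every planted truth the forward simulator needs: the true
#' ammonia-oxidation rate, the tracer design, the methodological bias
#' switches (substrate regeneration, nitrite consumption, over-spike
#' stimulation), analytical noise levels, and the seasonal structure of a
#' small dimictic shield lake (ice calendar, winter/summer nutrient and
#' chlorophyll levels, and the rate-NH4+ link).
#'
#' Defaults emulate the study conditions: winter-like ambient NH4+
#' (2.8 umol/L, summer mean 0.4), carrier addition of 0.25 umol/L NO2-,
#' 4 h in-lake incubations, analytical sigmas 6.8 per mil (delta-15N),
#' 0.2 and 0.06 umol/L (NH4+, NO3-+NO2-) and 0.3 ug/L (chl a), ice cover
#' Dec 10 to Apr 13, a spring NO3-+NO2- peak of 3.3 umol/L, winter chl a
#' 0.4 vs summer 4.0 ug/L, and seasonal AO rate levels of roughly 50
#' (open water) to 230 (winter) nmol/L/day with an NH4+ change point at
#' 2.6 umol/L.
#'
#' @param seed Integer seed.
#' @param r_true True AO rate, nmol/L/day (>= 0).
#' @param nh4_ambient,no2_ambient Ambient concentrations, umol/L.
#' @param spike_rule `"five_percent"` (5% of ambient with 0.05 floor),
#'   `"floor"` (always 0.05), or `"explicit"` (use `spike`).
#' @param spike Explicit spike, umol/L (only for `spike_rule = "explicit"`).
#' @param carrier Carrier NO2- addition, umol/L (default 0.25).
#' @param t_incubation Incubation duration, hours (default 4).
#' @param d15n_background Background delta-15N of the NO2- pool, per mil.
#' @param regeneration_rate Unlabelled NH4+ regeneration, umol/L/h (>= 0);
#'   dilutes the labelled fraction and biases estimates low.
#' @param no2_consumption_rate First-order NO2- consumption, fraction/h
#'   (>= 0); isotope-neutral on the delta scale.
#' @param overspike_stimulation Rate stimulation per unit spike/ambient
#'   (>= 0); biases estimates high when over-spiked.
#' @param noise Named list of one-sigma noise levels, see
#'   [analytical_precisions()].
#' @param seasonal Named list of seasonal parameters; see Details. Partial
#'   lists are merged over the defaults.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              r_true = 100,
                              nh4_ambient = 2.8,
                              no2_ambient = 0.05,
                              spike_rule = c("five_percent", "floor", "explicit"),
                              spike = NULL,
                              carrier = 0.25,
                              t_incubation = 4,
                              d15n_background = 0,
                              regeneration_rate = 0,
                              no2_consumption_rate = 0,
                              overspike_stimulation = 0,
                              noise = analytical_precisions(),
                              seasonal = list()) {
  spike_rule <- match.arg(spike_rule)
  stopifnot(
    r_true >= 0, nh4_ambient >= 0, no2_ambient >= 0, carrier >= 0,
    t_incubation > 0, t_incubation <= 24,
    regeneration_rate >= 0, no2_consumption_rate >= 0,
    overspike_stimulation >= 0,
    all(unlist(noise) >= 0)
  )
  if (spike_rule == "explicit" && (is.null(spike) || spike <= 0)) {
    rlang::abort("spike_rule = 'explicit' needs a positive spike")
  }
  seasonal_defaults <- list(
    year_start = as.Date("2011-10-01"),
    ice_on = as.Date("2011-12-10"),
    ice_off = as.Date("2012-04-13"),
    nh4_winter_mean = 2.8, nh4_spring_mean = 2.0,
    nh4_summer_mean = 0.4, nh4_autumn_mean = 1.5, nh4_sd = 0.3,
    no3_spring_peak = 3.3, no3_autumn_min = 0.2, no3_sd = 0.06,
    chla_winter = 0.4, chla_summer = 4.0, chla_shoulder = 2.0,
    rate_link = "saturation",
    rate_nh4_threshold = 2.6, rate_low = 50, rate_high = 230,
    rate_max = 350, rate_km = 1.5, rate_sd = 40
  )
  bad <- setdiff(names(seasonal), names(seasonal_defaults))
  if (length(bad) > 0) {
    rlang::abort(paste("unknown seasonal parameter(s):",
                       paste(bad, collapse = ", ")))
  }
  seasonal <- utils::modifyList(seasonal_defaults, seasonal)
  if (seasonal$ice_on >= seasonal$ice_off) {
    rlang::abort("ice_on must precede ice_off")
  }
  structure(
    list(
      seed = as.integer(seed), r_true = r_true, nh4_ambient = nh4_ambient,
      no2_ambient = no2_ambient, spike_rule = spike_rule, spike = spike,
      carrier = carrier, t_incubation = t_incubation,
      d15n_background = d15n_background,
      regeneration_rate = regeneration_rate,
      no2_consumption_rate = no2_consumption_rate,
      overspike_stimulation = overspike_stimulation,
      noise = noise, seasonal = seasonal
    ),
    class = "simulation_config"
  )
}

# Integral of the labelled fraction alpha(t) = spike / (N0 + rho * t) times
# the nitrite-pool correction exp(k * t) over the incubation, in hours.
# Closed form when consumption k = 0; numeric quadrature otherwise.
label_transfer_integral <- function(spike, n0, rho, k, t_h) {
  if (k == 0) {
    if (rho == 0) {
      spike / n0 * t_h
    } else {
      (spike / rho) * log1p(rho * t_h / n0)
    }
  } else {
    stats::integrate(function(u) spike / (n0 + rho * u) * exp(k * u),
                     0, t_h, rel.tol = 1e-10)$value
  }
}

#' Forward-simulate one 15N tracer incubation
#'
#' Generates the bottle-level measurements of a single end-point tracer
#' experiment under a planted true AO rate, including the methodological
#' biases the tracer design is vulnerable to:
#'
#' * substrate regeneration at `regeneration_rate` adds unlabelled NH4+
#'   continuously, so the labelled fraction decays as
#'   `alpha(t) = spike / (N0 + rho t)` (integrated in closed form) and the
#'   single-alpha rate equation under-estimates the truth;
#' * first-order NO2- consumption shrinks the receiving pool (isotope-neutral
#'   on the delta scale), concentrating the label;
#' * over-spike stimulation raises the realised oxidation rate by
#'   `1 + overspike_stimulation * spike/ambient`, the over-estimation risk
#'   that the 15% spike flag guards against.
#'
#' The accumulated atom-fraction excess of the NO2- pool is halved onto the
#' N2O measurement scale (azide method), converted to delta-15N, and
#' measured with Gaussian noise on duplicate t0 and end-point bottles.
#'
#' @param cfg A [simulation_config()].
#' @param sample_id Identifier for the generated incubation.
#' @return A list with `record` (a long-format bottle tibble directly
#'   consumable by [estimate_ao_rates()]) and `truth` (planted values:
#'   `r_true`, `r_realised` after stimulation, `spike`, `alpha0`,
#'   `af_excess_no2` at the end of the incubation).
#' @export
simulate_incubation <- function(cfg, sample_id = "sim-01") {
  stopifnot(inherits(cfg, "simulation_config"))
  spike <- switch(cfg$spike_rule,
    five_percent = design_spike(cfg$nh4_ambient),
    floor = 0.05,
    explicit = cfg$spike
  )
  no2_initial <- cfg$no2_ambient + cfg$carrier
  alpha0 <- compute_alpha(spike, cfg$nh4_ambient)
  stim_ratio <- if (cfg$nh4_ambient > 0) spike / cfg$nh4_ambient else 0
  r_realised <- cfg$r_true * (1 + cfg$overspike_stimulation * stim_ratio)

  n0 <- spike + cfg$nh4_ambient
  x_excess <- r_realised / 24 *
    label_transfer_integral(spike, n0, cfg$regeneration_rate,
                            cfg$no2_consumption_rate, cfg$t_incubation) /
    (no2_initial * 1000)

  af_nat <- delta_to_atom_fraction(cfg$d15n_background)
  d_t0 <- atom_fraction_to_delta(rep(af_nat, 2))
  d_tf <- atom_fraction_to_delta(rep(af_nat + x_excess / 2, 2))
  record <- withr::with_seed(cfg$seed, {
    tibble::tibble(
      sample_id = sample_id,
      bottle_role = c("t0", "t0", "tf", "tf"),
      d15n = c(d_t0, d_tf) + stats::rnorm(4, 0, cfg$noise$d15n),
      nh4_ambient = cfg$nh4_ambient,
      no2_initial = no2_initial,
      spike_15n = spike,
      carrier_no2 = cfg$carrier,
      t_incubation = cfg$t_incubation
    )
  })
  list(
    record = record,
    truth = list(
      r_true = cfg$r_true, r_realised = r_realised, spike = spike,
      alpha0 = alpha0, af_excess_no2 = x_excess
    )
  )
}

season_of <- function(date, seasonal) {
  in_ice <- date >= seasonal$ice_on & date <= seasonal$ice_off
  spring_end <- as.Date(format(seasonal$ice_off, "%Y-05-31"))
  summer_end <- as.Date(format(seasonal$ice_off, "%Y-09-30"))
  dplyr::case_when(
    in_ice ~ "winter",
    date > seasonal$ice_off & date <= spring_end ~ "spring",
    date > spring_end & date <= summer_end ~ "summer",
    TRUE ~ "autumn"
  )
}

# piecewise-linear seasonal NO3-+NO2- trajectory: low in autumn, ramping
# under ice to a spring peak two weeks after ice-out, then declining through
# the stratified period
no3_trajectory <- function(date, seasonal) {
  peak_date <- seasonal$ice_off + 15
  decline_end <- as.Date(format(seasonal$ice_off, "%Y-10-01"))
  lo <- seasonal$no3_autumn_min
  hi <- seasonal$no3_spring_peak
  dplyr::case_when(
    date < seasonal$ice_on ~ lo,
    date <= peak_date ~ lo + (hi - lo) *
      as.numeric(date - seasonal$ice_on) /
      as.numeric(peak_date - seasonal$ice_on),
    date <= decline_end ~ hi - (hi - lo) *
      as.numeric(date - peak_date) /
      as.numeric(decline_end - peak_date),
    TRUE ~ lo
  )
}

rate_from_nh4 <- function(nh4, seasonal) {
  if (seasonal$rate_link == "threshold") {
    ifelse(nh4 > seasonal$rate_nh4_threshold,
           seasonal$rate_high, seasonal$rate_low)
  } else {
    seasonal$rate_max * nh4 / (seasonal$rate_km + nh4)
  }
}

#' Simulate an annual under-ice lake time series
#'
#' Generates a 13-month seasonal sampling campaign for a small dimictic lake:
#' `n_dates` evenly spaced sampling dates, each visited at two depths (top =
#' 10% surface light, bottom = 1%) during day and night. Under-ice dates
#' carry `light_fraction = 0` and the winter season label. NH4+ is drawn
#' around seasonal means (high in winter after fall overturn, low in
#' stratified summer), NO3-+NO2- ramps under ice to a spring peak then
#' declines, chlorophyll a mirrors nutrients (low under ice, high in summer),
#' and the AO rate is a monotone function of NH4+ (saturating by default, or
#' a step at the configured threshold) plus noise, clipped at zero.
#' Dissolved-N2O deviation from saturation accumulates under ice within the
#' plausible range (about -0.06 to 0.12 ppm as mixing-ratio equivalent).
#'
#' @param cfg A [simulation_config()].
#' @param n_dates Number of sampling dates (>= 12).
#' @return A tibble, one row per date x depth x diel sample: `date`,
#'   `season`, `depth_label`, `diel`, `nh4`, `no3no2`, `o2`, `temp`,
#'   `light_fraction`, `chla`, `ao_rate`, `ao_rate_true` (noise-free rate),
#'   `delta_n2o` (nmol/L), `delta_n2o_ppm`, `under_ice`.
#' @export
simulate_year <- function(cfg, n_dates = 12) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (n_dates < 12) rlang::abort("n_dates must be >= 12")
  sl <- cfg$seasonal
  dates <- sl$year_start + round(seq(0, 395, length.out = n_dates))
  grid <- tidyr::expand_grid(
    date = dates,
    depth_label = c("top", "bottom"),
    diel = c("day", "night")
  )
  withr::with_seed(cfg$seed, {
    n <- nrow(grid)
    season <- season_of(grid$date, sl)
    under_ice <- grid$date >= sl$ice_on & grid$date <= sl$ice_off
    nh4_mean <- dplyr::case_when(
      season == "winter" ~ sl$nh4_winter_mean,
      season == "spring" ~ sl$nh4_spring_mean,
      season == "summer" ~ sl$nh4_summer_mean,
      TRUE ~ sl$nh4_autumn_mean
    )
    nh4 <- pmax(stats::rnorm(n, nh4_mean, sl$nh4_sd), 0.02)
    no3no2 <- pmax(stats::rnorm(n, no3_trajectory(grid$date, sl), sl$no3_sd),
                   0.01)
    temp_mean <- dplyr::case_when(
      season == "winter" ~ 1.5,
      season == "spring" ~ 6,
      season == "summer" & grid$depth_label == "top" ~ 20,
      season == "summer" ~ 10,
      TRUE ~ 8
    )
    temp <- pmax(stats::rnorm(n, temp_mean, 1), 0.5)
    o2_mean <- dplyr::case_when(
      season == "winter" ~ 11,
      season == "summer" & grid$depth_label == "bottom" ~ 5,
      season == "summer" ~ 9,
      TRUE ~ 10.5
    )
    o2 <- pmax(stats::rnorm(n, o2_mean, 0.5), 2.9)
    light_fraction <- ifelse(under_ice, 0,
                             ifelse(grid$depth_label == "top", 0.10, 0.01))
    chla_mean <- dplyr::case_when(
      season == "winter" ~ sl$chla_winter,
      season == "summer" ~ sl$chla_summer,
      TRUE ~ sl$chla_shoulder
    )
    chla <- pmax(stats::rnorm(n, chla_mean, cfg$noise$chla), 0.02)
    rate_true <- rate_from_nh4(nh4, sl)
    ao_rate <- pmax(rate_true + stats::rnorm(n, 0, sl$rate_sd), 0)
    # ppm-equivalent saturation deviation: linear build-up under ice
    ice_frac <- pmin(pmax(as.numeric(grid$date - sl$ice_on) /
                            as.numeric(sl$ice_off - sl$ice_on), 0), 1)
    dppm <- ifelse(under_ice,
                   0.02 + 0.10 * ice_frac + stats::rnorm(n, 0, 0.01),
                   stats::rnorm(n, 0, 0.02))
    dppm <- pmin(pmax(dppm, -0.06), 0.12)
    delta_n2o <- dppm * 1e-6 * n2o_solubility(temp) * 1e9
    tibble::tibble(
      date = grid$date, season = season, depth_label = grid$depth_label,
      diel = grid$diel, nh4 = nh4, no3no2 = no3no2, o2 = o2, temp = temp,
      light_fraction = light_fraction, chla = chla,
      ao_rate = ao_rate, ao_rate_true = rate_true,
      delta_n2o = delta_n2o, delta_n2o_ppm = dppm, under_ice = under_ice
    )
  })
}

#' Write a deterministic fixture bundle for every pipeline stage
#'
#' Generates and writes the CSV inputs each pipeline stage consumes --
#' calibration standards, tracer incubations, headspace equilibrations,
#' chlorophyll-a absorbances and a seasonal campaign -- plus a JSON manifest
#' of the planted truths. Identical seeds produce byte-identical bundles.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the written file paths.
#' @export
make_fixture_suite <- function(seed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    standards = file.path(dir, "standards.csv"),
    incubations = file.path(dir, "incubations.csv"),
    headspace = file.path(dir, "headspace.csv"),
    chla = file.path(dir, "chla.csv"),
    seasonal = file.path(dir, "seasonal.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  withr::with_seed(seed, {
    known <- nitrite_standards()
    standards <- tibble::tibble(
      standard_id = paste0("std", seq_along(known)),
      d15n_known = known,
      d15n_measured = (known - 1.5) / 0.97 + stats::rnorm(length(known), 0, 0.3)
    )

    inc_truth <- tibble::tibble(
      sample_id = sprintf("inc-%02d", 1:8),
      r_true = c(230, 180, 260, 120, 40, 60, 20, 90),
      nh4_ambient = c(2.8, 2.6, 3.1, 2.0, 0.4, 0.6, 0.3, 1.5)
    )
    inc_seeds <- sample.int(1e6, nrow(inc_truth))
    incubations <- purrr::map(seq_len(nrow(inc_truth)), function(i) {
      cfg <- simulation_config(
        seed = inc_seeds[i], r_true = inc_truth$r_true[i],
        nh4_ambient = inc_truth$nh4_ambient[i]
      )
      sim <- simulate_incubation(cfg, sample_id = inc_truth$sample_id[i])
      # raw (uncalibrated) deltas: invert the calibration line the standards
      # were generated under
      sim$record$d15n <- (sim$record$d15n - 1.5) / 0.97
      sim$record
    }) |>
      purrr::list_rbind()

    hs_dates <- as.Date("2012-01-15") + c(0, 30, 60, 120, 210, 300)
    hs <- tidyr::expand_grid(
      date = hs_dates, vial = 1:3
    ) |>
      dplyr::mutate(
        sample_id = format(.data$date, "hs-%Y%m%d"),
        depth_label = "top",
        under_ice = .data$date <= as.Date("2012-04-13"),
        temp_insitu = ifelse(.data$under_ice, 2, 15),
        temp_equil = 20,
        pressure = 1,
        x_air = 0.33,
        x_headspace = ifelse(.data$under_ice, 0.70, 0.38) +
          stats::rnorm(dplyr::n(), 0, 0.002),
        v_bottle = 1.12, v_headspace = 0.12
      ) |>
      dplyr::select(-"vial")

    chla_truth <- c(0.4, 2.1, 4.0, 3.2)
    chla <- tidyr::expand_grid(
      sample_id = paste0("chl-", seq_along(chla_truth)), replicate = 1:3
    ) |>
      dplyr::mutate(
        truth = rep(chla_truth, each = 3),
        v_extract = 10, v_filtered = 0.5, path_length = 1,
        a750_before = 0.005, a750_after = 0.005,
        # invert the Lorenzen form to absorbances, with replicate noise
        a665_after = 0.020,
        a665_before = .data$a665_after +
          (.data$truth + stats::rnorm(dplyr::n(), 0, 0.3)) *
          .data$v_filtered * .data$path_length / (26.7 * .data$v_extract)
      ) |>
      dplyr::select(-"truth")

    seasonal <- simulate_year(simulation_config(seed = seed), n_dates = 12)

    readr::write_csv(standards, paths$standards)
    readr::write_csv(incubations, paths$incubations)
    readr::write_csv(hs, paths$headspace)
    readr::write_csv(chla, paths$chla)
    readr::write_csv(seasonal, paths$seasonal)
    jsonlite::write_json(
      list(
        seed = seed,
        calibration = list(slope = 0.97, intercept = 1.5),
        incubations = inc_truth,
        chla_true = chla_truth,
        files = lapply(paths, basename)
      ),
      paths$manifest,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  })
  invisible(paths)
}
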