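# Independent oracles used across the suite. These re-derive expected values
# from first principles and deliberately avoid the package's own code paths.

# Direct evaluation of the printed rate equation:
# r = 2 * (n15_f - n15_i) * NO2(i) / (t * alpha), atom fractions measured on
# the N2O scale, NO2- in nmol/L, t in days, alpha = spike/(spike + ambient).
oracle_ao_rate <- function(d15n_t0, d15n_tf, nh4, no2, spike, t_h,
                           cal_slope = 1, cal_intercept = 0) {
  af <- function(d) {
    r <- 0.0036765 * (d / 1000 + 1)
    r / (1 + r)
  }
  n15_i <- mean(af(cal_slope * d15n_t0 + cal_intercept))
  n15_f <- mean(af(cal_slope * d15n_tf + cal_intercept))
  alpha <- spike / (spike + nh4)
  2 * (n15_f - n15_i) * no2 * 1000 / ((t_h / 24) * alpha)
}

# Place an atom-fraction excess (N2O scale) onto delta values around a
# baseline, for constructing incubation bottles with known enrichment.
delta_with_excess <- function(excess_n2o, baseline = 0) {
  r0 <- 0.0036765 * (baseline / 1000 + 1)
  af <- r0 / (1 + r0) + excess_n2o
  r <- af / (1 - af)
  (r / 0.0036765 - 1) * 1000
}

# Exhaustive best single split of a numeric/factor covariate table by SSE
# reduction: every midpoint between sorted unique values of numeric columns,
# every proper level subset of factor columns.
oracle_best_split <- function(data, response, covariates, min_leaf = 1) {
  y <- data[[response]]
  sse <- function(v) sum((v - mean(v))^2)
  best <- list(sse = Inf, variable = NA_character_, threshold = NA_real_)
  for (cl in covariates) {
    x <- data[[cl]]
    if (is.numeric(x)) {
      v <- sort(unique(x))
      if (length(v) < 2) next
      mids <- (v[-1] + v[-length(v)]) / 2
      for (m in mids) {
        left <- x < m
        if (sum(left) < min_leaf || sum(!left) < min_leaf) next
        s <- sse(y[left]) + sse(y[!left])
        if (s < best$sse) best <- list(sse = s, variable = cl, threshold = m)
      }
    } else {
      lev <- unique(as.character(x))
      if (length(lev) < 2) next
      for (k in seq_len(2^(length(lev) - 1) - 1)) {
        subset_lev <- lev[as.logical(intToBits(k))[seq_along(lev)]]
        left <- as.character(x) %in% subset_lev
        if (sum(left) < min_leaf || sum(!left) < min_leaf) next
        s <- sse(y[left]) + sse(y[!left])
        if (s < best$sse) best <- list(sse = s, variable = cl, threshold = NA)
      }
    }
  }
  best
}

# A quiet simulation config with all analytical noise switched off.
noiseless_config <- function(...) {
  simulation_config(..., noise = analytical_precisions(0, 0, 0, 0))
}

# Build an at-equilibrium headspace record: water equilibrated with air at
# the equilibration temperature, so shaking changes nothing.
equilibrium_headspace <- function(x_air = 0.33, temp = 12, pressure = 1,
                                  date = as.Date("2012-06-01"),
                                  sample_id = "eq") {
  tibble::tibble(
    sample_id = sample_id, date = date, x_headspace = x_air, x_air = x_air,
    temp_equil = temp, temp_insitu = temp, pressure = pressure,
    under_ice = FALSE
  )
}
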