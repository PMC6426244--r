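test_that("the rate equation matches direct arithmetic on a worked case", {
  # 0.00025 atom-fraction excess on the N2O scale, NO2-(i) = 0.3 umol/L,
  # 4 h, alpha = 0.05: 2 * 0.00025 * 300 / ((4/24) * 0.05) = 18.0 nmol/L/d
  d0 <- delta_with_excess(0)
  df <- delta_with_excess(0.00025)
  est <- ao_rate(d0, df, nh4_ambient = 0.95, no2_initial = 0.3,
                 spike_15n = 0.05, t_incubation = 4)
  expect_equal(est$alpha, 0.05)
  expect_equal(est$rate, 18.0, tolerance = 1e-6)
  expect_equal(est$rate,
               oracle_ao_rate(d0, df, 0.95, 0.3, 0.05, 4),
               tolerance = 1e-12)
})

test_that("zero enrichment is a valid detected zero; depletion is non-detect", {
  d0 <- delta_with_excess(0)
  est0 <- ao_rate(d0, d0, 1, 0.3, 0.05, 4)
  expect_true(est0$detected)
  expect_equal(est0$rate, 0)

  dneg <- delta_with_excess(-0.0001)
  estn <- ao_rate(d0, dneg, 1, 0.3, 0.05, 4)
  expect_false(estn$detected)
  expect_equal(estn$rate, 0)
  expect_lt(estn$raw_rate, 0)
})

test_that("over-spiked incubations are flagged above 15% of ambient", {
  est <- ao_rate(delta_with_excess(0), delta_with_excess(1e-4),
                 nh4_ambient = 1.0, no2_initial = 0.3, spike_15n = 0.5,
                 t_incubation = 4)
  expect_true(est$overspike_flag)
  expect_equal(est$overspike_ratio, 0.5)
  ok <- flag_overspike(0.05, 1.0)
  expect_false(ok$overspike_flag)
  expect_true(flag_overspike(0.05, 0)$overspike_flag)  # ambient zero
})

test_that("spike design follows the 5% rule with a 0.05 umol/L floor", {
  expect_equal(design_spike(2.0), 0.10)
  expect_equal(design_spike(0), 0.05)
  expect_equal(design_spike(1.0), 0.05)  # rules coincide at the boundary
  expect_error(design_spike(-1), ">= 0")
})

test_that("rate is linear in enrichment and NO2-, inverse in time and alpha", {
  set.seed(21)
  for (i in 1:25) {
    ex <- stats::runif(1, 1e-5, 5e-4)
    nh4 <- stats::runif(1, 0.1, 3)
    no2 <- stats::runif(1, 0.26, 0.6)
    spike <- stats::runif(1, 0.05, 0.2)
    t_h <- stats::runif(1, 2, 8)
    base <- ao_rate(delta_with_excess(0), delta_with_excess(ex),
                    nh4, no2, spike, t_h)$rate
    expect_equal(base,
                 oracle_ao_rate(delta_with_excess(0), delta_with_excess(ex),
                                nh4, no2, spike, t_h),
                 tolerance = 1e-9)
    expect_equal(ao_rate(delta_with_excess(0), delta_with_excess(2 * ex),
                         nh4, no2, spike, t_h)$rate, 2 * base,
                 tolerance = 1e-6)
    expect_equal(ao_rate(delta_with_excess(0), delta_with_excess(ex),
                         nh4, 2 * no2, spike, t_h)$rate, 2 * base,
                 tolerance = 1e-9)
    expect_equal(ao_rate(delta_with_excess(0), delta_with_excess(ex),
                         nh4, no2, spike, t_h / 2)$rate, 2 * base,
                 tolerance = 1e-9)
  }
})

test_that("more ambient NH4+ at fixed spike raises the rate (smaller alpha)", {
  rates <- vapply(c(0.5, 1, 2, 3), function(nh4) {
    ao_rate(delta_with_excess(0), delta_with_excess(2e-4), nh4,
            0.3, 0.05, 4)$rate
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("invalid incubation records are rejected", {
  d <- delta_with_excess(0)
  expect_error(ao_rate(d, d, 1, 0, 0.05, 4), "no2_initial")
  expect_error(ao_rate(d, d, 1, 0.3, 0.05, 0), "t_incubation")
  expect_error(ao_rate(d, d, 1, 0.3, 0.05, 30), "t_incubation")
  expect_error(ao_rate(d, d, 1, 0.1, 0.05, 4, carrier_no2 = 0.25), "carrier")
})

test_that("Monte-Carlo SD is zero without noise, seeded, and ~linear in
           delta noise when it dominates", {
  d0 <- delta_with_excess(0)
  df <- delta_with_excess(3e-4)
  zero <- propagate_rate_sd(d0, df, 1, 0.3, 0.05, 4, n_draws = 200, seed = 5,
                            precisions = analytical_precisions(0, 0, 0, 0))
  expect_equal(zero, 0)
  s1 <- propagate_rate_sd(d0, df, 1, 0.3, 0.05, 4, n_draws = 400, seed = 9,
                          precisions = analytical_precisions(6.8, 0, 0, 0))
  s1b <- propagate_rate_sd(d0, df, 1, 0.3, 0.05, 4, n_draws = 400, seed = 9,
                           precisions = analytical_precisions(6.8, 0, 0, 0))
  expect_identical(s1, s1b)
  s2 <- propagate_rate_sd(d0, df, 1, 0.3, 0.05, 4, n_draws = 400, seed = 9,
                          precisions = analytical_precisions(13.6, 0, 0, 0))
  expect_gt(s2 / s1, 1.7)
  expect_lt(s2 / s1, 2.3)
  expect_error(propagate_rate_sd(d0, df, 1, 0.3, 0.05, 4, n_draws = 10),
               "n_draws")
})

test_that("the long-format table interface reproduces per-record estimates", {
  d0 <- delta_with_excess(0)
  df <- delta_with_excess(2e-4)
  inc <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 4),
    bottle_role = rep(c("t0", "t0", "tf", "tf"), 2),
    d15n = c(d0, d0, df, df, d0, d0, d0, d0),
    nh4_ambient = 1, no2_initial = 0.3, spike_15n = 0.05,
    carrier_no2 = 0.25, t_incubation = 4,
    depth_label = rep(c("top", "bottom"), each = 4)
  )
  out <- estimate_ao_rates(inc, mc_draws = 100, seed = 2)
  expect_equal(nrow(out), 2)
  expect_equal(out$rate[out$sample_id == "a"],
               ao_rate(d0, df, 1, 0.3, 0.05, 4)$rate)
  expect_equal(out$rate[out$sample_id == "b"], 0)
  expect_true(all(out$rate_sd > 0))
  expect_true("depth_label" %in% names(out))
  expect_error(estimate_ao_rates(inc[, -3]), "missing columns")
  expect_error(
    estimate_ao_rates(dplyr::mutate(inc, bottle_role = "t0")),
    "tf bottle"
  )
})
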