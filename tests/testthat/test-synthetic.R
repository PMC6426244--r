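test_that("noiseless simulation inverts to the planted rate exactly", {
  for (r_true in c(0, 5, 123.4, 333)) {
    cfg <- noiseless_config(seed = 2, r_true = r_true)
    sim <- simulate_incubation(cfg)
    est <- estimate_ao_rates(sim$record)
    if (r_true == 0) {
      expect_equal(est$rate, 0)
      expect_true(est$detected)
    } else {
      expect_lt(abs(est$rate - r_true) / r_true, 1e-9)
    }
  }
})

test_that("spike rules and truth bookkeeping are honoured", {
  cfg <- noiseless_config(seed = 1, nh4_ambient = 2.0)
  sim <- simulate_incubation(cfg)
  expect_equal(unique(sim$record$spike_15n), 0.10)  # 5% rule
  expect_equal(sim$truth$alpha0, 0.10 / 2.10)
  cfg2 <- noiseless_config(seed = 1, nh4_ambient = 2.0, spike_rule = "floor")
  expect_equal(unique(simulate_incubation(cfg2)$record$spike_15n), 0.05)
  expect_error(simulation_config(spike_rule = "explicit"), "positive spike")
})

test_that("substrate regeneration biases the estimate low, monotonically", {
  ests <- vapply(c(0, 0.2, 0.5, 1.0), function(rho) {
    cfg <- noiseless_config(seed = 3, r_true = 100, regeneration_rate = rho)
    estimate_ao_rates(simulate_incubation(cfg)$record)$rate
  }, numeric(1))
  expect_equal(ests[1], 100, tolerance = 1e-9)
  expect_true(all(ests[-1] < 100))
  expect_true(all(diff(ests) < 0))
})

test_that("over-spike stimulation biases the estimate high, monotonically", {
  ests <- vapply(c(0, 0.5, 1, 2), function(s) {
    cfg <- noiseless_config(seed = 3, r_true = 100, nh4_ambient = 0.1,
                            spike_rule = "explicit", spike = 0.05,
                            overspike_stimulation = s)
    estimate_ao_rates(simulate_incubation(cfg)$record)$rate
  }, numeric(1))
  expect_equal(ests[1], 100, tolerance = 1e-9)
  expect_true(all(ests[-1] > 100))
  expect_true(all(diff(ests) > 0))
})

test_that("nitrite consumption concentrates the label (estimate high)", {
  base <- estimate_ao_rates(simulate_incubation(
    noiseless_config(seed = 3, r_true = 100)
  )$record)$rate
  cons <- estimate_ao_rates(simulate_incubation(
    noiseless_config(seed = 3, r_true = 100, no2_consumption_rate = 0.05)
  )$record)$rate
  expect_gt(cons, base)
})

test_that("rates are recovered within tolerance under analytical noise", {
  # study conditions: winter-like ambient, 5% spike, 4 h, delta sigma 6.8
  errs <- vapply(1:100, function(s) {
    cfg <- simulation_config(seed = s, r_true = 100)
    est <- estimate_ao_rates(simulate_incubation(cfg)$record)
    abs(est$rate - 100) / 100
  }, numeric(1))
  expect_lte(stats::median(errs), 0.25)
})

test_that("the seasonal generator reproduces the planted seasonal structure", {
  yrs <- purrr::map(1:15, function(s) {
    simulate_year(simulation_config(seed = s), n_dates = 12)
  }) |>
    purrr::list_rbind()
  expect_equal(nrow(yrs), 15 * 48)
  winter <- yrs[yrs$season == "winter", ]
  expect_gt(nrow(winter), 200)
  se <- stats::sd(winter$nh4) / sqrt(nrow(winter))
  expect_lt(abs(mean(winter$nh4) - 2.8), 2 * se + 0.05)
  summer <- yrs[yrs$season == "summer", ]
  expect_lt(abs(mean(summer$nh4) - 0.4), 0.1)
  # winter chl a is ~10% of summer
  ratio <- mean(winter$chla) / mean(summer$chla)
  expect_gt(ratio, 0.05)
  expect_lt(ratio, 0.2)
  # nitrate peaks in spring above the winter start
  expect_gt(max(yrs$no3no2[yrs$season == "spring"]), 3)
  # no light under ice; saturation deviation within the plausible range
  expect_true(all(yrs$light_fraction[yrs$under_ice] == 0))
  expect_true(all(yrs$delta_n2o_ppm >= -0.06 & yrs$delta_n2o_ppm <= 0.12))
  expect_true(all(yrs$ao_rate >= 0))
})

test_that("without noise the rate is a deterministic monotone map of NH4+", {
  cfg <- simulation_config(seed = 5)
  yr <- simulate_year(cfg, n_dates = 12)
  ord <- order(yr$nh4)
  expect_true(all(diff(yr$ao_rate_true[ord]) >= 0))
  # saturating link: strictly increasing in nh4
  expect_true(all(diff(yr$ao_rate_true[ord])[diff(yr$nh4[ord]) > 0] > 0))
  # threshold link: exactly two levels
  yr2 <- simulate_year(simulation_config(
    seed = 5, seasonal = list(rate_link = "threshold")
  ), n_dates = 12)
  expect_equal(sort(unique(yr2$ao_rate_true)), c(50, 230))
})

test_that("fixture bundles are byte-identical for identical seeds", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  make_fixture_suite(7, d1)
  make_fixture_suite(7, d2)
  make_fixture_suite(8, d3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_false(identical(readLines(file.path(d1, "incubations.csv")),
                         readLines(file.path(d3, "incubations.csv"))))
  # same schema either way
  expect_identical(readLines(file.path(d1, "incubations.csv"), n = 1),
                   readLines(file.path(d3, "incubations.csv"), n = 1))
})

test_that("manifest truths round-trip through the pipeline", {
  d <- withr::local_tempdir()
  make_fixture_suite(11, d)
  manifest <- jsonlite::read_json(file.path(d, "manifest.json"),
                                  simplifyVector = TRUE)
  res <- run_pipeline(d, mc_draws = 100, seed = 11)
  truth <- manifest$incubations
  got <- res$rates[match(truth$sample_id, res$rates$sample_id), ]
  # analytical noise (6.8 permil on duplicates) leaves a few percent of
  # scatter; planted rates span 20-260 nmol/L/d
  rel <- abs(got$rate - truth$r_true) / truth$r_true
  expect_lt(stats::median(rel), 0.25)
  expect_equal(manifest$seed, 11)
})
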