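test_that("Kruskal-Wallis and Dunn match hand-computed rank arithmetic", {
  # {1,2,3} vs {10,11,12}: ranks 1-3 vs 4-6, H = 12/42*(12^2/3+15^2/3)... =
  # 12/(6*7)*(36/3 + 225/3) - 3*7 = 3.857142857
  cmp <- compare_groups(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(cmp$kruskal$statistic, 3.857142857142854, tolerance = 1e-9)
  # Dunn z = (2 - 5) / sqrt(6*7/12 * (1/3+1/3)) = -1.963961
  expect_equal(cmp$dunn$z, -1.963961, tolerance = 1e-5)
  expect_equal(cmp$dunn$p_raw, 0.049535, tolerance = 1e-5)
  # single comparison: Holm leaves it unchanged
  expect_equal(cmp$dunn$p_adj, cmp$dunn$p_raw)
})

test_that("identical groups share a letter; separated groups do not", {
  set.seed(8)
  same <- stats::rnorm(30)
  cmp <- compare_groups(rep(same[1:10], 3), rep(c("a", "b", "c"), each = 10))
  expect_lt(cmp$kruskal$statistic, 1e-9)
  expect_equal(length(unique(cmp$letters$letters)), 1)

  x <- c(stats::rnorm(10, 0), stats::rnorm(10, 50), stats::rnorm(10, 100))
  cmp2 <- compare_groups(x, rep(c("lo", "mid", "hi"), each = 10))
  expect_lt(cmp2$kruskal$p_value, 0.001)
  lt <- cmp2$letters
  expect_false(lt$letters[lt$group == "lo"] == lt$letters[lt$group == "hi"])
})

test_that("Holm adjustment is monotone and never below the raw p", {
  set.seed(12)
  x <- c(stats::rnorm(8, 0), stats::rnorm(8, 1), stats::rnorm(8, 3),
         stats::rnorm(8, 10))
  cmp <- compare_groups(x, rep(letters[1:4], each = 8))
  expect_true(all(cmp$dunn$p_adj >= cmp$dunn$p_raw))
  # smallest raw p gets the largest multiplier (number of comparisons)
  k <- which.min(cmp$dunn$p_raw)
  expect_equal(cmp$dunn$p_adj[k],
               min(cmp$dunn$p_raw[k] * nrow(cmp$dunn), 1))
})

test_that("degenerate group data are refused", {
  expect_error(compare_groups(rep(1, 10), rep(c("a", "b"), 5)), "degenerate")
  expect_error(compare_groups(1:4, rep("a", 4)), "2 groups")
})

test_that("paired t matches the hand formula and handles degenerate pairs", {
  # pairs (1,2), (2,4), (3,5): differences {-1,-2,-2}, t = -5, df = 2
  out <- paired_test(c(1, 2, 3), c(2, 4, 5))
  expect_equal(out$t, -5, tolerance = 1e-9)
  expect_equal(out$df, 2)
  expect_equal(out$p_value, 0.03774955, tolerance = 1e-6)

  eq <- paired_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)

  expect_error(paired_test(c(1, 2, 3), c(2, 3, 4)), "degenerate")
  expect_error(paired_test(1:3, 1:4), "length")
})

test_that("Pearson correlation matches hand covariance arithmetic", {
  expect_equal(correlate(1:5, 1:5)$r, 1)
  expect_equal(correlate(1:5, -(1:5))$r, -1)
  # 4-point worked set {1,2,3,5} vs {2,1,4,6}
  expect_equal(correlate(c(1, 2, 3, 5), c(2, 1, 4, 6))$r, 0.9022436387,
               tolerance = 1e-9)
  expect_error(correlate(rep(1, 4), 1:4), "zero variance")
})

test_that("forward selection recovers a planted single predictor", {
  set.seed(3)
  n <- 40
  x1 <- stats::rnorm(n)
  x2 <- stats::rnorm(n)
  x3 <- stats::rnorm(n)
  y <- 5 * x1 + stats::rnorm(n, 0, 0.1)
  dat <- tibble::tibble(y = y, x1 = x1, x2 = x2, x3 = x3)
  m <- forward_mlr(dat, "y", c("x1", "x2", "x3"), transform = FALSE)
  expect_equal(m$selected[1], "x1")
  # exhaustive one-variable fits agree that x1 is best
  r2s <- vapply(c("x1", "x2", "x3"), function(v) {
    summary(stats::lm(stats::reformulate(v, "y"), dat))$r.squared
  }, numeric(1))
  expect_equal(names(which.max(r2s)), "x1")
  expect_gt(m$r2, 0.99)
  # noise covariates should not have entered at alpha = 0.05 (usually just x1;
  # allow at most one false entry from sampling noise)
  expect_lte(length(m$selected), 2)
})

test_that("a pure-noise response selects the empty model", {
  set.seed(5)
  dat <- tibble::tibble(y = stats::rnorm(40), x1 = stats::rnorm(40),
                        x2 = stats::rnorm(40))
  m <- forward_mlr(dat, "y", c("x1", "x2"), entry_alpha = 0.01,
                   transform = FALSE)
  expect_equal(length(m$selected), 0)
  expect_equal(m$r2, 0)
  expect_equal(nrow(tidy(m)), 0)
})

test_that("single-covariate selection reduces to simple regression", {
  set.seed(6)
  dat <- tibble::tibble(y = stats::rnorm(20, 1:20), x = 1:20)
  m <- forward_mlr(dat, "y", "x", transform = FALSE)
  expect_equal(m$r2, summary(stats::lm(y ~ x, dat))$r.squared,
               tolerance = 1e-9)
})

test_that("skewed covariates are log-transformed and recorded", {
  set.seed(7)
  dat <- tibble::tibble(
    skew = exp(stats::rnorm(50, 0, 1.5)),
    sym = stats::rnorm(50)
  )
  out <- transform_covariates(dat, c("skew", "sym"))
  tr <- attr(out, "transforms")
  expect_equal(unname(tr["skew"]), "log10_offset")
  expect_equal(unname(tr["sym"]), "identity")
  expect_equal(out$sym, dat$sym)
})

test_that("a noiseless step yields one split at the straddling midpoint", {
  dat <- tibble::tibble(x = c(0, 0.5, 1, 1.5, 3, 3.5, 2.5, 4, 4.5, 5, 5.5, 6),
                        y = ifelse(c(0, 0.5, 1, 1.5, 3, 3.5, 2.5, 4, 4.5, 5,
                                     5.5, 6) < 2, 0, 100))
  m <- fit_urt(dat, "y", "x", cv_folds = 5, seed = 2)
  expect_equal(nrow(m$splits), 1)
  expect_equal(m$splits$variable, "x")
  expect_equal(m$splits$threshold, 2, tolerance = 1e-9)  # midpoint of 1.5, 2.5
  expect_equal(m$r2, 1)
  expect_equal(sort(m$leaf_means$mean), c(0, 100))
})

test_that("a constant response gives a single leaf", {
  dat <- tibble::tibble(x = 1:12, y = rep(7, 12))
  m <- fit_urt(dat, "y", "x", seed = 1)
  expect_equal(nrow(m$splits), 0)
  expect_equal(m$leaf_means$mean, 7)
  expect_equal(m$r2, 0)
})

test_that("the root split equals the exhaustive brute-force best split", {
  set.seed(19)
  for (i in 1:5) {
    dat <- tibble::tibble(
      x1 = stats::runif(12, 0, 10),
      x2 = stats::runif(12, 0, 10),
      grp = sample(c("u", "v"), 12, replace = TRUE)
    )
    dat$y <- ifelse(dat$x1 > 5, 10, 0) + stats::rnorm(12, 0, 2)
    m <- fit_urt(dat, "y", c("x1", "x2", "grp"), cv_folds = 5, seed = i)
    oracle <- oracle_best_split(dat, "y", c("x1", "x2", "grp"), min_leaf = 3)
    if (nrow(m$splits) > 0) {
      root <- m$splits[m$splits$node == 1, ]
      expect_equal(root$variable, oracle$variable)
      if (!is.na(root$threshold)) {
        expect_equal(root$threshold, oracle$threshold, tolerance = 1e-9)
      }
    }
  }
})

test_that("tree SSE decreases monotonically with size before pruning", {
  yr <- simulate_year(simulation_config(seed = 23), n_dates = 12)
  m <- fit_urt(yr, "ao_rate", c("nh4", "o2", "temp", "light_fraction"),
               seed = 23)
  expect_true(all(diff(m$cv$rel_error) <= 1e-12))
  # chosen size minimises the cross-validated error
  chosen <- m$cv$n_splits[which.min(m$cv$cv_error)]
  expect_equal(nrow(m$splits), chosen)
})

test_that("factor covariates split on level subsets", {
  dat <- tibble::tibble(
    season = rep(c("winter", "spring", "summer", "autumn"), each = 5),
    y = rep(c(100, 10, 12, 8), each = 5) + stats::rnorm(20, 0, 1)
  )
  m <- fit_urt(dat, "y", "season", cv_folds = 5, seed = 4)
  root <- m$splits[1, ]
  expect_equal(root$variable, "season")
  expect_true(is.na(root$threshold))
  expect_gt(nchar(root$left_levels), 0)
  # winter is isolated on one side: its leaf mean is near 100
  expect_true(any(abs(m$leaf_means$mean - 100) < 5))
})
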