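test_that("average log-count conversion uses the geometric mean of R + 1", {
  # offsets cancel when all R = 1e6 - 1
  expect_equal(avg_log_count(c(0, 2.5), rep(1e6 - 1, 4)), c(0, 2.5))
  # direct substitution: ybar = 0, geomean(R + 1) = 1e7
  expect_equal(avg_log_count(0, rep(1e7 - 1, 3)), log2(10))
  # geometric, not arithmetic, mean for unequal sizes
  R <- c(2e6, 2e7)
  geo <- avg_log_count(0, R)
  ari <- 0 + log2(mean(R + 1)) - log2(1e6)
  expect_equal(geo, mean(log2(R + 1)) - log2(1e6))
  expect_equal(ari - geo, log2(mean(R + 1)) - mean(log2(R + 1)))
  expect_gt(ari, geo)
})

test_that("fitted log-counts shift by each sample's own library size", {
  mu <- matrix(c(1, 2), 1, 2)
  expect_equal(fitted_log_count(mu, rep(1e6 - 1, 2)), mu)
  l1 <- fitted_log_count(matrix(5), 2e6)
  l2 <- fitted_log_count(matrix(5), 2e5)
  expect_equal(unname(l1 - l2), matrix(log2((2e6 + 1) / (2e5 + 1))))
})

test_that("the trend smoother preserves constants and straight lines", {
  set.seed(31)
  x <- sort(runif(200, 2, 10))
  tr_const <- fit_trend(x, rep(2.25, 200))       # sqrt sd = 1.5
  expect_equal(tr_const$lo(c(3, 5, 9)), rep(1.5, 3), tolerance = 1e-8)

  s_sqrt <- 0.2 + 0.1 * x                         # exactly linear sqrt-sd
  tr_lin <- fit_trend(x, s_sqrt^2)
  mid <- seq(4, 8, by = 0.5)
  expect_equal(tr_lin$lo(mid), 0.2 + 0.1 * mid, tolerance = 0.01)
})

test_that("the trend is robust to a gross outlier and extrapolates flat", {
  set.seed(33)
  x <- sort(runif(500, 2, 12))
  s <- (1.5 - 0.08 * x + rnorm(500, 0, 0.02))^2
  tr0 <- fit_trend(x, s)
  s_out <- s; s_out[250] <- 400                   # one wild gene
  tr1 <- fit_trend(x, s_out)
  grid <- seq(2.5, 11.5, length.out = 50)
  expect_lt(max(abs(tr1$lo(grid) - tr0$lo(grid)) / tr0$lo(grid)), 0.01)
  # constant extrapolation beyond the knot range
  expect_equal(tr0$lo(-100), tr0$lo(min(tr0$knots_x)))
  expect_equal(tr0$lo(100), tr0$lo(max(tr0$knots_x)))
  expect_true(all(tr0$knots_y > 0))
  expect_error(fit_trend(x, rep(0, 500)), "zero")
})

test_that("voom weights equal the inverse fourth power of the trend", {
  sim <- small_sim(seed = 101)
  cm <- filter_by_total(sim$counts, 10)
  X <- two_group_design(3, 3)
  v <- voom(cm, X)
  expect_true(all(is.finite(v$weights)) && all(v$weights > 0))
  # identity w = lo(lambda-hat)^-4, and reconstructing lo from the knots
  # reproduces the weights bit-for-bit
  w2 <- v$trend$lo(v$fitted_logcount)^-4
  expect_true(all(w2 == v$weights))
  lo2 <- approxfun(v$trend$knots_x, v$trend$knots_y, rule = 2)
  expect_equal(lo2(v$fitted_logcount)^-4, unname(v$weights) * 1,
               ignore_attr = TRUE)
})

test_that("equal library sizes collapse voom weights to gene level", {
  sim <- small_sim(seed = 103, scenario = "null")
  cm <- filter_by_total(sim$counts, 10)
  X <- matrix(1, 6, 1)   # intercept-only: constant fitted value per gene
  v <- voom(cm, X)
  per_gene_range <- apply(v$weights, 1, function(w) diff(range(w)))
  expect_equal(max(per_gene_range), 0)
})

test_that("scaling all library sizes shifts fitted log-counts by a constant", {
  sim <- small_sim(seed = 107)
  cm <- filter_by_total(sim$counts, 10)
  X <- two_group_design(3, 3)
  f <- fit_genewise(to_log_cpm(cm), X)
  l1 <- fitted_log_count(f$fitted, cm$lib_sizes)
  l2 <- fitted_log_count(f$fitted, 4 * cm$lib_sizes + 3)
  expect_equal(l2 - l1, matrix(2, nrow(l1), ncol(l1)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("voom trend decreases then flattens on simulated null counts", {
  cfg <- nb_scenario("null", "equal", seed = 109, n_genes = 3000)
  sim <- simulate_nb_counts(cfg)
  cm <- filter_by_total(sim$counts, 10)
  v <- voom(cm, two_group_design(3, 3))
  # technical regime: predicted sd drops from low to mid counts;
  # biological regime: flat-ish for large counts
  lo <- v$trend$lo
  expect_gt(lo(1), lo(6))
  expect_gt(lo(4), lo(9))
  expect_lt(abs(lo(11) - lo(13)), 0.15 * lo(11))
})

test_that("trended prior recovers constant and log-linear variance shapes", {
  set.seed(41)
  a <- runif(300, 0, 10)
  pt_const <- prior_trend(rep(2, 300), a, df = 4)
  expect_equal(pt_const, rep(4, 300), tolerance = 1e-6)

  v_lin <- exp(1 - 0.2 * a)
  pt_lin <- prior_trend(sqrt(v_lin), a, df = 4)
  expect_equal(pt_lin, v_lin, tolerance = 0.02)
})

test_that("trended prior tracks a lowess of the log variances", {
  sim <- small_sim(seed = 113, n_genes = 1500, scenario = "null")
  cm <- filter_by_total(sim$counts, 10)
  f <- fit_genewise(to_log_cpm(cm), two_group_design(3, 3))
  ptv <- prior_trend(f$sigma, f$avg_logcpm, df = f$df_resid)
  lw <- lowess(f$avg_logcpm, log(f$sigma^2), f = 0.5)
  lofun <- approxfun(lw$x, lw$y, rule = 2, ties = mean)
  inner <- f$avg_logcpm > quantile(f$avg_logcpm, 0.1) &
           f$avg_logcpm < quantile(f$avg_logcpm, 0.9)
  expect_lt(median(abs(log(ptv[inner]) - lofun(f$avg_logcpm[inner]))), 0.25)
})
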