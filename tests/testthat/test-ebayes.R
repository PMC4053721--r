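test_that("prior estimation: zero excess variability gives infinite d0", {
  pr <- estimate_prior(rep(1.3, 50), df = 4)
  expect_equal(pr$d0, Inf)
  expect_equal(pr$s0sq, 1.3^2)

  # wildly different variances -> finite, small d0
  pr2 <- estimate_prior(c(0.01, 100), df = 4)
  expect_true(is.finite(pr2$d0))
  expect_lt(pr2$d0, 5)
})

test_that("prior df is recovered from scaled inverse chi-square variances", {
  set.seed(51)
  d0 <- 40; s0 <- 2; G <- 1e5; d <- 4
  sg2 <- s0^2 * d0 / rchisq(G, d0) * rchisq(G, d) / d
  pr <- estimate_prior(sqrt(sg2), df = d)
  expect_equal(pr$d0, d0, tolerance = 0.1)
  expect_equal(pr$s0sq, s0^2, tolerance = 0.05)
})

test_that("prior df recovery holds across d0 = 4, 10, 40", {
  set.seed(53)
  for (d0 in c(4, 10, 40)) {
    G <- 2e4; d <- 6
    sg2 <- 1.5 * d0 / rchisq(G, d0) * rchisq(G, d) / d
    pr <- estimate_prior(sqrt(sg2), df = d)
    expect_equal(pr$d0, d0, tolerance = 0.2)
  }
})

test_that("prior estimation agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(55)
  sg2 <- rchisq(2000, 5) / 5 * exp(rnorm(2000, 0, 0.4))
  a <- runif(2000, 0, 10)
  pr <- estimate_prior(sqrt(sg2), df = 5)
  ref <- limma::fitFDist(sg2, df1 = 5)
  expect_equal(pr$d0, ref$df2, tolerance = 1e-4)
  expect_equal(pr$s0sq, ref$scale, tolerance = 1e-4)

  prt <- estimate_prior(sqrt(sg2), df = 5, covariate = a)
  reft <- limma::fitFDist(sg2, df1 = 5, covariate = a)
  expect_equal(prt$d0, reft$df2, tolerance = 1e-4)
  expect_equal(unname(prt$s0sq), unname(reft$scale), tolerance = 1e-3)
})

test_that("variance squeezing is a convex combination with correct limits", {
  s2 <- c(0.5, 2, 8); d <- 4
  expect_equal(squeeze_var(s2, d, 0, 1), s2)                 # d0 = 0
  expect_equal(squeeze_var(s2, d, Inf, 1), rep(1, 3))        # d0 = Inf
  expect_equal(squeeze_var(2, 4, 4, 2), 2)                   # fixed point
  st <- squeeze_var(s2, d, 7, 1.5)
  expect_true(all(st >= pmin(s2, 1.5) & st <= pmax(s2, 1.5)))
  expect_equal(st, (7 * 1.5 + 4 * s2) / 11)
})

test_that("moderated t reduces to the ordinary t-test at d0 = 0", {
  set.seed(57)
  y <- matrix(rnorm(60), 10, 6)
  X <- two_group_design(3, 3)
  f <- fit_genewise(y, X)
  eb <- ebayes_moderate(f, prior_df = 0)
  ref_t <- apply(y, 1, function(v) t.test(v[4:6], v[1:3], var.equal = TRUE)$statistic)
  expect_equal(unname(eb$t[, 2]), unname(ref_t), tolerance = 1e-10)
  ref_p <- apply(y, 1, function(v) t.test(v[4:6], v[1:3], var.equal = TRUE)$p.value)
  expect_equal(unname(eb$p[, 2]), unname(ref_p), tolerance = 1e-10)
})

test_that("posterior variances lie between observed and prior variances", {
  set.seed(59)
  sim <- small_sim(seed = 59, scenario = "null")
  cm <- filter_by_total(sim$counts, 10)
  v <- voom(cm, two_group_design(3, 3))
  f <- fit_genewise(v$y, two_group_design(3, 3), weights = v$weights)
  eb <- ebayes_moderate(f)
  expect_true(all(eb$post_var >= pmin(f$sigma^2, eb$s0sq) - 1e-12))
  expect_true(all(eb$post_var <= pmax(f$sigma^2, eb$s0sq) + 1e-12))
  expect_true(all(eb$p >= 0 & eb$p <= 1))
})

test_that("null p-values are near-uniform and conservative at 0.01", {
  set.seed(61)
  sim <- simulate_nb_counts(nb_scenario("null", "equal", seed = 61,
                                        n_genes = 4000))
  cm <- filter_by_total(sim$counts, 10)
  fit <- voom_lm(cm, two_group_design(3, 3), method = "voom")
  p <- fit$eb$p[, 2]
  G <- length(p)
  mcse <- sqrt(0.01 * 0.99 / G)
  expect_lte(mean(p < 0.01), 0.01 + 3 * mcse)
  # gross uniformity of the body of the distribution
  expect_lt(abs(mean(p < 0.5) - 0.5), 0.08)
})

test_that("moderated F reduces to t^2 for one coefficient and matches a dense oracle", {
  set.seed(63)
  X <- cbind(1, rep(0:1, each = 3), rnorm(6))
  y <- matrix(rnorm(48), 8, 6)
  f <- fit_genewise(y, X)
  eb <- ebayes_moderate(f)
  f1 <- moderated_F(f, eb, coefs = 2)
  expect_equal(f1$F, unname(eb$t[, 2]^2), tolerance = 1e-10)
  expect_equal(f1$p, unname(eb$p[, 2]), tolerance = 1e-10)

  # two coefficients: brute-force quadratic form in the de-correlated t's
  f2 <- moderated_F(f, eb, coefs = 2:3)
  for (g in 1:8) {
    V <- f$cov_unscaled[2:3, 2:3, g]
    corr <- V / tcrossprod(sqrt(diag(V)))
    tg <- eb$t[g, 2:3]
    expect_equal(f2$F[g], drop(t(tg) %*% solve(corr) %*% tg) / 2,
                 tolerance = 1e-8)
  }
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.4), 0.4)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # step-up on a worked example: p = (.005, .04, .04, .8)
  expect_equal(bh_fdr(c(0.005, 0.04, 0.04, 0.8)),
               c(0.02, 160 / 3000, 160 / 3000, 0.8))
})

test_that("top tables carry the standard columns and rank by evidence", {
  set.seed(67)
  y <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("gene", 1:10), NULL))
  y[3, 4:6] <- y[3, 4:6] + 10           # one overwhelming gene
  X <- two_group_design(3, 3)
  f <- fit_genewise(y, X)
  eb <- ebayes_moderate(f)
  tt <- top_table(f, eb, coef = 2)
  expect_equal(names(tt), c("gene", "logFC", "AveExpr", "t", "P.Value", "FDR", "B"))
  expect_equal(tt$gene[1], "gene3")
  # constant df: ordering by p equals ordering by |t|
  expect_equal(order(tt$P.Value), order(-abs(tt$t)))
})

test_that("full moderated pipeline agrees with limma on shared input", {
  skip_if_not_installed("limma")
  set.seed(69)
  y <- matrix(rnorm(1200, sd = rep(runif(200, 0.5, 2), 6)), 200, 6)
  X <- two_group_design(3, 3)
  f <- fit_genewise(y, X)
  eb <- ebayes_moderate(f)
  lf <- limma::eBayes(limma::lmFit(y, X))
  expect_equal(eb$d0, lf$df.prior, tolerance = 1e-4)
  expect_equal(unname(eb$t[, 2]), unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(eb$p[, 2]), unname(lf$p.value[, 2]), tolerance = 1e-6)
  expect_equal(unname(eb$lods[, 2]), unname(lf$lods[, 2]), tolerance = 1e-4)
  expect_equal(unname(eb$F), unname(lf$F), tolerance = 1e-6)
})

test_that("z-score transform of t-statistics preserves sign and tail mass", {
  t <- c(-8, -1, 0, 1, 8, 30)
  z <- zscore_t(t, df = 10)
  expect_equal(sign(z), sign(t))
  expect_equal(pnorm(z), pt(t, 10), tolerance = 1e-10)
  expect_true(all(is.finite(zscore_t(c(-50, 50), 5))))
})
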