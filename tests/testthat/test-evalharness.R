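test_that("type I error counts use a strict inequality", {
  expect_equal(type1_error(c(0.005, 0.5, 0.9), 0.01), 1 / 3)
  expect_equal(type1_error(0.01, 0.01), 0)        # boundary excluded
  m <- 1000
  p <- (seq_len(m) - 0.5) / m
  expect_equal(type1_error(p, 0.05), 0.05)
  expect_error(type1_error(numeric(0), 0.01), "empty")
  # monotone in the cutoff
  cuts <- c(0.01, 0.05, 0.2, 0.9)
  vals <- vapply(cuts, function(ct) type1_error(p, ct), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("power and empirical FDR split calls by truth", {
  is_de <- c(rep(TRUE, 5), rep(FALSE, 10))
  p <- c(rep(1e-8, 5), rep(0.9, 10))
  r <- power_fdr(p, is_de, 0.1)
  expect_equal(r$TP, 5); expect_equal(r$FP, 0)
  expect_equal(r$empirical_fdr, 0)

  r_none <- power_fdr(rep(0.9, 15), is_de, 0.1)
  expect_equal(c(r_none$TP, r_none$FP, r_none$empirical_fdr), c(0, 0, 0))

  # hand-computed step-up on a 10-gene toy
  p10 <- c(0.001, 0.002, 0.003, 0.004, 0.2, 0.3, 0.5, 0.7, 0.9, 1)
  de10 <- c(TRUE, TRUE, TRUE, FALSE, rep(FALSE, 6))
  # q = (0.01, 0.01, 0.01, 0.01, 0.4, 0.5, 5*0.5/... ) -> first 4 called
  r10 <- power_fdr(p10, de10, 0.1)
  expect_equal(r10$TP, 3); expect_equal(r10$FP, 1)
  expect_equal(r10$empirical_fdr, 0.25)
  # cutoff 1 calls everything
  expect_equal(power_fdr(p10, de10, 1.0000001)$n_called, 10)
  expect_error(power_fdr(p10, de10[1:5]), "length")
})

test_that("false discovery curves behave for perfect, reversed and random rankings", {
  is_de <- c(rep(TRUE, 200), rep(FALSE, 800))
  perfect <- c(seq(0, 0.1, length.out = 200), seq(0.5, 1, length.out = 800))
  fdc <- fd_curve(perfect, is_de, 300)
  expect_equal(fdc[1:200], rep(0, 200))
  expect_equal(fdc[300], 100)
  expect_true(all(diff(fdc) >= 0))

  fdc_r <- fd_curve(1 - perfect, is_de, 1000)   # reversed ranking
  expect_equal(fdc_r[800], 800)       # all nulls come first
  expect_equal(fdc_r[1000], 800)

  set.seed(103)
  rnd <- rowMeans(replicate(200, fd_curve(runif(1000), is_de, 500)))
  # random ranking: expected false discoveries at k ~ k * (1 - prevalence)
  expect_equal(rnd[500], 500 * 0.8, tolerance = 0.03)
})

test_that("benchmark runner is deterministic and validates method names", {
  cfg <- nb_scenario("power", "equal", seed = 1, n_genes = 400,
                     n_de_per_group = 10)
  r1 <- run_benchmark(cfg, methods = "voom", n_sims = 2, seed = 5,
                      max_selected = 50)
  r2 <- run_benchmark(cfg, methods = "voom", n_sims = 2, seed = 5,
                      max_selected = 50)
  expect_identical(r1$voom$per_sim, r2$voom$per_sim)
  expect_identical(r1$voom$fd_curve, r2$voom$fd_curve)
  expect_error(run_benchmark(cfg, methods = "deseq"), "unknown method")
})

test_that("ordinary t-test is an exact special case of the engine", {
  sim <- small_sim(seed = 105)
  cm <- filter_by_total(sim$counts, 10)
  X <- two_group_design(3, 3)
  fit_ord <- voom_lm(cm, X, method = "ordinary_t")
  expect_equal(fit_ord$eb$d0, 0)
  y <- to_log_cpm(cm)$y
  ref_p <- apply(y, 1, function(v) t.test(v[4:6], v[1:3], var.equal = TRUE)$p.value)
  expect_equal(unname(fit_ord$eb$p[, 2]), unname(ref_p), tolerance = 1e-10)
})

test_that("voom_lm methods expose the fit in the usual S3 idiom", {
  sim <- small_sim(seed = 111)
  cm <- filter_by_total(sim$counts, 10)
  X <- two_group_design(3, 3)
  vfit <- voom_lm(cm, X, method = "voom")
  expect_s3_class(vfit, "voom_lm")
  expect_equal(dim(coef(vfit)), c(nrow(cm$counts), 2L))
  expect_equal(dim(fitted(vfit)), dim(cm$counts))
  r <- residuals(vfit)
  expect_equal(r + fitted(vfit), vfit$fit$y)
  expect_equal(predict(vfit), fitted(vfit), ignore_attr = TRUE)
  expect_equal(unname(predict(vfit, matrix(c(1, 1), 1, 2))[, 1]),
               unname(rowSums(coef(vfit))))
  s <- summary(vfit)
  expect_s3_class(s, "summary.voom_lm")
  expect_output(print(vfit), "voom_lm fit")
  expect_output(print(s), "prior df")
  expect_silent(grDevices::pdf(NULL))
  expect_invisible(plot(vfit))
  grDevices::dev.off()
})

test_that("voom pipeline matches the limma voom reference end to end", {
  skip_if_not_installed("limma")
  skip_if_not_installed("edgeR")
  sim <- simulate_nb_counts(nb_scenario("power", "unequal", seed = 117,
                                        n_genes = 2000))
  cm <- filter_by_total(sim$counts, 10)
  X <- two_group_design(3, 3)
  mine <- voom_lm(cm, X, method = "voom")
  dge <- edgeR::DGEList(counts = cm$counts, lib.size = cm$lib_sizes)
  v <- limma::voom(dge, X)
  lf <- limma::eBayes(limma::lmFit(v, X))
  expect_gt(cor(mine$eb$t[, 2], lf$t[, 2]), 0.9999)
  # small differences expected: the trend here uses one extra robustifying
  # iteration relative to the reference smoother
  expect_lt(max(abs(coef(mine)[, 2] - lf$coefficients[, 2])), 0.01)
  expect_equal(mine$eb$d0, lf$df.prior, tolerance = 0.02)
})
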