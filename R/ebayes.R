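#' Invert the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by Newton iteration on a
#' transformed scale. Used to recover the prior degrees of freedom from the
#' excess variability of log sample variances.
#'
#' @param x positive values.
#' @return y with `trigamma(y) = x`.
#' @keywords internal
trigamma_inverse <- function(x) {
  out <- x
  big <- x > 1e7          # trigamma(y) ~ 1/y for small y... here y large: ~1/y
  out[big] <- 1 / sqrt(x[big])
  small <- x < 1e-6       # trigamma(y) ~ 1/y for large y
  out[small] <- 1 / x[small]
  mid <- !big & !small
  if (any(mid)) {
    y <- 0.5 + 1 / x[mid]
    for (iter in 1:50) {
      tri <- trigamma(y)
      step <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2)
      y <- y + step
      if (max(-step / y) < 1e-8) break
    }
    out[mid] <- y
  }
  out
}

#' Estimate the variance prior by moment matching on log variances
#'
#' Models the gene-wise residual variances as draws from a scaled inverse
#' chi-square prior with `d0` degrees of freedom and scale `s0sq`. Writing
#' `z_g = log(s_g^2)`, the marginal mean and variance of `z_g` involve
#' digamma/trigamma functions of `d_g/2` and `d0/2`; `d0` is recovered by
#' inverting the trigamma equation on the excess variability of the `z_g`
#' beyond their expected sampling variability, and `s0sq` from the mean
#' equation. When a covariate (average log2-cpm) is supplied, the prior
#' scale becomes a gene-wise trend: a natural cubic spline of `z` on the
#' covariate replaces the constant mean (the limma-trend prior).
#'
#' @param sigma gene-wise residual standard deviations.
#' @param df residual degrees of freedom (scalar recycled, or per gene).
#' @param covariate optional per-gene covariate (average log2-cpm) for a
#'   trended prior.
#' @param spline_df spline degrees of freedom for the trend.
#' @return list with `d0` (prior df, possibly `Inf`) and `s0sq` (scalar, or
#'   per-gene vector when a covariate is given).
#' @export
estimate_prior <- function(sigma, df, covariate = NULL, spline_df = 4) {
  G <- length(sigma)
  df <- rep_len(as.numeric(df), G)
  ok <- df > 0 & is.finite(sigma)
  if (sum(ok) < 2) stop("need at least 2 genes with positive residual df")
  s2 <- sigma[ok]^2
  m <- stats::median(s2)
  if (m == 0) stop("more than half of the residual variances are zero")
  s2 <- pmax(s2, 1e-5 * m)
  dfo <- df[ok]
  z <- log(s2)
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  if (is.null(covariate)) {
    emean <- mean(e)
    evar <- stats::var(e)
  } else {
    if (length(covariate) != G) stop("covariate must have one value per gene")
    B <- splines::ns(covariate[ok], df = min(spline_df, sum(ok) - 2),
                     intercept = TRUE)
    lf <- stats::lm.fit(B, e)
    emean_ok <- lf$fitted.values
    evar <- sum(lf$residuals^2) / (length(e) - lf$rank)
    emean <- rep(NA_real_, G)
    emean[ok] <- emean_ok
    if (any(!ok)) {
      ap <- stats::approxfun(covariate[ok], emean_ok, rule = 2, ties = mean)
      emean[!ok] <- ap(covariate[!ok])
    }
  }
  evar <- evar - mean(trigamma(dfo / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- if (is.null(covariate)) mean(s2) else exp(emean)
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Squeeze gene-wise variances towards the prior
#'
#' Posterior variance `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`, a convex
#' combination of the observed and prior variances. `d0 = 0` returns the
#' observed variances unchanged; `d0 = Inf` returns the prior.
#'
#' @param sigma2 observed gene-wise variances.
#' @param df residual degrees of freedom (recycled).
#' @param d0 prior degrees of freedom (0 to `Inf`).
#' @param s0sq prior variance (scalar or per gene).
#' @return vector of posterior variances.
#' @export
squeeze_var <- function(sigma2, df, d0, s0sq) {
  if (d0 < 0) stop("d0 must be non-negative")
  G <- length(sigma2)
  df <- rep_len(as.numeric(df), G)
  s0sq <- rep_len(as.numeric(s0sq), G)
  if (is.infinite(d0)) return(s0sq)
  if (d0 == 0) return(as.numeric(sigma2))
  (d0 * s0sq + df * sigma2) / (d0 + df)
}

#' Empirical Bayes moderated inference for a gene-wise fit
#'
#' Shrinks the gene-wise residual variances towards a constant prior
#' (`trend = FALSE`) or towards a mean-variance trend in average log2-cpm
#' (`trend = TRUE`, the limma-trend prior), then forms moderated
#' t-statistics `t_g = beta_g / (s_tilde_g u_g)` on `d0 + d_g` degrees of
#' freedom, two-sided p-values, Benjamini-Hochberg adjusted q-values, a
#' moderated F across all coefficients, and the log posterior odds of
#' differential expression (B).
#'
#' Setting `prior_df = 0` disables moderation entirely, giving the
#' ordinary gene-wise t-test as an exact special case of the engine.
#'
#' @param fit a [fit_genewise()] (or [apply_contrasts()]) result.
#' @param trend logical; use a trended prior variance.
#' @param prior_df optional override of the estimated prior df `d0`
#'   (`0` = no squeezing, `Inf` = full squeezing).
#' @param proportion assumed prior proportion of differentially expressed
#'   genes, used by the B-statistic.
#' @param stdev_coef_lim limits for the prior standard deviation of
#'   coefficients (log2-fold-change scale) inside the B computation.
#' @param spline_df spline df for the trended prior.
#' @return An object of class `"ebfit"`: list with `d0`, `s0sq`,
#'   `post_var`, `df_total`, `t`, `p`, `fdr`, `lods` (all G x k), and `F`,
#'   `F_p` (per gene) when k > 1.
#' @export
ebayes_moderate <- function(fit, trend = FALSE, prior_df = NULL,
                            proportion = 0.01, stdev_coef_lim = c(0.1, 4),
                            spline_df = 4) {
  stopifnot(inherits(fit, "genefit"))
  sigma2 <- fit$sigma^2
  dfres <- fit$df_resid
  if (!is.null(prior_df) && prior_df == 0) {
    d0 <- 0
    s0sq <- NA_real_
    post_var <- sigma2
  } else {
    covariate <- if (trend) fit$avg_logcpm else NULL
    pr <- estimate_prior(fit$sigma, dfres, covariate = covariate,
                         spline_df = spline_df)
    d0 <- if (is.null(prior_df)) pr$d0 else prior_df
    s0sq <- pr$s0sq
    post_var <- squeeze_var(sigma2, dfres, d0, s0sq)
  }
  df_total <- pmin(dfres + d0, sum(dfres))
  tt <- fit$coefficients / fit$stdev_unscaled / sqrt(post_var)
  pp <- 2 * stats::pt(-abs(tt), df = df_total)
  qq <- apply(pp, 2, bh_fdr)
  dim(qq) <- dim(pp); dimnames(qq) <- dimnames(pp)
  lods <- .lods_stat(tt, fit$stdev_unscaled, df_total, proportion,
                     stdev_coef_lim, post_var)
  out <- list(d0 = d0, s0sq = s0sq, post_var = post_var,
              df_total = df_total, t = tt, p = pp, fdr = qq, lods = lods,
              proportion = proportion, trend = trend)
  if (ncol(tt) > 1) {
    Fres <- moderated_F_stat(fit, tt, df_total)
    out$F <- Fres$F
    out$F_p <- Fres$p
  }
  class(out) <- "ebfit"
  out
}

#' @export
print.ebfit <- function(x, ...) {
  cat(sprintf("ebfit: %d genes, %d coefficient(s)\n", nrow(x$t), ncol(x$t)))
  cat(sprintf("  prior df d0 = %s; prior variance s0^2 %s\n",
              format(x$d0, digits = 4),
              if (length(x$s0sq) > 1) "trended (per gene)"
              else paste("=", format(x$s0sq, digits = 4))))
  invisible(x)
}

# B-statistic: log posterior odds of differential expression, with the
# prior variance of true coefficients estimated from the tails of the
# moderated t-statistics (normal-mixture moment matching).
.lods_stat <- function(tt, stdev_unscaled, df_total, proportion,
                       stdev_coef_lim, post_var) {
  G <- nrow(tt)
  v0_lim <- stdev_coef_lim^2 / stats::median(post_var)
  lods <- tt
  for (j in seq_len(ncol(tt))) {
    v0 <- .tmixture(tt[, j], stdev_unscaled[, j], df_total, proportion, v0_lim)
    r <- (stdev_unscaled[, j]^2 + v0) / stdev_unscaled[, j]^2
    t2 <- tt[, j]^2
    kernel <- ifelse(df_total > 1e6,
                     t2 * (1 - 1 / r) / 2,
                     (1 + df_total) / 2 *
                       log((t2 + df_total) / (t2 / r + df_total)))
    lods[, j] <- log(proportion / (1 - proportion)) - log(r) / 2 + kernel
  }
  lods
}

# Estimate the unscaled prior variance v0 of true coefficients from the
# top fraction of |t|-statistics, equating observed tail quantiles with
# those implied by a two-component mixture.
.tmixture <- function(tstat, stdev_unscaled, df, proportion, v0_lim) {
  ngenes <- length(tstat)
  ntarget <- ceiling(proportion / 2 * ngenes)
  if (ntarget < 1) return(0)
  p <- max(ntarget / ngenes, proportion)
  atst <- abs(tstat)
  maxdf <- max(df)
  low <- df < maxdf
  if (any(low)) {
    tailp <- stats::pt(atst[low], df = df[low], lower.tail = FALSE, log.p = TRUE)
    atst[low] <- stats::qt(tailp, df = maxdf, lower.tail = FALSE, log.p = TRUE)
  }
  o <- order(atst, decreasing = TRUE)[seq_len(ntarget)]
  tt <- atst[o]
  v1 <- stdev_unscaled[o]^2
  p0 <- 2 * stats::pt(tt, df = maxdf, lower.tail = FALSE)
  ptarget <- ((seq_len(ntarget) - 0.5) / ngenes - (1 - p) * p0) / p
  v0 <- rep(0, ntarget)
  pos <- ptarget > p0
  if (any(pos)) {
    qtarget <- stats::qt(ptarget[pos] / 2, df = maxdf, lower.tail = FALSE)
    v0[pos] <- v1[pos] * ((tt[pos] / qtarget)^2 - 1)
  }
  mean(pmin(pmax(v0, v0_lim[1]), v0_lim[2]))
}

#' Moderated t-statistic and p-value for one coefficient
#'
#' @param fit a [fit_genewise()] result.
#' @param eb the matching [ebayes_moderate()] result.
#' @param coef coefficient name or index.
#' @return data frame with columns `t`, `p`, `df_total`.
#' @export
moderated_t <- function(fit, eb, coef = ncol(fit$coefficients)) {
  stopifnot(inherits(fit, "genefit"), inherits(eb, "ebfit"))
  data.frame(t = eb$t[, coef], p = eb$p[, coef], df_total = eb$df_total,
             row.names = rownames(fit$coefficients))
}

# Moderated F over all coefficients of tt: mean squared de-correlated t.
moderated_F_stat <- function(fit, tt, df_total) {
  G <- nrow(tt); k <- ncol(tt)
  Fs <- numeric(G)
  for (g in seq_len(G)) {
    V <- matrix(fit$cov_unscaled[, , g], k, k)
    corr <- V / tcrossprod(sqrt(diag(V)))
    R <- chol(corr)
    u <- backsolve(R, tt[g, ], transpose = TRUE)
    Fs[g] <- sum(u^2) / k
  }
  list(F = Fs, p = stats::pf(Fs, k, df_total, lower.tail = FALSE))
}

#' Moderated F-test over a set of coefficients
#'
#' Tests the joint null that the selected coefficients are all zero, using
#' the mean of squared de-correlated moderated t-statistics, referred to an
#' F distribution on (k, d0 + d_g) degrees of freedom.
#'
#' @param fit a [fit_genewise()] result.
#' @param eb the matching [ebayes_moderate()] result.
#' @param coefs coefficient names or indices (default: all).
#' @return data frame with columns `F`, `p`.
#' @export
moderated_F <- function(fit, eb, coefs = seq_len(ncol(fit$coefficients))) {
  stopifnot(inherits(fit, "genefit"), inherits(eb, "ebfit"))
  if (length(coefs) < 1) stop("need at least one coefficient")
  sub <- fit
  sub$coefficients <- fit$coefficients[, coefs, drop = FALSE]
  sub$cov_unscaled <- fit$cov_unscaled[coefs, coefs, , drop = FALSE]
  res <- moderated_F_stat(sub, eb$t[, coefs, drop = FALSE], eb$df_total)
  data.frame(F = res$F, p = res$p, row.names = rownames(fit$coefficients))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j >= i) m p_(j) / j`, capped at 1.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Ranked table of differential expression results
#'
#' One row per gene with the standard output columns: log2 fold change,
#' average log2-cpm, moderated t, p-value, BH-adjusted FDR and log-odds B.
#'
#' @param fit a [fit_genewise()] result.
#' @param eb the matching [ebayes_moderate()] result.
#' @param coef coefficient name or index to report.
#' @param sort_by `"p"`, `"B"`, `"logFC"` or `"none"`.
#' @param n number of rows to return (default all).
#' @return data frame with columns `gene`, `logFC`, `AveExpr`, `t`,
#'   `P.Value`, `FDR`, `B`.
#' @export
top_table <- function(fit, eb, coef = ncol(fit$coefficients),
                      sort_by = c("p", "B", "logFC", "none"), n = Inf) {
  stopifnot(inherits(fit, "genefit"), inherits(eb, "ebfit"))
  sort_by <- match.arg(sort_by)
  d <- data.frame(
    gene = rownames(fit$coefficients) %||% seq_len(nrow(fit$coefficients)),
    logFC = fit$coefficients[, coef],
    AveExpr = fit$avg_logcpm,
    t = eb$t[, coef],
    P.Value = eb$p[, coef],
    FDR = eb$fdr[, coef],
    B = eb$lods[, coef],
    row.names = NULL
  )
  ord <- switch(sort_by,
                p = order(d$P.Value),
                B = order(d$B, decreasing = TRUE),
                logFC = order(abs(d$logFC), decreasing = TRUE),
                none = seq_len(nrow(d)))
  utils::head(d[ord, , drop = FALSE], n)
}

#' Convert t-statistics to equivalent standard normal deviates
#'
#' Maps each t through its own cumulative distribution and back through the
#' normal quantile function, using log-scale tail probabilities for
#' numerical stability far out in the tails.
#'
#' @param t t-statistics.
#' @param df degrees of freedom (recycled).
#' @return z-scores with the same signs.
#' @export
zscore_t <- function(t, df) {
  df <- rep_len(df, length(t))
  z <- numeric(length(t))
  neg <- t <= 0
  z[neg] <- stats::qnorm(stats::pt(t[neg], df[neg], log.p = TRUE), log.p = TRUE)
  z[!neg] <- -stats::qnorm(stats::pt(-t[!neg], df[!neg], log.p = TRUE), log.p = TRUE)
  z
}
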