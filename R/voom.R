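#' Average log2-count of each gene
#'
#' Converts average log2-cpm values to the average log2-count scale on
#' which the mean-variance trend is estimated:
#' `r_tilde_g = ybar_g + log2(geomean(R_i + 1)) - log2(1e6)`.
#' The geometric mean of the (offset) library sizes is used so that the
#' conversion is an additive shift on the log scale.
#'
#' @param avg_logcpm numeric vector of average log2-cpm values (`ybar_g`).
#' @param lib_sizes positive library sizes `R_i`.
#' @return numeric vector of average log2-counts.
#' @export
avg_log_count <- function(avg_logcpm, lib_sizes) {
  if (any(lib_sizes <= 0)) stop("lib_sizes must be positive")
  avg_logcpm + mean(log2(lib_sizes + 1)) - log2(1e6)
}

#' Fitted log2-counts for every observation
#'
#' Converts fitted log2-cpm values to fitted log2-counts using each
#' sample's own library size:
#' `lambda_hat_gi = mu_hat_gi + log2(R_i + 1) - log2(1e6)`.
#' With unequal library sizes, observations of the same gene land at
#' different positions on the mean-variance trend — the reason precision
#' weights are assigned per observation rather than per gene.
#'
#' @param fitted_logcpm G x n matrix of fitted log2-cpm values.
#' @param lib_sizes positive library sizes, length n.
#' @return G x n matrix of fitted log2-counts.
#' @export
fitted_log_count <- function(fitted_logcpm, lib_sizes) {
  if (any(lib_sizes <= 0)) stop("lib_sizes must be positive")
  fitted_logcpm <- as.matrix(fitted_logcpm)
  if (ncol(fitted_logcpm) != length(lib_sizes))
    stop("fitted_logcpm columns must match lib_sizes length")
  t(t(fitted_logcpm) + log2(lib_sizes + 1) - log2(1e6))
}

#' Robust mean-variance trend of square-root standard deviations
#'
#' Fits a robust LOWESS curve to gene-wise square-root residual standard
#' deviations (`sqrt(s_g)`, which are roughly symmetrically distributed)
#' as a function of average log2-count, then interpolates it into a
#' continuous piecewise-linear function `lo()`. Beyond the range of the
#' observed average log-counts the function extrapolates as a constant, and
#' its values are floored at 1% of the smallest positive knot so that
#' predicted standard deviations stay strictly positive.
#'
#' @param avg_logcount numeric vector of average log2-counts (one per gene).
#' @param sigma numeric vector of residual standard deviations.
#' @param span LOWESS span (fraction of points in each local window).
#' @param iterations number of robustifying (bisquare) iterations.
#' @return An object of class `"meanvar_trend"`: list with `knots_x`,
#'   `knots_y` (sorted knot coordinates on the sqrt-sd scale) and `lo`,
#'   the interpolating function.
#' @export
fit_trend <- function(avg_logcount, sigma, span = 0.5, iterations = 4) {
  ok <- is.finite(avg_logcount) & is.finite(sigma)
  x <- avg_logcount[ok]
  s <- sigma[ok]
  if (length(x) < 10) stop("need at least 10 genes to estimate the trend")
  if (all(s == 0)) stop("all residual standard deviations are zero; degenerate data")
  l <- stats::lowess(x, sqrt(s), f = span, iter = iterations)
  # lowess returns sorted unique-ish x; collapse duplicate knots by averaging
  kx <- l$x; ky <- l$y
  if (anyDuplicated(kx)) {
    grp <- cumsum(c(TRUE, diff(kx) > 0))
    ky <- as.numeric(rowsum(ky, grp) / tabulate(grp))
    kx <- kx[!duplicated(kx)]
  }
  floor_val <- 0.01 * min(ky[ky > 0])
  ky <- pmax(ky, floor_val)
  lo <- stats::approxfun(kx, ky, rule = 2)
  structure(list(knots_x = kx, knots_y = ky, lo = lo),
            class = "meanvar_trend")
}

#' @export
print.meanvar_trend <- function(x, ...) {
  cat(sprintf("meanvar_trend: %d knots, log2-count range [%.2f, %.2f], sqrt-sd range [%.3f, %.3f]\n",
              length(x$knots_x), min(x$knots_x), max(x$knots_x),
              min(x$knots_y), max(x$knots_y)))
  invisible(x)
}

#' @export
plot.meanvar_trend <- function(x, ...) {
  graphics::plot(x$knots_x, x$knots_y, type = "l", lwd = 2, col = "red",
                 xlab = expression(log[2]~count), ylab = expression(sqrt(sigma)),
                 main = "Mean-variance trend", ...)
  invisible(x)
}

#' voom: observation-level precision weights from the mean-variance trend
#'
#' Transforms counts to log2-cpm, fits unweighted gene-wise linear models,
#' estimates a robust LOWESS trend of square-root residual standard
#' deviation against average log2-count, evaluates the trend at each
#' observation's fitted log2-count, and returns the inverse fourth power
#' `w_gi = lo(lambda_hat_gi)^-4` as the observation's precision weight
#' (the trend is on the square-root-sd scale, so the fourth power gives an
#' inverse variance). The log2-cpm values and weights are ready for a
#' weighted [fit_genewise()] followed by [ebayes_moderate()].
#'
#' @param cm a [count_matrix()], typically filtered and (optionally)
#'   TMM-normalized.
#' @param X design matrix (samples x coefficients).
#' @param span LOWESS span for the trend.
#' @param iterations robustifying iterations for the trend.
#' @param use_effective_sizes use `lib_sizes * norm_factors` in the cpm
#'   transform and the count conversions.
#' @param quantile normalize the log2-cpm matrix between samples with
#'   [quantile_normalize()] before fitting.
#' @return An object of class `"voom"`: list with `y` (a `"logcpm"`),
#'   `weights` (G x n), `trend` (a `"meanvar_trend"`), `fitted_logcount`
#'   (G x n) and `first_fit` (the unweighted `"genefit"`).
#' @export
voom <- function(cm, X, span = 0.5, iterations = 4,
                 use_effective_sizes = FALSE, quantile = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  lc <- to_log_cpm(cm, use_effective_sizes = use_effective_sizes)
  if (quantile) lc$y <- quantile_normalize(lc$y)
  fit <- fit_genewise(lc, X)
  R <- lc$lib_sizes_used
  rtilde <- avg_log_count(fit$avg_logcpm, R)
  use <- fit$df_resid > 0
  trend <- fit_trend(rtilde[use], fit$sigma[use], span = span,
                     iterations = iterations)
  lam <- fitted_log_count(fit$fitted, R)
  w <- trend$lo(lam)^-4
  dim(w) <- dim(lam)
  dimnames(w) <- dimnames(lc$y)
  structure(list(y = lc, weights = w, trend = trend,
                 fitted_logcount = lam, first_fit = fit),
            class = "voom")
}

#' @export
print.voom <- function(x, ...) {
  cat(sprintf("voom: %d genes x %d samples; weight range [%.3g, %.3g]\n",
              nrow(x$weights), ncol(x$weights),
              min(x$weights), max(x$weights)))
  print(x$trend)
  invisible(x)
}

#' Trended prior variance for gene-level moderation (limma-trend style)
#'
#' Fits a natural cubic regression spline of the log residual variances against average log2-cpm and returns the exponentiated fitted
#' curve as a per-gene prior variance. Used as the squeezing target when a
#' gene-level mean-variance trend is modelled instead of observation
#' weights.
#'
#' @param sigma gene-wise residual standard deviations.
#' @param avg_logcpm gene-wise average log2-cpm.
#' @param df residual degrees of freedom per gene (scalar recycled).
#' @param spline_df degrees of freedom of the spline.
#' @return numeric vector of per-gene trended prior variances.
#' @export
prior_trend <- function(sigma, avg_logcpm, df, spline_df = 4) {
  G <- length(sigma)
  if (G < spline_df + 2) stop("too few genes for a ", spline_df, "-df spline")
  df <- rep_len(df, G)
  ok <- df > 0 & is.finite(sigma)
  z <- log(pmax(sigma[ok]^2, 1e-300))
  B <- splines::ns(avg_logcpm[ok], df = spline_df, intercept = TRUE)
  fitz <- stats::lm.fit(B, z)$fitted.values
  out <- rep(NA_real_, G)
  out[ok] <- exp(fitz)
  # genes without residual df get the trend evaluated via interpolation
  if (any(!ok)) {
    ap <- stats::approxfun(avg_logcpm[ok], out[ok], rule = 2, ties = mean)
    out[!ok] <- ap(avg_logcpm[!ok])
  }
  out
}
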