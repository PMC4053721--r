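#' Fit a complete differential expression model to RNA-seq counts
#'
#' One-call pipeline from a count matrix to moderated inference. Four
#' engines share the same gene-wise linear model and empirical Bayes
#' machinery and differ only in how the mean-variance relationship is
#' handled:
#' \describe{
#'   \item{`"voom"`}{observation-level precision weights from the
#'     mean-variance trend ([voom()]), weighted least squares, constant
#'     variance prior.}
#'   \item{`"limma_trend"`}{unweighted least squares on log2-cpm, prior
#'     variance following a trend in average log2-cpm.}
#'   \item{`"limma_notrend"`}{unweighted least squares, constant prior.}
#'   \item{`"ordinary_t"`}{unweighted least squares, no moderation
#'     (prior df forced to 0) — the classical gene-wise t-test.}
#' }
#'
#' @param counts a [count_matrix()] or a genes x samples matrix of
#'   non-negative integer counts.
#' @param design design matrix (samples x coefficients), e.g. from
#'   [stats::model.matrix()].
#' @param method one of `"voom"`, `"limma_trend"`, `"limma_notrend"`,
#'   `"ordinary_t"`.
#' @param contrasts optional contrast matrix (coefficients x contrasts)
#'   applied before inference.
#' @param normalize `"none"`, `"tmm"` (scale-normalized effective library
#'   sizes) or `"quantile"` (quantile normalization of log2-cpm).
#' @param filter_min_total if not `NULL`, genes with fewer total reads are
#'   removed first (the simulation benchmark convention is 10).
#' @param span LOWESS span for the voom trend.
#' @param ... further arguments passed to [ebayes_moderate()].
#' @return An object of class `"voom_lm"`: list with components `cm`,
#'   `method`, `voom` (for the voom engine), `fit` (a `"genefit"`), `eb`
#'   (an `"ebfit"`), and `design`.
#' @examples
#' sim <- simulate_nb_counts(nb_sim_config(n_genes = 200, seed = 1))
#' X <- cbind(1, rep(c(0, 1), each = 3))
#' colnames(X) <- c("(Intercept)", "group2")
#' vfit <- voom_lm(sim$counts, X, filter_min_total = 10)
#' head(top_table(vfit$fit, vfit$eb, coef = "group2"))
#' @export
voom_lm <- function(counts, design,
                    method = c("voom", "limma_trend", "limma_notrend", "ordinary_t"),
                    contrasts = NULL,
                    normalize = c("none", "tmm", "quantile"),
                    filter_min_total = NULL, span = 0.5, ...) {
  method <- match.arg(method)
  normalize <- match.arg(normalize)
  cm <- if (inherits(counts, "count_matrix")) counts else count_matrix(counts)
  if (!is.null(filter_min_total)) cm <- filter_by_total(cm, filter_min_total)
  design <- as.matrix(design)
  use_eff <- FALSE
  if (normalize == "tmm") {
    cm$norm_factors <- tmm_factors(cm)
    use_eff <- TRUE
  }
  v <- NULL
  if (method == "voom") {
    v <- voom(cm, design, span = span, use_effective_sizes = use_eff,
              quantile = (normalize == "quantile"))
    fit <- fit_genewise(v$y, design, weights = v$weights)
  } else {
    lc <- to_log_cpm(cm, use_effective_sizes = use_eff)
    if (normalize == "quantile") lc$y <- quantile_normalize(lc$y)
    fit <- fit_genewise(lc, design)
  }
  if (!is.null(contrasts)) fit <- apply_contrasts(fit, contrasts)
  eb <- switch(method,
    voom = ebayes_moderate(fit, trend = FALSE, ...),
    limma_trend = ebayes_moderate(fit, trend = TRUE, ...),
    limma_notrend = ebayes_moderate(fit, trend = FALSE, ...),
    ordinary_t = ebayes_moderate(fit, trend = FALSE, prior_df = 0, ...)
  )
  structure(list(cm = cm, method = method, voom = v, fit = fit, eb = eb,
                 design = design),
            class = "voom_lm")
}

#' @export
print.voom_lm <- function(x, ...) {
  cat(sprintf("voom_lm fit (%s): %d genes, %d samples, %d coefficient(s)\n",
              x$method, nrow(x$fit$coefficients), ncol(x$fit$fitted),
              ncol(x$fit$coefficients)))
  print(x$eb)
  invisible(x)
}

#' @export
coef.voom_lm <- function(object, ...) object$fit$coefficients

#' @export
fitted.voom_lm <- function(object, ...) object$fit$fitted

#' @export
residuals.voom_lm <- function(object, ...) object$fit$y - object$fit$fitted

#' Predicted log2-cpm for a new design
#'
#' Evaluates each gene's fitted linear model at new covariate rows.
#'
#' @param object a [voom_lm()] fit.
#' @param newdesign matrix with the same columns as the fitted design;
#'   defaults to the original design (returning fitted values).
#' @param ... unused.
#' @return genes x rows matrix of predicted log2-cpm values.
#' @export
predict.voom_lm <- function(object, newdesign = object$design, ...) {
  newdesign <- as.matrix(newdesign)
  if (ncol(newdesign) != ncol(object$fit$coefficients))
    stop("newdesign must have ", ncol(object$fit$coefficients), " columns")
  object$fit$coefficients %*% t(newdesign)
}

#' Summary of a fitted differential expression model
#'
#' @param object a [voom_lm()] fit.
#' @param coef coefficient to summarize (default: last).
#' @param fdr_cutoffs FDR thresholds at which to count significant genes.
#' @param ... unused.
#' @return An object of class `"summary.voom_lm"` printed as the prior
#'   hyperparameters plus counts of up/down genes at each threshold.
#' @export
summary.voom_lm <- function(object, coef = ncol(object$fit$coefficients),
                            fdr_cutoffs = c(0.01, 0.05, 0.1), ...) {
  q <- object$eb$fdr[, coef]
  sgn <- sign(object$fit$coefficients[, coef])
  counts <- t(vapply(fdr_cutoffs, function(ct) {
    c(up = sum(q < ct & sgn > 0), down = sum(q < ct & sgn < 0))
  }, numeric(2)))
  rownames(counts) <- paste0("FDR<", fdr_cutoffs)
  structure(list(method = object$method, d0 = object$eb$d0,
                 s0sq = object$eb$s0sq, coef = coef, counts = counts),
            class = "summary.voom_lm")
}

#' @export
print.summary.voom_lm <- function(x, ...) {
  cat(sprintf("method: %s\nprior df d0: %s\n", x$method,
              format(x$d0, digits = 4)))
  if (length(x$s0sq) == 1)
    cat(sprintf("prior variance s0^2: %s\n", format(x$s0sq, digits = 4)))
  else cat("prior variance s0^2: trended (per gene)\n")
  cat("significant genes by direction:\n")
  print(x$counts)
  invisible(x)
}

#' Plot the mean-variance relationship of a voom fit
#'
#' Gene-wise square-root residual standard deviations against average
#' log2-count, with the fitted LOWESS trend overlaid (the classic voom
#' diagnostic plot).
#'
#' @param x a [voom_lm()] fit with `method = "voom"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.voom_lm <- function(x, ...) {
  if (is.null(x$voom)) stop("mean-variance plot requires method = 'voom'")
  ff <- x$voom$first_fit
  rt <- avg_log_count(ff$avg_logcpm, x$voom$y$lib_sizes_used)
  graphics::plot(rt, sqrt(ff$sigma), pch = 16, cex = 0.3,
                 col = "grey40", xlab = expression(log[2]~count),
                 ylab = expression(sqrt(sigma)),
                 main = "voom mean-variance trend", ...)
  graphics::lines(x$voom$trend$knots_x, x$voom$trend$knots_y,
                  col = "red", lwd = 2)
  invisible(x)
}
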