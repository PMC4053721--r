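#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes a scale normalization factor per sample to adjust library sizes
#' for compositional differences between libraries. For each sample, gene-wise
#' log2 ratios to a reference sample (M-values) and average log2 abundances
#' (A-values) are formed from the cpm profiles; the most extreme 30% of
#' M-values in each tail and 5% of A-values in each tail are trimmed, and the
#' factor is 2 to the power of the weighted mean of the remaining M-values,
#' with weights given by inverse asymptotic (binomial) variances. Factors are
#' re-centered so that their geometric mean is 1.
#'
#' @param cm a [count_matrix()].
#' @param ref_sample optional reference column index; by default the sample
#'   whose 75th percentile of cpm is closest to the mean of those percentiles.
#' @param logratio_trim fraction of M-values trimmed from each tail.
#' @param abundance_trim fraction of A-values trimmed from each tail.
#' @return numeric vector of normalization factors, geometric mean 1.
#'   Multiply `lib_sizes` by these to obtain effective library sizes.
#' @references Robinson MD, Oshlack A (2010). A scaling normalization method
#'   for differential expression analysis of RNA-seq data. Genome Biology 11:R25.
#' @export
tmm_factors <- function(cm, ref_sample = NULL,
                        logratio_trim = 0.3, abundance_trim = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  x <- cm$counts
  lib <- cm$lib_sizes
  n <- ncol(x)
  if (is.null(ref_sample)) {
    q75 <- apply(x, 2, function(col) stats::quantile(col / sum(col), 0.75))
    ref_sample <- which.min(abs(q75 - mean(q75)))
  }
  f <- vapply(seq_len(n), function(i) {
    .tmm_pair(x[, i], x[, ref_sample], lib[i], lib[ref_sample],
              logratio_trim, abundance_trim)
  }, numeric(1))
  # geometric-mean centering
  f / exp(mean(log(f)))
}

# One TMM factor: observed column vs reference column.
.tmm_pair <- function(obs, ref, nobs, nref, logratio_trim, abundance_trim) {
  keep <- obs > 0 & ref > 0
  if (!any(keep))
    stop("sample shares no expressed genes with the reference; cannot compute TMM factor")
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / nobs) / (ref / nref))
  A <- (log2(obs / nobs) + log2(ref / nref)) / 2
  # inverse asymptotic variance of M under binomial sampling
  v <- (nobs - obs) / (nobs * obs) + (nref - ref) / (nref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  nkeep <- length(M)
  loM <- floor(nkeep * logratio_trim) + 1
  hiM <- nkeep + 1 - loM
  loA <- floor(nkeep * abundance_trim) + 1
  hiA <- nkeep + 1 - loA
  rM <- rank(M); rA <- rank(A)
  trim <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(trim)) return(1)
  f <- sum(M[trim] / v[trim]) / sum(1 / v[trim])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Quantile normalization of a log-expression matrix
#'
#' Forces every column to share the same empirical distribution: the mean of
#' the column-wise order statistics. Ties within a column receive the mean of
#' the target values their positions span.
#'
#' @param y numeric matrix (genes x samples), no missing values.
#' @return matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(y) {
  y <- as.matrix(y)
  if (anyNA(y)) stop("missing values are not supported")
  if (ncol(y) < 2) return(y)
  sorted <- apply(y, 2, sort)
  target <- rowMeans(sorted)
  out <- y
  for (j in seq_len(ncol(y))) {
    r <- rank(y[, j], ties.method = "average")
    # non-integer ranks (ties) interpolate between adjacent order statistics
    lo <- floor(r); hi <- ceiling(r)
    out[, j] <- (target[lo] + target[hi]) / 2
  }
  out
}
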