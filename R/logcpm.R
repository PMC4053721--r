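#' Log2 counts-per-million
#'
#' Transforms counts to the log2 cpm scale:
#' `y_gi = log2((r_gi + 0.5) / (R_i + 1) * 1e6)`.
#' The count offset 0.5 avoids log of zero and damps the variability of
#' low counts; the library-size offset 1 guarantees
#' `(r + 0.5) / (R + 1)` lies strictly inside (0, 1), so y is finite for
#' every count including zero.
#'
#' @param cm a [count_matrix()].
#' @param use_effective_sizes if `TRUE`, library sizes are multiplied by the
#'   normalization factors (e.g. from [tmm_factors()]) before the transform.
#' @return An object of class `"logcpm"`: list with `y` (genes x samples
#'   matrix of log2 cpm) and `lib_sizes_used`.
#' @export
to_log_cpm <- function(cm, use_effective_sizes = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  R <- if (use_effective_sizes) effective_lib_sizes(cm) else cm$lib_sizes
  y <- t(log2(t(cm$counts + 0.5) / (R + 1) * 1e6))
  dimnames(y) <- dimnames(cm$counts)
  structure(list(y = y, lib_sizes_used = R), class = "logcpm")
}

#' @export
print.logcpm <- function(x, ...) {
  cat(sprintf("logcpm: %d genes x %d samples (log2 cpm)\n",
              nrow(x$y), ncol(x$y)))
  invisible(x)
}

#' Subtract log2 gene length to put log-cpm on an rpkm-like scale
#'
#' Precision weights are unchanged by a per-gene additive shift of the
#' log-expression values, so differential expression results are identical
#' on either scale; this helper only changes the reporting scale.
#'
#' @param lc a `"logcpm"` object.
#' @param gene_length_kb positive gene lengths in kilobases, one per gene.
#' @return a `"logcpm"` object with `log2(gene_length_kb)` subtracted rowwise.
#' @export
subtract_log_gene_length <- function(lc, gene_length_kb) {
  stopifnot(inherits(lc, "logcpm"), length(gene_length_kb) == nrow(lc$y),
            all(gene_length_kb > 0))
  lc$y <- lc$y - log2(gene_length_kb)
  lc
}

#' Squared coefficient of variation of a negative binomial count
#'
#' For a count with mean `lam` and quadratic mean-variance relationship
#' `var(r) = lam + phi * lam^2`, the squared CV is `1/lam + phi`: a
#' technical (Poisson) component that vanishes for large counts plus a
#' biological component `phi` that does not.
#'
#' @param lam expected count, positive.
#' @param phi dispersion (squared biological CV), non-negative.
#' @return `1/lam + phi`.
#' @export
cv2_of_counts <- function(lam, phi) {
  if (any(lam <= 0)) stop("lam must be positive")
  if (any(phi < 0)) stop("phi must be non-negative")
  1 / lam + phi
}

#' Delta-rule standard deviation of log-cpm
#'
#' First-order propagation of the count variance through the log transform:
#' on the natural-log scale the standard deviation of log-cpm approximately
#' equals the coefficient of variation of the count, `sqrt(1/lam + phi)`.
#' On the log2 scale this is divided by `ln 2`.
#'
#' @param lam expected count, positive.
#' @param phi dispersion, non-negative.
#' @param log_base2 if `TRUE`, return the sd on the log2 scale.
#' @return approximate sd of the log-cpm of the count.
#' @export
approx_sd_log_cpm <- function(lam, phi, log_base2 = FALSE) {
  s <- sqrt(cv2_of_counts(lam, phi))
  if (log_base2) s / log(2) else s
}
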