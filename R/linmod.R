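#' Gene-wise (weighted) least squares fits
#'
#' Fits the same linear model `E(y_g) = X beta_g` to every gene, optionally
#' with a different positive weight for every observation. Coefficients are
#' in log2-fold-change units when `y` holds log2 expression values. For gene
#' g the estimate minimizes `sum_i w_gi (y_gi - x_i' beta)^2`; the residual
#' variance is the weighted residual sum of squares divided by `n - p`.
#'
#' @param y a `"logcpm"` object or a genes x samples numeric matrix.
#' @param X design matrix (samples x coefficients), full column rank.
#' @param weights optional genes x samples matrix of strictly positive
#'   finite observation weights.
#' @return An object of class `"genefit"`: list with
#'   \describe{
#'     \item{coefficients}{G x p matrix of estimates}
#'     \item{fitted}{G x n matrix of fitted values}
#'     \item{sigma}{G-vector of residual standard deviations}
#'     \item{df_resid}{G-vector of residual degrees of freedom (n - p)}
#'     \item{avg_logcpm}{G-vector of unweighted row means of y}
#'     \item{stdev_unscaled}{G x p matrix, sqrt of the diagonal of
#'       `(X' W_g X)^{-1}`; the standard error of a coefficient is
#'       `sigma * stdev_unscaled`}
#'     \item{cov_unscaled}{p x p x G array of unscaled coefficient
#'       covariances}
#'     \item{design, weights}{the inputs}
#'   }
#' @export
fit_genewise <- function(y, X, weights = NULL) {
  if (inherits(y, "logcpm")) y <- y$y
  y <- as.matrix(y)
  X <- as.matrix(X)
  n <- ncol(y); G <- nrow(y); p <- ncol(X)
  if (nrow(X) != n) stop("design has ", nrow(X), " rows but y has ", n, " samples")
  if (n <= p) stop("need more samples than coefficients for variance estimation")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  qrX <- qr(X)
  if (qrX$rank < p) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!all(dim(weights) == dim(y)))
      stop("weights must have the same dimensions as y")
    if (any(!is.finite(weights)) || any(weights <= 0))
      stop("weights must be strictly positive and finite")
  }

  cov_unscaled <- array(NA_real_, c(p, p, G))
  if (is.null(weights)) {
    beta <- t(qr.coef(qrX, t(y)))
    mu <- beta %*% t(X)
    V <- chol2inv(chol(crossprod(X)))
    for (g in seq_len(G)) cov_unscaled[, , g] <- V
    rss <- rowSums((y - mu)^2)
    stdev_unscaled <- matrix(rep(sqrt(diag(V)), each = G), G, p)
  } else {
    # vectorized normal equations: X'W_gX entries via one big multiply
    idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    P2 <- X[, idx[, 1], drop = FALSE] * X[, idx[, 2], drop = FALSE]  # n x q
    XtWX <- weights %*% P2                                           # G x q
    XtWy <- (weights * y) %*% X                                      # G x p
    beta <- matrix(NA_real_, G, p)
    stdev_unscaled <- matrix(NA_real_, G, p)
    if (p == 2L) {
      # closed-form 2x2 inverse, vectorized over genes
      a <- XtWX[, 1]; b2 <- XtWX[, 2]; c2 <- XtWX[, 3]
      det <- a * c2 - b2^2
      beta[, 1] <- (c2 * XtWy[, 1] - b2 * XtWy[, 2]) / det
      beta[, 2] <- (a * XtWy[, 2] - b2 * XtWy[, 1]) / det
      cov_unscaled[1, 1, ] <- c2 / det
      cov_unscaled[2, 2, ] <- a / det
      cov_unscaled[1, 2, ] <- cov_unscaled[2, 1, ] <- -b2 / det
      stdev_unscaled[, 1] <- sqrt(c2 / det)
      stdev_unscaled[, 2] <- sqrt(a / det)
    } else {
      A <- matrix(0, p, p)
      for (g in seq_len(G)) {
        A[cbind(idx[, 1], idx[, 2])] <- XtWX[g, ]
        A[cbind(idx[, 2], idx[, 1])] <- XtWX[g, ]
        Vg <- chol2inv(chol(A))
        b <- Vg %*% XtWy[g, ]
        beta[g, ] <- b
        cov_unscaled[, , g] <- Vg
        stdev_unscaled[g, ] <- sqrt(diag(Vg))
      }
    }
    mu <- beta %*% t(X)
    rss <- rowSums(weights * (y - mu)^2)
  }
  df_resid <- rep(n - p, G)
  sigma <- sqrt(rss / df_resid)
  dimnames(beta) <- list(rownames(y), colnames(X))
  dimnames(stdev_unscaled) <- dimnames(beta)
  dimnames(mu) <- dimnames(y)
  structure(list(
    coefficients = beta, fitted = mu, sigma = sigma, df_resid = df_resid,
    avg_logcpm = rowMeans(y), stdev_unscaled = stdev_unscaled,
    cov_unscaled = cov_unscaled, design = X, weights = weights, y = y
  ), class = "genefit")
}

#' @export
print.genefit <- function(x, ...) {
  cat(sprintf("genefit: %d genes, %d samples, %d coefficient(s) [%s]\n",
              nrow(x$coefficients), ncol(x$fitted), ncol(x$coefficients),
              paste(colnames(x$coefficients), collapse = ", ")))
  invisible(x)
}

#' Re-parameterize a fit through a contrast matrix
#'
#' Transforms the fitted coefficients to `beta %*% C` and propagates the
#' unscaled covariance as `C' (X'WX)^{-1} C`. Residual standard deviations
#' and degrees of freedom are unchanged.
#'
#' @param fit a [fit_genewise()] result.
#' @param C numeric p x k contrast matrix (a vector is taken as one contrast).
#' @return a `"genefit"` with k re-parameterized coefficients.
#' @export
apply_contrasts <- function(fit, C) {
  stopifnot(inherits(fit, "genefit"))
  C <- as.matrix(C)
  p <- ncol(fit$coefficients)
  if (nrow(C) != p)
    stop("contrast matrix must have ", p, " rows (one per coefficient)")
  if (any(!is.finite(C))) stop("contrasts must be finite")
  if (is.null(colnames(C)))
    colnames(C) <- paste0("contrast", seq_len(ncol(C)))
  G <- nrow(fit$coefficients); k <- ncol(C)
  beta <- fit$coefficients %*% C
  cov_new <- array(NA_real_, c(k, k, G))
  su <- matrix(NA_real_, G, k, dimnames = list(rownames(beta), colnames(C)))
  for (g in seq_len(G)) {
    Vg <- t(C) %*% fit$cov_unscaled[, , g] %*% C
    cov_new[, , g] <- Vg
    su[g, ] <- sqrt(diag(Vg))
  }
  out <- fit
  out$coefficients <- beta
  out$cov_unscaled <- cov_new
  out$stdev_unscaled <- su
  out
}

#' Quadratic time-course design matrix
#'
#' Builds the design `{1, t, t^2}` for fitting a quadratic trend in time to
#' each gene's log-expression. The time covariate is centered and scaled to
#' unit range before squaring, for numerical conditioning; the fitted curve
#' is unchanged by this re-parameterization.
#'
#' @param times numeric vector of time points (e.g. developmental stage
#'   midpoints), one per sample; at least 3 distinct values.
#' @return design matrix with columns `(Intercept)`, `t`, `t2` and
#'   attributes `times`, `center`, `scale` used by [peak_time()].
#' @export
quadratic_time_design <- function(times) {
  times <- as.numeric(times)
  if (length(unique(times)) < 3)
    stop("need at least 3 distinct time points for a quadratic trend")
  ctr <- mean(range(times))
  scl <- diff(range(times))
  tt <- (times - ctr) / scl
  X <- cbind(`(Intercept)` = 1, t = tt, t2 = tt^2)
  attr(X, "times") <- times
  attr(X, "center") <- ctr
  attr(X, "scale") <- scl
  X
}

#' Peak time of a fitted quadratic trend
#'
#' For each gene, the observed time point at which the fitted quadratic is
#' largest. A concave curve with an interior vertex peaks at the observed
#' time nearest the vertex; monotone trends peak at the first or last time.
#'
#' @param fit a [fit_genewise()] result fitted with [quadratic_time_design()].
#' @param design the design matrix returned by [quadratic_time_design()].
#' @return numeric vector of peak times, one per gene.
#' @export
peak_time <- function(fit, design) {
  stopifnot(inherits(fit, "genefit"))
  times <- attr(design, "times")
  if (is.null(times)) stop("design must come from quadratic_time_design()")
  stages <- sort(unique(times))
  ctr <- attr(design, "center"); scl <- attr(design, "scale")
  tt <- (stages - ctr) / scl
  Xs <- cbind(1, tt, tt^2)
  pred <- fit$coefficients %*% t(Xs)   # G x n_stages
  stages[max.col(pred, ties.method = "first")]
}

#' Read a design or contrast matrix from a tab-delimited file
#'
#' Expects a header row of coefficient names and a first column of row
#' labels (sample names for a design, coefficient names for contrasts).
#'
#' @param path path to the file.
#' @return numeric matrix with dimnames.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  m
}
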