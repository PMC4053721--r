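#' Read gene sets from a GMT file
#'
#' Each tab-delimited line holds a set name, a description, and the member
#' gene IDs. Duplicate members are removed with a warning; a line with no
#' members is an error.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors of gene IDs.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": need name, description and at least one member")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop("malformed GMT line ", i, ": empty member list")
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", f[1], "' deduplicated")
      members <- unique(members)
    }
    sets[[f[1]]] <- members
  }
  sets
}

# Reparameterize the design so the contrast of interest becomes the last
# coefficient: X beta = (X Q) (Q' beta) with the first column of Q
# proportional to the contrast, then moved last.
.contrast_as_last_coef <- function(X, contrast) {
  p <- ncol(X)
  contrast <- as.numeric(contrast)
  if (length(contrast) != p) stop("contrast must have one entry per coefficient")
  Q <- qr.Q(qr(matrix(contrast, p, 1)), complete = TRUE)
  Q <- Q[, c(2:p, 1), drop = FALSE]      # tested direction last
  list(X = X %*% Q, scale = sqrt(sum(contrast^2)))
}

#' Self-contained rotation gene set test
#'
#' Tests whether the genes of a set are differentially expressed for a
#' given contrast, without reference to genes outside the set. For each set
#' gene the data are reduced, under the observation weights, to the
#' contrast effect plus the residual-space effects; random rotations of
#' this spherical vector (the same rotation applied to every gene, which
#' preserves inter-gene correlation) generate the null distribution of the
#' set statistic. Moderated t-statistics use variance squeezing with
#' hyperparameters estimated from all genes. The p-value is
#' `(b + 1) / (B + 1)` where `b` counts rotations at least as extreme, so
#' the smallest attainable p-value is `1/(B+1)` (0.0001 at the default
#' `B = 9999`).
#'
#' @param y a `"logcpm"` object or genes x samples matrix.
#' @param X design matrix.
#' @param contrast numeric contrast vector (length = columns of X).
#' @param set character vector of member gene IDs (rownames of y).
#' @param weights optional genes x samples positive weight matrix (e.g.
#'   from [voom()]).
#' @param B number of rotations.
#' @param stat `"mean"` (directional, mean of z-scores) or `"msq"` (mean
#'   squared z-score, sensitive to mixed-direction change).
#' @return An object of class `"geneset_result"`: list with `name`,
#'   `n_genes_used`, `statistic`, `p_value`, `direction`, `p_up`,
#'   `p_down`, `p_mixed`, `rotations_used`. For `stat = "mean"`,
#'   `p_value` is the one-sided rotation p in the observed direction
#'   (both directional p-values are always reported); for `stat = "msq"`
#'   it is the mixed-alternative p.
#' @export
rotation_set_test <- function(y, X, contrast, set, weights = NULL,
                              B = 9999, stat = c("mean", "msq")) {
  stat <- match.arg(stat)
  if (inherits(y, "logcpm")) y <- y$y
  y <- as.matrix(y); X <- as.matrix(X)
  if (B < 99) stop("B must be at least 99")
  n <- ncol(y); p <- ncol(X)
  d <- n - p
  if (d < 1) stop("need at least 1 residual degree of freedom")
  idx <- which(rownames(y) %in% set)
  if (length(idx) == 0) stop("no set members found in the expression matrix")

  rp <- .contrast_as_last_coef(X, contrast)
  X2 <- rp$X
  # moderation hyperparameters from all genes
  allfit <- fit_genewise(y, X2, weights = weights)
  pr <- estimate_prior(allfit$sigma, allfit$df_resid)

  # per set gene: (contrast effect, residual effects), length d + 1
  m <- length(idx)
  E <- matrix(NA_real_, m, d + 1)
  for (j in seq_len(m)) {
    g <- idx[j]
    w <- if (is.null(weights)) rep(1, n) else weights[g, ]
    sw <- sqrt(w)
    qr_g <- qr(X2 * sw)
    eff <- qr.qty(qr_g, y[g, ] * sw)
    E[j, ] <- eff[p:n]
  }
  norm2 <- rowSums(E^2)
  dft <- pr$d0 + d

  set_stats <- function(e1) {
    s2 <- (norm2 - e1^2) / d
    tmod <- e1 / sqrt(squeeze_var(s2, d, pr$d0, pr$s0sq))
    z <- zscore_t(tmod, dft)
    c(mean = mean(z), msq = mean(z^2))
  }
  obs <- set_stats(E[, 1])
  rot_mean <- numeric(B); rot_msq <- numeric(B)
  for (b in seq_len(B)) {
    r <- stats::rnorm(d + 1)
    r <- r / sqrt(sum(r^2))
    sb <- set_stats(as.numeric(E %*% r))
    rot_mean[b] <- sb["mean"]; rot_msq[b] <- sb["msq"]
  }
  p_up <- (sum(rot_mean >= obs["mean"]) + 1) / (B + 1)
  p_down <- (sum(rot_mean <= obs["mean"]) + 1) / (B + 1)
  p_mixed <- (sum(rot_msq >= obs["msq"]) + 1) / (B + 1)
  direction <- if (stat == "msq") "mixed"
               else if (obs["mean"] >= 0) "up" else "down"
  p_value <- switch(direction, up = p_up, down = p_down, mixed = p_mixed)
  structure(list(
    name = NULL, n_genes_used = m,
    statistic = unname(obs[if (stat == "mean") "mean" else "msq"]),
    p_value = p_value, direction = direction,
    p_up = p_up, p_down = p_down, p_mixed = p_mixed,
    rotations_used = B
  ), class = "geneset_result")
}

#' Competitive gene set test with inter-gene correlation correction
#'
#' Compares the moderated t-statistics (converted to normal-equivalent
#' z-scores) of the set's genes against all other genes with a two-sample
#' t-test whose set variance is inflated by the variance inflation factor
#' `VIF = 1 + (m - 1) * rho_bar`, where `rho_bar` is the mean pairwise
#' correlation of the set genes' residuals. With `rho_bar = 0` this reduces
#' to an ordinary two-sample comparison; positive correlation widens the
#' null, protecting against the anti-conservativeness of naive competitive
#' tests.
#'
#' @param t_stats per-gene moderated t-statistics (all genes).
#' @param df degrees of freedom of the t-statistics (recycled).
#' @param set_mask logical vector marking set membership, or a character
#'   vector of gene IDs matched against `names(t_stats)`.
#' @param residuals optional genes x samples matrix of residuals from the
#'   design fit, used to estimate `rho_bar` (required when the set has 2 or
#'   more genes unless `rho` is given).
#' @param weights optional observation weights; residuals are scaled by
#'   `sqrt(weights)` before correlations are computed.
#' @param rho optional known mean inter-gene correlation (overrides
#'   estimation).
#' @return An object of class `"geneset_result"` with `statistic` (the
#'   two-sample t), `p_value` (two-sided), `p_up`, `p_down`, `vif`,
#'   `n_genes_used`, `direction`.
#' @export
competitive_set_test <- function(t_stats, df, set_mask, residuals = NULL,
                                 weights = NULL, rho = NULL) {
  G <- length(t_stats)
  if (is.character(set_mask)) set_mask <- names(t_stats) %in% set_mask
  if (length(set_mask) != G) stop("set_mask must match t_stats length")
  m <- sum(set_mask)
  if (m == 0) stop("no genes in the set")
  m2 <- G - m
  if (m2 < 2) stop("too few genes outside the set")
  z <- zscore_t(t_stats, df)
  if (m == 1) {
    rho_bar <- 0
  } else if (!is.null(rho)) {
    rho_bar <- rho
  } else {
    if (is.null(residuals)) stop("residuals needed to estimate inter-gene correlation")
    rmat <- residuals[set_mask, , drop = FALSE]
    if (!is.null(weights)) rmat <- rmat * sqrt(weights[set_mask, , drop = FALSE])
    cc <- stats::cor(t(rmat))
    rho_bar <- mean(cc[upper.tri(cc)])
  }
  rho_bar <- max(rho_bar, -1 / (m - 1) + 1e-12)
  vif <- 1 + (m - 1) * rho_bar
  zs <- z[set_mask]; zr <- z[!set_mask]
  delta <- mean(zs) - mean(zr)
  s2 <- (sum((zs - mean(zs))^2) + sum((zr - mean(zr))^2)) / (G - 2)
  tstat <- delta / sqrt(s2 * (vif / m + 1 / m2))
  p_down <- stats::pt(tstat, df = G - 2)
  p_up <- stats::pt(tstat, df = G - 2, lower.tail = FALSE)
  structure(list(
    name = NULL, n_genes_used = m, statistic = tstat,
    p_value = 2 * min(p_down, p_up), direction = if (delta >= 0) "up" else "down",
    p_up = p_up, p_down = p_down, vif = vif, rho = rho_bar
  ), class = "geneset_result")
}

#' @export
print.geneset_result <- function(x, ...) {
  cat(sprintf("gene set test: %d genes, direction %s, statistic %.4g, p = %.4g\n",
              x$n_genes_used, x$direction, x$statistic, x$p_value))
  if (!is.null(x$vif)) cat(sprintf("  VIF = %.3f (rho = %.3f)\n", x$vif, x$rho))
  if (!is.null(x$rotations_used))
    cat(sprintf("  rotations = %d (min attainable p = %.2g)\n",
                x$rotations_used, 1 / (x$rotations_used + 1)))
  invisible(x)
}
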