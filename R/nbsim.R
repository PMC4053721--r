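#' Configuration for the negative binomial RNA-seq simulator
#'
#' The defaults reproduce the benchmark study conditions: 10,000 genes in
#' two groups of three libraries; equal library sizes of 11 million reads
#' (the unequal layout alternates 20 million and 2 million, keeping the
#' same 66 million total); 100 genes twofold upregulated in each group in
#' the power scenario; a dispersion trend `sqrt(psi) = 0.2 + lambda^(-1/2)`
#' asymptoting to a biological CV of 0.2 for large counts; and gene-wise
#' dispersion scatter `delta_g` with `40/delta_g ~ chisq(40)` (or a
#' log-normal alternative with log-scale sd 0.25, matched in log-scale CV).
#'
#' @param n_genes number of genes.
#' @param group_sizes integer vector of two group sizes.
#' @param lib_layout `"equal"` or `"unequal"`, used when `lib_sizes` is
#'   `NULL`.
#' @param lib_sizes optional explicit library sizes.
#' @param n_de_per_group number of genes upregulated in each group (0 for
#'   a null simulation).
#' @param fold_change fold change applied to DE genes.
#' @param disp_asymptote_sqrt large-count asymptote of the square-root
#'   dispersion trend (biological CV).
#' @param disp_df degrees of freedom of the inverse chi-square scatter.
#' @param disp_family `"inv_chisq"` or `"lognormal"`.
#' @param lognormal_sd log-scale sd of the log-normal scatter alternative.
#' @param baseline_log_sd log-scale sd of the log-normal baseline
#'   proportions (2.0 gives roughly five orders of magnitude of dynamic
#'   range, emulating a realistic cpm distribution).
#' @param seed integer seed; the simulation is bit-reproducible given the
#'   configuration.
#' @return a list of class `"nb_sim_config"`.
#' @export
nb_sim_config <- function(n_genes = 10000, group_sizes = c(3, 3),
                          lib_layout = c("equal", "unequal"),
                          lib_sizes = NULL,
                          n_de_per_group = 0, fold_change = 2,
                          disp_asymptote_sqrt = 0.2, disp_df = 40,
                          disp_family = c("inv_chisq", "lognormal"),
                          lognormal_sd = 0.25, baseline_log_sd = 2,
                          seed = 1) {
  lib_layout <- match.arg(lib_layout)
  disp_family <- match.arg(disp_family)
  n <- sum(group_sizes)
  if (is.null(lib_sizes)) {
    lib_sizes <- switch(lib_layout,
      equal = rep(11e6, n),
      unequal = ifelse(seq_len(n) %% 2 == 1, 20e6, 2e6))
  }
  if (length(lib_sizes) != n || any(lib_sizes <= 0))
    stop("lib_sizes must be ", n, " positive values")
  if (2 * n_de_per_group > n_genes)
    stop("too many DE genes for n_genes")
  if (fold_change <= 0) stop("fold_change must be positive")
  structure(list(
    n_genes = n_genes, group_sizes = group_sizes, lib_sizes = lib_sizes,
    n_de_per_group = n_de_per_group, fold_change = fold_change,
    disp_asymptote_sqrt = disp_asymptote_sqrt, disp_df = disp_df,
    disp_family = disp_family, lognormal_sd = lognormal_sd,
    baseline_log_sd = baseline_log_sd, seed = seed
  ), class = "nb_sim_config")
}

#' Scenario presets for the simulator
#'
#' `"null"` has no differentially expressed genes; `"power"` adds 100
#' twofold-upregulated genes per group. Combined with an equal or unequal
#' library-size layout.
#'
#' @param scenario `"null"` or `"power"`.
#' @param lib_layout `"equal"` or `"unequal"`.
#' @param seed integer seed.
#' @param ... overrides passed to [nb_sim_config()].
#' @return a `"nb_sim_config"`.
#' @export
nb_scenario <- function(scenario = c("null", "power"),
                        lib_layout = c("equal", "unequal"), seed = 1,
                        n_de_per_group = NULL, ...) {
  scenario <- match.arg(scenario)
  if (is.null(n_de_per_group))
    n_de_per_group <- if (scenario == "power") 100 else 0
  nb_sim_config(lib_layout = match.arg(lib_layout),
                n_de_per_group = n_de_per_group, seed = seed, ...)
}

#' Baseline expression proportions
#'
#' Generates the relative proportion of reads expected from each gene:
#' strictly positive, summing to one, heavy-tailed. Normalized draws from
#' a log-normal distribution with log-scale sd `log_sd` (default 2.0,
#' spanning roughly five orders of magnitude between extreme percentiles)
#' stand in for an empirical cpm distribution; any positive vector may be
#' supplied instead via `empirical`.
#'
#' @param n_genes number of genes.
#' @param log_sd log-scale standard deviation of the log-normal draws.
#' @param empirical optional user-supplied positive expression levels to
#'   normalize instead of drawing.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return numeric vector of proportions summing to 1.
#' @export
baseline_proportions <- function(n_genes, log_sd = 2, empirical = NULL,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- if (is.null(empirical)) {
    stats::rlnorm(n_genes, meanlog = 0, sdlog = log_sd)
  } else {
    if (length(empirical) != n_genes || any(empirical <= 0))
      stop("empirical must be ", n_genes, " positive values")
    as.numeric(empirical)
  }
  x / sum(x)
}

#' Dispersion trend as a function of expected count
#'
#' `psi = (a + lambda^(-1/2))^2` with asymptote `a^2` for large counts
#' (default `a = 0.2`, a 20% biological CV): low counts carry extra
#' dispersion, large counts approach the asymptotic biological variation.
#'
#' @param lam expected count(s), positive.
#' @param asymptote_sqrt the large-count asymptote of `sqrt(psi)`.
#' @return dispersion values, same shape as `lam`.
#' @export
dispersion_trend <- function(lam, asymptote_sqrt = 0.2) {
  if (any(lam <= 0)) stop("lam must be positive")
  (asymptote_sqrt + lam^(-0.5))^2
}

#' Gene-wise dispersion scatter
#'
#' Multiplicative gene-level factors `delta_g` around the dispersion
#' trend. The inverse chi-square family draws `delta = df / chisq(df)`
#' (mean `df/(df-2)`); the log-normal alternative has median exactly 1 and
#' a matched log-scale spread.
#'
#' @param n_genes number of genes.
#' @param family `"inv_chisq"` or `"lognormal"`.
#' @param df degrees of freedom of the inverse chi-square.
#' @param lognormal_sd log-scale sd of the log-normal alternative.
#' @param seed optional seed.
#' @return positive numeric vector of length `n_genes`.
#' @export
gene_dispersion_scatter <- function(n_genes, family = c("inv_chisq", "lognormal"),
                                    df = 40, lognormal_sd = 0.25, seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  switch(family,
         inv_chisq = df / stats::rchisq(n_genes, df = df),
         lognormal = stats::rlnorm(n_genes, meanlog = 0, sdlog = lognormal_sd))
}

#' Simulate an RNA-seq count matrix with known truth
#'
#' Expected counts are `lambda_gi = p_g * fc_gi * R_i`: baseline proportion
#' times library size, multiplied by the fold change for DE genes in their
#' upregulated group. Observation dispersions are
#' `phi_gi = psi(lambda_gi) * delta_g` (the trend is evaluated at the
#' realized expected count, fold change included). Counts are drawn as a
#' gamma-Poisson mixture with mean `lambda` and variance
#' `lambda + phi * lambda^2`, which is the negative binomial for any
#' positive `phi` and collapses to Poisson at `phi = 0`.
#'
#' @param cfg a [nb_sim_config()].
#' @param phi_override optional fixed dispersion replacing the trend and
#'   scatter (0 gives pure Poisson counts).
#' @return list with `counts` (a [count_matrix()]) and `truth`, a data
#'   frame with columns `gene`, `status`
#'   (`"null"`/`"up_in_group1"`/`"up_in_group2"`), `true_log2fc` (log2
#'   fold change of group 2 relative to group 1) and `is_de`.
#' @export
simulate_nb_counts <- function(cfg, phi_override = NULL) {
  stopifnot(inherits(cfg, "nb_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  n <- sum(cfg$group_sizes)
  group <- rep(c(1, 2), cfg$group_sizes)
  props <- baseline_proportions(G, log_sd = cfg$baseline_log_sd)

  status <- rep("null", G)
  nde <- cfg$n_de_per_group
  if (nde > 0) {
    de <- sample.int(G, 2 * nde)
    status[de[seq_len(nde)]] <- "up_in_group1"
    status[de[nde + seq_len(nde)]] <- "up_in_group2"
  }
  fc <- matrix(1, G, n)
  fc[status == "up_in_group1", group == 1] <- cfg$fold_change
  fc[status == "up_in_group2", group == 2] <- cfg$fold_change

  lam <- (props %o% cfg$lib_sizes) * fc
  if (is.null(phi_override)) {
    delta <- gene_dispersion_scatter(G, cfg$disp_family, df = cfg$disp_df,
                                     lognormal_sd = cfg$lognormal_sd)
    phi <- dispersion_trend(lam, cfg$disp_asymptote_sqrt) * delta
  } else {
    phi <- matrix(phi_override, G, n)
  }
  counts <- matrix(0L, G, n)
  pos <- phi > 0
  # gamma-Poisson: shape 1/phi, mean lambda -> NB(mean lambda, var lambda + phi lambda^2)
  if (any(pos)) {
    shape <- 1 / phi[pos]
    gm <- stats::rgamma(sum(pos), shape = shape, scale = lam[pos] * phi[pos])
    counts[pos] <- stats::rpois(sum(pos), gm)
  }
  if (any(!pos)) counts[!pos] <- stats::rpois(sum(!pos), lam[!pos])
  dim(counts) <- c(G, n)
  rownames(counts) <- paste0("gene", seq_len(G))
  colnames(counts) <- paste0(rep(c("grp1_", "grp2_"), cfg$group_sizes),
                             unlist(lapply(cfg$group_sizes, seq_len)))
  truth <- data.frame(
    gene = rownames(counts),
    status = status,
    true_log2fc = ifelse(status == "up_in_group2", log2(cfg$fold_change),
                  ifelse(status == "up_in_group1", -log2(cfg$fold_change), 0)),
    is_de = status != "null"
  )
  list(counts = count_matrix(counts, lib_sizes = cfg$lib_sizes),
       truth = truth, group = factor(group))
}

#' Construct the spike-in style benchmark truth table
#'
#' Mirrors the construction of a half-DE benchmark from two spike-in
#' mixes: of `n_transcripts` control transcripts, `n_nonde` have equal
#' concentration in both mixes and the remainder split into three equal
#' groups (fourfold higher in Mix 1, 1.5-fold higher in Mix 2, twofold
#' higher in Mix 2). Each non-DE transcript is replicated
#' `replicate_factor` times, yielding with the defaults
#' `(92 - 23) + 23 * 3 = 138` entries, exactly half DE.
#'
#' @param n_transcripts total spiked transcripts.
#' @param n_nonde number with equal concentration in both mixes.
#' @param replicate_factor times each non-DE transcript is replicated.
#' @return data frame with columns `transcript`, `source`, `group`
#'   (`"up4_mix1"`, `"up1.5_mix2"`, `"up2_mix2"`, `"non_de"`),
#'   `true_log2fc` (Mix 2 relative to Mix 1) and `is_de`.
#' @export
make_spikein_benchmark <- function(n_transcripts = 92, n_nonde = 23,
                                   replicate_factor = 3) {
  n_de <- n_transcripts - n_nonde
  if (n_de %% 3 != 0)
    stop("DE transcripts (", n_de, ") must split into three equal fold-change groups")
  k <- n_de / 3
  de <- data.frame(
    source = paste0("spike", seq_len(n_de)),
    group = rep(c("up4_mix1", "up1.5_mix2", "up2_mix2"), each = k),
    true_log2fc = rep(c(-log2(4), log2(1.5), log2(2)), each = k),
    is_de = TRUE
  )
  nd <- data.frame(
    source = rep(paste0("spike", n_de + seq_len(n_nonde)), each = replicate_factor),
    group = "non_de", true_log2fc = 0, is_de = FALSE
  )
  out <- rbind(de, nd)
  out$transcript <- make.unique(out$source, sep = "_rep")
  rownames(out) <- NULL
  out[, c("transcript", "source", "group", "true_log2fc", "is_de")]
}
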