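#' Proportion of p-values below a cutoff
#'
#' The empirical type I error rate at a nominal cutoff when applied to
#' null p-values. The inequality is strict: a p-value exactly at the
#' cutoff is not counted.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param cutoff nominal level (e.g. 0.01).
#' @return proportion of `p < cutoff`.
#' @export
type1_error <- function(p, cutoff) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  mean(p < cutoff)
}

#' True/false discoveries at an FDR threshold
#'
#' Applies Benjamini-Hochberg and calls genes with `q < fdr_cutoff`.
#' The empirical FDR is `FP / max(1, TP + FP)` (0 when nothing is called).
#'
#' @param p per-gene p-values.
#' @param is_de logical truth vector aligned with `p`.
#' @param fdr_cutoff q-value threshold (default 0.1).
#' @return list with `TP`, `FP`, `empirical_fdr`, `n_called`.
#' @export
power_fdr <- function(p, is_de, fdr_cutoff = 0.1) {
  if (length(p) != length(is_de)) stop("p and is_de must have the same length")
  q <- bh_fdr(p)
  called <- q < fdr_cutoff
  TP <- sum(called & is_de)
  FP <- sum(called & !is_de)
  list(TP = TP, FP = FP, empirical_fdr = FP / max(1, TP + FP),
       n_called = TP + FP)
}

#' False discovery curve
#'
#' Ranks genes by the statistic (ascending; ties broken by original
#' position) and returns, for each k up to `max_selected`, the number of
#' non-DE genes among the top k.
#'
#' @param rank_stat per-gene ranking statistic, smaller = more significant
#'   (typically p-values).
#' @param is_de logical truth vector.
#' @param max_selected length of the curve.
#' @return integer vector: cumulative false discoveries at each k.
#' @export
fd_curve <- function(rank_stat, is_de, max_selected = length(rank_stat)) {
  if (length(rank_stat) != length(is_de)) stop("length mismatch")
  max_selected <- min(max_selected, length(rank_stat))
  o <- order(rank_stat)                      # stable: ties by index
  cumsum(!is_de[o])[seq_len(max_selected)]
}

#' Run the simulation benchmark over the internal pipelines
#'
#' Repeats the count simulation `n_sims` times and runs each requested
#' method end-to-end (filter at 10 total reads, fit, moderated t for the
#' group effect), collecting type I error at the given cutoffs, true and
#' false positives at the FDR threshold, and the false discovery curve.
#' Per-simulation seeds are derived deterministically from the master
#' seed; Monte-Carlo standard errors of all averaged quantities are
#' reported so that tolerance checks can be principled.
#'
#' The `"ordinary_t"` method is the same engine with moderation disabled
#' (prior df 0) and unit weights, guaranteeing an apples-to-apples
#' comparison with the moderated pipelines.
#'
#' @param cfg a [nb_sim_config()]; its `seed` is ignored in favour of the
#'   derived per-simulation seeds.
#' @param methods subset of
#'   `c("voom", "limma_trend", "limma_notrend", "ordinary_t")`.
#' @param n_sims number of simulations.
#' @param seed master seed.
#' @param p_cutoffs nominal p-value cutoffs for type I error.
#' @param fdr_cutoff q-value threshold for power/FDR.
#' @param max_selected length of the false discovery curve.
#' @param filter_min_total total-count filter applied before analysis.
#' @return named list (one per method) of `"eval_result"` objects: lists
#'   with `method`, `n_sims`, `typeI` (matrix: mean and MC se per cutoff),
#'   `power` (mean TP), `empirical_fdr` (mean and se), `fd_curve` (mean
#'   curve), and `per_sim` (data frame of per-simulation metrics).
#' @export
run_benchmark <- function(cfg, methods = c("voom", "limma_trend",
                                           "limma_notrend", "ordinary_t"),
                          n_sims = 25, seed = 1,
                          p_cutoffs = c(0.01, 0.05), fdr_cutoff = 0.1,
                          max_selected = 500, filter_min_total = 10) {
  stopifnot(inherits(cfg, "nb_sim_config"))
  known <- c("voom", "limma_trend", "limma_notrend", "ordinary_t")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)

  res <- lapply(methods, function(m) {
    list(typeI = matrix(NA_real_, n_sims, length(p_cutoffs),
                        dimnames = list(NULL, paste0("p", p_cutoffs))),
         TP = numeric(n_sims), FP = numeric(n_sims),
         fdr = numeric(n_sims), fdc = NULL)
  })
  names(res) <- methods

  for (s in seq_len(n_sims)) {
    cfg$seed <- sim_seeds[s]
    sim <- simulate_nb_counts(cfg)
    cm <- filter_by_total(sim$counts, filter_min_total)
    truth <- sim$truth[match(rownames(cm$counts), sim$truth$gene), ]
    X <- stats::model.matrix(~sim$group)
    for (m in methods) {
      fit <- voom_lm(cm, X, method = m)
      p <- fit$eb$p[, 2]
      res[[m]]$typeI[s, ] <- vapply(p_cutoffs, function(ct) type1_error(p, ct),
                                    numeric(1))
      pf <- power_fdr(p, truth$is_de, fdr_cutoff)
      res[[m]]$TP[s] <- pf$TP; res[[m]]$FP[s] <- pf$FP
      res[[m]]$fdr[s] <- pf$empirical_fdr
      fdc <- fd_curve(p, truth$is_de, max_selected)
      if (length(fdc) < max_selected)
        fdc <- c(fdc, rep(utils::tail(fdc, 1), max_selected - length(fdc)))
      res[[m]]$fdc <- if (is.null(res[[m]]$fdc)) fdc / n_sims
                      else res[[m]]$fdc + fdc / n_sims
    }
  }

  mcse <- function(x) stats::sd(x) / sqrt(length(x))
  out <- lapply(methods, function(m) {
    r <- res[[m]]
    structure(list(
      method = m, n_sims = n_sims,
      typeI = rbind(mean = colMeans(r$typeI), se = apply(r$typeI, 2, mcse)),
      power = mean(r$TP),
      empirical_fdr = c(mean = mean(r$fdr), se = mcse(r$fdr)),
      fd_curve = r$fdc,
      per_sim = data.frame(sim = seq_len(n_sims), TP = r$TP, FP = r$FP,
                           fdr = r$fdr, r$typeI)
    ), class = "eval_result")
  })
  names(out) <- methods
  out
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: %s, %d simulations\n", x$method, x$n_sims))
  cat("type I error (mean +/- MC se):\n")
  for (j in colnames(x$typeI))
    cat(sprintf("  %s: %.5f +/- %.5f\n", j, x$typeI["mean", j], x$typeI["se", j]))
  cat(sprintf("mean TP at FDR threshold: %.1f\n", x$power))
  cat(sprintf("empirical FDR: %.4f +/- %.4f\n",
              x$empirical_fdr["mean"], x$empirical_fdr["se"]))
  invisible(x)
}
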