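# Small fixtures built in code.

toy_cm <- function(counts, lib_sizes = NULL) {
  count_matrix(as.matrix(counts), lib_sizes = lib_sizes)
}

two_group_design <- function(n1, n2) {
  X <- cbind(1, rep(c(0, 1), c(n1, n2)))
  colnames(X) <- c("(Intercept)", "group2")
  X
}

# Dense brute-force WLS oracle: normal equations solved directly.
wls_oracle <- function(X, y, w) {
  W <- diag(w)
  V <- solve(t(X) %*% W %*% X)
  beta <- V %*% t(X) %*% W %*% y
  mu <- X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(w * (y - mu)^2) / df
  list(beta = drop(beta), cov_unscaled = V, sigma2 = sigma2)
}

# A small simulated dataset shared by several tests.
small_sim <- function(seed = 7, n_genes = 600, scenario = "power") {
  cfg <- nb_scenario(scenario, "equal", seed = seed, n_genes = n_genes,
                     n_de_per_group = if (scenario == "power") 20 else 0)
  simulate_nb_counts(cfg)
}
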