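# Shared generator for competitive-test simulations: a null two-group
# experiment whose first `m` genes share a latent factor with pairwise
# correlation rho. Returns per-gene two-sample t statistics, the residual
# matrix after removing group means, and the correlated set.
simulate_camera_case <- function(seed, rho, n_per_group = 10, N = 500, m = 20) {
  set.seed(seed)
  n <- 2 * n_per_group
  Y <- matrix(rnorm(N * n), N, n)
  if (rho > 0) {
    f <- rnorm(n)
    Y[1:m, ] <- sqrt(rho) * matrix(f, m, n, byrow = TRUE) +
      sqrt(1 - rho) * Y[1:m, ]
  }
  g1 <- seq_len(n_per_group); g2 <- n_per_group + g1
  m1 <- rowMeans(Y[, g1]); m2 <- rowMeans(Y[, g2])
  sp <- sqrt((rowSums((Y[, g1] - m1)^2) + rowSums((Y[, g2] - m2)^2)) / (n - 2))
  stats <- setNames((m2 - m1) / (sp * sqrt(2 / n_per_group)), paste0("g", 1:N))
  R <- Y
  R[, g1] <- Y[, g1] - m1
  R[, g2] <- Y[, g2] - m2
  rownames(R) <- names(stats)
  list(stats = stats, residuals = R, set = list(s = paste0("g", 1:m)))
}
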