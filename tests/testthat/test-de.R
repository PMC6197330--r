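test_that("size factors match the definitional median-of-ratios oracle", {
  # identical columns -> all 1
  m <- matrix(rpois(40, 50) + 1, 10, 4)
  m2 <- cbind(m[, 1], m[, 1])
  colnames(m2) <- c("a", "b")
  expect_equal(unname(size_factors(m2)), c(1, 1))
  # exact doubling -> (1/sqrt(2), sqrt(2))
  m3 <- cbind(a = m[, 1], b = 2 * m[, 1])
  expect_equal(unname(size_factors(m3)), c(1 / sqrt(2), sqrt(2)))
  # random NB matrices agree with the direct computation
  set.seed(5)
  for (i in 1:5) {
    r <- matrix(rnbinom(200, mu = 100, size = 10), 20, 10)
    expect_equal(unname(size_factors(r)), unname(size_factors_direct(r)),
                 tolerance = 1e-12)
  }
  # gene-order invariance and one-sample-scaling equivariance
  r <- matrix(rnbinom(200, mu = 100, size = 10), 20, 10)
  expect_equal(size_factors(r), size_factors(r[sample(20), ]))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)), "pseudo_reference")
})

test_that("size factors are proportional to an independent reference", {
  skip_if_not_installed("DESeq2")
  set.seed(12)
  # odd number of reference genes so the linear- and log-space medians agree
  m <- matrix(rnbinom(610, mu = 80, size = 8), 61, 10)
  colnames(m) <- sprintf("s%02d", 1:10)
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # same factors up to the geometric-mean-1 rescaling convention
  expect_equal(unname(ours / ref), rep(mean(ours / ref), 10), tolerance = 1e-10)
})

test_that("dispersion estimation recovers truth and handles Poisson data", {
  X <- model.matrix(~ rep(0:1, each = 5))
  # Poisson data at high mean: median estimate near zero
  set.seed(1)
  pois <- matrix(rpois(500 * 10, 200), 500, 10)
  d <- estimate_dispersions(pois, X)
  expect_lte(median(d$alpha), 0.01)
  # alpha = 0.1 at n = 10/group
  nb <- matrix(rnbinom(500 * 20, mu = 200, size = 10), 500, 20)
  X2 <- model.matrix(~ rep(0:1, each = 10))
  d2 <- estimate_dispersions(nb, X2)
  expect_gte(median(d2$alpha), 0.05)
  expect_lte(median(d2$alpha), 0.2)
  # constant counts within cells: gene MoM 0, final at shrunk floor > 0
  const <- matrix(100, 5, 10)
  d3 <- estimate_dispersions(rbind(const, nb[1:20, 1:10]), X)
  expect_equal(unname(d3$alpha_mom[1:5]), rep(0, 5))
  expect_true(all(d3$alpha[1:5] > 0))
  # all-zero genes are flagged
  z <- rbind(0, nb[1:20, 1:10])
  dz <- estimate_dispersions(z, X)
  expect_true(dz$flagged[1])
  expect_true(is.na(dz$alpha[1]))
})

test_that("NB GLM closed forms and the Poisson reduction hold", {
  f <- fit_nb_glm(c(10, 10, 10, 10), matrix(1, 4, 1), 0, 0)
  expect_equal(unname(f$coef_log2), log2(10))
  expect_equal(unname(f$mu), rep(10, 4))
  X <- cbind(1, rep(0:1, each = 3))
  f2 <- fit_nb_glm(c(10, 10, 10, 20, 20, 20), X, 0, 0)
  expect_equal(unname(f2$coef_log2[2]), 1)
  # alpha = 0 equals an independent Poisson GLM fit
  set.seed(2)
  y <- rpois(6, c(10, 10, 10, 30, 30, 30))
  ref <- glm(y ~ X[, 2], family = poisson())
  f3 <- fit_nb_glm(y, X, 0, 0)
  expect_equal(unname(f3$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(f3$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  # optimality probe: optimum beats random perturbations
  f4 <- fit_nb_glm(y, X, 0, 0.1)
  ll_at <- function(b) sum(dnbinom(y, size = 10, mu = exp(drop(X %*% b)),
                                   log = TRUE))
  set.seed(3)
  pert <- replicate(100, ll_at(f4$beta + rnorm(2, 0, 0.05)))
  expect_true(all(pert <= f4$loglik + 1e-10))
  expect_error(fit_nb_glm(y, cbind(X, X[, 2]), 0, 0), "full rank")
})

test_that("LRT is zero for identical models and calibrated under the null", {
  X <- cbind(1, rep(0:1, each = 3))
  y <- c(12, 9, 11, 10, 13, 8)
  full <- fit_nb_glm(y, X, 0, 0.05)
  same <- fit_nb_glm(y, X, 0, 0.05)
  # full = reduced columnspace is rejected as non-nested; drop a column instead
  red <- fit_nb_glm(y, X[, 1, drop = FALSE], 0, 0.05)
  lr <- nb_lrt(full, red)
  expect_gte(lr$stat, 0)
  expect_equal(lr$df, 1)
  expect_error(nb_lrt(red, full), "nested")
  expect_error(nb_lrt(full, fit_nb_glm(y, X[, 1, drop = FALSE], 0, 0.2)),
               "dispersions")
  # stat and p match an independent generic-optimizer refit
  set.seed(4)
  for (i in 1:10) {
    yy <- rnbinom(6, mu = exp(1 + 0.5 * X[, 2]) * 20, size = 20)
    ff <- fit_nb_glm(yy, X, 0, 0.05)
    rr <- fit_nb_glm(yy, X[, 1, drop = FALSE], 0, 0.05)
    nll <- function(b, M) -sum(dnbinom(yy, size = 20,
                                       mu = exp(drop(M %*% b)), log = TRUE))
    of <- optim(c(log(mean(yy)), 0), nll, M = X, method = "BFGS")
    or <- optimize(function(b) nll(b, X[, 1, drop = FALSE]), c(-5, 15))
    stat_ref <- 2 * (or$objective - of$value)
    expect_equal(nb_lrt(ff, rr)$stat, stat_ref, tolerance = 1e-4)
  }
})

test_that("null interaction p-values are approximately uniform", {
  design <- design_cross_model(n_per_cell = 2)
  truth <- simulate_gene_truth(sprintf("g%04d", 1:400), seed = 31)
  cm <- simulate_counts(design, truth, seed = 32)
  res <- nb_de(cm$exonic, design,
               ~ phenotype + mutated_gene + time + phenotype:mutated_gene,
               reduced = ~ phenotype + mutated_gene + time)
  p <- res$pvalue[!is.na(res$pvalue)]
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("Wald test agrees with LRT at large n and recovers effect signs", {
  set.seed(6)
  n <- 200
  X <- cbind(1, rep(0:1, each = n / 2))
  y <- rnbinom(n, mu = exp(3 + 0.4 * X[, 2]), size = 20)
  f <- fit_nb_glm(y, X, 0, 0.05)
  r <- fit_nb_glm(y, X[, 1, drop = FALSE], 0, 0.05)
  w <- nb_wald(f, 2)
  lr <- nb_lrt(f, r)
  expect_equal(unname(w$stat)^2, lr$stat, tolerance = 0.05)
  # identity contrast of a zero coefficient -> p near 1
  y0 <- rep(c(20, 21, 19, 20), 5)
  f0 <- fit_nb_glm(y0, cbind(1, rep(0:1, 10)), 0, 0)
  expect_gt(nb_wald(f0, 2)$pvalue, 0.5)
  # planted strong effects: sign recovered in >= 99% of genes
  design <- design_two_group(3)
  truth <- simulate_gene_truth(sprintf("g%04d", 1:500), seed = 41,
                               prop_txn = 1, lfc_txn = 1, dispersion = 0.02)
  cm <- simulate_counts(design, truth, seed = 42)
  res <- nb_de(cm$exonic, design, ~genotype)
  strong <- truth$base_mean > 100
  expect_gte(mean(sign(res$log2FC[strong]) == sign(truth$delta_txn[strong])),
             0.99)
})

test_that("BH adjustment equals the textbook step-up and passes NAs through", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.37), 0.37)
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(5:200, 1))
    expect_equal(adjust_bh(p), bh_textbook(p), tolerance = 1e-14)
  }
  p <- c(0.01, NA, 0.5)
  a <- adjust_bh(p)
  expect_true(is.na(a[2]))
  expect_equal(a[c(1, 3)], bh_textbook(p[c(1, 3)]))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DE calling applies both the FDR and fold-change gates", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2FC = c(0.3, 2, -0.5, 0.1),
                    padj = c(0.005, 0.02, 0.001, 0.001))
  calls <- call_de(res, alpha = 0.01, lfc_min = 0.25)
  expect_equal(calls$up, "a")      # passes both gates
  expect_equal(calls$down, "c")    # b fails padj, d fails lfc
  expect_length(intersect(calls$up, calls$down), 0)
})
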