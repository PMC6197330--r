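test_that("panel transforms are exact, monotone and variance-stabilizing", {
  expect_equal(transform_panel(matrix(c(1, 2, 4), 1), "log2"),
               matrix(c(0, 1, 2), 1))
  expect_error(transform_panel(matrix(c(-1, 2), 1), "log2"), "glog")
  # glog -> log2 for x >> lambda
  x <- matrix(10^seq(4, 6, length.out = 10), 1)
  g <- transform_panel(x, "glog", lambda = 1)
  expect_lt(max(abs(g - log2(x)) / abs(log2(x))), 1e-6)
  # monotone
  xs <- matrix(sort(runif(100, 0, 50)), 1)
  expect_true(all(diff(drop(transform_panel(xs, "glog", lambda = 5))) > 0))
  # variance stabilization on mean-dependent noise across a 10-fold range
  set.seed(11)
  mu <- rep(c(20, 60, 200), each = 40)
  raw <- t(sapply(mu, function(m) rnorm(20, m, 0.3 * m)))
  raw[raw < 0] <- 0
  v_raw <- tapply(apply(raw, 1, var), mu, median)
  gl <- transform_panel(raw, "glog")
  v_gl <- tapply(apply(gl, 1, var), mu, median)
  expect_gt(max(v_raw) / min(v_raw), 10)
  expect_lt(max(v_gl) / min(v_gl), 3)
})

test_that("interaction linear model recovers closed-form cell means", {
  design <- design_metabolite(1)  # rows: wt CTR, wt DEX, mut CTR, mut DEX
  additive <- matrix(c(10, 12, 11, 13), 1, 4,
                     dimnames = list("m1", design$sample_id))
  f <- fit_interaction_lm(additive, design)
  expect_equal(f$beta_interaction, 0)
  withint <- matrix(c(10, 12, 11, 15), 1, 4,
                    dimnames = list("m1", design$sample_id))
  f2 <- fit_interaction_lm(withint, design)
  expect_equal(f2$beta_interaction, 2)
  # label-swap: interaction coefficient flips sign when one factor is relabeled
  design_sw <- design
  design_sw$treatment <- ifelse(design$treatment == "CTR", "DEX", "CTR")
  f3 <- fit_interaction_lm(withint, design_sw)
  expect_equal(f3$beta_interaction, -2)
})

test_that("interaction p-values are calibrated under the null", {
  design <- design_metabolite(5)
  truth <- simulate_metabolite_truth(sprintf("m%03d", 1:500), seed = 13,
                                     sigma = 0.2)
  panel <- simulate_metabolites(design, truth, seed = 14)
  fits <- fit_interaction_lm(log2(panel), design)
  p <- fits$interaction_pvalue
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
})

test_that("PCA scores separate planted clusters and reconstruct the input", {
  set.seed(15)
  base <- rnorm(30, 10)
  panel <- sapply(1:12, function(j) base + rnorm(30, 0, 0.05))
  panel[1:10, 7:12] <- panel[1:10, 7:12] + 3  # group shift along 10 features
  rownames(panel) <- sprintf("f%02d", 1:30)
  colnames(panel) <- sprintf("s%02d", 1:12)
  p <- pca_scores(panel)
  expect_gt(p$var_explained[1], 0.9)
  expect_gt(min(p$scores[7:12, 1]) - max(p$scores[1:6, 1]), 0)
  # reconstruction from all PCs equals the centered input
  centered <- scale(t(panel), scale = FALSE)
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - centered)), 1e-10)
  # scores orthogonal, loadings orthonormal
  expect_lt(max(abs(crossprod(p$scores) - diag(diag(crossprod(p$scores))))),
            1e-8)
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # isometry under orthogonal rotation of the feature space
  Q <- qr.Q(qr(matrix(rnorm(900), 30)))
  p2 <- pca_scores(t(t(panel) %*% t(Q)))
  expect_equal(as.numeric(dist(p2$scores)), as.numeric(dist(p$scores)),
               tolerance = 1e-8)
})

test_that("the mixed model matches the paired-differences oracle exactly", {
  truth <- simulate_patient_truth("m1", seed = 1, sigma_b = 0.5,
                                  sigma_e = 0.2, beta_treatment = 0.5)
  pan <- simulate_patients(5, truth, seed = 21)
  f <- fit_patient_lmm(pan)
  d <- pan$log2_value[pan$treatment == "Off"] -
    pan$log2_value[pan$treatment == "On"]
  n <- length(d)
  expect_equal(f$treatment_effect[["estimate"]], mean(d), tolerance = 1e-6)
  # ML variance convention: SE = sqrt(sum((d - mean)^2) / n^2)
  expect_equal(f$treatment_effect[["SE"]],
               sqrt(sum((d - mean(d))^2) / n^2), tolerance = 1e-6)
})

test_that("the mixed model reproduces an independent ML reference fit", {
  skip_if_not_installed("lme4")
  truth <- simulate_patient_truth("m1", seed = 1, sigma_b = 0.7, sigma_e = 0.3)
  pan <- simulate_patients(8, truth, seed = 22)
  f <- fit_patient_lmm(pan)
  pan$treatment <- factor(pan$treatment, levels = c("On", "Off"))  # match coding
  ref <- lme4::lmer(log2_value ~ age + treatment + (1 | patient_id),
                    data = pan, REML = FALSE)
  expect_equal(f$full$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(f$full$beta),
               unname(lme4::fixef(ref)[c("(Intercept)", "age", "treatmentOff")]),
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(f$full$sigma_b2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(f$full$sigma_e2, vc$vcov[2], tolerance = 1e-4)
})

test_that("variance components are recovered and the boundary case works", {
  truth <- simulate_patient_truth("m1", seed = 1, sigma_b = 1, sigma_e = 0.5)
  pan <- simulate_patients(200, truth, seed = 23)
  f <- fit_patient_lmm(pan)
  expect_lt(abs(sqrt(f$full$sigma_b2) - 1), 0.15)
  expect_lt(abs(sqrt(f$full$sigma_e2) - 0.5), 0.075)
  # boundary case: patient means made exactly equal, so the between-patient
  # variance component must be estimated at zero
  set.seed(1)
  n <- 50
  e <- rnorm(n)
  p0 <- data.frame(patient_id = rep(sprintf("P%02d", 1:n), each = 2),
                   age = rep(runif(n, 6, 16), each = 2),
                   treatment = rep(c("On", "Off"), n),
                   log2_value = as.vector(rbind(e, -e)))
  f0 <- fit_patient_lmm(p0)
  tot <- f0$full$sigma_b2 + f0$full$sigma_e2
  expect_lt(f0$full$sigma_b2 / tot, 1e-6)
})

test_that("the treatment LRT is calibrated under the null and has power", {
  # null: no treatment effect; calibration of the chi-squared reference is an
  # asymptotic property, checked at a patient count where it should hold
  truth <- simulate_patient_truth(sprintf("m%03d", 1:300), seed = 1,
                                  beta_treatment = 0, sigma_b = 0.5,
                                  sigma_e = 0.3)
  pan <- simulate_patients(40, truth, seed = 25)
  p_null <- vapply(split(pan, pan$metabolite),
                   function(d) fit_patient_lmm(d)$lrt$pvalue, 0)
  expect_gt(ks.test(p_null, "punif")$p.value, 0.01)
  # power against a treatment effect of twice the residual SD at the study's
  # size (5 patients x 2 states)
  truth2 <- simulate_metabolite_power_truth <-
    simulate_patient_truth(sprintf("m%03d", 1:200), seed = 2,
                           beta_treatment = 0.6, sigma_b = 0.5,
                           sigma_e = 0.3)
  pan2 <- simulate_patients(5, truth2, seed = 26)
  p_alt <- vapply(split(pan2, pan2$metabolite),
                  function(d) fit_patient_lmm(d)$lrt$pvalue, 0)
  expect_gte(mean(p_alt < 0.05), 0.5)
  # degenerate requests fail loudly
  one <- pan[pan$metabolite == "m001" & pan$treatment == "On", ]
  expect_error(fit_patient_lmm(one), "single state")
  expect_error(lmm_lrt(structure(list(method = "REML"), class = "lmm_fit"),
                       structure(list(method = "REML"), class = "lmm_fit")),
               "ML")
})
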