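# Metabolite panel statistics: log2 / glog variance-stabilizing transforms,
# per-feature genotype x treatment interaction linear models, PCA score QC,
# and a random-intercept linear mixed model for paired patient panels fitted
# by maximum likelihood (profiled over the variance ratio) with an LRT for
# the treatment effect.

#' Transform a metabolite panel
#'
#' `log2` is the element-wise logarithm (positive values required). `glog` is
#' the generalized logarithm `log2((x + sqrt(x^2 + lambda^2)) / 2)`: ~log2(x)
#' for `x >> lambda`, ~linear near zero, monotone throughout, suitable for
#' intensity data whose variance grows with the mean.
#'
#' @param panel Features x samples numeric matrix (positive for `log2`).
#' @param method `"log2"` or `"glog"`.
#' @param lambda glog scale parameter; `NULL` estimates it as the median SD of
#'   the lowest-intensity quartile of features.
#' @return Transformed matrix with a `lambda` attribute for glog.
#' @export
transform_panel <- function(panel, method = c("log2", "glog"), lambda = NULL) {
  method <- match.arg(method)
  panel <- as.matrix(panel)
  if (method == "log2") {
    if (any(panel <= 0))
      stopf("log2 requires positive values; use method = 'glog' for data with zeros")
    return(log2(panel))
  }
  if (is.null(lambda)) {
    mu <- rowMeans(panel)
    low <- mu <= stats::quantile(mu, 0.25)
    lambda <- stats::median(apply(panel[low, , drop = FALSE], 1, stats::sd))
    if (!is.finite(lambda) || lambda <= 0) lambda <- 1
  }
  if (lambda <= 0) stopf("glog lambda must be > 0")
  out <- log2((panel + sqrt(panel^2 + lambda^2)) / 2)
  attr(out, "lambda") <- lambda
  out
}

#' Per-feature genotype x treatment interaction linear models
#'
#' Fits `value ~ genotype * treatment` by OLS for every feature of a
#' transformed panel (treatment coding, wild_type/CTR reference) and tests
#' the interaction coefficient with a t-test; BH adjustment across features.
#'
#' @param panel Transformed features x samples matrix.
#' @param design Data frame with `genotype` and `treatment` for each sample
#'   (column order of `panel`).
#' @return Data frame per feature: `feature`, `beta0`, `beta_genotype`,
#'   `beta_treatment`, `beta_interaction`, their SEs, `interaction_pvalue`,
#'   `interaction_padj`. Features with an empty design cell get NA p-values.
#' @export
fit_interaction_lm <- function(panel, design) {
  design <- canonical_design(design)
  g <- design$genotype; t <- design$treatment
  if (nlevels(droplevels(g)) < 2 || nlevels(droplevels(t)) < 2)
    stopf("design needs two genotype and two treatment levels")
  full_cells <- all(table(g, t)[1:2, 1:2] >= 1)
  X <- stats::model.matrix(~ g * t)
  XtXi <- if (full_cells) solve(crossprod(X)) else NULL
  out <- data.frame(feature = rownames(panel), beta0 = NA_real_,
                    beta_genotype = NA_real_, beta_treatment = NA_real_,
                    beta_interaction = NA_real_, SE0 = NA_real_,
                    SE_genotype = NA_real_, SE_treatment = NA_real_,
                    SE_interaction = NA_real_,
                    interaction_pvalue = NA_real_,
                    interaction_padj = NA_real_, stringsAsFactors = FALSE)
  if (!full_cells) {
    warnf("empty genotype x treatment cell: interaction not estimable")
    return(out)
  }
  df <- nrow(X) - 4L
  for (i in seq_len(nrow(panel))) {
    y <- panel[i, ]
    fit <- stats::lm.fit(X, y)
    b <- fit$coefficients
    out[i, c("beta0", "beta_genotype", "beta_treatment", "beta_interaction")] <- b
    if (df >= 1) {
      s2 <- sum(fit$residuals^2) / df
      se <- sqrt(diag(XtXi) * s2)
      out[i, c("SE0", "SE_genotype", "SE_treatment", "SE_interaction")] <- se
      tval <- b[4] / se[4]
      out$interaction_pvalue[i] <-
        if (se[4] > 0) 2 * stats::pt(-abs(tval), df) else 1
    }
  }
  out$interaction_padj <- adjust_bh(out$interaction_pvalue)
  out
}

#' PCA scores for a transformed panel
#'
#' SVD of the centered (optionally unit-scaled) samples x features matrix.
#' Sign convention: within each component the largest-magnitude loading is
#' made positive. Constant features are dropped (with a message) when scaling.
#'
#' @param panel Transformed features x samples matrix.
#' @param center,scale. Centering/scaling flags (default center only).
#' @return List with `scores` (samples x PCs), `loadings` (features x PCs),
#'   `var_explained` (proportions).
#' @export
pca_scores <- function(panel, center = TRUE, scale. = FALSE) {
  x <- t(as.matrix(panel))  # samples x features
  if (nrow(x) < 2 || ncol(x) < 2) stopf("need >= 2 samples and >= 2 features")
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      message(sprintf("pca_scores: dropping %d constant feature(s)", sum(sds == 0)))
      x <- x[, sds > 0, drop = FALSE]
    }
  }
  p <- stats::prcomp(x, center = center, scale. = scale.)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, "*")
  loadings <- sweep(p$rotation, 2, flip, "*")
  list(scores = scores, loadings = loadings,
       var_explained = p$sdev^2 / sum(p$sdev^2))
}

# Profiled ML machinery for y = X beta + b[id] + e, b ~ N(0, sb2), e ~ N(0, se2).
# Given ratio lambda = sb2/se2, V_i = I + lambda J has closed-form inverse;
# beta and se2 profile out, leaving a 1-D likelihood in lambda.
lmm_profile <- function(lambda, y, X, id) {
  n <- length(y)
  ids <- split(seq_len(n), id)
  XtVX <- matrix(0, ncol(X), ncol(X)); XtVy <- numeric(ncol(X))
  logdet <- 0
  for (rows in ids) {
    ni <- length(rows)
    Xi <- X[rows, , drop = FALSE]; yi <- y[rows]
    c1 <- lambda / (1 + lambda * ni)
    XtVX <- XtVX + crossprod(Xi) - c1 * tcrossprod(colSums(Xi))
    XtVy <- XtVy + crossprod(Xi, yi) - c1 * colSums(Xi) * sum(yi)
    logdet <- logdet + log1p(lambda * ni)
  }
  beta <- solve(XtVX, XtVy)
  rss <- 0
  for (rows in ids) {
    ri <- y[rows] - drop(X[rows, , drop = FALSE] %*% beta)
    c1 <- lambda / (1 + lambda * length(rows))
    rss <- rss + sum(ri^2) - c1 * sum(ri)^2
  }
  se2 <- rss / n
  ll <- -n / 2 * (log(2 * pi * se2) + 1) - logdet / 2
  list(loglik = ll, beta = beta, se2 = se2, sb2 = lambda * se2,
       XtVX = XtVX, lambda = lambda)
}

#' Random-intercept linear mixed model by maximum likelihood
#'
#' Fits `y ~ fixed effects + (1 | id)` by ML: the profile log-likelihood in
#' the variance ratio `sigma_b^2 / sigma_e^2` is maximized by 1-D
#' optimization (fixed effects and the residual variance have closed forms
#' given the ratio); the boundary `sigma_b^2 = 0` is allowed. ML (not REML)
#' is used so that likelihood-ratio tests between models with different fixed
#' effects are valid.
#'
#' @param y Numeric response (e.g. log2 concentration).
#' @param X Fixed-effects model matrix (full rank).
#' @param id Grouping factor (patient).
#' @return Object of class `lmm_fit`: `beta`, `se` (model-based), `sigma_b2`,
#'   `sigma_e2`, `loglik`, `method = "ML"`.
#' @export
fit_lmm <- function(y, X, id) {
  X <- as.matrix(X)
  id <- factor(id)
  if (nlevels(id) < 2) stopf("need >= 2 grouping levels")
  if (qr(X)$rank < ncol(X))
    stopf("fixed-effects matrix is rank deficient (effect confounded with the grouping structure?)")
  nper <- table(id)
  if (max(nper) < 2 && ncol(X) > 1)
    stopf("no patient has repeated observations; within-patient effects are unidentifiable")
  obj <- function(loglam) -lmm_profile(exp(loglam), y, X, id)$loglik
  opt <- stats::optimize(obj, c(-30, 15), tol = 1e-10)
  cand <- lmm_profile(exp(opt$minimum), y, X, id)
  bound <- lmm_profile(0, y, X, id)
  best <- if (bound$loglik >= cand$loglik) bound else cand
  se <- sqrt(diag(solve(best$XtVX)) * best$se2)
  structure(list(beta = stats::setNames(drop(best$beta), colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 sigma_b2 = best$sb2, sigma_e2 = best$se2,
                 loglik = best$loglik, lambda = best$lambda,
                 n = length(y), method = "ML"),
            class = "lmm_fit")
}

#' Patient-panel mixed model: y ~ age + treatment + (1 | patient)
#'
#' Convenience wrapper fitting the full model and the reduced model without
#' treatment (both by ML) and comparing them with [lmm_lrt()].
#'
#' @param data Long data frame with columns `patient_id`, `age`, `treatment`
#'   and the response.
#' @param response Response column name (default `log2_value`; set
#'   `log_transform = TRUE` to use `log2(concentration)`).
#' @param log_transform Use `log2(concentration)` as the response.
#' @return List with `full`, `reduced` (class `lmm_fit`), `lrt`
#'   (`stat`, `df`, `pvalue`) and `treatment_effect` (estimate and SE for the
#'   Off-vs-On contrast).
#' @export
fit_patient_lmm <- function(data, response = "log2_value",
                            log_transform = FALSE) {
  y <- if (log_transform) log2(data$concentration) else data[[response]]
  trt <- as.numeric(data$treatment == "Off")
  if (length(unique(trt)) < 2) stopf("treatment column has a single state")
  Xf <- cbind(`(Intercept)` = 1, age = data$age, treatmentOff = trt)
  Xr <- Xf[, 1:2, drop = FALSE]
  full <- fit_lmm(y, Xf, data$patient_id)
  reduced <- fit_lmm(y, Xr, data$patient_id)
  list(full = full, reduced = reduced, lrt = lmm_lrt(full, reduced),
       treatment_effect = c(estimate = unname(full$beta["treatmentOff"]),
                            SE = unname(full$se["treatmentOff"])))
}

#' Likelihood-ratio test between nested ML mixed-model fits
#'
#' @param full,reduced `lmm_fit` objects fitted by ML on the same data; the
#'   reduced model has fewer fixed effects.
#' @param df Degrees of freedom (default: difference in fixed-effect counts).
#' @return List with `stat` (>= 0), `df`, `pvalue` from the chi-squared upper
#'   tail.
#' @export
lmm_lrt <- function(full, reduced, df = NULL) {
  if (!inherits(full, "lmm_fit") || !inherits(reduced, "lmm_fit"))
    stopf("inputs must be lmm_fit objects")
  if (full$method != "ML" || reduced$method != "ML")
    stopf("LRT requires ML fits (REML likelihoods are not comparable across fixed effects)")
  if (length(reduced$beta) > length(full$beta))
    stopf("reduced model must not have more fixed effects than the full model")
  if (is.null(df)) df <- length(full$beta) - length(reduced$beta)
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(stat = stat, df = df,
       pvalue = if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}
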