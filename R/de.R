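# Negative-binomial GLM differential expression: median-of-ratios
# normalization, method-of-moments dispersion estimation with a 1/mu trend and
# shrinkage, IRLS fitting with log link, Wald tests on single coefficients and
# likelihood-ratio tests for nested (interaction) designs.
#
# The dispersion machinery is deliberately simpler than full Cox-Reid/MAP
# apparatus: we promise calibration and recovery, not numerically identical
# output to any particular reference tool.

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over genes (expressed in every
#' sample) of the ratio of its count to the gene's geometric mean; factors are
#' rescaled so their geometric mean is 1.
#'
#' @param counts Nonnegative genes x samples matrix.
#' @param pseudo_reference If no gene is expressed in every sample, setting
#'   this to `TRUE` falls back to a pseudo-reference built from
#'   `log(count + 0.5)`; otherwise an error is raised.
#' @return Named positive numeric vector, one per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be nonnegative")
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    if (!pseudo_reference)
      stopf("no gene has nonzero counts in all samples; rerun with pseudo_reference = TRUE")
    use <- counts + 0.5
  } else use <- counts[ok, , drop = FALSE]
  geomean <- exp(rowMeans(log(use)))
  f <- apply(use / geomean, 2, stats::median)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# Canonical reference levels for the study factors, so that model
# coefficients read "mutant vs wild-type", "DEX vs CTR", etc.
canonical_design <- function(design) {
  lev <- list(genotype = c("wild_type", "mutant"),
              phenotype = c("wild_type", "mutant"),
              treatment = c("CTR", "DEX"),
              mutated_gene = c("fdx1b", "rx3", "none"))
  for (nm in names(design)) {
    if (nm %in% names(lev) && !is.factor(design[[nm]])) {
      found <- unique(design[[nm]])
      design[[nm]] <- factor(design[[nm]],
                             levels = c(intersect(lev[[nm]], found),
                                        setdiff(found, lev[[nm]])))
    } else if (is.character(design[[nm]]) && nm != "sample_id") {
      design[[nm]] <- factor(design[[nm]])
    }
  }
  design
}

#' Estimate per-gene NB dispersions with trend shrinkage
#'
#' Gene-level method-of-moments estimates
#' `alpha_g = max(0, (s^2 - mu) / mu^2)` are computed from normalized counts
#' pooled within design cells (unique rows of the model matrix), a mean
#' dispersion trend `alpha(mu) = a0 + a1/mu` is fitted by least squares on the
#' (lightly winsorized) gene estimates, and the final estimate shrinks the
#' gene value toward the trend with weight `d / (d + prior_df)` where `d` is
#' the pooled residual degrees of freedom. The trend deliberately targets the
#' conditional *mean* of the gene estimates rather than a robust center: the
#' sampling distribution of the moment estimator is right-skewed, and a
#' median-type trend systematically under-estimates dispersion, which
#' propagates into anti-conservative tests.
#'
#' @param counts Genes x samples integer matrix.
#' @param design_matrix Model matrix (samples x coefficients); its unique rows
#'   define the cells used for the within-cell moments.
#' @param sf Size factors (default computed from `counts`).
#' @param prior_df Shrinkage prior degrees of freedom (default 20).
#' @param alpha_min Lower floor for the returned dispersions.
#' @return List with `alpha` (final, named), `alpha_mom` (gene-level),
#'   `trend` (fitted values), `base_mean`, and logical `flagged` for genes
#'   with no information (all-zero).
#' @export
estimate_dispersions <- function(counts, design_matrix, sf = NULL,
                                 prior_df = 20, alpha_min = 1e-8) {
  counts <- as.matrix(counts)
  if (is.null(sf)) sf <- size_factors(counts, pseudo_reference = TRUE)
  q <- sweep(counts, 2, sf, "/")
  cell <- match(apply(design_matrix, 1, paste, collapse = "\r"),
                unique(apply(design_matrix, 1, paste, collapse = "\r")))
  ncell <- length(unique(cell))
  d <- ncol(counts) - ncell
  if (d < 1) stopf("need >= 1 residual degree of freedom within design cells")
  ssq <- 0
  for (cc in unique(cell)) {
    cols <- which(cell == cc)
    if (length(cols) > 1) {
      m <- rowMeans(q[, cols, drop = FALSE])
      ssq <- ssq + rowSums((q[, cols, drop = FALSE] - m)^2)
    }
  }
  s2 <- ssq / d
  base_mean <- rowMeans(q)
  flagged <- base_mean == 0
  alpha_mom <- rep(NA_real_, nrow(counts))
  alpha_mom[!flagged] <- pmax(0, (s2[!flagged] - base_mean[!flagged]) /
                                 base_mean[!flagged]^2)
  est <- which(!flagged)
  trend <- rep(NA_real_, nrow(counts))
  if (length(est) >= 10) {
    a <- alpha_mom[est]
    a <- pmin(a, stats::quantile(a, 0.995))  # guard the mean against blowups
    fit <- tryCatch(stats::lm(a ~ I(1 / base_mean[est])),
                    error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(stats::coef(fit)))) {
      trend[est] <- stats::coef(fit)[1] + stats::coef(fit)[2] / base_mean[est]
    }
  }
  if (all(is.na(trend[est])))
    trend[est] <- stats::median(alpha_mom[est], na.rm = TRUE)
  trend[est] <- pmax(trend[est], alpha_min)
  w <- d / (d + prior_df)
  alpha <- rep(NA_real_, nrow(counts))
  alpha[est] <- pmax(w * alpha_mom[est] + (1 - w) * trend[est], alpha_min)
  names(alpha) <- names(alpha_mom) <- names(trend) <- rownames(counts)
  list(alpha = alpha, alpha_mom = alpha_mom, trend = trend,
       base_mean = base_mean, flagged = flagged, df = d, weight = w)
}

nb_loglik <- function(y, mu, alpha) {
  if (alpha > 0) sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  else sum(stats::dpois(y, mu, log = TRUE))
}

#' Fit a negative-binomial GLM with log link to one gene
#'
#' Maximizes the NB log-likelihood by iteratively reweighted least squares
#' with step halving; `alpha = 0` reduces exactly to a Poisson GLM.
#' Coefficients are reported both on the natural-log scale (`beta`) and log2
#' (`coef_log2`).
#'
#' @param y Per-sample nonnegative integer counts.
#' @param X Full-rank model matrix.
#' @param offset Log-scale offsets (typically `log(size_factors)`), recycled.
#' @param alpha NB dispersion (>= 0).
#' @param tol Convergence tolerance on the coefficient step.
#' @param maxit Maximum IRLS iterations.
#' @return List with `beta`, `se`, `cov` (natural log), `coef_log2`,
#'   `se_log2`, `loglik`, `mu`, `converged`, and the inputs needed by
#'   [nb_lrt()].
#' @export
fit_nb_glm <- function(y, X, offset = 0, alpha = 0, tol = 1e-10, maxit = 100L) {
  X <- as.matrix(X)
  if (alpha < 0) stopf("alpha must be >= 0")
  if (qr(X)$rank < ncol(X)) stopf("model matrix is not full rank")
  offset <- rep_len(offset, length(y))
  if (all(y == 0)) {
    k <- ncol(X)
    return(list(beta = rep(NA_real_, k), se = rep(NA_real_, k), cov = NULL,
                coef_log2 = rep(NA_real_, k), se_log2 = rep(NA_real_, k),
                loglik = 0, mu = rep(0, length(y)), converged = FALSE,
                y = y, X = X, offset = offset, alpha = alpha))
  }
  beta <- stats::lm.fit(X, log(pmax(y, 0.5)) - offset)$coefficients
  eta <- drop(X %*% beta) + offset
  mu <- pmax(exp(eta), 1e-10)
  ll <- nb_loglik(y, mu, alpha)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      eta_try <- drop(X %*% beta_try) + offset
      mu_try <- pmax(pmin(exp(eta_try), 1e12), 1e-10)
      ll_try <- nb_loglik(y, mu_try, alpha)
      if (is.finite(ll_try) && (ll_try >= ll - 1e-12)) break
      step <- step / 2
      if (step < 1e-8) { beta_try <- beta; eta_try <- eta; mu_try <- mu
                         ll_try <- ll; break }
    }
    delta <- max(abs(beta_try - beta))
    beta <- beta_try; eta <- eta_try; mu <- mu_try
    improved <- ll_try - ll
    ll <- ll_try
    if (delta < tol * (1 + max(abs(beta))) || abs(improved) < 1e-12) {
      converged <- TRUE
      break
    }
  }
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(xtwx), error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else rep(NA_real_, ncol(X))
  list(beta = beta, se = se, cov = cov,
       coef_log2 = beta / log(2), se_log2 = se / log(2),
       loglik = ll, mu = mu, converged = converged,
       y = y, X = X, offset = offset, alpha = alpha)
}

is_nested <- function(X_full, X_reduced) {
  if (ncol(X_reduced) >= ncol(X_full)) return(FALSE)
  res <- stats::lm.fit(X_full, X_reduced)$residuals
  max(abs(res)) < 1e-8
}

#' Likelihood-ratio test between nested NB GLM fits
#'
#' @param full,reduced Fits from [fit_nb_glm()] on the same gene with the same
#'   dispersion; the reduced model matrix must span a subspace of the full one.
#' @return List with `stat` (chi-squared), `df`, `pvalue`.
#' @export
nb_lrt <- function(full, reduced) {
  if (!identical(full$y, reduced$y)) stopf("fits are not on the same counts")
  if (!isTRUE(all.equal(full$alpha, reduced$alpha)))
    stopf("fits use different dispersions")
  if (!is_nested(full$X, reduced$X)) stopf("models are not nested")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- ncol(full$X) - ncol(reduced$X)
  list(stat = stat, df = df,
       pvalue = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Wald test on one NB GLM coefficient
#'
#' @param fit A [fit_nb_glm()] result.
#' @param coef Coefficient name or index (default: last column).
#' @return List with `log2FC`, `SE` (log2), `stat` (z), `pvalue`.
#' @export
nb_wald <- function(fit, coef = NULL) {
  if (is.null(coef)) coef <- ncol(fit$X)
  if (is.character(coef)) coef <- match(coef, colnames(fit$X))
  if (is.na(coef) || coef < 1 || coef > ncol(fit$X)) stopf("unknown coefficient")
  b <- fit$beta[coef]; s <- fit$se[coef]
  z <- if (is.finite(b) && is.finite(s) && s > 0) b / s else NA_real_
  list(log2FC = b / log(2), SE = s / log(2), stat = z,
       pvalue = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; missing values are passed through unchanged and do
#' not enter the denominator.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stopf("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Call differentially expressed genes
#'
#' @param results Data frame with columns `gene_id`, `log2FC`, `padj`.
#' @param alpha FDR level (default 0.01).
#' @param lfc_min Minimum absolute log2 fold-change (default 0.25).
#' @return List with character vectors `up` and `down` (disjoint).
#' @export
call_de <- function(results, alpha = 0.01, lfc_min = 0.25) {
  sig <- !is.na(results$padj) & results$padj <= alpha
  list(up = results$gene_id[sig & results$log2FC >= lfc_min],
       down = results$gene_id[sig & results$log2FC <= -lfc_min])
}

#' Negative-binomial differential expression over a count matrix
#'
#' Per-gene NB GLM fits with either a Wald test on one coefficient or a
#' likelihood-ratio test of a full against a reduced formula (e.g. the
#' cross-model interaction
#' `~ phenotype + mutated_gene + time + phenotype:mutated_gene` against the
#' same formula without the interaction).
#'
#' @param counts Genes x samples integer matrix.
#' @param design Data frame of per-sample factors; character columns are
#'   converted to factors with study-canonical reference levels (wild_type,
#'   CTR, fdx1b).
#' @param full Full-model formula over `design` columns.
#' @param reduced Reduced-model formula; supplying it selects the LRT.
#' @param coef Coefficient (name or index) for the Wald test; default last.
#' @param sf Size factors; computed from `counts` when `NULL`.
#' @param dispersions Per-gene dispersions; estimated via
#'   [estimate_dispersions()] when `NULL`.
#' @param min_count Genes with mean normalized count below this are not tested
#'   (default 0: test everything non-degenerate).
#' @return A data frame (one row per gene): `gene_id`, `baseMean`, `log2FC`,
#'   `SE`, `stat`, `pvalue`, `padj`, `dispersion`, `converged`. For the LRT,
#'   `log2FC`/`SE` refer to the (single) dropped coefficient when the test has
#'   one degree of freedom.
#' @export
nb_de <- function(counts, design, full, reduced = NULL, coef = NULL,
                  sf = NULL, dispersions = NULL, min_count = 0) {
  counts <- as.matrix(counts)
  design <- canonical_design(design)
  X <- stats::model.matrix(full, design)
  if (qr(X)$rank < ncol(X)) stopf("full model matrix is not full rank")
  Xr <- if (!is.null(reduced)) stats::model.matrix(reduced, design) else NULL
  if (!is.null(Xr) && !is_nested(X, Xr)) stopf("reduced model is not nested in the full model")
  if (is.null(sf)) sf <- size_factors(counts, pseudo_reference = TRUE)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, X, sf)$alpha
  } else dispersions <- rep_len(dispersions, nrow(counts))
  offset <- log(sf)
  base_mean <- rowMeans(sweep(counts, 2, sf, "/"))
  test_coef <- coef
  if (!is.null(Xr) && ncol(X) - ncol(Xr) == 1L && is.null(test_coef)) {
    # report the dropped coefficient's effect size alongside the LRT
    dropped <- setdiff(colnames(X), colnames(Xr))
    test_coef <- if (length(dropped) == 1L) dropped else ncol(X)
  }
  if (is.null(test_coef)) test_coef <- ncol(X)
  n_g <- nrow(counts)
  out <- data.frame(gene_id = rownames(counts), baseMean = base_mean,
                    log2FC = NA_real_, SE = NA_real_, stat = NA_real_,
                    pvalue = NA_real_, padj = NA_real_,
                    dispersion = as.numeric(dispersions),
                    converged = FALSE, stringsAsFactors = FALSE)
  testable <- base_mean > min_count & !is.na(dispersions)
  for (g in which(testable)) {
    fit <- fit_nb_glm(counts[g, ], X, offset, dispersions[g])
    if (!fit$converged || anyNA(fit$se)) next
    out$converged[g] <- TRUE
    w <- nb_wald(fit, test_coef)
    out$log2FC[g] <- w$log2FC; out$SE[g] <- w$SE
    if (is.null(Xr)) {
      out$stat[g] <- w$stat; out$pvalue[g] <- w$pvalue
    } else {
      rfit <- fit_nb_glm(counts[g, ], Xr, offset, dispersions[g])
      if (!rfit$converged) { out$converged[g] <- FALSE; next }
      lr <- nb_lrt(fit, rfit)
      out$stat[g] <- lr$stat; out$pvalue[g] <- lr$pvalue
    }
  }
  out$padj <- adjust_bh(out$pvalue)
  rownames(out) <- NULL
  out
}
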