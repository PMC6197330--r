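# Competitive gene-set enrichment with inter-gene-correlation correction.
# The competitive test asks whether a set's per-gene statistics differ from
# the remaining genes'; because co-regulated genes are correlated, the naive
# two-sample variance is too small, and the set term is inflated by
# VIF = 1 + (m - 1) * rho, with rho the mean pairwise correlation of the
# set genes' residuals.

#' Read a GMT gene-set file
#'
#' Parsing is delegated to `fgsea::gmtPathways`.
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write gene sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

# Mean pairwise correlation (across samples) of the given rows of a
# residual matrix. Rows with zero variance are dropped.
mean_intergene_cor <- function(residuals, rows) {
  R <- residuals[rows, , drop = FALSE]
  R <- R - rowMeans(R)
  sd <- sqrt(rowSums(R^2))
  keep <- sd > 0
  R <- R[keep, , drop = FALSE] / sd[keep]
  m <- nrow(R)
  if (m < 2) return(NA_real_)
  cc <- tcrossprod(R)
  (sum(cc) - m) / (m * (m - 1))
}

#' Competitive gene-set test with variance-inflation correction
#'
#' For each set, the mean of the set genes' statistics is compared with the
#' mean of the remaining genes by a two-sample t-test whose set-term variance
#' is inflated by `VIF = 1 + (m - 1) * rho`, where `rho` is the mean pairwise
#' inter-gene correlation estimated from the supplied residual matrix
#' (model residuals, not raw counts). With `rho = 0` the test reduces exactly
#' to the uncorrected two-sample comparison.
#'
#' @param stats Named numeric vector of per-gene (moderated) statistics; the
#'   names are the gene universe.
#' @param sets Named list of character vectors (gene ids); members outside the
#'   universe are dropped (logged in `n_dropped`).
#' @param residuals Optional genes x samples residual matrix (rownames
#'   matching the universe) used to estimate `rho`. When absent, `inter_gene_cor`
#'   is used for every set.
#' @param inter_gene_cor Fixed correlation used when residuals are not
#'   supplied, or the floor used when a set's correlation is non-estimable
#'   (default 0.01).
#' @param min_size Sets smaller than this after intersection are skipped
#'   (default 5).
#' @param use_vif Set to `FALSE` for the uncorrected test (diagnostics only).
#' @return Data frame: `set`, `n_genes`, `n_dropped`, `correlation`, `vif`,
#'   `direction` (`Up`/`Down`), `stat`, `pvalue`, `padj`.
#' @export
camera_test <- function(stats, sets, residuals = NULL, inter_gene_cor = 0.01,
                        min_size = 5L, use_vif = TRUE) {
  if (is.null(names(stats))) stopf("`stats` must be named by gene id")
  if (any(!is.finite(stats))) stopf("`stats` must be finite")
  universe <- names(stats)
  N <- length(universe)
  if (!is.null(residuals) && !all(universe %in% rownames(residuals)))
    stopf("residual matrix does not cover the statistic universe")
  rows <- lapply(sets, function(s) which(universe %in% s))
  res <- lapply(names(sets), function(nm) {
    idx <- rows[[nm]]
    m <- length(idx)
    dropped <- length(unique(sets[[nm]])) - m
    if (m < min_size || N - m < 2) return(NULL)
    rho <- if (!is.null(residuals))
      mean_intergene_cor(residuals, universe[idx]) else NA_real_
    if (is.na(rho)) rho <- inter_gene_cor
    vif <- if (use_vif) max(1 + (m - 1) * rho, 0.1) else 1
    delta <- mean(stats[idx]) - mean(stats[-idx])
    df <- N - 2L
    s2 <- ((m - 1) * stats::var(stats[idx]) +
           (N - m - 1) * stats::var(stats[-idx])) / df
    se <- sqrt(s2 * (vif / m + 1 / (N - m)))
    tval <- delta / se
    data.frame(set = nm, n_genes = m, n_dropped = dropped, correlation = rho,
               vif = vif, direction = if (delta >= 0) "Up" else "Down",
               stat = tval, pvalue = 2 * stats::pt(-abs(tval), df),
               stringsAsFactors = FALSE)
  })
  skipped <- names(sets)[vapply(res, is.null, TRUE)]
  if (length(skipped))
    message(sprintf("camera_test: skipped %d set(s) below min_size: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out)) return(out)
  out$padj <- adjust_bh(out$pvalue)
  rownames(out) <- NULL
  out
}

#' Barcode-plot data for one gene set
#'
#' Genes are ranked by statistic from largest to smallest (ties broken by
#' gene-id order, deterministically); the set members' positions are the
#' barcode, and a smoothed relative density of member positions is the
#' enrichment "worm" (1 = no enrichment).
#'
#' @param stats Named numeric vector of per-gene statistics.
#' @param set Character vector of member gene ids (non-empty after
#'   intersection with the universe).
#' @param n_bins Number of evaluation points for the enrichment curve.
#' @return List with `positions` (sorted ranks in `[1, N]`), `n_universe`,
#'   `curve` (data frame `position`, `enrichment`).
#' @export
barcode_data <- function(stats, set, n_bins = 50L) {
  if (is.null(names(stats))) stopf("`stats` must be named by gene id")
  ord <- order(stats, names(stats), decreasing = c(TRUE, FALSE), method = "radix")
  ranked <- names(stats)[ord]
  pos <- sort(which(ranked %in% set))
  if (!length(pos)) stopf("empty gene set (no member in the universe)")
  N <- length(stats)
  centers <- seq(0.5, N + 0.5, length.out = n_bins + 1L)
  centers <- (centers[-1] + centers[-length(centers)]) / 2
  h <- max(N / n_bins, N / 20)  # smoothing half-width
  all_pos <- seq_len(N)
  dens <- vapply(centers, function(ct) {
    w_set <- sum(pmax(1 - abs(pos - ct) / h, 0))      # triangular kernel
    w_all <- sum(pmax(1 - abs(all_pos - ct) / h, 0))  # exact discrete norm
    w_set / w_all
  }, 0)
  expected <- length(pos) / N
  data_curve <- data.frame(position = centers, enrichment = dens / expected)
  list(positions = pos, n_universe = N, curve = data_curve)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing an overlap of at least `overlap` between a set of
#' size `set1_size` and a draw of `set2_size` from a universe of
#' `universe_size`.
#'
#' @param universe_size,set1_size,set2_size,overlap Integer sizes with
#'   `overlap <= min(set1_size, set2_size)` and both sets within the universe.
#' @return List with `pvalue` = P(X >= overlap) and `expected` overlap.
#' @export
hypergeom_overlap <- function(universe_size, set1_size, set2_size, overlap) {
  for (v in c("universe_size", "set1_size", "set2_size", "overlap"))
    check_scalar_number(get(v), v, lower = 0)
  if (set1_size > universe_size || set2_size > universe_size ||
      overlap > min(set1_size, set2_size))
    stopf("inconsistent sizes: need overlap <= min(K, n) and K, n <= N")
  p <- stats::phyper(overlap - 1, set1_size, universe_size - set1_size,
                     set2_size, lower.tail = FALSE)
  list(pvalue = p, expected = set2_size * set1_size / universe_size)
}
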