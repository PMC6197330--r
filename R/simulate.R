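# Synthetic data with known ground truth. The generators emit the statistical
# structure the downstream analyses assume: negative-binomial exonic and
# intronic counts sharing a transcriptional effect, with post-transcriptional
# effects applied to exonic counts only; log-normal metabolite concentrations
# with a genotype x treatment interaction; and paired patient panels with a
# per-patient random baseline.
#
# NB parameterization (used everywhere in this package):
#   variance = mu + alpha * mu^2, alpha >= 0 (alpha = 0 is the Poisson limit).

#' Build a two-group sample design table
#'
#' Defaults mirror a typical mutant-vs-sibling larval RNA-seq layout:
#' 3 biological replicates per genotype.
#'
#' @param n_per_group Replicates per genotype.
#' @param mutated_gene Label of the mutated gene for the mutant cohort.
#' @param time Time label applied to all samples.
#' @return A data frame with columns `sample_id`, `genotype`
#'   (`wild_type`/`mutant`), `treatment`, `mutated_gene`, `time`, `replicate`.
#' @export
design_two_group <- function(n_per_group = 3L, mutated_gene = "fdx1b",
                             time = "t0") {
  genotype <- rep(c("wild_type", "mutant"), each = n_per_group)
  data.frame(
    sample_id = sprintf("%s_%s_r%d", mutated_gene, c("wt", "mut")[
      rep(1:2, each = n_per_group)], rep(seq_len(n_per_group), 2L)),
    genotype = genotype, treatment = "CTR",
    mutated_gene = mutated_gene, time = time,
    replicate = rep(seq_len(n_per_group), 2L), stringsAsFactors = FALSE)
}

#' Build the cross-model interaction design
#'
#' Two mutant lines, each with wild-type-like and mutant phenotypes, sampled
#' at multiple times with replicates; the substrate for the
#' `~ phenotype + mutated_gene + time + phenotype:mutated_gene` model.
#'
#' @param lines Mutant line labels.
#' @param times Time level labels.
#' @param n_per_cell Replicates per line x phenotype x time cell.
#' @return A design data frame (one row per sample) with a `phenotype` column
#'   (`wild_type`/`mutant`) in addition to the two-group columns.
#' @export
design_cross_model <- function(lines = c("fdx1b", "rx3"),
                               times = c("ZT01", "ZT13"), n_per_cell = 3L) {
  g <- expand.grid(replicate = seq_len(n_per_cell),
                   phenotype = c("wild_type", "mutant"),
                   time = times, mutated_gene = lines,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$genotype <- g$phenotype
  g$treatment <- "CTR"
  g$sample_id <- sprintf("%s_%s_%s_r%d", g$mutated_gene,
                         c(wild_type = "wt", mutant = "mut")[g$phenotype],
                         g$time, g$replicate)
  g[c("sample_id", "genotype", "phenotype", "treatment", "mutated_gene",
      "time", "replicate")]
}

#' Draw a per-gene truth table
#'
#' Encodes every planted effect: a transcriptional log2 fold-change applied to
#' both regions, a post-transcriptional log2 fold-change applied to exonic
#' counts only, a baseline exonic mean, the intronic/exonic expectation ratio
#' and the NB dispersion.
#'
#' @param gene_ids Character vector of gene ids.
#' @param seed Integer seed.
#' @param prop_txn,prop_pt Proportions of genes given transcriptional /
#'   post-transcriptional effects (disjoint sets, transcriptional first).
#' @param lfc_txn,lfc_pt Planted log2 fold-changes (scalar or vector recycled
#'   over affected genes; sign drawn at random unless `signed = FALSE`).
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of the
#'   baseline exonic mean.
#' @param dispersion Either a fixed dispersion for all genes or `NULL` to draw
#'   per-gene dispersions from lognormal(log 0.02, 0.3).
#' @param intron_fraction Intronic/exonic expected-count ratio in (0, 1].
#' @param signed If `TRUE` (default) planted effects get random signs.
#' @return A `gene_truth` data frame: `gene_id`, `base_mean`,
#'   `intron_fraction`, `dispersion`, `delta_txn`, `delta_pt`.
#' @export
simulate_gene_truth <- function(gene_ids, seed = 1L, prop_txn = 0, prop_pt = 0,
                                lfc_txn = 1, lfc_pt = 1,
                                base_mean_meanlog = log(500),
                                base_mean_sdlog = 1,
                                dispersion = NULL, intron_fraction = 0.1,
                                signed = TRUE) {
  n <- length(gene_ids)
  if (intron_fraction <= 0 || intron_fraction > 1)
    stopf("intron_fraction must be in (0, 1]")
  with_child_seed(seed, "gene_truth", {
    base_mean <- stats::rlnorm(n, base_mean_meanlog, base_mean_sdlog)
    disp <- if (is.null(dispersion)) stats::rlnorm(n, log(0.02), 0.3)
            else rep_len(dispersion, n)
    if (any(disp < 0)) stopf("dispersion must be >= 0")
    delta_txn <- delta_pt <- numeric(n)
    n_txn <- round(prop_txn * n); n_pt <- round(prop_pt * n)
    if (n_txn + n_pt > n) stopf("prop_txn + prop_pt exceed 1")
    sgn <- function(k) if (signed) sample(c(-1, 1), k, replace = TRUE) else rep(1, k)
    if (n_txn) delta_txn[seq_len(n_txn)] <- rep_len(lfc_txn, n_txn) * sgn(n_txn)
    if (n_pt) delta_pt[n_txn + seq_len(n_pt)] <- rep_len(lfc_pt, n_pt) * sgn(n_pt)
    data.frame(gene_id = gene_ids, base_mean = base_mean,
               intron_fraction = intron_fraction, dispersion = disp,
               delta_txn = delta_txn, delta_pt = delta_pt,
               stringsAsFactors = FALSE)
  })
}

rnbinom_mu <- function(n, mu, alpha) {
  # alpha = 0 is the Poisson limit
  out <- numeric(n)
  pois <- alpha == 0 | mu == 0
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois), size = 1 / alpha[!pois],
                                               mu = mu[!pois])
  out
}

#' Simulate exonic and intronic count matrices
#'
#' Exonic count for gene g in sample j is NB with mean
#' `sf_j * base_mean_g * 2^((delta_txn_g + delta_pt_g) * x_j)` and the
#' intronic count NB with mean
#' `sf_j * base_mean_g * intron_fraction_g * 2^(delta_txn_g * x_j)`, where
#' `x_j` indicates the mutant phenotype. Single-exon genes (when `models` is
#' supplied) receive intronic count 0.
#'
#' @param design A design data frame with `sample_id` and `genotype` (or
#'   `phenotype`) columns.
#' @param truth A `gene_truth` table (see [simulate_gene_truth()]). When
#'   `models` is supplied every gene of the model set must be covered.
#' @param seed Integer seed.
#' @param size_factors Per-sample positive reals (recycled; default all 1).
#' @param models Optional [gene_model_set()]; fixes the gene universe and
#'   zeroes intronic counts of single-exon genes.
#' @param extra_lfc Optional genes x samples matrix of additional log2 effects
#'   applied to both regions (used for interaction designs); default none.
#' @return A `region_count_matrix`.
#' @export
simulate_counts <- function(design, truth, seed = 1L, size_factors = 1,
                            models = NULL, extra_lfc = NULL) {
  if (!is.null(models)) {
    missing <- setdiff(models$genes$gene_id, truth$gene_id)
    if (length(missing))
      stopf("truth table misses gene(s): %s", paste(missing, collapse = ", "))
    truth <- truth[match(models$genes$gene_id, truth$gene_id), , drop = FALSE]
  }
  sf <- rep_len(size_factors, nrow(design))
  if (any(sf <= 0)) stopf("size_factors must be positive")
  pheno <- if (!is.null(design$phenotype)) design$phenotype else design$genotype
  x <- as.numeric(pheno == "mutant")
  n_g <- nrow(truth); n_s <- nrow(design)
  mu_ex <- outer(truth$base_mean, sf) *
    2^(outer(truth$delta_txn + truth$delta_pt, x))
  mu_in <- outer(truth$base_mean * truth$intron_fraction, sf) *
    2^(outer(truth$delta_txn, x))
  if (!is.null(extra_lfc)) {
    mu_ex <- mu_ex * 2^extra_lfc
    mu_in <- mu_in * 2^extra_lfc
  }
  with_child_seed(seed, "counts", {
    a <- rep(truth$dispersion, n_s)
    ex <- matrix(rnbinom_mu(n_g * n_s, as.vector(mu_ex), a), n_g, n_s)
    it <- matrix(rnbinom_mu(n_g * n_s, as.vector(mu_in), a), n_g, n_s)
    if (!is.null(models)) {
      single <- tabulate(match(models$exons$gene_id, models$genes$gene_id),
                         nbins = n_g) == 1L
      it[single, ] <- 0L
    }
    storage.mode(ex) <- "integer"
    storage.mode(it) <- "integer"
    dimnames(ex) <- dimnames(it) <- list(truth$gene_id, design$sample_id)
    region_count_matrix(ex, it)
  })
}

#' Place synthetic reads realizing a count matrix
#'
#' For each gene and sample, exactly the requested number of single-end
#' fixed-length reads is placed uniformly, fully inside the gene's exonic
#' union (exonic counts) or fully inside its intronic intervals (intronic
#' counts). Read names carry the originating gene and region as a truth tag.
#' Genes whose target region is shorter than the read length are skipped with
#' a warning and recorded in the `skipped` attribute.
#'
#' @param counts A `region_count_matrix`.
#' @param models The [gene_model_set()] the counts refer to.
#' @param read_length Read length in bp.
#' @param seed Integer seed.
#' @return Named list (per sample) of BED6-style read data frames; attribute
#'   `skipped` lists (gene, region) pairs that could not be realized.
#' @export
simulate_reads <- function(counts, models, read_length = 50L, seed = 1L) {
  stopifnot(inherits(counts, "region_count_matrix"),
            inherits(models, "gene_model_set"))
  idx <- build_region_index(models)
  region_iv <- function(gr, gid) {
    sel <- gr[gr$gene_id == gid]
    data.frame(chrom = as.character(GenomicRanges::seqnames(sel)),
               start = GenomicRanges::start(sel) - 1L,
               end = GenomicRanges::end(sel),
               strand = as.character(GenomicRanges::strand(sel)))
  }
  skipped <- list()
  with_child_seed(seed, "reads", {
    out <- lapply(seq_along(counts$sample_ids), function(j) {
      recs <- list()
      for (layer in c("exonic", "intronic")) {
        cnt <- counts[[layer]][, j]
        for (gi in which(cnt > 0L)) {
          gid <- counts$gene_ids[gi]
          iv <- region_iv(idx[[layer]], gid)
          iv <- iv[iv$end - iv$start >= read_length, , drop = FALSE]
          if (!nrow(iv)) {
            skipped[[length(skipped) + 1L]] <<- data.frame(
              gene_id = gid, region = layer, sample = counts$sample_ids[j])
            next
          }
          w <- iv$end - iv$start - read_length + 1L
          pick <- sample.int(nrow(iv), cnt[gi], replace = TRUE,
                             prob = w / sum(w))
          off <- floor(stats::runif(cnt[gi]) * w[pick])
          recs[[length(recs) + 1L]] <- data.frame(
            chrom = iv$chrom[pick], start = iv$start[pick] + off,
            end = iv$start[pick] + off + read_length,
            name = sprintf("%s|%s|%s|%d", gid, layer, counts$sample_ids[j],
                           seq_len(cnt[gi])),
            score = 0, strand = iv$strand[pick], stringsAsFactors = FALSE)
        }
      }
      if (length(recs)) do.call(rbind, recs)
      else data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), score = numeric(0),
                      strand = character(0))
    })
    names(out) <- counts$sample_ids
    if (length(skipped)) {
      sk <- unique(do.call(rbind, skipped)[c("gene_id", "region")])
      warnf("%d gene/region pair(s) shorter than the read length were skipped",
            nrow(sk))
      attr(out, "skipped") <- sk
    } else attr(out, "skipped") <- data.frame(gene_id = character(0),
                                              region = character(0))
    out
  })
}

#' Draw a per-metabolite truth table
#'
#' @param metabolites Character vector of feature names.
#' @param seed Integer seed.
#' @param beta0_range Range of baseline log2 abundances.
#' @param prop_interaction Proportion of features with a planted
#'   genotype x treatment interaction.
#' @param beta_interaction Planted interaction effect (log2).
#' @param beta_genotype,beta_treatment Planted main effects (log2) applied to
#'   all features.
#' @param sigma Residual SD on the log2 scale (>= 0).
#' @return A `metabolite_truth` data frame.
#' @export
simulate_metabolite_truth <- function(metabolites, seed = 1L,
                                      beta0_range = c(6, 12),
                                      prop_interaction = 0,
                                      beta_interaction = 1,
                                      beta_genotype = 0, beta_treatment = 0,
                                      sigma = 0.2) {
  if (sigma < 0) stopf("sigma must be >= 0")
  n <- length(metabolites)
  with_child_seed(seed, "metabolite_truth", {
    k <- round(prop_interaction * n)
    data.frame(metabolite = metabolites,
               beta0 = stats::runif(n, beta0_range[1], beta0_range[2]),
               beta_genotype = rep_len(beta_genotype, n),
               beta_treatment = rep_len(beta_treatment, n),
               beta_interaction = c(rep_len(beta_interaction, k),
                                    numeric(n - k)),
               sigma = rep_len(sigma, n), stringsAsFactors = FALSE)
  })
}

#' Build the 2 x 2 metabolite design
#'
#' @param n_per_group Samples per genotype x treatment cell (default 5,
#'   typical for targeted larval metabolite panels).
#' @return Design data frame with `sample_id`, `genotype`, `treatment`.
#' @export
design_metabolite <- function(n_per_group = 5L) {
  g <- expand.grid(replicate = seq_len(n_per_group),
                   treatment = c("CTR", "DEX"),
                   genotype = c("wild_type", "mutant"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_%s_r%d",
                         c(wild_type = "wt", mutant = "mut")[g$genotype],
                         g$treatment, g$replicate)
  g[c("sample_id", "genotype", "treatment")]
}

#' Simulate a metabolite panel
#'
#' log2 concentration = beta0 + beta_genotype*g + beta_treatment*t +
#' beta_interaction*g*t + N(0, sigma^2); the returned panel is on the natural
#' (exponentiated) scale.
#'
#' @param design Data frame with `sample_id`, `genotype`, `treatment`.
#' @param truth A `metabolite_truth` table.
#' @param seed Integer seed.
#' @return Features x samples numeric matrix of concentrations.
#' @export
simulate_metabolites <- function(design, truth, seed = 1L) {
  if (length(unique(design$genotype)) < 2 || length(unique(design$treatment)) < 2)
    stopf("design needs both genotype and both treatment levels")
  if (any(truth$sigma < 0)) stopf("sigma must be >= 0")
  g <- as.numeric(design$genotype == "mutant")
  t <- as.numeric(design$treatment == "DEX")
  with_child_seed(seed, "metabolites", {
    lp <- outer(truth$beta0, rep(1, nrow(design))) +
      outer(truth$beta_genotype, g) + outer(truth$beta_treatment, t) +
      outer(truth$beta_interaction, g * t)
    y <- lp + matrix(stats::rnorm(length(lp), 0, rep(truth$sigma, nrow(design))),
                     nrow(lp), ncol(lp))
    m <- 2^y
    dimnames(m) <- list(truth$metabolite, design$sample_id)
    m
  })
}

#' Draw a patient-panel truth table
#'
#' @param metabolites Character vector of metabolite names.
#' @param seed Integer seed.
#' @param beta0,beta_age,beta_treatment Fixed effects (log2 scale; recycled).
#' @param sigma_b Random-intercept SD (per patient), >= 0.
#' @param sigma_e Residual SD, >= 0.
#' @return A `patient_truth` data frame.
#' @export
simulate_patient_truth <- function(metabolites, seed = 1L, beta0 = 6,
                                   beta_age = 0.02, beta_treatment = 0.5,
                                   sigma_b = 0.5, sigma_e = 0.2) {
  if (any(sigma_b < 0) || any(sigma_e < 0)) stopf("SDs must be >= 0")
  n <- length(metabolites)
  data.frame(metabolite = metabolites, beta0 = rep_len(beta0, n),
             beta_age = rep_len(beta_age, n),
             beta_treatment = rep_len(beta_treatment, n),
             sigma_b = rep_len(sigma_b, n), sigma_e = rep_len(sigma_e, n),
             stringsAsFactors = FALSE)
}

#' Simulate a paired on/off-treatment patient panel
#'
#' Each patient is sampled in both treatment states (On/Off), mirroring a
#' paired interruption-of-therapy design:
#' `y = beta0 + beta_age*age + beta_treatment*trt + b_i + e`, with
#' `b_i ~ N(0, sigma_b^2)` a patient-specific baseline shift and
#' `e ~ N(0, sigma_e^2)`. `y` is the log2 concentration; the returned
#' `concentration` column is `2^y`.
#'
#' @param n_patients Number of patients (>= 2).
#' @param truth A `patient_truth` table (one row per metabolite).
#' @param ages Patient ages in years (recycled to `n_patients`).
#' @param seed Integer seed.
#' @param states Treatment states sampled for every patient; must contain at
#'   least two distinct states or the treatment effect is unidentifiable
#'   within patient.
#' @return Long data frame: `patient_id`, `age`, `treatment`, `metabolite`,
#'   `concentration`, `log2_value`.
#' @export
simulate_patients <- function(n_patients, truth, ages = NULL, seed = 1L,
                              states = c("On", "Off")) {
  check_scalar_number(n_patients, "n_patients", lower = 2)
  if (length(unique(states)) < 2)
    stopf("at least two treatment states per patient are required (the treatment effect is unidentifiable within patient otherwise)")
  if (is.null(ages)) ages <- seq(6, 16, length.out = n_patients)
  ages <- rep_len(ages, n_patients)
  with_child_seed(seed, "patients", {
    rows <- lapply(seq_len(nrow(truth)), function(m) {
      b <- stats::rnorm(n_patients, 0, truth$sigma_b[m])
      grid <- expand.grid(state = states, patient = seq_len(n_patients),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      trt <- as.numeric(grid$state == "Off")
      y <- truth$beta0[m] + truth$beta_age[m] * ages[grid$patient] +
        truth$beta_treatment[m] * trt + b[grid$patient] +
        stats::rnorm(nrow(grid), 0, truth$sigma_e[m])
      data.frame(patient_id = sprintf("P%02d", grid$patient),
                 age = ages[grid$patient], treatment = grid$state,
                 metabolite = truth$metabolite[m], concentration = 2^y,
                 log2_value = y, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
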