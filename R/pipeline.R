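# Config-driven orchestration of the synthetic end-to-end analysis:
# simulate -> count -> de -> eisa -> enrich -> metabolites -> patients.
# All cross-stage data flows through files in the output directory; a JSON
# manifest records seeds, parameters and md5 checksums of every output.

pipeline_schema <- function() list(
  seed = NULL,                       # required, integer
  outdir = NULL,                     # required, path
  stages = c("simulate", "count", "de", "eisa", "enrich", "metabolites",
             "patients"),
  log_level = "info",
  genome = list(n_genes = 200L, n_chroms = 3L),
  simulate = list(n_per_group = 3L, prop_txn = 0.05, prop_pt = 0.05,
                  lfc_txn = 1, lfc_pt = 1, dispersion = NULL,
                  intron_fraction = 0.1, base_mean_meanlog = log(500),
                  base_mean_sdlog = 1, reads = FALSE, read_length = 50L),
  de = list(alpha = 0.01, lfc_min = 0.25),
  eisa = list(fdr = 0.05, lfc = 0.25, min_intron = 8, pseudocount = 0.5),
  enrich = list(n_sets = 20L, set_size = 25L, min_size = 5L),
  metabolites = list(n_features = 40L, n_per_group = 5L,
                     prop_interaction = 0.1, beta_interaction = 1,
                     sigma = 0.2),
  patients = list(n_patients = 5L, n_metabolites = 8L, beta_treatment = 0.5,
                  sigma_b = 0.5, sigma_e = 0.2))

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys, checks value
#' ranges, and fills defaults (differential-expression thresholds default to
#' adjusted p <= 0.01 and |log2FC| >= 0.25). All violations are reported in
#' one error.
#'
#' @param config Path to a YAML file, or a list.
#' @return Normalized configuration list with every default filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  schema <- pipeline_schema()
  errs <- character(0)
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    errs <- c(errs, sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  for (sec in intersect(names(config), names(schema))) {
    if (is.list(schema[[sec]]) && length(schema[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(schema[[sec]]))
      if (length(bad))
        errs <- c(errs, sprintf("unknown key(s) in '%s': %s", sec,
                                paste(bad, collapse = ", ")))
    }
  }
  cfg <- schema
  for (sec in intersect(names(config), names(schema))) {
    if (is.list(schema[[sec]]) && length(schema[[sec]])) {
      known <- intersect(names(config[[sec]]), names(schema[[sec]]))
      cfg[[sec]][known] <- config[[sec]][known]
    } else cfg[[sec]] <- config[[sec]]
  }
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    errs <- c(errs, "an explicit integer 'seed' is required")
  if (is.null(cfg$outdir) || !is.character(cfg$outdir))
    errs <- c(errs, "'outdir' is required")
  chk <- function(val, name, lo, hi) {
    if (!is.null(val) && (!is.numeric(val) || val < lo || val > hi))
      errs <<- c(errs, sprintf("'%s' must be in [%s, %s]", name, lo, hi))
  }
  chk(cfg$de$alpha, "de.alpha", 0, 1)
  chk(cfg$de$lfc_min, "de.lfc_min", 0, Inf)
  chk(cfg$eisa$fdr, "eisa.fdr", 0, 1)
  chk(cfg$simulate$intron_fraction, "simulate.intron_fraction", 1e-12, 1)
  chk(cfg$genome$n_genes, "genome.n_genes", 1, Inf)
  chk(cfg$metabolites$sigma, "metabolites.sigma", 0, Inf)
  chk(cfg$patients$sigma_b, "patients.sigma_b", 0, Inf)
  chk(cfg$patients$sigma_e, "patients.sigma_e", 0, Inf)
  bad_stage <- setdiff(cfg$stages, pipeline_schema()$stages)
  if (length(bad_stage))
    errs <- c(errs, sprintf("unknown stage(s): %s", paste(bad_stage, collapse = ", ")))
  if (length(errs))
    stopf("invalid configuration:\n  - %s", paste(errs, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

plog <- function(cfg, stage, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the configured pipeline
#'
#' Executes the requested stages in dependency order inside `outdir`; later
#' stages read earlier stages' files, so a subset run (e.g. only `eisa`) works
#' against cached outputs. Reruns with an identical configuration are
#' bit-identical for all deterministic outputs. A JSON manifest with the
#' package version, seeds, per-stage outputs and md5 checksums is written at
#' the end (or, on stage failure, a partial manifest of the completed stages).
#'
#' @param config Path to a YAML config or a list (see [validate_config()]).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(cfg$outdir, ...)
  hdr <- sprintf("eisakit %s", as.character(utils::packageVersion("eisakit")))
  manifest <- list(tool = hdr, seed = cfg$seed, stages = list())
  done <- function(stage, files) {
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- list(
      outputs = basename(files),
      md5 = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  }
  finish <- function(status) {
    manifest$status <- status
    jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(manifest)
  }
  stage_files <- list(
    simulate = c("genome.gtf", "design.tsv", "gene_truth.tsv",
                 "counts_exonic.tsv", "counts_intronic.tsv",
                 "counts_discarded.tsv"),
    de = "de.tsv", eisa = c("eisa.tsv", "eisa_scatter.tsv"),
    enrich = c("gene_sets.gmt", "enrichment.tsv", "barcode_top_set.json"),
    metabolites = c("metabolite_truth.tsv", "metabolite_design.tsv",
                    "metabolite_panel.tsv", "metabolite_fits.tsv",
                    "pca_scores.tsv"),
    patients = c("patient_truth.tsv", "patient_panel.tsv", "patient_lmm.tsv"))

  run_stage <- function(stage) {
    t0 <- Sys.time()
    switch(stage,
      simulate = stage_simulate(cfg, path),
      count = stage_count(cfg, path),
      de = stage_de(cfg, path),
      eisa = stage_eisa(cfg, path),
      enrich = stage_enrich(cfg, path),
      metabolites = stage_metabolites(cfg, path),
      patients = stage_patients(cfg, path))
    plog(cfg, stage, "done in %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  }
  order_all <- pipeline_schema()$stages
  todo <- intersect(order_all, cfg$stages)
  # pre-flight: every stage's file inputs must exist unless produced by an
  # earlier stage of this same invocation
  needs <- list(count = c("genome.gtf", "design.tsv"),
                de = c("counts_exonic.tsv", "design.tsv"),
                eisa = c("counts_exonic.tsv", "counts_intronic.tsv", "design.tsv"),
                enrich = c("de.tsv", "gene_truth.tsv"))
  produced_by <- list(simulate = c("genome.gtf", "design.tsv", "gene_truth.tsv",
                                   "counts_exonic.tsv", "counts_intronic.tsv"),
                      de = "de.tsv")
  available <- unlist(produced_by[intersect(names(produced_by), todo)])
  missing <- character(0)
  for (stage in todo) {
    req <- setdiff(needs[[stage]], available)
    req <- req[!file.exists(path(req))]
    missing <- c(missing, req)
  }
  if (length(missing))
    stopf("pre-flight check failed; missing input file(s): %s",
          paste(unique(missing), collapse = ", "))
  for (stage in todo) {
    ok <- tryCatch({ run_stage(stage); TRUE },
                   error = function(e) { plog(cfg, stage, "FAILED: %s",
                                              conditionMessage(e)); FALSE })
    if (!ok) { finish(sprintf("failed at stage '%s'", stage))
               stopf("pipeline halted at stage '%s'", stage) }
    if (stage %in% names(stage_files)) done(stage, path(stage_files[[stage]]))
    if (stage == "count" && isTRUE(cfg$simulate$reads))
      done("count", path(c("recounts_exonic.tsv", "recounts_intronic.tsv",
                           "recounts_discarded.tsv")))
  }
  finish("ok")
}

stage_simulate <- function(cfg, path) {
  s <- cfg$simulate
  models <- generate_genome(cfg$genome$n_genes, seed = cfg$seed,
                            n_chroms = cfg$genome$n_chroms)
  write_gtf(models, path("genome.gtf"))
  design <- design_two_group(s$n_per_group)
  write_tsv(design, path("design.tsv"))
  truth <- simulate_gene_truth(models$genes$gene_id, seed = cfg$seed,
                               prop_txn = s$prop_txn, prop_pt = s$prop_pt,
                               lfc_txn = s$lfc_txn, lfc_pt = s$lfc_pt,
                               base_mean_meanlog = s$base_mean_meanlog,
                               base_mean_sdlog = s$base_mean_sdlog,
                               dispersion = s$dispersion,
                               intron_fraction = s$intron_fraction)
  write_tsv(truth, path("gene_truth.tsv"))
  counts <- simulate_counts(design, truth, seed = cfg$seed, models = models)
  write_counts_table(counts, path("counts"))
  if (isTRUE(s$reads)) {
    reads <- simulate_reads(counts, models, read_length = s$read_length,
                            seed = cfg$seed)
    dir.create(path("reads"), showWarnings = FALSE)
    for (nm in names(reads)) write_bed(reads[[nm]], path("reads", paste0(nm, ".bed")))
  }
  invisible(NULL)
}

stage_count <- function(cfg, path) {
  if (!isTRUE(cfg$simulate$reads)) return(invisible(NULL))  # counts already on disk
  models <- read_gtf(path("genome.gtf"))
  idx <- build_region_index(models)
  beds <- list.files(path("reads"), pattern = "\\.bed$", full.names = TRUE)
  sets <- stats::setNames(as.list(beds), sub("\\.bed$", "", basename(beds)))
  design <- read_tsv(path("design.tsv"))
  sets <- sets[design$sample_id]
  cm <- count_matrix(sets, idx)
  write_counts_table(cm, path("recounts"))
  invisible(NULL)
}

counts_prefix <- function(cfg, path) {
  if (isTRUE(cfg$simulate$reads) && file.exists(path("recounts_exonic.tsv")))
    path("recounts") else path("counts")
}

stage_de <- function(cfg, path) {
  counts <- read_counts_table(counts_prefix(cfg, path))
  design <- read_tsv(path("design.tsv"))
  res <- nb_de(counts$exonic, design, ~genotype)
  write_tsv(res, path("de.tsv"))
  calls <- call_de(res, alpha = cfg$de$alpha, lfc_min = cfg$de$lfc_min)
  writeLines(calls$up, path("de_up.txt"))
  writeLines(calls$down, path("de_down.txt"))
  invisible(NULL)
}

stage_eisa <- function(cfg, path) {
  counts <- read_counts_table(counts_prefix(cfg, path))
  design <- read_tsv(path("design.tsv"))
  res <- eisa_fit(counts, design, min_intron = cfg$eisa$min_intron,
                  pseudocount = cfg$eisa$pseudocount)
  res <- classify_regulation(res, fdr = cfg$eisa$fdr, lfc = cfg$eisa$lfc)
  write_tsv(res, path("eisa.tsv"))
  scatter <- res[c("gene_id", "delta_exon", "delta_intron", "delta_diff",
                   "diff_padj", "class")]
  write_tsv(scatter, path("eisa_scatter.tsv"))
  invisible(NULL)
}

stage_enrich <- function(cfg, path) {
  de <- read_tsv(path("de.tsv"))
  de <- de[!is.na(de$stat), ]
  stats_v <- stats::setNames(de$stat, de$gene_id)
  e <- cfg$enrich
  sets <- with_child_seed(cfg$seed, "gene_sets", {
    truth <- read_tsv(path("gene_truth.tsv"))
    affected <- truth$gene_id[truth$delta_txn != 0 | truth$delta_pt != 0]
    affected <- intersect(affected, names(stats_v))
    rnd <- lapply(seq_len(e$n_sets - 1L), function(i)
      sample(names(stats_v), min(e$set_size, length(stats_v))))
    names(rnd) <- sprintf("random_set_%02d", seq_along(rnd))
    c(list(planted_effect_set = if (length(affected) >= e$min_size) affected
           else sample(names(stats_v), e$set_size)), rnd)
  })
  write_gmt(sets, path("gene_sets.gmt"))
  enr <- camera_test(stats_v, sets, min_size = e$min_size)
  write_tsv(enr, path("enrichment.tsv"))
  top <- enr$set[which.min(enr$pvalue)]
  bc <- barcode_data(stats_v, sets[[top]])
  jsonlite::write_json(list(set = top, positions = bc$positions,
                            n_universe = bc$n_universe, curve = bc$curve),
                       path("barcode_top_set.json"), digits = NA)
  invisible(NULL)
}

stage_metabolites <- function(cfg, path) {
  m <- cfg$metabolites
  design <- design_metabolite(m$n_per_group)
  truth <- simulate_metabolite_truth(sprintf("met%03d", seq_len(m$n_features)),
                                     seed = cfg$seed,
                                     prop_interaction = m$prop_interaction,
                                     beta_interaction = m$beta_interaction,
                                     sigma = m$sigma)
  panel <- simulate_metabolites(design, truth, seed = cfg$seed)
  write_tsv(truth, path("metabolite_truth.tsv"))
  write_tsv(design, path("metabolite_design.tsv"))
  write_tsv(data.frame(feature = rownames(panel), panel, check.names = FALSE),
            path("metabolite_panel.tsv"))
  tp <- transform_panel(panel, "log2")
  fits <- fit_interaction_lm(tp, design)
  write_tsv(fits, path("metabolite_fits.tsv"))
  pca <- pca_scores(tp)
  write_tsv(data.frame(sample_id = rownames(pca$scores),
                       pca$scores[, 1:min(4, ncol(pca$scores)), drop = FALSE],
                       check.names = FALSE),
            path("pca_scores.tsv"))
  invisible(NULL)
}

stage_patients <- function(cfg, path) {
  p <- cfg$patients
  truth <- simulate_patient_truth(sprintf("aa%02d", seq_len(p$n_metabolites)),
                                  seed = cfg$seed,
                                  beta_treatment = p$beta_treatment,
                                  sigma_b = p$sigma_b, sigma_e = p$sigma_e)
  panel <- simulate_patients(p$n_patients, truth, seed = cfg$seed)
  write_tsv(truth, path("patient_truth.tsv"))
  write_tsv(panel, path("patient_panel.tsv"))
  rows <- lapply(split(panel, panel$metabolite), function(d) {
    f <- fit_patient_lmm(d)
    data.frame(metabolite = d$metabolite[1],
               beta_age = unname(f$full$beta["age"]),
               beta_treatment = f$treatment_effect[["estimate"]],
               SE_treatment = f$treatment_effect[["SE"]],
               sigma_b2 = f$full$sigma_b2, sigma_e2 = f$full$sigma_e2,
               lrt_stat = f$lrt$stat, pvalue = f$lrt$pvalue)
  })
  res <- do.call(rbind, rows)
  res$padj <- adjust_bh(res$pvalue)
  write_tsv(res, path("patient_lmm.tsv"))
  invisible(NULL)
}
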