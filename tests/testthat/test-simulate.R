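test_that("simulated counts follow the planted construction", {
  design <- design_two_group(1)
  truth <- data.frame(gene_id = c("g1", "g2"), base_mean = 1e6,
                      intron_fraction = 0.5, dispersion = 0,
                      delta_txn = c(0, 0), delta_pt = c(1, 0))
  cm <- simulate_counts(design, truth, seed = 5)
  # Poisson limit at mean 1e6: observed within 1% of expectation
  expect_true(all(abs(cm$exonic[, 1] / 1e6 - 1) < 0.01))
  # delta_pt = 1: exonic ratio mutant/wt ~2, intronic ratio ~1
  expect_equal(cm$exonic["g1", 2] / cm$exonic["g1", 1], 2, tolerance = 0.03)
  expect_equal(cm$intronic["g1", 2] / cm$intronic["g1", 1], 1, tolerance = 0.03)
  expect_equal(cm$exonic["g2", 2] / cm$exonic["g2", 1], 1, tolerance = 0.03)
})

test_that("NB moments match mean and mean + alpha * mean^2", {
  design <- data.frame(sample_id = sprintf("s%d", 1:10000),
                       genotype = "wild_type")
  truth <- data.frame(gene_id = "g1", base_mean = 100, intron_fraction = 0.5,
                      dispersion = 0.1, delta_txn = 0, delta_pt = 0)
  cm <- simulate_counts(design, truth, seed = 8)
  x <- as.numeric(cm$exonic[1, ])
  mu <- 100; v <- mu + 0.1 * mu^2
  # 3 Monte-Carlo SEs
  se_mean <- sqrt(v / length(x))
  expect_lt(abs(mean(x) - mu), 3 * se_mean)
  kurt_excess <- 6 * 0.1 + (0.1 + 1 / mu) * 6  # rough NB excess kurtosis bound
  se_var <- v * sqrt((2 + kurt_excess) / length(x))
  expect_lt(abs(var(x) - v), 3 * se_var)
})

test_that("fixed seeds give identical outputs and truth covers every gene", {
  design <- design_two_group(2)
  models <- generate_genome(20, seed = 4)
  truth <- simulate_gene_truth(models$genes$gene_id, seed = 4, prop_pt = 0.2)
  a <- simulate_counts(design, truth, seed = 6, models = models)
  b <- simulate_counts(design, truth, seed = 6, models = models)
  expect_identical(a$exonic, b$exonic)
  expect_identical(a$intronic, b$intronic)
  expect_error(simulate_counts(design, truth[-1, ], seed = 6, models = models),
               truth$gene_id[1])
  # single-exon genes get intronic 0
  single <- names(which(table(models$exons$gene_id) == 1))
  if (length(single)) expect_true(all(a$intronic[single, ] == 0))
})

test_that("simulated reads land inside their target regions and round-trip", {
  models <- generate_genome(25, seed = 9, exon_length = c(80, 200),
                            intron_length = c(100, 400))
  design <- design_two_group(1)
  truth <- simulate_gene_truth(models$genes$gene_id, seed = 9,
                               base_mean_meanlog = log(50))
  cm <- simulate_counts(design, truth, seed = 10, models = models)
  reads <- simulate_reads(cm, models, read_length = 50, seed = 11)
  expect_named(reads, design$sample_id)
  expect_equal(nrow(reads[[1]]),
               sum(cm$exonic[, 1]) + sum(cm$intronic[, 1]))
  idx <- build_region_index(models)
  rc <- count_matrix(reads, idx)
  expect_identical(unname(rc$exonic), unname(cm$exonic))
  expect_identical(unname(rc$intronic), unname(cm$intronic))
  expect_true(all(rc$discarded == 0))
  # tagged origin: every exonic read's name carries its gene id
  tags <- sub("\\|.*", "", reads[[1]]$name)
  expect_true(all(tags %in% models$genes$gene_id))
})

test_that("zero counts produce an empty but valid read set", {
  models <- generate_genome(3, seed = 1)
  design <- design_two_group(1)
  ex <- matrix(0L, 3, 2, dimnames = list(models$genes$gene_id, design$sample_id))
  cm <- region_count_matrix(ex, ex)
  reads <- simulate_reads(cm, models, seed = 2)
  expect_equal(nrow(reads[[1]]), 0)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(reads[[1]], f)
  expect_equal(nrow(read_bed(f)), 0)
})

test_that("metabolite panels realize the interaction model", {
  design <- design_metabolite(5)
  # noiseless additive model reproduces cell means exactly
  truth <- simulate_metabolite_truth(c("m1", "m2"), seed = 1, sigma = 0,
                                     beta_genotype = 0.5, beta_treatment = -0.3)
  panel <- simulate_metabolites(design, truth, seed = 2)
  lp <- log2(panel)
  g <- design$genotype == "mutant"; t <- design$treatment == "DEX"
  expect_equal(lp[1, g & t] - lp[1, g & !t] - (lp[1, !g & t] - lp[1, !g & !t]),
               setNames(rep(0, sum(g & t)), colnames(panel)[g & t]))
  # planted interaction: mutant-DEX cell is 2x the additive prediction
  truth2 <- simulate_metabolite_truth("m1", seed = 1, sigma = 0,
                                      prop_interaction = 1, beta_interaction = 1)
  p2 <- log2(simulate_metabolites(design, truth2, seed = 3))
  additive <- mean(p2[1, g & !t]) + mean(p2[1, !g & t]) - mean(p2[1, !g & !t])
  expect_equal(mean(p2[1, g & t]) - additive, 1)
  expect_error(simulate_metabolites(design,
                 transform(truth, sigma = -1), seed = 1), "sigma")
})

test_that("interaction recovery over many simulated features is unbiased", {
  design <- design_metabolite(5)
  truth <- simulate_metabolite_truth(sprintf("m%03d", 1:500), seed = 7,
                                     prop_interaction = 1,
                                     beta_interaction = 1, sigma = 0.2)
  panel <- simulate_metabolites(design, truth, seed = 8)
  fits <- fit_interaction_lm(log2(panel), design)
  expect_lt(abs(mean(fits$beta_interaction) - 1), 0.02)
})

test_that("patient panels have the paired structure and variance components", {
  truth <- simulate_patient_truth(c("ala", "gln"), seed = 1)
  pan <- simulate_patients(5, truth, seed = 2)
  expect_equal(nrow(pan), 5 * 2 * 2)  # 5 patients x 2 states x 2 metabolites
  expect_equal(sort(unique(pan$treatment)), c("Off", "On"))
  expect_error(simulate_patients(5, truth, states = "On"), "unidentifiable")
  # noiseless values lie exactly on the fixed-effect plane
  t0 <- simulate_patient_truth("m", seed = 1, sigma_b = 0, sigma_e = 0,
                               beta0 = 5, beta_age = 0.1, beta_treatment = 1)
  p0 <- simulate_patients(4, t0, ages = c(8, 10, 12, 14), seed = 3)
  expect_equal(p0$log2_value,
               5 + 0.1 * p0$age + as.numeric(p0$treatment == "Off"))
  # variance decomposition at n = 500
  t1 <- simulate_patient_truth("m", seed = 1, sigma_b = 1, sigma_e = 0.5,
                               beta_age = 0)
  p1 <- simulate_patients(500, t1, ages = rep(10, 500), seed = 4)
  pm <- tapply(p1$log2_value, p1$patient_id, mean)
  wv <- tapply(p1$log2_value, p1$patient_id, var)
  sb2_hat <- var(pm) - mean(wv) / 2
  expect_lt(abs(sb2_hat - 1), 0.25)
})
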