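# eisakit

Total RNA-seq (ribosomal-depleted) measures two things at once: exonic reads
report the mature mRNA pool, and purely intronic reads report nascent
pre-mRNA, i.e. transcription. Comparing how the two change between conditions
separates **transcriptional** regulation (exon and intron move together) from
**post-transcriptional** regulation (the exonic change exceeds the intronic
one, indicating altered mRNA stability). This package implements that
exon–intron split analysis (EISA) end to end, for studies such as comparing a
glucocorticoid-deficient mutant against wild-type siblings, where key
metabolic enzymes turn out to be regulated through mRNA stability rather than
transcription.

For a gene with exonic/intronic log2 fold-changes Δexon and Δintron, the
quantity of interest is

    Δexon − Δintron  =  interaction coefficient of the joint NB GLM
                        counts ~ condition + region + condition:region

with variance = μ + αμ² (α = dispersion), per-region median-of-ratios
normalization offsets, and a Wald test on the interaction, BH-adjusted across
genes. The exon/intron normalized-count ratio additionally serves as a proxy
for relative mRNA half-life.

## What's inside

* **Counting** — exonic-union / intronic region indexes from gene models
  (GTF in/out, GenomicRanges arithmetic) and uniquely-mapped-read
  classification with exact conservation accounting (BED6 or in-memory
  alignments).
* **NB differential expression** — size factors, moment/trend/shrinkage
  dispersion estimation, IRLS GLM fits, Wald tests, and likelihood-ratio
  tests for interaction designs such as the two-mutant-line model
  `~ phenotype + mutated_gene + time + phenotype:mutated_gene`.
* **EISA** — joint interaction fits, half-life proxy, regulation-mode
  classification (`transcriptional` / `post_transcriptional` / `mixed` /
  `none` / `low_intron`).
* **Enrichment** — competitive gene-set tests with inter-gene-correlation
  (VIF) correction, barcode-plot data, exact hypergeometric overlap tests,
  GMT I/O.
* **Metabolite statistics** — log2/glog transforms, per-feature
  `~ genotype * treatment` interaction models, PCA scores, and a
  random-intercept mixed model `y ~ age + treatment + (1 | patient)` fitted
  by profiled ML with a treatment LRT, for paired on/off-treatment patient
  panels.
* **Synthetic data** — generators for genomes, NB counts with planted
  transcriptional and exon-only (stability) effects, reads realizing a count
  matrix exactly, metabolite panels, and patient panels — each with a ground
  truth table, so every claim the package makes is testable without any
  external data.
* **Pipeline** — `run_pipeline()` over a YAML config with deterministic
  outputs and an md5 manifest; a thin CLI wrapper lives in
  `inst/scripts/eisakit.R`.

## Worked example

Simulate a 500-gene genome, 3 mutant vs 3 wild-type samples with 5% of genes
given a transcriptional and 5% a post-transcriptional (exon-only) effect of
one log2 unit, then run the split analysis:

```r
library(eisakit)

models <- generate_genome(500, seed = 42)
design <- design_two_group(3)
truth  <- simulate_gene_truth(models$genes$gene_id, seed = 42,
                              prop_txn = 0.05, prop_pt = 0.05,
                              lfc_txn = 1, lfc_pt = 1)
counts <- simulate_counts(design, truth, seed = 42, models = models)

res <- classify_regulation(eisa_fit(counts, design))
table(res$class)
#>           low_intron                mixed                 none
#>                   73                    1                  379
#> post_transcriptional      transcriptional
#>                   13                   34

head(res[order(res$diff_padj),
         c("gene_id", "delta_exon", "delta_intron", "delta_diff",
           "diff_padj", "class")], 5)
#>     gene_id delta_exon delta_intron delta_diff diff_padj                class
#> 26 gene0026      -1.01      0.47189      -1.48  0.000341 post_transcriptional
#> 32 gene0032      -1.09      0.20148      -1.29  0.000341 post_transcriptional
#> 49 gene0049       1.21     -0.12131       1.33  0.000341 post_transcriptional
#> 29 gene0029       1.04     -0.09176       1.13  0.000902 post_transcriptional
#> 35 gene0035      -1.25      0.00421      -1.25  0.000902 post_transcriptional
```

Reading the table: `delta_diff` is Δexon − Δintron from the joint model, so
`gene0049` roughly doubled its mRNA (Δexon ≈ 1.2) with essentially unchanged
transcription (Δintron ≈ −0.1) — the signature of increased mRNA stability.
`low_intron` genes had too little intronic signal to test. Of the top 25
genes ranked this way, 17 of the 25 planted stability-effect genes are
recovered in this run.

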