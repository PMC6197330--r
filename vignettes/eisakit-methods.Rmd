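---
title: "Separating transcriptional from post-transcriptional regulation with eisakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating transcriptional from post-transcriptional regulation with eisakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eisakit)
```

## The idea

Total RNA-seq libraries (ribosomal-depleted, not poly(A)-selected) capture
both mature mRNA and unspliced pre-mRNA. Reads overlapping exons measure the
steady-state mRNA pool; reads falling entirely within introns measure nascent
transcription. Writing $\Delta$exon and $\Delta$intron for the log2
fold-changes of the two signals between two conditions (say a
glucocorticoid-deficient mutant versus wild-type siblings):

* a **transcriptional** change moves both signals together
  ($\Delta$exon $\approx$ $\Delta$intron);
* a **post-transcriptional** change (altered mRNA stability) moves the exonic
  signal only, so $\Delta$exon $-$ $\Delta$intron $\neq 0$.

This difference is the quantity of interest in exon–intron split analysis
(EISA). `eisakit` implements the whole chain: region indexing and counting,
negative-binomial (NB) inference, the split analysis itself, a relative
half-life proxy, competitive gene-set enrichment, and companion models for
metabolite panels — plus generators that simulate all of these data types with
recorded ground truth.

## Counting model

Gene models are loci with exon intervals (0-based half-open internally; GTF is
converted at the boundary). The **exonic region** of a gene is the union of
its exons. The **intronic region** is its locus minus the exonic union of
*all* genes overlapping that span, so another gene's exon inside an intron can
never contribute "intronic" reads. Classification of a read:

1. any exonic overlap with exactly one gene → exonic for that gene
   (exonic precedence: pre-mRNA evidence must be *fully* intronic);
2. no exonic overlap, fully contained in the intronic region of exactly one
   gene → intronic;
3. touching regions of more than one gene → discarded (`ambiguous_gene`);
4. partially overlapping a single gene's intronic region → discarded
   (`boundary`);
5. anything else, including non-uniquely-mapped reads → discarded
   (`unassigned`).

Discarding rather than fractionally assigning ambiguous reads keeps counts
integral and matches the "uniquely mapped reads per gene locus" convention.
The conservation identity exonic + intronic + discarded = input reads holds
exactly and is asserted in code. Duplicate reads are not removed. The default
strandedness is `unstranded` (the synthetic reads are unstranded); `reverse`
matches dUTP-based stranded total RNA chemistry. Alignments are consumed as
BED6 intervals or in-memory data frames; interval arithmetic is done with
GenomicRanges.

## NB differential expression

All count inference uses the NB parameterization
$\mathrm{Var}(Y) = \mu + \alpha\mu^2$ ($\alpha$ = dispersion; $\alpha = 0$ is
the Poisson limit), a log link, and log size-factor offsets.

* **Normalization** — median-of-ratios: for genes expressed in every sample,
  each sample's factor is the median of count / gene geometric mean, rescaled
  to geometric mean 1. Samples with no all-expressed gene can fall back to a
  pseudo-reference (`pseudo_reference = TRUE`).
* **Dispersion** — per-gene method-of-moments on normalized counts pooled
  within design cells, $\hat\alpha_g = \max(0, (s^2-\bar\mu)/\bar\mu^2)$; a
  mean trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted by least squares on lightly
  winsorized gene estimates; final estimates shrink the gene value toward the
  trend with weight $d/(d + d_0)$, $d$ = pooled residual degrees of freedom,
  $d_0 = 20$. The trend targets the conditional *mean* deliberately: the
  moment estimator's sampling distribution is right-skewed, and a median-type
  trend under-estimates dispersion, which directly inflates test statistics.
  This machinery is intentionally simpler than Cox–Reid/MAP apparatus; the
  package promises calibration and recovery, not numerically identical output
  to any reference tool.
* **Fitting** — IRLS with step halving per gene; coefficients are reported in
  log2. Non-converged genes are flagged and excluded from testing (and from
  the multiple-testing denominator).
* **Tests** — Wald on single coefficients; likelihood-ratio tests for nested
  designs, e.g. the cross-model interaction
  `~ phenotype + mutated_gene + time + phenotype:mutated_gene` against the
  same model without the interaction, with $\chi^2$ reference. Factor coding
  is treatment contrasts with explicit reference levels (wild_type, CTR,
  fdx1b). Benjamini–Hochberg adjustment (via `p.adjust`) is applied across
  tested genes; DE calls default to adjusted $p \le 0.01$ and
  $|\log_2 FC| \ge 0.25$.

At three replicates per group the $\chi^2_1$ LRT is mildly anti-conservative
(measured null rejection ~0.05–0.055 at nominal 0.05 on the 24-sample
cross-model design); this is the familiar finite-sample behaviour of GLM
likelihood-ratio tests, not an implementation artifact, and is why the
package's calibration checks run at realistic rather than token sample sizes.

## The split analysis

`eisa_fit()` stacks each gene's exonic and intronic counts and fits one joint
NB GLM with terms `condition + region + condition:region`, per-observation
offsets from **region-specific** size factors (exonic and intronic libraries
are normalized separately because their composition differs), and a per-gene
dispersion equal to the maximum of the exon- and intron-level estimates
(conservative). The interaction coefficient *is*
$\Delta$exon $-$ $\Delta$intron, with a proper standard error from the joint
fit; the naive two-step subtraction is reported alongside and agrees to
$10^{-3}$ on saturated designs. Genes with mean normalized intronic count
below 8 (configurable) are labelled `low_intron` and not tested — intronic
coverage is typically an order of magnitude below exonic coverage and
low-count ratios are unstable.

The **half-life proxy** per condition is
$\log_2\frac{\text{norm. exonic mean} + c}{\text{norm. intronic mean} + c}$
with pseudocount $c = 0.5$ normalized counts; the mutant-minus-control shift
is positive when mRNA is relatively stabilized. It is a *relative* quantity
only; no absolute half-lives are estimated.

Classification (`classify_regulation`) is exhaustive and exclusive:
`post_transcriptional` (interaction significant, no intron-level change),
`transcriptional` (intron-level change, or exon-level change without
interaction), `mixed` (both), `none`, `low_intron`.

**Power is dispersion-limited.** In a saturated two-group design the variance
of the interaction estimate is bounded below by $4\alpha/(3\ln^2 2)$ per
region pair at three replicates, so at $\alpha = 0.05$ the Wald statistic for
a one-log2-unit stability change cannot exceed ~2.7 however deep the
libraries. Detecting most such effects after FDR control therefore requires
either low biological dispersion (pooled, isogenic samples) or more
replicates; the package's own recovery checks report exactly what is
achievable under each simulated condition.

## Competitive gene-set enrichment

The competitive test compares a set's per-gene statistics against the
remaining genes with a two-sample t-test whose set-term variance is inflated
by $\mathrm{VIF} = 1 + (m-1)\bar\rho$, where $\bar\rho$ is the mean pairwise
correlation of the set genes' model residuals. With $\bar\rho = 0$ it reduces
exactly to the unadjusted comparison. $\bar\rho$ is estimated from residuals
(never raw counts); when no residual matrix is available a fixed prior of
0.01 is used. Correlation estimation needs replication: with only three
samples per group the per-set estimate (4 residual df) is noisy enough to
degrade calibration, which is why the package's calibration simulations use
ten samples per group and why reference implementations default to a small
fixed correlation. Barcode data (member ranks plus a kernel-smoothed relative
density normalized exactly over the discrete rank grid) supports the usual
enrichment visualization. Overlap questions between gene or metabolite sets
use the exact upper-tail hypergeometric test (`phyper`), with explicit
universe and set sizes as inputs.

## Metabolite panels and patient data

* **Transforms** — `log2` for concentration data;
  `glog(x) = log2((x + sqrt(x^2 + lambda^2))/2)` as the variance-stabilizing
  transform for intensity data, with $\lambda$ defaulting to the median SD of
  the lowest-intensity quartile of features.
* **Interaction models** — per feature, OLS of
  `value ~ genotype * treatment` (treatment coding); the interaction t-test
  asks whether the mutant-vs-wild-type difference itself changes under
  treatment, i.e. whether the treatment rescues the mutant phenotype. BH is
  applied within a panel; panels from different assay types are adjusted
  separately by default.
* **PCA** — SVD of the centered samples-by-features matrix with a fixed sign
  convention (largest-magnitude loading positive) for reproducible score
  plots.
* **Patient mixed model** — `y ~ age + treatment + (1 | patient)` on log2
  concentrations, fitted by maximum likelihood via 1-D profiling of the
  variance ratio $\sigma_b^2/\sigma_e^2$ (fixed effects and $\sigma_e^2$ have
  closed forms given the ratio; the boundary $\sigma_b^2 = 0$ is allowed).
  ML rather than REML because the treatment effect is tested by a
  likelihood-ratio test against `y ~ age + (1 | patient)`, and REML
  likelihoods are not comparable across fixed-effect structures. The
  $\chi^2_1$ reference is asymptotic: with five patients it is noticeably
  anti-conservative (as any ML LRT is at that size), so calibration checks
  run at larger patient counts while effect estimates — which coincide
  exactly with the paired-differences analysis in balanced designs — remain
  valid at any size. Variance-component tests are not performed.

## Synthetic data and what passing tests mean

The generators plant known effects and return them as truth tables:

* exonic counts $\sim \mathrm{NB}(sf_j\,\mu_g\,2^{(\delta^{txn}_g + \delta^{pt}_g) x_j},\ \alpha_g)$,
  intronic counts with mean $sf_j\,\mu_g\,f_g\,2^{\delta^{txn}_g x_j}$ — the
  post-transcriptional effect touches exonic counts only;
* baseline means are log-normal (median 500, log-sd 1), dispersions
  log-normal (median 0.02, log-sd 0.3) — values typical of replicated,
  pooled-larvae bulk RNA-seq; the intronic/exonic ratio defaults to 0.1,
  reflecting the generally much lower intronic coverage (the ratio is a free
  parameter, not a measured constant);
* default designs: 3 biological replicates per genotype; two mutant lines
  × two phenotypes × two times × 3 replicates for the cross-model design;
  2×2 genotype×treatment with 5 samples per cell for metabolites;
  5 patients × paired on/off states for patient panels;
* reads are single-end, fixed-length (50 bp), placed uniformly and entirely
  within their target region, with the source gene recorded in the read name
  so counting can be verified read-for-read.

All randomness flows from one top-level seed through named child streams
(`child_seed`), so every stage is independently reproducible and whole-
pipeline runs are byte-identical.

The generators emulate the *statistical* structure the analyses assume —
NB counts, shared transcriptional effects, exon-only stability effects,
log-normal concentrations, patient baseline shifts. They do not model
sequencing error, GC or fragment-length bias, junction reads (exonic reads
stay within single exons by default), multi-isoform structure, or peak
overlap in spectra. Passing recovery tests therefore demonstrates that the
inference machinery is correct and calibrated under its stated model, not
that real libraries satisfy that model.

## Numerical choices and degenerate inputs

* IRLS: convergence on coefficient change ($10^{-10}$ relative) with
  likelihood step-halving; all-zero genes are flagged, never fitted.
* Dispersions floored at $10^{-8}$; trend input winsorized at the 99.5th
  percentile.
* LMM profile optimized on $\log\lambda \in [-30, 15]$ to $10^{-10}$, with an
  explicit boundary evaluation at $\lambda = 0$.
* Ties in barcode ranking are broken by gene id, deterministically.
* Empty count tables, header-only files, unknown chromosomes, and
  single-treatment-state patient data all have defined behaviour (tested):
  valid empty outputs or immediate, named errors.

## Running the whole thing

`run_pipeline()` executes `simulate → count → de → eisa → enrich →
metabolites → patients` from one YAML/list configuration (unknown keys
rejected, all violations reported at once; DE thresholds default to adjusted
$p \le 0.01$, $|\log_2 FC| \ge 0.25$), writes every cross-stage artifact as
TSV/GTF/BED/GMT/JSON in the output directory, and records md5 checksums of
all outputs in `manifest.json`. Stage subsets rerun against cached files;
missing inputs fail a pre-flight check before anything executes. The demo
configuration used by the package's own end-to-end checks simulates 1,000
genes — small enough to run in seconds, large enough for FDR behaviour to be
meaningful.

## Known limitations

* No junction-aware quantification, multi-mapper rescue, UMI handling, or
  isoform resolution; counting is interval-based.
* No log2FC shrinkage, outlier replacement, or batch-effect estimation in the
  DE module.
* The competitive test is the parametric variant; no rank-based alternative.
* The half-life proxy is relative; comparing it across genes (rather than
  across conditions within a gene) conflates splicing efficiency with
  stability.
* With three replicates and moderate dispersion, interaction-type contrasts
  (the heart of EISA) have intrinsically limited power; see the power note
  above.
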