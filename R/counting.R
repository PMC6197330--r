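# Exonic/intronic region indexing and read counting. Exonic counts proxy
# mature mRNA; reads fully contained in intronic regions proxy pre-mRNA.
# Classification rules:
#   * any exonic overlap with exactly one gene        -> exonic
#   * zero exonic overlap, fully inside the intronic
#     region of exactly one gene                      -> intronic
#   * touching claimed regions of more than one gene  -> discarded: ambiguous_gene
#   * partial intronic overlap of a single gene       -> discarded: boundary
#   * everything else (incl. non-unique mappers)      -> discarded: unassigned

DISCARD_REASONS <- c("ambiguous_gene", "boundary", "unassigned")

#' Build the exonic/intronic region index for a gene model set
#'
#' The exonic region of a gene is the union of its exons. The intronic region
#' is its locus minus the exonic union of *all* genes overlapping that span,
#' so a read inside another gene's exon can never be called intronic. Bases
#' claimed by more than one gene are flagged in an ambiguity mask.
#'
#' @param models A [gene_model_set()].
#' @return An object of class `region_index` with GRanges elements `exonic`
#'   and `intronic` (metadata column `gene_id`), an `ambiguous` mask, and the
#'   gene id universe.
#' @export
build_region_index <- function(models) {
  if (!inherits(models, "gene_model_set")) stopf("`models` must be a gene_model_set")
  loci <- loci_granges(models)
  ex <- exons_granges(models)
  ex_by_gene <- GenomicRanges::reduce(
    GenomicRanges::split(ex, factor(ex$gene_id, levels = models$genes$gene_id)))
  exonic <- unlist(ex_by_gene, use.names = TRUE)
  exonic$gene_id <- names(exonic)
  names(exonic) <- NULL
  all_exonic <- GenomicRanges::reduce(ex, ignore.strand = TRUE)
  loci_by_gene <- GenomicRanges::split(loci,
    factor(loci$gene_id, levels = models$genes$gene_id))
  intr_by_gene <- GenomicRanges::setdiff(loci_by_gene,
    GenomicRanges::GRangesList(rep(list(all_exonic), length(loci_by_gene))),
    ignore.strand = TRUE)
  intronic <- unlist(intr_by_gene, use.names = TRUE)
  intronic$gene_id <- names(intronic)
  names(intronic) <- NULL
  # gene strand is carried on the ranges; restore for intronic (setdiff drops it)
  gstrand <- stats::setNames(models$genes$strand, models$genes$gene_id)
  GenomicRanges::strand(intronic) <- gstrand[intronic$gene_id]
  claimed <- c(GenomicRanges::granges(exonic), GenomicRanges::granges(intronic))
  claimed$gene_id <- c(exonic$gene_id, intronic$gene_id)
  cov <- GenomicRanges::coverage(claimed)
  ambiguous <- GenomicRanges::GRanges(IRanges::slice(cov, lower = 2L,
                                                     rangesOnly = TRUE))
  structure(list(exonic = exonic, intronic = intronic, ambiguous = ambiguous,
                 gene_ids = models$genes$gene_id, gene_strand = gstrand),
            class = "region_index")
}

#' @export
print.region_index <- function(x, ...) {
  cat(sprintf("region_index: %d genes, %d exonic / %d intronic ranges, %d ambiguous\n",
              length(x$gene_ids), length(x$exonic), length(x$intronic),
              length(x$ambiguous)))
  invisible(x)
}

strand_compatible <- function(read_strand, gene_strand, strandedness) {
  switch(strandedness,
         unstranded = rep(TRUE, length(read_strand)),
         forward = read_strand == "*" | read_strand == gene_strand,
         reverse = read_strand == "*" | read_strand != gene_strand,
         stopf("unknown strandedness '%s'", strandedness))
}

reads_to_granges <- function(reads) {
  GenomicRanges::GRanges(reads$chrom,
                         IRanges::IRanges(reads$start + 1L, reads$end),
                         strand = if (!is.null(reads$strand)) reads$strand else "*")
}

#' Count reads into exonic and intronic bins for one sample
#'
#' @param reads Data frame of read alignments: columns `chrom`, `start`, `end`
#'   (0-based half-open), optional `strand` and logical `unique` (non-unique
#'   mappers are discarded as `unassigned`). Alternatively a path to a BED6
#'   file.
#' @param index A [build_region_index()] result.
#' @param strandedness `"unstranded"` (default), `"forward"` (read strand must
#'   match the gene) or `"reverse"` (must oppose it, as in dUTP-based stranded
#'   total RNA libraries).
#' @return A list with integer vectors `exonic` and `intronic` (named by gene)
#'   and `discarded` (named by reason). Their sum equals the number of input
#'   reads exactly.
#' @export
count_reads <- function(reads, index,
                        strandedness = c("unstranded", "forward", "reverse")) {
  strandedness <- match.arg(strandedness)
  if (is.character(reads) && length(reads) == 1L) reads <- read_bed(reads)
  if (!inherits(index, "region_index")) stopf("`index` must be a region_index")
  n <- nrow(reads)
  exonic <- stats::setNames(integer(length(index$gene_ids)), index$gene_ids)
  intronic <- exonic
  discarded <- stats::setNames(integer(3L), DISCARD_REASONS)
  if (n == 0L)
    return(list(exonic = exonic, intronic = intronic, discarded = discarded))
  uq <- if (!is.null(reads$unique)) as.logical(reads$unique) else rep(TRUE, n)
  known_chrom <- reads$chrom %in% GenomeInfoDb::seqlevels(index$exonic)
  if (any(!known_chrom))
    warnf("%d read(s) on chromosome(s) absent from the index -> unassigned",
          sum(!known_chrom))
  active <- which(uq & known_chrom)
  discarded[["unassigned"]] <- n - length(active)
  if (!length(active))
    return(list(exonic = exonic, intronic = intronic, discarded = discarded))
  gr <- reads_to_granges(reads[active, , drop = FALSE])
  rs <- as.character(GenomicRanges::strand(gr))

  classify <- function(hits, subject_gene, subject_strand, within_hits = NULL) {
    ok <- strand_compatible(rs[S4Vectors::queryHits(hits)],
                            subject_strand[S4Vectors::subjectHits(hits)],
                            strandedness)
    q <- S4Vectors::queryHits(hits)[ok]
    g <- subject_gene[S4Vectors::subjectHits(hits)[ok]]
    keep <- !duplicated(paste(q, g))
    list(q = q[keep], g = g[keep])
  }

  ex_strand <- as.character(GenomicRanges::strand(index$exonic))
  fo <- GenomicRanges::findOverlaps(gr, index$exonic, ignore.strand = TRUE)
  exh <- classify(fo, index$exonic$gene_id, ex_strand)
  n_ex_genes <- tabulate(exh$q, nbins = length(gr))
  one_ex <- n_ex_genes == 1L
  hit1 <- exh$q %in% which(one_ex)
  tab <- table(factor(exh$g[hit1], levels = index$gene_ids))
  exonic[] <- as.integer(tab)
  discarded[["ambiguous_gene"]] <- sum(n_ex_genes >= 2L)

  rem <- which(n_ex_genes == 0L)
  if (length(rem)) {
    grr <- gr[rem]
    rsr <- rs[rem]
    in_strand <- as.character(GenomicRanges::strand(index$intronic))
    fo_any <- GenomicRanges::findOverlaps(grr, index$intronic, ignore.strand = TRUE)
    okA <- strand_compatible(rsr[S4Vectors::queryHits(fo_any)],
                             in_strand[S4Vectors::subjectHits(fo_any)], strandedness)
    qA <- S4Vectors::queryHits(fo_any)[okA]
    gA <- index$intronic$gene_id[S4Vectors::subjectHits(fo_any)[okA]]
    keepA <- !duplicated(paste(qA, gA))
    n_in_genes <- tabulate(qA[keepA], nbins = length(grr))
    fo_win <- GenomicRanges::findOverlaps(grr, index$intronic, type = "within",
                                          ignore.strand = TRUE)
    okW <- strand_compatible(rsr[S4Vectors::queryHits(fo_win)],
                             in_strand[S4Vectors::subjectHits(fo_win)], strandedness)
    qW <- unique(S4Vectors::queryHits(fo_win)[okW])
    within_flag <- seq_along(grr) %in% qW
    is_intronic <- n_in_genes == 1L & within_flag
    q_int <- qA[keepA][qA[keepA] %in% which(is_intronic)]
    g_int <- gA[keepA][qA[keepA] %in% which(is_intronic)]
    tab2 <- table(factor(g_int, levels = index$gene_ids))
    intronic[] <- as.integer(tab2)
    discarded[["ambiguous_gene"]] <- discarded[["ambiguous_gene"]] +
      sum(n_in_genes >= 2L)
    discarded[["boundary"]] <- sum(n_in_genes == 1L & !within_flag)
    discarded[["unassigned"]] <- discarded[["unassigned"]] + sum(n_in_genes == 0L)
  }
  stopifnot(sum(exonic) + sum(intronic) + sum(discarded) == n)
  list(exonic = exonic, intronic = intronic, discarded = discarded)
}

#' Assemble a region count matrix from per-sample read sets
#'
#' @param read_sets Named list (one element per sample) of read data frames or
#'   BED paths, as accepted by [count_reads()].
#' @param index A [build_region_index()] result.
#' @param strandedness Passed to [count_reads()].
#' @return A `region_count_matrix`.
#' @export
count_matrix <- function(read_sets, index, strandedness = "unstranded") {
  if (is.null(names(read_sets)) || anyDuplicated(names(read_sets)))
    stopf("`read_sets` must be a uniquely named list of samples")
  cols <- lapply(read_sets, count_reads, index = index, strandedness = strandedness)
  region_count_matrix(
    exonic = do.call(cbind, lapply(cols, `[[`, "exonic")),
    intronic = do.call(cbind, lapply(cols, `[[`, "intronic")),
    discarded = do.call(cbind, lapply(cols, `[[`, "discarded")))
}

#' Construct a region count matrix
#'
#' Genes x samples integer counts, one layer per region kind, plus per-sample
#' discard tallies by reason.
#'
#' @param exonic,intronic Nonnegative integer matrices with identical
#'   dimnames (genes x samples).
#' @param discarded Optional 3 x samples matrix with rows
#'   `ambiguous_gene`, `boundary`, `unassigned`.
#' @return An object of class `region_count_matrix`.
#' @export
region_count_matrix <- function(exonic, intronic, discarded = NULL) {
  exonic <- as.matrix(exonic); intronic <- as.matrix(intronic)
  if (!identical(dim(exonic), dim(intronic)))
    stopf("exonic and intronic matrices must have identical dimensions")
  if ((nrow(exonic) > 0 && is.null(rownames(exonic))) || is.null(colnames(exonic)))
    stopf("count matrices need gene rownames and sample colnames")
  if (nrow(exonic) == 0 && is.null(rownames(exonic)))
    rownames(exonic) <- rownames(intronic) <- character(0)
  if (!identical(dimnames(exonic), dimnames(intronic)))
    stopf("exonic and intronic dimnames differ")
  for (nm in c("exonic", "intronic")) {
    m <- get(nm)
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
      stopf("%s counts must be nonnegative integers; first offence at gene '%s', sample '%s'",
            nm, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
  }
  if (is.null(discarded))
    discarded <- matrix(0L, 3L, ncol(exonic),
                        dimnames = list(DISCARD_REASONS, colnames(exonic)))
  structure(list(gene_ids = rownames(exonic), sample_ids = colnames(exonic),
                 exonic = exonic, intronic = intronic, discarded = discarded),
            class = "region_count_matrix")
}

#' @export
print.region_count_matrix <- function(x, ...) {
  cat(sprintf("region_count_matrix: %d genes x %d samples (exonic + intronic layers)\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Write a region count matrix as TSV files
#'
#' Writes `<prefix>_exonic.tsv`, `<prefix>_intronic.tsv` and
#' `<prefix>_discarded.tsv` (genes/reasons x samples, first column the key).
#'
#' @param x A `region_count_matrix`.
#' @param prefix Output path prefix.
#' @param comment Optional comment lines for the file headers.
#' @export
write_counts_table <- function(x, prefix, comment = NULL) {
  stopifnot(inherits(x, "region_count_matrix"))
  for (layer in c("exonic", "intronic")) {
    df <- data.frame(gene_id = x$gene_ids, x[[layer]], check.names = FALSE)
    write_tsv(df, paste0(prefix, "_", layer, ".tsv"), comment = comment)
  }
  dd <- data.frame(reason = rownames(x$discarded), x$discarded, check.names = FALSE)
  write_tsv(dd, paste0(prefix, "_discarded.tsv"), comment = comment)
  invisible(prefix)
}

#' Read a region count matrix written by [write_counts_table()]
#' @param prefix Path prefix used at write time.
#' @return A `region_count_matrix`.
#' @export
read_counts_table <- function(prefix) {
  read_layer <- function(layer) {
    df <- read_tsv(paste0(prefix, "_", layer, ".tsv"))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
      stopf("malformed %s count at gene '%s', sample '%s'", layer,
            rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
    storage.mode(m) <- "integer"
    m
  }
  dpath <- paste0(prefix, "_discarded.tsv")
  discarded <- NULL
  if (file.exists(dpath)) {
    dd <- read_tsv(dpath)
    discarded <- as.matrix(dd[, -1, drop = FALSE])
    rownames(discarded) <- dd[[1]]
  }
  region_count_matrix(read_layer("exonic"), read_layer("intronic"), discarded)
}
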