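# Gene models: loci with exon structure, the substrate for exonic/intronic
# counting. Internal coordinates are 0-based half-open; GTF is converted at the
# boundary (1-based closed).

#' Construct a gene model set
#'
#' A gene model set holds one locus per gene together with its exons. The
#' exonic union of a gene is the merge of its exons; everything else inside the
#' locus is (potentially) intronic.
#'
#' @param genes A data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open locus).
#' @param exons A data frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open), one row per exon.
#' @return An object of class `gene_model_set` with elements `genes` and
#'   `exons` (validated, exons sorted within gene).
#' @export
gene_model_set <- function(genes, exons) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(genes))) stopf("`genes` needs columns: %s", paste(need, collapse = ", "))
  if (!all(c("gene_id", "start", "end") %in% names(exons)))
    stopf("`exons` needs columns gene_id, start, end")
  if (anyDuplicated(genes$gene_id)) stopf("gene_ids are not unique")
  if (!all(genes$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (any(genes$end <= genes$start)) stopf("gene loci must have positive width")
  if (any(exons$end <= exons$start)) stopf("exons must have positive width")
  if (!all(exons$gene_id %in% genes$gene_id)) stopf("exon rows reference unknown gene_ids")
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  # exons inside locus; every gene has >= 1 exon
  idx <- match(exons$gene_id, genes$gene_id)
  bad <- exons$start < genes$start[idx] | exons$end > genes$end[idx]
  if (any(bad))
    stopf("exon outside locus for gene(s): %s",
          paste(unique(exons$gene_id[bad]), collapse = ", "))
  no_exon <- setdiff(genes$gene_id, exons$gene_id)
  if (length(no_exon)) stopf("gene(s) without exons: %s", paste(no_exon, collapse = ", "))
  structure(list(genes = as.data.frame(genes), exons = as.data.frame(exons)),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("gene_model_set: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

# GRanges views (1-based closed internally to GRanges; converted from 0-based
# half-open by start+1).
loci_granges <- function(models) {
  g <- models$genes
  GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end),
                         strand = g$strand, gene_id = g$gene_id)
}

exons_granges <- function(models) {
  e <- models$exons
  idx <- match(e$gene_id, models$genes$gene_id)
  GenomicRanges::GRanges(models$genes$chrom[idx],
                         IRanges::IRanges(e$start + 1L, e$end),
                         strand = models$genes$strand[idx], gene_id = e$gene_id)
}

#' Simulate a synthetic genome annotation
#'
#' Genes are laid out left to right along each chromosome with random
#' inter-gene gaps; each gene gets a random number of exons with random exon
#' and intron lengths. The locus spans the first to the last exon, so the
#' single-exon case has an empty intronic region.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param exon_count Integer range (length-2) for exons per gene.
#' @param exon_length Integer range for exon lengths (bp, > 0).
#' @param intron_length Integer range for intron lengths (bp, > 0).
#' @param n_chroms Number of chromosomes genes are spread across.
#' @param gene_gap Integer range for the gap between consecutive genes;
#'   the default keeps genes non-overlapping. Negative lower bounds allow
#'   overlapping neighbours.
#' @return A [gene_model_set()].
#' @export
generate_genome <- function(n_genes, seed = 1L,
                            exon_count = c(1L, 8L),
                            exon_length = c(80L, 400L),
                            intron_length = c(100L, 1500L),
                            n_chroms = 3L,
                            gene_gap = c(500L, 5000L)) {
  check_scalar_number(n_genes, "n_genes", lower = 1)
  for (nm in c("exon_count", "exon_length", "intron_length", "gene_gap")) {
    v <- get(nm)
    if (length(v) != 2L || any(!is.finite(v)) || v[2] < v[1])
      stopf("`%s` must be a length-2 increasing range", nm)
  }
  if (exon_length[1] <= 0 || intron_length[1] <= 0 || exon_count[1] < 1)
    stopf("exon/intron length ranges must be positive and exon_count >= 1")
  with_child_seed(seed, "genome", {
    chrom <- sort(rep_len(paste0("chr", seq_len(n_chroms)), n_genes))
    pos <- stats::setNames(rep(0L, n_chroms), paste0("chr", seq_len(n_chroms)))
    genes <- vector("list", n_genes)
    exons <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      gid <- sprintf("gene%04d", i)
      ne <- sample(seq(exon_count[1], exon_count[2]), 1L)
      el <- sample(seq(exon_length[1], exon_length[2]), ne, replace = TRUE)
      il <- if (ne > 1) sample(seq(intron_length[1], intron_length[2]), ne - 1L,
                               replace = TRUE) else integer(0)
      gap <- sample(seq(gene_gap[1], gene_gap[2]), 1L)
      start <- max(0L, pos[[chrom[i]]] + gap)
      starts <- start + cumsum(c(0L, el[-ne] + il))
      ends <- starts + el
      strand <- sample(c("+", "-"), 1L)
      genes[[i]] <- data.frame(gene_id = gid, chrom = chrom[i], strand = strand,
                               start = start, end = ends[ne])
      exons[[i]] <- data.frame(gene_id = gid, start = starts, end = ends)
      pos[[chrom[i]]] <- max(pos[[chrom[i]]], ends[ne])
    }
    gene_model_set(do.call(rbind, genes), do.call(rbind, exons))
  })
}

#' Write a gene model set as GTF
#'
#' Emits one `gene` and one `exon` feature per locus/exon with `gene_id` and
#' `transcript_id` attributes, 1-based closed coordinates. Output bytes are a
#' pure function of the input (no timestamps), so identical models yield
#' identical files.
#'
#' @param models A [gene_model_set()].
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  g <- models$genes
  e <- models$exons
  idx <- match(e$gene_id, g$gene_id)
  fmt <- function(chrom, feat, start0, end0, strand, gid)
    sprintf("%s\teisakit\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
            chrom, feat, start0 + 1L, end0, strand, gid, gid)
  gene_lines <- fmt(g$chrom, "gene", g$start, g$end, g$strand, g$gene_id)
  exon_lines <- split(fmt(g$chrom[idx], "exon", e$start, e$end, g$strand[idx], e$gene_id),
                      factor(e$gene_id, levels = g$gene_id))
  ord <- order(g$chrom, g$start)
  lines <- unlist(lapply(ord, function(i) c(gene_lines[i], exon_lines[[i]])),
                  use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF annotation into a gene model set
#'
#' Parsing is delegated to `rtracklayer::import`; `gene` features define loci
#' and `exon` features define exons. When no `gene` features are present, loci
#' are inferred as the exon span per `gene_id`.
#'
#' @param path GTF file path.
#' @return A [gene_model_set()].
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   gene_id = gr$gene_id)
  ex <- df[df$type == "exon", c("gene_id", "start", "end", "chrom", "strand")]
  gn <- df[df$type == "gene", c("gene_id", "chrom", "strand", "start", "end")]
  if (!nrow(gn)) {
    gn <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d)
      data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1], strand = d$strand[1],
                 start = min(d$start), end = max(d$end))))
  }
  gn <- gn[order(gn$chrom, gn$start), ]
  gene_model_set(gn, ex[c("gene_id", "start", "end")])
}

#' Write genomic intervals as BED6
#'
#' @param x Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  need <- c("chrom", "start", "end", "name", "score", "strand")
  if (!all(need %in% names(x))) stopf("BED6 needs columns: %s", paste(need, collapse = ", "))
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), x$name, x$score, x$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file of read alignments
#'
#' Parsing via `rtracklayer::import`; returns the package's 0-based half-open
#' interval data frame.
#' @param path BED file path.
#' @return Data frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), score = numeric(0), strand = character(0)))
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else "",
             score = if (!is.null(gr$score)) gr$score else 0,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
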