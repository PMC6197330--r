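# Independent oracles used across tests. These are deliberately naive
# implementations (per-base scans, per-read loops, textbook formulas) kept
# separate from the package's code paths.

# Textbook Benjamini-Hochberg step-up: sort, p_(i) * n / i, cumulative min
# from the largest rank down, cap at 1.
bh_textbook <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Per-base region labeller: for every base of every chromosome, which genes
# claim it as exonic / intronic. Returns a data frame base -> labels.
label_bases_bruteforce <- function(models) {
  all_ex <- models$exons
  gidx <- match(all_ex$gene_id, models$genes$gene_id)
  chrom_of <- models$genes$chrom
  out <- list()
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    bases <- seq(g$start, g$end - 1L)
    ex_own <- all_ex[all_ex$gene_id == g$gene_id, , drop = FALSE]
    exonic <- rep(FALSE, length(bases))
    for (k in seq_len(nrow(ex_own)))
      exonic <- exonic | (bases >= ex_own$start[k] & bases < ex_own$end[k])
    # intronic = inside locus, not exonic for ANY gene on this chromosome
    any_ex <- rep(FALSE, length(bases))
    ex_chr <- all_ex[chrom_of[gidx] == g$chrom, , drop = FALSE]
    for (k in seq_len(nrow(ex_chr)))
      any_ex <- any_ex | (bases >= ex_chr$start[k] & bases < ex_chr$end[k])
    keep_ex <- which(exonic)
    keep_in <- which(!any_ex)
    out[[i]] <- rbind(
      if (length(keep_ex)) data.frame(chrom = g$chrom, base = bases[keep_ex],
                                      gene_id = g$gene_id, kind = "exonic"),
      if (length(keep_in)) data.frame(chrom = g$chrom, base = bases[keep_in],
                                      gene_id = g$gene_id, kind = "intronic"))
  }
  do.call(rbind, out)
}

# Brute-force read classifier mirroring the counting contract with plain
# per-read loops over genes.
count_reads_bruteforce <- function(reads, models) {
  genes <- models$genes
  exons <- models$exons
  exonic <- setNames(integer(nrow(genes)), genes$gene_id)
  intronic <- exonic
  disc <- c(ambiguous_gene = 0L, boundary = 0L, unassigned = 0L)
  ex_by_gene <- split(exons, exons$gene_id)
  # per-gene intronic intervals: locus minus ALL genes' exons on that chrom
  intr_by_gene <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    cut <- exons[genes$chrom[match(exons$gene_id, genes$gene_id)] == g$chrom, ]
    segs <- data.frame(start = g$start, end = g$end)
    for (k in seq_len(nrow(cut))) {
      new <- list()
      for (s in seq_len(nrow(segs))) {
        a <- segs$start[s]; b <- segs$end[s]
        cs <- cut$start[k]; ce <- cut$end[k]
        if (ce <= a || cs >= b) { new[[length(new) + 1]] <- c(a, b); next }
        if (cs > a) new[[length(new) + 1]] <- c(a, cs)
        if (ce < b) new[[length(new) + 1]] <- c(ce, b)
      }
      segs <- if (length(new)) as.data.frame(do.call(rbind, new)) else
        data.frame(V1 = numeric(0), V2 = numeric(0))
      names(segs) <- c("start", "end")
    }
    segs
  })
  names(intr_by_gene) <- genes$gene_id
  for (r in seq_len(nrow(reads))) {
    rs <- reads$start[r]; re <- reads$end[r]; rc <- reads$chrom[r]
    ex_hit <- character(0)
    for (i in seq_len(nrow(genes))) {
      if (genes$chrom[i] != rc) next
      ee <- ex_by_gene[[genes$gene_id[i]]]
      if (any(ee$start < re & ee$end > rs)) ex_hit <- c(ex_hit, genes$gene_id[i])
    }
    if (length(ex_hit) == 1L) { exonic[ex_hit] <- exonic[ex_hit] + 1L; next }
    if (length(ex_hit) > 1L) { disc["ambiguous_gene"] <- disc["ambiguous_gene"] + 1L; next }
    in_hit <- character(0); in_within <- character(0)
    for (i in seq_len(nrow(genes))) {
      if (genes$chrom[i] != rc) next
      ii <- intr_by_gene[[genes$gene_id[i]]]
      if (!nrow(ii)) next
      if (any(ii$start < re & ii$end > rs)) in_hit <- c(in_hit, genes$gene_id[i])
      if (any(ii$start <= rs & ii$end >= re)) in_within <- c(in_within, genes$gene_id[i])
    }
    if (length(in_hit) > 1L) disc["ambiguous_gene"] <- disc["ambiguous_gene"] + 1L
    else if (length(in_hit) == 1L && length(in_within) == 1L)
      intronic[in_hit] <- intronic[in_hit] + 1L
    else if (length(in_hit) == 1L) disc["boundary"] <- disc["boundary"] + 1L
    else disc["unassigned"] <- disc["unassigned"] + 1L
  }
  list(exonic = exonic, intronic = intronic, discarded = disc)
}

# Uniform random reads over the span of a gene model set (may fall anywhere,
# including outside genes).
random_reads <- function(models, n, read_length = 50L) {
  chroms <- unique(models$genes$chrom)
  span <- sapply(chroms, function(cc) max(models$genes$end[models$genes$chrom == cc]))
  cc <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, span[cc] + 200) )
  data.frame(chrom = cc, start = start, end = start + read_length,
             name = paste0("r", seq_len(n)), score = 0,
             strand = sample(c("+", "-"), n, TRUE), stringsAsFactors = FALSE)
}

# Direct median-of-ratios computation (definitional oracle for size_factors).
size_factors_direct <- function(counts) {
  ok <- apply(counts > 0, 1, all)
  gm <- exp(rowMeans(log(counts[ok, , drop = FALSE])))
  f <- apply(counts[ok, , drop = FALSE], 2, function(col) median(col / gm))
  f / exp(mean(log(f)))
}

# Vectorized form of the brute-force classifier: same rules, but the per-read
# interval scan is vectorized over reads for each gene/interval (needed for
# the large randomized-oracle comparisons).
count_reads_bruteforce_vec <- function(reads, models) {
  genes <- models$genes
  exons <- models$exons
  n <- nrow(reads)
  ex_genes <- matrix(0L, n, nrow(genes))
  in_any <- matrix(0L, n, nrow(genes))
  in_within <- matrix(0L, n, nrow(genes))
  chrom_of_exon <- genes$chrom[match(exons$gene_id, genes$gene_id)]
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    on_chr <- reads$chrom == g$chrom
    ee <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    hit <- rep(FALSE, n)
    for (k in seq_len(nrow(ee)))
      hit <- hit | (on_chr & reads$start < ee$end[k] & reads$end > ee$start[k])
    ex_genes[, i] <- hit
    # intronic intervals: locus minus every gene's exons on this chromosome
    segs <- data.frame(start = g$start, end = g$end)
    cut <- exons[chrom_of_exon == g$chrom, , drop = FALSE]
    for (k in seq_len(nrow(cut))) {
      new <- list()
      for (s in seq_len(nrow(segs))) {
        a <- segs$start[s]; b <- segs$end[s]
        cs <- cut$start[k]; ce <- cut$end[k]
        if (ce <= a || cs >= b) { new[[length(new) + 1]] <- c(a, b); next }
        if (cs > a) new[[length(new) + 1]] <- c(a, cs)
        if (ce < b) new[[length(new) + 1]] <- c(ce, b)
      }
      segs <- if (length(new)) setNames(as.data.frame(do.call(rbind, new)),
                                        c("start", "end"))
              else data.frame(start = numeric(0), end = numeric(0))
    }
    anyh <- withinh <- rep(FALSE, n)
    for (s in seq_len(nrow(segs))) {
      anyh <- anyh | (on_chr & reads$start < segs$end[s] & reads$end > segs$start[s])
      withinh <- withinh | (on_chr & reads$start >= segs$start[s] &
                              reads$end <= segs$end[s])
    }
    in_any[, i] <- anyh
    in_within[, i] <- withinh
  }
  n_ex <- rowSums(ex_genes)
  exonic <- setNames(integer(nrow(genes)), genes$gene_id)
  intronic <- exonic
  disc <- c(ambiguous_gene = 0L, boundary = 0L, unassigned = 0L)
  for (r in seq_len(n)) {
    if (n_ex[r] == 1L) {
      gi <- which(ex_genes[r, ] == 1L)
      exonic[gi] <- exonic[gi] + 1L
    } else if (n_ex[r] > 1L) {
      disc["ambiguous_gene"] <- disc["ambiguous_gene"] + 1L
    } else {
      ia <- which(in_any[r, ] == 1L)
      if (length(ia) > 1L) disc["ambiguous_gene"] <- disc["ambiguous_gene"] + 1L
      else if (length(ia) == 1L && in_within[r, ia] == 1L)
        intronic[ia] <- intronic[ia] + 1L
      else if (length(ia) == 1L) disc["boundary"] <- disc["boundary"] + 1L
      else disc["unassigned"] <- disc["unassigned"] + 1L
    }
  }
  list(exonic = exonic, intronic = intronic, discarded = disc)
}
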