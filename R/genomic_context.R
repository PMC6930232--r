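# Genomic context of insertion calls: feature classes, distance to TSS,
# megabase density correlation, metagene profiles, upstream enrichment.

#' Load gene models from a GFF3 file
#'
#' Reads `gene` and `exon` features (1-based inclusive GFF coordinates are
#' converted to 0-based half-open), merges overlapping exon records, and
#' falls back to a single exon spanning the gene when a gene has none.
#' Exons may point at the gene directly or through an mRNA parent.
#'
#' @param gff3 Path to a GFF3 file.
#' @return A `gene_models` object: list with `genes` (`data.frame`:
#'   `gene_id`, `chrom`, `strand`, `start`, `end`) and `exons`
#'   (`data.frame`: `gene_id`, `chrom`, `start`, `end`).
#' @export
load_genes <- function(gff3) {
  gr <- rtracklayer::import(gff3, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  if (!any(is_gene)) stop("No gene features in ", gff3)
  g <- gr[is_gene]
  strand <- as.character(BiocGenerics::strand(g))
  if (any(strand == "*")) {
    stop("Gene(s) without strand in ", gff3, ": ",
         paste(S4Vectors::mcols(g)$ID[strand == "*"], collapse = ", "))
  }
  genes <- data.frame(
    gene_id = as.character(S4Vectors::mcols(g)$ID),
    chrom = as.character(GenomicRanges::seqnames(g)),
    strand = strand,
    start = BiocGenerics::start(g) - 1L,
    end = BiocGenerics::end(g))

  # map transcript-level parents back to genes where needed
  id_of <- setNames(genes$gene_id, genes$gene_id)
  is_tx <- md$type %in% c("mRNA", "transcript")
  if (any(is_tx)) {
    tx <- gr[is_tx]
    tx_parent <- vapply(as.list(S4Vectors::mcols(tx)$Parent),
                        function(p) if (length(p)) p[[1L]] else NA_character_,
                        "")
    id_of <- c(id_of, setNames(tx_parent,
                               as.character(S4Vectors::mcols(tx)$ID)))
  }
  ex <- gr[md$type == "exon"]
  exon_rows <- list()
  if (length(ex)) {
    parents <- vapply(as.list(S4Vectors::mcols(ex)$Parent),
                      function(p) if (length(p)) p[[1L]] else NA_character_,
                      "")
    gene_of <- unname(id_of[parents])
    if (anyNA(gene_of)) stop("Exon(s) with unknown parent in ", gff3)
    exdf <- data.frame(gene_id = gene_of,
                       chrom = as.character(GenomicRanges::seqnames(ex)),
                       start = BiocGenerics::start(ex) - 1L,
                       end = BiocGenerics::end(ex))
    for (gid in unique(exdf$gene_id)) {
      rows <- exdf[exdf$gene_id == gid, ]
      grow <- genes[genes$gene_id == gid, ]
      if (nrow(grow) == 0L) stop("Exon parent '", gid, "' is not a gene")
      if (any(rows$start < grow$start | rows$end > grow$end)) {
        stop("Exon outside gene body for ", gid)
      }
      merged <- IRanges::reduce(IRanges::IRanges(rows$start + 1L, rows$end))
      exon_rows[[gid]] <- data.frame(
        gene_id = gid, chrom = rows$chrom[1L],
        start = IRanges::start(merged) - 1L, end = IRanges::end(merged))
    }
  }
  # genes without exon records: single exon spanning the gene
  for (gid in setdiff(genes$gene_id, names(exon_rows))) {
    grow <- genes[genes$gene_id == gid, ]
    exon_rows[[gid]] <- data.frame(gene_id = gid, chrom = grow$chrom,
                                   start = grow$start, end = grow$end)
  }
  exons <- do.call(rbind, exon_rows[genes$gene_id])
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write gene models as GFF3
#' @param genes A `gene_models` object.
#' @param path Output path.
#' @export
write_genes_gff3 <- function(genes, path) {
  g <- genes$genes
  e <- genes$exons
  gene_lines <- paste(g$chrom, "ripscan", "gene", g$start + 1L, g$end,
                      ".", g$strand, ".", paste0("ID=", g$gene_id),
                      sep = "\t")
  strand_of <- setNames(g$strand, g$gene_id)
  exon_lines <- paste(e$chrom, "ripscan", "exon", e$start + 1L, e$end,
                      ".", unname(strand_of[e$gene_id]), ".",
                      paste0("ID=", e$gene_id, ".exon",
                             stats::ave(seq_len(nrow(e)), e$gene_id,
                                        FUN = seq_along),
                             ";Parent=", e$gene_id),
                      sep = "\t")
  writeLines(c("##gff-version 3", gene_lines, exon_lines), path)
  invisible(path)
}

flank_intervals <- function(genes, flank, which = c("up", "down")) {
  which <- match.arg(which)
  g <- genes$genes
  upstream <- (which == "up") == (g$strand == "+")
  # for + strand genes, upstream lies left of start; mirrored for -
  start <- ifelse(upstream, pmax(0L, g$start - flank), g$end)
  end <- ifelse(upstream, g$start, g$end + flank)
  data.frame(chrom = g$chrom, start = start, end = end)
}

points_in <- function(chrom, pos, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  ir_p <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  ir_i <- GenomicRanges::GRanges(iv$chrom,
                                 IRanges::IRanges(iv$start + 1L, iv$end))
  IRanges::overlapsAny(ir_p, ir_i)
}

#' Classify genomic points into gene-context feature classes
#'
#' Precedence: exon > intron > up2kb > down2kb > intergenic. Up- and
#' downstream flanks are strand-aware (upstream of a minus-strand gene
#' lies to its right).
#'
#' @param chrom,pos Chromosome and 0-based position of each point (use the
#'   call's insertion point).
#' @param genes A `gene_models` object.
#' @param flank Flank width in bp (default 2000).
#' @return Character vector: `exon`, `intron`, `up2kb`, `down2kb`, or
#'   `intergenic`.
#' @export
classify_feature <- function(chrom, pos, genes, flank = 2000L) {
  stopifnot(all(pos >= 0))
  cls <- rep("intergenic", length(pos))
  g <- genes$genes
  in_gene <- points_in(chrom, pos, g[, c("chrom", "start", "end")])
  in_exon <- points_in(chrom, pos,
                       genes$exons[, c("chrom", "start", "end")])
  in_up <- points_in(chrom, pos, flank_intervals(genes, flank, "up"))
  in_down <- points_in(chrom, pos, flank_intervals(genes, flank, "down"))
  cls[in_down] <- "down2kb"
  cls[in_up] <- "up2kb"
  cls[in_gene & !in_exon] <- "intron"
  cls[in_exon] <- "exon"
  cls
}

#' Feature-class percentage table
#' @param classes Output of [classify_feature()].
#' @return Named numeric vector of percentages (sums to 100).
#' @export
feature_class_percentages <- function(classes) {
  lev <- c("exon", "intron", "up2kb", "down2kb", "intergenic")
  100 * table(factor(classes, levels = lev)) / length(classes)
}

#' Distance to the nearest transcriptional start site
#'
#' TSS is the strand-aware 5' end of a gene: `start` for plus-strand
#' genes, `end - 1` for minus-strand genes (0-based).
#'
#' @param chrom,pos Chromosome and 0-based positions.
#' @param genes A `gene_models` object.
#' @return Unsigned distances in bp; `NA` (with a warning) for points on
#'   chromosomes without genes.
#' @export
distance_to_tss <- function(chrom, pos, genes) {
  g <- genes$genes
  tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    t_ch <- tss[g$chrom == ch]
    if (length(t_ch) == 0L) {
      warning("No genes on ", ch, "; distance undefined")
      next
    }
    out[sel] <- vapply(pos[sel], function(p) min(abs(p - t_ch)), 0)
  }
  out
}

#' Correlation between insertion density and gene density in fixed bins
#'
#' Counts insertion points and gene starts per `bin`-bp window along each
#' chromosome and returns the Pearson correlation of the two vectors.
#'
#' @param chrom,pos Insertion points (0-based).
#' @param genes A `gene_models` object.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param bin Bin width in bp (default 1e6).
#' @return Pearson r, or `NULL` with a warning when fewer than 3 bins or
#'   a zero-variance vector.
#' @export
megabase_density_correlation <- function(chrom, pos, genes, chrom_lengths,
                                         bin = 1e6) {
  ins <- numeric(0)
  gen <- numeric(0)
  g <- genes$genes
  for (ch in names(chrom_lengths)) {
    nb <- max(1L, as.integer(ceiling(chrom_lengths[[ch]] / bin)))
    b_ins <- tabulate(pmin(assign_window(pos[chrom == ch], bin) + 1L, nb),
                      nbins = nb)
    b_gen <- tabulate(pmin(assign_window(g$start[g$chrom == ch], bin) + 1L,
                           nb), nbins = nb)
    ins <- c(ins, b_ins)
    gen <- c(gen, b_gen)
  }
  if (length(ins) < 3L) {
    warning("Fewer than 3 bins; correlation undefined")
    return(NULL)
  }
  if (stats::sd(ins) == 0 || stats::sd(gen) == 0) {
    warning("Zero-variance bin counts; correlation undefined")
    return(NULL)
  }
  cor(ins, gen)
}

#' Metagene profile of anchors around gene bodies
#'
#' Anchors within `[start - flank, end + flank)` of a gene contribute to
#' one profile bin: fixed `flank / flank_bin` bins on each side, gene
#' bodies rescaled to `body_bins` bins, minus-strand genes flipped. The
#' profile is normalized to sum to 1.
#'
#' @param chrom,pos Anchor positions (0-based).
#' @param genes A `gene_models` object.
#' @param flank Flank width (bp).
#' @param body_bins Bins across the gene body.
#' @param flank_bin Width of each flank bin (bp).
#' @return Numeric profile of length `2 * flank / flank_bin + body_bins`;
#'   a zero vector (with a warning) when no anchor falls near a gene.
#' @export
metagene_profile <- function(chrom, pos, genes, flank = 2000L,
                             body_bins = 100L, flank_bin = 50L) {
  nf <- as.integer(flank / flank_bin)
  total <- 2L * nf + body_bins
  profile <- numeric(total)
  if (length(pos) == 0L) {
    warning("Empty anchor set; returning a zero profile")
    return(profile)
  }
  g <- genes$genes
  for (i in seq_len(nrow(g))) {
    sel <- which(chrom == g$chrom[i] & pos >= g$start[i] - flank &
                   pos < g$end[i] + flank)
    if (!length(sel)) next
    x <- pos[sel]
    bin <- integer(length(x))
    left <- x < g$start[i]
    right <- x >= g$end[i]
    body <- !left & !right
    bin[left] <- (x[left] - (g$start[i] - flank)) %/% flank_bin
    bin[body] <- nf + pmin(
      as.integer(floor((x[body] - g$start[i]) /
                         (g$end[i] - g$start[i]) * body_bins)),
      body_bins - 1L)
    bin[right] <- nf + body_bins + (x[right] - g$end[i]) %/% flank_bin
    if (g$strand[i] == "-") bin <- total - 1L - bin
    tb <- tabulate(bin + 1L, nbins = total)
    profile <- profile + tb
  }
  s <- sum(profile)
  if (s == 0) {
    warning("No anchors near genes; returning a zero profile")
    return(profile)
  }
  profile / s
}

#' Count anchors in the strand-aware upstream flank of each gene
#' @param chrom,pos Anchor positions (0-based).
#' @param genes A `gene_models` object.
#' @param flank Upstream width in bp.
#' @return Named integer vector: gene_id -> anchor count.
#' @export
count_upstream_anchors <- function(chrom, pos, genes, flank = 2000L) {
  iv <- flank_intervals(genes, flank, "up")
  out <- setNames(integer(nrow(iv)), genes$genes$gene_id)
  for (i in seq_len(nrow(iv))) {
    out[i] <- sum(chrom == iv$chrom[i] & pos >= iv$start[i] &
                    pos < iv$end[i])
  }
  out
}

#' Genes with enriched upstream anchor depth in one group over another
#'
#' Counts are normalized to per-accession depth (count / group size)
#' before the ratio. The test is inclusive (`>= ratio`); a zero numerator
#' is always excluded, and a zero denominator is guarded by the
#' pseudocount `1 / denominator group size` so that strong signal over an
#' empty background still qualifies.
#'
#' @param num_counts,den_counts Named per-gene anchor counts for the
#'   numerator group (e.g. landrace) and denominator group (e.g.
#'   teosinte), as from [count_upstream_anchors()].
#' @param num_size,den_size Accessions per group.
#' @param ratio Enrichment ratio cutoff (default 5, inclusive).
#' @return Character vector of enriched gene ids.
#' @export
upstream_enrichment <- function(num_counts, den_counts, num_size,
                                den_size, ratio = 5) {
  if (missing(num_counts) || missing(den_counts)) {
    stop("Both groups' counts are required")
  }
  genes <- union(names(num_counts), names(den_counts))
  a <- setNames(rep(0, length(genes)), genes)
  b <- a
  a[names(num_counts)] <- num_counts / num_size
  b[names(den_counts)] <- den_counts / den_size
  pseudo <- 1 / den_size
  denom <- ifelse(b > 0, b, pseudo)
  sort(genes[a > 0 & a / denom >= ratio])
}
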