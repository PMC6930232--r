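# SAM-based evidence import: the path real data takes (external aligner
# output) into the same retention logic as the built-in scan.

FLAG_PAIRED <- 0x1L
FLAG_UNMAPPED <- 0x4L
FLAG_REVERSE <- 0x10L
FLAG_MATE1 <- 0x40L
FLAG_MATE2 <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

scan_sam <- function(sam_path) {
  bam <- tryCatch(
    Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE),
    error = function(e) stop("SAM parse error in '", sam_path, "': ",
                             conditionMessage(e)))
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  data.frame(qname = x$qname, flag = x$flag,
             rname = as.character(x$rname), pos = x$pos, mapq = x$mapq,
             seq = as.character(x$seq), stringsAsFactors = FALSE)
}

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Import anchor evidence from external alignments (SAM)
#'
#' `sam_vs_te` holds both mates of every pair aligned against the TE
#' library (reference names `family|superfamily|index`); `sam_vs_genome`
#' holds the TE-unmapped mates aligned against the genome. Retention
#' mirrors [scan_pairs()]: a pair counts when exactly one mate has any TE
#' alignment, and the genomic anchor must be unique — primary, not
#' secondary/supplementary, MAPQ at least `min_mapq`.
#'
#' @param sam_vs_te,sam_vs_genome SAM file paths (headers required).
#' @param accession Accession name recorded in the evidence.
#' @param min_mapq Minimum MAPQ for a unique genomic anchor (default 20).
#' @return Evidence `data.frame` as from [scan_pairs()].
#' @export
import_sam_evidence <- function(sam_vs_te, sam_vs_genome, accession,
                                min_mapq = 20L) {
  te <- scan_sam(sam_vs_te)
  ge <- scan_sam(sam_vs_genome)

  te$mapped <- !has_flag(te$flag, FLAG_UNMAPPED)
  bad <- te$mapped & !grepl("|", te$rname, fixed = TRUE)
  if (any(bad)) {
    stop("TE reference name '", te$rname[which(bad)[1L]],
         "' does not follow the family|superfamily|index convention")
  }
  te$mate <- ifelse(has_flag(te$flag, FLAG_MATE1), 1L,
                    ifelse(has_flag(te$flag, FLAG_MATE2), 2L, NA_integer_))
  if (anyNA(te$mate)) {
    stop("TE SAM contains records without a mate-1/mate-2 flag")
  }
  # per pair: which mates have at least one TE alignment
  agg <- data.table::as.data.table(te)[
    , .(m1 = any(mapped & mate == 1L), m2 = any(mapped & mate == 2L)),
    by = qname]
  discordant <- agg[xor(m1, m2)]
  te_mate_of <- setNames(ifelse(discordant$m1, 1L, 2L), discordant$qname)

  # family + original sequence of the TE-mapped mate (primary record;
  # undo reverse-complement storage for minus-strand alignments)
  dt_te <- data.table::as.data.table(te)
  prim <- dt_te[mapped & !has_flag(flag, FLAG_SECONDARY) &
                  !has_flag(flag, FLAG_SUPPLEMENTARY)]
  prim <- prim[qname %in% names(te_mate_of)]
  prim <- prim[mate == te_mate_of[qname]]
  prim <- prim[!duplicated(qname)]
  prim[, te_seq := data.table::fifelse(
    has_flag(flag, FLAG_REVERSE) & seq != "",
    reverse_complement(seq), seq)]
  fam_of <- setNames(te_target_family(prim$rname), prim$qname)
  seq_of <- setNames(prim$te_seq, prim$qname)

  ok <- !has_flag(ge$flag, FLAG_UNMAPPED) &
    !has_flag(ge$flag, FLAG_SECONDARY) &
    !has_flag(ge$flag, FLAG_SUPPLEMENTARY) &
    ge$mapq >= min_mapq &
    ge$qname %in% names(te_mate_of)
  anchors <- ge[ok, , drop = FALSE]
  anchors <- anchors[!duplicated(anchors$qname), , drop = FALSE]
  data.frame(accession = rep(accession, nrow(anchors)),
             family = unname(fam_of[anchors$qname]),
             chrom = anchors$rname,
             anchor_pos = anchors$pos - 1L,
             pair_id = anchors$qname,
             te_mate_seq = unname(seq_of[anchors$qname]),
             stringsAsFactors = FALSE)
}

sam_record <- function(qname, flag, rname, pos, mapq, seq) {
  cigar <- ifelse(has_flag(flag, FLAG_UNMAPPED), "*",
                  paste0(nchar(seq), "M"))
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

#' Export the built-in scan's mappings as SAM files
#'
#' Writes the two SAM files that [import_sam_evidence()] consumes: both
#' mates against the TE library, and the TE-unmapped mates of retained
#' pairs against the genome. Unique alignments get MAPQ 60, multi-mapping
#' ones MAPQ 0. Used to cross-check the two evidence paths against each
#' other.
#'
#' @param scan Result of [scan_pairs()] with `keep_mappings = TRUE`.
#' @param te_index,genome_index The indexes used for the scan.
#' @param te_sam,genome_sam Output SAM paths.
#' @export
export_scan_sam <- function(scan, te_index, genome_index, te_sam,
                            genome_sam) {
  stopifnot(is.list(scan), !is.null(scan$te_map1))
  header <- function(idx) {
    c("@HD\tVN:1.6\tSO:unknown",
      paste0("@SQ\tSN:", idx$seq_names, "\tLN:", idx$seq_lens))
  }
  rec_for <- function(map, reads, mate_flag) {
    flag <- FLAG_PAIRED + mate_flag +
      ifelse(map$status == "unmapped", FLAG_UNMAPPED, 0L) +
      ifelse(!is.na(map$strand) & map$strand == "-", FLAG_REVERSE, 0L)
    seq <- unname(reads[map$read])
    seq <- ifelse(!is.na(map$strand) & map$strand == "-",
                  reverse_complement(seq), seq)
    sam_record(map$read, flag,
               ifelse(map$status == "unmapped", "*", map$target),
               ifelse(map$status == "unmapped", 0L, map$pos + 1L),
               ifelse(map$status == "unique", 60L, 0L), seq)
  }
  writeLines(c(header(te_index),
               rec_for(scan$te_map1, scan$reads1, FLAG_MATE1),
               rec_for(scan$te_map2, scan$reads2, FLAG_MATE2)), te_sam)

  gm <- scan$genome_map
  anchor_is_mate1 <- !scan$te_mapped_is_mate1
  reads <- ifelse(anchor_is_mate1, scan$reads1[scan$retained],
                  scan$reads2[scan$retained])
  names(reads) <- scan$retained
  flag_mate <- ifelse(anchor_is_mate1, FLAG_MATE1, FLAG_MATE2)
  flag <- FLAG_PAIRED + flag_mate +
    ifelse(gm$status == "unmapped", FLAG_UNMAPPED, 0L) +
    ifelse(!is.na(gm$strand) & gm$strand == "-", FLAG_REVERSE, 0L)
  seq <- unname(reads[gm$read])
  seq <- ifelse(!is.na(gm$strand) & gm$strand == "-",
                reverse_complement(seq), seq)
  writeLines(c(header(genome_index),
               sam_record(gm$read, flag,
                          ifelse(gm$status == "unmapped", "*", gm$target),
                          ifelse(gm$status == "unmapped", 0L, gm$pos + 1L),
                          ifelse(gm$status == "unique", 60L, 0L), seq)),
             genome_sam)
  invisible(c(te_sam, genome_sam))
}
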