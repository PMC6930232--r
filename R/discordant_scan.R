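# Discordant-pair scan: seed-and-extend read mapping against the TE
# library and the genome, retaining pairs where exactly one mate hits the
# TE reference and the other anchors uniquely on the genome.

canonical_kmers <- function(kmers) {
  rc <- reverse_complement(kmers)
  fwd <- kmers <= rc
  kmers[!fwd] <- rc[!fwd]
  list(kmer = kmers, fwd = fwd)
}

#' Build a k-mer seed index over a set of sequences
#'
#' Indexes every overlapping k-mer of every sequence under its canonical
#' (lexicographically smaller of forward / reverse complement) form, so a
#' single lookup serves both strands. Used as the alignment stand-in for
#' an external short-read aligner on synthetic data.
#'
#' @param reference Named character vector of sequences, a FASTA path, or
#'   a `te_library` (flattened to `family|superfamily|index` targets).
#' @param k Seed length in bp (default 31, minimum 11).
#' @return A `seed_index` object.
#' @export
build_seed_index <- function(reference, k = 31L) {
  if (inherits(reference, "te_library")) {
    seqs <- character()
    for (f in names(reference$families)) {
      m <- reference$families[[f]]
      names(m) <- paste(f, reference$superfamily_of[[f]],
                        seq_along(m), sep = "|")
      seqs <- c(seqs, m)
    }
  } else if (is.character(reference) && length(reference) == 1L &&
             file.exists(reference)) {
    seqs <- read_fasta(reference)
  } else {
    seqs <- reference
  }
  k <- as.integer(k)
  stopifnot(k >= 11L)
  if (length(seqs) == 0L) stop("Cannot index an empty reference")
  lens <- nchar(seqs)
  if (all(lens < k)) {
    stop("k = ", k, " exceeds every reference sequence length; ",
         "the index would be empty")
  }
  tabs <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    n <- lens[i]
    if (n < k) next
    km <- substring(seqs[[i]], 1:(n - k + 1L), k:n)
    can <- canonical_kmers(km)
    tabs[[i]] <- data.table::data.table(kmer = can$kmer, tid = i,
                                        tpos = 0:(n - k), tfwd = can$fwd)
  }
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)
  concat <- paste(seqs, collapse = "")
  structure(list(k = k, dt = dt, seq_names = names(seqs), seq_lens = lens,
                 offsets = c(0L, cumsum(lens))[seq_along(seqs)],
                 raw = charToRaw(concat)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("Seed index: k =", x$k, "over", length(x$seq_names),
      "sequences (", sum(x$seq_lens), "bp,", nrow(x$dt), "k-mers)\n")
  invisible(x)
}

#' Map reads against a seed index
#'
#' Seed-and-extend: `n_seeds` evenly spaced k-mers per read are looked up
#' in the index; candidate (target, strand, diagonal) loci supported by at
#' least `min_seed_hits` distinct seeds are extended by full-length
#' ungapped comparison. A locus passes when its mismatch count is at most
#' `floor(max_mismatch_frac * read_length)`. A read is `unique` when one
#' passing locus exists, or when the best passing locus beats the
#' runner-up by at least 2 mismatches; `multi` when several pass without a
#' clear winner; `unmapped` otherwise.
#'
#' @param reads Named character vector of read sequences.
#' @param index A `seed_index`.
#' @param min_seed_hits Distinct seed hits required per candidate locus.
#' @param max_mismatch_frac Maximum mismatch fraction of the read length.
#' @param n_seeds Seeds per read.
#' @return `data.frame` with one row per read: `read`, `status`
#'   (`unique`/`multi`/`unmapped`), `target`, `pos` (0-based leftmost),
#'   `strand`, `mismatches` (best passing hit, `NA` when unmapped), and
#'   `n_pass` (number of passing loci).
#' @export
map_reads <- function(reads, index, min_seed_hits = 2L,
                      max_mismatch_frac = 0.05, n_seeds = 4L) {
  stopifnot(inherits(index, "seed_index"))
  nr <- length(reads)
  res <- data.table::data.table(
    read = names(reads) %||% as.character(seq_len(nr)),
    status = rep("unmapped", nr), target = NA_character_,
    pos = NA_integer_, strand = NA_character_,
    mismatches = NA_integer_, n_pass = 0L)
  if (nr == 0L) return(as.data.frame(res))
  k <- index$k
  lens <- nchar(reads)
  ok <- which(lens >= k)
  if (length(ok) == 0L) return(as.data.frame(res))

  # seed table over all eligible reads (offsets shared per read length)
  ulen <- unique(lens[ok])
  offs_list <- lapply(ulen, function(L)
    unique(as.integer(round(seq(0L, L - k, length.out = n_seeds)))))
  names(offs_list) <- as.character(ulen)
  n_off <- vapply(offs_list, length, 0L)[as.character(lens[ok])]
  q <- data.table::data.table(
    rid = rep(ok, n_off),
    off = unlist(offs_list[as.character(lens[ok])], use.names = FALSE))
  q[, kmer := substring(reads[rid], off + 1L, off + k)]
  can <- canonical_kmers(q$kmer)
  q[, `:=`(kmer = can$kmer, qfwd = can$fwd)]

  hits <- index$dt[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(as.data.frame(res))
  hits[, fwd := tfwd == qfwd]
  hits[, rlen := lens[rid]]
  hits[, start := data.table::fifelse(
    fwd, tpos - off, tpos - (rlen - k - off))]
  hits <- hits[start >= 0L & start + rlen <= index$seq_lens[tid]]
  if (nrow(hits) == 0L) return(as.data.frame(res))
  cand <- hits[, .(nseed = data.table::uniqueN(off), rlen = rlen[1L]),
               by = .(rid, tid, fwd, start)]
  cand <- cand[nseed >= min_seed_hits]
  if (nrow(cand) == 0L) return(as.data.frame(res))

  # ungapped extension on concatenated byte arrays
  used <- sort(unique(cand$rid))
  fwd_cat <- paste(reads[used], collapse = "")
  rc_cat <- paste(reverse_complement(reads[used]), collapse = "")
  q_off <- c(0L, cumsum(lens[used]))[seq_along(used)]
  names(q_off) <- as.character(used)
  qraw <- charToRaw(fwd_cat)
  qraw_rc <- charToRaw(rc_cat)
  cand[, qstart := q_off[as.character(rid)]]
  cand[, tstart := index$offsets[tid] + start]
  mm_f <- cand$fwd
  mm <- integer(nrow(cand))
  if (any(mm_f)) {
    mm[mm_f] <- .mismatch_counts(index$raw, cand$tstart[mm_f], qraw,
                                 cand$qstart[mm_f], cand$rlen[mm_f])
  }
  if (any(!mm_f)) {
    mm[!mm_f] <- .mismatch_counts(index$raw, cand$tstart[!mm_f], qraw_rc,
                                  cand$qstart[!mm_f], cand$rlen[!mm_f])
  }
  cand[, mm := mm]
  cand <- cand[mm <= floor(max_mismatch_frac * rlen)]
  if (nrow(cand) == 0L) return(as.data.frame(res))

  data.table::setorder(cand, rid, mm)
  best <- cand[, .(target = index$seq_names[tid[1L]], pos = start[1L],
                   strand = data.table::fifelse(fwd[1L], "+", "-"),
                   mismatches = mm[1L], n_pass = .N,
                   second = if (.N > 1L) mm[2L] else NA_integer_),
               by = rid]
  best[, status := data.table::fifelse(
    n_pass == 1L | (!is.na(second) & mismatches + 2L <= second),
    "unique", "multi")]
  res[best$rid, `:=`(status = best$status, target = best$target,
                     pos = best$pos, strand = best$strand,
                     mismatches = best$mismatches, n_pass = best$n_pass)]
  as.data.frame(res)
}

#' Map a single read
#'
#' Convenience wrapper around [map_reads()].
#' @inheritParams map_reads
#' @param read A single read sequence.
#' @return List with `status`, `chrom`, `pos`, `strand`, `target_label`.
#' @export
map_read <- function(read, index, min_seed_hits = 2L,
                     max_mismatch_frac = 0.05, n_seeds = 4L) {
  r <- map_reads(setNames(read, "r"), index, min_seed_hits,
                 max_mismatch_frac, n_seeds)
  list(status = r$status, chrom = if (is.na(r$target)) NULL else r$target,
       pos = if (is.na(r$pos)) NULL else r$pos,
       strand = if (is.na(r$strand)) NULL else r$strand,
       target_label = if (is.na(r$target)) NULL else r$target)
}

te_target_family <- function(target) {
  vapply(strsplit(target, "|", fixed = TRUE), `[`, "", 1L)
}

#' Scan read pairs for TE-insertion anchor evidence
#'
#' Both mates of every pair are mapped against the TE family library; a
#' pair is retained when exactly one mate hits the library (any hit —
#' families are internally repetitive, so TE-side uniqueness is not
#' required). The TE-unmapped mate is then mapped against the genome and
#' evidence is emitted only when that anchor mapping is unique. The family
#' label comes from the TE-mapped mate's best hit.
#'
#' @param fastq1,fastq2 Paths to the paired FASTQ files (optionally
#'   gzipped), or named character vectors of read sequences.
#' @param te_library A `te_library`, FASTA path, or prebuilt `seed_index`.
#' @param genome Named chromosome sequences, FASTA path, or `seed_index`.
#' @param accession Accession name recorded in the evidence.
#' @param min_seed_hits,max_mismatch_frac,n_seeds Mapper settings, see
#'   [map_reads()].
#' @param keep_mappings Also return the per-mate mapping tables (used for
#'   SAM export and debugging).
#' @return `data.frame` of anchor evidence: `accession`, `family`,
#'   `chrom`, `anchor_pos` (0-based leftmost), `pair_id`, `te_mate_seq`.
#'   With `keep_mappings = TRUE`, a list `(evidence, te_map1, te_map2,
#'   genome_map, reads1, reads2)`.
#' @export
scan_pairs <- function(fastq1, fastq2, te_library, genome, accession,
                       min_seed_hits = 2L, max_mismatch_frac = 0.05,
                       n_seeds = 4L, keep_mappings = FALSE) {
  r1 <- if (is.character(fastq1) && length(fastq1) == 1L &&
            file.exists(fastq1)) read_fastq(fastq1) else fastq1
  r2 <- if (is.character(fastq2) && length(fastq2) == 1L &&
            file.exists(fastq2)) read_fastq(fastq2) else fastq2
  if (length(r1) != length(r2)) {
    stop("Pairing error: ", length(r1), " mate-1 reads vs ", length(r2),
         " mate-2 reads")
  }
  if (!is.null(names(r1)) && !is.null(names(r2)) &&
      !identical(names(r1), names(r2))) {
    stop("Pairing error: read names of the two files do not match")
  }
  te_idx <- if (inherits(te_library, "seed_index")) te_library else
    build_seed_index(te_library)
  g_idx <- if (inherits(genome, "seed_index")) genome else
    build_seed_index(genome)

  m1 <- map_reads(r1, te_idx, min_seed_hits, max_mismatch_frac, n_seeds)
  m2 <- map_reads(r2, te_idx, min_seed_hits, max_mismatch_frac, n_seeds)
  te1 <- m1$status != "unmapped"
  te2 <- m2$status != "unmapped"
  keep <- xor(te1, te2)

  anchor_reads <- ifelse(te1[keep], r2[keep], r1[keep])
  names(anchor_reads) <- names(r1)[keep]
  gm <- map_reads(anchor_reads, g_idx, min_seed_hits, max_mismatch_frac,
                  n_seeds)
  ok <- gm$status == "unique"
  te_target <- ifelse(te1[keep], m1$target[keep], m2$target[keep])
  fam <- te_target_family(te_target)
  evidence <- data.frame(
    accession = rep(accession, sum(ok)),
    family = fam[ok],
    chrom = gm$target[ok],
    anchor_pos = gm$pos[ok],
    pair_id = names(anchor_reads)[ok],
    te_mate_seq = unname(ifelse(te1[keep], r1[keep], r2[keep]))[ok],
    stringsAsFactors = FALSE)
  if (!keep_mappings) return(evidence)
  list(evidence = evidence, te_map1 = m1, te_map2 = m2, genome_map = gm,
       reads1 = r1, reads2 = r2, retained = names(r1)[keep],
       te_mapped_is_mate1 = te1[keep])
}

#' Write / read anchor evidence as TSV
#' @param evidence Evidence `data.frame` from [scan_pairs()].
#' @param path TSV path.
#' @export
write_evidence <- function(evidence, path) write_tsv(evidence, path)

#' @rdname write_evidence
#' @export
read_evidence <- function(path) read_tsv(path)
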