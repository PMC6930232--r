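# Synthetic cohort with known TE-insertion truth: toy genome with planted
# reference TE copies, group-structured insertion pools, paired-end reads.

#' Describe a synthetic cohort
#'
#' Defaults describe the package's reference desk-scale cohort: three
#' germplasm groups (teosinte, landrace, improved) of four accessions each
#' on one 2 Mb chromosome; three 5 kb TE families with 25 planted reference
#' copies each; insertion pools of 10 shared loci, group pools of 15/30/5
#' loci (teosinte/landrace/improved — amplification during domestication,
#' contraction during improvement), and 5 private loci per accession;
#' 5X paired-end 2x100 bp coverage with 300+-30 bp fragments and 0.5%
#' per-base substitution error.
#'
#' @param genome_length Chromosome length in bp.
#' @param n_chroms Number of chromosomes.
#' @param n_families Number of TE families.
#' @param te_length Family element length in bp.
#' @param n_ref_copies Planted reference copies per family.
#' @param groups Named integer vector: accessions per group.
#' @param pool_shared Number of insertion loci shared by every accession.
#' @param pool_per_group Named integer vector (or scalar): loci shared by
#'   all accessions of one group only.
#' @param pool_private Private insertion loci per accession.
#' @param coverage Fold sequencing coverage.
#' @param read_length Read length in bp.
#' @param fragment_mean,fragment_sd Fragment length distribution (bp).
#' @param error_rate Per-base substitution probability.
#' @param divergence Per-base divergence of planted family members from the
#'   family prototype (members are non-identical, as in real libraries).
#' @param seed Integer master seed; all streams derive from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(genome_length = 2e6L, n_chroms = 1L,
                        n_families = 3L, te_length = 5000L,
                        n_ref_copies = 25L,
                        groups = c(teosinte = 4L, landrace = 4L,
                                   improved = 4L),
                        pool_shared = 10L,
                        pool_per_group = c(teosinte = 15L, landrace = 30L,
                                           improved = 5L),
                        pool_private = 5L,
                        coverage = 5, read_length = 100L,
                        fragment_mean = 300, fragment_sd = 30,
                        error_rate = 0.005, divergence = 0.01,
                        seed = 7L) {
  groups <- unlist(groups)            # accept YAML-style named lists
  pool_per_group <- unlist(pool_per_group)
  stopifnot(coverage > 0, read_length < fragment_mean,
            error_rate >= 0, error_rate < 1,
            pool_shared >= 0, all(pool_per_group >= 0), pool_private >= 0,
            n_families >= 1, length(groups) >= 1, all(groups >= 1))
  if (is.null(names(groups))) stop("groups must be named")
  if (length(pool_per_group) == 1L && is.null(names(pool_per_group))) {
    pool_per_group <- setNames(rep(pool_per_group, length(groups)),
                               names(groups))
  }
  if (!all(names(groups) %in% names(pool_per_group))) {
    stop("pool_per_group must name every group")
  }
  structure(list(genome_length = as.integer(genome_length),
                 n_chroms = as.integer(n_chroms),
                 n_families = as.integer(n_families),
                 te_length = as.integer(te_length),
                 n_ref_copies = as.integer(n_ref_copies),
                 groups = groups, pool_shared = as.integer(pool_shared),
                 pool_per_group = pool_per_group[names(groups)],
                 pool_private = as.integer(pool_private),
                 coverage = coverage, read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 error_rate = error_rate, divergence = divergence,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# i.i.d. substitutions at `rate` per base (no indels).
mutate_sequences <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  for (i in which(n_err > 0L)) {
    s <- seqs[[i]]
    for (p in sample.int(lens[i], n_err[i])) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(bases[bases != cur], 1L)
    }
    seqs[[i]] <- s
  }
  seqs
}

# Rejection-sample `n` start positions of `width`-bp intervals on a
# chromosome of `len` bp, keeping every placed interval >= spacing away
# from the others, from `occupied` intervals (matrix: start, end) and
# `pad` away from chromosome ends.
place_positions <- function(n, len, occupied, spacing, pad, width = 0L,
                            what = "loci") {
  pos <- integer(0)
  tries <- 0L
  while (length(pos) < n) {
    tries <- tries + 1L
    if (tries > 200L * max(n, 1L)) {
      stop("Could not place ", n, " ", what, " with ", spacing,
           " bp spacing on a ", len, " bp chromosome; ",
           "reduce pool sizes or enlarge the genome")
    }
    p <- as.integer(floor(runif(1L, pad, len - pad - width)))
    if (length(pos) && any(p < pos + width + spacing &
                           p + width + spacing > pos)) next
    if (nrow(occupied) &&
        any(p + width > occupied[, 1L] - spacing &
            p < occupied[, 2L] + spacing)) next
    pos <- c(pos, p)
  }
  sort(pos)
}

#' Generate a synthetic cohort with known insertion truth
#'
#' Builds a random reference genome with full-length TE family copies
#' planted at annotated positions (so the family-size filter has members to
#' count), draws shared / per-group / private insertion loci well away from
#' the planted copies and from each other, and realizes each accession's
#' donor genome by literally inserting a full family member copy at every
#' truth locus. Truth positions are reference coordinates. Families are
#' assigned to pool loci round-robin so every family participates in every
#' pool. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory; when given, writes `reference.fa`,
#'   `te_library.fa`, `te_annotation.bed`, `truth.tsv`, `genes.gff3`.
#' @return List with `reference` (named chromosome sequences), `te_bed`
#'   (annotation data.frame), `library` (`te_library`), `truth`
#'   (data.frame: accession, group, family, chrom, position), `donors`
#'   (named list of donor genomes), `genes` (gene model table, see
#'   [load_genes()]), and `spec`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(salt_seed(spec$seed, "cohort"))
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  reference <- setNames(
    vapply(chroms, function(x) random_dna(spec$genome_length), ""), chroms)

  fam_names <- sprintf("fam%02d", seq_len(spec$n_families))
  superfams <- rep_len(c("Copia", "Gypsy"), spec$n_families)
  prototypes <- setNames(
    vapply(fam_names, function(x) random_dna(spec$te_length), ""), fam_names)

  spacing <- as.integer(2 * spec$fragment_mean)
  pad <- as.integer(4 * spec$fragment_mean)

  # plant reference copies, replacing genome sequence in place
  bed <- list()
  members <- setNames(vector("list", spec$n_families), fam_names)
  occupied <- setNames(rep(list(matrix(0, 0, 2)), spec$n_chroms), chroms)
  for (fi in seq_len(spec$n_families)) {
    fam <- fam_names[fi]
    copy_chroms <- sample(chroms, spec$n_ref_copies, replace = TRUE)
    for (chrom in chroms) {
      n_here <- sum(copy_chroms == chrom)
      if (n_here == 0L) next
      starts <- place_positions(n_here, spec$genome_length,
                                occupied[[chrom]], spacing, pad,
                                width = spec$te_length,
                                what = "reference TE copies")
      for (s in starts) {
        copy <- mutate_sequences(prototypes[[fam]], spec$divergence)
        substr(reference[[chrom]], s + 1L, s + spec$te_length) <- copy
        members[[fam]] <- c(members[[fam]], copy)
        bed[[length(bed) + 1L]] <- data.frame(
          chrom = chrom, start = s, end = s + spec$te_length,
          name = paste0(fam, "#", superfams[fi]))
        occupied[[chrom]] <- rbind(occupied[[chrom]],
                                   c(s, s + spec$te_length))
      }
    }
  }
  te_bed <- do.call(rbind, bed)
  lib <- structure(list(
    families = lapply(members, unlist),
    superfamily_of = setNames(superfams, fam_names),
    member_count = vapply(members, length, 0L)), class = "te_library")

  # insertion loci: one global placement pass keeps every locus clear of
  # planted copies and of every other locus
  n_acc_total <- sum(spec$groups)
  pool_names <- c("shared", paste0("group:", names(spec$groups)),
                  unlist(lapply(names(spec$groups), function(g)
                    paste0("private:", g, seq_len(spec$groups[[g]])))))
  pool_n <- c(spec$pool_shared, unname(spec$pool_per_group),
              rep(spec$pool_private, n_acc_total))
  total_loci <- sum(pool_n)
  loci <- data.frame(pool = rep(pool_names, pool_n),
                     chrom = character(total_loci),
                     position = integer(total_loci),
                     family = character(total_loci),
                     member = integer(total_loci),
                     stringsAsFactors = FALSE)
  if (total_loci > 0L) {
    loci$chrom <- sample(chroms, total_loci, replace = TRUE)
    for (chrom in chroms) {
      idx <- which(loci$chrom == chrom)
      if (!length(idx)) next
      placed <- place_positions(length(idx), spec$genome_length,
                                occupied[[chrom]], spacing, pad,
                                what = "insertion loci")
      loci$position[idx] <- placed[sample.int(length(placed))]
    }
    # round-robin family assignment within each pool (balanced design)
    for (p in unique(loci$pool)) {
      idx <- which(loci$pool == p)
      loci$family[idx] <- fam_names[((seq_along(idx) - 1L) %%
                                       spec$n_families) + 1L]
    }
    loci$member <- vapply(loci$family, function(f)
      sample.int(length(lib$families[[f]]), 1L), 0L)
  }

  # truth table: shared + own group pool + own private pool
  accessions <- unlist(lapply(names(spec$groups), function(g)
    paste0(substr(g, 1, 1), toupper(substr(g, 2, 2)),
           "_", seq_len(spec$groups[[g]]))), use.names = FALSE)
  acc_group <- rep(names(spec$groups), spec$groups)
  truth <- list()
  for (i in seq_along(accessions)) {
    g <- acc_group[i]
    k <- sum(acc_group[seq_len(i)] == g)  # index within group
    mine <- loci$pool %in% c("shared", paste0("group:", g),
                             paste0("private:", g, k))
    if (!any(mine)) next
    truth[[i]] <- data.frame(accession = accessions[i], group = g,
                             family = loci$family[mine],
                             chrom = loci$chrom[mine],
                             position = loci$position[mine])
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(accession = character(), group = character(),
               family = character(), chrom = character(),
               position = integer())
  truth <- truth[order(truth$accession, truth$chrom, truth$position), ]
  rownames(truth) <- NULL

  # donor genomes: insert full member copies right-to-left so reference
  # coordinates stay valid during construction
  donors <- setNames(vector("list", length(accessions)), accessions)
  for (i in seq_along(accessions)) {
    donor <- reference
    rows <- truth[truth$accession == accessions[i], , drop = FALSE]
    if (nrow(rows)) {
      rows <- rows[order(rows$chrom, -rows$position), ]
      key <- match(paste(rows$chrom, rows$position), paste(loci$chrom, loci$position))
      for (j in seq_len(nrow(rows))) {
        fam <- rows$family[j]
        ins <- lib$families[[fam]][loci$member[key[j]]]
        p <- rows$position[j]
        chrom <- rows$chrom[j]
        donor[[chrom]] <- paste0(substr(donor[[chrom]], 1L, p), ins,
                                 substr(donor[[chrom]], p + 1L,
                                        nchar(donor[[chrom]])))
      }
    }
    donors[[i]] <- donor
  }

  genes <- toy_gene_models(spec)
  groups_tab <- data.frame(accession = accessions, group = acc_group)

  out <- list(reference = reference, te_bed = te_bed, library = lib,
              truth = truth, donors = donors, genes = genes,
              groups = groups_tab, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(reference, file.path(out_dir, "reference.fa"))
    write_te_library(lib, file.path(out_dir, "te_library.fa"))
    utils::write.table(te_bed, file.path(out_dir, "te_annotation.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    write_truth(truth, file.path(out_dir, "truth.tsv"))
    write_tsv(groups_tab, file.path(out_dir, "groups.tsv"))
    write_genes_gff3(genes, file.path(out_dir, "genes.gff3"))
  }
  out
}

# Uniformly spaced toy genes (3 exons, alternating strand) for the
# genomic-context module; purely an annotation layer over the genome.
toy_gene_models <- function(spec, gene_every = 50000L, gene_length = 3000L) {
  rows <- list()
  gid <- 0L
  for (ci in seq_len(spec$n_chroms)) {
    starts <- seq(10000L, spec$genome_length - gene_length - 10000L,
                  by = gene_every)
    for (s in starts) {
      gid <- gid + 1L
      rows[[gid]] <- data.frame(
        gene_id = sprintf("gene%04d", gid),
        chrom = paste0("chr", ci),
        strand = if (gid %% 2L == 1L) "+" else "-",
        start = s, end = s + gene_length)
    }
  }
  genes <- do.call(rbind, rows)
  exon_template <- rbind(c(0L, 600L), c(1200L, 2000L), c(2600L, 3000L))
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
               start = genes$start[i] + exon_template[, 1L],
               end = genes$start[i] + exon_template[, 2L])
  }))
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Simulate paired-end reads from a donor genome
#'
#' Fragment count is `floor(coverage * genome_length / (2 * read_length))`
#' per chromosome (lengths of the donor, not the reference). Fragment
#' lengths are Normal(`fragment_mean`, `fragment_sd`) truncated to
#' `[read_length, 3 * fragment_mean]`; starts are uniform; mate 2 is the
#' reverse complement of the fragment end; substitution errors are i.i.d.
#' at `error_rate`. Read names encode `accession:index:chrom:start:len`.
#' The stream is salted with the accession name, so per-accession
#' simulation is order-independent and reproducible.
#'
#' @param donor Named character vector of donor chromosome sequences.
#' @param spec A [cohort_spec()].
#' @param accession Accession name (also the seed salt).
#' @param out_prefix Optional path prefix; writes `<prefix>_1.fq.gz` and
#'   `<prefix>_2.fq.gz`.
#' @return List with `r1`, `r2` (named sequence vectors) and, if written,
#'   `files`.
#' @export
simulate_paired_reads <- function(donor, spec, accession,
                                  out_prefix = NULL) {
  stopifnot(length(donor) >= 1L, all(nchar(donor) > 0L))
  set.seed(salt_seed(spec$seed, paste0("reads:", accession)))
  L <- spec$read_length
  r1 <- r2 <- nm <- character(0)
  for (chrom in names(donor)) {
    glen <- nchar(donor[[chrom]])
    n_pairs <- floor(spec$coverage * glen / (2 * L))
    if (n_pairs < 1L) next
    flen <- round(rnorm(n_pairs, spec$fragment_mean, spec$fragment_sd))
    flen <- pmin(pmax(flen, L), 3 * spec$fragment_mean)
    flen <- pmin(flen, glen)
    start <- floor(runif(n_pairs) * (glen - flen + 1)) + 1  # 1-based
    m1 <- substring(donor[[chrom]], start, start + L - 1)
    m2 <- reverse_complement(
      substring(donor[[chrom]], start + flen - L, start + flen - 1))
    r1 <- c(r1, m1)
    r2 <- c(r2, m2)
    nm <- c(nm, paste(accession, seq_along(m1), chrom, start - 1, flen,
                      sep = ":"))
  }
  r1 <- setNames(mutate_sequences(r1, spec$error_rate), nm)
  r2 <- setNames(mutate_sequences(r2, spec$error_rate), nm)
  out <- list(r1 = r1, r2 = r2)
  if (!is.null(out_prefix)) {
    f1 <- paste0(out_prefix, "_1.fq.gz")
    f2 <- paste0(out_prefix, "_2.fq.gz")
    write_fastq(r1, nm, f1)
    write_fastq(r2, nm, f2)
    out$files <- c(f1, f2)
  }
  out
}

#' Write / read a ground-truth insertion table
#'
#' Columns `accession`, `group`, `family`, `chrom`, `position`; rows sorted
#' by accession, chromosome, position.
#' @param truth Truth `data.frame` (see [generate_cohort()]).
#' @param path Output TSV path.
#' @export
write_truth <- function(truth, path) {
  truth <- truth[order(truth$accession, truth$chrom, truth$position), ]
  write_tsv(truth, path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read_tsv(path)
}
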