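# Shared fixtures, built in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small six-accession cohort on a 300 kb chromosome; deep coverage so
# every planted insertion is comfortably supported.
tiny_spec <- function(error_rate = 0.005, seed = 11L) {
  cohort_spec(genome_length = 3e5L, n_families = 2L, te_length = 1000L,
              n_ref_copies = 5L,
              groups = c(teosinte = 2L, landrace = 2L, improved = 2L),
              pool_shared = 2L,
              pool_per_group = c(teosinte = 3L, landrace = 6L,
                                 improved = 1L),
              pool_private = 2L, coverage = 8, error_rate = error_rate,
              seed = seed)
}

tiny_cohort <- function() {
  memo("tiny_cohort", generate_cohort(tiny_spec()))
}

# Cohort plus a full scan/call pass over every accession.
tiny_run <- function() {
  memo("tiny_run", {
    coh <- tiny_cohort()
    te_idx <- build_seed_index(coh$library)
    g_idx <- build_seed_index(coh$reference)
    evs <- list()
    callsets <- list()
    for (acc in coh$groups$accession) {
      reads <- simulate_paired_reads(coh$donors[[acc]], coh$spec, acc)
      evs[[acc]] <- scan_pairs(reads$r1, reads$r2, te_idx, g_idx, acc)
      callsets[[acc]] <- call_insertions(evs[[acc]])
    }
    list(coh = coh, te_idx = te_idx, g_idx = g_idx, evs = evs,
         callsets = callsets)
  })
}

# Hand-built gene models: two genes on one chromosome, opposite strands.
toy_genes <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    strand = c("+", "-"),
    start = c(10000L, 50000L),
    end = c(13000L, 52000L))
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB"),
    chrom = "chr1",
    start = c(10000L, 12000L, 50000L),
    end = c(10500L, 13000L, 52000L))
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

# Evidence table builder for caller tests.
make_evidence <- function(positions, family = "fam01", chrom = "chr1",
                          accession = "acc1") {
  n <- length(positions)
  data.frame(accession = rep(accession, n), family = rep(family, n),
             chrom = rep(chrom, n), anchor_pos = as.integer(positions),
             pair_id = paste0("p", seq_len(n), recycle0 = TRUE),
             te_mate_seq = rep(strrep("A", 50L), n),
             stringsAsFactors = FALSE)
}
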