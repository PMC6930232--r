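# End-to-end pipeline: simulate -> scan -> call -> stats / pca / context,
# with a checksummed manifest and stage-level resume.

default_pipeline_config <- function() {
  list(window_size = 10000L, call_min_reads = 4L, copy_min_reads = 3L,
       common_threshold = 0.2, min_members = 20L, flank = 2000L,
       enrichment_ratio = 5, context_bin = 100000L)
}

validate_pipeline_config <- function(config) {
  bad <- character()
  num_pos <- c("window_size", "call_min_reads", "copy_min_reads",
               "min_members", "flank", "enrichment_ratio", "context_bin")
  for (k in num_pos) {
    if (!is.numeric(config[[k]]) || length(config[[k]]) != 1L ||
        config[[k]] <= 0) {
      bad <- c(bad, k)
    }
  }
  if (!is.numeric(config$common_threshold) ||
      config$common_threshold < 0 || config$common_threshold >= 1) {
    bad <- c(bad, "common_threshold")
  }
  if (is.null(config$out_dir)) bad <- c(bad, "out_dir")
  if (length(bad)) {
    stop("Invalid pipeline configuration key(s): ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(config)
}

stage_done <- function(manifest, stage, files) {
  rec <- manifest$stages[[stage]]
  if (is.null(rec)) return(FALSE)
  if (!all(file.exists(files))) return(FALSE)
  sums <- unname(tools::md5sum(files))
  identical(unname(unlist(rec$md5[files])), sums)
}

record_stage <- function(manifest, stage, files) {
  manifest$stages[[stage]] <- list(
    files = files, md5 = as.list(tools::md5sum(files)),
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  manifest
}

#' Run the full RIP pipeline on a synthetic cohort
#'
#' Executes simulate -> library -> scan -> call -> stats / pca / context
#' from a configuration (YAML path or list), writing TSV outputs and a
#' JSON manifest with per-stage file checksums under `out_dir`. Completed
#' stages whose outputs still match their recorded checksums are skipped
#' on rerun; per-accession stages are independent, so deleting one
#' accession's files recomputes only that accession. Deterministic given
#' the configured seed.
#'
#' Recognized keys (defaults in parentheses): `out_dir`; `cohort` — a list
#' of [cohort_spec()] arguments; `window_size` (10000), `call_min_reads`
#' (4), `copy_min_reads` (3), `common_threshold` (0.2), `min_members`
#' (20), `flank` (2000), `enrichment_ratio` (5), `context_bin` (100000).
#'
#' @param config YAML file path or configuration list.
#' @return The manifest (invisibly written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  config <- utils::modifyList(default_pipeline_config(), config)
  validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else {
    list(version = as.character(utils::packageVersion("ripscan")),
         stages = list())
  }
  manifest$config <- config

  spec <- do.call(cohort_spec, config$cohort %||% list())

  # --- simulate -------------------------------------------------------
  sim_files <- file.path(out_dir, c("reference.fa", "te_library.fa",
                                    "te_annotation.bed", "truth.tsv",
                                    "groups.tsv", "genes.gff3"))
  cohort <- NULL
  if (!stage_done(manifest, "simulate", sim_files)) {
    message("[simulate] generating cohort (seed ", spec$seed, ")")
    cohort <- generate_cohort(spec, out_dir = out_dir)
    manifest <- record_stage(manifest, "simulate", sim_files)
  }
  if (is.null(cohort)) cohort <- generate_cohort(spec)

  # --- TE library from the written annotation -------------------------
  intervals <- load_te_annotation(file.path(out_dir, "te_annotation.bed"))
  retained <- filter_families(intervals,
                              min_members = min(config$min_members,
                                                spec$n_ref_copies))
  lib <- extract_family_sequences(cohort$reference, intervals, retained)
  te_idx <- build_seed_index(lib)
  g_idx <- build_seed_index(cohort$reference)

  groups <- setNames(cohort$groups$group, cohort$groups$accession)
  accessions <- cohort$groups$accession

  # --- per-accession scan + call (order-invariant) --------------------
  callsets <- list()
  evidence_all <- list()
  for (acc in accessions) {
    ev_file <- file.path(out_dir, paste0(acc, ".evidence.tsv"))
    call_file <- file.path(out_dir, paste0(acc, ".calls.tsv"))
    if (stage_done(manifest, paste0("scan:", acc), c(ev_file, call_file))) {
      ev <- read_evidence(ev_file)
    } else {
      message("[scan] ", acc)
      reads <- simulate_paired_reads(cohort$donors[[acc]], spec, acc)
      ev <- scan_pairs(reads$r1, reads$r2, te_idx, g_idx, acc)
      write_evidence(ev, ev_file)
      cs_tmp <- call_insertions(ev, config$window_size,
                                config$call_min_reads)
      write_calls(cs_tmp, call_file)
      manifest <- record_stage(manifest, paste0("scan:", acc),
                               c(ev_file, call_file))
    }
    callsets[[acc]] <- call_insertions(ev, config$window_size,
                                       config$call_min_reads)
    evidence_all[[acc]] <- ev
  }

  # --- cohort statistics ----------------------------------------------
  message("[stats] RIP matrix and group statistics")
  rip <- build_rip_matrix(callsets, groups)
  write_rip_matrix(rip, file.path(out_dir, "rip_matrix.tsv"))
  sets <- group_rip_sets(rip)
  if (length(sets) == 3L) {
    venn <- venn_counts(sets)
    write_tsv(data.frame(region = names(venn$region_counts),
                         count = unname(venn$region_counts)),
              file.path(out_dir, "venn.tsv"))
  }
  cn <- lapply(callsets, copy_number, min_reads = config$copy_min_reads,
               per_family = TRUE)
  cn_summary <- family_copy_number_summary(cn, groups)
  write_tsv(cn_summary, file.path(out_dir, "copy_number_summary.tsv"))
  freq_rows <- lapply(unique(unname(groups)), function(g) {
    fr <- insertion_frequency(rip, g)
    common <- common_rip_fraction(fr, config$common_threshold)
    data.frame(group = g, mean_frequency = mean(fr),
               common_rip_fraction = common %||% NA_real_)
  })
  write_tsv(do.call(rbind, freq_rows),
            file.path(out_dir, "frequency_summary.tsv"))

  # --- PCA -------------------------------------------------------------
  pca <- rip_pca(compute_grm(encode_genotypes(rip)))
  write_pca(pca, groups, file.path(out_dir, "pca.tsv"))

  # --- genomic context -------------------------------------------------
  genes <- load_genes(file.path(out_dir, "genes.gff3"))
  chrom_lengths <- setNames(nchar(cohort$reference),
                            names(cohort$reference))
  ctx_rows <- list()
  for (g in unique(unname(groups))) {
    cls <- character(0)
    pts <- do.call(rbind, lapply(callsets[groups[accessions] == g],
                                 called_loci))
    if (!is.null(pts) && nrow(pts)) {
      cls <- classify_feature(pts$chrom, pts$insertion_point, genes,
                              config$flank)
      pct <- feature_class_percentages(cls)
      d <- distance_to_tss(pts$chrom, pts$insertion_point, genes)
      r <- megabase_density_correlation(pts$chrom, pts$insertion_point,
                                        genes, chrom_lengths,
                                        bin = config$context_bin)
      ctx_rows[[g]] <- data.frame(
        group = g, t(as.matrix(pct)), mean_tss_distance = mean(d,
                                                               na.rm = TRUE),
        density_gene_correlation = r %||% NA_real_, check.names = FALSE)
    }
  }
  if (length(ctx_rows)) {
    write_tsv(do.call(rbind, ctx_rows), file.path(out_dir, "context.tsv"))
  }

  stats_files <- file.path(out_dir, c("rip_matrix.tsv",
                                      "copy_number_summary.tsv",
                                      "frequency_summary.tsv", "pca.tsv"))
  manifest <- record_stage(manifest, "stats", stats_files)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Write / read an insertion call table as TSV
#' @param callset An `insertion_calls` object.
#' @param path TSV path.
#' @export
write_calls <- function(callset, path) {
  tab <- callset$table
  df <- data.frame(accession = rep(callset$accession,
                                   max(1L, nrow(tab)))[seq_len(nrow(tab))],
                   tab,
                   window_start = tab$window * callset$window_size,
                   window_end = (tab$window + 1L) * callset$window_size)
  write_tsv(df, path)
}

#' @rdname write_calls
#' @param window_size,min_reads Parameters recorded in the restored
#'   object.
#' @export
read_calls <- function(path, window_size = 10000L, min_reads = 4L) {
  df <- read_tsv(path)
  acc <- if (nrow(df)) df$accession[1L] else NA_character_
  tab <- df[, c("family", "chrom", "window", "count", "insertion_point",
                "called")]
  structure(list(accession = acc, window_size = as.integer(window_size),
                 min_reads = as.integer(min_reads), table = tab),
            class = "insertion_calls")
}
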