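test_that("window assignment is floor division over half-open tiles", {
  expect_equal(assign_window(0L), 0L)
  expect_equal(assign_window(9999L), 0L)
  expect_equal(assign_window(10000L), 1L)
  expect_equal(assign_window(123456L), 12L)
  expect_equal(assign_window(c(0, 25), window_size = 10L), c(0L, 2L))
  expect_error(assign_window(-1L), "Negative")
})

test_that("call rule is strictly more than three reads; copy number at least three", {
  ev <- rbind(make_evidence(c(100, 200, 300), family = "famA"),
              make_evidence(c(20100, 20200, 20300, 20400), family = "famB"))
  ev$accession <- "acc1"
  cs <- call_insertions(ev)
  tab <- cs$table
  expect_false(tab$called[tab$family == "famA"])  # exactly 3 reads
  expect_true(tab$called[tab$family == "famB"])   # 4 reads
  expect_equal(copy_number(cs), 2L)               # both windows have >= 3
  expect_equal(copy_number(cs, per_family = TRUE),
               c(famA = 1L, famB = 1L))
})

test_that("insertion point is the lower median of anchor positions", {
  ev <- make_evidence(c(100, 200, 400, 800))
  cs <- call_insertions(ev, min_reads = 4L)
  expect_equal(cs$table$insertion_point, 200L)  # lower median of 4
  ev5 <- make_evidence(c(5, 1, 3, 2, 4))
  expect_equal(call_insertions(ev5, min_reads = 1L)$table$insertion_point,
               3L)
})

test_that("mixed accessions are rejected and empty evidence yields empty calls", {
  ev <- rbind(make_evidence(1:5, accession = "a"),
              make_evidence(1:5, accession = "b"))
  expect_error(call_insertions(ev), "single accession")
  cs <- call_insertions(make_evidence(integer(0)))
  expect_equal(nrow(cs$table), 0L)
  expect_equal(copy_number(cs), 0L)
})

test_that("windowed counting matches a brute-force per-record tally", {
  set.seed(1234)
  for (trial in 1:25) {
    n <- sample(50:400, 1)
    ev <- data.frame(
      accession = "acc1",
      family = sample(c("f1", "f2", "f3"), n, replace = TRUE),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      anchor_pos = sample.int(200000L, n, replace = TRUE) - 1L,
      pair_id = paste0("p", seq_len(n)),
      te_mate_seq = "A", stringsAsFactors = FALSE)
    cs <- call_insertions(ev)
    # independent oracle: nested loop over records
    oracle <- new.env()
    for (i in seq_len(n)) {
      k <- paste(ev$family[i], ev$chrom[i],
                 ev$anchor_pos[i] %/% 10000L, sep = "|")
      oracle[[k]] <- (oracle[[k]] %||% 0L) + 1L
    }
    got <- setNames(cs$table$count,
                    paste(cs$table$family, cs$table$chrom,
                          cs$table$window, sep = "|"))
    keys <- ls(oracle)
    expect_setequal(names(got), keys)
    expect_equal(got[keys], unlist(mget(keys, oracle)),
                 ignore_attr = TRUE)
    # median oracle on one random occupied locus
    k1 <- sample(keys, 1)
    parts <- strsplit(k1, "|", fixed = TRUE)[[1]]
    pos <- sort(ev$anchor_pos[ev$family == parts[1] &
                                ev$chrom == parts[2] &
                                ev$anchor_pos %/% 10000L ==
                                as.integer(parts[3])])
    expect_equal(
      cs$table$insertion_point[paste(cs$table$family, cs$table$chrom,
                                     cs$table$window, sep = "|") == k1],
      pos[floor((length(pos) + 1) / 2)])
  }
})

test_that("raising the call threshold never adds a call", {
  set.seed(77)
  ev <- make_evidence(sample.int(100000L, 500, replace = TRUE))
  prev <- NULL
  for (mr in 1:8) {
    cs <- call_insertions(ev, min_reads = mr)
    keys <- with(called_loci(cs), paste(family, chrom, window))
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("well-supported truth insertions are called", {
  run <- tiny_run()
  coh <- run$coh
  for (acc in names(run$callsets)) {
    ev <- run$evs[[acc]]
    truth_acc <- coh$truth[coh$truth$accession == acc, ]
    calls <- called_loci(run$callsets[[acc]])
    for (i in seq_len(nrow(truth_acc))) {
      w <- assign_window(truth_acc$position[i])
      support <- sum(ev$family == truth_acc$family[i] &
                       ev$chrom == truth_acc$chrom[i] &
                       assign_window(ev$anchor_pos) == w)
      if (support >= 4L) {
        expect_true(any(calls$family == truth_acc$family[i] &
                          calls$chrom == truth_acc$chrom[i] &
                          calls$window == w))
      }
    }
  }
})

test_that("validation against carrier and non-carrier assemblies separates them", {
  # two-insertion single-accession cohort, error-free reads
  spec <- cohort_spec(genome_length = 1e5L, n_families = 1L,
                      te_length = 1000L, n_ref_copies = 2L,
                      groups = c(g1 = 1L), pool_shared = 2L,
                      pool_per_group = c(g1 = 0L), pool_private = 0L,
                      coverage = 10, error_rate = 0, seed = 19L)
  coh <- generate_cohort(spec)
  te_idx <- build_seed_index(coh$library)
  g_idx <- build_seed_index(coh$reference)
  acc <- coh$groups$accession[1]
  reads <- simulate_paired_reads(coh$donors[[acc]], spec, acc)
  ev <- scan_pairs(reads$r1, reads$r2, te_idx, g_idx, acc)
  cs <- call_insertions(ev)
  # restrict to non-reference calls (drop windows of planted ref copies)
  mask <- ripscan:::mask_windows(coh$te_bed, cs$window_size, 1L)
  keep <- !(paste(cs$table$family, cs$table$chrom, cs$table$window) %in%
              paste(mask$family, mask$chrom, mask$window))
  cs$table <- cs$table[keep, ]
  expect_gte(sum(cs$table$called), 2L)
  frac_donor <- validate_against_assembly(cs, ev, coh$donors[[acc]],
                                          coh$reference)
  expect_equal(frac_donor, 1.0)
  frac_ref <- validate_against_assembly(cs, ev, coh$reference,
                                        coh$reference)
  expect_lte(frac_ref, 0.1)
  # guards
  expect_warning(v <- validate_against_assembly(cs, ev, coh$reference,
                                                coh$reference, flank = 0),
                 "flank")
  expect_null(v)
  cs0 <- cs
  cs0$table <- cs0$table[0, ]
  expect_warning(v0 <- validate_against_assembly(cs0, ev, coh$reference,
                                                 coh$reference),
                 "No called windows")
  expect_null(v0)
})
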