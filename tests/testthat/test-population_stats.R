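mk_callset <- function(accession, keys, window_size = 10000L) {
  # keys like "fam:chr:window"
  parts <- strsplit(keys, ":", fixed = TRUE)
  n <- length(keys)
  tab <- data.frame(
    family = vapply(parts, `[`, "", 1),
    chrom = vapply(parts, `[`, "", 2),
    window = as.integer(vapply(parts, `[`, "", 3)),
    count = rep(5L, n), insertion_point = rep(1L, n),
    called = rep(TRUE, n))
  structure(list(accession = accession, window_size = window_size,
                 min_reads = 4L, table = tab), class = "insertion_calls")
}

test_that("the RIP matrix is the union of call sets with presence rows", {
  cs <- list(mk_callset("a1", c("f:chr1:1", "f:chr1:2", "f:chr2:1")),
             mk_callset("a2", c("g:chr1:1", "g:chr1:5", "g:chr2:9")),
             mk_callset("a3", character(0)))
  m <- build_rip_matrix(cs, c(a1 = "g1", a2 = "g1", a3 = "g2"))
  expect_equal(dim(m$presence), c(3L, 6L))
  expect_equal(unname(rowSums(m$presence)), c(3, 3, 0))
  # identical call sets give identical rows
  cs2 <- list(mk_callset("a1", c("f:chr1:1")), mk_callset("a2", c("f:chr1:1")))
  m2 <- build_rip_matrix(cs2, c(a1 = "g1", a2 = "g2"))
  expect_equal(m2$presence["a1", ], m2$presence["a2", ])
  expect_error(build_rip_matrix(list(mk_callset("a1", "f:chr1:1"),
                                     mk_callset("a1", "f:chr1:2")),
                                c(a1 = "g1")), "Duplicate")
})

test_that("group RIP sets use union semantics", {
  cs <- list(mk_callset("a1", c("f:chr1:1", "f:chr1:2")),
             mk_callset("a2", character(0)),
             mk_callset("a3", c("f:chr1:3")))
  m <- build_rip_matrix(cs, c(a1 = "g1", a2 = "g1", a3 = "g2"))
  sets <- group_rip_sets(m)
  expect_setequal(sets$g1, c("f:chr1:1", "f:chr1:2"))
  expect_setequal(sets$g2, "f:chr1:3")
})

test_that("Venn partition equals brute-force set enumeration", {
  v <- venn_counts(list(A = c(1, 2), B = c(2, 3), C = 2))
  expect_equal(unname(v$region_counts[["A&B&C"]]), 1L)
  expect_equal(unname(v$unique_counts), c(1L, 1L, 0L), ignore_attr = TRUE)
  set.seed(31)
  for (trial in 1:100) {
    u <- seq_len(sample(3:40, 1))
    sets <- list(A = sample(u, sample(0:length(u), 1)),
                 B = sample(u, sample(0:length(u), 1)),
                 C = sample(u, sample(0:length(u), 1)))
    v <- venn_counts(sets)
    # oracle: classify every element of the union by membership pattern
    un <- unique(unlist(sets))
    pat <- vapply(un, function(x)
      paste0(as.integer(c(x %in% sets$A, x %in% sets$B, x %in% sets$C)),
             collapse = ""), "")
    oracle <- table(factor(pat, levels = c("100", "010", "001", "110",
                                           "101", "011", "111")))
    expect_equal(unname(v$region_counts), as.vector(oracle))
    expect_equal(sum(v$region_counts), length(un))
  }
  expect_error(venn_counts(list(A = 1, B = 2)), "3 groups")
})

test_that("degenerate Venn configurations fill the expected regions", {
  s <- c("x", "y", "z")
  v_same <- venn_counts(list(A = s, B = s, C = s))
  expect_equal(unname(v_same$region_counts[["A&B&C"]]), 3L)
  expect_equal(sum(v_same$region_counts), 3L)
  v_disj <- venn_counts(list(A = "x", B = "y", C = "z"))
  expect_equal(unname(v_disj$region_counts[c("A", "B", "C")]),
               c(1L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(sum(v_disj$region_counts[4:7]), 0L)
})

test_that("insertion frequency is carriers over group size", {
  pres <- matrix(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0,
                   1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                   0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                 nrow = 10, ncol = 3,
                 dimnames = list(paste0("a", 1:10), c("f:c:1", "f:c:2",
                                                      "f:c:3")))
  pres["a1", "f:c:3"] <- 1  # keep locus present somewhere
  m <- structure(list(presence = pres,
                      groups = setNames(rep("g1", 10), paste0("a", 1:10)),
                      loci = data.frame(family = "f", chrom = "c",
                                        window = 1:3)),
                 class = "rip_matrix")
  fr <- insertion_frequency(m, "g1", colnames(pres))
  expect_equal(unname(fr), c(0.5, 1.0, 0.1))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_error(insertion_frequency(m, "nope"), "no accessions")
})

test_that("common-RIP fraction uses a strict threshold", {
  expect_equal(common_rip_fraction(c(0.1, 0.25, 0.3, 0.05)), 0.5)
  expect_equal(common_rip_fraction(rep(0.2, 5)), 0)
  expect_equal(common_rip_fraction(rep(1.0, 4)), 1)
  expect_warning(out <- common_rip_fraction(numeric(0)), "No frequencies")
  expect_null(out)
})

test_that("per-family copy-number group means are plain averages", {
  cn <- data.frame(accession = c("a1", "a2", "b1"),
                   family = "f1", copy_number = c(10, 20, 7))
  groups <- c(a1 = "g1", a2 = "g1", b1 = "g2")
  s <- family_copy_number_summary(cn, groups)
  expect_equal(s$g1[s$family == "f1"], 15)
  expect_equal(s$g2[s$family == "f1"], 7)
  # absent family counts as zero for every accession of the group
  cn2 <- rbind(cn, data.frame(accession = "b1", family = "f2",
                              copy_number = 8))
  s2 <- family_copy_number_summary(cn2, groups)
  expect_equal(s2$g1[s2$family == "f2"], 0)
  expect_equal(s2$g2[s2$family == "f2"], 8)
  expect_error(family_copy_number_summary(
    data.frame(accession = "zz", family = "f", copy_number = 1), groups),
    "No group assignment")
})

test_that("rank-sum comparison flags disjoint groups and not identical ones", {
  same <- list(g1 = rep(c(1, 2, 3), 4), g2 = rep(c(1, 2, 3), 4))
  r_same <- compare_group_distributions(same)
  expect_gt(r_same$p_value, 0.5)
  expect_false(r_same$significant)
  apart <- list(g1 = 1:10, g2 = 21:30)
  r_apart <- compare_group_distributions(apart)
  expect_lte(r_apart$p_value, 0.05)
  expect_true(r_apart$significant)
  expect_warning(out <- compare_group_distributions(list(g1 = 1, g2 = 1:5)),
                 "fewer than 2")
  expect_null(out)
})

test_that("RIP matrix round-trips through TSV", {
  cs <- list(mk_callset("a1", c("f:chr1:1", "f:chr1:2")),
             mk_callset("a2", c("f:chr1:2", "g:chr2:7")))
  m <- build_rip_matrix(cs, c(a1 = "g1", a2 = "g2"))
  path <- tempfile(fileext = ".tsv")
  write_rip_matrix(m, path)
  back <- read_rip_matrix(path)
  expect_equal(back$presence, m$presence)
  expect_equal(back$groups, m$groups)
  expect_equal(back$loci, m$loci)
})
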