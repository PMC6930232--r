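test_that("GFF3 round trip converts coordinates and merges exons", {
  gm <- toy_genes()
  path <- tempfile(fileext = ".gff3")
  write_genes_gff3(gm, path)
  back <- load_genes(path)
  expect_equal(back$genes[order(back$genes$gene_id), ],
               gm$genes[order(gm$genes$gene_id), ], ignore_attr = TRUE)
  expect_equal(back$exons[order(back$exons$gene_id, back$exons$start), ],
               gm$exons[order(gm$exons$gene_id, gm$exons$start), ],
               ignore_attr = TRUE)
  # 1-based GFF start maps to 0-based internal start
  lines <- readLines(path)
  gene_line <- grep("\tgene\t", lines, value = TRUE)[1]
  expect_equal(as.integer(strsplit(gene_line, "\t")[[1]][4]),
               gm$genes$start[1] + 1L)
})

test_that("overlapping exon records are merged and exonless genes span the body", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gX",
    "chr1\tsrc\texon\t1001\t1300\t.\t+\t.\tID=e1;Parent=gX",
    "chr1\tsrc\texon\t1200\t1500\t.\t+\t.\tID=e2;Parent=gX",
    "chr1\tsrc\tgene\t5001\t6000\t.\t-\t.\tID=gY"), path)
  gm <- load_genes(path)
  exX <- gm$exons[gm$exons$gene_id == "gX", ]
  expect_equal(nrow(exX), 1L)
  expect_equal(c(exX$start, exX$end), c(1000L, 1500L))
  exY <- gm$exons[gm$exons$gene_id == "gY", ]
  expect_equal(c(exY$start, exY$end), c(5000L, 6000L))
  expect_equal(gm$genes$start[gm$genes$gene_id == "gX"], 1000L)
})

test_that("feature classification follows the exon>intron>up>down precedence", {
  gm <- toy_genes()  # gA: + strand 10000-13000, exons 10000-10500,12000-13000
  pts <- c(10100,  # exon
           11000,  # intron
           9000,   # 1 kb upstream (+)
           13500,  # downstream (+)
           52500,  # upstream of the - strand gene (right side)
           49500,  # downstream of the - strand gene (left side)
           200000) # far away
  cls <- classify_feature(rep("chr1", length(pts)), pts, gm)
  expect_equal(cls, c("exon", "intron", "up2kb", "down2kb", "up2kb",
                      "down2kb", "intergenic"))
  # a point in an exon that is also near another gene stays exon
  gm2 <- gm
  gm2$genes <- rbind(gm2$genes,
                     data.frame(gene_id = "gC", chrom = "chr1",
                                strand = "+", start = 10600L, end = 11900L))
  gm2$exons <- rbind(gm2$exons,
                     data.frame(gene_id = "gC", chrom = "chr1",
                                start = 10600L, end = 11900L))
  expect_equal(classify_feature("chr1", 10100, gm2), "exon")
  pct <- feature_class_percentages(cls)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
})

test_that("TSS distance is strand-aware and picks the nearest gene", {
  gm <- toy_genes()  # TSS at 10000 (+) and 51999 (-)
  expect_equal(distance_to_tss("chr1", 9900, gm), 100)
  expect_equal(distance_to_tss("chr1", 10000, gm), 0)
  expect_equal(distance_to_tss("chr1", 51999, gm), 0)
  expect_equal(distance_to_tss("chr1", 40000, gm), 11999)
  expect_warning(d <- distance_to_tss("chrZ", 5, gm), "No genes")
  expect_true(is.na(d))
})

test_that("TSS distance is invariant to mirror-reflection with strand flip", {
  gm <- toy_genes()
  L <- 100000L
  mirror <- gm
  mirror$genes$start <- L - gm$genes$end
  mirror$genes$end <- L - gm$genes$start
  mirror$genes$strand <- ifelse(gm$genes$strand == "+", "-", "+")
  mirror$exons$start <- L - gm$exons$end
  mirror$exons$end <- L - gm$exons$start
  pts <- c(500, 9900, 10000, 30000, 52500, 99000)
  expect_equal(distance_to_tss("chr1", L - 1 - pts, mirror),
               distance_to_tss("chr1", pts, gm))
})

test_that("bin-level density correlation recovers constructed correlations", {
  # three 1 kb bins: insertions (1,2,3), gene starts (3,2,1)
  gm <- structure(list(
    genes = data.frame(
      gene_id = paste0("g", 1:6), chrom = "chr1", strand = "+",
      start = c(10, 20, 30, 1010, 1020, 2010),
      end = c(15, 25, 35, 1015, 1025, 2015)),
    exons = data.frame(gene_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0))),
    class = "gene_models")
  ins_pos <- c(100, 1100, 1200, 2100, 2200, 2300)
  r <- megabase_density_correlation(rep("chr1", 6), ins_pos, gm,
                                    c(chr1 = 3000), bin = 1000)
  expect_equal(r, -1)
  gm_pos <- gm
  gm_pos$genes$start <- c(10, 1010, 1020, 2010, 2020, 2030)
  gm_pos$genes$end <- gm_pos$genes$start + 5
  r_pos <- megabase_density_correlation(rep("chr1", 6), ins_pos, gm_pos,
                                        c(chr1 = 3000), bin = 1000)
  expect_equal(r_pos, 1)
  # constant gene vector -> undefined
  gm_flat <- gm
  gm_flat$genes$start <- c(10, 1010, 2010, 20, 1020, 2020)
  gm_flat$genes$end <- gm_flat$genes$start + 5
  expect_warning(r_flat <- megabase_density_correlation(
    rep("chr1", 6), c(100, 110, 1100, 1110, 2100, 2110), gm_flat,
    c(chr1 = 3000), bin = 1000), "Zero-variance")
  expect_null(r_flat)
  expect_warning(r_few <- megabase_density_correlation(
    "chr1", 100, gm, c(chr1 = 1500), bin = 1000), "Fewer than 3")
  expect_null(r_few)
})

test_that("metagene profile sums to one, spikes at the TSS bin, and flips with strand", {
  gm <- toy_genes()
  nf <- 40L  # 2000 / 50
  # anchors exactly at the TSS of each gene
  tss <- ifelse(gm$genes$strand == "+", gm$genes$start,
                gm$genes$end - 1L)
  prof <- metagene_profile(rep("chr1", 2), tss, gm)
  expect_equal(sum(prof), 1)
  expect_equal(prof[nf + 1L], 1)  # all mass in the first body bin
  # uniform anchors around one gene: profile roughly flat per bp
  set.seed(5)
  gm1 <- gm
  gm1$genes <- gm1$genes[1, ]
  gm1$exons <- gm1$exons[gm1$exons$gene_id == "gA", ]
  anchors <- sample(8000:14999, 10000, replace = TRUE)
  p <- metagene_profile(rep("chr1", length(anchors)), anchors, gm1)
  expect_equal(sum(p), 1)
  # flank bins cover 50 bp, body bins 30 bp here; compare per-bp rates
  flank_rate <- mean(p[1:nf]) / 50
  body_rate <- mean(p[(nf + 1):(nf + 100)]) / 30
  expect_equal(flank_rate / body_rate, 1, tolerance = 0.1)
  # strand flip reverses the profile exactly
  gm_flip <- gm
  gm_flip$genes$strand <- ifelse(gm$genes$strand == "+", "-", "+")
  pts <- sample(5000:60000, 3000, replace = TRUE)
  p1 <- metagene_profile(rep("chr1", length(pts)), pts, gm)
  p2 <- metagene_profile(rep("chr1", length(pts)), pts, gm_flip)
  expect_equal(p2, rev(p1))
  expect_warning(p0 <- metagene_profile(character(0), integer(0), gm),
                 "Empty anchor")
  expect_equal(p0, rep(0, 180))
})

test_that("upstream enrichment ratio is inclusive and pseudocount-guarded", {
  gm <- toy_genes()
  # counts: normalized landrace 10, teosinte 2 -> ratio exactly 5
  expect_equal(
    upstream_enrichment(c(gA = 240), c(gA = 20), num_size = 24,
                        den_size = 10, ratio = 5),
    "gA")
  # zero numerator is always excluded
  expect_length(
    upstream_enrichment(c(gA = 0), c(gA = 0), 24, 10), 0L)
  # zero denominator passes through the pseudocount guard
  expect_equal(
    upstream_enrichment(c(gA = 48), c(gA = 0), 24, 10), "gA")
  expect_length(
    upstream_enrichment(c(gA = 1), c(gA = 0), 24, 10), 0L)
  # counting helper is strand-aware
  cnt <- count_upstream_anchors(rep("chr1", 3), c(9500, 9900, 52500), gm)
  expect_equal(unname(cnt), c(2L, 1L))
})
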