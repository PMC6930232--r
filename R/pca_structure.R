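# Population structure from the RIP matrix: homozygous dosage encoding,
# GCTA-style genetic relationship matrix, leading principal components.

#' Encode a RIP matrix as a genotype dosage matrix
#'
#' Presence/absence becomes homozygous allele dosage (1 -> 2, 0 -> 0),
#' replicating what a ped-file conversion of binary markers feeds a
#' SNP-based PCA. Monomorphic columns are removed — they carry no
#' information and break the standardization.
#'
#' @param matrix A `rip_matrix`.
#' @return List with `dosage` (accessions x loci, entries 0/2), `p`
#'   (column allele frequencies in (0,1)), and `loci` (kept locus ids).
#' @export
encode_genotypes <- function(matrix) {
  x <- matrix$presence
  if (nrow(x) == 0L || ncol(x) == 0L) stop("Empty RIP matrix")
  dosage <- 2L * x
  p <- colMeans(dosage) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) {
    stop("All loci are monomorphic; no polymorphism to analyze")
  }
  list(dosage = dosage[, keep, drop = FALSE], p = p[keep],
       loci = colnames(x)[keep])
}

#' Genetic relationship matrix from dosages
#'
#' Standardizes each locus as `w_ij = (x_ij - 2 p_j) / sqrt(2 p_j (1 -
#' p_j))` and returns `A = W W' / m` over the `m` loci (the GCTA
#' convention).
#'
#' @param G Result of [encode_genotypes()].
#' @return Symmetric accessions x accessions relationship matrix.
#' @export
compute_grm <- function(G) {
  x <- G$dosage
  if (nrow(x) < 2L) stop("Need at least 2 accessions")
  p <- G$p
  if (any(p <= 0 | p >= 1)) {
    stop("Internal error: monomorphic locus reached compute_grm")
  }
  w <- sweep(x, 2L, 2 * p, "-")
  w <- sweep(w, 2L, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(w) / ncol(x)
  (A + t(A)) / 2
}

#' Principal components of a relationship matrix
#'
#' Top eigenpairs of the (symmetric) relationship matrix; coordinates are
#' eigenvector times the square root of its eigenvalue. Eigenvector signs
#' are fixed so the largest-magnitude entry of each is positive.
#'
#' @param A Symmetric relationship matrix.
#' @param n_components Number of components (default 2).
#' @return A `rip_pca` object: list with `coordinates` (accessions x
#'   components), `eigenvalues`, `variance_explained`.
#' @export
rip_pca <- function(A, n_components = 2L) {
  if (max(abs(A - t(A))) > 1e-8) {
    stop("Relationship matrix is not symmetric")
  }
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  n_components <- min(n_components, ncol(A))
  vals <- e$values[seq_len(n_components)]
  # null-space components carry pure numerical noise; zero them so
  # duplicated accessions get exactly identical coordinates
  vals[vals < 1e-9 * max(abs(e$values), 1e-300)] <- 0
  vecs <- e$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  if (diff(range(e$values)) < 1e-10) {
    warning("Degenerate spectrum: all eigenvalues equal; ",
            "coordinates are not informative")
  }
  coords <- sweep(vecs, 2L, sqrt(pmax(vals, 0)), "*")
  rownames(coords) <- rownames(A)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  pos <- pmax(e$values, 0)
  structure(list(coordinates = coords, eigenvalues = vals,
                 variance_explained = if (sum(pos) > 0)
                   pmax(vals, 0) / sum(pos) else rep(NA_real_,
                                                     n_components)),
            class = "rip_pca")
}

#' @export
print.rip_pca <- function(x, ...) {
  cat("RIP PCA:", nrow(x$coordinates), "accessions;",
      "eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\nvariance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write PC coordinates with group labels as TSV
#' @param pca A `rip_pca`.
#' @param groups Named character vector accession -> group.
#' @param path TSV path.
#' @export
write_pca <- function(pca, groups, path) {
  df <- data.frame(accession = rownames(pca$coordinates),
                   group = unname(groups[rownames(pca$coordinates)]),
                   pca$coordinates, check.names = FALSE)
  write_tsv(df, path)
}

#' Export a RIP matrix in PLINK ped/map text format
#'
#' Presence is written as the homozygous `A A` genotype, absence as
#' `T T`; the map file carries one marker per locus. Provided so users can
#' cross-check coordinates against external PLINK/GCTA runs on their own
#' data.
#'
#' @param matrix A `rip_matrix`.
#' @param prefix Output path prefix (writes `<prefix>.ped`,
#'   `<prefix>.map`).
#' @export
write_plink <- function(matrix, prefix) {
  x <- matrix$presence
  geno <- ifelse(x == 1L, "A A", "T T")
  ped <- cbind(rownames(x), rownames(x), 0, 0, 0, -9, geno)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  loci <- matrix$loci
  chrom_code <- as.integer(factor(loci$chrom))
  map <- data.frame(chrom_code, colnames(x), 0,
                    loci$window * 10000L + 1L)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".ped", ".map")))
}
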