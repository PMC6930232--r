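# Cohort-level RIP statistics: presence/absence matrix, group Venn
# partitions, insertion frequency spectra, copy-number summaries.

locus_id <- function(family, chrom, window) {
  paste(family, chrom, window, sep = ":")
}

#' Build the cohort RIP presence/absence matrix
#'
#' A RIP locus is a (family, chromosome, window) triple; two families in
#' one window are two distinct loci. The matrix holds 1 when the
#' accession's call set contains the locus.
#'
#' @param callsets List of `insertion_calls`, one per accession.
#' @param groups Named character vector or two-column `data.frame`
#'   (`accession`, `group`) assigning every accession to a group.
#' @return A `rip_matrix` object: list with `presence` (accessions x loci
#'   binary matrix), `groups` (named character), and `loci` (`data.frame`
#'   of `family`, `chrom`, `window`).
#' @export
build_rip_matrix <- function(callsets, groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group),
                       as.character(groups$accession))
  }
  accs <- vapply(callsets, function(x) x$accession, "")
  if (anyDuplicated(accs)) {
    stop("Duplicate accession names in call sets: ",
         paste(unique(accs[duplicated(accs)]), collapse = ", "))
  }
  if (!all(accs %in% names(groups))) {
    stop("No group assignment for: ",
         paste(setdiff(accs, names(groups)), collapse = ", "))
  }
  per_acc <- lapply(callsets, function(cs) {
    cl <- called_loci(cs)
    locus_id(cl$family, cl$chrom, cl$window)
  })
  all_loci <- sort(unique(unlist(per_acc)))
  presence <- matrix(0L, nrow = length(accs), ncol = length(all_loci),
                     dimnames = list(accs, all_loci))
  for (i in seq_along(per_acc)) {
    presence[i, per_acc[[i]]] <- 1L
  }
  parts <- strsplit(all_loci, ":", fixed = TRUE)
  loci <- data.frame(family = vapply(parts, `[`, "", 1L),
                     chrom = vapply(parts, `[`, "", 2L),
                     window = as.integer(vapply(parts, `[`, "", 3L)))
  structure(list(presence = presence, groups = groups[accs], loci = loci),
            class = "rip_matrix")
}

#' @export
print.rip_matrix <- function(x, ...) {
  cat("RIP matrix:", nrow(x$presence), "accessions x", ncol(x$presence),
      "loci;", "groups:",
      paste(names(table(x$groups)), table(x$groups), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-group RIP locus sets
#'
#' A locus belongs to a group when at least one accession of the group
#' carries it (union semantics).
#'
#' @param matrix A `rip_matrix`.
#' @return Named list: group -> character vector of locus ids.
#' @export
group_rip_sets <- function(matrix) {
  out <- list()
  for (g in unique(matrix$groups)) {
    rows <- matrix$presence[matrix$groups == g, , drop = FALSE]
    out[[g]] <- colnames(rows)[colSums(rows) > 0L]
  }
  out
}

#' Three-way Venn partition of group RIP sets
#'
#' @param sets Named list of exactly 3 locus sets.
#' @return A `group_venn` object: list with `region_counts` (the 7
#'   disjoint regions, named like `"A"`, `"A&B"`, `"A&B&C"`), `union_size`,
#'   `unique_fraction` and `triple_fraction` (fractions of the union).
#' @export
venn_counts <- function(sets) {
  if (length(sets) != 3L) {
    stop("venn_counts needs exactly 3 groups, got ", length(sets))
  }
  nm <- names(sets)
  u <- unique(unlist(sets))
  inA <- u %in% sets[[1L]]
  inB <- u %in% sets[[2L]]
  inC <- u %in% sets[[3L]]
  key <- paste0(ifelse(inA, "1", "0"), ifelse(inB, "1", "0"),
                ifelse(inC, "1", "0"))
  region_name <- function(code) {
    paste(nm[which(strsplit(code, "")[[1L]] == "1")], collapse = "&")
  }
  codes <- c("100", "010", "001", "110", "101", "011", "111")
  counts <- setNames(vapply(codes, function(cd) sum(key == cd), 0L),
                     vapply(codes, region_name, ""))
  triple <- counts[[paste(nm, collapse = "&")]]
  uniq <- counts[nm]
  structure(list(region_counts = counts, union_size = length(u),
                 unique_counts = uniq,
                 unique_fraction = if (length(u)) uniq / length(u) else
                   setNames(rep(NA_real_, 3L), nm),
                 triple_fraction = if (length(u)) triple / length(u) else
                   NA_real_),
            class = "group_venn")
}

#' @export
print.group_venn <- function(x, ...) {
  cat("Venn partition over", x$union_size, "loci:\n")
  print(x$region_counts)
  invisible(x)
}

#' Insertion frequency of RIP loci within a group
#'
#' Frequency of a locus is the number of group accessions carrying it
#' divided by the group size (analogous to allele frequency).
#'
#' @param matrix A `rip_matrix`.
#' @param group Group name.
#' @param loci Locus ids to report (default: the group's RIP set; loci the
#'   group does not carry get frequency 0).
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
insertion_frequency <- function(matrix, group, loci = NULL) {
  rows <- matrix$presence[matrix$groups == group, , drop = FALSE]
  if (nrow(rows) == 0L) stop("Group '", group, "' has no accessions")
  freq_all <- colSums(rows) / nrow(rows)
  if (is.null(loci)) {
    return(freq_all[freq_all > 0])
  }
  out <- setNames(rep(0, length(loci)), loci)
  known <- intersect(loci, names(freq_all))
  out[known] <- freq_all[known]
  out
}

#' Mean insertion frequency per family within a group
#'
#' Averages locus frequencies over the loci detected in the group's RIP
#' set for each family (group-detected denominator).
#'
#' @param matrix A `rip_matrix`.
#' @param group Group name.
#' @param denominator `"group-detected"` (default) averages over loci the
#'   group carries; `"cohort-detected"` over all loci of the family in the
#'   cohort matrix.
#' @return Named numeric vector: family -> mean frequency.
#' @export
family_mean_frequency <- function(matrix, group,
                                  denominator = c("group-detected",
                                                  "cohort-detected")) {
  denominator <- match.arg(denominator)
  rows <- matrix$presence[matrix$groups == group, , drop = FALSE]
  if (nrow(rows) == 0L) stop("Group '", group, "' has no accessions")
  freq <- colSums(rows) / nrow(rows)
  fams <- sort(unique(matrix$loci$family))
  out <- setNames(numeric(length(fams)), fams)
  for (f in fams) {
    sel <- matrix$loci$family == f
    fr <- freq[sel]
    if (denominator == "group-detected") fr <- fr[fr > 0]
    out[f] <- if (length(fr)) mean(fr) else 0
  }
  out
}

#' Fraction of common RIPs
#'
#' A common RIP has insertion frequency strictly above `threshold`
#' (default 0.2, i.e. "above 20%").
#'
#' @param freqs Named numeric vector of locus frequencies.
#' @param threshold Frequency cutoff (strict).
#' @return Fraction of loci above the threshold, or `NULL` with a warning
#'   for empty input.
#' @export
common_rip_fraction <- function(freqs, threshold = 0.2) {
  if (length(freqs) == 0L) {
    warning("No frequencies supplied")
    return(NULL)
  }
  mean(freqs > threshold)
}

#' Group means of per-family copy numbers
#'
#' @param copy_numbers `data.frame` with columns `accession`, `family`,
#'   `copy_number` (0 allowed), or a named list `accession -> named
#'   per-family vector` as from [copy_number()] with `per_family = TRUE`.
#' @param groups Named character vector or `data.frame` (`accession`,
#'   `group`).
#' @return `data.frame`: `family`, one column per group holding the group
#'   mean.
#' @export
family_copy_number_summary <- function(copy_numbers, groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group),
                       as.character(groups$accession))
  }
  if (is.list(copy_numbers) && !is.data.frame(copy_numbers)) {
    fams <- sort(unique(unlist(lapply(copy_numbers, names))))
    copy_numbers <- do.call(rbind, lapply(names(copy_numbers), function(a) {
      v <- copy_numbers[[a]]
      data.frame(accession = a, family = fams,
                 copy_number = as.numeric(
                   ifelse(fams %in% names(v), v[fams], 0)))
    }))
  }
  if (!all(copy_numbers$accession %in% names(groups))) {
    stop("No group assignment for: ",
         paste(setdiff(unique(copy_numbers$accession), names(groups)),
               collapse = ", "))
  }
  copy_numbers$group <- groups[copy_numbers$accession]
  fams <- sort(unique(copy_numbers$family))
  gs <- unique(unname(groups))
  out <- data.frame(family = fams)
  for (g in gs) {
    out[[g]] <- vapply(fams, function(f) {
      accs_g <- names(groups)[groups == g]
      v <- copy_numbers$copy_number[copy_numbers$family == f &
                                      copy_numbers$accession %in% accs_g]
      # accessions without a record for the family count as 0
      sum(v) / length(accs_g)
    }, 0)
  }
  out
}

#' Pairwise tests comparing copy-number distributions between groups
#'
#' Two-sided Wilcoxon rank-sum by default (the counts are skewed and the
#' groups small); Welch t-test by option. Significance marker at
#' p <= 0.05.
#'
#' @param values_by_group Named list: group -> numeric vector.
#' @param test `"wilcoxon"` or `"t"`.
#' @return `data.frame` with `group1`, `group2`, `p_value`, `significant`;
#'   `NULL` with a warning when any group is degenerate (n < 2).
#' @export
compare_group_distributions <- function(values_by_group,
                                        test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  ns <- vapply(values_by_group, length, 0L)
  if (any(ns < 2L)) {
    warning("Groups with fewer than 2 values: ",
            paste(names(ns)[ns < 2L], collapse = ", "))
    return(NULL)
  }
  gs <- names(values_by_group)
  pairs <- utils::combn(gs, 2L)
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    p_value = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- values_by_group[[pairs[1L, i]]]
    b <- values_by_group[[pairs[2L, i]]]
    p <- tryCatch({
      if (test == "wilcoxon") {
        suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
      } else {
        t.test(a, b)$p.value
      }
    }, error = function(e) NA_real_)
    out$p_value[i] <- p
  }
  out$significant <- !is.na(out$p_value) & out$p_value <= 0.05
  out
}

#' Write a RIP matrix as TSV
#'
#' Accessions in rows (first two columns `accession`, `group`), loci in
#' columns.
#' @param matrix A `rip_matrix`.
#' @param path TSV path.
#' @export
write_rip_matrix <- function(matrix, path) {
  df <- data.frame(accession = rownames(matrix$presence),
                   group = unname(matrix$groups),
                   matrix$presence, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a RIP matrix written by [write_rip_matrix()]
#' @param path TSV path.
#' @return A `rip_matrix`.
#' @export
read_rip_matrix <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  presence <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(presence) <- "integer"
  rownames(presence) <- df$accession
  parts <- strsplit(colnames(presence), ":", fixed = TRUE)
  loci <- data.frame(family = vapply(parts, `[`, "", 1L),
                     chrom = vapply(parts, `[`, "", 2L),
                     window = as.integer(vapply(parts, `[`, "", 3L)))
  structure(list(presence = presence,
                 groups = setNames(df$group, df$accession), loci = loci),
            class = "rip_matrix")
}
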