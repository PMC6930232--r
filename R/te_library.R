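# TE reference library: family-labelled member sequences extracted from a
# genome FASTA + annotation BED, after the family-size filter.

#' Load a TE annotation BED file
#'
#' Reads a BED4+ transposable-element annotation where column 4 encodes the
#' family and superfamily as `"family<sep>superfamily"` (default separator
#' `"#"`, e.g. `"ji#Copia"`). Coordinates are kept as in BED: 0-based,
#' half-open.
#'
#' @param bed_path Path to a BED file with at least 4 columns.
#' @param sep Separator between family and superfamily in the name column.
#' @param superfamilies Allowed superfamily tokens.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `family`,
#'   `superfamily` (one row per annotation record).
#' @export
load_te_annotation <- function(bed_path, sep = "#",
                               superfamilies = c("Copia", "Gypsy")) {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  lines <- readLines(bed_path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), family = character(),
                      superfamily = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4L) {
      stop("BED parse error at line ", i, ": fewer than 4 columns")
    }
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end)) {
      stop("BED parse error at line ", i, ": non-integer coordinates")
    }
    if (start < 0L || start >= end) {
      stop("BED parse error at line ", i, ": empty or inverted interval [",
           start, ", ", end, ")")
    }
    name <- strsplit(f[4L], sep, fixed = TRUE)[[1L]]
    if (length(name) < 2L || !nzchar(name[1L])) {
      stop("BED parse error at line ", i,
           ": name column not of the form family", sep, "superfamily")
    }
    if (!name[2L] %in% superfamilies) {
      stop("Unknown superfamily '", name[2L], "' at line ", i,
           " (expected one of: ", paste(superfamilies, collapse = ", "), ")")
    }
    out[[i]] <- data.frame(chrom = f[1L], start = start, end = end,
                           family = name[1L], superfamily = name[2L])
  }
  do.call(rbind, out)
}

#' Retain TE families with enough annotated members
#'
#' Applies the family-size filter: a family is kept when its annotated
#' member count is at least `min_members` (the boundary is inclusive).
#'
#' @param intervals TE annotation as returned by [load_te_annotation()].
#' @param min_members Minimum member count per family (default 20).
#' @return Character vector of retained family labels, sorted.
#' @export
filter_families <- function(intervals, min_members = 20L) {
  stopifnot(min_members >= 1L)
  if (nrow(intervals) == 0L) return(character())
  counts <- table(intervals$family)
  sort(names(counts)[counts >= min_members])
}

#' Extract member sequences for retained TE families
#'
#' Pulls the genome substring `[start, end)` for every annotation record of
#' a retained family. Member intervals are used verbatim (no consensus);
#' strand is ignored, reverse-complement matching is left to the mapper.
#'
#' @param genome Path to the genome FASTA, or a named character vector of
#'   chromosome sequences.
#' @param intervals TE annotation (see [load_te_annotation()]).
#' @param retained Family labels to keep (see [filter_families()]).
#' @return An object of class `te_library`: a list with `families` (list of
#'   character vectors of member sequences), `superfamily_of` (named
#'   character), and `member_count` (named integer).
#' @export
extract_family_sequences <- function(genome, intervals, retained) {
  seqs <- if (is.character(genome) && length(genome) == 1L &&
              file.exists(genome)) read_fasta(genome) else genome
  keep <- intervals[intervals$family %in% retained, , drop = FALSE]
  fams <- list()
  superfam <- character()
  for (i in seq_len(nrow(keep))) {
    r <- keep[i, ]
    if (!r$chrom %in% names(seqs)) {
      stop("Chromosome '", r$chrom, "' not present in genome")
    }
    len <- nchar(seqs[[r$chrom]])
    if (r$end > len) {
      stop("Interval [", r$start, ", ", r$end, ") exceeds length of ",
           r$chrom, " (", len, " bp)")
    }
    s <- toupper(substr(seqs[[r$chrom]], r$start + 1L, r$end))
    fams[[r$family]] <- c(fams[[r$family]], s)
    superfam[r$family] <- r$superfamily
  }
  structure(list(families = fams,
                 superfamily_of = superfam,
                 member_count = vapply(fams, length, 0L)),
            class = "te_library")
}

#' @export
print.te_library <- function(x, ...) {
  cat("TE family library:", length(x$families), "families,",
      sum(x$member_count), "member sequences\n")
  for (f in names(x$families)) {
    cat(sprintf("  %-14s %-6s %4d members\n", f, x$superfamily_of[[f]],
                x$member_count[[f]]))
  }
  invisible(x)
}

#' Write a TE library as multi-FASTA
#'
#' Headers follow the `family|superfamily|index` convention that the SAM
#' import path parses back.
#'
#' @param lib A `te_library`.
#' @param path Output FASTA path.
#' @export
write_te_library <- function(lib, path) {
  seqs <- character()
  for (f in names(lib$families)) {
    members <- lib$families[[f]]
    names(members) <- paste(f, lib$superfamily_of[[f]],
                            seq_along(members), sep = "|")
    seqs <- c(seqs, members)
  }
  write_fasta(seqs, path)
}

#' Read a TE library written by [write_te_library()]
#' @param path Multi-FASTA with `family|superfamily|index` headers.
#' @return A `te_library`.
#' @export
read_te_library <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 3L)
  if (length(bad)) {
    stop("TE library header not of the form family|superfamily|index: ",
         names(seqs)[bad[1L]])
  }
  fam <- vapply(parts, `[`, "", 1L)
  superfam <- vapply(parts, `[`, "", 2L)
  fams <- split(unname(seqs), fam)[unique(fam)]
  structure(list(families = fams,
                 superfamily_of = setNames(superfam, fam)[unique(fam)],
                 member_count = vapply(fams, length, 0L)),
            class = "te_library")
}

#' Per-family summary table of a TE library
#' @param lib A `te_library`.
#' @return `data.frame` with `family`, `superfamily`, `member_count`,
#'   `total_bp`.
#' @export
te_family_summary <- function(lib) {
  data.frame(
    family = names(lib$families),
    superfamily = unname(lib$superfamily_of[names(lib$families)]),
    member_count = unname(lib$member_count[names(lib$families)]),
    total_bp = vapply(lib$families, function(s) sum(nchar(s)), 0),
    row.names = NULL
  )
}
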