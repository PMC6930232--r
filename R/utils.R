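#' @useDynLib ripscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
#' @importFrom stats rnorm runif median wilcox.test t.test cor setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Deterministic 31-bit stream salt from (seed, label). Polynomial string
# hash so per-accession streams are order-independent.
salt_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# Plain FASTQ with constant Q40 qualities; the simulator carries no
# quality model. `path` ending in .gz writes through a gzip connection.
write_fastq <- function(seqs, names, path) {
  stopifnot(length(seqs) == length(names))
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  lines <- as.vector(rbind(paste0("@", names), seqs, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
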