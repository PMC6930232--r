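# Recovery metrics of call sets against a known insertion truth table.

truth_windows <- function(truth, window_size = 10000L) {
  data.frame(accession = truth$accession, family = truth$family,
             chrom = truth$chrom,
             window = assign_window(truth$position, window_size))
}

# windows (+- tol) covered by annotated reference TE intervals, per family
mask_windows <- function(te_bed, window_size = 10000L, tol = 1L,
                         sep = "#") {
  if (is.null(te_bed) || nrow(te_bed) == 0L) {
    return(data.frame(family = character(), chrom = character(),
                      window = integer()))
  }
  fam <- vapply(strsplit(te_bed$name, sep, fixed = TRUE), `[`, "", 1L)
  rows <- lapply(seq_len(nrow(te_bed)), function(i) {
    w <- assign_window(te_bed$start[i], window_size):
      assign_window(te_bed$end[i] - 1L, window_size)
    w <- unique(pmax(0L, c(outer(w, -tol:tol, "+"))))
    data.frame(family = fam[i], chrom = te_bed$chrom[i], window = w)
  })
  unique(do.call(rbind, rows))
}

#' Window-level recall and precision of call sets against truth
#'
#' A truth record is recovered when the accession's call set contains a
#' call of the same family and chromosome within `tol` windows of the
#' truth window. A call is a true positive under the same matching rule.
#' Calls in windows containing annotated reference TE copies (when
#' `te_bed` is given) are excluded from the precision denominator:
#' reference-resident elements legitimately produce anchor evidence in
#' every accession and are not errors of the caller.
#'
#' @param callsets List of `insertion_calls` objects.
#' @param truth Truth `data.frame` (accession, family, chrom, position).
#' @param te_bed Optional reference TE annotation (`chrom`, `start`,
#'   `end`, `name`) used to mask reference-copy windows.
#' @param window_size Window width in bp.
#' @param tol Window tolerance for matching (default 1).
#' @return List with `recall`, `precision`, `n_truth`, `n_recovered`,
#'   `n_calls`, `n_masked`, `n_true_positive`.
#' @export
evaluate_calls <- function(callsets, truth, te_bed = NULL,
                           window_size = 10000L, tol = 1L) {
  tw <- truth_windows(truth, window_size)
  calls <- do.call(rbind, lapply(callsets, function(cs) {
    cl <- called_loci(cs)
    if (nrow(cl) == 0L) return(NULL)
    data.frame(accession = cs$accession, family = cl$family,
               chrom = cl$chrom, window = cl$window)
  }))
  if (is.null(calls)) {
    calls <- data.frame(accession = character(), family = character(),
                        chrom = character(), window = integer())
  }
  key <- function(df) paste(df$accession, df$family, df$chrom, df$window)
  call_keys <- key(calls)
  # truth record recovered if any call within +-tol windows
  recovered <- vapply(seq_len(nrow(tw)), function(i) {
    any(paste(tw$accession[i], tw$family[i], tw$chrom[i],
              tw$window[i] + (-tol:tol)) %in% call_keys)
  }, TRUE)
  truth_keys <- key(tw)
  tp <- vapply(seq_len(nrow(calls)), function(i) {
    any(paste(calls$accession[i], calls$family[i], calls$chrom[i],
              calls$window[i] + (-tol:tol)) %in% truth_keys)
  }, TRUE)
  masked <- rep(FALSE, nrow(calls))
  if (!is.null(te_bed)) {
    mk <- mask_windows(te_bed, window_size, tol)
    masked <- paste(calls$family, calls$chrom, calls$window) %in%
      paste(mk$family, mk$chrom, mk$window)
  }
  denom <- sum(!masked)
  list(recall = if (nrow(tw)) mean(recovered) else NA_real_,
       precision = if (denom) sum(tp & !masked) / denom else NA_real_,
       n_truth = nrow(tw), n_recovered = sum(recovered),
       n_calls = nrow(calls), n_masked = sum(masked),
       n_true_positive = sum(tp & !masked))
}
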