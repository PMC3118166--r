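#' Mapping accuracy against simulation ground truth
#'
#' A read counts as correctly mapped iff its best reported mapping lands on
#' the true source record and strand with a start within `tolerance` bases
#' of the true template start (indels shift alignment starts, so a small
#' tolerance is needed for error-bearing reads). The denominator is the
#' total number of simulated reads: unmapped reads count against accuracy.
#'
#' @param mappings output of [map_reads()] (best mode; when several rows tie
#'   per read, the first — fewest errors, leftmost — is scored).
#' @param truth a `sim_read_set` or its `reads` data.frame / truth table.
#' @param tolerance allowed start deviation in bases.
#' @return the fraction of reads mapped back to their origin, with
#'   attributes `n_correct` and `n_reads`.
#' @export
evaluate_accuracy <- function(mappings, truth, tolerance = 10) {
  tr <- if (inherits(truth, "sim_read_set")) truth$reads else truth
  stopifnot(all(c("id", "record", "start", "strand") %in% names(tr)))
  m <- mappings[mappings$mapped & !duplicated(mappings$read_id), , drop = FALSE]
  i <- match(m$read_id, tr$id)
  ok <- !is.na(i) &
    m$record == tr$record[i] &
    m$strand == tr$strand[i] &
    abs(m$pos - tr$start[i]) <= tolerance
  acc <- sum(ok) / nrow(tr)
  attr(acc, "n_correct") <- sum(ok)
  attr(acc, "n_reads") <- nrow(tr)
  acc
}

#' Pooled base-pair matches per error (bp/err)
#'
#' Summarises alignment quality across accepted mappings as total matched
#' bases divided by total errors (mismatches plus inserted plus deleted
#' bases), the denominator floored at 1 so error-free sets report their
#' match total.
#'
#' @param mappings output of [map_reads()] / [map_read()].
#' @return a single number, or `NA` when there is no accepted mapping.
#' @export
matches_per_error <- function(mappings) {
  m <- mappings[!is.na(mappings$matches), , drop = FALSE]
  if (nrow(m) == 0L) return(NA_real_)
  sum(m$matches) / max(1, sum(m$errors))
}
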