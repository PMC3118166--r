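#' Banded global alignment with affine gap costs
#'
#' Minimum-cost global alignment of two segments under the Gotoh three-state
#' recurrence: matches cost 0, mismatches `scoring$mismatch`, and a gap of
#' length k costs `gap_open + k * gap_extend`. The dynamic program is
#' restricted to a diagonal band of half-width
#' `abs(nchar(a) - nchar(b)) + band_pad`, which contains every optimal path
#' whose net indel drift stays within the padding. Ties are broken
#' deterministically: match/mismatch over insertion over deletion.
#'
#' @param a read-side segment (string; consumed entirely).
#' @param b reference-side segment (string; consumed entirely).
#' @param scoring an [align_scoring()] object.
#' @return list with the operation string `ops` over `=`, `X`, `I`
#'   (read base absent from reference), `D` (reference base absent from
#'   read), its run-length `cigar`, and the total `cost`.
#' @examples
#' banded_affine_align("GCCCTA", "CCCAA")$cost  # 3
#' @export
banded_affine_align <- function(a, b, scoring = align_scoring()) {
  r <- cpp_gotoh(toupper(a), toupper(b), scoring$mismatch, scoring$gap_open,
                 scoring$gap_extend, scoring$band_pad, 0L)
  r[c("ops", "cigar", "cost")]
}

#' Semi-global alignment of a read end against a reference window
#'
#' All read symbols must be consumed, but reference overhang at the outer
#' end of the window (the left edge for `end = "left"`, the right edge for
#' `end = "right"`) is cost-free. When the window is truncated by a
#' reference boundary, any unplaceable read symbols are penalised as
#' insertions.
#'
#' @param segment read end segment (string).
#' @param window reference window (string); for a left end it must abut the
#'   first seed on its right edge, for a right end start at the last seed's
#'   end.
#' @param scoring an [align_scoring()] object.
#' @param end `"left"` or `"right"`.
#' @return list with `ops`, `cigar`, `cost` and `lead`, the number of
#'   cost-free leading reference bases skipped (left ends only): the
#'   alignment start within the window.
#' @export
semiglobal_end_align <- function(segment, window, scoring = align_scoring(),
                                 end = c("left", "right")) {
  end <- match.arg(end)
  r <- cpp_gotoh(toupper(segment), toupper(window), scoring$mismatch,
                 scoring$gap_open, scoring$gap_extend, scoring$band_pad,
                 if (end == "left") 1L else 2L)
  r[c("ops", "cigar", "cost", "lead")]
}

#' Extend a candidate chain into a full-read mapping
#'
#' The chain's seed occurrences decompose the read into seed blocks
#' (all-match runs by construction) and non-seed segments. Each inner
#' non-seed pair is aligned globally with the banded affine-gap DP, the two
#' read ends semi-globally against reference windows of
#' `segment length + end_slack` bases, and the blocks are stitched into one
#' edit path. The mapping start is the leftmost reference column consumed.
#'
#' @param index a `pyromap_index`.
#' @param read the read sequence (string).
#' @param chain one chain from [chain_occurrences()] (data.frame with
#'   `start`, `length`, `pos`).
#' @param scoring an [align_scoring()] object.
#' @return A mapping: list with `ok`, `record`, 1-based `pos`, global
#'   0-based `gstart0`, `ops`, `cigar`, tallies (`matches`, `mismatches`,
#'   `insertions`, `deletions`, `errors`), `identity` (matches / alignment
#'   columns) and `cost`; `ok = FALSE` (with everything else unset) when the
#'   chain's coordinates are inconsistent.
#' @export
extend_chain <- function(index, read, chain, scoring = align_scoring()) {
  stopifnot(inherits(index, "pyromap_index"), nrow(chain) >= 1L)
  r <- cpp_extend_chain(index$ptr, toupper(read),
                        as.integer(chain$start) - 1L, as.integer(chain$length),
                        chain$pos - 1,
                        scoring$mismatch, scoring$gap_open, scoring$gap_extend,
                        scoring$band_pad, scoring$end_slack)
  if (!r$ok) return(list(ok = FALSE))
  loc <- global_to_record(index, r$gstart0)
  list(ok = TRUE, record = loc$record, pos = loc$pos, gstart0 = r$gstart0,
       ops = r$ops, cigar = r$cigar,
       matches = r$matches, mismatches = r$mismatches,
       insertions = r$insertions, deletions = r$deletions,
       errors = r$mismatches + r$insertions + r$deletions,
       identity = r$identity, cost = r$cost, span = r$span)
}

#' Acceptance filter for a finished mapping
#'
#' Identity mode accepts when `identity * 100 >= t`; errors mode accepts
#' when `mismatches + inserted + deleted bases <= e`.
#'
#' @param mapping a mapping (from [extend_chain()] or a row of
#'   [map_reads()] output coerced to a list).
#' @param params a [pyromap_params()] object.
#' @return logical.
#' @export
accept_mapping <- function(mapping, params = pyromap_params()) {
  if (params$mode == "identity") {
    mapping$identity * 100 >= params$t
  } else {
    errs <- if (!is.null(mapping$errors)) mapping$errors
            else mapping$mismatches + mapping$insertions + mapping$deletions
    errs <= params$e
  }
}

#' Map a single read
#'
#' Runs seeding, chaining, candidate selection and extension on the forward
#' read and (by default) its reverse complement, applies the acceptance
#' filter, and reports either every accepted mapping or only the one(s) with
#' the fewest errors (ties: leftmost reference position, forward strand
#' first). An unmapped read yields a zero-row data.frame.
#'
#' @param index a `pyromap_index`.
#' @param read the read sequence (string).
#' @param params a [pyromap_params()] object.
#' @return data.frame, one row per reported mapping: `record`, 1-based
#'   `pos`, `strand` (`"+"`/`"-"`), `cigar` (using `=`/`X`/`I`/`D`),
#'   `matches`, `mismatches`, `insertions`, `deletions`, `errors`,
#'   `identity`.
#' @export
map_read <- function(index, read, params = pyromap_params()) {
  res <- map_reads(index, data.frame(id = "read", seq = read,
                                     stringsAsFactors = FALSE), params)
  res[res$mapped, setdiff(names(res), c("read_id", "mapped")), drop = FALSE]
}

#' Map a set of reads
#'
#' Vectorised driver for [map_read()]; the whole pipeline per read runs in
#' compiled code. Input read order is preserved; unmapped reads are kept as
#' rows with `mapped = FALSE`.
#'
#' @param index a `pyromap_index`.
#' @param reads a data.frame with columns `id` and `seq` (e.g. from
#'   [read_reads()]), a named character vector, or a FASTA/FASTQ path.
#' @param params a [pyromap_params()] object.
#' @return data.frame with `read_id`, `mapped`, `record`, `pos`, `strand`,
#'   `cigar`, tallies, `errors` and `identity`; multiple rows per read when
#'   `report = "all"` (or on best-mapping ties).
#' @export
map_reads <- function(index, reads, params = pyromap_params()) {
  stopifnot(inherits(index, "pyromap_index"), inherits(params, "pyromap_params"))
  reads <- as_read_df(reads)
  raw <- cpp_map_reads(index$ptr, toupper(reads$seq), params)
  loc <- global_to_record(index, raw$pos0)
  out <- data.frame(
    read_id = reads$id[raw$read],
    mapped = raw$mapped == 1L,
    record = loc$record,
    pos = loc$pos,
    strand = ifelse(is.na(raw$strand0), NA_character_,
                    ifelse(raw$strand0 == 0L, "+", "-")),
    cigar = raw$cigar,
    matches = raw$matches, mismatches = raw$mismatches,
    insertions = raw$insertions, deletions = raw$deletions,
    errors = raw$mismatches + raw$insertions + raw$deletions,
    identity = raw$identity,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
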