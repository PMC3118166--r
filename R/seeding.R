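#' Decompose a sequence into homopolymer runs
#'
#' A homopolymer is a maximal run of identical symbols; a single base counts
#' as a run of length one. This is the unit at which pyrosequencing reads a
#' template, and the unit at which the simulator injects errors.
#'
#' @param seq a single string.
#' @return data.frame with columns `base` and `length`; concatenating the
#'   runs reproduces `seq`.
#' @examples
#' homopolymer_runs("AAAACCCTT")
#' @export
homopolymer_runs <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L)
    return(data.frame(base = character(0), length = integer(0),
                      stringsAsFactors = FALSE))
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  data.frame(base = r$values, length = r$lengths, stringsAsFactors = FALSE)
}

#' Greedy maximal exact-match seeding of a read
#'
#' Repeatedly finds, from a cursor, the longest read prefix with exact
#' occurrences in the reference (via [longest_match()]) and emits it as a
#' seed. The cursor then advances by the skip rule: if the blocking read
#' symbol differs from the last matched symbol (a likely substitution), skip
#' exactly one symbol; if it repeats it, the mismatch happened inside a
#' homopolymer (a likely insertion), and the cursor jumps to the start of the
#' next homopolymer. A zero-length match (e.g. an `N` in the read) advances
#' the cursor by one. Seeding stops at the read end, or when a homopolymer
#' skip runs off the end of the read.
#'
#' Every emitted seed has at least one occurrence by construction. Seeds
#' shorter than `min_seed_len`, or with more than `max_occ` occurrences
#' (flagged `truncated`), are kept in the output but marked `anchor = FALSE`
#' and take no part in chaining; the read span they cover is recovered by the
#' gap-filling alignment during extension.
#'
#' @param index a `pyromap_index`.
#' @param read a single read sequence (string).
#' @param min_seed_len minimum anchor length.
#' @param max_occ occurrence cap per seed.
#' @param cursor 1-based read position where the first search starts. The
#'   whole-read mapper runs the decomposition from a few staggered cursors
#'   (see [pyromap_params()]) because a maximal match can be hijacked by a
#'   chance locus extending further than the read's true origin; a restart a
#'   few symbols deeper probes different boundaries and recovers such
#'   anchors.
#' @return data.frame of seeds in read order with 1-based `start`, `length`,
#'   occurrence count `occ`, flags `truncated` and `anchor`, the skip rule
#'   applied after the seed (`skip`: mismatch / homopolymer / read_end), and
#'   the internal reversed-index interval (`lo0`, `hi0`). The read is
#'   attached as attribute `"read"`.
#' @export
extract_seeds <- function(index, read, min_seed_len = 10L, max_occ = 500,
                          cursor = 1L) {
  stopifnot(inherits(index, "pyromap_index"), is.character(read), length(read) == 1L,
            cursor >= 1L)
  read <- toupper(read)
  df <- cpp_extract_seeds(index$ptr, read, as.integer(min_seed_len), max_occ,
                          as.integer(cursor) - 1L)
  df$start <- df$start0 + 1L
  df <- df[, c("start", "length", "occ", "truncated", "anchor", "skip", "lo0", "hi0", "start0")]
  attr(df, "read") <- read
  df
}

#' Seed diagnostics as BED-like rows
#'
#' @param seeds output of [extract_seeds()].
#' @param read_id label for the first column.
#' @return data.frame with `read`, 0-based `start`, `end`, `occ`.
#' @export
seed_bed <- function(seeds, read_id = "read") {
  data.frame(read = read_id, start = seeds$start0,
             end = seeds$start0 + seeds$length, occ = seeds$occ,
             stringsAsFactors = FALSE)
}
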