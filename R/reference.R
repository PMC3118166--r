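#' Encode reference records into a segment-aware concatenated text
#'
#' Uppercases the input, concatenates records with separator symbols and a
#' terminal sentinel, and replaces every maximal run of non-ACGT symbols by a
#' separator that splits the surrounding sequence into distinct segments.
#' Because the separator and sentinel sort below the DNA alphabet, no pattern
#' over \{A,C,G,T\} can ever match across a segment boundary, so alignments
#' never span assembly gaps or record junctions.
#'
#' @param records named character vector of sequences, or a data.frame with
#'   columns `id` and `seq`.
#' @return An object of class `reference_text`: a list with the encoded
#'   `text` (a single string ending in `"$"`), a `segments` data.frame with
#'   0-based global (`gstart0`, `gend0`) and record-local (`local0`)
#'   coordinates, and a `records` data.frame with original record lengths.
#' @examples
#' rt <- encode_reference(c(chr1 = "ACGT"))
#' rt$text  # "ACGT$"
#' @export
encode_reference <- function(records) {
  if (is.data.frame(records)) {
    x <- as.character(records$seq)
    names(x) <- as.character(records$id)
    records <- x
  }
  if (!is.character(records) || length(records) == 0L)
    stop("'records' must be a non-empty named character vector or data.frame")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("every record needs a name")
  seg_seq <- character(0)
  seg_rec <- integer(0)
  seg_local <- numeric(0)
  keep_names <- character(0)
  keep_len <- numeric(0)
  rec_id <- 0L
  for (r in seq_along(records)) {
    s <- toupper(records[[r]])
    runs <- gregexpr("[ACGT]+", s)[[1]]
    if (runs[1] == -1L) {
      warning("record '", names(records)[r], "' contains no ACGT symbols; dropped")
      next
    }
    keep_names <- c(keep_names, names(records)[r])
    keep_len <- c(keep_len, nchar(s))
    lens <- attr(runs, "match.length")
    for (k in seq_along(runs)) {
      seg_seq <- c(seg_seq, substr(s, runs[k], runs[k] + lens[k] - 1L))
      seg_rec <- c(seg_rec, rec_id)
      seg_local <- c(seg_local, runs[k] - 1)   # record-local, 0-based
    }
    rec_id <- rec_id + 1L
  }
  if (length(seg_seq) == 0L) stop("no usable sequence in 'records'")
  text <- paste0(paste(seg_seq, collapse = "#"), "$")
  lens <- nchar(seg_seq)
  gstart <- cumsum(c(0, lens[-length(lens)] + 1))  # one separator between segments
  structure(list(
    text = text,
    segments = data.frame(
      record = keep_names[seg_rec + 1L],
      rec_id = seg_rec,
      gstart0 = gstart,
      gend0 = gstart + lens,
      local0 = seg_local,
      stringsAsFactors = FALSE),
    records = data.frame(name = keep_names, length = keep_len,
                         stringsAsFactors = FALSE),
    n = nchar(text)
  ), class = "reference_text")
}

#' Map global text positions to record coordinates
#'
#' @param ref a `reference_text` or `pyromap_index`.
#' @param gpos0 numeric vector of 0-based global positions.
#' @return data.frame with `record` and 1-based record-local `pos`; positions
#'   falling on a separator yield `NA`.
#' @export
global_to_record <- function(ref, gpos0) {
  seg <- if (inherits(ref, "pyromap_index")) ref$segments else ref$segments
  i <- findInterval(gpos0, seg$gstart0)
  ok <- i >= 1L & gpos0 < seg$gend0[pmax(i, 1L)]
  data.frame(
    record = ifelse(ok, seg$record[pmax(i, 1L)], NA_character_),
    pos = ifelse(ok, seg$local0[pmax(i, 1L)] + (gpos0 - seg$gstart0[pmax(i, 1L)]) + 1, NA_real_),
    stringsAsFactors = FALSE)
}

#' Generate a uniform-random DNA reference
#'
#' Draws bases i.i.d. uniformly from \{A,C,G,T\} using the current RNG state
#' (use [set.seed()] for reproducibility).
#'
#' @param length number of bases.
#' @param name record name.
#' @return named character vector of length one.
#' @export
random_reference <- function(length, name = "ref") {
  stopifnot(length >= 1)
  s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  names(s) <- name
  s
}

#' Reverse-complement DNA strings
#'
#' @param x character vector over the IUPAC DNA alphabet (case preserved as
#'   upper case; `N` maps to `N`).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.reference_text <- function(x, ...) {
  cat("reference_text:", nrow(x$records), "record(s),",
      nrow(x$segments), "segment(s),", x$n, "symbols (incl. separators)\n")
  invisible(x)
}
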