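#' Suffix array of a terminated text
#'
#' Orders all suffixes of `text` lexicographically using prefix doubling
#' (practical for megabase-scale texts; never the naive quadratic sort).
#' Works on arbitrary byte alphabets; the caller supplies the terminated text
#' and the sentinel must be its lexicographically smallest symbol.
#'
#' @param text a single string ending in `"$"`.
#' @return integer vector of 1-based suffix start positions; subtract 1 for
#'   the 0-based convention used in the string-index literature.
#' @examples
#' build_suffix_array("abbbab$") - 1  # 6 4 0 5 3 2 1
#' @export
build_suffix_array <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (substr(text, nchar(text), nchar(text)) != "$")
    stop("'text' must end with the sentinel '$'")
  cpp_suffix_array(charToRaw(text)) + 1L
}

#' Burrows-Wheeler transform from a suffix array
#'
#' `BWT[i] = text[SA[i] - 1]`, wrapping at the first position, which is the
#' last column of the sorted rotations of the terminated text.
#'
#' @param text a single terminated string.
#' @param sa 1-based suffix array of `text` (see [build_suffix_array()]).
#' @return the BWT as a single string.
#' @examples
#' bwt_from_sa("abbbab$", build_suffix_array("abbbab$"))  # "bb$abba"
#' @export
bwt_from_sa <- function(text, sa) {
  n <- nchar(text)
  if (length(sa) != n) stop("suffix array length must equal text length")
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  idx <- ifelse(sa == 1L, n, sa - 1L)
  paste(ch[idx], collapse = "")
}

#' Build an FM-index over a reference
#'
#' Constructs the full query bundle: the encoded reference text, an FM-index
#' (BWT, cumulative counts, checkpointed ranks, sampled suffix array) over the
#' forward text for backward search, and a second FM-index over the reversed
#' text that realises forward longest-prefix matching as backward search with
#' position translation.
#'
#' @param ref a `reference_text`, a named character vector of sequences, or a
#'   path to a FASTA file.
#' @param rank_stride checkpoint spacing for rank queries (symbols).
#' @param sa_stride suffix-array sampling stride (text positions).
#' @return An object of class `pyromap_index`.
#' @export
build_index <- function(ref, rank_stride = 128L, sa_stride = 32L) {
  stopifnot(rank_stride >= 1, sa_stride >= 1)
  if (is.character(ref) && length(ref) == 1L && is.null(names(ref)) && file.exists(ref))
    ref <- read_fasta(ref)
  if (is.character(ref) || is.data.frame(ref)) ref <- encode_reference(ref)
  stopifnot(inherits(ref, "reference_text"))
  rec_id <- match(ref$segments$record, ref$records$name) - 1L
  ptr <- cpp_build_bundle(ref$text,
                          ref$segments$gstart0, ref$segments$gend0,
                          rec_id, ref$segments$local0,
                          ref$records$name, ref$records$length,
                          as.integer(rank_stride), as.integer(sa_stride))
  structure(list(ptr = ptr, text = ref$text, segments = ref$segments,
                 records = ref$records, n = ref$n,
                 rank_stride = as.integer(rank_stride),
                 sa_stride = as.integer(sa_stride)),
            class = "pyromap_index")
}

#' @export
print.pyromap_index <- function(x, ...) {
  cat("pyromap_index:", nrow(x$records), "record(s),", nrow(x$segments),
      "segment(s),", x$n, "indexed symbols",
      sprintf("(rank stride %d, SA stride %d)\n", x$rank_stride, x$sa_stride))
  invisible(x)
}

#' FM-index internals
#'
#' Returns the cumulative symbol counts (the C table: for each symbol, the
#' number of lexicographically smaller symbols in the text) and the BWT of
#' the forward index. Mainly useful for inspection and testing.
#'
#' @param index a `pyromap_index`.
#' @return list with elements `counts`, `bwt`, `n`, `rank_stride`,
#'   `sa_stride`.
#' @export
index_stats <- function(index) {
  stopifnot(inherits(index, "pyromap_index"))
  cpp_index_stats(index$ptr)
}

#' FM-index backward search
#'
#' Processes `pattern` right to left, one symbol per step, maintaining the
#' suffix-array interval of suffixes prefixed by the already-matched part.
#' Symbols outside \{A,C,G,T\} (and absent patterns) yield the empty interval.
#'
#' @param index a `pyromap_index`.
#' @param pattern a single string.
#' @return list with 0-based half-open interval `lo`, `hi` and its `size`.
#' @export
backward_search <- function(index, pattern) {
  stopifnot(inherits(index, "pyromap_index"), is.character(pattern), length(pattern) == 1L)
  iv <- cpp_backward_search(index$ptr, pattern)
  list(lo = iv[1], hi = iv[2], size = iv[2] - iv[1])
}

#' Locate the text positions of a suffix-array interval
#'
#' Resolves each row of the interval to a text position by LF-walking to the
#' nearest suffix-array sample. If the interval holds more than `max_occ`
#' rows, no positions are produced and the result is flagged truncated.
#'
#' @param index a `pyromap_index`.
#' @param lo,hi 0-based half-open interval (see [backward_search()]).
#' @param max_occ occurrence cap.
#' @return list with sorted 1-based global `pos` and logical `truncated`.
#' @export
locate_interval <- function(index, lo, hi, max_occ = Inf) {
  stopifnot(inherits(index, "pyromap_index"))
  r <- cpp_locate(index$ptr, lo, hi, max_occ)
  list(pos = r$pos + 1, truncated = r$truncated)
}

#' Longest exact match of a query prefix
#'
#' Finds the maximal `l >= 0` such that `substr(query, start, start + l - 1)`
#' occurs in the reference, together with the occurrence start positions.
#' Forward extension is realised by backward search over the FM-index of the
#' reversed text, with positions translated back to forward-strand starts.
#'
#' @param index a `pyromap_index`.
#' @param query a single string.
#' @param start 1-based start position in `query`.
#' @param max_occ occurrence cap; larger intervals report no positions and
#'   set `truncated`.
#' @return list with `length`, sorted 1-based global `pos`, and `truncated`.
#' @export
longest_match <- function(index, query, start = 1L, max_occ = Inf) {
  stopifnot(inherits(index, "pyromap_index"))
  r <- cpp_longest_match(index$ptr, query, as.integer(start) - 1L, max_occ)
  list(length = r$length, pos = r$pos + 1, truncated = r$truncated)
}

#' Persist an index to disk / load it back
#'
#' The on-disk format is a version-checked binary layout: an 8-byte magic
#' string, format version, strides, text length, record and segment tables,
#' the encoded text, and per index (forward and reversed) the BWT plus the
#' sampled suffix-array rows. Rank checkpoints and cumulative counts are
#' recomputed on load with a linear scan. Loading refuses files with a wrong
#' magic string or version, and truncated files fail cleanly.
#'
#' @param index a `pyromap_index`.
#' @param path file path.
#' @return `save_index` returns `path` invisibly; `load_index` returns a
#'   `pyromap_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "pyromap_index"))
  cpp_save_index(index$ptr, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  r <- cpp_load_index(path)
  segments <- data.frame(record = r$rec_names[r$seg_rec + 1L],
                         rec_id = r$seg_rec,
                         gstart0 = r$seg_start, gend0 = r$seg_end,
                         local0 = r$seg_local, stringsAsFactors = FALSE)
  structure(list(ptr = r$ptr, text = r$text, segments = segments,
                 records = data.frame(name = r$rec_names, length = r$rec_len,
                                      stringsAsFactors = FALSE),
                 n = r$n, rank_stride = r$rank_stride, sa_stride = r$sa_stride),
            class = "pyromap_index")
}
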