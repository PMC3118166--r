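#' Read a FASTA file
#'
#' Multi-record, wrapped lines, case-insensitive; record ids are taken up to
#' the first whitespace.
#'
#' @param path FASTA file.
#' @return named character vector of sequences (empty, with a warning, for
#'   an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  if (file.size(path) == 0L) {
    warning("'", path, "' is empty")
    return(setNames(character(0), character(0)))
  }
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop("malformed FASTA '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  s <- as.character(x)
  names(s) <- sub("\\s.*$", "", names(x))
  s
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' The format is auto-detected from the first character (`>` FASTA, `@`
#' FASTQ). Qualities are carried through unused by the mapping algorithm.
#'
#' @param path reads file.
#' @return data.frame with `id`, `seq` and (FASTQ only) `qual`.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  if (file.size(path) == 0L) {
    warning("'", path, "' is empty")
    return(data.frame(id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  first <- substr(readLines(path, n = 1L), 1, 1)
  if (first == ">") {
    s <- read_fasta(path)
    return(data.frame(id = names(s), seq = unname(s), stringsAsFactors = FALSE))
  }
  if (first != "@") stop("'", path, "' is neither FASTA nor FASTQ")
  x <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  data.frame(id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

# normalise the various read inputs into data.frame(id, seq[, qual])
as_read_df <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && is.null(names(reads)) &&
      file.exists(reads)) reads <- read_reads(reads)
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
    reads <- data.frame(id = ids, seq = unname(reads), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  reads
}

#' Write simulated reads as FASTA or FASTQ
#'
#' @param set a `sim_read_set` or a data.frame with `id` and `seq`.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"` (uniform `I` qualities).
#' @return `path`, invisibly.
#' @export
write_reads <- function(set, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  df <- if (inherits(set, "sim_read_set")) set$reads else set
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    writeLines(paste0(">", df$id, "\n", df$seq), con)
  } else {
    writeLines(paste0("@", df$id, "\n", df$seq, "\n+\n",
                      strrep("I", nchar(df$seq))), con)
  }
  invisible(path)
}

#' Write mappings as SAM
#'
#' Emits a valid minimal SAM file: `@HD`/`@SQ` header from the indexed
#' records, then one line per mapping in input read order. CIGARs use the
#' `=`/`X` operators (not `M`) so matches and mismatches are auditable from
#' the record alone; `NM` carries the error count; reverse-strand mappings
#' set FLAG 16 and store the reverse-complemented sequence per SAM
#' convention; unmapped reads get FLAG 4 and no coordinates.
#'
#' @param mappings output of [map_reads()].
#' @param index the `pyromap_index` used for mapping.
#' @param reads the read input given to [map_reads()] (for sequences and
#'   qualities).
#' @param path output SAM file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(mappings, index, reads, path) {
  stopifnot(inherits(index, "pyromap_index"))
  reads <- as_read_df(reads)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", index$records$name,
                   as.integer(index$records$length)),
           "@PG\tID:pyromap\tPN:pyromap")
  i <- match(mappings$read_id, reads$id)
  seqs <- toupper(reads$seq[i])
  quals <- if ("qual" %in% names(reads)) reads$qual[i] else rep(NA_character_, nrow(mappings))
  lines <- character(nrow(mappings))
  for (k in seq_len(nrow(mappings))) {
    m <- mappings[k, ]
    sq <- seqs[k]
    ql <- if (is.na(quals[k])) "*" else quals[k]
    if (!m$mapped) {
      lines[k] <- paste(m$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, sq, ql,
                        sep = "\t")
    } else {
      flag <- if (m$strand == "-") 16L else 0L
      if (m$strand == "-") {
        sq <- revcomp(sq)
        if (ql != "*") ql <- paste(rev(strsplit(ql, "")[[1]]), collapse = "")
      }
      lines[k] <- paste(m$read_id, flag, m$record, format(m$pos, scientific = FALSE),
                        255L, m$cigar, "*", 0L, 0L, sq, ql,
                        paste0("NM:i:", m$errors), sep = "\t")
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# minimal SAM reader for the evaluate CLI subcommand
read_sam_mappings <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0L)
    return(data.frame(read_id = character(0), mapped = logical(0),
                      record = character(0), pos = numeric(0),
                      strand = character(0), matches = integer(0),
                      errors = integer(0), stringsAsFactors = FALSE))
  f <- strsplit(ln, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  cig <- vapply(f, function(x) x[6], character(1))
  nmatch <- vapply(cig, function(cg) {
    if (cg == "*") return(NA_integer_)
    n <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[=XID]", cg))[[1]]
    sum(n[op == "="])
  }, integer(1), USE.NAMES = FALSE)
  data.frame(read_id = vapply(f, `[`, character(1), 1),
             mapped = bitwAnd(flag, 4L) == 0L,
             record = vapply(f, `[`, character(1), 3),
             pos = as.numeric(vapply(f, `[`, character(1), 4)),
             strand = ifelse(bitwAnd(flag, 16L) == 16L, "-", "+"),
             matches = nmatch, errors = nm, stringsAsFactors = FALSE)
}
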