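#' Simulator configuration
#'
#' Parameters of the pyrosequencing read simulator. Templates are random
#' contiguous subsequences of a source sequence with lengths drawn from
#' `Normal(mu_len, sd_len)`. Each homopolymer run of a template then suffers
#' exactly one of four mutually exclusive events: a substitution with
#' probability `p_sub`, an insertion with `p_ins`, a deletion with `p_del`,
#' or correct sequencing with `1 - (p_sub + p_ins + p_del)`. A substitution
#' replaces one uniformly chosen base of the run according to the miscall
#' matrix; an insertion lengthens the run by a Zipf-distributed number of
#' copies of its base; a deletion shortens it by a Zipf draw capped at the
#' run length. Indel lengths follow truncated power laws on `1..omega` with
#' exponents `gamma_ins` / `gamma_del`.
#'
#' Defaults are a typical GS FLX run at the low-error setting (1% per event
#' type per homopolymer, read length 250 +/- 50, `omega = 10`, `gamma = 3`,
#' equiprobable miscalls).
#'
#' @param n_reads number of reads.
#' @param mu_len,sd_len read length distribution (bases).
#' @param p_sub,p_ins,p_del per-homopolymer event probabilities; their sum
#'   must not exceed 1.
#' @param omega maximum gap length (positive integer).
#' @param gamma_ins,gamma_del Zipf exponents (> 0).
#' @param sub_matrix 4x4 miscall matrix over A,C,G,T: `sub_matrix[a, b]` is
#'   the probability that `a` is miscalled as `b`; zero diagonal, rows
#'   summing to 1. Default: uniform 1/3 off-diagonal.
#' @param strands `"forward"` (default) or `"both"` (strand sampled
#'   uniformly per read).
#' @param min_len floor on drawn read lengths (bases).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_reads = 2000L, mu_len = 250, sd_len = 50,
                       p_sub = 0.01, p_ins = 0.01, p_del = 0.01,
                       omega = 10L, gamma_ins = 3, gamma_del = 3,
                       sub_matrix = NULL, strands = c("forward", "both"),
                       min_len = 30L) {
  strands <- match.arg(strands)
  if (is.null(sub_matrix)) {
    sub_matrix <- matrix(1 / 3, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                                      c("A", "C", "G", "T")))
    diag(sub_matrix) <- 0
  }
  stopifnot(n_reads >= 0, mu_len > 0, sd_len >= 0,
            p_sub >= 0, p_ins >= 0, p_del >= 0, p_sub + p_ins + p_del <= 1,
            omega >= 1, gamma_ins > 0, gamma_del > 0,
            is.matrix(sub_matrix), all(dim(sub_matrix) == c(4, 4)),
            all(abs(diag(sub_matrix)) < 1e-12),
            all(abs(rowSums(sub_matrix) - 1) < 1e-9),
            min_len >= 1)
  structure(list(n_reads = as.integer(n_reads), mu_len = mu_len, sd_len = sd_len,
                 p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 omega = as.integer(omega), gamma_ins = gamma_ins,
                 gamma_del = gamma_del, sub_matrix = sub_matrix,
                 strands = strands, min_len = as.integer(min_len)),
            class = "sim_params")
}

#' Sample from a truncated Zipf (power-law) distribution
#'
#' Mass function `P(k) = k^-gamma / sum(j^-gamma, j = 1..omega)` on
#' `1..omega`. Uses the current RNG state.
#'
#' @param n number of draws.
#' @param omega support maximum (>= 1).
#' @param gamma shape (> 0); larger values favour shorter gaps.
#' @return integer vector in `1..omega`.
#' @export
zipf_sample <- function(n, omega, gamma) {
  stopifnot(n >= 0, omega >= 1, gamma > 0)
  if (n == 0L) return(integer(0))
  if (omega == 1L) return(rep(1L, n))
  p <- (seq_len(omega))^(-gamma)
  sample.int(omega, n, replace = TRUE, prob = p / sum(p))
}

#' Zipf probability mass function (for checks and plots)
#'
#' @param k integer vector.
#' @param omega,gamma distribution parameters.
#' @return numeric vector of probabilities (0 outside `1..omega`).
#' @export
zipf_pmf <- function(k, omega, gamma) {
  z <- sum((seq_len(omega))^(-gamma))
  ifelse(k >= 1 & k <= omega, k^(-gamma) / z, 0)
}

#' Simulate one read from a template location
#'
#' Extracts `substr(source, start, start + length - 1)` and applies the
#' per-homopolymer error model of [sim_params()], recording every event in
#' an edit log that deterministically reproduces the read via
#' [apply_edit_log()].
#'
#' @param source source sequence (string).
#' @param start 1-based template start.
#' @param length template length.
#' @param params a [sim_params()] object.
#' @return list with `seq` (the erroneous read), and `log`: a data.frame
#'   with one row per event (`run`, `base`, `run_len`, `event`, `sub_pos`,
#'   `sub_to`, `gap_len`).
#' @export
simulate_read <- function(source, start, length, params = sim_params()) {
  L <- nchar(source)
  if (start < 1 || length < 1 || start + length - 1 > L)
    stop("template [", start, ", ", start + length - 1, "] outside source of length ", L)
  template <- substr(source, start, start + length - 1)
  runs <- homopolymer_runs(template)
  H <- nrow(runs)
  u <- runif(H)
  ev <- rep("none", H)
  ev[u < params$p_sub] <- "sub"
  ev[u >= params$p_sub & u < params$p_sub + params$p_ins] <- "ins"
  ev[u >= params$p_sub + params$p_ins &
     u < params$p_sub + params$p_ins + params$p_del] <- "del"
  sub_pos <- rep(NA_integer_, H)
  sub_to <- rep(NA_character_, H)
  gap_len <- rep(NA_integer_, H)
  is_sub <- which(ev == "sub")
  for (i in is_sub) {  # per-run draws in read order, so replay is exact
    sub_pos[i] <- 1L + floor(runif(1) * runs$length[i])
    sub_to[i] <- sample(colnames(params$sub_matrix), 1L,
                        prob = params$sub_matrix[runs$base[i], ])
  }
  is_ins <- which(ev == "ins")
  if (length(is_ins)) gap_len[is_ins] <- zipf_sample(length(is_ins), params$omega,
                                                     params$gamma_ins)
  is_del <- which(ev == "del")
  if (length(is_del)) gap_len[is_del] <- zipf_sample(length(is_del), params$omega,
                                                     params$gamma_del)
  log <- data.frame(run = seq_len(H), base = runs$base, run_len = runs$length,
                    event = ev, sub_pos = sub_pos, sub_to = sub_to,
                    gap_len = gap_len, stringsAsFactors = FALSE)
  log <- log[log$event != "none", , drop = FALSE]
  rownames(log) <- NULL
  list(seq = apply_edit_log(template, log), log = log)
}

#' Replay an edit log against its template
#'
#' Applies the recorded per-homopolymer events to the template; by
#' construction the result equals the simulated read exactly, which makes
#' the truth tracking of the simulator verifiable.
#'
#' @param template template sequence (string).
#' @param log edit log data.frame (see [simulate_read()]).
#' @return the reconstructed read (string).
#' @export
apply_edit_log <- function(template, log) {
  runs <- homopolymer_runs(template)
  pieces <- strrep(runs$base, runs$length)
  if (nrow(log)) {
    for (k in seq_len(nrow(log))) {
      i <- log$run[k]
      ev <- log$event[k]
      if (ev == "sub") {
        s <- pieces[i]
        substr(s, log$sub_pos[k], log$sub_pos[k]) <- log$sub_to[k]
        pieces[i] <- s
      } else if (ev == "ins") {
        pieces[i] <- strrep(runs$base[i], runs$length[i] + log$gap_len[k])
      } else {
        pieces[i] <- strrep(runs$base[i], max(0L, runs$length[i] -
                                                   min(log$gap_len[k], runs$length[i])))
      }
    }
  }
  paste(pieces, collapse = "")
}

#' Generate a simulated read set with ground truth
#'
#' Draws `n_reads` template locations from the source (lengths
#' `Normal(mu_len, sd_len)` rounded and clamped to `[min_len, source
#' length]`, starts uniform over valid positions), applies the error model
#' per read, and tracks origins and edit logs. Deterministic given the RNG
#' state (`set.seed()`), bit-for-bit.
#'
#' @param source named character vector of length one (the source sequence),
#'   or an unnamed string (record name defaults to `"source"`).
#' @param params a [sim_params()] object.
#' @return list of class `sim_read_set` with `reads` (data.frame: `id`,
#'   `seq`, `record`, 1-based template `start`, template `length`, `strand`,
#'   `n_sub`, `n_ins`, `n_del` — the latter two in gap bases), `logs`
#'   (per-read edit logs), and `params`.
#' @export
generate_read_set <- function(source, params = sim_params()) {
  stopifnot(is.character(source), length(source) == 1L)
  rec <- if (is.null(names(source))) "source" else names(source)
  src <- toupper(source[[1]])
  L <- nchar(src)
  if (L <= params$mu_len)
    stop("source shorter than the mean read length")
  n <- params$n_reads
  if (n == 0L)
    return(structure(list(reads = data.frame(id = character(0), seq = character(0),
                                             record = character(0), start = numeric(0),
                                             length = integer(0), strand = character(0),
                                             n_sub = integer(0), n_ins = integer(0),
                                             n_del = integer(0), stringsAsFactors = FALSE),
                          logs = list(), params = params, source_name = rec),
                     class = "sim_read_set"))
  lens <- pmin(pmax(round(rnorm(n, params$mu_len, params$sd_len)), params$min_len), L)
  starts <- floor(runif(n) * (L - lens + 1)) + 1
  strands <- if (params$strands == "both")
    sample(c("+", "-"), n, replace = TRUE) else rep("+", n)
  ids <- sprintf("read%05d", seq_len(n))
  seqs <- character(n)
  logs <- vector("list", n)
  n_sub <- n_ins <- n_del <- integer(n)
  for (i in seq_len(n)) {
    r <- simulate_read(src, starts[i], lens[i], params)
    s <- r$seq
    if (strands[i] == "-") s <- revcomp(s)
    seqs[i] <- s
    logs[[i]] <- r$log
    lg <- r$log
    n_sub[i] <- sum(lg$event == "sub")
    n_ins[i] <- sum(lg$gap_len[lg$event == "ins"])
    n_del[i] <- sum(pmin(lg$gap_len[lg$event == "del"],
                         lg$run_len[lg$event == "del"]))
  }
  names(logs) <- ids
  structure(list(
    reads = data.frame(id = ids, seq = seqs, record = rec, start = starts,
                       length = as.integer(lens), strand = strands,
                       n_sub = n_sub, n_ins = n_ins, n_del = n_del,
                       stringsAsFactors = FALSE),
    logs = logs, params = params, source_name = rec), class = "sim_read_set")
}

#' @export
print.sim_read_set <- function(x, ...) {
  cat("sim_read_set:", nrow(x$reads), "reads from '", x$source_name, "' (",
      "p_sub=", x$params$p_sub, ", p_ins=", x$params$p_ins,
      ", p_del=", x$params$p_del, ")\n", sep = "")
  invisible(x)
}

#' Write the ground-truth table / read it back
#'
#' Tab-separated truth table: read id, source record, 1-based template
#' start, template length, strand, substitution events, inserted bases,
#' deleted bases.
#'
#' @param set a `sim_read_set`.
#' @param path output file.
#' @return `write_truth` returns `path` invisibly; `read_truth` a data.frame.
#' @export
write_truth <- function(set, path) {
  stopifnot(inherits(set, "sim_read_set"))
  write.table(set$reads[, c("id", "record", "start", "length", "strand",
                            "n_sub", "n_ins", "n_del")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
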