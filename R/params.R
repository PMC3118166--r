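#' Alignment scoring scheme
#'
#' Edit-like costs for the banded affine-gap (Gotoh) extension: matches are
#' free, a mismatch costs `mismatch`, and a gap of length k costs
#' `gap_open + k * gap_extend`. `band_pad` widens the DP band beyond the
#' length difference of the two segments; `end_slack` extends the reference
#' window beyond the read overhang at semi-global read ends.
#'
#' @param mismatch,gap_open,gap_extend non-negative integer costs.
#' @param band_pad band padding (bases) added to `|len(a) - len(b)|`.
#' @param end_slack extra reference bases in end windows.
#' @return list of class `align_scoring`.
#' @export
align_scoring <- function(mismatch = 1L, gap_open = 1L, gap_extend = 1L,
                          band_pad = 8L, end_slack = 16L) {
  stopifnot(mismatch >= 0, gap_open >= 0, gap_extend >= 0,
            band_pad >= 0, end_slack >= 0)
  structure(list(mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), band_pad = as.integer(band_pad),
                 end_slack = as.integer(end_slack)),
            class = "align_scoring")
}

#' Mapping parameters
#'
#' The full knob set of the seed-chain-extend pipeline. Acceptance is either
#' by overall alignment identity (`mode = "identity"`: accept when
#' `identity * 100 >= t`) or by error count (`mode = "errors"`: accept when
#' `mismatches + inserted + deleted bases <= e`).
#'
#' @param t identity threshold in percent (0-100).
#' @param e maximum error count (used when `mode = "errors"`).
#' @param mode `"identity"` or `"errors"`.
#' @param report `"best"` (fewest errors; ties broken by leftmost position,
#'   forward strand first) or `"all"` accepted mappings.
#' @param min_seed_len seeds shorter than this are found and reported but not
#'   used as chaining anchors.
#' @param max_occ seeds with more reference occurrences than this are flagged
#'   truncated and not used as anchors.
#' @param eps_min,rho chain-coherence slack: a link is coherent when the
#'   reference distance differs from the read distance `a` by at most
#'   `max(eps_min, ceiling(rho * a))`.
#' @param top number of largest candidates (span-ranked, leftmost first on
#'   ties) extended per decomposition pass and strand.
#' @param restart_offsets 0-based cursor offsets at which the greedy seed
#'   decomposition is (re)started. A single pass probes only one set of
#'   cursor positions, and at high error rates a maximal match is often
#'   hijacked by a chance locus that extends further than the read's true
#'   origin, silently dropping the true occurrence; extra passes starting a
#'   few symbols deeper decorrelate the seed boundaries and recover those
#'   anchors. Candidates from all passes compete under the fewest-errors
#'   rule. Use `0L` for the single textbook pass.
#' @param rescue enable the dense k-mer fallback: when the primary pipeline
#'   leaves a read unmapped or its best hit below `rescue_identity` percent
#'   identity, exact `rescue_k`-mer probes at `rescue_stride` spacing
#'   (each with at most `rescue_max_occ` occurrences) are clustered by
#'   alignment diagonal and extended with the ordinary machinery. This
#'   recovers reads so error-dense that no maximal-match anchor survives.
#' @param rescue_k,rescue_stride,rescue_max_occ,rescue_identity rescue
#'   tuning, see `rescue`.
#' @param polish refine every accepted candidate with one unconstrained
#'   whole-read semi-global alignment over its reference window, replacing
#'   the stitched alignment only when strictly cheaper. Removes start-
#'   placement artifacts that anchor conditioning can cause on noisy read
#'   heads.
#' @param scoring an [align_scoring()] object.
#' @param both_strands map the reverse complement as well.
#' @return list of class `pyromap_params`.
#' @export
pyromap_params <- function(t = 50, e = 0L, mode = c("identity", "errors"),
                           report = c("best", "all"),
                           min_seed_len = 10L, max_occ = 500,
                           eps_min = 5L, rho = 0.1, top = 8L,
                           restart_offsets = c(0L, 3L, 7L, 11L, 15L, 19L),
                           rescue = TRUE, rescue_k = 9L, rescue_stride = 1L,
                           rescue_max_occ = 64, rescue_identity = 68,
                           polish = TRUE,
                           scoring = align_scoring(), both_strands = TRUE) {
  mode <- match.arg(mode)
  report <- match.arg(report)
  stopifnot(t >= 0, t <= 100, e >= 0, min_seed_len >= 1, max_occ >= 1,
            eps_min >= 0, rho >= 0, top >= 1,
            length(restart_offsets) >= 1, all(restart_offsets >= 0),
            !anyDuplicated(restart_offsets),
            rescue_k >= 4, rescue_stride >= 1, rescue_max_occ >= 1,
            inherits(scoring, "align_scoring"))
  structure(c(list(t = t, e = as.integer(e), mode = mode, report = report,
                   min_seed_len = as.integer(min_seed_len), max_occ = max_occ,
                   eps_min = as.integer(eps_min), rho = rho, top = as.integer(top),
                   restart_offsets = as.integer(restart_offsets),
                   rescue = isTRUE(rescue), rescue_k = as.integer(rescue_k),
                   rescue_stride = as.integer(rescue_stride),
                   rescue_max_occ = rescue_max_occ,
                   rescue_identity = rescue_identity,
                   polish = isTRUE(polish),
                   both_strands = isTRUE(both_strands)),
              unclass(scoring)),
            class = "pyromap_params")
}
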