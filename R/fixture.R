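#' Construct the three-seed worked-example instance
#'
#' Builds, programmatically and deterministically, a small reference/read
#' pair with a fully known seeding and chaining structure: a 15-base read
#' whose template occurs at reference position 101 (1-based) with one
#' inserted base at read position 5 and one substituted base at read
#' position 9, so that greedy seeding yields exactly the three seeds
#' `AAAA` (unique, at 101), `CCCT` (only an accidental occurrence at a
#' decoy locus at 201) and `GGGTT` (unique, at 110). The first and third
#' seeds form a coherent chain spanning 9 seed bases; the lone decoy
#' occurrence spans 4 and is not selected. Extension of the winning chain
#' reproduces the template locus: position 101, CIGAR `4=1I3=1X6=`.
#'
#' The background sequence is a repeated `TGCA` unit, which cannot contain
#' any of the three seeds; every structural constraint (seed content,
#' uniqueness, occurrence positions, maximality of each seed, absence of a
#' `CCCTA` extension at the decoy) is asserted at generation time.
#'
#' @return list with `reference` (named character), `read` (named
#'   character), `template_pos` (101), `decoy_pos` (201), and the expected
#'   `seeds` data.frame (1-based read `start`, `length`, `occ_pos`).
#' @export
worked_example_fixture <- function() {
  read <- "AAAAGCCCTAGGGTT"
  template <- "AAAACCCAAGGGTT"   # read minus the insertion, with the
                                 # substituted base restored to 'A'
  # background units are chosen so no junction recreates a seed: the prefix
  # must not end in 'A' (would extend AAAA) and the tail after the decoy
  # must not start with 'A' (would extend CCCT into the read continuation)
  pre <- strrep("ACGT", 25)                      # positions 1..100, ends in T
  mid <- substr(strrep("ACGT", 23), 1, 86)       # positions 115..200
  tail <- strrep("TGCA", 24)                     # positions 205..300, starts T
  ref <- paste0(pre, template, mid, "CCCT", tail)
  stopifnot(nchar(ref) == 300)
  count <- function(p, s) {
    m <- gregexpr(p, s, fixed = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }
  at <- function(p, s) gregexpr(p, s, fixed = TRUE)[[1]][1]
  # template and decoy are where the construction says they are
  stopifnot(substr(ref, 101, 114) == template,
            substr(ref, 201, 204) == "CCCT")
  # seed occurrence structure of the worked example
  stopifnot(count("AAAA", ref) == 1L, at("AAAA", ref) == 101L,
            count("GGGTT", ref) == 1L, at("GGGTT", ref) == 110L,
            count("CCCT", ref) == 1L, at("CCCT", ref) == 201L)
  # maximality of each seed against the read continuation
  stopifnot(count("AAAAG", ref) == 0L,   # first seed cannot extend
            count("CCCTA", ref) == 0L)   # second seed cannot extend
  list(reference = c(ref = ref),
       read = c(worked_example = read),
       template_pos = 101L, decoy_pos = 201L,
       seeds = data.frame(start = c(1L, 6L, 11L), length = c(4L, 4L, 5L),
                          seq = c("AAAA", "CCCT", "GGGTT"),
                          occ_pos = c(101L, 201L, 110L),
                          stringsAsFactors = FALSE))
}
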