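#' Collect and sort the reference occurrences of anchor seeds
#'
#' Locates every occurrence of each anchor seed (seeds flagged short or
#' truncated are skipped) and returns them sorted by reference position,
#' ties broken by seed index, ready for the greedy left-to-right chain scan.
#'
#' @param index a `pyromap_index`.
#' @param seeds output of [extract_seeds()].
#' @return data.frame with `seed` (1-based row index into `seeds`), `start`,
#'   `length` (copied from the seed), and 1-based global position `pos`.
#' @export
collect_occurrences <- function(index, seeds) {
  stopifnot(inherits(index, "pyromap_index"))
  df <- cpp_collect_occurrences(index$ptr, seeds$start0, seeds$length,
                                seeds$lo0, seeds$hi0, seeds$anchor)
  data.frame(seed = df$seed0 + 1L,
             start = seeds$start[df$seed0 + 1L],
             length = seeds$length[df$seed0 + 1L],
             pos = df$pos0 + 1,
             stringsAsFactors = FALSE)
}

#' Test the coherence of two seed occurrences
#'
#' Two occurrences are coherent when they respect the seeds' read order, lie
#' in the same reference segment, and their reference distance matches the
#' read distance `a` between the seeds (the concatenation of everything
#' skipped between them) within slack `max(eps_min, ceiling(rho * a))`:
#' `a - eps <= p_next - (p_prev + len_prev) <= a + eps`.
#'
#' @param index a `pyromap_index`.
#' @param seeds output of [extract_seeds()].
#' @param prev,next_ single-row subsets of a [collect_occurrences()] result
#'   (or lists with `seed` and `pos`).
#' @param eps_min,rho slack policy.
#' @return logical.
#' @export
seed_coherent <- function(index, seeds, prev, next_, eps_min = 5L, rho = 0.1) {
  stopifnot(inherits(index, "pyromap_index"))
  cpp_coherent(index$ptr,
               as.integer(prev$seed) - 1L, prev$pos - 1,
               as.integer(next_$seed) - 1L, next_$pos - 1,
               seeds$start0, seeds$length, as.integer(eps_min), rho)
}

#' Greedy chaining of sorted seed occurrences
#'
#' A single left-to-right scan over the position-sorted occurrence list: the
#' current chain is extended by the next occurrence iff it is coherent with
#' the chain's tail; otherwise the chain is closed and a new one starts
#' there. Every occurrence belongs to exactly one chain, and partial chains
#' (containing only some of the read's seeds) are retained. The scan
#' performs exactly one coherence test per occurrence, so work is linear in
#' the number of occurrences rather than in the product of per-seed
#' occurrence counts.
#'
#' @param index a `pyromap_index`.
#' @param occs output of [collect_occurrences()].
#' @param seeds output of [extract_seeds()].
#' @param eps_min,rho slack policy (see [seed_coherent()]).
#' @return list of chains, each a data.frame of member occurrences (`seed`,
#'   `start`, `length`, `pos`) with attribute `span` (total seed bases).
#'   The list carries attribute `n_tests`, the number of coherence tests
#'   performed.
#' @export
chain_occurrences <- function(index, occs, seeds, eps_min = 5L, rho = 0.1) {
  stopifnot(inherits(index, "pyromap_index"))
  if (nrow(occs) == 0L) {
    out <- list()
    attr(out, "n_tests") <- 0
    return(out)
  }
  r <- cpp_chain(index$ptr, as.integer(occs$seed) - 1L, occs$pos - 1,
                 seeds$start0, seeds$length, as.integer(eps_min), rho)
  chains <- split(occs, r$chain0)
  chains <- lapply(chains, function(ch) {
    rownames(ch) <- NULL
    attr(ch, "span") <- sum(ch$length)
    ch
  })
  names(chains) <- NULL
  attr(chains, "n_tests") <- r$n_tests
  chains
}

#' Chain span (total seed bases covered)
#'
#' @param chain one element of a [chain_occurrences()] result.
#' @return integer.
#' @export
chain_span <- function(chain) sum(chain$length)

#' Select the largest candidate chains for extension
#'
#' Returns every chain tied for the maximal span (total seed bases covered),
#' up to `top`, in deterministic leftmost-first order. Downstream extension
#' breaks remaining ties by error count.
#'
#' @param chains a [chain_occurrences()] result.
#' @param top maximum number of candidates.
#' @return sub-list of `chains`.
#' @export
select_candidates <- function(chains, top = 5L) {
  if (length(chains) == 0L) return(chains)
  spans <- vapply(chains, chain_span, numeric(1))
  sel <- which(spans == max(spans))
  chains[sel[seq_len(min(length(sel), top))]]
}
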