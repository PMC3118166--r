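---
title: "Mapping pyrosequencing reads with pyromap: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping pyrosequencing reads with pyromap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyromap)
```

## The problem

454/GS FLX pyrosequencing reads a template one maximal homopolymer (run of
identical bases) at a time. Its dominant error mode is misjudging a run's
length — an insertion or deletion of identical bases — with substitutions
comparatively rare. Reads are a few hundred bases long. In re-sequencing,
where a close reference exists, the practical question is how to map hundreds
of thousands of such reads to a reference of megabases to gigabases, fast and
accurately, despite the indel-heavy error profile.

`pyromap` implements a seed-and-extend mapper built for exactly this error
profile, together with a generative simulator of the same error process and a
truth-based evaluation harness, so that every claim about mapping accuracy
can be checked end to end inside the package.

## The index

The reference records are uppercased and concatenated with separator symbols;
maximal runs of non-ACGT characters split the sequence into segments (we do
not invent bases for assembly gaps), and a terminal sentinel closes the text.
Separator and sentinel sort below the DNA alphabet, so no ACGT pattern can
match across a segment boundary, and no alignment can span one.

Over this text we build a suffix array by prefix doubling (O(n log² n) worst
case; on genomic text the ranks separate after a few rounds) and derive the
Burrows–Wheeler transform by `BWT[i] = text[SA[i] − 1]`. The FM-index keeps
the BWT, cumulative symbol counts, rank checkpoints every 128 symbols and
suffix-array samples every 32 text positions (both configurable; these are
conventional space/time trade-offs). Backward search processes a pattern
right-to-left, one symbol per step; `locate` resolves suffix-array rows by
LF-walking to the nearest sample.

Forward maximal-prefix matching — "how far does the read match, starting
here?" — is realised with a *second* FM-index over the reversed text:
occurrences of `p` in `g` correspond to occurrences of reversed `p` in
reversed `g`, so appending a symbol to the forward match is prepending to the
reversed pattern, which is exactly one backward-search step. Positions are
translated back to forward-strand starts. This keeps all matching on a single
primitive at the cost of one extra index (the dominant memory term, ~2× the
text).

## Seeding

From a cursor, the longest read prefix with at least one exact reference
occurrence becomes a seed. The skip rule then encodes the error model:

* if the blocking read symbol differs from the last matched symbol, the
  mismatch is most likely a substitution — skip exactly one symbol;
* if it repeats the last matched symbol, the difference sits inside a
  homopolymer and is most likely a length over-call — jump to the start of
  the next homopolymer.

A zero-length match advances the cursor by one; a homopolymer that runs to
the read end terminates seeding. Seeds shorter than `min_seed_len` (default
10) or with more than `max_occ` occurrences (default 500) are reported but
not used as chaining anchors — combinations of short, frequent seeds explode
combinatorially while carrying little positional information; their read span
is recovered later by the gap-filling alignment.

## Chaining

Occurrences of all anchor seeds are located and sorted by reference position
(ties: seed index). Two consecutive occurrences are *coherent* when they
respect the seeds' read order, lie in one segment, and the reference distance
matches the read distance `a` between the seeds within slack
`ε = max(eps_min, ⌈ρ·a⌉)` (defaults 5 and 0.1; the slack absorbs the net
indel drift expected between anchors). A single left-to-right scan partitions
the occurrence list into maximal runs of consecutive coherent occurrences —
one coherence test per occurrence, linear overall, versus the product of
per-seed occurrence counts a naive pairing would cost. Partial chains are
kept. The largest candidates — most seed bases covered — go forward to
extension.

## Extension

A candidate chain decomposes read and reference into seed blocks (exact by
construction) and intervening segments. Inner segment pairs are aligned
globally by a banded three-state Gotoh dynamic program under edit-like costs:
match 0, mismatch 1, gap of length k costs `1 + k` (open 1, extend 1). The
band is a diagonal corridor of the length difference plus `band_pad = 8`
columns — wider than the chain slack, so any chain-consistent alignment fits.
The two read ends are aligned semi-globally against reference windows of the
segment length plus `end_slack = 16` bases: reference overhang at the outer
end is free, all read symbols must be consumed, and windows truncated by a
segment boundary penalise the overhanging read bases as insertions. Ties are
broken deterministically (match/mismatch over insertion over deletion), and
blocks are stitched into one edit path whose leftmost consumed reference
column is the mapping position.

A mapping is accepted either when its identity — matches divided by all
alignment columns, the conservative definition — reaches the threshold `t`
(percent), or when its error count (mismatches + inserted + deleted bases)
stays within `e`. Both strands are always tried; `report = "best"` returns
the fewest-error mapping(s) with ties broken by leftmost position, then
forward strand.

## Hard reads: restarts, rescue, polish

Three additions, all switchable in `pyromap_params()`, address failure modes
that a single greedy decomposition provably hits at high error rates:

* **Staggered restarts.** The maximal match from a cursor is maximal over
  the *whole* reference: on a 2 Mbp random reference a chance locus extends a
  match to ~10–11 bp, so when the read's true-locus match is shorter, the
  true occurrence silently drops out of the seed's interval ("hijacking").
  One decomposition probes only one set of cursor positions; re-running the
  identical procedure from offsets 0, 3, 7, 11, 15, 19 decorrelates the seed
  boundaries and recovers lost anchors. Per pass, the `top = 8` largest
  candidates (span-ranked, leftmost first) are extended; extensions are
  deduplicated across passes by mapping diagonal, and all candidates compete
  under the fewest-errors rule.
* **Dense k-mer rescue.** When every pass fails (no accepted hit, or best
  identity below 68%), exact 9-mer probes at every read position are located,
  clustered by alignment diagonal, reduced to a non-overlapping coherent
  subset and extended by the ordinary machinery, ranked by anchored read
  bases. This recovers reads whose longest error-free stretch is too short to
  survive maximal-match seeding at all.
* **Final polish.** The stitched alignment is conditioned on its anchors;
  on a noisy read head that can misplace the reported start beyond the net
  indel drift. Each accepted candidate is therefore re-aligned once,
  unconstrained and semi-global, over its own reference window, and replaced
  only when the free alignment is strictly cheaper — exact stitched paths and
  their CIGARs are never perturbed.

These mechanisms matter only near the high end of the error range: at 1%
per-homopolymer error rates they almost never trigger and the textbook
pipeline alone maps essentially everything.

## The simulator

`generate_read_set()` draws template lengths from Normal(μ = 250, σ = 50)
(rounded, clamped to ≥ 30 bases and to the source length) and template starts
uniformly. Each homopolymer run of the template then experiences exactly one
of: substitution (probability `p_sub`), insertion (`p_ins`), deletion
(`p_del`), or correct sequencing (the remainder) — the events are mutually
exclusive per run. A substitution rewrites one uniformly chosen base of the
run according to the miscall matrix (default: uniform 1/3 off-diagonal); an
insertion lengthens the run by a draw from a truncated power law
`P(k) ∝ k^(−γ)` on `1..ω` (defaults ω = 10, γ = 3 for both gap types); a
deletion shortens it by a draw capped at the run length. Every event is
recorded in an edit log whose replay reproduces the read exactly — truth
tracking is testable, not assumed.

Deliberate simplifications (and what they mean for interpreting results):
errors are uniform along the read, whereas real quality decays towards the 3'
end; indel prevalence and size are independent of homopolymer length, whereas
real over/under-calls grow with run length; reads are generated forward-only
by default (a flag samples strands) so truth checks stay simple while the
mapper always tries both strands. Passing accuracy tests on this generator
therefore demonstrates robustness to the *rate* and *kind* of pyrosequencing
errors, not to their positional structure, nor to the repeat structure of
real genomes — a uniform-random reference is less repetitive than a real
chromosome, which makes anchoring easier at a given length.

Accuracy is scored as the fraction of all simulated reads whose best mapping
lands on the true record and strand within 10 bases of the true start; the
tolerance absorbs the start shifts that indels near read heads cause, and
unmapped reads count against accuracy.

## Numerical and design choices

* Coherence inequality: `a − ε ≤ d ≤ a + ε` with `d` the reference gap and
  `a` the read gap, generalised to the concatenated skipped region when
  intermediate seeds are absent from a chain.
* Identity denominator includes gap bases (columns), the conservative choice;
  errors count gap *bases*, not gap events, matching the matches-per-error
  (bp/err) reporting convention.
* Cost scheme is edit-distance-like (match 0) because acceptance is
  error-based; the affine structure (open + extend) is exposed for tuning.
* The worked 15-base example instance is mapped with `min_seed_len = 4`: its
  three seeds are 4–5 bp by construction, below the production default of 10.
* Degenerate inputs: records with no ACGT bases are dropped with a warning;
  non-ACGT read symbols terminate seeds and are alignable only as errors;
  empty patterns return the full suffix-array interval; empty alignments have
  cost 0.
* Problem sizes in the test suite: scaled synthetic-accuracy checks use a
  2 Mbp uniform-random reference and 2,000 reads per error setting; the
  banded-versus-unbanded comparison uses 100 reads at 1% error on 100 kbp;
  statistical checks on the simulator use ≥ 10⁵ homopolymer runs. These
  sizes give stable statistics while keeping the whole suite comfortably
  interactive.

## Known limitations

Base qualities are carried but ignored by scoring; there is no paired-read or
split/chimeric alignment; reporting is per-read (no mapping-quality model);
the index is rebuilt rather than updated for new references; and the rescue
stage, while cheap (it triggers on a small fraction of reads), makes the
effective seeding strategy adaptive, so runtimes grow somewhat with the error
rate.

## A five-line session

```{r example, eval = FALSE}
set.seed(1)
ref <- random_reference(1e6)
idx <- build_index(ref)
reads <- generate_read_set(ref, sim_params(n_reads = 500, p_sub = .05,
                                           p_ins = .05, p_del = .05))
res <- map_reads(idx, reads$reads, pyromap_params(t = 50))
evaluate_accuracy(res, reads, tolerance = 10)
```
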