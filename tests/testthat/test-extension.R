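# Banded affine-gap extension, semi-global ends, stitching, acceptance,
# whole-read mapping.

test_that("banded affine alignment reproduces hand-derived costs", {
  r <- banded_affine_align("GCCCTA", "CCCAA")
  expect_equal(r$cost, 3)  # 1-base gap (1+1) plus one mismatch
  o <- strsplit(r$ops, "")[[1]]
  expect_equal(sum(o == "="), 4)
  expect_equal(sum(o %in% c("X", "I", "D")), 2)  # two error bases
  # identical segments: all-match, cost 0
  id <- banded_affine_align("ACGTACGT", "ACGTACGT")
  expect_equal(id$cost, 0)
  expect_equal(id$ops, strrep("=", 8))
  # forced gap: open + 3 * extend
  gap <- banded_affine_align("AAA", "")
  expect_equal(gap$cost, 4)
  expect_equal(gap$ops, "III")
  # both empty
  expect_equal(banded_affine_align("", "")$cost, 0)
})

test_that("banded alignment matches the unbanded full-matrix oracle", {
  set.seed(71)
  for (rep in 1:30) {
    la <- sample(0:25, 1)
    a <- if (la) random_dna(la) else ""
    # related or unrelated b
    b <- if (runif(1) < 0.5) random_dna(sample(0:25, 1)) else {
      bc <- strsplit(a, "", fixed = TRUE)[[1]]
      if (length(bc) > 2) bc[sample(length(bc), 1)] <- "A"
      paste(bc, collapse = "")
    }
    got <- banded_affine_align(a, b, align_scoring(band_pad = 64))
    exp <- oracle_gotoh(a, b)
    expect_equal(got$cost, exp$cost, info = paste(a, b))
    expect_valid_edit_path(got$ops, nchar(a))
  }
})

test_that("alignment costs agree with an independent aligner on global instances", {
  skip_if_not_installed("Biostrings")
  set.seed(72)
  submat <- matrix(-1L, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  diag(submat) <- 0L
  for (rep in 1:15) {
    a <- random_dna(sample(5:30, 1))
    b <- random_dna(sample(5:30, 1))
    got <- banded_affine_align(a, b, align_scoring(band_pad = 64))
    pa <- suppressWarnings(Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = submat,
      gapOpening = 1, gapExtension = 1))
    expect_equal(got$cost, -as.numeric(Biostrings::score(pa)), info = paste(a, b))
  }
})

test_that("semi-global ends leave outer reference overhang cost-free", {
  # right end: match + mismatch beats the gapped alternative
  r <- semiglobal_end_align("AG", "ATG", end = "right")
  expect_equal(r$cost, 1)
  expect_equal(r$ops, "=X")
  # empty segment
  expect_equal(semiglobal_end_align("", "ACGT", end = "right")$cost, 0)
  expect_equal(semiglobal_end_align("", "ACGT", end = "left")$cost, 0)
  # no reference room: all insertions
  r2 <- semiglobal_end_align("ACG", "", end = "right")
  expect_equal(r2$cost, 1 + 3)
  # left end: leading overhang free, alignment abuts the right edge
  l <- semiglobal_end_align("TTT", "ACGTTT", end = "left")
  expect_equal(l$cost, 0)
  expect_equal(l$lead, 3)
})

test_that("chain extension stitches the worked example into the expected mapping", {
  fx <- worked_example_fixture()
  idx <- build_index(fx$reference)
  seeds <- extract_seeds(idx, fx$read[[1]], min_seed_len = 4)
  ch <- chain_occurrences(idx, collect_occurrences(idx, seeds), seeds)
  m <- extend_chain(idx, fx$read[[1]], select_candidates(ch)[[1]])
  expect_true(m$ok)
  expect_equal(m$pos, 101)
  expect_equal(m$cigar, "4=1I3=1X6=")
  expect_equal(m$matches, 13)
  expect_equal(m$insertions, 1)
  expect_equal(m$mismatches, 1)
  expect_equal(m$identity, 13 / 15, tolerance = 1e-12)
  expect_valid_edit_path(m$ops, 15)
})

test_that("an error-free read extends to an all-match path with identity 1", {
  set.seed(73)
  g <- random_dna(1000)
  idx <- build_index(c(g = g))
  r <- substr(g, 301, 420)
  seeds <- extract_seeds(idx, r)
  ch <- chain_occurrences(idx, collect_occurrences(idx, seeds), seeds)
  m <- extend_chain(idx, r, ch[[1]])
  expect_equal(m$identity, 1)
  expect_equal(m$ops, strrep("=", 120))
  expect_equal(m$pos, 301)
})

test_that("identity, error tallies and the edit path stay mutually consistent", {
  set.seed(74)
  ref <- random_reference(50000)
  idx <- build_index(ref)
  rs <- generate_read_set(ref, sim_params(n_reads = 40, p_sub = .03,
                                          p_ins = .03, p_del = .03))
  m <- map_reads(idx, rs$reads, pyromap_params())
  m <- m[m$mapped, ]
  expect_gt(nrow(m), 30)
  for (k in seq_len(nrow(m))) {
    n <- as.integer(regmatches(m$cigar[k], gregexpr("[0-9]+", m$cigar[k]))[[1]])
    op <- regmatches(m$cigar[k], gregexpr("[=XID]", m$cigar[k]))[[1]]
    expect_equal(sum(n[op %in% c("=", "X", "I")]),
                 nchar(rs$reads$seq[rs$reads$id == m$read_id[k]]))
    expect_equal(sum(n[op == "="]), m$matches[k])
    expect_equal(m$errors[k], m$mismatches[k] + m$insertions[k] + m$deletions[k])
    expect_equal(m$identity[k], m$matches[k] / sum(n), tolerance = 1e-12)
  }
})

test_that("acceptance thresholds behave at the boundaries", {
  mp <- list(identity = 13 / 15, errors = 2L, mismatches = 1L,
             insertions = 1L, deletions = 0L)
  expect_true(accept_mapping(mp, pyromap_params(t = 85)))
  expect_false(accept_mapping(mp, pyromap_params(t = 90)))
  perfect <- list(identity = 1, errors = 0L)
  expect_true(accept_mapping(perfect, pyromap_params(t = 100)))
  expect_true(accept_mapping(mp, pyromap_params(e = 2, mode = "errors")))
  mp3 <- mp; mp3$errors <- 3L
  expect_false(accept_mapping(mp3, pyromap_params(e = 2, mode = "errors")))
})

test_that("whole-read mapping finds unique origins on both strands", {
  set.seed(75)
  g <- random_dna(5000)
  idx <- build_index(c(g = g))
  r <- substr(g, 2001, 2200)
  fwd <- map_read(idx, r)
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$pos, 2001)
  expect_equal(fwd$strand, "+")
  expect_equal(fwd$identity, 1)
  rev <- map_read(idx, revcomp(r))
  expect_equal(rev$pos, 2001)
  expect_equal(rev$strand, "-")
  # unmapped read: empty result
  un <- map_read(idx, strrep("A", 60))
  expect_equal(nrow(un), 0L)
})

test_that("report = all returns every accepted locus of a repeated sequence", {
  core <- "ACCGTTAGGCATCCGATTACGGCATTAAC"
  g <- paste0(strrep("TGCA", 8), core, strrep("GACT", 8), core, strrep("TGCA", 8))
  idx <- build_index(c(g = g))
  all_hits <- map_read(idx, core, pyromap_params(report = "all", min_seed_len = 5))
  expect_equal(nrow(all_hits), 2L)
  expect_true(all(all_hits$identity == 1))
  best <- map_read(idx, core, pyromap_params(report = "best", min_seed_len = 5))
  # equal-error ties resolved to the leftmost first
  expect_equal(best$pos[1], min(all_hits$pos))
})
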