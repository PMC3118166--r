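# Index layer: reference encoding, suffix array, BWT, backward search,
# locate, forward longest match, persistence.

test_that("reference encoding splits segments at non-ACGT runs and round-trips coordinates", {
  rt <- encode_reference(c(chr1 = "ACGT"))
  expect_equal(rt$text, "ACGT$")
  expect_equal(nrow(rt$segments), 1L)
  expect_equal(rt$segments$gstart0, 0)
  expect_equal(rt$segments$gend0, 4)

  rt2 <- encode_reference(c(a = "ACG", b = "TT"))
  expect_equal(nrow(rt2$segments), 2L)
  # first base of record b round-trips to (b, 1)
  loc <- global_to_record(rt2, rt2$segments$gstart0[2])
  expect_equal(loc$record, "b")
  expect_equal(loc$pos, 1)

  rt3 <- encode_reference(c(c = "ACNNGT"))
  expect_equal(nrow(rt3$segments), 2L)
  expect_equal(rt3$segments$local0, c(0, 4))
  # positions inside the second segment map to record offsets past the Ns
  loc3 <- global_to_record(rt3, rt3$segments$gstart0[2] + 1)
  expect_equal(loc3$pos, 6)

  expect_error(encode_reference(character(0)))
  expect_warning(rt4 <- encode_reference(c(good = "ACGT", bad = "NNN")),
                 "no ACGT")
  expect_equal(nrow(rt4$records), 1L)
})

test_that("no search result ever crosses a segment split", {
  idx <- build_index(c(c = "ACGTACNNGTACGT"))
  # "CGTACG" spans the split in record coordinates: must not be found
  expect_equal(backward_search(idx, "ACGTACGT")$size, 0)
  # but each side is present
  expect_gt(backward_search(idx, "ACGTAC")$size, 0)
  expect_gt(backward_search(idx, "GTACGT")$size, 0)
  # oracle scan of each segment agrees with locate for a within-segment pattern
  iv <- backward_search(idx, "GTAC")
  pos <- locate_interval(idx, iv$lo, iv$hi)$pos
  expect_setequal(global_to_record(idx, pos - 1)$record, "c")
})

test_that("suffix array and BWT reproduce the classic worked text", {
  sa <- build_suffix_array("abbbab$")
  expect_equal(sa - 1, c(6, 4, 0, 5, 3, 2, 1))
  expect_equal(bwt_from_sa("abbbab$", sa), "bb$abba")
  expect_equal(build_suffix_array("a$") - 1, c(1, 0))
  expect_equal(bwt_from_sa("a$", build_suffix_array("a$")), "a$")
  expect_error(build_suffix_array("abc"))
})

test_that("suffix array equals the naive suffix sort and BWT equals the rotation sort", {
  set.seed(11)
  for (rep in 1:5) {
    txt <- paste0(random_dna(200), "$")
    sa <- build_suffix_array(txt)
    expect_equal(sa, naive_suffix_array(txt))
    expect_true(setequal(sa, seq_len(nchar(txt))))  # permutation
    bwt <- bwt_from_sa(txt, sa)
    expect_equal(bwt, rotation_bwt(txt))
    expect_equal(lf_inverse_bwt(bwt), txt)  # inversion reproduces the text
  }
})

test_that("cumulative counts and rank conservation hold on the DNA index", {
  idx <- build_index(c(r = "ACCGGGTTTT"))
  st <- index_stats(idx)
  # counts[c] = number of strictly smaller symbols in the text, under the
  # index's symbol order (sentinel < separator < A < C < G < T)
  sym_rank <- function(x) match(x, c("$", "#", "A", "C", "G", "T"))
  ch <- strsplit(idx$text, "", fixed = TRUE)[[1]]
  for (s in c("$", "#", "A", "C", "G", "T"))
    expect_equal(unname(st$counts[s]), sum(sym_rank(ch) < sym_rank(s)), info = s)
  # the BWT is a permutation of the text's symbols
  expect_equal(sort(strsplit(st$bwt, "")[[1]]), sort(ch))
})

test_that("backward search and locate agree with the naive substring scan", {
  set.seed(21)
  idx <- build_index(c(g = random_dna(1500)))
  g <- read_fasta_text <- idx$text
  for (rep in 1:40) {
    plen <- sample(1:12, 1)
    pat <- random_dna(plen)
    iv <- backward_search(idx, pat)
    pos <- locate_interval(idx, iv$lo, iv$hi)$pos
    expect_setequal(pos, naive_occurrences(g, pat))
  }
  # empty pattern: full interval
  expect_equal(backward_search(idx, "")$size, idx$n)
  # locate of full interval is a permutation of all positions
  full <- locate_interval(idx, 0, idx$n)
  expect_setequal(full$pos, seq_len(idx$n))
  # non-ACGT symbol: empty interval
  expect_equal(backward_search(idx, "ACNGT")$size, 0)
  # truncation flag
  ivA <- backward_search(idx, "A")
  tr <- locate_interval(idx, ivA$lo, ivA$hi, max_occ = 3)
  expect_true(tr$truncated)
  expect_length(tr$pos, 0)
})

test_that("forward longest match is maximal and agrees with the naive oracle", {
  idx <- build_index(c(g = "ACCCAC"))
  r <- longest_match(idx, "ACCCCA", 1)
  expect_equal(r$length, naive_longest_match("ACCCAC", "ACCCCA", 1))
  expect_equal(r$length, 4)  # "ACCC" occurs, "ACCCC" does not
  expect_equal(r$pos, 1)
  # start at query end
  expect_equal(longest_match(idx, "ACCCCA", 7)$length, 0)
  # first symbol absent
  expect_equal(longest_match(idx, "NACC", 1)$length, 0)
  # property on random instances
  set.seed(31)
  g2 <- random_dna(400)
  idx2 <- build_index(c(g = g2))
  q <- random_dna(60)
  for (s in sample(1:55, 12)) {
    r2 <- longest_match(idx2, q, s)
    l0 <- naive_longest_match(g2, q, s)
    expect_equal(r2$length, l0, info = paste("start", s))
    if (r2$length > 0)
      expect_setequal(r2$pos,
                      naive_occurrences(g2, substr(q, s, s + r2$length - 1)))
  }
})

test_that("index persistence round-trips all query results and rejects bad files", {
  set.seed(41)
  g <- random_dna(800)
  idx <- build_index(c(ref = g), rank_stride = 64, sa_stride = 16)
  path <- tempfile(fileext = ".idx")
  save_index(idx, path)
  idx2 <- load_index(path)
  expect_equal(idx2$rank_stride, 64L)
  expect_equal(idx2$sa_stride, 16L)
  for (rep in 1:100) {
    pat <- random_dna(sample(2:10, 1))
    a <- backward_search(idx, pat)
    b <- backward_search(idx2, pat)
    expect_identical(a, b)
    expect_identical(locate_interval(idx, a$lo, a$hi),
                     locate_interval(idx2, b$lo, b$hi))
  }
  # truncated file fails cleanly
  raw <- readBin(path, "raw", file.size(path))
  trunc <- tempfile()
  writeBin(raw[seq_len(200)], trunc)
  expect_error(load_index(trunc), "truncated|corrupt")
  # wrong magic refused
  bad <- tempfile()
  writeBin(c(charToRaw("NOTANIDX"), raw[-(1:8)]), bad)
  expect_error(load_index(bad), "not a pyromap index")
})
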