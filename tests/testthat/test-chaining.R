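# Coherent chaining: occurrence collection, the coherence predicate, the
# greedy left-to-right scan, candidate selection.

worked_setup <- function() {
  fx <- worked_example_fixture()
  idx <- build_index(fx$reference)
  seeds <- extract_seeds(idx, fx$read[[1]], min_seed_len = 4)
  list(fx = fx, idx = idx, seeds = seeds,
       occs = collect_occurrences(idx, seeds))
}

test_that("occurrences are sorted by position with seed-index tie-break", {
  w <- worked_setup()
  expect_equal(w$occs$pos, c(101, 110, 201))
  expect_equal(w$occs$seed, c(1L, 3L, 2L))
  # empty seed set
  empty <- w$seeds[0, ]
  expect_equal(nrow(collect_occurrences(w$idx, empty)), 0L)
})

test_that("occurrence collection equals a naive scan of every anchor seed", {
  set.seed(61)
  g <- random_dna(1200)
  idx <- build_index(c(g = g))
  r <- paste0(substr(g, 101, 140), "A", substr(g, 300, 340))
  seeds <- extract_seeds(idx, r, min_seed_len = 5)
  occs <- collect_occurrences(idx, seeds)
  expected <- do.call(rbind, lapply(which(seeds$anchor), function(i) {
    s <- substr(r, seeds$start[i], seeds$start[i] + seeds$length[i] - 1)
    data.frame(seed = i, pos = naive_occurrences(g, s))
  }))
  expected <- expected[order(expected$pos, expected$seed), ]
  expect_equal(occs$seed, expected$seed)
  expect_equal(occs$pos, expected$pos)
})

test_that("the coherence predicate honours order, segment and distance slack", {
  w <- worked_setup()
  o <- w$occs
  s1 <- o[o$seed == 1, ]; s2 <- o[o$seed == 2, ]; s3 <- o[o$seed == 3, ]
  # genome gap 5 vs read gap 6 within slack 5
  expect_true(seed_coherent(w$idx, w$seeds, s1, s3))
  # seed order violated: s3 at 110 before s2 at 201
  expect_false(seed_coherent(w$idx, w$seeds, s3, s2))
  # boundary: genome gap exactly the read gap at zero slack
  idx <- build_index(c(g = "ACGTTTGCAA"))
  seeds <- data.frame(start = c(1L, 6L), length = c(3L, 3L),
                      start0 = c(0L, 5L), stringsAsFactors = FALSE)
  a <- list(seed = 1, pos = 1); b <- list(seed = 2, pos = 6)  # gap 2 == read gap 2
  expect_true(seed_coherent(idx, seeds, a, b, eps_min = 0, rho = 0))
  b2 <- list(seed = 2, pos = 7)
  expect_false(seed_coherent(idx, seeds, a, b2, eps_min = 0, rho = 0))
})

test_that("greedy chaining reproduces the worked example and partitions occurrences", {
  w <- worked_setup()
  ch <- chain_occurrences(w$idx, w$occs, w$seeds)
  expect_length(ch, 2L)
  expect_equal(ch[[1]]$pos, c(101, 110))
  expect_equal(ch[[2]]$pos, 201)
  expect_equal(vapply(ch, chain_span, 1), c(9, 4))
  # partition property
  expect_equal(sum(vapply(ch, nrow, 1L)), nrow(w$occs))
  # single occurrence -> singleton chain
  ch1 <- chain_occurrences(w$idx, w$occs[1, ], w$seeds)
  expect_length(ch1, 1L)
  expect_equal(nrow(ch1[[1]]), 1L)
})

test_that("every adjacent pair in every chain re-checks as coherent", {
  set.seed(62)
  g <- random_dna(3000)
  idx <- build_index(c(g = g))
  for (rep in 1:5) {
    start <- sample(1:2700, 1)
    r <- substr(g, start, start + 120)
    rch <- strsplit(r, "", fixed = TRUE)[[1]]
    for (k in sample(15:100, 4)) rch[k] <- sample(c("A","C","G","T"), 1)
    r <- paste(rch, collapse = "")
    seeds <- extract_seeds(idx, r, min_seed_len = 6)
    occs <- collect_occurrences(idx, seeds)
    ch <- chain_occurrences(idx, occs, seeds)
    for (c in ch) {
      if (nrow(c) < 2) next
      for (k in 2:nrow(c))
        expect_true(seed_coherent(idx, seeds, c[k - 1, ], c[k, ]))
    }
  }
})

test_that("the greedy scan equals exhaustive enumeration on small instances", {
  # random synthetic occurrence lists over a toy index; <= 8 occurrences
  idx <- build_index(c(g = random_dna(500)))
  set.seed(63)
  for (rep in 1:40) {
    k <- sample(3:6, 1)                     # number of seeds
    starts <- cumsum(sample(3:10, k, TRUE))
    lens <- sample(3:8, k, TRUE)
    seeds <- data.frame(start = starts, length = lens,
                        start0 = starts - 1L, stringsAsFactors = FALSE)
    n <- sample(3:8, 1)
    occs <- data.frame(seed = sort(sample(seq_len(k), n, TRUE)),
                       pos = sort(sample(1:200, n)))
    occs <- occs[order(occs$pos, occs$seed), ]
    ch <- chain_occurrences(idx, occs, seeds)
    coh <- function(i, j) seed_coherent(idx, seeds, occs[i, ], occs[j, ])
    # independent re-derivation of the leftmost-maximal partition
    oracle_blocks <- enumerate_greedy_partition(n, coh)
    got_lens <- vapply(ch, nrow, 1L)
    expect_equal(unname(got_lens), vapply(oracle_blocks, length, 1L))
    # exhaustive enumeration: the greedy partition is among the partitions
    # into all-coherent consecutive blocks, and each of its blocks is maximal
    parts <- all_consecutive_partitions(n)
    is_valid <- function(p) all(vapply(p, function(bl) {
      length(bl) < 2 || all(vapply(2:length(bl),
                                   function(t) coh(bl[t - 1], bl[t]), TRUE))
    }, TRUE))
    greedy_part <- oracle_blocks
    expect_true(is_valid(greedy_part))
    expect_true(any(vapply(parts, function(p) identical(p, greedy_part), TRUE)))
    ends <- cumsum(vapply(greedy_part, length, 1L))
    for (e in ends[-length(ends)]) expect_false(coh(e, e + 1L))
  }
})

test_that("the number of coherence tests is linear in the occurrence count", {
  set.seed(64)
  g <- random_dna(2000)
  idx <- build_index(c(g = g))
  r <- paste0(substr(g, 101, 160), substr(g, 501, 560))
  seeds <- extract_seeds(idx, r, min_seed_len = 5)
  occs <- collect_occurrences(idx, seeds)
  ch <- chain_occurrences(idx, occs, seeds)
  expect_lte(attr(ch, "n_tests"), max(0, nrow(occs) - 1))
})

test_that("candidate selection keeps the spanning ties, leftmost first", {
  w <- worked_setup()
  ch <- chain_occurrences(w$idx, w$occs, w$seeds)
  sel <- select_candidates(ch)
  expect_length(sel, 1L)
  expect_equal(chain_span(sel[[1]]), 9)
  # one chain -> itself
  expect_identical(select_candidates(ch[1]), ch[1])
  # empty input -> empty output
  expect_length(select_candidates(list()), 0L)
  # two tied loci both returned, then broken downstream by error count
  g <- paste0(strrep("TGCA", 10), "AAACCCGGGTTTAT", strrep("TGCA", 10),
              "AAACCCGGGTTTGC", strrep("TGCA", 10))
  idx <- build_index(c(g = g))
  r <- "AAACCCGGGTTTAT"
  seeds <- extract_seeds(idx, r, min_seed_len = 4)
  occs <- collect_occurrences(idx, seeds)
  ch2 <- chain_occurrences(idx, occs, seeds)
  sel2 <- select_candidates(ch2)
  if (length(sel2) == 2L) {
    maps <- lapply(sel2, function(c) extend_chain(idx, r, c))
    errs <- vapply(maps, function(m) m$errors, 1)
    expect_true(min(errs) == 0)
  }
  best <- map_read(idx, r, pyromap_params(min_seed_len = 4))
  expect_equal(best$errors[1], 0)
})
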