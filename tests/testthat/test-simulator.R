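# Pyrosequencing read simulator: Zipf gaps, per-homopolymer events, truth
# tracking, evaluation metrics.

test_that("zipf sampling honours its analytic mass function", {
  expect_true(all(zipf_sample(50, omega = 1, gamma = 2) == 1L))
  # omega = 2, gamma = 1: P(1) = 2/3
  expect_equal(zipf_pmf(1, 2, 1), 2 / 3, tolerance = 1e-12)
  set.seed(81)
  draws <- zipf_sample(100000, omega = 2, gamma = 1)
  se <- sqrt(2 / 3 * 1 / 3 / 100000)
  expect_lt(abs(mean(draws == 1L) - 2 / 3), 3 * se)
  # omega = 10, gamma = 3: P(1) = 1 / sum k^-3
  expect_equal(zipf_pmf(1, 10, 3), 1 / sum((1:10)^-3), tolerance = 1e-12)
  expect_equal(zipf_pmf(1, 10, 3), 0.8350508, tolerance = 1e-6)
  expect_error(zipf_sample(5, omega = 0, gamma = 1))
  expect_error(zipf_sample(5, omega = 5, gamma = 0))
})

test_that("error-free simulation returns the template with an empty log", {
  set.seed(82)
  src <- random_dna(500)
  p0 <- sim_params(p_sub = 0, p_ins = 0, p_del = 0)
  r <- simulate_read(src, 101, 200, p0)
  expect_equal(r$seq, substr(src, 101, 300))
  expect_equal(nrow(r$log), 0L)
  expect_error(simulate_read(src, 450, 100, p0), "outside")
})

test_that("deletions are capped at the run length", {
  # a template of two-base runs with certain deletion and gaps drawn up to 10
  set.seed(83)
  src <- strrep("AACCGGTT", 20)
  pdel <- sim_params(p_sub = 0, p_ins = 0, p_del = 1, omega = 10,
                     gamma_del = 0.2)
  r <- simulate_read(src, 1, 80, pdel)
  # every run loses min(drawn gap, run length) bases, never more
  lost <- pmin(r$log$gap_len, r$log$run_len)
  expect_true(all(lost <= r$log$run_len))
  expect_equal(nchar(r$seq), 80L - sum(lost))
  # and a forced oversized deletion removes exactly the whole run
  one <- data.frame(run = 1L, base = "A", run_len = 2L, event = "del",
                    sub_pos = NA_integer_, sub_to = NA_character_,
                    gap_len = 5L, stringsAsFactors = FALSE)
  expect_equal(apply_edit_log("AACC", one), "CC")
})

test_that("substitution event counts match the binomial expectation", {
  set.seed(84)
  src <- random_dna(120000)
  p <- sim_params(p_sub = 0.05, p_ins = 0, p_del = 0)
  r <- simulate_read(src, 1, 120000, p)
  H <- nrow(homopolymer_runs(substr(src, 1, 120000)))
  nsub <- sum(r$log$event == "sub")
  se <- sqrt(H * 0.05 * 0.95)
  expect_lt(abs(nsub - 0.05 * H), 4 * se)
  # substituted bases are never the original base
  runs <- homopolymer_runs(substr(src, 1, 120000))
  subs <- r$log[r$log$event == "sub", ]
  expect_true(all(subs$sub_to != runs$base[subs$run]))
})

test_that("per-run event frequencies match their probabilities within 4 SE", {
  set.seed(85)
  src <- random_dna(150000)
  p <- sim_params(p_sub = 0.05, p_ins = 0.05, p_del = 0.05)
  r <- simulate_read(src, 1, 150000, p)
  H <- nrow(homopolymer_runs(src))
  expect_gt(H, 1e5)
  for (ev in c("sub", "ins", "del")) {
    se <- sqrt(H * 0.05 * 0.95)
    expect_lt(abs(sum(r$log$event == ev) - 0.05 * H), 4 * se, label = ev)
  }
})

test_that("indel gap lengths follow the truncated power law (chi-square, 1%)", {
  set.seed(86)
  src <- random_dna(200000)
  p <- sim_params(p_sub = 0, p_ins = 0.3, p_del = 0.3, omega = 10,
                  gamma_ins = 3, gamma_del = 3)
  r <- simulate_read(src, 1, 200000, p)
  pk <- zipf_pmf(1:10, 10, 3)
  for (ev in c("ins", "del")) {
    gl <- r$log$gap_len[r$log$event == ev]
    # deletions are drawn from the same law before capping; test the draws
    obs <- tabulate(gl, nbins = 10)
    keep <- pk * length(gl) >= 5
    test <- suppressWarnings(stats::chisq.test(obs[keep], p = pk[keep],
                                               rescale.p = TRUE))
    expect_gt(test$p.value, 0.01, label = ev)
  }
})

test_that("edit-log replay reproduces every simulated read exactly", {
  set.seed(87)
  ref <- random_reference(20000)
  rs <- generate_read_set(ref, sim_params(n_reads = 60, p_sub = .08,
                                          p_ins = .08, p_del = .08))
  for (i in seq_len(60)) {
    tmpl <- substr(ref[[1]], rs$reads$start[i],
                   rs$reads$start[i] + rs$reads$length[i] - 1)
    expect_identical(apply_edit_log(tmpl, rs$logs[[i]]), rs$reads$seq[i])
  }
})

test_that("read lengths follow the requested normal distribution", {
  set.seed(88)
  ref <- random_reference(100000)
  rs <- generate_read_set(ref, sim_params(n_reads = 5000, mu_len = 250,
                                          sd_len = 50, p_sub = 0, p_ins = 0,
                                          p_del = 0))
  se <- 50 / sqrt(5000)
  expect_lt(abs(mean(rs$reads$length) - 250), 3 * se)
  expect_true(all(rs$reads$length >= 30))
  expect_true(all(rs$reads$start >= 1 &
                  rs$reads$start + rs$reads$length - 1 <= 100000))
})

test_that("generation is deterministic under a fixed seed and n = 0 yields an empty set", {
  ref <- random_reference(5000)
  set.seed(89); a <- generate_read_set(ref, sim_params(n_reads = 25))
  set.seed(89); b <- generate_read_set(ref, sim_params(n_reads = 25))
  expect_identical(a$reads, b$reads)
  expect_identical(a$logs, b$logs)
  set.seed(90)
  empty <- generate_read_set(ref, sim_params(n_reads = 0))
  expect_equal(nrow(empty$reads), 0L)
})

test_that("accuracy scoring counts record, strand and start tolerance", {
  truth <- data.frame(id = sprintf("r%d", 1:10), record = "g",
                      start = seq(100, 1000, 100), strand = "+",
                      stringsAsFactors = FALSE)
  maps <- data.frame(read_id = truth$id, mapped = TRUE, record = "g",
                     pos = truth$start, strand = "+", stringsAsFactors = FALSE)
  expect_equal(as.numeric(evaluate_accuracy(maps, truth)), 1.0)
  maps2 <- maps
  maps2$pos[1:2] <- maps2$pos[1:2] + 500  # two deliberately wrong
  expect_equal(as.numeric(evaluate_accuracy(maps2, truth)), 0.8)
  # monotone in tolerance
  maps3 <- maps
  maps3$pos <- maps3$pos + 7
  expect_lte(as.numeric(evaluate_accuracy(maps3, truth, tolerance = 0)),
             as.numeric(evaluate_accuracy(maps3, truth, tolerance = 10)))
  expect_equal(as.numeric(evaluate_accuracy(maps3, truth, tolerance = 10)), 1.0)
})

test_that("pooled matches-per-error handles floors and empty input", {
  m <- data.frame(matches = 13L, errors = 2L)
  expect_equal(matches_per_error(m), 6.5)
  m2 <- data.frame(matches = 200L, errors = 0L)
  expect_equal(matches_per_error(m2), 200)  # denominator floored at one
  m3 <- data.frame(matches = c(10L, 20L), errors = c(1L, 3L))
  expect_equal(matches_per_error(m3), 7.5)
  expect_true(is.na(matches_per_error(data.frame(matches = integer(0),
                                                 errors = integer(0)))))
})
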