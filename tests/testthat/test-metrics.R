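test_that("the sampled-fraction series reproduces the known DNA values", {
  expect_equal(round(specificity_fraction(ry, p = 0.25), 3), 0.327)
  expect_equal(round(specificity_fraction(rr, p = 0.25), 3), 0.291)
  expect_equal(round(specificity_fraction(upper_bound_profile(4, 25),
                                          p = 0.25), 3), 0.332)
})

test_that("the series accepts any profile source and respects its tail bound", {
  # word set and its precomputed profile agree
  direct <- specificity_fraction(ry)
  via_profile <- specificity_fraction(run_hit_profile(ry, 30))
  expect_equal(direct, via_profile, tolerance = 1e-10)
  # syncmer schemes work through their exact profiles
  expect_gt(specificity_fraction(syncmer_scheme(w = 4, kind = "closed")), 0)
  # a short, unplateaued profile is refused
  expect_error(specificity_fraction(c(0.25, 0.5), p = 0.25), "tail")
  # a plateaued profile is evaluated exactly despite truncation
  expect_equal(specificity_fraction(pmin(1:6 / 4, 1), p = 0.25),
               specificity_fraction(upper_bound_profile(4, 40), p = 0.25))
})

test_that("entrywise-larger profiles give larger sampled fractions and coverage", {
  h_ry <- run_hit_profile(ry, 25)
  h_rr <- run_hit_profile(rr, 25)
  expect_gt(specificity_fraction(h_ry), specificity_fraction(h_rr))
  expect_lte(specificity_fraction(h_ry),
             specificity_fraction(upper_bound_profile(4, 25)) + 1e-12)
  expect_gt(expected_coverage(h_ry, m = 7, q = 0.9),
            expected_coverage(h_rr, m = 7, q = 0.9))
})

test_that("run-count distribution matches closed forms at small m", {
  d1 <- run_count_distribution(1, 0.7)
  expect_equal(d1$prob, c(0.3, 0.7))
  q <- 0.9
  d2 <- run_count_distribution(2, q)
  expect_equal(d2$prob[3], q^3)
  expect_equal(d2$prob[2], 2 * q^2 * (1 - q))
  expect_equal(sum(d2$prob), 1)
  d_cons <- run_count_distribution(5, 1)
  expect_equal(d_cons$prob[6], 1)
  expect_equal(sum(run_count_distribution(7, 0.37)$prob), 1)
  expect_error(run_count_distribution(13, 0.5), "m <= 12")
})

test_that("coverage collapses to density times conservation at m = 1", {
  pr <- run_hit_profile(ry, 3)
  expect_equal(expected_coverage(pr, m = 1, q = 0.8), 0.25 * 0.8)
  expect_error(expected_coverage(pr, m = 5, q = 0.8), "m = 5")
})

test_that("expected coverage matches a letter-coverage simulation", {
  m <- 7; q <- 0.9
  theory <- expected_coverage(run_hit_profile(ry, m), m = m, q = q)
  # simulate mutated pairs; a letter is covered when a sampled, fully
  # conserved length-m window overlaps it
  L <- 6000L
  reps <- 8L
  covered <- numeric(reps)
  for (r in seq_len(reps)) {
    anc <- generate_iid_sequence(L, seed = 1000 + r)
    pair <- mutate_sequence(anc, q, seed = 2000 + r)
    sampled <- rep(FALSE, L)
    sampled[sample_positions(anc, ry)$start + 1L] <- TRUE
    cons <- pair$conserved
    win_ok <- rep(TRUE, L - m + 1L)
    for (j in seq_len(m)) win_ok <- win_ok & cons[j:(L - m + j)]
    win_sampled <- win_ok & sampled[seq_len(L - m + 1L)]
    cov <- rep(FALSE, L)
    for (i in which(win_sampled)) cov[i:(i + m - 1L)] <- TRUE
    # focal letters away from the edges so exactly m windows cover each
    focal <- m:(L - m + 1L)
    covered[r] <- mean(cov[focal])
  }
  se <- stats::sd(covered) / sqrt(reps)
  expect_lt(abs(mean(covered) - theory), 3 * se + 1e-4)
})

test_that("distance distributions match hand derivations and simulation", {
  dd_all <- distance_distribution(word_set(all_kmers(2)), 5)
  expect_equal(dd_all$prob[1], 1)
  expect_equal(attr(dd_all, "variance"), 0)

  dd <- distance_distribution(ry, 80)
  expect_equal(dd$prob[1], 0)
  expect_equal(dd$prob[2], 1 / 4)
  expect_lt(attr(dd, "tail_mass"), 1e-9)
  expect_equal(attr(dd, "mean"), 4, tolerance = 1e-8)   # mean(D) = s

  # empirical gaps on a long simulated sequence
  s <- generate_iid_sequence(4e5, alphabet = c("r", "y"), seed = 31)
  gaps <- diff(sample_positions(s, ry)$start)
  emp <- tabulate(gaps, nbins = 80) / length(gaps)
  se <- sqrt(pmax(dd$prob * (1 - dd$prob), 1e-8) / length(gaps))
  expect_true(all(abs(emp - dd$prob) <= 4 * se + 1e-3))
  expect_equal(mean(gaps), 4, tolerance = 0.02)
})

test_that("mean distance equals sparsity across random word sets", {
  withr::with_seed(41, {
    for (i in 1:10) {
      k <- sample(2:4, 1)
      n <- sample(seq_len(2^k), 1)
      ws <- random_word_set(k, n)
      dd <- distance_distribution(ws, 600)
      if (attr(dd, "tail_mass") < 1e-8) {
        expect_equal(attr(dd, "mean"), 2^k / n, tolerance = 1e-6)
      }
    }
  })
})

test_that("maximizing long-run average hit probability minimizes distance variance", {
  # exhaustive at small scale: the two rankings coincide
  for (cfg in list(c(2, 2), c(3, 2), c(3, 3), c(3, 4))) {
    k <- cfg[1]; n <- cfg[2]
    kmers <- all_kmers(k)
    combos <- utils::combn(kmers, n, simplify = FALSE)
    score <- vapply(combos, function(w) {
      mean(run_hit_profile(word_set(w), 32)$h)
    }, numeric(1))
    neg_var <- vapply(combos, function(w) {
      -attr(distance_distribution(word_set(w), 400), "variance")
    }, numeric(1))
    if (stats::sd(score) == 0 || stats::sd(neg_var) == 0) {
      # all sets equivalent: both orderings must be flat
      expect_equal(diff(range(score)), 0)
      expect_equal(diff(range(neg_var)), 0)
    } else {
      expect_equal(stats::cor(score, neg_var, method = "spearman"), 1)
      expect_equal(which.max(score), which.max(neg_var))
    }
  }
})
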