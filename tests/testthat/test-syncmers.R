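test_that("scheme construction validates parameters and derives w, t", {
  s <- syncmer_scheme(k = 10, j = 6, kind = "open")
  expect_equal(s$w, 5L)
  expect_equal(s$t, 3L)   # ceiling(w/2) default
  expect_error(syncmer_scheme(k = 5, j = 7), "j")
  expect_error(syncmer_scheme(w = 4, kind = "open", t = 5), "t")
  expect_error(syncmer_scheme(w = 4, downsample = 0.5), "downsample")
  expect_error(syncmer_scheme(k = 10, j = 6, w = 4), "inconsistent")
})

test_that("rank windows classify by the position of the minimum", {
  closed3 <- syncmer_scheme(w = 3, kind = "closed")
  open2 <- syncmer_scheme(w = 3, kind = "open", t = 2)
  expect_true(classify_rank_window(c(1, 3, 2), closed3))
  expect_true(classify_rank_window(c(3, 1, 2), open2))
  expect_false(classify_rank_window(c(3, 2, 1), open2))
  expect_true(classify_rank_window(c(3, 2, 1), closed3))
  expect_error(classify_rank_window(c(1, 1, 2), open2), "tie")
  expect_error(classify_rank_window(c(1, 2), open2), "w = 3")
})

test_that("densities are 1/w (open) and 2/w (closed), divided by down-sampling", {
  expect_equal(syncmer_density(syncmer_scheme(w = 5, kind = "open")), 0.2)
  expect_equal(syncmer_density(syncmer_scheme(w = 4, kind = "closed")), 0.5)
  expect_equal(syncmer_density(syncmer_scheme(w = 5, kind = "open",
                                              downsample = 2)), 0.1)
  expect_equal(sparsity(syncmer_scheme(w = 6, kind = "closed")), 3)
})

test_that("exact profiles match hand-derived values", {
  expect_equal(syncmer_hit_profile_exact(
    syncmer_scheme(w = 2, kind = "open", t = 1), 1)$h[1], 0.5)
  expect_equal(syncmer_hit_profile_exact(
    syncmer_scheme(w = 2, kind = "closed"), 5)$h, rep(1, 5))
  expect_equal(syncmer_hit_profile_exact(
    syncmer_scheme(w = 3, kind = "open", t = 2), 2)$h[2], 2 / 3)
})

test_that("exact computation equals literal permutation enumeration", {
  schemes <- list(
    syncmer_scheme(w = 3, kind = "open", t = 1),
    syncmer_scheme(w = 3, kind = "open", t = 2),
    syncmer_scheme(w = 4, kind = "open", t = 3),
    syncmer_scheme(w = 4, kind = "closed"),
    syncmer_scheme(w = 2, kind = "open", t = 2)
  )
  for (sch in schemes) {
    h <- syncmer_hit_profile_exact(sch, 3)$h
    for (x in 1:3) {
      expect_equal(h[x], syncmer_hit_by_permutation(sch, x))
    }
  }
})

test_that("H_1 equals the scheme density, with and without down-sampling", {
  for (sch in list(syncmer_scheme(w = 5, kind = "open"),
                   syncmer_scheme(w = 5, kind = "closed"),
                   syncmer_scheme(w = 4, kind = "open", downsample = 3))) {
    expect_equal(syncmer_hit_profile_exact(sch, 1)$h[1], syncmer_density(sch))
  }
})

test_that("closed syncmers are universal: H_x = 1 exactly from x = 2s - 1", {
  for (w in 2:6) {
    h <- syncmer_hit_profile_exact(syncmer_scheme(w = w, kind = "closed"),
                                   2 * w)$h
    s <- w / 2
    expect_equal(h[(2 * s - 1):(2 * w)], rep(1, 2 * w - (2 * s - 1) + 1))
    if (w > 2) expect_lt(h[2 * s - 2], 1)
  }
})

test_that("open syncmers are polar: H_x sits on the upper bound below ceil(s/2)", {
  for (w in 2:6) {
    sch <- syncmer_scheme(w = w, kind = "open")   # t = ceiling(w/2)
    b <- ceiling(w / 2)
    h <- syncmer_hit_profile_exact(sch, b + 1)$h
    expect_equal(h[seq_len(b)], seq_len(b) / w)
    if (w > 2) expect_lt(h[b + 1], (b + 1) / w)
  }
})

test_that("the central offset maximizes the open-syncmer objective", {
  obj <- objective(8)
  for (w in 2:6) {
    scores <- vapply(seq_len(w), function(t) {
      objective_score(
        syncmer_hit_profile_exact(syncmer_scheme(w = w, kind = "open", t = t), 8),
        obj)
    }, numeric(1))
    expect_equal(scores[ceiling(w / 2)], max(scores))
    # mirror symmetry: offset t and w + 1 - t are equivalent
    expect_equal(scores, rev(scores))
  }
})

test_that("down-sampling lowers every run-hitting probability", {
  for (kind in c("open", "closed")) {
    full <- syncmer_hit_profile_exact(syncmer_scheme(w = 5, kind = kind), 10)$h
    half <- syncmer_hit_profile_exact(syncmer_scheme(w = 5, kind = kind,
                                                     downsample = 2), 10)$h
    expect_true(all(half < full))
    expect_true(all(diff(half) >= 0))
  }
})

test_that("Monte Carlo estimates agree with exact values and are reproducible", {
  sch <- syncmer_scheme(w = 3, kind = "open", t = 2)
  mc <- syncmer_hit_profile_mc(sch, 4, reps = 2e4, seed = 42)
  ex <- syncmer_hit_profile_exact(sch, 4)
  expect_true(all(abs(mc$h - ex$h) <= 3 * pmax(mc$se, 1e-6)))
  mc2 <- syncmer_hit_profile_mc(sch, 4, reps = 2e4, seed = 42)
  expect_identical(mc$h, mc2$h)
  expect_equal(syncmer_hit_profile_mc(syncmer_scheme(w = 2, kind = "closed"),
                                      3, reps = 500, seed = 1)$h, rep(1, 3))
  # down-sampled MC vs the independent-keep exact model
  schd <- syncmer_scheme(w = 4, kind = "closed", downsample = 2)
  mcd <- syncmer_hit_profile_mc(schd, 5, reps = 2e4, seed = 9)
  exd <- syncmer_hit_profile_exact(schd, 5)
  expect_true(all(abs(mcd$h - exd$h) <= 3 * pmax(mcd$se, 1e-6)))
})
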