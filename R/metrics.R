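#' Expected fraction of sampled maximal exact matches
#'
#' Between unrelated random sequences, maximal exact matches of length `y`
#' occur with frequency proportional to `p^y` (`p = 1/4` for DNA), and a
#' match of length `y >= m` is sampled with probability `H_(y-m+1)`.  The
#' expected fraction of maximal exact matches (length `>= m`) that get
#' sampled is therefore the series `(1-p) * sum_{x>=1} H_x p^(x-1)`.  This
#' measures the non-redundant hit load of one-hit seed-and-extend: larger
#' values mean more extensions from unrelated sequences.
#'
#' The series is truncated when the analytic bound on the remaining tail
#' (using `H <= 1`) drops below `tol`.  For a precomputed profile the tail
#' beyond the profile is evaluated with `H` frozen at the final entry; this
#' is exact once the profile has reached 1, and otherwise an error is raised
#' if the frozen-tail uncertainty exceeds `tol`.
#'
#' @param scheme a [word_set()], [syncmer_scheme()], `hit_profile` tibble,
#'   or plain numeric vector `H_1, H_2, ...`.
#' @param p per-position match-extension probability for unrelated
#'   sequences (1/4 for uniform DNA).
#' @param tol truncation tolerance for the series tail.
#' @param ... passed to methods.
#' @return a single probability.
#' @examples
#' specificity_fraction(word_set("ry"))           # ~0.327
#' specificity_fraction(upper_bound_profile(4, 10))  # ~0.332
#' @export
specificity_fraction <- function(scheme, p = 0.25, tol = 1e-12, ...) {
  UseMethod("specificity_fraction")
}

series_length_for <- function(p, tol) max(1L, as.integer(ceiling(log(tol) / log(p))))

eval_specificity_series <- function(h, p, tol) {
  stopifnot(p > 0, p < 1, tol > 0)
  X <- length(h)
  x <- seq_len(X)
  head_sum <- (1 - p) * sum(h * p^(x - 1))
  tail_val <- h[X] * p^X            # tail with H frozen at the last entry
  tail_err <- (1 - h[X]) * p^X      # frozen tail vs the H <= 1 bound
  if (tail_err >= tol) {
    stop("profile too short: tail uncertainty ", format(tail_err),
         " >= tol; supply more entries", call. = FALSE)
  }
  head_sum + tail_val
}

#' @export
specificity_fraction.word_set <- function(scheme, p = 0.25, tol = 1e-12, ...) {
  u <- series_length_for(p, tol)
  eval_specificity_series(run_hit_profile(scheme, u, ...)$h, p, tol)
}

#' @export
specificity_fraction.syncmer_scheme <- function(scheme, p = 0.25, tol = 1e-12, ...) {
  u <- series_length_for(p, tol)
  eval_specificity_series(syncmer_hit_profile_exact(scheme, u)$h, p, tol)
}

#' @export
specificity_fraction.hit_profile <- function(scheme, p = 0.25, tol = 1e-12, ...) {
  eval_specificity_series(scheme$h, p, tol)
}

#' @export
specificity_fraction.numeric <- function(scheme, p = 0.25, tol = 1e-12, ...) {
  eval_specificity_series(scheme, p, tol)
}

#' Distribution of the number of matches overlapping a letter
#'
#' For two related sequences under the substitution-only model (each letter
#' independently conserved with probability `q`), a focal letter is covered
#' by a length-`m` exact match for each of the `m` windows containing it
#' that is fully conserved.  `run_count_distribution()` returns the
#' distribution of the number `x` of such fully conserved windows,
#' i.e. of matches overlapping one letter, computed exactly by enumerating
#' all conservation patterns of the `2m - 1` letters those windows touch.
#'
#' @param m match (seed) length, `1 <= m <= 12` for exact enumeration.
#' @param q per-letter conservation probability in `[0, 1]`.
#' @return a tibble with columns `x` (0..m) and `prob`, carrying `m` and `q`
#'   as attributes; probabilities sum to 1.
#' @examples
#' run_count_distribution(2, 0.9)  # P(2) = q^3, P(1) = 2 q^2 (1-q)
#' @export
run_count_distribution <- function(m, q) {
  m <- as.integer(m)
  stopifnot(length(m) == 1L, m >= 1L, q >= 0, q <= 1)
  if (m > 12L) {
    stop("exact enumeration guarded at m <= 12 (2^(2m-1) patterns)", call. = FALSE)
  }
  L <- 2L * m - 1L
  pats <- 0:(2^L - 1)
  pop <- integer(length(pats))
  for (b in seq_len(L) - 1L) pop <- pop + bitwAnd(bitwShiftR(pats, b), 1L)
  prob_pat <- q^pop * (1 - q)^(L - pop)
  x <- integer(length(pats))
  for (i in seq_len(m)) {
    mask <- bitwShiftL(2L^m - 1L, i - 1L)
    x <- x + as.integer(bitwAnd(pats, mask) == mask)
  }
  probs <- as.numeric(rowsum(prob_pat, x))
  got <- sort(unique(x))
  full <- numeric(m + 1L)
  full[got + 1L] <- probs
  out <- tibble::tibble(x = 0:m, prob = full)
  attr(out, "m") <- m
  attr(out, "q") <- q
  class(out) <- c("run_count_distribution", class(out))
  out
}

#' Expected letter coverage of a sampling scheme
#'
#' The expected number of letters covered by sampled matches in a true
#' alignment is proportional to the probability that one letter is covered,
#' `sum_{x=1..m} H_x * P_run(x)`, where `P_run` is the
#' [run_count_distribution()].  Entrywise-larger hit profiles therefore give
#' larger expected coverage at every divergence level.
#'
#' @param profile a `hit_profile` (length `>= m`) or numeric `H` vector.
#' @param m match length.
#' @param q per-letter conservation probability.
#' @param run_dist optionally a precomputed [run_count_distribution()]
#'   (overrides `m`, `q`).
#' @return a single number (probability that a focal letter is covered).
#' @export
expected_coverage <- function(profile, m, q, run_dist = NULL) {
  if (is.null(run_dist)) run_dist <- run_count_distribution(m, q)
  m <- attr(run_dist, "m")
  h <- if (is.numeric(profile)) profile else profile$h
  if (length(h) < m) {
    stop("profile has ", length(h), " entries; need at least m = ", m, call. = FALSE)
  }
  sum(h[seq_len(m)] * run_dist$prob[-1L])
}

#' Distance between consecutive sampled positions
#'
#' Conditional on a word of the set occurring at position 0 of a random
#' iid sequence (the starting word uniform over the set), `P(D = d)` is the
#' probability that the next sampled position is exactly `d`, computed by a
#' renewal-style dynamic programming over the `|A|^k` suffix states: mass
#' reaching a state in the set at step `d` is recorded as a distance-`d`
#' renewal and removed.  The mean distance equals the sparsity `s` up to the
#' truncated tail, and minimizing the large-run-limit average hit
#' probability is empirically equivalent to minimizing `Var(D)`.
#'
#' @param ws a [word_set()].
#' @param d_max truncation point of the reported distribution.
#' @return a tibble with columns `d` (1..`d_max`) and `prob`, with
#'   attributes `tail_mass` (probability `D > d_max`), `mean` and
#'   `variance` (both computed over the truncated part; accurate when
#'   `tail_mass` is negligible).
#' @examples
#' distance_distribution(word_set("ry"), 10)
#' @export
distance_distribution <- function(ws, d_max) {
  stopifnot(inherits(ws, "word_set"))
  d_max <- as.integer(d_max)
  if (d_max < 1L) stop("`d_max` must be >= 1", call. = FALSE)
  B <- length(ws$alphabet)
  k <- ws$k
  n_states <- B^k
  q_idx <- word_codes(ws) + 1L
  base <- (0:(n_states - 1L)) %/% B
  pre <- lapply(0:(B - 1L), function(a) a * B^(k - 1) + base + 1L)

  v <- numeric(n_states)
  v[q_idx] <- 1 / ws$n
  prob <- numeric(d_max)
  for (d in seq_len(d_max)) {
    nv <- numeric(n_states)
    for (a in seq_len(B)) nv <- nv + v[pre[[a]]]
    nv <- nv / B
    prob[d] <- sum(nv[q_idx])
    nv[q_idx] <- 0
    v <- nv
  }
  mu <- sum(seq_len(d_max) * prob)
  va <- sum(seq_len(d_max)^2 * prob) - mu^2
  out <- tibble::tibble(d = seq_len(d_max), prob = prob)
  attr(out, "tail_mass") <- 1 - sum(prob)
  attr(out, "mean") <- mu
  attr(out, "variance") <- va
  class(out) <- c("distance_distribution", class(out))
  out
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat("<distance_distribution> mean ", format(attr(x, "mean")),
      "  variance ", format(attr(x, "variance")),
      "  tail mass ", format(attr(x, "tail_mass")), "\n", sep = "")
  NextMethod()
}
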