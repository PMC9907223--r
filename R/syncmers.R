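#' Syncmer sampling schemes
#'
#' A syncmer scheme selects a k-mer according to the position of its
#' minimum-hash length-`j` subword among the `w = k - j + 1` subwords:
#' "closed" if the minimum is the first or last subword, "open with offset
#' `t`" if it is the one at position `t`.  Down-sampling by a factor `ds`
#' additionally keeps each selected k-mer with probability `1/ds`, by a hash
#' of the whole k-mer.  All computations here use the random-hash rank
#' model: subword hashes are iid continuous draws, so only their relative
#' ranks matter and ties have probability zero.
#'
#' @param k k-mer length (optional if `w` is given).
#' @param j subword length (optional if `w` is given).
#' @param w number of subwords per k-mer, `k - j + 1`.
#' @param kind `"open"` or `"closed"`.
#' @param t offset of the minimum subword for open syncmers, in `1..w`;
#'   defaults to `ceiling(w/2)`, the sensitivity-optimal choice.
#' @param downsample down-sampling factor `>= 1`.
#' @return an object of class `syncmer_scheme`.
#' @examples
#' syncmer_scheme(w = 5, kind = "open")
#' syncmer_density(syncmer_scheme(w = 4, kind = "closed"))
#' @export
syncmer_scheme <- function(k = NULL, j = NULL, w = NULL,
                           kind = c("open", "closed"), t = NULL,
                           downsample = 1) {
  kind <- match.arg(kind)
  if (is.null(w)) {
    if (is.null(k) || is.null(j)) stop("give either `w` or both `k` and `j`", call. = FALSE)
    if (j < 1 || j > k) stop("need 1 <= j <= k", call. = FALSE)
    w <- k - j + 1
  } else if (!is.null(k) && !is.null(j) && w != k - j + 1) {
    stop("inconsistent k, j, w (w must equal k - j + 1)", call. = FALSE)
  }
  w <- as.integer(w)
  if (w < 1L) stop("`w` must be >= 1", call. = FALSE)
  if (kind == "open") {
    if (is.null(t)) t <- ceiling(w / 2)
    t <- as.integer(t)
    if (t < 1L || t > w) stop("open-syncmer offset `t` must be in 1..w", call. = FALSE)
  } else {
    t <- NA_integer_
  }
  if (downsample < 1) stop("`downsample` must be >= 1", call. = FALSE)
  structure(list(k = k, j = j, w = w, kind = kind, t = t,
                 downsample = downsample),
            class = "syncmer_scheme")
}

#' @export
print.syncmer_scheme <- function(x, ...) {
  cat("<syncmer_scheme> ", x$kind, " w=", x$w,
      if (x$kind == "open") paste0(" t=", x$t),
      if (x$downsample != 1) paste0(" downsample=", format(x$downsample)),
      "  density ", format(syncmer_density(x)), "\n", sep = "")
  invisible(x)
}

#' @rdname syncmer_scheme
#' @param scheme a `syncmer_scheme`.
#' @return `syncmer_density()`: the probability a position is sampled,
#'   `1/(w * downsample)` for open and `2/(w * downsample)` for closed
#'   schemes.
#' @export
syncmer_density <- function(scheme) {
  stopifnot(inherits(scheme, "syncmer_scheme"))
  base <- if (scheme$kind == "open") 1 else 2
  base / (scheme$w * scheme$downsample)
}

#' @export
sparsity.syncmer_scheme <- function(x, ...) 1 / syncmer_density(x)

#' Classify one rank window
#'
#' Decides whether a k-mer is a syncmer from the ranks of its `w` subword
#' hashes (down-sampling is ignored here: it is a property of the k-mer
#' hash, not of the subword ranks).
#'
#' @param ranks numeric vector of `w` distinct ranks (or raw hash values).
#' @param scheme a [syncmer_scheme()].
#' @return logical.
#' @export
classify_rank_window <- function(ranks, scheme) {
  stopifnot(inherits(scheme, "syncmer_scheme"))
  if (length(ranks) != scheme$w) {
    stop("need exactly w = ", scheme$w, " ranks", call. = FALSE)
  }
  if (anyDuplicated(ranks)) {
    stop("tied ranks: the rank model assumes distinct hash values", call. = FALSE)
  }
  pos <- which.min(ranks)
  if (scheme$kind == "closed") pos == 1L || pos == scheme$w else pos == scheme$t
}

# P(no retained syncmer among the x windows), by conditioning on the position
# of the globally minimal rank: windows containing it are syncmers only if it
# sits at a defining offset; the left and right remainders are independent
# sub-problems of the same form.
syncmer_miss_probs <- function(scheme, u) {
  w <- scheme$w
  t <- scheme$t
  keep <- 1 / scheme$downsample
  f <- numeric(u + 1L)  # f[x + 1] = P(no retained hit in x windows)
  f[1L] <- 1
  fx <- function(x) if (x <= 0L) 1 else f[x + 1L]
  for (x in seq_len(u)) {
    N <- x + w - 1L
    acc <- 0
    for (m in seq_len(N)) {
      n_sync <- if (scheme$kind == "open") {
        as.integer(m - t + 1L >= 1L && m - t + 1L <= x)
      } else {
        as.integer(m >= 1L && m <= x) + as.integer(m - w + 1L >= 1L && m - w + 1L <= x)
      }
      factor <- if (n_sync == 0L) 1 else (1 - keep)^n_sync
      if (factor > 0) acc <- acc + factor * fx(m - w) * fx(x - m)
    }
    f[x + 1L] <- acc / N
  }
  f[-1L]
}

#' Exact syncmer run-hitting probabilities
#'
#' `H_x` = probability that at least one of the `x` k-mer windows of a run
#' is a (retained) syncmer, over the `x + w - 1` iid subword hashes.
#' Computed exactly by recursive conditioning on the position of the global
#' minimum rank, which splits the run into independent sub-runs; this equals
#' the fraction of rank permutations containing a syncmer window (weighted
#' by retention probabilities when down-sampling).
#'
#' @param scheme a [syncmer_scheme()].
#' @param u largest run size.
#' @return a `hit_profile` tibble (see [run_hit_profile()]).
#' @examples
#' syncmer_hit_profile_exact(syncmer_scheme(w = 3, kind = "open", t = 2), u = 4)
#' @export
syncmer_hit_profile_exact <- function(scheme, u) {
  stopifnot(inherits(scheme, "syncmer_scheme"))
  u <- as.integer(u)
  if (u < 1L) stop("`u` must be >= 1", call. = FALSE)
  h <- 1 - syncmer_miss_probs(scheme, u)
  new_hit_profile(h, sparsity = sparsity(scheme),
                  scheme = format_syncmer(scheme))
}

format_syncmer <- function(scheme) {
  paste0("syncmer(", scheme$kind, ",w=", scheme$w,
         if (scheme$kind == "open") paste0(",t=", scheme$t),
         if (scheme$downsample != 1) paste0(",ds=", format(scheme$downsample)),
         ")")
}

#' @export
hit_profile.syncmer_scheme <- function(scheme, u, ...) {
  syncmer_hit_profile_exact(scheme, u)
}

#' Monte Carlo syncmer run-hitting probabilities
#'
#' Estimates `H_x` by simulating random subword-rank permutations (and
#' independent per-window retention events when down-sampling).  One
#' simulated run of `u + w - 1` positions yields all run sizes `x <= u` from
#' its window prefixes, so the estimates are monotone in `x` by
#' construction.  Deterministic given `seed`.
#'
#' @inheritParams syncmer_hit_profile_exact
#' @param reps number of simulated runs.
#' @param seed RNG seed.
#' @return a `hit_profile` tibble with an extra `se` column (binomial
#'   standard errors).
#' @export
syncmer_hit_profile_mc <- function(scheme, u, reps = 1e4, seed) {
  stopifnot(inherits(scheme, "syncmer_scheme"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  u <- as.integer(u)
  reps <- as.integer(reps)
  if (u < 1L || reps < 1L) stop("`u` and `reps` must be >= 1", call. = FALSE)
  w <- scheme$w
  N <- u + w - 1L
  h <- withr::with_seed(as.integer(seed), {
    ranks <- matrix(stats::runif(reps * N), nrow = reps)
    is_sync <- matrix(FALSE, nrow = reps, ncol = u)
    for (i in seq_len(u)) {
      win <- ranks[, i:(i + w - 1L), drop = FALSE]
      pos <- max.col(-win, ties.method = "first")
      is_sync[, i] <- if (scheme$kind == "closed") pos == 1L | pos == w
                      else pos == scheme$t
    }
    if (scheme$downsample > 1) {
      kept <- matrix(stats::runif(reps * u) < 1 / scheme$downsample,
                     nrow = reps)
      is_sync <- is_sync & kept
    }
    hit_any <- t(apply(is_sync, 1L, cumsum)) > 0
    colMeans(hit_any)
  })
  se <- sqrt(h * (1 - h) / reps)
  new_hit_profile(h, sparsity = sparsity(scheme),
                  scheme = paste0(format_syncmer(scheme), " MC[", reps, "]"),
                  se = se)
}
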