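#' Run-hitting probabilities
#'
#' The run-hitting probability `H_x` of a sampling scheme is the probability
#' that it samples at least one position in a run of `x` consecutive
#' positions of a random sequence of independent, equally probable letters.
#' For a word-based scheme this equals the probability that some word of the
#' set occurs in a sequence of length `x + k - 1`, computed exactly by
#' dynamic programming over the `|A|^k` length-`k` suffix states: `C(i, w)`
#' counts length-`i` sequences that end in `w` and contain no word of the
#' set, with base case `C(k, w) = 0` if `w` is in the set and 1 otherwise,
#' and `H_x = 1 - sum_w C(x+k-1, w) / |A|^(x+k-1)`.
#'
#' Counts are carried in doubles, which represent them exactly while
#' `x + k - 1 <= 53`; the default sequence-length cap is
#' `u + k - 1 <= 64`.
#'
#' @param ws a [word_set()].
#' @param u largest run size (profile covers `x = 1..u`).
#' @param length_limit cap on `u + k - 1` (lookup-table/precision guard).
#' @return a `hit_profile`: a tibble with columns `x`, `h`, `upper_bound`
#'   (`min(x/s, 1)`) and `deficit` (`upper_bound - h`), carrying the scheme's
#'   sparsity `s` and a label as attributes.
#' @examples
#' run_hit_profile(word_set("ry"), u = 3)  # H_2 = 1/2
#' @export
run_hit_profile <- function(ws, u, length_limit = 64) {
  stopifnot(inherits(ws, "word_set"))
  u <- as.integer(u)
  if (length(u) != 1L || is.na(u) || u < 1L) stop("`u` must be >= 1", call. = FALSE)
  B <- length(ws$alphabet)
  k <- ws$k
  if (u + k - 1 > length_limit) {
    stop("u + k - 1 = ", u + k - 1, " exceeds length limit ", length_limit,
         call. = FALSE)
  }
  n_states <- B^k
  in_q <- logical(n_states)
  in_q[word_codes(ws) + 1L] <- TRUE

  C <- as.numeric(!in_q)                 # C(k, w)
  base <- (0:(n_states - 1L)) %/% B      # state with final letter dropped
  pre <- lapply(0:(B - 1L), function(a) a * B^(k - 1) + base + 1L)

  h <- numeric(u)
  h[1L] <- 1 - sum(C) / B^k
  if (u > 1L) {
    for (x in 2:u) {
      newC <- numeric(n_states)
      for (a in seq_len(B)) newC <- newC + C[pre[[a]]]
      newC[in_q] <- 0
      C <- newC
      h[x] <- 1 - sum(C) / B^(x + k - 1)
    }
  }
  new_hit_profile(h, sparsity = sparsity(ws),
                  scheme = paste0("words{", paste(ws$words, collapse = ","), "}"))
}

new_hit_profile <- function(h, sparsity, scheme, se = NULL) {
  x <- seq_along(h)
  ub <- pmin(x / sparsity, 1)
  out <- tibble::tibble(x = x, h = h, upper_bound = ub, deficit = ub - h)
  if (!is.null(se)) out$se <- se
  attr(out, "sparsity") <- sparsity
  attr(out, "scheme") <- scheme
  class(out) <- c("hit_profile", class(out))
  out
}

#' @export
print.hit_profile <- function(x, ...) {
  cat("<hit_profile> scheme: ", attr(x, "scheme"),
      "  sparsity: ", format(attr(x, "sparsity")), "\n", sep = "")
  NextMethod()
}

#' Hit profile of any sampling scheme
#'
#' Generic front end: dispatches to the exact dynamic programming for word
#' sets and to the exact rank-model computation for syncmer schemes.
#'
#' @param scheme a scheme object ([word_set()], [syncmer_scheme()], ...).
#' @param u largest run size.
#' @param ... passed to methods.
#' @export
hit_profile <- function(scheme, u, ...) UseMethod("hit_profile")

#' @export
hit_profile.word_set <- function(scheme, u, ...) run_hit_profile(scheme, u, ...)

#' Brute-force count of sequences containing a word
#'
#' Exhaustively enumerates all `|A|^length` sequences and counts those that
#' contain at least one word of the set.  This is the independent oracle for
#' the dynamic programming: `H_x = count / |A|^(x+k-1)` with
#' `length = x + k - 1`.
#'
#' @param ws a [word_set()].
#' @param length sequence length (`>= k`); `|A|^length` is capped at `2^24`.
#' @return integer count.
#' @examples
#' dna <- c("a", "c", "g", "t")
#' brute_force_hit_count(word_set("acgt", alphabet = dna), 5)  # 8
#' brute_force_hit_count(word_set("aaaa", alphabet = dna), 5)  # 7
#' @export
brute_force_hit_count <- function(ws, length) {
  stopifnot(inherits(ws, "word_set"))
  length <- as.integer(length)
  B <- base::length(ws$alphabet)
  k <- ws$k
  if (length < k) stop("`length` must be at least k", call. = FALSE)
  if (B^length > 2^24) stop("|A|^length exceeds enumeration guard 2^24", call. = FALSE)
  in_q <- logical(B^k)
  in_q[word_codes(ws) + 1L] <- TRUE
  seqs <- 0:(B^length - 1)
  hit <- logical(B^length)
  for (i in seq_len(length - k + 1L)) {
    win <- (seqs %/% B^(length - i - k + 1)) %% B^k
    hit <- hit | in_q[win + 1L]
  }
  sum(hit)
}

#' Analytic profiles: upper bound, every-s-th and grid sampling
#'
#' `upper_bound_profile()` gives the best possible run-hitting probabilities
#' for any scheme of sparsity `s`: `min(x/s, 1)`.  `every_sth_profile()` is
#' the positional scheme that selects every s-th position of one sequence;
#' it attains the upper bound exactly.  `grid_scheme_profile()` restricts
#' matches to start coordinates divisible by `s` in both sequences; with a
#' uniformly random diagonal offset it hits a size-`x` run with probability
#' `min(x/s, 1) / s`, flatlining at `1/s` for `x >= s`.
#'
#' @param s sparsity (positions per sampled position), `>= 1`.
#' @param u largest run size.
#' @return a `hit_profile` tibble (see [run_hit_profile()]).
#' @export
upper_bound_profile <- function(s, u) {
  stopifnot(s >= 1, u >= 1)
  x <- seq_len(u)
  new_hit_profile(pmin(x / s, 1), sparsity = s, scheme = paste0("upper_bound(s=", s, ")"))
}

#' @rdname upper_bound_profile
#' @export
every_sth_profile <- function(s, u) {
  stopifnot(s >= 1, s == as.integer(s))
  p <- upper_bound_profile(s, u)
  attr(p, "scheme") <- paste0("every_sth(s=", s, ")")
  p
}

#' @rdname upper_bound_profile
#' @export
grid_scheme_profile <- function(s, u) {
  stopifnot(s >= 1, s == as.integer(s), u >= 1)
  x <- seq_len(u)
  new_hit_profile(pmin(x / s, 1) / s, sparsity = s,
                  scheme = paste0("grid(s=", s, ")"))
}

#' Run-size objectives
#'
#' The objective maximized when optimizing word sets: a (weighted) average
#' of the run-hitting probabilities for runs of size `1..u`, where the
#' weight decreases by a factor `decay` per unit increase of run size
#' (`weight_x = decay^(1-x)`).  `decay = 1` is the plain average; `decay > 1`
#' emphasizes short runs (distantly related sequences), `decay < 1` long
#' runs (closely related sequences).
#'
#' @param u run-size limit, `>= 1`.
#' @param decay weight-decay factor `d > 0`.
#' @param normalize divide by the total weight (default), so scores are
#'   comparable across `u`.
#' @export
objective <- function(u, decay = 1, normalize = TRUE) {
  u <- as.integer(u)
  stopifnot(length(u) == 1L, u >= 1L, decay > 0)
  structure(list(u = u, decay = decay, normalize = isTRUE(normalize)),
            class = "run_objective")
}

#' @export
print.run_objective <- function(x, ...) {
  cat("<run_objective> u=", x$u, " decay=", format(x$decay),
      if (x$normalize) " (normalized)" else "", "\n", sep = "")
  invisible(x)
}

#' Score a hit profile under an objective
#'
#' @param profile a `hit_profile` tibble or a plain numeric vector of
#'   `H_1..H_u` (at least `obj$u` entries).
#' @param obj a [objective()].
#' @return the weighted (or plain) average run-hitting probability.
#' @export
objective_score <- function(profile, obj) {
  stopifnot(inherits(obj, "run_objective"))
  h <- if (is.numeric(profile)) profile else profile$h
  if (length(h) < obj$u) {
    stop("profile has ", length(h), " entries; objective needs u = ", obj$u,
         call. = FALSE)
  }
  x <- seq_len(obj$u)
  w <- obj$decay^(1 - x)
  s <- sum(w * h[x])
  if (obj$normalize) s / sum(w) else s
}

#' Write a hit profile as TSV
#'
#' Columns `x`, `h`, `upper_bound`, `deficit` (mirroring
#' difference-from-upper-bound plots).
#'
#' @param profile a `hit_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
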