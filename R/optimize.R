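#' Optimize word sets for run-hitting probability
#'
#' Searches for sets of `n` length-`k` words maximizing the (weighted)
#' average run-hitting probability under an [objective()].  Two modes:
#' `enumerate_exact_optima()` evaluates every one of the `choose(|A|^k, n)`
#' candidate sets and returns all maximizers (feasible only for small `n`
#' and `k`); `simulated_annealing_search()` is a seeded stochastic search
#' for larger problems.
#'
#' @name optimize-words
NULL

# objective score of a set given by its word codes, with memoisation
make_scorer <- function(k, alphabet, obj, length_limit = 64) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(codes) {
    key <- paste(sort(codes), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ws <- word_set(codes_to_words(codes, k, alphabet), alphabet = alphabet)
    sc <- objective_score(run_hit_profile(ws, obj$u, length_limit = length_limit), obj)
    cache[[key]] <- sc
    sc
  }
}

#' Exhaustive word-set optimization
#'
#' @param k word length.
#' @param n number of words.
#' @param obj a [objective()].
#' @param alphabet scheme alphabet.
#' @param max_candidates guard on `choose(|A|^k, n)`; exceeding it is an
#'   error directing you to [simulated_annealing_search()].
#' @return a list with `score` (the maximum) and `optima`, a list of all
#'   maximizing [word_set()]s with sorted words, ordered lexicographically.
#'   Optima are reported in their found orientation (reversal-equivalent
#'   optima are distinct sets); apply [reverse_to_minimize_yr()] to orient
#'   a chosen set for vertebrate-like DNA.
#' @examples
#' enumerate_exact_optima(k = 2, n = 1, obj = objective(u = 2))
#' @export
enumerate_exact_optima <- function(k, n, obj, alphabet = c("r", "y"),
                                   max_candidates = 2e5) {
  stopifnot(inherits(obj, "run_objective"))
  B <- length(alphabet)
  total <- B^k
  if (n < 1 || n > total) stop("need 1 <= n <= |A|^k", call. = FALSE)
  n_cand <- choose(total, n)
  if (n_cand > max_candidates) {
    stop("choose(", total, ", ", n, ") = ", format(n_cand),
         " candidate sets exceed the exact-search budget; use ",
         "simulated_annealing_search()", call. = FALSE)
  }
  combos <- utils::combn(0:(total - 1L), n)
  best <- -Inf
  opt <- list()
  eps <- 1e-12
  for (j in seq_len(ncol(combos))) {
    codes <- combos[, j]
    ws <- word_set(codes_to_words(codes, k, alphabet), alphabet = alphabet)
    sc <- objective_score(run_hit_profile(ws, obj$u), obj)
    if (sc > best + eps) {
      best <- sc
      opt <- list(ws)
    } else if (sc >= best - eps) {
      opt <- c(opt, list(ws))
    }
  }
  key <- vapply(opt, function(w) paste(w$words, collapse = " "), character(1))
  opt <- opt[order(key)]
  list(score = best, optima = opt)
}

#' Simulated-annealing word-set search
#'
#' Stochastic search over sets of `n` length-`k` words: each move replaces
#' one uniformly chosen member with a uniformly chosen non-member, accepted
#' by the Metropolis rule `exp(delta/T)` under a geometric cooling schedule
#' `T <- cooling * T`.  The best set over all restarts is returned; scores
#' are memoised across the whole search since the dynamic programming
#' evaluation dominates the cost.  Deterministic given `seed`.
#'
#' @inheritParams enumerate_exact_optima
#' @param seed RNG seed (required for reproducibility).
#' @param steps annealing steps per restart.
#' @param t0 initial temperature.
#' @param cooling geometric cooling factor in (0, 1).
#' @param restarts independent restarts.
#' @return an object of class `anneal_search`: list with `best` (a
#'   canonicalized [word_set()]), `score`, `initial_score` (of the first
#'   random set of the best restart), `trace` (tibble: restart, step,
#'   temperature, score of current set, best-so-far) and the configuration.
#' @export
simulated_annealing_search <- function(k, n, obj, alphabet = c("r", "y"),
                                       seed, steps = 2000L, t0 = 0.05,
                                       cooling = 0.995, restarts = 4L) {
  stopifnot(inherits(obj, "run_objective"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  B <- length(alphabet)
  total <- B^k
  if (n < 1 || n > total) stop("need 1 <= n <= |A|^k", call. = FALSE)
  score_of <- make_scorer(k, alphabet, obj)
  trace_every <- max(1L, steps %/% 50L)

  res <- withr::with_seed(as.integer(seed), {
    best_codes <- NULL
    best_score <- -Inf
    best_init <- NA_real_
    trace <- list()
    for (r in seq_len(restarts)) {
      cur <- sort(sample(0:(total - 1L), n))
      cur_score <- score_of(cur)
      init_score <- cur_score
      r_best <- cur
      r_best_score <- cur_score
      temp <- t0
      tr <- if (n < total) seq_len(steps) else integer(0)  # full set: nothing to move
      for (step in tr) {
        out_pool <- setdiff(0:(total - 1L), cur)
        cand <- cur
        cand[sample.int(n, 1L)] <- out_pool[sample.int(length(out_pool), 1L)]
        cand <- sort(cand)
        cand_score <- score_of(cand)
        delta <- cand_score - cur_score
        if (delta >= 0 || stats::runif(1) < exp(delta / temp)) {
          cur <- cand
          cur_score <- cand_score
          if (cur_score > r_best_score) {
            r_best <- cur
            r_best_score <- cur_score
          }
        }
        temp <- temp * cooling
        if (step %% trace_every == 0L) {
          trace[[length(trace) + 1L]] <-
            list(restart = r, step = step, temperature = temp,
                 score = cur_score, best = r_best_score)
        }
      }
      if (r_best_score > best_score) {
        best_score <- r_best_score
        best_codes <- r_best
        best_init <- init_score
      }
    }
    list(best_codes = best_codes, best_score = best_score,
         best_init = best_init, trace = trace)
  })

  best_ws <- reverse_to_minimize_yr(
    word_set(codes_to_words(res$best_codes, k, alphabet), alphabet = alphabet))
  structure(
    list(best = best_ws, score = res$best_score, initial_score = res$best_init,
         trace = dplyr::bind_rows(res$trace),
         config = list(k = k, n = n, objective = obj, seed = as.integer(seed),
                       steps = steps, t0 = t0, cooling = cooling,
                       restarts = restarts)),
    class = "anneal_search"
  )
}

#' @export
print.anneal_search <- function(x, ...) {
  cfg <- x$config
  cat("<anneal_search> k=", cfg$k, " n=", cfg$n, " u=", cfg$objective$u,
      " d=", format(cfg$objective$decay), " seed=", cfg$seed, "\n", sep = "")
  cat("  score ", format(x$score), " (initial ", format(x$initial_score), ")\n",
      sep = "")
  print(x$best)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.anneal_search <- function(x, ...) x$trace

#' @export
glance.anneal_search <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    k = cfg$k, n = cfg$n, u = cfg$objective$u, decay = cfg$objective$decay,
    seed = cfg$seed, steps = cfg$steps, restarts = cfg$restarts,
    score = x$score, initial_score = x$initial_score,
    improved = x$score - x$initial_score
  )
}
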