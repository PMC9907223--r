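# shared fixtures and small independent oracles, built in code

ry <- word_set("ry")
rr <- word_set("rr")
dna <- c("a", "c", "g", "t")

all_kmers <- function(k, alphabet = c("r", "y")) {
  wordsamp:::codes_to_words(0:(length(alphabet)^k - 1), k, alphabet)
}

random_word_set <- function(k, n, alphabet = c("r", "y")) {
  word_set(sample(all_kmers(k, alphabet), n), alphabet = alphabet)
}

# literal permutation enumeration: the independent oracle for the exact
# syncmer computation (feasible for x + w - 1 <= 7)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

syncmer_hit_by_permutation <- function(scheme, x) {
  w <- scheme$w
  perms <- all_perms(seq_len(x + w - 1L))
  hits <- vapply(perms, function(p) {
    any(vapply(seq_len(x), function(i) {
      classify_rank_window(p[i:(i + w - 1L)], scheme)
    }, logical(1)))
  }, logical(1))
  mean(hits)
}
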