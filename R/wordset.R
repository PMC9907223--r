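#' Word-based sampling schemes
#'
#' A word set is a set `Q` of `n` distinct length-`k` words over a fixed
#' ordered alphabet (by default the two-letter purine/pyrimidine alphabet
#' `c("r", "y")`).  A word-based sampling scheme selects the positions in a
#' sequence where any word of `Q` occurs, so it samples on average
#' `n / |A|^k` of all positions; its sparsity is the reciprocal,
#' `s = |A|^k / n`.
#'
#' @param words character vector of distinct words, all of the same length,
#'   over `alphabet`.  Case-insensitive; stored in lower case, sorted.
#' @param alphabet ordered character vector of single letters.
#' @return An object of class `word_set` with fields `words`, `alphabet`,
#'   `k` (word length) and `n` (number of words).
#' @examples
#' ws <- word_set(c("rrry", "ryrr", "ryyr", "yyyr"))
#' ws$k
#' sparsity(ws)
#' @export
word_set <- function(words, alphabet = c("r", "y")) {
  if (length(alphabet) < 2L || any(nchar(alphabet) != 1L) ||
      anyDuplicated(alphabet)) {
    stop("`alphabet` must be two or more distinct single letters", call. = FALSE)
  }
  alphabet <- tolower(alphabet)
  words <- tolower(as.character(words))
  if (length(words) == 0L) stop("a word set needs at least one word", call. = FALSE)
  k <- nchar(words[1L])
  if (k < 1L) stop("words must be non-empty", call. = FALSE)
  if (any(nchar(words) != k)) {
    stop("all words must have the same length (first word has length ", k, ")",
         call. = FALSE)
  }
  if (anyDuplicated(words)) {
    stop("duplicate word(s): ",
         paste(unique(words[duplicated(words)]), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(paste(words, collapse = ""), "")[[1L]]), alphabet)
  if (length(bad) > 0L) {
    stop("letter(s) not in alphabet {", paste(alphabet, collapse = ","), "}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(alphabet)^k > 2^24) {
    stop("alphabet^k too large for lookup-table representation", call. = FALSE)
  }
  structure(
    list(words = sort(words), alphabet = alphabet, k = as.integer(k),
         n = length(words)),
    class = "word_set"
  )
}

#' @export
print.word_set <- function(x, ...) {
  cat("<word_set> ", x$n, " word(s) of length ", x$k,
      " over {", paste(x$alphabet, collapse = ","), "}  sparsity ",
      format(sparsity(x)), "\n", sep = "")
  shown <- utils::head(x$words, 16L)
  cat("  ", paste(shown, collapse = " "),
      if (x$n > 16L) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Sparsity of a sampling scheme
#'
#' Expected number of sequence positions per sampled position.  For a
#' word-based scheme this is `|A|^k / n`; for syncmer schemes it is the
#' reciprocal of the scheme density.
#'
#' @param x a scheme object.
#' @param ... passed to methods.
#' @export
sparsity <- function(x, ...) UseMethod("sparsity")

#' @export
sparsity.word_set <- function(x, ...) length(x$alphabet)^x$k / x$n

#' Read a word set from a text file
#'
#' One word per line; blank lines and lines starting with `#` are ignored;
#' case-insensitive.
#'
#' @param path file path, or a character vector of lines via [parse_word_set()].
#' @inheritParams word_set
#' @return a [word_set()].
#' @export
read_word_set <- function(path, alphabet = c("r", "y")) {
  parse_word_set(readLines(path, warn = FALSE), alphabet = alphabet)
}

#' @rdname read_word_set
#' @param lines character vector of raw lines.
#' @export
parse_word_set <- function(lines, alphabet = c("r", "y")) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("no words found (all lines blank or comments)", call. = FALSE)
  }
  word_set(lines, alphabet = alphabet)
}

#' Write a word set to a text file
#'
#' @param ws a [word_set()].
#' @param path output path.
#' @export
write_word_set <- function(ws, path) {
  stopifnot(inherits(ws, "word_set"))
  writeLines(ws$words, path)
  invisible(path)
}

# integer codes 0 .. B^k - 1, first letter most significant
word_codes <- function(ws) {
  B <- length(ws$alphabet)
  mat <- matrix(match(unlist(strsplit(ws$words, "")), ws$alphabet) - 1L,
                ncol = ws$k, byrow = TRUE)
  as.vector(mat %*% B^((ws$k - 1):0))
}

codes_to_words <- function(codes, k, alphabet) {
  B <- length(alphabet)
  out <- character(length(codes))
  for (i in seq_along(codes)) {
    c0 <- codes[i]
    letters <- integer(k)
    for (j in k:1) {
      letters[j] <- c0 %% B
      c0 <- c0 %/% B
    }
    out[i] <- paste(alphabet[letters + 1L], collapse = "")
  }
  out
}

#' Encode DNA as purines and pyrimidines
#'
#' Maps `a`/`g` to `r` (purine) and `c`/`t`/`u` to `y` (pyrimidine),
#' case-insensitively.  Any other character (e.g. `n`, gaps) is kept but
#' flagged invalid; sampling functions skip every window that overlaps an
#' invalid position, mirroring how runs of masked bases are skipped in
#' genomic data.
#'
#' @param seq a nucleotide string (single character value).
#' @return a list with `encoded` (string over `r`,`y`, invalid positions as
#'   `.`) and `valid` (logical vector, one element per position).
#' @examples
#' encode_dna_to_ry("ACGTn")
#' @export
encode_dna_to_ry <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(tolower(seq), "")[[1L]]
  enc <- rep(".", length(chars))
  enc[chars %in% c("a", "g")] <- "r"
  enc[chars %in% c("c", "t", "u")] <- "y"
  list(encoded = paste(enc, collapse = ""), valid = enc != ".")
}

#' Count dinucleotide occurrences in a word set
#'
#' Total number of (overlapping) occurrences of a two-letter string across
#' all words of the set.  Used by the reversal heuristic, which prefers the
#' orientation with fewer `yr` dinucleotides because of the elevated
#' vertebrate CpG (a `yr` site) substitution rate.
#'
#' @param ws a [word_set()].
#' @param pair a two-letter string over the set's alphabet.
#' @return integer count.
#' @export
count_dinucleotide <- function(ws, pair) {
  stopifnot(inherits(ws, "word_set"))
  pair <- tolower(pair)
  if (nchar(pair) != 2L ||
      !all(strsplit(pair, "")[[1L]] %in% ws$alphabet)) {
    stop("`pair` must be two letters over the word-set alphabet", call. = FALSE)
  }
  if (ws$k < 2L) return(0L)
  total <- 0L
  for (w in ws$words) {
    for (i in seq_len(ws$k - 1L)) {
      if (substr(w, i, i + 1L) == pair) total <- total + 1L
    }
  }
  total
}

reverse_words <- function(ws) {
  rev_w <- vapply(ws$words,
                  function(w) paste(rev(strsplit(w, "")[[1L]]), collapse = ""),
                  character(1), USE.NAMES = FALSE)
  word_set(rev_w, alphabet = ws$alphabet)
}

#' Reverse a word set if that lowers its yr count
#'
#' Reverses every word in the set when doing so strictly reduces the total
#' number of `yr` dinucleotides; ties and increases keep the original
#' orientation.  Reversal changes no run-hitting probability, so this is a
#' free specificity tweak for vertebrate-like DNA.
#'
#' @param ws a [word_set()] over the `r`/`y` alphabet.
#' @return a [word_set()], possibly reversed.
#' @export
reverse_to_minimize_yr <- function(ws) {
  stopifnot(inherits(ws, "word_set"))
  if (!setequal(ws$alphabet, c("r", "y"))) return(ws)
  rev_ws <- reverse_words(ws)
  if (count_dinucleotide(rev_ws, "yr") < count_dinucleotide(ws, "yr")) rev_ws else ws
}

#' Minimum separation of a word-based scheme
#'
#' The smallest possible distance between two sampled positions over all
#' sequences: the least shift `d >= 1` at which some word of the set can be
#' followed by some word of the set (suffix/prefix overlap-compatibility for
#' `d < k`; distance `k` is always realizable by concatenation).  A set whose
#' samples are guaranteed at least `b` apart is a polar set at spacing `b`.
#'
#' @param ws a [word_set()].
#' @return integer in `1..k`.
#' @export
min_separation <- function(ws) {
  stopifnot(inherits(ws, "word_set"))
  k <- ws$k
  for (d in seq_len(k - 1L)) {
    for (w1 in ws$words) {
      suf <- substr(w1, d + 1L, k)
      for (w2 in ws$words) {
        if (suf == substr(w2, 1L, k - d)) return(as.integer(d))
      }
    }
  }
  as.integer(k)
}

#' Maximum separation of a word-based scheme
#'
#' Over bi-infinite sequences, the largest possible distance between
#' consecutive sampled positions.  Computed on the order-(k-1) de Bruijn
#' graph whose edges are the k-mers: after deleting the edges in the set, a
#' surviving cycle means an arbitrarily long unsampled stretch exists
#' (`Inf`); otherwise the answer is one more than the longest surviving path
#' (in edges), i.e. one more than the longest possible run of consecutive
#' unsampled positions.  A finite value makes the set a universal hitting
#' set.
#'
#' @param ws a [word_set()].
#' @return integer, or `Inf`.
#' @export
max_separation <- function(ws) {
  stopifnot(inherits(ws, "word_set"))
  B <- length(ws$alphabet)
  k <- ws$k
  if (k == 1L) {
    return(if (ws$n == B) 1L else Inf)
  }
  n_nodes <- B^(k - 1)
  in_q <- logical(B^k)
  in_q[word_codes(ws) + 1L] <- TRUE
  # edge for k-mer code c: from node c %/% B (prefix) to node c %% B^(k-1) (suffix)
  codes <- which(!in_q) - 1L
  if (length(codes) == 0L) return(1L)
  from <- codes %/% B
  to <- codes %% n_nodes
  g <- igraph::graph_from_edgelist(cbind(from, to) + 1L, directed = TRUE)
  if (!igraph::is_dag(g)) return(Inf)
  # longest path in edges via DP in topological order
  ord <- as.integer(igraph::topo_sort(g, mode = "out"))
  longest_from <- integer(igraph::vcount(g))  # edges on longest path starting at node
  adj <- igraph::adjacent_vertices(g, igraph::V(g), mode = "out")
  for (v in rev(ord)) {
    nxt <- as.integer(adj[[v]])
    longest_from[v] <- if (length(nxt) == 0L) 0L else 1L + max(longest_from[nxt])
  }
  as.integer(1L + max(longest_from))
}

#' Separation report for a word set
#'
#' @param ws a [word_set()].
#' @return a one-row tibble with columns `min_separation`, `max_separation`
#'   (`Inf` when some sequence is never sampled), `is_polar_at` (the
#'   guaranteed minimum spacing) and `is_universal` (whether every
#'   sufficiently long sequence is sampled).
#' @examples
#' separation_report(word_set(c("rr", "yy", "ry")))
#' @export
separation_report <- function(ws) {
  mn <- min_separation(ws)
  mx <- max_separation(ws)
  tibble::tibble(
    min_separation = mn,
    max_separation = mx,
    is_polar_at = mn,
    is_universal = is.finite(mx)
  )
}
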