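#' Synthetic sequences: iid draws and substitution-mutated pairs
#'
#' `generate_iid_sequence()` draws a sequence of independent, equally
#' probable letters.  `mutate_sequence()` derives a related sequence under
#' the substitution-only evolution model: each position is independently
#' conserved with probability `q`, and otherwise replaced by a uniformly
#' chosen different letter.  Both are deterministic given `seed`.
#'
#' @param length sequence length, `>= 1`.
#' @param alphabet letters to draw from (default DNA).
#' @param seed RNG seed.
#' @return `generate_iid_sequence()`: a single string.
#' @examples
#' generate_iid_sequence(20, seed = 1)
#' @export
generate_iid_sequence <- function(length, alphabet = c("a", "c", "g", "t"), seed) {
  length <- as.integer(length)
  if (length < 1L) stop("`length` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    paste(sample(alphabet, length, replace = TRUE), collapse = "")
  })
}

#' @rdname generate_iid_sequence
#' @param seq ancestor sequence (a single string over `alphabet`).
#' @param q per-position conservation probability in `[0, 1]`.
#' @return `mutate_sequence()`: an object of class `sequence_pair` — list
#'   with `ancestor`, `derived`, logical `conserved`, and `q`.
#' @export
mutate_sequence <- function(seq, q, seed, alphabet = c("a", "c", "g", "t")) {
  stopifnot(is.character(seq), length(seq) == 1L, q >= 0, q <= 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  withr::with_seed(as.integer(seed), {
    conserved <- stats::runif(L) < q
    idx <- which(!conserved)
    if (length(idx) > 0L) {
      # uniformly chosen *different* letter
      shift <- sample.int(length(alphabet) - 1L, length(idx), replace = TRUE)
      old <- match(chars[idx], alphabet)
      chars[idx] <- alphabet[(old - 1L + shift) %% length(alphabet) + 1L]
    }
    structure(list(ancestor = seq, derived = paste(chars, collapse = ""),
                   conserved = conserved, q = q),
              class = "sequence_pair")
  })
}

#' @export
print.sequence_pair <- function(x, ...) {
  cat("<sequence_pair> length ", nchar(x$ancestor), ", q = ", x$q,
      ", conserved fraction ", format(mean(x$conserved)), "\n", sep = "")
  invisible(x)
}

# integer-encode a sequence against a scheme alphabet; non-alphabet -> NA.
# For the r/y alphabet, DNA letters are first collapsed to purine/pyrimidine.
encode_to_ints <- function(seq, alphabet) {
  codes <- utf8ToInt(tolower(seq))
  lut <- rep(NA_integer_, 128L)
  if (identical(alphabet, c("r", "y"))) {
    lut[utf8ToInt("a")] <- 0L; lut[utf8ToInt("g")] <- 0L
    lut[utf8ToInt("r")] <- 0L
    lut[utf8ToInt("c")] <- 1L; lut[utf8ToInt("t")] <- 1L
    lut[utf8ToInt("u")] <- 1L; lut[utf8ToInt("y")] <- 1L
  } else {
    lut[utf8ToInt(paste(alphabet, collapse = ""))] <- seq_along(alphabet) - 1L
  }
  out <- rep(NA_integer_, length(codes))
  ok <- codes >= 1 & codes <= 128
  out[ok] <- lut[codes[ok]]
  out
}

# rolling base-B window codes; NA where any window letter is invalid
window_codes <- function(enc, k, B) {
  L <- length(enc)
  if (L < k) return(numeric(0))
  W <- L - k + 1L
  code <- numeric(W)
  for (j in seq_len(k)) code <- code * B + enc[j:(W + j - 1L)]
  code
}

#' Sample positions of a sequence with a word-based scheme
#'
#' Selects every position whose length-`k` window, after encoding to the
#' scheme alphabet (purine/pyrimidine for r/y word sets), is a word of the
#' set.  Windows overlapping an invalid letter (anything that does not
#' encode, e.g. `n`) are never sampled.  Membership is tested with a
#' `|A|^k` lookup table.
#'
#' @param seq a nucleotide string.
#' @param ws a [word_set()].
#' @param name sequence name used in output (and BED export).
#' @return a `sampled_positions` tibble with columns `name`, `start`
#'   (0-based), `end` (`start + k`, half-open), carrying `k` and a scheme
#'   descriptor as attributes.
#' @examples
#' sample_positions("agct", word_set("ry"))
#' @export
sample_positions <- function(seq, ws, name = "seq") {
  stopifnot(inherits(ws, "word_set"), is.character(seq), length(seq) == 1L)
  B <- length(ws$alphabet)
  if (nchar(seq) < ws$k) stop("sequence shorter than k", call. = FALSE)
  enc <- encode_to_ints(seq, ws$alphabet)
  code <- window_codes(enc, ws$k, B)
  in_q <- logical(B^ws$k)
  in_q[word_codes(ws) + 1L] <- TRUE
  sampled <- !is.na(code) & in_q[code + 1L]
  start <- which(sampled) - 1L
  out <- tibble::tibble(name = name, start = start, end = start + ws$k)
  attr(out, "k") <- ws$k
  attr(out, "scheme") <- paste0("words{", paste(ws$words, collapse = ","), "}")
  class(out) <- c("sampled_positions", class(out))
  out
}

#' Empirical sparsity of a scheme in a sequence
#'
#' Number of valid length-`k` windows divided by the number sampled; in iid
#' random sequences this estimates the scheme sparsity `|A|^k / n`, and in
#' biological DNA it measures how evenly the scheme applies in practice.
#'
#' @inheritParams sample_positions
#' @return a single number.
#' @export
empirical_sparsity <- function(seq, ws) {
  stopifnot(inherits(ws, "word_set"))
  B <- length(ws$alphabet)
  enc <- encode_to_ints(seq, ws$alphabet)
  code <- window_codes(enc, ws$k, B)
  valid <- !is.na(code)
  in_q <- logical(B^ws$k)
  in_q[word_codes(ws) + 1L] <- TRUE
  n_sampled <- sum(in_q[code[valid] + 1L])
  if (n_sampled == 0L) {
    stop("no position was sampled: sparsity is undefined", call. = FALSE)
  }
  sum(valid) / n_sampled
}

#' Empirical run-hitting probabilities
#'
#' Estimates `H_x` as the fraction of disjoint runs of `x` consecutive
#' (valid) window positions that contain at least one sampled position.
#' Runs are taken at stride `x + k - 1`, so they cover disjoint stretches of
#' sequence and the binomial standard error is valid.
#'
#' @inheritParams sample_positions
#' @param u largest run size.
#' @return a `hit_profile` tibble with an `se` column.
#' @export
empirical_hit_profile <- function(seq, ws, u) {
  stopifnot(inherits(ws, "word_set"))
  B <- length(ws$alphabet)
  k <- ws$k
  enc <- encode_to_ints(seq, ws$alphabet)
  code <- window_codes(enc, k, B)
  in_q <- logical(B^k)
  in_q[word_codes(ws) + 1L] <- TRUE
  valid <- !is.na(code)
  sampled <- valid & in_q[ifelse(valid, code, 0) + 1L]
  W <- length(code)
  cs <- c(0, cumsum(sampled))
  cv <- c(0, cumsum(valid))
  h <- se <- numeric(u)
  for (x in seq_len(u)) {
    starts <- seq.int(1L, W - x + 1L, by = x + k - 1L)
    ok <- (cv[starts + x] - cv[starts]) == x
    hit <- (cs[starts + x] - cs[starts]) > 0
    nn <- sum(ok)
    if (nn == 0L) stop("no valid runs of size ", x, call. = FALSE)
    h[x] <- mean(hit[ok])
    se[x] <- sqrt(h[x] * (1 - h[x]) / nn)
  }
  new_hit_profile(h, sparsity = sparsity(ws),
                  scheme = paste0("empirical ", attr(run_hit_profile(ws, 1), "scheme")),
                  se = se)
}

# (i, j) pairs of identical m-mers with the seq1 m-mer at a sampled position,
# as a data.table with diagonal; shared by the match-counting functions
sampled_match_pairs <- function(seq1, seq2, ws, m) {
  stopifnot(inherits(ws, "word_set"))
  m <- as.integer(m)
  if (m < ws$k) stop("`m` must be >= word length k", call. = FALSE)
  if (4^m > 2^52) stop("`m` too large for integer m-mer codes", call. = FALSE)
  dna <- c("a", "c", "g", "t")
  c1 <- window_codes(encode_to_ints(seq1, dna), m, 4L)
  c2 <- window_codes(encode_to_ints(seq2, dna), m, 4L)
  sampled <- rep(FALSE, length(c1))
  sampled[sample_positions(seq1, ws)$start + 1L] <- TRUE
  sampled <- sampled[seq_along(c1)] & !is.na(c1)
  i <- which(sampled)
  dt1 <- data.table::data.table(code = c1[i], i = i)
  dt2 <- data.table::data.table(code = c2[which(!is.na(c2))],
                                j = which(!is.na(c2)))
  merged <- merge(dt1, dt2, by = "code", allow.cartesian = TRUE)
  data.table::set(merged, j = "diag", value = merged$j - merged$i)
  merged
}

#' Count sampled matches between two sequences
#'
#' Number of position pairs `(i, j)` whose length-`m` substrings are
#' identical and whose shared content starts with a word of the set (so the
#' match is sampled).  Sampledness depends only on match content, so it is
#' evaluated on the first sequence.  Computed by joining integer m-mer codes.
#'
#' @param seq1,seq2 nucleotide strings.
#' @param ws a [word_set()].
#' @param m match length, `>= k`.
#' @return integer count.
#' @export
count_sampled_matches <- function(seq1, seq2, ws, m) {
  nrow(sampled_match_pairs(seq1, seq2, ws, m))
}

#' Sampled maximal exact matches between two sequences
#'
#' Enumerates maximal exact matches of length `>= m` (maximal runs of
#' consecutive m-mer matches along each diagonal: a run of `r` consecutive
#' matched m-mer start pairs is one maximal match of length `r + m - 1`),
#' and counts how many contain at least one sampled match start.  Dividing
#' by the total is the empirical analogue of [specificity_fraction()].
#'
#' @inheritParams count_sampled_matches
#' @return a one-row tibble: `n_max_matches`, `n_sampled`, `fraction`.
#' @export
count_sampled_maximal_matches <- function(seq1, seq2, ws, m) {
  m <- as.integer(m)
  if (m < ws$k) stop("`m` must be >= word length k", call. = FALSE)
  dna <- c("a", "c", "g", "t")
  c1 <- window_codes(encode_to_ints(seq1, dna), m, 4L)
  c2 <- window_codes(encode_to_ints(seq2, dna), m, 4L)
  sampled <- rep(FALSE, length(c1))
  sampled[sample_positions(seq1, ws)$start + 1L] <- TRUE
  i_all <- which(!is.na(c1))
  dt1 <- data.table::data.table(code = c1[i_all], i = i_all)
  dt2 <- data.table::data.table(code = c2[which(!is.na(c2))],
                                j = which(!is.na(c2)))
  mm <- merge(dt1, dt2, by = "code", allow.cartesian = TRUE)
  if (nrow(mm) == 0L) {
    return(tibble::tibble(n_max_matches = 0L, n_sampled = 0L, fraction = NaN))
  }
  data.table::set(mm, j = "diag", value = mm$j - mm$i)
  data.table::setorderv(mm, c("diag", "i"))
  new_run <- c(TRUE, diff(mm$i) != 1L | diff(mm$diag) != 0L)
  run_id <- cumsum(new_run)
  hit <- sampled[mm$i]
  run_hit <- tapply(hit, run_id, any)
  tibble::tibble(
    n_max_matches = length(run_hit),
    n_sampled = sum(run_hit),
    fraction = sum(run_hit) / length(run_hit)
  )
}

#' Read and write sampled positions and FASTA
#'
#' `write_bed()`/`read_bed()` round-trip `sampled_positions` as 3-column BED
#' (0-based, half-open).  `read_fasta()` reads a (possibly gzipped)
#' multi-record FASTA as a named character vector.
#'
#' @param sp a `sampled_positions` tibble.
#' @param path file path.
#' @export
write_bed <- function(sp, path) {
  utils::write.table(data.frame(sp$name, sp$start, sp$end), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param k word length to record on the restored object.
#' @export
read_bed <- function(path, k = NULL) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("name", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  out <- tibble::as_tibble(df)
  attr(out, "k") <- if (is.null(k) && nrow(df) > 0L) df$end[1L] - df$start[1L] else k
  class(out) <- c("sampled_positions", class(out))
  out
}

#' @rdname write_bed
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(tolower(as.character(x)), names(x))
}
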