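#' Construct a frequency table
#'
#' @param tokens Character vector of unique tokens.
#' @param counts Positive numeric counts (or probabilities).
#' @param kind One of "syllable", "ngram", "positional".
#' @return A `frequency_table` (named numeric vector with a kind attribute).
#' @export
frequency_table <- function(tokens, counts, kind = c("syllable", "ngram",
                                                     "positional")) {
  kind <- match.arg(kind)
  tokens <- as.character(tokens)
  if (anyDuplicated(tokens)) stop_ss("duplicate tokens in frequency table")
  if (any(counts <= 0)) stop_ss("counts must be positive")
  structure(stats::setNames(as.numeric(counts), tokens),
            kind = kind, class = "frequency_table")
}

#' Read a frequency table from CSV
#'
#' Accepted layouts: `token,freq` (syllables), `ngram,freq`, or
#' `phoneme,position,freq` (positional tables; tokens become
#' `"<phoneme>@<position>"`).
#'
#' @param path CSV file.
#' @param kind Token kind; inferred from the header when NULL.
#' @export
read_frequency_table <- function(path, kind = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  if (all(c("phoneme", "position", "freq") %in% names(df))) {
    return(frequency_table(positional_token(df$phoneme, df$position),
                           df$freq, "positional"))
  }
  tok_col <- intersect(c("token", "ngram", "syllable"), names(df))[1]
  if (is.na(tok_col) || !"freq" %in% names(df))
    stop_ss("unrecognised corpus table layout in ", path)
  kind <- kind %||% if (tok_col == "ngram") "ngram" else "syllable"
  frequency_table(df[[tok_col]], df$freq, kind)
}

positional_token <- function(phoneme, position) paste0(phoneme, "@", position)

#' Uniformity filter on token frequencies
#'
#' Log-transforms the counts, z-scores them, and removes tokens whose
#' two-sided standard-normal tail probability is at or below `alpha` —
#' i.e. tokens that are too frequent or too infrequent to be compatible
#' with a uniform frequency-of-use distribution.  With constant counts the
#' z-score is defined as 0 (p = 1) and everything is kept; `alpha = 0`
#' keeps all tokens.
#'
#' @param freqs A `frequency_table` (>= 3 tokens).
#' @param alpha Rejection threshold in \[0, 1\].
#' @return A `uniformity_result`: data frame (token, freq, log_freq,
#'   z_score, p_value, kept) plus `alpha` and `kept` (character vector)
#'   attributes.
#' @export
uniformity_filter <- function(freqs, alpha = 0.05) {
  if (length(freqs) < 3L) stop_ss("need at least 3 tokens")
  if (alpha < 0 || alpha > 1) stop_ss("alpha must be in [0, 1]")
  lf <- log(as.numeric(freqs))
  s <- sd(lf)
  z <- if (is.na(s) || s == 0) rep(0, length(lf)) else (lf - mean(lf)) / s
  p <- 2 * pnorm(-abs(z))
  kept <- p > alpha
  res <- data.frame(token = names(freqs), freq = as.numeric(freqs),
                    log_freq = lf, z_score = z, p_value = p, kept = kept,
                    stringsAsFactors = FALSE)
  structure(res, alpha = alpha, kept = res$token[kept],
            class = c("uniformity_result", "data.frame"))
}

# words may be `word` objects or plain lists of syllables (parse_ipa output)
word_syllables <- function(word) {
  if (inherits(word, "word")) word$syllables else word
}

word_phonemes <- function(word) {
  unlist(lapply(word_syllables(word), function(s) s$phonemes),
         use.names = FALSE)
}

word_ngrams <- function(word, n) {
  ph <- word_phonemes(word)
  if (length(ph) < n) return(character(0))
  vapply(seq_len(length(ph) - n + 1L),
         function(i) paste(ph[i:(i + n - 1L)], collapse = ""),
         character(1))
}

ngram_tokens_ok <- function(tokens, table, alpha) {
  allowed <- names(table)
  if (!is.null(alpha)) allowed <- attr(uniformity_filter(table, alpha), "kept")
  all(tokens %in% allowed)
}

#' Filter a word register by phoneme n-gram statistics
#'
#' Removes words containing a phoneme n-gram (window of length `n`,
#' stride 1, over the word's flattened phoneme string) that is absent
#' from the corpus table; with `alpha` set, additionally removes words
#' containing an n-gram rejected by [uniformity_filter()] at that
#' threshold.
#'
#' @param words Word register (list of words).
#' @param ngrams A `frequency_table` of n-gram counts; tokens are phoneme
#'   strings pasted without separator.
#' @param n N-gram order (2 or 3).
#' @param alpha Optional uniformity threshold (NULL = presence filter only).
#' @return The filtered word register.
#' @export
ngram_filter <- function(words, ngrams, n = 2, alpha = NULL) {
  keep <- vapply(words, function(w)
    ngram_tokens_ok(word_ngrams(w, n), ngrams, alpha), logical(1))
  out <- words[keep]
  if (!length(out))
    stop_ss("no words survive the ", n, "-gram filter; ",
            "relax alpha or corpus thresholds to keep an adequate register")
  out
}

#' Filter a word register by positional phoneme statistics
#'
#' Tokens of the positional table are (phoneme, word position) pairs,
#' position = 0-based syllable index.  A word is removed when a checked
#' phoneme/position pair is absent from the table (or rejected by the
#' uniformity filter at `alpha`).
#'
#' @param words Word register.
#' @param positional A positional `frequency_table`.
#' @param position Syllable index to check (0-based); NULL checks all.
#' @param alpha Optional uniformity threshold.
#' @export
positional_filter <- function(words, positional, position = NULL,
                              alpha = NULL) {
  keep <- vapply(words, function(w) {
    syls <- word_syllables(w)
    idx <- if (is.null(position)) seq_along(syls) - 1L else position
    toks <- unlist(lapply(idx, function(i)
      positional_token(syls[[i + 1L]]$phonemes, i)))
    ngram_tokens_ok(toks, positional, alpha)
  }, logical(1))
  out <- words[keep]
  if (!length(out))
    stop_ss("no words survive the positional filter; ",
            "relax alpha or corpus thresholds to keep an adequate register")
  out
}

#' Generate a synthetic Zipf-distributed corpus
#'
#' Stands in for real speech corpora (not redistributable): draws
#' `n_tokens` syllable occurrences from a syllable register with
#' probabilities proportional to `rank^-zipf_s`, then derives syllable,
#' phoneme bigram/trigram, and positional (phoneme x word-position)
#' frequency tables from the simulated token sequence grouped into
#' `s_per_word`-syllable words.  Deterministic for a fixed seed.
#'
#' @param register A `syllable_register` (or a `feature_table`, from which
#'   a default "cV" register is built).
#' @param n_tokens Number of syllable tokens to draw (>= 1).
#' @param zipf_s Zipf exponent (0 = near-uniform).
#' @param seed Integer seed.
#' @param s_per_word Syllables per simulated word for the positional table.
#' @return List of `frequency_table`s: `syllables`, `bigrams`, `trigrams`,
#'   `positional`.
#' @export
generate_synthetic_corpus <- function(register, n_tokens = 5000,
                                      zipf_s = 1, seed = 1,
                                      s_per_word = 3) {
  if (inherits(register, "feature_table"))
    register <- build_syllable_register(register, "cV")
  if (n_tokens < 1) stop_ss("n_tokens must be >= 1")
  ids <- vapply(register, function(s) s$id, character(1))
  n <- length(ids)
  with_seed(seed, {
    rank <- sample(n)  # random rank assignment over syllables
    p <- rank^(-zipf_s)
    p <- p / sum(p)
    counts <- as.integer(rmultinom(1, n_tokens, p))
    seq_idx <- sample(rep(seq_len(n), counts))
  })
  seq_ids <- ids[seq_idx]
  syl_tab <- table(seq_ids)
  # words: consecutive chunks of s_per_word syllables (vectorised)
  n_words <- length(seq_idx) %/% s_per_word
  big <- character(0); tri <- character(0); pos <- character(0)
  if (n_words > 0) {
    used <- seq_idx[seq_len(n_words * s_per_word)]
    ph_per_syl <- length(register[[1]]$phonemes)
    ph_all <- unlist(lapply(register[used], function(s) s$phonemes),
                     use.names = FALSE)
    word_of <- rep(seq_len(n_words), each = s_per_word * ph_per_syl)
    L <- length(ph_all)
    i2 <- seq_len(L - 1L)
    same2 <- word_of[i2] == word_of[i2 + 1L]
    big <- paste0(ph_all[i2], ph_all[i2 + 1L])[same2]
    if (L >= 3) {
      i3 <- seq_len(L - 2L)
      same3 <- word_of[i3] == word_of[i3 + 2L]
      tri <- paste0(ph_all[i3], ph_all[i3 + 1L], ph_all[i3 + 2L])[same3]
    }
    syl_pos <- rep(rep(seq_len(s_per_word) - 1L, each = ph_per_syl), n_words)
    pos <- positional_token(ph_all, syl_pos)
  }
  big_tab <- table(big); tri_tab <- table(tri); pos_tab <- table(pos)
  list(
    syllables = frequency_table(names(syl_tab), as.numeric(syl_tab),
                                "syllable"),
    bigrams = frequency_table(names(big_tab), as.numeric(big_tab), "ngram"),
    trigrams = frequency_table(names(tri_tab), as.numeric(tri_tab), "ngram"),
    positional = frequency_table(names(pos_tab), as.numeric(pos_tab),
                                 "positional"))
}
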