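# Shared fixtures, built once per test run (code, not stored data).

fixture_env <- new.env()

fx <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

fx_table <- function() fx("table", function() load_feature_table())

fx_register <- function() fx("register", function()
  build_syllable_register(fx_table(), "cV"))

fx_words <- function() fx("words", function()
  generate_word_register(fx_register(), S = 3, n_words = 250,
                         max_word_tries = 25000, seed = 42))

fx_lexicon <- function() fx("lexicon", function()
  assemble_lexicons(fx_words(), n_lexicons = 1, max_overlap = 2,
                    max_word_matrix = 60, seed = 42)[[1]])

# A tiny inventory written to CSV at run time (exercises the loader).
write_tiny_table <- function(path,
                             rows = c(
  "phoneme,syl,son,cont,lat,nas,voi,cor,lab,hi,lo,back,tense,long",
  "b,-,-,-,-,-,+,-,+,-,-,-,-,-",
  "t,-,-,-,-,-,-,+,-,-,-,-,-,-",
  "k,-,-,-,-,-,-,-,-,+,-,+,-,-",
  "s,-,-,+,-,-,-,+,-,-,-,-,-,-",
  "m,-,+,-,-,+,+,-,+,-,-,-,-,-",
  "aː,+,+,+,-,-,+,-,-,-,+,-,+,+",
  "iː,+,+,+,-,-,+,-,-,+,-,-,+,+",
  "oː,+,+,+,-,-,+,-,+,-,-,+,+,+",
  "uː,+,+,+,-,-,+,-,+,+,-,+,+,+",
  "a,+,+,+,-,-,+,-,-,-,+,-,-,-",
  "ts,-,-,-,-,-,-,+,-,-,-,-,-,-")) {
  writeLines(rows, path, useBytes = TRUE)
  path
}

tiny_table <- function(...) {
  p <- tempfile(fileext = ".csv")
  on.exit(unlink(p))
  write_tiny_table(p)
  load_feature_table(p, ...)
}

# Hand-built word with an arbitrary feature matrix (for overlap tests).
stub_word <- function(fm, id = paste0("w", paste(as.integer(fm),
                                                 collapse = ""))) {
  structure(list(syllables = list(), feature_matrix = fm, id = id),
            class = "word")
}

# Minimal stream object over an explicit token sequence.
stub_stream <- function(tokens, alphabet = sort(unique(tokens)),
                        mode = "position_random",
                        word_index = rep(NA_integer_, length(tokens)),
                        word_position = rep(NA_integer_, length(tokens)),
                        lexicon = NULL) {
  structure(list(tokens = tokens, mode = mode, word_index = word_index,
                 word_position = word_position, lexicon = lexicon,
                 n_repetitions = NA, seed = NA, alphabet = alphabet),
            class = "stream")
}

# Brute-force PRI oracle: explicit double loop over windows and kernels.
pri_oracle <- function(x, kernels) {
  k <- attr(kernels, "k")
  matches <- 0L
  for (i in seq_len(length(x) - k + 1L)) {
    win <- x[i:(i + k - 1L)]
    for (kern in kernels) {
      if (all(win == kern)) {
        matches <- matches + 1L
        break
      }
    }
  }
  list(matches = matches, windows = length(x) - k + 1L,
       pri = matches / (length(x) - k + 1L))
}

# Exhaustive enumeration of Eulerian circuits of a multiplicity matrix,
# returning the set of realized transition-count matrices after dropping
# the closing edge (all start vertices).
enumerate_circuits <- function(mult) {
  n <- nrow(mult)
  results <- list()
  rec <- function(cur, rem, path) {
    if (sum(rem) == 0L) {
      tokens <- path[-length(path)]
      cnt <- matrix(0L, n, n)
      for (t in seq_len(length(tokens) - 1L))
        cnt[tokens[t], tokens[t + 1L]] <- cnt[tokens[t], tokens[t + 1L]] + 1L
      results[[length(results) + 1L]] <<- cnt
      return(invisible())
    }
    for (j in which(rem[cur, ] > 0L)) {
      rem[cur, j] <- rem[cur, j] - 1L
      rec(j, rem, c(path, j))
      rem[cur, j] <- rem[cur, j] + 1L
    }
  }
  for (s in which(rowSums(mult) > 0L)) rec(s, mult, s)
  unique(results)
}
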