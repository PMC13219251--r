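word_id <- function(word) render_ipa(word)

# Word-level feature matrix: one column per syllable; rows are the
# consonant feature subset evaluated on the syllable's (first) consonant
# slot, then the vowel feature subset evaluated on its (first) vowel slot.
word_feature_matrix <- function(word,
                                cons_feats = consonant_features(),
                                vow_feats = vowel_features()) {
  S <- length(word)
  rows <- c(paste0("C_", cons_feats), paste0("V_", vow_feats))
  m <- matrix(FALSE, nrow = length(rows), ncol = S,
              dimnames = list(rows, NULL))
  for (j in seq_len(S)) {
    syl <- word[[j]]
    slots <- strsplit(syl$pattern, "")[[1]]
    c_slot <- which(slots == "c")[1]
    v_slot <- which(slots %in% c("v", "V"))[1]
    fm <- syl$feature_matrix
    if (!is.na(c_slot))
      m[seq_along(cons_feats), j] <-
        fm[match(cons_feats, rownames(fm)), c_slot]
    if (!is.na(v_slot))
      m[length(cons_feats) + seq_along(vow_feats), j] <-
        fm[match(vow_feats, rownames(fm)), v_slot]
  }
  m
}

make_word <- function(syllables) {
  structure(list(syllables = syllables,
                 feature_matrix = word_feature_matrix(syllables),
                 id = paste(vapply(syllables, function(s) s$id,
                                   character(1)), collapse = "|")),
            class = "word")
}

#' @export
print.word <- function(x, ...) {
  cat("<word> ", x$id, "\n", sep = "")
  invisible(x)
}

syl_classes <- function(syl, table) {
  ph <- syl$phonemes
  cls <- lapply(ph, phono_class_of, table = table)
  vid <- stats::na.omit(vapply(cls, function(k) k$vowel_id, character(1)))
  place <- stats::na.omit(vapply(cls, function(k) k$place, character(1)))
  manner <- stats::na.omit(vapply(cls, function(k) k$manner, character(1)))
  list(place = place[1] %||% NA, manner = manner[1] %||% NA,
       vowel = vid[1] %||% NA)
}

#' Generate a pseudoword register under OCP constraints
#'
#' Samples words of `S` syllables from a syllable register.  A candidate
#' syllable is rejected when, per enabled OCP switch, its consonant's
#' place class, manner class, or its vowel identity equals that of any of
#' the previous `n_look_back` syllables already in the word.  Sampling is
#' seeded; generation stops at `n_words` words or `max_word_tries`
#' attempts, whichever comes first.  Duplicate words are dropped.
#'
#' @param syllables A `syllable_register`.
#' @param S Syllables per word (default 3).
#' @param n_words Target register size.
#' @param max_word_tries Attempt cap.
#' @param ocp Named logical vector/list with elements `place`, `manner`,
#'   `vowel` enabling each constraint.
#' @param n_look_back How many preceding syllables a candidate is checked
#'   against (default 2).
#' @param seed Integer seed.
#' @return List of `word` objects (class `word_register`).
#' @export
generate_word_register <- function(syllables, S = 3, n_words = 10000,
                                   max_word_tries = 100000,
                                   ocp = c(place = TRUE, manner = TRUE,
                                           vowel = TRUE),
                                   n_look_back = 2, seed = 1) {
  if (!length(syllables)) stop_ss("syllable register is empty")
  if (n_look_back < 1) stop_ss("n_look_back must be >= 1")
  table <- attr(syllables, "table")
  cls <- lapply(syllables, syl_classes, table = table)
  place <- vapply(cls, function(k) k$place, character(1))
  manner <- vapply(cls, function(k) k$manner, character(1))
  vowel <- vapply(cls, function(k) k$vowel, character(1))
  n <- length(syllables)
  words <- list()
  seen <- character(0)
  with_seed(seed, {
    tries <- 0L
    while (length(words) < n_words && tries < max_word_tries) {
      tries <- tries + 1L
      picks <- integer(0)
      ok <- TRUE
      for (slot in seq_len(S)) {
        cand <- seq_len(n)
        back <- utils::tail(picks, n_look_back)
        if (length(back)) {
          if (isTRUE(ocp[["place"]]))
            cand <- cand[!(place[cand] %in% place[back])]
          if (isTRUE(ocp[["manner"]]))
            cand <- cand[!(manner[cand] %in% manner[back])]
          if (isTRUE(ocp[["vowel"]]))
            cand <- cand[!(vowel[cand] %in% vowel[back])]
        }
        if (!length(cand)) { ok <- FALSE; break }
        picks <- c(picks, sample_one(cand))
      }
      if (!ok) next
      w <- make_word(syllables[picks])
      if (w$id %in% seen) next
      seen <- c(seen, w$id)
      words[[length(words) + 1L]] <- w
    }
  })
  if (!length(words))
    stop_ss("no word completed within max_word_tries; the register is ",
            "too small for the enabled OCP controls - disable some ",
            "controls or reduce n_look_back")
  structure(words, class = "word_register", table = table)
}

#' @export
print.word_register <- function(x, ...) {
  cat("<word_register> ", length(x), " pseudowords\n", sep = "")
  invisible(x)
}

#' Per-feature overlap flags between two pseudowords
#'
#' For each phonological feature row, the two words' per-syllable binary
#' sequences are compared (word b's sequence is cyclically shifted by
#' `lag - S` when a non-default `lag` is given).  A feature is flagged
#' when the sequences are identical and non-constant — such a feature
#' repeats at the word period in a stream and confounds the TP rhythm.
#'
#' @param a,b `word` objects sharing the same syllable count.
#' @param lag Comparison lag; default (NULL) is the word length S.
#' @return List with `flags` (named logical) and `total` (integer).
#' @export
pair_overlap <- function(a, b, lag = NULL) {
  fa <- a$feature_matrix
  fb <- b$feature_matrix
  S <- ncol(fa)
  if (ncol(fb) != S) stop_ss("words differ in syllable count")
  if (!is.null(lag) && lag != S) {
    sh <- ((lag - S) %% S)
    if (sh > 0) fb <- fb[, c((sh + 1):S, 1:sh), drop = FALSE]
  }
  flags <- vapply(seq_len(nrow(fa)), function(r) {
    ra <- fa[r, ]; rb <- fb[r, ]
    identical(ra, rb) && !all(ra) && any(ra)
  }, logical(1))
  names(flags) <- rownames(fa)
  list(flags = flags, total = sum(flags))
}

#' Pairwise feature-overlap matrix of a word register
#'
#' @param words Word register (list of `word`s).
#' @param lag See [pair_overlap()].
#' @return Symmetric integer matrix with zero diagonal (class
#'   `overlap_matrix` via attribute-free plain matrix).
#' @export
overlap_matrix <- function(words, lag = NULL) {
  n <- length(words)
  ids <- vapply(words, function(w) w$id, character(1))
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  S <- ncol(words[[1]]$feature_matrix)
  sh <- if (!is.null(lag) && lag != S) (lag - S) %% S else 0L
  colperm <- if (sh > 0) c((sh + 1):S, 1:sh) else seq_len(S)
  # encode each feature row of each word as an integer; a pair is flagged
  # on a feature iff codes are equal and non-constant (identical,
  # non-constant per-syllable sequences) -- vectorised pair_overlap()
  nf <- nrow(words[[1]]$feature_matrix)
  pow <- 2^(seq_len(S) - 1L)
  codes_a <- vapply(words, function(w)
    as.integer(w$feature_matrix %*% pow), integer(nf))
  codes_b <- vapply(words, function(w)
    as.integer(w$feature_matrix[, colperm, drop = FALSE] %*% pow),
    integer(nf))
  codes_a <- matrix(codes_a, nrow = nf)
  codes_b <- matrix(codes_b, nrow = nf)
  const <- c(0L, sum(pow))
  for (f in seq_len(nf)) {
    ca <- codes_a[f, ]; cb <- codes_b[f, ]
    eq <- outer(ca, cb, "==") & !(ca %in% const)
    # symmetrise: either orientation of the (unordered) pair may match
    add <- (eq | t(eq)) * 1L
    diag(add) <- 0L
    m <- m + add
  }
  m
}

words_share_syllables <- function(a, b) {
  any(vapply(a$syllables, function(s) s$id, character(1)) %in%
        vapply(b$syllables, function(s) s$id, character(1)))
}

make_lexicon <- function(words, overlap) {
  structure(list(words = words,
                 overlap = overlap,
                 total_overlap = sum(overlap[upper.tri(overlap)]),
                 S = ncol(words[[1]]$feature_matrix)),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon> ", length(x$words), " pseudowords, total overlap ",
      x$total_overlap, "\n", sep = "")
  for (w in x$words) cat("  ", w$id, "\n", sep = "")
  invisible(x)
}

#' Assemble minimal-overlap lexicons from a word register
#'
#' Draws a seeded subsample of at most `max_word_matrix` words, computes
#' the pairwise overlap matrix once, and enumerates word combinations in
#' non-decreasing total-overlap order with a lazy best-first search over
#' index-ordered prefixes (priority = accumulated overlap, an admissible
#' bound since adding words never decreases it; ties broken uniformly at
#' random under the seed).  With `binary_feature_control`, combinations
#' containing a pair with overlap >= `max_overlap` are pruned.
#'
#' @param register Word register.
#' @param n_lexicons How many lexicons to return.
#' @param n_words_per_lexicon Words per lexicon (default 4).
#' @param max_word_matrix Subsample size for the overlap matrix.
#' @param max_overlap Pairwise overlap bound (default 1: no overlap at all).
#' @param unique_words Later lexicons may not reuse words of earlier ones.
#' @param binary_feature_control Enable the pairwise overlap bound.
#' @param distinct_syllables Reject lexicons in which two words share a
#'   syllable (required for the stream graphs, where every syllable must
#'   have a unique word/position; default TRUE).
#' @param lag See [pair_overlap()].
#' @param seed Integer seed.
#' @return List of `lexicon` objects, non-decreasing in `total_overlap`.
#' @export
assemble_lexicons <- function(register, n_lexicons = 2,
                              n_words_per_lexicon = 4,
                              max_word_matrix = 200, max_overlap = 1,
                              unique_words = FALSE,
                              binary_feature_control = TRUE,
                              distinct_syllables = TRUE,
                              lag = NULL, seed = 1) {
  n <- length(register)
  if (n < n_words_per_lexicon)
    stop_ss("register smaller than n_words_per_lexicon")
  out <- with_seed(seed, {
    sub_idx <- if (n > max_word_matrix) sample(n, max_word_matrix) else seq_len(n)
    words <- register[sub_idx]
    m <- length(words)
    ov <- overlap_matrix(words, lag = lag)
    # pairwise admissibility, computed once
    compat <- matrix(TRUE, m, m)
    if (binary_feature_control) compat <- compat & (ov < max_overlap)
    if (distinct_syllables) {
      syl <- lapply(words, function(w)
        vapply(w$syllables, function(s) s$id, character(1)))
      for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
        if (compat[i, j] && any(syl[[i]] %in% syl[[j]]))
          compat[i, j] <- compat[j, i] <- FALSE
      }
    }
    diag(compat) <- FALSE
    max_prio <- choose(n_words_per_lexicon, 2) *
      nrow(words[[1]]$feature_matrix)
    q <- bucketq_new(max_prio)
    for (i in sample(m)) bucketq_push(q, 0L, c(i, 0L))  # node = (idx..., sum)
    lexicons <- list()
    used_words <- character(0)
    while (length(lexicons) < n_lexicons && bucketq_size(q) > 0L) {
      node <- bucketq_pop(q)
      k <- length(node) - 1L
      idx <- node[seq_len(k)]
      if (k == n_words_per_lexicon) {
        ws <- words[idx]
        ids <- vapply(ws, function(w) w$id, character(1))
        if (unique_words && any(ids %in% used_words)) next
        lexicons[[length(lexicons) + 1L]] <-
          make_lexicon(ws, ov[idx, idx, drop = FALSE])
        used_words <- c(used_words, ids)
        next
      }
      last <- idx[k]
      if (last < m) {
        cand <- (last + 1L):m
        ok <- cand[colSums(!compat[idx, cand, drop = FALSE]) == 0L]
        if (length(ok)) {
          add <- if (k == 1L) ov[ok, idx] else colSums(ov[idx, ok, drop = FALSE])
          sums <- node[k + 1L] + add
          for (t in sample(seq_along(ok)))  # randomized tie-breaks
            bucketq_push(q, sums[t], c(idx, ok[t], sums[t]))
        }
      }
    }
    if (!length(lexicons)) {
      off <- ov[upper.tri(ov)]
      stop_ss("no admissible lexicon under max_overlap = ", max_overlap,
              "; minimal achievable pairwise overlap in the subsample is ",
              if (length(off)) min(off) else NA)
    }
    lexicons
  })
  out
}

#' Write / read word registers and lexicons as plain text
#'
#' One word per line in the IPA `"|"`/`"_"` convention.
#'
#' @param words Word register or `lexicon`.
#' @param path Output file.
#' @export
write_word_register <- function(words, path) {
  if (inherits(words, "lexicon")) words <- words$words
  writeLines(vapply(words, function(w) w$id, character(1)), path,
             useBytes = TRUE)
}

#' @rdname write_word_register
#' @param table A `feature_table` for re-annotation.
#' @export
read_word_register <- function(path, table) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  words <- lapply(parse_ipa(lines, table), make_word)
  structure(words, class = "word_register", table = table)
}
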