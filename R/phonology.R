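#' Default distinctive-feature subsets
#'
#' Feature subsets carried through the pipeline as per-syllable annotations:
#' one set describes the consonant of a syllable, the other its vowel.
#' These are the features over which pseudoword feature matrices (and hence
#' overlap control and the Phonological Rhythmicity Index) are computed.
#'
#' @return Character vector of feature names.
#' @export
consonant_features <- function() {
  c("son", "cont", "lat", "nas", "voi", "cor", "lab", "hi", "back")
}

#' @rdname consonant_features
#' @export
vowel_features <- function() {
  c("lab", "hi", "lo", "back", "tense", "long")
}

canonical_features <- function() {
  c("syl", "son", "cons", "cont", "delrel", "lat", "nas", "strid", "voi",
    "sg", "cg", "ant", "cor", "distr", "lab", "hi", "lo", "back", "rnd",
    "tense", "long")
}

#' Path to the bundled miniature phoneme inventory
#'
#' A hand-curated synthetic stand-in (~30 German-like phonemes, 21 binary
#' distinctive features) for large phoneme databases that cannot be
#' redistributed.  Includes a few multi-character phonemes (affricates,
#' a diphthong) to exercise the single-character restriction.
#'
#' @return File path of the CSV.
#' @export
default_feature_table_path <- function() {
  system.file("extdata", "phoneme_features_synthetic.csv",
              package = "sylstream", mustWork = TRUE)
}

# A phoneme symbol counts as "single character" when, after stripping the
# IPA length mark U+02D0, exactly one character remains; long vowels like
# "aː" survive, affricates ("ts") and diphthongs do not.
is_single_char_symbol <- function(sym) {
  nchar(gsub("ː", "", sym, fixed = TRUE)) == 1L
}

#' Load a phoneme inventory with binary distinctive features
#'
#' Reads a CSV with a `phoneme` column and one column per feature, values
#' in \{+, -, 0, 1\}.  Ternary values collapse to binary presence: only
#' "+" or "1" count as present.
#'
#' @param path CSV file path; defaults to the bundled synthetic inventory.
#' @param feature_subset Optional character vector restricting the feature
#'   columns (order preserved as given).
#' @param single_char_only Keep only single-character IPA symbols (the
#'   length mark is not counted). Default TRUE.
#' @return A `feature_table`: list with `features` (logical matrix,
#'   phonemes x features), `symbols`, `feature_names`.
#' @export
load_feature_table <- function(path = default_feature_table_path(),
                               feature_subset = NULL,
                               single_char_only = TRUE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  if (!"phoneme" %in% names(df))
    stop_ss("feature table must have a 'phoneme' column")
  syms <- enc2utf8(as.character(df$phoneme))
  if (anyDuplicated(syms))
    stop_ss("duplicate phoneme symbol(s): ",
            paste(unique(syms[duplicated(syms)]), collapse = ", "))
  feats <- setdiff(names(df), "phoneme")
  if (!is.null(feature_subset)) {
    unknown <- setdiff(feature_subset, feats)
    if (length(unknown))
      stop_ss("unknown feature name(s) in subset: ",
              paste(unknown, collapse = ", "))
    feats <- feature_subset
  }
  m <- sapply(feats, function(f) as.character(df[[f]]) %in% c("+", "1"))
  m <- matrix(as.logical(m), nrow = length(syms),
              dimnames = list(syms, feats))
  if (single_char_only) m <- m[is_single_char_symbol(syms), , drop = FALSE]
  structure(list(features = m,
                 symbols = rownames(m),
                 feature_names = feats),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", length(x$symbols), " phonemes x ",
      length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

has_feature <- function(table, phoneme, feature) {
  if (!phoneme %in% x_syms(table))
    stop_ss("phoneme not in table: ", phoneme)
  if (!feature %in% table$feature_names) return(FALSE)
  table$features[phoneme, feature]
}

x_syms <- function(table) table$symbols

is_vowel <- function(table, phoneme) has_feature(table, phoneme, "syl")

#' Phono-articulatory class of a phoneme
#'
#' Collapses distinctive features into the classes used by the OCP
#' phonotactic constraints: consonants get a place (labial, apical, other;
#' labial takes precedence when both lab and cor are present) and a manner
#' (sonorant, plosive, fricative); vowels return their own symbol as
#' `vowel_id`.
#'
#' @param phoneme Phoneme symbol present in `table`.
#' @param table A `feature_table`.
#' @return List with `place`, `manner`, `vowel_id` (NA fields where not
#'   applicable).
#' @export
phono_class_of <- function(phoneme, table) {
  if (!phoneme %in% table$symbols)
    stop_ss("phoneme not in table: ", phoneme)
  if (is_vowel(table, phoneme)) {
    return(structure(list(place = NA_character_, manner = NA_character_,
                          vowel_id = phoneme), class = "phono_class"))
  }
  f <- table$features[phoneme, ]
  g <- function(nm) isTRUE(unname(f[nm]))
  place <- if (g("lab")) "labial" else if (g("cor")) "apical" else "other"
  manner <- if (g("son")) "sonorant" else if (g("cont")) "fricative" else "plosive"
  structure(list(place = place, manner = manner, vowel_id = NA_character_),
            class = "phono_class")
}

syllable_id <- function(phonemes) paste(phonemes, collapse = "_")

make_syllable <- function(phonemes, pattern, table) {
  fm <- t(table$features[phonemes, , drop = FALSE])
  colnames(fm) <- phonemes
  structure(list(phonemes = phonemes,
                 pattern = pattern,
                 feature_matrix = fm,
                 id = syllable_id(phonemes)),
            class = "syllable")
}

#' @export
print.syllable <- function(x, ...) {
  cat("<syllable> ", x$id, " (", x$pattern, ")\n", sep = "")
  invisible(x)
}

#' Build a syllable register from a fixed syllable pattern
#'
#' Takes the Cartesian product of eligible phonemes per slot.  Pattern
#' symbols: `c` = consonant (not syllabic), `v` = short vowel (syllabic,
#' not long), `V` = long vowel (syllabic and long).  Output order is
#' lexicographic in the syllable id.
#'
#' @param table A `feature_table`.
#' @param pattern Pattern string, e.g. `"cV"`.
#' @return List of `syllable` objects with class `syllable_register`.
#' @export
build_syllable_register <- function(table, pattern = "cV") {
  slots <- strsplit(pattern, "")[[1]]
  sym <- table$symbols
  vowel <- vapply(sym, function(p) is_vowel(table, p), logical(1))
  long <- if ("long" %in% table$feature_names)
    table$features[, "long"] else rep(FALSE, length(sym))
  pools <- lapply(slots, function(s) {
    pool <- switch(s,
      c = sym[!vowel],
      v = sym[vowel & !long],
      V = sym[vowel & long],
      stop_ss("unknown slot symbol in pattern: '", s, "'"))
    if (!length(pool))
      stop_ss("no eligible phonemes for slot '", s, "' in pattern '",
              pattern, "'")
    sort(pool, method = "radix")
  })
  grid <- expand.grid(rev(pools), stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(pools)), drop = FALSE]
  sylls <- lapply(seq_len(nrow(grid)), function(i)
    make_syllable(as.character(unlist(grid[i, ])), pattern, table))
  ids <- vapply(sylls, function(s) s$id, character(1))
  sylls <- sylls[order(ids, method = "radix")]
  structure(sylls, class = "syllable_register",
            pattern = pattern, table = table)
}

#' @export
print.syllable_register <- function(x, ...) {
  cat("<syllable_register> ", length(x), " syllables, pattern '",
      attr(x, "pattern"), "'\n", sep = "")
  invisible(x)
}

#' Parse IPA transcripts into syllabified words
#'
#' Input convention: one word per string, syllables separated by `"|"`,
#' phonemes within a syllable separated by `"_"` (e.g.
#' `"b_aː|g_oː|d_iː"`).  All words in one call must share
#' the same syllable count and per-syllable phoneme count.
#'
#' @param text Character vector of word transcripts.
#' @param table A `feature_table`; every phoneme must be present.
#' @param pattern Optional pattern string to attach to syllables; inferred
#'   from the features (c/v/V) when NULL.
#' @return List of words, each a list of `syllable` objects.
#' @export
parse_ipa <- function(text, table, pattern = NULL) {
  words <- lapply(text, function(w) {
    syl_strs <- strsplit(w, "|", fixed = TRUE)[[1]]
    lapply(syl_strs, function(s) {
      ph <- strsplit(s, "_", fixed = TRUE)[[1]]
      missing <- setdiff(ph, table$symbols)
      if (length(missing))
        stop_ss("unknown phoneme(s) ", paste(missing, collapse = ", "),
                " in word '", w, "'")
      pat <- pattern %||% paste(vapply(ph, function(p) {
        if (!is_vowel(table, p)) "c"
        else if (has_feature(table, p, "long")) "V" else "v"
      }, character(1)), collapse = "")
      make_syllable(ph, pat, table)
    })
  })
  ns <- vapply(words, length, integer(1))
  if (length(unique(ns)) > 1L)
    stop_ss("ragged syllable counts across words: ",
            paste(unique(ns), collapse = " vs "))
  np <- unique(unlist(lapply(words, function(w)
    vapply(w, function(s) length(s$phonemes), integer(1)))))
  if (length(np) > 1L)
    stop_ss("inconsistent phoneme counts across syllables")
  words
}

#' Render a word back to its IPA transcript
#'
#' Inverse of [parse_ipa()]: syllables joined by `"|"`, phonemes by `"_"`.
#'
#' @param word A list of `syllable` objects (one word).
#' @return Character scalar.
#' @export
render_ipa <- function(word) {
  paste(vapply(word, function(s) s$id, character(1)), collapse = "|")
}
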