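test_that("pair overlap flags identical non-constant feature sequences", {
  fm <- function(rows) matrix(as.logical(rows), nrow = length(rows) / 3,
                              byrow = TRUE)
  a <- stub_word(fm(c(1, 0, 0,   1, 1, 1,   0, 1, 0)))
  b <- stub_word(fm(c(1, 0, 0,   1, 1, 1,   1, 0, 0)))
  o <- pair_overlap(a, b)
  # row 1: [1 0 0] vs [1 0 0] identical, non-constant -> flagged
  # row 2: constant [1 1 1] -> not flagged
  # row 3: [0 1 0] vs [1 0 0] different -> not flagged
  expect_equal(unname(o$flags), c(TRUE, FALSE, FALSE))
  expect_equal(o$total, 1)
  expect_equal(pair_overlap(a, a)$total, 2)  # rows 1 and 3, not constant row

  all_zero <- stub_word(fm(rep(0, 9)))
  expect_equal(pair_overlap(all_zero, all_zero)$total, 0)

  short <- stub_word(matrix(TRUE, 3, 2))
  expect_error(pair_overlap(a, short), "syllable count")
})

test_that("overlap matrix is symmetric, zero-diagonal, equals pair_overlap", {
  words <- fx_words()[1:25]
  ov <- overlap_matrix(words)
  expect_true(isSymmetric(unname(ov)))
  expect_true(all(diag(ov) == 0))
  expect_true(all(ov >= 0 & ov <= nrow(words[[1]]$feature_matrix)))
  set.seed(5)
  for (k in 1:30) {
    ij <- sample(25, 2)
    expect_equal(ov[ij[1], ij[2]],
                 pair_overlap(words[[ij[1]]], words[[ij[2]]])$total)
  }
})

test_that("word generation respects OCP constraints and the seed", {
  ft <- fx_table()
  reg <- fx_register()
  words <- fx_words()
  classes <- function(syl) {
    cons <- syl$phonemes[1]
    vow <- syl$phonemes[2]
    cl <- phono_class_of(cons, ft)
    c(place = cl$place, manner = cl$manner, vowel = vow)
  }
  # no word may repeat place, manner, or vowel within a 2-syllable window
  for (w in words[1:60]) {
    cls <- t(vapply(w$syllables, classes, character(3)))
    for (i in 2:nrow(cls)) {
      back <- max(1, i - 2):(i - 1)
      expect_false(cls[i, "place"] %in% cls[back, "place"])
      expect_false(cls[i, "manner"] %in% cls[back, "manner"])
      expect_false(cls[i, "vowel"] %in% cls[back, "vowel"])
    }
  }

  w1 <- generate_word_register(reg, S = 3, n_words = 30,
                               max_word_tries = 3000, seed = 7)
  w2 <- generate_word_register(reg, S = 3, n_words = 30,
                               max_word_tries = 3000, seed = 7)
  expect_identical(vapply(w1, function(w) w$id, character(1)),
                   vapply(w2, function(w) w$id, character(1)))

  # vowel OCP with a single long vowel cannot complete any word
  tt <- tiny_table()
  onevowel <- load_feature_table(tempfile_with <- {
    p <- tempfile(fileext = ".csv")
    write_tiny_table(p, rows = c(
      "phoneme,syl,son,cont,lat,nas,voi,cor,lab,hi,lo,back,tense,long",
      "b,-,-,-,-,-,+,-,+,-,-,-,-,-",
      "t,-,-,-,-,-,-,+,-,-,-,-,-,-",
      "aː,+,+,+,-,-,+,-,-,-,+,-,+,+"))
    p
  })
  reg1 <- build_syllable_register(onevowel, "cV")
  expect_error(generate_word_register(reg1, S = 2, n_words = 5,
                                      max_word_tries = 50, seed = 1),
               "OCP|register")
})

test_that("lexicon assembly matches the exhaustive minimum on small registers", {
  words <- fx_words()[1:8]
  ov <- overlap_matrix(words)
  brute <- function(n_pick) {
    combos <- combn(length(words), n_pick)
    sums <- apply(combos, 2, function(ix) sum(ov[ix, ix]) / 2)
    min(sums)
  }
  for (sd in c(1, 2, 3)) {
    lex <- assemble_lexicons(words, n_lexicons = 1, n_words_per_lexicon = 4,
                             binary_feature_control = FALSE,
                             distinct_syllables = FALSE, seed = sd)[[1]]
    expect_equal(lex$total_overlap, brute(4))
  }
  # lexicons come out in non-decreasing overlap order
  lexs <- assemble_lexicons(words, n_lexicons = 6, n_words_per_lexicon = 4,
                            binary_feature_control = FALSE,
                            distinct_syllables = FALSE, seed = 1)
  tots <- vapply(lexs, function(l) l$total_overlap, numeric(1))
  expect_true(all(diff(tots) >= 0))
})

test_that("max_overlap = 1 yields lexicons with all pairwise overlaps 0", {
  # hand-built candidates (3 feature rows x 3 syllables): wa..wd are
  # pairwise overlap-0; x1 shares one non-constant row with each of
  # wa, wb, wc, so any 4-subset containing x1 is inadmissible
  fm <- function(rows) matrix(as.logical(rows), nrow = 3, byrow = TRUE)
  wa <- stub_word(fm(c(1, 0, 0,  0, 0, 0,  0, 0, 0)), "wa")
  wb <- stub_word(fm(c(0, 1, 1,  0, 1, 0,  1, 1, 0)), "wb")
  wc <- stub_word(fm(c(1, 1, 0,  1, 0, 1,  0, 0, 1)), "wc")
  wd <- stub_word(fm(c(1, 1, 1,  0, 0, 0,  1, 1, 1)), "wd")
  x1 <- stub_word(fm(c(1, 0, 0,  0, 1, 0,  0, 0, 1)), "x1")
  expect_equal(pair_overlap(x1, wa)$total, 1)
  expect_equal(pair_overlap(x1, wb)$total, 1)
  expect_equal(pair_overlap(x1, wc)$total, 1)

  lex <- assemble_lexicons(list(wa, wb, wc, wd, x1), n_lexicons = 1,
                           n_words_per_lexicon = 4,
                           max_overlap = 1, binary_feature_control = TRUE,
                           distinct_syllables = FALSE, seed = 1)[[1]]
  expect_true(all(lex$overlap[upper.tri(lex$overlap)] == 0))
  expect_equal(lex$total_overlap, 0)
  expect_false("x1" %in% vapply(lex$words, function(w) w$id, character(1)))

  # impossible bound -> error reporting the minimal achievable overlap
  clash <- lapply(1:5, function(i)
    stub_word(fm(c(1, 0, 0,  0, 1, 0,  0, 0, 1)), paste0("x", i)))
  expect_error(
    assemble_lexicons(clash, n_lexicons = 1, n_words_per_lexicon = 4,
                      max_overlap = 1, distinct_syllables = FALSE,
                      seed = 1),
    "minimal achievable")
})

test_that("unique_words and distinct_syllables are honored", {
  words <- fx_words()
  lexs <- assemble_lexicons(words, n_lexicons = 3, max_overlap = 2,
                            max_word_matrix = 60, unique_words = TRUE,
                            seed = 9)
  ids <- unlist(lapply(lexs, function(l)
    vapply(l$words, function(w) w$id, character(1))))
  expect_false(anyDuplicated(ids) > 0)
  for (l in lexs) {
    syl <- unlist(lapply(l$words, function(w)
      vapply(w$syllables, function(s) s$id, character(1))))
    expect_false(anyDuplicated(syl) > 0)
  }
})

test_that("registers round-trip through plain-text export", {
  ft <- fx_table()
  words <- fx_words()[1:10]
  p <- tempfile(fileext = ".txt")
  write_word_register(words, p)
  back <- read_word_register(p, ft)
  expect_identical(vapply(back, function(w) w$id, character(1)),
                   vapply(words, function(w) w$id, character(1)))
  expect_equal(back[[1]]$feature_matrix, words[[1]]$feature_matrix)
})
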