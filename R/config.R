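#' Default pipeline configuration
#'
#' Every parameter of the generation pipeline with its default, mirroring
#' the toolchain's canonical parameter sheet: syllable-stage controls
#' (corpus uniformity filter), word-stage controls (OCP phonotactics,
#' n-gram and positional corpus filters), lexicon-stage controls
#' (feature-overlap rejection), and stream-stage controls (TP modes,
#' repetitions, rhythmicity rejection).  A global `seed` and `output_dir`
#' are added for reproducibility and artifact output; every stochastic
#' stage derives its own child seed from `seed`.
#'
#' @return Named list (class `sylstream_config`).
#' @export
default_config <- function() {
  structure(list(
    lang = "deu",
    phoneme_pattern = "cV",
    syllable_control = TRUE,
    syllable_alpha = 0.05,
    syllable_corpus = NULL,
    n_syllables_per_word = 3,
    n_words = 10000,
    max_word_tries = 100000,
    phonotactic_control = TRUE,
    n_look_back = 2,
    bigram_control = TRUE,
    bigram_alpha = NULL,
    trigram_control = TRUE,
    trigram_alpha = NULL,
    positional_control = TRUE,
    positional_position = NULL,
    position_alpha = NULL,
    n_lexicons = 2,
    n_words_per_lexicon = 4,
    binary_feature_control = TRUE,
    max_overlap = 1,
    lag = NULL,
    max_word_matrix = 200,
    unique_words = FALSE,
    n_repetitions = 15,
    n_streams_per_lexicon = 2,
    tp_modes = c("word_structured", "position_random", "position_fixed"),
    max_rhythmicity = NULL,
    max_tries_randomize = 10,
    require_all_tp_modes = TRUE,
    seed = 1,
    output_dir = NULL
  ), class = "sylstream_config")
}

mode_aliases <- c(random = "position_random",
                  position_controlled = "position_fixed",
                  position_random = "position_random",
                  position_fixed = "position_fixed",
                  word_structured = "word_structured")

#' Validate and complete a configuration
#'
#' Unknown keys are rejected; missing keys take their defaults; TP-mode
#' aliases (`random`, `position_controlled`) are canonicalised.
#'
#' @param config Named list of overrides (possibly partial).
#' @return Complete `sylstream_config`.
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop_ss("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- def
  for (k in names(config)) cfg[[k]] <- config[[k]]
  if (!is.null(cfg$tp_modes)) {
    bad <- setdiff(cfg$tp_modes, names(mode_aliases))
    if (length(bad)) stop_ss("unknown tp_mode(s): ", paste(bad, collapse = ", "))
    cfg$tp_modes <- unname(mode_aliases[cfg$tp_modes])
  }
  stopifnot(cfg$n_syllables_per_word >= 2, cfg$n_repetitions >= 1,
            cfg$n_words_per_lexicon >= 2, cfg$n_look_back >= 1)
  cfg
}

#' Read / write a configuration file
#'
#' Flat YAML key/value file; `NULL`-valued keys may be written as `~`.
#'
#' @param path File path.
#' @export
load_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname load_config
#' @param config A configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_stage <- function(...) message("[sylstream] ", ...)

stage <- function(name, keys, expr) {
  tryCatch(expr, error = function(e)
    stop_ss("stage '", name, "' failed (config: ",
            paste(keys, collapse = ", "), "): ", conditionMessage(e)))
}

#' Run the full generation pipeline
#'
#' Executes the five steps with seeded determinism: (1) syllable register
#' from the phoneme inventory, with an optional corpus uniformity filter;
#' (2) pseudoword register under OCP constraints with n-gram/positional
#' corpus filters; (3) minimal-overlap lexicon assembly; (4) TP-controlled
#' stream generation per mode with optional rhythmicity rejection;
#' (5) metrics (and optional audio) reports.  Register sizes are logged
#' before and after each filter.  When `output_dir` is set, lexicon JSON,
#' stream CSVs, and PRI/metrics JSON are written there.
#'
#' @param config Partial or complete configuration (see
#'   [default_config()]).
#' @param feature_table A `feature_table`; default = bundled inventory.
#' @param corpus Optional list of `frequency_table`s (`syllables`,
#'   `bigrams`, `trigrams`, `positional`); default = synthetic Zipf
#'   corpus when any corpus-based control is on.
#' @param render_audio Also render and save stream WAVs (slow; default
#'   FALSE).
#' @return Invisible list: `config`, `syllables`, `words`, `lexicons`,
#'   `streams` (per lexicon, per mode), `pri` (reports).
#' @export
run_pipeline <- function(config = list(),
                         feature_table = load_feature_table(),
                         corpus = NULL, render_audio = FALSE) {
  cfg <- validate_config(config)
  seed <- cfg$seed

  reg <- stage("syllables", "phoneme_pattern",
               build_syllable_register(feature_table, cfg$phoneme_pattern))
  log_stage("syllable register: ", length(reg), " syllables")

  needs_corpus <- cfg$syllable_control || cfg$bigram_control ||
    cfg$trigram_control || cfg$positional_control
  if (is.null(corpus) && needs_corpus) {
    corpus <- if (!is.null(cfg$syllable_corpus)) {
      list(syllables = read_frequency_table(cfg$syllable_corpus))
    } else {
      # corpus size scales with the register so that n-gram presence
      # filters see realistic type coverage (real corpora are orders of
      # magnitude larger than the syllable inventory)
      generate_synthetic_corpus(reg, n_tokens = 400 * length(reg),
                                seed = child_seed(seed, 11),
                                s_per_word = cfg$n_syllables_per_word)
    }
  }

  if (cfg$syllable_control && !is.null(corpus$syllables)) {
    kept <- stage("syllable_filter", c("syllable_control", "syllable_alpha"),
                  attr(uniformity_filter(corpus$syllables,
                                         cfg$syllable_alpha), "kept"))
    ids <- vapply(reg, function(s) s$id, character(1))
    reg2 <- reg[ids %in% kept]
    log_stage("syllable uniformity filter: ", length(reg), " -> ",
              length(reg2))
    attributes(reg2) <- attributes(reg)[c("class", "pattern", "table")]
    reg <- reg2
  }
  if (!length(reg)) stop_ss("empty syllable register after filtering")

  ocp <- c(place = cfg$phonotactic_control, manner = cfg$phonotactic_control,
           vowel = cfg$phonotactic_control)
  words <- stage("words", c("n_words", "max_word_tries", "n_look_back"),
                 generate_word_register(
                   reg, S = cfg$n_syllables_per_word, n_words = cfg$n_words,
                   max_word_tries = cfg$max_word_tries, ocp = ocp,
                   n_look_back = cfg$n_look_back,
                   seed = child_seed(seed, 21)))
  log_stage("word register: ", length(words), " pseudowords")

  if (cfg$bigram_control && !is.null(corpus$bigrams)) {
    n0 <- length(words)
    words <- stage("bigram_filter", c("bigram_control", "bigram_alpha"),
                   ngram_filter(words, corpus$bigrams, n = 2,
                                alpha = cfg$bigram_alpha))
    log_stage("bigram filter: ", n0, " -> ", length(words))
  }
  if (cfg$trigram_control && !is.null(corpus$trigrams)) {
    n0 <- length(words)
    words <- stage("trigram_filter", c("trigram_control", "trigram_alpha"),
                   ngram_filter(words, corpus$trigrams, n = 3,
                                alpha = cfg$trigram_alpha))
    log_stage("trigram filter: ", n0, " -> ", length(words))
  }
  if (cfg$positional_control && !is.null(corpus$positional)) {
    n0 <- length(words)
    words <- stage("positional_filter",
                   c("positional_control", "positional_position",
                     "position_alpha"),
                   positional_filter(words, corpus$positional,
                                     position = cfg$positional_position,
                                     alpha = cfg$position_alpha))
    log_stage("positional filter: ", n0, " -> ", length(words))
  }

  lexicons <- stage("lexicons",
                    c("n_lexicons", "n_words_per_lexicon", "max_overlap"),
                    assemble_lexicons(
                      words, n_lexicons = cfg$n_lexicons,
                      n_words_per_lexicon = cfg$n_words_per_lexicon,
                      max_word_matrix = cfg$max_word_matrix,
                      max_overlap = cfg$max_overlap,
                      unique_words = cfg$unique_words,
                      binary_feature_control = cfg$binary_feature_control,
                      lag = cfg$lag, seed = child_seed(seed, 31)))
  log_stage("lexicons: ", length(lexicons), " (total overlap: ",
            paste(vapply(lexicons, function(l) l$total_overlap, numeric(1)),
                  collapse = ", "), ")")

  streams <- list()
  pri <- list()
  for (li in seq_along(lexicons)) {
    per_mode <- list()
    for (k in seq_len(cfg$n_streams_per_lexicon)) {
      acc <- stage("streams", c("tp_modes", "n_repetitions"),
                   reject_by_rhythmicity(
                     lexicons[[li]], tp_modes = cfg$tp_modes,
                     n_repetitions = cfg$n_repetitions,
                     max_rhythmicity = cfg$max_rhythmicity,
                     max_tries_randomize = cfg$max_tries_randomize,
                     require_all_tp_modes = cfg$require_all_tp_modes,
                     seed = child_seed(seed, 41 + 100 * li + k)))
      per_mode[[k]] <- acc
    }
    streams[[li]] <- per_mode
    pri[[li]] <- lapply(per_mode, function(acc)
      lapply(acc, function(s) stream_pri_report(s)))
  }

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      lapply(lexicons, function(l) list(
        words = vapply(l$words, function(w) w$id, character(1)),
        total_overlap = l$total_overlap)),
      file.path(cfg$output_dir, "lexicons.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (li in seq_along(streams)) for (k in seq_along(streams[[li]])) {
      for (mode in names(streams[[li]][[k]])) {
        s <- streams[[li]][[k]][[mode]]
        base <- sprintf("lex%d_stream%d_%s", li, k, mode)
        write_stream(s, file.path(cfg$output_dir, paste0(base, ".csv")))
        write_metrics_report(s, file.path(cfg$output_dir,
                                          paste0(base, "_metrics.json")))
        if (render_audio) {
          w <- render_stream_audio(s)
          write_wav(w, file.path(cfg$output_dir, paste0(base, ".wav")),
                    sample_rate = attr(w, "sample_rate"))
        }
      }
    }
  }

  invisible(list(config = cfg, syllables = reg, words = words,
                 lexicons = lexicons, streams = streams, pri = pri))
}
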