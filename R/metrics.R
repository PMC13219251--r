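transition_counts <- function(stream) {
  al <- stream$alphabet
  n <- length(al)
  m <- matrix(0L, n, n, dimnames = list(al, al))
  tok <- stream$tokens
  if (length(tok) >= 2) {
    i <- match(tok[-length(tok)], al)
    j <- match(tok[-1], al)
    for (k in seq_along(i)) m[i[k], j[k]] <- m[i[k], j[k]] + 1L
  }
  m
}

#' Empirical transition-probability matrix of a stream
#'
#' Final-position row-normalized transition counts over the stream's
#' alphabet; rows with no outgoing observations are all zero.
#'
#' @param stream A `stream` (length >= 2).
#' @return Numeric matrix (alphabet x alphabet).
#' @export
empirical_tp <- function(stream) {
  m <- transition_counts(stream)
  rs <- rowSums(m)
  tp <- m / ifelse(rs == 0, 1, rs)
  tp
}

#' Online surprisal, entropy, and KL-divergence traces
#'
#' At each transition t the empirical next-token distribution uses counts
#' observed strictly before t.  Surprisal applies add-one smoothing over
#' the N - 1 admissible successors (raw counts would make the first
#' observation of any pair infinitely surprising); entropy and the
#' divergence use raw normalized counts with the 0 log 0 = 0 convention.
#' `H(t)` is the mean conditional entropy over sources with observations
#' and `D(t) = log2(N - 1) - H(t) >= 0` measures distance from uniform
#' transitions, collapsing to zero exactly for perfectly uniform counts.
#'
#' @param stream A `stream` (length >= 2).
#' @return An `info_trace`: data frame with columns `t`, `surprisal`,
#'   `entropy`, `divergence`; attribute `N`.
#' @export
info_traces <- function(stream) {
  al <- stream$alphabet
  N <- length(al)
  tok <- match(stream$tokens, al)
  T_ <- length(tok)
  if (T_ < 2) stop_ss("stream too short")
  counts <- matrix(0, N, N)
  surp <- ent <- div <- numeric(T_ - 1L)
  log2u <- log2(N - 1)
  for (t in seq_len(T_ - 1L)) {
    i <- tok[t]; j <- tok[t + 1L]
    surp[t] <- -log2((counts[i, j] + 1) / (sum(counts[i, ]) + N - 1))
    rs <- rowSums(counts)
    obs <- which(rs > 0)
    if (length(obs)) {
      h <- vapply(obs, function(r) {
        p <- counts[r, ] / rs[r]
        p <- p[p > 0]
        -sum(p * log2(p))
      }, numeric(1))
      ent[t] <- mean(h)
    } else ent[t] <- 0
    div[t] <- log2u - ent[t]
    counts[i, j] <- counts[i, j] + 1
  }
  structure(data.frame(t = seq_len(T_ - 1L), surprisal = surp,
                       entropy = ent, divergence = div),
            N = N, class = c("info_trace", "data.frame"))
}

#' Final KL divergence from uniform transitions
#'
#' Divergence of the complete stream's empirical transition distribution
#' from the uniform distribution over the N - 1 admissible successors,
#' computed from all T - 1 realized transitions.
#'
#' @param stream A `stream`.
#' @return Scalar, bits.
#' @export
final_divergence <- function(stream) {
  m <- transition_counts(stream)
  rs <- rowSums(m)
  obs <- which(rs > 0)
  h <- vapply(obs, function(r) {
    p <- m[r, ] / rs[r]
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  log2(length(stream$alphabet) - 1) - mean(h)
}

#' Structure-aware surprisal
#'
#' Surprisal under an ideal observer that has already inferred the word
#' structure: 0 at within-word transitions (true TP = 1) and
#' log2(W - 1) at word boundaries.
#'
#' @param stream A `stream` with word annotations.
#' @param W Word count; defaults to the stream's lexicon size.
#' @return Numeric vector of length T - 1 (one value per transition).
#' @export
structure_aware_surprisal <- function(stream, W = NULL) {
  if (all(is.na(stream$word_position)))
    stop_ss("stream has no word annotations (position_random mode)")
  W <- W %||% length(stream$lexicon$words)
  wp <- stream$word_position[-1]
  ifelse(wp == 1L, log2(W - 1), 0)
}

#' Build the TP-decay kernel set
#'
#' Kernels are binary vectors holding two concatenated periods of the
#' TP-decay template at every cyclic lag; a binary feature sequence must
#' repeat for at least two consecutive periods to count as a pattern.
#' The default template for period `S` is one-hot (a single TP decay per
#' word), giving S kernels of length 2S with exactly two ones, e.g. for
#' S = 3: \code{[1 0 0 1 0 0]}, \code{[0 1 0 0 1 0]},
#' \code{[0 0 1 0 0 1]}.
#'
#' @param S Period (>= 2); ignored when `template` is given.
#' @param template Optional binary template of arbitrary length (may be
#'   non-uniformly periodic, e.g. `c(1, 1, 0)`).
#' @return A `kernel_set`: list of integer vectors (duplicates removed).
#' @export
make_kernels <- function(S = NULL, template = NULL) {
  if (is.null(template)) {
    if (is.null(S) || S < 2) stop_ss("S must be >= 2")
    template <- c(1L, rep(0L, S - 1L))
  }
  template <- as.integer(template != 0)
  if (!any(template == 1L)) stop_ss("all-zero kernel template")
  L <- length(template)
  kernels <- lapply(seq_len(L) - 1L, function(lag) {
    rot <- template[(seq_len(L) + lag - 1L) %% L + 1L]
    c(rot, rot)
  })
  kernels <- unique(kernels)
  structure(kernels, class = "kernel_set", k = 2L * L)
}

#' Phonological Rhythmicity Index of a binary feature vector
#'
#' Slides a window of the kernel length with stride 1 over the vector; a
#' window scores one match when it equals any kernel exactly (no double
#' counting).  PRI = matches / windows.
#'
#' @param feature_vector Binary vector (length >= kernel length).
#' @param kernels A `kernel_set` from [make_kernels()].
#' @return List with `matches`, `windows`, `pri`.
#' @export
compute_pri <- function(feature_vector, kernels) {
  k <- attr(kernels, "k")
  x <- as.integer(feature_vector != 0)
  L <- length(x)
  if (L < k) stop_ss("feature vector shorter than kernel length ", k)
  nw <- L - k + 1L
  # windows as rows; compare against each kernel at once
  win <- matrix(x[outer(seq_len(nw), seq_len(k) - 1L, `+`)], nrow = nw)
  hit <- rep(FALSE, nw)
  for (kern in kernels) {
    hit <- hit | (rowSums(win == matrix(kern, nrow = nw, ncol = k,
                                        byrow = TRUE)) == k)
  }
  list(matches = sum(hit), windows = nw, pri = sum(hit) / nw)
}

stream_feature_matrix <- function(stream) {
  lex <- stream$lexicon
  cols <- list()
  for (w in lex$words) {
    fm <- w$feature_matrix
    ids <- vapply(w$syllables, function(s) s$id, character(1))
    for (j in seq_along(ids)) cols[[ids[j]]] <- fm[, j]
  }
  missing <- setdiff(stream$tokens, names(cols))
  if (length(missing))
    stop_ss("syllable(s) without feature annotations: ",
            paste(unique(missing), collapse = ", "))
  do.call(cbind, cols[stream$tokens])
}

#' Phonological Rhythmicity Index report for a stream
#'
#' Expresses the stream as a binary matrix of phonological features
#' (rows) across syllable positions (columns), applies [compute_pri()]
#' per feature with the word-period kernel set, and reports per-feature
#' PRI and the maximum across features (the worst-case confound).
#'
#' @param stream A `stream`.
#' @param kernels Optional `kernel_set`; default uses the lexicon period.
#' @return A `pri_report`: list with `per_feature` (data frame: feature,
#'   matches, windows, pri) and `max_pri`.
#' @export
stream_pri_report <- function(stream, kernels = NULL) {
  fm <- stream_feature_matrix(stream)
  kernels <- kernels %||% make_kernels(stream$lexicon$S)
  per <- lapply(seq_len(nrow(fm)), function(r)
    compute_pri(fm[r, ], kernels))
  df <- data.frame(feature = rownames(fm),
                   matches = vapply(per, `[[`, numeric(1), "matches"),
                   windows = vapply(per, `[[`, numeric(1), "windows"),
                   pri = vapply(per, `[[`, numeric(1), "pri"),
                   stringsAsFactors = FALSE)
  structure(list(per_feature = df, max_pri = max(df$pri)),
            class = "pri_report")
}

#' @export
print.pri_report <- function(x, ...) {
  cat("<pri_report> max PRI =", format(x$max_pri, digits = 3), "\n")
  top <- x$per_feature[order(-x$per_feature$pri), ][1:min(5, nrow(x$per_feature)), ]
  for (i in seq_len(nrow(top)))
    cat("  ", top$feature[i], ": ", format(top$pri[i], digits = 3),
        "\n", sep = "")
  invisible(x)
}

#' Correlation between lexicon feature overlap and stream max-PRI
#'
#' For each lexicon, generates `n_streams` streams in `mode` (child
#' seeds) and averages their maximum PRI; returns the Pearson
#' correlation of those means with lexicon `total_overlap`.
#'
#' @param lexicons List of `lexicon`s (>= 3, spanning distinct overlaps).
#' @param n_streams Streams per lexicon.
#' @param mode Stream mode.
#' @param n_repetitions Token repetitions.
#' @param seed Integer seed.
#' @return List with `r` (NA when either variable is constant),
#'   `overlap`, `mean_max_pri`.
#' @export
overlap_pri_correlation <- function(lexicons, n_streams = 2,
                                    mode = "word_structured",
                                    n_repetitions = 15, seed = 1) {
  ov <- vapply(lexicons, function(l) l$total_overlap, numeric(1))
  mp <- vapply(seq_along(lexicons), function(i) {
    # child seeds keyed on lexicon identity, so reordering the input
    # list cannot change any lexicon's streams (permutation invariance)
    lid <- str_hash(paste(vapply(lexicons[[i]]$words, function(w) w$id,
                                 character(1)), collapse = "|"))
    pris <- vapply(seq_len(n_streams), function(k) {
      s <- generate_stream(lexicons[[i]], mode, n_repetitions,
                           seed = child_seed(seed, lid + k))
      stream_pri_report(s)$max_pri
    }, numeric(1))
    mean(pris)
  }, numeric(1))
  r <- if (var(ov) == 0 || var(mp) == 0) NA_real_ else cor(ov, mp)
  list(r = r, overlap = ov, mean_max_pri = mp)
}

#' Export a metrics report as JSON
#'
#' @param stream A `stream`.
#' @param path Output JSON path.
#' @export
write_metrics_report <- function(stream, path) {
  rep <- stream_pri_report(stream)
  tr <- info_traces(stream)
  jsonlite::write_json(
    list(mode = stream$mode,
         per_feature_pri = rep$per_feature,
         max_pri = rep$max_pri,
         tp_matrix = empirical_tp(stream),
         surprisal = tr$surprisal,
         entropy = tr$entropy,
         divergence = tr$divergence),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
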