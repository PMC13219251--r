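stream_modes <- function() c("word_structured", "position_random",
                             "position_fixed")

# Balanced complete digraph (no self-loops) on n vertices, out-degree d
# per vertex.  Base multiplicity floor(d/(n-1)) everywhere; the d mod
# (n-1) surplus edges are laid out as a circulant (offset 1..extra) in a
# seeded random relabeling of the vertices, which keeps all row and
# column sums equal to d while decorrelating structure across streams.
balanced_complete <- function(n, d) {
  if (n < 2) stop_ss("need at least 2 vertices for a TP graph")
  base <- d %/% (n - 1L)
  extra <- d %% (n - 1L)
  m <- matrix(base, n, n)
  diag(m) <- 0L
  if (extra > 0) {
    perm <- sample(n)
    for (off in seq_len(extra)) {
      src <- perm
      dst <- perm[(seq_len(n) + off - 1L) %% n + 1L]
      m[cbind(src, dst)] <- m[cbind(src, dst)] + 1L
    }
  }
  m
}

# Bipartite block (sources group -> targets group, both of size w),
# out-degree d per source, balanced column sums.
balanced_bipartite <- function(w, d) {
  base <- d %/% w
  extra <- d %% w
  m <- matrix(base, w, w)
  if (extra > 0) {
    ps <- sample(w)
    pt <- sample(w)
    for (off in seq_len(extra) - 1L) {
      src <- ps
      dst <- pt[(seq_len(w) + off - 1L) %% w + 1L]
      m[cbind(src, dst)] <- m[cbind(src, dst)] + 1L
    }
  }
  m
}

lexicon_syllable_ids <- function(lexicon) {
  lapply(lexicon$words, function(w)
    vapply(w$syllables, function(s) s$id, character(1)))
}

check_lexicon_for_streams <- function(lexicon) {
  ids <- unlist(lexicon_syllable_ids(lexicon))
  if (anyDuplicated(ids))
    stop_ss("lexicon words share syllables; stream modes require all ",
            "W x S syllables to be distinct (see assemble_lexicons(",
            "distinct_syllables = TRUE))")
  invisible(ids)
}

#' Build the transition multigraph for a stream mode
#'
#' The graph carries exactly T directed edges (T = stream length in
#' tokens), no self-loops, and equal in- and out-degree at every vertex,
#' so an Eulerian circuit exists.  Pair multiplicities within the set of
#' allowed pairs differ by at most one.
#'
#' \describe{
#'   \item{word_structured}{vertices = the W words; complete digraph;
#'     T = n_repetitions x W.}
#'   \item{position_random}{vertices = all N = W x S syllables; complete
#'     digraph; T = n_repetitions x W x S.}
#'   \item{position_fixed}{S position groups of W syllables; edges only
#'     from group p to group (p+1) mod S; each cross-group pair gets
#'     floor or ceiling of R = T / (S W^2) edges.}
#' }
#'
#' @param lexicon A `lexicon`.
#' @param mode Stream mode.
#' @param n_repetitions Repetitions of each token (default 15).
#' @param seed Integer seed (drives the surplus-edge layout).
#' @return A `transition_graph`: list with `vertices`, `mult` (N x N
#'   integer matrix), `mode`, `T`, and annotation lookups.
#' @export
build_transition_graph <- function(lexicon, mode = stream_modes(),
                                   n_repetitions = 15, seed = 1) {
  mode <- match.arg(mode)
  if (n_repetitions < 1) stop_ss("n_repetitions must be >= 1")
  W <- length(lexicon$words)
  S <- lexicon$S
  syl_ids <- lexicon_syllable_ids(lexicon)
  word_ids <- vapply(lexicon$words, function(w) w$id, character(1))
  g <- with_seed(seed, {
    if (mode == "word_structured") {
      if (W < 2) stop_ss("word_structured mode needs at least 2 words")
      mult <- balanced_complete(W, n_repetitions)
      dimnames(mult) <- list(word_ids, word_ids)
      list(vertices = word_ids, mult = mult,
           word_index = seq_len(W), word_position = rep(NA_integer_, W))
    } else {
      check_lexicon_for_streams(lexicon)
      verts <- unlist(syl_ids)
      N <- W * S
      widx <- rep(seq_len(W), each = S)
      wpos <- rep(seq_len(S), W)
      if (mode == "position_random") {
        if (N < 2) stop_ss("position_random mode needs at least 2 syllables")
        mult <- balanced_complete(N, n_repetitions)
        dimnames(mult) <- list(verts, verts)
      } else {
        mult <- matrix(0L, N, N, dimnames = list(verts, verts))
        for (p in seq_len(S)) {
          q <- p %% S + 1L
          src <- which(wpos == p)
          dst <- which(wpos == q)
          ok <- FALSE
          for (try in 1:20) {
            blk <- balanced_bipartite(W, n_repetitions)
            mult[src, dst] <- blk
            ok <- TRUE
            if (p == S) {
              # after closing the cycle, require strong connectivity
              ok <- is_strongly_connected(mult)
              if (!ok && try < 20) next
            }
            break
          }
          if (!ok) stop_ss("could not build a connected position_fixed ",
                           "graph; increase n_repetitions")
        }
      }
      list(vertices = verts, mult = mult,
           word_index = widx, word_position = wpos)
    }
  })
  mult <- g$mult
  stopifnot(all(diag(mult) == 0),
            all(rowSums(mult) == colSums(mult)))
  if (!is_strongly_connected(mult))
    stop_ss("transition graph is not strongly connected")
  structure(list(vertices = g$vertices, mult = mult, mode = mode,
                 T = sum(mult), n_repetitions = n_repetitions,
                 word_index = g$word_index,
                 word_position = g$word_position),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat("<transition_graph> ", x$mode, ": ", length(x$vertices),
      " vertices, ", x$T, " edges\n", sep = "")
  invisible(x)
}

# Greedy walk consuming rem edges from `from`, preferring the outgoing
# edge with the smallest traversal count so far (seeded random ties).
# Returns the visited vertex indices (excluding `from` itself); stops
# when stuck (at `from`, by degree balance).
greedy_walk <- function(from, rem, counts) {
  path <- integer(0)
  cur <- from
  repeat {
    cand <- which(rem[cur, ] > 0L)
    if (!length(cand)) break
    cc <- counts[cur, cand]
    best <- cand[cc == min(cc)]
    nxt <- sample_one(best)
    rem[cur, nxt] <- rem[cur, nxt] - 1L
    counts[cur, nxt] <- counts[cur, nxt] + 1L
    path <- c(path, nxt)
    cur <- nxt
  }
  list(path = path, rem = rem, counts = counts)
}

#' Walk an Eulerian circuit with the greedy minimum-count rule
#'
#' Hierholzer's algorithm: follow unused edges until stuck, then splice
#' in detours at visited vertices that still have unused out-edges.  At
#' every step the outgoing edge whose traversal count is smallest is
#' taken (seeded uniform tie-breaks), which drives empirical transition
#' counts toward uniformity from the very start of the stream.  The
#' closing return-to-start edge is dropped on emission, so a graph of T
#' edges yields T tokens and T - 1 realized transitions.
#'
#' @param graph A `transition_graph`.
#' @param seed Integer seed (start vertex and tie-breaks).
#' @return Character vector of T vertex ids.
#' @export
euler_circuit <- function(graph, seed = 1) {
  mult <- graph$mult
  if (any(rowSums(mult) != colSums(mult)))
    stop_ss("graph is not degree-balanced; no Eulerian circuit exists")
  if (!is_strongly_connected(mult))
    stop_ss("graph is not connected; no Eulerian circuit exists")
  n <- nrow(mult)
  with_seed(seed, {
    counts <- matrix(0L, n, n)
    start <- sample_one(which(rowSums(mult) > 0L))
    w <- greedy_walk(start, mult, counts)
    circuit <- c(start, w$path)
    rem <- w$rem
    counts <- w$counts
    while (sum(rem) > 0L) {
      at <- which(rowSums(rem[circuit, , drop = FALSE]) > 0L)[1]
      if (is.na(at)) stop_ss("internal error: leftover edges unreachable")
      w <- greedy_walk(circuit[at], rem, counts)
      circuit <- append(circuit, w$path, after = at)
      rem <- w$rem
      counts <- w$counts
    }
    stopifnot(circuit[1] == circuit[length(circuit)])
    graph$vertices[circuit[-length(circuit)]]
  })
}

new_stream <- function(tokens, mode, word_index, word_position, lexicon,
                       n_repetitions, seed, alphabet) {
  structure(list(tokens = tokens, mode = mode,
                 word_index = word_index, word_position = word_position,
                 lexicon = lexicon, n_repetitions = n_repetitions,
                 seed = seed, alphabet = alphabet),
            class = "stream")
}

#' @export
print.stream <- function(x, ...) {
  cat("<stream> ", x$mode, ": ", length(x$tokens), " syllables (",
      length(x$alphabet), " distinct), seed ", x$seed, "\n", sep = "")
  cat("  ", paste(head(x$tokens, 12), collapse = " "),
      if (length(x$tokens) > 12) " ..." else "", "\n", sep = "")
  invisible(x)
}

expand_word_walk <- function(walk_ids, lexicon) {
  word_ids <- vapply(lexicon$words, function(w) w$id, character(1))
  syl_ids <- lexicon_syllable_ids(lexicon)
  widx <- match(walk_ids, word_ids)
  S <- lexicon$S
  list(tokens = unlist(syl_ids[widx]),
       word_index = rep(widx, each = S),
       word_position = rep(seq_len(S), length(widx)))
}

#' Generate a TP-controlled syllable stream
#'
#' Builds the transition graph for the requested mode, walks an Eulerian
#' circuit, and (for `word_structured`) substitutes each word token by
#' its syllables, so that within-word transitional probabilities are
#' exactly 1 and boundary TPs are uniform.
#'
#' @inheritParams build_transition_graph
#' @return A `stream`: tokens (syllable ids), mode, per-token
#'   `word_index`/`word_position` annotations (NA in `position_random`),
#'   the lexicon, `n_repetitions`, and seed.
#' @export
generate_stream <- function(lexicon, mode = stream_modes(),
                            n_repetitions = 15, seed = 1) {
  mode <- match.arg(mode)
  graph <- build_transition_graph(lexicon, mode, n_repetitions,
                                  seed = child_seed(seed, 1))
  walk <- euler_circuit(graph, seed = child_seed(seed, 2))
  if (mode == "word_structured") {
    check_lexicon_for_streams(lexicon)
    ex <- expand_word_walk(walk, lexicon)
    new_stream(ex$tokens, mode, ex$word_index, ex$word_position,
               lexicon, n_repetitions, seed,
               alphabet = unlist(lexicon_syllable_ids(lexicon)))
  } else {
    idx <- match(walk, graph$vertices)
    wi <- graph$word_index[idx]
    wp <- graph$word_position[idx]
    if (mode == "position_random") {
      wi <- rep(NA_integer_, length(walk))
      wp <- rep(NA_integer_, length(walk))
    }
    new_stream(walk, mode, wi, wp, lexicon, n_repetitions, seed,
               alphabet = graph$vertices)
  }
}

# local swap repair of immediate repetitions in a token sequence
repair_repeats <- function(x, max_passes = 50) {
  n <- length(x)
  for (pass in seq_len(max_passes)) {
    bad <- which(x[-1] == x[-n]) + 1L
    if (!length(bad)) return(x)
    for (i in bad) {
      if (i <= n && x[i] == x[i - 1L]) {
        ok <- which(vapply(seq_len(n), function(j) {
          if (j == i || x[j] == x[i]) return(FALSE)
          xl <- if (j > 1) x[j - 1L] else ""
          xr <- if (j < n) x[j + 1L] else ""
          il <- x[i - 1L]
          ir <- if (i < n) x[i + 1L] else ""
          xl != x[i] && xr != x[i] && x[j] != il && x[j] != ir
        }, logical(1)))
        if (length(ok)) {
          j <- sample_one(ok)
          tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
        }
      }
    }
  }
  bad <- which(x[-1] == x[-n])
  if (length(bad)) NULL else x
}

#' Naively shuffled baseline stream
#'
#' Seeded random permutation of the same token multiset as
#' [generate_stream()] (words for `word_structured`, syllables
#' otherwise), repaired by local swaps so that no token immediately
#' repeats.  For `position_fixed` the shuffle happens within position
#' slots, so positions still cycle.  Used only as a comparison baseline:
#' its empirical boundary TPs are far more variable than Eulerian-walk
#' streams'.
#'
#' @inheritParams generate_stream
#' @param max_tries Reshuffle attempts when repair fails.
#' @export
naive_shuffle_stream <- function(lexicon, mode = stream_modes(),
                                 n_repetitions = 15, seed = 1,
                                 max_tries = 25) {
  mode <- match.arg(mode)
  W <- length(lexicon$words)
  S <- lexicon$S
  word_ids <- vapply(lexicon$words, function(w) w$id, character(1))
  syl_ids <- lexicon_syllable_ids(lexicon)
  with_seed(seed, {
    if (mode == "word_structured") {
      for (k in seq_len(max_tries)) {
        x <- repair_repeats(sample(rep(word_ids, n_repetitions)))
        if (!is.null(x)) break
      }
      if (is.null(x)) stop_ss("could not remove immediate repetitions")
      ex <- expand_word_walk(x, lexicon)
      new_stream(ex$tokens, mode, ex$word_index, ex$word_position,
                 lexicon, n_repetitions, seed, unlist(syl_ids))
    } else if (mode == "position_random") {
      check_lexicon_for_streams(lexicon)
      all_syl <- unlist(syl_ids)
      for (k in seq_len(max_tries)) {
        x <- repair_repeats(sample(rep(all_syl, n_repetitions)))
        if (!is.null(x)) break
      }
      if (is.null(x)) stop_ss("could not remove immediate repetitions")
      new_stream(x, mode, rep(NA_integer_, length(x)),
                 rep(NA_integer_, length(x)),
                 lexicon, n_repetitions, seed, all_syl)
    } else {
      check_lexicon_for_streams(lexicon)
      pos_pool <- lapply(seq_len(S), function(p)
        vapply(syl_ids, `[[`, character(1), p))
      chunks <- n_repetitions * W
      cols <- lapply(seq_len(S), function(p)
        sample(rep(pos_pool[[p]], n_repetitions)))
      x <- as.vector(t(matrix(unlist(cols), nrow = chunks)))
      all_syl <- unlist(syl_ids)
      wi <- vapply(x, function(id)
        which(vapply(syl_ids, function(s) id %in% s, logical(1)))[1],
        integer(1))
      wp <- rep(seq_len(S), chunks)
      new_stream(x, mode, wi, wp, lexicon, n_repetitions, seed, all_syl)
    }
  })
}

#' Generate streams with an optional rhythmicity bound
#'
#' Generates one stream per requested TP mode for a lexicon; any stream
#' whose maximum Phonological Rhythmicity Index exceeds
#' `max_rhythmicity` is regenerated with a fresh child seed, up to
#' `max_tries_randomize` times.  With `require_all_tp_modes`, the
#' lexicon yields no streams at all unless every requested mode passes.
#'
#' @param lexicon A `lexicon`.
#' @param tp_modes Character vector of stream modes.
#' @param n_repetitions Token repetitions.
#' @param max_rhythmicity Maximum admissible max-PRI (NULL = accept all).
#' @param max_tries_randomize Regeneration attempts per mode.
#' @param require_all_tp_modes All-or-none per lexicon.
#' @param seed Integer seed.
#' @return Named list of accepted `stream`s (possibly empty); attribute
#'   `failed_modes` lists modes that exhausted their retries.
#' @export
reject_by_rhythmicity <- function(lexicon, tp_modes = stream_modes(),
                                  n_repetitions = 15,
                                  max_rhythmicity = NULL,
                                  max_tries_randomize = 10,
                                  require_all_tp_modes = TRUE,
                                  seed = 1) {
  accepted <- list()
  failed <- character(0)
  for (mi in seq_along(tp_modes)) {
    mode <- tp_modes[mi]
    got <- NULL
    for (try in seq_len(max(1L, max_tries_randomize))) {
      s <- generate_stream(lexicon, mode, n_repetitions,
                           seed = child_seed(seed, mi * 1000L + try))
      if (is.null(max_rhythmicity) ||
          stream_pri_report(s)$max_pri <= max_rhythmicity) {
        got <- s
        break
      }
    }
    if (is.null(got)) failed <- c(failed, mode)
    else accepted[[mode]] <- got
  }
  if (require_all_tp_modes && length(failed)) accepted <- list()
  structure(accepted, failed_modes = failed)
}

#' Export a stream as CSV plus a JSON sidecar
#'
#' CSV columns: `position` (0-based), `syllable`, `word_index`,
#' `word_position`.  The sidecar carries mode, seed, n_repetitions, the
#' lexicon words, and the realized TP matrix.
#'
#' @param stream A `stream`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @export
write_stream <- function(stream, path) {
  df <- data.frame(position = seq_along(stream$tokens) - 1L,
                   syllable = stream$tokens,
                   word_index = stream$word_index,
                   word_position = stream$word_position)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  side <- list(mode = stream$mode, seed = stream$seed,
               n_repetitions = stream$n_repetitions,
               lexicon = vapply(stream$lexicon$words, function(w) w$id,
                                character(1)),
               tp_matrix = empirical_tp(stream))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
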