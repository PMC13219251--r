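#' @importFrom stats approx cor fft pnorm rmultinom runif sd var
#' @importFrom utils combn head read.csv write.csv
NULL

# Deterministic child-seed derivation: every stochastic operation in a
# pipeline run gets its own reproducible sub-stream.  Kept below 2^31 - 1.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483629L)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# sample() without the length-1 surprise
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ss <- function(...) stop(..., call. = FALSE)

# Strong connectivity of the directed support graph restricted to vertices
# that carry edges (double BFS).  Small N; no need for igraph.
is_strongly_connected <- function(adj) {
  active <- which(rowSums(adj) + colSums(adj) > 0)
  if (length(active) <= 1L) return(TRUE)
  reach <- function(a, start) {
    seen <- logical(nrow(a))
    seen[start] <- TRUE
    frontier <- start
    while (length(frontier)) {
      nxt <- which(colSums(a[frontier, , drop = FALSE] > 0) > 0)
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    seen
  }
  s <- active[1L]
  fwd <- reach(adj, s)
  bwd <- reach(t(adj), s)
  all(fwd[active]) && all(bwd[active])
}

# Monotone bucket priority queue over small non-negative integer
# priorities (pushes never carry a priority below the last pop, which
# holds for the lexicon search: a child's overlap sum >= its parent's).
# LIFO within a bucket; callers shuffle equal-priority insertions to
# randomize tie-breaking.  Used by the lazy best-first lexicon search.
bucketq_new <- function(max_prio) {
  env <- new.env(parent = emptyenv())
  env$buckets <- vector("list", max_prio + 1L)
  env$sizes <- integer(max_prio + 1L)
  env$cur <- 1L
  env$n <- 0L
  env
}

bucketq_push <- function(q, prio, item) {
  b <- prio + 1L
  q$sizes[b] <- q$sizes[b] + 1L
  if (is.null(q$buckets[[b]])) q$buckets[[b]] <- vector("list", 4L)
  if (q$sizes[b] > length(q$buckets[[b]]))  # grow by doubling
    q$buckets[[b]] <- c(q$buckets[[b]],
                        vector("list", length(q$buckets[[b]])))
  q$buckets[[b]][[q$sizes[b]]] <- item
  if (b < q$cur) q$cur <- b
  q$n <- q$n + 1L
  invisible(q)
}

bucketq_pop <- function(q) {
  while (q$cur <= length(q$sizes) && q$sizes[q$cur] == 0L)
    q$cur <- q$cur + 1L
  if (q$cur > length(q$sizes)) return(NULL)
  b <- q$cur
  item <- q$buckets[[b]][[q$sizes[b]]]
  q$buckets[[b]][q$sizes[b]] <- list(NULL)
  q$sizes[b] <- q$sizes[b] - 1L
  q$n <- q$n - 1L
  item
}

bucketq_size <- function(q) q$n
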