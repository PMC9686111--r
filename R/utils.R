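# Small internal helpers shared across modules.

# Sigmoid endpoint weight used everywhere a segment's information is
# discounted near its ends: w(d) = 1 / (1 + exp(-slope * (d - d0))).
sigmoid_weight <- function(d, d0 = 1.0, slope = 4.0) {
  1 / (1 + exp(-slope * (d - d0)))
}

# Maximal runs of TRUE in a logical vector; returns matrix with columns
# start, end (1-based, closed). Zero-row matrix when no TRUE present.
true_runs <- function(x) {
  n <- length(x)
  if (n == 0L) return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Union-find over 1..n (path compression, union by size).
uf_new <- function(n) list(parent = seq_len(n), size = rep(1L, n))

uf_find <- function(uf, i) {
  p <- uf$parent
  root <- i
  while (p[root] != root) root <- p[root]
  while (p[i] != root) { nxt <- p[i]; p[i] <- root; i <- nxt }
  uf$parent <- p
  list(uf = uf, root = root)
}

uf_union <- function(uf, i, j) {
  fi <- uf_find(uf, i); uf <- fi$uf
  fj <- uf_find(uf, j); uf <- fj$uf
  a <- fi$root; b <- fj$root
  if (a == b) return(uf)
  if (uf$size[a] < uf$size[b]) { tmp <- a; a <- b; b <- tmp }
  uf$parent[b] <- a
  uf$size[a] <- uf$size[a] + uf$size[b]
  uf
}

# Component labels 1..k (in order of first appearance) for n nodes under an
# edge list (2-column matrix of node indices).
components_from_edges <- function(n, edges) {
  uf <- uf_new(n)
  if (length(edges) && nrow(edges)) {
    for (e in seq_len(nrow(edges))) uf <- uf_union(uf, edges[e, 1L], edges[e, 2L])
  }
  roots <- integer(n)
  for (i in seq_len(n)) { f <- uf_find(uf, i); uf <- f$uf; roots[i] <- f$root }
  match(roots, unique(roots))
}

# Run `expr` under a temporary RNG seed without disturbing the caller's
# random stream. seed = NULL leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
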