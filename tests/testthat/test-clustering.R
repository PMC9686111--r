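# Fragments data.frame in the shape build_subclusters expects.
frag_df <- function(other_id, start, end, panel, side = 1L, seg_row = seq_along(start)) {
  n <- length(start)
  data.frame(seg_row = seg_row, other_id = other_id, chrom = rep("1", n),
             start = start, end = end, cm = panel$cm[end] - panel$cm[start],
             side = rep_len(side, n), kept = rep(TRUE, n),
             stringsAsFactors = FALSE)
}

test_that("subcluster membership follows the weighted overlap threshold", {
  # two long fragments; the individuals are homozygous at exactly n shared
  # proband-het sites deep inside both fragments (weights ~ 1 there)
  panel <- dense_panel(601, spacing_cm = 0.1)  # 60 cM
  build <- function(n_shared) {
    proband <- rep(0L, 601)
    shared <- 300L + seq_len(n_shared)
    proband[shared] <- 1L
    # both individuals hom-ref everywhere: informative (doubly homozygous)
    # exactly at the proband's het sites
    g <- gm(list(P = proband, i1 = rep(0L, 601), i2 = rep(0L, 601)), panel)
    asn <- list(fragments = frag_df(c("i1", "i2"), c(1L, 101L), c(500L, 601L), panel))
    build_subclusters(g, "P", asn)
  }
  same <- build(12)
  expect_equal(same$n_subclusters, 1L)
  split <- build(8)
  expect_equal(split$n_subclusters, 2L)
  empty <- build_subclusters(gm(list(P = rep(0L, 601)), panel), "P",
                             list(fragments = frag_df(character(0), integer(0),
                                                      integer(0), panel)))
  expect_equal(empty$n_subclusters, 0L)
})

test_that("connections join subclusters through multi-segment individuals", {
  panel <- dense_panel(100, spacing_cm = 0.5)
  fr <- frag_df(c("C", "C", "D"), c(1L, 50L, 1L), c(20L, 70L, 20L), panel,
                side = c(1L, 2L, 1L))
  fr$subcluster <- c(1L, 2L, 1L)
  e <- build_connection_graph(fr, shared_cm = c(C = 30, D = 12))
  expect_equal(nrow(e), 1L)
  expect_equal(e$weight, 30)
  expect_equal(e$parity, 1L)  # C sits on opposite local sides
  # an individual spanning three subclusters contributes three edges
  fr3 <- frag_df(rep("E", 3), c(1L, 40L, 80L), c(20L, 60L, 100L), panel)
  fr3$subcluster <- 1:3
  e3 <- build_connection_graph(fr3, shared_cm = c(E = 25))
  expect_equal(nrow(e3), 3L)
  expect_true(all(e3$parity == 0L))
  # individuals confined to one subcluster give an edgeless graph
  fr1 <- frag_df(c("C", "D"), c(1L, 1L), c(20L, 30L), panel)
  fr1$subcluster <- c(1L, 1L)
  expect_equal(nrow(build_connection_graph(fr1, c(C = 10, D = 10))), 0L)
})

test_that("orientation scoring satisfies edge parity and flip identities", {
  edges <- data.frame(i = 1L, j = 2L, parity = 0L, weight = 7, other_id = "x")
  expect_equal(score_orientation(edges, c(0L, 0L)), 7)   # same side satisfied
  expect_equal(score_orientation(edges, c(0L, 1L)), 0)
  set.seed(19)
  for (r in 1:10) {
    e <- random_connection_graph(6, 12)
    o <- sample(0:1, 6, replace = TRUE)
    # global flip symmetry
    expect_equal(score_orientation(e, o), score_orientation(e, 1L - o))
    # single-flip identity: the delta is the node's unsatisfied-minus-
    # satisfied incident weight
    v <- sample(6, 1)
    o2 <- o; o2[v] <- 1L - o2[v]
    inc <- e$i == v | e$j == v
    sat <- (o[e$i] != o[e$j]) == (e$parity == 1L)
    expect_equal(score_orientation(e, o2) - score_orientation(e, o),
                 sum(e$weight[inc & !sat]) - sum(e$weight[inc & sat]))
  }
})

test_that("greedy restarts find the planted and exhaustive optima", {
  # consistent planted component: all edges satisfiable simultaneously
  set.seed(29)
  truth <- sample(0:1, 3, replace = TRUE)
  edges <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                      parity = as.integer(c(truth[1] != truth[2],
                                            truth[1] != truth[3],
                                            truth[2] != truth[3])),
                      weight = c(10, 20, 30), other_id = c("a", "b", "c"))
  sc <- phase_superclusters(edges, 3L, ibd_phase_control(restarts = 50, seed = 1))
  expect_equal(score_orientation(edges, sc$orientation), 60)
  expect_true(all(sc$orientation == truth) || all(sc$orientation == 1L - truth))
  # random graphs: greedy-with-restarts equals the exhaustive optimum
  for (r in 1:5) {
    n <- sample(4:8, 1)
    e <- random_connection_graph(n, 3 * n)
    sc <- phase_superclusters(e, n, ibd_phase_control(restarts = 300, seed = r))
    expect_equal(score_orientation(e, sc$orientation),
                 exhaustive_best_score(e, n))
  }
  # edgeless graph: singleton superclusters
  sc0 <- phase_superclusters(random_connection_graph(3, 0)[0, ], 3L,
                             ibd_phase_control(restarts = 10, seed = 2))
  expect_equal(sc0$component, 1:3)
  expect_false(any(sc0$pruned))
})

test_that("supercluster phasing is reproducible under a fixed seed", {
  set.seed(43)
  e <- random_connection_graph(8, 20)
  a <- phase_superclusters(e, 8L, ibd_phase_control(restarts = 100, seed = 9))
  b <- phase_superclusters(e, 8L, ibd_phase_control(restarts = 100, seed = 9))
  expect_identical(a, b)
})

test_that("pruning removes weakly connected subclusters, cascading", {
  mk_edges <- function(pairs) {
    data.frame(i = pairs[, 1], j = pairs[, 2], parity = 0L, weight = 1,
               other_id = sprintf("x%d", seq_len(nrow(pairs))))
  }
  # node 4 hangs off a triangle by 2 connections: pruned; triangle nodes
  # have 3+ connections (2 triangle edges + duplicated edge): construct
  tri <- rbind(c(1, 2), c(1, 2), c(1, 3), c(1, 3), c(2, 3), c(2, 3),
               c(3, 4), c(3, 4))
  pr <- prune_superclusters(mk_edges(tri), comp = rep(1L, 4), min_connections = 3)
  expect_equal(pr, c(FALSE, FALSE, FALSE, TRUE))
  # a subcluster with exactly 3 connections is retained
  three <- rbind(c(1, 2), c(1, 2), c(1, 2))
  expect_equal(prune_superclusters(mk_edges(three), rep(1L, 2), 3),
               c(FALSE, FALSE))
  # chain with single connections: everything cascades away
  chain <- rbind(c(1, 2), c(2, 3))
  expect_equal(prune_superclusters(mk_edges(chain), rep(1L, 3), 3),
               rep(TRUE, 3))
  # singleton components are never pruned
  expect_equal(prune_superclusters(mk_edges(chain)[0, ], 1:3, 3), rep(FALSE, 3))
})
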