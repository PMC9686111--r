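# Shared fixtures and independent reference implementations used as test
# oracles. These deliberately re-derive results with plain per-site loops,
# not the package's vectorised/bitwise code paths.

# Single-chromosome panel with uniform spacing.
dense_panel <- function(n_sites, spacing_cm = 0.02, chrom = "1") {
  site_panel(chrom = rep(chrom, n_sites),
             pos = seq_len(n_sites) * 1000L,
             cm = (seq_len(n_sites) - 1L) * spacing_cm)
}

# genotype_matrix from a named list of call vectors.
gm <- function(calls, panel) {
  genotype_matrix(do.call(rbind, calls), panel)
}

# Naive per-site IBD scan: walks every site, closing a candidate run at
# each opposite-homozygote conflict, then applies the length and density
# rules gap by gap.
naive_ibd_reference <- function(g, a = rownames(g$calls)[1L],
                                b = rownames(g$calls)[2L],
                                min_cm = 8, min_trimmed = 5, max_gap = 0.05) {
  va <- g$calls[a, ]; vb <- g$calls[b, ]
  panel <- g$sites
  rows <- list()
  for (cc in unique(panel$chrom)) {
    ix <- which(panel$chrom == cc)
    run_start <- NA_integer_
    prev <- NA_integer_
    close_run <- function(s, e) {
      if (is.na(s)) return()
      cml <- panel$cm[e] - panel$cm[s]
      gaps <- if (e > s) diff(panel$cm[s:e]) else numeric(0)
      trm <- sum(gaps[gaps <= max_gap])
      if (cml >= min_cm && trm >= min_trimmed)
        rows[[length(rows) + 1L]] <<- data.frame(
          chrom = cc, start = s, end = e, cm_length = cml, trimmed_cm = trm,
          stringsAsFactors = FALSE)
    }
    for (i in ix) {
      conflict <- !is.na(va[i]) && !is.na(vb[i]) &&
        ((va[i] == 0L && vb[i] == 2L) || (va[i] == 2L && vb[i] == 0L))
      if (conflict) {
        close_run(run_start, prev)
        run_start <- NA_integer_
      } else if (is.na(run_start)) run_start <- i
      prev <- i
    }
    close_run(run_start, prev)
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      cm_length = numeric(0), trimmed_cm = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Exhaustive optimum of the supercluster objective over all 2^n
# orientations (n = number of subclusters referenced by the edges).
exhaustive_best_score <- function(edges, n) {
  best <- -Inf
  for (mask in 0:(2^n - 1L)) {
    o <- as.integer(intToBits(mask))[seq_len(n)]
    s <- score_orientation(edges, o)
    if (s > best) best <- s
  }
  best
}

# Random connection graph for optimiser tests.
random_connection_graph <- function(n, n_edges) {
  i <- sample(n, n_edges, replace = TRUE)
  j <- sample(n, n_edges, replace = TRUE)
  keep <- i != j
  data.frame(i = pmin(i, j)[keep], j = pmax(i, j)[keep],
             parity = sample(0:1, sum(keep), replace = TRUE),
             weight = round(stats::runif(sum(keep), 5, 50), 1),
             other_id = sprintf("x%d", seq_len(sum(keep))),
             stringsAsFactors = FALSE)
}

# Total weighted group-change cost of a fixed orientation sequence over the
# proband's het sites, replayed per site with the same assignment rule as
# the scan (first eligible informative site assigns; later disagreement
# at an eligible site costs that site's weight and moves the segment).
orientation_cost <- function(o_seq, entries, n_seg, min_w) {
  side <- integer(n_seg)
  cost <- 0
  for (j in seq_along(o_seq)) {
    rows <- which(entries$j == j & entries$w >= min_w)
    for (r in rows) {
      implied <- if (entries$allele[r] == o_seq[j]) 1L else 2L
      s <- entries$seg[r]
      if (side[s] == 0L) side[s] <- implied
      else if (side[s] != implied) { cost <- cost + entries$w[r]; side[s] <- implied }
    }
  }
  cost
}

# Constructed trio case: proband heterozygous everywhere, one parent
# homozygous at every site, so every site is trio-resolvable and the
# maternal allele is known exactly.
eval_fixture <- function(n = 100, spacing = 0.05, seed = 1) {
  set.seed(seed)
  panel <- dense_panel(n, spacing_cm = spacing)
  maternal <- sample(0:1, n, replace = TRUE)
  list(panel = panel, maternal = maternal,
       truth = trio_truth(proband_calls = rep(1L, n),
                          mother_calls = 2L * maternal,
                          father_calls = 2L * (1L - maternal)),
       perfect = list(hapA = maternal, hapB = 1L - maternal))
}

# Hand-built run summary in the shape extract_features and the confidence
# fallback expect: ten one-segment individuals on one supercluster, two of
# them with fragments on both global sides.
fake_fit <- function() {
  panel <- dense_panel(1001, spacing_cm = 0.1)  # 100 cM
  segments <- data.frame(proband_id = "P", other_id = sprintf("i%02d", 1:10),
                         chrom = "1", start = 1L, end = 501L,
                         cm_length = 50, trimmed_cm = 50, stringsAsFactors = FALSE)
  fr <- data.frame(seg_row = c(1:10, 9L, 10L),
                   other_id = sprintf("i%02d", c(1:10, 9:10)),
                   chrom = "1", start = c(rep(1L, 10), 251L, 251L),
                   end = c(rep(250L, 10), 501L, 501L),
                   cm = c(rep(24.9, 10), 25, 25),
                   side = 1L, kept = TRUE,
                   global_side = c(rep(1L, 10), 2L, 2L),
                   component = 1L, subcluster = c(rep(1L, 10), 2L, 2L),
                   pruned = FALSE, stringsAsFactors = FALSE)
  list(proband = "P", panel = panel, segments = segments, fragments = fr,
       largest_sc = 1L,
       family = list(graph = list(nodes = character(0),
                                  edges = data.frame(a = character(0),
                                                     b = character(0)))))
}

# Standard dense-coverage simulation used by several end-to-end tests.
dense_sim <- function(seed, n_chrom = 8, chrom_cm = 80, spacing = 0.025,
                      n_aunts = 4, n_cousins = 3, n_unrelated = 8) {
  panel <- sim_map(n_chrom = n_chrom, chrom_cm = chrom_cm, spacing_cm = spacing)
  sim_database(panel, n_aunts_per_side = n_aunts,
               n_cousins_per_aunt = n_cousins, n_unrelated = n_unrelated,
               seed = seed)
}
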