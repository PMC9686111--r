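# Subclusters and superclusters. A subcluster is a connected block of
# segment fragments that overlap each other well enough (weighted count of
# proband-het, doubly-homozygous sites) that their relative parental
# grouping is trustworthy. Subclusters are then aligned genome-wide into
# superclusters through database individuals that share IBD in several
# subclusters, by maximising the weight of connections kept on one parent.

#' Build subclusters of mutually overlapping fragments
#'
#' Two retained fragments are linked when the weighted count of sites that
#' are heterozygous in the proband and homozygous in both segments reaches
#' `min_weighted_overlap` (each site contributes the product of the two
#' fragments' endpoint weights); subclusters are the connected components
#' of this relation.
#'
#' @param g A [genotype_matrix()].
#' @param proband Proband ID.
#' @param assignment A [assign_parental_groups()] result.
#' @param control An [ibd_phase_control()].
#' @return The assignment's `fragments` data.frame (retained rows only)
#'   with a `subcluster` column, as list element `fragments`, plus
#'   `n_subclusters`.
#' @export
build_subclusters <- function(g, proband, assignment,
                              control = ibd_phase_control()) {
  panel <- g$sites
  gp <- g$calls[proband, ]
  frags <- assignment$fragments[assignment$fragments$kept, , drop = FALSE]
  rownames(frags) <- NULL
  frags$subcluster <- rep(NA_integer_, nrow(frags))
  next_id <- 0L
  for (cc in unique(frags$chrom)) {
    rows <- which(frags$chrom == cc)
    ix <- which(panel$chrom == cc)
    het_idx <- ix[!is.na(gp[ix]) & gp[ix] == 1L]
    nh <- length(het_idx)
    nf <- length(rows)
    if (nh == 0L || nf == 0L) { ids <- seq_len(nf); }
    else {
      Wm <- matrix(0, nrow = nh, ncol = nf)
      for (k in seq_len(nf)) {
        f <- frags[rows[k], ]
        jlo <- findInterval(f$start - 1L, het_idx) + 1L
        jhi <- findInterval(f$end, het_idx)
        if (jlo > jhi) next
        hets <- het_idx[jlo:jhi]
        oc <- g$calls[f$other_id, hets]
        hom <- !is.na(oc) & oc != 1L
        if (!any(hom)) next
        hh <- hets[hom]
        d <- pmin(panel$cm[hh] - panel$cm[f$start], panel$cm[f$end] - panel$cm[hh])
        Wm[(jlo:jhi)[hom], k] <- sigmoid_weight(d, control$weight_d0, control$weight_slope)
      }
      ov <- crossprod(Wm)
      adj <- which(ov >= control$min_weighted_overlap & row(ov) < col(ov), arr.ind = TRUE)
      ids <- components_from_edges(nf, adj)
    }
    frags$subcluster[rows] <- next_id + ids
    next_id <- next_id + max(ids, 0L)
  }
  list(fragments = frags, n_subclusters = next_id)
}

#' Build the subcluster connection graph
#'
#' For every database individual with fragments in two or more subclusters,
#' one edge is added per subcluster pair. The edge's parity records whether
#' the individual's fragments sit on matching local sides (so the
#' orientations of the two subclusters should align) and its weight is the
#' individual's total cM shared with the proband.
#'
#' @param fragments Subclustered fragments ([build_subclusters()] output).
#' @param shared_cm Named numeric: total proband-shared cM per individual.
#' @return data.frame of edges: `i`, `j` (subcluster ids, `i < j`),
#'   `parity` (0 = same local side, 1 = opposite), `weight`, `other_id`.
#' @export
build_connection_graph <- function(fragments, shared_cm) {
  empty <- data.frame(i = integer(0), j = integer(0), parity = integer(0),
                      weight = numeric(0), other_id = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(fragments)) return(empty)
  # majority-cM side of each (individual, subcluster)
  key <- paste(fragments$other_id, fragments$subcluster, fragments$side)
  cmsum <- tapply(fragments$cm, key, sum)
  parts <- do.call(rbind, strsplit(names(cmsum), " "))
  ps <- data.frame(other_id = parts[, 1L], subcluster = as.integer(parts[, 2L]),
                   side = as.integer(parts[, 3L]), cm = as.numeric(cmsum),
                   stringsAsFactors = FALSE)
  ps <- ps[order(ps$other_id, ps$subcluster, -ps$cm), ]
  ps <- ps[!duplicated(ps[, c("other_id", "subcluster")]), ]
  edges <- list()
  for (id in unique(ps$other_id)) {
    sub <- ps[ps$other_id == id, , drop = FALSE]
    if (nrow(sub) < 2L) next
    pr <- utils::combn(seq_len(nrow(sub)), 2L)
    edges[[id]] <- data.frame(
      i = sub$subcluster[pr[1L, ]], j = sub$subcluster[pr[2L, ]],
      parity = as.integer(sub$side[pr[1L, ]] != sub$side[pr[2L, ]]),
      weight = unname(shared_cm[id]), other_id = id, stringsAsFactors = FALSE)
  }
  if (!length(edges)) return(empty)
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  swap <- out$i > out$j
  tmp <- out$i[swap]; out$i[swap] <- out$j[swap]; out$j[swap] <- tmp
  out
}

#' Score a subcluster orientation
#'
#' Sum of the weights of connections whose parity is satisfied: an edge is
#' satisfied when `xor(orientation[i], orientation[j]) == parity`.
#'
#' @param edges Connection edges ([build_connection_graph()] output).
#' @param orientation Integer 0/1 per subcluster id.
#' @return Total satisfied weight.
#' @export
score_orientation <- function(edges, orientation) {
  if (!nrow(edges)) return(0)
  sat <- (orientation[edges$i] != orientation[edges$j]) == (edges$parity == 1L)
  sum(edges$weight[sat])
}

# Greedy local search on one component: repeatedly flip the single
# subcluster with the largest positive score gain (ties: lowest id).
greedy_component <- function(nodes, edges, orientation) {
  key <- as.character(nodes)
  ei <- as.character(edges$i); ej <- as.character(edges$j)
  gain <- stats::setNames(numeric(length(nodes)), key)
  sat <- (orientation[ei] != orientation[ej]) == (edges$parity == 1L)
  contrib <- ifelse(sat, -edges$weight, edges$weight)
  for (e in seq_along(contrib)) {
    gain[ei[e]] <- gain[ei[e]] + contrib[e]
    gain[ej[e]] <- gain[ej[e]] + contrib[e]
  }
  repeat {
    m <- max(gain)
    if (m <= 1e-12) break
    v <- key[which(gain == m)[1L]]   # ties: lowest subcluster id
    orientation[v] <- 1L - orientation[v]
    inc <- which(ei == v | ej == v)
    for (e in inc) {
      sat[e] <- !sat[e]
      d <- if (sat[e]) -2 * edges$weight[e] else 2 * edges$weight[e]
      other <- if (ei[e] == v) ej[e] else ei[e]
      gain[other] <- gain[other] + d
    }
    gain[v] <- -gain[v]
  }
  orientation
}

#' Phase subclusters into superclusters
#'
#' Connected components of the connection graph are optimised separately:
#' random initial orientations, then greedy single-subcluster flips until no
#' flip improves the satisfied connection weight, repeated over
#' `control$restarts` random restarts; the best-scoring orientation is kept.
#' Edgeless subclusters form singleton superclusters.
#'
#' @param edges Connection edges.
#' @param n_subclusters Number of subclusters.
#' @param control An [ibd_phase_control()] (`restarts`, `seed`,
#'   `min_connections`).
#' @return List of class `"superclusters"`: `component` (per subcluster),
#'   `orientation` (0/1 per subcluster: 1 means the subcluster's local side
#'   1 maps to global side 2), `score` (per component), `pruned` (logical
#'   per subcluster: dropped from its supercluster's confident core),
#'   `largest` (component id with most member fragments is filled in by
#'   the caller; here, most subclusters).
#' @export
phase_superclusters <- function(edges, n_subclusters,
                                control = ibd_phase_control()) {
  comp <- components_from_edges(n_subclusters,
                                cbind(edges$i, edges$j))
  orientation <- integer(n_subclusters)
  score <- numeric(max(comp, 0L))
  with_seed(control$seed, {
    for (cid in seq_len(max(comp, 0L))) {
      nodes <- which(comp == cid)
      if (length(nodes) == 1L) next
      ce <- edges[edges$i %in% nodes, , drop = FALSE]
      best <- NULL; best_score <- -Inf
      for (r in seq_len(control$restarts)) {
        o <- stats::setNames(sample(0:1, length(nodes), replace = TRUE), nodes)
        o <- greedy_component(nodes, ce, o)
        s <- score_orientation(ce, oo_vec(o, n_subclusters))
        if (s > best_score) { best_score <- s; best <- o }
      }
      orientation[nodes] <- unname(best[as.character(nodes)])
      score[cid] <- best_score
    }
  })
  pruned <- prune_superclusters(edges, comp, control$min_connections)
  structure(list(component = comp, orientation = orientation, score = score,
                 pruned = pruned),
            class = "superclusters")
}

# orientation named by node -> dense 0/1 vector over all subclusters
oo_vec <- function(o, n) {
  v <- integer(n)
  v[as.integer(names(o))] <- unname(o)
  v
}

#' Prune weakly connected subclusters
#'
#' Iteratively removes from each supercluster any subcluster with fewer
#' than `min_connections` connections (individual-pair edges) to the
#' remaining members. Pruning restricts the confident labelling only; the
#' genome-wide phase uses all subclusters.
#'
#' @param edges Connection edges.
#' @param comp Component id per subcluster.
#' @param min_connections Minimum connection count.
#' @return Logical vector: `TRUE` where the subcluster was pruned.
#' @export
prune_superclusters <- function(edges, comp, min_connections = 3L) {
  n <- length(comp)
  active <- rep(TRUE, n)
  # singleton components are never pruned (nothing to be connected to)
  multi <- comp %in% comp[duplicated(comp)]
  repeat {
    deg <- integer(n)
    keep <- if (nrow(edges)) active[edges$i] & active[edges$j] else logical(0)
    if (any(keep)) {
      deg <- tabulate(edges$i[keep], n) + tabulate(edges$j[keep], n)
    }
    drop <- active & multi & deg < min_connections
    if (!any(drop)) break
    active[drop] <- FALSE
  }
  !active
}
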