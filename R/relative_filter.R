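# Close-family screening. Individuals who may descend from both of the
# proband's parents (full siblings, nephews/nieces, grandchildren, and
# identical twins) share IBD on both sides of the family and would corrupt
# the parental-group separation, so their segments are discarded before
# phasing.

#' Select close relatives
#'
#' Database individuals whose total detected sharing with the proband
#' reaches `threshold_cm` (close enough that any individual related to both
#' parents will share detectable IBD with every other close relative).
#'
#' @param stats data.frame of [relationship_stats()] rows.
#' @param threshold_cm Total-sharing threshold in cM.
#' @return Character vector of individual IDs.
#' @export
select_close_relatives <- function(stats, threshold_cm = 400) {
  stats$other_id[stats$total_shared_cm >= threshold_cm]
}

#' Classify a close relationship
#'
#' Identical twin: at least `twin_ibd2_frac` (default 90%) of the genome in
#' IBD2 runs. Full sibling: total sharing of at least `sib_total_cm`
#' (default 1300 cM), IBD2-run coverage of at least `sib_ibd2_frac`
#' (default 9% -- full siblings expect ~25%), and genome-wide IBD1 rate
#' below `sib_ibd1_max` (default 99%; parent-child pairs share an allele
#' essentially everywhere and must not be called siblings). Everything
#' else, including parents, grandparents, aunts and cousins, is `other`.
#'
#' @param stats data.frame of [relationship_stats()] rows.
#' @param control An [ibd_phase_control()].
#' @return Character vector: `"identical_twin"`, `"full_sibling"` or
#'   `"other"` per row of `stats`.
#' @export
classify_relationship <- function(stats, control = ibd_phase_control()) {
  ifelse(stats$ibd2_run_fraction >= control$twin_ibd2_frac, "identical_twin",
  ifelse(stats$total_shared_cm >= control$sib_total_cm &
         stats$ibd2_run_fraction >= control$sib_ibd2_frac &
         stats$ibd1_rate < control$sib_ibd1_max, "full_sibling", "other"))
}

#' Build the close-family graph
#'
#' Nodes are the close relatives; an edge joins two of them when they share
#' at least one detected IBD segment with each other.
#'
#' @param g A [genotype_matrix()] containing the close relatives.
#' @param ids Close-relative IDs (from [select_close_relatives()]).
#' @param control An [ibd_phase_control()].
#' @return List with `nodes` and `edges` (two-column data.frame `a`, `b`).
#' @export
close_family_graph <- function(g, ids, control = ibd_phase_control()) {
  edges <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      seg <- detect_ibd_segments(g, ids[i], ids[(i + 1L):length(ids)], control)
      if (nrow(seg))
        edges[[i]] <- data.frame(a = ids[i], b = unique(seg$other_id),
                                 stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  list(nodes = ids, edges = edges)
}

#' Discard unreliable close relatives
#'
#' Removes identical twins and full siblings, and any close relative that
#' shares IBD with every other close relative (a candidate descendant of
#' both parents) -- provided at least two other close relatives exist, since
#' with fewer the all-others adjacency test is vacuous and would throw away
#' the most useful relatives.
#'
#' @param graph A [close_family_graph()].
#' @param classes Classifications per node, aligned with `graph$nodes`.
#' @return data.frame `id`, `reason` for every discarded individual.
#' @export
discard_unreliable <- function(graph, classes) {
  nodes <- graph$nodes
  out <- data.frame(id = character(0), reason = character(0), stringsAsFactors = FALSE)
  if (!length(nodes)) return(out)
  tw <- nodes[classes == "identical_twin"]
  sb <- nodes[classes == "full_sibling"]
  deg <- table(factor(c(graph$edges$a, graph$edges$b), levels = nodes))
  desc <- if (length(nodes) >= 3L) nodes[deg == length(nodes) - 1L] else character(0)
  desc <- setdiff(desc, c(tw, sb))
  rbind(out,
        data.frame(id = tw, reason = rep("identical_twin", length(tw)), stringsAsFactors = FALSE),
        data.frame(id = sb, reason = rep("full_sibling", length(sb)), stringsAsFactors = FALSE),
        data.frame(id = desc, reason = rep("descendant_candidate", length(desc)),
                   stringsAsFactors = FALSE))
}

#' Screen close family and drop unreliable IBD
#'
#' Computes IBD2 runs and relationship statistics for every close-relative
#' candidate, classifies them, builds the close-family graph, and removes
#' all IBD segments of discarded individuals.
#'
#' @param g A [genotype_matrix()].
#' @param proband Proband ID.
#' @param segments Detected IBD segments (proband vs database).
#' @param control An [ibd_phase_control()].
#' @return List: `segments` (kept), `discarded` (id/reason data.frame),
#'   `graph`, `close_stats` (per-close-relative statistics with a `class`
#'   column).
#' @export
filter_relatives <- function(g, proband, segments, control = ibd_phase_control()) {
  totals <- tapply(segments$cm_length, segments$other_id, sum)
  close <- names(totals)[totals >= control$close_cm]
  if (!length(close)) {
    return(list(segments = segments,
                discarded = data.frame(id = character(0), reason = character(0)),
                graph = list(nodes = character(0),
                             edges = data.frame(a = character(0), b = character(0))),
                close_stats = NULL))
  }
  stats <- do.call(rbind, lapply(close, function(id) {
    runs <- detect_ibd2_runs(g, proband, id, control)
    relationship_stats(g, proband, id,
                       segments[segments$other_id == id, , drop = FALSE], runs)
  }))
  stats$class <- classify_relationship(stats, control)
  graph <- close_family_graph(g, close, control)
  disc <- discard_unreliable(graph, stats$class[match(graph$nodes, stats$other_id)])
  list(segments = segments[!segments$other_id %in% disc$id, , drop = FALSE],
       discarded = disc, graph = graph, close_stats = stats)
}
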