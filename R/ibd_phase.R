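#' Genome-wide IBD phasing of a proband
#'
#' Runs the full pipeline: IBD and IBD2 detection against the database by
#' opposite-homozygote exclusion, close-family screening (identical twins,
#' full siblings and candidate descendants of both parents are discarded),
#' separation of segments into two parental groups per chromosome,
#' subclustering of mutually overlapping fragments, genome-wide alignment
#' of subclusters into superclusters by greedy optimisation with random
#' restarts, and emission of two genome-wide haplotypes with IBD-based
#' imputation and error correction, defaulting to the pre-phase where IBD
#' is uninformative.
#'
#' @param g A [genotype_matrix()] holding the proband and the database,
#'   with cM-annotated panel (see [apply_genetic_map()]).
#' @param proband Proband ID (row of `g`).
#' @param db_ids Database individual IDs; default all rows except the
#'   proband.
#' @param pre Optional [prephase()]; default a trivial frequency-based
#'   pre-phase ([make_prephase()]) seeded from `control$seed`.
#' @param segments Optional precomputed IBD segments (as returned by
#'   [detect_ibd_segments()]); detected when `NULL`.
#' @param detect_sites Optional integer vector of panel site indices to
#'   restrict IBD detection to (phasing still uses every site). Useful when
#'   genotype errors would otherwise break segments at the sites under
#'   study.
#' @param control An [ibd_phase_control()].
#' @return An object of class `"ibd_phase"`; see Details.
#' @details The returned object contains `phased` (a `phased_genome`:
#'   haplotypes `hapA`/`hapB`, per-site provenance, corrections log),
#'   `segments` (post-filter), `family` (close-family report), `assignment`
#'   (fragments, breakpoints, ignored sites, per-het-site orientation),
#'   `fragments` (retained fragments with `subcluster`, `component`,
#'   `global_side`, `pruned`), `superclusters`, `largest_sc`, `features`
#'   (confidence features) and `control`.
#' @seealso [evaluate_phase()], [extract_features()], [write_phased_vcf()]
#' @export
ibd_phase <- function(g, proband, db_ids = NULL, pre = NULL, segments = NULL,
                      detect_sites = NULL, control = ibd_phase_control()) {
  panel <- g$sites
  if (anyNA(panel$cm)) stop("panel has no genetic positions; apply a genetic map first")
  if (!proband %in% rownames(g$calls)) stop("unknown proband: ", proband)
  if (is.null(db_ids)) db_ids <- setdiff(rownames(g$calls), proband)
  if (is.null(pre)) pre <- make_prephase(g, proband, seed = control$seed)

  if (is.null(segments)) {
    if (is.null(detect_sites)) {
      segments <- detect_ibd_segments(g, proband, db_ids, control)
    } else {
      ds <- sort(unique(as.integer(detect_sites)))
      sub <- genotype_matrix(g$calls[, ds, drop = FALSE], panel[ds, ])
      segments <- detect_ibd_segments(sub, proband, db_ids, control)
      segments$start <- ds[segments$start]
      segments$end <- ds[segments$end]
    }
  }

  fam <- filter_relatives(g, proband, segments, control)
  segments <- fam$segments

  assignment <- assign_parental_groups(g, proband, segments, pre, control)
  subc <- build_subclusters(g, proband, assignment, control)
  shared_cm <- tapply(segments$cm_length, segments$other_id, sum)
  edges <- build_connection_graph(subc$fragments, shared_cm)
  sc <- phase_superclusters(edges, subc$n_subclusters, control)

  fragments <- subc$fragments
  if (nrow(fragments)) {
    ori <- sc$orientation[fragments$subcluster]
    fragments$global_side <- ifelse(ori == 1L, 3L - fragments$side, fragments$side)
    fragments$component <- sc$component[fragments$subcluster]
    fragments$pruned <- sc$pruned[fragments$subcluster]
  } else {
    fragments$global_side <- integer(0)
    fragments$component <- integer(0)
    fragments$pruned <- logical(0)
  }
  largest_sc <- if (nrow(fragments)) {
    as.integer(names(which.max(table(fragments$component))))
  } else NA_integer_

  phased <- phase_genome(g, proband, fragments, pre, control)

  fit <- structure(list(proband = proband, panel = panel, prephase = pre,
                        segments = segments, family = fam[c("discarded", "graph", "close_stats")],
                        assignment = assignment, fragments = fragments,
                        edges = edges, superclusters = sc, largest_sc = largest_sc,
                        phased = phased, control = control,
                        n_db = length(db_ids)),
                   class = "ibd_phase")
  fit$features <- extract_features(fit)
  fit
}

#' @export
print.ibd_phase <- function(x, ...) {
  pv <- table(factor(PROV_LEVELS[x$phased$provenance], levels = PROV_LEVELS))
  cat("Genome-wide IBD phasing of", x$proband, "\n")
  cat(sprintf("  %d IBD segments from %d individuals (%d discarded as unreliable family)\n",
              nrow(x$segments), length(unique(x$segments$other_id)),
              nrow(x$family$discarded)))
  cat(sprintf("  %d fragments in %d subclusters, %d supercluster(s); largest: component %s\n",
              nrow(x$fragments), length(unique(x$fragments$subcluster)),
              length(unique(x$fragments$component)), x$largest_sc))
  cat(sprintf("  sites phased from IBD on both sides: %d, one side: %d, pre-phase default: %d\n",
              pv[3L], pv[2L], pv[1L]))
  cat(sprintf("  corrections: %d; ignored proband het sites: %d\n",
              nrow(x$phased$corrections), length(x$assignment$ignored_sites)))
  invisible(x)
}

#' @export
summary.ibd_phase <- function(object, ...) {
  x <- object
  print(x)
  cat("\nPer-chromosome fragments:\n")
  if (nrow(x$fragments)) {
    tb <- table(x$fragments$chrom, factor(x$fragments$global_side, levels = 1:2,
                                          labels = c("A", "B")))
    print(tb)
  }
  if (!is.null(x$family$close_stats)) {
    cat("\nClose family:\n")
    print(x$family$close_stats[, c("other_id", "total_shared_cm",
                                   "ibd2_run_fraction", "ibd1_rate", "class")],
          row.names = FALSE, digits = 3)
  }
  cat("\nConfidence features:\n")
  print(round(unlist(x$features), 4))
  invisible(x)
}

#' Plot fragment side assignments along the genome
#'
#' One horizontal track per chromosome; retained fragments are drawn as
#' bars above (side A) or below (side B) the axis, shaded by supercluster
#' membership (grey when pruned from the confident core).
#'
#' @param x An `ibd_phase` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ibd_phase <- function(x, ...) {
  fr <- x$fragments
  chroms <- unique(x$panel$chrom)
  nc <- length(chroms)
  maxcm <- max(x$panel$cm)
  graphics::plot(NULL, xlim = c(0, maxcm), ylim = c(0.5, nc + 0.5),
                 xlab = "position (cM)", ylab = "chromosome", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nc), labels = chroms, las = 1)
  for (ci in seq_len(nc)) {
    ix <- which(x$panel$chrom == chroms[ci])
    graphics::segments(x$panel$cm[ix[1L]], ci, x$panel$cm[ix[length(ix)]], ci,
                       col = "grey60")
  }
  if (!nrow(fr)) return(invisible(x))
  ci <- match(fr$chrom, chroms)
  y0 <- ci + ifelse(fr$global_side == 1L, 0.08, -0.08)
  y1 <- ci + ifelse(fr$global_side == 1L, 0.32, -0.32)
  col <- ifelse(fr$pruned, "grey70",
                ifelse(fr$component == x$largest_sc, "#d95f02", "#7570b3"))
  graphics::rect(x$panel$cm[fr$start], y0, x$panel$cm[fr$end], y1,
                 col = col, border = NA)
  invisible(x)
}
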