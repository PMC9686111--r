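# Separation of IBD segments into two parental groups. The proband's
# heterozygous sites are scanned left to right on each chromosome; at each
# site the overlapping segments that are homozygous split into two camps
# (hom-ref vs hom-alt), and the site is oriented so that the weighted
# number of segments keeping their previous group is maximal. Segments
# forced to switch groups are broken; suspect sites (likely genotype
# errors in the proband) are ignored via a lookahead over neighbouring
# heterozygous sites.

#' Endpoint down-weighting of a segment's information at a site
#'
#' Detected IBD segments typically extend beyond the true shared haplotype,
#' so evidence near a segment end is discounted by a sigmoid of the cM
#' distance `d` to the nearer end: `1/(1 + exp(-slope*(d - d0)))`.
#'
#' @param seg One-row data.frame with `start`, `end` (site indices).
#' @param site_idx Site index inside the segment.
#' @param panel The [site_panel()].
#' @param control An [ibd_phase_control()] (supplies `weight_d0`,
#'   `weight_slope`).
#' @return Weight in `[0, 1]`.
#' @export
endpoint_weight <- function(seg, site_idx, panel, control = ibd_phase_control()) {
  if (any(site_idx < seg$start | site_idx > seg$end)) stop("site outside segment")
  d <- pmin(panel$cm[site_idx] - panel$cm[seg$start],
            panel$cm[seg$end] - panel$cm[site_idx])
  sigmoid_weight(d, control$weight_d0, control$weight_slope)
}

# Informative-entry table for one chromosome: one row per (het-site rank,
# segment) where the segment's individual is homozygous. Columns are
# parallel vectors sorted by het rank, with a pointer index for O(1)
# slicing per rank.
split_entries <- function(calls, segs, het_idx, cm_site, panel, control) {
  e_j <- list(); e_seg <- list(); e_allele <- list(); e_w <- list()
  for (s in seq_len(nrow(segs))) {
    jlo <- findInterval(segs$start[s] - 1L, het_idx) + 1L
    jhi <- findInterval(segs$end[s], het_idx)
    if (jlo > jhi) next
    hets <- het_idx[jlo:jhi]
    oc <- calls[segs$other_id[s], hets]
    hom <- !is.na(oc) & oc != 1L
    if (!any(hom)) next
    hh <- hets[hom]
    d <- pmin(panel$cm[hh] - panel$cm[segs$start[s]],
              panel$cm[segs$end[s]] - panel$cm[hh])
    e_j[[s]] <- (jlo:jhi)[hom]
    e_seg[[s]] <- rep.int(s, sum(hom))
    e_allele[[s]] <- oc[hom] %/% 2L
    e_w[[s]] <- sigmoid_weight(d, control$weight_d0, control$weight_slope)
  }
  j <- unlist(e_j); if (is.null(j)) j <- integer(0)
  ord <- order(j)
  list(j = j[ord], seg = unlist(e_seg)[ord], allele = unlist(e_allele)[ord],
       w = unlist(e_w)[ord],
       ptr = c(0L, cumsum(tabulate(j, length(het_idx)))))
}

# Greedy scan over one chromosome. Returns fragments, breakpoints, ignored
# sites and per-het-site orientation.
split_chromosome <- function(calls, segs, het_idx, pre, panel, control) {
  nh <- length(het_idx)
  ns <- nrow(segs)
  orientA <- integer(nh); resolved <- logical(nh); ignored <- logical(nh)
  fr_seg <- integer(0); fr_start <- integer(0); fr_end <- integer(0); fr_side <- integer(0)
  breakpoints <- integer(0)
  side <- integer(ns); fragstart <- integer(ns)
  if (nh == 0L)
    return(list(fragments = data.frame(), breakpoints = breakpoints,
                orient = data.frame(), side = side))
  ent <- split_entries(calls, segs, het_idx, NULL, panel, control)
  slice <- function(k) if (ent$ptr[k] < ent$ptr[k + 1L]) (ent$ptr[k] + 1L):(ent$ptr[k + 1L]) else integer(0)
  carry <- TRUE
  prev_orient <- 1L
  W <- control$lookahead_window

  pre_het <- !is.na(pre$hapA[het_idx]) & !is.na(pre$hapB[het_idx]) &
             (pre$hapA[het_idx] + pre$hapB[het_idx] == 1L)

  for (j in seq_len(nh)) {
    defA <- if (pre_het[j]) {
      if (carry) pre$hapA[het_idx[j]] else pre$hapB[het_idx[j]]
    } else prev_orient
    sl <- slice(j)
    if (!length(sl)) { orientA[j] <- defA; prev_orient <- defA; next }
    es <- ent$seg[sl]; ea <- ent$allele[sl]; ew <- ent$w[sl]
    sd <- side[es]
    asn <- sd > 0L
    implied1 <- ifelse(ea == 1L, 1L, 2L)
    sumW <- sum(ew[asn])
    agree1 <- sum(ew[asn & implied1 == sd])
    agree0 <- sumW - agree1
    o <- if (agree1 > agree0) 1L else if (agree0 > agree1) 0L else defA
    impliedO <- if (o == 1L) implied1 else 3L - implied1
    # only solidly weighted sites may move a segment between groups
    eligible <- ew >= control$min_assign_weight
    forced <- sum(ew[asn & eligible & impliedO != sd])

    if (forced >= control$lookahead_trigger - 1e-9) {
      chg <- es[asn & eligible & impliedO != sd]
      newside <- integer(ns)
      newside[chg] <- impliedO[match(chg, es)]
      cost <- 0
      for (k in c(max(1L, j - W):(j - 1L), if (j < nh) (j + 1L):min(nh, j + W))) {
        if (k == j || k < 1L || k > nh) next
        slk <- slice(k)
        if (!length(slk)) next
        ks <- ent$seg[slk]; ka <- ent$allele[slk]; kw <- ent$w[slk]
        kimp1 <- ifelse(ka == 1L, 1L, 2L)
        stable <- side[ks] > 0L & !(ks %in% chg)
        if (!any(stable)) next
        sWs <- sum(kw[stable])
        a1s <- sum(kw[stable & kimp1 == side[ks]])
        if (a1s * 2 == sWs) next
        ok <- if (a1s * 2 > sWs) 1L else 0L
        kimpO <- if (ok == 1L) kimp1 else 3L - kimp1
        inchg <- ks %in% chg
        # net disagreement: window votes against the proposed new sides,
        # less votes supporting them (a genuine break is supported on the
        # downstream side; a false heterozygote is contradicted on both)
        cost <- cost + sum(kw[inchg & kimpO != newside[ks]]) -
          sum(kw[inchg & kimpO == newside[ks]])
      }
      if (cost > control$lookahead_cost) {
        ignored[j] <- TRUE
        orientA[j] <- defA; prev_orient <- defA
        next
      }
    }

    # accept the site: break side-switching segments, bootstrap new ones
    sw <- which(asn & eligible & impliedO != sd)
    if (length(sw)) {
      h <- het_idx[j]
      breakpoints <- c(breakpoints, rep.int(h, length(sw)))
      fr_seg <- c(fr_seg, es[sw]); fr_start <- c(fr_start, fragstart[es[sw]])
      fr_end <- c(fr_end, rep.int(h - 1L, length(sw)))
      fr_side <- c(fr_side, side[es[sw]])
      side[es[sw]] <- impliedO[sw]
      fragstart[es[sw]] <- h
    }
    nw <- which(!asn & eligible)
    if (length(nw)) {
      side[es[nw]] <- impliedO[nw]
      fragstart[es[nw]] <- segs$start[es[nw]]
    }
    orientA[j] <- o; prev_orient <- o
    resolved[j] <- sumW > 0
    if (pre_het[j]) carry <- (o == pre$hapA[het_idx[j]])
  }

  open <- which(side > 0L)
  fr_seg <- c(fr_seg, open); fr_start <- c(fr_start, fragstart[open])
  fr_end <- c(fr_end, segs$end[open]); fr_side <- c(fr_side, side[open])

  fragments <- if (length(fr_seg))
    data.frame(seg = fr_seg, start = fr_start, end = fr_end, side = fr_side)
  else data.frame(seg = integer(0), start = integer(0), end = integer(0),
                  side = integer(0))
  list(fragments = fragments, breakpoints = breakpoints,
       orient = data.frame(site = het_idx, allele_on_A = orientA,
                           resolved = resolved, ignored = ignored),
       side = side)
}

# Merge same-side fragments of one segment separated by at most one site,
# then apply retention: fragments longer than min_fragment_cm are kept and
# the longest fragment is always kept.
finalize_fragments <- function(fragments, panel, control) {
  if (!nrow(fragments)) {
    fragments$cm <- numeric(0); fragments$kept <- logical(0)
    return(fragments)
  }
  merge_adjacent <- function(fr) {
    fr <- fr[order(fr$start), , drop = FALSE]
    i <- 1L
    while (i < nrow(fr)) {
      if (fr$side[i + 1L] == fr$side[i] && fr$start[i + 1L] - fr$end[i] <= 2L) {
        fr$end[i] <- fr$end[i + 1L]
        fr <- fr[-(i + 1L), , drop = FALSE]
      } else i <- i + 1L
    }
    fr
  }
  out <- lapply(split(fragments, fragments$seg), function(fr) {
    fr <- merge_adjacent(fr)
    fr$cm <- panel$cm[fr$end] - panel$cm[fr$start]
    kept <- fr$cm > control$min_fragment_cm
    kept[which.max(fr$cm)] <- TRUE
    # retained portions separated by a single discarded SNP count as one
    kf <- merge_adjacent(fr[kept, , drop = FALSE])
    kf$cm <- panel$cm[kf$end] - panel$cm[kf$start]
    kf$kept <- TRUE
    uf <- fr[!kept, , drop = FALSE]
    if (nrow(uf)) uf$kept <- FALSE
    rbind(kf, uf)
  })
  fragments <- do.call(rbind, out)
  rownames(fragments) <- NULL
  fragments
}

#' Separate IBD segments into two parental groups
#'
#' Runs the weighted greedy scan over every chromosome. Group labels (side
#' 1 / side 2) are consistent within a chromosome only up to the blocks of
#' overlapping evidence; genome-wide alignment is done later by
#' superclustering.
#'
#' @param g A [genotype_matrix()].
#' @param proband Proband ID.
#' @param segments Detected (and family-filtered) IBD segments.
#' @param pre A [prephase()] supplying the default orientation.
#' @param control An [ibd_phase_control()].
#' @return List of class `"group_assignment"`: `fragments` (data.frame:
#'   `seg_row` into `segments`, `other_id`, `chrom`, `start`, `end`, `cm`,
#'   `side`, `kept`), `breakpoints`, `orientation` (per proband het site:
#'   `site`, `allele_on_A`, `resolved`, `ignored`), `ignored_sites`,
#'   `unassigned` (rows of `segments` never assigned, e.g. IBD2 segments),
#'   and `segments` itself.
#' @export
assign_parental_groups <- function(g, proband, segments, pre,
                                   control = ibd_phase_control()) {
  panel <- g$sites
  gp <- g$calls[proband, ]
  frag_all <- list(); orient_all <- list(); bps <- integer(0)
  assigned_rows <- integer(0)
  for (cc in unique(panel$chrom)) {
    ix <- which(panel$chrom == cc)
    het_idx <- ix[!is.na(gp[ix]) & gp[ix] == 1L]
    rows <- which(segments$chrom == cc)
    segs <- segments[rows, , drop = FALSE]
    res <- split_chromosome(g$calls, segs, het_idx, pre, panel, control)
    if (nrow(res$fragments)) {
      fr <- finalize_fragments(res$fragments, panel, control)
      fr$seg_row <- rows[fr$seg]
      fr$other_id <- segments$other_id[fr$seg_row]
      fr$chrom <- cc
      frag_all[[cc]] <- fr[, c("seg_row", "other_id", "chrom", "start", "end",
                               "cm", "side", "kept")]
      assigned_rows <- c(assigned_rows, rows[res$side > 0L])
    }
    bps <- c(bps, res$breakpoints)
    if (nrow(res$orient)) orient_all[[cc]] <- res$orient
  }
  fragments <- if (length(frag_all)) do.call(rbind, frag_all) else
    data.frame(seg_row = integer(0), other_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), cm = numeric(0),
               side = integer(0), kept = logical(0), stringsAsFactors = FALSE)
  rownames(fragments) <- NULL
  orientation <- if (length(orient_all)) do.call(rbind, orient_all) else
    data.frame(site = integer(0), allele_on_A = integer(0),
               resolved = logical(0), ignored = logical(0))
  rownames(orientation) <- NULL
  structure(list(fragments = fragments, breakpoints = bps,
                 orientation = orientation,
                 ignored_sites = orientation$site[orientation$ignored],
                 unassigned = setdiff(seq_len(nrow(segments)), assigned_rows),
                 segments = segments),
            class = "group_assignment")
}
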