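#' SNP site panel
#'
#' The single coordinate system shared by every component: a table of
#' biallelic SNP sites with chromosome, 1-based physical position, and
#' genetic position in centimorgans. Sites are sorted by chromosome (in
#' order of first appearance) and position; the row number is the global
#' site index used by all interval types in the package.
#'
#' @param chrom Character (or coercible) chromosome labels.
#' @param pos Integer 1-based physical positions (bp).
#' @param cm Numeric genetic positions (cM), non-decreasing within each
#'   chromosome. May be `NA` until a genetic map is applied.
#' @return A data.frame of class `"site_panel"` with columns
#'   `chrom`, `pos`, `cm`.
#' @export
#' @examples
#' site_panel(chrom = c("1", "1", "2"), pos = c(100L, 200L, 50L),
#'            cm = c(0, 0.5, 0))
site_panel <- function(chrom, pos, cm = NA_real_) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  cm <- rep_len(as.numeric(cm), length(pos))
  if (length(chrom) != length(pos)) stop("chrom and pos lengths differ")
  ord <- order(match(chrom, unique(chrom)), pos)
  p <- data.frame(chrom = chrom[ord], pos = pos[ord], cm = cm[ord],
                  stringsAsFactors = FALSE)
  if (anyDuplicated(paste(p$chrom, p$pos))) stop("duplicated sites in panel")
  for (cc in unique(p$chrom)) {
    v <- p$cm[p$chrom == cc]
    if (!anyNA(v) && is.unsorted(v)) stop("cm not non-decreasing on chromosome ", cc)
  }
  class(p) <- c("site_panel", "data.frame")
  p
}

# Named list of index ranges (integer vectors of row indices) per chromosome.
panel_blocks <- function(panel) {
  split(seq_len(nrow(panel)), factor(panel$chrom, levels = unique(panel$chrom)))
}

#' Total genetic length of the panel
#'
#' Sum over chromosomes of the cM span from first to last site.
#'
#' @param panel A [site_panel()].
#' @return Genetic length in cM.
#' @export
genome_cm <- function(panel) {
  sum(vapply(panel_blocks(panel),
             function(ix) panel$cm[ix[length(ix)]] - panel$cm[ix[1L]], 0.0))
}

#' Read a genetic map
#'
#' Whitespace-delimited text with three columns: chromosome, physical
#' position (bp) and genetic position (cM), PLINK-map-like. cM must be
#' non-decreasing within each chromosome.
#'
#' @param path File path.
#' @return data.frame with columns `chrom`, `pos`, `cm`.
#' @export
read_genetic_map <- function(path) {
  m <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chrom", "pos", "cm"))
  m$chrom <- as.character(m$chrom)
  m
}

#' Annotate a panel with genetic positions from a map
#'
#' Each panel site receives a cM value by linear interpolation between the
#' flanking map rows of its chromosome; sites outside the mapped range take
#' the nearest map endpoint's cM.
#'
#' @param panel A [site_panel()].
#' @param map data.frame as returned by [read_genetic_map()].
#' @return The panel with its `cm` column filled in.
#' @export
apply_genetic_map <- function(panel, map) {
  for (cc in unique(panel$chrom)) {
    sel <- map$chrom == cc
    if (!any(sel)) stop("genetic map has no rows for chromosome ", cc)
    mp <- map[sel, , drop = FALSE]
    mp <- mp[order(mp$pos), , drop = FALSE]
    if (is.unsorted(mp$cm)) stop("non-monotone cM in genetic map on chromosome ", cc)
    ix <- which(panel$chrom == cc)
    if (nrow(mp) == 1L) {
      panel$cm[ix] <- mp$cm
    } else {
      panel$cm[ix] <- stats::approx(mp$pos, mp$cm, xout = panel$pos[ix],
                                    rule = 2, ties = "ordered")$y
    }
  }
  panel
}
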