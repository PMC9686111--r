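# IBD detection from unphased genotypes. Two individuals are IBD over a
# stretch of SNPs when they share at least one allele throughout; on
# unphased data the only hard evidence against sharing is an
# opposite-homozygote site (one hom-ref, the other hom-alt). Candidate
# segments are the maximal conflict-free runs, kept when they are at least
# `min_cm` long and still at least `min_trimmed_cm` long after discarding
# inter-SNP gaps above `max_gap_cm` (a SNP-density guard).

#' Homozygosity bitmaps for one individual
#'
#' Packs the individual's calls into three bit planes over the panel:
#' hom-ref, hom-alt and missing. These raw vectors drive the word-level
#' bitwise conflict scan.
#'
#' @param g A [genotype_matrix()].
#' @param individual Individual ID.
#' @return List with raw vectors `hom_ref`, `hom_alt`, `missing` and the
#'   site count `n` (bits beyond `n` are padding).
#' @export
homozygosity_bitmaps <- function(g, individual) {
  if (!individual %in% rownames(g$calls)) stop("unknown individual: ", individual)
  v <- g$calls[individual, ]
  n <- length(v)
  pad <- (8L - n %% 8L) %% 8L
  pack <- function(x) packBits(c(x, rep(FALSE, pad)))
  list(hom_ref = pack(!is.na(v) & v == 0L),
       hom_alt = pack(!is.na(v) & v == 2L),
       missing = pack(is.na(v)),
       n = n)
}

# Per-chromosome geometry reused across pairs: local index ranges, cm, and
# the cumulative density-trimmed length (gaps > max_gap_cm contribute 0).
panel_geometry <- function(panel, max_gap_cm) {
  lapply(panel_blocks(panel), function(ix) {
    cm <- panel$cm[ix]
    gaps <- diff(cm)
    list(ix = ix, cm = cm,
         cg = c(0, cumsum(gaps * (gaps <= max_gap_cm))))
  })
}

# Candidate runs between conflict sites on one chromosome block, filtered
# by raw and trimmed length. `conf_local` are local (within-block) indices.
runs_between <- function(conf_local, geo, min_cm, min_trimmed_cm) {
  len <- length(geo$ix)
  starts <- c(1L, conf_local + 1L)
  ends <- c(conf_local - 1L, len)
  ok <- starts <= ends
  starts <- starts[ok]; ends <- ends[ok]
  if (!length(starts)) return(NULL)
  cml <- geo$cm[ends] - geo$cm[starts]
  trm <- geo$cg[ends] - geo$cg[starts]
  keep <- cml >= min_cm & trm >= min_trimmed_cm
  if (!any(keep)) return(NULL)
  data.frame(start = geo$ix[starts[keep]], end = geo$ix[ends[keep]],
             cm_length = cml[keep], trimmed_cm = trm[keep])
}

#' Detect IBD segments between a proband and database individuals
#'
#' Bitwise scan: the conflict bitset is
#' `(hom_refA & hom_altB) | (hom_altA & hom_refB)`; candidate segments are
#' the maximal runs between conflict sites on each chromosome (missing
#' calls never break a segment), retained when at least `min_cm` cM long
#' and at least `min_trimmed_cm` cM after the density trim.
#'
#' @param g A [genotype_matrix()] with cM-annotated panel.
#' @param proband Proband ID.
#' @param others Character vector of database IDs.
#' @param control An [ibd_phase_control()].
#' @return data.frame: `proband_id`, `other_id`, `chrom`, `start`, `end`
#'   (1-based closed site indices), `cm_length`, `trimmed_cm`.
#' @export
detect_ibd_segments <- function(g, proband, others,
                                control = ibd_phase_control()) {
  panel <- g$sites
  if (anyNA(panel$cm)) stop("panel has no genetic positions; apply a genetic map first")
  geos <- panel_geometry(panel, control$max_gap_cm)
  bp <- homozygosity_bitmaps(g, proband)
  n <- bp$n
  out <- list()
  for (other in others) {
    bo <- homozygosity_bitmaps(g, other)
    conflict <- (bp$hom_ref & bo$hom_alt) | (bp$hom_alt & bo$hom_ref)
    cidx <- which(as.logical(rawToBits(conflict)))
    cidx <- cidx[cidx <= n]
    for (cc in names(geos)) {
      geo <- geos[[cc]]
      lo <- geo$ix[1L]; hi <- geo$ix[length(geo$ix)]
      conf_local <- cidx[cidx >= lo & cidx <= hi] - lo + 1L
      runs <- runs_between(conf_local, geo, control$min_cm, control$min_trimmed_cm)
      if (!is.null(runs)) {
        runs <- cbind(proband_id = proband, other_id = other, chrom = cc, runs,
                      stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- runs
      }
    }
  }
  if (!length(out))
    return(data.frame(proband_id = character(0), other_id = character(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      cm_length = numeric(0), trimmed_cm = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect IBD2 runs between two individuals
#'
#' Maximal runs of sites where the two genotypes are identical wherever
#' both are non-missing (missing calls never break a run), retained when at
#' least `ibd2_min_cm` cM long. Full siblings show such runs over about a
#' quarter of the genome, identical twins over virtually all of it.
#'
#' @inheritParams detect_ibd_segments
#' @param other Database individual ID.
#' @return data.frame: `other_id`, `chrom`, `start`, `end`, `cm_length`.
#' @export
detect_ibd2_runs <- function(g, proband, other, control = ibd_phase_control()) {
  panel <- g$sites
  a <- g$calls[proband, ]; b <- g$calls[other, ]
  brk <- which(!is.na(a) & !is.na(b) & a != b)
  out <- list()
  for (cc in names(panel_blocks(panel))) {
    ix <- panel_blocks(panel)[[cc]]
    lo <- ix[1L]; hi <- ix[length(ix)]
    bl <- brk[brk >= lo & brk <= hi] - lo + 1L
    len <- length(ix)
    starts <- c(1L, bl + 1L); ends <- c(bl - 1L, len)
    ok <- starts <= ends
    starts <- starts[ok]; ends <- ends[ok]
    if (!length(starts)) next
    cm <- panel$cm[ix]
    cml <- cm[ends] - cm[starts]
    keep <- cml >= control$ibd2_min_cm
    if (any(keep))
      out[[cc]] <- data.frame(other_id = other, chrom = cc,
                              start = ix[starts[keep]], end = ix[ends[keep]],
                              cm_length = cml[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(other_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), cm_length = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Pairwise relationship statistics
#'
#' Genome-wide sharing summaries used to classify a database individual's
#' relationship to the proband.
#'
#' @inheritParams detect_ibd2_runs
#' @param segments Detected IBD segments for the pair (rows of
#'   [detect_ibd_segments()] output).
#' @param runs Detected IBD2 runs for the pair.
#' @return One-row data.frame: `other_id`, `total_shared_cm` (summed cM of
#'   detected segments), `n_segments`, `ibd2_run_fraction` (genome cM
#'   fraction covered by IBD2 runs), `ibd1_rate` (fraction of comparable
#'   sites sharing at least one allele).
#' @export
relationship_stats <- function(g, proband, other, segments, runs) {
  a <- g$calls[proband, ]; b <- g$calls[other, ]
  comparable <- !is.na(a) & !is.na(b)
  if (!any(comparable)) stop("zero comparable sites between ", proband, " and ", other)
  share <- !((a == 0L & b == 2L) | (a == 2L & b == 0L))
  data.frame(other_id = other,
             total_shared_cm = sum(segments$cm_length),
             n_segments = nrow(segments),
             ibd2_run_fraction = sum(runs$cm_length) / genome_cm(g$sites),
             ibd1_rate = mean(share[comparable]),
             stringsAsFactors = FALSE)
}
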