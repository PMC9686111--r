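# Genome-wide phasing from sided IBD evidence. Each retained fragment,
# mapped to a global parental side, votes at every site where its database
# individual is homozygous (the homozygous allele must be the shared one),
# weighted by the endpoint sigmoid. Sites with enough evidence are phased
# (and, when the evidence contradicts the input, imputed or corrected);
# everywhere else the pre-phase supplies the call and orientation, carried
# forward from the previous IBD-resolved heterozygous site.

PROV_LEVELS <- c("prephase_default", "ibd_one_side", "ibd_both_sides")

# Weighted allele votes per global side over all panel sites.
accumulate_votes <- function(calls, fragments, panel, control) {
  S <- nrow(panel)
  v <- list(A0 = numeric(S), A1 = numeric(S), B0 = numeric(S), B1 = numeric(S))
  for (k in seq_len(nrow(fragments))) {
    f <- fragments[k, ]
    sites <- f$start:f$end
    oc <- calls[f$other_id, sites]
    hom <- !is.na(oc) & oc != 1L
    if (!any(hom)) next
    ss <- sites[hom]
    d <- pmin(panel$cm[ss] - panel$cm[f$start], panel$cm[f$end] - panel$cm[ss])
    w <- sigmoid_weight(d, control$weight_d0, control$weight_slope)
    al <- oc[hom] %/% 2L
    tag <- paste0(if (f$global_side == 1L) "A" else "B", al)
    for (t in unique(tag)) {
      sel <- tag == t
      v[[t]][ss[sel]] <- v[[t]][ss[sel]] + w[sel]
    }
  }
  v
}

# Vectorised per-site phase decision. Inputs are parallel vectors over the
# panel; `chrom` delimits the pre-phase carry. Returns haplotypes,
# provenance, corrections and same-side conflict sites.
phase_sites_impl <- function(vA0, vA1, vB0, vB1, orig, pre1, pre2, chrom,
                             control = ibd_phase_control()) {
  S <- length(orig)
  ti <- control$override_imputed; tg <- control$override_genotype
  aA <- ifelse(vA1 > vA0, 1L, 0L); aB <- ifelse(vB1 > vB0, 1L, 0L)
  tieA <- vA1 == vA0; tieB <- vB1 == vB0
  wA <- ifelse(tieA, 0, pmax(vA1, vA0)); wB <- ifelse(tieB, 0, pmax(vB1, vB0))
  eA <- wA > ti; eB <- wB > ti
  sA <- wA >= tg; sB <- wB >= tg
  conflict_side <- (pmin(vA1, vA0) > 0) | (pmin(vB1, vB0) > 0)

  hapA <- rep(NA_integer_, S); hapB <- rep(NA_integer_, S)
  prov <- ifelse(eA & eB, 3L, ifelse(eA | eB, 2L, 1L))

  het <- !is.na(orig) & orig == 1L
  hom <- !is.na(orig) & orig != 1L
  mis <- is.na(orig)
  ga <- orig %/% 2L

  ## heterozygous original call
  m <- het & eA & eB & aA != aB
  hapA[m] <- aA[m]; hapB[m] <- aB[m]
  m <- het & eA & eB & aA == aB & sA & sB               # hom override
  hapA[m] <- aA[m]; hapB[m] <- aA[m]
  m <- het & eA & eB & aA == aB & !(sA & sB)            # keep het, stronger side wins
  useA <- m & wA >= wB
  hapA[useA] <- aA[useA]; hapB[useA] <- 1L - aA[useA]
  useB <- m & wA < wB
  hapB[useB] <- aB[useB]; hapA[useB] <- 1L - aB[useB]
  m <- het & eA & !eB
  hapA[m] <- aA[m]; hapB[m] <- 1L - aA[m]
  m <- het & !eA & eB
  hapB[m] <- aB[m]; hapA[m] <- 1L - aB[m]

  ## homozygous original call: only a strong side may contradict
  effA <- hom & eA & (aA == ga | sA)   # side A vote in effect
  effB <- hom & eB & (aB == ga | sB)
  hA <- ifelse(hom & effA, aA, ga)     # allele on side A
  hB <- ifelse(hom & effB, aB, ga)
  hapA[hom] <- hA[hom]; hapB[hom] <- hB[hom]

  ## missing original call
  m <- mis & eA & eB
  hapA[m] <- aA[m]; hapB[m] <- aB[m]
  mis_oneA <- mis & eA & !eB
  hapA[mis_oneA] <- aA[mis_oneA]
  mis_oneB <- mis & !eA & eB
  hapB[mis_oneB] <- aB[mis_oneB]

  ## pre-phase carry: mapping of pre-phase hapA to global side A, updated at
  ## heterozygous sites whose full orientation was fixed by IBD evidence
  pre_het <- !is.na(pre1) & !is.na(pre2) & (pre1 + pre2 == 1L)
  det_het <- !is.na(hapA) & !is.na(hapB) & hapA != hapB & (eA | eB)
  upd <- det_het & pre_het
  upd_val <- hapA == pre1
  mapping <- rep(TRUE, S)
  for (cc in unique(chrom)) {
    ix <- which(chrom == cc)
    u <- which(upd[ix])
    if (!length(u)) next
    fi <- findInterval(seq_along(ix) - 1L, u)
    mapping[ix] <- ifelse(fi == 0L, TRUE, upd_val[ix][u][pmax(fi, 1L)])
  }
  preA <- ifelse(mapping, pre1, pre2)   # pre-phase allele on global side A
  preB <- ifelse(mapping, pre2, pre1)

  fill <- is.na(hapA)
  hapA[fill] <- preA[fill]
  fill <- is.na(hapB)
  hapB[fill] <- preB[fill]

  eg <- hapA + hapB
  gcorr <- which(!is.na(orig) & !is.na(eg) & eg != orig)
  icorr <- which(mis & !is.na(eg) & !is.na(pre1) & !is.na(pre2) & eg != pre1 + pre2)
  corrections <- rbind(
    if (length(gcorr)) data.frame(site = gcorr, original = orig[gcorr],
                                  emitted = eg[gcorr], kind = "genotype_override",
                                  stringsAsFactors = FALSE),
    if (length(icorr)) data.frame(site = icorr, original = NA_integer_,
                                  emitted = eg[icorr], kind = "imputed_override",
                                  stringsAsFactors = FALSE))
  if (is.null(corrections))
    corrections <- data.frame(site = integer(0), original = integer(0),
                              emitted = integer(0), kind = character(0),
                              stringsAsFactors = FALSE)
  list(hapA = hapA, hapB = hapB, provenance = prov, corrections = corrections,
       conflicts = which(conflict_side), evidence_A = wA, evidence_B = wB)
}

#' Phase a single site from weighted votes
#'
#' The per-site decision rule, exposed for inspection: a side with weighted
#' evidence of at least `override_imputed` contributes its majority allele;
#' evidence of at least `override_genotype` may contradict a non-missing
#' call (with one-sided evidence only homozygous calls are overridden);
#' with insufficient evidence the pre-phase call and orientation are kept.
#'
#' @param votes_A,votes_B Numeric length-2 vectors: weighted votes for
#'   allele 0 and allele 1 on each global side.
#' @param original Original diploid call (0/1/2 or `NA`).
#' @param pre Length-2 pre-phase haplotype pair at the site.
#' @param control An [ibd_phase_control()].
#' @return List: `hapA`, `hapB`, `provenance` (one of
#'   `"prephase_default"`, `"ibd_one_side"`, `"ibd_both_sides"`),
#'   `correction` (`NA`, `"genotype_override"` or `"imputed_override"`).
#' @export
phase_site <- function(votes_A, votes_B, original, pre,
                       control = ibd_phase_control()) {
  r <- phase_sites_impl(votes_A[1L], votes_A[2L], votes_B[1L], votes_B[2L],
                        as.integer(original), as.integer(pre[1L]),
                        as.integer(pre[2L]), chrom = "1", control = control)
  list(hapA = r$hapA, hapB = r$hapB,
       provenance = PROV_LEVELS[r$provenance],
       correction = if (nrow(r$corrections)) r$corrections$kind else NA_character_)
}

#' Phase the proband genome-wide
#'
#' Applies the per-site decision rule at every panel site using the
#' globally sided fragments' weighted votes.
#'
#' @param g A [genotype_matrix()].
#' @param proband Proband ID.
#' @param fragments Retained fragments with a `global_side` column
#'   (1 = side A, 2 = side B).
#' @param pre A [prephase()].
#' @param control An [ibd_phase_control()].
#' @return Object of class `"phased_genome"`: `hapA`, `hapB`, `provenance`
#'   (integer, see `PROV_LEVELS`), `corrections`, `conflict_sites`,
#'   `evidence_A`, `evidence_B` (per-site weighted majority evidence).
#' @export
phase_genome <- function(g, proband, fragments, pre,
                         control = ibd_phase_control()) {
  panel <- g$sites
  v <- accumulate_votes(g$calls, fragments, panel, control)
  r <- phase_sites_impl(v$A0, v$A1, v$B0, v$B1, g$calls[proband, ],
                        pre$hapA, pre$hapB, panel$chrom, control)
  structure(list(hapA = r$hapA, hapB = r$hapB, provenance = r$provenance,
                 corrections = r$corrections, conflict_sites = r$conflicts,
                 evidence_A = r$evidence_A, evidence_B = r$evidence_B),
            class = "phased_genome")
}
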