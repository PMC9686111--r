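# Trio-based evaluation. Where at least one parent is homozygous, the
# parental origin of each of the proband's two alleles at a heterozygous
# site is unambiguous; those sites are the standard against which the
# genome-wide phase is scored.

#' Trio truth at unambiguous sites
#'
#' Resolvable sites are those where the proband is heterozygous and at
#' least one parent is homozygous (Mendelian-inconsistent sites, e.g. both
#' parents homozygous for the same allele, are excluded).
#'
#' @param proband_calls,mother_calls,father_calls Integer call vectors on
#'   the shared panel.
#' @return List of class `"trio_truth"`: `sites` (panel indices) and
#'   `maternal` (the maternally inherited allele at each site).
#' @export
trio_truth <- function(proband_calls, mother_calls, father_calls) {
  het <- !is.na(proband_calls) & proband_calls == 1L
  mhom <- !is.na(mother_calls) & mother_calls != 1L
  fhom <- !is.na(father_calls) & father_calls != 1L
  m_al <- mother_calls %/% 2L
  f_al <- father_calls %/% 2L
  maternal <- rep(NA_integer_, length(proband_calls))
  both <- het & mhom & fhom
  ok <- both & (m_al + f_al == 1L)
  maternal[ok] <- m_al[ok]
  monly <- het & mhom & !fhom
  maternal[monly] <- m_al[monly]
  fonly <- het & !mhom & fhom
  maternal[fonly] <- 1L - f_al[fonly]
  sites <- which(!is.na(maternal))
  structure(list(sites = sites, maternal = maternal[sites]), class = "trio_truth")
}

# Comparable sites for local metrics: resolvable and emitted heterozygous.
# Returns state vector (TRUE where hapA carries the maternal allele) plus
# panel indices.
phase_states <- function(phased, truth) {
  hA <- phased$hapA[truth$sites]; hB <- phased$hapB[truth$sites]
  emhet <- !is.na(hA) & !is.na(hB) & hA + hB == 1L
  list(sites = truth$sites[emhet], state = hA[emhet] == truth$maternal[emhet])
}

#' Global phase error
#'
#' The fraction of resolvable sites whose allele-to-parent placement
#' disagrees with trio phase, keeping one haplotype assigned to one parent
#' genome-wide but allowing the more favourable of the two
#' haplotype-to-parent assignments. Sites emitted non-heterozygous or
#' missing count as errors under both assignments.
#'
#' @param phased A `phased_genome` (or any list with `hapA`, `hapB`).
#' @param truth A [trio_truth()].
#' @return Error percentage in `[0, 100]`.
#' @export
global_phase_error <- function(phased, truth) {
  n <- length(truth$sites)
  if (n == 0L) stop("no trio-resolvable sites")
  hA <- phased$hapA[truth$sites]; hB <- phased$hapB[truth$sites]
  emhet <- !is.na(hA) & !is.na(hB) & hA + hB == 1L
  e1 <- sum(!emhet | hA != truth$maternal)
  e2 <- sum(!emhet | hB != truth$maternal)
  100 * min(e1, e2) / n
}

#' Switch error rate
#'
#' The frequency with which the phase of a heterozygous SNP differs from
#' that of the previous heterozygous SNP with respect to trio phase,
#' counted within chromosomes over resolvable sites with a heterozygous
#' emitted call.
#'
#' @inheritParams global_phase_error
#' @param panel The [site_panel()].
#' @return Switch error percentage.
#' @export
switch_error_rate <- function(phased, truth, panel) {
  ps <- phase_states(phased, truth)
  if (length(ps$sites) < 2L) stop("fewer than two comparable heterozygous sites")
  switches <- 0L; pairs <- 0L
  for (cc in unique(panel$chrom)) {
    sel <- panel$chrom[ps$sites] == cc
    st <- ps$state[sel]
    if (length(st) < 2L) next
    switches <- switches + sum(st[-1L] != st[-length(st)])
    pairs <- pairs + length(st) - 1L
  }
  if (pairs == 0L) stop("fewer than two comparable heterozygous sites per chromosome")
  100 * switches / pairs
}

#' Proportion of SNPs in switch-free runs of at least 1 cM
#'
#' The fraction of comparable heterozygous sites that belong to maximal
#' switch-free runs spanning at least `min_cm` (local accuracy that does
#' not penalise small poorly phased regions).
#'
#' @inheritParams switch_error_rate
#' @param min_cm Minimum run span in cM.
#' @return Percentage in `[0, 100]`.
#' @export
pct_snps_in_1cm_runs <- function(phased, truth, panel, min_cm = 1.0) {
  ps <- phase_states(phased, truth)
  n <- length(ps$sites)
  if (n == 0L) return(0)
  inrun <- 0L
  for (cc in unique(panel$chrom)) {
    sel <- which(panel$chrom[ps$sites] == cc)
    if (!length(sel)) next
    st <- ps$state[sel]
    r <- rle(st)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    span <- panel$cm[ps$sites[sel[ends]]] - panel$cm[ps$sites[sel[starts]]]
    inrun <- inrun + sum(r$lengths[span >= min_cm])
  }
  100 * inrun / n
}

#' IBD segment assignment error
#'
#' Compares the global parental side of each retained fragment to the side
#' implied by truth (which parent actually shares that DNA), cM-weighted,
#' under the better of the two global side-to-parent mappings.
#'
#' @param fragments Retained fragments with `global_side` and `cm`.
#' @param truth_sides Integer truth side per fragment (1/2, e.g. from
#'   [true_fragment_sides()]); `NA` rows are dropped.
#' @param weights Per-fragment weights; default `fragments$cm`
#'   (set to 1 for count-weighting).
#' @return Error percentage.
#' @export
segment_assignment_error <- function(fragments, truth_sides,
                                     weights = fragments$cm) {
  ok <- !is.na(truth_sides)
  if (!any(ok)) stop("no truth-matchable fragments")
  gs <- fragments$global_side[ok]; ts <- truth_sides[ok]; w <- weights[ok]
  e1 <- sum(w[gs != ts]); e2 <- sum(w[gs == ts])
  100 * min(e1, e2) / sum(w)
}

#' Evaluate a phasing run against trio truth
#'
#' Convenience wrapper computing the four accuracy metrics for an
#' [ibd_phase()] result on simulated (or real trio) data.
#'
#' @param fit An `ibd_phase` object.
#' @param proband_calls,mother_calls,father_calls Call vectors (pass the
#'   unperturbed proband calls when genotypes were perturbed).
#' @param truth Optional simulation truth for the segment assignment error.
#' @return Named list: `global_error`, `switch_error`, `pct_1cm_runs`,
#'   `segment_error` (all percentages; `segment_error` is `NA` without
#'   truth).
#' @export
evaluate_phase <- function(fit, proband_calls, mother_calls, father_calls,
                           truth = NULL) {
  tt <- trio_truth(proband_calls, mother_calls, father_calls)
  seg_err <- NA_real_
  if (!is.null(truth) && nrow(fit$fragments)) {
    ts <- true_fragment_sides(truth, fit$proband, fit$fragments)
    seg_err <- segment_assignment_error(fit$fragments, ts)
  }
  list(global_error = global_phase_error(fit$phased, tt),
       switch_error = switch_error_rate(fit$phased, tt, fit$panel),
       pct_1cm_runs = pct_snps_in_1cm_runs(fit$phased, tt, fit$panel),
       segment_error = seg_err)
}
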