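#' Tuning parameters for the IBD phasing pipeline
#'
#' Collects every threshold used by the pipeline, with the defaults used
#' throughout the package. All genetic lengths are in centimorgans (cM).
#'
#' @param min_cm Minimum genetic length of a detected IBD segment (cM).
#'   Shorter candidate segments are discarded; short IBD is enriched for
#'   false (identity-by-state) sharing.
#' @param min_trimmed_cm Minimum density-trimmed length (cM): the segment
#'   length recomputed after discarding every inter-SNP gap larger than
#'   `max_gap_cm`, which guards against segments supported by sparse SNPs.
#' @param max_gap_cm Largest inter-SNP gap (cM) that still counts towards
#'   the trimmed length.
#' @param ibd2_min_cm Minimum length (cM) of a run of identical genotypes
#'   counted as an IBD2 run.
#' @param close_cm Total shared cM at or above which a database individual
#'   counts as close family.
#' @param twin_ibd2_frac Fraction of the genome in IBD2 runs at or above
#'   which an individual is called an identical twin of the proband.
#' @param sib_total_cm,sib_ibd2_frac,sib_ibd1_max Full-sibling rule: total
#'   sharing at least `sib_total_cm`, IBD2-run genome fraction at least
#'   `sib_ibd2_frac`, and genome-wide IBD1 rate below `sib_ibd1_max`
#'   (the last excludes parent/child pairs).
#' @param weight_d0,weight_slope Endpoint down-weighting sigmoid
#'   `1/(1 + exp(-slope*(d - d0)))` of the cM distance `d` to the nearer
#'   segment end; `weight_d0` is the distance at which the weight is 0.5.
#' @param lookahead_window Number of proband heterozygous sites examined on
#'   each side of a suspect site.
#' @param lookahead_trigger Weighted number of segments that must be forced
#'   to change parental group before the lookahead is consulted.
#' @param lookahead_cost Weighted disagreement across the lookahead window
#'   above which the suspect site is ignored.
#' @param min_assign_weight Minimum endpoint weight an informative site must
#'   have before it may assign a segment to a parental group or flip it to
#'   the other group. Sites below it still vote (with their weight) on the
#'   proband's orientation but cannot move segments: the down-weighted false
#'   extensions of detected segments otherwise seed groups from what is
#'   effectively noise.
#' @param min_weighted_overlap Minimum weighted count of doubly-homozygous
#'   proband-heterozygous sites for two segments to join one subcluster.
#' @param min_connections Minimum number of connections a subcluster needs
#'   to the rest of its supercluster to survive pruning.
#' @param restarts Random restarts of the greedy supercluster optimiser.
#' @param override_genotype Weighted one-side IBD evidence required to
#'   override a non-missing genotype call.
#' @param override_imputed Weighted evidence required to override an
#'   imputed (originally missing) call; also the evidence level at which a
#'   site counts as overlapped by a parental side.
#' @param min_fragment_cm Labelled segment fragments shorter than this are
#'   dropped (the longest fragment of each segment is always retained).
#' @param seed Integer seed for the restart randomisation (and for the
#'   default pre-phase when none is supplied). `NULL` leaves the RNG alone.
#'
#' @return A named list of class `"ibd_phase_control"`.
#' @export
#' @examples
#' ctl <- ibd_phase_control(min_cm = 10)
#' ctl$min_cm
ibd_phase_control <- function(min_cm = 8.0,
                              min_trimmed_cm = 5.0,
                              max_gap_cm = 0.05,
                              ibd2_min_cm = 5.0,
                              close_cm = 400,
                              twin_ibd2_frac = 0.90,
                              sib_total_cm = 1300,
                              sib_ibd2_frac = 0.09,
                              sib_ibd1_max = 0.99,
                              weight_d0 = 1.0,
                              weight_slope = 4.0,
                              lookahead_window = 20L,
                              lookahead_trigger = 1.0,
                              lookahead_cost = 1.0,
                              min_assign_weight = 0.2,
                              min_weighted_overlap = 10.0,
                              min_connections = 3L,
                              restarts = 1000L,
                              override_genotype = 1.0,
                              override_imputed = 0.1,
                              min_fragment_cm = 5.0,
                              seed = NULL) {
  ctl <- list(min_cm = min_cm, min_trimmed_cm = min_trimmed_cm,
              max_gap_cm = max_gap_cm, ibd2_min_cm = ibd2_min_cm,
              close_cm = close_cm, twin_ibd2_frac = twin_ibd2_frac,
              sib_total_cm = sib_total_cm, sib_ibd2_frac = sib_ibd2_frac,
              sib_ibd1_max = sib_ibd1_max, weight_d0 = weight_d0,
              weight_slope = weight_slope,
              lookahead_window = as.integer(lookahead_window),
              lookahead_trigger = lookahead_trigger,
              lookahead_cost = lookahead_cost,
              min_assign_weight = min_assign_weight,
              min_weighted_overlap = min_weighted_overlap,
              min_connections = as.integer(min_connections),
              restarts = as.integer(restarts),
              override_genotype = override_genotype,
              override_imputed = override_imputed,
              min_fragment_cm = min_fragment_cm, seed = seed)
  stopifnot(ctl$min_cm > 0, ctl$max_gap_cm > 0, ctl$restarts >= 1)
  class(ctl) <- "ibd_phase_control"
  ctl
}
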