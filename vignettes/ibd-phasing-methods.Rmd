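---
title: "Methods: genome-wide phasing from IBD segments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide phasing from IBD segments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ibdphaser)
```

## The model

A diploid genotype at a biallelic SNP is the unordered pair of a maternally
and a paternally inherited allele. An IBD segment between the proband and a
database individual is a stretch of the genome where one of the
individual's haplotypes is identical to one of the proband's, because both
descend from a common ancestor. The central observation used throughout
this package: at a site where the proband is heterozygous and the IBD
carrier is *homozygous*, the carrier's single allele must be the shared
one, so the carrier votes for the parental haplotype that carries that
allele. Two overlapping carriers homozygous for opposite alleles at such a
site therefore share opposite proband haplotypes. Carriers who share both
haplotypes (IBD2) are heterozygous wherever the proband is and never vote;
this is why full siblings are uninformative and are removed.

The pipeline (detection → family filter → parental split → subclusters →
superclusters → emission) assumes:

* biallelic SNPs on one shared panel with genetic (cM) positions that are
  non-decreasing within a chromosome;
* IBD detectable from unphased data by opposite-homozygote exclusion — a
  deliberately permissive detector whose false extensions beyond the true
  segment ends are handled downstream by endpoint down-weighting rather
  than up front;
* enough carriers that most heterozygous sites overlap at least one
  informative segment on some side; where none does, an externally supplied
  pre-phase (or the package's deliberately trivial frequency-based default)
  decides the call and its orientation.

## Coordinates

All site intervals are 1-based and closed (`[start, end]` row indices of
the site panel), both internally and in the IBD TSV interchange format;
physical base-pair positions appear only inside VCF records. R's 1-based
indexing makes this the convention least likely to produce off-by-one
errors here, and every interval operation in the package (overlap counts,
run lengths, fragment merging) goes through the panel's cM vector rather
than index arithmetic.

## Tunable parameters

All genetic lengths are in centimorgans. Defaults live in
`ibd_phase_control()`.

| parameter | default | role |
|---|---|---|
| `min_cm` | 8 | minimum IBD segment length; shorter sharing is increasingly identity-by-state, and admitting 5–6 cM segments degrades the supercluster phase |
| `min_trimmed_cm`, `max_gap_cm` | 5, 0.05 | SNP-density guard: the segment must still measure 5 cM after discarding inter-SNP gaps above 0.05 cM |
| `ibd2_min_cm` | 5 | minimum identical-genotype run counted as IBD2 |
| `close_cm` | 400 | total sharing above which an individual is close family (close enough that relatives of both parents will share ≥ 8 cM with all other close family) |
| `twin_ibd2_frac` | 0.90 | IBD2-run genome fraction calling an identical twin |
| `sib_total_cm`, `sib_ibd2_frac`, `sib_ibd1_max` | 1300, 0.09, 0.99 | full-sibling rule; the IBD1 ceiling keeps parent–child pairs (IBD1 ≈ 100%, IBD2 ≈ 0) out |
| `weight_d0`, `weight_slope` | 1.0 cM, 4.0 /cM | endpoint down-weighting sigmoid `1/(1+exp(-slope(d-d0)))`; detected ends overshoot true ends by about a cM at these segment lengths, so the weight is 0.5 one cM from the end and ≈ 0.02 at the end itself |
| `min_assign_weight` | 0.2 | minimum endpoint weight a site needs to *assign or move* a segment between groups (see below) |
| `lookahead_window`, `lookahead_trigger`, `lookahead_cost` | 20 sites, 1.0, 1.0 | proband-error guard on the scan |
| `min_weighted_overlap` | 10.0 | weighted doubly-homozygous overlap joining two fragments into a subcluster |
| `min_connections` | 3 | supercluster pruning threshold (labelling only) |
| `restarts` | 1000 | random restarts of the greedy orientation search |
| `override_genotype`, `override_imputed` | 1.0, 0.1 | weighted evidence needed to override a genotype call, and (strictly exceeded) to override an imputed call or a pre-phase orientation |
| `min_fragment_cm` | 5 | labelled fragments shorter than this are dropped; the longest fragment of each segment is always retained, and retained portions separated by a single SNP are merged |

Two of these deserve their own discussion.

**`min_assign_weight`.** The opposite-homozygote detector extends segments
past their true ends until a conflict happens to occur — typically a dozen
or two SNPs in dense data. Votes in that false extension are noise: with
the proband sharing nothing there, the carrier's homozygous allele is
uncorrelated with either proband haplotype. The endpoint sigmoid already
discounts these votes for *orientation* decisions, but a group assignment
is a discrete action: without a floor, a 0.05-weight noise vote could flip
a whole segment to the other parental group, and around recombination
points — where many segments end and begin at once — such flips can
cascade into a corrupted group state that the error-lookahead then freezes
in place. Requiring weight ≥ 0.2 (about 0.6 cM from a detected end) before
a site may assign or move a segment eliminates the cascade: in the
package's clean-data validation, broken segments drop from ~2 per segment
to ~1 in 10³, and side-label error from ~1.7% to 0. Low-weight sites still
contribute their (small) weight to the proband's orientation at the site.

**The lookahead cost.** When a site's best orientation still forces ≥ 1.0
weighted segments to change groups, the site is suspect: a proband call
erroneously recorded heterozygous collapses all overlapping carriers into
one group. The exact arithmetic for deciding to ignore the site is a
design choice here: for each of the 20 heterozygous sites up- and
downstream, the site's orientation is taken from the segments *not* being
moved, and the cost is the **net** weighted disagreement of the moved
segments with their proposed new sides (disagreements minus agreements)
over the window. A false heterozygote is contradicted in both directions
and accumulates a large positive cost (site ignored, assignments kept); a
genuine mid-segment side change is supported by the downstream window, the
net cost stays near zero, and the break is accepted. Costs above 1.0
ignore the site; the emitted phase at ignored sites still comes from the
final per-site votes, not from the scan.

## Numerical and procedural choices

* **Bitwise scan.** Homozygosity is packed into raw-vector bitplanes
  (hom-ref, hom-alt, missing); the conflict bitset is
  `(hrA & haB) | (haA & hrB)`. Tests assert exact agreement with a naive
  per-site loop.
* **Ties.** Orientation ties in the scan follow the pre-phase default
  carried from the previous heterozygous site (the first site of a
  chromosome defines side A as the allele on pre-phase haplotype A).
  Equal-gain flips in the supercluster search take the lowest subcluster
  id. Equal-weight allele votes on one side at emission count as no
  evidence and are logged as conflicts.
* **Trigger tolerance.** The lookahead trigger compares against
  `1.0 - 1e-9`: an interior endpoint weight approaches 1.0 asymptotically,
  and a single full-weight segment forced to move must engage the guard.
* **Subcluster overlap weighting.** A shared informative site contributes
  the *product* of the two fragments' endpoint weights, computed as a
  cross-product of per-fragment weight columns; interior sites contribute
  ≈ 1 each, so the 10.0 default reads as "ten solid double-homozygous
  sites". The overlap floor is one knob; analyses wanting the more
  conservative behaviour of requiring ~40 such sites can raise
  `min_weighted_overlap` — the two values bracket what the method tolerates
  and the default is the permissive end.
* **Restart randomness.** One seeded generator drives all restarts
  sequentially (restart *r* consumes the stream after restart *r−1*); runs
  are serial, so this is exactly reproducible for a given
  `control$seed`.
* **Retention and votes.** Fragment retention (drop < 5 cM pieces, always
  keep the longest, merge pieces separated by one SNP) defines the
  labelled output, and the same retained fragments cast the emission
  votes: unretained slivers are almost always detector-extension artifacts
  and carry no subcluster membership, hence no global side.
* **Degenerate inputs.** Zero IBD yields the pre-phase bit-for-bit with
  all-default provenance; a chromosome with no heterozygous sites yields
  no assignments; an empty connection graph makes every subcluster its own
  supercluster with arbitrary orientation (harmless, since side labels are
  only defined up to a global swap).
* **Pre-phase carry.** Between IBD-resolved heterozygous sites the mapping
  of pre-phase haplotype A to global side A is carried forward per
  chromosome, so locally coherent stretches of the pre-phase stay on one
  side; the shipped default pre-phase has no local coherence by design, so
  uncovered sites are phased at chance level — exactly the behaviour an
  uninformed fallback should have.

## What the simulator emulates — and what it does not

`sim_database()` builds a proband with parents and four grandparents
(parents held out of the database for trio evaluation), plus configurable
aunts/uncles, first cousins, full siblings, identical twins,
nephews/nieces and unrelated founders. Founder haplotypes are site-wise
independent draws from an allele-frequency spectrum (default
Uniform(0.05, 0.5)); each meiosis places Poisson(L/100) crossovers
uniformly in cM (no interference); genotypes can be perturbed with 1%
missingness and 0.2% het↔hom errors (homozygotes always flip to
heterozygous, heterozygotes to a random homozygote; overlaps resolve
missing-first). Transmission tracks label every allele with its founder
haplotype, so true IBD and true parental sides are known exactly.

The simulator deliberately omits: linkage disequilibrium and coalescent
founder structure (founders are site-independent), so background
identity-by-state sharing between "unrelated" individuals is weaker than
in real populations; endogamy and founder effects, where many individuals
share DNA with both of the proband's parents; array batch effects and
site-specific error rates; and crossover interference. Passing tests
therefore demonstrate the machinery's correctness under honest Mendelian
transmission and the stated noise model — not robustness to
population-structure confounding, which the confidence model is designed
to flag rather than the phaser to survive.

## Validation sizes

The test-suite and `scripts/acceptance.R` problem sizes are the package's
validation choices: detector-oracle equivalence on 200 random pairs of
2,000 sites; parental-split truth recovery on 20 probands with ten 100 cM
chromosomes at 0.02 cM spacing (~50k sites) and ~110 database relatives;
optimiser-oracle equivalence on 20 random graphs of up to 10 subclusters
(exhaustive 2¹⁰ reference); end-to-end recovery and the perturbation
experiment on eight 80 cM chromosomes at 0.025 cM spacing with ~36
relatives; relative-filter exactness on 20 families over twelve 150 cM
chromosomes (the 400/1300 cM thresholds are absolute, so the genome must
be realistically long for sibling totals to clear them); and 36
sparse-to-dense pipeline runs for the error-model correlation check.

## Known limitations

* The default pre-phase is intentionally skill-free; with a real local
  phaser as input, sites without IBD evidence inherit its local accuracy,
  and imputation accuracy at missing sites rises accordingly.
* Segment side labels are defined up to one global A/B swap (autosomal
  data cannot identify which side is the mother); all evaluation metrics
  take the better of the two mappings.
* The descendant-of-both-parents test requires at least two other close
  relatives; with fewer, the all-others adjacency test is vacuous and the
  relative is kept.
* Multiple siblings are not used jointly (grandparental breakpoint
  inference is out of scope), and no population-reference imputation is
  attempted — only IBD-evidence imputation.
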