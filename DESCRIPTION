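Package: ibdphaser
Title: Genome-Wide Haplotype Phasing from Identity-by-Descent Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates the maternally and paternally inherited alleles of a
    genotyped individual across the whole genome using identity-by-descent
    (IBD) segments shared with other individuals in a genotype database.
    Includes IBD and IBD2 detection from unphased genotypes by
    opposite-homozygote exclusion with bitwise scanning, close-relative
    screening (identical twins, full siblings, descendants of both parents),
    separation of IBD segments into two parental groups by a weighted greedy
    scan with an error-robust lookahead, clustering of overlapping segments
    into subclusters and genome-wide superclusters phased by greedy
    optimisation with random restarts, IBD-based imputation and genotype
    error correction, a random-forest model of genome-wide phase error, a
    pedigree simulator with Poisson recombination for validation against
    known truth, and trio-based evaluation metrics (global phase error,
    switch error rate, proportion of SNPs in switch-free 1 cM runs, and IBD
    segment assignment error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    vcfR,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
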