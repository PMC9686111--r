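#' Genotype matrix container
#'
#' Diploid calls for a set of individuals on a shared site panel. Calls
#' count alternate alleles: 0 (hom-ref), 1 (het), 2 (hom-alt); `NA` is a
#' missing call and is distinct from every diploid value.
#'
#' @param calls Integer matrix, individuals x sites, values in
#'   `{0, 1, 2, NA}`; rownames are individual IDs.
#' @param panel The [site_panel()] the columns are aligned to.
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `calls` and `sites`.
#' @export
genotype_matrix <- function(calls, panel) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(panel)) stop("calls/panel dimension mismatch")
  if (is.null(rownames(calls))) stop("calls must have individual IDs as rownames")
  if (anyDuplicated(rownames(calls))) stop("duplicated individual ID")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) stop("calls must be in {0,1,2,NA}")
  structure(list(calls = calls, sites = panel), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "individuals x", ncol(x$calls), "sites on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

# Dosage from a vector of GT strings ("0/1", "0|1", "./.", ...).
gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[gt %in% c("1/1", "1|1")] <- 2L
  known <- is.na(out) & !(gt %in% c("./.", ".|.", ".", NA))
  if (any(known)) stop("unparseable GT value(s), e.g. '", gt[which(known)[1L]], "'")
  out
}

#' Read unphased genotypes from a VCF
#'
#' Biallelic SNP records are read and aligned to `panel` by chromosome and
#' position. Panel sites absent from the file are left missing; file sites
#' absent from the panel are dropped with a warning. With `panel = NULL`
#' the panel is built from the file (cM unset until [apply_genetic_map()]).
#'
#' @param path Path to a VCF (plain or bgzip/gzip).
#' @param panel Optional [site_panel()] to align to.
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  if (!all(biallelic)) {
    warning(sum(!biallelic), " non-biallelic-SNP record(s) dropped")
  }
  chrom <- fix[biallelic, "CHROM"]
  pos <- as.integer(fix[biallelic, "POS"])
  gt <- v@gt[biallelic, -1L, drop = FALSE]
  ids <- colnames(gt)
  if (anyDuplicated(ids)) stop("duplicated individual ID in VCF: ",
                               ids[duplicated(ids)][1L])
  dos <- apply(gt, 2L, gt_to_dosage)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = sum(biallelic), dimnames = list(NULL, ids))
  if (is.null(panel)) {
    panel <- site_panel(chrom, pos)
    idx <- match(paste(panel$chrom, panel$pos), paste(chrom, pos))
    calls <- t(dos[idx, , drop = FALSE])
  } else {
    key_file <- paste(chrom, pos)
    key_panel <- paste(panel$chrom, panel$pos)
    hit <- match(key_file, key_panel)
    if (anyNA(hit)) warning(sum(is.na(hit)), " VCF site(s) absent from panel dropped")
    calls <- matrix(NA_integer_, nrow = length(ids), ncol = nrow(panel),
                    dimnames = list(ids, NULL))
    keep <- !is.na(hit)
    calls[, hit[keep]] <- t(dos[keep, , drop = FALSE])
  }
  rownames(calls) <- ids
  genotype_matrix(calls, panel)
}

#' Pre-phase container
#'
#' A locally phased haplotype pair for the proband, used as the default
#' phase wherever IBD evidence is uninformative. At sites where the raw
#' diploid call is present, `hapA + hapB` must equal it.
#'
#' @param hapA,hapB Integer vectors of alleles in `{0, 1, NA}`.
#' @param imputed Logical vector marking sites whose raw call was missing
#'   (the pre-phase carries an imputed genotype there).
#' @param raw Optional raw diploid call vector for invariant checking.
#' @return An object of class `"prephase"`.
#' @export
prephase <- function(hapA, hapB, imputed = NULL, raw = NULL) {
  hapA <- as.integer(hapA); hapB <- as.integer(hapB)
  if (length(hapA) != length(hapB)) stop("haplotype length mismatch")
  if (is.null(imputed)) imputed <- rep(FALSE, length(hapA))
  if (!is.null(raw)) {
    ok <- is.na(raw) | is.na(hapA) | is.na(hapB) | (hapA + hapB == raw)
    if (!all(ok)) stop("pre-phase inconsistent with raw calls at site ", which(!ok)[1L])
  }
  structure(list(hapA = hapA, hapB = hapB, imputed = imputed), class = "prephase")
}

#' Trivial frequency-based pre-phase
#'
#' A deliberately simple default pre-phase: missing proband calls are
#' imputed to the most likely genotype under Hardy-Weinberg proportions at
#' the database allele frequency, and heterozygous sites are oriented
#' uniformly at random. It supplies the interface a locally phased input
#' would (a defined haplotype pair at every site) with no local phasing
#' skill, so sites without IBD evidence are phased no better than chance.
#'
#' @param g A [genotype_matrix()] (the database, proband included).
#' @param proband Proband individual ID.
#' @param seed Integer seed for the random orientations.
#' @return A [prephase()].
#' @export
make_prephase <- function(g, proband, seed = NULL) {
  calls <- g$calls
  raw <- calls[proband, ]
  with_seed(seed, {
    f <- colMeans(calls, na.rm = TRUE) / 2
    f[is.na(f)] <- 0.5
    hw <- rbind((1 - f)^2, 2 * f * (1 - f), f^2)
    imp <- max.col(t(hw)) - 1L
    gcall <- ifelse(is.na(raw), imp, raw)
    flip <- stats::runif(length(gcall)) < 0.5
    hapA <- ifelse(gcall == 1L, ifelse(flip, 0L, 1L), gcall %/% 2L)
    hapB <- gcall - hapA
    prephase(hapA, hapB, imputed = is.na(raw), raw = raw)
  })
}

#' Write a phased genome to VCF
#'
#' Emits one sample with phased GT `a|b` (`.|.` where both haplotypes are
#' missing) and, when the phased object carries a corrections log, a
#' sidecar TSV with one row per overridden call.
#'
#' @param phased A `phased_genome` object (see [phase_genome()]) or a bare
#'   list with `hapA`, `hapB`.
#' @param panel The [site_panel()].
#' @param path Output path; written gzip-compressed (use a `.vcf.gz` name).
#' @param sample Sample name for the VCF column.
#' @param corrections_path Sidecar TSV path; default `<path>.corrections.tsv`.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(phased, panel, path, sample = "proband",
                             corrections_path = paste0(path, ".corrections.tsv")) {
  hapA <- phased$hapA; hapB <- phased$hapB
  if (length(hapA) != length(hapB) || length(hapA) != nrow(panel))
    stop("haplotype length mismatch")
  a <- ifelse(is.na(hapA), ".", as.character(hapA))
  b <- ifelse(is.na(hapB), ".", as.character(hapB))
  fix <- cbind(CHROM = panel$chrom, POS = as.character(panel$pos),
               ID = ".", REF = "A", ALT = "G", QUAL = ".", FILTER = ".", INFO = ".")
  gt <- cbind(FORMAT = "GT", paste0(a, "|", b))
  colnames(gt)[2L] <- sample
  meta <- c("##fileformat=VCFv4.2",
            paste0("##contig=<ID=", unique(panel$chrom), ">"),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  if (!is.null(phased$corrections) && nrow(phased$corrections)) {
    utils::write.table(phased$corrections, corrections_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a phased haplotype pair from a VCF
#'
#' Reads one sample's phased GT field aligned to `panel`; unphased
#' heterozygous records are rejected.
#'
#' @param path VCF path.
#' @param panel [site_panel()] to align to.
#' @param sample Sample name; default first sample.
#' @return List with integer vectors `hapA`, `hapB` (`NA` where missing).
#' @export
read_phased_vcf <- function(path, panel, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- colnames(v@gt)[-1L]
  if (is.null(sample)) sample <- ids[1L]
  gt <- sub(":.*$", "", v@gt[, sample])
  if (any(grepl("/", gt) & !gt %in% c("0/0", "1/1", "./.")))
    stop("unphased heterozygous GT in phased VCF")
  al <- strsplit(gt, "[|/]")
  a1 <- vapply(al, `[`, "", 1L); a2 <- vapply(al, `[`, "", 2L)
  hit <- match(paste(panel$chrom, panel$pos), paste(fix[, "CHROM"], fix[, "POS"]))
  num <- function(x) { x[x == "."] <- NA; as.integer(x) }
  list(hapA = num(a1[hit]), hapB = num(a2[hit]))
}

#' Read / write IBD segment tables
#'
#' Tab-separated with columns `proband_id`, `other_id`, `chrom`, `start`,
#' `end` (1-based closed site indices on the shared panel), `cm_length`
#' and `trimmed_cm`.
#'
#' @param segments data.frame of segments.
#' @param path File path.
#' @return `read_ibd_segments` returns the data.frame.
#' @export
write_ibd_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ibd_segments
#' @export
read_ibd_segments <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  m$chrom <- as.character(m$chrom)
  m
}
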