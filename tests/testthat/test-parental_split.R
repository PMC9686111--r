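# Builders for hand-crafted split instances: one chromosome, proband
# heterozygous everywhere, database individuals homozygous for a chosen
# haplotype pattern wherever informative.

split_fixture <- function(n_sites = 81, spacing = 0.25, seed = 1) {
  set.seed(seed)
  panel <- dense_panel(n_sites, spacing_cm = spacing)
  t_hapA <- sample(0:1, n_sites, replace = TRUE)
  list(panel = panel, t = t_hapA,
       proband = rep(1L, n_sites),
       pre = prephase(t_hapA, 1L - t_hapA))
}

hom_pattern <- function(t, side) if (side == 1) 2L * t else 2L * (1L - t)

seg_row <- function(id, start, end, panel) {
  data.frame(proband_id = "P", other_id = id, chrom = "1",
             start = start, end = end,
             cm_length = panel$cm[end] - panel$cm[start],
             trimmed_cm = panel$cm[end] - panel$cm[start],
             stringsAsFactors = FALSE)
}

test_that("endpoint weight is a sigmoid of distance to the nearer end", {
  panel <- dense_panel(101, spacing_cm = 0.1)  # 10 cM
  seg <- data.frame(start = 1L, end = 101L)
  ctl <- ibd_phase_control()
  expect_lte(endpoint_weight(seg, 1L, panel, ctl), 0.05)      # at the endpoint
  expect_equal(endpoint_weight(seg, 11L, panel, ctl), 0.5)    # d = d0 = 1 cM
  expect_gte(endpoint_weight(seg, 51L, panel, ctl), 0.999)    # >= 4 cM from ends
  expect_true(all(diff(endpoint_weight(seg, 1:51, panel, ctl)) >= 0))
  expect_error(endpoint_weight(seg, 102L, panel, ctl), "outside")
})

test_that("segments homozygous for opposite alleles land on opposite sides", {
  fx <- split_fixture()
  g <- gm(list(P = fx$proband,
               s1 = hom_pattern(fx$t, 1),
               s2 = hom_pattern(fx$t, 2)), fx$panel)
  segs <- rbind(seg_row("s1", 1L, 81L, fx$panel), seg_row("s2", 1L, 81L, fx$panel))
  asn <- assign_parental_groups(g, "P", segs, fx$pre)
  expect_equal(nrow(asn$fragments), 2L)
  expect_equal(length(unique(asn$fragments$side)), 2L)
  expect_equal(length(asn$breakpoints), 0L)
  expect_equal(length(asn$ignored_sites), 0L)
})

test_that("with no segments every site follows the pre-phase default", {
  fx <- split_fixture()
  g <- gm(list(P = fx$proband), fx$panel)
  asn <- assign_parental_groups(g, "P", seg_row("x", 1L, 81L, fx$panel)[0, ], fx$pre)
  expect_equal(nrow(asn$fragments), 0L)
  expect_equal(asn$orientation$allele_on_A, fx$pre$hapA)
  expect_false(any(asn$orientation$resolved))
})

test_that("an IBD2 segment is never assigned to either side", {
  fx <- split_fixture()
  g <- gm(list(P = fx$proband,
               s1 = hom_pattern(fx$t, 1),
               ibd2 = fx$proband), fx$panel)  # het wherever the proband is het
  segs <- rbind(seg_row("s1", 1L, 81L, fx$panel), seg_row("ibd2", 1L, 81L, fx$panel))
  asn <- assign_parental_groups(g, "P", segs, fx$pre)
  expect_equal(asn$unassigned, 2L)
  expect_false("ibd2" %in% asn$fragments$other_id)
})

test_that("the greedy scan attains the exhaustive minimum weighted change cost", {
  # 5 segments over 12 informative het sites; one segment's genotypes are
  # flipped in its right half, so the optimum is a single weighted break
  set.seed(3)
  n <- 61
  panel <- dense_panel(n, spacing_cm = 0.5)  # 30 cM
  t <- sample(0:1, n, replace = TRUE)
  het_sites <- 25:36  # >= 12 cM from both segment ends: full weight
  proband <- rep(0L, n); proband[het_sites] <- 1L
  mk <- function(side, flip_from = NA) {
    v <- rep(0L, n)
    v[het_sites] <- hom_pattern(t[het_sites], side)
    if (!is.na(flip_from)) {
      fl <- het_sites[het_sites >= flip_from]
      v[fl] <- hom_pattern(t[fl], 3 - side)
    }
    v
  }
  g <- gm(list(P = proband, s1 = mk(1), s2 = mk(1), s3 = mk(2), s4 = mk(2),
               s5 = mk(1, flip_from = het_sites[6])), panel)
  segs <- do.call(rbind, lapply(c("s1", "s2", "s3", "s4", "s5"),
                                seg_row, start = 1L, end = n, panel = panel))
  pre <- prephase(ifelse(proband == 1L, t, proband %/% 2L),
                  ifelse(proband == 1L, 1L - t, proband %/% 2L))
  ctl <- ibd_phase_control()
  asn <- assign_parental_groups(g, "P", segs, pre, ctl)

  # entry table for the oracle: same alleles and endpoint weights
  entries <- do.call(rbind, lapply(1:5, function(s) {
    oc <- g$calls[s + 1L, het_sites]
    w <- endpoint_weight(segs[s, ], het_sites, panel, ctl)
    data.frame(j = seq_along(het_sites), seg = s, allele = oc %/% 2L, w = w)
  }))
  greedy_seq <- asn$orientation$allele_on_A[match(het_sites, asn$orientation$site)]
  greedy_cost <- orientation_cost(greedy_seq, entries, 5L, ctl$min_assign_weight)
  best <- Inf
  for (mask in 0:(2^12 - 1L)) {
    o <- as.integer(intToBits(mask))[1:12]
    best <- min(best, orientation_cost(o, entries, 5L, ctl$min_assign_weight))
  }
  expect_equal(greedy_cost, best)
  frag5 <- asn$fragments[asn$fragments$other_id == "s5", ]
  expect_equal(nrow(frag5), 2L)
  expect_equal(length(unique(frag5$side)), 2L)
  expect_equal(length(asn$breakpoints), 1L)
  # all other segments stay in one piece
  expect_true(all(table(asn$fragments$seg_row[asn$fragments$other_id != "s5"]) == 1))
})

test_that("a false heterozygote with consistent neighbours is ignored", {
  fx <- split_fixture(seed = 5)
  m <- 41L
  mk <- function(side) {
    v <- hom_pattern(fx$t, side)
    v[m] <- 0L  # at the true hom-ref site every sharer is hom-ref
    v
  }
  g <- gm(list(P = fx$proband, a1 = mk(1), a2 = mk(1), a3 = mk(1),
               b1 = mk(2), b2 = mk(2), b3 = mk(2)), fx$panel)
  segs <- do.call(rbind, lapply(c("a1", "a2", "a3", "b1", "b2", "b3"),
                                seg_row, start = 1L, end = 81L, panel = fx$panel))
  asn <- assign_parental_groups(g, "P", segs, fx$pre)
  expect_true(m %in% asn$ignored_sites)
  expect_equal(length(asn$breakpoints), 0L)
  expect_equal(setdiff(asn$ignored_sites, m), numeric(0))
  # every genuine site past the low-weight leading ramp (where no segment is
  # yet eligible for assignment) keeps the evidence-driven orientation
  ok <- asn$orientation$site >= 5L & asn$orientation$site != m
  expect_true(all(asn$orientation$resolved[ok]))
})

test_that("a full-weight single-segment glitch triggers the lookahead", {
  fx <- split_fixture(seed = 7)
  m <- 41L
  glitch <- hom_pattern(fx$t, 1)
  glitch[m] <- hom_pattern(fx$t, 2)[m]
  g <- gm(list(P = fx$proband, a1 = hom_pattern(fx$t, 1), a2 = hom_pattern(fx$t, 1),
               b1 = hom_pattern(fx$t, 2), b2 = hom_pattern(fx$t, 2),
               s5 = glitch), fx$panel)
  segs <- do.call(rbind, lapply(c("a1", "a2", "b1", "b2", "s5"),
                                seg_row, start = 1L, end = 81L, panel = fx$panel))
  asn <- assign_parental_groups(g, "P", segs, fx$pre)
  expect_true(m %in% asn$ignored_sites)
  expect_equal(length(asn$breakpoints), 0L)
  expect_equal(nrow(asn$fragments[asn$fragments$other_id == "s5", ]), 1L)
})

test_that("a below-trigger glitch is accepted as a break instead", {
  fx <- split_fixture(seed = 9)
  # s5 ends at site 45; at site 41 its endpoint weight is 0.5 (< 1.0 trigger)
  m <- 41L
  glitch <- hom_pattern(fx$t, 1)
  glitch[m] <- hom_pattern(fx$t, 2)[m]
  g <- gm(list(P = fx$proband, a1 = hom_pattern(fx$t, 1), a2 = hom_pattern(fx$t, 1),
               b1 = hom_pattern(fx$t, 2), b2 = hom_pattern(fx$t, 2),
               s5 = glitch), fx$panel)
  segs <- rbind(
    do.call(rbind, lapply(c("a1", "a2", "b1", "b2"),
                          seg_row, start = 1L, end = 81L, panel = fx$panel)),
    seg_row("s5", 1L, 45L, fx$panel))
  asn <- assign_parental_groups(g, "P", segs, fx$pre)
  expect_gte(length(asn$breakpoints), 2L)  # flips out and back
  expect_equal(length(asn$ignored_sites), 0L)
  kept5 <- asn$fragments[asn$fragments$other_id == "s5" & asn$fragments$kept, ]
  expect_equal(nrow(kept5), 1L)  # retention keeps the long true piece
  expect_equal(kept5$side, asn$fragments$side[asn$fragments$other_id == "a1"])
})

test_that("planted proband genotype errors are ignored at roughly their rate", {
  panel <- sim_map(n_chrom = 4, chrom_cm = 60, spacing_cm = 0.03)
  sim <- sim_database(panel, n_aunts_per_side = 3, n_cousins_per_aunt = 2,
                      n_unrelated = 2, seed = 61)
  pert <- perturb_genotypes(sim$geno, missing_rate = 0, error_rate = 0.002,
                            individuals = sim$proband, seed = 62)
  segs <- detect_ibd_segments(pert$geno, sim$proband, sim$db_ids)
  pre <- make_prephase(pert$geno, sim$proband, seed = 63)
  asn <- assign_parental_groups(pert$geno, sim$proband, segs, pre)
  n_het <- nrow(asn$orientation)
  expect_lt(length(asn$ignored_sites) / n_het, 0.02)
})

test_that("the scan is deterministic", {
  panel <- sim_map(n_chrom = 2, chrom_cm = 60, spacing_cm = 0.04)
  sim <- sim_database(panel, n_aunts_per_side = 2, n_cousins_per_aunt = 1,
                      n_unrelated = 2, seed = 71)
  segs <- detect_ibd_segments(sim$geno, sim$proband, sim$db_ids)
  pre <- make_prephase(sim$geno, sim$proband, seed = 72)
  a <- assign_parental_groups(sim$geno, sim$proband, segs, pre)
  b <- assign_parental_groups(sim$geno, sim$proband, segs, pre)
  expect_identical(a, b)
})
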