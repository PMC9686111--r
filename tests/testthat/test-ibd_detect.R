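test_that("homozygosity bitmaps encode calls exactly", {
  panel <- dense_panel(4, spacing_cm = 0.1)
  g <- gm(list(a = c(0L, 1L, 2L, NA), b = rep(1L, 4)), panel)
  b <- homozygosity_bitmaps(g, "a")
  bits <- function(r, n) as.logical(rawToBits(r))[seq_len(n)]
  expect_equal(bits(b$hom_ref, 4), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(bits(b$hom_alt, 4), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(bits(b$missing, 4), c(FALSE, FALSE, FALSE, TRUE))
  allhet <- homozygosity_bitmaps(g, "b")
  expect_true(all(bits(allhet$hom_ref, 4) == FALSE))
  expect_true(all(bits(allhet$hom_alt, 4) == FALSE))
  expect_error(homozygosity_bitmaps(g, "zz"), "unknown individual")
})

test_that("bitmap popcounts equal direct genotype counts", {
  set.seed(42)
  panel <- dense_panel(1000, spacing_cm = 0.02)
  v <- sample(c(0L, 1L, 2L, NA), 1000, replace = TRUE)
  g <- gm(list(a = v), panel)
  b <- homozygosity_bitmaps(g, "a")
  pop <- function(r) sum(as.integer(rawToBits(r)))
  expect_equal(pop(b$hom_ref), sum(v == 0L, na.rm = TRUE))
  expect_equal(pop(b$hom_alt), sum(v == 2L, na.rm = TRUE))
  expect_equal(pop(b$missing), sum(is.na(v)))
})

test_that("a conflict-free dense 10 cM pair yields one segment over all sites", {
  panel <- dense_panel(501, spacing_cm = 0.02)  # exactly 10 cM
  g <- gm(list(a = rep(0L, 501), b = rep(0L, 501)), panel)
  seg <- detect_ibd_segments(g, "a", "b")
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 1L)
  expect_equal(seg$end, 501L)
  expect_equal(seg$cm_length, 10)
})

test_that("a single conflict halves a 12 cM region below the 8 cM threshold", {
  panel <- dense_panel(601, spacing_cm = 0.02)  # 12 cM
  a <- rep(0L, 601); b <- rep(0L, 601)
  b[301] <- 2L  # opposite homozygote at the midpoint
  g <- gm(list(a = a, b = b), panel)
  expect_equal(nrow(detect_ibd_segments(g, "a", "b")), 0L)
})

test_that("the density trim rejects gappy segments", {
  # two dense 2 cM clusters separated by a 5 cM void: raw length 9 cM
  # passes, but the trimmed length 4 cM fails the 5 cM floor
  cm <- c(seq(0, 2, by = 0.02), seq(7, 9, by = 0.02))
  panel <- site_panel(rep("1", length(cm)), seq_along(cm) * 1000L, cm)
  g <- gm(list(a = rep(0L, length(cm)), b = rep(0L, length(cm))), panel)
  seg <- detect_ibd_segments(g, "a", "b")
  expect_equal(nrow(seg), 0L)
  # the same geometry passes when only the raw length is required
  ctl <- ibd_phase_control(min_trimmed_cm = 0)
  seg2 <- detect_ibd_segments(g, "a", "b", ctl)
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$trimmed_cm, 4, tolerance = 1e-9)
})

test_that("missing calls never break a segment", {
  panel <- dense_panel(501, spacing_cm = 0.02)
  a <- rep(0L, 501); b <- rep(0L, 501)
  b[sample(501, 50)] <- NA
  g <- gm(list(a = a, b = b), panel)
  expect_equal(nrow(detect_ibd_segments(g, "a", "b")), 1L)
})

test_that("bitwise detection equals the naive per-site scan on random pairs", {
  set.seed(11)
  panel <- dense_panel(1500, spacing_cm = 0.02)
  for (rep in 1:20) {
    a <- sample(c(0L, 1L, 2L, NA), 1500, replace = TRUE, prob = c(.4, .3, .25, .05))
    b <- a
    # half the pairs share long stretches, half are unrelated noise
    if (rep %% 2 == 0) b <- sample(c(0L, 1L, 2L, NA), 1500, replace = TRUE,
                                   prob = c(.4, .3, .25, .05))
    else b[sample(1500, 400)] <- sample(c(0L, 1L, 2L), 400, replace = TRUE)
    g <- gm(list(a = a, b = b), panel)
    got <- detect_ibd_segments(g, "a", "b")
    ref <- naive_ibd_reference(g)
    expect_equal(got[, c("chrom", "start", "end", "cm_length", "trimmed_cm")],
                 ref, ignore_attr = TRUE)
  }
})

test_that("emitted segments never contain an opposite-homozygote site", {
  panel <- sim_map(n_chrom = 2, chrom_cm = 60, spacing_cm = 0.04)
  sim <- sim_database(panel, n_aunts_per_side = 2, n_cousins_per_aunt = 1,
                      n_unrelated = 3, seed = 23)
  segs <- detect_ibd_segments(sim$geno, sim$proband, sim$db_ids)
  gp <- sim$geno$calls[sim$proband, ]
  for (i in seq_len(nrow(segs))) {
    go <- sim$geno$calls[segs$other_id[i], segs$start[i]:segs$end[i]]
    gpp <- gp[segs$start[i]:segs$end[i]]
    expect_false(any((gpp == 0L & go == 2L) | (gpp == 2L & go == 0L), na.rm = TRUE))
  }
})

test_that("IBD2 runs respect the 5 cM floor and cover twins fully", {
  panel <- dense_panel(701, spacing_cm = 0.02)  # 14 cM
  a <- sample(c(0L, 1L, 2L), 701, replace = TRUE)
  b <- a
  b[301] <- if (a[301] == 0L) 1L else 0L  # one mismatch at 6 cM
  g <- gm(list(a = a, b = b), panel)
  runs <- detect_ibd2_runs(g, "a", "b")
  expect_equal(nrow(runs), 2L)          # 6 cM and 8 cM flanks both pass
  b2 <- a
  b2[c(201, 401)] <- ifelse(a[c(201, 401)] == 0L, 1L, 0L)
  runs2 <- detect_ibd2_runs(gm(list(a = a, b = b2), panel), "a", "b")
  expect_equal(nrow(runs2), 1L)  # only the 6 cM tail piece clears 5 cM
  # identical twins: runs cover the entire genome
  tw <- gm(list(a = a, b = a), panel)
  rt <- detect_ibd2_runs(tw, "a", "b")
  expect_equal(sum(rt$cm_length), genome_cm(panel))
})

test_that("relationship statistics distinguish twins, parents and unrelated pairs", {
  panel <- sim_map(n_chrom = 6, chrom_cm = 80, spacing_cm = 0.05)
  sim <- sim_database(panel, n_aunts_per_side = 0, n_cousins_per_aunt = 0,
                      n_twins = 1, n_unrelated = 2, seed = 37)
  g2 <- sim$geno
  pair_stats <- function(other) {
    segs <- detect_ibd_segments(g2, sim$proband, other)
    runs <- detect_ibd2_runs(g2, sim$proband, other)
    relationship_stats(g2, sim$proband, other, segs, runs)
  }
  tw <- pair_stats("TWIN01")
  expect_gte(tw$ibd2_run_fraction, 0.99)
  expect_gte(tw$ibd1_rate, 0.999)
  un <- pair_stats("UNREL01")
  expect_lt(un$ibd2_run_fraction, 0.05)
  # parent-child (outside db, but genotyped): IBD1 everywhere, no IBD2 excess
  pc <- pair_stats(sim$father)
  expect_gte(pc$ibd1_rate, 0.999)
  expect_gte(sum(detect_ibd_segments(g2, sim$proband, sim$father)$cm_length),
             0.97 * genome_cm(panel))
  g_empty <- gm(list(a = c(NA, NA), b = c(0L, 1L)), dense_panel(2, 0.1))
  expect_error(relationship_stats(g_empty, "a", "b",
                                  data.frame(cm_length = numeric(0)),
                                  data.frame(cm_length = numeric(0))),
               "comparable")
})

test_that("full siblings show about a quarter of the genome in IBD2 runs", {
  fr <- vapply(1:20, function(sd) {
    panel <- sim_map(n_chrom = 6, chrom_cm = 80, spacing_cm = 0.05)
    sim <- sim_database(panel, n_aunts_per_side = 0, n_cousins_per_aunt = 0,
                        include_grandparents = FALSE, n_siblings = 1,
                        n_unrelated = 0, seed = 100 + sd)
    runs <- detect_ibd2_runs(sim$geno, sim$proband, "SIB01")
    sum(runs$cm_length) / genome_cm(panel)
  }, numeric(1L))
  expect_lt(abs(mean(fr) - 0.25), 0.1)
})
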