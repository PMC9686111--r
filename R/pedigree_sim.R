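# Pedigree simulation: founder haplotypes drawn site-wise from an allele
# frequency spectrum, Mendelian transmission with Poisson-distributed
# crossovers placed uniformly in cM (no interference), transmission tracks
# (founder-haplotype labels) retained so true IBD is known exactly.

#' Build an evenly spaced simulation panel
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_cm Genetic length of each chromosome (cM); recycled.
#' @param spacing_cm Inter-SNP spacing (cM). The default 0.02 cM mimics a
#'   dense genotyping array.
#' @param bp_per_cm Physical scale used to synthesise bp positions.
#' @return A [site_panel()].
#' @export
sim_map <- function(n_chrom = 6L, chrom_cm = 100, spacing_cm = 0.02,
                    bp_per_cm = 1e6) {
  chrom_cm <- rep_len(chrom_cm, n_chrom)
  chrom <- character(0); pos <- integer(0); cm <- numeric(0)
  for (c in seq_len(n_chrom)) {
    v <- seq(0, chrom_cm[c], by = spacing_cm)
    chrom <- c(chrom, rep(as.character(c), length(v)))
    pos <- c(pos, as.integer(round(v * bp_per_cm)) + 1L)
    cm <- c(cm, v)
  }
  site_panel(chrom, pos, cm)
}

# One gamete: mosaic of the parent's two haplotypes with Poisson(L/100)
# crossovers per chromosome, uniform in cM. Returns hap, track, #crossovers.
sim_meiosis <- function(parent, panel, blocks = panel_blocks(panel)) {
  S <- nrow(panel)
  hap <- integer(S); trk <- integer(S); nxo <- 0L
  for (ix in blocks) {
    cms <- panel$cm[ix]
    L <- cms[length(cms)] - cms[1L]
    k <- stats::rpois(1L, L / 100)
    nxo <- nxo + k
    sel <- if (k > 0L) {
      xo <- sort(stats::runif(k, cms[1L], cms[length(cms)]))
      (sample(0:1, 1L) + findInterval(cms, xo)) %% 2L + 1L
    } else rep(sample(1:2, 1L), length(ix))
    hap[ix] <- parent$h[cbind(sel, ix)]
    trk[ix] <- parent$t[cbind(sel, ix)]
  }
  list(hap = hap, trk = trk, nxo = nxo)
}

# Mutable simulation state: haplotypes (2 x S, row 1 paternal), tracks,
# pedigree rows, next founder-haplotype label.
sim_state <- function(panel, freqs) {
  e <- new.env(parent = emptyenv())
  e$panel <- panel
  e$blocks <- panel_blocks(panel)
  e$freqs <- freqs
  e$h <- list(); e$t <- list()
  e$ped <- list()
  e$next_label <- 1L
  e$crossovers <- integer(0)
  e
}

sim_add_founder <- function(st, id) {
  S <- nrow(st$panel)
  h <- rbind(stats::rbinom(S, 1L, st$freqs), stats::rbinom(S, 1L, st$freqs))
  st$h[[id]] <- h
  st$t[[id]] <- rbind(rep(st$next_label, S), rep(st$next_label + 1L, S))
  st$next_label <- st$next_label + 2L
  st$ped[[id]] <- data.frame(id = id, father = NA_character_,
                             mother = NA_character_, stringsAsFactors = FALSE)
  id
}

sim_add_child <- function(st, id, father, mother) {
  gp <- sim_meiosis(list(h = st$h[[father]], t = st$t[[father]]), st$panel, st$blocks)
  gm <- sim_meiosis(list(h = st$h[[mother]], t = st$t[[mother]]), st$panel, st$blocks)
  st$h[[id]] <- rbind(gp$hap, gm$hap)
  st$t[[id]] <- rbind(gp$trk, gm$trk)
  st$crossovers <- c(st$crossovers, gp$nxo, gm$nxo)
  st$ped[[id]] <- data.frame(id = id, father = father, mother = mother,
                             stringsAsFactors = FALSE)
  id
}

sim_finish <- function(st, ids = names(st$h)) {
  calls <- t(vapply(ids, function(i) st$h[[i]][1L, ] + st$h[[i]][2L, ],
                    integer(nrow(st$panel))))
  rownames(calls) <- ids
  truth <- structure(list(haps = st$h, tracks = st$t,
                          pedigree = do.call(rbind, st$ped),
                          panel = st$panel, crossovers = st$crossovers),
                     class = "sim_truth")
  list(geno = genotype_matrix(calls, st$panel), truth = truth)
}

#' Simulate a random-mating population
#'
#' Founders are drawn site-wise from the allele-frequency spectrum; each
#' subsequent generation has the same size, every child from a random pair
#' of distinct parents in the previous generation. With zero generations
#' only founders are returned.
#'
#' @param panel A [site_panel()], e.g. from [sim_map()].
#' @param n_founders Number of founders.
#' @param n_generations Number of offspring generations.
#' @param freqs Per-site alternate-allele frequencies; default drawn from
#'   Uniform(0.05, 0.5).
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   simulation bit-exactly.
#' @return List with `geno` (a [genotype_matrix()]) and `truth`
#'   (haplotypes, transmission tracks, pedigree, crossover counts).
#' @export
simulate_population <- function(panel, n_founders = 20L, n_generations = 2L,
                                freqs = NULL, seed = NULL) {
  with_seed(seed, {
    if (is.null(freqs)) freqs <- stats::runif(nrow(panel), 0.05, 0.5)
    st <- sim_state(panel, freqs)
    prev <- vapply(seq_len(n_founders),
                   function(i) sim_add_founder(st, sprintf("F%03d", i)), "")
    for (gen in seq_len(n_generations)) {
      cur <- character(n_founders)
      for (i in seq_len(n_founders)) {
        pr <- sample(prev, 2L)
        cur[i] <- sim_add_child(st, sprintf("G%d_%03d", gen, i), pr[1L], pr[2L])
      }
      prev <- cur
    }
    sim_finish(st)
  })
}

#' Simulate a proband, relatives and database with known truth
#'
#' Builds a focal proband with parents and four grandparents, plus planted
#' relatives of chosen kinds, and unrelated individuals, so IBD coverage of
#' the proband can be dialled from zero to dense. The proband's parents are
#' never part of the database (they are held out for trio evaluation).
#'
#' @param panel A [site_panel()].
#' @param n_aunts_per_side Aunts/uncles (further children of each pair of
#'   grandparents).
#' @param n_cousins_per_aunt Children of each aunt/uncle with an unrelated
#'   spouse.
#' @param include_grandparents Put the four grandparents in the database.
#' @param n_siblings Full siblings of the proband (descendants of both
#'   parents; normally discarded by the relative filter).
#' @param n_twins Identical twins (copies of the proband's haplotypes).
#' @param n_nephews Children of the first sibling with an unrelated spouse
#'   (a sibling is created if needed but only entered in the database when
#'   `n_siblings > 0`).
#' @param n_unrelated Unrelated founders in the database.
#' @param spouses_in_db Also place the aunts'/sibling's spouses in the
#'   database (they are unrelated to the proband).
#' @param freqs,seed As in [simulate_population()].
#' @return List with `geno`, `truth`, `proband`, `father`, `mother`,
#'   `db_ids`, and `roles` (a named character vector id -> role).
#' @export
sim_database <- function(panel,
                         n_aunts_per_side = 4L,
                         n_cousins_per_aunt = 2L,
                         include_grandparents = TRUE,
                         n_siblings = 0L,
                         n_twins = 0L,
                         n_nephews = 0L,
                         n_unrelated = 10L,
                         spouses_in_db = FALSE,
                         freqs = NULL, seed = NULL) {
  with_seed(seed, {
    if (is.null(freqs)) freqs <- stats::runif(nrow(panel), 0.05, 0.5)
    st <- sim_state(panel, freqs)
    roles <- character(0)
    add <- function(id, role) { roles[id] <<- role; id }

    gps <- c("PGF", "PGM", "MGF", "MGM")
    for (id in gps) add(sim_add_founder(st, id), "grandparent")
    father <- add(sim_add_child(st, "FATHER", "PGF", "PGM"), "parent")
    mother <- add(sim_add_child(st, "MOTHER", "MGF", "MGM"), "parent")
    proband <- add(sim_add_child(st, "PROBAND", father, mother), "proband")

    db <- character(0)
    if (include_grandparents) db <- c(db, gps)

    spouses <- character(0)
    for (side in c("P", "M")) {
      gpair <- if (side == "P") c("PGF", "PGM") else c("MGF", "MGM")
      for (a in seq_len(n_aunts_per_side)) {
        aid <- add(sim_add_child(st, sprintf("AUNT_%s%02d", side, a),
                                 gpair[1L], gpair[2L]), "aunt")
        db <- c(db, aid)
        if (n_cousins_per_aunt > 0L) {
          sp <- add(sim_add_founder(st, sprintf("SP_%s%02d", side, a)), "spouse")
          spouses <- c(spouses, sp)
          for (k in seq_len(n_cousins_per_aunt)) {
            cid <- add(sim_add_child(st, sprintf("COUSIN_%s%02d_%d", side, a, k),
                                     aid, sp), "cousin")
            db <- c(db, cid)
          }
        }
      }
    }

    need_sib <- max(n_siblings, if (n_nephews > 0L) 1L else 0L)
    sibs <- character(0)
    for (s in seq_len(need_sib)) {
      sid <- add(sim_add_child(st, sprintf("SIB%02d", s), father, mother), "sibling")
      sibs <- c(sibs, sid)
      if (s <= n_siblings) db <- c(db, sid)
    }
    if (n_nephews > 0L) {
      sp <- add(sim_add_founder(st, "SP_SIB"), "spouse")
      spouses <- c(spouses, sp)
      for (k in seq_len(n_nephews)) {
        nid <- add(sim_add_child(st, sprintf("NEPHEW%02d", k), sibs[1L], sp), "nephew")
        db <- c(db, nid)
      }
    }
    for (tw in seq_len(n_twins)) {
      id <- sprintf("TWIN%02d", tw)
      st$h[[id]] <- st$h[[proband]]
      st$t[[id]] <- st$t[[proband]]
      st$ped[[id]] <- data.frame(id = id, father = father, mother = mother,
                                 stringsAsFactors = FALSE)
      add(id, "twin")
      db <- c(db, id)
    }
    for (u in seq_len(n_unrelated)) {
      uid <- add(sim_add_founder(st, sprintf("UNREL%02d", u)), "unrelated")
      db <- c(db, uid)
    }
    if (spouses_in_db) db <- c(db, spouses)

    out <- sim_finish(st)
    out$proband <- proband; out$father <- father; out$mother <- mother
    out$db_ids <- db; out$roles <- roles
    out
  })
}

#' True IBD segments from transmission tracks
#'
#' Maximal intervals where two individuals carry the same founder-haplotype
#' label on at least one of their haplotypes, at least `min_cm` long.
#'
#' @param truth `truth` element of a simulation result.
#' @param a,b Individual IDs.
#' @param min_cm Minimum genetic length.
#' @return data.frame with `chrom`, `start`, `end` (site indices) and
#'   `cm_length`.
#' @export
true_ibd_segments <- function(truth, a, b, min_cm = 8) {
  ta <- truth$tracks[[a]]; tb <- truth$tracks[[b]]
  if (is.null(ta) || is.null(tb)) stop("unknown individual")
  m <- (ta[1L, ] == tb[1L, ]) | (ta[1L, ] == tb[2L, ]) |
       (ta[2L, ] == tb[1L, ]) | (ta[2L, ] == tb[2L, ])
  panel <- truth$panel
  out <- list()
  for (cc in names(panel_blocks(panel))) {
    ix <- panel_blocks(panel)[[cc]]
    runs <- true_runs(m[ix])
    if (!nrow(runs)) next
    st <- ix[runs[, "start"]]; en <- ix[runs[, "end"]]
    cml <- panel$cm[en] - panel$cm[st]
    keep <- cml >= min_cm
    if (any(keep)) out[[cc]] <- data.frame(chrom = cc, start = st[keep],
                                           end = en[keep], cm_length = cml[keep],
                                           stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0), cm_length = numeric(0)))
  out <- do.call(rbind, out); rownames(out) <- NULL
  out
}

#' True parental side of labelled fragments
#'
#' For each fragment of IBD shared between the proband and `other`, decides
#' from the transmission tracks whether the shared haplotype sits on the
#' proband's paternal (1) or maternal (2) haplotype, by majority over the
#' fragment's sites.
#'
#' @param truth Simulation truth.
#' @param proband Proband ID.
#' @param fragments data.frame with columns `other_id`, `start`, `end`.
#' @return Integer vector of sides (1 paternal, 2 maternal; `NA` if the
#'   fragment matches neither track).
#' @export
true_fragment_sides <- function(truth, proband, fragments) {
  tp <- truth$tracks[[proband]]
  vapply(seq_len(nrow(fragments)), function(i) {
    to <- truth$tracks[[fragments$other_id[i]]]
    s <- fragments$start[i]:fragments$end[i]
    m1 <- sum(tp[1L, s] == to[1L, s] | tp[1L, s] == to[2L, s])
    m2 <- sum(tp[2L, s] == to[1L, s] | tp[2L, s] == to[2L, s])
    if (m1 == 0L && m2 == 0L) return(NA_integer_)
    if (m1 >= m2) 1L else 2L
  }, integer(1L))
}

#' Plant missing calls and genotype errors
#'
#' Replaces a fraction of calls with missing data and flips a fraction of
#' calls between heterozygous and homozygous states: a heterozygous call
#' becomes one of the two homozygotes (equiprobably); a homozygous call
#' always becomes heterozygous. Sites selected for both perturbations are
#' resolved missing-first.
#'
#' @param g A [genotype_matrix()].
#' @param missing_rate,error_rate Per-call perturbation probabilities.
#' @param individuals Rows to perturb (default: all).
#' @param seed Integer seed.
#' @return List with `geno` (perturbed) and `log` (data.frame: `id`,
#'   `site`, `kind`, `original`, `new`).
#' @export
perturb_genotypes <- function(g, missing_rate = 0.01, error_rate = 0.002,
                              individuals = rownames(g$calls), seed = NULL) {
  stopifnot(missing_rate >= 0, missing_rate <= 1, error_rate >= 0, error_rate <= 1)
  with_seed(seed, {
    calls <- g$calls
    logs <- list()
    for (id in individuals) {
      v <- calls[id, ]
      S <- length(v)
      miss <- which(stats::runif(S) < missing_rate & !is.na(v))
      err <- which(stats::runif(S) < error_rate & !is.na(v))
      err <- setdiff(err, miss)  # overlap resolved missing-first
      new_err <- ifelse(v[err] == 1L,
                        2L * stats::rbinom(length(err), 1L, 0.5),
                        1L)
      if (length(miss))
        logs[[paste0(id, ".m")]] <- data.frame(id = id, site = miss, kind = "missing",
                                               original = v[miss], new = NA_integer_,
                                               stringsAsFactors = FALSE)
      if (length(err))
        logs[[paste0(id, ".e")]] <- data.frame(id = id, site = err, kind = "error",
                                               original = v[err], new = as.integer(new_err),
                                               stringsAsFactors = FALSE)
      v[miss] <- NA_integer_
      v[err] <- as.integer(new_err)
      calls[id, ] <- v
    }
    log <- if (length(logs)) do.call(rbind, logs) else
      data.frame(id = character(0), site = integer(0), kind = character(0),
                 original = integer(0), new = integer(0))
    rownames(log) <- NULL
    list(geno = genotype_matrix(calls, g$sites), log = log)
  })
}
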