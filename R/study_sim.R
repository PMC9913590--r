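#' Simulate a study-like four-population microsatellite panel
#'
#' Generates a synthetic raw dataset emulating the sampling design of the
#' introduced-pike study: four populations (three of species 1 --
#' an introduced lake population `FLU`, and reference populations `TRA`
#' and `CAR`; one of species 2, `DRA`), genotyped at a 16-locus
#' microsatellite panel. Allele frequencies follow a hierarchical
#' F-model: per-locus ancestral frequencies (Dirichlet broken-stick),
#' species-level drift with `F_sp`, population-level drift with `F_pop`,
#' then Hardy-Weinberg genotype sampling. Defaults target the study
#' conditions: 2-33 alleles per locus, within-population expected
#' heterozygosity around 0.38-0.58, between-species theta around
#' 0.32-0.48 and within-species theta around 0.2-0.37.
#'
#' The raw panel carries the study's defects: one monomorphic locus,
#' four loci with more than 12% missing data in at least one population
#' (so the standard filter removes five of the sixteen loci), and
#' allelic dropout at rates low for most loci but 0.15-0.39 for a few.
#'
#' @param seed integer RNG seed.
#' @param n named sample sizes per population.
#' @param n_loci panel size (default 16).
#' @param f_sp species-level drift (default 0.25).
#' @param f_pop population-level drift, named per population; the
#'   introduced lake population is the least drifted (highest
#'   diversity), the supportively-bred lake population the most.
#' @param background_missing per-call missing probability outside the
#'   high-missing loci (default 0.01).
#' @return list with `table` (raw `geno_tab`), `species` (named map
#'   population -> species), `dropout` (true per-locus rates),
#'   `roles` (per-locus: "ok", "monomorphic", "high_missing",
#'   "high_dropout").
#' @export
simulate_study <- function(seed = 1L,
                           n = c(FLU = 58L, TRA = 20L, CAR = 28L, DRA = 22L),
                           n_loci = 16L, f_sp = 0.25,
                           f_pop = c(FLU = 0.12, TRA = 0.35, CAR = 0.28,
                                     DRA = 0.15),
                           background_missing = 0.01) {
  set.seed(seed)
  pops <- names(n)
  species <- c(FLU = 1L, TRA = 1L, CAR = 1L, DRA = 2L)[pops]
  f_pop <- f_pop[pops]
  loci <- sprintf("loc%02d", seq_len(n_loci))
  roles <- rep("ok", n_loci)
  roles[2] <- "monomorphic"
  hm <- c(5, 9, 13, 16)[c(5, 9, 13, 16) <= n_loci]
  roles[hm] <- "high_missing"
  dropout <- stats::runif(n_loci, 0, 0.06)
  hd <- c(7, 9, 13, 16)[c(7, 9, 13, 16) <= n_loci]   # locus 7 retained, high dropout
  dropout[hd] <- c(0.15, 0.2, 0.3, 0.39)[seq_along(hd)]
  dropout[2] <- 0
  # allele counts per locus, 2-33 with a long right tail
  k <- pmin(pmax(round(stats::rlnorm(n_loci, log(12), 0.45)), 4L), 33L)
  k[which.max(k)] <- 33L
  k[2] <- 1L
  csp <- (1 - f_sp) / f_sp
  cpop <- (1 - f_pop) / f_pop
  a1 <- a2 <- matrix(NA_integer_, sum(n), n_loci)
  popv <- rep(pops, n)
  rdir <- function(alpha) { g <- stats::rgamma(length(alpha), alpha); g / sum(g) }
  for (j in seq_len(n_loci)) {
    if (k[j] == 1L) {
      a1[, j] <- a2[, j] <- 150L
      next
    }
    labs <- sort(sample(seq(100L, 100L + 4L * (k[j] + 10L), by = 2L), k[j]))
    for (try in 1:20) {
      base <- rdir(rep(2, k[j]))
      fsp1 <- rdir(csp * base); fsp2 <- rdir(csp * base)
      for (p in seq_along(pops)) {
        fp <- rdir(cpop[p] * (if (species[p] == 1L) fsp1 else fsp2))
        i <- which(popv == pops[p])
        g <- matrix(sample.int(k[j], 2L * length(i), replace = TRUE, prob = fp),
                    ncol = 2)
        a1[i, j] <- labs[g[, 1]]; a2[i, j] <- labs[g[, 2]]
      }
      if (length(unique(c(a1[, j], a2[, j]))) >= 2L) break
    }
    # allelic dropout: each copy drops independently with rate d
    d <- dropout[j]
    if (d > 0) {
      for (i in seq_len(nrow(a1))) {
        d1 <- stats::runif(1) < d; d2 <- stats::runif(1) < d
        if (d1 && d2) { a1[i, j] <- NA; a2[i, j] <- NA }
        else if (d1) a1[i, j] <- a2[i, j]
        else if (d2) a2[i, j] <- a1[i, j]
      }
    }
    # missingness: background everywhere, heavy in one population at the
    # designated high-missing loci (a guaranteed >12% fraction there)
    drop_call <- stats::runif(length(popv)) < background_missing
    if (roles[j] == "high_missing") {
      hit <- sample(pops, 1)
      i <- which(popv == hit)
      m <- ceiling(stats::runif(1, 0.15, 0.3) * length(i))
      drop_call[sample(i, m)] <- TRUE
    }
    a1[drop_call, j] <- NA; a2[drop_call, j] <- NA
  }
  tab <- genotype_table(sprintf("%s_%02d", popv, unlist(lapply(n, seq_len))),
                        popv, a1, a2, loci)
  list(table = tab, species = stats::setNames(species, pops),
       dropout = stats::setNames(dropout, loci),
       roles = stats::setNames(roles, loci))
}

#' Wright-Fisher sample for estimator validation
#'
#' Single isolated population evolved under the island simulator
#' machinery (no migration), sampled after enough generations for
#' drift-generated linkage disequilibrium among unlinked loci to
#' equilibrate.
#'
#' @param N true (effective) number of breeders in the final
#'   generation(s) -- the quantity the LD method estimates.
#' @param S sample size; when `S > N` the sample is drawn as one
#'   offspring generation of size `S` produced by the `N` breeders
#'   (a juvenile sample from a small breeding population).
#' @param loci number of unlinked loci.
#' @param generations generations run at the ancestral size (default 60).
#' @param k allelic states (KAM).
#' @param mu mutation rate.
#' @param seed integer RNG seed.
#' @param N0 ancestral population size (default `N`). When `N0 > N` the
#'   population runs at `N0` and is then bottlenecked to `N` breeders
#'   for `bottleneck_generations` final generations -- a recently small
#'   breeding population that still carries ancestral diversity.
#' @param bottleneck_generations generations spent at size `N` after the
#'   bottleneck (default 2).
#' @return a `geno_tab` with one population `A1` of `S` individuals.
#' @export
wright_fisher_sample <- function(N, S = N, loci = 20L, generations = 60L,
                                 k = 12L, mu = 1e-3, seed = 1L, N0 = N,
                                 bottleneck_generations = 2L) {
  cfg <- island_config(demes = 1L, pops_per_deme = 1L, N = max(N0, N),
                       m_within = 0, m_between = 0, loci = loci,
                       mutation = "KAM", k = k, mu = mu,
                       generations = generations, seed = seed)
  tab <- simulate_island(cfg)
  A1 <- tab$a1; A2 <- tab$a2
  set.seed(seed + 1L)
  breed <- function(A1, A2, n_off) {
    n_par <- nrow(A1)
    mo <- sample.int(n_par, n_off, replace = TRUE)
    fa <- sample.int(n_par, n_off, replace = TRUE)
    gam <- function(par) {
      use1 <- matrix(stats::runif(n_off * loci) < 0.5, n_off, loci)
      out <- A2[par, , drop = FALSE]
      out[use1] <- A1[par, , drop = FALSE][use1]
      out
    }
    list(a1 = gam(mo), a2 = gam(fa))
  }
  if (N0 > N) {
    idx <- sample.int(nrow(A1), N)
    A1 <- A1[idx, , drop = FALSE]; A2 <- A2[idx, , drop = FALSE]
    for (g in seq_len(max(bottleneck_generations - 1L, 0L))) {
      off <- breed(A1, A2, N)
      A1 <- off$a1; A2 <- off$a2
    }
  }
  if (S <= nrow(A1) && N0 == N) {
    idx <- sample.int(nrow(A1), S)
    return(genotype_table(sprintf("A1_%03d", seq_len(S)), rep("A1", S),
                          A1[idx, , drop = FALSE], A2[idx, , drop = FALSE],
                          tab$loci))
  }
  off <- breed(A1, A2, S)
  genotype_table(sprintf("A1_%03d", seq_len(S)), rep("A1", S),
                 off$a1, off$a2, tab$loci)
}
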