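#' Genotypic class definitions for hybrid assignment
#'
#' Each class is defined by its gene-origin probability vector
#' `(z11, z12, z22)`: the probability that a random gene-copy pair of an
#' individual carries both copies from species 1, one copy from each, or
#' both from species 2. The roster covers pure parentals (P1, P2), F1 and
#' F2 hybrids, and first- and second-generation backcrosses towards each
#' parent (P1_bx, P1_bx1, P2_bx, P2_bx1).
#'
#' @return data.frame with columns `label`, `z11`, `z12`, `z22`,
#'   `pool1_share` (expected fraction of the genome from pool 1).
#' @export
hybrid_classes <- function() {
  data.frame(
    label = c("P1", "P2", "F1", "F2", "P1_bx", "P1_bx1", "P2_bx", "P2_bx1"),
    z11 = c(1, 0, 0, 0.25, 0.5, 0.75, 0, 0),
    z12 = c(0, 0, 1, 0.5, 0.5, 0.25, 0.5, 0.25),
    z22 = c(0, 1, 0, 0.25, 0, 0, 0.5, 0.75),
    pool1_share = c(1, 0, 0.5, 0.5, 0.75, 0.875, 0.25, 0.125),
    stringsAsFactors = FALSE)
}

#' Simulate offspring by multinomial gamete sampling
#'
#' Each offspring draws, at every locus independently, one gamete from
#' each parental pool; the gamete's allele is a multinomial draw from the
#' pool's allele frequencies. Pools are `allele_freqs` restricted to one
#' population (see [pool_freqs()]) and may themselves come from
#' previously simulated cohorts, which is how multi-generation crosses
#' (F2, backcrosses) are built.
#'
#' @param freqA,freqB single-population `allele_freqs` sharing a locus
#'   panel.
#' @param n number of offspring.
#' @param seed integer RNG seed.
#' @param pop population label for the offspring (default "SIM").
#' @param id_prefix prefix for offspring ids.
#' @return a `geno_tab` of `n` offspring. Loci undefined in either pool
#'   yield missing calls.
#' @export
hybridise <- function(freqA, freqB, n, seed = 1L, pop = "SIM",
                      id_prefix = pop) {
  if (!identical(freqA$loci, freqB$loci)) stop("locus panels differ between pools")
  set.seed(seed)
  L <- length(freqA$loci)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  draw <- function(f, n) {
    labs <- as.integer(colnames(f))
    pr <- as.numeric(f[1, ])
    if (anyNA(pr)) return(rep(NA_integer_, n))
    labs[sample.int(length(labs), n, replace = TRUE, prob = pr)]
  }
  for (j in seq_len(L)) {
    a1[, j] <- draw(freqA$freq[[j]], n)
    a2[, j] <- draw(freqB$freq[[j]], n)
  }
  genotype_table(sprintf("%s_%03d", id_prefix, seq_len(n)), rep(pop, n),
                 a1, a2, freqA$loci)
}

#' Simulate cohorts for a roster of genotypic classes
#'
#' Builds each requested class by multinomial gamete sampling with the
#' standard crossing topology: F1 = pool1 x pool2; F2 = F1 x F1;
#' first-generation backcross = parental pool x F1; second-generation
#' backcross = parental pool x first backcross. Each intermediate cohort
#' contributes its empirical allele frequencies as the gamete pool of the
#' next stage.
#'
#' @param freq1,freq2 single-population `allele_freqs` of the two
#'   parental reference pools (species 1 and species 2).
#' @param roster named integer vector of cohort sizes per class label
#'   (subset of [hybrid_classes()] labels).
#' @param seed integer RNG seed.
#' @param aux_n cohort size used for intermediate pools that are not
#'   themselves requested (default 200).
#' @return list with `table` (a `geno_tab`, one population per class) and
#'   `truth` (character vector of class labels per individual).
#' @export
simulate_classes <- function(freq1, freq2, roster, seed = 1L, aux_n = 200L) {
  labs <- names(roster)
  bad <- setdiff(labs, hybrid_classes()$label)
  if (length(bad)) stop("unknown class labels: ", paste(bad, collapse = ", "))
  if (any(roster <= 0)) stop("class counts must be positive")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 16)
  cohort <- list(); pool <- list(P1 = freq1, P2 = freq2)
  want <- function(lab) if (lab %in% labs) roster[[lab]] else aux_n
  mk <- function(lab, fa, fb, s) {
    tab <- hybridise(fa, fb, want(lab), seed = s, pop = lab)
    cohort[[lab]] <<- tab
    pool[[lab]] <<- pool_freqs(allele_freqs(tab), lab)
  }
  need_f1 <- any(c("F1", "F2", "P1_bx", "P1_bx1", "P2_bx", "P2_bx1") %in% labs)
  if ("P1" %in% labs) mk("P1", pool$P1, pool$P1, seeds[1])
  if ("P2" %in% labs) mk("P2", pool$P2, pool$P2, seeds[2])
  if (need_f1) mk("F1", pool$P1, pool$P2, seeds[3])
  if ("F2" %in% labs) mk("F2", pool$F1, pool$F1, seeds[4])
  if (any(c("P1_bx", "P1_bx1") %in% labs)) mk("P1_bx", pool$P1, pool$F1, seeds[5])
  if ("P1_bx1" %in% labs) mk("P1_bx1", pool$P1, pool$P1_bx, seeds[6])
  if (any(c("P2_bx", "P2_bx1") %in% labs)) mk("P2_bx", pool$P2, pool$F1, seeds[7])
  if ("P2_bx1" %in% labs) mk("P2_bx1", pool$P2, pool$P2_bx, seeds[8])
  cohort <- cohort[labs]
  tab <- do.call(bind_tables, cohort)
  list(table = tab, truth = tab$pop)
}

#' Sample a mixture from a labelled pool
#'
#' Uniform sampling without replacement; ground-truth labels follow the
#' sampled individuals.
#'
#' @param pool a `geno_tab`.
#' @param truth character vector of class labels, one per individual.
#' @param n mixture size (`0 <= n <=` pool size).
#' @param seed integer RNG seed.
#' @param pop population label given to the mixture (default "MIX").
#' @return list with `table` and `truth`.
#' @export
sample_mixture <- function(pool, truth, n, seed = 1L, pop = "MIX") {
  if (n > n_ind(pool)) stop("mixture size exceeds pool size")
  set.seed(seed)
  idx <- sample.int(n_ind(pool), n)
  tab <- pool[idx, ]
  tab$pop <- rep(pop, n)
  list(table = tab, truth = truth[idx])
}

#' Build the hatchery-introgression scenario (S1)
#'
#' Simulates `per_class` individuals for each roster class by gamete
#' sampling from two reference populations, samples a mixture of
#' `mixture` individuals uniformly without replacement, and assembles the
#' mixture together with the untouched reference populations for
#' analysis. The default roster (pure southern pike, F1, F2 and first-
#' and second-generation backcrosses towards the southern parent) has
#' five classes of 100, a 500-individual pool.
#'
#' @param x a `geno_tab` containing the two reference populations.
#' @param ref1,ref2 population labels of the species-1 and species-2
#'   references.
#' @param roster character vector of class labels to simulate.
#' @param per_class individuals per class (default 100).
#' @param mixture mixture sample size (default 50).
#' @param seed integer RNG seed.
#' @return list with `analysis` (`geno_tab` of ref1 + ref2 + mixture
#'   population "MIX"), `truth` (labels of the mixture individuals),
#'   `pool`, `pool_truth`.
#' @export
build_s1 <- function(x, ref1, ref2,
                     roster = c("P1", "F1", "F2", "P1_bx", "P1_bx1"),
                     per_class = 100L, mixture = 50L, seed = 1L) {
  af <- allele_freqs(x)
  f1 <- pool_freqs(af, ref1); f2 <- pool_freqs(af, ref2)
  sim <- simulate_classes(f1, f2, stats::setNames(rep(per_class, length(roster)),
                                                  roster), seed = seed)
  if (mixture > n_ind(sim$table)) stop("mixture size exceeds simulated pool")
  mix <- sample_mixture(sim$table, sim$truth, mixture, seed = seed + 1L)
  refs <- x[x$pop %in% c(ref1, ref2), ]
  analysis <- bind_with_union(refs, mix$table)
  list(analysis = analysis, truth = mix$truth,
       pool = sim$table, pool_truth = sim$truth)
}

# bind tables whose allele registries may differ (same loci)
bind_with_union <- function(a, b) {
  loci <- a$loci
  if (!identical(loci, b$loci)) stop("locus panels differ")
  genotype_table(c(a$id, b$id), c(a$pop, b$pop),
                 rbind(a$a1, b$a1), rbind(a$a2, b$a2), loci)
}
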