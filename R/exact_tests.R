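#' Hardy-Weinberg exact test by Markov-chain Monte Carlo
#'
#' One-sided exact test of Hardy-Weinberg proportions for one
#' (population, locus), conditional on the observed allele counts,
#' evaluated with the Guo-Thompson switch chain. The ordering statistic
#' is the heterozygote count: the heterozygote-deficit p-value is the
#' null probability of genotype tables with as few or fewer heterozygotes
#' than observed; the excess test mirrors it.
#'
#' @param x a `geno_tab`.
#' @param pop population label.
#' @param locus locus name or index.
#' @param direction `"deficit"` or `"excess"` (which departure is the
#'   alternative).
#' @param mc list of Markov-chain parameters: `demem` dememorization
#'   steps, `batches`, `iters` steps per batch (defaults 10000, 100,
#'   10000; the standard error comes from the batch means).
#' @param seed integer RNG seed.
#' @return list with `p`, `se`, `defined`, `n` (individuals used),
#'   `k` (alleles). A locus monomorphic in the population gives
#'   `defined = FALSE` and `p = NA` (excluded from batteries, never a
#'   silent p = 1).
#' @export
hw_exact_test <- function(x, pop, locus, direction = c("deficit", "excess"),
                          mc = list(demem = 10000, batches = 100, iters = 10000),
                          seed = 1L) {
  direction <- match.arg(direction)
  if (is.character(locus)) locus <- match(locus, x$loci)
  i <- x$pop == pop
  a1 <- x$a1[i, locus]; a2 <- x$a2[i, locus]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  al <- sort(unique(c(a1, a2)))
  und <- list(p = NA_real_, se = NA_real_, defined = FALSE,
              n = length(a1), k = length(al))
  if (length(a1) < 2L || length(al) < 2L) return(und)
  g1 <- match(a1, al) - 1L; g2 <- match(a2, al) - 1L
  set.seed(seed)
  res <- hw_chain_cpp(pmin(g1, g2), pmax(g1, g2), length(al),
                      as.integer(mc$demem), as.integer(mc$batches),
                      as.integer(mc$iters), direction == "deficit")
  list(p = res$p, se = res$se, defined = TRUE, n = length(a1), k = length(al))
}

# Monte Carlo exact G test of independence on a contingency table.
# Tables are drawn from the null conditional distribution with fixed
# margins (r2dtable); p = (1 + #{G* >= G_obs}) / (B + 1).
mc_g_test <- function(tab, B = 10000L, seed = 1L) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(p = NA_real_, defined = FALSE, g = NA_real_))
  gstat <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    i <- m > 0
    2 * sum(m[i] * log(m[i] / e[i]))
  }
  g0 <- gstat(tab)
  set.seed(seed)
  sims <- stats::r2dtable(B, rowSums(tab), colSums(tab))
  gs <- vapply(sims, gstat, 0)
  p <- (1 + sum(gs >= g0 - 1e-9)) / (B + 1)
  list(p = p, defined = TRUE, g = g0)
}

#' Exact test of genotypic linkage disequilibrium
#'
#' Monte Carlo exact G test of independence on the two-locus genotype
#' contingency table within one population (genotypic disequilibrium; no
#' gametic phase assumed). Null tables are drawn with fixed margins.
#'
#' @param x a `geno_tab`.
#' @param pop population label.
#' @param locusA,locusB locus names or indices.
#' @param B number of Monte Carlo tables (default 10000).
#' @param seed integer RNG seed.
#' @return list with `p`, `defined`, `g` (observed G statistic). Either
#'   locus monomorphic in the population gives `defined = FALSE`.
#' @export
ld_exact_test <- function(x, pop, locusA, locusB, B = 10000L, seed = 1L) {
  if (is.character(locusA)) locusA <- match(locusA, x$loci)
  if (is.character(locusB)) locusB <- match(locusB, x$loci)
  i <- x$pop == pop
  gA <- paste0(x$a1[i, locusA], "/", x$a2[i, locusA])
  gB <- paste0(x$a1[i, locusB], "/", x$a2[i, locusB])
  ok <- !is.na(x$a1[i, locusA]) & !is.na(x$a1[i, locusB])
  if (sum(ok) < 2L || n_alleles_obs(x, pop, locusA) < 2L ||
      n_alleles_obs(x, pop, locusB) < 2L)
    return(list(p = NA_real_, defined = FALSE, g = NA_real_))
  mc_g_test(table(gA[ok], gB[ok]), B = B, seed = seed)
}

#' Exact G tests of population differentiation
#'
#' Per-locus Monte Carlo exact G tests on genotype x population
#' contingency tables, combined across loci by Fisher's method
#' (`chi2 = -2 * sum(log p)` with `df = 2 *` number of loci with defined
#' tests).
#'
#' @param x a `geno_tab`.
#' @param pops subset of population labels (default all).
#' @param B Monte Carlo tables per locus.
#' @param seed integer RNG seed.
#' @return list with `per_locus` (data.frame locus/p/defined), `chi2`,
#'   `df`, `p` (combined).
#' @export
exact_g_diff <- function(x, pops = pop_names(x), B = 10000L, seed = 1L) {
  x <- x[x$pop %in% pops, ]
  pv <- rep(NA_real_, n_loc(x)); def <- logical(n_loc(x))
  for (j in seq_len(n_loc(x))) {
    g <- paste0(x$a1[, j], "/", x$a2[, j])
    ok <- !is.na(x$a1[, j])
    res <- mc_g_test(table(g[ok], x$pop[ok]), B = B, seed = seed + j)
    pv[j] <- res$p; def[j] <- res$defined
  }
  if (!any(def)) stop("no locus yields a defined differentiation test")
  chi2 <- -2 * sum(log(pv[def]))
  df <- 2L * sum(def)
  list(per_locus = data.frame(locus = x$loci, p = pv, defined = def,
                              stringsAsFactors = FALSE),
       chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Hardy-Weinberg test battery over populations and loci
#'
#' Runs [hw_exact_test()] for every (population, locus) pair in the given
#' direction, excluding undefined (monomorphic) combinations, and applies
#' the Benjamini-Yekutieli adjustment grouped by population.
#'
#' @inheritParams hw_exact_test
#' @param alpha significance level for flags (default 0.05).
#' @return data.frame with columns pop, locus, p, se, p_adj, signif,
#'   signif_adj, seed; one row per defined test.
#' @export
hw_battery <- function(x, direction = c("deficit", "excess"),
                       mc = list(demem = 10000, batches = 100, iters = 10000),
                       alpha = 0.05, seed = 1L) {
  direction <- match.arg(direction)
  pops <- pop_names(x)
  rows <- list()
  s <- seed
  for (p in pops) for (j in seq_len(n_loc(x))) {
    s <- s + 1L
    r <- hw_exact_test(x, p, j, direction, mc = mc, seed = s)
    if (!r$defined) next
    rows[[length(rows) + 1L]] <- data.frame(
      pop = p, locus = x$loci[j], p = r$p, se = r$se, seed = s,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- by_fdr(out$p, out$pop)
  out$signif <- out$p < alpha
  out$signif_adj <- out$p_adj < alpha
  out
}

#' Linkage-disequilibrium test battery over populations and locus pairs
#'
#' Runs [ld_exact_test()] for every (population, locus pair), excluding
#' undefined combinations, with the Benjamini-Yekutieli adjustment
#' grouped by locus pair.
#'
#' @inheritParams ld_exact_test
#' @param alpha significance level for flags.
#' @return data.frame with columns pop, locusA, locusB, p, p_adj, signif,
#'   signif_adj, seed.
#' @export
ld_battery <- function(x, B = 10000L, alpha = 0.05, seed = 1L) {
  pops <- pop_names(x)
  rows <- list()
  s <- seed
  for (p in pops) {
    for (ja in seq_len(n_loc(x) - 1L)) for (jb in (ja + 1L):n_loc(x)) {
      s <- s + 1L
      r <- ld_exact_test(x, p, ja, jb, B = B, seed = s)
      if (!r$defined) next
      rows[[length(rows) + 1L]] <- data.frame(
        pop = p, locusA = x$loci[ja], locusB = x$loci[jb], p = r$p, seed = s,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$pair <- paste(out$locusA, out$locusB, sep = "-")
  out$p_adj <- by_fdr(out$p, out$pair)
  out$signif <- out$p < alpha
  out$signif_adj <- out$p_adj < alpha
  out
}
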