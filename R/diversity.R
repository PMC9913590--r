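#' Allelic richness by rarefaction
#'
#' Expected number of distinct alleles in a rarefied sample of `g` gene
#' copies drawn without replacement from the observed copies:
#' `sum_a (1 - choose(G - G_a, g) / choose(G, g))` with `G` total copies
#' and `G_a` copies of allele `a`.
#'
#' @param counts integer vector of allele copy counts.
#' @param g rarefaction size (gene copies), `g <= sum(counts)`.
#' @return expected allele count (numeric).
#' @export
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  G <- sum(counts)
  if (g > G) stop("rarefaction size exceeds available gene copies")
  sum(1 - exp(lchoose(G - counts, g) - lchoose(G, g)))
}

# Per-(population, locus) building blocks used by summary_stats and the
# Weir-Cockerham within-population f: n (individuals with data), observed
# heterozygosity, unbiased expected heterozygosity, allele count, and the
# per-locus variance components b (between-individual) and c (within).
pop_locus_stats <- function(x, pop, locus, g = NULL) {
  i <- x$pop == pop
  a1 <- x$a1[i, locus]; a2 <- x$a2[i, locus]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n == 0L) return(NULL)
  al <- sort(unique(c(a1, a2)))
  cnt <- vapply(al, function(a) sum(a1 == a) + sum(a2 == a), 0L)
  p <- cnt / (2 * n)
  ho <- mean(a1 != a2)
  he <- if (n > 0) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else NA_real_
  # Weir-Cockerham single-population components, per allele
  hbar <- vapply(al, function(a) mean((a1 == a) != (a2 == a)), 0)
  b <- if (n > 1) (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
       else rep(NA_real_, length(al))
  cc <- hbar / 2
  ar <- if (!is.null(g)) allelic_richness(cnt, g) else NA_real_
  list(n = n, na = length(al), ho = ho, he = max(he, 0), ar = ar,
       b = sum(b), c = sum(cc))
}

#' Within-population diversity summary
#'
#' Per-population means (+/- SD over loci) of the number of alleles,
#' allelic richness at a common rarefaction size, unbiased expected
#' heterozygosity `(2n/(2n-1)) (1 - sum p^2)`, observed heterozygosity,
#' and the Weir-Cockerham within-population inbreeding coefficient f
#' (F_IS) with a percentile bootstrap-over-loci confidence interval.
#'
#' @param x a `geno_tab` (normally the filtered panel).
#' @param g rarefaction size in gene copies; default is the smallest
#'   per-(population, locus) gene-copy count in the dataset, so that
#'   richness is comparable across unequal sample sizes.
#' @param boot bootstrap replicates for the F_IS interval (default 10000).
#' @param seed integer RNG seed for the bootstrap.
#' @return data.frame, one row per population: `pop`, `n`, `n_a`,
#'   `n_a_sd`, `a_r`, `a_r_sd`, `h_e`, `h_e_sd`, `h_o`, `h_o_sd`, `f_is`,
#'   `f_is_lo`, `f_is_hi`. Attribute `"g"` records the rarefaction size.
#' @export
summary_stats <- function(x, g = NULL, boot = 10000L, seed = 1L) {
  pops <- pop_names(x)
  L <- n_loc(x)
  ncop <- matrix(NA_real_, length(pops), L)
  for (k in seq_along(pops)) for (j in seq_len(L)) {
    i <- x$pop == pops[k]
    ncop[k, j] <- 2 * sum(!is.na(x$a1[i, j]))
  }
  if (is.null(g)) g <- min(ncop[ncop > 0])
  if (any(ncop > 0 & ncop < g)) {
    bad <- which(ncop > 0 & ncop < g, arr.ind = TRUE)[1, ]
    stop("rarefaction size ", g, " exceeds gene copies at locus ",
         x$loci[bad[2]], " in population ", pops[bad[1]])
  }
  set.seed(seed)
  rows <- lapply(pops, function(p) {
    st <- lapply(seq_len(L), function(j) pop_locus_stats(x, p, j, g = g))
    st <- st[!vapply(st, is.null, TRUE)]
    get <- function(f) vapply(st, `[[`, 0, f)
    bsum <- get("b"); csum <- get("c")
    fis <- 1 - sum(csum) / sum(bsum + csum)
    idx <- matrix(sample.int(length(st), boot * length(st), replace = TRUE),
                  nrow = boot)
    bs <- matrix(bsum[idx], nrow = boot); cs <- matrix(csum[idx], nrow = boot)
    fboot <- 1 - rowSums(cs) / rowSums(bs + cs)
    ci <- stats::quantile(fboot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    data.frame(pop = p, n = sum(x$pop == p),
               n_a = mean(get("na")), n_a_sd = stats::sd(get("na")),
               a_r = mean(get("ar")), a_r_sd = stats::sd(get("ar")),
               h_e = mean(get("he")), h_e_sd = stats::sd(get("he")),
               h_o = mean(get("ho")), h_o_sd = stats::sd(get("ho")),
               f_is = fis, f_is_lo = ci[1], f_is_hi = ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "g") <- g
  out
}
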