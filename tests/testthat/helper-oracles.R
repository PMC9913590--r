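# Independent brute-force oracles. These deliberately re-derive each
# quantity with separate code so that agreement with the package
# implementations is informative.

# Exact one-sided Hardy-Weinberg p-value by complete enumeration of all
# genotype tables compatible with the allele counts (Levene conditional
# distribution), ordered by heterozygote count.
oracle_hw_enum <- function(a1, a2, direction = "deficit") {
  al <- sort(unique(c(a1, a2)))
  k <- length(al)
  n <- length(a1)
  counts <- vapply(al, function(a) sum(a1 == a) + sum(a2 == a), 0L)
  het_obs <- sum(a1 != a2)
  cells <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  tabs <- list()
  rec <- function(idx, rem, G) {
    if (idx > nrow(cells)) {
      if (all(rem == 0L)) tabs[[length(tabs) + 1L]] <<- G
      return(invisible())
    }
    i <- cells[idx, 1]; j <- cells[idx, 2]
    maxg <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (g in 0:maxg) {
      rem2 <- rem
      rem2[i] <- rem2[i] - g * (if (i == j) 2L else 1L)
      if (i != j) rem2[j] <- rem2[j] - g
      G[idx] <- g
      rec(idx + 1L, rem2, G)
    }
  }
  rec(1L, counts, integer(nrow(cells)))
  off <- cells[, 1] != cells[, 2]
  lp <- vapply(tabs, function(G)
    lfactorial(n) + sum(lfactorial(counts)) + sum(G[off]) * log(2) -
      lfactorial(2 * n) - sum(lfactorial(G)), 0)
  hets <- vapply(tabs, function(G) sum(G[off]), 0L)
  p <- exp(lp)
  stopifnot(abs(sum(p) - 1) < 1e-9)
  if (direction == "deficit") sum(p[hets <= het_obs]) else sum(p[hets >= het_obs])
}

# Weir-Cockerham theta, re-derived.
oracle_theta <- function(tab) {
  pops <- unique(tab$pop)
  num <- den <- 0
  for (j in seq_along(tab$loci)) {
    allA <- sort(unique(stats::na.omit(c(tab$a1[, j], tab$a2[, j]))))
    nvec <- vapply(pops, function(p) sum(tab$pop == p & !is.na(tab$a1[, j])), 0L)
    use <- nvec > 0
    if (sum(use) < 2) next
    nv <- nvec[use]; pp <- pops[use]
    rr <- length(nv)
    nbar <- mean(nv)
    nc <- (sum(nv) - sum(nv^2) / sum(nv)) / (rr - 1)
    for (a in allA) {
      pv <- hv <- numeric(rr)
      for (m in seq_along(pp)) {
        sel <- tab$pop == pp[m] & !is.na(tab$a1[, j])
        x1 <- tab$a1[sel, j]; x2 <- tab$a2[sel, j]
        pv[m] <- (sum(x1 == a) + sum(x2 == a)) / (2 * nv[m])
        hv[m] <- mean((x1 == a) != (x2 == a))
      }
      pbar <- sum(nv * pv) / sum(nv)
      hbar <- sum(nv * hv) / sum(nv)
      s2 <- sum(nv * (pv - pbar)^2) / ((rr - 1) * nbar)
      a_ <- nbar / nc * (s2 - (pbar * (1 - pbar) - (rr - 1) / rr * s2 - hbar / 4) / (nbar - 1))
      b_ <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (rr - 1) / rr * s2 -
                                   (2 * nbar - 1) / (4 * nbar) * hbar)
      c_ <- hbar / 2
      num <- num + a_; den <- den + a_ + b_ + c_
    }
  }
  num / den
}

# Jost's D per locus (Nei-Chesser unbiased estimators), re-derived.
oracle_jost_locus <- function(tab, j) {
  pops <- unique(tab$pop)
  dat <- lapply(pops, function(p) {
    sel <- tab$pop == p & !is.na(tab$a1[, j])
    list(x1 = tab$a1[sel, j], x2 = tab$a2[sel, j])
  })
  nv <- vapply(dat, function(d) length(d$x1), 0L)
  dat <- dat[nv > 0]; nv <- nv[nv > 0]
  K <- length(dat)
  if (K < 2) return(NA_real_)
  al <- sort(unique(unlist(lapply(dat, function(d) c(d$x1, d$x2)))))
  pm <- t(vapply(seq_len(K), function(m)
    vapply(al, function(a) (sum(dat[[m]]$x1 == a) + sum(dat[[m]]$x2 == a)) / (2 * nv[m]), 0),
    numeric(length(al))))
  ho <- mean(vapply(dat, function(d) mean(d$x1 != d$x2), 0))
  nh <- K / sum(1 / nv)
  hs <- (nh / (nh - 1)) * ((1 - mean(rowSums(pm^2))) - ho / (2 * nh))
  ht <- 1 - sum(colMeans(pm)^2) + hs / (nh * K) - ho / (2 * nh * K)
  if (1 - hs < 1e-12) return(NA_real_)
  (K / (K - 1)) * (ht - hs) / (1 - hs)
}

# unbiased expected heterozygosity, re-derived from genotype vectors
oracle_he <- function(x1, x2) {
  n <- length(x1)
  al <- unique(c(x1, x2))
  p <- vapply(al, function(a) (sum(x1 == a) + sum(x2 == a)) / (2 * n), 0)
  (2 * n / (2 * n - 1)) * (1 - sum(p^2))
}

# rarefied allelic richness via choose()
oracle_ar <- function(counts, g) {
  counts <- counts[counts > 0]
  G <- sum(counts)
  sum(vapply(counts, function(ca) 1 - choose(G - ca, g) / choose(G, g), 0))
}

# Benjamini-Yekutieli step-up, re-derived from the definition.
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# A random small genotype table for estimator cross-checks.
random_small_table <- function(n_pops = 2, n_per = 8, n_loci = 3,
                               n_alleles = 4, miss = 0) {
  pops <- rep(paste0("P", seq_len(n_pops)), each = n_per)
  n <- length(pops)
  a1 <- matrix(sample.int(n_alleles, n * n_loci, replace = TRUE) * 2L + 100L, n)
  a2 <- matrix(sample.int(n_alleles, n * n_loci, replace = TRUE) * 2L + 100L, n)
  if (miss > 0) {
    hit <- stats::runif(n * n_loci) < miss
    a1[hit] <- NA; a2[hit] <- NA
  }
  # guarantee data in every (pop, locus)
  for (p in unique(pops)) for (j in seq_len(n_loci)) {
    i <- which(pops == p)
    if (all(is.na(a1[i, j]))) { a1[i[1], j] <- 102L; a2[i[1], j] <- 104L }
  }
  genotype_table(paste0("i", seq_len(n)), pops, a1, a2,
                 paste0("L", seq_len(n_loci)))
}

# Fixed-difference reference panel: two populations fixed for alternative
# alleles at every locus.
fixed_diff_refs <- function(n1 = 20, n2 = 20, n_loci = 10) {
  mk <- function(n, allele, pop)
    genotype_table(paste0(pop, seq_len(n)), rep(pop, n),
                   matrix(allele, n, n_loci), matrix(allele, n, n_loci),
                   paste0("L", seq_len(n_loci)))
  bind_tables(mk(n1, 100L, "R1"), mk(n2, 200L, "R2"))
}
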