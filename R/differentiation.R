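#' Weir-Cockerham theta (F_ST)
#'
#' Variance-components estimator of F_ST for haphazardly sampled
#' populations of unequal size: per locus and allele the among-population
#' (a), between-individual (b) and within-individual (c) components are
#' computed, summed over alleles and loci, and the estimate is
#' `sum(a) / sum(a + b + c)`. Negative estimates are reported as
#' computed. The confidence interval is a percentile bootstrap over loci.
#'
#' @param x a `geno_tab`.
#' @param pops subset of population labels (default all; >= 2 required).
#' @param boot bootstrap replicates over loci (default 10000; 0 skips CI).
#' @param seed integer RNG seed.
#' @return list with `theta`, `ci` (length-2 or NULL), `per_locus`
#'   data.frame of locus components, `defined`.
#' @export
wc_theta <- function(x, pops = pop_names(x), boot = 10000L, seed = 1L) {
  if (length(pops) < 2L) stop("need >= 2 populations")
  x <- x[x$pop %in% pops, ]
  L <- n_loc(x)
  A <- B <- C <- rep(0, L)
  for (j in seq_len(L)) {
    comp <- wc_components(x, j)
    A[j] <- comp[1]; B[j] <- comp[2]; C[j] <- comp[3]
  }
  tot <- sum(A + B + C)
  if (tot == 0) return(list(theta = NA_real_, ci = NULL, defined = FALSE,
                            per_locus = data.frame(locus = x$loci, a = A, b = B, c = C)))
  theta <- sum(A) / tot
  ci <- NULL
  if (boot > 0 && L > 1) {
    set.seed(seed)
    idx <- matrix(sample.int(L, boot * L, replace = TRUE), nrow = boot)
    num <- matrix(A[idx], nrow = boot); den <- matrix((A + B + C)[idx], nrow = boot)
    tb <- rowSums(num) / rowSums(den)
    ci <- stats::quantile(tb, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  list(theta = theta, ci = ci, defined = TRUE,
       per_locus = data.frame(locus = x$loci, a = A, b = B, c = C,
                              stringsAsFactors = FALSE))
}

# Weir & Cockerham (1984) per-locus variance components summed over
# alleles; returns c(sum_a, sum_b, sum_c). Populations without data at
# the locus are dropped.
wc_components <- function(x, locus) {
  pops <- pop_names(x)
  ni <- pi <- hi <- NULL
  al <- x$alleles[[locus]]
  dat <- lapply(pops, function(p) {
    i <- x$pop == p
    a1 <- x$a1[i, locus]; a2 <- x$a2[i, locus]
    ok <- !is.na(a1)
    list(a1 = a1[ok], a2 = a2[ok], n = sum(ok))
  })
  dat <- dat[vapply(dat, `[[`, 0L, "n") > 0]
  r <- length(dat)
  if (r < 2L) return(c(0, 0, 0))
  n <- vapply(dat, `[[`, 0L, "n")
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  suma <- sumb <- sumc <- 0
  for (a in al) {
    p <- vapply(dat, function(d) (sum(d$a1 == a) + sum(d$a2 == a)) / (2 * d$n), 0)
    h <- vapply(dat, function(d) mean((d$a1 == a) != (d$a2 == a)), 0)
    pbar <- sum(n * p) / (r * nbar)
    hbar <- sum(n * h) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    av <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
            (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    bv <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
            ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cv <- hbar / 2
    suma <- suma + av; sumb <- sumb + bv; sumc <- sumc + cv
  }
  c(suma, sumb, sumc)
}

#' Jost's D differentiation estimator
#'
#' Per locus, `D = (K/(K-1)) (H_T - H_S) / (1 - H_S)` with the Nei-Chesser
#' unbiased estimators of within-population (`H_S`) and total (`H_T`)
#' gene diversity (harmonic-mean sample size correction). Loci are
#' combined by the harmonic mean of the per-locus estimates when all are
#' positive (the convention of the estimator's software lineage);
#' otherwise the arithmetic mean is used and flagged. The confidence
#' interval is a percentile bootstrap over loci of the combined value.
#'
#' @inheritParams wc_theta
#' @return list with `d` (combined), `combine` ("harmonic" or
#'   "arithmetic"), `ci`, `per_locus`, `defined`.
#' @export
jost_d <- function(x, pops = pop_names(x), boot = 10000L, seed = 1L) {
  if (length(pops) < 2L) stop("need >= 2 populations")
  x <- x[x$pop %in% pops, ]
  L <- n_loc(x)
  dl <- vapply(seq_len(L), function(j) jost_d_locus(x, j), 0)
  ok <- !is.na(dl)
  if (!any(ok)) return(list(d = NA_real_, ci = NULL, defined = FALSE,
                            per_locus = data.frame(locus = x$loci, d = dl)))
  comb <- function(v) {
    v <- v[!is.na(v)]
    if (all(abs(v) < 1e-12)) return(0)
    if (all(v > 0)) 1 / mean(1 / v) else mean(v)
  }
  d <- comb(dl)
  ci <- NULL
  if (boot > 0 && sum(ok) > 1) {
    set.seed(seed)
    vb <- dl[ok]
    idx <- matrix(sample.int(length(vb), boot * length(vb), replace = TRUE),
                  nrow = boot)
    db <- apply(idx, 1, function(i) comb(vb[i]))
    ci <- stats::quantile(db, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  list(d = d, combine = if (all(dl[ok] > 0) || all(abs(dl[ok]) < 1e-12))
         "harmonic" else "arithmetic",
       ci = ci, defined = TRUE,
       per_locus = data.frame(locus = x$loci, d = dl, stringsAsFactors = FALSE))
}

# Nei-Chesser unbiased H_S / H_T and Jost's D for one locus; NA when the
# locus has data in < 2 populations or H_S estimates at 1.
jost_d_locus <- function(x, locus) {
  pops <- pop_names(x)
  dat <- lapply(pops, function(p) {
    i <- x$pop == p
    a1 <- x$a1[i, locus]; a2 <- x$a2[i, locus]
    ok <- !is.na(a1)
    list(a1 = a1[ok], a2 = a2[ok], n = sum(ok))
  })
  dat <- dat[vapply(dat, `[[`, 0L, "n") > 0]
  K <- length(dat)
  if (K < 2L) return(NA_real_)
  al <- x$alleles[[locus]]
  n <- vapply(dat, `[[`, 0L, "n")
  ntilde <- K / sum(1 / n)
  pmat <- t(vapply(dat, function(d)
    vapply(al, function(a) (sum(d$a1 == a) + sum(d$a2 == a)) / (2 * d$n), 0),
    numeric(length(al))))
  ho <- mean(vapply(dat, function(d) mean(d$a1 != d$a2), 0))
  hs_plug <- 1 - mean(rowSums(pmat^2))
  hs <- (ntilde / (ntilde - 1)) * (hs_plug - ho / (2 * ntilde))
  pbar <- colMeans(pmat)
  ht <- 1 - sum(pbar^2) + hs / (ntilde * K) - ho / (2 * ntilde * K)
  if (1 - hs < 1e-12) return(NA_real_)
  (K / (K - 1)) * (ht - hs) / (1 - hs)
}

#' Pairwise differentiation matrices
#'
#' Pairwise Weir-Cockerham theta and Jost's D over all population pairs,
#' with bootstrap confidence intervals and exact G tests of
#' differentiation.
#'
#' @inheritParams wc_theta
#' @param B Monte Carlo tables per locus for the exact G tests.
#' @return list with matrices `theta`, `theta_lo`, `theta_hi`, `d_est`,
#'   `d_lo`, `d_hi`, `g_p` (exact-G combined p, B-Y adjusted across
#'   pairs in `g_p_adj`).
#' @export
pairwise_diff <- function(x, boot = 10000L, B = 10000L, seed = 1L) {
  pops <- pop_names(x)
  np <- length(pops)
  mk <- function() matrix(NA_real_, np, np, dimnames = list(pops, pops))
  th <- tlo <- thi <- dd <- dlo <- dhi <- gp <- mk()
  s <- seed
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    s <- s + 1L
    pr <- c(pops[i], pops[j])
    wt <- wc_theta(x, pr, boot = boot, seed = s)
    jd <- jost_d(x, pr, boot = boot, seed = s)
    gg <- exact_g_diff(x, pr, B = B, seed = s)
    th[i, j] <- th[j, i] <- wt$theta
    if (!is.null(wt$ci)) { tlo[i, j] <- tlo[j, i] <- wt$ci[1]; thi[i, j] <- thi[j, i] <- wt$ci[2] }
    dd[i, j] <- dd[j, i] <- jd$d
    if (!is.null(jd$ci)) { dlo[i, j] <- dlo[j, i] <- jd$ci[1]; dhi[i, j] <- dhi[j, i] <- jd$ci[2] }
    gp[i, j] <- gp[j, i] <- gg$p
  }
  up <- upper.tri(gp)
  gadj <- mk()
  gadj[up] <- by_fdr(gp[up])
  gadj[lower.tri(gadj)] <- t(gadj)[lower.tri(gadj)]
  list(theta = th, theta_lo = tlo, theta_hi = thi,
       d_est = dd, d_lo = dlo, d_hi = dhi, g_p = gp, g_p_adj = gadj)
}
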