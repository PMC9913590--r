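#' Bayesian MCMC assignment to genotypic classes
#'
#' Gibbs sampler over latent gene-copy origins, per-individual class
#' labels, per-pool allele frequencies (Jeffreys Dirichlet(1/2) priors)
#' and class mixing proportions. The likelihood of a genotype under a
#' class with gene-origin vector `(z11, z12, z22)` at a locus is
#' `z11 P(g | pool1) + z12 P(one copy from each pool) + z22 P(g | pool2)`.
#' Missing genotypes contribute likelihood 1 (marginalised). The
#' posterior membership `q` of an individual in a class is the frequency
#' of its class label after burn-in.
#'
#' Replicate runs are independent and reported separately; no merging is
#' forced. Because the two pools are exchangeable a priori, runs may
#' label-switch; each replicate is therefore re-anchored so that pool 1
#' is the pool under which the `anchor` reference population has the
#' higher aggregate membership, and the raw (pre-anchoring) matrices are
#' kept.
#'
#' @param x a `geno_tab` holding the mixture and any reference
#'   populations (all individuals are analysed jointly).
#' @param classes class roster data.frame as [hybrid_classes()].
#' @param iters,burn MCMC sweeps and burn-in (defaults 500000 / 100000).
#' @param replicates independent runs (default 5).
#' @param seed integer RNG seed (replicate r uses `seed + r`).
#' @param anchor optional label of the species-1 reference population
#'   used to resolve label switching (default: first population).
#' @param ref_classes optional named character vector `population ->
#'   class label` fixing the class of reference individuals (off by
#'   default: references carry no fixed priors).
#' @param fix_freqs optional list `(f1, f2)` of per-locus frequency
#'   vectors; when supplied, pool frequencies are held fixed (validation
#'   use).
#' @param fix_pi hold mixing proportions fixed at uniform (validation
#'   use).
#' @return a `newhyb_fit` list: `q` (list of per-replicate anchored
#'   membership matrices, individuals x classes), `q_raw`, `swapped`
#'   (logical per replicate), `classes`, `loglik_trace`, `meta`.
#' @export
newhybrids_fit <- function(x, classes = hybrid_classes(),
                           iters = 500000L, burn = 100000L, replicates = 5L,
                           seed = 1L, anchor = NULL, ref_classes = NULL,
                           fix_freqs = NULL, fix_pi = FALSE) {
  if (burn >= iters) stop("burn-in must be smaller than iters")
  L <- n_loc(x)
  regs <- x$alleles
  nall <- vapply(regs, length, 0L)
  a1 <- a2 <- matrix(-1L, n_ind(x), L)
  for (j in seq_len(L)) {
    a1[, j] <- match(x$a1[, j], regs[[j]]) - 1L
    a2[, j] <- match(x$a2[, j], regs[[j]]) - 1L
  }
  a1[is.na(a1)] <- -1L; a2[is.na(a2)] <- -1L
  z <- as.matrix(classes[, c("z11", "z12", "z22")])
  cfix <- rep(-1L, n_ind(x))
  if (!is.null(ref_classes)) {
    for (p in names(ref_classes)) {
      ci <- match(ref_classes[[p]], classes$label)
      if (is.na(ci)) stop("unknown class in ref_classes: ", ref_classes[[p]])
      cfix[x$pop == p] <- ci - 1L
    }
  }
  if (is.null(anchor)) anchor <- pop_names(x)[1]
  # initial pool frequencies: smoothed empirical frequencies of the two
  # most divergent populations if available, else perturbed global
  init_pools <- function(rep_seed) {
    if (!is.null(fix_freqs)) return(fix_freqs)
    af <- allele_freqs(x)
    pops <- pop_names(x)
    smooth <- function(krow, j) {
      v <- as.numeric(krow)
      v[is.na(v)] <- 0
      v <- v + 0.5 / nall[j]
      v / sum(v)
    }
    set.seed(rep_seed)
    if (length(pops) >= 2) {
      k1 <- match(anchor, pops)
      # the pool-2 seed population: the one most differentiated from anchor
      others <- setdiff(seq_along(pops), k1)
      k2 <- if (length(others) == 1L) others else {
        ths <- vapply(others, function(k)
          wc_theta(x, c(pops[k1], pops[k]), boot = 0)$theta, 0)
        others[which.max(ths)]
      }
      f1 <- lapply(seq_len(L), function(j) smooth(af$freq[[j]][k1, ], j))
      f2 <- lapply(seq_len(L), function(j) smooth(af$freq[[j]][k2, ], j))
    } else {
      f1 <- lapply(seq_len(L), function(j) {
        v <- colMeans(af$freq[[j]], na.rm = TRUE) + stats::runif(nall[j], 0, 0.1)
        v / sum(v)
      })
      f2 <- lapply(seq_len(L), function(j) {
        v <- colMeans(af$freq[[j]], na.rm = TRUE) + stats::runif(nall[j], 0, 0.1)
        v / sum(v)
      })
    }
    list(f1 = f1, f2 = f2)
  }
  mirror <- match(c("P1" = "P2", "P2" = "P1", "F1" = "F1", "F2" = "F2",
                    "P1_bx" = "P2_bx", "P1_bx1" = "P2_bx1",
                    "P2_bx" = "P1_bx", "P2_bx1" = "P1_bx1")[classes$label],
                  classes$label)
  qs <- qraw <- vector("list", replicates)
  traces <- vector("list", replicates)
  swapped <- logical(replicates)
  p1share <- classes$pool1_share
  for (r in seq_len(replicates)) {
    pools <- init_pools(seed + 1000L * r)
    set.seed(seed + r)
    res <- newhyb_gibbs_cpp(a1, a2, nall, z, pools$f1, pools$f2,
                            as.integer(iters), as.integer(burn),
                            !is.null(fix_freqs), fix_pi, cfix, 0.5)
    q <- res$q
    dimnames(q) <- list(x$id, classes$label)
    qraw[[r]] <- q
    anch <- x$pop == anchor
    if (any(anch) && is.null(fix_freqs)) {
      share <- mean(q[anch, , drop = FALSE] %*% p1share)
      if (share < 0.5) {
        q <- q[, mirror]
        colnames(q) <- classes$label
        swapped[r] <- TRUE
      }
    }
    qs[[r]] <- q
    traces[[r]] <- res$loglik_trace
  }
  structure(list(q = qs, q_raw = qraw, swapped = swapped, classes = classes,
                 loglik_trace = traces,
                 meta = list(iters = iters, burn = burn, seed = seed,
                             anchor = anchor)),
            class = "newhyb_fit")
}

#' @export
print.newhyb_fit <- function(x, ...) {
  cat("Bayesian genotypic-class fit:", length(x$q), "replicate run(s),",
      nrow(x$q[[1]]), "individuals,", ncol(x$q[[1]]), "classes\n")
  cat("  label-switch corrected in", sum(x$swapped), "replicate(s)\n")
  invisible(x)
}

#' Pairwise replicate agreement of modal assignments
#'
#' Fraction of individuals whose modal class coincides between each pair
#' of replicate runs.
#'
#' @param fit a `newhyb_fit`.
#' @return symmetric matrix of agreement fractions.
#' @export
replicate_agreement <- function(fit) {
  R <- length(fit$q)
  modal <- lapply(fit$q, function(q) max.col(q, ties.method = "first"))
  out <- matrix(1, R, R)
  for (i in seq_len(R - 1)) for (j in (i + 1):R)
    out[i, j] <- out[j, i] <- mean(modal[[i]] == modal[[j]])
  out
}
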