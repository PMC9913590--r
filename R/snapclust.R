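#' EM maximum-likelihood assignment with hybridity coefficients
#'
#' Fast likelihood assignment of individuals to two parental populations
#' and hybrid classes defined by gene-pool shares: each gene copy of an
#' individual in a class with share `a` is drawn independently from the
#' mixture `a * f1 + (1 - a) * f2` of the two parental allele-frequency
#' pools. F1 and F2 both have share 0.5 and are therefore not
#' distinguishable by this model; the default roster consequently has a
#' single F1 class. The E-step computes class memberships from genotype
#' likelihoods, the M-step re-estimates pool frequencies from
#' membership-weighted expected gene-copy origins, and the class mixing
#' proportions are updated by maximum likelihood. Initialisation is
#' geometric: individuals are split by the sign of their first principal
#' component, and pool frequencies seeded from the two groups.
#'
#' @param x a `geno_tab`.
#' @param shares named numeric vector of pool-1 shares per class
#'   (default P1 = 1, P2 = 0, F1 = 0.5, first backcrosses 0.75/0.25,
#'   second backcrosses 0.875/0.125).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param seed integer seed (used for restarts when a pool degenerates).
#' @param max_restarts restarts allowed on degenerate pools.
#' @param anchor optional population label anchoring pool 1: if, after
#'   convergence, that population's mean pool-1 share is below 0.5 the
#'   class labels are mirrored (P1 <-> P2 etc.), removing the arbitrary
#'   orientation of the geometric initialisation.
#' @param fix_freqs optional list `(f1, f2)` of per-locus frequency
#'   vectors (registry order) held fixed instead of re-estimated
#'   (validation use: with fixed frequencies and fixed uniform mixing
#'   proportions the memberships are the closed-form Bayes posterior).
#' @param fix_pi hold class mixing proportions fixed at uniform.
#' @return a `snapclust_fit` list: `q` (individuals x classes membership
#'   matrix), `loglik_trace`, `converged`, `f1`, `f2`, `pi`, `shares`.
#' @export
snapclust_fit <- function(x,
                          shares = c(P1 = 1, P1_bx1 = 0.875, P1_bx = 0.75,
                                     F1 = 0.5, P2_bx = 0.25, P2_bx1 = 0.125,
                                     P2 = 0),
                          max_iter = 200L, tol = 1e-6, seed = 1L,
                          max_restarts = 3L, anchor = NULL,
                          fix_freqs = NULL, fix_pi = FALSE) {
  N <- n_ind(x); L <- n_loc(x)
  C <- length(shares)
  regs <- x$alleles
  nall <- vapply(regs, length, 0L)
  i1 <- i2 <- matrix(NA_integer_, N, L)
  for (j in seq_len(L)) {
    i1[, j] <- match(x$a1[, j], regs[[j]])
    i2[, j] <- match(x$a2[, j], regs[[j]])
  }
  het <- !is.na(i1) & i1 != i2

  # geometric initialisation: sign of PC1 on allele counts
  ac <- allele_count_matrix(x)
  pc1 <- tryCatch(stats::prcomp(ac, center = TRUE, scale. = FALSE)$x[, 1],
                  error = function(e) stats::rnorm(N))
  grp <- pc1 >= stats::median(pc1)
  pool_from <- function(sel, wobble = 0) {
    lapply(seq_len(L), function(j) {
      v <- rep(0.5 / nall[j], nall[j])
      idx <- c(i1[sel, j], i2[sel, j])
      idx <- idx[!is.na(idx)]
      if (length(idx)) v <- v + tabulate(idx, nall[j])
      if (wobble > 0) v <- v + stats::runif(nall[j], 0, wobble)
      v / sum(v)
    })
  }
  eps <- 1e-12
  run_em <- function(f1, f2) {
    pi <- rep(1 / C, C)
    trace <- numeric(0)
    q <- matrix(1 / C, N, C)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # per-copy mixture frequencies per class
      ll <- matrix(0, N, C)
      for (c in seq_len(C)) {
        a <- shares[c]
        for (j in seq_len(L)) {
          m <- a * f1[[j]] + (1 - a) * f2[[j]]
          ok <- !is.na(i1[, j])
          px <- m[i1[ok, j]]; py <- m[i2[ok, j]]
          contr <- log(pmax(px * py, eps)) + log(1 + het[ok, j])
          ll[ok, c] <- ll[ok, c] + contr
        }
      }
      lw <- sweep(ll, 2, log(pmax(pi, eps)), `+`)
      mx <- apply(lw, 1, max)
      w <- exp(lw - mx)
      sw <- rowSums(w)
      q <- w / sw
      obs_ll <- sum(mx + log(sw))
      trace <- c(trace, obs_ll)
      if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) { converged <- TRUE; break }
      if (!is.null(fix_freqs)) {
        if (fix_pi) { converged <- it > 1; if (converged) break } else pi <- colMeans(q)
        next
      }
      # M-step: pool frequencies from expected copy origins
      newf1 <- newf2 <- vector("list", L)
      for (j in seq_len(L)) {
        c1 <- rep(eps, nall[j]); c2 <- rep(eps, nall[j])
        ok <- which(!is.na(i1[, j]))
        for (c in seq_len(C)) {
          a <- shares[c]
          m1 <- a * f1[[j]]; m2 <- (1 - a) * f2[[j]]
          mt <- m1 + m2
          for (copy in list(i1[, j], i2[, j])) {
            idx <- copy[ok]
            w1 <- m1[idx] / pmax(mt[idx], eps)
            qc <- q[ok, c]
            c1 <- c1 + vapply(seq_len(nall[j]), function(a0)
              sum(qc[idx == a0] * w1[idx == a0]), 0)
            c2 <- c2 + vapply(seq_len(nall[j]), function(a0)
              sum(qc[idx == a0] * (1 - w1[idx == a0])), 0)
          }
        }
        newf1[[j]] <- c1 / sum(c1); newf2[[j]] <- c2 / sum(c2)
      }
      if (any(!is.finite(unlist(newf1))) || any(!is.finite(unlist(newf2))))
        return(NULL)
      f1 <- newf1; f2 <- newf2
      if (!fix_pi) pi <- colMeans(q)
    }
    list(q = q, trace = trace, converged = converged, f1 = f1, f2 = f2, pi = pi)
  }
  res <- NULL
  set.seed(seed)
  if (!is.null(fix_freqs)) {
    res <- run_em(fix_freqs$f1, fix_freqs$f2)
  } else {
    for (r in 0:max_restarts) {
      f1 <- pool_from(grp, wobble = if (r > 0) 0.2 else 0)
      f2 <- pool_from(!grp, wobble = if (r > 0) 0.2 else 0)
      res <- run_em(f1, f2)
      if (!is.null(res)) break
      message("snapclust_fit: degenerate pool, restarting (", r + 1, ")")
      grp <- stats::runif(N) < 0.5
    }
  }
  if (is.null(res)) stop("EM failed after restarts")
  dimnames(res$q) <- list(x$id, names(shares))
  swapped <- FALSE
  if (!is.null(anchor)) {
    anch <- x$pop == anchor
    if (any(anch)) {
      share1 <- mean(res$q[anch, , drop = FALSE] %*% shares)
      if (share1 < 0.5) {
        mirror_idx <- match(1 - shares, shares)  # class with share 1 - a
        if (!anyNA(mirror_idx)) {
          res$q <- res$q[, mirror_idx, drop = FALSE]
          colnames(res$q) <- names(shares)
          tmp <- res$f1; res$f1 <- res$f2; res$f2 <- tmp
          res$pi <- res$pi[mirror_idx]
          swapped <- TRUE
        }
      }
    }
  }
  structure(list(q = res$q, loglik_trace = res$trace,
                 converged = res$converged, f1 = res$f1, f2 = res$f2,
                 pi = res$pi, shares = shares, swapped = swapped),
            class = "snapclust_fit")
}

#' @export
print.snapclust_fit <- function(x, ...) {
  cat("EM hybridity fit:", nrow(x$q), "individuals,", ncol(x$q), "classes;",
      length(x$loglik_trace), "iterations",
      if (x$converged) "(converged)" else "(iteration cap reached)", "\n")
  invisible(x)
}

#' Individuals x alleles dosage matrix
#'
#' Codes each individual as allele counts (0/1/2) over the concatenated
#' allele registries of all loci; missing loci are imputed with the mean
#' dosage of the allele (the standard coding for PCA/DAPC on
#' codominant markers).
#'
#' @param x a `geno_tab`.
#' @return numeric matrix, individuals x total alleles.
#' @export
allele_count_matrix <- function(x) {
  blocks <- lapply(seq_len(n_loc(x)), function(j) {
    al <- x$alleles[[j]]
    m <- sapply(al, function(a) (x$a1[, j] == a) + (x$a2[, j] == a))
    m <- matrix(as.numeric(m), ncol = length(al))
    colnames(m) <- paste0(x$loci[j], ".", al)
    mu <- colMeans(m, na.rm = TRUE)
    for (k in seq_len(ncol(m))) m[is.na(m[, k]), k] <- mu[k]
    m
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- x$id
  out
}
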