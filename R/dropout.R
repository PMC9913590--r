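#' Maximum-likelihood estimation of allelic dropout rates
#'
#' Per-locus dropout (null-allele / genotyping failure) rates are
#' estimated by EM under a simple observation model: each transmitted
#' allele copy drops independently with locus rate `d`; a heterozygote
#' with one dropped copy is observed as a homozygote, a genotype with
#' both copies dropped is observed as missing, and homozygotes remain
#' visible after a single drop. True genotype frequencies are modelled
#' with population allele frequencies plus a homozygote-excess
#' parameter `F`, so Hardy-Weinberg proportions are not assumed.
#'
#' Identifiability of `d` against `F` comes from the cross-locus
#' structure: `F` (inbreeding-like, genome-wide) is shared by all loci
#' of a population, while `d` is locus-specific and tied to the
#' missing-data rate (`d^2` of calls drop out entirely). The EM is run
#' jointly over the loci of each population; per-locus rates are then
#' sample-size-weighted averages across populations. The report includes
#' the Pearson correlation across individuals between missingness and
#' homozygosity (a positive correlation is the signature of dropout).
#'
#' @param x a `geno_tab` with >= 2 loci.
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   total log-likelihood.
#' @return A `dropout_model` list: `rates` (named per-locus vector),
#'   `by_pop` (population x locus matrix), `f_pop` (per-population
#'   homozygote excess), `converged` (per population),
#'   `miss_hom_cor` (list with `r`, `p`).
#' @export
estimate_dropout <- function(x, max_iter = 200L, tol = 1e-6) {
  if (n_loc(x) < 2L) stop("need >= 2 loci to estimate dropout rates")
  pops <- pop_names(x)
  L <- n_loc(x)
  rates <- matrix(NA_real_, length(pops), L, dimnames = list(pops, x$loci))
  conv <- stats::setNames(logical(length(pops)), pops)
  fpop <- stats::setNames(numeric(length(pops)), pops)
  npl <- matrix(0L, length(pops), L)
  for (k in seq_along(pops)) {
    i <- x$pop == pops[k]
    fit <- dropout_em_pop(x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE],
                          max_iter, tol)
    rates[k, ] <- fit$d; conv[k] <- fit$converged; fpop[k] <- fit$F
    npl[k, ] <- sum(i)
  }
  wrate <- colSums(rates * npl, na.rm = TRUE) / colSums(npl * !is.na(rates))
  miss <- rowSums(is.na(x$a1))
  nm <- rowSums(!is.na(x$a1))
  hom <- rowSums(x$a1 == x$a2, na.rm = TRUE) / pmax(nm, 1)
  ct <- if (stats::sd(miss) > 0 && stats::sd(hom) > 0)
    stats::cor.test(miss, hom) else NULL
  structure(list(rates = wrate, by_pop = rates, f_pop = fpop,
                 converged = conv,
                 miss_hom_cor = if (is.null(ct)) list(r = NA_real_, p = NA_real_)
                 else list(r = unname(ct$estimate), p = ct$p.value)),
            class = "dropout_model")
}

# Joint EM over the loci of one population: locus-specific dropout rates
# d_l and allele frequencies p_l, shared homozygote excess F.
dropout_em_pop <- function(a1, a2, max_iter = 200L, tol = 1e-6) {
  L <- ncol(a1)
  n <- nrow(a1)
  loc <- lapply(seq_len(L), function(j) {
    ok <- !is.na(a1[, j])
    al <- sort(unique(c(a1[ok, j], a2[ok, j])))
    list(ok = ok, al = al, K = length(al),
         ia = match(a1[ok, j], al), ib = match(a2[ok, j], al),
         nmiss = sum(!ok))
  })
  d <- vapply(loc, function(l) max(sqrt(l$nmiss / max(n, 1)), 0.02), 0)
  p <- lapply(loc, function(l) {
    if (l$K == 0) return(numeric(0))
    cnt <- tabulate(c(l$ia, l$ib), l$K)
    cnt / sum(cnt)
  })
  Fh <- 0.02
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    ll <- 0; ehet_tot <- 0; hexp_tot <- 0
    for (j in seq_len(L)) {
      l <- loc[[j]]
      if (l$K < 2L || length(l$ia) < 2L) { d[j] <- NA_real_; next }
      e <- dropout_estep(l, p[[j]], d[j], Fh, n)
      ll <- ll + e$ll
      d[j] <- min(max(e$edrops / (2 * n), 1e-6), 0.95)
      p[[j]] <- e$ecnt / sum(e$ecnt)
      ehet_tot <- ehet_tot + e$ehet
      hexp_tot <- hexp_tot + length(l$ia) * (1 - sum(p[[j]]^2))
    }
    Fh <- if (hexp_tot > 0) min(max(1 - ehet_tot / hexp_tot, 0), 0.99) else 0
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(d = d, F = Fh, converged = converged, p = p,
       alleles = lapply(loc, `[[`, "al"))
}

# One E-step for one locus given parameters: expected drop events,
# expected allele counts, expected heterozygote count among the
# genotyped individuals, and the observed-data log-likelihood.
dropout_estep <- function(l, p, d, Fh, n) {
  het <- l$ia != l$ib
  nhet <- sum(het)
  ll <- sum(log(pmax(2 * p[l$ia[het]] * p[l$ib[het]] * (1 - Fh), 1e-300))) +
    2 * nhet * log(max(1 - d, 1e-300))
  edrops <- 0; ehet <- nhet
  ecnt <- numeric(l$K)
  for (g in which(het)) {
    ecnt[l$ia[g]] <- ecnt[l$ia[g]] + 1
    ecnt[l$ib[g]] <- ecnt[l$ib[g]] + 1
  }
  for (a in seq_len(l$K)) {
    nhom_a <- sum(!het & l$ia == a)
    if (nhom_a == 0) next
    whom <- (p[a]^2 + Fh * p[a] * (1 - p[a])) * (1 - d^2)
    whet <- 2 * p[a] * (1 - p[a]) * (1 - Fh) * d * (1 - d)
    tot <- whom + whet
    ll <- ll + nhom_a * log(max(tot, 1e-300))
    post_het <- if (tot > 0) whet / tot else 0
    # drops: 1 when a heterozygote lost a copy; a visible homozygote may
    # also have lost one of its identical copies (expectation 2d/(1+d))
    edrops <- edrops + nhom_a * post_het +
      nhom_a * (1 - post_het) * 2 * d / (1 + d)
    ehet <- ehet + nhom_a * post_het
    ecnt[a] <- ecnt[a] + nhom_a * (2 * (1 - post_het) + post_het)
    pb <- p; pb[a] <- 0
    if (sum(pb) > 0) ecnt <- ecnt + nhom_a * post_het * pb / sum(pb)
  }
  if (l$nmiss > 0) {
    ll <- ll + l$nmiss * 2 * log(max(d, 1e-300))
    edrops <- edrops + 2 * l$nmiss
    ecnt <- ecnt + l$nmiss * 2 * p
  }
  list(ll = ll, edrops = edrops, ecnt = ecnt, ehet = ehet)
}

#' Correct genotypes for allelic dropout
#'
#' Replaces each observed homozygote by the most probable true genotype
#' under the fitted dropout model and the population allele frequencies:
#' a homozygote is re-called as a heterozygote with the most likely
#' partner allele when the dropout posterior favours it. Observed
#' heterozygotes are never altered. Missing genotypes are optionally
#' imputed with the most probable genotype (`impute_missing = TRUE`).
#'
#' @param x a `geno_tab`.
#' @param model a `dropout_model` from [estimate_dropout()].
#' @param seed integer seed (reserved for tie-breaking).
#' @param impute_missing also impute missing calls (default FALSE).
#' @return a corrected `geno_tab` with at least as many non-missing calls
#'   as the input.
#' @export
correct_genotypes <- function(x, model, seed = 1L, impute_missing = FALSE) {
  set.seed(seed)
  a1 <- x$a1; a2 <- x$a2
  pops <- pop_names(x)
  for (k in seq_along(pops)) {
    i <- which(x$pop == pops[k])
    Fh <- model$f_pop[pops[k]]
    for (j in seq_len(n_loc(x))) {
      v1 <- a1[i, j]; v2 <- a2[i, j]
      ok <- !is.na(v1)
      if (sum(ok) < 2L) next
      al <- sort(unique(c(v1[ok], v2[ok])))
      if (length(al) < 2L) next
      cnt <- vapply(al, function(a) sum(v1[ok] == a) + sum(v2[ok] == a), 0L)
      p <- cnt / sum(cnt)
      d <- model$by_pop[pops[k], j]
      if (is.na(d)) next
      for (m in which(ok & v1 == v2)) {
        a <- match(v1[m], al)
        whom <- (p[a]^2 + Fh * p[a] * (1 - p[a])) * (1 - d^2)
        pb <- p; pb[a] <- 0
        whets <- 2 * p[a] * pb * (1 - Fh) * d * (1 - d)
        if (max(whets) > whom) v2[m] <- al[which.max(whets)]
      }
      if (impute_missing) {
        hom_w <- p^2 + Fh * p * (1 - p)
        best_hom <- which.max(hom_w)
        pr <- outer(p, p) * 2 * (1 - Fh)
        diag(pr) <- 0
        bh <- which(pr == max(pr), arr.ind = TRUE)[1, ]
        if (max(pr) > hom_w[best_hom]) {
          g1 <- al[bh[1]]; g2 <- al[bh[2]]
        } else g1 <- g2 <- al[best_hom]
        v1[!ok] <- g1; v2[!ok] <- g2
      }
      a1[i, j] <- pmin(v1, v2); a2[i, j] <- pmax(v1, v2)
    }
  }
  genotype_table(x$id, x$pop, a1, a2, x$loci)
}
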