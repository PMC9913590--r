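#' Configuration for the hierarchical island simulator
#'
#' @param demes number of demes (default 2).
#' @param pops_per_deme populations per deme (default 2).
#' @param N diploid individuals per population.
#' @param m_within per-generation probability that an offspring's parents
#'   come from the sister population within the same deme.
#' @param m_between total probability that they come from a population of
#'   another deme (split evenly); the hierarchy requires
#'   `m_within >= m_between`.
#' @param loci number of loci.
#' @param mutation `"KAM"` (k-allele model) or `"SMM"` (stepwise).
#' @param k allelic states for KAM (default 20).
#' @param mu mutation rate per gamete per locus.
#' @param generations non-overlapping generations to run.
#' @param seed integer RNG seed.
#' @return validated `island_config` list.
#' @export
island_config <- function(demes = 2L, pops_per_deme = 2L, N = 100L,
                          m_within = 0.02, m_between = 0.002,
                          loci = 16L, mutation = c("KAM", "SMM"), k = 20L,
                          mu = 5e-4, generations = 400L, seed = 1L) {
  mutation <- match.arg(mutation)
  stopifnot(m_within >= 0, m_between >= 0, m_within <= 1, m_between <= 1,
            mu >= 0, mu <= 1)
  if (N < 2L) stop("degenerate configuration: N < 2")
  if (loci < 1L || generations < 1L) stop("loci and generations must be positive")
  # hierarchy acts per source population: exchange with a sister
  # population must be at least as likely as with any single population
  # of another deme
  n_sis <- max(pops_per_deme - 1L, 1L)
  n_out <- max(demes - 1L, 1L) * pops_per_deme
  if (m_within / n_sis < m_between / n_out - 1e-12)
    stop("hierarchy requires per-population m_within >= m_between")
  structure(list(demes = demes, pops_per_deme = pops_per_deme, N = N,
                 m_within = m_within, m_between = m_between, loci = loci,
                 mutation = mutation, k = k, mu = mu,
                 generations = generations, seed = seed),
            class = "island_config")
}

#' Forward-time hierarchical finite island simulation
#'
#' Simulates ideal microsatellite loci in a hierarchical island model:
#' each parent of each offspring is drawn by first picking a source
#' population (own, sister population within the deme, or a population
#' of another deme, per the migration kernel) and then a uniform
#' individual from it, so gene lineages migrate independently; each
#' transmitted allele mutates with probability `mu` under the chosen
#' model. Generations are
#' non-overlapping; the initial state is maximally diverse (uniform
#' random allelic states). The final generation is returned as genotypes.
#'
#' @param cfg an `island_config`.
#' @return a `geno_tab` with one population per simulated population,
#'   labelled `A1, A2, B1, B2, ...` (deme letter + population number).
#' @export
simulate_island <- function(cfg) {
  stopifnot(inherits(cfg, "island_config"))
  set.seed(cfg$seed)
  P <- cfg$demes * cfg$pops_per_deme
  N <- cfg$N; L <- cfg$loci
  deme_of <- rep(seq_len(cfg$demes), each = cfg$pops_per_deme)
  # migration kernel: rows = target pop, cols = source pop
  M <- matrix(0, P, P)
  for (t in seq_len(P)) {
    same_deme <- which(deme_of == deme_of[t] & seq_len(P) != t)
    other <- which(deme_of != deme_of[t])
    M[t, t] <- 1 - cfg$m_within - cfg$m_between
    if (length(same_deme)) M[t, same_deme] <- cfg$m_within / length(same_deme)
    if (length(other)) M[t, other] <- cfg$m_between / length(other)
  }
  if (any(M < 0)) stop("migration probabilities exceed 1")
  init <- function() matrix(sample.int(cfg$k, N * P * L, replace = TRUE), N * P, L)
  if (cfg$mutation == "SMM") {
    A1 <- matrix(100L + sample(-3:3, N * P * L, replace = TRUE), N * P, L)
    A2 <- matrix(100L + sample(-3:3, N * P * L, replace = TRUE), N * P, L)
  } else {
    A1 <- init(); A2 <- init()
  }
  popidx <- rep(seq_len(P), each = N)
  for (g in seq_len(cfg$generations)) {
    pick_parent <- function() {
      src <- integer(N * P)
      for (t in seq_len(P))
        src[popidx == t] <- sample.int(P, N, replace = TRUE, prob = M[t, ])
      (src - 1L) * N + sample.int(N, N * P, replace = TRUE)
    }
    mo <- pick_parent(); fa <- pick_parent()
    gam <- function(par) {
      use1 <- matrix(stats::runif(N * P * L) < 0.5, N * P, L)
      out <- A2[par, , drop = FALSE]
      out[use1] <- A1[par, , drop = FALSE][use1]
      out
    }
    N1 <- gam(mo); N2 <- gam(fa)
    mutate <- function(mat) {
      hit <- which(stats::runif(length(mat)) < cfg$mu)
      if (length(hit)) {
        if (cfg$mutation == "KAM") {
          step <- sample.int(cfg$k - 1L, length(hit), replace = TRUE)
          mat[hit] <- 1L + (mat[hit] - 1L + step) %% cfg$k
        } else {
          mat[hit] <- mat[hit] + sample(c(-1L, 1L), length(hit), replace = TRUE)
        }
      }
      mat
    }
    A1 <- mutate(N1); A2 <- mutate(N2)
  }
  labs <- paste0(rep(LETTERS[seq_len(cfg$demes)], each = cfg$pops_per_deme),
                 rep(seq_len(cfg$pops_per_deme), cfg$demes))
  genotype_table(sprintf("%s_%03d", labs[popidx], rep(seq_len(N), P)),
                 labs[popidx], A1, A2, sprintf("sim%02d", seq_len(L)))
}

#' Calibrate the island simulator to observed diversity levels
#'
#' Grid search over mutation rate, between-deme migration and population
#' size for a configuration whose simulated populations show mean
#' within-population expected heterozygosity and between-deme theta
#' inside the target windows.
#'
#' @param he_range target window for mean within-population H_E.
#' @param theta_range target window for between-deme theta.
#' @param grid data.frame of candidate `mu`, `m_between`, `N` values
#'   (a small default grid is supplied).
#' @param loci,generations simulation size per candidate.
#' @param seed integer RNG seed.
#' @return list with `config` (best `island_config`), `results`
#'   (data.frame of the grid with achieved `he` and `theta`).
#' @export
calibrate_island <- function(he_range = c(0.38, 0.58),
                             theta_range = c(0.3, 0.5),
                             grid = expand.grid(mu = c(4e-4, 8e-4, 1.6e-3),
                                                m_between = c(5e-4, 9e-4, 2e-3),
                                                N = 100),
                             loci = 12L, generations = 800L, seed = 1L) {
  res <- grid
  res$he <- res$theta <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- island_config(N = grid$N[i], m_within = 0.02,
                         m_between = grid$m_between[i], mu = grid$mu[i],
                         loci = loci, generations = generations,
                         seed = seed + i)
    tab <- simulate_island(cfg)
    ss <- summary_stats(tab, boot = 0L)
    res$he[i] <- mean(ss$h_e)
    # between-deme theta: first pop of each deme
    res$theta[i] <- wc_theta(tab, c("A1", "B1"), boot = 0L)$theta
  }
  mid <- function(r) mean(r)
  score <- abs(res$he - mid(he_range)) / diff(he_range) +
    abs(res$theta - mid(theta_range)) / diff(theta_range)
  ok <- res$he >= he_range[1] & res$he <= he_range[2] &
    res$theta >= theta_range[1] & res$theta <= theta_range[2]
  best <- if (any(ok)) which(ok)[which.min(score[ok])] else which.min(score)
  cfg <- island_config(N = grid$N[best], m_within = 0.02,
                       m_between = grid$m_between[best], mu = grid$mu[best],
                       loci = loci, generations = generations, seed = seed)
  list(config = cfg, results = res)
}

#' Default calibrated configuration for scenario S2
#'
#' The configuration selected by [calibrate_island()] for the study-like
#' targets (within-population H_E near 0.5, between-deme theta near 0.4);
#' see the methods vignette for the calibration run.
#'
#' @param loci number of loci (default 12).
#' @param seed integer RNG seed.
#' @return an `island_config`.
#' @export
island_default_config <- function(loci = 12L, seed = 1L) {
  island_config(N = 100L, m_within = 0.02, m_between = 5e-04,
                loci = loci, mutation = "KAM", k = 20L, mu = 8e-4,
                generations = 800L, seed = seed)
}

#' Build the simulated-baseline scenario (S2)
#'
#' Runs the hierarchical island simulation, uses one population per deme
#' (A2 and B1) as parental baselines to simulate hybrid classes and an
#' introgressed mixture exactly as in [build_s1()], and assembles the
#' mixture (labelled `A2B1`) with the two reference-but-not-parental
#' populations A1 and B2.
#'
#' @param cfg an `island_config` producing four populations.
#' @param roster,per_class,mixture as in [build_s1()].
#' @param seed integer RNG seed.
#' @return list with `analysis` (`geno_tab` of A1, B2 and the `A2B1`
#'   mixture), `truth` (labels of the mixture individuals), `pool`,
#'   `pool_truth`, `baselines` (the full simulated table).
#' @export
build_s2 <- function(cfg, roster = c("P1", "F1", "F2", "P1_bx", "P1_bx1"),
                     per_class = 100L, mixture = 50L, seed = 1L) {
  tab <- simulate_island(cfg)
  if (!all(c("A1", "A2", "B1", "B2") %in% pop_names(tab)))
    stop("configuration must produce populations A1, A2, B1, B2")
  af <- allele_freqs(tab)
  sim <- simulate_classes(pool_freqs(af, "A2"), pool_freqs(af, "B1"),
                          stats::setNames(rep(per_class, length(roster)), roster),
                          seed = seed)
  mix <- sample_mixture(sim$table, sim$truth, mixture, seed = seed + 1L,
                        pop = "A2B1")
  refs <- tab[tab$pop %in% c("A1", "B2"), ]
  list(analysis = bind_with_union(refs, mix$table), truth = mix$truth,
       pool = sim$table, pool_truth = sim$truth, baselines = tab)
}

#' FDIST-style F_ST outlier scan
#'
#' Screens loci for unusually high (or low) differentiation given their
#' heterozygosity. Neutral loci are simulated under a finite island
#' model: ancestral allele frequencies are drawn per locus, deme
#' frequencies follow the island-model equilibrium distribution
#' (Dirichlet with concentration `M = 4Nm` towards the ancestral
#' frequencies, the many-deme approximation with `ndemes` demes of which
#' the observed number of samples is taken), genotypes are sampled at the
#' observed sample sizes, and Weir-Cockerham theta is computed per
#' simulated locus. `M` is tuned iteratively so the simulated mean theta
#' matches the observed global theta. Each observed locus receives
#' `p = P(theta_sim >= theta_obs)` among simulated loci in its
#' heterozygosity bin.
#'
#' @param x a `geno_tab` with >= 2 populations.
#' @param ndemes demes assumed in the island model (default 100).
#' @param reps simulated neutral loci (default 100000).
#' @param bins heterozygosity bins for conditioning (default 50).
#' @param seed integer RNG seed.
#' @return data.frame per locus: `locus`, `he` (mean within-population
#'   expected heterozygosity), `theta`, `p`, `p_adj` (B-Y adjusted).
#'   Attribute `"M"` records the tuned migration parameter.
#' @export
fdist_scan <- function(x, ndemes = 100L, reps = 100000L, bins = 50L, seed = 1L) {
  pops <- pop_names(x)
  if (length(pops) < 2L) stop("need >= 2 populations")
  L <- n_loc(x)
  ss <- vapply(pops, function(p) sum(x$pop == p), 0L)
  obs <- data.frame(locus = x$loci, he = NA_real_, theta = NA_real_)
  Avec <- Dvec <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    comp <- wc_components(x, j)
    Avec[j] <- comp[1]; Dvec[j] <- sum(comp)
    obs$theta[j] <- if (Dvec[j] > 0) comp[1] / Dvec[j] else NA_real_
    hes <- vapply(pops, function(p) {
      st <- pop_locus_stats(x, p, j)
      if (is.null(st)) NA_real_ else st$he
    }, 0)
    obs$he[j] <- mean(hes, na.rm = TRUE)
  }
  gtheta <- sum(Avec, na.rm = TRUE) / sum(Dvec, na.rm = TRUE)
  if (!is.finite(gtheta) || gtheta <= 0)
    stop("observed mean theta is non-positive; outlier scan aborted")
  nall_obs <- vapply(seq_len(L), function(j)
    length(unique(stats::na.omit(c(x$a1[, j], x$a2[, j])))), 0L)
  nall_obs <- pmax(nall_obs, 2L)
  set.seed(seed)
  npop <- length(pops)
  nbar <- mean(ss)
  nc <- (npop * nbar - sum(ss^2) / (npop * nbar)) / (npop - 1)
  sim_batch <- function(M, n) {
    he <- th <- numeric(n)
    for (r in seq_len(n)) {
      k <- sample(nall_obs, 1L)
      anc <- stats::rgamma(k, 1); anc <- anc / sum(anc)
      pm <- hm <- matrix(0, npop, k)
      hesum <- 0
      for (pi in seq_len(npop)) {
        f <- stats::rgamma(k, M * anc); f <- f / sum(f)
        g1 <- sample.int(k, ss[pi], replace = TRUE, prob = f)
        g2 <- sample.int(k, ss[pi], replace = TRUE, prob = f)
        pm[pi, ] <- (tabulate(g1, k) + tabulate(g2, k)) / (2 * ss[pi])
        hvec <- g1 != g2
        for (a in seq_len(k)) hm[pi, a] <- mean(hvec & (g1 == a | g2 == a))
        nn <- ss[pi]
        hesum <- hesum + (2 * nn / (2 * nn - 1)) * (1 - sum(pm[pi, ]^2))
      }
      suma <- sumd <- 0
      for (a in seq_len(k)) {
        p <- pm[, a]; h <- hm[, a]
        pbar <- sum(ss * p) / (npop * nbar)
        hbar <- sum(ss * h) / (npop * nbar)
        s2 <- sum(ss * (p - pbar)^2) / ((npop - 1) * nbar)
        av <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                (pbar * (1 - pbar) - ((npop - 1) / npop) * s2 - hbar / 4))
        bv <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
                ((npop - 1) / npop) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
        suma <- suma + av; sumd <- sumd + av + bv + hbar / 2
      }
      th[r] <- if (sumd > 0) suma / sumd else NA_real_
      he[r] <- hesum / npop
    }
    data.frame(he = he, theta = th)
  }
  # tune M so simulated mean theta matches the observed global theta
  M <- max((1 - gtheta) / gtheta, 0.05)
  for (it in 1:3) {
    cal <- sim_batch(M, 400L)
    mt <- mean(cal$theta, na.rm = TRUE)
    if (!is.finite(mt) || mt <= 0 || mt >= 1) break
    M <- M * (mt / (1 - mt)) / (gtheta / (1 - gtheta))
  }
  sims <- sim_batch(M, reps)
  sims <- sims[is.finite(sims$theta) & is.finite(sims$he), ]
  brk <- seq(0, 1, length.out = bins + 1L)
  bin_of <- function(he) pmin(pmax(findInterval(he, brk, rightmost.closed = TRUE), 1L), bins)
  sims$bin <- bin_of(sims$he)
  obs$p <- NA_real_
  for (j in seq_len(L)) {
    if (!is.finite(obs$theta[j])) next
    b <- bin_of(obs$he[j])
    width <- 0L
    repeat {
      sel <- sims$theta[sims$bin >= b - width & sims$bin <= b + width]
      if (length(sel) >= 100L || width >= bins) break
      width <- width + 1L
    }
    obs$p[j] <- (1 + sum(sel >= obs$theta[j])) / (length(sel) + 1)
  }
  obs$p_adj <- by_fdr(obs$p)
  attr(obs, "M") <- M
  obs
}
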