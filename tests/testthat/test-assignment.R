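test_that("membership rows are proper probability vectors for both engines", {
  st <- simulate_study(seed = 31, n = c(FLU = 20L, TRA = 12L, CAR = 12L, DRA = 12L))
  tab <- filter_loci(st$table)$table
  fit <- newhybrids_fit(tab, iters = 3000, burn = 500, replicates = 2,
                        seed = 1, anchor = "TRA")
  for (q in fit$q) {
    expect_true(all(q >= 0))
    expect_equal(unname(rowSums(q)), rep(1, nrow(q)), tolerance = 1e-9)
  }
  em <- snapclust_fit(tab, seed = 2, anchor = "TRA")
  expect_true(all(em$q >= 0))
  expect_equal(unname(rowSums(em$q)), rep(1, nrow(em$q)), tolerance = 1e-9)
})

test_that("an all-heterozygous individual across fixed loci is an F1 with certainty", {
  refs <- fixed_diff_refs(15, 15, 10)
  f1 <- genotype_table("h1", "MIX", matrix(100L, 1, 10), matrix(200L, 1, 10),
                       refs$loci)
  tab <- pikemix:::bind_with_union(refs, f1)
  fit <- newhybrids_fit(tab, iters = 8000, burn = 2000, replicates = 1,
                        seed = 3, anchor = "R1")
  expect_gt(fit$q[[1]]["h1", "F1"], 0.99)
  em <- snapclust_fit(tab, seed = 4, anchor = "R1")
  expect_gt(em$q["h1", "F1"], 0.99)
  expect_gt(mean(em$q[tab$pop == "R1", "P1"]), 0.99)
  expect_gt(mean(em$q[tab$pop == "R2", "P2"]), 0.99)
})

test_that("the Gibbs posterior matches exact enumeration on a two-locus toy", {
  # three individuals with known genotypes, frozen pool frequencies and
  # uniform class proportions: the posterior is the normalised product
  # of class likelihoods
  classes <- hybrid_classes()
  f1 <- list(c(0.8, 0.2), c(0.7, 0.3))
  f2 <- list(c(0.1, 0.9), c(0.25, 0.75))
  tab <- genotype_table(c("i1", "i2", "i3"), rep("M", 3),
                        matrix(c(1L, 1L, 1L,  1L, 1L, 2L), 3),
                        matrix(c(1L, 2L, 2L,  1L, 2L, 2L), 3),
                        c("LA", "LB"))
  # analytic class likelihoods
  lik <- matrix(0, 3, nrow(classes))
  for (i in 1:3) for (c in seq_len(nrow(classes))) {
    z <- unlist(classes[c, c("z11", "z12", "z22")])
    ll <- 1
    for (j in 1:2) {
      x <- tab$a1[i, j]; y <- tab$a2[i, j]
      p11 <- if (x == y) f1[[j]][x]^2 else 2 * f1[[j]][x] * f1[[j]][y]
      p22 <- if (x == y) f2[[j]][x]^2 else 2 * f2[[j]][x] * f2[[j]][y]
      p12 <- if (x == y) f1[[j]][x] * f2[[j]][x] else
        f1[[j]][x] * f2[[j]][y] + f1[[j]][y] * f2[[j]][x]
      ll <- ll * (z[1] * p11 + z[2] * p12 + z[3] * p22)
    }
    lik[i, c] <- ll
  }
  oracle <- lik / rowSums(lik)
  # five independent short chains; compare the mean against the oracle
  # within 3 standard errors of the replicate means
  runs <- lapply(1:5, function(r)
    newhybrids_fit(tab, iters = 6000, burn = 1000, replicates = 1,
                   seed = 100 + r, fix_freqs = list(f1 = f1, f2 = f2),
                   fix_pi = TRUE)$q[[1]])
  qbar <- Reduce(`+`, runs) / 5
  qse <- sqrt(Reduce(`+`, lapply(runs, function(q) (q - qbar)^2)) / 4 / 5)
  expect_true(all(abs(qbar - oracle) < 3 * qse + 0.01))
})

test_that("EM memberships equal the Bayes rule on a one-locus toy with frozen pools", {
  x <- genotype_table(c("i1", "i2"), c("M", "M"),
                      matrix(c(1L, 1L), 2), matrix(c(1L, 2L), 2), "L")
  f1 <- list(c(0.9, 0.1)); f2 <- list(c(0.2, 0.8))
  fit <- snapclust_fit(x, shares = c(P1 = 1, F1 = 0.5, P2 = 0),
                       fix_freqs = list(f1 = f1, f2 = f2), fix_pi = TRUE)
  hom <- c(0.9^2, 0.55^2, 0.2^2)
  het <- c(2 * 0.9 * 0.1, 2 * 0.55 * 0.45, 2 * 0.2 * 0.8)
  expect_equal(unname(fit$q[1, ]), hom / sum(hom), tolerance = 1e-9)
  expect_equal(unname(fit$q[2, ]), het / sum(het), tolerance = 1e-9)
})

test_that("the EM log-likelihood never decreases on random datasets", {
  set.seed(6)
  for (r in 1:100) {
    tab <- random_small_table(n_pops = 2, n_per = 10, n_loci = 3,
                              n_alleles = 3, miss = sample(c(0, 0.1), 1))
    em <- snapclust_fit(tab, max_iter = 30, seed = r)
    expect_true(all(diff(em$loglik_trace) > -1e-6))
  }
})

test_that("EM results are invariant to individual order", {
  set.seed(7)
  st <- simulate_study(seed = 7, n = c(FLU = 15L, TRA = 10L, CAR = 10L, DRA = 10L))
  tab <- filter_loci(st$table)$table
  em1 <- snapclust_fit(tab, seed = 1, anchor = "TRA")
  o <- sample(n_ind(tab))
  em2 <- snapclust_fit(tab[o, ], seed = 1, anchor = "TRA")
  expect_equal(max(abs(em2$loglik_trace[length(em2$loglik_trace)] -
                         em1$loglik_trace[length(em1$loglik_trace)])), 0,
               tolerance = 1e-6)
  expect_equal(em2$q[tab$id, ], em1$q[tab$id, ], tolerance = 1e-4)
})

test_that("both engines agree on parental assignments over fixed-difference panels", {
  refs <- fixed_diff_refs(12, 12, 10)
  fit <- newhybrids_fit(refs, iters = 6000, burn = 1000, replicates = 1,
                        seed = 8, anchor = "R1")
  em <- snapclust_fit(refs, seed = 9, anchor = "R1")
  r1 <- refs$pop == "R1"
  expect_true(all(fit$q[[1]][r1, "P1"] > 0.9))
  expect_true(all(fit$q[[1]][!r1, "P2"] > 0.9))
  expect_true(all(em$q[r1, "P1"] > 0.9))
  expect_true(all(em$q[!r1, "P2"] > 0.9))
})

test_that("DAPC separates clone groups perfectly and ranks species first", {
  # two clone groups
  n <- 8
  a1 <- rbind(matrix(100L, n, 6), matrix(200L, n, 6))
  tab <- genotype_table(paste0("i", 1:(2 * n)), rep(c("G1", "G2"), each = n),
                        a1, a1, paste0("L", 1:6))
  dm <- dapc_fit(tab, n_pca = 2, seed = 1)
  expect_equal(mean(as.character(dm$assign) == tab$pop), 1)
  # 4-population study-like data: DF1 splits the two species
  st <- simulate_study(seed = 33)
  tab4 <- filter_loci(st$table)$table
  dm4 <- dapc_fit(tab4, seed = 2)
  expect_gte(mean(as.character(dm4$assign) == tab4$pop), 0.95)
  d1 <- tapply(dm4$ind_coord[, 1], tab4$pop, mean)
  gap_species <- min(abs(d1[c("FLU", "TRA", "CAR")] - d1["DRA"]))
  gap_within <- max(dist(d1[c("FLU", "TRA", "CAR")]))
  expect_gt(gap_species, gap_within)
})

test_that("held-out reassignment collapses to chance under permuted labels", {
  set.seed(11)
  st <- simulate_study(seed = 11)
  tab <- filter_loci(st$table)$table
  perm <- sample(rep(c("X", "Y"), length.out = n_ind(tab)))
  dm <- dapc_fit(tab, groups = perm, pca_grid = c(5, 15, 30), folds = 4, seed = 3)
  expect_lt(max(dm$cv$success, na.rm = TRUE), 0.5 + 0.2)
})

test_that("cluster inference finds one cluster in panmixia and four islands", {
  set.seed(12)
  one <- random_small_table(n_pops = 1, n_per = 60, n_loci = 8, n_alleles = 4)
  fc1 <- find_clusters(one, seed = 1)
  expect_equal(fc1$k, 1L)
  cfg <- island_config(N = 60, m_within = 4e-4, m_between = 1e-4, loci = 12,
                       mu = 1e-3, generations = 600, seed = 13)
  tab4 <- simulate_island(cfg)
  fc4 <- find_clusters(tab4, seed = 2)
  expect_equal(fc4$k, 4L)
  # agreement with the true populations (adjusted Rand via pair counting)
  tb <- table(fc4$labels, tab4$pop)
  agree <- sum(apply(tb, 1, max)) / sum(tb)
  expect_gt(agree, 0.95)
})

test_that("label-switch anchoring reports and repairs mirrored replicates", {
  refs <- fixed_diff_refs(10, 10, 8)
  fit <- newhybrids_fit(refs, iters = 4000, burn = 1000, replicates = 3,
                        seed = 21, anchor = "R1")
  # after anchoring, every replicate assigns R1 to P1
  for (q in fit$q) expect_gt(mean(q[refs$pop == "R1", "P1"]), 0.9)
  ag <- replicate_agreement(fit)
  expect_true(all(ag > 0.9))
})
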