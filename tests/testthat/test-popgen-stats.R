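test_that("rarefied allelic richness matches the combinatorial formula", {
  # copies (3,1), G = 4, g = 2: (1 - C(1,2)/C(4,2)) + (1 - C(3,2)/C(4,2)) = 1.5
  expect_equal(allelic_richness(c(3, 1), 2), 1.5, tolerance = 1e-12)
  expect_equal(allelic_richness(c(5, 5), 10), 2, tolerance = 1e-12)
  set.seed(2)
  for (r in 1:100) {
    cnt <- sample(1:10, sample(2:5, 1), replace = TRUE)
    g <- sample(seq_len(sum(cnt)), 1)
    expect_equal(allelic_richness(cnt, g), oracle_ar(cnt, g), tolerance = 1e-12)
  }
  expect_error(allelic_richness(c(2, 2), 5), "exceeds")
})

test_that("richness is non-decreasing in g and equals N_A at full depth", {
  set.seed(3)
  cnt <- c(7, 4, 2, 1)
  ar <- vapply(1:14, function(g) allelic_richness(cnt, g), 0)
  expect_true(all(diff(ar) > -1e-12))
  expect_equal(ar[14], 4, tolerance = 1e-12)
})

test_that("summary statistics behave on monomorphic and diagnostic loci", {
  n <- 10
  tab <- genotype_table(paste0("i", 1:n), rep("P", n),
                        cbind(matrix(1L, n), matrix(rep(c(1L, 2L), n / 2), n)),
                        cbind(matrix(1L, n), matrix(2L, n)),
                        c("mono", "poly"))
  ss <- summary_stats(tab, boot = 100, seed = 1)
  # per-locus means over {mono, poly}
  st_mono <- pikemix:::pop_locus_stats(tab, "P", 1, g = 2)
  expect_equal(st_mono$he, 0)
  expect_equal(st_mono$ho, 0)
  expect_equal(st_mono$ar, 1, tolerance = 1e-12)
  expect_true(ss$h_e[1] >= 0 && ss$h_e[1] <= 1)
})

test_that("unbiased H_E matches its definition on random data", {
  set.seed(4)
  for (r in 1:50) {
    x1 <- sample(1:4, 12, TRUE); x2 <- sample(1:4, 12, TRUE)
    tab <- genotype_table(paste0("i", 1:12), rep("P", 12),
                          matrix(x1), matrix(x2), "L")
    st <- pikemix:::pop_locus_stats(tab, "P", 1)
    expect_equal(st$he, oracle_he(pmin(x1, x2), pmax(x1, x2)), tolerance = 1e-12)
  }
})

test_that("theta is 1 for fixed differences and about 0 for identical pops", {
  tab <- fixed_diff_refs(10, 10, 3)
  expect_equal(wc_theta(tab, boot = 0)$theta, 1, tolerance = 1e-12)
  # two copies of the same sample; the finite-sample estimators hover
  # near zero with O(1/n) wobble, so use a large duplicated sample
  set.seed(6)
  one <- random_small_table(n_pops = 1, n_per = 150, n_loci = 5)
  two <- genotype_table(c(one$id, paste0("c", one$id)),
                        rep(c("P1", "P2"), each = 150),
                        rbind(one$a1, one$a1), rbind(one$a2, one$a2), one$loci)
  expect_lte(abs(wc_theta(two, boot = 0)$theta), 0.01)
  expect_lte(abs(jost_d(two, boot = 0)$d), 0.01)
})

test_that("theta equals the hand-computed variance components on a toy", {
  tab <- genotype_table(paste0("i", 1:6), rep(c("P1", "P2"), each = 3),
                        c(1L, 1L, 1L, 2L, 1L, 2L), c(1L, 1L, 2L, 2L, 2L, 2L),
                        "L")
  expect_equal(wc_theta(tab, boot = 0)$theta, oracle_theta(tab),
               tolerance = 1e-12)
})

test_that("theta and D match independent oracles on random tables", {
  set.seed(7)
  for (r in 1:60) {
    tab <- random_small_table(n_pops = sample(2:3, 1), n_per = sample(4:9, 1),
                              n_loci = sample(1:3, 1), n_alleles = sample(2:5, 1),
                              miss = sample(c(0, 0.15), 1))
    expect_equal(wc_theta(tab, boot = 0)$theta, oracle_theta(tab),
                 tolerance = 1e-12)
    jd <- jost_d(tab, boot = 0)
    for (j in seq_len(n_loc(tab)))
      expect_equal(jd$per_locus$d[j], oracle_jost_locus(tab, j),
                   tolerance = 1e-12)
  }
})

test_that("Jost's D hits its boundary cases", {
  # identical genotype arrays in both pops: D vanishes with sample size
  # (the unbiased estimators leave O(1/n) terms)
  a1 <- matrix(rep(c(1L, 2L), 100), 200)
  a2 <- matrix(2L, 200, 1)
  tab <- genotype_table(paste0("i", 1:200), rep(c("A", "B"), each = 100),
                        a1, a2, "L")
  expect_lt(abs(jost_d(tab, boot = 0)$d), 0.005)
  expect_equal(jost_d(fixed_diff_refs(10, 10, 2), boot = 0)$d, 1,
               tolerance = 1e-12)
})

test_that("bootstrap CIs contain the point estimate and tighten with loci", {
  set.seed(8)
  st <- simulate_study(seed = 8)
  tab <- filter_loci(st$table)$table
  wt <- wc_theta(tab, boot = 500, seed = 1)
  expect_true(wt$ci[1] <= wt$theta && wt$theta <= wt$ci[2])
  # quadruplicating the loci roughly halves the CI width
  tab4 <- genotype_table(tab$id, tab$pop,
                         cbind(tab$a1, tab$a1, tab$a1, tab$a1),
                         cbind(tab$a2, tab$a2, tab$a2, tab$a2),
                         paste0("L", seq_len(4 * n_loc(tab))))
  wt4 <- wc_theta(tab4, boot = 500, seed = 1)
  ratio <- diff(wt4$ci) / diff(wt$ci)
  expect_lt(ratio, 0.75)
})

test_that("exact G differentiation combines per-locus tests with df = 2L", {
  set.seed(9)
  st <- simulate_study(seed = 9)
  tab <- filter_loci(st$table)$table
  g <- exact_g_diff(tab, B = 300, seed = 2)
  expect_equal(g$df, 2L * 11L)
  expect_lt(g$p, 0.001)
  # fixed differences drive p to the Monte Carlo floor
  gf <- exact_g_diff(fixed_diff_refs(15, 15, 2), B = 500, seed = 3)
  expect_equal(gf$per_locus$p, rep(1 / 501, 2), tolerance = 1e-12)
})

test_that("global differentiation p-values are roughly uniform under panmixia", {
  set.seed(10)
  ps <- replicate(120, {
    pool <- matrix(sample(1:3, 80, TRUE), 20)
    tab <- genotype_table(paste0("i", 1:20), rep(c("A", "B"), each = 10),
                          pool[, 1:2], pool[, 3:4], c("L1", "L2"))
    exact_g_diff(tab, B = 200, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.65)
})
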