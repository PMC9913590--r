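test_that("monomorphic loci give an undefined HW test, not a silent p-value", {
  x <- genotype_table(paste0("i", 1:5), rep("P", 5),
                      matrix(1L, 5), matrix(1L, 5), "L")
  r <- hw_exact_test(x, "P", 1)
  expect_false(r$defined)
  expect_true(is.na(r$p))
})

test_that("the Markov-chain HW p-value matches complete enumeration", {
  # 5 diploids, 2 alleles (counts 4/6), both directions
  x <- genotype_table(paste0("i", 1:5), rep("P", 5),
                      c(1L, 1L, 1L, 2L, 1L), c(1L, 2L, 2L, 2L, 2L), "L")
  for (dir in c("deficit", "excess")) {
    p_exact <- oracle_hw_enum(x$a1[, 1], x$a2[, 1], dir)
    r <- hw_exact_test(x, "P", 1, dir,
                       mc = list(demem = 2000, batches = 60, iters = 3000),
                       seed = 5)
    expect_lt(abs(r$p - p_exact), 3 * r$se + 1e-6)
  }
  # a 3-allele case
  y <- genotype_table(paste0("i", 1:6), rep("P", 6),
                      c(1L, 1L, 2L, 3L, 1L, 2L), c(1L, 2L, 2L, 3L, 3L, 3L), "L")
  p_exact <- oracle_hw_enum(y$a1[, 1], y$a2[, 1], "deficit")
  r <- hw_exact_test(y, "P", 1, "deficit",
                     mc = list(demem = 2000, batches = 60, iters = 3000), seed = 6)
  expect_lt(abs(r$p - p_exact), 3 * r$se + 1e-6)
})

test_that("a duplicated locus shows maximal genotypic disequilibrium", {
  set.seed(8)
  a1 <- matrix(sample(1:4, 30, TRUE), 30)
  a2 <- matrix(sample(1:4, 30, TRUE), 30)
  tab <- genotype_table(paste0("i", 1:30), rep("P", 30),
                        cbind(a1, a1), cbind(a2, a2), c("LA", "LB"))
  r <- ld_exact_test(tab, "P", "LA", "LB", B = 2000, seed = 1)
  expect_lt(r$p, 0.01)
  # monomorphic partner -> undefined
  mono <- genotype_table(paste0("i", 1:30), rep("P", 30),
                         cbind(a1, matrix(1L, 30)), cbind(a2, matrix(1L, 30)),
                         c("LA", "LB"))
  expect_false(ld_exact_test(mono, "P", "LA", "LB")$defined)
})

test_that("LD p-values are approximately uniform under independence", {
  set.seed(21)
  ps <- replicate(400, {
    a1 <- matrix(sample(1:3, 60, TRUE), 30)
    a2 <- matrix(sample(1:3, 60, TRUE), 30)
    tab <- genotype_table(paste0("i", 1:30), rep("P", 30), a1, a2, c("LA", "LB"))
    r <- ld_exact_test(tab, "P", 1, 2, B = 400, seed = sample.int(1e6, 1))
    r$p
  })
  # discrete + conservative, so test mean and a coarse KS bound
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps), 0.62)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 1e-3)
})

test_that("binomial excess check matches direct pmf summation", {
  expect_equal(binomial_excess(0, 10)$p_exceed, 1)
  be <- binomial_excess(25, 63)
  brute <- sum(vapply(25:63, function(k)
    choose(63, k) * 0.05^k * 0.95^(63 - k), 0))
  expect_equal(be$p_exceed, brute, tolerance = 1e-12)
  # critical count: largest k0 with P(X >= k0+1) > alpha, by brute force
  tail_p <- function(k) sum(vapply(k:63, function(i)
    choose(63, i) * 0.05^i * 0.95^(63 - i), 0))
  crit_brute <- max(which(vapply(0:63, function(k0) tail_p(k0 + 1) > 0.05, NA))) - 1L
  expect_equal(be$critical_count, crit_brute)
  # the study-scale linkage battery: 78 of 480 is a clear excess
  expect_lt(binomial_excess(78, 480)$p_exceed, 0.05)
  expect_error(binomial_excess(1, 0), "positive")
})

test_that("B-Y adjustment matches the step-up definition and dominates B-H", {
  expect_equal(by_fdr(0.03), 0.03)  # c(1) = 1
  p <- c(0.01, 0.02, 0.05)
  expect_equal(by_fdr(p), oracle_by(p), tolerance = 1e-12)
  # manual value: c(3) = 11/6; smallest adjusted = 0.01 * 3 * 11/6 / 1 = 0.055
  expect_equal(by_fdr(p)[1], 0.055, tolerance = 1e-12)
  set.seed(3)
  for (r in 1:100) {
    pv <- stats::runif(sample(2:20, 1))
    adj <- by_fdr(pv)
    bh <- stats::p.adjust(pv, "BH")
    expect_true(all(adj >= bh - 1e-12))
    expect_true(all(bh >= pv - 1e-12))
    expect_true(all(adj <= 1 + 1e-12))
    # permutation invariance
    o <- sample(length(pv))
    expect_equal(by_fdr(pv[o]), adj[o], tolerance = 1e-12)
  }
  # grouped adjustment operates within groups only
  pv <- c(0.01, 0.5, 0.01, 0.5)
  g <- c("a", "a", "b", "b")
  expect_equal(by_fdr(pv, g)[1:2], oracle_by(pv[1:2]), tolerance = 1e-12)
})

test_that("test batteries exclude undefined combinations from denominators", {
  set.seed(9)
  tab <- random_small_table(n_pops = 2, n_per = 10, n_loci = 3, n_alleles = 3)
  # make locus 2 monomorphic in population P1 only
  i <- tab$pop == "P1"
  tab$a1[i, 2] <- 102L; tab$a2[i, 2] <- 102L
  b <- hw_battery(tab, mc = list(demem = 200, batches = 10, iters = 200), seed = 2)
  expect_equal(nrow(b), 2 * 3 - 1)  # one (pop, locus) cell undefined
  expect_true(all(b$p_adj >= b$p - 1e-12))
})

test_that("dropout rates are near zero for clean equilibrium data", {
  set.seed(14)
  n <- 150
  a1 <- matrix(sample(1:4, n * 3, TRUE), n)
  a2 <- matrix(sample(1:4, n * 3, TRUE), n)
  tab <- genotype_table(paste0("i", 1:n), rep("P", n), a1, a2,
                        paste0("L", 1:3))
  m <- estimate_dropout(tab)
  expect_true(all(m$rates < 0.02))
})

test_that("a simulated dropout rate of 0.2 is recovered within 0.05", {
  set.seed(15)
  n <- 200
  a1 <- matrix(sample(1:4, n * 2, TRUE), n)
  a2 <- matrix(sample(1:4, n * 2, TRUE), n)
  d <- 0.2
  for (i in 1:n) {
    d1 <- runif(1) < d; d2 <- runif(1) < d
    if (d1 && d2) { a1[i, 1] <- NA; a2[i, 1] <- NA }
    else if (d1) a1[i, 1] <- a2[i, 1]
    else if (d2) a2[i, 1] <- a1[i, 1]
  }
  tab <- genotype_table(paste0("i", 1:n), rep("P", n), a1, a2, c("L1", "L2"))
  m <- estimate_dropout(tab)
  expect_lt(abs(m$rates["L1"] - d), 0.05)
  expect_lt(m$rates["L2"], 0.05)
})

test_that("genotype correction only opens homozygotes or fills missing calls", {
  set.seed(16)
  st <- simulate_study(seed = 16, n = c(FLU = 30L, TRA = 15L, CAR = 15L, DRA = 15L))
  tab <- st$table
  m <- estimate_dropout(tab)
  cor <- correct_genotypes(tab, m, seed = 1)
  expect_identical(cor$loci, tab$loci)
  was_het <- !is.na(tab$a1) & tab$a1 != tab$a2
  # heterozygotes are untouched
  expect_identical(cor$a1[was_het], tab$a1[was_het])
  expect_identical(cor$a2[was_het], tab$a2[was_het])
  # non-missing never becomes missing
  expect_true(all(!is.na(cor$a1[!is.na(tab$a1)])))
  # homozygotes may only open up to a heterozygote carrying the original allele
  was_hom <- !is.na(tab$a1) & tab$a1 == tab$a2
  changed <- was_hom & (cor$a1 != tab$a1 | cor$a2 != tab$a2)
  expect_true(all(cor$a1[changed] == tab$a1[changed] |
                    cor$a2[changed] == tab$a1[changed]))
  # with imputation, missing calls become called
  imp <- correct_genotypes(tab, m, seed = 1, impute_missing = TRUE)
  expect_gte(sum(!is.na(imp$a1)), sum(!is.na(cor$a1)))
})
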