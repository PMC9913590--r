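test_that("the class roster carries the Mendelian gene-origin vectors", {
  cl <- hybrid_classes()
  expect_true(all(abs(rowSums(cl[, c("z11", "z12", "z22")]) - 1) < 1e-12))
  expect_equal(unlist(cl[cl$label == "F2", c("z11", "z12", "z22")],
                      use.names = FALSE), c(0.25, 0.5, 0.25))
  expect_equal(unlist(cl[cl$label == "P1_bx1", c("z11", "z12", "z22")],
                      use.names = FALSE), c(0.75, 0.25, 0))
})

test_that("F1 offspring of fixed-difference parents are heterozygous everywhere", {
  refs <- fixed_diff_refs(15, 15, 5)
  af <- allele_freqs(refs)
  f1 <- hybridise(pool_freqs(af, "R1"), pool_freqs(af, "R2"), 50, seed = 1)
  expect_true(all(f1$a1 == 100L & f1$a2 == 200L))
})

test_that("F2 genotype proportions are 1:2:1 at a fixed-difference locus", {
  refs <- fixed_diff_refs(15, 15, 1)
  af <- allele_freqs(refs)
  sim <- simulate_classes(pool_freqs(af, "R1"), pool_freqs(af, "R2"),
                          c(F2 = 10000L), seed = 2, aux_n = 20000L)
  g <- sim$table
  n <- n_ind(g)
  hom1 <- mean(g$a1[, 1] == 100 & g$a2[, 1] == 100)
  het <- mean(g$a1[, 1] != g$a2[, 1])
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(hom1 - 0.25), 3 * se)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.5 * 0.5 / n))
})

test_that("second-generation backcrosses show the (0.75, 0.25, 0) origin vector", {
  refs <- fixed_diff_refs(15, 15, 4)
  af <- allele_freqs(refs)
  sim <- simulate_classes(pool_freqs(af, "R1"), pool_freqs(af, "R2"),
                          c(P1_bx1 = 10000L), seed = 3, aux_n = 20000L)
  g <- sim$table
  z11 <- mean(g$a1 == 100 & g$a2 == 100)  # both copies species 1
  z12 <- mean(g$a1 != g$a2)
  z22 <- mean(g$a1 == 200 & g$a2 == 200)
  se <- sqrt(0.75 * 0.25 / (n_ind(g) * 4))
  expect_lt(abs(z11 - 0.75), 3 * se)
  expect_lt(abs(z12 - 0.25), 3 * se)
  expect_lt(z22, 3 * se)
})

test_that("simulated pure cohorts converge to their source frequencies", {
  set.seed(5)
  st <- simulate_study(seed = 5)
  tab <- filter_loci(st$table)$table
  af <- allele_freqs(tab)
  f <- pool_freqs(af, "TRA")
  tv <- function(n) {
    sim <- hybridise(f, f, n, seed = 7)
    afs <- allele_freqs(sim)
    mean(vapply(seq_len(n_loc(sim)), function(j) {
      obs <- afs$freq[[j]][1, ]
      src <- f$freq[[j]][1, colnames(afs$freq[[j]])]
      sum(abs(obs - src)) / 2
    }, 0))
  }
  expect_lt(tv(8000), tv(200))
  expect_lt(tv(8000), 0.03)
})

test_that("mixture sampling is uniform without replacement with label bookkeeping", {
  refs <- fixed_diff_refs(6, 6, 2)
  truth <- refs$pop
  # identity at n = pool size
  all_of <- sample_mixture(refs, truth, 12, seed = 1)
  expect_setequal(all_of$table$id, refs$id)
  expect_equal(sort(all_of$truth), sort(truth))
  # n = 0 gives an empty table without error
  none <- sample_mixture(refs, truth, 0, seed = 1)
  expect_equal(n_ind(none$table), 0L)
  expect_error(sample_mixture(refs, truth, 13), "exceeds")
  # class counts follow the hypergeometric
  set.seed(9)
  draws <- replicate(1000, sum(sample_mixture(refs, truth, 6,
                                              seed = sample.int(1e6, 1))$truth == "R1"))
  expect_lt(abs(mean(draws) - 3), 3 * sqrt(stats::var(draws) / 1000))
  hyper_var <- 6 * 0.5 * 0.5 * (12 - 6) / (12 - 1)
  expect_lt(abs(stats::var(draws) - hyper_var), 0.25)
})

test_that("scenario S1 assembles mixture plus untouched references", {
  st <- simulate_study(seed = 6)
  tab <- filter_loci(st$table)$table
  s1 <- build_s1(tab, "TRA", "DRA", per_class = 40, mixture = 30, seed = 2)
  expect_length(s1$truth, 30)
  expect_setequal(pop_names(s1$analysis), c("TRA", "DRA", "MIX"))
  refs_in <- s1$analysis[s1$analysis$pop == "TRA", ]
  refs_orig <- tab[tab$pop == "TRA", ]
  expect_identical(refs_in$a1, refs_orig$a1)
  # both 4-class and 5-class rosters are constructible
  s4 <- build_s1(tab, "TRA", "DRA", roster = c("P1", "F2", "P1_bx", "P1_bx1"),
                 per_class = 100, mixture = 50, seed = 3)
  expect_equal(n_ind(s4$pool), 400L)
  expect_equal(n_ind(s1$pool), 200L)
  s5 <- build_s1(tab, "TRA", "DRA", per_class = 100, mixture = 50, seed = 3)
  expect_equal(n_ind(s5$pool), 500L)
  expect_error(build_s1(tab, "TRA", "DRA", per_class = 10, mixture = 51),
               "exceeds")
})

test_that("mixtures are reproducible under a seed and vary across seeds", {
  st <- simulate_study(seed = 7)
  tab <- filter_loci(st$table)$table
  a <- build_s1(tab, "TRA", "DRA", per_class = 30, mixture = 25, seed = 5)
  b <- build_s1(tab, "TRA", "DRA", per_class = 30, mixture = 25, seed = 5)
  expect_identical(a$analysis$a1, b$analysis$a1)
  expect_identical(a$truth, b$truth)
  comp <- replicate(60, {
    s <- build_s1(tab, "TRA", "DRA", per_class = 30, mixture = 25,
                  seed = sample.int(1e6, 1))
    paste(sort(table(s$truth)), collapse = "-")
  })
  expect_gt(length(unique(comp)), 1)
})

test_that("crossing pools with different locus panels is refused", {
  refs <- fixed_diff_refs(5, 5, 3)
  af <- allele_freqs(refs)
  f1 <- pool_freqs(af, "R1")
  f2 <- pool_freqs(af, "R2")
  f2$loci <- rev(f2$loci)
  expect_error(hybridise(f1, f2, 5), "panels differ")
})
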