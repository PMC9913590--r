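test_that("a minimal GENEPOP file parses into the expected table", {
  f <- withr::local_tempfile()
  writeLines(c("two pops, one locus",
               "LocA",
               "POP",
               "a1 , 001001",
               "a2 , 001002",
               "POP",
               "b1 , 002002",
               "b2 , 002002"), f)
  tab <- read_genepop(f, pop_labels = c("X", "Y"))
  expect_equal(n_ind(tab), 4L)
  expect_equal(n_loc(tab), 1L)
  expect_equal(tab$alleles$LocA, c(1L, 2L))
  expect_equal(tab$pop, c("X", "X", "Y", "Y"))
  expect_false(anyNA(tab$a1))
})

test_that("genotype width mismatches raise a parse error naming the culprit", {
  f <- withr::local_tempfile()
  writeLines(c("t", "LocA", "POP", "a1 , 0101"), f)
  expect_error(read_genepop(f, dialect = "3-digit"), "0101")
})

test_that("missing genotypes are written as zeros and read back as missing", {
  tab <- genotype_table(c("i1", "i2"), c("P", "P"),
                        matrix(c(1L, NA), 2), matrix(c(2L, NA), 2), "L1")
  f <- withr::local_tempfile()
  write_genepop(tab, f)
  expect_true(any(grepl("000000", readLines(f))))
  back <- read_genepop(f)
  expect_true(is.na(back$a1[2, 1]))
})

test_that("an empty population cannot be written and wide alleles are rejected", {
  tab <- genotype_table("i1", "P", matrix(1500L), matrix(1500L), "L1")
  expect_error(write_genepop(tab, withr::local_tempfile(), dialect = "3-digit"),
               "not representable")
})

test_that("read/write round-trips random tables exactly", {
  set.seed(42)
  for (r in seq_len(1000)) {
    tab <- random_small_table(n_pops = sample(1:3, 1), n_per = sample(2:5, 1),
                              n_loci = sample(1:4, 1),
                              n_alleles = sample(2:6, 1),
                              miss = sample(c(0, 0.2), 1))
    f <- tempfile()
    write_genepop(tab, f)
    back <- read_genepop(f)
    unlink(f)
    expect_identical(back$a1, tab$a1)
    expect_identical(back$a2, tab$a2)
    expect_identical(back$pop, tab$pop)
    expect_identical(back$id, tab$id)
  }
})

test_that("the CSV dialect round-trips", {
  set.seed(7)
  tab <- random_small_table(miss = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_geno_csv(tab, f)
  back <- read_geno_csv(f)
  expect_identical(back$a1, tab$a1)
  expect_identical(back$pop, tab$pop)
})

test_that("half-calls are normalised to missing", {
  tab <- genotype_table("i", "P", matrix(5L), matrix(NA_integer_), "L")
  expect_true(is.na(tab$a1[1, 1]) && is.na(tab$a2[1, 1]))
})

test_that("allele frequencies count gene copies exactly and flag undefined cells", {
  x <- genotype_table(c("i1", "i2"), c("P", "P"),
                      matrix(c(1L, 1L)), matrix(c(1L, 2L)), "L")
  af <- allele_freqs(x)
  expect_equal(unname(af$freq$L[1, ]), c(0.75, 0.25))
  # counting oracle on random tables
  set.seed(11)
  for (r in 1:50) {
    tab <- random_small_table(miss = 0.2)
    af <- allele_freqs(tab)
    for (p in pop_names(tab)) for (j in seq_len(n_loc(tab))) {
      nonmiss <- sum(tab$pop == p & !is.na(tab$a1[, j]))
      expect_equal(unname(af$n[p, j]), 2 * nonmiss)
      if (nonmiss > 0) expect_equal(sum(af$freq[[j]][p, ]), 1, tolerance = 1e-12)
    }
  }
  # fully missing cell -> flagged undefined, not NaN-propagating
  y <- genotype_table(c("i1", "i2"), c("A", "B"),
                      matrix(c(1L, NA)), matrix(c(2L, NA)), "L")
  afy <- allele_freqs(y)
  expect_false(afy$defined["B", "L"])
  expect_true(afy$defined["A", "L"])
})

test_that("monomorphic frequency vector is a single 1", {
  x <- genotype_table(c("i1", "i2"), c("P", "P"),
                      matrix(c(3L, 3L)), matrix(c(3L, 3L)), "L")
  expect_equal(unname(allele_freqs(x)$freq$L[1, ]), 1)
})

test_that("filter_loci removes monomorphic and high-missing loci with reasons", {
  n <- 20
  a_mono <- matrix(7L, n, 1)
  a_poly <- matrix(sample(1:3, n, TRUE), n, 1)
  a_miss <- matrix(sample(1:3, n, TRUE), n, 1)
  a_miss[1:3, 1] <- NA  # 3/20 = 0.15 > 0.12
  a1 <- cbind(a_mono, a_poly, a_miss)
  tab <- genotype_table(paste0("i", 1:n), rep("P", n), a1, a1,
                        c("mono", "poly", "gappy"))
  out <- filter_loci(tab)
  expect_setequal(out$report$locus, c("mono", "gappy"))
  expect_match(out$report$reason[out$report$locus == "mono"], "monomorphic")
  expect_identical(out$table$loci, "poly")
  # idempotence
  again <- filter_loci(out$table)
  expect_equal(nrow(again$report), 0L)
  expect_error(filter_loci(tab[, "mono"]), "empty panel")
})

test_that("the study-like raw panel loses 5 of its 16 loci to the filter", {
  st <- simulate_study(seed = 101)
  out <- filter_loci(st$table)
  expect_equal(nrow(out$report), 5L)
  expect_equal(n_loc(out$table), 11L)
  expect_equal(sum(out$report$reason == "monomorphic"), 1L)
})

test_that("subsetting and binding preserve structure", {
  set.seed(5)
  tab <- random_small_table(n_pops = 2, n_per = 4, n_loci = 3)
  sub <- tab[tab$pop == "P1", c(1, 3)]
  expect_equal(n_ind(sub), 4L)
  expect_identical(sub$loci, tab$loci[c(1, 3)])
  both <- bind_tables(tab[tab$pop == "P1", ], tab[tab$pop == "P2", ])
  expect_equal(n_ind(both), n_ind(tab))
})
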