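#' Diploid codominant genotype tables
#'
#' A `geno_tab` holds diploid, codominant genotype calls (microsatellite
#' fragment sizes coded as integers) for a set of individuals grouped into
#' populations, over a shared locus panel. Missing genotypes are coded `NA`
#' on both gene copies; half-calls (one allele observed) are normalised to
#' missing, following the GENEPOP convention.
#'
#' @param id character vector of individual identifiers.
#' @param pop character vector of population labels, same length as `id`.
#' @param a1,a2 integer matrices (individuals x loci) of allele labels
#'   (fragment sizes); `NA` marks a missing gene copy.
#' @param loci character vector of locus names (columns of `a1`/`a2`).
#' @param alleles optional named list giving, per locus, the full allele
#'   registry (superset of observed alleles). Defaults to the observed
#'   alleles, sorted ascending.
#'
#' @return An object of class `geno_tab` with fields `id`, `pop`, `loci`,
#'   `alleles`, `a1`, `a2`.
#' @export
genotype_table <- function(id, pop, a1, a2, loci, alleles = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  id <- as.character(id); pop <- as.character(pop); loci <- as.character(loci)
  n <- length(id)
  if (length(pop) != n) stop("id and pop lengths differ")
  if (nrow(a1) != n || nrow(a2) != n) stop("allele matrices must have one row per individual")
  if (ncol(a1) != length(loci) || ncol(a2) != length(loci))
    stop("allele matrices must have one column per locus")
  if (anyDuplicated(loci)) stop("duplicate locus names: ",
                                paste(unique(loci[duplicated(loci)]), collapse = ", "))
  # zero-row tables are legal (e.g. an empty mixture sample); writers
  # and estimators reject them at their own boundaries
  if (any(!nzchar(pop))) stop("empty population label")
  # half-calls -> missing
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_integer_; a2[half] <- NA_integer_
  # unordered pair: store smaller allele first (canonical form)
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  dimnames(a1) <- dimnames(a2) <- list(id, loci)
  obs <- lapply(seq_along(loci), function(j) sort(unique(c(a1[, j], a2[, j]))))
  names(obs) <- loci
  if (is.null(alleles)) {
    alleles <- obs
  } else {
    alleles <- lapply(alleles, function(x) sort(unique(as.integer(x))))
    if (!setequal(names(alleles), loci)) stop("allele registry loci do not match panel")
    alleles <- alleles[loci]
    for (j in seq_along(loci)) {
      if (!all(obs[[j]] %in% alleles[[j]]))
        stop("observed allele outside registry at locus ", loci[j])
    }
  }
  structure(list(id = id, pop = pop, loci = loci, alleles = alleles,
                 a1 = a1, a2 = a2),
            class = "geno_tab")
}

#' @export
print.geno_tab <- function(x, ...) {
  cat("geno_tab:", n_ind(x), "individuals,", n_loc(x), "loci,",
      length(pop_names(x)), "populations\n")
  tb <- table(factor(x$pop, levels = pop_names(x)))
  cat("  populations:", paste(sprintf("%s (n=%d)", names(tb), tb), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$a1))
  cat(sprintf("  missing calls: %d / %d (%.1f%%)\n", nmiss, length(x$a1),
              100 * nmiss / length(x$a1)))
  invisible(x)
}

#' @rdname genotype_table
#' @param x a `geno_tab`.
#' @export
n_ind <- function(x) length(x$id)

#' @rdname genotype_table
#' @export
n_loc <- function(x) length(x$loci)

#' @rdname genotype_table
#' @export
pop_names <- function(x) unique(x$pop)

#' Subset a genotype table by individuals and/or loci
#'
#' @param x a `geno_tab`.
#' @param i individual index (logical, integer or id names).
#' @param j locus index (logical, integer or locus names).
#' @param ... unused.
#' @export
`[.geno_tab` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$id)
  if (missing(j)) j <- seq_along(x$loci)
  if (is.character(i)) i <- match(i, x$id)
  if (is.character(j)) j <- match(j, x$loci)
  loci <- x$loci[j]
  genotype_table(x$id[i], x$pop[i],
                 x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                 loci, alleles = x$alleles[loci])
}

#' Stack genotype tables sharing a locus panel
#'
#' @param ... `geno_tab` objects with identical locus panels.
#' @return a combined `geno_tab`; allele registries are unioned per locus.
#' @export
bind_tables <- function(...) {
  xs <- list(...)
  loci <- xs[[1]]$loci
  for (x in xs) if (!identical(x$loci, loci)) stop("locus panels differ")
  alleles <- lapply(loci, function(l)
    sort(unique(unlist(lapply(xs, function(x) x$alleles[[l]])))))
  names(alleles) <- loci
  genotype_table(unlist(lapply(xs, `[[`, "id")),
                 unlist(lapply(xs, `[[`, "pop")),
                 do.call(rbind, lapply(xs, `[[`, "a1")),
                 do.call(rbind, lapply(xs, `[[`, "a2")),
                 loci, alleles = alleles)
}

#' Per-population, per-locus allele counts
#'
#' @param x a `geno_tab`.
#' @param locus locus name or index.
#' @return matrix populations x alleles of gene-copy counts (missing calls
#'   contribute nothing).
#' @export
allele_counts <- function(x, locus) {
  if (is.character(locus)) locus <- match(locus, x$loci)
  al <- x$alleles[[locus]]
  pops <- pop_names(x)
  cnt <- matrix(0L, length(pops), length(al), dimnames = list(pops, al))
  pf <- factor(x$pop, levels = pops)
  for (a in list(x$a1[, locus], x$a2[, locus])) {
    t <- table(pf[!is.na(a)], factor(a[!is.na(a)], levels = al))
    cnt <- cnt + unclass(t)
  }
  cnt
}

#' Per-population, per-locus allele frequencies
#'
#' Frequencies are allele counts over gene copies, with missing calls
#' excluded. A (population, locus) cell in which every call is missing is
#' flagged undefined (`defined = FALSE`) rather than propagating `NaN`.
#'
#' @param x a `geno_tab`.
#' @return An object of class `allele_freqs`: list with `pops`, `loci`,
#'   `freq` (per locus, a populations x alleles frequency matrix), `n`
#'   (populations x loci gene-copy counts) and `defined` (logical matrix).
#' @export
allele_freqs <- function(x) {
  pops <- pop_names(x); loci <- x$loci
  n <- matrix(0L, length(pops), length(loci), dimnames = list(pops, loci))
  defined <- n > 0
  freq <- vector("list", length(loci)); names(freq) <- loci
  for (j in seq_along(loci)) {
    cnt <- allele_counts(x, j)
    tot <- rowSums(cnt)
    n[, j] <- tot
    defined[, j] <- tot > 0L
    f <- cnt / ifelse(tot > 0L, tot, NA_integer_)
    freq[[j]] <- f
  }
  structure(list(pops = pops, loci = loci, freq = freq, n = n, defined = defined),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("allele_freqs:", length(x$pops), "populations x", length(x$loci), "loci\n")
  invisible(x)
}

#' Extract the frequency vectors of one population
#'
#' @param af an `allele_freqs` object.
#' @param pop population label.
#' @return an `allele_freqs` restricted to one population (used as a gamete
#'   pool by the hybrid simulator).
#' @export
pool_freqs <- function(af, pop) {
  k <- match(pop, af$pops)
  if (is.na(k)) stop("unknown population: ", pop)
  freq <- lapply(af$freq, function(f) f[k, , drop = FALSE])
  structure(list(pops = pop, loci = af$loci, freq = freq,
                 n = af$n[k, , drop = FALSE],
                 defined = af$defined[k, , drop = FALSE]),
            class = "allele_freqs")
}

#' Genotype counts for one population x locus
#'
#' @param x a `geno_tab`.
#' @param pop population label.
#' @param locus locus name or index.
#' @return a named integer vector of genotype counts; names are "a/b" with
#'   a <= b. Missing calls are dropped.
#' @keywords internal
geno_counts <- function(x, pop, locus) {
  if (is.character(locus)) locus <- match(locus, x$loci)
  i <- x$pop == pop
  a1 <- x$a1[i, locus]; a2 <- x$a2[i, locus]
  ok <- !is.na(a1)
  if (!any(ok)) return(integer(0))
  table(paste0(a1[ok], "/", a2[ok]))
}

#' Count the alleles carried at one (population, locus)
#' @keywords internal
n_alleles_obs <- function(x, pop, locus) {
  if (is.character(locus)) locus <- match(locus, x$loci)
  i <- x$pop == pop
  length(unique(stats::na.omit(c(x$a1[i, locus], x$a2[i, locus]))))
}

#' Remove monomorphic and high-missing loci
#'
#' Drops loci that are monomorphic across all populations pooled, and loci
#' whose missing-call fraction exceeds `max_missing` in any single
#' population.
#'
#' @param x a `geno_tab`.
#' @param max_missing maximum tolerated per-population missing fraction
#'   (default 0.12, i.e. loci with more than 12% missing data in at least
#'   one population are dropped).
#' @return list with `table` (the filtered `geno_tab`) and `report`
#'   (data.frame of removed loci and reasons).
#' @export
filter_loci <- function(x, max_missing = 0.12) {
  pops <- pop_names(x)
  reasons <- character(0); dropped <- character(0)
  keep <- rep(TRUE, n_loc(x))
  for (j in seq_len(n_loc(x))) {
    nall <- length(unique(stats::na.omit(c(x$a1[, j], x$a2[, j]))))
    missfr <- vapply(pops, function(p) mean(is.na(x$a1[x$pop == p, j])), 0)
    if (nall <= 1L) {
      keep[j] <- FALSE
      dropped <- c(dropped, x$loci[j]); reasons <- c(reasons, "monomorphic")
    } else if (any(missfr > max_missing)) {
      keep[j] <- FALSE
      dropped <- c(dropped, x$loci[j])
      worst <- which.max(missfr)
      reasons <- c(reasons, sprintf("missing %.1f%% in %s",
                                    100 * max(missfr), pops[worst]))
    }
  }
  if (!any(keep)) stop("all loci removed by filtering: empty panel")
  list(table = x[, which(keep)],
       report = data.frame(locus = dropped, reason = reasons,
                           stringsAsFactors = FALSE))
}

#' Read / write the tabular CSV genotype dialect
#'
#' Wide CSV with columns `id`, `population`, then `<locus>:allele1` and
#' `<locus>:allele2` per locus; empty cells or 0 mark missing gene copies.
#'
#' @param path file path.
#' @return a `geno_tab`.
#' @export
read_geno_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("id", "population") %in% names(d))) stop("CSV lacks id/population columns")
  gc <- setdiff(names(d), c("id", "population"))
  loci <- unique(sub(":allele[12]$", "", gc))
  a1 <- sapply(paste0(loci, ":allele1"), function(cn) as.integer(d[[cn]]))
  a2 <- sapply(paste0(loci, ":allele2"), function(cn) as.integer(d[[cn]]))
  a1 <- matrix(a1, nrow(d)); a2 <- matrix(a2, nrow(d))
  a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
  genotype_table(d$id, d$population, a1, a2, loci)
}

#' @rdname read_geno_csv
#' @param x a `geno_tab`.
#' @export
write_geno_csv <- function(x, path) {
  d <- data.frame(id = x$id, population = x$pop, check.names = FALSE,
                  stringsAsFactors = FALSE)
  for (j in seq_len(n_loc(x))) {
    d[[paste0(x$loci[j], ":allele1")]] <- ifelse(is.na(x$a1[, j]), 0L, x$a1[, j])
    d[[paste0(x$loci[j], ":allele2")]] <- ifelse(is.na(x$a2[, j]), 0L, x$a2[, j])
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
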