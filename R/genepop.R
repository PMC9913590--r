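#' Read a GENEPOP genotype file
#'
#' Parses the classical GENEPOP layout: a free-text title line, one locus
#' name per line (or a single comma-separated line), then `POP`-delimited
#' sample blocks of `id , gggggg gggggg ...` lines with fixed-width
#' (2- or 3-digit) allele codes. `00`/`000` halves mark missing gene
#' copies; a genotype with either half missing is normalised to missing.
#'
#' Population labels: files written by [write_genepop()] carry the labels
#' in the title line (`pops: A,B,...`) and round-trip exactly. Otherwise
#' the label of each block is the id of its last individual (the GENEPOP
#' naming convention), unless `pop_labels` overrides.
#'
#' @param path file path.
#' @param dialect `"3-digit"` (default) or `"2-digit"` allele coding.
#' @param pop_labels optional character vector overriding population
#'   labels, in file order.
#' @return a `geno_tab`.
#' @export
read_genepop <- function(path, dialect = c("3-digit", "2-digit"),
                         pop_labels = NULL) {
  dialect <- match.arg(dialect)
  w <- if (dialect == "3-digit") 3L else 2L
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) == 1L]
  if (length(lines) < 3L) stop("not a GENEPOP file: too few lines")
  title <- lines[1]
  rest <- lines[-1]
  is_pop <- toupper(trimws(rest)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP separator found")
  loc_lines <- trimws(rest[seq_len(first_pop - 1L)])
  loci <- trimws(unlist(strsplit(loc_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("duplicate locus names: ",
                                paste(unique(loci[duplicated(loci)]), collapse = ", "))
  body <- rest[-(seq_len(first_pop - 1L))]
  blk <- cumsum(toupper(trimws(body)) == "POP")
  ind_lines <- body[toupper(trimws(body)) != "POP"]
  ind_blk <- blk[toupper(trimws(body)) != "POP"]
  if (length(ind_lines) == 0L) stop("no individuals found")
  n <- length(ind_lines)
  id <- character(n)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (i in seq_len(n)) {
    ln <- ind_lines[i]
    cpos <- regexpr(",", ln, fixed = TRUE)
    if (cpos < 0) stop("malformed individual line (no comma): ", ln)
    id[i] <- trimws(substr(ln, 1L, cpos - 1L))
    toks <- strsplit(trimws(substr(ln, cpos + 1L, nchar(ln))), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != length(loci))
      stop(sprintf("line %d: %d genotypes for %d loci", i, length(toks), length(loci)))
    bad <- nchar(toks) != 2L * w
    if (any(bad))
      stop(sprintf("parse error at individual '%s': genotype '%s' is not %d-digit diploid",
                   id[i], toks[which(bad)[1]], w))
    x1 <- as.integer(substr(toks, 1L, w))
    x2 <- as.integer(substr(toks, w + 1L, 2L * w))
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    a1[i, ] <- x1; a2[i, ] <- x2
  }
  # population labels
  labs <- pop_labels
  if (is.null(labs)) {
    m <- regmatches(title, regexec("pops:\\s*([^;]+)$", title))[[1]]
    if (length(m) == 2L) labs <- trimws(strsplit(m[2], ",")[[1]])
  }
  if (is.null(labs)) labs <- vapply(split(id, ind_blk), function(v) v[length(v)], "")
  nblk <- length(unique(ind_blk))
  if (length(labs) != nblk)
    stop(sprintf("%d population labels for %d POP blocks", length(labs), nblk))
  pop <- labs[ind_blk]
  genotype_table(id, pop, a1, a2, loci)
}

#' Write a GENEPOP genotype file
#'
#' Emits one locus name per line, `POP` separators in population order,
#' and `id ,  gggggg ...` individual lines. Missing genotypes are written
#' as all zeros. Population labels are stored on the title line so that
#' [read_genepop()] round-trips the table exactly.
#'
#' @param x a `geno_tab`.
#' @param path output file path.
#' @param dialect `"3-digit"` (default) or `"2-digit"` allele coding.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, dialect = c("3-digit", "2-digit")) {
  dialect <- match.arg(dialect)
  if (n_ind(x) == 0L) stop("cannot write an empty genotype table")
  w <- if (dialect == "3-digit") 3L else 2L
  maxlab <- max(0L, unlist(x$alleles))
  if (maxlab >= 10L^w)
    stop("allele label ", maxlab, " not representable with ", w, " digits")
  pops <- pop_names(x)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("pikemix genepop export; pops: %s",
                     paste(pops, collapse = ",")), con)
  writeLines(x$loci, con)
  fmt <- function(a) ifelse(is.na(a), strrep("0", w), formatC(a, width = w, flag = "0"))
  for (p in pops) {
    writeLines("POP", con)
    for (i in which(x$pop == p)) {
      g <- paste0(fmt(x$a1[i, ]), fmt(x$a2[i, ]))
      writeLines(paste(x$id[i], ", ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}
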