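#' Discriminant analysis of principal components
#'
#' Genotypes are coded as centred (and scaled) allele dosage vectors,
#' reduced by PCA, and linear discriminant functions are computed on the
#' retained principal components. The number of retained PCs is chosen
#' by stratified cross-validation (highest mean held-out reassignment
#' success over a grid), guarding against overfitting. The discriminant
#' eigenproblem is solved directly on the between- and pooled
#' within-group covariance of the PC scores (with a small ridge so that
#' perfectly separable groups do not break the decomposition);
#' discriminant axes are scaled to unit within-group variance so that
#' nearest-centroid assignment in discriminant space is the LDA rule
#' with equal priors.
#'
#' @param x a `geno_tab`.
#' @param groups group labels per individual (default: populations).
#' @param n_pca number of retained PCs; `NULL` (default) selects by
#'   cross-validation.
#' @param pca_grid candidate PC counts for cross-validation.
#' @param folds cross-validation folds (stratified; default 5).
#' @param seed integer RNG seed for fold assignment.
#' @return a `dapc_model` list: `n_pca`, `ind_coord` (discriminant
#'   coordinates), `eig` (discriminant eigenvalues), `var_explained`
#'   (per-DF share), `assign` (self-assignment), `groups`, `cv`
#'   (data.frame of the grid), `centroids`.
#' @export
dapc_fit <- function(x, groups = x$pop, n_pca = NULL, pca_grid = NULL,
                     folds = 5L, seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 3L)) stop("every group needs >= 3 individuals")
  ac <- allele_count_matrix(x)
  sds <- apply(ac, 2, stats::sd)
  ac <- ac[, sds > 0, drop = FALSE]
  ac <- scale(ac, center = TRUE, scale = TRUE)
  pc <- stats::prcomp(ac, center = FALSE, scale. = FALSE)
  npc_max <- min(nrow(ac) - nlevels(groups) - 1L, sum(pc$sdev > 1e-8))
  scores <- pc$x
  cv <- NULL
  if (is.null(n_pca)) {
    if (is.null(pca_grid))
      pca_grid <- unique(pmin(pmax(round(seq(2, npc_max, length.out = 8)), 2), npc_max))
    set.seed(seed)
    fold <- integer(nrow(ac))
    for (g in levels(groups)) {
      i <- which(groups == g)
      fold[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    acc <- vapply(pca_grid, function(np) {
      hits <- 0L; tot <- 0L
      for (f in seq_len(folds)) {
        tr <- fold != f; te <- !tr
        if (!all(table(groups[tr]) >= 2L)) next
        mdl <- lda_scores(scores[tr, seq_len(np), drop = FALSE], groups[tr])
        pr <- lda_predict(mdl, scores[te, seq_len(np), drop = FALSE])
        hits <- hits + sum(pr == groups[te]); tot <- tot + sum(te)
      }
      if (tot == 0L) NA_real_ else hits / tot
    }, 0)
    cv <- data.frame(n_pca = pca_grid, success = acc)
    n_pca <- pca_grid[which.max(acc)]
  }
  n_pca <- min(n_pca, npc_max)
  mdl <- lda_scores(scores[, seq_len(n_pca), drop = FALSE], groups)
  coord <- scores[, seq_len(n_pca), drop = FALSE] %*% mdl$vectors
  rownames(coord) <- x$id
  structure(list(n_pca = n_pca, ind_coord = coord, eig = mdl$eig,
                 var_explained = mdl$eig / sum(mdl$eig),
                 assign = lda_predict(mdl, scores[, seq_len(n_pca), drop = FALSE]),
                 groups = groups, cv = cv, centroids = mdl$centroids,
                 pca = list(rotation = pc$rotation, sdev = pc$sdev)),
            class = "dapc_model")
}

# Discriminant eigenanalysis on score matrices: between vs pooled within
# covariance, ridge-stabilised; axes scaled to unit within-group variance.
lda_scores <- function(s, groups, ridge = 1e-8) {
  groups <- droplevels(factor(groups))
  g <- nlevels(groups)
  mu <- colMeans(s)
  cent <- rowsum(s, groups) / as.vector(table(groups))
  W <- matrix(0, ncol(s), ncol(s))
  for (lev in levels(groups)) {
    d <- sweep(s[groups == lev, , drop = FALSE], 2, cent[lev, ])
    W <- W + crossprod(d)
  }
  W <- W / max(nrow(s) - g, 1)
  ng <- as.vector(table(groups))
  B <- crossprod(sweep(cent, 2, mu) * sqrt(ng)) / max(g - 1, 1)
  W <- W + diag(ridge * (mean(diag(W)) + 1), ncol(W))
  ev <- eigen(solve(W, B))
  ndf <- min(g - 1, ncol(s))
  vec <- Re(ev$vectors[, seq_len(ndf), drop = FALSE])
  eig <- pmax(Re(ev$values[seq_len(ndf)]), 0)
  # unit within-group variance along each axis
  for (k in seq_len(ndf)) {
    wv <- sqrt(drop(t(vec[, k]) %*% W %*% vec[, k]))
    if (wv > 0) vec[, k] <- vec[, k] / wv
  }
  list(vectors = vec, eig = eig,
       centroids = cent %*% vec, levels = levels(groups))
}

lda_predict <- function(mdl, s) {
  co <- s %*% mdl$vectors
  d <- as.matrix(stats::dist(rbind(co, mdl$centroids)))
  n <- nrow(co)
  dd <- d[seq_len(n), n + seq_along(mdl$levels), drop = FALSE]
  factor(mdl$levels[max.col(-dd)], levels = mdl$levels)
}

#' @export
print.dapc_model <- function(x, ...) {
  cat("DAPC:", x$n_pca, "retained PCs,", length(x$eig),
      "discriminant functions\n")
  cat("  variance explained by DFs:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Infer the number of genetic clusters by k-means and BIC
#'
#' Runs k-means on PCA scores of the allele dosage matrix for each
#' candidate number of clusters and scores each solution with
#' `BIC(k) = n log(WSS_k / n) + k log(n)`. The `diffNgroup` rule splits
#' the successive BIC decreases into a sharp and a shallow group
#' (2-means on the decreases) and keeps the solution after the last
#' sharp decrease; when the BIC curve is minimised at `k = 1` (no
#' structure), `k = 1` is returned.
#'
#' @param x a `geno_tab`.
#' @param k_range candidate cluster counts (default 1:8, truncated to
#'   `n - 1`).
#' @param n_pca PCs retained before clustering (default: enough to
#'   explain 95% of variance).
#' @param n_init k-means restarts per k.
#' @param seed integer RNG seed.
#' @return list with `k`, `labels`, `bic` (data.frame k/BIC), `scores`.
#' @export
find_clusters <- function(x, k_range = 1:8, n_pca = NULL, n_init = 10L,
                          seed = 1L) {
  ac <- allele_count_matrix(x)
  sds <- apply(ac, 2, stats::sd)
  ac <- scale(ac[, sds > 0, drop = FALSE])
  pc <- stats::prcomp(ac)
  if (is.null(n_pca)) {
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_pca <- max(which(cum >= 0.95)[1], 2L)
    if (is.na(n_pca)) n_pca <- ncol(pc$x)
  }
  s <- pc$x[, seq_len(min(n_pca, ncol(pc$x))), drop = FALSE]
  n <- nrow(s)
  k_range <- k_range[k_range >= 1 & k_range <= n - 1]
  set.seed(seed)
  fits <- lapply(k_range, function(k)
    stats::kmeans(s, centers = k, nstart = n_init, iter.max = 50))
  wss <- vapply(fits, function(f) f$tot.withinss, 0)
  bic <- n * log(wss / n) + k_range * log(n)
  k_sel <- k_range[1]
  if (which.min(bic) == 1L ||
      bic[1] - min(bic) <= 2 * log(n)) {
    # no solution improves on a single cluster by more than twice the
    # BIC penalty unit: no detectable structure
    k_sel <- k_range[1]
  } else if (length(bic) > 2L) {
    d <- -diff(bic)  # positive = decrease
    km <- stats::kmeans(matrix(d), centers = 2, nstart = 5)
    sharp <- which(km$cluster == which.max(km$centers))
    sharp <- sharp[d[sharp] > 0]
    k_sel <- if (length(sharp)) k_range[max(sharp) + 1L] else k_range[which.min(bic)]
  } else {
    k_sel <- k_range[which.min(bic)]
  }
  list(k = k_sel, labels = fits[[match(k_sel, k_range)]]$cluster,
       bic = data.frame(k = k_range, bic = bic), scores = s, n_pca = n_pca)
}
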