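#!/usr/bin/env Rscript
# Within-population diversity (N_A, rarefied A_R, H_E, H_O, F_IS with
# bootstrap CI) and between-population differentiation (global and
# pairwise Weir-Cockerham theta and Jost's D with bootstrap CIs, exact
# G tests with Fisher combination), plus model-free structure analyses
# (DAPC with cross-validated PC retention, k-means/BIC cluster count).

library(pikemix)
dir.create("results", showWarnings = FALSE)
seed <- 2023L

tab <- read_genepop("results/panel_filtered.gen")

ss <- summary_stats(tab, boot = 10000L, seed = seed + 10L)
cat("Within-population summary (rarefaction g =", attr(ss, "g"), "gene copies):\n")
print(ss, digits = 3)
write.table(format(ss, digits = 4), "results/summary_stats.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

glob <- wc_theta(tab, boot = 10000L, seed = seed + 11L)
cat(sprintf("\nGlobal theta = %.3f (CI95 %.3f-%.3f)\n",
            glob$theta, glob$ci[1], glob$ci[2]))
gt <- exact_g_diff(tab, B = 10000L, seed = seed + 12L)
cat(sprintf("Exact G global: chi2 = %.3f, df = %d, p = %.3g\n",
            gt$chi2, gt$df, gt$p))

pw <- pairwise_diff(tab, boot = 2000L, B = 2000L, seed = seed + 13L)
cat("\nPairwise theta (below diagonal):\n")
print(round(pw$theta, 3))
write.table(round(pw$theta, 4), "results/pairwise_theta.tsv", sep = "\t", quote = FALSE)
write.table(round(pw$d_est, 4), "results/pairwise_dest.tsv", sep = "\t", quote = FALSE)
write.table(signif(pw$g_p_adj, 3), "results/pairwise_g_padj.tsv", sep = "\t", quote = FALSE)

dm <- dapc_fit(tab, seed = seed + 14L)
cat(sprintf("\nDAPC: %d PCs retained by cross-validation; self-assignment %.1f%%\n",
            dm$n_pca, 100 * mean(as.character(dm$assign) == tab$pop)))
cat("  variance explained by DFs:",
    paste(sprintf("%.1f%%", 100 * dm$var_explained), collapse = ", "), "\n")
write.table(data.frame(id = rownames(dm$ind_coord), pop = tab$pop,
                       round(dm$ind_coord, 4)),
            "results/dapc_coords.tsv", sep = "\t", row.names = FALSE, quote = FALSE)

fc <- find_clusters(tab, seed = seed + 15L)
cat(sprintf("\nInferred number of clusters (diffNgroup/BIC): k = %d\n", fc$k))
print(table(cluster = fc$labels, population = tab$pop))
write.table(fc$bic, "results/cluster_bic.tsv", sep = "\t", row.names = FALSE, quote = FALSE)
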