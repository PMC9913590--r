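#!/usr/bin/env Rscript
# Hybrid scenario construction. S1: multinomial gamete sampling from
# the two reference populations (TRA as southern, DRA as northern
# parental pool) builds 100 individuals per genotypic class; 50 are
# drawn as an introgressed mixture and analysed with the untouched
# references. S2: the hierarchical island simulator provides four ideal
# microsatellite baselines; A2 x B1 parent the hybrids, while A1 and B2
# enter the analysis as reference-but-not-parental populations.

library(pikemix)
dir.create("results", showWarnings = FALSE)
seed <- 2023L

tab <- read_genepop("results/panel_filtered.gen")

s1 <- build_s1(tab, "TRA", "DRA", per_class = 100L, mixture = 50L,
               seed = seed + 50L)
cat("S1 mixture composition:\n")
print(table(s1$truth))
write_genepop(s1$analysis, "results/s1_analysis.gen")
write.table(data.frame(id = s1$analysis$id[s1$analysis$pop == "MIX"],
                       truth = s1$truth),
            "results/s1_truth.tsv", sep = "\t", row.names = FALSE, quote = FALSE)

icfg <- island_default_config(loci = 12L, seed = seed + 60L)
cat(sprintf("\nS2 island config: N = %d, m_within = %.4f, m_between = %.4f, mu = %.1e, %d generations\n",
            icfg$N, icfg$m_within, icfg$m_between, icfg$mu, icfg$generations))
s2 <- build_s2(icfg, per_class = 100L, mixture = 50L, seed = seed + 61L)
base <- s2$baselines
cat(sprintf("S2 baselines: mean He = %.3f, theta(A2,B1) = %.3f, theta(A1,A2) = %.3f\n",
            mean(summary_stats(base, boot = 0)$h_e),
            wc_theta(base, c("A2", "B1"), boot = 0)$theta,
            wc_theta(base, c("A1", "A2"), boot = 0)$theta))
cat("S2 mixture composition:\n")
print(table(s2$truth))
write_genepop(s2$analysis, "results/s2_analysis.gen")
write.table(data.frame(id = s2$analysis$id[s2$analysis$pop == "A2B1"],
                       truth = s2$truth),
            "results/s2_truth.tsv", sep = "\t", row.names = FALSE, quote = FALSE)
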