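#!/usr/bin/env Rscript
# Build the study-like synthetic genotype panel: four pike populations
# (three southern-pike samples FLU/TRA/CAR, one northern-pike sample
# DRA) typed at 16 microsatellite loci, with the raw panel's defects
# (one monomorphic locus, four high-missing loci, allelic dropout).
# Writes the raw panel as GENEPOP and CSV under results/.

library(pikemix)

dir.create("results", showWarnings = FALSE)
seed <- 2023L

st <- simulate_study(seed = seed)
cat("Simulated raw panel:\n")
print(st$table)
cat("\nTrue per-locus dropout rates (generator):\n")
print(round(st$dropout, 3))

write_genepop(st$table, "results/panel_raw.gen")
write_geno_csv(st$table, "results/panel_raw.csv")
write.table(data.frame(locus = names(st$roles), role = st$roles,
                       dropout = round(st$dropout, 4)),
            "results/panel_truth.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("\nWrote results/panel_raw.gen, results/panel_raw.csv, results/panel_truth.tsv\n")
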