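#!/usr/bin/env Rscript
# Differential-expression screen (|log2FC| > 1, p < 0.01 on Welch t), top-2
# up / top-2 down marker panel, and the 10-per-group K-means representative
# cases used for validation-style runs.

library(dsdwta)
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
outdir <- "results/analysis"
cohort <- read_cohort(file.path(outdir, "cohort"))

de <- compute_de(cohort$expr, cohort$clinical)
utils::write.table(de, file.path(outdir, "de_table.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
degs <- filter_degs(de, logfc_threshold = 1, p_threshold = 0.01)
cat(sprintf("DEG screen kept %d of %d genes\n", nrow(degs), nrow(de)))

panel <- select_top_markers(degs, n_up = 2, n_down = 2)
print(panel)
utils::write.table(
  data.frame(channel = rep(c("positive", "negative"), each = 2),
             rbind(panel$positive, panel$negative)),
  file.path(outdir, "panel.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

reps <- representative_cases(cohort$expr, cohort$clinical, k = 10,
                             seed = seed)
writeLines(unlist(reps), file.path(outdir, "representative_cases.txt"))
cat(sprintf("representative cases: %d tumor, %d normal\n",
            length(reps$tumor), length(reps$normal)))
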