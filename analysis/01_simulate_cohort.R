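#!/usr/bin/env Rscript
# Generate the study cohort: 443 tumor vs 46 normal samples, 200 miRNAs, four
# planted markers (log2FC +2.5/+1.8 up, -2.5/-1.8 down) over log2-scale noise
# SD 0.5, plus clinical lymph-node counts and the binary tissue-collection
# indicator. Writes the expression and clinical TSVs used by the later steps.

library(dsdwta)
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
outdir <- "results/analysis"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

spec <- cohort_spec(
  n_genes = 200, n_case = 443, n_control = 46,
  planted_markers = data.frame(gene = 1:4,
                               direction = c("up", "up", "down", "down"),
                               log2fc = c(2.5, 1.8, 2.5, 1.8)),
  sigma = 0.5, seed = seed)
cohort <- generate_cohort(spec)
paths <- write_cohort(cohort, file.path(outdir, "cohort"))

y <- log2(cohort$expr + 1)
case <- cohort$clinical$group == "tumor"
cat(sprintf("cohort: %d genes x %d samples (%d tumor / %d normal)\n",
            nrow(cohort$expr), ncol(cohort$expr), sum(case), sum(!case)))
cat("planted marker log2FC estimates (target +2.5 +1.8 -2.5 -1.8):\n")
print(round(rowMeans(y[1:4, case]) - rowMeans(y[1:4, !case]), 3))
cat("written:", paths, sep = "\n  ")
cat("\n")
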