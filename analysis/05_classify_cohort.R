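#!/usr/bin/env Rscript
# Classify the full cohort: per sample, compile the four-input circuit with
# FPKM-as-nM inputs and |log2FC| x k rates, integrate, read the endpoint
# FAM/ROX signals and call tumor / normal / indeterminate. Writes the
# per-sample results CSV and the confusion summary JSON.

library(dsdwta)
outdir <- "results/analysis"
cohort <- read_cohort(file.path(outdir, "cohort"))
panel_tab <- utils::read.delim(file.path(outdir, "panel.tsv"))
panel <- structure(list(
  positive = panel_tab[panel_tab$channel == "positive", c("gene_id", "log2FC")],
  negative = panel_tab[panel_tab$channel == "negative", c("gene_id", "log2FC")]),
  class = "biomarker_panel")

cls <- classify_cohort(cohort$expr, cohort$clinical, panel)
utils::write.csv(cls$results, file.path(outdir, "results.csv"),
                 row.names = FALSE)
s <- cls$summary
jsonlite::write_json(list(
  counts = as.data.frame.matrix(unclass(s$counts)),
  per_class_accuracy = as.list(s$per_class_accuracy),
  overall_accuracy = s$overall_accuracy,
  binary_accuracy = s$binary_accuracy, n = s$n),
  file.path(outdir, "confusion.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat("confusion counts (true class x call):\n")
print(s$counts)
cat(sprintf("overall accuracy %.1f%% | binary accuracy %.1f%% | n = %d\n",
            100 * s$overall_accuracy, 100 * s$binary_accuracy, s$n))
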