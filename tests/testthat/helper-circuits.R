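# four-input panel + sample used across circuit/kinetics/classification tests
make_panel4 <- function(lfc = c(2.5, 1.8, -2.5, -1.8)) {
  structure(list(
    positive = data.frame(gene_id = c("gp1", "gp2"), log2FC = lfc[1:2],
                          stringsAsFactors = FALSE),
    negative = data.frame(gene_id = c("gn1", "gn2"), log2FC = lfc[3:4],
                          stringsAsFactors = FALSE)),
    class = "biomarker_panel")
}

make_sample <- function(pos = c(15, 15), neg = c(20, 14))
  c(gp1 = pos[1], gp2 = pos[2], gn1 = neg[1], gn2 = neg[2])

# expression matrix from explicit log2(FPKM+1) values (genes x samples)
fpkm_from_log2 <- function(y) 2^y - 1

# four-marker cohort spec matching the planted-marker study conditions
marker_cohort_spec <- function(n_case, n_control, n_genes = 200, sigma = 0.5,
                               seed = 1L,
                               lfc = c(2.5, 1.8, 2.5, 1.8)) {
  cohort_spec(n_genes, n_case, n_control,
              planted_markers = data.frame(
                gene = 1:4,
                direction = c("up", "up", "down", "down"),
                log2fc = lfc),
              sigma = sigma, seed = seed)
}
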