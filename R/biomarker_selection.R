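#' Differential expression on the log2(FPKM+1) scale
#'
#' Per gene: log2FC = mean(case) - mean(control) on log2(FPKM+1), with a
#' two-sided Welch t-test p-value (Welch-Satterthwaite degrees of freedom).
#' With \code{shrink = TRUE} the per-group variances are squeezed toward the
#' across-gene mean variance before the t statistic is formed (a simple
#' moderated-t; \code{prior_df} pseudo-observations of the global variance).
#' A gene constant across all samples gets p = 1 and log2FC 0.
#'
#' @param expr Genes x samples FPKM matrix (non-negative).
#' @param clinical Data frame with \code{sample_id} matching \code{colnames(expr)}
#'   and \code{group} in {"tumor","normal"}.
#' @param shrink Apply variance shrinkage (default FALSE: plain Welch).
#' @param prior_df Prior degrees of freedom for shrinkage.
#' @return Data frame: gene_id, log2FC, p_value, mean_case, mean_control.
#' @export
compute_de <- function(expr, clinical, shrink = FALSE, prior_df = 3) {
  grp <- clinical$group[match(colnames(expr), clinical$sample_id)]
  if (anyNA(grp)) stop_msg("samples missing from clinical table")
  case <- grp == "tumor"; ctrl <- grp == "normal"
  n1 <- sum(case); n2 <- sum(ctrl)
  if (n1 < 2 || n2 < 2)
    stop_msg("need >= 2 samples per group for the variance estimate (got %d/%d)",
             n1, n2)
  y <- log2p1(expr)
  m1 <- rowMeans(y[, case, drop = FALSE])
  m2 <- rowMeans(y[, ctrl, drop = FALSE])
  v1 <- apply(y[, case, drop = FALSE], 1, stats::var)
  v2 <- apply(y[, ctrl, drop = FALSE], 1, stats::var)
  if (shrink) {
    v1 <- (prior_df * mean(v1) + (n1 - 1) * v1) / (prior_df + n1 - 1)
    v2 <- (prior_df * mean(v2) + (n2 - 1) * v2) / (prior_df + n2 - 1)
  }
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  const <- v1 == 0 & v2 == 0
  if (any(const)) {
    exact_tie <- const & (m1 == m2)
    p[const] <- ifelse(m1[const] != m2[const], 0, 1)
    if (any(const & m1 == m2))
      warn_msg("%d gene(s) constant across all samples; p set to 1",
               sum(exact_tie))
  }
  data.frame(gene_id = rownames(expr), log2FC = m1 - m2, p_value = p,
             mean_case = m1, mean_control = m2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter differentially expressed genes
#'
#' Keeps genes with |log2FC| strictly above \code{logfc_threshold} and p
#' strictly below \code{p_threshold} (defaults: the screening rule
#' |logFC| > 1 and p < 0.01). Optional Benjamini-Hochberg adjustment before
#' thresholding.
#'
#' @param de Output of \code{\link{compute_de}}.
#' @param logfc_threshold,p_threshold Positive thresholds.
#' @param adjust Apply BH-FDR to p before filtering (default FALSE: raw p, as
#'   in the screening rule).
#' @return Subset of \code{de}, original order preserved.
#' @export
filter_degs <- function(de, logfc_threshold = 1, p_threshold = 0.01,
                        adjust = FALSE) {
  stopifnot(logfc_threshold > 0, p_threshold > 0)
  p <- if (adjust) stats::p.adjust(de$p_value, "BH") else de$p_value
  de[abs(de$log2FC) > logfc_threshold & p < p_threshold, , drop = FALSE]
}

#' Select the top up- and down-regulated markers
#'
#' Ranks within each direction by |log2FC| descending, breaking ties by
#' smaller p then lexicographic gene id, and keeps the top \code{n_up} /
#' \code{n_down} as the positive (tumor) and negative (health) panel.
#'
#' @param degs Filtered DE table.
#' @param n_up,n_down Panel sizes (default 2 and 2: the four-input circuit).
#' @return A \code{biomarker_panel}: list with data frames \code{positive}
#'   and \code{negative} (gene_id, log2FC), each ordered by |log2FC|.
#' @export
select_top_markers <- function(degs, n_up = 2L, n_down = 2L) {
  rank_dir <- function(d) d[order(-abs(d$log2FC), d$p_value, d$gene_id), ]
  up <- rank_dir(degs[degs$log2FC > 0, , drop = FALSE])
  down <- rank_dir(degs[degs$log2FC < 0, , drop = FALSE])
  if (nrow(up) < n_up)
    stop_msg("need %d up-regulated markers, found %d", n_up, nrow(up))
  if (nrow(down) < n_down)
    stop_msg("need %d down-regulated markers, found %d", n_down, nrow(down))
  structure(list(
    positive = up[seq_len(n_up), c("gene_id", "log2FC"), drop = FALSE],
    negative = down[seq_len(n_down), c("gene_id", "log2FC"), drop = FALSE]),
    class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat("Biomarker panel\n  positive (tumor):",
      paste(sprintf("%s (log2FC %+0.2f)", x$positive$gene_id,
                    x$positive$log2FC), collapse = ", "),
      "\n  negative (health):",
      paste(sprintf("%s (log2FC %+0.2f)", x$negative$gene_id,
                    x$negative$log2FC), collapse = ", "), "\n")
  invisible(x)
}

# k-means++ seeding: first centre uniform, then each next centre drawn with
# probability proportional to squared distance to the nearest chosen centre
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    pick <- if (all(d2 == 0)) sample.int(n, 1L)
            else sample.int(n, 1L, prob = d2)
    centers[j + 1L] <- pick
    d2 <- pmin(d2, rowSums((x - matrix(x[pick, ], n, ncol(x), byrow = TRUE))^2))
  }
  x[centers, , drop = FALSE]
}

#' Representative cases by per-group K-means
#'
#' Within each clinical group, runs K-means (k-means++ seeding, Lloyd
#' iterations) on the per-sample log2(FPKM+1) expression vectors and returns
#' the medoid of each cluster: the actual sample nearest (Euclidean) its
#' cluster centroid. With two groups and the default k = 10 this yields the
#' 20 broadly typical cases used for validation.
#'
#' @param expr Genes x samples FPKM matrix.
#' @param clinical Clinical table with \code{sample_id}, \code{group}.
#' @param k Clusters per group.
#' @param seed Seed for the k-means++ initialisation.
#' @return Named list of sample-id character vectors, one per group.
#' @export
representative_cases <- function(expr, clinical, k = 10L, seed = 1L) {
  grp <- clinical$group[match(colnames(expr), clinical$sample_id)]
  y <- t(log2p1(expr))
  set.seed(as.integer(seed))
  out <- list()
  for (g in unique(grp)) {
    xg <- y[grp == g, , drop = FALSE]
    if (nrow(xg) < k)
      stop_msg("group '%s' has %d samples, fewer than k = %d", g, nrow(xg), k)
    if (nrow(xg) == k) { out[[g]] <- rownames(xg); next }
    init <- kmeanspp_centers(xg, k)
    km <- suppressWarnings(
      stats::kmeans(xg, centers = init, iter.max = 100L, algorithm = "Lloyd"))
    meds <- vapply(seq_len(k), function(j) {
      idx <- which(km$cluster == j)
      d2 <- rowSums((xg[idx, , drop = FALSE] -
                     matrix(km$centers[j, ], length(idx), ncol(xg),
                            byrow = TRUE))^2)
      rownames(xg)[idx[which.min(d2)]]
    }, character(1))
    out[[g]] <- meds
  }
  out
}
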