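#' Weighted co-expression adjacency
#'
#' Soft-thresholded adjacency a_ij = |cor(g_i, g_j)|^beta (unsigned network;
#' the signed variant uses ((1+cor)/2)^beta), with zero diagonal. Pearson
#' correlation is taken between per-gene log2(FPKM+1) profiles. Genes with
#' zero variance get zero correlation to everything, with a warning.
#'
#' @param expr Genes x samples FPKM matrix.
#' @param beta Soft-thresholding power (>= 1).
#' @param signed Use the signed adjacency transform.
#' @param log_transform Apply log2(FPKM+1) first (set FALSE when \code{expr}
#'   is already on a log or arbitrary numeric scale).
#' @return Symmetric genes x genes matrix in [0,1], zero diagonal.
#' @export
adjacency_matrix <- function(expr, beta, signed = FALSE, log_transform = TRUE) {
  stopifnot(beta >= 1, ncol(expr) >= 3)
  y <- if (log_transform) log2p1(expr) else expr
  sds <- apply(y, 1, stats::sd)
  if (any(sds == 0))
    warn_msg("%d zero-variance gene(s); their correlations set to 0",
             sum(sds == 0))
  cc <- suppressWarnings(stats::cor(t(y)))
  cc[is.na(cc)] <- 0
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 0
  a
}

#' Choose the soft-thresholding power by scale-free fit
#'
#' For each candidate power, computes the connectivity k_i = sum_j a_ij, bins
#' log10(k) into \code{nbins} equal-width bins (empty bins dropped), and
#' regresses log10(frequency) on log10(mean k per bin). The fit index is the
#' signed R^2 of that regression (negated when the slope is positive, so only
#' genuinely decreasing degree distributions score high). Returns the
#' smallest power whose fit reaches \code{r2_target}; if none does, the
#' argmax with a warning flag.
#'
#' @param expr Genes x samples FPKM matrix.
#' @param powers Candidate integer powers (default 1:20).
#' @param r2_target Required topology-model fit (default 0.8).
#' @param nbins Connectivity histogram bins (default 10, logarithmic).
#' @param signed,log_transform Passed to \code{\link{adjacency_matrix}}.
#' @return List: \code{beta}, \code{fit} (data frame power/fit_r2/slope/mean_k),
#'   \code{reached_target} logical.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.8,
                                nbins = 10L, signed = FALSE,
                                log_transform = TRUE) {
  stopifnot(length(powers) >= 1)
  y <- if (log_transform) log2p1(expr) else expr
  if (all(apply(y, 1, stats::sd) == 0)) stop_msg("all genes are constant")
  cc <- suppressWarnings(stats::cor(t(y)))
  cc[is.na(cc)] <- 0
  base <- if (signed) (1 + cc) / 2 else abs(cc)
  diag(base) <- 0
  fit <- data.frame(power = powers, fit_r2 = NA_real_, slope = NA_real_,
                    mean_k = NA_real_)
  for (i in seq_along(powers)) {
    k <- rowSums(base^powers[i])
    fit$mean_k[i] <- mean(k)
    sf <- scale_free_fit(k, nbins)
    fit$fit_r2[i] <- sf["fit_r2"]; fit$slope[i] <- sf["slope"]
  }
  ok <- which(fit$fit_r2 >= r2_target)
  reached <- length(ok) > 0
  beta <- if (reached) powers[ok[1]] else powers[which.max(fit$fit_r2)]
  if (!reached)
    warn_msg("no power reached fit R^2 >= %.2f; using argmax (power %d, R^2 %.3f)",
             r2_target, beta, max(fit$fit_r2))
  list(beta = beta, fit = fit, reached_target = reached)
}

# signed scale-free topology fit from a connectivity vector
scale_free_fit <- function(k, nbins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(c(fit_r2 = 0, slope = 0))
  br <- seq(min(log10(k)), max(log10(k)), length.out = nbins + 1L)
  bin <- cut(log10(k), br, include.lowest = TRUE)
  freq <- tabulate(bin, nbins)
  keep <- freq > 0
  if (sum(keep) < 3) return(c(fit_r2 = 0, slope = 0))
  mean_k <- vapply(split(k, bin), function(z) mean(z), numeric(1))[keep]
  f <- stats::lm(log10(freq[keep]) ~ log10(mean_k))
  r2 <- summary(f)$r.squared
  slope <- stats::coef(f)[2]
  c(fit_r2 = if (slope > 0) -r2 else r2, slope = unname(slope))
}

#' Topological overlap matrix
#'
#' Ravasz-style TOM:
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), TOM_ii = 1,
#' where k_i is the connectivity of gene i. Combines direct adjacency with
#' shared-neighbour weight.
#'
#' @param adjacency Symmetric adjacency in [0,1], zero diagonal.
#' @return Symmetric matrix in [0,1] with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect modules by hierarchical clustering of TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on 1 - TOM with a static cut at
#' \code{cut_height}; clusters smaller than \code{min_module_size} are
#' relabelled 0 (unassigned, the "grey" module). Remaining modules are
#' renumbered 1, 2, ... by decreasing size. Fully deterministic. The default
#' cut sits at 0.995 because topological-overlap dissimilarities compress
#' toward 1 as the soft power grows; unrelated genes pair near 0.999 while
#' module peripheries typically join their cluster below 0.995.
#'
#' @param tom Topological overlap matrix.
#' @param cut_height Static cut height in (0, 1].
#' @param min_module_size Minimum genes per retained module.
#' @return Named integer vector of labels (0 = unassigned).
#' @export
detect_modules <- function(tom, cut_height = 0.995, min_module_size = 30L) {
  if (cut_height <= 0 || cut_height > 1)
    stop_msg("cut_height must lie in (0, 1]")
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  # guard tiny floating-point inversions among tied merge heights
  if (is.unsorted(h$height)) h$height <- cummax(h$height)
  raw <- stats::cutree(h, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- integer(length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[as.character(keep)], keep)]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  }
  names(labels) <- rownames(tom)
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' per-gene z-scored log2(FPKM+1) submatrix, scaled to unit variance and
#' sign-oriented so its mean correlation with the member genes is positive.
#'
#' @param expr Genes x samples FPKM matrix.
#' @param labels Integer module labels as from \code{\link{detect_modules}}
#'   (0 = unassigned, skipped).
#' @param log_transform Apply log2(FPKM+1) first.
#' @return Samples x modules matrix, columns \code{ME<label>}.
#' @export
module_eigengene <- function(expr, labels, log_transform = TRUE) {
  y <- if (log_transform) log2p1(expr) else expr
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop_msg("no assigned modules")
  me <- matrix(NA_real_, nrow = ncol(y), ncol = length(mods),
               dimnames = list(colnames(y), paste0("ME", mods)))
  for (j in seq_along(mods)) {
    sub <- y[labels == mods[j], , drop = FALSE]
    if (nrow(sub) < 2) stop_msg("module %d has fewer than 2 genes", mods[j])
    sds <- apply(sub, 1, stats::sd)
    if (all(sds == 0))
      stop_msg("module %d contains only zero-variance genes", mods[j])
    sub <- sub[sds > 0, , drop = FALSE]
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (mean(stats::cor(e, t(sub))) < 0) e <- -e
    me[, j] <- e / stats::sd(e)
  }
  me
}

#' Module-trait Pearson correlations
#'
#' Pearson r and a two-sided t-distribution p-value for every module
#' eigengene x trait pair. Numeric traits are used as-is; binary traits must
#' already be coded 0/1. A constant trait yields r = 0, p = 1 with a warning.
#'
#' @param eigengenes Samples x modules matrix from \code{\link{module_eigengene}}.
#' @param clinical Clinical table with \code{sample_id} plus trait columns.
#' @param traits Character vector of trait column names (default: all numeric
#'   columns except sample_id).
#' @return Data frame: module, trait, pearson_r, p_value.
#' @export
module_trait_correlation <- function(eigengenes, clinical, traits = NULL) {
  idx <- match(rownames(eigengenes), clinical$sample_id)
  if (anyNA(idx)) stop_msg("eigengene samples missing from clinical table")
  clin <- clinical[idx, , drop = FALSE]
  if (is.null(traits))
    traits <- setdiff(names(clin)[vapply(clin, is.numeric, logical(1))],
                      "sample_id")
  out <- expand.grid(module = colnames(eigengenes), trait = traits,
                     stringsAsFactors = FALSE)
  out$pearson_r <- NA_real_; out$p_value <- NA_real_
  for (i in seq_len(nrow(out))) {
    tv <- clin[[out$trait[i]]]
    if (stats::sd(tv) == 0) {
      warn_msg("trait '%s' is constant; r reported as 0", out$trait[i])
      out$pearson_r[i] <- 0; out$p_value[i] <- 1
    } else {
      ct <- stats::cor.test(eigengenes[, out$module[i]], tv)
      out$pearson_r[i] <- unname(ct$estimate)
      out$p_value[i] <- ct$p.value
    }
  }
  out
}

#' Hub gene of a module
#'
#' Intramodular connectivity kWithin_i = sum over module members j of a_ij.
#' Plain mode returns the member with maximal kWithin ("adding all the weight
#' values of connective nodes"); trait-weighted mode multiplies kWithin by
#' |cor(gene, trait)| first, so the hub can change with the trait of
#' interest. Ties break by gene id.
#'
#' @param adjacency Adjacency matrix with gene ids as dimnames.
#' @param labels Module labels named by gene id.
#' @param module Module label to query.
#' @param expr,trait Optional: FPKM matrix and a numeric per-sample trait
#'   vector (aligned with \code{colnames(expr)}) for trait-weighted scoring.
#' @return List: \code{gene_id}, \code{score}, and the per-member score table.
#' @export
hub_gene <- function(adjacency, labels, module, expr = NULL, trait = NULL) {
  members <- names(labels)[labels == module]
  if (!length(members)) stop_msg("unknown or empty module '%s'", module)
  kwithin <- rowSums(adjacency[members, members, drop = FALSE])
  score <- kwithin
  if (!is.null(trait)) {
    if (is.null(expr)) stop_msg("trait-weighted mode needs expr")
    w <- abs(suppressWarnings(
      stats::cor(t(log2p1(expr[members, , drop = FALSE])), trait)))[, 1]
    w[is.na(w)] <- 0
    score <- kwithin * w
  }
  ord <- order(-score, members)
  list(gene_id = members[ord[1]], score = score[ord[1]],
       table = data.frame(gene_id = members, kWithin = kwithin,
                          score = score, row.names = NULL)[ord, ])
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted module structure (0 = chance,
#' 1 = identical partition).
#'
#' @param a,b Integer label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
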