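#' Plan a planted co-expression module
#'
#' A module is a set of genes driven by one latent factor: per sample the
#' factor is standard normal and each member gene receives
#' \code{loading * factor} on the log2(FPKM+1) scale. The member with maximal
#' loading is the planted hub. A module may optionally drive a clinical trait.
#'
#' @param members Integer vector of distinct gene indices.
#' @param loadings Per-member weights in [0.3, 1] (one per member). Default:
#'   one hub at 1.0, the rest equally spaced down to 0.5.
#' @param trait_name \code{"lymph_node_count"}, \code{"tissue_indicator"}, or
#'   \code{NULL} for a module that drives no trait.
#' @param trait_noise_sd Standard deviation of the Gaussian noise added to the
#'   latent factor before it is mapped to the trait scale (>= 0).
#' @param trait_sign +1 or -1: direction of the module-trait coupling.
#' @return A \code{module_plan} list.
#' @export
module_plan <- function(members, loadings = NULL, trait_name = NULL,
                        trait_noise_sd = 0, trait_sign = 1) {
  members <- as.integer(members)
  if (anyDuplicated(members)) stop_msg("module members must be distinct")
  if (is.null(loadings)) {
    loadings <- c(1, seq(0.95, 0.5, length.out = length(members) - 1L))
    if (length(members) == 1L) loadings <- 1
  }
  if (length(loadings) != length(members))
    stop_msg("need one loading per member (%d members, %d loadings)",
             length(members), length(loadings))
  if (any(loadings < 0.3 - 1e-12) || any(loadings > 1 + 1e-12))
    stop_msg("loadings must lie in [0.3, 1]")
  if (trait_noise_sd < 0) stop_msg("trait_noise_sd must be >= 0")
  if (!trait_sign %in% c(-1, 1)) stop_msg("trait_sign must be +1 or -1")
  structure(list(members = members, loadings = as.numeric(loadings),
                 hub = members[which.max(loadings)],
                 trait_name = trait_name,
                 trait_noise_sd = trait_noise_sd, trait_sign = trait_sign),
            class = "module_plan")
}

#' Specify a synthetic expression cohort
#'
#' Defines a two-group (tumor vs normal) cohort on the log2(FPKM+1) scale:
#' per-gene baselines, planted differentially expressed markers (cases are
#' shifted by +log2FC for up markers and -log2FC for down markers), planted
#' latent-factor co-expression modules, and i.i.d. Gaussian noise. Values are
#' back-transformed to FPKM and floored at zero.
#'
#' When \code{baseline_mu} is not supplied, non-marker baselines are drawn
#' uniformly on [3, 6] (FPKM roughly 7-63, the mid-abundance range the
#' circuit's nM mapping expects), up-markers are given baseline 2 and
#' down-markers baseline 5, so that tumor markers are near-silent in normal
#' tissue and health markers abundant there, as for the real miRNA panel.
#'
#' @param n_genes,n_case,n_control Positive counts.
#' @param planted_markers Data frame with columns \code{gene} (index),
#'   \code{direction} ("up"/"down") and \code{log2fc} (> 0), or NULL.
#' @param baseline_mu Per-gene log2(FPKM+1) means, or NULL to draw them.
#' @param sigma Log2-scale noise SD (>= 0).
#' @param modules List of \code{\link{module_plan}} objects with pairwise
#'   disjoint member sets, disjoint also from the planted markers.
#' @param seed Integer seed; all randomness derives from it.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_genes, n_case, n_control, planted_markers = NULL,
                        baseline_mu = NULL, sigma = 0.5, modules = list(),
                        seed = 1L) {
  stopifnot(n_genes >= 1, n_case >= 1, n_control >= 1, sigma >= 0)
  if (is.null(planted_markers))
    planted_markers <- data.frame(gene = integer(), direction = character(),
                                  log2fc = numeric())
  pm <- planted_markers
  if (!all(c("gene", "direction", "log2fc") %in% names(pm)))
    stop_msg("planted_markers needs columns gene, direction, log2fc")
  if (nrow(pm)) {
    if (anyDuplicated(pm$gene)) stop_msg("planted marker indices must be unique")
    if (any(pm$gene < 1L | pm$gene > n_genes))
      stop_msg("planted marker index out of gene range")
    if (!all(pm$direction %in% c("up", "down")))
      stop_msg("marker direction must be 'up' or 'down'")
    if (any(pm$log2fc <= 0)) stop_msg("log2FC magnitudes must be > 0")
  }
  mod_members <- unlist(lapply(modules, `[[`, "members"))
  if (anyDuplicated(mod_members))
    stop_msg("module member sets must be disjoint")
  if (any(mod_members > n_genes)) stop_msg("module member index out of range")
  clash <- intersect(mod_members, pm$gene)
  if (length(clash))
    stop_msg("gene index %d is both a planted marker and a module member",
             clash[1])
  if (!is.null(baseline_mu) && length(baseline_mu) != n_genes)
    stop_msg("baseline_mu must have length n_genes")
  structure(list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
                 n_control = as.integer(n_control), planted_markers = pm,
                 baseline_mu = baseline_mu, sigma = sigma, modules = modules,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic expression cohort with clinical traits
#'
#' Draws the cohort defined by a \code{\link{cohort_spec}}. On the
#' log2(FPKM+1) scale each value is
#' baseline + group shift + sum of module loading x latent factor + noise;
#' the matrix is back-transformed to FPKM and floored at 0. Latent factors are
#' standard normal per sample and are attached to the expression matrix as
#' \code{attr(, "latent_factors")} (modules x samples) so trait generation and
#' recovery tests can reference the ground truth. Deterministic given the
#' spec's seed.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return List with \code{expr} (genes x samples FPKM matrix) and
#'   \code{clinical} (data frame: sample_id, group, lymph_node_count,
#'   tissue_indicator).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_case + spec$n_control
  set.seed(child_seed(spec$seed, 0L))
  mu <- spec$baseline_mu
  if (is.null(mu)) {
    mu <- stats::runif(spec$n_genes, 3, 6)
    pm <- spec$planted_markers
    mu[pm$gene[pm$direction == "up"]] <- 2
    mu[pm$gene[pm$direction == "down"]] <- 5
  }
  gene_ids <- sprintf("gene_%04d", seq_len(spec$n_genes))
  sample_ids <- c(sprintf("T%04d", seq_len(spec$n_case)),
                  sprintf("N%04d", seq_len(spec$n_control)))
  group <- rep(c("tumor", "normal"), c(spec$n_case, spec$n_control))

  y <- matrix(mu, nrow = spec$n_genes, ncol = n,
              dimnames = list(gene_ids, sample_ids))
  is_case <- group == "tumor"
  pm <- spec$planted_markers
  if (nrow(pm)) {
    shift <- ifelse(pm$direction == "up", pm$log2fc, -pm$log2fc)
    y[pm$gene, is_case] <- y[pm$gene, is_case] + shift
  }
  n_mod <- length(spec$modules)
  factors <- matrix(numeric(0), nrow = 0, ncol = n,
                    dimnames = list(NULL, sample_ids))
  if (n_mod) {
    factors <- matrix(stats::rnorm(n_mod * n), nrow = n_mod,
                      dimnames = list(sprintf("module_%d", seq_len(n_mod)),
                                      sample_ids))
    for (m in seq_len(n_mod)) {
      plan <- spec$modules[[m]]
      y[plan$members, ] <- y[plan$members, ] +
        outer(plan$loadings, factors[m, ])
    }
  }
  if (spec$sigma > 0)
    y <- y + matrix(stats::rnorm(length(y), 0, spec$sigma), nrow = nrow(y))

  expr <- inv_log2p1(y)
  attr(expr, "latent_factors") <- factors
  clinical <- generate_traits(expr, spec$modules,
                              seed = child_seed(spec$seed, 1L))
  clinical$group <- group
  if (!"lymph_node_count" %in% names(clinical))
    clinical$lymph_node_count <- as.integer(round(stats::runif(n, 0, 105)))
  if (!"tissue_indicator" %in% names(clinical))
    clinical$tissue_indicator <- stats::rbinom(n, 1L, 0.5)
  clinical <- clinical[, c("sample_id", "group", "lymph_node_count",
                           "tissue_indicator")]
  list(expr = expr, clinical = clinical)
}

#' Generate clinical traits from module activity
#'
#' Each trait-bearing module contributes
#' \code{trait_sign x latent factor + N(0, trait_noise_sd)} to its named
#' trait; contributions of modules sharing a trait name are summed. The
#' continuous trait is then mapped to its scale: lymph-node counts by an
#' affine map onto [0, 105] followed by rounding (105 is the maximal reported
#' node count), the tissue-collection indicator by thresholding at 0. The
#' pre-rounding continuous traits are attached as \code{attr(, "continuous")}.
#'
#' @param expr Expression matrix carrying \code{attr(, "latent_factors")}
#'   (as produced by \code{\link{generate_cohort}}); if the attribute is
#'   absent, each module's factor is estimated as its eigengene.
#' @param modules List of \code{\link{module_plan}} objects.
#' @param seed Integer seed for the trait noise.
#' @return Data frame with \code{sample_id} and one column per named trait.
#' @export
generate_traits <- function(expr, modules, seed = 1L) {
  sample_ids <- colnames(expr)
  n <- ncol(expr)
  factors <- attr(expr, "latent_factors")
  set.seed(as.integer(seed))
  out <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  cont <- list()
  for (m in seq_along(modules)) {
    plan <- modules[[m]]
    if (is.null(plan$trait_name)) next
    if (!plan$trait_name %in% c("lymph_node_count", "tissue_indicator"))
      stop_msg("unknown trait scale for trait_name '%s'", plan$trait_name)
    if (any(plan$members > nrow(expr)))
      stop_msg("module member index exceeds gene count")
    f <- if (!is.null(factors) && nrow(factors) >= m) factors[m, ]
         else module_eigengene(expr, stats::setNames(
                ifelse(seq_len(nrow(expr)) %in% plan$members, 1L, 0L),
                rownames(expr)))[, 1]
    v <- plan$trait_sign * f + stats::rnorm(n, 0, plan$trait_noise_sd)
    cont[[plan$trait_name]] <- (cont[[plan$trait_name]] %||% 0) + v
  }
  for (trait in names(cont)) {
    v <- cont[[trait]]
    if (trait == "lymph_node_count") {
      rng <- range(v)
      scaled <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) * 105
                else rep(105 / 2, n)
      out[[trait]] <- as.integer(round(scaled))
    } else {
      out[[trait]] <- as.integer(v > 0)
    }
  }
  attr(out, "continuous") <- cont
  out
}

#' Write / read a cohort as TSV
#'
#' The expression table has a \code{gene_id} first column and one column per
#' sample; the clinical table has columns \code{sample_id, group,
#' lymph_node_count, tissue_indicator}. Values are written with full
#' (15 significant digit) precision so a round-trip is exact at written
#' precision.
#'
#' @param cohort List with \code{expr} and \code{clinical}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, "expression.tsv")
  clin_path <- file.path(dir, "clinical.tsv")
  df <- data.frame(gene_id = rownames(cohort$expr),
                   cohort$expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$clinical, clin_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression = expr_path, clinical = clin_path))
}

#' @rdname write_cohort
#' @param check_ragged Verify every row has the same field count before
#'   parsing (reports the offending row).
#' @export
read_cohort <- function(dir, check_ragged = TRUE) {
  expr_path <- file.path(dir, "expression.tsv")
  clin_path <- file.path(dir, "clinical.tsv")
  if (!file.exists(expr_path)) stop_msg("missing %s", expr_path)
  if (check_ragged) {
    nf <- utils::count.fields(expr_path, sep = "\t", quote = "")
    if (length(unique(nf)) > 1L)
      stop_msg("ragged expression table: row %d has %d fields, expected %d",
               which(nf != nf[1])[1], nf[which(nf != nf[1])[1]], nf[1])
  }
  df <- utils::read.delim(expr_path, check.names = FALSE,
                          colClasses = "character")
  if (names(df)[1] != "gene_id") stop_msg("first column must be gene_id")
  if (anyDuplicated(df$gene_id))
    stop_msg("duplicate gene id '%s'", df$gene_id[duplicated(df$gene_id)][1])
  if (anyDuplicated(names(df)[-1]))
    stop_msg("duplicate sample id in header")
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(df)[-1]))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop_msg("non-numeric value at gene '%s', sample '%s'",
             df$gene_id[bad[1, 1]], colnames(vals)[bad[1, 2]])
  if (any(vals < 0)) {
    neg <- which(vals < 0, arr.ind = TRUE)
    stop_msg("negative FPKM at gene '%s', sample '%s'",
             df$gene_id[neg[1, 1]], colnames(vals)[neg[1, 2]])
  }
  rownames(vals) <- df$gene_id
  clinical <- utils::read.delim(clin_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "lymph_node_count", "tissue_indicator")
  if (!all(need %in% names(clinical)))
    stop_msg("clinical table must have columns %s", paste(need, collapse = ", "))
  if (!setequal(clinical$sample_id, colnames(vals)))
    stop_msg("clinical sample ids do not match expression columns")
  list(expr = vals, clinical = clinical)
}
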