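#' Default pipeline configuration
#'
#' Returns the full configuration list with the pipeline defaults: the
#' cohort block mirrors the study conditions (443 tumor vs 46 normal; four
#' planted markers at log2FC +2.5, +1.8, -2.5, -1.8; log2-scale noise SD
#' 0.5), the screening thresholds are |logFC| > 1 and p < 0.01, and the
#' circuit block carries k = 0.003 nM^-1 s^-1 with a 1000 s horizon sampled
#' every 10 s. Callers override fields and pass the result (or a YAML file
#' with the same shape) to \code{\link{run_pipeline}}.
#'
#' @param seed Global seed; per-stage seeds derive from it by fixed offsets
#'   (\code{\link{child_seed}}).
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(
      synthetic = list(
        n_genes = 200L, n_case = 443L, n_control = 46L,
        markers = list(
          list(gene = 1L, direction = "up", log2fc = 2.5),
          list(gene = 2L, direction = "up", log2fc = 1.8),
          list(gene = 3L, direction = "down", log2fc = 2.5),
          list(gene = 4L, direction = "down", log2fc = 1.8)),
        sigma = 0.5)),
    de = list(logfc_threshold = 1, p_threshold = 0.01, shrink = FALSE,
              n_up = 2L, n_down = 2L),
    network = list(enabled = FALSE, powers = 1:20, r2_target = 0.8,
                   cut_height = 0.95, min_module_size = 30L),
    circuit = list(k_default = 0.003, topology = "shared_gate",
                   gate3 = NULL, t_end = 1000, dt = 10),
    call = list(floor_delta = 0.5, margin_eps = 1e-3),
    trajectories = list(write = TRUE, max_samples = 5L))
}

config_markers <- function(markers) {
  do.call(rbind, lapply(markers, function(m)
    data.frame(gene = as.integer(m$gene), direction = m$direction,
               log2fc = as.numeric(m$log2fc))))
}

# recursive merge: user values override defaults; unnamed lists (e.g. the
# marker list) replace wholesale instead of being merged element-wise
merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]) &&
        !is.null(names(user[[nm]])) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

validate_config <- function(config) {
  if (is.null(config$cohort))
    stop_msg("config must have a cohort block")
  has_syn <- !is.null(config$cohort$synthetic)
  has_file <- !is.null(config$cohort$files)
  if (has_syn && has_file)
    stop_msg("config is ambiguous: both synthetic and file cohort blocks given")
  if (!has_syn && !has_file)
    stop_msg("config needs either a synthetic or a files cohort block")
  if (is.null(config$seed)) stop_msg("config must carry a seed")
  invisible(TRUE)
}

#' Run the full expression-to-circuit pipeline
#'
#' Orchestrates: cohort (synthetic generation or TSV files) -> differential
#' expression -> marker panel -> optional co-expression network -> per-sample
#' circuit compilation and ODE simulation -> winner-take-all calls. Writes
#' under \code{outdir}: the cohort TSVs, the DE table, the panel, module and
#' module-trait tables when the network stage is enabled, up to
#' \code{trajectories$max_samples} per-sample trajectory CSVs, the results
#' CSV, the confusion JSON and a run manifest (seed, config hash, solver
#' tolerances, package version). Rerunning with the same config is
#' bit-identical.
#'
#' @param config Configuration list (see \code{\link{default_config}}) or
#'   path to a YAML file with the same shape.
#' @param outdir Output directory.
#' @return Invisibly, a list with the in-memory stage results and file paths.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  from_files <- !is.null(config$cohort$files)
  config <- merge_config(default_config(config$seed), config)
  if (from_files) config$cohort$synthetic <- NULL
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$cohort$synthetic)) {
    syn <- config$cohort$synthetic
    spec <- cohort_spec(n_genes = syn$n_genes, n_case = syn$n_case,
                        n_control = syn$n_control,
                        planted_markers = config_markers(syn$markers),
                        sigma = syn$sigma,
                        modules = syn$modules %||% list(),
                        seed = config$seed)
    cohort <- generate_cohort(spec)
  } else {
    cohort <- read_cohort(config$cohort$files$dir)
  }
  write_cohort(cohort, file.path(outdir, "cohort"))

  de <- compute_de(cohort$expr, cohort$clinical, shrink = config$de$shrink)
  de_out <- de
  de_out[-1] <- lapply(de_out[-1], function(x) signif(x, 12))
  utils::write.table(de_out, file.path(outdir, "de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  degs <- filter_degs(de, config$de$logfc_threshold, config$de$p_threshold)
  panel <- select_top_markers(degs, config$de$n_up, config$de$n_down)
  utils::write.table(
    data.frame(channel = rep(c("positive", "negative"),
                             c(nrow(panel$positive), nrow(panel$negative))),
               rbind(panel$positive, panel$negative)),
    file.path(outdir, "panel.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  network <- NULL
  if (isTRUE(config$network$enabled)) {
    pst <- pick_soft_threshold(cohort$expr, powers = config$network$powers,
                               r2_target = config$network$r2_target)
    adj <- adjacency_matrix(cohort$expr, pst$beta)
    tom <- topological_overlap(adj)
    labels <- detect_modules(tom, config$network$cut_height,
                             config$network$min_module_size)
    kwithin <- vapply(seq_along(labels), function(i) {
      m <- labels[i]
      if (m == 0) 0 else sum(adj[i, labels == m])
    }, numeric(1))
    utils::write.table(
      data.frame(gene_id = names(labels), module_label = unname(labels),
                 kWithin = signif(kwithin, 12)),
      file.path(outdir, "modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    mt <- NULL
    if (any(labels > 0)) {
      me <- module_eigengene(cohort$expr, labels)
      mt <- module_trait_correlation(me, cohort$clinical)
      mt_out <- mt; mt_out[3:4] <- lapply(mt_out[3:4], signif, 12)
      utils::write.table(mt_out, file.path(outdir, "module_trait.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    network <- list(beta = pst$beta, fit = pst$fit, labels = labels,
                    module_trait = mt)
  }

  cls <- classify_cohort(cohort$expr, cohort$clinical, panel,
                         k_default = config$circuit$k_default,
                         topology = config$circuit$topology,
                         gate3_conc = config$circuit$gate3,
                         t_end = config$circuit$t_end, dt = config$circuit$dt,
                         floor_delta = config$call$floor_delta,
                         margin_eps = config$call$margin_eps,
                         keep_trajectories = isTRUE(config$trajectories$write))
  res_out <- cls$results
  num <- vapply(res_out, is.numeric, logical(1))
  res_out[num] <- lapply(res_out[num], signif, 12)
  utils::write.csv(res_out, file.path(outdir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  if (isTRUE(config$trajectories$write)) {
    tdir <- file.path(outdir, "trajectories")
    dir.create(tdir, showWarnings = FALSE)
    keep <- utils::head(names(cls$trajectories),
                        config$trajectories$max_samples)
    for (id in keep)
      write_trajectory(cls$trajectories[[id]],
                       file.path(tdir, paste0(id, ".csv")))
    cls$trajectories <- NULL
  }
  confusion <- list(
    counts = as.data.frame.matrix(unclass(cls$summary$counts)),
    per_class_accuracy = as.list(cls$summary$per_class_accuracy),
    overall_accuracy = cls$summary$overall_accuracy,
    binary_accuracy = cls$summary$binary_accuracy,
    n = cls$summary$n)
  jsonlite::write_json(confusion, file.path(outdir, "confusion.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    ode_rtol = 1e-8, ode_atol = 1e-10,
    package_version = as.character(utils::packageVersion("dsdwta")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, de = de, panel = panel, network = network,
                 classification = cls, outdir = outdir))
}
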