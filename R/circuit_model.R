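#' Construct a circuit specification
#'
#' A \code{circuit_spec} holds the species table (id, role, channel, initial
#' concentration in nM), the bimolecular mass-action reaction list (two
#' reactants, one or two products, rate constant in nM^-1 s^-1), the
#' channel-to-signal readout map, and the sampling grid. Species are kept in
#' canonical (id-sorted) order so compilation is pure: the same inputs always
#' produce an identical spec.
#'
#' @param species Data frame: id, role, channel, conc_nM.
#' @param reactions List of lists: reactants (2 ids), products (1-2 ids),
#'   k (rate constant, nM^-1 s^-1).
#' @param readout Named character vector mapping channels (FAM, ROX) to
#'   signal species ids.
#' @param t_end,dt Readout horizon and sampling interval, seconds (defaults
#'   1000 s sampled every 10 s: 100 post-zero measurements).
#' @param topology Topology name, informational.
#' @return A \code{circuit_spec} object.
#' @export
circuit_spec <- function(species, reactions, readout, t_end = 1000,
                         dt = 10, topology = "shared_gate") {
  ord <- order(species$id)
  species <- species[ord, , drop = FALSE]
  rownames(species) <- NULL
  spec <- structure(list(species = species, reactions = reactions,
                         readout = readout, t_end = t_end, dt = dt,
                         topology = topology),
                    class = "circuit_spec")
  v <- validate_circuit(spec)
  if (length(v)) stop_msg("invalid circuit: %s", paste(v, collapse = "; "))
  spec
}

species_row <- function(id, role, channel = "none", conc = 0)
  data.frame(id = id, role = role, channel = channel, conc_nM = conc,
             stringsAsFactors = FALSE)

reaction <- function(reactants, products, k)
  list(reactants = reactants, products = products, k = k)

#' Compile a four-input diagnostic winner-take-all circuit
#'
#' Maps a biomarker panel plus one sample's FPKM values onto the two-layer
#' strand-displacement circuit. FPKM maps to nM identically. Layer 1: each
#' positive (tumor) input displaces gate 1 to release the tumor output
#' strand at rate |log2FC| x k_default; negative (health) inputs do the same
#' through gate 2. Gates 1 and 2 start at the summed concentration of their
#' inputs, so layer 1 is stoichiometrically non-limiting. Layer 2 depends on
#' \code{topology}:
#' \describe{
#'   \item{shared_gate}{both output pools compete for a single limiting
#'     gate 3, releasing the FAM (tumor) or ROX (health) signal; gate 3
#'     starts at the mean of the negative inputs' concentrations (the
#'     threshold rule that gave 17 nM for the original panel) unless
#'     \code{gate3_conc} overrides it.}
#'   \item{annihilation}{tumor and health outputs annihilate pairwise; the
#'     survivors report through per-channel reporters, each at the gate-3
#'     concentration.}
#'   \item{threshold_subtract}{the health output is first absorbed by a fast
#'     threshold complex at the gate-3 concentration; the remainder of both
#'     pools reports through non-limiting per-channel reporters.}
#' }
#'
#' @param panel A \code{biomarker_panel} from \code{\link{select_top_markers}}.
#' @param sample_fpkm Named numeric vector, gene id -> FPKM.
#' @param k_default Default binding rate constant, nM^-1 s^-1 (0.003).
#' @param topology One of shared_gate, annihilation, threshold_subtract.
#' @param gate3_conc Optional fixed gate-3 concentration (nM); default the
#'   mean of the negative-channel input concentrations.
#' @param t_end,dt Sampling grid (seconds).
#' @return A \code{circuit_spec}.
#' @export
compile_diagnostic_circuit <- function(panel, sample_fpkm, k_default = 0.003,
                                       topology = c("shared_gate",
                                                    "annihilation",
                                                    "threshold_subtract"),
                                       gate3_conc = NULL,
                                       t_end = 1000, dt = 10) {
  topology <- match.arg(topology)
  stopifnot(k_default > 0)
  genes <- c(panel$positive$gene_id, panel$negative$gene_id)
  missing <- setdiff(genes, names(sample_fpkm))
  if (length(missing))
    stop_msg("panel gene '%s' missing from sample", missing[1])
  lfc <- c(panel$positive$log2FC, panel$negative$log2FC)
  if (any(lfc == 0))
    stop_msg("log2FC of 0 for marker '%s': compiled rate would vanish",
             genes[which(lfc == 0)[1]])
  conc <- pmax(as.numeric(sample_fpkm[genes]), 0)
  names(conc) <- genes
  npos <- nrow(panel$positive)
  pos <- genes[seq_len(npos)]; neg <- genes[-seq_len(npos)]
  gate3 <- gate3_conc %||% mean(conc[neg])

  sp <- rbind(
    species_row(paste0("input_", genes), "input", conc = conc),
    species_row("gate1", "gate_complex", conc = sum(conc[pos])),
    species_row("gate2", "gate_complex", conc = sum(conc[neg])),
    species_row("out_tumor", "intermediate_output"),
    species_row("out_health", "intermediate_output"),
    species_row("sig_FAM", "signal", channel = "FAM"),
    species_row("sig_ROX", "signal", channel = "ROX"),
    species_row("waste", "waste"))
  rx <- c(
    lapply(seq_along(pos), function(i)
      reaction(c(paste0("input_", pos[i]), "gate1"), c("out_tumor", "waste"),
               abs(panel$positive$log2FC[i]) * k_default)),
    lapply(seq_along(neg), function(i)
      reaction(c(paste0("input_", neg[i]), "gate2"), c("out_health", "waste"),
               abs(panel$negative$log2FC[i]) * k_default)))

  if (topology == "shared_gate") {
    sp <- rbind(sp, species_row("gate3", "gate_complex", conc = gate3))
    rx <- c(rx, list(
      reaction(c("out_tumor", "gate3"), c("sig_FAM", "waste"), k_default),
      reaction(c("out_health", "gate3"), c("sig_ROX", "waste"), k_default)))
  } else if (topology == "annihilation") {
    sp <- rbind(sp,
      species_row("rep_FAM", "reporter_complex", conc = gate3),
      species_row("rep_ROX", "reporter_complex", conc = gate3))
    rx <- c(rx, list(
      reaction(c("out_tumor", "out_health"), "waste", k_default),
      reaction(c("out_tumor", "rep_FAM"), c("sig_FAM", "waste"), k_default),
      reaction(c("out_health", "rep_ROX"), c("sig_ROX", "waste"), k_default)))
  } else {
    sp <- rbind(sp,
      species_row("thresh", "gate_complex", conc = gate3),
      species_row("rep_FAM", "reporter_complex", conc = sum(conc[pos])),
      species_row("rep_ROX", "reporter_complex", conc = sum(conc[neg])))
    rx <- c(rx, list(
      # fast absorption so thresholding precedes reporting
      reaction(c("out_health", "thresh"), "waste", 20 * k_default),
      reaction(c("out_tumor", "rep_FAM"), c("sig_FAM", "waste"), k_default),
      reaction(c("out_health", "rep_ROX"), c("sig_ROX", "waste"), k_default)))
  }
  circuit_spec(sp, rx, c(FAM = "sig_FAM", ROX = "sig_ROX"),
               t_end = t_end, dt = dt, topology = topology)
}

#' Compile a two-input trait-classification circuit
#'
#' Same two-layer architecture as the diagnostic circuit but with a single
#' hub-gene input per channel (e.g. mir-99a vs mir-451a for lymph-node
#' count). Rates default to \code{k_default}; \code{rate_scale} (e.g. the
#' |module-trait correlation| per channel) rescales them. Gate 3 starts at
#' the negative input's concentration (the mean of a singleton).
#'
#' @param pos_hub,neg_hub Gene ids for the FAM (positive) and ROX (negative)
#'   channel inputs.
#' @param sample_fpkm Named numeric vector, gene id -> FPKM.
#' @param k_default Base rate constant, nM^-1 s^-1.
#' @param rate_scale Optional list/vector with elements \code{pos} and
#'   \code{neg}: multipliers on \code{k_default}.
#' @param topology,gate3_conc,t_end,dt As in
#'   \code{\link{compile_diagnostic_circuit}}.
#' @return A \code{circuit_spec}.
#' @export
compile_trait_circuit <- function(pos_hub, neg_hub, sample_fpkm,
                                  k_default = 0.003, rate_scale = NULL,
                                  topology = "shared_gate",
                                  gate3_conc = NULL, t_end = 1000, dt = 10) {
  scale_pos <- if (is.null(rate_scale)) 1 else as.numeric(rate_scale[["pos"]])
  scale_neg <- if (is.null(rate_scale)) 1 else as.numeric(rate_scale[["neg"]])
  panel <- structure(list(
    positive = data.frame(gene_id = pos_hub, log2FC = scale_pos),
    negative = data.frame(gene_id = neg_hub, log2FC = -scale_neg)),
    class = "biomarker_panel")
  compile_diagnostic_circuit(panel, sample_fpkm, k_default = k_default,
                             topology = topology, gate3_conc = gate3_conc,
                             t_end = t_end, dt = dt)
}

#' Validate a circuit specification
#'
#' Walks the species table and reaction graph and returns one message per
#' violated invariant (unique ids, declared reactants/products, non-negative
#' concentrations, positive finite rates, channelled signal species,
#' readout species present, positive horizon). An empty character vector
#' means the spec is well-formed.
#'
#' @param spec A \code{circuit_spec} (or a bare list with the same fields).
#' @return Character vector of violations (empty if valid).
#' @export
validate_circuit <- function(spec) {
  v <- character()
  sp <- spec$species
  if (anyDuplicated(sp$id))
    v <- c(v, sprintf("duplicate species id '%s'",
                      sp$id[duplicated(sp$id)][1]))
  bad_conc <- sp$id[is.na(sp$conc_nM) | sp$conc_nM < 0]
  for (id in bad_conc)
    v <- c(v, sprintf("species '%s' has negative or missing concentration", id))
  sig <- sp$role == "signal"
  for (id in sp$id[sig & !sp$channel %in% c("FAM", "ROX")])
    v <- c(v, sprintf("signal species '%s' carries no channel", id))
  for (id in sp$id[sp$role == "input" & sp$channel != "none"])
    v <- c(v, sprintf("input species '%s' must have channel 'none'", id))
  for (i in seq_along(spec$reactions)) {
    r <- spec$reactions[[i]]
    if (length(r$reactants) != 2L)
      v <- c(v, sprintf("reaction %d is not bimolecular", i))
    if (!length(r$products) %in% 1:2)
      v <- c(v, sprintf("reaction %d must have 1-2 products", i))
    undecl <- setdiff(c(r$reactants, r$products), sp$id)
    for (id in undecl)
      v <- c(v, sprintf("reaction %d references undeclared species '%s'", i, id))
    if (!is.finite(r$k) || r$k <= 0)
      v <- c(v, sprintf("reaction %d has non-positive or non-finite rate", i))
  }
  for (ch in names(spec$readout))
    if (!spec$readout[[ch]] %in% sp$id)
      v <- c(v, sprintf("readout channel %s maps to unknown species '%s'",
                        ch, spec$readout[[ch]]))
  if (is.null(spec$t_end) || spec$t_end <= 0)
    v <- c(v, "t_end must be > 0")
  v
}

#' Serialize / load a circuit spec as YAML
#'
#' @param spec A \code{circuit_spec}.
#' @param path Output file.
#' @export
write_circuit <- function(spec, path) {
  obj <- list(
    topology = spec$topology,
    species = lapply(seq_len(nrow(spec$species)), function(i)
      list(id = spec$species$id[i], role = spec$species$role[i],
           channel = spec$species$channel[i],
           conc_nM = spec$species$conc_nM[i])),
    reactions = lapply(spec$reactions, function(r)
      list(reactants = as.list(r$reactants), products = as.list(r$products),
           k_nM_s = r$k)),
    readout = as.list(spec$readout),
    t_end_s = spec$t_end, dt_s = spec$dt)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_circuit
#' @export
read_circuit <- function(path) {
  obj <- yaml::read_yaml(path)
  sp <- do.call(rbind, lapply(obj$species, function(s)
    species_row(s$id, s$role, s$channel, s$conc_nM)))
  rx <- lapply(obj$reactions, function(r)
    reaction(unlist(r$reactants), unlist(r$products), r$k_nM_s))
  circuit_spec(sp, rx, unlist(obj$readout), t_end = obj$t_end_s,
               dt = obj$dt_s, topology = obj$topology)
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf("Circuit (%s): %d species, %d reactions, horizon %gs @ %gs\n",
              x$topology, nrow(x$species), length(x$reactions),
              x$t_end, x$dt))
  invisible(x)
}
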