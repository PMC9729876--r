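#' Endpoint channel readout
#'
#' Concentrations of the FAM and ROX signal species at \code{readout_time}
#' (default the end of the grid), clipped at 0.
#'
#' @param traj A \code{trajectory_set} carrying a readout map.
#' @param readout_time A time on the sampling grid, seconds.
#' @return Named numeric: \code{fam}, \code{rox} (nM).
#' @export
read_out <- function(traj, readout_time = NULL) {
  readout_time <- readout_time %||% max(traj$times)
  i <- which(abs(traj$times - readout_time) < 1e-9)
  if (!length(i)) stop_msg("readout_time %g s is not on the sampling grid",
                           readout_time)
  ids <- traj$readout
  if (is.null(ids) || !all(ids %in% rownames(traj$conc)))
    stop_msg("trajectory lacks FAM/ROX readout species")
  c(fam = max(traj$conc[ids[["FAM"]], i], 0),
    rox = max(traj$conc[ids[["ROX"]], i], 0))
}

#' Winner-take-all call from endpoint signals
#'
#' Indeterminate when both channels stay below the detection floor
#' \code{floor_delta} (the "too dim to read" case) or when the channels tie
#' within \code{margin_eps}; otherwise positive (tumor) iff FAM > ROX.
#'
#' @param fam,rox Endpoint signals, nM (>= 0).
#' @param floor_delta Detection floor, nM.
#' @param margin_eps Tie margin, nM.
#' @return One of "positive", "negative", "indeterminate".
#' @export
call_sample <- function(fam, rox, floor_delta = 0.5, margin_eps = 1e-3) {
  if (fam < 0 || rox < 0) stop_msg("signals must be non-negative")
  if (max(fam, rox) < floor_delta) return("indeterminate")
  if (abs(fam - rox) <= margin_eps) return("indeterminate")
  if (fam > rox) "positive" else "negative"
}

#' Confusion summary of cohort calls
#'
#' Per-true-class counts of each call (indeterminate is a first-class
#' column), per-class accuracy, overall accuracy (indeterminate counts as
#' wrong) and binary accuracy among determinate calls.
#'
#' @param results Data frame with \code{true_class} ("tumor"/"normal") and
#'   \code{call} columns.
#' @return List: \code{counts} (class x call matrix), \code{per_class_accuracy},
#'   \code{overall_accuracy}, \code{binary_accuracy}, \code{n}.
#' @export
confusion_summary <- function(results) {
  calls <- factor(results$call,
                  levels = c("positive", "negative", "indeterminate"))
  truth <- factor(results$true_class, levels = c("tumor", "normal"))
  counts <- table(true_class = truth, call = calls)
  correct <- (truth == "tumor" & calls == "positive") |
             (truth == "normal" & calls == "negative")
  per_class <- vapply(levels(truth), function(g)
    if (!sum(truth == g)) NA_real_ else mean(correct[truth == g]),
    numeric(1))
  det <- calls != "indeterminate"
  list(counts = counts,
       per_class_accuracy = per_class,
       overall_accuracy = mean(correct),
       binary_accuracy = if (any(det)) mean(correct[det]) else NA_real_,
       n = length(calls))
}

#' Classify a cohort through the diagnostic circuit
#'
#' For every sample: compile the four-input winner-take-all circuit from the
#' panel and the sample's FPKM values, integrate its mass-action kinetics,
#' read the endpoint FAM/ROX signals and call tumor/health/indeterminate.
#'
#' @param expr Genes x samples FPKM matrix.
#' @param clinical Clinical table (sample_id, group).
#' @param panel A \code{biomarker_panel}.
#' @param k_default,topology,gate3_conc,t_end,dt Circuit parameters, see
#'   \code{\link{compile_diagnostic_circuit}}.
#' @param floor_delta,margin_eps Call parameters, see \code{\link{call_sample}}.
#' @param keep_trajectories Retain each sample's trajectory (memory!).
#' @return List: \code{results} data frame (sample_id, true_class,
#'   fam_final_nM, rox_final_nM, margin_nM, call), \code{summary}
#'   (\code{\link{confusion_summary}}), optionally \code{trajectories}.
#' @export
classify_cohort <- function(expr, clinical, panel, k_default = 0.003,
                            topology = "shared_gate", gate3_conc = NULL,
                            t_end = 1000, dt = 10, floor_delta = 0.5,
                            margin_eps = 1e-3, keep_trajectories = FALSE) {
  ids <- colnames(expr)
  res <- data.frame(sample_id = ids,
                    true_class = clinical$group[match(ids, clinical$sample_id)],
                    fam_final_nM = NA_real_, rox_final_nM = NA_real_,
                    margin_nM = NA_real_, call = NA_character_,
                    stringsAsFactors = FALSE)
  trajs <- if (keep_trajectories) vector("list", length(ids)) else NULL
  for (s in seq_along(ids)) {
    spec <- tryCatch(
      compile_diagnostic_circuit(panel, expr[, s], k_default = k_default,
                                 topology = topology, gate3_conc = gate3_conc,
                                 t_end = t_end, dt = dt),
      error = function(e) stop_msg("sample '%s': %s", ids[s], conditionMessage(e)))
    traj <- simulate_ode(spec)
    sig <- read_out(traj)
    res$fam_final_nM[s] <- sig[["fam"]]
    res$rox_final_nM[s] <- sig[["rox"]]
    res$margin_nM[s] <- sig[["fam"]] - sig[["rox"]]
    res$call[s] <- call_sample(sig[["fam"]], sig[["rox"]],
                               floor_delta, margin_eps)
    if (keep_trajectories) trajs[[s]] <- traj
  }
  out <- list(results = res, summary = confusion_summary(res))
  if (keep_trajectories) out$trajectories <- stats::setNames(trajs, ids)
  out
}

#' Bin lymph-node counts into the three prognostic parts
#'
#' part1: count <= 15 (15 being the survival-threshold boundary, assigned
#' low); part2: 16-28; part3: >= 29.
#'
#' @param count Non-negative integer vector.
#' @param boundaries Two increasing boundaries (default c(15, 28)).
#' @return Character vector of part labels.
#' @export
bin_lymph_nodes <- function(count, boundaries = c(15L, 28L)) {
  if (any(count < 0)) stop_msg("node counts must be >= 0")
  if (length(boundaries) != 2L || diff(boundaries) <= 0)
    stop_msg("boundaries must be two strictly increasing values")
  ifelse(count <= boundaries[1], "part1",
         ifelse(count <= boundaries[2], "part2", "part3"))
}

#' Classify a clinical trait through a two-input hub-gene circuit
#'
#' Per sample: compile the trait circuit from the two hub genes, simulate,
#' and call the winning channel; score against the channel expected for the
#' sample's trait level (\code{expected_channel}, config data, e.g.
#' \code{c(part1 = "FAM", part2 = "FAM", part3 = "ROX")} for lymph-node
#' parts or \code{c("0" = "ROX", "1" = "FAM")} for a binary indicator).
#' Indeterminate calls match no channel. Parts with no samples report NA.
#'
#' @param expr,clinical Cohort.
#' @param pos_hub,neg_hub FAM- and ROX-channel input genes.
#' @param trait Clinical column: "lymph_node_count" (binned into parts) or a
#'   binary 0/1 column used as its own level.
#' @param expected_channel Named vector level -> "FAM"/"ROX".
#' @param binning Lymph-node boundaries, see \code{\link{bin_lymph_nodes}}.
#' @param k_default,rate_scale,topology,gate3_conc,t_end,dt Circuit
#'   parameters.
#' @param floor_delta,margin_eps Call parameters.
#' @return List: \code{results} per-sample data frame, \code{per_level}
#'   accuracy table (level, n, n_correct, accuracy).
#' @export
classify_trait_cohort <- function(expr, clinical, pos_hub, neg_hub, trait,
                                  expected_channel,
                                  binning = c(15L, 28L), k_default = 0.003,
                                  rate_scale = NULL, topology = "shared_gate",
                                  gate3_conc = NULL, t_end = 1000, dt = 10,
                                  floor_delta = 0.5, margin_eps = 1e-3) {
  if (!trait %in% names(clinical)) stop_msg("trait '%s' not in clinical", trait)
  ids <- colnames(expr)
  tv <- clinical[[trait]][match(ids, clinical$sample_id)]
  level <- if (trait == "lymph_node_count") bin_lymph_nodes(tv, binning)
           else as.character(tv)
  res <- data.frame(sample_id = ids, level = level,
                    fam_final_nM = NA_real_, rox_final_nM = NA_real_,
                    call = NA_character_, winner = NA_character_,
                    stringsAsFactors = FALSE)
  for (s in seq_along(ids)) {
    spec <- compile_trait_circuit(pos_hub, neg_hub, expr[, s],
                                  k_default = k_default,
                                  rate_scale = rate_scale,
                                  topology = topology,
                                  gate3_conc = gate3_conc,
                                  t_end = t_end, dt = dt)
    sig <- read_out(simulate_ode(spec))
    res$fam_final_nM[s] <- sig[["fam"]]; res$rox_final_nM[s] <- sig[["rox"]]
    res$call[s] <- call_sample(sig[["fam"]], sig[["rox"]],
                               floor_delta, margin_eps)
    res$winner[s] <- switch(res$call[s], positive = "FAM", negative = "ROX",
                            NA_character_)
  }
  res$expected <- unname(expected_channel[res$level])
  res$correct <- !is.na(res$winner) & res$winner == res$expected
  lv <- names(expected_channel)
  per_level <- data.frame(
    level = lv,
    n = vapply(lv, function(l) sum(res$level == l), integer(1)),
    row.names = NULL)
  per_level$n_correct <- vapply(lv, function(l)
    sum(res$correct[res$level == l]), integer(1))
  per_level$accuracy <- ifelse(per_level$n > 0,
                               per_level$n_correct / per_level$n, NA_real_)
  list(results = res, per_level = per_level)
}
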