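#' Stoichiometry matrix of a circuit
#'
#' Species x reaction integer matrix S (net change of each species per firing)
#' plus the rate vector and reactant index pairs. The mass-action propensity
#' of reaction r with reactants (A, B) is k_r [A][B].
#'
#' @param spec A \code{circuit_spec}.
#' @return List: \code{S} (species x reactions, rownames = species ids),
#'   \code{k} (rate constants), \code{reactants} (2 x reactions index matrix).
#' @export
build_stoichiometry <- function(spec) {
  ids <- spec$species$id
  nr <- length(spec$reactions)
  S <- matrix(0L, nrow = length(ids), ncol = nr,
              dimnames = list(ids, NULL))
  ridx <- matrix(0L, nrow = 2, ncol = nr)
  k <- numeric(nr)
  for (j in seq_len(nr)) {
    r <- spec$reactions[[j]]
    for (id in r$reactants) S[id, j] <- S[id, j] - 1L
    for (id in r$products) S[id, j] <- S[id, j] + 1L
    ridx[, j] <- match(r$reactants, ids)
    k[j] <- r$k
  }
  list(S = S, k = k, reactants = ridx)
}

#' Deterministic mass-action trajectories
#'
#' Integrates d x / d t = S v(x), v_r = k_r [A_r][B_r], with a stiff-capable
#' adaptive integrator (lsoda), relative tolerance 1e-8 and absolute
#' tolerance 1e-10 nM, sampled on the spec's grid (0 to t_end by dt). Raw
#' solver output is stored untouched; tiny negative excursions are clipped
#' to 0 only on export/readout.
#'
#' @param spec A \code{circuit_spec}.
#' @param rtol,atol Solver tolerances.
#' @return A \code{trajectory_set}: list with \code{times} (seconds) and
#'   \code{conc} (species x time matrix, nM).
#' @export
simulate_ode <- function(spec, rtol = 1e-8, atol = 1e-10) {
  st <- build_stoichiometry(spec)
  x0 <- stats::setNames(spec$species$conc_nM, spec$species$id)
  times <- seq(0, spec$t_end, by = spec$dt)
  Sd <- st$S * 1.0
  r1 <- st$reactants[1, ]; r2 <- st$reactants[2, ]
  deriv <- function(t, x, p) {
    v <- st$k * x[r1] * x[r2]
    list(as.vector(Sd %*% v))
  }
  sol <- deSolve::lsoda(y = x0, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop_msg("ODE integration failed near t = %g s", max(sol[, 1]))
  conc <- t(unclass(sol)[, -1, drop = FALSE])
  rownames(conc) <- spec$species$id
  structure(list(times = times, conc = conc,
                 readout = spec$readout,
                 meta = list(rtol = rtol, atol = atol, engine = "lsoda")),
            class = "trajectory_set")
}

#' Gillespie stochastic simulation (direct method)
#'
#' Converts initial concentrations to molecule counts via
#' \code{volume_scale} (molecules per nM; default 100), then runs the exact
#' direct-method SSA, recording counts on the spec's sampling grid.
#' Propensity of A + B -> ... is k/volume_scale * xA * xB (and
#' k/volume_scale * xA (xA - 1) for A + A). Deterministic given the seed.
#'
#' @param spec A \code{circuit_spec}.
#' @param volume_scale Molecules per nM.
#' @param seed Integer seed.
#' @param n_runs Number of independent runs.
#' @return List: \code{times}, \code{counts} (species x time x runs array),
#'   \code{volume_scale}.
#' @export
simulate_ssa <- function(spec, volume_scale = 100, seed = 1L, n_runs = 1L) {
  st <- build_stoichiometry(spec)
  times <- seq(0, spec$t_end, by = spec$dt)
  x0 <- round(spec$species$conc_nM * volume_scale)
  nz <- spec$species$conc_nM > 0
  if (any(nz & x0 < 1))
    stop_msg("volume_scale %g maps species '%s' below one molecule",
             volume_scale, spec$species$id[nz & x0 < 1][1])
  ns <- length(x0); nt <- length(times); nr <- length(st$k)
  counts <- array(NA_real_, dim = c(ns, nt, n_runs),
                  dimnames = list(spec$species$id, NULL, NULL))
  set.seed(as.integer(seed))
  kv <- st$k / volume_scale
  r1 <- st$reactants[1, ]; r2 <- st$reactants[2, ]
  same <- which(r1 == r2)
  Scol <- lapply(seq_len(nr), function(j) st$S[, j])
  for (run in seq_len(n_runs)) {
    x <- x0; t_now <- 0; ti <- 1L
    repeat {
      a <- kv * x[r1] * x[r2]
      # A + A self-reactions: propensity uses x(x-1)
      for (j in same) a[j] <- kv[j] * x[r1[j]] * max(x[r1[j]] - 1, 0)
      a0 <- sum(a)
      t_next <- if (a0 > 0 && nr > 0) t_now + stats::rexp(1, a0) else Inf
      while (ti <= nt && times[ti] <= t_next) {
        counts[, ti, run] <- x
        ti <- ti + 1L
      }
      if (ti > nt || !is.finite(t_next)) break
      t_now <- t_next
      j <- sample.int(nr, 1L, prob = a)
      x <- x + Scol[[j]]
    }
    if (ti <= nt) counts[, ti:nt, run] <- x
  }
  list(times = times, counts = counts, volume_scale = volume_scale)
}

#' Conserved-moiety drift check
#'
#' Computes an orthonormal basis of the left null space of the stoichiometry
#' matrix (weighted species totals the reactions cannot change) and reports
#' the maximal absolute drift |c . x(t) - c . x(0)| over the trajectory for
#' each basis vector. Drift beyond \code{tol} indicates an integration or
#' bookkeeping fault.
#'
#' @param traj A \code{trajectory_set} from \code{\link{simulate_ode}}.
#' @param spec The circuit it was produced from.
#' @param tol Pass threshold, nM.
#' @return List: \code{moieties} (basis matrix, species x moieties),
#'   \code{max_drift} per moiety, \code{pass}.
#' @export
conservation_check <- function(traj, spec, tol = 1e-6) {
  st <- build_stoichiometry(spec)
  S <- st$S * 1.0
  sv <- svd(S, nu = nrow(S), nv = 0)
  rank <- sum(sv$d > max(dim(S)) * max(sv$d, 0) * 1e-12)
  if (rank == nrow(S))
    return(list(moieties = matrix(numeric(0), nrow(S), 0),
                max_drift = numeric(0), pass = TRUE))
  null_basis <- sv$u[, (rank + 1):nrow(S), drop = FALSE]
  rownames(null_basis) <- rownames(S)
  totals <- t(null_basis) %*% traj$conc[rownames(S), , drop = FALSE]
  drift <- apply(abs(totals - totals[, 1]), 1, max)
  list(moieties = null_basis, max_drift = drift,
       pass = all(drift <= tol))
}

#' Write per-sample trajectory CSV
#'
#' First column \code{time_s}, one column per species, concentrations
#' clipped at 0 on export.
#'
#' @param traj A \code{trajectory_set}.
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time_s = traj$times,
                   t(pmax(traj$conc, 0)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
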