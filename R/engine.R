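#' Construct a simulation state
#'
#' Bundles everything the time evolution needs: the bead table for the full
#' sequence, the positions of already-translated beads, the lateral-gate
#' state, translation progress and the model parameters.
#'
#' @param beads bead tibble from [map_sequence()] (full sequence).
#' @param geom a [sec_geometry()].
#' @param positions n-by-3 matrix of bead positions in \eqn{\sigma}; rows of
#'   `NA` mark beads not yet translated. `NULL` starts a fresh trajectory
#'   with the first bead fixed at the insertion point.
#' @param gate `"closed"` or `"open"`.
#' @param translating whether the last placed bead is currently held fixed
#'   under translation.
#' @param progress time already spent translating the current bead (s).
#' @param constants constants list from [sec_constants()].
#' @param table soft-core parameter table from [softcore_table()].
#' @return An object of class `sim_state`.
#' @export
sim_state <- function(beads, geom, positions = NULL, gate = "closed",
                      translating = is.null(positions), progress = 0,
                      constants = sec_constants(),
                      table = softcore_table(constants)) {
  n <- nrow(beads)
  force(translating)
  if (is.null(positions)) {
    positions <- matrix(NA_real_, n, 3)
    positions[1, ] <- geom$insertion_point
  }
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == n, ncol(positions) == 3)
  placed <- which(is.finite(positions[, 1]))
  n_placed <- if (length(placed)) max(placed) else 0L
  if (n_placed != length(placed)) {
    abort("translated beads must form a contiguous block from the start")
  }
  structure(
    list(beads = beads, geom = geom, positions = positions,
         gate = match.arg(gate, c("closed", "open")),
         n_placed = as.integer(n_placed),
         translating = isTRUE(translating) && n_placed >= 1 && n_placed <= n,
         progress = progress, time_s = 0,
         constants = constants, table = table),
    class = "sim_state"
  )
}

#' @export
print.sim_state <- function(x, ...) {
  cat("<sim_state>", x$n_placed, "of", nrow(x$beads), "beads translated;",
      "gate", x$gate, if (x$translating) "(translating)" else "", "\n")
  invisible(x)
}

.state_args <- function(state) {
  list(pos = state$positions, g = state$beads$g, q = state$beads$q,
       lo = state$beads$lambda_open, lc = state$beads$lambda_closed,
       gate = as.integer(state$gate == "open"),
       geom = .geom_matrices(state$geom),
       pars = .pars_list(state$constants, state$table))
}

#' Forces on the nascent-chain beads
#'
#' Analytic negative gradient of the total potential with respect to every
#' translated bead position, in \eqn{\epsilon/\sigma}.
#'
#' @param state a [sim_state()].
#' @return n-by-3 matrix (rows of `NA` for untranslated beads).
#' @export
forces <- function(state) {
  a <- .state_args(state)
  cg_forces(a$pos, a$g, a$q, a$lo, a$lc, a$gate, a$geom, a$pars)
}

#' One overdamped Langevin (Brownian dynamics) step
#'
#' First-order Euler update
#' \eqn{x \leftarrow x + \beta D F \Delta t + \sqrt{2 D \Delta t}\,R} with
#' \eqn{R} standard normal per coordinate. The bead currently held fixed
#' under translation is not moved. This is the reference single-step
#' operation; [run_trajectory()] runs the equivalent compiled loop with its
#' own deterministic random stream.
#'
#' @param state a [sim_state()].
#' @param step_forces force matrix from [forces()]; recomputed if `NULL`.
#' @param noise optional n-by-3 matrix of standard-normal draws (mainly for
#'   tests); drawn with [stats::rnorm()] if `NULL`.
#' @return The updated `sim_state`.
#' @export
langevin_step <- function(state, step_forces = NULL, noise = NULL) {
  if (is.null(step_forces)) step_forces <- forces(state)
  n <- nrow(state$beads)
  mobile_end <- state$n_placed - as.integer(state$translating)
  if (mobile_end < 1) {
    state$time_s <- state$time_s + state$constants$dt_s
    return(state)
  }
  if (is.null(noise)) noise <- matrix(rnorm(3 * n), n, 3)
  D <- d_sigma2(state$constants)
  dt <- state$constants$dt_s
  idx <- seq_len(mobile_end)
  disp <- D * dt * step_forces[idx, , drop = FALSE] +
    sqrt(2 * D * dt) * noise[idx, , drop = FALSE]
  if (!all(is.finite(disp))) abort("non-finite displacement in Langevin step")
  state$positions[idx, ] <- state$positions[idx, ] + disp
  state$time_s <- state$time_s + dt
  state
}

#' Free energy of opening the lateral gate
#'
#' \eqn{\Delta G_{open} = \Delta G_{empty} + U(x_n, x_c^{open}) -
#' U(x_n, x_c^{closed})}: the empty-channel opening penalty (3
#' \eqn{\epsilon}) plus the difference in nascent-chain-channel interaction
#' energy between the two gate conformations. Only terms involving the
#' nascent chain contribute; the fixed-bead self-energy difference is
#' absorbed into \eqn{\Delta G_{empty}}.
#'
#' @param state a [sim_state()].
#' @return energy in \eqn{\epsilon}.
#' @export
delta_g_open <- function(state) {
  a <- .state_args(state)
  cg_delta_g_open(a$pos, a$g, a$q, a$lo, a$lc, a$geom, a$pars)
}

#' Attempt a stochastic lateral-gate switch
#'
#' Glauber-form switching probabilities per attempt (one attempt per
#' timestep):
#' \deqn{p_{open} = \frac{\Delta t}{\tau_{LG}}
#'   \frac{e^{-\beta\Delta G_{open}}}{1 + e^{-\beta\Delta G_{open}}}, \qquad
#'   p_{close} = \frac{\Delta t}{\tau_{LG}}
#'   \frac{1}{1 + e^{-\beta\Delta G_{open}}},}
#' which satisfy detailed balance
#' (\eqn{p_{open}/p_{close} = e^{-\beta\Delta G_{open}}}). On acceptance all
#' channel beads switch conformation instantaneously.
#'
#' @param state a [sim_state()].
#' @param u optional uniform variate in \[0,1\] (for tests); drawn with
#'   [stats::runif()] if `NULL`.
#' @return The updated `sim_state`, with attributes `p_switch` (probability
#'   of the attempted switch) and `delta_g` attached.
#' @export
attempt_gating <- function(state, u = NULL) {
  dt <- state$constants$dt_s
  tau <- state$constants$tau_LG_s
  if (dt / tau > 1) abort("dt/tau_LG must be <= 1 for valid probabilities")
  dg <- delta_g_open(state)
  e <- exp(-dg)
  p <- if (state$gate == "closed") (dt / tau) * e / (1 + e)
       else (dt / tau) / (1 + e)
  if (is.null(u)) u <- runif(1)
  if (u < p) {
    state$gate <- if (state$gate == "closed") "open" else "closed"
  }
  attr(state, "p_switch") <- p
  attr(state, "delta_g") <- dg
  state
}

#' Advance ribosomal translation by one timestep
#'
#' During its translation window the C-terminal bead is held fixed and
#' advanced along +z by \eqn{\sigma\Delta t/t_{trans}} per step; after a
#' full period \eqn{t_{trans}} it is released to Langevin dynamics and the
#' next bead of the sequence appears at the insertion point. Interactions
#' of the fixed bead with all other beads are included throughout.
#'
#' @param state a [sim_state()].
#' @param t_trans per-bead translation time in s (default from the state's
#'   constants: 0.6 s, i.e. 5 residues/s at 3 residues per bead).
#' @return The updated `sim_state`.
#' @export
translation_step <- function(state, t_trans = state$constants$t_trans_s) {
  if (!state$translating) return(state)
  dt <- state$constants$dt_s
  tb <- state$n_placed
  state$positions[tb, 3] <- state$positions[tb, 3] + dt / t_trans
  state$progress <- state$progress + dt
  if (state$progress >= t_trans - 0.5 * dt) {
    if (state$n_placed < nrow(state$beads)) {
      state$n_placed <- state$n_placed + 1L
      state$positions[state$n_placed, ] <- state$geom$insertion_point
      state$progress <- 0
    } else {
      state$translating <- FALSE
    }
  }
  state
}

#' Run a simulation trajectory
#'
#' Iterates the five-step loop — (i) forces, (ii) Langevin move, (iii)
#' lateral-gate attempt, (iv) ribosomal translation, (v) termination check —
#' in compiled code with a private deterministic random stream, so the same
#' seed always yields the same trajectory.
#'
#' @param state initial [sim_state()].
#' @param seed integer seed for the trajectory's random stream.
#' @param max_time guard on simulated time in seconds; the trajectory stops
#'   with outcome `"none"` when it expires.
#' @param termination `"none"`, `"integration"` (H-segment integration vs
#'   translocation) or `"topology"` (final TMD orientation).
#' @param h_range integer length-2: first and last bead index (1-based) of
#'   the H-segment / TMD used by the termination predicate.
#' @param clearance channel clearance for integration (\eqn{\sigma}, 2).
#' @param slab_margin tolerance added to the slab half-width when testing
#'   membrane spanning (\eqn{\sigma}, 0.25, the switching width).
#' @param topo_clear channel clearance for the topology predicate
#'   (\eqn{\sigma}, 10).
#' @param save_every save a position frame every this many steps (0 = none).
#' @param t_trans per-bead translation time (s); overrides the state's
#'   constants.
#' @param field_grid optional tabulated channel field from
#'   [build_field_grid()]; when supplied, the channel soft-core sums are
#'   trilinearly interpolated instead of summed pairwise (the partially
#'   tabulated potential used for production ensembles).
#' @return A list of class `sec_trajectory`: the final `state`, `outcome`
#'   (`"none"`, `"integration"`, `"translocation"`, `"type1"`, `"type2"`),
#'   `finished` (logical: predicate met before the guard), `steps`, `time_s`,
#'   counters `n_open_steps`, `n_flips`, `n_redraws`, `release_times`, and
#'   (if saved) `frames` (n-by-3-by-T array) with `frame_times`.
#' @export
run_trajectory <- function(state, seed = 1, max_time = 1,
                           termination = c("none", "integration", "topology"),
                           h_range = NULL, clearance = 2, slab_margin = 0.25,
                           topo_clear = 10, save_every = 0,
                           t_trans = state$constants$t_trans_s,
                           field_grid = NULL) {
  termination <- match.arg(termination)
  mode <- match(termination, c("none", "integration", "topology")) - 1L
  if (mode > 0 && (is.null(h_range) || length(h_range) != 2)) {
    abort("termination predicate needs h_range = c(first, last) bead indices")
  }
  if (is.null(h_range)) h_range <- c(1, 1)
  constants <- state$constants
  constants$t_trans_s <- t_trans
  a <- list(pos = state$positions, g = state$beads$g, q = state$beads$q,
            lo = state$beads$lambda_open, lc = state$beads$lambda_closed,
            gate = as.integer(state$gate == "open"),
            geom = .geom_matrices(state$geom),
            pars = .pars_list(constants, state$table))
  max_steps <- ceiling(max_time / constants$dt_s)
  res <- cg_run_trajectory(
    a$pos, a$g, a$q, a$lo, a$lc, a$gate,
    as.integer(state$n_placed), state$translating, state$progress,
    a$geom, a$pars, as.numeric(seed), as.numeric(max_steps), mode,
    as.integer(h_range[1] - 1), as.integer(h_range[2] - 1),
    clearance, slab_margin, topo_clear, as.numeric(save_every), field_grid
  )
  out_state <- state
  out_state$positions <- res$positions
  out_state$n_placed <- res$n_placed
  out_state$translating <- res$translating
  out_state$progress <- res$progress
  out_state$gate <- if (res$gate == 1) "open" else "closed"
  out_state$time_s <- state$time_s + res$time_s
  outcome <- c("none", "integration", "translocation", "type1", "type2")[
    res$outcome + 1]
  traj <- list(state = out_state, outcome = outcome,
               finished = res$finished, steps = res$steps,
               time_s = res$time_s, n_open_steps = res$n_open_steps,
               n_flips = res$n_flips, n_redraws = res$n_redraws,
               release_times = res$release_times, seed = seed)
  if (!is.null(res$frames)) {
    traj$frames <- aperm(res$frames, c(2, 1, 3))
    traj$frame_times <- res$frame_times
  }
  class(traj) <- "sec_trajectory"
  traj
}

#' @export
print.sec_trajectory <- function(x, ...) {
  cat("<sec_trajectory>", format(x$steps, big.mark = ",", scientific = FALSE), "steps,",
      signif(x$time_s, 4), "s simulated; outcome:", x$outcome, "\n")
  invisible(x)
}

#' Tabulate the channel interaction fields on a 3D grid
#'
#' Precomputes the three channel soft-core sums (attractive bounding sum,
#' repulsive bounding sum, exterior sum) for both gate conformations on a
#' regular Cartesian grid covering the channel plus all interaction
#' cutoffs. [run_trajectory()] interpolates these fields trilinearly
#' instead of summing over channel beads each step, which makes ensemble
#' runs several-fold faster at an interpolation accuracy set by `spacing`.
#' Electrostatics, ribosome beads, the repulsive sphere and all
#' nascent-chain pair terms are always evaluated directly.
#'
#' @param geom a [sec_geometry()].
#' @param spacing grid spacing in \eqn{\sigma} (default 0.1).
#' @param padding margin added beyond the channel extent plus the largest
#'   soft-core cutoff (\eqn{\sigma}).
#' @param constants,table model parameters.
#' @return An opaque list consumed by [run_trajectory()].
#' @export
build_field_grid <- function(geom, spacing = 0.1, padding = 0.5,
                             constants = sec_constants(),
                             table = softcore_table(constants)) {
  gm <- .geom_matrices(geom)
  pars <- .pars_list(constants, table)
  cut <- max(pars$sc[, "r_cr"] * pars$sc[, "sigma_j"])
  ext <- rbind(gm$ch_closed, gm$ch_open, gm$ribo)
  lower <- apply(ext, 2, min) - cut - padding
  upper <- apply(ext, 2, max) + cut + padding
  cg_build_field_grid(gm, pars, spacing, lower, upper)
}
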