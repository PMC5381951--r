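#' Bonded, excluded-volume and electrostatic pair potentials
#'
#' Pairwise interaction terms of the coarse-grained potential, in model
#' units (\eqn{\epsilon}, \eqn{\sigma}):
#' * `fene()` — finite-extension nonlinear elastic bond,
#'   \eqn{-\tfrac12 K_0 R_0^2 \ln(1 - r^2/R_0^2)}, with
#'   \eqn{K_0 = 5.833\,\epsilon/\sigma^2}, \eqn{R_0 = 2\sigma}.
#' * `excluded_volume()` — purely repulsive (WCA-truncated) Lennard-Jones,
#'   zero beyond \eqn{2^{1/6}\sigma}.
#' * `debye_huckel()` — screened electrostatics
#'   \eqn{l_B q_i q_j e^{-r/\kappa}/r} with \eqn{l_B = \kappa = \sigma}.
#'
#' @param r centre-to-centre distance(s) in \eqn{\sigma}.
#' @param q_i,q_j bead charges.
#' @param constants constants list from [sec_constants()].
#' @return energy in \eqn{\epsilon}.
#' @examples
#' fene(1)                      # 3.356 eps
#' excluded_volume(1)           # 1 eps
#' debye_huckel(1, 1, 1)        # exp(-1) eps
#' @export
fene <- function(r, constants = sec_constants()) {
  R0 <- constants$R0
  if (any(r < 0) || any(r >= R0)) {
    abort(sprintf("bond overstretched: FENE is defined for 0 <= r < R0 = %g", R0))
  }
  -0.5 * constants$K0 * R0^2 * log(1 - r^2 / R0^2)
}

#' @rdname fene
#' @export
excluded_volume <- function(r, constants = sec_constants()) {
  stopifnot(all(r > 0))
  sr6 <- 1 / r^6
  ifelse(r < 2^(1 / 6), 4 * (sr6^2 - sr6) + 1, 0)
}

#' @rdname fene
#' @export
debye_huckel <- function(q_i, q_j, r, constants = sec_constants()) {
  if (any(r <= 0)) abort("Debye-Huckel potential requires r > 0")
  constants$l_B * q_i * q_j * exp(-r / constants$kappa) / r
}

#' Implicit-solvent (membrane partitioning) energy of a bead
#'
#' \eqn{g_i \, S_{mem}(x_i)}: the bead's water-membrane transfer free energy
#' scaled by the membrane characteristic function at its position.
#'
#' @param g bead transfer free energy in \eqn{\epsilon}.
#' @param position length-3 numeric or n-by-3 matrix, \eqn{\sigma}.
#' @param membrane membrane parameter list (see [sec_geometry()]).
#' @return energy in \eqn{\epsilon}.
#' @export
solvation <- function(g, position,
                      membrane = list(radius = 1.5, half_width = 2,
                                      switch_width = 0.25)) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  g * membrane_indicator(pos, membrane = membrane)
}

#' Soft-core Lennard-Jones channel interaction
#'
#' The capped soft-core form used for all nascent-chain-translocon
#' interactions:
#' \deqn{U(r) = 4\epsilon_{int}\left[(\alpha + (r/\sigma_j)^6)^{-2} -
#'   (\alpha + (r/\sigma_j)^6)^{-1}\right] - \epsilon_{cr}}
#' for \eqn{r < r_{cr}\sigma_j}, and 0 beyond. The shape parameter
#' \eqn{\alpha} caps the value at zero separation (here at 100
#' \eqn{\epsilon}), keeping energies finite through instantaneous gate
#' switches; the shift \eqn{\epsilon_{cr}} makes the potential continuous at
#' the cutoff.
#'
#' @param r distance(s) in \eqn{\sigma}.
#' @param params a one-row data frame or list with `eps_int`, `eps_cr`,
#'   `r_cr` (in units of `sigma_j`), `alpha`, `sigma_j` — one row of
#'   [softcore_table()].
#' @param shifted if `FALSE`, return the unshifted potential with no cutoff
#'   (used to evaluate the cutoff value itself).
#' @return energy in \eqn{\epsilon}.
#' @examples
#' row <- dplyr::filter(softcore_table(), potential == "ULLLopen")
#' softcore(2.5, row)      # 0 at the cutoff
#' @export
softcore <- function(r, params, shifted = TRUE) {
  stopifnot(all(r >= 0))
  t <- params$alpha + (r / params$sigma_j)^6
  u <- 4 * params$eps_int * (1 / t^2 - 1 / t)
  if (!shifted) return(u)
  ifelse(r < params$r_cr * params$sigma_j, u - params$eps_cr, 0)
}

#' Soft-core shape parameter from the energy cap
#'
#' Solves \eqn{4\epsilon_{int}(1/\alpha^2 - 1/\alpha) = cap} for the unique
#' root \eqn{\alpha \in (0, 1)}; this makes the unshifted potential equal
#' `cap` at zero separation. Closed form via the quadratic in
#' \eqn{1/\alpha}.
#'
#' @param eps_int interaction energy in \eqn{\epsilon} (> 0).
#' @param cap energy cap in \eqn{\epsilon} (default 100).
#' @return \eqn{\alpha \in (0, 1)}.
#' @examples
#' alpha_from_cap(9.85)   # 0.461
#' alpha_from_cap(0.46)   # 0.127
#' @export
alpha_from_cap <- function(eps_int, cap = 100) {
  if (any(eps_int <= 0)) abort("eps_int must be positive")
  u <- (1 + sqrt(1 + cap / eps_int)) / 2
  alpha <- 1 / u
  if (any(alpha <= 0 | alpha >= 1)) abort("no root in (0, 1)")
  alpha
}

#' Cutoff shift of a soft-core potential
#'
#' The unshifted soft-core value at the right cutoff radius
#' \eqn{r = r_{cr}\sigma_j}; subtracting it makes the truncated potential
#' continuous (zero) at the cutoff. For the purely repulsive rows the cutoff
#' sits at the potential minimum \eqn{(2-\alpha)^{1/6}\sigma_j}, where the
#' unshifted value is exactly \eqn{-\epsilon_{int}}.
#'
#' @param eps_int,alpha,r_cr soft-core parameters (`r_cr` in `sigma_j`
#'   units).
#' @return energy in \eqn{\epsilon}.
#' @examples
#' eps_cr_from_params(0.46, alpha_from_cap(0.46), 2.5)   # ~ -0.008
#' @export
eps_cr_from_params <- function(eps_int, alpha, r_cr) {
  t <- alpha + r_cr^6
  4 * eps_int * (1 / t^2 - 1 / t)
}

#' Channel-interaction parameter table
#'
#' The nine soft-core parameter sets defining nascent-chain-translocon
#' interactions: attractive/repulsive bounding potentials (`ULLL*`/`UDDD*`)
#' for each gate state and channel bead class (`normal`/`confined`), and the
#' bead-type-independent channel-exterior interaction `U_out`. The free
#' parameters per row are `eps_int`, `r_cr` and `sigma_j`; `alpha` is
#' derived from the 100 \eqn{\epsilon} zero-separation cap
#' ([alpha_from_cap()]) and `eps_cr` from [eps_cr_from_params()]. For the
#' purely repulsive confined rows the cutoff is the potential minimum,
#' \eqn{(2-\alpha)^{1/6}}, making them WCA-style repulsions of height
#' \eqn{\epsilon_{int}}.
#'
#' @param constants constants list from [sec_constants()] (supplies the
#'   energy cap).
#' @return A tibble with columns `potential`, `base` ("LLL", "DDD", "out"),
#'   `gate` ("open", "closed", NA), `confined`, `eps_int`, `eps_cr`, `r_cr`,
#'   `alpha`, `sigma_j`.
#' @export
softcore_table <- function(constants = sec_constants()) {
  tbl <- tibble(
    potential = c("ULLLopen", "ULLLclosed", "UDDDopen", "UDDDclosed",
                  "ULLLopen-confined", "ULLLclosed-confined",
                  "UDDDopen-confined", "UDDDclosed-confined", "Uout"),
    base = c("LLL", "LLL", "DDD", "DDD", "LLL", "LLL", "DDD", "DDD", "out"),
    gate = c("open", "closed", "open", "closed",
             "open", "closed", "open", "closed", NA),
    confined = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    eps_int = c(0.46, 0.30, 0.30, 0.30, 1.38, 1.41, 9.85, 0.51, 0.50),
    sigma_j = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.2, 1.2, 1.0)
  )
  tbl$alpha <- alpha_from_cap(tbl$eps_int, constants$energy_cap)
  # repulsive confined rows cut off at the soft-core minimum
  repulsive <- tbl$potential %in% c("UDDDopen-confined", "UDDDclosed-confined")
  tbl$r_cr <- ifelse(repulsive, (2 - tbl$alpha)^(1 / 6), 2.5)
  tbl$eps_cr <- eps_cr_from_params(tbl$eps_int, tbl$alpha, tbl$r_cr)
  tbl[, c("potential", "base", "gate", "confined", "eps_int", "eps_cr",
          "r_cr", "alpha", "sigma_j")]
}

# parameter list handed to the C++ kernels; sc matrix row order is
# LLLopen, LLLclosed, DDDopen, DDDclosed, then the confined variants in the
# same order, then Uout, then the ribosome-bead repulsion
.pars_list <- function(constants = sec_constants(),
                       table = softcore_table(constants)) {
  ord <- c("ULLLopen", "ULLLclosed", "UDDDopen", "UDDDclosed",
           "ULLLopen-confined", "ULLLclosed-confined",
           "UDDDopen-confined", "UDDDclosed-confined", "Uout")
  tab <- table[match(ord, table$potential), ]
  ribo_alpha <- alpha_from_cap(1, constants$energy_cap)
  ribo <- c(1, ribo_alpha, -1, (2 - ribo_alpha)^(1 / 6), 1.2)
  sc <- rbind(
    cbind(tab$eps_int, tab$alpha, tab$eps_cr, tab$r_cr, tab$sigma_j),
    ribo
  )
  colnames(sc) <- c("eps_int", "alpha", "eps_cr", "r_cr", "sigma_j")
  rownames(sc) <- NULL
  list(sc = sc,
       K0 = constants$K0, R0 = constants$R0,
       elec_cutoff = constants$elec_cutoff,
       dG_empty = constants$dG_empty,
       D = d_sigma2(constants), dt = constants$dt_s,
       tau_LG = constants$tau_LG_s, t_trans = constants$t_trans_s)
}

#' Channel interaction energy of one nascent-chain bead
#'
#' Evaluates the bead-translocon interaction: inside the aqueous channel the
#' bead's hydrophobicity coefficient \eqn{\lambda} mixes the attractive
#' (`ULLL`) and repulsive (`UDDD`) bounding potentials for the current gate
#' state and per-channel-bead class; in the membrane near the channel
#' exterior the bead-type-independent `U_out` applies. The two regimes are
#' blended by the membrane characteristic function:
#' \deqn{U = [1 - S_{mem}]\sum_j [\lambda U_{LLL} + (1-\lambda) U_{DDD}](r_{ij})
#'   + S_{mem}\sum_j U_{out}(r_{ij}).}
#'
#' @param bead one-row bead tibble (needs `g`, or explicit `lambda_open`/
#'   `lambda_closed`).
#' @param position length-3 numeric or n-by-3 matrix (\eqn{\sigma}).
#' @param gate `"open"` or `"closed"`.
#' @param geom a [sec_geometry()].
#' @param table parameter table from [softcore_table()].
#' @param constants constants list.
#' @return energy in \eqn{\epsilon} (vector over positions).
#' @export
channel_interaction <- function(bead, position, gate, geom,
                                table = softcore_table(constants),
                                constants = sec_constants()) {
  gate <- match.arg(gate, c("closed", "open"))
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  lam <- if (gate == "open") bead$lambda_open else bead$lambda_closed
  gm <- .geom_matrices(geom)
  ch <- if (gate == "open") gm$ch_open else gm$ch_closed
  S <- membrane_indicator(pos, membrane = geom$membrane)
  row_of <- function(base, conf) {
    nm <- if (base == "out") "Uout" else {
      paste0("U", base, gate, if (conf) "-confined" else "")
    }
    table[table$potential == nm, ]
  }
  vapply(seq_len(nrow(pos)), function(i) {
    d <- sqrt(colSums((t(ch) - pos[i, ])^2))
    conf <- gm$ch_conf == 1L
    aq <- sum(lam * softcore(d[!conf], row_of("LLL", FALSE)) +
                (1 - lam) * softcore(d[!conf], row_of("DDD", FALSE))) +
      sum(lam * softcore(d[conf], row_of("LLL", TRUE)) +
            (1 - lam) * softcore(d[conf], row_of("DDD", TRUE)))
    mem <- sum(softcore(d, row_of("out", FALSE)))
    (1 - S[i]) * aq + S[i] * mem
  }, numeric(1))
}

#' Ribosome repulsion energy at a position
#'
#' Sum of (i) the repulsive sphere standing in for the non-explicit ribosome
#' body — a WCA repulsion in the shifted distance \eqn{r_{ir} - 2\sigma}
#' from the sphere centre — and (ii) capped soft-core repulsions from the
#' explicit ribosome beads (\eqn{\epsilon_{int} = \epsilon},
#' \eqn{\sigma_j = 1.2\sigma}).
#'
#' @param position length-3 numeric or n-by-3 matrix (\eqn{\sigma}).
#' @param geom a [sec_geometry()].
#' @param constants constants list.
#' @return energy in \eqn{\epsilon} (vector over positions).
#' @export
ribosome_repulsion <- function(position, geom, constants = sec_constants()) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  gm <- .geom_matrices(geom)
  ribo_alpha <- alpha_from_cap(1, constants$energy_cap)
  ribo_row <- list(eps_int = 1, alpha = ribo_alpha, eps_cr = -1,
                   r_cr = (2 - ribo_alpha)^(1 / 6), sigma_j = 1.2)
  vapply(seq_len(nrow(pos)), function(i) {
    u <- 0
    if (geom$sphere_enabled) {
      s <- sqrt(sum((pos[i, ] - gm$sphere)^2)) - 2
      if (s < 2^(1 / 6)) {
        if (s <= 0) {
          u <- u + constants$energy_cap  # capped inside the hard offset
        } else {
          sr6 <- 1 / s^6
          u <- u + 4 * (sr6^2 - sr6) + 1
        }
      }
    }
    if (nrow(gm$ribo)) {
      d <- sqrt(colSums((t(gm$ribo) - pos[i, ])^2))
      u <- u + sum(softcore(d, ribo_row))
    }
    u
  }, numeric(1))
}

#' Total potential energy of a simulation state
#'
#' Sums the six terms of the coarse-grained potential — FENE bonds, excluded
#' volume, Debye-Huckel electrostatics, implicit-solvent transfer, channel
#' interactions and ribosome repulsion — over all pairs that involve at
#' least one nascent-chain bead. Interactions among fixed beads
#' (channel-channel, ribosome-ribosome, channel-ribosome) are excluded:
#' their conformation-dependent self-energy is absorbed into the empty-
#' channel gating penalty \eqn{\Delta G_{empty}}.
#'
#' @param state a [sim_state()].
#' @param by_term if `TRUE`, return the named per-term breakdown instead of
#'   the total.
#' @return energy in \eqn{\epsilon}.
#' @export
total_energy <- function(state, by_term = FALSE) {
  terms <- cg_energy(
    state$positions, state$beads$g, state$beads$q,
    state$beads$lambda_open, state$beads$lambda_closed,
    as.integer(state$gate == "open"),
    .geom_matrices(state$geom),
    .pars_list(state$constants, state$table)
  )
  if (by_term) unlist(terms) else sum(unlist(terms))
}
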