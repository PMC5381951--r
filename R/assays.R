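#' Toy test constructs for the integration and topology assays
#'
#' `h_segment_construct()` builds a minimal stop-transfer construct in the
#' spirit of the leader-peptidase (Lep) H-segment assay: a pre-insertable
#' hydrophobic TMD, a polar linker, a 19-residue H-segment containing
#' `n_leu` leucines (evenly spaced) with the remaining positions alanine,
#' and a short polar C-tail. `signal_anchor_construct()` builds a
#' signal-anchor construct for the topogenesis assay: a polar N-domain, a
#' hydrophobic TMD, and a polar C-terminal loop of `loop_res` residues.
#'
#' @param n_leu number of leucines in the 19-residue H-segment (0-7).
#' @param tmd_res,linker_res,tail_res,ndom_res,loop_res lengths (residues)
#'   of the flanking elements.
#' @return A list with `aa`, `ss` (strings) and `h_range` / `tmd_range`
#'   (residue index range of the probed segment).
#' @examples
#' h_segment_construct(3)$aa
#' @export
h_segment_construct <- function(n_leu, anchor_res = 3, tmd_res = 12,
                                linker_res = 30, tail_res = 6) {
  stopifnot(n_leu >= 0, n_leu <= 19)
  h <- rep("A", 19)
  if (n_leu > 0) {
    pos <- round(seq(1, 19, length.out = n_leu + 2))[2:(n_leu + 1)]
    h[pos] <- "L"
  }
  anchor <- substr(strrep("SG", anchor_res), 1, anchor_res)
  tmd <- strrep("L", tmd_res)
  # near-neutral hydrophobicity linker: translocates without dragging the
  # chain luminally before the H-segment can partition
  linker <- substr(strrep("CA", linker_res), 1, linker_res)
  tail <- substr(strrep("SG", tail_res), 1, tail_res)
  aa <- paste0(anchor, tmd, linker, paste(h, collapse = ""), tail)
  # the short polar anchor stays cytosolic at the TMD's N-terminal end;
  # the translocating linker (the lumenal domain the H-segment is embedded
  # in) is structured (hydrogen-bonded); the coil C-tail is strongly polar
  # and stays cytosolic
  ss <- paste0(strrep("C", anchor_res), strrep("H", tmd_res),
               strrep("H", linker_res), strrep("H", 19),
               strrep("C", tail_res))
  h0 <- anchor_res + tmd_res + linker_res
  list(aa = aa, ss = ss, h_range = c(h0 + 1, h0 + 19),
       tmd_range = c(anchor_res + 1, anchor_res + tmd_res))
}

#' @rdname h_segment_construct
#' @export
signal_anchor_construct <- function(loop_res, ndom_res = 12, tmd_res = 18) {
  ndom <- substr(strrep("SG", ndom_res), 1, ndom_res)
  loop <- substr(strrep("SG", loop_res), 1, loop_res)
  aa <- paste0(ndom, strrep("L", tmd_res), loop)
  # both soluble domains structured so either terminus can translocate
  ss <- strrep("H", ndom_res + tmd_res + loop_res)
  list(aa = aa, ss = ss, tmd_range = c(ndom_res + 1, ndom_res + tmd_res))
}

# beads whose residue span overlaps a residue range
.bead_range <- function(beads, res_range) {
  hit <- which(beads$res_end >= res_range[1] & beads$res_start <= res_range[2])
  c(min(hit), max(hit))
}

#' Initial state for the H-segment integration assay
#'
#' Reconstructs the co-translational stop-transfer intermediate: the
#' upstream TMD sits pre-inserted in the membrane at a lateral offset on
#' the lateral-gate side of the channel, oriented with its C-terminal end
#' lumenal; the downstream linker (the translocating lumenal domain) is
#' threaded under the channel, up through the pore and back to the
#' translation insertion point; the next bead of the sequence is staged at
#' the insertion point under translation. The placement is deterministic.
#'
#' @param beads full-sequence bead tibble from [map_sequence()].
#' @param geom a [sec_geometry()].
#' @param tmd_range integer length-2: bead index range of the pre-inserted
#'   TMD.
#' @param offset lateral distance of the TMD from the channel axis
#'   (\eqn{\sigma}), on the +y (lateral-gate) side.
#' @param constants,table model parameters.
#' @return A [sim_state()] with `translating = TRUE`.
#' @export
init_integration_assay <- function(beads, geom, tmd_range, offset = 2.5,
                                   constants = sec_constants(),
                                   table = softcore_table(constants)) {
  n <- nrow(beads)
  stopifnot(tmd_range[1] >= 1, tmd_range[2] <= n)
  pos <- matrix(NA_real_, n, 3)
  k <- tmd_range[2] - tmd_range[1] + 1
  # TMD spans N-cytosolic / C-lumenal, as after signal-anchor insertion
  zs <- seq(1.8, -1.8, length.out = max(k, 2))[seq_len(k)]
  pos[tmd_range[1]:tmd_range[2], ] <- cbind(0, offset, zs)
  # beads before the TMD stay on the cytosolic side above it
  if (tmd_range[1] > 1) {
    pre <- seq_len(tmd_range[1] - 1)
    pos[rev(pre), ] <- cbind(0, offset, max(zs) + 0.95 * seq_along(pre))
  }
  # beads after the TMD are mid-translocation: under the channel, up
  # through the pore, and back to the insertion point
  ins <- geom$insertion_point
  bot <- pos[tmd_range[2], ]
  verts <- rbind(bot,
                 c(0, 0.55 * offset, -2.9),
                 c(0, 0, -2.7),
                 c(0, 0, 2.6),
                 ins)
  avail <- n - tmd_range[2] - 1
  if (avail < 3) abort("construct too short to thread through the channel")
  seg <- diff(verts)
  total <- sum(sqrt(rowSums(seg^2)))
  m <- min(max(3, round(total / 0.95)), avail)
  path <- .polyline_points(verts, total / (m + 1))
  m <- nrow(path)
  post <- tmd_range[2] + seq_len(m)
  for (i in seq_along(post)) pos[post[i], ] <- path[i, ]
  n_placed <- max(post)
  translating <- n_placed < n
  if (translating) {
    n_placed <- n_placed + 1
    pos[n_placed, ] <- ins
  }
  sim_state(beads, geom, positions = pos, gate = "closed",
            translating = translating,
            constants = constants, table = table)
}

# points spaced ~`by` along a polyline from the first vertex (exclusive)
# to the last (the caller appends the endpoint separately)
.polyline_points <- function(verts, by) {
  seg <- diff(verts)
  lens <- sqrt(rowSums(seg^2))
  total <- sum(lens)
  m <- max(1, round(total / by) - 1)
  d <- seq_len(m) * total / (m + 1)
  t(vapply(d, function(s) {
    acc <- c(0, cumsum(lens))
    i <- max(which(acc <= s + 1e-12))
    i <- min(i, nrow(seg))
    f <- (s - acc[i]) / lens[i]
    verts[i, ] + f * seg[i, ]
  }, numeric(3)))
}

#' Initial state for the topogenesis assay
#'
#' Places the first four beads on the cytosolic side between the insertion
#' point and the channel mouth (not yet inside the translocon) and stages
#' the fifth bead at the insertion point under translation. Deterministic.
#'
#' @inheritParams init_integration_assay
#' @return A [sim_state()].
#' @export
init_topology_assay <- function(beads, geom,
                                constants = sec_constants(),
                                table = softcore_table(constants)) {
  n <- nrow(beads)
  if (n < 5) abort("topology assay needs at least 5 beads")
  pos <- matrix(NA_real_, n, 3)
  ins <- geom$insertion_point
  way <- rbind(c(0, 3.6, 3.6), c(0, 2.7, 3.1), c(0, 1.8, 2.9),
               c(0, 0.9, 3.1))
  for (i in 1:4) pos[i, ] <- way[i, ]
  pos[5, ] <- ins
  sim_state(beads, geom, positions = pos, gate = "closed",
            translating = TRUE, constants = constants, table = table)
}

#' Classify the outcome of an integration-assay state
#'
#' Integration: every H-segment bead is at least `clearance` (2
#' \eqn{\sigma}) from every channel bead, all H-segment beads lie within
#' the membrane slab (|z| within the half-width plus `slab_margin`), and
#' the beads flanking the H-segment sit on opposite sides of the membrane
#' midplane (the segment spans the membrane). Translocation: every
#' H-segment bead has crossed to the lumenal side (z below the slab).
#' Otherwise the trajectory continues (`"none"`).
#'
#' @param state a [sim_state()].
#' @param h_range bead index range of the H-segment.
#' @param clearance,slab_margin thresholds in \eqn{\sigma}.
#' @return `"integration"`, `"translocation"` or `"none"`.
#' @export
classify_integration <- function(state, h_range, clearance = 2,
                                 slab_margin = 0.25) {
  H <- state$geom$membrane$half_width
  hb <- h_range[1]:h_range[2]
  mobile_end <- state$n_placed - as.integer(state$translating)
  if (h_range[2] > mobile_end) return("none")
  z <- state$positions[hb, 3]
  if (all(z < -(H + slab_margin))) return("translocation")
  if (any(abs(z) > H + slab_margin)) return("none")
  before <- h_range[1] - 1
  after <- h_range[2] + 1
  if (before >= 1 && after <= state$n_placed) {
    if (state$positions[before, 3] * state$positions[after, 3] >= 0) {
      return("none")
    }
  }
  gm <- .geom_matrices(state$geom)
  ch <- if (state$gate == "open") gm$ch_open else gm$ch_closed
  for (i in hb) {
    d2 <- colSums((t(ch) - state$positions[i, ])^2)
    if (min(d2) < clearance^2) return("none")
  }
  "integration"
}

#' Classify the outcome of a topogenesis-assay state
#'
#' When the TMD spans the membrane slab and every TMD bead is at least
#' `topo_clear` (10 \eqn{\sigma}) from every channel bead, the topology is
#' read off the C-terminal bead: lumenal (z below the slab) is Type 2
#' (N-cytosolic/C-lumenal), cytosolic is Type 1. Otherwise `"none"`.
#'
#' @param state a [sim_state()].
#' @param tmd_range bead index range of the TMD.
#' @param topo_clear clearance threshold in \eqn{\sigma}.
#' @param slab_margin slab tolerance in \eqn{\sigma}.
#' @return `"type1"`, `"type2"` or `"none"`.
#' @export
classify_topology <- function(state, tmd_range, topo_clear = 10,
                              slab_margin = 0.25) {
  if (state$translating || state$n_placed < nrow(state$beads)) return("none")
  H <- state$geom$membrane$half_width
  tb <- tmd_range[1]:tmd_range[2]
  z <- state$positions[tb, 3]
  if (any(abs(z) > H + slab_margin)) return("none")
  gm <- .geom_matrices(state$geom)
  ch <- if (state$gate == "open") gm$ch_open else gm$ch_closed
  for (i in tb) {
    d2 <- colSums((t(ch) - state$positions[i, ])^2)
    if (min(d2) < topo_clear^2) return("none")
  }
  zc <- state$positions[nrow(state$beads), 3]
  if (zc < -H) return("type2")
  if (zc > H) return("type1")
  "none"
}

#' H-segment membrane integration probability
#'
#' Runs an ensemble of co-translational trajectories for each of the three
#' frameshifted bead representations of the sequence and reports the
#' fraction terminating by H-segment integration. The reported probability
#' is the mean of the three per-frame fractions (frames are equally
#' plausible representations, not poolable counts); the standard error is
#' binomial.
#'
#' @param aa,ss sequence and secondary structure strings.
#' @param h_range_res residue index range of the H-segment.
#' @param tmd_range_res residue range of the pre-inserted upstream TMD.
#' @param geom a [sec_geometry()].
#' @param n_traj trajectories per frame.
#' @param t_trans per-bead translation time (s).
#' @param max_time simulated-time guard per trajectory (s).
#' @param seed base seed; trajectory seeds are derived deterministically.
#' @param frames which frameshifts to run (default all three).
#' @param constants,table model parameters.
#' @param field_grid tabulated channel field from [build_field_grid()]
#'   (built once per call by default and shared across trajectories).
#' @return A tibble of class `sec_assay` with one row per frame plus an
#'   `"average"` row: columns `frame`, `n`, `n_integration`,
#'   `n_translocation`, `n_none`, `p_integration`, `se`.
#' @export
integration_probability <- function(aa, ss, h_range_res, tmd_range_res,
                                    geom, n_traj = 50,
                                    t_trans = sec_constants()$t_trans_s,
                                    max_time = 60 * t_trans, seed = 1,
                                    frames = 0:2,
                                    constants = sec_constants(),
                                    table = softcore_table(constants),
                                    field_grid = build_field_grid(
                                      geom, constants = constants,
                                      table = table)) {
  per_frame <- purrr::map_dfr(frames, function(f) {
    beads <- map_sequence(aa, ss, frame = f, constants = constants)
    hb <- .bead_range(beads, h_range_res)
    tb <- .bead_range(beads, tmd_range_res)
    init <- init_integration_assay(beads, geom, tb, constants = constants,
                                   table = table)
    outcomes <- vapply(seq_len(n_traj), function(k) {
      traj <- run_trajectory(init, seed = seed * 100000 + f * 10000 + k,
                             max_time = max_time,
                             termination = "integration", h_range = hb,
                             t_trans = t_trans, field_grid = field_grid)
      traj$outcome
    }, character(1))
    tibble(
      frame = as.character(f), n = n_traj,
      n_integration = sum(outcomes == "integration"),
      n_translocation = sum(outcomes == "translocation"),
      n_none = sum(outcomes == "none")
    )
  })
  per_frame$p_integration <- per_frame$n_integration / per_frame$n
  per_frame$se <- sqrt(per_frame$p_integration * (1 - per_frame$p_integration) /
                         per_frame$n)
  avg <- tibble(
    frame = "average", n = sum(per_frame$n),
    n_integration = sum(per_frame$n_integration),
    n_translocation = sum(per_frame$n_translocation),
    n_none = sum(per_frame$n_none),
    p_integration = mean(per_frame$p_integration),
    se = sqrt(sum(per_frame$se^2)) / nrow(per_frame)
  )
  out <- bind_rows(per_frame, avg)
  class(out) <- c("sec_assay", class(out))
  out
}

#' Apparent free energy of integration
#'
#' Two-state conversion of an integration probability,
#' \eqn{\Delta G_{app} = -kT \ln[p / (1 - p)]} with \eqn{kT} at 310 K, in
#' kcal/mol. For degenerate ensembles (p of exactly 0 or 1) a signed
#' infinity is returned; when the ensemble size `n` is supplied, a finite
#' Wilson-interval bound (95\%) is attached as attribute `wilson_bound`.
#'
#' @param p integration probability (vector).
#' @param n optional ensemble size(s) for the Wilson bound.
#' @param constants constants list.
#' @return \eqn{\Delta G_{app}} in kcal/mol.
#' @examples
#' dg_app(0.731)   # about -0.616 kcal/mol (-1 kT)
#' @export
dg_app <- function(p, n = NULL, constants = sec_constants()) {
  stopifnot(all(p >= 0 & p <= 1))
  out <- ifelse(p == 0, Inf,
                ifelse(p == 1, -Inf,
                       -constants$eps_kcal * log(p / (1 - p))))
  if (!is.null(n)) {
    z <- 1.96
    p_ad <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- pmax(p_ad - half, 1e-12)
    hi <- pmin(p_ad + half, 1 - 1e-12)
    bound <- ifelse(p == 0, -constants$eps_kcal * log(hi / (1 - hi)),
                    ifelse(p == 1, -constants$eps_kcal * log(lo / (1 - lo)),
                           NA_real_))
    attr(out, "wilson_bound") <- bound
  }
  out
}

#' Alanine and leucine apparent free energies from a leucine series
#'
#' Least-squares line through \eqn{\Delta G_{app}} versus the number of
#' leucines in a 19-residue H-segment,
#' \eqn{\Delta G_{app} = n_{Leu}(\Delta G^{Leu} - \Delta G^{Ala}) +
#' 19\,\Delta G^{Ala}}: the slope gives the leucine-alanine difference and
#' the intercept, divided by 19, the per-alanine value.
#'
#' @param n_leu numeric vector of leucine counts (at least two distinct).
#' @param dg numeric vector of \eqn{\Delta G_{app}} values (kcal/mol).
#' @return A list with `dg_ala`, `dg_leu` (kcal/mol), `slope`, `intercept`
#'   and the `fit` (an `lm`).
#' @examples
#' n <- 3:7
#' fit_ala_leu(n, n * (-0.43 - 0.13) + 19 * 0.13)
#' @export
fit_ala_leu <- function(n_leu, dg) {
  if (length(unique(n_leu)) < 2) abort("need at least two distinct n_leu values")
  ok <- is.finite(dg)
  fit <- stats::lm(dg[ok] ~ n_leu[ok])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  dg_ala <- intercept / 19
  list(dg_ala = dg_ala, dg_leu = slope + dg_ala,
       slope = slope, intercept = intercept, fit = fit)
}

#' Single-residue apparent free energy by reference substitution
#'
#' \eqn{\Delta G_{app}^{aa} = \Delta G_{app}^{x[aa]x} -
#' \Delta G_{app}^{x[ref]x} + \Delta G_{app}^{ref}}: the construct with the
#' probed residue at the H-segment midpoint, minus the same construct with
#' a reference residue, plus the reference residue's known value.
#'
#' @param dg_aa \eqn{\Delta G_{app}} of the probed construct (kcal/mol).
#' @param dg_ref_construct \eqn{\Delta G_{app}} of the reference construct.
#' @param dg_ref known \eqn{\Delta G_{app}} of the reference residue.
#' @return kcal/mol.
#' @examples
#' dg_app_residue(0.3, 0.5, 0.13)   # -0.07
#' @export
dg_app_residue <- function(dg_aa, dg_ref_construct, dg_ref) {
  stopifnot(is.finite(dg_aa), is.finite(dg_ref_construct), is.finite(dg_ref))
  dg_aa - dg_ref_construct + dg_ref
}

#' TMD topology versus C-terminal loop length and translation rate
#'
#' Runs the topogenesis assay for a family of signal-anchor constructs over
#' the given C-terminal loop lengths and per-bead translation times,
#' reporting the frame-averaged fraction of decided trajectories reaching
#' the Type 2 (C-lumenal) topology.
#'
#' @param loop_lengths C-terminal loop lengths in residues.
#' @param t_trans_values per-bead translation times in s (e.g. fast and
#'   slow translation).
#' @param geom a [sec_geometry()].
#' @param n_traj trajectories per frame.
#' @param max_time simulated-time guard per trajectory in s, applied to
#'   every condition; if `NULL`, scales with construct length and
#'   translation time.
#' @param seed base seed.
#' @param frames frameshifts to run.
#' @param ndom_res,tmd_res construct geometry (residues).
#' @param constants,table model parameters.
#' @param field_grid tabulated channel field from [build_field_grid()].
#' @return A tibble of class `sec_assay`: one row per (loop length,
#'   t_trans, frame) plus `"average"` rows, with counts, `p_type2` among
#'   decided trajectories and binomial `se`.
#' @export
topology_curve <- function(loop_lengths, t_trans_values, geom, n_traj = 50,
                           max_time = NULL, seed = 1, frames = 0:2,
                           ndom_res = 12, tmd_res = 18,
                           constants = sec_constants(),
                           table = softcore_table(constants),
                           field_grid = build_field_grid(
                             geom, constants = constants, table = table)) {
  grid <- expand.grid(loop_res = loop_lengths, t_trans = t_trans_values)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(gidx) {
    loop_res <- grid$loop_res[gidx]
    tt <- grid$t_trans[gidx]
    cons <- signal_anchor_construct(loop_res, ndom_res = ndom_res,
                                    tmd_res = tmd_res)
    guard <- if (is.null(max_time)) {
      (nchar(cons$aa) / 3 + 30) * tt * 2.5
    } else max_time
    per_frame <- purrr::map_dfr(frames, function(f) {
      beads <- map_sequence(cons$aa, cons$ss, frame = f, constants = constants)
      tb <- .bead_range(beads, cons$tmd_range)
      init <- init_topology_assay(beads, geom, constants = constants,
                                  table = table)
      outcomes <- vapply(seq_len(n_traj), function(k) {
        traj <- run_trajectory(
          init,
          seed = seed * 1000000 + loop_res * 10000 + f * 1000 + k +
            round(tt * 1e6) %% 997 * 100000,
          max_time = guard, termination = "topology", h_range = tb,
          t_trans = tt, field_grid = field_grid)
        traj$outcome
      }, character(1))
      n1 <- sum(outcomes == "type1")
      n2 <- sum(outcomes == "type2")
      tibble(loop_res = loop_res, t_trans = tt, frame = as.character(f),
             n = n_traj, n_type1 = n1, n_type2 = n2,
             n_none = sum(outcomes == "none"),
             p_type2 = if (n1 + n2 > 0) n2 / (n1 + n2) else NA_real_)
    })
    per_frame$se <- sqrt(per_frame$p_type2 * (1 - per_frame$p_type2) /
                           pmax(per_frame$n_type1 + per_frame$n_type2, 1))
    avg <- tibble(
      loop_res = loop_res, t_trans = tt, frame = "average",
      n = sum(per_frame$n), n_type1 = sum(per_frame$n_type1),
      n_type2 = sum(per_frame$n_type2), n_none = sum(per_frame$n_none),
      p_type2 = mean(per_frame$p_type2, na.rm = TRUE),
      se = sqrt(sum(per_frame$se^2, na.rm = TRUE)) / nrow(per_frame)
    )
    bind_rows(per_frame, avg)
  })
  class(out) <- c("sec_assay", class(out))
  out
}
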