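# shared fixtures, built once per test file

fixture_geom <- local({
  geom <- NULL
  function() {
    if (is.null(geom)) geom <<- synthetic_channel_fixture()
    geom
  }
})

# a small heterogeneous test state near the channel
toy_state <- function(gate = "open", constants = sec_constants()) {
  beads <- map_sequence("LKDLLQLSAWGT", "HHHCCHHHCCCC", constants = constants)
  pos <- rbind(c(0.3, 0.2, 0.5), c(0.8, 1.0, 1.2), c(0.2, 1.8, 2.0),
               c(1.2, 2.4, 2.8))
  sim_state(beads, fixture_geom(), positions = pos, gate = gate,
            translating = FALSE, constants = constants)
}

# independent naive O(N^2) total-energy oracle built from the R-level
# potential functions (plain loops, no cutoffs on electrostatics)
naive_total_energy <- function(state) {
  beads <- state$beads
  pos <- state$positions
  n <- state$n_placed
  geom <- state$geom
  cons <- state$constants
  tab <- state$table
  gm <- seccg:::.geom_matrices(geom)
  u <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (j == i + 1) u <- u + fene(r, cons)
      u <- u + excluded_volume(r, cons)
      u <- u + debye_huckel(beads$q[i], beads$q[j], r, cons)
    }
    u <- u + solvation(beads$g[i], pos[i, ], geom$membrane)
    u <- u + channel_interaction(beads[i, ], pos[i, ], state$gate, geom,
                                 table = tab, constants = cons)
    u <- u + ribosome_repulsion(pos[i, ], geom, cons)
    # electrostatics with fixed charges
    ch <- if (state$gate == "open") gm$ch_open else gm$ch_closed
    for (j in seq_len(nrow(ch))) {
      if (gm$ch_q[j] == 0 || beads$q[i] == 0) next
      r <- sqrt(sum((pos[i, ] - ch[j, ])^2))
      u <- u + debye_huckel(beads$q[i], gm$ch_q[j], r, cons)
    }
    for (j in seq_len(nrow(gm$ribo))) {
      if (gm$ribo_q[j] == 0 || beads$q[i] == 0) next
      r <- sqrt(sum((pos[i, ] - gm$ribo[j, ])^2))
      u <- u + debye_huckel(beads$q[i], gm$ribo_q[j], r, cons)
    }
  }
  u
}
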