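test_that("toy constructs have the intended architecture", {
  cons <- h_segment_construct(3)
  expect_equal(nchar(cons$aa), nchar(cons$ss))
  h <- substr(cons$aa, cons$h_range[1], cons$h_range[2])
  expect_equal(nchar(h), 19)
  expect_equal(sum(strsplit(h, "")[[1]] == "L"), 3)
  expect_equal(sum(strsplit(h, "")[[1]] == "A"), 16)
  expect_equal(h_segment_construct(0)$h_range, cons$h_range)
  sa <- signal_anchor_construct(12)
  expect_equal(substr(sa$aa, sa$tmd_range[1], sa$tmd_range[2]),
               strrep("L", 18))
})

test_that("assay initial states are valid and deterministic", {
  geom <- fixture_geom()
  cons <- h_segment_construct(5)
  beads <- map_sequence(cons$aa, cons$ss)
  tb <- seccg:::.bead_range(beads, cons$tmd_range)
  init <- init_integration_assay(beads, geom, tb)
  # TMD spans the slab at a lateral offset
  expect_true(all(abs(init$positions[tb[1]:tb[2], 3]) < 2))
  # bonds valid everywhere
  b <- sqrt(rowSums(diff(init$positions[seq_len(init$n_placed), ])^2))
  expect_true(all(b < sec_constants()$R0))
  expect_true(all(b > 0.4))
  expect_true(init$translating)
  # deterministic: identical on repeated construction
  expect_identical(init$positions,
                   init_integration_assay(beads, geom, tb)$positions)
  # finite energy (capped potentials)
  expect_true(is.finite(total_energy(init)))

  ti <- init_topology_assay(beads, geom)
  expect_equal(ti$n_placed, 5L)
  expect_true(all(ti$positions[1:4, 3] > 2))  # cytosolic, outside the slab
  b2 <- sqrt(rowSums(diff(ti$positions[1:5, ])^2))
  expect_true(all(b2 < sec_constants()$R0))
})

test_that("integration classifier implements the spanning criterion", {
  geom <- fixture_geom()
  beads <- map_sequence(strrep("A", 27), strrep("H", 27))  # 9 beads
  h_range <- c(3, 7)
  mk <- function(pos) {
    sim_state(beads, geom, positions = pos, translating = FALSE)
  }
  # membrane-spanning far from the channel, flanks on opposite sides
  span <- cbind(8, 0.3 * (1:9), seq(3.4, -3.4, length.out = 9))
  expect_equal(classify_integration(mk(span), h_range), "integration")
  # all H beads on the lumenal side: translocation
  lum <- cbind(8, 0.3 * (1:9), seq(-3, -7, length.out = 9))
  expect_equal(classify_integration(mk(lum), h_range), "translocation")
  # H-segment still in the pore: neither
  pore <- cbind(0.2, 0.2 * (1:9) - 1, seq(3.4, -3.4, length.out = 9))
  expect_equal(classify_integration(mk(pore), h_range), "none")
  # flanks on the same side: not spanning
  flat <- span
  flat[, 3] <- c(3, 2.5, 1.5, 1, 0.5, -0.5, -1, 2.5, 3)
  expect_equal(classify_integration(mk(flat), h_range), "none")
  # classification is stable under tiny coordinate perturbations
  eps <- matrix(1e-6, 9, 3)
  expect_equal(classify_integration(mk(span + eps), h_range), "integration")
  expect_equal(classify_integration(mk(lum - eps), h_range), "translocation")
})

test_that("topology classifier reads the C-terminal side", {
  geom <- fixture_geom()
  beads <- map_sequence(strrep("A", 27), strrep("H", 27))
  tmd <- c(4, 6)
  base <- cbind(15, 0.3 * (1:9), c(4, 3, 2.5, 1.8, 0, -1.8, -2.5, -3.5, -5))
  st2 <- sim_state(beads, geom, positions = base, translating = FALSE)
  expect_equal(classify_topology(st2, tmd), "type2")
  flipped <- base
  flipped[, 3] <- rev(base[, 3])
  st1 <- sim_state(beads, geom, positions = flipped, translating = FALSE)
  expect_equal(classify_topology(st1, tmd), "type1")
  # within ten sigma of the channel: undecided
  near <- base
  near[, 1] <- 7
  stn <- sim_state(beads, geom, positions = near, translating = FALSE)
  expect_equal(classify_topology(stn, tmd), "none")
  # incomplete translation: undecided
  part <- base
  part[9, ] <- NA
  stp <- sim_state(beads, geom, positions = part, translating = FALSE)
  expect_equal(classify_topology(stp, tmd), "none")
})

test_that("apparent free energy conversion follows the two-state form", {
  kT <- sec_constants()$eps_kcal
  expect_equal(dg_app(0.5), 0)
  expect_equal(dg_app(0.731), -kT * log(0.731 / 0.269), tolerance = 1e-9)
  expect_equal(dg_app(0.731), -0.616, tolerance = 0.01)
  # antisymmetry
  expect_equal(dg_app(0.2), -dg_app(0.8), tolerance = 1e-12)
  # logistic round trip: p -> dG -> p
  p <- c(0.1, 0.35, 0.62, 0.9)
  dg <- dg_app(p)
  expect_equal(1 / (1 + exp(dg / kT)), p, tolerance = 1e-12)
  # degenerate ensembles produce signed infinities with a Wilson bound
  d0 <- dg_app(0, n = 100)
  expect_equal(unclass(d0)[1], Inf)
  expect_true(is.finite(attr(d0, "wilson_bound")[1]))
  d1 <- dg_app(1, n = 100)
  expect_equal(unclass(d1)[1], -Inf)
})

test_that("leucine-series fit inverts the linear construction exactly", {
  dg_ala <- 0.13
  dg_leu <- -0.43
  n <- 3:7
  dg <- n * (dg_leu - dg_ala) + 19 * dg_ala
  fit <- fit_ala_leu(n, dg)
  expect_equal(fit$dg_ala, dg_ala, tolerance = 1e-12)
  expect_equal(fit$dg_leu, dg_leu, tolerance = 1e-12)
  # the 3-leucine construct value implied by the printed parameters
  expect_equal(dg[n == 3], 0.79, tolerance = 0.005)
  # zero slope collapses the two values
  f0 <- fit_ala_leu(n, rep(1, 5))
  expect_equal(f0$dg_leu, f0$dg_ala)
  expect_error(fit_ala_leu(c(2, 2), c(1, 1)), "distinct")
})

test_that("reference-substitution arithmetic is linear and exact", {
  expect_equal(dg_app_residue(0.3, 0.5, 0.13), -0.07, tolerance = 1e-12)
  expect_equal(dg_app_residue(0.5, 0.5, 0.13), 0.13)
  a <- dg_app_residue(0.1, 0.4, 0.2)
  b <- dg_app_residue(0.3, 0.4, 0.2)
  expect_equal(b - a, 0.2, tolerance = 1e-12)
})

test_that("ensemble bookkeeping averages frames, not pooled counts", {
  geom <- fixture_geom()
  fg <- build_field_grid(geom)
  cons <- h_segment_construct(7)
  res <- integration_probability(cons$aa, cons$ss, cons$h_range,
                                 cons$tmd_range, geom, n_traj = 2,
                                 t_trans = 0.001, max_time = 0.004,
                                 seed = 3, field_grid = fg)
  per <- res[res$frame != "average", ]
  avg <- res[res$frame == "average", ]
  expect_equal(nrow(per), 3)
  expect_equal(per$n_integration + per$n_translocation + per$n_none, per$n)
  expect_equal(avg$p_integration, mean(per$p_integration))
  expect_true(all(res$p_integration >= 0 & res$p_integration <= 1))
})
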