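test_that("bond, excluded-volume and electrostatic closed forms hold", {
  expect_equal(fene(0), 0)
  expect_equal(fene(1), -0.5 * 5.833 * 4 * log(0.75))
  expect_gt(fene(1.99), fene(1.9))
  expect_error(fene(2), "overstretched")
  expect_equal(excluded_volume(2^(1 / 6)), 0)
  expect_equal(excluded_volume(1), 1)
  expect_equal(excluded_volume(1.2), 0)
  expect_equal(debye_huckel(0, 5, 1), 0)
  expect_equal(debye_huckel(1, 1, 1), exp(-1))
  expect_equal(debye_huckel(1, -1, 2), -0.5 * exp(-2), tolerance = 1e-10)
  expect_error(debye_huckel(1, 1, 0), "r > 0")
})

test_that("solvation scales the membrane indicator by bead hydrophobicity", {
  expect_equal(solvation(-6.1, c(4, 0, 0)), -6.1, tolerance = 1e-3)
  expect_equal(solvation(5, c(0, 0, 10)), 0, tolerance = 1e-6)
  expect_equal(solvation(0, c(4, 0, 0)), 0)
})

test_that("soft-core potential is capped, continuous and correctly shifted", {
  tab <- softcore_table()
  llo <- tab[tab$potential == "ULLLopen", ]
  # unshifted value at r = 0 equals the 100 eps cap (within 1%)
  expect_equal(softcore(0, llo, shifted = FALSE), 100, tolerance = 0.01)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    expect_equal(softcore(0, row, shifted = FALSE), 100, tolerance = 0.01)
    cutoff <- row$r_cr * row$sigma_j
    expect_equal(softcore(cutoff + 1e-9, row), 0)
    expect_lt(abs(softcore(cutoff - 1e-4, row)), 1e-3)  # continuity
  }
})

test_that("alpha root-finding matches the printed table and a uniroot oracle", {
  expect_lt(abs(alpha_from_cap(9.85) - 0.461), 1e-3)
  expect_lt(abs(alpha_from_cap(0.46) - 0.127), 1e-3)
  for (eps in c(0.3, 0.51, 1.38, 9.85)) {
    oracle <- uniroot(function(a) 4 * eps * (1 / a^2 - 1 / a) - 100,
                      c(1e-6, 1 - 1e-6), tol = 1e-12)$root
    expect_equal(alpha_from_cap(eps), oracle, tolerance = 1e-9)
  }
  # larger cap -> smaller alpha, monotonically
  caps <- c(10, 100, 1000, 1e6)
  a <- vapply(caps, function(cc) alpha_from_cap(1, cc), numeric(1))
  expect_true(all(diff(a) < 0))
  expect_error(alpha_from_cap(-1), "positive")
})

test_that("published interaction table is self-consistent", {
  tab <- softcore_table()
  printed <- data.frame(
    potential = c("ULLLopen", "ULLLclosed", "UDDDopen", "UDDDclosed",
                  "ULLLopen-confined", "ULLLclosed-confined",
                  "UDDDopen-confined", "UDDDclosed-confined", "Uout"),
    eps_cr = c(-0.008, -0.005, -0.005, -0.005, -0.023, -0.023,
               -9.85, -0.51, -0.008),
    r_cr = c(2.5, 2.5, 2.5, 2.5, 2.5, 2.5, 1.075, 1.110, 2.5),
    alpha = c(0.127, 0.104, 0.104, 0.104, 0.209, 0.211, 0.461, 0.133, 0.132)
  )
  m <- merge(tab, printed, by = "potential")
  expect_equal(m$alpha.x, m$alpha.y, tolerance = 1e-3)
  expect_equal(m$eps_cr.x, m$eps_cr.y, tolerance = 1e-3)
  expect_equal(m$r_cr.x, m$r_cr.y, tolerance = 1e-3)
  # repulsive confined rows cut at the soft-core minimum with shift -eps_int
  rep_rows <- tab[tab$potential %in% c("UDDDopen-confined",
                                       "UDDDclosed-confined"), ]
  expect_equal(rep_rows$r_cr, (2 - rep_rows$alpha)^(1 / 6), tolerance = 1e-9)
  expect_equal(rep_rows$eps_cr, -rep_rows$eps_int, tolerance = 1e-9)
})

test_that("channel interaction mixes linearly and respects regimes", {
  geom <- fixture_geom()
  bead <- function(lo, lc) {
    tibble::tibble(g = 0, q = 0, lambda_open = lo, lambda_closed = lc)
  }
  pos <- c(0.4, 0.3, 0.2)
  u0 <- channel_interaction(bead(0, 0), pos, "open", geom)
  u1 <- channel_interaction(bead(1, 1), pos, "open", geom)
  uh <- channel_interaction(bead(0.37, 0.37), pos, "open", geom)
  expect_equal(uh, 0.37 * u1 + 0.63 * u0, tolerance = 1e-10)
  expect_lt(u1, u0)   # attractive bound below repulsive bound at the pore
  # far away: zero
  expect_equal(channel_interaction(bead(1, 1), c(0, 0, 30), "open", geom), 0)
  # deep in the membrane: only the exterior interaction contributes, which
  # no longer depends on lambda
  um0 <- channel_interaction(bead(0, 0), c(3.6, 0, 0), "closed", geom)
  um1 <- channel_interaction(bead(1, 1), c(3.6, 0, 0), "closed", geom)
  expect_equal(um0, um1, tolerance = 1e-3)
})

test_that("ribosome repulsion has the printed shifted-WCA geometry", {
  geom <- fixture_geom()
  ctr <- geom$sphere_center
  far <- ctr + c(2 + 2^(1 / 6), 0, 0)
  # at the WCA cutoff of the shifted distance the sphere term vanishes and
  # only remote bead terms could contribute (none at this position)
  expect_equal(ribosome_repulsion(far, geom), 0, tolerance = 1e-9)
  at3 <- ctr + c(3, 0, 0)
  expect_equal(ribosome_repulsion(at3, geom), 1, tolerance = 1e-9)
  expect_equal(ribosome_repulsion(ctr + c(50, 0, 0), geom), 0)
})

test_that("total energy equals the naive pairwise oracle", {
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(5:20, 1)
    aa <- paste(sample(c("L", "A", "K", "D", "Q", "S"), 3 * n, TRUE),
                collapse = "")
    ss <- paste(sample(c("H", "C"), 3 * n, TRUE), collapse = "")
    cons <- sec_constants(elec_cutoff = 1e6)  # oracle has no cutoff
    beads <- map_sequence(aa, ss, constants = cons)
    pos <- matrix(0, n, 3)
    pos[1, ] <- c(runif(1, -3, 3), runif(1, -3, 3), runif(1, -3, 5))
    for (i in seq_len(n - 1)) {
      step <- rnorm(3)
      pos[i + 1, ] <- pos[i, ] + 0.95 * step / sqrt(sum(step^2))
    }
    st <- sim_state(beads, fixture_geom(), positions = pos,
                    gate = sample(c("open", "closed"), 1),
                    translating = FALSE, constants = cons)
    expect_equal(total_energy(st), naive_total_energy(st), tolerance = 1e-10)
  }
})

test_that("electrostatic cutoff at six screening lengths is negligible", {
  cons_cut <- sec_constants()
  cons_inf <- sec_constants(elec_cutoff = 1e6)
  beads <- map_sequence("KKKDDDRRRLLL", strrep("H", 12))
  pos <- cbind(seq(0, 3, by = 1), 2, 1)
  st1 <- sim_state(beads, fixture_geom(), positions = pos,
                   translating = FALSE, constants = cons_cut)
  st2 <- sim_state(beads, fixture_geom(), positions = pos,
                   translating = FALSE, constants = cons_inf)
  expect_equal(total_energy(st1), total_energy(st2), tolerance = 1e-2)
})
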