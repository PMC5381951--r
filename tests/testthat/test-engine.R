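test_that("forces are the analytic gradient of the total energy", {
  st <- toy_state("open")
  F <- forces(st)
  h <- 1e-6
  for (i in 1:nrow(st$positions)) {
    for (d in 1:3) {
      sp <- st; sp$positions[i, d] <- sp$positions[i, d] + h
      sm <- st; sm$positions[i, d] <- sm$positions[i, d] - h
      num <- -(total_energy(sp) - total_energy(sm)) / (2 * h)
      expect_equal(F[i, d], num, tolerance = 1e-4)
    }
  }
})

test_that("langevin step is identity under zero force and zero noise", {
  beads <- map_sequence("AAA", "HHH")
  beads$g <- 0; beads$q <- 0L
  far <- sim_state(beads, fixture_geom(), positions = matrix(50, 1, 3),
                   translating = FALSE)
  out <- langevin_step(far, noise = matrix(0, 1, 3))
  expect_equal(out$positions, far$positions, tolerance = 1e-12)
  expect_equal(out$time_s, far$time_s + sec_constants()$dt_s)
  st <- toy_state()
  # the translating bead is never moved by the thermal update
  tr_state <- sim_state(st$beads, st$geom)
  before <- tr_state$positions[1, ]
  out2 <- langevin_step(tr_state)
  expect_equal(out2$positions[1, ], before)
})

test_that("gating probabilities have the Glauber form and detailed balance", {
  st <- toy_state("closed")
  dg <- delta_g_open(st)
  pref <- sec_constants()$dt_s / sec_constants()$tau_LG_s
  closed <- attempt_gating(st, u = 2)   # u > p: no switch
  expect_equal(attr(closed, "p_switch"),
               pref * exp(-dg) / (1 + exp(-dg)))
  sto <- st; sto$gate <- "open"
  opened <- attempt_gating(sto, u = 2)
  expect_equal(attr(opened, "p_switch"), pref / (1 + exp(-dg)))
  # algebraic identity p_open / p_close = exp(-beta dG)
  expect_equal(attr(closed, "p_switch") / attr(opened, "p_switch"),
               exp(-dg))
  # forced switch flips the conformation
  expect_equal(attempt_gating(st, u = 0)$gate, "open")
})

test_that("empty channel opening free energy equals the bare penalty", {
  beads <- map_sequence("LLLLLLLLL", "HHHHHHHHH")
  # chain far from the channel: only the empty-channel term remains
  pos <- cbind(40 + (1:3) * 0.9, 40, 40)
  st <- sim_state(beads, fixture_geom(), positions = pos, translating = FALSE)
  expect_equal(delta_g_open(st), 3, tolerance = 1e-6)
})

test_that("translation bookkeeping advances, releases and stages beads", {
  beads <- map_sequence(strrep("A", 9), strrep("H", 9))
  st <- sim_state(beads, fixture_geom())
  expect_equal(st$n_placed, 1L)
  expect_true(st$translating)
  # per-step displacement sigma * dt / t_trans; at the default 0.6 s this
  # is 5e-7 sigma
  z0 <- st$positions[1, 3]
  st1 <- translation_step(st)
  expect_equal(st1$positions[1, 3] - z0, sec_constants()$dt_s / 0.6)
  expect_equal(st1$positions[1, 3] - z0, 5e-7)
  # after a full t_trans the next bead appears at the insertion point
  t_tr <- 6e-4
  n_steps <- ceiling(t_tr / sec_constants()$dt_s)
  st2 <- st
  for (k in seq_len(n_steps)) st2 <- translation_step(st2, t_trans = t_tr)
  expect_equal(st2$n_placed, 2L)
  expect_equal(st2$positions[2, ], fixture_geom()$insertion_point)
})

test_that("trajectories are bit-reproducible for a given seed", {
  beads <- map_sequence(strrep("L", 30), strrep("H", 30))
  st <- sim_state(beads, fixture_geom())
  t1 <- run_trajectory(st, seed = 99, max_time = 0.003, t_trans = 0.002)
  t2 <- run_trajectory(st, seed = 99, max_time = 0.003, t_trans = 0.002)
  expect_identical(t1$state$positions, t2$state$positions)
  expect_identical(t1$n_flips, t2$n_flips)
  t3 <- run_trajectory(st, seed = 100, max_time = 0.003, t_trans = 0.002)
  expect_false(identical(t1$state$positions, t3$state$positions))
  # a single-step guard yields a single-step trajectory
  t4 <- run_trajectory(st, seed = 1, max_time = sec_constants()$dt_s)
  expect_equal(t4$steps, 1)
})

test_that("bonds never overstretch during a nominal run", {
  beads <- map_sequence(strrep("L", 36), strrep("H", 36))
  st <- sim_state(beads, fixture_geom())
  tr <- run_trajectory(st, seed = 5, max_time = 0.02, t_trans = 0.002,
                       save_every = 200)
  R0 <- sec_constants()$R0
  nf <- dim(tr$frames)[3]
  for (k in seq_len(nf)) {
    p <- tr$frames[, , k]
    placed <- which(is.finite(p[, 1]))
    if (length(placed) > 1) {
      b <- sqrt(rowSums(diff(p[placed, , drop = FALSE])^2))
      expect_true(all(b < R0))
    }
  }
})

test_that("dimer bond statistics match the Boltzmann quadrature oracle", {
  # two bonded beads with FENE + excluded volume only (far from geometry)
  beads <- map_sequence("AAAAAA", "HHHHHH")
  beads$g <- 0; beads$q <- c(0L, 0L)
  pos <- rbind(c(50, 50, 50), c(50.9, 50, 50))
  st <- sim_state(beads, fixture_geom(), positions = pos, translating = FALSE)
  tr <- run_trajectory(st, seed = 11, max_time = 0.6, save_every = 20)
  nf <- dim(tr$frames)[3]
  r <- vapply(seq_len(nf), function(k) {
    sqrt(sum((tr$frames[1, , k] - tr$frames[2, , k])^2))
  }, numeric(1))
  r <- r[-seq_len(200)]  # discard equilibration
  # oracle: <r^2> under p(r) ~ r^2 exp(-U_fene(r) - U_wca(r))
  rg <- seq(1e-3, 1.999, by = 1e-4)
  w <- rg^2 * exp(-(fene(rg) + excluded_volume(rg)))
  mr2 <- sum(rg^2 * w) / sum(w)
  expect_equal(mean(r^2), mr2, tolerance = 0.02)
})

test_that("tabulated-field trajectories track the direct evaluation", {
  geom <- fixture_geom()
  fg <- build_field_grid(geom)
  beads <- map_sequence(strrep("L", 24), strrep("H", 24))
  st <- sim_state(beads, geom)
  td <- run_trajectory(st, seed = 3, max_time = 0.004, t_trans = 0.002)
  tg <- run_trajectory(st, seed = 3, max_time = 0.004, t_trans = 0.002,
                       field_grid = fg)
  # same random stream, approximate potential: trajectories stay close
  # over short times
  expect_lt(max(abs(td$state$positions - tg$state$positions), na.rm = TRUE),
            0.5)
  # and the interpolated channel energy is close to the exact one at the
  # visited configurations
  expect_equal(td$n_flips > 0, tg$n_flips > 0)
})

test_that("free chain end-to-end distance grows with chain length", {
  geom_empty <- sec_geometry(
    tibble::tibble(id = integer(), group = character(),
                   conformation = character(), x = numeric(), y = numeric(),
                   z = numeric(), charge = numeric(), class = character(),
                   exterior = logical()),
    sphere_enabled = FALSE)
  ree2 <- function(n, seed) {
    beads <- map_sequence(strrep("A", 3 * n), strrep("H", 3 * n))
    beads$g <- 0
    beads$q <- rep(0L, n)
    pos <- cbind(0.95 * seq_len(n), 0, 0)
    st <- sim_state(beads, geom_empty, positions = pos, translating = FALSE)
    tr <- run_trajectory(st, seed = seed, max_time = 0.12, save_every = 400)
    nf <- dim(tr$frames)[3]
    v <- vapply(seq(nf %/% 3, nf), function(k) {
      sum((tr$frames[n, , k] - tr$frames[1, , k])^2)
    }, numeric(1))
    mean(v)
  }
  r8 <- ree2(8, 21)
  r16 <- ree2(16, 22)
  # freely-jointed scaling: doubling bead count about doubles <R_ee^2>
  # (slightly more with excluded volume); generous sampling tolerance
  expect_gt(r16 / r8, 1.5)
})
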