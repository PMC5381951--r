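test_that("pmf of a non-interacting bead is identically zero", {
  geom_empty <- sec_geometry(
    tibble::tibble(id = integer(), group = character(),
                   conformation = character(), x = numeric(), y = numeric(),
                   z = numeric(), charge = numeric(), class = character(),
                   exterior = logical()),
    sphere_enabled = FALSE)
  p <- pmf_numeric(list(g = 0), "open", geom_empty, z = seq(-3, 4.5, 0.5),
                   spacing = 0.1)
  expect_true(all(abs(p$F) < 1e-10))
})

test_that("normalization window zeroes the plateau and preserves differences", {
  geom <- fixture_geom()
  z <- seq(-3, 4.5, 0.25)
  p <- pmf_numeric(list(g = 3.8), "closed", geom, z = z, spacing = 0.1)
  expect_lt(abs(mean(p$F[p$z >= 4 & p$z <= 4.5])), 1e-6)
  p2 <- pmf_numeric(list(g = 3.8), "closed", geom, z = z, spacing = 0.1,
                    window = c(-3, -2.5))
  d1 <- diff(p$F)
  d2 <- diff(p2$F)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("pmf is monotone in the mixing coefficient at the pore centre", {
  geom <- fixture_geom()
  z <- seq(-0.5, 4.5, 0.5)
  Fs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(lam) {
    p <- pmf_numeric(list(g = 0), "open", geom, z = z, spacing = 0.1,
                     lambda = lam)
    p$F[p$z == 0]
  }, numeric(1))
  expect_true(all(diff(Fs) <= 1e-9))  # more attractive mixing lowers F(0)
})

test_that("quadrature agrees with Monte Carlo cross-section integration", {
  geom <- fixture_geom()
  z <- seq(-1, 3, 1)
  pq <- pmf_numeric(list(g = -6.1), "closed", geom, z = z, spacing = 0.0125,
                    lambda = 1, window = c(2.9, 3.1))
  # independent stochastic oracle: uniform Monte Carlo sampling of the disc
  set.seed(7)
  nmc <- 2e5
  pts <- matrix(runif(2 * nmc, -1.5, 1.5), ncol = 2)
  pts <- pts[pts[, 1]^2 + pts[, 2]^2 <= 1.5^2, ]
  a <- seccg:::.pars_list(sec_constants())
  gm <- seccg:::.geom_matrices(geom)
  Fmc <- vapply(z, function(zz) {
    fields <- seccg:::cg_single_bead_fields(cbind(pts, zz), 0L, gm, a)
    U <- -6.1 * fields[, 1] + (1 - fields[, 1]) * fields[, 2] +
      fields[, 1] * fields[, 4]
    -log(mean(exp(-U)))
  }, numeric(1))
  Fmc <- Fmc - mean(Fmc[z >= 2.9 & z <= 3.1])
  expect_equal(pq$F, Fmc, tolerance = 0.1)
})

test_that("lambda fitting recovers known coefficients including bounds", {
  geom <- fixture_geom()
  z <- seq(-2, 4.5, 0.25)
  for (lam_true in c(0.4, 1, 0)) {
    ref <- pmf_numeric(list(g = 3.8), "open", geom, z = z,
                       lambda = lam_true, spacing = 0.05)
    fit <- fit_lambda(ref, g = 3.8, "open", geom)
    expect_equal(fit$lambda, lam_true, tolerance = 0.01)
  }
  # flat objective is flagged: an empty geometry cannot discriminate
  geom_empty <- sec_geometry(
    tibble::tibble(id = integer(), group = character(),
                   conformation = character(), x = numeric(), y = numeric(),
                   z = numeric(), charge = numeric(), class = character(),
                   exterior = logical()),
    sphere_enabled = FALSE)
  ref0 <- tibble::tibble(z = z, F = 0 * z)
  expect_warning(f0 <- fit_lambda(ref0, g = 0, "open", geom_empty),
                 "flat")
  expect_true(f0$flat)
})

test_that("soft-core fitting recovers parameters and tracks well depth", {
  geom <- fixture_geom()
  z <- seq(-2, 4.5, 0.25)
  ref <- pmf_numeric(list(g = -6.1), "open", geom, z = z, lambda = 1,
                     spacing = 0.1)
  fit <- fit_softcore_to_pmf(ref, "open", geom, base = "LLL",
                             class_fit = "normal",
                             start = c(eps_int = 0.8, r_cr = 2.2,
                                       sigma_j = 1.1))
  expect_equal(fit$params$eps_int, 0.46, tolerance = 0.05 * 0.46)
  expect_lt(fit$residual, 1e-4)
  # a zero reference against a single-class scaffold drives the fitted
  # interaction to negligible effect
  ring <- purrr::map_dfr(1:6, function(j) {
    a <- j * pi / 3
    tibble::tibble(id = j, group = "channel",
                   conformation = c("closed", "open"),
                   x = 1.5 * cos(a), y = 1.5 * sin(a), z = 0,
                   charge = 0, class = "normal", exterior = FALSE)
  })
  mini <- sec_geometry(ring, sphere_enabled = FALSE)
  ref0 <- tibble::tibble(z = z, F = 0 * z)
  fit0 <- fit_softcore_to_pmf(ref0, "open", mini, base = "LLL", g = 0,
                              class_fit = "normal",
                              start = c(eps_int = 0.05, r_cr = 1.2,
                                        sigma_j = 0.6))
  expect_lt(fit0$residual, 1e-2)
  # deepening the reference well increases the fitted interaction energy
  tab <- softcore_table()
  deeper <- tab
  i <- which(deeper$potential == "ULLLopen")
  deeper$eps_int[i] <- 0.9
  deeper$alpha[i] <- alpha_from_cap(0.9)
  deeper$eps_cr[i] <- eps_cr_from_params(0.9, deeper$alpha[i], 2.5)
  ref_deep <- pmf_numeric(list(g = -6.1), "open", geom, z = z, lambda = 1,
                          spacing = 0.1, table = deeper)
  fit_deep <- fit_softcore_to_pmf(ref_deep, "open", geom, base = "LLL",
                                  class_fit = "normal")
  expect_gt(fit_deep$params$eps_int, fit$params$eps_int)
})

test_that("reference pmf files round-trip with optional rescaling", {
  p <- tibble::tibble(z = seq(-2, 2, 0.5), F = sin(seq(-2, 2, 0.5)))
  path <- tempfile(fileext = ".dat")
  write_pmf(p, path)
  back <- read_pmf(path)
  expect_equal(back$z, p$z, tolerance = 1e-9)
  expect_equal(back$F, p$F, tolerance = 1e-9)
  scaled <- read_pmf(path, rescale = 0.25)
  expect_equal(scaled$F, 0.25 * p$F, tolerance = 1e-9)
})
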