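test_that("membrane indicator matches its closed form and bounds", {
  expect_lt(membrane_indicator(0, 0, 0), 1e-4)       # channel lumen
  expect_gt(membrane_indicator(4, 0, 0), 1 - 1e-4)   # membrane core
  expect_lt(membrane_indicator(4, 0, 6), 1e-4)       # outside the slab
  # direct evaluation of the tanh product form
  s_direct <- function(x, y, z) {
    sxy <- 0.25 * (1 + tanh((sqrt(x^2 + y^2) + 1.5) / 0.25)) *
      (1 - tanh((sqrt(x^2 + y^2) - 1.5) / 0.25))
    sz <- 0.25 * (1 + tanh((z + 2) / 0.25)) * (1 - tanh((z - 2) / 0.25))
    (1 - sxy) * sz
  }
  pts <- expand.grid(x = seq(-4, 4, 1.1), y = seq(-4, 4, 1.3),
                     z = seq(-5, 5, 0.9))
  v <- membrane_indicator(as.matrix(pts))
  expect_equal(v, mapply(s_direct, pts$x, pts$y, pts$z))
  expect_true(all(v >= 0 & v <= 1))
  # radial symmetry about the z axis
  expect_equal(membrane_indicator(2, 0, 1), membrane_indicator(0, 2, 1))
  expect_equal(membrane_indicator(sqrt(2), sqrt(2), -1),
               membrane_indicator(2, 0, -1))
})

test_that("protein backbone maps to triplet centroid beads", {
  co <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE)
  b <- map_protein_to_beads(co, "AAA")
  expect_equal(nrow(b), 1)
  expect_equal(c(b$x, b$y, b$z), c(1, 0, 0))
  b6 <- map_protein_to_beads(rbind(co, co + 5), "AAAAAA")
  expect_equal(nrow(b6), 2)
  expect_equal(b6$charge, c(0L, 0L))
  expect_equal(map_protein_to_beads(co, "RKD")$charge, 1L)
  expect_error(map_protein_to_beads(co, "AAAA"), "lengths differ")
})

test_that("rna maps to two beads per nucleotide with backbone charge", {
  atoms <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(nucleotide = i, part = c("backbone", "backbone", "base"),
               x = i + c(0, 1, 2), y = 0, z = 0)
  }))
  b <- map_rna_to_beads(atoms)
  expect_equal(nrow(b), 20)
  expect_equal(sum(b$charge), -10)
  expect_equal(nrow(map_rna_to_beads(atoms[0, ])), 0)
  expect_error(map_rna_to_beads(data.frame(nucleotide = 1, part = "backbone",
                                           x = 0, y = 0, z = 0)),
               "atom groups")
})

test_that("alignment restores the origin and lateral-gate convention", {
  geom <- fixture_geom()
  shifted <- geom
  shifted$beads$x <- shifted$beads$x + 3
  shifted$beads$z <- shifted$beads$z - 1.5
  lg_ids <- unique(shifted$beads$id[shifted$beads$group == "channel"])[1:4]
  re <- align_and_center(shifted, lg_ids)
  closed <- re$beads$group == "channel" & re$beads$conformation == "closed"
  ctr <- colMeans(as.matrix(re$beads[closed, c("x", "y", "z")]))
  expect_true(all(abs(ctr) < 1e-6))
  lg <- re$beads$group == "channel" & re$beads$conformation == "open" &
    re$beads$id %in% lg_ids
  mid <- colMeans(as.matrix(re$beads[lg, c("x", "y")]))
  expect_lt(abs(mid[1]), 1e-8)
  expect_gt(mid[2], 0)
})

test_that("synthetic fixture is consistent and deterministic", {
  geom <- fixture_geom()
  b <- geom$beads
  closed <- b[b$group == "channel" & b$conformation == "closed", ]
  open_ <- b[b$group == "channel" & b$conformation == "open", ]
  expect_equal(nrow(closed), nrow(open_))
  expect_identical(closed$charge[order(closed$id)],
                   open_$charge[order(open_$id)])
  expect_identical(closed$class[order(closed$id)],
                   open_$class[order(open_$id)])
  expect_true(any(b$class == "confined"))
  # channel centroid at the origin
  ctr <- colMeans(as.matrix(closed[, c("x", "y", "z")]))
  expect_true(all(abs(ctr) < 1e-8))
  # same seed reproduces; different seed moves the jitter
  expect_identical(synthetic_channel_fixture(seed = 3)$beads,
                   synthetic_channel_fixture(seed = 3)$beads)
  expect_false(identical(synthetic_channel_fixture(seed = 3)$beads$x,
                         synthetic_channel_fixture(seed = 4)$beads$x))
  # membrane excluded from the pore interior
  expect_lt(membrane_indicator(0, 0, 0, geom$membrane), 1e-3)
})

test_that("geometry serialization round-trips bit-exactly", {
  geom <- fixture_geom()
  path <- tempfile(fileext = ".tsv")
  write_geometry(geom, path)
  back <- read_geometry(path)
  expect_identical(back$beads$x, geom$beads$x)
  expect_identical(back$beads$y, geom$beads$y)
  expect_identical(back$beads$z, geom$beads$z)
  expect_identical(back$beads$class, geom$beads$class)
  expect_equal(back$membrane, geom$membrane)
  expect_equal(back$insertion_point, geom$insertion_point)
})

test_that("pdb backbones map through the triplet centroid rule", {
  skip_if_not_installed("bio3d")
  path <- tempfile(fileext = ".pdb")
  res <- c("ALA", "ARG", "LYS", "ASP", "GLU", "LEU")
  lines <- vapply(seq_along(res), function(i) {
    sprintf("ATOM  %5d  CA  %s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, res[i], i, i * 1.0, 0, 0)
  }, character(1))
  writeLines(c(lines, "END"), path)
  b <- read_pdb_beads(path)
  expect_equal(nrow(b), 2)
  expect_equal(b$x, c(2, 5))
  expect_equal(b$triplet, c("ARK", "DEL"))
  expect_equal(b$charge, c(1L, -1L))
})
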