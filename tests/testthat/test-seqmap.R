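test_that("per-residue transfer free energies convert and penalize correctly", {
  # leucine: -1.25 kcal/mol in units of kT at 310 K
  expect_equal(residue_tfe("L", TRUE), -1.25 / sec_constants()$eps_kcal)
  expect_lt(residue_tfe("L", TRUE), 0)
  expect_gt(residue_tfe("D", TRUE), 0)
  # coil penalty is exactly +1.78 eps per residue
  expect_equal(residue_tfe("Q", FALSE) - residue_tfe("Q", TRUE), 1.78)
  expect_equal(residue_tfe(c("A", "G"), c(TRUE, FALSE)),
               c(residue_tfe("A", TRUE), residue_tfe("G", TRUE) + 1.78))
  expect_error(residue_tfe("X"), "unknown residue")
})

test_that("triplet anchors reproduce the published values", {
  expect_equal(3 * residue_tfe("L", TRUE), -6.1, tolerance = 0.1)
  expect_equal(3 * residue_tfe("Q", TRUE), 3.8, tolerance = 0.1)
  expect_equal(3 * residue_tfe("Q", FALSE), 9.1, tolerance = 0.1)
  expect_equal(3 * residue_tfe("D", FALSE), 23.1, tolerance = 0.1)
})

test_that("scale table covers the 20 residues with the right signs", {
  s <- ww_scale()
  expect_setequal(s$residue, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  expect_lt(s$dg_eps[s$residue == "L"], 0)
  expect_gt(s$dg_eps[s$residue == "D"], 0)
})

test_that("sequence mapping sums residues and applies terminal corrections", {
  beads <- map_sequence(strrep("L", 15), strrep("H", 15))
  expect_equal(nrow(beads), 5)
  inner <- beads[2:4, ]
  expect_equal(inner$g, rep(3 * residue_tfe("L", TRUE), 3))
  expect_equal(inner$q, rep(0L, 3))
  expect_true(all(abs(inner$lambda_open - 1) < 0.01))
  # terminal beads: +-1 charge and +6 eps
  expect_equal(beads$q[1], 1L)
  expect_equal(beads$q[5], -1L)
  expect_equal(beads$g[1], inner$g[1] + 6)
  # additivity on a heterogeneous bead
  b <- map_sequence("AQKDEF", "HHCCHH")
  expect_equal(b$g[1],
               sum(residue_tfe(c("A", "Q", "K"), c(TRUE, TRUE, FALSE))) + 6)
  expect_equal(b$q[2], sum(c(-1L, -1L, 0L)) - 1L)
})

test_that("total chain charge equals formal charge plus termini", {
  aa <- "MKRLLDDEAGRKWQ"
  ss <- strrep("H", nchar(aa))
  for (f in 0:2) {
    beads <- map_sequence(aa, ss, frame = f)
    formal <- sum(seccg:::residue_charge(strsplit(aa, "")[[1]]))
    expect_equal(sum(beads$q), formal + 1L - 1L)
  }
})

test_that("frameshifts conserve residues and differ by at most one bead", {
  aa <- paste(rep("ACDEFGHIKL", 9), collapse = "")   # 90 residues
  fr <- enumerate_frameshifts(aa, strrep("H", 90))
  expect_length(fr, 3)
  for (b in fr) {
    expect_equal(sum(nchar(b$triplet)), 90)
  }
  aa91 <- paste0(aa, "M")
  fr91 <- enumerate_frameshifts(aa91, strrep("H", 91))
  counts <- vapply(fr91, nrow, integer(1))
  expect_lte(diff(range(counts)), 1)
  # homopolymer: all frames give identical internal bead g profiles
  frh <- enumerate_frameshifts(strrep("L", 30), strrep("H", 30))
  gs <- lapply(frh, function(b) round(b$g[b$res_start > 3 & b$res_end < 28], 8))
  expect_true(all(vapply(gs, function(x) all(x == gs[[1]][1]), logical(1))))
  expect_error(map_sequence("", ""), "empty")
  expect_error(map_sequence("AA", "HH"), "too short")
  expect_error(map_sequence("AAAA", "HH"), "length")
})

test_that("lambda interpolation hits anchors, is monotone and clamps", {
  li <- lambda_interp(c(-6.1, 23.1, -20, 40))
  expect_equal(li$lambda_open[1], 1)
  expect_equal(li$lambda_closed[1], 1)
  expect_equal(li$lambda_open[2], 0)
  expect_equal(li$lambda_open[3], 1)   # clamped below
  expect_equal(li$lambda_open[4], 0)   # clamped above
  g <- seq(-10, 30, by = 0.5)
  li <- lambda_interp(g)
  expect_true(all(diff(li$lambda_open) <= 1e-12))
  expect_true(all(diff(li$lambda_closed) <= 1e-12))
  expect_true(all(li$lambda_open >= 0 & li$lambda_open <= 1))
})

test_that("translocon triplet charges take the sign of the sum", {
  expect_equal(translocon_triplet_charge(c("RKA", "DEK", "AAA", "RK")),
               c(1L, -1L, 0L, 1L))
})

test_that("fasta + secondary structure reading round-trips", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">toy", "LLLQQQ", "DDD"), fa)
  ssf <- tempfile(fileext = ".txt")
  writeLines(c("# comment", "HHHHHH", "CCC"), ssf)
  rs <- read_sequence(fa, ssf)
  expect_equal(rs$aa, "LLLQQQDDD")
  expect_equal(rs$ss, "HHHHHHCCC")
  out <- tempfile(fileext = ".tsv")
  write_bead_table(map_sequence(rs$aa, rs$ss), out)
  tab <- read.table(out, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 3)
  expect_true(all(c("g_eps", "lambda_open") %in% names(tab)))
})
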