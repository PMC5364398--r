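# data model, role dialects, readers/writers, selections, analysis window

write_gro_fixture <- function(path, records, box = "  10.00000  10.00000  10.00000",
                              title = "fixture, t= 0.0") {
  writeLines(c(title, sprintf("%5d", length(records)), records, box), path)
}

gro_rec <- function(resid, resname, atom, serial, x, y, z)
  sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", resid, resname, atom, serial, x, y, z)

test_that("a one-particle water GRO reads as a single WATER particle", {
  f <- withr::local_tempfile(fileext = ".gro")
  write_gro_fixture(f, gro_rec(1, "W", "W", 1, 1.5, 2.5, 3.5))
  st <- readStructure(f)
  expect_equal(nParticles(st$topology), 1L)
  expect_equal(particleData(st$topology)$role, "WATER")
  expect_equal(st$frame$positions[1, ], c(1.5, 2.5, 3.5))
  expect_equal(st$frame$box, c(10, 10, 10))
})

test_that("CG lipid bead names map to roles and tail positions 1..4", {
  beads <- c("NC3", "PO4", "GL1", "GL2", "C1A", "D2A", "C3A", "C4A",
             "C1B", "C2B", "C3B", "C4B")
  f <- withr::local_tempfile(fileext = ".gro")
  write_gro_fixture(f, vapply(seq_along(beads), function(i)
    gro_rec(1, "POPC", beads[i], i, i * 0.1, 0, 0), character(1)))
  st <- readStructure(f)
  p <- particleData(st$topology)
  expect_equal(p$role[1:4], c("LIPID_NC3", "LIPID_PO4", "LIPID_GLY", "LIPID_GLY"))
  expect_equal(p$role[5:8], rep("LIPID_TAIL_SN2", 4))
  expect_equal(p$role[9:12], rep("LIPID_TAIL_SN1", 4))
  expect_equal(p$tail_position[5:12], rep(1:4, 2))
})

test_that("unknown names error with a listing, or map to OTHER on opt-in", {
  f <- withr::local_tempfile(fileext = ".gro")
  write_gro_fixture(f, c(gro_rec(1, "XYZ", "QQ", 1, 1, 1, 1),
                         gro_rec(2, "W", "W", 2, 2, 2, 2)))
  expect_error(readStructure(f), "XYZ/QQ")
  st <- readStructure(f, builtinDialect("cg-martini", unknown_to_other = TRUE))
  expect_equal(particleData(st$topology)$role, c("OTHER", "WATER"))
})

test_that("malformed records raise a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("bad", "    1", "    1W        W    1   xx.yyy   0.000   0.000",
               "  10.0 10.0 10.0"), f)
  expect_error(readStructure(f), "line 3")
})

test_that("PDB coordinates are converted from Angstrom to nm", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1  100.000  100.000  100.000  90.00  90.00  90.00 P 1           1",
    sprintf("%-6s%5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
            "ATOM", 1, " O", "", "HOH", "A", 1, "", 12.5, 20.0, 30.0, 1, 0),
    "END"), f)
  st <- readStructure(f, builtinDialect("at-charmm-like"))
  expect_equal(st$frame$positions[1, ], c(1.25, 2.0, 3.0), tolerance = 1e-6)
  expect_equal(st$frame$box, c(10, 10, 10))
  expect_equal(particleData(st$topology)$role, "WATER")
})

test_that("write/read round-trip preserves positions to format precision and roles exactly", {
  model <- placeHydrophobicBands(buildHexagonalScaffold(length_bp = 8L), "1-ring")
  tt <- modelToTopology(model)
  f <- withr::local_tempfile(fileext = ".gro")
  writeStructure(tt$topology, tt$frame, f)
  st <- readStructure(f)
  expect_lt(max(abs(st$frame$positions - tt$frame$positions)), 1e-3)
  a <- particleData(st$topology); b <- particleData(tt$topology)
  expect_identical(a$role, b$role)
  expect_identical(a$helix_id, b$helix_id)
  expect_identical(a$strand_id, b$strand_id)
})

test_that("trajectory reading handles frame counts, times and stride", {
  tt <- modelToTopology(buildHexagonalScaffold(length_bp = 4L))
  f <- withr::local_tempfile(fileext = ".gro")
  lines <- unlist(lapply(0:9, function(k) {
    tf <- tempfile(fileext = ".gro")
    writeStructure(tt$topology,
                   modifyList(tt$frame, list(time = k * 50)), tf,
                   title = sprintf("frame, t= %.1f", k * 50))
    on.exit(unlink(tf))
    readLines(tf)
  }))
  writeLines(lines, f)

  tr1 <- readTrajectory(f, first = 1, last = 1)
  expect_equal(nFrames(tr1), 1L)
  expect_true(is.na(frameInterval(tr1)))

  tr3 <- readTrajectory(f, last = 3)
  expect_equal(frameInterval(tr3), 50)

  trs <- readTrajectory(f, stride = 2)
  expect_equal(nFrames(trs), 5L)
  expect_equal(frameTimes(trs), seq(0, 450, by = 100))

  # particle-count mismatch names the frame
  bad <- c(readLines(f),
           "extra frame, t= 500.0", "    1",
           gro_rec(1, "W", "W", 1, 1, 1, 1), "  10.0 10.0 10.0")
  f2 <- withr::local_tempfile(fileext = ".gro")
  writeLines(bad, f2)
  expect_error(readTrajectory(f2), "frame 11")
})

test_that("selections are deterministic, composable and may be empty", {
  tt <- modelToTopology(placeHydrophobicBands(buildHexagonalScaffold(), "7-band"))
  topo <- tt$topology
  expect_length(selectParticles(topo, role = "ION_NA"), 0L)
  dna <- selectParticles(topo, role = c("DNA_BB", "DNA_BASE", "ETHYL"))
  expect_length(dna, nParticles(topo))
  h0 <- selectParticles(topo, helix = 0L)
  expect_equal(length(h0), nParticles(topo) / 6)
  # conjunction equals intersection; idempotent
  a <- selectParticles(topo, role = "ETHYL", helix = 0L)
  expect_identical(a, intersect(selectParticles(topo, role = "ETHYL"), h0))
  expect_identical(selectParticles(topo, helix = 0L), h0)
  expect_error(selectParticles(topo, role = "NOT_A_ROLE"), "unknown role")
})

test_that("the trailing analysis window keeps inclusive endpoints", {
  topo <- make_topology("WATER", n = 2)
  nt <- 25001L   # 500 ns at 20 ps
  tr <- new("Trajectory", topology = topo, coords = array(0, c(2, 3, nt)),
            times = (seq_len(nt) - 1) * 20,
            box = matrix(18, nt, 3))
  w <- analysisWindow(tr, 300)
  expect_equal(nFrames(w), 15001L)
  expect_equal(frameTimes(w)[1], 200 * 1000)

  # last 400 ns of a 1000 ns trajectory: all times >= 600 ns
  nt2 <- 1001L
  tr2 <- new("Trajectory", topology = topo, coords = array(0, c(2, 3, nt2)),
             times = (seq_len(nt2) - 1) * 1000, box = matrix(18, nt2, 3))
  w2 <- analysisWindow(tr2, 400)
  expect_true(all(frameTimes(w2) >= 600 * 1000))
  expect_equal(nFrames(analysisWindow(tr2, 1000)), nt2)
  expect_error(analysisWindow(tr2, 1500), "exceeds")
})

test_that("role dialects round-trip through YAML", {
  d <- builtinDialect("cg-martini")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeDialect(d, f)
  d2 <- readDialect(f)
  expect_equal(d2@mapping$role, d@mapping$role)
  expect_equal(d2@mapping$atom, d@mapping$atom)
  expect_equal(d2@mapping$bead_radius, d@mapping$bead_radius)
})
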