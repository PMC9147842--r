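test_that("multi-MODEL PDB reading preserves counts, identities and numbering", {
  lines <- c(
    "MODEL        1",
    pdbAtomLine(1, "N", "ALA", "A", 46, 11.104, 6.134, -6.504, elem = "N"),
    pdbAtomLine(2, "CA", "ALA", "A", 46, 11.639, 6.071, -5.147, elem = "C"),
    pdbAtomLine(3, "CB", "ALA", "A", 46, 12.919, 6.898, -5.041, elem = "C"),
    pdbAtomLine(4, "N", "GLY", "A", 47, 10.000, 5.000, -4.000, elem = "N"),
    "ENDMDL",
    "MODEL        2",
    pdbAtomLine(1, "N", "ALA", "A", 46, 11.204, 6.134, -6.504, elem = "N"),
    pdbAtomLine(2, "CA", "ALA", "A", 46, 11.739, 6.071, -5.147, elem = "C"),
    pdbAtomLine(3, "CB", "ALA", "A", 46, 13.019, 6.898, -5.041, elem = "C"),
    pdbAtomLine(4, "N", "GLY", "A", 47, 10.100, 5.000, -4.000, elem = "N"),
    "ENDMDL",
    "MODEL        3",
    pdbAtomLine(1, "N", "ALA", "A", 46, 11.304, 6.134, -6.504, elem = "N"),
    pdbAtomLine(2, "CA", "ALA", "A", 46, 11.839, 6.071, -5.147, elem = "C"),
    pdbAtomLine(3, "CB", "ALA", "A", 46, 13.119, 6.898, -5.041, elem = "C"),
    pdbAtomLine(4, "N", "GLY", "A", 47, 10.200, 5.000, -4.000, elem = "N"),
    "ENDMDL", "END")
  tr <- readPDB(writeTempPDB(lines))
  expect_equal(nFrames(tr), 3L)
  r <- residues(tr)
  expect_equal(nrow(r), 2L)
  # author numbering is authoritative
  expect_equal(r$resno, c(46L, 47L))
  expect_equal(r$resname, c("ALA", "GLY"))
  a <- atoms(tr)
  expect_true(a$isBackbone[a$name == "CA"])
  expect_false(a$isBackbone[a$name == "CB"])
  # frame and atom order preserved: serials strictly increasing
  expect_true(all(diff(a$serial) > 0))
  expect_equal(coords(tr, 2)[1, ], c(11.204, 6.134, -6.504))
})

test_that("PDB reading rejects malformed inputs", {
  # inconsistent atom counts across MODELs
  bad <- c("MODEL        1",
           pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
           pdbAtomLine(2, "CB", "ALA", "A", 1, 1, 0, 0),
           "ENDMDL", "MODEL        2",
           pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
           "ENDMDL", "END")
  expect_error(readPDB(writeTempPDB(bad)), "inconsistent atom counts")
  # no coordinate records
  expect_error(readPDB(writeTempPDB(c("HEADER junk", "END"))), "no ATOM")
  # missing file
  expect_error(readPDB(tempfile()), "cannot read")
  # insertion codes rejected, not merged
  ins <- sub("A  46 ", "A  46A", pdbAtomLine(1, "CA", "ALA", "A", 46, 0, 0, 0))
  expect_error(readPDB(writeTempPDB(c(ins, "END"))), "insertion")
})

test_that("alternate locations resolve to highest occupancy, first on ties", {
  lines <- c(
    pdbAtomLine(1, "N", "ALA", "A", 1, 0, 0, 0, elem = "N"),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.4, alt = "A"),
    pdbAtomLine(3, "CA", "ALA", "A", 1, 2.0, 0, 0, occ = 0.6, alt = "B"),
    pdbAtomLine(4, "CB", "ALA", "A", 1, 3.0, 0, 0, occ = 0.5, alt = "A"),
    pdbAtomLine(5, "CB", "ALA", "A", 1, 4.0, 0, 0, occ = 0.5, alt = "B"),
    "END")
  tr <- readPDB(writeTempPDB(lines))
  a <- atoms(tr)
  expect_equal(nrow(a), 3L)
  xyz <- coords(tr, 1)
  expect_equal(xyz[a$name == "CA", 1], 2.0)  # higher occupancy wins
  expect_equal(xyz[a$name == "CB", 1], 3.0)  # tie: first encountered
})

test_that("waters are dropped by default and kept on request", {
  lines <- c(pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
             pdbAtomLine(2, "O", "HOH", "W", 1, 5, 0, 0, rec = "HETATM",
                         elem = "O"),
             "END")
  expect_equal(atomCount(readPDB(writeTempPDB(lines))), 1L)
  expect_equal(atomCount(readPDB(writeTempPDB(lines), keepWaters = TRUE)), 2L)
})

test_that("elements fall back to atom-name heuristics when the column is absent", {
  ln <- pdbAtomLine(1, "SD", "MET", "A", 1, 0, 0, 0)
  ln <- substr(ln, 1, 76)  # strip element columns
  ln2 <- substr(pdbAtomLine(2, "CG1", "VAL", "A", 2, 3, 0, 0), 1, 76)
  tr <- readPDB(writeTempPDB(c(ln, ln2, "END")))
  expect_equal(atoms(tr)$element, c("S", "C"))
})

test_that("trajectory concatenation checks atom counts and preserves order", {
  mk <- function(n, x0) {
    unlist(lapply(seq_len(n), function(f) c(
      sprintf("MODEL     %4d", f),
      pdbAtomLine(1, "CA", "ALA", "A", 1, x0 + f, 0, 0),
      pdbAtomLine(2, "CB", "ALA", "A", 1, x0 + f, 1, 0),
      "ENDMDL")))
  }
  f1 <- writeTempPDB(c(mk(5, 0), "END"))
  f2 <- writeTempPDB(c(mk(5, 100), "END"))
  topo <- readPDB(f1)@topology
  tr <- readTrajectory(topo, c(f1, f2), replicateId = "r1")
  expect_equal(nFrames(tr), 10L)
  expect_equal(coords(tr, 6)[1, 1], 101)  # path order respected
  # single-model file gives a 1-frame trajectory
  f3 <- writeTempPDB(c(pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
                       pdbAtomLine(2, "CB", "ALA", "A", 1, 1, 0, 0), "END"))
  expect_equal(nFrames(readTrajectory(topo, f3)), 1L)
  # mismatched atom count
  f4 <- writeTempPDB(c(pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0), "END"))
  expect_error(readTrajectory(topo, c(f1, f4)), "mismatch")
  expect_error(readTrajectory(topo, character(0)), "empty")
})

test_that("heavy-atom selection removes hydrogens always, backbone on demand", {
  topo <- pairTopology(c("N", "CA", "C", "O", "CB", "HB1", "HB2", "HB3"),
                       c("N", "CA", "C", "O", "HA"))
  a <- list(chain = "A", resno = 10L)
  b <- list(chain = "A", resno = 20L)
  expect_setequal(atoms(topo)$name[heavyAtoms(topo, "A", 10L)],
                  c("N", "CA", "C", "O", "CB"))
  expect_equal(atoms(topo)$name[heavyAtoms(topo, "A", 10L, excludeBackbone = TRUE)],
               "CB")
  # glycine-like residue: empty after backbone exclusion
  expect_length(heavyAtoms(topo, "A", 20L, excludeBackbone = TRUE), 0L)
})

test_that("PDB round trip preserves coordinates and identities", {
  set.seed(11)
  g <- generatePairSystem(syntheticSpec(nFrames = 12, seed = 5, f = 0.5,
                                        nPairs = 2))
  f <- tempfile(fileext = ".pdb")
  writePDB(g$trajectory, f)
  back <- readPDB(f)
  expect_equal(nFrames(back), 12L)
  expect_equal(atoms(back)$name, atoms(g$trajectory)$name)
  expect_equal(atoms(back)$resno, atoms(g$trajectory)$resno)
  expect_equal(atoms(back)$chain, atoms(g$trajectory)$chain)
  expect_equal(atoms(back)$element, atoms(g$trajectory)$element)
  expect_lt(max(abs(coords(back) - coords(g$trajectory))), 1e-3 + 1e-12)
  # write -> read -> write is a fixed point at field precision
  f2 <- tempfile(fileext = ".pdb")
  writePDB(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("result tables are written deterministically with header", {
  rec <- data.frame(pair_label = c("b", "a", "a"), frame_index = c(1L, 2L, 1L),
                    rrcs = c(0.123456789, 1.5, 2.25))
  f <- tempfile(fileext = ".csv")
  writeTable(rec, f)
  out <- readLines(f)
  expect_length(out, 4L)  # header + 3 records
  expect_match(out[1], "pair_label")
  back <- utils::read.csv(f)
  expect_equal(back$pair_label, c("a", "a", "b"))  # pair then frame order
  expect_equal(back$rrcs[1], signif(2.25, 6))
  # empty records give a header-only file
  f2 <- tempfile(fileext = ".csv")
  writeTable(rec[0, ], f2)
  expect_length(readLines(f2), 1L)
  # round trip preserves values at written precision
  expect_equal(back$rrcs, signif(c(2.25, 1.5, 0.123456789), 6))
})
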