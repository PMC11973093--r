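test_that("written complexes round-trip through the PDB format", {
  set.seed(21)
  cx <- randomFixture(11, decoyGroove = TRUE, anchors = c(2, 5, 7, 10))
  f <- tempfile(fileext = ".pdb")
  writePDB(cx, f)
  back <- readPDB(f, peptideChain = "P", anchors = c(2, 5, 7, 10))
  expect_identical(pepSequence(back), pepSequence(cx))
  a0 <- pepAtoms(cx); a1 <- pepAtoms(back)
  expect_identical(a1$elety, a0$elety)
  expect_identical(a1$resno, a0$resno)
  expect_lt(maxAtomShift(a0, a1), 1e-3)
  expect_lt(maxAtomShift(receptor(cx), receptor(back)), 1e-3)
  # TER between every chain (two receptor helices + peptide)
  expect_identical(sum(grepl("^TER", readLines(f))), 3L)
})

test_that("residue numbering is written as stored, not renumbered", {
  cx <- buildIdealPeptide(fixtureSpec("AAAA"))
  at <- pepAtoms(cx)
  at$resno <- at$resno + 100L
  cx@peptide@atoms <- at
  f <- tempfile(fileext = ".pdb")
  writePDB(cx, f)
  nums <- unique(as.integer(substr(grep("^ATOM", readLines(f), value = TRUE),
                                   23, 26)))
  expect_identical(sort(nums), c(101L, 102L, 103L, 104L))
})

test_that("written PDBs satisfy an independent third-party parser", {
  set.seed(22)
  cx <- randomFixture(9, decoyGroove = TRUE)
  f <- tempfile(fileext = ".pdb")
  writePDB(cx, f)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import gemmi; st = gemmi.read_structure('", f, "'); ",
    "print(st[0].count_atom_sites(), len(st[0]))"))),
    stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0L)
  counts <- as.integer(strsplit(tail(out, 1), " ")[[1]])
  expect_identical(counts[1], nrow(receptor(cx)) + nrow(pepAtoms(cx)))
  expect_identical(counts[2], 3L)   # chains A, B, P
})

test_that("degenerate and malformed inputs raise structure errors", {
  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(readPDB(empty), "parse|protein|chain")
  expect_error(readPDB(tempfile(fileext = ".pdb")), "not found")
  # no candidate peptide chain: single long chain only
  cx <- buildIdealPeptide(fixtureSpec(strrep("A", 31)))
  f <- tempfile(fileext = ".pdb")
  writePDB(cx, f)
  expect_error(readPDB(f), "candidate peptide")
})

test_that("a small fixture parses back exactly as built", {
  cx <- buildIdealPeptide(fixtureSpec("KGV"))
  f <- tempfile(fileext = ".pdb")
  writePDB(cx, f)
  back <- readPDB(f, peptideChain = "P")
  expect_identical(pepLength(back), 3L)
  expect_identical(pepSequence(back), "KGV")
})

test_that("peptide chain heuristic picks the shortest 8-30 residue chain", {
  set.seed(23)
  cx <- randomFixture(9, decoyGroove = TRUE)   # helices exceed 30 residues
  f <- tempfile(fileext = ".pdb")
  writePDB(cx, f)
  expect_identical(peptide(readPDB(f))@chainId, "P")
})

test_that("insertion codes in the peptide are rejected", {
  cx <- buildIdealPeptide(fixtureSpec("AAAAAAAAA"))
  f <- tempfile(fileext = ".pdb")
  writePDB(cx, f)
  lines <- readLines(f)
  i <- grep("^ATOM", lines)[3]
  substr(lines[i], 27, 27) <- "A"
  writeLines(lines, f)
  expect_error(readPDB(f, peptideChain = "P"), "insertion codes")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  cx <- buildIdealPeptide(fixtureSpec("AAAAAAAAA"))
  f <- tempfile(fileext = ".pdb")
  writePDB(cx, f)
  lines <- readLines(f)
  ca <- grep("^ATOM .*CA", lines)[1]
  mk <- function(alt, occ, x) {
    l <- lines[ca]
    substr(l, 17, 17) <- alt
    substr(l, 31, 38) <- sprintf("%8.3f", x)
    substr(l, 55, 60) <- sprintf("%6.2f", occ)
    l
  }
  lines <- append(lines, values = c(mk("B", 0.7, 99), mk("C", 0.2, 55)),
                  after = ca)
  lines[ca] <- mk("A", 0.1, 11)
  writeLines(lines, f)
  back <- readPDB(f, peptideChain = "P")
  at <- pepAtoms(back)
  expect_identical(sum(at$resno == 1 & at$elety == "CA"), 1L)
  expect_equal(at$x[at$resno == 1 & at$elety == "CA"], 99)
  # occupancy tie: altloc letter order wins
  lines[ca] <- mk("A", 0.7, 11)
  writeLines(lines, f)
  at <- pepAtoms(readPDB(f, peptideChain = "P"))
  expect_equal(at$x[at$resno == 1 & at$elety == "CA"], 11)
})

test_that("hydrogen stripping removes exactly the hydrogens, idempotently", {
  set.seed(24)
  cx <- randomFixture(10)
  cx <- addHydrogens(cx)
  at <- pepAtoms(cx)
  nH <- sum(at$elesy == "H")
  nHeavy <- sum(at$elesy != "H")
  expect_gt(nH, 0L)
  s1 <- stripHydrogens(cx)
  at1 <- pepAtoms(s1)
  expect_identical(nrow(at1), nHeavy)
  expect_identical(sum(at1$elesy == "H"), 0L)
  heavy <- at[at$elesy != "H", ]
  expect_identical(at1$x, heavy$x)
  expect_identical(at1$y, heavy$y)
  expect_identical(at1$z, heavy$z)
  expect_identical(pepAtoms(stripHydrogens(s1)), at1)
  # property over randomized fixtures: heavy count invariant
  for (i in 1:5) {
    cxi <- addHydrogens(randomFixture(sample(9:14, 1)))
    ati <- pepAtoms(cxi)
    expect_identical(nrow(pepAtoms(stripHydrogens(cxi))),
                     sum(ati$elesy != "H"))
  }
})

test_that("selenomethionine substitution renames MSE to MET in place", {
  cx <- buildIdealPeptide(fixtureSpec("KAMAK"))
  expect_identical(substituteMSE(cx), cx)    # no MSE: no-op
  at <- pepAtoms(cx)
  at$resid[at$resno == 3] <- "MSE"
  i <- which(at$resno == 3 & at$elety == "CB")
  at$elety[i] <- "SE"; at$elesy[i] <- "SE"
  xyz0 <- at[, c("x", "y", "z")]
  cx@peptide@atoms <- at
  out <- substituteMSE(cx)
  ato <- pepAtoms(out)
  expect_identical(unique(ato$resid[ato$resno == 3]), "MET")
  expect_identical(sum(ato$elety == "SE"), 0L)
  expect_identical(ato$elety[i], "SD")
  expect_identical(ato$elesy[i], "S")
  expect_identical(ato[, c("x", "y", "z")], xyz0)
  expect_identical(pepSequence(out), "KAMAK")
  expect_identical(pepAtoms(substituteMSE(out)), ato)
  # MSE lacking SE still renamed, with a warning
  cx2 <- buildIdealPeptide(fixtureSpec("KAMAK"))
  at2 <- pepAtoms(cx2)
  at2$resid[at2$resno == 3] <- "MSE"
  cx2@peptide@atoms <- at2
  expect_warning(out2 <- substituteMSE(cx2), "lacks an SE")
  expect_identical(pepSequence(out2), "KAMAK")
})

test_that("chain-break detection aborts on a torn backbone", {
  cx <- buildIdealPeptide(fixtureSpec("AAAAAAAAA"))
  expect_true(assertContinuous(peptide(cx)))
  at <- pepAtoms(cx)
  at$x[at$resno >= 5] <- at$x[at$resno >= 5] + 10
  cx@peptide@atoms <- at
  expect_error(assertContinuous(peptide(cx)), "chain break")
  expect_error(reversePeptide(cx), "chain break")
})
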