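test_that("renumbering inverts the sequence without touching coordinates", {
  # the two case-study peptides reported for reversed HLA-DP binders
  for (sq in c("KNLEKYKGKFVREID", "KVTVAFNQF")) {
    cx <- buildIdealPeptide(fixtureSpec(sq))
    out <- reverseNumbering(peptide(cx))
    expect_identical(pepSequence(out), revString(sq))
    a0 <- pepAtoms(cx); a1 <- atoms(out)
    expect_identical(sort(a1$x), sort(a0$x))
    expect_identical(maxAtomShift(a1[order(a1$resno), ],
                                  transform(a0, resno = nchar(sq) + 1L -
                                              resno)), 0)
  }
  expect_identical(
    pepSequence(reverseNumbering(peptide(
      buildIdealPeptide(fixtureSpec("KNLEKYKGKFVREID"))))),
    "DIERVFKGKYKELNK")
})

test_that("single-residue renumbering is the identity", {
  cx <- buildIdealPeptide(fixtureSpec("W"))
  out <- reverseNumbering(peptide(cx))
  expect_identical(pepSequence(out), "W")
  expect_identical(atoms(out)$x, pepAtoms(cx)$x)
})

test_that("backbone mirroring is the stated point inversion", {
  # CA(1)=(0,0,0), CA(2)=(3.8,0,0), O(1)=(1.2,1.9,0) -> O' = 2m - O
  df <- data.frame(
    resno = c(1, 1, 1, 1, 2, 2, 2, 2),
    resid = "GLY",
    elety = c("N", "CA", "C", "O", "N", "CA", "C", "O"),
    x = c(-1.0, 0.0, 1.4, 1.2, 2.6, 3.8, 4.9, 5.3),
    y = c(-0.8, 0.0, 0.6, 1.9, 0.4, 0.0, 0.9, 1.8),
    z = 0)
  ch <- chainFromAtoms(df)
  out <- atoms(mirrorBackbone(ch))
  o1 <- unlist(out[out$resno == 1 & out$elety == "O", c("x", "y", "z")],
               use.names = FALSE)
  expect_equal(o1, c(2 * 1.9 - 1.2, -1.9, 0))
  # CA untouched, terminal N(1), C(2), O(2) untouched
  for (sel in list(c(1, "CA"), c(2, "CA"), c(1, "N"), c(2, "C"),
                   c(2, "O"))) {
    i0 <- df$resno == as.integer(sel[1]) & df$elety == sel[2]
    i1 <- out$resno == as.integer(sel[1]) & out$elety == sel[2]
    expect_identical(c(out$x[i1], out$y[i1], out$z[i1]),
                     c(df$x[i0], df$y[i0], df$z[i0]))
  }
})

test_that("mirroring twice restores every atom bitwise", {
  set.seed(41)
  pep <- peptide(randomFixture(12))
  twice <- mirrorBackbone(mirrorBackbone(pep))
  expect_equal(atoms(twice)$x, atoms(pep)$x)
  expect_equal(atoms(twice)$y, atoms(pep)$y)
  expect_equal(atoms(twice)$z, atoms(pep)$z)
})

test_that("mirrored atoms stay in the local peptide plane", {
  set.seed(42)
  cx <- randomFixture(15)
  a0 <- pepAtoms(cx)
  a1 <- atoms(mirrorBackbone(peptide(cx)))
  g <- function(at, r, nm) unlist(at[at$resno == r & at$elety == nm,
                                     c("x", "y", "z")], use.names = FALSE)
  for (i in 1:14) {
    # brute-force best-fit plane of the five peptide-plane atoms
    pts <- rbind(g(a0, i, "CA"), g(a0, i, "C"), g(a0, i, "O"),
                 g(a0, i + 1, "N"), g(a0, i + 1, "CA"))
    ctr <- colMeans(pts)
    nrm <- svd(sweep(pts, 2, ctr))$v[, 3]
    for (sel in list(c(i, "C"), c(i, "O"), c(i + 1, "N"))) {
      r <- as.integer(sel[1])
      d0 <- abs(sum((g(a0, r, sel[2]) - ctr) * nrm))
      d1 <- abs(sum((g(a1, r, sel[2]) - ctr) * nrm))
      expect_lt(abs(d1 - d0), 0.15)
    }
  }
})

test_that("missing backbone atoms abort the mirror with the residue named", {
  cx <- buildIdealPeptide(fixtureSpec("AAAA"))
  at <- pepAtoms(cx)
  cx@peptide@atoms <- at[!(at$resno == 3 & at$elety == "O"), ]
  expect_error(mirrorBackbone(peptide(cx)), "residue 3")
})

test_that("reassignment conserves atoms and restores bonded C-N distances", {
  set.seed(43)
  cx <- randomFixture(10)
  pep0 <- reverseNumbering(peptide(cx))
  counts0 <- table(atoms(pep0)$resno)
  pep <- reassignAtoms(mirrorBackbone(pep0))
  at <- atoms(pep)
  expect_identical(nrow(at), nrow(atoms(pep0)))        # exact conservation
  counts1 <- table(at$resno)
  interior <- as.character(2:9)
  expect_identical(counts1[interior], counts0[interior])
  # every interior residue owns exactly one N, CA, C, O
  for (r in 2:9)
    for (nm in c("N", "CA", "C", "O"))
      expect_identical(sum(at$resno == r & at$elety == nm & !at$stale), 1L)
  # new peptide bonds are chemically short
  g <- function(r, nm) unlist(at[at$resno == r & at$elety == nm & !at$stale,
                                 c("x", "y", "z")][1, ], use.names = FALSE)
  for (r in 1:9)
    expect_lt(sqrt(sum((g(r, "C") - g(r + 1, "N"))^2)), 2.0)
  expect_error(reassignAtoms(pep0), "mirrorBackbone")
})

test_that("terminal groups are removed and regenerated at the right ends", {
  set.seed(44)
  cx <- randomFixture(9)
  pep <- reassignAtoms(mirrorBackbone(reverseNumbering(peptide(cx))))
  tm <- rebuildTermini(pep)
  at <- atoms(tm$chain)
  L <- 9L
  # exactly one OXT, at the new C-terminal residue
  expect_identical(sum(at$elety == "OXT"), 1L)
  expect_identical(at$resno[at$elety == "OXT"], L)
  # old terminal residue (now residue 1) retains N, CA, C, O and no OXT
  expect_setequal(intersect(at$elety[at$resno == 1],
                            c("N", "CA", "C", "O", "OXT")),
                  c("N", "CA", "C", "O"))
  g <- function(r, nm) unlist(at[at$resno == r & at$elety == nm,
                                 c("x", "y", "z")], use.names = FALSE)
  # OXT bonded to the terminal carbonyl carbon, in the carboxylate plane
  dOXT <- sqrt(sum((g(L, "OXT") - g(L, "C"))^2))
  expect_gt(dOXT, 1.2); expect_lt(dOXT, 1.35)
  pl <- planeFromPoints(g(L, "CA"), g(L, "C"), g(L, "O"))
  expect_lt(abs(sum((g(L, "OXT") - pl$origin) * pl$normal)), 0.1)
})

test_that("an input without OXT still gains exactly one at the new terminus", {
  cx <- buildIdealPeptide(fixtureSpec("KAVLFKAVQ"))
  at <- pepAtoms(cx)
  cx@peptide@atoms <- at[at$elety != "OXT", ]
  pep <- reassignAtoms(mirrorBackbone(reverseNumbering(peptide(cx))))
  out <- atoms(rebuildTermini(pep)$chain)
  expect_identical(sum(out$elety == "OXT"), 1L)
  expect_identical(out$resno[out$elety == "OXT"], 9L)
})

test_that("chirality correction reflects only D alpha-carbons", {
  set.seed(45)
  cx <- randomFixture(12)
  at <- pepAtoms(cx)
  # all-L input: no residue moves
  out <- fixChirality(peptide(cx))
  expect_identical(out$fixed, integer(0))
  expect_identical(atoms(out$chain)$x, at$x)
  # an injected D residue is repaired, and the CA moves by twice its
  # plane distance
  g <- function(a, r, nm) unlist(a[a$resno == r & a$elety == nm,
                                   c("x", "y", "z")], use.names = FALSE)
  r <- which(strsplit(pepSequence(cx), "")[[1]] != "G")[3]
  pl <- planeFromPoints(g(at, r, "N"), g(at, r, "C"), g(at, r, "CB"))
  ca <- g(at, r, "CA")
  i <- which(at$resno == r & at$elety == "CA")
  p <- reflectAcrossPlane(ca, pl)
  at$x[i] <- p[1]; at$y[i] <- p[2]; at$z[i] <- p[3]   # now D
  ch <- new("PeptideChain", chainId = "P", atoms = at)
  expect_identical(chiralityOf(at[at$resno == r, ]), "D")
  fixed <- fixChirality(ch)
  expect_identical(fixed$fixed, as.integer(r))
  af <- atoms(fixed$chain)
  expect_identical(chiralityOf(af[af$resno == r, ]), "L")
  dPlane <- abs(sum((p - pl$origin) * pl$normal))
  expect_equal(sqrt(sum((g(af, r, "CA") - p)^2)), 2 * dPlane,
               tolerance = 1e-6)
  # glycine coordinates are never touched
  gly <- which(strsplit(pepSequence(cx), "")[[1]] == "G")[1]
  expect_identical(g(af, gly, "CA"), g(at, gly, "CA"))
})

test_that("a non-glycine residue without CB stops the chirality fix", {
  cx <- buildIdealPeptide(fixtureSpec("AAAA"))
  at <- pepAtoms(cx)
  cx@peptide@atoms <- at[!(at$resno == 2 & at$elety == "CB"), ]
  expect_error(fixChirality(peptide(cx)), "CB")
})

test_that("proline rings are rebuilt closed, trans, with backbone untouched", {
  set.seed(46)
  cx <- buildIdealPeptide(fixtureSpec("KAPGPAVLK"))
  pep <- peptide(cx)
  at0 <- atoms(pep)
  # scramble the ring atoms, then rebuild
  i <- which(at0$resno %in% c(3, 5) & at0$elety %in% c("CB", "CG", "CD"))
  at1 <- at0
  at1$x[i] <- at1$x[i] + runif(length(i), -1, 1)
  out <- rebuildProline(new("PeptideChain", chainId = "P", atoms = at1))
  expect_identical(out$rebuilt, c(3L, 5L))
  at2 <- atoms(out$chain)
  g <- function(a, r, nm) unlist(a[a$resno == r & a$elety == nm,
                                   c("x", "y", "z")], use.names = FALSE)
  for (r in c(3, 5)) {
    d <- function(a, b) sqrt(sum((a - b)^2))
    dbg <- d(g(at2, r, "CB"), g(at2, r, "CG"))
    expect_gt(dbg, 1.45); expect_lt(dbg, 1.60)
    dgd <- d(g(at2, r, "CG"), g(at2, r, "CD"))
    expect_gt(dgd, 1.45); expect_lt(dgd, 1.60)
    dnd <- d(g(at2, r, "N"), g(at2, r, "CD"))
    expect_gt(dnd, 1.40); expect_lt(dnd, 1.60)
    for (nm in c("N", "CA", "C", "O"))
      expect_identical(g(at2, r, nm), g(at0, r, nm))
  }
})

test_that("omega of bonds preceding prolines stays trans through the pipeline", {
  set.seed(47)
  cx <- buildIdealPeptide(fixtureSpec("KAPLVGPQK",
                                      phi = runif(9, -140, -70),
                                      psi = runif(9, 110, 160)))
  rv <- reversePeptide(cx)
  md <- measureBackboneDihedrals(rv$complex)
  sq <- strsplit(pepSequence(rv$complex), "")[[1]]
  pro <- which(sq == "P")
  for (p in pro[pro > 1]) {
    dev <- abs(((md$omega[p - 1] - 180 + 180) %% 360) - 180)
    expect_lt(dev, 30)
  }
})

test_that("anchor renumbering is the pocket-preserving involution", {
  expect_identical(reverseAnchors(c(1, 4, 6, 9), 9), c(1L, 4L, 6L, 9L))
  expect_identical(reverseAnchors(c(3, 6, 8, 11), 15), c(5L, 8L, 10L, 13L))
  set.seed(48)
  for (i in 1:10) {
    L <- sample(9:20, 1)
    a <- sort(sample(L, 4))
    expect_identical(reverseAnchors(reverseAnchors(a, L), L), a)
  }
  expect_error(reverseAnchors(c(0, 4), 9), "\\[1, 9\\]")
  expect_error(reverseAnchors(c(4, 10), 9), "\\[1, 9\\]")
})

test_that("the full reversal meets its composed contract", {
  set.seed(49)
  for (i in 1:3) {
    cx <- randomFixture(sample(9:16, 1), anchors = c(2, 5, 7, 10))
    sq <- pepSequence(cx)
    L <- pepLength(cx)
    at0 <- pepAtoms(cx)
    rv <- reversePeptide(cx)
    out <- rv$complex
    expect_identical(pepSequence(out), revString(sq))
    expect_identical(anchors(out),
                     sort(L + 1L - c(2L, 5L, 7L, 10L)))
    qc <- validateGeometry(out)
    expect_identical(unname(qc@violations[["chirality"]]), 0L)
    # alpha carbons unmoved through renumber/mirror/reassign/termini
    mid <- rebuildTermini(reassignAtoms(mirrorBackbone(
      reverseNumbering(peptide(cx)))))$chain
    ca0 <- at0[at0$elety == "CA", ]
    ca1 <- atoms(mid)[atoms(mid)$elety == "CA", ]
    ca1 <- ca1[order(ca1$resno), ]
    ca0 <- transform(ca0, resno = L + 1L - resno)
    ca0 <- ca0[order(ca0$resno), ]
    expect_identical(ca1$x, ca0$x)
    expect_identical(ca1$y, ca0$y)
    expect_identical(ca1$z, ca0$z)
    # heavy atoms conserved up to the OXT bookkeeping
    expect_lte(abs(nrow(pepAtoms(out)) - nrow(at0)), 1L)
    # the peptide stays in the groove
    c0 <- colMeans(as.matrix(ca0[, c("x", "y", "z")]))
    caf <- pepAtoms(out)
    c1 <- colMeans(as.matrix(caf[caf$elety == "CA", c("x", "y", "z")]))
    expect_lt(sqrt(sum((c1 - c0)^2)), 1.0)
  }
})

test_that("side chains beyond the CB frame are never moved before regularization", {
  set.seed(50)
  cx <- randomFixture(11)
  at0 <- pepAtoms(cx)
  rv <- reversePeptide(cx, regularize = FALSE)
  at1 <- pepAtoms(rv$complex)
  L <- 11L
  sc0 <- at0[!at0$elety %in% c("N", "CA", "C", "O", "OXT") &
               at0$resid != "PRO", ]
  sc1 <- at1[!at1$elety %in% c("N", "CA", "C", "O", "OXT") &
               at1$resid != "PRO", ]
  sc0$resno <- L + 1L - sc0$resno
  expect_identical(maxAtomShift(sc0, sc1), 0)
})

test_that("reversal report captures the step-by-step diagnostics", {
  set.seed(51)
  cx <- randomFixture(10, anchors = c(2, 5, 7, 10))
  rv <- reversePeptide(cx)
  rep <- rv$report
  expect_identical(unname(rep@stepDisplacements["renumber"]), 0)
  expect_gt(rep@stepDisplacements[["mirror"]], 1)
  expect_gt(length(rep@chiralityFixed), 0L)
  expect_identical(rep@anchorMap[, "new"],
                   11L - rep@anchorMap[, "old"])
  expect_false(is.na(rep@regularizationRMSD))
  expect_output(show(rep), "ReversalReport")
})
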