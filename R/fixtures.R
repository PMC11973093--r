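## Ideal covalent geometry used by the chain builder, the terminus and
## proline rebuilds, and the regularizer's target values.  Bond lengths in
## Angstrom, angles/torsions in degrees.
.IDEAL <- list(
  b = c(`N-CA` = 1.458, `CA-C` = 1.525, `C-N` = 1.329, `C-O` = 1.231,
        `CA-CB` = 1.521, `C-OXT` = 1.25,
        `CB-CG` = 1.495, `CG-CD` = 1.507, `CD-N` = 1.521),
  a = c(`N-CA-C` = 111.2, `CA-C-N` = 116.2, `C-N-CA` = 121.7,
        `CA-C-O` = 120.8, `O-C-N` = 123.0, `N-CA-CB` = 110.4,
        `C-CA-CB` = 110.1, `CA-C-OXT` = 118.0, `O-C-OXT` = 121.2,
        `CA-CB-CG` = 104.5, `CB-CG-CD` = 106.1, `CG-CD-N` = 105.1,
        `CD-N-CA` = 103.9),
  ## improper torsion N-C-CA-CB fixing the L configuration at CA
  cbImproper = 122.6,
  ## pyrrolidine ring torsions (chi1 = N-CA-CB-CG, chi2 = CA-CB-CG-CD)
  ## solved once for exact ring closure on the ideal backbone frame
  proChi1 = 0.0, proChi2 = 19.26)

.elementOf <- function(elety) {
  e <- sub("^[0-9]+", "", elety)
  substr(e, 1L, 1L)
}

#' Create a fixture specification
#'
#' @param sequence one-letter amino-acid string.
#' @param phi,psi,omega backbone dihedrals in degrees, recycled to the
#'   sequence length; defaults are an extended polyproline-II-like strand
#'   with trans peptide bonds.
#' @param placement optional list(rotation = 3x3, translation = length 3)
#'   applied rigidly after building.
#' @param decoyGroove if TRUE, add a rigid dummy receptor: two short
#'   poly-alanine helices (chains A and B) flanking the peptide, standing in
#'   for the MHC groove walls in receptor-frame tests.
#' @return a [FixtureSpec-class].
#' @export
fixtureSpec <- function(sequence, phi = -75, psi = 145, omega = 180,
                        placement = list(), decoyGroove = FALSE) {
  n <- nchar(sequence)
  new("FixtureSpec", sequence = toupper(sequence),
      phi = rep_len(phi, n), psi = rep_len(psi, n),
      omega = rep_len(omega, n), placement = placement,
      decoyGroove = decoyGroove)
}

## grow backbone + CB (+ proline ring) by sequential NeRF placement;
## returns an atom table in N->C order numbered 1..L
.growChain <- function(seq1, phi, psi, omega, chainId) {
  L <- nchar(seq1)
  letters1 <- strsplit(seq1, "")[[1]]
  res3 <- unname(.AA3[letters1])
  if (anyNA(res3)) .stopf("unknown residue letter in '%s'", seq1)
  id <- .IDEAL
  rows <- list()
  add <- function(resno, resid, elety, p)
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chainId, resno = resno, resid = resid, insert = "",
      elety = elety, elesy = .elementOf(elety), alt = "",
      x = p[1L], y = p[2L], z = p[3L], o = 1, b = 0,
      stringsAsFactors = FALSE)

  N <- c(0, 0, 0)
  CA <- c(id$b[["N-CA"]], 0, 0)
  th <- (180 - id$a[["N-CA-C"]]) * pi / 180
  C <- CA + id$b[["CA-C"]] * c(cos(th), sin(th), 0)
  for (i in seq_len(L)) {
    add(i, res3[i], "N", N)
    add(i, res3[i], "CA", CA)
    if (res3[i] != "GLY") {
      CB <- .placeAtom(N, C, CA, id$b[["CA-CB"]], id$a[["C-CA-CB"]],
                       id$cbImproper)
      add(i, res3[i], "CB", CB)
      if (res3[i] == "PRO") {
        CG <- .placeAtom(N, CA, CB, id$b[["CB-CG"]], id$a[["CA-CB-CG"]],
                         id$proChi1)
        CD <- .placeAtom(CA, CB, CG, id$b[["CG-CD"]], id$a[["CB-CG-CD"]],
                         id$proChi2)
        add(i, res3[i], "CG", CG)
        add(i, res3[i], "CD", CD)
      }
    }
    add(i, res3[i], "C", C)
    O <- .placeAtom(N, CA, C, id$b[["C-O"]], id$a[["CA-C-O"]], psi[i] + 180)
    add(i, res3[i], "O", O)
    if (i < L) {
      Nn <- .placeAtom(N, CA, C, id$b[["C-N"]], id$a[["CA-C-N"]], psi[i])
      CAn <- .placeAtom(CA, C, Nn, id$b[["N-CA"]], id$a[["C-N-CA"]],
                        omega[i])
      Cn <- .placeAtom(C, Nn, CAn, id$b[["CA-C"]], id$a[["N-CA-C"]],
                       phi[i + 1L])
      N <- Nn; CA <- CAn; C <- Cn
    } else {
      OXT <- .placeAtom(N, CA, C, id$b[["C-OXT"]], id$a[["CA-C-OXT"]],
                        psi[i])
      add(i, res3[i], "OXT", OXT)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.applyRigid <- function(at, rotation, translation) {
  m <- .xyz(at) %*% t(rotation)
  m <- sweep(m, 2L, translation, "+")
  .setXyz(at, m)
}

## align helix principal axis to v1 and drop it at centroid + offset
.placeDecoyHelix <- function(helix, pepCA, offsetDir, offset) {
  h <- .xyz(helix[helix$elety == "CA", , drop = FALSE])
  hc <- colMeans(h)
  h1 <- svd(sweep(h, 2L, hc))$v[, 1L]
  pc <- colMeans(pepCA)
  v1 <- svd(sweep(pepCA, 2L, pc))$v[, 1L]
  ## minimal rotation taking h1 onto v1
  axis <- .cross(h1, v1)
  s <- sqrt(sum(axis^2))
  cth <- sum(h1 * v1)
  R <- if (s < 1e-9) diag(3) * sign(cth) else {
    k <- axis / s
    K <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0), 3L)
    diag(3) + s * K + (1 - cth) * (K %*% K)
  }
  at <- .applyRigid(helix, R, c(0, 0, 0))
  hc2 <- colMeans(.xyz(at[at$elety == "CA", , drop = FALSE]))
  .applyRigid(at, diag(3), pc + offset * offsetDir - hc2)
}

#' Build an ideal-geometry synthetic peptide (-MHC) fixture
#'
#' Grows a peptide chain by sequential internal-coordinate placement
#' (standard bond lengths and angles; CB placed with natural L chirality;
#' proline carries its pyrrolidine ring) and wraps it in a
#' [PMHCComplex-class].  With `decoyGroove = TRUE` two rigid poly-alanine
#' helices are added as receptor chains A and B, flanking the peptide, so
#' that receptor-superposition and receptor-fixing contracts can be tested
#' without an experimental structure.
#'
#' @param spec a [FixtureSpec-class] from [fixtureSpec()].
#' @param anchors optional anchor positions stored on the complex.
#' @param chainId peptide chain identifier (default "P").
#' @param sourceId provenance label (default "synthetic").
#' @return a [PMHCComplex-class].
#' @examples
#' cx <- buildIdealPeptide(fixtureSpec("GAVLK"))
#' pepSequence(cx)
#' @export
buildIdealPeptide <- function(spec, anchors = integer(),
                              chainId = "P", sourceId = "synthetic") {
  validObject(spec)
  at <- .growChain(spec@sequence, spec@phi, spec@psi, spec@omega, chainId)
  rec <- .emptyAtomTable()
  if (spec@decoyGroove) {
    ## 32-mer poly-Ala helices: long enough that the shortest-chain
    ## peptide heuristic can never mistake a groove wall for the ligand
    helix <- .growChain(paste(rep("A", 32L), collapse = ""),
                        rep(-57, 32L), rep(-47, 32L), rep(180, 32L), "A")
    pepCA <- .xyz(at[at$elety == "CA", , drop = FALSE])
    pc <- colMeans(pepCA)
    v2 <- svd(sweep(pepCA, 2L, pc))$v[, 2L]
    hA <- .placeDecoyHelix(helix, pepCA, v2, 9)
    hB <- helix; hB$chain <- "B"
    hB <- .placeDecoyHelix(hB, pepCA, -v2, 9)
    rec <- rbind(hA, hB)
  }
  if (length(spec@placement)) {
    at <- .applyRigid(at, spec@placement$rotation, spec@placement$translation)
    if (nrow(rec))
      rec <- .applyRigid(rec, spec@placement$rotation,
                         spec@placement$translation)
  }
  new("PMHCComplex", receptor = rec,
      peptide = new("PeptideChain", chainId = chainId, atoms = at),
      anchors = as.integer(anchors), sourceId = sourceId)
}

#' Measure backbone dihedrals of a peptide chain
#'
#' Returns per-residue phi/psi/omega in degrees.  phi of residue 1 is NA;
#' psi of the last residue is measured to OXT when present (the terminal
#' carboxylate takes the place of the next amide nitrogen), else NA; omega
#' of residue i is the peptide bond between residues i and i+1 (NA for the
#' last residue).
#'
#' @param x a [PeptideChain-class] or [PMHCComplex-class].
#' @return data.frame with columns resno, phi, psi, omega.
#' @export
measureBackboneDihedrals <- function(x) {
  at <- if (is(x, "PMHCComplex")) x@peptide@atoms else x@atoms
  rn <- .resOrder(at)
  L <- length(rn)
  out <- data.frame(resno = rn, phi = NA_real_, psi = NA_real_,
                    omega = NA_real_)
  for (i in seq_len(L)) {
    N <- .pos(at, rn[i], "N"); CA <- .pos(at, rn[i], "CA")
    C <- .pos(at, rn[i], "C")
    if (i > 1L) {
      Cp <- .pos(at, rn[i - 1L], "C")
      if (!is.null(Cp)) out$phi[i] <- dihedralAngle(Cp, N, CA, C)
    }
    nxt <- if (i < L) .pos(at, rn[i + 1L], "N") else .pos(at, rn[i], "OXT")
    if (!is.null(nxt)) out$psi[i] <- dihedralAngle(N, CA, C, nxt)
    if (i < L) {
      Nn <- .pos(at, rn[i + 1L], "N"); CAn <- .pos(at, rn[i + 1L], "CA")
      if (!is.null(Nn) && !is.null(CAn))
        out$omega[i] <- dihedralAngle(CA, C, Nn, CAn)
    }
  }
  out
}
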