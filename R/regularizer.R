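## Restrained geometry regularization of the reversed peptide.  The
## internal engine is a deterministic steepest descent with backtracking
## line search on bonded terms only -- bond lengths, bond angles,
## omega/carbonyl planarity and an alpha-carbon chirality hinge -- with the
## receptor excluded from the coordinate vector and therefore fixed
## exactly.  Nonbonded terms are deliberately absent: this step exists to
## repair the small covalent distortions left by the coordinate surgery,
## not to relax packing, and the drift cap bounds how far the peptide may
## move.

## row-wise cross product of n x 3 matrices
.vcross <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

.vnorm <- function(A) sqrt(rowSums(A^2))

## assemble bonded-term index lists for a peptide atom table; indices are
## row numbers into the atom table
.bondedTerms <- function(at) {
  rn <- .resOrder(at)
  id <- .IDEAL
  ix <- function(r, nm) {
    i <- which(at$resno == r & at$elety == nm)
    if (length(i)) i[1L] else NA_integer_
  }
  bonds <- list(); angles <- list(); dihedrals <- list(); chir <- list()
  bond <- function(i, j, r0) if (!is.na(i) && !is.na(j))
    bonds[[length(bonds) + 1L]] <<- c(i, j, r0)
  angle <- function(i, j, k, a0) if (!anyNA(c(i, j, k)))
    angles[[length(angles) + 1L]] <<- c(i, j, k, a0 * pi / 180)
  dihed <- function(i, j, k, l, t0) if (!anyNA(c(i, j, k, l)))
    dihedrals[[length(dihedrals) + 1L]] <<- c(i, j, k, l, t0 * pi / 180)
  for (q in seq_along(rn)) {
    r <- rn[q]
    res <- at$resid[match(r, at$resno)]
    N <- ix(r, "N"); CA <- ix(r, "CA"); C <- ix(r, "C"); O <- ix(r, "O")
    CB <- ix(r, "CB"); OXT <- ix(r, "OXT")
    bond(N, CA, id$b[["N-CA"]]); bond(CA, C, id$b[["CA-C"]])
    bond(C, O, id$b[["C-O"]])
    angle(N, CA, C, id$a[["N-CA-C"]])
    angle(CA, C, O, id$a[["CA-C-O"]])
    if (!is.na(CB)) {
      bond(CA, CB, id$b[["CA-CB"]])
      angle(N, CA, CB, id$a[["N-CA-CB"]])
      angle(C, CA, CB, id$a[["C-CA-CB"]])
      chir[[length(chir) + 1L]] <- c(N, CA, C, CB)
    }
    if (!is.na(OXT)) {
      bond(C, OXT, id$b[["C-OXT"]])
      angle(CA, C, OXT, id$a[["CA-C-OXT"]])
      angle(O, C, OXT, id$a[["O-C-OXT"]])
    }
    if (res == "PRO") {
      CG <- ix(r, "CG"); CD <- ix(r, "CD")
      bond(CB, CG, id$b[["CB-CG"]]); bond(CG, CD, id$b[["CG-CD"]])
      bond(CD, N, id$b[["CD-N"]])
      angle(CA, CB, CG, id$a[["CA-CB-CG"]])
      angle(CB, CG, CD, id$a[["CB-CG-CD"]])
      angle(CG, CD, N, id$a[["CG-CD-N"]])
      angle(CD, N, CA, id$a[["CD-N-CA"]])
    }
    if (q < length(rn)) {
      rr <- rn[q + 1L]
      Nn <- ix(rr, "N"); CAn <- ix(rr, "CA")
      bond(C, Nn, id$b[["C-N"]])
      angle(CA, C, Nn, id$a[["CA-C-N"]])
      angle(O, C, Nn, id$a[["O-C-N"]])
      angle(C, Nn, CAn, id$a[["C-N-CA"]])
      dihed(CA, C, Nn, CAn, 180)          # omega, trans
      dihed(CA, Nn, C, O, 180)            # carbonyl planarity improper
    }
  }
  list(bonds = do.call(rbind, bonds), angles = do.call(rbind, angles),
       dihedrals = do.call(rbind, dihedrals), chir = do.call(rbind, chir))
}

## energy and gradient of the bonded penalty at coordinates p (n x 3)
.bondedEnergy <- function(p, tm, cfg, grad = TRUE) {
  E <- 0
  G <- if (grad) matrix(0, nrow(p), 3L) else NULL
  scatter <- function(idx, contrib) {
    agg <- rowsum(contrib, idx)
    ii <- as.integer(rownames(agg))
    G[ii, ] <<- G[ii, ] + agg
  }
  if (!is.null(tm$bonds)) {
    i <- tm$bonds[, 1L]; j <- tm$bonds[, 2L]; r0 <- tm$bonds[, 3L]
    dv <- p[i, , drop = FALSE] - p[j, , drop = FALSE]
    d <- .vnorm(dv)
    E <- E + cfg@kBond * sum((d - r0)^2)
    if (grad) {
      gi <- (2 * cfg@kBond * (d - r0) / d) * dv
      scatter(c(i, j), rbind(gi, -gi))
    }
  }
  if (!is.null(tm$angles)) {
    a <- tm$angles[, 1L]; b <- tm$angles[, 2L]; k <- tm$angles[, 3L]
    th0 <- tm$angles[, 4L]
    u <- p[a, , drop = FALSE] - p[b, , drop = FALSE]
    v <- p[k, , drop = FALSE] - p[b, , drop = FALSE]
    nu <- .vnorm(u); nv <- .vnorm(v)
    h <- pmin(pmax(rowSums(u * v) / (nu * nv), -1), 1)
    th <- acos(h)
    E <- E + cfg@kAngle * sum((th - th0)^2)
    if (grad) {
      s <- pmax(sqrt(1 - h^2), 1e-8)
      uh <- u / nu; vh <- v / nv
      dta <- (h * uh - vh) / (nu * s)
      dtk <- (h * vh - uh) / (nv * s)
      w <- 2 * cfg@kAngle * (th - th0)
      scatter(c(a, k, b), rbind(w * dta, w * dtk, -w * (dta + dtk)))
    }
  }
  if (!is.null(tm$dihedrals)) {
    i1 <- tm$dihedrals[, 1L]; i2 <- tm$dihedrals[, 2L]
    i3 <- tm$dihedrals[, 3L]; i4 <- tm$dihedrals[, 4L]
    t0 <- tm$dihedrals[, 5L]
    b1 <- p[i2, , drop = FALSE] - p[i1, , drop = FALSE]
    b2 <- p[i3, , drop = FALSE] - p[i2, , drop = FALSE]
    b3 <- p[i4, , drop = FALSE] - p[i3, , drop = FALSE]
    n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
    nb2 <- .vnorm(b2)
    m1 <- .vcross(n1, b2 / nb2)
    phi <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
    E <- E + cfg@kPlanarity * sum(1 - cos(phi - t0))
    if (grad) {
      dphi <- cfg@kPlanarity * sin(phi - t0)
      ga <- (nb2 / rowSums(n1^2)) * n1
      gd <- -(nb2 / rowSums(n2^2)) * n2
      f1 <- rowSums(b1 * b2) / nb2^2
      f3 <- rowSums(b3 * b2) / nb2^2
      gb <- -(1 + f1) * ga + f3 * gd
      gc <- -(ga + gb + gd)
      scatter(c(i1, i2, i3, i4),
              rbind(dphi * ga, dphi * gb, dphi * gc, dphi * gd))
    }
  }
  if (!is.null(tm$chir)) {
    iN <- tm$chir[, 1L]; iCA <- tm$chir[, 2L]
    iC <- tm$chir[, 3L]; iCB <- tm$chir[, 4L]
    u <- p[iN, , drop = FALSE] - p[iCA, , drop = FALSE]
    v <- p[iC, , drop = FALSE] - p[iCA, , drop = FALSE]
    w <- p[iCB, , drop = FALSE] - p[iCA, , drop = FALSE]
    D <- rowSums(u * .vcross(v, w))
    hinge <- pmin(D - 1.0, 0)            # L form keeps det well above zero
    E <- E + cfg@kChirality * sum(hinge^2)
    if (grad && any(hinge < 0)) {
      f <- 2 * cfg@kChirality * hinge
      gN <- f * .vcross(v, w)
      gC <- f * .vcross(w, u)
      gB <- f * .vcross(u, v)
      scatter(c(iN, iC, iCB, iCA), rbind(gN, gC, gB, -(gN + gC + gB)))
    }
  }
  list(E = E, G = G)
}

## residual summary against the regularizer's own targets
.bondedResiduals <- function(p, tm) {
  out <- c(bond = 0, angle = 0, omega = 0)
  if (!is.null(tm$bonds)) {
    d <- .vnorm(p[tm$bonds[, 1L], , drop = FALSE] -
                p[tm$bonds[, 2L], , drop = FALSE])
    out["bond"] <- max(abs(d - tm$bonds[, 3L]))
  }
  if (!is.null(tm$angles)) {
    u <- p[tm$angles[, 1L], , drop = FALSE] - p[tm$angles[, 2L], , drop = FALSE]
    v <- p[tm$angles[, 3L], , drop = FALSE] - p[tm$angles[, 2L], , drop = FALSE]
    h <- pmin(pmax(rowSums(u * v) / (.vnorm(u) * .vnorm(v)), -1), 1)
    out["angle"] <- max(abs(acos(h) - tm$angles[, 4L])) * 180 / pi
  }
  out
}

#' Restore ideal bonded geometry of the peptide, receptor held fixed
#'
#' Minimizes a bonded-term penalty (bond lengths, bond angles, trans-omega
#' and carbonyl planarity, plus an L-chirality hinge on every alpha carbon)
#' over the peptide atoms by steepest descent with a backtracking
#' (Armijo) line search.  The penalty is non-increasing across iterations
#' by construction and the algorithm is fully deterministic.  Receptor
#' atoms are not part of the coordinate vector, so receptor fixing is
#' exact.  Minimization stops when bonds are within 0.03 A and angles
#' within 3 degrees of ideal, when the iteration budget is exhausted, or
#' when one more step would push the peptide-backbone RMSD past the drift
#' cap.
#'
#' @param x a [PMHCComplex-class].
#' @param cfg a [RegularizerConfig-class]; `cfg@engine = "external-MD"`
#'   delegates to `adapter`.
#' @param adapter for the external engine only: a
#'   `function(pdbIn, pdbOut, peptideChain, cfg)` contract writing the
#'   relaxed structure to `pdbOut` with the receptor unmoved.
#' @return list with `complex`, `drift` (peptide-backbone RMSD moved, A),
#'   `residuals` (max bond/angle deviation after the run) and `energies`
#'   (the penalty value after each accepted iteration).
#' @export
regularizeGeometry <- function(x, cfg = regularizerConfig(), adapter = NULL) {
  validObject(cfg)
  if (cfg@engine == "external-MD") {
    if (is.null(adapter))
      .stopf("external-MD engine requested but no adapter supplied")
    return(.runAdapter(x, cfg, adapter))
  }
  at <- x@peptide@atoms
  tm <- .bondedTerms(at)
  p0 <- .xyz(at)
  p <- p0
  chir0 <- .chainChirality(at)
  ev <- .bondedEnergy(p, tm, cfg)
  energies <- ev$E
  alpha <- 1e-4
  for (it in seq_len(cfg@steps)) {
    res <- .bondedResiduals(p, tm)
    if (res[["bond"]] < 0.03 && res[["angle"]] < 3) break
    g <- ev$G
    gn2 <- sum(g^2)
    if (gn2 < 1e-16) break
    accepted <- FALSE
    for (ls in 1:30) {
      pn <- p - alpha * g
      En <- .bondedEnergy(pn, tm, cfg, grad = FALSE)$E
      if (En <= ev$E - 1e-4 * alpha * gn2) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!accepted) break
    ## honour the drift cap before committing the step
    bb <- .isBackbone(at$elety)
    if (sqrt(mean(rowSums((pn[bb, , drop = FALSE] -
                           p0[bb, , drop = FALSE])^2))) > cfg@driftCap)
      break
    p <- pn
    ev <- .bondedEnergy(p, tm, cfg)
    energies <- c(energies, ev$E)
    alpha <- alpha * 2
  }
  res <- .bondedResiduals(p, tm)
  if (res[["bond"]] > 0.1 || res[["angle"]] > 8)
    .stopf("regularizer did not converge: residual bond %.3f A, angle %.1f deg",
           res[["bond"]], res[["angle"]])
  at <- .setXyz(at, p)
  if (!identical(.chainChirality(at), chir0))
    .stopf("regularizer introduced a chirality flip")
  bb <- .isBackbone(at$elety)
  drift <- sqrt(mean(rowSums((p[bb, , drop = FALSE] -
                              p0[bb, , drop = FALSE])^2)))
  x@peptide@atoms <- at
  list(complex = x, drift = drift, residuals = res, energies = energies)
}

.chainChirality <- function(at) {
  rn <- .resOrder(at)
  vapply(rn, function(r)
    chiralityOf(at[at$resno == r, , drop = FALSE]), character(1))
}

.runAdapter <- function(x, cfg, adapter) {
  fin <- tempfile(fileext = ".pdb"); fout <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(fin, fout)))
  writePDB(x, fin)
  adapter(fin, fout, x@peptide@chainId, cfg)
  y <- readPDB(fout, peptideChain = x@peptide@chainId,
               anchors = x@anchors, sourceId = x@sourceId)
  if (.maxDisplacement(x@receptor, y@receptor) > 1e-3)
    .stopf("external engine moved receptor atoms; adapter contract violated")
  y <- stripHydrogens(y)
  drift <- .rmsdOver(x@peptide@atoms, y@peptide@atoms)
  if (drift > cfg@driftCap)
    .stopf("external engine exceeded the drift cap (%.2f A > %.2f A)",
           drift, cfg@driftCap)
  list(complex = y, drift = drift,
       residuals = c(bond = NA_real_, angle = NA_real_))
}

## hydrogens carried by each heavy atom of the backbone + CB frame (and
## the proline ring); counts follow standard amide/aliphatic topology
.H_ON_CB <- c(ALA = 3L, ILE = 1L, THR = 1L, VAL = 1L, GLY = 0L,
              PRO = 2L, SER = 2L, CYS = 2L, ASP = 2L, ASN = 2L, LEU = 2L,
              PHE = 2L, TYR = 2L, TRP = 2L, HIS = 2L, MET = 2L, GLU = 2L,
              GLN = 2L, LYS = 2L, ARG = 2L)

#' Add hydrogens at ideal positions
#'
#' Places standard-protonation hydrogens on the peptide's backbone and
#' CB-frame atoms (amide H, H1-H3 on the N-terminal ammonium, HA or
#' HA2/HA3, HB set by residue type, and the proline ring HG/HD pairs).
#' The carboxylate O/OXT stay unprotonated.  Heavy atoms are never moved
#' and a second call adds nothing.  Hydrogens only feed the external-MD
#' engine path; the internal regularizer works on heavy atoms and leaves
#' structures de-protonated.
#'
#' @param x a [PMHCComplex-class] with complete backbone heavy atoms.
#' @return the protonated complex.
#' @export
addHydrogens <- function(x) {
  at <- x@peptide@atoms
  rn <- .resOrder(at)
  for (q in seq_along(rn)) {
    r <- rn[q]
    res <- at$resid[match(r, at$resno)]
    N <- .pos(at, r, "N"); CA <- .pos(at, r, "CA"); C <- .pos(at, r, "C")
    if (is.null(N) || is.null(CA) || is.null(C))
      .stopf("residue %s has incomplete backbone; cannot protonate", r)
    has <- function(nm) !is.null(.pos(at, r, nm))
    addH <- function(nm, p) at <<- .addAtom(at, r, nm, "H", p)
    ## amide / ammonium hydrogens
    if (q == 1L) {
      tors <- c(60, 180, -60)
      nms <- c("H1", "H2", "H3")
      if (res == "PRO") { tors <- c(60, -60); nms <- c("H1", "H2") }
      for (z in seq_along(tors))
        if (!has(nms[z]))
          addH(nms[z], .placeAtom(C, CA, N, 1.01, 109.5, tors[z]))
    } else if (res != "PRO" && !has("H")) {
      Cp <- .pos(at, rn[q - 1L], "C")
      if (!is.null(Cp))
        addH("H", N + 1.01 * .unit(-(.unit(Cp - N) + .unit(CA - N))))
    }
    ## alpha hydrogens
    if (res == "GLY") {
      if (!has("HA2") && !has("HA3")) {
        un <- .unit(N - CA); uc <- .unit(C - CA)
        b <- .unit(-(un + uc)); pp <- .unit(.cross(un, uc))
        th <- 54.75 * pi / 180
        addH("HA2", CA + 1.09 * (b * cos(th) + pp * sin(th)))
        addH("HA3", CA + 1.09 * (b * cos(th) - pp * sin(th)))
      }
    } else if (!has("HA") && has("CB")) {
      CB <- .pos(at, r, "CB")
      addH("HA", CA + 1.09 * .unit(-(.unit(N - CA) + .unit(C - CA) +
                                     .unit(CB - CA))))
    }
    ## CB hydrogens (count set by residue type), proline ring hydrogens
    nHB <- .H_ON_CB[[res]]
    if (!is.na(nHB) && nHB > 0L && has("CB")) {
      nms <- if (nHB == 3L) c("HB1", "HB2", "HB3")
             else if (nHB == 2L) c("HB2", "HB3") else "HB"
      if (!any(vapply(nms, has, logical(1)))) {
        CB <- .pos(at, r, "CB")
        occupied <- Filter(Negate(is.null),
                           list(.pos(at, r, "CG"), .pos(at, r, "CG1"),
                                .pos(at, r, "OG"), .pos(at, r, "OG1"),
                                .pos(at, r, "SG")))
        base <- if (length(occupied))
          dihedralAngle(N, CA, CB, occupied[[1L]]) else 60
        tors <- base + 120 * seq_len(nHB)
        for (z in seq_len(nHB))
          addH(nms[z], .placeAtom(N, CA, CB, 1.09, 109.5, tors[z]))
      }
    }
    if (res == "PRO" && has("CG") && has("CD")) {
      CB <- .pos(at, r, "CB"); CG <- .pos(at, r, "CG"); CD <- .pos(at, r, "CD")
      if (!has("HG2")) {
        for (z in 1:2)
          addH(c("HG2", "HG3")[z],
               .placeAtom(CA, CB, CG, 1.09, 109.5,
                          dihedralAngle(CA, CB, CG, CD) + 120 * z))
      }
      if (!has("HD2")) {
        for (z in 1:2)
          addH(c("HD2", "HD3")[z],
               .placeAtom(CB, CG, CD, 1.09, 109.5,
                          dihedralAngle(CB, CG, CD, N) + 120 * z))
      }
    }
  }
  x@peptide@atoms <- at
  x
}
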