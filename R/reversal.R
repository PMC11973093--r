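## The peptide-reversal pipeline: renumber -> mirror -> reassign ->
## rebuild termini -> fix chirality -> rebuild prolines (-> regularize).
## All steps operate on the peptide only; receptor atoms are never touched.

#' Step 1: reverse residue numbering
#'
#' Renumbers peptide residues in reverse order (resno r becomes L+1-r) and
#' reorders the stored residues accordingly, inverting the sequence string.
#' Every atom coordinate is bitwise unchanged; this step is pure
#' bookkeeping.  The peptide must be gap-free and numbered 1..L.
#'
#' @param chain a [PeptideChain-class].
#' @return the renumbered chain.
#' @export
reverseNumbering <- function(chain) {
  at <- chain@atoms
  L <- .assertNormalized(at)
  assertContinuous(chain)
  at$resno <- L + 1L - at$resno
  at <- at[order(at$resno), , drop = FALSE]
  rownames(at) <- NULL
  chain@atoms <- at
  chain
}

#' Step 2: mirror the peptide-bond atoms through CA-CA midpoints
#'
#' For every peptide bond, the carbonyl carbon and oxygen and the amide
#' nitrogen are replaced by their point inversion through the midpoint of
#' the two flanking alpha carbons (x -> 2m - x).  The midpoint lies, to
#' good approximation, in the peptide plane, so the mirrored atoms stay in
#' that plane while the spatial roles of C and N are exchanged -- the
#' geometric heart of the reversal.  Alpha carbons, side chains and the
#' free terminal groups (the chain-end amide N and carboxyl C/O) are left
#' untouched.  Applying the operation twice restores the input bitwise.
#'
#' The peptide-bond direction of each residue pair is detected from the
#' C-N distances, so the operation works identically before or after
#' [reverseNumbering()].
#'
#' @param chain a [PeptideChain-class]; all N, CA, C, O must be present.
#' @return the mirrored chain, with per-bond bookkeeping recorded for
#'   [reassignAtoms()].
#' @export
mirrorBackbone <- function(chain) {
  at <- chain@atoms
  rn <- .resOrder(at)
  for (r in rn)
    for (nm in c("N", "CA", "C", "O"))
      if (is.null(.pos(at, r, nm)))
        .stopf("residue %s lacks backbone atom %s; cannot mirror", r, nm)
  if (is.null(at$mirrorBond)) at$mirrorBond <- NA_integer_
  for (k in seq_len(length(rn) - 1L)) {
    a <- rn[k]; b <- rn[k + 1L]
    dab <- sqrt(sum((.pos(at, a, "C") - .pos(at, b, "N"))^2))
    dba <- sqrt(sum((.pos(at, b, "C") - .pos(at, a, "N"))^2))
    ## which residue donates the carbonyl into this bond
    co <- if (dab <= dba) a else b
    nn <- if (dab <= dba) b else a
    m <- midpoint(.pos(at, a, "CA"), .pos(at, b, "CA"))
    for (sel in list(c(co, "C"), c(co, "O"), c(nn, "N"))) {
      i <- which(at$resno == as.integer(sel[1L]) & at$elety == sel[2L])
      p <- invertThroughPoint(c(at$x[i], at$y[i], at$z[i]), m)
      at$x[i] <- p[1L]; at$y[i] <- p[2L]; at$z[i] <- p[3L]
      at$mirrorBond[i] <- if (is.na(at$mirrorBond[i])) k else NA_integer_
    }
  }
  chain@atoms <- at
  chain
}

#' Step 3: reassign mirrored atoms to their new residues
#'
#' Point inversion moves each mirrored carbonyl next to the opposite alpha
#' carbon of its peptide bond, so the atoms now chemically belong to the
#' neighbouring residue.  This step updates the bookkeeping: for each bond
#' the mirrored C and O move to the residue across the bond, and the
#' mirrored N moves the other way.  After reassignment every interior
#' residue owns exactly one N, CA, C and O.  The old termini's unpaired
#' backbone atoms (the original terminal carboxyl C/O/OXT and amide N) are
#' flagged stale for [rebuildTermini()] to consume.
#'
#' @param chain a [PeptideChain-class] that went through
#'   [mirrorBackbone()].
#' @return the reassigned chain.
#' @export
reassignAtoms <- function(chain) {
  at <- chain@atoms
  if (is.null(at$mirrorBond) || !any(!is.na(at$mirrorBond)))
    .stopf("reassignAtoms requires a chain processed by mirrorBackbone")
  rn <- .resOrder(at)
  resname <- at$resid[match(rn, at$resno)]
  names(resname) <- rn
  for (k in seq_len(length(rn) - 1L)) {
    idx <- which(at$mirrorBond == k)
    if (length(idx) != 3L)
      .stopf("internal-consistency error: bond %d has %d mirrored atoms",
             k, length(idx))
    pair <- c(rn[k], rn[k + 1L])
    for (i in idx) {
      other <- pair[pair != at$resno[i]]
      at$resno[i] <- other
      at$resid[i] <- resname[[as.character(other)]]
    }
  }
  ## flag the old termini's leftovers: unmirrored backbone atoms that now
  ## duplicate a reassigned one, plus an OXT stranded away from the new
  ## C-terminus
  at$stale <- FALSE
  key <- paste(at$resno, at$elety)
  for (d in unique(key[duplicated(key)])) {
    i <- which(key == d)
    old <- i[is.na(at$mirrorBond[i])]
    if (length(old) != length(i) - 1L)
      .stopf("internal-consistency error: duplicate %s not explained by the terminal groups", d)
    at$stale[old] <- TRUE
  }
  at$stale[at$elety == "OXT" & at$resno != rn[length(rn)]] <- TRUE
  ## canonical intra-residue atom order, stale leftovers last
  rank <- match(at$elety, c("N", "CA", "C", "O", "CB", "CG", "CG1", "CG2",
                            "CD", "CD1", "CD2", "OXT"))
  rank[is.na(rank)] <- 99L
  at <- at[order(match(at$resno, rn), at$stale, rank), , drop = FALSE]
  rownames(at) <- NULL
  chain@atoms <- at
  chain
}

#' Step 4 (termini): remove and regenerate the terminal groups
#'
#' Reversing the sequence moves the chain ends: the old C-terminal
#' carboxylate and old N-terminal amide must be removed and regenerated at
#' the opposite ends.  The new N-terminal amide N is rebuilt along the
#' direction of the old terminal carbonyl carbon at the ideal N-CA bond
#' length (the nitrogen is left bare; protonation is the regularizer's or
#' an external engine's concern).  The new C-terminal carbonyl C is rebuilt
#' from the old amide N direction, and O and OXT are placed trigonally in
#' the N-CA-C plane (C-OXT 1.25 A), giving a planar carboxylate.
#'
#' @param chain a [PeptideChain-class] after [reassignAtoms()] (stale
#'   terminal atoms flagged), or any chain whose termini should be
#'   normalized (a missing OXT is tolerated and added).
#' @return list with elements `chain`, `removed`, `added` (atom labels
#'   "resno:elety").
#' @export
rebuildTermini <- function(chain) {
  at <- chain@atoms
  id <- .IDEAL
  rn <- .resOrder(at)
  first <- rn[1L]; last <- rn[length(rn)]
  removed <- character(); added <- character()
  if (!is.null(at$stale) && any(at$stale)) {
    ## --- new N-terminus (carries the old C-terminal carboxylate) ---
    iC <- which(at$resno == first & at$elety == "C" & at$stale)
    CA1 <- .pos(at, first, "CA")
    if (!length(which(at$resno == first & at$elety == "N" & !at$stale))) {
      newN <- if (length(iC)) {
        oldC <- c(at$x[iC], at$y[iC], at$z[iC])
        CA1 + id$b[["N-CA"]] * .unit(oldC - CA1)
      } else {
        .placeAtom(.pos(at, first, "O"), .pos(at, first, "C"), CA1,
                   id$b[["N-CA"]], id$a[["N-CA-C"]], 0)
      }
      at <- .addAtom(at, first, "N", "N", newN)
      added <- c(added, sprintf("%d:N", first))
    }
    ## --- new C-terminus (carries the old N-terminal amide) ---
    iN <- which(at$resno == last & at$elety == "N" & at$stale)
    CAL <- .pos(at, last, "CA")
    if (!length(which(at$resno == last & at$elety == "C" & !at$stale))) {
      newC <- if (length(iN)) {
        oldN <- c(at$x[iN], at$y[iN], at$z[iN])
        CAL + id$b[["CA-C"]] * .unit(oldN - CAL)
      } else .stopf("cannot rebuild C-terminus of residue %s", last)
      at <- .addAtom(at, last, "C", "C", newC)
      added <- c(added, sprintf("%d:C", last))
      NL <- .pos(at, last, "N")
      O <- .placeAtom(NL, CAL, newC, id$b[["C-O"]], id$a[["CA-C-O"]], 180)
      OXT <- .placeAtom(NL, CAL, newC, id$b[["C-OXT"]], id$a[["CA-C-OXT"]], 0)
      at <- .addAtom(at, last, "O", "O", O)
      at <- .addAtom(at, last, "OXT", "O", OXT)
      added <- c(added, sprintf("%d:O", last), sprintf("%d:OXT", last))
    }
    drop <- which(at$stale)
    removed <- c(removed, sprintf("%d:%s", at$resno[drop], at$elety[drop]))
    at <- at[-drop, , drop = FALSE]
  } else {
    ## standalone normalization: strip stray OXT, complete the C-terminus
    stray <- which(at$elety == "OXT" & at$resno != last)
    if (length(stray)) {
      removed <- sprintf("%d:OXT", at$resno[stray])
      at <- at[-stray, , drop = FALSE]
    }
    if (is.null(.pos(at, last, "OXT"))) {
      NL <- .pos(at, last, "N"); CAL <- .pos(at, last, "CA")
      CL <- .pos(at, last, "C"); OL <- .pos(at, last, "O")
      tor <- dihedralAngle(NL, CAL, CL, OL) - 180
      OXT <- .placeAtom(NL, CAL, CL, id$b[["C-OXT"]], id$a[["CA-C-OXT"]], tor)
      at <- .addAtom(at, last, "OXT", "O", OXT)
      added <- sprintf("%d:OXT", last)
    }
  }
  rownames(at) <- NULL
  chain@atoms <- at
  list(chain = chain, removed = removed, added = added)
}

#' Step 5: correct alpha-carbon chirality (D to L)
#'
#' Exchanging the spatial roles of the backbone C and N around a fixed
#' CA/CB turns every chiral residue into its D form.  The natural L form
#' is restored by reflecting each D-labelled CA across the plane of its
#' own N, C and CB atoms.  N, C and CB lie on that plane, so all bonds to
#' CA keep their exact lengths; the CA moves by twice its distance to the
#' plane.  Glycines are achiral and skipped.
#'
#' @param chain a [PeptideChain-class].
#' @return list with `chain` and `fixed` (positions whose CA moved).
#' @export
fixChirality <- function(chain) {
  at <- chain@atoms
  rn <- .resOrder(at)
  fixed <- integer()
  for (r in rn) {
    res <- at[at$resno == r, , drop = FALSE]
    lab <- chiralityOf(res)
    if (lab == "D") {
      pl <- planeFromPoints(.pos(at, r, "N"), .pos(at, r, "C"),
                            .pos(at, r, "CB"))
      at <- .setPos(at, r, "CA", reflectAcrossPlane(.pos(at, r, "CA"), pl))
      fixed <- c(fixed, r)
    }
  }
  chain@atoms <- at
  list(chain = chain, fixed = fixed)
}

#' Rebuild proline pyrrolidine rings on the corrected backbone frame
#'
#' Regenerates CB, CG and CD from ideal internal coordinates anchored on
#' the (chirality-corrected) N-CA-C frame, closing the ring back onto the
#' amide nitrogen (N-CD about 1.52 A).  Backbone atoms are untouched.
#' The ring is built for the common trans isomer; a cis peptide bond
#' preceding the proline is reported with a warning.
#'
#' @param chain a [PeptideChain-class].
#' @param positions residue numbers to rebuild; defaults to all prolines.
#' @return list with `chain` and `rebuilt` positions.
#' @export
rebuildProline <- function(chain, positions = NULL) {
  at <- chain@atoms
  rn <- .resOrder(at)
  pro <- rn[at$resid[match(rn, at$resno)] == "PRO"]
  if (!is.null(positions)) pro <- intersect(pro, positions)
  id <- .IDEAL
  for (r in pro) {
    N <- .pos(at, r, "N"); CA <- .pos(at, r, "CA"); C <- .pos(at, r, "C")
    if (is.null(N) || is.null(CA) || is.null(C))
      .stopf("proline %s lacks its N/CA/C frame", r)
    CB <- .placeAtom(N, C, CA, id$b[["CA-CB"]], id$a[["C-CA-CB"]],
                     id$cbImproper)
    CG <- .placeAtom(N, CA, CB, id$b[["CB-CG"]], id$a[["CA-CB-CG"]],
                     id$proChi1)
    CD <- .placeAtom(CA, CB, CG, id$b[["CG-CD"]], id$a[["CB-CG-CD"]],
                     id$proChi2)
    for (nm in c("CB", "CG", "CD")) {
      p <- switch(nm, CB = CB, CG = CG, CD = CD)
      if (is.null(.pos(at, r, nm)))
        at <- .addAtom(at, r, nm, "C", p)
      else at <- .setPos(at, r, nm, p)
    }
    k <- match(r, rn)
    if (k > 1L) {
      CAp <- .pos(at, rn[k - 1L], "CA"); Cp <- .pos(at, rn[k - 1L], "C")
      if (!is.null(CAp) && !is.null(Cp)) {
        om <- dihedralAngle(CAp, Cp, N, CA)
        if (abs(om) < 90)
          .warnf("cis peptide bond (omega %.0f deg) precedes proline %s; ring built for the trans isomer",
                 om, r)
      }
    }
  }
  chain@atoms <- at
  list(chain = chain, rebuilt = as.integer(pro))
}

#' Renumber anchors for a reversed peptide
#'
#' An anchor keeps its binding pocket when the peptide is reversed, so its
#' position maps under the involution p -> L+1-p.  The canonical 9-mer
#' core anchor set \{1, 4, 6, 9\} maps onto itself.
#'
#' @param anchors integer anchor positions in 1..L.
#' @param L peptide length.
#' @return sorted reversed anchor positions.
#' @examples
#' reverseAnchors(c(3, 6, 8, 11), 15)
#' @export
reverseAnchors <- function(anchors, L) {
  anchors <- as.integer(anchors)
  L <- as.integer(L)
  if (any(anchors < 1L | anchors > L))
    .stopf("anchor positions must lie in [1, %d]", L)
  sort(L + 1L - anchors)
}

#' Reverse a bound peptide within its MHC groove
#'
#' Runs the full reversal pipeline on the peptide of a complex:
#' renumbering ([reverseNumbering()]), peptide-bond mirroring
#' ([mirrorBackbone()]), atom reassignment ([reassignAtoms()]), terminal
#' group reconstruction ([rebuildTermini()]), D-to-L chirality correction
#' ([fixChirality()]), proline ring rebuilding ([rebuildProline()]),
#' optional geometry regularization ([regularizeGeometry()]) and anchor
#' renumbering ([reverseAnchors()]).  The receptor is never moved.
#'
#' The output peptide has the exactly reversed sequence, occupies the same
#' groove (alpha carbons move only by the small chirality reflection and
#' regularization), and is all-L.
#'
#' @param x a [PMHCComplex-class], preprocessed (no hydrogens, no MSE;
#'   both are normalized here with a message if present).
#' @param config a [RegularizerConfig-class].
#' @param regularize run the geometry regularizer (default TRUE).
#' @return list with `complex` (the reversed [PMHCComplex-class]) and
#'   `report` (a [ReversalReport-class]).
#' @examples
#' cx <- buildIdealPeptide(fixtureSpec("KVTVAFNQF"), anchors = c(1, 4, 6, 9))
#' rev <- reversePeptide(cx)
#' pepSequence(rev$complex)
#' @export
reversePeptide <- function(x, config = regularizerConfig(),
                           regularize = TRUE) {
  stopifnot(is(x, "PMHCComplex"))
  if (any(x@peptide@atoms$elesy %in% c("H", "D")) ||
      any(x@receptor$elesy %in% c("H", "D"))) {
    message("reversePeptide: stripping hydrogens before reversal")
    x <- stripHydrogens(x)
  }
  if (any(c(x@peptide@atoms$resid, x@receptor$resid) == "MSE")) {
    message("reversePeptide: substituting selenomethionines")
    x <- substituteMSE(x)
  }
  pep <- x@peptide
  pep@atoms <- .normalizeNumbering(pep@atoms)
  L <- .assertNormalized(pep@atoms)
  seq0 <- pepSequence(pep)
  disp <- c(renumber = 0)

  stage <- function(name, f) {
    tryCatch(f(), error = function(e)
      .stopf("reversal failed at stage '%s': %s", name, conditionMessage(e)))
  }
  pep <- stage("renumber", function() reverseNumbering(pep))
  before <- pep@atoms
  pep <- stage("mirror", function() mirrorBackbone(pep))
  disp["mirror"] <- .maxDisplacement(before, pep@atoms)
  pep <- stage("reassign", function() reassignAtoms(pep))
  disp["reassign"] <- 0
  tm <- stage("termini", function() rebuildTermini(pep))
  pep <- tm$chain
  disp["termini"] <- 0
  before <- pep@atoms
  fc <- stage("chirality", function() fixChirality(pep))
  pep <- fc$chain
  disp["chirality"] <- .maxDisplacement(before, pep@atoms)
  before <- pep@atoms
  pr <- stage("proline", function() rebuildProline(pep))
  pep <- pr$chain
  disp["proline"] <- .maxDisplacement(before, pep@atoms)
  pep@atoms$mirrorBond <- NULL
  pep@atoms$stale <- NULL

  out <- x
  out@peptide <- pep
  regRMSD <- NA_real_
  if (regularize) {
    before <- out@peptide@atoms
    rg <- stage("regularize", function() regularizeGeometry(out, config))
    out <- rg$complex
    regRMSD <- rg$drift
    disp["regularize"] <- .maxDisplacement(before, out@peptide@atoms)
  }
  out@anchors <- reverseAnchors(x@anchors, L)

  stopifnot(identical(pepSequence(out),
                      paste(rev(strsplit(seq0, "")[[1]]), collapse = "")))
  report <- new("ReversalReport", stepDisplacements = disp,
                chiralityFixed = as.integer(fc$fixed),
                prolinesRebuilt = pr$rebuilt,
                terminalRemoved = tm$removed, terminalAdded = tm$added,
                anchorMap = cbind(old = x@anchors,
                                  new = rev(out@anchors)),
                regularizationRMSD = regRMSD)
  list(complex = out, report = report)
}
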