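## Receptor-frame superposition, binding-core ligand RMSD and automated
## geometry QC.

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rotation and translation minimizing the RMSD
#' between paired point sets; reflections are excluded by the standard
#' determinant correction.  The transform maps `mobile` onto `target`:
#' x' = R x + t.
#'
#' @param mobile,target n x 3 coordinate matrices, paired row by row,
#'   n >= 3 and not collinear.
#' @return a [SuperpositionResult-class].
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3L ||
      ncol(target) != 3L)
    .stopf("superpose needs equal-length paired n x 3 coordinate sets")
  n <- nrow(mobile)
  if (n < 3L) .stopf("superpose needs at least 3 paired atoms")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2L, cm); Q <- sweep(target, 2L, ct)
  if (min(svd(P)$d[2L], svd(Q)$d[2L]) < 1e-8)
    .stopf("superpose is degenerate: points are (nearly) collinear")
  s <- svd(crossprod(P, Q))          # H = P^T Q = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- ct - as.vector(R %*% cm)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  new("SuperpositionResult", rotation = R, translation = t, rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#'
#' @param fit a [SuperpositionResult-class].
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(fit, coords) {
  sweep(as.matrix(coords) %*% t(fit@rotation), 2L, fit@translation, "+")
}

## paired receptor coordinates (by chain, resno, atom name) of two
## complexes, restricted to the given atom names
.pairedReceptor <- function(model, reference, eletys = "CA") {
  am <- model@receptor; ar <- reference@receptor
  am <- am[am$elety %in% eletys, , drop = FALSE]
  ar <- ar[ar$elety %in% eletys, , drop = FALSE]
  km <- paste(am$chain, am$resno, am$insert, am$elety)
  kr <- paste(ar$chain, ar$resno, ar$insert, ar$elety)
  common <- intersect(km, kr)
  if (length(common) < 3L)
    .stopf("fewer than 3 shared receptor fit atoms between model and reference")
  list(mobile = .xyz(am)[match(common, km), , drop = FALSE],
       target = .xyz(ar)[match(common, kr), , drop = FALSE])
}

#' Binding-core ligand RMSD after receptor superposition
#'
#' Superposes the model on the reference using receptor CA atoms (Kabsch),
#' then returns the root-mean-square deviation over the peptide
#' binding-core backbone atoms in the reference frame -- no re-fitting on
#' the peptide, so the measure penalizes any rigid offset of the ligand
#' within the groove.
#'
#' `core` positions refer to the reference peptide numbering.  With
#' `map = "reversed"` the model peptide is numbered in the reversed frame
#' and reference position p is paired with model position L+1-p: a reversed
#' peptide keeps its anchors in the same pockets, so groove position is
#' the correspondence that survives reversal.
#'
#' @param model,reference [PMHCComplex-class] objects sharing receptor
#'   chain naming.
#' @param core integer core residue positions (reference numbering).
#' @param atomNames backbone atom subset scored (default N, CA, C, O).
#' @param map `"identity"` or `"reversed"` residue correspondence.
#' @return list with `lrmsd` (A), `nAtoms`, `fitRMSD` (receptor fit
#'   RMSD, A).
#' @export
coreLRMSD <- function(model, reference, core,
                      atomNames = c("N", "CA", "C", "O"),
                      map = c("identity", "reversed")) {
  map <- match.arg(map)
  pr <- .pairedReceptor(model, reference)
  fit <- superpose(pr$mobile, pr$target)
  am <- model@peptide@atoms
  ar <- reference@peptide@atoms
  L <- length(.resOrder(am))
  modelPos <- if (map == "reversed") L + 1L - core else core
  missing <- character()
  rows_m <- integer(); rows_r <- integer()
  for (z in seq_along(core)) {
    for (nm in atomNames) {
      im <- which(am$resno == modelPos[z] & am$elety == nm)
      ir <- which(ar$resno == core[z] & ar$elety == nm)
      if (!length(im)) missing <- c(missing, sprintf("model %d:%s",
                                                     modelPos[z], nm))
      if (!length(ir)) missing <- c(missing, sprintf("reference %d:%s",
                                                     core[z], nm))
      if (length(im) && length(ir)) {
        rows_m <- c(rows_m, im[1L]); rows_r <- c(rows_r, ir[1L])
      }
    }
  }
  if (length(missing))
    .stopf("missing core backbone atoms: %s", paste(missing, collapse = ", "))
  pm <- applyTransform(fit, .xyz(am)[rows_m, , drop = FALSE])
  pq <- .xyz(ar)[rows_r, , drop = FALSE]
  list(lrmsd = sqrt(mean(rowSums((pm - pq)^2))),
       nAtoms = length(rows_m), fitRMSD = fit@rmsd)
}

#' Automated geometry quality control
#'
#' Reports, per peptide residue, the alpha-carbon chirality label, the
#' backbone bond-length deviations from ideal values (N-CA 1.458, CA-C
#' 1.525, C-N 1.329, C-O 1.231 A) and the omega deviations from the trans
#' value, together with violation counts at the configured tolerances.
#' This is the automated stand-in for eyeballing each generated template.
#'
#' @param x a [PMHCComplex-class] or [PeptideChain-class].
#' @param bondTol bond-length tolerance in Angstrom.
#' @param omegaTol omega tolerance in degrees about 180.
#' @return a [GeometryReport-class] (reports; never raises on bad
#'   geometry).
#' @export
validateGeometry <- function(x, bondTol = 0.1, omegaTol = 30) {
  at <- if (is(x, "PMHCComplex")) x@peptide@atoms else x@atoms
  rn <- .resOrder(at)
  id <- .IDEAL
  chir <- vapply(rn, function(r) {
    res <- at[at$resno == r, , drop = FALSE]
    tryCatch(chiralityOf(res), error = function(e) NA_character_)
  }, character(1))
  names(chir) <- rn
  chir[is.na(chir)] <- "achiral"

  bonds <- list()
  addB <- function(r, nm, a, b, r0) {
    if (!is.null(a) && !is.null(b)) {
      d <- sqrt(sum((a - b)^2))
      bonds[[length(bonds) + 1L]] <<- data.frame(
        resno = r, bond = nm, length = d, ideal = r0, dev = d - r0)
    }
  }
  om <- list()
  for (q in seq_along(rn)) {
    r <- rn[q]
    N <- .pos(at, r, "N"); CA <- .pos(at, r, "CA")
    C <- .pos(at, r, "C"); O <- .pos(at, r, "O")
    addB(r, "N-CA", N, CA, id$b[["N-CA"]])
    addB(r, "CA-C", CA, C, id$b[["CA-C"]])
    addB(r, "C-O", C, O, id$b[["C-O"]])
    if (q < length(rn)) {
      Nn <- .pos(at, rn[q + 1L], "N"); CAn <- .pos(at, rn[q + 1L], "CA")
      addB(r, "C-N", C, Nn, id$b[["C-N"]])
      if (!is.null(CA) && !is.null(C) && !is.null(Nn) && !is.null(CAn)) {
        w <- dihedralAngle(CA, C, Nn, CAn)
        dev <- (w - 180) %% 360
        if (dev > 180) dev <- dev - 360
        om[[length(om) + 1L]] <- data.frame(resno = r, omega = w, dev = dev)
      }
    }
  }
  bondDev <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(resno = integer(), bond = character(), length = numeric(),
               ideal = numeric(), dev = numeric())
  omegaDev <- if (length(om)) do.call(rbind, om) else
    data.frame(resno = integer(), omega = numeric(), dev = numeric())
  new("GeometryReport", chirality = chir, bondDeviations = bondDev,
      omegaDeviations = omegaDev,
      violations = c(chirality = sum(chir == "D"),
                     bond = sum(abs(bondDev$dev) > bondTol),
                     omega = sum(abs(omegaDev$dev) > omegaTol)),
      tolerances = c(bond = bondTol, omega = omegaTol))
}
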