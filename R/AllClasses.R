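#' @import methods
NULL

## Canonical columns of the flat atom table carried by every structure object.
## One row per atom; coordinates are Angstrom at full double precision (PDB
## column precision is applied only when a file is written).
.ATOM_COLS <- c("chain", "resno", "resid", "insert", "elety", "elesy",
                "alt", "x", "y", "z", "o", "b")

.emptyAtomTable <- function() {
  data.frame(chain = character(), resno = integer(), resid = character(),
             insert = character(), elety = character(), elesy = character(),
             alt = character(), x = numeric(), y = numeric(), z = numeric(),
             o = numeric(), b = numeric(), stringsAsFactors = FALSE)
}

.checkAtomTable <- function(at, what = "atoms") {
  msg <- character()
  missing <- setdiff(.ATOM_COLS, names(at))
  if (length(missing))
    msg <- c(msg, sprintf("%s is missing columns: %s", what,
                          paste(missing, collapse = ", ")))
  if (!length(msg) && nrow(at)) {
    if (!all(is.finite(at$x)) || !all(is.finite(at$y)) || !all(is.finite(at$z)))
      msg <- c(msg, sprintf("%s contains non-finite coordinates", what))
    key <- paste(at$chain, at$resno, at$insert, at$elety, at$alt)
    if (anyDuplicated(key))
      msg <- c(msg, sprintf(
        "%s has duplicate atom names within a residue/altloc", what))
  }
  msg
}

#' Peptide chain: an ordered run of amino-acid residues
#'
#' Holds one protein chain as a flat atom table (one row per atom) whose
#' residue order is the chain reading order.  For a canonically oriented
#' chain the reading order is N-terminus to C-terminus; after reversal
#' renumbering the stored order is the reversed reading order.
#'
#' @slot chainId single-character PDB chain identifier.
#' @slot atoms data.frame with columns chain, resno, resid, insert, elety,
#'   elesy, alt, x, y, z, o, b; residues appear in chain reading order.
#'
#' @exportClass PeptideChain
setClass("PeptideChain",
         representation(chainId = "character", atoms = "data.frame"),
         prototype(chainId = "P", atoms = .emptyAtomTable()))

setValidity("PeptideChain", function(object) {
  msg <- character()
  if (length(object@chainId) != 1L || nchar(object@chainId) != 1L)
    msg <- c(msg, "chainId must be a single character")
  msg <- c(msg, .checkAtomTable(object@atoms, "peptide atoms"))
  if (!length(msg) && nrow(object@atoms)) {
    if (any(object@atoms$chain != object@chainId))
      msg <- c(msg, "atom table chain column disagrees with chainId")
    if (any(object@atoms$insert != ""))
      msg <- c(msg, "peptide residues must not carry insertion codes")
  }
  if (length(msg)) msg else TRUE
})

#' Peptide-MHC class II complex
#'
#' A receptor (MHC alpha and beta chains, kept as a single atom table) plus
#' one bound peptide chain and its anchor-position annotation.  Anchors are
#' 1-based positions along the peptide in its stored reading order; for
#' canonical binders the main anchors are P1/P4/P6/P9 of the core.
#'
#' @slot receptor data.frame atom table of all receptor chains.
#' @slot peptide a [PeptideChain-class].
#' @slot anchors strictly increasing integer vector of peptide positions.
#' @slot sourceId PDB identifier or synthetic label for provenance.
#'
#' @exportClass PMHCComplex
setClass("PMHCComplex",
         representation(receptor = "data.frame", peptide = "PeptideChain",
                        anchors = "integer", sourceId = "character"),
         prototype(receptor = .emptyAtomTable(),
                   peptide = new("PeptideChain"),
                   anchors = integer(), sourceId = "synthetic"))

setValidity("PMHCComplex", function(object) {
  msg <- .checkAtomTable(object@receptor, "receptor atoms")
  L <- length(unique(object@peptide@atoms$resno))
  a <- object@anchors
  if (length(a)) {
    if (any(a < 1L) || any(a > L))
      msg <- c(msg, sprintf("anchors must lie in [1, %d]", L))
    if (is.unsorted(a, strictly = TRUE))
      msg <- c(msg, "anchors must be strictly increasing")
  }
  if (nrow(object@receptor) &&
      object@peptide@chainId %in% unique(object@receptor$chain))
    msg <- c(msg, "peptide chain id collides with a receptor chain id")
  if (length(msg)) msg else TRUE
})

#' Per-run diagnostics of the peptide reversal pipeline
#'
#' @slot stepDisplacements named numeric, max single-atom displacement (A)
#'   introduced by each pipeline step.
#' @slot chiralityFixed integer positions whose CA was reflected D -> L.
#' @slot prolinesRebuilt integer positions whose pyrrolidine ring was rebuilt.
#' @slot terminalRemoved,terminalAdded character labels of terminal-group
#'   atoms deleted and regenerated ("resno:elety").
#' @slot anchorMap two-column matrix (old, new) of anchor renumbering.
#' @slot regularizationRMSD peptide-backbone RMSD (A) moved by the
#'   geometry regularizer (NA if regularization was skipped).
#'
#' @exportClass ReversalReport
setClass("ReversalReport",
         representation(stepDisplacements = "numeric",
                        chiralityFixed = "integer",
                        prolinesRebuilt = "integer",
                        terminalRemoved = "character",
                        terminalAdded = "character",
                        anchorMap = "matrix",
                        regularizationRMSD = "numeric"))

#' Geometry quality-control report
#'
#' @slot chirality named character vector, one of "L", "D", "achiral" per
#'   peptide position.
#' @slot bondDeviations data.frame (resno, bond, length, ideal, dev).
#' @slot omegaDeviations data.frame (resno, omega, dev) with dev measured
#'   from the trans value 180 degrees.
#' @slot violations named integer counts (chirality, bond, omega) at the
#'   configured tolerances.
#' @slot tolerances named numeric (bond A, omega degrees).
#'
#' @exportClass GeometryReport
setClass("GeometryReport",
         representation(chirality = "character",
                        bondDeviations = "data.frame",
                        omegaDeviations = "data.frame",
                        violations = "integer",
                        tolerances = "numeric"))

setValidity("GeometryReport", function(object) {
  msg <- character()
  tol <- object@tolerances
  v <- object@violations
  if (all(c("bond", "omega") %in% names(tol)) &&
      all(c("chirality", "bond", "omega") %in% names(v))) {
    if (v[["chirality"]] != sum(object@chirality == "D"))
      msg <- c(msg, "chirality violation count disagrees with labels")
    if (v[["bond"]] != sum(abs(object@bondDeviations$dev) > tol[["bond"]]))
      msg <- c(msg, "bond violation count disagrees with deviations")
    if (v[["omega"]] != sum(abs(object@omegaDeviations$dev) > tol[["omega"]]))
      msg <- c(msg, "omega violation count disagrees with deviations")
  } else msg <- c(msg, "tolerances/violations must be named")
  if (length(msg)) msg else TRUE
})

#' Result of a least-squares rigid superposition
#'
#' @slot rotation proper orthonormal 3x3 matrix.
#' @slot translation length-3 numeric (A).
#' @slot rmsd RMSD over the fitted atoms (A).
#'
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
         representation(rotation = "matrix", translation = "numeric",
                        rmsd = "numeric"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3L, 3L)))
    msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      msg <- c(msg, "rotation is not orthonormal")
    if (abs(det(R) - 1) > 1e-9)
      msg <- c(msg, "rotation is not proper (det != +1)")
  }
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must have length 3")
  if (length(msg)) msg else TRUE
})

#' A reversed-template database record
#'
#' @slot templateId string of the form `<PDBID>_reversed`, e.g.
#'   `3WEX_reversed`.
#' @slot alleles character vector of allele names (opaque labels).
#' @slot peptideSequence reversed one-letter peptide sequence.
#' @slot anchors reversed anchor positions.
#' @slot path file path of the emitted template PDB.
#'
#' @exportClass TemplateRecord
setClass("TemplateRecord",
         representation(templateId = "character", alleles = "character",
                        peptideSequence = "character", anchors = "integer",
                        path = "character"))

setValidity("TemplateRecord", function(object) {
  if (!grepl("^[0-9][A-Za-z0-9]{3}_reversed$", object@templateId))
    return(sprintf("templateId '%s' does not match '<PDBID>_reversed'",
                   object@templateId))
  TRUE
})

#' Specification of an ideal-geometry synthetic peptide fixture
#'
#' Drives the internal-coordinate (NeRF) chain builder.  phi/psi/omega are
#' per-residue backbone dihedrals in degrees; phi of residue 1 has no
#' upstream atoms and is ignored, psi of the last residue orients the
#' terminal carboxylate.
#'
#' @slot sequence one-letter amino-acid string.
#' @slot phi,psi,omega numeric vectors, one value per residue (degrees);
#'   omega defaults to trans (180).
#' @slot placement optional rigid transform applied after building: a list
#'   with 3x3 `rotation` and length-3 `translation`, or empty list.
#' @slot decoyGroove add a rigid dummy receptor (two short helices flanking
#'   the peptide) so receptor-frame operations can be exercised.
#'
#' @exportClass FixtureSpec
setClass("FixtureSpec",
         representation(sequence = "character", phi = "numeric",
                        psi = "numeric", omega = "numeric",
                        placement = "list", decoyGroove = "logical"),
         prototype(placement = list(), decoyGroove = FALSE))

setValidity("FixtureSpec", function(object) {
  n <- nchar(object@sequence)
  msg <- character()
  if (length(object@phi) != n || length(object@psi) != n ||
      length(object@omega) != n)
    msg <- c(msg, "phi, psi and omega must each have one value per residue")
  bad <- setdiff(strsplit(object@sequence, "")[[1]],
                 strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (length(bad))
    msg <- c(msg, sprintf("unknown residue letter(s): %s",
                          paste(unique(bad), collapse = "")))
  if (length(msg)) msg else TRUE
})

#' Configuration of the geometry regularizer
#'
#' The default engine is an internal restrained steepest descent on bonded
#' terms only (bond lengths, bond angles, omega/carbonyl planarity and an
#' alpha-carbon chirality restraint) with the receptor held exactly fixed.
#' The `external-MD` engine is an adapter contract mirroring the short
#' Langevin run this step classically performs (300 K, 10 steps); it is not
#' bundled.
#'
#' @slot engine "internal" or "external-MD".
#' @slot driftCap maximum allowed peptide-backbone RMSD drift (A, > 0).
#' @slot kBond,kAngle,kPlanarity,kChirality force constants of the internal
#'   penalty (per A^2, per rad^2, per rad^2, per A^6 hinge).
#' @slot temperature Kelvin; consumed by the external engine only.
#' @slot steps iteration budget (internal) or MD step count (external).
#' @slot seed integer random seed recorded for reproducibility (the
#'   internal engine is deterministic and does not consume it).
#'
#' @exportClass RegularizerConfig
setClass("RegularizerConfig",
         representation(engine = "character", driftCap = "numeric",
                        kBond = "numeric", kAngle = "numeric",
                        kPlanarity = "numeric", kChirality = "numeric",
                        temperature = "numeric", steps = "integer",
                        seed = "integer"),
         prototype(engine = "internal", driftCap = 0.8, kBond = 100,
                   kAngle = 20, kPlanarity = 5, kChirality = 10,
                   temperature = 300, steps = 300L, seed = 0L))

setValidity("RegularizerConfig", function(object) {
  msg <- character()
  if (!object@engine %in% c("internal", "external-MD"))
    msg <- c(msg, "engine must be 'internal' or 'external-MD'")
  if (object@driftCap <= 0) msg <- c(msg, "driftCap must be > 0")
  if (object@steps < 1L) msg <- c(msg, "steps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname RegularizerConfig-class
#' @param engine,driftCap,kBond,kAngle,kPlanarity,kChirality,temperature,steps,seed
#'   see the class slots.
#' @return a validated `RegularizerConfig`.
#' @export
regularizerConfig <- function(engine = "internal", driftCap = 0.8,
                              kBond = 100, kAngle = 20, kPlanarity = 5,
                              kChirality = 10, temperature = 300,
                              steps = 300L, seed = 0L) {
  new("RegularizerConfig", engine = engine, driftCap = driftCap,
      kBond = kBond, kAngle = kAngle, kPlanarity = kPlanarity,
      kChirality = kChirality, temperature = temperature,
      steps = as.integer(steps), seed = as.integer(seed))
}
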