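## PDB reading/writing and the standard preprocessing applied to template
## inputs before reversal.

#' @include AllClasses.R utils-atoms.R
NULL

.STANDARD_AA <- c(unname(.AA3), "MSE")

#' Read a peptide-MHC class II complex from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), drops waters and non-MSE
#' heteroatoms with a logged count, resolves alternate locations by keeping
#' the highest-occupancy conformer (ties broken by altloc letter), and
#' splits the structure into receptor chains and one peptide chain.
#'
#' The peptide chain is taken from `peptideChain` when given; otherwise the
#' shortest protein chain with 8-30 residues is used.  Insertion codes in
#' the peptide are rejected: the reversal renumbering assumes a gap-free
#' 1..L peptide.
#'
#' @param path PDB file path.
#' @param peptideChain explicit peptide chain id, or NULL for the
#'   shortest-chain heuristic.
#' @param anchors optional 1-based anchor positions along the peptide.
#' @param sourceId provenance label; defaults to the file stem.
#' @return a [PMHCComplex-class].
#' @export
readPDB <- function(path, peptideChain = NULL, anchors = integer(),
                    sourceId = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  ## altloc handling is ours (highest occupancy wins), so bio3d's ALT
  ## advisory is noise here
  pdb <- tryCatch(suppressWarnings(
    bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
                  error = function(e) .stopf("cannot parse PDB '%s': %s",
                                             path, conditionMessage(e)))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$elesy[is.na(at$elesy) | at$elesy == ""] <- .elementOf(
    at$elety[is.na(at$elesy) | at$elesy == ""])
  keep <- at$resid %in% .STANDARD_AA
  nd <- sum(!keep)
  if (nd) message(sprintf("readPDB: dropped %d non-protein atom(s) (waters/ligands)", nd))
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) .stopf("structure error: no protein chains in '%s'", path)

  at <- .resolveAltlocs(at)
  at <- at[, .ATOM_COLS, drop = FALSE]
  rownames(at) <- NULL

  chains <- unique(at$chain)
  lens <- vapply(chains, function(ch)
    length(unique(paste(at$resno, at$insert)[at$chain == ch])), integer(1))
  pepId <- if (!is.null(peptideChain)) {
    if (!peptideChain %in% chains)
      .stopf("structure error: no chain '%s' in '%s'", peptideChain, path)
    peptideChain
  } else {
    cand <- chains[lens >= 8L & lens <= 30L]
    if (!length(cand))
      .stopf("structure error: no candidate peptide chain (8-30 residues) in '%s'",
             path)
    cand[which.min(lens[match(cand, chains)])]
  }
  pep <- at[at$chain == pepId, , drop = FALSE]
  if (any(pep$insert != ""))
    .stopf("peptide chain '%s' carries insertion codes; reversal assumes a gap-free 1..L numbering",
           pepId)
  rec <- at[at$chain != pepId, , drop = FALSE]
  rownames(pep) <- rownames(rec) <- NULL
  new("PMHCComplex", receptor = rec,
      peptide = new("PeptideChain", chainId = pepId, atoms = pep),
      anchors = as.integer(anchors),
      sourceId = if (is.null(sourceId))
        toupper(tools::file_path_sans_ext(basename(path))) else sourceId)
}

## keep the highest-occupancy conformer per atom; ties by altloc letter
.resolveAltlocs <- function(at) {
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  if (!anyDuplicated(key)) { at$alt <- ""; return(at) }
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
           drop = FALSE]
  at$alt <- ""
  ## restore file order
  at[order(as.integer(rownames(at))), , drop = FALSE]
}

#' Write a complex to a PDB file
#'
#' Emits standard fixed-column ATOM records (receptor chains first, then
#' the peptide), a TER record after each chain and a final END.  Residue
#' numbering is written exactly as stored.  Coordinates are rounded to the
#' PDB's three decimal places at write time only.
#'
#' @param x a [PMHCComplex-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePDB <- function(x, path) {
  validObject(x)
  con <- tryCatch(file(path, "w"),
                  error = function(e) .stopf("cannot write '%s': %s", path,
                                             conditionMessage(e)))
  on.exit(close(con))
  serial <- 0L
  emitChain <- function(at) {
    for (i in seq_len(nrow(at))) {
      serial <<- serial + 1L
      name <- at$elety[i]
      ## PDB column alignment: 1-3 character names start in column 14
      name <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, name, at$resid[i], at$chain[i], at$resno[i],
        ifelse(at$insert[i] == "", " ", at$insert[i]),
        at$x[i], at$y[i], at$z[i], at$o[i], at$b[i], at$elesy[i]), con)
    }
    serial <<- serial + 1L
    n <- nrow(at)
    writeLines(sprintf("TER   %5d      %-3s %1s%4d", serial %% 100000L,
                       at$resid[n], at$chain[n], at$resno[n]), con)
  }
  rec <- x@receptor
  for (ch in unique(rec$chain))
    emitChain(rec[rec$chain == ch, , drop = FALSE])
  emitChain(x@peptide@atoms)
  writeLines("END", con)
  invisible(path)
}

#' Preprocessing: strip hydrogens
#'
#' Removes every hydrogen (and deuterium) atom; heavy atoms are untouched.
#' Idempotent.
#'
#' @param x a [PMHCComplex-class].
#' @return the complex without hydrogens.
#' @export
stripHydrogens <- function(x) {
  drop <- function(at) at[!at$elesy %in% c("H", "D"), , drop = FALSE]
  x@receptor <- drop(x@receptor)
  x@peptide@atoms <- drop(x@peptide@atoms)
  x
}

#' Preprocessing: replace selenomethionine by methionine
#'
#' Renames every MSE residue to MET and its selenium SE to the sulfur SD,
#' leaving all coordinates unchanged, so that downstream force fields see a
#' standard residue.  An MSE without an SE atom is renamed anyway with a
#' warning.  Idempotent.
#'
#' @param x a [PMHCComplex-class].
#' @return the complex with methionines.
#' @export
substituteMSE <- function(x) {
  fix <- function(at) {
    mse <- which(at$resid == "MSE")
    if (!length(mse)) return(at)
    for (r in unique(at$resno[mse])) {
      sel <- at$resid == "MSE" & at$resno == r
      if (!any(at$elety[sel] == "SE"))
        .warnf("MSE residue %s lacks an SE atom; renamed to MET anyway", r)
    }
    at$resid[mse] <- "MET"
    se <- mse[at$elety[mse] == "SE"]
    at$elety[se] <- "SD"
    at$elesy[se] <- "S"
    at
  }
  x@receptor <- fix(x@receptor)
  x@peptide@atoms <- fix(x@peptide@atoms)
  x
}

#' Detect chain breaks in a peptide
#'
#' Flags any consecutive residue pair whose C(i)-N(i+1) distance exceeds
#' the chain-break threshold (2.5 A); the mirroring steps assume a
#' continuous backbone.  Works in either reading direction.
#'
#' @param chain a [PeptideChain-class].
#' @param threshold break distance in Angstrom.
#' @return TRUE invisibly if continuous, otherwise an error.
#' @export
assertContinuous <- function(chain, threshold = 2.5) {
  at <- chain@atoms
  rn <- .resOrder(at)
  for (i in seq_len(length(rn) - 1L)) {
    d1 <- .pairBondLength(at, rn[i], rn[i + 1L])
    if (is.na(d1) || d1 > threshold)
      .stopf("chain break between peptide residues %s and %s (C-N %.2f A > %.1f A)",
             rn[i], rn[i + 1L], d1, threshold)
  }
  invisible(TRUE)
}

## C-N peptide-bond distance between two adjacent residues, direction
## agnostic: the smaller of C(a)-N(b) and C(b)-N(a)
.pairBondLength <- function(at, a, b) {
  ca <- .pos(at, a, "C"); nb <- .pos(at, b, "N")
  cb <- .pos(at, b, "C"); na_ <- .pos(at, a, "N")
  d1 <- if (!is.null(ca) && !is.null(nb)) sqrt(sum((ca - nb)^2)) else NA_real_
  d2 <- if (!is.null(cb) && !is.null(na_)) sqrt(sum((cb - na_)^2)) else NA_real_
  suppressWarnings(min(d1, d2, na.rm = TRUE))
}
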