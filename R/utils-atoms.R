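## Internal helpers over the flat atom table.

.AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
          H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
          P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
          W = "TRP", Y = "TYR")
.AA1 <- structure(names(.AA3), names = .AA3)

## residue numbers in stored (reading) order
.resOrder <- function(at) unique(at$resno)

.chainSequence <- function(at) {
  rn <- .resOrder(at)
  res3 <- at$resid[match(rn, at$resno)]
  one <- .AA1[res3]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

## coordinates of one named atom; NULL if absent
.pos <- function(at, resno, elety) {
  i <- which(at$resno == resno & at$elety == elety)
  if (!length(i)) return(NULL)
  c(at$x[i[1L]], at$y[i[1L]], at$z[i[1L]])
}

.setPos <- function(at, resno, elety, p) {
  i <- which(at$resno == resno & at$elety == elety)
  stopifnot(length(i) == 1L)
  at$x[i] <- p[1L]; at$y[i] <- p[2L]; at$z[i] <- p[3L]
  at
}

.xyz <- function(at) cbind(x = at$x, y = at$y, z = at$z)

.setXyz <- function(at, m) {
  at$x <- m[, 1L]; at$y <- m[, 2L]; at$z <- m[, 3L]
  at
}

## append one atom row inheriting chain/resid bookkeeping from the residue
.addAtom <- function(at, resno, elety, elesy, p) {
  i <- which(at$resno == resno)[1L]
  stopifnot(!is.na(i))
  row <- at[i, , drop = FALSE]
  row$elety <- elety; row$elesy <- elesy
  row$x <- p[1L]; row$y <- p[2L]; row$z <- p[3L]
  row$o <- 1; row$b <- 0; row$alt <- ""
  ## insert after the last atom of that residue to keep residues contiguous
  last <- max(which(at$resno == resno))
  out <- rbind(at[seq_len(last), , drop = FALSE], row)
  if (last < nrow(at))
    out <- rbind(out, at[(last + 1L):nrow(at), , drop = FALSE])
  rownames(out) <- NULL
  out
}

.dropAtoms <- function(at, resno, elety) {
  keep <- !(at$resno %in% resno & at$elety %in% elety)
  at[keep, , drop = FALSE]
}

## max per-atom displacement between two conformers of the same atom table
.maxDisplacement <- function(a, b) {
  ka <- paste(a$resno, a$elety)
  kb <- paste(b$resno, b$elety)
  common <- intersect(ka, kb)
  if (!length(common)) return(0)
  pa <- .xyz(a)[match(common, ka), , drop = FALSE]
  pb <- .xyz(b)[match(common, kb), , drop = FALSE]
  sqrt(max(rowSums((pa - pb)^2)))
}

.rmsdOver <- function(a, b, eletys = c("N", "CA", "C", "O")) {
  sa <- a[a$elety %in% eletys, , drop = FALSE]
  ka <- paste(sa$resno, sa$elety)
  sb <- b[b$elety %in% eletys, , drop = FALSE]
  kb <- paste(sb$resno, sb$elety)
  common <- intersect(ka, kb)
  pa <- .xyz(sa)[match(common, ka), , drop = FALSE]
  pb <- .xyz(sb)[match(common, kb), , drop = FALSE]
  sqrt(mean(rowSums((pa - pb)^2)))
}

.isBackbone <- function(elety) elety %in% c("N", "CA", "C", "O", "OXT")

## residues in stored order with their backbone positions as a list
.residueFrames <- function(at) {
  rn <- .resOrder(at)
  lapply(rn, function(r) {
    list(resno = r,
         resid = at$resid[match(r, at$resno)],
         N = .pos(at, r, "N"), CA = .pos(at, r, "CA"),
         C = .pos(at, r, "C"), O = .pos(at, r, "O"),
         CB = .pos(at, r, "CB"))
  })
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## peptide residues must be numbered 1..L without gaps or inserts
.assertNormalized <- function(at) {
  rn <- .resOrder(at)
  L <- length(rn)
  if (!(identical(sort(rn), seq_len(L)) || identical(sort(rn), rev(seq_len(L))) ||
        identical(as.integer(sort(rn)), seq_len(L))))
    .stopf("peptide must be numbered 1..L without gaps (found %s)",
           paste(range(rn), collapse = ".."))
  invisible(L)
}

## renumber peptide residues to 1..L in stored order
.normalizeNumbering <- function(at) {
  rn <- .resOrder(at)
  at$resno <- match(at$resno, rn)
  at
}
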