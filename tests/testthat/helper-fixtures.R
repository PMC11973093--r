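# Shared fixture generators.  Randomized peptides emulate MHC-II-bound
# cores: extended PPII-like backbones with per-residue dihedral
# heterogeneity, mixed sequences including glycine and proline.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomSequence <- function(L, forceGlyPro = TRUE) {
  s <- sample(.AA20, L, replace = TRUE)
  if (forceGlyPro && L >= 4) {
    s[sample(2:(L - 1), 1)] <- "G"
    s[sample(setdiff(2:(L - 1), which(s == "G")), 1)] <- "P"
  }
  paste(s, collapse = "")
}

randomFixture <- function(L = sample(9:20, 1), decoyGroove = FALSE,
                          anchors = integer()) {
  sq <- randomSequence(L)
  buildIdealPeptide(
    fixtureSpec(sq, phi = runif(L, -140, -70), psi = runif(L, 110, 160),
                decoyGroove = decoyGroove),
    anchors = anchors)
}

# minimal hand-built chain for arithmetic-level checks
chainFromAtoms <- function(df, chainId = "P") {
  df$chain <- chainId
  df$insert <- ""; df$alt <- ""; df$o <- 1; df$b <- 0
  df$elesy <- substr(sub("^[0-9]+", "", df$elety), 1, 1)
  new("PeptideChain", chainId = chainId,
      atoms = df[, c("chain", "resno", "resid", "insert", "elety", "elesy",
                     "alt", "x", "y", "z", "o", "b")])
}

pepAtoms <- function(x) atoms(peptide(x))

maxAtomShift <- function(a, b) {
  ka <- paste(a$resno, a$elety); kb <- paste(b$resno, b$elety)
  common <- intersect(ka, kb)
  pa <- as.matrix(a[match(common, ka), c("x", "y", "z")])
  pb <- as.matrix(b[match(common, kb), c("x", "y", "z")])
  sqrt(max(rowSums((pa - pb)^2)))
}

backboneRMSD <- function(a, b, eletys = c("N", "CA", "C", "O")) {
  a <- a[a$elety %in% eletys, ]; b <- b[b$elety %in% eletys, ]
  ka <- paste(a$resno, a$elety); kb <- paste(b$resno, b$elety)
  common <- intersect(ka, kb)
  pa <- as.matrix(a[match(common, ka), c("x", "y", "z")])
  pb <- as.matrix(b[match(common, kb), c("x", "y", "z")])
  sqrt(mean(rowSums((pa - pb)^2)))
}

revString <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")

randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigidlyMove <- function(cx, R = randomRotation(), t = rnorm(3, sd = 5)) {
  mv <- function(at) {
    m <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
    at$x <- m[, 1] + t[1]; at$y <- m[, 2] + t[2]; at$z <- m[, 3] + t[3]
    at
  }
  cx@receptor <- mv(cx@receptor)
  cx@peptide@atoms <- mv(cx@peptide@atoms)
  cx
}
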