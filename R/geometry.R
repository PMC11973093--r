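## Exact vector-geometry kernels.  Everything here is pure: points are
## length-3 numerics in Angstrom, angles are degrees.

#' Geometry kernels
#'
#' `midpoint(a, b)` returns (a+b)/2.  `invertThroughPoint(x, m)` returns the
#' point inversion 2m - x, the operator used to mirror a backbone carbonyl
#' and amide nitrogen through the midpoint between adjacent alpha carbons:
#' the midpoint lies (to good approximation) in the peptide plane, so
#' inversion maps that plane onto itself while swapping the spatial roles of
#' C and N.  `reflectAcrossPlane(x, p)` reflects across a plane given by
#' three non-collinear points.  Both transforms are isometries.
#'
#' @param a,b,x,m length-3 numeric points (Angstrom).
#' @param p a plane from [planeFromPoints()].
#' @return a length-3 numeric point.
#' @examples
#' midpoint(c(0, 0, 0), c(2, 0, 0))
#' invertThroughPoint(c(0.5, 1, 0), c(1, 0, 0))
#' @export
midpoint <- function(a, b) (a + b) / 2

#' @rdname midpoint
#' @export
invertThroughPoint <- function(x, m) 2 * m - x

#' Construct a plane from three points
#'
#' @param p1,p2,p3 length-3 numeric points; must not be collinear
#'   (triangle area > 1e-6 A^2).
#' @return a list with the defining `origin` and unit `normal`.
#' @export
planeFromPoints <- function(p1, p2, p3) {
  n <- .cross(p2 - p1, p3 - p1)
  area <- sqrt(sum(n^2)) / 2
  if (!is.finite(area) || area <= 1e-6)
    .stopf("degenerate plane: defining points are (nearly) collinear")
  list(origin = p1, normal = n / sqrt(sum(n^2)))
}

#' @rdname midpoint
#' @export
reflectAcrossPlane <- function(x, p) {
  d <- sum((x - p$origin) * p$normal)
  x - 2 * d * p$normal
}

.cross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Torsion angle of four points
#'
#' IUPAC sign convention, degrees in (-180, 180].  Used for phi/psi/omega
#' measurement and for the carbonyl-planarity restraint.
#'
#' @param a,b,c,d length-3 numeric points; consecutive points must be
#'   distinct and b-c must not be collinear with a or d.
#' @return angle in degrees.
#' @export
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  if (min(sum(b1^2), sum(b2^2), sum(b3^2)) < 1e-12)
    .stopf("dihedral undefined: coincident consecutive points")
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (min(sum(n1^2), sum(n2^2)) < 1e-12)
    .stopf("dihedral undefined: collinear points")
  y <- sum(.cross(n1, n2) * .unit(b2))
  ang <- atan2(y, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Alpha-carbon chirality of a residue
#'
#' Labels the residue L, D or achiral from the sign of
#' det[N-CA, C-CA, CB-CA].  The sign convention is calibrated against an
#' ideal L-alanine (built from standard internal coordinates and
#' cross-checked against an independent cheminformatics construction of
#' (S)-alanine): a positive determinant is the natural L form.  Glycine has
#' no CB and is achiral.
#'
#' @param residue either a one-residue slice of an atom table
#'   (data.frame) or a list with named positions `N`, `CA`, `C`, `CB` and a
#'   `resid` 3-letter code.
#' @return one of `"L"`, `"D"`, `"achiral"`.
#' @export
chiralityOf <- function(residue) {
  fr <- if (is.data.frame(residue)) {
    r <- residue$resno[1L]
    list(resid = residue$resid[1L],
         N = .pos(residue, r, "N"), CA = .pos(residue, r, "CA"),
         C = .pos(residue, r, "C"), CB = .pos(residue, r, "CB"))
  } else residue
  if (identical(fr$resid, "GLY")) return("achiral")
  if (is.null(fr$N) || is.null(fr$CA) || is.null(fr$C))
    .stopf("chirality undefined: residue lacks a complete N/CA/C frame")
  if (is.null(fr$CB))
    .stopf("chirality undefined: non-glycine residue lacks CB")
  d <- det(rbind(fr$N - fr$CA, fr$C - fr$CA, fr$CB - fr$CA))
  if (d > 0) "L" else "D"
}

## signed triple product underlying chiralityOf, for restraints/reports
.chiralityDet <- function(N, CA, C, CB) {
  det(rbind(N - CA, C - CA, CB - CA))
}

## NeRF placement: position D with |CD| = bond, angle(B,C,D) = ang (deg),
## torsion(A,B,C,D) = tor (deg).  The torsion follows the same sign
## convention as dihedralAngle.
.placeAtom <- function(A, B, C, bond, ang, tor) {
  th <- ang * pi / 180
  ph <- tor * pi / 180
  bc <- .unit(C - B)
  n <- .cross(B - A, bc)
  if (sum(n^2) < 1e-12)
    .stopf("cannot place atom: reference frame is collinear")
  n <- .unit(n)
  m <- .cross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}
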