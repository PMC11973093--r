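---
title: "Generating reversed-peptide templates for MHC class II modeling"
author: "RetroMHCII"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating reversed-peptide templates for MHC class II modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RetroMHCII)
```

## The problem

MHC class II molecules hold a ~9-residue peptide core in an open groove,
anchored at pockets P1/P4/P6/P9 and stabilized by a conserved
hydrogen-bond ladder between groove walls and peptide backbone. A subset
of HLA-DP allotypes binds peptides in the reverse orientation (C→N).
Because reversed and canonical binders use the same pockets and a very
similar (slightly shifted) hydrogen-bond pattern, the structural
information needed to model a reversed binder is already present in
canonical structures — if the canonical peptide can be turned into a
chemically valid reversed one *in place*. That coordinate transformation,
its quality control, and the binding-core L-RMSD used to judge the
resulting models are what this package implements. Downstream homology
modeling (restraint generation, side-chain threading, refinement) is a
separate engine's job and out of scope here.

## The reversal transformation

The central observation is that reversing a bound peptide is almost
entirely a *local* operation on each peptide bond. Writing $m_i$ for the
midpoint of $C\alpha_i$ and $C\alpha_{i+1}$, the pipeline is:

1. **Renumbering** ($r \mapsto L+1-r$): pure bookkeeping; the sequence
   string inverts, no atom moves.
2. **Peptide-bond mirroring**: $C_i$, $O_i$ and $N_{i+1}$ are replaced by
   their point inversion $x' = 2m_i - x$. We implement "mirroring across
   the midpoint" as point inversion rather than reflection across the
   perpendicular-bisector plane: the midpoint lies (exactly, for an ideal
   trans bond; approximately, in real structures) in the amide plane, and
   inversion through an in-plane point maps that plane onto itself, so
   the carbonyl and amide keep their plane — and hence the groove's
   hydrogen-bond directions — while C and N trade places. A
   perpendicular-bisector reflection would instead throw the carbonyl O
   out of plane. Inversion is also an involution, which makes the step
   exactly self-inverse and easy to audit.
3. **Reassignment**: inversion parks each mirrored carbonyl next to the
   opposite $C\alpha$ of its bond, so C/O move to the residue across the
   bond and N moves the other way. After this every interior residue owns
   exactly one N, CA, C, O.
4. **Terminal rebuild**: the old chain ends have no bond to mirror
   through. We delete the old carboxylate (C, O, OXT) and old amide N and
   regenerate the new terminal groups geometrically: the new N-terminal N
   along the old terminal-carbonyl direction at 1.458 Å; the new
   C-terminal C along the old amide-N direction at 1.525 Å, with O and
   OXT placed trigonally in the N–CA–C plane (C–OXT 1.25 Å). The
   published procedure only states that terminal groups are removed and
   regenerated (there with a structure-completion tool); the geometric
   construction is our choice and is deterministic, which keeps database
   builds byte-reproducible.
5. **Chirality correction**: swapping the spatial roles of N and C around
   a fixed CA/CB converts every chiral center to the D form. Each
   D-labelled CA is reflected across the plane of its own N, C and CB.
   Since those three atoms lie on the mirror plane, every bond from CA to
   them keeps its exact length; only angles change slightly. Glycine is
   achiral and skipped. The label itself is the sign of
   $\det[N-C\alpha,\; C-C\alpha,\; C\beta-C\alpha]$, with the convention
   (positive = L) calibrated once against an ideal L-alanine built from
   standard internal coordinates and cross-checked against an independent
   cheminformatics construction of (S)-alanine, rather than asserted a
   priori — a cheap insurance against a sign-convention bug.
6. **Proline rings**: reflection of CA breaks the pyrrolidine; CB, CG, CD
   are regenerated from fixed ideal internal coordinates on the corrected
   N–CA–C frame (ring torsions solved once so the N–CD closure lands at
   1.52 Å), after the chirality fix, because the ring geometry depends on
   the final CA position. The rebuild assumes the common trans isomer; a
   cis bond preceding a proline is reported with a warning rather than
   silently flipped, since converting it would require moving backbone
   atoms the mirroring step deliberately leaves untouched.

Anchor positions renumber by the involution $p \mapsto L+1-p$ — a
reversed peptide keeps its anchors in the same pockets — and we apply it
last, as pure bookkeeping independent of the coordinate steps.

## Geometry regularization

The coordinate surgery leaves small covalent distortions (the mirrored
C–N bond across each new peptide bond is slightly long, angles at the
reflected CA are a few degrees off). The default regularizer is an
internal restrained steepest descent with a backtracking (Armijo) line
search on bonded terms only:

| term         | target                                  | force constant |
|--------------|------------------------------------------|---------------|
| bond lengths | N–CA 1.458, CA–C 1.525, C–N 1.329, C–O 1.231, CA–CB 1.521 Å (+ ring, OXT) | 100 Å$^{-2}$ |
| bond angles  | standard backbone/ring values            | 20 rad$^{-2}$ |
| torsions     | ω = 180° and carbonyl-planarity improper | 5 (periodic, $1-\cos$) |
| chirality    | hinge keeping $\det > 1.0$ Å$^3$ per residue | 10 |

Gradients are analytic (verified against central differences), descent is
fully deterministic, and the penalty is non-increasing across iterations
by construction. The receptor is simply not part of the coordinate
vector, so receptor fixing is exact rather than approximate. Iteration
stops when bonds are within 0.03 Å and angles within 3° of ideal, at the
step budget (default 300), or when one more step would push the
peptide-backbone RMSD past the drift cap (default 0.8 Å); failure to
reach bond ±0.1 Å / angle ±8° raises a convergence error with the
residuals. Nonbonded terms are deliberately absent: this step exists to
repair covalent geometry, not to relax packing, and the drift cap bounds
how far the peptide can wander. A ten-step thermostatted MD run — the
classical way to do this repair — is supported as an adapter contract
(`engine = "external-MD"`: input PDB plus fixed-receptor mask, output
PDB, 300 K and 10 steps as defaults), with the receptor-fixity and
drift-cap contracts audited on the adapter's output; no MD engine is
bundled. `addHydrogens()` serves that path (amide/ammonium H, HA, HB by
residue type, proline ring hydrogens, carboxylate left bare); the
internal engine is heavy-atom only and skips protonation.

## Evaluation

`superpose()` is the closed-form Kabsch solution (SVD with the
determinant correction, so reflections are never returned) and
`coreLRMSD()` superposes model on reference using receptor CA atoms, then
scores the peptide core backbone (N, CA, C, O by default; N, CA, C
configurable) without re-fitting on the peptide — rigid offsets of the
ligand in the groove are therefore penalized, and any common rigid
transform of both structures cancels. Core correspondence between a
reversed model and a canonical reference is by groove position
(`map = "reversed"` pairs reversed index $L+1-p$ with canonical $p$),
because pockets, not sequence indices, are what reversal preserves.
`validateGeometry()` is the automated stand-in for eyeballing each
template: per-residue chirality, backbone bond deviations, ω deviations,
and violation counts at bond ±0.1 Å and ω ±30°; database builds
quarantine any template that violates it.

## Synthetic fixtures: what they emulate, and what they do not

`buildIdealPeptide()` grows chains by sequential internal-coordinate
(NeRF) placement: exact standard bond lengths and angles, user-specified
φ/ψ/ω, CB placed with natural L chirality, proline with a closed ring,
and optionally a rigid decoy groove — two 32-residue poly-alanine helices
flanking the peptide — so that receptor-superposition and
receptor-fixity contracts are exercisable without an experimental file.
Randomized suites draw lengths 9–20, sequences containing glycine and
proline, and per-residue φ ~ U(−140°, −70°), ψ ~ U(110°, 160°) — an
extended, PPII-like ensemble with the dihedral heterogeneity seen in
groove-bound cores (single-point defaults: φ = −75°, ψ = 145°, ω = 180°).

What passing on these fixtures does *not* show: real structures have
full side chains (fixtures stop at the CB frame except proline),
imperfect bond geometry, altlocs, waters and real groove contacts.
Preprocessing (altloc resolution by highest occupancy with ties broken
by altloc letter, hydrogen stripping, MSE→MET substitution) and the
QC gate are exercised on such inputs only through the PDB round-trip
tests, not against the crystallographic zoo. Results on ideal fixtures
bound the algorithm's intrinsic behaviour, not its robustness to
pathological files.

## Numerical choices and degenerate inputs

* Coordinates are double precision throughout; PDB column precision
  (10$^{-3}$ Å) applies only at write time.
* Peptide-bond direction per residue pair is detected from the two C–N
  distances, so mirroring works identically before or after renumbering;
  a C(i)–N(i+1) distance above 2.5 Å is a chain break and aborts the
  reversal (mirroring assumes a continuous backbone).
* Insertion codes in the peptide are rejected outright — the anchor
  involution assumes a gap-free 1..L numbering, which the pipeline
  normalizes to before reversing.
* Peptide chain selection: an explicit chain id wins; otherwise the
  shortest protein chain with 8–30 residues (MHC chains are far longer).
* Degenerate geometry raises: collinear plane points (area ≤ 10$^{-6}$
  Å$^2$), collinear/coincident dihedral atoms, superposition with n < 3
  or collinear sets.
* Torsions follow the IUPAC sign convention (invariant under atom-order
  reversal, sign-flipped by mirror reflection), verified against an
  independent implementation.

## Problem sizes

The test suite and `scripts/acceptance.R` use 20 randomized fixtures
(lengths 9–20; receptor-dependent checks on subsets of 6–8 with the
decoy groove), 1000 random rigid transforms for the Kabsch optimality
spot-check, and 25 random anchor sets for the involution property; the
full suite runs in well under a minute on a laptop-class core.

## Known limitations

* **Double reversal is not exact.** Reversing twice (regularization off)
  recovers the sequence exactly, but the chirality step reflects every
  CA across its N/C/CB plane — for ideal tetrahedral geometry the CA
  sits about half an Ångström off that plane, so each pass moves each CA
  by about twice that (the per-step displacement is printed in every
  `ReversalReport`). The second pass therefore inverts through slightly
  shifted midpoints, and the recovered backbone differs by a
  conformation-dependent floor that the acceptance script measures
  (`double_reversal_backbone_rmsd_angstrom`, median ≈ 0.7 Å on the
  extended ensemble; smaller for flatter, beta-like backbones). This is
  intrinsic to the reflect-the-CA construction, not an accuracy loss in
  the forward direction — a template is produced by a single pass.
* The regenerated terminal O/OXT orientation is a convention (in the
  N–CA–C plane), since the source structure has no atom there; the
  regularizer treats it like any other carbonyl.
* No nonbonded terms in the internal engine: clashes are bounded only by
  the drift cap, as in any short bonded-repair step.
* cis-prolines are flagged, not converted.
* Hydrogens are placed for the backbone + CB frame (and proline ring)
  only — sufficient for the adapter hand-off, not a full protonation of
  arbitrary side chains.
* Receptor domains are not annotated: the receptor fit uses all receptor
  CA atoms unless the caller restricts them.
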