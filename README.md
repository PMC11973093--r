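# RetroMHCII

Reversed-peptide template generation for MHC class II complexes.

Some HLA class II allotypes (notably several HLA-DP molecules) can bind
peptides in the reverse orientation — C-terminus to N-terminus — while
using the same groove pockets, and such reversed binders still activate
CD4+ T cells. Template-based modeling of these complexes is blocked by
data scarcity: only a couple of reversed pMHC-II structures exist, so
there is essentially nothing to thread a new reversed peptide onto.
RetroMHCII addresses this for structural immunologists by *manufacturing*
reversed templates from the abundant canonical structures: it takes a
canonically bound peptide in a pMHC-II complex and converts it, by exact
coordinate geometry, into a chemically valid reversed peptide occupying
the same groove.

## The algorithm

For a peptide of length L numbered 1..L in the groove, the reversal is:

1. **Renumber** residues in reverse (r → L+1−r), inverting the sequence
   without moving any atom.
2. **Mirror the peptide bonds**: for each bond i→i+1, the carbonyl C, O
   and amide N are replaced by their point inversion through the midpoint
   m of the flanking alpha carbons, x′ = 2m − x. The midpoint lies in the
   peptide plane, so the mirrored atoms stay in that plane — preserving
   the backbone hydrogen-bonding directions the groove relies on — while
   the spatial roles of C and N are exchanged.
3. **Reassign and rebuild termini**: mirrored atoms are re-owned by their
   new residues; the old terminal carboxylate (C/O/OXT) and ammonium N are
   removed and regenerated at the opposite ends.
4. **Correct chirality**: exchanging N and C around a fixed CA/CB turns
   every chiral residue into its D form; the natural L form is restored by
   reflecting each CA across its own N/C/CB plane (det[N−CA, C−CA, CB−CA]
   > 0 defines L; glycine is achiral and skipped). Proline pyrrolidine
   rings are rebuilt on the corrected frame in the trans configuration.
5. **Regularize**: a restrained minimization of bonded terms (bond
   lengths, angles, trans-ω and carbonyl planarity, an L-chirality hinge)
   removes the small covalent distortions, with the MHC receptor held
   exactly fixed and the peptide backbone capped at 0.8 Å drift.

Anchors renumber under the involution p → L+1−p (an anchor keeps its
pocket; the canonical 9-mer set {1,4,6,9} maps to itself). Models are
scored with the binding-core ligand RMSD: Kabsch superposition on
receptor CA atoms, then RMSD over the core backbone atoms (N, CA, C, O)
with no re-fitting on the peptide.

## Worked example

```r
library(RetroMHCII)

cx <- buildIdealPeptide(
  fixtureSpec("KVTVAFNQF", decoyGroove = TRUE),
  anchors = c(1, 4, 6, 9), sourceId = "SYN1")
rv <- reversePeptide(cx)
rv$complex
#> PMHCComplex 'SYN1'
#>   receptor: 2 chain(s) [A,B], 322 atoms
#>   peptide : chain 'P', 9 residues (FQNFAVTVK)
#>   anchors : 1, 4, 6, 9
rv$report
#> ReversalReport
#>   renumber           max displacement 0.000 A
#>   mirror             max displacement 3.527 A
#>   reassign           max displacement 0.000 A
#>   termini            max displacement 0.000 A
#>   chirality          max displacement 1.010 A
#>   proline            max displacement 0.000 A
#>   regularize         max displacement 1.114 A
#>   chirality fixed at: 1, 2, 3, 4, 5, 6, 7, 8, 9
#>   prolines rebuilt at: <none>
#>   regularization backbone RMSD: 0.516 A
validateGeometry(rv$complex)
#> GeometryReport: 0 chirality / 0 bond / 0 omega violation(s)
#>   tolerances: bond 0.10 A, omega 30 deg
```

The peptide KVTVAFNQF becomes FQNFAVTVK in place: the sequence is exactly
reversed, every alpha-carbon center is back in the natural L form, the
symmetric anchor set stays on its pockets, and the regularizer moved the
backbone by 0.52 Å while the two receptor chains did not move at all.

Batch construction of a template database from a directory of PDB files
(`<PDBID>.pdb` plus a YAML anchors table) emits one `<PDBID>_reversed.pdb`
and a JSON metadata sidecar per input, gated by the automated geometry QC:

```r
records <- buildReversedDB("structures/", "templates/",
                           anchorsTable = "anchors.yaml")
```

A thin command-line wrapper is installed at `inst/scripts/revmhc`
(subcommands `reverse`, `build-db`, `lrmsd`, `validate`, `make-fixture`).

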