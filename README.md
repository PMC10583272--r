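# ncAAlib

Preparing non-canonical amino acids (ncAAs) for NMR structure
calculation.  Peptides with post-translational modifications,
non-ribosomal residues or engineered side chains cannot be calculated
with the stock residue libraries of CYANA, CNS, Xplor-NIH or ARIA; this
package generates what those engines need from an explicit molecular
graph (PDB with CONECT records, or Mol2, all hydrogens present):

* **IUPAC/IUBMB atom renaming** of arbitrary side chains.  Heavy atoms
  are labelled by bond distance from Cα with transliterated Greek
  letters (β = 1 bond, γ = 2, …, ω = 23, then two-letter codes αα…ωω —
  600 positions in all), and equidistant branches get chain numbers from
  Cahn–Ingold–Prelog priority: atomic number first, then sorted
  atomic-number spheres of the hierarchical digraph (multiple bonds
  expanded into phantom duplicates), and for two identical branches at a
  tetrahedral centre the sign of the determinant

      | x_a  y_a  z_a  1 |
      | x_b  y_b  z_b  1 |     a, b: the branches compared
      | x_c  y_c  z_c  1 |     c: the central atom (stand-in 4th row)
      | x_r  y_r  z_r  1 |     r: the anchor, nearest the Cα

  Prochiral methylene hydrogens are numbered 2/3 by the same
  construction.  Ring-joining atoms take the lower chain id; a symmetry
  re-pass keeps chain numbers of duplicated rings consecutive.
* **Capped-template recognition and excision**: Ace–Ala–X–Ala–NMe,
  X–Ala–NMe and Ace–Ala–X are classified as internal / N-terminal /
  C-terminal submissions; the central group X is excised with named
  backbone atoms, attachment annotations and a CCD-style component CIF.
* **Side-chain linking for torsion-angle dynamics**: from two extended
  residue templates (each reaching beyond the linking bond, e.g.
  Cα–Cβ–Sγ–Sγ′–Cβ′ for a disulfide) it retypes the extension atoms as
  DUMMY (pseudoatoms untouched), writes one upper-distance restraint
  per overlap pair (default 0.04 Å, weight 10) and the link statement
  removing the repulsion between the bonded atoms; after calculation
  `finalizeStructure()` strips the DUMMY atoms and renames residues.
* **CNS building blocks**: standard atom types and charges retained for
  the backbone atoms N, HN, CA, HA, CB, O; fresh types elsewhere; the
  residual charge is absorbed by the non-backbone atom of largest
  charge magnitude so net charge is conserved to 1e-6 e; atom-type
  clashes between blocks are merged or deterministically renamed.

## Worked example

Build the capped ornithine template, excise and name the residue, then
link two extended cysteines into a disulfide:

```r
library(ncAAlib)

orn <- makeFixture("capped-ornithine")   # Ace-Ala-Orn-Ala-NMe
cls <- classifyTemplate(orn)
cls
#> TemplateClassification: internal
#>   X group: 18 atoms; caps/flanks: ace, ala_n, ala_c, nme
ex <- exciseResidue(orn, cls)
subset(nameMap(ex$naming), kind == "sidechain")
#>   serial oldName newName      kind
#> 1     21      CB      CB sidechain
#> 2     24      CG      CG sidechain
#> 3     27      CD      CD sidechain
#> 4     30      NE      NE sidechain

tmpl <- makeExtendedTemplate("CYSX")     # side chain CB-SG + image SD-CE
spec <- makeLinkSpec(tmpl, tmpl, 3, 12, c("SG", "SG"),
                     overlapA = c(SD = "SG", CE = "CB"),
                     overlapB = c(SD = "SG", CE = "CB"))
res <- linkTemplates(spec)
res
#> LinkResult: 4 restraints, 8 DUMMY atoms, link SG 3 - SG 12
writeUpl(restraints(res), "cysx.upl")
#>    3 CYSX  SD      12 CYSX  SG        0.04    10.00
#>    3 CYSX  CE      12 CYSX  CB        0.04    10.00
#>   12 CYSX  SD       3 CYSX  SG        0.04    10.00
#>   12 CYSX  CE       3 CYSX  CB        0.04    10.00
writeLinkStatement(linkStatement(res), "cysx.seq")
#> link SG 3 SG 12
```

The ornithine side chain is the unbranched chain Cβ–Cγ–Cδ–Nε, so the
sole-occupant rule drops every chain number (`CB`, `CG`, `CD`, `NE`);
the restraints pull each template's duplicated extension atoms (`SD`,
`CE` — the image of the partner's Sγ and Cβ) onto the partner's real
atoms with a 0.04 Å upper limit at weight 10, and the link statement
names the two Sγ atoms whose repulsion term is lifted.

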