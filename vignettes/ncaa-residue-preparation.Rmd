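---
title: "Preparing non-canonical amino acids for NMR structure calculation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparing non-canonical amino acids for NMR structure calculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncAAlib)
```

## The problem

NMR structure calculation engines (CYANA, CNS, Xplor-NIH, ARIA) ship
residue libraries for the canonical amino acids only.  A peptide carrying
a non-canonical amino acid (ncAA) — a post-translational modification, a
non-ribosomal residue such as ornithine, an engineered side chain — needs
three things before restraints can be turned into coordinates: a residue
template with *unique, IUPAC/IUBMB-conformant atom names*; a way to
describe *side-chain-to-side-chain bonds* (disulfides, biaryl ethers,
ring-closing-metathesis staples) inside torsion-angle dynamics; and, for
Cartesian-space refinement, a *CNS building block* whose backbone atoms
remain compatible with the standard protein force field.  `ncAAlib`
implements all three steps on explicit molecular graphs (PDB with CONECT
records, or Mol2), plus the capped-template convention used to submit an
ncAA in a realistic chemical environment.

## Atom renaming

Side-chain heavy atoms are labelled by their bond distance from the
alpha carbon: one bond is beta, two bonds gamma, and so on, using the
Roman transliteration A B G D E Z H Q I K L M V X O P R S T U F C Y W.
From position 25 the alphabet repeats as two-letter codes
(`AA` … `WW`), so the scheme supports 600 positions in total:

```{r}
length(positionLabels())
positionLabel(c(1, 2, 14, 23, 24, 599))
```

Branches equidistant from the alpha carbon are distinguished by a *chain
identifier* assigned from Cahn–Ingold–Prelog priority: the branch is
ranked by the atomic number of its first atom, then by the sorted
atomic numbers one bond away, and so on over expanding spheres of the
hierarchical digraph.  Multiple bonds are expanded into phantom
duplicate atoms beforehand, as CIP requires; an aromatic atom receives
one duplicate of its heaviest aromatic partner (a Kekulé-free
convention — the literature offers no single prescription here, and the
choice is configurable through `expandUnsaturation()`).

When two branches are graph-identical the geometry decides: for a
tetrahedral centre with exactly two identical substituents, the sign of
the determinant of the 4×4 matrix of homogeneous coordinates — the two
candidates in the top rows, the centre standing in for the fourth
substituent, and the anchor atom (the neighbour closest to the alpha
carbon, which always has the highest priority) in the bottom row —
assigns the lower chain number.  The same construction numbers the two
hydrogens of a methylene (suffixes 2/3, BMRB style) and the alpha
hydrogens of glycine.  Three identical branches are arbitrary by
rotation and no geometric step is attempted.

Two special rules complete the scheme.  An atom closing a ring is
reached by two chains and keeps the lower chain number (phenylalanine's
zeta carbon joins chains 1 and 2 and is plain `CZ`).  And after
assignment a symmetry re-pass renumbers chains born inside identical
sibling subtrees into consecutive blocks, so a side chain carrying two
identical phenyl rings yields rings numbered {1,2} and {3,4} rather
than the interleaved {1,3}/{2,4}:

```{r}
dph <- makeFixture("DPH")  # CH(phenyl)(phenyl) side chain
tb <- assignChains(dph, findBackbone(dph))@table
split(tb$serial, tb$chain)[3:4]
```

A chain-1 atom that is the only heavy atom in its distance shell drops
the chain number (`SG`, `OG`, `CZ`).  Read literally — as we do by
default — this also renders isoleucine's delta methyl as `CD`, where
common usage is `CD1`; the packaged reference table documents this as
the single deviation for the canonical residues, and
`renameResidue(..., stickySuffix = TRUE)` restores the suffix downstream
of any still-open branch without affecting ring joins.

```{r}
res <- renameResidue(makeFixture("ILE"))
subset(nameMap(res), kind == "sidechain")$newName
subset(nameMap(renameResidue(makeFixture("ILE"), stickySuffix = TRUE)),
       kind == "sidechain")$newName
```

### Determinism and arbitrary choices

The renamer must be reproducible: the same molecule must get the same
names regardless of atom order in the input file or of the coordinate
frame.  Decisions that are chemically arbitrary (methyl hydrogens,
enantiotopic aromatic pairs at planar centres) are therefore ordered by
a canonical geometric key — the sorted vector of squared distances from
the candidate to every atom of the molecule, rounded at 10⁻⁶ Å² — which
is invariant under atom permutation, rigid motion *and* reflection.
Exactly coincident profiles (true molecular symmetry) fall back to
input order with an audit note.  Every priority decision is recorded in
the audit trail of the `NamingResult`, and the CLI emits it as
JSON-lines at debug level, because misnamed diastereotopic atoms are a
documented source of archive errors.

A consequence worth knowing: reflecting a structure (a d-amino acid)
swaps the prochiral hydrogen numbers and nothing else for residues whose
heavy-atom branches are CIP-distinguishable (cysteine, ornithine,
lysine, aromatics).  For valine and leucine the CIP rules themselves
make the geminal methyl *numbers* geometry-dependent, so their heavy
names legitimately swap under reflection — this is correct nomenclature,
not an instability.

## Capped templates and excision

An ncAA is parameterised inside Ace–Ala–X–Ala–NMe (internal residue),
X–Ala–NMe (N-terminal) or Ace–Ala–X (C-terminal).  `classifyTemplate()`
finds the peptide-bond motifs N–C(·)–C(=O) on the bond graph (tolerating
N-substitution and missing alpha hydrogens, so sarcosine- and
Aib-like residues work), matches the acetyl and N-methyl-amide caps and
the flanking alanines, and `exciseResidue()` cuts X out, names its
backbone N/H/CA/HA/C/O, runs the side-chain renamer, and records the
severed peptide bonds as attachment annotations (not phantom atoms).
The excised component can be written as a CCD-style CIF
(`writeComponentCif()`), the format consumed by downstream
template-tree generators.  Backbone detection prefers atoms literally
named `CA` when present, because topology-builder and CCD inputs carry
names, and falls back to the subgraph motif for raw drawings.

## Side-chain linking

To link two side chains in torsion-angle dynamics, each residue's
template is *extended* at least one atom beyond the linking bond with an
image of its partner's atoms.  `linkTemplates()` takes the two extended
templates, the linking-bond atoms and the user's overlap mapping, and

* retypes every extension atom and its hydrogens as `DUMMY`
  (pseudoatom records are never altered) — only the type-code column of
  the library entry changes, byte for byte;
* writes one upper-distance restraint per mapped overlap pair, default
  limit 0.04 Å and weight 10 (both configurable: any positive limit
  within experimental uncertainty serves, the value is not special);
* emits the link statement that removes the repulsion between the two
  linking atoms, in a configurable dialect
  (`link <atom> <res> <atom> <res>` by default — the statement syntax
  is engine-version-dependent and the default is documented rather than
  claimed).

Restraints are generated for the mapped heavy pairs only;
`hydrogenRestraints = TRUE` additionally pairs the retyped extension
hydrogens with the partner's hydrogens in name order.  A residue in two
links (the central residue of vancomycin's tricycle) is handled by
feeding the modified template back in as input — retyping is idempotent,
so serial iteration is safe.  After structure calculation,
`finalizeStructure()` deletes the DUMMY atoms from every model, renames
the working residue codes (e.g. CYSX back to CYS), and repacks serials.

## CNS building blocks

For Cartesian refinement the building block keeps the standard CNS atom
types, charges and parameters for the backbone atoms N, HN, CA, HA, CB
and O, and mints fresh types for everything else.  The retained list
follows the published convention, which omits the carbonyl carbon;
whether that omission is intentional cannot be settled from the text, so
`retainC = TRUE` is offered but off by default.  Replacing input
backbone charges with standard ones breaks charge neutrality, so the
residual is added to the non-backbone atom of largest charge magnitude
(ties broken by atom-name order, for determinism); charges then sum to
the declared net charge within 10⁻⁶ e by construction.  Atom types from
independently parameterised blocks are not globally unique;
`resolveTypeClashes()` merges parameter-identical duplicates silently
and renames conflicting ones with a numeric suffix, reporting every
rename.  The standard backbone charge table is an input, not a
constant: a synthetic example ships in
`inst/extdata/cns_backbone_charges_synthetic.tsv` and real force-field
values can be substituted without code changes.

## The fixture generator and what it does (not) show

All test inputs are generated in code.  Molecules are built from
residue recipes (the 20 canonical residues, ornithine, Aib, sarcosine,
branch/ring toys and seeded random side chains of up to 18 heavy atoms)
and embedded with idealised internal coordinates: tetrahedral /
trigonal / linear frames aligned by a Kabsch rotation, element-pair
bond lengths around 1.0–2.0 Å.  The geometry is deliberately idealised —
ring-closure bond lengths are not relaxed and conformers are not
sampled — which is irrelevant to naming (rings resolve through the
graph, not geometry) but means the fixtures do not probe near-degenerate
stereocentres the way distorted experimental coordinates might; the
degeneracy guard (determinant below 10⁻⁹ relative to the product of edge
lengths raises an explicit error) covers that boundary instead.
Random side chains are trees: they exercise priority ranking broadly
but not ring joins, which is why the aromatic and fused-ring recipes
exist.  Passing the suite demonstrates correctness of the algorithms on
well-formed, hydrogen-complete inputs, not robustness to malformed
real-world files beyond the checks documented (missing CONECT is fatal;
apparent missing hydrogens warn and flag).

An independent brute-force CIP oracle (`bruteForceCip()`, its own BFS,
its own recursive digraph construction, its own cofactor determinant) is
held to agreement with the production path on every fixture and on 200
seeded random molecules of ≤ 25 heavy atoms; the suite also checks
permutation invariance (100 shuffles per fixture), rigid-motion
invariance, and the reflection property above.  These sizes keep the
default test run around half a minute on one core while still covering
every rule; they are comfortably representative because every decision
the algorithm can take is already reachable below 25 heavy atoms.

## Known limitations

* CIP is implemented to the depth the nomenclature needs: atomic number
  over expanding spheres plus the geometric step.  Mass numbers, E/Z and
  like/unlike auxiliary descriptors are out of scope, as is naming of
  non-amino-acid ligands.
* Bond perception is never attempted: connectivity must be explicit
  (CONECT, Mol2 bond table), and aromaticity is taken from the input.
* The CYANA library dialect here is the fixed-column one produced by
  `graphToTemplate()`; reading preserves unknown trailing columns
  verbatim, but exotic library variants were not sampled.
* Whether X may itself contain additional peptide bonds is left as an
  ambiguity error rather than a guess.
* Quantum-mechanical geometry optimisation, charge derivation and the
  torsion-tree generation consumed by torsion-angle engines are upstream
  tools' responsibilities and are not reimplemented.
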