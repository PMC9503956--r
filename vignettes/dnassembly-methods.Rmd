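---
title: "Template-based assembly of DNA tertiary structures: models and methods"
author: "dnassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based assembly of DNA tertiary structures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

Given a DNA sequence and its secondary structure — written in extended
dot-bracket notation with `()` for canonical pairs, `[]` for pseudoknot
pairs, `.` for unpaired bases and `&` separating chains — `dnassembly`
builds an all-atom three-dimensional model.  The method is template-based:
experimental structures are cut into fragments at the level of *smallest
secondary elements* (SSEs), the target is cut the same way, the
best-matching fragment is found for each target element, and the fragments
are glued back together by rigid superposition on the base pairs that
adjoining elements share.  When every element has a template with exactly
matching secondary structure the assembly itself is the final answer;
otherwise the assembly is refined by coarse-grained simulated-annealing
Monte Carlo (SAMC) under a knowledge-based statistical potential.

## Smallest secondary elements

An SSE is either a *stem* (a maximal run of stacked canonical pairs,
adjacent on both strands) or a loop element classified by the helix ends
that close it:

* **hairpin** — one helix end;
* **bulge / internal** — two helix ends, with exactly one / both of the
  intervening unpaired segments non-empty;
* **junction** — three or more helix ends;
* **open** — an exterior region holding the molecule's dangling 5'/3'
  termini outside any pair;
* **break** — a helix end whose two strands are separated by a chain
  break (`&`) lying between the helix's two paired segments.  Break loops
  look superficially like open loops but have helix and loop regions
  swapped, and they dominate multi-chain DNA.

Every loop element carries `min(2, helix length)` boundary base pairs from
each adjoining helix, so adjoining elements share up to two common pairs.
Those shared pairs are simultaneously the tree edges of the secondary
structure tree and the superposition interface used during assembly.

Classification choices that the notation itself does not force, and that
we therefore fixed as package policy:

* Pseudoknot pairs are recorded but treated as unpaired during
  decomposition; the SSE taxonomy has no pseudoknot element, and no
  published templating rule exists for them.
* An enclosed loop with no child helices that contains a chain break is a
  break loop; if a break occurs inside a two-or-more-ended loop, the loop
  keeps its arity-based kind and the `&` simply appears in its local
  dot-bracket string (and hence in its topology key).
* Exterior regions are split at chain breaks into strand-connected
  components; each component containing at least one unpaired position (or
  bridging two or more helices) becomes one open element.  Components
  consisting only of interior chain termini are still called open: they
  hold dangling ends, just not the global ones.
* Tree edges connect stems to loops only.  With helices of fewer than
  four pairs, two loops can share a boundary pair with each other as well;
  connecting loop pairs directly would create cycles, and the stem-loop
  restriction is what makes the decomposition a tree.

## Template library, scoring, search

Library construction filters a corpus the way the field curates one:
structures with no canonical pairs ("unStru") and pure duplexes ("Helix")
carry no loop information and are excluded, as are structures shorter than
4 nt and exact duplicates (same sequence and secondary structure).
Triplex/quadruplex annotation is accepted from the user but not inferred,
since a dot-bracket string cannot express those pairings.  What remains is
cut into one template per SSE.

Templates are indexed by their *topology key*: the local dot-bracket
string itself, including `&` placement.  Matching is scored as

> 5 points if the secondary structure is identical, otherwise 0; then 1
> point per identical nucleotide in the loop region and 0.2 points per
> identical nucleotide in the helix region.

Sequence points are counted only when the two sequences have equal length
(with unequal lengths there is no position-wise traversal to score).  Ties
are broken by preferring DNA sources over RNA, then better (smaller)
resolution, then lexicographic source id — a deterministic rule chosen by
the package.

Search proceeds DNA library → RNA library → de novo.  An RNA fragment is
converted on the fly (U→T gains the C7 methyl; A/C/G lose the 2'-OH) and
is never "perfect".  The de novo builder makes helices as ideal B-form
duplexes (36°/bp twist, 3.38 Å/bp rise) and lays unpaired nucleotides on a
smooth circular arc joining the attachment backbone atoms; the arc's bulge
height is chosen by a one-dimensional search minimizing the final
O3'–P closure gap.  The arc-side hint is computed from backbone atoms
only, so two targets with the same topology get the same loop geometry
regardless of sequence — this keeps homolog-based predictions consistent.
A distance-geometry construction would be an alternative here; we chose
deterministic ideal geometry because it is reproducible and needs no
stochastic embedding parameters.

## Ideal nucleotide geometry

Atom completion, base mutation, the de novo builder and the fixture
generator all draw on one internal table
(`inst/extdata/bform_unit.tsv`): an idealized B-form repeating unit with
one nucleotide per base type and a shared backbone, expressed in a helix
frame (axis z, twist 36°, rise 3.38 Å, Watson–Crick dyad about x).  The
unit was obtained by restrained least squares: covalent geometry
restrained to the chemical component dictionary's ideal residues, helical
closure restrained so that O3' of one step meets P of the next at 1.60 Å,
Watson–Crick hydrogen-bond distances restrained across the dyad, the
glycosidic torsion held in the anti range, and sugar chirality pinned by
signed-volume restraints.  The result is an idealized, self-consistent
fiber-like geometry — not a reproduction of any published fiber model —
with C1'–C1' pair distances of ~10.3 Å and P–P steps of ~6.6 Å.

Base mutation replaces base atoms through a *base frame*: origin at the
glycosidic nitrogen, x toward C1', z along the ring normal computed from
the atoms C2, C4, C6 (present in purines and pyrimidines alike, and the
same three atoms the coarse-grained model uses).  Backbone and sugar atoms
are never touched, so mutation is exactly invertible up to the ideal base
geometry.

## Assembly and connectivity repair

Assembly walks the secondary structure tree breadth-first from the root
(the element holding the global 5' terminus).  Each child template is
superposed onto the already-placed parent with the Kabsch algorithm using
**all heavy atoms** of the shared base pairs — at least three points, and
in practice 40–80, which fully constrains the orientation (superposing on
C1' atoms alone would not).  Where parent and child both provide an
interface residue the parent's copy is kept.  Disconnected components are
placed side by side with a fixed offset.  Finally every residue is mutated
to the target sequence.

The chain is then repaired by gradient descent on a harmonic objective:
every intra-chain O3'(i)–P(i+1) distance is restrained to 1.60 Å while
stiff positional springs (k = 0.05 vs. 1 for bonds) hold all atoms at
their input positions, so only junction neighbourhoods move.  A
backtracking line search guarantees the objective never increases; the
default iteration cap of 1000 mirrors the step count conventionally used
when a force-field minimizer does this job.  This is deliberately *not* an
energy minimization — its only contract is connectivity.

## Coarse-grained refinement

The refiner works at six beads per residue — P, C4', C2' (backbone and
sugar) and C2, C4, C6 (base).  Movable elements follow the secondary
structure: all helices are rigid bodies; hairpin loops with fewer than 5
unpaired nt and internal/bulge loops with fewer than 7 are rigid too; all
other loops move residue by residue (each residue itself a small rigid
body, which is what "residue-level" sampling means here).  A move
translates an element (≤ 2 Å), rotates it about its centroid, or rotates
it about an axis through its first phosphate (≤ 15°); acceptance is
Metropolis at the current temperature.  Temperature decays geometrically
from 5 to 0.1 (in units of the trained potential) over 50 stages, with
100 000 proposals by default — all of it overridable through
`samcConfig()`, and every run exactly reproducible from its seed.  A
harmonic term on consecutive P–P distances (k = 0.2, r0 = 6.5 Å) prevents
chain fragmentation, since the statistical potential alone has no bonded
terms.

The potential is a distance plus pseudo-torsion log-odds model,
`E = -ln((obs + c)/(ref + c))`, over 0.3 Å distance bins (0–20 Å) for the
21 unordered bead-type pairs and 10° bins for the two pseudo-torsions
eta (C4'(i−1)–P(i)–C4'(i)–P(i+1)) and theta
(P(i)–C4'(i)–P(i+1)–C4'(i+1)).  The reference state is quasi-chemical:
each distance bin's total count, apportioned by the overall frequency of
each bead-type pair.  Pair counting skips sequence neighbours (|i−j| < 2
within a chain), which would otherwise swamp the histograms with bonded
geometry.  The published parameterization of this family of potentials is
not reproduced; tables are trained from whatever corpus the user supplies
(`trainPotential()`), in the tests from the synthetic corpus itself.

Snapshots are clustered by greedy RMSD-threshold clustering (2.0 Å on the
coarse beads, largest cluster first); each cluster is represented by its
lowest-energy member and up to five representatives are returned by
energy.  All-atom detail is restored by applying each element's
accumulated rigid transform to the assembled all-atom model — possible
precisely because every element, including single flexible residues,
moves rigidly.

The selection rule is: perfect templates → the assembled structure is the
final answer and refinement is skipped; otherwise the rank-1 refined
structure is the answer.

## Evaluation

`evaluateRMSD()` reports the Kabsch-minimized all-heavy-atom RMSD, and a
"no open loop" variant that removes the unpaired nucleotides of open
elements from both structures before superposition (boundary pairs are
retained).  Dangling termini are genuinely flexible in solution — NMR
ensembles disagree wildly about them — so the no-open-loop number is
usually the fairer score.  Because the superposition is recomputed on the
reduced atom set, the no-open-loop RMSD is not mathematically guaranteed
to be smaller, and the package does not pretend it is.

## The synthetic corpus

Tests and the acceptance script run on a generated corpus
(`defaultFixtureMolecules()`): fourteen molecules covering hairpins with
and without dangling ends, bulge and internal loops, a three-way
junction, nicked hairpins with break loops, and a two-chain
open/bulge/break architecture of the kind that motivates the break-loop
element.  Every topology appears twice with different Watson–Crick
consistent sequences, so leave-one-out searches exercise homolog-based
(rather than self) templating.  Molecule sizes are 8–29 nt; refinement
runs in the tests use 10³–10⁴ proposals — small enough to keep the whole
suite under a minute, large enough for the statistical checks (the
two-state Metropolis test uses 3 × 10⁴ proposals at fixed temperature and
batch-means standard errors).

What the generator emulates: correct covalent geometry, B-form helices,
closed backbones, realistic element composition.  What it does not:
sequence-dependent helix deformation, non-canonical pairs, solvent and
ion effects, crystallographic disorder, or the structural diversity of a
real PDB-derived library.  Passing the suite therefore demonstrates the
machinery — decomposition, search, assembly, refinement, evaluation — is
correct, not that accuracy on experimental DNA matches a benchmark built
from thousands of real templates.

```{r example}
library(dnassembly)
fx <- generateFixtures(fixtureSpec(defaultFixtureMolecules()))
lib <- templateLibrary(unlist(lapply(fx, function(f)
  extractTemplates(f$structure, f$db, sourceId = f$id)), FALSE), "dna")
f <- fx[[1]]
res <- runPipeline(f$seq, paste(f$db@chains, collapse = "&"), lib,
                   exclude = f$id)
evaluateRMSD(res$best, f$structure, res$tree)
```

## Numerical choices and degenerate inputs

* Indices are global and 1-based; `&` is not counted, and chain identity
  is recovered from the break positions.
* A structure with no pairs decomposes to a single open element; its
  residues are sampled per-residue by the refiner.
* Helices of length 1 contribute a single interface pair
  (`min(2, length)` everywhere).
* Kabsch superposition enforces a proper rotation by flipping the
  smallest singular direction; collinear point sets still return a
  deterministic minimizing transform.
* Interface superposition refuses to proceed on fewer than 3 common
  atoms, naming the element pair.
* The altloc policy keeps the highest-occupancy copy (ties prefer 'A');
  only the first MODEL of multi-model files is read; residues lacking 3
  reference atoms for ideal-geometry completion are dropped with a
  message.
* Sugar pucker of RNA-derived templates is kept unchanged during U→T
  conversion; only the base and the 2'-OH change.

## Known limitations

* Pseudoknots are carried through parsing but not templated.
* G-quadruplex and triplex DNA are out of scope (class T/G structures are
  excluded at the corpus filter).
* The junction arm layout of the de novo builder is a generic splay; real
  junction geometry must come from templates.
* Clash resolution beyond junction repair is not attempted at the
  all-atom level; the refiner's excluded-volume information lives in the
  trained distance potential.
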