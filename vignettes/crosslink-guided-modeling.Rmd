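---
title: "Crosslink-guided scoring of structural models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crosslink-guided scoring of structural models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlmstools)
```

## The problem

Crosslinking mass spectrometry (XL-MS) with a lysine-reactive, MS-cleavable
reagent such as DSSO identifies pairs of lysine residues that were close in
space when the complex was crosslinked. Each identified spectrum is a
crosslink spectrum match (CSM); many CSMs can support the same unique
residue-pair crosslink. Because the reagent's spacer plus two lysine side
chains span a bounded distance, a crosslink is a distance restraint: on a
correct model of the complex, the C&alpha; atoms of the two linked lysines
should lie within roughly 35&ndash;40 &Aring;. This package uses 37 &Aring;
as the satisfaction cutoff, the working criterion for DSSO C&alpha;&ndash;C&alpha;
distances.

That restraint turns XL-MS data into a model-selection instrument for
integrative structural modeling of complexes such as the
HDAC2:MIER1:MHAP1 corepressor assembly: candidate models (from AlphaFold,
fragment assembly, docking, or anywhere else) are ranked by how many
observed crosslinks they satisfy, the satisfied crosslinks are re-exported
as explicit distance restraints for refinement and docking engines, and the
resulting assemblies are compared through contact maps, lysine&ndash;lysine
distance heatmaps and anchored superpositions.

## Workflow and the XL Score

The pipeline is a loop around external prediction engines, which are
boundary files here, never subprocess calls:

1. **Summarise** the CSM table: deduplicate to unique crosslinks, classify
   intra-/inter-molecular, count proteins and lysine coverage.
2. **Map** each unique crosslink onto a candidate model through a chain map
   (accession &rarr; chain, numbering offset).
3. **Measure** the Euclidean C&alpha;&ndash;C&alpha; distance (ED), and
   optionally the solvent-accessible surface distance (SASD), of each
   mapped crosslink.
4. **Score** each model: the XL Score is the count of crosslinks with
   distance at or below the cutoff. Models are ranked by it.
5. **Export** the satisfied crosslinks of the best model as distance
   restraints (fragment-assembly list dialect, or CNS-style `assign`
   tables for docking), feed them to the external engine, and re-score the
   refined models.
6. **Analyse** the final assemblies: 30 &Aring; contact maps, lysine
   heatmaps, difference maps between assemblies, and Kabsch superpositions
   anchored on a rigid domain.

Deduplication keys crosslinks on the unordered pair of
(accession, sequence position); peptide sequence and charge are ignored,
and endpoints are stored in canonical (sorted) order, so the result is
independent of row order and endpoint orientation. A crosslink is *intra*
exactly when the two accessions are equal; for a homo-oligomer an
accession may still map to several chains, in which case every candidate
chain pair is measured and the minimum-ED candidate is recorded. This is
the standard XL-MS convention; for a complex with one copy per protein it
changes nothing.

CSMs failing the search engine's FDR flag (1% in the source dataset) are
retained on parsing but excluded from summaries and scoring by default
(`fdr_only = TRUE`), since counts reported for such datasets refer to
FDR-passing identifications. Both modes are exposed.

### Ranking ties

"Highest XL Score" leaves ties unresolved. The ranking here is a
deterministic total order: descending satisfied count, then ascending mean
satisfied ED (a model holding the same crosslinks more tightly wins), then
lexicographic model id. Unmapped crosslinks (accession absent from the
chain map, or residue outside the model) never penalise a model's score,
but their count is reported so coverage differences between models remain
visible.

### Post-docking cluster selection

Docking engines report cluster scores (lower is better) with a standard
deviation. The selection window keeps every cluster whose score lies
within one SD &mdash; the best cluster's SD, a choice this package fixes
and documents since "within a standard deviation of each other" does not
name whose SD &mdash; of the best score; the final pick among the
shortlist is by XL Score of the cluster representatives.

## Distances

**Euclidean distance** is measured between C&alpha; atoms, not side-chain
nitrogens: the satisfaction criterion is explicitly a C&alpha; criterion,
and predicted models' side chains are the least reliable part.

**SASD** is the length of the shortest path between the two C&alpha;
positions that stays in solvent-accessible space &mdash; a straight line
through the protein core does not describe a physical crosslinker. It is
computed on a regular voxel grid over the model's bounding box padded by
the cutoff:

* grid spacing 1.0 &Aring; (configurable); a voxel is blocked when its
  center lies within (atom van der Waals radius + 1.4 &Aring; water probe)
  of any atom. Radii: C 1.7, N 1.55, O 1.52, S 1.8 &Aring;; conventional
  values.
* moves connect 26-neighbouring accessible voxels with Euclidean step
  costs (1, &radic;2, &radic;3 &times; spacing). This bounds the
  overestimate relative to the continuous shortest path at about 8% in
  free space (the worst direction lies between the axis and diagonal
  moves); the free-space limit test asserts exactly this envelope.
* the two endpoint C&alpha; atoms do not block (a residue must not wall
  itself in); endpoints still buried &mdash; typical, since neighbouring
  residues' spheres overlap them &mdash; are rescued by snapping to the
  nearest accessible voxel within 5 &Aring;. An endpoint sealed deeper
  than that is unreachable.
* the search abandons paths longer than 3 &times; cutoff. Any crosslink
  with an accessible-surface path that long is violated regardless, so the
  budget only bounds runtime.

Satisfaction is gated by ED at 37 &Aring; by default. SASD is reported
alongside; a configuration switch (`criterion = "sasd"`) gates on SASD
instead, with its own cutoff defaulting to the same 37 &Aring; &mdash;
flagged as an interpretation, since no separate SASD cutoff is
established for this workflow. SASD can only exceed ED (up to
discretization, SASD &ge; ED &minus; 2 &times; spacing, a property the
tests enforce), so ED-gating is the more permissive and more conventional
choice.

The grid search itself is exposed as `grid_shortest_path()` and is
verified voxel-for-voxel against an independent Dijkstra implementation
(igraph) on hand-built fixtures, including detours around walls and
sealed-off targets.

## Superposition

`kabsch()` is the closed-form least-squares rotation via SVD of the 3&times;3
covariance matrix, with the determinant forced to +1 by sign correction so
a physical structure is never mirrored. Collinear point sets are rejected
(the in-plane rotation is underdetermined). `superpose_on_anchor()` pairs
anchor residues by identical (chain, residue number) &mdash; models in
this workflow share numbering through the chain map, so alignment-based
pairing is out of scope &mdash; fits on the anchor C&alpha; atoms only,
transforms the whole moving model, and reports per-residue displacement
over all shared residues. Anchoring on a rigid, well-resolved domain (for
the corepressor complex, the deacetylase domain) isolates the motion of
everything else.

## Contact maps and hotspots

Residue contact maps threshold the full C&alpha; distance matrix between
two chains at 30 &Aring;, the same convention as the lysine heatmaps; the
(unstated) alternative of per-residue-pair minimum heavy-atom distance is
available behind `atoms = "all"` for models that carry side chains.
Difference maps label contact cells as exclusive to either assembly or
shared &mdash; the machine-readable counterpart of circling regions that
differ between the dimeric and trimeric assemblies. Interface "hotspots"
are operationalized as 4-connected components of the boolean contact
matrix, reported with sizes, rather than as manual annotations.

## The FRET efficiency formula

Acceptor-photobleaching FRET reports donor dequenching:
`E = (1 - I_pre / I_post) * 100` percent. The printed form of this
formula is typographically ambiguous (the fraction and the &times;100 run
together); the implementation follows the only reading consistent with
acceptor-photobleaching physics, where the donor brightens after the
acceptor is destroyed, giving E &gt; 0 when transfer was occurring.
Replicate-level statistics on efficiencies are out of scope.

## The synthetic data generator

Real inputs to this workflow &mdash; engine-exported CSM sheets and
predicted coordinates &mdash; are large and not redistributable, so the
package generates its own study data; every generated table flows through
the same readers as engine exports.

`make_structure()` builds C&alpha;-trace chains with ideal backbone
geometry: helical segments with 1.5 &Aring; rise and 100&deg; twist per
residue (3.6 residues/turn, ~3.8 &Aring; consecutive C&alpha; spacing) and
coil segments as a self-avoiding random walk with 3.8 &Aring; steps.
Lysines sit every 7th residue so crosslinkable sites exist at known
positions. The default spec &mdash; three partly helical chains of 90, 60
and 40 residues with axes 25&ndash;27 &Aring; apart &mdash; emulates a
three-subunit corepressor-sized assembly in which lysine pairs exist on
both sides of the 37 &Aring; criterion. When SASD is measured on these
C&alpha;-only traces, a blocking radius of 3.0 &Aring; per pseudo-atom
stands in for the missing side-chain volume.

`plant_crosslinks()` selects lysine pairs at ED &le; cutoff &minus; 5 &Aring;
(planted satisfied) and &ge; cutoff + 5 &Aring; (planted violated); the
5 &Aring; guard band keeps labels stable under the decoys' 0.5 &Aring;
coordinate noise. Twelve satisfied and six violated crosslinks are planted
by default &mdash; a deliberately violated-heavy mixture (25% violated)
chosen so the violated code path is exercised strongly. The CSM table is
emitted with duplicated rows across replicates, scrambled endpoint
orientation and shuffled row order, so recovering the planted counts
requires genuine deduplication.

`make_decoys()` draws one chain and one random unit direction per ladder
(seeded), then emits one decoy per magnitude by translating that chain by
direction &times; magnitude plus per-atom Gaussian noise &mdash; a
controlled dose-response series in perturbation size (0, 15, 30, 60,
120 &Aring; by default). Resampling chain and direction per rung would
confound the ladder with which subunit moved.

One behaviour of this design is worth stating plainly: a rigid
translation can carry a planted-*violated* inter-chain pair (&ge;42 &Aring;)
*inside* the cutoff, so a mid-ladder decoy occasionally satisfies strictly
more crosslinks than the unperturbed model. That is inherent to counting
satisfied restraints under a violated-heavy planted load, not a defect of
the scoring: the per-decoy count always matches a brute-force recount in
the tests. Consequently the seed-averaged score profile over the ladder is
tested for its decrease from the unperturbed rung to the strongly
perturbed rungs and for monotone decay from the first displaced rung on,
and the per-seed rank-recovery rate is reported as a measured quantity by
the acceptance script rather than assumed perfect.

`simulate_csm_dataset()` generates an SD3-style CSM sheet with planted
dataset-level marginals, defaulting to the summary statistics of the
HDAC2:MIER1:MHAP1 affinity-purification dataset this workflow was built
around: 525 CSMs collapsing to 165 intra- and 52 inter-molecular unique
crosslinks over 148 proteins. Its bait is an explicit stand-in: the real
bait sequence cannot be redistributed here, so `MHAP1_SYNTHETIC` is a
generated 180-residue sequence carrying exactly 20 lysines of which
exactly 4 appear crosslinked, reproducing the lysine-coverage structure
reported for the real protein. Summaries computed from this table are
therefore a check that the *pipeline* recovers planted marginals through
real parsing and deduplication &mdash; they are not an independent
re-derivation of the published counts, which would require the original
supplementary sheets.

What the generator does **not** emulate: real side chains and rotamer
flexibility, sequence-dependent crosslinkability, site-localization
error, decoy/target FDR structure in CSM scores, and the conformational
(rather than rigid-body) differences between real candidate models.
Passing tests on synthetic data show the machinery is correct, not that
any particular real model is.

## Numerical and degenerate-input choices

* Restraint bands encode [0, cutoff] as target = cutoff/2 with both
  margins = cutoff/2; files are sorted by (chain, residue) pairs and
  printed fixed-point with one decimal, so identical restraint content is
  byte-identical regardless of input order.
* An empty satisfied set emits an empty restraint set with a warning from
  the selector, and a hard error from the writer (a restraint file with no
  restraints is never useful downstream).
* Unmappable crosslinks are values with reason codes (`no-chain`,
  `no-residue`), never errors; mapped non-lysine endpoints (possible under
  site-localization ambiguity) warn and are flagged but kept.
* PDB parsing keeps the first altloc, collapses insertion-coded residues
  onto the author number and rejects any remaining duplicate
  (chain, residue, atom); predicted models have neither, so strictness is
  cheap.
* Self contact maps are symmetrized exactly and given an exact zero
  diagonal to remove floating-point round-off from the distance matrix
  identity.

## Problem sizes

The test suite and acceptance script run the full pipeline on the default
three-chain spec (190 residues), 50-seed replications for planted-truth
scoring and decoy ranking, SASD grids up to ~10^6 voxels, and oracle
fixtures up to 20^3 voxels; the complete suite runs in about a minute.
These sizes were chosen as the smallest at which every distance class,
chain-pair ambiguity and ladder rung is populated.

## Known limitations

* SASD endpoints are voxel centers; the reported path omits the sub-voxel
  segments to the true C&alpha; positions (within one grid step per end).
* All-atom contact maps cost O(atoms&sup2;) per chain pair in R; for
  large complexes the C&alpha; mode is the practical default.
* Anchor pairing requires shared residue numbering; superposing models
  with different numbering schemes needs the chain-map offsets applied
  first.
* The refinement loop is open: restraints go out as files, refined models
  come back as files. No engine is invoked.
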