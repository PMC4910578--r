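---
title: "Mapping ligand sites and conformational motion in pentameric ligand-gated ion channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ligand sites and conformational motion in pentameric ligand-gated ion channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plgicmap)
```

## The problem

Pentameric ligand-gated ion channels (pLGICs, the Cys-loop receptor
superfamily: GABA~A~, glycine, nicotinic acetylcholine and 5-HT~3~
receptors, plus the invertebrate GluCl and the bacterial GLIC/ELIC
channels) carry small-molecule binding sites in recurring locations:
at the extracellular-domain (ECD) interface between a principal (+) and
a complementary (−) subunit face, in the channel vestibule, inside the
ECD packing core, around the N-terminal helix, at and within the
transmembrane domain (TMD) helix bundle.  Because many of these sites
have only ever been seen crystallographically in *homologous* proteins,
locating them on a receptor of interest means transferring the
annotation across structures — and deciding whether the receiving
structure actually has room for the ligand.

`plgicmap` implements that workflow as composable, tested pieces:

1. **Coordinate handling** (`parse_structure`, `extract_ligands`,
   `select_calpha`, `write_structure`) with author numbering and
   insertion codes as the canonical addressing scheme.
2. **Residue correspondences** between chains, either from an
   anchor-annotated master alignment (`alignment_correspondence`) or
   sequence-independently from structure (`structural_correspondence`).
3. **Rigid superposition and RMSD bookkeeping** at domain, subunit and
   pentamer granularity (`kabsch_fit`, `superpose_subset`,
   `pairwise_rmsd`), plus a twist/tilt decomposition of inter-domain
   motion (`domain_motion`).
4. **Site detection, classification and transfer**
   (`ligand_contacts`, `classify_site`, `transfer_site`,
   `occlusion_score`, `build_site_atlas`) over a ten-class taxonomy.
5. **Pocket-geometry analysis across conformational states**
   (`distance_table`, `pocket_variability`, `group_conformations`).
6. A **synthetic pentamer generator** with planted ground truth
   (`make_pentamer`, `perturb_state`, `plant_ligand`), so every stage is
   testable without downloading a single coordinate file.

## Correspondences

All quantitative results are correspondence-driven: a correspondence is
an ordered, one-to-one, monotone pairing of residues between two
chains, and every RMSD or transferred annotation flows through one.

The *alignment route* uses a master alignment whose columns carry an
anchor track naming the classical pLGIC landmarks: binding-site loops
A–G, strands 5/5′/7/8′/9, the N-terminal helix 1, the junction segment
before M1, the TMD helices M1–M4, and the intracellular MX/MA helices.
Anchors are the package's coordinate system for "where" a residue sits;
they drive site classification and the distance definitions.  Rows must
match their chains' sequences; up to 2% mismatch is tolerated (and
flagged) to accommodate engineered constructs such as linker-replaced
intracellular domains.

The *structural route* needs no sequence information.  Secondary
structure is assigned from C^α^ geometry alone using distance masks:
helix when d(i,i+3) ∈ [4.4, 6.4] Å and d(i,i+4) ∈ [5.7, 7.7] Å over a
run of ≥5 residues; strand when d(i,i+2) ∈ [6.0, 7.4] Å with a
C^α^ pseudo-angle above 115° over ≥3 residues; coil otherwise.  These
windows are the standard C^α^-only (P-SEA-style) thresholds, fixed here
for reproducibility.  Matched secondary-structure segments seed a
Kabsch fit, which is refined by iterative nearest-neighbour pairing
within 3.5 Å.  At every round the pairing is forced one-to-one and
monotone (longest monotone subset by dynamic programming): generic
secondary-structure matching tolerates crossings, but pLGIC topology is
sequential, and monotonicity makes the result deterministic.  Iteration
stops when the pair set is stable or after 50 rounds.

A structurally conserved three-residue motif in the loop F region
(strand 8′: hydrophobic / any / hydrophobic-or-small, e.g. VTG in the
GABA~A~ β3 subunit) constrains alignments in an otherwise variable
region; `validate_strand8()` checks any alignment against it, with
hydrophobic = {A,V,L,I,M,F,W,C} and small = {G,A,S}.

## Superposition and domain motion

`kabsch_fit()` is the closed-form least-squares rigid fit with
reflections excluded; no outlier trimming is applied, so reported RMSDs
are over *all* matched C^α^ pairs.  `pairwise_rmsd()` in pentamer mode
minimizes each entry over the five cyclic chain assignments only —
mirror assignments would violate the conserved counter-clockwise
subunit arrangement (β−α−γ−β−α viewed from the extracellular side).

`domain_motion()` quantifies the hallmark pLGIC motion: the ECD and TMD
behave as nearly rigid bodies that twist and tilt relative to one
another.  The TMDs of the two conformations are superposed first; the
residual ECD-onto-ECD rotation, expressed in the TMD frame, is
decomposed by the quaternion swing–twist construction into a rotation
about the pore axis (*twist*) and a deviation of that axis (*tilt*).
The pore axis is the principal axis of the pooled M2-helix C^α^ cloud,
oriented toward the ECD.  Rotations below 0.1° are reported as 0 with a
degeneracy flag, since the axis of a near-identity rotation is
numerically meaningless.

## Site classification

Contacts are heavy-atom distances at a 4.0 Å cutoff (the convention of
ligand-interaction diagrams; configurable).  Classification is a
cascade:

* **Domain** from the anchor membership of the contact majority;
  junction contacts follow the TMD rules.
* **Pore exclusion**: TMD ligands whose centroid lies within the 8 Å
  pore-axis cylinder are channel blockers — flagged `pore_facing` and
  deliberately left unclassified.
* **Interface test**: at least two chains contributing at least two
  contact residues each.  The principal chain is the one presenting the
  plus face (loops A–C, strands 7/9 in the ECD; M2/M3 in the TMD).
* **ECD interface**: subsite 1 when the contact plurality lies in loops
  B/C/D/E, subsite 2 when in loops G/F and strand 7; a monatomic cation
  touching loop F or strand 7 is the cation site 3.  Ligands spanning
  both subsites are assigned the higher-fraction subsite.
* **ECD intra-subunit**: vestibule site 4 when the centroid falls
  inside the pore-axis cylinder; packing-core site 5 when contacts
  split between the inner (strands 5/5′/7) and outer (strands 8′/9)
  sheets; helix-1 site 6 on a helix-1 plurality.
* **TMD intra-subunit**: site 8 on an M1/M2/M3 plurality, site 9 on an
  M1/M4 plurality (the membrane-facing groove), site 10 on an M3/M4
  plurality in the lower third of the TMD span (toward the
  intracellular end).

The vestibule radius of 8 Å separates vestibule-facing from
packing-core ligands on the structures examined; it is a tunable
parameter, not a physical constant.

## Transfer and occlusion

`transfer_site()` maps each pocket residue through its chain's
correspondence, places the source ligand in the target frame by a
pocket-local Kabsch fit of the mapped residues (at least three are
required), and scores occlusion: the fraction of ligand heavy atoms
within the 2.8 Å clash distance of any non-pocket target heavy atom.
A fraction above 0.25 yields the verdict `occluded`.  This is the
package's operationalization of a qualitative criterion — the classic
case being the vestibule site, which in anion-selective receptors is
filled by a longer loop between strands 5 and 5′, so transferring it
produces a fully clashed footprint and the site is correctly rejected.
The 2.8 Å / 0.25 pair was fixed a priori: 2.8 Å is roughly the closest
non-bonded heavy-atom approach, and a quarter of the footprint is well
beyond what relaxed side chains could plausibly absorb.

## Pocket geometry across states

`distance_table()` evaluates named C^α^–C^α^ distances *internal to
each structure* (no superposition involved, so the table is invariant
under rigid motion of any state).  The default ECD-interface set holds
ten distances between the plus and minus subunits — loop B↔loop E (2),
loop C tip↔loop D (2), loop C tip↔loop E (1), loop A↔loop G (2),
loop A↔loop F (1), strand 7↔loop F (1), loop C↔loop F (1) — anchored at
block midpoints and tips; the loop C "tip" is the middle residue of its
anchor block.  The set is a declared default, editable per run.
`pocket_variability()` condenses the table to the maximal distance
change per pocket, and `group_conformations()` clusters a pairwise RMSD
matrix by single linkage, cut at 2.5 Å by default — between the
within-group (≤2 Å) and between-group (>3 Å) separations the pentamer
ensemble exhibits.

## The synthetic generator: what it emulates, and what it does not

`make_pentamer()` builds a C5-symmetric pentamer of two-domain
subunits: an N-terminal helix, two β-sandwich-like strand bundles (an
inner vestibule-lining pair and an outer pair) carrying all loop
anchors, a strand-8′ motif with the VTG sequence, and a four-helix TMD,
at a subunit ring radius of 17 Å with ~90 ECD and ~90 TMD residues per
subunit (about 178 residues per chain, 890 C^α^ atoms per pentamer —
sizes chosen so that each anchored element is long enough to carry its
signature while whole-ensemble analyses stay fast).  Fixtures are
C^α^-plus-pseudo-ligand only; contact detection on them therefore uses
C^α^ as the heavy-atom set with a 6.5 Å cutoff (versus 4.0 Å on real,
all-atom structures).

`perturb_state()` plants controlled motion: a rigid rotation of every
ECD about the pore axis (*twist*), a per-subunit rotation of each ECD
about its own radial axis through the domain junction (*tilt*), an
optional displacement of loop C along its line of sight to the
neighbouring loop D (the apparent capping/uncapping), and Gaussian
coordinate noise.  Note the geometry lesson encoded in the tests: a
pure global twist moves the entire ECD ring rigidly and leaves
inter-subunit distances unchanged; it is the *tilt* (and differential
motion) that reshapes interface pockets while intra-subunit pockets
stay rigid — exactly the behaviour the analysis is meant to detect.
The two-group ensemble used in the acceptance workflow perturbs one
group by 28° twist and 9° tilt with 0.15 Å noise, chosen once so the
within-group (≲0.4 Å) and between-group (≳3 Å) pentamer RMSDs sit on
the scales reported for real agonist-bound-like versus
antagonist/apo-like pLGIC conformations.

What the fixtures do **not** emulate: side chains (so no real packing
or chemistry in contacts), sequence divergence between subunits,
insertion-code numbering, experimental noise structure, or the
continuum of real conformational substates.  A passing synthetic suite
demonstrates that the machinery is correct and self-consistent, not
that any particular biological conclusion holds; conclusions about real
receptors require the deposited structures, for which the same code
paths apply unchanged at the real-structure cutoffs.

## Numerical choices and degenerate inputs

* Altloc policy: keep the highest-occupancy alternate, ties broken by
  label order — deterministic where deposition practice is not.
* Solvent/buffer exclusion list: HOH, DOD, NA, CL, K, SO4, PO4, GOL,
  EDO, PEG, ACT; Ba^2+^ and Zn^2+^ are *not* excluded because cations
  occupy genuine sites (the interface cation site and the TMD zinc
  site).
* Kabsch degenerate geometry (collinear points) raises an error rather
  than returning an arbitrary rotation; fewer than three pairs is an
  error everywhere a fit is attempted.
* Nearest-neighbour ties in structural matching break toward
  monotonicity, then toward the lower residue number.
* `cutree` at an infinite height is clamped to just above the
  dendrogram, so "one group at threshold ∞" holds exactly.
* Missing cells in distance tables are flagged (attribute `missing`),
  never silently dropped; a missing RMSD pair yields an `NA` entry and
  grouping refuses matrices with missing entries, listing the pairs.

## Design choices where the field leaves them open

* Whether deposited asymmetric-unit or biological-assembly coordinates
  are analysed is recorded per structure in the run configuration
  (`assembly` note) rather than decided globally; the package assumes
  files already contain the relevant pentamer and performs no symmetry
  expansion.
* The ECD/TMD boundary defaults to the anchor track (ECD = N-terminus
  through the pre-M1 junction; TMD = M1 through M4) and is configurable
  per analysis, since published domain definitions vary by a few
  residues.
* The exact residue endpoints of published interface-distance tables
  are not recoverable from main-text sources; the default ten-distance
  set is therefore a declared stand-in with the same coverage, and
  distance definitions are data (editable), not code.
* Correspondence mode is explicit everywhere (`alignment` vs
  `structural`): on engineered or divergent constructs the two can
  differ, and which one a number came from is part of its provenance
  (every exported correspondence carries its mode).

## Limitations

Occlusion scoring is clash-counting, not volumetric: it will miss a
pocket filled by atoms that sit just beyond the clash distance.  The
C^α^-only secondary-structure assignment under-calls the ends of
helices and strands (≈93% agreement with planted labels on fixtures).
Site classification depends on the anchor annotation; chains absent
from the master alignment fall back to `unclassified` with a
diagnostic rather than guessing.  The package deliberately does no
docking, no affinity scoring, no homology-model building and no
pore-blocker analysis.

## Reproducing the analyses

`scripts/acceptance.R` (run as
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`)
regenerates the synthetic study conditions from the given seed and
recomputes every headline quantity — superposition-oracle agreement,
planted-motion recovery, full plant→detect→classify→transfer closure,
occlusion rejection, correspondence-route agreement, motif-validator
agreement, ensemble grouping and pocket-variability contrasts — writing
them as JSON.  The test suite (`testthat`) covers the same ground at
finer granularity, plus one check over the deposited pentamer ensemble
that requires locally cached coordinate files (see `pdb_cache_paths()`).
```{r closure-demo}
pent <- make_pentamer(synthetic_spec(seed = 1))
pl <- plant_ligand(pent, site_class = 7)
cs <- ligand_contacts(pl$structure, pl$expected$ligand_key, cutoff = 6.5)
classify_site(cs, pl$structure, pent$truth$alignment)
```
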