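---
title: "Designing fluctuation-regulated affinity proteins: methods and rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing fluctuation-regulated affinity proteins: methods and rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flapr)
```

## The design problem

Antibodies bind antigen through their complementarity-determining regions
(CDRs), and in most antibody chains the longest contiguous stretch of
antigen-contacting residues is about six amino acids. This motivates a
minimal antibody-mimetic strategy: excise the hexapeptide that carries most
of the binding energy from a CDR and graft it into a small, stable non-Ig
scaffold — provided the scaffold can hold the grafted peptide in a rigid,
binding-competent conformation. A short peptide free in solution is
conformationally disordered; the same peptide inserted at a suitable
scaffold position can be immobilised by its flanking structural elements,
which removes much of the entropic penalty of binding.

flapr implements the computational arm of this strategy in three stages:

1. **Graft-acceptor (GA) site identification.** Candidate hexapeptide sites
   in a scaffold are loop windows sequentially flanked by alpha-helices,
   beta-strands, or disulfide-bonded cysteines. A site survives if every
   residue is solvent accessible (per-residue SASA strictly above
   15&nbsp;Å²) and the window's mean heavy-atom RMSF is below 1.0&nbsp;Å
   (the constrained-and-solvent-accessible, CSA, rule; a looser 1.5&nbsp;Å
   bound defines "constrained" sites). Each CSA site is then stress-tested
   by grafting all 20 homo-hexapeptides (A6 … Y6) and re-profiling: the
   site is a GA site only if **every** homo-hexapeptide stays below
   1.5&nbsp;Å mean RMSF. The homopolymers deliberately span the extremes of
   the 20^6 = 6.4×10⁷ hexapeptide space — smallest (G6), bulkiest (W6),
   most hydrophobic (I6), most acidic (E6), most basic (R6) — so a site
   that immobilises all of them can be expected to immobilise any graft.
2. **Antigen-binding CDR hexapeptide extraction.** In an antibody-antigen
   complex, every 6-mer window of the variable domain that overlaps a CDR
   is mutated in silico to an alanine hexapeptide and the binding-energy
   loss is recorded. Windows whose replacement costs the most binding
   energy carry the paratope; the top-ranked windows are selected.
3. **Design generation.** Selected CDR hexapeptides are grafted into every
   GA site (full cross product, named `<site>-<peptide>`, e.g.
   `Sca8-1-TH3`), and each design is evaluated by the grafted window's
   mean RMSF and by the heavy-atom RMSD of the grafted peptide against its
   conformation in the parent antibody.

## Fluctuation backends

The central observable is the RMSF of the heavy atoms of a hexapeptide
window. Two backends produce it:

* **Ensemble backend** (`rmsf_from_ensemble()`): takes a conformational
  ensemble (multi-model PDB, e.g. subsampled from an MD trajectory),
  superposes every frame onto the reference by least squares (Kabsch) over
  a fit selection, and computes each atom's RMSF about its mean position.
  The default fit selection is all backbone atoms; for graft evaluation
  the recommended selection excludes the grafted window
  (`backbone_fit_selection()`), so the measurement captures window motion
  relative to the scaffold. The default analysis window is the final half
  of the frames, which discards equilibration transients.
* **Gaussian network model backend** (`rmsf_from_enm()`): builds the
  Kirchhoff (connectivity) matrix over C-alpha atoms with a 7.5&nbsp;Å
  cutoff; per-residue mean-square fluctuations are the diagonal of its
  pseudoinverse (computed by eigendecomposition with the zero mode
  removed), broadcast to each residue's heavy atoms.

Network-model fluctuations are in relative units, while the selection
thresholds (1.0 / 1.5&nbsp;Å) are absolute. The package therefore makes
calibration explicit: `enm_calibration()` returns the constant that maps
raw model fluctuations to Å such that the median C-alpha RMSF of a
reference structure (by default the package's hairpin fixture) equals a
target of 0.8&nbsp;Å — a typical backbone RMSF for a small, well-folded
domain at 300&nbsp;K. The constant is logged in all reports, and the
thresholds should be read as values on this calibrated scale. On any other
backend (e.g. real MD ensembles) the thresholds apply directly in Å.

Because the network model sees only C-alpha topology, homo-hexapeptide
profiling under it is a test of the *site*, not of the side chains: all 20
variants share the backbone and therefore the profile. This matches the
model's role as a fast desk-scale screen; sequence-dependent immobilisation
differences require the ensemble backend on per-variant ensembles.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `sasa_min` | 15 | Å² | per-residue solvent accessibility floor (strict `>`); keeps graft positions displayable to the antigen |
| `rmsf_constrained` | 1.5 | Å | upper bound for a "constrained" window and for the GA verdict over all 20 homopolymers |
| `rmsf_csa` | 1.0 | Å | stricter bound defining CSA sites, the candidates worth profiling |
| enumeration `mode` | windowed | — | overlapping 6-mer windows inside loops; `strict` (whole loops of exactly six) retained for conservative runs |
| `flank_reach` | 2 | residues | loop residues tolerated between a window end and its anchoring element in windowed mode |
| GNM `cutoff` | 7.5 | Å | standard C-alpha Gaussian-network contact distance |
| `calibration_target` | 0.8 | Å | median C-alpha RMSF assigned to the reference structure |
| contact `cutoff` | 4.5 | Å | heavy-atom antigen-contact definition |
| energy `cutoff` | 12 | Å | nonbonded truncation; windows farther than this from the interface have exactly zero loss |
| SASA `probe` | 1.4 | Å | water probe |
| SASA `n_points` | 960 | points/atom | Shrake-Rupley lattice density; converged to ~1% on the fixtures |

Loop enumeration treats a disulfide-bonded cysteine as a valid flank
regardless of its own secondary-structure state; when a flanking residue is
both in a strand/helix and disulfide-bonded, the secondary-structure letter
wins in the motif name (so `SLC`-type motifs denote genuine coil cysteine
anchors). Site names are `<scaffold>-<ordinal>` with ordinals assigned
N-to-C after filtering, so re-runs produce identical names.

## The interface energy model

The alanine-hexapeptide scan needs only a *ranking* of windows by
binding-energy loss, so the package uses a deliberately simple,
deterministic physics score rather than a molecular-mechanics force field:
pairwise Lennard-Jones terms with per-element parameters
(Lorentz-Berthelot combination), Coulomb electrostatics with a
distance-dependent dielectric ε(r) = 4r and the factor 332 converting to
kcal/mol-like units, a coarse partial-charge table (split formal charges on
ionizable side-chain termini, backbone amide/carbonyl dipoles; shipped as
`inst/extdata/partial_charges.tsv`), and an optional per-residue burial
term. Binding energy is E(complex) − E(receptor) − E(ligand) as
single-point evaluations by default; an optional fixed-step
steepest-descent relaxation (iteration cap 200) is available and recorded
in output when used. In single-point mode all intra-chain terms cancel
exactly, which gives two useful invariants: an identity mutation has zero
loss, and a window entirely outside the nonbonded cutoff of the receptor
has zero loss to machine precision.

Absolute values of this score are **not** comparable to force-field
kcal/mol; consequently the default selection mode is rank-based (top-k per
antibody, k = 3 for a heavy chain), with an absolute-loss threshold mode
available for workflows that have calibrated their own energy scale. Ties
in rank mode break N-to-C, deterministically.

## Secondary structure and SASA

Secondary structure is assigned by Kabsch-Sander hydrogen-bond analysis:
amide hydrogens (absent from heavy-atom records) are reconstructed from the
preceding peptide unit, the electrostatic bond energy uses the standard
0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) form with a −0.5 kcal/mol
bond criterion, helix turns and sheet bridges are detected from the bond
pattern, and the result collapses to three states (helix classes → H,
strand/bridge → E, else C) — the only distinction the pipeline consumes.
On the package's deterministic fixtures the assignment agrees exactly with
an independent DSSP implementation (the frozen references live in the test
suite).

SASA is computed by Shrake-Rupley with a deterministic Fibonacci sphere
lattice. The lattice is oriented in the molecule's principal-axis frame
(axis signs fixed by third moments), so per-residue values are invariant
under rigid motion of the input, and identical inputs give bit-identical
output. "Buried SASA" in the selection rule is interpreted as the exposed
per-residue area in the intact folded monomer — the reading under which a
`> 15 Å²` *keep* rule selects solvent-accessible residues; a
`buried_delta` mode (isolated-minus-folded difference) would invert the
sense of the filter and is intentionally not the default.

## In-silico mutagenesis

`mutate_window()` replaces the six residues of a site on a fixed backbone:
side chains are rebuilt from idealized internal-coordinate templates
(standard bond lengths/angles; CB placed with the L-chirality constant
dihedral(C,N,CA,CB) = −122.5°) and relaxed by a discrete rotamer search —
χ angles over {−60°, 180°, +60°} (aromatics use ±90° for χ2) — choosing
the rotamer with the fewest heavy-atom clashes (pairs closer than 0.8 of
the summed vdW radii), ties resolved to the first, most common rotamer.
There is no continuous minimisation: the builder is deterministic and its
clash score is reported, which makes grafting reproducible and testable.
Backbone φ/ψ are never remodelled — grafting replaces residues on a fixed
scaffold backbone — so proline and glycine grafts are allowed anywhere with
the caveat that their backbone preferences are not re-checked.

## What the fixtures emulate — and what they do not

All tests run on synthetic structures with designed ground truth
(`fixture_structure()`, `fixture_ensemble()`):

* `helix`, `strand`, `linear_peptide`: ideal-geometry chains from canonical
  φ/ψ (−57/−47 helix, −120/+120 strand).
* `hairpin`: two 9-residue antiparallel strands closed by a 6-residue loop.
  The strand pairing and the loop closure were solved once by numerical
  optimisation of the loop dihedrals against an ideal antiparallel
  placement and frozen as constants, so the builder is exact and
  deterministic; an independent DSSP run labels the strands E and the loop
  C. A `loop = 10` variant carries a wide bulge whose window fluctuation
  falls *between* the two RMSF thresholds, exercising the
  constrained-but-not-CSA branch of the funnel.
* `clamped_hairpin`: the same hairpin with the loop pulled against the
  strands and the two loop-flanking residues replaced by a
  disulfide-bonded cysteine pair (SG-SG = 2.04 Å) — a site that
  immobilises grafts (GA).
* `helix_loop_helix`: two short helices far out of mutual contact range
  joined by a long crossover loop anchored only at its ends — a free loop
  that no graft can immobilise (not-GA). This kind extends the fixture set
  beyond the hairpin pair because a 6-10 residue loop *returning between
  paired strands* is intrinsically semi-constrained in a Gaussian network:
  its fluctuation cannot rise far above the constrained threshold, so the
  clean not-GA contrast needs a topologically free loop.
* `toy_complex`: an extended ligand chain with arginines at designed
  contact positions and a receptor of glutamates placed at salt-bridge
  distance opposite each one. Contact recovery, the longest contact run,
  and the alanine-scan ranking are all exact by construction.

Ensembles add independent per-residue Gaussian jitter (one displacement per
residue per frame; per-atom RMSF is then √3·σ in expectation) and,
optionally, random rigid-body motion to exercise superposition. The jitter
is *uncorrelated* — real backbone dynamics are not — but every statistic
the pipeline consumes is a per-atom second moment, for which this model is
sufficient. Passing tests on these fixtures therefore demonstrate the
correctness of the machinery (filters, profiling, scanning, bookkeeping)
and its qualitative physics (clamping lowers fluctuation; interface
residues carry binding energy); they do not demonstrate that the simplified
energy or the network model reproduce MD-scale RMSF values or force-field
energetics on real proteins — for that, feed the pipeline real ensembles
and calibrated thresholds.

## Numerical choices

* GNM pseudoinverse: dense symmetric eigendecomposition, zero modes
  removed at a relative tolerance of 1e-8; verified against an independent
  generalized-inverse computation to 1e-8 on graphs up to 50 nodes.
  Disconnected contact graphs are an error that names the component sizes.
* Kabsch superposition: SVD with determinant correction; verified against
  a quaternion-method oracle.
* Shrake-Rupley convergence: 960 points/atom changes total SASA by < 2%
  versus 4× the density on the fixtures; duplicate-coordinate atoms are an
  error.
* ALTLOC resolution: highest occupancy wins, ties by label order; PDB
  author numbering is preserved end-to-end and all windows are 1-based,
  inclusive.
* Disulfide matching is greedy nearest-first under a 2.5 Å SG-SG cutoff,
  so each cysteine joins at most one bridge.
* Degenerate inputs: single-frame ensembles, empty interfaces, sites not
  covered by a profile, and windows crossing numbering gaps all raise
  informative errors or warnings rather than silent results.

## Problem sizes

The test suite and the acceptance script run entirely on the fixture set:
scaffolds of 22-30 residues, ensembles of 500 frames, network models of up
to 50 nodes, and a 28-residue toy complex. These sizes keep the whole
pipeline deterministic and fast while leaving every code path — including
the 20-variant profiling and the full scan-profile-design chain —
exercised end to end.

## Known limitations

* The network model is sequence-blind at the C-alpha level; GA profiling
  under it probes site topology only (see above).
* The energy score has no solvent model beyond the optional burial term,
  no polarisation, and untuned absolute scale; only rankings are
  meaningful.
* Side-chain building uses idealized ring geometry and a minimal rotamer
  set; grafted side chains are starting points, not refined conformers.
* CDR boundaries are input annotation: the package does not implement
  Kabat/Chothia/IMGT numbering, which disagree with one another; users
  supply the convention they trust.
* mmCIF input, hydrogen placement and crystallographic symmetry expansion
  are out of scope.

## A worked fixture run

```{r pipeline, eval = FALSE}
scaffolds <- list(
  clamp = fixture_structure("clamped_hairpin", id = "clamp"),
  free  = fixture_structure("helix_loop_helix", id = "free"))
cal <- enm_calibration(fixture_structure("hairpin"), target = 0.8)
backend <- function(s) rmsf_from_enm(s, calibration = cal)

scan <- scan_scaffolds(scaffolds, backend = backend)
glance(scan)                      # funnel: enumerated >= sa >= constrained >= csa
ga <- profile_ga(scan, scaffolds, backend)
glance(ga)                        # clamp-1 is GA; the free loop is not

cx <- complex_spec(fixture_structure("toy_complex"), "R", "L",
                   cdr = tibble::tibble(chain = "L", name = c("C1", "C2"),
                                        start = c(8L, 21L), end = c(18L, 27L)),
                   chain_prefix = c(L = "TH"))
cdr <- extract_cdr(cx, top_k = 1) # the designed hot window wins
designs <- design_grafts(ga, cdr$selected, scaffolds, backend)
```
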