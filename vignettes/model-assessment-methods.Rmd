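---
title: "Assessing membrane-transporter models with memqc: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing membrane-transporter models with memqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memqc)
```

## The problem

Homology models of polytopic membrane transporters — for example MFS-fold
proteins such as the synaptic vesicle glycoprotein SV2A, built at very low
sequence identity to their templates — cannot be validated against a
crystal structure. Practitioners instead assemble indirect evidence: does
the hydrophobic-conservation pattern of a large alignment match the
predicted transmembrane (TM) helices? Do independent topology predictors
agree? Does the model stay folded in a lipid-bilayer molecular-dynamics
simulation (backbone RMSD plateau, retained helicity, stable cavity)? Do
ligand contacts seen in simulation predict the effect of point mutations in
a competition radioligand-binding assay? `memqc` implements each of those
analyses as a reusable, tested stage, plus deterministic synthetic-data
generators so every stage can be exercised at desk scale with known ground
truth.

## Models and procedures

### Hydrophobic conservation

For every non-gap position of a designated reference row, the profile
reports the percentage of aligned sequences carrying the modal residue
(identity) and the percentage carrying any residue from a class set,
defaulting to the hydrophobic class {M, A, V, I, L, C, Y, F, W}. High class
conservation with low identity conservation is the signature of a lipid- or
core-facing helix face, which is why the class percentage, not identity, is
used to corroborate TM helix placement.

Two denominators are supported because large automatically built alignments
are gap-rich and the choice is not innocuous: `all_rows` (default) counts
gaps against conservation, treating the full sequence set as the reference
population; `nongap_rows` restricts to sequences that align a residue at
that column. Non-standard letters (B, Z, X) are counted in the denominator
but never as class or identity matches. Ties for the modal residue are
broken alphabetically so reports are deterministic.

### Topology consensus

Per-residue binary tracks from any number of TM predictors are combined by
voting: a residue qualifies when the fraction of tracks marking it TM is at
least `threshold` (default 0.5; ties count as TM). Qualifying runs
separated by at most `max_gap` non-qualifying residues (default 3, about
one helix turn of predictor jitter) are merged, and merged runs shorter
than `min_len` (default 15, a canonical TM span) are discarded. All three
numbers are configuration values, not constants, because no published rule
exists for reconciling predictor disagreement — this module is an explicit,
reproducible stand-in for the manual reconciliation usually applied. An
expected helix count (12 for an MFS fold) can be supplied as a diagnostic;
a mismatch warns and never errors.

### Superposition RMSD

`kabsch_superpose()` computes the least-squares optimal rigid superposition
via SVD of the cross-covariance matrix with the determinant correction that
excludes reflections. The RMSD is evaluated from the actual residuals after
applying the optimal rotation rather than from the closed-form trace
expression: the two are algebraically identical, but the trace form loses
up to seven digits to cancellation near zero, which matters because
rigid-motion invariance is asserted at 1e-8 Å in the tests. Collinear point
sets are solved but flagged (`collinear = TRUE`), since the optimal
rotation is then not unique. `rmsd_series()` superposes every frame onto a
reference over the C-alpha atoms of a residue selection — the selection is
a required input because which residues constitute "the TM core" is a
modelling decision, not something the package can infer. Plateau statistics
(`rmsd_plateau()`) are the mean ± SD over the trailing quarter of frames by
default.

### Secondary structure and helicity conservation

The assigner implements the Kabsch–Sander electrostatic criterion: the
hydrogen-bond energy between an acceptor carbonyl (residue i) and a donor
amide (residue j) is

E = 0.084 · 332 · (1/r(ON) + 1/r(CH) − 1/r(OH) − 1/r(CN)) kcal/mol,

with a bond assigned when E < −0.5 kcal/mol. Amide hydrogens are
reconstructed 1.0 Å from N along the direction of the preceding C=O; the
first residue of a chain has no donor and proline never donates. Chains are
split where the C(i)–N(i+1) distance exceeds 2.5 Å (a peptide bond is
~1.33 Å, so anything beyond 2.5 Å is a genuine break). An n-turn at i is
the bond (i → i+n); two consecutive 4-turns start an α-helix (code `H`)
spanning four residues, with `G` (3-10) and `I` (π) assigned analogously
into positions not already `H`. β bookkeeping is out of scope. Under this
rule the first and last residues of a chain can never be α, which the tests
assert as an invariant.

Helicity conservation is the fraction of frames in which a residue carries
a code in `helical_codes` — `{H}` (α only) by default, since published
"helicity as defined by DSSP" statements rarely say whether 3-10/π count;
`c("H","G","I")` is available. Replica aggregation is mean ± SD with the
n−1 denominator, and a residue is classified "conserved" when the replica
mean is ≥ the criterion (default 0.60). The boundary is deliberately
inclusive: a residue helical in exactly 60% of frames passes.

### Pocket statistics

*Cavity volume* uses a seeded flood fill on a cubic grid (default spacing
1.0 Å, probe 1.4 Å — a water molecule): points within (van der Waals radius
+ probe) of any atom are blocked (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2 Å),
and the volume is the count of points 6-connected to the seed times
spacing³. This is the package's own operational definition — published
cavity volumes rarely state their algorithm, grid, probe or region, so
absolute volumes from different tools are not comparable and this module's
outputs should only be compared with themselves across frames or models.
The implementation is exact on an empty region, within 5% of the analytic
sphere volume for a single occluding atom at 0.5 Å spacing, and
monotonically non-increasing as atoms are added — all tested.

*Contact occupancy* is the fraction of frames in which at least one atom of
a residue lies within the cutoff (default 6.0 Å) of any ligand atom. Heavy
atoms only by default, since schematic interaction maps at this cutoff are
insensitive to hydrogens; a flag includes them. Pooling across replicas is
frame-weighted (total contact frames over total frames), so a longer
replica contributes proportionally more.

*Salt-bridge occupancy* takes per frame the minimum distance over all
donor–acceptor atom pairs (e.g. lysine amino hydrogens against aspartate
carboxylate oxygens) and reports the fraction of frames strictly below the
threshold (default 3.5 Å), plus the mean ± SD of the trace. All thresholds
in this module are strict (<): a frame at exactly 3.5 Å does not count.

*Area per lipid* is (box_x · box_y − A_protein) / (N_lipids/2), assuming two
equally populated leaflets; the protein cross-section correction defaults
to 0 and is an explicit opt-in, because the uncorrected number is the one
usually quoted as a bilayer sanity metric.

### Dose-response fitting

Competition binding curves are fitted with the variable-slope sigmoidal
(four-parameter logistic) model

Y = bottom + (top − bottom) / (1 + 10^((log10(IC50) − log10(X)) · hill)),

parameterised internally by pIC50 = −log10(IC50 in M) so the headline
quantity carries its own standard error. Fitting is bounded
Levenberg–Marquardt (minpack.lm) from data-driven starts (asymptotes from
the signal range, IC50 at the half-maximal concentration, hill ±1 by
response direction) plus three jittered restarts from a fixed internal seed;
the best residual sum of squares wins. Bounds are hill ∈ [−10, 10] and IC50
within [min_conc/100, max_conc·100]; estimates at a bound are flagged. A
fit requires ≥ 5 distinct concentrations spanning ≥ 2 log units. Flat
curves — fitted top − bottom below three residual SDs — are flagged
`no_inhibition` with pIC50 undefined rather than reporting a spurious
potency. Replicate experiments are aggregated as the mean ± SD of
per-experiment pIC50 values, not by pooled fitting, matching how assay
tables are conventionally reported. Fits are unweighted and, when a B0
(no-competitor binding) value is present, performed on percent-of-B0; the
pIC50 is scale-invariant either way, which the tests verify.

## The synthetic-data generators

The generators close the loop between every estimator and a known truth:

* `gen_msa()` draws each column from the class set with a prescribed
  frequency (and non-class residues otherwise), with optional per-column
  gap probability; row 1 is a gap-free reference.
* `build_backbone()` constructs N/CA/C/O backbones from dihedrals by
  internal-coordinate (NeRF) chain extension with standard geometry (N–CA
  1.458, CA–C 1.525, C–N 1.329, C=O 1.231 Å; angles N-CA-C 111.2°, CA-C-N
  116.6°, C-N-CA 121.9°); reconstructing dihedrals from the coordinates
  returns the inputs to ≤ 1e-6°.
* `gen_helix_trajectory()` builds replicas of an α-helix (φ = −57°,
  ψ = −47°) with Gaussian dihedral noise (SD 4°) and coordinate noise
  (SD 0.05 Å) — values chosen once as small thermal jitter that leaves
  ideal-helix hydrogen bonds intact, so clean residues stay helical.
  Flagged residues are redrawn from the extended region (φ ∈ [−180°,
  −120°], ψ ∈ [120°, 180°], guaranteed non-α) in an exact, deterministically
  sampled fraction of frames. Because unwinding residue r perturbs the
  i→i+4 bonds that span r, the ground-truth sidecar defines expected
  helicity only where construction determines it: 1 − u at flagged
  residues, 1 at interior residues ≥ 5 positions from any flagged residue,
  `NA` elsewhere.
* `gen_contact_trace()` and `gen_salt_bridge_trace()` place a pseudo-ligand
  atom (or donor–acceptor pair) inside the cutoff in exactly
  `round(f · n_frames)` frames, so the recovered occupancy equals the
  prescription exactly.
* `gen_dose_response()` is the 4PL forward model plus additive or
  multiplicative Gaussian noise — deliberately the same equation the fitter
  uses, closing the recovery loop.

All generators take a mandatory seed; per-component streams are derived by
a stable string hash (`derive_seed()`), so adding a generator never
perturbs existing streams, and reruns are byte-identical.

What the generators do **not** emulate: force-field physics, correlated
thermal motion, lipid coordinates (only box metadata), β structure, or
alignment phylogeny (columns are independent). Passing tests therefore
demonstrate the *estimators* are correct, not that any particular biological
model is; conclusions about a real transporter still require real
trajectories and assays.

## Default study conditions

The default pipeline bundle (`default_pipeline_config()`) is sized to run
end-to-end in seconds while preserving the statistical structure of a real
study: a 200 × 60 alignment at class frequency 0.8; 4 predictor tracks over
60 residues with two true TM segments and 5% label noise; three 60-frame
replicas of a 30-residue helix with residue 15 unwound in 40% of frames; a
bilayer whose box reproduces a mean area per lipid of 65.58 Å² (SD 0.82,
200 lipids), typical of a POPC patch at physiological temperature; contact
and salt-bridge traces at 21% and 35% prescribed occupancy; and three
simulated competition experiments at pIC50 7.1, hill 1, with 1%
multiplicative noise over 10 concentrations spanning 10 pM–100 µM. The
recovery checks in the test suite use larger sizes where the tolerance
demands it (e.g. 3 × 500 frames for helicity recovery within 0.05,
1000 alignment rows for class-frequency recovery within 3 points,
100 Monte-Carlo seeds for the pIC50 error distribution).

## Numerical choices and degenerate inputs

* Ties: modal residues alphabetical; vote fractions and the helicity
  criterion inclusive (≥); distance thresholds strict (<).
* Kabsch with < 3 points errors; collinear sets are flagged, not refused.
* Backbone chains split at C–N > 2.5 Å; residues missing backbone atoms
  make secondary-structure assignment fail loudly, listing the residues.
* Cavity seeds outside the region or inside an atom's exclusion sphere
  error; an atom-free region returns the exact region volume.
* The 4PL asymptotes are reported in canonical orientation (top > bottom);
  swapping asymptotes is algebraically equivalent to negating the hill
  slope, and the canonicalisation applies exactly that identity.
* Only orthorhombic boxes are supported and no periodic-image correction is
  applied; trajectory frames are assumed whole.

## Worked example

```{r example}
cfg <- default_pipeline_config(out_dir = tempfile("memqc_run"), seed = 1)
summary <- run_pipeline(cfg)
summary$pocket$salt_bridge$occupancy
summary$assay$mean_pIC50
```

## Known limitations

Trajectory input is multi-model PDB only (no XTC/DCD); full 8-class DSSP
fidelity (β-bridges, turns, bends) is out of scope; cavity volumes are
self-consistent but not comparable across tools; the consensus rule is a
documented stand-in for expert judgement; and the synthetic bundle's
independence assumptions (column-wise, frame-wise) are stronger than real
data satisfy.
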