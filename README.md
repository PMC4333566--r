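# memqc

Quality metrics for homology models of polytopic membrane transporters,
and the binding analyses used to validate them.

When a transporter (an MFS-fold protein such as the synaptic vesicle
glycoprotein SV2A, say) has no experimental structure and its templates sit
at 15–16% sequence identity, a model cannot be validated directly. The
working substitute is a battery of indirect checks, and `memqc` implements
each as a tested, scriptable stage:

* **Hydrophobic conservation** — per-column occurrence of the residue class
  {M, A, V, I, L, C, Y, F, W} in a multiple sequence alignment, mapped to
  reference residue numbering; high class conservation marks buried or
  lipid-facing helix faces and corroborates TM placement.
* **Topology consensus** — majority voting over per-residue tracks from
  several TM predictors, with gap merging (≤ 3 residues) and a minimum
  helix span (15), replacing ad-hoc manual reconciliation.
* **Trajectory metrics** — Kabsch (SVD) superposition RMSD series over a
  C-alpha selection with plateau mean ± SD; a Kabsch–Sander
  secondary-structure assigner built on the hydrogen-bond energy
  E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol (bond when
  E < −0.5); per-residue helicity conservation across replicas against a
  ≥ 60% criterion.
* **Pocket statistics** — seeded flood-fill cavity volume on a probe grid;
  ligand contact occupancy at a 6 Å cutoff (heavy atoms, strict <);
  salt-bridge occupancy below 3.5 Å from donor–acceptor minimum distances;
  area per lipid from box dimensions.
* **Binding assays** — variable-slope sigmoidal (4PL) fits,
  Y = bottom + (top − bottom) / (1 + 10^((log10 IC50 − log10 X)·h)),
  reporting pIC50 = −log10 IC50 with standard errors, no-inhibition
  flagging, and mean ± SD aggregation over replicate experiments.
* **Synthetic data** — seeded generators for every input (alignments with
  prescribed column frequencies, α-helical trajectories with controlled
  per-residue unwinding, contact/distance traces with exact occupancies,
  4PL curves), each carrying its ground truth, so the whole pipeline is
  testable without external data.

## Worked example

```r
library(memqc)
cfg <- default_pipeline_config(out_dir = "memqc_run", seed = 1)
summary <- run_pipeline(cfg)
```

This generates the default synthetic bundle (a 200-sequence alignment, 4
predictor tracks with two true TM segments, three 60-frame helix replicas
in a bilayer box, contact and salt-bridge traces, three simulated
competition experiments), runs every stage on the written files, and
prints per-stage tables under `memqc_run/` plus a `summary.json`. With
seed 1 the summary contains:

* consensus segments `TM1 6–25`, `TM2 31–50` — exactly the true segments
  behind the noisy tracks;
* 28 of 30 residues with helicity conservation ≥ 60%: the two failures are
  the deliberately unwound residue 15 (40% of frames, mean fraction ≈ 0.6
  boundary) and a fraying neighbour;
* contact occupancy 0.21 at the target residue and salt-bridge occupancy
  0.35 (mean distance 4.30 ± 0.96 Å) — the prescribed constructions
  recovered exactly;
* area per lipid 65.66 Å², matching the 65.58 Å² the bilayer box was built
  to represent;
* mean pIC50 7.098 ± 0.012 over three fits of curves generated at 7.1 with
  1% noise.

Single stages are available as plain functions, e.g.

```r
helix <- build_backbone(-57, -47, n_residues = 20)
paste(assign_secondary_structure(helix, frame = 1), collapse = "")
#> "-HHHHHHHHHHHHHHHHHH-"

fit <- fit_dose_response(gen_dose_response(7.1, 1, 100, 0,
                                           10^seq(-10, -4, length.out = 10)))
fit
#> 4PL fit: pIC50 7.100 (SE 0.000), hill 1.00, top 100.0, bottom 0.0, RSS 1.73e-15
```

and a thin CLI wrapper ships at `inst/scripts/memqc-cli.R` with subcommands
`simulate`, `conserve`, `topology`, `traj`, `pocket`, `assay`, `run-all`.

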