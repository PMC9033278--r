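# statecompare

Are two conformational states of a membrane protein the *same* state?
For the mechanosensitive channel MscL that question arises concretely:
the expanded state produced by membrane tension and the one produced by
pocket delipidation (e.g. the L89W pocket-entrance modification) can only
be called structurally analogous if independent probes classify the same
residues and regions the same way. `statecompare` implements the three
quantitative analysis arms such a comparison rests on, each exercisable
end-to-end on synthetic data with known ground truth:

* **ESEEM arm** — per-residue solvent (D₂O) accessibility from 3-pulse
  electron spin echo envelope modulation time traces. The echo envelope

  *V(T) = B(T)·[1 − (k/4)(1 − cos 2πν<sub>D</sub>τ)(1 − cos 2πν<sub>D</sub>(T+τ))e<sup>−T/t_d</sup>]*

  is deconvoluted (upper-envelope background, two-pass robust fit, joint
  refinement), and the modulation depth *k* is recovered two independent
  ways: a damped-harmonic-oscillation fit and the integrated deuterium
  peak of the Hamming-apodized, zero-filled magnitude spectrum. Panels
  are normalized so the most accessible residue is 100%, with a 5-point
  uncertainty floor, and states are compared per residue
  (deprotected / protected / no change).
* **HDX arm** — differential hydrogen-deuterium exchange at peptide
  level: coverage/redundancy statistics, per-peptide uptake differences
  summed over the time course, a global Wood's-plot significance
  threshold *t₁₋α/₂,df · √Σₜ(s²₁ₜ/n₁ + s²₂ₜ/n₂)* with pooled per-timepoint
  variances (99% CI by default), and conservative projection of peptide
  classes onto residues and contiguous regions.
* **MD arm** — structural metrics from (multi-model) PDB structures:
  Kabsch RMSD, helix tilt, phosphate-to-phosphate membrane thickness,
  HOLE-style largest-sphere pore radius profiles with the 1.15/2.3 Å
  water-passage classes, axial solvent density and dewetting calls,
  per-residue lipid contact maps and their relative differences,
  acyl-chain S<sub>CD</sub> order parameters, Shrake–Rupley pocket
  surface area, and pairwise Lennard-Jones/Coulomb group energies.

A `synthetic_data` module generates every input class (echo traces,
uptake tables, toy bilayer/pore/helix/water systems) with planted ground
truth, and a config-driven pipeline runs the arms and merges their
per-residue classifications into a state report that flags agreements and
conflicts.

## Worked example

Simulate a four-residue accessibility panel in two states — the second
with the most buried residue strongly deprotected and one exposed residue
protected — then recover and compare:

```r
library(statecompare)

shared <- eseem_sim_params(noise_sigma = 0.005, seed = 42)
wt  <- simulate_accessibility_panel(
         c(L72 = 0.012, V71 = 0.32, N70 = 0.36, K100 = 0.40), shared)
mut <- simulate_accessibility_panel(
         c(L72 = 0.15,  V71 = 0.22, N70 = 0.36, K100 = 0.40), shared)
panel_wt  <- analyze_panel(wt,  method = "fit")
panel_mut <- analyze_panel(mut, method = "fit")
compare_states(panel_wt, panel_mut)
#>   label  a_pct b_pct delta_pct fold_change       class
#> 1   L72   1.53  37.3      35.7      24.308 deprotected
#> 2   V71  80.29  55.2     -25.0       0.688   protected
#> 3   N70  90.18  90.2       0.0       1.000   no_change
#> 4  K100 100.00 100.0       0.0       1.000   no_change
```

The wild-type panel reads L72 ≈ 1.5% (most buried), V71 ≈ 80%, N70 ≈ 90%
against the K100 reference — the planted 3/80/90/100 ratio structure at
0.5% trace noise — and the comparison classifies exactly the two planted
changes: a >20-fold accessibility increase at L72 and a ~25-point
decrease at V71, with the untouched residues reported as no change.

Differential HDX with one deprotected region planted at residues 58–69
(10-fold protection loss):

```r
p    <- hdx_sim_params(deprotected_regions = list(c(58, 69, 10)), seed = 7)
tabs <- simulate_hdx_dataset(p)
dr   <- differential_uptake(tabs$A, tabs$B, alpha = 0.01)
attr(dr, "threshold")          # 0.258 Da global 99% threshold
map_regions(dr)$regions
#>   start end       class
#> 1    58  68 deprotected
```

22 of 161 peptides exceed the threshold and the residue-level consensus
returns a single contiguous deprotected region within one residue of the
planted bounds (the last residue is the non-exchanging first position of
the shortest covering peptide).

The pipeline runs all three arms from a config
(`run_pipeline("run.yaml")`, or the `inst/exec/statecompare` wrapper) and
writes CSV/JSON artifacts plus a per-residue `state_report` that marks
residues as concordant or conflicting between arms.

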