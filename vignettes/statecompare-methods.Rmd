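---
title: "Methods: quantifying channel-state differences from ESEEM, HDX-MS and MD metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying channel-state differences from ESEEM, HDX-MS and MD metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statecompare)
```

`statecompare` compares conformational states of a membrane protein —
prototypically the mechanosensitive channel MscL, closed versus expanded by
tension or by pocket delipidation — through three independent quantitative
probes: per-residue solvent accessibility from 3-pulse ESEEM, peptide-level
differential deuterium uptake from HDX-MS, and structural metrics computed
from structures or trajectories. Each arm is paired with a synthetic-data
generator with known ground truth, so the whole analysis chain is testable
without any external download. This vignette documents the models, the
defaults and their units, the numerical choices, and what the synthetic
conditions do and do not establish about real data.

## 1. ESEEM solvent accessibility

### Model

The stimulated-echo amplitude of a nitroxide-labelled site in D~2~O buffer
is modelled as

$$V(T) = B(T)\,\Big[1 - \tfrac{k}{4}\,(1-\cos 2\pi\nu_D\tau)\,
        (1-\cos 2\pi\nu_D(T+\tau))\,e^{-T/t_d}\Big] + \varepsilon,$$

where $k$ is the total deuterium modulation depth (proportional to the
number and proximity of matrix deuterons, hence to water accessibility),
$\nu_D$ the effective deuterium Larmor frequency, $\tau$ and $T$ the pulse
delays, $t_d$ an empirical damping time, and $B(T)$ a stretched-exponential
echo decay. A single effective deuterium line is used: nuclear quadrupole
splittings and combination harmonics are deliberately absorbed into the
damping term, which is exactly the approximation made when the deconvoluted
modulation is fitted by a damped harmonic oscillation.

The factor $(1-\cos 2\pi\nu_D\tau)$ carries the blind-spot behaviour: at
$\tau = m/\nu_D$ the deuterium modulation vanishes identically. The default
$\tau = 205$ ns sits on a proton blind spot (proton Larmor about 14.6 MHz
at X band) while staying close to the deuterium modulation maximum;
$\nu_D = 2.25$ MHz is the X-band default and is recorded as metadata, not
inferred as a measured fact, because the spectrometer field is an
acquisition choice.

### Acquisition defaults and a design calculation

Defaults: `t_start` 400 ns, `t_step` 12 ns, `n_points` 2048,
`damping_time` 8000 ns, `bg_time` 20000 ns, `bg_stretch` 0.9,
`noise_sigma` 0 (fraction of the echo amplitude). The damping and
background constants describe slow nuclear-modulation decay and a
stimulated-echo lifetime on the tens-of-microseconds scale typical of
frozen solutions at 80 K. Before implementation we computed the expected
weighted-least-squares covariance of the damped-harmonic amplitude on this
grid: at 0.5% noise the relative standard error of the depth parameter is
about 1.8% for the weakest panel member ($k = 0.05$) and well below 1% for
$k \ge 0.3$ — consistent with the conventional "fit SDs below 2%" quality
bar for this experiment, which the acceptance suite then verifies by
simulation rather than assumes.

### Background deconvolution

The deuterium modulation only ever reduces the echo, so the
oscillation-free background is the trace's upper envelope.
`correct_background()` takes per-period maxima (one period from the
spectral peak), fits the decay model (stretched exponential by default,
cubic-in-log fallback), and refits after masking outlying envelope
residuals — two passes of iterative masking. The nuclear modulation
function is then $m(T) = V(T)/\hat B(T) - 1$.

A staged deconvolution has a fundamental blind spot: a smooth error in
$\hat B$ is indistinguishable, within the modulation function alone, from a
smooth change in the modulation baseline, and with the envelope estimator
that error is noise-dependent (order statistics of the per-period maxima).
What identifies the decomposition is the *structure* of the modulation:
its decaying baseline and its oscillation share one amplitude. The final
estimator in `fit_modulation()` therefore refits background and damped
harmonic *jointly* on the reconstructed trace,

$$V(T) \approx a\,e^{-(T/t_0)^\beta}\Big[1 + A\,e^{-T/t_d}
      \big(\cos(2\pi\nu(T+\tau)+\phi) - 1\big)\Big],$$

seeded by the staged estimates, and then reports the damped-harmonic fit on
the refined modulation function. This removes the envelope bias (recovery
errors stay within a few percent down to $k = 0.05$ at 0.5% noise, and the
noiseless round trip is exact to better than $10^{-3}$) while the quoted
parameter covariance remains that of the damped-harmonic fit given the
deconvolution — the conventional way fit precisions are reported for this
experiment. Weights are proportional to $\hat B^2$, the inverse-variance
weighting for additive noise on the raw echo.

The depth is recovered from the fitted amplitude through
$A = k(1-\cos 2\pi\nu\tau)/4$; the `baseline = "free"` variant releases
the co-decaying baseline coefficient for data whose deconvolution does not
guarantee the locked shape.

### Two quantification routes and normalization

The Fourier route applies a Hamming window and at least 4x zero-filling to
the (mean-subtracted) modulation function and integrates the magnitude
spectrum in a +-0.5 MHz window around the deuterium line. The median
off-peak magnitude times the window width is subtracted: a magnitude
spectrum has an incoherent noise floor that would otherwise bias weak
peaks upward. Both routes quantify the same deconvoluted modulation
function, and on simulated panels they agree with Pearson r above 0.99.

Panels are normalized to the most accessible residue (100%), or to an
explicitly named reference. Uncertainties are propagated and floored at 5
percentage points — the conventional error bound that exceeds fitting and
relaxation-difference errors. State comparison normalizes each state's
panel on its own scale and classifies residues as deprotected/protected
when the percentage change exceeds the combined (floored) uncertainties;
with two 5-point floors the smallest detectable change is about 7 points.
Per-state normalization is the default because a joint scale would let a
change in the reference residue masquerade as a change everywhere else;
a joint panel can still be built by passing an explicit reference.

## 2. Differential HDX-MS

### Uptake model and generator

Residue-level exchange follows $1 - e^{-k_{int}t/P}$ with a uniform
intrinsic rate (10/min by default) and a uniform baseline protection
factor $P$ (100). Sequence-dependent intrinsic rates are deliberately out
of scope: differential analysis compares matched peptides between states,
so residue-specific rates cancel to first order. The first residue of each
peptide and prolines do not exchange (standard fast-back-exchange
bookkeeping). Deprotection is planted by dividing $P$ inside stated
regions by a fold change; replicate noise is i.i.d. Gaussian (0.05 Da
default), truncated at zero.

The default digest map is a union of 11-mers every 3 residues and 4-mers
every residue (redundancy about 7). Real pepsin maps are irregular, but
they do contain short fragments, and it is precisely the short peptides
that let region boundaries be localised; the regular tiling makes the
resolution analysis transparent.

### Significance and region mapping

For each shared peptide the per-timepoint difference in mean uptake is
summed over the five-point time course (0.5, 1, 2, 10, 60 min, three
replicates). Significance uses a single global threshold at the 99%
confidence level: Student-t critical value times the standard error of the
summed difference, with per-timepoint replicate variances pooled across
all peptides — the Wood's-plot convention of testing every peptide against
one global noise estimate. Degrees of freedom are the summed per-peptide
replicate degrees of freedom (20 for 3+3 replicates over 5 timepoints),
which is slightly conservative relative to counting the pooled variances'
true precision. A hybrid mode additionally requires one individually
significant timepoint (per-peptide Welch test); summed-only is the default
because the global threshold is what the plotted dotted line means.

Peptide classes are projected to residues by a conservative unanimity
rule: a residue is called deprotected (or protected) only when *every*
covering peptide is significant with that sign; any non-significant or
contradictory covering peptide vetoes the call. Majority voting over
significant peptides is available, but with strong effects every peptide
straddling a region boundary is significant, so majority voting smears
boundaries by about half a peptide length; the unanimity rule instead
recovers planted boundaries within about 2 residues (the veto window of
the shortest peptides), at the cost of undershooting by one residue where
a boundary residue is the non-exchanging first position of a short
peptide. Null calibration across 200 simulated experiments keeps the
flagged fraction at or below twice the nominal level.

## 3. Structural metrics

All coordinates are Angstrom internally; thicknesses are reported in nm
and energies in kJ/mol. The toy-structure generator emits a phosphate
bilayer (thickness exact by construction), tilted all-trans acyl chains
with explicit hydrogens, a pore lined with spheres realising cylinder,
cone or hourglass free-radius profiles, an ideal 30-residue alpha-helix
(2.3 Angstrom radius, 1.5 Angstrom rise, 100 degrees per residue) at a
stated tilt, and pore waters. Thirty residues keep the principal-axis tilt
recovery within 0.5 degrees — the axis estimate of a finite helix has an
error that decays quadratically with length.

* **RMSD** — Kabsch superposition via SVD with the determinant-sign
  correction; validated against a rotation-grid brute-force minimiser and
  bio3d's fitted RMSD.
* **Pore radius** — at each z slice the largest sphere radius
  $\max_{(x,y)} \min_i (|p-a_i| - R_i)$, maximised by Nelder-Mead seeded
  from the previous slice (the connected-pathway assumption that makes
  HOLE-style profiling stable); classes use the 1.15/2.3 Angstrom
  water-exclusion/free-passage thresholds. Agreement with a dense
  random-sampling oracle is within 0.1 Angstrom on all fixture shapes.
* **Hydration** — water counts in an axial cylinder per z bin converted to
  nm^-3; bulk from bins outside the membrane span; "hydrated" means no
  in-membrane bin falls below 0.2 x bulk (configurable — profiles, not a
  published cutoff, define dewetting). Bins a few Angstrom wide are needed
  for single-frame profiles; sub-Angstrom bins of a thin cylinder hold
  well under one water on average and Poisson zeros would read as
  dewetting.
* **Lipid contacts** — heavy-atom pairs within 4.0 Angstrom (no cutoff is
  printed for the original maps; 4.0 is the common heavy-atom convention
  and is recorded in the output), averaged per residue over frames.
  Relative differences are reported both per residue,
  $(C_t - C_r)/\max(C_r, 1)$, and normalized to the maximum reference
  count, since either normalization is defensible.
* **Order parameters** — $S_{CD} = \langle(3\cos^2\theta - 1)/2\rangle$
  per carbon; the all-trans vertical fixture gives exactly -0.5 and
  horizontal chains move mid-chain magnitudes toward the
  $(3\cos^2\phi-1)/4$ envelope.
* **Pocket SASA** — Shrake-Rupley with a deterministic golden-spiral point
  set (960 points, about 1% accuracy on a lone sphere; rotation-invariant
  only to the angular sampling resolution).
* **Pairwise energies** — plain-cutoff (12 Angstrom) Lennard-Jones with
  Lorentz-Berthelot combining plus Coulomb with
  $f = 138.935458$ kJ mol^-1 nm e^-2, averaged with SDs over an analysis
  window of frames (e.g. the final frames of a trajectory). The
  force-switch smoothing of simulation engines is not reproduced; for
  interaction-energy *comparisons* between conditions the plain cutoff
  changes window means far less than the frame-to-frame spread.

## 4. Pipeline

`run_pipeline()` takes a YAML/list config with per-arm sections, runs each
enabled arm independently (an arm failure is recorded while the others
complete), and writes CSV/JSON artifacts plus a manifest with MD5
checksums and the seed, so a fixed config reruns byte-identically.
`build_state_report()` merges per-residue classifications — ESEEM labels
are parsed for residue numbers, HDX classes come from the region mapping —
flags sign conflicts between arms without resolving them, and attaches the
MD summary. Residues absent from every arm never appear.

## 5. What the synthetic conditions do and do not show

The generators reproduce the statistical *structure* the analyses assume:
a single-line damped deuterium modulation on a smooth echo decay;
exchangeable-residue-additive uptake with Gaussian replicate noise; exact
geometric bodies for the structural metrics. Passing tests therefore
demonstrate correctness of the estimators under their stated models and
calibration of their error conventions — not robustness to quadrupole
structure or overlapping proton modulation in real ESEEM traces, EX1/
bimodal exchange or back-exchange gradients in real HDX data, or
force-field realism in real trajectories. Those effects are explicitly out
of scope, and the corresponding knobs (background model, baseline mode,
hybrid significance, contact cutoff, hydration fraction) are exposed so
real-data idiosyncrasies can be absorbed where they first appear.

Problem sizes used throughout the tests and the acceptance script — 26
traces of 1024-2048 points, about 160 peptides x 5 timepoints x 3
replicates x 200 null replicates, and toy systems of a few thousand
atoms — were chosen as the smallest sizes at which the quantities being
checked (panel maxima, null fractions, boundary offsets) are stable to
well within their test tolerances.
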