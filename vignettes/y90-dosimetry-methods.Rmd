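---
title: "Methods: pre-treatment Y-90 dosimetry from Tc-99m-MAA images"
author: "Y90dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-treatment Y-90 dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Y90dosimetry)
```

# The planning problem

Before a ⁹⁰Y radioembolization, a ⁹⁹ᵐTc-MAA surrogate injection is imaged
to predict where the microspheres will lodge. Planning dosimetry answers
two questions: how much activity escapes to the lungs, and how the rest
splits between tumors and normal liver. This vignette documents the models
implemented here, the assumptions behind them, and the numerical and
design choices a careful user should know about.

Throughout, the central modelling assumptions are:

* **identical biodistributions** — the ⁹⁹ᵐTc-MAA count image is taken as a
  faithful map of the eventual ⁹⁰Y microsphere distribution;
* **permanent trapping** — microspheres do not clear biologically, so the
  time-integral of activity is `1.443 · T½ · A` with the physical
  half-life only (no time-activity fitting);
* **uniform density** — compartment masses are volumes at 1 g/mL; voxel
  masses use a soft-tissue density (default 1.03 g/mL, below).

# Compartmental models

The lung shunt fraction comes from planar imaging:
`LSF(%) = 100·C_lung/(C_lung + C_WL)`, where both counts are geometric
means of the anterior and posterior ROI *totals* (not pixel-wise). The
geometric mean of totals is used because the anterior/posterior
attenuation factors approximately cancel at the organ scale; no explicit
attenuation or scatter correction is applied to the planar views.

The partition model (PM) splits the liver-bound activity
`A·(1 − LSF/100)` between the aggregated tumor TL and the target normal
liver NLt in proportion to mass times uptake:

```
D_TL  = 49.67 · A · (1 − LSF/100) · TNR / (M_TL·TNR + M_NLt)   [Gy]
D_NLt = D_TL / TNR
```

49.67 J/GBq is the total beta energy released per GBq of fully decayed
⁹⁰Y. Two identities follow and are enforced by tests: the energy balance
`M_TL·D_TL + M_NLt·D_NLt = 49.67·A·(1 − LSF/100)`, and
`D_TL/D_NLt = TNR` exactly. The whole-normal-liver dose is the NLt dose
rescaled by the mass ratio `M_NLt/M_NLw`.

The multi-tumor partition model (MTPM) treats each tumor as its own
compartment: `D_Ti` replaces the numerator `TNR` with the per-tumor
`TNRᵢ` while keeping the aggregate `TNR` in the denominator. Because the
aggregate ratio is the volume-weighted mean of the per-tumor ratios when
both are measured on the same count image, the volume-weighted mean of
`D_Ti` equals `D_TL` exactly — MTPM redistributes the PM tumor dose, it
does not change the total. On a single-tumor patient MTPM and PM
coincide.

`COV(TNRᵢ) = 100·SD/mean` summarises inter-tumor heterogeneity. The
convention for the SD (sample vs population) is not standardised; this
package uses the **sample (n−1) SD**, which is the common default in
clinical statistics software. At two or three tumors the difference is
visible, so the choice is stated here and fixed.

# Voxel dosimetry

Counts become activity through the patient-specific self-calibration
`A_voxel = C_voxel·(1 − LSF/100)·A / C_WL`: no system sensitivity factor
is needed because the liver total is forced to equal the liver-bound
activity. Counts outside the whole liver are excluded (with a warning) —
there is no extrahepatic dose model, and dosing voxels outside the
calibration region would silently break activity conservation.

The **local deposition method** (LDM) assumes every beta particle
deposits its energy in its voxel of emission:
`D = Ã · S`, with
`S = ⟨E_β⟩ / M_voxel` = 1.603 Gy/(GBq·s) for the 4.48 mm cubic voxel.
LDM requires cubic voxels; an anisotropic self-dose S-value is not
defined.

The **dose-point-kernel** (DPK) method convolves the cumulated-activity
map with a voxel S-value kernel covering the ~11 mm beta range. The
convolution is computed directly (offset-shifted accumulation), not by
FFT: grid sizes and kernel extents in this application are small enough
that the direct sum is fast, deterministic, and free of wrap-around
artefacts. **Zero padding** is used at the grid edge — energy carried
past the boundary is lost, which is the physically honest choice when the
liver lies in the grid interior (tests verify ≤0.1 % energy loss when the
kernel support fits inside the padding).

Kernels are pluggable inputs in a plain-text format (`readKernel()`), so
published voxel S-value tables can be used directly. The built-in
`buildDefaultKernel()` is a **synthetic** kernel: Monte-Carlo voxel-pair
integration of a Weibull-shaped radial energy-deposition profile
(shape 2, scaled so 90 % of the beta energy falls within 5.3 mm, hard
cutoff at 11.3 mm — standard figures for ⁹⁰Y in soft tissue), normalized
so the energy deposited per decay over all offsets equals ⟨E_β⟩ exactly.
It is energy-closed and qualitatively correct (self-dose below the LDM
S-value, monotone radial fall-off) but it is not a transport calculation;
results with it should be read as method demonstrations, not clinical
kernels.

## The inconsistent printed constants

The planning constants in clinical use are mutually inconsistent at the
0.3 % level: integrating ⟨E_β⟩ = 0.9267 MeV/decay over all decays of
1 GBq (T½ = 64.2 h) gives 49.52 J/GBq, not the canonical 49.67; and the
printed voxel S-value 1.603 Gy/(GBq·s) implies a voxel density of
1.03 g/mL while compartment masses conventionally use 1.00 g/mL. The
package keeps both conventions visible in `physicsConstants()`:

* `mode = "paper"` (default): every constant as printed. A uniform
  phantom then shows a fixed ≈3.3 % offset between compartment (PM/MTPM)
  and voxel (LDM) mean doses — 1.03 from the density ratio times 1.003
  from the energy-constant gap. This offset is asserted in the test suite
  to lie in [3.0 %, 3.6 %].
* `mode = "consistent"`: the voxel beta-energy constant is derived from
  49.67 J/GBq and the voxel density defaults to the compartment density,
  making LDM and MTPM agree to machine precision on uniform activity.
  This mode exists for validation, where exact closed-form agreement is
  the point.

# DVH metrics

`dvhDx()` is **rank-based without interpolation**: voxel doses are sorted
descending and the value at rank `ceiling(x·N/100)` is returned. The
alternative (interpolated quantiles) differs by a fraction of a voxel;
the rank rule was chosen because it is bit-exactly reproducible and its
definitional identity `Vx(Dx) ≥ x` holds without tolerance. Curves use a
default 0.5 Gy bin width — fine enough that plotted curves are smooth at
typical liver doses — but all endpoint metrics bypass the binning and use
raw voxel doses.

# Agreement statistics

Bland-Altman limits of agreement are **bias ± 2·SD** with the sample SD
of the differences — exactly 2, not 1.96, following the convention of the
clinical literature this package serves. In published comparison tables
the bracketed interval next to the bias is, on inspection, the bias ± 2 SD
span rather than a confidence interval of the bias; `agreementTable()`
therefore reports the interval explicitly labelled as limits of
agreement. Lin's concordance coefficient uses population (1/n) moments;
two identical constant series give 1 by convention. NMSE is
`100·Σ(test − ref)²/Σref²` with the LDM map as the conventional
reference. Pearson, Spearman, paired t and Wilcoxon tests are not
re-derived; use `stats::cor.test`, `stats::t.test`, `stats::wilcox.test`
on the exported per-VOI tables.

# The synthetic phantom

`phantomSpec()`/`generatePhantom()` emulate the *structure* of a clinical
study — an ellipsoidal liver (default semi-axes 100 × 70 × 60 mm,
≈1760 mL) on a 64³ grid at the 4.48 mm SPECT voxel, spherical tumors with
prescribed `TNRᵢ`, a normal-liver concentration of 500 counts/mL (≈0.9
million liver counts, comparable to a 10-minute MAA acquisition), a
planar pair consistent with the prescribed LSF, optional Gaussian PSF
blur (applied before Poisson sampling: detector response, then counting
statistics), and per-seed reproducible noise. `phantomCohort()` draws
randomized cohorts with tumor counts 1–4, volumes 0.6–351 mL
(log-uniform), uptake ratios 0.6–4.1 and shunts 1.4–10.7 % — ranges
chosen once to match the spread reported in clinical cohorts.

What the phantom deliberately does **not** model: collimator response and
distance-dependent resolution, attenuation and scatter, reconstruction
artefacts, partial-volume effects at contour boundaries, registration
error, or tissue-density heterogeneity. Passing the recovery tests
therefore demonstrates the *correctness of the dosimetry arithmetic* and
the internal consistency of the estimators — not that clinical accuracy
survives a real imaging chain, where those effects dominate the error
budget.

Ground-truth recovery on a noiseless, unblurred phantom is exact to
≤1e−10 relative (in consistent mode) for LSF, TNR, TNRᵢ and all mean
doses; with Poisson noise at the default count level the TNR estimator is
unbiased with SD well under 0.1.

# Numerical choices and degenerate inputs

* Masks are binary voxel sets on the activity grid; no sub-voxel partial
  volumes (contours are assumed already resampled to the SPECT grid).
* Derived VOIs (TL, NLt, NLw) are recomputed on access, never cached, so
  they cannot go stale; construction rejects overlapping tumors and
  tumors outside the PTV, naming the offending voxel count.
* Empty masks error in every estimator (an empty-mask volume is 0 mL with
  a warning); a zero NLt count total makes TNR undefined and errors.
* Kernel validity requires odd dimensions per axis and non-negative
  entries; convolution requires kernel/grid spacing agreement within
  1e−6 relative.
* DPK–oracle agreement is asserted at ≤1e−12 relative against a
  six-level-loop brute-force sum on grids up to 8³.
* Test and validation problem sizes are deliberately modest — 24³–32³
  phantom grids for property sweeps (100 random phantoms for the
  aggregation identity), the full 64³ default for the end-to-end CLI run
  — keeping the complete suite under a minute while exercising every code
  path at clinically shaped geometries.

# Known limitations

The package stops at the planning boundary: no SPECT reconstruction,
registration, contour authoring (DICOM-RT import is future work), no
body-surface-area activity planning, no biologically effective dose, and
no Monte-Carlo transport. The default kernel is synthetic (above);
clinical DPK work should load a published kernel table. Extrahepatic
uptake is flagged but not dosed.
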