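---
title: "HAbrush: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HAbrush: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HAbrush)
```

# The system

Hyaluronan (HA) synthase embedded in immobilized bacterial membrane
fragments polymerizes and extrudes HA directly from a surface, growing
end-tethered polymer layers — brushes — whose heights reach several
micrometres within hours. Three experimental readouts characterize such
brushes, and this package implements the quantification for all three:

* **Confocal fluorescence profiles.** The brush is labelled with a
  GFP–HA-binding-domain fusion (GFPn) or read out indirectly through
  the exclusion of fluorescent nanoparticles. Brush height and the
  shape of the monomer concentration profile come from intensity
  profiles through z-stacks.
* **Solid-state nanopore sensing.** Single HA chains translocating a
  nanopore produce resistive current pulses; the time-integrated
  current deficit of a pulse (the event charge deficit, ECD) is a
  monotone proxy for molecular weight, calibrated with
  quasi-monodisperse standards. This yields full molecular-weight
  distributions spanning two orders of magnitude.
* **Biofilm assays.** Bacterial colonization of brush, film and bare
  surfaces is compared by the total biovolume of fluorescent bacteria
  in confocal stacks.

A fourth module collects the closed-form polymer physics connecting
these readouts, and a synthetic-data module generates all three kinds
of raw data with known ground truth, which is how the analysis code is
validated end to end.

# Closed-form brush physics

One HA disaccharide weighs $m_0 = 400$ Da and contributes $b \approx 1$
nm of contour length, so a chain of molecular weight $M$ has monomer
count $N = M/m_0$ and contour length $L = N b$. The dry (collapsed)
thickness of a grafted layer obeys

$$H = N\,\tau^{-1}\,\sigma\,b^3,$$

with $\sigma$ the grafting density (chains/nm^2^) and $\tau$ the
solvent-quality virial factor ($\tau = 1$ for the poor-solvent, dry
state). `graftingDensityFromDryHeight()` inverts this; for a
polydisperse brush the number-average $M_n$ gives the upper density
bound and the weight-average $M_w$ the lower bound. A density $d$ per
µm^2^ corresponds to a mean inter-chain spacing $s = 1000/\sqrt{d}$ nm.
The hydrodynamic radius scales as $R_H \sim M^{\nu}$ with
$0.6 < \nu < 0.8$ for high-MW HA (default $\nu = 0.7$); no absolute
prefactor is available, so `hydrodynamicRadius()` requires an anchor
pair, by default (0.72 MDa, 100 nm). A layer is in the *brush regime*
when the chain diameter $2R_H$ exceeds the spacing
(`brushRegimeRatio()`).

Two reporting conventions are worth stating explicitly:

* `densityRatioPercent()` compares two densities *after* rounding each
  to two significant figures (740 and 2100 chains/µm^2^ rather than
  739.6 and 2066), because that is how headline densities are quoted;
  the full-precision ratio is available with `roundedInputs = FALSE`.
* The UV deactivation threshold for HA synthase
  ($2.13\times10^{-4}$ J/µm^2^ at 405 nm) is treated as **inclusive**:
  it is reported as a sufficiency bound, so a dose exactly at the
  threshold counts as deactivating (`uvDoseCheck()`).

# Confocal profile analysis

## Spherical brushes

Microspheres (8 µm silica beads; default radius 4 µm) carrying a brush
are located by thresholding the brush-label channel — Otsu's method
behind a noise-floor guard (`binarizeStack()`, below) — and taking the
centroids of the labelled 3-D components; by symmetry the centroid of a
brush shell is the bead centre. Around each centre, azimuthally
averaged radial profiles are extracted from cones (`coneProfile()`).
"30° cones" is interpreted as a **full aperture of 30°** (15° half
angle); this is configurable. Voxel indices are converted to physical
nanometres *before* binning, so the strong axial anisotropy of confocal
stacks (e.g. 50 nm lateral / 470 nm axial) is honoured without
resampling. Cones aimed at a neighbouring sphere's brush, or truncated
by the stack boundary before reaching the background regime, are
dropped automatically.

Background statistics come from the **last 50 profile bins** at the
edge of the image (`backgroundStats()`; the count is configurable and
an explicit error — not a silent shrink — if the profile is shorter).
The brush edge is the outermost bin whose intensity reaches the
background mean plus twice its standard deviation, sustained for
`kSustain = 3` consecutive bins inward to resist single-bin noise
spikes; the crossing is then refined by linear interpolation between
bins. Two numerical details:

* **Count-aware thresholding.** Radial bins do not have equal voxel
  support: near the cone apex a bin may average tens of voxels while
  tail bins average thousands, so a standard deviation estimated from
  the tail understates inner-bin noise by $\sqrt{n_\text{tail}/n_i}$.
  `detectBrushEdge(countAware = TRUE)` scales the per-bin threshold
  accordingly. The correction vanishes when bins have equal support —
  in particular for laterally averaged axial profiles and for the
  closed-form checks — and is what keeps brush-free stacks from
  producing spurious edges.
* **Degenerate backgrounds.** When the background sd is exactly zero
  (noise-free synthetic data), the threshold equals the background
  mean and bins exactly at background must not count as brush; the
  comparison switches from `>=` to `>` in that case only.

The sphere surface is the interior peak of the surface-marker (GFPn)
profile, refined parabolically; a monotone or boundary-peaked profile
falls back to the nominal sphere radius with a flag. Height = edge −
surface, averaged over clear cones per sphere, then over spheres.

## Planar brushes

For planar stacks the laterally averaged axial profile plays the role
of the radial profile. The particle-exclusion height
(`planarExclusionHeight()`) estimates the bulk plateau from the topmost
20% of slices and the floor from the bottommost slices, and places the
brush edge at the **half-maximum of the particle-intensity rise**
(linear sub-slice interpolation); this half-maximum convention is this
package's own definition of the exclusion edge, chosen because the
logistic-shaped penetration front has its inflection there. A
plateau–floor contrast below `minContrast` floor-sds flags the result
invalid instead of returning a number. `planarEdgeHeight()` applies the
same background + 2σ rule as the spherical pipeline to the brush-label
channel, so the two independent height readouts can be compared on the
same stack — the synthetic tests require them to agree.

Concentration profiles of polydisperse brushes are well described by an
exponential $I(r) = I_0 e^{-(r - r_s)/\lambda} + bg$;
`fitExponentialProfile()` fits it by Levenberg–Marquardt with
log-linear starting values, and refuses to fit (flag, not error) when
fewer than 5 bins rise above background.

# Nanopore molecular-weight analysis

Traces are 200 kHz ionic-current recordings at 200 mV. A 5 kHz digital
low-pass is applied first — a zero-phase (forward–backward) Butterworth
filter; detection operates on the filtered trace, following the order
of operations in the experimental processing chain. The trace is
extended by odd reflection at both ends before filtering and trimmed
after: recursive filters otherwise inject start-up transients at the
boundaries that masquerade as events.

The baseline is a rolling median, evaluated hierarchically for speed
(block medians of `window/25` samples, running median across one
window, interpolated back to sample resolution); noise σ is the scaled
MAD of the residuals. The window (default 50 001 samples, 0.25 s)
should stay ≳5× the longest expected event: a rolling median only
rejects events occupying a minority of its window, which is the
method's fundamental limit — second-long events at the far end of the
duration gate would require a different baseline strategy.

Events are maximal runs of samples deviating below baseline by more
than 5σ, extended outward to the nearest baseline re-crossings (so
shallow pulse shoulders are integrated), merged when extensions
overlap, and gated to durations in **[25 µs, 2.5 s], inclusive at both
ends** (the gate is quoted as a closed range). ECD is the rectangle-rule
integral of the deficit over the event, clamped at ≥ 0. ECD → MW uses a
power-law calibration (straight line in log–log space) fitted to
quasi-monodisperse standards, with a monotone-spline alternative and
explicit extrapolation flags outside the standards' range. The
vectorized detector is validated against `detectEventsNaive()`, an
independent sample-by-sample reference scan with identical semantics.

The moments of a per-molecule weight vector are
$M_n = \sum M_i / n$, $M_w = \sum M_i^2 / \sum M_i$,
$PDI = M_w / M_n \ge 1$.

# The synthetic-data generators

The generators define the regimes in which the analysis is validated;
their defaults are the measured conditions of the system they emulate:

* **Spherical brushes**: 4 µm bead radius, brush height 3.75 µm, decay
  length 1.5 µm, per-voxel SNR 20 ($I_0 = 100$, noise sd 5), voxels
  50 nm lateral / 470 nm axial. The brush channel is
  $I_0 e^{-r/\lambda}$ truncated at the brush height, plus Gaussian
  noise; a surface-marker channel peaks at the bead surface; the
  optional particle channel is excluded inside the brush through a
  logistic transition of width 2 voxels (the data show sharp exclusion
  but no analytic edge shape, so a logistic of configurable width is
  assumed). Default stacks are sized for cone analysis along ±x, with
  ≥ h + 3λ of clearance plus ≥ 50 pure-background bins along the
  analyzed axes; transverse extents only need to contain the sphere,
  so the segmented shell may touch the y/z borders (flagged, but not
  discarded).
* **Planar brushes**: height 2.62 µm (the 1 h growth value), 100 nm
  axial step, with particle, dextran (linear gradient, default 50%
  surface depletion) and surface-marker channels.
* **Nanopore traces**: one rectangular pulse per molecule, fixed
  amplitude (200 pA) and dwell ∝ MW (1 ms/MDa), so ECD ∝ MW — only the
  ECD, not the pulse shape, carries information downstream. Events are
  placed sequentially with exponential gaps plus a minimum gap, so they
  never overlap; the per-event truth (indices, rendered duration,
  noiseless ECD, MW) is returned. Pulse-edge smoothing is available
  (`riseSamples`) but off by default so the trivial pulse identities
  hold exactly.
* **Biofilms**: ellipsoidal bodies of 1 × 1 × 2 µm axes with random
  in-plane orientation near the substrate, Poisson-distributed at the
  requested surface density, blurred by 1 voxel and noised. Voxels are
  100 × 100 × 200 nm — no voxel geometry is stated for the original
  biofilm imaging, and 200 nm axial sampling is what resolves ~1 µm
  bodies. The *exact voxelized* body-union volume is returned as
  truth, so voxelization error is visible separately from segmentation
  error.

**Molecular-weight sampling.** The MW distribution family is
log-normal — the measured distributions are broad and right-skewed but
no family is named, and the log-normal is the standard choice whose
parameters $(\mu, \sigma)$ follow uniquely from targets $(M_n, M_w)$
via $PDI = e^{\sigma^2}$. The default sampling scheme is **stratified
inverse-CDF** (one mid-quantile per molecule, order permuted by the
seed). The reason is variance, not convenience: with $PDI \approx 2.8$
($\sigma \approx 1$), the sample $M_w$ of $10^5$ i.i.d. draws has a
Monte-Carlo sd of ~2% — the extreme tail dominates the second moment —
whereas mid-quantile stratification represents the tail
deterministically and recovers both moments to well under 1% (at the
cost of a small, documented truncation bias of the same order).
Plain Monte Carlo remains available as `method = "iid"`.

All generators route randomness through one seeded RNG and record the
seed in their truth metadata; a fixed seed gives bit-identical output.

# Biofilm quantification

High-pass filtering (stack minus its Gaussian-blurred copy, default
scale 2 µm — much larger than a cell, much smaller than the field)
removes smooth background; Otsu's method binarizes; biovolume is the
nonzero-voxel count times the voxel volume, reported both in total and
within a near-surface band (default 0–5 µm above the surface). Two
guards surround Otsu:

* the threshold is computed from the voxels above a preliminary noise
  level (median + 2 robust sds) rather than the pooled histogram —
  with a tiny foreground against an overwhelming background peak,
  pooled Otsu is biased toward the background and systematically
  dilates masks (by ~10% in the validation regime; the restricted
  variant is approximately unbiased). `restrictToSignal = FALSE`
  restores the pooled histogram;
* the threshold is never taken below median + 4 robust sds, which is
  what keeps bacteria-free fields empty (false-positive volume well
  under 0.1%).

Cell counts divide biovolume by an assumed per-cell volume (default
1 µm^3^, a typical rod bacterium) — an assumption, reported alongside
the count, since no conversion factor is measured.
`retentionComparison()` expresses surface retention as percent
reduction and fold ratio against a reference surface, with SEM over
imaged regions and an explicit flag for infinite folds.

# Validation strategy and problem sizes

Every stage is validated against either a closed form or the
generators' ground truth: the nine printed physics numbers at printed
precision; the edge rule against its analytic crossing
$\lambda \ln(I_0 / 2\sigma_{bg})$; spherical height recovery on 30
synthetic beads at SNR 20 (population mean within 0.30 µm of the
3.75 µm truth) and planar recovery within 0.2 µm of 2.62 µm; detector
equivalence with the reference scan on 100 random traces of up to
10^5^ samples, with recall = precision = 1 for well-separated ≥10σ
events and ECDs of rectangular/triangular pulses at their analytic
areas; moment recovery within 2% at $n = 10^5$ and end-to-end
(trace → detection → calibration → moments) within 5% of the generated
sample's own moments; ellipsoid biovolumes within voxelization error
and empty-field false positives below 0.1%. These sizes keep the whole
suite at a few minutes on one CPU while leaving each check's
statistical resolution well inside its tolerance.

```{r example}
brushPhysicsReport(2.42e6, 6.76e6, 12.5, enzymeDensityPerUm2 = 2040)
```

# What passing these tests does and does not show

The generators emulate exponential profiles with Gaussian noise,
rectangular pulses on a white-noise baseline, and ellipsoidal cells.
Real data add optics the generators deliberately omit: a non-Gaussian
point-spread function, depth-dependent attenuation and photobleaching,
correlated (1/f and capacitive) pore noise, folded and multi-level
translocation events, and bacterial aggregates. Passing the synthetic
suite therefore demonstrates that the *estimators* are correct and
unbiased in their stated regimes, not that those regimes cover every
instrument. Known limitations worth restating: the rolling-median
baseline cannot reject events comparable to its window; overlapping
translocations are not split; the 2σ edge rule depends on a correct
background estimate and the count-aware scaling assumes
shot/read-noise-like scaling of bin variance; and the planar
half-maximum convention, while internally consistent, is one of
several defensible exclusion-edge definitions.
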