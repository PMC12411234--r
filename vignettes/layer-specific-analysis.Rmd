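---
title: "Layer-specific cortical analysis: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-specific cortical analysis: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortilam)
```

## Scope and scientific question

`cortilam` implements a laminar analysis pipeline for the primary
somatosensory cortex (SI): how is the depth-wise microstructure of the
cortex (myelin-sensitive quantitative T1, QSM) organized into layer
compartments, where do low-myelin septa separate body-part representations
on the cortical sheet, and how do layer-specific functional responses,
psychophysics, and mouse barrel-cortex physiology relate to that
architecture. Because raw human MRI of this kind is not publicly
deposited, every analysis module is paired with a synthetic generator that
emits phantoms with the published group structure plus ground truth, so
the pipeline is validated in closed loop.

## Laminar model

A cortical patch is sampled at **21 depths** between the CSF/GM boundary
(index 1, superficial) and the GM/WM boundary (index 21, deep). Depth
placement uses the equivolume model: for equispaced volume fractions
$\rho$ between boundaries with areas $A_{in}$, $A_{out}$,

$$\alpha(\rho) = \frac{\sqrt{\rho A_{out}^2 + (1-\rho) A_{in}^2} - A_{in}}
{A_{out} - A_{in}},$$

which reduces to the equidistant grid when $A_{in}=A_{out}$
(`equivolume_depths()`).

**Compartmentalization** (`compartmentalize_profile()`): the two deepest
depths are removed (partial-volume contamination at the WM boundary), the
raw qT1 profile is differentiated with second-order central differences
(one-sided second-order stencils at the ends; no pre-smoothing), and the
two compartment boundaries are placed at the first two interior local
extrema of the first derivative at which the derivative magnitude is also
locally maximal. These are the plateau-to-plateau transition points of a
three-compartment profile. We deviated here from the simpler rule "first
extremum, then the next opposite-sign extremum": on monotone-decreasing
three-plateau profiles (which is what the published compartment means
imply: outer > middle > inner qT1), both transitions are minima of the
derivative and the only intervening maximum lies mid-plateau, so the
literal rule cannot recover the second boundary. The magnitude-maximal
rule coincides with the literal one on non-monotone (ridge/dip) profiles
and recovers both transitions on monotone ones.

Boundary positions are refined to continuous depth fractions by parabolic
interpolation around the discrete extremum. Without sub-grid refinement
the 19-depth grid quantizes compartment spans to 1/18 of the retained
range (~0.11 mm at 2 mm total thickness), which would be far coarser than
the 0.03 mm closed-loop tolerance the package holds itself to.

Compartment thickness is `total x span`. Whether the original analysis
applied an equivolume correction when converting spans to millimetres is
not documented; both modes are exposed in `compartment_thickness()` (the
uncorrected mode is the default and is what the closed-loop tests use).

## Low-myelin border detection

Septa are detected on the surface: five equally spaced geodesic paths run
inferior-to-superior (face toward little finger) across the patch; the
middle-compartment qT1 overlay is sampled along each path, averaging all
candidate vertices within one vertex-to-vertex distance of the sampling
axis; each signal is linearly detrended (the inferior-superior myelin
gradient is first order); interior local maxima are kept when their
topographic prominence exceeds `mean(|detrended|) + 2 sd(|detrended|)`
(the phrase "prominence > 2 s.d. from the mean of absolute detrended
values" is ambiguous; this scale-aware per-signal reading is the default
and a plain `2 sd` switch is provided); peaks are grouped across first and
second neighbour paths by a greedy nearest-neighbour rule with a **5 mm
geodesic** threshold, and groups with members on at least 3 of 5 paths
become borders. Features (prominence, FWHM at half prominence, qT1, ECM,
QSM variants) are averaged over member peaks; within-hand border features
are further averaged per subject.

Two geometric facts shape the operating characteristics, and both are
worth knowing before interpreting a green test:

* The 5 mm grouping threshold applies to the full geodesic distance, which
  includes the between-path separation. At the phantom's realized spacing
  of 4.75 mm, aligned peaks on first neighbours are 4.75 mm apart (just
  "near"), while second neighbours are 9.5 mm apart and can never group.
  A suprathreshold miss on the middle path therefore cannot be bridged;
  this is the sole failure mode of detection (measured detection rate
  0.97 at septum amplitude 100 ms over 300 phantom draws, localization
  error <= 1 mm otherwise).
* Making the family narrow enough for second-neighbour bridging
  (spacing < 2.5 mm, which is what the original description implies)
  raises the chance-coincidence rate of noise peaks to ~0.2 false borders
  per null phantom, because the along-path alignment window widens to
  ~4.4 mm. The wide-family geometry keeps false borders at ~0.015 per
  phantom. The package defaults to the wide family; the trade-off is
  inherent to the published rule set, not to the implementation.

A 50-phantom batch at a true detection rate of 0.97 fails a >= 0.95
cutoff with roughly 19% binomial probability; a red detection clause on a
single batch should be read against that base rate.

## The synthetic world

`gen_cortex_phantom()` builds a flat rectangular cortical strip
(20 x 30 mm, 0.25 mm vertex pitch, matching the ~0.28 mm vertex distance
of the real meshes) with a face band and five finger bands. Depth profiles
are three qT1 plateaus — outer 2100 ms (no group value is published for
the outer compartment; the same value is used for both cohorts), middle
1874.4 / inner 1636.3 ms (younger) and 1783.2 / 1547.6 ms (older) — with
logistic transitions at the cohort thickness fractions from the published
group means (younger total 2.06 mm, outer/middle/inner 0.41/0.56/1.10;
older 1.94, 0.40/0.85/0.69; n = 20/19). Per-subject total thickness is
Gaussian with s.d. 0.05 mm.

Noise is the sum of a **columnar biological field** (mesoscale myelin
variation: coherent across depths, Gaussian with 4 mm correlation along
the path direction, independent across the path-family direction) and
independent per-depth **measurement noise**; the split is 90/10 of the
total 30 ms variance. Two modelling points deserve emphasis. First, the
middle-compartment overlay used for border detection is a depth average,
which suppresses measurement noise but not columnar variation — with the
original naive i.i.d. noise model the published threshold rule produced
~4.5 false borders per null phantom, which no parameter of the detector
can fix because the rule is scale-invariant; only the noise *shape*
matters. Second, cross-path coherent qT1 ridges are exactly what a real
septum is, so a *null* phantom must not contain them; independence across
paths is a definition of the null, not a convenience. Septa are injected
as Gaussian ridges (default +100 ms, 1.5 mm width) spanning the middle
compartment in depth with soft edges.

What a green closed-loop test establishes: the pipeline recovers what this
generator encodes — plateau-structured profiles, coherent ridges,
phase-locked responses, logistic observers. What it does not establish:
robustness to cortical folding and curvature (the phantom is flat),
vascular and registration artifacts, non-plateau laminar profiles, or the
true spatial statistics of in vivo qT1 noise, none of which are published.

## Functional signals

Forward and reverse phase-encoded runs are averaged after time-reversing
the reverse run and circularly advancing it by 4 s (two TRs at TR 2 s) to
compensate the doubled hemodynamic lag (`average_phase_runs()`; the
generator constructs the reverse run as the exact mirror so the zero-noise
loop is closed). `fourier_amplitude()` computes the per-vertex DFT; the
stimulus bin is the `n_cycles`-th harmonic; the percent amplitude chain is
x2 (negative frequencies) x2 (peak-to-peak) / timepoints / mean brightness
x100; the F-ratio compares stimulus-bin power with the mean power of noise
bins at or above 0.005 Hz up to Nyquist, excluding the stimulus bin and
its first two harmonics (the exclusion set is an implementation choice;
the source only says "other noise frequencies").

Depth-response profiles are min-max normalized and calibrated by the
normalized resting-state fluctuation profile. The calibration operator is
not stated in the source; elementwise division with
`eps = 0.05 x rest range` is the default (resting fluctuation amplitude as
a scaling reference), subtraction is behind a flag. Note that division
makes "task = rest implies constant calibration" hold only away from the
normalized profile's zero. Peak and decay metrics exclude the most
superficial 20% of depths (veins), then integrate `calibrated - median`
over the middle compartment (peak) and `median - calibrated` over the two
flanks (decay, clipped at 0); anchoring the windows to the laminar
compartments is this package's choice where the source defines none.

1-D pRF fitting (`fit_prf_1d()`) z-scores and linearly detrends the
series, grid-searches Gaussian tuning parameters over
`[-1.25, 1.25] x (0, 1.25]` at step 0.05 (the search space deliberately
exceeds the stimulus space `[-1, 1]`), refines by Nelder-Mead on the
correlation objective, and estimates beta/baseline by least squares.
Fits with beta <= 0 are dropped from summaries. The noise ceiling is the
Spearman-Brown prophecy `2r/(1+r)` of the half-series correlation,
floored at 0. Eigenvector centrality uses rectified (non-negative)
Pearson correlations with zero diagonal and power iteration at 1e-10.

## Psychophysics and mouse physiology

* Staircase: 3-down/1-up, two interleaved staircases (0.02 g and 0.4 g
  starts on the log10(0.1 mg) filament ladder), stop when the s.d. of the
  last 30 intensities is at most one ladder step or at 100 trials;
  threshold = mean intensity over reversals in the last 10 trials (a
  session pinned at one ladder level returns that level). The 3-down/1-up
  procedure converges near the 79.4%-correct point, which is what the
  closed-loop recovery test checks against.
* d-prime: `z(hit) - z(fa)`; fa = 0 is replaced by 0.1 (task convention);
  rates of exactly 1 (or hit 0) are clamped by the half-count rule, which
  the source does not specify.
* 2PD: logistic regression of "two pins" on spacing; threshold at the 50%
  crossing; separation and out-of-range crossings produce warnings and
  non-finite thresholds rather than extrapolated numbers.
* Skin indentation: the printed formula is read as the power law
  `delta = (F/A)^(1/b) delta_hat` (A and b are material constants of a
  force-indentation power law, and F = A then maps to the reference
  indentation); the literal product reading is available behind a flag and
  is non-physical. The stimulation amplitude is `3 delta`.
* Precision grip: time within +-2.5% of the target force at 100 Hz.
* Calcium: dFF uses a zero-phase 60th-order windowed-sinc (Hamming) FIR
  low-pass at 1 Hz for the baseline estimate (5th percentile of the
  smoothed trace); movement labeling requires all three 0.5 cm/s criteria
  (instantaneous, 0.25 Hz low-passed, 1-s window mean) and merges
  inter-movement gaps under 500 ms. Because the filtered and windowed
  criteria average over +-0.5-1 s, the first and last fraction of a
  second of a bout are attenuated below threshold; labels cover the core
  of a bout, not its exact extent.
* Double- vs single-whisker classification uses evoked amplitudes (mean
  dFF 0-1 s post onset minus 1 s pre) compared by Welch t-test at
  alpha = 0.05; windows and test are this package's choices (the source
  reports only the resulting proportions), so the published 65%/51%
  additive proportions are context, not reproduction targets.

## Inference utilities

`perm_welch_t()` permutes group labels (Monte Carlo, or exhaustively for
small n), with the equal-tail two-sided p-value
`2 min(P(t* <= t), P(t* >= t))` capped at 1 and floored at `1/n_perm`
(plain proportions, honouring the printed floor convention rather than the
`(b+1)/(B+1)` estimator). The confidence interval is the observed mean
difference plus percentile bounds of the centred permutation distribution
of difference estimates; the source package's exact CI construction is
not documented, so this percentile convention is the package's choice.
`tau_from_r()` is `2/pi arcsin(r)`; `theil_sen_fit()` is the median of
pairwise slopes with median-residual intercept.

## Numerical choices and degenerate inputs

* Derivatives: second-order stencils throughout; linear profiles raise an
  explicit "no laminar structure" error (with a small epsilon guard so
  exactly-linear floating-point profiles do not produce spurious extrema).
* Path signals are resampled to a uniform 0.25 mm arc grid before peak
  analysis; FWHM and the 5 mm threshold are metric quantities.
* Peak ties (plateaus) resolve to the leftmost sample; boundary ties
  resolve toward the superficial side.
* Constant signals: peak detection returns an empty list; min-max
  normalization and the noise ceiling raise errors; ECM on an all-zero
  adjacency warns and returns the uniform vector.
* All generators are pure functions of (spec, seed); every generator
  emits its ground truth alongside the data.

## Known limitations

Flat-patch geodesics (edge-graph Dijkstra, not exact polyhedral
geodesics); group-level compartmentalization only (boundaries from the
cohort-mean profile); the equal-spacing construction of path families
shifts seeds along the anterior-posterior coordinate, which assumes the
patch's axes are aligned with the anatomical ones; and the acceptance
operating points quoted above are properties of the stated synthetic
world, not of in vivo data.
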