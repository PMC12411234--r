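# cortilam

Layer-specific analysis of cortical microstructure and function, built
around the primary somatosensory cortex (SI) hand area as a model system.

Aging and plasticity do not affect the cortex uniformly across its depth:
the cortical sheet is organized into laminar compartments — an outer
(layers II/III), a middle (input layer IV) and an inner (layers V/VI)
band — that can thin, thicken and remyelinate independently, and adjacent
body-part representations are separated on the sheet by narrow low-myelin
septa. `cortilam` provides the quantitative machinery to study this
architecture from high-resolution MRI and accompanying behavioral and
animal data:

* **Laminar structure** — equivolume construction of 21 cortical depths
  (`equivolume_depths()`); data-driven three-compartment segmentation of
  qT1 depth profiles from the extrema of the profile's first derivative,
  after removing the two deepest depths (`compartmentalize_profile()`);
  layer-specific cortical thickness (`compartment_thickness()`).
* **Low-myelin borders** — geodesic path families on triangulated cortical
  patches (`sample_parallel_paths()`), linear detrending and prominence-
  thresholded peak detection (`detrend_and_detect_peaks()`), grouping of
  peaks across at least 3 of 5 paths within a 5 mm geodesic radius
  (`group_peaks_to_borders()`), classification into hand–face vs
  within-hand borders with feature vectors
  (`classify_and_featurize()`); end to end via
  `detect_low_myelin_borders()`.
* **Layer-specific function** — mirror-symmetric averaging of forward and
  reverse phase-encoded BOLD runs, Fourier response amplitude / phase /
  F-ratio (`fourier_amplitude()`), rest-calibrated depth-response profiles
  with peak and decay metrics, 1-D Gaussian population receptive field
  fitting with a Spearman–Brown noise ceiling (`fit_prf_1d()`,
  `noise_ceiling()`), and eigenvector centrality on rectified correlations
  (`ecm_rlc()`).
* **Psychophysics** — 3-down/1-up staircase thresholds, d′, two-point
  discrimination, the skin-indentation power law
  δ = (F/A)^(1/b)·δ̂ (A = 0.2368 N, b = 2.0696, δ̂ = 1 mm), and precision-
  grip time-on-target.
* **Mouse barrel cortex** — ΔF/F with a zero-phase 60th-order 1-Hz FIR
  baseline filter, whisker-pad movement labeling (three 0.5 cm/s criteria
  plus the 500-ms gap rule), additive/reduced/unchanged classification of
  double- vs single-whisker responses, and depth-binned histological
  densities normalized to DAPI.
* **Inference** — Monte-Carlo permutation Welch t-tests with equal-tail
  p-values (floored at 1/n_perm), τ = 2/π·arcsin(r) cutoff conversion, and
  Theil–Sen regression.
* **Synthetic phantoms** — `gen_cortex_phantom()`,
  `gen_phase_encoded_bold()`, `gen_behavior_observer()`,
  `gen_calcium_traces()` emit every input the pipeline consumes, with the
  published group structure and full ground truth, so the entire pipeline
  is testable in closed loop without raw data.

## Worked example

Generate an "older adult" cortical phantom with a hand–face septum,
segment its laminar compartments, measure layer thickness, and detect the
border:

```r
library(cortilam)

ph <- gen_cortex_phantom(phantom_spec("older",
        septa = list(list(y = 10, amplitude = 100, width = 1.5)),
        seed = 42))

lc <- compartmentalize_profile(colMeans(ph$profiles))
lc
#> layer_compartments: b1 = 5 (f = 0.187), b2 = 13 (f = 0.581)
#>   spans outer/middle/inner: 0.208 / 0.438 / 0.355

compartment_thickness(mean(ph$truth$total_thickness), lc)
#> thickness_record: total 1.933 mm (outer 0.402, middle 0.846, inner 0.685)
```

The recovered compartment thicknesses sit within ~0.01 mm of the
generating cohort means (older: 0.40 / 0.85 / 0.69 mm) — the boundaries
were estimated from the phantom's mean qT1 profile alone. Border
detection runs five geodesic paths from the face band to the little
finger band and groups prominent detrended qT1 peaks:

```r
det <- detect_low_myelin_borders(ph$mesh, 41L, 120L * 81L + 41L)
b <- classify_and_featurize(det$borders[[1]],
       list(face = c(0, 10), thumb = c(10, 14), index = c(14, 18)),
       overlays = list(qt1 = function(p) 1850))
#> border: class hand_face at 10.00 mm on paths 3,4,5,
#> prominence 129.1 ms, FWHM 8.55 mm
```

The septum injected at y = 10 mm is recovered at 10.00 mm and classified
as a hand–face border. Group comparison of layer thickness uses the
permutation Welch test:

```r
perm_welch_t(c(0.41, 0.44, 0.40, 0.43), c(0.39, 0.40, 0.38, 0.41),
             n_perm = 10000, seed = 1)
#> perm Welch t-test: t = 2.236, df = 5.4, diff = 0.0250, p_perm = 0.0308
#>   95% CI_perm [0.0001, 0.0501], 10000 permutations
```

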