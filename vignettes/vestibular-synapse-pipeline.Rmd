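---
title: "Quantifying vestibular synapse deafferentation and vestibulo-ocular function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vestibular synapse deafferentation and vestibulo-ocular function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Excitotoxic injury to the inner ear transiently disconnects vestibular
hair cells from their primary afferent neurons. Histologically this
deafferentation is visible as a separation between presynaptic ribbons
(marked by CtBP2/RIBEYE) and the postsynaptic density of the afferent
terminal (marked by SHANK-1): in healthy epithelium a large fraction of
presynaptic puncta has a postsynaptic punctum within 1 µm, while after a
lesion that fraction collapses and recovers over days to weeks.
Functionally, the same injury degrades the angular vestibulo-ocular reflex
(aVOR), abolishes the otolith-driven maculo-ocular reflex (MOR), and
produces spontaneous vestibular nystagmus (SVN).

`vestisyn` implements the complete quantification chain for both readouts
— puncta detection and nearest-neighbour colocalisation analysis for
3D two-channel confocal stacks, and gain/bias/beat-rate analysis for 1 kHz
video-oculography traces — together with synthetic generators for both
data types, so that every stage can be exercised and validated end-to-end
without access to raw microscopy or eye-tracking data.

## The synapse model

A ground-truth observation field is a marked 3D point pattern in a box of
67.08 × 67.08 µm (the standard 4.5·10⁻³ mm² counting field) × 12 µm
axially. Its generating law has four ingredients:

* **Counts.** A sham utricle field holds 350 presynaptic and 450
  postsynaptic puncta (more postsynaptic than presynaptic, consistent with
  the relative abundance of the two markers; the absolute sham counts are
  a package choice at 3–5 ribbons per hair cell for a field of ~75–100
  hair cells, since absolute per-field counts are not published). Crista
  fields use 300/400.
* **Expression thinning.** Lesion/recovery groups keep the sham counts as
  a base and thin them binomially with the group's published expression
  fraction (e.g. 4 h utricle: presynaptic 0.63, postsynaptic 0.49; 3 week
  utricle: 0.88/0.93; 4 h crista: 0.38/0.39). Whether puncta are lost or
  displaced beyond detectability is not distinguishable from the published
  data; thinning is the modelling assumption.
* **Pairing.** A fraction `paired_fraction` of presynaptic puncta gets a
  postsynaptic partner displaced by a folded-normal magnitude
  |N(µ, σ)| in a uniformly random 3D direction. A two-parameter offset
  law plus the pairing fraction is the smallest family that can match the
  2–3 published cumulative-distance anchors per group.
* **Background.** All remaining puncta are uniform in the field. Uniform
  placement reproduces the long tail of the lesioned cumulative distance
  curves without committing to any displacement mechanism.

### Calibration

`calibrate_preset()` fits `(paired_fraction, µ, σ)` so that the
ground-truth presynaptic-to-postsynaptic nearest-neighbour cumulative
distribution matches the published anchors within 3 percentage points.
The background contribution B(d) is estimated once by simulating unpaired
fields; the mixture model

C(d) = B(d) + paired_fraction · F(d) · (1 − B(d)),

with F the folded-normal CDF, is then fit analytically over a grid on
(µ, σ), and the result is verified (and the pairing fraction refined) by
simulation. The procedure is deterministic given its seed. Utricle
presets are calibrated against their published 2–3 anchor curves; for the
crista only the 1 µm colocalisation level is published per group, so the
offset-law shape is fixed (sham: µ = 0.7, σ = 0.7 µm, a tighter
distribution consistent with the higher crista colocalisation; 4 h: the
lesioned utricle shape) and the pairing fraction alone is calibrated.
When a single anchor demands more than full pairing, pairing saturates at
1 and the offset scale is shrunk instead.

Shipped presets store the calibrated parameters and their anchors in
`inst/extdata/presets/field_presets.yaml`; the test suite re-simulates
every preset (≥ 5000 aggregated source puncta) and re-checks the anchors.

## Rendering

`render_field()` converts a point field into a synthetic confocal stack:
each punctum is an anisotropic Gaussian photon blob (PSF σ = 0.60 µm
axially, 0.15 µm laterally — typical for NA 1.40 confocal imaging),
integrated per voxel so the expected photon count per punctum equals
`photon_scale` (default 500), on a constant background (default 2
photons/voxel), with Poisson shot noise. The voxel grid is 0.40 µm
optical sections and 0.104 µm lateral pitch (63×/NA 1.40 at 1024×1024
over a ~107 µm field of view; the lateral pitch is a package choice, as
magnification and array size but not pixel pitch are published). The
default photon scale is a package choice too — no SNR figure accompanies
"subsaturating laser intensities" — and is exposed as a parameter.

The stack acquires a few z planes beyond each axial face of the field
(default 2 PSF σ) and records its physical origin. Without this padding,
puncta within ~1 µm of an axial face blur against the stack boundary, the
response peak saturates on the edge plane, and axial localisation fails
by up to 0.7 µm; padding restores uniform localisation quality across the
field, mirroring how a real acquisition sections through the full
epithelium rather than stopping exactly at the cell layer. Noise-free
rendering (`noise = FALSE`) exposes the linear expectation for tests.

## Detection

`detect_puncta()` replaces the interactive spot-detection step with a
deterministic, single-scale Laplacian-of-Gaussian detector: Gaussian
smoothing with anisotropy-corrected sigmas (defaults matching the
rendering PSF), negated 3D Laplacian with physical spacing, strict local
maxima above threshold, and greedy suppression below a 0.5 µm minimum
separation. Sub-voxel positions come from per-axis parabolic
interpolation of the response, which is exact for a Gaussian peak; an
intensity-weighted centroid over a fixed 3×3×3 window was evaluated first
and rejected because the window is narrower than the axial PSF, leaving
up to ~0.2 µm of systematic axial shrinkage — above the localisation
budget — whereas parabolic refinement leaves ~0.02 µm.

The default absolute response threshold (70 counts/µm²) sits above the
largest background-only response observed across seeds at the default
rendering settings (~50) and at about half the expected punctum response
(~140). At these settings the detector reaches ≥ 99% recall and
~100% precision with 0.065 µm mean 3D localisation error on sham-density
fields; residual misses are genuinely merged same-channel pairs closer
than the suppression radius. A percentile-of-positive threshold mode is
available for stacks whose absolute intensity scale is unknown.

`filter_by_mask()` encodes the "within or next to the hair cells" manual
curation rule deterministically: a punctum survives if its centroid lies
in the hair-cell mask channel or within a 1 µm margin of it.

## Distance metrics

`nn_distances()` computes exact directed 3D nearest-neighbour distances
(uniform-grid spatial index with expanding ring search; exactness, not
speed, is the contract, and the test suite compares it against an O(n²)
oracle). The primary reported direction is presynaptic → postsynaptic,
because presynaptic puncta are the scarcer species; the reverse direction
is always available by swapping arguments. Colocalisation uses the
inclusive 1 µm criterion, matching the "≤" phrasing of the cumulative
anchors. `normalized_expression()` expresses per-field counts as percent
of the sham mean, which maps the sham group itself to exactly 100%.

## Eye-movement simulation and analysis

Traces are synchronous head/eye position series at 1 kHz. Three trial
types are generated: sinusoidal aVOR rotations (0.2–1 Hz, 30°/s peak),
constant-velocity OVAR (50°/s, 17° tilt) probing the otolithic bias, and
spontaneous recordings with drift and resetting quick phases. The
simulators integrate the slow-phase velocity command and inject a
half-cosine resetting quick phase whenever eye eccentricity exceeds 15°;
spontaneous beats are laid on a jittered regular grid (a dispersed
renewal process) so the number of beats is exact by construction and
every beat's amplitude — hence quick-phase velocity — stays well above
the detection threshold. Position noise is Gaussian (default 0.1°).

The analysis chain mirrors standard oculography practice: zero-phase
4th-order Butterworth low-pass at 40 Hz on position, central-difference
differentiation, exclusion of samples deviating more than 50°/s from a
201 ms running-median slow-phase estimate (20 ms guard padding, 10 ms
minimum duration; the threshold and windows are package defaults, as the
published analyses reference external methods papers), then:

* `avor_gain()` — frequency-domain least squares of the retained eye
  velocity on sin/cos at the stimulus frequency; gain is the eye/head
  amplitude ratio. A whole-fit definition (not cycle medians) is the
  package's single normative definition; it is robust to excluded
  segments and recovers simulated gains within 2% across the sweep.
* `mor_bias()` — intercept plus sinusoid fit over whole rotation periods;
  the intercept is the otolithic bias, the sinusoid amplitude the
  modulation. The steady-state mean slow-phase velocity definition stands
  in for the bias extraction of the cited prior work.
* `svn_rate()` — excluded-interval count divided by trace duration in
  minutes; drift direction from the sign of the mean retained velocity.

Lesion presets store absolute parameters (baseline gain 0.55 at
0.2 Hz — a typical mouse dark-adapted value — times the published
normalised fraction; a 6°/s baseline OVAR bias; published beat rates), so
dividing a lesioned fit by a baseline fit reproduces the published
normalised time courses.

## Group statistics and the correlation grid

`anova_vs_reference()` performs one-way ANOVA with Dunnett comparisons of
every group against sham (single-step adjustment); all-constant input is
reported as a flagged degenerate case with p = 1 rather than an undefined
F. `repeated_anova()` handles the within-subject timecourses with the
Greenhouse–Geisser epsilon, reporting the corrected p-value whenever
ε < 0.75, plus Tukey pairwise comparisons. `build_correlation_grid()`
assembles percent-of-baseline trajectories — intact-synapse percentage
(presynaptic expression as proxy), normalised aVOR/MOR gains, and
externally scored posturo-locomotor percentages, which are never computed
by this package — into a fixed 8-timepoint wide table with explicit `NA`
for missing cells.

## Numerical and scale choices

* Blur, Laplacian response, local maxima and the NN index are compiled
  (Rcpp); a full 646×646×36-voxel two-channel field renders and detects
  in a few seconds, and the shipped validation workloads (10–12 fields
  per preset group, 10 oculomotor trials per condition) were sized so the
  whole suite and the acceptance script each run comfortably on one CPU.
* All coordinates are physical µm; the voxel `(i,j,k)` centre sits at
  `origin + (i − 0.5)·d` per axis. TIFF output is 16-bit, channel-major
  (CZYX), with voxel size, origin and channel labels in a JSON sidecar —
  the installed TIFF writer exposes no free-text tags, and reading
  without the sidecar is an error rather than a silent default.
* Ties in local maxima are broken by linear index; suppression is
  greedy from the strongest response.
* Degenerate inputs (empty channels, empty fields, zero-variance groups)
  return defined empty/flagged results; empty *target* sets for NN
  distances are an error, never infinities.

## What the synthetic data does and does not establish

The generators reproduce the published summary statistics (cumulative
distance anchors, colocalisation percentages, expression fractions,
normalised gains, beat rates) under controlled noise, so passing tests
demonstrate that the analysis chain is unbiased and precise under the
model's assumptions: isolated Gaussian-blob puncta, uniform background,
spatially homogeneous fields, Poisson-only noise, ideal sinusoidal
stimulation. They do not establish robustness to what real tissue adds —
clustered ribbons within single hair cells, striolar/extrastriolar
gradients, depth-dependent attenuation, bleed-through, antibody
variability, or pupil-tracking artefacts. Those would need real stacks
and recordings; the module boundaries (detector, metrics, analysers take
standard containers) are designed so real data can be substituted
directly.

## Known limitations

* No biophysical model of excitotoxic swelling, no per-hair-cell synapse
  counts, no type I/II hair-cell distinction, no spectral bleed-through
  or depth attenuation, no deconvolution.
* Eye kinematics are one-channel (horizontal); vertical/torsional
  components and skew deviation are out of scope.
* The crista presets rest on a single published anchor per group; their
  full cumulative curves are model extrapolations.
* The MOR bias definition and the quick-phase detection parameters stand
  in for details published only in cited prior work.
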