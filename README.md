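# vestisyn

Quantification of vestibular primary-synapse deafferentation and repair,
and of its vestibulo-ocular consequences, in the mouse excitotoxic-lesion
model.

## What it does

Transtympanic kainate transiently uncouples inner-ear hair cells from
their primary afferents. Two complementary read-outs track the lesion and
its spontaneous repair:

* **Synaptic pairing.** In 3D confocal stacks immunostained for the
  presynaptic ribbon (CtBP2/RIBEYE) and the postsynaptic scaffold
  (SHANK-1), each presynaptic punctum's distance to its nearest
  postsynaptic punctum is computed from the x, y, z centroid coordinates.
  The fraction of presynaptic puncta with a partner within 1 µm — the
  operational colocalisation criterion for an intact synapse — and the
  full cumulative distance curve C(d) = P(d_NN ≤ d) quantify
  deafferentation per 4.5·10⁻³ mm² observation field; per-field puncta
  counts normalised to the sham mean quantify expression.
* **Vestibulo-ocular function.** From 1 kHz video-oculography: the aVOR
  gain g = |Ê|/|Ĥ| (eye/head slow-phase velocity amplitudes from a
  least-squares sinusoid fit at the stimulus frequency, after 40 Hz
  zero-phase low-pass filtering, differentiation and quick-phase
  exclusion), the otolithic MOR bias (mean slow-phase velocity during
  off-vertical axis rotation at 50°/s), and the spontaneous nystagmus
  rate in beats/min.

The package implements the full analysis chain for both read-outs plus
calibrated synthetic generators — ground-truth puncta fields rendered
into noisy confocal stacks, and simulated eye-movement trials — so the
chain is validated end-to-end: detection error, PSF blur and quick-phase
contamination all lie between the generator and the statistics.

Intended users: inner-ear and vestibular physiology labs quantifying
ribbon-synapse colocalisation or VOR time courses, and method developers
needing a reproducible phantom for 3D two-channel spot detection.

## Worked example

One sham observation field through the whole chain:

```r
library(vestisyn)

preset <- load_field_preset("sham-utricle")
field  <- sample_field(preset, seed = 42)
stack  <- render_field(field, seed = 42)

pre  <- filter_by_mask(detect_puncta(stack, "ctbp2"),  stack)
post <- filter_by_mask(detect_puncta(stack, "shank1"), stack)
prof <- nn_distances(pre, post)

n_puncta(pre)
#> [1] 348
colocalization_fraction(prof, threshold = 1)
#> [1] 38.21839
cumulative_curve(prof, c(1, 2, 3))
#>   distance_um cumulative_pct
#> 1           1       38.21839
#> 2           2       75.28736
#> 3           3       92.24138
```

348 of the 350 generated presynaptic ribbons are recovered; ~38% of them
have a postsynaptic punctum within 1 µm and ~75% within 2 µm — one
field's draw of the healthy utricle profile, whose preset-level values
are 40%/75%. The same chain on the `ttk4h-utricle` preset
collapses the 1 µm fraction to ~15%.

A simulated lesioned aVOR trial, analysed:

```r
baseline <- load_oculo_preset("baseline")
lesioned <- load_oculo_preset("ttk4h")

trb <- preprocess_trace(simulate_avor(baseline, freq = 0.2, duration = 30, seed = 1))
trl <- preprocess_trace(simulate_avor(lesioned, freq = 0.2, duration = 30, seed = 2))
gb <- avor_gain(trb, segment_quick_phases(trb))
gl <- avor_gain(trl, segment_quick_phases(trl))
c(baseline = gb$gain, lesioned = gl$gain, normalised_pct = normalize_gain(gl, gb))
#>       baseline       lesioned normalised_pct
#>      0.5501262      0.1807976     32.8647570
```

The lesioned gain is ~33% of baseline, the published 4 h drop at 0.2 Hz.

See `vignettes/vestibular-synapse-pipeline.Rmd` for the model, the
calibration procedure, parameter defaults and their rationale.

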