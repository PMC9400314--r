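# endotraffic

Quantification of endosomal trafficking in fluorescence microscopy of
T cells.

Within minutes of T-cell-receptor triggering, T cells boost endocytic
uptake and recycling of transferrin and its receptor (TfR) through a
flotillin-dependent Rab5 → Rab11a pathway. Measuring that behaviour from
multi-channel time-lapse imaging takes a family of small, bespoke
procedures — object-based colocalization, an endosome-dispersion
statistic, cargo quantification inside marker-defined compartments, a
fusion-event classification rule for TIRF movies, and a per-timepoint
rank-sum divergence test — plus the deterministic fold-change arithmetic of
the accompanying cytometry and western-blot assays. endotraffic implements
all of them as a tested, reusable R pipeline, together with a
synthetic-data module that generates ground-truth-annotated inputs so
every stage is validated without external data.

## The statistics at its core

* **Object-based colocalization** — a vesicle is double-positive when its
  nearest cross-channel neighbour lies at or within *d* = 320 nm
  (centroid-to-centroid, inclusive). Chance levels come from seeded
  random-point controls inside the cell mask; for uniform points the
  expected control percentage is `100 (1 − (1 − πd²/A)^m)`.
* **Dispersion** — `D = Σᵢ wᵢ‖pᵢ − c‖ / Σᵢ wᵢ` over cell-mask pixels, with
  `c` the intensity-weighted centre of mass: low for compact perinuclear
  endosomes, high for scattered ones. Uniform disk of radius R gives
  `D = 2R/3`.
* **Co-fusion rule** — with `M₀` the footprint maximum of the event's
  initial frame and `M̄` the mean of the per-frame maxima over the last
  three frames, an event carries the traced marker when
  `(M₀ − M̄)/M₀ > 0.10` (strict).
* **Time of divergence** — a two-sided Wilcoxon rank-sum test at each
  timepoint on pooled group data; the divergence point is the first
  timepoint after which *all subsequent* p-values stay at or below α
  (0.05 and 0.01 both reported).
* **Assay arithmetic** — activated/resting MedianFI ratios, recycling
  relative to t = 0, treated/control normalization, minority-referenced
  conjugate percentages with −SEE subtraction, and actin-normalized band
  intensities.

Spot detection (difference-of-Gaussians, robust MAD threshold, sub-pixel
centre-of-mass refinement) and greedy mutual-nearest-neighbour track
linking feed the object-based analyses; all parameters are explicit
`*_params()` objects with documented defaults.

## Worked example

```r
library(endotraffic)

cfg <- synth_image_config(coloc_fraction = 0.5)   # 50% of ch2 spots co-positioned
sim <- generate_cell_image(cfg, seed = 42)

cell  <- segment_cell(sim$stack, channel = 1)
ves_a <- detect_vesicles(sim$stack, channel = 1)
ves_b <- detect_vesicles(sim$stack, channel = 2)
colocalize(ves_b, ves_a, cell)
#> # A tibble: 1 × 6
#>   n_reference n_query percent_double_positive random_mean_percent ...
#> 1          12      12                      50                3.75
```

All 12 spots per channel are recovered and exactly half the channel-2
vesicles sit within 320 nm of a channel-1 vesicle — the imposed fraction —
while matched random points colocalize at only ~3.8%.

```r
mean_dispersion(frame_matrix(sim$stack, 1), cell)[, 1:2]
#>   dispersion_px dispersion_nm
#> 1          25.2         4038.
```

The transferrin signal sits on average 4.0 µm from the cell's centre of
mass. And for a two-group time course whose distributions separate from
the fourth timepoint:

```r
sim2 <- generate_grouped_timeseries(effect_size = 10, shift_start_index = 4,
                                    seed = 5)
time_of_divergence(sim2$series)
#> <divergence_result> A vs B, 8 timepoints
#>   alpha 0.05: divergence from timepoint 4 (t = 30)
#>   alpha 0.01: divergence from timepoint 4 (t = 30)
```

`tidy()` returns the per-timepoint p-value table, `glance()` the
divergence indices, and `autoplot()` draws the p-value series with the
dotted (0.05) and dashed (0.01) reference lines.

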