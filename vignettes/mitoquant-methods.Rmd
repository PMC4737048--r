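---
title: "Methods: mitochondrial morphometry and respirometry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial morphometry and respirometry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

This vignette documents the models, definitions, numerical choices and
limitations behind the package. It is written for a reader who wants to know
exactly what each number means, which decisions were genuinely open, and what
the synthetic benchmarks do and do not demonstrate about real data.

## 1. Morphometry

### Measurement definitions

A field of view carries three channels: a mitochondrial membrane marker, a
diffuse cytoplasm marker and a nuclear counterstain. After per-channel
binarization the recorded parameter vector is:

| parameter | definition |
|---|---|
| `total_edge_length` | exposed pixel edges of the mitochondrial mask: for every foreground pixel, the number of its 4-neighbours that are background or outside the grid |
| `n_mitochondria` | 8-connected components of the mitochondrial mask |
| `avg_perimeter_per_mito` | `total_edge_length / n_mitochondria` |
| `total_network_area`, `total_cytoplasm_area` | foreground pixel counts |
| `fraction_filled` | `total_network_area / total_cytoplasm_area` |
| `n_nuclei` | 8-connected components of the nuclear mask |
| per-cell averages | areas divided by `n_nuclei` |
| `mean_cell_size` | `total_cytoplasm_area / n_nuclei` |

Two of these choices were open and are worth defending. **Connectivity** is
8-connected for objects because mitochondrial filaments are thin and
frequently diagonal: under 4-connectivity a one-pixel-wide diagonal filament
would fragment into its individual pixels, which is an artifact of the
lattice, not of the biology. The **perimeter estimator** stays 4-neighbour
based regardless, counting exposed pixel edges. It is exact in pixel-edge
units, additive over components, and satisfies the conservation identity
`avg_perimeter_per_mito * n_mitochondria = total_edge_length` exactly, which
the tests assert. It overestimates Euclidean length for diagonal boundaries
(a diagonal staircase of edge length `2L` has Euclidean length `L*sqrt(2)`);
since every group is measured with the same estimator, comparisons between
groups are unaffected.

Component labelling is a compiled flood fill; its correctness is established
by exact agreement with a naive queue-based oracle on hundreds of random
masks, not by construction.

### Binarization

The thresholding rule was an open choice; the default is Otsu's method per
channel (256 equal-width bins over the observed range, threshold at the
upper edge of the bin maximizing between-class variance, foreground strictly
above). Otsu is parameter-free and well suited to the strongly bimodal
histograms of fluorescence fields. A constant channel has no foreground. A
`fixed` per-channel override exists for instruments with calibrated
intensities. Tests cross-check the implementation against an independent one
(EBImage), which differs only in reporting the optimal bin's midpoint rather
than its edge.

No minimum-object-size filter is applied by default: nothing in the
measurement model justifies deleting small objects, and doing so would bias
`n_mitochondria` in fragmented morphologies precisely where it matters.

### Cell-size normalization

Mitochondrial content correlates with the inverse of average cell size: a
field that happens to sample smaller cells shows a higher fill fraction for
purely geometric reasons. With `x = 1/mean_cell_size` and `y =
fraction_filled`, each group is fitted by OLS `y = a + b x` and each field
adjusted to the group's median cell size:

`fraction_filled_normalized = y - b (x - x_med)`, `x_med = 1/median(mean_cell_size)`.

This removes the fitted size trend exactly — the sample correlation between
the normalized fill and `x` is zero to numerical precision whenever the
slope is estimable — while leaving the group's prediction at the median cell
size untouched. Exactly linear input collapses onto that single predicted
value. If every field in a group has the same cell size the slope is
undefined and the records pass through unchanged (with a message). The
average perimeter per mitochondrion is deliberately not adjusted: it shows
no cell-size correlation, and adjusting it would inject regression noise
into the primary morphology endpoint. The fit is per experimental group;
pooling groups would let a group difference in cell size masquerade as a
content difference.

### Outlier rejection and ordering

A field is discarded when any recorded parameter lies more than `k = 2`
sample standard deviations from its group mean — a single, non-iterated
pass, so the result cannot depend on the order in which records are
examined, and a parameter with zero spread excludes nobody. With the group
sizes in play (n = 9 fields) a single gross outlier sits at most
`(n-1)/sqrt(n) ≈ 2.67` SD out, so the rule has teeth but cannot discard from
very small groups (for n ≤ 5 the maximum attainable z is below 2 — a known
property of the rule, not a bug). The filter runs **before** the
normalization fit so that outlying fields cannot steer the regression;
summaries (mean ± SEM, SEM = SD/√n) are computed over retained records only.

## 2. Synthetic fields

The generator provides ground truth for every morphometric quantity, with
one scalar — `fragmentation` ∈ [0, 1] — sweeping the morphology from fused
to granular, mirroring the fusion/fission contrast between experimental
groups.

*Geometry.* Nuclei sit on a jittered near-square grid; each cell's cytoplasm
is the disk of `cytoplasm_radius_px` around its nucleus clipped to the field
and to the Voronoi territory of the nuclei, so cells abut without
overlapping and every field has a countable, known number of nuclei.
Edge-of-field clipping makes `mean_cell_size` vary across seeds, which is
what gives the normalization regression something to fit.

*Mitochondria.* Each cell grows filaments as correlated random walks
(persistent direction with Gaussian turning noise) from perinuclear anchors,
bouncing back toward the nucleus at the cytoplasm boundary; skeletons are
dilated to `filament_width_px`. Fragmentation removes evenly spaced interior
stretches of each walk, the removed gap being wider than the dilation so
granules cannot re-fuse. The break count per filament is stochastically
rounded so its expectation is continuous in `fragmentation`; without this
the dial is quantized to whole breaks per filament and intermediate
contrasts are unreachable. Truth statistics are computed on the final masks
with the same component/edge definitions as the measurement module, so
"measure the truth masks" reproduces the ground truth exactly, by
construction — that identity is a consistency check, not a validation of
segmentation.

*Rendering.* Channels are `background + foreground * mask`, blurred by a
Gaussian point-spread function and corrupted by additive Gaussian noise.
With blur and noise off, thresholding the mitochondrial channel at the
background level reproduces the truth mask exactly, giving a noiseless
round-trip anchor for the whole chain.

*Default conditions.* 256×256 px fields of 9 cells; nucleus/cytoplasm radii
7/34 px; 5 filaments per cell, 45 steps long, dilated to 3.5 px; PSF σ
0.8 px; foreground 100 over background 10 with noise SD 5. At a nominal
0.14 µm/px these are ~0.5 µm-wide mitochondria imaged near the diffraction
limit at a signal-to-noise ratio of 20 — ordinary confocal conditions.
Image dimensions and optics were free parameters (no magnification or pixel
size is specified for the original acquisitions); these values were fixed
once when the renderer was designed. Under these conditions segmentation
recovers component counts and edge length with median relative errors of
about 5–7 % and the fill fraction to better than ±0.01 absolute — the
residual error is the irreducible cost of blur and noise at a
parameter-free threshold, and it is what the recovery acceptance check
bounds (≤ 10 % median, ±0.02).

*What the generator does not emulate:* uneven illumination, photobleaching,
out-of-focus light and z-projection artifacts, marker-specific background
(e.g. cytoplasmic staining gradients), touching cells of heterogeneous
sizes, and optical crowding in perinuclear regions. Passing the recovery
benchmarks therefore shows the measurement chain is correct and robust to
blur and noise at realistic levels; it does not certify performance on
pathological acquisitions.

## 3. Respirometry

### Flux and units

The instrument dialect is flux in pmol O₂ s⁻¹ per 10⁶ cells. For
concentration-dialect inputs, flux is the negative central-difference
derivative of [O₂] (nmol/mL), boxcar-smoothed (default 10 s), scaled by
`chamber_volume_ml * 1000 / cell_count_millions`. The synthetic generator
integrates its sampled flux with the trapezoid rule under the same
convention, so the two dialects are mutually consistent by construction.
Sampling must be uniform to within 10 % jitter; the boxcar and the
difference scheme both preserve constants exactly, so a steady state passes
through the transform unchanged.

### Plateau detection

The protocol defines a state as "a consistent rate for three minutes or
longer"; only the 3-minute duration is prescribed, so the consistency
tolerances are conventions of this implementation, chosen to be strict
enough to reject ramps and generous enough to tolerate instrument noise:
fitted slope ≤ 1 %/min of the interval mean (`slope_tol = 0.01`) and CV ≤
5 % (`cv_tol = 0.05`), both exposed as arguments.

Detection proceeds in three steps. (1) Candidate samples are flagged stable
when the local trend of the boxcar-smoothed flux (central difference across
60 s) is below a deliberately generous multiple (4×) of the slope
tolerance — a strict per-sample flag would flicker at realistic noise
levels and shred true plateaus; unstable gaps shorter than 20 s inside a
run are closed for the same reason. (2) Run edges are trimmed while the
smoothed value deviates from the run median by more than the slope
tolerance, which removes transition bleed-in. (3) Each surviving run of
≥ 180 s is verified against the strict slope and CV tolerances computed on
the raw (unsmoothed) flux, and its mean, OLS slope and CV are reported.
Plateau means therefore come from raw data; smoothing only ever decides
membership.

One further rule matters: a plateau may not straddle a substrate addition.
Additions are known interventions, and some produce rate changes too small
for any slope criterion to notice — the intact-membrane cytochrome-c
response of a few percent is the canonical case, where the state 3 window
and the cytochrome-c window would otherwise merge into one "plateau"
spanning the addition. `analyze_trace()` passes the event times to
`detect_plateaus(split_at =)`, mirroring how oxygraph software anchors
analysis to titration marks.

### State assignment and RCR

Each addition opens a window ending at the next addition; a state's rate is
the **last** qualifying plateau wholly inside its window, operationalizing
"after respiration rates stabilized" (later = more stabilized; duration
ties break toward the later segment). The uncoupled rate is the **maximum**
plateau mean across FCCP steps — the titration proceeds "until maximal
uncoupling", and this makes the estimate robust to an overdosed final step.
Whether the original analysis used the maximal or the final step is not
stated; the maximum is the reading consistent with the stated intent.

RCR = state 3 PMGS / state 4 PMGS, computed per run. Cohort RCR is the mean
of per-run ratios, never the ratio of group means: the two differ whenever
rates covary across runs (for group means 187.82/54.88 the ratio is 3.42
while a cohort's mean of ratios can simultaneously be 3.35), and only the
per-run convention is an average of a per-sample physiological quantity.
The cytochrome-c check compares the post-addition rate to the preceding
state 3 (PMGS) rate; the 10 % tolerance is a convention (configurable) —
the underlying report is qualitative ("no significant increase" = intact
membranes). The generator inserts the cytochrome-c window after state 3
PMGS with rate `S3_PMGS * (1 + cytc_fractional_increase)`, so both the
intact (+3 %) and damaged (+30 %) branches are exercised.

*Default trace conditions.* A GK-like plan (30/154/241/53 pmol s⁻¹ 10⁻⁶
cells⁻¹, FCCP steps 300/375/350), 300 s states, 20 s ramps, 1 Hz sampling,
0.75×10⁶ cells in 2 mL, O₂ start 400 nmol/mL, absolute noise SD 1. A
`noise_rel` option provides noise proportional to the local rate (2 % of
level is the benchmark condition). Note the interaction between `cv_tol`
and absolute noise on low states: at rate 18 with noise SD 1 the CV is
5.6 % and the state 2 plateau is correctly — but perhaps surprisingly —
rejected; proportional noise or a higher `cv_tol` is the right dialect for
such runs.

## 4. Statistics

Two-tailed pooled-variance Student's t (the named test; Welch behind
`var_equal = FALSE`) and one-way ANOVA, with p-values from the closed forms

- `P(|T| > t) = I_{df/(df+t²)}(df/2, 1/2)`,
- `P(F > f) = I_{df2/(df2+df1 f)}(df2/2, df1/2)`,

where `I` is the regularized incomplete beta function (`stats::pbeta`).
Tests verify both against direct numerical integration of the densities
(1e−8) and the algebraic identity `F = t²` for two groups (1e−10), and
simulation confirms both tests hold their nominal 5 % type-I rate. There is
no multiple-testing correction, matching the reporting convention being
reproduced (per-comparison p at α = 0.05); fold changes divide by the
reference-group mean and are scale-invariant, so they change no p-value.
Error bars are SEM throughout.

`build_report()` assembles per-parameter group mean ± SEM tables and the
requested comparisons (t for two groups, ANOVA otherwise) with significance
markers, erroring on unmatched group labels.

## 5. Problem sizes and determinism

Every stochastic component is seeded (`withr::with_seed`), and generators
are bit-reproducible for a given spec. The validation suite uses: 200
random 16×16 masks for oracle equivalence; 50 default fields for the truth
round-trip; 30 noisy default fields for recovery; 10 seeds per level for
fragmentation monotonicity; 20 noisy traces for respirometry recovery; 5000
null replicates for type-I calibration; and 10 repetitions of the
9-vs-9-field two-group contrast (fragmentation 0.3 vs 0.5, a generator-true
perimeter ratio of ≈ 1.5). These sizes give comfortable Monte-Carlo margins
for the properties asserted while keeping the full suite around half a
minute on a laptop-class core.

## 6. Known limitations

- Morphometry is strictly 2D; no deconvolution, z-stacks, or live-cell
  tracking. Perimeters are in pixel-edge units and comparable only within a
  fixed estimator and magnification.
- Otsu assumes a bimodal histogram; a field that is nearly all background
  or all foreground can threshold poorly. The fixed-threshold override is
  the escape hatch.
- Plateau detection assumes near-uniform sampling and approximately
  piecewise-steady traces; oscillating or continuously drifting signals
  yield few or no qualifying plateaus (by design — those runs should be
  inspected, not averaged).
- No instrument background / oxygen back-diffusion correction is applied;
  rates are taken as delivered (or as derived from concentration).
- The outlier rule is single-pass by design and cannot reject anything in
  groups of five or fewer fields.
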