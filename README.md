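# mitoquant

Quantitative analysis of mitochondrial biology in cultured vascular smooth
muscle cells (SMCs), as used to compare diabetic (Goto-Kakizaki) and control
(Wistar) rat vasculature under nutrient stress. The package implements two
bespoke analysis pipelines plus the synthetic data needed to validate them:

1. **Fluorescence morphometry.** Multichannel fields (mitochondrial marker
   such as TOM20, diffuse cytoplasm marker, nuclear counterstain) are
   binarized per channel (Otsu by default) and measured. The two headline
   statistics are

   - *average perimeter per mitochondrion*
     `P̄ = E / N`, where `E` is the total exposed pixel-edge length of the
     mitochondrial mask and `N` the number of 8-connected components —
     higher values indicate a more fused network;
   - *fraction of cytoplasm filled*
     `F = A_mito / A_cyto` — a mitochondrial content proxy.

   Because content correlates with inverse average cell size
   (`x = 1 / (A_cyto / n_nuclei)`), `F` is adjusted to the group's median
   cell size through an OLS fit `F = a + b·x`:
   `F_norm = F − b·(x − x_med)`. Fields lying more than 2 sample SD from
   their group mean in **any** recorded parameter are discarded in a single
   pass, and groups are reported as mean ± SEM over the retained fields.

2. **Permeabilized-cell respirometry.** Oxygraph runs (2 mL chamber,
   0.5–1×10⁶ cells) follow the substrate-uncoupler titration
   PMG → ADP → succinate (+ cytochrome c) → oligomycin → stepwise FCCP.
   Flux is derived from the O₂ concentration when needed
   (`J = −d[O₂]/dt · V · 1000 / cells`), stable plateaus of ≥ 3 min are
   detected (slope ≤ 1 %/min of the level, CV ≤ 5 %), states are assigned
   from the addition sequence (last qualifying plateau per window; the
   uncoupled rate is the maximum across FCCP steps), rates are normalized to
   the recounted cell number, and the respiratory control ratio
   `RCR = S3_PMGS / S4_PMGS` is computed **per run** before any averaging
   (the ratio of group means is a different, biased quantity). A
   cytochrome-c rate increase above 10 % of state 3 flags outer-membrane
   damage.

Group comparisons use two-tailed pooled-variance Student's t-tests or
one-way ANOVA (α = 0.05, implemented from the closed form through the
regularized incomplete beta function) and fold-change-from-control
summaries.

Seeded generators (`image_spec()`/`generate_field()` and
`trace_spec()`/`generate_trace()`) produce fields and traces with exact
ground truth, so every stage of both pipelines is testable without any
external data.

## Worked example

```r
library(mitoquant)

# two groups of nine fields: a fused-like and a more fragmented morphology
fused   <- generate_group(image_spec(fragmentation = 0.3), 9, seed = 11)
control <- generate_group(image_spec(fragmentation = 0.5), 9, seed = 12)
records <- rbind(measure_group(fused, "fused"),
                 measure_group(control, "control"))
res <- morphometry_pipeline(records)   # outlier filter -> normalization -> summary
subset(res$summary$stats,
       parameter %in% c("avg_perimeter_per_mito", "fraction_filled_normalized"))
#>  group_label                  parameter n       mean          sem
#>        fused     avg_perimeter_per_mito 9 87.7819725 3.5749772577
#>        fused fraction_filled_normalized 9  0.1751698 0.0010345156
#>      control     avg_perimeter_per_mito 9 59.3508497 0.8203760639
#>      control fraction_filled_normalized 9  0.1571483 0.0009379777

students_t_test(
  res$records$avg_perimeter_per_mito[res$records$group_label == "fused"],
  res$records$avg_perimeter_per_mito[res$records$group_label == "control"])
#> Student t (two-tailed, pooled): statistic = 7.7513, df = 16, p = 8.333e-07 (significant at 0.05)

# one oxygraph run with 2% proportional noise
run <- generate_trace(trace_spec(noise_sd = 0, noise_rel = 0.02, seed = 4))
analyze_trace(run$trace)
#> Respiration state rates [pmol/s/10^6 cells]
#>   S2 (PMG)      29.99524
#>   S3 (PMG)      153.8551
#>   S3 (PMG/S)    240.7626
#>   S4 (PMG/S)    53.00671
#>   Uncoupled     374.8546
#>   Cytochrome c  248.1536
#>   RCR           4.542116
#>   membranes intact: TRUE
```

The fused group shows the larger perimeter per mitochondrion, the t-test
detects the morphology contrast, and the respirometry run recovers its
planned state rates (30 / 154 / 241 / 53, uncoupled 375) to a fraction of a
percent, with an RCR of ≈ 4.55 and an intact cytochrome-c check.

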