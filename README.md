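# slidenorm

Slide-to-slide normalization and evaluation for multiplexed immunofluorescence
(MxIF) single-cell intensity data.

Multiplexed imaging quantifies dozens of protein markers per segmented cell
across many tissue slides, but staining, optics and batch handling leave each
physical slide with its own technical signature: per-cell intensities are not
comparable across slides, thresholds drift, and downstream phenotyping picks up
slide identity instead of biology. `slidenorm` is for analysts working with
cell-level quantification tables (one row per segmented cell, one non-negative
integer intensity column per marker channel) who need that slide effect
measured and removed before inference.

## What it implements

Three intensity-scale transformations, applied per slide *i* and channel *c*
with slide mean μ<sub>ic</sub>:

| Transformation | Formula |
|---|---|
| log10 | log₁₀(y + 1) |
| Mean division | y / μ<sub>ic</sub> |
| Mean division log10 | log₁₀(y / μ<sub>ic</sub> + ½) |

crossed with two normalization algorithms:

* **ComBat-style empirical Bayes** — the location-scale model
  Y<sub>ic</sub>(u) = α<sub>c</sub> + γ<sub>ic</sub> + δ<sub>ic</sub>ε<sub>ic</sub>(u)
  with slide mean effects γ<sub>ic</sub> ~ N(γ̄<sub>c</sub>, τ̄²<sub>c</sub>) and
  variance effects δ²<sub>ic</sub> ~ IG(ω̄<sub>c</sub>, β̄<sub>c</sub>).
  Hyperparameters come from method-of-moments matching; per-slide effects are
  shrunk by an alternating empirical-Bayes fixed-point iteration and removed:
  Y* = (σ̂<sub>c</sub>/δ̂*<sub>ic</sub>)(Z − γ*<sub>ic</sub>) + α̂<sub>c</sub>.
* **Functional-data density registration** — each slide's intensity histogram
  is smoothed with a 21-df cubic B-spline basis, a strictly monotone warping
  function φ<sub>ic</sub> (2-df exponential-integral family, endpoints fixed)
  is fitted so the slide density aligns with the cross-slide average density,
  and cell intensities are transported through the warp.

plus the evaluation framework used to compare them: the k-sample
Anderson–Darling alignment statistic (midrank tie-corrected), Otsu threshold
discordance between slide-level and global thresholds, marker-positive
accuracy against manual labels, the slide-level variance proportion from a
REML random-intercept model, and UMAP/k-means adjusted Rand indices for slide
and tissue labels. A synthetic-data generator with known injected slide
effects makes every method and metric testable without external data.

## Worked example

```r
library(slidenorm)

sim <- simulate_table(sim_config(n_slides = 8, cells_per_slide = 1000, seed = 42))
raw_report <- evaluate_method(sim$table, sim$table, method = "None; None", seed = 1)

md <- apply_transform(sim$table, "mean_divide")
md_report <- evaluate_method(sim$table, md, method = "Mean division; None", seed = 1)

dplyr::bind_rows(glance(raw_report), glance(md_report))
```

```
               method mean_ad_stat mean_otsu_discordance ari_slide mean_variance_prop ari_tissue mean_accuracy
1          None; None       469.38                0.1570  0.126850           1.64e-01      0.792         0.816
2 Mean division; None         3.05                0.0144 -0.000118           1.52e-33      0.792         0.903
```

Reading the rows: on the raw data the slides are visibly different
distributions (Anderson–Darling statistic 469), 16% of cells flip their
positive/negative call between slide-level and global Otsu thresholds, 16% of
intensity variance sits at the slide level, and an embedding clusters partly
by slide (ARI 0.13). After dividing each cell by its slide-channel mean the
slides are nearly indistinguishable (AD 3.1, discordance 1.4%, slide variance
and slide ARI at zero) while biological structure is intact: the tissue-class
ARI is unchanged (0.79) and marker-positive accuracy against the manual labels
improves from 0.82 to 0.90.

`combat_normalize()` and `register_normalize()` slot into the same pipeline
between `apply_transform()` and `evaluate_method()`; `tidy()`/`glance()` pull
per-slide effects and convergence state out of a ComBat fit, and
`plot_slide_densities()` / `autoplot()` draw the standard diagnostics. A
command-line wrapper (`inst/cli/slidenorm.R`) exposes
`simulate` / `normalize` / `evaluate` subcommands over the same functions.

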