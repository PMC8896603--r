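---
title: "Normalizing slide effects in multiplexed immunofluorescence: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing slide effects in multiplexed immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidenorm)
```

## The problem

A multiplexed immunofluorescence experiment images many tissue slides, each
contributing thousands of segmented cells with one median-pixel intensity per
marker channel. Everything that happened to a physical slide — staining
batch, antibody lot, exposure, optics — is shared by all of its cells, so the
slide acts as a batch: per-cell intensities from different slides live on
subtly different scales. Left uncorrected, this inflates thresholding
disagreement across slides, leaks slide identity into embeddings and
clusters, and puts a substantial share of intensity variance at the slide
level where biology cannot explain it.

`slidenorm` treats the cell-quantification table as the unit of analysis: one
row per cell, a slide identifier, non-negative integer intensities (zeros are
data — a zero is a measured low intensity, not a missing value — and are kept
through every step), and optional tissue/marker labels used only for
evaluation.

## Scale transformations

Three strictly monotone rescalings are supported, each applied per slide and
channel with the slide mean $\mu_{ic}$ always computed from the *raw* values
and cached in the returned transform spec so the identical mapping can be
reapplied and audited:

* $\log_{10}(y + 1)$ — the offset of 1 keeps integer zeros finite;
* $y / \mu_{ic}$ — forces every slide mean to exactly 1, which by itself
  removes the slide-level mean effect;
* $\log_{10}(y/\mu_{ic} + 1/2)$ — compresses the right tail while centering
  the scale so that cells above half the slide mean are positive and below
  are negative; the lower bound is $\log_{10}(1/2)$ at $y = 0$.

A slide whose channel is all zeros has $\mu_{ic} = 0$ and no usable signal on
that channel; the mean-division transforms refuse it with a named error
rather than emitting NaNs.

## The empirical-Bayes (ComBat-style) model

For channel $c$ the location-scale model is
$Y_{ic}(u) = \alpha_c + \gamma_{ic} + \delta_{ic}\,\varepsilon_{ic}(u)$ with
$\varepsilon \sim N(0,1)$, slide mean effects
$\gamma_{ic} \sim N(\bar\gamma_c, \bar\tau^2_c)$ and variance effects
$\delta^2_{ic} \sim IG(\bar\omega_c, \bar\beta_c)$. Estimation proceeds by:

1. **Standardization.** $\hat\alpha_c$ is the cell-weighted grand mean (not
   the unweighted mean of slide means — slides contribute in proportion to
   their cells); $\hat\sigma^2_c$ is the mean squared residual after removing
   slide means; $Z = (Y - \hat\alpha_c)/\hat\sigma_c$. We divide by the
   standard deviation $\hat\sigma_c$, which is what makes
   $Z \mid i \sim N(\gamma_{ic}, \delta^2_{ic})$ dimensionally coherent, and
   multiply back by it in the adjustment. The naive per-slide effects
   $\hat\gamma_{ic}$, $\hat\delta^2_{ic}$ are the per-slide means and sample
   variances of $Z$.
2. **Method-of-moments hyperparameters.** $\bar\gamma_c$, $\bar\tau^2_c$ are
   the across-slide mean and variance of $\hat\gamma_{ic}$; matching the
   first two inverse-gamma moments to the mean $m$ and variance $v$ of
   $\hat\delta^2_{ic}$ gives $\bar\omega_c = m^2/v + 2$,
   $\bar\beta_c = m(\bar\omega_c - 1)$. When $v = 0$ the moments are
   undefined; the prior is flagged non-informative and set flat
   ($\bar\omega_c = 1$, $\bar\beta_c = 0$), so no variance pooling occurs.
3. **EB fixed point.** Alternating posterior-mean updates
   $$\delta^{2*}_{ic} = \frac{\bar\beta_c + \tfrac12\sum_u (Z_{ic}(u) - \gamma^*_{ic})^2}{U_{ic}/2 + \bar\omega_c - 1},
   \qquad
   \gamma^*_{ic} = \frac{U_{ic}\bar\tau^2_c\,\hat\gamma_{ic} + \delta^{2*}_{ic}\,\bar\gamma_c}{U_{ic}\bar\tau^2_c + \delta^{2*}_{ic}}$$
   run from $\gamma^* = \hat\gamma$, $\delta^{2*} = \hat\delta^2$ until the
   largest parameter change is below `tol` (default $10^{-5}$, at most 100
   iterations — standard practice for this family of solvers). An outer loop
   re-estimates the hyperparameters from the current shrunken effects and
   repeats until the whole system is stationary.
4. **Adjustment.**
   $Y^* = (\hat\sigma_c/\hat\delta^*_{ic})(Z - \gamma^*_{ic}) + \hat\alpha_c$.
   Negative adjusted intensities are legitimate under the Gaussian model and
   are kept by default; `clip_nonnegative = TRUE` clamps at zero for users
   who need raw-scale semantics.

Two properties of this scheme are worth knowing. First, shrinkage is partial:
the adjusted slide means equal
$\hat\alpha_c + \hat\sigma_c(\hat\gamma_{ic}-\gamma^*_{ic})/\hat\delta^*_{ic}$
exactly, so with very few cells per slide a visible residual remains; with
thousands of cells per slide ($U_{ic}\bar\tau^2_c \gg \delta^{2*}$) the
residual is negligible and slide-level variance is removed to well past three
decimals. Second, re-estimating the variance prior from shrunken effects can
legitimately converge to complete variance pooling (all $\delta^{2*}$ equal);
the fit stops at that fixed point rather than flipping to the flat prior,
which is reserved for degenerate inputs. This is the mechanism by which the
EB route removes *all* slide variability — including any that is
biologically real, which is its known cost.

## Density registration

The second normalizer is distribution-level. Per channel, each slide's
histogram (128 equal-width bins) is projected by least squares onto a
21-function cubic B-spline basis with 17 equally spaced interior knots on the
pooled range, clamped at zero (the unconstrained fit can dip negative — the
clamp is why heavily right-skewed channels, with most mass piled near zero,
are smoothed less faithfully) and renormalized to unit integral on a 512-point
grid. The grid resolution is deliberately far above the 21 basis functions so
quadrature error is negligible relative to smoothing error. The registration
target is the pointwise average of the slide densities, computed once from
the unwarped fits (single-pass registration).

Each slide's warp comes from the 2-degree-of-freedom family
$$\phi(x) = a + (b-a)\,\frac{W(x)}{W(b)}, \qquad
W(x) = \int_a^x \exp\{\beta_1 h_1(y) + \beta_2 h_2(y)\}\,dy,$$
with $h_1, h_2$ the two hat functions of a linear B-spline basis with no
interior knots. The positive integrand makes $\phi$ strictly increasing and
the normalization pins $\phi(a) = a$, $\phi(b) = b$, so the endpoint
constraints absorb the two integration constants and the printed lower limit
of the integral is immaterial. $(\beta_1, \beta_2)$ minimize the trapezoid
quadrature of $\int (f_{ic}(\phi(y)) - \bar f(y))^2\,dy$, solved with
L-BFGS-B from the identity start $(0,0)$ under box bounds $[-5, 5]$ — the
objective is smooth in two parameters, so a local method from the identity is
reliable, and a failed optimization falls back to the identity warp with a
warning. Everything is deterministic: repeated runs are byte-identical.

**Transport direction.** The objective aligns $f_{ic} \circ \phi$ with the
target, so for a slide shifted right of the average by $s$ the fitted warp is
$\phi(y) \approx y + s$ — and observations must therefore travel through
$\phi^{-1}$ (subtracting $s$) for their distribution to land on the target.
Applying $\phi$ itself moves the slide *away* from the average. `slidenorm`
consequently transports intensities through the numerically inverted warp by
default and exposes `direction = "as_fitted"` for the literal composition
$Y^* = \phi(Y)$; the default is the direction that actually aligns densities,
which is the method's purpose and is what the before/after Anderson–Darling
diagnostic verifies on every run.

## The evaluation framework

* **Density alignment** — the Scholz–Stephens k-sample Anderson–Darling
  statistic across slides, in its midrank form because median-pixel
  intensities are integers with heavy ties. The standardized variant
  $(A^2_{akN} - (k-1))/\sigma_N$ is the default (the raw variant is exposed);
  its magnitude grows with the number of cells, so values are comparable
  across methods on the same cells, not across datasets.
* **Otsu threshold discordance** — per channel, the mean over slides of the
  fraction of cells whose positive/negative call flips between the
  slide-level and global (all slides pooled) Otsu thresholds; 256 equal-width
  bins, the imaging convention. Lower is better.
* **Marker-positive accuracy** — agreement of global-threshold calls with
  manual labels, where available.
* **Variance proportion** — the intraclass correlation
  $\sigma^2_{slide}/(\sigma^2_{slide} + \sigma^2_{res})$ from a REML
  random-intercept fit (lme4); boundary fits report 0. A one-way ANOVA
  method-of-moments estimator is the fallback if the mixed model fails.
* **Embedding ARIs** — UMAP (15 neighbors, min-dist 0.1, Euclidean, fixed
  seed, single-threaded for determinism) on a slide-stratified 10% subsample
  of four architecture markers, k-means with k equal to the number of
  distinct labels, and the Hubert–Arabie adjusted Rand index. Stratifying by
  slide keeps small slides represented. With slide identifiers as labels,
  small is good (slide effects gone); with tissue classes, large is good
  (signal kept). The assumption that k-means on slide labels uses k = number
  of slides follows the same distinct-label-count rule.

All metrics except accuracy and tissue ARI are oriented so that smaller means
better normalization.

## The synthetic generator

`simulate_table()` draws the conditions the package is validated under: 20
slides × 2000 cells by default, six channels (four tissue-architecture
markers that differ by a latent epithelium/stroma class, two immune markers
with a 30% positive mixture), log-normal intensities (background log-mean 3,
expressing log-mean 5, log-SD 0.4–0.5) rounded to integers, slide mean
effects $\gamma_{ic} \sim N(0, \tau^2)$ with $\tau = 0.5$ added on the log
scale, and variance effects $\delta^2_{ic} \sim IG(50, 49)$ (prior mean 1,
mild spread). Applying slide effects on the log scale gives both the
mean-division and the log-family transforms genuine signal to remove.
Emitted tissue and manual-positive labels are flipped with probability 0.05
by default, mimicking their bronze-standard character; the returned truth
object keeps the clean values. Everything derives from one seed.

What the generator does *not* emulate: spatial structure and cell–cell
dependence within images, image-level nesting below the slide (the model
treats slide as the only batch level), marker–marker correlation beyond the
shared class structure, and the long right tails of real segmentation
artifacts. Tests passing on this generator therefore demonstrate correctness
of the algorithms and calibration of the metrics under the stated model, not
performance on any particular real dataset.

## Numerical and degenerate-input policy

Constant channels and single-slide tables are refused with typed errors;
all-zero slide-channels are flagged at validation and refused by the
mean-division transforms; a degenerate per-slide Otsu threshold scores that
slide against the global calls with a warning; single-cell slides take a
variance placeholder of 1 on the standardized scale. Otsu ties break toward
the smallest edge. Warp fitting failures return the identity warp rather
than failing the channel. Out-of-domain values in `apply_warp()` are clamped
to the endpoints, counted and warned about.

Problem sizes in the shipped tests were chosen to exercise each property at
the smallest scale where it is statistically identifiable — e.g. oracle
comparisons run on instances of at most a few thousand cells, and
intraclass-correlation recovery averages replicate simulations because a
single 20-slide draw carries a slide-sampling standard error of about 0.08.

## Known limitations

* The EB route assumes Gaussian residuals on the chosen scale; on bimodal or
  strongly right-skewed channels it over-normalizes, removing slide-level
  differences that may include biology.
* Registration relies on the B-spline smoothness of the density; heavily
  skewed channels with near-degenerate support are aligned less well, and
  the zero-clamp can distort mass near the boundary.
* The warp family has two degrees of freedom: it can shift and tilt a
  density but not fix multi-modal misalignment with independent mode
  movements.
* Standardized AD magnitudes are not comparable across implementations or
  sample sizes; use them to rank methods on the same cells.
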