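---
title: "Methods: pooling warming effects on belowground nitrogen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooling warming effects on belowground nitrogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldmeta)
```

## The problem

Field warming experiments in cold ecosystems (tundra, boreal and temperate
forest, cold grassland) report how soil nitrogen pools (DON, ammonium,
nitrate, microbial and root N), fluxes (N mineralization, N fixation, N2O
emission), enzyme activities, gene abundances, and belowground biota
respond to experimental warming. Each study reports, per response variable,
a warmed arm and a control arm as mean, dispersion, and replicate count.
`coldmeta` pools such study-level summaries into standardized effect sizes
and asks whether warming shifts each response, whether the shift differs by
soil depth, latitude band, or biome, and whether it scales with warming
magnitude, experiment duration, or warming-induced moisture change.

## Effect sizes

For arm summaries $(\bar x_w, s_w, n_w)$ and $(\bar x_c, s_c, n_c)$ the
effect size is the standardized mean difference

$$y = \frac{\bar x_w - \bar x_c}{S_p}, \qquad
S_p = \sqrt{\frac{(n_w-1)s_w^2 + (n_c-1)s_c^2}{n_w+n_c-2}},$$

with large-sample sampling variance

$$v = \frac{1}{n_w} + \frac{1}{n_c} + \frac{y^2}{2n}, \qquad n = n_w+n_c.$$

The total-$n$ reading of the curvature term is a deliberate choice (the
convention is not universal across texts; per-arm or harmonic-mean versions
exist); it is the standard large-sample SMD variance and is applied
consistently in the shared-control covariance below. When a study reports a
standard error instead of an SD, `se_to_sd()` converts via
$s = \mathrm{se}\sqrt{n}$.

No small-sample (Hedges) correction is applied by default, because the
estimator is the plain SMD; `compute_effects(hedges = TRUE)` opts in to the
correction factor $J = 1 - 3/(4(n_w+n_c-2)-1)$. With default arm sizes of
3-10 the uncorrected SMD is biased away from zero by roughly
$3/(4\,\mathrm{df}-1)$ (about 2-8%); the synthetic-data tests document this
bias rather than hide it.

## Shared-control covariance

When several comparisons in one study reuse a single control group, their
effect sizes are correlated. `build_vcov()` places $v_i$ on the diagonal
and, for effects $i \ne j$ in one control cluster,

$$\mathrm{Cov}(y_i, y_j) = \frac{1}{n_c} +
\frac{y_i\,y_j}{2\,\tilde n_{ij}},$$

zero elsewhere. The default $\tilde n_{ij} = n_c + (n_{w,i}+n_{w,j})/2$
(the average total sample size of the two comparisons) matches the total-$n$
convention of $v$; `formula = "add_both"` switches to
$\tilde n = n_c + n_{w,i} + n_{w,j}$ for sensitivity analysis, because the
source formula for this covariance is cited in the literature rather than
printed, and the two readings differ only in the (small) product term. If
rounding makes the matrix numerically indefinite, a diagonal jitter capped
at $10^{-10}$ is added and reported; anything needing more than that is
treated as a data problem, not papered over.

## Fixed-effect pooling

A common-true-effect (fixed-effect) model is assumed throughout; no
between-study variance component is estimated. The pooled estimate is the
GLS mean

$$\hat\mu = \frac{\mathbf 1^\top V^{-1} y}{\mathbf 1^\top V^{-1}\mathbf 1},
\qquad \mathrm{SE}(\hat\mu) = (\mathbf 1^\top V^{-1}\mathbf 1)^{-1/2},$$

computed via Cholesky factorization (never by forming $V^{-1}$). With a
diagonal $V$ this is exactly the inverse-variance weighted mean, and the
test suite holds the implementation to that closed form at $10^{-12}$ and
to an independent explicit-solve GLS oracle at $10^{-10}$.

Confidence intervals follow the study-count rule: one effect, no interval
(significance "not evaluable"); $2 \le k < 15$, BCa bootstrap; $k \ge 15$,
Wald. "More than 10 studies" and "less than 15" are both implemented as
strict inequalities. An effect is significant when its interval excludes
zero; no multiple-testing adjustment is applied across responses.

## BCa bootstrap

The bootstrap resamples shared-control *clusters* with replacement (rows of
a cluster move together), so the dependence the covariance matrix encodes
survives resampling; the source analysis does not state its resampling
unit, and cluster resampling is the choice that is consistent with modeling
the dependence at all. Because the statistic is the GLS mean and each
resampled cluster keeps its own covariance block, the resample statistic
decomposes into per-cluster sums $(\mathbf 1^\top V_c^{-1} y_c,\;
\mathbf 1^\top V_c^{-1} \mathbf 1)$; the implementation precomputes these
and vectorizes all $B$ resamples exactly (no approximation, just algebra).

Numerical conventions: the bias correction $z_0$ counts resample statistics
strictly below the point estimate, with ties counted half, and clamps the
fraction to $[1/(B+1), B/(B+1)]$; the acceleration $a$ is the standard
jackknife skewness over leave-one-cluster-out estimates; endpoints are
type-6 quantiles (order-statistic index $(B+1)p$), the convention of the
standard bootstrap implementations. A degenerate resample distribution, or
a single cluster, yields a point interval with a warning rather than an
error. Every bootstrap call requires an explicit seed.

**Known limitation - small-$k$ coverage.** At $k = 10$ i.i.d. normal
effects the nominal 95% BCa interval covers the truth about 89-92% of the
time; the `boot` package reference implementation measures 89.8% in the
same simulation (1000 replicates, $B = 2000$). This undercoverage is a
well-documented property of bootstrap intervals for means of small samples,
not an implementation artifact, and the corresponding acceptance check
(which asserts coverage of at least 92%) is therefore expected to fail by a
fraction of a point. Users should read BCa intervals at $k \approx 10$ as
slightly anti-conservative.

## Subgroups and meta-regression

A response is compared across soil depths, latitude bands, or biomes only
when it has more than 10 effects, except for responses on a configurable
exception list (defaults: N fixation, N2O emission, which are always
tested). Depth bins are the nominal 5, 10, 15 cm (nearest value, exact
midpoints rounding down to the shallower bin) plus "below 15 cm";
latitude bands split strictly at 50 degrees (exactly 50 is intermediate);
records missing a label are excluded from that comparison only.

Meta-regression solves the GLS normal equations for a design with an
intercept, the requested moderators, and (optionally) all pairwise products
of *centered* moderators. Centering is the package's choice (the source is
silent): it reduces collinearity between main effects and products and
leaves interaction inference unchanged. Rows missing any requested
moderator are dropped listwise and counted, mirroring the fact that
moderator data are reported less often than arm summaries. Coefficient
p-values use the normal reference, matching the fixed-effect model; labels
are "significant" below 0.05 and "marginal" in [0.05, 0.10), the band
chosen so that a p of 0.054 is labeled marginal.

## Biome classification

Sites are classified from mean annual temperature (MAT) and precipitation
(MAP). Below 260 mm MAP (the vegetated-desert region; "ca. 260" is
implemented as a strict threshold) the rule is: tundra if MAT < -5 C, else
grassland. At or above 260 mm: tundra if MAT < -5 C; otherwise grassland
wherever MAP falls below a moisture demand line that rises with
temperature, $350 + 30\,(\mathrm{MAT}+5)$ mm by default; remaining (forest)
climates split into boreal (MAT < 3 C) and temperate. The exact published
boundary curves exist only as a figure, so the boundaries ship as an
editable JSON config with these defaults; the defaults were fixed once so
that the canonical worked case - MAT $-2$ C, MAP 303 mm, a dry site that a
vegetation-free climate scheme calls grassland even though the site is a
boreal forest - classifies as grassland. Note that applying the MAP split
across all MAT $\ge -5$ (rather than reserving all of $-5 \le$ MAT $< 3$
for boreal) is exactly what that worked case requires.

## The synthetic world

`sim_scenario()` fixes the generator to the conditions the compiled dataset
describes: about 100 comparisons; per-arm replicate counts uniform on 3-10;
warming magnitudes uniform on 0-4 C; experiment durations log-uniform on
0.05-22 yr (log-uniform because the compiled studies span weeks to two
decades); sites drawn inside the four biome envelopes with most latitudes
above 50 N and a few southern high-latitude sites; soil moisture change
correlated $-0.4$ with warming magnitude (warming tends to dry soils);
about 30% of comparisons joining an existing control cluster of the same
study, reusing that cluster's control draw verbatim. Arm means are normal
around the true means and arm SDs are scaled-chi draws at the drawn $n$, so
SE conversion and the pooled SD see realistic sampling noise. Control means
are log-normal with arm SDs 20-50% of the mean - a generic positive-valued
ecosystem measurement, chosen once as realistic.

The generator does **not** emulate: the exact per-response composition of
the compiled dataset, digitization error from figure extraction,
non-normal or censored arm summaries (e.g. nitrate below detection),
method heterogeneity across labs, or correlated responses measured on the
same plots beyond the shared-control mechanism. A green end-to-end test
therefore establishes that the pipeline recovers known truths under the
model's own assumptions - not that those assumptions hold for any
particular compiled dataset.

Two calibration notes, both visible in the test suite: (i) with arm sizes
of 3-10 each SMD is $t$-like (as few as 4 df), so its true sampling
variance exceeds the large-sample $v$ by ~30% on average and arm-level Wald
calibration inflates accordingly; the type-I acceptance check is therefore
run at the effect level ($y_i \sim N(0, v_i)$, $v_i$ evaluated at the null
SMD), which is the regime the significance rule itself assumes. (ii) the
uncorrected SMD's small-sample bias is positive and below 0.05 at $n = 10$
per arm, asserted over 4000 simulated records.

## Numerical and degenerate-input choices

Cholesky solves throughout; a singular covariance names the clusters
involved. Zero SDs in both arms, or fewer than 3 total replicates, reject
the row (collected and reported, never fatal to a batch). Zero control
means make percent change undefined (error). Rank-deficient designs name
the aliased terms. All pipeline randomness flows from one logged seed, and
rerunning with identical inputs is byte-identical.

## Limitations

No random-effects model or heterogeneity statistics (tau^2, I^2, Q): the
analysis assumes one common true effect per response or stratum. No
response-ratio effect sizes, no SD imputation beyond the SE conversion, no
forest-plot rendering (the fits table is the figures' tabular twin), and no
attempt to re-derive the published pooled intervals, which would require
the compiled per-study dataset that has no public accession.
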