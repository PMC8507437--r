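---
title: "Aligning high-resolution lake water-quality retrievals to a reference ocean-colour sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning high-resolution lake water-quality retrievals to a reference ocean-colour sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakecal)
```

## The problem

Medium-resolution ocean-colour sensors (OLCI-class, ~300 m) carry the
heritage wavebands and calibration pedigree on which inland-water
chlorophyll-a and turbidity algorithms were developed, but their pixels are
too coarse for small lakes. High-resolution land imagers (MSI-class, 10–60 m)
resolve those lakes but differ in band placement, radiometry and atmospheric
correction behaviour, so the same algorithm applied to both sensors yields
systematically different products. `lakecal` implements the alignment
workflow: retrieve products from both sensors on co-located "matchup"
pixels, filter the matchups hard, then re-tune the high-resolution sensor's
algorithm coefficients so its products agree with the reference sensor's —
treating the reference sensor as the transfer standard rather than in-situ
truth.

## Retrieval models

All algorithms operate on normalized water-leaving reflectance $R_w(\lambda)$
on a canonical band grid (443, 490, 560, 665, 708, 778, 865 nm). The
red-edge and NIR channels of the two sensors (705/708.75 nm, 783/778.75 nm,
and the 709/779 nm of published formulations) are treated as the same
symbols `b708` and `b778`; `band_map()` records the mapping.

**Blue-green polynomials (OC2, OC3).** With
$x = \log_{10}(R_w(490)/R_w(560))$ (OC2) or
$x = \log_{10}(\max(R_w(443), R_w(490))/R_w(560))$ (OC3),

$$\log_{10} \mathrm{chl\,a} = a_0 + a_1 x + a_2 x^2 + a_3 x^3 + a_4 x^4 .$$

All logarithms here are base 10, the OCx convention. Valid for low chl-a
(roughly 0–10 mg m⁻³) in waters where pigment covaries with the other
optically active constituents.

**NIR-red power law.** With $x = R_w(708)/R_w(665)$,
$\mathrm{chl\,a} = (a x + b)^c$. The package stores $b$ signed, so the
published coefficient set reads $(35.75\,x - 19.30)^{1.124}$ with
$b = -19.30$; the source formulation prints $(ax - b)^c$ with a negative
$b$, which is internally inconsistent, and the signed-storage convention
reproduces the published numeric form. Suited to moderate-to-high chl-a
(2–200 mg m⁻³).

**Semi-analytical red/NIR (Gons05).**

$$\mathrm{chl\,a} = \frac{\frac{R_w(708)}{R_w(665)}\,(a_w(709) + b_b)
 - a_w(665) - b_b^{\,p}}{a^*_{chl}(665)}, \qquad
 b_b = \frac{0.6\, a_w(779)\, R_w(779)}{0.082 - 0.6\, R_w(779)} .$$

Only $p$ and $a^*_{chl}$ are tuned; the pure-water absorptions are frozen
constants. Published formulations do not fix the $a_w$ values used; the
defaults here ($a_w(665) = 0.40$, $a_w(709) = 0.70$, $a_w(779) = 2.71$
m⁻¹) follow the algorithm's original formulation, are configurable in
`gons_coefficients()`, and every result should be reported with the set
used. The retrieval may legitimately go negative for weak red-edge signal;
it is returned as computed and handled by the range gates.

**Single-band turbidity (Nechad form).**
$T = A_t R_w / (1 - R_w/C_t)$ in FNU, per band. The $A_t, C_t$ pairs are
external calibration inputs with no defaults in this package; the bundled
`nechad_coefficients_synthetic.json` is a clearly labelled synthetic test
fixture of the right order of magnitude, not an operational look-up table.

**Linear calibrations.** $y = a\,x + b$ serves twice: the tuned turbidity
$T_t = aT + b$, and the alternative blue-green pathway that maps the MSI
band ratio linearly onto the OLCI ratio and then applies the OLCI OC2
coefficients ("OC2scale").

## Matchup filtering

`run_filter_cascade()` applies, in a fixed order with exact survivor
accounting:

1–5. pixel masks: cloud/cirrus/shadow/land flags or missing clear-water
flag; any reflectance > 1 on either sensor; atmospheric-correction
out-of-bounds flags; snow/ice; fewer than five valid neighbours in the 3×3
macro-pixel;

6. the central-99.9% trim: values strictly outside the 0.05th/99.95th
percentiles of each sensor's product distribution are removed. Percentiles
are linear-interpolation (type 7) quantiles; the count removed per tail is
capped at $\lfloor 0.0005\,n \rfloor$, since "the top 0.05%" of a sample
below 2,000 values is an empty set — without the cap a strict quantile rule
would always delete the minimum and maximum of any distinct sample;

7. the 2-standard-deviation filter on the MSI product (sample sd, $n-1$
denominator; boundary values retained);

8. per-algorithm range gates on the products (reference-sensor chl-a
0.2–10 mg m⁻³ plus low turbidity for OC2/OC3, 2–200 mg m⁻³ for the
red-edge algorithms, 0–250 mg m⁻³ on the MSI side where wild values must be
excluded, positive turbidity on both sensors for the turbidity pathway).
The gate on "band ratio > 0" is applied to the MSI ratio for OC2, OC3 and
the NIR-red power law, and to the OLCI ratio for OC2/OC3 — the reading
adopted where the source table's column layout is ambiguous.

Steps 6–7 operate on the product of the algorithm currently being tuned,
computed with the initial coefficients, once over the whole dataset (not
per lake); for the turbidity pathway the same two steps are applied to the
turbidity product analogously. Every removal is attributed to the first
step that triggers it, so the `filter_report` counts telescope exactly.
Because steps 6–7 have data-dependent thresholds, re-running the cascade on
its own output is a no-op only when those steps are at a fixed point (for
example tie-heavy data, or any dataset small enough that the per-tail cap
is zero); on large continuous data a second pass would trim a further
0.1%-scale sliver. The cascade is intended to run once per dataset.

## Coefficient tuning

`fit_once()` minimises
$\sum_i \rho\!\left((f(x_i;\theta) - y_i)^2\right)$ where $f$ is the
algorithm's forward model evaluated on the MSI predictor, $y$ is the OLCI
product, and $\rho$ is the Cauchy loss
$C^2 \log(1 + z/C^2)$ that damps large outliers (set `loss = "linear"` for
plain least squares). Choices a user should know:

* **Objective space.** Residuals are formed in linear concentration units
  (mg m⁻³ / FNU), not log space: the robust loss exists precisely to damp
  the heavy right tail that a log transform would otherwise be needed for.
  `objective_space = "log10"` is available.
* **Loss scale.** The Cauchy scale defaults to $C = 1$ in the residual's
  units (one mg m⁻³ / one FNU); residuals well below $C$ behave
  quadratically, residuals far above contribute logarithmically.
* **Optimiser.** `stats::nlminb` (quasi-Newton), unbounded, relative
  tolerance $10^{-8}$ or tighter, at most 1,000 evaluations. Trial
  parameters that leave a model's domain (e.g. a non-positive power-law
  base) incur a large finite penalty so the search retreats rather than
  crashing. Only iteration/evaluation-limit exits count as
  non-convergence; `nlminb` labels an exact-optimum start "false
  convergence", which is accepted.
* **Bootstrap.** `bootstrap_tune()` draws, per replicate, 150 observations
  per lake with replacement — every lake weighs the same regardless of its
  archive size — and excludes lakes with fewer than 140 unique surviving
  matches (a unique match being a distinct lake/timestamp/lat/lon row).
  10,000 replicates by default; the per-parameter median is the tuned
  coefficient and the IQR measures dependence on the tuning set. One root
  seed spawns recorded per-replicate substream seeds, and the input table
  is order-normalised before sampling, so results are bit-reproducible.
* **Linear calibrations** (turbidity gain/offset, ratio scaling) are fitted
  by closed-form OLS inside the same bootstrap framework; the regression of
  the OLCI quantity on the MSI quantity is the adopted direction.
* **Per-lake tuning** (`per_lake_tune()`) fits each lake separately with no
  bootstrap (no size bias to remove) and summarises the coefficient spread;
  the median-of-per-lake set is available as an evaluation mode. Per-lake
  quartic fits on narrow predictor ranges are ill-conditioned by nature —
  wide per-lake coefficient spread is a finding, not a failure.

`coefficient_deviation()` reports tuned/initial multipliers; note that
multipliers recomputed from rounded published coefficient tables can differ
from published multipliers in the last digit.

## Evaluation

`compute_metrics()` implements, with $x$ the MSI and $y$ the OLCI product:
MAD $= \overline{|x-y|}$, MAPD $= 100\,\overline{|x-y|/y}$ (rows with
$y = 0$ excluded and counted), RMSD $= \sqrt{\overline{(x-y)^2}}$, Pearson
$R$, bias $= \overline{x-y}$, the 5th/50th/95th residual percentiles (same
type-7 quantile convention as the filters), and an OLS regression slope of
$x$ on $y$ — in log10 space for chl-a, mirroring how chl-a scatter is
conventionally displayed, and in linear space for turbidity. Welch's
two-sided unequal-variance $t$-test (`welch_test()`, $\alpha = 0.05$ by
default; neither stated in the source) asks whether a calibration shifted
the product mean. `residuals_by_distance()` summarises residuals in
distance-to-land bins and in a near/far split at 5 km, the standard lens on
adjacency contamination. `classify_owt()` assigns optical water types by
minimum spectral angle against user-supplied reference spectra
(scale-invariant, shape-only), and `stratified_metrics()` produces
per-group and per-label-set reports.

## The synthetic matchup generator

Real matchup archives cannot ship with a package, so `generate_dataset()`
manufactures paired-sensor tables with the statistical structure the
analysis assumes:

* ~20 lakes with per-lake counts on a geometric ladder (46 to ~47,000),
  emulating heavily skewed archives; the largest lakes are clearest, which
  funnels the blue-green algorithms' filtered data toward large clear lakes;
* lake-specific log-normal chl-a spanning roughly 0.2–200 mg m⁻³ overall;
* log-normal turbidity (meanlog 0.55, sdlog 1.25) putting ~80% of records
  below 5 FNU — the skewed-low regime typical of these archives;
* reference-sensor reflectances built by *exact inversion* of the retrieval
  formulas (closed forms for the power law and the turbidity model;
  bracketed root-finding on the monotone branch of the OCx quartic, with
  the branch bounds part of the configuration), so reference retrievals
  reproduce the truth to 1e-9;
* a near-linear inter-sensor distortion of the band ratios — by default the
  blue-green log-ratio is mapped through the inverse of the line
  $y = 1.442x - 0.51$, so regressing the reference ratio on the distorted
  one recovers that line (up to noise attenuation); a multiplicative
  amplitude distortion (default gain 1.15) on the red/NIR bands drives the
  turbidity misalignment; these defaults were fixed once when the generator
  was written;
* a common positive log-normal skew factor on the MSI blue-green bands,
  multiplicative band noise, and an adjacency perturbation whose standard
  deviation decays as $e^{-d/d_0}$ with distance to land ($d$ log-uniform
  on 0.1–100 km; amplitude and $d_0$ are free parameters, since no
  quantitative adjacency magnitude is available to target);
* independent Bernoulli flag contamination and a configurable neighbour
  count distribution — adequate for testing the filter logic, with no
  spatial correlation.

What passing tests on this generator do **not** show: atmospheric
correction pathology, spectrally correlated adjacency, bimodal reflectance
distributions, detector striping, or real optical-water-type structure
(the bundled 13-class OWT spectra are synthetic shapes for testing the
classifier, labelled as such). Absolute survivor counts of the real archive
are likewise out of reach by design; only the logic is reproduced.

## Problem sizes

The test suite runs the bootstrap engine at reduced size (tens to a few
hundred replicates, a few thousand rows); parameter-recovery checks use 16
lakes × 1,000 observations and 200 replicates per algorithm, enough for
stable medians and IQRs on a single CPU. The acceptance script additionally
runs the full archive-like synthetic experiment (~150,000 matchups, 200
replicates per algorithm). Production use with the 10,000-replicate default
is a matter of hours, and embarrassingly parallel if needed.

## Known limitations

* The OCx quartic is nearly unidentifiable when the filtered predictor
  range is narrow; bootstrap IQRs make this visible rather than hiding it.
* OLS on a noisy MSI ratio attenuates the fitted ratio-scaling gain toward
  zero (classical errors-in-variables dilution); the fitted line is the
  correct *predictive* alignment for sensor-to-sensor use, but not an
  estimate of the noise-free geometric relation.
* The turbidity pathway tunes a single band per run; cross-band consistency
  is the user's analysis.
* `welch_test` on millions of matchups will reject almost any calibration
  shift; effect size (bias, MAD) is the meaningful quantity at that scale.
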