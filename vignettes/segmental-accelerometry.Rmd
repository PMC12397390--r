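---
title: "Segmental moment analysis of rodent accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmental moment analysis of rodent accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Unilateral 6-OHDA lesioning of the median forebrain bundle is a standard
rat model of Parkinson's disease. Lesioned animals move less and more
slowly (bradykinesia), and the question this package addresses is whether
a single wrist-watch-grade MEMS accelerometer — 3 axes, 25 Hz, 16 bit,
±4 g, worn in a small backpack — carries enough signal to separate
lesioned animals from sham-operated controls over one 12-hour active
(dark) phase, without any video or gyroscope data.

The answer the pipeline operationalizes: reduce each recording to the
magnitude of the acceleration vector, describe one-minute windows by
their first four statistical moments, aggregate per animal, and compare
the groups with rank-based two-sample tests under a family-wise error
correction. `accelPD` implements that chain end to end, together with a
calibrated synthetic-cohort generator so that every stage is testable
without animal data (the original recordings are not publicly
available).

## The analysis chain

**Magnitude.** For animal $d$ with per-axis samples $x_{d,i}, y_{d,i},
z_{d,i}$ (m/s²),
$$m_{d,i} = \sqrt{x_{d,i}^2 + y_{d,i}^2 + z_{d,i}^2},$$
which removes the (unknown, drifting) sensor orientation. A resting
sensor reads $\approx 1\,g$; we fix $g = 9.81$ m/s² exactly. Recordings
are trimmed to a consistent 12 h window starting at 19:45 so that $I =
1{,}080{,}000$ samples enter the analysis per animal
(`trim_to_window()`; partial sampling intervals at the window edge are
truncated toward the interior).

**Segmentation.** The magnitude series is split into $N = \lfloor I/S
\rfloor$ non-overlapping segments of $S = 1500$ samples (one minute); a
trailing remainder is dropped. At full length, $N = 720$.

**Segmental moments.** Per segment, with $\mu$ the segment mean:
$$\sigma^2 = \frac{1}{S-1}\sum_s (m_s - \mu)^2, \qquad
\gamma = \frac{\frac{1}{S}\sum_s (m_s-\mu)^3}{\sqrt{\sigma^2}^{\,3}},
\qquad
\kappa = \frac{\frac{1}{S}\sum_s (m_s-\mu)^4}{\sqrt{\sigma^2}^{\,4}}.$$
Two conventions here are deliberate and load-bearing:

* the shape moments mix a $1/S$ numerator with powers of the *unbiased*
  standard deviation. This is not the textbook biased estimator, nor the
  bias-corrected one; `segment_moments()` implements it verbatim because
  all downstream levels depend on it. The test suite pins it against a
  literal brute-force loop at $10^{-12}$ relative tolerance.
* kurtosis is plain, not excess: a Gaussian segment scores $\approx 3$,
  and no $-3$ is subtracted anywhere.

For histogram display the moments are additionally normalized by powers
of $g$ matched to the moment order ($\mu/g$, $\sigma^2/g^2$,
$|\gamma|/g^3$, $\kappa/g^4$). The $g^3$/$g^4$ powers on the already
dimensionless shape moments are dimensionally odd but are the published
display convention; `normalize_moments()` applies them literally, the
raw columns are always retained, and **all group comparisons in this
package run on the raw scale**. The absolute value of skewness is used
both for normalization (log bins need positive values) and as the
per-animal comparison feature; the signed mean is kept alongside
(`skew_mean` vs `abs_skew_mean`).

Constant segments have $\sigma^2 = 0$ and undefined shape moments; they
are reported as `NA`, counted (`n_degenerate`), and excluded from the
per-animal means. Real accelerometer noise makes them essentially
impossible, but synthetic edge cases hit them.

**Per-animal aggregation.** `dataset_summary()` averages the segmental
moments over all $N$ segments ($\bar\mu_d$, $\bar\sigma^2_d$,
$\bar\gamma_d$, $\bar\kappa_d$) and also computes the overall variance
$\sigma^2_d$ of the full magnitude series with the $1/(I-1)$ convention
(at $I \approx 10^6$ the $1/I$ alternative is indistinguishable; we
chose the unbiased form once and use it everywhere).

## Outlier screening

Datasets with pathological variance (loose backpack, sensor fault)
distort rank tests at cohort sizes of 5–15, so screening precedes
testing.

* **PCA latent projection** (`pca_latent()`): the $D \times I$ magnitude
  matrix is column-centered and projected onto its two leading principal
  components, $T = U\Sigma$. This is diagnostic output for plotting.
  Because $D \le 18$ while $I$ is over a million, the decomposition runs
  on the $D \times D$ Gram matrix of the centered rows; the result
  equals the full SVD up to sign, which is fixed deterministically
  (largest-magnitude loading positive). Near-null components are only
  accurate to about the square root of machine precision on this route —
  irrelevant for screening, and the tests compare against a full-SVD
  oracle at that tolerance.
* **MAD-median rule** (`mad_median_scores()`): within each class, a
  dataset's overall variance is scored as
  $|\sigma^2_d - \mathrm{median}| / (\mathrm{MAD}/0.6745)$ and flagged
  above $K = \sqrt{\chi^2_{0.975,1}} \approx 2.24$. $K$ is computed from
  the quantile at run time, the median of an even count is the mean of
  the central order statistics, and a zero MAD is reported as a
  degenerate flag rather than divided through silently. Scores are
  scale- and location-invariant.

The published analysis combined the MAD rule with visual inspection of
the PCA plot; a visual step cannot be automated faithfully, so the
pipeline's exclusion decision is the MAD rule alone and the projection
is attached for human review. On the synthetic cohorts the two agree:
injected high-variance animals are extreme in both views.

## Hypothesis testing

Two features are tested per cohort, each with the same three-test
battery after outlier exclusion: the mean segmental variance
$\bar\sigma^2_d$ and the mean absolute segmental skewness. All tests are
two-sided and rank/ECDF-based, hence invariant under monotone
transformations of the pooled data:

* **Mann-Whitney U** — exact null distribution when $n_1 + n_2 \le 25$
  and tie-free, normal approximation with tie and continuity correction
  otherwise.
* **Kolmogorov-Smirnov** — exact small-sample p-values. Note that the
  exact two-sample KS is markedly conservative at 5-vs-10: its p-value
  support jumps from 0.0193 to 0.0606, so no rejection level between
  those values is achievable.
* **Baumgartner-Weiß-Schindler** — the rank statistic $B = (B_X +
  B_Y)/2$ that weights ECDF discrepancies by their null variance,
  up-weighting the distribution tails. No installed package provides it,
  so it is implemented here. The default p-value is full permutation
  enumeration of all $\binom{n_1+n_2}{n_1}$ assignments (3003 at
  5-vs-10), with a Monte Carlo fallback above $10^5$ assignments and an
  asymptotic path via the limiting distribution of $B$ — the
  Anderson-Darling-type weighted Brownian-bridge integral, evaluated by
  its alternating series. The asymptotic path is refused below a pooled
  size of 20. Ties are handled by midranks and flagged; under ties the
  permutation null is rebuilt from the observed midranks rather than
  taken from the tie-free cache.

**Holm-Bonferroni, literally.** Raw p-values are sorted ascending and
adjusted as $\tilde p_i = p_i (N_{HT} + 1 - i)$ — *without* the
cumulative-maximum monotonization of the standard step-down procedure,
so the largest raw p-value is always returned unchanged. This exactly
matches the published adjustment (which reports $\tilde p = p$ for the
largest entry of each battery, something a monotonized Holm cannot
produce), and `stats::p.adjust(method = "holm")` is therefore
deliberately *not* used in the implementation path. Significance still
follows the sequential rule — walk the sorted battery and once one
$\tilde p_i > \alpha$, that test and all later ones are non-significant
— so inferential decisions agree with standard Holm and the family-wise
error guarantee is intact (the suite verifies FWER $\le \alpha$ under a
global-null simulation). Adjusted values above 1 are capped and flagged;
decisions are unaffected.

Rotation rates (the apomorphine severity assay) are compared with
Welch's unequal-variance t-test, and the severity association is
reported as both Pearson and Spearman correlations, since the published
method is unspecified.

## The synthetic-cohort generator

`simulate_recording()` draws each axis as

$$a(t) = 9.81\, u(t) + b\,\xi(t)\,\mathbb{1}_{\text{active}}(t) +
\varepsilon(t),$$

* $u(t)$: a unit gravity direction whose spherical angles follow
  Gaussian random walks (intensity `orientation_drift_rate`, default
  0.01 rad/√s). Constructing the vector from angles keeps its norm at
  exactly 1, so the noiseless magnitude is pinned at $9.81$ m/s²
  regardless of drift — a property the tests assert to $10^{-12}$.
* rest/active bouts: a two-state alternating process with exponential
  durations (defaults: 120 s rest, 60 s active, i.e. one third of the
  night active) gates zero-mean Gaussian movement bursts of per-axis SD
  $b$.
* $\varepsilon$: white sensor noise (default SD 0.05 m/s² per axis,
  a realistic MEMS noise floor at 25 Hz), and optional quantization to
  the 16-bit ±4 g grid (on by default, matching the sensor).

**Calibration.** With active fraction $p$ and noise SD $\sigma_n$, the
expected mean segmental magnitude variance is approximately $p b^2 +
\sigma_n^2$ (the burst projects onto the gravity direction; higher-order
terms are $O(b^4/g^2)$). Solving for the published class levels of
0.279 (sham) and 0.163 m²/s⁴ (PD) at the default bout mix gives
`burst_sd_sham = 0.90` and `burst_sd_pd = 0.68` m/s². These defaults
*are* the study conditions of the package and are not tuned further.
Between-animal heterogeneity is a mean-one lognormal multiplier on the
burst variance with CV 0.35, chosen once to reproduce the published
within-class spread (classes overlap; single animals can cross class
levels). Rotation rates are drawn per class from normal models whose
means are the published group means and whose SDs are the sample SDs
recomputed from the published rotation table (0.51 and 1.17 rpm — the
table's ± values are standard errors, which a per-animal draw must not
use). Outlier animals get their burst variance multiplied by
`outlier_variance_multiplier` (default 10).

**What the generator reproduces, and what it does not.** It matches the
magnitude level (segmental means within 2% of 1 g, like the published
9.82), the class variance levels and their ordering, the bursty
right-tailed pooled magnitude distribution, occasional pathological
high-variance datasets, and the rotation separation. It does **not**
reproduce the published shape-moment levels: Gaussian bursts give mean
segmental kurtosis of roughly 5–20 (published: ≈50) and near-symmetric
within-segment distributions whose mean absolute skewness sits around
0.1–0.7 (published: 0.569 sham / 0.342 PD, with a class ordering the
generator does not encode). We document the achieved values rather than
force them with a heavier-tailed burst mixture; consequently, passing
synthetic tests validate the *machinery* (estimators, exclusion rule,
test battery, error control) and the variance-based separation, but say
nothing about skewness- or kurtosis-based separation on real animals.
Also out of scope: circadian structure beyond one active phase,
biomechanically realistic gait, and BLE packet loss (inputs are
gap-free by contract; the reader rejects non-uniform timestamps beyond
1 µs).

**Reproducibility.** One root seed; each animal's stream is derived from
`(seed, animal_id)`, so cohorts are bit-reproducible under reordering
and adding/removing animals never perturbs the others — the suite
checks both, and the generator restores the caller's RNG state.

## Numerical and design choices

* Canonical unit m/s² with $g = 9.81$ exactly; raw 16-bit counts convert
  by $4 \cdot 9.81 / 32768$ per count.
* On-disk format: one CSV (`time,x,y,z`) plus a YAML sidecar per animal
  and a YAML cohort manifest. The published work names no format; this
  one is plain-text, diffable, and round-trips to 15 significant
  digits.
* Log histograms: geometric edges, right-open bins except the last, 100
  bins by default over the positive data range (the published figures
  state neither); non-positive values are excluded with a count. A
  2k-bin histogram merges exactly onto the k-bin one.
* Permutation p-values include the observed assignment (never 0); the
  BWS tie-free null at a given $(n_1, n_2)$ is cached.
* Sequential-rule comparisons use $\tilde p \le \alpha$ for
  significance at $\alpha = 0.05$.
* Pipeline stage outputs are written as CSVs per run; no content-hash
  caching layer is used — runs are deterministic and each full-scale
  stage costs seconds, so a cache would add state without measurable
  benefit.
* Spherical convention for the supplementary directional transforms:
  $\theta$ polar from $+z$ in $[0, \pi]$, $\phi = \mathrm{atan2}(y, x)$;
  zero-magnitude samples yield `NA` angles. Integrals are cumulative
  trapezoids with $\Delta t = 1/f_s$ and no drift correction.

**Problem sizes in the test suite.** Structural and oracle tests run on
seconds-to-minutes of signal; the pipeline tests use 10-minute
recordings with 6-second segments; the cohort-separation study uses
twenty 5-vs-10 cohorts of 20-minute recordings (the mean segmental
variance estimate stabilizes far below 12 h, and its per-animal spread
is dominated by the between-animal multiplier, not by recording
length); the error-control study uses 2000 null simulations at 5-vs-10.
The acceptance script additionally runs one full-scale cohort: 18
animals at the complete $12\,\mathrm{h} \times 25\,\mathrm{Hz}$ length
with three injected outliers, mirroring the published cohort shape
(18 datasets, 3 excluded, 15 final).

## Known limitations

* The skewness/kurtosis levels of real lesioned-rat data are not
  emulated (see above); only the variance channel of the synthetic
  cohorts is calibrated.
* The exact KS test cannot reject below $p = 0.0606$ except at its two
  most extreme configurations at 5-vs-10; treat its non-rejections at
  these sizes accordingly.
* The literal Holm adjustment can order adjusted p-values
  non-monotonically (by design, to match the published convention);
  consumers who need monotone adjusted values should apply a running
  maximum — decisions will not change.
* The MAD-median rule assumes a roughly symmetric bulk within each
  class; with 3–5 datasets per class its median and MAD are themselves
  noisy, and the degenerate-MAD flag should be checked before trusting
  flags from very small classes.
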