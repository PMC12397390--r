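# accelPD

Segmental moment analysis of continuous rodent accelerometry, built to
ask one question of a 3-axis, 25 Hz, ±4 g body-worn sensor: does twelve
hours of overnight movement separate 6-OHDA-lesioned Parkinsonian rats
from sham-operated controls?

The package is aimed at preclinical researchers working with wearable or
implantable MEMS accelerometers in small-animal disease models, where
cohorts are small (5–15 animals), amplitudes are subtle, and a
transparent, fully reproducible statistical chain matters more than a
black-box classifier.

## The method

Each animal's recording is reduced to the orientation-free magnitude of
the acceleration vector,

$$m_{d,i} = \sqrt{x_{d,i}^2 + y_{d,i}^2 + z_{d,i}^2},$$

trimmed to a consistent 12 h active-phase window (I = 1,080,000 samples
at 25 Hz), and cut into N = 720 non-overlapping one-minute segments of
S = 1500 samples. Per segment the first four moments are computed — mean
μ, unbiased variance σ² (1/(S−1)), and skewness γ and kurtosis κ with
1/S central-moment numerators over powers of the unbiased standard
deviation (a deliberate mixed estimator; kurtosis is plain, not excess).
Per animal, the segment moments are averaged and the overall magnitude
variance σ²_d is kept for quality screening.

Screening combines a 2-D PCA latent projection of the D × I magnitude
matrix (diagnostic) with the MAD-median rule applied per class to σ²_d:
flag dataset d when

$$\frac{|\sigma^2_d - \mathrm{median}(\sigma^2_d)|}{\mathrm{MAD}(\sigma^2_d)/0.6745} > K,
\qquad K = \sqrt{\chi^2_{0.975,1}} \approx 2.24 .$$

After exclusion, the per-animal mean segmental variance and mean
absolute segmental skewness are each compared between groups with a
three-test nonparametric battery — Mann-Whitney U, Baumgartner-Weiß-
Schindler (exact permutation enumeration at these cohort sizes), and
Kolmogorov-Smirnov — adjusted by the literal Holm-Bonferroni step-down
p̃ᵢ = pᵢ·(N_HT + 1 − i) on ascending p-values with a sequential
rejection rule (no running-maximum monotonization: the largest raw p is
returned unchanged). Rotation-rate severity data get Welch's t-test and
Pearson/Spearman correlations.

Because the original animal recordings are not public, the package
includes a calibrated generator (`sim_config()`, `simulate_cohort()`):
gravity on a slowly drifting unit direction, rest/active bouts with
exponential durations gating Gaussian movement bursts, sensor noise,
and 16-bit quantization, with class burst amplitudes solved analytically
so mean segmental variances sit at the published levels (≈0.279 m²/s⁴
sham vs ≈0.163 m²/s⁴ lesioned). See the methods vignette
(`vignettes/segmental-accelerometry.Rmd`) for what the generator does
and does not emulate.

## Worked example

A scaled-down synthetic cohort (5 sham vs 10 lesioned, one hour per
animal, one injected high-variance dataset):

```r
library(accelPD)
cfg <- analysis_config(
  sim = sim_config(seed = 42, duration_s = 3600),
  S = 1500,
  outlier_ids = 12L
)
report <- run_analysis(cfg)
report
#> <accel_report>
#>   cohort: D_all = 15 -> D_final = 14
#>   excluded: 12 (score 75.79)
#>   variance:
#>     mann_whitney_u       p = 0.003996  p_adj = 0.01199  significant
#>     bws                  p = 0.004496  p_adj = 0.008991  significant
#>     kolmogorov_smirnov   p = 0.01399  p_adj = 0.01399  significant
#>   skewness:
#>     bws                  p = 0.1254  p_adj = 0.3761  n.s.
#>     mann_whitney_u       p = 0.1898  p_adj = 0.3796  n.s.
#>     kolmogorov_smirnov   p = 0.2258  p_adj = 0.2258  n.s.
#>   rotation (Welch): t = -11.369, p = 9.8e-08
#>   severity correlation: r = -0.795 (p = 0.000669), rho = -0.657 (p = 0.0129)
```

Reading it: the injected animal 12 is flagged by the MAD-median rule
(score 75.8 ≫ K = 2.24) and removed before testing; on the remaining 14
animals the variance battery rejects the null of one shared distribution
under all three tests after Holm adjustment (note the largest raw p,
0.01399, passes through the literal adjustment unchanged), while the
skewness battery does not — the same qualitative picture as the animal
study this pipeline is modeled on. The strongly negative severity
correlation is class-driven (lesioned animals rotate more and move
less).

The building blocks are exported individually:

```r
segment_moments(c(1, 2, 3, 4))
#>       mu      var     skew     kurt
#> 2.500000 1.666667 0.000000 0.922500

round(mad_threshold(), 2)
#> [1] 2.24

h <- holm_bonferroni(c(0.013, 0.018, 0.019))
as.data.frame(h)[, c("p", "p_adjusted", "significant")]
#>       p p_adjusted significant
#> 1 0.013      0.039        TRUE
#> 2 0.018      0.036        TRUE
#> 3 0.019      0.019        TRUE
```

There is also a small command line (`cli_main()`, wrapper in
`inst/scripts/accelpd`) with `simulate`, `analyze` and `report`
subcommands for shell-driven use.

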