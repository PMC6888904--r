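---
title: "Methods: epigenetic age acceleration, platform merging, and weight-loss trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic age acceleration, platform merging, and weight-loss trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
choices made where the design was genuinely open, and what the synthetic
data generator does and does not emulate.

## The clock model

A coefficient-defined epigenetic clock is a linear predictor on the
*calibrated* age scale. With adult-age constant $a$ (20 years by default,
stored per clock since it is a property of the coefficient set):

$$F(\mathrm{age}) = \begin{cases}
\log(\mathrm{age}+1) - \log(a+1) & \mathrm{age} \le a\\
(\mathrm{age}-a)/(a+1) & \mathrm{age} > a
\end{cases}$$

$F$ is continuous, strictly increasing, zero at $a$, and defined for ages
above $-1$. The clock score is $m = w_0 + \sum_j w_j \beta_j$ over its CpG
set and $\widehat{\mathrm{DNAm\ age}} = F^{-1}(m)$, with
$F^{-1}(m) = (1+a)e^m - 1$ for $m \le 0$ and $(1+a)m + a$ otherwise.
`calibrate_age()`/`uncalibrate_age()` implement the pair; tests verify the
round trip to $10^{-10}$ years over $(-0.9, 120)$.

**Reduced clocks.** When a platform lacks some clock CpGs (the EPIC array
does not carry the full published 353-CpG set), `reduce_clock()` drops the
absent CpGs and keeps the intercept and surviving weights *unchanged* — no
retraining — because that is how reduced clocks are built in practice from
published coefficients. This has a quantifiable cost. For the package's
generative truth clock the weights satisfy $w_j = 1/(n\lambda_j)$, so the
score of a clock reduced to a retained set $S$ obeys
$\sum_{j \in S} w_j \lambda_j = |S|/n$: the linear score, and with it any
slope estimated on DNAm age, is attenuated by exactly the retained
fraction. Dropping 17 of 336 CpGs therefore attenuates effect estimates by
$\approx 5\%$ *by construction*, which is why the chronological-age
coefficient of a reduced clock sits below 1 and why the years-per-10-BMI
conversion offers an age-normalized mode,
$10\,\hat\beta_{BMI}/\hat\beta_{age}$, in which the common attenuation
cancels. `years_per_10bmi()` reports both modes and asserts neither as the
only convention; the acceptance recovery experiment runs with all clock
CpGs present so that the scoring is calibrated and the raw
$\hat\beta_{BMI}$ is a consistent estimator of the generative effect.

**Missing values.** Default policy is `error`. `mean_impute` replaces a
per-sample missing beta with the CpG's cross-sample mean (the published
clock software imputes similarly) and reports every use with a message;
CpGs with no data at all cannot be imputed and must be removed with
`reduce_clock()` first.

## Platform merging and concordance

`merge_platforms()` intersects CpG sets (rows sorted lexicographically, the
documented order that makes the merge commutative and associative) and
concatenates disjoint sample sets — the "virtual 450k array" construction.
It deliberately implements *pure* intersection; any additional QC-based
probe dropping is upstream of this package, which starts from normalized
beta values (no IDAT parsing or background correction).

`platform_concordance()` compares paired samples (matched by sample id;
unmatched ones are dropped with a warning) and counts CpGs whose mean
absolute beta difference across samples is *strictly* below the threshold
(default 0.1), matching the "lower than" convention. Concordance reporting
at 323/336 and 318/336 CpGs reproduces 96.1% and 94.6%.

## Acceleration statistics

Epigenetic age acceleration is the residual of DNAm age regressed on
chronological age — deviation from the cohort's own age trend, not from the
identity line. The adjusted variant takes residuals of
`dnam_age ~ chron_age + sex + bmi`. Sex is coded female = 1, male = 0; a
constant sex vector is an error rather than a silent term drop. All linear
models go through `stats::lm` (tests verify agreement with the
normal-equations solution to $10^{-8}$); confidence intervals are Wald
intervals from the t distribution.

The power analysis uses the Fisher z approximation: the smallest population
correlation detectable at two-sided level $\alpha$ with power $1-\beta$ is
$\tanh\!\big((z_{1-\alpha/2}+z_{1-\beta})/\sqrt{n-3}\big)$, which gives
0.38 at $n = 52$ and 0.545 at $n = 24$; a Monte-Carlo bivariate-normal
simulation in the test suite confirms the approximation to within 5
percentage points of power at $n = 24$.

Quantile trimming (`percentile_trim()`) uses type-7 (linear interpolation)
quantiles and *strict* exclusion of the boundary values, matching the
"excluding younger/older" phrasing of middle-age reanalyses. Two-group
comparisons default to the equal-variance Student t test (Welch behind
`var_equal = FALSE`). No multiple-testing correction is applied anywhere:
nominal p values are reported, mirroring how such cohort analyses are
published.

## Weight-loss trajectories

%EBWL is implemented as the standard ratio
$100\,(BMI_0 - BMI_t)/(BMI_0 - 25)$ — the "difference between actual and
ideal weight loss" wording of the field is interpreted as a percentage, the
only reading under which the quantity is one. Baselines at or below the
ideal BMI of 25 kg/m² are an error.

The trajectory clustering follows the select-then-cluster scaffold of
group-based trajectory analysis:

1. **Ten summary measures** per subject (final, max, month of max, mean,
   early slope 3-12 mo, late slope 24-48 mo, overall least-squares slope,
   trapezoid AUC per month of follow-up, SD of successive increments,
   relative rebound). Missing visits are linearly interpolated inside the
   observed span, never extrapolated; subjects with fewer than 3 visits are
   excluded with a logged count. When a slope window holds fewer than two
   visits the overall slope substitutes.
2. **Redundancy screening**: pairs with $|r| > 0.95$ lose their later
   member; a principal-component factor decomposition of the remainder
   retains factors with eigenvalue > 1 and keeps the highest-loading
   measure per factor (ties resolved by measure order).
3. **k-means** on the standardized selected measures, 50 restarts, fixed
   internal seed, rows pre-sorted by subject id so results are invariant to
   input order; k is chosen over 2-5 by the Calinski-Harabasz
   variance-ratio index. A zero within-cluster sum of squares (possible on
   noise-free fixtures) is treated as an infinitely good CH value.
4. **Labels** NWL/IWL/LWL by descending mean final %EBWL, plus the binary
   NWL vs ILWL recode used by the logistic trend model.

`logistic_trend()` is a maximum-likelihood binomial GLM on one continuous
predictor; OR = exp(slope) with a Wald CI and a likelihood-ratio trend p.
Complete or quasi-complete separation is detected (|slope| > 20 or all
fitted probabilities at the boundary) and raised as an error rather than
reported as an absurd OR.

## The synthetic-data generator

`sim_config()` holds every knob with defaults emulating a severe-obesity
bariatric cohort:

- **n = 52**, sexes balanced within 1; chronological age uniform on 19-55
  years; BMI per sex normal (men 54.4 ± 9.1, women 48.9 ± 7.2 kg/m²)
  truncated below at 40 kg/m² by rejection sampling (the severe-obesity
  inclusion criterion). The truncation raises realized means by
  ~1-1.5 kg/m², which tests account for.
- **Metabolic syndrome** components are drawn around the NCEP ATP III
  thresholds (waist > 102/88 cm, TG ≥ 1.7, HDL < 1.03/1.29, BP ≥ 130/85,
  glucose ≥ 5.6 mmol/L — the updated glucose cut-off was chosen where two
  conventions exist, and the threshold table is an editable argument).
  Component means are placed so each criterion fires with the probability
  $q$ solving $P(\mathrm{Bin}(5, q) \ge 3) = $ target prevalence (0.5 by
  default, the matched-design rate); the two blood-pressure readings share
  a criterion and are calibrated at $1 - \sqrt{1-q}$ each. The stored flag
  is always derived via `classify_mets()`, so flag and components cannot
  disagree.
- **Methylation** at clock CpGs is the generative inversion of the clock:
  $\beta_{ij} = \mathrm{clip}(\mu_j + \lambda_j t_i + e_{ij}, 0, 1)$ with
  $t_i = F(\mathrm{age}_i + \mathrm{accel}_i)$,
  $\mathrm{accel}_i = s\,( BMI_i - \overline{BMI}) + \varepsilon_i$. The
  slope $s$ is 0.15 y per BMI unit in VAT and 0 in blood (the tissue
  specificity under study); centring on the cohort mean BMI makes the
  marginal mean DNAm age equal the mean chronological age.
  $\varepsilon_i \sim N(0, 7.5\ \mathrm{y})$ reproduces an age correlation
  of ~0.8 at the design age spread; $e_{ij} \sim N(0, 0.02)$ gives
  cross-platform mean |Δβ| ≈ 0.023, comfortably inside the 0.1 concordance
  band. The noise is redrawn (truncated) for the rare subject whose latent
  age would fall below the domain of $F$. `make_truth_clock()` validates up
  front that no beta can leave (0, 1) over the design age range ± 15 years.
  Both platforms are simulated for *all* subjects (shared biological
  target, independent technical noise) so concordance has paired samples;
  an alternating assignment provides the disjoint halves for merging. The
  EPIC matrix omits a seed-deterministic random subset of 17 clock CpGs
  (their real identities are not public and are treated as input data).
- **Trajectories**: three fixed piecewise-linear %EBWL archetypes (NWL
  plateaus near 86-88%, IWL near 62-65%, LWL near 26-31%) at months
  3, 6, 12, 18, 24, 36, 48; only the group *frequencies* (65/30/5%) are
  constrained by the emulated design, so the curve shapes are a documented
  modelling choice. NWL membership follows
  $\mathrm{logit}\,P(NWL) = \mathrm{logit}(0.65) + \log(1.21)\,
  \mathrm{accel}_i$; per-visit noise is $N(0, 4)$ %EBWL points and visits
  drop out independently with probability 0.05.

**What the generator does not emulate**: genome-wide non-clock CpGs,
cell-type composition, batch effects, array detection failures, matched-pair
recruitment (only post-hoc pairing would be possible and exact optimal
matching is out of scope), and any postsurgery methylation change. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated generative model, not robustness to those real-data phenomena.

## Problem sizes and reproducibility

The test suite and acceptance script use: study scale n = 52 for pipeline
runs; n = 500 × 50 replicates for the BMI-effect recovery (mean estimate
within 2 Monte-Carlo SE of the generative 0.15); n = 2000 × 50 replicates
for the odds-ratio recovery (Wald CI coverage of the generative 1.21
checked against its nominal level). These sizes make every simulation
estimate's Monte-Carlo error small relative to the tolerance being
asserted while keeping a full run in the minutes range. Every stochastic
step takes an explicit integer seed; `run_pipeline()` derives fixed small
offsets per stage and embeds the config hash in each artifact, so reports
regenerate byte-identically.

## Known limitations

- At n ≈ 52 with the default %EBWL noise, the factor screening can retain
  noise-dominated measures (late slope, increment SD) and the CH criterion
  then over-splits (k of 4-5 with imperfect archetype recovery). On
  noise-free archetypes recovery is exact (k = 3, ARI = 1). Users
  clustering small noisy cohorts may prefer passing
  `selected = c("final", "mean")` or a fixed `k_range = 3` on substantive
  grounds.
- The reduced-clock attenuation described above is inherent to unretrained
  reduction; consumers comparing effect sizes across platforms should use
  the age-normalized conversion.
- The Fisher z power formula is an approximation; it agrees with simulation
  to a few percentage points at the sample sizes used here but degrades for
  very small n.
- `classify_mets()` treats the two blood-pressure readings as one criterion
  via a logical OR; antihypertensive medication status, part of the formal
  ATP III definition, is not modelled.
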