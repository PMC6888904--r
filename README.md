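# vatclock

Epigenetic age acceleration in visceral adipose tissue (VAT) and blood,
with post-bariatric-surgery weight-loss trajectory modelling.

## The scientific problem

Severe obesity accelerates the epigenetic aging of metabolically active
tissues. Quantifying this requires a chain of steps that is rarely available
as one tested pipeline:

1. **DNAm age.** An epigenetic clock predicts age from a weighted sum of
   methylation beta values (`beta = C/(T+C)`, in `[0, 1]`) at a fixed set of
   CpG sites, passed through the nonlinear calibration
   `F(age) = log(age + 1) - log(a + 1)` for `age <= a` and
   `(age - a)/(a + 1)` above it (adult age `a = 20`):
   `DNAm age = F^-1(intercept + sum_j w_j * beta_j)`.
2. **Platform handling.** Cohorts assayed on both Illumina 450k and EPIC
   arrays are merged onto the intersection of their CpG sets (a "virtual
   450k array"); clock CpGs absent from EPIC are dropped *without*
   retraining, giving a reduced clock whose reporting (percent reduction,
   cross-platform concordance) the package reproduces.
3. **Age acceleration.** The residual from regressing DNAm age on
   chronological age; the *adjusted* variant additionally removes sex and
   BMI. Associations are tested with Pearson correlations (with Fisher-z
   power analysis), multivariate OLS (beta, 95% CI, p, adjusted R²), and the
   conversion to years of epigenetic aging per 10 BMI units.
4. **Weight-loss trajectories.** Percent excess body weight loss
   (`%EBWL = 100 * (BMI_0 - BMI_t) / (BMI_0 - 25)`) over months 3-48 after
   surgery is summarized into ten per-subject measures, screened for
   redundancy by a factor decomposition, clustered by k-means
   (Calinski-Harabasz choice of k), and labelled NWL / IWL / LWL (normal /
   intermediate / low weight loss). A binomial logistic model estimates the
   odds ratio of NWL membership per year of adjusted VAT acceleration.

Patient-level methylation for such cohorts is typically not public, so the
package ships a first-class synthetic-cohort generator that inverts the
clock generatively: per-CpG beta values are linear in the calibrated latent
age `t_i = F(chron_age_i + accel_i)`, and the matching "truth" clock
recovers `t_i` exactly in the noise-free case. Every downstream stage is
therefore testable against known ground truth.

## Worked example

```r
library(vatclock)
cfg <- sim_config(n_subjects = 52, seed = 1)   # severe-obesity cohort defaults
report <- run_pipeline(cfg)
print(report)
#> <run_report> n = 52, seed = 1, hash 5fb53c061c633d4ff1ae7aab2df513f5
#>   blood: r(chron, DNAm) = 0.811; r(accel, BMI) = 0.188 (p = 0.181); beta_BMI = 0.131
#>   vat: r(chron, DNAm) = 0.778; r(accel, BMI) = 0.230 (p = 0.102); beta_BMI = 0.158
#>   trajectories: k = 5 (NWL 38%, IWL 27%, LWL1 6%, LWL2 25%, LWL3 4%)
```

DNAm age tracks chronological age strongly in both tissues (r ≈ 0.8), while
the BMI effect on acceleration is simulated into VAT only. The multivariate
model for VAT:

```r
fit <- report$tissues$vat$multivariate
cbind(fit, adj_r2 = attr(fit, "adj_r2"))
#>          term estimate     se  ci_low ci_high        p adj_r2
#> 1 (Intercept)   -7.202 8.1884 -23.675   9.271 3.84e-01  0.633
#> 2   chron_age    0.767 0.0909   0.584   0.950 5.67e-11  0.633
#> 3         bmi    0.158 0.1301  -0.104   0.420 2.31e-01  0.633
#> 4         sex   -3.242 1.7968  -6.857   0.372 7.76e-02  0.633
#> 5        mets   -2.519 1.7588  -6.057   1.020 1.59e-01  0.633
```

The BMI coefficient (0.158 y per BMI unit here; generative truth 0.15) is
not significant at n = 52 — as the power analysis predicts: a correlation
of at least `required_r_for_power(52)` = 0.38 is needed for 80% power, and
the simulated effect sits below that. At n = 500 the estimate converges to
the generative value (see the acceptance script). Converting the fit,
`years_per_10bmi(fit)` gives 2.06 years of epigenetic aging per 10 BMI
units (age-normalized mode, i.e. `10 * beta_BMI / beta_age`).

A command-line wrapper is installed under
`system.file("scripts", "vatclock", package = "vatclock")` with subcommands
`simulate`, `score` (beta TSV + coefficient CSV in, DNAm-age TSV out) and
`run`.

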