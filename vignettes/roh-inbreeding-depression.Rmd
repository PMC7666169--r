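---
title: "Methods: ROH-based inbreeding-depression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH-based inbreeding-depression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rohid)
```

This vignette is the package's own account of its science: the models it
fits, the assumptions behind them, the defaults and why, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## 1. Model

### Directional dominance and inbreeding depression

Let locus *i* have B-allele frequency $p_i$ ($q_i = 1 - p_i$) and
genotypic values $(-a, d_i, +a)$ for B-allele counts $(0, 1, 2)$. When
loci combine additively across the genome, a population with inbreeding
coefficient $F$ has mean

$$M_F = M_0 - 2F\sum_i d_i\,p_i q_i ,$$

so inbreeding changes the mean only when the dominance deviations are
directionally biased ($\sum d_i p_i q_i \neq 0$), and the change is
linear in $F$. This linearity is what licenses estimating inbreeding
depression by regression of a trait on a genomic estimate of $F$. The
package exposes the closed form as `expected_depression(F, d, p)` and
uses it as the analytic oracle for the simulator.

### Genomic inbreeding coefficients

* `F_ROH` — the fraction of the autosomal genome in ROH longer than a
  threshold (default **1.5 Mb**, strictly greater). The denominator
  defaults to a fixed **3 Gb** autosomal length; for simulated genomes
  the summed chromosome length is used instead (the pipeline's
  `genome_length_bp = NA` convention). Long ROH proxy *recent*
  autozygosity: shorter ROH mostly reflect ancient haplotype sharing.
* `F_GRM` (Fhat3) — the correlation-between-uniting-gametes estimator
  computed from common SNPs (MAF > 0.05),
  $\frac{1}{N}\sum_i \frac{x_i^2-(1+2p_i)x_i+2p_i^2}{2p_iq_i}$. Exact
  identities used as tests: a fully heterozygous genome gives $-1$ at any
  frequencies; a fully homozygous genome gives $+1$ at $p = 0.5$; the
  HWE expectation is 0 (and the per-locus term has variance exactly 1,
  which the acceptance suite uses for its Monte-Carlo check).
* `F_outsideROH` — excess homozygosity restricted to SNPs outside called
  ROH, $(O'-E')/(N'-E')$ with the ROH SNPs subtracted from observed,
  expected and total counts. It is *not* an inbreeding estimator; it
  isolates common-variant homozygosity so that, jointly with `F_GRM`, a
  rare-recessive (dominance-hypothesis) architecture can be told apart
  from common-variant overdominance. With no ROH it reduces to the
  classic $(O-E)/(N-E)$.

### Two-step estimation

Step 1 fits the covariate model with a polygenic random effect,
$y = Xb + u + \varepsilon'$, $u \sim N(0, \sigma_g^2 A)$, by REML through
a single spectral decomposition of the GRM $A$ (the heritability ratio is
profiled by 1-D optimization, tolerance $10^{-6}$). The residual passed
on is $\hat\varepsilon' = y - X\hat b - \hat u$: the BLUP of $u$ is
subtracted because the model lists $u$ separately from $\varepsilon'$;
`keep_blup_in_residuals = TRUE` provides the sensitivity variant. With
$A = I$ the variance split is unidentifiable — the fit is flagged, the
boundary $\sigma_g^2 = 0$ reported, and the residuals are exactly the OLS
residuals. `A = NULL` requests a plain OLS step 1, appropriate for
simulated cohorts without polygenic correlation.

Step 2 regresses $\hat\varepsilon'$ on `F_ROH` (plus `F_outsideROH` by
default when available) by OLS, which is the ML solution for the
coefficients of a fixed-effects Gaussian regression. Standardized effects
divide $\hat\beta_{F_{ROH}}$ by the trait SD of the analyzed stratum, so
effects are comparable across traits and sexes; because OLS residuals
scale with the trait, the standardized effect is invariant to affine
trait rescaling. When `F_ROH` is orthogonal to the covariates the
two-step estimate equals the one-step joint OLS coefficient (asserted in
tests to $10^{-6}$ relative tolerance); otherwise the residual-regression
approximation attenuates the estimate slightly, which is the documented
cost of the two-step shortcut.

Reporting conventions: `predicted_change(est, F = 1/64)` gives the
expected trait change in the offspring of second cousins; the per-trait
Bonferroni level defaults to $0.05/14$ traits.

### Covariate models

`default_model_specs()` encodes the conventional specifications: every
trait adjusts for sex, age, centered-age², SES quintile, night-light
intensity and 15 genotype PCs; body-shape traits add height; circulatory
traits add BMI; the SES.Q model swaps SES.Q for education and occupation.
Categorical covariates become indicator contrasts; age is centered before
squaring purely for numerical conditioning (the fit is unchanged). For
urbanization strata (site night-light below vs at/above 5 units on the
0–63 satellite scale), `night_light` is dropped and `site` added to
absorb site-level confounding.

### Stratified and comparative analyses

`fit_stratified()` reruns the full two-step pipeline inside each stratum
and standardizes by the within-stratum trait SD. `compare_strata()` is
the ANCOVA interaction test
$\varepsilon' = \mu + \beta F + \gamma G + \delta (F\times G) + e$.
`compare_beta_sets()` compares two sets of standardized per-trait effects
by a two-sided Mann-Whitney test: exact by full enumeration of group
assignments (mid-ranks for ties) while
$\binom{n_a+n_b}{n_a} \le 2\times10^5$, normal approximation with tie
correction beyond. Treating each trait as one observation ignores
between-trait dependence; that limitation is inherent to the procedure
and not modeled.

### Regional scan

`make_windows()` tiles chromosomes into non-overlapping 3 Mb windows
(a 3000 Mb genome gives exactly 1000); a terminal remainder under 1 Mb is
merged into the previous window to avoid near-empty windows with unstable
fractions. `window_roh_fraction()` computes exact bp overlap fractions —
per sample they conserve total ROH length. `scan_windows()` regresses the
step-1 residuals on each window's fraction; windows with fewer than 25
informative samples (nonzero fraction) or degenerate columns are reported
untested, and the Bonferroni threshold is $\alpha$ divided by the number
of *tested* windows (0.05/1000 = $5\times10^{-5}$ when all 1000 are
tested). By default the fractions use the > 1.5 Mb ROH set, consistent
with `F_ROH`; the full > 300 kb call set is available via `filter_roh()`
since the choice is genuinely open.

## 2. ROH calling

`call_roh()` implements the sliding-window algorithm with the standard
array-data parameterization as defaults (`roh_params()`): 30-SNP windows
with at most 1 heterozygote and 5 missing calls; a SNP is in homozygous
state when at least 5% of the windows covering it are homozygous;
stretches split at inter-SNP gaps over 1000 kb; emitted runs need ≥ 30
SNPs, ≥ 300 kb span, and ≤ 30 kb/SNP density. No LD pruning is applied.
Dialect choices, flagged because callers differ here:

* near chromosome ends the hit-fraction denominator counts only windows
  that actually exist (truncation);
* segment bounds are the first and last in-state SNP positions, length
  `end - start + 1`;
* adjacent stretches separated by one out-of-state SNP are not merged;
* a heterozygote adjacent to a long run can end up in-state (a window
  holding a single het is still "homozygous"), so called segments may
  extend one or two SNPs into flanks — inherent to the algorithm.

`brute_force_roh()` re-executes the same definition with literal per-SNP
window enumeration and no shared shortcuts beyond the final emission
bookkeeping; the acceptance suite requires exact segment-list equality on
1000 random instances. Chromosomes with fewer SNPs than one window are
skipped with a warning.

## 3. The synthetic world

The generator emulates a multi-site African cohort setting: autosomes
only; markers as a Poisson process (default 10 kb mean spacing, the
density of a dense array); B-allele frequencies uniform on [0.05, 0.5];
per-individual target inbreeding coefficients exponential with mean 0.01
(capped at 0.5) — the same order as cohorts where most individuals carry
little recent autozygosity and a minority carry a lot; HBD segment
lengths exponential with mean 3 Mb, so most segments clear the 1.5 Mb
threshold; covariates mirroring the field's standard adjustment set
(sex, age 40–60, site, SES quintile, per-site night-light with both
low- and high-luminosity sites, education, occupation).

Design choices worth recording:

* **HBD placement.** Segments are accumulated greedily (uniform start,
  chromosome chosen proportional to length, overlaps merged) and the
  *final draw is truncated* to the remaining coverage needed, so the
  realized `F_true` equals the target within 1 bp. Pure greedy
  accumulation without truncation overshoots by about half a segment
  length, which would bias the realized mean away from the target law's
  mean and break the generator's own self-consistency check; truncation
  removes the bias at no cost since `F_true` is recorded anyway.
* **Emission inside HBD.** A single founder allele is drawn by frequency
  (BB with probability $p_i$), so heterozygosity inside true HBD is
  exactly zero at zero missingness — the definition of autozygosity.
* **Sex-specific effects** replace the locus-level dominance term with a
  direct $\beta_{sex}\times F_{true}$ contribution, so the planted
  sex-specific architecture is exact rather than emergent.
* **Polygenic term** defaults to independent normals; a GRM-correlated
  version is available so the mixed-model step is exercised in both
  regimes.

What the generator does **not** emulate: linkage disequilibrium beyond
HBD structure, recombination-map heterogeneity, allele-frequency
spectra from demography, the X chromosome, pedigrees, genotyping error.
A green test therefore establishes algorithmic correctness against the
stated model, not robustness to every artifact of real array data.

## 4. Acceptance-scenario sizing

Two acceptance scenarios were sized by explicit calculation rather than
trial:

* **Closed-form trait shift.** Two cohorts of 5000 (F = 1/16 vs 0) with
  100 loci at $d = 0.5$, $p = 0.5$ give an expected shift of exactly
  $-1.5625$ trait units against a Monte-Carlo SE of about 0.05.
* **Rare-recessive conditioning.** With $L$ rare causal loci of
  dominance $d$, the regression signal scales as $dL\bar p\bar q$ while
  the causal-locus noise SD scales as $d\sqrt{L}$, so the per-replicate
  conditional *t* grows as $\sqrt{L}$. The shipped scenario (n = 2000,
  300 loci of MAF 1–5% at $d = 1.5$, ~1000 common SNPs for `F_GRM`,
  target-F uniform on [0, 0.2]) yields $t \approx 5$ for
  $\beta_{F_{ROH}|F_{GRM}}$, making the required 90% win rate over
  50 replicates essentially deterministic *when the architecture really
  is rare-recessive*. An earlier draft with 60 loci at $d = 3$ had
  $t \approx 1$ — a reminder that under-powered simulation studies of
  this contrast are uninformative rather than conservative.

## 5. Numerical choices and degenerate inputs

* HWE exact test: direct enumeration of the conditional heterozygote
  distribution via log-gamma weights, no mid-p adjustment; p-values of
  outcomes no more probable than observed are summed with a $1+10^{-9}$
  relative guard against ties in floating point.
* `F_outsideROH` with $N' = E'$ returns `NA` with a warning, never a
  silent zero.
* `fit_bivariate()` refuses exposures with $|r| > 0.999$ and advises
  univariate fits.
* PC sign convention: the largest-magnitude loading of each component is
  made positive, so repeated runs are bit-identical.
* GRM eigenvalues slightly negative from floating point are clipped; a
  genuinely indefinite matrix raises an error naming the matrix.
* Strata below 50 samples are skipped with a warning rather than fitted.
* The pipeline derives per-stage seeds from one global seed by a fixed
  hash, so stages are independently reproducible; all outputs are pure
  functions of (inputs, config, seed).

## 6. Known limitations

* The two-step residual regression slightly attenuates effects when the
  exposures correlate with covariates (quantified by the orthogonal-case
  equality test); the one-step joint fit is not implemented.
* `F_ROH` inherits every dialect choice of the caller; comparisons with
  other callers' output should match parameters *and* dialect.
* The Mann-Whitney comparison treats traits as independent observations.
* IBD/PIHAT computation for the duplicate filter is out of scope; a
  precomputed kinship table is required.
* Real-data cohort numbers from controlled-access datasets are not
  reproducible here and are nowhere asserted; all quantitative test
  expectations come from the package's own closed forms, oracles and
  simulations.
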