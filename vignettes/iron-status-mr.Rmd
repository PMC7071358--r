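---
title: "Methods: two-sample Mendelian randomization of iron status and cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization of iron status and cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironmr)
```

## The design

`ironmr` implements summary-level two-sample Mendelian randomization (MR)
for the question of whether systemic iron status causally affects cancer
risk. Genetic variants that shift an iron biomarker — serum iron,
transferrin saturation, log10 ferritin, or serum transferrin — serve as
instrumental variables. Because alleles are assorted at random at
conception, the variant-stratified contrast is protected from the
confounding and reverse causation that afflict observational studies of
iron and cancer, provided the instruments affect cancer only through iron
status.

"Two-sample" means the two association sets come from different studies:
variant–biomarker effects $\hat\beta_j$ (in SD units per effect allele)
from a GWAS of 48,972 European-descent individuals, and variant–cancer
effects $\hat\gamma_j$ (log-odds per allele) from large cancer cohorts —
here a 367,643-person biobank cohort with 324 liver and 810 brain cancer
cases. The three primary instruments are rs1800562 and rs1799945 in *HFE*
and rs855791 in *TMPRSS6*, mutually uncorrelated ($r^2 < 0.01$) and
responsible for most of the instrumented variance of each biomarker.

## Estimators

All estimates are log odds ratios of cancer per SD of the genetically
predicted biomarker; 95% intervals use $z_{0.975} = 1.959964$ throughout.

**Wald ratio.** Per variant, $\hat\theta_j = \hat\gamma_j / \hat\beta_j$.
The default standard error is first-order,
$se(\hat\theta_j) = se(\hat\gamma_j)/|\hat\beta_j|$, which ignores the
uncertainty of the exposure beta; a second-order option adds it. First
order is the package default because it makes the per-variant z-statistic
(and p) equal that of the variant–outcome association — exactly the
pattern visible in the published per-variant rows, where each variant
shows the same p-value in all four biomarker columns.

**IVW.** With weights $w_j = se(\hat\theta_j)^{-2}$,
$\hat\theta = \sum w_j \hat\theta_j / \sum w_j$ and
$se_{fixed} = (\sum w_j)^{-1/2}$. The random-effects form is
*multiplicative*: the SE is inflated by
$\phi = \max\{1, \sqrt{Q/(L-1)}\}$, leaving the point estimate unchanged.
This choice is forced by the numbers it must reproduce: for serum
iron → liver cancer the fixed SE is 0.276 while the published interval
(0.81, 7.45) requires exactly the $\sqrt{Q/2}$-scaled SE. An additive
(DerSimonian–Laird) model would not reproduce it.

**Weighted median.** Ratios are sorted, weights normalized to $p_j$, and
the estimate interpolates the weighted empirical CDF at probability 0.5
evaluated at the cumulative midpoints $s_j = \sum_{k<j} p_k + p_j/2$. It
is consistent while valid instruments carry more than half the weight.
The standard error is a parametric bootstrap: each $\hat\theta_j$ is
resampled from $N(\hat\theta_j, se_j)$ and the median recomputed, 10,000
times by default, under a caller-supplied seed (the point estimate never
depends on the bootstrap). The published analysis does not state its
bootstrap settings, nor whether its intervals were normal-based or
quantile-based; normal $\pm 1.96\,se_{boot}$ is the default here, with a
quantile option. Weighted-median CIs are therefore compared against the
published ones only informally.

**MR-Egger.** After orienting every pair so $\hat\beta_j > 0$, weighted
least squares of $\hat\gamma_j$ on $\hat\beta_j$ with a free intercept and
weights $1/se(\hat\gamma_j)^2$. The slope estimates the causal effect
under the InSIDE assumption (pleiotropic effects independent of
instrument strength); a nonzero intercept indicates directional
pleiotropy. Standard errors are the weighted-regression SEs at unit
dispersion inflated by $\max\{1, \sqrt{Q_{res}/(L-2)}\}$, and inference
uses **normal** quantiles. With $L = 3$ this is again dictated by the
reproduced numbers: the published intercept interval for serum
iron → liver, $-0.662$ ($-1.124$, $-0.199$), corresponds to
$se = 0.236$ with a normal 1.96 multiplier; Student t with 1 df would be
several times wider.

**Heterogeneity.** Cochran's
$Q = \sum_j w_j (\hat\theta_j - \hat\theta_{fixed})^2$ on $L-1$ df, and
$I^2 = \max\{0, (Q - df)/Q\} \cdot 100$. The $I^2$ interval is the
test-based interval on $\ln H$ with $H = \max\{1, \sqrt{Q/df}\}$ and the
standard two-case SE (one expression for $Q > L$, another for $Q \le L$;
for $L = 2$ the small-$Q$ variance is undefined and the interval is
reported as the vacuous (0, 100)). The published tables print $I^2$
intervals without naming a method; this conventional one reproduces them
(e.g. 76 (23, 93) for serum iron → liver to within one integer unit), but
the interval is treated as descriptive, not as a reproduction target.

**Power.** For a binary outcome with case fraction $K$, outcome sample
size $n$ and instrument variance explained $R^2$, the causal log-OR has
approximate standard error $[n R^2 K(1-K)]^{-1/2}$, giving power
$\Phi(|\ln OR|\sqrt{n R^2 K(1-K)} - z_{1-\alpha/2})$. At $OR = 1$ this is
$\alpha/2$, and it is symmetric in $OR \leftrightarrow 1/OR$. The formula
is validated by these properties and by monotonicity, not against
published numbers (the original power appendix is not part of the
packaged inputs).

## Back-deriving outcome associations from printed tables

The cancer GWAS summary statistics are not redistributable, but the
published per-variant odds ratios and 95% CIs are, and under first-order
weights they are an invertible function of the underlying
$(\hat\gamma_j, se_j)$ given the exposure betas:
$\theta_j = \ln OR_j$, $se(\theta_j) = (\ln U_j - \ln L_j)/(2 \cdot
1.959964)$, then $\hat\gamma_j = \theta_j \hat\beta_j$ and
$se(\hat\gamma_j) = se(\theta_j)|\hat\beta_j|$. `backfill_from_ratio()`
implements this inversion and `iron_fixtures()` applies it to the bundled
tables, yielding eight harmonized three-variant sets (four biomarkers ×
liver/brain).

The printed inputs carry 2–3 significant figures, so every downstream
comparison budgets for input quantization: recomputed log odds ratios are
compared to published ones within 3% relative error plus an absolute
floor of 0.02 on the log scale (a 2-significant-figure OR near 1 is
quantized at up to ~0.03 in log units).

Two limitations of the printed inputs surfaced during this work and are
reported by `reproduce_published()` rather than hidden:

* the published **brain-cancer MR-Egger rows cannot be regenerated** from
  the printed per-variant rows at all (recomputed slopes of 2.20, 1.26,
  1.73, 1.46 versus printed 0.35, 0.68, 0.36, 1.38). The brain per-variant
  serum-iron column is internally inconsistent — its CIs imply z-scores
  that disagree with the shared per-variant p column, which matches the
  transferrin-saturation column instead — and an Egger regression on three
  points amplifies such input errors strongly. The liver Egger rows, where
  the signal is larger relative to rounding, reproduce fully;
* the rs855791 transferrin→liver CI bound is printed at one significant
  figure (0.01), which moves the recomputed Egger upper CI bound for that
  column beyond the 3% budget while the point estimate still reproduces.

All IVW and weighted-median cells, liver and brain, reproduce.

## Instrument handling

`read_association_table()` parses TSV/CSV summary files with a column
map, is decimal-point locale-independent, refuses rows with missing
beta/SE unless explicitly permitted, and floors p-values printed below
the double-precision underflow limit (the transferrin lead variant's
p = 8.4e-610) at the smallest positive double rather than letting them
collapse to an invalid zero.

`select_instruments()` keeps associations with $p$ below the genome-wide
threshold ($5\times10^{-8}$ by default) and prunes correlated pairs
(caller-supplied $r^2$, threshold 0.01) greedily by smallest p, ties
broken by smaller SE then lexicographic ID. Without a correlation matrix
all variants are assumed independent, with a warning — appropriate here
because the bundled instruments are stated independent.

`harmonize()` aligns outcome to exposure effect alleles. A single strand
interpretation (as-is or A↔T/C↔G complement) must explain both alleles;
mixed interpretations are rejected as incompatible. Palindromic variants
(A/T, C/G) default to the `eaf` policy with a ±0.08 ambiguity window
around frequency 0.5: both frequencies informative and on the same side —
keep; opposite sides — flip; otherwise exclude. `strict` and `drop`
policies are available. When a table omits the other allele (the bundled
instrument table prints effect alleles only), orientation is inferred
from the effect allele alone and a mismatch is an error, since a swap
cannot be told from a strand difference. The bundled harmonized sets are
aligned by construction and do not pass through this code path.

One naming quirk of the source tables is resolved in the fixtures: the
instrument table's fourth beta column is headed "Ferritin, g/L" but is
treated as **serum transferrin** — it has exactly the eight entries of
the transferrin instrument set, includes rs8177240 in *TF* (the
transferrin locus, beta 0.380), and its signs carry the inverse
iron–transferrin relationship used throughout the pooled tables.

## The synthetic-data generator

`simulate_two_sample()` emulates the study's data structure so every
estimator is testable with known truth. Under a mandatory seed:
effect-allele frequencies uniform on (0.05, 0.95); true exposure effects
$\beta_j$ standard-normal draws rescaled so
$\sum_j 2p_j(1-p_j)\beta_j^2$ equals the target variance explained
(3.4% at the serum-iron default); sampling noise with
$se(\hat\beta_j) = [2p_j(1-p_j)n_{exp}]^{-1/2}$ and
$se(\hat\gamma_j) = [2p_j(1-p_j)n_{out}K(1-K)]^{-1/2}$; variants
unlinked, matching the stated independence of the real instruments.

Pleiotropic effects $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha)$ enter in
the **exposure-increasing-allele frame**:
$\gamma_j = \theta\beta_j + \mathrm{sign}(\beta_j)\,\alpha_j$. This is
deliberate: directional pleiotropy is only defined relative to a fixed
orientation, and effects attached to an arbitrary allele labeling would
average to zero after the orientation step every Egger implementation
performs, making $\mu_\alpha$ unrecoverable in principle. InSIDE
violation is modelled by rank-reordering the $\alpha_j$ against
$|\beta_j|$ (Gaussian rank jitter, Spearman ≈ 0.8–0.9), preserving the
marginal distribution.

What the generator does *not* model: linkage disequilibrium, winner's
curse in instrument discovery, sample overlap between the two studies,
non-collapsibility of the odds ratio, or the real joint EAF–beta
distribution of the iron loci (the real instruments are carried by the
fixtures, not simulated). Passing calibration tests therefore shows the
estimators are implemented correctly, not that the design is robust to
those unmodelled features.

`cohort_scenario()` pins configurations to the study scale: exposure GWAS
of 48,972; outcome cohort of 367,643 with 324 (liver), 810 (brain) or
75,037 (overall) cases; three instruments.

## Calibration results and problem sizes

The analysis scripts and acceptance tests run, and the statements below
are exactly what they compute:

* at $L = 30$, $n = 10^6$ per study, $K = 0.1$, $R^2 = 0.1$ (chosen so
  Monte-Carlo error is well inside the ±0.01 assertion bands), 300–500
  replicates: mean IVW within ±0.01 of $\theta = 0.2$; with
  $\mu_\alpha = 0.05$ the mean Egger intercept is within ±0.01 of 0.05
  while IVW is biased far upward; under InSIDE violation the Egger slope
  is visibly biased too (directional check only);
* type-I error of the IVW test at $\theta = 0$, $L = 3$, over 1000
  seeded replicates lies in 0.05 ± 0.02. The calibration run uses the
  fixed-effects form: with the multiplicative inflation floored at 1 the
  random-effects test is conservative by construction at small $L$, so
  the size check targets the underlying Wald test, which is the one with
  a nominal size to verify;
* at the liver scale the sampling SD of the IVW log-OR is ≈ 0.3, and the
  analytic power at $OR = 1.5$ per SD is 0.27 — the design is genuinely
  low-powered for moderate effects, which is why the reproduced intervals
  are wide.

## Numerical choices

* $z_{0.975}$ fixed at 1.959964 everywhere (reproduces the printed CIs).
* P-values are reported at full precision; no multiple-testing
  correction anywhere, matching the source analysis's interpretive (not
  threshold-based) use of p-values.
* Weighted-median interpolation at the boundary: the cumulative
  midpoints satisfy $s_1 \le 0.5 \le s_L$ for any weights, so the
  boundary clauses (take an extreme ratio) are defensive only.
* Degenerate inputs error early and by name: zero exposure betas,
  non-positive SEs, zero-width CIs in the back-derivation, correlation
  matrices missing a retained pair.
* Estimator grids mark infeasible cells (weighted median or Egger on
  fewer than 3 variants after exclusion) as `NA` rows rather than
  failing the whole run.

## Limitations

Beyond the printed-input issues above: the package reproduces only the
liver and brain columns of the published analysis, because only their
per-variant statistics are printed — the remaining 21 cancer outcomes are
supported by the schema but carry no bundled outcome data. The
all-variant (5/6/8-instrument) sensitivity analyses likewise cannot be
reproduced from the packaged inputs and are exercised on synthetic data
instead. Everything here concerns iron status within its physiological
range, instrumented by common variants; nothing supports extrapolation to
iron overload states.
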