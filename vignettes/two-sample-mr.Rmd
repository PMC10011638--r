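---
title: "Two-sample Mendelian randomization with mrflow: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflow)
```

## The causal model and its assumptions

Two-sample Mendelian randomization estimates the causal effect $\theta$
of an exposure $X$ on an outcome $Y$ using $J$ genetic variants as
instruments, with the SNP–exposure associations
$(\hat\beta_{Xj}, \sigma_{Xj})$ and SNP–outcome associations
$(\hat\beta_{Yj}, \sigma_{Yj})$ drawn from two different studies'
summary statistics. Three core conditions make a variant a valid
instrument: it is associated with the exposure (relevance); it is
independent of confounders of the exposure–outcome relation
(independence); and it affects the outcome only through the exposure
(exclusion restriction). Under these conditions each instrument supplies
a consistent ratio estimate
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$, and the estimators below
differ only in how they pool the $\hat\theta_j$ and in which violations
of the exclusion restriction (horizontal pleiotropy) they tolerate.

Relevance is enforced empirically by the selection stage: genome-wide
significance filtering ($p < 5\times10^{-8}$), LD clumping so that
retained instruments are approximately independent
($r^2 < 0.001$ within $\pm 10{,}000$ kb by default), and the
per-instrument strength statistic $F_j = \hat\beta_{Xj}^2/\sigma_{Xj}^2$.
The default `f_min = 0` makes the F screen report-only — the convention
in applied work is to inspect the F range rather than exclude — while
`f_min = 10` applies the usual weak-instrument cutoff.

## Estimators

All combined estimators consume first-order Wald ratios: the ratio SE is
$\sigma_{Yj}/|\hat\beta_{Xj}|$, which ignores the exposure-side sampling
error. This is the standard two-sample convention for strong instruments,
and it has a structural payoff: the inverse-variance-weighted (IVW)
estimate becomes *exactly* weighted least squares of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ through the origin with weights $1/\sigma_{Yj}^2$. The
test suite exploits this identity by checking the package's closed-form
estimators against independently coded `lm()` fits to $10^{-8}$.

**IVW.** $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$ with
$w_j = 1/\mathrm{SE}(\hat\theta_j)^2$, fixed-effects SE
$(\sum w_j)^{-1/2}$. The random-effects variant is *multiplicative*: the
SE is inflated by $\max(1, \sqrt{Q/(J-1)})$ where $Q$ is Cochran's
statistic, so the point estimate is identical between modes and the RE
SE can never fall below the FE SE. An additive RE flavour would change
the point estimate; the multiplicative form was chosen because it is the
one implied by over-dispersed weighted regression and is what the
dominant MR software reports. IVW p-values use the standard normal;
Egger p-values use $t_{J-2}$. The normal-vs-$t$ choice for IVW is not
settled in the literature; the normal was chosen and is used
consistently.

**MR-Egger.** Weighted regression
$\hat\beta_{Yj} = \alpha + \theta\hat\beta_{Xj}$ with weights
$1/\sigma_{Yj}^2$, after orienting every instrument so
$\hat\beta_{Xj} > 0$ (the intercept is not invariant to allele coding;
orientation is applied automatically inside `mr_egger()`). The intercept
estimates the average directional pleiotropic effect; the slope is a
consistent causal estimate provided instrument strength is independent
of the direct effects (InSIDE). Standard errors are scaled by a residual
dispersion floored at 1 — the regression is never allowed to be more
precise than its weights claim ("no super-efficiency"). The known blind
spot is deliberate and documented: directional pleiotropy *correlated*
with instrument strength is absorbed into the slope and escapes the
intercept test.

**Weighted median.** Order the ratios, form cumulative normalized
weights $s_j = \sum_{k\le j} w_k - w_j/2$, and interpolate linearly at
$s = 0.5$. Consistent when instruments carrying at least half the weight
are valid. The SE comes from a parametric bootstrap (each ratio redrawn
from $N(\hat\theta_j, \mathrm{SE}_j)$, default 1000 replicates); a seed
is required, not optional, so results are reproducible by construction.

**Penalized IVW.** Each SNP's Cochran-Q contribution
$q_j = w_j(\hat\theta_j - \hat\theta_{IVW})^2$ is referred to
$\chi^2_1$, giving $p_j$, and the weight becomes
$w_j \min(1, 20p_j)$. The constant 20 follows the established
penalized-weights convention: instruments with $p_j \ge 0.05$ keep their
full weight, and the penalty decays linearly below that. The pipeline
adds this row whenever Cochran's Q has $p < 0.05$.

**Routing.** One surviving instrument reports the Wald ratio only (no
heterogeneity statistics are defined); two instruments report the IVW
pair plus Cochran's Q; three or more add Egger, the weighted median,
Rücker's Q, the intercept test and leave-one-out; MR-PRESSO requires at
least four. The headline row is IVW-RE.

## Sensitivity analysis

Cochran's $Q = \sum_j q_j$ (df $J-1$) tests homogeneity about the IVW
estimate; Rücker's $Q'$ is the weighted residual sum of squares about
the Egger fit (df $J-2$) and satisfies $Q' \le Q$ algebraically — both
the decomposition $\sum q_j = Q$ and the inequality are asserted as
invariants in the test suite. The $p < 0.05$ heterogeneity threshold
triggers the penalized-IVW row and flags the headline as
heterogeneity-affected.

MR-PRESSO compares each SNP's observed outcome effect with the effect
expected from the IVW slope fitted *without* it, and refers the weighted
residual sum of squares to a simulated no-pleiotropy null: `n_sim` times
(default 1000), $\beta_{Xj}^* \sim N(\hat\beta_{Xj},\sigma_{Xj})$ and
$\beta_{Yj}^* \sim N(\hat\beta_{Xj}\hat\theta_{(-j)}, \sigma_{Yj})$ are
redrawn and the statistic recomputed. Empirical p-values use
$(\#+1)/(n_{sim}+1)$ smoothing so the floor is $1/(n_{sim}+1)$ and zero
is never reported. Per-SNP outlier p-values come from each SNP's own
simulated residual distribution, compared at the Bonferroni-adjusted
level $\alpha/J$. The distortion test reports the two-sided empirical
probability, under random removal of as many SNPs as were flagged, of an
IVW shift at least as large as the observed one; with no flagged
outliers it is `NA` rather than 1, to distinguish "not applicable" from
"tested and null". In the pipeline, MR-PRESSO runs once, before the
estimator suite, and flagged SNPs are removed from *all* subsequent
methods (not just IVW) — a uniform-exclusion policy that keeps every
reported row on the same instrument set; removed SNPs are logged in the
provenance table.

Leave-one-out uses IVW-RE, matching the headline estimator, and flags
entries whose interval overturns the full-set sign conclusion. The
funnel table emits ratio-versus-precision columns only; symmetry is a
visual diagnostic and no statistic is attached to it.

## Harmonization policy

Allele reconciliation is mechanical except for palindromic (A/T, C/G)
variants, where labels carry no strand information. The package resolves
these by effect-allele frequency: keep only when both frequencies are
available and both lie outside $[0.5-b, 0.5+b]$, with matching sides
implying matching strands and discordant sides implying a strand flip.
The band default $b = 0.08$ (ambiguous within $[0.42, 0.58]$) is the
widely used conservative convention. Failures never abort an analysis;
they become dropped records with machine-readable reasons
(`palindromic_ambiguous`, `incompatible_alleles`, `missing_in_outcome`),
and the audit log plus the provenance table let attrition be reconciled
exactly at every stage. Duplicate outcome rows for one rsid resolve to
the smallest SE — deterministic and precision-favouring.

## The synthetic generator: what it emulates and what it does not

`generate_study()` draws, per SNP: a MAF uniform on
(`maf_low`, `maf_high`); exposure/outcome SEs
$1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$, the standardized-trait
formula, reused for binary outcomes with $n$ read as an effective
log-odds-scale sample size; a true effect $\gamma_j$ sized to hit a
target F drawn uniformly from `f_range` (default 30–400, spanning the
instrument-strength ranges typical of published thyroid-trait
instruments); a direct effect $\alpha_j \sim N$(`pleio_mean`,
`pleio_sd`) with `n_outliers` SNPs instead given a fixed
`outlier_offset`; and observed effects
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj})$,
$\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj})$.
Default sample sizes (72,167 exposure; 287,132 outcome) mirror a
well-powered thyroid-trait-to-disease design. All randomness flows from
one seed, and generation provably does not disturb the caller's RNG
stream.

The `gamma_sign` option records a genuine identifiability fact: with
alleles coded as a GWAS reports them (`"random"`, the default), positive
and negative true effects coexist, and re-orienting instruments to
$\hat\beta_{Xj}>0$ flips the sign of each flipped SNP's direct effect —
so a nonzero `pleio_mean` is *not* recoverable as an Egger intercept.
Simulations of directional pleiotropy therefore use `"positive"`
(instruments pre-coded by exposure-increasing allele), and the package's
tests verify intercept tracking only in that regime.

What the generator does **not** emulate: LD between instruments (the LD
matrix defaults to the identity; block structure can be attached for
clumping tests), winner's-curse bias from selecting instruments in the
same sample that estimated them, sample overlap between the two studies,
allele-frequency differences between populations, and non-normal effect
distributions. Passing recovery tests on this generator therefore
certifies the estimators and the plumbing, not robustness to those
real-data complications.

The regime fixtures (`fixture_study()`) reproduce, by construction
rather than calibration, the instrument-count regimes of a four-exposure
thyroid-function analysis: 39 surviving of 61 candidates
(many-instrument), 16 of 31 (moderate), a single strong instrument
(rs2235544, the Wald-only path), and 4 of 5 with heterogeneity
(few-instrument). Attrition is deterministic: sub-threshold candidates
have true effect zero, and clumped candidates echo an index SNP at 0.95
times its effect from 5 kb away at $r^2 = 0.9$ — the index is redrawn
until $p < 5\times10^{-9}$ so the echo still clears $5\times10^{-8}$ and
drops by clumping, never by the p filter. The heterogeneous regime uses
deterministic alternating direct effects of $\pm 2.2$ outcome-SE units:
large enough that Cochran's Q (df 3) rejects reliably, small enough that
individual SNPs usually survive the Bonferroni-adjusted MR-PRESSO
outlier test, and independent of the fixture seed.

## Numerical choices and degenerate inputs

- p-values of exactly 0 in source files are clamped to the smallest
  positive double with a warning (log-scale diagnostics need
  positivity); simulated p-values are floored the same way.
- Clumping ties on p break by smaller genomic position, then
  lexicographic rsid, making selection order-independent; candidates
  with unknown position are retained as their own clumps; pairs absent
  from the LD matrix are a hard error unless explicitly treated as
  independent (`allow_missing_ld`), which warns.
- The Egger system is solved in closed form from the 2×2 normal
  equations; an exact affine dataset yields $Q' = 0$ to machine
  precision.
- Empty estimator inputs are hard errors; a single instrument collapses
  IVW to the Wald ratio with a warning; below-minimum counts for
  Egger/median/PRESSO are hard errors in the functions and
  "not-estimable" markers in the pipeline, which continues.
- 95% CIs are estimate $\pm\,1.96\,$SE on the linear scale and are
  exponentiated exactly for binary outcomes (`or = exp(estimate)`).

## Problem sizes used by the verification suite

The package's statistical guarantees are checked at sizes chosen to make
Monte-Carlo error small relative to the asserted bands: IVW bias
(|bias| < 0.02) and CI coverage (93–97%) over 500 replicates at
$\theta=0$ and 200 at $\theta=0.3$ with $J=50$; Egger-intercept type-I
error (5% ± 2%) over 2000 replicates at $J=30$; MR-PRESSO detection on a
21-instrument study with one injected outlier at 10× the ratio spread,
$n_{sim}=1000$; oracle equivalence on 100 random instances. The
acceptance script (`scripts/acceptance.R`) recomputes all of these from
scratch under a caller-supplied seed.

## Known limitations

First-order ratio SEs understate uncertainty for weak instruments
(second-order corrections are out of scope); no mode-based, robust
adjusted profile score, multivariable or Steiger-directionality methods
are included; LD clumping requires a user-supplied r² matrix (the
package never computes LD from genotypes, and proxy-SNP substitution is
not attempted); and the Egger intercept's InSIDE blind spot applies as
discussed above.
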