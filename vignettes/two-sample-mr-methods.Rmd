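---
title: "Two-sample Mendelian randomization with mrsummary: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrsummary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsummary)
```

## The causal model

Mendelian randomization (MR) uses genetic variants as instrumental
variables for an exposure. Because alleles assort randomly at conception, a
SNP that (i) is robustly associated with the exposure, (ii) shares no
common cause with the outcome, and (iii) affects the outcome only through
the exposure, identifies the causal effect of the exposure free of the
confounding and reverse causation that afflict observational estimates.

In the two-sample design the SNP–exposure effects $\hat\beta_{X_j}$ (with
standard errors $\sigma_{X_j}$) and SNP–outcome effects $\hat\beta_{Y_j}$
(with $\sigma_{Y_j}$) come from separate GWAS of non-overlapping samples.
Under the instrumental assumptions each SNP supplies a Wald ratio
$\hat\theta_j = \hat\beta_{Y_j} / \hat\beta_{X_j}$ estimating the same
causal parameter $\theta$ — here the log-odds of disease per standard
deviation of the exposure. The package's worked setting is leukocyte
telomere length (exposure, SD units, GWAS meta-analysis of up to 78,592
Europeans) against total osteoarthritis (outcome, log-odds, UK Biobank,
10,083 cases / 40,425 controls); the 20-SNP instrument panel with its
per-allele effects on both traits ships as a transcribed fixture
(`loadTelomereOA()`), with provenance recorded in
`inst/extdata/telomere_manifest.yaml`.

## Instrument preparation

**Harmonization** (`harmonize()`) aligns every shared SNP to the exposure's
effect allele: a swapped allele pair negates the outcome beta exactly once
(`flipped`), a strand-complement representation of the same pair is
resolved likewise, and irreconcilable pairs are dropped with a logged
reason. Palindromic SNPs (A/T, C/G) cannot be strand-resolved from alleles
alone; they are **retained** and flagged rather than discarded, matching
the analysis the fixture reproduces. Frequency-based strand inference for
palindromes exists behind `inferStrand = TRUE` but is off by default
because it is unreliable for frequencies near 0.5. Proxy substitution is a
data contract: the caller supplies a proxy table and a proxy stands in only
at $r^2 > 0.8$; the package performs no reference-panel lookups.

**LD pruning** (`pruneLd()`) applies greedy clumping: rank instruments by
exposure p-value (ties by $|\beta_X|/\sigma_X$, then rsid), keep each
unless its $r^2$ with an already-kept SNP on the same chromosome within
the window (default 5,000 kb) exceeds the threshold (default 0.05). The
kept set therefore depends only on the instrument set, the LD table and
the threshold — not on input order. Pairwise LD is a user-supplied input;
in-window pairs missing from the table are treated as $r^2 = 0$ with a
warning. The packaged LD table carries synthetic representative values
(0.50 for the two TERT SNPs 1,220 bp apart, 0.01 for the three
chromosome-20 SNPs retained as independent sentinels) because only the
threshold relations, not the exact coefficients, were published; any
values on the same sides of 0.05 give the identical instrument set.

**Confounder exclusion** (`excludeByList()`) removes rsids named on a
manually curated list (here rs73624724, associated with body-fat
percentage) — database screening itself is outside the package.

**Instrument strength**: per SNP,
$$R^2 = \frac{2\,EAF(1-EAF)\beta^2}{2\,EAF(1-EAF)\beta^2 +
2\,EAF(1-EAF)N\sigma^2}, \qquad F = \frac{R^2 (N-2)}{1-R^2},$$
with $F \ge 10$ the conventional strength bar. When per-SNP sample sizes
are unavailable, `weakInstrumentReport()` defaults to $N = 78{,}592$, the
headline size of the telomere-length meta-analysis, which reproduces the
published per-SNP $R^2$/$F$ values exactly (display rounding: $R^2$ to 4
decimals, $F$ to integer).

## Estimators

All estimators consume the harmonized set $(\hat\beta_{X_j},
\hat\beta_{Y_j}, \sigma_{Y_j})$ and report the causal log-odds per SD with
a normal-theory 95% CI on the odds-ratio scale.

* **IVW** (`mrIVW()`): weighted least squares of $\hat\beta_Y$ on
  $\hat\beta_X$ through the origin with weights $1/\sigma_Y^2$ —
  algebraically the inverse-variance pooling of Wald ratios. The default
  mode is multiplicative random effects: the model SE is scaled by
  $\max(1, \sqrt{Q/(k-1)})$, so overdispersed sets get wider intervals
  while homogeneous sets reduce to the fixed-effect answer; the point
  estimate is identical in both modes. With one instrument the formula
  reduces to the Wald ratio, and the function permits that case with a
  message. Consistent only when every instrument is valid.
* **Weighted median** (`mrWeightedMedian()`): the ratio at cumulative
  weight 0.5 of the inverse-variance-weighted ratio distribution, via
  linear interpolation of midpoint cumulative sums
  $s_j = \sum_{i \le j} w_i - w_j/2$. Consistent when at least half the
  weight comes from valid instruments. The SE is a parametric bootstrap
  (default `nBoot = 1000`, `seed = 2021`); the point estimate does not
  depend on it, and `nBoot = 0` skips it.
* **MR-Egger** (`mrEgger()`): the same regression with an unconstrained
  intercept, after orienting all $\hat\beta_X \ge 0$ (negating pairs
  jointly). The intercept estimates average directional pleiotropy; the
  slope remains consistent under InSIDE (pleiotropy independent of
  instrument strength) even if all instruments are invalid. SEs use
  multiplicative residual scaling floored at 1; p-values use $t_{k-2}$.
* **Cochran's Q** (`mrCochranQ()`):
  $Q = \sum_j w_j (\hat\theta_j - \hat\theta_{IVW})^2$ with
  $w_j = (\hat\beta_{X_j}/\sigma_{Y_j})^2$, against $\chi^2_{k-1}$; excess
  Q signals heterogeneity from pleiotropy or invalid instruments. The
  Egger intercept test is reported alongside.
* **MR-PRESSO** (`mrPresso()`): residual sum of squares against
  leave-one-out IVW slopes, with a parametric simulated null
  ($\beta_X^* \sim N(\hat\beta_X, \sigma_X)$,
  $\beta_Y^* \sim N(\hat\beta_{-j}\hat\beta_{X_j}, \sigma_Y)$,
  leave-one-out slopes recomputed per simulated dataset). The global test
  uses the smoothed exceedance p $(r+1)/(n_{sim}+1)$; the per-SNP outlier
  test compares each observed weighted squared residual to its simulated
  distribution at the Bonferroni level $\alpha/k$; the distortion test
  compares raw vs outlier-corrected IVW slopes against removals of random
  same-size subsets. Defaults `nSim = 1000`, `alpha = 0.05`,
  `seed = 2021`. With no outliers the reported estimate is bit-identical
  to raw IVW. Leave-one-out residuals make the test sensitive, but a
  strong outlier contaminates the other SNPs' leave-one-out slopes, so a
  valid SNP is occasionally co-flagged alongside a true outlier; the
  procedure is single-pass (no iterative re-testing).
* **Leave-one-out** (`leaveOneOut()`): $k$ IVW refits each omitting one
  SNP, flagging omissions that change the qualitative conclusion.
* **E-value** (`eValue()`): the minimum risk-ratio association an
  unmeasured confounder needs with both exposure and outcome to explain
  away the estimate: $E = RR + \sqrt{RR(RR-1)}$ with $RR$ the (inverted if
  protective) risk ratio, approximated by the OR for a rare outcome or
  $\sqrt{OR}$ otherwise; the CI E-value is 1 when the interval crosses 1.

`runPipeline()` sequences the stages with per-stage error context, logs
every exclusion exactly once with a machine-readable reason, and is
deterministic given its seed. `reproduceTelomereOA()` runs it on the
packaged panel. This being an R analysis package, the exported functions
and this vignette are the interface; there is no shell front-end.

## The synthetic-data generator

`simulateSummary()` draws, per SNP: an effect-allele frequency uniform on
(0.1, 0.9); a true exposure effect $|N(0, 0.05)| + 0.02$ per allele
(matching the 0.03–0.14 instrument range realistic for a polygenic
quantitative trait; effect alleles are oriented exposure-increasing, the
panel convention — estimators are invariant to joint sign flips); the
exposure SE $1/\sqrt{2p(1-p)n_{exp}}$ for a standardized trait; the
outcome SE $1/\sqrt{2p(1-p)n_{out}\phi(1-\phi)}$ on the log-odds scale
with case fraction $\phi$; a pleiotropy intercept $\alpha_j = 0$ for valid
SNPs and $N(\alpha_{mean}, \alpha_{sd})$ for the configured invalid
fraction (balanced mode forces $\alpha_{mean} = 0$); the true outcome
effect $\theta\beta_X^{true} + \alpha_j$; and observed betas with normal
noise at the reported SEs. Defaults mirror the worked setting:
$k = 18$, $n_{exp} = 78{,}592$, $n_{out} = 50{,}508$, $\phi = 0.1996$
(10,083/50,508). These sample sizes reproduce the fixture's SE ranges
(exposure ≈ 0.006 at common frequencies, outcome ≈ 0.016–0.053), which is
the check that fixed them. Outcome effects are simulated directly on the
log-odds scale — no individual-level case-control draws — because the
estimators consume summary statistics only. No LD between instruments is
simulated (instruments are post-pruning by construction), `noiseScale = 0`
yields noiseless statistics on which every estimator recovers $\theta$ to
machine precision, and the truth record stores $\theta$, per-SNP validity
and $\alpha_j$. `simulateTelomerePanel()` rejection-samples 20
genome-wide-significant SNPs matching the fixture's marginal ranges for
realistic-scale fuzzing.

What passing simulation tests do **not** show about real data: the
generator has no weak instruments by construction at these sample sizes,
no sample overlap between the two GWAS, no LD, no allele-frequency
mismatch between studies, and pleiotropy that satisfies InSIDE; violations
of any of these in real data degrade the estimators in ways the suite does
not measure.

## Numerical and validation choices

* Display rounding follows the reporting convention (OR/CI and Q to 2 dp,
  p to 3 dp, $R^2$ to 4 dp, F to integer); full precision is kept
  internally, and estimates are matched to published values through the
  rounded OR/CI rather than p-values, whose z- vs t-conventions vary.
* A read-time check rejects rows whose reported p disagrees with
  $2\Phi(-|\beta|/\sigma)$ by more than a factor of 10 **and** whose
  implied z disagrees by more than 10%; the z branch exists because
  two-significant-figure rounding of $\beta/\sigma$ legitimately moves
  $\log_{10} p$ by several decades in the deep tail.
* Smoothed empirical p-values $(r+1)/(n_{sim}+1)$ avoid zeros; all
  stochastic components (WM bootstrap, PRESSO) take explicit seeds and
  restore the caller's RNG state.
* Greedy lowest-p clumping is the standard convention; tie-breaks are
  fixed (|z|, then rsid) so pruning is order-free.
* Validation problem sizes: parameter recovery uses 500 replicates at
  $k = 50$; the weighted-median breakdown comparison 300 replicates at
  $k = 20$ with 40% invalid instruments ($\alpha_{mean} = 0.05$); IVW
  type-I error 1,000 null replicates at $k = 18$ with balanced pleiotropy
  ($\alpha_{sd} = 0.01$, 30% invalid — modest pleiotropy comparable to
  the outcome SEs); outlier detection 100 seeds at $k = 10$ with a 10-SE
  planted shift plus 200 clean-null replicates. These sizes give
  Monte-Carlo standard errors small enough to resolve the biases under
  test while keeping the suite fast.

## Limitations

Univariable MR only: no multivariable or mode-based estimators, no Steiger
filtering, no colocalization, no conditional F-statistics. LD coefficients
and proxies are inputs, never computed or queried. Site-specific
osteoarthritis subgroups (knee, hip) are not part of the packaged fixture
because their per-SNP outcome effects were not published; the package
reproduces the total-OA analysis and validates subgroup-style questions
only through simulation. The E-value addresses unmeasured confounding of
the observational exposure–outcome association, not violations of the
instrumental assumptions themselves.
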