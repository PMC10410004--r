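---
title: "Two-sample Mendelian randomization with mrsummary: models, choices, limits"
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

## The model

Two-sample Mendelian randomization (MR) treats genetic variants as
instrumental variables for an exposure. For instrument $j$ we observe, from
two independent GWAS, the per-allele exposure association
$\hat\gamma_j \sim N(\gamma_j, \sigma_{x j}^2)$ and the outcome association
$\hat\Gamma_j \sim N(\Gamma_j, \sigma_{y j}^2)$. Under the linear structural
model with causal effect $\theta$ and per-SNP direct (pleiotropic) effect
$\alpha_j$,

$$\Gamma_j = \theta\,\gamma_j + \alpha_j .$$

A valid instrument has $\alpha_j = 0$; every estimator in the package is a
different compromise about how many $\alpha_j$ may be non-zero and how they
behave. All computation is on summary statistics — no genotype-level data
are touched.

### Instrument selection

Candidates are genome-wide significant SNPs ($p < 5\times10^{-8}$, strict),
greedily clumped so that only the most significant SNP within 1 Mb (and,
when a pairwise LD matrix is supplied, with $r^2 \le 0.001$) survives.
Instrument strength is graded per SNP by

$$R^2 = 2\beta^2\,\mathrm{EAF}\,(1-\mathrm{EAF}), \qquad
F = \frac{R^2}{1-R^2}\cdot\frac{N-k-1}{k},$$

and SNPs with $F < 10$ (strict) are excluded as weak. Two conventions here
deserve attention:

* **$k$ convention.** $k$ is the size of the candidate set at the moment $F$
  is evaluated (the 14-SNP overweight table packaged as
  `overweight_instruments()` uses $k = 14$), applied uniformly to all SNPs,
  and overridable via `filter_weak(k =)`. Published per-SNP $F$ values for
  this table are mutually inconsistent under any single $(N, k)$ when
  recomputed from the rounded $\beta$/EAF (the weak SNP reproduces at
  $k = 14$; two others better match $k = 13$), so the package reproduces the
  exactly recoverable cases and leaves the convention explicit rather than
  guessing at unrounded upstream inputs.
* **Tie-breaks in clumping.** Equal p-values are resolved by smaller SE,
  then lexicographic SNP id, which makes the pruned set independent of input
  row order.

Positions are 1-based base pairs; chromosome labels are opaque strings
compared by equality (`"1" != "chr1"`), and the distance rule is inclusive
($|\Delta\mathrm{pos}| \le$ window). The packaged overweight table carries
approximate GRCh37 positions for its 14 loci because the source table
reports only chromosome numbers; they matter only to the distance rule
(all 14 loci are mutually > 1 Mb apart).

### Harmonization

Records are matched by SNP id and aligned to the exposure's effect allele:
swapped alleles negate the outcome beta and complement its frequency; strand
complements (A/T, C/G letter swaps) are resolved first; palindromic SNPs are
aligned by minor-allele agreement only when both frequencies are at least
`palindrome_window` (default 0.08) away from 0.5, and dropped as ambiguous
otherwise. A palindromic SNP missing a frequency is dropped with reason
`invalid_record` — the ambiguity cannot even be assessed, and dropping with
an audited reason was preferred to failing the whole run or imputing. The
audit (`dropped` with reasons `missing_in_outcome`, `allele_mismatch`,
`ambiguous_palindrome`, `invalid_record`) is part of every pipeline report.
Harmonization never changes any $|\beta|$ or SE.

## The estimator battery

With Wald ratios $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ and first-order
SEs $\sigma_j = \sigma_{yj}/|\hat\gamma_j|$ (weights $w_j = \sigma_j^{-2}$):

* **IVW-FE**: $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$, SE
  $(\sum w_j)^{-1/2}$ — efficient when all instruments are valid.
* **IVW-MRE**: same point estimate; SE inflated by
  $\sqrt{\max(1, Q/(J-1))}$, where $Q$ is Cochran's statistic below. The
  floor at 1 stops under-dispersion from shrinking intervals.
* **MR-Egger**: weighted regression of $\hat\Gamma$ on $\hat\gamma$ *with*
  intercept after re-signing each record to $\hat\gamma_j \ge 0$ (the
  estimator's identifiability convention; the orientation is otherwise
  arbitrary in summary data). Coefficient variances carry the
  overdispersion factor $\max(1, \mathrm{RSS}_w/(J-2))$ and inference uses
  $t_{J-2}$. The intercept estimates the mean directional pleiotropy under
  InSIDE (instrument strength independent of direct effects).
* **Simple/weighted median**: linear interpolation of the ordered ratios at
  cumulative weight 0.5 ($s_j = \sum_{i\le j} w_i - w_j/2$); consistent when
  instruments carrying half the weight are valid.
* **Simple/weighted mode**: argmax of a normal-kernel density of the ratios
  with bandwidth `bandwidth_factor` $\times\,0.9\min(\mathrm{sd},
  \mathrm{mad})J^{-1/5}$ (modified Silverman), on a 1024-point grid spanning
  the ratio range; consistent when the largest group of agreeing instruments
  is valid.

Median and mode SEs come from a seeded parametric bootstrap (default
`n_boot = 1000`; each $\hat\theta_j$ resampled from
$N(\hat\theta_j, \sigma_j)$). CIs use $\pm 1.96$ SE (normal) everywhere
except Egger ($t_{J-2}$). Seeds are mandatory wherever randomness enters —
there is no hidden default in the pipeline configuration.

The first-order ratio SE ignores $\sigma_{xj}$ (the NOME approximation),
matching standard practice; `wald_ratios(second_order = TRUE)` provides the
corrected SE. One measurable consequence, seen in the package's own
simulations: with strong-but-finite instruments the Egger slope is
attenuated by roughly $E[\sigma_x^2]/\mathrm{var}(\gamma)$ (about 5% in the
default generator world), which displaces the intercept by about +0.001 —
the tests assert intercept centering only up to this bound.

## Sensitivity analyses

* **Cochran's Q** with the same first-order weights as IVW (coherence
  between test and estimator; the Egger-residual variant is a documented
  alternative, not implemented), $p$ from $\chi^2_{J-1}$.
* **Heterogeneity switch**: the primary estimate is IVW-FE unless
  $p_Q < 0.05$ (strict), in which case IVW-MRE is reported — the decision
  rule used in the applied literature this package operationalizes.
* **Leave-one-out**: J re-estimates, each without one instrument. "Less
  robust" is qualitative in prose; the operational flag here is a sign
  change of the estimate or a change in whether the 95% CI crosses zero,
  relative to the all-instrument reference.
* **MR-PRESSO**: the observed residual sum of squares about leave-one-out
  IVW fits, compared against parametric resimulations (global test, add-one
  empirical $p \ge 1/(1+n_\mathrm{sim})$, so never zero); per-SNP outlier
  tests Bonferroni-adjusted over $J$; and a distortion test comparing the
  outlier-corrected IVW shift (in percent,
  $100(\hat\theta_\mathrm{corr}-\hat\theta_\mathrm{raw})/|\hat\theta_\mathrm{corr}|$)
  against random same-size removals. Corrected fields are emitted only when
  outliers exist; published tables sometimes print `0 / 1` rows for such
  analyses, whose scale is unclear, and the package reproduces the
  semantics, not those numbers.

## Multivariable and mediation MR

`mvmr_ivw()` regresses outcome effects on an $J\times M$ matrix of exposure
effects (no intercept, weights $\sigma_y^{-2}$, overdispersion
$\max(1,\mathrm{RSS}_w/(J-M))$); with $M=1$ it reduces exactly to
univariable IVW (and its SE to the IVW-MRE SE, since the weighted RSS of the
no-intercept fit equals Q).

`run_mediation()` implements two-step mediation MR: `beta1` (exposure to
mediator) and `beta2` (mediator to outcome) are estimated by univariable MR
through the full pipeline, `beta0` is the total effect, the mediated effect
is `beta1*beta2` with first-order delta SE
$\sqrt{\beta_1^2 s_2^2 + \beta_2^2 s_1^2}$ (approximate — no covariance term
is available across samples), and the mediated proportion
`beta1*beta2/beta0` is emitted only when `beta0` is significant.
Classification follows the significance pattern: all three significant is
partial mediation; paths significant but total not is complete mediation; a
significant total with a null path is no mediation; the remaining patterns
are no causal effect. Two deliberate choices:

* `beta2` is estimated by *univariable* MR on mediator instruments, as the
  two-step procedure literally describes; this conflates direct and
  indirect mediator effects, so the mediator leg *excludes* SNPs that were
  exposure instruments (default, switchable), and an MVMR-based variant is
  the natural extension.
* The classification alpha is a required argument — published practice is
  silent between 0.05 and a Bonferroni-corrected level, so nothing is
  defaulted silently in pipeline mode.

The Bonferroni rule for a trait matrix is $p = 0.05/E/C$ for $E$ exposures
and $C$ outcomes; matrix reports show both nominal p-values and the
threshold flag, since applied reports typically quote nominal values.

## The synthetic-data generator: what it emulates, what it does not

`simulate_study()` draws, per SNP: frequency uniform on (0.05, 0.95); true
exposure effect with magnitude $|N(0.08, 0.02)|$ and random sign (the scale
of published anthropometric instruments, $\beta$ 0.05–0.14); true outcome
effect $\theta\gamma_j + \alpha_j$; summary SEs from the single-SNP
regression approximation $1/\sqrt{2n\,\mathrm{eaf}(1-\mathrm{eaf})}$; and
observed effects around the truth. Defaults emulate a GIANT-scale exposure
GWAS ($n = 158{,}945$) against a UK-Biobank-scale outcome
($n = 472{,}174$) with 50 instruments. Pleiotropy is `none`, `balanced`
($\alpha \sim N(0, 0.002)$) or `directional` ($\alpha$ centered at 0.002
*in the exposure-increasing allele orientation* — with random-sign $\gamma$
an unoriented constant would cancel in ratio space and bias nothing);
`inside_violation` correlates $\alpha$ with $\gamma$. Outliers add a stated
multiple (default 10) of the outcome SE. A configurable fraction of
palindromic (20%) and swapped-orientation (30%) records exercises
harmonization. One derived RNG stream per SNP means adding SNPs never
perturbs earlier draws.

What the generator does **not** emulate — and therefore what a green
calibration test does not establish: LD between instruments (instruments
are independent, the post-clumping assumption), binary-outcome
noncollapsibility (all traits are generated continuous; binary effects in
real data are treated as log odds ratios but never converted), sample
overlap between the two GWAS, population stratification, and
frequency-dependent effect architectures. With 50 candidate instruments the
default world leaves per-SNP $F$ near the conventional cutoff
($R^2 \approx 0.003$, $F \approx 10$ at $k = 50$), which is realistic; tests
that need uniformly strong instruments state a larger sample size
explicitly.

## Numerical and degenerate-input choices

* P-values are floored at the smallest positive double so the (0, 1]
  contract holds even for overwhelming signals.
* Empirical (PRESSO) p-values use the add-one form.
* Weighted-median interpolation clamps to the extreme order statistics when
  0.5 falls outside the $s$-grid.
* Mode bandwidth falls back to the SD when the MAD is zero (replicated
  ratios), and to $10^{-8}$ when both vanish; the grid argmax is then the
  common value.
* Egger and PRESSO refuse fewer than 3 and 4 instruments respectively;
  the pipeline records such refusals as notes instead of failing the run.
* A zero exposure effect makes the Wald ratio undefined and is an error
  naming the SNP (upstream significance filtering makes this unreachable in
  pipeline use).
* Missing EAF is permitted in the data model but every operation needing it
  (R², palindrome resolution) refuses to impute.

## Configuration and reproducibility

The CLI (`inst/cli/mrsummary`; verbs `run`, `matrix`, `simulate`,
`mediate`) reads a JSON configuration with sections mirroring
`analysis_config()` — JSON because it is the one structured-text format
with a guaranteed reader in the deployment environment. Every report embeds
the master seed and package version; all stochastic components (bootstraps,
PRESSO, simulation) draw from streams derived deterministically from that
one seed, and the test suite asserts byte-identical reports under a fixed
configuration.

## Known limitations

* First-order weights everywhere (estimator/test coherence) bring the NOME
  attenuation described above; the second-order ratio SE is available but
  not the default.
* The distortion-test null resamples outlier-sized subsets from the full
  instrument set; implementations differ on sampling from non-outliers
  only, and with few instruments the two differ noticeably.
* The mediated-proportion SE ignores cross-leg covariance (three separate
  GWAS make it unidentifiable anyway) and is flagged approximate.
* Steiger filtering, robust regression variants (MR-Lasso, contamination
  mixture), funnel asymmetry and $I^2$ are deliberately out of scope.
* External lookups (LD reference panels, trait-association scans for
  confounder discovery) are out of scope; LD enters only as a user-supplied
  pairwise $r^2$ table.
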