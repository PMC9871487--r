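---
title: "Two-sample Mendelian randomization with mrkit: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure (for instance a
circulating hormone level) on an outcome (for instance a binary disease
such as glaucoma) from observational data. Because genotypes are fixed at
conception, a variant that (1) is robustly associated with the exposure,
(2) is independent of confounders of the exposure–outcome relation, and
(3) affects the outcome only through the exposure, behaves like a
randomized allocation of exposure levels.

In the *two-sample* design the SNP–exposure and SNP–outcome associations
come from different GWAS cohorts, and only summary statistics are needed:
for SNP $j$, the estimated per-allele effects and standard errors
$(\hat\beta_{Xj}, \sigma_{Xj})$ on the exposure and
$(\hat\beta_{Yj}, \sigma_{Yj})$ on the outcome (log-odds scale for binary
outcomes). mrkit implements the whole workflow on such tables:
harmonization, instrument selection, five multi-SNP causal estimators plus
the single-SNP Wald ratio, and a sensitivity battery, together with a
synthetic-GWAS generator so that every step can be validated against known
ground truth without access to cohort data.

## Harmonization

Two GWAS may report the same SNP on different alleles or strands. A
harmonized instrument carries both effects on a *shared* effect allele:

* identical allele pairs are kept as-is;
* swapped pairs (outcome effect allele equals the exposure's other allele)
  get `beta_out` negated and EAF replaced by $1-\mathrm{EAF}$;
* opposite-strand records are matched after complementing the outcome
  alleles; a SNP that matches on *both* readings is dropped as ambiguous;
* palindromic SNPs (A/T, C/G) are always dropped — their strand cannot be
  resolved from alleles alone, and frequency-based rescue is deliberately
  not attempted because exposure-side frequencies are not guaranteed to be
  present;
* anything else is dropped as irreconcilable, with a per-reason log.

Harmonization is idempotent and never changes effect magnitudes, only
signs.

## Instrument selection

* **P-value threshold.** Default $P < 10^{-5}$ (locus-wide significance), a
  common relaxation when genome-wide significant hits are too few; it is a
  `study_config` parameter.
* **LD clumping** (`ld_clump`). Greedy: repeatedly promote the remaining
  SNP with the smallest p-value to index SNP and discard remaining SNPs on
  the same chromosome within the window (default 10,000 kb) with
  $r^2 \ge$ threshold (default 0.001). Ties in $p$ break lexicographically
  on SNP id so results are platform-independent. LD arrives as a
  precomputed matrix (or a pre-clumped index-SNP list in bypass mode);
  computing LD from genotype panels is out of scope.
* **Steiger directionality filtering** (`steiger_filter`). A valid
  instrument should explain more variance in the exposure than in the
  outcome. Per SNP we compare $r^2_{\mathrm{exp}}$ vs $r^2_{\mathrm{out}}$
  and retain SNPs with a strict inequality (ties are conservatively
  dropped); the reported p-value is the two-sample Fisher-z comparison of
  the implied correlations,
  $z = \frac{\operatorname{atanh} r_{\mathrm{exp}} -
  \operatorname{atanh} r_{\mathrm{out}}}
  {\sqrt{1/(n_{\mathrm{exp}}-3) + 1/(n_{\mathrm{out}}-3)}}$.
  Filtering runs after harmonization and clumping and before estimation;
  published pipelines rarely state this order, and placing it last means
  the retained set is exactly the analysis set.
* **Variance explained** (`snp_r2`). With an allele frequency $f$
  available we use the standardized-trait approximation
  $2\hat\beta^2 f(1-f)$; otherwise the z-statistic fallback
  $z^2/(z^2+n-2)$, which needs neither frequency nor case prevalence and
  behaves sensibly for binary traits on the log-odds scale. The choice is
  element-wise, so mixed tables work.
* **Instrument strength.** $F = R^2(n-k-1)/(k(1-R^2))$, with $F < 10$
  flagging a weak instrument. The pipeline reports per-SNP $F$ (with
  $k = 1$, matching the per-IV ranges reported in applied work) and a
  set-level $F$ with $k$ equal to the instrument count.

## Estimators

All estimators consume the harmonized set
$\{(\hat\beta_{Xj}, \sigma_{Xj}, \hat\beta_{Yj}, \sigma_{Yj})\}_{j=1}^J$
and return the log-scale effect $\hat\beta$ with SE, normal 95% CI, and the
odds-ratio transform $e^{\hat\beta}$.

* **Wald ratio** (single SNP): $\hat\beta = \hat\beta_Y/\hat\beta_X$, SE
  $\sigma_Y/|\hat\beta_X|$ (first order; a delta-method second-order SE
  including exposure uncertainty is available by flag).
* **IVW**: inverse-variance-weighted mean of the per-SNP ratios with
  first-order weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$ —
  algebraically the weighted regression of $\hat\beta_Y$ on $\hat\beta_X$
  through the origin. The default is the multiplicative random-effects SE,
  inflating the fixed-effect SE by $\max(1, \sqrt{Q/(J-1)})$; under-
  dispersed sets therefore fall back to fixed-effect behaviour. A single
  SNP delegates to the Wald ratio.
* **MR-Egger**: the same weighted regression with a free intercept, after
  orienting every SNP so $\hat\beta_X \ge 0$ (without a fixed orientation
  the intercept is meaningless). The slope is consistent under InSIDE even
  when all instruments are pleiotropic; the intercept estimates the mean
  directional pleiotropic effect. Residual variance is floored at 1 and
  p-values use $t_{J-2}$.
* **Weighted median**: sort the ratio estimates, normalize the IVW
  weights, and linearly interpolate the cumulative *midpoint* weights
  $s_j = \sum_{i<j} w_i + w_j/2$ at $s = 0.5$; consistent when instruments
  carrying at least half the weight are valid. The SE comes from a
  parametric bootstrap (default 1,000 replicates) resampling both effect
  vectors from their reported SEs; a seed is mandatory so results are
  bit-reproducible.
* **Maximum likelihood**: the joint-normal errors-in-variables model
  $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$,
  $\hat\beta_{Yj} \sim N(\beta\gamma_j, \sigma_{Yj}^2)$. For fixed
  $\beta$ the $\hat\gamma_j$ are closed-form, leaving the one-dimensional
  profile log-likelihood
  $\ell_p(\beta) = -\tfrac12\sum_j
  (\hat\beta_{Yj}-\beta\hat\beta_{Xj})^2 /
  (\sigma_{Yj}^2+\beta^2\sigma_{Xj}^2)$,
  maximized by golden-section search with an expanding bracket; the SE is
  the observed information from a central-difference second derivative.
  As $\sigma_X \to 0$ this reduces to fixed-effect IVW, which the tests
  exploit as a limiting oracle.
* **MR-RAPS**: solves the adjusted profile-score equation
  $\sum_j \psi(t_j)\, (-\partial t_j/\partial\beta) = 0$ with standardized
  residuals
  $t_j = (\hat\beta_{Yj}-\beta\hat\beta_{Xj}) /
  \sqrt{\sigma_{Yj}^2+\beta^2\sigma_{Xj}^2+\tau^2}$,
  which keeps weak instruments honest by carrying the exposure-side
  variance in the denominator. The default Huber $\psi$ (tuning constant
  1.345) bounds outlier influence; with overdispersion on (default) the
  systematic-pleiotropy variance $\tau^2$ solves the second-moment
  equation $\sum_j \psi(t_j)t_j = J\,E[\psi(Z)Z]$,
  $Z \sim N(0,1)$ (for the Huber score $E[\psi(Z)Z] = 2\Phi(c)-1$).
  $\beta$ and $\tau^2$ are iterated to joint convergence; the SE is the
  M-estimation sandwich. With the identity score and $\tau^2=0$ the score
  equation *is* the derivative of $\ell_p$, so the estimate coincides with
  the MLE — a documented equivalence the tests assert.

P-values are two-sided normal for IVW, weighted median, MLE and RAPS and
$t_{J-2}$ for both Egger coefficients, mirroring common practice. Stored
estimates are never rounded; rounding (2 decimals for ORs) happens only at
presentation.

## Sensitivity battery

* **Cochran's Q** (`cochran_q`): on the IVW basis,
  $Q=\sum_j w_j(\hat\beta_j - \hat\beta_{\mathrm{IVW}})^2$ against
  $\chi^2_{J-1}$; on the Egger basis, Rücker's Q′ (weighted residual sum
  of squares about the Egger fit) against $\chi^2_{J-2}$.
* **Egger intercept test**: the intercept row of the Egger fit; flags
  directional pleiotropy at $p<0.05$. Note that with the residual variance
  floor an exactly-fitting dataset retains the fixed-effect intercept SE,
  which vanishes only as the outcome SEs do.
* **MR-PRESSO** (`mr_presso`): the observed statistic is the weighted RSS
  of each SNP about its leave-one-out IVW prediction; the null
  distribution comes from parametric simulation of both effect vectors
  under the no-pleiotropy model (default 1,000 draws), with
  $(1+\#\{\mathrm{sim}\ge\mathrm{obs}\})/(1+n_{\mathrm{sim}})$ smoothing
  so empirical p-values are never zero. The per-SNP outlier test
  (Bonferroni-corrected over $J$) is *gated on a significant global test*,
  the two-stage structure of the original procedure; without the gate the
  joint false-positive rate of "any outlier or global rejection" on clean
  data measurably exceeds the nominal level. When outliers are found the
  IVW estimate is recomputed without them and a distortion test compares
  the raw-vs-corrected shift against shifts from removing random subsets
  of the same size.
* **Leave-one-out** (`leave_one_out`): $J$ IVW re-estimates, each omitting
  one SNP; every entry is bit-identical to an independent `ivw()` call on
  that subset.

Because the Egger-intercept and PRESSO verdicts can genuinely disagree on
real data, the study report always shows both side by side rather than a
single pleiotropy verdict.

## The synthetic generator

`simulate_gwas_pair()` draws, per causal SNP: MAF
$f_j \sim U(\texttt{maf\_range})$ (default 0.05–0.5, the common-variant
range instruments are typically drawn from); true SNP–exposure effect
$\gamma_j = |N(0, \texttt{gamma\_sd}^2)|$; sampling SEs
$\sigma = 1/\sqrt{2nf(1-f)}$ (the standardized-trait value, the simplest
form consistent with the `snp_r2` conventions); observed effects
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$ and
$\hat\beta_{Yj} \sim N(\beta\gamma_j + \alpha_j, \sigma_{Yj}^2)$. Direct
effects $\alpha_j$ are zero (`none`), mean-zero (`balanced`) or shifted
(`directional`), applied to a configurable fraction of instruments, and
independent of $\gamma_j$ by default so InSIDE holds by construction; a
`pleio_gamma_cor` knob violates InSIDE on purpose to demonstrate Egger
failure modes. Null SNPs have $\gamma_j = \alpha_j = 0$. LD blocks are
laid out so that each block is a distinct locus (blocks sit far beyond the
default clumping window, SNPs within a block 1 kb apart) and
`simulate_ld_matrix()` emits the matching block-diagonal $r^2$ matrix.

Two generator conventions deserve emphasis:

* **Allele orientation.** Effect alleles are reported as the
  exposure-increasing allele, hence the half-normal $\gamma_j$. Directional
  pleiotropy is only a meaningful concept relative to a fixed orientation:
  with sign-symmetric $\gamma_j$ and orientation-independent $\alpha_j$,
  Egger's own orientation step would convert directional into balanced
  pleiotropy and no estimator could distinguish them. Real instrument
  tables follow the same convention.
* **Seed sub-streams.** One master seed is split into per-component
  streams (MAF, effects, noise, alleles, swaps), so enlarging the panel
  appends draws without reshuffling earlier ones, and any component can be
  varied in isolation.

The generator emulates summary-level sampling structure only. It does not
simulate individual genotypes, case–control liability, allele-frequency
mismatch between cohorts, sample overlap, or population stratification —
so passing tests demonstrate correctness of the estimators under the
stated model, not robustness to those real-data complications.

Default generator values (50 instruments, causal effect 0.1 on the
log-odds scale, `gamma_sd` 0.05, cohort sizes 100,000) give per-SNP
F-statistics in the tens — strong but not extreme instruments, comparable
to a well-powered hormone GWAS feeding a disease outcome of similar size.

## Study orchestration

`run_study()` executes read → p-filter → clump → harmonize → Steiger → F
statistics → estimators → sensitivity → OR transform for every
exposure × outcome pair, with per-stage SNP counts logged and asserted
non-increasing. Estimator failures become per-cell NA records with a
reason; a pair with no surviving instruments yields an explicit
"no instruments" row. A replication-stage row is marked replicated when
the discovery row for the same exposure and trait is suggestive
($P_{\mathrm{IVW}} < \alpha$, default 0.05) and the replication row is
suggestive with the same sign — the narrative criterion applied in staged
MR studies, made explicit. No multiple-testing correction is applied to
the suggestive flags (matching the "suggestive" framing such studies use);
a Bonferroni-adjusted IVW p-value column is emitted for transparency but
does not drive any flag. Reports are byte-identical across reruns with the
same config.

## Numerical choices and degenerate inputs

* Instruments with $\hat\beta_X = 0$ raise a degenerate-instrument error
  naming the SNP (the ratio is undefined); Egger additionally rejects
  designs with no spread in the oriented $\hat\beta_X$.
* The MLE and RAPS root-finders start from fixed-effect IVW and expand
  their brackets geometrically; failure to bracket raises a convergence
  error rather than returning a boundary value.
* Empirical p-values (PRESSO) are add-one smoothed; analytic p-values are
  clamped away from exact 0 so they remain in $(0, 1]$.
* Clumping and the weighted median resolve ties deterministically
  (lexicographic SNP id; midpoint interpolation), so all outputs are
  platform-stable.

## Worked example

```{r example}
blocks <- list(list(size = 3, r2 = 0.9))
sim <- simulate_gwas_pair(sim_config(n_causal = 30, n_null = 20,
                                     true_beta = 0.1, seed = 11,
                                     ld_blocks = blocks))
ld <- simulate_ld_matrix(sim$exposure, blocks)
cfg <- study_config(
  exposures = list(hormone = sim$exposure),
  outcomes = list(disease = list(data = sim$outcome, stage = "discovery")),
  ld = ld, seed = 42
)
res <- run_study(cfg)
res$report[, c("n_total", "n_p_filter", "n_clump", "n_harmonized",
               "n_steiger", "F_min", "F_max")]
res$report[, c("P_IVW", "P_Egger", "P_WM", "P_MLE", "P_RAPS",
               "P_Q_IVW", "P_Egger_intercept", "P_PRESSO_global",
               "suggestive")]
```

## Validation strategy and problem sizes

The test suite checks every estimator against an independent route: IVW
and Egger against `stats::lm` weighted fits, the MLE against a brute-force
likelihood grid, the weighted median against hand-enumerated midpoint
interpolation, RAPS against its documented MLE equivalence, and PRESSO and
Q against seeded calibration and detection simulations. The simulation
sizes used throughout (2,000 homogeneous datasets for Q calibration, 500
replicates for recovery/coverage and robustness orderings, 100 replicates
for PRESSO rates, panels of 10–50 instruments at cohort sizes of 100,000)
were chosen to make Monte-Carlo error small relative to the properties
being asserted while keeping the whole suite fast enough to run routinely.
`scripts/acceptance.R` recomputes the same quantities from scratch under a
caller-supplied seed.

## Known limitations

* First-order ratio weights throughout IVW/Q (exposure-side uncertainty
  enters only the MLE and RAPS variances); with weak instruments IVW and
  Q inherit the usual first-order biases.
* No proxy-SNP lookup, genome-build liftover, VCF input, or LD estimation
  from reference panels; LD must be supplied.
* No multivariable MR, contamination-mixture or mode-based estimators.
* The distortion test's random-subset reference distribution treats the
  outlier count as fixed, as in the original procedure.
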