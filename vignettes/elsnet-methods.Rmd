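---
title: "Methods: network connectivity, attention bias and mediation in early-life-stress research"
author: "elsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network connectivity, attention bias and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elsnet)
```

# The scientific problem

Early-life stress (ELS; childhood abuse and neglect, measured by
questionnaire total scores) is robustly associated with later depression.
One mechanistic account runs through attention: stimulus-driven attention
is supported by the ventral attention network (VAN), and individuals with
ELS show altered attentional responses to emotional faces. `elsnet`
implements the full analysis chain that such studies use to test this
account in resting-state fMRI cohorts: connectivity statistics over a
network partition, a covariate-adjusted association screen with FDR
control, a cross-validated prediction check of robustness, and bootstrap
mediation models linking ELS to depression through (i) VAN within-network
connectivity and (ii) the sad-face attention bias from a dot-probe task.

The package deliberately starts *after* image preprocessing: its inputs are
per-subject ROI time-series matrices (time × node), a node-to-network
partition, a behavioral table, and trial-level dot-probe logs. Volumetric
data, motion correction, filtering and nuisance regression are out of
scope.

# Connectivity statistics

For a subject with time series $X \in \mathbb{R}^{T \times N}$, the
connectivity matrix $A$ holds the Pearson correlations of all node pairs
($T \ge 3$, no constant node). Over a partition of the $N$ nodes into
networks $a$ with sizes $N_a$, the two summary statistics are

$$W_a = \frac{\sum_{i,j\in a} A_{i,j}}{N_a^2}, \qquad
PB_{a-b} = \frac{\sum_{i\in a,\, j\in b} A_{i,j}}{N_a N_b} \;(a \ne b).$$

Two points deserve care:

* **Diagonal policy.** As printed, $W_a$ sums over *all* ordered pairs
  including $i = j$, so the unit diagonal contributes and each undirected
  link counts twice. We implement this literally as the default
  (`diagonalPolicy = "literal"`) because it is the stated formula, and
  expose the conventional mean of the strictly off-diagonal entries as
  `"exclude_diagonal"`. The two are related by
  $W^{lit} = ((N_a - 1)W^{excl} + 1)/N_a$, an identity the test suite
  asserts on random inputs, so results under one policy are an affine
  transform of the other per network and correlation-based downstream
  analyses are unaffected by the choice.
* **Raw correlations.** No Fisher z-transform and no thresholding are
  applied by default; negative correlations enter the averages as-is. A
  `fisherZ` option transforms off-diagonal entries before averaging (the
  unit diagonal is left untransformed so the literal statistic remains
  finite).

A cohort's profiles (10 within + 45 between values per subject for a
10-network partition) are assembled into a `ConnectivityExperiment`
extending `SummarizedExperiment`: rows are measures, columns subjects,
`colData` the behavioral table. Internally the per-subject profile is
computed from the block sums $U^\top A U$ (with $U$ the node-by-network
indicator), which is algebraically identical to the per-block definitions;
the equivalence, and the agreement of both with a brute-force double loop,
are tested.

# Screening with covariate adjustment and FDR

Each measure is related to the behavioral score by the partial correlation
given covariates (age and sex for the connectivity screen; a second preset
adds current stress, used for the behavior-to-behavior correlations that
motivate the mediation models — the two presets exist because the analyses
adjust differently at different stages). We compute $r$ through the inverse
covariance matrix of $(x, y, Z)$, with the two-sided p-value from
$t = r\sqrt{df/(1-r^2)}$, $df = n - 2 - k$. The screen residualizes the
target and all measures in a single QR decomposition — numerically
identical to per-measure partial correlations (asserted in tests to
$10^{-12}$).

FDR control uses the Benjamini–Hochberg step-up procedure (delegated to
`stats::p.adjust`; an independently hand-rolled step-up serves as the test
oracle). The FDR family is **all measures in one screen invocation** (55 by
default): correcting within- and between-network families jointly is the
conservative reading when the family definition is not stated; a subset
screen via the `measures` argument gives per-family correction. Two-sided
p-values are used throughout.

# Cross-validated prediction

Robustness of a brain–behavior association is assessed by predicting the
score from connectivity features with linear $\epsilon$-insensitive support
vector regression (via `e1071::svm`) under k-fold cross-validation, pooling
the out-of-fold predictions and reporting their Pearson correlation with
the observed targets, $r_{predicted,\,observed}$.

* **Balanced folds.** Subjects are sorted by outcome and consecutive groups
  of $k$ are dealt round-robin into folds (within-group order randomized by
  the seed). This keeps per-fold outcome distributions matched — tested as
  a variance reduction of per-fold means against random folds — and, as a
  side effect, removes most of the small negative bias that cross-validated
  correlations show under the null.
* **Defaults.** $k = 4$ folds, $C = 1$, $\epsilon = 0.1$, no inner tuning
  loop (a fixed-model design; a `costGrid` flag enables inner-CV tuning,
  and a `repeats` reading of the procedure can be obtained by averaging
  runs with different seeds). The fold count is a flag because both
  four-fold and ten-fold conventions are in circulation for this design;
  four is the default here.
* **Covariates** are handled by residualizing the outcome on the
  covariates with coefficients estimated on the training folds only;
  feature standardization likewise uses training-fold statistics only. A
  "canary" test verifies no leakage: perturbing one held-out subject cannot
  move any other held-out subject's prediction. Feature residualization is
  available behind a flag but off by default (the simplest reading of
  "controlling for" covariates in a prediction analysis).
* **Inference** is by permutation: the outcome is permuted, the whole CV
  procedure rerun, and $p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})$.

# Mediation with bias-corrected bootstrap

The simple mediation model is fitted by three OLS regressions with the same
covariates in each equation: $m \sim x + Z$ (path $a$), $y \sim x + m + Z$
(paths $c'$ and $b$), $y \sim x + Z$ (total effect $c$). $x$, $m$, $y$ are
z-scored before fitting so the paths are standardized coefficients;
covariates stay on their raw scale, which cannot change the focal
standardized paths. The OLS identity $c = c' + ab$ then holds exactly and
is asserted to $10^{-10}$.

The indirect effect $ab$ gets a case-resampling bootstrap CI (subjects
resampled with replacement, paths refitted per resample). The
bias-corrected (BC) interval computes
$z_0 = \Phi^{-1}(\text{prop. of bootstrap } ab \text{ below the estimate})$
— ties counted half, an explicit convention since discrete data make ties
possible — and reads the empirical quantiles at $\Phi(2z_0 \pm z_{1-\alpha/2})$.
When $z_0 = 0$ this reduces exactly to the percentile interval (tested).
No acceleration term is used (BC, not BCa), matching the bias-corrected
convention of the SPSS macros that popularized this analysis; BCa is a
possible extension. Degenerate resamples (constant $x$, $m$ or $y$) are
redrawn and counted; a bootstrap distribution entirely one side of the
point estimate is flagged pathological and the correction clamped.
Significance is "CI excludes zero". Default 2,000 resamples, 95% level,
covariates age and sex (the current-stress preset is available; the default
follows the convention of adjusting mediation models for demographics
only).

Without covariates the bootstrap uses a closed-form route: standardized
$a$, $b$ are explicit functions of the three resample correlations, letting
thousands of resamples be computed by vectorized column operations. With
covariates each resample is refitted by least squares. Both routes are
cross-checked against each other in the tests.

# Dot-probe attention-bias scoring

Trials carry condition (NH/NS/NA/NF: neutral paired with happy, sad, angry,
fearful), the side of the emotional face, the probe side, RT and accuracy.
The per-subject, per-emotion score is

$$\text{bias} = \tfrac{1}{2}\left[(RpLe - RpRe) + (LpRe - LpLe)\right],$$

with $XpYe$ the mean RT for probe side $X$ and emotional-face side $Y$ —
algebraically the mean incongruent-minus-congruent RT, positive when
attention is drawn toward the emotional face. The labels NA = neutral-anger
and NF = neutral-fear follow the task's trial-count listing (NH 40, NS 37,
NA 37, NF 37 per 151-trial block, two blocks). Scores use per-cell means
by default; a score is emitted only when all four
cells are nonempty, otherwise the row is flagged missing with a reason. A
`statistic = "median"` option substitutes per-cell medians.

Trial filtering — correct responses only, RT in [200, 1500] ms, optional
per-subject ±k·SD clip — is conventional dot-probe hygiene, not a protocol
fact: every threshold is an argument and the defaults are an artifact
choice. Location invariance, the L/R relabeling symmetries (swapping both
side labels preserves the score; swapping only the face side negates it),
and recovery of planted shifts are all property-tested.

# The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which everything else is validated.

* **Time series.** Zero-mean multivariate normal with a block-structured
  correlation matrix: compound-symmetric within each network (correlation
  $\rho_a$), constant $\rho_{ab}$ between networks — the simplest structure
  matching the within/between summary statistics. Positive definiteness is
  checked exactly via the reduced spectrum ($\{1-\rho_a\}$ plus the
  eigenvalues of a $K \times K$ matrix), with tolerance $10^{-10}$.
  Per-subject targets are the spec targets perturbed by
  $\mathcal{N}(0, 0.05)$ truncated to the valid range — without this
  inter-subject variance in true connectivity, brain–behavior correlations
  would be degenerate. When the perturbed $K\times K$ target matrix is
  itself PD the draw uses $K$ shared network factors plus node noise;
  otherwise a dense Cholesky (identical covariance either way).
* **Defaults as study conditions.** 300 subjects × 230 time points (8 min
  at TR = 2 s minus 10 discarded volumes) over the standard 227-node /
  10-network partition (community sizes DMN 58, SMN 35, VN 31, FPN 25,
  SN 18, CON 14, AN 13, SUB 13, DAN 11, VAN 9); within targets 0.25,
  between 0.08 — typical resting-state magnitudes. Demographics follow the
  published cohort description: age $\mathcal{N}(19.42, 1.40)$ truncated to
  16–26, sex Bernoulli(157/528), and instrument-scale means/SDs for ELS
  (37.35 ± 8.34), depression (7.05 ± 6.45) and current stress
  (46.70 ± 20.88).
* **Planted mediation.** Standardized latent paths $(a, b, c') =
  (0.5, 0.4, 0.2)$ by default. The published effect sizes in this
  literature are much smaller (r ≈ 0.12–0.20), which is detectable only at
  $n \gtrsim 500$–1000 after multiplicity correction; the defaults are
  deliberately strong enough that the planted structure is recoverable at
  the desk-scale cohort sizes the tests use, and are user parameters, not
  claims about real effect magnitudes. With a brain mediator the exposure
  is generated *from* the realized mediator ($X = a\,z(M) +
  \sqrt{1-a^2}\,\varepsilon$), which plants the population correlation $a$
  with the connectivity value actually computed from the time series —
  estimation noise in $M$ therefore attenuates downstream estimates
  exactly as it would in real data. The outcome disturbance is auto-scaled
  to unit outcome variance (so planted paths are exactly the standardized
  coefficients); an explicit `noiseSd` overrides this.
* **Dot probe.** RT = base (500 ms) + per-subject shift on incongruent
  trials + Gaussian noise (SD 60 ms); subject shifts are
  $\mathcal{N}(\text{shift}_e, 10)$ across subjects. Gaussian RT noise is a
  simplification (real RTs are right-skewed); nonpositive draws are
  resampled and counted. Errors are planted at 5%.
* **What passing tests do not show.** The generator has no autocorrelation,
  head motion, physiological noise, scanner drift or distributional
  skew, and its planted effects are linear and homoscedastic. Passing
  tests demonstrate the *statistical machinery* is correct and calibrated
  under the assumed model — not that real preprocessing artifacts are
  handled.

# Numerical and design notes

* Determinism: every stochastic stage derives its own 32-bit seed from the
  master seed and a stream id, so stages can be rerun in isolation and a
  full run is a pure function of (config, seed); RNG state is restored
  after each internal draw. Identical configuration reproduces result
  files byte for byte.
* Connectivity matrices are symmetrized against floating-point rounding and
  their unit diagonal enforced; partial correlations are clamped to
  $[-1, 1]$ before the t transform ($p = 0$ at $|r| = 1$).
* Constant features in a training fold standardize with unit scale rather
  than dividing by zero; constant outcomes, rank-deficient covariates and
  collinear mediation designs are errors with informative messages.
* Problem sizes in the acceptance-style tests (e.g. 500 null screens at
  n = 200; a 3 × 3 mediation-coverage grid with 300 replicates per cell at
  n = 500 and 1,000 resamples; 50 end-to-end replicates at n = 300) were
  chosen as the smallest scales at which the Monte-Carlo error bands are
  meaningful for the stated tolerances.
* The pipeline's CLI-style surface is the set of exported functions plus
  `analysisConfig()`/`runPipeline()`/`replicateScreen()`; configuration is
  a serializable list, and a manifest JSON (package version, seed, config
  checksum, artifact list) accompanies written outputs.

# Known limitations

* BCa (accelerated) bootstrap intervals, multiple mediators, moderated
  mediation and the Sobel test are not implemented.
* Graph-theoretic network measures (modularity, efficiency), dynamic
  connectivity, robust/rank correlations and permutation-based screen
  p-values are out of scope.
* E-prime raw exports are not parsed; trial logs must be converted to the
  documented CSV dialect.
* Simulated questionnaire scores are Gaussian on the instrument scale and
  can fall outside hard instrument bounds in the tails; range checks warn
  on user data but the generator does not truncate (truncation would
  distort the planted correlation structure).
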