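---
title: "Time-varying partial directed coherence: model, estimation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying partial directed coherence: model, estimation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tpdcflow estimates *directed* functional connectivity between a small number
of named brain-network time series (by default the seven Yeo resting-state
networks), classifies disease stage from the resulting connectivity patterns,
and relates connectivity to clinical scores. This vignette is the package's
account of the underlying model, the estimation machinery, the statistical
thresholding, and the design decisions taken where more than one reasonable
choice existed.

## The model

Each subject's data is a $T \times N$ matrix $X$ of BOLD-like time series
sampled every `TR` seconds. The generative model is a time-varying
multivariate autoregression of order $p$ (default $p = 1$):

$$X(t) = \sum_{k=1}^{p} A_k(t)\, X(t-k) + E(t),$$

where the $A_k(t)$ are time-varying $N \times N$ coefficient matrices and
$E(t)$ is Gaussian innovation noise. Throughout the package, **entry $(i, j)$
of any coupling or connectivity matrix is the influence of source channel $j$
(column) on target channel $i$ (row)**; every file written by the package
repeats this convention in its header, because orientation mix-ups are the
most common silent bug in directed-connectivity code.

The frequency-domain transfer of the model at time $t$ is

$$\bar{A}(f, t) = I - \sum_{k=1}^{p} A_k(t)\, e^{-i 2 \pi f k \cdot TR},$$

and temporal partial directed coherence is the column-normalized transfer
magnitude

$$\pi_{ij}(f, t) = \frac{|\bar{A}_{ij}(f, t)|}
{\sqrt{\sum_{k} |\bar{A}_{kj}(f, t)|^2}},$$

so that $\sum_i \pi_{ij}^2(f,t) = 1$ for every source $j$ at every frequency
and time point. This is the standard PDC normalization; it is what makes
"zero coupling implies zero off-diagonal influence" and the unit-sum
property hold, and both are verified to machine precision in the test suite.
The subject-level connectivity matrix is the arithmetic mean of
$\pi_{ij}(f,t)$ over the grid frequencies inside the band of interest
(default 0.009–0.08 Hz, the conventional resting-state BOLD band) and over
time points after an initial burn-in fraction.

## Dual extended Kalman filter

The time-varying coefficients are estimated by two coupled filters run
forward once over the series:

* a **state filter** — a companion-form Kalman filter that estimates the
  signal given the current coefficient estimate; its filtered lagged states
  are the regressors fed to
* a **parameter filter** — the stacked coefficients are treated as a
  random-walk state (process noise `process_noise` per coefficient per
  step), observed through the VAR regression equation.

Both filters are initialized from a stationary ordinary-least-squares VAR
fit of the whole series (`fit_stationary_var()`), which is also the
stationary-limit reference the estimator is tested against. Because the
parameter prior and process noise are isotropic and the observation noise is
taken diagonal, the joint parameter filter decouples exactly into $N$
independent row filters of dimension $N p$; the implementation (in compiled
code) exploits this, reducing the per-step cost from $O((N^2 p)^2)$ to
$O(N (N p)^2)$ without changing the estimator.

### Tuning constants and why

| parameter | default | role |
|---|---|---|
| `process_noise` | 1e-6 | random-walk variance per coefficient per step; sets the tracking-speed / coefficient-noise trade-off |
| `init_param_cov` | 1e-3 | initial coefficient covariance around the OLS initializer |
| `state_noise` | 1e-2 | observation-noise variance assumed by the state filter |
| `n_freqs` | 128 | uniform frequency grid over (0, Nyquist]; ≥ 30 bins fall inside 0.009–0.08 Hz at TR = 2 s |
| `burn_fraction` | 0.1 | initial fraction of estimated time points excluded from averaging (filter transient) |

The random-walk variance deserves comment. The steady-state posterior SD of
each coefficient scales like $(q\,r)^{1/4}$ for process noise $q$ and
innovation variance $r$; because TPDC takes an *absolute value*, that noise
becomes a positive bias on truly-zero couplings. At $q = 10^{-4}$ that bias
is large enough to drown the stationary-limit agreement the estimator is
supposed to have; the default $q = 10^{-6}$ keeps the bias inside the
stationary-limit margin while the filter still tracks a mid-series coupling
switch within a few hundred samples (both properties are tested). Users analysing series
with fast coefficient dynamics should raise `process_noise` and accept a
higher noise floor; all constants are exposed in `ekf_config()` and in the
pipeline YAML.

There is an irreducible estimation floor as well: on white noise of length
$T = 400$, the initializing OLS fit alone leaves coefficient noise of SD
$\approx 1/\sqrt{T}$, i.e. off-diagonal band-averaged TPDC around 0.1 even
though the true influence is zero. This is why raw TPDC values are never
interpreted directly but always passed through the surrogate bootstrap
below.

## Significance: bootstrap and permutation

**Subject level.** The null distribution per connection comes from
block-shuffle surrogates: the series is cut into `window_len = 10`
non-overlapping blocks and the block order is permuted **independently per
channel**. An independent per-channel permutation destroys the cross-channel
lag structure that directed measures feed on while preserving each channel's
local autocorrelation and amplitude distribution. (A *joint* permutation —
the same block order applied to all channels — preserves the cross-lag
structure inside every block and therefore carries essentially the full
causal signal; it is available through the explicit `perm` argument for
illustration, but it is not a usable null.) The full TPDC pipeline is
recomputed on 100 surrogates and the per-connection threshold is the 99th
percentile (type-7 quantile) of the surrogate values; observed values
**strictly above** threshold become 1 in the subject's binary adjacency, the
diagonal is forced to 0.

**Group level.** Subjects' binary matrices are summed into a frequency
matrix. Each of 1,000 permutations shuffles every subject's 42 off-diagonal
cells uniformly — preserving that subject's total edge count — and
re-aggregates; a group edge is significant when its observed frequency
strictly exceeds the 99th percentile of its null. A degree-preserving
variant (edge swaps that keep every row and column sum) is available behind
`method = "degree"` for users who want a stricter null; the flat shuffle is
the default because it is the scheme whose calibration and recovery behaviour
are verified in the acceptance checks.

## Stage classification

Per-subject matrices are flattened row-major into named features
(`"SRC->TGT"`, 49 with the diagonal, 42 without) and fed to a random forest
(100 trees). Features default to continuous TPDC values rather than binary
edges: the continuous values carry strictly more information, and the binary
mode remains available for sensitivity analyses. Evaluation uses a
stratified 70:30 split plus stratified 10-fold cross-validation; reported
metrics are accuracy, per-class precision/recall/F1, the confusion matrix,
the ROC/AUC from class-probability scores (two-class case) and normalized
impurity importances with the top five reported. Forest hyperparameters
other than the tree count stay at `randomForest` defaults and are recorded
in the report for reproducibility.

## Clinical statistics

Correlations between a connection's TPDC values and clinical scores use
Pearson's $r$ for continuous scores and Spearman's rank correlation for
ordinal ones; a score-type registry (`register_score()`) enforces this —
asking for Pearson on an ordinal score such as the Hoehn–Yahr stage is an
error, not a warning. Group contrasts are OLS regressions on a group
indicator, algebraically identical to the equal-variance two-sample t-test
(verified against `t.test()` in the suite), reporting the mean difference,
two-sided $p$ and $r^2$ (squared point-biserial correlation). Matched
multi-group comparisons use the Friedman test; fully tied inputs (identical
groups) are reported as statistic 0, $p = 1$ rather than NaN. Multiplicity
control is Bonferroni over an explicitly constructed family — all
connection-by-score tests of one run — never an implicit global one.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture. It emulates the
statistical structure the analysis assumes: seven channels named
`VIS, SMN, DAN, VAN, LIN, FPN, DMN` (fixed column order used by every
module), slow autocorrelated dynamics from stable VAR(1) processes with
spectral mass inside 0.009–0.08 Hz at the default TR of 2 s, group-specific
directed coupling templates, per-subject Gaussian jitter on the nonzero
couplings (rejection-sampled to stability, at most 100 retries), and
clinical scores that are linear in a designated true coupling plus noise.

Four built-in templates encode the qualitative stage patterns the analysis
is designed to detect — young controls with bidirectional
control–somatomotor coupling, older controls rerouting through
attention-to-control and limbic-to-somatomotor paths, a prodromal stage
whose somatomotor network has no outgoing edges, and a manifest stage that
adds somatomotor output to visual and default-mode targets. No quantitative
coupling strengths exist for these patterns, so the magnitudes
(`base_coupling`, default 0.3; `self_coupling`, default 0.5) are free,
documented parameters; 0.3–0.4 gives signal-to-noise at which one subject's
bootstrap usually, but not always, detects a true edge — the regime in which
group aggregation is actually needed.

What the generator does **not** emulate: hemodynamic-response convolution,
scanner drift, motion artefacts, physiological noise, inter-site
differences. Passing tests on this generator therefore demonstrate that the
estimation and inference machinery is correct under its own model
assumptions — not that those assumptions hold for any particular scanner's
data.

The noiseless clinical model (`slope = 1, noise_sd = 0`) reproduces the true
coupling exactly; setting `noise_sd` equal to the across-subject coupling SD
attenuates the expected correlation to $1/\sqrt{2} \approx 0.707$ by the
usual variance decomposition, which is the planted value the recovery checks
look for.

## Numerical choices and degenerate inputs

* VAR simulation discards 50 burn-in samples to remove the
  initial-condition transient.
* The frequency grid is $f_m = m \cdot f_{\mathrm{Nyq}} / n_{\mathrm{freqs}}$,
  $m = 1..n_{\mathrm{freqs}}$ — open at 0, closed at Nyquist; band selection
  is inclusive on both edges.
* Thresholds use type-7 quantiles and strict `>` comparisons, so a
  degenerate (constant) surrogate distribution yields threshold equal to
  that constant and the observed value is only significant if it exceeds it.
* Percentile thresholds, shuffles and permutations are all driven by
  explicit seeds; identical inputs and seeds give bit-identical outputs,
  including byte-identical files (floats are written with 17 significant
  digits, which round-trips doubles losslessly).
* A zero transfer column (which would make the TPDC denominator vanish) is
  reported as an error naming the source channel and frequency; it cannot
  arise from the filter output but can from hand-built models.
* Parameter-filter divergence (covariance trace beyond `cov_cap`) aborts
  with the time index rather than returning garbage.

## Scale of the verification experiments

The package's end-to-end checks run at deliberately chosen sizes: edge
recovery uses 20 cohorts of 20 subjects (T = 400, coupling 0.4, 100
bootstrap shuffles, 1,000 group permutations); null calibration uses 50
independent-noise cohorts of 12 subjects (T = 300) plus 1,000 null
correlation tests; the stationary-limit comparison averages the estimated
TPDC over 5 independent series of T = 2000 before comparing against the
closed-form PDC of the true coupling matrix, because the max-entry deviation
of a single series is dominated by $1/\sqrt{T}$ sampling noise rather than
by any property of the estimator. These sizes give Monte-Carlo error well
below the margins being tested while keeping the full suite runnable on a
laptop.

## Known limitations

* Filtering only, no smoothing: coefficient estimates at time $t$ use data
  up to $t$ only, so the estimate lags abrupt changes by roughly the filter
  time constant.
* Order selection is the user's responsibility (`p` defaults to 1); no
  AIC/BIC machinery is provided.
* The TPDC noise floor scales as $1/\sqrt{T}$; short series need the
  bootstrap, and between-group contrasts of *raw* TPDC values inherit this
  floor.
* The group permutation null assumes subjects are exchangeable within the
  group; it does not model site or scanner structure.
* The generator's linear-Gaussian world contains no nonlinearity, so these
  tests say nothing about the estimator's behaviour under nonlinear coupling.
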