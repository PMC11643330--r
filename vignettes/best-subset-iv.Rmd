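---
title: "Best-subset selection of invalid instruments: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Best-subset selection of invalid instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subsetIV)
```

## The problem

Instrumental-variable (IV) regression estimates the causal effect of an
exposure $X$ on an outcome $Y$ when $X$ is endogenous, using instruments $Z$
that move $X$ but — if valid — affect $Y$ only through $X$. In Mendelian
randomization, the instruments are SNP dosages and the exclusion restriction
is routinely threatened by pleiotropy: some instruments have a direct effect
on the outcome. The model is

$$Y_i = X_i^\top \beta_0 + Z_i^\top \delta_0 + \epsilon_i,
  \qquad X_i = \psi_0^\top Z_i + \mu_i,$$

with $n$ observations, $m$ exposures and $L$ candidate instruments.
Instrument $j$ is *valid* when $\delta_{0j} = 0$ and *invalid* otherwise.
Which instruments are invalid is unknown; estimating $\beta_0$ while
*selecting* the invalid set is the task this package addresses. Throughout we
work in the regime $n > L + m$ with at most $L - m$ instruments treated as
invalid (identification) and, for consistency arguments, fewer than half
invalid (the majority-valid condition under which the median-type estimators
are also consistent).

## Concentration into a sparse regression

Let $P_A$ be the orthogonal projector onto the column space of $A$ and
$M_A = I - P_A$. With $\hat X = P_Z X$, $\dot Y = M_{\hat X} P_Z Y$ and
$\dot Z = M_{\hat X} Z$, the cardinality-constrained least-squares problem

$$\min_{\beta, \delta} \tfrac12 \lVert P_Z (Y - X\beta - Z\delta)\rVert_2^2
  \quad \text{s.t.} \quad \lVert\delta\rVert_0 \le r$$

concentrates to a problem in $\delta$ alone,
$\min_{\lVert\delta\rVert_0 \le r} f(\delta)$ with
$f(\delta) = \tfrac12\lVert\dot Y - \dot Z\delta\rVert_2^2$, after which

$$\hat\beta = (\hat X^\top \hat X)^{-1}\hat X^\top (Y - Z\hat\delta).$$

`transform_problem()` computes these quantities through QR factorizations —
never through an explicit $(Z^\top Z)^{-1}$ — because the benchmark designs
include instrument correlations up to $\rho = 0.75$ and the applications
motivating the method use correlated SNP panels. By construction
$\dot Z$ has rank $L - m$: the concentrated Gram matrix is singular, a fact
that matters below. Numerical rank uses the standard threshold
$\max(\mathrm{dim}) \cdot \varepsilon \cdot \sigma_{\max}$.

Exogenous covariates (including an intercept) are handled by residualizing
$Y$, $X$ and $Z$ on them first (`validate_and_partial()`); by the
Frisch–Waugh argument this leaves the concentrated problem unchanged. The
simulation designs have no intercept, matching their zero-mean data; the CSV
reader adds one by default because real tabular data are rarely centered.
Instrument columns are *not* rescaled by default anywhere — the benchmark
designs put all instruments on a common scale, and the Lasso comparator
exposes a `standardize` flag for data that are not.

## Solvers for the best-subset step

**Hard-thresholding descent** (`dfo_solve()`). The projected-gradient
iteration
$\delta^{(t+1)} = S_r(\delta^{(t)} - L_c^{-1} f'(\delta^{(t)}))$, where
$S_r$ keeps the $r$ largest-magnitude coordinates and
$L_c = \lambda_{\max}(\dot Z^\top \dot Z)$ is the tightest gradient
Lipschitz constant, produces a non-increasing objective sequence that
converges; iteration stops when
$\lVert\delta^{(t+1)} - \delta^{(t)}\rVert_2^2 \le$ `tol` (default `1e-6`,
cap 1000 iterations). The ordering inside $S_r$ is by absolute value — the
squared-error projection forces magnitude ordering — with ties broken toward
the smallest index so results are reproducible. The method only guarantees a
stationary point, so the solver runs `n_starts` initializations (default 50):
the first is the hard-thresholded ridge solution
$(\dot Z^\top\dot Z + 10^{-6} I)^{-1}\dot Z^\top\dot Y$, the rest are
seeded random $r$-sparse vectors scaled to the ridge solution. Every final
support is polished by a least-squares refit (support unchanged, objective
weakly lower). All randomness sits behind one required seed.

**Enumeration** (`exact_subset_solve()`). For $\binom{L}{r}$ up to $10^6$
supports, an exhaustive least-squares scan returns the global minimizer with
a certificate; ties keep the lexicographically smallest support. At the
benchmark scales ($L \in \{10, 40\}$ with $r$ small) certification is nearly
free, so the default solver uses enumeration whenever
$\binom{L}{r} \le 20{,}000$ and multi-start descent otherwise. Both hot loops
are compiled (RcppArmadillo). A mixed-integer quadratic formulation of the
same problem — binary indicators $w_i$ with $w_i = 0 \Rightarrow \delta_i = 0$
via big-M or SOS1 constraints — is the route to certified solves at scales
where enumeration is infeasible; it needs an external MIQO solver (e.g.
Gurobi), which this package treats as an optional backend and reports as
such when absent.

**Big-M bounds** (`compute_bigM()`). Given any feasible objective value
`UB` (the descent objective works), the range of $\delta_i$ compatible with
$f(\delta) \le UB$ along the stationarity path
$\delta(\eta) = (\dot Z^\top\dot Z)^{+}(\dot Z^\top\dot Y + \eta\tau_i)$ has
the closed form $\delta^{ls}_i \pm \sqrt{2(UB - f_{\min})
[(\dot Z^\top\dot Z)^{+}]_{ii}}$. Because the Gram matrix has a null space
of dimension $m$, the pseudoinverse restricts this path to the row space of
$\dot Z$; the resulting $M_i$ provably bound the row-space projection of any
feasible $\delta$, but an $r$-sparse solution can carry an additional
null-space component and occasionally exceed them. They should be used as
data-driven magnitude guides for mixed-integer formulations (inflated if a
hard guarantee is needed), not as certificates — the package's tests assert
exactly the projection guarantee. These bounds require no statistical
tuning.

**Choosing the subset size.** `cv_subset_size()` runs K-fold (default
10-fold) cross-validation of the held-out concentrated error
$\lVert\dot Y_{\mathrm{te}} - \dot Z_{\mathrm{te}}
\hat\delta_{\mathrm{tr}}(r)\rVert^2$ over $r = 0,\dots,L-m-1$, rebuilding
the projections on the training rows of each fold (building them on all rows
leaks the held-out outcome and overfits badly — we verified this directly).
The default selection is the CV-error argmin with ties toward smaller $r$,
matching the benchmark protocol. Plain argmin CV over an $\ell_0$ grid is,
however, known to overselect: on a null design (no invalid instruments,
$n = 2000$) it returns $r = 0$ only about two thirds of the time, the rest
spread over small positive $r$. The `rule = "1se"` option picks the smallest
$r$ within one standard error of the minimum; it keeps the null design at
$r = 0$ in well over 90% of runs and still selects the true $r$ modally at
high signal-to-noise, at the cost of occasionally underselecting in
low-signal designs. `fit_bsiv()` warns when the selected $r$ reaches $L/2$,
the boundary of the majority-valid regime.

## Comparator estimators

* **OLS**: the benchmark tables' OLS regresses the outcome on the exposure
  *and all instruments*. We adopted that definition
  (`control_instruments = TRUE`) because its probability limit for the
  exposure coefficient, $\beta_0 + \sigma_{\mu\epsilon}/\sigma_\mu^2 =
  0.25$ under the benchmark parameters, is constant across all instrument
  correlations and signal strengths — exactly the pattern the published
  bias columns show (≈ 0.25 everywhere) — whereas a Y-on-X-only regression
  would drift with $\rho$. A flag gives the other variant.
* **Naive / oracle TSLS** (`fit_tsls()`): generalized two-stage least
  squares with a declared invalid set included as outcome controls;
  homoskedastic asymptotic covariance
  $\hat\sigma_\epsilon^2 (W^\top P_Z W)^{-1}$ with $\hat\sigma_\epsilon^2$
  from structural residuals (denominator $n - \mathrm{ncol}(W)$). The
  oracle variant — true invalid set — is the infeasible benchmark.
* **Lasso-type selector** (`fit_live()`): the $\ell_1$ surrogate
  $\tfrac12\lVert\dot Y - \dot Z\delta\rVert^2 + \lambda\lVert\delta\rVert_1$,
  solved by glmnet and polished by exact coordinate descent until the KKT
  conditions hold to $10^{-6}$ absolute (glmnet's own tolerance is relative
  to its standardized problem and is not tight enough on the raw scale).
  The penalty grid is geometric over
  $[10^{-3}\lambda_{\max}, \lambda_{\max}]$ with
  $\lambda_{\max} = \lVert\dot Z^\top\dot Y\rVert_\infty$, 100 points, and
  10-fold CV picks $\lambda$ with ties toward the larger (sparser) value.
* **Median and mode estimators** (`median_estimator()`,
  `mode_estimator()`): summary-statistic estimators built from
  per-instrument Wald ratios $\hat\Gamma_j/\hat\gamma_j$ (univariate
  reduced-form and first-stage regressions with intercept; delta-method
  standard errors treating the two slopes as independent). The benchmark
  publication names these estimators by citation without printing formulas,
  so the constructions here are deliberate defaults: the unweighted sample
  median (inverse-variance weighted CDF interpolation as an option), and
  the argmax over a fixed 512-point grid of a normal-kernel density with
  bandwidth $0.9\min(\mathrm{sd}, \mathrm{IQR}/1.34)L_{\mathrm{eff}}^{-1/5}$
  times a user factor, ties toward the smallest grid value. Instruments with
  a numerically zero first-stage slope are excluded as weak with a warning.
  The benchmark's median/mode rows are therefore treated as qualitative, not
  exact, references. Percentile bootstrap intervals (`bootstrap_ci()`,
  seeded, row resampling) provide their uncertainty statements.
* **Post-selection inference** (`post_selection_inference()`): standard
  errors re-fit by TSLS with the selected set treated as known. This
  ignores selection uncertainty — a documented limitation shared by the
  benchmark's reporting — and the bootstrap is the available alternative.

## The synthetic-data generator

`sim_config()` / `generate_dataset()` implement the benchmark designs: $Z
\sim N(0, \Sigma_z)$ with AR(1) entries $\rho^{|j-k|}$,
$(\epsilon, \mu)$ bivariate normal with $\sigma_\mu^2 = 1$ and
$\sigma_{\mu\epsilon} = 0.25$, $\beta_0 = 0$, every first-stage coefficient
$0.20$, and a direct effect of $0.20$ on the first 30% of instruments
($r = 3$ of $L = 10$, or $12$ of $40$). The invalid-signal strength is
$\mathrm{SNR} = \delta_0^\top Q_{11}\delta_0/\sigma_\epsilon^2$ with
$Q = \mathrm{plim}\, n^{-1}\dot Z^\top\dot Z$.

The benchmark design states its SNR values but not which parameter moves to
attain them. We calibrate $\sigma_\epsilon^2 =
\delta_0^\top Q_{11}\delta_0 / \mathrm{SNR}$ analytically (population $Q$,
so the calibration is identical across replications) with everything else
held at its printed value, because the published OLS and naive-TSLS bias
columns are constant across SNR levels — which pins $\delta_0$ and
$\sigma_{\mu\epsilon}$ as fixed and leaves only $\sigma_\epsilon^2$ free.
This reading has a hard limit: at SNR $\ge 2$ (with $L = 10$) the implied
error correlation $\sigma_{\mu\epsilon}/(\sigma_\mu\sigma_\epsilon)$ exceeds
1, so no joint error distribution exists and the high-SNR columns cannot be
generated under any plain reading of the design. When that happens the
generator caps the covariance at 0.99 of the admissible maximum and warns
loudly. Quantitative reproduction is therefore attempted only for the
SNR = 0.1 and SNR = 1 bias rows, which the calibration reaches exactly; the
high-SNR and MSE/RE cells are covered by qualitative property checks
(estimator ordering, consistency patterns) instead.

What the generator emulates: the exact joint distribution of the benchmark
designs, including instrument correlation and endogeneity. What it does not:
non-normal instruments or errors, weak first stages, heteroskedasticity,
clustered or two-sample structures, and real SNP panels (discrete dosages,
linkage disequilibrium). Passing tests on this generator therefore show
correctness of the estimators under the stated model, not robustness beyond
it.

Every replication uses a seed drawn deterministically from the master seed,
so any single replication is reproducible in isolation. Bias is reported as
$|\mathrm{mean}(\hat\beta) - \beta_0|$ (the tables are sign-free); the
squared-error summary is the mean by default with a median option (the
benchmark text says "median squared error" once while its table arithmetic
— bias² + variance ≈ MSE — matches the mean). Relative efficiency follows
the tables' arithmetic, $100 \cdot \mathrm{MSE}_{\mathrm{BSIVE}} /
\mathrm{MSE}_{\mathrm{other}}$ (the note's prose describes the reciprocal;
the printed numbers match this convention, e.g. $100 \cdot 0.0241/0.0166
\approx 145$ against a printed 144.9).

## Diagnostics

`sargan_test()` is the homoskedastic over-identification test ($n R^2$ of
TSLS residuals on all instruments, $\chi^2_{L - |\mathrm{in}| - m}$),
matching the model's conditional-homoskedasticity assumption; it requires
over-identification after conditioning. `first_stage_F()` is the standard
joint F of the first stage, reported per exposure column, with an `Inf`
sentinel for a zero-residual first stage. `snr_pve()` maps a direct-effect
vector and transformed instruments to the SNR and the proportion of
variance explained $\mathrm{SNR}/(1+\mathrm{SNR})$.

## Problem sizes used by the test suite

The packaged checks run the full pipeline at reduced but statistically
meaningful scales, chosen so the whole suite completes in a few minutes:
1000 replications for the $\rho = 0$ bias comparison, 500 for the
correlated and many-instrument designs and for the estimator-ordering
check (with 10-fold CV inside every replication), 2000 for oracle-interval
coverage, and 1000 for the Sargan size check and the descent-monotonicity
property. Deeper Monte Carlo (the full published grids) is available
through `run_monte_carlo()` and the `simulate` subcommand at any
replication count.

## Known limitations

* Homoskedastic inference only; no weak-instrument-robust or
  selective-inference corrections.
* The MIQO backend requires an external solver; within this package
  certified optimality comes from enumeration and is therefore bounded by
  the $\binom{L}{r}$ budget.
* Big-M bounds are row-space guarantees (see above).
* The high-dimensional regime $L > n$ is out of scope, as are panel or
  clustered data.
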