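---
title: "Two-way functional ANOVA with repeated measures by basis expansion"
author: "fanovarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-way functional ANOVA with repeated measures by basis expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanovarm)
```

## The problem

In biomechanics and many longitudinal settings the response of interest is a
curve: a knee-flexion angle over the gait cycle, an acceleration signal over
a time window. When every subject is observed under all of $m$ treatment
conditions (running speeds, movement types) and subjects are divided into
$g$ independent groups (age classes, cohorts), the natural questions are
whether the mean curves differ between treatments, between groups, and
whether the treatment profiles are parallel across groups (no interaction).
Summarising each curve by a few discrete landmarks discards most of the
waveform and can bias the answers; `fanovarm` tests these hypotheses on the
whole curves.

The model is a two-way functional ANOVA with repeated measures: for subject
$k$ of group $j$ under treatment $i$,

$$x_{ijk}(t) = \mu(t) + \alpha_i(t) + \beta_j(t) + \theta_{ij}(t) +
  \epsilon_{ijk}(t), \qquad t \in T,$$

under the sum-to-zero identifiability constraints
$\sum_i \alpha_i = \sum_j \beta_j = \sum_i \theta_{ij} =
\sum_j \theta_{ij} = 0$. The null hypotheses of interest are the nullity of
the treatment effects, of the group effects, and of the interaction
(equivalently, parallelism of the group profiles). Because the same subject
is measured under all $m$ treatments, the $m$ curves of one subject are
correlated, and that intra-subject correlation is exactly what the
repeated-measures machinery must accommodate.

## Basis expansion: curves become coefficient vectors

Curves are observed discretely (here on a common grid) and with noise. Each
sample curve is represented in a finite basis
$\Phi(t) = (\phi_1(t), \ldots, \phi_p(t))'$,

$$x_{ijk}(t) = \mathbf{y}_{ijk}'\Phi(t),$$

with the coefficient vector $\mathbf{y}_{ijk} \in \mathbb{R}^p$ estimated by
per-curve least squares (`fitCoefficients()`). This is the central
reduction: the two-way functional ANOVA becomes a two-way MANOVA with
repeated measures for the $p$-dimensional response of basis coefficients,
and all effect estimators are coefficient means
(`estimateEffects()` implements
$\hat\mu = \bar{\mathbf y}_{\ldots}$,
$\hat\alpha_i = \bar{\mathbf y}_{i..} - \bar{\mathbf y}_{\ldots}$, and so
on, with within-group weight $1/n_j$ and weight $1/g$ across groups).

Defaults and the parameters that matter:

* **Basis family.** Cubic B-splines (`makeBsplineBasis()`), the standard
  choice for non-periodic waveform data; a minimal Fourier alternative
  exists for periodic signals. Knots are equally spaced with boundary knots
  repeated to multiplicity = order; only the dimension $p$ and order are
  free. B-splines form a partition of unity, which gives cheap exactness
  checks (a constant curve is fitted exactly).
* **Dimension `p` (default 14).** Large enough to track the waveform,
  small enough that the multivariate tests keep error degrees of freedom.
  `gcvDimension()` implements generalized cross-validation (per-curve GCV
  with the trace-of-hat-matrix denominator, averaged over curves, ties to
  the smaller `p`) for data-driven selection, but a fixed `p` is the
  default analysis path.
* **Fitting.** Plain least squares through a QR factorization; no roughness
  penalty. Refitting fitted values is exactly idempotent and residuals are
  orthogonal to the basis span on the grid.

## Two testing engines

Write the coefficients of subject $k$ as one long row (treatment-major):
the $n \times pm$ matrix $\mathbf Y$ follows the multivariate linear model
$\mathbf Y = \mathcal X \mathbf B + \mathbf E$ with the $n \times g$
group-indicator design $\mathcal X$. Every hypothesis above is a general
linear hypothesis

$$H_0:\; \mathbf G' \mathbf B (\mathbf T \otimes \mathbf I_p) = 0,$$

where $\mathbf G$ ($g \times s$) holds between-group contrasts and
$\mathbf T$ ($m \times q$, orthonormal) within-treatment contrasts
(`buildContrasts()`): the interaction test uses a contrast basis in both
slots, the group test sets $\mathbf T = \mathbf I_m$, the treatment test
sets $\mathbf G = \mathbf I_g$. For $m = 3$ the treatment-contrast matrix is
pinned to columns $(1/\sqrt2, 0, -1/\sqrt2)'$ and
$(-1/\sqrt6, 2/\sqrt6, -1/\sqrt6)'$; for other $m$ an orthonormalized
Helmert basis is used. All four statistics are invariant to replacing
$\mathbf T$ by $\mathbf T\mathbf Q$ (orthonormal $\mathbf Q$) and to the
choice of contrast basis in $\mathbf G$, which the test suite checks.

**Doubly Multivariate Model (DMM, `dmmTest()`).** MANOVA on the reduced
response $\mathbf Y(\mathbf T \otimes \mathbf I_p)$: error SSCP about the
group-mean fit with $\nu = n - \mathrm{rank}(\mathcal X)$ degrees of
freedom, hypothesis SSCP in the usual sandwich form with a Moore–Penrose
generalized inverse. It assumes only a positive-definite covariance but
needs $n > pm$ (otherwise $S_e$ is singular) — the binding constraint in
practice, e.g. 29 subjects with $p = 27$, $m = 3$ leave the DMM infeasible.

**Mixed Multivariate Model (MMM, `mmmTest()`).** The rows of $\mathbf Y$
are rearranged into per-subject $m \times p$ blocks
($vec((\mathbf Y_i^*)') = \mathbf y_i$, `rearrangeForMmm()`), giving the
$p \times p$ matrices $S_e^*, S_h^*$ with error df $q\nu$; only
$nm > p$ is needed, and when its extra assumption holds the MMM is more
powerful than the DMM. Computationally `mmmSscp()` uses the exact identity
that $S_e^*$ and $S_h^*$ are the sums of the $q$ diagonal $p \times p$
blocks of the DMM reduced-model SSCPs, avoiding the $(nm) \times (nm)$
Kronecker projector; the literal Kronecker expressions are asserted on
small instances in the tests.

From the eigenvalues of $S_h S_e^{-1}$ (computed through the symmetric form
$S_e^{-1/2} S_h S_e^{-1/2}$, negatives clipped at zero) the four classical
statistics are available — Wilks' $\Lambda$ (default, and the one used in
the simulation study), Lawley–Hotelling, Pillai, Roy — with Rao's
F-approximation for Wilks, the standard approximations for Pillai and
Lawley–Hotelling, and the upper-bound F for Roy. The approximations were
verified against R's own `summary.manova()` and reduce exactly to the
univariate F and to paired Hotelling $T^2$ in the corresponding special
cases.

## Multivariate sphericity, and what to do when it fails

The MMM's extra assumption is *multivariate sphericity*: the covariance
$\Omega$ of the contrast-reduced response must be $\mathbf I_q \otimes
\Gamma$ — identical $p \times p$ blocks across contrast directions,
independence between directions. `sphericityTest()` implements the Gaussian
likelihood-ratio test

$$\mathrm{LRT} = \nu\,(q \ln|\hat\Gamma| - \ln|\hat\Omega|)
  \;\sim\; \chi^2_{qp(qp+1)/2 - p(p+1)/2},$$

with $\hat\Omega$ the unbiased (divisor $\nu$) residual covariance and
$\hat\Gamma$ the average diagonal block. The reference only cites this
test, so it is validated here by Monte-Carlo calibration (size near
nominal for large $n$, power approaching 1 against grossly unequal blocks)
rather than against a printed value. It needs $\nu > qp$; when
$\hat\Omega$ is singular the diagnostic is reported as not testable.

When sphericity fails, `adjustedMmmTest()` applies a Box-type correction:
both degrees of freedom of the F-approximation are multiplied by an
$\hat\epsilon \in [1/q, 1]$. The multivariate $\epsilon$ is not given in
closed form by the reference either; the implementation uses a block
partial-trace construction,

$$W_{ab} = \mathrm{tr}(\hat\Gamma^{-1}\hat\Omega_{ab})/p, \qquad
  \hat\epsilon = \frac{\mathrm{tr}(W)^2}{q\,\mathrm{tr}(W^2)},$$

where $W$ is symmetric PSD and equals $\mathbf I_q$ under exact
sphericity. This reproduces the univariate Box epsilon at $p = 1$, gives
$\hat\epsilon = 1$ exactly when $\hat\Omega = \mathbf I_q \otimes \Gamma$,
respects the $[1/q, 1]$ bounds by construction, and demonstrably moves the
type-I error toward the nominal level under violations (a simulation in the
test suite compares adjusted and unadjusted size under treatment-dependent
scales).

## The permutation procedure

For non-Gaussian data `permutationTest()` implements the repeated-measures
permutation scheme: compute $S_0$ on the data; for each of $F$ rounds,
independently reorder each subject's $m$ treatment-labelled coefficient
vectors, then (if $g > 1$) pool all subjects and reassign them without
replacement to groups of the original sizes; recompute the statistic; and
estimate the p-value as the proportion of $S_f \le S_0$ for Wilks
(small values are extreme) or $S_f \ge S_0$ for the other three. Notes:

* The plain proportion estimator is implemented verbatim and can return 0;
  an optional `addOne` flag switches to $(1 + \#)/(1 + F)$ for users who
  need guaranteed-positive p-values. Default $F = 1000$.
* A single seeded generator drives within-subject reordering then group
  reassignment, subject-major, so a seed fixes the whole stream.
* For tiny designs the test can be run on an explicitly enumerated
  permutation set; with $m = 2$, $g = 1$, $n = 3$ the $2^3$ within-subject
  flips reproduce the exact permutation law, which the tests verify.
* Pillai's trace is the default statistic on the `runAnalysis()`
  permutation path, being the most robust of the four to assumption
  violations; any of the four can be requested.
* A statistic that fails on a permuted dataset (numerically singular
  draw) is excluded with a warning and the denominator reduced.

## The simulation engine

`simulateScenario()` and `runPowerStudy()` reproduce the design of the
method's simulation study: $m = 3$, $g = 2$, curves generated on 101
equispaced points of $[0,1]$ from

$$x_{ijk}(t) = \alpha_i(t) + \beta_j(t) + \theta_{ij}(t) +
  \gamma_k \sin(\pi t) + \epsilon_{ijk}(t),$$

with four scenario families (M1–M4) of closed-form effect functions
(`effectFunction()`), i.i.d. Gaussian errors with SD $\sigma_\epsilon \in
\{0.10, 0.20, 0.40\}$ or (scenario M2) a Brownian error
$\epsilon(t) = B(t)/20$, and a subject effect
$\gamma_k \sim N(\mu_k, 0.2)$, $\mu_k \sim U(0, 0.05)$, drawn once per
subject and shared across that subject's three curves — this sharing is
precisely what makes the measures "repeated". Each replicate fits $p = 14$
cubic B-splines and runs the DMM and MMM Wilks tests for parallelism,
treatment and group; acceptance means $p \ge \alpha$ at $\alpha = 0.05$.

Generator choices worth stating explicitly:

* "i.i.d. $N(0, \sigma_\epsilon)$" is read with $\sigma_\epsilon$ as a
  standard deviation, consistent with its role as a dispersion parameter.
* The Brownian error is read as a zero-start Brownian motion whose
  increments have SD $\sigma_\epsilon\sqrt{\Delta t}$, then scaled by
  $1/20$. The alternative parameterizations differ only in overall scale;
  with this reading the full-null M2 acceptance reproduces the reference
  value within Monte-Carlo error, while the M2 curve noise is so small
  relative to the subject effect that false group/parallelism nulls are
  rejected in essentially every replicate (the reference's corresponding
  worst-case error is 7.8%; both are comfortably below the 8% narrative
  bound).
* The generator has no grand-mean function $\mu(t)$; the model is
  implemented exactly as specified for the study.
* The subject effect spans a one-dimensional function space
  ($\sin(\pi t)$), so for the group test (where it does not cancel) the
  error covariance is strongly anisotropic; this is a feature of the study
  design, not an artifact.

What the generator does *not* emulate about real waveform data: phase
misalignment (no registration/warping), heteroscedastic groups,
non-Gaussian errors, missing treatments, and ragged grids. Passing the
Monte-Carlo checks therefore demonstrates correctness of the testing
machinery under the stated conditions, not robustness to those departures —
the permutation path exists precisely for the distributional ones.

## Numerical choices

* Generalized inverses are Moore–Penrose throughout (SVD with a
  machine-epsilon-scaled singular-value cutoff).
* Wilks' lambda on the Monte-Carlo path is computed from Cholesky
  log-determinants, with an eigenproblem fallback when the factorization
  fails.
* When both $S_h$ and $S_e$ are at round-off zero relative to the data
  (identical curves), the $0/0$ statistic is reported at its null extreme
  ($W = 1$, $p = 1$) rather than as garbage from a Cholesky of a
  $10^{-32}$ matrix; an exactly singular $S_e$ alone raises an error
  naming the violated dimension condition.
* GCV ties break toward the smaller dimension; effect estimates are
  returned as coefficient vectors plus the basis (never dense grids), so
  downstream tests operate on coefficients.
* Unbalanced group sizes use the unweighted average of per-group means
  exactly as in the balanced formulas; properly weighted constraints for
  unbalanced designs are documented as unsupported.

## Problem sizes used in the checks

The packaged Monte-Carlo checks run 500 replicates per scenario cell (the
study's replication count) for: the M1 full-null grid (six cells), the
reference acceptance values of the M1/M2/M3/M4 anchor cells, the M2
$\sigma_\epsilon = 0.20$ false-null grid, and the M3 $\sigma_\epsilon =
0.40$ parallelism grid. Structural properties (oracle equivalences, exact
identities, exhaustive permutation law) run on small designs where
brute-force references are exact.

## A worked example

```{r example, eval = FALSE}
library(fanovarm)

## curves: 4 subjects per group, 2 groups, 3 treatments, 21 grid points
path <- system.file("extdata", "example_curves.csv", package = "fanovarm")
curves <- readCurves(path)
curves

coeffs <- fitCoefficients(curves, makeBsplineBasis(c(0, 1), p = 8))
est <- estimateEffects(coeffs)
decompositionCheck(est, coeffs)

mmmTest(coeffs, "treatment")
adjustedMmmTest(coeffs, "treatment")
permutationTest(coeffs,
                permutationPlan(nPerm = 500, seed = 1, statistic = "P",
                                model = "mmm", hypothesis = "treatment"))
```

## Limitations

* Balanced repeated measures only: every subject must be observed under
  all treatments, on a common grid.
* Roy's root uses the upper-bound F only (anti-conservative; prefer Wilks
  or Pillai for inference).
* No high-dimensional DMM variant for $pm \ge n$ and no heteroscedasticity
  corrections; the permutation path is the recommended fallback.
* No pointwise confidence bands for the effect functions.
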