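# fanovarm

Two-way functional ANOVA with repeated measures (FANOVA-RM) by basis
expansion.

## What problem this solves, and for whom

In gait analysis and similar studies the data are *curves* — a knee-flexion
angle over the movement cycle, an acceleration waveform — observed for each
subject under all of *m* treatment conditions (speeds, movement types),
with subjects split into *g* independent groups (e.g. age classes). The
questions are the classical two-way ANOVA ones, asked about whole curves:

* do the treatment mean curves differ?
* do the group mean curves differ?
* are the treatment profiles parallel across groups (no interaction)?

Reducing each curve to a few landmarks discards information and can bias
the answers. `fanovarm` is for biostatisticians and movement scientists who
want these tests on the complete curves, with the within-subject
correlation of repeated measures handled properly.

## The method

Each observed curve is projected onto a finite basis (cubic B-splines by
default), `x_ijk(t) = y_ijk' Φ(t)`, reducing the functional model

    x_ijk(t) = μ(t) + α_i(t) + β_j(t) + θ_ij(t) + ε_ijk(t)

to a MANOVA with repeated measures on the p-dimensional coefficient
vectors `y_ijk`. Every hypothesis becomes a general linear hypothesis
`G' B (T ⊗ I_p) = 0` on the coefficient model `Y = XB + E`, where `G`
holds between-group contrasts and `T` orthonormal within-treatment
contrasts. Two engines test it:

* **DMM** (doubly multivariate model): MANOVA on the reduced response
  `Y(T ⊗ I_p)`; assumes only a positive-definite covariance but needs
  `n > p·m`;
* **MMM** (mixed multivariate model): the response is rearranged into
  per-subject `m × p` blocks; needs only `n·m > p` and is more powerful,
  but assumes *multivariate sphericity* `Ω = I_q ⊗ Γ`, for which a
  likelihood-ratio test (`sphericityTest()`) and a Box-type
  degrees-of-freedom correction (`adjustedMmmTest()`) are provided.

Wilks' lambda, Lawley–Hotelling, Pillai and Roy statistics are available
with their standard F-approximations, plus a repeated-measures permutation
test (`permutationTest()`) for non-Gaussian data. A simulation engine
(`simulateScenario()`, `runPowerStudy()`) generates curve data under four
scenario families of effect functions with Gaussian or Brownian errors and
a per-subject random effect, and measures empirical size and power.

See the vignette `vignettes/fanova-repeated-measures.Rmd` for the full
model account, assumptions and numerical choices.

## A worked example

The package ships a small long-format dataset (8 subjects in 2 groups,
3 treatments, 21 grid points) with a real treatment effect and a weak
group effect:

```r
library(fanovarm)

path   <- system.file("extdata", "example_curves.csv", package = "fanovarm")
curves <- readCurves(path)
curves
#> CurveSet: 24 curves on 21 grid points | n = 8 subjects, m = 3 treatments, g = 2 groups

coeffs <- fitCoefficients(curves, makeBsplineBasis(c(0, 1), p = 8))
est    <- estimateEffects(coeffs)
decompositionCheck(est, coeffs)
#> [1] TRUE

mmmTest(coeffs, "treatment")
#> MMM treatment test (W): statistic = 4.85397e-05, F(32, 20) = 8.629, p = 2.463e-06
mmmTest(coeffs, "group")
#> MMM group test (W): statistic = 0.0517615, F(24, 32.5) = 2.405, p = 0.0102
mmmTest(coeffs, "interaction")
#> MMM interaction test (W): statistic = 0.0260436, F(16, 10) = 3.248, p = 0.03203

adjustedMmmTest(coeffs, "treatment")
#> MMM_ADJUSTED treatment test (W): statistic = 4.85397e-05, F(32, 20) = 8.629, p = 2.493e-06

permutationTest(coeffs,
                permutationPlan(nPerm = 500, seed = 1, statistic = "P",
                                model = "mmm", hypothesis = "treatment"))
#> PERMUTATION treatment test (P): statistic = 2.83199, p = 0.002
```

Reading the output: the Wilks statistic near 0 and p ≈ 2.5e-06 say the
treatment mean curves differ strongly (the simulated treatment effect
scales with the treatment index); the group test is borderline (a weak
group effect was injected); the interaction test is marginal at this tiny
sample size. The permutation p-value 0.002 (= 1/500) is the smallest value
its estimator can resolve at F = 500 and agrees with the parametric
conclusion. `runAnalysis()` wires the same steps — smoothing, feasibility
checks (it refuses the DMM whenever `n ≤ p·m`), tests, sphericity
diagnostic — into one call driven by a config list or YAML file, and
`inst/scripts/fanova-rm.R` exposes `test`/`simulate` subcommands for shell
use.

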