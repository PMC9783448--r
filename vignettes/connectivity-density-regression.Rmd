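---
title: "Connectivity density regression: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity density regression: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConnDensity)
```

## The idea

A subject's functional connectome is a symmetric matrix of correlations
between brain regions. Edgewise analyses assume the same region pair plays
the same functional role in every subject; when an intervention's footprint
wanders across subjects — as a 25 cm² stimulation electrode over frontal
cortex plausibly does — that assumption costs power, and at 78 regions it
also costs a 3003-fold multiplicity correction.

`ConnDensity` instead treats the `p(p-1)/2` edge correlations of subject
*i* as if they were draws from a subject-specific **connection density**
`f_i` on [−1, 1]. Any relabeling of regions leaves `f_i` unchanged, so the
summary is invariant to subject-specific topography by construction. The
density (suitably transformed) then enters a logistic regression for the
binary group label:

$$\operatorname{logit} P(A_i = 1 \mid X_i, f_i)
  = X_i^\top \beta + \int (T\hat f_i)(q)\, g(q)\, dq .$$

Putting the label on the left is inverse case–control regression: under
randomization, Bayes' rule shows this conditional model is consistent with
any forward model in which the group affects the density only through
$\langle T f_i, g\rangle$, and it spares us a probability model on the
space of densities. The cost of the density view is deliberate: all
localization information is discarded, so a genuinely localized effect is
better found by an edgewise method — the package ships both baselines so
the comparison is one function call.

## Density estimation

**Log-spline (default).** The log-density is expanded in 19 cubic
B-spline basis functions on [−1, 1] (an evenly spaced clamped knot
sequence) and fitted by penalized maximum likelihood with a
second-derivative roughness penalty; the normalization constant is
computed by composite Gauss–Legendre quadrature over the knot spans, and
the Newton iterations run in compiled code. The exponential form keeps
`f̂ > 0` everywhere and the support exactly [−1, 1] — both properties the
log-density-quantile transform needs. The penalty weight is chosen per
subject by minimizing deviance + 2·1.4·edf over the grid
`n·10^{0,…,−6}`, where edf is the ridge-type effective degrees of freedom
of the working model; the 1.4 inflation is the customary guard against
the undersmoothing of plain cross-validatory scores in density
estimation. Input correlations are clipped to `[−1+10⁻⁶, 1−10⁻⁶]` (finite
time series essentially never reach ±1 exactly and the basis needs
interior points), and edge values are sorted before fitting so a fit is a
function of the edge *multiset* — bit-for-bit label invariance.

**Kernel (comparison).** A Gaussian kernel estimate with Silverman's
rule-of-thumb bandwidth, reflected about both support ends to remove
boundary bias and renormalized exactly; pdf and cdf are closed-form
Gaussian-mixture expressions. Tail values can underflow; logs are floored
at 10⁻¹² with a warning. On smooth samples the two estimators' log
density quantile curves agree to well under 0.1 sup-norm, so downstream
conclusions do not hinge on the estimator.

**Evaluation contracts.** `evaluateDensity()` is exact (basis evaluation
or closed form), the cdf integrates the spline density by per-span
Gauss–Legendre, and `invertCdf()` bisects to 10⁻⁸ (sorted level grids are
passed through a running maximum to undo the ~10⁻⁸ bisection jitter).
Every estimate integrates to 1 within 10⁻⁶.

## Transforms and the quantile grid

Four transforms are provided: identity (`f̂` on a support grid — the
moment-style view), `log f̂`, the quantile function `F̂⁻¹`, and the **log
density quantile** `log f̂(F̂⁻¹(q)) = −log dF̂⁻¹/dq`, a curve indexed by
quantile level rather than correlation value. Quantile synchronization
aligns subjects by rank rather than by absolute correlation, which makes
tail effects comparable across subjects with different overall
connectivity levels; it is the package default.

Quantile-indexed transforms are evaluated on `quantileGrid(m = 101)`, the
midpoints `(j−½)/m`. Midpoints keep all levels strictly inside (0, 1),
where `F̂⁻¹` stays off the support boundary. Quadrature on this grid uses
the midpoint rule (each weight `1/m`, unit total mass) — the natural rule
for a midpoint grid, and the reason a constant coefficient function
against the exact uniform density integrates to exactly −log 2; support
grids use the trapezoid rule. 101 levels resolve every feature a
19-basis density can carry; doubling the grid changes nothing that
matters.

## Functional PCA and the fit

The transformed curves are reduced by functional PCA: eigendecomposition
of the sample covariance in the grid's quadrature inner product, with an
optional (default on) light penalized B-spline projection smoothing of
the covariance surface — 15 basis functions per margin and a small fixed
relative penalty (10⁻⁴). Components are retained up to 99% cumulative
variance. Heavier, data-driven covariance smoothing was examined and
rejected: generalized cross-validation consistently selects almost no
smoothing for these curves, because subject-to-subject curve variation is
genuinely high-dimensional here, not an artifact of estimation noise.

PC scores are *uncentered* inner products `⟨T f̂_i, φ_k⟩`, so the fitted
functional term equals the direct quadrature `∫ T f̂_i ĝ` for every
subject exactly (the mean offset moves into the intercept). The logistic
fit is ordinary maximum likelihood on `[X | scores]`. Perfect separation
— a real possibility at n ≈ 50 with ~10 components — triggers a
ridge-stabilized refit (L2 penalty 10⁻⁴) with a warning, and the fit
records the fallback so downstream inference can flag it.

**Inference.** The likelihood-ratio test compares against the
covariates-only logit on χ²_K; `bonferroni = 3` corrects across the three
non-identity transforms. The permutation test shuffles which density
belongs to which subject (covariate rows fixed — the exchangeable object
under the null is the curve assignment), refits, and compares in-sample
AUC; because the *set* of curves is unchanged, the FPCA basis is
permutation-invariant and only score rows shuffle, which makes 20,000
permutations affordable. Confidence bands are pointwise Wald/Bayes bands
from the inverse observed information propagated through the
eigenfunctions; a simultaneous band is not implemented.

## The simulator

`simulateStudy()` generates what the benchmark needs and nothing more:
per subject, edge angles `θ_ij` i.i.d. von Mises(μ_i, κ_i), connectivity
`cos θ_ij`; a "stimulation" rotates the angles at one region by φ and
takes the convex combination `w·C + (1−w)·cos(θ+φ)` on that region's
edges. At the defaults (φ = π, w = 0.75) this halves the stimulated row —
the rotation is implemented through `cospi`/`sinpi` and an incremental
update so the identity holds bit-exactly. The subject population
(μ_i wrapped-normal(1.2, 0.3), log κ_i normal(log 1.5, 0.4)) is a
stand-in chosen to give right-skewed, positive-mode edge densities of the
kind real resting-state studies show; the parameters a real study would
supply (per-subject fits to observed scans) are not publicly available,
and all four prior parameters are configuration fields.

What the simulator does **not** emulate: spatial correlation among edges
sharing a region, temporal autocorrelation of the underlying signals,
atrophy-driven heterogeneity, site or motion artifacts. Passing the
benchmark therefore demonstrates the statistical contrast it was designed
to show — non-localized effects invisible to edgewise scans but visible
to density regression — not performance on real scanner data.

## Numerical and design choices

- Canonical edge order is the row-major upper triangle (s < t);
  relabeling invariance is enforced by sorting edge values before
  density fitting.
- `invertCdf` rejects levels 0 and 1 (the inverse is the support
  boundary); bisection tolerance 10⁻⁸.
- Degenerate inputs fail loudly: fewer than 20 distinct edge values, a
  constant sample, non-symmetric or out-of-range matrices (the offending
  subject and entry are named), duplicate subject ids.
- Edgewise scans assign separated edges p = 1 (conservative); the PC
  model truncates components at n − q − 1 with a warning.
- The benchmark's per-method decision is "any familywise-significant
  finding at α" — Bonferroni-adjusted minimum p for the localized
  methods, the LRT for the density methods (the permutation test is
  exact but too costly inside 1000 replicates; it is available behind
  `permutationAucTest`).
- Per-replicate seeds derive deterministically from the master seed, so
  benchmark decision matrices are reproducible replicate by replicate.

## Known limitations

- **Small-sample LRT calibration.** The χ²_K reference is anticonservative
  when many components are retained relative to n: with ideal Gaussian
  scores at n = 50 the type-I rate is ≈0.07 at K = 5 and ≈0.13 at K = 11.
  Under the simulator's default population the log-density-quantile curve
  family is intrinsically high-rank, the 99% rule retains ≈11 components
  at n = 50, and the LRT's null positive rate lands near 0.13 rather than
  0.05. The calibration is restored at larger n (the suite demonstrates
  0.03–0.07 at n = 150, K = 3) and the permutation test is exact at any
  n; at n ≈ 50 the permutation p-value is the one to report.
- **Transform ranking is population-dependent.** Under the default
  stand-in population the identity-transform model is at least as
  powerful as the log-density-quantile model for the benchmark's
  perturbation; the tail-emphasizing advantage of quantile
  synchronization depends on where the effect sits in the density, so the
  ranking should be expected to vary with the connectivity population.
- **Induced-connectivity localization is qualitative.** The per-edge
  effect `g(Q)·log f(C)` vanishes wherever `f ≈ 1` regardless of `g`, so
  a perturbation that parks edges near unit density height is invisible
  to the diagnostic; with the default simulator its region-recovery rate
  is well under the levels a dedicated localization method achieves. It
  is a descriptive map, not a test.
- The fPCA ignores any density-implied constraints on the curves, and no
  longitudinal or multivariate-density extension is attempted.
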