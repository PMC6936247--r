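---
title: "Tri-isotope niche ellipsoids: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-isotope niche ellipsoids: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trisev)
```

## The model

A population's isotopic niche in (δ¹³C, δ¹⁵N, δ³⁴S) space is modelled as a
trivariate normal distribution N(μ, Σ). The *standard ellipsoid* is the
surface at squared Mahalanobis radius 1; its semi-axes a ≥ b ≥ c are the
square roots of the eigenvalues of Σ and its volume is

SEV = (4/3) π a b c = (4/3) π √det(Σ),

the three-dimensional analogue of the bivariate standard ellipse area (SEA).
Because the squared Mahalanobis radius of a trivariate normal is χ²₃, the
standard ellipsoid captures pchisq(1, 3) ≈ 19.9% of the population ("about
20%"), and the surface capturing any fraction p sits at squared radius
qchisq(p, 3). `scale_to_coverage()` multiplies the shape matrix by the ratio
of target to current χ²₃ quantiles, so rescaling composes and is exact under
the normality assumption. Volume comparisons are only meaningful
like-for-like, so every `ellipsoid` carries its coverage state; the
convention throughout is 0.75 ("75% ellipsoids", EV_B).

`ellipsoid_from_sample()` uses the unbiased (n−1) sample covariance. SEV from
a finite sample is biased low; the three-dimensional degrees-of-freedom
correction is SEV_C = SEV × (n−1)/(n−3) (`sev_c()`). Because the shape matrix
is already the unbiased covariance, the correction must be applied exactly
once — the function never applies it implicitly.

## Bayesian volumes (SEV_B, EV_B)

`fit_posterior()` Gibbs-samples the posterior of (μ, Σ). Both supported
priors are conjugate, so the conditionals are exact draws (normal for μ,
Inverse-Wishart via `stats::rWishart` for Σ) and the chain mixes immediately
— no tuning, no adaptation. Defaults mirror the conventional run lengths for
volume estimation (15,000 iterations, burn-in 10,000, thinning 25, giving
floor(5000/25) = 200 retained draws) and for overlap (7,500 / 5,000; the
thinning factor for overlap runs is not fixed by convention, so the pipeline
defaults to thin = 1 there). Each covariance draw is converted to a volume at
the requested coverage; `volume_posterior()` reports the median with the
25–75% interquartile range, and `overlap_posterior()` reports medians with
equal-tailed 95% credible intervals (linear-interpolation quantiles, type 7).
Equal-tailed intervals were chosen over HPD: they are quantile-based, so they
are invariant under the monotone rescalings used throughout (coverage,
det^(1/2)) and simpler to reproduce.

### Choice of default prior

The default prior is the multivariate Jeffreys prior p(μ, Σ) ∝
|Σ|^−(p+2)/2, under which the marginal posterior of Σ is Inverse-Wishart on
the centered sum of squares with n degrees of freedom. The proper
"vague" Normal-Inverse-Wishart alternative (`niw_prior()`: κ₀ = 10⁻³,
scale 10⁻³ I, ν₀ = 4) is available and exercised in the tests, but it is not
the default for a quantifiable reason: a proper IW prior with ν₀ extra
degrees of freedom multiplies the posterior-median volume by roughly
exp(−3(ν₀+1)/(2n)) — about −7% at n = 100 for ν₀ = 4, and its 95% volume
intervals cover the truth only ~83% of the time at n = 30. The Jeffreys
posterior shrinks volumes by only ≈ −3/(2n): still visibly negative at small
sample sizes (a median relative bias around −30% to −45% for n ≤ 8 in the
package's own simulations — the known small-n underestimation of Bayesian
ellipsoid volume), but ≲ 2% by n = 100, with near-nominal interval coverage
(92/100 at n = 30 in `test-bayes.R`). `small_sample_bias_sim()` reproduces
this bias curve on demand.

Posterior draws are paired by retained-draw index across groups when
computing overlap posteriors, and each group fit uses its own seeded
generator, so results are reproducible end to end.

## Mesh overlap

There is no convenient closed form for the intersection volume of two
arbitrary ellipsoids, so overlap is estimated geometrically. Each ellipsoid
is meshed with quadrilateral faces: the level-0 mesh is a 16×16
latitude–longitude grid on the unit sphere mapped through the Cholesky
factor of the shape matrix, and each subdivision level splits every quad
into four, reprojecting new vertices onto the surface ("subdivision 4" =
four quadrisections, 65,536 faces). The intersection of two ellipsoids is
convex, so the convex hull of

* vertices of mesh A inside ellipsoid B,
* vertices of mesh B inside ellipsoid A, and
* the crossing points of each mesh's edges with the other surface
  (a quadratic along each edge),

is an *inner* approximation of the true overlap volume: estimates increase
monotonically with subdivision and converge from below. The edge-crossing
points sharpen the hull near the intersection rim; the subdivision-
convergence tests confirm the bias still vanishes (the level-4 sphere–sphere
lens is within 0.1% of the closed form π(4R+d)(2R−d)²/12).

Directed percentages divide the intersection-hull volume by each mesh's own
hull volume *at the same subdivision*, not by the analytic SEV. This makes
the discretization bias cancel between numerator and denominator: identical
ellipsoids report exactly 100%, and the directed percentages are unbiased on
the interpretive 0–100% scale even at modest subdivision. Overlap of at
least 60% is flagged as significant niche overlap (`classify_overlap()`).

The hull volume itself is computed by a quickhull implementation in compiled
code (volume only). Points within 10⁻¹⁰ × extent of the current hull are
treated as interior — degenerate inputs (fewer than four points, coplanar
sets, tangent ellipsoids) therefore return volume 0 rather than erroring.
`mc_overlap_oracle()` provides an independent rejection-sampling check used
throughout the tests.

## Preprocessing

**Lipid correction.** Lipids are depleted in ¹³C; bulk δ¹³C of fatty muscle
is corrected by mass balance when C:N > 3.7:
δ¹³C_protein = [δ¹³C_sample × C:N + 7(C:N − 3.7)] / C:N, with protein C:N
3.7. The equation is not idempotent, so tables carry a `lipid_corrected`
flag and `prepare_isotopes()` refuses to apply it twice.

**Layman ranges.** CR/NR/SR are per-axis max − min within a group (after
lipid correction); they need at least two rows and are monotone under added
rows.

**Mardia's test.** Multivariate skewness b₁,₃ = n⁻² Σᵢⱼ gᵢⱼ³ and kurtosis
b₂,₃ = n⁻¹ Σᵢ gᵢᵢ², with gᵢⱼ the doubly-centered Mahalanobis inner products
computed from the MLE (n denominator) covariance. The skewness statistic
n b₁,₃/6 is referred to χ²₁₀, with the small-sample correction factor
(p+1)(n+1)(n+3)/[n((n+1)(p+1)−6)] applied automatically below n = 20; the
kurtosis z-score (b₂,₃ − 15)/√(120/n) is referred to N(0, 1). The skewness
sum is evaluated through the third-moment tensor (O(n p³) rather than the
n×n Gram matrix), so large samples are cheap. The tool only reports
verdicts; deciding whether non-normal groups represent genuinely divergent
individuals is left to the analyst.

## Synthetic data

`default_group_specs()` ships a 14-group synthetic community shaped like a
two-area atoll survey of seven sympatric reef predators, including one
single-fish group that the pipeline must skip (`min_n`, default 4). Group
means are survey-like values; per-axis standard deviations are reconstructed
from standard errors as SE·√n. What the generator does *not* emulate:
inter-isotope correlation (covariances are diagonal — summary tables cannot
identify correlations, so none are invented; `group_spec()` accepts full
covariances when you have them), non-normal tails, size-structured means, or
measurement error. Passing tests therefore demonstrate correctness of the
estimators under the stated trivariate-normal model, not robustness to
violations of it. C:N ratios are drawn uniform(2.9, 4.5) so both
lipid-correction branches are exercised.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at the sizes the
checks need, chosen once: Monte Carlo coverage checks use 10⁵ samples
(binomial SE ≈ 0.13%, comfortably inside the ±1% bands); mesh–Monte-Carlo
agreement uses 20 random pairs at subdivision 4 against 10⁶-point rejection
sampling (max(5%, 3 SE) band); the small-sample bias curve uses 100
replicates per n ∈ {5, 8, 100} with short chains (the conjugate sampler's
draws are nearly independent, so 233 retained draws per fit are plenty);
pipeline and posterior-overlap tests use coarser meshes (base 8, subdivision
1) where only the statistical contract, not mesh accuracy, is under test.
Other fixed choices: eigenvalues below 10⁻¹² × the largest trigger a
"degenerate covariance" error instead of silent regularization; equal
eigenvalues are an arbitrary axis-ordering tie that volumes never see;
coplanarity tolerance in the hull is 10⁻¹⁰ × extent; containment tests use a
10⁻⁹ boundary tolerance so surface vertices count as inside (this is what
makes self-overlap exactly 100%).

## Known limitations

* Overlap at subdivision 4 with the 16×16 base costs a few seconds per pair
  (hulls over ~10⁵ points); posterior overlap over hundreds of draws is
  therefore typically run at lower subdivision or a coarser base grid, at
  some cost in per-draw accuracy (percentage denominators still cancel).
* The mesh estimate is an inner bound; at subdivision 0–1 it can
  underestimate thin lens-shaped intersections noticeably.
* Only the three-dimensional case is implemented; nothing generalizes to
  p ≠ 3 here.
* Credible intervals are equal-tailed, not HPD; with ~200 retained draws the
  2.5%/97.5% endpoints carry visible Monte Carlo noise.
* The significance rule (≥ 60%) is a convention on the median directed
  overlap, not a hypothesis test.
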