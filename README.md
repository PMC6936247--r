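# trisev — tri-isotope niche ellipsoids

Quantitative trophic ecologists routinely summarize a population's isotopic
niche as the "standard ellipse" of its (δ¹³C, δ¹⁵N) values. Adding sulfur
(δ³⁴S) as a third axis separates production pathways that carbon and
nitrogen alone confound — but it also means the familiar bivariate ellipse
toolkit no longer applies. **trisev** provides the three-dimensional
machinery: niche *ellipsoids* for trivariate stable-isotope data, their
volumes, Bayesian uncertainty, and pairwise overlap.

For a trivariate-normal niche N(μ, Σ) with covariance eigenvalues
λ₁ ≥ λ₂ ≥ λ₃ and semi-axes a = √λ₁, b = √λ₂, c = √λ₃:

* **SEV** (standard ellipsoid volume) = (4/3)·π·a·b·c = (4/3)·π·√det(Σ),
  the 1-sigma ellipsoid containing ≈ 20% of the population
  (`P(χ²₃ ≤ 1) ≈ 0.199`);
* **SEV_C** = SEV × (n−1)/(n−3), the three-dimensional small-sample
  correction;
* any coverage fraction p is reached by scaling Σ by the χ²₃ quantile
  qchisq(p, 3) — "75% ellipsoids" are the reporting convention;
* **SEV_B / EV_B**: posterior volume distributions from a conjugate Gibbs
  sampler of (μ, Σ) (multivariate Jeffreys prior by default, proper
  Normal-Inverse-Wishart optional), summarized as median and IQR;
* **overlap**: ellipsoid surfaces are meshed with quadrilateral faces and the
  intersection approximated by the convex hull of mesh points inside both
  bodies plus edge–surface crossings; directed overlap is the hull volume as
  a percentage of each ellipsoid's own mesh-hull volume (identical
  ellipsoids ⇒ exactly 100%), with ≥ 60% flagged as significant. Overlap
  posteriors come from per-draw meshing of paired posterior samples.

Preprocessing utilities cover the standard fish-muscle workflow: arithmetic
lipid correction of δ¹³C when C:N > 3.7, Layman ranges (CR/NR/SR), Mardia's
multivariate normality test with its small-sample skewness correction, plus
a synthetic-community generator and a CLI.

## Worked example

```r
library(trisev)

tab  <- prepare_isotopes(simulate_groups(default_group_specs(), seed = 1))
grp  <- as.matrix(subset(tab, species == "Lutjanus bohar" & area == "inner",
                         c(d13C, d15N, d34S)))
e <- ellipsoid_from_sample(grp)
e
#> Trivariate niche ellipsoid
#>   center   : -14.920, 12.333, 18.681
#>   semi-axes: 2.668, 0.793, 0.441
#>   volume   : 3.9094  (coverage 19.9%, n = 12)
sev(e); sev_c(e)
#> [1] 3.909414
#> [1] 4.778173

fit <- fit_posterior(grp, seed = 2)         # 15,000 / 10,000 / 25
volume_posterior(fit, coverage = 0.75)
#> Posterior ellipsoid volume at 75% coverage: median 36.700 (IQR 28.146-48.206, 200 draws)
```

The ellipsoid is printed with its semi-axes (per mil) and 1-sigma volume
(‰³); `sev_c` applies the (12−1)/(12−3) correction. The Bayesian 75% volume
(EV_B) is the posterior median over 200 retained covariance draws, each
rescaled by qchisq(0.75, 3)^1.5 ≈ 8.33 relative to 1-sigma — hence ~36.7 ‰³
against the analytic 32.6 ‰³ for this n = 12 group.

```r
grp2 <- as.matrix(subset(tab, species == "Lutjanus gibbus" & area == "inner",
                         c(d13C, d15N, d34S)))
f1 <- fit_posterior(grp,  iterations = 7500, burn_in = 5000, thin = 25, seed = 2)
f2 <- fit_posterior(grp2, iterations = 7500, burn_in = 5000, thin = 25, seed = 3)
overlap_posterior(f1, f2, coverage = 0.75, subdivision = 2, base_n = 8)
#> Posterior niche overlap at 75% coverage (100 paired draws)
#>   A overlapped by B: 11% (95% CI 4-29)
#>   B overlapped by A: 64% (95% CI 40-100)
```

Overlap is directed: 11% of the (large) *L. bohar* ellipsoid lies inside the
*L. gibbus* ellipsoid, while 64% of *L. gibbus* lies inside *L. bohar* — a
significant overlap under the ≥ 60% rule (`classify_overlap(64)`).

The full pipeline (validation → lipid correction → Mardia/Layman → per-group
EV_B → per-area overlap matrices) runs from R via `run_pipeline()` or from a
shell:

```sh
Rscript inst/cli/trisev.R simulate --out table.csv --seed 1
Rscript inst/cli/trisev.R run --input table.csv --out-dir results/
```

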