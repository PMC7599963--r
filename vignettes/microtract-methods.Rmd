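---
title: "White-matter microstructure mapping and skeleton inference: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{White-matter microstructure mapping and skeleton inference: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtract)
```

## What the package computes

`microtract` implements a complete analysis chain for single-shell
diffusion-weighted MRI of white matter:

1. **Diffusion-tensor scalars.** Per voxel the signal is modelled as
   $S(\mathbf{g}, b) = S_0 \exp(-b\,\mathbf{g}^\top D\,\mathbf{g})$.
   From the sorted eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$ of
   $D$ we report FA, MD $=(\lambda_1+\lambda_2+\lambda_3)/3$,
   AD $=\lambda_1$ and RD $=(\lambda_2+\lambda_3)/2$.
2. **Return-probability (EAP) scalars.** The return-to-origin, -axis and
   -plane probabilities are integrals of the q-space signal over all of
   q-space, over the plane perpendicular to the principal axis, and
   along the principal axis. Under a Gaussian propagator with diffusion
   time $\tau$ they have closed forms in the eigenvalues:
   $\mathrm{RTOP} = (4\pi\tau)^{-3/2}(\lambda_1\lambda_2\lambda_3)^{-1/2}$,
   $\mathrm{RTPP} = (4\pi\tau\lambda_1)^{-1/2}$,
   $\mathrm{RTAP} = (4\pi\tau)^{-1}(\lambda_2\lambda_3)^{-1/2}$,
   so $\mathrm{RTOP} = \mathrm{RTPP}\times\mathrm{RTAP}$ identically.
3. **Apparent (single-shell) EAP scalars.** Without assuming a global
   Gaussian propagator, the shell signal yields a directional ADC
   $D(\mathbf u) = -\log(S(\mathbf u)/S_0)/b$, fitted with real *even*
   spherical harmonics (antipodal symmetry makes odd orders vanish and
   the gradient sign convention irrelevant). Extending the signal
   mono-exponentially along each ray — the radial-independence
   assumption — turns the three q-space integrals into directional
   averages:
   $\mathrm{RTOP} = (4\pi\tau)^{-3/2}\langle D(\mathbf u)^{-3/2}\rangle_{S^2}$,
   $\mathrm{RTPP} = (4\pi\tau D(\mathbf e_1))^{-1/2}$, and
   $\mathrm{RTAP} = (4\pi\tau)^{-1}\langle D(\mathbf u)^{-1}\rangle$
   over the great circle perpendicular to $\mathbf e_1$. On a noise-free
   tensor signal every ray *is* mono-exponential, so the apparent route
   must agree with the closed forms — the package's central
   cross-validation, which holds to well under 1% at spherical-harmonic
   order 6 on 61 directions.
4. **Skeleton group inference.** A mean-FA skeleton is extracted, each
   subject's maps are projected onto it, and two-group contrasts are
   tested voxel-wise with threshold-free cluster enhancement (TFCE) and
   permutation-based family-wise-error correction, with optional nuisance
   covariates (Freedman–Lane). Atlas regions summarise significant
   voxels.
5. **Cohort statistics.** The demographic-table tests (chi-square,
   Fisher exact, pooled t, Mann–Whitney U, Kruskal–Wallis, a
   Kolmogorov–Smirnov/Levene gate between parametric and rank tests) and
   region-wise Spearman correlations with Benjamini–Hochberg correction.

Because no imaging data ship with the package, a synthetic cohort
generator provides tensor-field phantoms with seeded group effects so
that every stage is testable end to end.

## Why two routes to the return probabilities

RTOP and RTAP involve $1/\sqrt{\lambda_3}$ and
$1/\sqrt{\lambda_2\lambda_3}$: in high-anisotropy voxels the smallest
eigenvalue of a noisy tensor fit wanders near (or below) zero and the
closed-form route produces absurdly large or undefined values. The
apparent route replaces per-voxel eigenvalues with integrals of the
smoothly-fitted ADC profile and is markedly more stable. The package
reproduces this contrast as a test: at baseline SNR 20 on a highly
anisotropic phantom, the unclamped tensor route yields values more than
$10^3\times$ the noise-free median (or non-finite) in more than 0.1% of
voxels, while the 99.9th percentile of the apparent route stays bounded.
For the closed-form route the eigendecomposition therefore clamps
eigenvalues at $\varepsilon_\lambda = 10^{-6}\,\mathrm{mm^2/s}$ and
counts how often the floor fires.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `tau` | 0.025 s | effective diffusion time; scales the return probabilities by fixed powers and cancels in group contrasts and ratios |
| `sh_order` | 6 | even SH order of the ADC fit; 28 coefficients against 61 directions |
| `equator_samples` | 48 | trapezoid points on the RTAP great circle |
| `n_theta`, `n_phi` | 24, 48 | Gauss–Legendre × azimuth product quadrature for the RTOP spherical mean |
| `fa_threshold` | 0.2 | mean-FA threshold separating white from gray matter |
| `n_permutations` | 5000 | permutations per contrast |
| `tfce_h`, `tfce_e` | 2, 0.5 | TFCE height/extent exponents (canonical defaults) |
| `tfce_nsteps` | 100 | threshold steps, `dh = max/100`, midpoint rule |
| `min_region_volume_mm3` | 30 | regions with no more than this significant volume are dropped from reports |
| `search_radius_mm` | 4 | projection search distance perpendicular to the skeleton |

The diffusion time is configurable because the acquisition does not pin
it down; every cross-check in the package passes `tau` through both
sides of each equality, and group inference is `tau`-free.

## Numerical choices

* **Tensor fit.** Weighted linear least squares on the log signal
  (design $[1, -b g_x^2, \dots, -2bg_yg_z]$), one reweighting pass with
  weights equal to the squared predicted signal; OLS available behind a
  flag. Signal ratios are clipped to $[10^{-6}, 1]$ before the log
  because the Rician floor can push $S > S_0$. A nonlinear
  least-squares fit on the raw signal is kept in the test suite as an
  independent oracle; at SNR 20 the two agree to ~1% median on MD.
* **Spherical averaging.** A fixed Gauss–Legendre (24 polar nodes) ×
  trapezoid (48 azimuths) product quadrature, exact for band-limited
  spherical integrands far beyond order 8, deterministic by
  construction. The equator average uses uniform trapezoid sampling,
  which converges exponentially for smooth periodic integrands.
* **TFCE integration.** Midpoint thresholds $h_k = (k - \tfrac12)\,dh$
  with $dh = \max/100$. The midpoint rule is exact for the degenerate
  $E \to 0, H = 1$ single-voxel case ($\max^2/2$) and keeps the
  map-normalized deviation from a 10× finer threshold sweep under 2%.
  Cluster connectivity is 26-neighbourhood restricted to the skeleton:
  skeletons are thin, and 6-connectivity fragments them.
* **Skeleton rule.** The mean FA is lightly smoothed (Gaussian, 1
  voxel); a voxel is kept when mean FA exceeds the threshold and is a
  local maximum of the smoothed map along the dominant
  negative-curvature direction of its Hessian — and, where the second
  curvature is comparably negative (tube-like cross-sections), along
  that direction too, and along the FA gradient where the gradient is
  non-trivial. The last rule suppresses the classic ridge-detector ring
  artifact at the FA inflection boundary. Grid-face voxels are excluded
  (their derivatives have one-sided support only). This is a
  TBSS-style rule, not a re-implementation of the original tool;
  voxel-level parity with it is a non-goal.
* **Permutations.** The corrected p includes the identity permutation:
  $p(v) = (1 + \#\{\max_\pi \ge \mathrm{TFCE}(v)\})/(1 + n_\pi)$, so the
  smallest attainable value is $1/(1+n_\pi)$ ($\approx 2\times10^{-4}$
  at 5000). When fewer distinct relabelings exist than requested
  permutations they are enumerated exactly. Nuisance covariates are
  removed by Freedman–Lane residualization before relabeling. Each
  contrast (and each one-sided direction) is corrected within itself,
  with no cross-contrast correction.

## The synthetic cohort: what it does and does not emulate

Phantoms are tubes and circular arcs with prescribed eigenvalues
(defaults $\lambda = (1.7, 0.3, 0.3)\times10^{-3}\,\mathrm{mm^2/s}$ in
tracts, isotropic $0.7\times10^{-3}$ background) on a 2 mm grid, imaged
with one baseline plus 61 Fibonacci-lattice directions at
$b = 1000\,\mathrm{s/mm^2}$ and Rician noise (magnitude of a complex
Gaussian perturbation; SNR defined as $S_0/\sigma$ on the baseline).
Group effects are multiplicative eigenvalue changes in selected
regions — the study conditions use $-10\%$ on $\lambda_1$ for the
chronic-migraine group, a magnitude chosen to be detectable at 25
subjects per group because the source analyses report only direction
and significance, not effect sizes. Between-subject variability is a
global eigenvalue scaling $\sim N(1, 0.02^2)$ truncated to
$[0.9, 1.1]$. Demographics are sampled per field from truncated
normals whose *truncated* means equal the configured ones
(mean-matching shift), with Bernoulli draws for sex, aura and
medication overuse; only marginals are modelled — no field-to-field
copula — because only marginals are reported for the cohort being
emulated.

What passing tests on this cohort demonstrate: correctness of the
estimators and inference machinery (identifiability, calibration, power
against a known truth). What they do not demonstrate: robustness to
crossing fibers, motion/eddy artifacts, field inhomogeneity,
registration error, or real anatomical geometry — all deliberately
outside the generator (real pipelines remove several of these in
preprocessing, which is also out of scope here).

## Validation studies built into the package

* `simulate_null_calibration()` — two groups drawn from one
  distribution on a 512-voxel block skeleton; the family-wise rejection
  rate at $\alpha = 0.05$ over 200 datasets of 12 + 12 subjects at 500
  permutations must land in the binomial band $[0.02, 0.09]$.
* `simulate_effect_recovery()` — the full pipeline (simulate → fit →
  scalars → skeleton → project → TFCE permutation test → region
  report) on a two-tract phantom, 25 subjects per group, SNR 20,
  $-10\%$ $\lambda_1$ in tract A; detection inside the affected tract
  with no significant voxel beyond one voxel outside it, the affected
  region listed in the report, and the paired opposite-direction RTPP
  effect, each in $\ge 90\%$ of seeded runs.

Problem sizes in the default test suite (1000 tensors for the
equivalence study, a $30\times22\times10$ phantom grid, 500–1000
permutations, 10–20 repeated runs) were chosen so the whole suite runs
in minutes on one core while keeping every Monte-Carlo band
comfortable.

## Design decisions that were genuinely open

* **Fit method.** The source tooling names a standard tensor-fit
  program without its algorithm; WLS with one reweighting pass is the
  common default and is what this package specifies, with OLS behind a
  flag and the NLS oracle in tests.
* **Apparent-EAP construction.** The "apparent" estimators are fixed
  here as the mono-exponential radial extension of the shell signal —
  the minimal model consistent with the radial-independence assumption —
  and validated by the Gaussian-equivalence oracle. This is an
  AMURA-style construction, not a bit-exact reimplementation of any
  external tool. The b-value is a free input: no validity cutoff is
  encoded, although apparent scalars at moderate b are known to be
  b-dependent quantities.
* **Principal direction for RTPP/RTAP.** Taken from the tensor fit's
  first eigenvector (both families of maps are computed from the same
  data); a maximum-of-$D(\mathbf u)$ alternative would differ only in
  degenerate voxels.
* **Volume rule for reports.** Regions whose significant volume does
  not *exceed* 30 mm³ are dropped, matching the convention that a
  30 mm³ region is excluded; the voxel volume comes from the grid, so
  the rule is stated in mm³, not voxels.
* **Two-sided Fisher convention.** Sum of hypergeometric probabilities
  of tables no more probable than the observed one (the common
  convention); pooled rather than Welch t because the printed degrees
  of freedom $108 = 54 + 56 - 2$ fix the pooled choice; chi-square
  without continuity correction, which reproduces the printed 2.48 on
  the 3×2 sex table.

## Known limitations

Single b-shell and single-tensor signal model only (no multi-shell EAP
reconstruction, no kurtosis, no crossing-fiber models); no image
registration — cohorts must share a grid, which the generator
guarantees but real data do not; the skeleton rule is TBSS-style, not
the original algorithm; Mann–Whitney from summary statistics is
impossible in principle (rank tests need raw data) and is rejected with
an error.

## A minimal end-to-end example

```{r example, eval = FALSE}
ph <- phantom_spec(
  volume_grid(c(30, 22, 10), c(2, 2, 2)),
  list(tract_tube(c(2, 8, 8), c(58, 8, 8), radius = 5,
                  evals = c(1.7e-3, 0.3e-3, 0.3e-3), name = "tractA"),
       tract_tube(c(2, 34, 8), c(58, 34, 8), radius = 5,
                  evals = c(1.7e-3, 0.3e-3, 0.3e-3), name = "tractB")))
scheme <- gradient_scheme(c(0, rep(1000, 61)),
                          cbind(0, t(fibonacci_directions(61))))
co <- generate_cohort(ph, list(group_effect("CM", 1L, factor_l1 = 0.9)),
                      list(EM = 25, CM = 25), scheme, sigma = 50, seed = 1)
maps <- lapply(co$dwis, function(dwi) {
  es <- eigendecompose(fit_tensor(dwi))
  dti_scalars(es)
})
cfg <- inference_config(n_permutations = 1000, seed = 2)
sk <- build_skeleton(lapply(maps, `[[`, "FA"), cfg)
proj <- project_cohort(sk, maps, "AD", cfg)
r <- permutation_fwe(proj$AD, co$table$group, NULL, sk$adjacency, cfg)
roi_report(r, "greater", co$labels, sk, cfg)
```
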