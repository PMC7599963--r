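# microtract

White-matter microstructure mapping and tract-skeleton group inference
for single-shell diffusion MRI, in R.

## The problem

Diffusion-tensor imaging (DTI) summarises water diffusion per voxel with
four scalars — fractional anisotropy (FA), mean/axial/radial diffusivity
(MD, AD = λ₁, RD = (λ₂+λ₃)/2) — but richer microstructure indices exist:
the return-to-origin, return-to-axis and return-to-plane probabilities
(RTOP, RTAP, RTPP), integrals of the ensemble-average propagator that
are sensitive to overall, radial and axial diffusion restriction. Under
a Gaussian propagator with diffusion time τ they reduce to closed forms
in the tensor eigenvalues,

    RTOP = (4πτ)^(-3/2) (λ₁λ₂λ₃)^(-1/2)
    RTPP = (4πτ λ₁)^(-1/2)
    RTAP = (4πτ)^(-1) (λ₂λ₃)^(-1/2)      (so RTOP = RTPP × RTAP),

but the inverse square roots of the *small* eigenvalues make that route
explode on noisy fits. `microtract` also computes the scalars the
"apparent" way from a single b-shell: fit the directional ADC
D(u) = −log(S(u)/S₀)/b with even spherical harmonics, extend the signal
mono-exponentially along each ray, and reduce each scalar to a
directional average of a power of D(u). On noise-free tensor signals
the two routes agree exactly — a built-in cross-validation — while on
noisy data the apparent route stays bounded where the tensor route
produces outliers.

Group comparison follows the tract-based spatial statistics idea: build
a mean-FA skeleton (FA > 0.2, centre-of-tract ridge), project each
subject's maps onto it, then test contrasts voxel-wise with
threshold-free cluster enhancement (H = 2, E = 0.5) and
permutation-based family-wise-error correction (5000 permutations,
α = 0.05, Freedman–Lane handling of covariates), reporting atlas
regions with significant volume above 30 mm³. Cohort-level statistics
(chi-square, Fisher exact, pooled t, Mann–Whitney U, Kruskal–Wallis, a
KS/Levene gate, Spearman correlations with Benjamini–Hochberg
correction) round out the pipeline.

A synthetic cohort generator — tensor-field tube/arc phantoms, Rician
noise, seeded group effects, demographics emulating a three-group
(HC/EM/CM) migraine cohort — makes the whole chain testable without
patient data.

## A worked example

Simulate 25 + 25 subjects with a −10% axial-diffusivity effect in one
of two tracts (baseline SNR 20), run the full pipeline, and ask which
atlas regions carry the effect:

```r
library(microtract)
r <- simulate_effect_recovery(seed = 5037, n_per_group = 25, snr = 20,
                              factor_l1 = 0.9, n_permutations = 1000)
r$report
#>   region volume_mm3  min_p_corr peak_x peak_y peak_z
#> 1 tractA        224 0.000999001     16      8      8
str(r[c("ad_detected", "ad_specific", "roi_listed", "rtpp_detected")])
#> List of 4
#>  $ ad_detected  : logi TRUE
#>  $ ad_specific  : logi TRUE
#>  $ roi_listed   : logi TRUE
#>  $ rtpp_detected: logi TRUE
```

The report says the seeded tract (and only it) shows a significant
AD reduction — 224 mm³ of skeleton at the permutation floor
p = 1/(1+1000) ≈ 0.001, peaking at the tube centre — and the same data
show the paired opposite-direction RTPP increase, as expected when λ₁
falls.

Table-style cohort statistics work from printed summaries too:

```r
contingency_tests(matrix(c(11, 39, 9, 45, 6, 50), nrow = 2), "chisq")
#> chi-square: stat = 2.483, df = 2, p = 0.289
two_sample_tests(list(mean = 14.1, sd = 11.1, n = 54),
                 list(mean = 19.6, sd = 10.4, n = 56), kind = "t")
#> t-pooled: stat = -2.683, df = 108, p = 0.00845
```

A thin CLI over the same functions lives in `inst/cli/microtract.R`
(subcommands `simulate`, `fit`, `scalars`, `tbss`, `stats`,
`correlate`).

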