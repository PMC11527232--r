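# cki — creatine kinase imaging by ³¹P MR fingerprinting

`cki` is an R implementation of 3D creatine kinase imaging (CKI): mapping
the forward rate constant of the creatine kinase reaction,
PCr + ADP ⇌ Cr + ATP, across the brain with a ³¹P
magnetization-transfer MR-fingerprinting sequence. It is aimed at people
developing or studying quantitative ³¹P methods: it contains the full
modelling, reconstruction and analysis chain at desk scale, exercised
end-to-end on a synthetic digital brain phantom (no scanner data is
included or required).

## What it computes

Each voxel's transient signal under a balanced-SSFP-type train of 800
variable flip angles (four sinusoidal blocks, `A·sin(π/200·x)^0.6`, A =
35°/25°, alternating 0°/180° RF phase, inversion preparations, alternating
TR 19.82/23.82 ms) is a fingerprint of four parameters of the two-pool
Bloch–McConnell exchange model

dM/dt = Γ(k_CK, Cr, T1ᴾᶜʳ, ΔB₀) · M,

where k_CK (s⁻¹) is the forward PCr → γATP rate (reverse rate fixed by
detailed balance, k_rev = k_CK·Cr), Cr = M₀(PCr)/M₀(ATP), T1ᴾᶜʳ the
longitudinal relaxation of PCr, and ΔB₀ the off-resonance in Hz; T1(ATP) =
1 s, T2(PCr) = 135 ms and T2(ATP) = 25 ms are fixed. Parameters are
estimated by maximum-inner-product matching of the conditioned,
unit-norm 1200-point fingerprint ([Re PCr, Im PCr, Re ATP]) against a
simulated dictionary.

The package provides, as separate composable modules:

* `build_schedule()` / `build_fa_pattern()` — the timed event list of the
  acquisition, serializable to a plain-text config;
* `simulate_evolution()` / `simulate_three_pool()` — compiled
  Bloch–McConnell propagation (two pools, or three with inorganic
  phosphate and the ATP-synthase exchange);
* `param_grid()`, `generate_dictionary()`, `condition_signal()`,
  `match_fingerprint()`, `monte_carlo_robustness()` — the fingerprinting
  core;
* `design_spiral()`, `voronoi_dcf()`, `apply_hanning()`, `grid_and_fft()`,
  `estimate_noise()`, `wsvd_combine()`, `mppca_denoise()`,
  `reconstruct()` — the non-Cartesian image reconstruction chain;
* `make_phantom()`, `coil_model()`, `inject_activation()`,
  `forward_simulate()` — the synthetic data generator (exact DFT forward
  model; no inverse crime);
* `match_images()`, `roi_summary()`, `split_half_cv()`, `fcki_map()`,
  `detect_clusters()`, `snr_db()`, `cv()`, `robustness_suite()` — maps,
  reproducibility, functional activation analysis and the simulation
  robustness experiments.

See the methods vignette (`vignettes/cki-methods.Rmd`) for the model,
conventions and design decisions.

## Worked example

Simulate an in-vivo-like gray-matter voxel, add noise at 15 dB, and match
it against a small dictionary:

```r
library(cki)

schedule <- build_schedule()
schedule
#> CKI acquisition schedule: 800 excitations in 4 blocks
#>   total duration 18.456 s
#>   TR (PCr) 19.82/23.82 ms  TR (ATP) 19.82 ms

params <- spin_params(k_ck = 0.30, cr = 1.27, t1_pcr = 4.67, delta_b0 = 5)
evo <- simulate_evolution(params, schedule)

grid <- param_grid(k_ck = seq(0.20, 0.40, by = 0.01),
                   cr = seq(1.1, 1.4, by = 0.05),
                   t1_pcr = seq(4.0, 5.5, by = 0.25),
                   delta_b0 = seq(-10, 10, by = 5))
dict <- generate_dictionary(grid, schedule)
dict
#> CKI dictionary: 5145 atoms x 1200 points

set.seed(7)
noisy <- add_noise_snr(evo$samples, snr_db = 15)
fit <- match_fingerprint(condition_signal(noisy, evo$target), dict)
fit
#>   signal k_ck   cr t1_pcr delta_b0     score atom
#> 1      1 0.29 1.25    4.5        5 0.9882826 2324

snr_db(condition_signal(noisy, evo$target)$vector, dict$atoms[fit$atom, ])
#> 16.2 dB
```

The match recovers the generating tuple to within one grid step per
parameter at this noise level (truth: 0.30 / 1.27 / 4.67 / 5; the
dictionary quantizes Cr 1.27 to 1.25): `score` is the inner product with
the best atom and the fit-based SNR estimates the data quality from the
matched-atom residual. The full pipeline — phantom → spiral raw data →
reconstruction → maps → activation clusters — is composed the same way;
`tests/testthat/test-acceptance.R` runs it end to end.

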