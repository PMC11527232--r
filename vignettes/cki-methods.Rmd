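---
title: "Creatine kinase imaging by 31P MR fingerprinting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Creatine kinase imaging by 31P MR fingerprinting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The creatine kinase (CK) reaction, PCr + ADP <-> Cr + ATP, buffers cellular
energy in brain and muscle. Its forward pseudo-first-order rate constant
kCK (s^-1) — the fraction of the phosphocreatine pool whose phosphate is
transferred to gamma-ATP per second — is measurable in vivo with 31P
magnetization-transfer (MT) NMR, because perturbing the longitudinal
magnetization of one exchange partner (classically by inversion or
saturation) propagates to the other at a rate set by kCK.

`cki` implements a desk-scale version of 3D creatine kinase imaging: an
MR-fingerprinting (MRF) acquisition whose flip angles, repetition times and
preparation pulses vary deliberately, so that the transient signal of each
voxel becomes a "fingerprint" of four free parameters:

* `k_ck` — the forward CK rate (s^-1),
* `cr` — the equilibrium magnetization ratio M0(PCr)/M0(ATP),
* `t1_pcr` — longitudinal relaxation of PCr (s),
* `delta_b0` — static off-resonance (Hz).

Parameters are decoded by maximum-inner-product matching against a
dictionary of simulated fingerprints. Around that core the package carries
the full chain a scanner pipeline would need: a spiral k-space
reconstruction (Voronoi density compensation, Kaiser-Bessel gridding,
whitened-SVD coil combination, Marchenko-Pastur PCA denoising), a digital
brain phantom with an exact Fourier forward model, and the functional
analysis that turns rest/stimulation pairs of kCK maps into activation
clusters (fCKI).

## Acquisition model

One repetition of the pattern (`build_schedule()`) contains 800 excitations
in four blocks of 200. The flip-angle envelope is
`A * sin(pi/200 * x)^0.6`, `x = 1..200`, with `A` = 35 deg for the two PCr
blocks (1 and 3) and 25 deg for the two gamma-ATP blocks (2 and 4); the RF
phase alternates 0/180 deg across all 800 pulses (a balanced-SSFP-type
train). Frequency selectivity comes from a 10 ms Gaussian pulse with a
170 Hz spectral FWHM; PCr and gamma-ATP are separated by about 304 Hz
(-2.52 ppm at 120.67 Hz/ppm), so the non-targeted metabolite sees roughly
1.4e-4 of the nominal flip.

Timing: the base TR is 19.82 ms; every second PCr excitation carries an
extra 4 ms delay before the acquisition (TR 23.82 ms), which encodes
off-resonance in the phase difference between odd and even PCr samples.
The acquisition delay between pulse end and readout start is 410 us. Each
block is preceded by a 40 ms inversion pulse, a 2 ms delay and an 8 ms
crusher, and followed by a 400 ms pause. One repetition lasts 18.456 s —
the analytic sum of all event durations. `audit_schedule()` reports, per
excitation, whether the window after the acquisition delay accommodates
the 8.61 ms spiral readout plus the 920 us refocusing delay; with the
protocol constants above the window is 0.12 ms short, which the audit
reports rather than hides (the signal model places a single sample per TR
and is unaffected).

Two documented conventions resolve ambiguities in the protocol
description:

* **Preparation pulses.** The asymmetric inversion pulses are modelled as
  per-pool longitudinal efficiencies in [-1, 1], applied at the pulse
  midpoint (configurable), with Bloch-McConnell evolution across the
  40 + 2 + 8 ms window and a crusher that nulls all transverse components.
  Which metabolite each asymmetric profile inverts is a configuration
  choice (`prep_eff`), because the profile orientation is not fully
  specified by the protocol text. The default follows the geometric
  reading of the carriers and the "opposite profiles" statement: prep 1
  (carrier +1.25 ppm) inverts everything upfield of its carrier, i.e.
  both PCr and gamma-ATP; preps 2 and 4 (carrier -1.25 ppm, opposite
  profile) invert PCr only; prep 3 (carrier -1.25 ppm, prep-1 profile)
  inverts gamma-ATP only. Every readout block is thus preceded by an
  inversion of its exchange partner — the classic inversion-transfer
  sensitization — and PCr additionally experiences inversion-recovery T1
  weighting. This mapping was also validated against the alternative
  (inverting each block's own target): both meet the Monte-Carlo
  precision bounds, but only the partner-inversion mapping keeps the kCK
  bias from a +-25% error in the fixed T1 of ATP near 10%; the
  alternative triples it, which is inconsistent with the robustness this
  sequence design is reported to achieve.
* **Receiver phase.** With a 0/180 deg alternating excitation phase the
  demodulated bSSFP samples alternate sign. The conditioning step phases
  the ATP samples by the phase of their mean, which is only meaningful if
  the receiver phase follows the excitation phase (standard phase-cycled
  acquisition); the sampling model therefore includes `exp(-i*rf_phase)`
  in the demodulation. Without this convention the mean of the ATP
  evolution cancels and the matching precision degrades by a factor of
  about three.

The acquisition delay is taken as 410 us (the protocol value), not the
rounded 0.5 ms quoted elsewhere.

## Spin model

`simulate_evolution()` propagates the two-pool Bloch-McConnell equations in
homogeneous coordinates: the state is (Mx, My, Mz) per pool, in units of
M0(ATP), plus a constant 1 that carries the T1 recovery terms, so every
event — free evolution (`expm` of the generator), instantaneous rotation,
preparation efficiency, crusher — is a matrix acting on the state. The
fixed rotating frame sits at the PCr frequency; block carrier changes
enter through the pulse-profile evaluation, the rotation-axis phase
`rf_phase + 2*pi*carrier*t` and the demodulation factor
`exp(-i*(2*pi*carrier*t + rf_phase))`. Exchange acts on all three
components of both pools (full Bloch-McConnell), with the reverse rate
fixed by detailed balance, `k_rev = k_ck * cr`. Fixed literature values:
T1(ATP) = 1 s, T2(PCr) = 135 ms, T2(ATP) = 25 ms.

The default excitation model is the profile-scaled instantaneous rotation
(single isochromat, nominal flip angle); a hard-pulse mode
(`apply_rf(mode = "hard")`) decomposes the shaped pulse into
piecewise-constant segments interleaved with free evolution and exists for
validation only.

The event walk is compiled once per schedule and executed by a small
RcppArmadillo kernel; per parameter tuple only the handful of distinct
duration propagators is re-exponentiated, and rotation operators are shared
across tuples with equal `delta_b0`, which keeps dictionary generation at
roughly a millisecond per atom.

`simulate_three_pool()` adds an inorganic phosphate pool coupled to
gamma-ATP (the ATP-synthase pathway). The Pi pool configuration defaults —
M0(Pi)/M0(ATP) = 0.35, T1(Pi) = 4 s, T2(Pi) = 0.1 s, +4.9 ppm, forward
rate swept over 0.05-0.30 s^-1 — are package choices in physiological
ranges, not protocol constants, and are exposed as arguments.

An independent explicit-Euler oracle (the recursion `M <- (I + dt*G) M`
evaluated as an exact matrix power, with steps chosen so the first-order
error stays below 1e-6 per segment) verifies both single propagations and
full 800-point evolutions in the test suite.

## Dictionary and matching

`condition_signal()` applies the phasing used for dictionary entries and
measured data alike: PCr samples are rotated by the phase of the mean of
the odd-indexed PCr samples (the transient without the extra delay), ATP
samples by the phase of their overall mean; the vector
[Re(PCr), Im(PCr), Re(ATP)] (1200 points) is normalized to unit L2 norm.
This makes matching invariant to global scale and phase by construction.

`generate_dictionary()` simulates one atom per tuple of a `param_grid()`
(row-major over the axes in declared order) and `match_fingerprint()`
performs the exhaustive inner-product argmax, with ties broken by the
lowest atom index (inner products can tie at float precision).
Constraints restrict the search to a sub-grid: scalars pin an axis
globally, vectors pin it per signal — the functional estimation mode fixes
`t1_pcr = 4.5` s and pins `delta_b0` and `cr` per voxel to the estimates
from the combined rest+stimulation data.

The default `param_grid()` covers kCK 0.05-0.60 s^-1 (step 0.01), Cr
0.5-6 (step 0.05 to 2, then 0.25; 6 is the dictionary bound used for the
in-vivo maps), T1(PCr) 2-7 s (step 0.25, keeping 4.5 s on-grid) and B0
±25 Hz (step 1). The simulation experiments use the focused
`evaluation_grid()` (kCK 0.18-0.45 step 0.005, Cr 1.0-1.6 step 0.05,
T1 2.5-6.5 step 0.25, B0 ±4 step 2 Hz): fine enough in kCK that grid
quantization contributes little to the measured spreads, wide enough that
the 8 dB error distributions are not clipped, and small enough (about
6e4 atoms) to regenerate in about a minute.

Monte-Carlo noise (`monte_carlo_robustness()`) is added to the complex
800-point evolution before conditioning, with the power-ratio SNR
definition `10*log10(mean|s|^2 / E|n|^2)`; the reported spread is the
population SD of the relative matching error per parameter.

## Reconstruction

The raw tensor is `[861 readout x 5 kz x 800 FA x coils x averages]`.
The chain (`reconstruct()`):

1. centred zero-fill of the 5 acquired kz planes to 11 and an inverse FFT
   along kz;
2. density compensation: Voronoi cell areas (half-plane clipping with
   nearest-neighbour early termination; boundary cells clipped to a disc
   of `kmax` plus half the mean sample spacing), multiplied by a radial
   half-period Hann window (1 at the centre, 0 at `kmax`) — read as a
   function of |k|, which is the interpretation that damps high spatial
   frequencies;
3. Kaiser-Bessel convolution gridding (width 4 cells on a 1.5x
   oversampled grid, shape parameter from the standard least-aliasing
   prescription), batched centred 2D inverse FFTs, deapodization by the
   numerically exact DFT of the integer-sampled kernel, centre cropping;
4. whitened-SVD coil combination per voxel (rank-1 approximation of the
   whitened coil-by-FA matrix; output phase fixed by making the dominant
   coil weight real-positive), with the coil covariance estimated from
   the interleaved subtraction of consecutive averages pushed through the
   same gridding chain;
5. optional MP-PCA denoising of the (voxels x 2*FA) real matrix (real and
   imaginary parts concatenated along the frame dimension), nulling
   singular values inside the Marchenko-Pastur bulk identified by the
   edge criterion `lambda_(p+1) - lambda_min <= 4*sqrt(gamma)*sigma^2`.

"33% kxy coverage" is interpreted as the sampled-area fraction of the
Nyquist disc — the spiral extends to `sqrt(0.33)` of the Nyquist radius —
because the protocol does not define the term; the spiral density law and
radial turn spacing are configurable (`design_spiral()`).

Two behaviours of this chain are worth knowing:

* At 33% coverage the reconstruction is deliberately band-limited:
  neighbouring voxels mix, which is why voxel-exact parameter recovery is
  only assessed at full coverage (below), while the realistic-coverage
  setting is judged at the cluster level.
* On reconstructed data the MP-PCA step retains nearly all components:
  gridding correlates the voxel noise spatially, so the i.i.d.
  Marchenko-Pastur edge is conservative there and the denoiser is close
  to the identity. Its statistical behaviour (noise-floor suppression on
  i.i.d. matrices, exact preservation of low-rank signal, error
  non-increase) is pinned by dedicated simulation tests.

## The digital phantom

`make_phantom()` builds an ellipsoidal head with a gray-matter shell, a
white-matter core and CSF ventricles on the 32 x 32 x 11 protocol grid
(any size works). Tissue means follow the in-vivo gray/white-matter
values — GM: kCK 0.30 s^-1, Cr 1.27, T1(PCr) 4.67 s; WM: 0.30, 1.23,
4.50; CSF gets a low proton-density-like amplitude (0.2) and soft
parameter values, since it carries little 31P signal. Per-tissue Gaussian
jitter (defaults 0.02 / 0.08 / 0.3 for kCK / Cr / T1; the first two follow
the reported between-subject spreads, the T1 jitter is kept below the
reported spread so that values stay well inside the dictionary) is seeded
and clamped to the dictionary bounds. The off-resonance field is smooth,
within ±10 Hz by default, with a stronger deviation towards the frontal
edge. A posterior gray-matter cap is labelled as the "occipital" ROI for
the functional experiments, and `inject_activation()` scales kCK inside
it (15% for the reference effect size, i.e. about +0.045 s^-1 on a GM
kCK of 0.30).

`forward_simulate()` simulates every in-brain voxel's evolution, forms
coil-weighted images per FA index (`coil_model()`: smooth complex
Gaussian-magnitude sensitivities, Toeplitz coil covariance with 0.2
neighbour correlation), transforms z to kz keeping the 5 central planes,
and samples the spiral by the exact discrete Fourier sum — deliberately
not the adjoint of the Kaiser-Bessel gridder, so reconstruction is never
tested against its own inverse. A fast NUFFT-style mode
(`mode = "adjoint"`, about 1% accurate) exists for experimentation and is
labelled approximate. The signal is held constant across each 8.61 ms
readout, matching the dictionary's single-sample-per-TR model. Correlated
complex Gaussian noise is added per average under a seed.

What the phantom does not emulate: anatomical fine structure, B1
inhomogeneity, motion and physiological noise, eddy currents and gradient
delays, multi-isochromat intra-voxel dephasing. Passing tests therefore
demonstrate the correctness and precision of the modelling/matching chain
under its own assumptions, not in-vivo accuracy.

## Analysis

* `snr_db()` — `10*log10` of fit power over residual power, with the
  matched atom scaled to the data by least squares first (the atom is
  unit-norm, the data is not; this is the documented reading of the
  fit/residual SNR definition).
* `cv()` — population SD over mean; for the two split-half estimates this
  reduces to |a-b|/(a+b).
* `split_half_cv()` — interleaved split of the averages, fully independent
  reconstruction and matching per half, voxelwise and ROI-level CV.
* `fcki_map()` — the three-step functional estimation (combined match,
  pinned rematch of each condition, percent difference), with the
  "combined dataset" implemented as the equal-weight average of the two
  reconstructions.
* `detect_clusters()` — connected components of voxels at or above the
  percent threshold (default 10%), dropping components smaller than 20
  voxels; 6-connectivity by default (26 optional), recorded in the
  output. An independent flood-fill oracle checks the labelling in the
  tests.
* `robustness_suite()` — one seeded run of the four simulation
  experiments: Monte-Carlo precision over an SNR sweep, the ±25%
  fixed-parameter bias grid, the three-pool ATP-synthase sweep and the
  bSSFP contamination scan.

## Numerical choices and edge cases

* Matrix exponentials via Pade approximation (RcppArmadillo `expmat`);
  event durations are deduplicated so about eight exponentials are
  computed per tuple.
* `sinpi()` is used for the flip-angle envelope so the block-final flip is
  exactly zero.
* Matching ties break to the lowest atom index; measured vectors are
  re-normalized defensively; an all-zero evolution raises an
  undefined-phase error rather than returning a silent NaN.
* Voronoi cells of duplicate k-space points are disambiguated by an
  epsilon jitter with a warning; degenerate cells raise errors naming the
  sample index.
* `snr_db()` returns +Inf / -Inf sentinels for zero residual / zero fit.
* Noiseless voxel-exact recovery is assessed on an on-grid phantom (zero
  tissue jitter, B0 snapped to the dictionary axis). With continuous
  parameter values the matched tuple necessarily rounds along
  near-degenerate kCK/T1 manifold directions — the score margin between
  adjacent atoms vanishes when the truth lies mid-cell — so voxel-exact
  recovery is only a well-posed criterion when quantization error is
  zero; jittered maps are covered by the conditioned-evolution error,
  split-half CV and cluster-level checks instead.

## Desk-scale problem sizes

The shipped experiments are sized for a single CPU: the evaluation
dictionary has about 6e4 atoms; Monte-Carlo runs use 200 realizations at
8 dB; voxel-exact recovery uses a 16 x 16 x 5 phantom at full coverage
with the Hann taper off; the functional experiment uses the full
32 x 32 x 11 grid, the 861-point 33%-coverage spiral, 2 coils and 4
averages, with the noise SD fixed at the raw signal rms (median pipeline
SNR about 18 dB, inside the usable in-vivo range). The same quantities
scale up by enlarging the grids and coil counts; nothing in the code is
specific to the reduced sizes.

## Known limitations

* The dictionary search is exhaustive; no compressed or learned matching.
* B1 is assumed homogeneous and excitation uses the nominal flip angle.
* The spiral is an analytic Archimedean design; no measured trajectories,
  off-resonance deblurring or gradient-delay correction.
* MP-PCA assumes spatially uncorrelated noise; on gridded data it is
  conservative (see above).
* Group-level inference (ANOVA, post-hoc tests) is out of scope; the
  analysis stops at descriptive per-dataset tables and cluster reports.
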