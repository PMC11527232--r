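## Small end-to-end fixtures shared across test files, built once per test
## run (R's copy-on-modify keeps cached objects safe to reuse).
.pipeline_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.pipeline_cache[[key]])) .pipeline_cache[[key]] <- fn()
  .pipeline_cache[[key]]
}

full_schedule <- function() cached("schedule", function() cki::build_schedule())

## 16 x 16 x 5 phantom with mild jitter, 2 coils, full-coverage spiral.
small_setup <- function(noise_sigma = 0, n_averages = 2, seed = 5,
                        phantom = NULL) {
  sch <- full_schedule()
  ph <- if (is.null(phantom)) {
    cki::make_phantom(seed = 11, nx = 16, ny = 16, nz = 5,
                      jitter = list(k_ck = 0.01, cr = 0.04, t1_pcr = 0.15),
                      b0_amplitude = 6)
  } else phantom
  coils <- cki::coil_model(n_coils = 2, nx = 16, ny = 16, nz = 5)
  tr <- cki::design_spiral(n_points = 600, coverage = 1, matrix_size = 16,
                           turn_spacing = 0.5)
  raw <- cki::forward_simulate(ph, sch, coils, tr, n_averages = n_averages,
                               noise_sigma = noise_sigma, seed = seed,
                               n_kz = 5)
  list(sch = sch, ph = ph, coils = coils, tr = tr, raw = raw)
}

small_setup_noiseless <- function() {
  cached("small-noiseless", function() small_setup())
}

## Dense-kCK dictionary for the small functional experiments: zero-jitter
## phantom values on-grid, B0 axis narrow.
fcki_dictionary <- function() {
  cached("fcki-dict", function() {
    g <- cki::param_grid(k_ck = seq(0.10, 0.55, by = 0.01),
                         cr = c(1.00, 1.23, 1.27),
                         t1_pcr = c(4.5, 4.67, 5.0),
                         delta_b0 = 0)
    cki::generate_dictionary(g, full_schedule())
  })
}
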