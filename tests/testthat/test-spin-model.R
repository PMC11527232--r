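test_that("free evolution reproduces closed-form inversion recovery", {
  p <- spin_params(k_ck = 0, cr = 1.4, t1_pcr = 3, delta_b0 = 0)
  m <- equilibrium_state(p)
  m[3] <- -p$cr   # inverted PCr
  for (t in c(0.05, 0.5, 2)) {
    out <- free_evolve(m, p, t)
    expect_equal(out[3], p$cr * (1 - 2 * exp(-t / p$t1_pcr)),
                 tolerance = 1e-10)
    expect_equal(out[6], 1, tolerance = 1e-10)  # ATP stays at equilibrium
  }
})

test_that("equilibrium is a fixed point of free evolution", {
  p <- spin_params(0.3, 1.25, 4.5, delta_b0 = 7)
  m <- equilibrium_state(p)
  expect_equal(free_evolve(m, p, 1.3), m, tolerance = 1e-12)
})

test_that("matrix-exponential propagation matches the explicit-Euler oracle", {
  set.seed(42)
  for (i in 1:100) {
    p <- spin_params(k_ck = runif(1, 0, 0.6), cr = runif(1, 0.5, 3),
                     t1_pcr = runif(1, 2, 7), delta_b0 = runif(1, -25, 25))
    m <- c(rnorm(6), 1)
    d <- runif(1, 1e-4, 0.05)
    a <- free_evolve(m, p, d)
    b <- euler_evolve(m, p, d)
    expect_lt(sqrt(sum((a - b)^2)) / sqrt(sum(b^2)), 1e-4)
  }
  ## the reference tuple at full precision
  p <- spin_params(0.3, 1.25, 4.5, delta_b0 = 5)
  m <- c(0.2, -0.1, 0.9, 0.05, 0.3, 0.8, 1)
  a <- free_evolve(m, p, 19.82e-3)
  b <- euler_evolve(m, p, 19.82e-3, tol = 1e-6)
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-6)
})

test_that("norm conservation and total-Mz relaxation hold", {
  ## no relaxation, no exchange: each pool's |M| is conserved
  p <- spin_params(k_ck = 0, cr = 1.2, t1_pcr = 1e9, t1_atp = 1e9,
                   t2_pcr = 1e9, t2_atp = 1e9, delta_b0 = 13)
  m <- c(0.3, 0.4, 0.5, -0.2, 0.1, 0.9, 1)
  out <- free_evolve(m, p, 0.8)
  expect_equal(sum(out[1:3]^2), sum(m[1:3]^2), tolerance = 1e-9)
  expect_equal(sum(out[4:6]^2), sum(m[4:6]^2), tolerance = 1e-9)
  ## with relaxation, total Mz -> cr + 1 from any start
  p2 <- spin_params(0.35, 1.5, 4, delta_b0 = -8)
  m2 <- c(0.5, -0.5, -1, 0.2, 0.2, -0.4, 1)
  out2 <- free_evolve(m2, p2, 60)
  expect_equal(out2[3] + out2[6], p2$cr + 1, tolerance = 1e-6)
})

test_that("exchange symmetry: relabeling pools leaves physics unchanged", {
  ## swap PCr <-> ATP roles with cr -> 1/cr and swapped relaxation/shifts;
  ## starting states that map onto each other must evolve identically.
  k <- 0.3; cr <- 1.6
  p1 <- spin_params(k, cr, t1_pcr = 4.5, delta_b0 = 3)
  ## swapped system: pool 1 is "ATP" (shift -2.52 ppm maps to +2.52 relative)
  p2 <- spin_params(k * cr, 1 / cr, t1_pcr = 1, t1_atp = 4.5,
                    t2_pcr = 0.025, t2_atp = 0.135, atp_ppm = 2.52,
                    delta_b0 = 3 - 2.52 * 120.67)
  m1 <- c(0.1, 0.2, 1.0, -0.3, 0.05, 0.7, 1)
  m2 <- c(m1[4:6], m1[1:3], 1) / 1   # swapped pools, in M0_ATP units of p1
  ## p2 states are in units of its own M0 ref = M0_PCr(p1); rescale
  s <- 1 / cr
  out1 <- free_evolve(m1, p1, 0.25)
  out2 <- free_evolve(c(m1[4:6] * s, m1[1:3] * s, 1), p2, 0.25)
  expect_equal(c(out2[4:6], out2[1:3]) / s, out1[1:6], tolerance = 1e-8)
})

test_that("RF pulse applies profile-scaled rotations", {
  p <- spin_params(0.3, 1.25, 4.5)
  m <- equilibrium_state(p)
  out <- apply_rf(m, p, flip_deg = 90, phase_deg = 0, carrier_hz = 0)
  ## on-resonance PCr tipped fully into the transverse plane
  expect_equal(out[3], 0, tolerance = 1e-10)
  expect_equal(sqrt(out[1]^2 + out[2]^2), p$cr, tolerance = 1e-10)
  ## ATP at ~304 Hz offset sees a 2^(-(2*304/170)^2) ~ 1.4e-4 profile
  off <- -2.52 * 120.67
  g <- gauss_profile(off)
  expect_equal(g, 2^(-(2 * off / 170)^2))
  expect_lt(g, 2e-4)
  expect_equal(out[6], cos(90 * pi / 180 * g), tolerance = 1e-10)
  expect_error(apply_rf(m, p, flip_deg = 200), "flip")
})

test_that("hard-pulse decomposition agrees with the instantaneous model", {
  ## long relaxation so only the rotation itself is compared
  p <- spin_params(k_ck = 0, cr = 1, t1_pcr = 1e6, t1_atp = 1e6,
                   t2_pcr = 1e6, t2_atp = 1e6)
  m <- equilibrium_state(p)
  hard <- apply_rf(m, p, flip_deg = 35, mode = "hard", n_slices = 400)
  inst <- apply_rf(m, p, flip_deg = 35)
  ang <- function(v) acos(v[3] / sqrt(sum(v[1:3]^2)))
  expect_equal(ang(hard), ang(inst), tolerance = 0.01)
})

test_that("preparation block inverts pools by efficiency and crushes", {
  p <- spin_params(0.3, 1.25, 4.5)
  m <- equilibrium_state(p)
  out <- apply_prep(m, p, efficiencies = c(-1, 1), timing = "end",
                    inv_delay = 1e-9, crusher_dur = 1e-9)
  expect_equal(out[3], -p$cr, tolerance = 1e-3)
  expect_equal(out[6], 1, tolerance = 1e-3)
  expect_equal(out[c(1, 2, 4, 5)], rep(0, 4))
  ## identity prep is pure relaxation over the window
  out2 <- apply_prep(m, p, efficiencies = c(1, 1))
  expect_equal(out2, free_evolve(m, p, 0.05) * c(0, 0, 1, 0, 0, 1, 1),
               tolerance = 1e-12)
  ## full inversion of both pools matches the Euler oracle with the same
  ## efficiency model (efficiency at midpoint)
  out3 <- apply_prep(m, p, efficiencies = c(-1, -1))
  mid <- euler_evolve(m, p, 0.02)
  mid[c(3, 6)] <- -mid[c(3, 6)]
  mid <- euler_evolve(mid, p, 0.03)
  mid[c(1, 2, 4, 5)] <- 0
  expect_equal(out3, mid, tolerance = 1e-6)
  expect_error(apply_prep(m, p, efficiencies = c(-2, 1)), "efficiencies")
})

test_that("simulated evolution is deterministic and matches the Euler walk", {
  sch <- short_schedule()
  p <- spin_params(0.30, 1.27, 4.67, delta_b0 = 0)
  e1 <- simulate_evolution(p, sch)
  e2 <- simulate_evolution(p, sch)
  expect_identical(e1$samples, e2$samples)
  oracle <- euler_walk(p, sch)
  rel_rms <- sqrt(mean(Mod(e1$samples - oracle)^2) / mean(Mod(oracle)^2))
  expect_lt(rel_rms, 1e-4)
  ## off-resonance case too
  p2 <- spin_params(0.45, 0.9, 3.2, delta_b0 = 12)
  e3 <- simulate_evolution(p2, sch)
  o3 <- euler_walk(p2, sch)
  expect_lt(sqrt(mean(Mod(e3$samples - o3)^2) / mean(Mod(o3)^2)), 1e-4)
})

test_that("ATP contamination of PCr samples is below 1% without exchange", {
  sch <- build_schedule()
  p <- spin_params(k_ck = 0, cr = 1, t1_pcr = 4.5, delta_b0 = 0)
  full <- cki:::simulate_core(p, sch)
  pcr_only <- cki:::simulate_core(p, sch, pool_select = c(1, 0))
  atp_only <- cki:::simulate_core(p, sch, pool_select = c(0, 1))
  idx <- full$target == "PCr"
  ratio <- max(Mod(atp_only$samples[idx])) / max(Mod(pcr_only$samples[idx]))
  expect_lt(ratio, 0.01)
})

test_that("three-pool model degenerates to two pools when k_atp = 0", {
  sch <- short_schedule()
  p2 <- spin_params(0.3, 1.25, 4.5, delta_b0 = 4)
  p3 <- spin_params3(0.3, 1.25, 4.5, delta_b0 = 4, k_atp = 0)
  e2 <- simulate_evolution(p2, sch)
  e3 <- simulate_three_pool(p3, sch)
  ## the Pi pool is never excited (far off every carrier) and uncoupled
  expect_equal(e3$samples, e2$samples, tolerance = 1e-10)
})

test_that("three-pool evolution matches the Euler oracle", {
  sch <- short_schedule()
  p3 <- spin_params3(0.3, 1.25, 4.5, delta_b0 = 2, k_atp = 0.2)
  e3 <- simulate_three_pool(p3, sch)
  o3 <- euler_walk(p3, sch)
  expect_lt(sqrt(mean(Mod(e3$samples - o3)^2) / mean(Mod(o3)^2)), 1e-4)
})

test_that("parameter validation rejects unphysical values", {
  expect_error(spin_params(-0.1, 1, 4.5), "k_ck")
  expect_error(spin_params(0.3, 0, 4.5), "cr")
  expect_error(spin_params(0.3, 1, Inf), "non-finite")
  expect_error(spin_params3(0.3, 1.25, 4.5, k_atp = -1), "k_atp")
  p <- spin_params(0.3, 1.25, 4.5)
  expect_error(free_evolve(equilibrium_state(p), p, -1), "duration")
})
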