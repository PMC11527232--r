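#' Two-pool spin-system parameters for the CK exchange model
#'
#' The free parameters of the PCr / gamma-ATP chemical-exchange system
#' estimated by CKI, together with the fixed literature values. Equilibrium
#' magnetizations are expressed in units of M0(ATP), so M0(PCr) = `cr`.
#' Detailed balance fixes the reverse rate at `k_rev = k_ck * cr`.
#'
#' @param k_ck forward PCr -> gamma-ATP pseudo-first-order rate (1/s).
#' @param cr concentration ratio M0(PCr) / M0(ATP).
#' @param t1_pcr longitudinal relaxation time of PCr (s).
#' @param delta_b0 global off-resonance added to both pools (Hz).
#' @param t1_atp,t2_pcr,t2_atp fixed relaxation times (s).
#' @param atp_ppm chemical shift of gamma-ATP relative to PCr (ppm).
#' @param larmor_hz_per_ppm Hz per ppm (120.67 for 31P at 7 T).
#' @return Object of class `cki_params`.
#' @export
spin_params <- function(k_ck, cr, t1_pcr, delta_b0 = 0,
                        t1_atp = 1, t2_pcr = 0.135, t2_atp = 0.025,
                        atp_ppm = -2.52, larmor_hz_per_ppm = 120.67) {
  vals <- c(k_ck = k_ck, cr = cr, t1_pcr = t1_pcr, delta_b0 = delta_b0,
            t1_atp = t1_atp, t2_pcr = t2_pcr, t2_atp = t2_atp)
  if (any(!is.finite(vals))) {
    stop("non-finite spin parameter: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (k_ck < 0) stop("k_ck must be >= 0")
  if (cr <= 0) stop("cr must be > 0")
  if (any(c(t1_pcr, t1_atp, t2_pcr, t2_atp) <= 0)) {
    stop("relaxation times must be > 0")
  }
  pools <- list(
    list(name = "PCr", ppm = 0, m0 = cr, t1 = t1_pcr, t2 = t2_pcr),
    list(name = "ATP", ppm = atp_ppm, m0 = 1, t1 = t1_atp, t2 = t2_atp))
  exchange <- list(list(from = 1L, to = 2L, k = k_ck))
  structure(list(pools = pools, exchange = exchange, delta_b0 = delta_b0,
                 larmor = larmor_hz_per_ppm, k_ck = k_ck, cr = cr,
                 t1_pcr = t1_pcr),
            class = "cki_params")
}

#' Three-pool spin-system parameters including inorganic phosphate
#'
#' Extends [spin_params()] with a Pi pool coupled to gamma-ATP through the
#' ATP-synthase exchange (forward Pi -> ATP rate `k_atp`, reverse rate by
#' detailed balance). Pi pool values are configuration defaults, not
#' literature constants.
#'
#' @inheritParams spin_params
#' @param k_atp forward Pi -> gamma-ATP rate (1/s).
#' @param m0_pi equilibrium Pi magnetization relative to M0(ATP).
#' @param t1_pi,t2_pi Pi relaxation times (s).
#' @param pi_ppm Pi chemical shift relative to PCr (ppm).
#' @return Object of class `c("cki_params3", "cki_params")`.
#' @export
spin_params3 <- function(k_ck, cr, t1_pcr, delta_b0 = 0, k_atp = 0,
                         m0_pi = 0.35, t1_pi = 4, t2_pi = 0.1,
                         pi_ppm = 4.9, ...) {
  p <- spin_params(k_ck, cr, t1_pcr, delta_b0, ...)
  if (k_atp < 0) stop("k_atp must be >= 0")
  if (m0_pi <= 0) stop("m0_pi must be > 0")
  p$pools[[3]] <- list(name = "Pi", ppm = pi_ppm, m0 = m0_pi,
                       t1 = t1_pi, t2 = t2_pi)
  p$exchange[[2]] <- list(from = 3L, to = 2L, k = k_atp)
  p$k_atp <- k_atp
  class(p) <- c("cki_params3", "cki_params")
  p
}

n_pools <- function(params) length(params$pools)

pool_freqs <- function(params) {
  vapply(params$pools, function(p) p$ppm * params$larmor, 0) + params$delta_b0
}

#' Thermal-equilibrium spin state
#'
#' State vectors are `(Mx, My, Mz)` per pool in units of M0(ATP), followed by
#' a homogeneous coordinate (always 1) that carries the T1-recovery terms.
#'
#' @param params a [spin_params()] or [spin_params3()].
#' @return Numeric vector of length `3 * n_pools + 1`.
#' @export
equilibrium_state <- function(params) {
  np <- n_pools(params)
  m <- numeric(3 * np + 1)
  for (p in seq_len(np)) m[3 * p] <- params$pools[[p]]$m0
  m[3 * np + 1] <- 1
  m
}

## Homogeneous-coordinate Bloch-McConnell generator. Precession convention:
## dM+/dt = +i*omega*M+ with omega = 2*pi*(ppm*larmor + delta_b0).
bm_generator <- function(params) {
  np <- n_pools(params)
  n <- 3 * np + 1
  G <- matrix(0, n, n)
  for (p in seq_len(np)) {
    pl <- params$pools[[p]]
    i <- 3 * (p - 1)
    w <- 2 * pi * (pl$ppm * params$larmor + params$delta_b0)
    G[i + 1, i + 1] <- -1 / pl$t2
    G[i + 2, i + 2] <- -1 / pl$t2
    G[i + 3, i + 3] <- -1 / pl$t1
    G[i + 1, i + 2] <- -w
    G[i + 2, i + 1] <- w
    G[i + 3, n] <- pl$m0 / pl$t1
  }
  for (e in params$exchange) {
    kf <- e$k
    kr <- kf * params$pools[[e$from]]$m0 / params$pools[[e$to]]$m0
    a <- 3 * (e$from - 1)
    b <- 3 * (e$to - 1)
    for (c in 1:3) {
      G[a + c, a + c] <- G[a + c, a + c] - kf
      G[b + c, a + c] <- G[b + c, a + c] + kf
      G[b + c, b + c] <- G[b + c, b + c] - kr
      G[a + c, b + c] <- G[a + c, b + c] + kr
    }
  }
  G
}

#' Free evolution under the Bloch-McConnell equations
#'
#' Propagates a spin state through `duration` seconds of precession,
#' relaxation and chemical exchange via the matrix exponential of the
#' homogeneous-coordinate generator.
#'
#' @param state state vector (see [equilibrium_state()]).
#' @param params a [spin_params()] or [spin_params3()].
#' @param duration time (s), `>= 0`.
#' @return Evolved state vector.
#' @export
free_evolve <- function(state, params, duration) {
  if (!is.numeric(duration) || length(duration) != 1 || !is.finite(duration) ||
      duration < 0) {
    stop("duration must be a single finite number >= 0")
  }
  if (duration == 0) return(state)
  G <- bm_generator(params)
  if (any(!is.finite(G))) stop("non-finite generator (check parameters)")
  drop(bm_propagators(G, duration)[, , 1] %*% state)
}

#' Unit-peak Gaussian excitation profile
#'
#' Frequency response of the Gaussian excitation pulse:
#' `2^(-(2 * offset / fwhm)^2)`, i.e. 0.5 at `offset = fwhm / 2`.
#'
#' @param offset_hz frequency offset from the pulse carrier (Hz).
#' @param fwhm_hz spectral full width at half maximum (Hz).
#' @export
gauss_profile <- function(offset_hz, fwhm_hz = 170) {
  2^(-(2 * offset_hz / fwhm_hz)^2)
}

## Rotation by alpha about a transverse axis with phase phi (Rodrigues).
rot3 <- function(alpha, phi) {
  c1 <- cos(alpha); s1 <- sin(alpha)
  cp <- cos(phi); sp <- sin(phi)
  matrix(c(1 - (1 - c1) * sp^2, (1 - c1) * sp * cp, -s1 * sp,
           (1 - c1) * sp * cp, 1 - (1 - c1) * cp^2, s1 * cp,
           s1 * sp, -s1 * cp, c1),
         3, 3)
}

## Full-state rotation matrix: per-pool flip alpha[p] (rad) about axis with
## phase phi (rad), identity on the homogeneous coordinate.
rotation_matrix <- function(alphas, phi, np) {
  n <- 3 * np + 1
  R <- diag(n)
  for (p in seq_len(np)) {
    i <- 3 * (p - 1)
    R[i + (1:3), i + (1:3)] <- rot3(alphas[p], phi)
  }
  R
}

#' Apply an RF excitation pulse
#'
#' Default mode: instantaneous rotation with the per-pool effective flip
#' `nominal * G(offset)` where `G` is the unit-peak Gaussian profile of the
#' 10 ms excitation pulse evaluated at the pool's offset from the pulse
#' carrier (off-resonance included). Validation mode `"hard"` decomposes the
#' shaped pulse into piecewise-constant hard pulses interleaved with free
#' evolution, from which the frequency selectivity emerges physically.
#'
#' @param state state vector.
#' @param params a [spin_params()].
#' @param flip_deg nominal flip angle (degrees, in `[0, 180]`).
#' @param phase_deg RF phase (degrees).
#' @param carrier_hz pulse carrier frequency relative to PCr (Hz).
#' @param t time of the rotation instant (s); enters the axis phase
#'   bookkeeping of the fixed PCr-frame simulation.
#' @param fwhm_hz spectral FWHM of the Gaussian pulse (Hz).
#' @param mode `"instant"` (default) or `"hard"`.
#' @param pulse_dur pulse duration (s), used by the hard-pulse mode.
#' @param n_slices hard-pulse discretization.
#' @return Evolved state. In `"instant"` mode only the rotation is applied
#'   (the schedule walker accounts for evolution during the pulse window);
#'   `"hard"` mode evolves through the full pulse duration.
#' @export
apply_rf <- function(state, params, flip_deg, phase_deg = 0, carrier_hz = 0,
                     t = 0, fwhm_hz = 170, mode = c("instant", "hard"),
                     pulse_dur = 10e-3, n_slices = 200) {
  mode <- match.arg(mode)
  if (!is.finite(flip_deg) || flip_deg < 0 || flip_deg > 180) {
    stop("flip angle must be in [0, 180] degrees")
  }
  np <- n_pools(params)
  f <- pool_freqs(params)
  if (mode == "instant") {
    alphas <- flip_deg * pi / 180 * gauss_profile(f - carrier_hz, fwhm_hz)
    phi <- phase_deg * pi / 180 + 2 * pi * carrier_hz * t
    return(drop(rotation_matrix(alphas, phi, np) %*% state))
  }
  ## hard-pulse decomposition of the truncated Gaussian envelope
  fwhm_t <- (4 * log(2) / pi) / fwhm_hz
  dt <- pulse_dur / n_slices
  tc <- (seq_len(n_slices) - 0.5) * dt
  env <- exp(-4 * log(2) * (tc - pulse_dur / 2)^2 / fwhm_t^2)
  d_alpha <- flip_deg * pi / 180 * env / sum(env)
  G <- bm_generator(params)
  P <- bm_propagators(G, dt)[, , 1]
  t0 <- t - pulse_dur
  m <- state
  for (i in seq_len(n_slices)) {
    m <- P %*% m
    phi <- phase_deg * pi / 180 + 2 * pi * carrier_hz * (t0 + tc[i])
    m <- rotation_matrix(rep(d_alpha[i], np), phi, np) %*% m
  }
  drop(m)
}

#' Apply a magnetization-preparation (inversion) block
#'
#' Models the 40 ms asymmetric inversion pulse as per-pool longitudinal
#' efficiencies applied at the configured instant within the pulse (default:
#' midpoint), with Bloch-McConnell free evolution across the pulse, the
#' post-inversion delay and the crusher window; the crusher nulls the
#' transverse magnetization of all pools at the end of its window.
#'
#' @param state state vector.
#' @param params a [spin_params()].
#' @param efficiencies numeric vector of per-pool longitudinal efficiencies
#'   in `[-1, 1]` (length `n_pools`); `-1` is perfect inversion, `+1` leaves
#'   the pool untouched.
#' @param inv_dur,inv_delay,crusher_dur window timing (s).
#' @param timing `"mid"` (default), `"start"` or `"end"` placement of the
#'   efficiency within the pulse.
#' @return Evolved state with zero transverse components.
#' @export
apply_prep <- function(state, params, efficiencies,
                       inv_dur = 40e-3, inv_delay = 2e-3,
                       crusher_dur = 8e-3, timing = c("mid", "start", "end")) {
  timing <- match.arg(timing)
  np <- n_pools(params)
  if (length(efficiencies) != np || any(abs(efficiencies) > 1)) {
    stop("efficiencies must have one entry per pool, each in [-1, 1]")
  }
  pre <- switch(timing, start = 0, mid = inv_dur / 2, end = inv_dur)
  m <- state
  if (pre > 0) m <- free_evolve(m, params, pre)
  m <- prep_matrix(efficiencies, np) %*% m
  m <- free_evolve(drop(m), params, inv_dur - pre + inv_delay + crusher_dur)
  drop(crusher_matrix(np) %*% m)
}

prep_matrix <- function(efficiencies, np) {
  d <- rep(1, 3 * np + 1)
  d[3 * seq_len(np)] <- efficiencies
  diag(d)
}

crusher_matrix <- function(np) {
  d <- rep(1, 3 * np + 1)
  for (p in seq_len(np)) d[3 * (p - 1) + (1:2)] <- 0
  diag(d)
}

## Shared operator cube for a schedule: [prep 1..4, crusher, per-excitation
## rotations]. Rotations depend on the pools' resonance offsets (hence
## delta_b0) but not on rates or relaxation, so dictionary generation shares
## the cube across all atoms with equal delta_b0.
simulation_operators <- function(schedule, params) {
  ex <- schedule$excitations
  np <- n_pools(params)
  n <- 3 * np + 1
  f <- pool_freqs(params)
  fwhm <- schedule$config$pulse_fwhm_hz
  eff <- prep_efficiencies(schedule$config, params)
  nexc <- nrow(ex)
  B <- array(0, c(n, n, 5 + nexc))
  for (b in 1:4) B[, , b] <- prep_matrix(eff[b, ], np)
  B[, , 5] <- crusher_matrix(np)
  alphas <- outer(ex$flip_deg * pi / 180, rep(1, np)) *
    gauss_profile(outer(-ex$carrier_hz, f, `+`), fwhm)
  phis <- ex$rf_phase_deg * pi / 180 +
    2 * pi * ex$carrier_hz * ex$t_pulse_end
  for (r in seq_len(nexc)) {
    B[, , 5 + r] <- rotation_matrix(alphas[r, ], phis[r], np)
  }
  B
}

prep_efficiencies <- function(config, params) {
  np <- n_pools(params)
  eff <- matrix(1, 4, np)
  nm <- tolower(vapply(params$pools, `[[`, "", "name"))
  for (p in seq_len(np)) {
    e <- config$prep_eff[[nm[p]]]
    if (!is.null(e)) eff[, p] <- e
  }
  eff
}

## Core simulator: walks the pre-compiled schedule op stream with the
## per-parameter duration propagators (cube A) and the shared
## prep/crusher/rotation cube (B) through the compiled event kernel.
## pool_select multiplies each pool's contribution to the sampled signal
## (used to separate per-pool contributions).
simulate_core <- function(params, schedule, operators = NULL,
                          pool_select = NULL) {
  np <- n_pools(params)
  comp <- schedule$compiled
  if (is.null(operators)) operators <- simulation_operators(schedule, params)
  if (dim(operators)[1] != 3 * np + 1) {
    stop("operator cube does not match the number of pools")
  }

  G <- bm_generator(params)
  if (any(!is.finite(G))) stop("non-finite generator (check parameters)")
  props <- bm_propagators(G, comp$udur)

  demod <- matrix(comp$demod, length(comp$demod), np)
  if (!is.null(pool_select)) {
    demod <- demod * matrix(pool_select, nrow(demod), np, byrow = TRUE)
  }

  ex <- schedule$excitations
  samples <- as.vector(bm_walk(props, operators, comp$ops, demod,
                               equilibrium_state(params)))
  structure(list(samples = samples, target = ex$target, te = ex$te_s,
                 t = ex$t_sample, params = params),
            class = "cki_evolution")
}

#' Simulate the CKI signal evolution of a two-pool spin system
#'
#' Walks the full acquisition schedule from thermal equilibrium and records
#' the complex transverse signal of both pools (demodulated at the active
#' block carrier) at the acquisition instant of each excitation.
#' Deterministic.
#'
#' @param params a [spin_params()].
#' @param schedule a [build_schedule()] result.
#' @param operators optional precomputed operator cube shared across calls
#'   with equal `delta_b0` (internal optimization for dictionary
#'   generation).
#' @return Object of class `cki_evolution`: `samples` (complex, one per
#'   excitation), `target`, `te`, `t`, `params`.
#' @export
simulate_evolution <- function(params, schedule, operators = NULL) {
  if (!inherits(params, "cki_params") || inherits(params, "cki_params3")) {
    stop("simulate_evolution expects two-pool parameters (see spin_params)")
  }
  simulate_core(params, schedule, operators)
}

#' Simulate the CKI signal evolution of the three-pool (PCr, ATP, Pi) system
#'
#' Same sampling contract as [simulate_evolution()], with the inorganic
#' phosphate pool coupled to gamma-ATP through the ATP-synthase exchange.
#' With `k_atp = 0` and an undisturbed Pi pool the PCr/ATP subsystem is
#' unaffected and the output reduces to the embedded two-pool simulation.
#'
#' @param params3 a [spin_params3()].
#' @inheritParams simulate_evolution
#' @export
simulate_three_pool <- function(params3, schedule, operators = NULL) {
  if (!inherits(params3, "cki_params3")) {
    stop("simulate_three_pool expects three-pool parameters (spin_params3)")
  }
  simulate_core(params3, schedule, operators)
}

#' @export
print.cki_evolution <- function(x, ...) {
  cat("CKI signal evolution:", length(x$samples), "samples (",
      sum(x$target == "PCr"), "PCr /", sum(x$target == "ATP"), "ATP )\n")
  invisible(x)
}

#' Steady-state contamination of the non-targeted metabolite
#'
#' Quantifies the bSSFP passband/stopband leakage of the pool that is not
#' being excited: a constant-flip, alternating-phase pulse train at the PCr
#' carrier is simulated with exchange disabled and equal pool sizes, and the
#' per-pool contributions to the demodulated signal are separated. The
#' reported ratio is the steady-state |ATP contribution| / |PCr
#' contribution|, maximized over the supplied flip angles.
#'
#' @param flips_deg flip angles to scan (degrees).
#' @param config a [cki_config()]; supplies TR, Te, pulse shape and shifts.
#' @param n_pulses length of the pulse train (steady state is assessed over
#'   the last quarter).
#' @param delta_b0 off-resonance (Hz).
#' @return Tibble with `flip_deg` and `ratio` (unitless).
#' @export
contamination_scan <- function(flips_deg = 1:35, config = cki_config(),
                               n_pulses = 400, delta_b0 = 0) {
  params <- spin_params(k_ck = 0, cr = 1, t1_pcr = 4.5,
                        delta_b0 = delta_b0,
                        atp_ppm = config$atp_ppm,
                        larmor_hz_per_ppm = config$larmor_hz_per_ppm)
  np <- n_pools(params)
  G <- bm_generator(params)
  tail_idx <- seq(floor(3 * n_pulses / 4), n_pulses)
  ratios <- vapply(flips_deg, function(fl) {
    P_pulse <- bm_propagators(G, config$pulse_dur)[, , 1]
    P_te <- bm_propagators(G, config$te)[, , 1]
    P_rem <- bm_propagators(G, config$tr1 - config$pulse_dur - config$te)[, , 1]
    f <- pool_freqs(params)
    alphas <- fl * pi / 180 * gauss_profile(f, config$pulse_fwhm_hz)
    m <- equilibrium_state(params)
    s_pcr <- s_atp <- complex(n_pulses)
    t <- 0
    for (k in seq_len(n_pulses)) {
      phi <- if (k %% 2 == 1) 0 else pi
      m <- P_pulse %*% m
      t <- t + config$pulse_dur
      m <- rotation_matrix(alphas, phi, np) %*% m
      m <- P_te %*% m
      t <- t + config$te
      s_pcr[k] <- complex(real = m[1], imaginary = m[2])
      s_atp[k] <- complex(real = m[4], imaginary = m[5])
      m <- P_rem %*% m
      t <- t + config$tr1 - config$pulse_dur - config$te
    }
    pc <- max(Mod(s_pcr[tail_idx]))
    if (pc == 0) return(NA_real_)
    max(Mod(s_atp[tail_idx])) / pc
  }, 0)
  tibble::tibble(flip_deg = flips_deg, ratio = ratios)
}
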