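## Independent oracles used across the test files.

## Explicit-Euler propagator for the Bloch-McConnell generator: the
## first-order recursion M <- (I + dt G) M iterated n times, evaluated
## exactly as the matrix power (I + dt G)^n by binary exponentiation so that
## sub-microsecond steps stay affordable. The step is chosen from the
## fastest precession frequency so the first-order amplitude error
## n (w dt)^2 / 2 stays below `tol` for the segment.
euler_propagator <- function(params, duration, tol = 1e-7, max_dt = 1e-6) {
  G <- cki:::bm_generator(params)
  if (duration == 0) return(diag(nrow(G)))
  w <- 2 * pi * (max(abs(vapply(params$pools, `[[`, 0, "ppm"))) *
                   params$larmor + abs(params$delta_b0)) + 1
  n_min <- max(duration / max_dt, (w * duration)^2 / (2 * tol))
  n <- 2^max(1, ceiling(log2(n_min)))
  dt <- duration / n
  E <- diag(nrow(G)) + dt * G
  P <- diag(nrow(G))
  while (n > 0) {
    if (n %% 2 == 1) P <- P %*% E
    E <- E %*% E
    n <- n %/% 2
  }
  P
}

euler_evolve <- function(state, params, duration, tol = 1e-7) {
  drop(euler_propagator(params, duration, tol) %*% state)
}

## Independent rotation using complex transverse arithmetic: rotate M+ into
## the axis frame, apply the (My, Mz) rotation there, rotate back.
oracle_rotate <- function(m, alphas, phi, np) {
  for (p in seq_len(np)) {
    i <- 3 * (p - 1)
    mp <- complex(real = m[i + 1], imaginary = m[i + 2]) * exp(-1i * phi)
    mz <- m[i + 3]
    a <- alphas[p]
    my2 <- Im(mp) * cos(a) - mz * sin(a)
    mz2 <- Im(mp) * sin(a) + mz * cos(a)
    mp2 <- complex(real = Re(mp), imaginary = my2) * exp(1i * phi)
    m[i + 1] <- Re(mp2); m[i + 2] <- Im(mp2); m[i + 3] <- mz2
  }
  m
}

## End-to-end explicit-Euler walk of a schedule: an independent, plain-R
## re-implementation of the event sequencing (no compiled op stream).
euler_walk <- function(params, schedule, tol = 1e-7) {
  cfg <- schedule$config
  np <- length(params$pools)
  f <- cki:::pool_freqs(params)
  eff <- cki:::prep_efficiencies(cfg, params)
  prop_cache <- new.env(parent = emptyenv())
  evolve <- function(m, d) {
    key <- format(d, digits = 17)
    if (is.null(prop_cache[[key]])) {
      prop_cache[[key]] <- euler_propagator(params, d, tol)
    }
    drop(prop_cache[[key]] %*% m)
  }
  ex <- schedule$excitations
  m <- cki::equilibrium_state(params)
  samples <- complex(nrow(ex))
  for (step in schedule$plan) {
    if (step$type == "evolve") {
      m <- evolve(m, step$dur)
    } else if (step$type == "prep") {
      d <- rep(1, 3 * np + 1)
      d[3 * seq_len(np)] <- eff[step$prep, ]
      m <- d * m
    } else if (step$type == "crush") {
      for (p in seq_len(np)) m[3 * (p - 1) + (1:2)] <- 0
    } else if (step$type == "rf") {
      r <- step$exc
      alphas <- ex$flip_deg[r] * pi / 180 *
        cki::gauss_profile(f - ex$carrier_hz[r], cfg$pulse_fwhm_hz)
      phi <- ex$rf_phase_deg[r] * pi / 180 +
        2 * pi * ex$carrier_hz[r] * ex$t_pulse_end[r]
      m <- oracle_rotate(m, alphas, phi, np)
    } else if (step$type == "sample") {
      r <- step$exc
      s <- 0
      for (p in seq_len(np)) {
        i <- 3 * (p - 1)
        s <- s + complex(real = m[i + 1], imaginary = m[i + 2])
      }
      samples[r] <- s * exp(-1i * (2 * pi * ex$carrier_hz[r] * ex$t_sample[r] +
                                     ex$rf_phase_deg[r] * pi / 180))
    }
  }
  samples
}

## Step-by-step re-implementation of the conditioning text used as the
## textual-procedure oracle.
oracle_condition <- function(samples, target) {
  pcr <- samples[target == "PCr"]
  atp <- samples[target == "ATP"]
  odd <- pcr[seq(1, length(pcr), by = 2)]
  phi_pcr <- Arg(mean(odd))
  phi_atp <- Arg(mean(atp))
  pcr <- pcr * exp(-1i * phi_pcr)
  atp <- atp * exp(-1i * phi_atp)
  v <- c(Re(pcr), Im(pcr), Re(atp))
  v / sqrt(sum(v^2))
}

## Short schedule used where full-length physics is not the point: 4 blocks
## of 20 excitations keep every structural feature (prep, Te+, pause).
short_schedule <- function(n_per_block = 20L) {
  cki::build_schedule(cki::cki_config(n_per_block = n_per_block))
}

## Small dictionary grids shared across test files.
coarse_grid <- function() {
  cki::param_grid(k_ck = seq(0.1, 0.5, by = 0.05),
                  cr = seq(0.75, 1.75, by = 0.25),
                  t1_pcr = seq(3.5, 5.5, by = 0.5),
                  delta_b0 = c(-10, 0, 10))
}
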