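test_that("spiral design satisfies the trajectory contract", {
  tr <- design_spiral()
  expect_length(tr$kxy, 861)
  expect_equal(tr$kmax, sqrt(0.33) * 16, tolerance = 1e-12)
  expect_lte(max(Mod(tr$kxy)), tr$kmax + 1e-9)
  ## monotone radius growth
  expect_true(all(diff(Mod(tr$kxy)) >= -1e-12))
  ## deterministic
  expect_identical(design_spiral()$kxy, tr$kxy)
  expect_error(design_spiral(n_points = 20, coverage = 1), "too small")
  expect_error(design_spiral(coverage = 0), "coverage")
})

test_that("Voronoi weights are equal for interior points of a uniform grid", {
  g <- expand.grid(x = -5:5, y = -5:5)
  tr <- list(kxy = complex(real = g$x, imaginary = g$y))
  w <- voronoi_dcf(tr, clip_radius = 100)
  interior <- abs(g$x) < 5 & abs(g$y) < 5
  expect_equal(unname(w[interior]), rep(1, sum(interior)), tolerance = 1e-9)
})

test_that("Voronoi weights match the scipy polygon-area oracle", {
  set.seed(31)
  n <- 200
  r <- sqrt(runif(n)) * 10
  th <- runif(n, 0, 2 * pi)
  px <- r * cos(th); py <- r * sin(th)
  tr <- list(kxy = complex(real = px, imaginary = py))
  w <- voronoi_dcf(tr, clip_radius = 1e4)
  ref <- scipy_voronoi_areas(px, py)
  idx <- which(is.finite(ref))
  expect_gt(length(idx), 100)
  expect_lt(max(abs(w[idx] - ref[idx]) / ref[idx]), 1e-9)
})

test_that("half-period Hann taper has the exact endpoint values", {
  tr <- list(kxy = c(0 + 0i, 3 + 0i, 0 + 6i))
  w <- apply_hanning(c(1, 1, 1), tr)
  expect_equal(w[1], 1)                     # centre: factor exactly 1
  expect_equal(w[2], 0.5 * (1 + cos(pi / 2)))
  expect_equal(w[3], 0)                     # |k| = kmax: factor exactly 0
})

test_that("a DC-only sample reconstructs to a flat image", {
  tr <- list(kxy = 0 + 0i, matrix_size = 16)
  img <- grid_and_fft(array(1 + 0i, c(1, 1)), tr, weights = 1, kz_out = 1)
  mag <- Mod(img[, , 1, 1])
  expect_lt((max(mag) - min(mag)) / mean(mag), 1e-3)
})

test_that("gridding and degridding are adjoint", {
  set.seed(8)
  n <- 150
  tr <- list(kxy = complex(real = runif(n, -7, 7), imaginary = runif(n, -7, 7)),
             matrix_size = 16)
  op <- cki:::grid_operator(tr)
  x <- complex(real = rnorm(n), imaginary = rnorm(n))
  gx <- as.vector(op$A %*% Re(x)) + 1i * as.vector(op$A %*% Im(x))
  Y <- matrix(complex(real = rnorm(op$ng^2), imaginary = rnorm(op$ng^2)),
              op$ng, op$ng)
  aty <- cki:::degrid_kspace(Y, tr)
  lhs <- sum(Conj(gx) * as.vector(Y))
  rhs <- sum(Conj(x) * aty)
  expect_lt(Mod(lhs - rhs) / Mod(rhs), 1e-6)
})

test_that("the gridding chain is linear", {
  set.seed(9)
  tr <- design_spiral(n_points = 200, coverage = 1, matrix_size = 16)
  w <- voronoi_dcf(tr)
  X <- array(complex(real = rnorm(200), imaginary = rnorm(200)), c(200, 1))
  Y <- array(complex(real = rnorm(200), imaginary = rnorm(200)), c(200, 1))
  a <- 2.3 - 1.1i; b <- -0.7 + 0.4i
  lhs <- grid_and_fft(a * X + b * Y, tr, w, kz_out = 1)
  rhs <- a * grid_and_fft(X, tr, w, kz_out = 1) +
    b * grid_and_fft(Y, tr, w, kz_out = 1)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("a Gaussian object sampled on a full-coverage spiral reconstructs", {
  N <- 32
  tr <- design_spiral(n_points = 4000, coverage = 1, matrix_size = N,
                      turn_spacing = 0.5)
  w <- voronoi_dcf(tr)
  sig <- 2.5
  ## continuous Fourier transform of the centred Gaussian object
  u <- tr$kxy / N   # cycles per voxel
  samples <- (sig * sqrt(2 * pi))^2 *
    exp(-2 * pi^2 * sig^2 * (Re(u)^2 + Im(u)^2))
  img <- grid_and_fft(array(samples, c(length(samples), 1)), tr, w,
                      kz_out = 1)
  got <- Re(img[, , 1, 1])
  xc <- N / 2 + 1
  xs <- seq_len(N) - xc
  want <- outer(exp(-xs^2 / (2 * sig^2)), exp(-xs^2 / (2 * sig^2)))
  got <- got / max(got); want <- want / max(want)
  nrmse <- sqrt(mean((got - want)^2)) / sqrt(mean(want^2))
  expect_lt(nrmse, 0.05)
})

test_that("interleaved-subtraction noise estimate behaves correctly", {
  tr <- design_spiral(n_points = 200, coverage = 1, matrix_size = 8)
  w <- voronoi_dcf(tr)
  ## identical averages -> exactly zero noise
  base <- array(complex(real = rnorm(200 * 1 * 3 * 2),
                        imaginary = rnorm(200 * 1 * 3 * 2)),
                c(200, 1, 3, 2, 1))
  raw <- array(0i, c(200, 1, 3, 2, 2))
  raw[, , , , 1] <- base; raw[, , , , 2] <- base
  est <- estimate_noise(raw, tr, w, kz_out = 1)
  expect_equal(max(Mod(est$samples)), 0)
  ## correlated two-coil noise: recovered covariance within 10% per entry
  set.seed(12)
  rho <- 0.5
  C <- matrix(c(1, rho, rho, 1), 2, 2)
  L <- chol(C)
  n_fa <- 40
  raw2 <- array(0i, c(200, 1, n_fa, 2, 2))
  for (a in 1:2) {
    Z <- matrix(complex(real = rnorm(200 * n_fa * 2),
                        imaginary = rnorm(200 * n_fa * 2)),
                ncol = 2) %*% L
    raw2[, , , , a] <- array(Z, c(200, 1, n_fa, 2))
  }
  est2 <- estimate_noise(raw2, tr, w, kz_out = 1, fa_subset = seq_len(n_fa))
  Cn <- est2$covariance / mean(Re(diag(est2$covariance)))
  expect_equal(Re(Cn), C, tolerance = 0.1)
  expect_error(estimate_noise(raw2[, , , , 1, drop = FALSE], tr, w),
               "averages")
})

test_that("whitened-SVD combination satisfies its contracts", {
  set.seed(21)
  nfa <- 60
  s <- complex(real = cos(seq_len(nfa) / 5), imaginary = sin(seq_len(nfa) / 7))
  ## single coil, identity covariance: output equals input up to phase
  one <- array(s, c(1, 1, 1, nfa, 1))
  out1 <- wsvd_combine(one, diag(1))
  ph <- out1[1, 1, 1, ] / s
  expect_equal(Mod(drop(out1)), Mod(s), tolerance = 1e-10)
  expect_lt(max(Mod(ph - mean(ph))), 1e-8)
  ## two coils (s, 0): output proportional to s with the full energy
  two <- array(0i, c(1, 1, 1, nfa, 2))
  two[1, 1, 1, , 1] <- s
  out2 <- drop(wsvd_combine(two, diag(2)))
  expect_equal(sum(Mod(out2)^2), sum(Mod(s)^2), tolerance = 1e-10)
  expect_lt(max(Mod(out2 / s - mean(out2 / s))), 1e-8)
  ## 8 coils, correlated noise: better signal correlation than sum-of-squares
  nc <- 8; nvox <- 24
  sens <- matrix(complex(real = rnorm(nvox * nc), imaginary = rnorm(nvox * nc)),
                 nvox, nc)
  rho <- 0.4
  C <- rho^abs(outer(1:nc, 1:nc, "-"))
  L <- chol(C)
  imgs <- array(0i, c(nvox, 1, 1, nfa, nc))
  for (v in seq_len(nvox)) {
    noise <- matrix(complex(real = rnorm(nfa * nc), imaginary = rnorm(nfa * nc)),
                    nfa, nc) %*% L * 0.4
    imgs[v, 1, 1, , ] <- outer(s, sens[v, ]) + noise
  }
  comb <- wsvd_combine(imgs, C)
  sos <- apply(imgs, c(1, 4), function(z) sqrt(sum(Mod(z)^2)))
  cor_w <- mean(sapply(seq_len(nvox), function(v) {
    abs(stats::cor(Mod(comb[v, 1, 1, ]), Mod(s)))
  }))
  cor_s <- mean(sapply(seq_len(nvox), function(v) {
    abs(stats::cor(sos[v, ], Mod(s)))
  }))
  expect_gte(cor_w, cor_s)
  expect_error(wsvd_combine(imgs, matrix(0, nc, nc)), "singular")
})

test_that("whitened-SVD is invariant to invertible coil recombination", {
  set.seed(33)
  nfa <- 40; nc <- 4
  s <- complex(real = rnorm(nfa), imaginary = rnorm(nfa))
  sens <- complex(real = rnorm(nc), imaginary = rnorm(nc))
  C <- 0.3^abs(outer(1:nc, 1:nc, "-"))
  imgs <- array(0i, c(1, 1, 1, nfa, nc))
  imgs[1, 1, 1, , ] <- outer(s, sens)
  T <- matrix(complex(real = rnorm(nc * nc), imaginary = rnorm(nc * nc)),
              nc, nc)
  imgsT <- imgs
  imgsT[1, 1, 1, , ] <- imgs[1, 1, 1, , ] %*% t(T)
  CT <- T %*% C %*% Conj(t(T))
  a <- drop(wsvd_combine(imgs, C))
  b <- drop(wsvd_combine(imgsT, CT))
  ## equal up to a global phase
  ph <- b / a
  expect_lt(max(Mod(ph - mean(ph))), 1e-6)
  expect_equal(Mod(b), Mod(a), tolerance = 1e-8)
})

test_that("MP-PCA suppresses pure noise and preserves low-rank signal", {
  set.seed(14)
  X <- matrix(complex(real = rnorm(400 * 100), imaginary = rnorm(400 * 100)),
              400, 100)
  den <- mppca_denoise(X)
  expect_lte(mean(Mod(den$series)^2), 0.1 * mean(Mod(X)^2))
  ## exact rank-1 signal, no noise: preserved to 1e-8
  u <- complex(real = rnorm(300), imaginary = rnorm(300))
  v <- complex(real = rnorm(80), imaginary = rnorm(80))
  S1 <- outer(u, v)
  den1 <- mppca_denoise(S1)
  expect_lt(max(Mod(den1$series - S1)), 1e-8 * max(Mod(S1)))
  ## rank-3 + noise at 10 dB: denoised closer to clean than input
  S3 <- outer(u, v) +
    outer(rev(u), complex(real = rnorm(80), imaginary = rnorm(80))) +
    outer(u * (1:300) / 300, complex(real = rnorm(80), imaginary = rnorm(80)))
  sigma <- sqrt(mean(Mod(S3)^2) / 10^(10 / 10))
  noisy <- S3 + sqrt(sigma^2 / 2) *
    matrix(complex(real = rnorm(300 * 80), imaginary = rnorm(300 * 80)),
           300, 80)
  den3 <- mppca_denoise(noisy)
  rmse_in <- sqrt(mean(Mod(noisy - S3)^2))
  rmse_out <- sqrt(mean(Mod(den3$series - S3)^2))
  expect_lt(rmse_out, rmse_in)
  expect_error(mppca_denoise(matrix(1 + 0i, 1, 5)), "voxels")
})
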