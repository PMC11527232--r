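#' Digital brain-like phantom for CKI
#'
#' Ellipsoidal "brain" with a gray-matter shell, white-matter core and
#' CSF-filled ventricles on the reconstruction grid, carrying per-voxel
#' kCK / Cr / T1PCr / B0 maps, a proton-density-like amplitude and tissue
#' labels, plus a posterior "occipital" ROI used by the functional
#' experiments. Tissue means follow the in-vivo gray/white-matter values
#' (GM: kCK 0.30 1/s, Cr 1.27, T1PCr 4.67 s; WM: 0.30, 1.23, 4.50); voxel
#' values are jittered per tissue with seeded Gaussian noise and clamped to
#' the dictionary bounds. The B0 field is smooth, within ±`b0_amplitude` Hz,
#' with a stronger gradient towards the frontal (anterior, low-y) edge.
#'
#' @param seed RNG seed for the jitter.
#' @param nx,ny,nz grid size (default the 32 x 32 x 11 protocol matrix).
#' @param fov_mm field of view (mm), for serialization metadata.
#' @param jitter per-tissue SDs for `k_ck`, `cr`, `t1_pcr` (set all to 0 for
#'   piecewise-constant maps).
#' @param tissues named list (`gm`, `wm`, `csf`) of tissue parameter lists
#'   (`k_ck`, `cr`, `t1_pcr`, `amp`).
#' @param b0_amplitude half-range of the off-resonance field (Hz).
#' @return Object of class `cki_phantom`: `maps` (list of 3D arrays `k_ck`,
#'   `cr`, `t1_pcr`, `delta_b0`, `amplitude`), `labels` (0 background, 1 GM,
#'   2 WM, 3 CSF), `roi` (list of logical arrays), `geometry`.
#' @export
make_phantom <- function(seed = 1, nx = 32, ny = 32, nz = 11,
                         fov_mm = c(230, 230, 220),
                         jitter = list(k_ck = 0.02, cr = 0.08, t1_pcr = 0.3),
                         tissues = list(
                           gm = list(k_ck = 0.30, cr = 1.27, t1_pcr = 4.67,
                                     amp = 1),
                           wm = list(k_ck = 0.30, cr = 1.23, t1_pcr = 4.50,
                                     amp = 1),
                           csf = list(k_ck = 0.15, cr = 1.00, t1_pcr = 5.00,
                                      amp = 0.2)),
                         b0_amplitude = 10) {
  dims <- c(nx, ny, nz)
  xr <- array(rep((seq_len(nx) - (nx + 1) / 2) / (nx / 2), ny * nz), dims)
  yr <- array(rep(rep((seq_len(ny) - (ny + 1) / 2) / (ny / 2), each = nx),
                  nz), dims)
  zr <- array(rep((seq_len(nz) - (nz + 1) / 2) / (nz / 2), each = nx * ny),
              dims)

  head <- (xr / 0.85)^2 + (yr / 0.92)^2 + (zr / 0.88)^2 <= 1
  wm <- (xr / 0.55)^2 + (yr / 0.62)^2 + (zr / 0.60)^2 <= 1
  csf <- ((xr - 0.18) / 0.14)^2 + (yr / 0.32)^2 + (zr / 0.35)^2 <= 1 |
    ((xr + 0.18) / 0.14)^2 + (yr / 0.32)^2 + (zr / 0.35)^2 <= 1
  labels <- array(0L, dims)
  labels[head] <- 1L
  labels[head & wm] <- 2L
  labels[head & csf] <- 3L

  ## posterior (occipital) ROI: rear gray-matter cap
  occ <- labels == 1L & yr > 0.45

  ## smooth off-resonance with a stronger frontal (anterior) deviation
  b0 <- 0.25 * xr + 0.2 * yr + 0.1 * zr -
    1.2 * exp(-((yr + 0.85)^2 / 0.25 + xr^2 / 0.9))
  b0 <- b0_amplitude * pmax(pmin(b0, 1), -1)
  b0[labels == 0L] <- 0

  maps <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (fld in c("k_ck", "cr", "t1_pcr")) {
    m <- array(0, dims)
    for (ti in 1:3) {
      tv <- tissues[[c("gm", "wm", "csf")[ti]]]
      idx <- which(labels == ti)
      m[idx] <- tv[[fld]] + stats::rnorm(length(idx), 0, jitter[[fld]])
    }
    lim <- switch(fld, k_ck = c(0.05, 0.60), cr = c(0.5, 6),
                  t1_pcr = c(2, 7))
    m <- pmax(pmin(m, lim[2]), lim[1])
    m[labels == 0L] <- 0
    maps[[fld]] <- m
  }
  maps$delta_b0 <- b0
  amp <- array(0, dims)
  for (ti in 1:3) {
    amp[labels == ti] <- tissues[[c("gm", "wm", "csf")[ti]]]$amp
  }
  maps$amplitude <- amp

  structure(list(maps = maps, labels = labels,
                 roi = list(occipital = occ),
                 geometry = list(nx = nx, ny = ny, nz = nz, fov_mm = fov_mm),
                 seed = seed),
            class = "cki_phantom")
}

#' @export
print.cki_phantom <- function(x, ...) {
  g <- x$geometry
  cat("CKI digital phantom:", g$nx, "x", g$ny, "x", g$nz, "voxels;",
      sum(x$labels > 0), "in brain (",
      sum(x$labels == 1), "GM /", sum(x$labels == 2), "WM /",
      sum(x$labels == 3), "CSF )\n")
  invisible(x)
}

#' Inject a focal kCK activation into a phantom ROI
#'
#' Multiplies `k_ck` by `1 + relative_increase` inside the named ROI,
#' emulating the functional increase during stimulation.
#'
#' @param phantom a [make_phantom()] result.
#' @param roi ROI name (default `"occipital"`).
#' @param relative_increase fractional increase (0.15 for the 15% effect).
#' @return The modified phantom.
#' @export
inject_activation <- function(phantom, roi = "occipital",
                              relative_increase = 0.15) {
  if (!roi %in% names(phantom$roi)) {
    stop("unknown ROI '", roi, "'; available: ",
         paste(names(phantom$roi), collapse = ", "))
  }
  idx <- phantom$roi[[roi]]
  phantom$maps$k_ck[idx] <- phantom$maps$k_ck[idx] * (1 + relative_increase)
  phantom
}

#' Smooth complex coil sensitivities and noise covariance
#'
#' Coils are placed around the head; each sensitivity is a broad Gaussian
#' magnitude with a smooth linear phase (nonzero everywhere over the
#' object). The coil noise covariance defaults to a Toeplitz matrix with
#' `rho` neighbour correlation.
#'
#' @param n_coils number of receive coils.
#' @param nx,ny,nz grid size (match the phantom).
#' @param rho neighbour noise correlation.
#' @return Object of class `cki_coils`: `sens` (complex array
#'   `[nx, ny, nz, n_coils]`), `covariance`.
#' @export
coil_model <- function(n_coils = 4, nx = 32, ny = 32, nz = 11, rho = 0.2) {
  dims <- c(nx, ny, nz)
  xr <- array(rep((seq_len(nx) - (nx + 1) / 2) / (nx / 2), ny * nz), dims)
  yr <- array(rep(rep((seq_len(ny) - (ny + 1) / 2) / (ny / 2), each = nx),
                  nz), dims)
  sens <- array(0i, c(dims, n_coils))
  for (cc in seq_len(n_coils)) {
    a <- 2 * pi * (cc - 1) / n_coils
    cx <- 1.15 * cos(a); cy <- 1.15 * sin(a)
    mag <- exp(-((xr - cx)^2 + (yr - cy)^2) / (2 * 0.8^2))
    ph <- 0.6 * (xr * cos(a) + yr * sin(a)) + a / 3
    sens[, , , cc] <- mag * exp(1i * ph)
  }
  structure(list(sens = sens,
                 covariance = rho^abs(outer(seq_len(n_coils),
                                            seq_len(n_coils), "-"))),
            class = "cki_coils")
}

## Exact discrete-Fourier sampling operator: spiral samples of a centred
## nx x ny image (0-based centre at nx/2, ny/2), matching the gridding
## chain's FFT conventions.
dft_operator <- function(trajectory, nx, ny) {
  kx <- Re(trajectory$kxy); ky <- Im(trajectory$kxy)
  x <- (0:(nx - 1)) - nx / 2
  y <- (0:(ny - 1)) - ny / 2
  px <- exp(-2i * pi * outer(kx, x) / nx)   # n_read x nx
  py <- exp(-2i * pi * outer(ky, y) / ny)   # n_read x ny
  ## E[s, v] with v = x + nx * y (column-major voxel order)
  E <- matrix(0i, length(kx), nx * ny)
  for (j in seq_len(ny)) {
    E[, (j - 1) * nx + seq_len(nx)] <- px * py[, j]
  }
  E
}

## Centred forward DFT along z (inverse of the recon's kz -> z transform).
z_to_kz <- function(arr_znfirst) {
  n <- dim(arr_znfirst)[1]
  d <- dim(arr_znfirst)
  m <- matrix(arr_znfirst, n, prod(d[-1]))
  m <- m[ifftshift_idx(n), , drop = FALSE]
  out <- stats::mvfft(m)
  out <- out[fftshift_idx(n), , drop = FALSE]
  dim(out) <- d
  out
}

#' Forward-simulate multi-coil spiral raw data from a phantom
#'
#' Simulates the signal evolution of every in-brain voxel with the
#' Bloch-McConnell model, forms coil-weighted images per flip-angle index,
#' transforms to kz (keeping the `n_kz` central planes), samples the spiral
#' with the exact discrete Fourier sum (reference mode; no inverse crime
#' against the Kaiser-Bessel adjoint used in reconstruction) or a fast
#' NUFFT-style interpolation (`mode = "adjoint"`, labelled approximate), and
#' adds correlated complex Gaussian noise per average.
#'
#' @param phantom a [make_phantom()] result.
#' @param schedule a [build_schedule()] result.
#' @param coils a [coil_model()] result (sensitivities matching the grid).
#' @param trajectory a [design_spiral()] result.
#' @param n_averages number of repeated acquisitions.
#' @param noise_sigma complex noise SD per sample (0 for noiseless).
#' @param seed RNG seed for the noise.
#' @param mode `"dft"` (exact, default) or `"adjoint"` (fast, approximate).
#' @param n_kz number of acquired kz planes (central planes of the phantom
#'   z-axis).
#' @return Object of class `cki_raw`: `tensor`
#'   `[n_read, n_kz, n_fa, n_coil, n_avg]`, `trajectory`, `evolutions`
#'   (per-voxel noiseless evolutions, voxels x fa), `mask`, `meta`.
#' @export
forward_simulate <- function(phantom, schedule, coils, trajectory,
                             n_averages = 2, noise_sigma = 0, seed = 1,
                             mode = c("dft", "adjoint"), n_kz = NULL) {
  mode <- match.arg(mode)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  g <- phantom$geometry
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  if (is.null(n_kz)) n_kz <- min(5L, nz)
  if (n_kz > nz) stop("n_kz cannot exceed the phantom z size")
  if (!all(dim(coils$sens)[1:3] == c(nx, ny, nz))) {
    stop("coil sensitivities do not match the phantom grid")
  }
  nfa <- nrow(schedule$excitations)
  n_read <- length(trajectory$kxy)
  n_coil <- dim(coils$sens)[4]

  mask <- which(phantom$maps$amplitude > 0)
  V <- matrix(0i, nx * ny * nz, nfa)
  cache <- new.env(parent = emptyenv())
  for (v in mask) {
    p <- spin_params(phantom$maps$k_ck[v], phantom$maps$cr[v],
                     phantom$maps$t1_pcr[v], phantom$maps$delta_b0[v])
    key <- paste(format(c(p$k_ck, p$cr, p$t1_pcr, p$delta_b0), digits = 12),
                 collapse = ",")
    evo <- cache[[key]]
    if (is.null(evo)) {
      evo <- simulate_evolution(p, schedule)$samples
      cache[[key]] <- evo
    }
    V[v, ] <- evo
  }

  kz_sel <- floor((nz - n_kz) / 2) + seq_len(n_kz)
  E <- if (mode == "dft") dft_operator(trajectory, nx, ny) else NULL

  S0 <- array(0i, c(n_read, n_kz, nfa, n_coil))
  for (cc in seq_len(n_coil)) {
    wvox <- as.vector(phantom$maps$amplitude) * as.vector(coils$sens[, , , cc])
    A <- array(wvox * V, c(nx * ny, nz, nfa))
    A <- z_to_kz(aperm(A, c(2, 1, 3)))          # [nz(kz), nx*ny, nfa]
    for (m in seq_len(n_kz)) {
      plane <- A[kz_sel[m], , ]                 # [nx*ny, nfa]
      S0[, m, , cc] <- if (mode == "dft") E %*% plane else
        nufft_forward(plane, trajectory, nx, ny)
    }
  }

  tensor <- array(0i, c(n_read, n_kz, nfa, n_coil, n_averages))
  if (noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    L <- chol(coils$covariance)
    nsamp <- n_read * n_kz * nfa
    for (a in seq_len(n_averages)) {
      Z <- matrix(complex(real = stats::rnorm(nsamp * n_coil),
                          imaginary = stats::rnorm(nsamp * n_coil)),
                  nsamp, n_coil) %*% L * (noise_sigma / sqrt(2))
      tensor[, , , , a] <- S0 + array(Z, dim(S0))
    }
  } else {
    for (a in seq_len(n_averages)) tensor[, , , , a] <- S0
  }

  structure(list(tensor = tensor, trajectory = trajectory,
                 evolutions = V[mask, , drop = FALSE], mask = mask,
                 meta = list(n_kz = n_kz, nz = nz, mode = mode,
                             noise_sigma = noise_sigma, seed = seed,
                             n_averages = n_averages,
                             schedule_hash = config_hash(schedule$config))),
            class = "cki_raw")
}

#' @export
print.cki_raw <- function(x, ...) {
  cat("CKI raw k-space tensor:", paste(dim(x$tensor), collapse = " x "),
      "(read x kz x fa x coil x avg)\n")
  invisible(x)
}

## Fast approximate spiral sampling: zero-pad the image spectrum on a 2x
## oversampled grid and interpolate with the Kaiser-Bessel kernel
## (deapodization applied in image space first).
nufft_forward <- function(plane, trajectory, nx, ny, osf = 2, width = 4) {
  ng <- nx * osf
  beta <- kb_beta(width, osf)
  dea <- kb_deapod_grid(ng, width, beta, normalize = FALSE)
  lo <- ng / 2 + 1 - nx / 2
  idx <- lo:(lo + nx - 1)
  out <- matrix(0i, length(trajectory$kxy), ncol(plane))
  dcorr <- outer(dea[idx], dea[idx])
  for (j in seq_len(ncol(plane))) {
    img <- matrix(plane[, j], nx, ny) / dcorr
    pad <- matrix(0i, ng, ng)
    pad[idx, idx] <- img
    K <- pad[ifftshift_idx(ng), ifftshift_idx(ng)]
    K <- stats::mvfft(t(stats::mvfft(K)))
    K <- t(K)[fftshift_idx(ng), fftshift_idx(ng)]
    out[, j] <- degrid_kspace(K, list(kxy = trajectory$kxy), osf = osf,
                              width = width)
  }
  out
}
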