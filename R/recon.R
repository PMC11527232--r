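#' Design the spiral readout trajectory
#'
#' Archimedean spiral covering a centred disc in kxy. "Coverage" is the
#' sampled-area fraction of the Nyquist disc: the spiral extends to
#' `kmax = sqrt(coverage) * matrix_size / 2` (in cycles/FOV), with radial
#' turn spacing at the Nyquist distance of 1 cycle/FOV. The default density
#' law (`"archimedean"`, radius linear in sample index) is denser near the
#' k-space centre; `"uniform"` distributes samples uniformly per unit area.
#'
#' @param n_points number of readout samples.
#' @param coverage sampled-area fraction of the Nyquist disc, in (0, 1].
#' @param matrix_size in-plane reconstruction matrix (voxels).
#' @param fov_mm in-plane field of view (mm).
#' @param dwell sample dwell time (s).
#' @param density `"archimedean"` or `"uniform"`.
#' @param turn_spacing radial distance between successive turns
#'   (cycles/FOV); 1 is the Nyquist spacing.
#' @return Object of class `cki_trajectory`: `kxy` (complex, cycles/FOV),
#'   `kmax`, `dwell`, `coverage`, `matrix_size`, `fov_mm`, `n_turns`.
#' @export
design_spiral <- function(n_points = 861, coverage = 0.33, matrix_size = 32,
                          fov_mm = 230, dwell = 1e-5,
                          density = c("archimedean", "uniform"),
                          turn_spacing = 1) {
  density <- match.arg(density)
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  if (turn_spacing <= 0) stop("turn_spacing must be > 0")
  k_nyq <- matrix_size / 2
  kmax <- sqrt(coverage) * k_nyq
  n_turns <- max(1, ceiling(kmax / turn_spacing))
  if (n_points < 8 * n_turns) {
    stop("n_points too small for ", n_turns, " Nyquist-spaced turns")
  }
  tau <- (seq_len(n_points) - 1) / (n_points - 1)
  r <- kmax * switch(density, archimedean = tau, uniform = sqrt(tau))
  theta <- 2 * pi * n_turns * tau
  structure(list(kxy = complex(real = r * cos(theta),
                               imaginary = r * sin(theta)),
                 kmax = kmax, dwell = dwell, coverage = coverage,
                 matrix_size = matrix_size, fov_mm = fov_mm,
                 n_turns = n_turns, density = density),
            class = "cki_trajectory")
}

## Sutherland-Hodgman clip of polygon (px, py) against half-plane
## nx*x + ny*y <= c. Returns list(x, y) (possibly empty).
clip_halfplane <- function(px, py, nx, ny, cc) {
  d <- nx * px + ny * py - cc
  inside <- d <= 0
  if (all(inside)) return(list(x = px, y = py))
  if (!any(inside)) return(list(x = numeric(0), y = numeric(0)))
  n <- length(px)
  jn <- c(seq_len(n)[-1], 1L)
  ox <- numeric(0); oy <- numeric(0)
  for (i in seq_len(n)) {
    j <- jn[i]
    if (inside[i]) { ox <- c(ox, px[i]); oy <- c(oy, py[i]) }
    if (xor(inside[i], inside[j])) {
      t <- d[i] / (d[i] - d[j])
      ox <- c(ox, px[i] + t * (px[j] - px[i]))
      oy <- c(oy, py[i] + t * (py[j] - py[i]))
    }
  }
  list(x = ox, y = oy)
}

polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(seq_len(n)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Voronoi density compensation weights
#'
#' One weight per readout sample: the area of its Voronoi cell, with
#' boundary cells clipped to a disc of radius `kmax` plus half the mean
#' sample spacing. Cells are computed by half-plane (perpendicular-bisector)
#' clipping with nearest-neighbour early termination.
#'
#' @param trajectory a [design_spiral()] result (or any object with complex
#'   `kxy`).
#' @param clip_radius disc radius for boundary clipping; default
#'   `kmax + half mean nearest-neighbour spacing`.
#' @return Numeric vector of positive weights, one per sample.
#' @export
voronoi_dcf <- function(trajectory, clip_radius = NULL) {
  k <- trajectory$kxy
  n <- length(k)
  px <- Re(k); py <- Im(k)
  ## duplicate handling: jitter exact duplicates by a tiny epsilon
  o <- order(px, py)
  dup <- which(diff(px[o]) == 0 & diff(py[o]) == 0)
  if (length(dup)) {
    warning(length(dup), " duplicate k-space points jittered")
    eps <- 1e-9 * max(1, max(Mod(k)))
    idx <- o[dup + 1]
    px[idx] <- px[idx] + eps * seq_along(idx)
    py[idx] <- py[idx] + eps * seq_along(idx)
  }
  if (is.null(clip_radius)) {
    nn <- vapply(seq_len(n), function(i) {
      d2 <- (px - px[i])^2 + (py - py[i])^2
      sqrt(min(d2[-i]))
    }, 0)
    clip_radius <- max(Mod(k)) + mean(nn) / 2
  }
  R <- clip_radius
  ## circumscribed polygon of the clipping disc (tangent half-planes)
  m_disc <- 256L
  ang <- 2 * pi * (seq_len(m_disc) - 1) / m_disc
  w <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (px - px[i])^2 + (py - py[i])^2
    ord <- order(d2)[-1]
    ## start from a bounding square
    poly <- list(x = px[i] + c(-2, 2, 2, -2) * R,
                 y = py[i] + c(-2, -2, 2, 2) * R)
    for (j in ord) {
      dmax2 <- max((poly$x - px[i])^2 + (poly$y - py[i])^2)
      if (d2[j] > 4 * dmax2) break
      mx <- (px[i] + px[j]) / 2; my <- (py[i] + py[j]) / 2
      nx <- px[j] - px[i]; ny <- py[j] - py[i]
      poly <- clip_halfplane(poly$x, poly$y, nx, ny, nx * mx + ny * my)
      if (length(poly$x) < 3) {
        stop("degenerate Voronoi cell at sample index ", i)
      }
    }
    ## clip to the disc (tangent half-planes, applied only where violated)
    if (any(poly$x^2 + poly$y^2 > R^2)) {
      for (a in ang) {
        nx <- cos(a); ny <- sin(a)
        if (any(nx * poly$x + ny * poly$y > R)) {
          poly <- clip_halfplane(poly$x, poly$y, nx, ny, R)
          if (length(poly$x) < 3) {
            stop("degenerate Voronoi cell at sample index ", i)
          }
        }
      }
    }
    w[i] <- polygon_area(poly$x, poly$y)
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("non-positive Voronoi weight at index ",
         paste(which(!is.finite(w) | w <= 0), collapse = ", "))
  }
  w
}

#' Radial half-period Hann taper of the density compensation weights
#'
#' Multiplies the weights by `0.5 * (1 + cos(pi * |k| / kmax))`: exactly 1
#' at the k-space centre and 0 at `|k| = kmax`, damping the influence of the
#' outermost samples.
#'
#' @param weights DCF weights (from [voronoi_dcf()]).
#' @param trajectory the matching trajectory.
#' @param kmax taper extent; defaults to the largest sampled radius.
#' @return Filtered weights.
#' @export
apply_hanning <- function(weights, trajectory, kmax = NULL) {
  r <- Mod(trajectory$kxy)
  if (is.null(kmax)) kmax <- max(r)
  weights * 0.5 * (1 + cos(pi * pmin(r / kmax, 1)))
}

## Kaiser-Bessel kernel machinery (width in oversampled grid cells,
## shape parameter per the standard optimal-kernel prescription).
kb_beta <- function(width, osf) {
  pi * sqrt((width / osf)^2 * (osf - 0.5)^2 - 0.8)
}

kb_kernel <- function(u, width, beta) {
  z <- 1 - (2 * u / width)^2
  out <- numeric(length(u))
  ok <- z >= 0
  out[ok] <- besselI(beta * sqrt(z[ok]), 0) / besselI(beta, 0)
  out
}

## Image-domain transform of the KB kernel (deapodization function),
## evaluated at pixel offset x for an oversampled grid of ng cells.
kb_deapod <- function(x, width, beta, ng) {
  arg <- beta^2 - (pi * width * x / ng)^2
  out <- numeric(length(x))
  pos <- arg > 0
  out[pos] <- sinh(sqrt(arg[pos])) / sqrt(arg[pos])
  out[!pos] <- sinc0(sqrt(-arg[!pos]))
  out
}

sinc0 <- function(z) ifelse(z == 0, 1, sin(z) / z)

## Deapodization profile as the centred inverse DFT of the kernel sampled at
## the integer grid offsets: exact for on-grid samples, and within the
## kernel's approximation error elsewhere. Normalized to 1 at the centre.
kb_deapod_grid <- function(ng, width, beta, normalize = TRUE) {
  kern <- kb_kernel(seq_len(ng) - (ng / 2 + 1), width, beta)
  f <- Re(stats::fft(kern[ifftshift_idx(ng)], inverse = TRUE))[fftshift_idx(ng)]
  if (normalize) f / f[ng / 2 + 1] else f
}

## Sparse gridding operator: maps n_read spiral samples (already
## density-compensated) onto the oversampled ng x ng Cartesian grid.
grid_operator <- function(trajectory, matrix_size = NULL, osf = 1.5,
                          width = 4) {
  if (is.null(matrix_size)) matrix_size <- trajectory$matrix_size
  ng <- round(matrix_size * osf)
  dk <- matrix_size / ng          # grid spacing in cycles/FOV
  beta <- kb_beta(width, osf)
  ic <- ng / 2 + 1
  k <- trajectory$kxy
  ux <- Re(k) / dk + ic
  uy <- Im(k) / dk + ic
  half <- width / 2
  ii <- list(); jj <- list(); vv <- list()
  for (ox in seq(-ceiling(half), ceiling(half))) {
    gx <- round(ux) + ox
    wx <- kb_kernel(gx - ux, width, beta)
    for (oy in seq(-ceiling(half), ceiling(half))) {
      gy <- round(uy) + oy
      wy <- kb_kernel(gy - uy, width, beta)
      wgt <- wx * wy
      keep <- wgt > 0 & gx >= 1 & gx <= ng & gy >= 1 & gy <= ng
      if (any(keep)) {
        ii[[length(ii) + 1]] <- gx[keep] + (gy[keep] - 1) * ng
        jj[[length(jj) + 1]] <- which(keep)
        vv[[length(vv) + 1]] <- wgt[keep]
      }
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(ng * ng, length(k)))
  list(A = A, ng = ng, dk = dk, beta = beta, width = width, osf = osf,
       matrix_size = matrix_size)
}

## Interpolate Cartesian k-space (ng x ng) back onto the spiral samples.
## Written as its own kernel-evaluation loop (not the transpose of the
## sparse operator) so gridding adjointness is a meaningful test.
degrid_kspace <- function(kgrid, trajectory, osf = 1.5, width = 4) {
  ng <- nrow(kgrid)
  matrix_size <- ng / osf
  dk <- matrix_size / ng
  beta <- kb_beta(width, osf)
  ic <- ng / 2 + 1
  ux <- Re(trajectory$kxy) / dk + ic
  uy <- Im(trajectory$kxy) / dk + ic
  half <- ceiling(width / 2)
  out <- complex(length(ux))
  for (s in seq_along(ux)) {
    gx <- round(ux[s]) + (-half:half)
    gy <- round(uy[s]) + (-half:half)
    wx <- kb_kernel(gx - ux[s], width, beta)
    wy <- kb_kernel(gy - uy[s], width, beta)
    ok_x <- gx >= 1 & gx <= ng & wx > 0
    ok_y <- gy >= 1 & gy <= ng & wy > 0
    if (any(ok_x) && any(ok_y)) {
      sub <- kgrid[gx[ok_x], gy[ok_y], drop = FALSE]
      out[s] <- sum(t(wx[ok_x] * sub) * wy[ok_y])
    }
  }
  out
}

## result[i] = x[idx[i]]: fftshift moves the DC bin (index 1) to the centred
## position floor(n/2)+1; ifftshift is its inverse. Valid for any n >= 1.
fftshift_idx <- function(n) ((seq_len(n) - 1 - floor(n / 2)) %% n) + 1
ifftshift_idx <- function(n) ((seq_len(n) - 1 + floor(n / 2)) %% n) + 1

## Batched centred 2D inverse FFT: arr[ng, ng, batch] of centred k-space ->
## centred image space.
batch_ifft2 <- function(arr) {
  d <- dim(arr); ng <- d[1]; batch <- prod(d[-(1:2)])
  dim(arr) <- c(ng, ng, batch)
  arr <- arr[ifftshift_idx(ng), ifftshift_idx(ng), , drop = FALSE]
  m <- stats::mvfft(matrix(arr, ng, ng * batch), inverse = TRUE)
  a2 <- aperm(array(m, c(ng, ng, batch)), c(2, 1, 3))
  m2 <- stats::mvfft(matrix(a2, ng, ng * batch), inverse = TRUE)
  out <- aperm(array(m2, c(ng, ng, batch)), c(2, 1, 3)) / ng^2
  out <- out[fftshift_idx(ng), fftshift_idx(ng), , drop = FALSE]
  dim(out) <- d
  out
}

## Centred 1D inverse FFT along the first dimension (kz -> z).
batch_ifft1 <- function(arr) {
  d <- dim(arr); n <- d[1]
  m <- matrix(arr, n, prod(d[-1]))
  m <- m[ifftshift_idx(n), , drop = FALSE]
  out <- stats::mvfft(m, inverse = TRUE) / n
  out <- out[fftshift_idx(n), , drop = FALSE]
  dim(out) <- d
  out
}

#' Grid spiral k-space data and transform to the image domain
#'
#' The image-formation chain for one or more frames: centred zero-filling
#' along kz, 1D inverse FFT to slices, density compensation, Kaiser-Bessel
#' convolution gridding onto a 1.5x oversampled Cartesian grid, batched 2D
#' inverse FFT, deapodization by the kernel transform and centre cropping.
#'
#' @param raw complex array `[n_read, n_kz, n_fa, n_coil]` (trailing
#'   dimensions may be dropped).
#' @param trajectory a [design_spiral()] result.
#' @param weights density compensation weights (e.g. [voronoi_dcf()]
#'   followed by [apply_hanning()]).
#' @param kz_out number of output slices (centred zero-fill; default 11 for
#'   5 acquired planes, or `n_kz` if larger).
#' @param osf,width gridding oversampling factor and kernel width.
#' @return Complex array `[matrix, matrix, kz_out, n_fa, n_coil]`.
#' @export
grid_and_fft <- function(raw, trajectory, weights, kz_out = NULL, osf = 1.5,
                         width = 4) {
  d <- dim(raw)
  if (is.null(d)) d <- c(length(raw), 1L)
  if (d[1] != length(trajectory$kxy)) {
    stop("readout length ", d[1], " does not match trajectory (",
         length(trajectory$kxy), ")")
  }
  if (length(weights) != d[1]) stop("weights length mismatch")
  n_kz <- if (length(d) >= 2) d[2] else 1L
  batch_dims <- if (length(d) > 2) d[-(1:2)] else 1L
  dim(raw) <- c(d[1], n_kz, prod(batch_dims))
  if (is.null(kz_out)) kz_out <- max(n_kz, if (n_kz == 5) 11L else n_kz)
  if (kz_out < n_kz) stop("kz_out must be >= acquired kz planes")

  ## centred zero-fill along kz, then kz -> z
  zf <- array(0i, c(d[1], kz_out, dim(raw)[3]))
  off <- floor((kz_out - n_kz) / 2)
  zf[, off + seq_len(n_kz), ] <- raw
  zf <- aperm(zf, c(2, 1, 3))
  zf <- batch_ifft1(zf)
  zf <- aperm(zf, c(2, 1, 3))

  op <- grid_operator(trajectory, osf = osf, width = width)
  ng <- op$ng; ms <- op$matrix_size
  S <- matrix(zf * weights, d[1], kz_out * dim(zf)[3])
  dea <- kb_deapod_grid(ng, op$width, op$beta)
  dea2 <- as.vector(outer(dea, dea))
  lo <- ng / 2 + 1 - ms / 2
  sel <- lo:(lo + ms - 1)

  ## frames are processed in chunks to bound the memory of the oversampled
  ## intermediates
  nb <- ncol(S)
  out <- array(0i, c(ms, ms, nb))
  chunk <- max(1L, floor(2^22 / ng^2))
  for (s0 in seq(1, nb, by = chunk)) {
    cols <- s0:min(s0 + chunk - 1, nb)
    K <- as.matrix(op$A %*% Re(S[, cols, drop = FALSE])) +
      1i * as.matrix(op$A %*% Im(S[, cols, drop = FALSE]))
    dim(K) <- c(ng, ng, length(cols))
    img <- batch_ifft2(K) / dea2          # deapodize, recycled per slice
    out[, , cols] <- img[sel, sel, , drop = FALSE]
  }
  array(out, c(ms, ms, kz_out, batch_dims))
}

#' Voxel-domain noise samples from interleaved average subtraction
#'
#' Pairwise differences of consecutive averages, scaled by `1/sqrt(2)`, are
#' pushed through the same gridding chain as the data; the resulting voxel
#' values are pure noise with the receive chain's coil covariance.
#'
#' @param raw complex array `[n_read, n_kz, n_fa, n_coil, n_avg]`.
#' @param trajectory,weights,kz_out,osf,width as in [grid_and_fft()].
#' @param fa_subset indices of FA frames to reconstruct for noise
#'   estimation (default: first `min(50, n_fa)`).
#' @return List: `samples` (complex matrix, voxels*frames x coil) and
#'   `covariance` (coil x coil Hermitian).
#' @export
estimate_noise <- function(raw, trajectory, weights, kz_out = NULL,
                           osf = 1.5, width = 4, fa_subset = NULL) {
  d <- dim(raw)
  if (length(d) != 5) stop("raw must be [read, kz, fa, coil, avg]")
  if (d[5] < 2) stop("at least 2 averages are required for noise estimation")
  if (is.null(fa_subset)) fa_subset <- seq_len(min(50, d[3]))
  n_pairs <- d[5] %/% 2
  samp <- list()
  for (pr in seq_len(n_pairs)) {
    diff <- (raw[, , fa_subset, , 2 * pr, drop = FALSE] -
               raw[, , fa_subset, , 2 * pr - 1, drop = FALSE]) / sqrt(2)
    dim(diff) <- c(d[1], d[2], length(fa_subset), d[4])
    img <- grid_and_fft(diff, trajectory, weights, kz_out = kz_out,
                        osf = osf, width = width)
    di <- dim(img)
    samp[[pr]] <- matrix(img, prod(di[1:4]), di[5])
  }
  X <- do.call(rbind, samp)
  list(samples = X,
       covariance = crossprod(Conj(X), X) / nrow(X))
}

#' Whitened-SVD coil combination
#'
#' Per voxel, the coil-by-frame matrix is whitened by the inverse square
#' root of the coil noise covariance and replaced by its rank-1
#' approximation; the principal temporal component (scaled by the singular
#' value) is returned, with the output phase fixed by making the dominant
#' coil weight real-positive.
#'
#' @param imgs complex array `[nx, ny, nz, n_fa, n_coil]`.
#' @param covariance coil noise covariance (Hermitian positive-definite).
#' @return Complex array `[nx, ny, nz, n_fa]`.
#' @export
wsvd_combine <- function(imgs, covariance) {
  d <- dim(imgs)
  if (length(d) != 5) stop("imgs must be [nx, ny, nz, fa, coil]")
  nc <- d[5]
  if (!all(dim(covariance) == c(nc, nc))) stop("covariance dimension mismatch")
  eg <- eigen((covariance + Conj(t(covariance))) / 2, symmetric = TRUE)
  if (min(eg$values) <= 1e-12 * max(eg$values)) {
    stop("singular coil covariance; regularize (e.g. add a small ridge)")
  }
  W <- eg$vectors %*% diag(1 / sqrt(eg$values), nc) %*% Conj(t(eg$vectors))
  nvox <- prod(d[1:3])
  nfa <- d[4]
  Y <- matrix(imgs, nvox * nfa, nc)
  out <- matrix(0i, nvox, nfa)
  for (v in seq_len(nvox)) {
    idx <- v + nvox * (seq_len(nfa) - 1)
    Yv <- W %*% t(Y[idx, , drop = FALSE])     # coil x fa, whitened
    M <- Yv %*% Conj(t(Yv))
    u1 <- eigen(M, symmetric = TRUE)$vectors[, 1]
    comb <- drop(Conj(t(u1)) %*% Yv)
    jmax <- which.max(Mod(u1))
    out[v, ] <- comb * exp(1i * Arg(u1[jmax]))
  }
  array(out, d[1:4])
}

#' Marchenko-Pastur PCA denoising
#'
#' The frame series is flattened to a (voxels x 2*frames) real matrix (real
#' and imaginary parts concatenated along the frame dimension), the noise
#' bulk of the singular spectrum is identified by the Marchenko-Pastur edge
#' criterion, bulk components are nulled and the series is rebuilt. By
#' default one global spatial block is used; `window` activates an optional
#' sliding-window variant along the voxel dimension.
#'
#' @param imgs complex array `[nx, ny, nz, n_fa]` (or a matrix voxels x fa).
#' @param window optional block length (voxels) for the sliding variant.
#' @return List: `series` (denoised, same shape), `rank` (retained
#'   components), `sigma` (estimated noise SD per real component).
#' @export
mppca_denoise <- function(imgs, window = NULL) {
  d <- dim(imgs)
  mat <- if (length(d) > 2) matrix(imgs, prod(d[-length(d)]), d[length(d)])
  else as.matrix(imgs)
  if (nrow(mat) < 2) stop("MP-PCA needs at least 2 voxels")
  if (is.null(window)) {
    res <- mppca_block(mat)
  } else {
    res <- mat * 0
    rk <- 0; sg <- 0
    starts <- seq(1, nrow(mat), by = window)
    for (s in starts) {
      e <- min(s + window - 1, nrow(mat))
      blk <- mppca_block(mat[s:e, , drop = FALSE])
      res[s:e, ] <- blk$series
      rk <- max(rk, blk$rank); sg <- max(sg, blk$sigma)
    }
    res <- list(series = res, rank = rk, sigma = sg)
  }
  out <- res$series
  if (length(d) > 2) dim(out) <- d
  list(series = out, rank = res$rank, sigma = res$sigma)
}

mppca_block <- function(mat) {
  X <- cbind(Re(mat), Im(mat))
  M <- nrow(X); N <- ncol(X)
  sv <- svd(X)
  R <- length(sv$d)
  O <- max(M, N)
  lam <- sv$d^2 / O
  p <- R
  for (q in 0:(R - 1)) {
    tail <- lam[(q + 1):R]
    gam <- (R - q) / O
    if (lam[q + 1] - lam[R] <= 4 * sqrt(gam) * mean(tail)) {
      p <- q
      break
    }
  }
  sigma <- if (p < R) sqrt(mean(lam[(p + 1):R])) else 0
  Xd <- if (p == 0) X * 0 else
    sv$u[, 1:p, drop = FALSE] %*% (sv$d[1:p] * t(sv$v[, 1:p, drop = FALSE]))
  half <- ncol(mat)
  series <- Xd[, 1:half, drop = FALSE] +
    1i * Xd[, (half + 1):(2 * half), drop = FALSE]
  list(series = series, rank = p, sigma = sigma)
}

#' Full reconstruction chain for a raw CKI acquisition
#'
#' Average combination, gridding to image space, whitened-SVD coil
#' combination (noise covariance from interleaved average subtraction when
#' at least two averages are present) and optional MP-PCA denoising; also
#' emits the bSSFP-type PCr and ATP magnitude images (mean |signal| over the
#' respective FA indices).
#'
#' @param raw a `cki_raw` object (see [forward_simulate()]) or a complex
#'   array `[read, kz, fa, coil, avg]`.
#' @param trajectory trajectory; taken from `raw` if absent.
#' @param schedule the acquisition schedule (for the PCr/ATP FA labels).
#' @param weights optional DCF weights; computed by [voronoi_dcf()] if
#'   missing.
#' @param hanning apply the radial half-period Hann taper to the DCF.
#' @param denoise apply MP-PCA.
#' @param coil_cov optional coil covariance; estimated from the averages
#'   when possible, identity otherwise.
#' @param kz_out,osf,width gridding options, see [grid_and_fft()].
#' @param noise_fa_subset FA frames used for noise estimation.
#' @return Object of class `cki_images`: `series` `[nx,ny,nz,fa]`,
#'   `pcr_image`, `atp_image`, `coil_images`, `coil_cov`, `mp` (MP-PCA
#'   diagnostics), `meta`.
#' @export
reconstruct <- function(raw, trajectory = NULL, schedule = NULL,
                        weights = NULL, hanning = TRUE, denoise = TRUE,
                        coil_cov = NULL, kz_out = NULL, osf = 1.5, width = 4,
                        noise_fa_subset = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("reconstruction stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (inherits(raw, "cki_raw")) {
    if (is.null(trajectory)) trajectory <- raw$trajectory
    tensor <- raw$tensor
  } else tensor <- raw
  if (is.null(trajectory)) stop("trajectory required")
  d <- dim(tensor)
  if (length(d) == 4) { dim(tensor) <- c(d, 1L); d <- dim(tensor) }
  if (length(d) != 5) stop("raw tensor must be [read, kz, fa, coil, avg]")

  if (is.null(weights)) {
    weights <- stage("dcf", {
      w <- voronoi_dcf(trajectory)
      if (hanning) w <- apply_hanning(w, trajectory)
      w
    })
  }
  avg <- stage("average", {
    a <- tensor[, , , , 1, drop = FALSE]
    if (d[5] > 1) {
      a[] <- 0
      for (i in seq_len(d[5])) a <- a + tensor[, , , , i, drop = FALSE] / d[5]
    }
    array(a, d[1:4])
  })
  coil_imgs <- stage("gridding", {
    grid_and_fft(avg, trajectory, weights, kz_out = kz_out, osf = osf,
                 width = width)
  })
  if (is.null(coil_cov)) {
    coil_cov <- if (d[5] >= 2) {
      stage("noise", {
        estimate_noise(tensor, trajectory, weights, kz_out = kz_out,
                       osf = osf, width = width,
                       fa_subset = noise_fa_subset)$covariance
      })
    } else diag(d[4])
  }
  series <- stage("wsvd", wsvd_combine(coil_imgs, coil_cov))
  mp <- NULL
  if (denoise) {
    mp <- stage("mppca", mppca_denoise(series))
    series <- mp$series
    mp$series <- NULL
  }
  pcr_image <- atp_image <- NULL
  if (!is.null(schedule)) {
    tg <- schedule$excitations$target
    pcr_image <- apply(abs(series[, , , tg == "PCr", drop = FALSE]), 1:3,
                       mean)
    atp_image <- apply(abs(series[, , , tg == "ATP", drop = FALSE]), 1:3,
                       mean)
  }
  structure(list(series = series, pcr_image = pcr_image,
                 atp_image = atp_image, coil_images = coil_imgs,
                 coil_cov = coil_cov, mp = mp,
                 meta = list(hanning = hanning, denoise = denoise,
                             osf = osf, width = width)),
            class = "cki_images")
}

#' @export
print.cki_images <- function(x, ...) {
  d <- dim(x$series)
  cat("CKI image series:", paste(d, collapse = " x "),
      if (!is.null(x$mp)) sprintf("(MP-PCA rank %d)", x$mp$rank), "\n")
  invisible(x)
}
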