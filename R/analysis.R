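#' Fit-based SNR in decibels
#'
#' Ratio of signal power to noise power: the matched dictionary entry,
#' scaled to the measured vector by least squares, is the signal; the
#' residual of the scaled fit and the measurement is the noise
#' approximation. `10 * log10(sum|fit|^2 / sum|measured - fit|^2)`.
#'
#' @param measured measured (conditioned) vector.
#' @param atom matched dictionary atom (unit norm or not).
#' @return SNR in dB; `Inf` for a zero residual, `-Inf` for a zero fit.
#' @export
snr_db <- function(measured, atom) {
  if (inherits(measured, "cki_atom")) measured <- measured$vector
  if (inherits(atom, "cki_atom")) atom <- atom$vector
  if (length(measured) != length(atom)) stop("length mismatch")
  aa <- sum(Mod(atom)^2)
  if (aa == 0) return(-Inf)
  scale <- sum(Conj(atom) * measured) / aa
  fit <- scale * atom
  p_fit <- sum(Mod(fit)^2)
  p_res <- sum(Mod(measured - fit)^2)
  if (p_fit == 0) return(-Inf)
  if (p_res == 0) return(Inf)
  10 * log10(p_fit / p_res)
}

#' Coefficient of variation
#'
#' Population standard deviation divided by the mean:
#' `sqrt(E[(X - E[X])^2]) / E[X]`.
#'
#' @param values numeric vector (at least 2 values, nonzero mean).
#' @return Unitless CV.
#' @export
cv <- function(values) {
  if (length(values) < 2) stop("cv needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("cv undefined for zero mean")
  sqrt(mean((values - m)^2)) / m
}

#' Match a reconstructed image series voxel by voxel
#'
#' Conditions each voxel's complex evolution and matches it against the
#' dictionary; voxels whose evolution is identically zero (or outside the
#' mask) are skipped.
#'
#' @param images a [reconstruct()] result (or a complex array
#'   `[nx, ny, nz, n_fa]`).
#' @param dictionary a [generate_dictionary()] result.
#' @param schedule a [build_schedule()] result (for the PCr/ATP layout).
#' @param mask optional logical/index array selecting voxels.
#' @param constraints passed to [match_fingerprint()].
#' @return Object of class `cki_maps`: list of 3D arrays `k_ck`, `cr`,
#'   `t1_pcr`, `delta_b0`, `score`, `snr_db` (NA outside the mask) plus the
#'   match tibble and `mask`.
#' @export
match_images <- function(images, dictionary, schedule, mask = NULL,
                         constraints = NULL) {
  series <- if (inherits(images, "cki_images")) images$series else images
  d <- dim(series)
  nvox <- prod(d[1:3])
  S <- matrix(series, nvox, d[4])
  if (is.null(mask)) {
    mask <- which(rowSums(Mod(S)) > 0)
  } else if (is.logical(mask)) mask <- which(as.vector(mask))
  if (!length(mask)) stop("empty mask")
  target <- schedule$excitations$target
  V <- vapply(mask, function(v) condition_signal(S[v, ], target)$vector,
              numeric(2 * sum(target == "PCr") + sum(target == "ATP")))
  if (!is.null(constraints)) {
    constraints <- lapply(constraints, function(x) {
      if (length(x) == nvox) x[mask] else x
    })
  }
  fit <- match_fingerprint(V, dictionary, constraints = constraints)
  maps <- list()
  for (nm in c("k_ck", "cr", "t1_pcr", "delta_b0", "score")) {
    m <- array(NA_real_, d[1:3])
    m[mask] <- fit[[nm]]
    maps[[nm]] <- m
  }
  snr <- array(NA_real_, d[1:3])
  snr[mask] <- vapply(seq_along(mask), function(i) {
    snr_db(V[, i], dictionary$atoms[fit$atom[i], ])
  }, 0)
  maps$snr_db <- snr
  structure(list(maps = maps, fit = fit, mask = mask, dim = d[1:3]),
            class = "cki_maps")
}

#' @export
print.cki_maps <- function(x, ...) {
  cat("CKI parameter maps:", paste(x$dim, collapse = " x "), "voxels,",
      length(x$mask), "matched\n")
  invisible(x)
}

#' ROI summary table of parameter maps
#'
#' Mean and SD per labelled region per parameter, in the shape of the
#' in-vivo summary tables.
#'
#' @param maps a [match_images()] result, or a named list of 3D arrays.
#' @param labels integer array of region labels (0 = outside).
#' @param label_names optional names for the labels (named by level).
#' @return Tibble: `roi`, `parameter`, `mean`, `sd`, `n_voxels`.
#' @export
roi_summary <- function(maps, labels, label_names = NULL) {
  m <- if (inherits(maps, "cki_maps")) maps$maps else maps
  lev <- sort(unique(as.vector(labels)))
  lev <- lev[lev != 0]
  out <- list()
  for (lv in lev) {
    idx <- which(labels == lv)
    nm <- if (!is.null(label_names) && as.character(lv) %in% names(label_names))
      label_names[[as.character(lv)]] else as.character(lv)
    for (par in names(m)) {
      vals <- m[[par]][idx]
      vals <- vals[is.finite(vals)]
      if (!length(vals)) {
        warning("empty label ", nm, " for ", par, "; skipped")
        next
      }
      out[[length(out) + 1]] <- tibble::tibble(
        roi = nm, parameter = par, mean = mean(vals), sd = stats::sd(vals),
        n_voxels = length(vals))
    }
  }
  do.call(rbind, out)
}

#' Split-half reproducibility of the full pipeline
#'
#' Splits the averages into two interleaved halves, reconstructs and
#' matches each half independently, and reports the voxelwise CV (over the
#' two estimates) per parameter, plus an ROI summary when labels are given.
#'
#' @param raw a `cki_raw` object with an even number of averages.
#' @param dictionary,schedule matching inputs.
#' @param labels optional label array for the ROI table.
#' @param mask optional voxel mask (defaults to voxels matched in both
#'   halves).
#' @param ... forwarded to [reconstruct()].
#' @return List: `cv_maps` (per parameter), `roi_table` (or NULL), and the
#'   two half `cki_maps`.
#' @export
split_half_cv <- function(raw, dictionary, schedule, labels = NULL,
                          mask = NULL, ...) {
  d <- dim(raw$tensor)
  if (d[5] %% 2 != 0) stop("split-half CV needs an even number of averages")
  halves <- list(seq(1, d[5], by = 2), seq(2, d[5], by = 2))
  fits <- lapply(halves, function(av) {
    sub <- raw
    sub$tensor <- raw$tensor[, , , , av, drop = FALSE]
    img <- reconstruct(sub, schedule = schedule, ...)
    match_images(img, dictionary, schedule, mask = mask)
  })
  cv_maps <- list()
  for (par in c("k_ck", "cr", "t1_pcr")) {
    a <- fits[[1]]$maps[[par]]
    b <- fits[[2]]$maps[[par]]
    m <- array(NA_real_, dim(a))
    ok <- is.finite(a) & is.finite(b) & (a + b) != 0
    m[ok] <- abs(a[ok] - b[ok]) / (a[ok] + b[ok])
    cv_maps[[par]] <- m
  }
  roi_table <- if (!is.null(labels)) roi_summary(cv_maps, labels) else NULL
  list(cv_maps = cv_maps, roi_table = roi_table, half1 = fits[[1]],
       half2 = fits[[2]])
}

#' Functional CKI percent-difference map
#'
#' The functional estimation mode: (1) the combined dataset (average of the
#' REST and STIM reconstructions) is matched over the full grid to fix
#' per-voxel B0 and Cr; (2) REST and STIM are re-matched with T1 of PCr
#' fixed at 4.5 s and (B0, Cr) pinned to the combined estimates; (3) the
#' map `DIFF = 100 * (kCK_STIM - kCK_REST) / kCK_REST` is formed. Voxels
#' with zero REST kCK are masked.
#'
#' @param rest_raw,stim_raw `cki_raw` objects for the two conditions.
#' @param dictionary,schedule matching inputs.
#' @param mask optional voxel mask.
#' @param t1_fixed fixed T1 of PCr for the functional rematch (s).
#' @param ... forwarded to [reconstruct()].
#' @return List: `diff` (percent map), `rest`, `stim`, `combined`
#'   (`cki_maps`), `mask`.
#' @export
fcki_map <- function(rest_raw, stim_raw, dictionary, schedule, mask = NULL,
                     t1_fixed = 4.5, ...) {
  img_rest <- reconstruct(rest_raw, schedule = schedule, ...)
  img_rest$coil_images <- NULL
  img_stim <- reconstruct(stim_raw, schedule = schedule, ...)
  img_stim$coil_images <- NULL
  comb <- img_rest$series / 2 + img_stim$series / 2
  fit_comb <- match_images(comb, dictionary, schedule, mask = mask)
  pin <- list(t1_pcr = t1_fixed,
              delta_b0 = fit_comb$fit$delta_b0,
              cr = fit_comb$fit$cr)
  fit_rest <- match_images(img_rest, dictionary, schedule,
                           mask = fit_comb$mask, constraints = pin)
  fit_stim <- match_images(img_stim, dictionary, schedule,
                           mask = fit_comb$mask, constraints = pin)
  kr <- fit_rest$maps$k_ck
  ks <- fit_stim$maps$k_ck
  diff <- array(NA_real_, dim(kr))
  ok <- is.finite(kr) & is.finite(ks) & kr != 0
  diff[ok] <- 100 * (ks[ok] - kr[ok]) / kr[ok]
  list(diff = diff, rest = fit_rest, stim = fit_stim, combined = fit_comb,
       mask = fit_comb$mask)
}

#' Detect supra-threshold activation clusters
#'
#' Connected components (6-connectivity in 3D by default, 26 optionally) of
#' voxels whose percent change meets the threshold; components smaller than
#' the minimum size are dropped.
#'
#' @param diff percent-difference map (3D array; NA = outside mask).
#' @param threshold percent-change threshold (default 10).
#' @param min_size minimum cluster size in voxels (default 20).
#' @param connectivity 6 or 26.
#' @return Object of class `cki_clusters`: `clusters` tibble (`cluster`,
#'   `size`, `mean_change`), `label_map` (3D integer array), and the
#'   thresholds used.
#' @export
detect_clusters <- function(diff, threshold = 10, min_size = 20,
                            connectivity = 6) {
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  d <- dim(diff)
  if (length(d) != 3) stop("diff must be a 3D array")
  supra <- !is.na(diff) & diff >= threshold
  lab <- array(0L, d)
  nb <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1, -1:1))[-14, ]
  }
  nxt <- 0L
  rows <- which(supra, arr.ind = TRUE)
  idx_of <- function(m) m[, 1] + (m[, 2] - 1) * d[1] +
    (m[, 3] - 1) * d[1] * d[2]
  for (s in seq_len(nrow(rows))) {
    start <- rows[s, , drop = FALSE]
    if (lab[idx_of(start)] != 0L) next
    nxt <- nxt + 1L
    frontier <- start
    lab[idx_of(start)] <- nxt
    while (nrow(frontier)) {
      cand <- do.call(rbind, lapply(seq_len(nrow(nb)), function(k) {
        sweep(frontier, 2, nb[k, ], "+")
      }))
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      ci <- idx_of(cand)
      keep <- supra[ci] & lab[ci] == 0L
      cand <- unique(cand[keep, , drop = FALSE])
      if (nrow(cand)) lab[idx_of(cand)] <- nxt
      frontier <- cand
    }
  }
  sizes <- tabulate(lab[lab > 0L], nbins = nxt)
  keep <- which(sizes >= min_size)
  out <- array(0L, d)
  rows_tab <- list()
  for (i in seq_along(keep)) {
    vox <- which(lab == keep[i])
    out[vox] <- i
    rows_tab[[i]] <- tibble::tibble(cluster = i, size = length(vox),
                                    mean_change = mean(diff[vox]))
  }
  clusters <- if (length(rows_tab)) do.call(rbind, rows_tab) else
    tibble::tibble(cluster = integer(), size = integer(),
                   mean_change = numeric())
  structure(list(clusters = clusters, label_map = out,
                 threshold = threshold, min_size = min_size,
                 connectivity = connectivity),
            class = "cki_clusters")
}

#' @export
print.cki_clusters <- function(x, ...) {
  cat("CKI activation clusters (>=", x$threshold, "%, size >=", x$min_size,
      ",", x$connectivity, "-connectivity):", nrow(x$clusters), "found\n")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Robustness experiment suite
#'
#' Reproduces the simulation-based robustness analyses as one seeded run:
#' (a) Monte-Carlo matching precision over an SNR sweep, (b) the ±25%
#' fixed-parameter bias grid (T1 of ATP, T2 of PCr, T2 of ATP altered in
#' the simulated truth while the dictionary keeps nominal values), (c) the
#' three-pool ATP-synthase bias sweep matched against the two-pool
#' dictionary, and (d) the bSSFP contamination scan of the non-targeted
#' metabolite.
#'
#' @param dictionary a [generate_dictionary()] result (used by a, b, c).
#' @param schedule a [build_schedule()] result.
#' @param seed RNG seed (Monte-Carlo only; the rest is deterministic).
#' @param true_params in-vivo-like reference tuple.
#' @param snr_db_levels SNR sweep for the Monte-Carlo study (dB).
#' @param n_reps Monte-Carlo repetitions per level.
#' @param k_atp_range ATP-synthase forward-rate sweep (1/s).
#' @param flips_deg flip angles for the contamination scan.
#' @return List of class `cki_robustness` with elements `monte_carlo`
#'   (tibble), `fixed_param_bias` (tibble), `three_pool_bias` (tibble),
#'   `contamination` (tibble), and `summary` (named numbers: the four
#'   headline percentages).
#' @export
robustness_suite <- function(dictionary, schedule, seed = 1,
                             true_params = spin_params(0.3, 1.25, 4.5, 0),
                             snr_db_levels = c(20, 14, 8),
                             n_reps = 200,
                             k_atp_range = seq(0.05, 0.30, by = 0.05),
                             flips_deg = 1:35) {
  mc <- monte_carlo_robustness(true_params, dictionary, schedule,
                               snr_db_levels = snr_db_levels,
                               n_reps = n_reps, seed = seed)

  fixed_bias <- fixed_param_bias(dictionary, schedule, true_params)
  three_pool <- three_pool_bias(dictionary, schedule, true_params,
                                k_atp_range)
  contam <- contamination_scan(flips_deg, schedule$config)

  mc8 <- mc[mc$snr_db == min(snr_db_levels), ]
  summary <- c(
    mc_sd_k_ck_pct = 100 * mc8$sd_rel_error[mc8$parameter == "k_ck"],
    mc_sd_cr_pct = 100 * mc8$sd_rel_error[mc8$parameter == "cr"],
    mc_sd_t1_pcr_pct = 100 * mc8$sd_rel_error[mc8$parameter == "t1_pcr"],
    max_fixed_param_bias_pct = 100 * max(abs(fixed_bias$rel_error_k_ck)),
    max_three_pool_bias_pct = 100 * max(three_pool$rel_error_k_ck),
    max_contamination_pct = 100 * max(contam$ratio, na.rm = TRUE))
  structure(list(monte_carlo = mc, fixed_param_bias = fixed_bias,
                 three_pool_bias = three_pool, contamination = contam,
                 summary = summary),
            class = "cki_robustness")
}

#' @export
print.cki_robustness <- function(x, ...) {
  cat("CKI robustness suite:\n")
  for (nm in names(x$summary)) {
    cat(sprintf("  %-26s %8.3f\n", nm, x$summary[[nm]]))
  }
  invisible(x)
}

#' Bias from ±25% errors in the fixed model parameters
#'
#' Simulates noiseless truth with each fixed parameter (T1 ATP, T2 PCr,
#' T2 ATP) at 0.75x and 1.25x its nominal value, matches against the
#' nominal-assumption dictionary, and reports the relative kCK error.
#'
#' @inheritParams robustness_suite
#' @return Tibble: `parameter`, `factor`, `k_ck_hat`, `rel_error_k_ck`.
#' @export
fixed_param_bias <- function(dictionary, schedule,
                             true_params = spin_params(0.3, 1.25, 4.5, 0)) {
  nominal <- list(t1_atp = 1, t2_pcr = 0.135, t2_atp = 0.025)
  out <- list()
  for (par in names(nominal)) {
    for (f in c(0.75, 1.25)) {
      args <- list(k_ck = true_params$k_ck, cr = true_params$cr,
                   t1_pcr = true_params$t1_pcr,
                   delta_b0 = true_params$delta_b0)
      args[[par]] <- nominal[[par]] * f
      p <- do.call(spin_params, args)
      v <- condition_signal(simulate_evolution(p, schedule))$vector
      fit <- match_fingerprint(v, dictionary)
      out[[length(out) + 1]] <- tibble::tibble(
        parameter = par, factor = f, k_ck_hat = fit$k_ck,
        rel_error_k_ck = (fit$k_ck - true_params$k_ck) / true_params$k_ck)
    }
  }
  do.call(rbind, out)
}

#' kCK overestimation from the neglected ATP-synthase exchange
#'
#' Simulates noiseless three-pool (PCr, gamma-ATP, Pi) evolutions with the
#' forward Pi -> ATP rate swept over the configured in-vivo range and
#' matches them against the two-pool dictionary.
#'
#' @inheritParams robustness_suite
#' @param ... forwarded to [spin_params3()] (Pi pool configuration).
#' @return Tibble: `k_atp`, `k_ck_hat`, `rel_error_k_ck`.
#' @export
three_pool_bias <- function(dictionary, schedule,
                            true_params = spin_params(0.3, 1.25, 4.5, 0),
                            k_atp_range = seq(0.05, 0.30, by = 0.05), ...) {
  out <- list()
  for (ka in k_atp_range) {
    p3 <- spin_params3(true_params$k_ck, true_params$cr,
                       true_params$t1_pcr, true_params$delta_b0,
                       k_atp = ka, ...)
    v <- condition_signal(simulate_three_pool(p3, schedule))$vector
    fit <- match_fingerprint(v, dictionary)
    out[[length(out) + 1]] <- tibble::tibble(
      k_atp = ka, k_ck_hat = fit$k_ck,
      rel_error_k_ck = (fit$k_ck - true_params$k_ck) / true_params$k_ck)
  }
  do.call(rbind, out)
}

#' Dice overlap of a cluster with a reference ROI
#'
#' @param cluster_voxels logical array or voxel indices of the detected
#'   cluster.
#' @param roi_voxels logical array or voxel indices of the reference ROI.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(cluster_voxels, roi_voxels) {
  a <- if (is.logical(cluster_voxels)) which(cluster_voxels) else
    cluster_voxels
  b <- if (is.logical(roi_voxels)) which(roi_voxels) else roi_voxels
  if (!length(a) && !length(b)) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
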