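test_that("SNR follows the fit/residual power-ratio definition", {
  a <- c(1, 0, 0, 0)
  ## exact match: infinite SNR
  expect_equal(snr_db(a * 3, a), Inf)
  ## residual power equal to fit power: 0 dB
  expect_equal(snr_db(c(1, 1, 0, 0), a), 0)
  ## fit power 10x residual power: exactly 10 dB
  expect_equal(snr_db(c(1, sqrt(0.1), 0, 0), a), 10)
  expect_equal(snr_db(c(0, 1, 0, 0), a), -Inf)
  ## least-squares scaling makes the result scale-invariant in the atom
  expect_equal(snr_db(c(1, 0.5, 0, 0), a * 7),
               snr_db(c(1, 0.5, 0, 0), a))
})

test_that("coefficient of variation follows the population formula", {
  expect_equal(cv(c(1, 1, 1)), 0)
  expect_equal(cv(c(0.9, 1.1)), 0.1)
  expect_equal(cv(c(4, 6)), 0.2)
  ## scale invariance
  x <- c(2.3, 3.1, 2.8, 2.2)
  expect_equal(cv(10 * x), cv(x))
  expect_error(cv(1), "at least 2")
  expect_error(cv(c(-1, 1)), "zero mean")
})

test_that("ROI summary is exact on constants and permutation-invariant", {
  labels <- array(rep(1:2, each = 12), c(4, 3, 2))
  maps <- list(k_ck = array(0.3, c(4, 3, 2)))
  tab <- roi_summary(maps, labels)
  expect_equal(tab$mean, c(0.3, 0.3))
  expect_equal(tab$sd, c(0, 0))
  expect_equal(tab$n_voxels, c(12, 12))
  ## permuting voxels within a label leaves the summary unchanged
  set.seed(2)
  m <- array(rnorm(24, 1), c(4, 3, 2))
  t1 <- roi_summary(list(v = m), labels)
  m2 <- m
  i1 <- which(labels == 1)
  m2[i1] <- m[sample(i1)]
  t2 <- roi_summary(list(v = m2), labels)
  expect_equal(t1$mean, t2$mean, tolerance = 1e-12)
  expect_equal(t1$sd, t2$sd, tolerance = 1e-12)
  ## phantom GM label on the ground-truth map recovers the tissue mean
  ph <- make_phantom(seed = 6)
  tab3 <- roi_summary(list(k_ck = ph$maps$k_ck), ph$labels,
                      label_names = c("1" = "GM", "2" = "WM", "3" = "CSF"))
  gm <- tab3[tab3$roi == "GM" & tab3$parameter == "k_ck", ]
  expect_equal(gm$mean, 0.30, tolerance = 0.01)
  expect_warning(roi_summary(list(a = array(NA_real_, c(2, 2, 2))),
                             array(1L, c(2, 2, 2))), "empty label")
})

test_that("cluster detection applies the threshold and size rules", {
  d <- c(12, 12, 6)
  m <- array(0, d)
  ## all-zero map: empty report
  expect_equal(nrow(detect_clusters(m)$clusters), 0)
  ## a single 19-voxel supra-threshold blob is dropped by the size rule
  m1 <- array(0, d)
  m1[1:19] <- 12
  expect_equal(nrow(detect_clusters(m1, min_size = 20)$clusters), 0)
  expect_equal(nrow(detect_clusters(m1, min_size = 19)$clusters), 1)
  ## two disjoint 25-voxel blobs at +12%: two clusters of size 25
  m2 <- array(0, d)
  m2[1:5, 1:5, 1] <- 12
  m2[6:10, 6:10, 6] <- 12
  rep2 <- detect_clusters(m2, threshold = 10, min_size = 20)
  expect_equal(nrow(rep2$clusters), 2)
  expect_equal(rep2$clusters$size, c(25, 25))
  expect_equal(rep2$clusters$mean_change, c(12, 12))
  ## sub-threshold voxels never join a cluster
  m2[3, 3, 2] <- 9.9
  rep3 <- detect_clusters(m2, threshold = 10, min_size = 20)
  expect_equal(sum(rep3$label_map > 0), 50)
})

test_that("cluster labelling equals the brute-force flood-fill oracle", {
  set.seed(77)
  for (conn in c(6, 26)) {
    for (rep in 1:5) {
      d <- c(10, 9, 7)
      m <- array(stats::runif(prod(d), 0, 20), d)
      m[sample(prod(d), 200)] <- NA
      got <- detect_clusters(m, threshold = 10, min_size = 1,
                             connectivity = conn)
      supra <- !is.na(m) & m >= 10
      want <- oracle_flood_fill(supra, conn)
      expect_equal(label_sizes(got$label_map), label_sizes(want))
      ## identical partitions, not just identical size multisets
      agree <- tapply(want[supra], got$label_map[supra],
                      function(v) length(unique(v)))
      expect_true(all(agree == 1))
    }
  }
  ## diagonal-only contact merges under 26- but not 6-connectivity
  m <- array(0, c(4, 4, 4))
  m[1, 1, 1] <- 15; m[2, 2, 2] <- 15
  expect_equal(nrow(detect_clusters(m, min_size = 1,
                                    connectivity = 6)$clusters), 2)
  expect_equal(nrow(detect_clusters(m, min_size = 1,
                                    connectivity = 26)$clusters), 1)
})

test_that("functional difference map is zero for identical conditions and
          recovers an injected activation", {
  su <- small_setup_noiseless()
  d <- fcki_dictionary()
  ## STIM = REST: DIFF = 0 everywhere
  res0 <- fcki_map(su$raw, su$raw, d, su$sch, hanning = FALSE,
                   denoise = FALSE, kz_out = 5,
                   coil_cov = su$coils$covariance)
  expect_equal(max(abs(res0$diff), na.rm = TRUE), 0)

  ## zero-jitter phantom with a 15% occipital increase, noiseless
  ph0 <- make_phantom(seed = 11, nx = 16, ny = 16, nz = 5,
                      jitter = list(k_ck = 0, cr = 0, t1_pcr = 0),
                      b0_amplitude = 0)
  su_r <- small_setup(phantom = ph0)
  su_s <- small_setup(phantom = inject_activation(ph0, "occipital", 0.15))
  res <- fcki_map(su_r$raw, su_s$raw, d, su_r$sch, hanning = FALSE,
                  denoise = FALSE, kz_out = 5,
                  coil_cov = su_r$coils$covariance)
  roi <- which(ph0$roi$occipital)
  expect_equal(mean(res$diff[roi], na.rm = TRUE), 15, tolerance = 0.25)
  ## outside the activated ROI the map stays near zero
  rest_gm <- which(ph0$labels == 2L)
  expect_lt(abs(mean(res$diff[rest_gm], na.rm = TRUE)), 3)
  ## antisymmetry up to the denominator convention
  res_swap <- fcki_map(su_s$raw, su_r$raw, d, su_r$sch, hanning = FALSE,
                       denoise = FALSE, kz_out = 5,
                       coil_cov = su_r$coils$covariance)
  kr <- res$rest$maps$k_ck; ks <- res$stim$maps$k_ck
  ok <- which(is.finite(res$diff) & is.finite(res_swap$diff) & ks != 0)
  expect_equal(res_swap$diff[ok], -res$diff[ok] * kr[ok] / ks[ok],
               tolerance = 1e-8)
})

test_that("split-half CV is zero for duplicated data and swap-symmetric", {
  su <- small_setup_noiseless()   # two identical noiseless averages
  d <- fcki_dictionary()
  sh <- split_half_cv(su$raw, d, su$sch, labels = su$ph$labels,
                      hanning = FALSE, denoise = FALSE, kz_out = 5,
                      coil_cov = su$coils$covariance)
  expect_equal(max(sh$cv_maps$k_ck, na.rm = TRUE), 0)
  expect_equal(max(sh$cv_maps$t1_pcr, na.rm = TRUE), 0)
  expect_true(all(sh$roi_table$mean == 0))
  ## swapping the halves leaves the CV unchanged
  swp <- su$raw
  swp$tensor <- su$raw$tensor[, , , , c(2, 1), drop = FALSE]
  sh2 <- split_half_cv(swp, d, su$sch, hanning = FALSE, denoise = FALSE,
                       kz_out = 5, coil_cov = su$coils$covariance)
  expect_equal(sh2$cv_maps$k_ck, sh$cv_maps$k_ck)
  odd <- su$raw
  odd$tensor <- su$raw$tensor[, , , , 1, drop = FALSE]
  expect_error(split_half_cv(odd, d, su$sch), "even number")
})

test_that("robustness experiment tables are deterministic under a seed", {
  sch <- full_schedule()
  g <- param_grid(k_ck = seq(0.2, 0.4, by = 0.02), cr = c(1.2, 1.25, 1.3),
                  t1_pcr = c(4.25, 4.5, 4.75), delta_b0 = 0)
  d <- generate_dictionary(g, sch)
  r1 <- robustness_suite(d, sch, seed = 5, snr_db_levels = 14, n_reps = 20,
                         k_atp_range = c(0.1, 0.3), flips_deg = c(10, 35))
  r2 <- robustness_suite(d, sch, seed = 5, snr_db_levels = 14, n_reps = 20,
                         k_atp_range = c(0.1, 0.3), flips_deg = c(10, 35))
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$monte_carlo, r2$monte_carlo)
  ## deterministic components do not depend on the seed
  r3 <- robustness_suite(d, sch, seed = 99, snr_db_levels = 14, n_reps = 20,
                         k_atp_range = c(0.1, 0.3), flips_deg = c(10, 35))
  expect_identical(r1$fixed_param_bias, r3$fixed_param_bias)
  expect_identical(r1$three_pool_bias, r3$three_pool_bias)
  expect_identical(r1$contamination, r3$contamination)
})

test_that("Dice overlap behaves at its extremes", {
  a <- array(FALSE, c(3, 3, 3)); a[1:5] <- TRUE
  expect_equal(dice_overlap(a, a), 1)
  b <- array(FALSE, c(3, 3, 3)); b[10:14] <- TRUE
  expect_equal(dice_overlap(a, b), 0)
  expect_equal(dice_overlap(which(a), c(which(a)[1:3], 20:21)), 0.6)
})
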