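# Quantization, first-order and shape features: hand-computed examples,
# closed-form oracles and the bank-wide invariants.

test_that("quantize covers the contract cases", {
  m <- make_mask(c(4, 4, 4), spacing = c(1, 1, 1))
  # constant VOI -> all level 1
  q0 <- quantize(make_volume(array(40, c(4, 4, 4)), spacing = c(1, 1, 1)), m, 16L)
  expect_true(all(q0$levels == 1L))
  # identity binning: HU 0..63 with 64 bins -> level = HU + 1
  v <- make_volume(array(0:63, c(4, 4, 4)), spacing = c(1, 1, 1))
  q <- quantize(v, m, 64L)
  expect_identical(as.vector(q$levels), as.integer(0:63 + 1L))
  # max HU lands in the top bin
  expect_identical(max(q$levels), 64L)
  expect_error(quantize(v, m, 1L), "n_bins")
})

test_that("first-order features match hand calculations", {
  m <- make_mask(c(4, 4, 4), spacing = c(1, 1, 1))
  fo_const <- intensity_features(
    make_volume(array(50, c(4, 4, 4)), spacing = c(1, 1, 1)), m)
  expect_length(fo_const, 24L)
  expect_equal(unname(fo_const["fo_mean"]), 50)
  expect_equal(unname(fo_const["fo_variance"]), 0)
  expect_equal(unname(fo_const["fo_entropy"]), 0)
  expect_equal(unname(fo_const["fo_uniformity"]), 1)
  expect_equal(unname(fo_const["fo_skewness"]), 0)

  # two-voxel VOI {0, 10}: population convention
  lab <- array(0L, c(3, 3, 3)); lab[1:2, 1, 1] <- 1L
  hu <- array(0, c(3, 3, 3)); hu[2, 1, 1] <- 10
  fo <- intensity_features(ct_volume(hu, c(1, 1, 5)), roi_mask(lab, c(1, 1, 5)))
  expect_equal(unname(fo["fo_mean"]), 5)
  expect_equal(unname(fo["fo_range"]), 10)
  expect_equal(unname(fo["fo_variance"]), 25)    # population: ((5)^2+(5)^2)/2
  expect_equal(unname(fo["fo_sd"]), 5)
  expect_equal(unname(fo["fo_energy"]), 100)
  expect_equal(unname(fo["fo_total_energy"]), 500)

  # symmetric histogram -> skewness 0
  hu2 <- array(rep(c(-3, -1, 1, 3), 16), c(4, 4, 4))
  fo2 <- intensity_features(make_volume(hu2, spacing = c(1, 1, 1)), m)
  expect_equal(unname(fo2["fo_skewness"]), 0, tolerance = 1e-9)
})

test_that("intensity shift covariance: +c shifts location stats exactly", {
  set.seed(8)
  hu <- array(rnorm(64, 40, 20), c(4, 4, 4))
  m <- make_mask(c(4, 4, 4), spacing = c(1, 1, 1))
  f0 <- intensity_features(make_volume(hu, spacing = c(1, 1, 1)), m)
  f1 <- intensity_features(make_volume(hu + 25, spacing = c(1, 1, 1)), m)
  for (nm in c("fo_mean", "fo_median", "fo_minimum", "fo_maximum",
               "fo_p10", "fo_p90"))
    expect_equal(unname(f1[nm] - f0[nm]), 25, tolerance = 1e-9)
  for (nm in c("fo_variance", "fo_sd", "fo_range", "fo_iqr", "fo_entropy",
               "fo_uniformity"))
    expect_equal(unname(f1[nm]), unname(f0[nm]), tolerance = 1e-9)
})

test_that("shape features: unit cell, sphere convergence, rod moments", {
  # single voxel at spacing (1,1,5): volume = 5 mm^3
  lab <- array(0L, c(5, 5, 5)); lab[3, 3, 3] <- 1L
  sh1 <- geometric_features(roi_mask(lab, c(1, 1, 5)))
  expect_length(sh1, 20L)
  expect_equal(unname(sh1["shape_voxel_volume"]), 5)
  expect_true(all(is.finite(sh1)))

  # digitized balls: sphericity approaches 1 as the radius grows
  s_small <- geometric_features(ball_mask(5))["shape_sphericity"]
  s_big <- geometric_features(ball_mask(12))["shape_sphericity"]
  expect_gt(s_big, 0.95)
  expect_lt(abs(s_big - 1), abs(s_small - 1) + 0.02)
  # surface area within 5% of the analytic sphere at r = 12
  a_big <- geometric_features(ball_mask(12))["shape_surface_area"]
  expect_lt(abs(a_big - 4 * pi * 144) / (4 * pi * 144), 0.05)

  # 1 x 1 x k rod: second-moment closed form of a line of k unit-spaced points
  k <- 7L
  lab2 <- array(0L, c(3, 3, k + 2L)); lab2[2, 2, 2:(k + 1L)] <- 1L
  sh2 <- geometric_features(roi_mask(lab2, c(1, 1, 1)))
  lam1 <- mean((seq_len(k) - mean(seq_len(k)))^2)   # brute-force moment
  expect_equal(unname(sh2["shape_major_axis_length"]), 4 * sqrt(lam1))
  expect_equal(unname(sh2["shape_elongation"]), 0)
  expect_equal(unname(sh2["shape_flatness"]), 0)
})

test_that("bank invariants: translation invariance and monotone volume", {
  set.seed(21)
  base <- array(0L, c(12, 12, 8))
  base[3:6, 3:6, 2:4] <- 1L
  hu_block <- array(rnorm(4 * 4 * 3, 50, 15), c(4, 4, 3))
  hu <- array(-100, c(12, 12, 8)); hu[3:6, 3:6, 2:4] <- hu_block
  f1 <- extract_all(ct_volume(hu, c(1, 1, 5)), roi_mask(base, c(1, 1, 5)))
  shifted <- array(0L, c(12, 12, 8)); shifted[6:9, 7:10, 4:6] <- 1L
  hu2 <- array(-100, c(12, 12, 8)); hu2[6:9, 7:10, 4:6] <- hu_block
  f2 <- extract_all(ct_volume(hu2, c(1, 1, 5)), roi_mask(shifted, c(1, 1, 5)))
  expect_equal(f1, f2, tolerance = 1e-12)

  # adding a disjoint voxel adds exactly one cell volume
  base2 <- base; base2[10, 10, 7] <- 1L
  v1 <- geometric_features(roi_mask(base, c(1, 1, 5)))["shape_voxel_volume"]
  v2 <- geometric_features(roi_mask(base2, c(1, 1, 5)))["shape_voxel_volume"]
  expect_equal(unname(v2 - v1), 5)
})

test_that("extract_all matches the registry and is deterministic", {
  coh <- generate_cohort(cohort_config(n_patients = 1, seed = 33))
  f <- extract_all(coh[[1]]$volume, coh[[1]]$mask)
  reg <- feature_registry()
  expect_identical(names(f), reg$name)
  expect_identical(attr(f, "category"), reg$category)
  expect_true(all(is.finite(f)))
  f2 <- extract_all(coh[[1]]$volume, coh[[1]]$mask)
  expect_identical(unclass(f), unclass(f2))
})
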