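frame1 <- list(r = c(1, 0, 0), c = c(0, 1, 0), l = c(0, 0, 1))

test_that("helix and sheet angles reproduce their defining projections", {
  expect_equal(helix_angle(frame1$c, frame1)$angle, 0)
  expect_equal(helix_angle(c(0, 1, 1) / sqrt(2), frame1)$angle, 45)
  expect_equal(helix_angle(c(0, 1, -1) / sqrt(2), frame1)$angle, -45)
  expect_equal(sheet_angle(frame1$r, frame1)$angle, 0)
  ## purely longitudinal projection resolves to +90 by the tie rule
  expect_equal(sheet_angle(frame1$l, frame1)$angle, 90)
  expect_equal(helix_angle(frame1$l, frame1)$angle, 90)
  ## near-radial myocytes are flagged invalid
  h <- helix_angle(c(0.999, 0.03, 0.03), frame1)
  expect_false(h$valid)
  expect_error(helix_angle(c(0, 0, 0), frame1), "zero vector")
})

test_that("angles are invariant to eigenvector sign flips", {
  set.seed(1)
  v <- matrix(rnorm(3000), 1000, 3)
  v <- v / sqrt(rowSums(v^2))
  ha1 <- helix_angle(v, frame1)$angle
  ha2 <- helix_angle(-v, frame1)$angle
  expect_identical(ha1, ha2)
  e1 <- sheet_angle(v, frame1)$angle
  e2 <- sheet_angle(-v, frame1)$angle
  expect_identical(e1, e2)
  expect_true(all(ha1 >= -90 & ha1 <= 90))
  expect_true(all(e1 >= -90 & e1 <= 90))
})

test_that("flipping fitted eigenvector signs leaves HA/E2A maps unchanged", {
  ph <- build_phantom(small_spec())
  field <- fit_tensor(simulate_dwi(ph$truth, std_scheme(), snr = 25,
                                   seed = 6),
                      std_scheme(), ph$geometry$mask)
  maps <- angle_maps(field, ph$geometry)
  flipped <- field
  set.seed(2)
  for (j in 1:3) {
    pick <- sample(c(TRUE, FALSE), nrow(field$evals), replace = TRUE)
    flipped$evecs[pick, , j] <- -flipped$evecs[pick, , j]
  }
  maps2 <- angle_maps(flipped, ph$geometry)
  expect_identical(maps$ha, maps2$ha)
  expect_identical(maps2$e2a, maps$e2a)
})

test_that("transmural profiles bin the prescribed law and mark absent bins", {
  ph <- build_phantom(phantom_spec())
  rec <- recover_phantom(phantom_spec(), scheme = std_scheme(),
                         window = NULL)
  prof <- rec$profile
  occ <- prof$n_voxels > 0 & prof$depth_pct >= 20 & prof$depth_pct <= 80
  expect_true(all(abs(prof$mean_ha[occ] -
                        (60 - 1.2 * prof$depth_pct[occ])) < 2))
  expect_true(all(is.na(prof$mean_ha[prof$n_voxels == 0])))
  ## uniform field: every occupied bin mean is exactly the constant
  ha <- ph$truth$ha
  ha[ph$geometry$mask] <- 10
  u <- transmural_profile(ha, ph$geometry$depth, ph$geometry$labels)
  expect_true(all(u$mean_ha[u$n_voxels > 0] == 10))
  ## coverage restricted to 40-60 % leaves outside bins absent
  ha2 <- ph$truth$ha
  d <- ph$geometry$depth
  ha2[!is.na(d) & (d < 40 | d > 60)] <- NA
  p2 <- transmural_profile(ha2, d, ph$geometry$labels, segment = 1)
  expect_true(all(p2$n_voxels[p2$depth_pct < 39 | p2$depth_pct > 61] == 0))
  expect_error(transmural_profile(ha2, d, ph$geometry$labels, segment = 5),
               "no usable voxels")
})

test_that("segment E2A means recover the prescribed constant", {
  rec <- recover_phantom(small_spec(e2a = 30), scheme = std_scheme(),
                         window = NULL)
  ph <- rec$phantom
  s <- segment_e2a(rec$maps$e2a, ph$geometry$labels, 1,
                   valid = rec$maps$valid)
  expect_equal(s$mean, 30, tolerance = 1 / 30)
  expect_lt(s$sd, 2)
  ## voxelwise recovery within 1 degree at infinite SNR
  err <- abs(rec$maps$e2a[rec$maps$valid] - 30)
  expect_lt(max(err), 1)
  ## symmetric +/- field averages to zero; singletons have zero SD
  e2a <- array(NA_real_, dim(ph$geometry$mask))
  lab <- array(0L, dim(ph$geometry$mask))
  e2a[1:10] <- rep(c(25, -25), 5)
  lab[1:10] <- 2L
  z <- segment_e2a(e2a, lab, 2)
  expect_lt(abs(z$mean), 1e-9)
  lab1 <- lab; lab1[] <- 0L; lab1[3] <- 3L
  one <- segment_e2a(e2a, lab1, 3)
  expect_equal(one$n, 1L)
  expect_identical(one$sd, 0)
})

test_that("recovered HA is right-handed at endo, left-handed at epi", {
  rec <- recover_phantom(phantom_spec(snr = 25, seed = 12),
                         scheme = std_scheme(), window = NULL)
  prof <- rec$profile
  occ <- prof$n_voxels > 0
  expect_gt(mean(prof$mean_ha[occ & prof$depth_pct < 50]), 0)
  expect_lt(mean(prof$mean_ha[occ & prof$depth_pct > 50]), 0)
  ## end-to-end law recovery: RMSE < 3 degrees over the 20-80 % bins
  sel <- occ & prof$depth_pct >= 20 & prof$depth_pct <= 80
  rmse <- sqrt(mean((prof$mean_ha[sel] -
                       (60 - 1.2 * prof$depth_pct[sel]))^2))
  expect_lt(rmse, 3)
})

test_that("profiles round-trip through the TSV writer", {
  rec <- recover_phantom(small_spec(), scheme = std_scheme(), window = NULL)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(rec$profile, path)
  back <- read_profile_tsv(path)
  expect_equal(back$mean_ha, rec$profile$mean_ha, tolerance = 1e-12)
  expect_identical(back$n_voxels, rec$profile$n_voxels)
})
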