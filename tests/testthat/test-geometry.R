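## Brute-force nearest-boundary oracle for the distance-transform depth.
brute_depth <- function(mask, endo, epi, voxel_size) {
  dims <- dim(mask)
  out <- array(NA_real_, dims)
  for (k in seq_len(dims[3])) {
    en <- which(endo[, , k], arr.ind = TRUE)
    ep <- which(epi[, , k], arr.ind = TRUE)
    mv <- which(mask[, , k], arr.ind = TRUE)
    for (i in seq_len(nrow(mv))) {
      de <- min(sqrt(((mv[i, 1] - en[, 1]) * voxel_size[1])^2 +
                     ((mv[i, 2] - en[, 2]) * voxel_size[2])^2))
      dp <- min(sqrt(((mv[i, 1] - ep[, 1]) * voxel_size[1])^2 +
                     ((mv[i, 2] - ep[, 2]) * voxel_size[2])^2))
      out[mv[i, 1], mv[i, 2], k] <- 100 * de / (de + dp)
    }
  }
  out
}

annulus_masks <- function() {
  ph <- build_phantom(phantom_spec(n_slices = 1L))
  bnd <- extract_boundaries(ph$geometry$mask, ph$geometry$cavity == 1)
  list(ph = ph, endo = bnd$endo, epi = bnd$epi)
}

test_that("annulus EDT depth ramps 0 to 100 across the wall", {
  am <- annulus_masks()
  mask <- am$ph$geometry$mask
  depth <- compute_depth(mask, am$endo, am$epi, c(2, 2, 4))
  expect_true(all(depth[mask] >= 0 & depth[mask] <= 100))
  expect_true(all(depth[am$endo] == 0))
  expect_true(all(depth[am$epi] == 100))
  ## voxel nearest radius 28 mm sits near 50 % depth (one 2 mm voxel on the
  ## 16 mm wall is 12.5 % tolerance)
  d2d <- am$ph$truth$depth
  mid <- which(abs(d2d - 50) == min(abs(d2d - 50), na.rm = TRUE))[1]
  expect_lt(abs(depth[mid] - 50), 13)
})

test_that("EDT depth equals the exhaustive nearest-boundary oracle", {
  ## non-convex C-shaped wall
  mask <- array(FALSE, c(20, 20, 1))
  for (i in 1:20) for (j in 1:20) {
    r <- sqrt((i - 10.5)^2 + (j - 10.5)^2)
    th <- atan2(j - 10.5, i - 10.5)
    if (r >= 4 && r <= 8 && !(th > -0.6 & th < 0.6)) mask[i, j, 1] <- TRUE
  }
  ## boundary voxel sets prescribed directly (inner/outer rings of the C)
  r2 <- sqrt((row(mask[, , 1]) - 10.5)^2 + (col(mask[, , 1]) - 10.5)^2)
  bnd <- list(endo = mask & array(r2 < 5, dim(mask)),
              epi = mask & array(r2 > 7, dim(mask)))
  vs <- c(1.5, 1.5, 4)
  got <- compute_depth(mask, bnd$endo, bnd$epi, vs)
  ref <- brute_depth(mask, bnd$endo, bnd$epi, vs)
  expect_equal(got, ref, tolerance = 1e-9)
  ## anisotropic in-plane spacing takes the exhaustive path; same contract
  vs2 <- c(1, 2, 4)
  expect_equal(compute_depth(mask, bnd$endo, bnd$epi, vs2),
               brute_depth(mask, bnd$endo, bnd$epi, vs2), tolerance = 1e-9)
  expect_error(compute_depth(mask, bnd$endo & FALSE, bnd$epi, vs), "empty")
  expect_error(compute_depth(mask, bnd$epi, bnd$epi, vs), "overlap")
})

test_that("depth ignores far-field background and is monotone along rays", {
  am <- annulus_masks()
  mask <- am$ph$geometry$mask
  vs <- c(2, 2, 4)
  depth <- compute_depth(mask, am$endo, am$epi, vs)
  ## padding the grid (pure background growth) leaves in-mask depth unchanged
  pad <- function(a, fill) {
    out <- array(fill, dim(a) + c(8, 8, 0))
    out[5:(4 + dim(a)[1]), 5:(4 + dim(a)[2]), ] <- a
    out
  }
  depth_p <- compute_depth(pad(mask, FALSE), pad(am$endo, FALSE),
                           pad(am$epi, FALSE), vs)
  expect_equal(depth_p[5:104, 5:104, , drop = FALSE], depth)
  ## monotone outward along the central row
  n <- dim(mask)[1]
  row <- depth[(n / 2 + 1):n, n / 2, 1]
  row <- row[is.finite(row)]
  expect_true(all(diff(row) > 0))
})

test_that("the depth-gradient frame matches analytic radials within 2 degrees", {
  am <- annulus_masks()
  mask <- am$ph$geometry$mask
  depth <- compute_depth(mask, am$endo, am$epi, c(2, 2, 4))
  fr <- local_frame(depth, mask, c(2, 2, 4))
  idx <- which(fr$valid)
  nvox <- prod(dim(mask))
  r_est <- cbind(fr$r[idx], fr$r[idx + nvox], fr$r[idx + 2 * nvox])
  r_true <- cbind(am$ph$geometry$frame$r[idx],
                  am$ph$geometry$frame$r[idx + nvox],
                  am$ph$geometry$frame$r[idx + 2 * nvox])
  ang <- acos(pmin(abs(rowSums(r_est * r_true)), 1)) * 180 / pi
  ## interior voxels (boundary voxels use one-sided differences); lattice
  ## jaggedness leaves a small error tail, so test the bulk and the tail
  interior <- depth[idx] > 15 & depth[idx] < 85
  expect_lt(stats::median(ang[interior]), 2)
  expect_lt(stats::quantile(ang[interior], 0.95), 6)
  ## orthonormal right-handed everywhere valid
  c_est <- cbind(fr$c[idx], fr$c[idx + nvox], fr$c[idx + 2 * nvox])
  l_est <- cbind(fr$l[idx], fr$l[idx + nvox], fr$l[idx + 2 * nvox])
  expect_lt(max(abs(rowSums(r_est * c_est))), 1e-6)
  det3 <- rowSums(r_est * cbind(c_est[, 2] * l_est[, 3] - c_est[, 3] * l_est[, 2],
                                c_est[, 3] * l_est[, 1] - c_est[, 1] * l_est[, 3],
                                c_est[, 1] * l_est[, 2] - c_est[, 2] * l_est[, 1]))
  expect_true(all(abs(det3 - 1) < 1e-9))
})

test_that("the frame is equivariant under in-plane 90-degree rotation", {
  am <- annulus_masks()
  mask <- am$ph$geometry$mask
  depth <- compute_depth(mask, am$endo, am$epi, c(2, 2, 4))
  fr <- local_frame(depth, mask, c(2, 2, 4))
  n <- dim(mask)[1]
  ## in-plane +90-degree rotation: new (i, j) <- old (j, n + 1 - i)
  rot3 <- function(a) {
    out <- a
    for (k in seq_len(dim(a)[3])) out[, , k] <- t(a[, , k][, n:1])
    out
  }
  fr_r <- local_frame(rot3(depth), rot3(mask), c(2, 2, 4))
  ## at a matched voxel the radial vector rotates by +90 degrees:
  ## r_new = (-ry_old, rx_old)
  nvox <- prod(dim(mask))
  idx_old <- which(fr$valid & depth > 20 & depth < 80)[c(10, 100, 400)]
  for (io in idx_old) {
    ij <- arrayInd(io, dim(mask))
    inew <- cbind(n + 1 - ij[2], ij[1], ij[3])
    io_new <- inew[1] + (inew[2] - 1) * n + (inew[3] - 1) * n * n
    r_old <- c(fr$r[io], fr$r[io + nvox])
    r_new <- c(fr_r$r[io_new], fr_r$r[io_new + nvox])
    expect_equal(r_new, c(-r_old[2], r_old[1]), tolerance = 1e-6)
  }
})

test_that("segment label maps round-trip and are validated", {
  ph <- build_phantom(small_spec())
  dir <- withr::local_tempdir()
  write_nifti_map(ph$geometry$labels, file.path(dir, "seg.nii.gz"), c(2, 2, 4))
  lab <- load_segments(file.path(dir, "seg.nii.gz"), expected = 1:4)
  expect_equal(array(lab, dim(lab)), ph$geometry$labels)
  expect_named(attr(lab, "counts"),
               c("anterior", "septum", "posterior", "lateral", "rv"))
  bad <- ph$geometry$labels
  bad[1, 1, 1] <- 7L
  expect_error(load_segments(bad), "unknown segment label")
  expect_warning(load_segments(ph$geometry$labels, expected = 1:5),
                 "empty segment")
})
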