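#' Read a DWI volume set with its gradient table
#'
#' @param image_path 4-D NIfTI of magnitude DWI volumes.
#' @param bval_path,bvec_path FSL-dialect gradient table files.
#' @return List with `data` (4-D array), `scheme` (`gradient_scheme`; b0
#'   volumes identified by b < 50 s/mm^2) and `voxel_size`.
#' @details Non-unit direction vectors on diffusion-weighted volumes are
#'   normalized with a warning; a volume count mismatch between image and
#'   table, or a table with no diffusion-weighted volume, is an error.
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  img <- read_nifti_map(image_path)
  if (length(dim(img$data)) != 4) stop("DWI image must be 4-D")
  scheme <- read_fsl_gradients(bval_path, bvec_path)
  if (length(scheme$bvals) != dim(img$data)[4])
    stop(sprintf("gradient table has %d volumes but image has %d",
                 length(scheme$bvals), dim(img$data)[4]))
  if (all(scheme$b0)) stop("no diffusion-weighted volumes")
  nrm <- vnorm(scheme$bvecs)
  bad <- !scheme$b0 & abs(nrm - 1) > 1e-6
  if (any(bad)) {
    warning("non-unit bvec on diffusion-weighted volume(s); normalizing")
    scheme$bvecs[bad, ] <- scheme$bvecs[bad, , drop = FALSE] / nrm[bad]
  }
  list(data = img$data, scheme = scheme, voxel_size = img$voxel_size)
}

#' Fit the diffusion tensor per voxel by log-linear least squares
#'
#' For each in-mask voxel the b0 volumes are averaged into a reference
#' `S0bar` and the model `ln(S/S0bar) = -b (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz +
#' 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)` is solved by unweighted least
#' squares over the diffusion-weighted volumes. Non-positive or non-finite
#' signals are clamped to `1e-6 * S0bar` and the voxel flagged (flagged
#' voxels are excluded from segment statistics downstream). The fit is exact
#' on noiseless data. Eigenvalues are sorted descending; eigenvector signs
#' are canonicalized so each vector's largest-magnitude component is
#' positive (helix/sheet angles are invariant to these sign choices).
#'
#' @param volumes 4-D DWI array.
#' @param scheme A [gradient_scheme()].
#' @param mask Logical 3-D array of voxels to fit.
#' @return Object of class `tensor_field`: `dim`, `mask`, `voxels` (linear
#'   indices of fitted voxels), `D` (n x 6: xx, yy, zz, xy, xz, yz, mm^2/s),
#'   `evals` (n x 3, descending), `evecs` (n x 3 x 3; `[, , j]` is the j-th
#'   eigenvector), `md`, `fa`, `flag` (logical, clamped/degenerate fits).
#' @export
fit_tensor <- function(volumes, scheme, mask) {
  dims <- dim(volumes)[1:3]
  stopifnot(all(dim(mask) == dims))
  dw <- !scheme$b0
  if (sum(scheme$b0) < 1) stop("at least one b0 volume is required")
  g <- scheme$bvecs[dw, , drop = FALSE]
  if (qr(g)$rank < 3 || nrow(unique(round(g, 12))) < 6)
    stop("fewer than 6 distinct diffusion directions")
  b <- scheme$bvals[dw]
  X <- -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                  2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                  2 * g[, 2] * g[, 3])
  qx <- qr(X)
  if (qx$rank < 6)
    stop("rank-deficient design: directions do not span the six tensor ",
         "components")
  idx <- which(mask)
  vmat <- matrix(volumes, prod(dims), dim(volumes)[4])[idx, , drop = FALSE]
  s0 <- rowMeans(vmat[, scheme$b0, drop = FALSE])
  s <- vmat[, dw, drop = FALSE]
  floor_ <- 1e-6 * s0
  flag <- rowSums(!(s > 0) | !is.finite(s)) > 0 | !(s0 > 0)
  s <- pmax(s, floor_)
  y <- log(s / s0)
  beta <- t(qr.coef(qx, t(y)))  # n x 6

  n <- length(idx)
  evals <- matrix(NA_real_, n, 3)
  evecs <- array(NA_real_, dim = c(n, 3, 3))
  for (i in seq_len(n)) {
    d6 <- beta[i, ]
    m <- matrix(c(d6[1], d6[4], d6[5],
                  d6[4], d6[2], d6[6],
                  d6[5], d6[6], d6[3]), 3, 3)
    e <- eigen(m, symmetric = TRUE)
    evals[i, ] <- e$values
    v <- e$vectors
    for (j in 1:3) {
      k <- which.max(abs(v[, j]))
      if (v[k, j] < 0) v[, j] <- -v[, j]
    }
    evecs[i, , ] <- v
  }
  md <- rowMeans(evals)
  fa <- fa_from_evals(evals)
  flag <- flag | rowSums(evals < 0) > 0
  structure(list(dim = dims, mask = mask, voxels = idx, D = beta,
                 evals = evals, evecs = evecs, md = md, fa = fa,
                 flag = flag),
            class = "tensor_field")
}

fa_from_evals <- function(evals) {
  ev <- pmax(evals, 0)  # negative eigenvalues clamped for FA
  md <- rowMeans(ev)
  num <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- sqrt(1.5 * num / pmax(den, .Machine$double.xmin))
  fa[den == 0] <- 0  # all-zero tensor: FA defined as 0
  pmin(fa, 1)
}

#' Mean diffusivity and fractional anisotropy maps
#'
#' `MD` is the mean eigenvalue; `FA = sqrt(3/2) ||lambda - MD|| / ||lambda||`
#' (normalized eigenvalue dispersion, 0 isotropic to 1 stick-like). Negative
#' eigenvalues are clamped to zero for FA and the voxel flagged; an all-zero
#' tensor has FA 0.
#'
#' @param field A `tensor_field`.
#' @return List with 3-D arrays `md` and `fa` (`NA` outside the mask) and
#'   `flag`.
#' @export
tensor_metrics <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  md <- array(NA_real_, dim = field$dim)
  fa <- array(NA_real_, dim = field$dim)
  fl <- array(FALSE, dim = field$dim)
  md[field$voxels] <- field$md
  fa[field$voxels] <- fa_from_evals(field$evals)
  fl[field$voxels] <- field$flag | rowSums(field$evals < 0) > 0
  list(md = md, fa = fa, flag = fl)
}

#' Plan the optimal diffusion b-value for a given diffusivity
#'
#' The highest b-value that loses no diffusion information for tissue of
#' apparent diffusion coefficient `adc` is `b = 1.11 / adc`, truncated toward
#' zero to a whole number of s/mm^2. For fixed myocardium with
#' `adc = 1.30e-3 mm^2/s` this gives 853 s/mm^2. A relative guard of 1e-9 is
#' applied before truncation so that exact divisions are not pushed below the
#' integer by floating-point representation.
#'
#' @param adc Apparent diffusion coefficient, mm^2/s (> 0).
#' @return b-value, integer s/mm^2.
#' @examples
#' optimal_bvalue(1.30e-3)  # 853
#' @export
optimal_bvalue <- function(adc) {
  if (!is.numeric(adc) || any(adc <= 0)) stop("adc must be positive")
  b <- 1.11 / adc
  trunc(b * (1 + 1e-9))
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf(
    "tensor field: %s grid, %d fitted voxels (%d flagged), MD %.3g, FA %.3g\n",
    paste(x$dim, collapse = "x"), length(x$voxels), sum(x$flag),
    stats::median(x$md), stats::median(x$fa)))
  invisible(x)
}
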