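#' Simulate a diffusion-weighted acquisition of a phantom
#'
#' Generates magnitude DWI volumes from a ground-truth tensor field under the
#' monoexponential diffusion signal model `S = S0 exp(-b g' D g)` with Rician
#' noise: independent Gaussian noise of standard deviation `sigma = S0 / SNR`
#' is added to the real and imaginary channels of each voxel/volume before
#' taking the magnitude, and `n_averages` independent repeats are averaged in
#' magnitude, as in magnitude-reconstructed MR with signal averaging.
#' Out-of-mask voxels carry zero true signal (pure noise background).
#'
#' @param truth A `ground_truth` (see [build_phantom()]).
#' @param scheme A [gradient_scheme()].
#' @param s0 Non-weighted signal amplitude.
#' @param snr Signal-to-noise ratio `s0 / sigma`; `Inf` for noiseless.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param n_averages Number of magnitude averages; defaults to the scheme's.
#' @return 4-D array (x, y, z, volume) of magnitude signals.
#' @export
simulate_dwi <- function(truth, scheme, s0 = 100, snr = Inf, seed = 0L,
                         n_averages = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!(snr > 0)) stop("snr must be positive (possibly Inf)")
  n_averages <- as.integer(n_averages %||%
                             (if (is.na(scheme$n_averages)) 1L
                              else scheme$n_averages))
  dims <- dim(truth$tensor)[1:3]
  nvox <- prod(dims)
  nv <- length(scheme$bvals)
  dmat <- matrix(truth$tensor, nvox, 6)
  in_mask <- is.finite(dmat[, 1])
  g <- scheme$bvecs
  b <- scheme$bvals
  ## g' D g per voxel/volume: quadratic-form design applied to the 6 unique
  ## tensor components
  q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  s <- matrix(0, nvox, nv)
  dm <- dmat[in_mask, , drop = FALSE]
  s[in_mask, ] <- s0 * exp(-(dm %*% t(q * b)))
  if (is.finite(snr)) {
    sigma <- s0 / snr
    s <- with_seed(seed, {
      acc <- 0
      for (a in seq_len(n_averages)) {
        re <- s + sigma * stats::rnorm(nvox * nv)
        im <- sigma * stats::rnorm(nvox * nv)
        acc <- acc + sqrt(re^2 + im^2)
      }
      acc / n_averages
    })
  }
  array(s, dim = c(dims, nv))
}

#' Write a simulated phantom dataset to disk
#'
#' Writes the DWI as 4-D NIfTI with FSL-dialect `bvals`/`bvecs`, the segment
#' label map and depth map as NIfTI, the myocardium/cavity masks, the
#' ground-truth HA/E2A maps, and a JSON sidecar of the phantom specification.
#'
#' @param dwi 4-D signal array from [simulate_dwi()].
#' @param scheme The [gradient_scheme()] used.
#' @param phantom The list returned by [build_phantom()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(dwi, scheme, phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- phantom$geometry$voxel_size
  wr <- function(a, name) write_nifti_map(a, file.path(dir, name), vs)
  wr(dwi, "dwi.nii.gz")
  wr(phantom$geometry$labels, "segments.nii.gz")
  wr(phantom$geometry$depth, "depth.nii.gz")
  wr(phantom$geometry$mask * 1L, "mask.nii.gz")
  wr(phantom$geometry$cavity, "cavity.nii.gz")
  wr(phantom$truth$ha, "true_ha.nii.gz")
  wr(phantom$truth$e2a, "true_e2a.nii.gz")
  write_fsl_gradients(scheme, file.path(dir, "bvals"), file.path(dir, "bvecs"))
  sp <- phantom$spec
  sp$snr <- if (is.finite(sp$snr)) sp$snr else "Inf"
  jsonlite::write_json(unclass(sp), file.path(dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Write an array as NIfTI with voxel dimensions
#'
#' @param a Numeric array (3-D or 4-D); `NA` is written as NaN.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param voxel_size Voxel dimensions in mm, length 3.
#' @export
write_nifti_map <- function(a, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(a * 1)
  RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(a)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI image as a plain array
#'
#' @param path NIfTI path.
#' @return List with `data` (array) and `voxel_size` (first three pixdims).
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 2) d <- c(d, 1L)  # single-slice images
  list(data = array(as.numeric(img), dim = d),
       voxel_size = RNifti::pixdim(img)[1:3])
}
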