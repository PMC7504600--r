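#' Extract endocardial and epicardial boundary voxels
#'
#' Boundary voxels are myocardial voxels with an in-plane 4-neighbour in the
#' cavity (endocardial) or in the background (epicardial), per slice.
#'
#' @param mask Logical 3-D myocardium mask.
#' @param cavity Logical 3-D cavity mask (the chamber whose wall is being
#'   parameterized).
#' @return List of logical arrays `endo` and `epi`.
#' @export
extract_boundaries <- function(mask, cavity) {
  bg <- !mask & !cavity
  adj <- function(a) {
    n1 <- array(FALSE, dim = dim(a))
    nx <- dim(a)[1]
    ny <- dim(a)[2]
    n1[-nx, , ] <- n1[-nx, , ] | a[-1, , ]
    n1[-1, , ] <- n1[-1, , ] | a[-nx, , ]
    n1[, -ny, ] <- n1[, -ny, ] | a[, -1, ]
    n1[, -1, ] <- n1[, -1, ] | a[, -ny, ]
    n1
  }
  list(endo = mask & adj(cavity), epi = mask & adj(bg))
}

#' Transmural depth from endocardial and epicardial boundaries
#'
#' For every myocardial voxel, depth = `100 * d_endo / (d_endo + d_epi)`
#' where `d_endo`/`d_epi` are in-plane Euclidean distances (mm) to the
#' nearest endocardial/epicardial boundary voxel, computed per short-axis
#' slice: 0 % at the endocardium, 100 % at the epicardium. With equal
#' in-plane voxel sizes the distances come from an exact Euclidean distance
#' transform; anisotropic in-plane spacing falls back to exhaustive
#' nearest-boundary search.
#'
#' @param mask Logical 3-D myocardium mask.
#' @param endo,epi Logical 3-D boundary-voxel arrays (see
#'   [extract_boundaries()]).
#' @param voxel_size Voxel dimensions in mm.
#' @return 3-D depth array in percent; `NA` outside the mask.
#' @export
compute_depth <- function(mask, endo, epi, voxel_size = c(1, 1, 1)) {
  if (!any(endo) || !any(epi)) stop("empty endocardial/epicardial boundary")
  dx <- voxel_size[1]
  dy <- voxel_size[2]
  nz <- dim(mask)[3]
  d_en <- array(NA_real_, dim = dim(mask))
  d_ep <- array(NA_real_, dim = dim(mask))
  for (k in seq_len(nz)) {
    if (!any(mask[, , k])) next
    if (!any(endo[, , k]) || !any(epi[, , k]))
      stop(sprintf("slice %d: empty endocardial/epicardial boundary", k))
    d_en[, , k] <- slice_boundary_distance(endo[, , k], dx, dy)
    d_ep[, , k] <- slice_boundary_distance(epi[, , k], dx, dy)
  }
  tot <- d_en + d_ep
  if (any(tot[mask] == 0))
    stop("endocardial and epicardial boundaries overlap")
  depth <- array(NA_real_, dim = dim(mask))
  depth[mask] <- 100 * d_en[mask] / tot[mask]
  depth
}

## Distance (mm) from every pixel of a slice to the nearest boundary pixel.
slice_boundary_distance <- function(bnd, dx, dy) {
  if (dx == dy) {
    img <- matrix(1, nrow(bnd), ncol(bnd))
    img[bnd] <- 0
    as.matrix(EBImage::distmap(img, metric = "euclidean")) * dx
  } else {
    ij <- which(bnd, arr.ind = TRUE)
    px <- matrix(0, nrow(bnd), ncol(bnd))
    xs <- row(px) * dx
    ys <- col(px) * dy
    bx <- ij[, 1] * dx
    by <- ij[, 2] * dy
    d <- matrix(Inf, nrow(bnd), ncol(bnd))
    for (b in seq_len(nrow(ij)))
      d <- pmin(d, sqrt((xs - bx[b])^2 + (ys - by[b])^2))
    d
  }
}

#' Local radial/circumferential/longitudinal frame from the depth map
#'
#' The radial direction is the normalized in-plane spatial gradient of the
#' transmural depth (pointing endocardium to epicardium); the longitudinal
#' direction is the slice normal (apex to base, out of plane); the
#' circumferential direction is their cross product `c = l x r`, making the
#' frame right-handed and endocardial right-handed helices positive. Voxels
#' whose depth gradient is degenerate (norm below `1e-6`) are flagged
#' invalid and excluded downstream.
#'
#' @param depth 3-D depth array (percent; `NA` outside the wall).
#' @param mask Logical 3-D myocardium mask.
#' @param voxel_size Voxel dimensions in mm.
#' @param slice_normal Length-3 unit vector of the longitudinal axis in voxel
#'   coordinates (apex to base); default `c(0, 0, 1)`.
#' @param smooth_sigma In-plane Gaussian smoothing (in voxels, normalized
#'   convolution within the mask) applied to the depth map before taking its
#'   gradient; damps the lattice wobble of the discrete distance transform.
#'   `0` disables smoothing. Default 2 voxels.
#' @return List of arrays `r`, `c`, `l` (dims x 3) and logical `valid`.
#' @export
local_frame <- function(depth, mask, voxel_size = c(1, 1, 1),
                        slice_normal = c(0, 0, 1), smooth_sigma = 2) {
  dims <- dim(depth)
  if (smooth_sigma > 0) depth <- smooth_masked(depth, mask, smooth_sigma)
  gx <- masked_gradient(depth, mask, 1, voxel_size[1])
  gy <- masked_gradient(depth, mask, 2, voxel_size[2])
  nrm <- sqrt(gx^2 + gy^2)
  valid <- mask & is.finite(nrm) & nrm > 1e-6
  if (!any(valid)) stop("no voxel has a usable depth gradient")
  idx <- which(valid)
  rv <- cbind(gx[idx] / nrm[idx], gy[idx] / nrm[idx], 0)
  lv <- matrix(rep(slice_normal / sqrt(sum(slice_normal^2)),
                   each = length(idx)), ncol = 3)
  cv <- cross_rows(lv, rv)
  list(r = vec_field(dims, idx, rv), c = vec_field(dims, idx, cv),
       l = vec_field(dims, idx, lv), valid = valid)
}

## In-plane normalized-convolution Gaussian smoothing: values outside the
## mask carry zero weight, so the smoothed field is defined on the mask only.
smooth_masked <- function(a, mask, sigma) {
  half <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  kern <- outer(k, k)
  out <- array(NA_real_, dim(a))
  for (s in seq_len(dim(a)[3])) {
    v <- a[, , s]
    m <- mask[, , s] * 1
    v[m == 0 | is.na(v)] <- 0
    num <- EBImage::filter2(v, kern, boundary = 0)
    den <- EBImage::filter2(m, kern, boundary = 0)
    sl <- num / pmax(den, 1e-12)
    sl[m == 0] <- NA_real_
    out[, , s] <- sl
  }
  out
}

## Central differences inside the mask, one-sided at mask edges.
masked_gradient <- function(a, mask, axis, h) {
  dims <- dim(a)
  sh <- function(arr, by) {
    out <- array(NA_real_, dim = dims)
    n <- dims[axis]
    src <- seq_len(n - abs(by))
    if (by > 0) dst <- src + by else dst <- src
    if (by > 0) from <- src else from <- src + abs(by)
    if (axis == 1) out[dst, , ] <- arr[from, , ]
    else out[, dst, ] <- arr[, from, ]
    out
  }
  ap <- sh(a, 1)   # value at i-1 shifted into i? see below
  am <- sh(a, -1)
  ## sh(a, 1): out[i] = a[i-1]; sh(a, -1): out[i] = a[i+1]
  fwd <- (am - a) / h
  bwd <- (a - ap) / h
  ctr <- (am - ap) / (2 * h)
  g <- ctr
  g[is.na(g)] <- fwd[is.na(g)]
  g[is.na(g)] <- bwd[is.na(g)]
  g[!mask] <- NA_real_
  g
}

#' Load and validate a five-segment label map
#'
#' Labels: 0 background, 1 anterior, 2 septum, 3 posterior, 4 lateral,
#' 5 RV free wall. Unknown labels are an error; an empty expected segment
#' produces a warning (downstream tables omit that segment).
#'
#' @param x NIfTI path or integer 3-D array.
#' @param expected Segment ids expected to be present (default 1:5; use
#'   e.g. `1:4` for an LV-only annulus).
#' @return Integer label array with attribute `counts` (voxels per segment).
#' @export
load_segments <- function(x, expected = 1:5) {
  if (is.character(x)) x <- read_nifti_map(x)$data
  lab <- array(as.integer(round(x)), dim = dim(x))
  bad <- setdiff(unique(as.vector(lab)), 0:5)
  if (length(bad))
    stop("unknown segment label(s): ", paste(bad, collapse = ", "))
  counts <- vapply(1:5, function(s) sum(lab == s), integer(1))
  names(counts) <- segment_names()
  empty <- intersect(which(counts == 0), expected)
  if (length(empty))
    warning("empty segment(s): ",
            paste(segment_names()[empty], collapse = ", "),
            "; skipped in statistics")
  attr(lab, "counts") <- counts
  lab
}

segment_names <- function() {
  c("anterior", "septum", "posterior", "lateral", "rv")
}
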