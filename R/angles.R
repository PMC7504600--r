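#' Helix angle of a myocyte direction in the local frame
#'
#' The helix angle (HA) is the angle between the projection of the primary
#' eigenvector onto the circumferential-longitudinal plane and the
#' circumferential axis, positive towards the longitudinal (apex-base) axis:
#' `HA = atan2(e1 . l, e1 . c)` after flipping `e1` so that `e1 . c >= 0`
#' (an eigenvector's sign is arbitrary; the result lies in (-90, +90], with
#' the tie at a purely longitudinal projection resolved to +90). Projections
#' with norm below `min_proj` (near-radial myocytes) are flagged invalid.
#'
#' @param e1 Unit vector (length 3) or n x 3 matrix of primary eigenvectors.
#' @param frame List with `r`, `c`, `l` unit vectors: length 3 each, or
#'   n x 3 matrices matching `e1`.
#' @param min_proj Minimum in-plane projection norm; smaller is flagged.
#' @return List with `angle` (degrees, in \[-90, 90\]) and `valid` (logical).
#' @export
helix_angle <- function(e1, frame, min_proj = 0.1) {
  project_angle(e1, frame$c, frame$l, min_proj)
}

#' Sheet angle of the secondary eigenvector in the local frame
#'
#' The sheet angle (E2A) is the angle between the projection of the
#' secondary eigenvector onto the radial-longitudinal plane and the radial
#' axis: `E2A = atan2(e2 . l, e2 . r)` after flipping `e2` so that
#' `e2 . r >= 0`. Conventions as in [helix_angle()].
#'
#' @param e2 Unit vector or n x 3 matrix of secondary eigenvectors.
#' @inheritParams helix_angle
#' @return List with `angle` (degrees, in \[-90, 90\]) and `valid`.
#' @export
sheet_angle <- function(e2, frame, min_proj = 0.1) {
  project_angle(e2, frame$r, frame$l, min_proj)
}

## Signed angle of v's projection onto span(a1, a2) from a1, after
## canonicalizing v's sign so v.a1 >= 0 (ties towards v.a2 >= 0).
project_angle <- function(v, a1, a2, min_proj) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  tomat <- function(a) if (is.null(dim(a)))
    matrix(a, nrow(v), 3, byrow = TRUE) else a
  a1 <- tomat(a1)
  a2 <- tomat(a2)
  if (any(vnorm(v) < 1e-12)) stop("zero vector has no direction")
  p1 <- rowSums(v * a1)
  p2 <- rowSums(v * a2)
  flip <- p1 < 0 | (p1 == 0 & p2 < 0)
  p1[flip] <- -p1[flip]
  p2[flip] <- -p2[flip]
  list(angle = deg(atan2(p2, p1)),
       valid = sqrt(p1^2 + p2^2) >= min_proj)
}

#' Per-voxel helix- and sheet-angle maps from a fitted tensor field
#'
#' Applies [helix_angle()] and [sheet_angle()] at every fitted voxel using
#' the local frame of the supplied geometry. Voxels flagged by the tensor
#' fit, lacking a valid frame, or with degenerate projections are marked
#' invalid.
#'
#' @param field A `tensor_field` (see [fit_tensor()]).
#' @param geometry A `myocardial_geometry`, or any list with a `frame`
#'   component as returned by [local_frame()].
#' @param min_proj Minimum projection norm for a valid angle.
#' @return List of 3-D arrays `ha`, `e2a` (degrees, `NA` where undefined)
#'   and logical `valid`.
#' @export
angle_maps <- function(field, geometry, min_proj = 0.1) {
  frame <- geometry$frame %||% geometry
  dims <- field$dim
  idx <- field$voxels
  nvox <- prod(dims)
  pick <- function(a) cbind(a[idx], a[idx + nvox], a[idx + 2 * nvox])
  fr <- list(r = pick(frame$r), c = pick(frame$c), l = pick(frame$l))
  okf <- frame$valid[idx] & is.finite(fr$r[, 1])
  e1 <- field$evecs[, , 1]
  e2 <- field$evecs[, , 2]
  ha <- array(NA_real_, dim = dims)
  e2a <- array(NA_real_, dim = dims)
  valid <- array(FALSE, dim = dims)
  sub <- which(okf & !field$flag)
  if (length(sub)) {
    hres <- helix_angle(e1[sub, , drop = FALSE],
                        lapply(fr, function(m) m[sub, , drop = FALSE]),
                        min_proj)
    sres <- sheet_angle(e2[sub, , drop = FALSE],
                        lapply(fr, function(m) m[sub, , drop = FALSE]),
                        min_proj)
    ha[idx[sub]] <- hres$angle
    e2a[idx[sub]] <- sres$angle
    valid[idx[sub]] <- hres$valid & sres$valid
  }
  list(ha = ha, e2a = e2a, valid = valid)
}

#' Transmural profile: mean HA per integer percent of wall depth
#'
#' Pools the voxels of one segment (or of the whole wall) across all slices
#' and averages HA within depth bins of `bin_width` percent. Bins with no
#' voxels are reported with `n_voxels = 0` and `mean_ha = NA` (absent, never
#' zero-filled).
#'
#' @param ha 3-D HA array (degrees).
#' @param depth 3-D transmural depth array (percent).
#' @param labels Integer segment label array.
#' @param segment Segment id (1-5), or `NULL` to pool all labelled voxels.
#' @param bin_width Bin width in percent of depth (default 1).
#' @param valid Optional logical array; invalid voxels are excluded.
#' @return Data frame of class `transmural_profile` with columns `segment`,
#'   `depth_pct`, `mean_ha`, `n_voxels`.
#' @export
transmural_profile <- function(ha, depth, labels, segment = NULL,
                               bin_width = 1, valid = NULL) {
  sel <- if (is.null(segment)) labels > 0 else labels == segment
  sel <- sel & is.finite(ha) & is.finite(depth)
  if (!is.null(valid)) sel <- sel & valid
  if (!any(sel)) stop("segment has no usable voxels")
  centers <- seq(0, 100, by = bin_width)
  bin <- round(depth[sel] / bin_width) * bin_width
  agg_m <- tapply(ha[sel], bin, mean)
  agg_n <- tapply(ha[sel], bin, length)
  out <- data.frame(segment = if (is.null(segment)) NA_integer_ else segment,
                    depth_pct = centers,
                    mean_ha = NA_real_,
                    n_voxels = 0L)
  pos <- match(as.numeric(names(agg_m)), centers)
  out$mean_ha[pos] <- as.numeric(agg_m)
  out$n_voxels[pos] <- as.integer(agg_n)
  class(out) <- c("transmural_profile", "data.frame")
  out
}

#' Segment-mean sheet angle
#'
#' Arithmetic mean and SD of valid-voxel E2A over the whole segment (all
#' depths and slices).
#'
#' @param e2a 3-D E2A array (degrees).
#' @param labels Integer segment label array.
#' @param segment Segment id.
#' @param valid Optional logical array of usable voxels.
#' @return List with `mean`, `sd` (0 when n = 1) and `n`.
#' @export
segment_e2a <- function(e2a, labels, segment, valid = NULL) {
  sel <- labels == segment & is.finite(e2a)
  if (!is.null(valid)) sel <- sel & valid
  vals <- e2a[sel]
  if (length(vals) == 0) stop("segment has no usable voxels")
  list(mean = mean(vals),
       sd = if (length(vals) > 1) stats::sd(vals) else 0,
       n = length(vals))
}

#' Write transmural profiles as TSV
#'
#' Columns: `segment`, `depth_pct`, `mean_ha`, `n_voxels`.
#'
#' @param profile A `transmural_profile` (or row-bound several).
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read transmural profiles written by [write_profile_tsv()]
#' @param path TSV path.
#' @return A `transmural_profile` data frame.
#' @export
read_profile_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE)
  class(out) <- c("transmural_profile", "data.frame")
  out
}
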