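#' Build a diffusion gradient scheme with interleaved b0 volumes
#'
#' Assembles the per-volume gradient table of an acquisition: one b0 reference
#' volume first, the diffusion directions in blocks, and a further b0 volume
#' after every run of `b0_every` directions (the acquisition interleaves
#' non-weighted volumes to limit gradient load). With 32 directions and
#' `b0_every = 10` this yields 36 volumes with b0 at positions 1, 12, 23, 34.
#'
#' @param directions n x 3 matrix of unit diffusion directions (one
#'   hemisphere; see [generate_half_shell_directions()]).
#' @param b Diffusion weighting of the non-b0 volumes, s/mm^2.
#' @param delta Diffusion gradient duration, ms.
#' @param Delta Diffusion gradient separation, ms.
#' @param b0_every Insert a b0 volume after every this many directions.
#' @param n_averages Number of signal averages acquired.
#' @return An object of class `gradient_scheme`: list with `bvals` (length V),
#'   `bvecs` (V x 3, zero rows for b0), `delta`, `Delta`, `n_averages`,
#'   `b0` (logical per volume).
#' @export
gradient_scheme <- function(directions, b = 853, delta = 20.67, Delta = 27.09,
                            b0_every = 10L, n_averages = 2L) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3, nrow(directions) >= 1, b > 0)
  if (any(abs(vnorm(directions) - 1) > 1e-12))
    stop("diffusion directions must be unit vectors")
  n <- nrow(directions)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / b0_every))
  bvecs <- matrix(0, 0, 3)
  bvals <- numeric(0)
  for (idx in blocks) {
    bvecs <- rbind(bvecs, c(0, 0, 0), directions[idx, , drop = FALSE])
    bvals <- c(bvals, 0, rep(b, length(idx)))
  }
  out <- list(bvals = bvals, bvecs = bvecs, delta = delta, Delta = Delta,
              n_averages = as.integer(n_averages), b0 = bvals < 50)
  class(out) <- "gradient_scheme"
  validate_scheme(out)
  out
}

#' Validate a gradient scheme
#'
#' Checks the acquisition contract: unit non-b0 directions, a single shared
#' b-value, all directions within one closed hemisphere with no antipodal
#' duplicates, and a b0 volume before the first direction and after every run
#' of ten directions.
#'
#' @param scheme A `gradient_scheme`.
#' @return The scheme, invisibly; errors on violation.
#' @export
validate_scheme <- function(scheme) {
  g <- scheme$bvecs[!scheme$b0, , drop = FALSE]
  if (nrow(g) == 0) stop("no diffusion-weighted volumes")
  if (any(abs(vnorm(g) - 1) > 1e-12))
    stop("non-b0 directions must have unit norm")
  bs <- unique(scheme$bvals[!scheme$b0])
  if (length(bs) != 1)
    stop("all diffusion-weighted volumes must share one b-value")
  gg <- tcrossprod(g)
  if (any(gg[upper.tri(gg)] < -1 + 1e-9))
    stop("antipodal duplicate directions found")
  can <- canonicalize_hemisphere(g)
  if (any(abs(can - g) > 0))
    stop("directions are not in the canonical closed hemisphere")
  if (scheme$b0[1] != TRUE)
    stop("first volume must be b0")
  runlen <- 0
  for (i in seq_along(scheme$b0)[-1]) {
    if (scheme$b0[i]) runlen <- 0 else runlen <- runlen + 1
    if (runlen > 10) stop("more than ten directions without a b0 volume")
  }
  invisible(scheme)
}

#' Write a gradient scheme as FSL bvals/bvecs files
#'
#' `bvals` is one whitespace-separated row; `bvecs` is three rows (x, y, z),
#' columns ordered as volumes.
#'
#' @param scheme A `gradient_scheme`.
#' @param bval_path,bvec_path Output paths.
#' @export
write_fsl_gradients <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(t(scheme$bvecs), 1, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' Read FSL bvals/bvecs files
#'
#' @param bval_path,bvec_path Input paths.
#' @return A `gradient_scheme` (pulse timings unknown from FSL files: `NA`).
#' @export
read_fsl_gradients <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) scan(text = l, quiet = TRUE))
  rows <- rows[vapply(rows, length, 1L) > 0]
  if (length(rows) != 3) stop("bvecs file must have three rows")
  bvecs <- t(do.call(rbind, rows))
  if (nrow(bvecs) != length(bvals))
    stop("bvals/bvecs column counts disagree")
  out <- list(bvals = bvals, bvecs = bvecs, delta = NA_real_, Delta = NA_real_,
              n_averages = NA_integer_, b0 = bvals < 50)
  class(out) <- "gradient_scheme"
  out
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("gradient scheme: %d volumes (%d b0), b = %s s/mm^2\n",
              length(x$bvals), sum(x$b0),
              paste(unique(x$bvals[!x$b0]), collapse = ", ")))
  invisible(x)
}
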