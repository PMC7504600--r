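#' Generate a half-shell set of diffusion-encoding directions
#'
#' Produces `n` unit vectors spread as uniformly as possible over the sphere
#' under antipodal symmetry (a diffusion measurement along `g` is identical to
#' one along `-g`), then canonicalizes every vector into a single closed
#' hemisphere. Uniformity is obtained by electrostatic-repulsion minimization:
#' each direction and its antipode carry a unit charge and the configuration
#' descends the Coulomb energy on the sphere until the step size collapses.
#'
#' @param n Number of directions; at least 6 are needed to determine a
#'   diffusion tensor.
#' @param seed Integer seed for the random initial configuration. The result
#'   is deterministic given `(n, seed)`.
#' @param n_iter Maximum number of descent iterations.
#' @return An `n` x 3 matrix of unit row vectors, each with third component
#'   >= 0 (ties broken towards positive second, then first, component).
#' @examples
#' g <- generate_half_shell_directions(32, seed = 0)
#' range(sqrt(rowSums(g^2)))
#' @export
generate_half_shell_directions <- function(n, seed = 0L, n_iter = 2000L) {
  if (n < 6)
    stop("at least 6 directions are required (tensor underdetermined)")
  p <- with_seed(seed, matrix(stats::rnorm(3 * n), n, 3))
  p <- unit_rows(p)
  step <- 0.1
  e_old <- repulsion_energy(p)
  for (it in seq_len(n_iter)) {
    f <- repulsion_force(p)
    cand <- unit_rows(p + step * f)
    e_new <- repulsion_energy(cand)
    if (e_new < e_old) {
      p <- cand
      e_old <- e_new
      step <- step * 1.05
    } else {
      step <- step / 2
      if (step < 1e-12) break
    }
  }
  canonicalize_hemisphere(p)
}

## Coulomb energy of the antipodally symmetrized configuration (pairs i<j,
## both sign combinations; the constant self/antipode term is omitted).
repulsion_energy <- function(p) {
  g <- tcrossprod(p)
  dm <- sqrt(pmax(2 - 2 * g, 1e-12))
  dp <- sqrt(pmax(2 + 2 * g, 1e-12))
  e <- 1 / dm + 1 / dp
  diag(e) <- 0
  sum(e) / 2
}

## Tangential component of the Coulomb force on each point.
repulsion_force <- function(p) {
  g <- tcrossprod(p)
  wm <- pmax(2 - 2 * g, 1e-12)^(-1.5)
  wp <- pmax(2 + 2 * g, 1e-12)^(-1.5)
  diag(wm) <- 0
  diag(wp) <- 0
  f <- (rowSums(wm) + rowSums(wp)) * p - wm %*% p + wp %*% p
  f - p * rowSums(f * p)
}

#' Canonicalize direction signs into one closed hemisphere
#'
#' Flips each row so its third component is positive; rows lying exactly on
#' the equator are flipped towards positive second, then first, component.
#'
#' @param p Matrix of row vectors.
#' @return Matrix of the same shape with canonical signs.
#' @export
canonicalize_hemisphere <- function(p) {
  flip <- p[, 3] < 0 |
    (p[, 3] == 0 & (p[, 2] < 0 | (p[, 2] == 0 & p[, 1] < 0)))
  p[flip, ] <- -p[flip, , drop = FALSE]
  p
}

#' Minimum pairwise angular separation of a direction set
#'
#' Angles are measured between undirected axes (`g` and `-g` identified), in
#' degrees.
#'
#' @param p Matrix of unit row vectors.
#' @return Smallest pairwise angle in degrees.
#' @export
min_angular_separation <- function(p) {
  g <- abs(tcrossprod(p))
  a <- acos(pmin(g[upper.tri(g)], 1))
  deg(min(a))
}
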