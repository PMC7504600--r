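## Shared fixtures, built once per test run.

## The standard 36-volume half-shell scheme (b = 853, b0 every ten).
std_scheme <- local({
  sch <- NULL
  function() {
    if (is.null(sch))
      sch <<- gradient_scheme(generate_half_shell_directions(32, seed = 0))
    sch
  }
})

## Reduced annulus for fast simulation studies: 32x32 grid, one slice,
## 14 mm wall (7 voxels).
small_spec <- function(...) {
  phantom_spec(matrix_size = 32L, n_slices = 1L, r_endo = 8, r_epi = 22, ...)
}

## A ground_truth with the same constant 6-component tensor at every voxel.
constant_truth <- function(d6, dims = c(5, 5, 1)) {
  tensor <- array(rep(d6, each = prod(dims)), dim = c(dims, 6))
  structure(list(tensor = tensor,
                 ha = array(0, dims), e2a = array(0, dims),
                 depth = array(50, dims),
                 labels = array(1L, dims)),
            class = "ground_truth")
}

## True primary eigenvector field of a phantom (myocyte direction from the
## HA law in the circumferential-longitudinal plane).
true_e1 <- function(phantom, idx) {
  fr <- phantom$geometry$frame
  nvox <- prod(dim(phantom$geometry$mask))
  pick <- function(a) cbind(a[idx], a[idx + nvox], a[idx + 2 * nvox])
  h <- phantom$truth$ha[idx] * pi / 180
  cos(h) * pick(fr$c) + sin(h) * pick(fr$l)
}
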