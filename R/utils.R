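#' @keywords internal
"_PACKAGE"

## Run an expression under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

vnorm <- function(x) sqrt(rowSums(x^2))

unit_rows <- function(x) x / vnorm(x)

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

deg <- function(x) x * 180 / pi
rad <- function(x) x * pi / 180

`%||%` <- function(a, b) if (is.null(a)) b else a
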