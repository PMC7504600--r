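#' Fit the linear HA-depth relationship (HA gradient and asymmetry)
#'
#' Ordinary least squares of mean helix angle on transmural depth over the
#' occupied per-percent bins inside the fit window (default 20-80 % depth;
#' 20-70 % is used where the transmural course is non-linear beyond 70 %,
#' as in situs inversus). When several specimens' profiles are pooled, every
#' specimen's per-percent bin enters as one point. The HA asymmetry `HA0` is
#' the depth at which the fitted line crosses zero (`-intercept/slope`),
#' reported only when the crossing lies in \[0, 100\] %; its confidence
#' interval is taken from the intersections of the 95 % confidence band of
#' the fitted mean line with HA = 0, normalized to `lower <= upper`.
#'
#' @param profile A `transmural_profile` data frame (or several row-bound),
#'   needing columns `depth_pct` and `mean_ha`; rows with `NA` mean HA are
#'   ignored. Per-voxel fits are possible by passing voxel-level depth/HA
#'   pairs in the same columns.
#' @param window Length-2 fit window in percent depth.
#' @param level Confidence level of the band (default 0.95).
#' @return Object of class `ha_gradient_fit`: `slope` (deg/%), `intercept`
#'   (deg at 0 %), `se_slope`, `sigma2` (residual variance), `df`
#'   (n - 2), `n`, `window`, `ha0` (% depth or `NA`), `ha0_ci`
#'   (`c(lower, upper)`, `NA` when the band never closes around the
#'   crossing), plus internals used by the band (`xbar`, `sxx`).
#' @export
fit_ha_gradient <- function(profile, window = c(20, 80), level = 0.95) {
  stopifnot(length(window) == 2, window[1] < window[2])
  d <- profile$depth_pct
  yv <- profile$mean_ha
  keep <- is.finite(d) & is.finite(yv) & d >= window[1] & d <= window[2]
  x <- d[keep]
  yv <- yv[keep]
  n <- length(x)
  if (n < 10)
    stop("fewer than 10 occupied depth bins inside the fit window")
  xbar <- mean(x)
  sxx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (yv - mean(yv))) / sxx
  intercept <- mean(yv) - slope * xbar
  res <- yv - intercept - slope * x
  dfree <- n - 2
  sigma2 <- sum(res^2) / dfree
  se_slope <- sqrt(sigma2 / sxx)

  ha0 <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (slope != 0) {
    x0 <- -intercept / slope
    if (x0 >= 0 && x0 <= 100) {
      ha0 <- x0
      ci <- band_zero_crossings(intercept, slope, sigma2, n, xbar, sxx,
                                dfree, level)
    }
  }
  structure(list(slope = slope, intercept = intercept, se_slope = se_slope,
                 sigma2 = sigma2, df = dfree, n = n, window = window,
                 ha0 = ha0, ha0_ci = ci, xbar = xbar, sxx = sxx,
                 level = level),
            class = "ha_gradient_fit")
}

## Depths where the confidence band of the fitted mean line crosses HA = 0:
## solve (a + b x)^2 = q (1/n + (x - xbar)^2 / sxx) with q = t^2 s^2. When
## the slope is significantly non-zero the two roots bracket -a/b.
band_zero_crossings <- function(a, b, sigma2, n, xbar, sxx, dfree, level) {
  if (sigma2 == 0) return(rep(-a / b, 2))  # noiseless: zero-width interval
  q <- stats::qt(1 - (1 - level) / 2, dfree)^2 * sigma2
  A <- b^2 - q / sxx
  B <- 2 * a * b + 2 * q * xbar / sxx
  C <- a^2 - q / n - q * xbar^2 / sxx
  if (A <= 0) return(c(NA_real_, NA_real_))
  ## when A > 0 the two crossings exist (the quadratic is negative at the
  ## fitted crossing and positive at infinity); clamp cancellation error
  disc <- max(B^2 - 4 * A * C, 0)
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  sort(roots)
}

#' Classify myocyte handedness dominance from the HA asymmetry
#'
#' `HA0 < 50 %` indicates predominantly left-handed (epicardial-type)
#' myocytes, `HA0 > 50 %` predominantly right-handed (endocardial-type)
#' myocytes.
#'
#' @param fit An `ha_gradient_fit`, or a numeric `HA0` value.
#' @return `"left-handed-dominant"`, `"right-handed-dominant"`,
#'   `"symmetric"`, or `"undefined"` when `HA0` is absent.
#' @export
classify_asymmetry <- function(fit) {
  ha0 <- if (inherits(fit, "ha_gradient_fit")) fit$ha0 else fit
  if (!is.finite(ha0)) return("undefined")
  if (ha0 < 50) "left-handed-dominant"
  else if (ha0 > 50) "right-handed-dominant"
  else "symmetric"
}

#' Compare two fitted HA gradients (two-slope Welch t-test)
#'
#' Tests equality of two regression slopes using the error variance of each
#' slope: `t = (b1 - b2) / sqrt(SE1^2 + SE2^2)`, with Welch-Satterthwaite
#' degrees of freedom weighting each error variance by its degrees of
#' freedom, and a two-sided p-value from the t distribution.
#'
#' @param fit1,fit2 `ha_gradient_fit` objects.
#' @return Object of class `slope_comparison`: `t`, `df`, `p`,
#'   `degenerate` (TRUE when both SEs are zero with unequal slopes).
#' @export
compare_slopes <- function(fit1, fit2) {
  b1 <- fit1$slope
  b2 <- fit2$slope
  v1 <- fit1$se_slope^2
  v2 <- fit2$se_slope^2
  degenerate <- FALSE
  if (v1 + v2 == 0) {
    if (b1 == b2) {
      t <- 0
      p <- 1
      dfree <- fit1$df + fit2$df
    } else {
      t <- sign(b1 - b2) * Inf
      p <- 0
      dfree <- fit1$df + fit2$df
      degenerate <- TRUE
    }
  } else {
    t <- (b1 - b2) / sqrt(v1 + v2)
    dfree <- (v1 + v2)^2 / (v1^2 / fit1$df + v2^2 / fit2$df)
    p <- 2 * stats::pt(-abs(t), dfree)
  }
  structure(list(t = t, df = dfree, p = p, degenerate = degenerate),
            class = "slope_comparison")
}

#' Compare segment sheet angles between two groups
#'
#' Welch two-sample t-test on the voxelwise E2A values of the two groups,
#' reporting per-group mean and SD alongside the test.
#'
#' @param a,b Numeric vectors of voxel E2A values (degrees), each of length
#'   at least 2.
#' @return List with `mean_diff`, `t`, `df`, `p`, and per-group `mean_a`,
#'   `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`.
#' @export
compare_e2a <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  tt <- stats::t.test(a, b)
  list(mean_diff = mean(a) - mean(b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
       mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b))
}

#' Assemble group-by-segment result tables
#'
#' Builds the three standard result tables from per-group, per-segment fits
#' and E2A summaries: HA gradients (deg/%), HA asymmetries formatted
#' `"x.x [lo:hi]"`, and mean E2A formatted `"m +/- s"`, plus pairwise
#' between-group slope and E2A comparisons per segment with a significance
#' flag at `p < 0.01`. Segments absent from a group are reported `NA`.
#'
#' @param results Nested list: `results[[group]][[segment_name]]` is a list
#'   with components `fit` (an `ha_gradient_fit`) and optionally `e2a`
#'   (output of [segment_e2a()]) and `e2a_values` (voxel values, used for
#'   the comparisons).
#' @param alpha Significance threshold for highlighting (default 0.01).
#' @return List of data frames `gradient`, `asymmetry`, `e2a`,
#'   `comparisons`.
#' @export
group_tables <- function(results, alpha = 0.01) {
  groups <- names(results)
  segs <- segment_names()
  getcell <- function(g, s) results[[g]][[s]]
  grad <- asym <- e2a <- data.frame(group = groups)
  for (s in segs) {
    grad[[s]] <- vapply(groups, function(g) {
      cell <- getcell(g, s)
      if (is.null(cell)) NA_real_ else cell$fit$slope
    }, numeric(1))
    asym[[s]] <- vapply(groups, function(g) {
      cell <- getcell(g, s)
      if (is.null(cell)) NA_character_ else format_asymmetry(cell$fit)
    }, character(1))
    e2a[[s]] <- vapply(groups, function(g) {
      cell <- getcell(g, s)
      if (is.null(cell) || is.null(cell$e2a)) NA_character_
      else sprintf("%.0f ± %.0f", cell$e2a$mean, cell$e2a$sd)
    }, character(1))
  }
  comp <- NULL
  if (length(groups) > 1) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    rows <- list()
    for (pr in pairs) for (s in segs) {
      c1 <- getcell(pr[1], s)
      c2 <- getcell(pr[2], s)
      if (is.null(c1) || is.null(c2)) next
      sc <- compare_slopes(c1$fit, c2$fit)
      row <- data.frame(group_a = pr[1], group_b = pr[2], segment = s,
                        slope_t = sc$t, slope_p = sc$p,
                        slope_significant = sc$p < alpha,
                        e2a_p = NA_real_, e2a_significant = NA)
      if (!is.null(c1$e2a_values) && !is.null(c2$e2a_values)) {
        ec <- compare_e2a(c1$e2a_values, c2$e2a_values)
        row$e2a_p <- ec$p
        row$e2a_significant <- ec$p < alpha
      }
      rows[[length(rows) + 1]] <- row
    }
    comp <- do.call(rbind, rows)
  }
  list(gradient = grad, asymmetry = asym, e2a = e2a, comparisons = comp)
}

## "x.x [lo:hi]" with the CI normalized to lower <= upper.
format_asymmetry <- function(fit) {
  if (!is.finite(fit$ha0)) return("undefined")
  if (any(!is.finite(fit$ha0_ci)))
    return(sprintf("%.1f [NA:NA]", fit$ha0))
  sprintf("%.1f [%.1f:%.1f]", fit$ha0, fit$ha0_ci[1], fit$ha0_ci[2])
}

#' Write a result table as TSV (round-trips with [read_result_table()])
#' @param x Data frame.
#' @param path Output path.
#' @export
write_result_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path TSV path.
#' @return Data frame.
#' @export
read_result_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.ha_gradient_fit <- function(x, ...) {
  cat(sprintf(
    "HA gradient fit over [%g, %g]%% depth (n = %d bins)\n", x$window[1],
    x$window[2], x$n))
  cat(sprintf("  slope     %+.3f deg/%% (SE %.3f)\n", x$slope, x$se_slope))
  cat(sprintf("  intercept %+.2f deg\n", x$intercept))
  if (is.finite(x$ha0))
    cat(sprintf("  HA0       %.1f%% depth, %g%% CI [%.1f:%.1f] (%s)\n",
                x$ha0, 100 * x$level, x$ha0_ci[1], x$ha0_ci[2],
                classify_asymmetry(x)))
  else cat("  HA0       undefined\n")
  invisible(x)
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("slope comparison: t = %.3f, df = %.1f, p = %.4g%s\n",
              x$t, x$df, x$p, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
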