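exact_profile <- function(slope = -1.2, intercept = 60, d = 20:80) {
  data.frame(depth_pct = d, mean_ha = intercept + slope * d)
}

test_that("a noiseless linear profile is fitted exactly", {
  f <- fit_ha_gradient(exact_profile())
  expect_equal(f$slope, -1.2)
  expect_equal(f$intercept, 60)
  expect_equal(f$ha0, 50)
  expect_equal(f$sigma2, 0)
  expect_equal(f$ha0_ci, c(50, 50))
  expect_equal(f$df, 59)
  expect_error(fit_ha_gradient(exact_profile(d = 20:27)), "fewer than 10")
  ## zero slope: HA0 undefined
  fz <- fit_ha_gradient(data.frame(depth_pct = 20:80, mean_ha = 5))
  expect_true(is.na(fz$ha0))
  expect_identical(classify_asymmetry(fz), "undefined")
})

test_that("HA0 transforms correctly under axis and offset changes", {
  ## doubling depth halves the slope, HA0 in percent unchanged once mapped
  p <- exact_profile()
  p2 <- data.frame(depth_pct = 2 * p$depth_pct, mean_ha = p$mean_ha)
  f1 <- fit_ha_gradient(p)
  f2 <- fit_ha_gradient(p2, window = c(40, 160))
  expect_equal(f2$slope, f1$slope / 2, tolerance = 1e-12)
  ## adding a constant c shifts the zero crossing by -c/slope exactly
  for (cshift in c(6, -12)) {
    pc <- exact_profile()
    pc$mean_ha <- pc$mean_ha + cshift
    fc <- fit_ha_gradient(pc)
    expect_equal(fc$ha0, 50 - cshift / (-1.2), tolerance = 1e-9)
  }
})

test_that("handedness classification follows the 50 % rule", {
  expect_identical(classify_asymmetry(50.0), "symmetric")
  expect_identical(classify_asymmetry(75.1), "right-handed-dominant")
  expect_identical(classify_asymmetry(34.9), "left-handed-dominant")
  expect_identical(classify_asymmetry(NA_real_), "undefined")
})

test_that("slope comparison matches the hand formula and handles degeneracy", {
  mkfit <- function(slope, se, df) {
    structure(list(slope = slope, se_slope = se, df = df),
              class = "ha_gradient_fit")
  }
  f1 <- mkfit(-1.0, 0.1, 59)
  f2 <- mkfit(-0.5, 0.1, 59)
  sc <- compare_slopes(f1, f2)
  expect_equal(sc$t, -0.5 / sqrt(0.02), tolerance = 1e-10)
  expect_equal(sc$t, -3.5355339, tolerance = 1e-6)
  expect_equal(sc$df, 0.02^2 / (2 * 0.01^2 / 59), tolerance = 1e-10)
  expect_equal(sc$p, 2 * pt(-abs(sc$t), sc$df), tolerance = 1e-12)
  ## identical fits
  id <- compare_slopes(f1, f1)
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  ## zero-SE degeneracies
  z1 <- mkfit(-1.2, 0, 59)
  z2 <- mkfit(-1.0, 0, 59)
  expect_equal(compare_slopes(z1, z1)$p, 1)
  deg <- compare_slopes(z1, z2)
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
})

test_that("E2A group comparison reproduces opposing-sheet-angle detection", {
  ## identical samples: no difference
  x <- c(-3, 0, 5, 9)
  same <- compare_e2a(x, x)
  expect_equal(same$p, 1)
  expect_equal(same$mean_diff, 0)
  ## groups drawn at the study's septal means: detected at p < 0.001
  set.seed(20)
  a <- rnorm(500, 17, 18)
  b <- rnorm(500, -20, 49)
  res <- compare_e2a(a, b)
  expect_lt(res$p, 0.001)
  expect_gt(res$mean_a, 0)
  expect_lt(res$mean_b, 0)
  expect_error(compare_e2a(1, x), "at least 2")
})

test_that("the E2A test keeps its nominal type-I error under the null", {
  set.seed(99)
  p <- replicate(1000, compare_e2a(rnorm(50), rnorm(50))$p)
  expect_gt(mean(p < 0.05), 0.030)
  expect_lt(mean(p < 0.05), 0.070)
})

test_that("fitting the shorter window removes the transition-zone lack of fit", {
  ## situs-inversus-like wall: linear to 70 % depth, then constant
  spec <- phantom_spec(ha_transition_depth = 70, snr = Inf)
  rec <- recover_phantom(spec, scheme = std_scheme(), window = NULL)
  f_full <- fit_ha_gradient(rec$profile, window = c(20, 80))
  f_short <- fit_ha_gradient(rec$profile, window = c(20, 70))
  expect_lt(f_short$sigma2, f_full$sigma2)
})

test_that("group tables carry all five segments and round-trip as TSV", {
  mkcell <- function(slope, seed) {
    set.seed(seed)
    d <- 20:80
    y <- -50 * slope + slope * d + rnorm(61, 0, 2)  # crossing at 50 %
    vals <- rnorm(80, 10, 15)
    list(fit = fit_ha_gradient(data.frame(depth_pct = d, mean_ha = y)),
         e2a = list(mean = mean(vals), sd = sd(vals), n = length(vals)),
         e2a_values = vals)
  }
  segs <- c("anterior", "septum", "posterior", "lateral", "rv")
  res <- list(
    g1 = setNames(lapply(seq_along(segs), function(i) mkcell(-1.2, i)), segs),
    g2 = setNames(lapply(seq_along(segs), function(i) mkcell(-0.6, 10 + i)),
                  segs))
  tabs <- group_tables(res)
  expect_identical(names(tabs$gradient), c("group", segs))
  expect_false(anyNA(tabs$gradient[segs]))
  expect_true(all(grepl("\\[.*:.*\\]", unlist(tabs$asymmetry[segs]))))
  expect_identical(nrow(tabs$comparisons), 5L)
  ## CI strings normalized lower <= upper
  ci <- res$g1$anterior$fit$ha0_ci
  expect_lte(ci[1], ci[2])
  ## RV-only group: LV cells absent, RV present
  res2 <- list(uni = list(rv = mkcell(-0.4, 30)), g1 = res$g1)
  t2 <- group_tables(res2)
  expect_true(is.na(t2$gradient$anterior[t2$gradient$group == "uni"]))
  expect_false(is.na(t2$gradient$rv[t2$gradient$group == "uni"]))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(tabs$asymmetry, path)
  back <- read_result_table(path)
  expect_identical(back$septum, tabs$asymmetry$septum)
})
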