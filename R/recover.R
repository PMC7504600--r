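#' Simulate a phantom acquisition and recover its transmural HA profile
#'
#' One-call convenience chaining [build_phantom()], [simulate_dwi()],
#' [fit_tensor()], [angle_maps()] and [transmural_profile()] using the
#' phantom's analytic geometry (depth and frame), as used for recovery
#' studies and calibration simulations.
#'
#' @param spec A [phantom_spec()].
#' @param scheme A [gradient_scheme()]; default is the standard 36-volume
#'   half-shell scheme at b = 853 s/mm^2 (directions seeded from `spec`).
#' @param segment Segment id for the profile, or `NULL` to pool the wall.
#' @param window Fit window passed to [fit_ha_gradient()], or `NULL` to skip
#'   the fit.
#' @return List with `phantom`, `field` (tensor fit), `maps` (HA/E2A),
#'   `profile`, and `fit` (when `window` is given).
#' @export
recover_phantom <- function(spec, scheme = NULL, segment = NULL,
                            window = c(20, 80)) {
  if (is.null(scheme))
    scheme <- gradient_scheme(
      generate_half_shell_directions(32, seed = spec$seed))
  ph <- build_phantom(spec)
  dwi <- simulate_dwi(ph$truth, scheme, s0 = spec$s0, snr = spec$snr,
                      seed = spec$seed)
  field <- fit_tensor(dwi, scheme, ph$geometry$mask)
  maps <- angle_maps(field, ph$geometry)
  prof <- transmural_profile(maps$ha, ph$geometry$depth,
                             ph$geometry$labels, segment,
                             valid = maps$valid)
  fit <- if (!is.null(window)) fit_ha_gradient(prof, window = window)
  list(phantom = ph, field = field, maps = maps, profile = prof, fit = fit)
}
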