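#' Build a run configuration
#'
#' Assembles and validates the configuration of a full simulate-fit-angles
#' -statistics run. Configurations are plain lists and can be read from a
#' YAML file with [read_run_config()].
#'
#' @param specimens Named list: specimen id -> list of [phantom_spec()]
#'   arguments (each may carry its own `seed`; otherwise seeds derive from
#'   the run seed).
#' @param groups Named list: group name -> list with `ids` (character vector
#'   of specimen ids) and optional `window` (fit window, default
#'   `c(20, 80)`).
#' @param seed Base integer seed of the run.
#' @param scheme List of [gradient_scheme()] parameters: `n_directions`,
#'   `b`, `delta`, `Delta`, `b0_every`, `n_averages`.
#' @param min_proj Projection-norm floor below which angles are invalid.
#' @param alpha Significance threshold for table highlighting.
#' @return List of class `run_config`.
#' @export
run_config <- function(specimens, groups, seed = 0L,
                       scheme = list(), min_proj = 0.1, alpha = 0.01) {
  sdef <- list(n_directions = 32L, b = 853, delta = 20.67, Delta = 27.09,
               b0_every = 10L, n_averages = 2L)
  sdef[names(scheme)] <- scheme
  cfg <- list(specimens = specimens, groups = groups,
              seed = as.integer(seed), scheme = sdef,
              min_proj = min_proj, alpha = alpha)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (length(cfg$specimens) == 0 || is.null(names(cfg$specimens)))
    stop("config needs a named list of specimens")
  if (length(cfg$groups) == 0 || is.null(names(cfg$groups)))
    stop("config needs a named list of groups")
  for (g in names(cfg$groups)) {
    grp <- cfg$groups[[g]]
    missing_ids <- setdiff(grp$ids, names(cfg$specimens))
    if (length(missing_ids))
      stop(sprintf("group '%s' references missing specimen(s): %s", g,
                   paste(missing_ids, collapse = ", ")))
    w <- grp$window %||% c(20, 80)
    if (length(w) != 2 || w[1] < 0 || w[2] > 100 || w[1] >= w[2])
      stop(sprintf("group '%s': fit window must lie within [0, 100]", g))
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#' @param path YAML file with `specimens`, `groups`, and optional `seed`,
#'   `scheme`, `min_proj`, `alpha` entries.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(specimens = y$specimens, groups = y$groups,
             seed = y$seed %||% 0L, scheme = y$scheme %||% list(),
             min_proj = y$min_proj %||% 0.1, alpha = y$alpha %||% 0.01)
}

#' A small demonstration configuration
#'
#' Two synthetic groups of three annulus specimens each on a reduced grid:
#' one group with the default symmetric helix-angle law (zero crossing at
#' 50 % depth), one with a rightward-shifted law (crossing at 40 %), both
#' with the same transmural gradient.
#'
#' @param seed Base seed.
#' @param matrix_size In-plane grid size (reduced for speed).
#' @param snr Simulated signal-to-noise ratio.
#' @return A `run_config`.
#' @export
demo_config <- function(seed = 0L, matrix_size = 48L, snr = 25) {
  mk <- function(ha_endo, ha_epi, e2a, seed) {
    list(geometry = "annulus", matrix_size = matrix_size, n_slices = 1L,
         ha_endo = ha_endo, ha_epi = ha_epi, e2a = e2a,
         snr = snr, seed = seed)
  }
  specimens <- list(
    symA1 = mk(60, -60, 20, seed + 11), symA2 = mk(60, -60, 20, seed + 12),
    symA3 = mk(60, -60, 20, seed + 13),
    shiftB1 = mk(48, -72, -20, seed + 21),
    shiftB2 = mk(48, -72, -20, seed + 22),
    shiftB3 = mk(48, -72, -20, seed + 23))
  run_config(specimens = specimens,
             groups = list(
               symmetric = list(ids = c("symA1", "symA2", "symA3")),
               shifted = list(ids = c("shiftB1", "shiftB2", "shiftB3"))),
             seed = seed)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> write/read -> tensor fit -> geometry (transmural
#' depth and local frame recomputed from the written masks) -> HA/E2A maps
#' -> per-segment transmural profiles -> group-level HA-gradient fits,
#' asymmetries and E2A comparisons, writing every intermediate artifact and
#' a JSON log of parameters and seeds. Re-running with the same
#' configuration reproduces all outputs.
#'
#' @param cfg A `run_config`.
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the per-group fits and the result tables.
#' @export
run_pipeline <- function(cfg, out_dir, quiet = FALSE) {
  validate_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  sc <- cfg$scheme
  dirs <- generate_half_shell_directions(sc$n_directions, seed = cfg$seed)
  scheme <- gradient_scheme(dirs, b = sc$b, delta = sc$delta,
                            Delta = sc$Delta, b0_every = sc$b0_every,
                            n_averages = sc$n_averages)
  spec_out <- list()
  ids <- names(cfg$specimens)
  for (i in seq_along(ids)) {
    id <- ids[i]
    args <- cfg$specimens[[id]]
    args$seed <- args$seed %||% (cfg$seed + i)
    spec <- do.call(phantom_spec, args)
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed for specimen '%s': %s", what, id,
                     conditionMessage(e)), call. = FALSE))
    }
    say("specimen %s: simulating", id)
    ph <- stage("phantom", build_phantom(spec))
    dwi <- stage("simulate",
                 simulate_dwi(ph$truth, scheme, s0 = spec$s0,
                              snr = spec$snr, seed = spec$seed))
    sdir <- file.path(out_dir, "specimens", id)
    stage("write", write_phantom_dataset(dwi, scheme, ph, sdir))

    say("specimen %s: fitting", id)
    dat <- stage("read", read_dwi(file.path(sdir, "dwi.nii.gz"),
                                  file.path(sdir, "bvals"),
                                  file.path(sdir, "bvecs")))
    mask <- read_nifti_map(file.path(sdir, "mask.nii.gz"))$data > 0
    cavity <- read_nifti_map(file.path(sdir, "cavity.nii.gz"))$data
    labels <- stage("segments",
                    load_segments(file.path(sdir, "segments.nii.gz"),
                                  expected = sort(unique(
                                    ph$geometry$labels[ph$geometry$labels > 0]))))
    field <- stage("fit", fit_tensor(dat$data, dat$scheme, mask))

    say("specimen %s: geometry and angles", id)
    geom <- stage("geometry",
                  mask_geometry(mask, cavity, labels, dat$voxel_size))
    maps <- stage("angles", angle_maps(field, geom, min_proj = cfg$min_proj))
    metrics <- tensor_metrics(field)
    write_nifti_map(maps$ha, file.path(sdir, "ha.nii.gz"), dat$voxel_size)
    write_nifti_map(maps$e2a, file.path(sdir, "e2a.nii.gz"), dat$voxel_size)
    write_nifti_map(metrics$md, file.path(sdir, "md.nii.gz"), dat$voxel_size)
    write_nifti_map(metrics$fa, file.path(sdir, "fa.nii.gz"), dat$voxel_size)

    present <- sort(unique(labels[labels > 0]))
    profs <- lapply(present, function(s)
      transmural_profile(maps$ha, geom$depth, labels, s,
                         valid = maps$valid))
    prof <- do.call(rbind, profs)
    write_profile_tsv(prof, file.path(sdir, "profiles.tsv"))
    e2a_vals <- lapply(present, function(s)
      maps$e2a[labels == s & maps$valid & is.finite(maps$e2a)])
    names(e2a_vals) <- segment_names()[present]
    spec_out[[id]] <- list(profiles = prof, e2a_values = e2a_vals)
  }

  say("group statistics")
  results <- list()
  for (g in names(cfg$groups)) {
    grp <- cfg$groups[[g]]
    window <- grp$window %||% c(20, 80)
    cells <- list()
    pooled <- do.call(rbind, lapply(spec_out[grp$ids],
                                    function(s) s$profiles))
    for (s in sort(unique(pooled$segment))) {
      segname <- segment_names()[s]
      sub <- pooled[pooled$segment == s, ]
      fit <- fit_ha_gradient(sub, window = window)
      vals <- unlist(lapply(spec_out[grp$ids],
                            function(sp) sp$e2a_values[[segname]]))
      cells[[segname]] <- list(
        fit = fit,
        e2a = list(mean = mean(vals),
                   sd = if (length(vals) > 1) stats::sd(vals) else 0,
                   n = length(vals)),
        e2a_values = vals)
    }
    results[[g]] <- cells
  }
  tables <- group_tables(results, alpha = cfg$alpha)
  write_result_table(tables$gradient, file.path(out_dir, "ha_gradient.tsv"))
  write_result_table(tables$asymmetry, file.path(out_dir, "ha_asymmetry.tsv"))
  write_result_table(tables$e2a, file.path(out_dir, "e2a.tsv"))
  if (!is.null(tables$comparisons))
    write_result_table(tables$comparisons,
                       file.path(out_dir, "comparisons.tsv"))
  log <- list(package = "helixdti",
              version = as.character(utils::packageVersion("helixdti")),
              seed = cfg$seed, scheme = cfg$scheme,
              min_proj = cfg$min_proj, alpha = cfg$alpha,
              groups = lapply(cfg$groups, function(g)
                list(ids = g$ids, window = g$window %||% c(20, 80))))
  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, tables = tables, out_dir = out_dir))
}

#' Geometry (depth and frame) from masks and labels
#'
#' Reconstructs the transmural depth and local frame from a myocardium mask,
#' a cavity label map (1 = LV cavity, 2 = RV cavity) and the segment labels:
#' LV segments (1-4) are parameterized against the LV cavity, the RV free
#' wall (5) against the RV cavity, each via boundary extraction and the
#' Euclidean-distance-transform depth.
#'
#' @param mask Logical myocardium mask.
#' @param cavity Integer cavity label array (0 none, 1 LV, 2 RV).
#' @param labels Integer segment label array.
#' @param voxel_size Voxel dimensions, mm.
#' @return A list shaped like a `myocardial_geometry` (with `depth` and
#'   `frame` recomputed from the masks).
#' @export
mask_geometry <- function(mask, cavity, labels, voxel_size) {
  depth <- array(NA_real_, dim = dim(mask))
  walls <- list(list(sel = array(labels %in% 1:4, dim(mask)), cav = cavity == 1),
                list(sel = labels == 5, cav = cavity == 2))
  for (w in walls) {
    if (!any(w$sel)) next
    bnd <- extract_boundaries(w$sel, w$cav)
    depth[w$sel] <- compute_depth(w$sel, bnd$endo, bnd$epi,
                                  voxel_size)[w$sel]
  }
  frame <- local_frame(depth, mask, voxel_size)
  structure(list(mask = mask, cavity = cavity, labels = labels,
                 depth = depth, frame = frame, voxel_size = voxel_size),
            class = "myocardial_geometry")
}
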