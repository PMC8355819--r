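#' Run the full expiratory-dynamics analysis pipeline
#'
#' Orchestrates phantom generation (or input loading), end-inspiration
#' detection, phase-grid construction, downsampling, voxel-wise density and
#' SACJ exponential regression, whole-lung mechanics, and the regional
#' summary analyses, writing parameter maps, summary TSV tables, a JSON
#' report and a checksummed output manifest. Deterministic for a fixed
#' seed.
#'
#' Configuration entries (all optional unless noted):
#' \describe{
#'   \item{out_dir}{output directory (required).}
#'   \item{seed}{base RNG seed, default 1.}
#'   \item{conditions}{character subset of `c("baseline", "injured")`.}
#'   \item{phantom}{named list of [phantom_spec()] overrides (e.g.
#'     `grid_shape`, `n_phases`).}
#'   \item{inputs}{instead of `phantom`: named list with `sequence`,
#'     `mask`, `jacobian`, `trace` file paths plus `n_phases`,
#'     `respiratory_rate_per_min`, optionally `ie_ratio`,
#'     `end_insp_index_override`, `gravity_axis`.}
#'   \item{downsample_factor}{block size before regression, default 2.}
#'   \item{alpha}{F-filter significance level, default 0.05.}
#'   \item{prm_bin_hu}{PRM bin width, default 25.}
#'   \item{height_bins}{height-profile bin count, default 10.}
#' }
#'
#' @param config named list or path to a JSON file.
#' @return invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$out_dir)) stop("config must name 'out_dir'")
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  conditions <- if (is.null(config$conditions)) {
    c("baseline", "injured")
  } else config$conditions
  ds <- if (is.null(config$downsample_factor)) 2L else
    as.integer(config$downsample_factor)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  prm_bin <- if (is.null(config$prm_bin_hu)) 25 else config$prm_bin_hu
  height_bins <- if (is.null(config$height_bins)) 10 else
    config$height_bins

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (!is.null(config$inputs)) {
    for (f in unlist(config$inputs[c("sequence", "mask", "jacobian",
                                     "trace")])) {
      if (!is.null(f) && !file.exists(f)) {
        stop("stage 'validate' failed: missing input file: ", f)
      }
    }
  }

  report <- list(seed = seed, conditions = list())
  fit_tables <- list()
  sacj_tables <- list()

  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    cdir <- file.path(out_dir, cond)
    if (!dir.exists(cdir)) dir.create(cdir, recursive = TRUE)

    if (is.null(config$inputs)) {
      spec <- stage("phantom", do.call(phantom_spec, c(
        list(condition = cond, seed = seed + 100L * ci),
        config$phantom)))
      ph <- stage("phantom", write_phantom(spec, file.path(cdir, "phantom")))
      seq_full <- ph$sequence
      trace <- ph$trace
      defo <- stage("deformation",
                    render_deformation(ph$truth, spec, "analytic-jacobian"))
      gravity_axis <- spec$gravity_axis
    } else {
      inp <- config$inputs
      grid0 <- build_phase_grid(inp$n_phases, inp$respiratory_rate_per_min,
                                if (is.null(inp$ie_ratio)) c(1, 2) else
                                  inp$ie_ratio, 1L)
      seq_full <- stage("load", load_sequence(inp$sequence, inp$mask,
                                              grid0))
      jac <- stage("load", RNifti::readNifti(inp$jacobian))
      trace <- stage("load", read_trace_csv(inp$trace))
      defo <- structure(list(mode = "analytic-jacobian",
                             jacobian = unclass(jac),
                             reference_phase = 1L, grid = grid0,
                             spacing_mm = seq_full$spacing_mm),
                        class = "deformation_set")
      gravity_axis <- if (is.null(inp$gravity_axis)) 2L else
        inp$gravity_axis
    }

    end_insp <- stage("timing", {
      if (!is.null(config$end_insp_index_override)) {
        as.integer(config$end_insp_index_override)
      } else {
        detect_end_inspiration(seq_full)
      }
    })
    grid <- stage("timing", build_phase_grid(
      dim(seq_full$intensity)[4],
      seq_full$grid$respiratory_rate_per_min,
      seq_full$grid$ie_ratio, end_insp))
    seq_full$grid <- grid

    seq_ds <- stage("downsample", block_downsample(seq_full, ds))
    fits <- stage("fit_density", fit_all_voxels(seq_ds, grid,
                                                alpha = alpha))
    stage("fit_density", write_parameter_maps(fits, cdir, "density"))

    # downsample the Jacobian stack identically to the intensities
    defo_ds <- defo
    if (ds > 1) {
      jac4 <- defo$jacobian
      m <- dim(jac4)[1:3] %/% ds
      vols <- lapply(seq_len(dim(jac4)[4]), function(p) {
        .block_reduce3d(jac4[, , , p], ds)
      })
      defo_ds$jacobian <- array(unlist(vols, use.names = FALSE),
                                c(m, dim(jac4)[4]))
    }
    sacj <- stage("sacj", sacj_series(seq_ds, defo_ds, grid))
    sacj_fits <- stage("sacj", fit_sacj_time_constants(sacj, alpha))
    stage("sacj", write_parameter_maps(sacj_fits, cdir, "sacj"))

    mech <- stage("mechanics", fit_volume_time_constant(trace))

    fractions <- stage("regional",
                       class_volume_fractions(classify_aeration(fits$d_ee)))
    tau_by_class <- stage("regional", group_tau_by_class(
      fits, classify_aeration(fits$d_ee)))
    hp <- stage("regional", height_profile(fits, seq_ds$mask,
                                           gravity_axis,
                                           n_bins = height_bins))
    conv <- stage("regional", normalized_convergence(fits))

    utils::write.table(tau_by_class,
                       file.path(cdir, "tau_by_class.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(hp),
                       file.path(cdir, "height_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    fit_tables[[cond]] <- fits
    sacj_tables[[cond]] <- sacj_fits
    report$conditions[[cond]] <- list(
      n_masked_voxels = nrow(fits),
      excluded_fraction = mean(!fits$significant),
      class_volume_fractions = as.list(fractions),
      tau_volume_s = mech$tau_volume_s,
      driving_pressure_cmh2o = mech$driving_pressure_cmh2o,
      tidal_volume_l = mech$tidal_volume_l,
      dynamic_elastance_cmh2o_per_l = mech$dynamic_elastance_cmh2o_per_l,
      tau_density_median_s =
        stats::median(fits$tau_s[fits$significant], na.rm = TRUE),
      tau_sacj_median_s =
        stats::median(sacj_fits$tau_s[sacj_fits$significant],
                      na.rm = TRUE),
      convergence_points = nrow(conv$points)
    )
  }

  for (cond in conditions) {
    prm <- stage("regional", build_prm(fit_tables[[cond]],
                                       bin_width_hu = prm_bin))
    prm_df <- data.frame(
      i = rep(seq_len(nrow(prm$probability)), ncol(prm$probability)),
      j = rep(seq_len(ncol(prm$probability)),
              each = nrow(prm$probability)),
      probability = as.vector(prm$probability),
      median_tau_s = as.vector(prm$median_tau_s),
      included = as.vector(prm$inclusion_mask))
    utils::write.table(prm_df[prm_df$probability > 0, ],
                       file.path(out_dir, cond, "prm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  corr <- stage("regional", tau_correlation(fit_tables, sacj_tables))
  report$tau_correlation <- list(
    fraction_significant = corr$fraction_significant,
    per_subject = corr$per_subject)

  tcd <- stage("regional", {
    g <- attr(fit_tables[[1]], "grid")
    times <- g$expiratory_times_s[
      unique(round(seq(1, length(g$expiratory_times_s), length.out = 5)))]
    lapply(fit_tables, time_course_distributions, times_s = times)
  })
  for (cond in names(tcd)) {
    utils::write.table(tcd[[cond]],
                       file.path(out_dir, cond, "time_course.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("lungtau")),
    seed = seed,
    files = lapply(stats::setNames(files, substring(
      files, nchar(out_dir) + 2)), function(f) {
        list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))
      }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
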