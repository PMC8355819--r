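#' Construct an aligned 4D sequence
#'
#' Container for a registered 4DCT sequence: every phase has been deformed
#' into the geometry of a single reference (end-inspiratory) phase, so a
#' voxel indexes the same piece of tissue at every phase.
#'
#' @param intensity 4D numeric array (X, Y, Z, phase) of HU intensities.
#' @param spacing_mm length-3 positive numeric, voxel size per axis.
#' @param mask 3D logical array, lung mask in reference geometry.
#' @param grid a [build_phase_grid()] object; its phase count must match.
#' @return object of class `aligned_sequence`.
#' @export
aligned_sequence <- function(intensity, spacing_mm, mask, grid) {
  if (length(dim(intensity)) != 4) {
    stop("'intensity' must be a 4D array (X, Y, Z, phase); got ",
         length(dim(intensity)), " dimensions")
  }
  if (length(dim(mask)) != 3 ||
      !all(dim(mask) == dim(intensity)[1:3])) {
    stop("'mask' must be a 3D array matching the spatial grid of 'intensity'")
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("lung mask is empty (0 voxels)")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("'spacing_mm' must be 3 positive voxel sizes")
  }
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "breath_phase_grid"))
    if (grid$n_phases != dim(intensity)[4]) {
      stop(sprintf("phase grid has %d phases but sequence has %d",
                   grid$n_phases, dim(intensity)[4]))
    }
  }
  nvox <- prod(dim(mask))
  idx <- which(mask)
  for (p in seq_len(dim(intensity)[4])) {
    bad <- sum(!is.finite(intensity[(p - 1L) * nvox + idx]))
    if (bad > 0) {
      stop(sprintf("non-finite intensities inside the mask: %d voxels at phase %d",
                   bad, p))
    }
  }
  structure(list(intensity = intensity, spacing_mm = spacing_mm,
                 mask = mask, grid = grid),
            class = "aligned_sequence")
}

#' @export
print.aligned_sequence <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("Aligned 4DCT sequence: %d x %d x %d voxels, %d phases\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %.3g x %.3g x %.3g mm, %d masked voxels\n",
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              sum(x$mask)))
  invisible(x)
}

.write_nifti <- function(arr, spacing_mm, path, time_step_s = 1) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  pd <- if (nd == 4) c(spacing_mm, time_step_s) else spacing_mm
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load and validate an aligned sequence from NIfTI files
#'
#' Reads a 4D HU sequence and its 3D lung mask, validates geometry and
#' finiteness, and reports the voxel count in each aeration class at the
#' reference (end-inspiratory) phase.
#'
#' @param path 4D NIfTI file (X, Y, Z, phase).
#' @param mask_path 3D NIfTI lung mask (nonzero = lung).
#' @param grid a [build_phase_grid()] timing object.
#' @return an [aligned_sequence].
#' @export
load_sequence <- function(path, mask_path, grid) {
  for (f in c(path, mask_path)) {
    if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(mask_path)
  if (length(dim(img)) != 4) {
    stop("expected a 4D sequence (X, Y, Z, phase) but '", path, "' has ",
         length(dim(img)), " dimensions")
  }
  if (length(dim(msk)) != 3) {
    stop("expected a 3D mask but '", mask_path, "' has ",
         length(dim(msk)), " dimensions")
  }
  if (!all(dim(msk) == dim(img)[1:3])) {
    stop(sprintf("mask grid (%s) does not match sequence grid (%s)",
                 paste(dim(msk), collapse = "x"),
                 paste(dim(img)[1:3], collapse = "x")))
  }
  sp_img <- RNifti::pixdim(img)[1:3]
  sp_msk <- RNifti::pixdim(msk)[1:3]
  if (any(abs(sp_img - sp_msk) > 1e-4 * pmax(sp_img, 1))) {
    stop(sprintf("voxel spacing mismatch between sequence (%s mm) and mask (%s mm)",
                 paste(signif(sp_img, 4), collapse = "x"),
                 paste(signif(sp_msk, 4), collapse = "x")))
  }
  seq <- aligned_sequence(unclass(img)[, , , , drop = FALSE], sp_img,
                          array(msk != 0, dim(msk)), grid)
  ref <- if (is.null(grid)) 1L else grid$end_insp_index
  nvox <- prod(dim(seq$mask))
  ref_hu <- seq$intensity[(ref - 1L) * nvox + which(seq$mask)]
  tab <- table(classify_aeration(ref_hu))
  message("loaded sequence; reference-phase aeration classes: ",
          paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                collapse = ", "))
  seq
}

#' Write per-voxel regression products as NIfTI maps and a TSV table
#'
#' Produces one 3D NIfTI map per fitted quantity (initial density D0,
#' equilibrium density Dinf, time constant tau, intratidal change,
#' nonequilibrated change, and the regression p-value), with voxels excluded
#' by the F-filter (and voxels outside the mask) encoded as `NaN`, plus a
#' long-format TSV of the full per-voxel fit table.
#'
#' @param fits a `voxel_fit_table` from [fit_all_voxels()].
#' @param out_dir output directory (created if missing).
#' @param prefix filename prefix (default `"fit"`).
#' @return invisibly, a named character vector of file paths.
#' @export
write_parameter_maps <- function(fits, out_dir, prefix = "fit") {
  stopifnot(inherits(fits, "voxel_fit_table"))
  dims <- attr(fits, "vol_dim")
  spacing <- attr(fits, "spacing_mm")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  fields <- c(d0 = "d0", dinf = "dinf", tau = "tau_s",
              intratidal = "intratidal_change",
              nonequilibrated = "nonequilibrated_change",
              p_value = "p_value")
  sig <- fits$significant & !is.na(fits$tau_s)
  paths <- character(0)
  for (nm in names(fields)) {
    vol <- array(NaN, dims)
    if (nm == "p_value") {
      vol[fits$voxel] <- fits[[fields[[nm]]]]
    } else {
      vol[fits$voxel[sig]] <- fits[[fields[[nm]]]][sig]
    }
    f <- file.path(out_dir, sprintf("%s_%s.nii.gz", prefix, nm))
    .write_nifti(vol, spacing, f)
    paths[nm] <- f
  }
  tsv <- file.path(out_dir, sprintf("%s_voxels.tsv", prefix))
  utils::write.table(as.data.frame(fits), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["table"] <- tsv
  invisible(paths)
}

#' Write a ventilator waveform trace as CSV
#'
#' Column layout: `time_s,pressure_cmh2o,volume_ml` (comma-separated,
#' header row, UTF-8).
#'
#' @param trace a `ventilator_trace` data frame.
#' @param path output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace[, c("time_s", "pressure_cmh2o", "volume_ml")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ventilator waveform trace from CSV
#'
#' Reconstructs the sampling rate from the time column and the pressure
#' levels (P_insp, PEEP) from the square-wave extremes.
#'
#' @param path CSV with columns `time_s,pressure_cmh2o,volume_ml`.
#' @return a `ventilator_trace` data frame.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "pressure_cmh2o", "volume_ml")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns ", paste(need, collapse = ", "))
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("trace time must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * stats::median(dt)) {
    stop("trace must be sampled at a constant interval")
  }
  ventilator_trace(df$time_s, df$pressure_cmh2o, df$volume_ml)
}

ventilator_trace <- function(time_s, pressure_cmh2o, volume_ml,
                             peep_cmh2o = min(pressure_cmh2o),
                             p_insp_cmh2o = max(pressure_cmh2o)) {
  df <- data.frame(time_s = time_s, pressure_cmh2o = pressure_cmh2o,
                   volume_ml = volume_ml)
  attr(df, "sample_rate_hz") <- 1 / stats::median(diff(time_s))
  attr(df, "peep_cmh2o") <- peep_cmh2o
  attr(df, "p_insp_cmh2o") <- p_insp_cmh2o
  class(df) <- c("ventilator_trace", "data.frame")
  df
}

#' Read a run configuration from JSON
#'
#' @param path JSON file of pipeline settings; see [run_pipeline()].
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
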