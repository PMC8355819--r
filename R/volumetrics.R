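# central differences along one axis of a 3D array, one-sided at the ends,
# scaled by the voxel spacing; exact for fields linear in position
.grad3d <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  ip <- c(2:n, n)      # forward neighbour (clamped)
  im <- c(1, 1:(n - 1)) # backward neighbour (clamped)
  den <- rep(2 * h, n)
  den[1] <- h
  den[n] <- h
  sl <- function(i) switch(axis,
                           a[i, , , drop = FALSE],
                           a[, i, , drop = FALSE],
                           a[, , i, drop = FALSE])
  g <- (sl(ip) - sl(im))
  den_full <- switch(axis,
                     array(rep(den, times = d[2] * d[3]), dim = d),
                     aperm(array(rep(den, times = d[1] * d[3]),
                                 dim = c(d[2], d[1], d[3])), c(2, 1, 3)),
                     aperm(array(rep(den, times = d[1] * d[2]),
                                 dim = c(d[3], d[1], d[2])), c(2, 3, 1)))
  array(g, dim = d) / den_full
}

#' Jacobian determinant of a displacement field
#'
#' Computes `J = det(I + grad(u))` for a 3-vector displacement field `u`
#' (mm) on the voxel grid, using second-order central differences in the
#' interior and one-sided differences at the grid boundary. The scheme is
#' exact for affine displacement fields. `J` is the ratiometric volume
#' change of each voxel relative to the reference configuration; nonpositive
#' values inside the mask indicate folding and trigger a warning (values
#' are retained).
#'
#' @param displacement 4D array (X, Y, Z, component) of displacements in
#'   mm.
#' @param spacing_mm length-3 voxel size in mm.
#' @param mask optional 3D logical array; only used for the folding check.
#' @return 3D array of Jacobian determinants.
#' @export
jacobian_from_displacement <- function(displacement, spacing_mm,
                                       mask = NULL) {
  d <- dim(displacement)
  if (length(d) != 4 || d[4] != 3) {
    stop("'displacement' must be a 4D array (X, Y, Z, 3)")
  }
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  g <- vector("list", 9)
  dim(g) <- c(3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      g[[i, j]] <- .grad3d(displacement[, , , i], j, spacing_mm[j])
      if (i == j) g[[i, j]] <- g[[i, j]] + 1
    }
  }
  J <- g[[1, 1]] * (g[[2, 2]] * g[[3, 3]] - g[[2, 3]] * g[[3, 2]]) -
    g[[1, 2]] * (g[[2, 1]] * g[[3, 3]] - g[[2, 3]] * g[[3, 1]]) +
    g[[1, 3]] * (g[[2, 1]] * g[[3, 2]] - g[[2, 2]] * g[[3, 1]])
  J <- array(J, d[1:3])
  if (!is.null(mask)) {
    n_fold <- sum(J[mask] <= 0)
    if (n_fold > 0) {
      warning(sprintf("nonpositive Jacobian inside the mask at %d voxels (folding)",
                      n_fold))
    }
  }
  J
}

#' Specific air volume change by corrected Jacobian (SACJ)
#'
#' `SACJ_n = J_n0 * (I_n / I_0) - 1`, the relative change in voxel gas
#' volume between phase n and the end-inspiratory reference, under the
#' two-compartment assumption that gas and tissue exhibit CT intensities of
#' -1000 and 0 HU. Intensities are clamped to [-1000, 0] HU before use;
#' voxels with no gas at the reference phase (I_0 >= 0 after clamping) are
#' undefined, returned as `NA`, and counted in a message. SACJ is zero at
#' the reference phase and negative where gas volume is lost.
#'
#' @param J Jacobian determinants `J_n0` (array or vector).
#' @param I_n HU intensities at phase n (same shape).
#' @param I_0 HU intensities at the reference phase (same shape).
#' @return SACJ values, same shape as the inputs.
#' @export
compute_sacj <- function(J, I_n, I_0) {
  i0 <- pmin(pmax(I_0, -1000), 0)
  ino <- pmin(pmax(I_n, -1000), 0)
  bad <- i0 >= 0
  sacj <- J * (ino / i0) - 1
  if (any(bad, na.rm = TRUE)) {
    sacj[bad] <- NA_real_
    message(sprintf("SACJ undefined for %d gas-free voxels (I0 >= 0 HU); excluded",
                    sum(bad, na.rm = TRUE)))
  }
  if (is.array(I_n)) sacj <- array(sacj, dim(I_n))
  sacj
}

#' Build the per-voxel SACJ series over the expiratory phases
#'
#' @param seq an [aligned_sequence].
#' @param defo a `deformation_set` carrying either a 4D `jacobian` stack or
#'   a `displacement` field stack (Jacobians are then computed with
#'   [jacobian_from_displacement()]).
#' @param grid a [build_phase_grid()]; defaults to the grid of `seq`.
#' @return object of class `sacj_series`: matrix `sacj` (voxel x expiratory
#'   phase; reference column exactly 0), `times_s`, `voxel` (linear
#'   indices), and `gas_free` (logical, voxels excluded for lacking gas at
#'   reference).
#' @export
sacj_series <- function(seq, defo, grid = seq$grid) {
  stopifnot(inherits(seq, "aligned_sequence"),
            inherits(defo, "deformation_set"))
  idx <- which(seq$mask)
  nvox <- prod(dim(seq$mask))
  phases <- grid$expiratory_phase_indices
  ref <- grid$end_insp_index
  jac_at <- function(k) {
    if (!is.null(defo$jacobian)) {
      defo$jacobian[(k - 1L) * nvox + idx]
    } else {
      J <- jacobian_from_displacement(defo$displacement[, , , , k],
                                      defo$spacing_mm, seq$mask)
      J[idx]
    }
  }
  i0 <- seq$intensity[(ref - 1L) * nvox + idx]
  i0c <- pmin(pmax(i0, -1000), 0)
  gas_free <- i0c >= 0
  out <- matrix(NA_real_, length(idx), length(phases))
  for (p in seq_along(phases)) {
    k <- phases[p]
    if (k == ref) {
      out[, p] <- 0
    } else {
      out[, p] <- suppressMessages(
        compute_sacj(jac_at(k), seq$intensity[(k - 1L) * nvox + idx], i0))
    }
  }
  out[gas_free, ] <- NA_real_
  if (any(gas_free)) {
    message(sprintf("SACJ series excludes %d gas-free voxels", sum(gas_free)))
  }
  structure(list(sacj = out, times_s = grid$expiratory_times_s,
                 voxel = idx, gas_free = gas_free, grid = grid,
                 vol_dim = dim(seq$mask), spacing_mm = seq$spacing_mm),
            class = "sacj_series")
}

#' Fit exhalation time constants to the SACJ series
#'
#' Applies the same exponential regression and F-filter used for density to
#' the per-voxel SACJ trajectories; the initial value is estimated freely
#' (not pinned to the definitional SACJ = 0 at end-inspiration), exactly as
#' for density. Output rows align with the voxel order of the series so
#' density and SACJ fits can be paired.
#'
#' @param series an [sacj_series()].
#' @param alpha per-voxel significance level.
#' @return a `voxel_fit_table` (see [fit_all_voxels()]); `tau_s` is the
#'   SACJ time constant.
#' @export
fit_sacj_time_constants <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "sacj_series"))
  ok <- !series$gas_free
  if (!any(ok)) stop("no voxels with defined SACJ")
  df_all <- data.frame(voxel = series$voxel)
  fits <- .vp_fit_matrix(series$times_s, t(series$sacj[ok, , drop = FALSE]),
                         series$grid$t_exp_s)
  ft <- .f_test(fits$sse_mean, fits$sse_model, length(series$times_s))
  fits$f_stat <- ft$f_stat
  fits$p_value <- ft$p_value
  fits$significant <- ft$p_value <= alpha
  coords <- arrayInd(series$voxel[ok], series$vol_dim)
  out <- cbind(data.frame(voxel = series$voxel[ok],
                          x = coords[, 1], y = coords[, 2],
                          z = coords[, 3]), fits)
  attr(out, "vol_dim") <- series$vol_dim
  attr(out, "spacing_mm") <- series$spacing_mm
  attr(out, "grid") <- series$grid
  attr(out, "alpha") <- alpha
  attr(out, "signal") <- "sacj"
  class(out) <- c("voxel_fit_table", "data.frame")
  out
}

#' Model-predicted relative gas-volume change at given expiratory times
#'
#' Evaluates the fitted exponential trajectory of each voxel at the
#' requested times; with SACJ fits the value is the relative gas-volume
#' change from end-inspiration. Times outside the fitted expiratory window
#' are allowed but flagged as extrapolation.
#'
#' @param fits a `voxel_fit_table` (typically from
#'   [fit_sacj_time_constants()]).
#' @param times_s expiratory times at which to evaluate (>= 0).
#' @param t_exp_s exhalation duration; defaults to the grid attached to
#'   `fits`.
#' @return matrix (voxel x time) with attribute `extrapolated` (logical per
#'   time).
#' @export
relative_gas_volume_trajectory <- function(fits, times_s,
                                           t_exp_s = attr(fits, "grid")$t_exp_s) {
  stopifnot(inherits(fits, "voxel_fit_table"))
  pred <- vapply(times_s, function(t) {
    ifelse(is.na(fits$tau_s), fits$d0,
           fits$dinf + (fits$d0 - fits$dinf) * exp(-t / fits$tau_s))
  }, numeric(nrow(fits)))
  pred <- matrix(pred, nrow = nrow(fits))
  extrap <- times_s < 0 | times_s > t_exp_s
  if (any(extrap)) {
    message(sprintf("%d of %d requested times lie outside [0, %.3f] s (extrapolation)",
                    sum(extrap), length(times_s), t_exp_s))
  }
  attr(pred, "extrapolated") <- extrap
  pred
}
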