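#' Block-mean downsampling of an aligned sequence
#'
#' Before voxel-wise regression the sequence is downsampled by block
#' averaging to reduce the influence of noise on parameter estimation
#' (factor 2 halves the grid per axis and divides the noise SD by
#' sqrt(8)). The mask is downsampled by majority vote (a block stays in the
#' mask when at least half of its child voxels are masked). Axes not
#' divisible by the factor are cropped to the largest multiple.
#'
#' @param seq an [aligned_sequence].
#' @param factor positive integer block size per axis; 1 is the identity.
#' @return a downsampled [aligned_sequence] with spacing scaled by `factor`.
#' @export
block_downsample <- function(seq, factor = 2L) {
  stopifnot(inherits(seq, "aligned_sequence"))
  factor <- as.integer(factor)
  if (factor < 1) stop("'factor' must be a positive integer")
  if (factor == 1) return(seq)
  d <- dim(seq$intensity)[1:3]
  if (any(factor > d)) {
    stop(sprintf("downsampling factor %d exceeds grid extent (%s)",
                 factor, paste(d, collapse = "x")))
  }
  n_phases <- dim(seq$intensity)[4]
  m <- d %/% factor
  vols <- lapply(seq_len(n_phases), function(p) {
    .block_reduce3d(seq$intensity[, , , p], factor)
  })
  intensity <- array(unlist(vols, use.names = FALSE), c(m, n_phases))
  mask <- .block_reduce3d(seq$mask + 0, factor) >= 0.5
  aligned_sequence(intensity, seq$spacing_mm * factor,
                   array(mask, m), seq$grid)
}

.block_reduce3d <- function(a, f) {
  d <- dim(a)
  m <- d %/% f
  a <- a[seq_len(m[1] * f), seq_len(m[2] * f), seq_len(m[3] * f),
         drop = FALSE]
  dim(a) <- c(f, m[1], f, m[2], f, m[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(f^3, prod(m))
  out <- colMeans(a)
  dim(out) <- m
  out
}

# Vectorized variable-projection least squares for the exhalation model
#   I(t) = Dinf + (D0 - Dinf) * exp(-t / tau)
# For fixed tau the model is linear in (Dinf, A = D0 - Dinf); the profiled
# SSE is scanned over log10(tau) on a 0.01-decade lattice and refined per
# voxel by golden-section search. Deterministic: fixed grid, no randomness.
# Y: n x V matrix (one column per voxel). Returns a data.frame.
.vp_fit_matrix <- function(times, Y, t_exp_s,
                           log10_tau_bounds = c(-3, 2),
                           grid_step = 0.01, golden_iter = 45L) {
  n <- length(times)
  if (n < 4) stop("need at least 4 samples (3 parameters + 1 dof)")
  if (abs(times[1]) > 1e-9) stop("times must start at 0 (end-inspiration)")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  Y <- as.matrix(Y)
  V <- ncol(Y)

  ybar <- colMeans(Y)
  Yc <- sweep(Y, 2, ybar)          # centering: intercept absorbs the shift
  Syy <- colSums(Yc^2)
  sse_mean <- Syy

  const <- sse_mean <= n * 1e-18 * pmax(ybar^2, 1)

  # profiled SSE at a given per-voxel (or scalar) tau; returns list
  sse_at <- function(tau) {
    if (length(tau) == 1) {
      x <- exp(-times / tau)
      Sx <- sum(x); Sxx <- sum(x^2)
      Sxy <- as.numeric(crossprod(x, Yc))
      den <- n * Sxx - Sx^2
      if (den > n * 1e-12) {
        A <- n * Sxy / den
      } else {
        A <- numeric(V)
      }
    } else {
      X <- exp(-outer(times, 1 / tau))
      Sx <- colSums(X); Sxx <- colSums(X^2)
      Sxy <- colSums(X * Yc)
      den <- n * Sxx - Sx^2
      A <- ifelse(den > n * 1e-12, n * Sxy / den, 0)
    }
    dinf_c <- -A * Sx / n
    sse <- Syy - A * Sxy
    bad <- A == 0
    sse[bad] <- Syy[bad]
    list(sse = pmax(sse, 0), A = A, dinf_c = dinf_c)
  }

  lg <- seq(log10_tau_bounds[1], log10_tau_bounds[2], by = grid_step)
  best_sse <- Syy
  best_lg <- rep(NA_real_, V)
  for (l in lg) {
    r <- sse_at(10^l)
    upd <- r$sse < best_sse
    if (any(upd)) {
      best_sse[upd] <- r$sse[upd]
      best_lg[upd] <- l
    }
  }
  no_fit <- is.na(best_lg)
  best_lg[no_fit] <- mean(log10_tau_bounds)

  # golden-section refinement of log10(tau) per voxel
  gr <- (sqrt(5) - 1) / 2
  a <- pmax(best_lg - grid_step, log10_tau_bounds[1])
  b <- pmin(best_lg + grid_step, log10_tau_bounds[2])
  c1 <- b - gr * (b - a)
  c2 <- a + gr * (b - a)
  f1 <- sse_at(10^c1)$sse
  f2 <- sse_at(10^c2)$sse
  for (i in seq_len(golden_iter)) {
    left <- f1 < f2
    b[left] <- c2[left]
    a[!left] <- c1[!left]
    c1 <- b - gr * (b - a)
    c2 <- a + gr * (b - a)
    f1 <- sse_at(10^c1)$sse
    f2 <- sse_at(10^c2)$sse
  }
  lg_ref <- (a + b) / 2
  r_ref <- sse_at(10^lg_ref)

  # keep the better of grid optimum and refined optimum
  r_grid <- sse_at(10^best_lg)
  use_ref <- r_ref$sse <= r_grid$sse
  tau <- 10^ifelse(use_ref, lg_ref, best_lg)
  sse_model <- ifelse(use_ref, r_ref$sse, r_grid$sse)
  A <- ifelse(use_ref, r_ref$A, r_grid$A)
  dinf <- ifelse(use_ref, r_ref$dinf_c, r_grid$dinf_c) + ybar
  d0 <- dinf + A

  at_bound <- abs(log10(tau) - log10_tau_bounds[1]) < 2 * grid_step |
    abs(log10(tau) - log10_tau_bounds[2]) < 2 * grid_step

  tau[const | no_fit] <- NA_real_
  d0[const] <- ybar[const]
  dinf[const] <- ybar[const]
  sse_model[const] <- sse_mean[const]
  at_bound[const | no_fit] <- FALSE

  d_ee <- ifelse(is.na(tau), dinf,
                 dinf + (d0 - dinf) * exp(-t_exp_s / tau))
  data.frame(
    d0 = d0, dinf = dinf, tau_s = tau,
    sse_model = sse_model, sse_mean = sse_mean,
    at_bound = at_bound,
    d_ee = d_ee,
    intratidal_change = d_ee - d0,
    nonequilibrated_change = dinf - d_ee
  )
}

.f_test <- function(sse_mean, sse_model, n_samples) {
  if (n_samples <= 3) stop("F test needs more than 3 samples")
  df2 <- n_samples - 3
  f <- pmax(sse_mean - sse_model, 0) / 2 / (sse_model / df2)
  f[sse_model <= 0 & sse_mean > 0] <- Inf
  f[sse_mean <= 0] <- 0
  p <- ifelse(is.infinite(f), 0,
              stats::pf(f, 2, df2, lower.tail = FALSE))
  p[sse_mean <= 0] <- 1
  list(f_stat = f, p_value = p)
}

#' F-test for the contribution of the exponential regression
#'
#' Compares the 3-parameter exponential model against the mean-only model:
#' `F = ((sse_mean - sse_model) / 2) / (sse_model / (n - 3))`, referred to
#' the F distribution with (2, n - 3) degrees of freedom. Voxels with
#' p > alpha are excluded from further analysis. A perfect fit
#' (`sse_model = 0`) gives p = 0; no improvement gives F = 0, p = 1.
#'
#' @param fit a list or data frame with `sse_mean` and `sse_model`
#'   (e.g. a [fit_exponential()] result or rows of a fit table).
#' @param n_samples number of time points used in the regression (> 3).
#' @return list with vectors `f_stat` and `p_value`.
#' @export
f_significance <- function(fit, n_samples) {
  .f_test(fit$sse_mean, fit$sse_model, n_samples)
}

#' Fit the exhalation exponential to a single time series
#'
#' Least-squares fit of `I(t) = D0 + (Dinf - D0) * (1 - exp(-t / tau))` to
#' any scalar expiratory series (CT density, SACJ, exhaled volume).
#' Estimation is deterministic: the time constant is profiled over a fixed
#' log-spaced lattice (bounds 1e-3 to 1e2 s) and refined by golden-section
#' search; the linear parameters are solved exactly at each candidate tau.
#' Estimates at the tau bounds are flagged `at_bound`.
#'
#' @param times_s expiratory times, starting at 0, strictly increasing
#'   (>= 4 samples).
#' @param values observed series at `times_s`.
#' @param t_exp_s exhalation duration used for the derived end-expiratory
#'   prediction `d_ee`; defaults to the last sample time.
#' @param alpha significance level of the F-filter.
#' @return object of class `voxel_exp_fit`: `d0`, `dinf`, `tau_s`,
#'   `sse_model`, `sse_mean`, `f_stat`, `p_value`, `significant`,
#'   `at_bound`, `d_ee`, `intratidal_change`, `nonequilibrated_change`,
#'   `n`, `t_exp_s`.
#' @export
fit_exponential <- function(times_s, values, t_exp_s = max(times_s),
                            alpha = 0.05) {
  if (length(values) != length(times_s)) {
    stop("'times_s' and 'values' must have equal length")
  }
  df <- .vp_fit_matrix(times_s, matrix(values, ncol = 1), t_exp_s)
  ft <- .f_test(df$sse_mean, df$sse_model, length(times_s))
  out <- c(as.list(df[1, ]),
           list(f_stat = ft$f_stat[1], p_value = ft$p_value[1],
                significant = ft$p_value[1] <= alpha,
                n = length(times_s), t_exp_s = t_exp_s))
  class(out) <- "voxel_exp_fit"
  out
}

#' @export
print.voxel_exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit: D0 = %.2f, Dinf = %.2f, tau = %s s\n",
              x$d0, x$dinf,
              if (is.na(x$tau_s)) "NA" else sprintf("%.4f", x$tau_s)))
  cat(sprintf("  F = %.3g, p = %.3g (%ssignificant), n = %d\n",
              x$f_stat, x$p_value, if (x$significant) "" else "not ",
              x$n))
  invisible(x)
}

#' Fit the exhalation exponential to every masked voxel
#'
#' Extracts the expiratory samples (including the end-inspiratory t = 0
#' anchor) of every masked voxel, fits the exponential model by vectorized
#' variable projection, applies the F-filter, and reports the excluded
#' fraction together with its aeration-class composition (excluded voxels
#' are classified by their observed end-expiratory intensity).
#'
#' @param seq an [aligned_sequence] (downsample first; see
#'   [block_downsample()]).
#' @param grid a [build_phase_grid()]; defaults to the grid attached to
#'   `seq`.
#' @param mask optional logical array overriding `seq$mask`.
#' @param alpha per-voxel significance level (no multiple-testing
#'   correction, configurable).
#' @return a `voxel_fit_table`: data frame with `voxel` (linear index),
#'   `x`, `y`, `z`, the model parameters and diagnostics of
#'   [fit_exponential()], plus attributes `dim`, `spacing_mm`, `grid`,
#'   `alpha`.
#' @export
fit_all_voxels <- function(seq, grid = seq$grid, mask = seq$mask,
                           alpha = 0.05) {
  stopifnot(inherits(seq, "aligned_sequence"),
            inherits(grid, "breath_phase_grid"))
  idx <- which(mask)
  if (length(idx) == 0) stop("mask is empty")
  nvox <- prod(dim(mask))
  times <- grid$expiratory_times_s
  phases <- grid$expiratory_phase_indices
  Y <- vapply(phases, function(p) seq$intensity[(p - 1L) * nvox + idx],
              numeric(length(idx)))
  df <- .vp_fit_matrix(times, t(Y), grid$t_exp_s)
  ft <- .f_test(df$sse_mean, df$sse_model, length(times))
  df$f_stat <- ft$f_stat
  df$p_value <- ft$p_value
  df$significant <- ft$p_value <= alpha

  coords <- arrayInd(idx, dim(mask))
  out <- cbind(data.frame(voxel = idx, x = coords[, 1], y = coords[, 2],
                          z = coords[, 3]), df)

  excl <- !out$significant
  if (any(excl)) {
    ee_col <- which(phases == grid$end_exp_index)[1]
    cls <- classify_aeration(Y[excl, ee_col])
    tab <- table(cls)
    message(sprintf(
      "F-filter excluded %d/%d voxels (%.1f%%); end-expiratory classes: %s",
      sum(excl), nrow(out), 100 * mean(excl),
      paste(sprintf("%s=%d", names(tab), as.integer(tab)),
            collapse = ", ")))
  }
  attr(out, "vol_dim") <- dim(mask)
  attr(out, "spacing_mm") <- seq$spacing_mm
  attr(out, "grid") <- grid
  attr(out, "alpha") <- alpha
  class(out) <- c("voxel_fit_table", "data.frame")
  out
}

#' Whole-lung mechanical time constant from a ventilator trace
#'
#' Locates the first complete expiratory window (airway pressure at PEEP,
#' bracketed by inspiratory segments), fits the exhalation exponential to
#' the exhaled-volume curve, and reads driving pressure (P_insp - PEEP) and
#' tidal volume from the trace.
#'
#' @param trace a `ventilator_trace` (see [render_ventilator_trace()] /
#'   [read_trace_csv()]).
#' @return object of class `global_mechanics`: `tau_volume_s`,
#'   `driving_pressure_cmh2o`, `tidal_volume_l`,
#'   `dynamic_elastance_cmh2o_per_l`, and the underlying `fit`.
#' @export
fit_volume_time_constant <- function(trace) {
  p <- trace$pressure_cmh2o
  v <- trace$volume_ml
  t <- trace$time_s
  p_hi <- max(p); p_lo <- min(p)
  if (p_hi - p_lo < 0.5) {
    stop("no identifiable expiratory window: pressure waveform is flat")
  }
  expir <- p < (p_hi + p_lo) / 2
  r <- rle(expir)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values &
                  seq_along(r$values) > 1 &
                  seq_along(r$values) < length(r$values))
  if (length(cand) == 0) {
    stop("no identifiable expiratory window: trace contains no complete expiration")
  }
  w <- starts[cand[1]]:ends[cand[1]]
  vw <- v[w]
  if (max(vw) - min(vw) <= 1e-9) {
    stop("no identifiable expiratory window: exhaled volume has zero amplitude")
  }
  fit <- fit_exponential(t[w] - t[w][1], vw - vw[1],
                         t_exp_s = t[w][length(w)] - t[w][1])
  dp <- p_hi - p_lo
  vt_l <- max(vw) / 1000
  out <- list(tau_volume_s = fit$tau_s,
              driving_pressure_cmh2o = dp,
              tidal_volume_l = vt_l,
              dynamic_elastance_cmh2o_per_l = dynamic_elastance(dp, vt_l),
              fit = fit)
  class(out) <- "global_mechanics"
  out
}

#' @export
print.global_mechanics <- function(x, ...) {
  cat(sprintf(
    "Whole-lung mechanics: tau = %.3f s, driving pressure = %.1f cmH2O,\n",
    x$tau_volume_s, x$driving_pressure_cmh2o))
  cat(sprintf("  tidal volume = %.1f ml, dynamic elastance = %.1f cmH2O/L\n",
              1000 * x$tidal_volume_l, x$dynamic_elastance_cmh2o_per_l))
  invisible(x)
}

#' Dynamic elastance
#'
#' Quotient of driving pressure and tidal volume, valid when inspiratory
#' flow is near zero at end-inspiration (pressure-controlled ventilation
#' with an inspiratory plateau).
#'
#' @param driving_pressure_cmh2o P_insp - PEEP, in cmH2O (>= 0).
#' @param tidal_volume_l tidal volume in litres (> 0).
#' @return dynamic elastance in cmH2O per litre.
#' @export
dynamic_elastance <- function(driving_pressure_cmh2o, tidal_volume_l) {
  if (tidal_volume_l <= 0) stop("'tidal_volume_l' must be positive")
  if (driving_pressure_cmh2o < 0) {
    stop("'driving_pressure_cmh2o' must be >= 0")
  }
  driving_pressure_cmh2o / tidal_volume_l
}
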