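#' Temporal sampling frequency of a gated image sequence
#'
#' A respiratory-gated sequence with `n_phases` volumes per breath acquired
#' at `respiratory_rate_per_min` breaths per minute samples each voxel at
#' `n_phases * rate / 60` Hz. A 21-phase sequence at 20 breaths/min is
#' sampled at 7 Hz.
#'
#' @param n_phases number of image volumes per breath cycle.
#' @param respiratory_rate_per_min ventilator rate in breaths per minute.
#' @return sampling frequency in Hz.
#' @export
sampling_frequency <- function(n_phases, respiratory_rate_per_min) {
  if (n_phases <= 0) stop("'n_phases' must be positive")
  if (respiratory_rate_per_min <= 0) {
    stop("'respiratory_rate_per_min' must be positive")
  }
  n_phases * respiratory_rate_per_min / 60
}

#' Scanner rotation frequency
#'
#' @param rotation_period_s gantry rotation period in seconds
#'   (e.g. 0.25 s gives 4 Hz).
#' @return rotation frequency in Hz.
#' @export
rotation_frequency <- function(rotation_period_s) {
  if (rotation_period_s <= 0) stop("'rotation_period_s' must be positive")
  1 / rotation_period_s
}

#' Build the breath-phase timing grid
#'
#' Assigns elapsed expiratory time to each phase of a periodic gated
#' sequence. With an inspiratory:expiratory ratio of i:e, the expiratory
#' portion of the cycle spans `e/(i+e)` of the breath period; at 1:2,
#' inspiration lasts T and exhalation 2T. Expiratory phases are counted
#' cyclically from the end-inspiratory phase, with elapsed time
#' `t_k = k * phase_interval_s` (t = 0 at end-inspiration). The number of
#' expiratory intervals is the expiratory fraction of `n_phases`, rounded to
#' the nearest integer with ties resolved toward more expiratory phases
#' (maximizing the number of regression samples).
#'
#' @param n_phases number of phases per breath (>= 3).
#' @param respiratory_rate_per_min breaths per minute.
#' @param ie_ratio length-2 numeric, inspiratory:expiratory duration ratio
#'   (default `c(1, 2)`).
#' @param end_insp_index 1-based index of the end-inspiratory phase.
#' @return an object of class `breath_phase_grid`: a list with phase counts,
#'   `phase_interval_s`, `expiratory_times_s`, 1-based
#'   `expiratory_phase_indices`, `end_insp_index`, `end_exp_index`,
#'   `t_insp_s`, `t_exp_s` and `sampling_frequency_hz`.
#' @export
build_phase_grid <- function(n_phases, respiratory_rate_per_min,
                             ie_ratio = c(1, 2), end_insp_index = 1L) {
  if (n_phases < 3) stop("'n_phases' must be at least 3")
  if (respiratory_rate_per_min <= 0) {
    stop("'respiratory_rate_per_min' must be positive")
  }
  if (length(ie_ratio) != 2 || any(!is.finite(ie_ratio)) ||
      any(ie_ratio <= 0)) {
    stop("'ie_ratio' must be two positive numbers (inspiratory, expiratory)")
  }
  n_phases <- as.integer(n_phases)
  end_insp_index <- as.integer(end_insp_index)
  if (end_insp_index < 1L || end_insp_index > n_phases) {
    stop("'end_insp_index' must lie in [1, n_phases]")
  }

  period_s <- 60 / respiratory_rate_per_min
  phase_interval_s <- period_s / n_phases
  exp_fraction <- ie_ratio[2] / sum(ie_ratio)
  # ties toward more expiratory phases
  n_exp_intervals <- as.integer(floor(n_phases * exp_fraction + 0.5))
  n_exp_intervals <- max(2L, min(n_exp_intervals, n_phases - 1L))

  expiratory_phase_indices <-
    ((end_insp_index - 1L + 0:n_exp_intervals) %% n_phases) + 1L
  expiratory_times_s <- (0:n_exp_intervals) * phase_interval_s

  grid <- list(
    n_phases = n_phases,
    respiratory_rate_per_min = respiratory_rate_per_min,
    ie_ratio = ie_ratio,
    period_s = period_s,
    phase_interval_s = phase_interval_s,
    n_exp_intervals = n_exp_intervals,
    end_insp_index = end_insp_index,
    end_exp_index = expiratory_phase_indices[length(expiratory_phase_indices)],
    expiratory_phase_indices = expiratory_phase_indices,
    expiratory_times_s = expiratory_times_s,
    t_insp_s = period_s * ie_ratio[1] / sum(ie_ratio),
    t_exp_s = period_s * exp_fraction,
    sampling_frequency_hz = sampling_frequency(n_phases,
                                               respiratory_rate_per_min)
  )
  class(grid) <- "breath_phase_grid"
  grid
}

#' @export
print.breath_phase_grid <- function(x, ...) {
  cat(sprintf(
    "Breath phase grid: %d phases at %g/min (I:E %g:%g)\n",
    x$n_phases, x$respiratory_rate_per_min, x$ie_ratio[1], x$ie_ratio[2]))
  cat(sprintf("  phase interval %.4f s, sampling %.3f Hz\n",
              x$phase_interval_s, x$sampling_frequency_hz))
  cat(sprintf(
    "  end-inspiration phase %d, end-expiration phase %d, t_exp %.3f s\n",
    x$end_insp_index, x$end_exp_index, x$t_exp_s))
  cat(sprintf("  %d expiratory samples over [0, %.3f] s\n",
              length(x$expiratory_times_s),
              max(x$expiratory_times_s)))
  invisible(x)
}

#' Detect the end-inspiratory phase of an aligned sequence
#'
#' End-inspiration is the phase of maximal aeration: the lung holds the most
#' gas, so the within-mask mean CT density is at its minimum. The detection
#' statistic is the within-mask mean HU per phase, an automated monotone
#' surrogate for visual inspection of time-varying intensity histograms.
#' Ties break deterministically to the lowest phase index.
#'
#' @param seq an [aligned_sequence] (4D HU stack plus lung mask).
#' @param tol_hu phases are considered indistinguishable when the range of
#'   phase means is below this tolerance (HU); an error then instructs a
#'   manual override.
#' @return 1-based phase index of end-inspiration.
#' @export
detect_end_inspiration <- function(seq, tol_hu = 1e-3) {
  stopifnot(inherits(seq, "aligned_sequence"))
  n_phases <- dim(seq$intensity)[4]
  if (n_phases < 3) stop("need at least 3 phases")
  idx <- which(seq$mask)
  if (length(idx) == 0) stop("lung mask is empty")
  nvox <- prod(dim(seq$mask))
  phase_means <- vapply(seq_len(n_phases), function(p) {
    mean(seq$intensity[(p - 1L) * nvox + idx])
  }, numeric(1))
  if (diff(range(phase_means)) < tol_hu) {
    stop("phase intensity histograms are indistinguishable; ",
         "set 'end_insp_index_override' in the run configuration")
  }
  which.min(phase_means)
}
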