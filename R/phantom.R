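#' Specification of a synthetic 4D lung phantom
#'
#' Describes the study conditions emulated by the phantom generator:
#' pressure-controlled ventilation at a 1:2 I:E ratio, retrospectively gated
#' sequences of 13-21 phases per breath, per-voxel single-exponential
#' density decay during passive exhalation, gravitationally graded aeration
#' and time constants, and additive HU noise.
#'
#' @param grid_shape integer length-3, voxels per axis (all >= 4).
#' @param spacing_mm isotropic voxel size in mm.
#' @param n_phases phases per breath cycle (>= 3; the study setting is
#'   13-21).
#' @param respiratory_rate_per_min breaths per minute (study range 20-32).
#' @param ie_ratio inspiratory:expiratory duration ratio, default `c(1, 2)`.
#' @param condition `"baseline"` or `"injured"`. Injury shifts the aeration
#'   quotas toward poorly/non-aerated tissue, enlarges intratidal density
#'   amplitudes in poorly aerated regions, and speeds the overall exhaled
#'   volume time constant relative to density dynamics.
#' @param noise_sigma_hu SD of additive i.i.d. Gaussian HU noise (>= 0).
#' @param tau_range_s length-2 positive, range of the ground-truth density
#'   time-constant field in seconds.
#' @param seed RNG seed; identical spec + seed gives bitwise-identical
#'   output.
#' @param gravity_axis axis index (1-3) treated as dorsal-to-ventral; low
#'   indices are dorsal (dependent in the supine posture).
#' @param class_quota named fractions (hyper, normal, poor, non) of masked
#'   voxels in each aeration class at equilibrium density; defaults depend
#'   on `condition`.
#' @param paradoxical_fraction fraction of voxels whose density decreases
#'   during exhalation (gas gain; mapped above the PRM identity line).
#' @param volume_trace_tau_s ground-truth overall exhaled-volume time
#'   constant in seconds; default 0.35 (baseline) or 0.25 (injured).
#' @param p_insp_cmh2o,peep_cmh2o inspiratory and end-expiratory pressures
#'   of the square ventilator waveform; defaults follow typical
#'   pressure-controlled settings for a ~10 kg animal (20.8/8.1 baseline,
#'   25.4/7.7 injured).
#' @param tidal_volume_ml exhaled tidal volume; default 91 ml baseline,
#'   75 ml injured.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48),
                         spacing_mm = 1.2,
                         n_phases = 21,
                         respiratory_rate_per_min = 20,
                         ie_ratio = c(1, 2),
                         condition = c("baseline", "injured"),
                         noise_sigma_hu = 15,
                         tau_range_s = c(0.15, 1.0),
                         seed = 1L,
                         gravity_axis = 2L,
                         class_quota = NULL,
                         paradoxical_fraction = 0.02,
                         volume_trace_tau_s = NULL,
                         p_insp_cmh2o = NULL,
                         peep_cmh2o = NULL,
                         tidal_volume_ml = NULL) {
  condition <- match.arg(condition)
  if (length(grid_shape) != 3 || any(grid_shape < 4)) {
    stop("'grid_shape' must give 3 axes with at least 4 voxels each")
  }
  if (n_phases < 3) stop("'n_phases' must be at least 3")
  if (noise_sigma_hu < 0) stop("'noise_sigma_hu' must be >= 0")
  if (length(tau_range_s) != 2 || any(tau_range_s <= 0) ||
      tau_range_s[1] > tau_range_s[2]) {
    stop("'tau_range_s' must be a positive (min, max) pair")
  }
  if (spacing_mm <= 0) stop("'spacing_mm' must be positive")
  if (!(gravity_axis %in% 1:3)) stop("'gravity_axis' must be 1, 2 or 3")
  if (paradoxical_fraction < 0 || paradoxical_fraction > 0.5) {
    stop("'paradoxical_fraction' must lie in [0, 0.5]")
  }
  if (is.null(class_quota)) {
    class_quota <- if (condition == "baseline") {
      c(hyper = 0.05, normal = 0.70, poor = 0.20, non = 0.05)
    } else {
      c(hyper = 0.03, normal = 0.45, poor = 0.35, non = 0.17)
    }
  }
  if (!setequal(names(class_quota),
                c("hyper", "normal", "poor", "non")) ||
      any(class_quota < 0) || abs(sum(class_quota) - 1) > 1e-8) {
    stop("'class_quota' must be fractions named hyper/normal/poor/non summing to 1")
  }
  class_quota <- class_quota[c("hyper", "normal", "poor", "non")]
  if (is.null(volume_trace_tau_s)) {
    volume_trace_tau_s <- if (condition == "baseline") 0.35 else 0.25
  }
  if (volume_trace_tau_s <= 0) stop("'volume_trace_tau_s' must be positive")
  if (is.null(p_insp_cmh2o)) {
    p_insp_cmh2o <- if (condition == "baseline") 20.8 else 25.4
  }
  if (is.null(peep_cmh2o)) {
    peep_cmh2o <- if (condition == "baseline") 8.1 else 7.7
  }
  if (is.null(tidal_volume_ml)) {
    tidal_volume_ml <- if (condition == "baseline") 91 else 75
  }
  if (p_insp_cmh2o <= peep_cmh2o) {
    stop("'p_insp_cmh2o' must exceed 'peep_cmh2o'")
  }
  structure(list(
    grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
    n_phases = as.integer(n_phases),
    respiratory_rate_per_min = respiratory_rate_per_min,
    ie_ratio = ie_ratio, condition = condition,
    noise_sigma_hu = noise_sigma_hu, tau_range_s = tau_range_s,
    seed = as.integer(seed), gravity_axis = as.integer(gravity_axis),
    class_quota = class_quota,
    paradoxical_fraction = paradoxical_fraction,
    volume_trace_tau_s = volume_trace_tau_s,
    p_insp_cmh2o = p_insp_cmh2o, peep_cmh2o = peep_cmh2o,
    tidal_volume_ml = tidal_volume_ml
  ), class = "phantom_spec")
}

# ellipsoidal lung interior minus a cylindrical airway channel running along
# the third axis; the channel supplies excluded-structure voxels analogous
# to airways/vasculature
.phantom_mask <- function(grid_shape) {
  d <- grid_shape
  cx <- (d + 1) / 2
  x <- (seq_len(d[1]) - cx[1]) / (0.42 * d[1])
  y <- (seq_len(d[2]) - cx[2]) / (0.42 * d[2])
  z <- (seq_len(d[3]) - cx[3]) / (0.45 * d[3])
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  ell <- r2 <= 1
  rad <- max(1.5, 0.05 * min(d[1:2]))
  xy2 <- outer((seq_len(d[1]) - cx[1])^2, (seq_len(d[2]) - cx[2])^2, `+`)
  channel <- array(rep(xy2 <= rad^2, d[3]), dim = d)
  ell & !channel
}

# spatially smooth standard-normal field: box-blurred white noise,
# re-standardized; 'passes' controls the correlation length (~voxels)
.smooth_field <- function(grid_shape, passes = 8) {
  a <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
  blur_axis <- function(a, ax) {
    n <- dim(a)[ax]
    lo <- c(1, seq_len(n - 1))
    hi <- c(seq_len(n - 1) + 1, n)
    if (ax == 1) (a[lo, , , drop = FALSE] + a + a[hi, , , drop = FALSE]) / 3
    else if (ax == 2) (a[, lo, , drop = FALSE] + a + a[, hi, , drop = FALSE]) / 3
    else (a[, , lo, drop = FALSE] + a + a[, , hi, drop = FALSE]) / 3
  }
  for (i in seq_len(passes)) for (ax in 1:3) a <- blur_axis(a, ax)
  (a - mean(a)) / stats::sd(a)
}

# HU spans used when drawing equilibrium densities for each aeration class
.class_ranges <- list(hyper = c(-980, -900), normal = c(-900, -500),
                      poor = c(-500, -100), non = c(-100, 40))

#' Generate ground-truth parameter fields for a phantom
#'
#' Builds smooth fields of initial density D0, equilibrium density Dinf and
#' the density time constant tau with the spatial structure the analysis
#' expects: dorsal (dependent) voxels are denser at equilibrium and drain
#' faster (smaller tau); aeration-class quotas at Dinf are hit exactly by
#' rank-based quantile mapping of a gravity-dominated latent field;
#' intratidal amplitudes concentrate in normally and poorly aerated tissue
#' while hyper- and non-aerated voxels are mostly static; a small
#' paradoxical fraction loses density during exhalation. The analytic
#' tissue-conserving Jacobian for every phase is included.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_truth`: `d0_map`, `dinf_map`, `tau_map`
#'   (3D arrays, `NA` outside the mask), `mask`, `jac_truth` (4D),
#'   `volume_trace_tau_s`, the phase `grid`, and the generating `spec`.
#' @export
generate_parameter_fields <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$grid_shape
  mask <- .phantom_mask(d)
  idx <- which(mask)
  V <- length(idx)
  coords <- arrayInd(idx, d)
  h <- relative_height(coords, mask, spec$gravity_axis)

  # noise fields are demeaned within each height slab so the gravitational
  # profile is exactly the designed monotone one
  demean_slab <- function(g) {
    pos <- coords[, spec$gravity_axis]
    g - stats::ave(g, pos)
  }
  g_dens <- demean_slab(.smooth_field(d)[idx])
  g_patch <- .smooth_field(d, passes = 12)[idx]
  g_tau <- demean_slab(.smooth_field(d)[idx])

  # equilibrium density: gravity-dominated latent, quantile-mapped so the
  # class quotas at Dinf hold exactly
  latent <- (1 - h) + 0.2 * g_dens
  u <- (rank(latent, ties.method = "first") - 0.5) / V
  cum <- cumsum(spec$class_quota)
  lo <- c(0, cum[-4])
  dinf <- numeric(V)
  for (k in 1:4) {
    cls <- names(spec$class_quota)[k]
    # ascending HU: hyper first (least dense = lowest latent rank reversed)
    sel <- u > lo[k] & u <= cum[k] + (k == 4) * 1e-12
    rng <- .class_ranges[[cls]]
    # low u = low latent = ventral/aerated = low HU
    dinf[sel] <- rng[1] + (rng[2] - rng[1]) *
      (u[sel] - lo[k]) / max(cum[k] - lo[k], 1e-12)
  }

  cls_dinf <- classify_aeration(dinf)
  amp <- numeric(V)
  nrm <- cls_dinf == "normal"
  poor <- cls_dinf == "poor"
  amp[nrm] <- stats::runif(sum(nrm), 70, 180)
  if (spec$condition == "injured") {
    # patchy regions of large intratidal change within poorly aerated tissue
    patchy <- poor & g_patch > stats::quantile(g_patch, 0.5)
    amp[poor] <- stats::runif(sum(poor), 90, 250)
    amp[patchy] <- stats::runif(sum(patchy), 120, 300)
  } else {
    amp[poor] <- stats::runif(sum(poor), 90, 250)
  }
  static_cls <- cls_dinf %in% c("hyper", "non")
  dyn <- static_cls & stats::runif(V) < 0.2
  amp[dyn] <- stats::runif(sum(dyn), 20, 60)

  n_par <- round(spec$paradoxical_fraction * V)
  if (n_par > 0) {
    par_idx <- sample.int(V, n_par)
    amp[par_idx] <- -stats::runif(n_par, 30, 80)
  }
  # keep D0 within the physical HU window
  amp <- pmin(amp, dinf + 995)
  amp <- pmax(amp, dinf - 100)
  d0 <- dinf - amp

  s_tau <- h + 0.2 * g_tau
  s_tau <- (s_tau - min(s_tau)) / (max(s_tau) - min(s_tau))
  tau <- spec$tau_range_s[1] + diff(spec$tau_range_s) * s_tau

  to_map <- function(v) {
    a <- array(NA_real_, d)
    a[idx] <- v
    a
  }
  truth <- structure(list(
    d0_map = to_map(d0), dinf_map = to_map(dinf), tau_map = to_map(tau),
    mask = mask, spacing_mm = rep(spec$spacing_mm, 3),
    grid = build_phase_grid(spec$n_phases, spec$respiratory_rate_per_min,
                            spec$ie_ratio, 1L),
    volume_trace_tau_s = spec$volume_trace_tau_s,
    class_quota = spec$class_quota,
    spec = spec
  ), class = "phantom_truth")
  truth$jac_truth <- .phantom_jacobian(truth)
  truth
}

# noiseless model intensity of every masked voxel at phase k (1-based);
# expiratory phases follow the exponential decay, the inspiratory remainder
# re-inflates linearly from D_EE back to D0 (placeholder; never fitted)
.phantom_intensity <- function(truth, k) {
  grid <- truth$grid
  idx <- which(truth$mask)
  d0 <- truth$d0_map[idx]
  dinf <- truth$dinf_map[idx]
  tau <- truth$tau_map[idx]
  pos <- match(k, grid$expiratory_phase_indices)
  if (!is.na(pos)) {
    t_k <- grid$expiratory_times_s[pos]
    return(dinf + (d0 - dinf) * exp(-t_k / tau))
  }
  t_last <- grid$expiratory_times_s[length(grid$expiratory_times_s)]
  d_ee <- dinf + (d0 - dinf) * exp(-t_last / tau)
  insp <- setdiff(seq_len(grid$n_phases), grid$expiratory_phase_indices)
  # order inspiratory phases cyclically after end-expiration
  rel <- (insp - grid$end_exp_index) %% grid$n_phases
  insp <- insp[order(rel)]
  f <- match(k, insp) / (length(insp) + 1)
  d_ee + (d0 - d_ee) * f
}

.phantom_jacobian <- function(truth) {
  d <- dim(truth$mask)
  n_phases <- truth$grid$n_phases
  idx <- which(truth$mask)
  i0 <- .phantom_intensity(truth, truth$grid$end_insp_index)
  jac <- array(1, c(d, n_phases))
  nvox <- prod(d)
  for (k in seq_len(n_phases)) {
    ik <- .phantom_intensity(truth, k)
    if (any(ik <= -1000)) {
      stop("nonphysical total-gas voxel: intensity <= -1000 HU at phase ", k)
    }
    jac[(k - 1L) * nvox + idx] <- (i0 + 1000) / (ik + 1000)
  }
  jac
}

#' Render the 4D HU image sequence of a phantom
#'
#' For every expiratory phase n at elapsed time t_n the noiseless intensity
#' is `D0 + (Dinf - D0) * (1 - exp(-t_n / tau))`; inspiratory phases are a
#' time-reversed re-inflation placeholder (they are never fitted), and
#' i.i.d. Gaussian HU noise is added everywhere. The reference phase is
#' end-inspiration (index 1) with noiseless intensity D0. Voxels outside
#' the lung mask are soft tissue (20 HU).
#'
#' @param truth a [generate_parameter_fields()] result.
#' @param spec the generating [phantom_spec()].
#' @return an [aligned_sequence].
#' @export
render_sequence <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "phantom_truth"))
  set.seed(spec$seed + 1L)
  d <- spec$grid_shape
  n_phases <- spec$n_phases
  idx <- which(truth$mask)
  nvox <- prod(d)
  intensity <- array(20, c(d, n_phases))
  for (k in seq_len(n_phases)) {
    intensity[(k - 1L) * nvox + idx] <- .phantom_intensity(truth, k)
  }
  if (spec$noise_sigma_hu > 0) {
    intensity <- intensity +
      stats::rnorm(length(intensity), 0, spec$noise_sigma_hu)
  }
  aligned_sequence(intensity, rep(spec$spacing_mm, 3), truth$mask,
                   truth$grid)
}

#' Render per-phase deformation for a phantom
#'
#' `"analytic-jacobian"` mode emits the tissue-conserving Jacobian
#' `J_n0 = (I0 + 1000) / (I_n + 1000)` computed from the noiseless
#' intensities (the gas volume of a voxel changes, its tissue volume does
#' not). `"displacement"` mode emits a uniform per-phase compression along
#' the gravity axis whose Jacobian has the closed form `J = s_k` everywhere;
#' the closed form is stored alongside for verification.
#'
#' @param truth a [generate_parameter_fields()] result.
#' @param spec the generating [phantom_spec()].
#' @param mode `"analytic-jacobian"` or `"displacement"`.
#' @return object of class `deformation_set` with either `jacobian`
#'   (4D array) or `displacement` (5D array X,Y,Z,3,phase) plus
#'   `closed_form_jacobian`.
#' @export
render_deformation <- function(truth, spec = truth$spec,
                               mode = c("analytic-jacobian",
                                        "displacement")) {
  stopifnot(inherits(truth, "phantom_truth"))
  mode <- match.arg(mode)
  grid <- truth$grid
  if (mode == "analytic-jacobian") {
    out <- list(mode = mode, jacobian = truth$jac_truth,
                reference_phase = grid$end_insp_index, grid = grid,
                spacing_mm = truth$spacing_mm)
  } else {
    d <- spec$grid_shape
    ax <- spec$gravity_axis
    n_phases <- grid$n_phases
    disp <- array(0, c(d, 3, n_phases))
    scales <- numeric(n_phases)
    centre <- (d[ax] + 1) / 2 * spec$spacing_mm
    pos <- seq_len(d[ax]) * spec$spacing_mm
    for (k in seq_len(n_phases)) {
      p <- match(k, grid$expiratory_phase_indices)
      if (!is.na(p)) {
        t_k <- grid$expiratory_times_s[p]
        s_k <- 1 - 0.12 * (1 - exp(-t_k / spec$volume_trace_tau_s))
      } else {
        insp <- setdiff(seq_len(n_phases), grid$expiratory_phase_indices)
        rel <- (insp - grid$end_exp_index) %% n_phases
        insp <- insp[order(rel)]
        f <- match(k, insp) / (length(insp) + 1)
        t_last <- max(grid$expiratory_times_s)
        s_ee <- 1 - 0.12 * (1 - exp(-t_last / spec$volume_trace_tau_s))
        s_k <- s_ee + (1 - s_ee) * f
      }
      scales[k] <- s_k
      u_axis <- (s_k - 1) * (pos - centre)
      # broadcast u along 'ax' over the other axes
      u3 <- switch(ax,
        array(rep(u_axis, times = d[2] * d[3]), dim = d),
        aperm(array(rep(u_axis, times = d[1] * d[3]),
                    dim = c(d[2], d[1], d[3])), c(2, 1, 3)),
        aperm(array(rep(u_axis, times = d[1] * d[2]),
                    dim = c(d[3], d[1], d[2])), c(2, 3, 1)))
      disp[, , , ax, k] <- u3
    }
    closed <- array(rep(scales, each = prod(d)), c(d, n_phases))
    out <- list(mode = mode, displacement = disp,
                closed_form_jacobian = closed,
                reference_phase = grid$end_insp_index, grid = grid,
                spacing_mm = truth$spacing_mm)
  }
  class(out) <- "deformation_set"
  out
}

#' Render a synthetic ventilator waveform trace
#'
#' 200 Hz square pressure wave between P_insp and PEEP; exhaled volume
#' (referenced to end-inspiration) rises as
#' `VT * (1 - exp(-t / volume_trace_tau_s))` during each expiration and
#' returns linearly to zero during inspiration.
#'
#' @param truth a [generate_parameter_fields()] result.
#' @param spec the generating [phantom_spec()].
#' @param n_breaths number of breath cycles (>= 3 recommended).
#' @param sample_rate_hz waveform sampling rate (study setting 200 Hz).
#' @return a `ventilator_trace` data frame with attributes
#'   `sample_rate_hz`, `peep_cmh2o`, `p_insp_cmh2o`.
#' @export
render_ventilator_trace <- function(truth, spec = truth$spec,
                                    n_breaths = 3,
                                    sample_rate_hz = 200) {
  stopifnot(inherits(truth, "phantom_truth"))
  period <- 60 / spec$respiratory_rate_per_min
  t_i <- period * spec$ie_ratio[1] / sum(spec$ie_ratio)
  n <- round(n_breaths * period * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  ph <- t %% period
  insp <- ph < t_i
  vt <- spec$tidal_volume_ml
  vol <- ifelse(insp,
                vt * (1 - ph / t_i),
                vt * (1 - exp(-(ph - t_i) / truth$volume_trace_tau_s)))
  pres <- ifelse(insp, spec$p_insp_cmh2o, spec$peep_cmh2o)
  ventilator_trace(t, pres, vol,
                   peep_cmh2o = spec$peep_cmh2o,
                   p_insp_cmh2o = spec$p_insp_cmh2o)
}

#' Write a complete phantom data set to disk
#'
#' Emits the 4D HU sequence, the lung mask, the analytic Jacobian stack,
#' the ground-truth parameter maps, the ventilator trace CSV and a JSON
#' sidecar with the spec and phase timing.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a named list of file paths plus the in-memory objects.
#' @export
write_phantom <- function(spec, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  truth <- generate_parameter_fields(spec)
  seq <- render_sequence(truth, spec)
  trace <- render_ventilator_trace(truth, spec)
  sp <- rep(spec$spacing_mm, 3)
  dt <- truth$grid$phase_interval_s
  paths <- list(
    sequence = file.path(out_dir, "sequence.nii.gz"),
    mask = file.path(out_dir, "mask.nii.gz"),
    jacobian = file.path(out_dir, "jacobian.nii.gz"),
    d0 = file.path(out_dir, "truth_d0.nii.gz"),
    dinf = file.path(out_dir, "truth_dinf.nii.gz"),
    tau = file.path(out_dir, "truth_tau.nii.gz"),
    trace = file.path(out_dir, "trace.csv"),
    sidecar = file.path(out_dir, "phantom.json")
  )
  .write_nifti(seq$intensity, sp, paths$sequence, dt)
  .write_nifti(array(as.numeric(truth$mask), dim(truth$mask)), sp,
               paths$mask)
  .write_nifti(truth$jac_truth, sp, paths$jacobian, dt)
  .write_nifti(truth$d0_map, sp, paths$d0)
  .write_nifti(truth$dinf_map, sp, paths$dinf)
  .write_nifti(truth$tau_map, sp, paths$tau)
  write_trace_csv(trace, paths$trace)
  sidecar <- c(unclass(spec),
               list(phase_interval_s = truth$grid$phase_interval_s,
                    expiratory_times_s = truth$grid$expiratory_times_s,
                    t_exp_s = truth$grid$t_exp_s,
                    end_insp_index = truth$grid$end_insp_index,
                    end_exp_index = truth$grid$end_exp_index))
  jsonlite::write_json(sidecar, paths$sidecar, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, truth = truth, sequence = seq,
                 trace = trace))
}
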