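.aeration_levels <- c("hyper", "normal", "poor", "non")

#' Classify CT density into aeration classes
#'
#' Standard HU thresholds: hyper-aerated below -900, normally aerated
#' [-900, -500), poorly aerated [-500, -100), non-aerated at or above
#' -100 HU. Intervals are closed on the lower (more negative) edge.
#'
#' @param density_hu numeric vector/array of HU values; `NA` is propagated.
#' @param thresholds_hu strictly increasing length-3 breakpoints.
#' @return factor with levels `hyper < normal < poor < non`.
#' @export
classify_aeration <- function(density_hu,
                              thresholds_hu = c(-900, -500, -100)) {
  if (length(thresholds_hu) != 3 || any(diff(thresholds_hu) <= 0)) {
    stop("'thresholds_hu' must be 3 strictly increasing HU values")
  }
  k <- findInterval(density_hu, thresholds_hu) + 1L
  factor(.aeration_levels[k], levels = .aeration_levels, ordered = TRUE)
}

#' Volume fraction of each aeration class
#'
#' @param classmap factor from [classify_aeration()] (NA entries dropped).
#' @return named numeric summing to 1 across hyper/normal/poor/non.
#' @export
class_volume_fractions <- function(classmap) {
  classmap <- classmap[!is.na(classmap)]
  if (length(classmap) == 0) stop("no classified voxels")
  tab <- table(factor(classmap, levels = .aeration_levels))
  fr <- as.numeric(tab) / length(classmap)
  names(fr) <- .aeration_levels
  fr
}

#' Summarize time constants by aeration class
#'
#' Median and interquartile range of the fitted time constant within each
#' aeration class, using significant fits only (the F-filter exclusion is
#' applied before grouping). Empty classes are reported as absent (`NA`),
#' not zero.
#'
#' @param fits a `voxel_fit_table`.
#' @param classmap aeration class per row of `fits` (e.g. from
#'   `classify_aeration(fits$d_ee)`).
#' @return data frame with class, n, median/q25/q75 of `tau_s`.
#' @export
group_tau_by_class <- function(fits, classmap) {
  stopifnot(nrow(fits) == length(classmap))
  keep <- fits$significant & !is.na(fits$tau_s) & !is.na(classmap)
  out <- lapply(.aeration_levels, function(cl) {
    v <- fits$tau_s[keep & classmap == cl]
    if (length(v) == 0) {
      data.frame(class = cl, n = 0L, tau_median_s = NA_real_,
                 tau_q25_s = NA_real_, tau_q75_s = NA_real_)
    } else {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(class = cl, n = length(v), tau_median_s = q[2],
                 tau_q25_s = q[1], tau_q75_s = q[3])
    }
  })
  do.call(rbind, out)
}

#' Relative height along the gravitational axis
#'
#' Maps a voxel position to [0, 1] along the dorsal-ventral axis, with 0 at
#' the dorsal-most and 1 at the ventral-most masked extent (supine
#' posture: dorsal is dependent). Normalization uses the whole-lung mask
#' bounding range on the gravity axis.
#'
#' @param coords integer matrix of voxel indices (rows = voxels, columns =
#'   axes) or a vector of positions along the gravity axis.
#' @param mask 3D logical lung mask defining the extent.
#' @param gravity_axis axis index (1-3), dorsal at low indices.
#' @return numeric vector in [0, 1].
#' @export
relative_height <- function(coords, mask, gravity_axis) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  rng <- range(idx[, gravity_axis])
  if (rng[1] == rng[2]) {
    stop("degenerate mask extent along the gravity axis")
  }
  pos <- if (is.matrix(coords)) coords[, gravity_axis] else coords
  (pos - rng[1]) / (rng[2] - rng[1])
}

#' Gravitational height profile of fitted quantities
#'
#' Bins significant voxels by relative height along the dorsal-ventral axis
#' and reports per-bin median and IQR of end-inspiratory density (D0 =
#' D_EI), end-expiratory density (D_EE), intratidal change and the density
#' time constant.
#'
#' @param fits a `voxel_fit_table` with voxel coordinates.
#' @param mask 3D logical lung mask (defines the height normalization).
#' @param gravity_axis axis index (1-3).
#' @param n_bins number of height bins partitioning [0, 1].
#' @param min_count bins with fewer significant voxels are flagged
#'   (`sparse = TRUE`).
#' @return object of class `height_profile`: data frame with bin centres,
#'   counts and per-quantity median/q25/q75.
#' @export
height_profile <- function(fits, mask, gravity_axis, n_bins = 10,
                           min_count = 10) {
  stopifnot(inherits(fits, "voxel_fit_table"))
  keep <- fits$significant & !is.na(fits$tau_s)
  f <- fits[keep, ]
  h <- relative_height(as.matrix(f[, c("x", "y", "z")]), mask,
                       gravity_axis)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(h, edges, rightmost.closed = TRUE), 1),
              n_bins)
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  rows <- lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    base <- data.frame(bin = b,
                       height_mid = (edges[b] + edges[b + 1]) / 2,
                       n = sum(sel), sparse = sum(sel) < min_count)
    if (!any(sel)) {
      vals <- rep(NA_real_, 12)
    } else {
      vals <- c(qs(f$d0[sel]), qs(f$d_ee[sel]),
                qs(f$intratidal_change[sel]), qs(f$tau_s[sel]))
    }
    nm <- as.vector(outer(c("q25", "median", "q75"),
                          c("d0", "d_ee", "intratidal", "tau_s"),
                          function(a, b) paste(b, a, sep = "_")))
    base[nm] <- as.list(vals)
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("height_profile", "data.frame")
  out
}

#' Parametric response map of initial vs. equilibrium density
#'
#' Two-dimensional histogram of lung voxels over (initial density D_EI,
#' predicted equilibrium density Dinf), averaged across subjects as a
#' probability distribution. The equilibrium density stands in for the
#' quasi-static end-expiratory density of conventional PRMs. Per-cell
#' median time constants and median nonequilibrated change are overlaid
#' only where at least half of the subjects contribute at least
#' `min_voxels_per_subject` voxels.
#'
#' @param fits a `voxel_fit_table` or a list of them (one per subject).
#' @param bin_width_hu histogram bin width on both axes.
#' @param range_hu length-2 HU range of both axes.
#' @param min_voxels_per_subject per-cell inclusion threshold (default 5).
#' @return object of class `prm_grid`: `bin_edges_hu`, `probability`
#'   (cells x cells, averaged across subjects, summing to 1),
#'   `median_tau_s`, `median_nonequilibrated_hu`, `inclusion_mask`,
#'   `n_subjects`.
#' @export
build_prm <- function(fits, bin_width_hu = 25, range_hu = c(-1000, 100),
                      min_voxels_per_subject = 5) {
  if (inherits(fits, "voxel_fit_table")) fits <- list(fits)
  n_subjects <- length(fits)
  if (n_subjects == 0) stop("need at least one subject's fit table")
  edges <- seq(range_hu[1], range_hu[2], by = bin_width_hu)
  if (edges[length(edges)] < range_hu[2]) edges <- c(edges, range_hu[2])
  nb <- length(edges) - 1
  cell_of <- function(v) {
    pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1), nb)
  }
  counts <- array(0L, c(nb, nb, n_subjects))
  tau_cell <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    f <- fits[[s]]
    keep <- f$significant & !is.na(f$tau_s)
    f <- f[keep, ]
    ci <- cell_of(f$d0)       # initial density axis
    cj <- cell_of(f$dinf)     # equilibrium density axis
    tab <- table(factor(ci, levels = seq_len(nb)),
                 factor(cj, levels = seq_len(nb)))
    counts[, , s] <- as.integer(tab)
    tau_cell[[s]] <- data.frame(i = ci, j = cj, tau = f$tau_s,
                                noneq = f$nonequilibrated_change)
  }
  probs <- apply(counts, 3, function(m) {
    tot <- sum(m)
    if (tot == 0) m * 0 else m / tot
  })
  probability <- array(rowMeans(probs), c(nb, nb))

  n_ge <- apply(counts >= min_voxels_per_subject, c(1, 2), sum)
  inclusion <- n_ge >= ceiling(n_subjects / 2)

  pooled <- do.call(rbind, tau_cell)
  median_tau <- array(NA_real_, c(nb, nb))
  median_noneq <- array(NA_real_, c(nb, nb))
  if (nrow(pooled) > 0) {
    key <- (pooled$i - 1L) * nb + pooled$j
    for (cellkey in unique(key[inclusion[cbind(pooled$i, pooled$j)]])) {
      sel <- key == cellkey
      i <- (cellkey - 1L) %/% nb + 1L
      j <- (cellkey - 1L) %% nb + 1L
      median_tau[i, j] <- stats::median(pooled$tau[sel])
      median_noneq[i, j] <- stats::median(pooled$noneq[sel])
    }
  }
  structure(list(bin_edges_hu = edges, probability = probability,
                 median_tau_s = median_tau,
                 median_nonequilibrated_hu = median_noneq,
                 inclusion_mask = inclusion,
                 counts = counts,
                 n_subjects = n_subjects,
                 min_voxels_per_subject = min_voxels_per_subject),
            class = "prm_grid")
}

#' Nonequilibrated density change
#'
#' `Dinf - D_EE`: the density change still expected beyond end-expiration,
#' where `D_EE = D0 + (Dinf - D0) * (1 - exp(-t_exp / tau))`. Zero when the
#' voxel equilibrates within the breath (tau << t_exp).
#'
#' @param fits a `voxel_fit_table`.
#' @param significant_only restrict to F-filter survivors (default TRUE).
#' @return numeric vector of HU changes.
#' @export
nonequilibrated_change_map <- function(fits, significant_only = TRUE) {
  stopifnot(inherits(fits, "voxel_fit_table"))
  if (significant_only) fits <- fits[fits$significant & !is.na(fits$tau_s), ]
  fits$nonequilibrated_change
}

#' Theoretical convergence curve for exponential decay
#'
#' Fraction of the total density change still remaining at end-expiration
#' as a function of the normalized time constant `x = tau / t_exp`:
#' `f(x) = exp(-1/x)`. At `x = 0.2` (tau one fifth of the exhalation) the
#' remaining fraction is `exp(-5)`, about 0.674%.
#'
#' @param x normalized time constant tau / t_exp (> 0).
#' @return remaining fraction of the total expected change.
#' @export
convergence_curve <- function(x) exp(-1 / x)

#' Normalized convergence of voxels at end-expiration
#'
#' For each significant voxel, pairs the normalized time constant
#' `tau / t_exp` with the nonequilibrated change normalized by the total
#' expected change `(Dinf - D_EE) / (Dinf - D0)`. On exact
#' single-exponential fits the points fall on the theoretical curve
#' `exp(-t_exp/tau)`. Voxels with total expected change below
#' `amplitude_floor_hu` are omitted (normalization would blow up) and
#' counted.
#'
#' @param fits a `voxel_fit_table`.
#' @param t_exp_s exhalation duration (defaults to the attached grid).
#' @param amplitude_floor_hu minimum |Dinf - D0| (HU).
#' @return list with `points` (data frame `tau_norm`,
#'   `remaining_fraction`), `n_omitted`, and the theoretical `curve`
#'   function.
#' @export
normalized_convergence <- function(fits,
                                   t_exp_s = attr(fits, "grid")$t_exp_s,
                                   amplitude_floor_hu = 5) {
  stopifnot(inherits(fits, "voxel_fit_table"))
  f <- fits[fits$significant & !is.na(fits$tau_s), ]
  amp <- f$dinf - f$d0
  keep <- abs(amp) >= amplitude_floor_hu
  n_omitted <- sum(!keep)
  f <- f[keep, ]
  pts <- data.frame(tau_norm = f$tau_s / t_exp_s,
                    remaining_fraction =
                      (f$dinf - f$d_ee) / (f$dinf - f$d0))
  list(points = pts, n_omitted = n_omitted, curve = convergence_curve)
}

#' Correlation between density and SACJ time constants
#'
#' Pairs voxels significant in both regressions and computes a per-subject
#' rank correlation (Spearman) between the density and SACJ time
#' constants, the fraction of subjects with a significant correlation, and
#' an aggregate 2D histogram over (tau_density, tau_SACJ) with the identity
#' line as reference.
#'
#' @param density_fits,sacj_fits `voxel_fit_table`s or lists of them
#'   (subjects in the same order). Rows are matched on the `voxel` column.
#' @param alpha significance level for the per-subject correlation test.
#' @param min_pairs subjects with fewer paired voxels are skipped.
#' @param bins number of histogram bins per axis for the aggregate density.
#' @return list with `per_subject` (data frame subject/n/rho/p/significant),
#'   `fraction_significant`, and `aggregate` (list of `breaks`
#'   and probability matrix over paired time constants).
#' @export
tau_correlation <- function(density_fits, sacj_fits, alpha = 0.05,
                            min_pairs = 10, bins = 40) {
  if (inherits(density_fits, "voxel_fit_table")) {
    density_fits <- list(density_fits)
  }
  if (inherits(sacj_fits, "voxel_fit_table")) sacj_fits <- list(sacj_fits)
  stopifnot(length(density_fits) == length(sacj_fits))
  pairs <- list()
  rows <- list()
  for (s in seq_along(density_fits)) {
    fd <- density_fits[[s]]
    fs <- sacj_fits[[s]]
    fd <- fd[fd$significant & !is.na(fd$tau_s), c("voxel", "tau_s")]
    fs <- fs[fs$significant & !is.na(fs$tau_s), c("voxel", "tau_s")]
    m <- merge(fd, fs, by = "voxel", suffixes = c("_density", "_sacj"))
    if (nrow(m) < min_pairs) {
      message(sprintf("subject %d skipped: only %d paired voxels", s,
                      nrow(m)))
      rows[[s]] <- data.frame(subject = s, n = nrow(m), rho = NA_real_,
                              p = NA_real_, significant = NA)
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(m$tau_s_density, m$tau_s_sacj, method = "spearman",
                      exact = FALSE))
    rows[[s]] <- data.frame(subject = s, n = nrow(m),
                            rho = unname(ct$estimate), p = ct$p.value,
                            significant = ct$p.value <= alpha)
    pairs[[s]] <- m
  }
  per_subject <- do.call(rbind, rows)
  pooled <- do.call(rbind, pairs)
  aggregate <- NULL
  if (!is.null(pooled) && nrow(pooled) > 0) {
    rng <- range(c(pooled$tau_s_density, pooled$tau_s_sacj))
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
    ci <- cut(pooled$tau_s_density, breaks, include.lowest = TRUE)
    cj <- cut(pooled$tau_s_sacj, breaks, include.lowest = TRUE)
    h2 <- table(ci, cj)
    aggregate <- list(breaks = breaks,
                      probability = unclass(h2 / sum(h2)))
  }
  list(per_subject = per_subject,
       fraction_significant = mean(per_subject$significant, na.rm = TRUE),
       aggregate = aggregate)
}

#' Distributions of model-predicted change at successive expiratory times
#'
#' For each requested time t, histograms the model-predicted change from
#' end-inspiration `(Dinf - D0) * (1 - exp(-t / tau))` across significant
#' voxels. Applied to density fits this is the density change (HU); applied
#' to SACJ fits it is the relative gas-volume change. Each per-time
#' histogram is probability-normalized.
#'
#' @param fits a `voxel_fit_table`.
#' @param times_s expiratory times (s).
#' @param breaks histogram breaks (numeric vector) or a bin count.
#' @return long data frame with `time_s`, `bin_mid`, `probability`.
#' @export
time_course_distributions <- function(fits, times_s, breaks = 50) {
  stopifnot(inherits(fits, "voxel_fit_table"))
  f <- fits[fits$significant & !is.na(fits$tau_s), ]
  if (nrow(f) == 0) stop("no significant fits")
  changes <- lapply(times_s, function(t) {
    (f$dinf - f$d0) * (1 - exp(-t / f$tau_s))
  })
  if (length(breaks) == 1) {
    rng <- range(unlist(changes))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = breaks + 1)
  }
  out <- lapply(seq_along(times_s), function(k) {
    h <- graphics::hist(changes[[k]], breaks = breaks, plot = FALSE)
    data.frame(time_s = times_s[k], bin_mid = h$mids,
               probability = h$counts / sum(h$counts))
  })
  do.call(rbind, out)
}
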