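test_that("aeration classification follows the standard HU thresholds", {
  expect_equal(as.character(classify_aeration(
    c(-950, -700, -300, -50))), c("hyper", "normal", "poor", "non"))
  # lower-edge-inclusive boundary convention
  expect_equal(as.character(classify_aeration(c(-900, -500, -100))),
               c("normal", "poor", "non"))
  expect_true(is.na(classify_aeration(NA_real_)))
  expect_error(classify_aeration(-500, thresholds_hu = c(-1, -2, -3)),
               "increasing")
})

test_that("class volume fractions partition the lung", {
  expect_equal(class_volume_fractions(classify_aeration(rep(-700, 10))),
               c(hyper = 0, normal = 1, poor = 0, non = 0))
  tr <- clean_phantom_small()$truth
  fr <- class_volume_fractions(classify_aeration(tr$dinf_map[tr$mask]))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_true(all(abs(fr - tr$class_quota) <= 0.05))
  expect_error(class_volume_fractions(classify_aeration(numeric(0))),
               "no classified voxels")
})

test_that("per-class tau summaries respect construction and exclusion", {
  ft <- make_fit_table(d0 = rep(c(-700, -300), each = 50),
                       dinf = rep(c(-650, -250), each = 50),
                       tau_s = rep(c(0.8, 0.3), each = 50))
  cls <- classify_aeration(ft$d_ee)
  g <- group_tau_by_class(ft, cls)
  expect_equal(g$tau_median_s[g$class == "normal"], 0.8)
  expect_equal(g$tau_median_s[g$class == "poor"], 0.3)
  expect_true(is.na(g$tau_median_s[g$class == "hyper"]))
  expect_equal(g$n[g$class == "hyper"], 0L)

  # excluded voxels contribute to no summary
  ft2 <- ft
  ft2$significant[1:50] <- FALSE
  g2 <- group_tau_by_class(ft2, cls)
  expect_equal(g2$n[g2$class == "normal"], 0L)

  # uniform tau gives equal class medians
  ft3 <- make_fit_table(d0 = rep(c(-700, -300), each = 50),
                        dinf = rep(c(-650, -250), each = 50),
                        tau_s = 0.5)
  g3 <- group_tau_by_class(ft3, classify_aeration(ft3$d_ee))
  expect_equal(g3$tau_median_s[g3$class == "normal"],
               g3$tau_median_s[g3$class == "poor"])
})

test_that("relative height maps mask extent onto [0, 1]", {
  mask <- array(FALSE, c(5, 9, 5))
  mask[, 2:8, ] <- TRUE
  co <- rbind(c(3, 2, 3), c(3, 8, 3), c(3, 5, 3))
  h <- relative_height(co, mask, 2)
  expect_equal(h, c(0, 1, 0.5))
  flat <- array(FALSE, c(5, 9, 5))
  flat[, 4, ] <- TRUE
  expect_error(relative_height(co, flat, 2), "degenerate")
})

test_that("height profiles recover the imposed gravitational gradients", {
  ph <- clean_phantom_full()
  fits <- fit_cached("clean48", ph$seq)
  hp <- height_profile(fits, ph$seq$mask, ph$spec$gravity_axis,
                       n_bins = 10)
  expect_equal(sum(hp$n), sum(fits$significant & !is.na(fits$tau_s)))
  # dorsal fast / ventral slow; dorsal dense / ventral aerated
  expect_equal(cor(hp$bin, hp$tau_s_median, method = "spearman"), 1)
  expect_equal(cor(hp$bin, hp$d_ee_median, method = "spearman"), -1)
  expect_equal(cor(hp$bin, hp$d0_median, method = "spearman"), -1)
})

test_that("flat fields give flat height profiles", {
  ft <- make_fit_table(d0 = rep(-600, 200), dinf = rep(-500, 200),
                       tau_s = 0.5, dim = c(200, 5, 5))
  ft$x <- seq_len(200)
  mask <- array(FALSE, c(200, 5, 5))
  mask[cbind(ft$x, ft$y, ft$z)] <- TRUE
  hp <- height_profile(ft, mask, 1, n_bins = 5)
  expect_equal(unique(hp$tau_s_median), 0.5)
  expect_equal(unique(hp$d_ee_median), ft$d_ee[1])
})

test_that("PRM mass sits on the identity line when nothing changes", {
  ft <- make_fit_table(d0 = runif(100, -900, -200),
                       dinf = NA, tau_s = 0.4)
  ft$dinf <- ft$d0
  prm <- build_prm(ft, bin_width_hu = 25)
  expect_equal(sum(prm$probability), 1, tolerance = 1e-12)
  occupied <- which(prm$probability > 0, arr.ind = TRUE)
  expect_true(all(occupied[, 1] == occupied[, 2]))
})

test_that("PRM cell gating requires half the subjects with 5+ voxels", {
  # cell A: subject 1 contributes 6 voxels, others 1 -> excluded (1 < 2)
  # cell B: subjects 1 and 2 contribute 5 voxels each -> included
  mk <- function(nA, nB) {
    make_fit_table(d0 = c(rep(-712, nA), rep(-312, nB)),
                   dinf = c(rep(-712, nA), rep(-312, nB)),
                   tau_s = 0.5)
  }
  subjects <- list(mk(6, 5), mk(1, 5), mk(1, 1), mk(1, 1))
  prm <- build_prm(subjects, bin_width_hu = 25)
  cellA <- c(cut(-712, prm$bin_edges_hu, labels = FALSE),
             cut(-712, prm$bin_edges_hu, labels = FALSE))
  cellB <- c(cut(-312, prm$bin_edges_hu, labels = FALSE),
             cut(-312, prm$bin_edges_hu, labels = FALSE))
  expect_false(prm$inclusion_mask[cellA[1], cellA[2]])
  expect_true(prm$inclusion_mask[cellB[1], cellB[2]])
  expect_true(is.na(prm$median_tau_s[cellA[1], cellA[2]]))
  expect_equal(prm$median_tau_s[cellB[1], cellB[2]], 0.5)
  # constructed counts are preserved per subject
  expect_equal(prm$counts[cellA[1], cellA[2], 1], 6L)
  expect_equal(prm$counts[cellB[1], cellB[2], 2], 5L)
  # raising the inclusion threshold never adds cells
  prm6 <- build_prm(subjects, bin_width_hu = 25,
                    min_voxels_per_subject = 6)
  expect_true(all(prm$inclusion_mask | !prm6$inclusion_mask))
})

test_that("nonequilibrated change follows the closed form", {
  g <- build_phase_grid(21, 20, c(1, 2), 1)
  t <- g$expiratory_times_s
  mk_fit <- function(tau) {
    y <- -250 + (-400 - -250) * exp(-t / tau)
    fit_exponential(t, y, t_exp_s = 2)
  }
  # tau = t_exp / 5: remaining change is e^-5 of the full amplitude
  f5 <- mk_fit(2 / 5)
  expect_equal(f5$nonequilibrated_change, 150 * exp(-5), tolerance = 1e-6)
  # D0 = -400, Dinf = -250, tau = 1, t_exp = 2 -> 150 * e^-2 = 20.30 HU
  f1 <- mk_fit(1)
  expect_equal(f1$nonequilibrated_change, 150 * exp(-2), tolerance = 1e-6)
  expect_equal(f1$nonequilibrated_change, 20.30, tolerance = 1e-3)
  # instant equilibration
  f0 <- mk_fit(1e-3)
  expect_lt(abs(f0$nonequilibrated_change), 1e-9)
})

test_that("normalized convergence points fall on the theoretical curve", {
  ph <- clean_phantom_small()
  fits <- fit_cached("clean24", ph$seq)
  nc <- normalized_convergence(fits, t_exp_s = 2)
  expect_equal(nc$points$remaining_fraction,
               nc$curve(nc$points$tau_norm), tolerance = 1e-8)
  expect_equal(convergence_curve(0.2), exp(-5))
  expect_equal(convergence_curve(1), exp(-1))
  expect_gt(convergence_curve(1e9), 0.999)  # no decay in the limit
  # amplitude floor omits near-static voxels
  ft <- make_fit_table(d0 = c(-500, -500), dinf = c(-499, -400),
                       tau_s = 0.5)
  nc2 <- normalized_convergence(ft, t_exp_s = 2)
  expect_equal(nrow(nc2$points), 1L)
  expect_equal(nc2$n_omitted, 1L)
})

test_that("identical time constants correlate perfectly; null pairs at alpha", {
  ft <- make_fit_table(d0 = runif(50, -800, -300),
                       dinf = runif(50, -800, -300),
                       tau_s = runif(50, 0.2, 1))
  r <- tau_correlation(ft, ft)
  expect_equal(r$per_subject$rho, 1)
  expect_equal(r$fraction_significant, 1)

  # independent tau pairs: significant fraction near the nominal level
  set.seed(99)
  subs_d <- lapply(1:300, function(i)
    make_fit_table(d0 = rep(-600, 30), dinf = rep(-500, 30),
                   tau_s = runif(30, 0.2, 1)))
  subs_s <- lapply(1:300, function(i)
    make_fit_table(d0 = rep(-600, 30), dinf = rep(-500, 30),
                   tau_s = runif(30, 0.2, 1)))
  rn <- tau_correlation(subs_d, subs_s)
  expect_gt(rn$fraction_significant, 0.008)
  expect_lt(rn$fraction_significant, 0.10)

  # too few pairs: subject skipped, not fabricated
  small <- make_fit_table(d0 = rep(-600, 4), dinf = rep(-500, 4),
                          tau_s = 0.5)
  expect_message(rs <- tau_correlation(small, small), "skipped")
  expect_true(is.na(rs$per_subject$rho))
})

test_that("time-course distributions are normalized and start at zero change", {
  ft <- make_fit_table(d0 = runif(200, -800, -400),
                       dinf = runif(200, -500, -200),
                       tau_s = runif(200, 0.2, 1))
  d <- time_course_distributions(ft, times_s = c(0, 0.5, 1, 2))
  for (tm in unique(d$time_s)) {
    expect_equal(sum(d$probability[d$time_s == tm]), 1, tolerance = 1e-12)
  }
  d0only <- d[d$time_s == 0 & d$probability > 0, ]
  expect_equal(nrow(d0only), 1L)  # all mass in the zero-change bin
  expect_lt(abs(d0only$bin_mid), diff(d$bin_mid[1:2]))

  # end-expiration distribution agrees with direct computation of D_EE - D0
  dee <- (ft$dinf - ft$d0) * (1 - exp(-2 / ft$tau_s))
  dT <- d[d$time_s == 2, ]
  step <- diff(dT$bin_mid[1:2])
  expect_equal(sum(dT$bin_mid * dT$probability), mean(dee),
               tolerance = step)
})
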