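# shared phantom fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

fixture_phantom <- function(key, spec) {
  if (is.null(.fixture_cache[[key]])) {
    truth <- generate_parameter_fields(spec)
    seq <- render_sequence(truth, spec)
    .fixture_cache[[key]] <- list(spec = spec, truth = truth, seq = seq)
  }
  .fixture_cache[[key]]
}

# desk-scale noiseless phantom for exact-recovery checks
clean_phantom_small <- function() {
  fixture_phantom("clean24", phantom_spec(grid_shape = c(24, 24, 24),
                                          noise_sigma_hu = 0, seed = 5))
}

# full-scale noiseless phantom (structure-recovery checks)
clean_phantom_full <- function() {
  fixture_phantom("clean48", phantom_spec(noise_sigma_hu = 0, seed = 21))
}

# full-scale noisy phantom at the study noise level
noisy_phantom_full <- function() {
  fixture_phantom("noisy48", phantom_spec(seed = 11))
}

fit_cached <- function(key, seq, downsample = 1L, alpha = 0.05) {
  ck <- paste0("fits_", key)
  if (is.null(.fixture_cache[[ck]])) {
    s <- if (downsample > 1) block_downsample(seq, downsample) else seq
    .fixture_cache[[ck]] <- suppressMessages(
      fit_all_voxels(s, seq$grid, alpha = alpha))
  }
  .fixture_cache[[ck]]
}

# block-mean ground truth aligned with a downsampled fit table
block_truth <- function(truth, factor) {
  zero_na <- function(a) ifelse(is.na(a), 0, a)
  br <- lungtau:::.block_reduce3d
  w <- br(zero_na(!is.na(truth$tau_map) + 0), factor)
  list(
    amp = br(zero_na(truth$dinf_map - truth$d0_map), factor),
    tau = br(zero_na(truth$tau_map), factor) / pmax(w, 1e-9),
    mask_frac = w
  )
}

# hand-constructed voxel fit table for PRM / grouping tests
make_fit_table <- function(d0, dinf, tau_s, significant = TRUE,
                           t_exp_s = 2, dim = c(10, 10, 10)) {
  n <- length(d0)
  tau_s <- rep_len(tau_s, n)
  significant <- rep_len(significant, n)
  d_ee <- dinf + (d0 - dinf) * exp(-t_exp_s / tau_s)
  out <- data.frame(
    voxel = seq_len(n), x = seq_len(n), y = 1L, z = 1L,
    d0 = d0, dinf = dinf, tau_s = tau_s,
    sse_model = 1, sse_mean = 100, at_bound = FALSE,
    d_ee = d_ee, intratidal_change = d_ee - d0,
    nonequilibrated_change = dinf - d_ee,
    f_stat = 50, p_value = ifelse(significant, 1e-6, 0.5),
    significant = significant)
  attr(out, "vol_dim") <- dim
  attr(out, "spacing_mm") <- rep(1.2, 3)
  attr(out, "grid") <- build_phase_grid(21, 20, c(1, 2), 1)
  attr(out, "alpha") <- 0.05
  class(out) <- c("voxel_fit_table", "data.frame")
  out
}
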