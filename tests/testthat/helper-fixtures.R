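# Shared fixtures: rendered frames with known ground truth and helpers for
# matching detections to truth.

# Integrated intensity giving a peak amplitude of `snr` times the pixel
# noise level of the scene's camera model.
snr_intensity <- function(spec, snr) {
  noise_sd <- sqrt(spec$background * spec$photon_scale +
                     spec$read_noise_sd^2)
  s_px <- spec$psf_sigma / spec$pixel_size
  snr * noise_sd * 2 * pi * s_px^2
}

# Truth + rendered frame with n spots of fixed SNR, kept off the border.
rendered_frame <- function(spec, n, snr = 10, seed = 1) {
  truth <- gen_spot_field(spec, n = n, margin = 0.5, seed = seed)
  truth$intensity <- snr_intensity(spec, snr)
  img <- render_tirf_frame(truth, spec, seed = seed + 5000L)
  list(truth = truth, image = img)
}

# Match detections to ground truth within a radius. Recall asks whether
# any detection lies within the radius of each truth (sensitivity);
# localization error is measured over greedy one-to-one truth-detection
# pairs, so a detection covering a merged pair is charged to recall, not
# to accuracy.
match_spots <- function(truth, detected, radius) {
  if (nrow(detected) == 0L)
    return(list(recall = 0, false_pos = 0, rms = NA_real_, pair_d2 = numeric()))
  d2 <- outer(truth$x, detected$x, "-")^2 + outer(truth$y, detected$y, "-")^2
  matched <- apply(d2, 1, function(r) any(r < radius^2))
  fp <- sum(!apply(d2, 2, function(cc) any(cc < radius^2)))
  used_t <- rep(FALSE, nrow(truth))
  used_d <- rep(FALSE, nrow(detected))
  pair_d2 <- numeric()
  for (k in order(d2)) {
    if (d2[k] >= radius^2) break
    i <- (k - 1L) %% nrow(truth) + 1L
    j <- (k - 1L) %/% nrow(truth) + 1L
    if (!used_t[i] && !used_d[j]) {
      used_t[i] <- used_d[j] <- TRUE
      pair_d2 <- c(pair_d2, d2[k])
    }
  }
  list(recall = mean(matched), false_pos = fp,
       rms = sqrt(mean(pair_d2)), pair_d2 = pair_d2)
}

# Simulation scenario used for the rate-recovery studies (single-molecule
# synthesis rate paired with the slow overexpression-regime degradation).
recovery_params <- function()
  kinetic_params(F_max = 1, n_syn = 2, tau_syn = 1 / 1.09,
                 n_deg = 2, tau_deg = 1 / 0.13)

recovery_grid <- function() seq(-2, 15, by = 0.5)
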