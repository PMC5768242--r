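# Fixtures built in code: recordings, parametric spectra with known 1/f
# background, and hand-made hemisphere datasets.

make_rec <- function(x, fs, ids = NULL, min_dur = 1) {
  lfp_recording(as.matrix(x), fs = fs, channel_ids = ids,
                min_duration_s = min_dur)
}

sine_rec <- function(freq, amp = 1, fs = 200, dur = 120, id = "2") {
  t <- (0:(fs * dur - 1)) / fs
  make_rec(amp * sin(2 * pi * freq * t), fs, ids = id)
}

# contact_spectra object from an explicit PSD vector
make_spec <- function(freqs, psd, id = "2") {
  structure(list(freqs = freqs, psd = matrix(psd, ncol = 1,
                                             dimnames = list(NULL, id)),
                 channel_ids = id, n_windows = 1L, win_s = 1, overlap = 0),
            class = "contact_spectra")
}

# parametric test spectrum: A * f^-alpha background times Gaussian bumps
# expressed in dB; returns the spectrum plus the true bump profile so a
# brute-force oracle can subtract the exact background.
bump_spectrum <- function(freqs = seq(1, 60, by = 0.5), A = 10, alpha = 1.3,
                          centers = numeric(), heights_db = numeric(),
                          widths = numeric(), id = "2") {
  bump_db <- rep(0, length(freqs))
  for (i in seq_along(centers))
    bump_db <- bump_db + heights_db[i] *
      exp(-(freqs - centers[i])^2 / (2 * widths[i]^2))
  psd <- A * freqs^(-alpha) * 10^(bump_db / 10)
  list(spec = make_spec(freqs, psd, id), freqs = freqs, bump_db = bump_db)
}

# independent oracle: on the exact background-subtracted profile, find local
# maxima inside the band and keep the most prominent one above the threshold
brute_force_peak <- function(freqs, bump_db, band = c(13, 35),
                             prominence_db = 3) {
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  is_max <- vapply(in_band, function(i) {
    left <- if (i > 1) bump_db[i - 1] else -Inf
    right <- if (i < length(freqs)) bump_db[i + 1] else -Inf
    bump_db[i] >= left && bump_db[i] >= right
  }, logical(1))
  cand <- in_band[is_max & bump_db[in_band] >= prominence_db]
  if (!length(cand)) return(list(present = FALSE, peak_freq = NA))
  list(present = TRUE, peak_freq = freqs[cand[which.max(bump_db[cand])]])
}

# hand-made hemisphere dataset from explicit per-contact vectors (ids 2..7)
make_hemi <- function(id, beta, efficacy, tw = rev(seq_along(beta)),
                      has_peak = TRUE, rigidity = 3) {
  ids <- as.character(2:7)
  hemisphere_dataset(
    id,
    beta = data.frame(contact_id = ids, value = beta,
                      used_fallback = !has_peak),
    clinical = data.frame(contact_id = ids, efficacy = efficacy, tw = tw),
    has_beta_peak = has_peak,
    review = data.frame(hemisphere_id = id, contact_id = ids,
                        rigidity_baseline = rigidity,
                        rigidity_on_stim = rigidity / 2,
                        test_current = 2, effect_threshold = 1,
                        side_effect_threshold = 3),
    level_of_max_beta = "dorsal")
}

# fast simulation settings for tests (short, low sampling rate)
fast_cfg <- function(...) {
  defaults <- list(n_hemispheres = 6, fs = 150, duration_s = 30, seed = 7L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
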