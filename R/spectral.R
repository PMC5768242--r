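#' Welch power spectral density per contact
#'
#' Averaged, Hann-tapered periodogram of each channel. Segments are demeaned
#' before tapering and the one-sided density is scaled so that the integral of
#' the PSD over \[0, fs/2\] matches the signal variance (Parseval property).
#' The default 1-second window gives 1 Hz frequency resolution, enough to
#' separate low (13-20 Hz) from high (20-35 Hz) beta.
#'
#' @param rec An [lfp_recording()].
#' @param win_s Window length in seconds.
#' @param overlap Fractional overlap between successive windows, in \[0, 1).
#' @return Object of class `contact_spectra`: list with `freqs` (Hz),
#'   `psd` (matrix, frequencies x channels, microV^2/Hz), `channel_ids`,
#'   `n_windows`, `win_s`, `overlap`.
#' @export
compute_psd <- function(rec, win_s = 1, overlap = 0.5) {
  st <- stft_psd(rec, win_s = win_s,
                 step_s = win_s * (1 - overlap))
  psd <- vapply(st$power, rowMeans, numeric(length(st$freqs)))
  colnames(psd) <- rec$channel_ids
  structure(list(freqs = st$freqs, psd = psd, channel_ids = rec$channel_ids,
                 n_windows = length(st$times), win_s = win_s,
                 overlap = overlap),
            class = "contact_spectra")
}

#' @export
print.contact_spectra <- function(x, ...) {
  cat(sprintf(
    "Contact spectra: %d channel(s), %g-%g Hz at %.3g Hz resolution, %d window(s)\n",
    length(x$channel_ids), min(x$freqs), max(x$freqs),
    x$freqs[2] - x$freqs[1], x$n_windows))
  invisible(x)
}

#' Time-frequency spectrogram per contact
#'
#' Short-time PSD on sliding windows; each time slice uses the same scaling
#' as [compute_psd()], so averaging the map over time recovers the Welch
#' estimate computed with the corresponding overlap.
#'
#' @inheritParams compute_psd
#' @param step_s Hop between successive windows in seconds.
#' @return Object of class `contact_spectrogram`: list with `freqs`, `times`
#'   (window centers, s), `power` (named list of frequency x time matrices,
#'   one per channel).
#' @export
compute_spectrogram <- function(rec, win_s = 1, step_s = 0.5) {
  st <- stft_psd(rec, win_s = win_s, step_s = step_s)
  structure(list(freqs = st$freqs, times = st$times, power = st$power,
                 channel_ids = rec$channel_ids),
            class = "contact_spectrogram")
}

# shared STFT core: demeaned, Hann-tapered, one-sided density scaling
stft_psd <- function(rec, win_s, step_s) {
  fs <- rec$fs
  n <- nrow(rec$samples)
  L <- round(win_s * fs)
  if (L < 2L) stop("window must span at least 2 samples")
  if (L > n) stop("recording shorter than one window")
  step <- max(1L, round(step_s * fs))
  for (j in seq_along(rec$channel_ids))
    if (anyNA(rec$samples[, j]))
      stop("NaN/NA samples in channel ", rec$channel_ids[j])
  w <- signal::hanning(L)
  starts <- seq(1L, n - L + 1L, by = step)
  nf <- L %/% 2L + 1L
  # one-sided density: 2/(fs * sum(w^2)), no doubling at DC (and Nyquist)
  sc <- 2 / (fs * sum(w^2))
  one_sided <- rep(sc, nf)
  one_sided[1L] <- sc / 2
  if (L %% 2L == 0L) one_sided[nf] <- sc / 2
  idx <- outer(0:(L - 1L), starts, `+`)
  power <- lapply(seq_along(rec$channel_ids), function(j) {
    segs <- matrix(rec$samples[idx, j], nrow = L)
    segs <- sweep(segs, 2L, colMeans(segs)) * w
    X <- stats::mvfft(segs)
    (Mod(X[seq_len(nf), , drop = FALSE])^2) * one_sided
  })
  names(power) <- rec$channel_ids
  list(freqs = (0:(nf - 1L)) * fs / L,
       times = (starts - 1L + L / 2) / fs,
       power = power)
}

# integrated band power by the trapezoid rule with interpolated band edges
band_power <- function(freqs, psd, lo, hi) {
  if (hi <= lo) stop("empty band")
  if (lo < min(freqs) || hi > max(freqs))
    stop(sprintf("band [%g, %g] Hz outside spectrum support [%g, %g] Hz",
                 lo, hi, min(freqs), max(freqs)))
  inside <- freqs > lo & freqs < hi
  f <- c(lo, freqs[inside], hi)
  p <- c(stats::approx(freqs, psd, xout = lo)$y, psd[inside],
         stats::approx(freqs, psd, xout = hi)$y)
  pracma::trapz(f, p)
}

get_psd <- function(spec, channel = NULL) {
  if (is.null(channel)) {
    if (ncol(spec$psd) != 1L)
      stop("spectrum holds several channels; supply `channel`")
    channel <- spec$channel_ids[1L]
  }
  j <- match(as.character(channel), spec$channel_ids)
  if (is.na(j)) stop("unknown channel: ", channel)
  spec$psd[, j]
}

# log-log linear 1/f background fit on fit_range, excluding the beta band
fit_background <- function(freqs, psd, fit_range = c(5, 45),
                           exclude = c(13, 35)) {
  sel <- freqs >= fit_range[1] & freqs <= fit_range[2] &
    !(freqs >= exclude[1] & freqs <= exclude[2]) & psd > 0
  if (sum(sel) < 3L) stop("too few points to fit the 1/f background")
  fit <- stats::lm(y ~ x, data = data.frame(x = log10(freqs[sel]),
                                            y = log10(psd[sel])))
  cf <- stats::coef(fit)
  function(f) 10^(cf[[1]] + cf[[2]] * log10(f))
}

#' Detect a beta peak over the 1/f background
#'
#' Fits a linear 1/f background to the log-log spectrum over `fit_range`
#' (excluding the beta band itself), then searches the 13-35 Hz band for local
#' maxima of the background-subtracted spectrum. A peak is reported when the
#' largest such maximum rises at least `prominence_db` decibels above the
#' fitted background; among several qualifying maxima the most prominent one
#' wins. The peak band is the peak frequency plus/minus `halfwidth_hz`,
#' clipped to the beta band, and the peak is classified as "low" (<= 20 Hz)
#' or "high" (> 20 Hz).
#'
#' @param spec A `contact_spectra` object from [compute_psd()].
#' @param channel Channel id to analyse (may be omitted for a single-channel
#'   spectrum).
#' @param band Beta band limits in Hz.
#' @param prominence_db Required height above the fitted background, in dB.
#' @param halfwidth_hz Half-width of the peak band in Hz.
#' @param fit_range Frequency range used for the background fit.
#' @return Object of class `beta_peak`: list with `present`, `peak_freq`,
#'   `peak_band`, `classification`, `prominence_db`, `fallback_band`.
#' @export
detect_beta_peak <- function(spec, channel = NULL, band = c(13, 35),
                             prominence_db = 3, halfwidth_hz = 3,
                             fit_range = c(5, 45)) {
  freqs <- spec$freqs
  psd <- get_psd(spec, channel)
  if (band[1] < min(freqs) || band[2] > max(freqs))
    stop(sprintf("beta band [%g, %g] Hz outside spectrum support", band[1], band[2]))
  no_peak <- structure(list(present = FALSE, peak_freq = NA_real_,
                            peak_band = c(NA_real_, NA_real_),
                            classification = NA_character_,
                            prominence_db = NA_real_,
                            fallback_band = c(band[1], 20)),
                       class = "beta_peak")
  if (all(psd[freqs >= fit_range[1] & freqs <= fit_range[2]] <= 0))
    return(no_peak)
  bg <- fit_background(freqs, psd, fit_range = fit_range, exclude = band)
  resid_db <- 10 * (log10(pmax(psd, .Machine$double.xmin)) - log10(bg(pmax(freqs, 1e-6))))
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  is_max <- vapply(in_band, function(i) {
    left <- if (i > 1L) resid_db[i - 1L] else -Inf
    right <- if (i < length(freqs)) resid_db[i + 1L] else -Inf
    resid_db[i] >= left && resid_db[i] >= right
  }, logical(1))
  cand <- in_band[is_max & resid_db[in_band] >= prominence_db]
  if (!length(cand)) return(no_peak)
  best <- cand[which.max(resid_db[cand])]
  pf <- freqs[best]
  pb <- c(max(band[1], pf - halfwidth_hz), min(band[2], pf + halfwidth_hz))
  structure(list(present = TRUE, peak_freq = pf, peak_band = pb,
                 classification = if (pf <= 20) "low" else "high",
                 prominence_db = resid_db[best],
                 fallback_band = c(band[1], 20)),
            class = "beta_peak")
}

#' @export
print.beta_peak <- function(x, ...) {
  if (x$present)
    cat(sprintf("Beta peak at %.1f Hz (%s beta), band %.1f-%.1f Hz, %.1f dB above 1/f\n",
                x$peak_freq, x$classification, x$peak_band[1], x$peak_band[2],
                x$prominence_db))
  else
    cat(sprintf("No beta peak; fallback band %.1f-%.1f Hz\n",
                x$fallback_band[1], x$fallback_band[2]))
  invisible(x)
}

#' Normalized beta statistic for one contact
#'
#' Integrated power in the detected beta-peak band divided by integrated power
#' in the whole 13-35 Hz beta band. When no peak is present the low beta band
#' (13-20 Hz) is used as numerator and the result is flagged as a fallback.
#' Because the numerator band is a subset of the denominator band the value
#' lies in \[0, 1\], and it is invariant to any overall gain applied to the
#' channel. With `statistic = "amplitude"` the square root of each band power
#' is used instead (an amplitude rather than power ratio; the contact ranking
#' is unchanged since the square root is monotone).
#'
#' @param spec A `contact_spectra` object.
#' @param peak A `beta_peak` from [detect_beta_peak()].
#' @param channel Channel id (may be omitted for a single-channel spectrum).
#' @param band Beta band limits in Hz (denominator band).
#' @param statistic `"power"` (default) or `"amplitude"`.
#' @return data.frame with columns `contact_id`, `value`, `used_fallback`.
#' @export
normalized_beta <- function(spec, peak, channel = NULL, band = c(13, 35),
                            statistic = c("power", "amplitude")) {
  statistic <- match.arg(statistic)
  psd <- get_psd(spec, channel)
  if (is.null(channel)) channel <- spec$channel_ids[1L]
  num_band <- if (peak$present) peak$peak_band else peak$fallback_band
  den <- band_power(spec$freqs, psd, band[1], band[2])
  if (den <= 0)
    stop("zero power in the ", band[1], "-", band[2],
         " Hz band for channel ", channel)
  num <- band_power(spec$freqs, psd, num_band[1], num_band[2])
  value <- if (statistic == "power") num / den else sqrt(num) / sqrt(den)
  data.frame(contact_id = as.character(channel), value = value,
             used_fallback = !peak$present)
}

#' Normalized beta profile across the six directional contacts
#'
#' Hemisphere-level analysis: computes Welch spectra for all six segmented
#' contacts, detects the beta peak once -- on the contact with the largest raw
#' 13-35 Hz power -- and reuses that peak band for every contact, so the
#' normalized values are comparable across contacts (a per-contact band choice
#' would confound band selection with power).
#'
#' @param rec An [lfp_recording()] with one channel per segmented contact.
#' @param lead A [directional_lead()].
#' @inheritParams compute_psd
#' @inheritParams detect_beta_peak
#' @inheritParams normalized_beta
#' @return data.frame (class `beta_profile`) with one row per segmented
#'   contact: `contact_id`, `value`, `used_fallback`, plus attributes
#'   `peak` (the hemisphere-level `beta_peak`), `ref_channel` (contact the
#'   peak was detected on) and `spectra`.
#' @export
hemisphere_beta_profile <- function(rec, lead = directional_lead(),
                                    win_s = 1, overlap = 0.5, band = c(13, 35),
                                    prominence_db = 3, halfwidth_hz = 3,
                                    fit_range = c(5, 45),
                                    statistic = c("power", "amplitude")) {
  statistic <- match.arg(statistic)
  wanted <- as.character(lead$segmented_ids)
  missing_ids <- setdiff(wanted, rec$channel_ids)
  if (length(missing_ids))
    stop("missing channel(s) for segmented contact(s): ",
         paste(missing_ids, collapse = ", "))
  spec <- compute_psd(rec, win_s = win_s, overlap = overlap)
  raw_beta <- vapply(wanted, function(id)
    band_power(spec$freqs, get_psd(spec, id), band[1], band[2]), numeric(1))
  ref <- wanted[which.max(raw_beta)]
  peak <- detect_beta_peak(spec, channel = ref, band = band,
                           prominence_db = prominence_db,
                           halfwidth_hz = halfwidth_hz, fit_range = fit_range)
  rows <- do.call(rbind, lapply(wanted, function(id)
    normalized_beta(spec, peak, channel = id, band = band,
                    statistic = statistic)))
  rownames(rows) <- NULL
  structure(rows, peak = peak, ref_channel = ref, raw_beta = raw_beta,
            spectra = spec, class = c("beta_profile", "data.frame"))
}

#' Export contact spectra as delimited text
#'
#' @param spec A `contact_spectra` object.
#' @param path Output path (tab-delimited; `freq` column then one `c<id>`
#'   column per contact).
#' @export
write_spectra_tsv <- function(spec, path) {
  out <- data.frame(freq = spec$freqs, spec$psd, check.names = FALSE)
  names(out) <- c("freq", paste0("c", spec$channel_ids))
  utils::write.table(format(out, digits = 8, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
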