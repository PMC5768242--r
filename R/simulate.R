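#' Simulation configuration for synthetic directional-LFP cohorts
#'
#' Defines the generative model used throughout the test suite: a beta source
#' at an angular position and a depth (level) between the two segmented rings
#' drives (a) the beta-band oscillation seen by each contact, attenuated
#' exponentially with angular distance and level distance, on top of an
#' independent 1/f background per contact, and (b) the clinical response
#' (efficacy and therapeutic window) through the same source-proximity
#' signal, so LFP-guided contact selection has genuine predictive value.
#'
#' Hemispheres without a clear oscillatory peak (probability
#' `1 - peak_prob`, emulating the 7-of-19 no-peak hemispheres of a typical
#' cohort) receive a weak low-beta oscillation (`nopeak_amp_frac` of the full
#' amplitude, frequency drawn from 14-19 Hz) that stays below the detection
#' threshold, so the low-beta fallback path is exercised while directional
#' information remains partially present.
#'
#' @param n_hemispheres Cohort size (default 19).
#' @param fs Sampling rate in Hz (default 1000).
#' @param duration_s Recording length per hemisphere in seconds (default 120).
#' @param source_angle_deg Beta source angle; `NULL` draws uniformly on
#'   \[0, 360).
#' @param source_level Beta source depth on the contact-level axis, in
#'   \[2, 3\]; `NULL` draws `2 + rbeta(2.2, 1.2)` (dorsally weighted, as
#'   beta sources sit in the dorsolateral motor region).
#' @param beta_freq Peak frequency in Hz; `NULL` draws uniformly on
#'   \[15, 30\] (14-19 for no-peak hemispheres).
#' @param beta_amp Oscillation RMS amplitude at the source, microvolts.
#' @param angular_decay Amplitude attenuation per degree of angular distance.
#' @param level_decay Amplitude attenuation per unit of level distance.
#' @param one_over_f_exponent Spectral slope of the background.
#' @param bg_scale Background PSD scale (microV^2/Hz at 1 Hz).
#' @param noise_floor Additive white PSD floor (microV^2/Hz).
#' @param peak_prob Probability that a hemisphere has a clear beta peak
#'   (default 12/19).
#' @param nopeak_amp_frac Fraction of `beta_amp` given to no-peak hemispheres.
#' @param coupling Efficacy gained per unit source proximity (percent/mA);
#'   0 decouples clinical response from beta.
#' @param eff_base Baseline efficacy (percent/mA) at zero proximity.
#' @param efficacy_noise_sd SD of the Gaussian efficacy noise (percent/mA).
#' @param tw_base,tw_gain,tw_noise_sd Therapeutic-window model (mA):
#'   `tw_base + tw_gain * proximity + noise`, clipped at 0.
#' @param effect_base,effect_gain,effect_noise_sd Effect-threshold model
#'   (mA): `effect_base - effect_gain * proximity + noise`, floored at 0.5.
#' @param test_current Current used for rigidity testing (mA).
#' @param current_ceiling Maximum tested current; side-effect thresholds
#'   beyond it are recorded as not reached.
#' @param seed Base seed; each hemisphere uses an independent derived
#'   substream, so cohorts are reproducible.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_hemispheres = 19, fs = 1000, duration_s = 120,
                       source_angle_deg = NULL, source_level = NULL,
                       beta_freq = NULL, beta_amp = 3,
                       angular_decay = 0.006, level_decay = 0.7,
                       one_over_f_exponent = 1.5, bg_scale = 10,
                       noise_floor = 0.02, peak_prob = 12 / 19,
                       nopeak_amp_frac = 0.2,
                       coupling = 20, eff_base = 15, efficacy_noise_sd = 8,
                       tw_base = 0.6, tw_gain = 1.2, tw_noise_sd = 0.4,
                       effect_base = 2.5, effect_gain = 1.5,
                       effect_noise_sd = 0.3,
                       test_current = 2, current_ceiling = 5, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, name) if (!isTRUE(ok)) bad <<- c(bad, name)
  chk(cfg$n_hemispheres >= 0, "n_hemispheres")
  chk(is.numeric(cfg$fs) && cfg$fs > 70, "fs")
  chk(cfg$duration_s > 0, "duration_s")
  chk(cfg$peak_prob >= 0 && cfg$peak_prob <= 1, "peak_prob")
  chk(cfg$beta_amp >= 0, "beta_amp")
  chk(cfg$angular_decay >= 0, "angular_decay")
  chk(cfg$level_decay >= 0, "level_decay")
  chk(cfg$noise_floor >= 0, "noise_floor")
  chk(cfg$bg_scale >= 0, "bg_scale")
  chk(cfg$nopeak_amp_frac >= 0 && cfg$nopeak_amp_frac <= 1, "nopeak_amp_frac")
  chk(cfg$efficacy_noise_sd >= 0, "efficacy_noise_sd")
  chk(cfg$tw_noise_sd >= 0, "tw_noise_sd")
  chk(cfg$test_current > 0, "test_current")
  chk(cfg$current_ceiling > 0, "current_ceiling")
  if (!is.null(cfg$source_level))
    chk(cfg$source_level >= 2 && cfg$source_level <= 3, "source_level")
  if (length(bad))
    stop("invalid simulation config field(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d hemisphere(s), fs = %g Hz, %g s, peak_prob = %.2f, coupling = %g\n",
    x$n_hemispheres, x$fs, x$duration_s, x$peak_prob, x$coupling))
  invisible(x)
}

# colored-noise synthesis by frequency-domain shaping of white noise;
# target is the one-sided PSD function S(f) in microV^2/Hz
shaped_noise <- function(n, fs, S) {
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                     # two-sided frequency map
  H <- sqrt(pmax(S(pmax(f, 0.5)), 0) * fs / 2)
  H[1] <- 0                                # no DC
  Z <- stats::fft(stats::rnorm(n))
  Re(stats::fft(Z * H, inverse = TRUE)) / n
}

# narrowband process: white noise through a Gaussian frequency window
# centered at f0 (sd 1 Hz, effectively +/- 2 Hz), normalized to unit RMS
narrowband_noise <- function(n, fs, f0, bw_sd = 1) {
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  G <- exp(-(f - f0)^2 / (2 * bw_sd^2))
  Z <- stats::fft(stats::rnorm(n))
  b <- Re(stats::fft(Z * G, inverse = TRUE)) / n
  b / stats::sd(b)
}

# per-contact amplitude attenuation given the source position
source_attenuation <- function(cfg, lead, source_angle, source_level) {
  con <- lead$contacts[lead$contacts$is_segmented, ]
  a <- exp(-cfg$angular_decay * ang_dist_deg(con$angle_deg, source_angle)) *
    exp(-cfg$level_decay * abs(con$level - source_level))
  stats::setNames(a, as.character(con$id))
}

#' Simulate one hemisphere's directional LFP recording
#'
#' Each segmented contact records an independent 1/f background plus a shared
#' narrowband beta oscillation whose amplitude decays exponentially with the
#' contact's angular and level distance from the beta source. Because the
#' oscillation is shared, contacts aligned on adjacent levels carry
#' correlated beta, reproducing the characteristic motif of a dominant
#' contact together with its aligned partner.
#'
#' @param cfg A [sim_config()].
#' @param hemisphere_id Identifier used in the ground truth.
#' @param seed Seed for this hemisphere's substream (defaults to `cfg$seed`).
#' @return List with `recording` (an [lfp_recording()] over contacts 2-7)
#'   and `truth` (source position, peak frequency and presence, per-contact
#'   true oscillation power and proximity, and the generative best contact).
#' @export
simulate_hemisphere_lfp <- function(cfg, hemisphere_id = "h1",
                                    seed = cfg$seed) {
  validate_sim_config(cfg)
  set.seed(seed)
  lead <- directional_lead()
  source_angle <- if (is.null(cfg$source_angle_deg)) stats::runif(1, 0, 360)
                  else cfg$source_angle_deg
  source_level <- if (is.null(cfg$source_level)) 2 + stats::rbeta(1, 2.2, 1.2)
                  else cfg$source_level
  has_peak <- stats::runif(1) < cfg$peak_prob
  f0 <- if (!is.null(cfg$beta_freq)) cfg$beta_freq
        else if (has_peak) stats::runif(1, 15, 30)
        else stats::runif(1, 14, 19)
  amp <- cfg$beta_amp * if (has_peak) 1 else cfg$nopeak_amp_frac

  atten <- source_attenuation(cfg, lead, source_angle, source_level)
  n <- round(cfg$fs * cfg$duration_s)
  S_bg <- function(f) cfg$bg_scale * f^(-cfg$one_over_f_exponent) +
    cfg$noise_floor
  beta_sig <- if (amp > 0) narrowband_noise(n, cfg$fs, f0) else numeric(n)
  x <- vapply(seq_along(atten), function(i)
    shaped_noise(n, cfg$fs, S_bg) + amp * atten[i] * beta_sig,
    numeric(n))
  rec <- lfp_recording(x, fs = cfg$fs, channel_ids = names(atten),
                       min_duration_s = min(60, cfg$duration_s))
  prox <- atten / max(atten)
  truth <- list(hemisphere_id = hemisphere_id,
                source_angle_deg = source_angle, source_level = source_level,
                beta_freq = f0, has_peak = has_peak,
                true_power = (amp * atten)^2, proximity = prox,
                best_contact = names(atten)[which.max(atten)])
  list(recording = rec, truth = truth)
}

#' Simulate a monopolar review from generative ground truth
#'
#' Expected clinical efficacy rises linearly with the contact's proximity to
#' the beta source (slope `coupling`), with additive Gaussian noise; rigidity
#' improvement is bounded to \[-50, 100\] percent. The effect threshold falls
#' and the therapeutic window widens with proximity; side-effect thresholds
#' exceeding the current ceiling are recorded as not reached (`NA`).
#' Rigidity on stimulation is stored as a continuous score (a within-session
#' average of repeated ratings), so contact-level efficacy contrasts are not
#' quantized away.
#'
#' @param cfg A [sim_config()].
#' @param truth Ground truth from [simulate_hemisphere_lfp()].
#' @param seed Seed for the review substream.
#' @return data.frame, one row per segmented contact, with the monopolar
#'   review columns.
#' @export
simulate_review <- function(cfg, truth, seed = cfg$seed) {
  validate_sim_config(cfg)
  set.seed(seed)
  prox <- truth$proximity
  k <- length(prox)
  eff <- cfg$eff_base + cfg$coupling * prox +
    stats::rnorm(k, 0, cfg$efficacy_noise_sd)
  improvement <- pmin(pmax(eff * cfg$test_current, -50), 100)  # percent
  baseline <- sample(2:4, 1)
  on_stim <- baseline * (1 - improvement / 100)
  effect_thr <- pmax(0.5, cfg$effect_base - cfg$effect_gain * prox +
                       stats::rnorm(k, 0, cfg$effect_noise_sd))
  tw <- pmax(0, cfg$tw_base + cfg$tw_gain * prox +
               stats::rnorm(k, 0, cfg$tw_noise_sd))
  side_thr <- effect_thr + tw
  side_thr[side_thr > cfg$current_ceiling] <- NA   # not reached
  data.frame(hemisphere_id = as.character(truth$hemisphere_id),
             contact_id = names(prox),
             rigidity_baseline = baseline,
             rigidity_on_stim = round(on_stim, 3),
             test_current = cfg$test_current,
             effect_threshold = round(effect_thr, 2),
             side_effect_threshold = round(side_thr, 2))
}

#' Generate a synthetic directional-LFP cohort
#'
#' Draws `n_hemispheres` independent hemispheres (each from its own seed
#' substream, so generation is reproducible and parallelizable), pairing an
#' LFP recording with a monopolar review coupled to the same beta source.
#' Optionally serializes everything to a directory; see [write_cohort()].
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @param format `"tsv"` or `"edf"` for the LFP files when writing.
#' @return Object of class `lfp_cohort`: list of per-hemisphere lists
#'   (`hemisphere_id`, `recording`, `review`, `truth`), with the config as
#'   attribute.
#' @export
generate_cohort <- function(cfg, dir = NULL, format = c("tsv", "edf")) {
  validate_sim_config(cfg)
  format <- match.arg(format)
  set.seed(cfg$seed)
  n <- cfg$n_hemispheres
  sub_seeds <- if (n > 0) sample.int(.Machine$integer.max - 1L, 2L * n)
               else integer()
  hems <- lapply(seq_len(n), function(i) {
    hid <- sprintf("h%02d", i)
    sim <- simulate_hemisphere_lfp(cfg, hemisphere_id = hid,
                                   seed = sub_seeds[2L * i - 1L])
    review <- simulate_review(cfg, sim$truth, seed = sub_seeds[2L * i])
    list(hemisphere_id = hid, recording = sim$recording, review = review,
         truth = sim$truth)
  })
  cohort <- structure(hems, config = cfg, class = "lfp_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir, format = format)
  cohort
}

#' @export
print.lfp_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  npk <- sum(vapply(x, function(h) isTRUE(h$truth$has_peak), logical(1)))
  cat(sprintf("Synthetic LFP cohort: %d hemisphere(s) (%d with beta peak), fs = %g Hz, %g s\n",
              length(x), npk, cfg$fs, cfg$duration_s))
  invisible(x)
}

#' Serialize / load a synthetic cohort
#'
#' Directory layout: `config.json` (the echoed simulation config),
#' `review.tsv` (all hemispheres), `ground_truth.tsv`, and one LFP file per
#' hemisphere under `lfp/` (`h01.tsv` or `h01.edf`).
#'
#' @param cohort An `lfp_cohort` from [generate_cohort()].
#' @param dir Directory path.
#' @param format LFP file format, `"tsv"` or `"edf"`.
#' @return `dir` (for `write_cohort`) or an `lfp_cohort` (for `read_cohort`),
#'   the latter without truth-level attenuation details beyond the stored
#'   table.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "edf")) {
  format <- match.arg(format)
  cfg <- attr(cohort, "config")
  ok <- dir.create(file.path(dir, "lfp"), recursive = TRUE,
                   showWarnings = FALSE)
  if (!dir.exists(file.path(dir, "lfp")))
    stop("cannot create cohort directory: ", file.path(dir, "lfp"))
  cfg_out <- cfg
  class(cfg_out) <- NULL
  cfg_out[vapply(cfg_out, is.null, logical(1))] <- NA
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  reviews <- do.call(rbind, lapply(cohort, `[[`, "review"))
  if (is.null(reviews))
    reviews <- data.frame(hemisphere_id = character(),
                          contact_id = character(),
                          rigidity_baseline = numeric(),
                          rigidity_on_stim = numeric(),
                          test_current = numeric(),
                          effect_threshold = numeric(),
                          side_effect_threshold = numeric())
  write_review_table(reviews, file.path(dir, "review.tsv"))
  truth <- do.call(rbind, lapply(cohort, function(h) {
    tr <- h$truth
    data.frame(hemisphere_id = tr$hemisphere_id,
               contact_id = names(tr$proximity),
               source_angle_deg = tr$source_angle_deg,
               source_level = tr$source_level,
               beta_freq = tr$beta_freq, has_peak = tr$has_peak,
               true_power = as.numeric(tr$true_power),
               proximity = as.numeric(tr$proximity),
               best_contact = tr$best_contact)
  }))
  if (is.null(truth))
    truth <- data.frame(hemisphere_id = character(), contact_id = character(),
                        source_angle_deg = numeric(), source_level = numeric(),
                        beta_freq = numeric(), has_peak = logical(),
                        true_power = numeric(), proximity = numeric(),
                        best_contact = character())
  utils::write.table(format(truth, digits = 8, trim = TRUE),
                     file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (h in cohort) {
    fn <- file.path(dir, "lfp", paste0(h$hemisphere_id, ".", format))
    if (format == "tsv") write_lfp_tsv(h$recording, fn)
    else write_edf(h$recording, fn, recording_id = h$hemisphere_id)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) stop("no config.json in ", dir)
  raw <- jsonlite::read_json(cfg_path)
  raw <- lapply(raw, function(v) if (is.null(v) || isTRUE(is.na(v))) NULL else v)
  cfg <- do.call(sim_config, raw[intersect(names(raw),
                                           names(formals(sim_config)))])
  reviews <- read_review_table(file.path(dir, "review.tsv"))
  truth_tab <- utils::read.delim(file.path(dir, "ground_truth.tsv"))
  files <- sort(list.files(file.path(dir, "lfp"), full.names = TRUE))
  hems <- lapply(files, function(fn) {
    hid <- tools::file_path_sans_ext(basename(fn))
    rec <- if (grepl("\\.edf$", fn)) read_edf(fn, min_duration_s = 1)
           else read_lfp_tsv(fn, fs = cfg$fs, min_duration_s = 1)
    tr_rows <- truth_tab[truth_tab$hemisphere_id == hid, ]
    truth <- if (nrow(tr_rows)) {
      list(hemisphere_id = hid,
           source_angle_deg = tr_rows$source_angle_deg[1],
           source_level = tr_rows$source_level[1],
           beta_freq = tr_rows$beta_freq[1],
           has_peak = as.logical(tr_rows$has_peak[1]),
           true_power = stats::setNames(tr_rows$true_power,
                                        tr_rows$contact_id),
           proximity = stats::setNames(tr_rows$proximity, tr_rows$contact_id),
           best_contact = as.character(tr_rows$best_contact[1]))
    } else NULL
    list(hemisphere_id = hid, recording = rec,
         review = reviews[reviews$hemisphere_id == hid, ], truth = truth)
  })
  structure(hems, config = cfg, class = "lfp_cohort")
}
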