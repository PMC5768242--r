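test_that("a pure sine concentrates its power a^2/2 at its frequency", {
  rec <- sine_rec(freq = 20, amp = 3, fs = 200, dur = 120)
  spec <- compute_psd(rec)
  total <- pracma::trapz(spec$freqs, spec$psd[, 1])
  expect_equal(total, 3^2 / 2, tolerance = 0.02)
  near <- spec$freqs >= 18 & spec$freqs <= 22
  expect_gt(pracma::trapz(spec$freqs[near], spec$psd[near, 1]) / total, 0.95)
})

test_that("zero signal gives an identically zero PSD and spectrogram", {
  rec <- make_rec(matrix(0, 2000, 1), fs = 100, ids = "2")
  expect_true(all(compute_psd(rec)$psd == 0))
  sg <- compute_spectrogram(rec)
  expect_true(all(sg$power[["2"]] == 0))
})

test_that("integrated PSD matches white-noise variance (Parseval)", {
  set.seed(11)
  for (sigma in c(0.5, 2)) {
    x <- rnorm(120 * 100, sd = sigma)
    rec <- make_rec(matrix(x, ncol = 1), fs = 100, ids = "2")
    spec <- compute_psd(rec)  # >= 60 windows at 1 s / 50% overlap
    expect_gte(spec$n_windows, 60)
    expect_equal(pracma::trapz(spec$freqs, spec$psd[, 1]), var(x),
                 tolerance = 0.05)
  }
})

test_that("PSD input validation names the offending channel", {
  x <- matrix(rnorm(400), ncol = 2)
  x[7, 2] <- NaN
  rec <- make_rec(x, fs = 100, ids = c(2, 5))
  expect_error(compute_psd(rec), "channel 5")
  short <- make_rec(matrix(rnorm(50), ncol = 1), fs = 100, ids = "2",
                    min_dur = 0.1)
  expect_error(compute_psd(short), "shorter than one window")
  expect_error(compute_psd(sine_rec(20, fs = 200, dur = 2), win_s = 1e-3),
               "2 samples")
})

test_that("a stationary sine gives the same peak bin in every time slice", {
  rec <- sine_rec(freq = 20, amp = 1, fs = 200, dur = 30)
  sg <- compute_spectrogram(rec, win_s = 1, step_s = 0.5)
  peaks <- apply(sg$power[["2"]], 2, which.max)
  expect_equal(length(unique(peaks)), 1L)
  expect_equal(sg$freqs[peaks[1]], 20)
})

test_that("an amplitude step is localized in time with the right power ratio", {
  fs <- 200; dur <- 60
  t <- (0:(fs * dur - 1)) / fs
  amp <- ifelse(t < dur / 2, 1, 3)  # on-step in the second half
  rec <- make_rec(amp * sin(2 * pi * 22 * t), fs, ids = "2")
  sg <- compute_spectrogram(rec, win_s = 1, step_s = 1)
  band <- sg$freqs >= 13 & sg$freqs <= 35
  bp <- colSums(sg$power[["2"]][band, ])
  first <- mean(bp[sg$times < dur / 2 - 1])
  second <- mean(bp[sg$times > dur / 2 + 1])
  expect_equal(second / first, 9, tolerance = 0.05)
})

test_that("time-averaged spectrogram equals the Welch PSD on the same windows", {
  set.seed(12)
  rec <- make_rec(matrix(rnorm(200 * 30), ncol = 1), fs = 200, ids = "2")
  sg <- compute_spectrogram(rec, win_s = 1, step_s = 0.5)
  spec <- compute_psd(rec, win_s = 1, overlap = 0.5)
  expect_equal(rowMeans(sg$power[["2"]]), spec$psd[, 1], tolerance = 1e-12,
               ignore_attr = TRUE)
})
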