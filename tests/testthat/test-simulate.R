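test_that("config validation names every offending field", {
  expect_error(sim_config(fs = 50, beta_amp = -1),
               "fs.*beta_amp|beta_amp.*fs")
  expect_error(sim_config(peak_prob = 1.5), "peak_prob")
  expect_error(sim_config(source_level = 3.5), "source_level")
})

test_that("a fixed seed reproduces recordings and reviews bit for bit", {
  cfg <- fast_cfg(n_hemispheres = 2, duration_s = 10)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a[[1]]$recording$samples, b[[1]]$recording$samples)
  expect_identical(a[[2]]$review, b[[2]]$review)
  expect_identical(a[[1]]$truth, b[[1]]$truth)
  # different hemispheres use different substreams
  expect_false(identical(a[[1]]$recording$samples, a[[2]]$recording$samples))
})

test_that("zero decay and zero background make all contacts identical", {
  cfg <- sim_config(n_hemispheres = 1, fs = 100, duration_s = 5,
                    angular_decay = 0, level_decay = 0, bg_scale = 0,
                    noise_floor = 0, peak_prob = 1, seed = 3)
  sim <- simulate_hemisphere_lfp(cfg, seed = 3)
  for (j in 2:6)
    expect_equal(sim$recording$samples[, j], sim$recording$samples[, 1])
})

test_that("a source at angle 0, level 3 puts max raw beta power on contact 5", {
  cfg <- sim_config(n_hemispheres = 1, fs = 150, duration_s = 30,
                    source_angle_deg = 0, source_level = 3, bg_scale = 0,
                    noise_floor = 0, peak_prob = 1, seed = 4)
  sim <- simulate_hemisphere_lfp(cfg, seed = 4)
  expect_identical(sim$truth$best_contact, "5")
  spec <- compute_psd(sim$recording)
  bp <- apply(spec$psd, 2, function(p) pracma::trapz(spec$freqs[spec$freqs >= 13 & spec$freqs <= 35],
                                                     p[spec$freqs >= 13 & spec$freqs <= 35]))
  expect_identical(names(which.max(bp)), "5")
  lvl2 <- bp[c("2", "3", "4")]
  expect_identical(names(which.max(lvl2)), "2")  # aligned partner
})

test_that("clinical coupling behaves at its extremes", {
  cfg0 <- fast_cfg(coupling = 0)
  set.seed(71)
  rhos <- vapply(1:200, function(i) {
    prox <- runif(6)  # arbitrary source geometry
    truth <- list(hemisphere_id = "h", proximity = setNames(prox, 2:7))
    rev <- simulate_review(cfg0, truth, seed = i)
    suppressWarnings(as.numeric(spearman_rho(prox, clinical_efficacy(rev))))
  }, numeric(1))
  expect_gt(one_sample_t(rhos)$p, 0.01)  # independence not rejected

  cfg1 <- fast_cfg(coupling = 25, efficacy_noise_sd = 0, tw_noise_sd = 0)
  for (i in 1:20) {
    prox <- setNames(runif(6), 2:7)
    truth <- list(hemisphere_id = "h", proximity = prox)
    rev <- simulate_review(cfg1, truth, seed = i)
    sc <- suppressWarnings(score_review(rev))
    expect_identical(sc$contact_id[which.max(sc$efficacy)],
                     names(which.max(prox)))
    # TW ordering matches proximity ordering wherever the cap doesn't bind,
    # for pairs separated by more than the 0.01 mA recording resolution
    uncapped <- which(is.finite(rev$side_effect_threshold))
    for (a in uncapped) for (b in uncapped)
      if (cfg1$tw_gain * (prox[a] - prox[b]) > 0.025)
        expect_gt(sc$tw[a], sc$tw[b])
  }
})

test_that("the no-peak fraction matches its binomial target", {
  cfg <- sim_config(n_hemispheres = 500, fs = 100, duration_s = 2,
                    peak_prob = 12 / 19, seed = 99)
  co <- generate_cohort(cfg)
  frac <- mean(!vapply(co, function(h) h$truth$has_peak, logical(1)))
  se <- sqrt((7 / 19) * (12 / 19) / 500)
  expect_lt(abs(frac - 7 / 19), 3 * se)
})

test_that("the screening curve at k=2 rises with the clinical coupling", {
  set.seed(72)
  k2 <- vapply(c(0, 5, 10, 20, 40), function(cpl) {
    cfg <- fast_cfg(coupling = cpl)
    p2 <- vapply(1:30, function(r) {
      hems <- lapply(1:6, function(j) {
        prox <- setNames(runif(6), 2:7)
        truth <- list(hemisphere_id = paste0("h", j), proximity = prox)
        rev <- simulate_review(cfg, truth, seed = sample.int(1e6, 1))
        make_hemi(paste0("h", j), beta = prox + rnorm(6, 0, 0.02),
                  efficacy = suppressWarnings(clinical_efficacy(rev)))
      })
      lfp_strategy_curve(hems, "efficacy")$probability[2]
    }, numeric(1))
    mean(p2)
  }, numeric(1))
  expect_gt(cor(k2, 1:5, method = "spearman"), 0.8)
})
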