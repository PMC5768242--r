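screen_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      co <- generate_cohort(fast_cfg(n_hemispheres = 8, duration_s = 30))
      fit <<- beta_screening(co)
    }
    fit
  }
})

test_that("the fitted object carries curves, tests, tally and log", {
  fit <- screen_fit()
  expect_s3_class(fit, "beta_screening")
  expect_lte(length(fit$hemispheres), 8L)
  cm <- coef(fit)
  expect_true(all(c("efficacy_all", "tw_all", "random") %in% colnames(cm)))
  expect_equal(nrow(cm), 6L)
  for (j in seq_len(ncol(cm))) {
    expect_true(all(diff(cm[, j]) >= -1e-12))
    expect_equal(unname(cm[6, j]), 1)
  }
  expect_equal(cm[, "random"], (1:6) / 6, ignore_attr = TRUE)
  expect_s3_class(fit$rho_test, "group_test")
  expect_equal(fit$rho_test$df, length(fit$hemispheres) - 1L)
  expect_equal(sum(fit$tally), length(fit$hemispheres))
  expect_equal(nrow(fit$correlations), length(fit$hemispheres))
  expect_true(all(abs(fit$correlations$rho) <= 1, na.rm = TRUE))
})

test_that("print and summary report the headline probabilities", {
  fit <- screen_fit()
  expect_output(print(fit), "P\\(best-efficacy contact in top-k beta\\)")
  expect_output(summary(fit), "Screening curves")
  expect_output(summary(fit), "Top-2 beta contacts vs rest")
})

test_that("plotting writes a two-panel figure", {
  fit <- screen_fit()
  png_path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(png_path, width = 800, height = 400)
  plot(fit)
  grDevices::dev.off()
  expect_gt(file.info(png_path)$size, 0)
})

test_that("predict/recommend return a screening order with evidence", {
  fit <- screen_fit()
  sim <- simulate_hemisphere_lfp(fast_cfg(n_hemispheres = 1, peak_prob = 1,
                                          beta_amp = 6), seed = 81)
  rec <- predict(fit, sim$recording)
  expect_s3_class(rec, "contact_recommendation")
  expect_setequal(rec$order, as.character(2:7))
  expect_identical(rec$top2, rec$order[1:2])
  expect_equal(rec$minutes_full, 240)
  expect_equal(rec$minutes_lfp, 80)
  expect_output(print(rec), "240 min vs LFP-guided 80 min")
})

test_that("a flat recording is recommended in id order with a warning", {
  x <- matrix(rep(sin(2 * pi * 10 * (0:4499) / 150), 6), ncol = 6)
  rec <- make_rec(x, fs = 150, ids = 2:7)
  expect_warning(rc <- recommend_contacts(rec), "tied")
  expect_identical(rc$order, as.character(2:7))
})

test_that("recommend rejects recordings with the wrong channels", {
  x <- matrix(rnorm(150 * 30 * 3), ncol = 3)
  expect_error(recommend_contacts(make_rec(x, fs = 150, ids = c(2, 3, 4))),
               "segmented-contact channels")
})

test_that("hand-built hemisphere datasets can be analyzed without recordings", {
  set.seed(82)
  co <- lapply(1:5, function(i) {
    b <- runif(6)
    make_hemi(paste0("h", i), beta = b,
              efficacy = 10 + 30 * b + rnorm(6, 0, 4),
              tw = 0.5 + b + rnorm(6, 0, 0.2))
  })
  fit <- beta_screening(co)
  expect_equal(length(fit$hemispheres), 5L)
  cm <- coef(fit)
  expect_gt(cm[2, "efficacy_all"], cm[2, "random"])
})

test_that("analyze_cohort writes a deterministic results bundle", {
  co <- generate_cohort(fast_cfg(n_hemispheres = 4, duration_s = 20))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fit <- analyze_cohort(co, d1)
  expect_s3_class(fit, "beta_screening")
  for (fn in c("beta_values.tsv", "rankings.tsv", "curves_efficacy.tsv",
               "curves_tw.tsv", "correlations.tsv", "group_tests.tsv",
               "level_tally.tsv", "exclusions.tsv", "analysis_log.txt",
               "curves.png", "hemisphere_panels.png"))
    expect_true(file.exists(file.path(d1, fn)), label = fn)
  analyze_cohort(co, d2)
  for (fn in c("beta_values.tsv", "rankings.tsv", "curves_efficacy.tsv",
               "group_tests.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, fn))),
                     unname(tools::md5sum(file.path(d2, fn))))
})

test_that("a cohort failing the filters yields an exclusion log, not results", {
  co <- lapply(1:3, function(i)
    make_hemi(paste0("h", i), beta = runif(6), efficacy = rep(15, 6)))
  fit <- beta_screening(co)
  expect_equal(length(fit$hemispheres), 0L)
  expect_equal(nrow(fit$exclusions), 3L)
  expect_null(fit$curves)
  d <- withr::local_tempdir()
  analyze_cohort(co, d)
  expect_true(file.exists(file.path(d, "exclusions.tsv")))
  expect_false(file.exists(file.path(d, "curves_efficacy.tsv")))
})
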