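rev_row <- function(baseline = 2, on_stim = 1, current = 2, effect = 1,
                    side = 2.5)
  data.frame(rigidity_baseline = baseline, rigidity_on_stim = on_stim,
             test_current = current, effect_threshold = effect,
             side_effect_threshold = side)

test_that("clinical efficacy is percent improvement per mA", {
  expect_equal(clinical_efficacy(rev_row(2, 1, 2)), 25)
  expect_equal(clinical_efficacy(rev_row(3, 3, 2)), 0)
  expect_equal(clinical_efficacy(rev_row(3, 0, 2.5)), 40)
  expect_error(clinical_efficacy(rev_row(current = 0)), "current")
  expect_error(clinical_efficacy(rev_row(baseline = 0)), "baseline")
  expect_warning(clinical_efficacy(rev_row(2, 3, 2)), "worsened")
})

test_that("efficacy is invariant to the rigidity units and can use the threshold current", {
  expect_equal(clinical_efficacy(rev_row(4, 2, 2)),
               clinical_efficacy(rev_row(2, 1, 2)))
  expect_equal(clinical_efficacy(rev_row(2, 1, 2, effect = 1.25),
                                 current_basis = "threshold"), 40)
})

test_that("therapeutic window subtracts thresholds with cap and clip", {
  expect_equal(therapeutic_window(rev_row(effect = 1, side = 2.5)), 1.5)
  expect_warning(
    tw <- therapeutic_window(rev_row(effect = 2, side = NA)), "capped")
  expect_equal(tw, 3)
  expect_warning(
    tw0 <- therapeutic_window(rev_row(effect = 2, side = 2)), NA)
  expect_equal(tw0, 0)
  expect_warning(
    twn <- therapeutic_window(rev_row(effect = 2.5, side = 2)), "clipped")
  expect_equal(twn, 0)
  expect_error(therapeutic_window(rev_row(effect = NA)), "effect threshold")
})

test_that("TW is monotone in both thresholds", {
  side <- seq(1, 5, by = 0.5)
  tw <- therapeutic_window(rev_row(effect = 1, side = side))
  expect_true(all(diff(tw) >= 0))
  eff <- seq(0.5, 3, by = 0.5)
  tw2 <- suppressWarnings(therapeutic_window(rev_row(effect = eff, side = 3)))
  expect_true(all(diff(tw2) <= 0))
})

test_that("inclusion filters drop low-rigidity and flat-response hemispheres", {
  good <- make_hemi("good", beta = 6:1, efficacy = c(40, 30, 20, 10, 5, 0))
  low_rig <- make_hemi("lowrig", beta = 6:1,
                       efficacy = c(40, 30, 20, 10, 5, 0), rigidity = 1)
  flat <- make_hemi("flat", beta = 6:1, efficacy = rep(20, 6))
  res <- apply_inclusion_filters(list(good, low_rig, flat))
  expect_equal(vapply(res$cohort, `[[`, "", "hemisphere_id"), "good")
  expect_setequal(res$exclusions$hemisphere_id, c("lowrig", "flat"))
  expect_match(res$exclusions$reason[res$exclusions$hemisphere_id == "lowrig"],
               "rigidity")
  expect_match(res$exclusions$reason[res$exclusions$hemisphere_id == "flat"],
               "range")
  # idempotent
  res2 <- apply_inclusion_filters(res$cohort)
  expect_equal(length(res2$cohort), 1L)
  expect_equal(nrow(res2$exclusions), 0L)
})

test_that("review tables round trip through TSV with strict headers", {
  review <- data.frame(hemisphere_id = "h01", contact_id = as.character(2:7),
                       rigidity_baseline = 3, rigidity_on_stim = 1.5,
                       test_current = 2, effect_threshold = 1:6 / 2,
                       side_effect_threshold = c(2, 3, NA, 4, 2.5, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_review_table(review, path)
  expect_match(readLines(path)[4], "NR")
  back <- read_review_table(path)
  expect_equal(back$side_effect_threshold, review$side_effect_threshold)
  expect_equal(back$effect_threshold, review$effect_threshold)

  bad <- review; names(bad)[3] <- "rigidity"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_review_table(path2), "rigidity_baseline")
})
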