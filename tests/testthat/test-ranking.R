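test_that("beta ranking is descending with ties broken by lower id", {
  h <- make_hemi("a", beta = c(0.2, 0.5, 0.1, 0.9, 0.4, 0.3),
                 efficacy = 1:6)
  expect_identical(as.character(rank_by_beta(h)),
                   c("5", "3", "6", "7", "2", "4"))
  tied <- make_hemi("b", beta = rep(0.3, 6), efficacy = 1:6)
  r <- rank_by_beta(tied)
  expect_identical(as.character(r), as.character(2:7))
  expect_equal(length(attr(r, "ties")), 1L)
})

test_that("ranking is equivariant under relabeling of contacts", {
  vals <- c(0.2, 0.5, 0.1, 0.9, 0.4, 0.3)
  h <- make_hemi("a", beta = vals, efficacy = 1:6)
  perm <- c(4, 1, 2, 6, 3, 5)
  h2 <- make_hemi("b", beta = vals[perm], efficacy = 1:6)
  ids <- as.character(2:7)
  # in h2, contact ids[j] holds the value contact ids[perm[j]] had in h,
  # so the ranking of h2 is that relabeling applied to the ranking of h
  map <- setNames(ids, ids[perm])
  expect_identical(as.character(rank_by_beta(h2)),
                   unname(map[as.character(rank_by_beta(h))]))
})

test_that("the LFP curve counts best-contact hits among top-k", {
  # best clinical contact at beta rank 1, 2 and 4 -> (1/3, 2/3, 2/3, 1, 1, 1)
  h1 <- make_hemi("h1", beta = c(6, 5, 4, 3, 2, 1), efficacy = c(9, 1, 2, 3, 4, 5))
  h2 <- make_hemi("h2", beta = c(6, 5, 4, 3, 2, 1), efficacy = c(1, 9, 2, 3, 4, 5))
  h3 <- make_hemi("h3", beta = c(6, 5, 4, 3, 2, 1), efficacy = c(1, 2, 3, 9, 4, 5))
  cv <- lfp_strategy_curve(list(h1, h2, h3), "efficacy")
  expect_equal(cv$probability, c(1, 2, 2, 3, 3, 3) / 3)

  # perfectly concordant rankings -> 1 everywhere
  co <- list(make_hemi("c", beta = 6:1, efficacy = 6:1))
  expect_equal(lfp_strategy_curve(co, "efficacy")$probability, rep(1, 6))
  expect_error(lfp_strategy_curve(list(), "efficacy"), "empty")
})

test_that("curves are monotone and reach 1 at k = 6; TW criterion is independent", {
  set.seed(51)
  co <- lapply(1:8, function(i)
    make_hemi(paste0("h", i), beta = runif(6), efficacy = runif(6, 0, 40),
              tw = runif(6, 0, 3), has_peak = i <= 5))
  for (crit in c("efficacy", "tw")) for (sub in c("all", "beta_peak_only")) {
    cv <- lfp_strategy_curve(co, crit, sub)
    expect_true(all(diff(cv$probability) >= 0))
    expect_equal(cv$probability[6], 1)
    expect_equal(attr(cv, "n_hemispheres"), if (sub == "all") 8L else 5L)
  }
})

test_that("the random baseline is exactly k/6", {
  cv <- random_strategy_curve(6)
  expect_identical(cv$probability, (1:6) / 6)
  expect_equal(cv$probability[3], 0.5)
  expect_equal(round(cv$probability[1], 2), 0.17)
})

test_that("top-2 vs rest handles constant metrics and strong coupling", {
  co <- lapply(1:5, function(i)
    make_hemi(paste0("h", i), beta = runif(6), efficacy = rep(20, 6)))
  cmp <- top2_vs_rest(co, "efficacy")
  expect_equal(cmp$test$statistic, 0)
  expect_equal(cmp$test$p, 1)
  expect_equal(unname(cmp$top2 - cmp$rest), rep(0, 5))

  set.seed(52)
  co2 <- lapply(1:30, function(i) {
    b <- runif(6)
    make_hemi(paste0("h", i), beta = b, efficacy = 10 + 30 * b + rnorm(6, 0, 2))
  })
  cmp2 <- top2_vs_rest(co2, "efficacy")
  expect_gt(cmp2$mean_top2, cmp2$mean_rest)
  expect_gt(cmp2$test$statistic, 0)
})

test_that("top-2 means are invariant to consistent relabeling", {
  vals <- c(0.2, 0.5, 0.1, 0.9, 0.4, 0.3)
  eff <- c(10, 20, 5, 40, 15, 12)
  perm <- c(3, 5, 1, 2, 6, 4)
  co_a <- list(make_hemi("a", beta = vals, efficacy = eff),
               make_hemi("a2", beta = rev(vals), efficacy = rev(eff)))
  co_b <- list(make_hemi("b", beta = vals[perm], efficacy = eff[perm]),
               make_hemi("b2", beta = rev(vals), efficacy = rev(eff)))
  ca <- top2_vs_rest(co_a, "efficacy"); cb <- top2_vs_rest(co_b, "efficacy")
  expect_equal(unname(ca$top2), unname(cb$top2))
  expect_equal(unname(ca$rest), unname(cb$rest))
})

test_that("the dorsal-level tally counts labels exactly", {
  expect_equal(dorsal_level_tally(rep("dorsal", 4)),
               c(ventral = 0L, middle = 0L, dorsal = 4L))
  expect_equal(dorsal_level_tally(c("dorsal", "middle", "dorsal", "ventral")),
               c(ventral = 1L, middle = 1L, dorsal = 2L))
  expect_equal(sum(dorsal_level_tally(character())), 0L)
  expect_error(dorsal_level_tally(c("dorsal", "apex")), "apex")
})
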