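#' Rank contacts by normalized beta
#'
#' Deterministic total order over a hemisphere's six segmented contacts,
#' highest normalized beta first. Exact ties are broken by lower contact id,
#' and tied groups are recorded in the `ties` attribute so callers can log
#' them.
#'
#' @param h A [hemisphere_dataset()], or a data.frame with columns
#'   `contact_id` and `value`.
#' @return Character vector of contact ids in screening order, with a `ties`
#'   attribute (list of tied id groups, empty if none).
#' @export
rank_by_beta <- function(h) {
  beta <- if (inherits(h, "hemisphere_dataset")) h$beta else h
  if (anyNA(beta$value)) stop("missing beta values")
  ids <- as.character(beta$contact_id)
  ord <- order(-beta$value, as.integer(ids))
  tied <- split(ids, beta$value)
  tied <- unname(tied[vapply(tied, length, 1L) > 1L])
  structure(ids[ord], ties = tied)
}

best_clinical_contact <- function(h, criterion = c("efficacy", "tw")) {
  criterion <- match.arg(criterion)
  v <- h$clinical[[criterion]]
  ids <- as.character(h$clinical$contact_id)
  cand <- ids[v == max(v)]
  cand[order(as.integer(cand))][1L]
}

new_strategy_curve <- function(k, probability, criterion, subset, n, strategy) {
  structure(data.frame(k = k, probability = probability),
            criterion = criterion, subset = subset, n_hemispheres = n,
            strategy = strategy, class = c("strategy_curve", "data.frame"))
}

#' LFP-guided screening curve
#'
#' For each k = 1..6, the fraction of hemispheres whose best clinical contact
#' (maximum efficacy, or maximum therapeutic window for `criterion = "tw"`;
#' clinical ties broken by lower contact id) lies among the top-k contacts of
#' the beta ranking. The curve is nondecreasing in k and reaches 1 at k = 6.
#'
#' @param cohort List of [hemisphere_dataset()] objects.
#' @param criterion `"efficacy"` or `"tw"`.
#' @param subset `"all"` or `"beta_peak_only"` (restrict to hemispheres with
#'   a clear beta peak).
#' @return data.frame of class `strategy_curve` with columns `k`,
#'   `probability` and attributes `criterion`, `subset`, `n_hemispheres`,
#'   `strategy`.
#' @export
lfp_strategy_curve <- function(cohort, criterion = c("efficacy", "tw"),
                               subset = c("all", "beta_peak_only")) {
  criterion <- match.arg(criterion)
  subset <- match.arg(subset)
  if (subset == "beta_peak_only")
    cohort <- Filter(function(h) isTRUE(h$has_beta_peak), cohort)
  if (!length(cohort)) stop("empty cohort")
  pos <- vapply(cohort, function(h) {
    ranked <- rank_by_beta(h)
    match(best_clinical_contact(h, criterion), ranked)
  }, numeric(1))
  n_contacts <- nrow(cohort[[1L]]$beta)
  k <- seq_len(n_contacts)
  prob <- vapply(k, function(kk) mean(pos <= kk), numeric(1))
  new_strategy_curve(k, prob, criterion, subset, length(cohort), "lfp")
}

#' Uniform-random screening baseline
#'
#' Analytic baseline for screening contacts in a random order: with the best
#' contact equally likely to sit at any position, the probability of having
#' found it after k of n contacts is exactly k/n (no Monte-Carlo involved).
#' For the six segmented contacts this is the 0.17-per-contact increment.
#'
#' @param n_contacts Number of contacts screened (6 for a directional lead).
#' @return data.frame of class `strategy_curve`.
#' @export
random_strategy_curve <- function(n_contacts = 6) {
  if (n_contacts < 1) stop("need at least one contact")
  k <- seq_len(n_contacts)
  new_strategy_curve(k, k / n_contacts, criterion = "any", subset = "all",
                     n = NA_integer_, strategy = "random")
}

#' @export
print.strategy_curve <- function(x, ...) {
  cat(sprintf("%s screening curve (criterion: %s, subset: %s, n = %s)\n",
              toupper(attr(x, "strategy")), attr(x, "criterion"),
              attr(x, "subset"), attr(x, "n_hemispheres")))
  cat(paste(sprintf("  k=%d: %.2f", x$k, x$probability), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
plot.strategy_curve <- function(x, add = FALSE, col = "red", ...) {
  if (!add)
    graphics::plot(x$k, x$probability, type = "b", col = col, pch = 16,
                   ylim = c(0, 1), xlab = "contacts tested (k)",
                   ylab = "P(best contact found)", ...)
  else
    graphics::lines(x$k, x$probability, type = "b", col = col, pch = 16, ...)
  invisible(x)
}

#' Top-2 beta contacts versus the remaining four
#'
#' Per hemisphere, the mean of a clinical metric over the two contacts with
#' the highest normalized beta and over the remaining four contacts, plus the
#' paired t test across hemispheres.
#'
#' @param cohort List of [hemisphere_dataset()] objects (>= 2 for the test).
#' @param metric `"efficacy"` or `"tw"`.
#' @return Object of class `top2_comparison`: list with per-hemisphere vectors
#'   `top2` and `rest`, their `mean_top2`/`sem_top2`/`mean_rest`/`sem_rest`,
#'   and `test` (a `group_test` from [paired_t()]; when the paired
#'   differences are constant a degenerate test with t = 0, p = 1 -- or
#'   infinite t for a constant nonzero difference -- is reported).
#' @export
top2_vs_rest <- function(cohort, metric = c("efficacy", "tw")) {
  metric <- match.arg(metric)
  if (length(cohort) < 2L) stop("need at least 2 hemispheres")
  means <- t(vapply(cohort, function(h) {
    if (nrow(h$clinical) < 6L) stop("fewer than 6 contacts in hemisphere ",
                                    h$hemisphere_id)
    ranked <- rank_by_beta(h)
    v <- h$clinical[[metric]][match(ranked, as.character(h$clinical$contact_id))]
    c(top2 = mean(v[1:2]), rest = mean(v[3:6]))
  }, numeric(2)))
  d <- means[, "top2"] - means[, "rest"]
  test <- if (stats::sd(d) > 0) {
    paired_t(means[, "top2"], means[, "rest"])
  } else {
    # degenerate case: constant paired differences (t = 0 when all zero)
    structure(list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                   df = length(d) - 1L, p = if (mean(d) == 0) 1 else 0,
                   mean = mean(d), sem = 0),
              class = "group_test")
  }
  structure(list(metric = metric,
                 top2 = means[, "top2"], rest = means[, "rest"],
                 mean_top2 = mean(means[, "top2"]),
                 sem_top2 = stats::sd(means[, "top2"]) / sqrt(nrow(means)),
                 mean_rest = mean(means[, "rest"]),
                 sem_rest = stats::sd(means[, "rest"]) / sqrt(nrow(means)),
                 test = test),
            class = "top2_comparison")
}

#' @export
print.top2_comparison <- function(x, ...) {
  unit <- if (x$metric == "efficacy") "%/mA" else "mA"
  cat(sprintf("Top-2 beta contacts vs rest (%s): %.2f +/- %.2f vs %.2f +/- %.2f %s\n",
              x$metric, x$mean_top2, x$sem_top2, x$mean_rest, x$sem_rest, unit))
  print(x$test)
  invisible(x)
}

#' Tally of anatomical levels housing the max-beta contact
#'
#' Counts, across hemispheres, which anatomical zone of the subthalamic
#' nucleus (ventral / middle / dorsal) contains the ring level with the
#' highest-beta contact.
#'
#' @param levels Character vector, one label per hemisphere, each one of
#'   `"ventral"`, `"middle"`, `"dorsal"`.
#' @return Named integer vector with counts for ventral, middle, dorsal
#'   (summing to `length(levels)`).
#' @export
dorsal_level_tally <- function(levels) {
  zones <- c("ventral", "middle", "dorsal")
  bad <- setdiff(unique(levels), zones)
  if (length(bad))
    stop("unknown level label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(levels, levels = zones))
  stats::setNames(as.integer(counts), zones)
}

#' Export strategy curves as delimited text
#'
#' @param curves Named list of `strategy_curve` objects sharing the same k
#'   grid (e.g. `list(p_lfp_all = ..., p_lfp_peak_only = ..., p_random = ...)`).
#' @param path Output path (tab-delimited).
#' @export
write_curves_tsv <- function(curves, path) {
  k <- curves[[1L]]$k
  out <- data.frame(k = k)
  for (nm in names(curves)) out[[nm]] <- curves[[nm]]$probability
  utils::write.table(format(out, digits = 6, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
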