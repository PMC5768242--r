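#' Fit the LFP-guided contact-screening analysis to a cohort
#'
#' The central analysis of the package. For every hemisphere it computes the
#' normalized-beta profile of the six segmented contacts
#' ([hemisphere_beta_profile()]) and the clinical scores from the monopolar
#' review ([score_review()]), applies the hemisphere inclusion filters, and
#' then quantifies how well beta-ranked screening predicts the clinically
#' best contact:
#' \itemize{
#'   \item per-hemisphere Spearman correlation between normalized beta and
#'     clinical efficacy, with a one-sample t test of the correlations
#'     against zero across hemispheres;
#'   \item top-k screening curves ([lfp_strategy_curve()]) for the
#'     best-efficacy and widest-therapeutic-window contact, on all
#'     hemispheres and on the beta-peak subset, against the analytic
#'     uniform-random baseline ([random_strategy_curve()]);
#'   \item paired comparison of the two highest-beta contacts against the
#'     remaining four ([top2_vs_rest()]) for both clinical metrics;
#'   \item tally of the anatomical level housing the max-beta contact.
#' }
#'
#' @param cohort An `lfp_cohort` from [generate_cohort()] / [read_cohort()],
#'   or a plain list of [hemisphere_dataset()] objects (in which case the
#'   spectral step is skipped).
#' @param lead A [directional_lead()].
#' @param win_s,overlap,prominence_db,halfwidth_hz,statistic Spectral
#'   parameters, see [hemisphere_beta_profile()].
#' @param current_basis,current_ceiling Clinical parameters, see
#'   [score_review()].
#' @param min_rigidity,min_range Inclusion filters, see
#'   [apply_inclusion_filters()].
#' @param level_zones Named character vector mapping contact levels to
#'   anatomical zones for the tally.
#' @return Object of class `beta_screening` with components `hemispheres`
#'   (the retained [hemisphere_dataset()]s), `exclusions`, `correlations`
#'   (per-hemisphere rho), `rho_test` (one-sample t), `curves` (named list of
#'   `strategy_curve`s: `efficacy_all`, `efficacy_peak_only`, `tw_all`,
#'   `tw_peak_only`, `random`), `top2` (list with `efficacy` and `tw`
#'   comparisons), `tally`, `log` (character vector of tie-breaks, fallbacks,
#'   caps and exclusions) and `settings`.
#' @seealso [summary.beta_screening()], [plot.beta_screening()],
#'   [predict.beta_screening()], [recommend_contacts()]
#' @export
beta_screening <- function(cohort, lead = directional_lead(),
                           win_s = 1, overlap = 0.5, prominence_db = 3,
                           halfwidth_hz = 3,
                           statistic = c("power", "amplitude"),
                           current_basis = c("fixed", "threshold"),
                           current_ceiling = 5,
                           min_rigidity = 2, min_range = 5,
                           level_zones = c("1" = "ventral", "2" = "middle",
                                           "3" = "dorsal", "4" = "dorsal")) {
  statistic <- match.arg(statistic)
  current_basis <- match.arg(current_basis)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  hems <- lapply(cohort, function(h) {
    if (inherits(h, "hemisphere_dataset")) return(h)
    prof <- hemisphere_beta_profile(h$recording, lead = lead, win_s = win_s,
                                    overlap = overlap,
                                    prominence_db = prominence_db,
                                    halfwidth_hz = halfwidth_hz,
                                    statistic = statistic)
    peak <- attr(prof, "peak")
    if (!peak$present)
      note("hemisphere %s: no beta peak; low-beta fallback band used",
           h$hemisphere_id)
    capped <- !is.finite(h$review$side_effect_threshold)
    if (any(capped))
      note("hemisphere %s: side-effect threshold not reached on contact(s) %s; capped at %g mA",
           h$hemisphere_id,
           paste(h$review$contact_id[capped], collapse = ","),
           current_ceiling)
    scores <- withCallingHandlers(
      score_review(h$review, current_basis = current_basis,
                   current_ceiling = current_ceiling),
      warning = function(w) invokeRestart("muffleWarning"))
    max_id <- prof$contact_id[which.max(prof$value)]
    lev <- lead$contacts$level[match(as.integer(max_id), lead$contacts$id)]
    hemisphere_dataset(h$hemisphere_id, beta = prof, clinical = scores,
                       has_beta_peak = peak$present, review = h$review,
                       level_of_max_beta = unname(level_zones[as.character(lev)]))
  })
  if (!length(hems)) stop("empty cohort")

  filt <- apply_inclusion_filters(hems, min_rigidity = min_rigidity,
                                  min_range = min_range)
  for (i in seq_len(nrow(filt$exclusions)))
    note("hemisphere %s excluded (%s)", filt$exclusions$hemisphere_id[i],
         filt$exclusions$reason[i])
  kept <- filt$cohort
  if (!length(kept))
    return(structure(list(hemispheres = kept, exclusions = filt$exclusions,
                          correlations = NULL, rho_test = NULL, curves = NULL,
                          top2 = NULL, tally = NULL, log = log_lines,
                          settings = list(statistic = statistic,
                                          current_basis = current_basis,
                                          min_rigidity = min_rigidity,
                                          min_range = min_range)),
                     class = "beta_screening"))

  for (h in kept) {
    ties <- attr(rank_by_beta(h), "ties")
    for (grp in ties)
      note("hemisphere %s: beta tie among contacts %s broken by lower id",
           h$hemisphere_id, paste(grp, collapse = ","))
  }

  correlations <- data.frame(
    hemisphere_id = vapply(kept, function(h) as.character(h$hemisphere_id), ""),
    rho = vapply(kept, function(h)
      suppressWarnings(as.numeric(spearman_rho(h$beta$value,
                                               h$clinical$efficacy))),
      numeric(1)),
    has_beta_peak = vapply(kept, function(h) isTRUE(h$has_beta_peak),
                           logical(1)))
  rho_ok <- correlations$rho[is.finite(correlations$rho)]
  rho_test <- if (length(rho_ok) >= 2 && stats::sd(rho_ok) > 0)
    one_sample_t(rho_ok) else NULL

  n_peak <- sum(correlations$has_beta_peak)
  curves <- list(efficacy_all = lfp_strategy_curve(kept, "efficacy", "all"),
                 tw_all = lfp_strategy_curve(kept, "tw", "all"),
                 random = random_strategy_curve(6))
  if (n_peak > 0) {
    curves$efficacy_peak_only <-
      lfp_strategy_curve(kept, "efficacy", "beta_peak_only")
    curves$tw_peak_only <- lfp_strategy_curve(kept, "tw", "beta_peak_only")
  }
  top2 <- if (length(kept) >= 2)
    list(efficacy = top2_vs_rest(kept, "efficacy"),
         tw = top2_vs_rest(kept, "tw")) else NULL
  tally <- dorsal_level_tally(
    vapply(kept, function(h) h$level_of_max_beta, ""))

  structure(list(hemispheres = kept, exclusions = filt$exclusions,
                 correlations = correlations, rho_test = rho_test,
                 curves = curves, top2 = top2, tally = tally,
                 log = log_lines,
                 settings = list(statistic = statistic,
                                 current_basis = current_basis,
                                 min_rigidity = min_rigidity,
                                 min_range = min_range,
                                 win_s = win_s, overlap = overlap,
                                 prominence_db = prominence_db,
                                 halfwidth_hz = halfwidth_hz,
                                 current_ceiling = current_ceiling,
                                 lead = lead)),
            class = "beta_screening")
}

#' @export
print.beta_screening <- function(x, ...) {
  cat(sprintf("LFP-guided contact screening: %d hemisphere(s) analyzed, %d excluded\n",
              length(x$hemispheres), nrow(x$exclusions)))
  if (is.null(x$curves)) return(invisible(x))
  eff <- x$curves$efficacy_all$probability
  tw <- x$curves$tw_all$probability
  cat(sprintf("  P(best-efficacy contact in top-k beta): k=1: %.2f, k=2: %.2f (random: 0.17, 0.33)\n",
              eff[1], eff[2]))
  cat(sprintf("  P(widest-TW contact in top-k beta):     k=1: %.2f, k=2: %.2f\n",
              tw[1], tw[2]))
  if (!is.null(x$rho_test))
    cat(sprintf("  beta-efficacy Spearman rho: mean %.2f (t(%d) = %.2f, p = %.3g)\n",
                x$rho_test$mean, x$rho_test$df, x$rho_test$statistic,
                x$rho_test$p))
  invisible(x)
}

#' Summarize a contact-screening analysis
#'
#' @param object A `beta_screening` fit.
#' @param ... Unused.
#' @export
summary.beta_screening <- function(object, ...) {
  x <- object
  print(x)
  if (is.null(x$curves)) {
    if (nrow(x$exclusions)) {
      cat("Exclusions:\n"); print(x$exclusions, row.names = FALSE)
    }
    return(invisible(x))
  }
  cat("\nScreening curves (probability best contact among top-k):\n")
  print(round(coef(x), 3))
  if (!is.null(x$top2)) {
    cat("\n"); print(x$top2$efficacy)
    print(x$top2$tw)
  }
  cat("\nLevel of max-beta contact:",
      paste(names(x$tally), x$tally, sep = " = ", collapse = ", "), "\n")
  if (nrow(x$exclusions)) {
    cat("Exclusions:\n"); print(x$exclusions, row.names = FALSE)
  }
  if (length(x$log)) cat("\nLog:\n", paste(" -", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Screening-curve probabilities of a fitted analysis
#'
#' @param object A `beta_screening` fit.
#' @param ... Unused.
#' @return Matrix with one row per k (1..6) and one column per strategy
#'   curve.
#' @export
coef.beta_screening <- function(object, ...) {
  if (is.null(object$curves)) return(NULL)
  sapply(object$curves, function(cv) cv$probability)
}

#' Plot screening curves of a fitted analysis
#'
#' Draws the top-k probability curves for the best-efficacy contact
#' (`which = 1`) and the widest-therapeutic-window contact (`which = 2`),
#' LFP-guided strategies in red (solid: all hemispheres; dashed: beta-peak
#' subset) against the analytic uniform-random baseline in blue.
#'
#' @param x A `beta_screening` fit.
#' @param which Which panels to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.beta_screening <- function(x, which = 1:2, ...) {
  if (is.null(x$curves)) stop("nothing to plot: no hemispheres retained")
  panels <- list(
    list(all = "efficacy_all", sub = "efficacy_peak_only",
         main = "Best-efficacy contact"),
    list(all = "tw_all", sub = "tw_peak_only",
         main = "Widest-therapeutic-window contact"))
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  for (i in which) {
    p <- panels[[i]]
    plot(x$curves[[p$all]], col = "red", main = p$main, ...)
    if (!is.null(x$curves[[p$sub]]))
      graphics::lines(x$curves[[p$sub]]$k, x$curves[[p$sub]]$probability,
                      col = "red", lty = 2, type = "b", pch = 1)
    graphics::lines(x$curves$random$k, x$curves$random$probability,
                    col = "blue", type = "b", pch = 15)
    graphics::legend("bottomright", bty = "n",
                     legend = c("LFP-guided (all)", "LFP-guided (peak only)",
                                "random"),
                     col = c("red", "red", "blue"), lty = c(1, 2, 1),
                     pch = c(16, 1, 15))
  }
  invisible(x)
}

#' Recommend a screening order for a new hemisphere
#'
#' Applies the fitted analysis settings to a fresh six-contact recording and
#' returns the beta-ranked screening order with its evidence.
#'
#' @param object A `beta_screening` fit.
#' @param newdata An [lfp_recording()] over the six segmented contacts.
#' @param ... Unused.
#' @return A `contact_recommendation`, see [recommend_contacts()].
#' @export
predict.beta_screening <- function(object, newdata, ...) {
  s <- object$settings
  recommend_contacts(newdata, lead = s$lead, win_s = s$win_s,
                     overlap = s$overlap, prominence_db = s$prominence_db,
                     halfwidth_hz = s$halfwidth_hz, statistic = s$statistic)
}

#' Beta-ranked screening recommendation for one hemisphere
#'
#' Computes the normalized-beta profile of a six-contact recording, ranks the
#' contacts (highest beta first, ties to the lower id with a warning) and
#' reports the two recommended screening targets together with the evidence
#' (beta values, detected peak band, fallback flag) and the screening-time
#' model: at `minutes_per_contact` per contact, a full bilateral review of 12
#' segmented contacts is compared with screening only the top 2 per side.
#'
#' @param rec An [lfp_recording()] with channels for contacts 2-7.
#' @param lead A [directional_lead()].
#' @inheritParams hemisphere_beta_profile
#' @param minutes_per_contact Assessment time per contact, minutes.
#' @return Object of class `contact_recommendation`: list with `order`,
#'   `top2`, `profile`, `peak`, `minutes_full`, `minutes_lfp`.
#' @export
recommend_contacts <- function(rec, lead = directional_lead(), win_s = 1,
                               overlap = 0.5, prominence_db = 3,
                               halfwidth_hz = 3,
                               statistic = c("power", "amplitude"),
                               minutes_per_contact = 20) {
  statistic <- match.arg(statistic)
  wanted <- as.character(lead$segmented_ids)
  if (!setequal(rec$channel_ids, wanted))
    stop("expected exactly the 6 segmented-contact channels (",
         paste(wanted, collapse = ", "), "); got ",
         paste(rec$channel_ids, collapse = ", "))
  prof <- hemisphere_beta_profile(rec, lead = lead, win_s = win_s,
                                  overlap = overlap,
                                  prominence_db = prominence_db,
                                  halfwidth_hz = halfwidth_hz,
                                  statistic = statistic)
  ranked <- rank_by_beta(prof)
  if (length(attr(ranked, "ties")))
    warning("tied beta values; screening order broken by lower contact id")
  structure(list(order = as.character(ranked), top2 = as.character(ranked[1:2]),
                 profile = prof, peak = attr(prof, "peak"),
                 minutes_per_contact = minutes_per_contact,
                 minutes_full = 12 * minutes_per_contact,
                 minutes_lfp = 2 * 2 * minutes_per_contact),
            class = "contact_recommendation")
}

#' @export
print.contact_recommendation <- function(x, ...) {
  cat("Recommended screening order (highest normalized beta first):\n  ",
      paste(x$order, collapse = " > "), "\n")
  cat("Screen first:", paste(x$top2, collapse = ", "), "\n")
  print(x$peak)
  tab <- x$profile
  tab <- tab[order(-tab$value), ]
  cat("Evidence (normalized beta):\n")
  print(data.frame(contact = tab$contact_id, value = round(tab$value, 3),
                   fallback = tab$used_fallback), row.names = FALSE)
  cat(sprintf("Estimated review time, both sides: full %d min vs LFP-guided %d min (%d min/contact)\n",
              x$minutes_full, x$minutes_lfp, x$minutes_per_contact))
  invisible(x)
}
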