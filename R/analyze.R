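#' End-to-end cohort analysis with a written results bundle
#'
#' Reads a cohort (from disk or in memory), fits [beta_screening()] and
#' writes a deterministic, tab-delimited results bundle to `out_dir`:
#' `beta_values.tsv` (per contact: normalized beta, fallback flag, clinical
#' scores), `rankings.tsv`, `curves_efficacy.tsv` / `curves_tw.tsv`,
#' `correlations.tsv`, `group_tests.tsv`, `level_tally.tsv`,
#' `exclusions.tsv`, `analysis_log.txt` and, unless `plots = FALSE`,
#' `curves.png` and `hemisphere_panels.png` (per-hemisphere ranked
#' beta-vs-efficacy scatter panels). Repeated runs on the same inputs
#' produce byte-identical tables.
#'
#' @param cohort An `lfp_cohort`, list of [hemisphere_dataset()]s, or a
#'   directory path readable by [read_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param plots Write PNG figures?
#' @param ... Passed to [beta_screening()].
#' @return The `beta_screening` fit, invisibly.
#' @export
analyze_cohort <- function(cohort, out_dir, plots = TRUE, ...) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  fit <- beta_screening(cohort, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, fn) utils::write.table(
    format(df, digits = 6, trim = TRUE), file.path(out_dir, fn),
    sep = "\t", quote = FALSE, row.names = FALSE)

  if (length(fit$hemispheres)) {
    beta_tab <- do.call(rbind, lapply(fit$hemispheres, function(h)
      data.frame(hemisphere_id = h$hemisphere_id,
                 merge(h$beta, h$clinical, by = "contact_id"),
                 has_beta_peak = h$has_beta_peak)))
    wt(beta_tab, "beta_values.tsv")
    rank_tab <- do.call(rbind, lapply(fit$hemispheres, function(h)
      data.frame(hemisphere_id = h$hemisphere_id,
                 rank = 1:6, contact_id = as.character(rank_by_beta(h)))))
    wt(rank_tab, "rankings.tsv")
    write_curves_tsv(list(p_lfp_all = fit$curves$efficacy_all,
                          p_lfp_peak_only = fit$curves$efficacy_peak_only %||%
                            fit$curves$efficacy_all,
                          p_random = fit$curves$random),
                     file.path(out_dir, "curves_efficacy.tsv"))
    write_curves_tsv(list(p_lfp_all = fit$curves$tw_all,
                          p_lfp_peak_only = fit$curves$tw_peak_only %||%
                            fit$curves$tw_all,
                          p_random = fit$curves$random),
                     file.path(out_dir, "curves_tw.tsv"))
    wt(fit$correlations, "correlations.tsv")
    tests <- data.frame(
      test = c("rho_vs_zero", "top2_vs_rest_efficacy", "top2_vs_rest_tw"),
      statistic = c(if (is.null(fit$rho_test)) NA else fit$rho_test$statistic,
                    fit$top2$efficacy$test$statistic,
                    fit$top2$tw$test$statistic),
      df = c(if (is.null(fit$rho_test)) NA else fit$rho_test$df,
             fit$top2$efficacy$test$df, fit$top2$tw$test$df),
      p = c(if (is.null(fit$rho_test)) NA else fit$rho_test$p,
            fit$top2$efficacy$test$p, fit$top2$tw$test$p))
    wt(tests, "group_tests.tsv")
    wt(data.frame(zone = names(fit$tally), count = as.integer(fit$tally)),
       "level_tally.tsv")
  }
  wt(fit$exclusions, "exclusions.tsv")
  writeLines(fit$log, file.path(out_dir, "analysis_log.txt"))

  if (plots && length(fit$hemispheres)) {
    grDevices::png(file.path(out_dir, "curves.png"), width = 900, height = 450)
    plot(fit)
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "hemisphere_panels.png"),
                   width = 1000, height = 800)
    n <- length(fit$hemispheres)
    nc <- ceiling(sqrt(n))
    old <- graphics::par(mfrow = c(ceiling(n / nc), nc),
                         mar = c(3, 3, 2, 1), mgp = c(1.8, 0.6, 0))
    for (h in fit$hemispheres) {
      rb <- rank(h$beta$value)
      re <- rank(h$clinical$efficacy)
      rho <- suppressWarnings(spearman_rho(h$beta$value, h$clinical$efficacy))
      best <- which.max(h$beta$value)
      graphics::plot(rb, re, pch = 16, col = "grey40",
                     xlab = "ranked normalized beta",
                     ylab = "ranked efficacy",
                     main = sprintf("%s  rho = %.2f", h$hemisphere_id,
                                    as.numeric(rho)))
      graphics::points(rb[best], re[best], pch = 16, col = "black", cex = 1.6)
    }
    graphics::par(old)
    grDevices::dev.off()
  }
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
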