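#' Clinical efficacy of a contact from its monopolar review
#'
#' Percent rigidity improvement per milliampere:
#' `100 * (baseline - on_stim) / baseline / current`. The current in the
#' denominator is, by default, the test current at which rigidity was scored
#' (`current_basis = "fixed"`); `current_basis = "threshold"` divides by the
#' effect threshold instead. Worsening under stimulation (negative
#' improvement) is allowed but flagged with a warning.
#'
#' @param review data.frame with columns `rigidity_baseline`,
#'   `rigidity_on_stim`, and `test_current` (or `effect_threshold`).
#' @param current_basis Which current to use as denominator.
#' @return Numeric vector of efficacies in percent per mA.
#' @examples
#' clinical_efficacy(data.frame(rigidity_baseline = 2, rigidity_on_stim = 1,
#'                              test_current = 2))  # 25 %/mA
#' @export
clinical_efficacy <- function(review, current_basis = c("fixed", "threshold")) {
  current_basis <- match.arg(current_basis)
  b <- review$rigidity_baseline
  s <- review$rigidity_on_stim
  cur <- if (current_basis == "fixed") review$test_current
         else review$effect_threshold
  if (any(!is.finite(b)) || any(b <= 0))
    stop("rigidity baseline must be positive")
  if (any(!is.finite(cur)) || any(cur <= 0))
    stop("stimulation current must be positive")
  if (any(s > b))
    warning("rigidity worsened under stimulation for ",
            sum(s > b), " contact(s)")
  100 * (b - s) / b / cur
}

#' Therapeutic window of a contact
#'
#' Side-effect threshold minus effect threshold, in mA. Side-effect thresholds
#' that were never reached (`NA`) are capped at `current_ceiling` (the maximum
#' tested current, default 5 mA) so the window stays finite; negative windows
#' (side effects at or below the effect threshold) are clipped to 0. Both
#' events are flagged with a warning.
#'
#' @param review data.frame with columns `effect_threshold` and
#'   `side_effect_threshold` (`NA` = not reached).
#' @param current_ceiling Maximum tested current in mA.
#' @return Numeric vector of therapeutic windows in mA.
#' @examples
#' therapeutic_window(data.frame(effect_threshold = 1,
#'                               side_effect_threshold = 2.5))  # 1.5 mA
#' @export
therapeutic_window <- function(review, current_ceiling = 5) {
  eff <- review$effect_threshold
  se <- review$side_effect_threshold
  if (any(!is.finite(eff)))
    stop("missing effect threshold")
  capped <- !is.finite(se)
  if (any(capped)) {
    warning("side-effect threshold not reached for ", sum(capped),
            " contact(s); capped at ", current_ceiling, " mA")
    se[capped] <- current_ceiling
  }
  tw <- se - eff
  neg <- tw < 0
  if (any(neg)) {
    warning("negative therapeutic window clipped to 0 for ", sum(neg),
            " contact(s)")
    tw[neg] <- 0
  }
  tw
}

#' Score a monopolar review table
#'
#' Computes [clinical_efficacy()] and [therapeutic_window()] for every
#' contact of one hemisphere's review.
#'
#' @param review data.frame, one row per contact, with the review columns
#'   (`contact_id`, `rigidity_baseline`, `rigidity_on_stim`, `test_current`,
#'   `effect_threshold`, `side_effect_threshold`).
#' @inheritParams clinical_efficacy
#' @inheritParams therapeutic_window
#' @return data.frame with columns `contact_id`, `efficacy` (percent/mA),
#'   `tw` (mA).
#' @export
score_review <- function(review, current_basis = c("fixed", "threshold"),
                         current_ceiling = 5) {
  data.frame(contact_id = as.character(review$contact_id),
             efficacy = clinical_efficacy(review, current_basis),
             tw = therapeutic_window(review, current_ceiling))
}

review_columns <- c("hemisphere_id", "contact_id", "rigidity_baseline",
                    "rigidity_on_stim", "test_current", "effect_threshold",
                    "side_effect_threshold")

#' Read a monopolar review table
#'
#' Tab-delimited, one row per (hemisphere, contact), with a strict header:
#' `hemisphere_id`, `contact_id`, `rigidity_baseline`, `rigidity_on_stim`,
#' `test_current`, `effect_threshold`, `side_effect_threshold`. A side-effect
#' threshold of `NR` (not reached) is read as `NA`.
#'
#' @param path File path.
#' @return data.frame with the columns above.
#' @export
read_review_table <- function(path) {
  dat <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(review_columns, names(dat))
  if (length(missing_cols))
    stop("review table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(dat), review_columns)
  if (length(extra))
    stop("review table ", path, " has unknown column(s): ",
         paste(extra, collapse = ", "))
  dat$side_effect_threshold[dat$side_effect_threshold %in% c("NR", "")] <- NA
  num_cols <- setdiff(review_columns, c("hemisphere_id", "contact_id"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(dat[[cc]]))
    bad <- which(is.na(v) & !is.na(dat[[cc]]))
    if (length(bad))
      stop("review table ", path, ": non-numeric value in column ", cc,
           ", row ", bad[1L] + 1L)
    dat[[cc]] <- v
  }
  if (any(stats::na.omit(dat$effect_threshold > dat$side_effect_threshold)))
    warning("effect threshold exceeds side-effect threshold in ", path)
  dat
}

#' @rdname read_review_table
#' @param review The review data.frame to write.
#' @export
write_review_table <- function(review, path) {
  out <- review[, review_columns]
  out$side_effect_threshold <- ifelse(is.finite(out$side_effect_threshold),
                                      format(out$side_effect_threshold), "NR")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hemisphere dataset: paired electrophysiology and clinical scores
#'
#' Bundles, for one hemisphere, the normalized-beta profile of the six
#' segmented contacts and their clinical scores from the monopolar review.
#'
#' @param hemisphere_id Identifier.
#' @param beta data.frame `contact_id`, `value`, `used_fallback` (e.g. a
#'   [hemisphere_beta_profile()]).
#' @param clinical data.frame `contact_id`, `efficacy`, `tw` (e.g. from
#'   [score_review()]).
#' @param has_beta_peak Logical: was a clear beta peak present?
#' @param review Optional raw review table for this hemisphere.
#' @param level_of_max_beta Optional anatomical label ("ventral", "middle",
#'   "dorsal") of the ring level containing the max-beta contact.
#' @return Object of class `hemisphere_dataset`.
#' @export
hemisphere_dataset <- function(hemisphere_id, beta, clinical,
                               has_beta_peak = NA, review = NULL,
                               level_of_max_beta = NA_character_) {
  beta <- beta[order(beta$contact_id), ]
  clinical <- clinical[order(clinical$contact_id), ]
  if (nrow(beta) != 6L || nrow(clinical) != 6L)
    stop("hemisphere ", hemisphere_id,
         ": expected 6 segmented contacts in both beta and clinical tables")
  if (!identical(as.character(beta$contact_id),
                 as.character(clinical$contact_id)))
    stop("hemisphere ", hemisphere_id,
         ": beta and clinical tables disagree on contact ids")
  structure(list(hemisphere_id = hemisphere_id, beta = beta,
                 clinical = clinical, has_beta_peak = has_beta_peak,
                 review = review, level_of_max_beta = level_of_max_beta),
            class = "hemisphere_dataset")
}

#' @export
print.hemisphere_dataset <- function(x, ...) {
  cat(sprintf("Hemisphere %s (beta peak: %s)\n", x$hemisphere_id,
              ifelse(is.na(x$has_beta_peak), "unknown", x$has_beta_peak)))
  tab <- merge(x$beta, x$clinical, by = "contact_id")
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Hemisphere inclusion filters
#'
#' Keeps only hemispheres with (a) baseline upper-limb rigidity of at least
#' `min_rigidity` points and (b) a spread of responses across the six
#' contacts, max minus min efficacy, strictly greater than `min_range`.
#' These filters avoid floor effects (too little rigidity to measure
#' improvement) and ceiling effects (no contrast between contacts).
#'
#' @param cohort List of [hemisphere_dataset()] objects (hemispheres whose
#'   review lacks a baseline-rigidity entry are never excluded on rigidity).
#' @param min_rigidity Minimum baseline rigidity (points).
#' @param min_range Minimum efficacy range across contacts (percent/mA).
#' @return List with `cohort` (retained hemispheres) and `exclusions`
#'   (data.frame `hemisphere_id`, `reason`). Filtering is idempotent.
#' @export
apply_inclusion_filters <- function(cohort, min_rigidity = 2, min_range = 5) {
  keep <- logical(length(cohort))
  excl <- list()
  for (i in seq_along(cohort)) {
    h <- cohort[[i]]
    reason <- NULL
    if (!is.null(h$review) && "rigidity_baseline" %in% names(h$review)) {
      base <- max(h$review$rigidity_baseline)
      if (base < min_rigidity) reason <- c(reason, "rigidity")
    }
    rng <- diff(range(h$clinical$efficacy))
    if (!(rng > min_range)) reason <- c(reason, "range")
    if (is.null(reason)) keep[i] <- TRUE
    else excl[[length(excl) + 1L]] <-
        data.frame(hemisphere_id = as.character(h$hemisphere_id),
                   reason = paste(reason, collapse = "+"))
  }
  exclusions <- if (length(excl)) do.call(rbind, excl)
    else data.frame(hemisphere_id = character(), reason = character())
  list(cohort = cohort[keep], exclusions = exclusions)
}
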