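#' Multichannel LFP recording
#'
#' Container for a per-hemisphere local field potential recording: one channel
#' per contact, in microvolts, with a common sampling rate. The sampling rate
#' must exceed 70 Hz so that the 13-35 Hz beta band is resolvable, and the
#' duration must reach a configurable minimum (default 60 s; intraoperative
#' recordings are typically 100-120 s).
#'
#' @param samples Numeric matrix, one column per channel (rows are samples).
#' @param fs Sampling rate in Hz.
#' @param channel_ids Contact ids, one per column (defaults to column names).
#' @param min_duration_s Minimum accepted duration in seconds.
#' @return An object of class `lfp_recording` with elements `samples`, `fs`,
#'   `channel_ids`, `duration_s`.
#' @examples
#' x <- matrix(rnorm(2000 * 2), ncol = 2)
#' rec <- lfp_recording(x, fs = 200, channel_ids = c(2, 5), min_duration_s = 5)
#' @export
lfp_recording <- function(samples, fs, channel_ids = NULL, min_duration_s = 60) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (is.null(channel_ids)) {
    channel_ids <- colnames(samples)
    if (is.null(channel_ids)) channel_ids <- as.character(seq_len(ncol(samples)))
  }
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != ncol(samples))
    stop("channel_ids length must match the number of columns")
  if (anyDuplicated(channel_ids)) stop("duplicate channel ids")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 70)
    stop("fs must be a single finite value > 70 Hz (beta band must be resolvable)")
  duration_s <- nrow(samples) / fs
  if (duration_s < min_duration_s)
    stop(sprintf("recording duration %.1f s is below the minimum of %g s",
                 duration_s, min_duration_s))
  colnames(samples) <- channel_ids
  structure(list(samples = samples, fs = fs, channel_ids = channel_ids,
                 duration_s = duration_s),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("LFP recording: %d channel(s) [%s], fs = %g Hz, %.1f s\n",
              length(x$channel_ids), paste(x$channel_ids, collapse = ", "),
              x$fs, x$duration_s))
  invisible(x)
}

#' Read / write an LFP recording as delimited text
#'
#' Tab-delimited layout: optional first column `time` (seconds), then one
#' column per contact with header `c<id>` (a bare numeric header is also
#' accepted). If no `time` column is present, `fs` must be supplied.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz (ignored when a `time` column is present).
#' @param min_duration_s Passed to [lfp_recording()].
#' @return An `lfp_recording`.
#' @export
read_lfp_tsv <- function(path, fs = NULL, min_duration_s = 60) {
  dat <- utils::read.delim(path, check.names = FALSE)
  if (ncol(dat) < 1L) stop("empty LFP file: ", path)
  nm <- names(dat)
  if (tolower(nm[1L]) == "time") {
    tt <- dat[[1L]]
    if (length(tt) < 2L) stop("time column too short in ", path)
    fs <- 1 / stats::median(diff(tt))
    dat <- dat[, -1L, drop = FALSE]
    nm <- nm[-1L]
  } else if (is.null(fs)) {
    stop("no time column in ", path, " and no fs supplied")
  }
  ids <- sub("^c", "", nm)
  lfp_recording(as.matrix(dat), fs = fs, channel_ids = ids,
                min_duration_s = min_duration_s)
}

#' @rdname read_lfp_tsv
#' @param rec An `lfp_recording`.
#' @param time Logical; write an explicit time column.
#' @export
write_lfp_tsv <- function(rec, path, time = FALSE) {
  out <- as.data.frame(rec$samples)
  names(out) <- paste0("c", rec$channel_ids)
  if (time)
    out <- cbind(time = (seq_len(nrow(out)) - 1L) / rec$fs, out)
  utils::write.table(format(out, digits = 8, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
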