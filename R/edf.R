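# Minimal European Data Format (EDF) I/O: 16-bit samples, fixed 1-second data
# records, plain EDF (no annotations). Sufficient for interchange of the
# multichannel LFP recordings this package analyses.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

#' Write an LFP recording to an EDF file
#'
#' Plain EDF, one-second data records, 16-bit integers. Each channel is scaled
#' to its own physical range, so the quantization step is (max - min)/65535
#' microvolts. The duration is truncated to a whole number of seconds.
#'
#' @param rec An [lfp_recording()].
#' @param path Output path.
#' @param patient,recording_id Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "dirlfp") {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n_rec <- nrow(rec$samples) %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)")
  if (n_rec * fs < nrow(rec$samples))
    warning("truncating recording to ", n_rec, " whole second(s) for EDF")
  x <- rec$samples[seq_len(n_rec * fs), , drop = FALSE]
  ns <- ncol(x)

  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- round(sweep(sweep(x, 2, pmin_), 2, scale, `*`)) + dmin
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(paste0(vapply(x, edf_pad, "", width = w),
                                        collapse = ""),
                                 con, eos = NULL)
  wr("0", 8)                                   # version
  wr(patient, 80); wr(recording_id, 80)
  wr("01.01.00", 8); wr("00.00.00", 8)         # start date/time (unused)
  wr(as.character(256L + ns * 256L), 8)        # header bytes
  wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8)       # n records, record duration
  wr(as.character(ns), 4)
  wr(paste0("c", rec$channel_ids), 16)         # labels
  wr(rep("", ns), 80)                          # transducer
  wr(rep("uV", ns), 8)                         # physical dimension
  wr(formatC(pmin_, format = "g", digits = 7), 8)
  wr(formatC(pmax_, format = "g", digits = 7), 8)
  wr(rep(as.character(dmin), ns), 8)
  wr(rep(as.character(dmax), ns), 8)
  wr(rep("", ns), 80)                          # prefiltering
  wr(rep(as.character(fs), ns), 8)             # samples per record
  wr(rep("", ns), 32)

  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(as.vector(dig[rows, , drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file as an LFP recording
#'
#' Reads plain EDF with a common sampling rate across channels and a fixed
#' record duration. Digital values are rescaled to physical units.
#'
#' @param path EDF file path.
#' @param min_duration_s Passed to [lfp_recording()].
#' @return An [lfp_recording()].
#' @export
read_edf <- function(path, min_duration_s = 60) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8); rd(80); rd(80); rd(8); rd(8)
  if (ver != "0") stop("unsupported EDF version in ", path)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)             # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("channels with differing sampling rates are not supported: ", path)
  fs <- spr[1L] / rec_dur

  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_rec * sum(spr)) stop("truncated EDF data in ", path)
  x <- matrix(0, nrow = n_rec * spr[1L], ncol = ns)
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    block <- matrix(raw[((r - 1L) * per_rec + 1L):(r * per_rec)], ncol = ns)
    x[((r - 1L) * spr[1L] + 1L):(r * spr[1L]), ] <- block
  }
  for (j in seq_len(ns))
    x[, j] <- pmin_[j] + (x[, j] - dmin[j]) * (pmax_[j] - pmin_[j]) /
      (dmax[j] - dmin[j])
  ids <- sub("^c", "", labels)
  lfp_recording(x, fs = fs, channel_ids = ids, min_duration_s = min_duration_s)
}
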