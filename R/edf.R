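# Minimal European Data Format (EDF) codec: 16-bit continuous recordings,
# one-second data records, physical units microvolts. Covers exactly what
# the pipeline needs to round-trip its own recordings.

.fmt_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)  # left-justified, space padded
}

.fmt_num8 <- function(x) {
  for (d in 6:1) {
    s <- trimws(formatC(x, digits = d, format = "g"))
    if (nchar(s) <= 8) return(s)
  }
  substr(trimws(as.character(x)), 1, 8)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits with a per-channel symmetric physical
#' range; the maximum round-trip error is one quantization step. The
#' recording is zero-padded to a whole number of 1-s data records.
#'
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  data <- recording$data
  fs <- recording$sample_rate
  assert_that(fs == round(fs), "EDF writer requires an integer sample rate")
  ns <- nrow(data)
  n_rec <- ceiling(ncol(data) / fs)
  if (ncol(data) < n_rec * fs) {
    data <- cbind(data, matrix(0, ns, n_rec * fs - ncol(data)))
  }
  # symmetric physical range per channel, stored at 8-char precision so the
  # reader reconstructs with the same scale
  pmax_raw <- apply(abs(data), 1, max)
  pmax_raw[pmax_raw == 0] <- 1
  pmax_chr <- vapply(pmax_raw * 1.0001, .fmt_num8, character(1))
  pmax_num <- as.numeric(pmax_chr)
  recinfo <- sprintf("participant=%s session=%s condition=%s",
                     recording$participant_id, recording$session_id,
                     recording$condition)
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, width) writeChar(.fmt_field(x, width), con, nchars = width,
                                     eos = NULL)
  wf("0", 8); wf("X", 80); wf(recinfo, 80)
  wf("01.01.00", 8); wf("00.00.00", 8)
  wf(256 + ns * 256, 8); wf("", 44); wf(n_rec, 8); wf("1", 8); wf(ns, 4)
  for (lab in rownames(data)) wf(lab, 16)
  for (i in seq_len(ns)) wf("", 80)          # transducer
  for (i in seq_len(ns)) wf("uV", 8)         # physical dimension
  for (i in seq_len(ns)) wf(paste0("-", pmax_chr[i]), 8)
  for (i in seq_len(ns)) wf(pmax_chr[i], 8)
  for (i in seq_len(ns)) wf("-32767", 8)
  for (i in seq_len(ns)) wf("32767", 8)
  for (i in seq_len(ns)) wf("", 80)          # prefiltering
  for (i in seq_len(ns)) wf(fs, 8)
  for (i in seq_len(ns)) wf("", 32)
  dig <- round(sweep(data, 1, pmax_num, "/") * 32767)
  dig <- pmin(pmax(dig, -32767), 32767)
  for (r in seq_len(n_rec)) {
    cols <- (r - 1) * fs + seq_len(fs)
    writeBin(as.integer(t(dig[, cols])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @param layout optional `channel_layout`; when the file's labels match the
#'   packaged montage the full layout is attached, otherwise a bare layout
#'   with zero positions is constructed.
#' @return an `eeg_recording` (probe times are carried in the report table,
#'   not the EDF, and are empty here).
#' @export
read_edf <- function(path, layout = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    s <- readChar(con, width, useBytes = TRUE)
    assert_that(nchar(s) == width, "truncated EDF header")
    trimws(s)
  }
  rd(8)                       # version
  rd(80)                      # patient
  recinfo <- rd(80)
  rd(8); rd(8)                # date, time
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  assert_that(!is.na(n_rec), "malformed EDF header: n data records")
  dur <- as.numeric(rd(8))
  assert_that(isTRUE(dur == 1), "malformed EDF header: record duration")
  ns <- as.integer(rd(4))
  assert_that(!is.na(ns) && ns > 0, "malformed EDF header: signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_v <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_v <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_v <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_v <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  assert_that(all(is.finite(c(pmin_v, pmax_v, dmin_v, dmax_v))),
              "malformed EDF header: physical/digital ranges")
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  assert_that(length(unique(spr)) == 1, "mixed sampling rates not supported")
  fs <- spr[1]
  for (i in seq_len(ns)) rd(32)
  data <- matrix(0, ns, n_rec * fs)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), n = ns * fs, size = 2,
                     endian = "little")
    data[, (r - 1) * fs + seq_len(fs)] <- t(matrix(block, fs, ns))
  }
  scale <- (pmax_v - pmin_v) / (dmax_v - dmin_v)
  data <- sweep(sweep(data, 1, dmin_v), 1, scale, `*`) + pmin_v
  meta <- list(participant = "p1", session = "s1", condition = "task")
  for (kv in strsplit(recinfo, " ")[[1]]) {
    parts <- strsplit(kv, "=")[[1]]
    if (length(parts) == 2) {
      key <- sub("participant", "participant", parts[1])
      meta[[parts[1]]] <- parts[2]
    }
  }
  std <- make_layout()
  if (is.null(layout)) {
    layout <- if (identical(labels, std$labels)) std else
      structure(list(labels = labels,
                     positions = matrix(0, ns, 2,
                                        dimnames = list(labels, c("x", "y")))),
                class = "channel_layout")
  }
  rownames(data) <- labels
  new_recording(data, fs, layout, numeric(0),
                condition = meta$condition,
                participant_id = meta$participant,
                session_id = meta$session)
}
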