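#' Minimal EDF writer and reader
#'
#' A deliberately small implementation of the continuous-recording subset of
#' the European Data Format: one fixed record duration, identical sampling
#' rate across signals, 16-bit samples with per-signal physical scaling. It
#' covers round-tripping epoched trials to and from acquisition-style files;
#' annotations, discontinuous recordings, and EDF+ extensions are out of
#' scope (use the TSV layout for anything richer).
#'
#' Amplitude resolution is bounded by the 16-bit quantisation: values round
#' trip to within `(physical range) / 65535` per channel.
#'
#' @param trial A [raw_trial()] (or any list with `samples` and
#'   `sampling_rate`).
#' @param path Output file.
#' @param record_sec Data-record duration in seconds (default 1). Samples
#'   beyond the last whole record are dropped.
#' @return `write_edf` returns `path` invisibly. `read_edf` returns a list
#'   with `samples` (channels x time, rownames = signal labels) and
#'   `sampling_rate`.
#' @export
write_edf <- function(trial, path, record_sec = 1) {
  x <- trial$samples
  fs <- trial$sampling_rate
  ns <- nrow(x)
  spr <- round(fs * record_sec)
  n_rec <- floor(ncol(x) / spr)
  if (n_rec < 1) stop("trial shorter than one data record")
  x <- x[, seq_len(n_rec * spr), drop = FALSE]
  labels <- rownames(x)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))

  pmin <- apply(x, 1, min)
  pmax <- apply(x, 1, max)
  flat <- pmax - pmin == 0
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768
  dmax <- 32767

  pad <- function(v, width) {
    s <- substr(as.character(v), 1, width)
    sprintf("%-*s", width, s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic", 80), pad("crossday", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(256 * (ns + 1), 8), pad("", 44),
                pad(n_rec, 8), pad(format(record_sec), 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(pad(labels, 16), collapse = ""), con, eos = NULL)
  writeChar(paste0(pad(rep("", ns), 80), collapse = ""), con, eos = NULL)
  writeChar(paste0(pad(rep("uV", ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(pad(sprintf("%.6g", pmin), 8), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(pad(sprintf("%.6g", pmax), 8), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(pad(rep(dmin, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(pad(rep(dmax, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(pad(rep("HP:1Hz", ns), 80), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(pad(rep(spr, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(pad(rep("", ns), 32), collapse = ""), con, eos = NULL)

  # Re-read the printed physical ranges so scaling matches what a reader
  # will parse (the 8-character fields truncate precision).
  pmin_r <- as.numeric(substr(sprintf("%.6g", pmin), 1, 8))
  pmax_r <- as.numeric(substr(sprintf("%.6g", pmax), 1, 8))
  gain <- (pmax_r - pmin_r) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      d <- round((x[s, idx] - pmin_r[s]) / gain[s]) + dmin
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  record_sec <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)            # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")

  gain <- (pmax - pmin) / (dmax - dmin)
  out <- matrix(0, ns, n_rec * spr[1], dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                   endian = "little")
      out[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        pmin[s] + (d - dmin[s]) * gain[s]
    }
  }
  list(samples = out, sampling_rate = spr[1] / record_sec)
}
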