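# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores a 256-byte ASCII global header, 256 bytes of ASCII header per
# signal, then fixed-duration data records of little-endian 16-bit integers.
# We write one data record per second (samples-per-record = rate) and a
# shared symmetric physical range across channels, which keeps the
# quantization step uniform: (phys_max - phys_min) / 65535.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Writes standard EDF (16-bit) with one data record per second. Amplitudes
#' are quantized onto a symmetric physical range covering the data, so a
#' round trip reproduces samples within
#' \code{(phys_max - phys_min) / 65535} microvolts.
#'
#' @param rec an \code{\link{swd_recording}}. The sampling rate must be a
#'   whole number of samples per second.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "swd_recording"))
  fs <- rec$rate_hz
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$samples)
  n_total <- ncol(rec$samples)
  n_rec <- ceiling(n_total / fs)
  # pad the final partial second with zeros
  x <- rec$samples
  if (n_rec * fs > n_total)
    x <- cbind(x, matrix(0, ns, n_rec * fs - n_total))
  pmax_ <- max(1, ceiling(max(abs(x))))
  pmin_ <- -pmax_
  dmax <- 32767L; dmin <- -32768L
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- round((x - pmin_) * scale) + dmin
  dig[dig > dmax] <- dmax; dig[dig < dmin] <- dmin

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(paste("X X X", rec$patient_id), 80),
    .edf_pad("Startdate X X X X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad("1", 8),
    .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, .edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(paste("EEG", rec$channel_names), 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(rep(format(pmin_), ns), 8)
  field(rep(format(pmax_), ns), 8)
  field(rep(format(dmin), ns), 8)
  field(rep(format(dmax), ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(fs, ns), 8)                        # samples per record
  field(rep("", ns), 32)                       # reserved
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the EDF header and 16-bit data records, rescales to physical
#' units, and returns an \code{\link{swd_recording}}. All signals must
#' share one sampling rate.
#'
#' @param path EDF file path.
#' @param patient_id optional identifier overriding the EDF patient field.
#' @return An \code{swd_recording} with reference \code{"original"}.
#' @export
read_edf <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                        # version
  pat <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) trimws(readChar(con, w, useBytes = TRUE)), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop("EDF signals have heterogeneous sampling rates; not supported")
  fs <- spr[1] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, integer(), n = ns * spr[1], size = 2, signed = TRUE,
                   endian = "little")
    out[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      matrix(blk, nrow = ns, byrow = TRUE)
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  out <- out * gain + (pmin_ - dmin * gain)
  if (is.null(patient_id)) {
    parts <- strsplit(pat, " +")[[1]]
    patient_id <- if (length(parts) >= 4) parts[4] else pat
  }
  swd_recording(out, fs, normalize_channel_names(labels),
                reference = "original", patient_id = patient_id)
}
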