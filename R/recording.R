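#' Canonical 16-channel 10-20 montage
#'
#' The reduced 16-channel subset of the international 10-20 system used as
#' the canonical feature space for spatial analysis. Dense-array or modern
#' nomenclature inputs are mapped onto these labels by
#' \code{\link{normalize_channel_names}}.
#'
#' @return Character vector of 16 channel labels, anterior to posterior.
#' @export
channels_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4",
    "T3", "T4", "P3", "P4", "T5", "T6", "O1", "O2")
}

# modern (10-10) aliases for the classic temporal labels, both directions
.channel_aliases <- c(
  "T7" = "T3", "T8" = "T4", "P7" = "T5", "P8" = "T6"
)

#' Normalize EEG channel labels to the canonical 10-20 names
#'
#' Strips an optional \code{"EEG "} prefix, fixes case, and maps the modern
#' temporal labels (T7/T8/P7/P8) to their classic 10-20 equivalents
#' (T3/T4/T5/T6).
#'
#' @param x character vector of channel labels.
#' @return Character vector of normalized labels.
#' @export
normalize_channel_names <- function(x) {
  x <- sub("^EEG[ _]*", "", x, ignore.case = TRUE)
  x <- sub("[-_].*$", "", x)  # drop reference suffixes like "Fp1-Ref"
  canon <- c(channels_1020(), "Cz", "Fz", "Pz", names(.channel_aliases))
  m <- match(toupper(x), toupper(canon))
  x[!is.na(m)] <- canon[m[!is.na(m)]]
  ali <- match(x, names(.channel_aliases))
  x[!is.na(ali)] <- .channel_aliases[ali[!is.na(ali)]]
  x
}

#' Construct an EEG recording object
#'
#' A recording is a channels x samples matrix of amplitudes in microvolts
#' with a sampling rate, ordered channel labels, a reference state and a
#' patient identifier.
#'
#' @param samples numeric matrix, channels in rows, samples in columns (uV).
#' @param rate_hz sampling rate in Hz (> 0).
#' @param channel_names character vector, one unique label per row.
#' @param reference one of \code{"original"}, \code{"Cz"},
#'   \code{"common_average"}.
#' @param patient_id scalar identifier.
#' @return An object of class \code{"swd_recording"}.
#' @export
swd_recording <- function(samples, rate_hz, channel_names,
                          reference = c("original", "Cz", "common_average"),
                          patient_id = "P01") {
  reference <- match.arg(reference)
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("'samples' must be numeric")
  if (length(channel_names) != nrow(samples))
    stop("channel_names length (", length(channel_names),
         ") != number of channels (", nrow(samples), ")")
  if (anyDuplicated(channel_names))
    stop("duplicate channel names: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("'rate_hz' must be a single positive number")
  rownames(samples) <- channel_names
  structure(
    list(samples = samples, rate_hz = rate_hz,
         channel_names = as.character(channel_names),
         reference = reference, patient_id = as.character(patient_id)),
    class = "swd_recording")
}

#' @export
print.swd_recording <- function(x, ...) {
  cat(sprintf("<swd_recording> patient %s: %d channels x %d samples @ %g Hz (%.1f s), ref=%s\n",
              x$patient_id, nrow(x$samples), ncol(x$samples), x$rate_hz,
              ncol(x$samples) / x$rate_hz, x$reference))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an \code{swd_recording}.
#' @return Numeric scalar, seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$rate_hz

#' Build and validate an SWD event table
#'
#' Each row describes one spike-wave discharge: onset and offset in seconds
#' from recording start, patient ID, and an optional behavioral label
#' (0 = spared, 1 = impaired, NA = unlabeled).
#'
#' @param patient_id character or factor.
#' @param onset_s,offset_s numeric, seconds; \code{0 <= onset < offset}.
#' @param label integer 0/1 or NA.
#' @param swd_id optional event identifiers (default sequential).
#' @return data.frame with columns patient_id, swd_id, onset_s, offset_s,
#'   label.
#' @export
swd_events <- function(patient_id, onset_s, offset_s, label = NA_integer_,
                       swd_id = NULL) {
  n <- length(onset_s)
  if (is.null(swd_id)) swd_id <- seq_len(n)
  ev <- data.frame(patient_id = as.character(rep_len(patient_id, n)),
                   swd_id = rep_len(swd_id, n),
                   onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s),
                   label = as.integer(rep_len(label, n)),
                   stringsAsFactors = FALSE)
  validate_events(ev)
  ev
}

validate_events <- function(events, rec = NULL) {
  need <- c("patient_id", "swd_id", "onset_s", "offset_s", "label")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(events$onset_s < 0)) stop("event onset_s must be >= 0")
  if (any(events$offset_s <= events$onset_s))
    stop("event offset_s must exceed onset_s")
  bad <- !(events$label %in% c(0L, 1L) | is.na(events$label))
  if (any(bad)) stop("labels must be 0 (spared), 1 (impaired) or NA")
  if (!is.null(rec)) {
    dur <- recording_duration(rec)
    over <- events$offset_s > dur + 1e-9
    if (any(over))
      stop("event(s) ", paste(events$swd_id[over], collapse = ", "),
           " extend beyond recording end (", round(dur, 3), " s)")
  }
  invisible(events)
}
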