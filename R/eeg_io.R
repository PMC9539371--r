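#' Read a recording and its SWD annotations
#'
#' Loads an EDF file and the accompanying annotation CSV
#' (columns \code{patient_id, swd_id, onset_s, offset_s, label}), keeps the
#' rows matching the recording's patient, and validates every event against
#' the recording duration.
#'
#' @param path EDF file path.
#' @param annotations path to the annotation CSV, or a data.frame.
#' @return \code{list(recording = swd_recording, events = data.frame)}.
#' @export
read_recording <- function(path, annotations) {
  rec <- read_edf(path)
  ev <- if (is.data.frame(annotations)) annotations else {
    if (!file.exists(annotations)) stop("annotation file not found: ", annotations)
    utils::read.csv(annotations, stringsAsFactors = FALSE)
  }
  validate_events(ev)
  ev <- ev[ev$patient_id == rec$patient_id, , drop = FALSE]
  validate_events(ev, rec)
  list(recording = rec, events = ev)
}

#' Preprocess a recording for feature analysis
#'
#' Selects and canonically orders a channel subset (with 10-20 name
#' normalization), resamples to the target rate with an anti-aliased
#' polyphase filter, band-pass filters 0.5 to min(100, Nyquist - 1) Hz,
#' and re-references.
#'
#' @param rec an \code{\link{swd_recording}}.
#' @param target_rate_hz working rate; must not exceed the native rate.
#'   The default 256 Hz is the lowest rate across typical clinical cohorts,
#'   so heterogeneous recordings land in one feature space.
#' @param reference \code{"common_average"} (default), \code{"Cz"}, or
#'   \code{"original"} (leave as recorded).
#' @param channel_subset channels to keep, in canonical order
#'   (default: the 16-channel 10-20 subset).
#' @param band_pass logical; apply the 0.5 Hz high-pass / low-pass filter.
#' @return A new \code{swd_recording}.
#' @export
preprocess <- function(rec, target_rate_hz = 256,
                       reference = c("common_average", "Cz", "original"),
                       channel_subset = channels_1020(),
                       band_pass = TRUE) {
  stopifnot(inherits(rec, "swd_recording"))
  reference <- match.arg(reference)
  if (target_rate_hz > rec$rate_hz)
    stop("target rate (", target_rate_hz, " Hz) exceeds native rate (",
         rec$rate_hz, " Hz)")
  have <- normalize_channel_names(rec$channel_names)
  want <- normalize_channel_names(channel_subset)
  if (reference == "Cz" && !("Cz" %in% have))
    stop("Cz reference requested but channel Cz is absent")
  idx <- match(want, have)
  if (anyNA(idx))
    stop("requested channel(s) not present: ",
         paste(channel_subset[is.na(idx)], collapse = ", "))
  x <- rec$samples[idx, , drop = FALSE]
  ref_sig <- if (reference == "Cz") rec$samples[match("Cz", have), ] else NULL

  fs <- rec$rate_hz
  if (target_rate_hz < fs) {
    frac <- .as_ratio(target_rate_hz / fs)
    x <- t(apply(x, 1, function(ch) signal::resample(ch, frac[1], frac[2])))
    if (!is.null(ref_sig)) ref_sig <- signal::resample(ref_sig, frac[1], frac[2])
    fs <- target_rate_hz
  }
  if (band_pass) {
    f_high <- min(100, fs / 2 - 1)
    bf <- signal::butter(4, c(0.5, f_high) / (fs / 2), type = "pass")
    x <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
    if (!is.null(ref_sig)) ref_sig <- signal::filtfilt(bf, ref_sig)
  }
  if (reference == "common_average") {
    x <- sweep(x, 2, colMeans(x))
  } else if (reference == "Cz") {
    x <- sweep(x, 2, ref_sig)
  } else {
    reference <- rec$reference
  }
  swd_recording(x, fs, want, reference = reference, patient_id = rec$patient_id)
}

# smallest integer ratio p/q approximating r (r <= 1)
.as_ratio <- function(r, max_den = 4096) {
  den <- seq_len(max_den)
  num <- round(r * den)
  ok <- which(abs(num / den - r) < 1e-9)
  if (!length(ok)) ok <- which.min(abs(num / den - r))
  c(num[ok[1]], den[ok[1]])
}

#' Preictal/ictal window configuration
#'
#' Defaults are 1000 ms preictal and 500 ms ictal, the sizes at which the
#' spared predictive value peaks for CSP features. The validated ranges are
#' the grids the search covers: preictal 100-5000 ms, ictal 100-1000 ms;
#' values outside them are rejected unless \code{allow_extrapolation}.
#'
#' @param pre_ms preictal window length, ms.
#' @param ict_ms ictal window length, ms.
#' @param allow_extrapolation permit values outside the searched ranges.
#' @return An object of class \code{"window_config"}.
#' @export
window_config <- function(pre_ms = 1000, ict_ms = 500,
                          allow_extrapolation = FALSE) {
  if (!allow_extrapolation) {
    if (pre_ms < 100 || pre_ms > 5000)
      stop("pre_ms must lie in [100, 5000] ms (got ", pre_ms,
           "); set allow_extrapolation = TRUE to override")
    if (ict_ms < 100 || ict_ms > 1000)
      stop("ict_ms must lie in [100, 1000] ms (got ", ict_ms,
           "); set allow_extrapolation = TRUE to override")
  }
  structure(list(pre_ms = pre_ms, ict_ms = ict_ms), class = "window_config")
}

#' Extract the preictal/ictal window pair for one event
#'
#' Windows are half-open in samples: the preictal window covers
#' \code{[onset - pre_ms, onset)} and the ictal window
#' \code{[onset, onset + ict_ms)}; the onset sample belongs to the ictal
#' window. Sample counts are \code{round(len_ms * rate / 1000)}.
#'
#' Events with insufficient preictal context (or running past the recording
#' end) are excluded rather than zero-padded: the function signals a
#' condition of class \code{"swd_window_skip"} (a warning) and returns
#' \code{NULL}, so callers can log and drop the event.
#'
#' @param rec an \code{\link{swd_recording}}.
#' @param event one-row data.frame as in \code{\link{swd_events}}.
#' @param cfg a \code{\link{window_config}}.
#' @return \code{list(preictal, ictal, event)} of class
#'   \code{"window_pair"}, or \code{NULL} if the event was skipped.
#' @export
extract_windows <- function(rec, event, cfg = window_config()) {
  stopifnot(inherits(rec, "swd_recording"))
  fs <- rec$rate_hz
  n_pre <- round(cfg$pre_ms * fs / 1000)
  n_ict <- round(cfg$ict_ms * fs / 1000)
  i_on <- round(event$onset_s * fs)           # 0-based onset sample
  n_tot <- ncol(rec$samples)
  if (i_on - n_pre < 0 || i_on + n_ict > n_tot) {
    warning(structure(
      class = c("swd_window_skip", "warning", "condition"),
      list(message = sprintf(
             "event %s at %.2f s skipped: window [%g ms pre, %g ms ict] outside recording",
             event$swd_id, event$onset_s, cfg$pre_ms, cfg$ict_ms),
           call = sys.call())))
    return(NULL)
  }
  structure(list(
    preictal = rec$samples[, (i_on - n_pre + 1):i_on, drop = FALSE],
    ictal    = rec$samples[, (i_on + 1):(i_on + n_ict), drop = FALSE],
    event    = event),
    class = "window_pair")
}

#' Extract window pairs for a whole event table
#'
#' Applies \code{\link{extract_windows}} across recordings and events,
#' silently collecting skip conditions.
#'
#' @param recordings list of \code{swd_recording} (named or not); matched to
#'   events by \code{patient_id}.
#' @param events event table (\code{\link{swd_events}}).
#' @param cfg a \code{\link{window_config}}.
#' @return \code{list(pairs = list of window_pair, events = retained rows,
#'   skipped = dropped rows)}.
#' @export
extract_all_windows <- function(recordings, events, cfg = window_config()) {
  ids <- vapply(recordings, function(r) r$patient_id, "")
  pairs <- vector("list", nrow(events))
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    ri <- match(events$patient_id[i], ids)
    if (is.na(ri)) stop("no recording for patient ", events$patient_id[i])
    wp <- withCallingHandlers(
      extract_windows(recordings[[ri]], events[i, ], cfg),
      swd_window_skip = function(w) invokeRestart("muffleWarning"))
    if (!is.null(wp)) { pairs[[i]] <- wp; keep[i] <- TRUE }
  }
  list(pairs = pairs[keep],
       events = events[keep, , drop = FALSE],
       skipped = events[!keep, , drop = FALSE])
}
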