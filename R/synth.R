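# Synthetic EEG cohort generator: labeled spike-wave discharges embedded in
# background EEG, with class contrasts in duration, wave amplitude,
# preictal delta power and scalp topography.

.default_topography <- function(channels = channels_1020(), anterior = TRUE) {
  grp <- function(frontal, central, parietal, occipital) {
    w <- stats::setNames(numeric(length(channels)), channels)
    w[grepl("^(Fp|F)", channels)] <- frontal
    w[grepl("^(C|T3|T4)", channels)] <- central
    w[grepl("^(P|T5|T6)", channels)] <- parietal
    w[grepl("^O", channels)] <- occipital
    w
  }
  if (anterior) grp(1.0, 0.75, 0.55, 0.45) else grp(0.65, 0.85, 1.0, 0.95)
}

#' Configuration of the synthetic SWD cohort generator
#'
#' Defaults emulate the labeled clinical cohorts: 130 SWDs (81 spared, 49
#' impaired) in 34 patients, spared/impaired duration means 947 vs 4336 ms
#' (lognormal, SDs from the reported dispersion, truncated to
#' [300 ms, 20 s]), doubled wave-component amplitude and doubled preictal
#' delta amplitude for impaired SWDs, and distinct scalp topographies
#' (anterior-dominant for spared, posterior-shifted for impaired) so that
#' spatial-filter features carry class information.
#'
#' @param n_patients number of synthetic patients.
#' @param n_spared_swd,n_impaired_swd class counts (>= 0, total >= 1).
#' @param rate_hz sampling rate (Hz).
#' @param n_channels channel count; 16 uses the canonical 10-20 subset.
#' @param duration_ms_spared,duration_ms_impaired \code{c(mean, sd)} of the
#'   lognormal SWD duration in ms.
#' @param swd_freq_hz spike-wave fundamental in [2.5, 5] Hz (each event is
#'   jittered by up to 5\%).
#' @param amplitude_uv_spared,amplitude_uv_impaired wave-component
#'   amplitude in uV (> 0).
#' @param preictal_delta_uv baseline preictal delta amplitude, uV.
#' @param preictal_delta_gain_impaired multiplier (>= 1) on the preictal
#'   delta amplitude for impaired SWDs.
#' @param topography_weights per-channel gain of the SWD waveform for
#'   spared events (default anterior-dominant).
#' @param topography_weights_impaired per-channel gain for impaired events
#'   (default posterior-shifted).
#' @param background_noise_uv RMS of the 1/f background noise, uV.
#' @param alpha_uv amplitude of the posterior 10 Hz alpha rhythm, uV.
#' @param gap_s silent gap before each SWD (also the lead-in), s; must
#'   leave room for the longest preictal window.
#' @param recording_duration_s optional fixed per-patient duration; events
#'   that do not fit raise an error.
#' @param class_purity if TRUE, each patient receives SWDs of one class
#'   only (for patient-level experiments).
#' @param seed RNG seed; identical (config, seed) pairs give bit-identical
#'   output.
#' @return Object of class \code{"synth_config"}.
#' @export
synth_config <- function(n_patients = 34L,
                         n_spared_swd = 81L, n_impaired_swd = 49L,
                         rate_hz = 256, n_channels = 16L,
                         duration_ms_spared = c(947, 414),
                         duration_ms_impaired = c(4336, 3269),
                         swd_freq_hz = 3.5,
                         amplitude_uv_spared = 45,
                         amplitude_uv_impaired = 90,
                         preictal_delta_uv = 8,
                         preictal_delta_gain_impaired = 2,
                         topography_weights = NULL,
                         topography_weights_impaired = NULL,
                         background_noise_uv = 10,
                         alpha_uv = 5,
                         gap_s = 6,
                         recording_duration_s = NULL,
                         class_purity = FALSE,
                         seed = 1L) {
  if (n_patients < 1L) stop("n_patients must be >= 1")
  if (n_spared_swd < 0L || n_impaired_swd < 0L ||
      n_spared_swd + n_impaired_swd < 1L)
    stop("need at least one SWD; class counts must be >= 0")
  if (rate_hz <= 0) stop("rate_hz must be positive")
  if (swd_freq_hz < 2.5 || swd_freq_hz > 5)
    stop("swd_freq_hz must lie in [2.5, 5]")
  if (amplitude_uv_spared <= 0 || amplitude_uv_impaired <= 0)
    stop("amplitudes must be positive")
  if (any(c(duration_ms_spared[1], duration_ms_impaired[1]) <= 0))
    stop("duration means must be positive")
  if (preictal_delta_gain_impaired < 1)
    stop("preictal_delta_gain_impaired must be >= 1")
  channels <- if (n_channels == 16L) channels_1020() else
    paste0("ch", seq_len(n_channels))
  if (is.null(topography_weights))
    topography_weights <- .default_topography(channels, anterior = TRUE)
  if (is.null(topography_weights_impaired))
    topography_weights_impaired <- .default_topography(channels, anterior = FALSE)
  structure(list(
    n_patients = as.integer(n_patients),
    n_spared_swd = as.integer(n_spared_swd),
    n_impaired_swd = as.integer(n_impaired_swd),
    rate_hz = rate_hz, n_channels = as.integer(n_channels),
    channels = channels,
    duration_ms_spared = duration_ms_spared,
    duration_ms_impaired = duration_ms_impaired,
    swd_freq_hz = swd_freq_hz,
    amplitude_uv_spared = amplitude_uv_spared,
    amplitude_uv_impaired = amplitude_uv_impaired,
    preictal_delta_uv = preictal_delta_uv,
    preictal_delta_gain_impaired = preictal_delta_gain_impaired,
    topography_weights = topography_weights,
    topography_weights_impaired = topography_weights_impaired,
    background_noise_uv = background_noise_uv, alpha_uv = alpha_uv,
    gap_s = gap_s, recording_duration_s = recording_duration_s,
    class_purity = isTRUE(class_purity), seed = as.integer(seed)),
    class = "synth_config")
}

# truncated lognormal durations (ms) parameterized by arithmetic mean/sd
.rdur <- function(n, mean_sd, lo = 300, hi = 20000) {
  if (n == 0L) return(numeric(0))
  m <- mean_sd[1]; s <- mean_sd[2]
  sdl <- sqrt(log(1 + (s / m)^2))
  ml <- log(m) - sdl^2 / 2
  out <- numeric(n); got <- 0L
  for (i in 1:100) {
    d <- stats::rlnorm(n, ml, sdl)
    d <- d[d >= lo & d <= hi]
    take <- min(length(d), n - got)
    if (take > 0) { out[(got + 1):(got + take)] <- d[seq_len(take)]; got <- got + take }
    if (got == n) break
  }
  if (got < n) out[(got + 1):n] <- pmin(pmax(m, lo), hi)
  out
}

# 1/f-shaped noise, unit RMS
.pink_noise <- function(n, fs) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- (0:(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  g <- 1 / sqrt(pmax(f, 0.5))
  x <- Re(stats::fft(sp * g, inverse = TRUE)) / n
  x / stats::sd(x)
}

# spike-plus-wave composite over a time grid (s, relative to onset)
.swd_waveform <- function(t_rel, freq, amp, phase, fs) {
  wave <- sin(2 * pi * freq * t_rel + phase)
  # spikes: ~20 ms Gaussian transients riding each wave peak
  k_range <- floor(freq * max(t_rel)) + 1L
  peaks <- ((pi / 2 - phase) / (2 * pi) + seq(-1, k_range)) / freq
  peaks <- peaks[peaks >= 0 & peaks <= max(t_rel)]
  spike <- numeric(length(t_rel))
  for (tp in peaks)
    spike <- spike + exp(-0.5 * ((t_rel - tp) / 0.008)^2)
  dur <- max(t_rel)
  ramp_len <- min(0.1, dur / 4)
  env <- rep(1, length(t_rel))
  r1 <- t_rel < ramp_len
  env[r1] <- 0.5 * (1 - cos(pi * t_rel[r1] / ramp_len))
  r2 <- t_rel > dur - ramp_len
  env[r2] <- 0.5 * (1 - cos(pi * (dur - t_rel[r2]) / ramp_len))
  amp * env * (wave + 1.3 * spike)
}

#' Generate a labeled synthetic SWD cohort
#'
#' Builds one continuous multichannel recording per patient: 1/f background
#' noise plus a posterior 10 Hz alpha rhythm, with spike-plus-wave events
#' (sharp ~20 ms transients riding a 2.5-5 Hz wave) inserted at spaced
#' onsets, scaled by the class topography, and preceded by a 2 s frontal
#' preictal delta component whose amplitude is elevated for impaired
#' events. SWDs are distributed round-robin across patients (or by class
#' when \code{class_purity}).
#'
#' @param config a \code{\link{synth_config}}.
#' @return \code{list(recordings = list of swd_recording,
#'   events = data.frame)} with exactly the requested label counts.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, .generate_dataset_impl(config))
}

.generate_dataset_impl <- function(cf) {
  fs <- cf$rate_hz
  n_tot <- cf$n_spared_swd + cf$n_impaired_swd
  labels <- c(rep(0L, cf$n_spared_swd), rep(1L, cf$n_impaired_swd))
  ord <- sample(n_tot)
  labels <- labels[ord]

  if (cf$class_purity && cf$n_spared_swd > 0L && cf$n_impaired_swd > 0L) {
    n_imp_pat <- max(1L, min(cf$n_patients - 1L,
      round(cf$n_patients * cf$n_impaired_swd / n_tot)))
    pat_class <- c(rep(0L, cf$n_patients - n_imp_pat), rep(1L, n_imp_pat))
    patient <- integer(n_tot)
    for (cl in 0:1) {
      idx <- which(labels == cl); pats <- which(pat_class == cl)
      patient[idx] <- pats[(seq_along(idx) - 1L) %% length(pats) + 1L]
    }
  } else {
    patient <- (seq_len(n_tot) - 1L) %% cf$n_patients + 1L
  }

  dur_ms <- numeric(n_tot)
  dur_ms[labels == 0L] <- .rdur(sum(labels == 0L), cf$duration_ms_spared)
  dur_ms[labels == 1L] <- .rdur(sum(labels == 1L), cf$duration_ms_impaired)
  freq <- pmin(pmax(cf$swd_freq_hz * stats::runif(n_tot, 0.95, 1.05), 2.5), 5)
  amp <- ifelse(labels == 0L, cf$amplitude_uv_spared, cf$amplitude_uv_impaired)
  phase <- stats::runif(n_tot, 0, 2 * pi)

  pat_ids <- sprintf("P%02d", seq_len(cf$n_patients))
  recordings <- vector("list", cf$n_patients)
  ev_rows <- vector("list", n_tot)
  topo <- list(`0` = cf$topography_weights, `1` = cf$topography_weights_impaired)
  post_w <- .default_topography(cf$channels, anterior = FALSE)

  for (p in seq_len(cf$n_patients)) {
    mine <- which(patient == p)
    pos <- cf$gap_s
    onsets <- numeric(length(mine))
    for (j in seq_along(mine)) {
      onsets[j] <- pos
      pos <- pos + dur_ms[mine[j]] / 1000 + cf$gap_s
    }
    total_s <- if (is.null(cf$recording_duration_s)) pos else cf$recording_duration_s
    if (pos > total_s + 1e-9)
      stop("patient ", pat_ids[p], ": total SWD time (", round(pos, 1),
           " s) exceeds recording length (", total_s, " s)")
    n_samp <- ceiling(total_s * fs)
    t_grid <- (0:(n_samp - 1)) / fs
    x <- matrix(0, cf$n_channels, n_samp)
    for (ch in seq_len(cf$n_channels))
      x[ch, ] <- cf$background_noise_uv * .pink_noise(n_samp, fs)
    # posterior alpha with a slow amplitude envelope
    alpha_env <- 1 + 0.5 * sin(2 * pi * 0.2 * t_grid + stats::runif(1, 0, 2 * pi))
    alpha_sig <- cf$alpha_uv * alpha_env * sin(2 * pi * 10 * t_grid +
                                               stats::runif(1, 0, 2 * pi))
    x <- x + outer(post_w, alpha_sig)

    for (j in seq_along(mine)) {
      i <- mine[j]
      on_s <- onsets[j]; off_s <- on_s + dur_ms[i] / 1000
      idx <- which(t_grid >= on_s & t_grid < off_s)
      wf <- .swd_waveform(t_grid[idx] - on_s, freq[i], amp[i], phase[i], fs)
      x[, idx] <- x[, idx] + outer(topo[[as.character(labels[i])]], wf)
      # preictal delta component over the 2 s before onset
      pidx <- which(t_grid >= on_s - 2 & t_grid < on_s)
      dfreq <- stats::runif(1, 1.5, 3.5)
      damp <- cf$preictal_delta_uv *
        (if (labels[i] == 1L) cf$preictal_delta_gain_impaired else 1)
      denv <- sin(pi * seq_along(pidx) / length(pidx))^2  # smooth on/off
      x[, pidx] <- x[, pidx] + outer(
        topo[[as.character(labels[i])]],
        damp * denv * sin(2 * pi * dfreq * (t_grid[pidx] - on_s) +
                          stats::runif(1, 0, 2 * pi)))
      ev_rows[[i]] <- data.frame(patient_id = pat_ids[p],
                                 swd_id = sprintf("swd%03d", i),
                                 onset_s = on_s, offset_s = off_s,
                                 label = labels[i],
                                 stringsAsFactors = FALSE)
    }
    recordings[[p]] <- swd_recording(x, fs, cf$channels,
                                     reference = "common_average",
                                     patient_id = pat_ids[p])
  }
  events <- do.call(rbind, ev_rows)
  rownames(events) <- NULL
  list(recordings = recordings, events = events)
}

#' Per-class contrasts of the generated cohort
#'
#' Computes, per event, the SWD duration, the ictal wave-band power and
#' the preictal delta power, and returns class means with rank-sum
#' p-values — the three contrasts the generator is built to reproduce
#' (impaired > spared under the default configuration).
#'
#' @param recordings,events a generated cohort (labels required).
#' @param windows a \code{\link{window_config}}.
#' @return data.frame with one row per measure: spared/impaired means and
#'   rank-sum p.
#' @export
summarize_contrasts <- function(recordings, events, windows = window_config()) {
  if (anyNA(events$label)) stop("summarize_contrasts requires labeled events")
  if (min(table(events$label)) < 5L)
    stop("need at least 5 events per class")
  ew <- extract_all_windows(recordings, events, windows)
  fs <- recordings[[1]]$rate_hz
  mp <- function(win, band) {
    mean(apply(win, 1, function(ch) {
      sp <- welch_psd(ch, fs); .band_power(sp, band[1], band[2])
    }))
  }
  vals <- t(vapply(ew$pairs, function(wp) c(
    duration_ms = (wp$event$offset_s - wp$event$onset_s) * 1000,
    wave_power = mp(wp$ictal, c(2.5, 6)),
    preictal_delta = mp(wp$preictal, c(1, 4))), numeric(3)))
  lab <- ew$events$label
  out <- lapply(colnames(vals), function(m) {
    data.frame(measure = m,
               mean_spared = mean(vals[lab == 0L, m]),
               mean_impaired = mean(vals[lab == 1L, m]),
               p_value = rank_sum_test(vals[lab == 0L, m], vals[lab == 1L, m]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a cohort to disk as EDF + annotation CSV
#'
#' One EDF file per patient (\code{<patient_id>.edf}) and a single
#' \code{annotations.csv} with columns
#' \code{patient_id, swd_id, onset_s, offset_s, label}, the format
#' \code{\link{read_recording}} consumes.
#'
#' @param recordings,events a cohort as from \code{\link{generate_dataset}}.
#' @param dir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_dataset <- function(recordings, events, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edf <- vapply(recordings, function(r) {
    path <- file.path(dir, paste0(r$patient_id, ".edf"))
    write_edf(r, path)
    path
  }, "")
  csv <- file.path(dir, "annotations.csv")
  utils::write.csv(events, csv, row.names = FALSE)
  invisible(list(edf = edf, annotations = csv))
}
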