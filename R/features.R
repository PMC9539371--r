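# Time- and frequency-domain features of preictal/ictal EEG windows.
#
# All scalar features are computed per channel and averaged across channels
# (one value per window), matching how clinical feature tables report them.
# Per-channel values are available via aggregate = FALSE.

# Canonical EEG bands (Hz, half-open [lo, hi)). The spike/wave bands
# decompose the spike-wave complex: the 2.5-6 Hz wave captures the
# fundamental, 15-50 Hz the sharp transient's energy.
.bands <- function(fs) {
  ny <- fs / 2
  list(
    wave  = c(2.5, 6),
    spike = c(15, min(50, ny - 1)),
    delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30),
    low_gamma = c(30, min(50, ny - 1)),
    high_gamma = c(50, min(100, ny - 1)))
}

#' Welch power spectral density
#'
#' Hamming-windowed averaged periodogram with 50\% overlap, one-sided,
#' normalized so that \code{sum(psd) * df} equals the mean power of the
#' detrended signal.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param nseg segment length (default \code{min(length(x), 256)}).
#' @return \code{list(freq, psd)}; \code{freq} in Hz.
#' @export
welch_psd <- function(x, fs, nseg = min(length(x), 256L)) {
  n <- length(x)
  nseg <- min(nseg, n)
  step <- max(1L, floor(nseg / 2))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))
  if (nseg == 1L) w <- 1
  u <- sum(w^2)
  nf <- floor(nseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[1:nf])^2 / (fs * u)
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nseg even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / nseg, psd = psd * dbl)
}

# integrate a PSD over [lo, hi): mean power (uV^2) in the band
.band_power <- function(spec, lo, hi) {
  df <- spec$freq[2] - spec$freq[1]
  sel <- spec$freq >= lo & spec$freq < hi
  sum(spec$psd[sel]) * df
}

#' Hjorth parameters of a signal
#'
#' Activity is the variance; mobility is
#' \code{sqrt(var(diff(x)) / var(x))} with the per-sample first difference;
#' complexity is the mobility of the derivative over the mobility of the
#' signal. A constant signal has mobility and complexity 0 by convention.
#'
#' @param x numeric vector.
#' @return Named numeric: activity, mobility, complexity.
#' @export
hjorth_params <- function(x) {
  v0 <- stats::var(x)
  if (!is.finite(v0) || v0 <= 0)
    return(c(activity = if (is.finite(v0)) v0 else 0, mobility = 0, complexity = 0))
  d1 <- diff(x); d2 <- diff(d1)
  v1 <- stats::var(d1)
  mob <- sqrt(v1 / v0)
  comp <- if (v1 > 0) sqrt(stats::var(d2) / v1) / mob else 0
  c(activity = v0, mobility = mob, complexity = comp)
}

#' Permutation entropy of a time series
#'
#' Shannon entropy (nats) of the distribution of ordinal patterns of
#' \code{order} consecutive values (delay \code{tau}). Ties are broken by
#' position. A strictly monotone series realizes a single pattern and has
#' entropy 0; iid noise approaches \code{log(factorial(order))}.
#'
#' @param x numeric vector, length > order * tau.
#' @param order pattern length (embedding dimension), default 4.
#' @param tau delay, default 1.
#' @return Entropy in nats.
#' @export
permutation_entropy <- function(x, order = 4L, tau = 1L) {
  n <- length(x) - (order - 1L) * tau
  if (n < 1L) stop("series too short for order ", order, " / delay ", tau)
  emb <- sapply(seq_len(order), function(j) x[(1:n) + (j - 1L) * tau])
  if (n == 1L) emb <- matrix(emb, nrow = 1)
  codes <- apply(emb, 1, function(r) paste(order(r), collapse = ""))
  p <- table(codes) / n
  -sum(p * log(p))
}

#' Multiscale permutation entropy
#'
#' Mean over time scales of the permutation entropy of the coarse-grained
#' series (non-overlapping window averaging at each scale).
#'
#' @param x numeric vector.
#' @param order,tau see \code{\link{permutation_entropy}}.
#' @param scales integer vector of coarse-graining factors, default 1:3.
#' @return Mean entropy in nats.
#' @export
multiscale_permutation_entropy <- function(x, order = 4L, tau = 1L,
                                           scales = 1:3) {
  vals <- vapply(scales, function(s) {
    m <- floor(length(x) / s)
    cg <- if (s == 1L) x[seq_len(m)] else
      colMeans(matrix(x[seq_len(m * s)], nrow = s))
    permutation_entropy(cg, order, tau)
  }, 0)
  mean(vals)
}

.moments <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(c(mean = m, var = 0, skew = 0, kurt = 0))
  c(mean = m, var = s2 * length(x) / max(1, length(x) - 1),
    skew = mean((x - m)^3) / s2^1.5,
    kurt = mean((x - m)^4) / s2^2)   # non-excess: Gaussian -> 3
}

.extended_one_channel <- function(x, fs, pe_order, pe_scales) {
  bp <- .bands(fs)
  spec <- welch_psd(x, fs)
  pows <- vapply(bp, function(b) .band_power(spec, b[1], b[2]), 0)
  hj <- hjorth_params(x)
  vm <- .moments(x)
  pm <- .moments(x^2)
  pe <- if (stats::var(x) > 0)
    multiscale_permutation_entropy(x, order = pe_order, scales = pe_scales)
  else 0
  c(spike_power = unname(pows["spike"]), wave_power = unname(pows["wave"]),
    hjorth_activity = unname(hj["activity"]),
    hjorth_mobility = unname(hj["mobility"]),
    hjorth_complexity = unname(hj["complexity"]),
    mean_vrms = sqrt(mean(x^2)),
    delta_power = unname(pows["delta"]), theta_power = unname(pows["theta"]),
    alpha_power = unname(pows["alpha"]), beta_power = unname(pows["beta"]),
    low_gamma_power = unname(pows["low_gamma"]),
    high_gamma_power = unname(pows["high_gamma"]),
    volt_mean = unname(vm["mean"]), volt_var = unname(vm["var"]),
    volt_skew = unname(vm["skew"]), volt_kurt = unname(vm["kurt"]),
    power_mean = unname(pm["mean"]), power_var = unname(pm["var"]),
    power_skew = unname(pm["skew"]), power_kurt = unname(pm["kurt"]),
    mpe = pe)
}

.basic_names <- c("spike_power", "wave_power")

#' Extended feature set of one window
#'
#' Computes, per channel and averaged across channels: spike- and wave-band
#' power, the three Hjorth parameters, root-mean-square amplitude, six
#' canonical band powers (delta through high gamma), the first four moments
#' of the voltage and of the instantaneous power \code{x(t)^2} (kurtosis
#' non-excess), and multiscale permutation entropy. The ictal vector also
#' carries the SWD duration in ms.
#'
#' @param window channels x samples matrix (one window).
#' @param fs sampling rate, Hz.
#' @param rate_hz synonym kept for clarity in pipelines.
#' @param duration_ms if non-NULL, appended as feature \code{duration_ms}.
#' @param aggregate average across channels (default). If FALSE, returns a
#'   channels x features matrix.
#' @param pe_order,pe_scales permutation-entropy parameters.
#' @return Named numeric vector (or matrix when \code{aggregate = FALSE}).
#' @export
window_features <- function(window, fs, duration_ms = NULL, aggregate = TRUE,
                            pe_order = 4L, pe_scales = 1:3, rate_hz = NULL) {
  if (!is.null(rate_hz)) fs <- rate_hz
  window <- as.matrix(window)
  if (ncol(window) < 26L)
    stop("window too short (", ncol(window), " samples) for entropy order ",
         pe_order, " at scale ", max(pe_scales))
  per_ch <- t(apply(window, 1, .extended_one_channel, fs = fs,
                    pe_order = pe_order, pe_scales = pe_scales))
  out <- if (aggregate) colMeans(per_ch) else per_ch
  if (!is.null(duration_ms)) {
    if (aggregate) out <- c(out, duration_ms = duration_ms)
    else out <- cbind(out, duration_ms = duration_ms)
  }
  out
}

#' Basic features of a window pair
#'
#' The minimal clinically interpretable set: mean spike-band power
#' (15-50 Hz) and wave-band power (2.5-6 Hz) of each window, both averaged
#' across channels, plus the SWD duration in milliseconds attached to the
#' ictal vector only.
#'
#' @param wp a \code{window_pair} from \code{\link{extract_windows}}.
#' @param fs sampling rate, Hz.
#' @return \code{list(preictal, ictal)} of named numeric vectors.
#' @export
basic_features <- function(wp, fs) {
  ef <- extended_features(wp, fs)
  list(preictal = ef$preictal[.basic_names],
       ictal = ef$ictal[c(.basic_names, "duration_ms")])
}

#' Extended features of a window pair
#'
#' Applies \code{\link{window_features}} to both windows; the basic features
#' are a subset of these computations.
#'
#' @inheritParams basic_features
#' @param ... passed to \code{\link{window_features}}.
#' @return \code{list(preictal, ictal)} of named numeric vectors; the ictal
#'   vector includes \code{duration_ms}.
#' @export
extended_features <- function(wp, fs, ...) {
  dur <- (wp$event$offset_s - wp$event$onset_s) * 1000
  list(preictal = window_features(wp$preictal, fs, ...),
       ictal = window_features(wp$ictal, fs, duration_ms = dur, ...))
}
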