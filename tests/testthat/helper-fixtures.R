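# Shared fixtures, built in code once per test run.

# small labeled cohort: 6 patients, 18 spared / 12 impaired SWDs
tiny_cohort <- local({
  cfg <- synth_config(n_patients = 6, n_spared_swd = 18, n_impaired_swd = 12,
                      seed = 42)
  generate_dataset(cfg)
})

tiny_data <- prepare_swd_data(tiny_cohort$recordings, tiny_cohort$events)

# a plain sinusoidal multichannel recording with one annotated event
sine_recording <- function(freq = 3.5, fs = 256, dur_s = 30, n_ch = 4,
                           amp = 1, patient_id = "S01") {
  t <- (0:(dur_s * fs - 1)) / fs
  x <- matrix(amp * sin(2 * pi * freq * t), n_ch, length(t), byrow = TRUE)
  swd_recording(x, fs, paste0("ch", seq_len(n_ch)), patient_id = patient_id)
}

# deterministic 2-channel epochs whose population covariance is exactly
# diag(c1, c2): orthogonal +-1 carriers scaled per channel
diag_epoch <- function(c1, c2, n = 64) {
  z1 <- rep(c(1, 1, -1, -1), n / 4)
  z2 <- rep(c(1, -1), n / 2)
  rbind(sqrt(c1) * z1, sqrt(c2) * z2)
}

# independent whiten-then-diagonalize CSP oracle (two-step construction)
csp_oracle <- function(epochs_s, epochs_i, k) {
  cov1 <- function(x) { x <- x - rowMeans(x); C <- tcrossprod(x) / ncol(x); C / sum(diag(C)) }
  C_s <- Reduce(`+`, lapply(epochs_s, cov1)) / length(epochs_s)
  C_i <- Reduce(`+`, lapply(epochs_i, cov1)) / length(epochs_i)
  C_c <- C_s + C_i
  ec <- eigen(C_c, symmetric = TRUE)
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)      # whitener
  es <- eigen(P %*% C_i %*% t(P), symmetric = TRUE)
  W <- t(es$vectors) %*% P                              # filters in rows
  lam <- es$values
  ord <- order(pmax(lam, 1 - lam), decreasing = TRUE)[seq_len(k)]
  list(filters = W[ord, , drop = FALSE], eigenvalues = lam[ord])
}

# brute-force two-sided rank-sum p by subset enumeration
ranksum_enum_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  subs <- utils::combn(n, nx)
  ws <- apply(subs, 2, function(i) sum(r[i]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
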