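# Common spatial patterns: supervised spatial filters maximizing the
# variance ratio between the impaired and spared classes.

.epoch_cov <- function(x) {
  x <- x - rowMeans(x)
  C <- tcrossprod(x) / ncol(x)
  C / sum(diag(C))
}

#' Fit common spatial pattern filters
#'
#' Per-epoch spatial covariances are trace-normalized and averaged within
#' each class, giving \code{C_s} (spared) and \code{C_i} (impaired). The
#' filters solve the generalized eigenproblem
#' \code{C_i w = lambda (C_s + C_i) w}; each eigenvalue \code{lambda} in
#' [0, 1] is the share of composite variance carried by the impaired class
#' along its filter. The \code{k} filters with the largest discriminability
#' \code{max(lambda, 1 - lambda)} are kept (an odd \code{k} is allowed),
#' each normalized so that \code{w' (C_s + C_i) w = 1}; jointly the kept
#' filters whiten the composite covariance.
#'
#' A rank-deficient composite covariance is regularized by adding
#' \code{1e-8 * trace/channels} to the diagonal, with a warning.
#'
#' @param epochs_spared,epochs_impaired lists of channels x samples
#'   matrices (at least 2 per class, equal channel counts).
#' @param k number of filters to keep (<= channels); default 5.
#' @param window_tag "preictal" or "ictal", carried for bookkeeping.
#' @param channel_names optional channel labels.
#' @return Object of class \code{"csp_model"}: \code{filters} (k x channels,
#'   one filter per row), \code{eigenvalues} (impaired variance share, in
#'   decreasing discriminability order), \code{window_tag},
#'   \code{channel_names}.
#' @export
fit_csp <- function(epochs_spared, epochs_impaired, k = 5L,
                    window_tag = "ictal", channel_names = NULL) {
  if (length(epochs_spared) < 2L || length(epochs_impaired) < 2L)
    stop("need at least 2 epochs per class")
  nch <- nrow(epochs_spared[[1]])
  all_ep <- c(epochs_spared, epochs_impaired)
  if (any(vapply(all_ep, nrow, 0L) != nch))
    stop("epochs disagree on channel count")
  if (k > nch) stop("k (", k, ") exceeds channel count (", nch, ")")
  C_s <- Reduce(`+`, lapply(epochs_spared, .epoch_cov)) / length(epochs_spared)
  C_i <- Reduce(`+`, lapply(epochs_impaired, .epoch_cov)) / length(epochs_impaired)
  C_c <- C_s + C_i
  ev_c <- eigen(C_c, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_c) < 1e-10 * max(ev_c)) {
    warning("rank-deficient composite covariance; regularizing diagonal")
    C_c <- C_c + diag(1e-8 * sum(diag(C_c)) / nch, nch)
  }
  # generalized eigensolve C_i w = lambda C_c w
  eg <- eigen(solve(C_c, C_i))
  W <- Re(eg$vectors); lam <- Re(eg$values)
  # normalize in the composite metric: w' C_c w = 1
  nrm <- sqrt(colSums(W * (C_c %*% W)))
  W <- sweep(W, 2, nrm, "/")
  lam <- pmin(pmax(lam, 0), 1)
  ord <- order(pmax(lam, 1 - lam), decreasing = TRUE)[seq_len(k)]
  if (is.null(channel_names)) channel_names <- rownames(epochs_spared[[1]])
  structure(list(filters = t(W[, ord, drop = FALSE]),
                 eigenvalues = lam[ord],
                 window_tag = window_tag,
                 channel_names = channel_names),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d filters x %d channels (%s window)\n",
              nrow(x$filters), ncol(x$filters), x$window_tag))
  cat("  impaired variance share per filter:",
      paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n")
  invisible(x)
}

#' Plot CSP eigenvalue spectrum
#'
#' Barplot of each filter's impaired-class variance share; 0.5 means no
#' discrimination along that filter.
#'
#' @param x a \code{csp_model}.
#' @param ... passed to \code{barplot}.
#' @export
plot.csp_model <- function(x, ...) {
  graphics::barplot(x$eigenvalues, names.arg = seq_along(x$eigenvalues),
                    ylim = c(0, 1), xlab = "filter",
                    ylab = "impaired variance share", ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Normalized log-variance CSP features of a window
#'
#' Projects a window onto the model's filters and returns
#' \code{log(var_j / sum(var_j'))} per filter: the log share of projected
#' variance, invariant to overall window scaling. With a single filter the
#' feature is identically 0.
#'
#' @param model a \code{\link{fit_csp}} model.
#' @param window channels x samples matrix.
#' @return Named numeric vector \code{csp1..cspk}.
#' @export
csp_features <- function(model, window) {
  window <- as.matrix(window)
  if (nrow(window) != ncol(model$filters))
    stop("window has ", nrow(window), " channels; model expects ",
         ncol(model$filters))
  proj <- model$filters %*% (window - rowMeans(window))
  v <- apply(proj, 1, stats::var)
  tot <- sum(v)
  if (tot <= 0) stop("all filter projections have zero variance (degenerate input)")
  stats::setNames(log(v / tot), paste0("csp", seq_along(v)))
}

#' Export CSP filters as a tidy table
#'
#' One row per (filter, channel) weight with the filter's eigenvalue, for
#' topographic inspection; optionally written to CSV.
#'
#' @param model a \code{csp_model}.
#' @param path optional CSV path.
#' @return data.frame with columns channel, filter_index, weight,
#'   eigenvalue, window.
#' @export
export_filters <- function(model, path = NULL) {
  k <- nrow(model$filters); nch <- ncol(model$filters)
  ch <- model$channel_names
  if (is.null(ch)) ch <- paste0("ch", seq_len(nch))
  out <- data.frame(
    channel = rep(ch, times = k),
    filter_index = rep(seq_len(k), each = nch),
    weight = as.vector(t(model$filters)),
    eigenvalue = rep(model$eigenvalues, each = nch),
    window = model$window_tag,
    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
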