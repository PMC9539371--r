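# Scalar scoring of feature vectors: Fisher linear discriminant or linear
# SVM, both oriented so that larger scores mean more impaired.

#' Train a scalar scorer on labeled features
#'
#' Features are z-scored with training statistics (zero-variance columns
#' dropped with a warning). \code{"LDA"} fits the Fisher linear discriminant
#' with a pseudo-inverse of the pooled covariance, so duplicated or
#' collinear columns degrade gracefully; the score is
#' \code{(x - midpoint)' w}. \code{"SVM"} fits a linear support vector
#' machine (cost 1) and scores by the signed decision value. Either way the
#' score is oriented so that larger means more impaired.
#'
#' @param X numeric matrix, events x features, named columns.
#' @param y 0/1 labels (0 spared, 1 impaired), both classes present.
#' @param kind \code{"LDA"} or \code{"SVM"}.
#' @param cost SVM cost parameter.
#' @return Object of class \code{"swd_scorer"}.
#' @export
train_scorer <- function(X, y, kind = c("LDA", "SVM"), cost = 1) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes required to train a scorer")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  keep <- sd_ > 0
  if (!all(keep))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  if (!any(keep)) stop("no non-constant features left")
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], "/")

  obj <- list(kind = kind, feature_names = colnames(X), keep = keep,
              center = mu, scale = sd_)
  if (kind == "LDA") {
    m0 <- colMeans(Z[y == 0L, , drop = FALSE])
    m1 <- colMeans(Z[y == 1L, , drop = FALSE])
    n0 <- sum(y == 0L); n1 <- sum(y == 1L)
    S0 <- stats::cov(Z[y == 0L, , drop = FALSE])
    S1 <- stats::cov(Z[y == 1L, , drop = FALSE])
    Sp <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
    w <- MASS::ginv(Sp) %*% (m1 - m0)
    obj$w <- drop(w)
    obj$midpoint <- (m0 + m1) / 2
  } else {
    fit <- e1071::svm(Z, factor(y, levels = c(0L, 1L)), kernel = "linear",
                      cost = cost, scale = FALSE, probability = FALSE)
    dec <- drop(attr(stats::predict(fit, Z, decision.values = TRUE),
                     "decision.values"))
    obj$flip <- mean(dec[y == 1L]) < mean(dec[y == 0L])
    obj$fit <- fit
  }
  class(obj) <- "swd_scorer"
  obj
}

#' @export
print.swd_scorer <- function(x, ...) {
  cat(sprintf("<swd_scorer> %s on %d feature(s)\n", x$kind, sum(x$keep)))
  invisible(x)
}

#' Score feature vectors with a trained scorer
#'
#' @param object an \code{swd_scorer}.
#' @param newdata events x features matrix with the training columns.
#' @param ... unused.
#' @return Numeric scores (larger = more impaired).
#' @export
predict.swd_scorer <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(object$feature_names))
      stop("feature count mismatch: got ", ncol(X), ", expected ",
           length(object$feature_names))
    colnames(X) <- object$feature_names
  }
  miss <- setdiff(object$feature_names, colnames(X))
  if (length(miss))
    stop("missing feature(s) at prediction time: ", paste(miss, collapse = ", "))
  X <- X[, object$feature_names, drop = FALSE]
  keep <- object$keep
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, object$center[keep]), 2,
             object$scale[keep], "/")
  if (object$kind == "LDA") {
    drop(sweep(Z, 2, object$midpoint) %*% object$w)
  } else {
    dec <- drop(attr(stats::predict(object$fit, Z, decision.values = TRUE),
                     "decision.values"))
    if (object$flip) -dec else dec
  }
}

#' Linear weights of a scorer
#'
#' @param object an \code{swd_scorer}.
#' @param ... unused.
#' @return Named weight vector on the standardized feature scale (SVM:
#'   primal weights of the linear machine).
#' @export
coef.swd_scorer <- function(object, ...) {
  nm <- object$feature_names[object$keep]
  if (object$kind == "LDA") return(stats::setNames(object$w, nm))
  w <- drop(crossprod(object$fit$coefs, object$fit$SV))
  if (object$flip) w <- -w
  stats::setNames(w, nm)
}
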