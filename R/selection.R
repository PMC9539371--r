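# Univariate feature selection by the Wilcoxon rank-sum test.

#' Selection configuration
#'
#' @param p_threshold significance level for keeping a feature
#'   (default 0.001, the level at which spared predictive value peaks).
#' @param scope \code{"per_fold"} (selection re-run inside each training
#'   fold; the leakage-free default) or \code{"global"} (selection on the
#'   whole labeled set before cross-validation).
#' @return Object of class \code{"selection_config"}.
#' @export
selection_config <- function(p_threshold = 0.001,
                             scope = c("per_fold", "global")) {
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must lie in (0, 1)")
  structure(list(p_threshold = p_threshold, scope = match.arg(scope)),
            class = "selection_config")
}

# exact null distribution of the rank-sum of the x-sample:
# dynamic program over subsets, using doubled midranks so ties stay integer.
.ranksum_exact_p <- function(r2x_sum, r2, nx) {
  n <- length(r2)
  # dist[[j]] = table over achievable sums using j chosen ranks
  max_sum <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
  counts <- matrix(0, nrow = nx + 1L, ncol = max_sum + 1L)
  counts[1L, 1L] <- 1
  for (v in r2) {
    for (j in rev(seq_len(nx))) {
      nz <- which(counts[j, ] > 0)
      tgt <- nz + v
      ok <- tgt <= max_sum + 1L
      counts[j + 1L, tgt[ok]] <- counts[j + 1L, tgt[ok]] + counts[j, nz[ok]]
    }
  }
  dist <- counts[nx + 1L, ]
  total <- sum(dist)
  sums <- which(dist > 0) - 1L
  mu <- nx * sum(r2) / n
  dev <- abs(r2x_sum - mu)
  p <- sum(dist[sums + 1L][abs(sums - mu) >= dev - 1e-9]) / total
  min(1, p)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares two independent samples by the Mann-Whitney/rank-sum statistic.
#' For combined sample sizes up to 12 with no ties, the p-value comes from
#' exact enumeration of the rank-sum null distribution (two-sided as the
#' probability of a rank sum at least as far from its mean as observed);
#' larger or tied samples use the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric vectors, each non-empty, jointly at least 4 values.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (n < 4L) stop("need at least 4 values in total")
  r <- rank(c(x, y))          # midranks
  w <- sum(r[seq_len(nx)])
  ties <- any(duplicated(c(x, y)))
  if (n <= 12L && !ties) {
    r2 <- as.integer(round(2 * r))
    return(.ranksum_exact_p(as.integer(round(2 * w)), r2, nx))
  }
  mu <- nx * (n + 1) / 2
  tie_tab <- table(r)
  sig2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sig2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sig2)   # continuity correction
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

#' Select features by class-wise rank-sum tests
#'
#' Tests every (non-CSP) feature column for a spared-vs-impaired location
#' difference and keeps those with \code{p < p_threshold}. CSP features
#' (columns named \code{csp*}) bypass the test: they are already limited by
#' the filter count and always pass through.
#'
#' @param feature_matrix numeric matrix, events in rows, named feature
#'   columns.
#' @param labels 0/1 vector (0 spared, 1 impaired), both classes present.
#' @param cfg a \code{\link{selection_config}}.
#' @return \code{list(mask = named logical, p_table = data.frame(feature,
#'   mean_spared, mean_impaired, p_value, selected))}.
#' @export
select_features <- function(feature_matrix, labels, cfg = selection_config()) {
  feature_matrix <- as.matrix(feature_matrix)
  labels <- as.integer(labels)
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("both classes must be present for selection")
  is_csp <- grepl("^csp[0-9]+$", colnames(feature_matrix))
  p <- rep(NA_real_, ncol(feature_matrix))
  for (j in which(!is_csp)) {
    p[j] <- rank_sum_test(feature_matrix[labels == 0L, j],
                          feature_matrix[labels == 1L, j])
  }
  mask <- is_csp | (!is.na(p) & p < cfg$p_threshold)
  names(mask) <- colnames(feature_matrix)
  tab <- data.frame(
    feature = colnames(feature_matrix),
    mean_spared = colMeans(feature_matrix[labels == 0L, , drop = FALSE]),
    mean_impaired = colMeans(feature_matrix[labels == 1L, , drop = FALSE]),
    p_value = p, selected = mask, row.names = NULL,
    stringsAsFactors = FALSE)
  list(mask = mask, p_table = tab)
}
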