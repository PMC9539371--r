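# The central fitting routine: feature assembly, selection, CSP, scoring,
# fusion and conservative calibration behind one classed model object.

#' Model configuration
#'
#' One cell of the model grid: a feature set, a window strategy and a
#' classifier. The full cross product is 4 x 4 x 2 = 32 configurations
#' (\code{\link{build_model_grid}}).
#'
#' @param feature_set \code{"basic"}, \code{"extended"}, \code{"csp"} or
#'   \code{"all"}.
#' @param window_strategy \code{"preictal"}, \code{"ictal"},
#'   \code{"concatenation"} or \code{"fusion"}.
#' @param classifier \code{"LDA"} or \code{"SVM"}.
#' @return Object of class \code{"model_config"}.
#' @export
model_config <- function(feature_set = c("csp", "basic", "extended", "all"),
                         window_strategy = c("fusion", "preictal", "ictal",
                                             "concatenation"),
                         classifier = c("LDA", "SVM")) {
  structure(list(feature_set = match.arg(feature_set),
                 window_strategy = match.arg(window_strategy),
                 classifier = match.arg(classifier)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %s features | %s windows | %s\n",
              x$feature_set, x$window_strategy, x$classifier))
  invisible(x)
}

#' Prepare a dataset for model fitting
#'
#' Extracts preictal/ictal window pairs for every event and (optionally)
#' precomputes the extended feature matrices, which depend only on the data
#' and can safely be shared across cross-validation folds. CSP features and
#' feature selection are training-dependent and are always recomputed
#' inside \code{\link{fit_swd_model}}.
#'
#' @param recordings list of \code{\link{swd_recording}} (all at one rate).
#' @param events event table (\code{\link{swd_events}}).
#' @param windows a \code{\link{window_config}}.
#' @param extended compute the extended feature matrices now (default TRUE).
#' @param pe_order,pe_scales permutation-entropy parameters.
#' @return Object of class \code{"swd_data"}.
#' @export
prepare_swd_data <- function(recordings, events, windows = window_config(),
                             extended = TRUE, pe_order = 4L, pe_scales = 1:3) {
  rates <- unique(vapply(recordings, function(r) r$rate_hz, 0))
  if (length(rates) != 1L)
    stop("recordings must share one sampling rate (preprocess first); got ",
         paste(rates, collapse = ", "))
  ew <- extract_all_windows(recordings, events, windows)
  if (!length(ew$pairs)) stop("no events with valid windows")
  feats <- NULL
  if (extended) {
    fl <- lapply(ew$pairs, extended_features, fs = rates,
                 pe_order = pe_order, pe_scales = pe_scales)
    feats <- list(pre = do.call(rbind, lapply(fl, `[[`, "preictal")),
                  ict = do.call(rbind, lapply(fl, `[[`, "ictal")))
  }
  structure(list(pairs = ew$pairs, events = ew$events, skipped = ew$skipped,
                 features = feats, fs = rates, windows = windows),
            class = "swd_data")
}

#' @export
print.swd_data <- function(x, ...) {
  lab <- x$events$label
  cat(sprintf("<swd_data> %d events (%d spared / %d impaired / %d unlabeled) @ %g Hz; windows %g/%g ms\n",
              nrow(x$events), sum(lab == 0L, na.rm = TRUE),
              sum(lab == 1L, na.rm = TRUE), sum(is.na(lab)),
              x$fs, x$windows$pre_ms, x$windows$ict_ms))
  invisible(x)
}

#' @export
`[.swd_data` <- function(x, i, ...) {
  structure(list(pairs = x$pairs[i], events = x$events[i, , drop = FALSE],
                 skipped = x$skipped,
                 features = if (is.null(x$features)) NULL else
                   list(pre = x$features$pre[i, , drop = FALSE],
                        ict = x$features$ict[i, , drop = FALSE]),
                 fs = x$fs, windows = x$windows),
            class = "swd_data")
}

# feature matrices for one config; csp_models = list(pre=, ict=) or NULL
.design_matrices <- function(data, feature_set, csp_models = NULL) {
  base_cols <- c("spike_power", "wave_power")
  get_ext <- function() {
    if (is.null(data$features))
      stop("extended features not prepared; call prepare_swd_data(extended = TRUE)")
    data$features
  }
  csp_mat <- function(tag) {
    win <- if (tag == "pre") "preictal" else "ictal"
    do.call(rbind, lapply(data$pairs, function(wp)
      csp_features(csp_models[[tag]], wp[[win]])))
  }
  switch(feature_set,
    basic = {
      f <- get_ext()
      list(pre = f$pre[, base_cols, drop = FALSE],
           ict = f$ict[, c(base_cols, "duration_ms"), drop = FALSE])
    },
    extended = get_ext(),
    csp = list(pre = csp_mat("pre"), ict = csp_mat("ict")),
    all = {
      f <- get_ext()
      list(pre = cbind(f$pre, csp_mat("pre")),
           ict = cbind(f$ict, csp_mat("ict")))
    })
}

# selection with fallback: never return an empty design
.apply_selection <- function(X, labels, cfg, forced_mask = NULL) {
  if (!is.null(forced_mask)) {
    mask <- forced_mask[colnames(X)]
    return(list(mask = mask, p_table = NULL))
  }
  sel <- select_features(X, labels, cfg)
  if (!any(sel$mask)) {
    j <- which.min(sel$p_table$p_value)
    sel$mask[j] <- TRUE
    warning("no feature passed p < ", cfg$p_threshold,
            "; keeping best-ranked feature '", colnames(X)[j], "'")
  }
  sel
}

# fit the training-dependent scoring chain (CSP, selection, scorers) on
# one labeled slice; returns everything needed to score new events
.fit_scoring_chain <- function(data, config, selection, n_filters,
                               forced_masks = NULL) {
  labels <- as.integer(data$events$label)
  csp_models <- NULL
  if (config$feature_set %in% c("csp", "all")) {
    sp <- which(labels == 0L); im <- which(labels == 1L)
    csp_models <- list(
      pre = fit_csp(lapply(data$pairs[sp], `[[`, "preictal"),
                    lapply(data$pairs[im], `[[`, "preictal"),
                    k = n_filters, window_tag = "preictal",
                    channel_names = rownames(data$pairs[[1]]$preictal)),
      ict = fit_csp(lapply(data$pairs[sp], `[[`, "ictal"),
                    lapply(data$pairs[im], `[[`, "ictal"),
                    k = n_filters, window_tag = "ictal",
                    channel_names = rownames(data$pairs[[1]]$ictal)))
  }
  mats <- .design_matrices(data, config$feature_set, csp_models)
  sel_pre <- .apply_selection(mats$pre, labels, selection, forced_masks$pre)
  sel_ict <- .apply_selection(mats$ict, labels, selection, forced_masks$ict)
  Xp <- mats$pre[, sel_pre$mask, drop = FALSE]
  Xi <- mats$ict[, sel_ict$mask, drop = FALSE]
  chain <- list(csp = csp_models,
                masks = list(pre = sel_pre$mask, ict = sel_ict$mask),
                p_tables = list(pre = sel_pre$p_table, ict = sel_ict$p_table))
  if (config$window_strategy == "fusion") {
    chain$scorers <- list(pre = train_scorer(Xp, labels, config$classifier),
                          ict = train_scorer(Xi, labels, config$classifier))
  } else {
    X <- switch(config$window_strategy,
      preictal = Xp, ictal = Xi,
      concatenation = {
        colnames(Xp) <- paste0("pre_", colnames(Xp))
        colnames(Xi) <- paste0("ict_", colnames(Xi))
        cbind(Xp, Xi)
      })
    chain$scorers <- list(single = train_scorer(X, labels, config$classifier))
  }
  chain
}

# score events with a fitted chain; list(pre=, ict=) or list(single=)
.chain_scores <- function(chain, config, data) {
  mats <- .design_matrices(data, config$feature_set, chain$csp)
  Xp <- mats$pre[, chain$masks$pre, drop = FALSE]
  Xi <- mats$ict[, chain$masks$ict, drop = FALSE]
  if (config$window_strategy == "fusion") {
    list(pre = predict(chain$scorers$pre, Xp),
         ict = predict(chain$scorers$ict, Xi))
  } else {
    X <- switch(config$window_strategy,
      preictal = Xp, ictal = Xi,
      concatenation = {
        colnames(Xp) <- paste0("pre_", colnames(Xp))
        colnames(Xi) <- paste0("ict_", colnames(Xi))
        cbind(Xp, Xi)
      })
    list(single = predict(chain$scorers$single, X))
  }
}

#' Fit the SWD spared/impaired classification model
#'
#' The core fitting routine. Given prepared window data with behavioral
#' labels it (1) fits CSP filters per window when the feature set calls for
#' them, (2) assembles the configured feature matrices, (3) selects
#' features by rank-sum test (CSP features bypass selection), (4) trains
#' the configured scorer(s), (5) for the fusion strategy fits the weighted
#' Bayesian fusion model with its inner cross-validated alpha search, and
#' (6) calibrates the conservative decision threshold. After fitting, zero
#' false-spared on the training data is asserted.
#'
#' The fusion model and the threshold are calibrated on \emph{out-of-fold}
#' training scores: the whole scoring chain (CSP, selection, scorer) is
#' refit in an internal stratified 5-fold split so that every training
#' event is scored by a chain that never saw it. Calibrating on
#' resubstitution scores would inherit their optimistic separation and set
#' the safety threshold too permissively for unseen SWDs; out-of-fold
#' calibration keeps the zero-false-spared construction meaningful beyond
#' the training set. (With fewer than 3 events in a class the fit falls
#' back to resubstitution scores.)
#'
#' @param data an \code{\link{swd_data}} with labels on every event.
#' @param config a \code{\link{model_config}}.
#' @param selection a \code{\link{selection_config}}.
#' @param n_filters CSP filters per window (default 5; with the default the
#'   CSP feature vector over both windows is 10-dimensional).
#' @param alpha_grid candidate preictal fusion weights.
#' @param margin conservative threshold margin: a non-negative number, or
#'   \code{"auto"} (default) for a data-driven margin equal to the larger
#'   of (a) half the separating gap between the highest spared and lowest
#'   impaired calibration score, and (b) the spacing between the lowest
#'   and third-lowest impaired calibration scores. The sample minimum of
#'   the impaired scores overestimates the population lower tail, so the
#'   bare min-score rule parks the threshold at the impaired edge of the
#'   class gap and an unseen impaired event just below it is admitted;
#'   (a) moves the threshold to the max-margin midpoint of the gap
#'   (which never sacrifices a calibration spared call), while (b)
#'   extrapolates one order-statistic spacing down the impaired tail.
#' @param seed RNG seed for the inner fusion folds.
#' @param forced_masks optional named list \code{list(pre=, ict=)} of
#'   logical masks, used by global-scope selection in cross-validation.
#' @return Object of class \code{"swd_model"}.
#' @export
fit_swd_model <- function(data, config = model_config(),
                          selection = selection_config(),
                          n_filters = 5L,
                          alpha_grid = seq(0, 1, by = 0.01),
                          margin = "auto", cal_repeats = 3L, seed = 1L,
                          forced_masks = NULL) {
  stopifnot(inherits(data, "swd_data"))
  labels <- as.integer(data$events$label)
  if (anyNA(labels)) stop("all training events must be labeled")
  if (length(unique(labels)) < 2L) stop("both classes required for fitting")

  chain <- .fit_scoring_chain(data, config, selection, n_filters, forced_masks)

  # out-of-fold calibration scores: refit the chain with each internal
  # fold held out, so calibration never sees resubstitution optimism.
  # Repeating over several fold assignments and pooling gives a fuller
  # picture of the lower tail of the impaired generalization scores, which
  # is exactly what the min-score threshold keys on.
  k_cal <- min(5L, min(table(labels)))
  cal_labels <- labels
  if (k_cal >= 3L) {
    cal_scores <- list()
    for (rep_i in seq_len(cal_repeats)) {
      folds <- make_stratified_folds(labels, k = k_cal,
                                     seed = seed + 1000L * (rep_i - 1L))
      rep_sc <- list()
      for (f in sort(unique(folds))) {
        tr <- which(folds != f); te <- which(folds == f)
        ch_f <- suppressWarnings(
          .fit_scoring_chain(data[tr], config, selection, n_filters, forced_masks))
        sc <- .chain_scores(ch_f, config, data[te])
        for (nm in names(sc)) {
          if (is.null(rep_sc[[nm]])) rep_sc[[nm]] <- numeric(length(labels))
          rep_sc[[nm]][te] <- sc[[nm]]
        }
      }
      for (nm in names(rep_sc))
        cal_scores[[nm]] <- c(cal_scores[[nm]], rep_sc[[nm]])
    }
    cal_labels <- rep(labels, cal_repeats)
  } else {
    cal_scores <- .chain_scores(chain, config, data)
  }

  obj <- c(chain,
           list(config = config, selection = selection,
                n_filters = n_filters, margin = margin,
                windows = data$windows, n_train = length(labels),
                train_prevalence = mean(labels == 0L)))

  full_scores <- .chain_scores(chain, config, data)
  if (config$window_strategy == "fusion") {
    obj$fusion <- fit_fusion(cal_scores$pre, cal_scores$ict, cal_labels,
                             alpha_grid = alpha_grid, margin = 0,
                             seed = seed)
    fused_cal <- fuse_scores(obj$fusion, cal_scores$pre, cal_scores$ict)
    fused_full <- fuse_scores(obj$fusion, full_scores$pre, full_scores$ict)
  } else {
    fused_cal <- cal_scores$single
    fused_full <- full_scores$single
  }
  if (identical(margin, "auto") || identical(margin, "tail")) {
    t_imp <- sort(fused_cal[cal_labels == 1L])
    spacing <- t_imp[min(3L, length(t_imp))] - t_imp[1]
    half_gap <- max(0, (t_imp[1] - max(fused_cal[cal_labels == 0L])) / 2)
    margin <- if (identical(margin, "tail")) spacing else
      max(spacing, half_gap)
  }
  obj$margin <- margin
  # calibration pool: out-of-fold and resubstitution scores jointly, so the
  # zero-false-spared construction holds for both views of the training set
  obj$cal <- calibrate_threshold(c(fused_cal, fused_full),
                                 c(cal_labels, labels), margin = margin)
  obj$cal_scores <- fused_cal
  obj$train_scores <- fused_full
  obj$train_labels <- labels
  class(obj) <- "swd_model"
  # zero false-spared on the training data, by construction
  train_pred <- predict(obj, data)
  stopifnot(all(train_pred[labels == 1L] == 1L))
  obj$train_confusion <- table(truth = labels, pred = train_pred)
  obj
}

#' Predict spared/impaired for new events
#'
#' Rebuilds the configured feature matrices on the new data (projecting
#' through the stored CSP filters), applies the stored selection masks and
#' scorers, fuses scores when the model uses fusion, and thresholds
#' conservatively. Labels on \code{newdata} are never consulted.
#'
#' @param object an \code{swd_model}.
#' @param newdata an \code{\link{swd_data}}.
#' @param type \code{"class"} (integer 0 spared / 1 impaired) or
#'   \code{"score"} (fused impaired-score).
#' @param ... unused.
#' @return Integer predictions or numeric scores, one per event.
#' @export
predict.swd_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "swd_data"))
  sc <- .chain_scores(object, object$config, newdata)
  fused <- if (object$config$window_strategy == "fusion")
    fuse_scores(object$fusion, sc$pre, sc$ict) else sc$single
  if (type == "score") return(fused)
  apply_threshold(object$cal, fused)
}

#' @export
print.swd_model <- function(x, ...) {
  cat(sprintf("<swd_model> %s features | %s windows | %s\n",
              x$config$feature_set, x$config$window_strategy,
              x$config$classifier))
  cat(sprintf("  trained on %d SWDs (%.0f%% spared); threshold tau = %.3f (margin %g)\n",
              x$n_train, 100 * x$train_prevalence, x$cal$tau, x$cal$margin))
  if (!is.null(x$fusion))
    cat(sprintf("  fusion alpha (preictal weight) = %.2f\n", x$fusion$alpha))
  invisible(x)
}

#' @export
summary.swd_model <- function(object, ...) {
  print(object)
  cat("  selected features (preictal):",
      paste(names(which(object$masks$pre)), collapse = ", "), "\n")
  cat("  selected features (ictal):  ",
      paste(names(which(object$masks$ict)), collapse = ", "), "\n")
  met <- .spared_metrics(apply_threshold(object$cal, object$train_scores) == 0L,
                         object$train_labels)
  cat(sprintf("  training spared PPV = %s, spared sensitivity = %.3f\n",
              ifelse(is.na(met["ppv"]), "NA", sprintf("%.3f", met["ppv"])),
              met["sens"]))
  invisible(object)
}

#' Scorer coefficients of a fitted model
#'
#' @param object an \code{swd_model}.
#' @param ... unused.
#' @return Named list of per-scorer standardized weights.
#' @export
coef.swd_model <- function(object, ...) {
  lapply(object$scorers, coef)
}
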