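# Cross-validation, spared-oriented metrics, window-size search,
# patient-level aggregation and labeled-to-unlabeled generalization.

#' Stratified fold assignment
#'
#' Assigns fold ids 1..k so that each class is spread evenly across folds.
#'
#' @param labels class labels (any atomic type, no NA).
#' @param k number of folds.
#' @param seed RNG seed for the shuffle.
#' @return Integer vector of fold ids, same length as \code{labels}.
#' @export
make_stratified_folds <- function(labels, k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  folds <- integer(length(labels))
  rng <- .with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(sample(k), length(idx))
    }
    folds
  })
  rng
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Spared-positive evaluation report
#'
#' Confusion counts with spared as the positive class: TP = predicted and
#' truly spared, FP = predicted spared but impaired, FN = predicted
#' impaired but spared, TN = both impaired. Zero-denominator ratios are
#' reported as NA, never silently 0 or 1.
#'
#' @param truth,pred integer 0/1 vectors (0 spared, 1 impaired).
#' @param fold optional fold ids for a per-fold breakdown.
#' @return Object of class \code{"swd_eval"}: counts, \code{spared_ppv},
#'   \code{spared_sensitivity}, optional \code{per_fold} table.
#' @export
eval_report <- function(truth, pred, fold = NULL) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  cnt <- function(t, p) {
    c(TP = sum(p == 0L & t == 0L), FP = sum(p == 0L & t == 1L),
      FN = sum(p == 1L & t == 0L), TN = sum(p == 1L & t == 1L))
  }
  co <- cnt(truth, pred)
  ratio <- function(a, b) if (a + b > 0) unname(a / (a + b)) else NA_real_
  per_fold <- NULL
  if (!is.null(fold)) {
    per_fold <- do.call(rbind, lapply(sort(unique(fold)), function(f) {
      cf <- cnt(truth[fold == f], pred[fold == f])
      data.frame(fold = f, t(cf),
                 spared_ppv = ratio(cf["TP"], cf["FP"]),
                 spared_sensitivity = ratio(cf["TP"], cf["FN"]),
                 row.names = NULL)
    }))
  }
  structure(list(TP = unname(co["TP"]), FP = unname(co["FP"]),
                 FN = unname(co["FN"]), TN = unname(co["TN"]),
                 n = length(truth),
                 spared_ppv = ratio(co["TP"], co["FP"]),
                 spared_sensitivity = ratio(co["TP"], co["FN"]),
                 per_fold = per_fold),
            class = "swd_eval")
}

#' @export
print.swd_eval <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA (undefined)" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("<swd_eval> n = %d | TP %d FP %d FN %d TN %d (spared positive)\n",
              x$n, x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("  spared predictive value: %s\n", fmt(x$spared_ppv)))
  cat(sprintf("  spared sensitivity:      %s\n", fmt(x$spared_sensitivity)))
  invisible(x)
}

#' Enumerate the full model grid
#'
#' The cross product of 4 feature sets, 4 window strategies and 2
#' classifiers: 32 configurations in a fixed deterministic order.
#'
#' @param feature_sets,window_strategies,classifiers optional restrictions.
#' @return List of \code{\link{model_config}} objects.
#' @export
build_model_grid <- function(feature_sets = c("basic", "extended", "csp", "all"),
                             window_strategies = c("preictal", "ictal",
                                                   "concatenation", "fusion"),
                             classifiers = c("LDA", "SVM")) {
  grid <- expand.grid(classifier = classifiers,
                      window_strategy = window_strategies,
                      feature_set = feature_sets,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    model_config(grid$feature_set[i], grid$window_strategy[i],
                 grid$classifier[i]))
}

#' Stratified k-fold cross-validation of one model configuration
#'
#' Splits labeled events into stratified folds at the SWD level (optionally
#' grouping folds by patient), and per fold runs the entire training
#' pipeline — feature selection, CSP fitting, scorer training, fusion and
#' conservative calibration — on the training fold only, then predicts the
#' held-out fold. Predictions are pooled across folds into one
#' spared-positive report.
#'
#' @param x an \code{\link{swd_data}}, or a
#'   \code{list(recordings=, events=)} which is prepared first.
#' @param config a \code{\link{model_config}}.
#' @param k number of folds (default 10).
#' @param seed RNG seed controlling fold assignment and inner searches.
#' @param selection a \code{\link{selection_config}}; with scope
#'   \code{"global"} the selection mask is computed once on the full
#'   labeled set and reused in every fold.
#' @param n_filters,alpha_grid,margin passed to \code{\link{fit_swd_model}}.
#' @param group_by_patient keep each patient's SWDs in one fold
#'   (guards against patient-identity leakage; default FALSE, mirroring
#'   per-SWD folds).
#' @return An \code{\link{eval_report}} with per-fold breakdown and the
#'   per-event pooled predictions in \code{$predictions}.
#' @export
cross_validate <- function(x, config = model_config(), k = 10L, seed = 1L,
                           selection = selection_config(),
                           n_filters = 5L, alpha_grid = seq(0, 1, by = 0.01),
                           margin = "auto", group_by_patient = FALSE,
                           windows = window_config()) {
  data <- if (inherits(x, "swd_data")) x else
    prepare_swd_data(x$recordings, x$events, windows,
                     extended = config$feature_set %in% c("basic", "extended", "all"))
  labels <- as.integer(data$events$label)
  if (anyNA(labels)) stop("cross-validation requires labeled events")
  if (min(table(labels)) < k && !group_by_patient)
    stop("fewer events in a class (", min(table(labels)),
         ") than folds (", k, ")")

  if (group_by_patient) {
    pats <- unique(data$events$patient_id)
    pat_lab <- vapply(pats, function(p)
      as.integer(any(labels[data$events$patient_id == p] == 1L)), 0L)
    pat_folds <- make_stratified_folds(pat_lab, k = k, seed = seed)
    folds <- pat_folds[match(data$events$patient_id, pats)]
  } else {
    folds <- make_stratified_folds(labels, k = k, seed = seed)
  }
  # re-stratify if some training fold lost a class
  for (tries in 1:25) {
    ok <- all(vapply(sort(unique(folds)), function(f)
      length(unique(labels[folds != f])) == 2L, TRUE))
    if (ok) break
    folds <- make_stratified_folds(labels, k = k, seed = seed + tries)
  }
  if (!ok) stop("could not stratify folds with both classes in every training set")

  forced <- NULL
  if (selection$scope == "global" && config$feature_set != "csp") {
    # global masks cover the non-CSP block; CSP columns are appended TRUE
    mats <- .design_matrices(data, if (config$feature_set == "all") "extended"
                                   else config$feature_set, csp_models = NULL)
    g_pre <- .apply_selection(mats$pre, labels, selection)
    g_ict <- .apply_selection(mats$ict, labels, selection)
    pad <- function(m) {
      if (config$feature_set == "all") {
        csp_cols <- stats::setNames(rep(TRUE, n_filters),
                                    paste0("csp", seq_len(n_filters)))
        c(m, csp_cols)
      } else m
    }
    forced <- list(pre = pad(g_pre$mask), ict = pad(g_ict$mask))
  }

  pred <- integer(length(labels))
  for (f in sort(unique(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    fit <- fit_swd_model(data[tr], config, selection = selection,
                         n_filters = n_filters, alpha_grid = alpha_grid,
                         margin = margin, seed = seed,
                         forced_masks = forced)
    pred[te] <- predict(fit, data[te])
  }
  rep <- eval_report(labels, pred, fold = folds)
  rep$predictions <- data.frame(data$events[, c("patient_id", "swd_id")],
                                truth = labels, pred = pred, fold = folds)
  rep$config <- config
  rep
}

#' Grid search over preictal/ictal window sizes
#'
#' Runs \code{\link{cross_validate}} for every (preictal, ictal) window
#' length pair and ranks cells by spared predictive value, ties broken by
#' spared sensitivity. Failed cells are recorded as missing.
#'
#' @param recordings,events the labeled dataset.
#' @param config a \code{\link{model_config}}.
#' @param pre_grid,ict_grid window lengths in ms (defaults: the searched
#'   ranges at 100 ms steps for CSP features).
#' @param ... passed to \code{\link{cross_validate}}.
#' @return \code{list(table = data.frame, best = window_config)}.
#' @export
window_grid_search <- function(recordings, events, config = model_config(),
                               pre_grid = seq(100, 1000, by = 100),
                               ict_grid = seq(100, 500, by = 100), ...) {
  if (!length(pre_grid) || !length(ict_grid)) stop("grids must be non-empty")
  cells <- expand.grid(pre_ms = pre_grid, ict_ms = ict_grid)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    wc <- window_config(cells$pre_ms[i], cells$ict_ms[i])
    tryCatch({
      data <- prepare_swd_data(recordings, events, wc,
                               extended = config$feature_set %in%
                                 c("basic", "extended", "all"))
      r <- cross_validate(data, config, ...)
      c(spared_ppv = r$spared_ppv, spared_sensitivity = r$spared_sensitivity)
    }, error = function(e) c(spared_ppv = NA_real_,
                             spared_sensitivity = NA_real_))
  })
  tab <- cbind(cells, do.call(rbind, res))
  key_ppv <- ifelse(is.na(tab$spared_ppv), -Inf, tab$spared_ppv)
  key_sen <- ifelse(is.na(tab$spared_sensitivity), -Inf, tab$spared_sensitivity)
  best <- order(-key_ppv, -key_sen)[1L]
  list(table = tab,
       best = window_config(tab$pre_ms[best], tab$ict_ms[best]))
}

#' Aggregate SWD-level predictions to the patient level
#'
#' A patient is impaired if any of their SWDs is predicted impaired, and
#' spared only if all are predicted spared (logical OR over impaired
#' predictions).
#'
#' @param predictions data.frame with columns \code{patient_id} and
#'   \code{pred} (0/1); at least one prediction per patient.
#' @return data.frame with one row per patient: \code{patient_id},
#'   \code{pred} (0/1), \code{n_swd}.
#' @export
aggregate_patient <- function(predictions) {
  if (!nrow(predictions)) stop("no predictions to aggregate")
  sp <- split(predictions$pred, predictions$patient_id)
  if (any(vapply(sp, length, 0L) == 0L)) stop("patient with no predictions")
  data.frame(patient_id = names(sp),
             pred = vapply(sp, function(p) as.integer(any(p == 1L)), 0L),
             n_swd = vapply(sp, length, 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Validate a trained model on an external cohort with patient-level labels
#'
#' Trains on the fully labeled cohort, predicts every SWD of the held-out
#' cohort (whose events are unlabeled at the SWD level), aggregates to
#' patients, and scores against the patient-level labels with
#' spared-positive metrics. Patients without any extractable SWD window are
#' excluded with a warning.
#'
#' @param train_data an \code{\link{swd_data}} with SWD-level labels.
#' @param test_recordings,test_events the external cohort.
#' @param patient_labels data.frame \code{patient_id}, \code{label} (0/1).
#' @param config a \code{\link{model_config}}.
#' @param ... passed to \code{\link{fit_swd_model}}.
#' @return \code{list(report = swd_eval, patients = data.frame,
#'   model = swd_model)}.
#' @export
external_validate <- function(train_data, test_recordings, test_events,
                              patient_labels, config = model_config(), ...) {
  fit <- fit_swd_model(train_data, config, ...)
  test <- prepare_swd_data(test_recordings, test_events, train_data$windows,
                           extended = config$feature_set %in%
                             c("basic", "extended", "all"))
  pred <- predict(fit, test)
  per_pat <- aggregate_patient(data.frame(patient_id = test$events$patient_id,
                                          pred = pred))
  missing_pat <- setdiff(patient_labels$patient_id, per_pat$patient_id)
  if (length(missing_pat))
    warning("patient(s) without scoreable SWDs excluded: ",
            paste(missing_pat, collapse = ", "))
  m <- merge(per_pat, patient_labels, by = "patient_id")
  rep <- eval_report(m$label, m$pred)
  list(report = rep, patients = m, model = fit)
}
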