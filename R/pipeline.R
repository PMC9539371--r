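# End-to-end orchestration: simulate / load -> preprocess -> features ->
# train/evaluate -> export, driven by a config list or YAML file.

.known_keys <- c("out_dir", "seed", "k", "windows", "selection", "model",
                 "synthetic", "paths", "n_filters", "margin",
                 "allow_extrapolation")

.read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), .known_keys)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  config
}

#' Run the full classification pipeline
#'
#' Loads or simulates a cohort, extracts windows and features, runs either
#' one model configuration or the whole 32-model grid under stratified
#' cross-validation, and writes all artifacts (feature matrix, p-value
#' table, CSP filter export, model bundle, evaluation report, log, and the
#' fully resolved config) into the output directory. \code{demo = TRUE}
#' runs self-contained from the synthetic generator.
#'
#' @param config list or YAML path. Recognized fields: \code{out_dir},
#'   \code{seed}, \code{k}, \code{windows} (pre_ms/ict_ms),
#'   \code{selection} (p_threshold/scope), \code{model}
#'   (feature_set/window_strategy/classifier, or the string "grid"),
#'   \code{synthetic} (\code{\link{synth_config}} fields), \code{paths}
#'   (edf_dir, annotations), \code{n_filters}, \code{margin},
#'   \code{allow_extrapolation}.
#' @param demo ignore \code{paths} and run from the synthetic generator.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the evaluation results and artifact
#'   paths.
#' @export
run_pipeline <- function(config = list(), demo = FALSE, quiet = FALSE) {
  cf <- .read_pipeline_config(config)
  out_dir <- cf$out_dir %||% tempfile("swd_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cf$seed %||% 7L)
  k <- as.integer(cf$k %||% 10L)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  logf("swdclass pipeline: seed %d, k = %d", seed, k)

  wc <- do.call(window_config, c(cf$windows %||% list(),
    if (isTRUE(cf$allow_extrapolation)) list(allow_extrapolation = TRUE)))
  sc <- do.call(selection_config, cf$selection %||% list())

  if (demo || !is.null(cf$synthetic)) {
    sargs <- cf$synthetic %||% list()
    if (is.null(sargs$seed)) sargs$seed <- seed
    scfg <- do.call(synth_config, sargs)
    logf("simulating cohort: %d patients, %d spared / %d impaired SWDs",
         scfg$n_patients, scfg$n_spared_swd, scfg$n_impaired_swd)
    cohort <- generate_dataset(scfg)
  } else {
    if (is.null(cf$paths)) stop("config field 'paths' (or 'synthetic'/demo) required")
    files <- list.files(cf$paths$edf_dir, pattern = "\\.edf$", full.names = TRUE)
    if (!length(files)) stop("no EDF files in ", cf$paths$edf_dir)
    loaded <- lapply(files, read_recording, annotations = cf$paths$annotations)
    cohort <- list(recordings = lapply(loaded, `[[`, "recording"),
                   events = do.call(rbind, lapply(loaded, `[[`, "events")))
    logf("loaded %d recordings, %d events", length(files), nrow(cohort$events))
  }

  model_cf <- cf$model %||% list()
  grid_mode <- identical(model_cf, "grid")
  need_ext <- grid_mode ||
    (model_cf$feature_set %||% "csp") %in% c("basic", "extended", "all")
  data <- prepare_swd_data(cohort$recordings, cohort$events, wc,
                           extended = need_ext)
  logf("windows extracted: %d events retained, %d skipped",
       nrow(data$events), nrow(data$skipped))

  if (!is.null(data$features)) {
    fm <- cbind(data$events[, c("swd_id", "patient_id")],
                as.data.frame(rbind2_named(data$features)), label = data$events$label)
    utils::write.csv(fm, file.path(out_dir, "features.csv"), row.names = FALSE)
  }

  results <- list()
  if (grid_mode) {
    grid <- build_model_grid()
    logf("evaluating full model grid (%d configurations)", length(grid))
    rows <- lapply(grid, function(g) {
      r <- cross_validate(data, g, k = k, seed = seed, selection = sc,
                          n_filters = cf$n_filters %||% 5L,
                          margin = cf$margin %||% "auto")
      data.frame(feature_set = g$feature_set,
                 window_strategy = g$window_strategy,
                 classifier = g$classifier,
                 TP = r$TP, FP = r$FP, FN = r$FN, TN = r$TN,
                 spared_ppv = r$spared_ppv,
                 spared_sensitivity = r$spared_sensitivity)
    })
    results$grid <- do.call(rbind, rows)
    utils::write.csv(results$grid, file.path(out_dir, "evaluation_grid.csv"),
                     row.names = FALSE)
  } else {
    mc <- do.call(model_config, model_cf)
    logf("cross-validating %s/%s/%s", mc$feature_set, mc$window_strategy,
         mc$classifier)
    rep <- cross_validate(data, mc, k = k, seed = seed, selection = sc,
                          n_filters = cf$n_filters %||% 5L,
                          margin = cf$margin %||% "auto")
    results$cv <- rep
    utils::write.csv(rep$predictions,
                     file.path(out_dir, "cv_predictions.csv"), row.names = FALSE)
    fit <- fit_swd_model(data, mc, selection = sc,
                         n_filters = cf$n_filters %||% 5L,
                         margin = cf$margin %||% "auto", seed = seed)
    results$model <- fit
    saveRDS(fit, file.path(out_dir, "model.rds"))
    if (!is.null(fit$csp)) {
      filt <- rbind(export_filters(fit$csp$pre), export_filters(fit$csp$ict))
      utils::write.csv(filt, file.path(out_dir, "csp_filters.csv"),
                       row.names = FALSE)
    }
    if (!is.null(fit$p_tables$pre)) {
      pt <- rbind(cbind(window = "preictal", fit$p_tables$pre),
                  cbind(window = "ictal", fit$p_tables$ict))
      utils::write.csv(pt, file.path(out_dir, "p_values.csv"), row.names = FALSE)
    }
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(list(
        TP = rep$TP, FP = rep$FP, FN = rep$FN, TN = rep$TN,
        spared_ppv = rep$spared_ppv,
        spared_sensitivity = rep$spared_sensitivity,
        alpha = if (!is.null(fit$fusion)) fit$fusion$alpha else NULL),
        file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  # archive the resolved config for provenance
  resolved <- list(out_dir = out_dir, seed = seed, k = k,
                   windows = unclass(wc), selection = unclass(sc),
                   model = if (grid_mode) "grid" else model_cf,
                   synthetic = if (demo || !is.null(cf$synthetic))
                     cf$synthetic %||% list() else NULL)
  if (requireNamespace("yaml", quietly = TRUE))
    yaml::write_yaml(resolved, file.path(out_dir, "config.yaml"))
  logf("done; artifacts in %s", out_dir)
  invisible(c(results, list(out_dir = out_dir)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# prefix and bind the preictal/ictal feature blocks side by side
rbind2_named <- function(features) {
  pre <- features$pre; colnames(pre) <- paste0("pre_", colnames(pre))
  ict <- features$ict; colnames(ict) <- paste0("ict_", colnames(ict))
  cbind(pre, ict)
}
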