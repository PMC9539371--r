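test_that("the model grid enumerates the full cross product", {
  grid <- build_model_grid()
  expect_length(grid, 32L)
  keys <- vapply(grid, function(g)
    paste(g$feature_set, g$window_strategy, g$classifier), "")
  expect_equal(anyDuplicated(keys), 0L)
  expect_length(build_model_grid(classifiers = "LDA"), 16L)
})

test_that("spared-positive metrics match hand-computed confusion counts", {
  r <- eval_report(truth = c(rep(0, 10), rep(1, 5)),
                   pred = c(rep(0, 9), 1, rep(1, 5)))
  expect_equal(r$TP, 9L); expect_equal(r$FP, 0L); expect_equal(r$FN, 1L)
  expect_equal(r$spared_ppv, 1.0)
  expect_equal(r$spared_sensitivity, 0.9)
  expect_equal(r$TP + r$FP + r$FN + r$TN, r$n)
  # undefined ratios surface as NA, never 0 or 1
  r2 <- eval_report(truth = rep(1, 4), pred = rep(1, 4))
  expect_true(is.na(r2$spared_ppv))
  expect_true(is.na(r2$spared_sensitivity))
})

test_that("stratified folds balance classes and respect the seed", {
  y <- rep(0:1, c(60, 40))
  f1 <- make_stratified_folds(y, 10, seed = 5)
  f2 <- make_stratified_folds(y, 10, seed = 5)
  expect_identical(f1, f2)
  tab <- table(f1[y == 1])
  expect_true(max(tab) - min(tab) <= 1)
  expect_error(make_stratified_folds(y, 1), "k must be")
})

test_that("cross-validation pools all events and is deterministic", {
  r1 <- cross_validate(tiny_data, model_config("csp", "ictal", "LDA"),
                       k = 3, seed = 4)
  r2 <- cross_validate(tiny_data, model_config("csp", "ictal", "LDA"),
                       k = 3, seed = 4)
  expect_identical(r1$predictions, r2$predictions)
  expect_equal(nrow(r1$predictions), nrow(tiny_data$events))
  expect_equal(sum(r1$per_fold$TP + r1$per_fold$FP +
                     r1$per_fold$FN + r1$per_fold$TN), r1$n)
  expect_error(cross_validate(tiny_data, k = 20), "folds")
})

test_that("well-separated synthetic classes reach perfect spared PPV", {
  r <- cross_validate(tiny_data, model_config("csp", "ictal", "LDA"),
                      k = 5, seed = 8)
  expect_equal(r$spared_ppv, 1.0)
  expect_gte(r$spared_sensitivity, 0.8)
})

test_that("per-fold and global selection scopes both run leakage-free", {
  for (scope in c("per_fold", "global")) {
    r <- suppressWarnings(
      cross_validate(tiny_data, model_config("extended", "ictal", "LDA"),
                     k = 3, seed = 9,
                     selection = selection_config(0.001, scope)))
    expect_equal(r$n, nrow(tiny_data$events))
  }
})

test_that("shuffled labels drive spared PPV toward prevalence", {
  set.seed(40)
  ppv <- c()
  base <- tiny_data
  for (i in 1:20) {
    base$events$label <- sample(tiny_data$events$label)
    r <- suppressWarnings(
      cross_validate(base, model_config("basic", "ictal", "LDA"),
                     k = 3, seed = i))
    ppv <- c(ppv, r$spared_ppv)
  }
  prevalence <- mean(tiny_data$events$label == 0L)
  expect_equal(mean(ppv, na.rm = TRUE), prevalence, tolerance = 0.25)
})

test_that("masking test labels does not change predictions", {
  idx_te <- which(make_stratified_folds(tiny_data$events$label, 3, 1) == 1)
  fit <- fit_swd_model(tiny_data[-idx_te], model_config("csp", "fusion", "LDA"),
                       seed = 1)
  te <- tiny_data[idx_te]
  p1 <- predict(fit, te)
  te$events$label <- NA_integer_
  p2 <- predict(fit, te)
  expect_identical(p1, p2)
})

test_that("window grid search ranks cells and returns the argmax", {
  d <- tiny_cohort
  gs <- window_grid_search(d$recordings, d$events,
                           model_config("csp", "ictal", "LDA"),
                           pre_grid = c(500, 1000), ict_grid = c(250, 500),
                           k = 3, seed = 2)
  expect_equal(nrow(gs$table), 4L)
  best_row <- which(gs$table$pre_ms == gs$best$pre_ms &
                      gs$table$ict_ms == gs$best$ict_ms)
  key <- order(-ifelse(is.na(gs$table$spared_ppv), -Inf, gs$table$spared_ppv),
               -ifelse(is.na(gs$table$spared_sensitivity), -Inf,
                       gs$table$spared_sensitivity))
  expect_equal(best_row, key[1])
  # degenerate one-cell grid returns that cell
  gs1 <- window_grid_search(d$recordings, d$events,
                            model_config("csp", "ictal", "LDA"),
                            pre_grid = 1000, ict_grid = 500, k = 3, seed = 2)
  expect_equal(gs1$best$pre_ms, 1000)
  expect_equal(gs1$best$ict_ms, 500)
  expect_error(window_grid_search(d$recordings, d$events,
                                  pre_grid = numeric(0)), "non-empty")
})

test_that("patient aggregation is a logical OR over impaired calls", {
  expect_equal(aggregate_patient(
    data.frame(patient_id = "a", pred = c(0, 0, 0)))$pred, 0L)
  expect_equal(aggregate_patient(
    data.frame(patient_id = "a", pred = c(0, 1)))$pred, 1L)
  # monotone: adding an impaired prediction never flips impaired -> spared
  base <- data.frame(patient_id = rep(c("a", "b"), each = 2),
                     pred = c(0, 1, 0, 0))
  agg1 <- aggregate_patient(base)
  agg2 <- aggregate_patient(rbind(base, data.frame(patient_id = c("a", "b"),
                                                   pred = c(1, 1))))
  expect_true(all(agg2$pred >= agg1$pred))
  expect_error(aggregate_patient(base[0, ]), "no predictions")
})

test_that("external validation scores patients with spared-positive metrics", {
  train_cfg <- synth_config(n_patients = 6, n_spared_swd = 18,
                            n_impaired_swd = 12, seed = 50)
  test_cfg <- synth_config(n_patients = 8, n_spared_swd = 12,
                           n_impaired_swd = 12, class_purity = TRUE, seed = 51)
  tr <- generate_dataset(train_cfg)
  te <- generate_dataset(test_cfg)
  pat_lab <- aggregate_patient(data.frame(patient_id = te$events$patient_id,
                                          pred = te$events$label))
  names(pat_lab)[names(pat_lab) == "pred"] <- "label"
  te$events$label <- NA_integer_
  train_data <- prepare_swd_data(tr$recordings, tr$events, extended = FALSE)
  out <- external_validate(train_data, te$recordings, te$events,
                           pat_lab[, c("patient_id", "label")],
                           model_config("csp", "fusion", "LDA"), seed = 50)
  expect_equal(out$report$n, 8L)
  expect_equal(out$report$spared_ppv, 1.0)
  # an all-impaired cohort leaves spared sensitivity undefined
  imp_cfg <- synth_config(n_patients = 3, n_spared_swd = 0,
                          n_impaired_swd = 9, seed = 52)
  imp <- generate_dataset(imp_cfg)
  pl <- data.frame(patient_id = unique(imp$events$patient_id), label = 1L)
  imp$events$label <- NA_integer_
  out2 <- external_validate(train_data, imp$recordings, imp$events, pl,
                            model_config("csp", "fusion", "LDA"), seed = 50)
  expect_true(is.na(out2$report$spared_sensitivity))
})
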