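test_that("both scorers separate a separable 1-D problem on training data", {
  X <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(0:1, each = 20)
  for (kind in c("LDA", "SVM")) {
    sc <- train_scorer(X, y, kind)
    s <- predict(sc, X)
    expect_true(all(s[y == 1] > max(s[y == 0])), info = kind)
  }
  expect_error(train_scorer(X, rep(0L, 40), "LDA"), "both classes")
})

test_that("random labels give chance-level cross-validated accuracy", {
  set.seed(30)
  n <- 200
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(0:1, each = n / 2)
  folds <- make_stratified_folds(y, 5, seed = 30)
  acc <- 0
  for (f in 1:5) {
    sc <- train_scorer(X[folds != f, ], y[folds != f], "LDA")
    s <- predict(sc, X[folds == f, ])
    acc <- acc + sum((s > 0) == (y[folds == f] == 1))
  }
  expect_equal(acc / n, 0.5, tolerance = 0.2)
})

test_that("duplicated feature columns leave LDA scores unchanged", {
  set.seed(31)
  X <- matrix(c(rnorm(30), rnorm(30, 2)), ncol = 2,
              dimnames = list(NULL, c("u", "v")))
  y <- rep(0:1, each = 15)
  s1 <- predict(train_scorer(X, y, "LDA"), X)
  X2 <- cbind(X, u2 = X[, "u"])
  s2 <- suppressWarnings(predict(train_scorer(X2, y, "LDA"), X2))
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("hand-rolled Fisher discriminant matches the reference LDA direction", {
  set.seed(32)
  n <- 120
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n) > 0)
  sc <- train_scorer(X, y, "LDA")
  ref <- MASS::lda(X, grouping = y)
  s_ref <- drop(predict(ref, X)$x)
  if (cor(s_ref, predict(sc, X)) < 0) s_ref <- -s_ref
  expect_gt(cor(predict(sc, X), s_ref), 1 - 1e-10)
})

test_that("zero-variance features are dropped with a warning", {
  X <- cbind(good = c(rnorm(10), rnorm(10, 3)), flat = rep(1, 20))
  y <- rep(0:1, each = 10)
  expect_warning(sc <- train_scorer(X, y, "LDA"), "flat")
  expect_length(coef(sc), 1L)
  expect_error(predict(sc, X[, "flat", drop = FALSE]), "missing feature")
})

test_that("fusion at degenerate weights reduces to single-window posteriors", {
  set.seed(33)
  n <- 60
  y <- rep(0:1, each = n / 2)
  s_pre <- rnorm(n, mean = 2 * y, sd = 0.7)
  s_ict <- rnorm(n, mean = 3 * y, sd = 1.2)
  for (al in c(0, 1)) {
    fm <- fit_fusion(s_pre, s_ict, y, alpha_grid = al, repeats = 1)
    fused <- fuse_scores(fm, s_pre, s_ict)
    par <- if (al == 1) fm$pre else fm$ict
    s <- if (al == 1) s_pre else s_ict
    post <- dnorm(s, par$impaired$mu, par$impaired$sigma, log = TRUE) -
      dnorm(s, par$spared$mu, par$spared$sigma, log = TRUE)
    expect_identical(order(fused), order(post))
  }
})

test_that("a symmetric fusion model scores the midpoint as zero", {
  fm <- structure(list(
    alpha = 0.5,
    pre = list(spared = list(mu = -1, sigma = 1), impaired = list(mu = 1, sigma = 1)),
    ict = list(spared = list(mu = -1, sigma = 1), impaired = list(mu = 1, sigma = 1)),
    prior_impaired = 0.5), class = "swd_fusion")
  expect_equal(fuse_scores(fm, 0, 0), 0)
  expect_error(fuse_scores(list(), 0, 0), "not trained")
})

test_that("the alpha search favors the informative window", {
  set.seed(34)
  n <- 80
  y <- rep(0:1, each = n / 2)
  noise <- rnorm(n)
  sep <- c(rnorm(n / 2, -4), rnorm(n / 2, 4))
  fm <- fit_fusion(noise, sep, y, seed = 34)
  expect_lte(fm$alpha, 0.1)
  fm3 <- fit_fusion(noise, sep, y, alpha_grid = c(0, 0.5, 1), seed = 34)
  expect_equal(fm3$alpha, 0)
  # both windows identical: every alpha ties, smallest grid value wins
  fmt <- fit_fusion(sep, sep, y, alpha_grid = c(0.2, 0.6, 0.9), seed = 34)
  expect_equal(fmt$alpha, 0.2)
  expect_error(fit_fusion(noise, sep, y, alpha_grid = numeric(0)), "empty")
  expect_error(fit_fusion(noise, sep, y, alpha_grid = c(0.5, 2)), "0, 1")
})

test_that("conservative calibration recovers the separable case exactly", {
  cal <- calibrate_threshold(c(-2, -1, 1, 2), c(0, 0, 1, 1), margin = 0)
  expect_equal(cal$tau, 1)
  pred <- apply_threshold(cal, c(-2, -1, 1, 2))
  expect_equal(pred, c(0L, 0L, 1L, 1L))
  expect_error(calibrate_threshold(1:4, c(0, 0, 0, 0)), "no impaired")
  expect_error(calibrate_threshold(1:4, c(0, 0, 1, 1), margin = -1), ">= 0")
})

test_that("overlapping classes sacrifice spared calls, never safety", {
  set.seed(35)
  y <- rep(0:1, each = 30)
  s <- c(rnorm(30, 0), rnorm(30, 1))    # heavy overlap
  cal <- calibrate_threshold(s, y)
  pred <- apply_threshold(cal, s)
  expect_equal(sum(pred == 0L & y == 1L), 0L)   # zero false-spared
  expect_lt(sum(pred == 0L & y == 0L), 30L)     # some spared sacrificed
})

test_that("sensitivity falls monotonically with the safety margin", {
  set.seed(36)
  y <- rep(0:1, each = 40)
  s <- c(rnorm(40, -2), rnorm(40, 2))
  sens <- vapply(c(0, 1, 2, 4, 8), function(m) {
    pred <- apply_threshold(calibrate_threshold(s, y, margin = m), s)
    sum(pred == 0L & y == 0L) / 40
  }, 0)
  expect_true(all(diff(sens) <= 0))
})

test_that("concatenation strategy doubles the scorer input dimension", {
  fit <- fit_swd_model(tiny_data, model_config("csp", "concatenation", "LDA"),
                       seed = 1)
  expect_length(fit$scorers$single$feature_names, 10L)
  expect_length(coef(fit)$single, 10L)
})

test_that("unlabeled events are predictable once a model is trained", {
  fit <- fit_swd_model(tiny_data, model_config("csp", "fusion", "LDA"),
                       seed = 1)
  unl <- tiny_data
  unl$events$label <- NA_integer_
  pred <- predict(fit, unl)
  expect_true(all(pred %in% 0:1))
  expect_length(pred, nrow(tiny_data$events))
})

test_that("every trained bundle commits zero false-spared on training data", {
  for (cfgs in list(c("basic", "ictal", "LDA"),
                    c("extended", "fusion", "SVM"),
                    c("csp", "fusion", "LDA"),
                    c("all", "concatenation", "SVM"))) {
    fit <- suppressWarnings(
      fit_swd_model(tiny_data, model_config(cfgs[1], cfgs[2], cfgs[3]),
                    seed = 2))
    pred <- predict(fit, tiny_data)
    truth <- tiny_data$events$label
    expect_equal(sum(pred == 0L & truth == 1L), 0L,
                 info = paste(cfgs, collapse = "/"))
  }
})
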