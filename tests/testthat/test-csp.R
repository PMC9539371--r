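test_that("identical classes give eigenvalues of one half", {
  set.seed(10)
  ep <- replicate(6, matrix(rnorm(4 * 128), 4), simplify = FALSE)
  m <- fit_csp(ep, ep, k = 4)
  expect_equal(m$eigenvalues, rep(0.5, 4), tolerance = 1e-6)
})

test_that("diagonal two-channel toy matches the closed-form eigenvalues", {
  ep_s <- list(diag_epoch(1, 4), diag_epoch(1, 4))
  ep_i <- list(diag_epoch(4, 1), diag_epoch(4, 1))
  m <- fit_csp(ep_s, ep_i, k = 2)
  expect_equal(sort(m$eigenvalues), c(0.2, 0.8), tolerance = 1e-9)
  # filters along the coordinate axes (up to sign and scale)
  for (j in 1:2) {
    w <- m$filters[j, ]
    expect_lt(min(abs(w)) / max(abs(w)), 1e-6)
  }
})

test_that("filters whiten the composite covariance and lambda is ordered", {
  set.seed(11)
  ep_s <- replicate(8, matrix(rnorm(6 * 200), 6), simplify = FALSE)
  ep_i <- replicate(8, matrix(rnorm(6 * 200, sd = rep(c(1, 3), each = 3)), 6),
                    simplify = FALSE)
  m <- fit_csp(ep_s, ep_i, k = 6)
  cov1 <- function(x) { x <- x - rowMeans(x); C <- tcrossprod(x) / ncol(x); C / sum(diag(C)) }
  C_c <- Reduce(`+`, lapply(ep_s, cov1)) / 8 + Reduce(`+`, lapply(ep_i, cov1)) / 8
  W <- t(m$filters)                      # channels x k
  expect_equal(t(W) %*% C_c %*% W, diag(6), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(diff(pmax(m$eigenvalues, 1 - m$eigenvalues)) <= 1e-12))
  expect_true(all(m$eigenvalues >= 0 & m$eigenvalues <= 1))
})

test_that("swapping class roles reflects eigenvalues and keeps filters", {
  set.seed(12)
  ep_s <- replicate(6, matrix(rnorm(4 * 150), 4), simplify = FALSE)
  ep_i <- replicate(6, matrix(rnorm(4 * 150, sd = c(1, 1, 2, 3)), 4),
                    simplify = FALSE)
  a <- fit_csp(ep_s, ep_i, k = 4)
  b <- fit_csp(ep_i, ep_s, k = 4)
  expect_equal(sort(b$eigenvalues), sort(1 - a$eigenvalues), tolerance = 1e-8)
  agree <- abs(a$filters %*% MASS::ginv(b$filters))
  expect_equal(sort(apply(agree, 1, max)), rep(1, 4), tolerance = 1e-6)
})

test_that("generalized eigensolve matches the whiten-then-diagonalize oracle", {
  set.seed(13)
  for (nch in 2:4) {
    ep_s <- replicate(5, matrix(rnorm(nch * 120), nch), simplify = FALSE)
    ep_i <- replicate(5, matrix(rnorm(nch * 120, sd = seq(1, 2, length.out = nch)),
                                nch), simplify = FALSE)
    m <- fit_csp(ep_s, ep_i, k = nch)
    o <- csp_oracle(ep_s, ep_i, k = nch)
    expect_equal(m$eigenvalues, o$eigenvalues, tolerance = 1e-6)
    agree <- abs(m$filters %*% MASS::ginv(o$filters))
    expect_equal(sort(apply(agree, 1, max)), rep(1, nch), tolerance = 1e-4)
  }
})

test_that("rotating all epochs rotates filters but not eigenvalues", {
  set.seed(14)
  ep_s <- replicate(5, matrix(rnorm(4 * 150), 4), simplify = FALSE)
  ep_i <- replicate(5, matrix(rnorm(4 * 150, sd = c(1, 1, 3, 3)), 4),
                    simplify = FALSE)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  a <- fit_csp(ep_s, ep_i, k = 4)
  b <- fit_csp(lapply(ep_s, function(e) Q %*% e),
               lapply(ep_i, function(e) Q %*% e), k = 4)
  expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-8)
  # b's filters composed with Q recover a's filters up to sign
  agree <- abs((b$filters %*% Q) %*% MASS::ginv(a$filters))
  expect_equal(sort(apply(agree, 1, max)), rep(1, 4), tolerance = 1e-6)
})

test_that("rank-deficient covariance is regularized with a warning", {
  ep <- replicate(4, {
    z <- matrix(rnorm(1 * 100), 1)
    rbind(z, z, z[1, ] * 2)          # rank-1 epochs
  }, simplify = FALSE)
  expect_warning(m <- fit_csp(ep, ep, k = 2), "regulariz")
  expect_true(all(is.finite(m$eigenvalues)))
  expect_error(fit_csp(ep, ep, k = 5), "exceeds channel count")
})

test_that("csp features are log variance shares", {
  set.seed(15)
  ep_s <- replicate(5, matrix(rnorm(4 * 150), 4), simplify = FALSE)
  ep_i <- replicate(5, matrix(rnorm(4 * 150, sd = c(1, 1, 2, 2)), 4),
                    simplify = FALSE)
  m <- fit_csp(ep_s, ep_i, k = 3)
  win <- matrix(rnorm(4 * 200), 4)
  f <- csp_features(m, win)
  expect_equal(length(f), 3L)
  expect_equal(sum(exp(f)), 1, tolerance = 1e-12)
  # invariant to overall scaling of the window
  expect_equal(f, csp_features(m, 7.3 * win), tolerance = 1e-10)
  # a single filter normalizes to log(1) = 0
  m1 <- fit_csp(ep_s, ep_i, k = 1)
  expect_equal(unname(csp_features(m1, win)), 0)
  expect_error(csp_features(m, matrix(0, 4, 50)), "degenerate")
  expect_error(csp_features(m, win[1:3, ]), "channels")
})

test_that("filter export is tidy, ordered and round-trips through CSV", {
  sp <- which(tiny_data$events$label == 0L)
  im <- which(tiny_data$events$label == 1L)
  m <- fit_csp(lapply(tiny_data$pairs[sp], `[[`, "ictal"),
               lapply(tiny_data$pairs[im], `[[`, "ictal"), k = 5)
  tab <- export_filters(m)
  expect_equal(nrow(tab), 80L)                 # 5 filters x 16 channels
  per_filter <- tab$eigenvalue[!duplicated(tab$filter_index)]
  expect_true(all(diff(pmax(per_filter, 1 - per_filter)) <= 1e-12))
  path <- tempfile(fileext = ".csv")
  export_filters(m, path)
  back <- read.csv(path)
  expect_equal(back$weight, tab$weight)
})
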