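test_that("a planted single-feature signal is recovered in every fold", {
  set.seed(41)
  n <- 500
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("F", 1:6)))
  y <- x[, 3] + rnorm(n, sd = 0.05)
  fit <- fit_evaluate(x, y, model_config(outer_folds = 10,
                                         alpha_grid = c(0, 0.5, 1),
                                         seed = 1))
  expect_gte(mean(fit$folds$spearman), 0.95)
  top <- fit$coefficients |>
    dplyr::filter(term != "(Intercept)") |>
    dplyr::group_by(fold) |>
    dplyr::slice_max(abs(estimate), n = 1)
  expect_true(all(top$term == "F3"))
})

test_that("no-signal input yields near-zero held-out correlation", {
  set.seed(42)
  x <- matrix(rnorm(300 * 5), 300, 5)
  y <- rnorm(300)
  fit <- fit_evaluate(x, y, model_config(outer_folds = 10,
                                         alpha_grid = c(0, 0.5, 1),
                                         seed = 2))
  expect_lt(abs(mean(fit$folds$spearman)), 0.1)
})

# coordinate-descent lasso on centered data, glmnet objective
# 1/(2n)||y - Xb||^2 + lambda ||b||_1
oracle_lasso <- function(x, y, lambda, iters = 5000) {
  n <- nrow(x); p <- ncol(x)
  b <- rep(0, p)
  xs <- colSums(x^2) / n
  for (it in seq_len(iters)) {
    for (j in seq_len(p)) {
      r <- y - x[, -j, drop = FALSE] %*% b[-j]
      rho <- sum(x[, j] * r) / n
      b[j] <- sign(rho) * max(abs(rho) - lambda, 0) / xs[j]
    }
  }
  b
}

test_that("the ridge and lasso limits match independent references", {
  set.seed(43)
  n <- 100; p <- 5
  x <- scale(matrix(rnorm(n * p), n, p))
  beta <- c(2, -1, 0.5, 0, 0)
  y0 <- as.vector(x %*% beta + rnorm(n))
  # center and scale y by its 1/n sd so the solver's internal response
  # normalization is an exact no-op
  y <- (y0 - mean(y0)) / sqrt(mean((y0 - mean(y0))^2))
  x <- matrix(as.numeric(x), n, p)
  lambda <- 0.2

  # paper convention: alpha = 1 is the pure ridge limit
  b_ridge <- fit_penalized(x, y, alpha = 1, lambda = lambda)[-1]
  ref_ridge <- solve(crossprod(x) / n + diag(lambda, p), crossprod(x, y) / n)
  expect_equal(unname(b_ridge), as.vector(ref_ridge), tolerance = 1e-4)

  # alpha = 0 is the pure lasso limit
  b_lasso <- fit_penalized(x, y, alpha = 0, lambda = lambda)[-1]
  ref_lasso <- oracle_lasso(x, y, lambda)
  expect_equal(unname(b_lasso), as.vector(ref_lasso), tolerance = 1e-4)
})

test_that("duplicated features receive near-identical coefficients (grouping)", {
  set.seed(44)
  n <- 400
  x <- matrix(rnorm(n * 4), n, 4)
  y <- x[, 1] + 0.5 * x[, 2] + rnorm(n, sd = 0.3)
  xd <- cbind(x, dup = x[, 1])
  colnames(xd) <- c("F1", "F2", "F3", "F4", "F1dup")
  b <- fit_penalized(scale(xd), as.vector(scale(y)),
                     alpha = 0.5, lambda = 0.05)[-1]
  pair <- abs(c(b["F1"], b["F1dup"]))
  expect_lte(abs(pair[1] - pair[2]), 0.1 * mean(pair))
})

test_that("fold standardization is train-only (no leakage)", {
  set.seed(45)
  x <- matrix(rexp(200 * 3, rate = 0.2), 200, 3)
  y <- rnorm(200, mean = 50, sd = 10)
  test_idx <- 151:200
  fold <- regscore:::prepare_fold(x, y, test_idx)
  expect_equal(unname(colMeans(fold$xtr)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(fold$xtr, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(mean(fold$ytr), 0, tolerance = 1e-12)
  # held-out rows transformed with training statistics are NOT 0/1
  expect_false(all(abs(colMeans(fold$xte)) < 1e-3))
  expect_false(abs(mean(fold$yte)) < 1e-3 &&
               abs(sd(fold$yte) - 1) < 1e-3)
})

test_that("fits are bitwise reproducible given config and seed", {
  set.seed(46)
  x <- matrix(rnorm(120 * 4), 120, 4)
  y <- x[, 1] + rnorm(120)
  cfg <- model_config(outer_folds = 3, alpha_grid = c(0, 1), seed = 9)
  f1 <- fit_evaluate(x, y, cfg)
  f2 <- fit_evaluate(x, y, cfg)
  expect_identical(f1$folds, f2$folds)
  expect_identical(f1$coefficients, f2$coefficients)
  f3 <- fit_evaluate(x, y, model_config(outer_folds = 3,
                                        alpha_grid = c(0, 1), seed = 10))
  expect_false(identical(f1$folds, f3$folds))
})

fake_fit <- function(coef_by_fold) {
  folds <- tibble::tibble(fold = seq_along(coef_by_fold), alpha = 0.5,
                          lambda = 0.1, spearman = 0.5, mse = 1,
                          n_nonzero = 1)
  coefs <- purrr::imap_dfr(coef_by_fold, function(v, f)
    tibble::tibble(fold = f, term = names(v), estimate = unname(v)))
  structure(list(folds = folds, coefficients = coefs,
                 features = setdiff(names(coef_by_fold[[1]]),
                                    "(Intercept)"),
                 n = 10, config = model_config()),
            class = "regscore_fit")
}

test_that("coefficient stability is the across-fold sample sd", {
  f <- fake_fit(list(c("(Intercept)" = 0, A = 0, B = 1),
                     c("(Intercept)" = 0, A = 2, B = 1)))
  st <- coefficient_stability(f)
  expect_equal(st$sd[st$term == "A"], sqrt(2), tolerance = 1e-12)
  expect_equal(st$sd[st$term == "A"], 1.4142, tolerance = 1e-4)
  expect_equal(st$sd[st$term == "B"], 0)

  set.seed(47)
  vals <- replicate(10, c("(Intercept)" = 0, A = rnorm(1), B = rnorm(1)),
                    simplify = FALSE)
  f10 <- fake_fit(vals)
  st <- coefficient_stability(f10)
  expect_equal(st$sd[st$term == "A"],
               sd(vapply(vals, `[[`, numeric(1), "A")), tolerance = 1e-12)

  f1 <- fake_fit(list(c("(Intercept)" = 0, A = 1)))
  expect_error(coefficient_stability(f1), "folds")
})

test_that("tidy and glance summarize folds", {
  f <- fake_fit(list(c("(Intercept)" = 1, A = 0, B = 3),
                     c("(Intercept)" = 1, A = 2, B = 3)))
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "A"], 1)
  expect_equal(td$n_nonzero_folds[td$term == "A"], 1L)
  g <- glance(f)
  expect_equal(g$mean_spearman, 0.5)
  expect_equal(g$outer_folds, 2L)
  expect_equal(unname(mean_coefficients(f)["B"]), 3)
})

test_that("degenerate model inputs error", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(fit_evaluate(x, rep(1, 20), model_config()), "constant")
  expect_error(fit_evaluate(x, rnorm(21), model_config()), "aligned")
  expect_error(fit_evaluate(x[1:6, ], rnorm(6),
                            model_config(inner_folds = 6)),
               "inner folds")
})
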