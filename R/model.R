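# Run code under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration of the nested Monte-Carlo cross-validated elastic net
#'
#' The expression model is `argmin_beta ||y - X beta||^2 +
#' lambda * (alpha ||beta||_2^2 + (1 - alpha) ||beta||_1)`, so `alpha = 1`
#' is pure ridge and `alpha = 0` pure lasso (note this is the reverse of
#' the `glmnet` convention; the mapping is handled internally). `alpha` is
#' searched on `alpha_grid` and `lambda` on a per-alpha path of `n_lambda`
#' log-spaced values spanning four orders of magnitude below the smallest
#' all-zeroing `lambda`, both by minimizing the inner-CV mean squared
#' error.
#'
#' @param outer_folds Number of outer Monte-Carlo resamples (default 10).
#' @param test_fraction Held-out fraction per outer fold (default 0.2).
#' @param inner_folds Inner CV folds for the `(alpha, lambda)` search
#'   (default 6).
#' @param alpha_grid Ridge/lasso mixing values in `[0, 1]` (default 0 to 1
#'   in steps of 0.01).
#' @param n_lambda Length of the per-alpha `lambda` path.
#' @param seed Integer seed controlling all fold assignments.
#' @param penalty `"elastic_net"` (search `alpha_grid`), `"lasso"`
#'   (`alpha = 0`) or `"ridge"` (`alpha = 1`).
#' @return A `model_config` list.
#' @export
model_config <- function(outer_folds = 10L, test_fraction = 0.2,
                         inner_folds = 6L,
                         alpha_grid = seq(0, 1, by = 0.01),
                         n_lambda = 100L, seed = 1L,
                         penalty = c("elastic_net", "lasso", "ridge")) {
  penalty <- match.arg(penalty)
  if (test_fraction <= 0 || test_fraction >= 1)
    abort("test_fraction must be in (0, 1)")
  if (any(alpha_grid < 0 | alpha_grid > 1))
    abort("alpha_grid values must be in [0, 1]")
  alpha_grid <- switch(penalty,
    elastic_net = alpha_grid, lasso = 0, ridge = 1)
  structure(
    list(outer_folds = as.integer(outer_folds),
         test_fraction = test_fraction,
         inner_folds = as.integer(inner_folds),
         alpha_grid = alpha_grid, n_lambda = as.integer(n_lambda),
         seed = as.integer(seed), penalty = penalty),
    class = "model_config")
}

scale_cols <- function(m, center, scale) {
  out <- sweep(m, 2, center, "-")
  sweep(out, 2, ifelse(scale > 0, scale, 1), "/")
}

# Standardize one outer fold: center/scale x columns and y using the
# training rows only; test rows are transformed with the training
# statistics.
prepare_fold <- function(x, y, test_idx) {
  xtr <- x[-test_idx, , drop = FALSE]
  ctr <- colMeans(xtr)
  str <- apply(xtr, 2, stats::sd)
  ym <- mean(y[-test_idx])
  ys <- stats::sd(y[-test_idx])
  if (ys == 0) abort("constant response in a training fold")
  list(
    xtr = scale_cols(xtr, ctr, str),
    xte = scale_cols(x[test_idx, , drop = FALSE], ctr, str),
    ytr = (y[-test_idx] - ym) / ys,
    yte = (y[test_idx] - ym) / ys)
}

#' Single elastic-net fit at fixed penalty
#'
#' Fits the penalized linear model at one `(alpha, lambda)` pair on
#' already-standardized data (no internal standardization, no intercept
#' search beyond the ordinary one). `alpha` follows the convention of
#' [model_config()]: 1 is pure ridge, 0 pure lasso.
#'
#' @param x Numeric matrix.
#' @param y Numeric response.
#' @param alpha Ridge/lasso mix in `[0, 1]` (1 = ridge).
#' @param lambda Non-negative penalty strength.
#' @return Named coefficient vector (first element `(Intercept)`).
#' @export
fit_penalized <- function(x, y, alpha, lambda) {
  fit <- glmnet::glmnet(as.matrix(x), y, alpha = 1 - alpha,
                        lambda = lambda, standardize = FALSE,
                        family = "gaussian",
                        thresh = 1e-12, maxit = 1e6)
  b <- as.matrix(stats::coef(fit))[, 1]
  names(b)[1] <- "(Intercept)"
  b
}

#' Fit and evaluate the penalized expression model
#'
#' For each outer fold a random `1 - test_fraction` share of the genes is
#' used for training. Features and response are centered and scaled to unit
#' variance using training rows only (the held-out rows are transformed
#' with the training statistics, so no information leaks). `(alpha,
#' lambda)` are chosen by minimizing the mean squared error of an
#' inner cross-validation with shared fold assignments across the alpha
#' grid; the reported coefficients are refit on the full training split at
#' the chosen pair. Held-out performance is summarized by the Spearman
#' correlation and MSE between predicted and observed (standardized)
#' expression.
#'
#' @param x Numeric gene-by-feature matrix (e.g. `build_design()$x`).
#' @param y Numeric response aligned with the rows of `x`.
#' @param config A [model_config()].
#' @return A `regscore_fit` with per-fold metrics (`$folds`), per-fold
#'   coefficients (`$coefficients`, long form) and the configuration.
#' @export
fit_evaluate <- function(x, y, config = model_config()) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) abort("x and y are not row-aligned")
  if (stats::sd(y) == 0) abort("constant response")
  n <- nrow(x)
  n_test <- max(1L, round(config$test_fraction * n))
  n_train <- n - n_test
  if (n_train < config$inner_folds)
    abort("fewer training rows than inner folds")
  feats <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- feats

  with_preserved_seed(config$seed, {
    folds <- vector("list", config$outer_folds)
    coefs <- vector("list", config$outer_folds)
    for (f in seq_len(config$outer_folds)) {
      test_idx <- sample.int(n, n_test)
      fold <- prepare_fold(x, y, test_idx)
      xtr <- fold$xtr; xte <- fold$xte; ytr <- fold$ytr; yte <- fold$yte

      foldid <- sample(rep_len(seq_len(config$inner_folds), n_train))
      best <- NULL
      for (a in config$alpha_grid) {
        cvf <- glmnet::cv.glmnet(
          xtr, ytr, alpha = 1 - a, foldid = foldid,
          nlambda = config$n_lambda, lambda.min.ratio = 1e-4,
          standardize = FALSE, family = "gaussian")
        err <- min(cvf$cvm)
        if (is.null(best) || err < best$err)
          best <- list(err = err, alpha = a, fit = cvf)
      }
      beta <- as.matrix(stats::coef(best$fit, s = "lambda.min"))[, 1]
      pred <- as.vector(cbind(1, xte) %*% beta)
      rho <- suppressWarnings(
        stats::cor(pred, yte, method = "spearman"))
      folds[[f]] <- tibble(
        fold = f, alpha = best$alpha,
        lambda = best$fit$lambda.min,
        spearman = if (is.na(rho)) 0 else rho,
        mse = mean((pred - yte)^2),
        n_nonzero = sum(beta[-1] != 0))
      coefs[[f]] <- tibble(fold = f, term = names(beta),
                           estimate = unname(beta))
    }
    structure(
      list(folds = bind_rows(folds), coefficients = bind_rows(coefs),
           features = feats, n = n, config = config),
      class = "regscore_fit")
  })
}

#' Fit the expression model straight from a feature matrix
#'
#' Convenience wrapper: [build_design()] then [fit_evaluate()].
#'
#' @inheritParams build_design
#' @inheritParams fit_evaluate
#' @return A `regscore_fit`.
#' @export
fit_expression_model <- function(features, expression,
                                 config = model_config()) {
  d <- build_design(features, expression)
  fit <- fit_evaluate(d$x, d$y, config)
  fit$variant <- variant_of(features)
  fit
}

#' @export
print.regscore_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<regscore_fit> %d features, %d genes, %d outer folds\n",
    length(x$features), x$n, nrow(x$folds)))
  cat(sprintf("  test Spearman %.3f (sd %.3f), MSE %.3f, mean ||beta||_0 %.1f\n",
              g$mean_spearman, g$sd_spearman, g$mean_mse, g$mean_nonzero))
  invisible(x)
}

#' Per-feature coefficient summary across outer folds
#'
#' @param x A `regscore_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term: mean `estimate` across
#'   outer folds, its standard deviation `sd`, and the number of folds in
#'   which the term was selected (nonzero).
#' @export
tidy.regscore_fit <- function(x, ...) {
  x$coefficients |>
    group_by(.data$term) |>
    summarise(sd = stats::sd(.data$estimate),
              n_nonzero_folds = sum(.data$estimate != 0),
              estimate = mean(.data$estimate)) |>
    select("term", "estimate", "sd", "n_nonzero_folds") |>
    arrange(match(.data$term, c("(Intercept)", x$features)))
}

#' One-row model summary
#'
#' @param x A `regscore_fit`.
#' @param ... Unused.
#' @return A tibble with the across-fold mean and sd of the held-out
#'   Spearman correlation and MSE, the mean number of nonzero
#'   coefficients, and the modal `(alpha, lambda)`.
#' @export
glance.regscore_fit <- function(x, ...) {
  tibble(
    mean_spearman = mean(x$folds$spearman),
    sd_spearman = stats::sd(x$folds$spearman),
    mean_mse = mean(x$folds$mse),
    sd_mse = stats::sd(x$folds$mse),
    mean_nonzero = mean(x$folds$n_nonzero),
    median_alpha = stats::median(x$folds$alpha),
    outer_folds = nrow(x$folds))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Across-fold standard deviation of each feature's coefficient
#'
#' Low values indicate stable feature selection across the outer
#' Monte-Carlo resamples.
#'
#' @param fit A `regscore_fit` with at least 2 folds.
#' @return A tibble with `term` and `sd` (intercept excluded).
#' @export
coefficient_stability <- function(fit) {
  if (nrow(fit$folds) < 2) abort("need >= 2 outer folds")
  tidy(fit) |>
    filter(.data$term != "(Intercept)") |>
    select("term", "sd")
}

#' Mean coefficient per feature (intercept dropped)
#'
#' Handy for ranking TFs before [gold_standard_eval()].
#'
#' @param fit A `regscore_fit`.
#' @return A named numeric vector of mean coefficients.
#' @export
mean_coefficients <- function(fit) {
  td <- tidy(fit) |> filter(.data$term != "(Intercept)")
  stats::setNames(td$estimate, td$term)
}
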