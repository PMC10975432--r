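#' Goodness-of-fit metrics
#'
#' Training-set fit statistics for a QSPR model with `p` descriptors:
#' `R2` is the squared Pearson correlation between observed and fitted
#' values, `R2_adj = 1 - (1 - R2)(n - 1)/(n - p - 1)`,
#' `RMSE = sqrt(mean(e^2))`, `MAE = mean(|e|)` and the standard error of
#' estimate `s = sqrt(sum(e^2)/(n - p - 1))`.
#'
#' @param y Observed responses.
#' @param y_hat Fitted/predicted responses.
#' @param p Number of descriptors in the model.
#' @return A one-row tibble: `r2`, `r2_adj`, `rmse`, `mae`, `s`.
#' @export
fit_metrics <- function(y, y_hat, p) {
  if (length(y) != length(y_hat)) abort("`y` and `y_hat` differ in length.")
  n <- length(y)
  if (n <= p + 1L) abort("Need n > p + 1.")
  if (sd(y) == 0) abort("R2 undefined: zero variance in `y`.")
  e <- y - y_hat
  r2 <- if (sd(y_hat) == 0) 0 else cor(y, y_hat)^2
  tibble(
    r2 = r2,
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    rmse = sqrt(mean(e^2)),
    mae = mean(abs(e)),
    s = sqrt(sum(e^2) / (n - p - 1))
  )
}

#' Leave-one-out cross-validated Q2
#'
#' For each observation `i` the model is refit on the remaining `n - 1`
#' observations and used to predict observation `i`;
#' `Q2_LOO = 1 - sum((y_i - y_hat_(-i))^2) / sum((y_i - mean(y))^2)` with
#' the mean taken over the full sample. `method = "refit"` runs the literal
#' n-refit loop for any learner; `method = "press"` uses the exact
#' closed-form PRESS shortcut `e_i / (1 - h_ii)` available for linear least
#' squares, and errors for anything else.
#'
#' @param data Data frame with descriptors and response.
#' @param response Response column name.
#' @param refit A function `function(data) -> model` returning an object
#'   with a `predict(model, newdata)` method (e.g. a [fit_mlr()] or
#'   [fit_learner()] wrapper).
#' @param method `"refit"` (default) or `"press"` (OLS only; `refit` must
#'   produce a `kca_mlr`).
#' @return Scalar Q2.
#' @export
q2_loo <- function(data, response = "log_kca", refit, method = c("refit", "press")) {
  method <- match.arg(method)
  data <- as.data.frame(data, check.names = FALSE)
  n <- nrow(data)
  if (n < 3L) abort("Q2_LOO needs at least 3 observations.")
  y <- data[[response]]
  if (method == "press") {
    model <- refit(data)
    if (!inherits(model, "kca_mlr")) {
      abort("PRESS shortcut requires an OLS (`kca_mlr`) model.")
    }
    X1 <- cbind(1, .descriptor_matrix(data, model$descriptors))
    h <- rowSums((X1 %*% solve(crossprod(X1))) * X1)
    press <- sum((model$residuals / (1 - h))^2)
    return(1 - press / sum((y - mean(y))^2))
  }
  press <- 0
  for (i in seq_len(n)) {
    model <- tryCatch(refit(data[-i, , drop = FALSE]), error = function(e) {
      abort(paste0("LOO refit failed at fold ", i, ": ", conditionMessage(e)))
    })
    pred <- unname(predict(model, data[i, , drop = FALSE]))
    press <- press + (y[i] - pred)^2
  }
  unname(1 - press / sum((y - mean(y))^2))
}

#' Bootstrap cross-validated Q2 (1/5 holdout)
#'
#' Repeats `iterations` times: hold out a random fifth (`holdout_fraction`)
#' of the distinct observations, draw a bootstrap resample of size `n` from
#' the remaining points, refit, and predict the held-out set. Predictive
#' residual sums of squares and the matching total sums of squares (about
#' the full-sample mean) are pooled across iterations:
#' `Q2_BOOT = 1 - sum(PRESS) / sum(TSS)`. The reference resampling scheme
#' uses 5000 iterations; reduce for quick checks.
#'
#' @inheritParams q2_loo
#' @param iterations Number of bootstrap iterations (default 5000).
#' @param holdout_fraction Fraction of distinct points held out (default 0.2).
#' @param seed Integer seed; same seed, same value.
#' @return Scalar Q2.
#' @export
q2_boot <- function(data, response = "log_kca", refit, iterations = 5000L,
                    holdout_fraction = 0.2, seed = 1L) {
  data <- as.data.frame(data, check.names = FALSE)
  n <- nrow(data)
  if (n < 10L) abort("Q2_BOOT needs at least 10 observations.")
  if (iterations < 1L) abort("`iterations` must be >= 1.")
  y <- data[[response]]
  ybar <- mean(y)
  n_out <- max(1L, round(holdout_fraction * n))
  press <- tss <- 0
  withr::with_seed(seed, {
    for (b in seq_len(iterations)) {
      out <- sample.int(n, n_out)
      pool <- setdiff(seq_len(n), out)
      boot <- sample(pool, n, replace = TRUE)
      model <- refit(data[boot, , drop = FALSE])
      pred <- predict(model, data[out, , drop = FALSE])
      press <- press + sum((y[out] - pred)^2)
      tss <- tss + sum((y[out] - ybar)^2)
    }
  })
  1 - press / tss
}

#' External (test-set) validation metrics
#'
#' Predictive metrics on a held-out test set: `r2_ext` is the squared
#' Pearson correlation; `q2_ext` the external explained variance
#' `1 - sum((y - y_hat)^2) / sum((y - ybar_train)^2)`, centered by default
#' on the training-set mean (the classical "F1" form; `"F2"` centers on the
#' test mean, `"F3"` rescales by training variance); `ccc` is Lin's
#' concordance correlation coefficient
#' `2 cov(y, y_hat) / (var(y) + var(y_hat) + (mean(y) - mean(y_hat))^2)`
#' with n-denominator moments, penalizing location and scale disagreement
#' that plain correlation ignores. `s_ext` uses `n - p - 1` degrees of
#' freedom.
#'
#' @param y_ext Observed test responses (length >= 3).
#' @param y_hat_ext Predicted test responses.
#' @param ybar_train Training-set response mean (used by the F1 form).
#' @param p Number of descriptors (for `s_ext`; default 4).
#' @param variant `"F1"` (default), `"F2"` or `"F3"`.
#' @param y_train Full training response vector; required for `"F3"`.
#' @return One-row tibble: `r2_ext`, `q2_ext`, `ccc`, `rmse_ext`, `mae_ext`,
#'   `s_ext`.
#' @export
external_metrics <- function(y_ext, y_hat_ext, ybar_train, p = 4L,
                             variant = c("F1", "F2", "F3"), y_train = NULL) {
  variant <- match.arg(variant)
  if (length(y_ext) != length(y_hat_ext)) abort("Length mismatch.")
  n <- length(y_ext)
  if (n < 3L) abort("External validation needs at least 3 test points.")
  if (sd(y_ext) == 0) abort("Zero variance in `y_ext`.")
  e <- y_ext - y_hat_ext
  sse <- sum(e^2)
  q2 <- switch(variant,
    F1 = 1 - sse / sum((y_ext - ybar_train)^2),
    F2 = 1 - sse / sum((y_ext - mean(y_ext))^2),
    F3 = {
      if (is.null(y_train)) abort("F3 variant needs `y_train`.")
      1 - (sse / n) / (sum((y_train - mean(y_train))^2) / length(y_train))
    }
  )
  my <- mean(y_ext); mp <- mean(y_hat_ext)
  vy <- mean((y_ext - my)^2); vp <- mean((y_hat_ext - mp)^2)
  cv <- mean((y_ext - my) * (y_hat_ext - mp))
  tibble(
    r2_ext = if (sd(y_hat_ext) == 0) 0 else cor(y_ext, y_hat_ext)^2,
    q2_ext = q2,
    ccc = 2 * cv / (vy + vp + (my - mp)^2),
    rmse_ext = sqrt(mean(e^2)),
    mae_ext = mean(abs(e)),
    # undefined when the test set is no larger than the model dimension
    s_ext = if (n > p + 1) sqrt(sse / (n - p - 1)) else NA_real_
  )
}

#' Acceptance thresholds for QSPR model validation
#'
#' The strict threshold battery used to admit a cuticle-air QSPR model:
#' `r2_adj > 0.7`, `q2_loo > 0.6`, `q2_boot > 0.6`, `r2_ext > 0.7`,
#' `q2_ext > 0.6` and `ccc > 0.85`.
#'
#' @return A tibble with columns `metric`, `threshold`.
#' @export
validation_thresholds <- function() {
  tibble(
    metric = c("r2_adj", "q2_loo", "q2_boot", "r2_ext", "q2_ext", "ccc"),
    threshold = c(0.7, 0.6, 0.6, 0.7, 0.6, 0.85)
  )
}

#' Assemble a validation report and check it against the thresholds
#'
#' Either supply a data frame of already-computed metric values (one row per
#' model, columns named as in [validation_thresholds()]), or let the
#' function compute everything from a refitter and a split dataset.
#'
#' @param metrics A data frame with (at least) columns `r2_adj`, `q2_loo`,
#'   `q2_boot`, `r2_ext`, `q2_ext`, `ccc`, and optionally a `model` id
#'   column.
#' @return A tibble in long form: `model`, `metric`, `value`, `threshold`,
#'   `pass` (thresholds are strict inequalities; metrics without a threshold
#'   are carried with `pass = NA`).
#' @export
check_thresholds <- function(metrics) {
  metrics <- as_tibble(metrics)
  if (!"model" %in% names(metrics)) {
    metrics$model <- paste0("model_", seq_len(nrow(metrics)))
  }
  th <- validation_thresholds()
  long <- metrics |>
    tidyr::pivot_longer(-dplyr::any_of("model"), names_to = "metric",
                        values_to = "value") |>
    dplyr::left_join(th, by = "metric") |>
    dplyr::mutate(pass = ifelse(is.na(.data$threshold), NA,
                                .data$value > .data$threshold))
  long
}

#' Full validation battery for one model on a split dataset
#'
#' Convenience driver: takes a refitter, a training and a test table, and
#' returns the whole report (fit metrics, LOO and bootstrap Q2, external
#' metrics) plus threshold verdicts.
#'
#' @param train,test Data frames with descriptors and the response.
#' @param response Response column name.
#' @param refit Function `data -> model` (with a `predict` method).
#' @param p Number of descriptors.
#' @param boot_iterations Bootstrap iterations (default 200 for interactive
#'   use; the reference scheme uses 5000).
#' @param seed Integer seed.
#' @param q2ext_variant Passed to [external_metrics()].
#' @return An object of class `validation_report`: a list with `metrics`
#'   (one-row tibble), `verdicts` (from [check_thresholds()]), `n_tra`,
#'   `n_ext`.
#' @export
validation_report <- function(train, test, response = "log_kca", refit,
                              p, boot_iterations = 200L, seed = 1L,
                              q2ext_variant = "F1") {
  model <- refit(train)
  y_tra <- train[[response]]
  fitm <- fit_metrics(y_tra, predict(model, train), p)
  q2l <- q2_loo(train, response, refit)
  q2b <- q2_boot(train, response, refit, iterations = boot_iterations,
                 seed = seed)
  ext <- external_metrics(test[[response]], predict(model, test),
                          ybar_train = mean(y_tra), p = p,
                          variant = q2ext_variant, y_train = y_tra)
  metrics <- dplyr::bind_cols(
    tibble(r2_adj = fitm$r2_adj, q2_loo = q2l, q2_boot = q2b,
           mae_tra = fitm$mae, rmse_tra = fitm$rmse, s_tra = fitm$s),
    ext
  )
  structure(
    list(metrics = metrics,
         verdicts = check_thresholds(metrics),
         n_tra = nrow(train), n_ext = nrow(test),
         model = model),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> n_tra =", x$n_tra, ", n_ext =", x$n_ext, "\n")
  v <- x$verdicts[!is.na(x$verdicts$pass), ]
  for (i in seq_len(nrow(v))) {
    cat(sprintf("  %-8s %6.3f  (> %.2f)  %s\n", v$metric[i], v$value[i],
                v$threshold[i], ifelse(v$pass[i], "PASS", "FAIL")))
  }
  invisible(x)
}

#' Cumulative distribution of absolute residuals across models
#'
#' For each model, the empirical CDF of residuals and the fraction of
#' residuals inside (-1, 1) log unit — the standard visual comparison of
#' competing QSPR models.
#'
#' @param predictions A data frame with columns `model`, `y`, `y_hat` (long
#'   form, one row per prediction).
#' @return A list with `fraction_within_1` (tibble `model`, `fraction`) and
#'   `cdf` (tibble `model`, `abs_residual`, `cdf`, non-decreasing and ending
#'   at 1 for every model).
#' @export
residual_cdf <- function(predictions) {
  predictions <- as_tibble(predictions)
  need <- c("model", "y", "y_hat")
  if (!all(need %in% names(predictions))) {
    abort("`predictions` needs columns model, y, y_hat.")
  }
  predictions <- predictions |>
    dplyr::mutate(residual = .data$y - .data$y_hat)
  frac <- predictions |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(fraction = mean(abs(.data$residual) < 1), .groups = "drop")
  cdf <- predictions |>
    dplyr::group_by(.data$model) |>
    dplyr::arrange(abs(.data$residual), .by_group = TRUE) |>
    dplyr::mutate(abs_residual = abs(.data$residual),
                  cdf = dplyr::row_number() / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("model", "abs_residual", "cdf")
  list(fraction_within_1 = frac, cdf = cdf)
}
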