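#' Construct an explicit linear QSPR model
#'
#' A linear model is the affine map `y_hat = X beta + b` over named
#' descriptor columns. Use this to encode literature-reported coefficient
#' sets or any externally fitted MLR model.
#'
#' @param coefficients A named numeric vector of slopes (log Kca per
#'   descriptor unit).
#' @param intercept Scalar intercept (log Kca units).
#' @return An object of class `linear_model`.
#' @seealso [mlr_preset()] for the published cuticle-air models.
#' @export
linear_model <- function(coefficients, intercept) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    abort("`coefficients` must be a fully named numeric vector.")
  }
  stopifnot(is.numeric(coefficients), is.numeric(intercept),
            length(intercept) == 1L)
  structure(
    list(coefficients = coefficients, intercept = unname(intercept),
         descriptors = names(coefficients)),
    class = "linear_model"
  )
}

#' Literature MLR models for log Kca
#'
#' The two reported four-descriptor MLR equations for the cuticle-air
#' partition coefficient: `"replicate"` was fitted on the replicate-level
#' dataset (one record per species/tissue measurement, n_tra = 204) over
#' `VE1_L`, `LLS_02`, `H_Dz(p)` and `SpMax2_Bh(v)`; `"averaged"` on the
#' compound-averaged dataset (n_tra = 84) over `SpPos_A`, `LLS_02`, `LLS_01`
#' and `SpMax2_Bh(v)`.
#'
#' @param which `"replicate"` or `"averaged"`.
#' @return A [linear_model()].
#' @examples
#' predict(mlr_preset("averaged"),
#'         tibble::tibble(SpPos_A = 0, LLS_02 = 0, LLS_01 = 0,
#'                        `SpMax2_Bh(v)` = 0))  # the intercept, -15.724
#' @export
mlr_preset <- function(which = c("replicate", "averaged")) {
  which <- match.arg(which)
  if (which == "replicate") {
    linear_model(
      c("VE1_L" = 2.006, "LLS_02" = 14.945, "H_Dz(p)" = 0.094,
        "SpMax2_Bh(v)" = -1.044),
      intercept = -13.433
    )
  } else {
    linear_model(
      c("SpPos_A" = 1.325, "LLS_02" = 12.317, "LLS_01" = 7.385,
        "SpMax2_Bh(v)" = -1.517),
      intercept = -15.724
    )
  }
}

#' @export
print.linear_model <- function(x, ...) {
  cat("<linear_model> log_kca ~", paste(x$descriptors, collapse = " + "), "\n")
  print(round(c(x$coefficients, `(intercept)` = x$intercept), 4))
  invisible(x)
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  X <- .descriptor_matrix(newdata, object$descriptors)
  drop(X %*% object$coefficients + object$intercept)
}

# Validate + extract the named descriptor columns as a numeric matrix;
# never reorders silently: requested names drive the column order.
.descriptor_matrix <- function(data, descriptors) {
  data <- as.data.frame(data, check.names = FALSE)
  missing <- setdiff(descriptors, names(data))
  if (length(missing)) {
    abort(paste0("Descriptor column(s) missing from data: ",
                 paste(missing, collapse = ", ")))
  }
  X <- as.matrix(data[descriptors])
  if (!is.numeric(X)) abort("Descriptor columns must be numeric.")
  if (any(!is.finite(X))) abort("Descriptor columns contain non-finite values.")
  X
}

#' Ordinary least squares fit of log Kca on descriptors
#'
#' QR-based least squares (via [stats::lm()]) of a response on named
#' descriptor columns, returned as a `kca_mlr` object that also behaves as a
#' [linear_model()] for prediction. Per-coefficient t-test p-values and
#' residuals are retained.
#'
#' @param data A data frame holding descriptor columns and the response.
#' @param response Name of the response column (default `"log_kca"`).
#' @param descriptors Character vector of descriptor column names; default:
#'   every numeric column except the response.
#' @return A `kca_mlr` object with elements `coefficients`, `intercept`,
#'   `descriptors`, `p_values`, `residuals`, `fitted`, `sigma`, `n`, `p`.
#' @export
fit_mlr <- function(data, response = "log_kca", descriptors = NULL) {
  data <- as.data.frame(data, check.names = FALSE)
  if (!response %in% names(data)) {
    abort(paste0("Response column '", response, "' not found."))
  }
  if (is.null(descriptors)) {
    descriptors <- names(data)[vapply(data, is.numeric, logical(1))]
    descriptors <- setdiff(descriptors, response)
  }
  if (!length(descriptors)) abort("No descriptor columns to fit.")
  y <- data[[response]]
  X <- .descriptor_matrix(data, descriptors)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) abort("Need n > p + 1 observations to fit OLS.")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1L) {
    dep <- descriptors[qrX$pivot[seq(qrX$rank + 1L, p + 1L)] - 1L]
    abort(paste0("Rank-deficient design; dependent column(s): ",
                 paste(dep, collapse = ", ")))
  }
  fit <- lm(y ~ X)   # matrix interface: descriptor names may be non-syntactic
  # noiseless synthetic responses are a supported use; summary()'s
  # perfect-fit warning is expected there
  sm <- suppressWarnings(summary(fit))
  cf <- coef(fit)
  structure(
    list(
      coefficients = setNames(cf[-1L], descriptors),
      intercept = unname(cf[1L]),
      descriptors = descriptors,
      p_values = setNames(sm$coefficients[-1L, 4L], descriptors),
      residuals = unname(fit$residuals),
      fitted = unname(fit$fitted.values),
      sigma = sm$sigma,
      n = n, p = p,
      lm = fit
    ),
    class = c("kca_mlr", "linear_model")
  )
}

#' @export
print.kca_mlr <- function(x, ...) {
  cat("<kca_mlr> n =", x$n, ", p =", x$p, "\n")
  print(round(c(x$coefficients, `(intercept)` = x$intercept), 4))
  invisible(x)
}

#' @export
tidy.kca_mlr <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble(
    term = c("(Intercept)", x$descriptors),
    estimate = unname(sm[, 1L]),
    std.error = unname(sm[, 2L]),
    statistic = unname(sm[, 3L]),
    p.value = unname(sm[, 4L])
  )
}

#' @export
glance.kca_mlr <- function(x, ...) {
  y <- x$fitted + x$residuals
  m <- fit_metrics(y, x$fitted, x$p)
  dplyr::bind_cols(tibble(n = x$n, p = x$p), m)
}

#' Drop uninformative and redundant descriptor columns
#'
#' The two-step prefilter applied to a raw descriptor pool before model
#' building: (1) remove columns with any missing value, zero variance, or
#' near-constant values (the modal value occupying more than
#' `near_constant_fraction` of rows); (2) walk the remaining columns in
#' decreasing order of absolute correlation with the response and greedily
#' drop the weaker member of every pair whose absolute Pearson correlation
#' exceeds `r_max` — so of two interchangeable descriptors the one more
#' correlated with `y` survives.
#'
#' @param data Data frame of descriptor columns (plus optionally the
#'   response and id columns, which pass through untouched).
#' @param response Name of the response column used for tie-breaking
#'   (default `"log_kca"`); must be present.
#' @param r_max Pairwise absolute-correlation ceiling (default 0.9).
#' @param near_constant_fraction Modal-share threshold above which a column
#'   counts as near-constant (default 0.95).
#' @return The filtered tibble; dropped column names and reasons are in
#'   attribute `"dropped"`.
#' @export
prefilter_descriptors <- function(data, response = "log_kca", r_max = 0.9,
                                  near_constant_fraction = 0.95) {
  data <- as_tibble(data)
  if (!response %in% names(data)) {
    abort(paste0("Response column '", response, "' not found."))
  }
  y <- data[[response]]
  keep_always <- names(data)[!vapply(data, is.numeric, logical(1))]
  keep_always <- union(keep_always, response)
  cand <- setdiff(names(data), keep_always)

  dropped <- list()
  ok <- character()
  for (nm in cand) {
    x <- data[[nm]]
    if (anyNA(x)) {
      dropped[[nm]] <- "missing values"
    } else if (var(x) == 0) {
      dropped[[nm]] <- "constant"
    } else if (max(table(x)) / length(x) > near_constant_fraction) {
      dropped[[nm]] <- "near-constant"
    } else {
      ok <- c(ok, nm)
    }
  }
  # greedy correlation filter, scan order = decreasing |cor with y|
  ok <- ok[order(-abs(vapply(ok, function(nm) cor(data[[nm]], y), numeric(1))))]
  kept <- character()
  for (nm in ok) {
    r_with_kept <- vapply(kept, function(k) abs(cor(data[[nm]], data[[k]])),
                          numeric(1))
    if (length(r_with_kept) && any(r_with_kept > r_max)) {
      dropped[[nm]] <- paste0("|r| > ", r_max, " with ",
                              kept[which.max(r_with_kept)])
    } else {
      kept <- c(kept, nm)
    }
  }
  if (!length(kept)) abort("Prefilter removed every descriptor column.")
  out <- data[c(intersect(names(data), keep_always),
                intersect(names(data), kept))]
  attr(out, "dropped") <- if (length(dropped)) {
    tibble(column = names(dropped), reason = unlist(dropped))
  } else {
    tibble(column = character(), reason = character())
  }
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from the OLS regression of
#' descriptor `j` on all other descriptors plus an intercept. Perfectly
#' collinear columns report `Inf` rather than erroring.
#'
#' @param data A data frame; all numeric columns are used.
#' @param descriptors Optional character vector restricting the columns.
#' @return A tibble with columns `descriptor`, `vif`.
#' @export
vif <- function(data, descriptors = NULL) {
  data <- as.data.frame(data, check.names = FALSE)
  if (is.null(descriptors)) {
    descriptors <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  if (length(descriptors) < 2L) abort("VIF needs at least 2 descriptor columns.")
  X <- .descriptor_matrix(data, descriptors)
  if (nrow(X) <= ncol(X) + 1L) abort("VIF needs n > p + 1 rows.")
  v <- vapply(seq_along(descriptors), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(descriptor = descriptors, vif = v)
}

#' Forward-stepwise MLR with backward elimination and a VIF gate
#'
#' Classic stepwise descriptor selection: at each step the candidate with
#' the smallest entry p-value below `p_enter` is added — unless adding it
#' pushes any variance inflation factor to `vif_max` or beyond — then any
#' included descriptor whose p-value has drifted above `p_remove` is dropped
#' again. Selection stops when `max_p` descriptors are included or no
#' admissible candidate remains. Entry/removal thresholds default to the
#' common stepwise-regression convention (0.05 / 0.10).
#'
#' @param data Data frame with descriptors and response.
#' @param response Response column name (default `"log_kca"`).
#' @param descriptors Candidate descriptor names; default all numeric
#'   columns except the response.
#' @param max_p Maximum number of descriptors in the final model (default 4).
#' @param vif_max VIF ceiling; a step creating `VIF >= vif_max` is rejected
#'   (default 10).
#' @param p_enter,p_remove Entry / removal p-value thresholds.
#' @return The final `kca_mlr` fit, with the selection trace (a tibble of
#'   `step`, `action`, `descriptor`, `p_value`) in attribute `"trace"`.
#' @export
stepwise_mlr <- function(data, response = "log_kca", descriptors = NULL,
                         max_p = 4L, vif_max = 10, p_enter = 0.05,
                         p_remove = 0.10) {
  data <- as.data.frame(data, check.names = FALSE)
  if (is.null(descriptors)) {
    descriptors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                           response)
  }
  included <- character()
  trace <- list()
  step_no <- 0L
  best_rejected <- NULL

  entry_p <- function(cand) {
    tryCatch({
      fit <- fit_mlr(data, response, c(included, cand))
      unname(fit$p_values[cand])
    }, error = function(e) Inf)   # rank-deficient trial -> inadmissible
  }
  repeat {
    if (length(included) >= max_p) break
    cands <- setdiff(descriptors, included)
    if (!length(cands)) break
    pvals <- vapply(cands, entry_p, numeric(1))
    ord <- order(pvals)
    added <- FALSE
    for (k in ord) {
      if (pvals[k] >= p_enter) break
      trial <- c(included, cands[k])
      if (length(trial) >= 2L) {
        v <- vif(data, trial)$vif
        if (any(v >= vif_max)) {
          best_rejected <- best_rejected %||% cands[k]
          next
        }
      }
      included <- trial
      step_no <- step_no + 1L
      trace[[length(trace) + 1L]] <- tibble(
        step = step_no, action = "add", descriptor = cands[k],
        p_value = unname(pvals[k])
      )
      added <- TRUE
      break
    }
    if (!added) break
    # backward pass
    repeat {
      fit <- fit_mlr(data, response, included)
      worst <- which.max(fit$p_values)
      if (fit$p_values[worst] <= p_remove || length(included) == 1L) break
      step_no <- step_no + 1L
      trace[[length(trace) + 1L]] <- tibble(
        step = step_no, action = "remove",
        descriptor = included[worst],
        p_value = unname(fit$p_values[worst])
      )
      included <- included[-worst]
    }
  }
  if (!length(included)) {
    msg <- "No descriptor passed the entry threshold."
    if (!is.null(best_rejected)) {
      msg <- paste0(msg, " Best candidate rejected by the VIF gate: ",
                    best_rejected, ".")
    }
    abort(msg)
  }
  fit <- fit_mlr(data, response, included)
  attr(fit, "trace") <- dplyr::bind_rows(trace)
  fit
}
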