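#' Default hyperparameter grids for the nonlinear learners
#'
#' Modest, fully documented defaults: distance-weighted KNN searches the
#' neighborhood size, the gradient-boosted trees search ensemble size, tree
#' depth and shrinkage, and the single-hidden-layer network searches width
#' and weight decay. Any grid can be overridden via the `grid` argument of
#' [fit_learner()].
#'
#' @param learner One of `"knn"`, `"gbdt"`, `"mlp"`, `"mlr"`.
#' @return A named list of candidate value vectors (empty for `"mlr"`).
#' @export
default_grid <- function(learner = c("knn", "gbdt", "mlp", "mlr")) {
  learner <- match.arg(learner)
  switch(learner,
    knn  = list(k = 1:15),
    gbdt = list(n_trees = c(50L, 100L, 200L, 500L), max_depth = 2:5,
                learning_rate = c(0.05, 0.1, 0.2)),
    mlp  = list(size = c(4L, 8L, 16L), decay = c(1e-4, 1e-3, 1e-2)),
    mlr  = list()
  )
}

#' Fit a QSPR learner with grid-searched k-fold cross-validation
#'
#' Exhaustive grid search over the supplied hyperparameter grid, scored by
#' the mean k-fold cross-validated score (`"r2"` — squared Pearson
#' correlation between held-out observations and predictions — by default,
#' `"rmse"` selectable). The winning cell is refit on the full training
#' data. Fold assignment, learner initialization and the final refit are all
#' derived deterministically from `seed`.
#'
#' Learners: `"mlr"` (ordinary least squares; grid ignored), `"knn"`
#' (distance-weighted k-nearest-neighbor regression on standardized
#' descriptors), `"gbdt"` (stagewise least-squares gradient boosting over
#' depth-limited regression trees, shrunk by a learning rate), `"mlp"`
#' (single-hidden-layer feed-forward network on standardized descriptors
#' and response). Standardization parameters are learned on the training
#' folds only.
#'
#' @param data Data frame with descriptor columns and the response.
#' @param response Response column name (default `"log_kca"`).
#' @param learner `"mlr"`, `"knn"`, `"gbdt"` or `"mlp"`.
#' @param descriptors Descriptor column names; default all numeric columns
#'   except the response.
#' @param grid Hyperparameter grid (named list of candidate vectors);
#'   default [default_grid()].
#' @param folds Number of CV folds (default 5; must be >= 2 and <= n).
#' @param seed Integer seed.
#' @param metric CV scoring metric, `"r2"` (maximized) or `"rmse"`
#'   (minimized).
#' @return A `kca_learner` object: elements `learner`, `params` (winning
#'   cell), `cv` (tibble of every cell's mean score), `state`,
#'   `descriptors`, `seed`. Predict with [predict.kca_learner()].
#' @export
fit_learner <- function(data, response = "log_kca",
                        learner = c("mlr", "knn", "gbdt", "mlp"),
                        descriptors = NULL, grid = NULL, folds = 5L,
                        seed = 1L, metric = c("r2", "rmse")) {
  learner <- match.arg(learner)
  metric <- match.arg(metric)
  data <- as.data.frame(data, check.names = FALSE)
  if (is.null(descriptors)) {
    descriptors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                           response)
  }
  X <- .descriptor_matrix(data, descriptors)
  y <- data[[response]]
  n <- nrow(X)
  if (folds < 2L || folds > n) abort("`folds` must be in 2..n.")
  grid <- grid %||% default_grid(learner)
  if (learner != "mlr" && !length(grid)) {
    abort("Nonlinear learners need a non-empty hyperparameter grid.")
  }
  cells <- if (length(grid)) {
    expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(row.names = 1)
  }

  engine <- .learner_engine(learner)
  cv_scores <- rep(NA_real_, nrow(cells))
  failures <- character()

  if (nrow(cells) > 1L) {
    fold_id <- withr::with_seed(seed, sample(rep(seq_len(folds),
                                                 length.out = n)))
    for (ci in seq_len(nrow(cells))) {
      params <- as.list(cells[ci, , drop = FALSE])
      scores <- numeric(folds)
      bad <- FALSE
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        res <- tryCatch({
          st <- withr::with_seed(seed + f, engine$fit(X[tr, , drop = FALSE],
                                                      y[tr], params))
          pred <- engine$predict(st, X[!tr, , drop = FALSE])
          .cv_score(y[!tr], pred, metric)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures <- c(failures, paste0("cell ", ci, " fold ", f, ": ",
                                         conditionMessage(res)))
          bad <- TRUE
          break
        }
        scores[f] <- res
      }
      if (!bad) cv_scores[ci] <- mean(scores)
    }
    if (all(is.na(cv_scores))) {
      abort(paste0("Every grid cell failed. First failure: ", failures[1]))
    }
    best <- if (metric == "r2") which.max(cv_scores) else which.min(cv_scores)
  } else {
    best <- 1L
  }
  params <- as.list(cells[best, , drop = FALSE])
  state <- withr::with_seed(seed, engine$fit(X, y, params))
  structure(
    list(
      learner = learner,
      params = params,
      cv = dplyr::bind_cols(as_tibble(cells),
                            tibble(score = cv_scores))[
                              order(cv_scores,
                                    decreasing = (metric == "r2")), ],
      metric = metric,
      folds = folds,
      seed = seed,
      state = state,
      descriptors = descriptors,
      failures = failures
    ),
    class = "kca_learner"
  )
}

.cv_score <- function(y, pred, metric) {
  if (metric == "rmse") return(sqrt(mean((y - pred)^2)))
  if (sd(pred) < 1e-12 || sd(y) < 1e-12) return(0)
  cor(y, pred)^2
}

#' @export
print.kca_learner <- function(x, ...) {
  cat("<kca_learner>", x$learner, "on",
      paste(x$descriptors, collapse = ", "), "\n")
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict from a fitted QSPR learner
#'
#' @param object A `kca_learner` from [fit_learner()].
#' @param newdata Data frame containing the training descriptor columns (a
#'   name mismatch is an error, never a silent reordering).
#' @param ... Unused.
#' @return A numeric vector of predictions, one per row.
#' @export
predict.kca_learner <- function(object, newdata, ...) {
  X <- .descriptor_matrix(newdata, object$descriptors)
  engine <- .learner_engine(object$learner)
  pred <- engine$predict(object$state, X)
  if (any(!is.finite(pred))) abort("Learner produced non-finite predictions.")
  pred
}

# ---- engines ---------------------------------------------------------------

.learner_engine <- function(learner) {
  switch(learner,
    mlr = list(
      fit = function(X, y, params) {
        df <- data.frame(y = y, X)
        list(fit = lm(y ~ ., data = df), cols = colnames(X))
      },
      predict = function(state, X) {
        unname(predict(state$fit, data.frame(X)))
      }
    ),
    knn = list(
      fit = function(X, y, params) {
        k <- params$k %||% 5L
        if (k < 1L || k > nrow(X)) stop("k outside 1..n_train")
        mu <- colMeans(X); sdv <- apply(X, 2, sd)
        sdv[sdv == 0] <- 1
        list(X = sweep(sweep(X, 2, mu), 2, sdv, "/"), y = y, k = k,
             mu = mu, sd = sdv)
      },
      predict = function(state, X) {
        Xs <- sweep(sweep(X, 2, state$mu), 2, state$sd, "/")
        apply(Xs, 1, function(q) {
          d <- sqrt(colSums((t(state$X) - q)^2))
          nn <- order(d)[seq_len(state$k)]
          dn <- d[nn]
          if (any(dn < 1e-12)) return(mean(state$y[nn[dn < 1e-12]]))
          w <- 1 / dn
          sum(w * state$y[nn]) / sum(w)
        })
      }
    ),
    gbdt = list(
      fit = function(X, y, params) {
        n_trees <- params$n_trees %||% 100L
        depth <- params$max_depth %||% 3L
        lr <- params$learning_rate %||% 0.1
        df <- data.frame(X)
        f <- rep(mean(y), length(y))
        trees <- vector("list", n_trees)
        mse <- numeric(n_trees)
        ctrl <- rpart::rpart.control(maxdepth = depth, cp = 0, xval = 0,
                                     minsplit = max(2L, min(10L, length(y) %/% 5L)),
                                     minbucket = 1L)
        for (m in seq_len(n_trees)) {
          df$.r <- y - f
          tr <- rpart::rpart(.r ~ ., data = df, method = "anova",
                             control = ctrl)
          f <- f + lr * unname(predict(tr, df))
          trees[[m]] <- tr
          mse[m] <- mean((y - f)^2)
        }
        list(f0 = mean(y), trees = trees, lr = lr, stage_mse = mse,
             cols = colnames(df)[colnames(df) != ".r"])
      },
      predict = function(state, X) {
        df <- data.frame(X)
        pred <- rep(state$f0, nrow(df))
        for (tr in state$trees) pred <- pred + state$lr * unname(predict(tr, df))
        pred
      }
    ),
    mlp = list(
      fit = function(X, y, params) {
        size <- params$size %||% 8L
        decay <- params$decay %||% 1e-3
        mu <- colMeans(X); sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
        ym <- mean(y); ys <- sd(y); if (ys == 0) ys <- 1
        Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
        fit <- nnet::nnet(Xs, (y - ym) / ys, size = size, decay = decay,
                          linout = TRUE, maxit = 500, trace = FALSE)
        list(fit = fit, mu = mu, sd = sdv, ym = ym, ys = ys)
      },
      predict = function(state, X) {
        Xs <- sweep(sweep(X, 2, state$mu), 2, state$sd, "/")
        drop(predict(state$fit, Xs)) * state$ys + state$ym
      }
    ),
    abort(paste0("Unknown learner '", learner, "'."))
  )
}
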