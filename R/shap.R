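#' Exact Shapley attributions by coalition enumeration
#'
#' Model-agnostic Shapley values with the interventional (marginal) value
#' function: for a coalition `S` of descriptors, `v(S)` is the model
#' prediction averaged over the background rows with the descriptors in `S`
#' fixed at the query values. The attribution of descriptor `j` is the
#' Shapley sum over all `2^(p-1)` coalitions not containing `j`,
#' `phi_j = sum_S |S|! (p - |S| - 1)! / p! * (v(S + j) - v(S))`.
#' With the four-descriptor models used here the 16 coalitions are
#' enumerated exactly — no sampling, fully deterministic — and the
#' efficiency axiom `baseline + sum_j phi_j = prediction` holds to
#' round-off.
#'
#' @param model Any model with a `predict(model, newdata)` method over named
#'   descriptor columns (a [linear_model()], [fit_mlr()] or [fit_learner()]
#'   result).
#' @param background Data frame of background rows defining the reference
#'   distribution (typically the training set). Capped at `max_background`
#'   rows by seeded subsampling.
#' @param query Data frame of rows to explain (default: the background).
#' @param descriptors Descriptor names; default `model$descriptors`.
#' @param max_background Cap on background rows (default 500).
#' @param seed Seed for the background subsample.
#' @return A `shap_explanation`: tibble with one row per query row, the
#'   per-descriptor Shapley columns (log Kca units), plus `baseline` and
#'   `prediction`. Descriptor values of the query rows are retained in
#'   attribute `"query"`.
#' @export
exact_shap <- function(model, background, query = background,
                       descriptors = NULL, max_background = 500L, seed = 1L) {
  descriptors <- descriptors %||% model$descriptors
  if (is.null(descriptors)) abort("Supply `descriptors` for this model type.")
  p <- length(descriptors)
  if (p > 12L) {
    abort(paste0("Exact enumeration over 2^", p, " coalitions is infeasible;",
                 " p <= 12 required (a sampling approximation is out of scope)."))
  }
  B <- as.data.frame(background, check.names = FALSE)[descriptors]
  if (!nrow(B)) abort("Background set is empty.")
  if (nrow(B) > max_background) {
    B <- B[withr::with_seed(seed, sample.int(nrow(B), max_background)), ,
           drop = FALSE]
  }
  Q <- as.data.frame(query, check.names = FALSE)[descriptors]
  nb <- nrow(B); nq <- nrow(Q)

  # all 2^p coalitions as a logical matrix (rows = coalitions)
  coal <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  colnames(coal) <- descriptors
  sizes <- rowSums(coal)
  fact <- factorial(0:p)
  # |S|! (p - |S| - 1)! / p!; the full coalition never acts as an S, so its
  # slot is zeroed rather than indexing (-1)!
  w <- numeric(length(sizes))
  partial <- sizes < p
  w[partial] <- fact[sizes[partial] + 1L] * fact[p - sizes[partial]] /
    fact[p + 1L]

  # v(S) for every coalition and query row; one batched predict per
  # coalition over the nq * nb synthetic rows
  v <- matrix(NA_real_, nrow(coal), nq)
  B_rep <- B[rep(seq_len(nb), times = nq), , drop = FALSE]
  q_idx <- rep(seq_len(nq), each = nb)
  for (ci in seq_len(nrow(coal))) {
    S <- coal[ci, ]
    if (!any(S)) {
      v[ci, ] <- mean(predict(model, B))
      next
    }
    mixed <- B_rep
    mixed[, S] <- Q[q_idx, S, drop = FALSE]
    pred <- predict(model, mixed)
    v[ci, ] <- colMeans(matrix(pred, nrow = nb, ncol = nq))
  }

  coal_key <- apply(coal, 1, paste0, collapse = "")
  phi <- matrix(0, nq, p, dimnames = list(NULL, descriptors))
  for (j in seq_len(p)) {
    without <- which(!coal[, j])
    for (ci in without) {
      Sj <- coal[ci, ]; Sj[j] <- TRUE
      cj <- match(paste0(Sj, collapse = ""), coal_key)
      phi[, j] <- phi[, j] + w[ci] * (v[cj, ] - v[ci, ])
    }
  }
  baseline <- v[match(paste0(rep(FALSE, p), collapse = ""), coal_key), 1L]
  out <- as_tibble(phi)
  out$baseline <- baseline
  out$prediction <- drop(v[match(paste0(rep(TRUE, p), collapse = ""), coal_key), ])
  attr(out, "query") <- as_tibble(Q)
  attr(out, "descriptors") <- descriptors
  class(out) <- c("shap_explanation", class(out))
  out
}

#' Rank descriptors by mean absolute Shapley value
#'
#' The global importance of a descriptor is the mean of its absolute Shapley
#' values across samples, reported in descending order (the ordering used on
#' the y-axis of SHAP summary plots). The sign of association between a
#' descriptor's value and its attribution is the Spearman correlation across
#' samples, labeled positive/negative when `|rho|` exceeds `rho_threshold`
#' and indeterminate otherwise.
#'
#' @param explanation A `shap_explanation` from [exact_shap()] with >= 2
#'   rows.
#' @param rho_threshold Association threshold on `|rho|` (default 0.3).
#' @return A tibble with `descriptor`, `mean_abs_shap`, `rho`,
#'   `association`, sorted by decreasing `mean_abs_shap`.
#' @export
shap_summary <- function(explanation, rho_threshold = 0.3) {
  if (!inherits(explanation, "shap_explanation")) {
    abort("`explanation` must come from exact_shap().")
  }
  if (nrow(explanation) < 2L) {
    abort("Need at least 2 explained samples to summarise.")
  }
  descriptors <- attr(explanation, "descriptors")
  qvals <- attr(explanation, "query")
  rows <- purrr::map(descriptors, function(d) {
    phi <- explanation[[d]]
    x <- qvals[[d]]
    rho <- if (sd(phi) == 0 || sd(x) == 0) 0 else {
      suppressWarnings(cor(x, phi, method = "spearman"))
    }
    tibble(
      descriptor = d,
      mean_abs_shap = mean(abs(phi)),
      rho = rho,
      association = dplyr::case_when(
        abs(rho) <= rho_threshold ~ "indeterminate",
        rho > 0 ~ "positive",
        TRUE ~ "negative"
      )
    )
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(dplyr::desc(.data$mean_abs_shap))
}

#' Beeswarm-style summary plot of Shapley attributions
#'
#' @param explanation A `shap_explanation`.
#' @param ... Unused.
#' @return A ggplot: per-descriptor Shapley value distributions, descriptors
#'   ordered by mean absolute attribution, points coloured by the (scaled)
#'   descriptor value.
#' @export
autoplot.shap_explanation <- function(explanation, ...) {
  descriptors <- attr(explanation, "descriptors")
  qvals <- attr(explanation, "query")
  ord <- shap_summary(explanation)$descriptor
  long <- purrr::map(descriptors, function(d) {
    x <- qvals[[d]]
    scaled <- if (sd(x) == 0) rep(0.5, length(x)) else {
      (x - min(x)) / (max(x) - min(x))
    }
    tibble(descriptor = d, shap = explanation[[d]], value = scaled)
  }) |> dplyr::bind_rows()
  long$descriptor <- factor(long$descriptor, levels = rev(ord))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$shap, y = .data$descriptor,
                                     colour = .data$value)) +
    ggplot2::geom_jitter(height = 0.15, alpha = 0.7) +
    ggplot2::scale_colour_gradient(low = "#3b4cc0", high = "#b40426",
                                   name = "descriptor\nvalue (scaled)") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Shapley value (log Kca)", y = NULL) +
    ggplot2::theme_minimal()
}
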