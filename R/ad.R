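#' Leverage-based applicability domain (Williams table)
#'
#' Computes, for every query point, the leverage
#' `h = x' (X'X)^{-1} x` on the intercept-augmented training descriptor
#' matrix, the standardized residual `delta = residual / s`, and the
#' Williams-plot class: points with `h > h*` and `|delta| > 3` are
#' structural outliers predicted badly; `h > h*` with `|delta| <= 3` are
#' "good high leverage" points; `h <= h*` with `|delta| > 3` are response
#' outliers; everything else is in-domain. The warning leverage is the
#' standard `h* = 3 (p + 1) / n_train`. For nonlinear learners the leverage
#' is computed on the same descriptor design matrix (it is a property of
#' the descriptor space, not of the fitted function), mirroring common QSAR
#' practice.
#'
#' @param train Data frame of training descriptors.
#' @param query Data frame of query descriptors (may be the training set
#'   itself; default).
#' @param residuals Residuals for the query points (observed - predicted).
#' @param s Standard error of estimate used to standardize residuals.
#' @param descriptors Descriptor column names; default all numeric columns
#'   shared by `train` and `query`.
#' @return A `williams_table`: tibble with columns `h`, `delta`, `class`
#'   (factor: `in_domain`, `good_high_leverage`, `response_outlier`,
#'   `structural_outlier`), plus attributes `h_star`, `p`, `n_train`.
#' @export
applicability_domain <- function(train, query = train, residuals, s,
                                 descriptors = NULL) {
  train <- as.data.frame(train, check.names = FALSE)
  query <- as.data.frame(query, check.names = FALSE)
  if (is.null(descriptors)) {
    descriptors <- intersect(
      names(train)[vapply(train, is.numeric, logical(1))],
      names(query)[vapply(query, is.numeric, logical(1))]
    )
    descriptors <- setdiff(descriptors, c("log_kca", "split"))
  }
  Xt <- cbind(1, .descriptor_matrix(train, descriptors))
  Xq <- cbind(1, .descriptor_matrix(query, descriptors))
  if (length(residuals) != nrow(Xq)) {
    abort("`residuals` must have one value per query row.")
  }
  if (!is.numeric(s) || length(s) != 1L || s <= 0) {
    abort("`s` must be a positive scalar standard error.")
  }
  XtX <- crossprod(Xt)
  inv <- tryCatch(solve(XtX), error = function(e) {
    abort("Singular X'X: training descriptors are collinear.")
  })
  h <- rowSums((Xq %*% inv) * Xq)
  p <- length(descriptors)
  n_tra <- nrow(Xt)
  h_star <- 3 * (p + 1) / n_tra
  delta <- residuals / s
  class <- dplyr::case_when(
    h > h_star & abs(delta) > 3 ~ "structural_outlier",
    h > h_star ~ "good_high_leverage",
    abs(delta) > 3 ~ "response_outlier",
    TRUE ~ "in_domain"
  )
  out <- tibble(
    h = h, delta = delta,
    class = factor(class, levels = c("in_domain", "good_high_leverage",
                                     "response_outlier", "structural_outlier"))
  )
  if ("compound_id" %in% names(query)) {
    out <- dplyr::bind_cols(tibble(compound_id = query$compound_id), out)
  }
  attr(out, "h_star") <- h_star
  attr(out, "p") <- p
  attr(out, "n_train") <- n_tra
  class(out) <- c("williams_table", class(out))
  out
}

#' Williams plot of a leverage/residual table
#'
#' @param object A `williams_table` from [applicability_domain()].
#' @param ... Unused.
#' @return A ggplot: leverage versus standardized residual with the `h*`
#'   and `|delta| = 3` guides.
#' @export
autoplot.williams_table <- function(object, ...) {
  h_star <- attr(object, "h_star")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$h, y = .data$delta,
                                       colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = h_star, linetype = "dashed") +
    ggplot2::labs(x = "leverage h", y = expression(delta),
                  title = "Williams plot",
                  subtitle = sprintf("h* = %.4f", h_star)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.williams_table
#' @param x A `williams_table`.
#' @param y Ignored.
#' @export
plot.williams_table <- function(x, y, ...) print(autoplot(x, ...))
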