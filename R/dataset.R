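#' Derive log Kca from cuticle-water and air-water partition coefficients
#'
#' Thermodynamic identity on the log10 scale: a compound's cuticle-air
#' partition coefficient is the ratio of its cuticle-water and air-water
#' coefficients, so `log_kca = log_kcw - log_kaw`. Rows that already carry a
#' measured `log_kca` are left untouched.
#'
#' @param data A data frame of measurement records. Needs either a `log_kca`
#'   column or the pair `log_kcw`, `log_kaw` (row-wise, exactly one of the
#'   two routes per record).
#' @return `data` as a tibble with `log_kca` filled for every row.
#' @examples
#' derive_log_kca(tibble::tibble(log_kcw = 5, log_kaw = 2, log_kca = NA))
#' @export
derive_log_kca <- function(data) {
  data <- as_tibble(data)
  if (!"log_kca" %in% names(data)) data$log_kca <- NA_real_
  needs <- is.na(data$log_kca)
  if (any(needs)) {
    if (!all(c("log_kcw", "log_kaw") %in% names(data))) {
      abort("Rows without `log_kca` need both `log_kcw` and `log_kaw`.")
    }
    kcw <- data$log_kcw[needs]; kaw <- data$log_kaw[needs]
    if (any(!is.finite(kcw)) || any(!is.finite(kaw))) {
      abort("Non-finite log_kcw/log_kaw where log_kca must be derived.")
    }
    data$log_kca[needs] <- kcw - kaw
  }
  if (any(!is.finite(data$log_kca))) abort("Non-finite log_kca after derivation.")
  data
}

#' Average replicate measurements to one record per compound
#'
#' Collapses a replicate-level dataset (one row per measurement, possibly
#' several plant species and tissues per compound) to a compound-level
#' dataset by the arithmetic mean of `log_kca` within each `compound_id`.
#' Species/tissue columns are dropped; other constant-within-compound columns
#' (e.g. `smiles`) keep their first value.
#'
#' @param data A data frame with `compound_id` and `log_kca` columns.
#' @return A tibble with exactly one row per unique `compound_id`, carrying
#'   `n_replicates` and provenance attribute `"provenance" = "averaged"`.
#' @export
average_by_compound <- function(data) {
  data <- as_tibble(data)
  if (nrow(data) == 0L) abort("Cannot average an empty dataset.")
  if (!all(c("compound_id", "log_kca") %in% names(data))) {
    abort("`data` needs `compound_id` and `log_kca` columns.")
  }
  if (identical(attr(data, "provenance"), "averaged")) {
    abort("Dataset is already averaged (provenance 'averaged').")
  }
  carry <- setdiff(names(data), c("compound_id", "log_kca", "species", "tissue"))
  out <- data |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      n_replicates = dplyr::n(),
      log_kca = mean(.data$log_kca),
      .groups = "drop"
    )
  attr(out, "provenance") <- "averaged"
  out
}

#' Flag outlying values by the Pauta (3-sigma) criterion
#'
#' Flags any value farther than three sample standard deviations (n-1
#' denominator) from the sample mean — the data-quality screen applied to
#' measured log Kca compilations before modeling.
#'
#' @param values A numeric vector, length >= 3.
#' @return A tibble with columns `value`, `z` (standardized deviation, 0 when
#'   the sample has zero variance) and `outlier`; the sample `mean` and `sd`
#'   are attached as attributes.
#' @examples
#' pauta_check(c(0, 0, 0, 0, 100))  # all pass: 100 is within 3 sigma
#' @export
pauta_check <- function(values) {
  if (!is.numeric(values) || length(values) < 3L) {
    abort("Pauta criterion needs a numeric vector of length >= 3.")
  }
  m <- mean(values); s <- sd(values)
  z <- if (s > 0) (values - m) / s else rep(0, length(values))
  out <- tibble(value = values, z = z, outlier = abs(z) > 3)
  attr(out, "mean") <- m
  attr(out, "sd") <- if (s > 0) s else 0
  out
}

#' Response-ranked (Y-ranking) train/test split
#'
#' Sorts records ascending by `log_kca` (ties broken by `compound_id` for
#' determinism), partitions the ranking into `n_test` consecutive blocks of
#' near-equal size, and assigns exactly one record per block to the test set
#' by a seeded draw — so the test set interpolates the full response range.
#' The records holding the global minimum and maximum response are never
#' candidates for the test set (unless alone in their block), keeping the
#' test response range inside the training range. `n_test` is exactly
#' `n - floor(train_fraction * n)`: a 255-record replicate dataset splits
#' 204/51, a 106-compound averaged dataset 84/22.
#'
#' @param data A data frame with a `log_kca` column (and ideally
#'   `compound_id`); >= 5 rows.
#' @param train_fraction Fraction assigned to training, in (0, 1);
#'   default 0.8.
#' @param seed Integer seed for the within-block draws.
#' @param group_by_compound If `TRUE`, replicate rows of one compound are
#'   kept in the same partition (averaging ranks first); default `FALSE`,
#'   mirroring replicate-level splits in which the same compound may occur on
#'   both sides.
#' @return `data` as a tibble with a `split` column (`"train"`/`"test"`),
#'   original row order preserved.
#' @export
y_ranking_split <- function(data, train_fraction = 0.8, seed = 1L,
                            group_by_compound = FALSE) {
  data <- as_tibble(data)
  if (!"log_kca" %in% names(data)) abort("`data` needs a `log_kca` column.")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  if (nrow(data) < 5L) abort("Need at least 5 records to split.")

  if (group_by_compound) {
    if (!"compound_id" %in% names(data)) {
      abort("`group_by_compound = TRUE` needs a `compound_id` column.")
    }
    key <- data |>
      dplyr::group_by(.data$compound_id) |>
      dplyr::summarise(log_kca = mean(.data$log_kca), .groups = "drop")
    key$split <- .rank_block_split(key$log_kca, key$compound_id,
                                   train_fraction, seed)
    data$split <- key$split[match(data$compound_id, key$compound_id)]
    return(data)
  }

  tie_key <- if ("compound_id" %in% names(data)) {
    as.character(data$compound_id)
  } else {
    sprintf("%09d", seq_len(nrow(data)))
  }
  data$split <- .rank_block_split(data$log_kca, tie_key, train_fraction, seed)
  data
}

# Core block assignment on a response vector: returns "train"/"test" labels.
.rank_block_split <- function(y, tie_key, train_fraction, seed) {
  n <- length(y)
  n_test <- n - floor(train_fraction * n)
  ord <- order(y, tie_key)
  # n_test consecutive blocks over the ranking, sizes differing by at most 1
  sizes <- rep(floor(n / n_test), n_test)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1L
  split <- rep("train", n)
  withr::with_seed(seed, {
    for (b in seq_len(n_test)) {
      block <- ord[starts[b]:stops[b]]
      cand <- setdiff(block, c(ord[1L], ord[n]))
      if (!length(cand)) cand <- block
      pick <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      split[pick] <- "test"
    }
  })
  split
}
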