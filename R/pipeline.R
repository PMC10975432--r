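#' End-to-end QSPR pipeline run
#'
#' Orchestrates the full workflow on a replicate-level Kca dataset (measured
#' or synthetic): average to the compound-level dataset, quality-check with
#' the 3-sigma rule, response-ranked split, descriptor prefilter, stepwise
#' MLR, optional nonlinear learners, the validation battery, the leverage
#' applicability domain, and exact Shapley attributions for the best
#' learner. All stage outputs are written as plain CSV/JSON into `out_dir`
#' together with the resolved configuration and seed, so a rerun with the
#' same inputs is reproducible file-for-file.
#'
#' @param data Replicate-level measurement tibble (as from
#'   [generate_kca_dataset()], or a measured table with `compound_id`,
#'   descriptor columns and `log_kca`). If `NULL`, a synthetic dataset is
#'   generated from `synth`.
#' @param out_dir Output directory (created if missing).
#' @param learners Character vector of learners to fit besides the stepwise
#'   MLR (subset of `"knn"`, `"gbdt"`, `"mlp"`; default `"gbdt"`).
#' @param average Collapse replicates to one record per compound before
#'   modeling (default `TRUE`; `FALSE` models the replicate-level table).
#' @param synth A [synth_config()] used when `data` is `NULL`.
#' @param train_fraction,seed,max_p,vif_max,r_max,boot_iterations Stage
#'   parameters, passed through to the respective functions.
#' @param grids Optional named list of hyperparameter grids per learner.
#' @return Invisibly, a list with every stage result (`dataset`, `split`,
#'   `model`, `learners`, `reports`, `williams`, `shap`, `shap_ranking`,
#'   `out_dir`).
#' @export
run_pipeline <- function(data = NULL, out_dir = tempfile("kca_run_"),
                         learners = "gbdt", average = TRUE,
                         synth = synth_config(), train_fraction = 0.8,
                         seed = 1L, max_p = 4L, vif_max = 10, r_max = 0.9,
                         boot_iterations = 200L, grids = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), ..., "\n", file = log_path,
        append = TRUE)
  }
  stage <- function(name, expr) {
    log_line("stage:", name)
    tryCatch(expr, error = function(e) {
      log_line("FAILED:", name, "-", conditionMessage(e))
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  log_line("seed:", seed, "| package cuticleqspr",
           as.character(utils::packageVersion("cuticleqspr")))

  raw <- stage("dataset", {
    d <- data %||% generate_kca_dataset(synth)
    if (!"log_kca" %in% names(d)) d <- derive_log_kca(d)
    readr::write_csv(d, file.path(out_dir, "dataset_replicates.csv"))
    d
  })

  ds <- stage("average", {
    d <- if (average) average_by_compound(raw) else raw
    qc <- pauta_check(d$log_kca)
    readr::write_csv(qc, file.path(out_dir, "pauta_qc.csv"))
    d
  })

  split_ds <- stage("split", {
    s <- y_ranking_split(ds, train_fraction = train_fraction, seed = seed)
    readr::write_csv(s, file.path(out_dir, "dataset_split.csv"))
    s
  })
  train <- dplyr::filter(split_ds, .data$split == "train")
  test <- dplyr::filter(split_ds, .data$split == "test")

  train_f <- stage("prefilter", {
    keep_cols <- setdiff(names(train), c("split", "log_kca_true",
                                         "n_replicates"))
    prefilter_descriptors(train[keep_cols], r_max = r_max)
  })

  mlr <- stage("stepwise_mlr", {
    m <- stepwise_mlr(train_f, max_p = max_p, vif_max = vif_max)
    jsonlite::write_json(
      list(learner = "mlr", descriptors = m$descriptors,
           coefficients = as.list(m$coefficients), intercept = m$intercept,
           seed = seed),
      file.path(out_dir, "model_mlr.json"), auto_unbox = TRUE, digits = NA
    )
    m
  })
  selected <- mlr$descriptors

  fitted <- list(mlr = mlr)
  for (lr in learners) {
    fitted[[lr]] <- stage(paste0("fit_", lr), {
      m <- fit_learner(train, learner = lr, descriptors = selected,
                       grid = grids[[lr]], seed = seed)
      jsonlite::write_json(
        list(learner = lr, descriptors = selected, params = m$params,
             seed = seed),
        file.path(out_dir, paste0("model_", lr, ".json")),
        auto_unbox = TRUE, digits = NA
      )
      m
    })
  }

  reports <- list()
  for (nm in names(fitted)) {
    reports[[nm]] <- stage(paste0("validate_", nm), {
      refit <- if (nm == "mlr") {
        function(d) fit_mlr(d, descriptors = selected)
      } else {
        params <- fitted[[nm]]$params
        function(d) fit_learner(d, learner = nm, descriptors = selected,
                                grid = lapply(params, function(v) v),
                                seed = seed)
      }
      validation_report(train, test, refit = refit, p = length(selected),
                        boot_iterations = boot_iterations, seed = seed)
    })
  }
  stage("write_reports", {
    metrics <- purrr::imap(reports, function(r, nm) {
      dplyr::bind_cols(tibble(model = nm, n_tra = r$n_tra, n_ext = r$n_ext),
                       r$metrics)
    }) |> dplyr::bind_rows()
    readr::write_csv(metrics, file.path(out_dir, "validation_metrics.csv"))
    jsonlite::write_json(metrics, file.path(out_dir, "validation_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    metrics
  })

  williams <- stage("applicability_domain", {
    model <- fitted$mlr
    all_pred <- predict(model, split_ds)
    wt <- applicability_domain(
      train, split_ds, residuals = split_ds$log_kca - all_pred,
      s = model$sigma, descriptors = selected
    )
    readr::write_csv(dplyr::bind_cols(split_ds["compound_id"],
                                      as_tibble(wt)[c("h", "delta", "class")]),
                     file.path(out_dir, "williams.csv"))
    wt
  })

  best <- if (length(learners)) fitted[[learners[[1]]]] else mlr
  shap <- stage("shap", {
    ex <- exact_shap(best, background = train, query = train,
                     descriptors = selected, seed = seed)
    readr::write_csv(as_tibble(ex), file.path(out_dir, "shap_values.csv"))
    ex
  })
  ranking <- stage("shap_summary", {
    r <- shap_summary(shap)
    readr::write_csv(r, file.path(out_dir, "shap_summary.csv"))
    r
  })

  jsonlite::write_json(
    list(seed = seed, train_fraction = train_fraction, max_p = max_p,
         vif_max = vif_max, r_max = r_max, boot_iterations = boot_iterations,
         learners = learners, average = average,
         selected_descriptors = selected),
    file.path(out_dir, "config_resolved.json"), auto_unbox = TRUE, digits = NA
  )
  log_line("done")
  invisible(list(dataset = ds, split = split_ds, model = mlr,
                 learners = fitted, reports = reports, williams = williams,
                 shap = shap, shap_ranking = ranking, out_dir = out_dir))
}
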