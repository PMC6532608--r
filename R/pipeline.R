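# Pipeline orchestration: preprocessing -> ranking -> model/feature search
# -> selection and reporting, behind one fitting function (sig_discover)
# returning a classed result with the usual model-object methods, plus a
# checkpoint/resume entry point.

#' Pipeline configuration
#'
#' Collects every tunable of the discovery pipeline with its documented
#' default.
#'
#' @param problem_type `"auto"`, `"classification"` or `"regression"`.
#' @param train_fraction Training fraction for the stratified split
#'   (default 2/3; 1 disables sampling).
#' @param exclude Feature names to drop before analysis.
#' @param missing_markers Cell values treated as missing on load.
#' @param ranking_threshold Minimum absolute merit (default 0.01).
#' @param ranking_cap Maximum retained features (default 1000).
#' @param criteria Optimisation criteria; `NULL` picks the problem-type
#'   default (classification `c("mcc","auc","ber","acc")`, regression
#'   `c("cc","rmse")`).
#' @param methods Stepwise search methods (default all four).
#' @param k_list Top-k sizes (default `c(1,5,10,15,20,25,30,40,50,75,
#'   100)`).
#' @param classifiers A registry list from [default_classifiers()] (or
#'   custom `classifier_spec`s); `NULL` picks the default panel. The
#'   character shortcuts `"default"` and `"fast"` select the built-in
#'   presets.
#' @param strategy A [selection_strategy()].
#' @param ensemble_rule_threshold,ensemble_max_models Ensemble inclusion
#'   rule (the published default prints the threshold as "average MCC
#'   lower than 0.6"; this implementation defaults to the quality-filter
#'   direction, at or above 0.6, configurable via
#'   `ensemble_rule_direction`).
#' @param ensemble_rule_direction `"ge"` or `"le"`.
#' @param r_min,score_epsilon Correlated-feature thresholds (defaults 0.95
#'   and 0.01).
#' @param folds CV folds (default 10).
#' @param repeats Repeats for repeated holdout and bootstrap (default
#'   100).
#' @param loocv_limit Skip LOOCV above this many instances (default 500).
#' @param seed Master seed (default 1).
#' @param cores Concurrency degree (default 1; results are independent of
#'   it).
#' @param output_dir Optional run directory for the checkpointed registry,
#'   serialized models and reports.
#' @param test_path Optional separate test-set file used instead of
#'   sampling.
#' @param topk_per_criterion Evaluate top-k under every criterion.
#' @param progress Log progress.
#' @return A `sig_config` list.
#' @export
sig_config <- function(problem_type = "auto", train_fraction = 2 / 3,
                       exclude = character(0),
                       missing_markers = DEFAULT_MISSING_MARKERS,
                       ranking_threshold = 0.01, ranking_cap = 1000L,
                       criteria = NULL, methods = SEARCH_METHODS,
                       k_list = DEFAULT_TOP_K, classifiers = NULL,
                       strategy = selection_strategy(),
                       ensemble_rule_threshold = 0.6,
                       ensemble_rule_direction = "ge",
                       ensemble_max_models = 10L,
                       r_min = 0.95, score_epsilon = 0.01, folds = 10L,
                       repeats = 100L, loocv_limit = 500L, seed = 1L,
                       cores = 1L, output_dir = NULL, test_path = NULL,
                       topk_per_criterion = FALSE, progress = FALSE) {
  structure(as.list(environment()), class = "sig_config")
}

resolve_registry <- function(config, problem_type) {
  cl <- config$classifiers
  if (is.null(cl)) cl <- "default"
  if (is.character(cl))
    cl <- default_classifiers(problem_type, preset = cl)
  cl
}

resolve_criteria <- function(config, problem_type) {
  if (!is.null(config$criteria)) return(config$criteria)
  if (problem_type == "classification") c("mcc", "auc", "ber", "acc")
  else c("cc", "rmse")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

as_tables <- function(x, class_name, config) {
  if (inherits(x, "merged_dataset")) return(x)
  if (inherits(x, "raw_table")) return(list(x))
  if (is.data.frame(x)) return(list(raw_table_from_df(x, class_name)))
  if (is.character(x))
    return(lapply(x, function(p) {
      t <- load_table(p, missing_markers = config$missing_markers)
      if (class_name %in% t$feature_names) t$class_name <- class_name
      t
    }))
  if (is.list(x)) {
    if (all(vapply(x, inherits, logical(1), "raw_table"))) return(x)
    if (all(vapply(x, is.data.frame, logical(1))))
      return(lapply(x, raw_table_from_df))
  }
  stop("unsupported input: pass file path(s), data.frame(s), raw_table(s) ",
       "or a merged_dataset", call. = FALSE)
}

#' Discover biomarker signatures and predictive models
#'
#' Runs the full discovery pipeline: load and inner-join the input tables,
#' drop excluded features, split off a stratified holdout test set, impute
#' missing values with training-set means/modes, rank features by
#' Information Gain (classification) or ReliefF (regression) and keep the
#' best, search every classifier x criterion x subset-search combination,
#' evaluate each candidate across resampling procedures, select the most
#' stable model, and enrich its signature with correlated features.
#'
#' @param x Input data: file path(s) to delimited tables, data.frame(s)
#'   (first column = sample id), `raw_table`(s), or a ready
#'   `merged_dataset`.
#' @param class_name Name of the class/outcome column.
#' @param config A [sig_config()].
#' @param ... Convenience overrides for `config` fields (e.g. `seed = 7`,
#'   `classifiers = "fast"`).
#' @return A `sig_run` object with components `config`, `split`,
#'   `ranking`, `models`, `best`, `signature` (enriched), `dataset` (the
#'   imputed full dataset) and methods `print`, `summary`, `predict`,
#'   `plot`, `coef`.
#' @export
sig_discover <- function(x, class_name, config = sig_config(), ...) {
  dots <- list(...)
  for (nm in names(dots)) config[[nm]] <- dots[[nm]]

  merged <- stage("dataio", {
    if (inherits(x, "merged_dataset")) x
    else {
      tables <- as_tables(x, class_name, config)
      merge_datasets(tables, class_name, problem_type = config$problem_type)
    }
  })
  merged <- stage("dataio", exclude_features(merged, config$exclude))

  split <- stage("sampling", {
    if (!is.null(config$test_path)) {
      test_tab <- load_table(config$test_path, class_name = class_name,
                             missing_markers = config$missing_markers)
      test <- merge_datasets(list(test_tab), class_name,
                             problem_type = merged$problem_type)
      structure(list(train = merged, test = test, train_fraction = 1,
                     seed = config$seed), class = "split_dataset")
    } else {
      stratified_split(merged, config$train_fraction, config$seed)
    }
  })
  split <- stage("imputation", {
    split$train <- impute_missing(split$train)
    if (n_samples(split$test) > 0L)
      split$test <- impute_missing(split$train, split$test)
    split
  })

  ranking <- stage("ranking",
    rank_and_reduce(split$train, threshold = config$ranking_threshold,
                    cap = config$ranking_cap, seed = config$seed))

  registry <- resolve_registry(config, merged$problem_type)
  criteria <- resolve_criteria(config, merged$problem_type)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(split, file.path(config$output_dir, "split.rds"))
    saveRDS(ranking, file.path(config$output_dir, "ranking.rds"))
  }
  models <- stage("search",
    run_search(ranking, registry, criteria, config$methods, split,
               seed = config$seed, k_list = config$k_list,
               folds = config$folds, repeats = config$repeats,
               loocv_limit = config$loocv_limit, cores = config$cores,
               checkpoint_dir = config$output_dir,
               topk_per_criterion = config$topk_per_criterion,
               progress = config$progress))
  if (!length(models$candidates))
    stop("pipeline stage 'search' produced no candidate model",
         call. = FALSE)

  finish_run(models, split, ranking, config, class_name)
}

# selection / enrichment / reporting shared by sig_discover and sig_resume
finish_run <- function(models, split, ranking, config, class_name) {
  strategy <- config$strategy
  if (split$train$problem_type == "regression" &&
      strategy$metric_key == "avg_mcc")
    strategy <- selection_strategy("avg_cc", strategy$std_threshold)
  config$strategy <- strategy
  best <- stage("selection", best_model(models, strategy, split))
  full <- if (n_samples(split$test) > 0L) {
    new_merged_dataset(c(split$train$sample_ids, split$test$sample_ids),
                       rbind(split$train$data, split$test$data),
                       c(split$train$y, split$test$y),
                       split$train$problem_type, split$train$class_name)
  } else split$train
  signature <- stage("correlation",
    correlated_features(best$selected_features, full, ranking,
                        r_min = config$r_min,
                        score_epsilon = config$score_epsilon))
  run <- structure(list(config = config, class_name = class_name,
                        split = split, ranking = ranking, models = models,
                        best = best, signature = signature,
                        dataset = full),
                   class = "sig_run")
  if (!is.null(config$output_dir))
    write_run_reports(run, config$output_dir)
  run
}

write_run_reports <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg_path <- file.path(dir, "registry.csv")
  if (!file.exists(reg_path))
    write_model_registry(run$models, reg_path)
  utils::write.csv(run$signature$recovered,
                   file.path(dir, "correlated_features.csv"),
                   row.names = FALSE)
  export_signature_subset(run$dataset, run$best$selected_features,
                          file.path(dir, "signature_subset.csv"))
  txt <- utils::capture.output({
    cat("Best model report\n=================\n")
    print(run$best)
    cat("\nSignature:", paste(run$best$selected_features, collapse = ", "),
        "\n\n")
    print(run$best$report)
    cat("\nRecovered correlated features:",
        nrow(run$signature$recovered), "\n")
  })
  writeLines(txt, file.path(dir, "best_model.txt"))
  invisible(dir)
}

#' Resume selection and reporting from a run checkpoint
#'
#' Reads the (possibly partial) registry and serialized candidates from a
#' run directory and performs best-model selection, correlated-feature
#' enrichment and report writing on whatever candidates exist. Explicit
#' model identifiers can be given to report on specific models regardless
#' of the selection strategy.
#'
#' @param run_directory Directory written by a checkpointed
#'   [sig_discover()] run.
#' @param config A [sig_config()] (selection/correlation settings are
#'   honoured).
#' @param model_ids Optional candidate identifiers to select manually.
#' @return A `sig_run` built from the checkpointed candidates.
#' @export
sig_resume <- function(run_directory, config = sig_config(),
                       model_ids = NULL) {
  reg_path <- file.path(run_directory, "registry.csv")
  if (!file.exists(reg_path))
    stop("no registry checkpoint in ", run_directory, call. = FALSE)
  reg <- read_model_registry(reg_path)
  if (!nrow(reg)) stop("empty registry checkpoint", call. = FALSE)
  model_files <- file.path(run_directory, "models",
                           paste0(reg$unique_id, ".rds"))
  cands <- lapply(model_files[file.exists(model_files)], readRDS)
  if (!length(cands))
    stop("no serialized candidate models in ", run_directory,
         call. = FALSE)
  models <- structure(list(candidates = cands), class = "sig_model_list")
  split <- readRDS(file.path(run_directory, "split.rds"))
  ranking <- readRDS(file.path(run_directory, "ranking.rds"))
  if (!is.null(model_ids)) {
    ids <- vapply(cands, `[[`, character(1), "unique_id")
    missing <- setdiff(model_ids, ids)
    if (length(missing))
      stop("unknown model id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    models$candidates <- cands[match(model_ids, ids)]
  }
  config$output_dir <- run_directory
  finish_run(models, split, ranking, config,
             split$train$class_name)
}

# ---- sig_run methods ----------------------------------------------------

#' @export
print.sig_run <- function(x, ...) {
  cat("sig_run: biomarker signature discovery\n")
  cat(sprintf("  %d candidate model(s) searched; problem: %s\n",
              length(x$models$candidates), x$split$train$problem_type))
  cat("  best: ")
  print(x$best)
  summ <- x$best$report$summary
  cat("  stability:", paste(names(summ), round(summ, 3), sep = "=",
                            collapse = ", "), "\n")
  if (!is.null(x$best$report$procedures$holdout)) {
    h <- x$best$report$procedures$holdout
    key <- if (x$split$train$problem_type == "classification") "mcc"
           else "cc"
    cat(sprintf("  holdout %s: %.3f\n", key, h[[key]]))
  }
  cat(sprintf("  signature: %d core + %d recovered feature(s)\n",
              length(x$signature$core),
              length(unique(x$signature$recovered$feature))))
  invisible(x)
}

#' @export
summary.sig_run <- function(object, ...) {
  df <- do.call(rbind, lapply(object$models$candidates, registry_row))
  key <- if (object$split$train$problem_type == "classification")
    "avg_mcc" else "avg_cc"
  df <- df[order(-df[[key]]), ]
  structure(list(candidates = df, best_id = object$best$unique_id,
                 signature = object$signature), class = "summary.sig_run")
}

#' @export
print.summary.sig_run <- function(x, ...) {
  cols <- intersect(c("unique_id", "criterion", "method", "n_features",
                      "avg_mcc", "std_mcc", "avg_cc", "std_cc",
                      "holdout_mcc", "estimator_632plus"),
                    names(x$candidates))
  print(utils::head(x$candidates[, cols], 10L), row.names = FALSE)
  cat("best:", x$best_id, "\n")
  invisible(x)
}

#' Predict outcomes with a discovery run's best model
#'
#' @param object A `sig_run`.
#' @param newdata File path, data.frame (first column = id unless all
#'   feature columns present), or `merged_dataset` containing the
#'   signature features.
#' @param ... Unused.
#' @return Classification: list with `class` and `prob`; regression:
#'   numeric vector.
#' @export
predict.sig_run <- function(object, newdata, ...) {
  df <- if (is.character(newdata)) {
    t <- load_table(newdata)
    t$values
  } else if (inherits(newdata, "merged_dataset")) {
    newdata$data
  } else {
    newdata
  }
  predict(object$best$report$model, df)
}

#' @export
coef.sig_run <- function(object, ...) {
  feats <- object$best$selected_features
  stats::setNames(object$ranking$merit[feats], feats)
}

#' Plot the candidate stability landscape
#'
#' Draws every candidate's summary average metric against its
#' cross-procedure standard deviation, marks the stability gate, and
#' highlights the selected best model.
#'
#' @param x A `sig_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sig_run <- function(x, ...) {
  key <- if (x$split$train$problem_type == "classification") "mcc" else "cc"
  avg <- vapply(x$models$candidates, function(c)
    unname(c$report$summary[[paste0("avg_", key)]]), numeric(1))
  std <- vapply(x$models$candidates, function(c)
    unname(c$report$summary[[paste0("std_", key)]]), numeric(1))
  graphics::plot(std, avg, xlab = paste0("std_", key),
                 ylab = paste0("avg_", key),
                 main = "Candidate stability landscape", pch = 19,
                 col = "grey50", ...)
  graphics::abline(v = x$config$strategy$std_threshold, lty = 2)
  ids <- vapply(x$models$candidates, `[[`, character(1), "unique_id")
  b <- which(ids == x$best$unique_id)
  graphics::points(std[b], avg[b], pch = 19, col = "red3", cex = 1.4)
  invisible(x)
}
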