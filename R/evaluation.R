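# Resampling-based model evaluation. Every candidate model is assessed by
# 10-fold CV, leave-one-out CV, holdout on the reserved test set, repeated
# holdout, out-of-bag bootstrap, and the 0.632+ estimator; the agreement
# between procedures (mean and population SD of MCC/BER, or CC/RMSE for
# regression) is the stability summary used for best-model selection.

derive_seed <- function(seed, salt) {
  # deterministic 31-bit child seed
  (as.numeric(seed) * 7919 + as.numeric(salt) * 104729) %% 2147483629
}

#' Build (stratified) cross-validation folds
#'
#' Classification folds are stratified: each class's shuffled indices are
#' dealt round-robin so every fold keeps the class balance. Regression folds
#' deal shuffled indices round-robin. Deterministic for a fixed seed.
#'
#' @param y Outcome vector.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @param stratified Stratify on class labels (classification).
#' @return List of disjoint index vectors covering `seq_along(y)`.
#' @export
make_folds <- function(y, folds = 10L, seed = 1L, stratified = TRUE) {
  n <- length(y)
  folds <- min(folds, n)
  rng <- local_rng(seed)
  groups <- if (stratified && !is.numeric(y)) {
    split(seq_len(n), as.character(y))
  } else {
    list(seq_len(n))
  }
  out <- vector("list", folds)
  offset <- 0L
  for (g in groups) {
    sh <- rng$sample(g, length(g))
    fold_of <- ((offset + seq_along(sh) - 1L) %% folds) + 1L
    for (i in seq_along(sh))
      out[[fold_of[i]]] <- c(out[[fold_of[i]]], sh[i])
    offset <- offset + length(sh)
  }
  lapply(out, sort)
}

# Fit on train indices, predict the rest; returns truth/pred/prob chunks.
fit_predict_idx <- function(spec, dataset, features, fit_idx, pred_idx,
                            seed) {
  fitted <- train_classifier(spec, subset_samples(dataset, fit_idx),
                             features, seed = seed)
  pred <- predict(fitted, subset_samples(dataset, pred_idx))
  if (dataset$problem_type == "classification") {
    list(truth = as.character(dataset$y[pred_idx]), class = pred$class,
         prob = pred$prob)
  } else {
    list(truth = dataset$y[pred_idx], class = pred)
  }
}

chunk_metrics <- function(chunk, problem_type, classes) {
  metrics_from_predictions(chunk$truth, chunk$class, chunk$prob,
                           problem_type, classes)
}

average_metric_rows <- function(rows) {
  m <- do.call(rbind, rows)
  out <- colMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' k-fold cross-validation of a classifier over a feature subset
#'
#' Partitions the training set into `folds` (stratified for classification)
#' subsamples, trains on all but one and evaluates on the held-out one, and
#' averages the metric vectors over folds. A fold missing a class entirely
#' simply contributes no per-class value for it. Deterministic for a fixed
#' seed.
#'
#' @param spec A `classifier_spec`.
#' @param features Feature names to use.
#' @param train A `merged_dataset`.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @param fold_list Optional precomputed fold partition (overrides
#'   `folds`/`seed` fold construction; fits are still seeded from `seed`).
#' @return Averaged metric vector.
#' @export
cross_validate <- function(spec, features, train, folds = 10L, seed = 1L,
                           fold_list = NULL) {
  if (is.null(fold_list))
    fold_list <- make_folds(train$y, folds, seed,
                            train$problem_type == "classification")
  classes <- if (train$problem_type == "classification")
    sort(unique(as.character(train$y))) else NULL
  rows <- lapply(seq_along(fold_list), function(i) {
    test_idx <- fold_list[[i]]
    chunk <- fit_predict_idx(spec, train, features,
                             setdiff(seq_len(n_samples(train)), test_idx),
                             test_idx, derive_seed(seed, i))
    suppressWarnings(chunk_metrics(chunk, train$problem_type, classes))
  })
  average_metric_rows(rows)
}

#' Leave-one-out cross-validation
#'
#' Fits `n` models, each leaving one instance out, and computes a single
#' metric vector on the pooled held-out predictions.
#'
#' @inheritParams cross_validate
#' @return Metric vector on the pooled predictions.
#' @export
loocv <- function(spec, features, train, seed = 1L) {
  n <- n_samples(train)
  if (n < 2L) stop("LOOCV needs at least 2 instances", call. = FALSE)
  classes <- if (train$problem_type == "classification")
    sort(unique(as.character(train$y))) else NULL
  chunks <- lapply(seq_len(n), function(i)
    fit_predict_idx(spec, train, features, setdiff(seq_len(n), i), i,
                    derive_seed(seed, i)))
  pooled <- list(truth = unlist(lapply(chunks, `[[`, "truth")),
                 class = unlist(lapply(chunks, `[[`, "class")),
                 prob = if (train$problem_type == "classification")
                   do.call(rbind, lapply(chunks, function(c)
                     as_prob_matrix(c$prob, classes))) else NULL)
  suppressWarnings(chunk_metrics(pooled, train$problem_type, classes))
}

#' Holdout evaluation of an already-trained model
#'
#' Predicts the reserved test set with a model trained on the training set
#' only. An empty test set yields all-`NA` metrics (undefined), never zeros.
#'
#' @param trained_model A `sig_model`.
#' @param test A `merged_dataset`.
#' @return Metric vector on the test predictions.
#' @export
holdout_evaluate <- function(trained_model, test) {
  pt <- trained_model$problem_type
  empty <- if (pt == "classification")
    c(acc = NA_real_, ber = NA_real_, mcc = NA_real_, auc = NA_real_,
      auprc = NA_real_, sensitivity = NA_real_, specificity = NA_real_)
  else c(cc = NA_real_, rmse = NA_real_)
  if (n_samples(test) == 0L) return(empty)
  pred <- predict(trained_model, test)
  if (pt == "classification") {
    suppressWarnings(metrics_from_predictions(
      as.character(test$y), pred$class, pred$prob, pt,
      trained_model$classes))
  } else {
    metrics_from_predictions(test$y, pred, problem_type = pt)
  }
}

#' Repeated holdout evaluation
#'
#' Repeatedly holds out a fraction of the training sample (sampling without
#' replacement, stratified), trains on the remainder, evaluates on the
#' held-out part, and averages the per-repeat metric vectors.
#'
#' @inheritParams cross_validate
#' @param repeats Number of repeats (default 100).
#' @param holdout_fraction Held-out fraction per repeat (default 1/3).
#' @return Averaged metric vector.
#' @export
repeated_holdout <- function(spec, features, train, repeats = 100L,
                             holdout_fraction = 1 / 3, seed = 1L) {
  classes <- if (train$problem_type == "classification")
    sort(unique(as.character(train$y))) else NULL
  rows <- lapply(seq_len(repeats), function(r) {
    sp <- stratified_split(train, 1 - holdout_fraction,
                           seed = derive_seed(seed, r))
    test_idx <- match(sp$test$sample_ids, train$sample_ids)
    chunk <- fit_predict_idx(spec, train, features,
                             match(sp$train$sample_ids, train$sample_ids),
                             test_idx, derive_seed(seed, r + repeats))
    suppressWarnings(chunk_metrics(chunk, train$problem_type, classes))
  })
  average_metric_rows(rows)
}

#' Out-of-bag bootstrap evaluation
#'
#' Each repeat trains on an n-sized resample drawn with replacement and
#' evaluates on the out-of-bag instances; repeats with an empty out-of-bag
#' set are redrawn. Metric vectors are averaged over repeats.
#'
#' @inheritParams repeated_holdout
#' @return Averaged metric vector, with attribute `"oob_error"` carrying
#'   the mean out-of-bag prediction error (misclassification rate, or mean
#'   squared error for regression) used by the 0.632+ estimator.
#' @export
bootstrap_evaluate <- function(spec, features, train, repeats = 100L,
                               seed = 1L) {
  n <- n_samples(train)
  classes <- if (train$problem_type == "classification")
    sort(unique(as.character(train$y))) else NULL
  rng <- local_rng(seed)
  rows <- vector("list", repeats)
  errs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    repeat {
      bag <- rng$resample(n, n)                  # n draws with replacement
      oob <- setdiff(seq_len(n), bag)
      if (length(oob)) break
    }
    chunk <- fit_predict_idx(spec, train, features, bag, oob,
                             derive_seed(seed, r))
    rows[[r]] <- suppressWarnings(chunk_metrics(chunk, train$problem_type,
                                                classes))
    errs[r] <- if (train$problem_type == "classification")
      mean(chunk$truth != chunk$class)
    else mean((chunk$truth - chunk$class)^2)
  }
  out <- average_metric_rows(rows)
  attr(out, "oob_error") <- mean(errs)
  out
}

#' The 0.632+ bootstrap estimator
#'
#' Efron-Tibshirani blend of the resubstitution error and the out-of-bag
#' bootstrap error. With `gamma` the no-information error rate, the
#' relative-overfitting ratio is
#' `R = (err_boot' - err_resub) / (gamma - err_resub)` (with `err_boot'`
#' clipped to at most `gamma`, and `R` to \[0, 1\]; `R = 0` whenever
#' `gamma <= err_resub`), the weight `w = 0.632 / (1 - 0.368 R)`, and the
#' estimate `(1 - w) err_resub + w err_boot'`. The reported bias is
#' `estimate - err_resub`, which tends to 0 for a non-overfitting model.
#'
#' @param err_resub Resubstitution error of the model on its training set.
#' @param err_boot Out-of-bag bootstrap error.
#' @param gamma No-information error rate (marginal truth x prediction
#'   mismatch rate).
#' @return List with `estimate`, `bias`, `R`, `weight`.
#' @export
estimator_632plus <- function(err_resub, err_boot, gamma) {
  err_boot_c <- min(err_boot, gamma)
  R <- if (gamma <= err_resub || err_boot_c <= err_resub) 0 else
    (err_boot_c - err_resub) / (gamma - err_resub)
  R <- min(1, max(0, R))
  w <- 0.632 / (1 - 0.368 * R)
  est <- (1 - w) * err_resub + w * err_boot_c
  list(estimate = est, bias = est - err_resub, R = R, weight = w)
}

no_information_error <- function(truth, predicted, problem_type) {
  if (problem_type == "classification") {
    p <- table(truth) / length(truth)
    q <- table(factor(predicted, levels = names(p))) / length(predicted)
    sum(p * (1 - q))
  } else {
    mean(outer(truth, predicted, `-`)^2)
  }
}

#' Evaluate one candidate's feature subset across all procedures
#'
#' Runs 10-fold CV, LOOCV (skipped with a warning above `loocv_limit`
#' instances), repeated holdout, out-of-bag bootstrap, holdout on the
#' reserved test set (when present), and the 0.632+ estimator, then fills
#' the cross-procedure stability summary. An incompatible classifier/data
#' pair (classifier error) returns `NULL` so the caller can skip the
#' candidate.
#'
#' @param spec A `classifier_spec`.
#' @param features Nonempty feature-name vector.
#' @param split A `split_dataset`.
#' @param folds CV folds (default 10).
#' @param repeats Repeats for repeated holdout and bootstrap (default 100).
#' @param loocv_limit Max n for LOOCV (default 500).
#' @param seed Integer seed.
#' @return An `evaluation_report`, or `NULL` when the classifier is
#'   incompatible with the data.
#' @export
evaluate_candidate <- function(spec, features, split, folds = 10L,
                               repeats = 100L, loocv_limit = 500L,
                               seed = 1L) {
  stopifnot(length(features) > 0L)
  train <- split$train
  res <- tryCatch({
    procedures <- list()
    procedures$cv10 <- cross_validate(spec, features, train, folds,
                                      derive_seed(seed, 1))
    if (n_samples(train) <= loocv_limit) {
      procedures$loocv <- loocv(spec, features, train, derive_seed(seed, 2))
    } else {
      warning("LOOCV skipped: n = ", n_samples(train), " exceeds limit ",
              loocv_limit, call. = FALSE)
    }
    full_model <- train_classifier(spec, train, features,
                                   derive_seed(seed, 3))
    if (n_samples(split$test) > 0L)
      procedures$holdout <- holdout_evaluate(full_model, split$test)
    procedures$repeated_holdout <-
      repeated_holdout(spec, features, train, repeats,
                       seed = derive_seed(seed, 4))
    boot <- bootstrap_evaluate(spec, features, train, repeats,
                               seed = derive_seed(seed, 5))
    procedures$bootstrap <- boot

    resub_pred <- predict(full_model, train)
    if (train$problem_type == "classification") {
      err_resub <- mean(as.character(train$y) != resub_pred$class)
      gamma <- no_information_error(as.character(train$y),
                                    resub_pred$class, "classification")
    } else {
      err_resub <- mean((train$y - resub_pred)^2)
      gamma <- no_information_error(train$y, resub_pred, "regression")
    }
    e632 <- estimator_632plus(err_resub, attr(boot, "oob_error"), gamma)

    report <- structure(list(procedures = procedures,
                             err_resub = err_resub,
                             err_boot = attr(boot, "oob_error"),
                             gamma = gamma,
                             estimator_632plus = e632$estimate,
                             bias_632plus = e632$bias,
                             problem_type = train$problem_type,
                             model = full_model),
                        class = "evaluation_report")
    report$summary <- stability_summary(report)
    report
  }, error = function(e) {
    message("classifier '", spec$id, "' skipped: ", conditionMessage(e))
    NULL
  })
  res
}

#' Cross-procedure stability summary
#'
#' Arithmetic mean and population standard deviation, over the procedures
#' that actually ran, of MCC and BER (classification) or CC and RMSE
#' (regression).
#'
#' @param report An `evaluation_report`.
#' @return Named numeric vector (`avg_mcc`, `std_mcc`, `avg_ber`,
#'   `std_ber`, or the cc/rmse analogues).
#' @export
stability_summary <- function(report) {
  keys <- if (report$problem_type == "classification") c("mcc", "ber")
          else c("cc", "rmse")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  if (length(report$procedures) == 1L)
    warning("stability summary computed from a single procedure",
            call. = FALSE)
  out <- numeric(0)
  for (k in keys) {
    vals <- vapply(report$procedures, function(m) unname(m[[k]]),
                   numeric(1))
    vals <- vals[!is.na(vals)]
    out[paste0("avg_", k)] <- mean(vals)
    out[paste0("std_", k)] <- if (length(vals)) pop_sd(vals) else NA_real_
  }
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (", x$problem_type, ")\n", sep = "")
  m <- do.call(rbind, x$procedures)
  print(round(m, 3))
  cat("summary:", paste(names(x$summary), round(x$summary, 3), sep = "=",
                        collapse = ", "), "\n")
  cat(sprintf("0.632+: estimate %.3f, bias %.3f\n", x$estimator_632plus,
              x$bias_632plus))
  invisible(x)
}
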