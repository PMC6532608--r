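# Best-model selection, ensemble vote classifiers, correlated-feature
# signature enrichment, and the CSV model registry.

#' Best-model selection strategy
#'
#' @param metric_key Summary metric to optimise: an `avg_*` stability key
#'   (`avg_mcc`, `avg_ber`, `avg_cc`, `avg_rmse`), a `test_*` holdout key
#'   (e.g. `test_mcc`), or `train_test_bs_mcc` (bootstrap MCC on merged
#'   train+test, computed on demand).
#' @param std_threshold Stability gate: only candidates whose matching
#'   `std_*` is below this pass (default 0.1; applies to `avg_*` keys).
#' @param direction `"maximize"` or `"minimize"`; `NULL` infers from the
#'   metric name (error metrics ber/rmse are minimised).
#' @return A `selection_strategy`.
#' @export
selection_strategy <- function(metric_key = "avg_mcc", std_threshold = 0.1,
                               direction = NULL) {
  if (is.null(direction)) {
    base <- sub("^(avg_|std_|test_|train_test_bs_)", "", metric_key)
    dirs <- criterion_directions()
    direction <- if (base %in% names(dirs)) dirs[[base]] else "maximize"
  }
  structure(list(metric_key = metric_key, std_threshold = std_threshold,
                 direction = direction),
            class = "selection_strategy")
}

# Resolve a strategy metric for one candidate; split needed only for
# train_test_bs_* keys.
candidate_metric <- function(cand, key, split = NULL, repeats = 100L) {
  rep_ <- cand$report
  if (is.null(rep_)) return(NA_real_)
  if (key %in% names(rep_$summary)) return(unname(rep_$summary[[key]]))
  if (startsWith(key, "test_")) {
    m <- rep_$procedures$holdout
    if (is.null(m)) return(NA_real_)
    return(unname(m[[sub("^test_", "", key)]]))
  }
  if (startsWith(key, "train_test_bs_")) {
    if (is.null(split)) return(NA_real_)
    merged <- if (n_samples(split$test) > 0L) {
      new_merged_dataset(c(split$train$sample_ids, split$test$sample_ids),
                         rbind(split$train$data, split$test$data),
                         c(split$train$y, split$test$y),
                         split$train$problem_type, split$train$class_name)
    } else split$train
    m <- bootstrap_evaluate(cand$task$classifier, cand$selected_features,
                            merged, repeats = repeats,
                            seed = cand$seed %||% 1L)
    return(unname(m[[sub("^train_test_bs_", "", key)]]))
  }
  stop("unresolvable selection metric '", key, "'", call. = FALSE)
}

#' Select the best candidate model
#'
#' Among candidates passing the stability gate (matching `std_*` summary
#' value strictly below the threshold), returns the one with the best
#' summary metric. When no candidate passes the gate, falls back to the
#' candidate with the smallest standard deviation, with a prominent
#' warning.
#'
#' @param models A `sig_model_list`.
#' @param strategy A [selection_strategy()].
#' @param split Optional `split_dataset` (needed for `train_test_bs_*`
#'   keys).
#' @return The selected `sig_candidate`.
#' @export
best_model <- function(models, strategy = selection_strategy(),
                       split = NULL) {
  cands <- models$candidates
  if (!length(cands)) stop("empty model list", call. = FALSE)
  vals <- vapply(cands, candidate_metric, numeric(1),
                 key = strategy$metric_key, split = split)
  ok <- !is.na(vals)
  if (!any(ok)) stop("no candidate carries metric '", strategy$metric_key,
                     "'", call. = FALSE)
  gated <- ok
  std_key <- sub("^avg_", "std_", strategy$metric_key)
  if (startsWith(strategy$metric_key, "avg_") &&
      std_key != strategy$metric_key) {
    stds <- vapply(cands, function(c)
      if (is.null(c$report)) NA_real_ else
        unname(c$report$summary[[std_key]]), numeric(1))
    gated <- ok & !is.na(stds) & stds < strategy$std_threshold
    if (!any(gated)) {
      warning("no candidate passes the stability gate (", std_key, " < ",
              strategy$std_threshold, "); falling back to the smallest-",
              std_key, " candidate", call. = FALSE)
      return(cands[[which.min(stds)]])
    }
  }
  vals[!gated] <- NA
  idx <- if (strategy$direction == "maximize") which.max(vals)
         else which.min(vals)
  cands[[idx]]
}

# ---- ensembles ----------------------------------------------------------

#' Build an ensemble vote classifier
#'
#' Members are chosen either manually by unique identifier or by a
#' metric-dependent inclusion rule, then truncated to `max_models` by the
#' metric (best first). Feature occurrences across members are tallied.
#'
#' @param models A `sig_model_list`.
#' @param member_ids Optional character vector of candidate ids (manual
#'   selection; overrides the rule).
#' @param combination `"average"`, `"product"`, `"majority"` or
#'   `"median"`.
#' @param rule_key Summary metric for the inclusion rule (default
#'   `avg_mcc`).
#' @param rule_threshold Inclusion threshold (default 0.6).
#' @param rule_direction `"ge"` (include members at or above the
#'   threshold; the quality-filter default) or `"le"`.
#' @param max_models Maximum number of members (default 10).
#' @return A `sig_ensemble`: members, combination, `feature_occurrences`.
#' @export
build_ensemble <- function(models, member_ids = NULL,
                           combination = c("average", "product",
                                           "majority", "median"),
                           rule_key = "avg_mcc", rule_threshold = 0.6,
                           rule_direction = c("ge", "le"),
                           max_models = 10L) {
  combination <- match.arg(combination)
  rule_direction <- match.arg(rule_direction)
  cands <- models$candidates
  ids <- vapply(cands, `[[`, character(1), "unique_id")
  if (!is.null(member_ids)) {
    missing <- setdiff(member_ids, ids)
    if (length(missing))
      stop("unknown model id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    members <- cands[match(member_ids, ids)]
  } else {
    vals <- vapply(cands, candidate_metric, numeric(1), key = rule_key)
    sel <- if (rule_direction == "ge") which(vals >= rule_threshold)
           else which(vals <= rule_threshold)
    if (!length(sel))
      stop("inclusion rule (", rule_key, " ", rule_direction, " ",
           rule_threshold, ") selects no model; pass member_ids instead",
           call. = FALSE)
    sel <- sel[order(-vals[sel])]
    members <- cands[utils::head(sel, max_models)]
  }
  feats <- unlist(lapply(members, `[[`, "selected_features"))
  occ <- sort(table(feats), decreasing = TRUE)
  structure(list(members = members, combination = combination,
                 feature_occurrences = occ),
            class = "sig_ensemble")
}

#' @export
print.sig_ensemble <- function(x, ...) {
  cat(sprintf("sig_ensemble (%s) with %d member(s): %s\n", x$combination,
              length(x$members),
              paste(vapply(x$members, `[[`, character(1), "unique_id"),
                    collapse = ", ")))
  invisible(x)
}

combine_probs <- function(prob_list, combination) {
  classes <- colnames(prob_list[[1L]])
  n <- nrow(prob_list[[1L]])
  arr <- simplify2array(prob_list)         # n x classes x members
  if (length(dim(arr)) == 2L) arr <- array(arr, c(n, length(classes), 1L))
  out <- switch(combination,
    average = apply(arr, c(1, 2), mean),
    product = {
      m <- apply(pmax(arr, 1e-9), c(1, 2), prod)
      m / rowSums(m)
    },
    median = {
      m <- apply(arr, c(1, 2), stats::median)
      sw <- rowSums(m)
      m / ifelse(sw == 0, 1, sw)
    },
    majority = {
      avg <- apply(arr, c(1, 2), mean)
      votes <- matrix(0, n, length(classes))
      for (j in seq_len(dim(arr)[3L])) {
        w <- max.col(matrix(arr[, , j], nrow = n), ties.method = "first")
        votes[cbind(seq_len(n), w)] <- votes[cbind(seq_len(n), w)] + 1
      }
      onehot <- matrix(0, n, length(classes))
      for (i in seq_len(n)) {
        top <- which(votes[i, ] == max(votes[i, ]))
        pick <- if (length(top) > 1L) top[which.max(avg[i, top])] else top
        onehot[i, pick] <- 1
      }
      onehot
    })
  colnames(out) <- classes
  out
}

#' Predict with an ensemble vote classifier
#'
#' Combines the members' class-probability vectors: `average` is the
#' arithmetic mean, `product` the elementwise product renormalised (with a
#' 1e-9 floor so no member can veto a class outright), `median` the
#' elementwise median renormalised, and `majority` a one-hot of the modal
#' predicted class (ties broken by the highest average probability).
#'
#' @param object A `sig_ensemble`.
#' @param newdata A `merged_dataset` or feature data.frame.
#' @param ... Unused.
#' @return List with `class` and `prob` (instances x classes).
#' @export
predict.sig_ensemble <- function(object, newdata, ...) {
  df <- if (inherits(newdata, "merged_dataset")) newdata$data else newdata
  prob_list <- lapply(object$members, function(m) {
    missing <- setdiff(m$selected_features, colnames(df))
    if (length(missing))
      stop("member ", m$unique_id, " requires missing feature(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    predict(m$report$model, df)$prob
  })
  classes <- sort(unique(unlist(lapply(prob_list, colnames))))
  prob_list <- lapply(prob_list, as_prob_matrix, levels = classes)
  prob <- combine_probs(prob_list, object$combination)
  list(class = prob_to_class(prob), prob = prob)
}

# ---- correlated features ------------------------------------------------

#' Recover correlated and rank-neighbour features for a signature
#'
#' For every signature feature, every other feature of the full
#' (pre-reduction) dataset whose absolute Pearson or Spearman correlation
#' with it reaches `r_min` is recovered with its coefficient, so redundant
#' features discarded during selection (including those cut by the ranking
#' cap) are restored for interpretation. Ranked features whose merit lies
#' within `score_epsilon` of a signature feature's merit are additionally
#' recovered as ranking neighbours. Nominal signature features are skipped
#' for Pearson with a warning; Spearman is still attempted on rank-encoded
#' values.
#'
#' @param signature Character vector of signature (core) feature names.
#' @param full_dataset The pre-reduction `merged_dataset`.
#' @param ranking Optional `ranked_features` (enables merit neighbours).
#' @param r_min Correlation threshold (default 0.95).
#' @param score_epsilon Merit-difference threshold (default 0.01).
#' @return An `enriched_signature`: `core`, `recovered` (data.frame:
#'   feature, signature_feature, evidence, value), `r_min`,
#'   `score_epsilon`.
#' @export
correlated_features <- function(signature, full_dataset, ranking = NULL,
                                r_min = 0.95, score_epsilon = 0.01) {
  data <- full_dataset$data
  unknown <- setdiff(signature, colnames(data))
  if (length(unknown))
    stop("signature feature(s) absent from dataset: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  num_encode <- function(col) {
    if (is.numeric(col)) col else as.numeric(factor(col))
  }
  is_num <- vapply(data, is.numeric, logical(1))
  others <- setdiff(colnames(data), signature)
  xmat <- vapply(data[others], num_encode, numeric(nrow(data)))
  rec <- list()
  for (sf in signature) {
    col <- data[[sf]]
    if (!is.numeric(col)) {
      warning("nominal signature feature '", sf,
              "' skipped for Pearson; Spearman uses rank-encoded values",
              call. = FALSE)
    }
    v <- num_encode(col)
    pear <- if (is.numeric(col))
      suppressWarnings(as.vector(stats::cor(xmat[, is_num[others],
                                                 drop = FALSE], v)))
    else NULL
    spear <- suppressWarnings(as.vector(stats::cor(apply(xmat, 2, rank),
                                                   rank(v))))
    if (!is.null(pear)) {
      hit <- which(!is.na(pear) & abs(pear) >= r_min - 1e-12)
      nms <- others[is_num[others]][hit]
      if (length(hit))
        rec[[length(rec) + 1L]] <-
          data.frame(feature = nms, signature_feature = sf,
                     evidence = "pearson", value = pear[hit],
                     stringsAsFactors = FALSE)
    }
    hit <- which(!is.na(spear) & abs(spear) >= r_min - 1e-12)
    if (length(hit))
      rec[[length(rec) + 1L]] <-
        data.frame(feature = others[hit], signature_feature = sf,
                   evidence = "spearman", value = spear[hit],
                   stringsAsFactors = FALSE)
    if (!is.null(ranking) && sf %in% names(ranking$merit)) {
      dm <- abs(ranking$merit - ranking$merit[[sf]])
      nb <- setdiff(names(ranking$merit)[dm <= score_epsilon &
                                           abs(ranking$merit) > 0],
                    signature)
      if (length(nb))
        rec[[length(rec) + 1L]] <-
          data.frame(feature = nb, signature_feature = sf,
                     evidence = "merit_neighbor", value = dm[nb],
                     stringsAsFactors = FALSE)
    }
  }
  recovered <- if (length(rec)) do.call(rbind, rec) else
    data.frame(feature = character(0), signature_feature = character(0),
               evidence = character(0), value = numeric(0))
  recovered <- recovered[!recovered$feature %in% signature, , drop = FALSE]
  rownames(recovered) <- NULL
  structure(list(core = signature, recovered = recovered, r_min = r_min,
                 score_epsilon = score_epsilon),
            class = "enriched_signature")
}

#' @export
print.enriched_signature <- function(x, ...) {
  cat(sprintf("enriched_signature: %d core + %d recovered feature(s)\n",
              length(x$core), length(unique(x$recovered$feature))))
  invisible(x)
}

# ---- registry CSV -------------------------------------------------------

registry_row <- function(cand) {
  r <- cand$report
  flat <- list(unique_id = cand$unique_id,
               classifier = cand$task$classifier$id,
               family = cand$task$classifier$family,
               hyperparameters = paste(
                 names(cand$task$classifier$hyperparameters),
                 unlist(cand$task$classifier$hyperparameters),
                 sep = "=", collapse = ";"),
               criterion = cand$task$criterion,
               method = cand$task$method,
               k = cand$task$k,
               criterion_score = cand$criterion_score,
               n_features = length(cand$selected_features),
               features = paste(cand$selected_features, collapse = "|"),
               degenerate = isTRUE(cand$degenerate),
               seed = cand$seed)
  proc_names <- c("cv10", "loocv", "holdout", "repeated_holdout",
                  "bootstrap")
  metric_names <- if (!is.null(r) && r$problem_type == "regression")
    c("cc", "rmse")
  else c("acc", "ber", "mcc", "auc", "auprc", "sensitivity", "specificity")
  for (p in proc_names) for (m in metric_names) {
    val <- if (!is.null(r) && !is.null(r$procedures[[p]]))
      unname(r$procedures[[p]][[m]]) else NA_real_
    flat[[paste(p, m, sep = "_")]] <- val
  }
  if (!is.null(r)) {
    for (s in names(r$summary)) flat[[s]] <- unname(r$summary[[s]])
    flat$estimator_632plus <- r$estimator_632plus
    flat$bias_632plus <- r$bias_632plus
    flat$err_resub <- r$err_resub
    flat$err_boot <- r$err_boot
  }
  as.data.frame(flat, stringsAsFactors = FALSE)
}

#' Write (or append to) the CSV model registry
#'
#' One row per candidate: identifier, classifier and hyperparameters,
#' criterion, search method, selected features, every per-procedure metric,
#' the stability summary and the 0.632+ estimate. Appending preserves
#' earlier rows byte-identically, so the file doubles as the run
#' checkpoint.
#'
#' @param models A `sig_model_list`.
#' @param path Output CSV path.
#' @param append Append to an existing registry (header written only when
#'   the file does not yet exist).
#' @return `path`, invisibly.
#' @export
write_model_registry <- function(models, path, append = FALSE) {
  rows <- lapply(models$candidates, registry_row)
  df <- do.call(rbind, rows)
  write_header <- !(append && file.exists(path))
  utils::write.table(df, path, sep = ",", qmethod = "double",
                     row.names = FALSE, col.names = write_header,
                     append = append && file.exists(path))
  invisible(path)
}

#' Read a model registry CSV
#'
#' @param path Registry CSV path.
#' @return Data frame of candidate rows.
#' @export
read_model_registry <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export the signature subset of a dataset
#'
#' Writes a delimited table with the id column, the signature feature
#' columns and the class column, for use in external visualisation tools.
#'
#' @param dataset A `merged_dataset`.
#' @param signature Nonempty character vector of feature names.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
export_signature_subset <- function(dataset, signature, path, sep = ",") {
  if (!length(signature)) stop("empty signature", call. = FALSE)
  unknown <- setdiff(signature, colnames(dataset$data))
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  df <- data.frame(id = dataset$sample_ids,
                   dataset$data[, signature, drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[[dataset$class_name]] <- dataset$y
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
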