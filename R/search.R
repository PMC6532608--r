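# Combined feature-subset and model search. For every classifier and every
# optimisation criterion, four stepwise searches (FSS, BSS, FSSBSE, BSSFSE)
# walk the merit-ranked feature list, tentatively adding each feature and
# keeping it only when the 10-fold-CV criterion strictly improves; the *BSE
# variants re-try removal of previously kept features after each
# acceptance. A per-classifier top-k baseline completes the candidate list.

SEARCH_METHODS <- c("FSS", "BSS", "FSSBSE", "BSSFSE")
DEFAULT_TOP_K <- c(1L, 5L, 10L, 15L, 20L, 25L, 30L, 40L, 50L, 75L, 100L)

string_hash <- function(s) {
  h <- 5381
  for (c in utf8ToInt(s)) h <- (h * 33 + c) %% 2147483647
  h
}

#' Construct a search task
#'
#' @param classifier A `classifier_spec`.
#' @param criterion Criterion name (see [criterion_directions()]).
#' @param method One of `"FSS"`, `"BSS"`, `"FSSBSE"`, `"BSSFSE"`,
#'   `"TOPK"`.
#' @param k Subset size (TOPK only).
#' @return A `search_task`.
#' @export
search_task <- function(classifier, criterion, method, k = NA_integer_) {
  if (!method %in% c(SEARCH_METHODS, "TOPK"))
    stop("unknown search method '", method, "'", call. = FALSE)
  if (!criterion %in% names(criterion_directions()))
    stop("unknown criterion '", criterion, "'", call. = FALSE)
  structure(list(classifier = classifier, criterion = criterion,
                 method = method, k = k),
            class = "search_task")
}

task_id <- function(task) {
  if (task$method == "TOPK")
    sprintf("%s_%s_top%d", task$classifier$id, task$criterion, task$k)
  else
    sprintf("%s_%s_%s", task$classifier$id, task$criterion, task$method)
}

new_candidate <- function(task, features, score, report, trace = NULL,
                          degenerate = FALSE, seed = NA_integer_,
                          folds = NA_integer_) {
  structure(list(unique_id = task_id(task), task = task,
                 selected_features = features, criterion_score = score,
                 report = report, trace = trace, degenerate = degenerate,
                 seed = seed, folds = folds),
            class = "sig_candidate")
}

#' @export
print.sig_candidate <- function(x, ...) {
  cat(sprintf("sig_candidate %s: %d feature(s), %s = %.4f%s\n",
              x$unique_id, length(x$selected_features), x$task$criterion,
              x$criterion_score,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

# Criterion value of a subset by k-fold CV with a fixed fold partition.
subset_criterion <- function(spec, features, train, fold_list, seed,
                             criterion) {
  m <- cross_validate(spec, features, train, seed = seed,
                      fold_list = fold_list)
  criterion_value(m, criterion)$value
}

#' Stepwise feature-subset selection for one classifier and criterion
#'
#' Walks the ranked feature order (inverted for the backward variants),
#' tentatively adding each feature and evaluating the subset by k-fold CV
#' on the optimisation criterion; a feature is kept only when the criterion
#' strictly improves (ties reject, so equally predictive features are kept
#' by order of appearance). For the elimination variants (FSSBSE, BSSFSE),
#' each acceptance triggers a backward scan over the previously kept
#' features, from the one before the last kept back to the first, removing
#' any whose removal strictly improves the criterion; the improved score is
#' carried forward. The criterion starts from the worst value (0 when
#' maximised, 1000 when minimised). If no feature is ever accepted, a
#' degenerate single-feature candidate (the best-ranked feature) is
#' returned with a flag.
#'
#' @param ranked A `ranked_features` object.
#' @param task A `search_task` with a stepwise method.
#' @param train Training `merged_dataset`.
#' @param folds CV folds (default 10).
#' @param seed Integer seed.
#' @param evaluate Run the full [evaluate_candidate()] battery on the final
#'   subset (default TRUE). Disable for trace-only runs.
#' @param split `split_dataset` used when `evaluate = TRUE`; defaults to a
#'   no-test split of `train`.
#' @param repeats,loocv_limit Passed to [evaluate_candidate()].
#' @param record_trace Keep the add/remove decision trace.
#' @return A `sig_candidate` (with `trace` rows: feature, action,
#'   score, accepted when requested).
#' @export
stepwise_select <- function(ranked, task, train, folds = 10L, seed = 1L,
                            evaluate = TRUE, split = NULL, repeats = 100L,
                            loocv_limit = 500L, record_trace = FALSE) {
  stopifnot(task$method %in% SEARCH_METHODS)
  ord <- ranked$order
  if (task$method %in% c("BSS", "BSSFSE")) ord <- rev(ord)
  dir <- criterion_directions()[[task$criterion]]
  better <- if (dir == "maximize") function(a, b) a > b
            else function(a, b) a < b
  score <- if (dir == "maximize") 0 else 1000
  fold_list <- make_folds(train$y, folds, seed,
                          train$problem_type == "classification")
  eval_subset <- function(feats)
    subset_criterion(task$classifier, feats, train, fold_list, seed,
                     task$criterion)

  selected <- character(0)
  accepted_any <- FALSE
  trace <- list()
  note <- function(feature, action, sc, accepted) {
    if (record_trace)
      trace[[length(trace) + 1L]] <<-
        data.frame(feature = feature, action = action, score = sc,
                   accepted = accepted, stringsAsFactors = FALSE)
  }
  eliminate <- task$method %in% c("FSSBSE", "BSSFSE")

  for (a in ord) {
    cand_score <- eval_subset(c(selected, a))
    if (!better(cand_score, score)) {
      note(a, "add", cand_score, FALSE)
      next
    }
    selected <- c(selected, a)
    score <- cand_score
    accepted_any <- TRUE
    note(a, "add", cand_score, TRUE)
    if (eliminate && length(selected) > 1L) {
      # scan previously kept features, before-last back to first
      for (f in rev(selected[-length(selected)])) {
        sub_score <- eval_subset(setdiff(selected, f))
        if (better(sub_score, score)) {
          selected <- setdiff(selected, f)
          score <- sub_score
          note(f, "remove", sub_score, TRUE)
        } else {
          note(f, "remove", sub_score, FALSE)
        }
      }
    }
  }

  degenerate <- FALSE
  if (!accepted_any) {
    selected <- ranked$order[1L]
    score <- eval_subset(selected)
    degenerate <- TRUE
  }
  report <- NULL
  if (evaluate) {
    if (is.null(split))
      split <- stratified_split(train, 1, seed)
    report <- evaluate_candidate(task$classifier, selected, split, folds,
                                 repeats, loocv_limit, seed)
    if (is.null(report)) return(NULL)
  }
  new_candidate(task, selected, score, report,
                trace = if (record_trace) do.call(rbind, trace) else NULL,
                degenerate = degenerate, seed = seed, folds = folds)
}

#' Top-k feature-subset baseline
#'
#' Takes the first `k` features of the ranked order (clipped with a warning
#' when fewer are available) and evaluates the subset like any candidate.
#'
#' @inheritParams stepwise_select
#' @param task A `search_task` with method `"TOPK"` and a `k`.
#' @return A `sig_candidate`.
#' @export
top_k_select <- function(ranked, task, train, folds = 10L, seed = 1L,
                         evaluate = TRUE, split = NULL, repeats = 100L,
                         loocv_limit = 500L) {
  stopifnot(task$method == "TOPK")
  k <- task$k
  if (k > length(ranked$order)) {
    warning("k = ", k, " clipped to ", length(ranked$order),
            " ranked features", call. = FALSE)
    k <- length(ranked$order)
  }
  selected <- ranked$order[seq_len(k)]
  fold_list <- make_folds(train$y, folds, seed,
                          train$problem_type == "classification")
  score <- subset_criterion(task$classifier, selected, train, fold_list,
                            seed, task$criterion)
  report <- NULL
  if (evaluate) {
    if (is.null(split)) split <- stratified_split(train, 1, seed)
    report <- evaluate_candidate(task$classifier, selected, split, folds,
                                 repeats, loocv_limit, seed)
    if (is.null(report)) return(NULL)
  }
  new_candidate(task, selected, score, report, seed = seed, folds = folds)
}

compatible_with <- function(spec, dataset) {
  if (!dataset$problem_type %in% spec$supports) return(FALSE)
  if (dataset$problem_type == "classification" && spec$binary_only &&
      length(unique(as.character(dataset$y))) > 2L) return(FALSE)
  TRUE
}

build_task_list <- function(registry, criteria, methods, k_list,
                            topk_per_criterion = FALSE) {
  tasks <- list()
  for (spec in registry) {
    for (crit in criteria)
      for (m in methods)
        tasks[[length(tasks) + 1L]] <- search_task(spec, crit, m)
    topk_crit <- if (topk_per_criterion) criteria else criteria[1L]
    for (crit in topk_crit)
      for (k in k_list)
        tasks[[length(tasks) + 1L]] <- search_task(spec, crit, "TOPK", k)
  }
  tasks
}

#' Run the full classifier x criterion x search-method model search
#'
#' For every classifier in the registry: one stepwise candidate per
#' criterion and method, plus one top-k candidate per `k` (evaluated under
#' the first criterion; per-criterion top-k is available via
#' `topk_per_criterion`). Classifier/data incompatibilities are skipped
#' with a log line. Every task derives its own seed by stable hashing of
#' (classifier id, criterion, method, k) combined with the master seed, so
#' results are identical for any concurrency degree. Candidates are
#' appended to the checkpointed model registry as they complete.
#'
#' @param ranked A `ranked_features` object.
#' @param registry List of `classifier_spec` objects.
#' @param criteria Character vector of criterion names.
#' @param methods Stepwise methods to run (default all four).
#' @param split A `split_dataset`.
#' @param seed Master seed.
#' @param k_list Top-k sizes (default `c(1,5,10,15,20,25,30,40,50,75,100)`).
#' @param folds,repeats,loocv_limit Evaluation sizes.
#' @param cores Concurrency degree (forked workers; results are identical
#'   to sequential execution).
#' @param checkpoint_dir Optional run directory; when set, the registry CSV
#'   and per-candidate model files are written as candidates complete.
#' @param topk_per_criterion Evaluate top-k under every criterion.
#' @param progress Log progress counts.
#' @return A `sig_model_list` (list of `sig_candidate`s).
#' @export
run_search <- function(ranked, registry, criteria, methods = SEARCH_METHODS,
                       split = NULL, seed = 1L, k_list = DEFAULT_TOP_K,
                       folds = 10L, repeats = 100L, loocv_limit = 500L,
                       cores = 1L, checkpoint_dir = NULL,
                       topk_per_criterion = FALSE, progress = FALSE) {
  train <- ranked$dataset
  if (is.null(split)) split <- stratified_split(train, 1, seed)
  if (!length(registry))
    return(structure(list(candidates = list()), class = "sig_model_list"))
  tasks <- build_task_list(registry, criteria, methods, k_list,
                           topk_per_criterion)
  compat <- vapply(tasks, function(t) compatible_with(t$classifier, train),
                   logical(1))
  for (t in tasks[!compat])
    message("skipping incompatible task ", task_id(t))
  tasks <- tasks[compat]
  if (!is.null(checkpoint_dir))
    dir.create(file.path(checkpoint_dir, "models"), recursive = TRUE,
               showWarnings = FALSE)

  run_one <- function(i) {
    task <- tasks[[i]]
    tseed <- (string_hash(task_id(task)) + as.numeric(seed)) %% 2147483629
    cand <- if (task$method == "TOPK") {
      top_k_select(ranked, task, train, folds, tseed, split = split,
                   repeats = repeats, loocv_limit = loocv_limit)
    } else {
      stepwise_select(ranked, task, train, folds, tseed, split = split,
                      repeats = repeats, loocv_limit = loocv_limit)
    }
    if (progress)
      message(sprintf("[%d/%d] %s %s", i, length(tasks), task_id(task),
                      if (is.null(cand)) "(skipped)" else "done"))
    cand
  }

  if (cores > 1L) {
    results <- parallel::mclapply(seq_along(tasks), run_one,
                                  mc.cores = cores)
    failed <- vapply(results, inherits, logical(1), "try-error")
    if (any(failed)) stop("parallel task failed: ",
                          results[[which(failed)[1L]]], call. = FALSE)
  } else {
    results <- vector("list", length(tasks))
    for (i in seq_along(tasks)) {
      results[[i]] <- run_one(i)
      if (!is.null(checkpoint_dir) && !is.null(results[[i]]))
        checkpoint_candidate(results[[i]], checkpoint_dir)
    }
  }
  results <- Filter(Negate(is.null), results)
  if (cores > 1L && !is.null(checkpoint_dir))
    for (cand in results) checkpoint_candidate(cand, checkpoint_dir)
  structure(list(candidates = results), class = "sig_model_list")
}

checkpoint_candidate <- function(cand, dir) {
  write_model_registry(structure(list(candidates = list(cand)),
                                 class = "sig_model_list"),
                       file.path(dir, "registry.csv"), append = TRUE)
  saveRDS(cand, file.path(dir, "models", paste0(cand$unique_id, ".rds")))
}

#' @export
print.sig_model_list <- function(x, ...) {
  cat(sprintf("sig_model_list: %d candidate model(s)\n",
              length(x$candidates)))
  invisible(x)
}

#' @export
length.sig_model_list <- function(x) length(x$candidates)
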