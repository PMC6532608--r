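# Independent oracles and fixture builders shared by the test files. These
# are deliberately plain, loop-based implementations coded straight from
# the textbook definitions / the published pseudocode, kept separate from
# the package's own code paths.

# ---- brute-force metric oracles ----------------------------------------

oracle_binary_metrics <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  pos <- tp + fn; neg <- fp + tn
  ber_terms <- c(if (pos > 0) fn / pos, if (neg > 0) fp / neg)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  # one-vs-rest per class, then averaged weighted by class prevalence
  # (classes without true instances, or with undefined values, excluded)
  sens_class <- c(if (pos > 0) tp / pos else NA_real_,
                  if (neg > 0) tn / neg else NA_real_)
  spec_class <- c(if (neg > 0) tn / neg else NA_real_,   # pos class spec
                  if (pos > 0) tp / pos else NA_real_)   # neg class spec
  w <- c(pos, neg) / n
  wmean <- function(v, has_truth) {
    ok <- has_truth & !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  has_truth <- c(pos > 0, neg > 0)
  list(acc = (tp + tn) / n, ber = mean(ber_terms), mcc = mcc,
       sens = wmean(sens_class, has_truth),
       spec = wmean(spec_class, has_truth))
}

# AUC by exhaustive pairwise comparison (ties count 1/2).
oracle_pairwise_auc <- function(scores, positive) {
  ps <- scores[positive]; ns <- scores[!positive]
  if (!length(ps) || !length(ns)) return(NA_real_)
  total <- 0
  for (p in ps) for (q in ns)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(ps) * length(ns))
}

# Average precision by direct summation over the ranked list.
oracle_average_precision <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  ap <- 0; tp <- 0
  for (i in seq_along(pos)) {
    if (pos[i]) {
      tp <- tp + 1
      ap <- ap + tp / i
    }
  }
  ap / sum(positive)
}

# Information gain for nominal inputs by direct entropy summation.
oracle_ig <- function(feature, classes) {
  ent <- function(v) {
    out <- 0
    for (lv in unique(v)) {
      p <- sum(v == lv) / length(v)
      out <- out - p * log2(p)
    }
    out
  }
  cond <- 0
  for (lv in unique(feature)) {
    idx <- feature == lv
    cond <- cond + sum(idx) / length(feature) * ent(classes[idx])
  }
  ent(classes) - cond
}

# ---- textbook RReliefF oracle ------------------------------------------
# Plain-loop regression ReliefF with uniform neighbour weights, iterating
# over every instance (so it is comparable to relieff() run with
# sample_iterations = n, where the sampled set is all instances).
oracle_rrelieff <- function(x, y, k) {
  n <- nrow(x); p <- ncol(x)
  norm <- apply(x, 2, function(c) {
    r <- range(c); if (diff(r) == 0) rep(0, n) else (c - r[1]) / diff(r)
  })
  yr <- range(y)
  yn <- if (diff(yr) == 0) rep(0, n) else (y - yr[1]) / diff(yr)
  n_dc <- 0; n_da <- numeric(p); n_dcda <- numeric(p)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sum(abs(norm[j, ] - norm[i, ]))
    nb <- order(d, seq_len(n))
    nb <- nb[nb != i][seq_len(k)]
    for (j in nb) {
      ddy <- abs(yn[j] - yn[i])
      n_dc <- n_dc + ddy / k
      for (f in seq_len(p)) {
        dda <- abs(norm[j, f] - norm[i, f])
        n_da[f] <- n_da[f] + dda / k
        n_dcda[f] <- n_dcda[f] + dda * ddy / k
      }
    }
  }
  n_dcda / n_dc - (n_da - n_dcda) / (n - n_dc)
}

# ---- straight-from-pseudocode stepwise reference -----------------------
# Reference realisation of the published subset-search loops, with the two
# documented clarifications: strict improvement (ties reject) and the
# post-elimination score carried forward. `eval_fn(features)` must return
# the 10-CV criterion value; `maximize` gives the direction.
ref_stepwise <- function(order, method, eval_fn, maximize = TRUE) {
  if (method %in% c("BSS", "BSSFSE")) order <- rev(order)
  score <- if (maximize) 0 else 1000
  rule <- if (maximize) function(new, cur) new <= cur  # "lesser than" reject
          else function(new, cur) new >= cur
  selected <- character(0)
  trace <- list()
  push <- function(feature, action, sc, accepted)
    trace[[length(trace) + 1L]] <<- list(feature = feature, action = action,
                                         score = sc, accepted = accepted)
  for (a in order) {
    new_score <- eval_fn(c(selected, a))
    if (rule(new_score, score)) {
      push(a, "add", new_score, FALSE)
      next
    }
    selected <- c(selected, a)
    score <- new_score
    push(a, "add", new_score, TRUE)
    if (method %in% c("FSSBSE", "BSSFSE") && length(selected) > 1L) {
      scan <- rev(selected[-length(selected)])
      for (f in scan) {
        sub_score <- eval_fn(setdiff(selected, f))
        if (!rule(sub_score, score)) {
          selected <- setdiff(selected, f)
          score <- sub_score
          push(f, "remove", sub_score, TRUE)
        } else {
          push(f, "remove", sub_score, FALSE)
        }
      }
    }
  }
  list(selected = selected, score = score,
       trace = do.call(rbind, lapply(trace, as.data.frame)))
}

# Independent 1-nearest-neighbour fold-averaged CV accuracy: features are
# standardised with training-fold mean/sd, distances are Euclidean, ties go
# to the lowest training index.
ref_knn1_cv_acc <- function(data, y, features, fold_list) {
  x <- as.matrix(data[, features, drop = FALSE])
  accs <- numeric(length(fold_list))
  for (i in seq_along(fold_list)) {
    te <- fold_list[[i]]
    tr <- setdiff(seq_len(nrow(x)), te)
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdv[is.na(sdv) | sdv == 0] <- Inf      # constant column contributes 0
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    pred <- character(length(te))
    for (j in seq_along(te)) {
      d <- sqrt(rowSums((xtr - matrix(xte[j, ], nrow(xtr), ncol(xtr),
                                      byrow = TRUE))^2))
      pred[j] <- as.character(y[tr])[which.min(d)]
    }
    accs[i] <- mean(pred == as.character(y[te]))
  }
  mean(accs)
}

# ---- fixture builders ---------------------------------------------------

# Tiny dataset with one perfectly separating feature and pure noise.
make_separable_dataset <- function(n = 40, n_noise = 9, seed = 1,
                                   gap = 6) {
  set.seed(seed)
  y <- rep(c("A", "B"), length.out = n)
  df <- data.frame(f1 = ifelse(y == "B", gap, 0) + rnorm(n, sd = 0.3))
  for (i in seq_len(n_noise)) df[[paste0("n", i)]] <- rnorm(n)
  sigselect:::new_merged_dataset(sprintf("s%02d", 1:n), df, y,
                                 "classification", "class")
}

make_ranked <- function(dataset, order) {
  merit <- stats::setNames(rev(seq_along(order)) / length(order), order)
  reduced <- dataset
  reduced$data <- dataset$data[, order, drop = FALSE]
  structure(list(dataset = reduced, merit = merit, order = order,
                 threshold = 0.01, cap = 1000L),
            class = "ranked_features")
}

knn1_spec <- function() {
  Filter(function(s) s$id == "knn1",
         default_classifiers("classification"))[[1]]
}

# Lightweight stand-in candidate for selection-level tests.
make_fake_candidate <- function(id, avg_mcc, std_mcc, features = c("g1"),
                                test_mcc = NA_real_) {
  report <- structure(list(
    procedures = list(holdout = c(acc = NA, ber = NA, mcc = test_mcc,
                                  auc = NA, auprc = NA, sensitivity = NA,
                                  specificity = NA)),
    summary = c(avg_mcc = avg_mcc, std_mcc = std_mcc,
                avg_ber = (1 - avg_mcc) / 2, std_ber = std_mcc / 2),
    problem_type = "classification"), class = "evaluation_report")
  task <- search_task(knn1_spec(), "mcc", "FSS")
  structure(list(unique_id = id, task = task,
                 selected_features = features, criterion_score = avg_mcc,
                 report = report, degenerate = FALSE, seed = 1L,
                 folds = 10L),
            class = "sig_candidate")
}

# Classifier spec that always predicts a fixed probability vector; used by
# the ensemble combination tests.
constant_prob_spec <- function(id, prob) {
  classifier_spec(id, "constant",
    fit = function(x, y, h) list(prob = prob,
                                 lv = sort(unique(as.character(y)))),
    predict = function(m, x) {
      p <- matrix(rep(m$prob, each = nrow(x)), nrow(x))
      colnames(p) <- m$lv
      list(class = colnames(p)[max.col(p, ties.method = "first")], prob = p)
    })
}
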