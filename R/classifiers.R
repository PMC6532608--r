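# Classifier registry. Each entry is a classifier_spec: an identifier, a
# family (used for priority scheduling: fast families first), hyperparameters
# and fit/predict closures with a uniform interface:
#   fit(x_df, y, hyper)                -> opaque model
#   predict(model, x_df)               -> list(class, prob) | numeric vector
# Classification predictions always carry a probability matrix whose columns
# are the training class levels (sorted); the predicted class is the argmax,
# ties resolved by column order. Stochastic learners are seeded by the
# caller (see train_classifier), so every fit is reproducible.

#' Construct a classifier specification
#'
#' @param id Unique identifier.
#' @param family Algorithm family (e.g. "nearest-neighbor", "bayes", "tree",
#'   "forest", "linear", "svm", "neural").
#' @param fit Function `(x_df, y, hyper)` returning a fitted model.
#' @param predict Function `(model, x_df)` returning predictions.
#' @param hyperparameters Named list of hyperparameter values.
#' @param supports Character subset of `c("classification", "regression")`.
#' @param binary_only Logical; skip for multi-class problems.
#' @param priority Integer; lower trains earlier (fast families first).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(id, family, fit, predict, hyperparameters = list(),
                            supports = "classification", binary_only = FALSE,
                            priority = 5L) {
  structure(list(id = id, family = family, hyperparameters = hyperparameters,
                 supports = supports, binary_only = binary_only,
                 priority = as.integer(priority), fit = fit,
                 predict = predict),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters))
    paste(names(x$hyperparameters), unlist(x$hyperparameters), sep = "=",
          collapse = ", ") else "defaults"
  cat(sprintf("classifier_spec %s [%s; %s] (%s)\n", x$id, x$family, hp,
              paste(x$supports, collapse = "/")))
  invisible(x)
}

# Numeric design-matrix encoder. Numeric columns are standardised with
# training mean/sd (constant columns map to 0); nominal columns become 0/1
# level indicators over the training levels (unseen test levels encode as
# all-zero). Returns a closure applicable to new data.
make_encoder <- function(train_df) {
  stats_ <- lapply(train_df, function(col) {
    if (is.numeric(col)) {
      list(kind = "num", mu = mean(col), sd = stats::sd(col))
    } else {
      list(kind = "nom", levels = sort(unique(as.character(col))))
    }
  })
  function(df) {
    cols <- lapply(names(stats_), function(nm) {
      st <- stats_[[nm]]
      col <- df[[nm]]
      if (st$kind == "num") {
        v <- if (is.na(st$sd) || st$sd == 0) rep(0, length(col)) else
          (col - st$mu) / st$sd
        m <- matrix(v, ncol = 1)
        colnames(m) <- nm
      } else {
        m <- outer(as.character(col), st$levels, `==`) * 1
        colnames(m) <- paste(nm, st$levels, sep = ".")
      }
      m
    })
    do.call(cbind, cols)
  }
}

prob_to_class <- function(prob) {
  colnames(prob)[max.col(prob, ties.method = "first")]
}

as_prob_matrix <- function(prob, levels) {
  m <- matrix(0, nrow(prob), length(levels), dimnames = list(NULL, levels))
  common <- intersect(colnames(prob), levels)
  m[, common] <- prob[, common]
  m
}

# ---- internal k-nearest-neighbour learner -------------------------------
# Hand-rolled so that full per-class vote probabilities and a deterministic
# distance tie rule (lowest training index wins) are available for both
# classification and regression.
knn_fit <- function(x_df, y, hyper) {
  enc <- make_encoder(x_df)
  list(enc = enc, x = enc(x_df), y = y, k = hyper$k %||% 5L)
}

knn_predict_raw <- function(model, x_df) {
  xq <- model$enc(x_df)
  k <- min(model$k, nrow(model$x))
  nb <- apply(xq, 1, function(q) {
    d <- sqrt(colSums((t(model$x) - q)^2))
    order(d, seq_along(d))[seq_len(k)]
  })
  if (is.null(dim(nb))) nb <- matrix(nb, nrow = 1L)  # k = 1
  t(nb)                                  # instances x k
}

knn_class_predict <- function(model, x_df) {
  nb <- knn_predict_raw(model, x_df)
  levels <- sort(unique(as.character(model$y)))
  prob <- t(apply(nb, 1, function(idx) {
    votes <- table(factor(as.character(model$y)[idx], levels = levels))
    as.numeric(votes) / length(idx)
  }))
  colnames(prob) <- levels
  list(class = prob_to_class(prob), prob = prob)
}

knn_reg_predict <- function(model, x_df) {
  nb <- knn_predict_raw(model, x_df)
  apply(nb, 1, function(idx) mean(model$y[idx]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- registry -----------------------------------------------------------

classification_registry <- function() {
  factorize <- function(df) {
    df[] <- lapply(df, function(c) if (is.numeric(c)) c else factor(c))
    df
  }
  list(
    classifier_spec("knn1", "nearest-neighbor",
      fit = knn_fit, predict = knn_class_predict,
      hyperparameters = list(k = 1L), priority = 1L),
    classifier_spec("knn5", "nearest-neighbor",
      fit = knn_fit, predict = knn_class_predict,
      hyperparameters = list(k = 5L), priority = 1L),
    classifier_spec("knn11", "nearest-neighbor",
      fit = knn_fit, predict = knn_class_predict,
      hyperparameters = list(k = 11L), priority = 1L),
    classifier_spec("nb", "bayes",
      fit = function(x, y, h) {
        list(m = e1071::naiveBayes(factorize(x), factor(y)),
             lv = sort(unique(as.character(y))), f = factorize)
      },
      predict = function(mod, x) {
        prob <- stats::predict(mod$m, mod$f(x), type = "raw")
        prob <- as_prob_matrix(prob, mod$lv)
        list(class = prob_to_class(prob), prob = prob)
      }, priority = 1L),
    classifier_spec("lda", "linear",
      fit = function(x, y, h) {
        enc <- make_encoder(x)
        xm <- enc(x)
        keep <- apply(xm, 2, function(c) stats::sd(c) > 0)
        list(m = MASS::lda(xm[, keep, drop = FALSE], grouping = factor(y)),
             enc = enc, keep = keep, lv = sort(unique(as.character(y))))
      },
      predict = function(mod, x) {
        p <- stats::predict(mod$m, mod$enc(x)[, mod$keep, drop = FALSE])
        prob <- as_prob_matrix(p$posterior, mod$lv)
        list(class = prob_to_class(prob), prob = prob)
      }, priority = 2L),
    classifier_spec("logistic", "linear",
      fit = function(x, y, h) {
        enc <- make_encoder(x)
        lv <- sort(unique(as.character(y)))
        df <- as.data.frame(enc(x))
        names(df) <- make.names(names(df))
        df$.y <- as.integer(as.character(y) == lv[2L])
        list(m = suppressWarnings(stats::glm(.y ~ ., data = df,
                                             family = stats::binomial())),
             enc = enc, lv = lv)
      },
      predict = function(mod, x) {
        df <- as.data.frame(mod$enc(x))
        names(df) <- make.names(names(df))
        p2 <- suppressWarnings(stats::predict(mod$m, df, type = "response"))
        prob <- cbind(1 - p2, p2)
        colnames(prob) <- mod$lv
        list(class = prob_to_class(prob), prob = prob)
      }, binary_only = TRUE, priority = 2L),
    classifier_spec("rpart", "tree",
      fit = function(x, y, h) {
        df <- factorize(x); df$.y <- factor(y)
        list(m = rpart::rpart(.y ~ ., data = df, method = "class"),
             lv = sort(unique(as.character(y))), f = factorize)
      },
      predict = function(mod, x) {
        prob <- stats::predict(mod$m, mod$f(x), type = "prob")
        prob <- as_prob_matrix(prob, mod$lv)
        list(class = prob_to_class(prob), prob = prob)
      }, priority = 2L),
    classifier_spec("rf100", "forest",
      fit = function(x, y, h) {
        list(m = randomForest::randomForest(factorize(x), factor(y),
                                            ntree = h$ntree %||% 100L),
             lv = sort(unique(as.character(y))), f = factorize)
      },
      predict = function(mod, x) {
        prob <- stats::predict(mod$m, mod$f(x), type = "prob")
        prob <- as_prob_matrix(prob, mod$lv)
        list(class = prob_to_class(prob), prob = prob)
      }, hyperparameters = list(ntree = 100L), priority = 4L),
    classifier_spec("svm_linear", "svm",
      fit = function(x, y, h) {
        enc <- make_encoder(x)
        list(m = e1071::svm(enc(x), factor(y), kernel = "linear",
                            cost = h$cost %||% 1, probability = TRUE),
             enc = enc, lv = sort(unique(as.character(y))))
      },
      predict = function(mod, x) {
        p <- stats::predict(mod$m, mod$enc(x), probability = TRUE)
        prob <- as_prob_matrix(attr(p, "probabilities"), mod$lv)
        list(class = prob_to_class(prob), prob = prob)
      }, hyperparameters = list(cost = 1), priority = 4L),
    classifier_spec("svm_rbf", "svm",
      fit = function(x, y, h) {
        enc <- make_encoder(x)
        list(m = e1071::svm(enc(x), factor(y), kernel = "radial",
                            cost = h$cost %||% 1, probability = TRUE),
             enc = enc, lv = sort(unique(as.character(y))))
      },
      predict = function(mod, x) {
        p <- stats::predict(mod$m, mod$enc(x), probability = TRUE)
        prob <- as_prob_matrix(attr(p, "probabilities"), mod$lv)
        list(class = prob_to_class(prob), prob = prob)
      }, hyperparameters = list(cost = 1), priority = 4L),
    classifier_spec("nnet5", "neural",
      fit = function(x, y, h) {
        enc <- make_encoder(x)
        yf <- factor(y)
        m <- nnet::nnet(enc(x), nnet::class.ind(yf),
                        size = h$size %||% 5L, decay = h$decay %||% 0.1,
                        maxit = 150L, trace = FALSE, softmax = TRUE)
        list(m = m, enc = enc, lv = levels(yf))
      },
      predict = function(mod, x) {
        prob <- stats::predict(mod$m, mod$enc(x))
        colnames(prob) <- mod$lv
        prob <- as_prob_matrix(prob, sort(mod$lv))
        list(class = prob_to_class(prob), prob = prob)
      }, hyperparameters = list(size = 5L, decay = 0.1), priority = 6L)
  )
}

regression_registry <- function() {
  list(
    classifier_spec("knnreg5", "nearest-neighbor",
      fit = knn_fit, predict = knn_reg_predict,
      hyperparameters = list(k = 5L), supports = "regression",
      priority = 1L),
    classifier_spec("lm", "linear",
      fit = function(x, y, h) {
        enc <- make_encoder(x)
        df <- as.data.frame(enc(x)); names(df) <- make.names(names(df))
        df$.y <- y
        list(m = stats::lm(.y ~ ., data = df), enc = enc)
      },
      predict = function(mod, x) {
        df <- as.data.frame(mod$enc(x)); names(df) <- make.names(names(df))
        unname(stats::predict(mod$m, df))
      }, supports = "regression", priority = 1L),
    classifier_spec("rpart_reg", "tree",
      fit = function(x, y, h) {
        df <- x; df[] <- lapply(df, function(c) if (is.numeric(c)) c
                                else factor(c))
        df$.y <- y
        list(m = rpart::rpart(.y ~ ., data = df, method = "anova"))
      },
      predict = function(mod, x) {
        df <- x; df[] <- lapply(df, function(c) if (is.numeric(c)) c
                                else factor(c))
        unname(stats::predict(mod$m, df))
      }, supports = "regression", priority = 2L),
    classifier_spec("rf100_reg", "forest",
      fit = function(x, y, h) {
        enc <- make_encoder(x)
        list(m = randomForest::randomForest(enc(x), y,
                                            ntree = h$ntree %||% 100L),
             enc = enc)
      },
      predict = function(mod, x) unname(stats::predict(mod$m, mod$enc(x))),
      hyperparameters = list(ntree = 100L), supports = "regression",
      priority = 4L),
    classifier_spec("svm_rbf_reg", "svm",
      fit = function(x, y, h) {
        enc <- make_encoder(x)
        list(m = e1071::svm(enc(x), y, kernel = "radial"), enc = enc)
      },
      predict = function(mod, x) unname(stats::predict(mod$m, mod$enc(x))),
      supports = "regression", priority = 4L)
  )
}

#' Default classifier registry
#'
#' Returns the built-in panel of classifier configurations for a problem
#' type. The `"default"` preset spans the families most used in biomedical
#' prediction (nearest-neighbour, naive Bayes, linear discriminant,
#' logistic, decision tree, random forest, SVM, small neural network); the
#' `"fast"` preset keeps only the cheapest families and is intended for
#' exploratory runs and small panels.
#'
#' @param problem_type `"classification"` or `"regression"`.
#' @param preset `"default"` or `"fast"`.
#' @return List of `classifier_spec` objects, ordered by priority.
#' @export
default_classifiers <- function(problem_type = c("classification",
                                                 "regression"),
                                preset = c("default", "fast")) {
  problem_type <- match.arg(problem_type)
  preset <- match.arg(preset)
  reg <- if (problem_type == "classification") classification_registry()
         else regression_registry()
  if (preset == "fast") {
    fast_ids <- c("knn5", "nb", "lda", "knnreg5", "lm")
    reg <- Filter(function(s) s$id %in% fast_ids, reg)
  }
  reg[order(vapply(reg, `[[`, integer(1), "priority"))]
}

#' Fit a classifier specification on data
#'
#' Restricts the dataset to the given features, seeds the RNG so stochastic
#' learners (random forest, neural networks) are reproducible, and fits.
#'
#' @param spec A `classifier_spec`.
#' @param dataset A `merged_dataset`.
#' @param features Feature names to use.
#' @param seed Integer seed.
#' @return A `sig_model`: list with `spec`, `features`, `model`, `classes`.
#' @export
train_classifier <- function(spec, dataset, features, seed = 1L) {
  x <- dataset$data[, features, drop = FALSE]
  rng <- local_rng(seed)
  model <- rng$with(function() spec$fit(x, dataset$y, spec$hyperparameters))
  structure(list(spec = spec, features = features, model = model,
                 classes = if (dataset$problem_type == "classification")
                   sort(unique(as.character(dataset$y))) else NULL,
                 problem_type = dataset$problem_type),
            class = "sig_model")
}

#' Predict with a fitted classifier
#'
#' @param object A `sig_model` from [train_classifier()].
#' @param newdata A `merged_dataset` or feature data.frame containing the
#'   model's features.
#' @param ... Unused.
#' @return For classification, a list with `class` (labels) and `prob`
#'   (matrix, columns = training class levels); for regression a numeric
#'   vector.
#' @export
predict.sig_model <- function(object, newdata, ...) {
  df <- if (inherits(newdata, "merged_dataset")) newdata$data else newdata
  missing <- setdiff(object$features, colnames(df))
  if (length(missing))
    stop("feature(s) absent from new data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  object$spec$predict(object$model, df[, object$features, drop = FALSE])
}
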