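test_that("folds partition the data exactly once, stratified by class", {
  y <- rep(c("A", "B"), c(24, 12))
  f <- make_folds(y, 10, seed = 2)
  expect_length(f, 10)
  expect_setequal(unlist(f), seq_along(y))
  expect_equal(sum(lengths(f)), length(y))          # pairwise disjoint
  # every fold keeps roughly the 2:1 balance
  for (fold in f)
    expect_lte(abs(sum(y[fold] == "A") - 2 * sum(y[fold] == "B")), 2)
  # n = 10, folds = 10 -> singleton test folds
  expect_true(all(lengths(make_folds(rep(c("A", "B"), 5), 10, 1)) == 1))
})

test_that("cross-validation is perfect on a separable fixture and seeded", {
  ds <- make_separable_dataset(n = 30, n_noise = 2, seed = 1)
  m <- cross_validate(knn1_spec(), "f1", ds, folds = 10, seed = 7)
  expect_equal(unname(m["acc"]), 1)
  expect_equal(unname(m["mcc"]), 1)
  m2 <- cross_validate(knn1_spec(), "f1", ds, folds = 10, seed = 7)
  expect_identical(m, m2)
})

test_that("LOOCV performs n fits and pools the held-out predictions", {
  fits <- 0L
  counting_majority <- classifier_spec("majority", "baseline",
    fit = function(x, y, h) {
      fits <<- fits + 1L
      tab <- sort(table(as.character(y)), decreasing = TRUE)
      list(lab = names(tab)[1], lv = sort(unique(as.character(y))))
    },
    predict = function(m, x) {
      prob <- matrix(as.numeric(m$lv == m$lab), nrow(x), length(m$lv),
                     byrow = TRUE, dimnames = list(NULL, m$lv))
      list(class = rep(m$lab, nrow(x)), prob = prob)
    })
  y <- c("A", "A", "A", "B")
  ds <- sigselect:::new_merged_dataset(paste0("s", 1:4),
                                       data.frame(f = c(1, 2, 3, 4)), y,
                                       "classification", "class")
  m <- suppressWarnings(loocv(counting_majority, "f", ds))
  expect_equal(fits, 4L)
  # the held-out B is predicted A; the three As are predicted A
  expect_equal(unname(m["acc"]), 3 / 4)
  # deterministic classifier -> identical repeated results
  expect_equal(m, suppressWarnings(loocv(counting_majority, "f", ds)))
})

test_that("holdout evaluation scores the reserved test set only", {
  ds <- make_separable_dataset(n = 30, n_noise = 1, seed = 2)
  model <- train_classifier(knn1_spec(), ds, "f1", seed = 1)
  same <- holdout_evaluate(model, ds)   # test = copy of train, perfect fit
  expect_equal(unname(same["acc"]), 1)
  empty <- sigselect:::subset_samples(ds, integer(0))
  m <- holdout_evaluate(model, empty)
  expect_true(all(is.na(m)))            # undefined, not zeros
  # feature missing from test data -> error
  bad <- ds; bad$data$f1 <- NULL
  expect_error(holdout_evaluate(model, bad), "absent")
})

test_that("repeated holdout with one repeat equals a single stratified split", {
  ds <- make_separable_dataset(n = 36, n_noise = 3, seed = 3)
  seed <- 11
  m1 <- repeated_holdout(knn1_spec(), "f1", ds, repeats = 1, seed = seed)
  sp <- stratified_split(ds, 2 / 3, seed = sigselect:::derive_seed(seed, 1))
  model <- train_classifier(knn1_spec(), sp$train, "f1",
                            seed = sigselect:::derive_seed(seed, 2))
  m2 <- holdout_evaluate(model, sp$test)
  expect_equal(unname(m1["acc"]), unname(m2["acc"]))
  # determinism and separable-fixture accuracy
  expect_identical(m1, repeated_holdout(knn1_spec(), "f1", ds,
                                        repeats = 1, seed = seed))
  m25 <- repeated_holdout(knn1_spec(), "f1", ds, repeats = 25, seed = 5)
  expect_gte(unname(m25["acc"]), 0.95)
})

test_that("bootstrap tests out-of-bag instances at the classical rate", {
  oob_sizes <- integer(0)
  probe <- classifier_spec("probe", "baseline",
    fit = function(x, y, h) list(lv = sort(unique(as.character(y)))),
    predict = function(m, x) {
      oob_sizes <<- c(oob_sizes, nrow(x))
      prob <- matrix(1 / length(m$lv), nrow(x), length(m$lv),
                     dimnames = list(NULL, m$lv))
      list(class = rep(m$lv[1], nrow(x)), prob = prob)
    })
  n <- 100
  ds <- sigselect:::new_merged_dataset(
    sprintf("s%03d", 1:n), data.frame(f = rnorm(n)),
    rep(c("A", "B"), n / 2), "classification", "class")
  invisible(bootstrap_evaluate(probe, "f", ds, repeats = 200, seed = 3))
  # classical limits: unique in-bag fraction ~ 0.632, out-of-bag ~ 0.368
  oob_frac <- mean(oob_sizes) / n
  expect_equal(oob_frac, (1 - 1 / n)^n, tolerance = 0.05)
  expect_equal(1 - oob_frac, 1 - (1 - 1 / n)^n, tolerance = 0.05)

  ds2 <- make_separable_dataset(n = 40, n_noise = 2, seed = 4)
  b <- bootstrap_evaluate(knn1_spec(), "f1", ds2, repeats = 30, seed = 1)
  cv <- cross_validate(knn1_spec(), "f1", ds2, seed = 1)
  expect_lt(abs(unname(b["acc"]) - unname(cv["acc"])), 0.05)
  expect_identical(b, bootstrap_evaluate(knn1_spec(), "f1", ds2,
                                         repeats = 30, seed = 1))
})

test_that("the 0.632+ estimator reproduces its closed form and limits", {
  # no overfitting: estimate collapses to the common error
  e <- estimator_632plus(0.2, 0.2, 0.5)
  expect_equal(e$estimate, 0.2)
  expect_equal(e$bias, 0)
  # hand-computed mid case
  e2 <- estimator_632plus(0.1, 0.3, 0.5)
  expect_equal(e2$R, 0.5)
  expect_equal(e2$weight, 0.632 / (1 - 0.368 * 0.5), tolerance = 1e-12)
  expect_equal(e2$estimate, 0.2549, tolerance = 5e-4)
  # maximal overfitting: weight 1, estimate = bootstrap error
  e3 <- estimator_632plus(0, 0.5, 0.5)
  expect_equal(e3$R, 1)
  expect_equal(e3$weight, 1, tolerance = 1e-12)
  expect_equal(e3$estimate, 0.5)
  # degenerate gamma: R defined as 0
  expect_equal(estimator_632plus(0.4, 0.5, 0.3)$R, 0)
})

test_that("0.632+ estimates stay between the two component errors", {
  set.seed(41)
  for (i in 1:50) {
    er <- runif(1, 0, 0.5); eb <- runif(1, 0, 0.8); g <- runif(1, 0.2, 1)
    est <- estimator_632plus(er, eb, g)$estimate
    lo <- min(er, min(eb, g)); hi <- max(er, min(eb, g))
    expect_gte(est, lo - 1e-12)
    expect_lte(est, hi + 1e-12)
  }
})

test_that("evaluate_candidate fills all procedures and the stability summary", {
  ds <- make_separable_dataset(n = 45, n_noise = 2, seed = 5, gap = 8)
  sp <- stratified_split(ds, 2 / 3, seed = 1)
  rep_ <- evaluate_candidate(knn1_spec(), "f1", sp, repeats = 15, seed = 2)
  expect_s3_class(rep_, "evaluation_report")
  expect_setequal(names(rep_$procedures),
                  c("cv10", "loocv", "holdout", "repeated_holdout",
                    "bootstrap"))
  expect_equal(unname(rep_$summary["avg_mcc"]), 1)
  expect_equal(unname(rep_$summary["std_mcc"]), 0)

  # sampling disabled -> holdout omitted from procedures and summary
  sp0 <- stratified_split(ds, 1, seed = 1)
  rep0 <- evaluate_candidate(knn1_spec(), "f1", sp0, repeats = 10,
                             seed = 2)
  expect_false("holdout" %in% names(rep0$procedures))

  # incompatible classifier -> NULL, candidate skipped
  broken <- classifier_spec("broken", "none",
    fit = function(x, y, h) stop("unsupported data"),
    predict = function(m, x) NULL)
  expect_message(out <- evaluate_candidate(broken, "f1", sp, seed = 1),
                 "skipped")
  expect_null(out)
})

test_that("stability summaries are means and population SDs over procedures", {
  mk <- function(vals) {
    procedures <- lapply(vals, function(v) c(mcc = v, ber = 1 - v))
    names(procedures) <- paste0("p", seq_along(vals))
    structure(list(procedures = procedures,
                   problem_type = "classification"),
              class = "evaluation_report")
  }
  s <- stability_summary(mk(rep(0.8, 5)))
  expect_equal(unname(s["avg_mcc"]), 0.8)
  expect_equal(unname(s["std_mcc"]), 0)
  s2 <- stability_summary(mk(c(1, 0)))
  expect_equal(unname(s2["avg_mcc"]), 0.5)
  expect_equal(unname(s2["std_mcc"]), 0.5)      # population SD
  # adding a procedure at the mean keeps the mean, shrinks the SD
  s3 <- stability_summary(mk(c(1, 0, 0.5)))
  expect_equal(unname(s3["avg_mcc"]), 0.5)
  expect_lt(unname(s3["std_mcc"]), unname(s2["std_mcc"]))
  expect_warning(stability_summary(mk(0.7)), "single procedure")
})

test_that("train-side procedures never depend on test-set values", {
  ds <- make_separable_dataset(n = 36, n_noise = 2, seed = 6)
  sp <- stratified_split(ds, 2 / 3, seed = 3)
  r1 <- evaluate_candidate(knn1_spec(), "f1", sp, repeats = 10, seed = 4)
  corrupted <- sp
  corrupted$test$data$f1 <- rev(corrupted$test$data$f1) + 100
  r2 <- evaluate_candidate(knn1_spec(), "f1", corrupted, repeats = 10,
                           seed = 4)
  for (p in c("cv10", "loocv", "repeated_holdout", "bootstrap"))
    expect_identical(r1$procedures[[p]], r2$procedures[[p]])
  expect_identical(r1$err_resub, r2$err_resub)
  expect_identical(r1$err_boot, r2$err_boot)
})
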