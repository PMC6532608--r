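test_that("the stability gate prefers stable models over nominally better ones", {
  ml <- structure(list(candidates = list(
    make_fake_candidate("m1", avg_mcc = 0.90, std_mcc = 0.05),
    make_fake_candidate("m2", avg_mcc = 0.95, std_mcc = 0.20))),
    class = "sig_model_list")
  expect_equal(best_model(ml)$unique_id, "m1")

  single <- structure(list(candidates = ml$candidates[1]),
                      class = "sig_model_list")
  expect_equal(best_model(single)$unique_id, "m1")

  unstable <- structure(list(candidates = list(
    make_fake_candidate("m1", 0.9, 0.30),
    make_fake_candidate("m2", 0.7, 0.12),
    make_fake_candidate("m3", 0.8, 0.25))),
    class = "sig_model_list")
  expect_warning(pick <- best_model(unstable), "stability gate")
  expect_equal(pick$unique_id, "m2")     # smallest std fallback

  expect_error(best_model(structure(list(candidates = list()),
                                    class = "sig_model_list")), "empty")
})

test_that("alternative selection keys use the holdout metrics", {
  ml <- structure(list(candidates = list(
    make_fake_candidate("m1", 0.9, 0.05, test_mcc = 0.2),
    make_fake_candidate("m2", 0.6, 0.05, test_mcc = 0.9))),
    class = "sig_model_list")
  pick <- best_model(ml, selection_strategy("test_mcc"))
  expect_equal(pick$unique_id, "m2")
  # error criteria are minimised
  pick2 <- best_model(ml, selection_strategy("avg_ber"))
  expect_equal(pick2$unique_id, "m1")
})

test_that("ensembles are assembled manually or by a sorted, truncated rule", {
  cands <- list(make_fake_candidate("m1", 0.9, 0.02, features = c("g1", "g7")),
                make_fake_candidate("m2", 0.8, 0.02, features = c("g2", "g7")),
                make_fake_candidate("m3", 0.7, 0.02, features = "g3"),
                make_fake_candidate("m4", 0.65, 0.02, features = "g4"),
                make_fake_candidate("m5", 0.62, 0.02, features = "g5"))
  ml <- structure(list(candidates = cands), class = "sig_model_list")
  manual <- build_ensemble(ml, member_ids = c("m1", "m3"))
  expect_equal(vapply(manual$members, `[[`, character(1), "unique_id"),
               c("m1", "m3"))
  top3 <- build_ensemble(ml, rule_threshold = 0.6, max_models = 3)
  expect_equal(vapply(top3$members, `[[`, character(1), "unique_id"),
               c("m1", "m2", "m3"))
  both <- build_ensemble(ml, member_ids = c("m1", "m2"))
  expect_equal(unname(both$feature_occurrences[["g7"]]), 2)
  expect_error(build_ensemble(ml, rule_threshold = 0.99), "no model")
  expect_error(build_ensemble(ml, member_ids = "zz"), "unknown model id")
})

make_prob_member <- function(id, prob) {
  y <- rep(c("A", "B"), 5)
  ds <- sigselect:::new_merged_dataset(paste0("s", 1:10),
                                       data.frame(f = rnorm(10)), y,
                                       "classification", "class")
  spec <- constant_prob_spec(id, prob)
  model <- train_classifier(spec, ds, "f", seed = 1)
  cand <- make_fake_candidate(id, 0.8, 0.01, features = "f")
  cand$report$model <- model
  cand
}

test_that("combination rules follow their stated arithmetic", {
  m1 <- make_prob_member("m1", c(0.6, 0.4))
  m2 <- make_prob_member("m2", c(0.8, 0.2))
  newdata <- data.frame(f = c(0, 1))
  mk <- function(comb, members = list(m1, m2))
    predict(structure(list(members = members, combination = comb),
                      class = "sig_ensemble"), newdata)
  avg <- mk("average")
  expect_equal(unname(avg$prob[1, ]), c(0.7, 0.3))
  prod_ <- mk("product")
  expect_equal(unname(prod_$prob[1, ]), c(0.48, 0.08) / 0.56,
               tolerance = 1e-12)
  med <- mk("median")
  expect_equal(unname(med$prob[1, ]), c(0.7, 0.3))
  m3 <- make_prob_member("m3", c(0.1, 0.9))
  maj <- mk("majority", list(m1, m2, m3))
  expect_equal(unname(maj$prob[1, ]), c(1, 0))     # votes A, A, B
  expect_equal(maj$class[1], "A")
})

test_that("an ensemble of identical members degenerates to the single member", {
  ds <- make_separable_dataset(n = 30, n_noise = 2, seed = 8)
  model <- train_classifier(knn1_spec(), ds, "f1", seed = 1)
  cand <- make_fake_candidate("m1", 0.9, 0.01, features = "f1")
  cand$report$model <- model
  single <- predict(model, ds)
  for (comb in c("average", "product", "majority", "median")) {
    ens <- structure(list(members = list(cand, cand, cand),
                          combination = comb), class = "sig_ensemble")
    pred <- predict(ens, ds)
    expect_equal(pred$class, single$class, info = comb)
  }
})

test_that("correlated features are recovered by Pearson, Spearman and merit", {
  set.seed(51)
  n <- 50
  y <- rep(c("A", "B"), n / 2)
  g1 <- ifelse(y == "B", 2, 0) + rnorm(n)
  df <- data.frame(g1 = g1, g1_copy = g1, g1_anti = -g1,
                   noise = rnorm(n))
  ds <- sigselect:::new_merged_dataset(sprintf("s%02d", 1:n), df, y,
                                       "classification", "class")
  enr <- correlated_features("g1", ds)
  pear <- enr$recovered[enr$recovered$evidence == "pearson", ]
  expect_true("g1_copy" %in% pear$feature)
  expect_equal(pear$value[pear$feature == "g1_copy"], 1)
  expect_true("g1_anti" %in% pear$feature)
  expect_equal(pear$value[pear$feature == "g1_anti"], -1)
  expect_false("noise" %in% enr$recovered$feature)
  expect_false(any(enr$recovered$feature %in% enr$core))
})

test_that("Spearman recovery follows the rank-correlation threshold exactly", {
  df <- data.frame(x = c(1, 2, 3, 4, 5), y = c(1, 2, 3, 5, 4),
                   z = c(5, 1, 4, 2, 3))
  ds <- sigselect:::new_merged_dataset(paste0("s", 1:5), df,
                                       c("A", "B", "A", "B", "A"),
                                       "classification", "class")
  # rho(x, y) = 1 - 6*2/(5*24) = 0.9
  at_09 <- correlated_features("x", ds, r_min = 0.9)
  expect_true("y" %in%
                at_09$recovered$feature[at_09$recovered$evidence ==
                                          "spearman"])
  above <- correlated_features("x", ds, r_min = 0.95)
  expect_false("y" %in%
                 above$recovered$feature[above$recovered$evidence ==
                                           "spearman"])
})

test_that("nominal signature features fall back to rank-encoded Spearman", {
  df <- data.frame(grp = c("a", "a", "b", "b"), num = c(1, 1, 2, 2))
  ds <- sigselect:::new_merged_dataset(paste0("s", 1:4), df,
                                       c("A", "A", "B", "B"),
                                       "classification", "class")
  expect_warning(enr <- correlated_features("grp", ds), "nominal")
  expect_true("num" %in% enr$recovered$feature)
})

test_that("duplicates cut by the ranking cap are still recovered", {
  spec <- fixture_spec(n_samples = 60, n_features = 40, n_informative = 6,
                       n_duplicates = 4, effect_size = 2, seed = 6)
  fx <- generate_classification_data(spec)
  ds <- merge_datasets(fx$tables, "class")
  ranked <- rank_and_reduce(ds, cap = 3L)   # cap far below the duplicates
  dropped_dups <- setdiff(names(fx$truth$duplicates), ranked$order)
  expect_gt(length(dropped_dups), 0)
  sig <- intersect(unname(fx$truth$duplicates), colnames(ds$data))
  enr <- correlated_features(sig, ds, ranked)
  for (d in dropped_dups) {
    hits <- enr$recovered[enr$recovered$feature == d &
                            enr$recovered$evidence == "pearson", ]
    expect_true(any(abs(hits$value) == 1), info = d)
  }
})

test_that("the model registry round-trips and appends byte-identically", {
  ml <- structure(list(candidates = list(
    make_fake_candidate("m1", 0.9, 0.05),
    make_fake_candidate("m2", 0.7, 0.02))),
    class = "sig_model_list")
  path <- tempfile(fileext = ".csv")
  write_model_registry(ml, path)
  tab <- read_model_registry(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$unique_id, c("m1", "m2"))
  # sorting the CSV by avg_mcc reproduces the default selection
  expect_equal(tab$unique_id[which.max(tab$avg_mcc)],
               best_model(ml)$unique_id)

  before <- readLines(path)
  extra <- structure(list(candidates = list(
    make_fake_candidate("m3", 0.5, 0.01))), class = "sig_model_list")
  write_model_registry(extra, path, append = TRUE)
  after <- readLines(path)
  expect_identical(after[seq_along(before)], before)
  expect_equal(nrow(read_model_registry(path)), 3L)
})

test_that("signature subsets export and round-trip exactly", {
  set.seed(61)
  n <- 20
  ds <- sigselect:::new_merged_dataset(
    sprintf("s%02d", 1:n),
    data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n)),
    rep(c("A", "B"), n / 2), "classification", "class")
  path <- tempfile(fileext = ".csv")
  export_signature_subset(ds, c("a", "c", "d"), path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(dim(back), c(20L, 5L))     # id + 3 features + class
  expect_equal(back$a, ds$data$a)
  expect_equal(back$class, ds$y)
  expect_error(export_signature_subset(ds, character(0), path), "empty")
  expect_error(export_signature_subset(ds, "zz", path), "unknown")
})
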