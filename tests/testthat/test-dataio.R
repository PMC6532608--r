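test_that("separator detection picks the consistent candidate with fixed precedence", {
  expect_equal(detect_separator(c("id,f1,f2", "s1,0.2,0.3")), ",")
  expect_equal(detect_separator(c("id\tf1\tf2", "s1\t1\t2")), "\t")
  # comma is inconsistent (2 vs 1 columns); semicolon is consistent
  expect_equal(detect_separator(c("a;b;c,d", "1;2;3")), ";")
  expect_error(detect_separator(c("oneword", "another")), "unparseable")
  expect_error(detect_separator(c("a,b", "")), "2 non-empty lines")
})

write_tmp_table <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

test_that("load_table infers column kinds and normalises missing markers", {
  path <- write_tmp_table(c("id,g1,g2,grp",
                            "s1,1.5,x,high",
                            "s2,NA,y,low",
                            "s3,2,?,high"))
  t <- load_table(path)
  expect_s3_class(t, "raw_table")
  expect_equal(t$sample_ids, c("s1", "s2", "s3"))
  expect_equal(t$feature_names, c("g1", "g2", "grp"))
  expect_type(t$values$g1, "double")
  expect_equal(t$values$g1, c(1.5, NA, 2))
  expect_type(t$values$g2, "character")
  expect_true(is.na(t$values$g2[3]))   # "?" normalised
})

test_that("load_table rejects duplicate names and missing class columns", {
  dup_id <- write_tmp_table(c("id,g1", "s1,1", "s1,2"))
  expect_error(load_table(dup_id), "duplicate sample identifiers")
  dup_feat <- write_tmp_table(c("id,g1,g1", "s1,1,2"))
  expect_error(load_table(dup_feat), "duplicate feature names")
  ok <- write_tmp_table(c("id,g1", "s1,1", "s2,2"))
  expect_error(load_table(ok, class_name = "outcome"), "not found")
})

test_that("merge inner-joins on sample id and detaches the class column", {
  t1 <- raw_table_from_df(data.frame(id = c("a", "b", "c"), g1 = 1:3,
                                     g2 = 4:6, class = c("x", "y", "x")),
                          class_name = "class")
  # q = 1: identity join minus the class column
  m1 <- merge_datasets(list(t1), "class")
  expect_equal(m1$sample_ids, c("a", "b", "c"))
  expect_equal(colnames(m1$data), c("g1", "g2"))
  expect_equal(m1$y, c("x", "y", "x"))

  t2 <- raw_table_from_df(data.frame(id = c("b", "c", "d"), g3 = 7:9,
                                     g4 = 10:12, g5 = 13:15))
  m2 <- merge_datasets(list(t1, t2), "class")
  expect_equal(m2$sample_ids, c("b", "c"))         # 'a' and 'd' ignored
  expect_equal(ncol(m2$data), 5L)
  expect_equal(m2$data["c", "g3"], 8)

  # 3- and 4-column tables, one holding the class -> 6 merged features
  ta <- raw_table_from_df(data.frame(id = c("u", "v"), f1 = 1:2, f2 = 3:4,
                                     f3 = 5:6))
  tb <- raw_table_from_df(data.frame(id = c("u", "v"), f4 = 1:2, f5 = 3:4,
                                     f6 = 5:6, class = c("p", "q")),
                          class_name = "class")
  expect_equal(ncol(merge_datasets(list(ta, tb), "class")$data), 6L)
})

test_that("merge errors on ambiguous class column and empty joins", {
  t1 <- raw_table_from_df(data.frame(id = "a", class = "x"),
                          class_name = "class")
  t2 <- raw_table_from_df(data.frame(id = "a", class = "y"),
                          class_name = "class")
  expect_error(merge_datasets(list(t1, t2), "class"), "several tables")
  t3 <- raw_table_from_df(data.frame(id = "zz", g1 = 1))
  expect_error(merge_datasets(list(t1, t3), "class"), "empty join")
  expect_error(merge_datasets(list(t3), "class"), "absent from every")
})

test_that("feature exclusion drops listed columns, ignores unknown, guards class", {
  m <- merge_datasets(list(raw_table_from_df(
    data.frame(id = c("a", "b"), f1 = 1:2, f2 = 3:4, f3 = 5:6,
               class = c("x", "y")), class_name = "class")), "class")
  expect_identical(exclude_features(m, character(0)), m)
  expect_equal(colnames(exclude_features(m, "f2")$data), c("f1", "f3"))
  expect_warning(out <- exclude_features(m, "fX"), "unknown")
  expect_equal(colnames(out$data), c("f1", "f2", "f3"))
  expect_error(exclude_features(m, "class"), "class column")
})

test_that("imputation uses training means and lexicographic-min modes", {
  m <- merge_datasets(list(raw_table_from_df(
    data.frame(id = paste0("s", 1:4),
               num = c(1, 3, NA, 5),
               nom = c("a", "a", "b", NA),
               class = c("x", "y", "x", "y")), class_name = "class")),
    "class")
  out <- impute_missing(m)
  expect_equal(out$data$num[3], mean(c(1, 3, 5)))
  expect_equal(out$data$nom[4], "a")
  # mode tie (a and b both occur once) -> lexicographically smallest
  m2 <- m
  m2$data$nom <- c("b", "a", NA, NA)
  out2 <- impute_missing(m2)
  expect_equal(out2$data$nom[3], "a")
  # no missing -> identity
  clean <- impute_missing(out)
  expect_identical(clean$data, out$data)
})

test_that("imputation never leaks from the set being filled", {
  train <- merge_datasets(list(raw_table_from_df(
    data.frame(id = paste0("s", 1:4), g = c(2, 4, 6, NA),
               class = rep(c("x", "y"), 2)), class_name = "class")),
    "class")
  test1 <- train; test1$data$g <- c(NA, 100, 100, 100)
  test2 <- train; test2$data$g <- c(NA, -5, 0, 7)
  f1 <- impute_missing(train, test1)$data$g[1]
  f2 <- impute_missing(train, test2)$data$g[1]
  expect_equal(f1, mean(c(2, 4, 6)))
  expect_equal(f1, f2)   # fill depends only on train
})

test_that("a column entirely missing in train is dropped with a warning", {
  m <- merge_datasets(list(raw_table_from_df(
    data.frame(id = c("a", "b"), g1 = c(NA_real_, NA_real_), g2 = c(1, 2),
               class = c("x", "y")), class_name = "class")), "class")
  expect_warning(out <- impute_missing(m), "entirely missing")
  expect_equal(colnames(out$data), "g2")
})

test_that("stratified split preserves class balance within one sample", {
  y <- rep(c("A", "B"), c(40, 20))
  m <- sigselect:::new_merged_dataset(
    sprintf("s%02d", 1:60),
    data.frame(f = stats::rnorm(60)), y, "classification", "class")
  sp <- stratified_split(m, 2 / 3, seed = 5)
  expect_equal(n_samples(sp$train) + n_samples(sp$test), 60L)
  trainA <- sum(sp$train$y == "A")
  expect_true(abs(trainA - 2 / 3 * 40) <= 1)
  expect_true(abs(sum(sp$train$y == "B") - 2 / 3 * 20) <= 1)
  expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0)

  # disabled sampling
  sp1 <- stratified_split(m, 1, seed = 5)
  expect_equal(n_samples(sp1$test), 0L)

  # determinism
  sp_again <- stratified_split(m, 2 / 3, seed = 5)
  expect_identical(sp$train$sample_ids, sp_again$train$sample_ids)
})

test_that("class proportions stay stratified across a seed sweep", {
  y <- rep(c("A", "B"), c(40, 20))
  m <- sigselect:::new_merged_dataset(
    sprintf("s%02d", 1:60),
    data.frame(f = stats::rnorm(60)), y, "classification", "class")
  overall <- mean(y == "A")
  for (seed in 1:100) {
    sp <- stratified_split(m, 2 / 3, seed = seed)
    expect_true(abs(mean(sp$train$y == "A") - overall) <=
                  1 / sum(sp$train$y == "A") + 1e-9)
  }
})

test_that("split parts re-merge to the original sample set", {
  y <- rep(c("A", "B"), c(12, 8))
  m <- sigselect:::new_merged_dataset(
    sprintf("s%02d", 1:20), data.frame(f = stats::rnorm(20)), y,
    "classification", "class")
  sp <- stratified_split(m, 0.6, seed = 2)
  expect_setequal(c(sp$train$sample_ids, sp$test$sample_ids), m$sample_ids)
})

test_that("regression splits stratify on outcome quartiles", {
  set.seed(7)
  m <- sigselect:::new_merged_dataset(
    sprintf("s%03d", 1:100), data.frame(f = rnorm(100)),
    sort(rnorm(100)), "regression", "out")
  sp <- stratified_split(m, 2 / 3, seed = 3)
  # each quartile should contribute ~2/3 of its members to train
  qs <- stats::quantile(m$y, c(0.25, 0.5, 0.75))
  bins <- findInterval(m$y, qs)
  for (b in unique(bins)) {
    in_train <- sum(m$sample_ids[bins == b] %in% sp$train$sample_ids)
    expect_true(abs(in_train - 2 / 3 * sum(bins == b)) <= 1)
  }
})

test_that("datasets round-trip through write_dataset/load_table", {
  m <- merge_datasets(list(raw_table_from_df(
    data.frame(id = c("a", "b"), g1 = c(1.25, -2), grp = c("u", "v"),
               class = c("x", "y")), class_name = "class")), "class")
  path <- tempfile(fileext = ".csv")
  write_dataset(m, path)
  back <- merge_datasets(list(load_table(path, class_name = "class")),
                         "class")
  expect_equal(back$data$g1, m$data$g1)
  expect_equal(back$y, m$y)
})
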