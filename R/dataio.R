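# Missing-value markers accepted in input tables. "?" is the Weka-style
# marker, "NA"/"NaN" the usual omics-export ones; an empty cell always counts.
DEFAULT_MISSING_MARKERS <- c("", "NA", "NaN", "?")

#' Detect the field separator of a delimited table
#'
#' Inspects the first lines of a file and returns the candidate separator
#' (tab, comma or semicolon) that yields an identical column count greater
#' than one on every sampled line. Ties are broken by the fixed precedence
#' tab > comma > semicolon.
#'
#' @param first_lines Character vector of at least two non-empty lines.
#' @return A single character: `"\t"`, `","` or `";"`.
#' @export
detect_separator <- function(first_lines) {
  lines <- first_lines[nzchar(first_lines)]
  if (length(lines) < 2L)
    stop("separator detection needs at least 2 non-empty lines", call. = FALSE)
  for (sep in c("\t", ",", ";")) {
    counts <- vapply(strsplit(lines, sep, fixed = TRUE), length, integer(1))
    if (counts[1L] > 1L && all(counts == counts[1L]))
      return(sep)
  }
  stop("unparseable table: no candidate separator yields a consistent ",
       "column count > 1", call. = FALSE)
}

#' Load a delimited sample-by-feature table
#'
#' Reads a header-first delimited file with sample identifiers in the first
#' column. The separator is auto-detected unless given. Column kinds are
#' inferred: a column is numeric iff every non-missing cell parses as a
#' number, otherwise nominal. All missing markers are normalised to `NA`.
#'
#' @param path Path to the file.
#' @param class_name Optional name of the class/outcome column expected in
#'   this table.
#' @param sep Separator character; `NULL` (default) auto-detects.
#' @param missing_markers Cell values treated as missing.
#' @return A `raw_table` object: list with `source_path`, `separator`,
#'   `sample_ids`, `feature_names`, `values` (data.frame, character/numeric
#'   columns), `class_name`.
#' @export
load_table <- function(path, class_name = NULL, sep = NULL,
                       missing_markers = DEFAULT_MISSING_MARKERS) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("table must have a header and at least one row: ", path,
         call. = FALSE)
  if (is.null(sep)) sep <- detect_separator(utils::head(lines, 10L))

  cells <- strsplit(lines, sep, fixed = TRUE)
  ncol0 <- length(cells[[1L]])
  # trailing empty fields are dropped by strsplit; pad back
  cells <- lapply(cells, function(x) c(x, rep("", max(0L, ncol0 - length(x)))))
  bad <- which(vapply(cells, length, integer(1)) != ncol0)
  if (length(bad))
    stop("row ", bad[1L], " has a different number of fields than the header",
         call. = FALSE)
  header <- trimws(cells[[1L]])
  body <- do.call(rbind, cells[-1L])
  body <- trimws(body)

  sample_ids <- body[, 1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  feature_names <- header[-1L]
  if (anyDuplicated(feature_names))
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]),
               collapse = ", "), call. = FALSE)
  if (!is.null(class_name) && !(class_name %in% feature_names))
    stop("class column '", class_name, "' not found in ", path, call. = FALSE)

  values <- as.data.frame(body[, -1L, drop = FALSE],
                          stringsAsFactors = FALSE)
  names(values) <- feature_names
  rownames(values) <- sample_ids
  for (j in seq_along(values)) {
    col <- values[[j]]
    col[col %in% missing_markers] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    if (!any(is.na(num) & !is.na(col))) {
      values[[j]] <- num            # numeric column (all non-missing parse)
    } else {
      values[[j]] <- col            # nominal column
    }
  }

  structure(list(source_path = path, separator = sep,
                 sample_ids = sample_ids, feature_names = feature_names,
                 values = values, class_name = class_name),
            class = "raw_table")
}

#' Construct a raw table directly from a data frame
#'
#' Convenience constructor used by the synthetic generator and tests; applies
#' the same validation as [load_table()].
#'
#' @param df Data frame whose first column holds sample identifiers.
#' @param class_name Optional class column name.
#' @return A `raw_table`.
#' @export
raw_table_from_df <- function(df, class_name = NULL) {
  sample_ids <- as.character(df[[1L]])
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers",
                                      call. = FALSE)
  values <- df[, -1L, drop = FALSE]
  if (anyDuplicated(names(values))) stop("duplicate feature names",
                                         call. = FALSE)
  if (!is.null(class_name) && !(class_name %in% names(values)))
    stop("class column '", class_name, "' not found", call. = FALSE)
  values[] <- lapply(values, function(x) if (is.factor(x)) as.character(x)
                     else x)
  rownames(values) <- sample_ids
  structure(list(source_path = NA_character_, separator = ",",
                 sample_ids = sample_ids, feature_names = names(values),
                 values = values, class_name = class_name),
            class = "raw_table")
}

#' Merge several raw tables into one dataset
#'
#' Inner-joins tables on the sample identifier: identifiers absent from any
#' table are dropped. Exactly one table must contain the class column, which
#' is detached into the class vector. Feature order is table order, then
#' within-table column order. Sample order follows the first table.
#'
#' @param tables List of `raw_table` objects.
#' @param class_name Name of the class/outcome column.
#' @param problem_type `"classification"`, `"regression"` or `"auto"`
#'   (numeric class column implies regression).
#' @return A `merged_dataset`: list with `sample_ids`, `data` (data.frame of
#'   features; numeric or character columns), `y`, `problem_type`,
#'   `class_name`.
#' @export
merge_datasets <- function(tables, class_name,
                           problem_type = c("auto", "classification",
                                            "regression")) {
  problem_type <- match.arg(problem_type)
  if (!length(tables)) stop("need at least one table", call. = FALSE)
  if (inherits(tables, "raw_table")) tables <- list(tables)
  has_class <- vapply(tables, function(t) class_name %in% t$feature_names,
                      logical(1))
  if (sum(has_class) == 0L)
    stop("class column '", class_name, "' absent from every table",
         call. = FALSE)
  if (sum(has_class) > 1L)
    stop("class column '", class_name, "' found in several tables",
         call. = FALSE)

  ids <- Reduce(intersect, lapply(tables, `[[`, "sample_ids"))
  ids <- tables[[1L]]$sample_ids[tables[[1L]]$sample_ids %in% ids]
  if (!length(ids)) stop("empty join: no sample identifier is shared by all ",
                         "tables", call. = FALSE)

  parts <- lapply(tables, function(t) t$values[ids, , drop = FALSE])
  all_feat <- unlist(lapply(parts, names))
  if (anyDuplicated(all_feat))
    stop("feature names duplicated across tables: ",
         paste(unique(all_feat[duplicated(all_feat)]), collapse = ", "),
         call. = FALSE)
  data <- do.call(cbind, parts)
  rownames(data) <- ids

  y <- data[[class_name]]
  data[[class_name]] <- NULL
  if (problem_type == "auto")
    problem_type <- if (is.numeric(y)) "regression" else "classification"
  if (problem_type == "classification") y <- as.character(y)
  if (problem_type == "regression" && !is.numeric(y))
    stop("regression requested but class column is not numeric",
         call. = FALSE)
  if (anyNA(y)) stop("class column contains missing values", call. = FALSE)

  new_merged_dataset(ids, data, y, problem_type, class_name)
}

new_merged_dataset <- function(ids, data, y, problem_type, class_name) {
  structure(list(sample_ids = ids, data = data, y = y,
                 problem_type = problem_type, class_name = class_name),
            class = "merged_dataset")
}

#' @export
print.merged_dataset <- function(x, ...) {
  cat(sprintf("merged_dataset: %d samples x %d features (%s, class '%s')\n",
              length(x$sample_ids), ncol(x$data), x$problem_type,
              x$class_name))
  invisible(x)
}

#' Number of samples in a merged dataset
#' @param dataset A `merged_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(dataset) length(dataset$sample_ids)

#' Drop user-excluded feature columns
#'
#' Removes the listed feature columns from the dataset. Unknown names are
#' ignored with a warning; the class column cannot be excluded.
#'
#' @param dataset A `merged_dataset`.
#' @param names Character vector of feature names to drop.
#' @return The reduced `merged_dataset`.
#' @export
exclude_features <- function(dataset, names) {
  if (!length(names)) return(dataset)
  if (dataset$class_name %in% names)
    stop("cannot exclude the class column '", dataset$class_name, "'",
         call. = FALSE)
  unknown <- setdiff(names, colnames(dataset$data))
  if (length(unknown))
    warning("ignoring unknown feature(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  keep <- setdiff(colnames(dataset$data), names)
  dataset$data <- dataset$data[, keep, drop = FALSE]
  dataset
}

#' Impute missing values with training-set means and modes
#'
#' Numeric columns are filled with the training-set column mean, nominal
#' columns with the training-set mode (ties broken by the lexicographically
#' smallest mode). Statistics are always computed on `train` only, so no
#' information can leak from a test set passed as `apply_to`. A column that
#' is entirely missing in `train` is dropped from the result with a warning.
#'
#' @param train `merged_dataset` providing the fill statistics.
#' @param apply_to `merged_dataset` to fill; defaults to `train`.
#' @return `apply_to` with no missing cells.
#' @export
impute_missing <- function(train, apply_to = train) {
  drop <- character(0)
  for (nm in colnames(train$data)) {
    tcol <- train$data[[nm]]
    if (all(is.na(tcol))) { drop <- c(drop, nm); next }
    if (!nm %in% colnames(apply_to$data)) next
    acol <- apply_to$data[[nm]]
    if (!anyNA(acol)) next
    fill <- if (is.numeric(tcol)) {
      mean(tcol, na.rm = TRUE)
    } else {
      tab <- table(tcol[!is.na(tcol)])
      modes <- names(tab)[tab == max(tab)]
      sort(modes)[1L]
    }
    acol[is.na(acol)] <- fill
    apply_to$data[[nm]] <- acol
  }
  if (length(drop)) {
    warning("dropping column(s) entirely missing in train: ",
            paste(drop, collapse = ", "), call. = FALSE)
    keep <- setdiff(colnames(apply_to$data), drop)
    apply_to$data <- apply_to$data[, keep, drop = FALSE]
  }
  apply_to
}

subset_samples <- function(dataset, idx) {
  new_merged_dataset(dataset$sample_ids[idx],
                     dataset$data[idx, , drop = FALSE],
                     dataset$y[idx], dataset$problem_type,
                     dataset$class_name)
}

#' Stratified train/test split
#'
#' Classification: samples are allocated per class, taking
#' `round(train_fraction * n_class)` shuffled samples of each class for
#' training, so class balance is preserved to within one sample. Regression:
#' stratification uses outcome quartile bins, keeping the outcome
#' distribution balanced across the parts. `train_fraction = 1` disables
#' sampling and leaves the test set empty. Deterministic for a fixed seed.
#'
#' @param dataset A `merged_dataset`.
#' @param train_fraction Fraction of samples assigned to training
#'   (default 2/3).
#' @param seed Integer seed.
#' @return A `split_dataset`: list with `train`, `test` (possibly 0-row),
#'   `train_fraction`, `seed`.
#' @export
stratified_split <- function(dataset, train_fraction = 2 / 3, seed = 1L) {
  if (train_fraction <= 0 || train_fraction > 1)
    stop("train_fraction must be in (0, 1]", call. = FALSE)
  n <- n_samples(dataset)
  if (train_fraction == 1) {
    return(structure(list(train = dataset,
                          test = subset_samples(dataset, integer(0)),
                          train_fraction = 1, seed = seed),
                     class = "split_dataset"))
  }
  strata <- if (dataset$problem_type == "classification") {
    dataset$y
  } else {
    qs <- stats::quantile(dataset$y, probs = c(0.25, 0.5, 0.75), type = 7)
    as.character(findInterval(dataset$y, unique(qs)))
  }
  rng <- local_rng(seed)
  train_idx <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 2L) {
      warning("stratum '", s, "' has fewer than 2 samples; all assigned to ",
              "train", call. = FALSE)
      train_idx <- c(train_idx, idx)
      next
    }
    k <- round(train_fraction * length(idx))
    k <- max(1L, min(length(idx) - 1L, k))
    train_idx <- c(train_idx, rng$sample(idx, k))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  structure(list(train = subset_samples(dataset, train_idx),
                 test = subset_samples(dataset, test_idx),
                 train_fraction = train_fraction, seed = seed),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("split_dataset: %d train / %d test (fraction %.3f, seed %d)\n",
              n_samples(x$train), n_samples(x$test), x$train_fraction,
              x$seed))
  invisible(x)
}

# Isolated RNG helper: evaluates sampling with a private seed without
# touching the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(as.integer(seed %% 2147483647))
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  })
  env$with <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr_fun()
  }
  env$sample <- function(x, size) env$with(function()
    x[sample.int(length(x), size)])
  env$resample <- function(n, size) env$with(function()
    sample.int(n, size, replace = TRUE))
  env
}

#' Export a dataset to a delimited file
#'
#' Writes a `merged_dataset` back to the delimited-table dialect the package
#' reads: id column first, then features, then the class column.
#'
#' @param dataset A `merged_dataset`.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, sep = ",") {
  df <- data.frame(id = dataset$sample_ids, dataset$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[[dataset$class_name]] <- dataset$y
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
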