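# Synthetic omics-like tables with planted ground truth. The generator
# emulates the p >> n, class-unbalanced tables the pipeline targets:
# informative features are class-conditional Gaussians separated by a
# chosen effect size (in pooled-SD units), noise features are standard
# Gaussians, duplicates are exact copies of informative features, and
# missing cells can be injected. Tables can be split column-wise into
# several sources sharing sample identifiers to exercise the join.

#' Specification of a synthetic fixture
#'
#' @param n_samples Number of samples (default 150).
#' @param n_features Total number of features (default 1000).
#' @param n_informative Planted informative features (default 10).
#' @param n_duplicates Exact copies of informative features (default 0).
#' @param effect_size Class-mean shift in pooled-SD units, or the
#'   regression coefficient scale (default 1.5).
#' @param class_proportions Class mixing proportions (default `c(0.6,
#'   0.4)`; must sum to 1).
#' @param missing_rate Fraction of feature cells set missing (default 0).
#' @param n_sources Number of column-wise source tables (default 1).
#' @param snr Signal-to-noise variance ratio for regression outcomes
#'   (default 3).
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_samples = 150L, n_features = 1000L,
                         n_informative = 10L, n_duplicates = 0L,
                         effect_size = 1.5, class_proportions = c(0.6, 0.4),
                         missing_rate = 0, n_sources = 1L, snr = 3,
                         seed = 1L) {
  if (n_informative + n_duplicates > n_features)
    stop("n_informative + n_duplicates must not exceed n_features",
         call. = FALSE)
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 n_duplicates = as.integer(n_duplicates),
                 effect_size = effect_size,
                 class_proportions = class_proportions,
                 missing_rate = missing_rate,
                 n_sources = as.integer(n_sources), snr = snr,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

feature_names_for <- function(p) sprintf("feat%04d", seq_len(p))

assemble_fixture <- function(spec, x, y, informative_idx, dup_map,
                             class_name) {
  n <- spec$n_samples
  rng <- local_rng(spec$seed + 13L)
  if (spec$missing_rate > 0) {
    n_cells <- length(x)
    miss <- rng$sample(seq_len(n_cells),
                       max(0L, round(spec$missing_rate * n_cells)))
    x[miss] <- NA
  }
  df <- as.data.frame(x)
  ids <- sprintf("s%03d", seq_len(n))
  truth <- list(informative = colnames(x)[informative_idx],
                duplicates = dup_map, class_name = class_name)
  # split column-wise into n_sources tables; class goes in table 1
  src <- rep_len(seq_len(spec$n_sources), ncol(df))
  tables <- lapply(seq_len(spec$n_sources), function(s) {
    part <- df[, src == s, drop = FALSE]
    out <- data.frame(id = ids, part, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (s == 1L) out[[class_name]] <- y
    raw_table_from_df(out, class_name = if (s == 1L) class_name else NULL)
  })
  list(tables = tables, truth = truth)
}

#' Generate a synthetic classification fixture
#'
#' Informative features are drawn class-conditionally with means spaced
#' `effect_size` pooled SDs apart; noise features are standard normal;
#' duplicates are exact copies of randomly chosen informative features.
#' Fully seeded: the same spec yields byte-identical tables.
#'
#' @param spec A [fixture_spec()].
#' @param class_name Name of the class column (default `"class"`).
#' @return List with `tables` (list of `raw_table`s) and `truth`
#'   (`informative`, `duplicates` named map copy -> source, `class_name`).
#' @export
generate_classification_data <- function(spec, class_name = "class") {
  n <- spec$n_samples; p <- spec$n_features
  k <- length(spec$class_proportions)
  counts <- round(spec$class_proportions * n)
  counts[k] <- n - sum(counts[-k])
  y <- rep(LETTERS[seq_len(k)], counts)
  rng <- local_rng(spec$seed)
  x <- matrix(rng$with(function() stats::rnorm(n * p)), n, p)
  colnames(x) <- feature_names_for(p)
  informative_idx <- rng$sample(seq_len(p),
                                spec$n_informative + spec$n_duplicates)
  dup_idx <- utils::tail(informative_idx,
                         spec$n_duplicates)
  informative_idx <- utils::head(informative_idx, spec$n_informative)
  shifts <- spec$effect_size * (match(y, LETTERS) - 1L)
  for (j in informative_idx) x[, j] <- x[, j] + shifts
  dup_map <- character(0)
  if (spec$n_duplicates > 0L) {
    src <- rep_len(informative_idx, spec$n_duplicates)
    for (i in seq_along(dup_idx)) x[, dup_idx[i]] <- x[, src[i]]
    dup_map <- stats::setNames(colnames(x)[src], colnames(x)[dup_idx])
  }
  assemble_fixture(spec, x, y, informative_idx, dup_map, class_name)
}

#' Generate a synthetic regression fixture
#'
#' The outcome is a linear combination of the informative features (all
#' coefficients equal to `effect_size`) plus Gaussian noise scaled so the
#' signal-to-noise variance ratio equals `snr`.
#'
#' @inheritParams generate_classification_data
#' @return As [generate_classification_data()], with a numeric outcome.
#' @export
generate_regression_data <- function(spec, class_name = "outcome") {
  n <- spec$n_samples; p <- spec$n_features
  rng <- local_rng(spec$seed)
  x <- matrix(rng$with(function() stats::rnorm(n * p)), n, p)
  colnames(x) <- feature_names_for(p)
  informative_idx <- rng$sample(seq_len(p),
                                spec$n_informative + spec$n_duplicates)
  dup_idx <- utils::tail(informative_idx, spec$n_duplicates)
  informative_idx <- utils::head(informative_idx, spec$n_informative)
  signal <- if (length(informative_idx))
    rowSums(x[, informative_idx, drop = FALSE]) * spec$effect_size
  else rep(0, n)
  noise_sd <- if (stats::sd(signal) > 0) stats::sd(signal) / sqrt(spec$snr)
              else 1
  y <- signal + rng$with(function() stats::rnorm(n, sd = noise_sd))
  dup_map <- character(0)
  if (spec$n_duplicates > 0L) {
    src <- rep_len(informative_idx, spec$n_duplicates)
    for (i in seq_along(dup_idx)) x[, dup_idx[i]] <- x[, src[i]]
    dup_map <- stats::setNames(colnames(x)[src], colnames(x)[dup_idx])
  }
  assemble_fixture(spec, x, y, informative_idx, dup_map, class_name)
}

#' Generate the interaction-pair (XOR) fixture
#'
#' Builds a small classification table where two features separate the
#' classes only jointly: within each latent cluster `z` in {0, 1}, class A
#' keeps `f3 ~ z` while class B flips it (`f3 ~ 1 - z`), so neither `f2`
#' (the cluster coordinate) nor `f3` carries much marginal signal, but the
#' pair is (almost) perfectly separating for a nearest-neighbour
#' classifier. `f1` is a weakly shifted noisy feature that helps alone but
#' degrades the joint pair. This is the designed stress case for the
#' backward-elimination step: forward selection keeps `f1`, elimination
#' removes it once `f2` and `f3` are in. Extra pure-noise features can be
#' appended.
#'
#' @param n Number of samples (even; default 60).
#' @param n_noise Extra pure-noise features (default 0).
#' @param seed Integer seed.
#' @param class_name Class column name.
#' @return List with `dataset` (a `merged_dataset`), `order` (the intended
#'   ranked feature order, `f1` first) and `truth`.
#' @export
generate_xor_fixture <- function(n = 60L, n_noise = 0L, seed = 1L,
                                 class_name = "class") {
  rng <- local_rng(seed)
  y <- rep(c("A", "B"), length.out = n)
  z <- rng$with(function() stats::rbinom(n, 1L, 0.5))
  f1 <- rng$with(function() stats::rnorm(n, mean = ifelse(y == "B", 0.7, 0),
                                         sd = 1.3))
  f2 <- z + 0.08 * (y == "B") +
    rng$with(function() stats::rnorm(n, sd = 0.08))
  f3 <- ifelse(y == "A", z, 1 - z) +
    rng$with(function() stats::rnorm(n, sd = 0.08))
  df <- data.frame(f1 = f1, f2 = f2, f3 = f3)
  if (n_noise > 0L) {
    noise <- matrix(rng$with(function() stats::rnorm(n * n_noise)), n)
    colnames(noise) <- sprintf("noise%02d", seq_len(n_noise))
    df <- cbind(df, as.data.frame(noise))
  }
  ds <- new_merged_dataset(sprintf("s%03d", seq_len(n)), df, y,
                           "classification", class_name)
  list(dataset = ds, order = c("f1", "f2", "f3",
                               setdiff(colnames(df), c("f1", "f2", "f3"))),
       truth = list(joint_pair = c("f2", "f3"), weak = "f1"))
}

#' Write a fixture's tables and truth record to disk
#'
#' Emits the same delimited format the loader reads plus a small
#' machine-readable truth file (`truth.txt`, key=value lines with
#' comma-joined names).
#'
#' @param fixture Result of a generator call.
#' @param dir Output directory (created if needed).
#' @param sep Field separator.
#' @return Character vector of the table paths, invisibly.
#' @export
write_fixture <- function(fixture, dir, sep = ",") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(fixture$tables), function(i) {
    path <- file.path(dir, sprintf("table%d.csv", i))
    t <- fixture$tables[[i]]
    df <- data.frame(id = t$sample_ids, t$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE, na = "NA")
    path
  }, character(1))
  truth_lines <- c(
    paste0("class_name=", fixture$truth$class_name),
    paste0("informative=", paste(fixture$truth$informative,
                                 collapse = ",")),
    paste0("duplicates=",
           paste(names(fixture$truth$duplicates),
                 fixture$truth$duplicates, sep = ":", collapse = ",")))
  writeLines(truth_lines, file.path(dir, "truth.txt"))
  invisible(paths)
}
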