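# Univariate feature ranking: Information Gain (classification) and ReliefF
# (RReliefF for regression). Numeric features entering Information Gain are
# first discretised by supervised entropy-minimisation with the MDL stopping
# rule (Fayyad & Irani); a feature whose discretisation collapses to a
# single interval carries no information about the class and scores 0.

entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0 || length(counts) < 2L) return(0)
  p <- counts / n
  -sum(p * log2(p))
}

# Entropy of each row of a class-count matrix (candidates x classes).
row_entropy <- function(m) {
  n <- rowSums(m)
  p <- m / ifelse(n == 0, 1, n)
  lp <- ifelse(p > 0, log2(p), 0)
  -rowSums(p * lp)
}

#' Supervised entropy-minimisation cut points (MDL-stopped)
#'
#' Recursively splits a numeric feature at the boundary minimising the
#' class-entropy of the partition, accepting a split only when its
#' information gain passes the minimum-description-length criterion.
#'
#' @param x Numeric feature vector.
#' @param y Class label vector.
#' @return Numeric vector of cut points (possibly empty).
#' @export
mdl_cuts <- function(x, y) {
  ok <- !is.na(x)
  x <- x[ok]; y <- as.character(y)[ok]
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  classes <- unique(y)
  ymat <- outer(y, classes, `==`) * 1L
  cuts <- numeric(0)

  split_segment <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L) return()
    xs <- x[lo:hi]
    cum <- apply(ymat[lo:hi, , drop = FALSE], 2, cumsum)
    cum <- matrix(cum, nrow = n)
    total <- cum[n, ]
    # candidate boundaries: between adjacent distinct values
    cand <- which(diff(xs) > 0)
    if (!length(cand)) return()
    left <- cum[cand, , drop = FALSE]
    right <- matrix(total, nrow = length(cand), ncol = length(total),
                    byrow = TRUE) - left
    nl <- rowSums(left); nr <- rowSums(right)
    e_parent <- entropy_bits(total)
    e_split <- (nl * row_entropy(left) + nr * row_entropy(right)) / n
    best <- which.min(e_split)
    gain <- e_parent - e_split[best]
    k <- sum(total > 0)
    k1 <- sum(left[best, ] > 0); k2 <- sum(right[best, ] > 0)
    delta <- log2(3^k - 2) -
      (k * e_parent - k1 * entropy_bits(left[best, ]) -
         k2 * entropy_bits(right[best, ]))
    if (gain <= (log2(n - 1) + delta) / n) return()
    cut_at <- cand[best]
    cuts <<- c(cuts, (xs[cut_at] + xs[cut_at + 1L]) / 2)
    split_segment(lo, lo + cut_at - 1L)
    split_segment(lo + cut_at, hi)
  }
  split_segment(1L, length(x))
  sort(cuts)
}

#' Information gain of a feature with respect to a class
#'
#' Returns \eqn{H(Y) - H(Y|A)} in bits. Nominal features are used as-is;
#' numeric features are first discretised with [mdl_cuts()]. Fewer than two
#' classes, or a numeric feature reduced to a single interval, yield 0.
#'
#' @param feature Numeric or character/factor feature vector.
#' @param classes Class label vector.
#' @return Information gain in bits (>= 0).
#' @export
information_gain <- function(feature, classes) {
  y <- as.character(classes)
  if (length(unique(y)) < 2L) return(0)
  a <- if (is.numeric(feature)) {
    cuts <- mdl_cuts(feature, y)
    if (!length(cuts)) return(0)
    findInterval(feature, cuts)
  } else {
    as.character(feature)
  }
  tab <- table(a, y)
  n <- sum(tab)
  h_y <- entropy_bits(colSums(tab))
  h_y_given_a <- sum(rowSums(tab) / n * row_entropy(unclass(tab)))
  max(0, h_y - h_y_given_a)
}

# 0-1 normalised feature representation used by ReliefF distances: numeric
# columns scaled by their range, nominal columns expanded so that
# diff(a, b) = 1{a != b} contributes through 0/1 level indicators scaled
# by 1/2 (two indicator columns differ when levels differ).
relief_matrix <- function(data) {
  cols <- lapply(data, function(col) {
    if (is.numeric(col)) {
      rng <- range(col)
      d <- rng[2] - rng[1]
      matrix(if (d == 0) rep(0, length(col)) else (col - rng[1]) / d,
             ncol = 1)
    } else {
      lev <- sort(unique(as.character(col)))
      m <- outer(as.character(col), lev, `==`) * 0.5
      m
    }
  })
  groups <- rep(seq_along(cols), vapply(cols, ncol, integer(1)))
  list(x = do.call(cbind, cols), groups = groups)
}

#' ReliefF / RReliefF feature weights
#'
#' Estimates each feature's relevance by repeatedly sampling an instance and
#' contrasting feature-value differences to its nearest neighbours. For
#' classification, nearest hits (same class) decrease and nearest misses
#' (other classes, prior-weighted) increase a feature's weight. For a
#' numeric outcome the regression variant (RReliefF) is used: weights are
#' positive when feature differences track outcome differences among
#' nearest neighbours. Weights lie in \[-1, 1\]; a constant feature scores
#' 0. Deterministic for a fixed seed.
#'
#' @param dataset A `merged_dataset` (imputed).
#' @param k_neighbors Number of nearest neighbours (default 10; reduced with
#'   a warning when the sample is too small).
#' @param sample_iterations Number of sampled instances (default
#'   `min(n, 250)`).
#' @param seed Integer seed.
#' @return Named numeric vector of signed weights, one per feature.
#' @export
relieff <- function(dataset, k_neighbors = 10L, sample_iterations = NULL,
                    seed = 1L) {
  n <- n_samples(dataset)
  if (is.null(sample_iterations)) sample_iterations <- min(n, 250L)
  if (n < k_neighbors + 1L) {
    warning("k_neighbors reduced to ", n - 1L, " (only ", n, " instances)",
            call. = FALSE)
    k_neighbors <- n - 1L
  }
  rep_ <- relief_matrix(dataset$data)
  x <- rep_$x
  p <- ncol(dataset$data)
  rng <- local_rng(seed)
  picks <- rng$sample(seq_len(n), n)[seq_len(sample_iterations)]

  if (dataset$problem_type == "regression") {
    yr <- range(dataset$y)
    dy <- if (diff(yr) == 0) rep(0, n) else (dataset$y - yr[1]) / diff(yr)
    n_dc <- 0
    n_da <- n_dcda <- numeric(ncol(x))
    m_total <- 0
    for (r in picks) {
      d <- rowSums(abs(x - matrix(x[r, ], n, ncol(x), byrow = TRUE)))
      ord <- order(d, seq_len(n))
      nb <- setdiff(ord, r)[seq_len(k_neighbors)]
      w <- 1 / k_neighbors
      ddy <- abs(dy[nb] - dy[r])
      dda <- abs(x[nb, , drop = FALSE] -
                   matrix(x[r, ], length(nb), ncol(x), byrow = TRUE))
      n_dc <- n_dc + sum(ddy) * w
      n_da <- n_da + colSums(dda) * w
      n_dcda <- n_dcda + colSums(dda * ddy) * w
      m_total <- m_total + 1
    }
    wvec <- if (n_dc == 0 || m_total - n_dc == 0) rep(0, ncol(x)) else
      n_dcda / n_dc - (n_da - n_dcda) / (m_total - n_dc)
  } else {
    y <- as.character(dataset$y)
    priors <- table(y) / n
    wvec <- numeric(ncol(x))
    m <- sample_iterations
    for (r in picks) {
      d <- rowSums(abs(x - matrix(x[r, ], n, ncol(x), byrow = TRUE)))
      ord <- order(d, seq_len(n))
      ord <- setdiff(ord, r)
      same <- y[ord] == y[r]
      hits <- ord[same][seq_len(min(k_neighbors, sum(same)))]
      if (length(hits)) {
        dh <- abs(x[hits, , drop = FALSE] -
                    matrix(x[r, ], length(hits), ncol(x), byrow = TRUE))
        wvec <- wvec - colMeans(dh) / m
      }
      for (cl in setdiff(names(priors), y[r])) {
        is_cl <- y[ord] == cl
        miss <- ord[is_cl][seq_len(min(k_neighbors, sum(is_cl)))]
        if (!length(miss)) next
        dm <- abs(x[miss, , drop = FALSE] -
                    matrix(x[r, ], length(miss), ncol(x), byrow = TRUE))
        coef <- priors[[cl]] / (1 - priors[[y[r]]])
        wvec <- wvec + coef * colMeans(dm) / m
      }
    }
  }
  # collapse indicator-expanded nominal columns back to one weight each
  out <- vapply(seq_len(p), function(g) sum(wvec[rep_$groups == g]),
                numeric(1))
  out <- pmin(1, pmax(-1, out))
  stats::setNames(out, colnames(dataset$data))
}

#' Rank features and reduce the dataset to the best ones
#'
#' Scores every feature (Information Gain for classification, ReliefF for
#' regression), drops those with absolute merit at or below `threshold`,
#' sorts the rest by absolute merit (descending; ties keep column order) and
#' truncates to the `cap` best.
#'
#' @param dataset An imputed `merged_dataset`.
#' @param threshold Minimum absolute merit (default 0.01).
#' @param cap Maximum number of retained features (default 1000).
#' @param seed Seed for ReliefF sampling.
#' @param k_neighbors,sample_iterations Passed to [relieff()].
#' @return A `ranked_features` object: list with `dataset` (restricted to
#'   the retained features, in merit order), `merit` (named scores of all
#'   scored features), `order` (retained feature names, best first),
#'   `threshold`, `cap`.
#' @export
rank_and_reduce <- function(dataset, threshold = 0.01, cap = 1000L,
                            seed = 1L, k_neighbors = 10L,
                            sample_iterations = NULL) {
  merit <- if (dataset$problem_type == "classification") {
    vapply(dataset$data, information_gain, numeric(1),
           classes = dataset$y)
  } else {
    relieff(dataset, k_neighbors = k_neighbors,
            sample_iterations = sample_iterations, seed = seed)
  }
  names(merit) <- colnames(dataset$data)
  keep <- which(abs(merit) > threshold)
  if (!length(keep))
    stop("empty ranking: no feature has |merit| > ", threshold,
         call. = FALSE)
  ord <- keep[order(-abs(merit[keep]), keep)]
  if (length(ord) > cap) ord <- ord[seq_len(cap)]
  order_names <- colnames(dataset$data)[ord]
  reduced <- dataset
  reduced$data <- dataset$data[, order_names, drop = FALSE]
  structure(list(dataset = reduced, merit = merit, order = order_names,
                 threshold = threshold, cap = cap),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("ranked_features: %d retained of %d scored (|merit| > %g)\n",
              length(x$order), length(x$merit), x$threshold))
  top <- utils::head(x$order, 5L)
  cat("  top:", paste(sprintf("%s (%.3f)", top, x$merit[top]),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Export a ranking table
#'
#' Writes the scored features as a CSV with columns feature, merit,
#' abs_merit, rank (retained features first, in merit order; dropped
#' features get rank `NA`).
#'
#' @param ranked A `ranked_features` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranked, path) {
  rank_idx <- match(names(ranked$merit), ranked$order)
  df <- data.frame(feature = names(ranked$merit),
                   merit = unname(ranked$merit),
                   abs_merit = abs(unname(ranked$merit)),
                   rank = rank_idx)
  df <- df[order(is.na(df$rank), df$rank, -df$abs_merit), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
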