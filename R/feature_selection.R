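# assemble a ranking data.frame (ordered by score desc, ties by original
# column order) with class kcr_ranking
new_ranking <- function(names, score, p_value = NA_real_, method, params) {
  ord <- order(-score, seq_along(score))
  out <- data.frame(name = names[ord],
                    score = score[ord],
                    p_value = if (length(p_value) > 1L) p_value[ord]
                              else rep(p_value, length(ord)),
                    rank = seq_along(ord))
  structure(out, class = c("kcr_ranking", "data.frame"),
            method = method, params = params)
}

#' @export
print.kcr_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("<kcr_ranking> method=%s, %d features\n",
              attr(x, "method"), nrow(x)))
  print.data.frame(utils::head(x, n))
  invisible(x)
}

# extract matrix + labels from a kcr_features object or matrix
fs_inputs <- function(x, labels) {
  if (inherits(x, "kcr_features")) {
    labels <- x$labels
    x <- x$x
  }
  labels <- as_kcr_label(labels)
  if (length(unique(labels)) < 2L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  list(x = as.matrix(x), labels = labels)
}

#' Chi-square feature ranking
#'
#' Each continuous feature is binarised at its global mean (or median) and
#' crossed with the class label in a 2x2 contingency table; the chi-square
#' statistic (1 df, no continuity correction) and its p-value score the
#' feature. Constant features get statistic 0 and p-value 1. Features are
#' ranked by statistic, descending.
#'
#' @param x Numeric feature matrix (windows x dimensions) or a
#'   \code{kcr_features} object.
#' @param labels Class labels (ignored if \code{x} is \code{kcr_features}).
#' @param binarize \code{"mean"} (default) or \code{"median"} cut point.
#' @return A \code{kcr_ranking} data.frame (\code{name}, \code{score},
#'   \code{p_value}, \code{rank}).
#' @export
chi2_rank <- function(x, labels = NULL, binarize = c("mean", "median")) {
  binarize <- match.arg(binarize)
  inp <- fs_inputs(x, labels)
  x <- inp$x
  pos <- inp$labels == "positive"
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  cut <- if (binarize == "mean") colMeans(x) else
    apply(x, 2, stats::median)
  high <- sweep(x, 2, cut, ">")
  a <- colSums(high & pos)          # (pos, high)
  b <- sum(pos) - a                 # (pos, low)
  cc <- colSums(high & !pos)        # (neg, high)
  d <- sum(!pos) - cc               # (neg, low)
  N <- nrow(x)
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  stat <- ifelse(denom > 0, N * (a * d - b * cc)^2 / denom, 0)
  p <- ifelse(denom > 0, stats::pchisq(stat, df = 1, lower.tail = FALSE), 1)
  new_ranking(colnames(x), stat, p, "chi2", list(binarize = binarize))
}

#' Gradient-boosted-tree importance ranking
#'
#' Fits a seeded gradient-boosted tree ensemble (xgboost, binary logistic
#' objective, single thread for determinism) and ranks features by total
#' split-gain importance; features never used in a split score 0. The
#' subset with importance strictly greater than the average over all
#' features is reported in the \code{"above_average"} attribute.
#'
#' @inheritParams chi2_rank
#' @param seed Integer seed.
#' @param nrounds Boosting rounds, default 100.
#' @param max_depth,eta Tree depth and learning rate.
#' @return A \code{kcr_ranking} with attribute \code{"above_average"}
#'   (character vector of feature names).
#' @export
gbm_importance_rank <- function(x, labels = NULL, seed = 1, nrounds = 100L,
                                max_depth = 6L, eta = 0.3) {
  inp <- fs_inputs(x, labels)
  x <- inp$x
  if (all(x == x[1])) stop("degenerate feature matrix (single value)",
                           call. = FALSE)
  y <- as.integer(inp$labels == "positive")
  imp_score <- with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1),
      data = dtrain, nrounds = nrounds, verbose = 0)
    imp <- xgboost::xgb.importance(model = bst)
    s <- stats::setNames(rep(0, ncol(x)), colnames(x))
    s[imp$Feature] <- imp$Gain
    s
  })
  out <- new_ranking(colnames(x), unname(imp_score), NA_real_, "gbm",
                     list(seed = seed, nrounds = nrounds))
  attr(out, "above_average") <- out$name[out$score > mean(imp_score)]
  out
}

# pairwise distances between feature columns of a min-max scaled matrix;
# euclidean is per-sample RMS-normalised so its magnitude is commensurate
# with a correlation (O(1) rather than O(sqrt(n)))
column_distances <- function(xs, distance) {
  p <- ncol(xs)
  if (distance == "euclidean") {
    as.matrix(stats::dist(t(xs))) / sqrt(nrow(xs))
  } else {
    cp <- crossprod(xs)
    sq <- diag(cp)
    if (distance == "cosine") {
      nrm <- sqrt(sq)
      sim <- cp / outer(pmax(nrm, .Machine$double.eps),
                        pmax(nrm, .Machine$double.eps))
      1 - sim
    } else {  # tanimoto
      den <- outer(sq, sq, "+") - cp
      sim <- ifelse(den > 0, cp / den, 1)
      1 - sim
    }
  }
}

#' Max-relevance-max-distance (MRMD) feature ranking
#'
#' Scores each feature by the unweighted sum of its relevance to the label
#' (absolute Pearson correlation; 0 for zero-variance features) and its
#' mean pairwise distance to all other feature columns, computed on
#' columns min-max scaled to [0, 1] for comparability. The Euclidean
#' distance is RMS-normalised (divided by the square root of the sample
#' count) so the two terms share an O(1) scale; cosine and Tanimoto
#' distances are bounded already. Higher scores mean relevant-yet-
#' non-redundant features. Default distance: Euclidean.
#'
#' @inheritParams chi2_rank
#' @param distance \code{"euclidean"} (default), \code{"cosine"} or
#'   \code{"tanimoto"}.
#' @return A \code{kcr_ranking} with columns \code{relevance} and
#'   \code{distance} alongside the composite \code{score}.
#' @export
mrmd_rank <- function(x, labels = NULL,
                      distance = c("euclidean", "cosine", "tanimoto")) {
  distance <- match.arg(distance)
  inp <- fs_inputs(x, labels)
  x <- inp$x
  if (ncol(x) < 2L) stop("MRMD requires at least 2 features", call. = FALSE)
  y <- as.numeric(inp$labels == "positive")
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  xs <- sweep(x, 2, rng[1, ])
  xs <- sweep(xs, 2, ifelse(span > 0, span, 1), "/")
  rel <- suppressWarnings(abs(as.vector(stats::cor(x, y))))
  rel[!is.finite(rel)] <- 0
  D <- column_distances(xs, distance)
  mean_dist <- (rowSums(D)) / (ncol(x) - 1L)
  score <- rel + mean_dist
  out <- new_ranking(colnames(x), score, NA_real_, "mrmd",
                     list(distance = distance))
  ord <- match(out$name, colnames(x))
  out$relevance <- rel[ord]
  out$distance <- mean_dist[ord]
  out
}

#' Select the top of a feature ranking
#'
#' Either the top \code{k} features or, in threshold mode, every feature
#' with p-value below \code{p_threshold}. Ties were already broken by
#' original column order when the ranking was built, so the selection is
#' deterministic.
#'
#' @param ranked A \code{kcr_ranking}.
#' @param k Number of features to keep (top-k mode).
#' @param p_threshold p-value cut-off (threshold mode; requires a ranking
#'   with p-values, i.e. chi-square).
#' @return Ordered character vector of retained feature names.
#' @export
#' @examples
#' r <- chi2_rank(matrix(rnorm(40), 10, dimnames = list(NULL, letters[1:4])),
#'                rep(c("positive", "negative"), 5))
#' select_top(r, k = 2)
select_top <- function(ranked, k = NULL, p_threshold = NULL) {
  stopifnot(inherits(ranked, "kcr_ranking"))
  if (is.null(k) == is.null(p_threshold)) {
    stop("supply exactly one of `k` or `p_threshold`", call. = FALSE)
  }
  if (!is.null(k)) {
    if (k > nrow(ranked)) {
      stop("k = ", k, " exceeds the ", nrow(ranked), " ranked features",
           call. = FALSE)
    }
    ranked$name[seq_len(k)]
  } else {
    if (all(is.na(ranked$p_value))) {
      stop("threshold mode requires a ranking with p-values", call. = FALSE)
    }
    ranked$name[!is.na(ranked$p_value) & ranked$p_value < p_threshold]
  }
}

#' Write a ranking / selection to disk
#'
#' The ranking goes out as CSV (\code{name,score,p_value,rank}); a selected
#' column subset as a plain-text list, one name per line.
#'
#' @param ranked A \code{kcr_ranking}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
kcr_write_ranking <- function(ranked, path) {
  utils::write.csv(as.data.frame(ranked)[, c("name", "score", "p_value",
                                             "rank")],
                   path, row.names = FALSE)
  invisible(path)
}
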