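#' Fisher discriminant ratio of one feature
#'
#' The intra/inter variance criterion: the variance of the class centroids
#' (external variance) divided by the average variance inside the classes
#' (internal variance). A large value means well-separated class means and
#' reproducible replicates, i.e. a discriminative feature.
#'
#' The criterion names the two quantities without fixing divisors; the
#' defaults use the population variance (divide by the number of classes /
#' class size) for the centroids and the unweighted mean of the per-class
#' population variances, matching the "average variance inside each
#' category" reading. Sample-variance (n-1) conventions are available; the
#' induced feature ordering is unaffected when every class has the same
#' replicate count.
#'
#' @param values Numeric vector, one feature across all measurements.
#' @param labels Class label per measurement (factor or character).
#' @param centroid_variance `"population"` (default) or `"sample"` divisor
#'   for the between-centroid variance.
#' @param within_variance `"population"` (default) or `"sample"` divisor
#'   for each class's internal variance.
#' @return Nonnegative scalar; `Inf` when the internal variance is exactly 0
#'   but centroids differ, `NaN` when the feature is constant (both 0).
#' @export
fisher_ratio <- function(values, labels,
                         centroid_variance = c("population", "sample"),
                         within_variance = c("population", "sample")) {
  centroid_variance <- match.arg(centroid_variance)
  within_variance <- match.arg(within_variance)
  stopifnot(is.numeric(values), length(values) == length(labels))
  labels <- factor(labels)
  labels <- droplevels(labels)
  k <- nlevels(labels)
  if (k < 2L) stop("need at least two classes", call. = FALSE)
  n_c <- tabulate(labels)
  if (any(n_c < 2L)) stop("need at least two observations per class", call. = FALSE)
  pop_var <- function(x) mean((x - mean(x))^2)
  centroids <- tapply(values, labels, mean)
  external <- if (centroid_variance == "population") {
    pop_var(centroids)
  } else {
    stats::var(as.numeric(centroids))
  }
  wvar <- tapply(values, labels, function(x) {
    if (within_variance == "population") pop_var(x) else stats::var(x)
  })
  internal <- mean(wvar)
  if (internal == 0) {
    return(if (external == 0) NaN else Inf)
  }
  external / internal
}

#' Rank all features by Fisher ratio
#'
#' Scores every column of a (normalized) feature matrix with
#' [fisher_ratio()] and orders features from most to least discriminative.
#' Infinite scores (zero within-class variance) sort first; constant
#' features (undefined ratio) sort last; ties keep ascending column order.
#'
#' @param fm A labelled `feature_matrix`.
#' @param ... Passed to [fisher_ratio()] (variance conventions).
#' @return A `ranked_features` data frame: `rank`, `feature`, `vr`.
#' @export
rank_features <- function(fm, ...) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$y))
  vr <- vapply(
    seq_len(ncol(fm$X)),
    function(j) fisher_ratio(fm$X[, j], fm$y, ...),
    numeric(1)
  )
  key <- vr
  key[is.nan(key)] <- -Inf
  ord <- order(-key) # stable: ties resolved by ascending column index
  structure(
    data.frame(
      rank = seq_along(ord),
      feature = colnames(fm$X)[ord],
      vr = vr[ord],
      row.names = NULL
    ),
    class = c("ranked_features", "data.frame")
  )
}

#' Select the top-k ranked features
#'
#' @param ranking A `ranked_features` data frame from [rank_features()].
#' @param k Number of features to keep, `1 <= k <=` total feature count.
#' @return Character vector of the `k` best feature names, best first.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "ranked_features"))
  if (length(k) != 1L || is.na(k) || k < 1L || k > nrow(ranking)) {
    stop("k must lie in [1, ", nrow(ranking), "]", call. = FALSE)
  }
  ranking$feature[seq_len(as.integer(k))]
}

#' Write a feature ranking to CSV
#'
#' @param ranking A `ranked_features` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.csv(as.data.frame(ranking), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
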