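#' Confusion matrix with rows = real, columns = predicted
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels.
#' @param classes Ordered class labels; default [quality_classes()].
#' @return A `confusion_matrix`: integer matrix, rows the actual classes,
#'   columns the predicted ones.
#' @export
confusion_matrix <- function(truth, predicted, classes = quality_classes()) {
  truth <- factor(as.character(truth), levels = classes)
  predicted <- factor(as.character(predicted), levels = classes)
  if (anyNA(truth) || anyNA(predicted)) stop("labels outside the class set", call. = FALSE)
  cm <- table(real = truth, predicted = predicted)
  structure(unclass(cm), class = c("confusion_matrix", "matrix"))
}

#' Classification success rate of a confusion matrix
#'
#' `100 * trace / total`: percent of measurements on the diagonal. Returned
#' at full precision; displays round to whole percents.
#'
#' @param cm A `confusion_matrix` (any square count matrix works).
#' @return Percent correct in `[0, 100]`.
#' @export
success_rate <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm)) / total
}

# Train the named classifier on (X, y) and predict rows of X_new.
fit_and_predict <- function(classifier, X, y, X_new,
                            hyper = artmap_hyperparams(), priors = NULL) {
  switch(classifier,
    artmap = {
      m <- fuzzy_artmap(X, y, hyper = hyper)
      predict(m, X_new)
    },
    lda = {
      m <- fit_lda(X, y, priors = priors)
      predict(m, X_new)
    },
    stop("unknown classifier '", classifier, "'", call. = FALSE)
  )
}

#' Leave-one-out cross-validation of one classifier on one feature subset
#'
#' Runs `n` folds: fold `i` trains on every measurement but `i` and
#' predicts measurement `i`; the held-out predictions accumulate into a
#' confusion matrix. Folds execute in row order. If a fold's training set
#' lacks a class entirely (possible on tiny datasets), the fold still runs
#' with the remaining classes and a message is emitted.
#'
#' In the default (study-faithful) mode `fm` is already normalized and
#' ranked globally, and folds only subset rows. With `fold_safe = TRUE`,
#' `fm` must be the raw (unnormalized) matrix: each fold recomputes the
#' column normalization — and, when `rank_k` is given, the Fisher ranking
#' and top-`rank_k` selection — from its 149 training rows only, and
#' replays them onto the held-out row (clipped to `[0, 1]`).
#'
#' @param fm A labelled `feature_matrix`.
#' @param classifier `"artmap"` or `"lda"`.
#' @param features Character vector of feature columns to use; default all.
#' @param fold_safe Recompute normalization (and ranking) inside each fold?
#' @param rank_k In fold-safe mode, select the top-`rank_k` features per
#'   fold instead of using `features`.
#' @param hyper ARTMAP hyperparameters ([artmap_hyperparams()]).
#' @param priors LDA priors (default empirical).
#' @return A `confusion_matrix` over all held-out predictions.
#' @export
loocv <- function(fm, classifier = c("artmap", "lda"), features = NULL,
                  fold_safe = FALSE, rank_k = NULL,
                  hyper = artmap_hyperparams(), priors = NULL) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$y))
  n <- nrow(fm$X)
  if (n < nlevels(fm$y) + 1L) stop("too few measurements for LOOCV", call. = FALSE)
  if (is.null(features)) features <- colnames(fm$X)
  classes <- levels(fm$y)
  pred <- character(n)
  warned_missing <- FALSE
  for (i in seq_len(n)) {
    y_tr <- fm$y[-i]
    if (!warned_missing && nlevels(droplevels(y_tr)) < length(classes)) {
      message("fold ", i, ": training set lacks a class; fold executed anyway")
      warned_missing <- TRUE
    }
    if (fold_safe) {
      Xtr_raw <- fm$X[-i, , drop = FALSE]
      norm <- normalize_columns(Xtr_raw)
      stats <- attr(norm, "norm_stats")
      Xte <- normalize_columns(fm$X[i, , drop = FALSE], stats = stats)
      sel <- features
      if (!is.null(rank_k)) {
        fm_tr <- structure(list(X = norm, y = droplevels(y_tr), normalized = TRUE),
          class = "feature_matrix"
        )
        sel <- select_top_k(rank_features(fm_tr), rank_k)
      }
      Xtr <- norm[, sel, drop = FALSE]
      Xte <- Xte[, sel, drop = FALSE]
    } else {
      Xtr <- fm$X[-i, features, drop = FALSE]
      Xte <- fm$X[i, features, drop = FALSE]
    }
    p <- fit_and_predict(classifier, Xtr, droplevels(y_tr), Xte,
      hyper = hyper, priors = priors
    )
    pred[i] <- as.character(p)
  }
  confusion_matrix(fm$y, pred, classes = classes)
}

#' Run the full classifier x feature-subset comparison
#'
#' The complete benchmark grid: features are ranked by Fisher ratio, then
#' for every subset size `k` and every classifier a leave-one-out
#' cross-validation produces a confusion matrix and success rate. In the
#' default mode normalization and ranking are computed once on the full
#' matrix (the study-faithful protocol, which leaks the held-out row into
#' the column maxima and the ranking); `fold_safe = TRUE` recomputes both
#' inside every fold.
#'
#' @param fm A labelled `feature_matrix`, unnormalized (the function
#'   normalizes it) or already normalized.
#' @param ks Feature-subset sizes; default `c(10, 20, 30, 49)` capped at
#'   the matrix width.
#' @param classifiers Which classifiers to run.
#' @param fold_safe Fold-safe normalization/ranking (see [loocv()]).
#' @param hyper ARTMAP hyperparameters.
#' @param priors LDA priors.
#' @param seed Seed recorded in the report metadata (the grid itself is
#'   deterministic).
#' @return An `experiment_report`: list with `ranking`, `cells` (per
#'   `classifier x k`: `confusion`, `success_rate`, `features`), and
#'   `metadata`.
#' @export
run_experiment <- function(fm, ks = c(10, 20, 30, 49),
                           classifiers = c("artmap", "lda"),
                           fold_safe = FALSE,
                           hyper = artmap_hyperparams(), priors = NULL,
                           seed = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$y))
  classifiers <- match.arg(classifiers, c("artmap", "lda"), several.ok = TRUE)
  ks <- sort(unique(pmin(as.integer(ks), ncol(fm$X))))
  fm_norm <- if (fm$normalized) fm else normalize_columns(fm)
  ranking <- rank_features(fm_norm)
  cells <- list()
  for (k in ks) {
    feats <- select_top_k(ranking, k)
    for (clf in classifiers) {
      cm <- if (fold_safe) {
        loocv(fm, clf, fold_safe = TRUE, rank_k = k, hyper = hyper, priors = priors)
      } else {
        loocv(fm_norm, clf, features = feats, hyper = hyper, priors = priors)
      }
      cells[[paste0(clf, "_k", k)]] <- list(
        classifier = clf, k = k, features = feats,
        confusion = cm, success_rate = success_rate(cm)
      )
    }
  }
  structure(
    list(
      ranking = ranking, cells = cells,
      metadata = list(
        n = nrow(fm$X), p = ncol(fm$X), ks = ks, classifiers = classifiers,
        fold_safe = fold_safe, seed = seed, hyper = hyper,
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "Leave-one-out comparison: %d measurements, %d features (%s mode)\n\n",
    md$n, md$p, if (md$fold_safe) "fold-safe" else "global normalization/ranking"
  ))
  for (clf in md$classifiers) {
    cat(toupper(clf), "\n")
    for (k in md$ks) {
      cell <- x$cells[[paste0(clf, "_k", k)]]
      cat(sprintf(
        "  k = %2d   success rate %3.0f%%  (%.2f%%)\n",
        k, round(cell$success_rate), cell$success_rate
      ))
      cm <- cell$confusion
      hdr <- paste(sprintf("%5s", colnames(cm)), collapse = "")
      cat("          ", hdr, "\n")
      for (r in seq_len(nrow(cm))) {
        cat(sprintf("      %-4s%s\n", rownames(cm)[r], paste(sprintf("%5d", cm[r, ]), collapse = "")))
      }
    }
    cat("\n")
  }
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' Stable serialization of the grid: ranking, per-cell confusion matrices
#' and full-precision success rates, and the configuration metadata.
#' Volatile fields (timestamps) are dropped so identical runs produce
#' byte-identical files.
#'
#' @param report An `experiment_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  md <- report$metadata
  md$timestamp <- NULL
  obj <- list(
    metadata = md,
    ranking = report$ranking,
    cells = lapply(report$cells, function(cell) {
      list(
        classifier = cell$classifier, k = cell$k, features = cell$features,
        success_rate = cell$success_rate,
        confusion = lapply(seq_len(nrow(cell$confusion)), function(r) {
          as.integer(cell$confusion[r, ])
        }),
        classes = rownames(cell$confusion)
      )
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
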