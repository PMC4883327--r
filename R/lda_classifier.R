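#' Fit a multiclass linear discriminant model from scatter matrices
#'
#' Classical LDA: find directions maximizing between-class over
#' within-class scatter. The within-class scatter `Sw` is the pooled sum of
#' centered cross-products; the between-class scatter `Sb` weights each
#' class-mean deviation from the grand mean by its class size. The
#' discriminant directions are the leading eigenvectors of `Sw^-1 Sb`,
#' computed through the symmetric whitening `Sw^-1/2 Sb Sw^-1/2` for
#' numerical stability; at most `min(p, C - 1)` directions exist (two for
#' the three quality classes).
#'
#' A (near-)singular `Sw` — e.g. 49 correlated features on 149 training
#' rows — is handled by a small ridge (`lambda * I`, default
#' `1e-8 * trace(Sw)/p`) plus an eigenvalue-truncated pseudo-inverse.
#' Eigenvector signs are fixed so each direction's largest-magnitude
#' loading is positive, making score plots reproducible.
#'
#' @param X Numeric matrix (rows = measurements) or `feature_matrix`.
#' @param y Class labels (factor); taken from `X$y` for a `feature_matrix`.
#' @param priors Named per-class prior probabilities; default empirical
#'   class frequencies.
#' @param lambda Ridge added to `Sw`; `NULL` for the trace-scaled default.
#' @return An object of class `rose_lda`: list with `class_means`,
#'   `within_scatter`, `between_scatter`, `directions` (p x r), `priors`,
#'   `explained_ratio`, `grand_mean`, `pooled_cov_inv`, `levels`.
#' @export
fit_lda <- function(X, y = NULL, priors = NULL, lambda = NULL) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in feature matrix", call. = FALSE)
  y <- droplevels(factor(y))
  C <- nlevels(y)
  n <- nrow(X)
  p <- ncol(X)
  if (C < 2L) stop("need at least two classes", call. = FALSE)
  if (n <= C) stop("need more rows than classes", call. = FALSE)
  n_c <- tabulate(y)
  if (any(n_c < 2L)) {
    stop("every class needs at least two rows (", paste(levels(y)[n_c < 2L], collapse = ", "), ")", call. = FALSE)
  }
  if (is.null(priors)) {
    priors <- n_c / n
  } else {
    priors <- priors[levels(y)]
    priors <- as.numeric(priors) / sum(priors)
  }
  names(priors) <- levels(y)

  grand <- colMeans(X)
  M <- matrix(0, C, p, dimnames = list(levels(y), colnames(X)))
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (k in seq_len(C)) {
    Xk <- X[y == levels(y)[k], , drop = FALSE]
    M[k, ] <- colMeans(Xk)
    D <- sweep(Xk, 2, M[k, ])
    Sw <- Sw + crossprod(D)
    db <- M[k, ] - grand
    Sb <- Sb + n_c[k] * tcrossprod(db)
  }
  Sw <- (Sw + t(Sw)) / 2
  Sb <- (Sb + t(Sb)) / 2

  if (is.null(lambda)) lambda <- 1e-8 * sum(diag(Sw)) / p
  if (!is.finite(lambda) || lambda < 0) lambda <- 1e-8
  Swr <- Sw + diag(lambda, p)
  es <- eigen(Swr, symmetric = TRUE)
  tol <- max(es$values) * 1e-12
  keep <- es$values > tol
  # pseudo-inverse square root of the regularized within scatter
  Wih <- es$vectors[, keep, drop = FALSE] %*%
    (t(es$vectors[, keep, drop = FALSE]) / sqrt(es$values[keep]))
  Msym <- Wih %*% Sb %*% Wih
  Msym <- (Msym + t(Msym)) / 2
  eb <- eigen(Msym, symmetric = TRUE)
  r <- min(C - 1L, p, sum(eb$values > max(eb$values[1], 0) * 1e-10))
  r <- max(r, 1L)
  A <- Wih %*% eb$vectors[, seq_len(r), drop = FALSE]
  # unit-length directions with a fixed sign convention
  for (j in seq_len(r)) {
    A[, j] <- A[, j] / sqrt(sum(A[, j]^2))
    i_max <- which.max(abs(A[, j]))
    if (A[i_max, j] < 0) A[, j] <- -A[, j]
  }
  colnames(A) <- paste0("LD", seq_len(r))
  rownames(A) <- colnames(X)
  ev <- pmax(eb$values[seq_len(r)], 0)
  expl <- if (sum(ev) > 0) ev / sum(ev) else rep(1 / r, r)

  # pooled covariance inverse for the equal-covariance Gaussian rule
  Sigma_inv <- (n - C) * Wih %*% Wih

  structure(
    list(
      class_means = M, within_scatter = Sw, between_scatter = Sb,
      directions = A, priors = priors, explained_ratio = expl,
      grand_mean = grand, pooled_cov_inv = Sigma_inv, levels = levels(y),
      lambda = lambda, n = n
    ),
    class = "rose_lda"
  )
}

#' @export
print.rose_lda <- function(x, ...) {
  cat(sprintf(
    "<rose_lda> %d classes, %d features, %d discriminant direction(s)\n",
    length(x$levels), nrow(x$directions), ncol(x$directions)
  ))
  cat(
    "explained discriminatory variance:",
    paste0(sprintf("%s %.1f%%", colnames(x$directions), 100 * x$explained_ratio), collapse = ", "), "\n"
  )
  invisible(x)
}

check_lda_newdata <- function(object, X) {
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  if (ncol(X) != nrow(object$directions)) {
    stop(
      "newdata has ", ncol(X), " columns; model expects ",
      nrow(object$directions), call. = FALSE
    )
  }
  X
}

#' Project measurements onto the discriminant plane
#'
#' Centers on the training grand mean and projects onto the discriminant
#' directions, yielding the LD1/LD2 score coordinates used for score plots.
#' The training grand mean maps to the origin.
#'
#' @param object A fitted `rose_lda` model.
#' @param X New data (matrix or `feature_matrix`) with the training columns.
#' @return Numeric matrix, one row per measurement, columns `LD1`, `LD2`
#'   (as many as retained directions).
#' @export
project_lda <- function(object, X) {
  stopifnot(inherits(object, "rose_lda"))
  X <- check_lda_newdata(object, X)
  sweep(X, 2, object$grand_mean) %*% object$directions
}

#' Classify measurements with a fitted LDA model
#'
#' The equal-covariance Gaussian rule: assign to the class maximizing
#' `x' S^-1 m_k - m_k' S^-1 m_k / 2 + log(prior_k)` with `S` the pooled
#' within-class covariance (equivalently, the prior-adjusted nearest
#' centroid under Mahalanobis distance). Exact ties go to the class with
#' the larger prior, then to the lower class index.
#'
#' @param object A fitted `rose_lda` model.
#' @param newdata Matrix or `feature_matrix` with the training columns.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.rose_lda <- function(object, newdata, ...) {
  X <- check_lda_newdata(object, newdata)
  M <- object$class_means
  Si <- object$pooled_cov_inv
  W <- Si %*% t(M) # p x C
  b <- -0.5 * colSums(t(M) * W) + log(object$priors)
  scores <- X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE)
  idx <- apply(scores, 1, function(s) {
    best <- which(s == max(s))
    if (length(best) > 1L) {
      pr <- object$priors[best]
      best <- best[pr == max(pr)]
    }
    best[1]
  })
  factor(object$levels[idx], levels = object$levels)
}

#' Export LDA scores for plotting
#'
#' Writes the Fig.-style score-plot data: one row per measurement with its
#' LD coordinates and true class.
#'
#' @param object A fitted `rose_lda`.
#' @param fm A labelled `feature_matrix` restricted to the training columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lda_scores <- function(object, fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  S <- project_lda(object, fm)
  d <- data.frame(measurement_id = rownames(fm$X), S, check.names = FALSE)
  if (!is.null(fm$y)) d$true_class <- as.character(fm$y)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
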