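#' Complement-code an input vector
#'
#' Adaptive-resonance networks represent an input `a` in `[0,1]^M` as
#' `I = (a, 1 - a)`, which preserves amplitude information and fixes the
#' city-block norm: `|I| = M` for every valid input. This constant norm is
#' what keeps category weights from eroding to zero during fuzzy learning.
#'
#' @param a Numeric vector with every component in `[0, 1]`.
#' @return Numeric vector of length `2 * length(a)`.
#' @examples
#' complement_code(c(0.3, 0.7))
#' @export
complement_code <- function(a) {
  nms <- names(a)
  a <- as.numeric(a)
  bad <- which(!is.finite(a) | a < 0 | a > 1)
  if (length(bad) > 0L) {
    nm <- nms[bad[1]]
    stop(
      "input component ", if (!is.null(nm) && nzchar(nm)) nm else bad[1],
      " outside [0, 1]; normalize features first", call. = FALSE
    )
  }
  c(a, 1 - a)
}

# Choice function: T_j = |I ^ w_j| / (alpha + |w_j|), fuzzy AND = pmin,
# |.| = city-block norm. W holds weights column-wise (2M x n_categories).
artmap_choice <- function(I, W, wnorm, alpha) {
  colSums(pmin(W, I)) / (alpha + wnorm)
}

# Match score |I ^ w| / |I|; for complement-coded I the norm is exactly M.
artmap_match <- function(I, w) {
  sum(pmin(I, w)) / (length(I) / 2)
}

# Resonant weight update; beta = 1 is fast learning (w <- I ^ w).
artmap_learn <- function(w, I, beta) {
  beta * pmin(I, w) + (1 - beta) * w
}

#' Hyperparameters of the Fuzzy ARTMAP classifier
#'
#' @param rho_a_baseline Baseline vigilance of the category module, in
#'   `[0, 1]`. 0 allows the coarsest categories; match tracking refines
#'   them only when a training prediction fails.
#' @param rho_ab Map-field vigilance, near 1 so that distinct class labels
#'   occupy distinct map-field nodes. With one-hot class labels any value
#'   above 0.5 reduces the map-field test to exact class agreement.
#' @param alpha Choice parameter, small and positive; values well below 1
#'   prevent ties in the category competition.
#' @param beta Learning rate in `(0, 1]`; 1 is fast learning (a single
#'   presentation commits and fully learns a category).
#' @param epsilon Match-tracking increment added to the matched fraction
#'   after a predictive error (MT+).
#' @param max_epochs Maximum passes over the training set; learning stops
#'   earlier once no weight changes and no new categories occur in a pass.
#' @return List of validated hyperparameters.
#' @export
artmap_hyperparams <- function(rho_a_baseline = 0, rho_ab = 0.99, alpha = 0.001,
                               beta = 1, epsilon = 0.001, max_epochs = 10L) {
  stopifnot(
    rho_a_baseline >= 0, rho_a_baseline <= 1,
    rho_ab >= 0, rho_ab <= 1,
    alpha > 0, beta > 0, beta <= 1, epsilon > 0, max_epochs >= 1
  )
  list(
    rho_a_baseline = rho_a_baseline, rho_ab = rho_ab, alpha = alpha,
    beta = beta, epsilon = epsilon, max_epochs = as.integer(max_epochs)
  )
}

#' Train a Fuzzy ARTMAP classifier
#'
#' Supervised adaptive-resonance classifier in its category-prediction
#' (simplified) form: a fuzzy ART category module whose committed
#' categories are linked through a map field directly to class labels.
#' For each training pattern the network complement-codes the input,
#' lets committed categories compete through the choice function
#' `T_j = |I ^ w_j| / (alpha + |w_j|)`, and tests the winner's match
#' `|I ^ w_j| / |I|` against the current vigilance. If the winning
#' category predicts the wrong class, match tracking raises the vigilance
#' just above the winner's match (MT+) and the search resumes; when no
#' committed category qualifies, a new category is committed with
#' `w = I` and mapped to the pattern's class. Resonant categories learn
#' `w <- beta * (I ^ w) + (1 - beta) * w`; with `beta = 1` (fast
#' learning) a category is fully learned from a single presentation.
#' Training iterates over the set until weights stabilize.
#'
#' The algorithm is deterministic: no randomness enters unless
#' `shuffle = TRUE` (then a seeded permutation fixes the presentation
#' order, which ARTMAP is sensitive to).
#'
#' @param X Numeric matrix with all entries in `[0, 1]` (rows =
#'   measurements), or a normalized `feature_matrix`.
#' @param y Class labels; taken from `X$y` for a `feature_matrix`.
#' @param hyper Hyperparameters from [artmap_hyperparams()].
#' @param shuffle Shuffle presentation order with `seed`?
#' @param seed Seed for the optional shuffle.
#' @return A `fuzzy_artmap` model: list with `weights` (2M x n_categories
#'   matrix), `category_class` (factor, one class per committed category),
#'   `hyper`, `input_dim`, `levels`, `features`, `epochs_run`.
#' @export
fuzzy_artmap <- function(X, y = NULL, hyper = artmap_hyperparams(),
                         shuffle = FALSE, seed = 1L) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  stopifnot(nrow(X) == length(y), nrow(X) >= 1L)
  if (any(!is.finite(X)) || any(X < 0) || any(X > 1)) {
    stop("training features must lie in [0, 1]; normalize first", call. = FALSE)
  }
  M <- ncol(X)
  model <- structure(
    list(
      weights = matrix(numeric(0), nrow = 2L * M, ncol = 0L),
      category_class = integer(0),
      hyper = hyper, input_dim = M, levels = levels(y),
      features = colnames(X), epochs_run = 0L
    ),
    class = "fuzzy_artmap"
  )
  ord <- seq_len(nrow(X))
  if (shuffle) ord <- with_seed(seed, sample(ord))
  artmap_fit(model, X[ord, , drop = FALSE], as.integer(y)[ord])
}

# Core incremental fit: presents patterns in row order for up to max_epochs
# passes, stopping when a full pass changes nothing.
artmap_fit <- function(model, X, y_idx) {
  hp <- model$hyper
  M <- model$input_dim
  W <- model$weights
  wnorm <- if (ncol(W) > 0L) colSums(W) else numeric(0)
  cls <- model$category_class
  T_unc <- M / (hp$alpha + 2 * M) # choice of the uncommitted node (w = 1)
  for (epoch in seq_len(hp$max_epochs)) {
    changed <- FALSE
    for (i in seq_len(nrow(X))) {
      I <- c(X[i, ], 1 - X[i, ])
      yi <- y_idx[i]
      rho <- hp$rho_a_baseline
      if (ncol(W) > 0L) {
        sj <- colSums(pmin(W, I))
        Tj <- sj / (hp$alpha + wnorm)
        match_j <- sj / M
      } else {
        Tj <- numeric(0)
        match_j <- numeric(0)
      }
      eligible <- rep(TRUE, ncol(W))
      repeat {
        ok <- eligible & match_j >= rho
        # uncommitted node competes too; committed wins ties (lower index)
        if (any(ok) && max(Tj[ok]) >= T_unc) {
          J <- which(ok)[which.max(Tj[ok])]
          if (cls[J] == yi) { # map-field test: class agreement (rho_ab > 0.5)
            w_new <- artmap_learn(W[, J], I, hp$beta)
            if (any(w_new != W[, J])) {
              W[, J] <- w_new
              wnorm[J] <- sum(w_new)
              changed <- TRUE
            }
            break
          }
          # match tracking: raise vigilance just above the failed match
          rho <- match_j[J] + hp$epsilon
          eligible[J] <- FALSE
        } else {
          # commit a new category for this pattern
          W <- cbind(W, I)
          wnorm <- c(wnorm, sum(I))
          cls <- c(cls, yi)
          changed <- TRUE
          break
        }
      }
    }
    model$epochs_run <- model$epochs_run + 1L
    if (!changed) break
  }
  model$weights <- W
  model$category_class <- cls
  model
}

#' Incrementally update a trained Fuzzy ARTMAP
#'
#' Continues training an existing model on new labelled patterns — the
#' online-learning property of adaptive resonance: new categories can be
#' committed without retraining or degrading what was already learned
#' (weights only shrink toward observed patterns, never reset).
#'
#' @param model A fitted `fuzzy_artmap`.
#' @param X New patterns in `[0, 1]` with the model's feature columns.
#' @param y Their class labels.
#' @return The updated `fuzzy_artmap` model.
#' @export
artmap_update <- function(model, X, y) {
  stopifnot(inherits(model, "fuzzy_artmap"))
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) stop("feature dimension mismatch", call. = FALSE)
  if (any(!is.finite(X)) || any(X < 0) || any(X > 1)) {
    stop("features must lie in [0, 1]", call. = FALSE)
  }
  y <- as.character(y)
  if (!all(y %in% model$levels)) {
    model$levels <- union(model$levels, unique(y))
  }
  y_idx <- match(y, model$levels)
  artmap_fit(model, X, y_idx)
}

#' @export
print.fuzzy_artmap <- function(x, ...) {
  cat(sprintf(
    "<fuzzy_artmap> %d committed categories over %d features, %d classes (%d epoch(s))\n",
    ncol(x$weights), x$input_dim, length(x$levels), x$epochs_run
  ))
  invisible(x)
}

#' Classify patterns with a trained Fuzzy ARTMAP
#'
#' Each pattern is complement-coded and assigned the class mapped to the
#' committed category with the highest choice value among those passing
#' the baseline vigilance (with the baseline at 0 this is a pure argmax).
#' Ties go to the lowest category index, mirroring training.
#'
#' @param object A fitted `fuzzy_artmap` model.
#' @param newdata Matrix (or `feature_matrix`) in `[0, 1]` with the
#'   training feature columns.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.fuzzy_artmap <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$X
  X <- as.matrix(newdata)
  if (ncol(X) != object$input_dim) stop("feature dimension mismatch", call. = FALSE)
  if (ncol(object$weights) == 0L) stop("model has no committed categories", call. = FALSE)
  if (any(!is.finite(X)) || any(X < 0) || any(X > 1)) {
    stop("features must lie in [0, 1]", call. = FALSE)
  }
  hp <- object$hyper
  W <- object$weights
  wnorm <- colSums(W)
  M <- object$input_dim
  idx <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    I <- c(X[i, ], 1 - X[i, ])
    sj <- colSums(pmin(W, I))
    Tj <- sj / (hp$alpha + wnorm)
    ok <- (sj / M) >= hp$rho_a_baseline
    cand <- which(ok)
    if (length(cand) == 0L) cand <- seq_along(Tj)
    idx[i] <- cand[which.max(Tj[cand])]
  }
  factor(object$levels[object$category_class[idx]], levels = object$levels)
}

#' Serialize / restore a Fuzzy ARTMAP model as JSON
#'
#' The JSON carries the category weights, the category-to-class map, the
#' hyperparameters and the feature names, so a model can be stored,
#' shipped, and later updated incrementally with [artmap_update()].
#'
#' @param model A `fuzzy_artmap` model (for writing).
#' @param path JSON file path.
#' @return `write_artmap()` returns `path` invisibly; `read_artmap()`
#'   returns the restored `fuzzy_artmap`.
#' @export
write_artmap <- function(model, path) {
  stopifnot(inherits(model, "fuzzy_artmap"))
  obj <- list(
    input_dim = model$input_dim,
    levels = model$levels,
    features = model$features,
    hyper = model$hyper,
    category_class = model$category_class,
    weights = t(model$weights), # one row per category
    epochs_run = model$epochs_run
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_artmap
#' @export
read_artmap <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- obj$weights
  if (is.null(dim(W))) W <- matrix(W, nrow = max(1L, length(obj$category_class)))
  structure(
    list(
      weights = t(W),
      category_class = as.integer(obj$category_class),
      hyper = do.call(artmap_hyperparams, as.list(obj$hyper)),
      input_dim = as.integer(obj$input_dim),
      levels = as.character(obj$levels),
      features = as.character(obj$features),
      epochs_run = as.integer(obj$epochs_run)
    ),
    class = "fuzzy_artmap"
  )
}
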