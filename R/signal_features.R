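#' Segment a transient into baseline / injection / recovery
#'
#' Splits the sample index range at the injection and purge times of the
#' transient's schedule (default boundaries 60 s and 260 s). Intervals are
#' half-open on the right: a sample at exactly 60 s belongs to the
#' injection phase.
#'
#' @param tr A `sensor_transient`.
#' @return Named list of three integer index vectors: `baseline`,
#'   `injection`, `recovery`. They are disjoint, contiguous and together
#'   exhaust the samples.
#' @export
segment_phases <- function(tr) {
  stopifnot(inherits(tr, "sensor_transient"))
  sch <- tr$schedule
  t <- tr$t
  if (is.unsorted(t, strictly = TRUE)) stop("sample times must be strictly increasing", call. = FALSE)
  if (max(t) < sch$total_s - sch$sample_period_s - 1e-9) {
    stop("transient does not span the full schedule (truncated recording)", call. = FALSE)
  }
  list(
    baseline = which(t < sch$t_injection_s),
    injection = which(t >= sch$t_injection_s & t < sch$t_purge_s),
    recovery = which(t >= sch$t_purge_s & t < sch$total_s)
  )
}

# First time (linear interpolation between samples) at which the fractional
# progress (ref - R)/(ref - target_base) reaches `frac`, searching the given
# index window. Returns NA when never reached.
first_crossing_time <- function(t, R, idx, Ri, dR, frac, rising = FALSE) {
  if (dR == 0) return(NA_real_)
  prog <- (Ri - R[idx]) / dR # 0 at baseline level, 1 at full response
  if (rising) prog <- 1 - prog # recovery: progress back toward baseline
  hit <- which(prog >= frac)
  if (length(hit) == 0L) return(NA_real_)
  j <- hit[1]
  if (j == 1L) return(t[idx[1]])
  # interpolate between samples j-1 and j of the window
  p0 <- prog[j - 1]
  p1 <- prog[j]
  t0 <- t[idx[j - 1]]
  t1 <- t[idx[j]]
  if (p1 == p0) return(t1)
  t0 + (frac - p0) * (t1 - t0) / (p1 - p0)
}

#' Extract the seven response features of one sensor transient
#'
#' Computes the canonical MOS response descriptors from one transient:
#' five steady-state features built from the baseline resistance `Ri` and
#' the injection plateau resistance `Rf` (and the conductances
#' `Gi = 1/Ri`, `Gf = 1/Rf`), plus two kinetic features:
#' \describe{
#'   \item{f1}{`Ri / Rf`}
#'   \item{f2}{`Ri - Rf` (Ohm)}
#'   \item{f3}{`(Ri - Rf) / Ri`, the fractional resistance change}
#'   \item{f4}{`Gf - Gi` (Siemens)}
#'   \item{f5}{`(Gf - Gi) / Gi`, the fractional conductance change, known to
#'     linearize MOS response against concentration}
#'   \item{f6}{response time `Ti`: seconds from injection start until the
#'     resistance first covers 90% of `Ri - Rf`}
#'   \item{f7}{recovery time `Tr`: seconds from purge start until the
#'     resistance first returns to within 10% of `Ri - Rf` of baseline}
#' }
#' `Ri` is the mean resistance over the last `ri_window_s` of the baseline
#' phase (robust to settling); `Rf` the mean over the last `rf_window_s` of
#' the injection phase (the plateau). Threshold crossings are located with
#' linear interpolation between samples. If a 90% threshold is never
#' crossed, the corresponding time is set to the full phase duration with a
#' warning.
#'
#' @param tr A `sensor_transient`.
#' @param ri_window_s,rf_window_s Averaging windows (seconds) at the end of
#'   the baseline and injection phases.
#' @return Named numeric vector `f1`..`f7`, with `Ri` and `Rf` attached as
#'   attributes.
#' @export
extract_features <- function(tr, ri_window_s = 30, rf_window_s = 20) {
  ph <- segment_phases(tr)
  sch <- tr$schedule
  t <- tr$t
  R <- tr$R
  if (any(R <= 0)) stop("resistances must be > 0", call. = FALSE)
  bi <- ph$baseline
  ii <- ph$injection
  Ri <- mean(R[bi][t[bi] >= sch$t_injection_s - ri_window_s])
  Rf <- mean(R[ii][t[ii] >= sch$t_purge_s - rf_window_s])
  if (!is.finite(Ri) || !is.finite(Rf) || Ri == 0 || Rf == 0) {
    stop("degenerate Ri/Rf estimate", call. = FALSE)
  }
  Gi <- 1 / Ri
  Gf <- 1 / Rf
  dR <- Ri - Rf
  f6 <- first_crossing_time(t, R, ii, Ri, dR, 0.9)
  if (is.na(f6)) {
    warning("90% response level never reached; Ti set to injection duration")
    f6 <- sch$injection_s
  } else {
    f6 <- f6 - sch$t_injection_s
  }
  ri_idx <- ph$recovery
  f7 <- first_crossing_time(t, R, ri_idx, Ri, dR, 0.9, rising = TRUE)
  if (is.na(f7)) {
    warning("90% recovery level never reached; Tr set to recovery duration")
    f7 <- sch$recovery_s
  } else {
    f7 <- f7 - sch$t_purge_s
  }
  out <- c(
    f1 = Ri / Rf, f2 = dR, f3 = dR / Ri,
    f4 = Gf - Gi, f5 = (Gf - Gi) / Gi, f6 = f6, f7 = f7
  )
  attr(out, "Ri") <- Ri
  attr(out, "Rf") <- Rf
  out
}

#' Assemble the measurement x feature matrix
#'
#' Extracts the seven features from every sensor of every measurement and
#' stacks them into an `n x (7 * n_sensors)` matrix with columns named
#' `S1f1 ... S1f7, S2f1, ...` (49 columns for the seven-sensor array).
#'
#' @param measurements List of measurement records as produced by
#'   [generate_dataset()] (each with `measurement_id` and a named list
#'   `transients`).
#' @param labels Optional data frame with `measurement_id` and `class`
#'   columns (e.g. `dataset$labels`), or a vector of class labels in row
#'   order.
#' @param ... Passed to [extract_features()].
#' @return A `feature_matrix`: list with `X` (numeric matrix, rownames =
#'   measurement ids), `y` (factor of class labels or `NULL`), and
#'   `normalized` flag.
#' @export
build_feature_matrix <- function(measurements, labels = NULL, ...) {
  if (inherits(measurements, "enose_dataset")) {
    if (is.null(labels)) labels <- measurements$labels
    measurements <- measurements$measurements
  }
  stopifnot(length(measurements) >= 1L)
  ids <- vapply(measurements, function(m) m$measurement_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate measurement ids", call. = FALSE)
  sensor_ids <- sort(unique(unlist(lapply(measurements, function(m) {
    nm <- names(m$transients)
    if (is.null(nm)) nm <- vapply(m$transients, `[[`, character(1), "sensor_id")
    nm
  }))))
  feat_names <- as.vector(t(outer(sensor_ids, paste0("f", 1:7), paste0)))
  X <- matrix(NA_real_,
    nrow = length(measurements), ncol = length(feat_names),
    dimnames = list(ids, feat_names)
  )
  for (i in seq_along(measurements)) {
    m <- measurements[[i]]
    have <- names(m$transients)
    missing <- setdiff(sensor_ids, have)
    if (length(missing) > 0L) {
      stop(
        "measurement ", m$measurement_id, " is missing sensor(s): ",
        paste(missing, collapse = ", "), call. = FALSE
      )
    }
    for (s in sensor_ids) {
      f <- extract_features(m$transients[[s]], ...)
      X[i, paste0(s, "f", 1:7)] <- as.numeric(f)
    }
  }
  y <- NULL
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      y <- labels$class[match(ids, labels$measurement_id)]
    } else {
      y <- labels
    }
    y <- factor(as.character(y), levels = quality_classes())
    if (anyNA(y)) stop("labels missing for some measurements", call. = FALSE)
  }
  structure(list(X = X, y = y, normalized = FALSE), class = "feature_matrix")
}

#' Scale feature columns to the unit interval
#'
#' Divides each column by its maximum (the convention that preserves zero
#' and suits nonnegative MOS features), leaving all-zero columns untouched.
#' If a column contains negative values, divide-by-max cannot bound it in
#' `[0, 1]`, so that column falls back to min-max scaling with a warning.
#' The per-column statistics are stored in the result so the identical
#' transform can be replayed on new rows (e.g. a held-out cross-validation
#' row); replayed values are clipped to `[0, 1]`.
#'
#' @param fm A `feature_matrix` (or bare numeric matrix).
#' @param stats Optional normalization statistics from a previous call
#'   (`attr(out, "norm_stats")`), to apply a training-set transform to new
#'   data.
#' @return The normalized `feature_matrix`, columns in `[0, 1]`, with
#'   attribute `norm_stats` (data frame: `feature`, `method`, `max`, `min`).
#' @export
normalize_columns <- function(fm, stats = NULL) {
  bare <- !inherits(fm, "feature_matrix")
  X <- if (bare) as.matrix(fm) else fm$X
  if (is.null(stats)) {
    method <- character(ncol(X))
    mx <- apply(X, 2, max)
    mn <- apply(X, 2, min)
    method <- ifelse(mn < 0, "minmax", ifelse(mx == 0, "identity", "max"))
    if (any(method == "minmax")) {
      warning(
        "negative feature values in column(s) ",
        paste(colnames(X)[method == "minmax"], collapse = ", "),
        "; using min-max scaling for those columns"
      )
    }
    stats <- data.frame(
      feature = colnames(X), method = method, max = mx, min = mn,
      row.names = NULL
    )
  } else {
    if (!identical(stats$feature, colnames(X))) {
      stop("normalization stats do not match matrix columns", call. = FALSE)
    }
  }
  for (j in seq_len(ncol(X))) {
    X[, j] <- switch(stats$method[j],
      max = X[, j] / stats$max[j],
      minmax = if (stats$max[j] > stats$min[j]) {
        (X[, j] - stats$min[j]) / (stats$max[j] - stats$min[j])
      } else {
        X[, j] * 0
      },
      identity = X[, j]
    )
  }
  X <- pmin(pmax(X, 0), 1)
  if (bare) {
    attr(X, "norm_stats") <- stats
    return(X)
  }
  out <- structure(list(X = X, y = fm$y, normalized = TRUE), class = "feature_matrix")
  attr(out, "norm_stats") <- stats
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d measurements x %d features%s%s\n",
    nrow(x$X), ncol(x$X),
    if (x$normalized) ", normalized to [0,1]" else "",
    if (is.null(x$y)) "" else ", labelled"
  ))
  invisible(x)
}

#' Write a feature matrix to CSV
#'
#' One row per measurement: `measurement_id`, the feature columns, and a
#' final `class` column when labels are present.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  d <- data.frame(measurement_id = rownames(fm$X), fm$X, check.names = FALSE)
  if (!is.null(fm$y)) d$class <- as.character(fm$y)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
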