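# Shared builders for the test suite. Everything is generated in code so the
# suite carries no binary fixtures.

# Gaussian class blobs: k classes at the given center rows, shared sd.
make_blobs <- function(centers, n_per = 20, sd = 0.5, seed = 1) {
  centers <- as.matrix(centers)
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
      matrix(stats::rnorm(n_per * ncol(centers), sd = sd),
        nrow = n_per, byrow = TRUE
      ) + matrix(centers[k, ], n_per, ncol(centers), byrow = TRUE)
    }))
    y <- factor(rep(paste0("C", seq_len(nrow(centers))), each = n_per))
    list(X = X, y = y)
  })
}

# Wrap a bare matrix + labels as a feature_matrix object.
as_fm <- function(X, y = NULL, normalized = FALSE) {
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.null(rownames(X))) rownames(X) <- paste0("m", seq_len(nrow(X)))
  structure(list(X = X, y = if (is.null(y)) NULL else factor(y), normalized = normalized),
    class = "feature_matrix"
  )
}

# Brute-force Fisher ratio straight from the definitions: population variance
# of class centroids over the unweighted mean of within-class population
# variances. Kept deliberately naive and independent of fisher_ratio().
oracle_fisher <- function(values, labels) {
  labels <- factor(labels)
  cents <- vapply(levels(labels), function(l) mean(values[labels == l]), numeric(1))
  ext <- sum((cents - mean(cents))^2) / length(cents)
  wvars <- vapply(levels(labels), function(l) {
    v <- values[labels == l]
    sum((v - mean(v))^2) / length(v)
  }, numeric(1))
  int <- mean(wvars)
  if (int == 0) {
    return(if (ext == 0) NaN else Inf)
  }
  ext / int
}

# One noiseless transient with explicit depth on a 100 kOhm sensor.
toy_transient <- function(depth = 0.5, noise_cv = 0, tau_rise = 20,
                          tau_recovery = 80, schedule = phase_schedule()) {
  generate_transient(
    sensor = list(sensor_id = "S1", baseline_ohm = 1e5),
    schedule = schedule, tau_rise = tau_rise, tau_recovery = tau_recovery,
    noise_cv = noise_cv, depth = depth
  )
}

# A small 3-class labelled dataset in [0,1] with tight clusters, suitable
# for ARTMAP and LDA alike.
make_unit_clusters <- function(n_per = 10, p = 5, spread = 0.03, seed = 42) {
  centers <- withr::with_seed(seed, matrix(stats::runif(3 * p, 0.15, 0.85), nrow = 3))
  b <- make_blobs(centers, n_per = n_per, sd = spread, seed = seed + 1)
  b$X <- pmin(pmax(b$X, 0), 1)
  colnames(b$X) <- paste0("V", seq_len(p))
  b
}
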