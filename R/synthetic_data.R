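# Reproducible RNG helpers. A single root seed drives the whole generator;
# every genotype and every measurement draws from its own substream (derived
# from root seed + counter), so a subset of measurements is reproducible
# without generating the rest.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

substream_seed <- function(root, counter) {
  stopifnot(is.numeric(root), is.numeric(counter), counter >= 0)
  as.integer((abs(root) %% 1e6) * 2039 + counter)
}

# sd of log-resistance giving a multiplicative coefficient of variation cv
lognorm_sd <- function(cv) sqrt(log1p(cv^2))

#' Default seven-sensor MOS array descriptor
#'
#' Describes an array of seven metal-oxide-semiconductor gas sensors of the
#' TGS/SP families typically used for volatile organics (organic solvent
#' vapours, alcohols, hydrocarbons, ammonia). Each sensor has a clean-air
#' baseline resistance and a mean fractional response depth per quality
#' class: the relative resistance drop `d = (Ri - Rf)/Ri` elicited by the
#' headspace of an oil of that class.
#'
#' The depth patterns encode partially selective, overlapping sensitivities:
#' some sensors respond monotonically with the key-constituent total
#' (solvent/alcohol sensors), others peak at middle quality or dip for it,
#' so the three classes are not linearly ordered along any single direction
#' of sensor space. That mixture is what makes the classification task
#' non-trivially nonlinear.
#'
#' @return Data frame with columns `sensor_id`, `name`, `target`,
#'   `baseline_ohm`, `depth_C1`, `depth_C2`, `depth_C3`.
#' @export
default_sensor_array <- function() {
  data.frame(
    sensor_id = paste0("S", 1:7),
    name = c(
      "TGS-822", "TGS-842", "SP-15A", "SP-32", "SP-53",
      "TGS-2610", "TGS-2620"
    ),
    target = c(
      "organic solvent vapours", "methane", "LP gas", "alcohol",
      "ammonia", "LP gas", "organic solvent vapours"
    ),
    baseline_ohm = c(45e3, 120e3, 30e3, 80e3, 150e3, 25e3, 60e3),
    depth_C1 = c(0.25, 0.30, 0.28, 0.20, 0.28, 0.30, 0.42),
    depth_C2 = c(0.45, 0.31, 0.50, 0.40, 0.29, 0.48, 0.62),
    depth_C3 = c(0.70, 0.32, 0.31, 0.65, 0.30, 0.68, 0.45)
  )
}

#' Default per-class ranges for the key-constituent total
#'
#' Class-conditional sampling ranges (percent) for the six-constituent total
#' of generated genotypes, aligned with the 10%/50% quality thresholds, and
#' the number of genotypes per class. The default 4/3/3 split over ten
#' genotypes matches the reference GC-MS panel.
#'
#' @return Named list, one entry per class, each `list(range = c(lo, hi),
#'   n_genotypes = k)`.
#' @export
default_class_spec <- function() {
  list(
    C1 = list(range = c(2, 9), n_genotypes = 4L),
    C2 = list(range = c(12, 45), n_genotypes = 3L),
    C3 = list(range = c(55, 80), n_genotypes = 3L)
  )
}

validate_class_spec <- function(class_spec) {
  bounds <- list(C1 = c(0, 10), C2 = c(10, 50), C3 = c(50, 100))
  if (!all(names(class_spec) %in% names(bounds))) {
    stop("class_spec names must be among C1, C2, C3", call. = FALSE)
  }
  for (cl in names(class_spec)) {
    r <- class_spec[[cl]]$range
    n <- class_spec[[cl]]$n_genotypes
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2]) {
      stop("infeasible range for class ", cl, call. = FALSE)
    }
    if (r[1] < bounds[[cl]][1] || r[2] >= bounds[[cl]][2]) {
      stop(
        "class ", cl, " range must lie inside [", bounds[[cl]][1], ", ",
        bounds[[cl]][2], ")", call. = FALSE
      )
    }
    if (is.null(n) || n < 1L) stop("n_genotypes must be >= 1 for class ", cl, call. = FALSE)
  }
  invisible(class_spec)
}

#' Synthetic e-nose experiment configuration
#'
#' Bundles everything the generator needs to emulate a replicated
#' electronic-nose campaign over a panel of oil genotypes: the sensor array,
#' the measurement-cycle schedule, first-order response kinetics, and the
#' noise structure. Defaults emulate the reference campaign: 10 genotypes
#' x 15 replicates = 150 measurements on a 7-sensor array over a 760-s
#' cycle.
#'
#' Noise has three nested levels, all multiplicative (MOS noise scales with
#' signal): `genotype_cv` scatters each genotype's mean response pattern
#' around its class pattern (once per genotype x sensor), `depth_jitter_cv`
#' jitters the response depth per measurement, and `noise_cv` perturbs every
#' resistance sample.
#'
#' @param n_genotypes Number of oil genotypes.
#' @param replicates_per_genotype Replicate measurements per genotype.
#' @param sensors Sensor array descriptor; see [default_sensor_array()].
#' @param schedule A [phase_schedule()].
#' @param class_spec Per-class total ranges and genotype counts; see
#'   [default_class_spec()].
#' @param noise_cv Coefficient of variation of per-sample multiplicative
#'   resistance noise (unitless).
#' @param depth_jitter_cv CV of per-measurement response-depth jitter.
#' @param genotype_cv CV of the per-genotype scatter of response depths
#'   around the class pattern.
#' @param conc_exponent Exponent of the power law linking response depth to
#'   the genotype's key-constituent total (relative to its class's
#'   mid-range total). MOS response grows sublinearly with analyte
#'   concentration; 0.5 is a typical power-law exponent, 0 switches the
#'   coupling off. This makes genotypes near a class boundary respond like
#'   their neighbours across the boundary — the main source of class
#'   overlap.
#' @param tau_rise,tau_recovery First-order time constants (seconds) of the
#'   injection rise and purge recovery, at a response depth of 0.5.
#' @param kinetic_coupling Strength of the depth dependence of the time
#'   constants: the effective constants are
#'   `tau * (1 + kinetic_coupling * (d - 0.5))`, so deeper responses (more
#'   adsorbed analyte) rise and recover more slowly. 0 makes kinetics
#'   depth-independent.
#' @param rng_seed Integer root seed (< 2^31) for all randomness.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_genotypes = 10L,
                             replicates_per_genotype = 15L,
                             sensors = default_sensor_array(),
                             schedule = phase_schedule(),
                             class_spec = default_class_spec(),
                             noise_cv = 0.01,
                             depth_jitter_cv = 0.015,
                             genotype_cv = 0.08,
                             conc_exponent = 0.5,
                             tau_rise = 20,
                             tau_recovery = 80,
                             kinetic_coupling = 0.5,
                             rng_seed = 1L) {
  stopifnot(inherits(schedule, "phase_schedule"))
  if (n_genotypes < 1L || replicates_per_genotype < 1L) {
    stop("n_genotypes and replicates_per_genotype must be >= 1", call. = FALSE)
  }
  if (noise_cv < 0 || depth_jitter_cv < 0 || genotype_cv < 0) {
    stop("noise coefficients of variation must be >= 0", call. = FALSE)
  }
  if (conc_exponent < 0) stop("conc_exponent must be >= 0", call. = FALSE)
  if (tau_rise <= 0 || tau_recovery <= 0) {
    stop("tau_rise and tau_recovery must be > 0", call. = FALSE)
  }
  if (kinetic_coupling < 0 || kinetic_coupling > 2) {
    stop("kinetic_coupling must lie in [0, 2] (positive time constants)", call. = FALSE)
  }
  if (any(sensors$baseline_ohm <= 0)) stop("baseline resistances must be > 0", call. = FALSE)
  validate_class_spec(class_spec)
  n_spec <- sum(vapply(class_spec, function(s) as.integer(s$n_genotypes), integer(1)))
  if (n_spec != n_genotypes) {
    stop("class_spec genotype counts must sum to n_genotypes", call. = FALSE)
  }
  structure(
    list(
      n_genotypes = as.integer(n_genotypes),
      replicates_per_genotype = as.integer(replicates_per_genotype),
      sensors = sensors, schedule = schedule, class_spec = class_spec,
      noise_cv = noise_cv, depth_jitter_cv = depth_jitter_cv,
      genotype_cv = genotype_cv, conc_exponent = conc_exponent,
      tau_rise = tau_rise, tau_recovery = tau_recovery,
      kinetic_coupling = kinetic_coupling,
      rng_seed = as.integer(rng_seed)
    ),
    class = "generator_config"
  )
}

#' Read a generator configuration from YAML
#'
#' Reads the scalar fields of [generator_config()] (and optionally a
#' `schedule` block with the four phase durations) from a YAML file;
#' unspecified fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `generator_config` object.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c(
    "n_genotypes", "replicates_per_genotype", "noise_cv", "depth_jitter_cv",
    "genotype_cv", "conc_exponent", "tau_rise", "tau_recovery",
    "kinetic_coupling", "rng_seed"
  ))]
  if (!is.null(y$schedule)) args$schedule <- do.call(phase_schedule, y$schedule)
  do.call(generator_config, args)
}

#' Generate a GC-MS-style constituent table
#'
#' Draws, per genotype, a six-constituent total within its class's range and
#' splits it over the six key constituents by normalized Gamma proportions
#' (a Dirichlet split), so each column sums exactly to its drawn total. In
#' `"fixture"` mode no random generation happens: the packaged reference
#' panel of ten genotypes is returned verbatim.
#'
#' @param config A [generator_config()].
#' @param class_spec Overrides `config$class_spec` if given.
#' @param mode `"random"` (default) or `"fixture"`.
#' @return A `constituent_table` data frame (six key-constituent rows in
#'   random mode), genotypes ordered g1, g2, ... with C1 genotypes first.
#' @export
generate_constituent_table <- function(config, class_spec = NULL,
                                       mode = c("random", "fixture")) {
  mode <- match.arg(mode)
  if (mode == "fixture") {
    return(rose_constituent_table())
  }
  stopifnot(inherits(config, "generator_config"))
  spec <- validate_class_spec(if (is.null(class_spec)) config$class_spec else class_spec)
  n_total <- sum(vapply(spec, function(s) as.integer(s$n_genotypes), integer(1)))
  keys <- key_constituents()
  with_seed(substream_seed(config$rng_seed, 0L), {
    cols <- list()
    g <- 0L
    for (cl in intersect(quality_classes(), names(spec))) {
      s <- spec[[cl]]
      for (i in seq_len(s$n_genotypes)) {
        g <- g + 1L
        total <- stats::runif(1, s$range[1], s$range[2])
        w <- stats::rgamma(length(keys), shape = 1.5)
        cols[[paste0("g", g)]] <- total * w / sum(w)
      }
    }
    data.frame(constituent = keys, cols, check.names = FALSE)
  })
}

#' Simulate one MOS sensor transient
#'
#' Piecewise first-order response over the three-phase cycle. During
#' baseline the resistance sits at `Ri`. At injection it relaxes
#' exponentially (time constant `tau_rise`) toward the plateau
#' `Rf = Ri * (1 - depth)`, where `depth` in (0,1) is the fractional
#' resistance drop. At purge it relaxes back toward `Ri` with
#' `tau_recovery`. Multiplicative log-normal noise with coefficient of
#' variation `noise_cv` perturbs each sample (mean-one, so `noise_cv = 0`
#' gives the exact closed form).
#'
#' @param class Quality class `"C1"`, `"C2"` or `"C3"`; selects the sensor's
#'   class-mean depth. Ignored when `depth` is given.
#' @param sensor One sensor descriptor: a one-row data frame or list with
#'   `sensor_id`, `baseline_ohm`, and `depth_C1/2/3` (the latter needed only
#'   when `depth` is missing).
#' @param schedule A [phase_schedule()].
#' @param tau_rise,tau_recovery Time constants, seconds.
#' @param noise_cv Per-sample multiplicative noise CV; 0 for a noiseless
#'   curve.
#' @param depth Optional explicit fractional resistance drop in (0,1).
#' @return A `sensor_transient`: list with `sensor_id`, `t` (s), `R` (Ohm),
#'   `schedule`.
#' @export
generate_transient <- function(class = NULL, sensor, schedule = phase_schedule(),
                               tau_rise = 20, tau_recovery = 80,
                               noise_cv = 0, depth = NULL) {
  sensor <- as.list(sensor)
  Ri <- sensor$baseline_ohm
  if (is.null(Ri) || Ri <= 0) stop("sensor baseline resistance must be > 0", call. = FALSE)
  if (is.null(depth)) {
    if (is.null(class) || !class %in% quality_classes()) {
      stop("class must be one of ", paste(quality_classes(), collapse = ", "), call. = FALSE)
    }
    depth <- sensor[[paste0("depth_", class)]]
  }
  if (is.null(depth) || !is.finite(depth) || depth <= 0 || depth >= 1) {
    stop("response depth must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (tau_rise <= 0 || tau_recovery <= 0) stop("time constants must be > 0", call. = FALSE)
  t <- schedule_times(schedule)
  Rf <- Ri * (1 - depth)
  t_inj <- schedule$t_injection_s
  t_pur <- schedule$t_purge_s
  R <- numeric(length(t))
  base <- t < t_inj
  inj <- t >= t_inj & t < t_pur
  rec <- t >= t_pur
  R[base] <- Ri
  R[inj] <- Rf + (Ri - Rf) * exp(-(t[inj] - t_inj) / tau_rise)
  R_purge <- Rf + (Ri - Rf) * exp(-(t_pur - t_inj) / tau_rise)
  R[rec] <- Ri + (R_purge - Ri) * exp(-(t[rec] - t_pur) / tau_recovery)
  if (noise_cv > 0) {
    s <- lognorm_sd(noise_cv)
    R <- R * exp(stats::rnorm(length(R), mean = -s^2 / 2, sd = s))
  }
  structure(
    list(sensor_id = sensor$sensor_id, t = t, R = R, schedule = schedule),
    class = "sensor_transient"
  )
}

#' Generate a full synthetic e-nose dataset
#'
#' Runs the whole simulated campaign: draws a constituent table (or takes
#' the packaged reference panel), labels each genotype by the 10%/50% rule,
#' then simulates `replicates_per_genotype` measurements per genotype, each
#' holding one transient per sensor. Response depths combine the sensor's
#' class-mean depth, a concentration factor
#' `(total_g / class_mid_total)^conc_exponent` tying the response to the
#' genotype's actual key-constituent total, a fixed per-genotype
#' multiplicative scatter (`genotype_cv`) and per-measurement jitter
#' (`depth_jitter_cv`); depths are clamped to (0.02, 0.95).
#'
#' @param config A [generator_config()].
#' @param constituents `"random"` to draw a table, `"fixture"` for the
#'   packaged reference panel (requires the default 10-genotype layout), or
#'   a ready `constituent_table`.
#' @return An `enose_dataset`: list with `measurements` (list of records,
#'   each with `measurement_id`, `genotype`, `transients`), `labels` (data
#'   frame `measurement_id`, `genotype`, `class`), `genotype_labels`,
#'   `constituents`, `config`.
#' @export
generate_dataset <- function(config = generator_config(),
                             constituents = "random") {
  stopifnot(inherits(config, "generator_config"))
  tab <- if (is.data.frame(constituents)) {
    validate_constituent_table(constituents)
  } else {
    generate_constituent_table(config, mode = match.arg(constituents, c("random", "fixture")))
  }
  geno_labels <- label_dataset(tab)
  if (nrow(geno_labels) != config$n_genotypes) {
    stop("constituent table genotype count does not match config", call. = FALSE)
  }
  sensors <- config$sensors
  n_sens <- nrow(sensors)
  # fixed per-genotype scatter of the class response pattern
  sd_g <- lognorm_sd(config$genotype_cv)
  gfac <- matrix(1, nrow = config$n_genotypes, ncol = n_sens)
  for (g in seq_len(config$n_genotypes)) {
    gfac[g, ] <- with_seed(
      substream_seed(config$rng_seed, g),
      exp(stats::rnorm(n_sens, mean = 0, sd = sd_g))
    )
  }
  # concentration factor: genotypes with key-constituent totals above/below
  # their class's geometric mid-range respond more/less strongly
  class_mid <- vapply(config$class_spec, function(s) {
    sqrt(max(s$range[1], 0.5) * s$range[2])
  }, numeric(1))
  conc <- rep(1, config$n_genotypes)
  if (config$conc_exponent > 0) {
    mid <- class_mid[as.character(geno_labels$class)]
    conc <- (geno_labels$total_percent / mid)^config$conc_exponent
  }
  sd_j <- lognorm_sd(config$depth_jitter_cv)
  n_meas <- config$n_genotypes * config$replicates_per_genotype
  id_width <- max(3L, nchar(as.character(n_meas)))
  measurements <- vector("list", n_meas)
  labels <- data.frame(
    measurement_id = character(n_meas), genotype = character(n_meas),
    class = character(n_meas)
  )
  m <- 0L
  for (g in seq_len(config$n_genotypes)) {
    cls <- as.character(geno_labels$class[g])
    depth_cols <- paste0("depth_", cls)
    for (rep_i in seq_len(config$replicates_per_genotype)) {
      m <- m + 1L
      mid <- sprintf(paste0("m%0", id_width, "d"), m)
      trans <- with_seed(substream_seed(config$rng_seed, 1000L + m), {
        out <- vector("list", n_sens)
        for (s in seq_len(n_sens)) {
          d0 <- sensors[[depth_cols]][s] * conc[g] * gfac[g, s]
          d <- d0 * if (sd_j > 0) exp(stats::rnorm(1, 0, sd_j)) else 1
          d <- min(max(d, 0.02), 0.95)
          # deeper responses (more adsorbed analyte) have slower kinetics
          kin <- 1 + config$kinetic_coupling * (d - 0.5)
          out[[s]] <- generate_transient(
            sensor = sensors[s, ], schedule = config$schedule,
            tau_rise = config$tau_rise * kin,
            tau_recovery = config$tau_recovery * kin,
            noise_cv = config$noise_cv, depth = d
          )
        }
        names(out) <- sensors$sensor_id
        out
      })
      measurements[[m]] <- list(
        measurement_id = mid, genotype = geno_labels$genotype[g],
        transients = trans
      )
      labels$measurement_id[m] <- mid
      labels$genotype[m] <- geno_labels$genotype[g]
      labels$class[m] <- cls
    }
  }
  labels$class <- factor(labels$class, levels = quality_classes())
  names(measurements) <- labels$measurement_id
  structure(
    list(
      measurements = measurements, labels = labels,
      genotype_labels = geno_labels, constituents = tab, config = config
    ),
    class = "enose_dataset"
  )
}

#' @export
print.enose_dataset <- function(x, ...) {
  cat(sprintf(
    "<enose_dataset> %d measurements (%d genotypes x %d replicates), %d sensors\n",
    length(x$measurements), x$config$n_genotypes,
    x$config$replicates_per_genotype, nrow(x$config$sensors)
  ))
  print(table(x$labels$class))
  invisible(x)
}

#' Write / read an e-nose dataset as CSV
#'
#' `write_enose_csv()` writes three plain CSVs into `dir`:
#' `measurements.csv` (long format: `measurement_id`, `sensor_id`, `t_s`,
#' `resistance_ohm`), `labels.csv` (`measurement_id`, `genotype`, `class`)
#' and `constituents.csv`. `read_enose_csv()` reads them back; the schedule
#' is not stored in the CSVs and must be supplied.
#'
#' @param dataset An `enose_dataset` (or, for reading, the directory).
#' @param dir Output/input directory; created if missing.
#' @param schedule The [phase_schedule()] the measurements were sampled on.
#' @return `write_enose_csv()` returns `dir` invisibly; `read_enose_csv()`
#'   returns an `enose_dataset` (without generator config).
#' @export
write_enose_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "enose_dataset") || is.list(dataset))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- do.call(rbind, lapply(dataset$measurements, function(m) {
    do.call(rbind, lapply(m$transients, function(tr) {
      data.frame(
        measurement_id = m$measurement_id, sensor_id = tr$sensor_id,
        t_s = tr$t, resistance_ohm = tr$R
      )
    }))
  }))
  utils::write.csv(long, file.path(dir, "measurements.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$labels, file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$constituents, file.path(dir, "constituents.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_enose_csv
#' @export
read_enose_csv <- function(dir, schedule = phase_schedule()) {
  long <- utils::read.csv(file.path(dir, "measurements.csv"))
  labels <- utils::read.csv(file.path(dir, "labels.csv"))
  labels$class <- factor(labels$class, levels = quality_classes())
  tab <- read_constituent_table(file.path(dir, "constituents.csv"))
  measurements <- lapply(seq_len(nrow(labels)), function(i) {
    mid <- labels$measurement_id[i]
    sub <- long[long$measurement_id == mid, ]
    trans <- lapply(split(sub, sub$sensor_id), function(d) {
      d <- d[order(d$t_s), ]
      structure(
        list(sensor_id = d$sensor_id[1], t = d$t_s, R = d$resistance_ohm, schedule = schedule),
        class = "sensor_transient"
      )
    })
    list(measurement_id = mid, genotype = labels$genotype[i], transients = trans)
  })
  names(measurements) <- labels$measurement_id
  structure(
    list(
      measurements = measurements, labels = labels,
      genotype_labels = NULL, constituents = tab, config = NULL
    ),
    class = "enose_dataset"
  )
}
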