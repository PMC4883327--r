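#' Measurement-cycle phase schedule
#'
#' One electronic-nose measurement cycle has three phases: baseline (clean
#' dry air, sensors at rest), injection (sample headspace reaches the sensor
#' chamber and resistance drops), and recovery (chamber purged, resistance
#' relaxes back to baseline). The default schedule is 60 s / 200 s / 500 s,
#' a 760 s cycle sampled at 1 Hz.
#'
#' @param baseline_s,injection_s,recovery_s Phase durations in seconds.
#' @param sample_period_s Sampling period of the acquisition in seconds;
#'   must divide each phase duration to within one sample.
#' @return A `phase_schedule` object (list with the four durations and the
#'   derived `total_s`, `t_injection_s` and `t_purge_s` phase boundaries).
#' @examples
#' phase_schedule()
#' @export
phase_schedule <- function(baseline_s = 60, injection_s = 200, recovery_s = 500,
                           sample_period_s = 1) {
  durs <- c(baseline_s, injection_s, recovery_s, sample_period_s)
  if (!all(is.finite(durs)) || any(durs <= 0)) {
    stop("all schedule durations must be positive and finite", call. = FALSE)
  }
  for (d in c(baseline_s, injection_s, recovery_s)) {
    k <- d / sample_period_s
    if (abs(k - round(k)) > 1) {
      stop("sample_period_s must divide each phase to within one sample", call. = FALSE)
    }
  }
  structure(
    list(
      baseline_s = baseline_s, injection_s = injection_s,
      recovery_s = recovery_s, sample_period_s = sample_period_s,
      total_s = baseline_s + injection_s + recovery_s,
      t_injection_s = baseline_s,
      t_purge_s = baseline_s + injection_s
    ),
    class = "phase_schedule"
  )
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf(
    "<phase_schedule> baseline %gs | injection %gs | recovery %gs (total %gs, dt = %gs)\n",
    x$baseline_s, x$injection_s, x$recovery_s, x$total_s, x$sample_period_s
  ))
  invisible(x)
}

#' Time grid of a schedule
#'
#' Sample times covering one full cycle: `0, dt, ..., total - dt`.
#' @param schedule A [phase_schedule()].
#' @return Numeric vector of sample times in seconds.
#' @export
schedule_times <- function(schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  seq(0, schedule$total_s - schedule$sample_period_s,
    by = schedule$sample_period_s
  )
}
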