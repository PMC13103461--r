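# Streaming landmark capture.
#
# A landmark is recorded by holding the tracked pointer still: n_samples
# probe-tip points are collected at rate_hz and averaged. If any point lands
# more than max_step_mm from its predecessor (a slipping probe), the series
# is discarded and restarted, so a trembling hand is averaged out while a
# slip is detected reliably. Tip points are already expressed in the
# reference-sensor frame, so head motion during capture cancels by
# construction.

#' Acquisition configuration
#'
#' @param n_samples Samples per accepted series (default 60).
#' @param rate_hz Sampling rate in Hz (default 40, one sample every 25 ms).
#' @param max_step_mm Restart threshold on the Euclidean distance between
#'   consecutive raw samples (default 0.5 mm).
#' @param max_restarts Maximum number of discarded series before the capture
#'   is declared unstable (default `Inf`).
#' @param restart_seeds_series If `TRUE` (default) the sample that violated
#'   the threshold becomes the first sample of the new series, modelling a
#'   probe that slipped to a new stable position; if `FALSE` it is dropped.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(n_samples = 60L, rate_hz = 40, max_step_mm = 0.5,
                               max_restarts = Inf, restart_seeds_series = TRUE) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L)
    emnav_stop("emnav_schema_error", "n_samples must be >= 2")
  if (max_step_mm <= 0)
    emnav_stop("emnav_schema_error", "max_step_mm must be > 0")
  if (rate_hz <= 0)
    emnav_stop("emnav_schema_error", "rate_hz must be > 0")
  structure(list(n_samples = n_samples, rate_hz = rate_hz,
                 max_step_mm = max_step_mm, max_restarts = max_restarts,
                 restart_seeds_series = restart_seeds_series),
            class = "acquisition_config")
}

#' Acquire one landmark from a probe-tip point stream
#'
#' Scans the stream for the first contiguous run of `n_samples` points in
#' which every consecutive pair is at most `max_step_mm` apart, and returns
#' the arithmetic mean of that run. Each threshold violation discards the
#' series collected so far and (by default) starts the next series at the
#' violating sample. Deterministic: a fixed stream always yields the same
#' result.
#'
#' @param stream n x 3 matrix of probe-tip points in the reference frame, mm,
#'   in arrival order.
#' @param config An [acquisition_config()].
#' @return An object of class `acquisition_result`: `mean_point` (mm),
#'   `samples_used`, `restarts`, `duration_s` (samples consumed / rate).
#' @examples
#' pts <- matrix(rep(c(12, -3, 40), each = 60), ncol = 3)
#' acquire_landmark(pts, acquisition_config())
#' @export
acquire_landmark <- function(stream, config = acquisition_config()) {
  if (!inherits(config, "acquisition_config"))
    emnav_stop("emnav_schema_error", "'config' must be an acquisition_config")
  stream <- as_points(stream, "stream")
  n <- nrow(stream)
  restarts <- 0L
  series_start <- 1L
  i <- 1L
  while (i <= n) {
    if (i > series_start &&
        sqrt(sum((stream[i, ] - stream[i - 1L, ])^2)) > config$max_step_mm) {
      restarts <- restarts + 1L
      if (restarts > config$max_restarts)
        emnav_stop("emnav_instability_error", sprintf(
          "acquisition restarted more than %s times", config$max_restarts),
          data = list(restarts = restarts))
      series_start <- if (config$restart_seeds_series) i else i + 1L
    }
    if (i - series_start + 1L == config$n_samples) {
      run <- stream[series_start:i, , drop = FALSE]
      return(structure(list(
        mean_point = colMeans(run),
        samples_used = config$n_samples,
        restarts = restarts,
        duration_s = i / config$rate_hz), class = "acquisition_result"))
    }
    i <- i + 1L
  }
  emnav_stop("emnav_acquisition_error", sprintf(
    "stream exhausted after %d samples without a stable series of %d",
    n, config$n_samples), data = list(restarts = restarts))
}

#' @export
print.acquisition_result <- function(x, ...) {
  cat(sprintf("acquisition_result: mean (%.3f, %.3f, %.3f) mm, %d samples, %d restart(s), %.2f s\n",
              x$mean_point[1], x$mean_point[2], x$mean_point[3],
              x$samples_used, x$restarts, x$duration_s))
  invisible(x)
}

#' Probe-tip position in the reference-sensor frame
#'
#' Expresses the tracked pointer's tip in the reference frame: the probe pose
#' is first taken relative to the reference sensor, then the calibrated tip
#' offset (given in the probe sensor frame) is applied.
#'
#' @param probe_pose,reference `pose_sample` objects in the tracker frame.
#' @param tip_offset Length-3 tip offset in the probe sensor frame, mm.
#' @param tol_s Timestamp synchronization tolerance, seconds.
#' @return Length-3 tip position in the reference-sensor frame, mm.
#' @export
probe_tip_point <- function(probe_pose, reference, tip_offset = c(0, 0, 0),
                            tol_s = 0.005) {
  rel <- relative_pose(probe_pose, reference, tol_s = tol_s)
  rt_apply(rel, as.numeric(tip_offset))
}
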