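#' Frame-sampled position-time trace
#'
#' The common currency of the analysis pipeline: one particle's position
#' sampled at a uniform camera frame interval, whether it came from a
#' frame-averaged simulation, the synthetic generator, or an imported
#' tracking file.
#'
#' @param positions Numeric vector of positions (nm), one per frame,
#'   plus-end positive. At least 2 finite values.
#' @param frame_dt Frame interval (s), default 0.286 (3.5 frames/s).
#' @param origin One of `"simulated"`, `"synthetic"`, `"imported"`.
#' @return An object of class `sampled_trace` with fields `positions`,
#'   `frame_dt`, `total_duration` (span between first and last frame, s)
#'   and `origin`.
#' @export
sampled_trace <- function(positions, frame_dt = 0.286,
                          origin = c("imported", "simulated", "synthetic")) {
  origin <- match.arg(origin)
  positions <- as.numeric(positions)
  if (length(positions) < 2L) stop("a trace needs at least 2 frames")
  if (any(!is.finite(positions))) stop("positions must be finite")
  if (!is.numeric(frame_dt) || frame_dt <= 0) stop("`frame_dt` must be > 0")
  structure(list(positions = positions, frame_dt = frame_dt,
                 total_duration = (length(positions) - 1L) * frame_dt,
                 origin = origin),
            class = "sampled_trace")
}

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf("<sampled_trace> %d frames @ %g s (%s), %.1f s, net %.0f nm\n",
              length(x$positions), x$frame_dt, x$origin,
              x$total_duration,
              x$positions[length(x$positions)] - x$positions[1]))
  invisible(x)
}

#' Average a simulated trajectory into camera frames
#'
#' Converts the event-resolved, piecewise-constant cargo path of a
#' [simulate_pair()] trajectory into a frame-sampled trace: frame `k`
#' holds the time-weighted mean cargo position over
#' `[k * frame_dt, (k + 1) * frame_dt)`, emulating camera exposure
#' averaging at the acquisition frame rate (0.286 s frames for the
#' reference protocol). A trailing partial frame is discarded.
#'
#' @param traj A `motor_trajectory`.
#' @param frame_dt Frame interval (s).
#' @return A [sampled_trace] with origin `"simulated"`. The stored
#'   positions are frame means; frame `k`'s value is stamped at the
#'   frame start for windowing purposes.
#' @export
frame_average <- function(traj, frame_dt = 0.286) {
  stopifnot(inherits(traj, "motor_trajectory"))
  if (frame_dt <= 0) stop("`frame_dt` must be > 0")
  times <- traj$times
  cargo <- traj$cargo
  n <- length(times)
  t_end <- times[n]
  n_frames <- floor(t_end / frame_dt + 1e-9)
  if (n_frames < 1) stop("trajectory shorter than one frame")
  if (n_frames < 2) stop("trajectory shorter than two frames")
  # cumulative integral of the piecewise-constant cargo path; the cargo
  # value at the final event (possibly NA after double detachment) is
  # never integrated over
  cum <- c(0, cumsum(cargo[-n] * diff(times)))
  bounds <- pmin((0:n_frames) * frame_dt, t_end)
  idx <- pmin(pmax(findInterval(bounds, times, rightmost.closed = TRUE),
                   1L), n - 1L)
  cum_b <- cum[idx] + cargo[idx] * (bounds - times[idx])
  frames <- diff(cum_b) / frame_dt
  sampled_trace(frames, frame_dt, origin = "simulated")
}

#' Instantaneous velocities over fixed windows
#'
#' Splits a trace into non-overlapping windows of approximately `window`
#' seconds (`round(window / frame_dt)` frames; 3 frames, i.e. 0.858 s,
#' for a 1 s window at 0.286 s frames) and reports the end-to-end
#' displacement of each window divided by its actual time span, which
#' removes the quantisation bias of the frame grid. A trailing partial
#' window is discarded.
#'
#' @param trace A [sampled_trace].
#' @param window Window length (s), default 1.
#' @return Numeric vector of window velocities (nm/s); empty if the
#'   trace is shorter than one window.
#' @export
instantaneous_velocities <- function(trace, window = 1) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (window <= 0) stop("`window` must be > 0")
  nf <- max(1L, as.integer(round(window / trace$frame_dt)))
  pos <- trace$positions
  n_win <- (length(pos) - 1L) %/% nf
  if (n_win < 1L) return(numeric(0))
  ends <- 1L + nf * (0:n_win)
  diff(pos[ends]) / (nf * trace$frame_dt)
}

#' Whole-trace velocity
#'
#' Net displacement over total duration: positive velocities are
#' kinesin-dominated (plus-end) motility, negative are DDB-dominated.
#'
#' @param trace A [sampled_trace].
#' @return Velocity (nm/s).
#' @export
trace_velocity <- function(trace) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (trace$total_duration <= 0) stop("trace has zero duration")
  pos <- trace$positions
  (pos[length(pos)] - pos[1]) / trace$total_duration
}

#' Fast/slow trace classification
#'
#' Splits motor-pair traces into the fast plus-end population (kinesin
#' walking with DDB weakly bound or detached) and the slow population
#' (both motors engaged), by thresholding the trace velocity. The
#' reference thresholds are 250 nm/s for DDB-Kin1/3 pairs and 125 nm/s
#' for DDB-Kin2, chosen where the two trace-velocity peaks separate.
#' Classification is strict: a trace exactly at the threshold is slow.
#'
#' @param trace_vel Trace velocity or vector of velocities (nm/s).
#' @param threshold Velocity threshold (nm/s), > 0.
#' @return Factor with levels `"slow"`, `"fast"`.
#' @export
classify_fast_slow <- function(trace_vel, threshold = 250) {
  if (threshold <= 0) stop("`threshold` must be > 0")
  factor(ifelse(trace_vel > threshold, "fast", "slow"),
         levels = c("slow", "fast"))
}

#' Mode of a velocity distribution
#'
#' Location of the maximum of a Gaussian kernel-density estimate of the
#' pooled velocity sample, evaluated on a fine grid; used to report the
#' peak of instantaneous-velocity distributions. The KDE bandwidth is
#' `bin_width` (the histogram bin that the density replaces); the
#' default `NULL` uses Silverman's rule-of-thumb ([stats::bw.nrd0()]),
#' which adapts to the spread of the sample. With
#' `method = "histogram"` the centre of the fullest bin is returned
#' instead (then `bin_width` defaults to 10 nm/s).
#'
#' @param velocities Numeric vector (nm/s); at least one finite value.
#' @param bin_width Kernel bandwidth / histogram bin width (nm/s), or
#'   `NULL` for the data-driven default.
#' @param method `"kde"` (default) or `"histogram"`.
#' @return Peak location (nm/s).
#' @export
distribution_peak <- function(velocities, bin_width = NULL,
                              method = c("kde", "histogram")) {
  method <- match.arg(method)
  velocities <- velocities[is.finite(velocities)]
  if (length(velocities) == 0L) stop("no finite velocities")
  if (length(unique(velocities)) == 1L) return(velocities[1])
  if (is.null(bin_width)) {
    bin_width <- if (method == "kde") stats::bw.nrd0(velocities) else 10
  }
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  if (method == "kde") {
    d <- stats::density(velocities, bw = bin_width, n = 4096)
    d$x[which.max(d$y)]
  } else {
    rng <- range(velocities)
    breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                  ceiling(rng[2] / bin_width) * bin_width + bin_width,
                  by = bin_width)
    h <- graphics::hist(velocities, breaks = breaks, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
}
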