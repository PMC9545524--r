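#' Specification for a synthetic piecewise-linear trace
#'
#' Describes the latent motion and the imaging model of one synthetic
#' particle trace: a plan of constant-velocity segments, the camera
#' frame interval, the pixel size, and i.i.d. Gaussian localisation
#' noise per frame. Defaults emulate the reference TIRF acquisition:
#' 3.5 frames/s (0.286 s frames) for up to 100 s, 73 nm pixels, and a
#' 20 nm localisation error (a typical figure for single-particle
#' tracking of this kind; the tracking precision itself is a knob, not
#' a measured constant).
#'
#' @param plan Data frame (or 2-column matrix) with columns `velocity`
#'   (nm/s) and `duration` (s), one row per latent segment.
#' @param frame_dt Frame interval (s).
#' @param pixel Pixel size (nm).
#' @param noise_sigma Localisation noise s.d. (nm).
#' @param max_duration Imaging window (s); the plan is truncated here.
#' @return An object of class `trace_spec`.
#' @export
trace_spec <- function(plan, frame_dt = 0.286, pixel = 73,
                       noise_sigma = 20, max_duration = 100) {
  plan <- as.data.frame(plan)
  if (nrow(plan) == 0L) stop("`plan` must have at least one segment")
  if (!all(c("velocity", "duration") %in% names(plan))) {
    names(plan)[1:2] <- c("velocity", "duration")
  }
  if (any(plan$duration <= 0)) stop("segment durations must be > 0")
  if (frame_dt <= 0 || pixel <= 0 || max_duration <= 0) {
    stop("`frame_dt`, `pixel` and `max_duration` must be > 0")
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  structure(list(plan = plan[, c("velocity", "duration")],
                 frame_dt = frame_dt, pixel = pixel,
                 noise_sigma = noise_sigma, max_duration = max_duration),
            class = "trace_spec")
}

# Sample a piecewise-linear latent path at the frame grid and add noise.
sample_plan <- function(plan, frame_dt, noise_sigma, max_duration) {
  total <- min(sum(plan$duration), max_duration)
  knots_t <- c(0, cumsum(plan$duration))
  knots_x <- c(0, cumsum(plan$velocity * plan$duration))
  n_frames <- floor(total / frame_dt + 1e-9) + 1L
  t_frames <- (seq_len(n_frames) - 1L) * frame_dt
  latent <- stats::approx(knots_t, knots_x, xout = t_frames,
                          rule = 2)$y
  latent + stats::rnorm(n_frames, sd = noise_sigma)
}

plan_truth <- function(plan, frame_dt, pixel, max_duration) {
  t0 <- c(0, cumsum(plan$duration)[-nrow(plan)])
  t1 <- pmin(cumsum(plan$duration), max_duration)
  keep <- t1 > t0
  plan <- plan[keep, , drop = FALSE]
  t0 <- t0[keep]; t1 <- t1[keep]
  dur <- t1 - t0
  disp <- plan$velocity * dur
  # frame k sits at (k - 1) * frame_dt; a boundary exactly on the grid
  # sends that frame to the following segment
  end_frame <- pmax(floor(t1 / frame_dt - 1e-9) + 1L, 1L)
  data.frame(velocity = plan$velocity, duration = dur,
             start_time = t0, end_time = t1,
             start_frame = c(1L, utils::head(end_frame, -1L) + 1L),
             end_frame = end_frame,
             displacement = disp,
             state = classify_segment(disp, pixel))
}

#' Generate a synthetic trace from a segment plan
#'
#' Builds the piecewise-linear latent path described by the spec's
#' segment plan, samples it at the camera frame grid, adds Gaussian
#' localisation noise, and returns both the trace and the ground-truth
#' segmentation in analysis-ready form. Uses R's global random number
#' stream; seed with [set.seed()].
#'
#' @param spec A [trace_spec].
#' @return List with `trace` (a [sampled_trace], origin `"synthetic"`)
#'   and `truth` (data frame of latent segments with velocities,
#'   durations, frame ranges and pause/plus/minus states).
#' @examples
#' set.seed(1)
#' g <- gen_segmented_trace(trace_spec(data.frame(
#'   velocity = c(0, 200), duration = c(10, 10)), noise_sigma = 0))
#' trace_velocity(g$trace)
#' @export
gen_segmented_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  pos <- sample_plan(spec$plan, spec$frame_dt, spec$noise_sigma,
                     spec$max_duration)
  list(trace = sampled_trace(pos, spec$frame_dt, origin = "synthetic"),
       truth = plan_truth(spec$plan, spec$frame_dt, spec$pixel,
                          spec$max_duration))
}

#' Two-state (processive/stuck) DDB motility model
#'
#' Parameters of a continuous-time alternating renewal model of DDB
#' motility: exponentially distributed sojourns in a processive state
#' (velocity drawn once per sojourn from a normal distribution) and a
#' stuck state (velocity 0). The long-run stuck-time fraction of such a
#' model is `stuck_dwell_mean / (stuck_dwell_mean + proc_dwell_mean)`,
#' so the processive dwell mean is derived from the target stuck
#' fraction unless given explicitly.
#'
#' Defaults emulate DDB's own motility: processive sojourns at the
#' unloaded DDB speed (-360 nm/s, minus-end), a 26% stuck-time fraction
#' and a 2.8 s mean stuck (pause) duration -- the processive/stuck
#' alternation describes DDB stepping, while near-zero net pair
#' velocities arise from the tug-of-war, not from slow DDB sojourns.
#'
#' A third, diffusive state (zero drift, Brownian wiggle) can be
#' enabled via `diffusive`; it is off by default because the
#' trace-analysis pipeline classifies only pause/plus/minus.
#'
#' @param v_mean,v_sd Mean and s.d. of per-sojourn processive velocity
#'   (nm/s; minus-end negative).
#' @param stuck_dwell_mean Mean stuck dwell (s).
#' @param stuck_fraction Target long-run fraction of time stuck.
#' @param proc_dwell_mean Mean processive dwell (s); overrides
#'   `stuck_fraction` when given.
#' @param diffusive `NULL` (default) or
#'   `list(prob = , dwell_mean = , D = )`: probability that a break in
#'   processive motion is diffusive rather than stuck, its mean dwell
#'   (s) and diffusion coefficient (nm^2/s).
#' @return An object of class `ddb_state_model`.
#' @export
ddb_state_model <- function(v_mean = -360, v_sd = 50,
                            stuck_dwell_mean = 2.8,
                            stuck_fraction = 0.26,
                            proc_dwell_mean = NULL,
                            diffusive = NULL) {
  if (stuck_dwell_mean <= 0) stop("`stuck_dwell_mean` must be > 0")
  if (is.null(proc_dwell_mean)) {
    if (stuck_fraction < 0 || stuck_fraction >= 1) {
      stop("`stuck_fraction` must be in [0, 1)")
    }
    # stuck_fraction = 0 gives an infinite processive dwell: no pauses
    proc_dwell_mean <- if (stuck_fraction == 0) Inf else
      stuck_dwell_mean * (1 - stuck_fraction) / stuck_fraction
  }
  if (proc_dwell_mean <= 0) stop("`proc_dwell_mean` must be > 0")
  stuck_fraction <- stuck_dwell_mean / (stuck_dwell_mean + proc_dwell_mean)
  if (!is.null(diffusive)) {
    stopifnot(is.list(diffusive),
              all(c("prob", "dwell_mean", "D") %in% names(diffusive)))
  }
  structure(list(v_mean = v_mean, v_sd = v_sd,
                 stuck_dwell_mean = stuck_dwell_mean,
                 proc_dwell_mean = proc_dwell_mean,
                 stuck_fraction = stuck_fraction,
                 diffusive = diffusive),
            class = "ddb_state_model")
}

#' Generate a synthetic DDB-style state-switching trace
#'
#' Simulates the alternating processive/stuck renewal process of a
#' [ddb_state_model()] for `duration` seconds, samples the resulting
#' piecewise-linear path at the camera frame grid and adds localisation
#' noise. Uses R's global random number stream; seed with [set.seed()].
#'
#' @param model A [ddb_state_model].
#' @param duration Trace duration (s).
#' @param frame_dt Frame interval (s).
#' @param noise_sigma Localisation noise s.d. (nm).
#' @param pixel Pixel size (nm) used to classify truth segments.
#' @return List with `trace` (a [sampled_trace]) and `truth` (the latent
#'   state plan: per-sojourn state, velocity, duration, frame range).
#' @export
gen_ddb_state_trace <- function(model, duration = 100, frame_dt = 0.286,
                                noise_sigma = 20, pixel = 73) {
  stopifnot(inherits(model, "ddb_state_model"))
  if (duration <= 0) stop("`duration` must be > 0")
  t_acc <- 0
  vel <- numeric(0)
  dur <- numeric(0)
  state <- character(0)
  diffusing <- logical(0)
  # start in a state drawn with the stationary time fractions
  in_proc <- stats::runif(1) > model$stuck_fraction
  while (t_acc < duration) {
    if (in_proc) {
      d <- if (is.finite(model$proc_dwell_mean)) {
        stats::rexp(1, 1 / model$proc_dwell_mean)
      } else {
        Inf
      }
      v <- stats::rnorm(1, model$v_mean, model$v_sd)
      state <- c(state, "processive")
      diffusing <- c(diffusing, FALSE)
    } else {
      is_diff <- !is.null(model$diffusive) &&
        stats::runif(1) < model$diffusive$prob
      if (is_diff) {
        d <- stats::rexp(1, 1 / model$diffusive$dwell_mean)
        state <- c(state, "diffusive")
      } else {
        d <- stats::rexp(1, 1 / model$stuck_dwell_mean)
        state <- c(state, "stuck")
      }
      diffusing <- c(diffusing, is_diff)
      v <- 0
    }
    d <- min(d, duration - t_acc + 1)  # keep the plan finite
    vel <- c(vel, v)
    dur <- c(dur, d)
    t_acc <- t_acc + d
    in_proc <- !in_proc
  }
  plan <- data.frame(velocity = vel, duration = dur)
  pos <- sample_plan(plan, frame_dt, noise_sigma, duration)
  if (any(diffusing)) {
    # add Brownian wiggle on diffusive sojourns
    t_frames <- (seq_along(pos) - 1) * frame_dt
    t0 <- c(0, cumsum(dur))[-(length(dur) + 1)]
    t1 <- cumsum(dur)
    for (i in which(diffusing)) {
      in_seg <- t_frames >= t0[i] & t_frames < t1[i]
      nseg <- sum(in_seg)
      if (nseg > 0) {
        step_sd <- sqrt(2 * model$diffusive$D * frame_dt)
        pos[in_seg] <- pos[in_seg] + cumsum(stats::rnorm(nseg, 0, step_sd))
      }
    }
  }
  truth <- plan_truth(plan, frame_dt, pixel, duration)
  truth$state_label <- state[seq_len(nrow(truth))]
  list(trace = sampled_trace(pos, frame_dt, origin = "synthetic"),
       truth = truth)
}

#' Configuration for a synthetic trace population
#'
#' Mixture of "fast" traces (kinesin walking at near-unloaded speed,
#' short durations) and "slow" traces (both motors engaged: near-zero
#' net velocity with DDB-style pauses, long durations), emulating the
#' two-population structure of motor-pair trace velocities. Defaults
#' emulate the DDB-Kin1 condition: 52% fast traces, fast velocities
#' near the lightly loaded Kin1 speed, slow-trace durations with a
#' 22 s exponential mean, and a 100 s imaging window that censors
#' longer traces.
#'
#' @param n_traces Number of traces.
#' @param fast_fraction Mixture weight of the fast population.
#' @param fast_v_mean,fast_v_sd Fast-trace velocity distribution (nm/s).
#' @param fast_dur_mean Mean fast-trace duration (s).
#' @param slow_dur_mean Mean slow-trace duration (s).
#' @param slow_model [ddb_state_model()] for the slow traces.
#' @param frame_dt,pixel,noise_sigma,max_duration Imaging model, as in
#'   [trace_spec()].
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_traces = 100, fast_fraction = 0.52,
                              fast_v_mean = 504, fast_v_sd = 80,
                              fast_dur_mean = 3, slow_dur_mean = 22,
                              slow_model = ddb_state_model(),
                              frame_dt = 0.286, pixel = 73,
                              noise_sigma = 20, max_duration = 100) {
  if (fast_fraction < 0 || fast_fraction > 1) {
    stop("`fast_fraction` must be in [0, 1]")
  }
  structure(list(n_traces = n_traces, fast_fraction = fast_fraction,
                 fast_v_mean = fast_v_mean, fast_v_sd = fast_v_sd,
                 fast_dur_mean = fast_dur_mean,
                 slow_dur_mean = slow_dur_mean, slow_model = slow_model,
                 frame_dt = frame_dt, pixel = pixel,
                 noise_sigma = noise_sigma, max_duration = max_duration),
            class = "population_config")
}

#' Generate a synthetic two-population trace set
#'
#' Draws per-trace labels from the fast/slow mixture, generates each
#' trace accordingly, and returns the traces together with a truth
#' table. Durations are exponential with the configured means,
#' truncated (and flagged as censored) at the imaging window. Uses R's
#' global random number stream; seed with [set.seed()].
#'
#' @param config A [population_config()].
#' @return List with `traces` (list of [sampled_trace]) and `truth`
#'   (data frame: `trace_id`, `label`, `duration`, `censored`,
#'   `true_velocity`).
#' @export
gen_population <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_traces
  min_dur <- 3 * config$frame_dt
  labels <- ifelse(stats::runif(n) < config$fast_fraction,
                   "fast", "slow")
  traces <- vector("list", n)
  dur_out <- vel_out <- numeric(n)
  censored <- logical(n)
  for (i in seq_len(n)) {
    if (labels[i] == "fast") {
      d <- stats::rexp(1, 1 / config$fast_dur_mean)
      v <- stats::rnorm(1, config$fast_v_mean, config$fast_v_sd)
      d <- max(d, min_dur)
      censored[i] <- d > config$max_duration
      d <- min(d, config$max_duration)
      spec <- trace_spec(data.frame(velocity = v, duration = d),
                         frame_dt = config$frame_dt,
                         pixel = config$pixel,
                         noise_sigma = config$noise_sigma,
                         max_duration = config$max_duration)
      traces[[i]] <- gen_segmented_trace(spec)$trace
      vel_out[i] <- v
    } else {
      d <- stats::rexp(1, 1 / config$slow_dur_mean)
      d <- max(d, min_dur)
      censored[i] <- d > config$max_duration
      d <- min(d, config$max_duration)
      g <- gen_ddb_state_trace(config$slow_model, duration = d,
                               frame_dt = config$frame_dt,
                               noise_sigma = config$noise_sigma,
                               pixel = config$pixel)
      traces[[i]] <- g$trace
      vel_out[i] <- sum(g$truth$displacement) / sum(g$truth$duration)
    }
    dur_out[i] <- d
  }
  list(traces = traces,
       truth = data.frame(trace_id = seq_len(n), label = labels,
                          duration = dur_out, censored = censored,
                          true_velocity = vel_out))
}
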