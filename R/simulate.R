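params_vec <- function(p) {
  c(p$direction, p$step_size, p$k_forward0, p$k_backstep, p$k_detach0,
    p$f_detach, p$k_reattach, p$f_stall, p$stiffness,
    as.numeric(identical(p$superstall, "clamp")))
}

new_trajectory <- function(raw, params_k, params_d, t_max) {
  ev <- factor(EVENT_LABELS[raw$event], levels = EVENT_LABELS)
  structure(
    list(times = raw$times, pos_k = raw$pos_k, pos_d = raw$pos_d,
         cargo = raw$cargo,
         attached_k = as.logical(raw$attached_k),
         attached_d = as.logical(raw$attached_d),
         events = ev, t_max = t_max,
         terminated_early = isTRUE(raw$terminated_early),
         truncated = isTRUE(raw$truncated),
         params_k = params_k, params_d = params_d),
    class = "motor_trajectory")
}

#' Simulate one kinesin-DDB run (Gillespie SSA)
#'
#' Event-driven simulation of the coupled pair: starting from both motors
#' attached at position 0 (configurable), events (forward step, backstep,
#' detachment, reattachment, for each motor) are drawn by the exact
#' stochastic simulation algorithm with rates re-evaluated after every
#' event, until the clock exceeds `t_max` or both motors are detached.
#'
#' Two engines produce bitwise-identical trajectories for the same seed:
#' a compiled one (default) and a plain-R reference built directly from
#' [event_rates()], [draw_event()] and [apply_event()], kept for
#' cross-validation and readability.
#'
#' @param params_k,params_d [motor_params] for kinesin and DDB.
#' @param t_max Maximum recorded time (s); the reference protocol records
#'   50 s per run.
#' @param seed Optional integer seed applied via [set.seed()] before the
#'   run; `NULL` uses the current RNG state.
#' @param attached Logical length-2: initial attachment of (kinesin,
#'   DDB). Setting one motor detached with `k_reattach = 0` simulates a
#'   single motor.
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference).
#' @param max_events Safety cap on stored events.
#' @return A `motor_trajectory`: event times, motor and cargo positions,
#'   attachment flags, event labels, and termination flags.
#' @examples
#' tr <- simulate_pair(motor_presets("Kin1"), motor_presets("DDB"),
#'                     t_max = 5, seed = 1)
#' tr
#' @export
simulate_pair <- function(params_k, params_d, t_max = 50, seed = NULL,
                          attached = c(TRUE, TRUE),
                          engine = c("cpp", "R"), max_events = 500000L) {
  stopifnot(inherits(params_k, "motor_params"),
            inherits(params_d, "motor_params"))
  if (t_max <= 0) stop("`t_max` must be > 0")
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  raw <- if (engine == "cpp") {
    pair_ssa_cpp(params_vec(params_k), params_vec(params_d), t_max,
                 attached[1], attached[2], as.integer(max_events))
  } else {
    pair_ssa_r(params_k, params_d, t_max, attached, max_events)
  }
  if (isTRUE(raw$truncated)) {
    warning("event cap reached before t_max; trajectory truncated")
  }
  new_trajectory(raw, params_k, params_d, t_max)
}

# Reference engine: the literal loop over the exported state operations.
pair_ssa_r <- function(params_k, params_d, t_max, attached, max_events) {
  state <- pair_state(0, 0, 0, attached[1], attached[2])
  if (!state$attached_k && !state$attached_d) {
    stop("at least one motor must start attached")
  }
  cargo0 <- cargo_position(state, params_k, params_d)
  times <- state$t; xk <- state$pos_k; xd <- state$pos_d; cg <- cargo0
  ak <- state$attached_k; ad <- state$attached_d; ev <- NA_integer_
  terminated_early <- FALSE; truncated <- FALSE
  repeat {
    if (!(state$t < t_max && (state$attached_k || state$attached_d))) break
    if (length(times) >= max_events) { truncated <- TRUE; break }
    rates <- event_rates(state, params_k, params_d)
    drawn <- draw_event(rates)
    if (state$t + drawn$dt > t_max) {
      state$t <- t_max
      times <- c(times, t_max); xk <- c(xk, state$pos_k)
      xd <- c(xd, state$pos_d)
      cg <- c(cg, cargo_position(state, params_k, params_d))
      ak <- c(ak, state$attached_k); ad <- c(ad, state$attached_d)
      ev <- c(ev, NA_integer_)
      break
    }
    state <- apply_event(state, drawn$event, params_k, params_d, drawn$dt)
    both_off <- !state$attached_k && !state$attached_d
    if (both_off) terminated_early <- TRUE
    times <- c(times, state$t); xk <- c(xk, state$pos_k)
    xd <- c(xd, state$pos_d)
    cg <- c(cg, if (both_off) NA_real_ else
      cargo_position(state, params_k, params_d))
    ak <- c(ak, state$attached_k); ad <- c(ad, state$attached_d)
    ev <- c(ev, match(drawn$event, EVENT_LABELS))
    if (both_off) break
  }
  list(times = times, pos_k = xk, pos_d = xd, cargo = cg,
       attached_k = ak, attached_d = ad, event = ev,
       terminated_early = terminated_early, truncated = truncated)
}

#' @export
print.motor_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<motor_trajectory> %s + %s, %d events over %.3g s\n",
              x$params_k$name, x$params_d$name, n - 1L,
              x$times[n]))
  if (x$terminated_early) cat("  terminated early (both motors detached)\n")
  invisible(x)
}

#' Simulate an ensemble of independent runs
#'
#' Repeats [simulate_pair()] `n_runs` times with per-run seeds derived
#' deterministically from `seed` (a seeded draw of substream seeds), so
#' the ensemble is reproducible regardless of evaluation order.
#'
#' @inheritParams simulate_pair
#' @param n_runs Number of independent runs (reference protocol: 1000).
#' @param seed Master integer seed (required).
#' @param FUN Optional function applied to each trajectory; when given,
#'   the list of `FUN` results is returned instead of the trajectories,
#'   which keeps memory flat for large ensembles.
#' @return List of `motor_trajectory` objects (or of `FUN` results).
#' @export
simulate_ensemble <- function(params_k, params_d, n_runs = 1000,
                              t_max = 50, seed, attached = c(TRUE, TRUE),
                              engine = c("cpp", "R"), FUN = NULL) {
  stopifnot(n_runs >= 1)
  engine <- match.arg(engine)
  set.seed(seed)
  run_seeds <- sample.int(2147483646L, n_runs)
  lapply(seq_len(n_runs), function(i) {
    tr <- simulate_pair(params_k, params_d, t_max = t_max,
                        seed = run_seeds[i], attached = attached,
                        engine = engine)
    if (is.null(FUN)) tr else FUN(tr)
  })
}

#' Pooled instantaneous-velocity sample for a simulated ensemble
#'
#' Runs the full reference protocol in one call: simulate `n_runs` of up
#' to `t_max` seconds each, average the cargo position into camera frames
#' of `frame_dt` seconds, compute instantaneous velocities over
#' non-overlapping windows of `window` seconds, and pool the windows of
#' all runs.
#'
#' @inheritParams simulate_ensemble
#' @param frame_dt Camera frame interval (s); 0.286 s emulates the
#'   3.5 frames/s acquisition.
#' @param window Velocity window (s).
#' @return Numeric vector of pooled window velocities (nm/s).
#' @examples
#' \donttest{
#' v <- ensemble_velocities(motor_presets("Kin1"), motor_presets("DDB"),
#'                          n_runs = 20, t_max = 10, seed = 1)
#' distribution_peak(v)
#' }
#' @export
ensemble_velocities <- function(params_k, params_d, n_runs = 1000,
                                t_max = 50, seed, frame_dt = 0.286,
                                window = 1) {
  per_run <- simulate_ensemble(
    params_k, params_d, n_runs = n_runs, t_max = t_max, seed = seed,
    FUN = function(tr) {
      if (utils::tail(tr$times, 1) < 2 * frame_dt) return(numeric(0))
      instantaneous_velocities(frame_average(tr, frame_dt), window)
    })
  unlist(per_run, use.names = FALSE)
}
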