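# Shared fixtures: reference parameter sets and hand-built objects.

kin1 <- motor_presets("Kin1")
kin2 <- motor_presets("Kin2")
kin3 <- motor_presets("Kin3")
ddb <- motor_presets("DDB")

# Minimal trajectory carrying just what frame_average() needs: an event
# time grid and a piecewise-constant cargo path.
make_traj <- function(times, cargo) {
  structure(list(times = times, cargo = cargo), class = "motor_trajectory")
}

# Hand-built segment set for the segment-statistics operations.
make_segments <- function(states, durations, velocities,
                          frame_dt = 0.286, pixel = 73) {
  n <- cumsum(round(durations / frame_dt))
  out <- data.frame(
    start_frame = c(1L, utils::head(n, -1L) + 1L), end_frame = n,
    n_frames = diff(c(0L, n)), velocity = velocities,
    duration = durations, displacement = velocities * durations,
    state = factor(states, levels = c("pause", "plus", "minus")))
  structure(out, class = c("segment_set", "data.frame"),
            frame_dt = frame_dt, pixel = pixel)
}

# Noiseless synthetic trace from a velocity/duration plan.
noiseless_trace <- function(velocity, duration, frame_dt = 0.286) {
  gen_segmented_trace(trace_spec(
    data.frame(velocity = velocity, duration = duration),
    frame_dt = frame_dt, noise_sigma = 0,
    max_duration = sum(duration)))
}
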