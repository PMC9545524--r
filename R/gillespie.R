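EVENT_LABELS <- c("forward_k", "back_k", "detach_k", "reattach_k",
                  "forward_d", "back_d", "detach_d", "reattach_d")

#' Instantaneous state of a motor pair
#'
#' One kinesin and one DDB motor connected by linear springs to a shared,
#' massless cargo. Positions are lab-frame nanometres (plus-end
#' positive). The cargo position is not free: with both motors attached
#' it sits at the force-balance point of the two springs
#' (stiffness-weighted mean of the motor positions; midpoint for equal
#' stiffness), and with one motor attached it coincides with that motor.
#' A state with both motors detached is terminal.
#'
#' @param t Time (s).
#' @param pos_k,pos_d Kinesin and DDB positions (nm).
#' @param attached_k,attached_d Attachment flags.
#' @return An object of class `pair_state`.
#' @export
pair_state <- function(t = 0, pos_k = 0, pos_d = 0,
                       attached_k = TRUE, attached_d = TRUE) {
  structure(list(t = t, pos_k = pos_k, pos_d = pos_d,
                 attached_k = isTRUE(attached_k),
                 attached_d = isTRUE(attached_d)),
            class = "pair_state")
}

#' Cargo position from the motor configuration
#'
#' Force balance of a massless cargo held by the springs of the attached
#' motors: both attached gives the stiffness-weighted mean of the motor
#' positions (the midpoint for equal stiffness), one attached snaps the
#' cargo to that motor.
#'
#' @param state A [pair_state].
#' @param params_k,params_d [motor_params] for the kinesin and DDB motor.
#' @return Cargo position (nm).
#' @export
cargo_position <- function(state, params_k, params_d) {
  if (state$attached_k && state$attached_d) {
    kk <- params_k$stiffness
    kd <- params_d$stiffness
    (kk * state$pos_k + kd * state$pos_d) / (kk + kd)
  } else if (state$attached_k) {
    state$pos_k
  } else if (state$attached_d) {
    state$pos_d
  } else {
    stop("both motors detached: terminal state has no cargo position")
  }
}

#' Event rates of the pair in its current state
#'
#' For each attached motor: the load-dependent forward stepping rate, the
#' constant backstepping rate and the load-dependent detachment rate,
#' evaluated at the current linkage tension; its reattachment rate is 0.
#' For each detached motor: only the reattachment rate is non-zero.
#'
#' @inheritParams cargo_position
#' @return Named numeric vector of 8 non-negative rates (1/s) in the
#'   order `forward_k, back_k, detach_k, reattach_k, forward_d, back_d,
#'   detach_d, reattach_d`.
#' @export
event_rates <- function(state, params_k, params_d) {
  rates <- numeric(8)
  names(rates) <- EVENT_LABELS
  cargo <- cargo_position(state, params_k, params_d)
  if (state$attached_k) {
    f_lab <- linkage_force(state$pos_k, cargo, params_k$stiffness)
    load <- motor_load(f_lab, params_k$direction)
    rates[1] <- forward_rate_under_load(load, params_k)
    rates[2] <- params_k$k_backstep
    rates[3] <- detach_rate_under_load(load, params_k)
  } else {
    rates[4] <- params_k$k_reattach
  }
  if (state$attached_d) {
    f_lab <- linkage_force(state$pos_d, cargo, params_d$stiffness)
    load <- motor_load(f_lab, params_d$direction)
    rates[5] <- forward_rate_under_load(load, params_d)
    rates[6] <- params_d$k_backstep
    rates[7] <- detach_rate_under_load(load, params_d)
  } else {
    rates[8] <- params_d$k_reattach
  }
  rates
}

#' Draw the next event and waiting time (Gillespie SSA)
#'
#' Standard stochastic simulation algorithm draw: the waiting time is
#' exponential with the total rate, and the event is chosen with
#' probability proportional to its rate. Rates are held constant over the
#' waiting interval, which is exact because the state does not change
#' between events. Uses R's global random number stream (two uniform
#' draws per call); seed with [set.seed()].
#'
#' @param rates Named non-negative rate vector, e.g. from [event_rates()].
#' @return List with `event` (name) and `dt` (waiting time, s).
#' @export
draw_event <- function(rates) {
  total <- sum(rates)
  if (total <= 0) stop("total rate is zero: no event can occur")
  dt <- -log(stats::runif(1)) / total
  u <- stats::runif(1) * total
  idx <- which(u <= cumsum(rates))[1]
  list(event = names(rates)[idx], dt = dt)
}

#' Apply one event to a pair state
#'
#' Forward/backward steps move the stepping motor one step size along
#' (against) its own direction; a detachment clears the motor's flag,
#' upon which the cargo snaps to the remaining attached motor; a
#' reattachment places the motor at the current cargo position. The time
#' is advanced by `dt`.
#'
#' @inheritParams cargo_position
#' @param event Event label (one of the names of [event_rates()] output).
#' @param dt Waiting time to add to the state clock (s).
#' @return The updated `pair_state`.
#' @export
apply_event <- function(state, event, params_k, params_d, dt = 0) {
  cargo <- cargo_position(state, params_k, params_d)
  s <- state
  s$t <- state$t + dt
  switch(event,
    forward_k = {
      if (!s$attached_k) stop("kinesin cannot step while detached")
      s$pos_k <- s$pos_k + params_k$direction * params_k$step_size
    },
    back_k = {
      if (!s$attached_k) stop("kinesin cannot step while detached")
      s$pos_k <- s$pos_k - params_k$direction * params_k$step_size
    },
    detach_k = {
      if (!s$attached_k) stop("kinesin already detached")
      s$attached_k <- FALSE
    },
    reattach_k = {
      if (s$attached_k) stop("kinesin already attached")
      s$attached_k <- TRUE
      s$pos_k <- cargo
    },
    forward_d = {
      if (!s$attached_d) stop("DDB cannot step while detached")
      s$pos_d <- s$pos_d + params_d$direction * params_d$step_size
    },
    back_d = {
      if (!s$attached_d) stop("DDB cannot step while detached")
      s$pos_d <- s$pos_d - params_d$direction * params_d$step_size
    },
    detach_d = {
      if (!s$attached_d) stop("DDB already detached")
      s$attached_d <- FALSE
    },
    reattach_d = {
      if (s$attached_d) stop("DDB already attached")
      s$attached_d <- TRUE
      s$pos_d <- cargo
    },
    stop("unknown event: ", event)
  )
  s
}
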