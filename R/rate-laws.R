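#' Load-dependent stepping and detachment rate laws
#'
#' The per-motor rate laws of the stepping model, evaluated at the load
#' carried by the motor's linkage.
#'
#' `forward_rate_under_load()` implements a linear force-velocity
#' relation. Loads are expressed in the motor's own convention: positive
#' = assisting (pulling the motor in its stepping direction), negative =
#' hindering. Assisting or zero load leaves the forward rate at
#' `k_forward0`; a hindering load of magnitude `m <= f_stall` interpolates
#' linearly down to `k_backstep` at stall, so the net stepping velocity
#' `(k_forward - k_backstep) * step_size` vanishes exactly at the stall
#' force. Beyond stall the behaviour follows the motor's `superstall`
#' setting: `"linear"` (default) continues the line, floored at a zero
#' rate, so super-stall loads drag the motor backward at up to
#' `k_backstep` net; `"clamp"` holds the forward rate at `k_backstep`
#' (net zero stepping under any super-stall load). Rates never go
#' negative in either convention.
#'
#' `detach_rate_under_load()` implements Bell-model slip-bond detachment,
#' `k_detach0 * exp(|F| / f_detach)`, using the magnitude of the linkage
#' tension (the model states no separate assisting-load law, so tension
#' magnitude is used symmetrically). An ideal bond (`f_detach = Inf`)
#' detaches at `k_detach0` regardless of load, as used for DDB.
#'
#' `motor_load()` converts a lab-frame linkage force (plus-end positive)
#' into the motor's assisting/hindering convention by multiplying by the
#' motor's direction sign.
#'
#' `linkage_force()` is the linear spring law: the lab-frame force on a
#' motor whose linkage is stretched between the motor and the cargo,
#' `stiffness * (cargo_pos - motor_pos)`, i.e. pulling the motor toward
#' the cargo.
#'
#' @param load Force on the motor in its own convention (pN; assisting
#'   positive, hindering negative). Vectorised.
#' @param p A [motor_params] object.
#' @param force_lab Lab-frame force (pN, plus-end positive).
#' @param direction Motor direction sign (+1/-1).
#' @param motor_pos,cargo_pos Positions (nm, lab frame).
#' @param stiffness Spring constant (pN/nm).
#' @return Rates in 1/s; forces in pN.
#' @examples
#' kin1 <- motor_presets("Kin1")
#' forward_rate_under_load(0, kin1)      # 76.25
#' forward_rate_under_load(-6, kin1)     # 3 = k_backstep (stall)
#' detach_rate_under_load(-6.8, kin1)    # 0.96 * e
#' linkage_force(0, 30, 0.2)             # +6 pN
#' @name rate_laws
NULL

#' @rdname rate_laws
#' @export
forward_rate_under_load <- function(load, p) {
  stopifnot(inherits(p, "motor_params"))
  hind <- pmax(-load, 0)
  if (identical(p$superstall, "clamp")) hind <- pmin(hind, p$f_stall)
  pmax(p$k_forward0 + (p$k_backstep - p$k_forward0) * hind / p$f_stall, 0)
}

#' @rdname rate_laws
#' @export
detach_rate_under_load <- function(load, p) {
  stopifnot(inherits(p, "motor_params"))
  if (is.infinite(p$f_detach)) {
    rep(p$k_detach0, length(load))
  } else {
    p$k_detach0 * exp(abs(load) / p$f_detach)
  }
}

#' @rdname rate_laws
#' @export
motor_load <- function(force_lab, direction) {
  direction * force_lab
}

#' @rdname rate_laws
#' @export
linkage_force <- function(motor_pos, cargo_pos, stiffness) {
  if (any(stiffness <= 0)) stop("`stiffness` must be > 0")
  stiffness * (cargo_pos - motor_pos)
}
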