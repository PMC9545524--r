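#' Motor parameter set
#'
#' Container for the full kinetic and mechanical description of one motor
#' species in the tug-of-war model: a plus-end-directed kinesin or the
#' minus-end-directed dynein-dynactin-BicD2 (DDB) complex. All forces are
#' handled internally in a single lab frame with the microtubule plus-end
#' positive; `direction` converts lab-frame linkage forces into the
#' assisting/hindering convention of the load-dependent rate laws.
#'
#' The unloaded forward stepping rate is tied to the unloaded velocity by
#' `k_forward0 = v0 / step_size + k_backstep`, and the unloaded detachment
#' rate to the unloaded run length by `k_detach0 = v0 / run_length0`. When
#' a supplied value agrees with its derivation to within rounding
#' (0.5 1/s), the exact derived value is used, treating the supplied
#' number as a rounded display value. A supplied value that disagrees by
#' more is kept verbatim (published parameter tables are authoritative)
#' and a validation warning is emitted.
#'
#' @param name Species label, e.g. `"Kin1"` or `"DDB"`.
#' @param direction `+1` for a plus-end-directed motor (kinesin), `-1` for
#'   a minus-end-directed motor (DDB).
#' @param v0 Unloaded velocity (nm/s).
#' @param step_size Step size along the microtubule lattice (nm).
#' @param k_backstep Backstepping rate (1/s), load-independent.
#' @param k_forward0 Unloaded forward stepping rate (1/s). Derived from
#'   `v0` when omitted.
#' @param k_detach0 Unloaded detachment rate (1/s). Derived from
#'   `run_length0` when omitted.
#' @param run_length0 Unloaded run length (nm), optional.
#' @param f_stall Stall force (pN): hindering load at which net stepping
#'   velocity reaches zero.
#' @param f_detach Bell-model detachment force parameter (pN);
#'   `Inf` encodes an ideal bond whose off-rate is load-independent.
#' @param k_reattach First-order reattachment rate of the detached,
#'   cargo-tethered motor (1/s).
#' @param stiffness Linkage (motor + DNA tether) spring constant (pN/nm).
#' @param superstall Forward-rate behaviour for hindering loads beyond
#'   the stall force: `"linear"` (default) continues the linear
#'   force-velocity relation past stall, floored at a zero rate, so a
#'   super-stall load produces net backward drift at up to `k_backstep`;
#'   `"clamp"` holds the forward rate at `k_backstep` (net zero
#'   stepping) for any super-stall load.
#'
#' @return An object of class `motor_params`.
#' @examples
#' kin1 <- motor_params("Kin1", direction = +1, v0 = 586, step_size = 8,
#'                      k_backstep = 3, k_detach0 = 0.96, f_stall = 6,
#'                      f_detach = 6.8, k_reattach = 100, stiffness = 0.2)
#' kin1$k_forward0  # 586/8 + 3 = 76.25
#' @seealso [motor_presets()] for the bundled reference parameter sets.
#' @export
motor_params <- function(name, direction, v0, step_size = 8, k_backstep,
                         k_forward0 = NULL, k_detach0 = NULL,
                         run_length0 = NULL, f_stall, f_detach,
                         k_reattach, stiffness,
                         superstall = c("linear", "clamp")) {
  superstall <- match.arg(superstall)
  stopifnot(is.character(name), length(name) == 1L)
  if (!direction %in% c(-1, 1)) {
    stop("`direction` must be +1 (plus-end) or -1 (minus-end)")
  }
  check_nonneg <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
      stop("`", nm, "` must be a single non-negative finite number")
    }
  }
  check_pos <- function(x, nm) {
    check_nonneg(x, nm)
    if (x <= 0) stop("`", nm, "` must be strictly positive")
  }
  check_nonneg(v0, "v0")
  check_pos(step_size, "step_size")
  check_nonneg(k_backstep, "k_backstep")
  check_pos(f_stall, "f_stall")
  check_pos(stiffness, "stiffness")
  check_nonneg(k_reattach, "k_reattach")
  if (!(is.numeric(f_detach) && length(f_detach) == 1L && f_detach > 0)) {
    stop("`f_detach` must be positive (use Inf for an ideal bond)")
  }

  derived_fwd <- derive_forward_rate(v0, step_size, k_backstep)
  if (is.null(k_forward0)) {
    k_forward0 <- derived_fwd
  } else {
    check_nonneg(k_forward0, "k_forward0")
    if (abs(k_forward0 - derived_fwd) <= 0.5) {
      k_forward0 <- derived_fwd
    } else {
      warning(sprintf(
        "%s: supplied k_forward0 = %g differs from v0/step_size + k_backstep = %g; using supplied value",
        name, k_forward0, derived_fwd), call. = FALSE)
    }
  }

  if (!is.null(run_length0)) check_pos(run_length0, "run_length0")
  if (is.null(k_detach0)) {
    if (is.null(run_length0)) {
      stop("supply `k_detach0` or `run_length0`")
    }
    k_detach0 <- derive_unloaded_detach_rate(v0, run_length0)
  } else {
    check_nonneg(k_detach0, "k_detach0")
    if (!is.null(run_length0)) {
      derived_det <- derive_unloaded_detach_rate(v0, run_length0)
      if (abs(k_detach0 - derived_det) > 0.05 * max(derived_det, 0.01)) {
        warning(sprintf(
          "%s: supplied k_detach0 = %g differs from v0/run_length0 = %g; using supplied value",
          name, k_detach0, derived_det), call. = FALSE)
      }
    }
  }
  if (k_backstep > k_forward0) {
    warning(sprintf("%s: k_backstep exceeds k_forward0; unloaded motor walks backwards",
                    name), call. = FALSE)
  }

  structure(
    list(name = name, direction = as.integer(direction), v0 = v0,
         step_size = step_size, k_forward0 = k_forward0,
         k_backstep = k_backstep, k_detach0 = k_detach0,
         run_length0 = run_length0, f_stall = f_stall,
         f_detach = f_detach, k_reattach = k_reattach,
         stiffness = stiffness, superstall = superstall),
    class = "motor_params")
}

#' @export
print.motor_params <- function(x, ...) {
  end <- if (x$direction > 0) "plus-end" else "minus-end"
  cat(sprintf("<motor_params> %s (%s-directed)\n", x$name, end))
  cat(sprintf("  v0 = %g nm/s, step = %g nm, k_forward0 = %g /s, k_backstep = %g /s\n",
              x$v0, x$step_size, x$k_forward0, x$k_backstep))
  fd <- if (is.infinite(x$f_detach)) "ideal bond" else sprintf("%g pN", x$f_detach)
  cat(sprintf("  k_detach0 = %g /s, F_detach = %s, F_stall = %g pN\n",
              x$k_detach0, fd, x$f_stall))
  cat(sprintf("  k_reattach = %g /s, stiffness = %g pN/nm\n",
              x$k_reattach, x$stiffness))
  invisible(x)
}

#' Thermal energy scale
#'
#' `k_B T` at the assay temperature, in pN nm. Used to convert the
#' Bell-model distance parameter delta into a detachment force parameter.
#' @export
KBT_PN_NM <- 4.1

#' Closed-form parameter derivations
#'
#' Small closed forms linking the measurable single-molecule quantities to
#' the rate parameters of the stepping model:
#'
#' * `derive_forward_rate()`: unloaded forward stepping rate
#'   `v0 / step_size + k_backstep` (1/s). The net unloaded stepping rate
#'   `v0 / step_size` plus the backstepping rate it must compensate.
#' * `derive_unloaded_detach_rate()`: unloaded off-rate `v0 / run_length0`
#'   (1/s).
#' * `detach_rate_from_engaged_time()`: off-rate `1 / engaged_time` (1/s)
#'   from a mean (or median, for an exponential) microtubule-engaged time
#'   measured under load.
#' * `derive_detach_force()`: Bell detachment force parameter
#'   `k_B T / delta` (pN) from the distance parameter delta (nm).
#' * `derive_reattach_rate()`: first-order reattachment rate
#'   `k_on * tubulin_conc` (1/s) from the bimolecular microtubule on-rate
#'   constant (1/(uM s)) and the effective local tubulin concentration
#'   (uM).
#' * `derive_linkage_stiffness()`: linear spring constant
#'   `force / extension` (pN/nm) from a force-extension calibration point.
#'
#' @param v0 Unloaded velocity (nm/s).
#' @param step_size Step size (nm), > 0.
#' @param k_backstep Backstepping rate (1/s).
#' @param run_length0 Unloaded run length (nm), > 0.
#' @param engaged_time Mean engaged time under load (s), > 0.
#' @param delta Bell distance parameter (nm), > 0.
#' @param thermal_energy `k_B T` (pN nm), default [KBT_PN_NM].
#' @param on_rate_constant Bimolecular on-rate constant (1/(uM s)).
#' @param tubulin_conc Effective tubulin concentration (uM).
#' @param force Calibration force (pN).
#' @param extension Calibration extension (nm), > 0.
#' @return A single rate (1/s), force (pN) or stiffness (pN/nm).
#' @examples
#' derive_forward_rate(586, 8, 3)        # 76.25 /s
#' derive_unloaded_detach_rate(1200, 6300) # 0.19 /s
#' derive_detach_force(0.6)              # 6.83 pN
#' derive_reattach_rate(1.1, 125)        # 137.5 /s
#' derive_linkage_stiffness(6, 30)       # 0.2 pN/nm
#' @name derive_rates
NULL

#' @rdname derive_rates
#' @export
derive_forward_rate <- function(v0, step_size, k_backstep) {
  if (any(step_size <= 0)) stop("`step_size` must be > 0")
  if (any(v0 < 0) || any(k_backstep < 0)) stop("rates and v0 must be >= 0")
  v0 / step_size + k_backstep
}

#' @rdname derive_rates
#' @export
derive_unloaded_detach_rate <- function(v0, run_length0) {
  if (any(run_length0 <= 0)) stop("`run_length0` must be > 0")
  if (any(v0 < 0)) stop("`v0` must be >= 0")
  v0 / run_length0
}

#' @rdname derive_rates
#' @export
detach_rate_from_engaged_time <- function(engaged_time) {
  if (any(engaged_time <= 0)) stop("`engaged_time` must be > 0")
  1 / engaged_time
}

#' @rdname derive_rates
#' @export
derive_detach_force <- function(delta, thermal_energy = KBT_PN_NM) {
  if (any(delta <= 0)) stop("`delta` must be > 0")
  if (any(thermal_energy <= 0)) stop("`thermal_energy` must be > 0")
  thermal_energy / delta
}

#' @rdname derive_rates
#' @export
derive_reattach_rate <- function(on_rate_constant, tubulin_conc) {
  if (any(on_rate_constant < 0) || any(tubulin_conc < 0)) {
    stop("inputs must be >= 0")
  }
  on_rate_constant * tubulin_conc
}

#' @rdname derive_rates
#' @export
derive_linkage_stiffness <- function(force, extension) {
  if (any(extension <= 0)) stop("`extension` must be > 0")
  force / extension
}
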