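the_cache <- new.env(parent = emptyenv())

#' Load motor parameter sets from a JSON config
#'
#' Reads a structured config with one block per motor species, keys
#' named exactly as the [motor_params()] fields (`f_detach` may be the
#' string `"ideal"` for a load-independent ideal bond). Each block is
#' validated through `motor_params()`, which surfaces derivation
#' inconsistencies (e.g. a tabulated `k_forward0` that does not match
#' `v0 / step_size + k_backstep`) as warnings.
#'
#' @param path Path to a JSON file with a top-level `motors` object (or
#'   a bare object of species blocks).
#' @return Named list of `motor_params`.
#' @export
load_motor_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  motors <- if (!is.null(cfg$motors)) cfg$motors else cfg
  required <- c("name", "direction", "v0", "step_size", "k_backstep",
                "f_stall", "f_detach", "k_reattach", "stiffness")
  out <- lapply(names(motors), function(nm) {
    block <- motors[[nm]]
    missing_keys <- setdiff(required, names(block))
    if (length(missing_keys)) {
      stop("motor block '", nm, "' is missing required keys: ",
           paste(missing_keys, collapse = ", "))
    }
    fd <- block$f_detach
    if (is.character(fd)) {
      if (!tolower(fd) %in% c("ideal", "inf", "infinite")) {
        stop("motor block '", nm, "': unrecognised f_detach value '",
             fd, "'")
      }
      fd <- Inf
    }
    motor_params(name = block$name, direction = block$direction,
                 v0 = block$v0, step_size = block$step_size,
                 k_backstep = block$k_backstep,
                 k_forward0 = block$k_forward0,
                 k_detach0 = block$k_detach0,
                 run_length0 = block$run_length0,
                 f_stall = block$f_stall, f_detach = fd,
                 k_reattach = block$k_reattach,
                 stiffness = block$stiffness)
  })
  names(out) <- names(motors)
  out
}

#' Reference motor parameter sets
#'
#' The bundled parameter sets for Kin1 (KHC, kinesin-1), Kin2
#' (KIF3A/A, kinesin-2), Kin3 (KIF1A, kinesin-3) and the DDB complex
#' used throughout the simulations. Values come from
#' `inst/extdata/reference_params.json`. Known quirk: the tabulated DDB
#' forward rate (60 1/s) exceeds `v0 / step_size + k_backstep` (50 1/s
#' for the nominal 360 nm/s and 8 nm steps); the tabulated value is
#' used, and [load_motor_params()] reports the discrepancy as a
#' warning (`quiet = FALSE` shows it here too).
#'
#' @param species One of `"Kin1"`, `"Kin2"`, `"Kin3"`, `"DDB"`, or
#'   `NULL` for the full named list.
#' @param quiet Suppress validation warnings (default `TRUE`; they are
#'   properties of the published table, not of the caller's input).
#' @return A `motor_params` object, or a named list of them.
#' @examples
#' motor_presets("Kin1")
#' @export
motor_presets <- function(species = NULL, quiet = TRUE) {
  if (is.null(the_cache$presets)) {
    path <- system.file("extdata", "reference_params.json",
                        package = "motortug", mustWork = TRUE)
    the_cache$presets <- if (quiet) {
      suppressWarnings(load_motor_params(path))
    } else {
      load_motor_params(path)
    }
  }
  presets <- the_cache$presets
  if (is.null(species)) return(presets)
  if (!species %in% names(presets)) {
    stop("unknown species '", species, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[species]]
}

#' Read and write position-time trace CSV files
#'
#' One file per trace, columns `time_s` and `position_nm`. Reading
#' checks that the sampling is uniform and infers the frame interval.
#'
#' @param trace A [sampled_trace].
#' @param path File path.
#' @param origin Origin tag for the trace read back.
#' @return `write_trace_csv()` returns `path` invisibly;
#'   `read_trace_csv()` returns a [sampled_trace].
#' @name trace_csv
NULL

#' @rdname trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sampled_trace"))
  df <- data.frame(
    time_s = (seq_along(trace$positions) - 1) * trace$frame_dt,
    position_nm = trace$positions)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_csv
#' @export
read_trace_csv <- function(path, origin = "imported") {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "position_nm") %in% names(df))) {
    stop("trace CSV must have columns time_s and position_nm")
  }
  dts <- diff(df$time_s)
  if (length(dts) < 1L) stop("trace has fewer than 2 frames")
  if (diff(range(dts)) > 1e-6 * max(dts)) {
    stop("trace sampling is not uniform")
  }
  sampled_trace(df$position_nm, frame_dt = stats::median(dts),
                origin = origin)
}

#' Write a synthetic population as trace CSVs with manifest and truth
#'
#' Emits one CSV per trace plus `manifest.csv` (`trace_id`, `file`,
#' `condition`, `frame_dt`, `pixel_nm`) and `truth.csv` (the generator
#' ground truth) into `dir`.
#'
#' @param pop Result of [gen_population()].
#' @param dir Output directory (created if needed).
#' @param condition Condition label for the manifest.
#' @param pixel Pixel size recorded in the manifest (nm).
#' @return The manifest data frame, invisibly.
#' @export
write_population_csv <- function(pop, dir, condition = "synthetic",
                                 pixel = 73) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("trace_%04d.csv", pop$truth$trace_id)
  for (i in seq_along(pop$traces)) {
    write_trace_csv(pop$traces[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(trace_id = pop$truth$trace_id, file = files,
                         condition = condition,
                         frame_dt = vapply(pop$traces, `[[`, 0, "frame_dt"),
                         pixel_nm = pixel)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(pop$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Full single-trace analysis
#'
#' Convenience wrapper running the whole pipeline on one trace:
#' segmentation, pause/direction classification, time fractions,
#' directional switches, and the trace velocity with its fast/slow
#' class.
#'
#' @param trace A [sampled_trace].
#' @param threshold Fast/slow trace-velocity threshold (nm/s).
#' @inheritParams segment_trace
#' @return List with `segments`, `fractions`, `switches`,
#'   `trace_velocity`, `class`.
#' @export
analyze_trace <- function(trace, threshold = 250, min_frames = 3L,
                          min_dv = 10, pixel = 73) {
  segs <- segment_trace(trace, min_frames = min_frames, min_dv = min_dv,
                        pixel = pixel)
  list(segments = segs,
       fractions = time_fractions(segs),
       switches = count_directional_switches(segs),
       trace_velocity = trace_velocity(trace),
       class = classify_fast_slow(trace_velocity(trace), threshold))
}

#' Simulated instantaneous-velocity distributions for the motor pairs
#'
#' Runs the reference simulation protocol for the requested DDB-kinesin
#' pairs — `n_runs` runs of up to `t_max` seconds each, cargo positions
#' averaged into `frame_dt` frames, velocities over `window` windows,
#' pooled — and summarises each pooled distribution by its KDE peak,
#' median and quartiles. Setting `k_reattach` overrides the kinesin
#' reattachment rate (e.g. 5 1/s for the slow-rebinding variant);
#' `NULL` keeps each motor's reference value.
#'
#' @param seed Master seed; each condition uses a sub-seed derived from
#'   it.
#' @param conditions Kinesin species to pair with DDB.
#' @param k_reattach Optional kinesin reattachment override (1/s).
#' @param n_runs,t_max,frame_dt,window See [ensemble_velocities()].
#' @param bin_width KDE bandwidth for the peak (nm/s); `NULL` for the
#'   data-driven default.
#' @param out_dir Optional directory; writes `summary.csv` and one
#'   velocity-sample CSV per condition.
#' @return List with `summary` (data frame) and `velocities` (named
#'   list of pooled velocity vectors).
#' @export
simulate_velocity_distributions <- function(seed,
                                            conditions = c("Kin1", "Kin2", "Kin3"),
                                            k_reattach = NULL,
                                            n_runs = 1000, t_max = 50,
                                            frame_dt = 0.286, window = 1,
                                            bin_width = NULL,
                                            out_dir = NULL) {
  ddb <- motor_presets("DDB")
  set.seed(seed)
  cond_seeds <- sample.int(2147483646L, length(conditions))
  velocities <- list()
  rows <- list()
  for (i in seq_along(conditions)) {
    kin <- motor_presets(conditions[i])
    if (!is.null(k_reattach)) kin$k_reattach <- k_reattach
    v <- ensemble_velocities(kin, ddb, n_runs = n_runs, t_max = t_max,
                             seed = cond_seeds[i], frame_dt = frame_dt,
                             window = window)
    velocities[[conditions[i]]] <- v
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    rows[[i]] <- data.frame(
      condition = conditions[i],
      k_reattach = if (is.null(k_reattach)) kin$k_reattach else k_reattach,
      n_runs = n_runs, t_max = t_max, n_windows = length(v),
      peak = distribution_peak(v, bin_width),
      q25 = q[1], median = q[2], q75 = q[3])
  }
  summary <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    for (nm in names(velocities)) {
      utils::write.csv(data.frame(velocity_nm_s = velocities[[nm]]),
                       file.path(out_dir, paste0("velocities_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  list(summary = summary, velocities = velocities)
}
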