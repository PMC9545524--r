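# Prefix-sum linear-fit machinery: RSS of an ordinary least-squares line
# through frames a..b in O(1) after O(n) setup.
seg_stats <- function(x, y) {
  list(Sx = cumsum(c(0, x)), Sy = cumsum(c(0, y)),
       Sxx = cumsum(c(0, x * x)), Sxy = cumsum(c(0, x * y)),
       Syy = cumsum(c(0, y * y)))
}

seg_fit <- function(st, a, b) {
  n <- b - a + 1
  Sx <- st$Sx[b + 1] - st$Sx[a]
  Sy <- st$Sy[b + 1] - st$Sy[a]
  Sxx <- st$Sxx[b + 1] - st$Sxx[a]
  Sxy <- st$Sxy[b + 1] - st$Sxy[a]
  Syy <- st$Syy[b + 1] - st$Syy[a]
  vx <- Sxx - Sx * Sx / n
  vxy <- Sxy - Sx * Sy / n
  slope <- ifelse(vx > 0, vxy / vx, 0)
  rss <- pmax(Syy - Sy * Sy / n - slope * vxy, 0)
  list(slope = slope, intercept = (Sy - slope * Sx) / n, rss = rss)
}

#' Segment a trace into constant-velocity pieces
#'
#' Decomposes a position-time trace into contiguous piecewise-linear
#' (constant-velocity) segments by exact penalised change-point
#' detection: dynamic programming minimises the total least-squares
#' residual plus a per-segment penalty over all partitions whose
#' segments span at least `min_frames` frames. This automates the
#' segmentation rules used for manual kymograph annotation: every
#' segment is at least 3 frames (0.858 s at the reference frame rate),
#' and adjacent segments whose fitted velocities differ by less than
#' `min_dv` (the minimum detectable velocity change, 10 nm/s) are merged
#' afterwards.
#'
#' The penalty defaults to `5 * sigma^2 * log(n)` where `sigma` is a
#' robust noise estimate from second differences of the positions
#' (`mad(diff(y, differences = 2)) / sqrt(6)`), with a small
#' scale-relative floor so that noiseless traces are recovered exactly.
#' The multiplier is deliberately above the BIC scale (each changepoint
#' adds two parameters) because short admissible segments at the trace
#' edges otherwise overfit localisation noise.
#'
#' Segment velocity is the least-squares slope over the segment's
#' frames; segment duration is `n_frames * frame_dt` (so segments tile
#' the full imaging time); net displacement is `velocity * duration`.
#' Each segment is classified with [classify_segment()].
#'
#' @param trace A [sampled_trace].
#' @param min_frames Minimum segment length in frames (default 3).
#' @param min_dv Minimum velocity difference between adjacent segments
#'   (nm/s, default 10); closer pairs are merged.
#' @param pixel Camera pixel size (nm, default 73) for pause
#'   classification.
#' @param penalty Per-changepoint penalty (nm^2); `NULL` (default) uses
#'   the noise-adaptive choice above.
#' @return A `segment_set`: a data frame with one row per segment
#'   (`start_frame`, `end_frame`, `n_frames`, `velocity`, `duration`,
#'   `displacement`, `state`) carrying the trace's `frame_dt` and
#'   `pixel` as attributes. A trace shorter than `min_frames` yields a
#'   degenerate single-segment set with a warning.
#' @export
segment_trace <- function(trace, min_frames = 3L, min_dv = 10,
                          pixel = 73, penalty = NULL) {
  stopifnot(inherits(trace, "sampled_trace"))
  y <- trace$positions
  n <- length(y)
  dt <- trace$frame_dt
  x <- (seq_len(n) - 1) * dt
  min_frames <- as.integer(min_frames)
  sigma <- if (n >= 4) stats::mad(diff(y, differences = 2)) / sqrt(6) else 0
  if (n < min_frames) {
    warning("trace shorter than `min_frames`; returning a single segment")
    ends <- n
  } else {
    st <- seg_stats(x, y)
    if (is.null(penalty)) {
      penalty <- max(5 * sigma^2 * log(n), 1e-6 * stats::var(y), 1e-9)
    }
    # Fcost[b+1]: minimal cost of segmenting frames 1..b;
    # cp[b]: start frame of the last segment in that optimum
    Fcost <- rep(Inf, n + 1)
    Fcost[1] <- -penalty  # so a single segment costs rss + 0 extra
    cp <- integer(n)
    for (b in min_frames:n) {
      a_cand <- 1:(b - min_frames + 1)
      a_cand <- a_cand[is.finite(Fcost[a_cand])]
      fit <- seg_fit(st, a_cand, b)
      cost <- Fcost[a_cand] + fit$rss + penalty
      j <- which.min(cost)
      Fcost[b + 1] <- cost[j]
      cp[b] <- a_cand[j]
    }
    ends <- integer(0)
    b <- n
    while (b >= 1) {
      ends <- c(b, ends)
      b <- cp[b] - 1L
    }
  }
  starts <- c(1L, utils::head(ends, -1L) + 1L)

  # Merge adjacent segments whose velocities differ by < min_dv. When
  # such a pair is separated by a genuine discontinuity (merging would
  # cost more residual than the changepoint penalty the optimiser
  # already paid, e.g. two pauses at different levels bridged by a
  # sub-frame step), the boundary is carved into a min_frames "step"
  # segment instead -- the way a visible step is annotated manually.
  st <- seg_stats(x, y)
  if (is.null(penalty)) penalty <- Inf  # degenerate single-segment path
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 4L * n) break  # safety cap; merges strictly dominate carves
    v <- mapply(function(a, b) seg_fit(st, a, b)$slope, starts, ends)
    if (length(v) < 2L) break
    dv <- abs(diff(v))
    if (all(dv >= min_dv)) break
    i <- which.min(dv)
    fit_l <- seg_fit(st, starts[i], ends[i])
    fit_r <- seg_fit(st, starts[i + 1L], ends[i + 1L])
    rss_merged <- seg_fit(st, starts[i], ends[i + 1L])$rss
    b <- ends[i]
    # fitted-level discontinuity at the shared boundary
    xm <- (x[b] + x[min(b + 1L, n)]) / 2
    gap <- abs((fit_l$intercept + fit_l$slope * xm) -
                 (fit_r$intercept + fit_r$slope * xm))
    lo <- b - (min_frames - 1L) %/% 2L
    hi <- lo + min_frames - 1L
    carvable <- (lo - starts[i] >= min_frames) &&
      (ends[i + 1L] - hi >= min_frames)
    if (rss_merged - fit_l$rss - fit_r$rss > penalty &&
        gap > max(2 * sigma, 1) && carvable) {
      k <- length(ends)
      keep_s <- if (i + 1L < k) starts[seq(i + 2L, k)] else integer(0)
      keep_e <- if (i + 1L < k) ends[seq(i + 2L, k)] else integer(0)
      starts <- c(starts[seq_len(i)], lo, hi + 1L, keep_s)
      ends <- c(ends[seq_len(i - 1L)], lo - 1L, hi, ends[i + 1L], keep_e)
    } else {
      starts <- starts[-(i + 1L)]
      ends <- ends[-i]
    }
  }

  v <- as.numeric(mapply(function(a, b) seg_fit(st, a, b)$slope,
                         starts, ends))
  nseg <- ends - starts + 1L
  duration <- nseg * dt
  displacement <- v * duration
  out <- data.frame(start_frame = starts, end_frame = ends,
                    n_frames = nseg, velocity = v, duration = duration,
                    displacement = displacement,
                    state = classify_segment(displacement, pixel))
  structure(out, class = c("segment_set", "data.frame"),
            frame_dt = dt, pixel = pixel)
}

#' Classify segments as pause / plus / minus
#'
#' A pause is any segment whose net movement is less than one camera
#' pixel (strictly: `|displacement| < pixel`); otherwise the sign of the
#' displacement gives the direction.
#'
#' @param displacement Net segment displacement(s) (nm), or a
#'   `segment_set` whose `displacement` column is used.
#' @param pixel Pixel size (nm, default 73).
#' @return Factor with levels `"pause"`, `"plus"`, `"minus"`.
#' @export
classify_segment <- function(displacement, pixel = 73) {
  if (inherits(displacement, "segment_set")) {
    pixel <- attr(displacement, "pixel") %||% pixel
    displacement <- displacement$displacement
  }
  if (pixel <= 0) stop("`pixel` must be > 0")
  state <- ifelse(abs(displacement) < pixel, "pause",
                  ifelse(displacement > 0, "plus", "minus"))
  factor(state, levels = c("pause", "plus", "minus"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count directional switches
#'
#' A directional switch is a pair of sequential moving segments with
#' opposite directions (each moving at least one pixel). By default only
#' immediately adjacent moving segments count; `skip_pauses = TRUE`
#' additionally counts opposite-direction moving segments separated
#' only by pauses.
#'
#' @param segs A `segment_set`.
#' @param skip_pauses Ignore intervening pauses when pairing moving
#'   segments (default `FALSE`).
#' @return List with `count` and `frequency` (switches per second of
#'   trace time).
#' @export
count_directional_switches <- function(segs, skip_pauses = FALSE) {
  stopifnot(inherits(segs, "segment_set"))
  s <- as.character(segs$state)
  total_t <- sum(segs$duration)
  if (skip_pauses) s <- s[s != "pause"]
  moving_pair <- (s[-length(s)] == "plus" & s[-1] == "minus") |
    (s[-length(s)] == "minus" & s[-1] == "plus")
  count <- sum(moving_pair)
  list(count = count, frequency = count / total_t)
}

#' Time fractions of the motility states
#'
#' Duration-weighted fraction of trace time spent paused, moving toward
#' the plus-end, and moving toward the minus-end.
#'
#' @param segs A `segment_set`, or a list of them (pooled).
#' @return Named numeric vector `(pause, plus, minus)` summing to 1.
#' @export
time_fractions <- function(segs) {
  if (inherits(segs, "segment_set")) segs <- list(segs)
  dur <- unlist(lapply(segs, function(s) {
    tapply(s$duration, s$state, sum, default = 0)
  }))
  tot <- tapply(dur, names(dur), sum)
  out <- c(pause = 0, plus = 0, minus = 0)
  out[names(tot)] <- tot
  out / sum(out)
}

#' Duration-weighted segment-velocity sample
#'
#' Expands segments into 1 s velocity samples: each segment contributes
#' `round(duration)` copies of its velocity, so long segments carry
#' proportionally more weight. Pauses are excluded by default, matching
#' the instantaneous-velocity distributions computed for moving
#' segments only.
#'
#' @param segs A `segment_set` or list of them.
#' @param include_pauses Keep paused segments (default `FALSE`).
#' @return Numeric vector of velocities (nm/s), one per whole second.
#' @export
weighted_velocity_distribution <- function(segs, include_pauses = FALSE) {
  if (inherits(segs, "segment_set")) segs <- list(segs)
  unlist(lapply(segs, function(s) {
    if (!include_pauses) s <- s[s$state != "pause", , drop = FALSE]
    rep(s$velocity, times = round(s$duration))
  }), use.names = FALSE)
}
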