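# Body-angle kinematics: the three-point angle, left/right direction,
# threshold-based event classification (wags vs LAMs) and per-window
# summaries.

#' Compute the body angle from tracked head/mid-trunk/tail points
#'
#' The body angle is the angle subtended at the mid-trunk point M by lines
#' from the head H and the tail T, reported on a 180-360 degree scale:
#'
#'   theta = 360 - (180/pi) * acos( (H-M) . (T-M) / (|H-M| |T-M|) )
#'
#' A straight larva (H, M, T collinear with the tail opposite the head) is
#' at 180 degrees, the resting posture; the angle grows as the tail bends,
#' and the arccos forces theta into [180, 360]. Because the arccos discards
#' the bend side, direction is recovered from the sign of the planar cross
#' product (H-M) x (T-M): positive means a left-directed excursion under
#' the convention that left movements plot above the resting line. The
#' arccos argument is clamped to [-1, 1] to absorb floating-point overshoot
#' on collinear frames.
#'
#' @param track A `point_track` tibble (columns Hx, Hy, Mx, My, Tx, Ty) as
#'   produced by [simulate_trajectory()] or [read_track()], or any data
#'   frame with those columns plus a `frame_rate` via attribute or argument.
#' @param frame_rate Frames per second; taken from the track attribute when
#'   absent.
#' @return An `angle_trace` tibble: frame, time (s), theta (degrees),
#'   signed_theta (degrees, +(theta-180) left / -(theta-180) right),
#'   direction ("left", "right" or "none" on exactly collinear frames).
#' @examples
#' tr <- tibble::tibble(frame = 1:2, Hx = 0, Hy = 1, Mx = 0, My = 0,
#'                      Tx = c(0, 1), Ty = c(-1, 0))
#' compute_body_angle(tr, frame_rate = 300)$theta  # 180, 270
#' @export
compute_body_angle <- function(track, frame_rate = NULL) {
  fr <- frame_rate %||% attr(track, "frame_rate")
  if (is.null(fr) || !is.numeric(fr) || fr <= 0) {
    abort("supply a positive `frame_rate` (argument or track attribute)")
  }
  need <- c("Hx", "Hy", "Mx", "My", "Tx", "Ty")
  if (!all(need %in% names(track))) {
    abort(paste("track must contain columns", paste(need, collapse = ", ")))
  }
  hx <- track$Hx - track$Mx
  hy <- track$Hy - track$My
  tx <- track$Tx - track$Mx
  ty <- track$Ty - track$My
  nh <- sqrt(hx^2 + hy^2)
  nt <- sqrt(tx^2 + ty^2)
  bad <- which(nh == 0 | nt == 0)
  if (length(bad)) {
    abort(sprintf("degenerate frame %d: H or T coincides with M", bad[1]))
  }
  arg <- pmin(1, pmax(-1, (hx * tx + hy * ty) / (nh * nt)))
  theta <- 360 - 180 / pi * acos(arg)
  cross <- hx * ty - hy * tx
  direction <- dplyr::case_when(cross > 0 ~ "left", cross < 0 ~ "right",
                                TRUE ~ "none")
  out <- tibble(
    frame = seq_along(theta), time = (seq_along(theta) - 1) / fr,
    theta = theta,
    signed_theta = ifelse(direction == "right", -1, 1) * (theta - 180),
    direction = direction
  )
  attr(out, "frame_rate") <- fr
  class(out) <- c("angle_trace", class(out))
  out
}

#' Assign left/right direction to an angle trace
#'
#' Adds/overwrites the signed angle and per-frame direction of `trace` from
#' the planar cross product of the tracked points (positive = left). This
#' automates a judgement historically made by replaying videos; the
#' convention is covered by a mirror-symmetry property: reflecting all
#' x-coordinates flips every direction and changes nothing else.
#'
#' @param track The `point_track` the trace was derived from.
#' @param trace An `angle_trace` from [compute_body_angle()].
#' @param rest_band Half-width (degrees) of the rest band about 180; frames
#'   inside it carry direction "none".
#' @return The trace with `signed_theta` and `direction` filled in.
#' @export
assign_direction <- function(track, trace, rest_band = 5) {
  if (nrow(track) != nrow(trace)) {
    abort("track and trace must have the same number of frames")
  }
  fresh <- compute_body_angle(track, frame_rate = frame_rate(trace))
  trace$signed_theta <- fresh$signed_theta
  trace$direction <- ifelse(trace$theta <= 180 + rest_band, "none",
                            fresh$direction)
  trace
}

new_movement_events <- function(df) {
  out <- as_tibble(df)
  class(out) <- c("movement_events", class(out))
  out
}

empty_events <- function() {
  new_movement_events(tibble(
    event = integer(0), onset = numeric(0), offset = numeric(0),
    duration = numeric(0), duration_ms = numeric(0), peak_angle = numeric(0),
    direction = character(0), event_class = character(0),
    truncated = logical(0), split = logical(0)
  ))
}

#' Detect and classify tail movement events
#'
#' An event spans from the moment the body angle leaves the rest band
#' (180 +/- `rest_band` degrees; the angle scale cannot go below 180) while
#' moving in a single direction until it re-enters the band. Events are
#' classified by peak angle: wags below 200 degrees, large-angle movements
#' (LAMs) between 200 and 270, and "extreme" events at 270 or above, which
#' are reported but never counted as LAMs. Peaks of exactly 200 resolve to
#' wag and exactly 270 to extreme (the LAM definition uses strict
#' inequalities). Onset is the last in-band frame before the excursion and
#' offset the first in-band frame after it, so durations measure the full
#' rest-to-rest movement. Excursions whose signed angle changes side
#' without reaching rest are split at the direction change and flagged
#' `split`; an excursion still in progress at either edge of the trace is
#' flagged `truncated` and should be excluded from duration statistics
#' (see [summarize_events()]).
#'
#' @param trace An `angle_trace` from [compute_body_angle()].
#' @param rest_band Half-width of the rest band in degrees (default 5).
#'   Exit and re-entry use the same threshold.
#' @param min_duration Minimum number of above-band frames for an event to
#'   be kept (default 3).
#' @param median_filter Apply a 3-frame running-median filter to the angle
#'   before detection (off by default; useful for noisy tracks).
#' @return A `movement_events` tibble: event, onset, offset, duration (s),
#'   duration_ms, peak_angle, direction, event_class, truncated, split.
#' @export
detect_events <- function(trace, rest_band = 5, min_duration = 3,
                          median_filter = FALSE) {
  check_number(rest_band, "rest_band", 0, strict = TRUE)
  check_number(min_duration, "min_duration", 1)
  if (nrow(trace) == 0) return(empty_events())
  if (isTRUE(median_filter) && nrow(trace) >= 3) {
    trace$signed_theta <- stats::runmed(trace$signed_theta, 3,
                                        endrule = "keep")
    trace$theta <- 180 + abs(trace$signed_theta)
  }
  fr <- frame_rate(trace)
  upper <- 180 + rest_band
  above <- trace$theta > upper
  if (!any(above)) return(empty_events())

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- tibble(start = starts[r$values], end = ends[r$values])

  segs <- map_dfr(seq_len(nrow(runs)), function(i) {
    i1 <- runs$start[i]; i2 <- runs$end[i]
    sgn <- sign(trace$signed_theta[i1:i2])
    sgn[sgn == 0] <- 1
    chg <- which(diff(sgn) != 0)
    sub_start <- i1 + c(0L, chg)
    sub_end <- c(i1 + chg - 1L, i2)
    tibble(
      first_above = sub_start, last_above = sub_end,
      split = length(chg) > 0,
      trunc_start = sub_start == i1 & i1 == 1,
      trunc_end = sub_end == i2 & i2 == nrow(trace),
      interior_start = sub_start != i1,
      interior_end = sub_end != i2
    )
  })

  segs <- filter(segs, .data$last_above - .data$first_above + 1 >= min_duration)
  if (nrow(segs) == 0) return(empty_events())

  events <- map_dfr(seq_len(nrow(segs)), function(i) {
    f1 <- segs$first_above[i]; f2 <- segs$last_above[i]
    # rest-to-rest span: one frame beyond the above-band run on each side,
    # except at trace edges or interior splits (shared crossing frame)
    on_f <- if (segs$interior_start[i] || segs$trunc_start[i]) f1 else f1 - 1L
    off_f <- if (segs$interior_end[i] || segs$trunc_end[i]) f2 else f2 + 1L
    pk <- f1 - 1L + which.max(trace$theta[f1:f2])
    peak <- trace$theta[pk]
    tibble(
      onset = trace$time[on_f], offset = trace$time[off_f],
      peak_angle = peak,
      direction = if (trace$signed_theta[pk] >= 0) "left" else "right",
      event_class = if (peak <= 200) "wag"
                    else if (peak < 270) "LAM" else "extreme",
      truncated = segs$trunc_start[i] || segs$trunc_end[i],
      split = segs$split[i]
    )
  })
  events <- events |>
    arrange(.data$onset) |>
    mutate(
      event = row_number(), duration = .data$offset - .data$onset,
      duration_ms = .data$duration * 1000
    ) |>
    select("event", "onset", "offset", "duration", "duration_ms",
           "peak_angle", "direction", "event_class", "truncated", "split")
  new_movement_events(events)
}

#' Summarize detected events per recording window
#'
#' Counts LAMs per window (half-open windows `[k*window, (k+1)*window)` by
#' event onset), collects wag and LAM duration lists, and reports their
#' means with standard errors plus the right-continuous empirical
#' cumulative distribution of LAM durations. Truncated events contribute to
#' counts but are excluded from all duration statistics; extreme events
#' (peak >= 270 degrees) are never counted as LAMs.
#'
#' @param events A `movement_events` tibble from [detect_events()].
#' @param window Window length in seconds (default 20).
#' @return A `kinematics_summary` list: `window`, `counts` (tibble
#'   window_start, lam_count, wag_count, extreme_count), `lam_durations`
#'   and `wag_durations` (seconds), `stats` (tibble event_class, n,
#'   mean_ms, sem_ms) and `lam_ecdf` (a [stats::ecdf] function, NULL when
#'   no LAM durations exist).
#' @export
summarize_events <- function(events, window = 20) {
  check_number(window, "window", 0, strict = TRUE)
  win_id <- floor(events$onset / window)
  wins <- if (nrow(events)) seq(0, max(win_id)) else numeric(0)
  counts <- tibble(
    window_start = wins * window,
    lam_count = vapply(wins, function(w)
      sum(win_id == w & events$event_class == "LAM"), numeric(1)),
    wag_count = vapply(wins, function(w)
      sum(win_id == w & events$event_class == "wag"), numeric(1)),
    extreme_count = vapply(wins, function(w)
      sum(win_id == w & events$event_class == "extreme"), numeric(1))
  )
  ok <- !events$truncated
  lam_d <- events$duration[ok & events$event_class == "LAM"]
  wag_d <- events$duration[ok & events$event_class == "wag"]
  stat_row <- function(cls, d) {
    tibble(event_class = cls, n = length(d),
           mean_ms = if (length(d)) mean(d) * 1000 else NA_real_,
           sem_ms = if (length(d) > 1) sd(d) / sqrt(length(d)) * 1000
                    else if (length(d) == 1) 0 else NA_real_)
  }
  structure(
    list(
      window = window, counts = counts,
      lam_durations = lam_d, wag_durations = wag_d,
      stats = bind_rows(stat_row("LAM", lam_d), stat_row("wag", wag_d)),
      lam_ecdf = if (length(lam_d)) ecdf(lam_d) else NULL
    ),
    class = "kinematics_summary"
  )
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat("Kinematics summary (window ", x$window, " s)\n", sep = "")
  print(x$counts)
  print(x$stats)
  invisible(x)
}

#' @rdname summarize_events
#' @param x A `kinematics_summary`.
#' @param ... Unused.
#' @method tidy kinematics_summary
#' @export
tidy.kinematics_summary <- function(x, ...) x$stats

#' @rdname summarize_events
#' @method glance kinematics_summary
#' @export
glance.kinematics_summary <- function(x, ...) {
  tibble(
    windows = nrow(x$counts),
    lam_count_mean = if (nrow(x$counts)) mean(x$counts$lam_count) else 0,
    lam_mean_ms = x$stats$mean_ms[x$stats$event_class == "LAM"],
    wag_mean_ms = x$stats$mean_ms[x$stats$event_class == "wag"]
  )
}
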