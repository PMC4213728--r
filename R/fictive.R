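# Spike detection and ISI-based burst/episode segmentation of fictive swim
# recordings, with the four motor-pattern metrics: spikes per burst, burst
# duration, burst period and bursts per episode.

#' Detect spikes in an extracellular voltage trace
#'
#' One spike per rising-edge threshold crossing, with crossings closer than
#' the refractory interval to the previous accepted spike discarded. When
#' `threshold = "auto"` a robust estimate is used: median + 5 x (median
#' absolute deviation / 0.6745) of the trace, i.e. five robust standard
#' deviations above baseline.
#'
#' @param trace A `voltage_trace` tibble (columns time, voltage) or any
#'   data frame with those columns; uniform sampling is assumed.
#' @param threshold Numeric threshold in the trace's voltage units, or
#'   `"auto"`.
#' @param refractory Minimum separation between spikes, ms (default 1).
#' @return Numeric vector of spike times (seconds).
#' @export
detect_spikes <- function(trace, threshold = "auto", refractory = 1) {
  if (!all(c("time", "voltage") %in% names(trace))) {
    abort("trace must contain `time` and `voltage` columns")
  }
  v <- trace$voltage
  if (any(!is.finite(v))) abort("trace contains non-finite voltages")
  if (identical(threshold, "auto")) {
    s <- mad(v)  # mad() already scales by 1/0.6745
    if (s == 0) abort("no spike activity detectable: trace is constant under the robust noise estimate")
    threshold <- median(v) + 5 * s
  }
  check_number(threshold, "threshold")
  check_number(refractory, "refractory", 0)
  rising <- which(v >= threshold & dplyr::lag(v, default = threshold - 1) < threshold)
  if (length(rising) == 0) return(numeric(0))
  times <- trace$time[rising]
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory / 1000) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Segment spike times into bursts nested within episodes
#'
#' A single left-to-right pass over inter-spike intervals (ISIs): an ISI
#' below `intra_burst_isi_max` keeps the spike in the current burst; an ISI
#' from `intra_burst_isi_max` up to and including `episode_isi_max` starts
#' a new burst within the same episode; a longer ISI starts a new episode.
#' With the defaults this sorts spikes into bursts (ISIs < 10 ms) and
#' episodes (ISIs between 10 and 100 ms); boundary ISIs of exactly 10 ms
#' open a new burst and exactly 100 ms stay within the episode. A lone
#' spike forms a burst of one with duration zero.
#'
#' @param spike_times Strictly increasing spike times in seconds.
#' @param intra_burst_isi_max Intra-burst ISI bound, ms (default 10).
#' @param episode_isi_max Within-episode ISI bound, ms (default 100).
#' @return A `spike_segmentation` list: `spikes` (tibble time, burst,
#'   episode), `bursts` (tibble episode, burst, start, end, n_spikes,
#'   duration_ms), `episodes` (tibble episode, n_bursts, start, end) and
#'   the two thresholds.
#' @examples
#' seg <- segment_spikes(c(0, 5, 9, 50, 55, 200) / 1000)
#' seg$bursts$n_spikes  # 3, 2, 1
#' @export
segment_spikes <- function(spike_times, intra_burst_isi_max = 10,
                           episode_isi_max = 100) {
  check_number(intra_burst_isi_max, "intra_burst_isi_max", 0, strict = TRUE)
  check_number(episode_isi_max, "episode_isi_max", intra_burst_isi_max)
  if (length(spike_times) && any(diff(spike_times) <= 0)) {
    abort("spike times must be strictly increasing")
  }
  n <- length(spike_times)
  if (n == 0) {
    spikes <- tibble(time = numeric(0), burst = integer(0), episode = integer(0))
    return(structure(
      list(
        spikes = spikes,
        bursts = tibble(episode = integer(0), burst = integer(0),
                        start = numeric(0), end = numeric(0),
                        n_spikes = integer(0), duration_ms = numeric(0)),
        episodes = tibble(episode = integer(0), n_bursts = integer(0),
                          start = numeric(0), end = numeric(0)),
        intra_burst_isi_max = intra_burst_isi_max,
        episode_isi_max = episode_isi_max
      ),
      class = "spike_segmentation"
    ))
  } else {
    isi_ms <- diff(spike_times) * 1000
    burst <- cumsum(c(1L, as.integer(isi_ms >= intra_burst_isi_max)))
    episode <- cumsum(c(1L, as.integer(isi_ms > episode_isi_max)))
    spikes <- tibble(time = spike_times, burst = burst, episode = episode)
  }
  bursts <- spikes |>
    group_by(.data$episode, .data$burst) |>
    summarise(start = min(.data$time), end = max(.data$time),
              n_spikes = dplyr::n(), .groups = "drop") |>
    mutate(duration_ms = (.data$end - .data$start) * 1000) |>
    arrange(.data$burst) |>
    select("episode", "burst", "start", "end", "n_spikes", "duration_ms")
  episodes <- bursts |>
    group_by(.data$episode) |>
    summarise(n_bursts = dplyr::n(), start = min(.data$start),
              end = max(.data$end), .groups = "drop")
  structure(
    list(spikes = spikes, bursts = bursts, episodes = episodes,
         intra_burst_isi_max = intra_burst_isi_max,
         episode_isi_max = episode_isi_max),
    class = "spike_segmentation"
  )
}

#' @export
print.spike_segmentation <- function(x, ...) {
  cat("Spike segmentation: ", nrow(x$spikes), " spikes, ", nrow(x$bursts),
      " bursts, ", nrow(x$episodes), " episodes (ISI bands: <",
      x$intra_burst_isi_max, " ms burst, <=", x$episode_isi_max,
      " ms episode)\n", sep = "")
  invisible(x)
}

#' @rdname segment_spikes
#' @param x A `spike_segmentation`.
#' @param ... Unused.
#' @method tidy spike_segmentation
#' @export
tidy.spike_segmentation <- function(x, ...) x$bursts

#' Motor-pattern metrics from a spike segmentation
#'
#' Computes the four metrics: spikes per burst, burst duration (time from
#' first to last spike of a burst; zero for a lone spike), burst period
#' (time between successive burst start times, defined only within an
#' episode -- an episode with a single burst contributes no period), and
#' bursts per episode, together with per-recording means and standard
#' errors.
#'
#' @param seg A `spike_segmentation` from [segment_spikes()].
#' @return A `burst_metrics` list: `bursts` (the per-burst tibble with a
#'   `period_ms` column, NA where undefined), `per_episode` (tibble
#'   episode, n_bursts), and `summary` (tibble metric, n, mean, sem; times
#'   in ms).
#' @export
burst_metrics <- function(seg) {
  stopifnot(inherits(seg, "spike_segmentation"))
  bursts <- seg$bursts |>
    group_by(.data$episode) |>
    mutate(period_ms = (dplyr::lead(.data$start) - .data$start) * 1000) |>
    ungroup()
  summ <- function(metric, x) {
    x <- x[!is.na(x)]
    tibble(metric = metric, n = length(x),
           mean = if (length(x)) mean(x) else NA_real_,
           sem = if (length(x) > 1) sd(x) / sqrt(length(x))
                 else if (length(x) == 1) 0 else NA_real_)
  }
  structure(
    list(
      bursts = bursts,
      per_episode = select(seg$episodes, "episode", "n_bursts"),
      summary = bind_rows(
        summ("spikes_per_burst", bursts$n_spikes),
        summ("burst_duration_ms", bursts$duration_ms),
        summ("burst_period_ms", bursts$period_ms),
        summ("bursts_per_episode", seg$episodes$n_bursts)
      )
    ),
    class = "burst_metrics"
  )
}

#' @export
print.burst_metrics <- function(x, ...) {
  cat("Burst metrics\n")
  print(x$summary)
  invisible(x)
}

#' @rdname burst_metrics
#' @param x A `burst_metrics`.
#' @param ... Unused.
#' @method tidy burst_metrics
#' @export
tidy.burst_metrics <- function(x, ...) x$summary

#' @rdname burst_metrics
#' @method glance burst_metrics
#' @export
glance.burst_metrics <- function(x, ...) {
  s <- x$summary
  tibble(
    n_bursts = nrow(x$bursts), n_episodes = nrow(x$per_episode),
    spikes_per_burst = s$mean[s$metric == "spikes_per_burst"],
    burst_duration_ms = s$mean[s$metric == "burst_duration_ms"],
    burst_period_ms = s$mean[s$metric == "burst_period_ms"],
    bursts_per_episode = s$mean[s$metric == "bursts_per_episode"]
  )
}
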