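# Synthetic-data generators for the four input kinds the analyses consume:
# tail point-tracks, fictive-swim spike trains, dose-survival tables and
# behavioral phenotype counts. Every generator is bit-reproducible given
# (params, seed) and returns its ground truth alongside the data so the
# detection/segmentation stages can be closed-loop tested.

new_point_track <- function(df, frame_rate) {
  out <- as_tibble(df)
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("point_track", class(out))
  out
}

#' Frame rate of a point track or angle trace
#' @param x A `point_track` or `angle_trace` object.
#' @return Frames per second.
#' @export
frame_rate <- function(x) {
  fr <- attr(x, "frame_rate")
  if (is.null(fr)) abort("object carries no frame_rate attribute")
  fr
}

# Draw event durations (seconds) from the truncated normal the scheduler
# uses; the lower bound keeps every event at least 5 frames long so it
# survives the detector's minimum-duration filter.
draw_event_durations <- function(n, mean_ms, sd_ms, frame_rate) {
  lower <- 5 / frame_rate
  rtnorm(n, mean_ms / 1000, sd_ms / 1000, lower = lower)
}

#' Sample event durations from a trajectory generator's distribution
#'
#' Draws wag or LAM durations from the same truncated-normal distribution
#' [simulate_trajectory()] schedules with, without building a trajectory.
#' Useful for power calculations on duration contrasts between phenotypes.
#'
#' @param params A [trajectory_params()] object.
#' @param n Number of durations to draw.
#' @param class `"lam"` or `"wag"`.
#' @return Numeric vector of durations in seconds.
#' @export
sample_event_durations <- function(params, n, class = c("lam", "wag")) {
  stopifnot(inherits(params, "trajectory_params"))
  class <- match.arg(class)
  withr::with_seed(derive_seed(params$seed, 97), {
    if (class == "lam") {
      draw_event_durations(n, params$lam_duration_mean, params$lam_duration_sd,
                           params$frame_rate)
    } else {
      draw_event_durations(n, params$wag_duration_mean, params$wag_duration_sd,
                           params$frame_rate)
    }
  })
}

# Place `blocks` (durations in s) uniformly in [0, window] without overlap,
# keeping `guard` seconds between blocks. Uniform placement with rejection
# of overlaps; when the window is too crowded for rejection sampling to
# succeed, falls back to random gap allocation (uniform spacings around a
# random block order), which succeeds whenever the events fit at all.
# Errors only if the window genuinely cannot fit the requested events.
place_blocks <- function(durations, window, guard, max_tries = 2000) {
  n <- length(durations)
  if (n == 0) return(numeric(0))
  if (sum(durations) + guard * (n - 1) > window) {
    abort("cannot fit the requested events in the recording window")
  }
  starts <- numeric(0)
  ends <- numeric(0)
  placed_all <- TRUE
  for (d in sort(durations, decreasing = TRUE)) {
    placed <- FALSE
    for (i in seq_len(max_tries)) {
      s <- runif(1, 0, window - d)
      if (all(s > ends + guard | s + d < starts - guard)) {
        starts <- c(starts, s)
        ends <- c(ends, s + d)
        placed <- TRUE
        break
      }
    }
    if (!placed) { placed_all <- FALSE; break }
  }
  if (placed_all) {
    ord <- order(order(durations, decreasing = TRUE))
    return(starts[ord])
  }
  perm <- sample.int(n)
  free <- window - sum(durations) - guard * (n - 1)
  extra <- diff(c(0, sort(runif(n)))) * free
  seq_starts <- cumsum(c(0, durations[perm][-n] + guard)) + cumsum(extra)
  seq_starts[order(perm)]
}

#' Simulate a tracked tail trajectory with known events
#'
#' Generates a per-frame point track of the three tracked body points --
#' head H and mid-trunk M fixed (the head is embedded), tail T on the unit
#' circle about M -- whose body angle is a resting baseline near 180 deg
#' plus scheduled half-sine excursions: clustered low-amplitude wags and
#' sparse large-angle movements (LAMs). Event counts are Poisson, placements
#' uniform with overlap rejection. The scheduled event list and the exact
#' angle trace are returned alongside the coordinates for closed-loop
#' testing: recomputing the body angle from the track reproduces the
#' generated angle to numerical round-off.
#'
#' @param params A [trajectory_params()] object.
#' @return A `sim_trajectory` list with elements `track` (a `point_track`
#'   tibble: frame, Hx, Hy, Mx, My, Tx, Ty), `angle` (frame, time, theta,
#'   signed_theta in degrees), `events` (ground-truth tibble: onset, offset,
#'   duration, duration_ms, peak_angle, direction, event_class) and `params`.
#' @examples
#' sim <- simulate_trajectory(trajectory_preset("control", seed = 7))
#' nrow(sim$track)
#' dplyr::count(sim$events, event_class)
#' @export
simulate_trajectory <- function(params) {
  stopifnot(inherits(params, "trajectory_params"))
  fr <- params$frame_rate
  n_frames <- round(params$duration * fr)
  t_frame <- (seq_len(n_frames) - 1) / fr
  guard <- 4 / fr

  withr::with_seed(derive_seed(params$seed, 1), {
    n_lam <- rpois(1, params$lam_rate)
    n_clusters <- rpois(1, params$wag_cluster_rate * params$duration)
    lam_dur <- draw_event_durations(n_lam, params$lam_duration_mean,
                                    params$lam_duration_sd, fr)
    lam_peak <- runif(n_lam, params$lam_peak_range[1], params$lam_peak_range[2])
    wags_k <- draw_counts(params$wags_per_cluster, n_clusters)
    wag_dur <- draw_event_durations(sum(wags_k), params$wag_duration_mean,
                                    params$wag_duration_sd, fr)
    wag_peak <- runif(sum(wags_k), params$wag_peak_range[1],
                      params$wag_peak_range[2])

    # a cluster is one block of back-to-back wags separated by `guard`
    cluster_id <- rep(seq_len(n_clusters), wags_k)
    cluster_dur <- if (n_clusters) {
      as.numeric(tapply(wag_dur, cluster_id, sum)) +
        guard * (wags_k - 1)
    } else numeric(0)
    block_dur <- c(lam_dur, cluster_dur)
    block_start <- place_blocks(block_dur, params$duration, guard)

    events <- tibble(
      onset = numeric(0), duration = numeric(0), peak_angle = numeric(0),
      event_class = character(0)
    )
    if (n_lam) {
      events <- bind_rows(events, tibble(
        onset = block_start[seq_len(n_lam)], duration = lam_dur,
        peak_angle = lam_peak, event_class = "LAM"
      ))
    }
    if (n_clusters) {
      offs <- unlist(lapply(seq_len(n_clusters), function(i) {
        d <- wag_dur[cluster_id == i]
        cumsum(c(0, head(d + guard, -1)))
      }))
      events <- bind_rows(events, tibble(
        onset = block_start[n_lam + cluster_id] + offs, duration = wag_dur,
        peak_angle = wag_peak, event_class = "wag"
      ))
    }
    events <- arrange(events, .data$onset)

    n_ev <- nrow(events)
    side <- if (n_ev == 0) character(0) else switch(params$laterality_mode,
      alternating = rep_len(
        if (runif(1) < 0.5) c("left", "right") else c("right", "left"), n_ev
      ),
      unilateral = rep(if (runif(1) < 0.5) "left" else "right", n_ev),
      mixed = ifelse(runif(n_ev) < 0.5, "left", "right")
    )
    events$direction <- side
    events$offset <- events$onset + events$duration
    events$duration_ms <- events$duration * 1000
    events <- select(events, "onset", "offset", "duration", "duration_ms",
                     "peak_angle", "direction", "event_class")

    # baseline jitter around rest, then overwrite event windows
    mag <- abs(rnorm(n_frames, 0, params$rest_jitter_sd))
    sgn <- ifelse(runif(n_frames) < 0.5, 1, -1)
    for (i in seq_len(n_ev)) {
      on <- events$onset[i]; d <- events$duration[i]
      idx <- which(t_frame > on & t_frame < on + d)
      mag[idx] <- (events$peak_angle[i] - 180) * sin(pi * (t_frame[idx] - on) / d)
      sgn[idx] <- if (events$direction[i] == "left") 1 else -1
    }
    theta <- 180 + mag
    signed_theta <- sgn * mag
  })

  # reconstruct T on the unit circle about M; the angle between MH and MT
  # is 360 - theta, and left excursions put the tail at negative x
  alpha <- (360 - theta) * pi / 180
  Tx <- ifelse(signed_theta >= 0, -1, 1) * sin(alpha)
  Ty <- cos(alpha)
  track <- new_point_track(
    tibble(frame = seq_len(n_frames), Hx = 0, Hy = 1, Mx = 0, My = 0,
           Tx = Tx, Ty = Ty),
    frame_rate = fr
  )
  structure(
    list(
      track = track,
      angle = tibble(frame = seq_len(n_frames), time = t_frame,
                     theta = theta, signed_theta = signed_theta),
      events = events,
      params = params
    ),
    class = "sim_trajectory"
  )
}

#' Simulate a fictive-swim recording with known burst structure
#'
#' Generates spike times organized as episodes of rhythmic bursts: episode
#' count is Poisson at `episode_rate` per minute, episodes are separated by
#' quiescent gaps longer than 100 ms, bursts within an episode start at
#' intervals drawn around `burst_period_mean`, and spikes within a burst are
#' evenly spaced so intra-burst inter-spike intervals stay below 10 ms while
#' inter-burst gaps stay in the 10-100 ms episode band. Optionally renders a
#' voltage trace: gaussian baseline noise plus a stereotyped sharp-onset
#' waveform at each spike time.
#'
#' @param params A [spike_train_params()] object.
#' @param include_trace Render the voltage trace? Skipping it is much
#'   cheaper when only spike times are needed.
#' @return A `sim_spike_train` list with `spike_times` (seconds, strictly
#'   increasing), `ground_truth` (list of `spikes`, `bursts`, `episodes`
#'   tibbles built from the schedule, independent of any detector), `trace`
#'   (tibble time, voltage, or NULL) and `params`.
#' @examples
#' sim <- simulate_spike_train(spike_train_preset("control", seed = 3),
#'                             include_trace = FALSE)
#' nrow(sim$ground_truth$bursts)
#' @export
simulate_spike_train <- function(params, include_trace = TRUE) {
  stopifnot(inherits(params, "spike_train_params"))
  withr::with_seed(derive_seed(params$seed, 2), {
    n_ep <- rpois(1, params$episode_rate * params$recording_duration / 60)
    if (n_ep == 0) {
      empty <- list(
        spikes = tibble(time = numeric(0), burst = integer(0), episode = integer(0)),
        bursts = tibble(episode = integer(0), burst = integer(0),
                        start = numeric(0), end = numeric(0),
                        n_spikes = integer(0), duration_ms = numeric(0)),
        episodes = tibble(episode = integer(0), n_bursts = integer(0),
                          start = numeric(0), end = numeric(0))
      )
      trace <- if (include_trace) render_trace(numeric(0), params) else NULL
      return(structure(
        list(spike_times = numeric(0), ground_truth = empty, trace = trace,
             params = params),
        class = "sim_spike_train"
      ))
    }

    k_bursts <- draw_counts(params$bursts_per_episode, n_ep)
    ep <- vector("list", n_ep)
    for (e in seq_len(n_ep)) {
      k <- k_bursts[e]
      m <- draw_counts(params$spikes_per_burst, k)
      # truncate draws so the generated ISIs honor the segmentation bands:
      # intra-burst ISI < 10 ms, inter-burst gap strictly inside (10, 100) ms
      dur <- rtnorm(k, params$burst_duration_mean, params$burst_duration_sd,
                    lower = pmax(0.5 * (m - 1), 0.5),
                    upper = 9.5 * pmax(m - 1, 1))
      dur[m == 1] <- 0
      gap <- rtnorm(k - 1,
                    params$burst_period_mean - params$burst_duration_mean,
                    params$burst_period_sd, lower = 10.5, upper = 99.5)
      start <- cumsum(c(0, head(dur, -1) + gap)) / 1000
      spikes <- lapply(seq_len(k), function(j) {
        if (m[j] == 1) start[j] else start[j] + seq(0, dur[j] / 1000, length.out = m[j])
      })
      ep[[e]] <- list(start = start, dur = dur / 1000, m = m, spikes = spikes,
                      span = start[k] + dur[k] / 1000)
    }

    spans <- vapply(ep, function(x) x$span, numeric(1))
    min_gap <- 0.110
    free <- params$recording_duration - sum(spans) - min_gap * (n_ep - 1)
    if (free < 0) {
      abort("cannot fit the requested episodes in the recording window")
    }
    w <- diff(c(0, sort(runif(n_ep)))) * free
    ep_start <- numeric(n_ep)
    t0 <- 0
    for (e in seq_len(n_ep)) {
      ep_start[e] <- t0 + w[e]
      t0 <- ep_start[e] + spans[e] + min_gap
    }

    burst_offset <- c(0L, cumsum(k_bursts))
    bursts <- map_dfr(seq_len(n_ep), function(e) {
      tibble(
        episode = e, burst = burst_offset[e] + seq_along(ep[[e]]$start),
        start = ep_start[e] + ep[[e]]$start,
        end = ep_start[e] + ep[[e]]$start + ep[[e]]$dur,
        n_spikes = ep[[e]]$m, duration_ms = ep[[e]]$dur * 1000
      )
    })
    spikes <- map_dfr(seq_len(n_ep), function(e) {
      tibble(
        time = ep_start[e] + unlist(ep[[e]]$spikes),
        burst = burst_offset[e] + rep(seq_along(ep[[e]]$m), ep[[e]]$m),
        episode = e
      )
    })
    episodes <- bursts |>
      group_by(.data$episode) |>
      summarise(n_bursts = dplyr::n(), start = min(.data$start),
                end = max(.data$end), .groups = "drop")

    spike_times <- sort(spikes$time)
    trace <- if (include_trace) render_trace(spike_times, params) else NULL
  })
  structure(
    list(spike_times = spike_times,
         ground_truth = list(spikes = arrange(spikes, .data$time),
                             bursts = bursts, episodes = episodes),
         trace = trace, params = params),
    class = "sim_spike_train"
  )
}

# Voltage trace = gaussian baseline + a sharp-onset kernel at each spike
# sample, so a rising-edge threshold detector fires at the spike sample.
render_trace <- function(spike_times, params) {
  fs <- params$sample_rate
  n <- round(params$recording_duration * fs)
  v <- rnorm(n, 0, params$noise_sd)
  kernel <- params$spike_amplitude * c(1, 0.6, 0.3, 0.1)
  for (t in spike_times) {
    i <- round(t * fs) + 1
    idx <- i:min(i + 3, n)
    v[idx] <- v[idx] + kernel[seq_along(idx)]
  }
  out <- tibble(time = (seq_len(n) - 1) / fs, voltage = v)
  attr(out, "sample_rate") <- fs
  class(out) <- c("voltage_trace", class(out))
  out
}

#' Simulate a dose-survival table
#'
#' Expected survival follows a logistic (Hill-type) dose-response,
#' `1 / (1 + (dose / lc50)^hill_slope)`, which equals exactly 0.5 at
#' `dose = lc50`; surviving counts per dose are binomial draws.
#'
#' @param params A [survival_params()] object.
#' @return A `dose_survival` tibble: dose, n, surviving, fraction.
#' @examples
#' simulate_survival(survival_params(seed = 11))
#' @export
simulate_survival <- function(params) {
  stopifnot(inherits(params, "survival_params"))
  p <- expected_survival(params$doses, params$lc50, params$hill_slope)
  withr::with_seed(derive_seed(params$seed, 3), {
    surv <- rbinom(length(params$doses), params$n_per_dose, p)
  })
  out <- tibble(
    dose = params$doses, n = params$n_per_dose, surviving = surv,
    fraction = surv / params$n_per_dose
  )
  class(out) <- c("dose_survival", class(out))
  out
}

#' Simulate behavioral phenotype counts
#'
#' Per condition, per batch, per phenotype: the number of larvae scored as
#' presenting the phenotype, drawn binomially with the condition's
#' phenotype probability.
#'
#' @param params A [behavior_count_params()] object.
#' @return A `behavior_counts` tibble: condition, batch, phenotype,
#'   affected, total.
#' @examples
#' simulate_behavior_counts(behavior_count_params(seed = 5))
#' @export
simulate_behavior_counts <- function(params) {
  stopifnot(inherits(params, "behavior_count_params"))
  grid <- tidyr::expand_grid(
    condition = params$conditions,
    batch = seq_len(params$batches),
    phenotype = names(params$phenotype_probabilities[[1]])
  )
  probs <- map_dbl(seq_len(nrow(grid)), function(i) {
    params$phenotype_probabilities[[grid$condition[i]]][[grid$phenotype[i]]]
  })
  withr::with_seed(derive_seed(params$seed, 4), {
    affected <- rbinom(nrow(grid), params$larvae_per_batch, probs)
  })
  out <- mutate(grid, affected = affected, total = params$larvae_per_batch)
  class(out) <- c("behavior_counts", class(out))
  out
}
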