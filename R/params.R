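# Parameter objects for the synthetic-data generators. Each constructor
# validates its invariants up front so downstream simulators can assume a
# well-formed parameter set.

check_number <- function(x, name, min = -Inf, strict = FALSE, len = 1) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric of length %d", name, len))
  }
  bad <- if (strict) any(x <= min) else any(x < min)
  if (bad) {
    abort(sprintf(
      "`%s` must be %s %s", name, if (strict) ">" else ">=", format(min)
    ))
  }
  invisible(x)
}

check_range <- function(x, name, lo, hi) {
  check_number(x, name, len = 2)
  if (x[1] > x[2] || x[1] <= lo || x[2] >= hi) {
    abort(sprintf(
      "`%s` must be an increasing range strictly inside (%s, %s)",
      name, format(lo), format(hi)
    ))
  }
  invisible(x)
}

# A count distribution is either a fixed count (length 1) or an inclusive
# integer range (length 2) sampled uniformly.
check_count_dist <- function(x, name, min = 1) {
  if (!is.numeric(x) || !length(x) %in% c(1, 2) || any(x != round(x)) ||
      any(x < min) || (length(x) == 2 && x[1] > x[2])) {
    abort(sprintf(
      "`%s` must be a fixed count or an increasing integer range, all >= %d",
      name, min
    ))
  }
  invisible(as.integer(x))
}

draw_counts <- function(dist, n) {
  if (length(dist) == 1) rep(dist, n) else sample(seq(dist[1], dist[2]), n, replace = TRUE)
}

# Truncated-normal draws by inverse-CDF so a single runif stream drives them.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) {
    return(pmin(pmax(rep_len(mean, n), lower), upper))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Deterministic substream seeds derived from one user-facing seed, kept
# below 2^31 so they are valid R integers.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 2^31 * 69069 + 12345 + offset) %% 2147483647)
}

#' Parameters for the synthetic tail-trajectory generator
#'
#' Defines a 20-s, 300-fps recording of a head-embedded larva whose body
#' angle rests near 180 deg, with clustered low-amplitude wags
#' (peak angle < 200 deg) and sparse large-angle movements
#' (LAMs, peak angle in 200-270 deg). Defaults reproduce a control larva:
#' on average 13.2 LAMs of 57 ms mean duration per 20-s window, wags of
#' about 40 ms. Use [trajectory_preset()] for the manganese-treated and
#' recovered phenotypes.
#'
#' @param frame_rate Frames per second (default 300).
#' @param duration Recording duration in seconds (default 20).
#' @param rest_angle Resting body angle in degrees; fixed at 180.
#' @param rest_jitter_sd Standard deviation (degrees) of the small
#'   frame-to-frame excursions around rest.
#' @param wag_cluster_rate Wag clusters per second.
#' @param wags_per_cluster Fixed count or inclusive integer range of wags in
#'   one cluster.
#' @param wag_peak_range Range (degrees) of wag peak angles, strictly inside
#'   (180, 200).
#' @param wag_duration_mean,wag_duration_sd Wag duration mean and sd in ms.
#' @param lam_rate Expected number of LAMs per recording window (Poisson).
#' @param lam_duration_mean,lam_duration_sd LAM duration mean and sd in ms.
#' @param lam_peak_range Range (degrees) of LAM peak angles, strictly inside
#'   (200, 270).
#' @param laterality_mode One of `"alternating"`, `"unilateral"`, `"mixed"`:
#'   whether successive events alternate left/right, stay on one side, or are
#'   assigned a random side.
#' @param seed Integer seed; the generator is bit-reproducible given
#'   (params, seed).
#' @return A `trajectory_params` list.
#' @seealso [simulate_trajectory()], [trajectory_preset()]
#' @export
trajectory_params <- function(frame_rate = 300,
                              duration = 20,
                              rest_angle = 180,
                              rest_jitter_sd = 0.5,
                              wag_cluster_rate = 0.8,
                              wags_per_cluster = c(3L, 8L),
                              wag_peak_range = c(187, 195),
                              wag_duration_mean = 39.8,
                              wag_duration_sd = 5,
                              lam_rate = 13.2,
                              lam_duration_mean = 57,
                              lam_duration_sd = 10,
                              lam_peak_range = c(210, 260),
                              laterality_mode = c("alternating", "unilateral", "mixed"),
                              seed = 1L) {
  laterality_mode <- match.arg(laterality_mode)
  check_number(frame_rate, "frame_rate", 0, strict = TRUE)
  check_number(duration, "duration", 0, strict = TRUE)
  if (!identical(as.numeric(rest_angle), 180)) {
    abort("`rest_angle` is fixed at 180 degrees (the collinear resting posture)")
  }
  check_number(rest_jitter_sd, "rest_jitter_sd", 0)
  check_number(wag_cluster_rate, "wag_cluster_rate", 0)
  check_count_dist(wags_per_cluster, "wags_per_cluster")
  check_range(wag_peak_range, "wag_peak_range", 180, 200)
  check_number(wag_duration_mean, "wag_duration_mean", 0, strict = TRUE)
  check_number(wag_duration_sd, "wag_duration_sd", 0)
  check_number(lam_rate, "lam_rate", 0)
  check_number(lam_duration_mean, "lam_duration_mean", 0, strict = TRUE)
  check_number(lam_duration_sd, "lam_duration_sd", 0)
  check_range(lam_peak_range, "lam_peak_range", 200, 270)
  structure(
    list(
      frame_rate = frame_rate, duration = duration, rest_angle = 180,
      rest_jitter_sd = rest_jitter_sd, wag_cluster_rate = wag_cluster_rate,
      wags_per_cluster = as.integer(wags_per_cluster),
      wag_peak_range = wag_peak_range,
      wag_duration_mean = wag_duration_mean, wag_duration_sd = wag_duration_sd,
      lam_rate = lam_rate, lam_duration_mean = lam_duration_mean,
      lam_duration_sd = lam_duration_sd, lam_peak_range = lam_peak_range,
      laterality_mode = laterality_mode, seed = as.integer(seed)
    ),
    class = "trajectory_params"
  )
}

#' Trajectory presets for the three study phenotypes
#'
#' Control larvae show frequent, short LAMs with alternating left/right
#' beats; manganese-treated larvae show rare, long, unilateral LAMs; larvae
#' recovered in clean medium return to control-like kinematics. Group means
#' behind the presets: LAM counts per 20 s of 13.2 (control), 2 (Mn-treated)
#' and 15.3 (recovered); LAM durations of 57, 163.4 and 54.7 ms; wag
#' durations of 39.8 and 36.9 ms (control vs Mn).
#'
#' @param preset `"control"`, `"mn"`, or `"recovered"`.
#' @param ... Overrides passed on to [trajectory_params()].
#' @return A `trajectory_params` list.
#' @export
trajectory_preset <- function(preset = c("control", "mn", "recovered"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    control = list(
      lam_rate = 13.2, lam_duration_mean = 57, lam_duration_sd = 10,
      wag_duration_mean = 39.8, laterality_mode = "alternating"
    ),
    mn = list(
      lam_rate = 2, lam_duration_mean = 163.4, lam_duration_sd = 30,
      wag_duration_mean = 36.9, wag_cluster_rate = 0.4,
      laterality_mode = "unilateral"
    ),
    recovered = list(
      lam_rate = 15.3, lam_duration_mean = 54.7, lam_duration_sd = 10,
      wag_duration_mean = 39.8, laterality_mode = "alternating"
    )
  )
  do.call(trajectory_params, utils::modifyList(base, list(...)))
}

#' Parameters for the synthetic fictive-swim spike-train generator
#'
#' Emulates a 2-minute extracellular recording of spontaneous fictive swim
#' motor patterns: episodes (swim bouts) separated by quiescent gaps longer
#' than 100 ms, each containing rhythmic bursts whose intra-burst
#' inter-spike intervals are below 10 ms and whose inter-burst gaps fall in
#' the 10-100 ms band, so the generated ground truth is a valid segmentation
#' under the same ISI rules the analysis applies.
#'
#' @param recording_duration Recording length in seconds (default 120).
#' @param episode_rate Episodes per minute (Poisson).
#' @param bursts_per_episode Fixed count or integer range.
#' @param burst_period_mean,burst_period_sd Time between successive burst
#'   starts within an episode, ms.
#' @param burst_duration_mean,burst_duration_sd Burst duration, ms; must be
#'   shorter than the period so inter-burst gaps stay in the episode band.
#' @param spikes_per_burst Fixed count or integer range.
#' @param spike_amplitude Spike waveform amplitude, mV.
#' @param noise_sd Baseline gaussian noise sd, mV.
#' @param sample_rate Voltage-trace sampling rate, Hz.
#' @param seed Integer seed.
#' @return A `spike_train_params` list.
#' @seealso [simulate_spike_train()], [spike_train_preset()]
#' @export
spike_train_params <- function(recording_duration = 120,
                               episode_rate = 6,
                               bursts_per_episode = c(6L, 12L),
                               burst_period_mean = 35,
                               burst_period_sd = 4,
                               burst_duration_mean = 10,
                               burst_duration_sd = 1.5,
                               spikes_per_burst = c(3L, 5L),
                               spike_amplitude = 1,
                               noise_sd = 0.05,
                               sample_rate = 10000,
                               seed = 1L) {
  check_number(recording_duration, "recording_duration", 0, strict = TRUE)
  check_number(episode_rate, "episode_rate", 0)
  check_count_dist(bursts_per_episode, "bursts_per_episode")
  check_number(burst_period_mean, "burst_period_mean", 0, strict = TRUE)
  check_number(burst_period_sd, "burst_period_sd", 0)
  check_number(burst_duration_mean, "burst_duration_mean", 0, strict = TRUE)
  check_number(burst_duration_sd, "burst_duration_sd", 0)
  check_count_dist(spikes_per_burst, "spikes_per_burst")
  check_number(spike_amplitude, "spike_amplitude", 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  check_number(sample_rate, "sample_rate", 0, strict = TRUE)
  if (burst_duration_mean >= burst_period_mean) {
    abort("requested structure violates ISI bands: burst_duration_mean must be < burst_period_mean")
  }
  gap <- burst_period_mean - burst_duration_mean
  if (gap <= 10 || gap >= 100) {
    abort("requested structure violates ISI bands: mean inter-burst gap (period - duration) must lie in (10, 100) ms")
  }
  m <- max(spikes_per_burst)
  if (m > 1 && burst_duration_mean / (m - 1) >= 10) {
    abort("requested structure violates ISI bands: intra-burst ISI (duration / (spikes - 1)) must be < 10 ms")
  }
  structure(
    list(
      recording_duration = recording_duration, episode_rate = episode_rate,
      bursts_per_episode = as.integer(bursts_per_episode),
      burst_period_mean = burst_period_mean, burst_period_sd = burst_period_sd,
      burst_duration_mean = burst_duration_mean,
      burst_duration_sd = burst_duration_sd,
      spikes_per_burst = as.integer(spikes_per_burst),
      spike_amplitude = spike_amplitude, noise_sd = noise_sd,
      sample_rate = sample_rate, seed = as.integer(seed)
    ),
    class = "spike_train_params"
  )
}

#' Fictive-swim presets for the three study phenotypes
#'
#' Manganese-treated larvae produce long-duration bursts at a slower cycle
#' period with fewer episodes than controls; recovered larvae return to
#' control-like patterns. The numeric defaults are modeling choices (the
#' phenotype contrasts, not their exact values, are the constraint).
#'
#' @inheritParams trajectory_preset
#' @return A `spike_train_params` list.
#' @export
spike_train_preset <- function(preset = c("control", "mn", "recovered"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    control = list(
      episode_rate = 6, burst_period_mean = 35, burst_duration_mean = 10,
      spikes_per_burst = c(3L, 5L)
    ),
    mn = list(
      episode_rate = 3, burst_period_mean = 70, burst_period_sd = 6,
      burst_duration_mean = 25, burst_duration_sd = 3,
      spikes_per_burst = c(4L, 7L), bursts_per_episode = c(3L, 8L)
    ),
    recovered = list(
      episode_rate = 6, burst_period_mean = 36, burst_duration_mean = 11,
      spikes_per_burst = c(3L, 5L)
    )
  )
  do.call(spike_train_params, utils::modifyList(base, list(...)))
}

#' Parameters for the synthetic dose-survival generator
#'
#' Survival after a fixed exposure follows a logistic (Hill-type)
#' dose-response with 50% survival at `lc50`; per-dose surviving counts are
#' binomial. Default doses span 0.2-10 mM as in a dose-ranging series.
#'
#' @param lc50 Concentration (mM) at which expected survival is 50%.
#' @param hill_slope Dimensionless steepness of the logistic in log-dose.
#' @param doses Vector of tested doses, mM (non-negative, distinct).
#' @param n_per_dose Larvae per dose.
#' @param seed Integer seed.
#' @return A `survival_params` list.
#' @seealso [simulate_survival()], [lc50_estimate()]
#' @export
survival_params <- function(lc50 = 2,
                            hill_slope = 4,
                            doses = c(0.2, 0.5, 1, 2, 4, 6, 10),
                            n_per_dose = 20,
                            seed = 1L) {
  check_number(lc50, "lc50", 0, strict = TRUE)
  check_number(hill_slope, "hill_slope", 0, strict = TRUE)
  check_number(doses, "doses", 0, len = length(doses))
  if (length(doses) < 2 || anyDuplicated(doses)) {
    abort("`doses` must contain at least two distinct values")
  }
  check_number(n_per_dose, "n_per_dose", 1)
  p <- expected_survival(sort(doses), lc50, hill_slope)
  if (!(min(p) < 0.5 && max(p) > 0.5)) {
    abort("no dose pair brackets 50% survival in expectation; widen `doses`")
  }
  structure(
    list(
      lc50 = lc50, hill_slope = hill_slope, doses = sort(doses),
      n_per_dose = as.integer(n_per_dose), seed = as.integer(seed)
    ),
    class = "survival_params"
  )
}

expected_survival <- function(dose, lc50, hill_slope) {
  ifelse(dose <= 0, 1, 1 / (1 + (dose / lc50)^hill_slope))
}

#' Parameters for the synthetic behavioral-scoring generator
#'
#' Larvae are scored per batch as presenting or not presenting each
#' phenotype (sideways floating, curved spine, spontaneous circling,
#' circling on tap); counts are binomial within batches of 20. Default
#' probabilities follow the study proportions: 98% sideways floating and
#' 65% curved spine in Mn-treated larvae versus 12% and 27% after recovery,
#' and none in controls.
#'
#' @param conditions Condition labels.
#' @param batches Batches per condition (default 3).
#' @param larvae_per_batch Larvae per batch (default 20).
#' @param phenotype_probabilities Named list: one named numeric vector of
#'   per-phenotype probabilities per condition. All conditions must share
#'   the same phenotype names.
#' @param seed Integer seed.
#' @return A `behavior_count_params` list.
#' @seealso [simulate_behavior_counts()], [chi_square_counts()]
#' @export
behavior_count_params <- function(conditions = c("control", "mn", "recovered"),
                                  batches = 3,
                                  larvae_per_batch = 20,
                                  phenotype_probabilities = NULL,
                                  seed = 1L) {
  if (is.null(phenotype_probabilities)) {
    phenotype_probabilities <- list(
      control = c(sideways_floating = 0, curved_spine = 0,
                  circling_spontaneous = 0, circling_on_tap = 0),
      mn = c(sideways_floating = 0.98, curved_spine = 0.65,
             circling_spontaneous = 0.95, circling_on_tap = 0.95),
      recovered = c(sideways_floating = 0.12, curved_spine = 0.27,
                    circling_spontaneous = 0, circling_on_tap = 0.40)
    )[conditions]
    if (any(vapply(phenotype_probabilities, is.null, logical(1)))) {
      abort("no default probabilities for these conditions; supply `phenotype_probabilities`")
    }
  }
  if (!is.list(phenotype_probabilities) ||
      !setequal(names(phenotype_probabilities), conditions)) {
    abort("`phenotype_probabilities` must be a named list with one entry per condition")
  }
  phen <- names(phenotype_probabilities[[1]])
  for (cond in conditions) {
    p <- phenotype_probabilities[[cond]]
    if (!is.numeric(p) || !identical(names(p), phen) || any(p < 0 | p > 1)) {
      abort("each probability vector must share phenotype names and lie in [0, 1]")
    }
  }
  check_number(batches, "batches", 1)
  check_number(larvae_per_batch, "larvae_per_batch", 1)
  structure(
    list(
      conditions = conditions, batches = as.integer(batches),
      larvae_per_batch = as.integer(larvae_per_batch),
      phenotype_probabilities = phenotype_probabilities[conditions],
      seed = as.integer(seed)
    ),
    class = "behavior_count_params"
  )
}
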