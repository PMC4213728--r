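# End-to-end demo pipeline: simulate the three phenotypes, run kinematics,
# fictive segmentation and the statistics layer, and write every table,
# report and a manifest so reruns with an identical config are
# byte-identical.

#' Build and validate a pipeline configuration
#'
#' Collects every tunable of the pipeline with defaults anchored to the
#' study conditions: 300 fps, 20-s kinematic windows, 200/270 degree class
#' bounds via the detector, a 5-degree rest band, 10/100 ms ISI limits and
#' 2-minute fictive recordings. Validation happens here, before any stage
#' runs.
#'
#' @param presets Phenotype presets to simulate and compare.
#' @param seed Integer seed driving every generator substream.
#' @param stages Which stages to run.
#' @param frame_rate,duration,window,rest_band,min_duration Kinematics
#'   settings (fps, s, s, degrees, frames).
#' @param median_filter Apply the optional 3-frame median filter before
#'   event detection.
#' @param recording_duration Fictive recording length, s.
#' @param intra_burst_isi_max,episode_isi_max ISI limits, ms.
#' @param spike_threshold `"auto"` or a numeric threshold, mV.
#' @param refractory Spike refractory interval, ms.
#' @param lc50_method `"interpolation"` or `"logistic"`.
#' @param trajectory_overrides,spike_overrides Named lists of per-preset
#'   overrides forwarded to [trajectory_preset()] / [spike_train_preset()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(presets = c("control", "mn", "recovered"),
                       seed = 1L,
                       stages = c("simulate", "kinematics", "fictive", "stats"),
                       frame_rate = 300, duration = 20, window = 20,
                       rest_band = 5, min_duration = 3, median_filter = FALSE,
                       recording_duration = 120,
                       intra_burst_isi_max = 10, episode_isi_max = 100,
                       spike_threshold = "auto", refractory = 1,
                       lc50_method = "interpolation",
                       trajectory_overrides = list(),
                       spike_overrides = list()) {
  presets <- match.arg(presets, several.ok = TRUE)
  stages <- match.arg(stages, several.ok = TRUE)
  check_number(seed, "seed")
  check_number(window, "window", 0, strict = TRUE)
  check_number(rest_band, "rest_band", 0, strict = TRUE)
  check_number(min_duration, "min_duration", 1)
  if (!intra_burst_isi_max < episode_isi_max) {
    abort("intra_burst_isi_max must be smaller than episode_isi_max")
  }
  lc50_method <- match.arg(lc50_method, c("interpolation", "logistic"))
  # building the parameter objects validates every generator tunable
  # (e.g. inverted LAM peak bounds fail here, before any stage runs)
  traj <- lapply(presets, function(p) {
    do.call(trajectory_preset, c(
      list(preset = p, frame_rate = frame_rate, duration = duration,
           seed = derive_seed(seed, match(p, presets))),
      trajectory_overrides
    ))
  })
  spk <- lapply(presets, function(p) {
    do.call(spike_train_preset, c(
      list(preset = p, recording_duration = recording_duration,
           seed = derive_seed(seed, 10 + match(p, presets))),
      spike_overrides
    ))
  })
  structure(
    list(presets = presets, seed = as.integer(seed), stages = stages,
         frame_rate = frame_rate, duration = duration, window = window,
         rest_band = rest_band, min_duration = min_duration,
         median_filter = median_filter,
         recording_duration = recording_duration,
         intra_burst_isi_max = intra_burst_isi_max,
         episode_isi_max = episode_isi_max,
         spike_threshold = spike_threshold, refractory = refractory,
         lc50_method = lc50_method,
         trajectory_params = stats::setNames(traj, presets),
         spike_params = stats::setNames(spk, presets)),
    class = "run_config"
  )
}

#' Run the full demo pipeline
#'
#' Executes the selected stages for each phenotype preset: simulate tail
#' trajectories and fictive recordings; detect and classify movement
#' events; segment spikes into bursts and episodes and compute burst
#' metrics; run the statistics layer (Kruskal-Wallis on LAM durations
#' across presets, chi-square phenotype scoring, LC50 estimation on a
#' simulated dose-survival table). Writes per-preset tracks, event tables,
#' spike lists, metrics reports, a statistics report and a manifest
#' recording the package version, seed and every parameter. Reruns with an
#' identical config produce byte-identical outputs.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results; files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output directory %s", out_dir))
  res <- list(config = config)

  if ("simulate" %in% config$stages) {
    res$trajectories <- lapply(config$trajectory_params, simulate_trajectory)
    res$spike_trains <- lapply(config$spike_params, simulate_spike_train,
                               include_trace = FALSE)
    res$survival <- simulate_survival(
      survival_params(seed = derive_seed(config$seed, 20))
    )
    res$behavior <- simulate_behavior_counts(
      behavior_count_params(conditions = config$presets,
                            seed = derive_seed(config$seed, 21))
    )
    for (p in config$presets) {
      write_track(res$trajectories[[p]]$track,
                  file.path(out_dir, paste0("track_", p, ".csv")))
      write_spikes(res$spike_trains[[p]]$spike_times,
                   file.path(out_dir, paste0("spikes_", p, ".txt")))
    }
    readr::write_csv(res$survival, file.path(out_dir, "survival.csv"),
                     progress = FALSE)
    readr::write_csv(res$behavior, file.path(out_dir, "behavior_counts.csv"),
                     progress = FALSE)
  }

  if ("kinematics" %in% config$stages) {
    res$events <- lapply(config$presets, function(p) {
      trace <- compute_body_angle(res$trajectories[[p]]$track)
      detect_events(trace, rest_band = config$rest_band,
                    min_duration = config$min_duration,
                    median_filter = config$median_filter)
    })
    names(res$events) <- config$presets
    res$kin_summaries <- lapply(res$events, summarize_events,
                                window = config$window)
    for (p in config$presets) {
      write_events(res$events[[p]],
                   file.path(out_dir, paste0("events_", p, ".csv")))
      write_report(res$kin_summaries[[p]],
                   file.path(out_dir, paste0("kinematics_", p, ".txt")))
    }
  }

  if ("fictive" %in% config$stages) {
    res$segmentations <- lapply(config$presets, function(p) {
      segment_spikes(res$spike_trains[[p]]$spike_times,
                     intra_burst_isi_max = config$intra_burst_isi_max,
                     episode_isi_max = config$episode_isi_max)
    })
    names(res$segmentations) <- config$presets
    res$burst_metrics <- lapply(res$segmentations, burst_metrics)
    for (p in config$presets) {
      readr::write_csv(res$segmentations[[p]]$bursts,
                       file.path(out_dir, paste0("bursts_", p, ".csv")),
                       progress = FALSE)
      write_report(res$burst_metrics[[p]],
                   file.path(out_dir, paste0("fictive_", p, ".txt")))
    }
  }

  if ("stats" %in% config$stages) {
    stats_out <- list()
    if (!is.null(res$kin_summaries) && length(config$presets) >= 2) {
      dur <- map_dfr(config$presets, function(p) {
        tibble(group = p,
               value = res$kin_summaries[[p]]$lam_durations * 1000)
      })
      if (all(table(dur$group) > 0) && length(unique(dur$group)) >= 2) {
        stats_out$lam_duration_kw <- kruskal_wallis(dur)
      }
    }
    if (!is.null(res$behavior)) {
      float <- filter(res$behavior, .data$phenotype == "sideways_floating")
      stats_out$floating_chisq <- tryCatch(
        chi_square_counts(float), error = function(e) NULL
      )
    }
    if (!is.null(res$survival)) {
      stats_out$lc50 <- lc50_estimate(res$survival, method = config$lc50_method)
    }
    res$stats <- stats_out
    report <- bind_rows(
      if (!is.null(stats_out$lam_duration_kw))
        mutate(stats_out$lam_duration_kw, analysis = "lam_duration_across_presets"),
      if (!is.null(stats_out$floating_chisq))
        mutate(stats_out$floating_chisq, analysis = "sideways_floating_scoring"),
      if (!is.null(stats_out$lc50))
        tibble(analysis = "lc50_mM", statistic = stats_out$lc50$lc50,
               method = stats_out$lc50$method)
    )
    write_report(as.data.frame(report), file.path(out_dir, "statistics.txt"))
  }

  write_manifest(config, file.path(out_dir, "manifest.txt"))
  invisible(res)
}

# One manifest per run: package version, seed, and every tunable including
# the full per-preset generator parameter sets.
write_manifest <- function(config, path) {
  flat <- function(p) {
    lapply(p, function(v) if (is.list(v)) unlist(v) else v)
  }
  sections <- list(
    run = list(
      package = "larvamotor",
      version = as.character(packageVersion("larvamotor")),
      seed = config$seed,
      presets = config$presets,
      stages = config$stages,
      frame_rate = config$frame_rate,
      duration_s = config$duration,
      window_s = config$window,
      rest_band_deg = config$rest_band,
      min_duration_frames = config$min_duration,
      median_filter = config$median_filter,
      recording_duration_s = config$recording_duration,
      intra_burst_isi_max_ms = config$intra_burst_isi_max,
      episode_isi_max_ms = config$episode_isi_max,
      spike_threshold = config$spike_threshold,
      refractory_ms = config$refractory,
      lc50_method = config$lc50_method
    )
  )
  for (p in config$presets) {
    sections[[paste0("trajectory_", p)]] <-
      flat(unclass(config$trajectory_params[[p]]))
    sections[[paste0("spike_train_", p)]] <-
      flat(unclass(config$spike_params[[p]]))
  }
  write_report_lines(sections, path)
}
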