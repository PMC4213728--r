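# Plain-text readers and writers: comma-separated tables for tracks,
# traces, survival and count data; one-spike-time-per-line text; structured
# key-value reports. All inputs are validated with line numbers on failure.

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) {
    warn(sprintf("empty %s file: %s", what, path))
    return(tibble())
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s file %s lacks columns: %s", what, path,
                  paste(missing, collapse = ", ")))
  }
  for (col in required) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      abort(sprintf("%s file %s: non-numeric or missing `%s` at data line %d",
                    what, path, col, bad[1]))
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Read a tracked-point table
#'
#' Reads a comma-separated table with header
#' `frame,Hx,Hy,Mx,My,Tx,Ty` into a `point_track`. Frames where H or T
#' coincides with M are rejected with the offending line number.
#'
#' @param path File path.
#' @param frame_rate Frames per second of the recording.
#' @return A `point_track` tibble (empty, with a warning, for an empty
#'   file).
#' @export
read_track <- function(path, frame_rate = 300) {
  check_number(frame_rate, "frame_rate", 0, strict = TRUE)
  cols <- c("frame", "Hx", "Hy", "Mx", "My", "Tx", "Ty")
  df <- read_csv_checked(path, cols, "track")
  if (nrow(df) == 0) {
    return(new_point_track(
      tibble(frame = integer(0), Hx = numeric(0), Hy = numeric(0),
             Mx = numeric(0), My = numeric(0), Tx = numeric(0),
             Ty = numeric(0)),
      frame_rate
    ))
  }
  deg <- which((df$Hx == df$Mx & df$Hy == df$My) |
               (df$Tx == df$Mx & df$Ty == df$My))
  if (length(deg)) {
    abort(sprintf("track file %s: degenerate frame at data line %d (H or T coincides with M)",
                  path, deg[1]))
  }
  new_point_track(df[cols], frame_rate)
}

#' Write a tracked-point table
#' @param track A `point_track` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  readr::write_csv(track, path, progress = FALSE)
  invisible(path)
}

#' Read spike times (one time in seconds per line)
#'
#' @param path File path.
#' @return Numeric vector of strictly increasing spike times (empty, with a
#'   warning, for an empty file).
#' @export
read_spikes <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn(sprintf("empty spike file: %s", path))
    return(numeric(0))
  }
  times <- suppressWarnings(as.numeric(lines))
  if (anyNA(times)) {
    abort(sprintf("spike file %s: non-numeric value at line %d",
                  path, which(is.na(times))[1]))
  }
  bad <- which(diff(times) <= 0)
  if (length(bad)) {
    abort(sprintf("spike file %s: times not strictly increasing at line %d",
                  path, bad[1] + 1))
  }
  times
}

#' Write spike times, one per line
#' @param spike_times Numeric vector, seconds.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spike_times, path) {
  readr::write_lines(format_num(spike_times, 6), path)
  invisible(path)
}

#' Read a time,voltage trace table
#' @param path File path to a comma-separated table with header
#'   `time,voltage`.
#' @return A `voltage_trace` tibble with a `sample_rate` attribute inferred
#'   from the time column.
#' @export
read_trace <- function(path) {
  df <- read_csv_checked(path, c("time", "voltage"), "trace")
  if (nrow(df) == 0) {
    out <- tibble(time = numeric(0), voltage = numeric(0))
  } else {
    bad <- which(diff(df$time) <= 0)
    if (length(bad)) {
      abort(sprintf("trace file %s: time not strictly increasing at data line %d",
                    path, bad[1] + 1))
    }
    out <- df[c("time", "voltage")]
    attr(out, "sample_rate") <- 1 / median(diff(df$time))
  }
  class(out) <- c("voltage_trace", class(out))
  out
}

#' Read a dose-survival table
#' @param path Comma-separated table with header `dose,fraction` or
#'   `dose,surviving,n`.
#' @return A `dose_survival` tibble.
#' @export
read_dose_survival <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("dose", "surviving", "n") %in% names(df))) {
    df <- read_csv_checked(path, c("dose", "surviving", "n"), "dose-survival")
    df$fraction <- df$surviving / df$n
  } else {
    df <- read_csv_checked(path, c("dose", "fraction"), "dose-survival")
  }
  class(df) <- c("dose_survival", class(df))
  df
}

#' Read a behavioral count table
#' @param path Comma-separated table with header
#'   `condition,batch,phenotype,affected,total`.
#' @return A `behavior_counts` tibble.
#' @export
read_behavior_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("condition", "batch", "phenotype", "affected", "total")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("count file %s lacks columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (any(df$affected < 0 | df$affected > df$total)) {
    abort(sprintf("count file %s: affected outside [0, total] at data line %d",
                  path, which(df$affected < 0 | df$affected > df$total)[1]))
  }
  class(df) <- c("behavior_counts", class(df))
  df
}

format_num <- function(x, digits) {
  formatC(x, digits = digits, format = "f", drop0trailing = FALSE)
}

#' Write a movement-event table
#'
#' Stable column order `onset_s,offset_s,duration_ms,peak_deg,direction,class`
#' at fixed precision (times to 0.01 ms, angles to 0.01 degrees). An empty
#' event list yields a header-only file.
#'
#' @param events A `movement_events` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- tibble(
    onset_s = format_num(events$onset, 5),
    offset_s = format_num(events$offset, 5),
    duration_ms = format_num(events$duration_ms, 2),
    peak_deg = format_num(events$peak_angle, 2),
    direction = events$direction,
    class = events$event_class
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Structured key-value report: one `key: value` per line, sections as
# `[name]`. Used for summaries, metrics, statistics and manifests.
write_report_lines <- function(sections, path) {
  lines <- unlist(lapply(names(sections), function(nm) {
    vals <- sections[[nm]]
    c(sprintf("[%s]", nm),
      vapply(names(vals), function(k) {
        v <- vals[[k]]
        v <- if (is.numeric(v)) paste(format(v, digits = 10), collapse = " ")
             else paste(as.character(v), collapse = " ")
        sprintf("%s: %s", k, v)
      }, character(1)),
      "")
  }))
  readr::write_lines(lines, path)
  invisible(path)
}

fmt_p <- function(p) signif(p, 3)

#' Write a structured-text report for an analysis result
#'
#' Serializes a result object (`kinematics_summary`, `burst_metrics`,
#' `lc50_fit` or a statistics tibble) as human-auditable `key: value`
#' sections, with numbers at fixed precision (angles 0.01 degrees, times
#' 0.01 ms, p-values 3 significant figures). Undefined quantities (e.g. a
#' burst period when every episode holds one burst) are written as NA,
#' never 0.
#'
#' @param results A supported result object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  UseMethod("write_report")
}

#' @export
write_report.kinematics_summary <- function(results, path) {
  st <- results$stats
  write_report_lines(list(
    kinematics_summary = list(
      window_s = results$window,
      n_windows = nrow(results$counts),
      lam_count_per_window = results$counts$lam_count,
      wag_count_per_window = results$counts$wag_count,
      extreme_count_per_window = results$counts$extreme_count,
      lam_n = st$n[st$event_class == "LAM"],
      lam_mean_ms = round(st$mean_ms[st$event_class == "LAM"], 2),
      lam_sem_ms = round(st$sem_ms[st$event_class == "LAM"], 2),
      wag_n = st$n[st$event_class == "wag"],
      wag_mean_ms = round(st$mean_ms[st$event_class == "wag"], 2),
      wag_sem_ms = round(st$sem_ms[st$event_class == "wag"], 2)
    )
  ), path)
}

#' @export
write_report.burst_metrics <- function(results, path) {
  s <- results$summary
  row <- function(m, f) {
    v <- s[[f]][s$metric == m]
    if (length(v) == 0 || is.na(v)) NA else round(v, 2)
  }
  write_report_lines(list(
    burst_metrics = list(
      n_bursts = nrow(results$bursts),
      n_episodes = nrow(results$per_episode),
      spikes_per_burst_mean = row("spikes_per_burst", "mean"),
      spikes_per_burst_sem = row("spikes_per_burst", "sem"),
      burst_duration_ms_mean = row("burst_duration_ms", "mean"),
      burst_duration_ms_sem = row("burst_duration_ms", "sem"),
      burst_period_ms_mean = row("burst_period_ms", "mean"),
      burst_period_ms_sem = row("burst_period_ms", "sem"),
      bursts_per_episode_mean = row("bursts_per_episode", "mean"),
      bursts_per_episode_sem = row("bursts_per_episode", "sem")
    )
  ), path)
}

#' @export
write_report.lc50_fit <- function(results, path) {
  write_report_lines(list(
    lc50 = list(
      lc50 = round(results$lc50, 4),
      method = results$method,
      note = results$note
    )
  ), path)
}

#' @export
write_report.data.frame <- function(results, path) {
  vals <- lapply(seq_len(nrow(results)), function(i) {
    row <- as.list(results[i, ])
    lapply(row, function(v) if (is.numeric(v)) fmt_p(v) else v)
  })
  sections <- stats::setNames(
    vals, paste0("result_", seq_len(nrow(results)))
  )
  write_report_lines(sections, path)
}
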