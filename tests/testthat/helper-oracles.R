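# Independent oracles used across the suite. Each is deliberately written
# with a different mechanism than the implementation it checks.

# Frame-by-frame scan for movement events: walks the trace with explicit
# state instead of run-length encoding. Returns one row per event with the
# first/last above-band frame, peak, class and flags under the same
# conventions as detect_events.
brute_force_events <- function(trace, rest_band = 5, min_duration = 3) {
  n <- nrow(trace)
  upper <- 180 + rest_band
  out <- list()
  i <- 1
  while (i <= n) {
    if (trace$theta[i] > upper) {
      j <- i
      while (j < n && trace$theta[j + 1] > upper) j <- j + 1
      # split the run wherever the signed angle changes side
      sgn <- sign(trace$signed_theta[i:j])
      sgn[sgn == 0] <- 1
      ks <- i
      for (k in i:j) {
        if (k == j || sgn[k - i + 1] != sgn[k - i + 2]) {
          f1 <- ks; f2 <- k
          if (f2 - f1 + 1 >= min_duration) {
            on_f <- if (f1 == i && i > 1) f1 - 1 else f1
            off_f <- if (f2 == j && j < n) f2 + 1 else f2
            pk <- f1 - 1 + which.max(trace$theta[f1:f2])
            peak <- trace$theta[pk]
            out[[length(out) + 1]] <- data.frame(
              onset = trace$time[on_f], offset = trace$time[off_f],
              peak_angle = peak,
              direction = if (trace$signed_theta[pk] >= 0) "left" else "right",
              event_class = if (peak <= 200) "wag"
                            else if (peak < 270) "LAM" else "extreme",
              truncated = (f1 == i && i == 1) || (f2 == j && j == n)
            )
          }
          ks <- k + 1
        }
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    data.frame(onset = numeric(0), offset = numeric(0),
               peak_angle = numeric(0), direction = character(0),
               event_class = character(0), truncated = logical(0))
  } else {
    do.call(rbind, out)
  }
}

# Pairwise O(n^2) grouping oracle for burst/episode segmentation: spikes i
# and j share a burst iff every ISI between them is < intra_max ms, and an
# episode iff every ISI between them is <= episode_max ms. Partitions are
# built from the pairwise relation, not by a left-to-right pass.
brute_force_segmentation <- function(times, intra_max = 10, episode_max = 100) {
  n <- length(times)
  if (n == 0) return(list(burst = integer(0), episode = integer(0)))
  isi <- diff(times) * 1000
  same <- function(bound, strict) {
    id <- integer(n)
    id[1] <- 1L
    for (j in seq_len(n)[-1]) {
      linked <- FALSE
      for (i in seq_len(j - 1)) {
        gaps <- isi[i:(j - 1)]
        ok <- if (strict) all(gaps < bound) else all(gaps <= bound)
        if (ok) { linked <- TRUE; id[j] <- id[i]; break }
      }
      if (!linked) id[j] <- max(id) + 1L
    }
    id
  }
  list(burst = same(intra_max, strict = TRUE),
       episode = same(episode_max, strict = FALSE))
}

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(n1+n2, n1) group assignments, mirroring the convention of doubling
# the smaller tail and capping at 1.
enumerated_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  w_null <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(w_null <= w_obs)
  p_hi <- mean(w_null >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Monte-Carlo permutation p-value for a 2-condition affected/unaffected
# table: permutes subject labels and recomputes the Pearson statistic from
# its definition.
permutation_chisq_p <- function(a1, n1, a2, n2, reps = 10000) {
  pearson <- function(a1, a2) {
    m <- rbind(c(a1, n1 - a1), c(a2, n2 - a2))
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  obs <- pearson(a1, a2)
  subjects <- c(rep(1, a1 + a2), rep(0, n1 + n2 - a1 - a2))
  stat <- replicate(reps, {
    lab <- sample(subjects)
    pearson(sum(lab[seq_len(n1)]), sum(lab[-seq_len(n1)]))
  })
  mean(stat >= obs - 1e-12)
}

# Build an angle_trace directly from a signed excursion series (degrees).
make_trace <- function(signed, frame_rate = 300) {
  out <- tibble::tibble(
    frame = seq_along(signed),
    time = (seq_along(signed) - 1) / frame_rate,
    theta = 180 + abs(signed),
    signed_theta = signed,
    direction = dplyr::case_when(signed > 0 ~ "left", signed < 0 ~ "right",
                                 TRUE ~ "none")
  )
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("angle_trace", class(out))
  out
}

# Random bounded signed-excursion trace for property tests.
random_trace <- function(n, frame_rate = 300) {
  signed <- cumsum(rnorm(n, 0, 8))
  signed <- 100 * sin(signed / 40) + rnorm(n, 0, 2)
  make_trace(signed, frame_rate)
}

# Random spike train with ISIs spanning the three bands.
random_spike_train <- function(max_spikes = 200) {
  n <- sample(0:max_spikes, 1)
  if (n == 0) return(numeric(0))
  isi_ms <- sample(c(runif(n, 0.5, 9.9), runif(n, 10, 100), runif(n, 101, 400)),
                   n, replace = TRUE)
  cumsum(isi_ms) / 1000
}
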