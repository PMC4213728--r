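make_track <- function(Tx, Ty, Hx = 0, Hy = 1, Mx = 0, My = 0, fps = 300) {
  tibble::tibble(frame = seq_along(Tx), Hx = Hx, Hy = Hy, Mx = Mx, My = My,
                 Tx = Tx, Ty = Ty)
}

test_that("body angle matches hand-computed configurations", {
  tr <- make_track(Tx = c(0, 1, 0.5), Ty = c(-1, 0, -0.8660254))
  th <- compute_body_angle(tr, frame_rate = 300)$theta
  expect_equal(th[1], 180)                 # collinear rest
  expect_equal(th[2], 270)                 # perpendicular: 360 - 90
  expect_equal(th[3], 210, tolerance = 1e-7)  # 150 deg separation: 360 - 150
})

test_that("angle stays in [180, 360] and the arccos argument is clamped", {
  set.seed(42)
  for (i in 1:50) {
    tr <- make_track(Tx = rnorm(100), Ty = rnorm(100),
                     Hx = rnorm(1), Hy = rnorm(1) + 2)
    th <- compute_body_angle(tr, frame_rate = 300)$theta
    expect_true(all(th >= 180 - 1e-12 & th <= 360 + 1e-12))
  }
  # numerically collinear points must not produce NaN
  tr <- make_track(Tx = 0, Ty = -1e8)
  expect_false(anyNA(compute_body_angle(tr, frame_rate = 300)$theta))
})

test_that("degenerate frames are rejected by index", {
  tr <- make_track(Tx = c(1, 0), Ty = c(0, 0))
  expect_error(compute_body_angle(tr, frame_rate = 300),
               "degenerate frame 2")
})

test_that("direction follows the cross-product convention", {
  tr <- make_track(Tx = c(1, -1, 0), Ty = c(0, 0, -1))
  trace <- compute_body_angle(tr, frame_rate = 300)
  expect_equal(trace$direction, c("right", "left", "none"))
  expect_equal(trace$signed_theta, c(-90, 90, 0))
  # rest-band frames carry "none" after assign_direction
  trace2 <- assign_direction(tr, trace)
  expect_equal(trace2$direction[3], "none")
})

test_that("mirror symmetry flips direction and nothing else", {
  sim <- simulate_trajectory(trajectory_preset("control", seed = 21))
  mirrored <- dplyr::mutate(sim$track, Hx = -Hx, Mx = -Mx, Tx = -Tx)
  attr(mirrored, "frame_rate") <- 300
  t1 <- compute_body_angle(sim$track)
  t2 <- compute_body_angle(mirrored, frame_rate = 300)
  expect_equal(t2$theta, t1$theta)
  e1 <- detect_events(t1)
  e2 <- detect_events(t2)
  expect_equal(e2$onset, e1$onset)
  expect_equal(e2$duration, e1$duration)
  expect_equal(e2$event_class, e1$event_class)
  flip <- c(left = "right", right = "left")
  expect_equal(e2$direction, unname(flip[e1$direction]))
})

test_that("theta is invariant under rigid rotation and translation", {
  sim <- simulate_trajectory(trajectory_params(duration = 2, seed = 8))
  phi <- 0.73
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  rot <- function(x, y, dx, dy) {
    p <- R %*% rbind(x, y)
    list(x = p[1, ] + dx, y = p[2, ] + dy)
  }
  tr <- sim$track
  H <- rot(tr$Hx, tr$Hy, 3, -2); M <- rot(tr$Mx, tr$My, 3, -2)
  T_ <- rot(tr$Tx, tr$Ty, 3, -2)
  moved <- tibble::tibble(frame = tr$frame, Hx = H$x, Hy = H$y,
                          Mx = M$x, My = M$y, Tx = T_$x, Ty = T_$y)
  expect_equal(compute_body_angle(moved, frame_rate = 300)$theta,
               compute_body_angle(tr)$theta, tolerance = 1e-9)
})

test_that("constant rest trace yields zero events", {
  trace <- make_trace(rep(0, 600))
  expect_equal(nrow(detect_events(trace)), 0)
  s <- summarize_events(detect_events(trace))
  expect_equal(nrow(s$counts), 0)
  expect_length(s$lam_durations, 0)
})

test_that("a single excursion is classified by its peak with the 200-degree tie to wag", {
  half_sine <- function(peak, frames) (peak - 180) * sin(pi * seq_len(frames) / (frames + 1))
  pad <- rep(0, 20)
  for (case in list(list(peak = 190, class = "wag"),
                    list(peak = 200, class = "wag"),
                    list(peak = 250, class = "LAM"),
                    list(peak = 269.9, class = "LAM"),
                    list(peak = 270, class = "extreme"),
                    list(peak = 300, class = "extreme"))) {
    sig <- c(pad, half_sine(case$peak, 31), pad)
    # force the exact peak onto the grid
    sig[20 + 16] <- case$peak - 180
    ev <- detect_events(make_trace(sig))
    expect_equal(nrow(ev), 1)
    expect_equal(ev$event_class, case$class)
    expect_equal(ev$peak_angle, case$peak)
    expect_equal(ev$direction, "left")
  }
})

test_that("rest-to-rest duration of a half-sine excursion is recovered to a frame period", {
  p <- trajectory_params(lam_rate = 1, wag_cluster_rate = 0, rest_jitter_sd = 0,
                         lam_duration_mean = 60, lam_duration_sd = 0,
                         lam_peak_range = c(249.99, 250.01), seed = 5)
  sim <- simulate_trajectory(p)
  expect_equal(nrow(sim$events), 1)
  ev <- detect_events(compute_body_angle(sim$track))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_class, "LAM")
  expect_equal(ev$direction, sim$events$direction)
  expect_lt(abs(ev$duration - sim$events$duration), 2 / 300 + 1e-9)
})

test_that("events shorter than min_duration are discarded", {
  sig <- rep(0, 100)
  sig[50:51] <- c(30, 30)  # two above-band frames only
  expect_equal(nrow(detect_events(make_trace(sig), min_duration = 3)), 0)
  expect_equal(nrow(detect_events(make_trace(sig), min_duration = 2)), 1)
})

test_that("the optional median filter suppresses single-frame spikes", {
  sig <- rep(0, 100)
  sig[50] <- 40  # one-frame tracking glitch
  expect_equal(nrow(detect_events(make_trace(sig), min_duration = 1)), 1)
  expect_equal(nrow(detect_events(make_trace(sig), min_duration = 1,
                                  median_filter = TRUE)), 0)
  # a genuine excursion survives filtering
  sig2 <- c(rep(0, 40), 30 * sin(pi * seq_len(15) / 16), rep(0, 40))
  expect_equal(nrow(detect_events(make_trace(sig2), median_filter = TRUE)), 1)
})

test_that("an excursion still above band at the trace end is flagged truncated", {
  sig <- c(rep(0, 50), seq(10, 60, length.out = 30))
  ev <- detect_events(make_trace(sig))
  expect_equal(nrow(ev), 1)
  expect_true(ev$truncated)
  s <- summarize_events(ev)
  expect_equal(s$counts$lam_count, 1)          # counted
  expect_length(s$lam_durations, 0)            # excluded from durations
})

test_that("direction reversals without reaching rest are split and flagged", {
  sig <- c(rep(0, 20), seq(10, 40, length.out = 10), seq(-40, -10, length.out = 10),
           rep(0, 20))
  ev <- detect_events(make_trace(sig))
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$split))
  expect_equal(ev$direction, c("left", "right"))
})

test_that("detector matches the frame-scan oracle on random traces", {
  set.seed(99)
  for (i in 1:30) {
    trace <- random_trace(sample(50:1000, 1))
    got <- detect_events(trace)
    want <- brute_force_events(trace)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$onset, want$onset)
      expect_equal(got$offset, want$offset)
      expect_equal(got$peak_angle, want$peak_angle)
      expect_equal(got$event_class, want$event_class)
      expect_equal(got$direction, want$direction)
      expect_equal(got$truncated, want$truncated)
    }
  }
})

test_that("summaries report counts, duration moments and a proper ECDF", {
  ev <- new_events <- tibble::tibble(
    event = 1:3, onset = c(1, 5, 9), offset = c(1.057, 5.057, 9.057),
    duration = rep(0.057, 3), duration_ms = rep(57, 3),
    peak_angle = c(220, 230, 240), direction = rep("left", 3),
    event_class = rep("LAM", 3), truncated = FALSE, split = FALSE
  )
  class(ev) <- c("movement_events", class(ev))
  s <- summarize_events(ev, window = 20)
  expect_equal(s$counts$lam_count, 3)
  expect_equal(s$stats$mean_ms[s$stats$event_class == "LAM"], 57)
  expect_equal(s$stats$sem_ms[s$stats$event_class == "LAM"], 0)
  expect_equal(s$lam_ecdf(max(s$lam_durations)), 1)
  expect_equal(tidy(s), s$stats)
  expect_equal(glance(s)$lam_count_mean, 3)
})

test_that("window assignment is half-open by onset", {
  ev <- tibble::tibble(
    event = 1:2, onset = c(19.99, 20.0), offset = c(20.05, 20.06),
    duration = c(0.06, 0.06), duration_ms = c(60, 60),
    peak_angle = c(220, 220), direction = "left", event_class = "LAM",
    truncated = FALSE, split = FALSE
  )
  s <- summarize_events(ev, window = 20)
  expect_equal(s$counts$lam_count, c(1, 1))
})
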