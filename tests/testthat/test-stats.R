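test_that("chi-square scoring rejects the reconstructed floating contrast", {
  tab <- tibble::tibble(condition = c("mn", "recovered"),
                        affected = c(59, 7), total = c(60, 60))
  res <- chi_square_counts(tab)
  expect_lt(res$p_value, 1e-4)
  expect_equal(res$df, 1)
})

test_that("identical proportions give a zero statistic and p = 1", {
  tab <- tibble::tibble(condition = c("a", "b"), affected = c(12, 12),
                        total = c(60, 60))
  res <- chi_square_counts(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("chi-square p agrees with a label-permutation oracle", {
  set.seed(55)
  res <- chi_square_counts(tibble::tibble(
    condition = c("a", "b"), affected = c(30, 15), total = c(60, 60)
  ))
  p_perm <- permutation_chisq_p(30, 60, 15, 60, reps = 10000)
  # Monte-Carlo noise plus the residual chi-square approximation error
  expect_lt(abs(res$p_value - p_perm), 0.01)
})

test_that("zero margins and malformed counts are rejected", {
  expect_error(chi_square_counts(tibble::tibble(
    condition = c("a", "b"), affected = c(0, 0), total = c(10, 10)
  )), "margin")
  expect_error(chi_square_counts(tibble::tibble(
    condition = "a", affected = 11, total = 10
  )), "\\[0, total\\]")
})

test_that("stratified layout keeps batches as rows with larger df", {
  tab <- tibble::tibble(
    condition = rep(c("mn", "recovered"), each = 3), batch = rep(1:3, 2),
    affected = c(20, 19, 20, 2, 3, 2), total = 20
  )
  pooled <- chi_square_counts(tab)
  strat <- chi_square_counts(tab, layout = "stratified")
  expect_equal(pooled$df, 1)
  expect_equal(strat$df, 5)
  expect_lt(pooled$p_value, 1e-4)
})

test_that("rank-sum Bonferroni arithmetic and edge cases", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 6),
                      value = rep(seq(1, 6), 2))
  res <- rank_sum_bonferroni(d, list(c("a", "b")))
  expect_equal(res$p_adjusted, 1)
  # three comparisons: adjusted = min(1, 3p)
  d3 <- tibble::tibble(group = rep(c("a", "b", "c", "d"), each = 10),
                       value = c(rnorm(10), rnorm(10, 4), rnorm(10), rnorm(10)))
  res3 <- rank_sum_bonferroni(d3, list("a:b", "a:c", "a:d"))
  expect_equal(res3$p_adjusted, pmin(1, 3 * res3$p_value))
  expect_error(rank_sum_bonferroni(d, list()), "at least one")
  expect_error(rank_sum_bonferroni(d, list(c("a", "zz"))), "unknown group")
})

test_that("small-sample rank-sum p-values equal exhaustive enumeration", {
  set.seed(20)
  for (i in 1:10) {
    n1 <- sample(3:5, 1)
    n2 <- sample(3:7, 1)
    x <- sample(seq_len(40), n1 + n2)  # distinct -> tie-free, exact branch
    d <- tibble::tibble(group = rep(c("a", "b"), c(n1, n2)), value = x)
    got <- rank_sum_bonferroni(d, list(c("a", "b")))$p_value
    want <- enumerated_ranksum_p(x[seq_len(n1)], x[-seq_len(n1)])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis is consistent with the two-sample rank-sum", {
  set.seed(3)
  d <- tibble::tibble(group = rep(c("a", "b"), each = 15),
                      value = c(rnorm(15), rnorm(15, 1)))
  kw <- kruskal_wallis(d)
  rs <- rank_sum_bonferroni(d, list(c("a", "b")))
  # same data, equivalent tests: p-values agree closely for two groups
  expect_lt(abs(kw$p_value - rs$p_value), 0.01)
})

test_that("identical groups give H = 0 with p = 1", {
  d <- tibble::tibble(group = rep(c("a", "b", "c"), each = 5), value = 2)
  res <- kruskal_wallis(d)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("Kruskal-Wallis separates control-like from Mn-like LAM durations", {
  reject <- vapply(1:200, function(s) {
    d <- tibble::tibble(
      group = rep(c("control", "mn"), each = 50),
      value = c(
        sample_event_durations(trajectory_preset("control", seed = s), 50),
        sample_event_durations(trajectory_preset("mn", seed = s + 1000), 50)
      )
    )
    kruskal_wallis(d)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})

test_that("the Lilliefors statistic matches the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(sample(10:60, 1), 3, 2)
    ours <- lilliefors_test(x, mc_reps = 2000)
    ref <- nortest::lillie.test(x)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("the normality gate routes clean and heavy-tailed data correctly", {
  branch <- function(gen, seed) {
    set.seed(seed)
    d <- tidyr::expand_grid(subject = 1:20, group = c("a", "b", "c"))
    d$value <- gen(nrow(d)) + rep(rnorm(20), each = 3)
    gated_paired_test(d, mc_reps = 1000)$test
  }
  normal_hits <- vapply(1:20, function(s)
    branch(function(n) rnorm(n), s) == "repeated-measures ANOVA", logical(1))
  heavy_hits <- vapply(1:20, function(s)
    branch(function(n) exp(rnorm(n, 0, 1.5)), s) == "Friedman", logical(1))
  # three groups are gated jointly, so the clean-data branch rate is
  # bounded by (1 - alpha)^3, not 1 - alpha
  expect_gte(mean(normal_hits), 0.7)
  expect_gte(mean(heavy_hits), 0.85)
})

test_that("identical paired columns give p = 1 and unbalanced pairing errors", {
  d <- tidyr::expand_grid(subject = 1:6, group = c("a", "b"))
  d$value <- rep(rnorm(6), each = 2)
  res <- gated_paired_test(d, mc_reps = 500)
  expect_equal(res$p_value, 1)
  expect_error(gated_paired_test(d[-1, ], mc_reps = 500), "unbalanced")
})

test_that("gate decisions are recorded and reproducible", {
  set.seed(5)
  d <- tidyr::expand_grid(subject = 1:10, group = c("a", "b"))
  d$value <- rnorm(20)
  r1 <- gated_paired_test(d, mc_reps = 1000)
  r2 <- gated_paired_test(d, mc_reps = 1000)
  expect_identical(attr(r1, "gate"), attr(r2, "gate"))
  expect_named(attr(r1, "gate"), c("group", "statistic", "p_value", "normal"))
})

test_that("LC50 interpolation honors an exact 50% point and log-linear brackets", {
  expect_equal(lc50_estimate(tibble::tibble(
    dose = c(1, 2, 4), fraction = c(0.9, 0.5, 0.1)
  ))$lc50, 2)
  # full drop between two doses: log-linear midpoint is the geometric mean
  fit <- lc50_estimate(tibble::tibble(dose = c(1, 4), fraction = c(1, 0)))
  expect_equal(fit$lc50, 2)
  expect_error(lc50_estimate(tibble::tibble(
    dose = c(1, 2), fraction = c(0.9, 0.8)
  )), "outside tested range")
})

test_that("LC50 estimates are scale-equivariant in dose", {
  tab <- tibble::tibble(dose = c(0.5, 1, 2, 4, 8),
                        surviving = c(19, 17, 10, 3, 1), n = 20)
  tab$fraction <- tab$surviving / tab$n
  for (m in c("interpolation", "logistic")) {
    base <- lc50_estimate(tab, method = m)$lc50
    scaled <- lc50_estimate(dplyr::mutate(tab, dose = dose * 3), method = m)$lc50
    expect_equal(scaled, 3 * base, tolerance = 1e-8)
  }
})

test_that("logistic LC50 recovery is accurate on simulated curves", {
  est <- vapply(1:20, function(s) {
    tab <- simulate_survival(survival_params(seed = s))
    # steep realized curves can separate perfectly; the point estimate is
    # still well-defined for the median across seeds
    suppressWarnings(lc50_estimate(tab, method = "logistic")$lc50)
  }, numeric(1))
  expect_lt(abs(median(est) - 2), 0.25)
})

test_that("group relabeling permutes results consistently", {
  set.seed(8)
  d <- tibble::tibble(group = rep(c("a", "b", "c"), each = 10),
                      value = rnorm(30))
  relab <- dplyr::mutate(d, group = dplyr::recode(group, a = "z", b = "y", c = "x"))
  expect_equal(kruskal_wallis(d)$statistic, kruskal_wallis(relab)$statistic)
  r1 <- rank_sum_bonferroni(d, list(c("a", "b")))
  r2 <- rank_sum_bonferroni(relab, list(c("z", "y")))
  expect_equal(r1$p_value, r2$p_value)
})
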