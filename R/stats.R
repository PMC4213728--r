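# The statistical layer: chi-square phenotype scoring, rank-sum tests with
# Bonferroni correction, Kruskal-Wallis, a Lilliefors-gated paired test
# (repeated-measures ANOVA vs Friedman) and LC50 estimation.

#' Chi-square test on phenotype count tables
#'
#' Pearson chi-square (continuity correction off by default) on counts of
#' larvae presenting vs not presenting a phenotype across conditions. Two
#' layouts are offered: `"pooled"` collapses batches into one
#' affected/unaffected column pair per condition (a 2 x C table, df = C-1);
#' `"stratified"` keeps each condition-batch cell as its own row (a
#' (C*B) x 2 table), which inflates the degrees of freedom but exposes
#' batch heterogeneity. Pooled is the default.
#'
#' @param counts A tibble with columns `condition`, `affected`, `total`
#'   (and optionally `batch`), e.g. one phenotype's rows from
#'   [simulate_behavior_counts()], or a named numeric of affected counts
#'   plus `totals`.
#' @param layout `"pooled"` or `"stratified"`.
#' @param correct Apply Yates continuity correction (2 x 2 only)?
#' @return A one-row tibble: statistic, df, p_value, method, layout.
#' @examples
#' tab <- tibble::tibble(condition = c("mn", "recovered"),
#'                       affected = c(59, 7), total = c(60, 60))
#' chi_square_counts(tab)$p_value < 1e-4
#' @export
chi_square_counts <- function(counts, layout = c("pooled", "stratified"),
                              correct = FALSE) {
  layout <- match.arg(layout)
  if (!all(c("condition", "affected", "total") %in% names(counts))) {
    abort("counts must contain columns condition, affected, total")
  }
  if (any(counts$affected < 0 | counts$affected > counts$total)) {
    abort("affected counts must lie in [0, total]")
  }
  if (layout == "pooled") {
    pooled <- counts |>
      group_by(.data$condition) |>
      summarise(affected = sum(.data$affected), total = sum(.data$total),
                .groups = "drop")
    m <- rbind(affected = pooled$affected,
               unaffected = pooled$total - pooled$affected)
    colnames(m) <- pooled$condition
  } else {
    if (!"batch" %in% names(counts)) {
      abort("stratified layout requires a `batch` column")
    }
    m <- cbind(affected = counts$affected,
               unaffected = counts$total - counts$affected)
    rownames(m) <- paste(counts$condition, counts$batch, sep = ".")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("chi-square undefined: a row or column margin is zero")
  }
  ht <- suppressWarnings(chisq.test(m, correct = correct))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value), method = "Pearson chi-square",
         layout = layout)
}

parse_pairs <- function(comparisons, groups) {
  pairs <- lapply(comparisons, function(p) {
    if (is.character(p) && length(p) == 1 && grepl(":", p)) {
      p <- strsplit(p, ":", fixed = TRUE)[[1]]
    }
    if (length(p) != 2) abort("each comparison must name two groups")
    p
  })
  for (p in pairs) {
    if (!all(p %in% groups)) {
      abort(sprintf("unknown group in comparison: %s", paste(p, collapse = " vs ")))
    }
  }
  pairs
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Runs a two-sample Wilcoxon rank-sum (Mann-Whitney) test for each
#' requested pair of groups -- exact p-values for small tie-free samples,
#' normal approximation otherwise, as in [stats::wilcox.test()] -- and
#' Bonferroni-adjusts across the requested pairs:
#' `p_adjusted = min(1, m * p)` with m the number of comparisons.
#'
#' @param data A tibble with a grouping column and a value column.
#' @param comparisons List of pairs, each `c("A", "B")` or `"A:B"`.
#' @param value,group Column names (strings) of observations and labels.
#' @return A tibble with one row per pair: group1, group2, statistic (W),
#'   p_value, p_adjusted.
#' @export
rank_sum_bonferroni <- function(data, comparisons, value = "value",
                                group = "group") {
  if (!all(c(value, group) %in% names(data))) {
    abort(sprintf("data must contain columns `%s` and `%s`", value, group))
  }
  if (length(comparisons) < 1) abort("supply at least one comparison")
  g <- as.character(data[[group]])
  x <- data[[value]]
  pairs <- parse_pairs(comparisons, unique(g))
  m <- length(pairs)
  map_dfr(pairs, function(p) {
    xa <- x[g == p[1]]
    xb <- x[g == p[2]]
    if (length(xa) == 0 || length(xb) == 0) {
      abort(sprintf("empty group in comparison %s vs %s", p[1], p[2]))
    }
    ht <- suppressWarnings(wilcox.test(xa, xb))
    tibble(group1 = p[1], group2 = p[2], statistic = unname(ht$statistic),
           p_value = ht$p.value, p_adjusted = pmin(1, m * ht$p.value))
  })
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected Kruskal-Wallis H statistic against a chi-square reference
#' distribution. When every observation is identical the statistic is 0
#' with p = 1 (no evidence of group differences, not an error).
#'
#' @inheritParams rank_sum_bonferroni
#' @return A one-row tibble: statistic (H), df, p_value, method.
#' @export
kruskal_wallis <- function(data, value = "value", group = "group") {
  if (!all(c(value, group) %in% names(data))) {
    abort(sprintf("data must contain columns `%s` and `%s`", value, group))
  }
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least two groups")
  x <- data[[value]]
  if (length(unique(x)) == 1) {
    return(tibble(statistic = 0, df = nlevels(g) - 1, p_value = 1,
                  method = "Kruskal-Wallis"))
  }
  ht <- kruskal.test(x, g)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, method = "Kruskal-Wallis")
}

#' Lilliefors test for normality with a Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov distance between the sample's empirical CDF and a
#' normal distribution with mean and standard deviation estimated from the
#' same sample. Because parameters are estimated, the classical KS null
#' does not apply; the p-value is obtained by Monte-Carlo simulation of the
#' statistic under normal samples of the same size, using a fixed internal
#' random stream so results are reproducible and independent of the
#' caller's RNG state.
#'
#' @param x Numeric sample (n >= 4, non-constant).
#' @param mc_reps Monte-Carlo replicates (default 10000).
#' @return A one-row tibble: statistic (D), p_value, n, method.
#' @export
lilliefors_test <- function(x, mc_reps = 10000) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) abort("Lilliefors test needs at least 4 observations")
  if (sd(x) == 0) abort("Lilliefors test undefined for a constant sample")
  d_obs <- lilliefors_stat(x)
  d_null <- withr::with_seed(271828L, {
    vapply(seq_len(mc_reps), function(i) lilliefors_stat(rnorm(n)), numeric(1))
  })
  tibble(statistic = d_obs, p_value = (sum(d_null >= d_obs) + 1) / (mc_reps + 1),
         n = n, method = "Lilliefors (Monte-Carlo)")
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  max(max(seq_len(n) / n - p), max(p - (seq_len(n) - 1) / n))
}

#' Normality-gated paired group comparison
#'
#' Implements the gate used for paired region-of-interest intensity data:
#' each group is screened for normality with the Monte-Carlo
#' [lilliefors_test()]; if every group passes at `alpha`, a one-way
#' repeated-measures ANOVA (subject as error stratum) is run, otherwise a
#' Friedman test. A constant group cannot be screened and routes to the
#' Friedman branch. The result records which branch fired and the per-group
#' gate decisions.
#'
#' @param data Tibble in long format.
#' @param value,group,subject Column names (strings): observations, group
#'   labels, and the pairing key (e.g. ROI or batch). Every subject must
#'   appear exactly once in every group.
#' @param alpha Gate level (default 0.05).
#' @param mc_reps Monte-Carlo replicates for the Lilliefors p-values.
#' @return A one-row tibble: test, statistic, df (and df2 for the ANOVA
#'   branch), p_value; the per-group gate table is attached as attribute
#'   `"gate"`.
#' @export
gated_paired_test <- function(data, value = "value", group = "group",
                              subject = "subject", alpha = 0.05,
                              mc_reps = 10000) {
  if (!all(c(value, group, subject) %in% names(data))) {
    abort("data must contain the value, group and subject columns")
  }
  g <- factor(data[[group]])
  s <- factor(data[[subject]])
  x <- data[[value]]
  tab <- table(s, g)
  if (any(tab != 1)) {
    abort("unbalanced pairing: every subject must appear exactly once per group")
  }
  gate <- map_dfr(levels(g), function(lev) {
    xi <- x[g == lev]
    if (sd(xi) == 0) {
      tibble(group = lev, statistic = NA_real_, p_value = NA_real_,
             normal = FALSE)
    } else {
      lt <- lilliefors_test(xi, mc_reps = mc_reps)
      tibble(group = lev, statistic = lt$statistic, p_value = lt$p_value,
             normal = lt$p_value > alpha)
    }
  })
  all_equal_within <- all(tapply(x, s, function(v) length(unique(v)) == 1))
  if (all(gate$normal) && !all_equal_within) {
    fit <- aov(x ~ g + Error(s))
    st <- summary(fit)[["Error: Within"]][[1]]
    res <- tibble(
      test = "repeated-measures ANOVA", statistic = st[["F value"]][1],
      df = st[["Df"]][1], df2 = st[["Df"]][2],
      p_value = st[["Pr(>F)"]][1]
    )
  } else if (all_equal_within) {
    # identical paired columns: no within-subject variation, p = 1 either way
    res <- tibble(test = if (all(gate$normal)) "repeated-measures ANOVA"
                         else "Friedman",
                  statistic = 0, df = nlevels(g) - 1, df2 = NA_real_,
                  p_value = 1)
  } else {
    ht <- friedman.test(x, g, s)
    res <- tibble(test = "Friedman", statistic = unname(ht$statistic),
                  df = unname(ht$parameter), df2 = NA_real_,
                  p_value = ht$p.value)
  }
  attr(res, "gate") <- gate
  res
}

#' Estimate the LC50 from a dose-survival table
#'
#' The LC50 is the dose at which half the animals survive the stated
#' exposure. Two estimators are provided. `"interpolation"` (default): if a
#' tested dose shows exactly 50% survival that dose is returned; otherwise
#' the survival curve is linearly interpolated in log-dose between the two
#' consecutive doses bracketing 50% (falling back to the natural dose scale
#' when the lower bracket is dose zero). `"logistic"`: a two-parameter
#' logistic regression of surviving counts on log-dose
#' (binomial GLM; rows at dose zero are dropped since log-dose is
#' undefined there), with LC50 the dose at which the fitted survival
#' crosses 0.5 and a delta-method standard error as the confidence note.
#'
#' @param data A `dose_survival` tibble with columns `dose` and `fraction`
#'   (or `surviving` and `n`, from which fractions are computed).
#' @param method `"interpolation"` or `"logistic"`.
#' @return An `lc50_fit` list: `lc50` (same units as `dose`), `method`,
#'   `note`, and for the logistic method `se` and the underlying `fit`.
#' @examples
#' tab <- tibble::tibble(dose = c(1, 2, 4), fraction = c(0.9, 0.5, 0.1))
#' lc50_estimate(tab)$lc50  # 2
#' @export
lc50_estimate <- function(data, method = c("interpolation", "logistic")) {
  method <- match.arg(method)
  if (!"dose" %in% names(data)) abort("data must contain a `dose` column")
  if (!"fraction" %in% names(data)) {
    if (all(c("surviving", "n") %in% names(data))) {
      data$fraction <- data$surviving / data$n
    } else {
      abort("data must contain `fraction` or `surviving` + `n` columns")
    }
  }
  if (nrow(data) < 2 || anyDuplicated(data$dose)) {
    abort("data must contain at least two distinct doses")
  }
  data <- arrange(data, .data$dose)
  f <- data$fraction
  d <- data$dose
  if (!(max(f) >= 0.5 && min(f) <= 0.5)) {
    abort("LC50 outside tested range: survival never crosses 50%")
  }

  if (method == "interpolation") {
    hit <- which(f == 0.5)
    if (length(hit)) {
      lc50 <- d[hit[1]]
      note <- "a tested dose shows exactly 50% survival"
    } else {
      i <- which((f[-length(f)] - 0.5) * (f[-1] - 0.5) < 0)
      if (length(i) == 0) abort("LC50 outside tested range: survival never crosses 50%")
      i <- i[1]
      w <- (0.5 - f[i]) / (f[i + 1] - f[i])
      if (d[i] <= 0) {
        lc50 <- d[i] + w * (d[i + 1] - d[i])
        note <- "linear interpolation (lower bracket at dose zero)"
      } else {
        lc50 <- exp(log(d[i]) + w * (log(d[i + 1]) - log(d[i])))
        note <- sprintf("log-linear interpolation between %g and %g",
                        d[i], d[i + 1])
      }
    }
    out <- list(lc50 = lc50, method = method, note = note)
  } else {
    if (!all(c("surviving", "n") %in% names(data))) {
      data$n <- 100L
      data$surviving <- round(data$fraction * data$n)
    }
    pos <- data$dose > 0
    fit <- glm(cbind(surviving, n - surviving) ~ log(dose),
               family = binomial(), data = data[pos, ])
    b <- coef(fit)
    if (b[2] >= 0) {
      warn("fitted survival is non-decreasing in dose; LC50 unreliable")
    }
    log_lc50 <- -b[1] / b[2]
    V <- vcov(fit)
    grad <- c(-1 / b[2], b[1] / b[2]^2)
    se_log <- sqrt(drop(t(grad) %*% V %*% grad))
    lc50 <- exp(log_lc50)
    out <- list(lc50 = unname(lc50), method = method,
                se = unname(lc50 * se_log),
                note = sprintf("two-parameter logistic fit on log-dose; se %.3g (delta method)",
                               lc50 * se_log),
                fit = fit)
  }
  structure(out, class = "lc50_fit")
}

#' @export
print.lc50_fit <- function(x, ...) {
  cat("LC50 estimate: ", format(x$lc50, digits = 4), " (", x$method, ")\n  ",
      x$note, "\n", sep = "")
  invisible(x)
}

#' @rdname lc50_estimate
#' @param x An `lc50_fit`.
#' @param ... Unused.
#' @export
tidy.lc50_fit <- function(x, ...) {
  tibble(term = "lc50", estimate = x$lc50,
         std.error = x$se %||% NA_real_, method = x$method)
}

#' @rdname lc50_estimate
#' @export
glance.lc50_fit <- function(x, ...) {
  tibble(lc50 = x$lc50, method = x$method, note = x$note)
}
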