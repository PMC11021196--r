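#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis into the K2
#' statistic, referred to a chi-squared distribution with 2 df. Requires
#' `n >= 20` for the kurtosis transformation to be reliable.
#'
#' @param x Numeric sample.
#' @return An object of class `htest` (statistic `K2`, `p.value`).
#' @export
dagostino_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20) {
    abort("D'Agostino-Pearson test requires n >= 20.",
          class = "blastopack_insufficient_sample")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    abort("Zero-variance sample.", class = "blastopack_degenerate_sample")
  }
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_beta1 * (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  structure(
    list(statistic = c(K2 = k2),
         p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
         method = "D'Agostino-Pearson omnibus normality test",
         data.name = deparse(substitute(x))),
    class = "htest"
  )
}

#' Normality gate for a single sample
#'
#' Returns `TRUE` when the configured normality test(s) fail to reject at
#' `alpha` — i.e. the sample is treated as normal and routed to the
#' parametric branch. When several tests are configured, all must pass.
#' Constant (zero-variance) samples fail the gate and are flagged degenerate.
#'
#' @param values Numeric sample, `n >= 3`.
#' @param alpha Gate significance level (default 0.05).
#' @param tests Character subset of `c("shapiro", "dagostino")`; the default
#'   is Shapiro-Wilk alone.
#' @return Logical scalar with attributes `p_values` (named numeric) and
#'   `degenerate` (logical).
#' @export
normality_gate <- function(values, alpha = 0.05, tests = "shapiro") {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    abort("Normality gate requires n >= 3.",
          class = "blastopack_insufficient_sample")
  }
  tests <- match.arg(tests, c("shapiro", "dagostino"), several.ok = TRUE)
  if (var(values) == 0) {
    return(structure(FALSE, p_values = setNames(rep(NA_real_, length(tests)),
                                                tests),
                     degenerate = TRUE))
  }
  p <- vapply(tests, function(t) {
    switch(t,
           shapiro = shapiro.test(values)$p.value,
           dagostino = dagostino_test(values)$p.value)
  }, numeric(1))
  structure(all(p > alpha), p_values = p, degenerate = FALSE)
}

group_summaries <- function(data, alpha, tests) {
  data |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      normal = purrr::map_lgl(
        split(data$value, data$group)[as.character(.data$group)],
        function(v) as.logical(normality_gate(v, alpha, tests))),
      degenerate = .data$sd == 0
    )
}

check_groups <- function(data, expected = NULL) {
  if (!is.data.frame(data) || !all(c("group", "value") %in% names(data))) {
    abort("`data` must be a data frame with columns `group` and `value`.",
          class = "blastopack_domain_error")
  }
  data$group <- factor(data$group)
  k <- nlevels(data$group)
  if (!is.null(expected) && k != expected) {
    abort(sprintf("Expected %d groups, found %d.", expected, k),
          class = "blastopack_domain_error")
  }
  ns <- table(data$group)
  if (any(ns < 3)) {
    abort(sprintf("Every group needs n >= 3 (smallest has %d).", min(ns)),
          class = "blastopack_insufficient_sample")
  }
  data
}

#' Normality-gated two-group comparison
#'
#' Applies the normality gate to both groups; if both pass (and neither is
#' degenerate) the groups are compared with an unpaired two-tailed Student's
#' t-test, otherwise with a two-tailed Mann-Whitney (Wilcoxon rank-sum)
#' test. The route taken is recorded in the result.
#'
#' @param data Data frame with columns `group` (exactly two levels) and
#'   `value`; each group `n >= 3`.
#' @param alpha Significance level (default 0.05, i.e. 95% confidence).
#' @param gate_alpha Significance level of the normality gate (defaults to
#'   `alpha`).
#' @param gate_tests Normality test(s) for the gate; see [normality_gate()].
#' @param welch If `TRUE`, use the Welch (unequal-variance) t statistic on
#'   the parametric route instead of the pooled-variance Student default.
#' @return A `test_result` object; see [tidy.test_result()].
#' @examples
#' df <- make_group_table(c(20, 20), means = c(0, 1), sds = 1, seed = 2)
#' tidy(compare_two(df))
#' @export
compare_two <- function(data, alpha = 0.05, gate_alpha = alpha,
                        gate_tests = "shapiro", welch = FALSE) {
  data <- check_groups(data, expected = 2)
  summ <- group_summaries(data, gate_alpha, gate_tests)
  vals <- split(data$value, data$group)
  parametric <- all(summ$normal) && !any(summ$degenerate)
  if (parametric) {
    ht <- t.test(vals[[1]], vals[[2]], var.equal = !welch,
                 alternative = "two.sided", paired = FALSE)
    test_name <- if (welch) "Welch t-test" else "Student t-test"
  } else {
    ht <- suppressWarnings(
      wilcox.test(vals[[1]], vals[[2]], alternative = "two.sided",
                  paired = FALSE, exact = FALSE, correct = TRUE))
    test_name <- "Mann-Whitney"
  }
  structure(
    list(test = test_name, statistic = unname(ht$statistic),
         p_value = ht$p.value, alpha = alpha,
         comparison = "two-group", parametric = parametric,
         group_summaries = summ),
    class = "test_result"
  )
}

# Dunn's rank-sum z tests versus a control group, with tie correction.
dunn_vs_control <- function(vals, control) {
  all_v <- unlist(vals)
  n_total <- length(all_v)
  rk <- rank(all_v)
  ties <- table(all_v)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_total - 1))
  rk_groups <- split(rk, rep(names(vals), lengths(vals)))
  rbar <- vapply(rk_groups, mean, numeric(1))
  ns <- lengths(vals)
  others <- setdiff(names(vals), control)
  z <- vapply(others, function(g) {
    se <- sqrt((n_total * (n_total + 1) / 12 - tie_corr) *
                 (1 / ns[[g]] + 1 / ns[[control]]))
    (rbar[[g]] - rbar[[control]]) / se
  }, numeric(1))
  p_raw <- 2 * pnorm(-abs(z))
  tibble(comparison = paste(others, "vs", control),
         statistic = unname(z), p_raw = unname(p_raw),
         p_adj = unname(p.adjust(p_raw, method = "holm")))
}

#' Normality-gated many-group comparison versus a control
#'
#' When every group passes the normality gate the groups are compared with a
#' one-way ANOVA followed by Dunnett's comparisons against the control;
#' otherwise with a Kruskal-Wallis test followed by Dunn's rank-sum
#' comparisons against the control, Holm-adjusted. Adjusted p-values are
#' reported per comparison.
#'
#' @param data Data frame with columns `group` (>= 3 levels) and `value`;
#'   each group `n >= 3`.
#' @param control Name of the control group (must be a level of `group`).
#' @inheritParams compare_two
#' @return A `test_result_many` object; [tidy()] gives the per-comparison
#'   table, [glance()] the omnibus test.
#' @export
compare_many <- function(data, control, alpha = 0.05, gate_alpha = alpha,
                         gate_tests = "shapiro") {
  data <- check_groups(data)
  if (nlevels(data$group) < 3) {
    abort("`compare_many` needs at least 3 groups; use `compare_two`.",
          class = "blastopack_domain_error")
  }
  if (missing(control) || !control %in% levels(data$group)) {
    abort("`control` must name one of the groups.",
          class = "blastopack_domain_error")
  }
  summ <- group_summaries(data, gate_alpha, gate_tests)
  vals <- split(data$value, data$group)
  parametric <- all(summ$normal) && !any(summ$degenerate)
  if (parametric) {
    data$group <- stats::relevel(data$group, ref = control)
    fit <- aov(value ~ group, data = data)
    an <- summary(fit)[[1]]
    omnibus <- list(test = "one-way ANOVA",
                    statistic = an[["F value"]][1],
                    p_value = an[["Pr(>F)"]][1])
    # multcomp's single-step Dunnett p-values use quasi-Monte-Carlo
    # integration; pin the stream so results are reproducible
    comparisons <- with_seed(1L, {
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
      adj <- summary(gl)
      raw <- summary(gl, test = multcomp::adjusted("none"))
      tibble(
        comparison = names(adj$test$coefficients),
        statistic = unname(adj$test$tstat),
        p_raw = unname(raw$test$pvalues[seq_along(adj$test$tstat)]),
        p_adj = unname(adj$test$pvalues[seq_along(adj$test$tstat)])
      )
    })
    posthoc <- "Dunnett"
  } else {
    kw <- kruskal.test(value ~ group, data = data)
    omnibus <- list(test = "Kruskal-Wallis",
                    statistic = unname(kw$statistic),
                    p_value = kw$p.value)
    comparisons <- dunn_vs_control(vals, control)
    posthoc <- "Dunn (Holm-adjusted)"
  }
  comparisons$significant <- comparisons$p_adj < alpha
  structure(
    list(omnibus = omnibus, posthoc = posthoc, comparisons = comparisons,
         control = control, alpha = alpha, parametric = parametric,
         comparison = "multi-group vs control", group_summaries = summ),
    class = "test_result_many"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s (%s route): statistic = %.4g, p = %.4g\n",
              x$test, if (x$parametric) "parametric" else "nonparametric",
              x$statistic, x$p_value))
  invisible(x)
}

#' @export
print.test_result_many <- function(x, ...) {
  cat(sprintf("<test_result_many> %s + %s vs '%s': omnibus p = %.4g\n",
              x$omnibus$test, x$posthoc, x$control, x$omnibus$p_value))
  print(x$comparisons)
  invisible(x)
}
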