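#' Two-tailed Welch t test
#'
#' Two-sided Welch (unequal-variance) t test with Satterthwaite degrees of
#' freedom and the mean difference (A minus B) with its 95% CI.  Degenerate
#' zero-variance inputs are handled by convention: identical constant
#' groups give statistic 0 and p 1.
#'
#' @param a,b Numeric samples.
#' @param conf_level Confidence level for the difference.
#' @return Object of class `comparison_result`: `test`, `statistic`, `df`,
#'   `p_value`, `estimate`, `conf_int`.
#' @export
#' @examples
#' welch_t(rnorm(10), rnorm(10, 1))
welch_t <- function(a, b, conf_level = 0.95) {
  .assert(is.numeric(a) && is.numeric(b) && length(a) >= 2 && length(b) >= 2,
          "'a' and 'b' must be numeric with at least 2 values each")
  est <- mean(a) - mean(b)
  if (var(a) + var(b) == 0) {
    res <- list(statistic = if (est == 0) 0 else sign(est) * Inf,
                parameter = length(a) + length(b) - 2,
                p.value = if (est == 0) 1 else 0,
                conf.int = c(est, est))
  } else {
    tt <- t.test(a, b, var.equal = FALSE, conf.level = conf_level)
    res <- list(statistic = unname(tt$statistic), parameter = unname(tt$parameter),
                p.value = tt$p.value, conf.int = as.numeric(tt$conf.int))
  }
  structure(list(test = "Welch two-sample t (two-tailed)",
                 statistic = res$statistic, df = res$parameter,
                 p_value = res$p.value, estimate = est,
                 conf_int = res$conf.int, pairwise = NULL),
            class = "comparison_result")
}

#' One-way ANOVA with Tukey post hoc comparisons
#'
#' One-way analysis of variance across groups followed by all pairwise
#' Tukey honest-significant-difference comparisons (studentized-range
#' adjustment).
#'
#' @param values Numeric vector of observations, or a named list of group
#'   vectors (in which case `group` is ignored).
#' @param group Factor/character of group labels parallel to `values`.
#' @param conf_level Confidence level of the Tukey intervals.
#' @return A `comparison_result`; `pairwise` holds the Tukey table
#'   (difference, CI, adjusted p).
#' @export
#' @examples
#' oneway_anova_tukey(list(A = rnorm(8), B = rnorm(8), C = rnorm(8, 1)))
oneway_anova_tukey <- function(values, group = NULL, conf_level = 0.95) {
  if (is.list(values)) {
    group <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  .assert(length(values) == length(group), "'values' and 'group' lengths differ")
  group <- factor(group)
  .assert(nlevels(group) >= 2, "at least 2 groups are required")
  dat <- data.frame(y = values, g = group)
  fit <- aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]
  # an exactly-null between-group variance yields F = 0, not NaN
  if (is.na(Fv) && an[["Sum Sq"]][1] == 0) Fv <- 0
  pv <- an[["Pr(>F)"]][1]
  if (is.na(pv) && identical(Fv, 0)) pv <- 1
  tk <- TukeyHSD(fit, conf.level = conf_level)$g
  pw <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"], row.names = NULL)
  gm <- tapply(values, group, mean)
  structure(list(test = "one-way ANOVA + Tukey HSD", statistic = Fv,
                 df = c(df1 = an[["Df"]][1], df2 = an[["Df"]][2]),
                 p_value = pv, estimate = max(gm) - min(gm),
                 conf_int = NULL, pairwise = pw),
            class = "comparison_result")
}

.check_balanced <- function(table, metric) {
  d <- table[table$metric == metric, , drop = FALSE]
  .assert(nrow(d) > 0, sprintf("metric '%s' not present in table", metric))
  tab <- table(d$subject_id, d$time_s)
  .assert(all(tab == 1),
          paste("unbalanced table: every subject needs exactly one value per",
                "timepoint.  Complete the cases (or average duplicates) before",
                "calling rm_group_time()."))
  grp <- unique(d[, c("subject_id", "group")])
  .assert(!any(duplicated(grp$subject_id)), "subjects must belong to a single group")
  .assert(length(unique(table(grp$group))) == 1,
          "unbalanced table: groups must have equal numbers of subjects")
  d
}

#' Group x time repeated-measures comparison
#'
#' Balanced two-way repeated-measures ANOVA with ventilation group as the
#' between-subject factor and timepoint as the within-subject factor:
#' group is tested against the subject-within-group stratum, time and
#' group:time against the within-subject residual.  This closed-form
#' decomposition is exact for the balanced complete tables the simulator
#' produces; unbalanced tables are rejected with guidance rather than
#' silently approximated.  Pairwise group contrasts (Tukey studentized
#' range on subject means, using the between-subject stratum) are attached.
#'
#' @param table Long-format cohort table with columns `subject_id`,
#'   `group`, `time_s`, `metric`, `value`.
#' @param metric Which metric to analyse.
#' @return A `comparison_result`; `statistic`/`p_value` refer to the
#'   group:time interaction, `terms` holds all three F tests, `pairwise`
#'   the Tukey group contrasts.
#' @export
rm_group_time <- function(table, metric) {
  .assert(all(c("subject_id", "group", "time_s", "metric", "value") %in% names(table)),
          "'table' must have columns subject_id, group, time_s, metric, value")
  d <- .check_balanced(table, metric)
  d$group <- factor(d$group); d$time <- factor(d$time_s)
  d$subject_id <- factor(d$subject_id)
  fit <- aov(value ~ group * time + Error(subject_id), data = d)
  s <- summary(fit)
  between <- s[["Error: subject_id"]][[1]]
  within <- s[["Error: Within"]][[1]]
  terms <- data.frame(
    term = c("group", "time", "group:time"),
    df1 = c(between["group", "Df"], within["time", "Df"], within["group:time", "Df"]),
    df2 = c(between["Residuals", "Df"], within["Residuals", "Df"],
            within["Residuals", "Df"]),
    F = c(between["group", "F value"], within["time", "F value"],
          within["group:time", "F value"]),
    p = c(between["group", "Pr(>F)"], within["time", "Pr(>F)"],
          within["group:time", "Pr(>F)"]))
  # an exactly-null effect must report F = 0, not NaN or a ratio of
  # floating-point residue
  ss <- c(between["group", "Sum Sq"], within["time", "Sum Sq"],
          within["group:time", "Sum Sq"])
  ss_tot <- sum(between[, "Sum Sq"]) + sum(within[, "Sum Sq"])
  for (i in seq_len(3)) {
    if (is.na(terms$F[i]) || ss[i] <= 1e-12 * ss_tot) {
      terms$F[i] <- 0; terms$p[i] <- 1
    }
  }

  # Tukey group contrasts on subject means against the between-subject stratum
  sm <- aggregate(value ~ subject_id + group, data = d, FUN = mean)
  ng <- nlevels(d$group)
  n_per <- nrow(sm) / ng
  ms_between <- between["Residuals", "Mean Sq"] / nlevels(d$time)
  gm <- tapply(sm$value, sm$group, mean)
  cmb <- utils::combn(names(gm), 2)
  se <- sqrt(ms_between / n_per)
  pw <- data.frame(comparison = paste(cmb[2, ], cmb[1, ], sep = "-"),
                   diff = gm[cmb[2, ]] - gm[cmb[1, ]], row.names = NULL)
  pw$p_adj <- ptukey(abs(pw$diff) / se, nmeans = ng,
                     df = between["Residuals", "Df"], lower.tail = FALSE)
  structure(list(test = "repeated-measures ANOVA (group x time)",
                 statistic = terms$F[3],
                 df = c(df1 = terms$df1[3], df2 = terms$df2[3]),
                 p_value = terms$p[3], estimate = max(gm) - min(gm),
                 conf_int = NULL, terms = terms, pairwise = pw),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$test, "\n")
  if (!is.null(x$terms)) {
    for (i in seq_len(nrow(x$terms)))
      cat(sprintf("  %-10s F(%d, %d) = %.4g, p = %.4g\n", x$terms$term[i],
                  x$terms$df1[i], x$terms$df2[i], x$terms$F[i], x$terms$p[i]))
  } else {
    cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n", x$statistic,
                paste(signif(x$df, 4), collapse = ", "), x$p_value))
  }
  if (!is.null(x$conf_int))
    cat(sprintf("  estimate %.4g [%.4g, %.4g]\n", x$estimate,
                x$conf_int[1], x$conf_int[2]))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Tukey-adjusted):\n")
    print.data.frame(x$pairwise, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Figure-style cohort summary with the applicable test
#'
#' Per-group mean +/- SD for every metric in the table plus the comparison
#' the study design calls for: a two-tailed Welch t test for two groups, a
#' one-way ANOVA with Tukey post hoc for three or more.  Tables with
#' multiple timepoints are first averaged within subject unless
#' `time_s` is given.
#'
#' @param table Long cohort table (`subject_id`, `group`, `time_s`,
#'   `metric`, `value`).
#' @param time_s Restrict to one timepoint (default: average over time
#'   within subject).
#' @return List of class `cohort_summary`: `summary` data frame (metric,
#'   group, n, mean, sd) and `comparisons` (named list of
#'   `comparison_result`).
#' @export
summarize_cohort <- function(table, time_s = NULL) {
  .assert(all(c("subject_id", "group", "metric", "value") %in% names(table)),
          "'table' must have columns subject_id, group, metric, value")
  if (!is.null(time_s)) table <- table[table$time_s %in% time_s, , drop = FALSE]
  agg <- aggregate(value ~ subject_id + group + metric, data = table, FUN = mean)
  summ <- do.call(rbind, lapply(split(agg, agg$metric), function(d) {
    do.call(rbind, lapply(split(d, d$group, drop = TRUE), function(g)
      data.frame(metric = g$metric[1], group = g$group[1], n = nrow(g),
                 mean = mean(g$value), sd = sd(g$value))))
  }))
  rownames(summ) <- NULL
  comparisons <- lapply(split(agg, agg$metric), function(d) {
    gs <- split(d$value, d$group, drop = TRUE)
    if (length(gs) == 2) welch_t(gs[[1]], gs[[2]])
    else oneway_anova_tukey(d$value, d$group)
  })
  structure(list(summary = summ, comparisons = comparisons),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (mean +/- SD by group)\n")
  s <- x$summary
  s$mean <- signif(s$mean, 4); s$sd <- signif(s$sd, 4)
  print.data.frame(s, row.names = FALSE)
  cat("\nComparisons:\n")
  for (m in names(x$comparisons))
    cat(sprintf("  %-24s %s  p = %.4g\n", m, x$comparisons[[m]]$test,
                x$comparisons[[m]]$p_value))
  invisible(x)
}
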