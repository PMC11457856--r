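test_that("Welch t test matches the closed-form statistic to 1e-10", {
  set.seed(11)
  a <- rnorm(20); b <- rnorm(20, 0.4)
  res <- welch_t(a, b)
  # independent formula: Welch statistic and Satterthwaite df
  se2a <- var(a) / length(a); se2b <- var(b) / length(b)
  t_ref <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df_ref <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(res$statistic, t_ref, tolerance = 1e-10)
  expect_equal(res$df, df_ref, tolerance = 1e-10)
  expect_equal(res$p_value, p_ref, tolerance = 1e-10)
  expect_true(res$conf_int[1] <= res$estimate && res$estimate <= res$conf_int[2])
})

test_that("Welch t degenerate and shift cases", {
  res <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res <- welch_t(c(1, 2, 3) + 10, c(1, 2, 3))
  expect_equal(res$estimate, 10)
  expect_equal(res$statistic, welch_t(c(1, 2, 3), c(-9, -8, -7))$statistic)
})

test_that("one-way ANOVA: zero between-group variance gives F = 0", {
  res <- oneway_anova_tukey(list(A = c(1, 2, 3), B = c(2, 1, 3), C = c(3, 2, 1)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("one-way ANOVA F matches a brute-force sums-of-squares oracle", {
  set.seed(12)
  g <- rep(c("A", "B", "C"), each = 8)
  y <- rnorm(24) + rep(c(0, 0.5, 1), each = 8)
  res <- oneway_anova_tukey(y, g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  F_ref <- (ssb / 2) / (ssw / 21)
  expect_equal(res$statistic, F_ref, tolerance = 1e-10)
  expect_equal(res$p_value, pf(F_ref, 2, 21, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("with two groups the ANOVA F equals the squared pooled t", {
  set.seed(13)
  a <- rnorm(10); b <- rnorm(10, 1)
  res <- oneway_anova_tukey(list(A = a, B = b))
  t_pooled <- t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(res$statistic, unname(t_pooled)^2, tolerance = 1e-8)
})

test_that("Tukey-adjusted p values never fall below the unadjusted pairwise p", {
  set.seed(14)
  for (r in 1:5) {
    g <- rep(c("A", "B", "C"), each = 6)
    y <- rnorm(18)
    res <- oneway_anova_tukey(y, g)
    ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
    mse <- ssw / 15
    gm <- tapply(y, g, mean)
    for (i in seq_len(nrow(res$pairwise))) {
      pair <- strsplit(res$pairwise$comparison[i], "-")[[1]]
      t_un <- abs(gm[pair[1]] - gm[pair[2]]) / sqrt(mse * (1 / 6 + 1 / 6))
      p_un <- 2 * pt(-t_un, 15)
      expect_gte(res$pairwise$p_adj[i] + 1e-12, p_un)
    }
  }
})

make_rm_table <- function(values, groups, times, subjects_per_group) {
  n <- subjects_per_group * length(groups)
  data.frame(subject_id = rep(sprintf("s%02d", seq_len(n)), times = length(times)),
             group = rep(rep(groups, each = subjects_per_group), length(times)),
             time_s = rep(times, each = n),
             metric = "m", value = values)
}

test_that("constructed effects: group shift is detected, flat time gives F = 0", {
  base <- rep(c(0, 5, 10), each = 4) + rep(seq(0, 0.3, length.out = 4), 3)
  tab <- make_rm_table(c(base, base), c("A", "B", "C"), c(1, 2), 4)
  res <- rm_group_time(tab, "m")
  terms <- res$terms
  expect_gt(terms$F[terms$term == "group"], 100)
  expect_equal(terms$F[terms$term == "time"], 0)
  expect_equal(terms$F[terms$term == "group:time"], 0)
})

test_that("repeated-measures F matches a brute-force sums-of-squares oracle to 1e-8", {
  set.seed(15)
  groups <- c("A", "B", "C"); times <- c(1, 2, 3); npg <- 5
  n <- npg * length(groups)
  y <- rnorm(n * length(times)) + rep(c(0, 0.5, 1), each = npg)
  tab <- make_rm_table(y, groups, times, npg)
  res <- rm_group_time(tab, "m")

  d <- tab
  d$cell <- interaction(d$group, d$time_s)
  gm <- mean(d$value)
  T <- length(times); G <- length(groups)
  subj_means <- tapply(d$value, d$subject_id, mean)
  subj_group <- tapply(as.character(d$group), d$subject_id, `[`, 1)
  grp_means <- tapply(d$value, d$group, mean)
  time_means <- tapply(d$value, d$time_s, mean)
  cell_means <- tapply(d$value, d$cell, mean)
  ss_group <- T * npg * sum((grp_means - gm)^2)
  ss_subj <- T * sum((subj_means - grp_means[subj_group])^2)
  ss_time <- G * npg * sum((time_means - gm)^2)
  ss_cells <- npg * sum((cell_means - gm)^2)
  ss_int <- ss_cells - ss_group - ss_time
  ss_tot <- sum((d$value - gm)^2)
  ss_res <- ss_tot - ss_group - ss_subj - ss_time - ss_int
  F_group <- (ss_group / (G - 1)) / (ss_subj / (G * (npg - 1)))
  df_res <- (G * npg - G) * (T - 1)
  F_time <- (ss_time / (T - 1)) / (ss_res / df_res)
  F_int <- (ss_int / ((G - 1) * (T - 1))) / (ss_res / df_res)

  terms <- res$terms
  expect_equal(terms$F[terms$term == "group"], F_group, tolerance = 1e-8)
  expect_equal(terms$F[terms$term == "time"], F_time, tolerance = 1e-8)
  expect_equal(terms$F[terms$term == "group:time"], F_int, tolerance = 1e-8)
})

test_that("unbalanced tables are rejected with guidance", {
  tab <- make_rm_table(rnorm(24), c("A", "B", "C"), c(1, 2), 4)
  tab <- tab[-1, ]
  expect_error(rm_group_time(tab, "m"), "unbalanced")
  expect_error(rm_group_time(make_rm_table(rnorm(24), c("A", "B", "C"),
                                           c(1, 2), 4), "absent"),
               "not present")
})

test_that("cohort summary dispatches on group count and is reproducible", {
  set.seed(16)
  two <- make_rm_table(rnorm(16), c("A", "B"), c(1, 2), 4)
  s2 <- summarize_cohort(two)
  expect_match(s2$comparisons$m$test, "Welch")
  three <- make_rm_table(rnorm(24), c("A", "B", "C"), c(1, 2), 4)
  s3 <- summarize_cohort(three)
  expect_match(s3$comparisons$m$test, "ANOVA")
  expect_identical(summarize_cohort(three), s3)
  expect_equal(s3$summary$n, rep(4, 3))
})

test_that("power rises with simulated effect size at fixed n", {
  set.seed(17)
  reject <- vapply(c(0, 1, 2), function(delta) {
    mean(vapply(1:60, function(i)
      welch_t(rnorm(10), rnorm(10, delta))$p_value < 0.05, logical(1)))
  }, numeric(1))
  expect_true(all(diff(reject) > 0))
  expect_lt(reject[1], 0.2)
  expect_gt(reject[3], 0.9)
})
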