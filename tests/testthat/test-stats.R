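test_that("the assumption gate selects the documented branch", {
  set.seed(21)
  a <- rnorm(25); b <- rnorm(25, 0.4)
  res <- compare_groups(a, b)
  expect_equal(res$test, "student_t")
  expect_equal(res$df, 48)
  expect_equal(res$effect, 2 * res$statistic / sqrt(48))
  # strongly skewed data fails the normality gate
  res2 <- compare_groups(rexp(25)^3, rexp(25)^3)
  expect_equal(res2$test, "mann_whitney")
  expect_true(res2$effect >= 0 && res2$effect <= 1)
})

test_that("forced Mann-Whitney matches hand-computable cases", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6), force = "mann_whitney")
  expect_equal(res$statistic, 0)  # no pairwise wins for the first group
  same <- compare_groups(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5),
                         force = "mann_whitney")
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  tt <- compare_groups(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5),
                       force = "student_t")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)
  expect_equal(tt$effect, 0)
  expect_error(compare_groups(rep(1, 5), rep(1, 5)), "degenerate")
  expect_error(compare_groups(1:2, 1:5), "n >= 3")
})

test_that("U equals the exhaustive pairwise-win oracle on small samples", {
  set.seed(5)
  for (n1 in 3:6) for (n2 in 3:6) {
    for (rep in 1:25) {
      a <- sample(0:4, n1, replace = TRUE)  # small alphabet forces ties
      b <- sample(0:4, n2, replace = TRUE)
      if (length(unique(c(a, b))) == 1L) next
      res <- compare_groups(a, b, force = "mann_whitney")
      expect_equal(res$statistic, oracle_u(a, b))
    }
  }
})

test_that("t_from_summaries agrees with the raw-sample t branch", {
  set.seed(13)
  for (rep in 1:20) {
    a <- rnorm(sample(5:30, 1), sd = runif(1, .5, 2))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    raw <- compare_groups(a, b, force = "student_t")
    summ <- t_from_summaries(mean(a), sd(a), length(a),
                             mean(b), sd(b), length(b))
    expect_equal(raw$statistic, summ$t, tolerance = 1e-12)
    expect_equal(raw$p, summ$p, tolerance = 1e-12)
    expect_equal(raw$effect, summ$d, tolerance = 1e-12)
  }
  expect_error(t_from_summaries(1, 0, 10, 2, 1, 10), "positive")
})

test_that("type-I error of the gated test is near alpha under the null", {
  set.seed(99)
  reps <- 600
  hits <- vapply(seq_len(reps), function(i)
    compare_groups(rnorm(20), rnorm(20))$p < 0.05, logical(1))
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(hits) - 0.05), 3 * se)
})

test_that("pearson correlation and r-squared", {
  x <- 1:10
  res <- pearson_correlation(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$r2, 1)
  y <- rnorm(20)
  x2 <- rnorm(20)
  y_orth <- residuals(lm(y ~ x2))
  expect_equal(pearson_correlation(x2, y_orth)$r, 0, tolerance = 1e-10)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:4, 1:5), "equal length")
})

test_that("mixed ANOVA eta2 matches a sums-of-squares oracle (6 subjects)", {
  toy <- data.frame(
    subject = rep(1:6, each = 2),
    group = rep(c("ASD", "TD"), each = 6),
    task = rep(c("book", "picture"), 6),
    value = c(10, 4, 12, 5, 9, 3, 15, 6, 14, 7, 16, 8))
  res <- mixed_anova(toy)
  # independent decomposition from cell/marginal means
  g <- mean(toy$value)
  ss_total <- sum((toy$value - g)^2)
  m_task <- tapply(toy$value, toy$task, mean)
  ss_task <- sum(6 * (m_task - g)^2)
  m_group <- tapply(toy$value, toy$group, mean)
  ss_group <- sum(6 * (m_group - g)^2)
  m_cell <- tapply(toy$value, list(toy$group, toy$task), mean)
  ss_cells <- sum(3 * (m_cell - g)^2)
  ss_inter <- ss_cells - ss_task - ss_group
  eff <- res$effects
  expect_equal(eff$eta2[eff$effect == "task"], ss_task / ss_total)
  expect_equal(eff$eta2[eff$effect == "group"], ss_group / ss_total)
  expect_equal(eff$eta2[eff$effect == "group:task"], ss_inter / ss_total)
  expect_equal(unique(eff$df_den), 4L)  # n_complete - 2
  expect_true(res$sphericity_ok)
})

test_that("mixed ANOVA behavior: injected effects, constants, missingness", {
  set.seed(31)
  n <- 12
  base <- rnorm(2 * n, 10)
  d <- data.frame(subject = rep(seq_len(2 * n), each = 2),
                  group = rep(c("ASD", "TD"), each = 2 * n),
                  task = rep(c("book", "picture"), 2 * n),
                  value = rep(base, each = 2) +
                    rep(c(5, 0), 2 * n) + rnorm(4 * n, sd = .5))
  res <- mixed_anova(d)
  eff <- res$effects
  expect_lt(eff$p[eff$effect == "task"], 0.001)
  expect_gt(eff$p[eff$effect == "group"], 0.05)

  dc <- d; dc$value <- 7
  effc <- mixed_anova(dc)$effects
  expect_equal(effc$F, c(0, 0, 0))

  # subjects missing one task are excluded as incomplete cases
  dm <- d[-1, ]
  expect_equal(mixed_anova(dm)$n_complete, 2 * n - 1)
  expect_error(mixed_anova(d[d$subject <= 2, ]), "two groups")
})

test_that("bonferroni screen multiplies and thresholds", {
  set.seed(17)
  tab <- data.frame(group = rep(c("ASD", "TD"), each = 20))
  for (i in 1:5) tab[[paste0("v", i)]] <- rnorm(40)
  out <- bonferroni_screen(tab, paste0("v", 1:5))
  expect_equal(attr(out, "m"), 5L)
  expect_equal(attr(out, "threshold"), 0.01)
  expect_equal(out$p_bonferroni, pmin(1, out$p * 5))
  # raw p .01 with m = 70 is no longer significant
  expect_equal(min(1, 0.01 * 70), 0.7)
  one <- bonferroni_screen(tab, "v1")
  expect_equal(one$p_bonferroni, one$p)  # m = 1 is the identity
  # degenerate variable is skipped, not fatal
  tab$flat <- 1
  sk <- bonferroni_screen(tab, c("v1", "flat"))
  expect_equal(sk$test[sk$variable == "flat"], "skipped")
})
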