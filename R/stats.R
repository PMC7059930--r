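# The two-group battery: assumption-gated Student t / Mann-Whitney U with
# Cohen's d and r effect sizes, summary-statistic t, Pearson correlations,
# 2 (group) x 2 (task) mixed ANOVA, and a Bonferroni-corrected screen.

#' Brown-Forsythe / Levene homogeneity test
#'
#' One-way ANOVA on absolute deviations from the group center
#' (median by default, the Brown-Forsythe variant).
#'
#' @param values Numeric vector.
#' @param groups Grouping factor (2+ levels).
#' @param center `median` (default) or `mean`.
#' @return list(statistic, df, p).
#' @export
levene_test <- function(values, groups, center = stats::median) {
  groups <- factor(groups)
  z <- abs(values - stats::ave(values, groups, FUN = center))
  fit <- stats::anova(stats::lm(z ~ groups))
  list(statistic = fit[["F value"]][1L],
       df = c(fit$Df[1L], fit$Df[2L]),
       p = fit[["Pr(>F)"]][1L])
}

group_summaries <- function(a, b, names = c("a", "b")) {
  data.frame(group = names,
             mean = c(mean(a), mean(b)),
             sd = c(stats::sd(a), stats::sd(b)),
             n = c(length(a), length(b)),
             stringsAsFactors = FALSE)
}

# Mann-Whitney with midranks: U1 = wins of sample a (+ half ties),
# tie-corrected normal approximation for Z and the two-sided p.
mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  mu <- n1 * n2 / 2
  z <- if (sigma2 > 0) (u1 - mu) / sqrt(sigma2) else 0
  p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  list(U = min(u1, u2), U1 = u1, U2 = u2, Z = z, p = min(p, 1),
       r = abs(z) / sqrt(N))
}

student_t_pooled <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se > 0) (mean(a) - mean(b)) / se else 0
  p <- if (se > 0) 2 * stats::pt(-abs(t), df) else 1
  list(t = t, df = df, p = p, d = 2 * t / sqrt(df))
}

#' Assumption-gated two-group comparison
#'
#' Applies Student's pooled-variance t-test when both groups pass a
#' Shapiro-Wilk normality check and the groups pass a Levene
#' (center = median) homogeneity check, each at `alpha`; otherwise the
#' Mann-Whitney U test with a tie-corrected normal approximation. Effect
#' sizes: Cohen's `d = 2t/sqrt(df)` for the t branch, `r = |Z|/sqrt(N)` for
#' the U branch.
#'
#' @param values_a,values_b Numeric samples (each n >= 3).
#' @param alpha Gate level for the assumption checks (default .05).
#' @param variable Variable name carried into the result.
#' @param force Optional: `"student_t"` or `"mann_whitney"` to bypass the
#'   gate.
#' @return An object of class `comparison_result`.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05,
                           variable = "value", force = NULL) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 3L || length(b) < 3L)
    stop("compare_groups: each sample needs n >= 3")
  if (stats::var(a) == 0 && stats::var(b) == 0 && length(unique(c(a, b))) == 1L)
    stop("compare_groups: degenerate samples (no variance in either group)")
  gate <- list(normal_a = NA, normal_b = NA, homogeneous = NA)
  if (is.null(force)) {
    sw_p <- function(x) {
      if (stats::var(x) == 0) return(0)  # constant sample: clearly non-normal
      stats::shapiro.test(x)$p.value
    }
    gate$normal_a <- sw_p(a) > alpha
    gate$normal_b <- sw_p(b) > alpha
    gate$homogeneous <- levene_test(c(a, b),
                                    rep(c("a", "b"), c(length(a), length(b)))
                                    )$p > alpha
    use_t <- gate$normal_a && gate$normal_b && gate$homogeneous
  } else {
    use_t <- match.arg(force, c("student_t", "mann_whitney")) == "student_t"
  }
  gs <- group_summaries(a, b)
  if (use_t) {
    fit <- student_t_pooled(a, b)
    res <- list(variable = variable, test = "student_t",
                statistic = fit$t, z = NA_real_, df = fit$df, p = fit$p,
                effect = fit$d, effect_type = "cohen_d",
                gate = gate, group_summaries = gs)
  } else {
    fit <- mann_whitney(a, b)
    res <- list(variable = variable, test = "mann_whitney",
                statistic = fit$U, z = fit$Z, df = NA_real_, p = fit$p,
                effect = fit$r, effect_type = "r",
                gate = gate, group_summaries = gs)
  }
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (x$test == "student_t") {
    cat(sprintf("%s: t(%d) = %.3f, p = %.4f, d = %.3f\n",
                x$variable, x$df, x$statistic, x$p, x$effect))
  } else {
    cat(sprintf("%s: U = %.1f, Z = %.3f, p = %.4f, r = %.3f\n",
                x$variable, x$statistic, x$z, x$p, x$effect))
  }
  invisible(x)
}

#' Pooled t-test from group summary statistics
#'
#' Recomputes the independent-samples Student t-test (pooled variance,
#' df = n1 + n2 - 2) from printed group means, SDs and sizes, with Cohen's
#' d = 2t/sqrt(df).
#'
#' @param m1,sd1,n1 Mean, SD, size of group 1.
#' @param m2,sd2,n2 Mean, SD, size of group 2.
#' @return list(t, df, p, d); t is signed (group1 - group2).
#' @export
t_from_summaries <- function(m1, sd1, n1, m2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("t_from_summaries: sds must be positive")
  if (n1 < 2 || n2 < 2) stop("t_from_summaries: ns must be >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), d = 2 * t / sqrt(df))
}

#' Pearson correlation with r-squared
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return An object of class `correlation_result`: list(r, r2, p, n).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("pearson_correlation: n >= 3 required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
                 p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f, r2 = %.2f, p = %.4g, n = %d\n",
              x$r, x$r2, x$p, x$n))
  invisible(x)
}

#' Two-way mixed ANOVA (2 groups x 2 repeated tasks)
#'
#' Between-subjects factor `group`, within-subjects factor `task` with two
#' levels. Only complete cases (subjects with both task values) enter.
#' Effects are tested on the subject-mean / subject-difference
#' decomposition with unweighted (type III) means, so unbalanced groups are
#' handled as standard mixed-ANOVA software does. With two within-subject
#' levels sphericity holds by construction and is reported as satisfied.
#' Eta-squared is classical: SS_effect / SS_total. Bonferroni post-hoc task
#' contrasts (paired t) are reported overall and per group (per-group p
#' values adjusted for the two contrasts).
#'
#' @param data data.frame with columns `subject`, `group`, `task`, `value`.
#' @return An object of class `mixed_anova_result`: `effects` table
#'   (effect, F, df_num, df_den, p, eta2), `sphericity_ok`, `posthoc`,
#'   `n_complete`.
#' @export
mixed_anova <- function(data) {
  need <- c("subject", "group", "task", "value")
  stopifnot(all(need %in% names(data)))
  data <- data[stats::complete.cases(data[need]), need]
  tasks <- sort(unique(data$task))
  groups <- sort(unique(data$group))
  if (length(tasks) != 2L || length(groups) != 2L)
    stop("mixed_anova: exactly two tasks and two groups required")
  wide <- stats::reshape(data, idvar = c("subject", "group"),
                         timevar = "task", direction = "wide")
  v1 <- paste0("value.", tasks[1L]); v2 <- paste0("value.", tasks[2L])
  wide <- wide[stats::complete.cases(wide[c(v1, v2)]), ]
  n_g <- table(wide$group)
  if (length(n_g) < 2L || any(n_g < 2L))
    stop("mixed_anova: fewer than 2 complete subjects in a group")
  N <- nrow(wide)
  y1 <- wide[[v1]]; y2 <- wide[[v2]]
  g <- factor(wide$group)
  avg <- (y1 + y2) / 2
  dif <- y1 - y2

  grand <- mean(c(y1, y2))
  ss_total <- sum((c(y1, y2) - grand)^2)

  # between-subjects stratum: one-way ANOVA on subject means
  gm <- tapply(avg, g, mean)
  ss_group <- 2 * sum(n_g * (gm - mean(avg))^2)  # type I on avg; 2 obs/subj
  ss_subj <- 2 * sum((avg - grand)^2)
  ss_err_between <- 2 * sum((avg - gm[g])^2)
  df_between <- N - 2L
  ms_err_between <- ss_err_between / df_between
  f_group <- if (ms_err_between > 0) (ss_group / 1) / ms_err_between else 0

  # within-subjects stratum via subject differences; Var(d) = 2 * within MS
  dm <- tapply(dif, g, mean)
  dbar_u <- mean(dm)                       # unweighted (type III) task mean
  ss_err_within <- sum((dif - dm[g])^2) / 2
  ms_err_within <- ss_err_within / df_between
  # effective n for the unweighted mean: 1/(1/4 * sum(1/n_g)) on d-scale
  ss_task <- dbar_u^2 / (sum(1 / n_g) / 4) / 2
  ss_inter <- sum(n_g * (dm - dbar_u)^2) / 2
  f_task <- if (ms_err_within > 0) ss_task / ms_err_within else 0
  f_inter <- if (ms_err_within > 0) ss_inter / ms_err_within else 0

  p_of <- function(f, df2) {
    if (f == 0) 1 else stats::pf(f, 1, df2, lower.tail = FALSE)
  }
  eta2 <- function(ss) if (ss_total > 0) ss / ss_total else 0
  effects <- data.frame(
    effect = c("group", "task", "group:task"),
    F = c(f_group, f_task, f_inter),
    df_num = 1L,
    df_den = df_between,
    p = c(p_of(f_group, df_between), p_of(f_task, df_between),
          p_of(f_inter, df_between)),
    eta2 = c(eta2(ss_group), eta2(ss_task), eta2(ss_inter)),
    stringsAsFactors = FALSE)

  paired_p <- function(d) {
    if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
    stats::t.test(d)$p.value
  }
  posthoc <- data.frame(
    contrast = c(paste0(tasks[1L], " vs ", tasks[2L]),
                 paste0(tasks[1L], " vs ", tasks[2L], " | ", groups[1L]),
                 paste0(tasks[1L], " vs ", tasks[2L], " | ", groups[2L])),
    scope = c("overall", groups),
    p_raw = c(paired_p(dif),
              paired_p(dif[g == groups[1L]]),
              paired_p(dif[g == groups[2L]])),
    stringsAsFactors = FALSE)
  posthoc$p_bonferroni <- pmin(1, posthoc$p_raw * c(1, 2, 2))

  structure(list(effects = effects, sphericity_ok = TRUE,
                 posthoc = posthoc, n_complete = N,
                 ss = c(group = ss_group, task = ss_task,
                        interaction = ss_inter, total = ss_total)),
            class = "mixed_anova_result")
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat("Mixed ANOVA (", x$n_complete, "complete cases ), sphericity",
      if (x$sphericity_ok) "ok\n" else "violated\n")
  for (i in seq_len(nrow(x$effects)))
    cat(sprintf("  %-10s F(%d, %d) = %.3f, p = %.4g, eta2 = %.3f\n",
                x$effects$effect[i], x$effects$df_num[i],
                x$effects$df_den[i], x$effects$F[i], x$effects$p[i],
                x$effects$eta2[i]))
  invisible(x)
}

#' Bonferroni-corrected morphosyntactic screen
#'
#' Runs the gated two-group comparison for each variable and applies the
#' Bonferroni family-wise correction: adjusted threshold `alpha / m` and
#' adjusted p `min(1, p * m)` for `m` variables. Variables that are
#' degenerate (no variance in either group) are reported as skipped.
#'
#' @param feature_table data.frame with a `group` column and the variables.
#' @param variables Character vector of column names to screen (m >= 2).
#' @param alpha Family-wise level.
#' @return data.frame with per-variable test, statistic, p, p_bonferroni,
#'   significant_raw, significant_adjusted; attributes `alpha`,
#'   `threshold`, `m`.
#' @export
bonferroni_screen <- function(feature_table, variables, alpha = 0.05) {
  stopifnot("group" %in% names(feature_table), length(variables) >= 1L)
  m <- length(variables)
  groups <- sort(unique(feature_table$group))
  if (length(groups) != 2L) stop("bonferroni_screen: exactly two groups")
  rows <- lapply(variables, function(v) {
    x <- feature_table[[v]]
    a <- x[feature_table$group == groups[1L]]
    b <- x[feature_table$group == groups[2L]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    res <- tryCatch(compare_groups(a, b, alpha = alpha, variable = v),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(variable = v, test = "skipped",
                        statistic = NA_real_, p = NA_real_,
                        effect = NA_real_, stringsAsFactors = FALSE))
    data.frame(variable = v, test = res$test, statistic = res$statistic,
               p = res$p, effect = res$effect, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * m)
  out$significant_raw <- !is.na(out$p) & out$p < alpha
  out$significant_adjusted <- !is.na(out$p) & out$p < alpha / m
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- alpha / m
  attr(out, "m") <- m
  out
}
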