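test_that("generator config validates its invariants", {
  expect_s3_class(generator_config(), "generator_config")
  r <- default_rates <- generator_config()$rates
  r$ASD$book$pos[1] <- -1
  expect_error(generator_config(rates = r), ">= 0")
  expect_error(generator_config(missing = c(book = 0, picture = 1.2)),
               "\\[0, 1\\]")
})

test_that("feature table generation: determinism, rates, missingness", {
  cfg <- generator_config(seed = 404)
  t1 <- generate_feature_table(cfg)
  t2 <- generate_feature_table(cfg)
  expect_identical(t1, t2)
  expect_true(all(t1$abstraction ==
                    t1$n_dav + 2 * t1$n_iav + 3 * t1$n_sv))
  # book rows complete, picture rows thinned by the missing probability
  expect_equal(sum(t1$task == "book"), 50L)
  expect_lt(sum(t1$task == "picture"), 50L)

  # large-sample means approach the configured targets (law of large numbers)
  big <- generate_feature_table(generator_config(n_per_group = 4000,
                                                 missing = c(book = 0,
                                                             picture = 0),
                                                 seed = 10))
  bb <- big[big$task == "book", ]
  for (g in c("ASD", "TD")) {
    r <- generator_config()$rates[[g]]$book
    for (v in c("pos", "neg", "dav", "sv")) {
      m <- mean(bb[[paste0("n_", v)]][bb$group == g])
      se <- r[[v]][2] / sqrt(4000)
      expect_lt(abs(m - r[[v]][1]), 4 * se)
    }
  }

  # zero rates -> all-zero counts and abstraction
  zr <- rapply(generator_config()$rates, function(x) c(0, 1), how = "replace")
  zt <- generate_feature_table(generator_config(rates = zr, seed = 2))
  expect_true(all(zt$abstraction == 0))
  expect_true(all(zt$n_tokens == 0))
})

test_that("corpus generation closes the loop through the pipeline", {
  sent <- toy_sentiment(); lcm <- toy_lcm()
  cfg <- generator_config(n_per_group = 4, seed = 77)
  gen <- generate_corpus(cfg, sent, lcm)
  expect_s3_class(gen$corpus, "lcm_corpus")
  expect_equal(length(gen$token_tables), nrow(gen$truth))
  for (i in seq_len(nrow(gen$truth))) {
    row <- gen$truth[i, ]
    key <- paste(row$participant_id, row$task, sep = "_")
    ann <- annotate(gen$token_tables[[key]], sent, lcm)
    fv <- extract_features(ann, row$participant_id, row$group, row$task)
    expect_equal(fv$n_pos, row$n_pos)
    expect_equal(fv$n_neg, row$n_neg)
    expect_equal(fv$n_dav, row$n_dav)
    expect_equal(fv$n_iav, row$n_iav)
    expect_equal(fv$n_sv, row$n_sv)
    expect_equal(fv$n_tokens, row$n_tokens)
    expect_equal(fv$abstraction, row$abstraction)
  }
  # same seed twice -> identical realization
  gen2 <- generate_corpus(cfg, sent, lcm)
  expect_identical(gen$token_tables, gen2$token_tables)
})

test_that("single-participant micro-world yields the exact counts", {
  sent <- toy_sentiment(); lcm <- toy_lcm()
  rates <- generator_config()$rates
  for (g in names(rates)) for (tk in names(rates[[g]])) {
    rates[[g]][[tk]] <- list(pos = c(0, 1), neg = c(0, 1), dav = c(0, 1),
                             iav = c(0, 1), sv = c(0, 1), filler = c(0, 1))
  }
  rates$ASD$book <- list(pos = c(2, 1e-9), neg = c(0, 1), dav = c(0, 1),
                         iav = c(0, 1), sv = c(1, 1e-9), filler = c(3, 1e-9))
  cfg <- generator_config(n_per_group = 1, rates = rates,
                          missing = c(book = 0, picture = 1), seed = 3)
  gen <- generate_corpus(cfg, sent, lcm)
  row <- gen$truth[gen$truth$group == "ASD", ]
  expect_equal(row$n_pos, 2L)
  expect_equal(row$n_sv, 1L)
  expect_equal(row$abstraction, 3)
  ann <- annotate(gen$token_tables[[paste0(row$participant_id, "_book")]],
                  sent, lcm)
  fv <- extract_features(ann, row$participant_id, "ASD", "book")
  expect_equal(fv$n_pos, 2L)
  expect_equal(fv$n_sv, 1L)
  expect_equal(fv$abstraction, 3)
  # missing-task probability 1 -> no picture rows at all
  expect_false(any(gen$truth$task == "picture"))
})

test_that("an injected abstraction effect is recovered by compare_groups", {
  cfg <- generator_config(seed = 12)
  tab <- generate_feature_table(cfg)
  book <- tab[tab$task == "book", ]
  res <- compare_groups(book$abstraction[book$group == "TD"],
                        book$abstraction[book$group == "ASD"],
                        variable = "abstraction")
  # the configured group means differ by d ~ .7; direction must be TD > ASD
  expect_gt(mean(book$abstraction[book$group == "TD"]),
            mean(book$abstraction[book$group == "ASD"]))
  expect_lt(res$p, 0.2)
})

test_that("injected effect size is recovered on average (n=200/group)", {
  set.seed(55)
  d_true <- 0.6
  ds <- vapply(1:200, function(i) {
    a <- rnorm(200); b <- rnorm(200, d_true)
    res <- compare_groups(b, a, force = "student_t")
    res$effect
  }, numeric(1))
  expect_lt(abs(mean(ds) - d_true), 0.15)
})

test_that("power curve calibrates against the analytic oracle", {
  pc <- power_curve(effect_sizes = c(0, 0.8), n_values = c(15, 30),
                    reps = 300, seed = 8)
  null_rows <- pc[pc$effect == 0, ]
  expect_true(all(abs(null_rows$power - 0.05) < 0.05))
  # monotone non-decreasing in n at fixed d (within MC error)
  p8 <- pc[pc$effect == 0.8, ]
  expect_gt(p8$power[p8$n == 30] - p8$power[p8$n == 15], -0.05)
  analytic <- power.t.test(n = 30, delta = 0.8, sd = 1)$power
  expect_lt(abs(p8$power[p8$n == 30] - analytic),
            0.05 + 2 * p8$mc_se[p8$n == 30])
})
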