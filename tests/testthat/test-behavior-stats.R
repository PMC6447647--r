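test_that("length normalization divides by the subject total", {
  d <- make_behavior(list(c(80, 90, 60, 100)), list(c(100, 300, 0, 600)))
  n <- normalize_lengths(d)
  expect_equal(n$norm_len, c(0.1, 0.3, 0, 0.6))

  d1 <- make_behavior(list(c(80, 60)), list(c(0, 250)))
  expect_equal(normalize_lengths(d1)$norm_len, c(0, 1))

  d0 <- make_behavior(list(c(80, 60), c(70, 90)),
                      list(c(0, 0), c(10, 30)))
  expect_warning(n0 <- normalize_lengths(d0), "zero total")
  expect_identical(unique(n0$subject_id), "s02")
  expect_error(suppressWarnings(normalize_lengths(
    make_behavior(list(c(80, 60)), list(c(0, 0))))), "no subjects")
})

test_that("normalized lengths sum to one within every subject", {
  set.seed(10)
  d <- generate_dataset(generator_config(n_subjects = 25), seed = 10)
  n <- normalize_lengths(d)
  sums <- tapply(n$norm_len, n$subject_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("confidence bands use the exact printed boundaries", {
  c_vals <- c(0, 49, 50, 75, 75.5, 76, 99, 100)
  expect_equal(confidence_band(c_vals, "analyzed"),
               c_vals >= 50)
  expect_equal(confidence_band(c_vals, "lower"),
               c_vals >= 50 & c_vals <= 75)
  expect_equal(confidence_band(c_vals, "upper"),
               c_vals > 75)
  expect_equal(confidence_band(c_vals, "certain"), c_vals == 100)
  # 75 is in the lower band only
  expect_true(confidence_band(75, "lower"))
  expect_false(confidence_band(75, "upper"))
})

test_that("probability of superiority counts pairs with half-credit ties", {
  expect_equal(probability_of_superiority(c(3, 5), c(1, 2)), 1.0)
  expect_equal(probability_of_superiority(c(1, 3), c(2, 4)), 0.25)
  expect_equal(probability_of_superiority(c(2, 2), c(2, 2)), 0.5)
  expect_error(probability_of_superiority(numeric(0), 1), "nonempty")

  set.seed(6)
  for (i in 1:25) {
    a <- sample(1:5, sample(2:8, 1), replace = TRUE)
    b <- sample(1:5, sample(2:8, 1), replace = TRUE)
    expect_identical(probability_of_superiority(a, b), ps_oracle(a, b))
  }
})

test_that("PS is consistent with the mid-rank Mann-Whitney U statistic", {
  set.seed(7)
  for (i in 1:20) {
    a <- sample(seq(0, 3, by = 0.5), 7, replace = TRUE)
    b <- sample(seq(0, 3, by = 0.5), 5, replace = TRUE)
    u <- suppressWarnings(wilcox.test(a, b))$statistic
    expect_equal(probability_of_superiority(a, b),
                 unname(u) / (length(a) * length(b)))
  }
})

test_that("group comparison reports test, effect size and bootstrap CIs", {
  set.seed(11)
  a <- rnorm(30, 1)
  b <- rnorm(30, 0)
  mw <- compare_groups(a, b, "mann-whitney", n_boot = 500, seed = 1)
  expect_s3_class(mw, "group_comparison")
  expect_identical(mw$effect_name, "PS")
  expect_equal(mw$effect_size, probability_of_superiority(a, b))
  expect_lt(mw$p_value, 0.05)
  expect_true(mw$ci["a", 1] <= median(a) && median(a) <= mw$ci["a", 2])

  tt <- compare_groups(a, b, "t", n_boot = 500, seed = 1)
  expect_identical(tt$effect_name, "d")
  sp <- sqrt((var(a) + var(b)) / 2)
  expect_equal(tt$effect_size, (mean(a) - mean(b)) / sp)

  pt <- compare_groups(a, b, "paired-t", n_boot = 500, seed = 1)
  expect_identical(pt$effect_name, "d_z")
  expect_equal(pt$effect_size, mean(a - b) / sd(a - b))

  # identical groups: one-sided evidence cannot be strong
  x <- rnorm(15)
  expect_gte(compare_groups(x, x, "mann-whitney", n_boot = 100)$p_value,
             0.5)
  # constant paired shift has zero-variance differences
  deg <- compare_groups(x + 10, x, "paired-t", n_boot = 100)
  expect_true(deg$degenerate)
  same <- compare_groups(x, x, "paired-t", n_boot = 100)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_error(compare_groups(1, 1:3, "t"), "insufficient")
  expect_error(compare_groups(1:4, 1:3, "paired-t"), "equal-length")
})

test_that("Mann-Whitney detects a one-sd location shift reliably", {
  set.seed(13)
  hits <- 0L
  for (i in 1:100) {
    a <- rnorm(30, 1)
    b <- rnorm(30, 0)
    p <- suppressWarnings(wilcox.test(a, b, alternative = "greater",
                                      exact = FALSE))$p.value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 85L)
})

test_that("dot-product statistic matches the hand-computed unit vectors", {
  d <- make_behavior(list(c(80, 60)), list(c(80, 20)))
  res <- dot_product_surrogate_test(d, n_surrogate = 200, seed = 1)
  expect_equal(res$observed_stat, 0.76 / sqrt(0.68), tolerance = 1e-12)
  expect_identical(res$theoretical_max, 1L)

  # lengths proportional to confidences: statistic at its maximum
  d2 <- make_behavior(
    list(c(95, 80, 65, 55), c(60, 70, 85, 90), c(52, 64, 78, 97)),
    list(c(95, 80, 65, 55) * 3, c(60, 70, 85, 90) * 2,
         c(52, 64, 78, 97) * 5))
  res2 <- dot_product_surrogate_test(d2, n_surrogate = 400, seed = 2)
  expect_equal(res2$observed_stat, 3, tolerance = 1e-12)
  expect_lt(res2$p_value, 0.05)
})

test_that("dot-product test restricts to analyzed words and is scale invariant", {
  # words below confidence 50 are ignored entirely
  d <- make_behavior(list(c(80, 60, 30), c(90, 55, 10)),
                     list(c(50, 30, 999), c(70, 10, 999)))
  d_no <- make_behavior(list(c(80, 60), c(90, 55)),
                        list(c(50, 30), c(70, 10)))
  r1 <- dot_product_surrogate_test(d, n_surrogate = 100, seed = 3)
  r2 <- dot_product_surrogate_test(d_no, n_surrogate = 100, seed = 3)
  expect_equal(r1$observed_stat, r2$observed_stat)
  expect_identical(r1$null_samples, r2$null_samples)

  # rescaling one subject's lengths changes nothing
  d3 <- d
  d3$essay_len[d3$subject_id == "s01"] <-
    d3$essay_len[d3$subject_id == "s01"] * 7.3
  r3 <- dot_product_surrogate_test(d3, n_surrogate = 100, seed = 3)
  expect_equal(r3$observed_stat, r1$observed_stat)
  expect_equal(r3$null_samples, r1$null_samples)
})

test_that("letter-reassignment test matches hand expectations", {
  d <- make_behavior(list(c(100, 100, 80)), list(c(30, 10, 50)),
                     list(c("spontaneous", "forced", "spontaneous")))
  res <- letter_reassignment_surrogate_test(d, n_surrogate = 4000, seed = 4)
  expect_equal(res$observed_stat, 0.75)          # 30 / (30 + 10)
  expect_equal(mean(res$null_samples), 0.5, tolerance = 0.02)
  expect_identical(res$theoretical_max, 1L)

  # only spontaneous certain words: contribution pinned at 1
  d2 <- make_behavior(list(c(100, 100)), list(c(12, 30)),
                      list(c("spontaneous", "spontaneous")))
  res2 <- letter_reassignment_surrogate_test(d2, n_surrogate = 50, seed = 5)
  expect_equal(res2$observed_stat, 1)
  expect_true(all(res2$null_samples == 1))
  expect_equal(res2$p_value, 1)

  # no certain words at all
  d3 <- make_behavior(list(c(90, 80)), list(c(5, 5)))
  expect_error(letter_reassignment_surrogate_test(d3), "qualify")
})

test_that("surrogate statistics always stay within [0, n_subjects]", {
  set.seed(14)
  for (i in 1:20) {
    cfg <- generator_config(n_subjects = sample(3:8, 1), n_words = 8,
                            n_forced = 2, forced_conf_boost = 30)
    d <- generate_dataset(cfg)
    dp <- dot_product_surrogate_test(d, n_surrogate = 50)
    expect_true(dp$observed_stat >= 0 &&
                  dp$observed_stat <= dp$theoretical_max)
    expect_true(all(dp$null_samples >= 0 &
                      dp$null_samples <= dp$theoretical_max))
    lt <- tryCatch(letter_reassignment_surrogate_test(d, n_surrogate = 50),
                   error = function(e) NULL)
    if (!is.null(lt)) {
      expect_true(lt$observed_stat >= 0 &&
                    lt$observed_stat <= lt$theoretical_max)
      expect_true(all(lt$null_samples >= 0 &
                        lt$null_samples <= lt$theoretical_max))
    }
  }
})

test_that("experiment-1 pipeline recovers a planted confidence-length effect", {
  cfg <- generator_config(n_subjects = 32, n_forced = 0, conf_effect = 0.7,
                          length_effect = 1.5, forced_conf_boost = 0)
  d <- generate_dataset(cfg, seed = 15)
  rep1 <- analyze_experiment1(d, n_surrogate = 500, seed = 15,
                              n_boot = 200)
  expect_s3_class(rep1, "exp1_report")
  expect_lt(rep1$length_comparison$p_value, 0.05)
  expect_lt(rep1$dot_product_test$p_value, 0.05)

  all_low <- make_behavior(list(c(10, 20, 30)), list(c(5, 5, 5)))
  expect_error(analyze_experiment1(all_low), "analyzed")
})

test_that("experiment-2 pipeline detects forced-confidence inflation", {
  cfg <- generator_config(n_subjects = 30, n_forced = 2,
                          forced_conf_boost = 40, conf_effect = 0.5,
                          length_effect = 1)
  d <- generate_dataset(cfg, seed = 16)
  rep2 <- analyze_experiment2(d, n_surrogate = 300, seed = 16, n_boot = 200)
  expect_s3_class(rep2, "exp2_report")
  expect_lt(rep2$certain_comparison$p_value, 0.01)
  # forced words carry higher certainty rates than spontaneous words
  expect_gt(rep2$certain_comparison$centers[1],
            rep2$certain_comparison$centers[2])
  expect_s3_class(rep2$letter_test, "surrogate_result")

  d_nf <- d[d$condition == "spontaneous", ]
  expect_error(analyze_experiment2(d_nf), "forced")
})

test_that("certain-word summaries support proportion and count scales", {
  cfg <- generator_config(n_subjects = 12, forced_conf_boost = 40)
  d <- generate_dataset(cfg, seed = 17)
  r_prop <- analyze_experiment2(d, n_surrogate = 100, seed = 1,
                                n_boot = 100)
  r_cnt <- analyze_experiment2(d, n_surrogate = 100, seed = 1,
                               n_boot = 100, certain_as = "count")
  expect_true(all(r_prop$certain_comparison$centers <= 1))
  expect_gte(max(r_cnt$certain_comparison$centers),
             max(r_prop$certain_comparison$centers))
})
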