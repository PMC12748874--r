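test_that("trial-wise regressions recover known coefficients", {
  ## simulate directly from the linear model behind the uncertainty formula
  set.seed(14)
  n <- 500
  tab <- data.frame(
    participant = 1L, block = rep(1:4, each = 125),
    phase_label = sample(c("self_other", "control_other"), n, TRUE),
    trial_in_phase = sample(1:16, n, TRUE), trial_in_block = 1,
    self_rating = 50, other_rating = 50, control_rating = 0.5,
    objective_error = 1, self_score = 50, other_score = 50,
    is_ad = runif(n) < 0.25, is_switch = FALSE, feedback = 50,
    true_self = 50, true_other_level = 50, true_control = 0.5)
  d <- derive_measures(tab)
  b <- c(ad_lag1 = -0.4, ad_lag2 = -0.25, trial_number = -0.3,
         other_changed = 0.35, phase = 0.1)
  z <- function(x) (x - mean(x)) / sd(x)
  d$model_uncertainty <- as.numeric(
    b["ad_lag1"] * z(d$ad_lag1) + b["ad_lag2"] * z(d$ad_lag2) +
      b["trial_number"] * z(d$trial_in_phase) +
      b["other_changed"] * z(d$other_changed) +
      b["phase"] * z(as.numeric(d$phase_label == "control_other")) +
      rnorm(n, 0, 0.5))
  res <- fit_trialwise_regression(d, "ad_uncertainty")
  sdy <- sd(d$model_uncertainty)
  for (tm in names(b)) {
    row <- res[res$term == tm, ]
    expect_lt(abs(row$estimate - b[[tm]] / sdy), 3 * row$se)
  }
})

test_that("pure-noise outcomes yield intervals that cover zero", {
  set.seed(30)
  base <- small_participant()
  covered <- total <- 0
  for (i in 1:100) {
    d <- base
    d$model_uncertainty <- rnorm(nrow(d))
    res <- fit_trialwise_regression(d, "ad_uncertainty")
    res <- res[res$term != "(Intercept)", ]
    covered <- covered + sum(res$ci_lo <= 0 & res$ci_hi >= 0)
    total <- total + nrow(res)
  }
  expect_gte(covered / total, 0.90)
})

test_that("agents assign prediction errors in proportion to their control", {
  tab <- default_cohort_table()
  res <- fit_trialwise_regression(tab, "credit_self")
  gt <- group_coef_ttest(res)
  expect_gt(gt$mean_beta[gt$term == "tpe"], 0)
  expect_gt(gt$mean_beta[gt$term == "tpe_x_control"], 0)
  expect_lt(gt$p[gt$term == "tpe"], 0.05)
  ## for other updates the credit-assignment signature is the interaction
  ## with the other player's control share
  res_o <- fit_trialwise_regression(tab, "credit_other")
  gt_o <- group_coef_ttest(res_o)
  expect_gt(gt_o$mean_beta[gt_o$term == "tpe_x_control"], 0)
  expect_lt(gt_o$p[gt_o$term == "tpe_x_control"], 0.05)
})

test_that("participants with too few usable trials are skipped with a note", {
  tab <- small_participant()
  short <- tab[tab$block == 1 & tab$phase_label == "self_other" &
                 tab$trial_in_phase <= 5, ]
  expect_message(
    res <- fit_trialwise_regression(short, "credit_self", min_trials = 8L),
    "skipped")
  expect_equal(nrow(res), 0)
})

test_that("the control-inference regression is exercised by both backends", {
  tab <- default_cohort_table()
  two <- suppressMessages(fit_control_inference(tab))
  expect_s3_class(two, "control_inference")
  expect_true(all(c("fd", "inv_self", "fd_x_inv", "prev_control") %in%
                    two$group$term))
  expect_output(print(two), "two-stage")
  hier <- suppressMessages(fit_control_inference(tab, hierarchical = TRUE))
  ## both backends agree on the sign of the feedback-difference effect
  fd2 <- two$group$estimate[two$group$term == "fd"]
  fdh <- hier$group$estimate[hier$group$term == "fd"]
  expect_equal(sign(fd2), sign(fdh))
  expect_gt(fd2, 0)
})

test_that("participants with too few switch trials are excluded", {
  tab <- default_cohort_table()
  expect_message(try(fit_control_inference(tab, min_switch = 200L),
                     silent = TRUE), "excluded")
  expect_error(suppressMessages(fit_control_inference(tab, min_switch = 200L)),
               "no usable switch trials")
})

test_that("mixed ANOVA detects within-participant shifts and degenerates sanely", {
  ## the same participant values duplicated in both samples: the
  ## between-sample means coincide, so the sample effect has F = 0, p = 1
  set.seed(99)
  base <- rnorm(10, 0.6, 0.1)
  d0 <- expand.grid(id = 1:20, time = c("start", "end"))
  d0$sample <- ifelse(d0$id <= 10, "mri", "online")
  d0$y <- base[(d0$id - 1) %% 10 + 1] + ifelse(d0$time == "end", 0.2, 0)
  a0 <- mixed_anova(d0, "y", within = "time", between = "sample", id = "id")
  expect_gt(a0$p[a0$effect == "sample"], 0.99)
  ## a 1-SD within shift at n = 30 is detected in >= 80% of seeds
  hit <- logical(40)
  for (i in seq_along(hit)) {
    set.seed(500 + i)
    d <- expand.grid(id = 1:30, time = c("start", "end"))
    d$sample <- rep(rep(c("mri", "online"), each = 15), 2)
    d$y <- rnorm(60) + ifelse(d$time == "end", 1, 0)
    a <- mixed_anova(d, "y", within = "time", between = "sample", id = "id")
    hit[i] <- a$p[a$effect == "time"] < 0.05
  }
  expect_gte(mean(hit), 0.8)
  ## single-group input reduces to the within test with a warning
  d1 <- d0[d0$sample == "mri", ]
  expect_warning(a1 <- mixed_anova(d1, "y", within = "time",
                                   between = "sample", id = "id"),
                 "single")
  expect_true("time" %in% a1$effect)
})

test_that("group-level t-tests report effect sizes per term", {
  tab <- default_cohort_table()
  res <- fit_trialwise_regression(tab, "ad_uncertainty")
  gt <- group_coef_ttest(res)
  expect_true(all(c("mean_beta", "t", "df", "p", "cohens_d") %in% names(gt)))
  expect_equal(gt$df, rep(29, nrow(gt)))
})
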