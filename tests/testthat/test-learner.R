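test_that("credible interval widths match closed forms and limits", {
  expect_equal(credible_interval_width(dist_normal(50, 30), 0.90), 98.70,
               tolerance = 0.01 / 98.70)
  expect_equal(credible_interval_width(dist_normal(0, 1), 0.90),
               2 * qnorm(0.95), tolerance = 1e-10)
  expect_equal(credible_interval_width(learner_prior(self_mean = 50), 0.90,
                                       param = "self"),
               98.70, tolerance = 0.01 / 98.70)
  ## shrinking level shrinks the width to zero
  expect_lt(credible_interval_width(dist_normal(0, 10), 1e-6), 1e-3)
  ## sample quantile route
  set.seed(1)
  expect_equal(credible_interval_width(rnorm(2e5, 0, 30), 0.90),
               98.69, tolerance = 0.01)
  expect_warning(credible_interval_width(rep(3, 10)), "degenerate")
})

test_that("phase uncertainty combines the credible widths of what is learnt", {
  expect_equal(compute_uncertainty("self_other", ci_self = 98.70,
                                   ci_other = 98.70), 98.70)
  expect_equal(compute_uncertainty("control_other", ci_control = 0.5,
                                   ci_other = 40), 45)
  expect_error(compute_uncertainty("control_other", ci_self = 10,
                                   ci_other = 40), "ci_control")
})

test_that("grid filter matches a dense brute-force posterior on toy instances", {
  ## 2-trial instance (one normal, one AD): each variant's posterior means
  ## must agree with direct dense-grid summation within 2% of the range
  pr <- learner_prior(other_mean = 40, control_mean = 0.5)
  fb <- c(44, 10); ad <- c(FALSE, TRUE)
  for (v in c("active", "ignorant", "passive")) {
    use_fb <- fb; use_ad <- ad
    if (v == "ignorant") use_ad <- c(FALSE, FALSE)
    if (v == "passive") { use_fb <- fb[1]; use_ad <- FALSE }
    orc <- oracle_control_other(use_fb, use_ad, 50, pr)
    fit <- fit_learner(data.frame(feedback = fb, is_ad = ad), v,
                       "control_other", pr, clamped = list(self = 50))
    cf <- coef(fit)
    expect_lt(abs(cf[["other"]] - orc$other_mean), 0.02 * 100)
    expect_lt(abs(cf[["control"]] - orc$control_mean), 0.02 * 1)
  }
  ## 3-trial all-normal instance
  fb3 <- c(52, 61, 48); ad3 <- rep(FALSE, 3)
  orc <- oracle_control_other(fb3, ad3, 70, pr)
  fit <- fit_learner(data.frame(feedback = fb3, is_ad = ad3), "active",
                     "control_other", pr, clamped = list(self = 70))
  expect_lt(abs(coef(fit)[["other"]] - orc$other_mean), 2)
  expect_lt(abs(coef(fit)[["control"]] - orc$control_mean), 0.02)
})

test_that("the three learners coincide on AD-free sequences", {
  set.seed(8)
  fb <- round(runif(10, 20, 80), 1)
  trials <- data.frame(feedback = fb, is_ad = rep(FALSE, 10))
  for (ctx in c("self_other", "control_other")) {
    cl <- if (ctx == "self_other") list(control = 0.6) else list(self = 55)
    fits <- lapply(c("active", "ignorant", "passive"), function(v)
      fit_learner(trials, v, ctx, learner_prior(), cl))
    for (col in c("other_mean", "other_sd", "uncertainty"))
      for (k in 2:3)
        expect_equal(fits[[k]]$trials[[col]], fits[[1]]$trials[[col]],
                     tolerance = 1e-12)
  }
})

test_that("alternating normal/AD feedback recovers the worked-example control", {
  fb <- rep(c(44, 4), 7); ad <- rep(c(FALSE, TRUE), 7)
  fit <- fit_learner(data.frame(feedback = fb, is_ad = ad), "active",
                     "control_other",
                     learner_prior(other_mean = 50, control_mean = 0.5),
                     clamped = list(self = 50),
                     settings = learner_settings(other_reset_trial = 99))
  expect_lt(abs(coef(fit)[["control"]] - 0.8), 0.05)
  ## the implied other level is what the AD feedback reveals: 4 / (1 - 0.8)
  expect_lt(abs(coef(fit)[["other"]] - 20), 3)
})

test_that("posterior summaries respect parameter supports and CI ordering", {
  set.seed(21)
  for (i in 1:8) {
    n <- sample(3:8, 1)
    trials <- data.frame(feedback = runif(n, 0, 100),
                         is_ad = runif(n) < 0.3)
    ctx <- sample(c("self_other", "control_other"), 1)
    cl <- if (ctx == "self_other") list(control = runif(1)) else
      list(self = runif(1, 10, 90))
    fit <- fit_learner(trials, "active", ctx, learner_prior(), cl)
    tr <- fit$trials
    expect_true(all(tr$self_mean >= 0 & tr$self_mean <= 100))
    expect_true(all(tr$other_mean >= 0 & tr$other_mean <= 100))
    expect_true(all(tr$control_mean >= 0 & tr$control_mean <= 1))
    for (p in c("self", "other", "control")) {
      expect_true(all(tr[[paste0(p, "_lo")]] <= tr[[paste0(p, "_mean")]] + 1e-9))
      expect_true(all(tr[[paste0(p, "_hi")]] >= tr[[paste0(p, "_mean")]] - 1e-9))
    }
    expect_true(all(tr$uncertainty >= 0))
  }
})

test_that("uncertainty declines over a phase for the Active learner", {
  ## Monte-Carlo: final-trial uncertainty below first-trial uncertainty in
  ## at least 95% of seeds
  less <- logical(100)
  for (i in 1:100) {
    set.seed(3000 + i)
    other <- draw_other_score(60, 6.5, 16)
    ad <- runif(16) < 0.25
    fb <- compute_feedback(ifelse(ad, 0, 45), other, 0.4)
    fit <- fit_learner(data.frame(feedback = fb, is_ad = ad), "active",
                       "control_other", learner_prior(),
                       clamped = list(self = 45))
    less[i] <- fit$trials$uncertainty[16] < fit$trials$uncertainty[1]
  }
  expect_gte(mean(less), 0.95)
})

test_that("the other player is re-estimated mid-phase under a fresh prior", {
  fb <- rep(44, 14); ad <- rep(FALSE, 14)
  fit <- fit_learner(data.frame(feedback = fb, is_ad = ad), "active",
                     "control_other", learner_prior(),
                     clamped = list(self = 50))
  w <- fit$trials$other_hi - fit$trials$other_lo
  ## credible width shrinks up to trial 11, then jumps at the reset trial
  expect_lt(w[11], w[1])
  expect_gt(w[12], w[11] * 2)
})

test_that("a passive learner with an all-AD prefix reports prior summaries", {
  trials <- data.frame(feedback = c(12, 10), is_ad = c(TRUE, TRUE))
  fit <- fit_learner(trials, "passive", "control_other", learner_prior(),
                     clamped = list(self = 50))
  expect_true(all(fit$trials$prior_only))
  expect_equal(fit$trials$other_mean[2], fit$prior_summary$other_mean)
})

test_that("belief_filter methods expose fit, predictions and residuals", {
  fb <- c(44, 4, 46, 5); ad <- c(FALSE, TRUE, FALSE, TRUE)
  fit <- fit_learner(data.frame(feedback = fb, is_ad = ad), "active",
                     "control_other", learner_prior(), clamped = list(self = 50))
  expect_named(coef(fit), c("self", "other", "control", "sigma_self",
                            "sigma_other"))
  p <- predict(fit)
  expect_length(p, 4)
  ## first prediction comes from the prior means
  expect_equal(p[1], compute_feedback(50, fit$prior_summary$other_mean,
                                      fit$prior_summary$control_mean))
  expect_equal(residuals(fit), fb - p)
  expect_output(print(fit), "Active|active")
  expect_output(print(summary(fit)), "Uncertainty")
})
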