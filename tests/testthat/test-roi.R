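test_that("the double-gamma HRF has the canonical shape", {
  t <- seq(0, 32, by = 0.01)
  h <- double_gamma_hrf(t)
  expect_equal(max(h), 1)
  expect_lt(abs(t[which.max(h)] - 5), 1)       # gamma(6,1) mode at 5 s
  expect_lt(min(h), 0)                          # undershoot
  expect_equal(double_gamma_hrf(-1), 0)
  expect_lt(abs(t[which.min(h)] - 15), 1.5)
})

test_that("synthetic onsets and BOLD synthesis are reproducible", {
  tab <- attach_onsets(small_participant(), spacing = 10, start = 4)
  expect_equal(tab$onset[1:3], c(4, 14, 24))
  ev <- data.frame(onset = c(20, 60), duration = 1, x = c(1, -1))
  s1 <- synth_bold(ev, c(x = 1.5), noise_sd = 1, seed = 9)
  s2 <- synth_bold(ev, c(x = 1.5), noise_sd = 1, seed = 9)
  expect_identical(s1, s2)
  expect_error(synth_bold(ev, c(nope = 1), seed = 1), "unknown beta")
})

test_that("epoching drops edge events and interpolates accurately", {
  tr <- 1.36
  n <- 200
  t0 <- (0:(n - 1)) * tr
  ## constant signal: epochs are identically zero after normalisation
  ep <- epoch_and_upsample(rep(5, n), onsets = c(30, 60), tr = tr)
  expect_true(all(ep$epochs == 0))
  ## pure sine, period >= 4 samples: spline error under 1% of amplitude
  per <- 6 * tr
  y <- sin(2 * pi * t0 / per)
  ep2 <- epoch_and_upsample(y, onsets = c(60, 100), tr = tr)
  for (i in 1:2) {
    tt <- ep2$onsets[i] + ep2$times
    truth <- sin(2 * pi * tt / per) / sd(y) - mean(y) / sd(y)
    expect_lt(max(abs(ep2$epochs[i, ] - truth)), 0.01 * max(abs(truth)))
  }
  ## onset too close to the end of the recording is dropped and counted
  ep3 <- epoch_and_upsample(y, onsets = c(60, max(t0) - 5), tr = tr)
  expect_equal(ep3$n_dropped, 1)
  expect_equal(nrow(ep3$epochs), 1)
  expect_error(epoch_and_upsample(y, onsets = numeric(0)), "non-empty")
})

test_that("per-timepoint OLS recovers injected effects exactly without noise", {
  set.seed(2)
  ## spacing exceeds the window + HRF tail, so events do not overlap
  ev <- data.frame(onset = 40 + (0:17) * 50, duration = 1,
                   x = rnorm(18), w = rnorm(18))
  b_inj <- c(x = 2)
  sig <- synth_bold(ev, b_inj, noise_sd = 0, seed = 1)
  ep <- epoch_and_upsample(sig, ev$onset)
  bt <- timepoint_glm(ep, ev[, c("x", "w")])
  ## peak location equals the peak of the boxcar-convolved HRF
  dt <- 0.05
  h <- double_gamma_hrf(seq(0, 32, by = dt))
  conv <- convolve(c(rep(1, round(1 / dt)), rep(0, 800)), rev(h),
                   type = "open") * dt
  expect_lt(abs(ep$times[which.max(bt$betas["x", ])] -
                  dt * (which.max(conv) - 1)), 0.15)
  ## the x beta time course is proportional to the HRF response shape
  pos <- ep$times >= 0
  shape <- approx(seq_along(conv) * dt - dt, conv, xout = ep$times[pos],
                  rule = 2)$y
  expect_gt(cor(bt$betas["x", pos], shape), 0.9999)
  ## the orthogonal second term is untouched by the injected first
  expect_lt(max(abs(bt$betas["w", ])), 0.05 * max(abs(bt$betas["x", ])))
  expect_error(timepoint_glm(ep, cbind(ev["x"], x2 = ev$x * 2)), "rank")
})

test_that("the design registry selects the documented trials and terms", {
  tab <- attach_onsets(small_participant())
  d1 <- roi_design(tab, "glm1")
  expect_named(d1, c("onset", "duration", "next_control", "control_update"))
  co <- tab[tab$phase_label == "control_other", ]
  expect_equal(nrow(d1), sum(tab$phase_label == "control_other" &
                               tab$trial_in_phase < 16))
  d2 <- roi_design(tab, "glm2")
  expect_named(d2, c("onset", "duration", "fd_ad_to_normal",
                     "fd_normal_to_ad", "inverse_self", "ad"))
  dm <- derive_measures(tab)
  expect_equal(nrow(d2), sum(dm$phase_label == "control_other" & dm$is_switch &
                               !is.na(dm$feedback_difference)))
  for (g in c("glm3", "glm4", "glm5", "glm6")) {
    d <- roi_design(tab, g)
    expect_equal(nrow(d), sum(tab$phase_label == "self_other" & !tab$is_ad))
  }
  expect_named(roi_design(tab, "glm6")[3:4], c("tpe", "control"))
  d7 <- roi_design(tab, "glm7")
  expect_named(d7[3:4], c("feedback", "feedback_change"))
  expect_error(roi_design(tab, "glm9"), "glm_id")
})

test_that("the direction-split feedback-difference terms read out H1 coding", {
  ## inject the same beta on both direction terms (the order-independent,
  ## normal-minus-AD hypothesis): the sum contrast carries the effect and the
  ## difference contrast vanishes; an order-dependent injection reverses this
  tab <- attach_onsets(small_participant(), spacing = 40)
  ev <- roi_design(tab[tab$block <= 2, ], "glm2")
  read_contrasts <- function(betas_inj) {
    sig <- synth_bold(ev, betas_inj, noise_sd = 0, seed = 3)
    ep <- epoch_and_upsample(sig, ev$onset)
    bt <- timepoint_glm(ep, ev)
    pk <- which.max(abs(colMeans(rbind(bt$betas["fd_ad_to_normal", ],
                                       bt$betas["fd_normal_to_ad", ]))))
    b1 <- unname(bt$betas["fd_ad_to_normal", pk])
    b2 <- unname(bt$betas["fd_normal_to_ad", pk])
    c(h1 = (b1 + b2) / 2, h2 = (b1 - b2) / 2)
  }
  same <- read_contrasts(c(fd_ad_to_normal = 2, fd_normal_to_ad = 2))
  expect_gt(abs(same["h1"]), 10 * abs(same["h2"]))
  flip <- read_contrasts(c(fd_ad_to_normal = 2, fd_normal_to_ad = -2))
  expect_gt(abs(flip["h2"]), 10 * abs(flip["h1"]))
})

test_that("leave-one-out peak selection never touches the held-out series", {
  set.seed(6)
  times <- seq(-2, 15, by = 1.36 / 20)
  B <- matrix(rnorm(8 * length(times)), 8)
  res <- loo_peak_test(B, times)
  ## permuting the held-out participant's series leaves their peak unchanged
  B2 <- B
  B2[3, ] <- sample(B2[3, ])
  res2 <- loo_peak_test(B2, times)
  expect_equal(res2$peak_times[3], res$peak_times[3])
  expect_error(loo_peak_test(B[1:2, ], times), "at least 3")
  expect_error(loo_peak_test(B, times, window = c(40, 50)), "window")
  expect_warning(loo_peak_test(matrix(0, 4, length(times)), times), "flat")
})

test_that("an injected common effect is detected with high power", {
  set.seed(17)
  times <- seq(-2, 15, by = 1.36 / 20)
  hits <- logical(30)
  shape <- double_gamma_hrf(pmax(times, 0)); shape[times < 0] <- 0
  for (r in seq_along(hits)) {
    B <- t(replicate(31, shape + rnorm(length(times))))  # SNR 1
    hits[r] <- loo_peak_test(B, times)$p < 0.05
  }
  expect_gte(mean(hits), 0.9)
})
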