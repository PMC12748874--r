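## Sequential Bayesian observer models (Active / Ignorant / Passive learners).
##
## Inference is a deterministic dense-grid filter: the joint posterior over the
## free parameters lives on a fixed product grid and each trial multiplies in
## one likelihood term, which is identical to refitting the model to trials
## 1..t at every t (the likelihood factorises over trials). Parameter supports
## are bounded (scores 0-100, control 0-1, positive sigmas), so truncation is
## built into the support rather than applied post hoc.

#' Prior specification for the belief models
#'
#' Mean parameters are Gaussians centred on the first-trial ratings with wide
#' SDs (30 score units for self and other, 0.3 for control); the
#' performance-variability parameters sigma_self and sigma_other have
#' half-normal priors with scale 5.
#'
#' @param self_mean,other_mean prior means for the performance levels (first
#'   trial ratings), 0-100.
#' @param control_mean prior mean for control (first-trial rating), 0-1.
#' @param self_sd,other_sd prior SDs for the performance levels.
#' @param control_sd prior SD for control.
#' @param sigma_scale half-normal scale of the sigma priors.
#' @return Object of class \code{"learner_prior"}.
#' @export
learner_prior <- function(self_mean = 50, other_mean = 50, control_mean = 0.5,
                          self_sd = 30, other_sd = 30, control_sd = 0.3,
                          sigma_scale = 5) {
  check_range(self_mean, 0, 100, "self_mean")
  check_range(other_mean, 0, 100, "other_mean")
  check_range(control_mean, 0, 1, "control_mean")
  if (any(c(self_sd, other_sd, control_sd, sigma_scale) <= 0))
    stop("all prior SDs must be > 0")
  structure(as.list(environment()), class = "learner_prior")
}

#' Numerical settings of the grid filter
#'
#' @param score_step grid step for the self/other performance levels
#'   (score units; grid spans 0-100).
#' @param control_step grid step for control (grid spans 0-1).
#' @param n_sigma number of equal-prior-mass grid points for each sigma.
#' @param sigma_min,sigma_max sigma support bounds (score units). The lower
#'   bound keeps the likelihood bounded on the grid (feedback is displayed at
#'   integer resolution, so sub-unit performance variability is not
#'   identifiable).
#' @param ci_level credible-interval level used for the uncertainty read-out.
#' @param other_reset_trial 1-based within-phase trial at which the other
#'   player is re-estimated as a new player (fresh prior).
#' @param other_reset_sd SD of the fresh other prior, centred on the most
#'   recent posterior mean.
#' @param sd_floor lower bound applied to likelihood SDs (score units),
#'   guarding the degenerate corner control = 1 on AD trials.
#' @return Object of class \code{"learner_settings"}.
#' @export
learner_settings <- function(score_step = 2, control_step = 0.02, n_sigma = 8,
                             sigma_min = 1, sigma_max = 18, ci_level = 0.90,
                             other_reset_trial = 12, other_reset_sd = 30,
                             sd_floor = 0.5) {
  if (score_step <= 0 || control_step <= 0 || n_sigma < 2) stop("invalid grid settings")
  if (ci_level <= 0 || ci_level >= 1) stop("'ci_level' must be in (0,1)")
  structure(as.list(environment()), class = "learner_settings")
}

## uniform sigma grid on [lo, hi]; the half-normal(scale) prior enters as
## normalised log-density weights at the grid points
sigma_grid <- function(n, lo, hi) seq(lo, hi, length.out = n)

## array with values varying along dimension k
arr_along <- function(vals, k, dims) {
  perm <- c(k, seq_along(dims)[-k])
  aperm(array(vals, dim = dims[perm]), order(perm))
}


## marginal over dimension k: reduce leading dims with colSums, trailing with rowSums
marg_dim <- function(p, k) {
  q <- if (k > 1) colSums(p, dims = k - 1) else p
  if (is.null(dim(q)) || length(dim(q)) <= 1) return(as.vector(q))
  rowSums(q, dims = 1)
}

log_trunc_norm <- function(grid, mean, sd) {
  lp <- stats::dnorm(grid, mean, sd, log = TRUE)
  lp - logsumexp(lp)
}

#' Initialise a belief-filter state
#'
#' Usually called through [fit_learner()]; exposed for step-wise simulation.
#'
#' @param variant one of \code{"active"}, \code{"ignorant"}, \code{"passive"}.
#'   Variants share the grid and priors and differ only in how AD trials enter
#'   the likelihood: the Active learner models them as self-free feedback, the
#'   Ignorant learner treats them as normal trials, the Passive learner drops
#'   them.
#' @param phase_context \code{"self_other"} (control clamped to the instructed
#'   level; self, other and both sigmas free), \code{"control_other"} (self
#'   clamped to the known level with sigma_self = 5; other, sigma_other and
#'   control free) or \code{"self_only"} (control = 1; self and sigma_self
#'   free).
#' @param prior a [learner_prior()].
#' @param clamped list of clamped values: \code{control} for
#'   \code{self_other}, \code{self} (and optionally \code{sigma_self},
#'   default 5) for \code{control_other}.
#' @param settings a [learner_settings()].
#' @return Opaque state list for [learner_step()] / [learner_summary()].
#' @export
learner_init <- function(variant = c("active", "ignorant", "passive"),
                         phase_context = c("self_other", "control_other", "self_only"),
                         prior = learner_prior(), clamped = list(),
                         settings = learner_settings()) {
  variant <- match.arg(variant)
  phase_context <- match.arg(phase_context)
  sg <- seq(0, 100, by = settings$score_step)
  cg <- seq(0, 1, by = settings$control_step)
  sig <- sigma_grid(settings$n_sigma, settings$sigma_min, settings$sigma_max)
  lsig <- log_trunc_norm(sig, 0, prior$sigma_scale)
  st <- list(variant = variant, context = phase_context, prior = prior,
             settings = settings, t = 0L, n_used = 0L)
  if (phase_context == "self_other") {
    c0 <- clamped$control
    if (is.null(c0)) stop("self_other context requires clamped$control")
    check_range(c0, 0, 1, "clamped$control")
    dims <- c(length(sg), length(sg), length(sig), length(sig))
    S <- arr_along(sg, 1, dims); O <- arr_along(sg, 2, dims)
    Ss <- arr_along(sig, 3, dims); So <- arr_along(sig, 4, dims)
    st$grids <- list(self = sg, other = sg, sigma_self = sig, sigma_other = sig)
    st$free <- c("self", "other", "sigma_self", "sigma_other")
    st$clamped <- list(control = c0)
    st$mean_normal <- S * c0 + O * (1 - c0)
    st$sd_normal <- pmax(sqrt(Ss^2 * c0^2 + So^2 * (1 - c0)^2), settings$sd_floor)
    st$mean_ad <- O * (1 - c0)
    st$sd_ad <- pmax(So * (1 - c0), settings$sd_floor)
    st$logpost <- arr_along(log_trunc_norm(sg, prior$self_mean, prior$self_sd), 1, dims) +
      arr_along(log_trunc_norm(sg, prior$other_mean, prior$other_sd), 2, dims) +
      arr_along(lsig, 3, dims) + arr_along(lsig, 4, dims)
  } else if (phase_context == "control_other") {
    S0 <- clamped$self
    if (is.null(S0)) stop("control_other context requires clamped$self")
    check_range(S0, 0, 100, "clamped$self")
    ss <- if (is.null(clamped$sigma_self)) 5 else clamped$sigma_self
    dims <- c(length(sg), length(sig), length(cg))
    O <- arr_along(sg, 1, dims); So <- arr_along(sig, 2, dims)
    C <- arr_along(cg, 3, dims)
    st$grids <- list(other = sg, sigma_other = sig, control = cg)
    st$free <- c("other", "sigma_other", "control")
    st$clamped <- list(self = S0, sigma_self = ss)
    st$mean_normal <- S0 * C + O * (1 - C)
    st$sd_normal <- pmax(sqrt(ss^2 * C^2 + So^2 * (1 - C)^2), settings$sd_floor)
    st$mean_ad <- O * (1 - C)
    st$sd_ad <- pmax(So * (1 - C), settings$sd_floor)
    st$logpost <- arr_along(log_trunc_norm(sg, prior$other_mean, prior$other_sd), 1, dims) +
      arr_along(log_trunc_norm(cg, prior$control_mean, prior$control_sd), 3, dims) +
      arr_along(lsig, 2, dims)
  } else {
    dims <- c(length(sg), length(sig))
    S <- arr_along(sg, 1, dims); Ss <- arr_along(sig, 2, dims)
    st$grids <- list(self = sg, sigma_self = sig)
    st$free <- c("self", "sigma_self")
    st$clamped <- list(control = 1)
    st$mean_normal <- S
    st$sd_normal <- pmax(Ss, settings$sd_floor)
    st$mean_ad <- NULL; st$sd_ad <- NULL
    st$logpost <- arr_along(log_trunc_norm(sg, prior$self_mean, prior$self_sd), 1, dims) +
      arr_along(lsig, 2, dims)
  }
  st$lsig <- lsig
  st$dims <- dim(st$logpost)
  st
}

## marginal posterior over free-parameter dimension k
marginal_k <- function(state, k) {
  lp <- state$logpost
  p <- exp(lp - max(lp))
  m <- marg_dim(p, k)
  m / sum(m)
}

## re-estimate the other player under a fresh prior, keeping the marginal of
## the remaining parameters (independence is re-imposed at the reset)
reset_other <- function(state) {
  p <- exp(state$logpost - max(state$logpost)); p <- p / sum(p)
  sett <- state$settings
  if (state$context == "self_other") {
    m_other <- sum(marg_dim(p, 2) * state$grids$other)
    lrest <- log(pmax(rowSums(aperm(p, c(1, 3, 2, 4)), dims = 2), 1e-300)) # (self, sigma_self)
    lo <- log_trunc_norm(state$grids$other, m_other, sett$other_reset_sd)
    dims <- state$dims
    a_rest <- aperm(array(lrest, dim = c(dims[1], dims[3], dims[2], dims[4])),
                    c(1, 3, 2, 4))
    state$logpost <- a_rest + arr_along(lo, 2, dims) + arr_along(state$lsig, 4, dims)
  } else if (state$context == "control_other") {
    m_other <- sum(marg_dim(p, 1) * state$grids$other)
    lc <- log(pmax(marg_dim(p, 3), 1e-300))
    lo <- log_trunc_norm(state$grids$other, m_other, sett$other_reset_sd)
    dims <- state$dims
    state$logpost <- arr_along(lo, 1, dims) + arr_along(lc, 3, dims) +
      arr_along(state$lsig, 2, dims)
  }
  state
}

#' Advance a belief filter by one trial
#'
#' @param state state from [learner_init()] or a previous step.
#' @param feedback observed feedback, 0-100.
#' @param is_ad logical: was the trial an active disambiguation?
#' @param trial_in_phase 1-based within-phase trial index; when it equals
#'   \code{settings$other_reset_trial} the other player is re-estimated under a
#'   fresh prior before the trial's feedback is incorporated.
#' @return Updated state.
#' @export
learner_step <- function(state, feedback, is_ad, trial_in_phase = state$t + 1L) {
  check_range(feedback, 0, 100, "feedback")
  if (state$context != "self_only" &&
      trial_in_phase == state$settings$other_reset_trial)
    state <- reset_other(state)
  treat_ad <- switch(state$variant,
                     active = isTRUE(is_ad),
                     ignorant = FALSE,
                     passive = if (isTRUE(is_ad)) NA else FALSE)
  skip <- is.na(treat_ad) || (state$context == "self_only" && isTRUE(is_ad))
  if (!skip) {
    if (isTRUE(treat_ad) && state$context != "self_only") {
      ll <- stats::dnorm(feedback, state$mean_ad, state$sd_ad, log = TRUE)
    } else {
      ll <- stats::dnorm(feedback, state$mean_normal, state$sd_normal, log = TRUE)
    }
    lp <- state$logpost + ll
    z <- logsumexp(lp)
    if (!is.finite(z))
      stop(sprintf("belief update degenerate at trial %d (all posterior mass lost)",
                   trial_in_phase))
    state$logpost <- lp - z
    state$n_used <- state$n_used + 1L
  }
  state$t <- as.integer(trial_in_phase)
  state
}

grid_quantile <- function(grid, w, probs) {
  if (length(grid) == 1L) return(rep(grid, length(probs)))
  cdf <- cumsum(w) - w / 2
  stats::approx(cdf, grid, xout = probs, rule = 2, ties = "ordered")$y
}

#' Posterior summaries of a belief-filter state
#'
#' Returns posterior means, SDs, central credible-interval bounds for the free
#' parameters (clamped parameters are reported at their clamped value with
#' zero width), and the phase-specific scalar uncertainty (see
#' [compute_uncertainty()]).
#'
#' @param state a belief-filter state.
#' @return One-row \code{data.frame}.
#' @export
learner_summary <- function(state) {
  lev <- state$settings$ci_level
  probs <- c((1 - lev) / 2, (1 + lev) / 2)
  p <- exp(state$logpost - max(state$logpost))
  p <- p / sum(p)
  out <- list(trial = state$t, n_used = state$n_used,
              prior_only = state$n_used == 0L)
  for (par in c("self", "other", "control", "sigma_self", "sigma_other")) {
    k <- match(par, state$free)
    if (!is.na(k)) {
      g <- state$grids[[par]]
      w <- marg_dim(p, k)
      w <- w / sum(w)
      mu <- sum(w * g)
      sdev <- sqrt(max(sum(w * g^2) - mu^2, 0))
      qq <- grid_quantile(g, w, probs)
    } else if (!is.null(state$clamped[[par]])) {
      mu <- state$clamped[[par]]; sdev <- 0; qq <- c(mu, mu)
    } else {
      mu <- NA_real_; sdev <- NA_real_; qq <- c(NA_real_, NA_real_)
    }
    out[[paste0(par, "_mean")]] <- mu
    out[[paste0(par, "_sd")]] <- sdev
    out[[paste0(par, "_lo")]] <- qq[1]
    out[[paste0(par, "_hi")]] <- qq[2]
  }
  out$uncertainty <- compute_uncertainty(
    state$context,
    ci_self = out$self_hi - out$self_lo,
    ci_other = out$other_hi - out$other_lo,
    ci_control = out$control_hi - out$control_lo)
  as.data.frame(out)
}

#' Phase-specific scalar uncertainty
#'
#' The trial-wise uncertainty is the average of credible-interval widths over
#' the quantities being learnt in the current phase: \code{(ci_self +
#' ci_other) / 2} in the Self-Other phase and \code{(100 * ci_control +
#' ci_other) / 2} in the Control-Other phase (control widths are rescaled to
#' score units). For Self-only trials, where only the self level is learnt,
#' the self width is used (a policy-level extension; the paired-phase
#' definitions are the substantive ones).
#'
#' @param phase_label \code{"self_other"}, \code{"control_other"} or
#'   \code{"self_only"}.
#' @param ci_self,ci_other,ci_control credible-interval widths.
#' @return Scalar uncertainty in score units.
#' @export
compute_uncertainty <- function(phase_label, ci_self = NULL, ci_other = NULL,
                                ci_control = NULL) {
  need <- function(x, nm) {
    if (is.null(x) || length(x) == 0L || is.na(x))
      stop(sprintf("'%s' is required for phase '%s'", nm, phase_label))
    x
  }
  switch(phase_label,
         self_other = (need(ci_self, "ci_self") + need(ci_other, "ci_other")) / 2,
         control_other = (100 * need(ci_control, "ci_control") +
                            need(ci_other, "ci_other")) / 2,
         self_only = need(ci_self, "ci_self"),
         stop("unknown phase_label: ", phase_label))
}

#' Fit a Bayesian observer model to a trial sequence
#'
#' Sequentially filters the feedback/AD sequence of one task phase and records
#' posterior summaries after every trial, equivalent to refitting the model to
#' trials 1..t for each t. From the reset trial (default the 12th) onward the
#' other player is re-estimated under a fresh prior centred on the most recent
#' posterior mean.
#'
#' @param trials \code{data.frame} with columns \code{feedback} (0-100),
#'   \code{is_ad} (logical) and optionally \code{trial_in_phase} (defaults to
#'   the row number).
#' @inheritParams learner_init
#' @return Object of class \code{"belief_filter"} with components
#'   \code{trials} (per-trial posterior summaries), \code{prior_summary},
#'   \code{data}, \code{variant}, \code{phase_context}, \code{clamped},
#'   \code{prior} and \code{settings}.
#' @seealso [learner_init()], [learner_step()], [compute_uncertainty()]
#' @export
fit_learner <- function(trials, variant = c("active", "ignorant", "passive"),
                        phase_context = c("self_other", "control_other", "self_only"),
                        prior = learner_prior(), clamped = list(),
                        settings = learner_settings()) {
  variant <- match.arg(variant)
  phase_context <- match.arg(phase_context)
  if (!is.data.frame(trials) || !all(c("feedback", "is_ad") %in% names(trials)))
    stop("'trials' must be a data.frame with columns 'feedback' and 'is_ad'")
  if (nrow(trials) < 1L) stop("need at least one trial")
  tip <- if ("trial_in_phase" %in% names(trials)) trials$trial_in_phase
         else seq_len(nrow(trials))
  st <- learner_init(variant, phase_context, prior, clamped, settings)
  prior_summary <- learner_summary(st)
  rows <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    st <- learner_step(st, trials$feedback[i], trials$is_ad[i], tip[i])
    rows[[i]] <- learner_summary(st)
  }
  structure(list(trials = do.call(rbind, rows), prior_summary = prior_summary,
                 data = data.frame(feedback = trials$feedback,
                                   is_ad = trials$is_ad, trial_in_phase = tip),
                 variant = variant, phase_context = phase_context,
                 clamped = st$clamped, prior = prior, settings = settings),
            class = "belief_filter")
}

#' @export
print.belief_filter <- function(x, ...) {
  cat(sprintf("Belief filter (%s learner, %s context): %d trials, %d used\n",
              x$variant, x$phase_context, nrow(x$trials),
              utils::tail(x$trials$n_used, 1)))
  cat("Final posterior means:\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
coef.belief_filter <- function(object, ...) {
  last <- object$trials[nrow(object$trials), ]
  out <- c(self = last$self_mean, other = last$other_mean,
           control = last$control_mean, sigma_self = last$sigma_self_mean,
           sigma_other = last$sigma_other_mean)
  out[!is.na(out)]
}

#' @export
summary.belief_filter <- function(object, ...) {
  structure(list(fit = object), class = "summary.belief_filter")
}

#' @export
print.summary.belief_filter <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("\nUncertainty: %.1f (prior) -> %.1f (final)\n",
              f$prior_summary$uncertainty, utils::tail(f$trials$uncertainty, 1)))
  cols <- intersect(c("trial", "self_mean", "other_mean", "control_mean",
                      "uncertainty"), names(f$trials))
  print(round(f$trials[, cols], 3), row.names = FALSE)
  invisible(x)
}

#' Estimated feedback implied by the beliefs entering each trial
#'
#' For trial t the prediction uses the posterior means after trials 1..t-1
#' (the prior for t = 1), combined through the feedback rule with the clamped
#' parameter of the phase.
#'
#' @param object a \code{"belief_filter"}.
#' @param ... unused.
#' @return Numeric vector, one prediction per trial.
#' @export
predict.belief_filter <- function(object, ...) {
  pre <- rbind(object$prior_summary, object$trials[-nrow(object$trials), ])
  switch(object$phase_context,
         self_other = compute_feedback(pre$self_mean, pre$other_mean,
                                       object$clamped$control),
         control_other = compute_feedback(object$clamped$self, pre$other_mean,
                                          pre$control_mean),
         self_only = pre$self_mean)
}

#' @export
residuals.belief_filter <- function(object, ...) {
  object$data$feedback - predict(object)
}

#' Plot posterior-mean trajectories with credible intervals
#'
#' @param x a \code{"belief_filter"}.
#' @param ... passed to \code{matplot}.
#' @export
plot.belief_filter <- function(x, ...) {
  tr <- x$trials
  pars <- c("self", "other", "control")
  pars <- pars[vapply(pars, function(p) any(tr[[paste0(p, "_sd")]] > 0), TRUE)]
  old <- graphics::par(mfrow = c(length(pars), 1), mar = c(3, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    mu <- tr[[paste0(p, "_mean")]]
    lo <- tr[[paste0(p, "_lo")]]; hi <- tr[[paste0(p, "_hi")]]
    graphics::matplot(tr$trial, cbind(lo, mu, hi), type = "l",
                      lty = c(2, 1, 2), col = c("grey60", "black", "grey60"),
                      xlab = "trial", ylab = p, main = p, ...)
  }
  invisible(x)
}

#' Width of a central credible interval
#'
#' @param x samples (numeric vector), a [dist_normal()] specification, or a
#'   [learner_prior()] (use \code{param} to pick the marginal).
#' @param level interval level in (0, 1).
#' @param ... method arguments.
#' @return Interval width (scalar).
#' @examples
#' credible_interval_width(dist_normal(50, 30), 0.90) # 98.70
#' @export
credible_interval_width <- function(x, level = 0.90, ...) {
  if (level <= 0 || level >= 1) stop("'level' must be in (0,1)")
  UseMethod("credible_interval_width")
}

#' @export
credible_interval_width.default <- function(x, level = 0.90, ...) {
  if (!is.numeric(x)) stop("no credible_interval_width method for this input")
  w <- unname(diff(stats::quantile(x, c((1 - level) / 2, (1 + level) / 2))))
  if (w == 0) warning("degenerate distribution: interval width is 0")
  w
}

#' Normal distribution specification
#' @param mean,sd distribution parameters.
#' @return Object of class \code{"dist_normal"}.
#' @export
dist_normal <- function(mean, sd) {
  if (sd < 0) stop("'sd' must be >= 0")
  structure(list(mean = mean, sd = sd), class = "dist_normal")
}

#' @export
credible_interval_width.dist_normal <- function(x, level = 0.90, ...) {
  w <- 2 * stats::qnorm((1 + level) / 2) * x$sd
  if (w == 0) warning("degenerate distribution: interval width is 0")
  w
}

#' @export
credible_interval_width.learner_prior <- function(x, level = 0.90,
                                                  param = c("self", "other", "control"),
                                                  ...) {
  param <- match.arg(param)
  sd <- switch(param, self = x$self_sd, other = x$other_sd, control = x$control_sd)
  credible_interval_width(dist_normal(0, sd), level)
}
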