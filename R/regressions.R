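## Trial-wise regression registry and group-level statistics. All regressions
## are OLS on z-scored outcome and predictors (standardized betas), applied
## after trial selection.

trialwise_formulas <- c("credit_self", "credit_other", "ad_uncertainty",
                        "ad_rating_error")

## build the (outcome, design) pair for one participant and one formula
build_regression_data <- function(tab, formula_id, errors = "ratings") {
  switch(formula_id,
    credit_self = {
      sel <- tab$phase_label == "self_other" & !is.na(tab$tpe_lag1) &
        !is.na(tab$self_update) & tab$prev_is_ad %in% FALSE
      d <- tab[sel, ]
      list(y = d$self_update,
           X = data.frame(tpe = d$tpe_lag1, control = d$true_control,
                          tpe_x_control = d$tpe_lag1 * d$true_control,
                          trial_number = d$trial_in_phase))
    },
    credit_other = {
      sel <- tab$phase_label == "self_other" & !is.na(tab$tpe_lag1) &
        !is.na(tab$other_update) & tab$prev_is_ad %in% FALSE
      d <- tab[sel, ]
      oc <- 1 - d$true_control
      list(y = d$other_update,
           X = data.frame(tpe = d$tpe_lag1, control = oc,
                          tpe_x_control = d$tpe_lag1 * oc,
                          trial_number = d$trial_in_phase))
    },
    ad_uncertainty = {
      sel <- tab$phase_label %in% c("self_other", "control_other")
      d <- tab[sel, ]
      if (is.null(d$model_uncertainty))
        stop("'ad_uncertainty' needs the model_uncertainty column")
      list(y = d$model_uncertainty,
           X = data.frame(ad_lag1 = d$ad_lag1, ad_lag2 = d$ad_lag2,
                          trial_number = d$trial_in_phase,
                          other_changed = d$other_changed,
                          phase = as.numeric(d$phase_label == "control_other")))
    },
    ad_rating_error = {
      sel <- tab$phase_label %in% c("self_other", "control_other")
      d <- tab[sel, ]
      y <- if (errors == "model") {
        if (is.null(d$model_other)) stop("'errors = \"model\"' needs model_* columns")
        ifelse(d$phase_label == "self_other",
               abs(d$model_self - d$true_self) +
                 abs(d$model_other - d$true_other_level),
               abs(d$model_other - d$true_other_level) +
                 100 * abs(d$model_control - d$true_control))
      } else d$summed_rating_errors
      list(y = y,
           X = data.frame(ad_lag1 = d$ad_lag1, ad_lag2 = d$ad_lag2,
                          trial_number = d$trial_in_phase,
                          phase = as.numeric(d$phase_label == "control_other")))
    },
    stop("unknown formula_id '", formula_id, "'; registry: ",
         paste(trialwise_formulas, collapse = ", ")))
}

std_lm <- function(y, X, min_trials = 8L) {
  ok <- stats::complete.cases(X) & !is.na(y)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (length(y) < min_trials) return(NULL)
  Z <- as.data.frame(lapply(X, standardize))
  fit <- stats::lm(standardize(y) ~ ., data = Z)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("rank-deficient design; collinear terms: ", paste(bad, collapse = ", "))
  }
  ci <- stats::confint(fit, level = 0.95)
  data.frame(term = names(cf), estimate = unname(cf),
             se = unname(sqrt(diag(stats::vcov(fit)))),
             ci_lo = ci[, 1], ci_hi = ci[, 2], n_trials = length(y),
             row.names = NULL)
}

#' Fit a registered trial-wise regression per participant
#'
#' The registry mirrors the study's behavioural analyses:
#' \describe{
#'   \item{credit_self}{self rating update on the previous trial's total
#'     prediction error, control, their interaction and trial number;
#'     Self-Other trials whose previous trial was normal.}
#'   \item{credit_other}{as above for other rating updates, with 1 - control.}
#'   \item{ad_uncertainty}{model uncertainty on lagged AD indicators, trial
#'     number, the other-change indicator and phase; all paired-phase trials.}
#'   \item{ad_rating_error}{summed rating errors (participant ratings, or the
#'     Active learner's estimates with \code{errors = "model"}) on lagged AD
#'     indicators, trial number and phase.}
#' }
#' Outcome and predictors are z-scored on the analysed subset, so estimates
#' are standardized betas with 95\% intervals.
#'
#' @param table a derived trial table (see [derive_measures()]; applied
#'   automatically if derived columns are missing).
#' @param formula_id one of the registry names.
#' @param errors for \code{ad_rating_error}: \code{"ratings"} or
#'   \code{"model"}.
#' @param min_trials participants with fewer usable trials are skipped (with
#'   a message).
#' @return \code{data.frame} of class \code{"regression_result"}: one row per
#'   term per participant, with the formula id and trial counts.
#' @export
fit_trialwise_regression <- function(table, formula_id, errors = "ratings",
                                     min_trials = 8L) {
  if (is.null(table$tpe)) table <- derive_measures(table)
  part <- if (is.null(table$participant)) rep(1L, nrow(table)) else table$participant
  out <- list()
  for (p in unique(part)) {
    res <- std_lm_safe(table[part == p, ], formula_id, errors, min_trials)
    if (is.null(res)) {
      message("participant ", p, " skipped (fewer than ", min_trials,
              " usable trials for ", formula_id, ")")
      next
    }
    res$participant <- p
    out[[length(out) + 1L]] <- res
  }
  if (!length(out)) {
    res <- data.frame(term = character(), estimate = numeric(),
                      se = numeric(), ci_lo = numeric(), ci_hi = numeric(),
                      n_trials = integer(), participant = integer(),
                      formula_id = character())
  } else {
    res <- do.call(rbind, out)
    res$formula_id <- formula_id
  }
  class(res) <- c("regression_result", "data.frame")
  res
}

std_lm_safe <- function(tab, formula_id, errors, min_trials) {
  dat <- build_regression_data(tab, formula_id, errors)
  std_lm(dat$y, dat$X, min_trials)
}

#' Control-inference regression on Control-Other switch trials
#'
#' Regresses the next trial's control estimate on the normal-minus-AD
#' feedback difference, the inverse self estimate, their interaction, and the
#' previous control estimate, on switch trials of the Control-Other phase.
#' The interaction is the signature of feedback-difference control inference:
#' a given feedback difference implies more control when the self level is
#' low.
#'
#' Predictors and outcome are z-scored across participants on the analysed
#' subset. With \code{hierarchical = FALSE} (the deterministic default) the
#' model is fit per participant and each term is summarised by a one-sample
#' t-test across participants; with \code{hierarchical = TRUE} a single
#' random-slope mixed model (\pkg{lme4}) is fit and fixed effects are
#' reported with Wald intervals.
#'
#' @param table a derived trial table (multiple participants).
#' @param hierarchical logical; see above.
#' @param outcome_col column whose next-trial value is the regression
#'   outcome; defaults to \code{control_col}. Point it at a learner
#'   variant's estimate column (see [variant_control_series()]) to explain
#'   what an observer holding that model would infer from the same data; the
#'   regressors stay at the observed ratings, so all variants face an
#'   identical design.
#' @param control_col,self_col columns feeding the previous-control regressor
#'   and inverse self.
#' @param min_switch participants with fewer usable switch trials are
#'   excluded (with a message).
#' @return List of class \code{"control_inference"}: \code{group} (term,
#'   estimate, CI, p), \code{per_participant} betas (two-stage path),
#'   \code{excluded}, \code{hierarchical}.
#' @export
fit_control_inference <- function(table, hierarchical = FALSE,
                                  outcome_col = control_col,
                                  control_col = "control_rating",
                                  self_col = "self_rating", min_switch = 3L) {
  if (is.null(table$feedback_difference)) table <- derive_measures(table)
  part <- if (is.null(table$participant)) rep(1L, nrow(table)) else table$participant
  ctrl <- table[[control_col]]
  if (is.null(ctrl)) stop("no column '", control_col, "'")
  outc <- table[[outcome_col]]
  if (is.null(outc)) stop("no column '", outcome_col, "'")
  selfv <- table[[self_col]]
  key <- interaction(part, table$block, drop = TRUE)
  nxt <- rep(NA_real_, nrow(table))
  for (idx in split(seq_len(nrow(table)), key)) {
    co <- idx[table$phase_label[idx] == "control_other"]
    co <- co[order(table$trial_in_phase[co])]
    if (length(co)) nxt[co] <- lead_within(outc[co])
  }
  keep <- table$phase_label == "control_other" & table$is_switch &
    !is.na(table$feedback_difference) & !is.na(nxt)
  d <- data.frame(participant = part,
                  y = nxt,
                  fd = table$feedback_difference,
                  inv_self = log(1 / pmax(selfv, 1)),
                  prev_control = ctrl)[keep, ]
  ## z-score across participants on the analysed subset
  d$y <- standardize(d$y); d$fd <- standardize(d$fd)
  d$inv_self <- standardize(d$inv_self)
  d$prev_control <- standardize(d$prev_control)
  d$fd_x_inv <- d$fd * d$inv_self
  counts <- table(d$participant)
  excluded <- names(counts)[counts < min_switch]
  if (length(excluded))
    message("excluded (fewer than ", min_switch, " usable switch trials): ",
            paste(excluded, collapse = ", "))
  d <- d[!d$participant %in% excluded, ]
  if (!nrow(d)) stop("no usable switch trials")
  terms <- c("fd", "inv_self", "fd_x_inv", "prev_control")
  if (hierarchical) {
    fit <- lme4::lmer(
      y ~ fd + inv_self + fd_x_inv + prev_control +
        (fd + inv_self + fd_x_inv + prev_control | participant),
      data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    group <- data.frame(term = names(fe), estimate = unname(fe),
                        ci_lo = unname(fe - 1.96 * se),
                        ci_hi = unname(fe + 1.96 * se),
                        p = 2 * stats::pnorm(-abs(unname(fe / se))),
                        row.names = NULL)
    pp <- NULL
  } else {
    pp <- do.call(rbind, lapply(split(d, d$participant), function(dd) {
      fit <- stats::lm(y ~ fd + inv_self + fd_x_inv + prev_control, data = dd)
      cf <- stats::coef(fit)
      data.frame(participant = dd$participant[1], term = names(cf),
                 estimate = unname(cf), row.names = NULL)
    }))
    pp <- pp[!is.na(pp$estimate), ]
    group <- do.call(rbind, lapply(c("(Intercept)", terms), function(tm) {
      est <- pp$estimate[pp$term == tm]
      if (length(est) < 2) return(NULL)
      tt <- stats::t.test(est)
      data.frame(term = tm, estimate = unname(tt$estimate),
                 ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
                 p = tt$p.value, n = length(est), row.names = NULL)
    }))
  }
  structure(list(group = group, per_participant = pp, excluded = excluded,
                 hierarchical = hierarchical, n_trials = nrow(d)),
            class = "control_inference")
}

#' @export
print.control_inference <- function(x, ...) {
  cat(sprintf("Control-inference regression (%s; %d switch trials)\n",
              if (x$hierarchical) "hierarchical" else "two-stage", x$n_trials))
  print(transform(x$group, estimate = round(estimate, 3),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Replace the control/self series with a learner variant's estimates
#'
#' Refits the chosen Bayesian observer (Active/Ignorant/Passive) to each
#' participant x block Control-Other feedback sequence, using priors centred
#' on the recorded first-trial ratings, and appends \code{variant_control}
#' (the belief entering each trial, i.e. the model's control rating) and
#' \code{variant_self} columns. Feed these to [fit_control_inference()] via
#' \code{control_col}/\code{self_col} to ask what an observer with that
#' assumption about AD trials would have inferred from the same feedback.
#'
#' @param table a trial table.
#' @param variant \code{"active"}, \code{"ignorant"} or \code{"passive"}.
#' @param settings [learner_settings()].
#' @return The table with \code{variant_control} and \code{variant_self}
#'   columns (NA outside Control-Other phases).
#' @export
variant_control_series <- function(table, variant,
                                   settings = learner_settings()) {
  part <- if (is.null(table$participant)) rep(1L, nrow(table)) else table$participant
  table$variant_control <- NA_real_
  table$variant_self <- NA_real_
  key <- interaction(part, table$block, drop = TRUE)
  for (idx in split(seq_len(nrow(table)), key)) {
    co <- idx[table$phase_label[idx] == "control_other"]
    if (!length(co)) next
    co <- co[order(table$trial_in_phase[co])]
    prior <- learner_prior(other_mean = table$other_rating[co][1],
                           control_mean = table$control_rating[co][1])
    fit <- fit_learner(data.frame(feedback = table$feedback[co],
                                  is_ad = table$is_ad[co],
                                  trial_in_phase = table$trial_in_phase[co]),
                       variant, "control_other", prior,
                       clamped = list(self = table$true_self[co][1]), settings)
    ## belief entering trial t = posterior after t-1
    entering <- c(fit$prior_summary$control_mean,
                  fit$trials$control_mean[-nrow(fit$trials)])
    ## outcome for trial t is the belief after t = entering t+1; store the
    ## posterior-after series shifted so lead_within() lines up as for ratings
    table$variant_control[co] <- entering
    table$variant_self[co] <- table$true_self[co][1]
    ## the "next trial's control" for the last trial exists for the model
    ## (posterior after the last feedback) but is dropped for comparability
    ## with the rating-based path
  }
  table
}

#' One-sample t-tests on per-participant coefficients
#'
#' @param result a \code{"regression_result"} from
#'   [fit_trialwise_regression()].
#' @return \code{data.frame} with, per term: mean beta, t, df, two-tailed p,
#'   Cohen's d and the 95\% CI.
#' @export
group_coef_ttest <- function(result) {
  do.call(rbind, lapply(split(result, result$term), function(rr) {
    tt <- stats::t.test(rr$estimate)
    data.frame(term = rr$term[1], mean_beta = mean(rr$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               cohens_d = mean(rr$estimate) / stats::sd(rr$estimate),
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               n = nrow(rr), row.names = NULL)
  }))
}

#' Mixed ANOVA with one within- and one between-participant factor
#'
#' Classical aov decomposition (\code{Error(id/within)}) reporting F, df, p
#' and eta squared per effect. With a single between-group level the between
#' factor is dropped and the within effect reduces to a paired comparison,
#' with a warning.
#'
#' @param data long-format \code{data.frame}.
#' @param dv,within,between,id column names.
#' @return \code{data.frame} with one row per effect.
#' @export
mixed_anova <- function(data, dv, within, between, id) {
  data[[within]] <- factor(data[[within]])
  data[[id]] <- factor(data[[id]])
  single_group <- length(unique(data[[between]])) < 2
  if (single_group) {
    warning("single between-participant group: reducing to the within-factor test")
    f <- stats::as.formula(paste(dv, "~", within, "+ Error(", id, "/", within, ")"))
  } else {
    data[[between]] <- factor(data[[between]])
    f <- stats::as.formula(paste(dv, "~", between, "*", within,
                                 "+ Error(", id, "/", within, ")"))
  }
  fit <- stats::aov(f, data = data)
  tabs <- summary(fit)
  rows <- list()
  ss_total <- 0
  for (stratum in tabs) {
    tt <- stratum[[1]]
    ss_total <- ss_total + sum(tt[["Sum Sq"]])
  }
  for (stratum in tabs) {
    tt <- stratum[[1]]
    effs <- trimws(rownames(tt))
    for (i in seq_along(effs)) {
      if (effs[i] == "Residuals") next
      rows[[length(rows) + 1L]] <- data.frame(
        effect = effs[i], F = tt[["F value"]][i],
        df1 = tt[["Df"]][i], df2 = tt[["Df"]][nrow(tt)],
        p = tt[["Pr(>F)"]][i],
        eta_sq = tt[["Sum Sq"]][i] / ss_total, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Spearman validation of detected against reported AD counts
#'
#' Correlates the number of AD trials detected in behaviour with the
#' post-session self-reported per-game count; the confidence interval uses
#' the Fisher-z approximation with the Spearman variance inflation.
#'
#' @param reported,detected per-participant counts.
#' @param conf_level interval level.
#' @return List with \code{rho}, \code{p} (two-sided), \code{ci}, \code{n}.
#' @export
spearman_ad_validation <- function(reported, detected, conf_level = 0.95) {
  ok <- stats::complete.cases(reported, detected)
  reported <- reported[ok]; detected <- detected[ok]
  n <- length(reported)
  if (n < 4) stop("need at least 4 participants")
  ct <- suppressWarnings(stats::cor.test(reported, detected, method = "spearman",
                                         exact = FALSE))
  rho <- unname(ct$estimate)
  if (abs(rho) < 1) {
    z <- atanh(rho)
    se <- sqrt((1 + rho^2 / 2) / (n - 3))
    q <- stats::qnorm((1 + conf_level) / 2)
    ci <- tanh(c(z - q * se, z + q * se))
  } else ci <- c(rho, rho)
  list(rho = rho, p = ct$p.value, ci = ci, n = n)
}
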