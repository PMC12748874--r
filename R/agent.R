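## Agent-based cohort simulator. Agents are Active learners with a noisy
## rating read-out and an uncertainty-driven active-disambiguation (AD)
## policy; they stand in for human participants so the downstream pipeline is
## testable without real data.

#' Agent behavioural parameters
#'
#' @param rating_noise_sd SD of the truncated-Gaussian read-out noise on the
#'   0-100 performance ratings (score units).
#' @param control_rating_noise_sd SD of the read-out noise on the 0-1 control
#'   rating (fraction).
#' @param ad_base_rate baseline AD probability.
#' @param ad_uncertainty_gain AD probability added per unit of normalised
#'   uncertainty (uncertainty / 100).
#' @param self_only_ad_factor multiplicative suppression of AD on Self-only
#'   trials, where AD is uninformative.
#' @param error_sd half-normal scale of the agent's objective game error
#'   (error units).
#' @param debrief_noise_sd SD of the rounded Gaussian noise on the
#'   post-session reported per-game AD count.
#' @return Object of class \code{"agent_params"}.
#' @export
agent_params <- function(rating_noise_sd = 5, control_rating_noise_sd = 0.05,
                         ad_base_rate = 0.05, ad_uncertainty_gain = 0.65,
                         self_only_ad_factor = 0.15, error_sd = 10,
                         debrief_noise_sd = 2) {
  if (any(c(rating_noise_sd, control_rating_noise_sd, error_sd,
            debrief_noise_sd) < 0))
    stop("noise SDs must be >= 0")
  check_range(ad_base_rate, 0, 1, "ad_base_rate")
  if (error_sd <= 0) stop("'error_sd' must be > 0")
  structure(as.list(environment()), class = "agent_params")
}

## half-normal draw truncated above (normal trials) or shifted beyond the AD
## threshold (AD trials)
draw_objective_error <- function(is_ad, calib) {
  if (is_ad) {
    calib$ad_threshold + abs(stats::rnorm(1, 0, calib$error_sd))
  } else {
    Fthr <- 2 * stats::pnorm(calib$ad_threshold / calib$error_sd) - 1
    u <- stats::runif(1, 0, Fthr)
    calib$error_sd * stats::qnorm((u + 1) / 2)
  }
}

#' Simulate one participant performing the task
#'
#' The agent holds an Active-learner belief state (see [fit_learner()]) that
#' it updates trial by trial. Ratings are the current posterior means plus
#' truncated Gaussian read-out noise (first-trial ratings are noisy priors).
#' AD is chosen with probability \code{clip(ad_base_rate +
#' ad_uncertainty_gain * uncertainty / 100, 0, 1)}, suppressed by
#' \code{self_only_ad_factor} on Self-only trials. The objective error is then
#' drawn, mapped through the logistic calibration, and combined with the other
#' player's drawn score into the feedback.
#'
#' @param schedule an \code{"ad_schedule"} from [generate_schedule()].
#' @param params an [agent_params()].
#' @param seed integer seed; identical seeds give bit-identical tables.
#' @param settings [learner_settings()] used for the agent's belief filter.
#' @param participant id recorded in the \code{participant} column.
#' @return A trial table (one row per trial) with the trial-record fields
#'   (\code{block}, \code{phase_label}, \code{trial_in_phase},
#'   \code{trial_in_block}, ratings, \code{objective_error},
#'   \code{self_score}, \code{other_score}, \code{is_ad}, \code{is_switch},
#'   \code{feedback}, true levels) plus \code{participant} and the agent's
#'   noise-free belief read-outs entering each trial (\code{model_self},
#'   \code{model_other}, \code{model_control}, \code{model_uncertainty}).
#' @export
simulate_participant <- function(schedule, params = agent_params(), seed = 1L,
                                 settings = learner_settings(),
                                 participant = 1L) {
  validate_schedule(schedule)
  if (!inherits(params, "agent_params")) stop("'params' must be agent_params")
  set.seed(as.integer(seed))
  settings$other_reset_trial <- schedule$other_change_trial
  rows <- list()
  for (b in seq_along(schedule$blocks)) {
    blk <- schedule$blocks[[b]]
    calib <- mapping_calibration(blk$true_self, params$error_sd)
    calib$error_sd <- params$error_sd
    self_belief <- NULL   # carried across phases within a block
    trial_in_block <- 0L
    for (ph in blk$phase_specs) {
      lab <- ph$phase_label
      ## gut-feeling first-trial ratings seed the priors
      r1_self <- switch(lab,
        self_other = rtnorm(1, 50, 15, 0, 100),
        self_only = rtnorm(1, self_belief, params$rating_noise_sd, 0, 100),
        control_other = rtnorm(1, blk$true_self, params$rating_noise_sd, 0, 100))
      r1_other <- if (lab == "self_only") NA_real_ else rtnorm(1, 50, 15, 0, 100)
      r1_control <- switch(lab,
        self_other = ph$true_control,
        self_only = 1,
        control_other = rtnorm(1, 0.5, 0.15, 0, 1))
      prior <- learner_prior(
        self_mean = r1_self,
        other_mean = if (is.na(r1_other)) 50 else r1_other,
        control_mean = r1_control)
      clamped <- switch(lab,
        self_other = list(control = ph$true_control),
        self_only = list(),
        control_other = list(self = blk$true_self))
      st <- learner_init("active", lab, prior, clamped, settings)
      summ <- learner_summary(st)
      prev_ad <- NA
      for (t in seq_len(ph$n_trials)) {
        ## ratings: belief means (or knowns) + read-out noise
        if (t == 1L) {
          self_rating <- r1_self; other_rating <- r1_other
          control_rating <- r1_control
        } else {
          self_rating <- if (lab == "control_other")
            rtnorm(1, blk$true_self, params$rating_noise_sd, 0, 100)
          else rtnorm(1, summ$self_mean, params$rating_noise_sd, 0, 100)
          other_rating <- if (lab == "self_only") NA_real_
          else rtnorm(1, summ$other_mean, params$rating_noise_sd, 0, 100)
          control_rating <- switch(lab,
            self_other = ph$true_control,
            self_only = 1,
            control_other = rtnorm(1, summ$control_mean,
                                   params$control_rating_noise_sd, 0, 1))
        }
        p_ad <- clip(params$ad_base_rate +
                       params$ad_uncertainty_gain * summ$uncertainty / 100, 0, 1)
        if (lab == "self_only") p_ad <- p_ad * params$self_only_ad_factor
        is_ad <- stats::runif(1) < p_ad
        objective_error <- draw_objective_error(is_ad, calib)
        mp <- map_performance(objective_error, calib)
        self_score <- mp$self_score
        stopifnot(identical(mp$is_ad, is_ad))
        if (lab == "self_only") {
          other_score <- NA_real_
          true_other <- NA_real_
          feedback <- self_score
        } else {
          true_other <- if (t < schedule$other_change_trial) ph$other_level_early
                        else ph$other_level_late
          other_score <- draw_other_score(true_other, ph$other_sd)
          feedback <- compute_feedback(self_score, other_score, ph$true_control)
        }
        st <- learner_step(st, feedback, is_ad, t)
        trial_in_block <- trial_in_block + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          participant = participant, block = b, phase_label = lab,
          trial_in_phase = t, trial_in_block = trial_in_block,
          self_rating = self_rating, other_rating = other_rating,
          control_rating = control_rating, objective_error = objective_error,
          self_score = self_score, other_score = other_score, is_ad = is_ad,
          is_switch = !is.na(prev_ad) && xor(prev_ad, is_ad),
          feedback = feedback, true_self = blk$true_self,
          true_other_level = true_other, true_control = ph$true_control,
          model_self = summ$self_mean,
          model_other = if (lab == "self_only") NA_real_ else summ$other_mean,
          model_control = summ$control_mean,
          model_uncertainty = summ$uncertainty)
        prev_ad <- is_ad
        summ <- learner_summary(st)
      }
      self_belief <- summ$self_mean
    }
  }
  do.call(rbind, rows)
}

#' Cohort parameter prior
#'
#' Ranges from which per-agent behavioural parameters are drawn uniformly,
#' giving the between-participant heterogeneity real cohorts show (e.g., in
#' how readily participants deploy AD).
#'
#' @param rating_noise_sd,control_rating_noise_sd,ad_base_rate,ad_uncertainty_gain,error_sd
#'   two-element ranges.
#' @param self_only_ad_factor,debrief_noise_sd fixed scalars.
#' @return Object of class \code{"cohort_params_prior"}.
#' @export
cohort_params_prior <- function(rating_noise_sd = c(3, 8),
                                control_rating_noise_sd = c(0.03, 0.08),
                                ad_base_rate = c(0.02, 0.08),
                                ad_uncertainty_gain = c(0.45, 0.85),
                                error_sd = c(8, 12),
                                self_only_ad_factor = 0.15,
                                debrief_noise_sd = 2) {
  structure(as.list(environment()), class = "cohort_params_prior")
}

draw_agent_params <- function(prior) {
  u <- function(r) if (length(r) == 2L) stats::runif(1, r[1], r[2]) else r
  agent_params(rating_noise_sd = u(prior$rating_noise_sd),
               control_rating_noise_sd = u(prior$control_rating_noise_sd),
               ad_base_rate = u(prior$ad_base_rate),
               ad_uncertainty_gain = u(prior$ad_uncertainty_gain),
               self_only_ad_factor = prior$self_only_ad_factor,
               error_sd = u(prior$error_sd),
               debrief_noise_sd = prior$debrief_noise_sd)
}

#' Simulate a cohort of participants
#'
#' Draws per-participant behavioural parameters from \code{params_prior},
#' simulates each participant with an independently derived seed, and records
#' a manifest including the post-session debrief item: the reported per-game
#' AD count is the true mean AD count per game plus rounded (integer)
#' Gaussian noise, floored at zero.
#'
#' @param n number of participants (>= 1).
#' @param schedule an \code{"ad_schedule"}.
#' @param params_prior a [cohort_params_prior()], or a single
#'   [agent_params()] used for every participant.
#' @param seed master seed; per-participant streams are derived from it.
#' @param settings [learner_settings()] for the agents' belief filters.
#' @return List with \code{manifest} (class \code{"cohort_manifest"}: seeds,
#'   per-participant parameters, detected and reported AD counts) and
#'   \code{trials} (row-bound trial tables with a \code{participant} column).
#' @export
simulate_cohort <- function(n, schedule, params_prior = cohort_params_prior(),
                            seed = 1L, settings = learner_settings()) {
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  p_seeds <- sample.int(.Machine$integer.max - 1L, n)
  if (inherits(params_prior, "agent_params")) {
    plist <- rep(list(params_prior), n)
  } else {
    plist <- lapply(seq_len(n), function(i) draw_agent_params(params_prior))
  }
  debrief_seeds <- sample.int(.Machine$integer.max - 1L, n)
  tabs <- vector("list", n)
  detected <- reported <- numeric(n)
  n_games <- length(schedule$blocks)
  for (i in seq_len(n)) {
    tabs[[i]] <- simulate_participant(schedule, plist[[i]], p_seeds[i],
                                      settings, participant = i)
    detected[i] <- sum(tabs[[i]]$is_ad) / n_games
    set.seed(debrief_seeds[i])
    reported[i] <- max(0, detected[i] +
                         round(stats::rnorm(1, 0, plist[[i]]$debrief_noise_sd)))
  }
  manifest <- structure(list(n_participants = n, seed = as.integer(seed),
                             participant_seeds = p_seeds, params = plist,
                             detected_ad_count = detected,
                             reported_ad_count = reported),
                        class = "cohort_manifest")
  list(manifest = manifest, trials = do.call(rbind, tabs))
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (seed %d)\n",
              x$n_participants, x$seed))
  cat(sprintf("Detected AD per game: mean %.1f (range %.1f-%.1f)\n",
              mean(x$detected_ad_count), min(x$detected_ad_count),
              max(x$detected_ad_count)))
  invisible(x)
}

trial_record_cols <- c("block", "phase_label", "trial_in_phase", "trial_in_block",
                       "self_rating", "other_rating", "control_rating",
                       "objective_error", "self_score", "other_score", "is_ad",
                       "is_switch", "feedback", "true_self", "true_other_level",
                       "true_control")

#' Read/write trial tables as CSV
#'
#' The CSV carries exactly the trial-record columns (model read-out columns
#' and the participant id are in-memory extras and are dropped on write).
#'
#' @param table a trial table.
#' @param path file path.
#' @return \code{write_trials} returns the path invisibly;
#'   \code{read_trials} the table.
#' @export
write_trials <- function(table, path) {
  miss <- setdiff(trial_record_cols, names(table))
  if (length(miss)) stop("missing trial-record columns: ", paste(miss, collapse = ", "))
  utils::write.csv(table[, trial_record_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Validate trial-record invariants
#'
#' Checks every row of a trial table: ratings within their scales, AD trials
#' carry a zero self score, feedback obeys the control-weighted rule (equals
#' the self score on Self-only trials), and switch flags match the AD
#' sequence.
#'
#' @param table a trial table.
#' @param tol floating-point tolerance for the feedback identity.
#' @return \code{TRUE} invisibly; errors describing the first violation.
#' @export
validate_trials <- function(table, tol = 1e-8) {
  miss <- setdiff(trial_record_cols, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  check_range(table$self_rating, 0, 100, "self_rating")
  check_range(table$control_rating, 0, 1, "control_rating")
  check_range(table$other_rating[!is.na(table$other_rating)], 0, 100, "other_rating")
  check_range(table$feedback, 0, 100, "feedback")
  if (any(table$is_ad & table$self_score != 0))
    stop("AD trials must have self_score = 0")
  so <- table$phase_label == "self_only"
  if (any(abs(table$feedback[so] - table$self_score[so]) > tol))
    stop("self_only feedback must equal self_score")
  fb <- compute_feedback(table$self_score[!so],
                         ifelse(is.na(table$other_score[!so]), 0,
                                table$other_score[!so]),
                         table$true_control[!so])
  if (any(abs(table$feedback[!so] - fb) > tol))
    stop("feedback must equal self*control + other*(1-control)")
  part <- if (is.null(table$participant)) rep(1L, nrow(table)) else table$participant
  sp <- split(seq_len(nrow(table)), list(part, table$block, table$phase_label))
  for (idx in sp) {
    if (!length(idx)) next
    ad <- table$is_ad[idx]
    sw <- c(FALSE, xor(ad[-1], ad[-length(ad)]))
    if (!identical(as.logical(table$is_switch[idx]), sw))
      stop("is_switch inconsistent with the AD sequence")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
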