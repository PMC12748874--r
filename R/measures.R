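#' Estimated feedback implied by a set of ratings
#'
#' The outcome a rater expects given their beliefs: \code{self_rating *
#' control + other_rating * (1 - control)}. In the Self-Other phase the
#' control estimate is the instructed true control level.
#'
#' @param self_rating,other_rating performance ratings, 0-100.
#' @param control_estimate control belief, 0-1.
#' @return Expected feedback, 0-100.
#' @export
estimated_feedback <- function(self_rating, other_rating, control_estimate) {
  compute_feedback(self_rating, other_rating, control_estimate)
}

#' Rating accuracy against a true level
#'
#' \code{1 - |rating - true| / max(100 - true, true)}: the absolute rating
#' error normalised by the largest error possible at that true level. Both
#' arguments must be on the 0-100 scale (multiply control quantities by 100
#' first).
#'
#' @param rating rating on 0-100.
#' @param true_level true level on 0-100.
#' @return Accuracy in \[0, 1\]. Vectorised.
#' @export
rating_accuracy <- function(rating, true_level) {
  check_range(true_level, 0, 100, "true_level")
  check_range(rating, 0, 100, "rating")
  1 - abs(rating - true_level) / pmax(100 - true_level, true_level)
}

#' Total prediction error and its self/other split
#'
#' The total prediction error is the signed difference between observed and
#' estimated feedback; it is attributed to self and other in proportion to
#' control: \code{sPE = tPE * control}, \code{oPE = tPE * (1 - control)}, the
#' unique linear split satisfying \code{sPE + oPE = tPE}.
#'
#' @param feedback observed feedback.
#' @param estimated_feedback expected feedback from the ratings.
#' @param control_estimate control belief in \[0, 1\] (true control in the
#'   Self-Other phase).
#' @return List with \code{tpe}, \code{spe}, \code{ope}.
#' @export
compute_tpe_and_split <- function(feedback, estimated_feedback, control_estimate) {
  check_range(control_estimate, 0, 1, "control_estimate")
  tpe <- feedback - estimated_feedback
  spe <- tpe * control_estimate
  ## the other portion is the remainder, so the split sums to tPE exactly
  list(tpe = tpe, spe = spe, ope = tpe - spe)
}

lag_within <- function(x, k = 1L) {
  n <- length(x)
  if (n <= k) return(rep(NA_real_, n))
  c(rep(NA_real_, k), x[seq_len(n - k)])
}

lead_within <- function(x) {
  n <- length(x)
  c(x[-1], NA_real_)
}

#' Derive the trial-wise behavioural measures
#'
#' Adds, per participant x block x phase, the derived columns used by the
#' regression registry: the control estimate in effect (instructed control in
#' Self-Other, the control rating in Control-Other), estimated feedback, the
#' total prediction error and its self/other split, rating errors and
#' accuracies (including the estimated-feedback accuracy, whose reference is
#' the phase mean of the feedback on normal trials), summed rating errors
#' (control errors enter x100 in Control-Other), rating updates, lagged AD
#' indicators, the mid-phase other-change indicator, inverse self
#' (\code{ln(1/self_rating)} with ratings floored at 1), the normal-minus-AD
#' feedback difference on switch trials (and its split by switch direction),
#' the trial-to-trial feedback change, and next-trial control columns.
#'
#' @param table a trial table from [simulate_participant()] /
#'   [simulate_cohort()] (or read from CSV).
#' @param other_change_trial 1-based within-phase trial of the unannounced
#'   other change.
#' @return The table with derived columns appended, original row order.
#' @export
derive_measures <- function(table, other_change_trial = 12) {
  part <- if (is.null(table$participant)) rep(1L, nrow(table)) else table$participant
  key <- interaction(part, table$block, table$phase_label, drop = TRUE)
  idx_list <- split(seq_len(nrow(table)), key)

  is_so <- table$phase_label == "self_other"
  is_co <- table$phase_label == "control_other"
  is_only <- table$phase_label == "self_only"

  ce <- ifelse(is_so, table$true_control,
               ifelse(is_only, 1, table$control_rating))
  table$control_estimate <- ce
  other_in <- ifelse(is.na(table$other_rating), 0, table$other_rating)
  table$estimated_feedback <- table$self_rating * ce + other_in * (1 - ce)
  pe <- compute_tpe_and_split(table$feedback, table$estimated_feedback, ce)
  table$tpe <- pe$tpe; table$spe <- pe$spe; table$ope <- pe$ope

  table$self_error <- abs(table$self_rating - table$true_self)
  table$other_error <- abs(table$other_rating - table$true_other_level)
  table$control_error <- abs(table$control_rating - table$true_control)
  table$self_accuracy <- rating_accuracy(table$self_rating, table$true_self)
  table$other_accuracy <- ifelse(is.na(table$other_rating), NA_real_,
    rating_accuracy(other_in, ifelse(is.na(table$true_other_level), 0,
                                     table$true_other_level)))
  table$control_accuracy <- rating_accuracy(100 * table$control_rating,
                                            100 * table$true_control)
  table$summed_rating_errors <- ifelse(
    is_so, table$self_error + table$other_error,
    ifelse(is_co, table$self_error + table$other_error + 100 * table$control_error,
           table$self_error))
  table$inverse_self <- log(1 / pmax(table$self_rating, 1))
  table$other_changed <- as.integer(!is_only & table$trial_in_phase >= other_change_trial)

  n <- nrow(table)
  table$self_update <- table$other_update <- table$control_update <- NA_real_
  table$tpe_lag1 <- table$ad_lag1 <- table$ad_lag2 <- NA_real_
  table$feedback_change <- table$feedback_difference <- NA_real_
  table$next_control <- NA_real_
  table$prev_is_ad <- NA
  table$est_feedback_accuracy <- NA_real_
  for (idx in idx_list) {
    fb <- table$feedback[idx]; ad <- table$is_ad[idx]
    table$self_update[idx] <- table$self_rating[idx] - lag_within(table$self_rating[idx])
    table$other_update[idx] <- table$other_rating[idx] - lag_within(table$other_rating[idx])
    table$control_update[idx] <- table$control_rating[idx] - lag_within(table$control_rating[idx])
    table$tpe_lag1[idx] <- lag_within(table$tpe[idx])
    adl1 <- lag_within(as.numeric(ad)); adl2 <- lag_within(as.numeric(ad), 2L)
    table$ad_lag1[idx] <- ifelse(is.na(adl1), 0, adl1)
    table$ad_lag2[idx] <- ifelse(is.na(adl2), 0, adl2)
    table$prev_is_ad[idx] <- as.logical(lag_within(as.numeric(ad)))
    table$feedback_change[idx] <- fb - lag_within(fb)
    prev_ad <- lag_within(as.numeric(ad))
    fd <- ifelse(!is.na(prev_ad) & prev_ad == 1 & !ad, fb - lag_within(fb),
                 ifelse(!is.na(prev_ad) & prev_ad == 0 & ad, lag_within(fb) - fb,
                        NA_real_))
    table$feedback_difference[idx] <- fd
    table$next_control[idx] <- lead_within(table$control_rating[idx])
    ref <- mean(fb[!ad])
    if (is.finite(ref))
      table$est_feedback_accuracy[idx] <-
        rating_accuracy(clip(table$estimated_feedback[idx], 0, 100), clip(ref, 0, 100))
  }
  table$fd_ad_to_normal <- ifelse(table$is_switch & !table$is_ad,
                                  table$feedback_difference, 0)
  table$fd_normal_to_ad <- ifelse(table$is_switch & table$is_ad,
                                  table$feedback_difference, 0)
  table
}
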