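#' Control-weighted feedback for a joint trial
#'
#' The single outcome shown on a trial is the participant's own score and the
#' other player's score, weighted by the participant's control over the
#' outcome: \code{feedback = self * control + other * (1 - control)}. On
#' Self-only trials \code{control = 1}, so the feedback equals the self score.
#'
#' @param self_score own performance score, 0-100.
#' @param other_score other player's performance score, 0-100.
#' @param control own control over the feedback, fraction in \[0, 1\].
#' @return Feedback score in \[0, 100\]. Vectorised over its arguments.
#' @examples
#' compute_feedback(50, 20, 0.8) # 44
#' @export
compute_feedback <- function(self_score, other_score, control) {
  check_range(self_score, 0, 100, "self_score")
  check_range(other_score, 0, 100, "other_score")
  check_range(control, 0, 1, "control")
  self_score * control + other_score * (1 - control)
}

#' Point inference of control from a feedback difference
#'
#' On a normal trial the feedback reflects both players; on an active
#' disambiguation (AD) trial the self score is forced to zero, so the feedback
#' reflects only the other player. The difference between the two feedbacks,
#' divided by one's own performance level, is then a direct point estimate of
#' control: \code{control = (normal feedback - AD feedback) / self}.
#'
#' @param feedback_difference normal-trial feedback minus AD-trial feedback.
#' @param self_level own performance level (must be > 0).
#' @return Control estimate, clipped to \[0, 1\].
#' @examples
#' infer_control_point(44 - 4, 50) # 0.8
#' @export
infer_control_point <- function(feedback_difference, self_level) {
  if (!is.numeric(self_level) || any(!is.finite(self_level)) || any(self_level <= 0))
    stop("'self_level' must be > 0: control is undefined without own performance")
  if (!is.numeric(feedback_difference) || any(!is.finite(feedback_difference)))
    stop("'feedback_difference' must be finite numeric")
  clip(feedback_difference / self_level, 0, 1)
}

#' Calibration of the objective-error to score mapping
#'
#' Objective game errors (pixels, milliseconds, ...) are mapped to a 0-100
#' score through a decreasing logistic curve; errors at or beyond
#' \code{ad_threshold} are obvious, extreme mistakes: they score 0 and are
#' flagged as active disambiguation (AD). The curve's scale \code{M} is set so
#' that the expected non-AD score of an agent whose errors are half-normal
#' with scale \code{error_sd} (truncated below the AD threshold) equals
#' \code{target_mean}. This keeps the mean score on the experimenter's
#' schedule while preserving the trial-to-trial ranking of objective errors.
#'
#' @param target_mean scheduled mean score, 0-100.
#' @param error_sd scale of the agent's half-normal objective-error
#'   distribution, in error units.
#' @param slope logistic steepness per error unit (> 0).
#' @param midpoint logistic midpoint in error units; defaults to
#'   \code{1.5 * error_sd}.
#' @param ad_threshold AD detection threshold in error units (must exceed the
#'   midpoint); defaults to \code{4 * error_sd}.
#' @return An object of class \code{"mapping_calibration"}.
#' @export
mapping_calibration <- function(target_mean, error_sd, slope = 0.4,
                                midpoint = 1.5 * error_sd,
                                ad_threshold = 4 * error_sd) {
  stop_if_not_scalar_number(target_mean, "target_mean")
  stop_if_not_scalar_number(error_sd, "error_sd")
  check_range(target_mean, 0, 100, "target_mean")
  if (slope <= 0) stop("'slope' must be > 0")
  if (error_sd <= 0) stop("'error_sd' must be > 0")
  if (ad_threshold <= midpoint) stop("'ad_threshold' must exceed 'midpoint'")
  ## expected base logistic value under the truncated half-normal error law
  base <- function(e) stats::plogis(-slope * (e - midpoint))
  dens <- function(e) stats::dnorm(e, 0, error_sd)
  mass <- stats::pnorm(ad_threshold, 0, error_sd) - 0.5
  eb <- stats::integrate(function(e) base(e) * dens(e), 0, ad_threshold)$value / mass
  M <- target_mean / eb
  if (M > 100)
    stop("calibration infeasible: required curve scale exceeds the score range; ",
         "lower 'target_mean' or raise 'midpoint'")
  structure(list(target_mean = target_mean, error_sd = error_sd, slope = slope,
                 midpoint = midpoint, ad_threshold = ad_threshold, scale = M),
            class = "mapping_calibration")
}

#' Map an objective game error to a self-performance score
#'
#' @param objective_error non-negative objective error(s) in game units.
#' @param calib a [mapping_calibration()] object.
#' @return A list with \code{self_score} (0-100, strictly decreasing in the
#'   error on the non-AD branch) and \code{is_ad} (logical; score forced to 0).
#' @export
map_performance <- function(objective_error, calib) {
  if (!inherits(calib, "mapping_calibration")) stop("'calib' must be a mapping_calibration")
  if (!is.numeric(objective_error) || any(!is.finite(objective_error)))
    stop("'objective_error' must be finite numeric")
  if (any(objective_error < 0)) stop("'objective_error' must be >= 0")
  is_ad <- objective_error >= calib$ad_threshold
  score <- calib$scale * stats::plogis(-calib$slope * (objective_error - calib$midpoint))
  score[is_ad] <- 0
  list(self_score = clip(score, 0, 100), is_ad = is_ad)
}

#' Other player's trial score
#'
#' Draws the other player's per-trial score from a normal distribution centred
#' on the scheduled true level (SD 6.5 score units by default), truncated to
#' the 0-100 score range.
#'
#' @param level true other level, 0-100.
#' @param sd trial-to-trial SD in score units (>= 0).
#' @param n number of draws.
#' @return Numeric vector of scores in \[0, 100\].
#' @export
draw_other_score <- function(level, sd = 6.5, n = 1) {
  check_range(level, 0, 100, "level")
  if (sd < 0) stop("'sd' must be >= 0")
  rtnorm(n, level, sd, 0, 100)
}
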