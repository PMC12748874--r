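#' Schedule configuration
#'
#' Defaults encode the task's block/phase structure: 4 blocks, each with a
#' 16-trial Self-Other phase (control instructed, self and other unknown),
#' 4 Self-only trials (full control, feedback = own score), and a 16-trial
#' Control-Other phase (self known, control and a new other unknown) - 144
#' trials in total. Within each 16-trial phase the other player's true level
#' changes unannounced from the 12th trial. True levels are randomised within
#' the configured ranges unless explicit levels are supplied via
#' \code{blocks}.
#'
#' @param n_blocks number of blocks.
#' @param n_self_other,n_self_only,n_control_other trials per phase.
#' @param self_range range the block-constant true self level is drawn from.
#' @param other_range range other levels are drawn from.
#' @param min_other_change minimum absolute jump of the other's level at the
#'   unannounced mid-phase change (score units).
#' @param control_levels candidate instructed/true control levels for the
#'   paired phases.
#' @param other_sd trial-to-trial SD of the other's score (score units).
#' @param other_change_trial 1-based within-phase trial from which the late
#'   other level applies.
#' @param blocks optional list of fully specified blocks (passed through
#'   unchanged, after validation).
#' @return A list of class \code{"schedule_config"}.
#' @export
schedule_config <- function(n_blocks = 4, n_self_other = 16, n_self_only = 4,
                            n_control_other = 16, self_range = c(30, 75),
                            other_range = c(20, 85), min_other_change = 20,
                            control_levels = c(0.2, 0.35, 0.5, 0.65, 0.8),
                            other_sd = 6.5, other_change_trial = 12,
                            blocks = NULL) {
  if (min_other_change >= diff(range(other_range)))
    stop("'min_other_change' is infeasible within 'other_range'")
  structure(as.list(environment()), class = "schedule_config")
}

new_phase_spec <- function(phase_label, n_trials, true_control,
                           other_level_early = NA_real_,
                           other_level_late = NA_real_, other_sd = 6.5) {
  list(phase_label = phase_label, n_trials = n_trials,
       true_control = true_control, other_level_early = other_level_early,
       other_level_late = other_level_late, other_sd = other_sd)
}

#' Generate a task schedule
#'
#' @param config a [schedule_config()].
#' @param seed integer seed; the same seed yields an identical schedule.
#' @return An object of class \code{"ad_schedule"}: a list with \code{blocks},
#'   each holding \code{game_id}, \code{true_self} and the ordered
#'   \code{phase_specs} (Self-Other, Self-only, Control-Other).
#' @export
generate_schedule <- function(config = schedule_config(), seed = 1L) {
  if (!inherits(config, "schedule_config")) stop("'config' must be a schedule_config")
  if (!is.null(config$blocks)) {
    sched <- structure(list(blocks = config$blocks,
                            other_change_trial = config$other_change_trial),
                       class = "ad_schedule")
    validate_schedule(sched)
    return(sched)
  }
  set.seed(as.integer(seed))
  draw_other_pair <- function() {
    early <- stats::runif(1, config$other_range[1], config$other_range[2])
    lo <- config$other_range[1]; hi <- config$other_range[2]
    up_room <- hi - early; down_room <- early - lo
    dir <- if (up_room < config$min_other_change) -1
           else if (down_room < config$min_other_change) 1
           else sample(c(-1, 1), 1)
    room <- if (dir > 0) up_room else down_room
    late <- early + dir * stats::runif(1, config$min_other_change, room)
    round(c(early, late), 1)
  }
  n_lv <- length(config$control_levels)
  c_so <- config$control_levels[sample.int(n_lv, config$n_blocks, replace = n_lv < config$n_blocks)]
  c_co <- config$control_levels[sample.int(n_lv, config$n_blocks, replace = n_lv < config$n_blocks)]
  blocks <- lapply(seq_len(config$n_blocks), function(b) {
    so <- draw_other_pair(); co <- draw_other_pair()
    list(game_id = paste0("game", b),
         true_self = round(stats::runif(1, config$self_range[1], config$self_range[2]), 1),
         phase_specs = list(
           new_phase_spec("self_other", config$n_self_other, c_so[b],
                          so[1], so[2], config$other_sd),
           new_phase_spec("self_only", config$n_self_only, 1),
           new_phase_spec("control_other", config$n_control_other, c_co[b],
                          co[1], co[2], config$other_sd)))
  })
  sched <- structure(list(blocks = blocks,
                          other_change_trial = config$other_change_trial),
                     class = "ad_schedule")
  validate_schedule(sched)
  sched
}

#' Validate schedule invariants
#'
#' Checks the structural contract: 144 trials in the default geometry, a
#' block-constant self level, Self-only phases with full control and no other
#' levels, paired phases with control in \[0, 1\] and both other levels in
#' \[0, 100\].
#'
#' @param schedule an \code{"ad_schedule"}.
#' @return The schedule, invisibly; errors on violation.
#' @export
validate_schedule <- function(schedule) {
  if (!inherits(schedule, "ad_schedule")) stop("not an ad_schedule")
  for (blk in schedule$blocks) {
    check_range(blk$true_self, 0, 100, "true_self")
    labs <- vapply(blk$phase_specs, `[[`, "", "phase_label")
    if (!identical(labs, c("self_other", "self_only", "control_other")))
      stop("phases must be self_other, self_only, control_other in order")
    for (ph in blk$phase_specs) {
      if (ph$n_trials < 1) stop("phase must have at least one trial")
      if (ph$phase_label == "self_only") {
        if (ph$true_control != 1) stop("self_only phases must have true_control = 1")
      } else {
        check_range(ph$true_control, 0, 1, "true_control")
        check_range(ph$other_level_early, 0, 100, "other_level_early")
        check_range(ph$other_level_late, 0, 100, "other_level_late")
        if (ph$other_sd < 0) stop("other_sd must be >= 0")
      }
    }
  }
  invisible(schedule)
}

#' Total number of trials in a schedule
#' @param schedule an \code{"ad_schedule"}.
#' @return Integer trial count.
#' @export
n_trials <- function(schedule) {
  sum(vapply(schedule$blocks, function(b)
    sum(vapply(b$phase_specs, `[[`, 0, "n_trials")), 0))
}

#' @export
print.ad_schedule <- function(x, ...) {
  cat(sprintf("Task schedule: %d blocks, %d trials\n", length(x$blocks), n_trials(x)))
  for (b in x$blocks) {
    ph <- b$phase_specs
    cat(sprintf("  %s  self=%g | SO: n=%d c=%g other %g->%g | CO: n=%d c=%g other %g->%g\n",
                b$game_id, b$true_self,
                ph[[1]]$n_trials, ph[[1]]$true_control,
                ph[[1]]$other_level_early, ph[[1]]$other_level_late,
                ph[[3]]$n_trials, ph[[3]]$true_control,
                ph[[3]]$other_level_early, ph[[3]]$other_level_late))
  }
  invisible(x)
}

#' Read/write schedules as JSON
#'
#' @param schedule an \code{"ad_schedule"}.
#' @param path file path.
#' @return \code{write_schedule} returns the path invisibly;
#'   \code{read_schedule} returns the schedule.
#' @export
write_schedule <- function(schedule, path) {
  validate_schedule(schedule)
  jsonlite::write_json(unclass(schedule), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  raw$blocks <- lapply(raw$blocks, function(b) {
    b$phase_specs <- lapply(b$phase_specs, function(p) {
      p$other_level_early <- if (is.null(p$other_level_early)) NA_real_ else p$other_level_early
      p$other_level_late <- if (is.null(p$other_level_late)) NA_real_ else p$other_level_late
      p
    })
    b
  })
  sched <- structure(raw, class = "ad_schedule")
  validate_schedule(sched)
  sched
}

#' The package's canonical task schedule
#'
#' A fixed, pre-determined schedule (the same for every simulated
#' participant, as in a within-participant design) whose self, other and
#' control levels were chosen to decorrelate the quantities that must be
#' inferred: self levels span the scale and are crossed with both high and
#' low control levels across blocks, other levels jump by at least 20 points
#' at the unannounced mid-phase change, and instructed Self-Other control
#' levels differ from the Control-Other levels of the same block.
#'
#' @param other_sd trial-to-trial SD of the other's score.
#' @return An \code{"ad_schedule"}.
#' @export
default_schedule <- function(other_sd = 6.5) {
  spec <- list(
    ## game, self, SO control, SO other early/late, CO control, CO other early/late
    ## self x Control-Other control form a 2x2 crossing so that the
    ## feedback-difference-per-unit-self slope is identified at both self
    ## levels; Control-Other other levels are set so the mean normal-trial
    ## feedback implies the same mid-scale control signal in every block,
    ## decorrelating what normal trials alone reveal about control from the
    ## scheduled control level itself
    list("rockslide", 40, 0.20, 25, 55, 0.25, 47, 27),
    list("darts",     40, 0.80, 70, 40, 0.75, 60, 80),
    list("curling",   60, 0.35, 45, 75, 0.25, 53, 73),
    list("archery",   60, 0.65, 60, 30, 0.75, 40, 20))
  blocks <- lapply(spec, function(s)
    list(game_id = s[[1]], true_self = s[[2]],
         phase_specs = list(
           new_phase_spec("self_other", 16, s[[3]], s[[4]], s[[5]], other_sd),
           new_phase_spec("self_only", 4, 1),
           new_phase_spec("control_other", 16, s[[6]], s[[7]], s[[8]], other_sd))))
  sched <- structure(list(blocks = blocks, other_change_trial = 12),
                     class = "ad_schedule")
  validate_schedule(sched)
  sched
}
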