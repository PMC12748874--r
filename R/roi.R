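## ROI time-course GLM machinery: double-gamma HRF synthesis, epoching with
## cubic-spline upsampling, per-timepoint OLS, and the leave-one-out peak
## test. Inputs are already-extracted ROI time series; image-space
## preprocessing is out of scope.

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response peaking at \code{peak} s,
#' undershoot peaking at \code{undershoot} s, undershoot amplitude
#' \code{1/ratio}), normalised to a maximum of 1.
#'
#' @param t time in seconds (vector).
#' @param peak,undershoot,ratio shape parameters, in seconds / unitless.
#' @return HRF values at \code{t}.
#' @export
double_gamma_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  tt <- seq(0, 32, by = 0.01)
  hmax <- max(stats::dgamma(tt, shape = peak, rate = 1) -
                stats::dgamma(tt, shape = undershoot, rate = 1) / ratio)
  h / hmax
}

#' Attach synthetic scanner onsets to a trial table
#'
#' Places one outcome-phase event per trial on a regular grid, giving the
#' simulated session a time axis for BOLD synthesis and epoching.
#'
#' @param table a trial table.
#' @param spacing seconds between consecutive trial onsets.
#' @param start onset of the first trial in seconds.
#' @return The table with an \code{onset} column (per participant).
#' @export
attach_onsets <- function(table, spacing = 10, start = 4) {
  part <- if (is.null(table$participant)) rep(1L, nrow(table)) else table$participant
  table$onset <- NA_real_
  for (idx in split(seq_len(nrow(table)), part))
    table$onset[idx] <- start + (seq_along(idx) - 1) * spacing
  table
}

#' Event set and design terms for the ROI time-course GLMs
#'
#' Encodes the seven designs and their trial-selection rules:
#' \describe{
#'   \item{glm1}{next-trial control and control update; all Control-Other
#'     trials with a next rating.}
#'   \item{glm2}{the normal-minus-AD feedback difference split by switch
#'     direction, inverse self and the AD flag; Control-Other switch trials.}
#'   \item{glm3/glm4/glm5}{sPE and/or oPE; Self-Other normal trials.}
#'   \item{glm6}{total prediction error and (true) control; Self-Other normal
#'     trials.}
#'   \item{glm7}{feedback and trial-to-trial feedback change; normal trials
#'     following normal trials, both paired phases.}
#' }
#'
#' @param table a derived trial table for one participant with an
#'   \code{onset} column ([attach_onsets()]).
#' @param glm_id \code{"glm1"} ... \code{"glm7"}.
#' @return \code{data.frame} with \code{onset}, \code{duration} and one
#'   column per design term (unstandardized; [timepoint_glm()] z-scores).
#' @export
roi_design <- function(table, glm_id) {
  if (is.null(table$onset)) stop("table needs an 'onset' column; see attach_onsets()")
  if (is.null(table$tpe)) table <- derive_measures(table)
  co <- table$phase_label == "control_other"
  so <- table$phase_label == "self_other"
  d <- switch(glm_id,
    glm1 = {
      sel <- co & !is.na(table$next_control)
      data.frame(onset = table$onset[sel],
                 next_control = table$next_control[sel],
                 control_update = table$next_control[sel] -
                   table$control_rating[sel])
    },
    glm2 = {
      sel <- co & table$is_switch & !is.na(table$feedback_difference)
      data.frame(onset = table$onset[sel],
                 fd_ad_to_normal = table$fd_ad_to_normal[sel],
                 fd_normal_to_ad = table$fd_normal_to_ad[sel],
                 inverse_self = table$inverse_self[sel],
                 ad = as.numeric(table$is_ad[sel]))
    },
    glm3 = {
      sel <- so & !table$is_ad
      data.frame(onset = table$onset[sel], spe = table$spe[sel])
    },
    glm4 = {
      sel <- so & !table$is_ad
      data.frame(onset = table$onset[sel], ope = table$ope[sel])
    },
    glm5 = {
      sel <- so & !table$is_ad
      data.frame(onset = table$onset[sel], spe = table$spe[sel],
                 ope = table$ope[sel])
    },
    glm6 = {
      sel <- so & !table$is_ad
      data.frame(onset = table$onset[sel], tpe = table$tpe[sel],
                 control = table$true_control[sel])
    },
    glm7 = {
      sel <- (so | co) & !table$is_ad & table$prev_is_ad %in% FALSE &
        !is.na(table$feedback_change)
      data.frame(onset = table$onset[sel], feedback = table$feedback[sel],
                 feedback_change = table$feedback_change[sel])
    },
    stop("unknown glm_id; use \"glm1\"..\"glm7\""))
  d$duration <- 1
  d[, c("onset", "duration", setdiff(names(d), c("onset", "duration")))]
}

#' Synthesise an ROI BOLD time series with injected effects
#'
#' Builds, for each design term, a boxcar regressor from the (z-scored) event
#' values, convolves it with the double-gamma HRF, scales it by the injected
#' beta, sums terms, samples the result at the repetition time and adds white
#' noise. A linear system identity follows: with zero noise and a single
#' nonzero beta the epoch-averaged response is proportional to the HRF shape.
#'
#' @param events event \code{data.frame} from [roi_design()] (onset,
#'   duration, term columns).
#' @param betas named vector of injected effect sizes, keyed by design terms
#'   (unknown names are an error; omitted terms get 0).
#' @param tr repetition time in seconds.
#' @param noise_sd white-noise SD (signal units).
#' @param seed integer seed.
#' @param pad seconds of recording appended after the last onset.
#' @param hrf_args list of [double_gamma_hrf()] parameters.
#' @return List of class \code{"roi_signal"}: \code{time}, \code{signal},
#'   \code{tr}.
#' @export
synth_bold <- function(events, betas, tr = 1.36, noise_sd = 1, seed = 1L,
                       pad = 24, hrf_args = list()) {
  terms <- setdiff(names(events), c("onset", "duration"))
  unknown <- setdiff(names(betas), terms)
  if (length(unknown))
    stop("unknown beta term(s): ", paste(unknown, collapse = ", "))
  set.seed(as.integer(seed))
  dt <- 0.05
  total <- max(events$onset + events$duration) + pad
  fine_t <- seq(0, total, by = dt)
  x <- numeric(length(fine_t))
  for (tm in names(betas)) {
    z <- standardize(events[[tm]])
    for (i in seq_len(nrow(events))) {
      on <- events$onset[i]; off <- on + events$duration[i]
      sel <- fine_t >= on & fine_t < off
      x[sel] <- x[sel] + betas[[tm]] * z[i]
    }
  }
  h <- do.call(double_gamma_hrf, c(list(t = seq(0, 32, by = dt)), hrf_args))
  conv <- stats::convolve(x, rev(h), type = "open")[seq_along(fine_t)] * dt
  samp_t <- seq(0, total, by = tr)
  sig <- stats::approx(fine_t, conv, xout = samp_t, rule = 2)$y +
    stats::rnorm(length(samp_t), 0, noise_sd)
  structure(list(time = samp_t, signal = sig, tr = tr), class = "roi_signal")
}

#' Epoch a time series around events, with cubic-spline upsampling
#'
#' The series is normalised (mean 0, SD 1), upsampled by the given factor
#' with cubic-spline interpolation, and cut into fixed windows (default -2 s
#' to +15 s) around each onset. Events whose window is not fully covered by
#' the recording are dropped (counted in \code{n_dropped}).
#'
#' @param signal an \code{"roi_signal"}, or a numeric vector with \code{tr}
#'   supplied.
#' @param onsets event onsets in seconds (non-empty).
#' @param tr repetition time (ignored when \code{signal} is an
#'   \code{"roi_signal"}).
#' @param window two-element window in seconds relative to onset.
#' @param upsample upsampling factor.
#' @return List of class \code{"epoched_timecourse"}: \code{epochs} (events x
#'   timepoints matrix), \code{times} (window grid), \code{onsets} (kept),
#'   \code{n_dropped}.
#' @export
epoch_and_upsample <- function(signal, onsets, tr = 1.36, window = c(-2, 15),
                               upsample = 20) {
  if (inherits(signal, "roi_signal")) {
    tr <- signal$tr; t0 <- signal$time; y <- signal$signal
  } else {
    y <- as.numeric(signal); t0 <- (seq_along(y) - 1) * tr
  }
  if (length(onsets) == 0) stop("'onsets' must be non-empty")
  y <- standardize(y)
  fine_dt <- tr / upsample
  sf <- stats::splinefun(t0, y)
  rel <- seq(window[1], window[2], by = fine_dt)
  keep <- onsets + window[1] >= min(t0) & onsets + window[2] <= max(t0)
  kept <- onsets[keep]
  ep <- t(vapply(kept, function(on) sf(on + rel), numeric(length(rel))))
  structure(list(epochs = ep, times = rel, onsets = kept,
                 n_dropped = sum(!keep)), class = "epoched_timecourse")
}

#' Per-timepoint OLS over epochs
#'
#' Fits an ordinary least-squares GLM independently at every timepoint of the
#' epoch window, with a constant and z-scored parametric regressors, giving
#' one beta time course per term.
#'
#' @param epochs an \code{"epoched_timecourse"} whose rows correspond to the
#'   rows of \code{design}.
#' @param design \code{data.frame} of term values per event (onset/duration
#'   columns are ignored).
#' @return List of class \code{"beta_timecourse"}: \code{betas} (terms x
#'   timepoints, including the constant), \code{times}, \code{terms}.
#' @export
timepoint_glm <- function(epochs, design) {
  if (!inherits(epochs, "epoched_timecourse")) stop("'epochs' must be epoched")
  terms <- setdiff(names(design), c("onset", "duration"))
  n_ev <- nrow(epochs$epochs)
  if (nrow(design) != n_ev)
    stop("design rows (", nrow(design), ") != epochs (", n_ev, ")")
  if (n_ev < length(terms) + 3)
    stop("need at least n_terms + 3 events")
  X <- cbind(constant = 1,
             as.matrix(as.data.frame(lapply(design[terms], standardize))))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; involved terms: ", paste(bad, collapse = ", "))
  }
  B <- qr.coef(qr_x, epochs$epochs)
  structure(list(betas = B, times = epochs$times,
                 terms = colnames(X)), class = "beta_timecourse")
}

#' Leave-one-out peak test on beta time courses
#'
#' For each participant, the mean absolute beta time course of the remaining
#' participants is computed and its peak located within the test window
#' (default 4-10 s; flat time courses take the earliest window point, with a
#' warning). The held-out participant's beta at that unbiasedly selected time
#' is collected, and the collected values are tested against zero with a
#' two-tailed one-sample t-test.
#'
#' @param betas participants x timepoints matrix of beta time courses for one
#'   term (or a list of \code{"beta_timecourse"} objects plus \code{term}).
#' @param times timepoint grid in seconds.
#' @param window two-element test window in seconds.
#' @param term term name, when \code{betas} is a list of fits.
#' @return List of class \code{"loo_peak"}: \code{peak_times},
#'   \code{peak_betas}, \code{t}, \code{df}, \code{p}, \code{mean}.
#' @export
loo_peak_test <- function(betas, times = NULL, window = c(4, 10), term = NULL) {
  if (is.list(betas) && !is.matrix(betas)) {
    if (is.null(term)) stop("'term' is required with a list of fits")
    times <- betas[[1]]$times
    betas <- do.call(rbind, lapply(betas, function(b) b$betas[term, ]))
  }
  if (is.null(times)) stop("'times' is required")
  n <- nrow(betas)
  if (n < 3) stop("leave-one-out peak test needs at least 3 participants")
  win <- which(times >= window[1] & times <= window[2])
  if (!length(win)) stop("'window' lies outside the epoch")
  peak_t <- peak_b <- numeric(n)
  any_flat <- FALSE
  for (i in seq_len(n)) {
    m <- abs(colMeans(betas[-i, , drop = FALSE]))[win]
    if (max(m) - min(m) < .Machine$double.eps^0.5) {
      any_flat <- TRUE
      j <- 1L
    } else j <- which.max(m)
    peak_t[i] <- times[win[j]]
    peak_b[i] <- betas[i, win[j]]
  }
  if (any_flat)
    warning("flat mean time course: taking the earliest window point")
  tt <- stats::t.test(peak_b)
  structure(list(peak_times = peak_t, peak_betas = peak_b,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean = mean(peak_b)), class = "loo_peak")
}

#' @export
print.loo_peak <- function(x, ...) {
  cat(sprintf("LOO peak test: mean beta %.3f at %.1f-%.1f s peaks, t(%d) = %.2f, p = %.4g\n",
              x$mean, min(x$peak_times), max(x$peak_times), x$df, x$t, x$p))
  invisible(x)
}
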