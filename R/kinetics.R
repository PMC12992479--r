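#' Resample a trial onto normalized movement time
#'
#' Linearly interpolates the selected series onto \code{n} points evenly
#' spaced over \code{[onset, offset]} (normalized time 0..1). The first and
#' last resampled points equal the onset and offset samples exactly.
#'
#' @param samples data.frame of trial samples (\code{t} plus value columns).
#' @param onset,offset Sample indices bounding the movement.
#' @param n Number of output points (default 1000).
#' @param cols Columns to resample.
#' @return data.frame with \code{u} (normalized time) and resampled columns.
#' @export
resample_trajectory <- function(samples, onset, offset, n = 1000,
                                cols = c("x", "y", "fx", "fy")) {
  if (offset - onset + 1 < 2)
    stop("resampling error: fewer than 2 samples between onset and offset")
  i <- onset:offset
  t0 <- samples$t[i]
  u_in <- (t0 - t0[1]) / (t0[length(t0)] - t0[1])
  u <- seq(0, 1, length.out = n)
  out <- data.frame(u = u)
  for (cl in cols)
    out[[cl]] <- approx(u_in, samples[[cl]][i], xout = u, ties = "ordered")$y
  out
}

#' Landmark fractions of the movement
#'
#' Mean normalized position of the peak-velocity and ballistic-end events
#' within the movement, over a set of trials:
#' \code{(event - onset) / (offset - onset)}. In the emulated study these
#' land near 23\% and 69\% of the movement.
#'
#' @param events data.frame/data.table with columns \code{onset},
#'   \code{offset}, \code{peak_vel}, \code{ballistic_end} (one row per
#'   trial), e.g. a subset of an \code{\link{extract_measures}} table.
#' @return Named numeric vector \code{c(f_peak, f_ballistic)},
#'   0 < f_peak < f_ballistic <= 1.
#' @export
landmark_fractions <- function(events) {
  if (NROW(events) == 0) stop("landmark error: empty trial set")
  span <- events$offset - events$onset
  if (any(span <= 0)) stop("landmark error: invalid event ordering")
  f_peak <- mean((events$peak_vel - events$onset) / span)
  f_ball <- mean((events$ballistic_end - events$onset) / span)
  c(f_peak = f_peak, f_ballistic = f_ball)
}

#' Channel force profiles for the left hand
#'
#' For every force-channel catch trial, resamples the lateral force the
#' hand applied against the channel wall onto 1000 points of normalized
#' movement time. The applied force is the negative of the measured wall
#' reaction on the hand, projected on the lateral (counterclockwise-
#' positive) axis of the home-to-target line, so a counterclockwise push
#' is positive, matching the kinematic sign convention.
#'
#' @param exp A \code{bireach_experiment}.
#' @param measures Measure table from \code{\link{extract_measures}}
#'   (supplies the per-trial event indices); computed if missing.
#' @param n Number of resampled points.
#' @return data.table of class \code{channel_profiles}: one row per channel
#'   trial and resampled point, columns \code{trial_uid}, metadata,
#'   \code{u}, \code{force} (N).
#' @export
extract_channel_profiles <- function(exp, measures = NULL, n = 1000) {
  stopifnot(inherits(exp, "bireach_experiment"))
  ch_uid <- exp$trials[channel == TRUE, trial_uid]
  if (length(ch_uid) == 0) stop("kinetics error: no channel trials in experiment")
  if (is.null(measures)) measures <- extract_measures(exp, trial_uids = ch_uid)
  ev <- data.table::as.data.table(measures)[trial_uid %in% ch_uid,
    .(trial_uid, onset, offset)]
  info <- exp$trials[trial_uid %in% ch_uid,
                     .(trial_uid, participant, group, block, trial, target_deg)]
  sm <- exp$samples[trial_uid %in% ch_uid]
  sm <- ev[sm, on = "trial_uid"]
  sm <- info[, .(trial_uid, target_deg)][sm, on = "trial_uid"]
  prof <- sm[, {
    th <- target_deg[1] * pi / 180
    wx <- -sin(th); wy <- cos(th)
    applied <- -(fx * wx + fy * wy)
    rs <- resample_trajectory(data.frame(t = t, f = applied),
                              onset[1], offset[1], n = n, cols = "f")
    list(u = rs$u, force = rs$f)
  }, by = trial_uid]
  out <- info[prof, on = "trial_uid"]
  data.table::setattr(out, "class", c("channel_profiles", class(out)))
  out
}

#' Channel force at the movement landmarks
#'
#' Reads each trial's resampled 1000-point force profile at the landmark
#' fractions (peak velocity, ballistic end) and at movement end (fraction
#' 1.0), using index \code{round(f * (n - 1)) + 1}.
#'
#' @param profiles A \code{channel_profiles} table.
#' @param fractions Numeric \code{c(f_peak, f_ballistic)} in (0, 1].
#' @return data.table, one row per channel trial: metadata plus
#'   \code{f_peak}, \code{f_ballistic}, \code{f_end} forces (N).
#' @export
channel_forces_at_landmarks <- function(profiles, fractions) {
  if (any(fractions <= 0 | fractions > 1))
    stop("invalid parameter: landmark fractions must lie in (0, 1]")
  p <- data.table::as.data.table(profiles)
  n <- p[, .N, by = trial_uid]$N[1]
  idx <- round(c(fractions[1], fractions[2], 1) * (n - 1)) + 1
  res <- p[, .(f_peak = force[idx[1]], f_ballistic = force[idx[2]],
               f_end = force[idx[3]]), by = trial_uid]
  meta <- unique(p[, .(trial_uid, participant, group, block, trial)])
  meta[res, on = "trial_uid"]
}

#' Mean channel force profile by group and phase
#'
#' Pointwise mean and SD of the 1000-point applied-force profiles within
#' each group x phase cell (profiles averaged per trial first).
#'
#' @param profiles A \code{channel_profiles} table with a \code{phase}
#'   column (add one, e.g. early/late exposure, before calling).
#' @return data.table with columns \code{group}, \code{phase}, \code{u},
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
mean_force_profile <- function(profiles) {
  p <- data.table::as.data.table(profiles)
  if (!"phase" %in% names(p))
    stop("kinetics error: profiles need a phase column")
  if (nrow(p) == 0) stop("kinetics error: empty profile set")
  out <- p[, .(mean = mean(force),
               sd = if (data.table::uniqueN(trial_uid) > 1) sd(force) else 0,
               n = data.table::uniqueN(trial_uid)),
           by = .(group, phase, u)]
  out[]
}
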