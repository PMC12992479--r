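#' Movement onset and offset detection
#'
#' Threshold rule on the tangential speed profile: onset is the first
#' sample whose speed exceeds \code{threshold_fraction} of the peak speed
#' and stays above it for at least \code{min_duration}; offset is the last
#' sample of the last supra-threshold run.
#'
#' @param speed Non-negative tangential speed series.
#' @param dt Sample interval in seconds.
#' @param threshold_fraction Fraction of peak speed (default 0.05).
#' @param min_duration Minimum supra-threshold duration for onset, seconds
#'   (default 0.05).
#' @return List with integer \code{onset} and \code{offset} indices,
#'   \code{onset < offset}.
#' @export
detect_onset_offset <- function(speed, dt, threshold_fraction = 0.05,
                                min_duration = 0.05) {
  if (length(speed) == 0 || any(speed < 0))
    stop("detection error: speed series must be non-empty and non-negative")
  pk <- max(speed)
  if (pk <= 0) stop("detection error: all-zero speed series")
  thr <- threshold_fraction * pk
  above <- speed > thr
  if (!any(above)) stop("detection error: no supra-threshold samples")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  min_len <- max(1L, as.integer(ceiling(min_duration / dt)))
  ok <- which(r$values & r$lengths >= min_len)
  if (length(ok) == 0)
    stop("detection error: no supra-threshold run of at least min_duration")
  onset <- starts[ok[1]]
  runs <- which(r$values)
  offset <- ends[runs[length(runs)]]
  if (offset <= onset) stop("detection error: offset not after onset")
  list(onset = onset, offset = offset)
}

#' Index of peak tangential velocity
#'
#' Argmax of the speed series on \code{[onset, offset]}; ties broken to the
#' earliest sample.
#'
#' @param speed Tangential speed series.
#' @param onset,offset Window bounds (indices).
#' @return Integer index in \code{[onset, offset]}.
#' @export
find_peak_velocity <- function(speed, onset, offset) {
  stopifnot(onset >= 1, offset <= length(speed), onset < offset)
  onset + which.max(speed[onset:offset]) - 1L
}

#' End of the initial ballistic movement
#'
#' First sample after peak velocity that is a strict local minimum of speed
#' (the start of a secondary movement) or where speed has effectively
#' reached zero (<= \code{zero_fraction} of peak; a reversal), whichever
#' occurs first; \code{offset} if neither occurs.
#'
#' @param speed Tangential speed series.
#' @param peak_idx Peak-velocity index.
#' @param offset Movement offset index.
#' @param zero_fraction Zero-speed threshold as a fraction of peak speed.
#' @return Integer index in \code{(peak_idx, offset]}.
#' @export
find_ballistic_end <- function(speed, peak_idx, offset, zero_fraction = 0.01) {
  stopifnot(peak_idx < offset)
  thr <- zero_fraction * speed[peak_idx]
  for (j in (peak_idx + 1L):offset) {
    if (speed[j] <= thr) return(j)
    if (j > 1 && j < length(speed) &&
        speed[j] < speed[j - 1] && speed[j] < speed[j + 1]) return(j)
  }
  offset
}

#' Signed angular error of a point relative to the target direction
#'
#' Angle between the home-to-point vector and the home-to-target vector,
#' in degrees, counterclockwise-positive, in (-180, 180]. For the 90 and
#' 270 degree targets this makes deviations into polar quadrants 1 and 3
#' negative (clockwise).
#'
#' @param point,home,target Numeric length-2 coordinates (m).
#' @return Signed angle in degrees.
#' @export
signed_angular_error <- function(point, home, target) {
  vp <- point - home
  vt <- target - home
  if (all(vp == 0)) stop("undefined-angle error: point coincides with home")
  cross <- vt[1] * vp[2] - vt[2] * vp[1]
  dot <- sum(vt * vp)
  ang <- rad2deg(atan2(cross, dot))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Normalized root-mean-square trajectory error
#'
#' RMS of the perpendicular distances of the samples in
#' \code{[onset, offset]} from the straight home-to-target line, divided by
#' the movement length (by default the hand's traversed path length over
#' the same window; optionally the straight home-target distance).
#'
#' @param x,y Sample coordinates (m).
#' @param onset,offset Window indices.
#' @param home,target Length-2 coordinates.
#' @param denominator \code{"path"} (default) or \code{"straight"}.
#' @return Dimensionless RMSE, >= 0.
#' @export
compute_rmse <- function(x, y, onset, offset, home, target,
                         denominator = c("path", "straight")) {
  denominator <- match.arg(denominator)
  i <- onset:offset
  u <- target - home
  u <- u / sqrt(sum(u^2))
  dx <- x[i] - home[1]
  dy <- y[i] - home[2]
  perp <- u[1] * dy - u[2] * dx
  len <- if (denominator == "path") {
    sum(sqrt(diff(x[i])^2 + diff(y[i])^2))
  } else sqrt(sum((target - home)^2))
  if (len <= 0) stop("degenerate-trial error: zero movement length")
  sqrt(mean(perp^2)) / len
}

# signed lateral (perpendicular) displacement from the home->target line,
# counterclockwise-positive, meters
lateral_displacement <- function(px, py, home, target) {
  u <- target - home
  u <- u / sqrt(sum(u^2))
  u[1] * (py - home[2]) - u[2] * (px - home[1])
}

#' Reach events for one trial
#'
#' Convenience wrapper chaining onset/offset detection, peak-velocity
#' search and the ballistic-end rule on one sampled trajectory.
#'
#' @param vx,vy Velocity samples (m/s).
#' @param dt Sample interval (s).
#' @param ... Passed to \code{\link{detect_onset_offset}}.
#' @return List with \code{onset}, \code{offset}, \code{peak_vel},
#'   \code{ballistic_end} indices satisfying
#'   onset < peak_vel <= ballistic_end <= offset.
#' @export
reach_events <- function(vx, vy, dt, ...) {
  speed <- sqrt(vx^2 + vy^2)
  oo <- detect_onset_offset(speed, dt, ...)
  pk <- find_peak_velocity(speed, oo$onset, oo$offset)
  be <- find_ballistic_end(speed, pk, oo$offset)
  list(onset = oo$onset, offset = oo$offset, peak_vel = pk, ballistic_end = be)
}

#' Per-trial kinematic error measures
#'
#' Computes the four outcome measures for one trial: normalized RMSE over
#' \code{[onset, offset]}; initial directional error (IDE), the signed
#' angular error at peak tangential velocity; initial endpoint error (IEE),
#' the signed angular error at the end of the initial ballistic movement;
#' and final endpoint error (FEE), the signed lateral displacement (cm,
#' counterclockwise-positive) of the hand from the target line at movement
#' offset. When \code{use_cursor} is TRUE (a rotation-on right-hand
#' trial), RMSE, IDE and IEE are evaluated on the displayed (rotated)
#' cursor path -- the task frame in which adaptation reduces error; FEE
#' always uses hand coordinates.
#'
#' @param x,y,vx,vy Trajectory samples.
#' @param dt Sample interval (s).
#' @param home,target Length-2 coordinates.
#' @param use_cursor Evaluate IDE in cursor coordinates.
#' @param rotation_deg Clockwise cursor rotation applied this trial.
#' @param events Optional precomputed \code{\link{reach_events}} list.
#' @return One-row data.frame: \code{rmse}, \code{ide_deg}, \code{iee_deg},
#'   \code{fee_cm}, plus the four event indices.
#' @export
compute_measures <- function(x, y, vx, vy, dt, home, target,
                             use_cursor = FALSE, rotation_deg = 0,
                             events = NULL) {
  if (is.null(events)) events <- reach_events(vx, vy, dt)
  cx <- x; cy <- y
  if (use_cursor && rotation_deg != 0) {
    th <- deg2rad(rotation_deg) # clockwise rotation about home
    dx <- x - home[1]; dy <- y - home[2]
    cx <- home[1] + cos(th) * dx + sin(th) * dy
    cy <- home[2] - sin(th) * dx + cos(th) * dy
  }
  pk <- events$peak_vel
  ide <- signed_angular_error(c(cx[pk], cy[pk]), home, target)
  be <- events$ballistic_end
  iee <- signed_angular_error(c(cx[be], cy[be]), home, target)
  off <- events$offset
  fee <- 100 * lateral_displacement(x[off], y[off], home, target)
  rmse <- compute_rmse(cx, cy, events$onset, events$offset, home, target)
  data.frame(rmse = rmse, ide_deg = ide, iee_deg = iee, fee_cm = fee,
             onset = events$onset, offset = events$offset,
             peak_vel = events$peak_vel, ballistic_end = events$ballistic_end)
}

#' Extract the per-trial measure table from a simulated experiment
#'
#' Applies \code{\link{compute_measures}} to every hand-trial. IDE for the
#' right hand is evaluated on the cursor during rotation-on trials (the
#' error the participant sees); all other measures, and the left hand
#' throughout, use hand coordinates.
#'
#' @param exp A \code{bireach_experiment}.
#' @param trial_uids Optional subset of trials to process.
#' @param engine \code{"cpp"} (default, fast batch path) or \code{"r"}
#'   (per-trial reference implementation); both give identical results.
#' @return data.table: trial metadata plus \code{rmse}, \code{ide_deg},
#'   \code{iee_deg}, \code{fee_cm} and event indices, of class
#'   \code{reach_measures}.
#' @export
extract_measures <- function(exp, trial_uids = NULL, engine = c("cpp", "r")) {
  stopifnot(inherits(exp, "bireach_experiment"))
  engine <- match.arg(engine)
  cfg <- exp$config
  dt_s <- cfg$record_dt
  dist <- cfg$reach_distance
  rot <- cfg$rotation_deg
  trials <- exp$trials
  if (!is.null(trial_uids)) trials <- trials[trial_uid %in% trial_uids]
  sm <- exp$samples[trial_uid %in% trials$trial_uid]
  data.table::setkey(sm, trial_uid)
  if (engine == "cpp") {
    cnt <- sm[, .N, by = trial_uid]
    tr <- trials[cnt, on = "trial_uid"] # row order matches sample blocks
    start <- cumsum(c(1L, head(cnt$N, -1L)))
    th <- deg2rad(tr$target_deg)
    mm <- trial_measures_cpp(sm$x, sm$y, sm$vx, sm$vy,
                             start, cnt$N,
                             dist * cos(th), dist * sin(th),
                             tr$rotation_on, rot, dt_s,
                             0.05, 0.05, 0.01)
    res <- data.table::as.data.table(mm)
    res[, trial_uid := cnt$trial_uid]
    if (anyNA(res$rmse))
      warning("measure extraction failed (event detection) on ",
              sum(is.na(res$rmse)), " trial(s); rows set to NA")
  } else {
    info <- trials[, .(trial_uid, target_deg, rotation_on)]
    smj <- info[sm, on = "trial_uid"]
    res <- smj[, {
      tg <- dist * c(cos(target_deg[1] * pi / 180), sin(target_deg[1] * pi / 180))
      compute_measures(x, y, vx, vy, dt_s, home = c(0, 0), target = tg,
                       use_cursor = rotation_on[1], rotation_deg = rot)
    }, by = trial_uid]
  }
  out <- trials[res, on = "trial_uid"]
  data.table::setattr(out, "class", c("reach_measures", class(out)))
  out
}

#' Baseline-correct a measure table
#'
#' Subtracts, per participant and measure, the mean of that participant's
#' baseline block: the kinesthetic baseline (KBL) for the left hand, the
#' visual baseline (VBL) for the right hand. Corrected columns get the
#' suffix \code{_bc}; the corrected baseline-block mean is exactly zero.
#'
#' @param measures A table from \code{\link{extract_measures}}.
#' @param cols Measure columns to correct.
#' @return The table with \code{<col>_bc} columns added.
#' @export
baseline_correct <- function(measures,
                             cols = c("rmse", "ide_deg", "iee_deg", "fee_cm")) {
  m <- data.table::as.data.table(measures)
  m[, baseline_block := ifelse(hand == "L", "KBL", "VBL")]
  for (cl in cols) {
    bl <- m[block == baseline_block,
            .(.bl_mean = mean(get(cl))), by = .(participant, hand)]
    if (any(!unique(m[, .(participant, hand)])$participant %in% bl$participant))
      stop("missing-baseline error: a participant lacks baseline-block trials")
    m <- bl[m, on = c("participant", "hand")]
    if (anyNA(m$.bl_mean))
      stop("missing-baseline error: baseline block absent for some participant/hand")
    m[, (paste0(cl, "_bc")) := get(cl) - .bl_mean]
    m[, .bl_mean := NULL]
  }
  m[, baseline_block := NULL]
  data.table::setattr(m, "class", c("reach_measures", "data.table", "data.frame"))
  m
}

#' Bin trials and extract analysis phases
#'
#' Bins trials within each block into consecutive groups of
#' \code{bin_size} (figure-style bin means) and labels the analysis
#' phases: \code{early_exp} (first 30 EXP trials), \code{late_exp}
#' (last 30 EXP trials), and \code{post} (first 30 POST trials, the
#' aftereffect window).
#'
#' @param measures A measure table (baseline-corrected or raw).
#' @param bin_size Trials per bin (default 10).
#' @param phase_width Trials per analysis phase (default 30).
#' @return List with \code{bins} (per-bin means of every numeric measure
#'   column by participant, hand, block, bin) and \code{phases} (the
#'   measure table restricted to the three phases, with a \code{phase}
#'   column).
#' @export
bin_and_phase <- function(measures, bin_size = 10, phase_width = 30) {
  m <- data.table::as.data.table(measures)
  if (min(m[, .N, by = .(participant, hand, block)]$N) < bin_size)
    stop("binning error: a block is shorter than one bin")
  mcols <- intersect(c("rmse", "ide_deg", "iee_deg", "fee_cm",
                       paste0(c("rmse", "ide_deg", "iee_deg", "fee_cm"), "_bc")),
                     names(m))
  m[, bin := (trial - 1L) %/% bin_size + 1L]
  bins <- m[, lapply(.SD, mean), .SDcols = mcols,
            by = .(group, participant, hand, block, bin)]
  nexp <- max(m[block == "EXP", trial])
  phases <- data.table::rbindlist(list(
    m[block == "EXP" & trial <= phase_width][, phase := "early_exp"],
    m[block == "EXP" & trial > nexp - phase_width][, phase := "late_exp"],
    m[block == "POST" & trial <= phase_width][, phase := "post"]
  ), use.names = TRUE)
  list(bins = bins[], phases = phases[])
}
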