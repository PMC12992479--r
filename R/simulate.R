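#' @useDynLib bireach, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats rnorm approx coef lm nls optimize pf pt ptukey qf sd var
#'   aggregate anova as.formula complete.cases median predict quantile setNames
#' @importFrom utils head tail write.csv read.csv
NULL

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi
dir_vec <- function(deg) c(cos(deg2rad(deg)), sin(deg2rad(deg)))

#' Minimum-jerk reference trajectory
#'
#' One-dimensional minimum-jerk position and speed profile along the reach
#' axis: \eqn{s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5}, \eqn{\tau = t/T}.
#' Peak speed is \eqn{1.875\, d/T} at \eqn{t = T/2}.
#'
#' @param distance Reach amplitude in meters.
#' @param duration Movement duration in seconds.
#' @param dt Sample interval in seconds.
#' @return A data.frame with columns \code{t}, \code{position}, \code{speed}.
#' @export
min_jerk_reference <- function(distance, duration, dt) {
  if (distance <= 0 || duration <= 0 || dt <= 0)
    stop("invalid parameter: distance, duration and dt must be > 0")
  if (dt >= duration)
    stop("invalid parameter: dt must be smaller than duration")
  t <- seq(0, duration, by = dt)
  if (t[length(t)] < duration) t <- c(t, duration)
  tau <- t / duration
  pos <- distance * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  spd <- distance * (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / duration
  data.frame(t = t, position = pos, speed = spd)
}

#' Clockwise cursor rotation
#'
#' Maps a hand displacement (relative to the home position) to the displayed
#' cursor displacement under a clockwise visuomotor rotation about home.
#'
#' @param hand_displacement Numeric length-2 vector (m), hand minus home.
#' @param rotation_deg_cw Rotation in degrees, clockwise-positive.
#' @return Numeric length-2 cursor displacement; same norm as the input.
#' @examples
#' apply_rotation(c(0, 0.10), 45)  # c(0.0707, 0.0707)
#' @export
apply_rotation <- function(hand_displacement, rotation_deg_cw) {
  if (!is.finite(rotation_deg_cw)) stop("invalid parameter: rotation must be finite")
  th <- deg2rad(rotation_deg_cw)
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2) # clockwise
  as.numeric(R %*% hand_displacement)
}

#' Velocity-dependent curl-field force
#'
#' Force orthogonal to the instantaneous hand velocity with magnitude
#' \code{gain} newtons per m/s of speed. \code{"CW"} rotates the velocity
#' vector 90 degrees clockwise (for a forward reach the force pushes
#' rightward), \code{"CCW"} the opposite.
#'
#' @param velocity Numeric length-2 velocity (m/s).
#' @param gain Field gain in N.s/m, >= 0.
#' @param sense \code{"CW"} or \code{"CCW"}.
#' @return Numeric length-2 force (N), orthogonal to \code{velocity}.
#' @export
curl_force <- function(velocity, gain, sense = c("CW", "CCW")) {
  sense <- match.arg(sense)
  if (gain < 0) stop("invalid parameter: gain must be >= 0")
  s <- if (sense == "CW") 1 else -1
  s * gain * c(velocity[2], -velocity[1])
}

#' Force-channel wall force
#'
#' Lateral restoring force of the virtual spring-damper channel. Inside the
#' channel (|lateral position| <= half-width) the force is zero; outside,
#' the wall applies \code{ramp_factor * (stiffness * penetration +
#' damping * lateral velocity)} directed toward the channel centerline.
#'
#' @param lateral_pos Lateral position (m), signed, 0 on the centerline.
#'   Vectorized.
#' @param lateral_vel Lateral velocity (m/s), recycled to match.
#' @param channel List with \code{stiffness} (N/m), \code{half_width} (m),
#'   \code{damping} (N.s/m).
#' @param ramp_factor Channel engagement in \[0, 1\] (ramped up during the
#'   inter-trial hold; fully on before movement onset).
#' @return Signed lateral force (N); negative for positive penetration.
#' @export
channel_wall_force <- function(lateral_pos, lateral_vel = 0,
                               channel = reach_config()$channel,
                               ramp_factor = 1) {
  if (channel$stiffness < 0 || channel$damping < 0)
    stop("invalid parameter: stiffness and damping must be >= 0")
  if (any(ramp_factor < 0 | ramp_factor > 1))
    stop("invalid parameter: ramp_factor must lie in [0, 1]")
  lateral_vel <- rep_len(lateral_vel, length(lateral_pos))
  pen <- pmax(abs(lateral_pos) - channel$half_width, 0)
  out <- numeric(length(lateral_pos))
  idx <- pen > 0
  out[idx] <- -ramp_factor * (channel$stiffness * pen[idx] * sign(lateral_pos[idx]) +
                              channel$damping * lateral_vel[idx])
  out
}

#' Single-rate state-space adaptation update
#'
#' Trial-by-trial linear learner \eqn{x' = a x + b e} with retention
#' \eqn{a} and learning rate \eqn{b} applied to the experienced error
#' \eqn{e}. For a constant error the fixed point is \eqn{b e / (1 - a)}
#' (when \eqn{a < 1}).
#'
#' @param estimate Current internal estimate (degrees for the rotation
#'   learner, compensation fraction for the curl learner).
#' @param error Experienced error on this trial, same units.
#' @param retention Retention factor \eqn{a} in \[0, 1\].
#' @param rate Learning rate \eqn{b} in \[0, 1\].
#' @return Updated estimate.
#' @export
update_adaptation <- function(estimate, error, retention, rate) {
  if (retention < 0 || retention > 1 || rate < 0 || rate > 1)
    stop("invalid parameter: retention and rate must lie in [0, 1]")
  retention * estimate + rate * error
}

#' Interlimb crosstalk aim bias
#'
#' Left-hand aim bias (degrees, counterclockwise-positive) induced by the
#' right hand's adaptation states: \code{kappa_rot * rot_estimate +
#' kappa_dyn * dyn_estimate * bias_scale_dyn}. Zero when both states are
#' zero; linear in each state.
#'
#' @param rot_estimate Right-hand rotation estimate, degrees.
#' @param dyn_estimate Right-hand curl compensation fraction.
#' @param kappa_rot,kappa_dyn Crosstalk gains, >= 0.
#' @param bias_scale_dyn Degrees of bias at full curl compensation.
#' @return Aim bias in degrees, counterclockwise-positive.
#' @export
crosstalk_aim_bias <- function(rot_estimate, dyn_estimate,
                               kappa_rot, kappa_dyn, bias_scale_dyn = 15) {
  if (kappa_rot < 0 || kappa_dyn < 0)
    stop("invalid parameter: crosstalk gains must be >= 0")
  kappa_rot * rot_estimate + kappa_dyn * dyn_estimate * bias_scale_dyn
}

# Closed-form per-trial adaptation states for one group across the whole
# session. The learner update after each trial is x' = a x + b (P - x) with
# P the perturbation magnitude currently on (rotation degrees, or 1 for the
# normalized curl learner); baseline blocks leave x = 0, the post block
# decays it. Returns the PRE-trial state for overall trials 1..N.
adaptation_series <- function(cfg, group) {
  n <- sum(cfg$blocks)
  nb <- cumsum(cfg$blocks)
  exp_idx <- (nb[["KBL"]] + 1):nb[["EXP"]]
  post_idx <- if (cfg$blocks[["POST"]] > 0) (nb[["EXP"]] + 1):nb[["POST"]] else integer(0)

  one <- function(a, b, P, on) {
    x <- numeric(n)
    if (!on || P == 0) return(x)
    rho <- a - b
    xinf <- b * P / (1 - rho)
    j <- seq_along(exp_idx)
    x[exp_idx] <- xinf * (1 - rho^(j - 1))
    if (length(post_idx)) {
      x_end <- xinf * (1 - rho^length(exp_idx)) # state after last EXP update
      x[post_idx] <- x_end * rho^(seq_along(post_idx) - 1)
    }
    x
  }
  ad <- cfg$adaptation
  list(
    rot = one(ad$retention_rot, ad$rate_rot, cfg$rotation_deg,
              group %in% c("visuomotor", "combined")),
    dyn = one(ad$retention_dyn, ad$rate_dyn, 1,
              group %in% c("dynamic", "combined"))
  )
}

block_levels <- c("VBL", "KBL", "EXP", "POST")

#' Simulate a single reach
#'
#' Runs the closed-loop point-mass controller for one trial: a PD
#' controller (defaults kp = 800 N/m, kd = 40 N.s/m, mass 1 kg) tracks a
#' minimum-jerk reference aimed at the target direction plus any aim
#' deviation, with optional curl field, feedforward curl compensation,
#' and force channel. With noise off and no perturbation the hand path is
#' straight to the target.
#'
#' @param cfg A \code{\link{reach_config}}.
#' @param rot_estimate Right-hand internal rotation estimate (degrees); the
#'   hand aims this many degrees counterclockwise of the target.
#' @param dyn_estimate Curl compensation fraction; scales a feedforward
#'   force opposing the expected field.
#' @param aim_bias_deg Additional aim deviation (degrees, CCW-positive),
#'   e.g. interlimb crosstalk for the left hand.
#' @param target_deg Target direction (degrees).
#' @param rotation_on Whether the cursor rotation is applied this trial.
#' @param curl_on Whether the curl field is applied this trial.
#' @param channel Whether the force channel is engaged this trial.
#' @param duration Intended movement duration (s).
#' @param noise Draw aim/endpoint/sensor noise (uses the session RNG).
#' @return An object of class \code{reach_trial}: list with \code{samples}
#'   (data.frame \code{t, x, y, vx, vy, fx, fy}; \code{fx, fy} is the
#'   measured environment force on the hand), \code{target_deg},
#'   \code{target} (coordinates), \code{rotation_deg} (applied cursor
#'   rotation, 0 if off), \code{movement_time}, \code{timing_class}.
#' @export
simulate_trial <- function(cfg = reach_config(),
                           rot_estimate = 0, dyn_estimate = 0,
                           aim_bias_deg = 0, target_deg = 90,
                           rotation_on = FALSE, curl_on = FALSE,
                           channel = FALSE,
                           duration = cfg$duration_mean,
                           noise = FALSE) {
  validate_config(cfg)
  sgn <- if (cfg$curl_sense == "CW") 1 else -1
  aim <- target_deg + rot_estimate + aim_bias_deg
  if (noise) aim <- aim + rnorm(1, 0, cfg$noise$aim_sd_deg_vision)
  goal <- cfg$reach_distance * dir_vec(aim)
  if (noise) goal <- goal + rnorm(2, 0, cfg$noise$endpoint_sd_m_vision)
  res <- simulate_trials_cpp(
    duration = duration, goal_x = goal[1], goal_y = goal[2],
    field_gain = if (curl_on) sgn * cfg$curl_gain else 0,
    comp_gain = sgn * dyn_estimate * cfg$curl_gain,
    channel_on = channel, chan_dir_rad = deg2rad(target_deg),
    dt = cfg$dt, settle = cfg$settle_time,
    kp = cfg$controller$kp, kd = cfg$controller$kd, mass = cfg$controller$mass,
    chan_k = cfg$channel$stiffness, chan_b = cfg$channel$damping,
    chan_halfw = cfg$channel$half_width, chan_ramp = 1,
    record_every = max(1L, as.integer(round(cfg$record_dt / cfg$dt))))
  s <- as.data.frame(res$samples)
  names(s) <- c("t", "x", "y", "vx", "vy", "fx", "fy")
  if (noise && cfg$noise$sensor_sd_N > 0) {
    s$fx <- s$fx + rnorm(nrow(s), 0, cfg$noise$sensor_sd_N)
    s$fy <- s$fy + rnorm(nrow(s), 0, cfg$noise$sensor_sd_N)
  }
  mt <- res$movement_time[1]
  out <- list(samples = s, target_deg = target_deg,
              target = cfg$reach_distance * dir_vec(target_deg),
              home = c(0, 0),
              rotation_deg = if (rotation_on) cfg$rotation_deg else 0,
              movement_time = mt,
              timing_class = timing_class(mt, cfg$movement_window))
  class(out) <- "reach_trial"
  out
}

timing_class <- function(mt, window) {
  ifelse(mt < window[1], "short", ifelse(mt > window[2], "long", "ideal"))
}

#' Generate a full synthetic experiment
#'
#' Simulates every trial of every participant: for each participant,
#' VBL/KBL/EXP/POST blocks of bimanual reaches with pseudorandom,
#' 50/50-balanced forward/backward targets (both hands matched), the
#' group's right-hand perturbation during EXP, single-rate state-space
#' adaptation of the right hand, interlimb crosstalk biasing the left
#' hand's aim, and force channels on a fixed proportion of left-hand
#' trials per block. Fully reproducible from \code{seed}.
#'
#' @param cfg A \code{\link{reach_config}}.
#' @param seed Integer RNG seed.
#' @param noise Logical; set \code{FALSE} for deterministic trials.
#' @return Object of class \code{bireach_experiment}: list with
#'   \code{trials} (per-trial metadata, one row per participant x block x
#'   trial x hand), \code{samples} (long table of recorded samples keyed by
#'   \code{trial_uid}), \code{config}, \code{seed}.
#' @export
generate_experiment <- function(cfg = reach_config(), seed = 1, noise = TRUE) {
  validate_config(cfg)
  set.seed(as.integer(seed))
  npp <- cfg$participants_per_group
  nblk <- cfg$blocks[block_levels]
  ntr <- sum(nblk)
  sgn <- if (cfg$curl_sense == "CW") 1 else -1

  meta_list <- vector("list", length(cfg$groups) * npp)
  li <- 0
  for (g in cfg$groups) {
    st <- adaptation_series(cfg, g)
    bias <- crosstalk_aim_bias(st$rot, st$dyn,
                               cfg$crosstalk$kappa_rot, cfg$crosstalk$kappa_dyn,
                               cfg$crosstalk$bias_scale_dyn)
    for (p in seq_len(npp)) {
      pid <- sprintf("%s_%02d", g, p)
      targets <- integer(0)
      chan <- logical(0)
      for (b in block_levels) {
        nb <- nblk[[b]]
        half <- nb %/% 2
        tg <- c(rep(cfg$target_angles[1], half),
                rep(cfg$target_angles[2], nb - half))
        targets <- c(targets, sample(tg))
        nchan <- round(cfg$channel_fraction * nb)
        ch <- rep(FALSE, nb)
        if (nchan > 0) ch[sample.int(nb, nchan)] <- TRUE
        chan <- c(chan, ch)
      }
      block <- rep(block_levels, times = nblk)
      trial <- unlist(lapply(nblk, seq_len), use.names = FALSE)
      exp_on <- block == "EXP"
      rot_on <- exp_on & g %in% c("visuomotor", "combined")
      fld_on <- exp_on & g %in% c("dynamic", "combined")
      meta <- data.table::data.table(
        participant = pid, group = g,
        block = rep(block, 2), trial = rep(trial, 2),
        trial_overall = rep(seq_len(ntr), 2),
        hand = rep(c("R", "L"), each = ntr),
        target_deg = rep(targets, 2),
        channel = c(rep(FALSE, ntr), chan),
        rotation_on = c(rot_on, rep(FALSE, ntr)),
        field_on = c(fld_on, rep(FALSE, ntr)),
        rot_estimate = rep(st$rot, 2),
        dyn_estimate = rep(st$dyn, 2),
        aim_bias = c(rep(0, ntr), bias))
      li <- li + 1
      meta_list[[li]] <- meta
    }
  }
  trials <- data.table::rbindlist(meta_list)
  trials[, trial_uid := .I]

  n <- nrow(trials)
  left <- trials$hand == "L"
  vision <- !left | trials$block == "VBL" # left loses the cursor after VBL
  aim_sd <- ifelse(vision, cfg$noise$aim_sd_deg_vision, cfg$noise$aim_sd_deg_novision)
  end_sd <- ifelse(vision, cfg$noise$endpoint_sd_m_vision, cfg$noise$endpoint_sd_m_novision)

  aim <- trials$target_deg + ifelse(left, trials$aim_bias, trials$rot_estimate)
  if (noise) aim <- aim + rnorm(n, 0, aim_sd)
  goal_x <- cfg$reach_distance * cos(deg2rad(aim))
  goal_y <- cfg$reach_distance * sin(deg2rad(aim))
  if (noise) {
    goal_x <- goal_x + rnorm(n, 0, end_sd)
    goal_y <- goal_y + rnorm(n, 0, end_sd)
  }
  duration <- rep(cfg$duration_mean, n)
  if (noise && cfg$duration_sd > 0)
    duration <- pmin(pmax(rnorm(n, cfg$duration_mean, cfg$duration_sd),
                          cfg$movement_window[1]), cfg$movement_window[2])

  res <- simulate_trials_cpp(
    duration = duration, goal_x = goal_x, goal_y = goal_y,
    field_gain = ifelse(trials$field_on, sgn * cfg$curl_gain, 0),
    comp_gain = ifelse(left, 0, sgn * trials$dyn_estimate * cfg$curl_gain),
    channel_on = trials$channel, chan_dir_rad = deg2rad(trials$target_deg),
    dt = cfg$dt, settle = cfg$settle_time,
    kp = cfg$controller$kp, kd = cfg$controller$kd, mass = cfg$controller$mass,
    chan_k = cfg$channel$stiffness, chan_b = cfg$channel$damping,
    chan_halfw = cfg$channel$half_width, chan_ramp = 1,
    record_every = max(1L, as.integer(round(cfg$record_dt / cfg$dt))))

  samples <- data.table::as.data.table(res$samples)
  data.table::setnames(samples, c("t", "x", "y", "vx", "vy", "fx", "fy"))
  samples[, trial_uid := res$trial]
  if (noise && cfg$noise$sensor_sd_N > 0) {
    samples[, fx := fx + rnorm(.N, 0, cfg$noise$sensor_sd_N)]
    samples[, fy := fy + rnorm(.N, 0, cfg$noise$sensor_sd_N)]
  }
  data.table::setcolorder(samples, c("trial_uid", "t", "x", "y", "vx", "vy", "fx", "fy"))
  data.table::setkey(samples, trial_uid)

  trials[, movement_time := res$movement_time]
  trials[, timing_class := timing_class(movement_time, cfg$movement_window)]

  out <- list(trials = trials, samples = samples, config = cfg, seed = seed)
  class(out) <- "bireach_experiment"
  out
}

#' @export
print.bireach_experiment <- function(x, ...) {
  cat("Simulated bimanual reaching experiment\n")
  cat(sprintf("  seed %s; %d participants (%s), %d hand-trials, %d samples\n",
              format(x$seed), length(unique(x$trials$participant)),
              paste(x$config$groups, collapse = ", "),
              nrow(x$trials), nrow(x$samples)))
  chp <- x$trials[hand == "L", mean(channel)]
  cat(sprintf("  left-hand channel trials: %.1f%%\n", 100 * chp))
  invisible(x)
}

#' @export
summary.bireach_experiment <- function(object, ...) {
  tc <- object$trials[, table(timing_class)]
  cat("Trial counts per participant and hand:\n")
  print(object$trials[, .N, by = .(participant, hand)][, table(N)])
  cat("Timing classes:\n")
  print(tc)
  invisible(object)
}

#' Write / read an experiment as plain CSV tables
#'
#' \code{write_experiment} writes \code{trials.csv} (per-trial metadata) and
#' \code{samples.csv} (long sample table with metadata columns joined);
#' \code{read_experiment} reconstructs the experiment object from such a
#' directory.
#'
#' @param exp A \code{bireach_experiment}.
#' @param dir Output directory (created if missing).
#' @return \code{write_experiment}: the directory, invisibly;
#'   \code{read_experiment}: a \code{bireach_experiment}.
#' @export
write_experiment <- function(exp, dir) {
  stopifnot(inherits(exp, "bireach_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(exp$trials, file.path(dir, "trials.csv"))
  key <- exp$trials[, .(trial_uid, participant_id = participant, group, block,
                        trial, hand, target_deg, channel)]
  full <- key[exp$samples, on = "trial_uid"]
  data.table::fwrite(full, file.path(dir, "samples.csv"))
  jsonlite::write_json(exp$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  tf <- file.path(dir, "trials.csv")
  sf <- file.path(dir, "samples.csv")
  if (!file.exists(tf) || !file.exists(sf))
    stop("user error: trials.csv / samples.csv not found in ", dir)
  trials <- data.table::fread(tf)
  samples <- data.table::fread(sf)
  samples <- samples[, .(trial_uid, t, x, y, vx, vy, fx, fy)]
  data.table::setkey(samples, trial_uid)
  cfgf <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfgf)) {
    raw <- jsonlite::read_json(cfgf, simplifyVector = TRUE)
    raw$blocks <- unlist(raw$blocks)
    cc <- reach_config()
    for (nm in intersect(names(raw), names(cc))) cc[[nm]] <- raw[[nm]]
    cc$participants_per_group <- as.integer(cc$participants_per_group)
    validate_config(cc)
    cc
  } else reach_config()
  out <- list(trials = trials, samples = samples, config = cfg, seed = NA)
  class(out) <- "bireach_experiment"
  out
}
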