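#' Experiment configuration
#'
#' Builds the configuration object describing one bimanual reaching
#' experiment: group roster, block schedule, task geometry, perturbation
#' mechanics, force-channel mechanics, the trial-by-trial adaptation model,
#' interlimb crosstalk gains, and noise levels. Defaults reproduce the study
#' design the package emulates: 4 groups x 15 participants, blocks of
#' 30 (visual baseline, VBL) / 30 (kinesthetic baseline, KBL) /
#' 250 (exposure, EXP) / 50 (post-exposure, POST) trials, 10 cm forward and
#' backward reaches, a 45 degree clockwise cursor rotation and/or a
#' 20 N.s/m curl field on the right hand during EXP, no left-hand cursor
#' from KBL onward, and force channels on 20\% of left-hand trials.
#'
#' @param participants_per_group Number of simulated participants per group.
#' @param blocks Named integer vector of block lengths, names
#'   \code{c("VBL","KBL","EXP","POST")}.
#' @param groups Character vector of groups to simulate; any subset of
#'   \code{c("control","visuomotor","dynamic","combined")}.
#' @param reach_distance Home-to-target distance in meters.
#' @param target_angles Target directions in degrees (polar,
#'   counterclockwise-positive); both hands always share the direction.
#' @param dt Integration time step in seconds.
#' @param record_dt Output sampling interval in seconds (samples are
#'   decimated from \code{dt} to \code{record_dt}).
#' @param settle_time Extra simulated time after the reference movement ends,
#'   in seconds, so terminal corrections play out.
#' @param movement_window Two timing bounds in seconds; movement times inside
#'   the window are classed \code{"ideal"}, below \code{"short"}, above
#'   \code{"long"}.
#' @param duration_mean,duration_sd Mean and SD (seconds) of the per-trial
#'   intended movement duration; draws are clipped to \code{movement_window}.
#' @param rotation_deg Clockwise cursor rotation applied to the right hand
#'   during EXP in the visuomotor and combined groups, degrees.
#' @param curl_gain Curl-field gain in N.s/m (force magnitude per m/s of hand
#'   speed), right hand during EXP in the dynamic and combined groups.
#' @param curl_sense Rotational sense of the curl field, \code{"CW"} or
#'   \code{"CCW"}.
#' @param channel List of force-channel parameters: \code{stiffness} (N/m),
#'   \code{half_width} (m), \code{damping} (N.s/m), \code{ramp_s} (s).
#' @param channel_fraction Proportion of left-hand trials per block that are
#'   force-channel catch trials.
#' @param adaptation List with single-rate state-space learner parameters
#'   \code{retention_rot}, \code{rate_rot}, \code{retention_dyn},
#'   \code{rate_dyn}, all in \[0, 1\].
#' @param crosstalk List with interlimb crosstalk gains \code{kappa_rot},
#'   \code{kappa_dyn} (dimensionless, >= 0) and \code{bias_scale_dyn}
#'   (degrees of left-hand aim bias at full curl compensation).
#' @param noise List of noise levels: \code{aim_sd_deg_vision},
#'   \code{aim_sd_deg_novision} (aim-direction SD, degrees),
#'   \code{endpoint_sd_m_vision}, \code{endpoint_sd_m_novision} (planned
#'   endpoint SD, meters), \code{sensor_sd_N} (force sensor SD, newtons).
#' @param controller List with point-mass controller parameters \code{kp}
#'   (N/m), \code{kd} (N.s/m), \code{mass} (kg).
#'
#' @return An object of class \code{reach_config} (a validated list).
#' @examples
#' cfg <- reach_config(participants_per_group = 2,
#'                     blocks = c(VBL = 4, KBL = 4, EXP = 10, POST = 4))
#' cfg
#' @export
reach_config <- function(participants_per_group = 15,
                         blocks = c(VBL = 30, KBL = 30, EXP = 250, POST = 50),
                         groups = c("control", "visuomotor", "dynamic", "combined"),
                         reach_distance = 0.10,
                         target_angles = c(90, 270),
                         dt = 0.001,
                         record_dt = 0.005,
                         settle_time = 0.30,
                         movement_window = c(0.300, 0.450),
                         duration_mean = 0.375,
                         duration_sd = 0.025,
                         rotation_deg = 45,
                         curl_gain = 20,
                         curl_sense = c("CW", "CCW"),
                         channel = list(stiffness = 2000, half_width = 0.000125,
                                        damping = 5, ramp_s = 1.5),
                         channel_fraction = 0.20,
                         adaptation = list(retention_rot = 0.995, rate_rot = 0.08,
                                           retention_dyn = 0.995, rate_dyn = 0.08),
                         crosstalk = list(kappa_rot = 0.15, kappa_dyn = 0.15,
                                          bias_scale_dyn = 15),
                         noise = list(aim_sd_deg_vision = 1.5,
                                      aim_sd_deg_novision = 2.5,
                                      endpoint_sd_m_vision = 0.002,
                                      endpoint_sd_m_novision = 0.004,
                                      sensor_sd_N = 0.1),
                         controller = list(kp = 800, kd = 40, mass = 1)) {
  curl_sense <- match.arg(curl_sense)
  cfg <- list(
    participants_per_group = as.integer(participants_per_group),
    blocks = blocks, groups = groups,
    reach_distance = reach_distance, target_angles = target_angles,
    dt = dt, record_dt = record_dt, settle_time = settle_time,
    movement_window = movement_window,
    duration_mean = duration_mean, duration_sd = duration_sd,
    rotation_deg = rotation_deg,
    curl_gain = curl_gain, curl_sense = curl_sense,
    channel = channel, channel_fraction = channel_fraction,
    adaptation = adaptation, crosstalk = crosstalk,
    noise = noise, controller = controller
  )
  class(cfg) <- "reach_config"
  validate_config(cfg)
  cfg
}

#' @rdname reach_config
#' @param x,object A \code{reach_config}.
#' @param ... Unused.
#' @export
print.reach_config <- function(x, ...) {
  cat("Bimanual reaching experiment configuration\n")
  cat(sprintf("  groups: %s (%d participants each)\n",
              paste(x$groups, collapse = ", "), x$participants_per_group))
  cat(sprintf("  blocks: VBL %d / KBL %d / EXP %d / POST %d trials\n",
              x$blocks[["VBL"]], x$blocks[["KBL"]], x$blocks[["EXP"]],
              x$blocks[["POST"]]))
  cat(sprintf("  reach: %.0f cm to %s deg; timing window %d-%d ms\n",
              x$reach_distance * 100,
              paste(x$target_angles, collapse = "/"),
              round(1000 * x$movement_window[1]),
              round(1000 * x$movement_window[2])))
  cat(sprintf("  perturbations: %.0f deg CW rotation, %.0f N.s/m curl (%s)\n",
              x$rotation_deg, x$curl_gain, x$curl_sense))
  cat(sprintf("  channel: %.0f N/m, half-width %.3g m, %.0f%% of left-hand trials\n",
              x$channel$stiffness, x$channel$half_width,
              100 * x$channel_fraction))
  invisible(x)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "reach_config"))
  if (cfg$participants_per_group < 1)
    stop("invalid parameter: participants_per_group must be >= 1")
  if (!all(c("VBL", "KBL", "EXP", "POST") %in% names(cfg$blocks)))
    stop("invalid parameter: blocks must be named VBL, KBL, EXP, POST")
  if (any(cfg$blocks <= 0))
    stop("invalid parameter: all block lengths must be > 0")
  if (cfg$reach_distance <= 0) stop("invalid parameter: reach_distance must be > 0")
  if (cfg$dt <= 0 || cfg$record_dt <= 0)
    stop("invalid parameter: dt and record_dt must be > 0")
  if (cfg$record_dt < cfg$dt)
    stop("invalid parameter: record_dt must be >= dt")
  if (cfg$channel_fraction < 0 || cfg$channel_fraction > 1)
    stop("invalid parameter: channel_fraction must lie in [0, 1]")
  ad <- cfg$adaptation
  if (any(unlist(ad[c("retention_rot", "retention_dyn")]) < 0) ||
      any(unlist(ad[c("retention_rot", "retention_dyn")]) > 1))
    stop("invalid parameter: retention must lie in [0, 1]")
  if (any(unlist(ad[c("rate_rot", "rate_dyn")]) < 0) ||
      any(unlist(ad[c("rate_rot", "rate_dyn")]) > 1))
    stop("invalid parameter: learning rate must lie in [0, 1]")
  if (cfg$channel$stiffness < 0 || cfg$channel$damping < 0)
    stop("invalid parameter: channel stiffness and damping must be >= 0")
  if (any(!cfg$groups %in% c("control", "visuomotor", "dynamic", "combined")))
    stop("invalid parameter: unknown group name")
  if (cfg$curl_gain < 0) stop("invalid parameter: curl_gain must be >= 0")
  invisible(cfg)
}

#' Turn all simulation noise off
#'
#' Returns a copy of the configuration with every noise source (aim,
#' endpoint, sensor, movement-duration jitter) set to zero, so trials are
#' fully deterministic given the adaptation state. Used for geometric checks.
#'
#' @param cfg A \code{reach_config}.
#' @return The modified \code{reach_config}.
#' @export
noise_off <- function(cfg) {
  stopifnot(inherits(cfg, "reach_config"))
  cfg$noise <- lapply(cfg$noise, function(z) 0)
  names(cfg$noise) <- c("aim_sd_deg_vision", "aim_sd_deg_novision",
                        "endpoint_sd_m_vision", "endpoint_sd_m_novision",
                        "sensor_sd_N")[seq_along(cfg$noise)]
  cfg$duration_sd <- 0
  cfg
}

#' Read a configuration from a YAML or JSON file
#'
#' Fields present in the file override the defaults of
#' \code{\link{reach_config}}; nested lists (\code{channel},
#' \code{adaptation}, \code{crosstalk}, \code{noise}, \code{controller}) are
#' merged element-wise.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{reach_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("user error: config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- reach_config()
  nested <- c("channel", "adaptation", "crosstalk", "noise", "controller")
  args <- list()
  for (nm in names(raw)) {
    if (!nm %in% names(base)) stop("user error: unknown config field: ", nm)
    if (nm %in% nested) {
      merged <- base[[nm]]
      merged[names(raw[[nm]])] <- raw[[nm]]
      args[[nm]] <- merged
    } else if (nm == "blocks") {
      args[[nm]] <- unlist(raw[[nm]])
    } else {
      args[[nm]] <- raw[[nm]]
    }
  }
  do.call(reach_config, args)
}
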