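#' Default analysis plan
#'
#' The battery of mixed-design ANOVAs the pipeline runs, mirroring the
#' structure of the emulated study's results: right-hand adaptation
#' (RMSE and IDE, early vs late exposure), right-hand aftereffects (RMSE,
#' late exposure vs first 30 post-exposure trials), left-hand interference
#' in all four kinematic measures, and the channel lateral force at the
#' three movement landmarks. The first-10-exposure-trials t test between
#' the visuomotor and dynamic groups is run separately.
#'
#' @return data.frame, one row per planned mixed ANOVA: \code{name},
#'   \code{hand}, \code{measure}, \code{phase_a}, \code{phase_b}.
#' @export
analysis_plan <- function() {
  data.frame(
    name = c("right_adaptation_rmse", "right_adaptation_ide",
             "right_aftereffect_rmse",
             "left_interference_rmse", "left_interference_ide",
             "left_interference_iee", "left_interference_fee",
             "kinetic_peak_velocity", "kinetic_ballistic_end",
             "kinetic_movement_end"),
    hand = c("R", "R", "R", "L", "L", "L", "L", "L", "L", "L"),
    measure = c("rmse_bc", "ide_deg_bc", "rmse_bc",
                "rmse_bc", "ide_deg_bc", "iee_deg_bc", "fee_cm_bc",
                "f_peak", "f_ballistic", "f_end"),
    phase_a = c("early_exp", "early_exp", "late_exp",
                "early_exp", "early_exp", "early_exp", "early_exp",
                "early_exp", "early_exp", "early_exp"),
    phase_b = c("late_exp", "late_exp", "post",
                "late_exp", "late_exp", "late_exp", "late_exp",
                "late_exp", "late_exp", "late_exp"),
    stringsAsFactors = FALSE)
}

subject_phase_means <- function(phases, hand_sel, measure, phase_a, phase_b) {
  p <- phases[hand == hand_sel & phase %in% c(phase_a, phase_b)]
  p[, .(value = mean(get(measure))), by = .(group, participant, phase)]
}

#' Run the full simulate-measure-analyze pipeline
#'
#' Generates a synthetic experiment, extracts and baseline-corrects the
#' kinematic measures, analyzes the channel trials, runs the planned
#' mixed-design ANOVA battery with simple-effects one-way ANOVAs and Tukey
#' HSD post-hocs (when the group effect or interaction is significant at
#' \code{alpha}), performs the first-10-exposure-trials t tests, and writes
#' all tables plus a manifest to \code{out_dir}. Deterministic given
#' \code{(cfg, seed)}.
#'
#' @param cfg A \code{\link{reach_config}}.
#' @param seed Integer seed.
#' @param out_dir Output directory (created). \code{NULL} skips writing.
#' @param write_samples Also write the (large) per-sample trial table.
#' @param alpha Significance level gating post-hoc tests.
#' @return Object of class \code{bireach_report}: list with
#'   \code{anovas} (named list of \code{anova_mixed}), \code{simple_effects},
#'   \code{posthoc}, \code{t_tests}, \code{landmarks}, \code{phases},
#'   \code{bins}, \code{force_profiles}, \code{manifest}.
#' @export
run_pipeline <- function(cfg = reach_config(), seed = 1, out_dir = NULL,
                         write_samples = FALSE, alpha = 0.05) {
  stage <- "simulate"
  res <- tryCatch({
    exp <- generate_experiment(cfg, seed = seed)

    stage <- "kinematics"
    meas <- extract_measures(exp)
    meas <- baseline_correct(meas)
    bp <- bin_and_phase(meas)
    phases <- bp$phases

    stage <- "kinetics"
    ev_left <- meas[hand == "L" & channel == FALSE & block == "EXP",
                    .(onset, offset, peak_vel, ballistic_end)]
    fracs <- landmark_fractions(ev_left)
    profiles <- extract_channel_profiles(exp, measures = meas)
    nexp <- cfg$blocks[["EXP"]]
    profiles[, phase := ifelse(block == "EXP" & trial <= 30, "early_exp",
                        ifelse(block == "EXP" & trial > nexp - 30, "late_exp", NA))]
    prof_phase <- profiles[!is.na(phase)]
    forces <- channel_forces_at_landmarks(prof_phase, fracs)
    forces[, phase := prof_phase[match(forces$trial_uid, prof_phase$trial_uid), phase]]
    force_profiles <- mean_force_profile(prof_phase)

    stage <- "stats"
    plan <- analysis_plan()
    anovas <- list(); simple <- list(); posthoc <- list()
    for (i in seq_len(nrow(plan))) {
      pl <- plan[i, ]
      cell <- if (startsWith(pl$measure, "f_")) {
        fo <- forces[phase %in% c(pl$phase_a, pl$phase_b)]
        fo[, .(value = mean(get(pl$measure))), by = .(group, participant, phase)]
      } else {
        subject_phase_means(phases, pl$hand, pl$measure, pl$phase_a, pl$phase_b)
      }
      cell <- cell[complete.cases(cell)]
      an <- mixed_anova(as.data.frame(cell), dv = "value",
                        between = "group", within = "phase",
                        id = "participant")
      anovas[[pl$name]] <- an
      sig <- an$table$p_hf[c(1, 3)] < alpha # group main effect or interaction
      if (any(sig)) {
        for (ph in unique(cell$phase)) {
          sub <- cell[phase == ph]
          ow <- one_way_anova(sub$value, sub$group)
          simple[[paste(pl$name, ph, sep = ".")]] <- ow
          if (ow$p < alpha) {
            mns <- tapply(sub$value, sub$group, mean)
            nn <- min(table(sub$group))
            posthoc[[paste(pl$name, ph, sep = ".")]] <-
              tukey_hsd(mns, ow$ss_error / ow$df_den, ow$df_den, nn)
          }
        }
      }
    }

    # right-hand first-10-EXP-trials comparison, visuomotor vs dynamic
    t_tests <- list()
    if (all(c("visuomotor", "dynamic") %in% cfg$groups)) {
      f10 <- meas[hand == "R" & block == "EXP" & trial <= 10]
      f10 <- f10[, .(rmse = mean(rmse_bc), ide = mean(ide_deg_bc),
                     iee = mean(iee_deg_bc)), by = .(group, participant)]
      for (mm in c("rmse", "ide", "iee")) {
        t_tests[[paste0("first10_", mm)]] <- independent_t_test(
          f10[group == "visuomotor"][[mm]], f10[group == "dynamic"][[mm]])
      }
    }

    manifest <- list(
      package_version = as.character(utils::packageVersion("bireach")),
      seed = seed,
      config_hash = config_hash(cfg),
      n_trials = nrow(exp$trials),
      n_samples = nrow(exp$samples),
      n_channel_trials = sum(exp$trials$channel),
      landmark_fractions = as.list(fracs),
      analyses = names(anovas))

    out <- list(anovas = anovas, simple_effects = simple, posthoc = posthoc,
                t_tests = t_tests,
                landmarks = fracs, phases = phases, bins = bp$bins,
                forces = forces, force_profiles = force_profiles,
                manifest = manifest, config = cfg, experiment = exp,
                measures = meas)
    class(out) <- "bireach_report"
    out
  }, error = function(e) {
    stop("pipeline error in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) write_report(res, out_dir, write_samples = write_samples)
  res
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a pipeline report to disk
#'
#' Emits TSV tables (ANOVAs, simple effects, post-hocs, t tests, phase
#' means, bin means, landmark forces, mean force profiles), a Markdown
#' summary and a JSON manifest.
#'
#' @param report A \code{bireach_report}.
#' @param out_dir Output directory.
#' @param write_samples Also write trial/sample CSVs of the experiment.
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(report, out_dir, write_samples = FALSE) {
  stopifnot(inherits(report, "bireach_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  an <- data.table::rbindlist(
    lapply(names(report$anovas),
           function(nm) cbind(analysis = nm, report$anovas[[nm]]$table)))
  wtsv(an, "anova_tables.tsv")
  if (length(report$simple_effects))
    wtsv(data.table::rbindlist(
      lapply(names(report$simple_effects),
             function(nm) cbind(analysis = nm, report$simple_effects[[nm]]))),
      "simple_effects.tsv")
  if (length(report$posthoc))
    wtsv(data.table::rbindlist(
      lapply(names(report$posthoc),
             function(nm) cbind(analysis = nm, report$posthoc[[nm]]))),
      "tukey_posthoc.tsv")
  if (length(report$t_tests))
    wtsv(data.frame(test = names(report$t_tests),
                    t = vapply(report$t_tests, `[[`, 0, "t"),
                    df = vapply(report$t_tests, `[[`, 0, "df"),
                    p = vapply(report$t_tests, `[[`, 0, "p")),
         "t_tests.tsv")
  wtsv(report$bins, "bin_means.tsv")
  wtsv(report$forces, "landmark_forces.tsv")
  wtsv(report$force_profiles, "mean_force_profiles.tsv")
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  md <- c("# Bimanual interference pipeline report", "",
          sprintf("- seed: %s", report$manifest$seed),
          sprintf("- config hash: %s", report$manifest$config_hash),
          sprintf("- trials: %d (%d channel)", report$manifest$n_trials,
                  report$manifest$n_channel_trials),
          sprintf("- landmark fractions: peak velocity %.3f, ballistic end %.3f",
                  report$landmarks[["f_peak"]], report$landmarks[["f_ballistic"]]),
          "", "## Mixed ANOVA p values (HF-corrected)", "")
  for (nm in names(report$anovas)) {
    tb <- report$anovas[[nm]]$table
    md <- c(md, sprintf("- %s: group p=%.3g, phase p=%.3g, interaction p=%.3g",
                        nm, tb$p_hf[1], tb$p_hf[2], tb$p_hf[3]))
  }
  writeLines(md, file.path(out_dir, "summary.md"))

  if (write_samples) write_experiment(report$experiment, out_dir)
  invisible(out_dir)
}

#' @export
print.bireach_report <- function(x, ...) {
  cat("Bimanual interference pipeline report\n")
  cat(sprintf("  seed %s, %d planned mixed ANOVAs, %d simple-effects tests, %d post-hoc tables\n",
              format(x$manifest$seed), length(x$anovas),
              length(x$simple_effects), length(x$posthoc)))
  cat(sprintf("  landmark fractions: f_peak=%.3f f_ballistic=%.3f\n",
              x$landmarks[["f_peak"]], x$landmarks[["f_ballistic"]]))
  for (nm in names(x$anovas)) {
    tb <- x$anovas[[nm]]$table
    cat(sprintf("  %-24s group F(%d,%d)=%.2f p=%.3g ges=%.2f\n", nm,
                tb$df_num[1], tb$df_den[1], tb$F[1], tb$p_hf[1], tb$ges[1]))
  }
  invisible(x)
}

#' Recover the channel stiffness from quasi-static wall presses
#'
#' Holds the simulated hand at several penetration depths beyond the
#' channel wall with zero lateral velocity and the ramp complete, records
#' the lateral restoring force, and returns the least-squares slope of
#' force on depth in N/cm. With the default channel this recovers
#' 20 N/cm.
#'
#' @param depths_cm Penetration depths in cm (>= 2 distinct values; >= 3
#'   recommended).
#' @param cfg A \code{\link{reach_config}} (supplies the channel).
#' @param ramp_factor Channel engagement in \[0, 1\].
#' @return List with \code{slope_N_per_cm}, \code{intercept_N} and the
#'   per-depth \code{forces_N}.
#' @export
recover_channel_stiffness <- function(depths_cm = c(0.25, 0.5, 1.0),
                                      cfg = reach_config(), ramp_factor = 1) {
  if (length(unique(depths_cm)) < 2)
    stop("design error: need at least 2 distinct penetration depths")
  lat <- cfg$channel$half_width + depths_cm / 100
  f <- abs(channel_wall_force(lat, 0, cfg$channel, ramp_factor))
  fit <- lm(f ~ depths_cm)
  list(slope_N_per_cm = unname(coef(fit)[2]),
       intercept_N = unname(coef(fit)[1]),
       forces_N = f)
}

#' Recover the adaptation model parameters from the exposure error curve
#'
#' Fits the single-rate state-space learner to the right-hand cursor IDE
#' series across the exposure block of the visuomotor group. The mean
#' per-trial cursor error implies an internal rotation estimate
#' \code{x_t = rotation + mean IDE_t}; the deterministic learner predicts
#' \code{x_t = X_inf (1 - rho^(t-1))} with \code{rho = retention - rate}
#' and \code{X_inf = rate * rotation / (1 - rho)}, from which retention
#' and rate are recovered by nonlinear least squares.
#'
#' @param measures A measure table from \code{\link{extract_measures}} (or
#'   \code{\link{baseline_correct}}) containing right-hand EXP trials of
#'   the visuomotor (or combined) group.
#' @param cfg The generating \code{\link{reach_config}} (for the rotation
#'   magnitude).
#' @param group Which group's curve to fit.
#' @return Object of class \code{adaptation_fit}: list with
#'   \code{retention}, \code{rate}, \code{rho}, \code{asymptote_deg},
#'   \code{identifiable}, \code{curve} (per-trial mean estimates).
#' @export
recover_learning_rate <- function(measures, cfg = reach_config(),
                                  group = "visuomotor") {
  grp_sel <- group
  m <- data.table::as.data.table(measures)
  m <- m[hand == "R" & block == "EXP"]
  m <- m[m[["group"]] == grp_sel]
  if (nrow(m) == 0) stop("design error: no right-hand exposure trials for group ", group)
  if (max(m$trial) < 50) stop("design error: need >= 50 exposure trials")
  curve <- m[, .(x_hat = cfg$rotation_deg + mean(ide_deg)), by = trial]
  data.table::setorder(curve, trial)
  xs <- curve$x_hat
  tt <- curve$trial
  if (sd(xs) < 1e-9 || max(abs(xs)) < 1) {
    out <- list(retention = NA_real_, rate = NA_real_, rho = NA_real_,
                asymptote_deg = mean(xs), identifiable = FALSE, curve = curve)
    class(out) <- "adaptation_fit"
    return(out)
  }
  fit <- tryCatch(
    nls(x_hat ~ A * (1 - rho^(trial - 1)), data = curve,
        start = list(A = max(xs), rho = 0.9),
        control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(retention = NA_real_, rate = NA_real_, rho = NA_real_,
                asymptote_deg = NA_real_, identifiable = FALSE, curve = curve)
    class(out) <- "adaptation_fit"
    return(out)
  }
  A <- unname(coef(fit)["A"])
  rho <- unname(coef(fit)["rho"])
  rate <- A * (1 - rho) / cfg$rotation_deg
  retention <- rho + rate
  out <- list(retention = retention, rate = rate, rho = rho,
              asymptote_deg = A,
              identifiable = is.finite(rate) && abs(A) >= 1 && rho < 1,
              curve = curve)
  class(out) <- "adaptation_fit"
  out
}

#' @export
print.adaptation_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("Adaptation fit: non-identifiable (flat exposure curve)\n")
  } else {
    cat(sprintf("Adaptation fit: retention=%.4f rate=%.4f (rho=%.4f, asymptote %.2f deg)\n",
                x$retention, x$rate, x$rho, x$asymptote_deg))
  }
  invisible(x)
}

#' @export
coef.adaptation_fit <- function(object, ...) {
  c(retention = object$retention, rate = object$rate)
}

#' Null-calibration experiment for the group effect
#'
#' Repeatedly simulates scaled-down experiments with all crosstalk gains
#' set to zero (so left-hand trials are exchangeable across groups), runs
#' the left-hand RMSE mixed ANOVA (early vs late exposure x group), and
#' returns the proportion of simulations whose group main effect rejects
#' at \code{alpha}. A calibrated test rejects at close to \code{alpha}.
#'
#' @param n_sims Number of simulated experiments.
#' @param seed Base seed; simulation i uses \code{seed + i}.
#' @param cfg Configuration; defaults to a scaled-down null design
#'   (4 participants/group, 10/10/60/5 blocks, coarser integration).
#' @param alpha Significance level.
#' @param phase_width Trials per early/late window.
#' @return List with \code{rejection_rate}, \code{n_sims}, \code{p_values}.
#' @export
null_calibration <- function(n_sims = 200, seed = 1,
                             cfg = NULL, alpha = 0.05, phase_width = 30) {
  if (is.null(cfg)) {
    cfg <- reach_config(participants_per_group = 4,
                        blocks = c(VBL = 10, KBL = 10, EXP = 60, POST = 5),
                        dt = 0.002, record_dt = 0.008)
    cfg$crosstalk$kappa_rot <- 0
    cfg$crosstalk$kappa_dyn <- 0
  }
  nexp <- cfg$blocks[["EXP"]]
  pvals <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    exp <- generate_experiment(cfg, seed = seed + i)
    uid <- exp$trials[hand == "L" &
                      ((block == "KBL") |
                       (block == "EXP" & (trial <= phase_width |
                                          trial > nexp - phase_width))),
                      trial_uid]
    meas <- extract_measures(exp, trial_uids = uid)
    meas <- baseline_correct(meas, cols = "rmse")
    ms <- meas[block == "EXP"]
    ms[, phase := ifelse(trial <= phase_width, "early_exp", "late_exp")]
    cell <- ms[, .(value = mean(rmse_bc)), by = .(group, participant, phase)]
    an <- mixed_anova(as.data.frame(cell), dv = "value", between = "group",
                      within = "phase", id = "participant")
    pvals[i] <- an$table$p[1]
  }
  list(rejection_rate = mean(pvals < alpha), n_sims = n_sims, p_values = pvals)
}

#' Late-exposure interference summary by group
#'
#' Group-level summary of left-hand interference in the late-exposure
#' window: magnitude of the group-mean baseline-corrected IDE and the
#' group-mean RMSE.
#'
#' @param phases The \code{phases} table from \code{\link{bin_and_phase}}
#'   (baseline-corrected).
#' @return data.table with one row per group: \code{abs_mean_ide_deg},
#'   \code{mean_rmse}.
#' @export
interference_summary <- function(phases) {
  p <- data.table::as.data.table(phases)
  p <- p[hand == "L" & phase == "late_exp"]
  p[, .(abs_mean_ide_deg = abs(mean(ide_deg_bc)),
        mean_rmse = mean(rmse_bc)), by = group]
}
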