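test_that("onset detection lands near the true start of a padded reach", {
  dt <- 0.001
  tau <- seq(0, 1, by = dt / 0.4)
  speed <- 1.875 * 0.10 / 0.4 * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  pad <- rep(0, 200) # 200 ms of rest either side
  s <- c(pad, speed, pad)
  oo <- detect_onset_offset(s, dt)
  # the analytic 5%-of-peak crossing for this profile is ~23.7 ms in
  true_start <- length(pad) + 1
  expect_lte((oo$onset - true_start) * dt, 0.025)
  expect_gte(oo$onset, true_start)
  expect_lte((length(pad) + length(speed) - oo$offset) * dt, 0.025)
  expect_error(detect_onset_offset(rep(0, 100), dt), "detection error")
  expect_error(detect_onset_offset(numeric(0), dt), "detection error")
  # a blip shorter than min_duration cannot be the onset
  blip <- c(rep(0, 50), rep(1, 10), rep(0, 200), speed, pad)
  expect_gt(detect_onset_offset(blip, dt)$onset, 260)
})

test_that("peak velocity takes the earliest tie and ballistic end splits double peaks", {
  s <- c(0, 1, 3, 3, 2, 1, 0.5, 0)
  expect_identical(find_peak_velocity(s, 1L, 8L), 3L)
  # dip between two submovements: ballistic end at the strict local minimum
  s2 <- c(0, 2, 5, 3, 1, 2.5, 4, 2, 0)
  ev <- list(onset = 2L, offset = 8L)
  pk <- find_peak_velocity(s2, ev$onset, ev$offset)
  expect_identical(pk, 3L)
  expect_identical(find_ballistic_end(s2, pk, ev$offset), 5L)
  # monotone decay to near zero: first sub-threshold sample
  s3 <- c(0, 5, 4, 3, 2, 1, 0.04, 0.01, 0)
  expect_identical(find_ballistic_end(s3, 2L, 8L), 7L)
  # no dip and no near-zero: falls back to offset
  s4 <- c(0, 5, 4.5, 4, 3.5, 3)
  expect_identical(find_ballistic_end(s4, 2L, 6L), 6L)
})

test_that("signed angular error is CCW-positive with clockwise quadrants negative", {
  home <- c(0, 0)
  # forward target, point rotated clockwise into quadrant 1: -45
  expect_equal(signed_angular_error(c(0.0707, 0.0707), home, c(0, 0.10)), -45,
               tolerance = 1e-3)
  expect_equal(signed_angular_error(c(-0.0707, 0.0707), home, c(0, 0.10)), 45,
               tolerance = 1e-3)
  # backward target, point in quadrant 3 is clockwise of it: -45
  expect_equal(signed_angular_error(c(-0.0707, -0.0707), home, c(0, -0.10)), -45,
               tolerance = 1e-3)
  expect_equal(signed_angular_error(c(0, 0.05), home, c(0, 0.10)), 0)
  # mirror antisymmetry about the target line
  set.seed(3)
  for (i in 1:10) {
    p <- runif(2, -0.1, 0.1)
    a1 <- signed_angular_error(p, home, c(0, 0.10))
    a2 <- signed_angular_error(c(-p[1], p[2]), home, c(0, 0.10))
    expect_equal(a1, -a2, tolerance = 1e-10)
  }
  expect_error(signed_angular_error(c(0, 0), home, c(0, 0.1)),
               "undefined-angle error")
})

test_that("normalized RMSE matches a hand-computed path and is rotation invariant", {
  # square detour: out 1 right, forward 1, back 1 left along a 2-long reach
  x <- c(0, 1, 1, 0, 0)
  y <- c(0, 0, 1, 1, 2)
  # perp distances (0,1,1,0,0), path length 4 + 1 = 5... compute directly:
  perp <- x
  plen <- sum(sqrt(diff(x)^2 + diff(y)^2))
  expect_equal(compute_rmse(x, y, 1, 5, c(0, 0), c(0, 2)),
               sqrt(mean(perp^2)) / plen)
  expect_equal(compute_rmse(x, y, 1, 5, c(0, 0), c(0, 2),
                            denominator = "straight"),
               sqrt(mean(perp^2)) / 2)
  # rigid rotation of path and target leaves the measure unchanged
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  p2 <- R %*% rbind(x, y)
  tg2 <- as.numeric(R %*% c(0, 2))
  expect_equal(compute_rmse(p2[1, ], p2[2, ], 1, 5, c(0, 0), tg2),
               compute_rmse(x, y, 1, 5, c(0, 0), c(0, 2)), tolerance = 1e-12)
  expect_gte(compute_rmse(x, y, 1, 5, c(0, 0), c(0, 2)), 0)
})

test_that("all four measures vanish on a straight noise-free reach", {
  cfg <- reach_config()
  tr <- simulate_trial(cfg, noise = FALSE)
  s <- tr$samples
  m <- compute_measures(s$x, s$y, s$vx, s$vy, cfg$record_dt, c(0, 0), tr$target)
  expect_lt(m$rmse, 1e-3)
  expect_lt(abs(m$ide_deg), 0.5)
  expect_lt(abs(m$iee_deg), 0.5)
  expect_lt(abs(m$fee_cm), 0.05)
  expect_true(m$onset < m$peak_vel)
  expect_true(m$peak_vel <= m$ballistic_end)
  expect_true(m$ballistic_end <= m$offset)
})

test_that("cursor-frame and hand-frame directional errors differ by the rotation", {
  cfg <- reach_config()
  tr <- simulate_trial(cfg, rotation_on = TRUE, noise = FALSE)
  s <- tr$samples
  mh <- compute_measures(s$x, s$y, s$vx, s$vy, cfg$record_dt, c(0, 0), tr$target)
  mc <- compute_measures(s$x, s$y, s$vx, s$vy, cfg$record_dt, c(0, 0), tr$target,
                         use_cursor = TRUE, rotation_deg = cfg$rotation_deg)
  expect_equal(mc$ide_deg - mh$ide_deg, -cfg$rotation_deg, tolerance = 1)
})

test_that("baseline correction subtracts the hand-appropriate block mean", {
  cfg <- tiny_config()
  e <- generate_experiment(cfg, seed = 11)
  m <- extract_measures(e)
  bc <- baseline_correct(m)
  expect_true(all(paste0(c("rmse", "ide_deg", "iee_deg", "fee_cm"), "_bc")
                  %in% names(bc)))
  # corrected baseline-block mean is exactly zero per participant/hand
  zl <- bc[hand == "L" & block == "KBL",
           .(mu = mean(ide_deg_bc)), by = participant]
  zr <- bc[hand == "R" & block == "VBL",
           .(mu = mean(rmse_bc)), by = participant]
  expect_true(all(abs(zl$mu) < 1e-12))
  expect_true(all(abs(zr$mu) < 1e-12))
  # shift invariance: adding a constant leaves corrected values unchanged
  m2 <- data.table::copy(m)[, ide_deg := ide_deg + 7]
  bc2 <- baseline_correct(m2)
  expect_equal(bc2$ide_deg_bc, bc$ide_deg_bc, tolerance = 1e-12)
  # hand-worked numbers: baseline mean 3 removed
  toy <- data.table::data.table(
    participant = "p1", hand = "L", group = "control",
    block = c("KBL", "KBL", "EXP"), trial = c(1, 2, 1),
    rmse = 0, ide_deg = c(2, 4, 6), iee_deg = 0, fee_cm = 0)
  expect_equal(baseline_correct(toy)$ide_deg_bc, c(-1, 1, 3))
  expect_error(baseline_correct(toy[block == "EXP"]), "missing-baseline error")
})

test_that("binning averages consecutive trials and phases pick the right windows", {
  cfg <- tiny_config()
  trials <- data.table::CJ(participant = "p1", hand = "L", group = "control",
                           block = "EXP", trial = 1:20)
  trials[, rmse := as.numeric(trial)]
  trials[, c("ide_deg", "iee_deg", "fee_cm") := 0]
  bp <- bin_and_phase(trials, bin_size = 5, phase_width = 5)
  expect_equal(nrow(bp$bins), 4)
  expect_equal(bp$bins$rmse, c(3, 8, 13, 18)) # means of 1:5, 6:10, ...
  expect_identical(sort(unique(bp$phases$phase)), c("early_exp", "late_exp"))
  expect_equal(sort(bp$phases[phase == "early_exp", trial]), 1:5)
  expect_equal(sort(bp$phases[phase == "late_exp", trial]), 16:20)
  # constant series: every bin equals the constant
  trials[, rmse := 2.5]
  expect_true(all(bin_and_phase(trials, 5, 5)$bins$rmse == 2.5))
  expect_error(bin_and_phase(trials, bin_size = 50, phase_width = 5),
               "binning error")
})

test_that("the batch extraction engine reproduces the reference implementation", {
  cfg <- tiny_config()
  e <- generate_experiment(cfg, seed = 21)
  mc <- extract_measures(e, engine = "cpp")
  mr <- extract_measures(e, engine = "r")
  data.table::setkey(mc, trial_uid); data.table::setkey(mr, trial_uid)
  for (cl in c("rmse", "ide_deg", "iee_deg", "fee_cm"))
    expect_equal(mc[[cl]], mr[[cl]], tolerance = 1e-10)
  for (cl in c("onset", "offset", "peak_vel", "ballistic_end"))
    expect_equal(as.integer(mc[[cl]]), as.integer(mr[[cl]]))
})
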