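test_that("minimum-jerk reference satisfies its boundary conditions and peak", {
  ref <- min_jerk_reference(0.10, 0.4, 0.001)
  expect_equal(ref$position[1], 0)
  expect_equal(ref$position[nrow(ref)], 0.10, tolerance = 1e-12)
  expect_equal(ref$speed[1], 0)
  expect_equal(ref$speed[nrow(ref)], 0, tolerance = 1e-12)
  # closed form: peak speed 1.875 d / T at T/2, single interior maximum
  expect_equal(max(ref$speed), 1.875 * 0.10 / 0.4, tolerance = 1e-9)
  expect_equal(ref$t[which.max(ref$speed)], 0.2, tolerance = 1e-9)
  d <- diff(ref$speed)
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1) # one sign change
  expect_error(min_jerk_reference(-1, 0.4, 0.001), "invalid parameter")
  expect_error(min_jerk_reference(0.1, 0.4, 0.5), "invalid parameter")
})

test_that("cursor rotation is clockwise, norm-preserving, with identity at zero", {
  expect_equal(apply_rotation(c(0, 0.10), 0), c(0, 0.10))
  expect_equal(apply_rotation(c(0, 0.10), 45),
               c(0.10 * sin(pi / 4), 0.10 * cos(pi / 4)), tolerance = 1e-9)
  # a hand rotated 45 deg counterclockwise of the target puts the cursor on it
  expect_equal(apply_rotation(c(-0.0707107, 0.0707107), 45), c(0, 0.10),
               tolerance = 1e-6)
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(2); r <- runif(1, -180, 180)
    expect_equal(sqrt(sum(apply_rotation(v, r)^2)), sqrt(sum(v^2)),
                 tolerance = 1e-12)
  }
})

test_that("curl force is orthogonal with magnitude gain times speed", {
  expect_equal(curl_force(c(0, 0), 20, "CW"), c(0, 0))
  f <- curl_force(c(0, 1), 20, "CW")
  expect_equal(sqrt(sum(f^2)), 20)
  expect_equal(sum(f * c(0, 1)), 0)
  expect_equal(f[1], 20) # clockwise: forward velocity pushed rightward
  expect_equal(curl_force(c(0, 1), 20, "CCW")[1], -20)
  set.seed(2)
  for (i in 1:20) {
    v <- rnorm(2)
    f <- curl_force(v, 20, "CW")
    expect_equal(sum(f * v), 0, tolerance = 1e-12)
    expect_equal(sqrt(sum(f^2)), 20 * sqrt(sum(v^2)), tolerance = 1e-12)
  }
  expect_error(curl_force(c(0, 1), -1), "invalid parameter")
})

test_that("channel wall force is zero inside, spring-damper outside, gated by ramp", {
  ch <- reach_config()$channel
  expect_equal(channel_wall_force(0.0001, 0, ch, 1), 0) # inside half-width
  # 1 cm penetration at 2000 N/m = 20 N restoring force
  expect_equal(abs(channel_wall_force(ch$half_width + 0.01, 0, ch, 1)), 20)
  expect_lt(channel_wall_force(ch$half_width + 0.01, 0, ch, 1), 0) # toward center
  expect_equal(channel_wall_force(0.05, 2, ch, 0), 0) # ramp off
  bad <- ch; bad$stiffness <- -1
  expect_error(channel_wall_force(0.01, 0, bad, 1), "invalid parameter")
})

test_that("state-space learner follows x' = a x + b e with the right fixed point", {
  expect_equal(update_adaptation(10, 99, 1, 0), 10) # perfect retention, no learning
  expect_equal(update_adaptation(0, 45, 0.99, 0.05), 2.25)
  # constant error: converges to b e / (1 - a)
  x <- 0
  for (i in 1:3000) x <- update_adaptation(x, 10, 0.9, 0.05)
  expect_equal(x, 0.05 * 10 / (1 - 0.9), tolerance = 1e-8)
  expect_error(update_adaptation(0, 1, 1.5, 0.1), "invalid parameter")
})

test_that("crosstalk bias is linear, zero at rest, increasing in the rotation state", {
  expect_equal(crosstalk_aim_bias(0, 0, 0.3, 0.9), 0)
  expect_equal(crosstalk_aim_bias(45, 0, 0.15, 0.7), 6.75)
  b1 <- crosstalk_aim_bias(10, 0.5, 0.15, 0.15, 15)
  expect_equal(b1, 0.15 * 10 + 0.15 * 0.5 * 15)
  xs <- crosstalk_aim_bias(seq(0, 45, 5), 0, 0.15, 0)
  expect_true(all(diff(xs) > 0))
  expect_error(crosstalk_aim_bias(1, 1, -0.1, 0.1), "invalid parameter")
})

test_that("noise-free unperturbed trial is straight, on target and well timed", {
  cfg <- reach_config()
  tr <- simulate_trial(cfg, noise = FALSE)
  s <- tr$samples
  expect_lt(max(abs(s$x)), 5e-4)                       # < 0.5 mm lateral
  expect_lt(abs(s$y[nrow(s)] - 0.10), 5e-4)            # stops in the target
  expect_identical(tr$timing_class, "ideal")
  m <- compute_measures(s$x, s$y, s$vx, s$vy, cfg$record_dt,
                        c(0, 0), tr$target)
  expect_lt(abs(m$ide_deg), 0.5)
  expect_lt(m$rmse, 0.005)
})

test_that("unadapted rotation trial shows a 45-degree clockwise cursor error", {
  cfg <- reach_config()
  tr <- simulate_trial(cfg, rotation_on = TRUE, noise = FALSE)
  m <- compute_measures(tr$samples$x, tr$samples$y, tr$samples$vx,
                        tr$samples$vy, cfg$record_dt, c(0, 0), tr$target,
                        use_cursor = TRUE, rotation_deg = tr$rotation_deg)
  expect_equal(abs(m$ide_deg), 45, tolerance = 2)
  expect_lt(m$ide_deg, 0) # clockwise deviations are negative
})

test_that("unadapted curl trial deviates with the sense of the field", {
  cfg <- reach_config() # CW field: forward reach pushed rightward (negative lateral)
  for (tg in c(90, 270)) {
    tr <- simulate_trial(cfg, curl_on = TRUE, target_deg = tg, noise = FALSE)
    s <- tr$samples
    ev <- reach_events(s$vx, s$vy, cfg$record_dt)
    u <- dir <- c(cos(tg * pi / 180), sin(tg * pi / 180))
    early <- ev$onset:ev$peak_vel
    lat <- u[1] * s$y[early] - u[2] * s$x[early]
    expect_true(all(lat[-1] < 0)) # clockwise throughout the early reach
  }
  # feedforward compensation at full adaptation restores a straight reach
  tr2 <- simulate_trial(cfg, dyn_estimate = 1, curl_on = TRUE, noise = FALSE)
  expect_lt(max(abs(tr2$samples$x)), 1e-3)
})

test_that("generated experiments honor schedule, channel proportion and determinism", {
  cfg <- tiny_config()
  e1 <- generate_experiment(cfg, seed = 5)
  e2 <- generate_experiment(cfg, seed = 5)
  expect_identical(e1$trials, e2$trials)
  expect_identical(e1$samples, e2$samples)
  e3 <- generate_experiment(cfg, seed = 6)
  expect_false(identical(e1$samples, e3$samples))

  n_per <- e1$trials[, .N, by = .(participant, hand)]
  expect_true(all(n_per$N == sum(cfg$blocks)))
  # exact per-block channel counts on the left hand, none on the right
  chk <- e1$trials[hand == "L", .(n_chan = sum(channel), .N),
                   by = .(participant, block)]
  expect_true(all(chk$n_chan == round(cfg$channel_fraction * chk$N)))
  expect_true(all(!e1$trials[hand == "R", channel]))
  # balanced forward/backward targets per block, both hands matched
  bal <- e1$trials[, .(fwd = sum(target_deg == 90), .N),
                   by = .(participant, hand, block)]
  expect_true(all(abs(bal$fwd - bal$N / 2) <= 0.5))
  wide <- data.table::dcast(e1$trials, participant + block + trial ~ hand,
                            value.var = "target_deg")
  expect_true(all(wide$L == wide$R))
})

test_that("right-hand adaptation converges near the rotation and rebounds after removal", {
  cfg <- reach_config()
  st <- bireach:::adaptation_series(cfg, "visuomotor")
  nb <- cumsum(cfg$blocks)
  late <- st$rot[(nb[["EXP"]] - 29):nb[["EXP"]]]
  expect_true(all(abs(late - cfg$rotation_deg) / cfg$rotation_deg < 0.10))
  post <- st$rot[(nb[["EXP"]] + 1):nb[["POST"]]]
  expect_gt(post[1], 35)            # aftereffect present at removal
  expect_true(all(diff(post) < 0))  # and washing out
})
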