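test_that("generalized eta squared matches hand-computed ratios", {
  expect_equal(generalized_eta_squared(0, c(10, 5)), 0)
  expect_equal(generalized_eta_squared(10, 10), 0.5)
  expect_equal(generalized_eta_squared(30, c(40, 30)), 0.3)
  expect_equal(generalized_eta_squared(1, numeric(0)), 1)
  expect_error(generalized_eta_squared(-1, 1), "invalid parameter")
  expect_error(generalized_eta_squared(0, c(0, 0)), "undefined-effect-size")
})

test_that("sphericity correction is exactly 1 for two levels and under compound symmetry", {
  expect_identical(huynh_feldt_epsilon(diag(2), 30)$hf, 1)
  expect_identical(huynh_feldt_epsilon(matrix(c(4, 1, 1, 9), 2), 12)$hf, 1)
  # compound symmetry with k = 3: sphericity holds, epsilon clips to 1
  S <- matrix(0.3, 3, 3); diag(S) <- 1
  e <- huynh_feldt_epsilon(S, 20, 2)
  expect_equal(e$gg, 1, tolerance = 1e-12)
  expect_identical(e$hf, 1)
  # a strongly non-spherical matrix gives gg in [1/(k-1), 1) and hf >= gg
  S2 <- diag(c(1, 1, 25))
  e2 <- huynh_feldt_epsilon(S2, 10, 1)
  expect_lt(e2$gg, 1)
  expect_gte(e2$gg, 0.5)
  expect_gte(e2$hf, e2$gg)
  # gg agrees with the classical sum formula on a toy covariance
  S3 <- matrix(c(2, 0.5, 0.1, 0.5, 1.5, 0.3, 0.1, 0.3, 1), 3)
  C <- diag(3) - matrix(1 / 3, 3, 3)
  D <- C %*% S3 %*% C
  gg_ref <- sum(diag(D))^2 / (2 * sum(D^2))
  expect_equal(huynh_feldt_epsilon(S3, 15, 1)$gg, gg_ref, tolerance = 1e-12)
  expect_error(huynh_feldt_epsilon(matrix(1, 1, 1), 10), "invalid parameter")
})

test_that("the mixed ANOVA reproduces an independent sums-of-squares oracle", {
  d <- toy_mixed_data(seed = 42)
  fit <- mixed_anova(d, dv = "value")
  orc <- oracle_mixed_anova(d)
  tb <- fit$table
  expect_equal(tb$ss_effect, unname(orc$ss[c("group", "w", "int")]),
               tolerance = 1e-10)
  expect_equal(tb$ss_error, unname(orc$ss[c("subj", "werr", "werr")]),
               tolerance = 1e-10)
  expect_equal(tb$F, unname(orc$F), tolerance = 1e-10)
  expect_equal(tb$p, unname(orc$p), tolerance = 1e-10)
  expect_equal(tb$ges, unname(orc$ges), tolerance = 1e-10)
  expect_equal(tb$df_num, c(3, 1, 3))
  expect_equal(tb$df_den, c(8, 8, 8))
  # two within levels: uncorrected and corrected p coincide
  expect_equal(tb$p_hf, tb$p, tolerance = 1e-12)
})

test_that("the mixed ANOVA agrees with the base aov split-plot fit", {
  d <- toy_mixed_data(seed = 7, n_per_group = 4)
  fit <- mixed_anova(d, dv = "value")
  a <- summary(aov(value ~ group * phase + Error(participant),
                   data = transform(d, participant = factor(participant),
                                    group = factor(group),
                                    phase = factor(phase))))
  btab <- a[["Error: participant"]][[1]]
  wtab <- a[["Error: Within"]][[1]]
  expect_equal(fit$table$F[1], btab["group", "F value"], tolerance = 1e-8)
  expect_equal(fit$table$F[2], wtab["phase", "F value"], tolerance = 1e-8)
  expect_equal(fit$table$F[3], wtab["group:phase", "F value"], tolerance = 1e-8)
  expect_equal(fit$table$p[1], btab["group", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(fit$table$p[2], wtab["phase", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(fit$table$p[3], wtab["group:phase", "Pr(>F)"], tolerance = 1e-8)
})

test_that("a flat within factor yields F = 0 and p = 1, not NaN", {
  d <- expand.grid(participant = paste0("s", 1:8),
                   phase = c("early", "late"), stringsAsFactors = FALSE)
  d$group <- rep(c("a", "b"), each = 4)[match(d$participant,
                                              paste0("s", 1:8))]
  d$value <- rep(c(1, 2, 3, 4, 5, 6, 7, 8), 2) # identical across phases
  fit <- mixed_anova(d, dv = "value")
  expect_equal(fit$table$F[2], 0)
  expect_equal(fit$table$p[2], 1)
  expect_equal(fit$table$F[3], 0)
  expect_equal(fit$table$p[3], 1)
  expect_error(mixed_anova(d[d$phase == "early", ], dv = "value"),
               "design error")
})

test_that("the one-way ANOVA squares the two-group t statistic", {
  set.seed(9)
  a <- rnorm(15, 0); b <- rnorm(15, 0.8)
  ow <- one_way_anova(c(a, b), rep(c("a", "b"), each = 15))
  tt <- independent_t_test(a, b)
  expect_equal(ow$F, tt$t^2, tolerance = 1e-10)
  expect_equal(ow$p, tt$p, tolerance = 1e-10)
  expect_equal(ow$df_den, 28)
  # hand-worked toy: groups (1,2,3) and (4,5,6)
  ow2 <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(ow2$ss_effect, 13.5)
  expect_equal(ow2$ss_error, 4)
  expect_equal(ow2$F, 13.5 / 1)
  expect_equal(ow2$ges, 13.5 / 17.5)
})

test_that("Tukey comparisons give p = 1 for identical means and order by distance", {
  tk <- tukey_hsd(c(a = 2, b = 2, c = 2), ms_error = 1, df_error = 20, n = 5)
  expect_true(all(tk$p_adj == 1))
  expect_true(all(tk$q == 0))
  tk2 <- tukey_hsd(c(a = 0, b = 1, c = 3), ms_error = 0.5, df_error = 30, n = 10)
  expect_equal(nrow(tk2), 3)
  # q matches the definition and p decreases with distance between means
  expect_equal(tk2$q, abs(tk2$diff) / sqrt(0.5 / 10))
  p_ab <- tk2$p_adj[tk2$pair == "a - b"]
  p_ac <- tk2$p_adj[tk2$pair == "a - c"]
  expect_gt(p_ab, p_ac)
  # p agrees with a direct ptukey evaluation
  expect_equal(p_ac, ptukey(3 / sqrt(0.05), 3, 30, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(tukey_hsd(c(a = 1), 1, 10, 5), "design error")
  expect_error(tukey_hsd(c(a = 1, b = 2), 0, 10, 5), "invalid parameter")
})

test_that("the pooled t test reports 28 degrees of freedom for 15 vs 15", {
  set.seed(4)
  a <- rnorm(15); b <- rnorm(15, 1)
  tt <- independent_t_test(a, b)
  expect_equal(tt$df, 28)
  # hand computation of the pooled statistic
  sp2 <- ((14 * var(a)) + (14 * var(b))) / 28
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 15))
  expect_equal(tt$t, t_ref, tolerance = 1e-12)
  expect_equal(tt$p, 2 * pt(abs(t_ref), 28, lower.tail = FALSE),
               tolerance = 1e-12)
  z <- rep(3, 10)
  expect_equal(independent_t_test(z, z)$t, 0)
  expect_equal(independent_t_test(z, z)$p, 1)
  expect_error(independent_t_test(rep(1, 5), rep(2, 5)), "degenerate samples")
  expect_error(independent_t_test(1, c(1, 2)), "design error")
})
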