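#' Generalized eta squared
#'
#' Effect size for designs with manipulated factors only:
#' \code{SS_effect / (SS_effect + sum(SS_error))}, where the denominator
#' pools every error (subject-variance) stratum of the design, making the
#' value comparable across between-, within- and mixed designs.
#'
#' @param ss_effect Effect sum of squares, >= 0.
#' @param ss_errors Numeric vector of all error sums of squares.
#' @return Value in \[0, 1\].
#' @export
generalized_eta_squared <- function(ss_effect, ss_errors) {
  if (ss_effect < 0 || any(ss_errors < 0))
    stop("invalid parameter: sums of squares must be >= 0")
  den <- ss_effect + sum(ss_errors)
  if (den == 0) stop("undefined-effect-size error: all sums of squares are zero")
  ss_effect / den
}

#' Huynh-Feldt sphericity correction factor
#'
#' Estimates the Box/Greenhouse-Geisser epsilon from the within-subject
#' covariance matrix and applies the Huynh-Feldt adjustment for a
#' split-plot design with \code{n} subjects in \code{g} groups. For a
#' two-level within factor sphericity holds trivially and the function
#' returns exactly 1. Estimates above 1 are clipped to 1.
#'
#' @param S k x k covariance matrix of the within-subject level scores
#'   (pooled within groups for a mixed design).
#' @param n Number of subjects.
#' @param g Number of between-subject groups (1 for a pure within design).
#' @return List with \code{gg} (Greenhouse-Geisser estimate) and \code{hf}
#'   (Huynh-Feldt estimate), both clipped to \[1/(k-1), 1\].
#' @export
huynh_feldt_epsilon <- function(S, n, g = 1) {
  S <- as.matrix(S)
  k <- nrow(S)
  if (k < 2 || ncol(S) != k) stop("invalid parameter: S must be k x k with k >= 2")
  if (n <= 1) stop("invalid parameter: need more than one subject")
  if (any(!is.finite(S))) stop("invalid parameter: covariance contains non-finite values")
  if (k == 2) return(list(gg = 1, hf = 1))
  # double-center and use the trace form of Box's epsilon
  C <- diag(k) - matrix(1 / k, k, k)
  D <- C %*% S %*% C
  tr <- sum(diag(D))
  if (tr <= 0) stop("invalid parameter: singular within-subject covariance")
  gg <- tr^2 / ((k - 1) * sum(D^2))
  hf <- (n * (k - 1) * gg - 2) / ((k - 1) * (n - g - (k - 1) * gg))
  lo <- 1 / (k - 1)
  list(gg = min(max(gg, lo), 1), hf = min(max(hf, lo), 1))
}

#' Mixed-design (split-plot) ANOVA
#'
#' Classical univariate mixed ANOVA with one between-subject factor and
#' one within-subject factor: sums of squares are decomposed into the
#' between stratum (group, subjects within groups) and the within stratum
#' (within factor, group x within interaction, within x subjects error).
#' F ratios follow the standard expected mean squares; effect sizes are
#' generalized eta squared with both error strata in the denominator; for
#' within factors with three or more levels the Huynh-Feldt epsilon
#' rescales the degrees of freedom of the within-stratum p values.
#'
#' @param data data.frame with the value, group, within-level and subject
#'   columns.
#' @param dv,between,within,id Column names.
#' @return Object of class \code{anova_mixed}: list with \code{table}
#'   (one row per effect: df, SS, MS, F, p, ges, epsilon_hf,
#'   p_hf) and the error strata.
#' @examples
#' d <- expand.grid(id = 1:6, phase = c("early", "late"))
#' d$group <- rep(c("a", "b", "c"), each = 2)[d$id]
#' set.seed(1); d$y <- rnorm(nrow(d))
#' mixed_anova(d, dv = "y", between = "group", within = "phase", id = "id")
#' @export
mixed_anova <- function(data, dv, between = "group", within = "phase",
                        id = "participant") {
  y <- data[[dv]]
  grp <- factor(data[[between]])
  w <- factor(data[[within]])
  subj <- factor(data[[id]])
  if (nlevels(grp) < 2) stop("design error: need at least 2 groups")
  k <- nlevels(w)
  if (k < 2) stop("design error: need at least 2 within-factor levels")
  tab <- table(subj, w)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (any(tab != 1))
    stop("incomplete-design error: every subject needs exactly one value per within level")
  subj_grp <- tapply(as.character(grp), subj, function(z) unique(z)[1])
  n_by_grp <- table(factor(subj_grp, levels = levels(grp)))
  if (any(n_by_grp < 2)) stop("design error: need >= 2 subjects per group")
  N <- nlevels(subj)
  g <- nlevels(grp)

  grand <- mean(y)
  subj_mean <- tapply(y, subj, mean)
  grp_mean <- tapply(y, grp, mean)
  w_mean <- tapply(y, w, mean)
  cell_mean <- tapply(y, list(grp, w), mean)
  grp_of_subj <- factor(subj_grp, levels = levels(grp))

  ss_between_subj <- k * sum((subj_mean - grand)^2)
  ss_group <- k * sum(as.numeric(n_by_grp) * (grp_mean - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_within_total <- sum((y - subj_mean[subj])^2)
  ss_w <- N * sum((w_mean - grand)^2)
  ss_int <- sum(outer(as.numeric(n_by_grp), rep(1, k)) *
                (cell_mean - outer(grp_mean, rep(1, k)) -
                 outer(rep(1, g), w_mean) + grand)^2)
  ss_err_w <- ss_within_total - ss_w - ss_int
  ss_err_w <- max(ss_err_w, 0)

  df_group <- g - 1
  df_subj <- N - g
  df_w <- k - 1
  df_int <- (g - 1) * (k - 1)
  df_err_w <- (N - g) * (k - 1)

  ms <- function(ss, df) ss / df
  F_group <- ms(ss_group, df_group) / ms(ss_subj_within, df_subj)
  F_w <- ms(ss_w, df_w) / ms(ss_err_w, df_err_w)
  F_int <- ms(ss_int, df_int) / ms(ss_err_w, df_err_w)

  errs <- c(ss_subj_within, ss_err_w)
  ges <- c(generalized_eta_squared(ss_group, errs),
           generalized_eta_squared(ss_w, errs),
           generalized_eta_squared(ss_int, errs))

  eps <- 1
  if (k > 2) {
    # pooled within-group covariance of the subject x level score matrix
    Y <- tapply(y, list(subj, w), mean)
    Sp <- matrix(0, k, k)
    for (gl in levels(grp)) {
      Yg <- Y[grp_of_subj == gl, , drop = FALSE]
      Sp <- Sp + stats::cov(Yg) * (nrow(Yg) - 1)
    }
    Sp <- Sp / (N - g)
    eps <- huynh_feldt_epsilon(Sp, N, g)$hf
  }

  p_group <- pf(F_group, df_group, df_subj, lower.tail = FALSE)
  p_w <- pf(F_w, df_w, df_err_w, lower.tail = FALSE)
  p_int <- pf(F_int, df_int, df_err_w, lower.tail = FALSE)
  p_w_hf <- pf(F_w, df_w * eps, df_err_w * eps, lower.tail = FALSE)
  p_int_hf <- pf(F_int, df_int * eps, df_err_w * eps, lower.tail = FALSE)

  # degenerate within variance: no evidence against the null
  if (ss_w == 0 && ss_err_w == 0) { F_w <- 0; p_w <- 1; p_w_hf <- 1 }
  if (ss_int == 0 && ss_err_w == 0) { F_int <- 0; p_int <- 1; p_int_hf <- 1 }

  table <- data.frame(
    effect = c(between, within, paste0(between, ":", within)),
    df_num = c(df_group, df_w, df_int),
    df_den = c(df_subj, df_err_w, df_err_w),
    ss_effect = c(ss_group, ss_w, ss_int),
    ss_error = c(ss_subj_within, ss_err_w, ss_err_w),
    F = c(F_group, F_w, F_int),
    p = c(p_group, p_w, p_int),
    ges = ges,
    epsilon_hf = c(NA, eps, eps),
    p_hf = c(p_group, p_w_hf, p_int_hf))
  out <- list(table = table, dv = dv,
              strata = c(subjects_within_groups = ss_subj_within,
                         within_x_subjects = ss_err_w),
              n_subjects = N, n_groups = g, k_within = k)
  class(out) <- "anova_mixed"
  out
}

#' @export
print.anova_mixed <- function(x, ...) {
  cat(sprintf("Mixed-design ANOVA on '%s' (%d subjects, %d groups, %d within levels)\n",
              x$dv, x$n_subjects, x$n_groups, x$k_within))
  tb <- x$table
  tb$F <- round(tb$F, 3)
  tb$p <- signif(tb$p, 3)
  tb$p_hf <- signif(tb$p_hf, 3)
  tb$ges <- round(tb$ges, 3)
  tb$ss_effect <- signif(tb$ss_effect, 4)
  tb$ss_error <- signif(tb$ss_error, 4)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' One-way between-subjects ANOVA
#'
#' Standard between-groups F test (via \code{lm}/\code{anova}) with an
#' eta-squared-style generalized effect size
#' \code{SS_between / (SS_between + SS_within)}. Used for simple-effects
#' analyses within a block.
#'
#' @param values Numeric response.
#' @param group Grouping factor.
#' @return One-row data.frame: \code{df_num}, \code{df_den},
#'   \code{ss_effect}, \code{ss_error}, \code{F}, \code{p}, \code{ges}.
#' @export
one_way_anova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("design error: need at least 2 groups")
  if (any(table(group) < 2)) stop("design error: need >= 2 values per group")
  fit <- anova(lm(values ~ group))
  ssb <- fit$`Sum Sq`[1]
  ssw <- fit$`Sum Sq`[2]
  data.frame(df_num = fit$Df[1], df_den = fit$Df[2],
             ss_effect = ssb, ss_error = ssw,
             F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
             ges = generalized_eta_squared(ssb, ssw))
}

#' Tukey HSD post-hoc comparisons
#'
#' All-pairs comparisons of cell means with the studentized-range
#' statistic \code{q = |diff| / sqrt(MS_error / n)} and family-wise
#' adjusted p values from the studentized range distribution with family
#' size equal to the number of cells.
#'
#' @param means Named vector of cell means.
#' @param ms_error Error mean square (> 0).
#' @param df_error Error degrees of freedom.
#' @param n Per-cell sample size (scalar, balanced cells).
#' @return data.frame, one row per unordered pair: \code{pair},
#'   \code{diff}, \code{q}, \code{p_adj}.
#' @export
tukey_hsd <- function(means, ms_error, df_error, n) {
  if (length(means) < 2) stop("design error: need at least 2 cells")
  if (ms_error <= 0) stop("invalid parameter: ms_error must be > 0")
  if (n < 2) stop("design error: need n >= 2 per cell")
  k <- length(means)
  if (is.null(names(means))) names(means) <- paste0("cell", seq_len(k))
  pairs <- utils::combn(names(means), 2)
  se <- sqrt(ms_error / n)
  out <- data.frame(
    pair = apply(pairs, 2, paste, collapse = " - "),
    diff = means[pairs[1, ]] - means[pairs[2, ]], row.names = NULL)
  out$q <- abs(out$diff) / se
  out$p_adj <- ptukey(out$q, nmeans = k, df = df_error, lower.tail = FALSE)
  out
}

#' Independent-samples t test (pooled variance)
#'
#' Two-sided Student t test with pooled variance and
#' \code{df = n_a + n_b - 2} (so two groups of 15 give t(28)).
#'
#' @param a,b Numeric samples (>= 2 values each).
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
independent_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("design error: need >= 2 values per sample")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("degenerate samples: zero pooled variance with unequal means (infinite t)")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
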