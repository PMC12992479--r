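# Small configurations and fixtures shared across test files.

tiny_config <- function(...) {
  reach_config(participants_per_group = 2,
               blocks = c(VBL = 6, KBL = 6, EXP = 20, POST = 6),
               dt = 0.002, record_dt = 0.004, ...)
}

small_config <- function(...) {
  reach_config(participants_per_group = 3,
               blocks = c(VBL = 10, KBL = 10, EXP = 60, POST = 30),
               dt = 0.002, record_dt = 0.006, ...)
}

# a balanced 4-group x 2-phase toy dataset for the mixed ANOVA oracle tests
toy_mixed_data <- function(seed = 42, n_per_group = 3) {
  set.seed(seed)
  g <- rep(c("a", "b", "c", "d"), each = n_per_group)
  id <- paste0("s", seq_along(g))
  d <- expand.grid(participant = id, phase = c("early", "late"),
                   stringsAsFactors = FALSE)
  d$group <- g[match(d$participant, id)]
  d$value <- rnorm(nrow(d)) +
    ifelse(d$group %in% c("c", "d"), 1, 0) +
    ifelse(d$phase == "late", 0.5, 0) +
    ifelse(d$group == "d" & d$phase == "late", 0.8, 0)
  d
}

# independent mixed-ANOVA oracle: explicit loop-based sums of squares
oracle_mixed_anova <- function(d) {
  subs <- unique(d$participant)
  groups <- sort(unique(d$group))
  phases <- sort(unique(d$phase))
  k <- length(phases)
  N <- length(subs)
  g <- length(groups)
  grand <- mean(d$value)

  ss_group <- 0; ss_subj <- 0; ss_w <- 0; ss_int <- 0; ss_werr <- 0
  grp_of <- sapply(subs, function(s) d$group[d$participant == s][1])
  smean <- sapply(subs, function(s) mean(d$value[d$participant == s]))
  gmean <- sapply(groups, function(gg) mean(d$value[d$group == gg]))
  wmean <- sapply(phases, function(p) mean(d$value[d$phase == p]))
  for (gg in groups) {
    ng <- sum(grp_of == gg)
    ss_group <- ss_group + k * ng * (gmean[gg] - grand)^2
  }
  for (s in subs)
    ss_subj <- ss_subj + k * (smean[s] - gmean[grp_of[s]])^2
  for (p in phases)
    ss_w <- ss_w + N * (wmean[p] - grand)^2
  for (gg in groups) for (p in phases) {
    ng <- sum(grp_of == gg)
    cm <- mean(d$value[d$group == gg & d$phase == p])
    ss_int <- ss_int + ng * (cm - gmean[gg] - wmean[p] + grand)^2
  }
  for (i in seq_len(nrow(d))) {
    s <- d$participant[i]; p <- d$phase[i]
    cm <- mean(d$value[d$group == grp_of[s] & d$phase == p])
    ss_werr <- ss_werr +
      (d$value[i] - smean[s] - cm + gmean[grp_of[s]])^2
  }
  Fg <- (ss_group / (g - 1)) / (ss_subj / (N - g))
  Fw <- (ss_w / (k - 1)) / (ss_werr / ((N - g) * (k - 1)))
  Fi <- (ss_int / ((g - 1) * (k - 1))) / (ss_werr / ((N - g) * (k - 1)))
  ss_group <- unname(ss_group); ss_subj <- unname(ss_subj)
  ss_w <- unname(ss_w); ss_int <- unname(ss_int); ss_werr <- unname(ss_werr)
  Fg <- unname(Fg); Fw <- unname(Fw); Fi <- unname(Fi)
  list(ss = c(group = ss_group, subj = ss_subj, w = ss_w, int = ss_int,
              werr = ss_werr),
       F = c(group = Fg, w = Fw, int = Fi),
       p = c(group = pf(Fg, g - 1, N - g, lower.tail = FALSE),
             w = pf(Fw, k - 1, (N - g) * (k - 1), lower.tail = FALSE),
             int = pf(Fi, (g - 1) * (k - 1), (N - g) * (k - 1),
                      lower.tail = FALSE)),
       ges = c(group = ss_group / (ss_group + ss_subj + ss_werr),
               w = ss_w / (ss_w + ss_subj + ss_werr),
               int = ss_int / (ss_int + ss_subj + ss_werr)))
}
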