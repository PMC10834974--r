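# Shared fixtures and independent oracles used across the suite.

# Brute-force pairwise concordance AUC: counts case > control pairs, ties
# one half. Independent of the rank-based implementation under test.
bruteForceAUC <- function(control, case) {
  conc <- 0
  for (a in case) for (c in control)
    conc <- conc + (a > c) + 0.5 * (a == c)
  conc / (length(control) * length(case))
}

# Exhaustive Youden search over every real cutoff and both orientations.
bruteForceYouden <- function(control, case) {
  cuts <- sort(unique(c(control, case)))
  cuts <- c(cuts[1] - 1, cuts, cuts + 1e-9,
            (cuts[-1] + cuts[-length(cuts)]) / 2)
  best <- -Inf
  for (cut in cuts) {
    j_high <- mean(case > cut) + mean(control <= cut) - 1
    j_low <- mean(case < cut) + mean(control >= cut) - 1
    best <- max(best, j_high, j_low)
  }
  max(0, best)
}

# Closed-form simple OLS slope/intercept.
olsOracle <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  list(slope = slope, intercept = (sy - slope * sx) / n)
}

# A tiny panel with hand-picked parameters for fast deterministic cohorts.
toyPanel <- function(n_null = 5, effect = 0, slope = 0, noise_cv = 0.2,
                     baseline = 100) {
  k <- n_null + 1
  MetabolitePanel(data.frame(
    name = c("Marker", paste0("Null", seq_len(n_null))),
    class_label = rep("other", k),
    baseline = rep(baseline, k),
    age_slope = c(slope, rep(0, n_null)),
    group_log2_effect = c(effect, rep(0, n_null)),
    noise_cv = rep(noise_cv, k)))
}

# Minimal table built directly from a concentration matrix.
toyTable <- function(conc, group, age) {
  ConcentrationTable(conc, group = factor(group,
                                          levels = c("control", "case")),
                     age = age)
}

# Panel used by the strong-signal recovery studies: `n_affected` markers
# with |log2 effect| >= 1 among null fillers.
signalPanel <- function(n_affected = 11, n_filler = 29, noise_cv = 0.2) {
  k <- n_affected + n_filler
  eff <- rep(0, k)
  eff[seq_len(n_affected)] <- ifelse(seq_len(n_affected) %% 2 == 0, -1, 1) *
    (1 + 0.05 * seq_len(n_affected))
  MetabolitePanel(data.frame(
    name = c(sprintf("Signal%02d", seq_len(n_affected)),
             sprintf("Filler%02d", seq_len(n_filler))),
    class_label = "other",
    baseline = rep(c(50, 5, 120, 0.5, 20), length.out = k),
    age_slope = 0,
    group_log2_effect = eff,
    noise_cv = noise_cv))
}
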