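# Small in-code fixtures shared across test files.

# a compact three-study aggregate table with realistic blood-pressure-like
# numbers (used where the full ten-trial fixture would be slow)
small_agg <- function() {
  meta_aggregate(data.frame(
    study = rep(c("A", "B", "C"), each = 2),
    arm = rep(c("treated", "control"), 3),
    n = c(80, 75, 120, 110, 60, 65),
    mean_base = c(152.3, 153.1, 189.9, 191.6, 177.3, 178.2),
    sd_base = c(15.2, 15.7, 16.2, 17.6, 15.9, 15.1),
    mean_final = c(132.9, 139.8, 165.1, 179.9, 156.9, 170.5),
    sd_final = c(16.7, 17.9, 20.0, 22.2, 21.3, 26.9),
    corr = c(0.27, 0.28, 0.34, 0.33, 0.46, 0.53)),
    outcome_label = "SBP", outcome_units = "mmHg")
}

# scenario with heterogeneity in every random term, away from variance
# boundaries, so REML optima are interior and well identified
rich_scenario <- function(seed, n_studies = 4, n_per_arm = 60) {
  sim_scenario(n_studies = n_studies, n_per_arm = n_per_arm,
               mu_baseline = seq(150, 190, length.out = n_studies),
               sigma_baseline = seq(12, 16, length.out = n_studies),
               beta0 = seq(140, 170, length.out = n_studies),
               beta1 = -10,
               beta2 = seq(0.2, 0.35, length.out = n_studies),
               tau1_sq = 9, residual_structure = "by_study_arm",
               sigma_resid = seq(14, 21, length.out = 2 * n_studies),
               seed = seed)
}

expect_scaled_equal <- function(a, b, tol, label = NULL) {
  expect_lt(max(abs(a - b) / (1 + abs(a))), tol, label = label)
}

# absolute agreement at one unit in the last printed decimal
expect_within <- function(x, target, tol = 0.01) {
  expect_lt(abs(x - target), tol, label = deparse(substitute(x)))
}
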