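# shared fixtures and independent oracles, built in code

# a minimal complete F1-LD-F2 cohort around a single variable `y`
make_toy_cohort <- function(n1 = 4, n2 = 3, values = NULL, seed = 1) {
  n <- n1 + n2
  coh <- expand.grid(phase = c("pre", "post"), time = c("T1", "T10"),
                     subject_id = sprintf("S%02d", seq_len(n)),
                     stringsAsFactors = FALSE)
  coh$treatment <- ifelse(coh$subject_id %in% sprintf("S%02d", seq_len(n1)),
                          "-55C", "-110C")
  if (is.null(values)) {
    set.seed(seed)
    values <- stats::rnorm(nrow(coh))
  }
  coh$y <- values
  coh[, c("subject_id", "treatment", "time", "phase", "y")]
}

# brute-force pairwise definition of the relative effect of each condition:
# p_c = mean over (z in pooled set, x in condition c) of 1(z < x) + .5 1(z = x)
brute_force_relative_effects <- function(values, cond) {
  pool <- values
  vapply(split(values, cond), function(xs) {
    mean(outer(pool, xs, function(z, x) (z < x) + 0.5 * (z == x)))
  }, numeric(1))
}

# permutation oracle for the phase main effect: within-subject pre/post
# label flips (independently at each time level), recomputing the
# ANOVA-type statistic for each flip pattern
phase_permutation_p <- function(Y, group, n_perm = 10000, seed = 1) {
  obs <- cryohrv:::ats_engine(Y, group, effects = "Phase")
  set.seed(seed)
  N <- nrow(Y)
  stats <- replicate(n_perm, {
    Yp <- Y
    sw1 <- stats::runif(N) < 0.5
    sw2 <- stats::runif(N) < 0.5
    Yp[sw1, c(1, 2)] <- Y[sw1, c(2, 1)]
    Yp[sw2, c(3, 4)] <- Y[sw2, c(4, 3)]
    cryohrv:::ats_engine(Yp, group, effects = "Phase")$statistic
  })
  list(p_ats = obs$p_value, p_perm = mean(stats >= obs$statistic - 1e-12))
}
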