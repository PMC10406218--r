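# Shared fixtures: small simulated cohorts and brute-force oracles.

# A perfectly separable cohort: stable features never flip, so within an
# individual the non-transient community is constant and each twin's
# discriminative features are private to that twin.
separable_cohort <- function(n_twin_pairs = 10, n_features = 300,
                             frac_discriminative = 0.06,
                             depth_mean = 4000, seed = 1) {
  simulate_cohort(sim_config(
    n_twin_pairs = n_twin_pairs, n_features = n_features,
    frac_discriminative = frac_discriminative, frac_shared_core = 0.30,
    frac_transient = 0.50, transient_presence_prob = 0.85,
    presence_flip_prob = 0, tp1_extra_flip_prob = 0,
    depth_mean = depth_mean, seed = seed))
}

# Brute-force AUC: P(MZT > Self) + 0.5 P(tie) over all cross pairs.
brute_auc <- function(self, mzt) {
  cmp <- outer(mzt, self, function(m, s) (m > s) + 0.5 * (m == s))
  mean(cmp)
}

# Exhaustive Youden maximizer over every candidate threshold, used as an
# independent check of the threshold scan.
brute_best_youden <- function(self_lrs, mzt_lrs) {
  pooled <- sort(unique(c(self_lrs, mzt_lrs)))
  cands <- c(pooled[1] / 2,
             (pooled[-length(pooled)] + pooled[-1]) / 2,
             pooled[length(pooled)] * 2, pooled)
  max(vapply(cands, function(t)
    mean(self_lrs > t) + mean(mzt_lrs <= t) - 1, numeric(1)))
}

# Random count vector whose positive entries are all >= min_count.
random_counts <- function(n, min_count = 0, max_count = 50,
                          p_zero = 0.3) {
  v <- sample(min_count:max_count, n, replace = TRUE)
  v[stats::runif(n) < p_zero] <- 0L
  as.integer(v)
}
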