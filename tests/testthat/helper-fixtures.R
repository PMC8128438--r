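# Shared fixtures: small simulated datasets and Monte-Carlo oracles.

# Monte-Carlo moments of |dmu0 + ddelta|, ddelta ~ Normal(0, 2 * gamma * z):
# the independent oracle for the folded-normal closed forms.
mc_folded <- function(dmu0, gamma, z, n = 1e6, seed = 101) {
  set.seed(seed)
  dd <- rnorm(n, 0, sqrt(2 * gamma * z))
  x <- abs(dmu0 + dd)
  flip <- sign(dmu0 + dd) != sign(dmu0)
  soa <- ifelse(dd > -dmu0, dd, -dd)   # piecewise SoA definition, dmu0 >= 0
  list(mean = mean(x), var = var(x), se_mean = sd(x) / sqrt(n),
       se_var = sd((x - mean(x))^2) / sqrt(n),
       p_flip = mean(flip),
       soa_mean = mean(soa), se_soa = sd(soa) / sqrt(n))
}

# A small complete simulated dataset shared across tests.
small_sim <- local({
  cache <- NULL
  function(n_subjects = 4, seed = 11) {
    if (is.null(cache)) {
      cache <<- simulate_experiment(sim_config(n_subjects = n_subjects,
                                               seed = seed))
    }
    cache
  }
})

# A deterministic toy trial table with hand-set ratings.
toy_trials <- function() {
  data.frame(
    subject = 1, trial = 1:4, condition = "neutral",
    vr0_a = c(0.8, 0.8, 0.6, 0.5), vr0_b = c(0.3, 0.3, 0.5, 0.5),
    vcr0_a = c(0.5, 0.5, 0.6, 0.4), vcr0_b = c(0.7, 0.7, 0.6, 0.4),
    choice = c("b", "b", "a", "a"), rt_s = c(1.5, 2.0, 2.5, 3.0),
    confidence = c(0.7, 0.8, 0.6, 0.5), effort = c(0.3, 0.4, 0.5, 0.6),
    vr1_a = c(0.4, 0.7, 0.7, 0.5), vr1_b = c(0.6, 0.2, 0.4, 0.5),
    vcr1_a = c(0.6, 0.5, 0.7, 0.4), vcr1_b = c(0.8, 0.7, 0.7, 0.4),
    stringsAsFactors = FALSE
  )
}
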