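test_that("sigmoid confidence behaves like the Gaussian tail probability", {
  expect_equal(confidence_given_belief(0, 1, 1), 0.5)
  # moment-matched sigmoid at dmu=1, sigma=0.5 each: s(pi/sqrt(3))
  expect_equal(confidence_given_belief(1, 0.5, 0.5),
               plogis(pi / sqrt(3)), tolerance = 1e-12)
  # within 0.02 of the exact Gaussian tail P(N(1,1) > 0) = pnorm(1)
  expect_lt(abs(confidence_given_belief(1, 0.5, 0.5) - pnorm(1)), 0.02)
  # depends on |dmu| only
  expect_equal(confidence_given_belief(-1, 0.5, 0.5),
               confidence_given_belief(1, 0.5, 0.5))
  expect_error(confidence_given_belief(1, -1, 1), "positive")
})

test_that("posterior variance is a linear precision update", {
  expect_equal(posterior_variance(2.5, 1, 0), 2.5)
  expect_equal(posterior_variance(2.5, 0, 7), 2.5)
  expect_equal(posterior_variance(1, 1, 1), 0.5)
  # exact precision-gain identity: 1/sigma(z) - 1/sigma0 = beta * z
  z <- seq(0, 5, by = 0.5)
  expect_equal(1 / posterior_variance(1.7, 0.3, z) - 1 / 1.7, 0.3 * z)
})

test_that("folded-normal moments match the Monte-Carlo oracle", {
  # closed forms at the origin
  expect_equal(expected_abs_dmu(0.4, 1, 0), 0.4)
  expect_equal(expected_abs_dmu(-0.4, 0, 3), 0.4)
  expect_equal(variance_abs_dmu(0.4, 1, 0), 0)
  # dmu0 = 0, 2*gamma*z = 2: E|X| = 2/sqrt(pi), V = 2 - 4/pi
  expect_equal(expected_abs_dmu(0, 1, 1), 2 / sqrt(pi), tolerance = 1e-10)
  expect_equal(variance_abs_dmu(0, 1, 1), 2 - 4 / pi, tolerance = 1e-10)
  # Monte-Carlo oracle on a parameter battery. Against a stochastic oracle a
  # correct closed form still lands beyond 3 SE at ~0.3% of points, so the
  # family-level check is: every point within 5 SE, >= 95% within 3 SE.
  cases <- expand.grid(dmu0 = c(0, 0.5, 2), gamma = c(0.2, 1), z = c(0.5, 1))
  dev_mean <- dev_var <- numeric(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    mc <- mc_folded(cs$dmu0, cs$gamma, cs$z, n = 1e6, seed = 100 + i)
    dev_mean[i] <- abs(expected_abs_dmu(cs$dmu0, cs$gamma, cs$z) - mc$mean) /
      mc$se_mean
    dev_var[i] <- abs(variance_abs_dmu(cs$dmu0, cs$gamma, cs$z) - mc$var) /
      mc$se_var
  }
  expect_lt(max(dev_mean, dev_var), 5)
  expect_gte(mean(c(dev_mean, dev_var) < 3), 0.95)
})

test_that("expected absolute difference dominates the prior and grows with z", {
  z <- c(0, 0.1, 0.5, 1, 2, 5)
  for (d in c(0, 0.3, 1.5)) {
    e <- expected_abs_dmu(d, 0.5, z)
    expect_true(all(e >= abs(d) - 1e-12))
    expect_true(all(diff(e) > 0))
  }
  expect_equal(expected_abs_dmu(0.3, 0.5, 0), 0.3)  # equality iff gamma*z = 0
})

test_that("expected confidence reduces to the prior at z = 0 and increases in z", {
  expect_equal(expected_confidence(0.6, 1.4, 0.5, 0.2, 0),
               confidence_given_belief(0.6, 1.4, 1.4))
  z <- c(0, 0.5, 1, 2, 5)
  expect_true(all(diff(expected_confidence(1, 1, 1, 1, z)) > 0))
  expect_true(all(diff(expected_confidence(0.3, 2, 0.4, 0, z)) > 0))
  expect_true(all(diff(expected_confidence(0.3, 2, 0, 0.4, z)) > 0))
  # flat when both efficacies vanish
  expect_equal(diff(expected_confidence(0.3, 2, 0, 0, z)),
               rep(0, length(z) - 1))
  # independent re-evaluation of the composed closed form
  e <- expected_abs_dmu(0, 1, 1)       # = 2/sqrt(pi)
  v <- 2 - e^2
  s_z <- 1 / (1 / 1 + 0 * 1)
  expect_equal(expected_confidence(0, 1, 0, 1, 1),
               plogis(pi * e / sqrt(6 * (s_z + v / 2))), tolerance = 1e-12)
})

test_that("change-of-mind probability matches its sign-flip oracle", {
  expect_equal(change_of_mind_prob(0.5, 0, 3), 0)
  expect_equal(change_of_mind_prob(0.5, 1, 0), 0)
  expect_equal(change_of_mind_prob(0, 1, 1), 0.5)
  expect_true(all(change_of_mind_prob(seq(-2, 2, 0.25), 0.7, 1.3) <= 0.5))
  mc <- mc_folded(1, 1, 1, n = 1e6)
  se_flip <- sqrt(mc$p_flip * (1 - mc$p_flip) / 1e6)
  expect_lt(abs(change_of_mind_prob(1, 1, 1) - mc$p_flip),
            max(3 * se_flip, 0.001))
  expect_lt(abs(change_of_mind_prob(1, 1, 1) - mc$p_flip), 0.02)
  # decreasing in |dmu0|
  q <- change_of_mind_prob(seq(0, 2, 0.2), 0.5, 1)
  expect_true(all(diff(q) < 0))
})

test_that("expected spreading of alternatives matches the piecewise-definition oracle", {
  expect_equal(expected_soa(0.5, 0, 2), 0)
  expect_equal(expected_soa(0.5, 1, 0), 0)
  expect_equal(expected_soa(0, 1, 1), 2 / sqrt(pi), tolerance = 1e-10)
  mc <- mc_folded(1, 1, 1, n = 1e6)
  expect_lt(abs(expected_soa(1, 1, 1) - mc$soa_mean), 3 * mc$se_soa)
  # increasing in z, decreasing in |dmu0|
  expect_true(all(diff(expected_soa(0.4, 0.5, c(0.1, 0.5, 1, 2))) > 0))
  expect_true(all(diff(expected_soa(seq(0, 2, 0.25), 0.5, 1)) < 0))
})

test_that("certainty gain is the precision-gain product", {
  expect_equal(certainty_gain(0, 4), 0)
  expect_equal(certainty_gain(2, 0), 0)
  expect_equal(certainty_gain(2, 3), 6)
})

test_that("parameter and input constructors enforce invariants", {
  expect_error(mcd_params(alpha = 0), "alpha")
  expect_error(mcd_params(beta = -1), "beta")
  expect_error(mcd_params(kR = 0), "kR")
  expect_error(trial_inputs(0.5, 0), "sigma0")
  expect_error(trial_inputs(0.5, 1, "weird"), "condition")
  ti <- trial_inputs(c(0.1, -0.2), 1.5, c("neutral", "penalized"))
  expect_equal(nrow(ti), 2)
})

test_that("EVC applies condition-effective importance and cost", {
  p <- mcd_params(alpha = 0.1, beta = 0.5, gamma = 0.1, R = 1, kR = 2,
                  kAlpha = 0.3)
  z <- c(0, 1, 2)
  neutral <- evc(z, trial_inputs(0.4, 1.5, "neutral"), p)
  conseq <- evc(z, trial_inputs(0.4, 1.5, "consequential"), p)
  penal <- evc(z, trial_inputs(0.4, 1.5, "penalized"), p)
  pc <- expected_confidence(0.4, 1.5, 0.5, 0.1, z)
  expect_equal(neutral, pc - 0.1 * z)
  expect_equal(conseq, 2 * pc - 0.1 * z)
  expect_equal(penal, pc - 0.4 * z)
  expect_equal(evc(0, trial_inputs(0.4, 1.5), p), pc[1])
})

test_that("optimizer agrees with a brute-force grid argmax", {
  set.seed(42)
  n_cases <- 25
  for (k in seq_len(n_cases)) {
    p <- mcd_params(alpha = exp(runif(1, log(0.02), log(0.3))),
                    beta = exp(runif(1, log(0.05), log(1.5))),
                    gamma = exp(runif(1, log(0.01), log(0.5))),
                    R = 1, kR = exp(runif(1, 0, log(3))),
                    kAlpha = runif(1, 0, 0.2))
    ti <- trial_inputs(runif(1, -1, 1), runif(1, 1, 3),
                       sample(c("neutral", "consequential", "penalized"), 1))
    got <- suppressWarnings(optimize_z(ti, p))$z_opt
    zg <- seq(0, 10, length.out = 1e5)
    brute <- zg[which.max(evc(zg, ti, p))]
    expect_lt(abs(got - brute), 1e-4)
  }
})

test_that("optimizer returns zero effort when effort cannot pay off", {
  ti <- trial_inputs(0.4, 1.5)
  expect_equal(optimize_z(ti, mcd_params(beta = 0, gamma = 0))$z_opt, 0)
  expect_equal(
    optimize_z(ti, mcd_params(alpha = 1e6, beta = 0.5, gamma = 0.1))$z_opt, 0)
})

test_that("optimizer warns when the maximizer is truncated at z_max", {
  ti <- trial_inputs(0.05, 2)
  p <- mcd_params(alpha = 1e-5, beta = 0.5, gamma = 0.2)
  expect_warning(optimize_z(ti, p), "z_max")
})

test_that("optimal effort respects the value of the zero-effort fallback", {
  set.seed(7)
  for (k in 1:10) {
    p <- mcd_params(alpha = runif(1, 0.02, 0.3), beta = runif(1, 0, 1),
                    gamma = runif(1, 0, 0.3))
    ti <- trial_inputs(runif(1, -1, 1), runif(1, 1, 3))
    opt <- suppressWarnings(optimize_z(ti, p))
    expect_gte(opt$evc_opt, evc(0, ti, p) - 1e-10)
  }
})

test_that("trial prediction composes the corollary quantities at z_opt", {
  ti <- trial_inputs(c(0.3, -0.6), c(1.5, 2), c("neutral", "neutral"))
  p <- mcd_params()
  pred <- predict_trial(ti, p)
  opt <- optimize_z(ti, p)
  expect_equal(pred$z_opt, opt$z_opt)
  expect_equal(pred$confidence,
               expected_confidence(ti$dmu0, ti$sigma0, p$beta, p$gamma,
                                   pred$z_opt))
  expect_equal(pred$q_change,
               change_of_mind_prob(ti$dmu0, p$gamma, pred$z_opt))
  expect_equal(pred$certainty_gain, p$beta * pred$z_opt)
  expect_true(all(pred$sigma_post <= ti$sigma0))
  # no efficacy: all decision-related outputs collapse
  p0 <- mcd_params(beta = 0, gamma = 0)
  pred0 <- predict_trial(ti, p0)
  expect_equal(pred0$z_opt, c(0, 0))
  expect_equal(pred0$q_change, c(0, 0))
  expect_equal(pred0$soa_expected, c(0, 0))
  expect_equal(pred0$certainty_gain, c(0, 0))
  expect_equal(pred0$confidence,
               confidence_given_belief(ti$dmu0, ti$sigma0, ti$sigma0))
})

test_that("optimal effort responds monotonically to cost and importance", {
  ti <- trial_inputs(0.3, 1.5)
  alphas <- c(0.02, 0.05, 0.1, 0.2, 0.5)
  z_by_alpha <- vapply(alphas, function(a) {
    optimize_z(ti, mcd_params(alpha = a))$z_opt
  }, numeric(1))
  expect_true(all(diff(z_by_alpha) <= 1e-8))
  p <- mcd_params()
  z_n <- optimize_z(trial_inputs(0.3, 1.5, "neutral"), p)$z_opt
  z_c <- optimize_z(trial_inputs(0.3, 1.5, "consequential"), p)$z_opt
  z_p <- optimize_z(trial_inputs(0.3, 1.5, "penalized"), p)$z_opt
  expect_gte(z_c, z_n)
  expect_lte(z_p, z_n)
  # attained confidence can only improve on the zero-effort level
  pred <- predict_trial(trial_inputs(0.3, 1.5), p)
  expect_gte(pred$confidence,
             expected_confidence(0.3, 1.5, p$beta, p$gamma, 0) - 1e-10)
})
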