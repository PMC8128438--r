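# Fits in these tests use reduced restart/iteration budgets: the properties
# under test (determinism, factorization, interface contracts) do not depend
# on reaching the exact posterior mode.
fast_opts <- list(n_restarts = 2, maxit = 80, seed = 7)

test_that("fitting is deterministic given data, seed and options", {
  sim <- small_sim()
  tr <- sim$trials[sim$trials$subject == 1, ]
  f1 <- fit_subject(tr, fitted_vars = c("log_rt", "effort"),
                    options = fast_opts)
  f2 <- fit_subject(tr, fitted_vars = c("log_rt", "effort"),
                    options = fast_opts)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$log_evidence, f2$log_evidence)
  expect_identical(f1$postdictions, f2$postdictions)
})

test_that("restricted fits ignore excluded variable columns entirely", {
  sim <- small_sim()
  tr <- sim$trials[sim$trials$subject == 2, ]
  f_ref <- fit_subject(tr, fitted_vars = c("log_rt", "effort"),
                       options = fast_opts)
  tr_perm <- tr
  set.seed(1)
  perm <- sample(nrow(tr))
  for (cl in c("confidence", "vr1_a", "vr1_b", "vcr1_a", "vcr1_b")) {
    tr_perm[[cl]] <- tr[[cl]][perm]
  }
  f_perm <- fit_subject(tr_perm, fitted_vars = c("log_rt", "effort"),
                        options = fast_opts)
  expect_identical(f_ref$theta, f_perm$theta)
  expect_identical(f_ref$diagnostics$best_objective,
                   f_perm$diagnostics$best_objective)
})

test_that("fit results carry a valid Laplace approximation", {
  sim <- small_sim()
  tr <- sim$trials[sim$trials$subject == 3, ]
  fit <- fit_subject(tr, options = fast_opts)
  expect_equal(fit$vcov, t(fit$vcov))
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_true(is.finite(fit$log_evidence))
  expect_true(all(vapply(fit$postdictions, function(x) all(is.finite(x)),
                         TRUE)))
  expect_error(fit_subject(tr[1:5, ]), "at least 10")
  expect_error(fit_subject(tr, fitted_vars = character(0)), "non-empty")
})

test_that("out-of-sample prediction refuses overlapping variable sets", {
  sim <- small_sim()
  tr <- sim$trials[sim$trials$subject == 1, ]
  fit <- fit_subject(tr, fitted_vars = c("log_rt", "effort"),
                     options = fast_opts)
  expect_error(predict_out_of_sample(fit, tr, c("effort", "confidence")),
               "fitted")
  oos <- predict_out_of_sample(fit, tr, c("confidence", "com", "soa",
                                          "gain"))
  expect_equal(names(oos), c("confidence", "com", "soa", "gain"))
  expect_equal(nrow(oos), nrow(tr))
  expect_true(all(is.finite(unlist(oos))))
})

test_that("core parameters are identified up to the fixed R scale", {
  # R is fixed to 1 in the fit; the latent prediction map over a test grid
  # must distinguish distinct core parameter vectors (numeric injectivity)
  grid <- trial_inputs(dmu0 = rep(c(0.1, 0.3, 0.6), each = 2),
                       sigma0 = rep(c(1.2, 2.0), 3))
  base <- mcd_params(alpha = 0.05, beta = 0.4, gamma = 0.08, R = 1)
  pred_base <- predict_trial(grid, base)
  variants <- list(
    mcd_params(alpha = 0.07, beta = 0.4, gamma = 0.08, R = 1),
    mcd_params(alpha = 0.05, beta = 0.6, gamma = 0.08, R = 1),
    mcd_params(alpha = 0.05, beta = 0.4, gamma = 0.12, R = 1)
  )
  for (v in variants) {
    pv <- predict_trial(grid, v)
    dist <- max(abs(unlist(pv[c("z_opt", "confidence", "q_change")]) -
                      unlist(pred_base[c("z_opt", "confidence",
                                         "q_change")])))
    expect_gt(dist, 1e-3)
  }
})

test_that("permutation chance levels are near zero and reproducible", {
  sim <- small_sim()
  tr <- sim$trials
  preds <- data.frame(confidence = tr$confidence + rnorm(nrow(tr), 0, 0.1),
                      log_rt = log(tr$rt_s))
  ch1 <- permutation_chance_level(tr, preds, n_perm = 200, seed = 5)
  ch2 <- permutation_chance_level(tr, preds, n_perm = 200, seed = 5)
  expect_identical(ch1, ch2)
  # shuffling destroys association: thresholds are small positive numbers
  expect_true(all(ch1 < 0.25))
  expect_true(all(ch1 > 0))
  expect_error(permutation_chance_level(tr, preds, n_perm = 10), "200")
})

test_that("permutation chance level decreases with trial count", {
  set.seed(42)
  mk <- function(n_tr, n_sub = 6) {
    do.call(rbind, lapply(seq_len(n_sub), function(s) {
      data.frame(subject = s, trial = seq_len(n_tr), condition = "neutral",
                 vr0_a = runif(n_tr), vr0_b = runif(n_tr),
                 vcr0_a = runif(n_tr), vcr0_b = runif(n_tr),
                 choice = "a", rt_s = exp(rnorm(n_tr)),
                 confidence = runif(n_tr), effort = runif(n_tr),
                 vr1_a = runif(n_tr), vr1_b = runif(n_tr),
                 vcr1_a = runif(n_tr), vcr1_b = runif(n_tr),
                 stringsAsFactors = FALSE)
    }))
  }
  tr_small <- mk(15)
  tr_big <- mk(120)
  ch_small <- permutation_chance_level(
    tr_small, data.frame(log_rt = rnorm(nrow(tr_small))), 200, seed = 2)
  ch_big <- permutation_chance_level(
    tr_big, data.frame(log_rt = rnorm(nrow(tr_big))), 200, seed = 2)
  expect_lt(ch_big, ch_small)
})

test_that("recovery harness reports and a shuffled-truth control is null", {
  # tiny smoke recovery: structure of the report, not statistical quality
  rec <- parameter_recovery(sim_config(n_subjects = 3, seed = 17),
                            fit_options = list(n_restarts = 1, maxit = 40,
                                               seed = 2))
  expect_equal(rec$summary$parameter, c("alpha", "beta", "gamma"))
  expect_true(all(is.finite(rec$summary$rank_correlation)))
  expect_equal(nrow(rec$estimates), 3)
  # negative control: correlating estimates against shuffled truth gives
  # rank correlations centered on zero (exact under permutation symmetry)
  set.seed(9)
  est <- rnorm(12)
  truth <- rnorm(12)
  null_rs <- replicate(200, cor(est, sample(truth), method = "spearman"))
  expect_lt(abs(mean(null_rs)), 0.1)
})
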