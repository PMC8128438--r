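# Generative simulator of the full experiment: subjects, trials, and all six
# dependent variables under the MCD generative process. Emulates the design
# of the source study (41 subjects; 60 neutral + 7 consequential + 7
# penalized two-item food choices per subject; all ratings on [0,1] scales)
# so that fitting, prediction and analysis are testable without any external
# data.

#' Simulation configuration
#'
#' Bundles every knob of the experiment simulator. Defaults emulate the
#' reference study design: 41 subjects, 60/7/7 trials per condition, value
#' ratings drawn from Beta(2,2) and certainty ratings from Beta(4,2) on the
#' unit scale, and a log-normal population of subject-level MCD parameters
#' around the package's default [mcd_params()], calibrated so the simulated
#' group shows a realistic change-of-mind rate (~15-25%), mean confidence
#' around 0.7, and small positive spreading of alternatives and certainty
#' gain.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_neutral,n_consequential,n_penalized Trials per condition.
#' @param rating_shape1,rating_shape2 Beta parameters of value ratings.
#' @param certainty_shape1,certainty_shape2 Beta parameters of certainty
#'   ratings.
#' @param pop_location An [mcd_params()] giving the population median of each
#'   core parameter.
#' @param pop_scale Named numeric, SDs of the log-normal population draws for
#'   `alpha`, `beta`, `gamma`, `kR`, `kAlpha` (0 makes every subject
#'   identical to the location).
#' @param obs An [observation_params()] giving the affine output maps and
#'   noise SDs shared across subjects; per-subject intercept jitter is added
#'   with SD `map_jitter_sd`.
#' @param map_jitter_sd Gaussian SD of per-subject affine-intercept jitter.
#' @param epsilon Certainty floor used by the input proxies.
#' @param z_max Upper bound of the effort search interval.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 41, n_neutral = 60, n_consequential = 7,
                       n_penalized = 7,
                       rating_shape1 = 2, rating_shape2 = 2,
                       certainty_shape1 = 4, certainty_shape2 = 2,
                       pop_location = mcd_params(),
                       pop_scale = c(alpha = 0.3, beta = 0.3, gamma = 0.3,
                                     kR = 0.2, kAlpha = 0.2),
                       obs = observation_params(),
                       map_jitter_sd = 0.05,
                       epsilon = 0.01, z_max = 10, seed = 1L) {
  stopifnot(n_subjects >= 1, n_neutral >= 0, n_consequential >= 0,
            n_penalized >= 0, all(pop_scale >= 0))
  structure(list(n_subjects = n_subjects, n_neutral = n_neutral,
                 n_consequential = n_consequential,
                 n_penalized = n_penalized,
                 rating_shape1 = rating_shape1, rating_shape2 = rating_shape2,
                 certainty_shape1 = certainty_shape1,
                 certainty_shape2 = certainty_shape2,
                 pop_location = pop_location, pop_scale = pop_scale,
                 obs = obs, map_jitter_sd = map_jitter_sd,
                 epsilon = epsilon, z_max = z_max, seed = as.integer(seed)),
            class = "sim_config")
}

# One RNG stream per subject, derived from (seed, subject id) so that
# per-subject simulation is reproducible independently of execution order.
subject_seed <- function(seed, subject) {
  (as.integer(seed) + 99991L * as.integer(subject)) %% 2147483647L
}

#' Draw subject-level parameters from the population model
#'
#' Core parameters are drawn log-normally around the population location
#' (respecting positivity); affine-map intercepts get Gaussian jitter around
#' the configured maps; slopes and noise SDs are shared. Uses the current
#' RNG state.
#'
#' @param config A [sim_config()].
#' @return List with elements `core` ([mcd_params()]) and `obs`
#'   ([observation_params()]).
#' @export
sample_subject_params <- function(config) {
  loc <- config$pop_location
  sc <- config$pop_scale
  draw <- function(m, s) m * exp(stats::rnorm(1, 0, s))
  core <- mcd_params(alpha = draw(loc$alpha, sc[["alpha"]]),
                     beta = draw(loc$beta, sc[["beta"]]),
                     gamma = draw(loc$gamma, sc[["gamma"]]),
                     R = loc$R,
                     kR = draw(loc$kR, sc[["kR"]]),
                     kAlpha = draw(loc$kAlpha, sc[["kAlpha"]]))
  obs <- config$obs
  if (config$map_jitter_sd > 0) {
    for (v in names(obs$maps)) {
      obs$maps[[v]]$intercept <- obs$maps[[v]]$intercept +
        stats::rnorm(1, 0, config$map_jitter_sd)
    }
  }
  list(core = core, obs = obs)
}

#' Draw the pre-choice portion of a subject's trial table
#'
#' Value ratings iid Beta, certainty ratings iid Beta, condition labels laid
#' out per the 60/7/7 design and shuffled. Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `trial`, `condition`, `vr0_a`, `vr0_b`,
#'   `vcr0_a`, `vcr0_b`.
#' @export
sample_trial_inputs <- function(config) {
  n <- config$n_neutral + config$n_consequential + config$n_penalized
  cond <- sample(rep(c("neutral", "consequential", "penalized"),
                     c(config$n_neutral, config$n_consequential,
                       config$n_penalized)))
  data.frame(
    trial = seq_len(n),
    condition = cond,
    vr0_a = stats::rbeta(n, config$rating_shape1, config$rating_shape2),
    vr0_b = stats::rbeta(n, config$rating_shape1, config$rating_shape2),
    vcr0_a = stats::rbeta(n, config$certainty_shape1, config$certainty_shape2),
    vcr0_b = stats::rbeta(n, config$certainty_shape1, config$certainty_shape2),
    stringsAsFactors = FALSE
  )
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Latent value units and rating units are identified (the identity read-out
# map): post-choice ratings are pre-choice ratings plus the latent mode
# perturbations, clipped to the rating scale. Isolated here so an alternative
# read-out can be swapped in.
rating_readout <- function(pre_rating, delta) clip01(pre_rating + delta)

#' Simulate the outcome of trials given subject parameters
#'
#' Completes a pre-choice trial table under the MCD generative process:
#' computes the MCD-optimal allocation `z_opt` per trial, draws per-option
#' mode perturbations `delta ~ Normal(0, gamma * z_opt)`, takes the choice as
#' the sign of the post-effort mode difference (exact ties broken at
#' random), and emits all observed variables: confidence (the sigmoid
#' confidence at the realized post-effort belief, plus noise), RT (log-RT
#' affine in `z_opt`, plus noise), effort rating (affine in `z_opt`, plus
#' noise, clipped), post-choice value ratings (pre ratings plus perturbation,
#' clipped), and post-choice certainty ratings (pre ratings plus the mapped
#' precision gain, plus noise, clipped). Latent per-trial quantities are
#' returned alongside for simulator-vs-theory checks.
#'
#' @param pre Data frame from [sample_trial_inputs()].
#' @param core An [mcd_params()].
#' @param obs An [observation_params()].
#' @param epsilon,z_max See [sim_config()].
#' @return The completed trial data frame, with latent columns `z_opt`,
#'   `q_change`, `soa_latent`, `dmu0`, `dmu_post`.
#' @export
simulate_trial <- function(pre, core, obs = observation_params(),
                           epsilon = 0.01, z_max = 10) {
  n <- nrow(pre)
  inputs <- proxy_inputs(pre, epsilon = epsilon)
  pred <- predict_trial(inputs, core, z_max = z_max)
  z <- pred$z_opt
  delta_a <- stats::rnorm(n, 0, sqrt(core$gamma * z))
  delta_b <- stats::rnorm(n, 0, sqrt(core$gamma * z))
  dmu_post <- inputs$dmu0 + (delta_a - delta_b)
  tie <- dmu_post == 0
  choice <- ifelse(dmu_post > 0, "a", "b")
  if (any(tie)) choice[tie] <- sample(c("a", "b"), sum(tie), replace = TRUE)
  sigma_post <- pred$sigma_post
  conf_latent <- confidence_given_belief(dmu_post, sigma_post, sigma_post)
  gain_latent <- core$beta * z
  # realized SoA per the piecewise definition on the latent modes
  ddelta <- delta_a - delta_b
  soa_latent <- ifelse(choice == "a", ddelta, -ddelta)
  nd <- obs$noise_sd
  out <- pre
  out$choice <- choice
  out$rt_s <- exp(apply_map(obs$maps$log_rt, z) +
                    stats::rnorm(n, 0, nd[["log_rt"]]))
  out$confidence <- clip01(apply_map(obs$maps$confidence, conf_latent) +
                             stats::rnorm(n, 0, nd[["confidence"]]))
  out$effort <- clip01(apply_map(obs$maps$effort, z) +
                         stats::rnorm(n, 0, nd[["effort"]]))
  out$vr1_a <- rating_readout(pre$vr0_a, delta_a)
  out$vr1_b <- rating_readout(pre$vr0_b, delta_b)
  gain_shift <- apply_map(obs$maps$gain, gain_latent) -
    obs$maps$gain$intercept
  out$vcr1_a <- clip01(pre$vcr0_a + gain_shift +
                         stats::rnorm(n, 0, nd[["gain"]]))
  out$vcr1_b <- clip01(pre$vcr0_b + gain_shift +
                         stats::rnorm(n, 0, nd[["gain"]]))
  out$z_opt <- z
  out$q_change <- pred$q_change
  out$soa_latent <- soa_latent
  out$dmu0 <- inputs$dmu0
  out$dmu_post <- dmu_post
  out
}

#' Simulate the full multi-subject experiment
#'
#' Draws per-subject parameters and trial tables, simulates every trial, and
#' returns both the trial table (in the canonical CSV schema plus latent
#' columns) and the ground-truth parameter table for recovery studies. Each
#' subject uses an RNG stream seeded from `(seed, subject id)`, so output is
#' reproducible and independent of execution order.
#'
#' @param config A [sim_config()].
#' @return List with `trials` (data frame, `n_subjects * trials_per_subject`
#'   rows) and `truth` (one row per subject: the generating core parameters).
#' @export
simulate_experiment <- function(config = sim_config()) {
  trials <- vector("list", config$n_subjects)
  truth <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    set.seed(subject_seed(config$seed, s))
    # reject parameter draws whose effort optima saturate the search bound
    # on this subject's trials: such behavior is an artifact of the finite
    # z interval (the optimizer warns about it), not a regime worth
    # emulating
    for (try in 1:20) {
      pars <- sample_subject_params(config)
      pre <- sample_trial_inputs(config)
      tr <- withCallingHandlers(
        simulate_trial(pre, pars$core, pars$obs,
                       epsilon = config$epsilon, z_max = config$z_max),
        warning = function(w) invokeRestart("muffleWarning"))
      if (max(tr$z_opt) < config$z_max - 1e-3) break
    }
    if (max(tr$z_opt) >= config$z_max - 1e-3) {
      warning("subject ", s, ": effort optima remain at z_max after 20 ",
              "parameter redraws", call. = FALSE)
    }
    tr <- cbind(subject = s, tr)
    trials[[s]] <- tr
    truth[[s]] <- data.frame(subject = s,
                             alpha = pars$core$alpha, beta = pars$core$beta,
                             gamma = pars$core$gamma, R = pars$core$R,
                             kR = pars$core$kR, kAlpha = pars$core$kAlpha)
  }
  list(trials = do.call(rbind, trials), truth = do.call(rbind, truth))
}
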