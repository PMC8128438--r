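# Observation model: pre-choice ratings -> model inputs, latent predictions ->
# observable variables via affine nuisance maps, and trial likelihoods.

mcd_variables <- c("confidence", "soa", "gain", "log_rt", "effort", "com")
mcd_continuous_vars <- c("confidence", "soa", "gain", "log_rt", "effort")

#' Affine nuisance map
#'
#' Linear rescaling from a latent model variable to its empirical counterpart,
#' with a positivity constraint on the slope so the map cannot invert the
#' latent ordering.
#'
#' @param intercept Numeric.
#' @param slope Positive numeric.
#' @return A list of class `affine_map`.
#' @export
affine_map <- function(intercept = 0, slope = 1) {
  if (slope <= 0) stop("`slope` must be positive", call. = FALSE)
  structure(list(intercept = intercept, slope = slope), class = "affine_map")
}

apply_map <- function(map, x) map$intercept + map$slope * x

#' Observation (nuisance) parameters
#'
#' One [affine_map()] plus one Gaussian noise SD per continuous output
#' variable. The latent quantity behind each map: expected confidence for
#' `confidence`, expected spreading of alternatives for `soa`, the precision
#' gain `beta * z_opt` for `gain`, and the optimal allocation `z_opt` itself
#' for both `log_rt` and `effort`. The binary change-of-mind variable has no
#' nuisance map: its success probability is the unmapped `Q(z_opt)`.
#'
#' @param maps Named list of [affine_map()]s for
#'   `confidence`, `soa`, `gain`, `log_rt`, `effort`.
#' @param noise_sd Named positive numeric vector, same names.
#' @return A list of class `observation_params`.
#' @export
observation_params <- function(maps = NULL, noise_sd = NULL) {
  default_maps <- list(
    confidence = affine_map(0, 1),
    soa = affine_map(0, 1),
    gain = affine_map(0, 0.1),
    log_rt = affine_map(0.4, 0.4),
    effort = affine_map(0.15, 0.25)
  )
  default_sd <- c(confidence = 0.08, soa = 0.05, gain = 0.05,
                  log_rt = 0.15, effort = 0.10)
  if (!is.null(maps)) default_maps[names(maps)] <- maps
  if (!is.null(noise_sd)) default_sd[names(noise_sd)] <- noise_sd
  stopifnot(all(vapply(default_maps, inherits, TRUE, "affine_map")),
            all(default_sd > 0))
  structure(list(maps = default_maps, noise_sd = default_sd),
            class = "observation_params")
}

validate_ratings <- function(trials, cols) {
  for (cl in cols) {
    bad <- which(trials[[cl]] < 0 | trials[[cl]] > 1)
    if (length(bad)) {
      stop(sprintf("rating column `%s` out of [0,1] at row(s) %s",
                   cl, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(trials)
}

#' Model inputs from pre-choice ratings
#'
#' Empirical proxies for the prior decision state: the prior mode difference
#' is the pre-choice value-rating difference, `dmu0 = vr0_a - vr0_b`, and the
#' prior precision is the mean pre-choice certainty rating,
#' `1/sigma0 = mean(vcr0_a, vcr0_b)`, floored at `epsilon` so that fully
#' uncertain ratings yield a large but finite prior variance.
#'
#' @param trials A trial table with columns `vr0_a`, `vr0_b`, `vcr0_a`,
#'   `vcr0_b`, `condition` (see [read_trials()] for the schema).
#' @param epsilon Positive numeric floor on the mean certainty rating.
#' @return A [trial_inputs()] data frame, one row per trial.
#' @export
proxy_inputs <- function(trials, epsilon = 0.01) {
  stopifnot(epsilon > 0)
  validate_ratings(trials, c("vr0_a", "vr0_b", "vcr0_a", "vcr0_b"))
  vcr0 <- (trials$vcr0_a + trials$vcr0_b) / 2
  trial_inputs(dmu0 = trials$vr0_a - trials$vr0_b,
               sigma0 = 1 / pmax(vcr0, epsilon),
               condition = trials$condition)
}

#' Map latent MCD predictions to observable variables
#'
#' Applies the affine nuisance maps to the latent predictions: confidence to
#' observed confidence, expected SoA to observed SoA, precision gain
#' `beta * z_opt` to the certainty-rating gain, and `z_opt` to both log-RT
#' and the effort rating. Change of mind keeps the unmapped probability
#' `Q(z_opt)`. Outputs are not clipped; clipping belongs to the simulator's
#' rating emulation only.
#'
#' @param pred A data frame from [predict_trial()].
#' @param obs An [observation_params()] object.
#' @return A data frame with columns `confidence_hat`, `soa_hat`, `gain_hat`,
#'   `log_rt_hat`, `effort_hat`, `com_prob`.
#' @export
predict_observables <- function(pred, obs = observation_params()) {
  data.frame(
    confidence_hat = apply_map(obs$maps$confidence, pred$confidence),
    soa_hat = apply_map(obs$maps$soa, pred$soa_expected),
    gain_hat = apply_map(obs$maps$gain, pred$certainty_gain),
    log_rt_hat = apply_map(obs$maps$log_rt, pred$z_opt),
    effort_hat = apply_map(obs$maps$effort, pred$z_opt),
    com_prob = pred$q_change
  )
}

# Observed counterparts of the requested model variables, derived from a
# trial table: log-RT is the modeled RT quantity; SoA, certainty gain and
# the change-of-mind class come from the rating-based constructions of the
# analysis module. `com` is NA on trials excluded by tie-breaking. Only the
# requested variables are constructed, so pre-only tables can be fitted on
# effort-related variables.
observed_outcomes <- function(trials, vars = mcd_variables) {
  out <- data.frame(row.names = seq_len(nrow(trials)))
  for (v in vars) out[[v]] <- outcome_vector(trials, v)
  out
}

#' Log-likelihood of observed trials under the MCD observation model
#'
#' Sums, over the requested variables, the Gaussian log-density of each
#' observed continuous variable around its affine-mapped latent prediction
#' (log-RT being the modeled RT quantity), and the Bernoulli log-mass of the
#' observed change-of-mind class with success probability `Q(z_opt)` clamped
#' to `[1e-6, 1 - 1e-6]`. The terms decompose additively over variables, so
#' fitting a subset of variables is invariant to the content of the others.
#'
#' @param trials A trial table (full schema, post-choice columns included).
#' @param core An [mcd_params()] object.
#' @param obs An [observation_params()] object.
#' @param fitted_vars Character subset of
#'   `c("confidence", "soa", "gain", "log_rt", "effort", "com")`.
#' @param epsilon Floor for the certainty-rating proxy (see [proxy_inputs()]).
#' @param ... Passed to [optimize_z()] (`z_max`, `n_grid`, `tol`).
#' @return A single numeric: the summed log-likelihood.
#' @export
trial_loglik <- function(trials, core, obs = observation_params(),
                         fitted_vars = mcd_variables, epsilon = 0.01, ...) {
  if (!length(fitted_vars)) stop("`fitted_vars` must be non-empty",
                                 call. = FALSE)
  fitted_vars <- match.arg(fitted_vars, mcd_variables, several.ok = TRUE)
  inputs <- proxy_inputs(trials, epsilon = epsilon)
  pred <- predict_trial(inputs, core, ...)
  hat <- predict_observables(pred, obs)
  y <- observed_outcomes(trials, fitted_vars)
  ll <- 0
  for (v in intersect(fitted_vars, mcd_continuous_vars)) {
    ll <- ll + sum(stats::dnorm(y[[v]], mean = hat[[paste0(v, "_hat")]],
                                sd = obs$noise_sd[[v]], log = TRUE))
  }
  if ("com" %in% fitted_vars) {
    p <- pmin(pmax(hat$com_prob, 1e-6), 1 - 1e-6)
    keep <- !is.na(y$com)
    ll <- ll + sum(y$com[keep] * log(p[keep]) +
                     (1 - y$com[keep]) * log(1 - p[keep]))
  }
  ll
}
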