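# Per-subject estimation of MCD parameters from trial tables, out-of-sample
# prediction, parameter recovery, and permutation chance levels.
#
# Estimation target: the posterior mode (MAP) of the five free core
# parameters on the log scale, with a Laplace (finite-difference Hessian)
# approximation of the posterior covariance and model evidence. The affine
# nuisance maps and noise SDs of the fitted continuous variables are profiled
# out in closed form at every core-parameter value (flat priors on nuisance
# parameters), which makes the joint mode equal to the profile mode while
# keeping the outer optimization five-dimensional. R is fixed to 1: its
# overall scale trades off exactly with alpha's units and the affine output
# maps, so only the condition modifier kR is identified within subject.

#' Prior specification for subject-level fitting
#'
#' Independent Gaussian priors on the log core parameters
#' `log(alpha)`, `log(beta)`, `log(gamma)`, `log(kR)`,
#' `log(kAlpha + offset)`. Weakly informative by default (scale 2 covers
#' three orders of magnitude); the default locations assume the fitting
#' convention that effort is measured in log-RT units (the log-RT affine
#' slope fixed to 1, see [fit_subject()]), under which allocations of order
#' one correspond to e-fold RT changes. Nuisance (affine and noise)
#' parameters carry flat priors and are profiled out.
#'
#' @param location Named numeric, prior means of the log parameters.
#' @param scale Named positive numeric, prior SDs.
#' @param kAlpha_offset Positive offset making `log(kAlpha + offset)` finite
#'   at the boundary `kAlpha = 0`.
#' @return List of class `prior_spec`.
#' @export
prior_spec <- function(location = c(alpha = log(0.1), beta = log(0.75),
                                    gamma = log(0.12), kR = log(2),
                                    kAlpha = log(0.1)),
                       scale = c(alpha = 2, beta = 2, gamma = 2,
                                 kR = 1, kAlpha = 2),
                       kAlpha_offset = 1e-3) {
  nm <- c("alpha", "beta", "gamma", "kR", "kAlpha")
  stopifnot(all(nm %in% names(location)), all(nm %in% names(scale)),
            all(scale > 0), kAlpha_offset > 0)
  structure(list(location = location[nm], scale = scale[nm],
                 kAlpha_offset = kAlpha_offset),
            class = "prior_spec")
}

core_from_theta <- function(theta, priors) {
  mcd_params(alpha = exp(theta[[1]]), beta = exp(theta[[2]]),
             gamma = exp(theta[[3]]), R = 1, kR = exp(theta[[4]]),
             kAlpha = max(exp(theta[[5]]) - priors$kAlpha_offset, 0))
}

# Latent predictions for all trials at one core-parameter value.
latents_for <- function(inputs, core, z_max, n_grid) {
  suppressWarnings(predict_trial(inputs, core, z_max = z_max,
                                 n_grid = n_grid))
}

latent_of <- function(pred, v) {
  switch(v,
    confidence = pred$confidence,
    soa = pred$soa_expected,
    gain = pred$certainty_gain,
    log_rt = pred$z_opt,
    effort = pred$z_opt,
    stop("no latent for `", v, "`", call. = FALSE))
}

# Closed-form profile of one continuous variable's affine map and noise SD:
# OLS of observed on latent, slope clamped positive, SD at its conditional
# MLE. A fixed slope (used to pin the arbitrary effort units via the log-RT
# channel) skips the slope profiling. Returns the Gaussian log-likelihood at
# the profiled values.
profile_gaussian <- function(y, x, min_slope = 1e-6, min_sd = 1e-4,
                             fixed_slope = NULL) {
  if (!is.null(fixed_slope)) {
    slope <- fixed_slope
  } else {
    vx <- stats::var(x)
    slope <- if (is.na(vx) || vx <= 0) min_slope
             else max(stats::cov(x, y) / vx, min_slope)
  }
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  sdv <- max(sqrt(mean(res^2)), min_sd)
  list(intercept = intercept, slope = slope, sd = sdv,
       loglik = sum(stats::dnorm(res, 0, sdv, log = TRUE)))
}

#' Fit the MCD model to one subject's trials
#'
#' MAP estimation of the five free core parameters (`alpha`, `beta`,
#' `gamma`, `kR`, `kAlpha`; `R` fixed to 1 for identifiability) on the log
#' scale by multi-start Nelder-Mead on the log-joint (profiled likelihood
#' plus log-prior), followed by a Laplace approximation: posterior
#' covariance from the central-finite-difference Hessian at the mode, and
#' approximate log model evidence. All requested dependent variables are fit
#' concurrently with the single set of core parameters; the affine nuisance
#' rescaling of each continuous variable is profiled in closed form.
#'
#' @param trials Single-subject trial table, >= 10 rows.
#' @param priors A [prior_spec()].
#' @param fitted_vars Non-empty subset of
#'   `c("confidence", "soa", "gain", "log_rt", "effort", "com")`.
#' @param options List: `n_restarts` (default 8), `maxit` per restart
#'   (default 300), `seed` for the restart jitter (default 1), `z_max`
#'   (default 10), `n_grid` (grid size for the effort optimizer inside the
#'   likelihood, default 128), `hessian_step` (default 1e-3), `rt_slope`
#'   (default 1: the log-RT affine slope is fixed, pinning the arbitrary
#'   effort units — the likelihood is exactly invariant under joint
#'   rescaling of `alpha`, `beta`, `gamma` against `z`, so one slope must
#'   be fixed for the core parameters to be identifiable; set `NULL` to
#'   free it).
#' @return Object of class `mcd_fit`: posterior mode (log and natural
#'   scale), profiled observation parameters, Laplace covariance, log
#'   evidence, per-trial postdictions for the fitted variables, and
#'   convergence diagnostics.
#' @export
fit_subject <- function(trials, priors = prior_spec(),
                        fitted_vars = mcd_variables, options = list()) {
  if (!length(fitted_vars)) stop("`fitted_vars` must be non-empty",
                                 call. = FALSE)
  fitted_vars <- match.arg(fitted_vars, mcd_variables, several.ok = TRUE)
  if (nrow(trials) < 10) stop("need at least 10 trials", call. = FALSE)
  o <- utils::modifyList(list(n_restarts = 8, maxit = 300, seed = 1L,
                              z_max = 10, n_grid = 128, hessian_step = 1e-3,
                              epsilon = 0.01, rt_slope = 1,
                              polish_maxit = 60), options)
  inputs <- proxy_inputs(trials, epsilon = o$epsilon)
  y <- observed_outcomes(trials, fitted_vars)
  cont <- intersect(fitted_vars, mcd_continuous_vars)
  use_com <- "com" %in% fitted_vars
  com_keep <- !is.na(y$com)

  neg_logjoint <- function(theta) {
    core <- core_from_theta(theta, priors)
    pred <- latents_for(inputs, core, o$z_max, o$n_grid)
    ll <- 0
    for (v in cont) {
      fs <- if (v == "log_rt") o$rt_slope else NULL
      ll <- ll + profile_gaussian(y[[v]], latent_of(pred, v),
                                  fixed_slope = fs)$loglik
    }
    if (use_com) {
      p <- pmin(pmax(pred$q_change[com_keep], 1e-6), 1 - 1e-6)
      yc <- y$com[com_keep]
      ll <- ll + sum(yc * log(p) + (1 - yc) * log(1 - p))
    }
    lp <- sum(stats::dnorm(theta, priors$location, priors$scale, log = TRUE))
    if (!is.finite(ll + lp)) return(1e10)
    -(ll + lp)
  }

  set.seed(o$seed)
  starts <- matrix(priors$location, o$n_restarts, 5, byrow = TRUE)
  if (o$n_restarts > 1) {
    jit <- matrix(stats::rnorm((o$n_restarts - 1) * 5, 0, 1),
                  o$n_restarts - 1, 5)
    starts[-1, ] <- starts[-1, ] + jit
  }
  best <- NULL
  n_conv <- 0L
  for (r in seq_len(o$n_restarts)) {
    fit <- stats::optim(starts[r, ], neg_logjoint, method = "Nelder-Mead",
                        control = list(maxit = o$maxit, reltol = 1e-8))
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # quasi-Newton polish from the best simplex mode
  polish <- tryCatch(
    stats::optim(best$par, neg_logjoint, method = "BFGS",
                 control = list(maxit = o$polish_maxit, reltol = 1e-10)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value < best$value) best <- polish
  theta <- best$par
  names(theta) <- c("alpha", "beta", "gamma", "kR", "kAlpha")

  # Laplace: central-difference Hessian of the negative log-joint
  h <- o$hessian_step
  d <- length(theta)
  H <- matrix(0, d, d)
  f0 <- neg_logjoint(theta)
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- ej <- rep(0, d)
      ei[i] <- h; ej[j] <- h
      H[i, j] <- H[j, i] <-
        (neg_logjoint(theta + ei + ej) - neg_logjoint(theta + ei - ej) -
           neg_logjoint(theta - ei + ej) + neg_logjoint(theta - ei - ej)) /
        (4 * h^2)
    }
  }
  eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, 1e-8)       # PSD repair for near-flat directions
  vcov <- eg$vectors %*% diag(1 / ev, d) %*% t(eg$vectors)
  dimnames(vcov) <- list(names(theta), names(theta))
  log_evidence <- -f0 + d / 2 * log(2 * pi) - 0.5 * sum(log(ev))

  core <- core_from_theta(theta, priors)
  pred <- latents_for(inputs, core, o$z_max, o$n_grid)
  obs_maps <- list()
  noise_sd <- c()
  postdict <- data.frame(row.names = seq_len(nrow(trials)))
  for (v in cont) {
    pg <- profile_gaussian(y[[v]], latent_of(pred, v),
                           fixed_slope = if (v == "log_rt") o$rt_slope
                                         else NULL)
    obs_maps[[v]] <- affine_map(pg$intercept, pg$slope)
    noise_sd[[v]] <- pg$sd
    postdict[[v]] <- pg$intercept + pg$slope * latent_of(pred, v)
  }
  if (use_com) postdict$com <- pred$q_change
  grad <- vapply(seq_len(d), function(i) {
    ei <- rep(0, d); ei[i] <- h
    (neg_logjoint(theta + ei) - neg_logjoint(theta - ei)) / (2 * h)
  }, numeric(1))

  structure(list(
    theta = theta, core = core,
    obs = if (length(obs_maps))
      observation_params(maps = obs_maps, noise_sd = noise_sd) else NULL,
    vcov = vcov, log_evidence = log_evidence,
    postdictions = postdict, fitted_vars = fitted_vars, priors = priors,
    options = o,
    diagnostics = list(n_restarts = o$n_restarts, n_converged = n_conv,
                       best_objective = best$value,
                       grad_norm = sqrt(sum(grad^2)))
  ), class = "mcd_fit")
}

#' @export
print.mcd_fit <- function(x, ...) {
  cat("MCD subject fit (MAP + Laplace)\n")
  cat("  fitted variables:", paste(x$fitted_vars, collapse = ", "), "\n")
  cat("  core parameters (natural scale):\n")
  print(round(c(alpha = x$core$alpha, beta = x$core$beta,
                gamma = x$core$gamma, kR = x$core$kR,
                kAlpha = x$core$kAlpha), 4))
  cat(sprintf("  log evidence (Laplace): %.2f\n", x$log_evidence))
  cat(sprintf("  restarts converged: %d/%d, |grad| = %.3g\n",
              x$diagnostics$n_converged, x$diagnostics$n_restarts,
              x$diagnostics$grad_norm))
  invisible(x)
}

#' Out-of-sample predictions for held-out variables
#'
#' Latent model predictions for variables that were not part of the fit,
#' computed from the fitted core parameters alone. Held-out variables have
#' no estimated nuisance map; since evaluation uses cross-trial Pearson
#' correlation (affine-invariant), the latent predictions are returned
#' unmapped.
#'
#' @param fit An [fit_subject()] result.
#' @param trials Trial table to predict (same subject).
#' @param held_out_vars Variables disjoint from `fit$fitted_vars`.
#' @return Data frame of per-trial latent predictions, one column per
#'   held-out variable.
#' @export
predict_out_of_sample <- function(fit, trials, held_out_vars) {
  held_out_vars <- match.arg(held_out_vars, mcd_variables, several.ok = TRUE)
  overlap <- intersect(held_out_vars, fit$fitted_vars)
  if (length(overlap)) {
    stop("held-out variables were fitted: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  inputs <- proxy_inputs(trials, epsilon = fit$options$epsilon)
  pred <- latents_for(inputs, fit$core, fit$options$z_max, fit$options$n_grid)
  out <- data.frame(row.names = seq_len(nrow(trials)))
  for (v in held_out_vars) {
    out[[v]] <- if (v == "com") pred$q_change else latent_of(pred, v)
  }
  out
}

#' Parameter-recovery study
#'
#' Simulates subjects from the generative model, refits each with
#' [fit_subject()], and reports, per core parameter, the Spearman rank
#' correlation between generating and recovered values, plus bias and RMSE
#' on the log scale.
#'
#' @param config A [sim_config()]; `config$n_subjects` simulated subjects
#'   are fitted (>= 10 recommended).
#' @param seed Integer, overrides `config$seed`.
#' @param fit_options Options passed to [fit_subject()].
#' @param priors A [prior_spec()].
#' @return List with `summary` (data frame: parameter, rank_correlation,
#'   bias_log, rmse_log) and `estimates` (truth and estimates per subject).
#' @export
parameter_recovery <- function(config = sim_config(n_subjects = 20),
                               seed = NULL, fit_options = list(),
                               priors = prior_spec()) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sim <- simulate_experiment(config)
  subjects <- unique(sim$trials$subject)
  est <- lapply(subjects, function(s) {
    fit <- fit_subject(sim$trials[sim$trials$subject == s, , drop = FALSE],
                       priors = priors, options = fit_options)
    data.frame(subject = s, alpha_hat = fit$core$alpha,
               beta_hat = fit$core$beta, gamma_hat = fit$core$gamma,
               kR_hat = fit$core$kR, kAlpha_hat = fit$core$kAlpha)
  })
  est <- do.call(rbind, est)
  tab <- merge(sim$truth, est, by = "subject")
  pars <- c("alpha", "beta", "gamma")
  summ <- do.call(rbind, lapply(pars, function(p) {
    lt <- log(tab[[p]])
    le <- log(pmax(tab[[paste0(p, "_hat")]], 1e-12))
    data.frame(parameter = p,
               rank_correlation = stats::cor(lt, le, method = "spearman"),
               bias_log = mean(le - lt),
               rmse_log = sqrt(mean((le - lt)^2)),
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, estimates = tab)
}

#' Permutation chance level for prediction accuracy
#'
#' Null distribution of the group-average observed-vs-predicted correlation
#' obtained by shuffling predicted values across trials within each subject.
#' Returns the 95th percentile per variable: the accuracy a predictor with
#' no trial-level information would exceed only 5% of the time.
#'
#' @param trials Multi-subject trial table.
#' @param predictions Data frame of per-trial predictions aligned to
#'   `trials`, one column per variable.
#' @param n_perm Number of permutations (>= 200).
#' @param seed Integer seed.
#' @param probs Percentile(s) to return (default 0.95).
#' @return Named numeric vector: chance level per variable.
#' @export
permutation_chance_level <- function(trials, predictions, n_perm = 200,
                                     seed = 1L, probs = 0.95) {
  if (n_perm < 200) stop("`n_perm` must be >= 200", call. = FALSE)
  set.seed(as.integer(seed))
  subjects <- unique(trials$subject)
  vars <- colnames(predictions)
  obs_by_subj <- lapply(subjects, function(s) {
    idx <- which(trials$subject == s)
    ys <- lapply(vars, function(v) {
      outcome_vector(trials[idx, , drop = FALSE], v)
    })
    names(ys) <- vars
    list(idx = idx, ys = ys)
  })
  null_mat <- matrix(NA_real_, n_perm, length(vars),
                     dimnames = list(NULL, vars))
  for (k in seq_len(n_perm)) {
    rs <- matrix(NA_real_, length(subjects), length(vars))
    for (si in seq_along(subjects)) {
      idx <- obs_by_subj[[si]]$idx
      perm <- sample(length(idx))
      for (vi in seq_along(vars)) {
        yv <- obs_by_subj[[si]]$ys[[vi]]
        pv <- predictions[idx, vars[vi]][perm]
        ok <- !is.na(yv)
        if (sum(ok) >= 3 && stats::sd(yv[ok]) > 0 &&
            stats::sd(pv[ok]) > 0) {
          rs[si, vi] <- stats::cor(yv[ok], pv[ok])
        }
      }
    }
    null_mat[k, ] <- colMeans(rs, na.rm = TRUE)
  }
  apply(null_mat, 2, stats::quantile, probs = probs, names = FALSE)
}
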