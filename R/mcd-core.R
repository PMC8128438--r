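# Throughout this package, sigma denotes the VARIANCE of a value
# representation, not its standard deviation. This follows the convention of
# the metacognitive-control-of-decisions (MCD) model, in which a probabilistic
# value representation is summarized by its mode (mu) and its variance (sigma),
# and allocated cognitive resources z increase the precision 1/sigma linearly.

sigmoid <- function(x) stats::plogis(x)

#' Choice confidence given a pair of value beliefs
#'
#' Confidence is the probability that the chosen option's (to-be-experienced)
#' value exceeds the unchosen one's, under Gaussian value beliefs with mode
#' difference `dmu` and variances `sigma1`, `sigma2`. Choice is assumed to
#' follow the sign of `dmu`, so confidence depends on `|dmu|` only. The exact
#' Gaussian tail probability is replaced by its standard moment-matched
#' sigmoid approximation \eqn{s(\pi |\Delta\mu| / \sqrt{3(\sigma_1+\sigma_2)})}.
#'
#' @param dmu Numeric, difference between the modes of the two value beliefs.
#' @param sigma1,sigma2 Positive numerics, the variances (not SDs) of the two
#'   value beliefs.
#' @return Numeric in `[0.5, 1)`: 0.5 at `dmu = 0`, increasing in `|dmu|`.
#' @examples
#' confidence_given_belief(0, 1, 1)    # 0.5
#' confidence_given_belief(1, 0.5, 0.5)
#' @export
confidence_given_belief <- function(dmu, sigma1, sigma2) {
  if (any(sigma1 <= 0) || any(sigma2 <= 0)) {
    stop("variances `sigma1` and `sigma2` must be positive", call. = FALSE)
  }
  sigmoid(pi * abs(dmu) / sqrt(3 * (sigma1 + sigma2)))
}

#' Posterior variance of a value belief after resource allocation
#'
#' Allocating an amount `z` of cognitive resources increases the precision of
#' a value belief linearly: \eqn{1/\sigma(z) = 1/\sigma_0 + \beta z}, a
#' Gaussian-likelihood Bayesian precision update where `beta` (type #1
#' efficacy) is the precision gained per unit resource.
#'
#' @param sigma0 Positive numeric, prior variance.
#' @param beta Non-negative numeric, type #1 effort efficacy.
#' @param z Non-negative numeric, allocated resources.
#' @return Posterior variance `1 / (1/sigma0 + beta * z)`, always `<= sigma0`.
#' @export
posterior_variance <- function(sigma0, beta, z) {
  stopifnot(all(sigma0 > 0), all(beta >= 0), all(z >= 0))
  1 / (1 / sigma0 + beta * z)
}

#' Expected absolute mode difference after resource allocation
#'
#' First moment of `|dmu0 + ddelta|` where the cumulative mode perturbation
#' `ddelta ~ Normal(0, 2 * gamma * z)` (each option's mode is independently
#' perturbed with variance `gamma * z`). This is the exact folded-normal
#' first moment
#' \deqn{2\sqrt{\gamma z/\pi}\, e^{-\Delta\mu_0^2/(4\gamma z)} +
#'   \Delta\mu_0 (2\Phi(\Delta\mu_0/\sqrt{2\gamma z}) - 1),}
#' using the Gaussian CDF rather than its moment-matched sigmoid
#' approximation (which errs by up to ~0.02 and would break the dominance
#' property `E >= |dmu0|` at large `|dmu0|`).
#'
#' @param dmu0 Numeric, prior mode difference.
#' @param gamma Non-negative numeric, type #2 effort efficacy.
#' @param z Non-negative numeric, allocated resources.
#' @return Numeric `>= |dmu0|`, with equality iff `gamma * z = 0`.
#' @export
expected_abs_dmu <- function(dmu0, gamma, z) {
  stopifnot(all(gamma >= 0), all(z >= 0))
  gz <- gamma * z
  out <- abs(dmu0) + 0 * gz                    # gz == 0 limit
  pos <- gz > 0
  if (any(pos)) {
    d <- rep_len(dmu0, length(out))[pos]
    g <- rep_len(gz, length(out))[pos]
    out[pos] <- 2 * sqrt(g / pi) * exp(-d^2 / (4 * g)) +
      d * (2 * stats::pnorm(d / sqrt(2 * g)) - 1)
  }
  out
}

#' Variance of the absolute mode difference after resource allocation
#'
#' Second central moment of the folded normal `|dmu0 + ddelta|`,
#' `ddelta ~ Normal(0, 2 * gamma * z)`:
#' \eqn{2\gamma z + \Delta\mu_0^2 - E[|\Delta\mu|]^2}. Floored at zero
#' against floating-point cancellation at extreme inputs.
#'
#' @inheritParams expected_abs_dmu
#' @return Non-negative numeric; exactly 0 at `z = 0`.
#' @export
variance_abs_dmu <- function(dmu0, gamma, z) {
  stopifnot(all(gamma >= 0), all(z >= 0))
  e <- expected_abs_dmu(dmu0, gamma, z)
  pmax(2 * gamma * z + dmu0^2 - e^2, 0)
}

#' Expected choice confidence as a function of allocated resources
#'
#' The anticipated confidence \eqn{\bar{P}_c(z)} that would result from
#' allocating `z` resources, before the ensuing value-relevant information is
#' actually processed. Combines the precision gain (type #1 efficacy) and the
#' expected folded-normal moments of the perturbed mode difference (type #2
#' efficacy):
#' \deqn{\bar{P}_c(z) = s\left(\frac{\pi E[|\Delta\mu| \mid z]}
#'   {\sqrt{6(\sigma(z) + V[|\Delta\mu| \mid z]/2)}}\right)}
#' At `z = 0` this reduces to [confidence_given_belief()] evaluated at the
#' prior. It is strictly increasing in `z` whenever `beta != 0` or
#' `gamma != 0`.
#'
#' @inheritParams expected_abs_dmu
#' @param sigma0 Positive numeric, shared prior variance of the two beliefs.
#' @param beta Non-negative numeric, type #1 effort efficacy.
#' @return Probability in `(0, 1)`.
#' @export
expected_confidence <- function(dmu0, sigma0, beta, gamma, z) {
  stopifnot(all(sigma0 > 0))
  e <- expected_abs_dmu(dmu0, gamma, z)
  v <- variance_abs_dmu(dmu0, gamma, z)
  s_z <- posterior_variance(sigma0, beta, z)
  sigmoid(pi * e / sqrt(6 * (s_z + v / 2)))
}

#' Probability of changing one's mind
#'
#' Probability that the post-effort preference `sign(dmu0 + ddelta)`
#' contradicts the prior preference `sign(dmu0)`, with
#' `ddelta ~ Normal(0, 2 * gamma * z)`:
#' \eqn{Q(z) = \Phi(-|\Delta\mu_0| / \sqrt{2\gamma z})} (the exact Gaussian
#' tail, for which the moment-matched sigmoid
#' \eqn{s(-\pi|\Delta\mu_0|/\sqrt{6\gamma z})} is the usual approximation).
#' Defined as 0 by continuity when `gamma * z = 0`: no resources, or
#' resources that cannot move the modes, cannot reverse a preference.
#'
#' @inheritParams expected_abs_dmu
#' @return Probability in `[0, 0.5]`; equals 0.5 at `dmu0 = 0` with
#'   `gamma * z > 0`.
#' @export
change_of_mind_prob <- function(dmu0, gamma, z) {
  stopifnot(all(gamma >= 0), all(z >= 0))
  gz <- gamma * z
  out <- 0 * (gz + dmu0)
  pos <- gz > 0
  if (any(pos)) {
    d <- rep_len(dmu0, length(out))[pos]
    g <- rep_len(gz, length(out))[pos]
    out[pos] <- stats::pnorm(-abs(d) / sqrt(2 * g))
  }
  out
}

#' Expected spreading of alternatives
#'
#' Expected choice-induced increase of the chosen-minus-unchosen value
#' difference (SoA), obtained by averaging the piecewise SoA definition over
#' the perturbation `ddelta ~ Normal(0, 2 * gamma * z)` (truncated-Gaussian
#' first moments): \eqn{2\sqrt{\gamma z/\pi}\,\exp(-\Delta\mu_0^2/(4\gamma z))}.
#' Zero by continuity when `gamma * z = 0`.
#'
#' @inheritParams expected_abs_dmu
#' @return Non-negative numeric, decreasing in `|dmu0|` at fixed `z > 0`.
#' @export
expected_soa <- function(dmu0, gamma, z) {
  stopifnot(all(gamma >= 0), all(z >= 0))
  gz <- gamma * z
  out <- 0 * (gz + dmu0)
  pos <- gz > 0
  if (any(pos)) {
    d <- rep_len(dmu0, length(out))[pos]
    g <- rep_len(gz, length(out))[pos]
    out[pos] <- 2 * sqrt(g / pi) * exp(-d^2 / (4 * g))
  }
  out
}

#' Choice-induced value certainty gain
#'
#' The increase in precision of the value beliefs after allocating `z`
#' resources: `1/sigma(z) - 1/sigma0 = beta * z`. Zero when `beta = 0`.
#'
#' @param beta Non-negative numeric, type #1 effort efficacy.
#' @param z Non-negative numeric, allocated resources.
#' @return `beta * z`.
#' @export
certainty_gain <- function(beta, z) {
  stopifnot(all(beta >= 0), all(z >= 0))
  beta * z
}

#' Subject-level MCD parameters
#'
#' Bundles the core parameters of the metacognitive control of decisions
#' model. `R` weighs expected confidence against effort cost; `alpha` is the
#' effort unitary cost; `beta` and `gamma` are the type #1 (precision gain)
#' and type #2 (mode perturbation) effort efficacies. Condition effects enter
#' through `kR`, a multiplicative boost of `R` on consequential trials, and
#' `kAlpha`, an additive extra unitary cost on penalized trials.
#'
#' @param alpha Positive numeric, effort unitary cost.
#' @param beta Non-negative numeric, type #1 efficacy.
#' @param gamma Non-negative numeric, type #2 efficacy.
#' @param R Positive numeric, decision importance weight (neutral baseline).
#' @param kR Positive numeric, multiplicative boost of `R` in consequential
#'   trials (`> 1` means consequential decisions are more important).
#' @param kAlpha Non-negative numeric, additive extra unitary cost in
#'   penalized trials.
#' @return An object of class `mcd_params`.
#' @export
mcd_params <- function(alpha = 0.04, beta = 0.36, gamma = 0.04, R = 1,
                       kR = 2, kAlpha = 0.1) {
  stopifnot(length(alpha) == 1, length(beta) == 1, length(gamma) == 1,
            length(R) == 1, length(kR) == 1, length(kAlpha) == 1)
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  if (beta < 0) stop("`beta` must be non-negative", call. = FALSE)
  if (gamma < 0) stop("`gamma` must be non-negative", call. = FALSE)
  if (R <= 0) stop("`R` must be positive", call. = FALSE)
  if (kR <= 0) stop("`kR` must be positive", call. = FALSE)
  if (kAlpha < 0) stop("`kAlpha` must be non-negative", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, R = R,
                 kR = kR, kAlpha = kAlpha),
            class = "mcd_params")
}

#' @export
print.mcd_params <- function(x, ...) {
  cat("MCD parameters\n")
  cat(sprintf("  alpha (unitary cost)        : %.4g\n", x$alpha))
  cat(sprintf("  beta  (type #1 efficacy)    : %.4g\n", x$beta))
  cat(sprintf("  gamma (type #2 efficacy)    : %.4g\n", x$gamma))
  cat(sprintf("  R     (importance, neutral) : %.4g\n", x$R))
  cat(sprintf("  kR    (consequential boost) : %.4g\n", x$kR))
  cat(sprintf("  kAlpha (penalty extra cost) : %.4g\n", x$kAlpha))
  invisible(x)
}

mcd_conditions <- c("neutral", "consequential", "penalized")

#' Prior decision state for one or more trials
#'
#' The inputs to the MCD model: the prior mode difference `dmu0` between the
#' two options' value beliefs, their shared prior variance `sigma0`, and the
#' trial condition.
#'
#' @param dmu0 Numeric vector, prior mode differences.
#' @param sigma0 Positive numeric vector, prior variances.
#' @param condition Character vector in
#'   `c("neutral", "consequential", "penalized")` (recycled).
#' @return A data frame of class `trial_inputs`.
#' @export
trial_inputs <- function(dmu0, sigma0, condition = "neutral") {
  if (any(sigma0 <= 0)) stop("`sigma0` must be positive", call. = FALSE)
  condition <- as.character(condition)
  if (!all(condition %in% mcd_conditions)) {
    stop("`condition` must be one of: ",
         paste(mcd_conditions, collapse = ", "), call. = FALSE)
  }
  n <- max(length(dmu0), length(sigma0), length(condition))
  out <- data.frame(dmu0 = rep_len(dmu0, n),
                    sigma0 = rep_len(sigma0, n),
                    condition = rep_len(condition, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_inputs", "data.frame")
  out
}

# Condition-effective importance weight and unitary cost.
effective_R <- function(params, condition) {
  ifelse(condition == "consequential", params$R * params$kR, params$R)
}
effective_alpha <- function(params, condition) {
  ifelse(condition == "penalized", params$alpha + params$kAlpha, params$alpha)
}

#' Expected value of control
#'
#' The cost-benefit objective whose maximizer is the MCD-optimal resource
#' allocation: \eqn{R' \bar{P}_c(z) - \alpha' z}, where `R'` and `alpha'` are
#' the condition-effective importance weight (`R * kR` on consequential
#' trials) and unitary cost (`alpha + kAlpha` on penalized trials).
#'
#' @param z Non-negative numeric vector of candidate allocations.
#' @param inputs A single-row [trial_inputs()] (or anything with `dmu0`,
#'   `sigma0`, `condition`).
#' @param params An [mcd_params()] object.
#' @return Numeric vector of EVC values, one per element of `z`.
#' @export
evc <- function(z, inputs, params) {
  stopifnot(all(z >= 0))
  r_eff <- effective_R(params, inputs$condition[1])
  a_eff <- effective_alpha(params, inputs$condition[1])
  pc <- expected_confidence(inputs$dmu0[1], inputs$sigma0[1],
                            params$beta, params$gamma, z)
  r_eff * pc - a_eff * z
}

# Vectorized EVC maximization over [0, z_max] for n trials at once:
# a uniform grid scan locates the basin of the global maximum, then a
# golden-section search refines all trials simultaneously. Returns the
# smallest maximizer when several grid points tie within tolerance.
optimize_z_batch <- function(dmu0, sigma0, r_eff, a_eff, beta, gamma,
                             z_max = 10, n_grid = 512, tol = 1e-6) {
  n <- length(dmu0)
  if (beta == 0 && gamma == 0) {
    return(rep(0, n))    # benefit flat in z, cost increasing
  }
  zg <- seq(0, z_max, length.out = n_grid)
  # (n x n_grid) matrix of EVC values, built columnwise on recycled trials
  e_mat <- outer(dmu0, zg, function(d, z) {
    expected_abs_dmu(d, gamma, z)
  })
  v_mat <- 2 * gamma * matrix(zg, n, n_grid, byrow = TRUE) + dmu0^2 - e_mat^2
  v_mat[v_mat < 0] <- 0
  s_mat <- 1 / (1 / sigma0 + beta * matrix(zg, n, n_grid, byrow = TRUE))
  pc_mat <- sigmoid(pi * e_mat / sqrt(6 * (s_mat + v_mat / 2)))
  evc_mat <- r_eff * pc_mat - a_eff * matrix(zg, n, n_grid, byrow = TRUE)
  best <- max.col(evc_mat, ties.method = "first")
  # golden-section refinement on the bracket around the best grid point
  lo <- zg[pmax(best - 1L, 1L)]
  hi <- zg[pmin(best + 1L, n_grid)]
  evc_vec <- function(z) {
    e <- expected_abs_dmu(dmu0, gamma, z)
    v <- pmax(2 * gamma * z + dmu0^2 - e^2, 0)
    s <- 1 / (1 / sigma0 + beta * z)
    r_eff * sigmoid(pi * e / sqrt(6 * (s + v / 2))) - a_eff * z
  }
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- evc_vec(x1)
  f2 <- evc_vec(x2)
  n_iter <- ceiling(log(tol / (z_max / (n_grid - 1))) / log(gr)) + 2L
  for (i in seq_len(max(n_iter, 1L))) {
    left <- f1 >= f2     # ">=" keeps the smaller maximizer on exact ties
    hi[left] <- x2[left]
    x2[left] <- x1[left]
    f2[left] <- f1[left]
    x1[left] <- hi[left] - gr * (hi[left] - lo[left])
    f1[left] <- evc_vec(x1)[left]
    rt <- !left
    lo[rt] <- x1[rt]
    x1[rt] <- x2[rt]
    f1[rt] <- f2[rt]
    x2[rt] <- lo[rt] + gr * (hi[rt] - lo[rt])
    f2[rt] <- evc_vec(x2)[rt]
  }
  z_opt <- (lo + hi) / 2
  # prefer the boundary z = 0 whenever it is at least as good (smallest
  # maximizer convention; also guards the refined point against being a hair
  # below the true boundary optimum)
  z_opt[evc_vec(rep(0, n)) >= evc_vec(z_opt) | z_opt < tol] <- 0
  z_opt
}

#' MCD-optimal resource allocation
#'
#' Numerically maximizes the expected value of control
#' \eqn{R' \bar{P}_c(z) - \alpha' z} over `[0, z_max]`, by a uniform grid
#' scan followed by golden-section refinement of the bracketing interval.
#' Effort units are arbitrary (the affine observation maps absorb scale), so
#' `z_max = 10` is a generous default; a warning is raised if the maximizer
#' lands within tolerance of `z_max`, which suggests truncation.
#'
#' @param inputs A [trial_inputs()] data frame (any number of rows).
#' @param params An [mcd_params()] object.
#' @param z_max Positive numeric, upper bound of the search interval.
#' @param n_grid Integer, number of grid points for the initial scan.
#' @param tol Numeric, absolute tolerance on the maximizer.
#' @return A data frame with columns `z_opt` (the allocation) and `evc_opt`
#'   (the attained objective), one row per input trial. Ties within tolerance
#'   resolve to the smallest maximizer.
#' @export
optimize_z <- function(inputs, params, z_max = 10, n_grid = 512, tol = 1e-6) {
  stopifnot(z_max > 0)
  r_eff <- effective_R(params, inputs$condition)
  a_eff <- effective_alpha(params, inputs$condition)
  n <- nrow(inputs)
  # bound the n x n_grid working set (~8 matrices) to keep memory flat for
  # very large trial batches
  chunk <- max(floor(2e6 / n_grid), 1L)
  if (n <= chunk) {
    z_opt <- optimize_z_batch(inputs$dmu0, inputs$sigma0, r_eff, a_eff,
                              params$beta, params$gamma,
                              z_max = z_max, n_grid = n_grid, tol = tol)
  } else {
    z_opt <- numeric(n)
    for (st in seq(1, n, by = chunk)) {
      en <- min(st + chunk - 1L, n)
      z_opt[st:en] <- optimize_z_batch(
        inputs$dmu0[st:en], inputs$sigma0[st:en], r_eff[st:en], a_eff[st:en],
        params$beta, params$gamma, z_max = z_max, n_grid = n_grid, tol = tol)
    }
  }
  if (any(z_opt > z_max - max(tol, 1e-3))) {
    warning("optimal allocation is at the z_max boundary; ",
            "consider increasing `z_max`", call. = FALSE)
  }
  pc <- expected_confidence(inputs$dmu0, inputs$sigma0,
                            params$beta, params$gamma, z_opt)
  data.frame(z_opt = z_opt, evc_opt = r_eff * pc - a_eff * z_opt)
}

#' Latent MCD predictions for one or more trials
#'
#' Composes [optimize_z()] with the corollary predictions of the model: at
#' the MCD-optimal allocation `z_opt`, returns the expected confidence
#' \eqn{\bar{P}_c(\hat{z})}, the probability of changing one's mind
#' \eqn{Q(\hat{z})}, the expected spreading of alternatives, the certainty
#' gain \eqn{\beta\hat{z}}, the posterior variance \eqn{\sigma(\hat{z})}, and
#' the folded-normal moments of the post-effort mode difference.
#'
#' @inheritParams optimize_z
#' @return A data frame (one row per trial) with columns `z_opt`,
#'   `confidence`, `q_change`, `soa_expected`, `certainty_gain`,
#'   `sigma_post`, `e_abs_dmu`, `v_abs_dmu`.
#' @export
predict_trial <- function(inputs, params, z_max = 10, n_grid = 512,
                          tol = 1e-6) {
  opt <- optimize_z(inputs, params, z_max = z_max, n_grid = n_grid, tol = tol)
  z <- opt$z_opt
  data.frame(
    z_opt = z,
    confidence = expected_confidence(inputs$dmu0, inputs$sigma0,
                                     params$beta, params$gamma, z),
    q_change = change_of_mind_prob(inputs$dmu0, params$gamma, z),
    soa_expected = expected_soa(inputs$dmu0, params$gamma, z),
    certainty_gain = certainty_gain(params$beta, z),
    sigma_post = posterior_variance(inputs$sigma0, params$beta, z),
    e_abs_dmu = expected_abs_dmu(inputs$dmu0, params$gamma, z),
    v_abs_dmu = variance_abs_dmu(inputs$dmu0, params$gamma, z)
  )
}
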