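# Model-free analyses: observed-variable construction (change of mind, SoA,
# certainty gain), within-subject standardized regressions, group-level
# random-effects tests, median-split summaries, and prediction-accuracy
# reporting.

choice_sign <- function(choice) ifelse(choice == "a", 1, -1)

#' Classify each choice as change of mind, error, or consistent
#'
#' A change of mind requires (i) a choice incongruent with the prior
#' preference inferred from pre-choice value ratings and (ii) congruent with
#' the posterior preference inferred from post-choice value ratings. A choice
#' that contradicts both is an "error" (e.g., an attentional or motor lapse).
#' A choice congruent with the prior preference is "consistent", whatever the
#' posterior ordering. Trials where the deciding comparison is exactly tied
#' (tied pre-choice ratings; or, for a prior-incongruent choice, tied
#' post-choice ratings) are flagged `excluded_tie`.
#'
#' @param trials A trial table with pre/post value ratings and `choice`.
#' @return A factor with levels `change_of_mind`, `error`, `consistent`,
#'   `excluded_tie`, one element per trial.
#' @export
classify_change_of_mind <- function(trials) {
  need <- c("vr0_a", "vr0_b", "vr1_a", "vr1_b", "choice")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("missing columns for change-of-mind classification: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pre <- sign(trials$vr0_a - trials$vr0_b)
  post <- sign(trials$vr1_a - trials$vr1_b)
  ch <- choice_sign(trials$choice)
  out <- rep("consistent", nrow(trials))
  incongruent <- ch != pre
  out[incongruent & ch == post] <- "change_of_mind"
  out[incongruent & post != 0 & ch != post] <- "error"
  out[pre == 0] <- "excluded_tie"
  out[incongruent & pre != 0 & post == 0] <- "excluded_tie"
  factor(out, levels = c("change_of_mind", "error", "consistent",
                         "excluded_tie"))
}

#' Observed spreading of alternatives
#'
#' The choice-induced increase of the chosen-minus-unchosen value-rating
#' difference: `(post_chosen - post_unchosen) - (pre_chosen - pre_unchosen)`,
#' in rating units.
#'
#' @param trials A trial table with pre/post value ratings and `choice`.
#' @return Numeric vector, one SoA value per trial.
#' @export
observed_soa <- function(trials) {
  s <- choice_sign(trials$choice)
  s * ((trials$vr1_a - trials$vr1_b) - (trials$vr0_a - trials$vr0_b))
}

#' Observed value certainty gain
#'
#' Choice-induced change in value-certainty ratings, averaged (default) or
#' summed over the two items of the choice set.
#'
#' @param trials A trial table with pre/post certainty ratings.
#' @param average If `TRUE` (default) average over the two items, else sum.
#' @return Numeric vector in `[-1, 1]` (averaged) per trial.
#' @export
observed_certainty_gain <- function(trials, average = TRUE) {
  tot <- (trials$vcr1_a - trials$vcr0_a) + (trials$vcr1_b - trials$vcr0_b)
  if (average) tot / 2 else tot
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Outcome vector for one of the six model variables from a trial table;
# RT is analyzed as log-RT throughout.
outcome_vector <- function(trials, outcome) {
  switch(outcome,
    log_rt = log(trials$rt_s),
    effort = trials$effort,
    confidence = trials$confidence,
    com = {
      cls <- classify_change_of_mind(trials)
      ifelse(cls == "excluded_tie", NA_real_,
             as.numeric(cls == "change_of_mind"))
    },
    soa = observed_soa(trials),
    gain = observed_certainty_gain(trials),
    stop("unknown outcome `", outcome, "`", call. = FALSE)
  )
}

#' Within-subject standardized regression
#'
#' Ordinary least squares of a within-subject z-scored outcome on
#' within-subject z-scored `|dVR0|` (absolute pre-choice value-rating
#' difference) and `VCR0` (mean pre-choice certainty rating), plus an
#' intercept. With `include_conditions = TRUE`, raw 0/1 dummies for the
#' consequential and penalized conditions are appended (unstandardized, so
#' their weights read as shifts of the z-scored outcome). Trials with an
#' undefined outcome (tie-excluded change-of-mind trials) are dropped.
#'
#' @param trials Trial table for a single subject (>= 10 usable trials).
#' @param outcome One of `"log_rt"`, `"effort"`, `"confidence"`, `"com"`,
#'   `"soa"`, `"gain"`.
#' @param include_conditions Logical, append condition dummies.
#' @param outcome_values Optional numeric vector overriding the outcome
#'   construction (used to regress model predictions with the same design).
#' @return Named numeric vector of standardized weights: `intercept`,
#'   `adVR0`, `VCR0` (+ `consequential`, `penalized`).
#' @export
standardized_regression <- function(trials, outcome,
                                    include_conditions = FALSE,
                                    outcome_values = NULL) {
  y <- if (is.null(outcome_values)) outcome_vector(trials, outcome)
       else outcome_values
  keep <- !is.na(y)
  if (sum(keep) < 10) stop("need at least 10 usable trials", call. = FALSE)
  adv <- abs(trials$vr0_a - trials$vr0_b)[keep]
  vcr <- ((trials$vcr0_a + trials$vcr0_b) / 2)[keep]
  X <- cbind(intercept = 1, adVR0 = zscore(adv), VCR0 = zscore(vcr))
  if (include_conditions) {
    X <- cbind(X,
               consequential = as.numeric(trials$condition[keep] ==
                                            "consequential"),
               penalized = as.numeric(trials$condition[keep] == "penalized"))
  }
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design (constant regressor?)", call. = FALSE)
  }
  w <- stats::lm.fit(X, zscore(y[keep]))$coefficients
  names(w) <- colnames(X)
  w
}

#' Group-level random-effects test on per-subject regression weights
#'
#' One-sample t-tests on each column of a subjects-by-weights matrix,
#' treating subjects as random effects. Sidedness is per weight:
#' `"two.sided"`, `"less"` (negative expected) or `"greater"`.
#'
#' @param weights Numeric matrix, one row per subject, named columns.
#' @param sidedness Character vector recycled over columns.
#' @return Data frame with columns `weight`, `mean`, `sem`, `t`, `df`, `p`.
#' @export
group_random_effects <- function(weights, sidedness = "two.sided") {
  weights <- as.matrix(weights)
  if (nrow(weights) < 3) stop("need at least 3 subjects", call. = FALSE)
  sidedness <- rep_len(sidedness, ncol(weights))
  rows <- lapply(seq_len(ncol(weights)), function(j) {
    tt <- stats::t.test(weights[, j], alternative = sidedness[j])
    data.frame(weight = colnames(weights)[j] %||% paste0("w", j),
               mean = mean(weights[, j]),
               sem = stats::sd(weights[, j]) / sqrt(nrow(weights)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the standardized-regression battery over all subjects
#'
#' Convenience wrapper: computes [standardized_regression()] per subject for
#' one outcome and stacks the weights.
#'
#' @inheritParams standardized_regression
#' @param trials Multi-subject trial table (column `subject`).
#' @return Matrix of weights, one row per subject.
#' @export
subject_regressions <- function(trials, outcome, include_conditions = FALSE) {
  subjects <- unique(trials$subject)
  w <- lapply(subjects, function(s) {
    standardized_regression(trials[trials$subject == s, , drop = FALSE],
                            outcome, include_conditions = include_conditions)
  })
  out <- do.call(rbind, w)
  rownames(out) <- subjects
  out
}

#' Median-split summary of observed and predicted data
#'
#' Within each subject, trials are median-split on `VCR0` (low/high) and
#' binned into within-subject quantile bins of `|dVR0|`; per-cell means are
#' then averaged across subjects, yielding the classic three-way summary of
#' a variable against prior value difference and prior certainty.
#'
#' @param trials Multi-subject trial table.
#' @param variable One of the six model variables (see
#'   [standardized_regression()]).
#' @param predictions Optional numeric vector aligned to `trials` rows
#'   (e.g. model postdictions or out-of-sample predictions), summarized with
#'   the same binning.
#' @param n_bins Number of `|dVR0|` quantile bins (default 5).
#' @return Data frame with one row per (vcr_half, bin): group mean and SEM of
#'   the observed variable, and of `predictions` when given.
#' @export
median_split_summary <- function(trials, variable, predictions = NULL,
                                 n_bins = 5) {
  if (!is.null(predictions) && length(predictions) != nrow(trials)) {
    stop("`predictions` must align with `trials` rows", call. = FALSE)
  }
  subjects <- unique(trials$subject)
  acc <- list()
  for (s in subjects) {
    idx <- trials$subject == s
    tr <- trials[idx, , drop = FALSE]
    y <- outcome_vector(tr, variable)
    adv <- abs(tr$vr0_a - tr$vr0_b)
    vcr <- (tr$vcr0_a + tr$vcr0_b) / 2
    half <- ifelse(vcr <= stats::median(vcr), "low", "high")
    qs <- stats::quantile(adv, probs = seq(0, 1, length.out = n_bins + 1))
    bin <- cut(adv, breaks = unique(qs), include.lowest = TRUE,
               labels = FALSE)
    cell <- stats::aggregate(y ~ half + bin,
                             data = data.frame(y = y, half = half, bin = bin),
                             FUN = mean, na.rm = TRUE, na.action = NULL)
    cell$subject <- s
    if (!is.null(predictions)) {
      p <- predictions[idx]
      cellp <- stats::aggregate(p ~ half + bin,
                                data = data.frame(p = p, half = half,
                                                  bin = bin),
                                FUN = mean, na.rm = TRUE, na.action = NULL)
      cell <- merge(cell, cellp, by = c("half", "bin"), all = TRUE)
    }
    acc[[length(acc) + 1]] <- cell
  }
  all_cells <- do.call(rbind, acc)
  agg <- function(v) {
    stats::aggregate(all_cells[[v]],
                     by = list(vcr_half = all_cells$half,
                               bin = all_cells$bin),
                     FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                                         sem = stats::sd(x, na.rm = TRUE) /
                                           sqrt(sum(!is.na(x)))))
  }
  obs <- agg("y")
  out <- data.frame(vcr_half = obs$vcr_half, adv_bin = obs$bin,
                    observed_mean = obs$x[, "mean"],
                    observed_sem = obs$x[, "sem"])
  if (!is.null(predictions)) {
    pr <- agg("p")
    out$predicted_mean <- pr$x[, "mean"]
    out$predicted_sem <- pr$x[, "sem"]
  }
  out[order(out$vcr_half, out$adv_bin), ]
}

#' Within-subject prediction-accuracy table
#'
#' For each variable and each fitting protocol, the group mean and SEM of the
#' within-subject (across-trial) Pearson correlation between observed data
#' and model predictions (postdictions for fitted variables, out-of-sample
#' predictions otherwise). Correlation is affine-invariant, so the missing
#' nuisance maps of held-out variables are irrelevant.
#'
#' @param trials Multi-subject trial table.
#' @param predictions Named list: one entry per protocol (e.g. `"full"`,
#'   `"decision"`, `"effort"`), each a data frame of per-trial predicted
#'   values aligned to `trials`, with one column per predicted variable.
#' @param chance Optional named numeric of permutation chance levels per
#'   variable (appended as a column).
#' @return Data frame: `protocol`, `variable`, `kind` (postdiction or
#'   prediction), `mean_r`, `sem_r` (+ `chance`).
#' @export
prediction_accuracy_report <- function(trials, predictions, chance = NULL) {
  subjects <- unique(trials$subject)
  rows <- list()
  for (prot in names(predictions)) {
    pred_df <- predictions[[prot]]$values
    kind_map <- predictions[[prot]]$kind
    for (v in colnames(pred_df)) {
      rs <- vapply(subjects, function(s) {
        idx <- trials$subject == s
        y <- outcome_vector(trials[idx, , drop = FALSE], v)
        ok <- !is.na(y)
        if (sum(ok) < 3 || stats::sd(y[ok]) == 0 ||
            stats::sd(pred_df[idx, v][ok]) == 0) return(NA_real_)
        stats::cor(y[ok], pred_df[idx, v][ok])
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        protocol = prot, variable = v,
        kind = if (is.null(kind_map)) "postdiction" else kind_map[[v]],
        mean_r = mean(rs, na.rm = TRUE),
        sem_r = stats::sd(rs, na.rm = TRUE) / sqrt(sum(!is.na(rs))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(chance)) out$chance <- unname(chance[out$variable])
  out
}
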