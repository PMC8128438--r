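# mcdecide

Effort–confidence tradeoffs in value-based decisions: an R implementation of
the **metacognitive control of decisions (MCD)** model, with a full
experiment simulator, per-subject probabilistic fitting, out-of-sample
prediction, and the standard model-free analyses.

## The problem and who this is for

When people choose between two options they like (say, two snacks), they
decide *how hard to think* before they decide *what to pick*. The MCD model
formalizes this: each option's subjective value is a probabilistic belief —
a Gaussian with mode $\mu_i$ and **variance** $\sigma_i$ (a variance, not an
SD, throughout this package) — and the brain allocates cognitive resources
$z$ to maximize the expected value of control

$$\hat z = \arg\max_z \; R\,\bar P_c(z) - \alpha z,$$

the tradeoff between anticipated choice confidence $\bar P_c(z)$, weighted
by decision importance $R$, and linear effort cost $\alpha z$. Resources act
in two ways: **type #1 efficacy** $\beta$ raises the precision of value
beliefs ($1/\sigma(z) = 1/\sigma_0 + \beta z$), and **type #2 efficacy**
$\gamma$ stochastically perturbs their modes
($\delta_i \sim \mathcal N(0, \gamma z)$). From two pre-choice measurements
per trial — the value-rating difference and the mean value-certainty
rating — the model then predicts six trial-level variables at $\hat z$:
response time, subjective effort, choice confidence, the probability of
changing one's mind, the choice-induced spreading of alternatives, and the
value-certainty gain.

The package is aimed at decision neuroscientists and computational
modelers who want to simulate this class of rating/choice experiments, fit
the model to trial tables, and reproduce the standard analyses
(within-subject standardized regressions, group-level random-effects tests,
median splits, out-of-sample prediction with permutation chance levels).

## A worked example

Simulate a small study, look at one trial's latent predictions, fit one
subject, and predict held-out variables:

```r
library(mcdecide)

sim <- simulate_experiment(sim_config(n_subjects = 4, seed = 11))
head(sim$trials[, c("subject", "condition", "vr0_a", "vr0_b", "rt_s",
                    "confidence", "effort")], 3)
#>   subject condition     vr0_a     vr0_b      rt_s confidence    effort
#> 1       1   neutral 0.4888596 0.7775758 10.270258  0.6387351 1.0000000
#> 2       1   neutral 0.9925444 0.2269018  2.160871  0.5279570 0.5657924
#> 3       1   neutral 0.3629009 0.5825226 11.463350  0.8327758 1.0000000
```

This first simulated subject drew a low effort unitary cost, so its harder
trials (rows 1 and 3, where the two value ratings are close) get long RTs
and effort ratings pinned at the top of the scale, while the easy trial
(row 2, ratings 0.99 vs 0.23) is dispatched in two seconds with little
effort. A single trial's latent predictions:

```r
pred <- predict_trial(trial_inputs(dmu0 = 0.1, sigma0 = 1.5), mcd_params())
round(unlist(pred), 3)
#>          z_opt     confidence       q_change   soa_expected certainty_gain
#>          2.030          0.621          0.402          0.312          0.731
#>     sigma_post      e_abs_dmu      v_abs_dmu
#>          0.716          0.331          0.063
```

A near-tied pair (value difference 0.1 on the unit rating scale) recruits
about 2 units of resources; the agent expects modest confidence (0.62), a
40% chance of reversing its near-indifferent initial preference, and a
precision gain of 0.73. Fitting one simulated subject and predicting its held-out
effort-related variables from decision-related variables only:

```r
tr1 <- sim$trials[sim$trials$subject == 1, ]
fit <- fit_subject(tr1, fitted_vars = c("confidence", "soa", "gain", "com"))
oos <- predict_out_of_sample(fit, tr1, c("log_rt", "effort"))
cor(log(tr1$rt_s), oos$log_rt)
#> [1] 0.9766386
```

The out-of-sample correlation (affine-invariant, so no nuisance map is
needed for held-out variables) is well above the permutation chance level
that `permutation_chance_level()` computes.

Group-level model-free statistics, as they are usually reported:

```r
w <- subject_regressions(sim$trials, "log_rt")
group_random_effects(w[, c("adVR0", "VCR0")], sidedness = "less")
#>   weight        mean        sem          t df          p
#> 1  adVR0 -0.22093828 0.12000203 -1.8411213  3 0.08142803
#> 2   VCR0 -0.01733144 0.09005018 -0.1924643  3 0.42983518
```

Both group-mean weights are negative — log-RT decreases with the absolute
value-rating difference and (weakly) with rating certainty, the canonical
effort pattern — though with only four demo subjects the t-tests are
unsurprisingly soft; at the study's full size (41 subjects) the
value-difference effect is highly significant.

## Command line

`inst/cli/mcd.R` wraps the package for shell pipelines:

```sh
Rscript inst/cli/mcd.R simulate --seed 1 --out trials.csv
Rscript inst/cli/mcd.R fit --trials trials.csv --vars decision --out fits/
Rscript inst/cli/mcd.R predict --fit fits/ --trials trials.csv \
    --heldout effort --out pred.csv
Rscript inst/cli/mcd.R analyze --trials trials.csv --predictions pred.csv \
    --report report.json
```

Every run writes a `.provenance.json` record (package version, seed, config
hash, timestamp).

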