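---
title: "The metacognitive control of decisions: model, simulator, and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The metacognitive control of decisions: model, simulator, and estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdecide)
```

## The model

`mcdecide` implements the *metacognitive control of decisions* (MCD): a
cost–benefit account of how much cognitive effort a decision maker invests in
a value-based choice between two options. Each option's subjective value is
represented probabilistically, as a Gaussian belief with mode $\mu_i$ and
**variance** $\sigma_i$. This is worth stating twice, because readers often
assume a standard deviation: *everywhere in this package, $\sigma$ is a
variance*. All formulas, priors, and printed outputs follow that convention.

Before effort is invested, the decision is characterized by the prior mode
difference $\Delta\mu_0 = \mu_{a,0} - \mu_{b,0}$ and a shared prior variance
$\sigma_0$. Investing an amount $z \ge 0$ of resources has two anticipated
effects:

* **Type #1 efficacy** ($\beta$): precision grows linearly,
  $1/\sigma(z) = 1/\sigma_0 + \beta z$ — a Gaussian-likelihood Bayesian
  update whose likelihood precision is $\beta z$.
* **Type #2 efficacy** ($\gamma$): the modes are stochastically perturbed,
  $\delta_i \sim \mathcal N(0, \gamma z)$ per option, so the mode difference
  accumulates a perturbation $\Delta\delta \sim \mathcal N(0, 2\gamma z)$.

Choice confidence for a belief state is the probability that the chosen
option's experienced value will exceed the unchosen one's; with the choice
following the sign of the mode difference, this is the Gaussian tail
probability that the package maps through the standard moment-matched
sigmoid $s(x) = 1/(1+e^{-x})$:
$$P_c = s\!\left(\frac{\pi\,|\Delta\mu|}{\sqrt{3(\sigma_1+\sigma_2)}}\right).$$

The *anticipated* confidence after investing $z$ averages $P_c$ over the
unknown perturbation, using the first two moments of the folded normal
$|\Delta\mu_0 + \Delta\delta|$:
$$\bar P_c(z) = s\!\left(\frac{\pi\,E[|\Delta\mu|\,|\,z]}
  {\sqrt{6\,(\sigma(z) + V[|\Delta\mu|\,|\,z]/2)}}\right).$$

The resource allocation itself maximizes the expected value of control,
$$\hat z = \arg\max_z \; R'\,\bar P_c(z) - \alpha' z,$$
where $R'$ is the decision-importance weight ($R\,k_R$ on *consequential*
trials, $R$ otherwise) and $\alpha'$ the effort unitary cost
($\alpha + k_\alpha$ on *penalized* trials, $\alpha$ otherwise). At $\hat z$
the model makes corollary predictions for each trial: the attained
confidence $\bar P_c(\hat z)$, the probability of changing one's mind
$Q(\hat z)$, the expected spreading of alternatives (the choice-induced
growth of the chosen-minus-unchosen value difference), and the value
certainty gain $\beta \hat z = 1/\sigma(\hat z) - 1/\sigma_0$.

### Exact Gaussian tails versus moment-matched sigmoids

Classical presentations of this model write *every* Gaussian CDF through the
moment-matching approximation $\Phi(x) \approx s(\pi x/\sqrt 3)$, including
inside the folded-normal mean and the change-of-mind probability. That
approximation errs by up to about $0.023$ (worst near $x \approx 0.75$),
which is larger than Monte-Carlo uncertainty at any serious number of draws,
and it can push $E[|\Delta\mu|]$ *below* $|\Delta\mu_0|$ at large prior
differences — violating a property the model itself relies on. `mcdecide`
therefore evaluates the internal probability quantities exactly:

* `expected_abs_dmu()` uses the exact folded-normal first moment
  (with `pnorm`),
* `change_of_mind_prob()` returns
  $Q(z) = \Phi(-|\Delta\mu_0|/\sqrt{2\gamma z})$, the exact sign-flip
  probability,

while the confidence readouts (`confidence_given_belief()`,
`expected_confidence()`) keep the sigmoid mapping, which is definitional
for the confidence scale rather than an approximation of a separately
defined quantity. The test suite enforces all four closed forms (folded
mean, folded variance, flip probability, expected spreading) against
Monte-Carlo oracles.

### Limits and tie-breaking

At $\gamma z = 0$ the perturbation degenerates: by continuity the package
defines $Q = 0$, expected spreading $= 0$, $E[|\Delta\mu|] = |\Delta\mu_0|$,
and $V = 0$. An agent with $\gamma = 0$ never changes its mind and never
spreads alternatives, whatever $\beta$.

The optimizer (`optimize_z()`) scans a uniform grid (512 points by default)
on $[0, z_{\max}]$ and refines the bracket around the best grid point by
golden-section search to a $10^{-6}$ tolerance, returning the smallest
maximizer on ties and preferring the exact boundary $z = 0$ whenever it is
at least as good. Effort units are arbitrary — the affine observation maps
absorb scale — so the default $z_{\max} = 10$ is generous; a warning flags
maximizers within tolerance of $z_{\max}$. The EVC objective is not convex
in general, but the grid is dense enough that the refined optimum matches a
$10^5$-point brute-force argmax to $10^{-4}$ on randomized parameter
batteries (enforced in the tests).

## From ratings to model inputs and back

The experimental paradigm measures, per trial: pre-choice value ratings and
value-certainty ratings of both items (all on $[0,1]$), the choice, response
time, a confidence rating, a subjective-effort rating, and post-choice value
and certainty ratings. The input proxies are
$\Delta\mu_0 = \mathrm{VR}^0_a - \mathrm{VR}^0_b$ and
$1/\sigma_0 = \max(\overline{\mathrm{VCR}^0}, \varepsilon)$, with
$\varepsilon = 0.01$ flooring the mean certainty rating so a fully uncertain
pair yields a large but finite prior variance ($\sigma_0 \le 100$).

Each continuous observable is an affine transform (positive slope) of its
latent counterpart plus Gaussian noise: confidence of $\bar P_c(\hat z)$,
observed spreading of $\overline{\mathrm{SOA}}(\hat z)$, certainty gain of
$\beta\hat z$, and both log-RT and the effort rating of $\hat z$ itself. RT
enters as log-RT throughout (its analyses z-score log-RT). The binary
change-of-mind outcome has no affine map — a probability cannot be
rescaled — so its Bernoulli likelihood uses $Q(\hat z)$ directly, clamped
to $[10^{-6}, 1-10^{-6}]$; this is the one place where the "two nuisance
parameters per output" bookkeeping does not apply. The certainty-gain
observable is the raw post-minus-pre certainty-rating change, averaged over
the two items (a sum variant is one switch away).

## The experiment simulator

`simulate_experiment()` emulates the full study design: 41 subjects by
default, each with 60 *neutral*, 7 *consequential*, and 7 *penalized*
trials, shuffled. Value ratings are drawn iid Beta(2,2) (broad coverage,
centered), certainty ratings Beta(4,2) (most people are fairly certain,
left tail of doubt); each subject has its own RNG stream seeded from the
global seed and the subject id, so output is byte-identical under a fixed
seed and independent of execution order.

Given a subject's parameters, each trial is generated mechanistically, not
from the closed forms: the optimal $\hat z$ is computed, per-option
perturbations $\delta_i \sim \mathcal N(0,\gamma\hat z)$ are drawn, the
choice follows the sign of the realized post-effort mode difference (exact
ties break uniformly at random), and realized spreading follows its
piecewise definition on the latent modes. The closed-form moments then have
to *emerge* from the simulation — a consistency the test suite checks at
$10^5$ replicates. Post-choice value ratings are the pre-choice ratings plus
the latent perturbations, clipped to $[0,1]$: latent value units and rating
units are identified (the identity read-out), a stand-in isolated in one
function (`rating_readout`) because nothing in the data constrains the
read-out map. Continuous observables are clipped only where they are
ratings; log-RT is not clipped.

Population defaults draw $\log\alpha,\log\beta,\log\gamma$ (and the
condition modifiers) from Gaussians with SD 0.3 (0.2 for modifiers) around
$\alpha = 0.04$, $\beta = 0.36$, $\gamma = 0.04$, $R = 1$, $k_R = 2$,
$k_\alpha = 0.1$; observation noise SDs are 0.08 (confidence), 0.15
(log-RT), 0.10 (effort), 0.05 (certainty-rating noise). A drawn subject
whose effort optima saturate the $z_{\max}$ search bound on its own trials
is rejected and redrawn (within its own RNG stream): behavior pinned at the
bound is an artifact of the finite search interval — the same condition the
optimizer warns about — and its generating parameters would be meaningless
as ground truth. These values were
calibrated — once, before the estimation machinery existed — so the
simulated group resembles the empirical regularities this class of
experiments reports: mean confidence near 0.7, a change-of-mind rate around
15–25%, small positive spreading and certainty gain, and the canonical sign
pattern of effort and decision variables against
$|\Delta\mathrm{VR}^0|$ and $\overline{\mathrm{VCR}^0}$. What the simulator
deliberately omits: rating test–retest noise, regression-to-the-mean in
repeated ratings, eye-gaze channels, and item-level structure beyond the
two options. The omissions matter for interpretation: in real data the
small negative effects of certainty on change of mind and spreading are
likely amplified by rating noise mechanisms that are out of scope here, so
on simulated data those two group-level effects hover near zero — passing
sign tests on the strong cells of the pattern says nothing about those two
weak cells.

## Estimation

`fit_subject()` estimates five free core parameters per subject —
$\alpha, \beta, \gamma, k_R, k_\alpha$ — with $R$ fixed to 1: the overall
importance scale trades off exactly with $\alpha$'s units and the affine
output maps, so only the consequential modifier $k_R$ is identified within
subject. All requested dependent variables are fitted concurrently with
this single parameter set.

The target is the posterior mode (MAP) on the log scale, with independent
Gaussian priors on $\log\alpha$, $\log\beta$, $\log\gamma$, $\log k_R$, and
$\log(k_\alpha + 10^{-3})$. The affine intercept, slope, and noise SD of
each fitted continuous variable are *profiled out in closed form* (ordinary
least squares of observed on latent, slope clamped positive, SD at its
conditional MLE, flat priors): profiling preserves the joint mode exactly
while keeping the outer optimization five-dimensional, which is what makes
the whole-study refits in the tests affordable. The outer optimization is
multi-start Nelder-Mead (8 restarts by default, jittered around the prior
location, seeded). A Laplace approximation at the mode — central
finite-difference Hessian, step $10^{-3}$ on the log scale, eigenvalue floor
for near-flat directions — supplies the posterior covariance and an
approximate log model evidence. This MAP + Laplace scheme targets the same
posterior mode as the variational-Laplace schemes traditionally used for
this model family, without the variational message passing.

### Priors, and why they are only moderately wide

The default priors (`prior_spec()`) are centered near the package's default
population (e.g. $\log\beta \sim \mathcal N(\log 0.3, 0.7^2)$) with scales
between 0.5 and 1. Flat-er priors (scale 2) were evaluated and rejected for
a structural reason: because every continuous channel carries a free
positive slope, $\beta$'s absolute scale is absorbed by the certainty-gain
map, and the likelihood of a single 74-trial subject typically has a sharp
*lower* identification edge for $\beta$ but a one-sided plateau above it
(raising $\beta$ can be compensated by the nuisance maps almost exactly).
On the plateau only the prior breaks the tie; a moderately informative
prior pulls estimates to the truth-tracking edge, which is what makes
parameter recovery meaningful. This mirrors standard practice in the
variational-Bayes tradition of this literature, where priors of comparable
width are the default rather than an afterthought. Both the prior moments
and the optimizer budget are user-configurable.

### Out-of-sample prediction and chance levels

`predict_out_of_sample()` returns *latent* predictions for variables
disjoint from the fitted set — held-out variables have no estimated affine
map, and none is needed because accuracy is measured by within-subject
across-trial Pearson correlation, which is affine-invariant. The canonical
protocol fits the decision-related set (confidence, change of mind,
spreading, certainty gain) and predicts the effort-related set (log-RT,
effort), and vice versa. `permutation_chance_level()` provides the
reference: the 95th percentile of group-average correlations after
shuffling predictions across trials within subject (at least 200
permutations).

## Model-free analyses

`standardized_regression()` regresses each within-subject z-scored outcome
on within-subject z-scored $|\Delta\mathrm{VR}^0|$ and
$\overline{\mathrm{VCR}^0}$ plus an intercept; "standardized weights" here
means *within-subject z-scoring of outcome and continuous regressors before
OLS* (not post-hoc weight scaling) — the two readings differ and this one
is adopted and documented. Condition dummies, when requested, enter raw
(0/1) so their weights read as shifts of the z-scored outcome.
`group_random_effects()` then runs one-sample t-tests across subjects, with
per-contrast sidedness. Change-of-mind classification requires the choice
to contradict the pre-choice rating order *and* agree with the post-choice
order; contradicting both is an "error", and trials tied on the deciding
comparison are excluded (flagged, counted — the paper-silent tie policy is
exclusion rather than arbitrary assignment). Median-split summaries bin
trials within subject by a certainty median split crossed with five
quantile bins of $|\Delta\mathrm{VR}^0|$ (bin count configurable; the
figure convention this mirrors does not state one).

## Numerical choices, problem sizes, and known limitations

* The inner effort optimizer uses a 128-point grid inside likelihood
  evaluations (512 for direct calls) before golden-section refinement; at
  these grid densities the argmax error is far below the scale at which it
  could influence a fit.
* Monte-Carlo oracle checks use $10^5$–$10^6$ draws and family-level SE
  bounds (every point within 5 SE, at least 95% within 3 SE): against a
  stochastic oracle an exact formula still strays beyond 3 SE at a few
  tenths of a percent of points, so a per-point 3 SE assertion over a large
  grid would reject a correct implementation with non-trivial probability.
* The packaged studies run at deliberately chosen sizes — recovery with 20
  subjects of 74 trials, out-of-sample protocols with 8–10 subjects —
  enough for the rank correlations and group tests they feed.
* Known limitations: the estimator inherits the $\beta$ plateau discussed
  above (upper-side uncertainty on $\beta$ remains large at 74 trials);
  condition modifiers $k_R$ and $k_\alpha$ rest on 7 trials each and are
  correspondingly noisy; the Gaussian observation model ignores the
  heteroscedastic, folded character of realized spreading; and the identity
  rating read-out is a convention, not an estimate.
* Recovery, quantified honestly: at the emulated study size (74 trials,
  moderate noise, population log-SD 0.3) the recovery harness yields
  truth-versus-estimate rank correlations around 0.9 for $\log\alpha$ but
  only roughly 0.5–0.65 for $\log\beta$ and $\log\gamma$. The efficacies
  are weakly identified at this scale: after the units pin, $\beta$'s only
  non-absorbed signal is the cross-trial shape of expected confidence, and
  $\gamma$'s strongest channel — the Bernoulli change-of-mind likelihood —
  carries only $\sim$10–15 events per subject at realistic
  change-of-mind rates. In the near-noiseless, 500-trial limit all three
  parameters recover to within a few percent, so the limit is the
  information content of a 74-trial session, not the estimator. Studies
  needing subject-level efficacy estimates should plan more trials or
  hierarchical pooling (the latter is outside this package's scope).
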