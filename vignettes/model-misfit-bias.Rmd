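---
title: "How parameter misfit and model misspecification bias model-based fMRI betas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How parameter misfit and model misspecification bias model-based fMRI betas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlbias)
```

## The problem

In model-based fMRI a learning model is fitted to behavior, its latent
variables (value $V_t$, reward prediction error
$\delta_t$) are recomputed trial by trial, and a GLM regresses the
neural signal $y_t$ on them.  The estimated coefficients — *beta
values* — are then carried to a second level: compared between groups,
or correlated with a trait.  The beta value, however, depends not only
on the neural coding but also on how well the regressor matches the
signal-generating latent variable.  If the analysis model is misfit in
a way that is *correlated with group membership*, the betas acquire a
group-dependent bias and the second-level test detects a difference
that does not exist in the neural coding.

`rlbias` implements two concrete instances:

1. **Parameter misfit.**  Both groups' signals follow
   $y_t = \beta_\delta \delta^*_t + \varepsilon_t$ with the same
   $\beta_\delta$, but the groups learn at different true rates
   $\alpha^*$ while the analyst rebuilds $\hat\delta_t$ with one common
   rate $\hat\alpha$ (a widespread practice adopted to stabilize
   regressors).
2. **Model misspecification.**  Behavior is generated by a Q-learning
   model in which the *unchosen* option's value decays toward a default
   ($V_{t+1}(j) = V_t(j) + \phi(\mu - V_t(j))$), the decay rate $\phi$
   differs between groups, and the analyst fits a standard model
   without the decay — even with per-subject maximum-likelihood fits,
   the group with stronger forgetting is modeled worse and its betas
   shrink.

## Closed-form beta statistics

For the Rescorla–Wagner model under an i.i.d. Bernoulli($p_r$) reward
sequence the long-run (centered) moments of the true and refit
regressors have closed forms; writing $c = T p_r (1-p_r)$,

$$S(\hat\delta,\hat\delta) = \frac{2}{2-\hat\alpha} c \hat\rho^2,
\quad
S(\delta,\hat\delta) = \frac{\alpha^*+\hat\alpha}
{\alpha^*+\hat\alpha-\alpha^*\hat\alpha} c \rho^*\hat\rho,
\quad
S(\hat V,\hat V) = \frac{\hat\alpha}{2-\hat\alpha} c \hat\rho^2,
\quad
S(V,\hat V) = \frac{\alpha^*\hat\alpha}
{\alpha^*+\hat\alpha-\alpha^*\hat\alpha} c \rho^*\hat\rho,$$

with $S(r, V) \approx 0$.  Substituted into the OLS identities
$E[\hat\beta] = (X'X)^{-1}X'X^*\beta$ and
$\mathrm{Cov}[\hat\beta] = \sigma_\varepsilon^2 (X'X)^{-1}$
(`beta_stats_general()`), they yield the expectation and variance of
every beta in the three GLM variants (`beta_stats_glm1()`,
`beta_stats_glm2()`, `beta_stats_glm2prime()`).  Two structural facts
drive all results:

* the refit RPE variance $2/(2-\hat\alpha)$ *increases* with the
  learning rate, so analyzing a fast learner with a too-small common
  rate under-scales the regressor and inflates the beta — and vice
  versa;
* the reward regressor's moments involve no learning rate at all, so
  the GLM2 reward beta is immune to the misfit while the
  negative-value beta absorbs it undiluted.

During development we re-derived the GLM2′ reward-beta expectation
from the matrix identities; the misfit term is
$\frac{\hat\alpha-\alpha^*}{\alpha^*+\hat\alpha-\alpha^*\hat\alpha}
\rho^* \beta_\delta$, i.e. it scales with $\rho^*$ only — a
Monte-Carlo check at $\rho^* = 1.5$, $\hat\rho = 2$ confirms this —
and that is what the package implements.  (All replication presets use
$\hat\rho = 1$, where the distinction vanishes.)

Effect sizes follow as $d_1 = E[\hat\beta]/\sqrt{Var[\hat\beta]}$ for
the one-sample second-level test and
$d_2 = (E_1-E_2)/\sqrt{(V_1+V_2)/2}$ for the two-group comparison;
power comes from the noncentral t-distribution with
$\lambda = d_1\sqrt{n}$ or $\lambda = d_2\sqrt{n_1 n_2/(n_1+n_2)}$,
two-sided throughout.  Group 1 is the control group by convention, so
positive $d_2$ means the beta is diminished in patients.

The moments ignore the initial transient of the value process (a few
$1/\alpha$ trials), so the closed forms are large-$T$ approximations:
below roughly 50 trials treat them as indicative.  The test suite
verifies them against Monte-Carlo OLS at $T \in \{50, 100, 200\}$ with
2000 replicates per trial count — expectations against a fresh
schedule-plus-noise ensemble, variances against noise-conditional
replicates averaged over 20 schedules — agreeing within three
Monte-Carlo standard errors.

## Default configurations

The defaults of the experiment functions are the study conditions the
statistics describe, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `n_trials`, `p_reward` | 100, 0.4 | conditioning task length and fixed reward probability; the schedule holds exactly 40 rewards in shuffled order and is shared by all subjects of an experiment |
| `alpha_control`, `alpha_patient`, `alpha_fit` | 0.4, 0.2, 0.3 | true group learning rates and the common analysis rate (the group mean) |
| `sigma_eps`, `beta_delta` | 0.5, 1 | signal noise sd and true RPE coefficient (identical across groups) |
| `n_per_group` | 20 | subjects per group in the conditioning comparison |
| forgetting task | 180 trials, 0.8/0.2, one reversal after 90 | probabilistic reversal learning; reversals are what make forgetting visible in behavior |
| forgetting agents | $\alpha=0.5$, $\beta_{it}=4$, $\mu=0.5$, $\phi = 0.05$ vs $0.4$, $N=30$ per group | control (Low-F) vs patient (High-F) generating parameters |
| MLE | bounds $\alpha,\phi\in[0,1]$, $\beta_{it}\in[0,20]$, 10 uniform random restarts, $\mu$ fixed at 0.5 | the inverse-temperature bound comfortably contains the generating value 4; correctness is defined by the likelihood, not the optimizer |

Where a choice was genuinely open we fixed it once:

* **Intercept, no centering.**  OLS fits include an intercept instead
  of mean-centering signal and regressors; the closed forms assume
  centered variables.  The discrepancy is $O(1/T)$ and covered by the
  Monte-Carlo tolerances.
* **Trial space, raw regressors.**  Regressors are not convolved with
  a hemodynamic response function and not z-scored (a `zscore` flag
  exists but no replication preset uses it).
* **Chosen-option latents.**  In the bandit task the RPE regressor is
  the chosen option's $\delta$ and the value regressor the chosen
  option's $-V$ — the prediction error is only defined for the
  experienced outcome.
* **Reversal placement.**  $k$ reversals are placed at equal spacing
  $\lfloor T/(k+1)\rfloor$, which reproduces the single-reversal task
  at $T/2$; outcomes are drawn online as choices occur, with
  contingencies (not outcome sequences) pre-generated.
* **Dimensional trait.**  The trait is
  $50 - 100\,\alpha^* + \mathcal{N}(0, 7.5^2)$ over
  $\alpha^* \sim \mathcal{N}(0.3, 0.1^2)$ truncated to $[0,1]$, giving
  a trait–learning-rate correlation near $-0.8$; only the sign and
  significance structure of the resulting trait–beta correlations is
  treated as meaningful.
* **Seeding.**  Every experiment is a pure function of
  `(config, seed)`; subjects and replicates receive deterministic
  31-bit child seeds, so reruns are bit-identical and the caller's RNG
  stream is never touched.

## Numerical safeguards and degenerate inputs

* Choice probabilities in the likelihood are floored at $10^{-30}$, so
  the objective is finite everywhere in the box.
* OLS refuses rank-deficient designs (QR rank check).  Two degenerate
  situations produce them legitimately: a subject *analyzed* with
  $\hat\alpha = 0$ (constant value regressor), and a standard-model
  MLE that collapses to the unidentified random-choice solution
  ($\hat\beta_{it} = 0$, where the likelihood is flat in $\alpha$).
  Such subjects get `NA` betas and are dropped from the affected group
  test (about 1 in 2000 subject-level fits in the misspecification
  pipeline).
* `rw_moments()` rejects $p_r \in \{0, 1\}$ (zero reward variance) and
  the GLM2/GLM2′ statistics reject $\hat\alpha = 0$.
* Exact-count schedules require $T p_r$ to be integral; sweeps over
  trial counts fall back to Bernoulli draws where it is not.

## What the generator emulates — and what it does not

The synthetic data reproduce the *structure* of a model-based fMRI
study: trial-wise latent regressors, i.i.d. Gaussian signal noise, a
first-level OLS per subject, and a second-level t-test or correlation.
They deliberately omit hemodynamic convolution, autocorrelated (AR)
noise, voxelwise multiplicity, session/run structure, and hierarchical
parameter estimation.  Passing tests therefore demonstrate the
statistical mechanism of misfit-induced bias, not the magnitude it
would take in any particular scanner dataset.

## Known limitations and observed caveats

* The closed forms are stationary approximations; short runs
  ($T < 50$) inherit transient bias of order a few percent.
* Replicate-ensemble means of Cohen's d differ from the population
  $d_2$ by a few percent: the usual small-sample inflation of $d$
  ($\approx 2\%$ at 20 subjects per group) is more than offset by
  finite-realization effects — the realized schedule moments enter
  both the between-group difference and the estimated standard
  deviation, and the value process's initial transient biases the
  moments slightly.  In the default conditioning configuration the
  ensemble center of the GLM1 RPE effect sits near 0.61 against the
  analytic $d_2 = 0.637$.
* With 180-trial runs the forgetting-model MLE is noisy and the
  forgetting rate of low-$\phi$ subjects is boundary-biased upward
  (mean $\hat\phi \approx 0.10$ for $\phi^* = 0.05$).  Because an
  overestimated decay rate shrinks the refit value's variance, the
  control group's negative-value beta is *inflated* even under the
  correctly specified model: the pipeline shows a residual mean
  $d \approx 0.5$ for the GLM2 negative-value beta with per-subject
  forgetting-model fits, while the GLM1 RPE beta is calibrated
  ($\approx 5\%$ rejection).  This is a genuine consequence of
  estimation error near a parameter bound, and a caution that
  "correctly specified" does not mean "bias-free" at realistic trial
  counts.
* A single simulated experiment is noisy: with 20 subjects per group
  the per-run Cohen's d has a sampling sd near 0.4, so individual runs
  scatter widely around the analytic $d_2$ — which is precisely why
  the replication functions work with replicate ensembles.

## Validation problem sizes

The test suite runs the closed-form/Monte-Carlo agreement at
$T \in \{50, 100, 200\}$ with 2000 replicates each, the conditioning
group comparison over 200 replicate seeds, the misspecification
pipeline over 100 replicate seeds (both fit models, 10 restarts per
subject), parameter recovery at $T = 10{,}000$, and a 2000-replicate
type-I calibration of the matched-parameter group test.  The
acceptance script uses 1000 conditioning replicates and 100
misspecification replicates.
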