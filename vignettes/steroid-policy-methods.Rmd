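---
title: "Methods: learning and evaluating corticosteroid dosing policies in sepsis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning and evaluating corticosteroid dosing policies in sepsis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Corticosteroids in sepsis are a decades-old controversy: trials show faster
shock reversal but equivocal survival effects, and guidelines reserve them
for vasopressor-refractory shock. `sepsisrl` implements an offline
reinforcement-learning pipeline that treats each septic ICU admission as a
sequence of daily decisions — one of five hydrocortisone-equivalent dose
levels per 24 h — and learns a dosing policy from retrospective data with ICU
mortality as the (terminal) reward. Because the learned policy differs from
the clinicians' logged behavior, its value cannot be read off the observed
outcomes; the package therefore ships high-confidence off-policy evaluation
(HCOPE) alongside the learner, plus explainability tooling (layer-wise
relevance propagation and a random-forest behavior clone).

Real ICU databases of this kind are access-restricted, so the package is
built around a synthetic EHR generator with a fully known ground-truth
decision process. Every downstream claim the test suite makes is checked
against exact quantities computed from that process.

## The decision process

Each admission carries a latent daily severity $s_t \in [0,1]$ following a
mean-reverting random walk
$$s_{t+1} = s_t + \kappa(\mu - s_t) - d_{a_t}(s_t - s^\*) + \varepsilon_t,
\qquad \varepsilon_t \sim N(0, \sigma^2),$$
clipped to $[0,1]$, with defaults $\kappa = 0.15$, $\mu = 0.35$,
$\sigma = 0.07$, pivot $s^\* = 0.45$ and small per-action drift coefficients
$d_a$. After each day the stay terminates with a geometric discharge hazard
$1/\text{mean LOS}$ (default mean 8 days, capped at 60); at termination the
patient dies with probability
$$\Pr(\text{death}) = \operatorname{logit}^{-1}\!\big(\alpha_0 + \alpha_1 s_t
 + \beta_a + \tau_a (s_t - s^\*)\big),$$
and otherwise leaves alive. The terminal reward is $+1$ for alive discharge
and $-1$ for ICU death; intermediate rewards are 0. With rewards in
$[-1, 1]$, a policy value $J$ maps to an expected mortality of $(1 - J)/2$,
which is what the "normalized expected mortality" reports.

Defaults: $\alpha_0 = -3.0$, $\alpha_1 = 4.5$, toxicity
$\beta = (0, 0.2, 0.3, 0.4, 0.8)$ and interaction
$\tau = (0, -1.5, -3.0, -2.0, +1.0)$ across the five actions. The
interaction makes low-to-moderate doses protective above the severity pivot
and harmful below it; the toxicity term keeps every active dose harmful in
mild disease and makes the highest dose harmful almost everywhere. These
coefficients were fixed once, using the exact dynamic-programming oracle, so
that (i) behavior-policy mortality is about 27% — in the range reported for
severe sepsis cohorts; (ii) the optimal member of the severity-threshold
family (withhold below a threshold, fixed dose above) is "moderate dose
above severity 0.55", about 0.07 better in value than the clinician
behavior; and (iii) every constant policy is at least 0.05 worse than that
optimum, so policy-recovery experiments cannot be passed by a degenerate
always-one-action policy.

The simulated clinicians follow a severity-monotone softmax,
$b(a \mid s) \propto \exp(c_a + g_a s)$ with $g_a$ increasing in dose:
sicker patients get more steroids, which is exactly the confounding-by-
indication pattern that makes naive outcome comparisons misleading and
off-policy evaluation necessary.

A discrete-severity variant (severity on a uniform grid, default 21 levels;
Gaussian innovations integrated over grid cells) makes the process a finite
MDP. `true_policy_value()` solves its Bellman system exactly — no sampling —
and serves as the oracle for coverage, unbiasedness and policy-recovery
checks. `simulate_severity_stays()` simulates the same discrete process, so
simulation and oracle agree by construction (the only approximation is the
60-day cap, whose probability mass is below $10^{-3}$).

## The synthetic event layer

`generate_cohort()` wraps the decision process in a realistic event-table
skin: irregularly sampled vitals (Poisson sampling rates, thinned by
missingness), daily-ish laboratory values whose means move with severity in
the clinically expected directions (MAP falls; lactate, creatinine,
bilirubin rise; platelets, GCS, P/F ratio fall), vasopressor infusion rates
on shocked days, ventilation flags, culture/antibiotic pairs for the septic
fraction, and corticosteroid boluses drawn from several compounds whose
hydrocortisone-equivalent daily sum falls inside the true action's dose bin
(kept clear of the bin edges, so discretization recovers the true action
exactly). Septic admissions start with severity at least 0.22 — organ
dysfunction is part of the sepsis definition — except for a 10% late-onset
subgroup that starts mild and deteriorates, exercising the
"2-point SOFA rise" inclusion pathway. Under-18 and sub-24 h admissions are
generated deliberately as exclusion-rule fodder.

What the generator does *not* emulate: real sampling schedules (timestamps
are uniform within the day), measurement-device artifacts, inter-variable
noise correlation, informative missingness beyond the severity-driven
presence of vasopressor/ventilation data, and any treatment other than
corticosteroids affecting the outcome. Passing tests therefore demonstrate
that the pipeline recovers what it is supposed to recover *when its
assumptions hold*; they say nothing about confounding structures the
generator does not contain (notably unmeasured confounding, which off-policy
evaluation cannot repair on real data either).

## Cohort extraction

Sepsis-3 is operationalized as: suspected infection (a culture and an
antibiotic within a −24 h/+72 h window of each other; the windows are
configurable because published operationalizations vary) **and** a SOFA
total of at least 2 on the admission day or a rise of at least 2 points over
its running minimum, with adults only and stays of at least 24 h. The six
SOFA subscores use the standard published thresholds, encoded once in
`R/registries.R`; each 24 h window is scored with its worst value, and a
missing input scores 0 — no pre-ICU baseline is assumed. The rise is
measured against the running minimum since admission (not the admission
value) so that late deterioration after early recovery still counts as new
organ dysfunction. Septic shock is flagged as any vasopressor use plus any
lactate above 2 mmol/L during the stay. Repeated admissions are independent
episodes.

## Features

Events are binned into 24 h windows counted from sepsis onset.
Measurement-class variables contribute within-day mean, maximum, minimum and
population standard deviation (a single observation has sd 0); drug-class
variables contribute the 24 h cumulative dose; corticosteroids are excluded
from the state because they define the action. Variables observed in no
more than 2% of training admission-days are dropped. Laboratory and vital
columns are forward-filled within an admission; remaining leading gaps take
the training-split median (zero-filling a lab would encode "normal"
incorrectly); drug columns are zero-filled. Min–max normalization maps the
training range onto $[-1, 1]$; out-of-range validation/test values are
clipped and constant variables map to 0. Every fitted quantity — coverage
decisions, medians, bounds — is computed on the training split only and
frozen into a reusable fit object; a property test corrupts all
non-training data and asserts bit-identical fits and training behavior.
The pre-imputation availability mask is returned alongside the states.

## The learner

The agent is a temporal-difference actor-critic with two separate
multilayer perceptrons (default two tanh hidden layers of 64 units): the
actor maps the state to five action logits (softmax policy), the critic to
a scalar value. Per shuffled minibatch the TD error
$\delta = r + \gamma V(s') - V(s)$ (with $V(\text{terminal}) = 0$) drives a
semi-gradient critic update on $\tfrac12\delta^2$ and an actor ascent on
$\delta \nabla_\theta \log \pi_\theta(a_t \mid s_t)$ plus an entropy bonus
decayed linearly to zero. Training is pure offline regression on logged
transitions — no importance correction inside the update — so the critic
estimates the *behavior* value function and the actor's fixed point is the
policy greedy with respect to the behavior Q-function; on the default
scenario that greedy policy coincides with the optimal threshold policy,
which is why policy recovery is achievable at all and why the OPE module,
not the training loss, is the arbiter of policy quality.

Optimization uses Adam (critic step 1e-3, actor 3e-4, batch 256) — plain
momentum SGD is selectable but converges far too slowly at these problem
sizes. The per-epoch "relative error" is the mean critic loss divided by
the epoch-1 mean critic loss (so epoch 1 is 1 by definition); training stops
early when it moves less than 1e-3 over 25 epochs. On terminal-reward-only
clinical data most of the TD loss is irreducible outcome noise, so the
relative error plateaus well above zero; the logged concordance and action
histogram are the more informative convergence traces. The default
discount is 0.99; experiments that compare against the exact oracle use
$\gamma = 1$ so values have the closed mortality interpretation.

## Off-policy evaluation

The behavior policy $b(a \mid s)$ is estimated either by the random-forest
behavior clone or by empirical per-cluster action frequencies (k-means
states), then floored at $p_{\min} = 0.01$ and renormalized — the floor
bounds importance ratios away from infinity and is the single most
assumption-laden step of the whole pipeline, since no ICU database records
the clinicians' true action probabilities. Trajectory-level importance
weights $w(\tau) = \min(c, \prod_t \pi_e/b)$ (default truncation $c = 100$)
multiply the returns, and the 95% lower bound on the evaluation-policy value
uses, by default, the empirical-Bernstein concentration bound
$$\bar x - \sqrt{\tfrac{2 \hat v \log(2/\delta)}{n}}
        - \tfrac{7 R \log(2/\delta)}{3(n-1)},$$
with $\hat v$ the sample variance and $R$ the *empirical* range (a
degenerate all-equal sample yields itself; when the sample does not span
the support the bound is approximate, which the coverage experiment
quantifies empirically). Student-t and BCa-bootstrap bounds are selectable.
Truncation biases the point estimate downward, which is conservative for a
lower bound; the unbiasedness test therefore runs untruncated.

Concordance analysis labels each test-split day-state concordant iff the
recommendation equals the logged action and compares day-level mortality
(every day of a non-survivor counts as a death-day) between the groups,
overall, split by agent-withheld versus agent-prescribed, and by septic
shock. Per-day usage and mean-dose curves (bin midpoints; 350 mg for the
open top bin) mirror the usual length-of-stay-adjusted treatment-pattern
figures.

## Explainability

Layer-wise relevance propagation uses the $\varepsilon$-rule
($\varepsilon = 0.01$ by default) on the recommended action's pre-softmax
logit. Each layer's bias is treated as an extra input unit that absorbs
relevance, so conservation is exact at $\varepsilon = 0$: feature
relevances plus the bias relevance equal the explained logit. Global
rankings are mean absolute relevance, ties broken alphabetically. The
behavior clone is a 500-tree probability forest with class-frequency
weights; its validation-split micro-average one-vs-rest AUROC and impurity
importances are reported, and agent-versus-clone rankings are joined with a
Spearman correlation. A constructed scenario in the test suite — clinicians
keying on a vasopressor flag that has no bearing on outcome — verifies that
the clone ranks the flag above the agent's ranking of it.

## Numerical and design choices

* Dose bins are half-open on the left, closed on the right:
  0 / (0,100] / (100,200] / (200,300] / (300,∞) mg hydrocortisone per 24 h.
  Potencies: hydrocortisone 1, cortisone 0.8, prednis(ol)one 4,
  methylprednisolone 5, dexamethasone 26.7 (configurable registry).
* The 70/20/10 split is by admission with largest-remainder rounding
  (3051 admissions give exactly 2136/610/305) and never by day.
* Argmax ties break toward the lower (more restrictive) action.
* Coverage threshold domain is $[0, 1)$: a threshold of 0 keeps anything
  observed at least once.
* Degenerate inputs: an admission with no events scores SOFA 0 with a
  warning; constant features normalize to 0; an all-equal bound sample
  returns its constant; empty concordance strata report `NA` and are
  flagged.
* Problem sizes in the test suite were chosen so the full suite and the
  acceptance script run comfortably on a laptop-class single core:
  policy recovery trains on 2000 simulated admissions for up to 300 epochs;
  coverage uses 200 replicates of 300 stays; unbiasedness uses 50,000
  stays; the event-level pipeline tests use cohorts of 120–250 admissions.

## Known limitations

The generator's independence assumptions make the behavior clone's job
easier than on real data (its AUROC here is near-ceiling); the LRP
implementation supports the package's own tanh MLPs only; trajectory-level
importance sampling has exponential-in-horizon variance, which truncation
controls at the price of downward bias; and nothing in the pipeline
addresses unmeasured confounding — on real data the learned policy's value
bound is conditional on the recorded state capturing everything the
clinicians acted on.
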