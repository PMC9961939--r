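# sepsisrl

Offline reinforcement learning for corticosteroid dosing in septic ICU
patients: a tested, end-to-end R pipeline from raw ICU event tables to an
evaluated treatment policy.

## The problem

Whether, when and how much to dose corticosteroids in sepsis is
controversial: steroids speed shock reversal but trials disagree about
survival, and clinicians largely reserve them for vasopressor-refractory
shock. Retrospective ICU databases record thousands of septic admissions
under varying dosing practice — enough variation, in principle, to learn an
individualized policy. `sepsisrl` implements that program for users in
clinical ML and pharmaco-epidemiology:

1. **Cohort** — operationalized Sepsis-3 extraction from long-format event
   tables: daily SOFA scoring (worst value per 24 h window, standard
   subscore grid), suspected infection as a culture/antibiotic pair within
   −24 h/+72 h, inclusion iff SOFA ≥ 2 at admission or a ≥ 2-point rise over
   the running minimum, adults staying ≥ 24 h; septic shock flagged as
   vasopressor use plus lactate > 2 mmol/L.
2. **Features** — 24 h binning from sepsis onset (mean/max/min/population sd
   for measurements, 24 h sums for drugs), a >2% coverage filter,
   forward-fill/zero-fill imputation and min–max normalization to [−1, 1],
   everything fitted on the training split only.
3. **MDP** — five dose actions per day (none, (0,100], (100,200],
   (200,300], >300 mg hydrocortisone-equivalent; potency registry for
   compound conversion), terminal reward +1/−1 for ICU discharge/death,
   admission-level 70/20/10 split with largest-remainder rounding.
4. **Agent** — a temporal-difference actor-critic (two separate tanh MLPs;
   policy `π_θ(a|s)` and value `V_w(s)`), trained offline on logged
   transitions: `δ = r + γV(s′) − V(s)`, critic descends `δ²`, actor
   ascends `δ ∇_θ log π_θ(a_t|s_t)` with a decaying entropy bonus.
5. **Evaluation** — high-confidence off-policy evaluation: behavior policy
   from a random-forest behavior clone (or state-cluster frequencies) with
   a probability floor, truncated trajectory-level importance weights
   `w(τ) = min(c, Π_t π_e/b)`, and a 95% empirical-Bernstein lower bound on
   the policy value, plus concordance-stratified mortality and per-day
   usage/dose curves.
6. **Explainability** — layer-wise relevance propagation (ε-rule, bias
   treated as a relevance-absorbing unit so conservation is exact) for the
   agent, random-forest importances and micro-average multiclass AUROC for
   the clinician clone, and a Spearman comparison of the two rankings.

Real databases of this kind are access-restricted, so the package ships a
**synthetic EHR generator** with a fully known ground-truth decision
process (latent mean-reverting daily severity; severity-monotone clinician
policy; logistic death model in which moderate doses help at high severity
and harm at low severity). A discrete-severity variant is exactly solvable
by dynamic programming, giving oracles for every statistical claim:
coverage of the lower bound, unbiasedness of importance sampling, and
recovery of the optimal policy.

## Worked example

```r
library(sepsisrl)

dir <- "runs/demo"
cfg <- run_config(list(
  seed = 1,
  simulate = list(n_admissions = 250, seed = 1),
  train    = list(epochs = 15, hidden = c(16, 16), seed = 1),
  explain  = list(num_trees = 100, n_relevance_states = 40)))
report <- run_pipeline(cfg, dir)
```

which logs, stage by stage (abridged):

```
[INFO] simulate: 250 admissions, 50137 events
[INFO] cohort: 189/250 admissions included
[INFO] features: 53 features, 1681 admission-days, 32.36% imputed
[INFO] mdp: 189 trajectories, 1681 day-states
[INFO] train: 15 epochs, final relative error 0.5546, concordance 0.217
[INFO] evaluate: J_e=2.867, J_b=0.492, bound=-24.260
[INFO] explain: clone AUROC 0.702, Spearman -0.343
```

Reading the numbers: 189 of 250 simulated admissions meet the Sepsis-3
criteria (the rest lack an infection pair, are under 18, or stay < 24 h);
their 1681 ICU days form the day-state dataset. This deliberately tiny
15-epoch demonstration run stops while the agent still agrees with the
logged clinician action on only 21.7% of day-states — essentially the 20%
chance level of a five-action space — and the off-policy numbers show what
honest evaluation at this scale looks like: with 38 validation
trajectories the importance-weighted point estimate (`J_e = 2.867`) is
dominated by weight variance (a true value can never leave [−1, 1]) and
the 95% lower bound collapses far below the clinicians' average return
(`J_b = 0.492`), so nothing is certified. Longer training and larger
cohorts tighten all three numbers; the ground-truth experiment below shows
the converged behavior. The full artifact set (states.csv,
trajectories.jsonl, model.json, ope_report.json, rankings.csv,
run_report.json, …) lands in `runs/demo/`.

For a policy-learning experiment with ground truth, work with the
enumerable severity MDP directly:

```r
cfg  <- sim_config(n_admissions = 2000, seed = 5)
mdp  <- severity_mdp(cfg)
b    <- behavior_action_probs(mdp$s, cfg)
sim  <- simulate_severity_stays(mdp, b, 2000, seed = 5)
traj <- severity_trajectories(sim, gamma = 1)
fit  <- train_actor_critic(traj, train_config(gamma = 1, epochs = 300))

rec <- recommend_action(fit$model, matrix(2 * mdp$s - 1, ncol = 1))
pol <- matrix(0, length(mdp$s), 5); pol[cbind(seq_along(rec), rec + 1)] <- 1
true_policy_value(mdp, pol)   # 0.476  (learned policy, exact DP value)
true_policy_value(mdp, b)     # 0.369  (clinician behavior policy)
```

The learned policy withholds steroids below severity ≈ 0.5 and gives a
moderate dose above it, worth 0.476 in expected return (mortality 26.2%)
versus 0.369 (31.5%) for the simulated clinicians; the exact optimum over
severity-threshold policies is 0.482.

A thin CLI wrapper with the same stages lives at `inst/cli/sepsisrl.R`:

```sh
Rscript inst/cli/sepsisrl.R --config demo.yaml --out runs/demo --seed 1
```

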