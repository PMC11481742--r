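# herbrx

Offline reinforcement learning for sequential herbal prescription planning.

## What problem this solves

Chronic-disease care in Traditional Chinese Medicine is sequential: at each
clinic visit the practitioner observes a symptom set, prescribes a
multi-herb formula, and the patient returns with a changed symptom set.
Choosing prescriptions that optimise the *whole treatment trajectory* — a
dynamic treatment regime — is different from recommending the best single
prescription. `herbrx` is for computational researchers working with
longitudinal visit records (patient id, visit order, symptom terms, herb
terms) who want to learn and evaluate such sequential policies without
interacting with live patients.

The pipeline:

1. **States** — a visit's symptoms become a binary vector over the symptom
   vocabulary; the *symptom score* (weighted count, unit weights by
   default) proxies disease severity.
2. **Actions** — distinct prescriptions are K-means-clustered on binary
   herb membership (multiplicity-weighted); each cluster is one discrete
   action, validated by pairwise chi-square tests on herb-composition
   tables and summarised as −log₁₀ P.
3. **Virtual environment** — consecutive visit pairs become tetrads
   (s₁, a, r, s₂) with reward

   R(s, a) = γₑ Σᵢ αᵢ (sᵢ − sᵢ′) + β · Jac(a, a′),  Jac(a, a′) = |a∩a′| / |a∪a′|

   (symptom-score drop plus a Jaccard risk term against recorded care);
   state transitions are predicted by Jaccard-nearest-neighbour lookup in
   the tetrad bank, and episodes stop when the score falls to ≤ 3, drops
   by 60% from baseline, or exceeds 15 iterations.
4. **Agents** — deep Q-learning with experience replay and a target
   network: a feed-forward DQN (400/300 hidden units by default) and a
   recurrent DRQN (300/512 stem, 512-unit LSTM). The networks and their
   training loop are implemented in base-R matrix code and
   finite-difference-verified.
5. **Evaluation** — single-step return (SSR), single-step cumulative
   return (SCR) and multi-step cumulative return (MCR) against the
   recorded-clinician baseline and a uniform-random floor, with relative
   improvement percentages.
6. **Recommendation** — a multi-label sigmoid network maps symptoms (plus,
   optionally, the planned prescription cluster) to a concrete herb set,
   screened by a filter threshold and scored by precision/recall/F1/IoU.

A seeded synthetic cohort generator with a planted syndrome → effective
prescription structure stands in for protected clinical data; its marginals
(≈49.6% single-visit patients, mean ≈3.68 visits, ≈10.4 symptoms per visit,
≈10.1 herbs per prescription) and its treatment-effect gap are documented
in the methods vignette (`vignettes/treatment-planning.Rmd`).

## Worked example

```r
library(herbrx)

gen    <- generate_cohort(generator_config(n_patients = 500, seed = 1))
cohort <- gen$cohort
multi  <- filter_multivisit(cohort)
sp     <- split_cohort(multi, 0.8, seed = 1)

mat <- build_prescription_matrix(sp$train)
sel <- select_cluster_number(mat, c(3, 5, 8), seed = 1)
sel$summary
#>   k mean_neglog10p sd_neglog10p
#> 1 3          300.0          0.0
#> 2 5          233.5        114.8
#> 3 8          204.7        122.2
model <- sel$models[[as.character(sel$best_k)]]

bank <- build_tetrads(sp$train, model)
bank
#> <tetrad bank: 1099 tetrads, 3 actions, state dim 60>
env    <- virtual_env(bank, model)
starts <- do.call(rbind, lapply(sp$train$patients, function(p)
  encode_state(p$visits[[1]], cohort$symptom_vocab)))

dqn <- train_agent(env, starts,
                   qnetwork_spec("dqn", ncol(starts), c(64, 64),
                                 n_actions = model$k),
                   train_config(n_episodes = 120, seed = 1))

rnd <- uniform_policy(model$k)
report <- return_report(list(
  doctor = doctor_returns(sp$test),
  dqn    = list(ssr = policy_ssr(dqn, sp$test, env),
                scr = policy_scr(dqn, sp$test, env),
                mcr = policy_mcr(dqn, sp$test, env)$mcr),
  random = list(ssr = policy_ssr(rnd, sp$test, env, seed = 1),
                scr = policy_scr(rnd, sp$test, env, seed = 1),
                mcr = policy_mcr(rnd, sp$test, env, seed = 1)$mcr)))
print(report, digits = 3)
#>   policy    ssr    scr  mcr ssr_improvement_pct scr_improvement_pct mcr_improvement_pct
#> 1 doctor  0.163  0.706 3.33                  NA                  NA                  NA
#> 2    dqn -0.635  0.513 8.35                -489               -27.3               150.9
#> 3 random -1.439 -0.999 5.80                -981              -241.6                74.4
```

Reading the numbers: on the planted-structure synthetic cohort the trained
policy's multi-step cumulative return (8.35 — roughly, symptoms resolved
over a whole simulated treatment sequence plus the risk-containment credit)
is 151% above the recorded-care baseline (3.33) and well above the
uniform-random floor (5.80). Its *one-step* return is worse than the
clinician's — the policy optimises the long-run return, not the next visit,
and single greedy steps through a nearest-neighbour environment are noisy.
The random policy's high MCR relative to the doctor's is a quirk of
rollout lengths: simulated episodes run until a stopping rule fires,
accumulating reward over more steps than the short recorded sequences.

Recommendation, with and without the planned cluster as input:

```r
rec <- run_recommendation_experiment(cohort, model, thresholds = c(0.2, 0.3),
                                     hidden_sizes = c(64, 32), epochs = 40,
                                     seed = 21)
rec[, c("input_mode", "filter_threshold", "n_herbs_mean",
        "precision", "recall", "f1")]
#>            input_mode filter_threshold n_herbs_mean precision recall    f1
#> 1             symptom              0.2         2.76     0.389  0.115 0.177
#> 2 symptom_plus_scheme              0.2         3.60     0.617  0.231 0.336
#> 3             symptom              0.3         3.95     0.390  0.168 0.235
#> 4 symptom_plus_scheme              0.3         5.51     0.613  0.351 0.447
```

Knowing the treatment scheme (the prescription cluster) roughly doubles F1
over symptoms alone — the degradation experiment that justifies coupling
the planner to the recommender.

A thin command-line front end over the same functions lives at
`inst/cli/herbrx.R`:

```sh
Rscript inst/cli/herbrx.R all --seed 1 --outdir out/
```

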