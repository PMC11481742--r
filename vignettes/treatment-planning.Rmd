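---
title: "Offline Q-learning for sequential herbal prescription planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Offline Q-learning for sequential herbal prescription planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbrx)
```

## The problem

In Traditional Chinese Medicine (TCM) a chronic-disease patient is treated
over a sequence of clinic visits. At each visit the clinician observes a set
of symptoms, infers a syndrome, and prescribes a multi-herb formula; at the
next visit some symptoms have resolved, some persist, and some have
reappeared. Choosing the prescription that maximises the outcome of the
*whole sequence* — not just the next visit — is a dynamic-treatment-regime
problem. `herbrx` treats it as offline reinforcement learning: longitudinal
visit records become a virtual treatment environment, a Q-learning agent
learns a policy over a discrete space of prescription *clusters*, and a
multi-label neural network turns the planned cluster plus the current
symptoms into a concrete herb set.

Because real sequential TCM records are protected clinical data, the package
includes a seeded synthetic cohort generator with a planted latent syndrome
structure, so that every stage of the pipeline — and every claim the test
suite makes — can be exercised end to end on data whose ground truth is
known.

## State, action, reward

**State.** A patient's state is the binary indicator vector of the symptom
vocabulary: `encode_state()` marks present symptoms 1 and absent ones 0.
Symptom grading is hard to obtain for diabetes-like conditions, so all
symptom weights default to 1 and the *symptom score* of a state is simply
its symptom count — a patient with 5 symptoms has score 5.

**Action.** Visit-level prescriptions are herb sets; thousands of distinct
sets are far too many discrete actions. `build_prescription_matrix()`
deduplicates prescriptions into binary herb-membership rows with
multiplicities, and `cluster_prescriptions()` runs multiplicity-weighted
K-means (k-means++ seeding, Lloyd iterations, farthest-point repair of empty
clusters). One cluster is one action. Each cluster also carries a
*representative* herb set — by default its `round(mean herbs per
prescription)` most frequent herbs — which stands in for the cluster
whenever a concrete herb set is needed (the Jaccard risk term below).

**Reward.** The per-step reward is

$$R(s, a) \;=\; \gamma_e \sum_i \alpha_i\,(s_i - s_i') \;+\; \beta\,
\mathrm{Jac}(a, a'),\qquad
\mathrm{Jac}(a, a') = \frac{|a \cap a'|}{|a \cup a'|},$$

a therapeutic-effect term (drop in weighted symptom score between
consecutive states) plus a risk-containment term rewarding similarity
between the proposed herb set $a'$ and the clinician's recorded one $a$.
The two weights have no canonical values; the package defaults to
$\gamma_e = \beta = 1$, which puts the two terms on comparable scales
(score drops are a few symptom units; Jaccard is in $[0,1]$), and exposes
both in `reward_config()`. Note that $\gamma_e$ (`effect_weight`) is
distinct from the temporal discount used in training (`discount`, default
0.9); conflating the two symbols is a common source of confusion.

## Choosing the number of clusters

`pairwise_cluster_difference()` scores a clustering by how distinct its
clusters' herb compositions are: for each cluster pair it builds a
$2 \times H'$ contingency table of multiplicity-weighted herb occurrence
counts (dropping all-zero herb columns), computes the chi-square statistic
with $H'-1$ degrees of freedom and no continuity correction, and reports
$-\log_{10} P$. The p-value is computed on the log scale
(`pchisq(log.p = TRUE)`), so the statistic is exact far beyond double
underflow, and then clipped at 300 for storage and display.

`select_cluster_number()` fits a grid of `k` values and picks the `k` with
the largest mean off-diagonal $-\log_{10} P$. Two behaviours of this
criterion matter in practice:

* the statistic grows with the counts in the table, so *merging* clusters
  that are already well separated never lowers it — the criterion favours
  the smallest `k` that still separates the data, and the mean difference
  decreases monotonically as `k` grows past the intrinsic structure;
* on strongly structured data every `k` at or below the intrinsic cluster
  count saturates the clip, producing exact ties at 300.

Ties are therefore broken toward the **larger** `k`: at equal statistical
separation the finer action space is preferred, as it gives the policy more
personalised prescriptions to choose from. On planted-template cohorts this
rule recovers the planted cluster count; the per-`k` mean ± sd summary is
always returned so the full profile can be inspected.

## The virtual environment

Training on live patients is impossible, so consecutive visit pairs are
compiled into *tetrads* $(s_1, a, r, s_2)$ by `build_tetrads()`: the action
is the cluster of the recorded prescription and the reward is evaluated
with the recorded herbs standing in for the prediction (their Jaccard with
themselves is 1). The tetrad bank *is* the environment:

* **Transition.** `predict_transition()` screens the bank for tetrads with
  the queried action and returns the $s_2$ of the tetrad whose $s_1$
  symptom set is most Jaccard-similar to the current state. Ties break to
  the lowest tetrad index; if no tetrad carries the action the globally
  nearest tetrad is used and flagged.
* **Off-policy reward.** When the agent picks an action that differs from
  the recorded one, the reward is recomputed from the realised transition:
  the effect term from the current state and the matched tetrad's $s_2$,
  and the risk term between the matched tetrad's recorded herbs and the
  chosen cluster's representative set. A config flag
  (`use_stored_reward`) reuses the tetrad's stored reward instead; the
  recomputed form is the default because it reflects the state the episode
  actually visited.
* **Termination.** Three stopping rules, checked in fixed order: symptom
  score at or below 3; a 60% reduction from the initial score (between the
  30% "effective" and 70% "markedly effective" clinical criteria); more
  than 15 treatment iterations. The fixed order makes the reported reason
  deterministic when several rules hold at once.

## The agents

Two Q-networks are provided (`qnetwork_spec()`):

* **DQN** — fully connected, input → 400 → 300 → `n_actions` by default,
  rectified-linear hidden layers and a linear output;
* **DRQN** — a fully connected stem (300, 512 by default), an LSTM layer
  (512 units) and a linear action-value head, so the value estimate can
  condition on the visit history rather than the current state alone.

There is no deep-learning framework dependency: the dense and LSTM layers,
their backward passes, and the SGD/Adam updates are implemented directly on
base-R matrices and verified against finite differences in the test suite.

Training (`train_agent()`) is standard deep Q-learning: regression target
$y = r + \gamma \max_a Q_\text{target}(s', a)$ with $y = r$ at episode ends,
squared TD-error loss, epsilon-greedy behaviour policy with a constant
exploration rate, uniform without-replacement replay minibatches, one
gradient batch per environment step after a warm-up of one batch, and a
target network hard-copied every `target_sync_interval` batches. Defaults
follow the conventional setting for this problem: learning rate 0.01 (plain
SGD), discount 0.9, exploration 0.1, batch 32, target sync every 100
batches. A global-norm gradient clip (default 5) is applied as a numerical
safeguard; on the tabular-limit test it never binds.

Protocol details the method itself leaves open, fixed here and exposed in
`train_config()`:

* **Replay source.** `"mixed"` (default) pre-fills the replay buffer with
  the recorded tetrads and appends rollout transitions; `"bank"` trains on
  recorded tetrads only (fitted-Q style, no rollouts); `"rollout"` uses
  only simulated experience. Bank transitions carry no episode-end marker
  and are treated as non-terminal; rollout transitions carry their
  termination flag.
* **Recurrent training.** The DRQN trains on contiguous episode windows of
  `sequence_length` (default 8) steps, zero-initialised context, padding
  masked out of the loss; target values run the target network over the
  next-state sequence from a zero context (a truncated-history
  approximation).
* **Replay capacity** defaults to 10,000 transitions; no prioritisation,
  no annealing, no double/dueling variants — deliberately the plainest
  correct algorithm.

## Evaluation

Three return metrics (`doctor_returns()`, `policy_ssr()`, `policy_scr()`,
`policy_mcr()`):

* **SSR** — mean one-step reward from each test patient's first-visit
  state;
* **SCR** — mean one-step reward over *all* recorded visit states except
  each last one, pooled over steps (a per-patient-first averaging variant
  is available, as the pooled/per-patient choice is a genuine ambiguity);
* **MCR** — mean over patients of the summed rewards of a full greedy
  rollout through the virtual environment until a stopping rule fires.

Returns are undiscounted sums at evaluation time — the 0.9 discount is a
training device — and evaluation policies are greedy
($\epsilon = 0$). The clinician baseline computes the same metrics on the
recorded sequences; its risk term is the self-Jaccard (1) by default, with
an option to exclude it. `improvement_rate()` reports
$100\,(\text{model}-\text{baseline})/\text{baseline}$, the format used for
benchmark comparisons.

## Herb recommendation

`train_recommender()` fits a fully connected multi-label network (two
hidden layers, 256/128 by default) from the symptom vector — optionally
concatenated with a one-hot block for the planned prescription cluster —
to independent per-herb sigmoid probabilities under binary cross-entropy,
with Adam updates. `predict_prescription()` screens the probabilities with
a *filter threshold* in $(0,1)$: smaller values are stricter. Under the
default `one_minus_threshold` mapping a herb is kept when its probability
is at least $1-\text{threshold}$, so the predicted herb count grows with
the threshold, matching the "stricter/looser screening" semantics; the
`direct` mapping is available for the opposite reading. Predictions never
come back empty (the top herb is the fallback).

`run_recommendation_experiment()` is the degradation experiment: train a
symptom-only model and a symptom-plus-scheme model on a patient-level
train split, evaluate both across a threshold grid, and report precision,
recall, F1 (harmonic mean of the averaged precision and recall), IoU and
the predicted herb count mean ± sd. The `"scrambled"` scheme source
replaces the recorded cluster with a random one — the ablation control
that should (and in tests does) erase the scheme's advantage.

## The synthetic cohort generator

`generate_cohort()` emulates the marginal structure reported for a
sequential diabetes cohort and plants a recoverable treatment signal:

* **Visit counts** — a point mass at 1 visit (probability 0.496) mixed
  with $2 + \text{Poisson}(\lambda)$, $\lambda$ solved so the mixture mean
  is 3.68. Writing the multi-visit branch as $2 + \text{Poisson}$ keeps
  "multi-visit" patients at two or more visits while preserving the mean.
* **Symptom counts** — rounded normal with mean 10.386 (sd 4, a free
  parameter), truncated to 1..40 by rejection; symptoms are drawn without
  replacement, weighted by the patient's syndrome template.
* **Herb counts** — rounded normal, mean 10.059 (sd 4), truncated to the
  vocabulary.
* **Latent structure** — each patient carries one of `n_syndromes` latent
  classes; each class has a symptom core (16 terms by default, a
  configurable fraction shared across classes) and a disjoint matched herb
  template. The recorded clinician draws from the matched template with
  probability `doctor_skill` (default 0.7 — good but improvable care,
  which is the premise that makes learned policies interesting).
* **Dynamics** — between visits each present symptom resolves with
  probability 0.30 under matched treatment and 0.10 under mismatched
  treatment; each absent core symptom relapses with probability 0.45.

The dynamics defaults were calibrated once, analytically, to keep the
symptom-count marginal approximately stationary across visits: with core
size $K$, mean cure rate $q$ and relapse rate $r$, the core symptom count
equilibrates at $K r/(q+r)$. With $K = 16$, the recorded-care mix
$q \approx 0.7\cdot 0.30 + 0.3\cdot 0.10 = 0.24$ and $r = 0.45$ this gives
$\approx 10.4$, matching the target mean of 10.386; matched-only treatment
equilibrates lower ($\approx 9.6$) and random treatment higher
($\approx 11.7$), which is exactly the planted effect gap the policy tests
rely on.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: real symptom co-occurrence structure beyond
the syndrome cores, vocabulary sizes in the thousands, non-stationary
disease progression, dosage, comorbidity, or clinician heterogeneity.
Results on synthetic cohorts validate the machinery (the pipeline learns a
signal that is truly there), not clinical effectiveness.

Ground-truth labels (syndrome per patient, matched flag per visit) are
written to a sidecar file, never into the cohort itself, so downstream
stages cannot leak them.

## Numerical and scale choices

* Chi-square entries are clipped at 300; degenerate one-column tables warn
  and score 0; a single-prescription cluster is still tested.
* K-means uses 5 k-means++ restarts by default and breaks assignment ties
  to the first (lowest-index) centroid; all stochastic stages take an
  explicit seed and leave the global RNG untouched (`withr::with_seed`).
* Greedy action ties resolve to the lowest action id; transition-similarity
  ties to the lowest tetrad index.
* The test suite and the acceptance script run the full pipeline at desk
  scale: 500-patient cohorts, 3–5 syndromes, 60–90-term vocabularies,
  64-unit hidden layers and 120 training episodes. These sizes are the
  package's chosen defaults for reproducible examples; the architecture
  defaults (400/300 DQN, 300/512/LSTM-512 DRQN, 30 actions) match the
  full-scale setting and are what `qnetwork_spec()` produces out of the
  box.
* Unknown symptom terms at encode time are an error, never silently
  dropped — silent drops would corrupt symptom scores.

## Known limitations

* The nearest-neighbour transition model replays recorded outcomes; it
  cannot extrapolate to states far from the bank, and rollouts that leave
  the support of the data fall back to the globally nearest tetrad.
* The risk term rewards agreement with recorded care, which regularises
  the policy toward clinician behaviour; a policy that is genuinely better
  than *and different from* recorded care is penalised on that term.
* Sequence lengths of learned policies tend to exceed the clinician's
  (termination is score-driven and the agents are not penalised for long
  sequences) — visible in `sequence_length_stats()` output.
* Improvement percentages over a baseline are scale-free but noisy on
  small test splits; the package reports means without significance tests.
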