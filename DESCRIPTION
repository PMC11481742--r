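Package: herbrx
Title: Offline Reinforcement Learning for Sequential Herbal Prescription Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for learning dynamic herbal treatment regimes from
    longitudinal clinical visit records. Visit sequences (symptom sets and
    multi-herb prescriptions) are turned into an offline virtual treatment
    environment: prescriptions are K-means clustered into a discrete action
    space validated by pairwise chi-square tests, consecutive visits become
    (state, action, reward, next state) tetrads, and state transitions are
    predicted by Jaccard nearest neighbour lookup. Deep Q-learning agents
    (feed-forward and recurrent) are trained against this environment and
    evaluated by single-step, single-step-cumulative and multi-step
    cumulative returns against the recorded clinician baseline. A multi-label
    neural recommender maps symptoms plus a planned prescription cluster to a
    concrete herb set. A seeded synthetic cohort generator with a planted
    latent syndrome structure makes the full pipeline testable without
    protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
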