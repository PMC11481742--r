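test_that("symptom score, Jaccard and the reward reproduce direct substitutions", {
  expect_equal(symptom_score(c(1, 1, 1, 1, 1, 0, 0)), 5)
  expect_equal(symptom_score(numeric(4)), 0)
  expect_equal(symptom_score(c(1, 1, 1), c(2, 1, 0)), 3)
  expect_error(symptom_score(c(1, 0), c(1, 1, 1)), "length")

  expect_equal(jaccard(c("A", "B", "C"), c("A", "B", "C")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard(character(0), character(0)), 1)
  expect_equal(jaccard(character(0), "A"), 0)

  mk <- function(n, d = 15) { v <- numeric(d); v[seq_len(n)] <- 1; v }
  cfg <- reward_config(1, 1)
  expect_equal(reward(mk(13), mk(8), c("A", "B"), c("A", "B"), cfg), 6)
  cfg0 <- reward_config(1, 0)
  expect_equal(reward(mk(13), mk(8), c("A", "B"), c("X"), cfg0), 5)
  # zero score change, risk weight 2, Jaccard 1/4 -> reward 0.5
  cfg2 <- reward_config(1, 2)
  expect_equal(reward(mk(10), mk(10), c("A", "B"), c("A", "C", "D"), cfg2), 0.5)
})

test_that("reward is affine in the effect and risk weights", {
  withr::with_seed(11L, {
    for (i in 1:20) {
      d <- 12L
      s <- rbinom(d, 1L, 0.5); s2 <- rbinom(d, 1L, 0.5)
      a <- sample(letters[1:6], 3); b <- sample(letters[1:6], 3)
      g1 <- runif(1, 0, 3); g2 <- runif(1, 0, 3)
      b1 <- runif(1, 0, 3); b2 <- runif(1, 0, 3)
      r_g1 <- reward(s, s2, a, b, reward_config(g1, b1))
      r_g2 <- reward(s, s2, a, b, reward_config(g2, b1))
      r_mid <- reward(s, s2, a, b, reward_config((g1 + g2) / 2, b1))
      expect_equal(r_mid, (r_g1 + r_g2) / 2, tolerance = 1e-12)
      r_b2 <- reward(s, s2, a, b, reward_config(g1, b2))
      r_bmid <- reward(s, s2, a, b, reward_config(g1, (b1 + b2) / 2))
      expect_equal(r_bmid, (r_g1 + r_b2) / 2, tolerance = 1e-12)
    }
  })
})

test_that("tetrad banks count one transition per consecutive visit pair", {
  g <- generate_cohort(generator_config(n_patients = 40L, seed = 6L))
  multi <- filter_multivisit(g$cohort)
  m <- build_prescription_matrix(multi)
  model <- cluster_prescriptions(m, 3L, seed = 1L)
  bank <- build_tetrads(multi, model)
  expect_equal(n_tetrads(bank), sum(visit_counts(multi) - 1L))
  # rewards carry the self-Jaccard risk term
  expect_equal(bank$reward[1],
               sum(bank$s1[1, ]) - sum(bank$s2[1, ]) + 1)
  expect_error(build_tetrads(g$cohort, model), "single-visit")
  # persistence round-trip
  tmp <- tempfile(fileext = ".jsonl")
  write_tetrads(bank, tmp)
  back <- read_tetrads(tmp)
  expect_equal(back$s1, bank$s1, ignore_attr = TRUE)
  expect_equal(back$action, bank$action)
  expect_equal(back$reward, bank$reward)
  expect_equal(back$doctor_herbs, bank$doctor_herbs)
})

test_that("transition prediction matches an exhaustive Jaccard scan", {
  bank <- random_bank(50L, 12L, 3L, seed = 14L)
  oracle <- function(state, action) {
    cand <- which(bank$action == action)
    if (length(cand) == 0L) cand <- seq_len(n_tetrads(bank))
    sims <- vapply(cand, function(i) {
      a <- which(bank$s1[i, ] != 0); b <- which(state != 0)
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1))
    cand[which.max(sims)]
  }
  withr::with_seed(15L, {
    for (q in 1:30) {
      state <- rbinom(12L, 1L, 0.3)
      if (sum(state) == 0) state[1] <- 1
      action <- sample.int(3L, 1L)
      got <- predict_transition(state, action, bank)
      expect_equal(got$index, oracle(state, action))
    }
  })
  # exact s1 match dominates
  got <- predict_transition(bank$s1[7, ], bank$action[7], bank)
  expect_equal(got$similarity, 1)
  expect_equal(got$next_state, bank$s2[got$index, ], ignore_attr = TRUE)
  # tie-break: equal-similarity candidates resolve to the lowest index
  tie <- bank
  tie$s1 <- rbind(c(1, 1, rep(0, 10)), c(1, 1, rep(0, 10)))
  tie$s2 <- rbind(c(1, rep(0, 11)), c(0, 1, rep(0, 10)))
  tie$action <- c(1L, 1L); tie$reward <- c(0, 0)
  tie$doctor_herbs <- list("h", "h"); tie$patient_id <- c("a", "b")
  tie$visit_index <- c(0L, 0L); tie$by_action <- split(1:2, tie$action)
  expect_equal(predict_transition(c(1, 1, rep(0, 10)), 1L, tie)$index, 1L)
  # missing action falls back to the global nearest tetrad
  fb <- predict_transition(bank$s1[1, ], 999L, bank)
  expect_true(fb$fallback)
})

test_that("termination rules fire with the documented precedence", {
  cfg <- termination_config()
  ep <- function(score, initial, steps) {
    s <- numeric(40); s[seq_len(score)] <- 1
    structure(list(current = s, initial_score = initial, step_count = steps,
                   done = FALSE, termination_reason = "none"),
              class = "herbrx_episode")
  }
  # a sequence starting at score 13 and reaching 2 stops on the absolute rule
  expect_equal(is_terminal(ep(2, 13, 5), cfg),
               list(done = TRUE, reason = "score_low"))
  expect_equal(is_terminal(ep(4, 10, 3), cfg),
               list(done = TRUE, reason = "reduced"))
  expect_equal(is_terminal(ep(15, 20, 16), cfg),
               list(done = TRUE, reason = "max_steps"))
  expect_equal(is_terminal(ep(15, 20, 15), cfg)$done, FALSE)
  # precedence: score_low wins when several rules hold at once
  expect_equal(is_terminal(ep(2, 100, 99), cfg)$reason, "score_low")
  expect_equal(is_terminal(ep(4, 100, 99), cfg)$reason, "reduced")
  # monotonicity in the config parameters
  withr::with_seed(16L, {
    for (i in 1:25) {
      e <- ep(sample(1:30, 1), sample(5:40, 1), sample(0:20, 1))
      c1 <- termination_config(runif(1, 1, 6), runif(1, 0.2, 0.8),
                               sample(3:18, 1))
      if (is_terminal(e, c1)$done) {
        c2 <- termination_config(c1$score_threshold + 1,
                                 min(c1$reduction_fraction + 0.1, 0.95),
                                 max(1L, c1$max_steps - 2L))
        expect_true(is_terminal(e, c2)$done)
      }
    }
  })
})

test_that("episodes step deterministically and telescope their rewards", {
  g <- generate_cohort(generator_config(n_patients = 40L, seed = 19L))
  multi <- filter_multivisit(g$cohort)
  model <- cluster_prescriptions(build_prescription_matrix(multi), 3L, seed = 1L)
  rcfg <- reward_config(1, 0)  # pure score drop
  bank <- build_tetrads(multi, model, rcfg)
  tcfg <- termination_config(max_steps = 6L)
  run <- function() {
    ep <- env_reset(multi$patients[[1]]$visits[[1]], multi$symptom_vocab)
    total <- 0
    while (!ep$done) {
      st <- env_step(ep, 1L, bank, model, rcfg, tcfg)
      total <- total + st$reward
      ep <- st$state
    }
    list(total = total, final = symptom_score(ep$current),
         reason = ep$termination_reason, ep = ep)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1, r2)  # deterministic rollouts
  # undiscounted pure-effect rewards telescope to initial - final score
  init <- symptom_score(encode_state(multi$patients[[1]]$visits[[1]],
                                     multi$symptom_vocab))
  expect_equal(r1$total, init - r1$final)
  expect_error(env_step(r1$ep, 1L, bank, model, rcfg, tcfg), "finished")
})
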