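test_that("network architectures match their specs with closed-form parameter counts", {
  spec <- qnetwork_spec("dqn", 200L, n_actions = 30L)
  expect_equal(spec$hidden_sizes, c(400L, 300L))
  expect_equal(agent_parameter_count(spec),
               200 * 400 + 400 + 400 * 300 + 300 + 300 * 30 + 30)  # 209,730
  agent <- init_agent(spec, seed = 1L)
  expect_equal(agent_parameter_count(agent), 209730L)
  # drqn: stem 10 -> 20 -> 16, LSTM 16, head 16 -> 4
  dspec <- qnetwork_spec("drqn", 10L, c(20L, 16L), recurrent_size = 16L,
                         n_actions = 4L)
  expect_equal(agent_parameter_count(dspec),
               (10 * 20 + 20) + (20 * 16 + 16) +
                 (16 * 64 + 16 * 64 + 64) + (16 * 4 + 4))
  # deterministic initialisation
  expect_identical(init_agent(spec, seed = 9L)$params,
                   init_agent(spec, seed = 9L)$params)
  expect_error(qnetwork_spec("dqn", 0L), "positive")
})

test_that("forward passes respect zero weights, batching and recurrent causality", {
  spec <- qnetwork_spec("dqn", 5L, c(6L), n_actions = 3L)
  agent <- init_agent(spec, seed = 2L)
  zero <- agent
  zero$params$mlp$W <- lapply(zero$params$mlp$W, function(w) w * 0)
  zero$params$mlp$b <- lapply(zero$params$mlp$b, function(b) b * 0)
  expect_equal(q_values(zero, rep(1, 5))$q, rep(0, 3))
  # batch independence: row order does not change per-row outputs
  X <- withr::with_seed(3L, matrix(rbinom(20, 1L, 0.5), 4L, 5L))
  q_all <- q_values(agent, X)$q
  q_rev <- q_values(agent, X[4:1, ])$q
  expect_equal(q_all, q_rev[4:1, ])
  expect_error(q_values(agent, rep(1, 7)), "dimension")
  # drqn: a length-1 sequence from zero context equals treating it as a start
  dspec <- qnetwork_spec("drqn", 5L, c(6L, 6L), recurrent_size = 6L,
                         n_actions = 3L)
  dag <- init_agent(dspec, seed = 4L)
  s <- c(1, 0, 1, 0, 0)
  expect_equal(q_values(dag, s)$q,
               q_values(dag, matrix(s, nrow = 1L))$q)
  # context carries: two-step sequence differs from the bare second state
  s2 <- c(0, 1, 1, 0, 1)
  q_seq <- q_values(dag, rbind(s, s2))$q
  q_bare <- q_values(dag, s2)$q
  expect_false(isTRUE(all.equal(q_seq, q_bare)))
  # but equals stepping with the carried context
  ctx <- q_values(dag, s)$context
  expect_equal(q_values(dag, s2, ctx)$q, q_seq)
})

test_that("epsilon-greedy selection is greedy, tie-breaking and uniform at the extremes", {
  spec <- qnetwork_spec("dqn", 2L, c(4L), n_actions = 3L)
  agent <- init_agent(spec, seed = 5L)
  # craft exact outputs through a zeroed head with fixed biases
  agent$params$mlp$W <- lapply(agent$params$mlp$W, function(w) w * 0)
  agent$params$mlp$b[[1]] <- rep(0, 4)
  agent$params$mlp$b[[2]] <- c(0.1, 0.9, 0.3)
  expect_equal(select_action(agent, c(1, 0), epsilon = 0)$action, 2L)
  agent$params$mlp$b[[2]] <- c(0.5, 0.5, 0.5)
  expect_equal(select_action(agent, c(1, 0), epsilon = 0)$action, 1L)
  # epsilon = 1: empirical frequencies uniform within 3 sigma
  n <- 6000L
  draws <- withr::with_seed(6L, vapply(seq_len(n), function(i)
    select_action(agent, c(1, 0), epsilon = 1)$action, integer(1)))
  p <- 1 / 3
  sigma <- sqrt(p * (1 - p) / n)
  for (a in 1:3) expect_lt(abs(mean(draws == a) - p), 3 * sigma)
})

test_that("Q-learning on the chain MDP recovers the value-iteration solution", {
  bank <- mk_chain_bank()
  env <- virtual_env(bank, NULL)
  spec <- qnetwork_spec("dqn", 2L, c(32L, 32L), n_actions = 2L)
  cfg <- train_config(replay_source = "bank", n_episodes = 150L,
                      bank_steps_per_episode = 40L, seed = 3L)
  agent <- train_agent(env, NULL, spec, cfg)
  oracle <- chain_mdp_oracle(0.9)
  q <- rbind(q_values(agent, c(1, 0))$q, q_values(agent, c(0, 1))$q)
  expect_equal(max.col(q), max.col(oracle))
  expect_lt(max(abs(q - oracle)), 0.05)
  # myopic limit: discount 0 learns immediate rewards, greedy = argmax r
  cfg0 <- train_config(replay_source = "bank", discount = 0,
                       n_episodes = 60L, bank_steps_per_episode = 40L,
                       seed = 3L)
  ag0 <- train_agent(env, NULL, spec, cfg0)
  q0 <- rbind(q_values(ag0, c(1, 0))$q, q_values(ag0, c(0, 1))$q)
  expect_equal(max.col(q0), c(2L, 1L))
  expect_lt(max(abs(q0 - rbind(c(0, 1), c(1, 0)))), 0.1)
})

test_that("training runs are reproducible and checkpoints restore greedy behaviour", {
  bank <- mk_chain_bank()
  env <- virtual_env(bank, NULL)
  spec <- qnetwork_spec("dqn", 2L, c(8L), n_actions = 2L)
  cfg <- train_config(replay_source = "bank", n_episodes = 10L,
                      bank_steps_per_episode = 10L, seed = 8L)
  a1 <- train_agent(env, NULL, spec, cfg)
  a2 <- train_agent(env, NULL, spec, cfg)
  expect_identical(a1$params, a2$params)
  expect_identical(a1$curve, a2$curve)
  tmp <- tempfile(fileext = ".rds")
  save_agent(a1, tmp)
  back <- load_agent(tmp)
  expect_equal(q_values(back, c(1, 0))$q, q_values(a1, c(1, 0))$q)
  expect_true(file.exists(paste0(tmp, ".json")))
  # recurrent training also runs and is reproducible at a tiny scale
  dspec <- qnetwork_spec("drqn", 2L, c(8L, 8L), recurrent_size = 8L,
                         n_actions = 2L)
  d1 <- train_agent(env, NULL, dspec,
                    train_config(replay_source = "bank", n_episodes = 5L,
                                 bank_steps_per_episode = 5L, seed = 8L))
  d2 <- train_agent(env, NULL, dspec,
                    train_config(replay_source = "bank", n_episodes = 5L,
                                 bank_steps_per_episode = 5L, seed = 8L))
  expect_identical(d1$params, d2$params)
})
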