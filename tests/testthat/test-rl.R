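# RL tuner: value network, rollout bookkeeping, clipped update, loop
# invariants.

test_that("value network output is sigmoid-bounded and 0.5 when untrained", {
  vn <- new_value_net(d = 8, hidden = 6, seed = 2)
  set.seed(3)
  vals <- vapply(seq_len(1000), function(i) {
    estimate_value(vn, rnorm(8, sd = 5))
  }, numeric(1))
  expect_true(all(vals > 0 & vals < 1))
  # zero-initialized final layer puts every estimate at sigmoid(0)
  expect_true(all(abs(vals - 0.5) < 1e-12))
  expect_error(estimate_value(vn, rnorm(5)), class = "rxnrl_error_shape")
})

test_that("value regression converges to a constant reward", {
  vn <- new_value_net(d = 4, hidden = 8, seed = 1)
  opt <- rxnrl:::new_adam()
  states <- withr::with_seed(2, lapply(1:20, function(i) rnorm(4)))
  for (step in 1:200) {
    vn <- rxnrl:::value_update(vn, states, rep(0.7, 20), opt, lr = 1e-2)
  }
  preds <- vapply(states, function(s) estimate_value(vn, s), numeric(1))
  expect_true(all(abs(preds - 0.7) < 0.05))
})

# A micro reward model that needs no encoder: known tables only.
stub_reward_model <- function(known) {
  recs <- make_labeled_toy(5, 15)
  rm <- fit_reward_model(recs, epochs = 1, seed = 1)
  rm$known_pos <- known$reaction[known$label == "positive"]
  rm$known_neg <- known$reaction[known$label == "negative"]
  rm
}

test_that("rollouts record zero KL at initialization and obey kl_coeff", {
  fit <- tiny_trained_policy()
  rx <- small_reaction_set()
  rx$label <- "positive"
  rm <- stub_reward_model(rx)
  vn <- new_value_net(fit$policy$dims$d, seed = 1)
  cfg <- rl_config(kl_coeff = 0.1, rollout_lhs = 5, samples_per_lhs = 2,
                   seed = 4)
  batch <- collect_rollouts(fit$policy, fit$policy, rm, rx$lhs, vn, cfg)
  kls <- vapply(batch$items, `[[`, numeric(1), "kl")
  expect_true(all(abs(kls) < 1e-9))
  expect_equal(batch$mean_kl, 0, tolerance = 1e-9)
  # kl_coeff = 0 makes the shaped reward equal the raw reward
  cfg0 <- rl_config(kl_coeff = 0, rollout_lhs = 5, samples_per_lhs = 2,
                    seed = 4)
  b0 <- collect_rollouts(fit$policy, fit$policy, rm, rx$lhs, vn, cfg0)
  for (it in b0$items) expect_identical(it$rtilde, it$reward)
  # rewards bounded
  expect_true(all(vapply(batch$items, `[[`, numeric(1), "reward") >= 0))
  expect_true(all(vapply(batch$items, `[[`, numeric(1), "reward") <= 1))
})

test_that("zero advantages leave the policy untouched; on-policy clip fraction is zero", {
  fit <- tiny_trained_policy()
  rx <- small_reaction_set()
  rx$label <- "positive"
  rm <- stub_reward_model(rx)
  vn <- new_value_net(fit$policy$dims$d, seed = 1)
  cfg <- rl_config(rollout_lhs = 4, samples_per_lhs = 1, seed = 2,
                   adv_normalize = FALSE)
  batch <- collect_rollouts(fit$policy, fit$policy, rm, rx$lhs, vn, cfg)
  zeroed <- batch
  zeroed$items <- lapply(zeroed$items, function(it) {
    it$advantage <- 0
    it
  })
  upd <- policy_update(fit$policy, vn, zeroed, cfg)
  expect_identical(upd$policy$params, fit$policy$params)
  # genuine on-policy first step: ratios are one, nothing clips
  upd2 <- policy_update(fit$policy, vn, batch, cfg)
  expect_identical(upd2$stats$clip_fraction, 0)
})

test_that("a one-token bandit concentrates probability on the rewarded arm", {
  vocab <- structure(c("<bos>", "<eos>", "C", "O", "N"), class = "rxnrl_vocab")
  pol <- new_policy(vocab, d = 8, n_heads = 2, ff = 12, n_enc = 1, n_dec = 1,
                    max_len = 1, seed = 6)
  vn <- new_value_net(8, seed = 1)
  cfg <- rl_config(kl_coeff = 0, rollout_lhs = 1, samples_per_lhs = 16,
                   lr_policy = 5e-3, adv_normalize = FALSE, seed = 3)
  opt_p <- rxnrl:::new_adam()
  opt_v <- rxnrl:::new_adam()
  p_arm <- function(p) {
    enc_out <- rxnrl:::encoder_fwd(p, 3L)$out
    exp(rxnrl:::next_token_logp(p, enc_out, 1L))[3]
  }
  p0 <- p_arm(pol)
  traj <- numeric(50)
  for (step in seq_len(50)) {
    items <- withr::with_seed(step, lapply(seq_len(16), function(i) {
      s <- sample_decode(pol, "C", max_len = 1)
      state <- rxnrl:::lhs_state(pol, "C")
      list(lhs = "C", tokens = s$tokens, smiles = s$smiles,
           logp_policy = sum(s$logp), logp_ref = sum(s$logp),
           reward = as.numeric(s$tokens[1] == 3L), kl = 0,
           rtilde = as.numeric(s$tokens[1] == 3L), state = state,
           value = estimate_value(vn, state),
           advantage = as.numeric(s$tokens[1] == 3L) -
             estimate_value(vn, state))
    }))
    batch <- structure(
      list(items = items,
           mean_reward = mean(vapply(items, `[[`, numeric(1), "reward")),
           mean_kl = 0),
      class = "rollout_batch"
    )
    upd <- policy_update(pol, vn, batch, cfg, opt_p, opt_v)
    pol <- upd$policy
    vn <- upd$value_net
    traj[step] <- p_arm(pol)
  }
  expect_gt(traj[50], 0.9)
  expect_gt(traj[50], p0)
  # the probability of the rewarded arm rises essentially monotonically
  expect_true(mean(diff(traj) >= -0.02) > 0.9)
})

test_that("train_rl freezes the reference, is deterministic, and guards KL", {
  fit <- tiny_trained_policy()
  rx <- small_reaction_set()
  rx$label <- "positive"
  bundle <- rxnrl:::new_reaction_bundle(
    train = rx, valid = rx[1:4, ], test = rx[5:8, ], seed = 1,
    ratios = c(40, 30, 30)
  )
  rm <- stub_reward_model(rx)
  cfg <- rl_config(epochs = 2, rollout_lhs = 4, samples_per_lhs = 1,
                   eval_every = 1, eval_beams = 2, seed = 5)
  before <- fit$policy$params
  out1 <- train_rl(fit$policy, bundle, rm, cfg)
  expect_identical(out1$ref_policy$params, before)
  out2 <- train_rl(fit$policy, bundle, rm, cfg)
  expect_identical(out1$history, out2$history)
  h <- out1$history
  expect_true(all(h$mean_reward >= 0 & h$mean_reward <= 1))
  expect_true(all(h$mean_kl >= -1e-9))
  expect_identical(nrow(h), 2L)
  # the KL guard aborts with a diagnostic
  cfg_guard <- rl_config(epochs = 1, rollout_lhs = 4, samples_per_lhs = 1,
                         kl_guard = -1, seed = 5)
  expect_error(train_rl(fit$policy, bundle, rm, cfg_guard),
               class = "rxnrl_error_kl_collapse")
})
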