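# The RLHF-style tuner: rollouts from the policy, rewards from the reward
# model, a sigmoid-output value network as baseline, and a clipped
# policy-gradient update anchored to the frozen reference policy by a
# KL penalty on the per-sequence reward.

#' Configuration for RL tuning
#'
#' @param kl_coeff Weight of the per-sequence KL penalty towards the
#'   reference policy (>= 0).
#' @param clip_eps Clipping half-width for the surrogate ratio (> 0).
#' @param rollout_lhs Left-hand sides sampled per epoch.
#' @param samples_per_lhs Products sampled per left-hand side.
#' @param epochs Number of collect/update cycles.
#' @param minibatch Rollouts per policy-gradient step (each rollout
#'   batch is split into minibatches, giving several small clipped
#'   steps per epoch).
#' @param lr_policy,lr_value Adam learning rates.
#' @param temperature Sampling temperature for rollouts.
#' @param seed Integer seed.
#' @param binary_reward Use the thresholded (binary) reward mode.
#' @param adv_normalize Standardize advantages within each batch.
#' @param neg_adv_scale Multiplier on negative advantages (< 1 damps the
#'   "unlearning" side of the update; 1 leaves advantages untouched).
#' @param anchor_weight Relative learning rate of the replay anchor:
#'   each epoch an MLE step on held-in pretraining-domain reactions
#'   (passed to [train_rl()] as `anchor_data`) pulls the policy back to
#'   fluent chemistry, the practical stabilizer for policy-gradient
#'   tuning of language models.
#' @param anchor_per_epoch Anchor reactions per epoch.
#' @param ppo_epochs Surrogate update passes per rollout batch.
#' @param eval_every Validate every this many epochs.
#' @param eval_beams Beam width for validation monitoring.
#' @param kl_guard Abort threshold on the mean sequence KL (training
#'   collapse guard).
#' @param max_len Maximum sampled product length during rollouts
#'   (truncated samples simply receive the invalid reward).
#' @param verbose Print a line per epoch.
#' @return Named list of settings.
#' @export
rl_config <- function(kl_coeff = 0.05, clip_eps = 0.2, rollout_lhs = 96L,
                      samples_per_lhs = 2L, epochs = 15L, minibatch = 96L,
                      lr_policy = 1e-4, lr_value = 1e-2, temperature = 1.0,
                      seed = 1L, binary_reward = FALSE, adv_normalize = FALSE,
                      neg_adv_scale = 1, anchor_weight = 0.5,
                      anchor_per_epoch = 48L, ppo_epochs = 1L,
                      eval_every = 2L, eval_beams = 3L, kl_guard = 50,
                      max_len = 30L, verbose = FALSE) {
  stopifnot(kl_coeff >= 0, clip_eps > 0, temperature > 0, epochs >= 1)
  list(kl_coeff = kl_coeff, clip_eps = clip_eps, rollout_lhs = rollout_lhs,
       samples_per_lhs = samples_per_lhs, epochs = epochs,
       minibatch = minibatch, lr_policy = lr_policy, lr_value = lr_value,
       temperature = temperature, seed = seed, binary_reward = binary_reward,
       adv_normalize = adv_normalize, neg_adv_scale = neg_adv_scale,
       anchor_weight = anchor_weight, anchor_per_epoch = anchor_per_epoch,
       ppo_epochs = ppo_epochs, eval_every = eval_every,
       eval_beams = eval_beams, kl_guard = kl_guard, max_len = max_len,
       verbose = verbose)
}

## ---- value network -------------------------------------------------------

#' Create a value network
#'
#' Two linear layers separated by a ReLU, with a sigmoid at the output, so
#' the value estimate (the expected-reward baseline for a left-hand side)
#' is strictly inside (0, 1). The input is the pooled encoder state of
#' the precursors under the current policy.
#'
#' @param d Input width (policy encoder width).
#' @param hidden Hidden-layer width.
#' @param seed Seed for initialization (the final layer starts at zero,
#'   so the untrained output is 0.5).
#' @return An object of class `value_network`.
#' @export
new_value_net <- function(d, hidden = 32L, seed = 1L) {
  params <- withr::with_seed(seed, list(
    W1 = rmat(d, hidden, sd = 0.1), b1 = rep(0, hidden),
    W2 = matrix(0, hidden, 1), b2 = 0
  ))
  structure(list(params = params, d = d, hidden = hidden),
            class = "value_network")
}

#' Value estimate for a pooled policy state
#'
#' @param value_net A `value_network`.
#' @param state Numeric vector (pooled encoder state, length `d`).
#' @return Scalar in (0, 1).
#' @export
estimate_value <- function(value_net, state) {
  if (length(state) != value_net$d) {
    cli::cli_abort("State has length {length(state)}, expected {value_net$d}.",
                   class = "rxnrl_error_shape")
  }
  p <- value_net$params
  h <- pmax(as.numeric(state %*% p$W1) + p$b1, 0)
  z <- sum(h * p$W2) + p$b2
  1 / (1 + exp(-z))
}

# One MSE regression step of the value net towards targets.
value_update <- function(value_net, states, targets, opt, lr) {
  p <- value_net$params
  g <- list(W1 = p$W1 * 0, b1 = p$b1 * 0, W2 = p$W2 * 0, b2 = 0)
  n <- length(targets)
  for (i in seq_len(n)) {
    s <- states[[i]]
    h0 <- as.numeric(s %*% p$W1) + p$b1
    h <- pmax(h0, 0)
    z <- sum(h * p$W2) + p$b2
    v <- 1 / (1 + exp(-z))
    dz <- 2 * (v - targets[i]) * v * (1 - v) / n
    g$W2 <- g$W2 + dz * h
    g$b2 <- g$b2 + dz
    dh <- dz * as.numeric(p$W2) * (h0 > 0)
    g$W1 <- g$W1 + outer(s, dh)
    g$b1 <- g$b1 + dh
  }
  value_net$params <- adam_step(p, g, opt, lr = lr)
  value_net
}

## ---- rollouts ------------------------------------------------------------

# Pooled encoder state of a left-hand side under the policy.
lhs_state <- function(policy, lhs, pv = flat_params(policy)) {
  src <- token_ids(tokenize_smiles(lhs), policy$vocab)
  as.numeric(cpp_encode_pool(pv, policy$dims, length(policy$vocab),
                             policy$pos, src, seq_along(src)))
}

#' Collect a batch of policy rollouts
#'
#' Samples products for left-hand sides drawn from the training pool,
#' scores each with the reward model, records per-sequence
#' log-probabilities under the policy and the frozen reference, and
#' applies the KL-penalized reward r~ = r - kl_coeff (log pi - log pi_ref).
#' Invalid samples are not errors; they simply receive the invalid
#' reward.
#'
#' @param policy Current `seq2seq_policy`.
#' @param ref_policy Frozen reference policy.
#' @param rm A `reward_model`.
#' @param lhs_pool Character vector of candidate left-hand sides.
#' @param value_net A `value_network` for the baseline.
#' @param config Settings from [rl_config()].
#' @param seed Seed for this batch (defaults to `config$seed`).
#' @return A `rollout_batch`: list of items (lhs, tokens, logp_policy,
#'   logp_ref, reward, shaped reward, state, value, advantage) plus batch
#'   means.
#' @export
collect_rollouts <- function(policy, ref_policy, rm, lhs_pool, value_net,
                             config = rl_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  items <- withr::with_seed(seed, {
    chosen <- lhs_pool[sample.int(length(lhs_pool),
                                  min(config$rollout_lhs, length(lhs_pool)))]
    chosen <- rep(chosen, each = config$samples_per_lhs)
    lapply(chosen, function(l) {
      s <- sample_decode(policy, l, temperature = config$temperature,
                         max_len = config$max_len)
      list(lhs = l, tokens = s$tokens, smiles = s$smiles,
           logp_policy = sum(s$logp), truncated = s$truncated)
    })
  })
  rewards <- compute_reward(rm,
                            vapply(items, `[[`, character(1), "lhs"),
                            vapply(items, `[[`, character(1), "smiles"))
  for (i in seq_along(items)) {
    it <- items[[i]]
    it$reward <- rewards[i]
    it$logp_ref <- sequence_log_prob(ref_policy, it$lhs, it$tokens)
    it$kl <- it$logp_policy - it$logp_ref
    it$rtilde <- it$reward - config$kl_coeff * it$kl
    it$state <- lhs_state(policy, it$lhs)
    it$value <- estimate_value(value_net, it$state)
    it$advantage <- it$rtilde - it$value
    items[[i]] <- it
  }
  kls <- vapply(items, `[[`, numeric(1), "kl")
  structure(
    list(
      items = items,
      mean_reward = mean(rewards),
      # non-negative KL estimate (exp(d) - d - 1 with d = logp_ref - logp_pol)
      mean_kl = mean(pmin(exp(-kls), 1e6) + kls - 1)
    ),
    class = "rollout_batch"
  )
}

#' @export
print.rollout_batch <- function(x, ...) {
  cli::cli_text("<rollout_batch> {length(x$items)} rollouts, mean reward {signif(x$mean_reward, 3)}, mean KL {signif(x$mean_kl, 3)}")
  invisible(x)
}

## ---- policy update -------------------------------------------------------

#' One clipped policy-gradient update
#'
#' Performs a clipped-surrogate policy-gradient step on a rollout batch
#' (advantage = shaped reward minus the value baseline; the importance
#' ratio against the rollout-time policy is clipped to
#' `[1 - clip_eps, 1 + clip_eps]`), followed by a value-network
#' regression step towards the realized shaped rewards. Reward is
#' terminal and credited uniformly over the sequence.
#'
#' @param policy Current `seq2seq_policy`.
#' @param value_net A `value_network`.
#' @param batch A `rollout_batch`.
#' @param config Settings from [rl_config()].
#' @param opt_policy,opt_value Optional persistent Adam states.
#' @return List: updated `policy`, `value_net`, and `stats` (one-row
#'   tibble: mean_reward, mean_kl, clip_fraction, mean_advantage).
#' @export
policy_update <- function(policy, value_net, batch, config = rl_config(),
                          opt_policy = NULL, opt_value = NULL) {
  stopifnot(length(batch$items) > 0)
  if (is.null(opt_policy)) opt_policy <- new_adam()
  if (is.null(opt_value)) opt_value <- new_adam()
  adv <- vapply(batch$items, `[[`, numeric(1), "advantage")
  # always center within the batch: a miscalibrated value baseline must
  # not push the whole sampled distribution up or down
  if (length(adv) > 1) adv <- adv - mean(adv)
  if (isTRUE(config$adv_normalize) && length(adv) > 1 && stats::sd(adv) > 1e-8) {
    adv <- adv / stats::sd(adv)
  }
  if (!is.null(config$neg_adv_scale) && config$neg_adv_scale != 1) {
    adv[adv < 0] <- adv[adv < 0] * config$neg_adv_scale
  }
  n <- length(batch$items)
  V <- length(policy$vocab)
  clip_hits <- 0L
  mb_size <- if (is.null(config$minibatch)) n else max(1L, config$minibatch)
  for (pass in seq_len(config$ppo_epochs)) {
    mbs <- split(seq_len(n), ceiling(seq_len(n) / mb_size))
    for (mb in mbs) {
      pv <- flat_params(policy)
      gv <- numeric(length(pv))
      any_grad <- FALSE
      for (i in mb) {
        it <- batch$items[[i]]
        if (abs(adv[i]) < 1e-12) next
        src <- token_ids(tokenize_smiles(it$lhs), policy$vocab)
        tout <- it$tokens
        tin <- c(1L, tout[tout != 2L])
        if (length(tin) != length(tout)) tin <- tin[seq_along(tout)]
        lp <- cpp_policy_logp(pv, policy$dims, V, policy$pos, src, tin, tout)
        ratio <- exp(sum(lp) - it$logp_policy)
        unclipped <- ratio * adv[i]
        clipped <- max(min(ratio, 1 + config$clip_eps), 1 - config$clip_eps) * adv[i]
        if (clipped < unclipped - 1e-12) {
          clip_hits <- clip_hits + 1L
          next  # gradient of the clipped branch w.r.t. theta is zero
        }
        # the kernel accumulates gradients of sum_t w * (-log p_t); with
        # w = ratio * A, minimizing that objective maximizes the
        # surrogate ratio * A
        w <- ratio * adv[i] / length(mb)
        cpp_policy_grad(pv, gv, policy$dims, V, policy$pos, src, tin, tout, w)
        any_grad <- TRUE
      }
      if (any_grad) {
        if (!all(is.finite(gv))) {
          cli::cli_abort("Non-finite policy gradient.",
                         class = "rxnrl_error_nonfinite_gradient")
        }
        policy$params <- adam_step(policy$params, gv, opt_policy,
                                   lr = config$lr_policy)
      }
    }
  }
  value_net <- value_update(
    value_net,
    lapply(batch$items, `[[`, "state"),
    vapply(batch$items, `[[`, numeric(1), "rtilde"), opt_value,
    lr = config$lr_value
  )
  stats_row <- tibble::tibble(
    mean_reward = batch$mean_reward,
    mean_kl = batch$mean_kl,
    clip_fraction = clip_hits / (n * config$ppo_epochs),
    mean_advantage = mean(vapply(batch$items, `[[`, numeric(1), "advantage"))
  )
  list(policy = policy, value_net = value_net, stats = stats_row)
}

## ---- training loop -------------------------------------------------------

#' Tune a policy with RL feedback from negative data
#'
#' Alternates rollout collection and clipped policy-gradient updates for
#' `config$epochs` epochs. The reference policy is a frozen copy of the
#' input policy taken before any update; rollout left-hand sides are
#' drawn from the training reactions (positives and negatives share
#' left-hand sides by construction, so the pool covers both). Validation
#' top-1 positive accuracy is monitored and the best checkpoint
#' returned.
#'
#' @param policy Starting `seq2seq_policy` (becomes pi_ref).
#' @param bundle A `reaction_bundle`; train supplies the rollout pool,
#'   valid the monitoring positives.
#' @param rm A fitted `reward_model`.
#' @param config Settings from [rl_config()].
#' @param anchor_data Optional reaction records from the pretraining
#'   domain used as a replay anchor (an MLE step per epoch at
#'   `anchor_weight` times the policy learning rate).
#' @return An `rl_fit`: list with `policy` (best checkpoint),
#'   `ref_policy`, `value_net`, `history` (tibble epoch / mean_reward /
#'   mean_kl / clip_fraction / valid_top1) and `config`.
#' @export
train_rl <- function(policy, bundle, rm, config = rl_config(),
                     anchor_data = NULL) {
  ref_policy <- policy
  rm$binary <- isTRUE(config$binary_reward) || rm$binary
  value_net <- new_value_net(policy$dims$d, seed = config$seed)
  lhs_pool <- unique(bundle$train$lhs)
  opt_policy <- new_adam()
  opt_value <- new_adam()
  history <- list()
  best <- list(acc = -Inf, params = policy$params)
  for (epoch in seq_len(config$epochs)) {
    batch <- collect_rollouts(policy, ref_policy, rm, lhs_pool, value_net,
                              config,
                              seed = (config$seed * 131L + epoch) %% 2147483647L)
    if (batch$mean_kl > config$kl_guard) {
      cli::cli_abort(
        "Mean KL {signif(batch$mean_kl, 3)} exceeded the guard threshold {config$kl_guard} at epoch {epoch}: RL training collapsed.",
        class = "rxnrl_error_kl_collapse"
      )
    }
    upd <- policy_update(policy, value_net, batch, config, opt_policy, opt_value)
    policy <- upd$policy
    value_net <- upd$value_net
    if (!is.null(anchor_data) && nrow(anchor_data) > 0 &&
        config$anchor_weight > 0) {
      idx <- withr::with_seed((config$seed * 977L + epoch) %% 2147483647L, {
        sample.int(nrow(anchor_data),
                   min(config$anchor_per_epoch, nrow(anchor_data)))
      })
      pv <- flat_params(policy)
      gv <- numeric(length(pv))
      V <- length(policy$vocab)
      for (i in idx) {
        pr <- seq_pair_ids(policy, anchor_data$lhs[i],
                           tokenize_smiles(anchor_data$product[i]))
        cpp_policy_grad(pv, gv, policy$dims, V, policy$pos,
                        pr$src, pr$tin, pr$tout,
                        1 / (length(pr$tout) * length(idx)))
      }
      policy$params <- adam_step(policy$params, gv, opt_policy,
                                 lr = config$lr_policy * config$anchor_weight)
    }
    vacc <- NA_real_
    if (epoch %% config$eval_every == 0L || epoch == config$epochs) {
      vacc <- topk_positive_accuracy(policy, bundle$valid, k = 1L,
                                     beams = config$eval_beams)
      if (vacc > best$acc) best <- list(acc = vacc, params = policy$params)
    }
    if (config$verbose) {
      cli::cli_inform("epoch {epoch}: reward {signif(batch$mean_reward, 3)}, KL {signif(batch$mean_kl, 3)}, valid top-1 {signif(vacc, 3)}")
    }
    history[[epoch]] <- dplyr::bind_cols(
      tibble::tibble(epoch = epoch), upd$stats, tibble::tibble(valid_top1 = vacc)
    )
  }
  policy$params <- best$params
  structure(
    list(policy = policy, ref_policy = ref_policy, value_net = value_net,
         history = dplyr::bind_rows(history), config = config),
    class = "rl_fit"
  )
}

#' @export
print.rl_fit <- function(x, ...) {
  h <- x$history
  cli::cli_text(
    "<rl_fit> {nrow(h)} epoch{?s}, final mean reward {signif(utils::tail(h$mean_reward, 1), 3)}, best valid top-1 {signif(max(c(h$valid_top1, -Inf), na.rm = TRUE), 3)}"
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rl_fit <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.rl_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    final_mean_reward = utils::tail(x$history$mean_reward, 1),
    final_mean_kl = utils::tail(x$history$mean_kl, 1),
    best_valid_top1 = suppressWarnings(max(x$history$valid_top1, na.rm = TRUE))
  )
}

#' RL training-curve plot
#'
#' @param object An `rl_fit`.
#' @param ... Unused.
#' @return A ggplot of reward, KL, clip fraction and validation accuracy
#'   against epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.rl_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -dplyr::all_of("epoch"),
                              names_to = "metric", values_to = "value")
  long <- long[!is.na(long$value), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
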