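# The transformer core: gradients, normalization, capacity.

test_that("analytic gradients match finite differences", {
  vocab <- structure(c("<bos>", "<eos>", "C", "O", "c", "1"),
                     class = "rxnrl_vocab")
  pol <- new_policy(vocab, d = 8, n_heads = 2, ff = 12, n_enc = 1, n_dec = 1,
                    max_len = 10, seed = 3)
  src <- c(3L, 4L, 5L, 6L)
  tin <- c(1L, 3L, 4L)
  tout <- c(3L, 4L, 2L)
  nll <- function(p) {
    pol2 <- pol
    pol2$params <- p
    enc <- rxnrl:::encoder_fwd(pol2, src)
    dec <- rxnrl:::decoder_fwd(pol2, enc$out, tin)
    P <- rxnrl:::softmax_rows(dec$logits)
    -mean(log(P[cbind(seq_along(tout), tout)] + 1e-12))
  }
  g <- new.env(parent = emptyenv())
  enc <- rxnrl:::encoder_fwd(pol, src)
  dec <- rxnrl:::decoder_fwd(pol, enc$out, tin)
  fw <- list(enc = enc, dec = dec, P = rxnrl:::softmax_rows(dec$logits))
  rxnrl:::seq_backward(pol, fw, tout, 1 / length(tout), g)
  eps <- 1e-5
  set.seed(11)
  for (nm in names(pol$params)) {
    an <- g[[nm]]
    expect_false(is.null(an), label = paste("gradient present for", nm))
    for (i in sample(length(pol$params[[nm]]),
                     min(3, length(pol$params[[nm]])))) {
      p1 <- pol$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- pol$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (nll(p1) - nll(p2)) / (2 * eps)
      expect_lt(abs(num - an[i]) / max(1e-4, abs(num) + abs(an[i])), 1e-3)
    }
  }
})

test_that("next-token distributions are normalized", {
  pol <- tiny_random_policy()
  enc_out <- rxnrl:::encoder_fwd(pol, c(3L, 4L))$out
  lp <- rxnrl:::next_token_logp(pol, enc_out, 1L)
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-8)
  # one-step model: token probabilities over the vocabulary sum to one
  lp2 <- rxnrl:::next_token_logp(pol, enc_out, c(1L, 3L))
  expect_equal(sum(exp(lp2)), 1, tolerance = 1e-8)
})

test_that("a single reaction can be memorized to near-zero loss", {
  rx <- reaction_table("CC.O>>CCO")
  vocab <- build_vocab(rx)
  pol <- new_policy(vocab, d = 24, n_heads = 2, ff = 32, n_enc = 1, n_dec = 1,
                    max_len = 10, seed = 2)
  fit <- train_mle(pol, rx, config = mle_config(epochs = 80, lr_decay = 1,
                                                batch_size = 1))
  expect_lt(tail(fit$history$loss, 1), 0.01)
})

test_that("ten distinct reactions are overfit to perfect top-1", {
  fit <- tiny_trained_policy()
  acc <- topk_positive_accuracy(fit$policy, small_reaction_set(), k = 1,
                                beams = 3)
  expect_identical(acc, 1)
})

test_that("policy creation is deterministic given a seed and OOV is caught", {
  vocab <- build_vocab(small_reaction_set())
  p1 <- new_policy(vocab, seed = 9)
  p2 <- new_policy(vocab, seed = 9)
  expect_identical(p1$params, p2$params)
  expect_false(identical(p1$params, new_policy(vocab, seed = 10)$params))
  expect_error(rxnrl:::token_ids(c("C", "Zz"), vocab),
               class = "rxnrl_error_oov")
})

test_that("MLE uses positives only and flags divergence input checks", {
  rx <- small_reaction_set()
  rx$label <- c(rep("positive", 5), rep("negative", 5))
  vocab <- build_vocab(rx)
  pol <- new_policy(vocab, d = 16, n_heads = 2, ff = 16, n_enc = 1, n_dec = 1,
                    max_len = 15, seed = 1)
  expect_message(
    fit <- train_mle(pol, rx, config = mle_config(epochs = 1)),
    "negative"
  )
  expect_identical(nrow(fit$history), 1L)
})
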