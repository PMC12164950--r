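# Reward model: embeddings, classification tuning, separation
# diagnostics, imbalance-aware SVM, composite reward rules.

test_that("embeddings are deterministic, canonical and of fixed length", {
  recs <- make_labeled_toy(5, 5)
  enc <- new_reaction_encoder(build_vocab(recs), d = 16, n_heads = 2, ff = 24,
                              n_layers = 1, seed = 4)
  emb <- embed_reactions(enc, recs)
  expect_identical(dim(emb), c(10L, 16L))
  expect_identical(emb, embed_reactions(enc, recs))
  # equivalent non-canonical serialization maps to the same vector
  v1 <- embed_reactions(enc, "CC.O>>CCO")
  v2 <- embed_reactions(enc, "CC.O>>OCC")
  expect_equal(v1, v2)
})

test_that("classification tuning is deterministic and label-sensitive", {
  recs <- make_labeled_toy(30, 90)
  base <- as_reaction_encoder(mini_base()$policy)
  tuned <- classification_tune(base, recs, epochs = 3, seed = 1)
  # tuning moves the encoder and is deterministic given the seed
  expect_false(identical(tuned$params, base$params))
  tuned2 <- classification_tune(base, recs, epochs = 3, seed = 1)
  expect_identical(tuned$params, tuned2$params)
  # no-signal control: shuffled labels give chance-level held-out accuracy
  shuf <- recs
  shuf$label <- withr::with_seed(3, sample(shuf$label))
  tuned_s <- classification_tune(base, shuf, epochs = 3, seed = 1)
  acc_s <- rxnrl:::heldout_balanced_accuracy(
    embed_reactions(tuned_s, shuf), shuf$label, seed = 1
  )
  expect_lt(abs(acc_s - 0.5), 0.25)
  # single-class input is rejected
  expect_error(classification_tune(base, recs[recs$label == "positive", ]),
               class = "rxnrl_error_single_class")
})

test_that("separation report behaves on degenerate and separable controls", {
  set.seed(8)
  cloud <- matrix(rnorm(120), ncol = 4)
  labels <- rep(c("positive", "negative"), each = 15)
  # identical clouds: inter- and intra-class distances coincide
  rep1 <- separation_report(rbind(cloud[1:15, ], cloud[1:15, ]), labels)
  expect_equal(rep1$separation_ratio, 1, tolerance = 0.15)
  expect_lt(abs(rep1$balanced_accuracy - 0.5), 0.3)
  # well-separated clouds: perfect held-out separator
  far <- rbind(cloud[1:15, ] + 50, cloud[16:30, ])
  rep2 <- separation_report(far, labels)
  expect_gt(rep2$separation_ratio, 5)
  expect_identical(rep2$balanced_accuracy, 1)
  # all points identical: measures undefined, no crash
  rep3 <- separation_report(matrix(1, 10, 3),
                            rep(c("positive", "negative"), each = 5))
  expect_true(is.na(rep3$separation_ratio))
  expect_identical(rep3$balanced_accuracy, 0.5)
  expect_error(separation_report(cloud, c("positive", rep("negative", 29))),
               class = "rxnrl_error_single_class")
  expect_s3_class(autoplot(rep2), "ggplot")
})

test_that("class weighting handles the 22 vs 748 imbalance", {
  set.seed(21)
  n_pos <- 22; n_neg <- 748
  X <- rbind(
    matrix(rnorm(n_pos * 2, mean = 1.2), ncol = 2),
    matrix(rnorm(n_neg * 2, mean = 0), ncol = 2)
  )
  y <- c(rep("positive", n_pos), rep("negative", n_neg))
  ho <- rbind(
    matrix(rnorm(200 * 2, mean = 1.2), ncol = 2),
    matrix(rnorm(200 * 2, mean = 0), ncol = 2)
  )
  yho <- rep(c("positive", "negative"), each = 200)
  balacc <- function(clf) {
    p <- predict_prob(clf, ho) >= 0.5
    mean(c(mean(p[yho == "positive"]), mean(!p[yho == "negative"])))
  }
  weighted <- fit_reward_classifier(X, y, seed = 1)
  unweighted <- fit_reward_classifier(X, y, weights = "none", seed = 1)
  expect_gt(balacc(weighted), 0.5)
  expect_gt(balacc(weighted), balacc(unweighted))
})

test_that("a separable problem is fit perfectly and calibration is monotone", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40, 5), ncol = 2), matrix(rnorm(40, -5), ncol = 2))
  y <- rep(c("positive", "negative"), each = 20)
  clf <- fit_reward_classifier(X, y, seed = 1)
  pred <- stats::predict(clf$svm, X)
  expect_identical(mean(pred == y), 1)
  grid <- cbind(seq(-6, 6, length.out = 50), seq(-6, 6, length.out = 50))
  pr <- predict_prob(clf, grid)
  dv <- attr(stats::predict(clf$svm, grid, decision.values = TRUE),
             "decision.values")[, 1]
  expect_true(all(pr > 0 & pr < 1))
  # probability is monotone in the decision margin
  expect_equal(abs(cor(rank(pr), rank(dv))), 1, tolerance = 1e-8)
  expect_error(fit_reward_classifier(X, rep("positive", 40)),
               class = "rxnrl_error_single_class")
})

test_that("the composite reward follows its exact-match rules", {
  recs <- make_labeled_toy(10, 30)
  rm <- fit_reward_model(recs, epochs = 1, seed = 1)
  pos1 <- recs[recs$label == "positive", ][1, ]
  neg1 <- recs[recs$label == "negative", ][1, ]
  expect_identical(compute_reward(rm, pos1$lhs, "c1cc("), 0)      # invalid
  expect_identical(compute_reward(rm, pos1$lhs, pos1$product), 1) # known positive
  expect_identical(compute_reward(rm, neg1$lhs, neg1$product), 0) # known negative
  # unknown products get the calibrated probability, always in [0, 1]
  r <- compute_reward(rm, rep(pos1$lhs, 3), c("CCO", "CCN", "CCCC"))
  expect_true(all(r >= 0 & r <= 1))
  # binary mode collapses the classifier branch to {0, 1}
  rmb <- rm
  rmb$binary <- TRUE
  rb <- compute_reward(rmb, rep(pos1$lhs, 3), c("CCO", "CCN", "CCCC"))
  expect_true(all(rb %in% c(0, 1)))
  # total function on garbage decoder output
  expect_identical(compute_reward(rm, pos1$lhs, ""), 0)
  expect_identical(compute_reward(rm, pos1$lhs, "))(("), 0)
})

test_that("the fitted reward model is label-faithful on its training data", {
  recs <- make_labeled_toy(30, 90)
  rm <- fit_reward_model(recs, encoder = as_reaction_encoder(mini_base()$policy),
                         epochs = 2, seed = 3)
  # exact-match rules dominate: labeled reactions score their labels
  r_pos <- compute_reward(rm, recs$lhs[recs$label == "positive"],
                          recs$product[recs$label == "positive"])
  r_neg <- compute_reward(rm, recs$lhs[recs$label == "negative"],
                          recs$product[recs$label == "negative"])
  expect_true(all(r_pos == 1))
  expect_true(all(r_neg == 0))
  expect_gt(mean(r_pos), mean(r_neg))
})
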