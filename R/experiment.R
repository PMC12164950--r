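# The comparison harness: pretrain a base forward model on the toy
# corpus, then per data-split seed construct the high/low positive-data
# regimes, fine-tune (MLE) and RL-tune from the same base, and evaluate
# both on the identical splits. This is the package's end-to-end
# experiment; every stage is also callable on its own.

#' Pretrain the base forward model on the toy corpus
#'
#' Generates the pretraining corpus (products disjoint from the
#' regioselectivity family), builds the joint vocabulary, and trains an
#' untrained policy by maximum likelihood. The held-out corpus slice
#' gives the pretraining-domain accuracy used later for
#' catastrophic-forgetting checks.
#'
#' @param spec A [toy_spec()].
#' @param d,n_heads,ff,n_enc,n_dec Policy architecture.
#' @param epochs,lr,lr_decay MLE settings.
#' @param target_valid Early-stop target on the held-out corpus slice.
#' @param eval_beams Beam width for corpus-slice evaluation.
#' @param verbose Print progress.
#' @return List of class `base_model`: `policy`, `corpus` (tibble with
#'   `slice` column), `vocab`, `pretrain_top1` (held-out top-1) and the
#'   underlying `fit`.
#' @export
pretrain_base <- function(spec = toy_spec(), d = 48L, n_heads = 4L, ff = 96L,
                          n_enc = 2L, n_dec = 2L, epochs = 48L, lr = 1.5e-3,
                          lr_decay = 0.98, eval_beams = 2L,
                          target_valid = 0.905, verbose = FALSE) {
  pool_products <- regio_scaffold_table(spec)$product
  corpus <- make_pretrain_corpus(spec, exclude_products = pool_products,
                                 test_fraction = 1 / 16)
  fam_probe <- regio_scaffold_table(spec)
  vocab <- build_vocab(c(
    corpus$reaction,
    paste0(fam_probe$lhs, ">>", fam_probe$product)
  ))
  policy <- new_policy(vocab, d = d, n_heads = n_heads, ff = ff,
                       n_enc = n_enc, n_dec = n_dec,
                       max_len = 50L, seed = spec$seed)
  train <- corpus[corpus$slice == "train", , drop = FALSE]
  test <- corpus[corpus$slice == "test", , drop = FALSE]
  fit <- train_mle(policy, train, valid = test,
                   config = mle_config(epochs = epochs, lr = lr,
                                       lr_decay = lr_decay,
                                       seed = spec$seed, eval_every = 4L,
                                       eval_beams = eval_beams,
                                       target_valid = target_valid,
                                       verbose = verbose))
  top1 <- topk_positive_accuracy(fit$policy, test, k = 1L, beams = 3L)
  class_corpus <- make_classification_corpus(
    spec, exclude_reactions = corpus$reaction
  )
  structure(
    list(policy = fit$policy, corpus = corpus, vocab = vocab,
         class_corpus = class_corpus, pretrain_top1 = top1, fit = fit),
    class = "base_model"
  )
}

#' @export
print.base_model <- function(x, ...) {
  cli::cli_text("<base_model> corpus {nrow(x$corpus)} reactions, held-out top-1 {signif(x$pretrain_top1, 3)}")
  invisible(x)
}

#' Fine-tune and RL-tune from the same base on one regime
#'
#' The two strategies of the comparison: maximum-likelihood fine-tuning
#' on the regime's training positives, and RL tuning chained after that
#' fine-tuning (the fine-tuned checkpoint becomes the frozen reference),
#' with a reward model fitted on the regime's labeled training reactions
#' and a pretraining-replay anchor. Both arms are evaluated on the
#' identical validation and test positives, so the RL column measures
#' what negative-data feedback adds on top of likelihood training.
#'
#' @param base A `base_model`.
#' @param bundle A `reaction_bundle` regime.
#' @param mle_cfg [mle_config()] for the fine-tuning arm.
#' @param rl_cfg [rl_config()] for the RL arm.
#' @param reward_seed Seed for reward-model fitting.
#' @param final_beams Beam width for the final test evaluation.
#' @param forgetting_slice Optional reaction records (the pretraining
#'   held-out slice) to re-evaluate after RL.
#' @return One-row tibble of metrics (ft/rl validation and test top-1,
#'   invalid fractions, forgetting drop), with fits attached as the
#'   `"fits"` attribute.
#' @export
run_regime <- function(base, bundle, mle_cfg = mle_config(),
                       rl_cfg = rl_config(), reward_seed = 1L,
                       final_beams = 10L, forgetting_slice = NULL) {
  train_pos <- bundle$train[!is.na(bundle$train$label) &
                              bundle$train$label == "positive", , drop = FALSE]
  ft <- train_mle(base$policy, train_pos, valid = bundle$valid, config = mle_cfg)
  rm <- fit_reward_model(bundle$train,
                         encoder = as_reaction_encoder(base$policy),
                         seed = reward_seed)
  # RL starts from the fine-tuned checkpoint (which becomes pi_ref) and is
  # anchored by pretraining replay -- the chained workflow used for
  # screening data, which a desk-scale base model requires throughout
  rl <- train_rl(ft$policy, bundle, rm, config = rl_cfg,
                 anchor_data = base$corpus[base$corpus$slice == "train", ])
  ft_valid <- suppressWarnings(max(ft$history$valid_top1, na.rm = TRUE))
  rl_valid <- suppressWarnings(max(rl$history$valid_top1, na.rm = TRUE))
  ft_test <- evaluate_policy(ft$policy, bundle$test, ks = c(1L, 2L),
                             beams = final_beams)
  rl_test <- evaluate_policy(rl$policy, bundle$test, ks = c(1L, 2L),
                             beams = final_beams)
  forget <- NA_real_
  if (!is.null(forgetting_slice)) {
    before <- topk_positive_accuracy(ft$policy, forgetting_slice, k = 1L,
                                     beams = 3L)
    after <- topk_positive_accuracy(rl$policy, forgetting_slice, k = 1L,
                                    beams = 3L)
    forget <- before - after
  }
  out <- tibble::tibble(
    ft_valid_top1 = ft_valid,
    rl_valid_top1 = rl_valid,
    ft_test_top1 = ft_test$topk_accuracy[ft_test$k == 1L],
    rl_test_top1 = rl_test$topk_accuracy[rl_test$k == 1L],
    ft_test_top2 = ft_test$topk_accuracy[ft_test$k == 2L],
    rl_test_top2 = rl_test$topk_accuracy[rl_test$k == 2L],
    ft_invalid_top1 = ft_test$invalid_fraction[ft_test$k == 1L],
    rl_invalid_top1 = rl_test$invalid_fraction[rl_test$k == 1L],
    forgetting_drop = forget
  )
  attr(out, "fits") <- list(ft = ft, rl = rl, reward = rm)
  out
}

#' The full low-data comparison for one data-split seed
#'
#' Builds the regioselectivity family for the seed, derives the low-data
#' regime by subsampling training positives (all negatives retained),
#' and runs [run_regime()] on both regimes from the shared base model.
#'
#' @param base A `base_model`.
#' @param seed Data-split seed.
#' @param spec The family [toy_spec()] (its `seed` is replaced by
#'   `seed`).
#' @param subsample_fraction Fraction of training positives kept in the
#'   low-data regime.
#' @param mle_cfg,rl_cfg Training settings; seeds inside are replaced by
#'   `seed`.
#' @param regimes Which regimes to run ("low", "high").
#' @return One-row tibble with `low_`/`high_`-prefixed metrics.
#' @export
run_split_experiment <- function(base, seed, spec = toy_spec(),
                                 subsample_fraction = 0.2,
                                 mle_cfg = mle_config(epochs = 20L),
                                 rl_cfg = rl_config(),
                                 regimes = c("low", "high")) {
  spec$seed <- as.integer(seed)
  fam <- make_regio_family(spec)
  klow <- subsample_positives(fam, fraction = subsample_fraction, seed = seed)
  mle_cfg$seed <- seed
  rl_cfg$seed <- seed
  slice <- base$corpus[base$corpus$slice == "test", , drop = FALSE]
  out <- tibble::tibble(.rows = 1)
  if ("low" %in% regimes) {
    low <- run_regime(base, klow, mle_cfg, rl_cfg, reward_seed = seed,
                      forgetting_slice = slice)
    names(low) <- paste0("low_", names(low))
    out <- dplyr::bind_cols(out, low)
  }
  if ("high" %in% regimes) {
    high <- run_regime(base, fam, mle_cfg, rl_cfg, reward_seed = seed,
                       forgetting_slice = slice)
    names(high) <- paste0("high_", names(high))
    out <- dplyr::bind_cols(out, high)
  }
  out
}

#' Reward-embedding ordering study
#'
#' For several seeds, classification-tunes the pretrained reaction
#' encoder on labeled reactions and compares the held-out balanced
#' accuracy of the fitted class-weighted SVM in the tuned space against
#' the untuned (base) space. Each seed controls the half-split used for
#' held-out evaluation and the tuning order.
#'
#' @param base A `base_model`.
#' @param labeled Labeled reaction record tibble (both classes).
#' @param seeds Integer seeds.
#' @param epochs Tuning epochs.
#' @return Tibble with `seed`, `bal_base`, `bal_tuned`, `win`.
#' @export
reward_tuning_ordering <- function(base, labeled, seeds = 1:5, epochs = 2L) {
  enc0 <- as_reaction_encoder(base$policy)
  emb0 <- embed_reactions(enc0, labeled)
  balacc <- function(emb, s) {
    n <- nrow(emb)
    idx <- withr::with_seed(s, sample.int(n, floor(n / 2)))
    if (length(unique(labeled$label[idx])) < 2L) idx <- seq_len(floor(n / 2))
    clf <- fit_reward_classifier(emb[idx, , drop = FALSE],
                                 labeled$label[idx], seed = s)
    p <- predict_prob(clf, emb[-idx, , drop = FALSE]) >= 0.5
    truth <- labeled$label[-idx] == "positive"
    mean(c(mean(p[truth]), mean(!p[!truth])))
  }
  purrr::map_dfr(seeds, function(s) {
    tuned <- classification_tune(enc0, labeled, epochs = epochs, seed = s)
    emb1 <- embed_reactions(tuned, labeled)
    b0 <- balacc(emb0, s)
    b1 <- balacc(emb1, s)
    tibble::tibble(seed = s, bal_base = b0, bal_tuned = b1, win = b1 > b0)
  })
}

#' Run the complete benchmark study
#'
#' The package's end-to-end protocol at its default desk scale: pretrain
#' the base model once, then for each data-split seed build the
#' regioselectivity family, derive the low-data regime (20 training
#' positives, every negative retained), and compare maximum-likelihood
#' fine-tuning against RL tuning; the high-data regime is run on the
#' first seed. Also runs the reward-embedding ordering study.
#'
#' @param seed Master seed; data-split seeds are `seed + 0:(n_seeds-1)`.
#' @param n_seeds Number of low-data data-split seeds (>= 3 for the
#'   majority comparison).
#' @param pretrain_epochs,ft_epochs,rl_epochs Stage training lengths.
#' @param verbose Print stage progress.
#' @return List: `base`, `low` (a `multi_seed_report`), `high` (one-row
#'   tibble), `klow_counts` (one-row tibble from [glance()]),
#'   `reward_ordering` (tibble).
#' @export
run_acceptance_study <- function(seed = 1L, n_seeds = 3L,
                                 pretrain_epochs = 48L, ft_epochs = 20L,
                                 rl_epochs = 10L, verbose = FALSE) {
  spec <- toy_spec(seed = seed)
  base <- pretrain_base(spec, epochs = pretrain_epochs, verbose = verbose)
  seeds <- seed + seq_len(n_seeds) - 1L
  # both arms are monitored with the same beam width and the same
  # number of checkpoint evaluations, so neither gets more chances to
  # catch a favourable noise peak
  mle_cfg <- mle_config(epochs = ft_epochs, eval_every = 2L,
                        eval_beams = 2L)
  rl_cfg <- rl_config(epochs = rl_epochs, rollout_lhs = 64L,
                      minibatch = 64L, eval_every = 1L,
                      eval_beams = 2L, verbose = verbose)
  low <- multi_seed_report(function(s) {
    run_split_experiment(
      base, s, spec = spec, subsample_fraction = 1 / 3,
      mle_cfg = mle_cfg, rl_cfg = rl_cfg, regimes = "low"
    )
  }, seeds = seeds)
  high <- run_split_experiment(
    base, seeds[1], spec = spec, subsample_fraction = 1 / 3,
    mle_cfg = mle_cfg, rl_cfg = rl_cfg, regimes = "high"
  )
  spec$seed <- seeds[1]
  fam <- make_regio_family(spec)
  klow <- subsample_positives(fam, fraction = 1 / 3, seed = seeds[1])
  ordering <- reward_tuning_ordering(base, klow$train, seeds = seed + 0:4)
  list(base = base, low = low, high = high, klow_counts = glance(klow),
       reward_ordering = ordering)
}
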