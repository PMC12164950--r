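# The reward model: reaction-fingerprint embeddings from a compact
# bidirectional transformer encoder, optional classification tuning of
# that encoder, an imbalance-aware SVM over the embeddings, separation
# diagnostics, and the composite reward consumed by the RL tuner.

#' Create a reaction-fingerprint encoder
#'
#' A bidirectional (non-causal) transformer encoder over full serialized
#' reaction strings ("lhs>>product"); pooled hidden states are the
#' reaction fingerprints used as the reward classifier's feature space.
#' The encoder is separate from the forward model.
#'
#' @param vocab Vocabulary from [build_vocab()] (must cover the reaction
#'   arrow token).
#' @param d Encoder width (fingerprint length).
#' @param n_heads Attention heads.
#' @param ff Feed-forward width.
#' @param n_layers Encoder layers.
#' @param pooling "product" (mean over product-side tokens, the
#'   default: those states see the precursors through attention but stay
#'   sensitive to the product's structure), "mean" (whole reaction) or
#'   "first" token pooling.
#' @param max_len Maximum reaction length in tokens.
#' @param seed Seed for weight initialization.
#' @return An object of class `reaction_encoder`.
#' @export
new_reaction_encoder <- function(vocab, d = 32, n_heads = 4, ff = 64,
                                 n_layers = 2,
                                 pooling = c("product", "mean", "first"),
                                 max_len = 120, seed = 1L) {
  pooling <- match.arg(pooling)
  stopifnot(d %% n_heads == 0)
  V <- length(vocab)
  params <- withr::with_seed(seed, {
    p <- list(emb = rmat(V, d))
    for (i in seq_len(n_layers)) p <- c(p, init_layer_params(sprintf("e%d_", i), d, ff))
    p
  })
  structure(
    list(
      params = params,
      vocab = vocab,
      dims = list(d = d, n_heads = n_heads, ff = ff, n_enc = n_layers,
                  max_len = max_len),
      pos = pos_encoding(max_len + 2L, d),
      pooling = pooling
    ),
    class = "reaction_encoder"
  )
}

#' Derive a reaction encoder from a pretrained forward model
#'
#' Copies the encoder stack (token embeddings and self-attention layers)
#' of a pretrained sequence-to-sequence policy into a standalone
#' bidirectional reaction encoder. Starting the reward representation
#' from the pretrained chemical language model — rather than from random
#' weights — is what makes a handful of positives sufficient for
#' classification tuning: the pretrained states already encode ring
#' topology and substituent positions.
#'
#' @param policy A trained `seq2seq_policy`.
#' @param pooling Fingerprint pooling (see [new_reaction_encoder()]).
#' @param max_len Maximum reaction length in tokens.
#' @return A `reaction_encoder`.
#' @export
as_reaction_encoder <- function(policy, pooling = "product",
                                max_len = 120L) {
  keep <- c("emb", grep("^e[0-9]+_", names(policy$params), value = TRUE))
  structure(
    list(
      params = policy$params[keep],
      vocab = policy$vocab,
      dims = list(d = policy$dims$d, n_heads = policy$dims$n_heads,
                  ff = policy$dims$ff, n_enc = policy$dims$n_enc,
                  max_len = max_len),
      pos = pos_encoding(max_len + 2L, policy$dims$d),
      pooling = pooling
    ),
    class = "reaction_encoder"
  )
}

#' @export
print.reaction_encoder <- function(x, ...) {
  cli::cli_text("<reaction_encoder> {x$dims$n_enc} layers, width {x$dims$d}, {x$pooling} pooling")
  invisible(x)
}

# 1-based positions whose hidden states are averaged into the
# fingerprint, given the tokenized reaction.
pool_positions <- function(tokens, pooling) {
  switch(pooling,
    first = 1L,
    mean = seq_along(tokens),
    product = {
      arrow <- match(">>", tokens)
      if (is.na(arrow) || arrow >= length(tokens)) seq_along(tokens)
      else (arrow + 1L):length(tokens)
    }
  )
}

#' Embed reactions as fingerprint vectors
#'
#' Tokenizes each serialized reaction, runs the encoder and pools to a
#' fixed-length vector. Identical canonical reaction strings map to
#' identical vectors (inputs are canonicalized first).
#'
#' @param encoder A `reaction_encoder`.
#' @param reactions Character vector of reaction strings (or a reaction
#'   record tibble).
#' @return Numeric matrix, one row per reaction, `encoder$dims$d` columns.
#' @export
embed_reactions <- function(encoder, reactions) {
  if (is.data.frame(reactions)) reactions <- reactions$reaction
  canon <- canonicalize_reaction_or_na(reactions)
  if (anyNA(canon)) {
    cli::cli_abort("Invalid reaction{?s}: {.val {reactions[is.na(canon)]}}",
                   class = "rxnrl_error_invalid_molecule")
  }
  pv <- flat_params(encoder)
  t(vapply(canon, function(rx) {
    toks <- tokenize_smiles(rx)
    ids <- token_ids(toks, encoder$vocab)
    as.numeric(cpp_encode_pool(pv, encoder$dims, length(encoder$vocab),
                               encoder$pos, ids,
                               pool_positions(toks, encoder$pooling)))
  }, numeric(encoder$dims$d), USE.NAMES = FALSE))
}

#' Tune the reaction encoder on success/failure classification
#'
#' Attaches a logistic head to the pooled fingerprint and trains encoder
#' and head jointly on positive/negative labels with class-weighted
#' cross-entropy; the head is then discarded and the tuned encoder
#' returned. This is the representation step that casts negatives apart
#' from positives in fingerprint space before the SVM is fitted.
#'
#' @param encoder A `reaction_encoder`.
#' @param labeled Reaction record tibble with both classes present.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Examples per gradient-accumulation step.
#' @param freeze "none" (tune all encoder weights) or "lower" (tune the
#'   top self-attention block and the head only, preserving pretrained
#'   lower-layer geometry).
#' @param seed Seed controlling example order.
#' @return The tuned `reaction_encoder`.
#' @export
classification_tune <- function(encoder, labeled, epochs = 4L, lr = 3e-4,
                                batch_size = 16L,
                                freeze = c("lower", "none"), seed = 1L) {
  freeze <- match.arg(freeze)
  y <- labeled$label
  if (length(unique(y[!is.na(y)])) < 2L) {
    cli::cli_abort("Classification tuning needs both positive and negative reactions.",
                   class = "rxnrl_error_single_class")
  }
  toks_list <- lapply(labeled$reaction, tokenize_smiles)
  ids_list <- lapply(toks_list, token_ids, vocab = encoder$vocab)
  idx_list <- lapply(toks_list, pool_positions, pooling = encoder$pooling)
  ybin <- as.numeric(y == "positive")
  n_pos <- sum(ybin == 1)
  n_neg <- sum(ybin == 0)
  wt <- ifelse(ybin == 1, length(ybin) / (2 * n_pos), length(ybin) / (2 * n_neg))
  d <- encoder$dims$d
  head_w <- withr::with_seed(seed, stats::rnorm(d, sd = 0.05))
  head_b <- 0
  opt <- new_adam()
  V <- length(encoder$vocab)
  # flat-index mask of tunable encoder coordinates
  lens <- vapply(encoder$params, length, integer(1))
  ends <- cumsum(lens)
  tune_mask <- rep(TRUE, sum(lens))
  if (freeze == "lower") {
    top <- sprintf("e%d_", encoder$dims$n_enc)
    keep <- startsWith(names(encoder$params), top)
    for (i in seq_along(lens)) {
      if (!keep[i]) tune_mask[(ends[i] - lens[i] + 1L):ends[i]] <- FALSE
    }
  }
  for (epoch in seq_len(epochs)) {
    ord <- withr::with_seed(seed * 1000L + epoch, sample.int(length(ids_list)))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (batch in batches) {
      pv <- flat_params(encoder)
      gv <- numeric(length(pv))
      g_head_w <- numeric(d)
      g_head_b <- 0
      for (i in batch) {
        h <- as.numeric(cpp_encode_pool(pv, encoder$dims, V, encoder$pos,
                                        ids_list[[i]], idx_list[[i]]))
        z <- sum(h * head_w) + head_b
        p <- 1 / (1 + exp(-z))
        dz <- wt[i] * (p - ybin[i]) / length(batch)
        cpp_encoder_pool_grad(pv, gv, encoder$dims, V, encoder$pos,
                              ids_list[[i]], dz * head_w, idx_list[[i]])
        g_head_w <- g_head_w + dz * h
        g_head_b <- g_head_b + dz
      }
      gv[!tune_mask] <- 0
      params <- encoder$params
      params$.head_w <- head_w
      params$.head_b <- head_b
      params <- adam_step(params, c(gv, g_head_w, g_head_b), opt, lr = lr)
      head_w <- params$.head_w
      head_b <- params$.head_b
      params$.head_w <- NULL
      params$.head_b <- NULL
      encoder$params <- params
    }
  }
  encoder
}

#' Class-separation diagnostics in fingerprint space
#'
#' Projects embeddings onto their first two principal components and
#' reports scalar separation measures: the ratio of the between-class
#' centroid distance to the mean within-class spread, and the balanced
#' accuracy of a held-out linear separator fitted on half the points.
#'
#' @param embeddings Numeric matrix, one row per reaction.
#' @param labels "positive"/"negative" per row (>= 2 points per class).
#' @param seed Seed for the held-out split.
#' @return A `separation_report`: list with `projection` (tibble PC1,
#'   PC2, label), `separation_ratio`, `balanced_accuracy`. Degenerate
#'   (zero-variance) inputs give NA measures rather than an error.
#' @export
separation_report <- function(embeddings, labels, seed = 1L) {
  stopifnot(nrow(embeddings) == length(labels))
  if (min(table(labels)) < 2L) {
    cli::cli_abort("Need at least two points per class.",
                   class = "rxnrl_error_single_class")
  }
  tot_var <- sum(apply(embeddings, 2, stats::var))
  if (!is.finite(tot_var) || tot_var < 1e-12) {
    proj <- tibble::tibble(PC1 = rep(0, nrow(embeddings)),
                           PC2 = 0, label = labels)
    return(structure(list(projection = proj, separation_ratio = NA_real_,
                          balanced_accuracy = 0.5),
                     class = "separation_report"))
  }
  pc <- stats::prcomp(embeddings, rank. = min(2L, ncol(embeddings)))
  proj <- tibble::tibble(
    PC1 = pc$x[, 1],
    PC2 = if (ncol(pc$x) > 1) pc$x[, 2] else 0,
    label = labels
  )
  # separation ratio: mean pairwise distance between classes over mean
  # pairwise distance within classes (1 = indistinguishable clouds)
  D <- as.matrix(stats::dist(embeddings))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  inter <- mean(D[!is.na(same) & !same])
  intra <- mean(D[!is.na(same) & same])
  ratio <- if (!is.finite(intra) || intra < 1e-12) NA_real_ else inter / intra
  bal <- tryCatch(
    heldout_balanced_accuracy(embeddings, labels, seed = seed),
    error = function(e) NA_real_
  )
  structure(
    list(projection = proj, separation_ratio = ratio, balanced_accuracy = bal),
    class = "separation_report"
  )
}

# Balanced accuracy of a logistic separator fitted on a seeded half of
# the points (in PC space to keep p < n) and evaluated on the other half.
heldout_balanced_accuracy <- function(embeddings, labels, seed = 1L) {
  y <- as.numeric(labels == "positive")
  n <- length(y)
  idx <- withr::with_seed(seed, sample.int(n, floor(n / 2)))
  if (length(unique(y[idx])) < 2L) idx <- seq_len(floor(n / 2))
  if (length(unique(y[idx])) < 2L) return(NA_real_)
  pc <- stats::prcomp(embeddings, rank. = min(10L, ncol(embeddings), n - 1L))
  X <- pc$x
  dat <- data.frame(y = y, X)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = dat[idx, , drop = FALSE], family = stats::binomial())
  )
  pred <- suppressWarnings(
    stats::predict(fit, dat[-idx, , drop = FALSE], type = "response")
  ) >= 0.5
  truth <- y[-idx] == 1
  sens <- if (any(truth)) mean(pred[truth]) else NA_real_
  spec <- if (any(!truth)) mean(!pred[!truth]) else NA_real_
  mean(c(sens, spec), na.rm = TRUE)
}

#' @export
print.separation_report <- function(x, ...) {
  cli::cli_text(
    "<separation_report> separation ratio {signif(x$separation_ratio, 3)}, held-out balanced accuracy {signif(x$balanced_accuracy, 3)}"
  )
  invisible(x)
}

#' @exportS3Method generics::glance
glance.separation_report <- function(x, ...) {
  tibble::tibble(separation_ratio = x$separation_ratio,
                 balanced_accuracy = x$balanced_accuracy)
}

#' Principal-component scatter of positive and negative fingerprints
#'
#' @param object A `separation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.separation_report <- function(object, ...) {
  ggplot2::ggplot(object$projection,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = NULL)
}

#' Fit the imbalance-aware reward classifier
#'
#' A maximum-margin classifier (radial-kernel SVM) over fingerprint
#' embeddings with class weights inversely proportional to class
#' frequency, so that a handful of positives among hundreds of negatives
#' still shapes the margin; probability calibration (sigmoid fit) yields
#' the graded reward.
#'
#' @param embeddings Numeric matrix of fingerprints.
#' @param labels "positive"/"negative" per row (both classes required).
#' @param cost SVM cost parameter.
#' @param kernel SVM kernel (default "radial").
#' @param weights "balanced" (inverse class frequency, the default) or
#'   "none" (unweighted, for ablation).
#' @param seed Seed for the calibration's internal cross-validation.
#' @return An object of class `reward_classifier` with a `predict_prob()`
#'   accessor used by [compute_reward()].
#' @export
fit_reward_classifier <- function(embeddings, labels, cost = 1,
                                  kernel = "radial",
                                  weights = c("balanced", "none"),
                                  seed = 1L) {
  weights <- match.arg(weights)
  labels <- factor(labels, levels = c("negative", "positive"))
  if (length(unique(labels)) < 2L) {
    cli::cli_abort("Both classes are required to fit the reward classifier.",
                   class = "rxnrl_error_single_class")
  }
  tab <- table(labels)
  cw <- if (weights == "balanced") {
    stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
  } else {
    stats::setNames(c(1, 1), names(tab))
  }
  fit <- withr::with_seed(seed, e1071::svm(
    x = embeddings, y = labels, kernel = kernel, cost = cost,
    class.weights = cw, probability = TRUE, scale = FALSE
  ))
  structure(list(svm = fit, class_weights = cw,
                 prior = mean(labels == "positive")),
            class = "reward_classifier")
}

#' Calibrated probability that reactions are positive
#'
#' With `balance_prior = TRUE` the calibrated probability is converted
#' to the balanced-prior scale (Bayes correction for the training class
#' frequencies), so that a reward consumer sees scores spread around
#' 0.5 rather than compressed towards the raw positive prior. The
#' correction is strictly monotone in the raw probability.
#'
#' @param classifier A `reward_classifier`.
#' @param embeddings Fingerprint matrix.
#' @param balance_prior Undo the training class prior (default TRUE).
#' @return Probabilities in (0, 1).
#' @export
predict_prob <- function(classifier, embeddings, balance_prior = TRUE) {
  pr <- stats::predict(classifier$svm, embeddings, probability = TRUE)
  p <- attr(pr, "probabilities")[, "positive"]
  if (balance_prior && !is.null(classifier$prior)) {
    pi0 <- min(max(classifier$prior, 1e-6), 1 - 1e-6)
    lr <- (p / pi0) / pmax((1 - p) / (1 - pi0), 1e-12)
    p <- lr / (lr + 1)
  }
  p
}

#' Assemble a reward model
#'
#' Bundles the fingerprint encoder, the fitted classifier and the exact
#' match bookkeeping into the composite reward function used by the RL
#' tuner: an invalid product scores `invalid_reward`; a canonical match
#' to a recorded positive for that left-hand side scores `match_bonus`; a
#' match to a recorded negative scores 0; anything else scores the
#' calibrated classifier probability (thresholded at 0.5 to {0, 1} in
#' binary mode).
#'
#' @param encoder A `reaction_encoder` (typically classification-tuned).
#' @param classifier A `reward_classifier` from [fit_reward_classifier()].
#' @param known Reaction record tibble of labeled reactions whose exact
#'   products are trusted.
#' @param invalid_reward Reward for unparsable products (default 0).
#' @param match_bonus Reward for a recorded positive (default 1).
#' @param binary Threshold classifier probabilities at 0.5 (the
#'   high-throughput-screening reward mode).
#' @return An object of class `reward_model`.
#' @export
reward_model <- function(encoder, classifier, known,
                         invalid_reward = 0, match_bonus = 1,
                         binary = FALSE) {
  structure(
    list(
      encoder = encoder,
      classifier = classifier,
      known_pos = known$reaction[!is.na(known$label) & known$label == "positive"],
      known_neg = known$reaction[!is.na(known$label) & known$label == "negative"],
      invalid_reward = invalid_reward,
      match_bonus = match_bonus,
      binary = binary
    ),
    class = "reward_model"
  )
}

#' @export
print.reward_model <- function(x, ...) {
  cli::cli_text(
    "<reward_model> {length(x$known_pos)} known positives, {length(x$known_neg)} known negatives, {if (x$binary) 'binary' else 'graded'} reward"
  )
  invisible(x)
}

#' Fit the full reward model from labeled reactions
#'
#' Convenience wrapper: classification-tunes the encoder on the labeled
#' reactions, embeds them, fits the class-weighted SVM, and assembles the
#' composite reward with the same reactions as the exact-match tables.
#'
#' @param records Labeled reaction record tibble (both classes); supplies
#'   the SVM training data and the exact-match tables.
#' @param encoder Optional starting `reaction_encoder`; by default a
#'   fresh one is created from the records' vocabulary (in the full
#'   pipeline, pass [as_reaction_encoder()] of the pretrained policy).
#' @param tune_data Labeled reactions for classification tuning of the
#'   encoder. Should be disjoint from the evaluation domain; defaults to
#'   `records`.
#' @param tune Classification-tune the encoder first (default TRUE).
#' @param epochs,lr Tuning settings, see [classification_tune()].
#' @param cost SVM cost.
#' @param binary Binary reward mode.
#' @param seed Seed for initialization, tuning and calibration.
#' @return A `reward_model`.
#' @export
fit_reward_model <- function(records, encoder = NULL, tune_data = NULL,
                             tune = TRUE, epochs = 4L, lr = 3e-4, cost = 1,
                             binary = FALSE, seed = 1L) {
  if (is.null(encoder)) {
    encoder <- new_reaction_encoder(build_vocab(records), seed = seed)
  }
  # enumerated negatives can canonicalize to tokens outside the encoder
  # vocabulary; such records stay in the exact-match tables but cannot
  # enter the fingerprint space
  enc_ok <- vapply(records$reaction, function(rx) {
    all(tokenize_smiles(rx) %in% encoder$vocab)
  }, logical(1))
  if (any(!enc_ok)) {
    cli::cli_inform(
      "{sum(!enc_ok)} reaction{?s} outside the encoder vocabulary excluded from embedding."
    )
  }
  fitting <- records[enc_ok, , drop = FALSE]
  if (tune) {
    if (is.null(tune_data)) {
      tune_data <- fitting
    } else {
      tune_ok <- vapply(tune_data$reaction, function(rx) {
        all(tokenize_smiles(rx) %in% encoder$vocab)
      }, logical(1))
      tune_data <- tune_data[tune_ok, , drop = FALSE]
    }
    encoder <- classification_tune(encoder, tune_data, epochs = epochs,
                                   lr = lr, seed = seed)
  }
  emb <- embed_reactions(encoder, fitting)
  clf <- fit_reward_classifier(emb, fitting$label, cost = cost, seed = seed)
  reward_model(encoder, clf, known = records, binary = binary)
}

#' Composite reward for predicted products
#'
#' Total function on raw decoder output: every product string receives a
#' reward in `[0, 1]` following the composite rule described in
#' [reward_model()]. Known labels override the classifier.
#'
#' @param model A `reward_model`.
#' @param lhs Character vector of canonical precursor sides.
#' @param product Character vector of predicted product SMILES (raw
#'   decoder output; may be invalid).
#' @return Numeric vector of rewards in `[0, 1]`.
#' @export
compute_reward <- function(model, lhs, product) {
  stopifnot(length(lhs) == length(product))
  canon <- canonicalize_or_na(product)
  reward <- rep(model$invalid_reward, length(product))
  ok <- !is.na(canon)
  if (any(ok)) {
    rxn <- paste0(lhs[ok], ">>", canon[ok])
    r <- rep(NA_real_, length(rxn))
    r[rxn %in% model$known_pos] <- model$match_bonus
    r[is.na(r) & rxn %in% model$known_neg] <- 0
    todo <- is.na(r)
    if (any(todo)) {
      # a decoded product can canonicalize to tokens the reward encoder
      # never saw (e.g. radical bracket atoms); such reactions fall
      # outside the fingerprint space and score the invalid reward
      known_tok <- vapply(rxn[todo], function(x) {
        all(tryCatch(tokenize_smiles(x), error = function(e) NA_character_)
            %in% model$encoder$vocab)
      }, logical(1))
      scores <- rep(model$invalid_reward, sum(todo))
      if (any(known_tok)) {
        emb <- embed_reactions(model$encoder, rxn[todo][known_tok])
        p <- predict_prob(model$classifier, emb)
        if (model$binary) p <- as.numeric(p >= 0.5)
        scores[known_tok] <- p
      }
      r[todo] <- scores
    }
    reward[ok] <- r
  }
  pmin(pmax(reward, 0), 1)
}
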