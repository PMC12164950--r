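# Maximum-likelihood training of the forward model (pretraining and
# fine-tuning share the same loop: token-level cross-entropy with teacher
# forcing, Adam, best checkpoint by validation top-1 positive accuracy).

#' Configuration for maximum-likelihood training
#'
#' @param epochs Passes over the data.
#' @param lr Adam learning rate.
#' @param lr_decay Multiplicative learning-rate decay per epoch (1 = none).
#' @param batch_size Sequences per gradient-accumulation step.
#' @param seed Seed controlling example order.
#' @param eval_every Validate every this many epochs.
#' @param eval_beams Beam width used for validation top-1 monitoring.
#' @param target_valid Optional early-stop target: training ends at the
#'   first evaluation whose validation top-1 reaches this value.
#' @param verbose Print a line per evaluation.
#' @return Named list of settings.
#' @export
mle_config <- function(epochs = 10L, lr = 1.5e-3, lr_decay = 0.95,
                       batch_size = 4L, seed = 1L, eval_every = 2L,
                       eval_beams = 3L, target_valid = NULL,
                       verbose = FALSE) {
  list(epochs = epochs, lr = lr, lr_decay = lr_decay,
       batch_size = batch_size, seed = seed, eval_every = eval_every,
       eval_beams = eval_beams, target_valid = target_valid,
       verbose = verbose)
}

#' Train a policy by maximum likelihood
#'
#' Minimizes token-level cross-entropy with teacher forcing on the
#' positive reactions of `records` (negative reactions never enter MLE;
#' they contribute only through the RL reward). When a validation set is
#' given, the checkpoint with the best validation top-1 positive accuracy
#' is returned.
#'
#' @param policy A `seq2seq_policy` (untrained, or pretrained for
#'   fine-tuning).
#' @param records Reaction record tibble; rows labeled "negative" are
#'   dropped with a message.
#' @param valid Optional validation reaction record tibble (positives).
#' @param config Settings from [mle_config()].
#' @return An `mle_fit`: list with `policy` (best checkpoint), `history`
#'   (tibble epoch/loss/valid_top1) and `config`.
#' @export
train_mle <- function(policy, records, valid = NULL, config = mle_config()) {
  is_neg <- !is.na(records$label) & records$label == "negative"
  if (any(is_neg)) {
    cli::cli_inform("Dropping {sum(is_neg)} negative reaction{?s} from MLE training.")
    records <- records[!is_neg, , drop = FALSE]
  }
  stopifnot(nrow(records) > 0)
  pairs <- lapply(seq_len(nrow(records)), function(i) {
    seq_pair_ids(policy, records$lhs[i], tokenize_smiles(records$product[i]))
  })
  opt <- new_adam()
  history <- list()
  best <- list(acc = -Inf, params = policy$params)
  for (epoch in seq_len(config$epochs)) {
    ord <- withr::with_seed(config$seed * 10000L + epoch, sample.int(length(pairs)))
    total <- 0
    decay <- if (is.null(config$lr_decay)) 1 else config$lr_decay
    lr_epoch <- config$lr * decay^(epoch - 1)
    bs <- if (is.null(config$batch_size)) 1L else max(1L, config$batch_size)
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    V <- length(policy$vocab)
    for (batch in batches) {
      pv <- flat_params(policy)
      gv <- numeric(length(pv))
      for (i in batch) {
        pr <- pairs[[i]]
        lp <- cpp_policy_grad(pv, gv, policy$dims, V, policy$pos,
                              pr$src, pr$tin, pr$tout,
                              1 / (length(pr$tout) * length(batch)))
        loss <- -mean(lp)
        if (!is.finite(loss)) {
          cli::cli_abort("Training loss became non-finite at epoch {epoch}.",
                         class = "rxnrl_error_divergence")
        }
        total <- total + loss
      }
      policy$params <- adam_step(policy$params, gv, opt, lr = lr_epoch)
    }
    vacc <- NA_real_
    if (!is.null(valid) &&
        (epoch %% config$eval_every == 0L || epoch == config$epochs)) {
      vacc <- topk_positive_accuracy(policy, valid, k = 1L,
                                     beams = config$eval_beams)
      if (vacc > best$acc) best <- list(acc = vacc, params = policy$params)
      if (config$verbose) {
        cli::cli_inform("epoch {epoch}: loss {signif(total / length(pairs), 4)}, valid top-1 {signif(vacc, 3)}")
      }
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = total / length(pairs), valid_top1 = vacc
    )
    if (!is.null(config$target_valid) && !is.na(vacc) &&
        vacc >= config$target_valid) {
      break
    }
  }
  if (is.null(valid)) best$params <- policy$params
  policy$params <- best$params
  structure(
    list(policy = policy, history = dplyr::bind_rows(history), config = config),
    class = "mle_fit"
  )
}

#' @export
print.mle_fit <- function(x, ...) {
  h <- x$history
  cli::cli_text(
    "<mle_fit> {nrow(h)} epoch{?s}, final loss {signif(utils::tail(h$loss, 1), 4)}, best valid top-1 {signif(max(c(h$valid_top1, -Inf), na.rm = TRUE), 3)}"
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mle_fit <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.mle_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    final_loss = utils::tail(x$history$loss, 1),
    best_valid_top1 = suppressWarnings(max(x$history$valid_top1, na.rm = TRUE))
  )
}

#' Training-curve plot for an MLE fit
#'
#' @param object An `mle_fit`.
#' @param ... Unused.
#' @return A ggplot of loss and validation accuracy against epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.mle_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -dplyr::all_of("epoch"),
                              names_to = "metric", values_to = "value")
  long <- long[!is.na(long$value), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL)
}
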