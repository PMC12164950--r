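# Decoders: beam search, ancestral sampling, and teacher-forced sequence
# log-probabilities. All decoders condition on the precursor side of a
# reaction and generate product token sequences.

# Log-probabilities of the next token given a decoder prefix (compiled
# kernel; `pv` lets tight loops reuse the flattened parameters).
next_token_logp <- function(policy, enc_out, tin_ids, pv = flat_params(policy)) {
  cpp_next_logp(pv, policy$dims, length(policy$vocab), policy$pos, enc_out,
                tin_ids)
}

# Encoder output for a left-hand side (compiled kernel).
encode_lhs <- function(policy, lhs, pv = flat_params(policy)) {
  src <- token_ids(tokenize_smiles(lhs), policy$vocab)
  cpp_encode(pv, policy$dims, length(policy$vocab), policy$pos, src)
}

#' Beam-search decoding of a product
#'
#' Standard length-bounded beam search over the decoder, without length
#' normalization. Candidates are ranked by total sequence log-probability
#' (non-increasing down the ranking).
#'
#' @param policy A `seq2seq_policy`.
#' @param lhs Precursor SMILES ("a.b.c" serialized left-hand side).
#' @param beams Beam width (default 10).
#' @param max_len Maximum product length in tokens (default: model limit).
#' @return A `decode_result` tibble: `rank`, `smiles`, `log_prob`,
#'   `truncated` (hit the length bound before emitting the end sentinel).
#' @export
beam_decode <- function(policy, lhs, beams = 10L, max_len = NULL) {
  stopifnot(beams >= 1L)
  if (is.null(max_len)) max_len <- policy$dims$max_len
  pv <- flat_params(policy)
  enc_out <- encode_lhs(policy, lhs, pv)
  alive <- list(list(tin = 1L, logp = 0))
  done <- list()
  for (step in seq_len(max_len)) {
    cand <- done
    for (b in alive) {
      lp <- next_token_logp(policy, enc_out, b$tin, pv)
      ord <- order(lp, decreasing = TRUE)[seq_len(min(beams, length(lp)))]
      for (tok in ord) {
        nb <- list(tin = c(b$tin, tok), logp = b$logp + lp[tok],
                   finished = tok == 2L, truncated = FALSE)
        cand[[length(cand) + 1L]] <- nb
      }
    }
    scores <- vapply(cand, function(z) z$logp, numeric(1))
    keep <- cand[order(scores, decreasing = TRUE)[seq_len(min(beams, length(cand)))]]
    done <- keep[vapply(keep, function(z) isTRUE(z$finished), logical(1))]
    alive <- keep[!vapply(keep, function(z) isTRUE(z$finished), logical(1))]
    if (length(alive) == 0L) break
  }
  for (b in alive) {
    b$finished <- TRUE
    b$truncated <- TRUE
    done[[length(done) + 1L]] <- b
  }
  scores <- vapply(done, function(z) z$logp, numeric(1))
  done <- done[order(scores, decreasing = TRUE)]
  done <- done[seq_len(min(beams, length(done)))]
  out <- tibble::tibble(
    rank = seq_along(done),
    smiles = vapply(done, function(z) {
      toks <- z$tin[-1]
      toks <- toks[toks != 2L]
      detokenize_smiles(policy$vocab[toks])
    }, character(1)),
    log_prob = vapply(done, function(z) z$logp, numeric(1)),
    truncated = vapply(done, function(z) isTRUE(z$truncated), logical(1))
  )
  class(out) <- c("decode_result", class(out))
  attr(out, "beams") <- beams
  out
}

#' Sample a product from the policy
#'
#' Ancestral sampling from the decoder at a given temperature. The
#' returned log-probabilities are those of the sampled tokens under the
#' untempered policy (temperature enters the proposal only), which is what
#' the RL tuner needs. Deterministic given `seed`.
#'
#' @param policy A `seq2seq_policy`.
#' @param lhs Precursor SMILES.
#' @param temperature Sampling temperature (> 0); as it approaches 0 the
#'   sample approaches the greedy decode.
#' @param seed Optional integer seed.
#' @param max_len Maximum product length; a sequence still unfinished
#'   there is truncated and flagged.
#' @return List: `smiles`, `tokens` (ids incl. end sentinel), `logp`
#'   (per-token log-probabilities under the policy), `truncated`.
#' @export
sample_decode <- function(policy, lhs, temperature = 1.0, seed = NULL,
                          max_len = NULL) {
  stopifnot(temperature > 0)
  if (is.null(max_len)) max_len <- policy$dims$max_len
  pv <- flat_params(policy)
  run <- function() {
    enc_out <- encode_lhs(policy, lhs, pv)
    tin <- 1L
    ids <- integer(0)
    logps <- numeric(0)
    truncated <- TRUE
    for (step in seq_len(max_len)) {
      lp <- next_token_logp(policy, enc_out, tin, pv)
      z <- (lp - max(lp)) / temperature
      pr <- exp(z)
      pr <- pr / sum(pr)
      tok <- sample.int(length(pr), 1L, prob = pr)
      ids <- c(ids, tok)
      logps <- c(logps, lp[tok])
      tin <- c(tin, tok)
      if (tok == 2L) {
        truncated <- FALSE
        break
      }
    }
    toks <- ids[ids != 2L]
    list(
      smiles = detokenize_smiles(policy$vocab[toks]),
      tokens = ids,
      logp = logps,
      truncated = truncated
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Sequence log-probability under a policy
#'
#' Teacher-forced sum of per-token conditional log-probabilities of a
#' product (including the end sentinel unless the sequence was truncated).
#'
#' @param policy A `seq2seq_policy`.
#' @param lhs Precursor SMILES.
#' @param product Product SMILES string, or an integer vector of token ids
#'   as returned by [sample_decode()].
#' @return Scalar log-probability (<= 0).
#' @export
sequence_log_prob <- function(policy, lhs, product) {
  if (is.character(product)) {
    product <- c(token_ids(tokenize_smiles(product), policy$vocab), 2L)
  }
  src <- token_ids(tokenize_smiles(lhs), policy$vocab)
  tin <- c(1L, product[product != 2L])
  tout <- product
  if (length(tout) != length(tin)) tin <- tin[seq_along(tout)]
  sum(cpp_policy_logp(flat_params(policy), policy$dims, length(policy$vocab),
                      policy$pos, src, tin, tout))
}
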