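# Compact encoder-decoder transformer with hand-written backpropagation.
#
# Parameters live in a flat named list of numeric arrays; gradients are
# accumulated in an environment keyed by the same names; optimization is
# Adam. The analytic gradients are checked against finite differences in
# the test suite. Everything runs one sequence pair at a time: the toy
# reaction language uses short sequences, so BLAS-level matrix products
# dominate and batching adds nothing but complexity.

.LN_EPS <- 1e-5

## ---- vocabulary ----------------------------------------------------------

#' Build a token vocabulary from reaction records
#'
#' Tokens are gathered from the full serialized reactions, so the same
#' vocabulary serves the forward model (precursors -> product) and the
#' reaction-fingerprint encoder. Begin/end sentinels occupy the first two
#' slots.
#'
#' @param records Reaction record tibble (or character vector of strings).
#' @return Character vector of vocabulary symbols, class `rxnrl_vocab`.
#' @export
build_vocab <- function(records) {
  strings <- if (is.data.frame(records)) records$reaction else records
  toks <- unique(unlist(lapply(strings, tokenize_smiles)))
  structure(c("<bos>", "<eos>", sort(toks)), class = "rxnrl_vocab")
}

token_ids <- function(tokens, vocab) {
  ids <- match(tokens, vocab)
  if (anyNA(ids)) {
    cli::cli_abort(
      "Token{?s} outside the model vocabulary: {.val {unique(tokens[is.na(ids)])}}",
      class = "rxnrl_error_oov", tokens = unique(tokens[is.na(ids)])
    )
  }
  ids
}

## ---- parameter initialization -------------------------------------------

# Xavier/Glorot-scaled Gaussian init by default.
rmat <- function(nr, nc, sd = sqrt(2 / (nr + nc))) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

init_layer_params <- function(prefix, d, ff, cross = FALSE) {
  p <- list()
  p[[paste0(prefix, "Wq")]] <- rmat(d, d)
  p[[paste0(prefix, "Wk")]] <- rmat(d, d)
  p[[paste0(prefix, "Wv")]] <- rmat(d, d)
  p[[paste0(prefix, "Wo")]] <- rmat(d, d)
  p[[paste0(prefix, "ln1_g")]] <- rep(1, d)
  p[[paste0(prefix, "ln1_b")]] <- rep(0, d)
  if (cross) {
    p[[paste0(prefix, "Cq")]] <- rmat(d, d)
    p[[paste0(prefix, "Ck")]] <- rmat(d, d)
    p[[paste0(prefix, "Cv")]] <- rmat(d, d)
    p[[paste0(prefix, "Co")]] <- rmat(d, d)
    p[[paste0(prefix, "ln2_g")]] <- rep(1, d)
    p[[paste0(prefix, "ln2_b")]] <- rep(0, d)
  }
  p[[paste0(prefix, "W1")]] <- rmat(d, ff)
  p[[paste0(prefix, "b1")]] <- rep(0, ff)
  p[[paste0(prefix, "W2")]] <- rmat(ff, d)
  p[[paste0(prefix, "b2")]] <- rep(0, d)
  p[[paste0(prefix, "ln3_g")]] <- rep(1, d)
  p[[paste0(prefix, "ln3_b")]] <- rep(0, d)
  p
}

pos_encoding <- function(max_len, d) {
  pos <- seq_len(max_len) - 1
  i <- seq_len(d %/% 2) - 1
  ang <- outer(pos, 1 / (10000^(2 * i / d)))
  pe <- matrix(0, max_len, d)
  pe[, seq(1, d, by = 2)] <- sin(ang)
  pe[, seq(2, d, by = 2)] <- cos(ang)
  pe
}

#' Create an untrained sequence-to-sequence policy
#'
#' A compact encoder-decoder transformer over SMILES tokens, sized for
#' desk-scale experiments. The same object serves as the trainable RL
#' policy; a plain copy of it is the frozen reference policy.
#'
#' @param vocab Vocabulary from [build_vocab()].
#' @param d Model width (must be divisible by `n_heads`).
#' @param n_heads Number of attention heads.
#' @param ff Feed-forward width.
#' @param n_enc,n_dec Encoder / decoder layer counts.
#' @param max_len Maximum decoded length (tokens).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `seq2seq_policy`.
#' @export
new_policy <- function(vocab, d = 48, n_heads = 4, ff = 96, n_enc = 2,
                       n_dec = 2, max_len = 60, seed = 1L) {
  stopifnot(d %% n_heads == 0)
  V <- length(vocab)
  params <- withr::with_seed(seed, {
    p <- list(emb = rmat(V, d), out_W = rmat(d, V), out_b = rep(0, V))
    for (i in seq_len(n_enc)) p <- c(p, init_layer_params(sprintf("e%d_", i), d, ff))
    for (i in seq_len(n_dec)) p <- c(p, init_layer_params(sprintf("d%d_", i), d, ff, cross = TRUE))
    p
  })
  structure(
    list(
      params = params,
      vocab = vocab,
      dims = list(d = d, n_heads = n_heads, ff = ff, n_enc = n_enc,
                  n_dec = n_dec, max_len = max_len),
      pos = pos_encoding(max_len + 2L, d)
    ),
    class = "seq2seq_policy"
  )
}

#' @export
print.seq2seq_policy <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cli::cli_text(
    "<seq2seq_policy> {x$dims$n_enc}+{x$dims$n_dec} layers, width {x$dims$d}, {x$dims$n_heads} heads, |V| = {length(x$vocab)}, {format(n_par, big.mark = ',')} parameters"
  )
  invisible(x)
}

## ---- primitive blocks (forward + backward) -------------------------------

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + .LN_EPS)
  Xhat <- Xc * inv
  list(Y = sweep(Xhat, 2, g, `*`) + matrix(b, nrow(X), length(b), byrow = TRUE),
       cache = list(Xhat = Xhat, inv = inv, g = g))
}

ln_bwd <- function(dY, cache) {
  Xhat <- cache$Xhat
  dXhat <- sweep(dY, 2, cache$g, `*`)
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * Xhat)
  dX <- (dXhat - m1 - Xhat * m2) * cache$inv
  list(dX = dX, dg = colSums(dY * Xhat), db = colSums(dY))
}

head_cols <- function(d, nh) {
  dk <- d %/% nh
  lapply(seq_len(nh), function(h) (h - 1L) * dk + seq_len(dk))
}

attn_fwd <- function(Xq, Xkv, Wq, Wk, Wv, Wo, nh, causal = FALSE) {
  d <- ncol(Xq)
  cols <- head_cols(d, nh)
  dk <- d %/% nh
  Q <- Xq %*% Wq; K <- Xkv %*% Wk; V <- Xkv %*% Wv
  O <- matrix(0, nrow(Xq), d)
  P_list <- vector("list", nh)
  for (h in seq_len(nh)) {
    S <- tcrossprod(Q[, cols[[h]], drop = FALSE], K[, cols[[h]], drop = FALSE]) / sqrt(dk)
    if (causal && nrow(S) > 1) S[upper.tri(S)] <- -1e30
    P <- softmax_rows(S)
    P_list[[h]] <- P
    O[, cols[[h]]] <- P %*% V[, cols[[h]], drop = FALSE]
  }
  list(Y = O %*% Wo,
       cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V, P = P_list,
                    O = O, Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo, nh = nh))
}

attn_bwd <- function(dY, cache) {
  nh <- cache$nh
  d <- ncol(cache$Q)
  cols <- head_cols(d, nh)
  dk <- d %/% nh
  dWo <- crossprod(cache$O, dY)
  dO <- tcrossprod(dY, cache$Wo)
  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  for (h in seq_len(nh)) {
    ix <- cols[[h]]
    P <- cache$P[[h]]
    dOh <- dO[, ix, drop = FALSE]
    dV[, ix] <- crossprod(P, dOh)
    dP <- tcrossprod(dOh, cache$V[, ix, drop = FALSE])
    dS <- P * (dP - rowSums(dP * P)) / sqrt(dk)
    dQ[, ix] <- dS %*% cache$K[, ix, drop = FALSE]
    dK[, ix] <- crossprod(dS, cache$Q[, ix, drop = FALSE])
  }
  list(
    dXq = tcrossprod(dQ, cache$Wq),
    dXkv = tcrossprod(dK, cache$Wk) + tcrossprod(dV, cache$Wv),
    dWq = crossprod(cache$Xq, dQ),
    dWk = crossprod(cache$Xkv, dK),
    dWv = crossprod(cache$Xkv, dV),
    dWo = dWo
  )
}

ffn_fwd <- function(X, W1, b1, W2, b2) {
  H0 <- sweep(X %*% W1, 2, b1, `+`)
  H <- pmax(H0, 0)
  list(Y = sweep(H %*% W2, 2, b2, `+`),
       cache = list(X = X, H = H, mask = H0 > 0, W1 = W1, W2 = W2))
}

ffn_bwd <- function(dY, cache) {
  dH <- tcrossprod(dY, cache$W2) * cache$mask
  list(
    dX = tcrossprod(dH, cache$W1),
    dW1 = crossprod(cache$X, dH), db1 = colSums(dH),
    dW2 = crossprod(cache$H, dY), db2 = colSums(dY)
  )
}

gadd <- function(g, name, val) {
  cur <- g[[name]]
  g[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

## ---- encoder / decoder forward ------------------------------------------

embed_ids <- function(policy, ids) {
  d <- policy$dims$d
  policy$params$emb[ids, , drop = FALSE] * sqrt(d) +
    policy$pos[seq_along(ids), , drop = FALSE]
}

encoder_fwd <- function(policy, src_ids) {
  p <- policy$params
  nh <- policy$dims$n_heads
  X <- embed_ids(policy, src_ids)
  caches <- vector("list", policy$dims$n_enc)
  for (i in seq_len(policy$dims$n_enc)) {
    pf <- sprintf("e%d_", i)
    a <- attn_fwd(X, X, p[[paste0(pf, "Wq")]], p[[paste0(pf, "Wk")]],
                  p[[paste0(pf, "Wv")]], p[[paste0(pf, "Wo")]], nh)
    l1 <- ln_fwd(X + a$Y, p[[paste0(pf, "ln1_g")]], p[[paste0(pf, "ln1_b")]])
    f <- ffn_fwd(l1$Y, p[[paste0(pf, "W1")]], p[[paste0(pf, "b1")]],
                 p[[paste0(pf, "W2")]], p[[paste0(pf, "b2")]])
    l3 <- ln_fwd(l1$Y + f$Y, p[[paste0(pf, "ln3_g")]], p[[paste0(pf, "ln3_b")]])
    caches[[i]] <- list(attn = a$cache, ln1 = l1$cache, ffn = f$cache,
                        ln3 = l3$cache)
    X <- l3$Y
  }
  list(out = X, caches = caches, src_ids = src_ids)
}

encoder_bwd <- function(policy, enc, dOut, g) {
  nh <- policy$dims$n_heads
  dX <- dOut
  for (i in rev(seq_len(policy$dims$n_enc))) {
    pf <- sprintf("e%d_", i)
    cc <- enc$caches[[i]]
    l3 <- ln_bwd(dX, cc$ln3)
    gadd(g, paste0(pf, "ln3_g"), l3$dg); gadd(g, paste0(pf, "ln3_b"), l3$db)
    f <- ffn_bwd(l3$dX, cc$ffn)
    gadd(g, paste0(pf, "W1"), f$dW1); gadd(g, paste0(pf, "b1"), f$db1)
    gadd(g, paste0(pf, "W2"), f$dW2); gadd(g, paste0(pf, "b2"), f$db2)
    dl1 <- l3$dX + f$dX
    l1 <- ln_bwd(dl1, cc$ln1)
    gadd(g, paste0(pf, "ln1_g"), l1$dg); gadd(g, paste0(pf, "ln1_b"), l1$db)
    a <- attn_bwd(l1$dX, cc$attn)
    gadd(g, paste0(pf, "Wq"), a$dWq); gadd(g, paste0(pf, "Wk"), a$dWk)
    gadd(g, paste0(pf, "Wv"), a$dWv); gadd(g, paste0(pf, "Wo"), a$dWo)
    dX <- l1$dX + a$dXq + a$dXkv
  }
  # embedding gradient
  d <- policy$dims$d
  demb_rows <- dX * sqrt(d)
  gacc <- g[["emb"]]
  if (is.null(gacc)) gacc <- array(0, dim(policy$params$emb))
  for (t in seq_along(enc$src_ids)) {
    gacc[enc$src_ids[t], ] <- gacc[enc$src_ids[t], ] + demb_rows[t, ]
  }
  g[["emb"]] <- gacc
  invisible(NULL)
}

decoder_fwd <- function(policy, enc_out, tin_ids) {
  p <- policy$params
  nh <- policy$dims$n_heads
  X <- embed_ids(policy, tin_ids)
  caches <- vector("list", policy$dims$n_dec)
  for (i in seq_len(policy$dims$n_dec)) {
    pf <- sprintf("d%d_", i)
    a <- attn_fwd(X, X, p[[paste0(pf, "Wq")]], p[[paste0(pf, "Wk")]],
                  p[[paste0(pf, "Wv")]], p[[paste0(pf, "Wo")]], nh, causal = TRUE)
    l1 <- ln_fwd(X + a$Y, p[[paste0(pf, "ln1_g")]], p[[paste0(pf, "ln1_b")]])
    cx <- attn_fwd(l1$Y, enc_out, p[[paste0(pf, "Cq")]], p[[paste0(pf, "Ck")]],
                   p[[paste0(pf, "Cv")]], p[[paste0(pf, "Co")]], nh)
    l2 <- ln_fwd(l1$Y + cx$Y, p[[paste0(pf, "ln2_g")]], p[[paste0(pf, "ln2_b")]])
    f <- ffn_fwd(l2$Y, p[[paste0(pf, "W1")]], p[[paste0(pf, "b1")]],
                 p[[paste0(pf, "W2")]], p[[paste0(pf, "b2")]])
    l3 <- ln_fwd(l2$Y + f$Y, p[[paste0(pf, "ln3_g")]], p[[paste0(pf, "ln3_b")]])
    caches[[i]] <- list(attn = a$cache, ln1 = l1$cache, cross = cx$cache,
                        ln2 = l2$cache, ffn = f$cache, ln3 = l3$cache)
    X <- l3$Y
  }
  logits <- sweep(X %*% p$out_W, 2, p$out_b, `+`)
  list(logits = logits, dec_out = X, caches = caches, tin_ids = tin_ids)
}

decoder_bwd <- function(policy, dec, dLogits, g) {
  p <- policy$params
  gadd(g, "out_W", crossprod(dec$dec_out, dLogits))
  gadd(g, "out_b", colSums(dLogits))
  dX <- tcrossprod(dLogits, p$out_W)
  dEnc <- NULL
  for (i in rev(seq_len(policy$dims$n_dec))) {
    pf <- sprintf("d%d_", i)
    cc <- dec$caches[[i]]
    l3 <- ln_bwd(dX, cc$ln3)
    gadd(g, paste0(pf, "ln3_g"), l3$dg); gadd(g, paste0(pf, "ln3_b"), l3$db)
    f <- ffn_bwd(l3$dX, cc$ffn)
    gadd(g, paste0(pf, "W1"), f$dW1); gadd(g, paste0(pf, "b1"), f$db1)
    gadd(g, paste0(pf, "W2"), f$dW2); gadd(g, paste0(pf, "b2"), f$db2)
    dl2 <- l3$dX + f$dX
    l2 <- ln_bwd(dl2, cc$ln2)
    gadd(g, paste0(pf, "ln2_g"), l2$dg); gadd(g, paste0(pf, "ln2_b"), l2$db)
    cx <- attn_bwd(l2$dX, cc$cross)
    gadd(g, paste0(pf, "Cq"), cx$dWq); gadd(g, paste0(pf, "Ck"), cx$dWk)
    gadd(g, paste0(pf, "Cv"), cx$dWv); gadd(g, paste0(pf, "Co"), cx$dWo)
    dEnc <- if (is.null(dEnc)) cx$dXkv else dEnc + cx$dXkv
    dl1 <- l2$dX + cx$dXq
    l1 <- ln_bwd(dl1, cc$ln1)
    gadd(g, paste0(pf, "ln1_g"), l1$dg); gadd(g, paste0(pf, "ln1_b"), l1$db)
    a <- attn_bwd(l1$dX, cc$attn)
    gadd(g, paste0(pf, "Wq"), a$dWq); gadd(g, paste0(pf, "Wk"), a$dWk)
    gadd(g, paste0(pf, "Wv"), a$dWv); gadd(g, paste0(pf, "Wo"), a$dWo)
    dX <- l1$dX + a$dXq + a$dXkv
  }
  d <- policy$dims$d
  demb_rows <- dX * sqrt(d)
  gacc <- g[["emb"]]
  if (is.null(gacc)) gacc <- array(0, dim(policy$params$emb))
  for (t in seq_along(dec$tin_ids)) {
    gacc[dec$tin_ids[t], ] <- gacc[dec$tin_ids[t], ] + demb_rows[t, ]
  }
  g[["emb"]] <- gacc
  dEnc
}

## ---- sequence-level objective -------------------------------------------

# Tokenized source/target for a reaction: source = precursor side tokens,
# decoder input = <bos> + product tokens, decoder target = product + <eos>.
seq_pair_ids <- function(policy, lhs, product_tokens) {
  src <- token_ids(tokenize_smiles(lhs), policy$vocab)
  tgt <- token_ids(product_tokens, policy$vocab)
  list(src = src, tin = c(1L, tgt), tout = c(tgt, 2L))
}

# Forward pass returning per-token log-probabilities of `tout`.
seq_forward <- function(policy, src, tin, tout) {
  enc <- encoder_fwd(policy, src)
  dec <- decoder_fwd(policy, enc$out, tin)
  P <- softmax_rows(dec$logits)
  lp <- log(P[cbind(seq_along(tout), tout)] + 1e-12)
  list(enc = enc, dec = dec, P = P, logp = lp)
}

# Accumulate the gradient of sum_t w[t] * (-log p(tout[t])) into `g`.
# With w = 1/length(tout) this is the mean token cross-entropy; RL passes
# a signed per-sequence coefficient instead.
seq_backward <- function(policy, fw, tout, w, g) {
  dLogits <- fw$P * w
  dLogits[cbind(seq_along(tout), tout)] <-
    dLogits[cbind(seq_along(tout), tout)] - w
  dEnc <- decoder_bwd(policy, fw$dec, dLogits, g)
  encoder_bwd(policy, fw$enc, dEnc, g)
  invisible(NULL)
}

## ---- flat-parameter fast path -------------------------------------------

# Flat parameter vector in construction order (the layout the compiled
# kernels assume).
flat_params <- function(obj) unlist(obj$params, use.names = FALSE)

# Restore a flat gradient vector to the named-list layout (diagnostics).
unflatten_like <- function(params, vec) {
  lens <- vapply(params, length, integer(1))
  ends <- cumsum(lens)
  out <- params
  for (i in seq_along(params)) {
    x <- vec[(ends[i] - lens[i] + 1L):ends[i]]
    if (!is.null(dim(params[[i]]))) dim(x) <- dim(params[[i]])
    out[[i]] <- x
  }
  out
}

## ---- Adam ----------------------------------------------------------------

new_adam <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e
}

# Adam over the whole parameter list at once: parameters and gradients
# are flattened into single vectors (the layout is cached in the state),
# so the update is a handful of long vectorized operations instead of
# hundreds of small ones. `grads` may be a named list (one entry per
# parameter) or an already-flat numeric vector in parameter order.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 1.0) {
  nms <- names(params)
  if (is.null(state$layout) || !identical(state$layout$names, nms)) {
    lens <- vapply(params, length, integer(1))
    state$layout <- list(names = nms, lens = lens, ends = cumsum(lens),
                         dims = lapply(params, dim))
    state$m <- numeric(sum(lens))
    state$v <- numeric(sum(lens))
  }
  lay <- state$layout
  if (is.numeric(grads) && !is.list(grads)) {
    stopifnot(length(grads) == lay$ends[length(lay$ends)])
    gvec <- grads
  } else {
    gvec <- numeric(lay$ends[length(lay$ends)])
    for (i in seq_along(nms)) {
      gi <- grads[[nms[i]]]
      if (!is.null(gi)) {
        gvec[(lay$ends[i] - lay$lens[i] + 1L):lay$ends[i]] <- gi
      }
    }
  }
  gn <- sqrt(sum(gvec^2))
  if (is.finite(gn) && gn > clip) gvec <- gvec * (clip / gn)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * gvec
  state$v <- beta2 * state$v + (1 - beta2) * gvec^2
  step <- lr * (state$m / (1 - beta1^state$t)) /
    (sqrt(state$v / (1 - beta2^state$t)) + eps)
  pvec <- unlist(params, use.names = FALSE) - step
  out <- vector("list", length(nms))
  names(out) <- nms
  for (i in seq_along(nms)) {
    x <- pvec[(lay$ends[i] - lay$lens[i] + 1L):lay$ends[i]]
    if (!is.null(lay$dims[[i]])) dim(x) <- lay$dims[[i]]
    out[[i]] <- x
  }
  out
}
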