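# Dataset construction: corpus cleaning, regiochemical negative
# enumeration, yield-threshold labeling, reproducible splits and the
# high/low positive-data regimes.

.halogens <- c("F", "Cl", "Br", "I")

#' Clean a reaction corpus
#'
#' Applies the standard cleaning rules for forward-prediction corpora, in
#' order: drop reactions with invalid species, drop duplicate reaction
#' strings, drop reactions whose product equals one of its own precursors
#' (a residual reactant on the product side), and drop reactions whose
#' product is in `exclude_products` (preventing leakage of fine-tuning
#' products into a pretraining corpus). Idempotent.
#'
#' @param records Reaction record tibble.
#' @param exclude_products Character vector of canonical product SMILES to
#'   exclude.
#' @return The cleaned tibble, with a `"cleaning_report"` attribute giving
#'   per-rule removal counts (also retrievable with [cleaning_report()]).
#' @export
clean_corpus <- function(records, exclude_products = character(0)) {
  canon <- canonicalize_reaction_or_na(records$reaction)
  ok_valid <- !is.na(canon)
  records <- records[ok_valid, , drop = FALSE]
  records$reaction <- canon[ok_valid]
  parts <- stringr::str_split_fixed(records$reaction, stringr::fixed(">>"), 2)
  records$lhs <- parts[, 1]
  records$product <- parts[, 2]

  dup <- duplicated(records$reaction)
  records2 <- records[!dup, , drop = FALSE]

  residual <- purrr::map2_lgl(
    strsplit(records2$lhs, ".", fixed = TRUE), records2$product,
    function(p, q) q %in% p
  )
  records3 <- records2[!residual, , drop = FALSE]

  leaked <- records3$product %in% exclude_products
  out <- records3[!leaked, , drop = FALSE]

  attr(out, "cleaning_report") <- list(
    invalid = sum(!ok_valid),
    duplicate = sum(dup),
    residual_reactant = sum(residual),
    excluded_product = sum(leaked)
  )
  out
}

#' Per-rule removal counts from a cleaning step
#'
#' @param records Output of [clean_corpus()].
#' @return Named list of removal counts.
#' @export
cleaning_report <- function(records) {
  attr(records, "cleaning_report")
}

# Identify the movable halogen of a positive reaction: the halogen atom
# whose removal from the product gives back one of the precursors. A
# halogen already present in a precursor (e.g. a 2-bromophenyl group) is
# thereby never selected. Ties are broken by lowest atom index.
find_movable_halogen <- function(graph, precursors) {
  hal_idx <- which(graph$atoms %in% .halogens)
  if (length(hal_idx) == 0L) {
    cli::cli_abort("Product contains no halogen atom.",
                   class = "rxnrl_error_no_halogen")
  }
  for (idx in hal_idx) {
    scaffold <- graph_delete(graph, idx)
    smi <- graph_to_smiles(scaffold)
    if (!is.na(smi) && smi %in% precursors) {
      return(list(idx = idx, symbol = graph$atoms[idx], scaffold = scaffold,
                  scaffold_smiles = smi))
    }
  }
  cli::cli_abort(
    "Cannot identify the added halogen: removing no halogen atom recovers a precursor.",
    class = "rxnrl_error_ambiguous_halogen"
  )
}

#' Enumerate regiochemical negative products
#'
#' For a positive halogenation reaction, generates every distinct valid
#' product obtained by moving the newly installed halogen to another
#' aromatic C-H position of the substrate. The moved halogen is identified
#' as the one whose removal from the product recovers a precursor, so
#' halogens carried in from the precursors are never repositioned. The
#' true product is excluded and products are deduplicated canonically.
#'
#' @param reaction A positive reaction string "lhs>>product" (or a
#'   one-row reaction record tibble).
#' @return Reaction record tibble of negatives (possibly 0 rows), sharing
#'   the positive's precursors, with `label = "negative"`.
#' @examples
#' \donttest{
#' generate_regio_negatives("c1ccncc1.BrBr>>Brc1ccncc1")
#' }
#' @export
generate_regio_negatives <- function(reaction) {
  if (is.data.frame(reaction)) reaction <- reaction$reaction[1]
  cached <- .negatives_cache[[reaction]]
  if (!is.null(cached)) return(cached)
  out <- generate_regio_negatives_impl(reaction)
  .negatives_cache[[reaction]] <- out
  out
}

# enumeration is deterministic, so results are memoized per session
.negatives_cache <- new.env(parent = emptyenv())

generate_regio_negatives_impl <- function(reaction) {
  rx <- parse_reaction(reaction)
  pg <- mol_graph(rx$product)
  mov <- find_movable_halogen(pg, rx$precursors)
  sites <- aromatic_ch_sites(mov$scaffold)
  if (length(sites) == 0L) {
    cli::cli_abort(
      "Substrate has no aromatic C-H position to halogenate.",
      class = "rxnrl_error_no_sites"
    )
  }
  candidates <- unique(stats::na.omit(vapply(
    sites,
    function(s) graph_to_smiles(graph_attach(mov$scaffold, s, mov$symbol)),
    character(1)
  )))
  negatives <- setdiff(candidates, rx$product)
  if (length(negatives) == 0L) {
    return(reaction_table(character(0)))
  }
  reaction_table(
    vapply(negatives, function(p) reaction_string(rx$precursors, p), character(1)),
    label = "negative", canonicalize = FALSE
  )
}

#' Label reactions by a yield threshold
#'
#' Assigns `label = "positive"` when `yield` strictly exceeds
#' `threshold_pct` (default 1, i.e. observed yield higher than 1 percent)
#' and `"negative"` otherwise.
#'
#' @param records Reaction record tibble with a `yield` column.
#' @param threshold_pct Strict threshold in percent.
#' @return The tibble with `label` filled in.
#' @export
label_by_yield <- function(records, threshold_pct = 1.0) {
  if (is.null(records$yield) || anyNA(records$yield)) {
    cli::cli_abort("All records need a yield to be labeled by threshold.",
                   class = "rxnrl_error_missing_yield")
  }
  records$label <- ifelse(records$yield > threshold_pct, "positive", "negative")
  records
}

# Largest-remainder apportionment of n into parts proportional to ratios.
largest_remainder_sizes <- function(n, ratios) {
  p <- ratios / sum(ratios)
  raw <- n * p
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    order_idx <- order(raw - sizes, decreasing = TRUE)
    sizes[order_idx[seq_len(left)]] <- sizes[order_idx[seq_len(left)]] + 1L
  }
  as.integer(sizes)
}

new_reaction_bundle <- function(train, valid, test, seed, ratios) {
  structure(
    list(train = train, valid = valid, test = test, seed = seed,
         ratios = ratios),
    class = "reaction_bundle"
  )
}

#' Train/validation/test positive-to-negative bookkeeping
#'
#' @param bundle A `reaction_bundle`.
#' @return Train positives divided by train negatives (NA when no
#'   negatives are present).
#' @export
pos_neg_ratio <- function(bundle) {
  np <- sum(bundle$train$label == "positive", na.rm = TRUE)
  nn <- sum(bundle$train$label == "negative", na.rm = TRUE)
  if (nn == 0L) return(NA_real_)
  np / nn
}

#' Split a labeled corpus into train/validation/test
#'
#' Positive (and unlabeled) reactions are randomly partitioned into the
#' three splits with sizes proportional to `ratios` (largest-remainder
#' rounding). Negative reactions are placed in the training split only:
#' accuracy is measured on positive samples, so validation and test
#' contain positives exclusively. Deterministic given `seed`.
#'
#' @param records Reaction record tibble.
#' @param ratios Length-3 non-negative weights, e.g. `c(40, 30, 30)`.
#' @param seed Integer seed controlling the permutation.
#' @return A `reaction_bundle` with elements `train`, `valid`, `test`.
#' @export
split_dataset <- function(records, ratios = c(40, 30, 30), seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) == 0) {
    cli::cli_abort("ratios must be three non-negative weights, not all zero.",
                   class = "rxnrl_error_ratio")
  }
  if (nrow(records) == 0L) {
    cli::cli_abort("Cannot split an empty record set.",
                   class = "rxnrl_error_ratio")
  }
  is_neg <- !is.na(records$label) & records$label == "negative"
  pos <- records[!is_neg, , drop = FALSE]
  neg <- records[is_neg, , drop = FALSE]
  sizes <- largest_remainder_sizes(nrow(pos), ratios)
  perm <- withr::with_seed(seed, sample.int(nrow(pos)))
  idx_train <- perm[seq_len(sizes[1])]
  idx_valid <- perm[sizes[1] + seq_len(sizes[2])]
  idx_test <- perm[sizes[1] + sizes[2] + seq_len(sizes[3])]
  new_reaction_bundle(
    train = dplyr::bind_rows(pos[idx_train, , drop = FALSE], neg),
    valid = pos[idx_valid, , drop = FALSE],
    test = pos[idx_test, , drop = FALSE],
    seed = seed, ratios = ratios
  )
}

#' Subsample training positives (low-data regime)
#'
#' Reduces the training positives to `round(fraction * count)` by uniform
#' sampling without replacement; all training negatives and the
#' validation/test splits are retained unchanged. This turns a high-data
#' regime bundle into its low-data counterpart while keeping the negative
#' pool identical.
#'
#' @param bundle A `reaction_bundle`.
#' @param fraction Fraction of training positives to keep, in (0, 1].
#' @param seed Integer seed.
#' @return A `reaction_bundle`.
#' @export
subsample_positives <- function(bundle, fraction = 0.1, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  is_pos <- is.na(bundle$train$label) | bundle$train$label != "negative"
  pos <- bundle$train[is_pos, , drop = FALSE]
  neg <- bundle$train[!is_pos, , drop = FALSE]
  keep_n <- round(fraction * nrow(pos))
  if (keep_n < 1L) {
    cli::cli_abort("Subsampling would leave no positive training reaction.",
                   class = "rxnrl_error_empty_positives")
  }
  keep <- withr::with_seed(seed, sample.int(nrow(pos), keep_n))
  new_reaction_bundle(
    train = dplyr::bind_rows(pos[sort(keep), , drop = FALSE], neg),
    valid = bundle$valid, test = bundle$test,
    seed = seed, ratios = bundle$ratios
  )
}

#' @export
print.reaction_bundle <- function(x, ...) {
  g <- glance(x)
  cli::cli_text(
    "<reaction_bundle> train: {g$train_pos} pos / {g$train_neg} neg (ratio {signif(g$pos_neg_ratio, 3)}), valid: {g$valid_pos} pos, test: {g$test_pos} pos, seed {x$seed}"
  )
  invisible(x)
}

#' Tidy a reaction bundle into per-split label counts
#'
#' @param x A `reaction_bundle`.
#' @param ... Unused.
#' @return Tibble with columns `split`, `label`, `n`.
#' @exportS3Method generics::tidy
tidy.reaction_bundle <- function(x, ...) {
  purrr::map_dfr(c("train", "valid", "test"), function(s) {
    d <- x[[s]]
    lab <- ifelse(is.na(d$label), "positive", d$label)
    dplyr::count(tibble::tibble(split = s, label = lab), split, label,
                 name = "n")
  })
}

#' One-row summary of a reaction bundle
#'
#' @param x A `reaction_bundle`.
#' @param ... Unused.
#' @return One-row tibble: positive/negative counts per split, the train
#'   positive:negative ratio and the split seed.
#' @exportS3Method generics::glance
glance.reaction_bundle <- function(x, ...) {
  lab <- function(d) ifelse(is.na(d$label), "positive", d$label)
  tibble::tibble(
    train_pos = sum(lab(x$train) == "positive"),
    train_neg = sum(lab(x$train) == "negative"),
    pos_neg_ratio = pos_neg_ratio(x),
    valid_pos = sum(lab(x$valid) == "positive"),
    test_pos = sum(lab(x$test) == "positive"),
    seed = x$seed
  )
}
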