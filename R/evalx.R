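# Evaluation: top-k positive accuracy, invalid fraction, multi-seed
# summaries. Accuracy is measured on positive reactions only; a candidate
# matches when its canonical SMILES equals the canonical true product, so
# invalid candidates can never match.

#' Top-k positive accuracy
#'
#' Fraction of positive reactions whose true product appears among the
#' top-k beam-search candidates (candidates are canonicalized before
#' comparison; invalid candidates never match).
#'
#' @param policy A `seq2seq_policy`.
#' @param positives Reaction record tibble of positive reactions.
#' @param k Ranking depth (<= `beams`).
#' @param beams Beam width.
#' @return Accuracy in `[0, 1]`.
#' @export
topk_positive_accuracy <- function(policy, positives, k = 1L, beams = 10L) {
  report <- evaluate_policy(policy, positives, ks = k, beams = beams)
  report$topk_accuracy[report$k == k]
}

#' Evaluate a policy on positive reactions
#'
#' Beam-decodes every left-hand side once and reports top-k positive
#' accuracy and the invalid fraction at each requested depth. The invalid
#' fraction at depth k is the share of the k x n candidate slots whose
#' SMILES fails validation.
#'
#' @param policy A `seq2seq_policy`.
#' @param positives Reaction record tibble of positive reactions.
#' @param ks Ranking depths.
#' @param beams Beam width (>= max(ks)).
#' @return An `eval_report` tibble with columns `k`, `topk_accuracy`,
#'   `invalid_fraction`, `n_eval`; beam results attached as attribute
#'   `"decodes"`.
#' @export
evaluate_policy <- function(policy, positives, ks = c(1L, 2L), beams = 10L) {
  if (max(ks) > beams) {
    cli::cli_abort("k = {max(ks)} exceeds the beam width {beams}.",
                   class = "rxnrl_error_k_beams")
  }
  decodes <- lapply(positives$lhs, function(l) beam_decode(policy, l, beams = beams))
  all_cand <- unlist(lapply(decodes, function(d) d$smiles))
  canon <- canonicalize_or_na(all_cand)
  offs <- cumsum(c(0, vapply(decodes, nrow, numeric(1))))
  hit_rank <- vapply(seq_along(decodes), function(i) {
    ci <- canon[(offs[i] + 1):offs[i + 1]]
    h <- which(!is.na(ci) & ci == positives$product[i])
    if (length(h)) min(h) else Inf
  }, numeric(1))
  out <- tibble::tibble(
    k = as.integer(ks),
    topk_accuracy = vapply(ks, function(k) mean(hit_rank <= k), numeric(1)),
    invalid_fraction = vapply(ks, function(k) {
      invalid_fraction(decodes, k, .canon = canon, .offsets = offs)
    }, numeric(1)),
    n_eval = nrow(positives)
  )
  class(out) <- c("eval_report", class(out))
  attr(out, "decodes") <- decodes
  out
}

#' Fraction of invalid candidates at ranking depth k
#'
#' Denominated over candidate slots (k per input, across all inputs), not
#' per input: with n inputs there are k x n slots and the fraction counts
#' the slots whose SMILES does not parse.
#'
#' @param decode_results List of `decode_result` objects from
#'   [beam_decode()].
#' @param k Ranking depth.
#' @param .canon,.offsets Internal precomputed canonicalizations.
#' @return Fraction in `[0, 1]`.
#' @export
invalid_fraction <- function(decode_results, k = 1L, .canon = NULL,
                             .offsets = NULL) {
  if (is.null(.canon)) {
    all_cand <- unlist(lapply(decode_results, function(d) d$smiles))
    .canon <- canonicalize_or_na(all_cand)
    .offsets <- cumsum(c(0, vapply(decode_results, nrow, numeric(1))))
  }
  bad <- 0L
  total <- 0L
  for (i in seq_along(decode_results)) {
    nk <- min(k, nrow(decode_results[[i]]))
    ci <- .canon[.offsets[i] + seq_len(nk)]
    bad <- bad + sum(is.na(ci))
    total <- total + k
  }
  bad / total
}

#' Run an experiment across several seeds
#'
#' Repeats an experiment once per seed (each seed typically controls the
#' data split and any initialization inside `experiment_fn`) and reports
#' the per-seed metric breakdown together with mean and standard
#' deviation per metric. A failing seed is recorded, not fatal.
#'
#' @param experiment_fn Function of one integer seed returning a named
#'   numeric vector or one-row data frame of metrics.
#' @param seeds Integer vector of seeds (>= 2; the conventional protocol
#'   uses five).
#' @return List of class `multi_seed_report`: `per_seed` (tibble with a
#'   `seed` column), `summary` (tibble metric/mean/sd/n_seeds),
#'   `failures` (named list of error messages).
#' @export
multi_seed_report <- function(experiment_fn, seeds = 1:5) {
  stopifnot(length(seeds) >= 2L)
  rows <- list()
  failures <- list()
  for (s in seeds) {
    res <- tryCatch(experiment_fn(s), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(s)]] <- conditionMessage(res)
    } else {
      row <- tibble::as_tibble(as.list(unlist(res)))
      row$seed <- s
      rows[[length(rows) + 1L]] <- row
    }
  }
  per_seed <- dplyr::bind_rows(rows)
  metrics <- setdiff(names(per_seed), "seed")
  summary <- purrr::map_dfr(metrics, function(m) {
    tibble::tibble(
      metric = m,
      mean = mean(per_seed[[m]]),
      sd = stats::sd(per_seed[[m]]),
      n_seeds = nrow(per_seed)
    )
  })
  structure(
    list(per_seed = per_seed, summary = summary, failures = failures),
    class = "multi_seed_report"
  )
}

#' @export
print.multi_seed_report <- function(x, ...) {
  cli::cli_text("<multi_seed_report> {nrow(x$per_seed)} seed{?s}, {length(x$failures)} failure{?s}")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.multi_seed_report <- function(x, ...) x$per_seed

#' @exportS3Method generics::glance
glance.multi_seed_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$summary[c("metric", "mean")], names_from = "metric", values_from = "mean"
  )
  wide$n_seeds <- nrow(x$per_seed)
  wide$n_failures <- length(x$failures)
  wide
}

#' Per-seed metric breakdown plot
#'
#' @param object A `multi_seed_report`.
#' @param ... Unused.
#' @return A ggplot showing each metric per seed.
#' @exportS3Method ggplot2::autoplot
autoplot.multi_seed_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_seed, -dplyr::all_of("seed"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$seed), y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "seed", y = NULL)
}
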