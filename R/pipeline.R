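# Pipeline orchestration: staged execution with a config, artifact
# manifest and structured logs. Each stage is a thin wrapper over the
# package functions, so everything here is also reproducible
# interactively.

#' Default pipeline configuration
#'
#' @param seed Global seed (drives data generation and training).
#' @param out Output directory.
#' @return Nested configuration list (serializable as YAML).
#' @export
default_run_config <- function(seed = 1L, out = "rxnrl_run") {
  list(
    seed = as.integer(seed),
    out = out,
    toy = list(n_scaffolds = 850L, n_pretrain = 2400L, n_positive = 150L,
               target_neg_pos_ratio = 14),
    model = list(d = 48L, n_heads = 4L, ff = 96L, n_enc = 2L, n_dec = 2L),
    pretrain = list(epochs = 48L, lr = 1.5e-3),
    finetune = list(epochs = 16L, lr = 1.5e-3, subsample_fraction = 1 / 3),
    reward = list(tune_epochs = 4L, lr = 3e-4, cost = 1),
    rl = list(kl_coeff = 0.05, clip_eps = 0.2, rollout_lhs = 64L,
              samples_per_lhs = 2L, epochs = 8L, lr_policy = 1e-4,
              temperature = 1.0),
    evaluate = list(beams = 10L, ks = c(1L, 2L))
  )
}

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(default_run_config(), config)
}

artifact_path <- function(config, ...) file.path(config$out, ...)

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    cli::cli_abort(
      "Stage {.val {stage}} needs the artifact {.path {path}}; run the producing stage first.",
      class = "rxnrl_error_dependency", artifact = path
    )
  }
  path
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing: the serialized object carries its
#' vocabulary and architecture dimensions.
#'
#' @param object A policy, encoder, reward model or fit object.
#' @param path Destination file.
#' @return `path` (`save_checkpoint`) or the restored object
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(object, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

log_line <- function(config, stage, msg, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, message = msg), list(...))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = file.path(config$out, "log.jsonl"), append = TRUE)
}

#' Run the staged pipeline
#'
#' Executes the requested stages in dependency order on a configuration:
#' `generate` (toy datasets), `pretrain` (base model), `finetune` (MLE on
#' the regime positives), `reward` (reward model), `rl` (RL tuning) and
#' `evaluate` (test metrics for both tuned models). Writes a manifest
#' with inputs, outputs, seeds, a config hash and per-stage wall times.
#'
#' @param config Configuration list (see [default_run_config()]) or path
#'   to a YAML file.
#' @param stages Character subset of
#'   `c("generate", "pretrain", "finetune", "reward", "rl", "evaluate")`.
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("generate", "pretrain", "finetune",
                                    "reward", "rl", "evaluate")) {
  config <- read_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    stages = list()
  )
  spec <- toy_spec(
    n_scaffolds = config$toy$n_scaffolds, n_pretrain = config$toy$n_pretrain,
    n_positive = config$toy$n_positive,
    target_neg_pos_ratio = config$toy$target_neg_pos_ratio,
    seed = config$seed
  )
  timed <- function(stage, fn) {
    t0 <- Sys.time()
    res <- fn()
    dt <- as.numeric(Sys.time() - t0, units = "secs")
    manifest$stages[[stage]] <<- list(
      wall_time_s = round(dt, 2),
      outputs = res
    )
    log_line(config, stage, "done", wall_time_s = round(dt, 2))
    res
  }

  if ("generate" %in% stages) {
    timed("generate", function() {
      fam <- make_regio_family(spec)
      klow <- subsample_positives(fam, config$finetune$subsample_fraction,
                                  seed = config$seed)
      dir.create(artifact_path(config, "data"), showWarnings = FALSE,
                 recursive = TRUE)
      paths <- c(
        train = artifact_path(config, "data", "family_train.csv"),
        valid = artifact_path(config, "data", "family_valid.csv"),
        test = artifact_path(config, "data", "family_test.csv"),
        train_low = artifact_path(config, "data", "family_train_low.csv")
      )
      write_reactions(fam$train, paths[["train"]])
      write_reactions(fam$valid, paths[["valid"]])
      write_reactions(fam$test, paths[["test"]])
      write_reactions(klow$train, paths[["train_low"]])
      yaml::write_yaml(unclass(spec), artifact_path(config, "data", "toy_spec.yaml"))
      as.list(paths)
    })
  }

  if ("pretrain" %in% stages) {
    timed("pretrain", function() {
      base <- pretrain_base(
        spec, d = config$model$d, n_heads = config$model$n_heads,
        ff = config$model$ff, n_enc = config$model$n_enc,
        n_dec = config$model$n_dec,
        epochs = config$pretrain$epochs, lr = config$pretrain$lr
      )
      p <- artifact_path(config, "models", "base.rds")
      save_checkpoint(base, p)
      readr::write_csv(base$fit$history,
                       artifact_path(config, "models", "pretrain_history.csv"))
      list(base = p, pretrain_top1 = base$pretrain_top1)
    })
  }

  load_family <- function(stage) {
    train <- read_reactions(require_artifact(
      artifact_path(config, "data", "family_train_low.csv"), stage), quiet = TRUE)
    valid <- read_reactions(require_artifact(
      artifact_path(config, "data", "family_valid.csv"), stage), quiet = TRUE)
    test <- read_reactions(require_artifact(
      artifact_path(config, "data", "family_test.csv"), stage), quiet = TRUE)
    new_reaction_bundle(train, valid, test, config$seed, c(40, 30, 30))
  }

  if ("finetune" %in% stages) {
    timed("finetune", function() {
      base <- load_checkpoint(require_artifact(
        artifact_path(config, "models", "base.rds"), "finetune"))
      bundle <- load_family("finetune")
      fit <- train_mle(
        base$policy,
        bundle$train[bundle$train$label %in% "positive", , drop = FALSE],
        valid = bundle$valid,
        config = mle_config(epochs = config$finetune$epochs,
                            lr = config$finetune$lr, seed = config$seed)
      )
      p <- artifact_path(config, "models", "ft.rds")
      save_checkpoint(fit, p)
      readr::write_csv(fit$history,
                       artifact_path(config, "models", "ft_history.csv"))
      list(ft = p)
    })
  }

  if ("reward" %in% stages) {
    timed("reward", function() {
      base <- load_checkpoint(require_artifact(
        artifact_path(config, "models", "base.rds"), "reward"))
      bundle <- load_family("reward")
      rm <- fit_reward_model(bundle$train,
                             encoder = as_reaction_encoder(base$policy),
                             epochs = config$reward$tune_epochs,
                             lr = config$reward$lr, cost = config$reward$cost,
                             seed = config$seed)
      p <- artifact_path(config, "models", "reward.rds")
      save_checkpoint(rm, p)
      meta <- list(pooling = rm$encoder$pooling,
                   class_weights = as.list(rm$classifier$class_weights),
                   invalid_reward = rm$invalid_reward,
                   match_bonus = rm$match_bonus, binary = rm$binary)
      jsonlite::write_json(meta,
                           artifact_path(config, "models", "reward_meta.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      list(reward = p)
    })
  }

  if ("rl" %in% stages) {
    timed("rl", function() {
      base <- load_checkpoint(require_artifact(
        artifact_path(config, "models", "base.rds"), "rl"))
      rm <- load_checkpoint(require_artifact(
        artifact_path(config, "models", "reward.rds"), "rl"))
      start_policy <- base$policy
      ft_path <- artifact_path(config, "models", "ft.rds")
      if (file.exists(ft_path)) start_policy <- load_checkpoint(ft_path)$policy
      bundle <- load_family("rl")
      cfg <- rl_config(
        kl_coeff = config$rl$kl_coeff, clip_eps = config$rl$clip_eps,
        rollout_lhs = config$rl$rollout_lhs,
        minibatch = config$rl$rollout_lhs,
        samples_per_lhs = config$rl$samples_per_lhs,
        epochs = config$rl$epochs, lr_policy = config$rl$lr_policy,
        temperature = config$rl$temperature, seed = config$seed
      )
      fit <- train_rl(start_policy, bundle, rm, config = cfg,
                      anchor_data = base$corpus[base$corpus$slice == "train", ])
      p <- artifact_path(config, "models", "rl.rds")
      save_checkpoint(fit, p)
      readr::write_csv(fit$history,
                       artifact_path(config, "models", "rl_history.csv"))
      list(rl = p)
    })
  }

  if ("evaluate" %in% stages) {
    timed("evaluate", function() {
      bundle <- load_family("evaluate")
      rows <- list()
      for (m in c("ft", "rl")) {
        p <- artifact_path(config, "models", paste0(m, ".rds"))
        if (!file.exists(p)) next
        fit <- load_checkpoint(p)
        rep <- evaluate_policy(fit$policy, bundle$test,
                               ks = config$evaluate$ks,
                               beams = config$evaluate$beams)
        rep$model <- m
        rows[[m]] <- tibble::as_tibble(rep)
      }
      if (length(rows) == 0L) {
        cli::cli_abort(
          "Stage {.val evaluate} found no trained checkpoint (expected {.path {artifact_path(config, 'models', 'ft.rds')}} or {.path {artifact_path(config, 'models', 'rl.rds')}}).",
          class = "rxnrl_error_dependency",
          artifact = artifact_path(config, "models", "ft.rds")
        )
      }
      res <- dplyr::bind_rows(rows)
      pj <- artifact_path(config, "metrics.json")
      jsonlite::write_json(res, pj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
      readr::write_csv(res, artifact_path(config, "metrics.csv"))
      list(metrics = pj)
    })
  }

  jsonlite::write_json(manifest, artifact_path(config, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
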