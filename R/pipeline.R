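#' Default pipeline run configuration
#'
#' A nested list with a `paths` block (all file locations inside `out_dir`),
#' a `hyperparameters` block (defaults from [prd_hparams()], the model's
#' reference configuration), a `synthetic`
#' block ([synth_config()] defaults), an `extract` block and an
#' `evaluation` block (hold-out rate 0.3, Hits@{1,5,10}, fixed seeds so
#' runs are reproducible by default).
#'
#' @param out_dir Directory for all pipeline artifacts.
#' @return A nested configuration list.
#' @export
default_run_config <- function(out_dir = "prd_run") {
  list(
    paths = list(
      dir = out_dir,
      basic = file.path(out_dir, "basic_triples.tsv"),
      ddi = file.path(out_dir, "ddi_triples.tsv"),
      corpus = file.path(out_dir, "corpus.tsv"),
      vocabulary = file.path(out_dir, "vocabulary.txt"),
      aliases = file.path(out_dir, "aliases.tsv"),
      ddi_extracted = file.path(out_dir, "ddi_extracted.tsv"),
      checkpoint = file.path(out_dir, "model.rds"),
      split = file.path(out_dir, "split.rds"),
      trace = file.path(out_dir, "trace.tsv"),
      predictions = file.path(out_dir, "predictions.tsv"),
      metrics = file.path(out_dir, "metrics.json"),
      ranks = file.path(out_dir, "ranks.tsv"),
      roc = file.path(out_dir, "roc_points.tsv"),
      pr = file.path(out_dir, "pr_points.tsv"),
      manifest = file.path(out_dir, "manifest.json")
    ),
    hyperparameters = unclass(prd_hparams()),
    synthetic = unclass(synth_config()),
    extract = list(top_n = 5, use_extracted = FALSE),
    predict = list(drug_u = NULL, drug_v = NULL, top_n = 5),
    evaluation = list(rate = 0.3, ks = c(1, 5, 10), split_seed = 1L,
                      classifier_seed = 1L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the [default_run_config()] defaults;
#' everything else keeps its default.
#'
#' @param path YAML file path.
#' @param out_dir Default output directory when the file sets none.
#' @return A configuration list.
#' @export
read_run_config <- function(path, out_dir = "prd_run") {
  override <- yaml::read_yaml(path)
  cfg <- merge_config(default_run_config(out_dir), override)
  cfg
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

stage_error <- function(stage, msg) {
  abort_typed(paste0("stage '", stage, "': ", msg), "prddi_stage_error")
}

require_file <- function(stage, path, hint) {
  if (!file.exists(path)) {
    stage_error(stage, paste0("missing prerequisite ", hint, " (", path,
                              "); run the producing stage first"))
  }
}

#' Run the end-to-end prediction pipeline
#'
#' Executes an ordered subset of the stages `simulate` (write a synthetic
#' fixture directory), `extract` (TF-IDF label extraction from the
#' sentence corpus), `train` (build the KG, hold out DDI pairs, train the
#' joint model), `predict` (decode labels for a requested drug pair, or
#' for all held-out pairs) and `evaluate` (ranking metrics and binary
#' classification). Each stage writes its artifacts atomically; a manifest
#' records the configuration hash, seeds, package version and per-stage
#' timings. Re-running with the same configuration and seeds reproduces
#' identical outputs.
#'
#' @param config Configuration list (see [default_run_config()]) or a path
#'   to a YAML file.
#' @param stages Character vector, subset of
#'   `c("simulate", "extract", "train", "predict", "evaluate")`.
#' @param verbose Emit per-stage messages.
#' @return Invisibly, a list with the written artifact paths and in-memory
#'   results of the executed stages.
#' @export
run_prd_pipeline <- function(config = default_run_config(),
                             stages = c("simulate", "extract", "train",
                                        "predict", "evaluate"),
                             verbose = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  all_stages <- c("simulate", "extract", "train", "predict", "evaluate")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) {
    abort_typed(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
                "prddi_domain_error")
  }
  stages <- all_stages[all_stages %in% stages]
  if (length(stages) == 0) return(invisible(list(stages = character())))

  paths <- config$paths
  if (!dir.exists(paths$dir)) dir.create(paths$dir, recursive = TRUE)
  results <- list(stages = stages)
  timings <- list()
  note <- function(...) if (verbose) message(sprintf(...))

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    if (stage == "simulate") {
      synth_args <- config$synthetic[
        intersect(names(config$synthetic), names(formals(synth_config)))
      ]
      cfg <- do.call(synth_config, synth_args)
      results$simulate <- simulate_fixture_dir(cfg, paths$dir)
      note("simulate: wrote fixture to %s", paths$dir)
    } else if (stage == "extract") {
      require_file(stage, paths$corpus, "sentence corpus")
      corpus <- read_ddi_corpus(paths$corpus)
      aliases <- if (file.exists(paths$aliases)) {
        read_alias_table(paths$aliases)
      } else NULL
      vocab <- if (file.exists(paths$vocabulary)) {
        read_label_vocabulary(paths$vocabulary)
      } else NULL
      ex <- extract_ddi_triples(corpus, n = config$extract$top_n,
                                aliases = aliases, vocabulary = vocab)
      write_atomic(function(p) write_ddi_triples(ex$ddi, p),
                   paths$ddi_extracted)
      if (is.null(vocab)) {
        write_atomic(function(p) write_label_vocabulary(ex$vocabulary, p),
                     paths$vocabulary)
      }
      results$extract <- ex
      note("extract: %d DDI records, %d labels", nrow(ex$ddi),
           length(ex$vocabulary))
    } else if (stage == "train") {
      require_file(stage, paths$basic, "basic triple file")
      ddi_path <- if (isTRUE(config$extract$use_extracted)) {
        paths$ddi_extracted
      } else {
        paths$ddi
      }
      require_file(stage, ddi_path, "DDI triple file")
      require_file(stage, paths$vocabulary, "label vocabulary")
      basic <- read_basic_triples(paths$basic)
      ddi <- read_ddi_triples(ddi_path)
      vocab <- read_label_vocabulary(paths$vocabulary)
      kg <- build_kg(basic, ddi, vocabulary = vocab)
      hp <- do.call(prd_hparams, config$hyperparameters)
      split <- split_ddi(kg, rate = config$evaluation$rate,
                         seed = config$evaluation$split_seed)
      model <- prd_train(split$train_kg, hp, verbose = verbose)
      write_atomic(function(p) save_prd_model(model, p), paths$checkpoint)
      write_atomic(function(p) saveRDS(split, p), paths$split)
      write_atomic(function(p) {
        readr::write_tsv(model$trace, p, progress = FALSE)
      }, paths$trace)
      results$train <- list(model = model, split = split)
      note("train: final objective %.3f",
           utils::tail(model$trace$objective, 1))
    } else if (stage == "predict") {
      require_file(stage, paths$checkpoint, "model checkpoint")
      model <- results$train$model %||% load_prd_model(paths$checkpoint)
      pc <- config$predict
      if (!is.null(pc$drug_u) && !is.null(pc$drug_v)) {
        preds <- predict_ddi_labels(model, pc$drug_u, pc$drug_v,
                                    top_n = pc$top_n)
        preds <- dplyr::mutate(preds, drug_u = pc$drug_u,
                               drug_v = pc$drug_v, .before = "label")
      } else {
        require_file(stage, paths$split, "evaluation split")
        split <- results$train$split %||% readRDS(paths$split)
        pairs <- ddi_pairs_of(split$test_positives)
        preds <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
          dplyr::mutate(
            predict_ddi_labels(model, pairs$drug_u[i], pairs$drug_v[i],
                               top_n = pc$top_n),
            drug_u = pairs$drug_u[i], drug_v = pairs$drug_v[i],
            .before = "label"
          )
        })
      }
      write_atomic(function(p) readr::write_tsv(preds, p, progress = FALSE),
                   paths$predictions)
      results$predict <- preds
      note("predict: wrote %d label predictions", nrow(preds))
    } else if (stage == "evaluate") {
      require_file(stage, paths$checkpoint, "model checkpoint")
      require_file(stage, paths$split, "evaluation split")
      model <- results$train$model %||% load_prd_model(paths$checkpoint)
      split <- results$train$split %||% readRDS(paths$split)
      ev <- evaluate_model(model, split, ks = config$evaluation$ks,
                           classifier_seed = config$evaluation$classifier_seed)
      metrics <- list(
        mean_rank = list(
          raw = report_metric(ev$report, "mean_rank", "raw"),
          filtered = report_metric(ev$report, "mean_rank", "filtered")
        ),
        hits_at = lapply(
          stats::setNames(config$evaluation$ks, config$evaluation$ks),
          function(k) list(
            raw = report_metric(ev$report, paste0("hits_at_", k), "raw"),
            filtered = report_metric(ev$report, paste0("hits_at_", k),
                                     "filtered")
          )
        ),
        binary = list(auroc = ev$binary$auroc, aupr = ev$binary$aupr)
      )
      write_atomic(function(p) {
        jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA)
      }, paths$metrics)
      write_atomic(function(p) readr::write_tsv(ev$ranks, p, progress = FALSE),
                   paths$ranks)
      write_atomic(function(p) {
        readr::write_tsv(ev$binary$roc, p, progress = FALSE)
      }, paths$roc)
      write_atomic(function(p) {
        readr::write_tsv(ev$binary$pr, p, progress = FALSE)
      }, paths$pr)
      results$evaluate <- ev
      note("evaluate: filtered Hits@5 = %.2f, AUROC = %.3f",
           report_metric(ev$report, "hits_at_5", "filtered"),
           ev$binary$auroc)
    }
    timings[[stage]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("prddi")),
    r_version = as.character(getRversion()),
    config_hash = rlang::hash(config),
    seeds = list(
      hyperparameters = config$hyperparameters$seed,
      synthetic = config$synthetic$seed,
      split = config$evaluation$split_seed,
      classifier = config$evaluation$classifier_seed
    ),
    stages = stages,
    timings_seconds = timings
  )
  write_atomic(function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }, paths$manifest)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
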