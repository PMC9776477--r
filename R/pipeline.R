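#' Configure an end-to-end pipeline run
#'
#' Bundles every stage's settings: median-filter preprocessing, optional
#' hyperparameter tuning by improved bald eagle search, synergic ensemble
#' training, LSTM head training over the ensemble's feature sequences, and
#' evaluation on the held-out test split.
#'
#' @param data manifest tibble with an `image` list-column plus `subclass`
#'   and `superclass` columns (e.g. from [generate_dataset()]); or `NULL`
#'   with `manifest_path` pointing at a `path,subclass,superclass` CSV.
#' @param manifest_path manifest CSV path (used when `data` is `NULL`).
#' @param mode `"subclass"` (all subclasses) or `"binary"` (superclass
#'   labels); fixes K for every downstream stage.
#' @param kernel median-filter kernel size (odd).
#' @param sdl an [sdl_config()]; `num_classes`/`input_shape` are overridden
#'   to match the data.
#' @param tune run hyperparameter tuning before the final fit.
#' @param tune_space [search_space_spec()] for tuning (default: `lambda`
#'   linear in `[0, 1]`, `lr` log10 in `[-2, -0.5]`).
#' @param tune_params [bes_params()] tuning budget.
#' @param tune_epochs reduced epoch count for the proxy fits inside the
#'   tuning fitness (the winning configuration is retrained at full
#'   epochs).
#' @param tune_folds stratified CV folds inside the fitness.
#' @param obl OBL schedule for the tuner (`"off"` ablates to plain BES).
#' @param lstm_hidden,lstm_lr,lstm_epochs,lstm_loss LSTM head settings.
#' @param split train/val/test proportions (named, summing to 1).
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir optional run directory for artifacts (checkpoint,
#'   predictions CSV, metrics JSON, confusion CSV, JSON-lines log).
#' @param verbose print stage progress.
#' @return a `run_config` list.
#' @export
run_config <- function(data = NULL, manifest_path = NULL,
                       mode = c("subclass", "binary"), kernel = 3L,
                       sdl = sdl_config(), tune = FALSE,
                       tune_space = NULL, tune_params = NULL,
                       tune_epochs = 3L, tune_folds = 2L,
                       obl = "per-candidate",
                       lstm_hidden = 16L, lstm_lr = 0.5,
                       lstm_epochs = 80L, lstm_loss = "squared",
                       split = c(train = 0.7, val = 0.15, test = 0.15),
                       seed = 1L, out_dir = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.null(data) && is.null(manifest_path))
    stopf("supply `data` or `manifest_path`")
  if (is.null(tune_space))
    tune_space <- search_space_spec(c("lambda", "lr"), lb = c(0, -2),
                                    ub = c(1, -0.5),
                                    scale = c("linear", "log10"))
  if (is.null(tune_params))
    tune_params <- bes_params(n_pop = 4L, max_iter = 2L, seed = seed)
  structure(list(data = data, manifest_path = manifest_path, mode = mode,
                 kernel = as.integer(kernel), sdl = sdl, tune = tune,
                 tune_space = tune_space, tune_params = tune_params,
                 tune_epochs = as.integer(tune_epochs),
                 tune_folds = as.integer(tune_folds), obl = obl,
                 lstm_hidden = as.integer(lstm_hidden), lstm_lr = lstm_lr,
                 lstm_epochs = as.integer(lstm_epochs),
                 lstm_loss = lstm_loss, split = split,
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = verbose),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes, in order: manifest loading, median-filter preprocessing,
#' stratified splitting, optional hyperparameter tuning (improved bald
#' eagle search over reduced-epoch proxy fits), synergic ensemble training,
#' feature-sequence extraction, LSTM head training, and evaluation on the
#' test split. Every stage is seeded from the master seed, so a rerun with
#' the same config reproduces identical predictions and metrics.
#'
#' @param cfg a [run_config()].
#' @return a `pipeline_run`: `metrics` ([compute_metrics()] report on the
#'   test split), `predictions` tibble (`path`, `label`, `.pred_class`,
#'   score columns), `sdl_fit`, `lstm_fit`, `tuning` (a `tune_result` or
#'   `NULL`), `log` tibble, and `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- list()
  note <- function(stage, ...) {
    msg <- sprintf(...)
    if (cfg$verbose) message("[", stage, "] ", msg)
    log[[length(log) + 1L]] <<- tibble::tibble(stage = stage, detail = msg)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)))
  }

  data <- run_stage("load", {
    d <- cfg$data %||% read_manifest(cfg$manifest_path)
    stopifnot(all(c("image", "subclass", "superclass") %in% names(d)))
    d
  })
  label_col <- if (cfg$mode == "binary") "superclass" else "subclass"
  if (!is.null(data$path)) data <- dplyr::arrange(data, .data$path)
  data$label <- factor(data[[label_col]],
                       levels = sort(unique(data[[label_col]])))
  note("load", "%d images, %d classes (mode = %s)",
       nrow(data), nlevels(data$label), cfg$mode)

  data <- run_stage("preprocess", {
    data$image <- lapply(data$image, median_filter, size = cfg$kernel)
    data
  })
  note("preprocess", "median filter, kernel %d", cfg$kernel)

  data <- run_stage("split",
                    split_dataset(data, cfg$split,
                                  seed = derive_seed(cfg$seed, 11L)))
  train <- data[data$split == "train", ]
  test <- data[data$split == "test", ]
  note("split", "train %d / val %d / test %d", sum(data$split == "train"),
       sum(data$split == "val"), sum(data$split == "test"))

  img_dim <- dim(data$image[[1]])
  sdl_cfg <- cfg$sdl
  sdl_cfg$num_classes <- nlevels(data$label)
  sdl_cfg$input_shape <- as.integer(img_dim)
  sdl_cfg$seed <- derive_seed(cfg$seed, 21L)

  tuning <- NULL
  if (cfg$tune) {
    tuning <- run_stage("tune", {
      proxy <- sdl_cfg
      proxy$epochs <- cfg$tune_epochs
      tune_hyperparameters(train, cfg$tune_space, cfg$tune_params,
                           base_config = proxy, folds = cfg$tune_folds,
                           obl = cfg$obl)
    })
    for (nm in names(tuning$best_params))
      sdl_cfg[[nm]] <- tuning$best_params[[nm]]
    if (!is.function(sdl_cfg$lr_schedule) && !is.null(sdl_cfg$lr)) {
      lr <- sdl_cfg$lr
      sdl_cfg$lr_schedule <- function(z) lr
    }
    if ("lr" %in% names(tuning$best_params)) {
      lr <- tuning$best_params$lr
      sdl_cfg$lr_schedule <- function(z) lr
    }
    note("tune", "best fitness %.3f at %s", tuning$best_fitness,
         paste(names(tuning$best_params),
               signif(unlist(tuning$best_params), 4),
               sep = "=", collapse = ", "))
  }

  sdl_fit <- run_stage("sdl_train", sdl_train(train, sdl_cfg))
  note("sdl_train", "final ce %.4f, synergic %.4f",
       utils::tail(sdl_fit$trace$ce_loss, 1),
       utils::tail(sdl_fit$trace$synergic_loss, 1))

  train_feats <- run_stage("features", sdl_extract_features(sdl_fit, train))
  train_feats$label <- train$label
  test_feats <- sdl_extract_features(sdl_fit, test)
  note("features", "k = %d feature vectors of length %d per image",
       sdl_cfg$k, sdl_cfg$feature_dim)

  lstm_fit <- run_stage("lstm_train",
    lstm_train(train_feats, hidden_size = cfg$lstm_hidden, lr = cfg$lstm_lr,
               epochs = cfg$lstm_epochs, loss = cfg$lstm_loss,
               seed = derive_seed(cfg$seed, 31L)))
  note("lstm_train", "final loss %.5f", utils::tail(lstm_fit$trace$loss, 1))

  predictions <- run_stage("evaluate", {
    pred <- lstm_predict(lstm_fit, test_feats)
    dplyr::bind_cols(tibble::tibble(path = test$path, label = test$label),
                     pred)
  })
  metrics <- evaluate_predictions(predictions,
                                  class_names = levels(data$label))
  note("evaluate", "macro accuracy %.2f, macro recall %.2f",
       metrics$macro$accuracy, metrics$macro$recall)

  run <- structure(list(metrics = metrics, predictions = predictions,
                        sdl_fit = sdl_fit, lstm_fit = lstm_fit,
                        tuning = tuning, log = dplyr::bind_rows(log),
                        config = cfg),
                   class = "pipeline_run")
  if (!is.null(cfg$out_dir)) write_run_artifacts(run, cfg$out_dir)
  run
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_checkpoint(list(sdl_fit = run$sdl_fit, lstm_fit = run$lstm_fit,
                       config = run$config),
                  file.path(out_dir, "checkpoint.rds"))
  readr::write_csv(run$predictions, file.path(out_dir, "predictions.csv"))
  jsonlite::write_json(
    list(per_class = run$metrics$per_class, macro = run$metrics$macro),
    file.path(out_dir, "metrics.json"), dataframe = "rows", digits = NA)
  utils::write.csv(as.data.frame(unclass(run$metrics$confusion)),
                   file.path(out_dir, "confusion.csv"))
  writeLines(
    vapply(seq_len(nrow(run$log)), function(i)
      jsonlite::toJSON(as.list(run$log[i, ]), auto_unbox = TRUE),
      character(1)),
    file.path(out_dir, "log.jsonl"))
  if (!is.null(run$tuning))
    readr::write_csv(run$tuning$report,
                     file.path(out_dir, "tuning_report.csv"))
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  cat(sprintf("  test samples: %d, classes: %d\n",
              nrow(x$predictions), nrow(x$metrics$per_class)))
  cat(sprintf("  macro accuracy %.2f | precision %.2f | recall %.2f\n",
              x$metrics$macro$accuracy, x$metrics$macro$precision,
              x$metrics$macro$recall))
  invisible(x)
}
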