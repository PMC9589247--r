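#' Validated run configuration
#'
#' Builds the configuration object the pipeline commands consume, from a
#' named list or a YAML/JSON file. Unknown keys are an error — typos never
#' silently fall back to defaults.
#'
#' @param config A named list, or a path to a YAML/JSON file with the same
#'   structure. Recognized top-level keys: `seed`, `encoders` (list of
#'   `{name, k|kgap|lag}`), `selection` (`strategy`, `n_select`, `methods`,
#'   `damping`, `block_size`, `patience`, `max_features`), `model` (fields of
#'   [cnn_config()]), `threshold`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  known <- c("seed", "encoders", "selection", "model", "threshold")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "dbpkit_config_error")
  }
  seed <- as.integer(config$seed %||% 1L)

  enc_specs <- config$encoders %||% list(list(name = "monodikgap", kgap = 2),
                                         list(name = "kmer", k = 2))
  encoders <- map(enc_specs, function(e) {
    extra <- setdiff(names(e), c("name", "k", "kgap", "lag", "profiles"))
    if (length(extra)) {
      abort(sprintf("unknown encoder key(s): %s", paste(extra, collapse = ", ")),
            class = "dbpkit_config_error")
    }
    switch(e$name %||% "",
      kmer = encoder_kmer(e$k %||% 2),
      monodikgap = encoder_monodikgap(e$kgap %||% 2),
      ccpssm = encoder_ccpssm(e$lag %||% 2, profiles = e$profiles),
      abort(sprintf("unknown encoder name '%s'", e$name %||% "<missing>"),
            class = "dbpkit_config_error")
    )
  })

  sel <- config$selection %||% list()
  sel_known <- c("strategy", "n_select", "methods", "damping", "block_size",
                 "patience", "max_features", "n_rounds")
  sel_unknown <- setdiff(names(sel), sel_known)
  if (length(sel_unknown)) {
    abort(sprintf("unknown selection key(s): %s",
                  paste(sel_unknown, collapse = ", ")),
          class = "dbpkit_config_error")
  }
  selection <- list(
    strategy = match.arg(sel$strategy %||% "ensemble", c("ensemble", "adaboost")),
    n_select = as.integer(sel$n_select %||% 441L),
    methods = sel$methods %||% c("anova_f", "mutual_info", "lasso", "mrmr"),
    damping = sel$damping %||% 0.85,
    block_size = as.integer(sel$block_size %||% 10L),
    patience = sel$patience %||% 3,
    max_features = sel$max_features,
    n_rounds = as.integer(sel$n_rounds %||% 100L)
  )

  mod <- config$model %||% list()
  mod_known <- setdiff(names(formals(cnn_config)), "seed")
  mod_unknown <- setdiff(names(mod), mod_known)
  if (length(mod_unknown)) {
    abort(sprintf("unknown model key(s): %s", paste(mod_unknown, collapse = ", ")),
          class = "dbpkit_config_error")
  }
  model <- do.call(cnn_config, c(mod, list(seed = seed)))

  structure(list(seed = seed, encoders = encoders, selection = selection,
                 model = model, threshold = config$threshold %||% 0.5),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> seed %d, %d encoder(s), %s selection, threshold %.2f\n",
              x$seed, length(x$encoders), x$selection$strategy, x$threshold))
  invisible(x)
}

write_manifest <- function(out_dir, command, inputs, seed, extra = list()) {
  hashes <- map(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  })
  manifest <- c(list(
    command = command,
    package_version = as.character(packageVersion("dbpkit")),
    seed = seed,
    inputs = hashes
  ), extra)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Pipeline commands
#'
#' One exported function per pipeline stage, mirroring the shell front-end in
#' `inst/cli/dbpkit.R`; each writes its artifact plus a JSON manifest
#' (input hashes, seed, package version) into `out_dir`.
#'
#' @param spec A [sim_spec()] (for `cmd_simulate`).
#' @param out_dir Output directory, created if missing.
#' @param with_pssms Whether `cmd_simulate` also writes synthetic PSSMs.
#' @return Each command invisibly returns the paths (or objects) it produced.
#' @name pipeline_commands
NULL

#' @rdname pipeline_commands
#' @export
cmd_simulate <- function(spec, out_dir, with_pssms = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_dataset(spec)
  fasta <- file.path(out_dir, "sequences.fasta")
  labels <- file.path(out_dir, "labels.tsv")
  write_fasta(ds, fasta)
  write_labels(ds, labels)
  pssm_manifest <- NULL
  if (with_pssms) {
    profiles <- generate_pssms(ds, spec)
    pssm_manifest <- write_pssm_set(profiles, file.path(out_dir, "pssm"))
  }
  write_manifest(out_dir, "simulate", list(), spec$seed,
                 extra = list(n_pos = spec$n_pos, n_neg = spec$n_neg,
                              length_range = spec$length_range))
  invisible(list(fasta = fasta, labels = labels, pssm_manifest = pssm_manifest,
                 dataset = ds))
}

#' @rdname pipeline_commands
#' @param fasta,labels Paths to the sequence FASTA and label TSV.
#' @param config A [run_config()] (or anything `run_config()` accepts).
#' @export
cmd_encode <- function(fasta, labels, config = run_config(), out_dir) {
  config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- read_fasta(fasta)
  flt <- filter_standard(records)
  ds <- read_labels(labels, flt$kept)
  X <- encode_matrix(ds, config$encoders)
  matrix_path <- file.path(out_dir, "features.tsv")
  write_feature_matrix(X, matrix_path)
  write_labels(ds, file.path(out_dir, "labels.tsv"))
  write_manifest(out_dir, "encode", list(fasta = fasta, labels = labels),
                 config$seed,
                 extra = list(n_removed = length(flt$removed),
                              removed = flt$removed,
                              n_features = ncol(X)))
  invisible(list(matrix = matrix_path, X = X, dataset = ds))
}

#' @rdname pipeline_commands
#' @param matrix_path Path to a feature-matrix TSV from `cmd_encode`.
#' @export
cmd_select <- function(matrix_path, labels, config = run_config(), out_dir) {
  config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  X <- read_feature_matrix(matrix_path)
  y <- read_label_vector(labels, rownames(X))
  sel <- config$selection
  if (sel$strategy == "adaboost") {
    ranked <- adaboost_rank(X, y, n_select = min(sel$n_select, ncol(X)),
                            n_rounds = sel$n_rounds, seed = config$seed)
    features <- selected_features(ranked)
  } else {
    res <- ensemble_select(X, y, methods = sel$methods, damping = sel$damping,
                           block_size = sel$block_size, patience = sel$patience,
                           max_features = sel$max_features %||% ncol(X),
                           seed = config$seed)
    ranked <- res$ranking
    features <- res$features
  }
  reduced <- X[, features, drop = FALSE]
  reduced_path <- file.path(out_dir, "features_selected.tsv")
  write_feature_matrix(reduced, reduced_path)
  ranking_path <- file.path(out_dir, "ranking.tsv")
  utils::write.table(tidy(ranked), ranking_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "select",
                 list(matrix = matrix_path, labels = labels), config$seed,
                 extra = list(strategy = sel$strategy,
                              n_selected = length(features)))
  invisible(list(matrix = reduced_path, ranking = ranking_path,
                 ranked = ranked, features = features))
}

#' @rdname pipeline_commands
#' @export
cmd_train <- function(matrix_path, labels, config = run_config(), out_dir) {
  config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  X <- read_feature_matrix(matrix_path)
  y <- read_label_vector(labels, rownames(X))
  model <- train_cnn(X, y, config$model)
  bundle <- file.path(out_dir, "model")
  save_model(model, bundle)
  utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "train",
                 list(matrix = matrix_path, labels = labels), config$seed)
  invisible(list(bundle = bundle, model = model))
}

#' @rdname pipeline_commands
#' @param model_dir Path to a saved model bundle.
#' @export
cmd_evaluate <- function(model_dir, matrix_path, labels,
                         config = run_config(), out_dir) {
  config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- load_model(model_dir)
  X <- read_feature_matrix(matrix_path)
  y <- read_label_vector(labels, rownames(X))
  probs <- predict_proba(model, X)
  report <- evaluate_scores(y, probs$prob_1, threshold = config$threshold)
  write_metrics(report, file.path(out_dir, "metrics.json"),
                y_true = y, y_score = probs$prob_1)
  write_manifest(out_dir, "evaluate",
                 list(model = file.path(model_dir, "weights.rds"),
                      matrix = matrix_path, labels = labels), config$seed)
  invisible(list(report = report, probs = probs))
}

#' @rdname pipeline_commands
#' @param pssm_manifest Optional PSSM manifest TSV when the model was trained
#'   with CC-PSSM features.
#' @export
cmd_predict <- function(model_dir, fasta, config = run_config(),
                        pssm_manifest = NULL, out_dir) {
  config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- load_model(model_dir)
  records <- filter_standard(read_fasta(fasta))$kept
  encoders <- config$encoders
  if (!is.null(pssm_manifest)) {
    encoders <- map(encoders, function(e) {
      if (e$name == "ccpssm" && is.null(e$profiles)) {
        encoder_ccpssm(e$params$lag, profiles = pssm_manifest)
      } else e
    })
  }
  X <- encode_matrix(records, encoders)
  X <- X[, model$vocabulary, drop = FALSE]
  probs <- predict_proba(model, X)
  probs$class <- as.integer(probs$prob_1 >= config$threshold)
  pred_path <- file.path(out_dir, "predictions.tsv")
  utils::write.table(probs, pred_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_manifest(out_dir, "predict", list(fasta = fasta), config$seed)
  invisible(list(predictions = pred_path, probs = probs))
}

#' Run the full pipeline on one dataset
#'
#' Chains encode, select, train and evaluate in one call — the composition
#' of the staged commands. A stratified test split (`test_fraction`) is set
#' aside *before* feature selection, so the reported metrics are free of
#' selection bias; selection and the CNN (with its own internal
#' train/validation split) see only the remaining samples.
#'
#' @param dataset A labeled dataset tibble (`id`, `sequence`, `label`).
#' @param config A [run_config()] or compatible list.
#' @param out_dir Optional directory for artifacts; a temporary directory is
#'   used when omitted.
#' @param test_fraction Fraction of samples held out untouched for the final
#'   evaluation. Set to 0 to disable (metrics then fall back to the model's
#'   internal validation split, which selection has seen).
#' @return A list with the trained `model`, the `ranking`, the selected
#'   `features`, the evaluation `report` on the held-out test split and
#'   `probs`.
#' @export
run_pipeline <- function(dataset, config = run_config(), out_dir = NULL,
                         test_fraction = 0.2) {
  config <- as_run_config(config)
  stopifnot(all(c("id", "sequence", "label") %in% names(dataset)),
            test_fraction >= 0, test_fraction < 1)
  X_all <- encode_matrix(dataset, config$encoders)
  y_all <- dataset$label
  if (test_fraction > 0) {
    set.seed(config$seed)
    holdout <- stratified_split_idx(y_all, 1 - test_fraction)
    X <- X_all[holdout$train, , drop = FALSE]
    y <- y_all[holdout$train]
    X_test <- X_all[holdout$val, , drop = FALSE]
    y_test <- y_all[holdout$val]
  } else {
    X <- X_all
    y <- y_all
  }
  sel <- config$selection
  if (sel$strategy == "adaboost") {
    ranked <- adaboost_rank(X, y, n_select = min(sel$n_select, ncol(X)),
                            n_rounds = sel$n_rounds, seed = config$seed)
    features <- selected_features(ranked)
  } else {
    res <- ensemble_select(X, y, methods = sel$methods, damping = sel$damping,
                           block_size = sel$block_size, patience = sel$patience,
                           max_features = sel$max_features %||% ncol(X),
                           seed = config$seed)
    ranked <- res$ranking
    features <- res$features
  }
  Xsel <- X[, features, drop = FALSE]
  model <- train_cnn(Xsel, y, config$model)
  if (test_fraction > 0) {
    Xev <- X_test[, features, drop = FALSE]
    yev <- y_test
  } else {
    Xev <- Xsel[model$split$val, , drop = FALSE]
    yev <- y[model$split$val]
  }
  probs <- predict_proba(model, Xev)
  report <- evaluate_scores(yev, probs$prob_1, threshold = config$threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(model, file.path(out_dir, "model"))
    write_metrics(report, file.path(out_dir, "metrics.json"),
                  y_true = yev, y_score = probs$prob_1)
    utils::write.table(tidy(ranked), file.path(out_dir, "ranking.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_manifest(out_dir, "pipeline", list(), config$seed,
                   extra = list(n_selected = length(features)))
  }
  list(model = model, ranking = ranked, features = features,
       report = report, probs = probs)
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) config else run_config(config)
}

read_label_vector <- function(labels_path, ids) {
  records <- tibble(id = ids, sequence = "X")  # sequence unused here
  lines <- read_input_lines(labels_path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lab_ids <- vapply(parts, `[[`, character(1), 1)
  lab <- as.integer(vapply(parts, `[[`, character(1), 2))
  if (!all(ids %in% lab_ids)) {
    abort(sprintf("rows without a label: %s",
                  paste(setdiff(ids, lab_ids), collapse = ", ")),
          class = "dbpkit_alignment_error")
  }
  if (!all(lab %in% c(0L, 1L))) {
    abort("labels must be 0/1", class = "dbpkit_value_error")
  }
  lab[match(ids, lab_ids)]
}
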