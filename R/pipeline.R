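# End-to-end pipeline: multi-source encoding + selection, semantic
# embedding, sequence network, fused-feature voting ensemble; plus the
# config-file driven runner behind the command-line interface.

#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the full model.  The `"desk"`
#' preset (default) keeps the published architecture — selected feature
#' block + transformer embeddings + conv(3,32)/conv(3,16)/BiLSTM(16) +
#' SVM/RF/cascade vote — at sizes that train in seconds per fold; the
#' `"reference"` preset raises the embedder, network schedule and cascade to
#' the reference combinations.
#'
#' @param preset `"desk"` or `"reference"`.
#' @param ... Named overrides of top-level fields (`pgkm`, `pseknc`,
#'   `use_npcp`, `selector`, `embedder`, `seqnet`, `ensemble`); list values
#'   are merged field-wise into the preset.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("desk", "reference"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    pgkm = list(gap_max = 5L, tuple_pairs = NULL),
    pseknc = list(k_max = 3L),
    use_npcp = TRUE,
    selector = list(n_estimators = 100L, max_depth = 1L),
    embedder = list(backend = "onehot", k = 3L, n_layers = 1L,
                    n_heads = 2L, model_dim = 16L, mask_fraction = 0.15,
                    epochs = 1L, lr = 1e-3, path = NULL),
    seqnet = list(kernel_widths = c(3L, 3L), filters = c(32L, 16L),
                  lstm_units = 16L, attention_dim = 16L, epochs = 10L,
                  patience = 3L, batch_size = 128L, lr = 1e-2,
                  weight_decay = 5e-3, val_fraction = 0.15),
    ensemble = list(preset = "desk", svm = list(), random_forest = list(),
                    cascade_forest = list())
  )
  if (preset == "reference") {
    cfg$embedder <- utils::modifyList(cfg$embedder, list(
      backend = "transformer", n_layers = 2L, n_heads = 4L, model_dim = 32L,
      epochs = 5L))
    cfg$seqnet <- utils::modifyList(cfg$seqnet, list(
      epochs = 100L, patience = 5L, batch_size = 32L, lr = 1e-3,
      weight_decay = 1e-3))
    cfg$ensemble$preset <- "reference"
  }
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) {
    stop_enfusion("unknown pipeline_config field(s): ",
                  paste(bad, collapse = ", "))
  }
  for (nm in names(overrides)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      bad2 <- setdiff(names(overrides[[nm]]), names(cfg[[nm]]))
      if (length(bad2)) {
        stop_enfusion("unknown ", nm, " field(s): ",
                      paste(bad2, collapse = ", "))
      }
      utils::modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      overrides[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

build_embedder <- function(dataset, ecfg, seed) {
  switch(
    ecfg$backend,
    transformer = train_toy_embedder(
      dataset, k = ecfg$k, n_layers = ecfg$n_layers, n_heads = ecfg$n_heads,
      model_dim = ecfg$model_dim, mask_fraction = ecfg$mask_fraction,
      epochs = ecfg$epochs, lr = ecfg$lr, seed = seed),
    onehot = onehot_embedder(k = ecfg$k),
    import = import_embedder(ecfg$path, k = ecfg$k),
    stop_enfusion("unknown embedder backend: ", ecfg$backend)
  )
}

#' Train the full stacked-fusion pipeline
#'
#' Runs the stages in order: multi-source encoding, boosted-tree feature
#' selection, semantic embedding, sequence-network training and refined
#' dynamic feature extraction, feature fusion with standardization, and
#' the three-member voting ensemble.
#'
#' @param dataset A labelled [seq_dataset()] with both classes present.
#' @param config A [pipeline_config()].
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it.
#' @return An `enfusion_model` usable with [predict.enfusion_model()],
#'   [save_model()] and [occlusion_contribution()].
#' @export
train_pipeline <- function(dataset, config = pipeline_config(), seed = 1L) {
  stopifnot(inherits(dataset, "seq_dataset"), inherits(config, "pipeline_config"))
  if (is.null(dataset$label)) stop_enfusion("dataset must be labelled")
  y <- dataset$label
  if (length(unique(y)) < 2L) stop_enfusion("both classes must be present")

  pg <- pgkm_config(config$pgkm$gap_max, config$pgkm$tuple_pairs)
  pk <- pseknc_config(config$pseknc$k_max)
  X_ms <- encode_multisource(dataset, pg, pk, config$use_npcp)
  selector <- fit_selector(X_ms, y,
                           n_estimators = config$selector$n_estimators,
                           max_depth = config$selector$max_depth,
                           seed = derive_seed(seed, "selector"))
  X_sel <- apply_selector(selector, X_ms)

  embedder <- build_embedder(dataset, config$embedder,
                             derive_seed(seed, "embedder"))
  emb <- embed_dataset(dataset, embedder)
  scfg <- do.call(seqnet_config,
                  c(config$seqnet, list(seed = derive_seed(seed, "seqnet"))))
  seqnet <- train_seqnet(emb, y, scfg)
  refined <- extract_refined_features(seqnet, emb)

  fused <- fuse_features(X_sel, refined)
  ecfg <- ensemble_config(config$ensemble$preset,
                          svm = config$ensemble$svm,
                          random_forest = config$ensemble$random_forest,
                          cascade_forest = config$ensemble$cascade_forest,
                          seed = derive_seed(seed, "ensemble"))
  ensemble <- train_ensemble(fused, y, ecfg)

  structure(list(
    selector = selector, embedder = embedder, seqnet = seqnet,
    ensemble = ensemble, config = config, seed = as.integer(seed),
    feature_names = colnames(X_ms)
  ), class = "enfusion_model")
}

#' @export
print.enfusion_model <- function(x, ...) {
  cat("<enfusion_model> ", length(x$selector$selected_indices),
      " selected multi-source features + ",
      x$seqnet$refined_dim %||% "?", " dynamic features; ",
      "3-member hard-voting ensemble\n", sep = "")
  invisible(x)
}

#' Predict enhancer labels with a fitted pipeline
#'
#' @param object An `enfusion_model`.
#' @param dataset A [seq_dataset()] (labels, if any, are ignored).
#' @param ... Unused.
#' @return Data frame: id, the three base labels, vote fraction, class.
#' @export
predict.enfusion_model <- function(object, dataset, ...) {
  stopifnot(inherits(dataset, "seq_dataset"))
  config <- object$config
  pg <- pgkm_config(config$pgkm$gap_max, config$pgkm$tuple_pairs)
  pk <- pseknc_config(config$pseknc$k_max)
  X_ms <- encode_multisource(dataset, pg, pk, config$use_npcp)
  X_sel <- apply_selector(object$selector, X_ms)
  emb <- embed_dataset(dataset, object$embedder)
  refined <- extract_refined_features(object$seqnet, emb)
  fused <- fuse_features(X_sel, refined, scaling = object$ensemble$scaling)
  predict(object$ensemble, fused)
}

# ---------------------------------------------------------------------------
# config-file driven runner (the engine behind the CLI)
# ---------------------------------------------------------------------------

RUN_CONFIG_SCHEMA <- list(
  seed = NULL, out_dir = NULL, verbose = NULL,
  data = list(simulate = list(n_pos = NULL, n_neg = NULL, length = NULL,
                              label_noise = NULL, instances_per_positive = NULL),
              positives = NULL, negatives = NULL, fasta = NULL, labels = NULL),
  pipeline = list(preset = NULL, pgkm = list(gap_max = NULL, tuple_pairs = NULL),
                  pseknc = list(k_max = NULL), use_npcp = NULL,
                  selector = list(n_estimators = NULL, max_depth = NULL),
                  embedder = list(backend = NULL, k = NULL, n_layers = NULL,
                                  n_heads = NULL, model_dim = NULL,
                                  mask_fraction = NULL, epochs = NULL,
                                  lr = NULL, path = NULL),
                  seqnet = list(kernel_widths = NULL, filters = NULL,
                                lstm_units = NULL, attention_dim = NULL,
                                epochs = NULL, patience = NULL,
                                batch_size = NULL, lr = NULL,
                                weight_decay = NULL, val_fraction = NULL),
                  ensemble = list(preset = NULL, svm = NULL,
                                  random_forest = NULL, cascade_forest = NULL)),
  evaluation = list(mode = NULL, test_fraction = NULL, k = NULL)
)

check_config_keys <- function(cfg, schema, path = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop_enfusion("unknown configuration key: ", path, unknown[1L])
  }
  for (nm in names(cfg)) {
    if (is.list(schema[[nm]]) && is.list(cfg[[nm]])) {
      check_config_keys(cfg[[nm]], schema[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Run the full pipeline from a configuration list or file
#'
#' Executes simulate/load -> encode -> select -> embed -> train ->
#' predict -> evaluate in order, writing every artifact (model bundle,
#' per-sample predictions, metric report and a manifest recording inputs,
#' configuration hash and seed) under `out_dir`.  Unknown configuration
#' keys are rejected by name; a rerun with an identical configuration and
#' seed reproduces the metric report exactly.
#'
#' @param config Nested configuration list, or a path to a JSON/YAML file
#'   holding one.  Top-level keys: `seed`, `out_dir`, `data`, `pipeline`,
#'   `evaluation`.
#' @return Invisibly, a list with the fitted model, the metric report and
#'   the artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  check_config_keys(config, RUN_CONFIG_SCHEMA)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop_enfusion("config must set out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  verbose <- isTRUE(config$verbose %||% TRUE)
  say <- function(...) if (verbose) message("[enfusion] ", ...)

  # --- data stage -----------------------------------------------------------
  t0 <- Sys.time()
  dcfg <- config$data %||% stop_enfusion("config must set data")
  truth <- NULL
  if (!is.null(dcfg$simulate)) {
    sim_args <- dcfg$simulate
    sim_args$seed <- derive_seed(seed, "simulate")
    scfg <- do.call(synthetic_config, sim_args)
    sim <- generate_dataset(scfg)
    dataset <- sim$dataset
    truth <- sim$truth
    say("simulated ", length(dataset), " sequences")
  } else if (!is.null(dcfg$positives)) {
    dataset <- assemble_dataset(read_fasta(dcfg$positives),
                                read_fasta(dcfg$negatives))
    say("loaded ", length(dataset), " sequences from FASTA pair")
  } else if (!is.null(dcfg$fasta)) {
    dataset <- read_fasta(dcfg$fasta)
    if (!is.null(dcfg$labels)) {
      dataset <- set_labels(dataset, read_label_map(dcfg$labels))
    }
    say("loaded ", length(dataset), " sequences")
  } else {
    stop_enfusion("data must specify simulate, positives/negatives, or fasta")
  }

  if (is.null(dataset$label)) {
    stop_enfusion("stage 'data': loaded sequences carry no labels; ",
                  "supply a label map or a positives/negatives pair")
  }
  pcfg <- do.call(pipeline_config,
                  c(list(preset = config$pipeline$preset %||% "desk"),
                    config$pipeline[setdiff(names(config$pipeline), "preset")]))

  # --- evaluation -----------------------------------------------------------
  ecfg <- config$evaluation %||% list()
  mode <- ecfg$mode %||% "holdout"
  if (identical(mode, "cv")) {
    say("running ", ecfg$k %||% 10L, "-fold cross-validation")
    report <- cross_validate(dataset, pcfg, k = ecfg$k %||% 10L, seed = seed)
    model <- train_pipeline(dataset, pcfg, seed = seed)
    pred <- predict(model, dataset)
  } else {
    frac <- ecfg$test_fraction %||% 0.2
    split <- with_seed(derive_seed(seed, "holdout"), {
      make_stratified_folds(dataset$label, max(2L, round(1 / frac)))
    })
    train <- dataset[split != 1L]
    test <- dataset[split == 1L]
    say("training on ", length(train), ", evaluating on ", length(test))
    model <- train_pipeline(train, pcfg, seed = seed)
    pred <- predict(model, test)
    fold_df <- cbind(fold = 1L, metric_row(test$label, pred$class, pred$vote))
    report <- structure(list(folds = fold_df,
                             mean = colMeans(fold_df[, -1L], na.rm = TRUE),
                             sd = apply(fold_df[, -1L], 2L, stats::sd),
                             k = 1L, seed = seed),
                        class = "metric_report")
  }

  # --- artifacts ------------------------------------------------------------
  model_dir <- file.path(out_dir, "model")
  save_model(model, model_dir)
  pred_path <- file.path(out_dir, "predictions.tsv")
  utils::write.table(pred, pred_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  metrics_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(list(mean = as.list(report$mean),
                            sd = as.list(report$sd),
                            folds = report$folds),
                       metrics_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  if (!is.null(truth)) {
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_sequences = length(dataset),
    artifacts = c("model", "predictions.tsv", "metrics.json", "config.json"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("enfusion"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say(sprintf("done in %.1fs; mean ACC %.3f, MCC %.3f",
              manifest$elapsed_sec, report$mean[["acc"]],
              report$mean[["mcc"]]))
  invisible(list(model = model, report = report, out_dir = out_dir,
                 predictions = pred))
}

read_run_config <- function(path) {
  if (!file.exists(path)) stop_enfusion("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_enfusion("YAML configs need the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  }
}
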