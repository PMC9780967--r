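# End-to-end orchestration: simulate -> binarize -> stride features ->
# (optional) cortical features -> selection -> training -> evaluation.

#' Default pipeline configuration
#'
#' A nested list mirroring the YAML layout accepted by [run_pipeline()]:
#' `synth` (generator), `trigger` (binarizer), `mrp` (EEG branch on/off and
#' STFT controls), `select` (alpha, pairing), `train` (model families and
#' network controls), and the dataset manifest parameters.
#'
#' @param eeg Enable the EEG branch (default `FALSE`: the deployed
#'   configuration keeps only the EMG branch active, the cortical features
#'   being non-discriminative for wearing-off).
#' @param models Model families to train (default `"dnn4"`).
#' @return Nested configuration list.
#' @export
default_config <- function(eeg = FALSE, models = "dnn4") {
  list(
    seed = 1L,
    synth = list(snr_db = 20, subject_sd_scale = 0.03, curve_steps_k = 0L,
                 dc_source = "table"),
    manifest = list(n_train = 3L, n_test = 2L, runs_per_session = 8L,
                    steps_per_run = 150L),
    trigger = list(k_on = 3, k_off = 1.5, debounce_ms = 30, refine = TRUE),
    mrp = list(eeg = eeg, frame = 128L, hop = 64L),
    select = list(alpha = 0.05, pairing = "indexwise", selected_only = FALSE),
    train = list(models = models, epochs = 200L, batch_size = 32L,
                 patience = 20L, lr = 0.001))
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()] (missing fields
#' keep their defaults).
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists(default_config(), user)
}

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

simulate_subject_session <- function(cfg, subject_id, condition, n_strides,
                                     master_seed, eeg) {
  par <- default_params(condition, dc_source = cfg$synth$dc_source %||% "table")
  shift <- subject_effects(subject_id, master_seed,
                           sd = cfg$synth$subject_sd_scale %||% 0.03)
  simulate_session(par, n_strides = n_strides,
                   seed = derive_seed(master_seed, subject_id),
                   snr_db = cfg$synth$snr_db %||% 20,
                   subject_id = subject_id, subject_shift = shift,
                   eeg = eeg, curve_steps_k = cfg$synth$curve_steps_k %||% 0L)
}

#' Run the full wearing-off tracking pipeline
#'
#' Simulates one Pre- and one Post-levodopa session per subject of the
#' manifest, converts every sEMG channel to a binary trigger, segments
#' strides and computes the muscular indexes, optionally appends the cortical
#' features, runs the paired-t feature selection on the training partition,
#' trains the configured classifiers on the training partition and evaluates
#' them on the held-out test subjects. Test subjects never contribute to
#' training, standardization statistics or feature selection. Every stage
#' seed is derived from the master seed, so a rerun with the same
#' configuration is reproducible.
#'
#' @param config Nested configuration list (see [default_config()]) or a
#'   YAML file path.
#' @param seed Optional master-seed override.
#' @param out_dir Optional directory; when given, tables and reports are
#'   persisted as delimiter-separated/JSON files.
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `wo_pipeline`: `manifest`, `tables` (train/test
#'   feature tables), `selection`, `models`, `evals`, `summary`, `config`.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (!is.null(seed)) config$seed <- seed
  master_seed <- as.integer(config$seed %||% 1L)
  say <- function(...) if (!quiet) message(sprintf(...))

  man <- dataset_manifest(n_train = config$manifest$n_train %||% 3L,
                          n_test = config$manifest$n_test %||% 2L,
                          runs_per_session = config$manifest$runs_per_session %||% 8L,
                          steps_per_run = config$manifest$steps_per_run %||% 150L)
  validate_manifest(man)
  eeg_on <- isTRUE(config$mrp$eeg)
  tcfg <- trigger_config(k_on = config$trigger$k_on %||% 3,
                         k_off = config$trigger$k_off %||% 1.5,
                         debounce_ms = config$trigger$debounce_ms %||% 30,
                         refine = config$trigger$refine %||% TRUE)

  tables <- list(train = NULL, test = NULL)
  for (i in seq_len(nrow(man))) {
    sid <- man$subject_id[i]
    part <- man$partition[i]
    n_strides <- as.integer(round(man$steps_per_session[i] / 2))
    for (cond in c("pre", "post")) {
      rec <- simulate_subject_session(config, sid, cond, n_strides,
                                      master_seed, eeg = eeg_on)
      tab <- session_features(rec, cfg = tcfg)
      if (eeg_on) {
        mrp <- session_mrp_features(rec$eeg, tab$onset_samp,
                                    frame = config$mrp$frame %||% 128L,
                                    hop = config$mrp$hop %||% 64L)
        tab <- cbind(tab, as.data.frame(mrp))
        tab <- tab[stats::complete.cases(tab[colnames(mrp)]), , drop = FALSE]
      }
      attr(tab, "triggers") <- NULL
      say("%s/%s (%s): %d strides detected", sid, cond, part, nrow(tab))
      tables[[part]] <- rbind(tables[[part]], tab)
    }
  }

  sel_tab <- tables$train
  selection <- build_selection_report(
    sel_tab[sel_tab$condition == "pre", ],
    sel_tab[sel_tab$condition == "post", ],
    alpha = config$select$alpha %||% 0.05,
    pairing = config$select$pairing %||% "indexwise")

  feats <- muscular_features()
  if (isTRUE(config$select$selected_only)) {
    feats <- intersect(feats, selection$feature[selection$selected])
  }

  families <- config$train$models %||% "dnn4"
  models <- list()
  evals <- list()
  for (fam in families) {
    mdl <- wo_train(model_spec(fam), tables$train,
                    seed = derive_seed(master_seed, paste0("train-", fam)),
                    features = feats,
                    epochs = config$train$epochs %||% 200L,
                    batch_size = config$train$batch_size %||% 32L,
                    patience = config$train$patience %||% 20L,
                    lr = config$train$lr %||% 0.001)
    ev <- evaluate_model(mdl, tables$test)
    say("%s: test accuracy %.2f%%, AUC %.3f", fam,
        ev$metrics$accuracy_pct, ev$auc)
    models[[fam]] <- mdl
    evals[[fam]] <- ev
  }

  summary <- list(
    seed = master_seed,
    n_train_rows = nrow(tables$train), n_test_rows = nrow(tables$test),
    rows_by_partition_condition = table(
      partition = c(rep("train", nrow(tables$train)), rep("test", nrow(tables$test))),
      condition = c(tables$train$condition, tables$test$condition)),
    selected_features = selection$feature[selection$selected],
    test_metrics = lapply(evals, function(e)
      c(accuracy = e$metrics$accuracy_pct, recall = e$metrics$recall_pct,
        precision = e$metrics$precision_pct, f1 = e$metrics$f1_pct,
        specificity = e$metrics$specificity_pct, auc = e$auc)))

  out <- structure(list(manifest = man, tables = tables, selection = selection,
                        models = models, evals = evals, summary = summary,
                        config = config),
                   class = "wo_pipeline")
  if (!is.null(out_dir)) persist_pipeline(out, out_dir)
  out
}

persist_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$tables$train, file.path(out_dir, "features_train.csv"),
            row.names = FALSE)
  write.csv(res$tables$test, file.path(out_dir, "features_test.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(res$selection), file.path(out_dir, "selection.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(seed = res$summary$seed,
         n_train_rows = res$summary$n_train_rows,
         n_test_rows = res$summary$n_test_rows,
         selected_features = res$summary$selected_features,
         test_metrics = res$summary$test_metrics),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  for (fam in names(res$models)) {
    if (is_dnn(fam)) {
      save_model(res$models[[fam]], file.path(out_dir, paste0("model_", fam, ".json")))
    }
  }
  invisible(out_dir)
}

#' @export
print.wo_pipeline <- function(x, ...) {
  cat(sprintf("<wo_pipeline> seed %d: %d train rows, %d test rows\n",
              x$summary$seed, x$summary$n_train_rows, x$summary$n_test_rows))
  cat("  selected:", paste(x$summary$selected_features, collapse = ", "), "\n")
  for (fam in names(x$summary$test_metrics)) {
    m <- x$summary$test_metrics[[fam]]
    cat(sprintf("  %s: accuracy %.2f%%, F1 %.2f%%, AUC %.3f\n",
                fam, m[["accuracy"]], m[["f1"]], m[["auc"]]))
  }
  invisible(x)
}
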