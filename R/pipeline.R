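# Reproducible end-to-end orchestration: a validated run configuration plus
# cmd_* stages (generate -> train -> predict -> evaluate -> sweep). A thin
# command-line wrapper over these functions ships in inst/cli/coroflow.R.

run_config_defaults <- function() {
  list(
    master_seed = 1L,
    corpus = list(
      n_base_train = 4L, n_base_test = 2L, expansions_per_base = 3L,
      n_query = 1024L, surface_density = 0.05,
      field_kinds = c("velocity", "pressure"),
      op_states = c("preoperative", "postoperative"),
      ranges = list()
    ),
    network = list(
      fc1_width = 64L, fc2_width = 64L, fc3_width = 512L, fc4_width = 128L,
      fc5_width = 64L, share_weights = TRUE, single_channel = FALSE,
      learning_rate = 0.001, epochs = 20L
    ),
    evaluation = list(
      error_threshold = 10, ffr_distal_offset = 0.03,
      ffr_reference_pa = 13332, region = "aorta_and_branches",
      sweep_fractions = seq(0.1, 1, by = 0.1)
    ),
    io = list(out_dir = "coroflow_runs")
  )
}

merge_checked <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s) under '%s': %s",
                  path, paste(unknown, collapse = ", ")))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_checked(defaults[[nm]], user[[nm]],
                                      paste(path, nm, sep = "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Accepts a YAML file path or a nested list; unknown keys anywhere in the
#' document are rejected before any work starts, and numeric blocks are
#' sanity-checked (counts, ranges, fractions).
#'
#' @param config Path to a YAML file, a list, or `NULL` for defaults.
#' @return A validated `run_config` list.
#' @export
run_config <- function(config = NULL) {
  if (inherits(config, "run_config")) return(config)
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    abort("config must be a YAML path or a list")
  }
  cfg <- merge_checked(run_config_defaults(), user, "config")
  cb <- cfg$corpus
  if (cb$n_base_train < 1 || cb$n_base_test < 1 || cb$expansions_per_base < 1) {
    abort("corpus counts must be >= 1")
  }
  if (!all(cb$field_kinds %in% c("velocity", "pressure"))) {
    abort("corpus.field_kinds must be velocity and/or pressure")
  }
  if (!all(cb$op_states %in% c("preoperative", "postoperative"))) {
    abort("corpus.op_states must be preoperative and/or postoperative")
  }
  # Range overrides are validated by geometry_ranges itself (schema + bounds).
  do.call(geometry_ranges, cb$ranges)
  if (any(cfg$evaluation$sweep_fractions <= 0 |
            cfg$evaluation$sweep_fractions > 1)) {
    abort("evaluation.sweep_fractions must lie in (0, 1]")
  }
  structure(cfg, class = c("run_config", "list"))
}

corpus_dir_name <- function(op_state, field_kind) {
  paste(op_state, field_kind, sep = "_")
}

config_net <- function(cfg, seed, single_channel = NULL) {
  args <- cfg$network
  if (!is.null(single_channel)) args$single_channel <- single_channel
  args$seed <- seed
  do.call(net_config, args)
}

#' Generate all configured corpora on disk
#'
#' Builds one corpus per (op_state, field_kind) pair in the configuration and
#' writes each, with its manifest, under the output directory. Regenerating
#' with the same configuration and seed reproduces the corpora exactly.
#'
#' @param config A [run_config()] (path, list or object).
#' @return Tibble of generated corpora (invisible): directory, op_state,
#'   field_kind, sample counts.
#' @export
cmd_generate <- function(config = NULL) {
  cfg <- run_config(config)
  cb <- cfg$corpus
  ranges <- do.call(geometry_ranges, cb$ranges)
  rows <- list()
  for (op in cb$op_states) {
    for (fk in cb$field_kinds) {
      corpus <- build_corpus(
        n_base_train = cb$n_base_train, n_base_test = cb$n_base_test,
        expansions_per_base = cb$expansions_per_base,
        op_state = op, field_kind = fk, ranges = ranges,
        n_query = cb$n_query, surface_density = cb$surface_density,
        master_seed = cfg$master_seed
      )
      dir <- file.path(cfg$io$out_dir, corpus_dir_name(op, fk))
      write_corpus(corpus, dir)
      rows[[length(rows) + 1]] <- tibble(
        dir = dir, op_state = op, field_kind = fk,
        n_train = length(corpus$train), n_test = length(corpus$test)
      )
    }
  }
  invisible(dplyr::bind_rows(rows))
}

#' Train a network on a corpus directory
#'
#' @param config A [run_config()].
#' @param corpus_dir Directory written by [cmd_generate()].
#' @param single_channel Override the configured channel ablation flag.
#' @param weights_path Where to store the trained weights (default
#'   `weights.rds` inside the corpus directory); the per-epoch loss history
#'   is written alongside as `loss_history.csv`.
#' @return The `hemo_fit` (invisible).
#' @export
cmd_train <- function(config = NULL, corpus_dir, single_channel = NULL,
                      weights_path = file.path(corpus_dir, "weights.rds")) {
  cfg <- run_config(config)
  if (!dir.exists(corpus_dir)) abort(sprintf("no such corpus directory: %s", corpus_dir))
  corpus <- read_corpus(corpus_dir)
  net_cfg <- config_net(cfg, derive_seed(cfg$master_seed, 31L), single_channel)
  fit <- net_train(net_build(net_cfg), corpus)
  save_weights(fit, weights_path)
  readr::write_csv(tidy(fit), file.path(dirname(weights_path), "loss_history.csv"),
                   progress = FALSE)
  invisible(fit)
}

#' Predict the test split of a corpus and write per-model prediction tables
#'
#' @param config A [run_config()].
#' @param corpus_dir Corpus directory.
#' @param weights_path Trained weights from [cmd_train()].
#' @param out_dir Output directory for `<model_id>_pred.csv` files.
#' @return Tibble of written files (invisible).
#' @export
cmd_predict <- function(config = NULL, corpus_dir,
                        weights_path = file.path(corpus_dir, "weights.rds"),
                        out_dir = file.path(corpus_dir, "predictions")) {
  run_config(config)
  corpus <- read_corpus(corpus_dir)
  model <- load_weights(weights_path)
  check_weights_meta(model, corpus)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(corpus$test, function(s) {
    pr <- net_predict(model, s$surface, s$query)
    path <- file.path(out_dir, paste0(s$model_id, "_pred.csv"))
    readr::write_csv(
      dplyr::bind_cols(s$query[c("x", "y", "z")], pr), path, progress = FALSE
    )
    tibble(model_id = s$model_id, path = path)
  })
  invisible(dplyr::bind_rows(rows))
}

check_weights_meta <- function(model, corpus) {
  meta <- attr(model, "meta")
  if (is.null(meta)) return(invisible())
  if (!is.null(meta$field_kind) && meta$field_kind != corpus$field_kind) {
    abort(sprintf("field_kind mismatch: weights trained on %s, corpus is %s",
                  meta$field_kind, corpus$field_kind))
  }
  if (!is.null(meta$op_state) && meta$op_state != corpus$op_state) {
    abort(sprintf("op_state mismatch: weights trained on %s, corpus is %s",
                  meta$op_state, corpus$op_state))
  }
  invisible()
}

read_predictions_dir <- function(predictions_dir, corpus) {
  preds <- list()
  for (s in corpus$test) {
    path <- file.path(predictions_dir, paste0(s$model_id, "_pred.csv"))
    if (!file.exists(path)) {
      abort(sprintf("prediction/corpus mismatch: no predictions for model '%s'",
                    s$model_id))
    }
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(df) != nrow(s$query)) {
      abort(sprintf("prediction/corpus mismatch for '%s': %d rows vs %d query points",
                    s$model_id, nrow(df), nrow(s$query)))
    }
    preds[[s$model_id]] <- df
  }
  preds
}

#' Evaluate test predictions: regional errors, clinical indices, agreement
#'
#' Reads the corpus and either a predictions directory (from [cmd_predict()])
#' or trained weights (predictions recomputed on the fly); writes the
#' regional NMAE/MRE report, per-model clinical indices (FFR for pressure
#' corpora, graft flow for postoperative velocity corpora) and their
#' truth-vs-prediction agreement statistics as CSV files next to the corpus.
#'
#' @param config A [run_config()].
#' @param corpus_dir Corpus directory.
#' @param predictions_dir Optional predictions directory.
#' @param weights_path Trained weights (used when `predictions_dir` is NULL
#'   and for clinical indices).
#' @param out_dir Report output directory.
#' @return List with `report`, `clinical`, `agreement` (invisible).
#' @export
cmd_evaluate <- function(config = NULL, corpus_dir, predictions_dir = NULL,
                         weights_path = file.path(corpus_dir, "weights.rds"),
                         out_dir = file.path(corpus_dir, "reports")) {
  cfg <- run_config(config)
  corpus <- read_corpus(corpus_dir)
  model <- load_weights(weights_path)
  check_weights_meta(model, corpus)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  samples <- corpus$test
  if (!is.null(predictions_dir)) {
    preds <- read_predictions_dir(predictions_dir, corpus)
    samples <- lapply(samples, function(s) {
      s$query$px <- preds[[s$model_id]]$px
      s$query$py <- preds[[s$model_id]]$py
      s$query$pz <- preds[[s$model_id]]$pz
      s
    })
  } else {
    samples <- lapply(samples, add_predictions, fit = model)
  }

  report <- regional_report(samples)
  readr::write_csv(as_tibble(report), file.path(out_dir, "regional_errors.csv"),
                   progress = FALSE)

  clinical <- NULL
  agree <- NULL
  ev <- cfg$evaluation
  if (corpus$field_kind == "pressure") {
    rows <- lapply(samples, function(s) {
      sol <- solve_network(s$tree)
      truth <- compute_ffr(s$tree, pressure_accessor_oracle(s$tree, sol),
                           ev$ffr_distal_offset, ev$ffr_reference_pa)
      pred <- compute_ffr(s$tree, pressure_accessor_network(model, s$surface),
                          ev$ffr_distal_offset, ev$ffr_reference_pa)
      tibble(model_id = s$model_id, ffr_truth = truth$ffr, ffr_pred = pred$ffr)
    })
    clinical <- dplyr::bind_rows(rows)
    if (nrow(clinical) >= 3) {
      agree <- agreement(clinical$ffr_pred, clinical$ffr_truth)
    }
  } else if (corpus$op_state == "postoperative") {
    rows <- lapply(samples, function(s) {
      sol <- solve_network(s$tree)
      tibble(
        model_id = s$model_id,
        flow_truth = graft_flow(s$tree, velocity_accessor_oracle(s$tree, sol)),
        flow_pred = graft_flow(s$tree, velocity_accessor_network(model, s$surface))
      )
    })
    clinical <- dplyr::bind_rows(rows)
    if (nrow(clinical) >= 3) {
      agree <- agreement(clinical$flow_pred, clinical$flow_truth)
    }
  }
  if (!is.null(clinical)) {
    readr::write_csv(clinical, file.path(out_dir, "clinical_indices.csv"),
                     progress = FALSE)
  }
  if (!is.null(agree)) {
    readr::write_csv(glance(agree), file.path(out_dir, "agreement.csv"),
                     progress = FALSE)
  }
  invisible(list(report = report, clinical = clinical, agreement = agree))
}

#' Training-set-size sweep over a corpus directory
#'
#' @param config A [run_config()].
#' @param corpus_dir Corpus directory.
#' @param out_path CSV output path for the fraction-vs-MRE curve.
#' @return The sweep tibble (invisible).
#' @export
cmd_sweep <- function(config = NULL, corpus_dir,
                      out_path = file.path(corpus_dir, "sweep.csv")) {
  cfg <- run_config(config)
  corpus <- read_corpus(corpus_dir)
  curve <- training_size_sweep(
    corpus, fractions = cfg$evaluation$sweep_fractions,
    region = cfg$evaluation$region,
    config = config_net(cfg, derive_seed(cfg$master_seed, 41L)),
    seed = derive_seed(cfg$master_seed, 42L)
  )
  readr::write_csv(curve, out_path, progress = FALSE)
  invisible(curve)
}
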