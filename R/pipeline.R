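# End-to-end orchestration: tag -> label -> featurize -> fit -> evaluate ->
# benchmark, with seeded reproducibility and artifact files a downstream
# analyst can pick up (mentions CSV, labels CSV, cohort summary JSON, model
# JSON, metrics JSON, ROC CSV).

#' Read registry / diagnosis / gold-set CSV inputs
#'
#' @param path File path.
#' @return Data.frame with character identifier columns.
#' @export
read_registry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  need <- c("patient_id", "stage_at_dx")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("registry file missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_registry_csv
#' @export
read_diagnoses_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(patient_id = "character",
                                 code = "character"))
}

#' Write a cohort's input files to a directory
#'
#' Serializes a synthetic cohort in the formats the pipeline consumes:
#' notes JSONL, registry CSV, diagnoses CSV, plus the ground-truth manifest
#' as JSONL for oracle checks.
#'
#' @param cohort An `mbc_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    notes = file.path(dir, "notes.jsonl"),
    registry = file.path(dir, "registry.csv"),
    diagnoses = file.path(dir, "diagnoses.csv"),
    truth_patients = file.path(dir, "truth_patients.csv"),
    manifest = file.path(dir, "truth_manifest.jsonl"))
  write_notes_jsonl(cohort$notes, paths$notes)
  utils::write.csv(cohort$registry, paths$registry, row.names = FALSE)
  utils::write.csv(cohort$diagnoses, paths$diagnoses, row.names = FALSE)
  utils::write.csv(cohort$truth$patients, paths$truth_patients,
                   row.names = FALSE)
  con <- file(paths$manifest, open = "w")
  jsonlite::stream_out(cohort$truth$manifest, con, verbose = FALSE)
  close(con)
  invisible(paths)
}

#' Run the full detection pipeline
#'
#' Stages: tag the corpus, assign cohort labels, build features, fit the
#' requested classifier configurations, evaluate distant labels and
#' classifiers against a gold set, and run the ICD-9 benchmark. Every
#' artifact is stamped with the config hash and seed; rerunning with the
#' same config reproduces the artifacts.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `notes`, `registry`, `diagnoses` (input paths), optional `lexicon`,
#'   `adjudicated` (CSV patient_id,label), `gold_set` (CSV patient_id,truth),
#'   `out_dir`, `features` (subset of "A","B","C"; default "B"),
#'   `seed`, `n_folds`, `bootstrap_B`.
#' @return Invisibly, a run report list (also written to `run_report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(lexicon = NULL, adjudicated = NULL,
                                gold_set = NULL, out_dir = "mbc_run",
                                features = "B", seed = 1L, n_folds = 10L,
                                bootstrap_B = 1000L, window = 6L),
                           config)
  for (p in c("notes", "registry", "diagnoses")) {
    if (is.null(cfg[[p]]) || !file.exists(cfg[[p]])) {
      stop("pipeline config error: input '", p, "' missing or not found")
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = config_hash(cfg), seed = cfg$seed)

  lexicon <- if (is.null(cfg$lexicon)) load_lexicon()
             else load_lexicon(cfg$lexicon)
  notes <- read_notes_jsonl(cfg$notes)
  registry <- read_registry_csv(cfg$registry)
  diagnoses <- read_diagnoses_csv(cfg$diagnoses)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  mentions <- run_stage("tag", tag_corpus(notes, lexicon,
                                          window = cfg$window))
  utils::write.csv(mentions, file.path(cfg$out_dir, "mentions.csv"),
                   row.names = FALSE)

  adj <- if (!is.null(cfg$adjudicated)) {
    utils::read.csv(cfg$adjudicated, stringsAsFactors = FALSE,
                    colClasses = c(patient_id = "character"))
  }
  labels <- run_stage("label", label_cohort(registry, mentions, notes,
                                            adjudicated = adj))
  utils::write.csv(labels, file.path(cfg$out_dir, "labels.csv"),
                   row.names = FALSE)
  summary <- summarize_cohort(labels)
  jsonlite::write_json(c(summary, stamp),
                       file.path(cfg$out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  gold <- if (!is.null(cfg$gold_set)) {
    utils::read.csv(cfg$gold_set, stringsAsFactors = FALSE,
                    colClasses = c(patient_id = "character"))
  }

  metrics <- list()
  if (!is.null(gold)) {
    lab_at <- labels$label[match(gold$patient_id, labels$patient_id)]
    yhat <- as.integer(lab_at == "distant_positive")
    rep_dl <- evaluate_predictions(gold$truth, yhat, B = cfg$bootstrap_B,
                                   seed = cfg$seed, with_auc = FALSE)
    metrics$distant_labels <- eval_report_to_list(rep_dl)
  }

  models <- list()
  for (conf in intersect(c("A", "B", "C"), cfg$features)) {
    spec <- feature_spec(conf, lexicon = lexicon)
    dm <- run_stage(paste0("featurize_", conf),
                    assemble_design_matrix(registry, mentions, labels, spec))
    model <- run_stage(paste0("fit_", conf),
                       fit_recurrence_model(dm$X, dm$y,
                                            fit_config(n_folds = cfg$n_folds,
                                                       seed = cfg$seed)))
    write_model_json(model, file.path(cfg$out_dir,
                                      paste0("model_", conf, ".json")))
    models[[conf]] <- model
    if (!is.null(gold)) {
      Xg <- run_stage(paste0("featurize_gold_", conf),
                      gold_design_matrix(gold, registry, mentions, spec))
      prob <- predict_prob(model, Xg)
      rep_m <- evaluate_predictions(gold$truth, prob, cutoff = model$cutoff,
                                    B = cfg$bootstrap_B, seed = cfg$seed,
                                    with_auc = TRUE)
      metrics[[paste0("classifier_", conf)]] <- eval_report_to_list(rep_m)
      utils::write.csv(roc_points(prob, gold$truth),
                       file.path(cfg$out_dir, paste0("roc_", conf, ".csv")),
                       row.names = FALSE)
    }
  }

  bench <- run_stage("benchmark",
                     classify_icd9_cohort(diagnoses, registry$patient_id))
  utils::write.csv(bench, file.path(cfg$out_dir, "icd9_benchmark.csv"),
                   row.names = FALSE)
  if (!is.null(gold)) {
    yhat <- as.integer(bench$icd9_mbc[match(gold$patient_id,
                                            bench$patient_id)])
    rep_b <- evaluate_predictions(gold$truth, yhat, B = cfg$bootstrap_B,
                                  seed = cfg$seed, with_auc = FALSE)
    metrics$icd9_benchmark <- eval_report_to_list(rep_b)
  }
  jsonlite::write_json(c(metrics, stamp),
                       file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- c(list(n_patients = nrow(registry), n_notes = nrow(notes),
                   n_mentions = nrow(mentions),
                   skipped_notes = attr(mentions, "skipped"),
                   cohort_summary = summary,
                   features = as.list(cfg$features)), stamp)
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, metrics = metrics, models = models,
                 labels = labels, mentions = mentions))
}

# Feature matrix for gold-set patients, aligned to a spec.
gold_design_matrix <- function(gold, registry, mentions, spec) {
  ids <- as.character(gold$patient_id)
  reg_idx <- match(ids, as.character(registry$patient_id))
  if (anyNA(reg_idx)) stop("gold set contains unknown patient ids")
  split_m <- split(seq_len(nrow(mentions)), mentions$patient_id)
  rows <- lapply(seq_along(ids), function(i) {
    parts <- numeric(0)
    if (spec$use_nlp) {
      idx <- split_m[[ids[i]]]
      m <- if (is.null(idx)) empty_mentions() else mentions[idx, , drop = FALSE]
      parts <- c(parts, build_nlp_features(m, spec))
    }
    if (spec$use_registry) {
      parts <- c(parts, build_registry_features(registry[reg_idx[i], ], spec))
    }
    parts
  })
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  X
}

eval_report_to_list <- function(rep) {
  out <- list()
  for (m in c("sensitivity", "specificity", "ppv", "npv", "f1", "accuracy")) {
    out[[m]] <- rep[[m]]
    out[[paste0(m, "_ci")]] <- c(rep$ci[[m]]$lo, rep$ci[[m]]$hi)
  }
  out$n <- rep$n
  out$prevalence <- rep$prevalence
  if (!is.null(rep$auc)) {
    out$auc <- rep$auc
    out$auc_ci <- c(rep$auc_ci$lo, rep$auc_ci$hi)
  }
  out
}

config_hash <- function(cfg) {
  # fingerprint of the run parameters (paths excluded: they vary across
  # machines without changing the computation); no digest dependency needed
  cfg <- cfg[setdiff(names(cfg), c("notes", "registry", "diagnoses",
                                   "lexicon", "adjudicated", "gold_set",
                                   "out_dir"))]
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(as.character(s))) %% 97 + 1)) %%
            .Machine$integer.max)
}
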