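#' Full-pipeline run configuration
#'
#' One structured configuration object wiring the stages (simulate ->
#' label-reports -> preprocess/train -> evaluate) into a single reproducible
#' run. Every random behaviour derives from `seed`.
#'
#' @param out_dir Run directory (created; all artifacts live under it).
#' @param stages Character subset of
#'   `c("simulate", "label_reports", "train", "evaluate")`, executed in that
#'   order.
#' @param corpus A [corpus_config()].
#' @param labeler A [labeler_config()].
#' @param preprocess A [preprocess_config()].
#' @param train A [train_config()].
#' @param k Cross-validation folds for the training stage.
#' @param backbone_arch Backbone preset name.
#' @param tile_size Working tile edge for bags (see [case_to_bag()]).
#' @param seed Master seed.
#' @return A list of class `pathmil_run_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("pathmil_run_"),
                            stages = c("simulate", "label_reports", "train", "evaluate"),
                            corpus = corpus_config(),
                            labeler = labeler_config(),
                            preprocess = preprocess_config(),
                            train = train_config(),
                            k = 2L, backbone_arch = "tiny", tile_size = 32L,
                            seed = 1L) {
  structure(list(out_dir = out_dir, stages = stages, corpus = corpus,
                 labeler = labeler, preprocess = preprocess, train = train,
                 k = as.integer(k), backbone_arch = backbone_arch,
                 tile_size = as.integer(tile_size), seed = as.integer(seed),
                 version = as.character(utils::packageVersion("pathmil"))),
            class = "pathmil_run_config")
}

#' Validate a run configuration
#'
#' @param config A [pipeline_config()].
#' @return Character vector of problems; empty iff the configuration is
#'   runnable.
#' @export
validate_config <- function(config) {
  problems <- character()
  known <- c("simulate", "label_reports", "train", "evaluate")
  bad <- setdiff(config$stages, known)
  if (length(bad) > 0) {
    problems <- c(problems, paste0("stages: unknown stage ", paste(bad, collapse = ", ")))
  }
  if (config$corpus$n_cases < 1) {
    problems <- c(problems, "corpus$n_cases: must be >= 1")
  }
  n_patients <- ceiling(config$corpus$n_cases / config$corpus$bags_per_patient)
  if ("train" %in% config$stages && config$k > n_patients) {
    problems <- c(problems,
                  sprintf("k: %d folds exceed the %d patients the corpus yields",
                          config$k, n_patients))
  }
  thr <- config$train$decision_threshold
  if (thr <= 0 || thr >= 1) {
    problems <- c(problems, "train$decision_threshold: must be in (0, 1)")
  }
  if (!config$backbone_arch %in% c("tiny", "resnet34")) {
    problems <- c(problems, "backbone_arch: must be 'tiny' or 'resnet34'")
  }
  rates <- c(mislabel = config$corpus$mislabel_rate,
             negation = config$corpus$negation_rate,
             distractor = config$corpus$distractor_rate)
  for (nm in names(rates)) {
    if (rates[[nm]] < 0 || rates[[nm]] > 1) {
      problems <- c(problems, paste0("corpus$", nm, "_rate: must be in [0, 1]"))
    }
  }
  problems
}

stage_log <- function(run_dir, stage, seed, files) {
  sums <- map_chr(files, function(f) {
    if (file.exists(f)) rlang::hash(readBin(f, "raw", file.size(f))) else "missing"
  })
  tibble(stage = stage, seed = seed, file = basename(files), hash = sums,
         time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order, each consuming only the previous
#' stage's declared outputs under the run directory: `simulate` writes the
#' synthetic corpus (reports, ground-truth and noisy labels, manifest),
#' `label_reports` extracts weak labels from the reports and scores them
#' against ground truth, `train` cross-validates the MIL classifier on bags
#' labeled with the extracted weak labels, and `evaluate` collates WSI and
#' patch metrics into `summary.json`. Deterministic stages reproduce
#' bit-identically under the same configuration.
#'
#' @param config A [pipeline_config()].
#' @param gazetteer Gazetteer tibble; defaults to the bundled colon table.
#' @return Invisibly, a list with `run_dir`, `summary` and stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), gazetteer = read_gazetteer()) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    abort(paste0("invalid configuration:\n", paste("-", problems, collapse = "\n")),
          class = "pathmil_validation_error")
  }
  run_dir <- config$out_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(stages = config$stages, seed = config$seed,
                        version = config$version,
                        config_hash = rlang::hash(unclass(config))),
                   file.path(run_dir, "run.yaml"))
  logs <- list()
  summary <- list(seed = config$seed, version = config$version)
  out <- list(run_dir = run_dir)

  need_bags <- "train" %in% config$stages
  corpus <- NULL
  if ("simulate" %in% config$stages) {
    transform <- if (need_bags) {
      function(case) {
        case$bag <- case_to_bag(case, config$preprocess, config$tile_size)
        case$slide <- NULL; case$region_mask <- NULL
        case
      }
    } else NULL
    corpus <- synth_corpus(config$corpus, render_slides = need_bags,
                           transform = transform)
    write_reports_jsonl(corpus$reports, file.path(run_dir, "reports.jsonl"))
    write_label_csv(corpus$labels_gt, file.path(run_dir, "labels_gt.csv"))
    write_label_csv(corpus$labels_noisy, file.path(run_dir, "labels_noisy.csv"))
    readr::write_csv(corpus$manifest, file.path(run_dir, "manifest.csv"))
    logs$simulate <- stage_log(run_dir, "simulate", config$corpus$seed,
                               file.path(run_dir, c("reports.jsonl", "labels_gt.csv",
                                                    "labels_noisy.csv", "manifest.csv")))
    out$corpus <- corpus
  }

  weak_labels <- NULL
  if ("label_reports" %in% config$stages) {
    reports <- if (!is.null(corpus)) corpus$reports else
      read_reports_jsonl(file.path(run_dir, "reports.jsonl"))
    if (is.null(reports) || nrow(reports) == 0) {
      abort("label_reports needs reports.jsonl; enable the simulate stage or provide it",
            class = "pathmil_validation_error")
    }
    gt <- if (file.exists(file.path(run_dir, "labels_gt.csv"))) {
      read_label_csv(file.path(run_dir, "labels_gt.csv"))
    } else NULL
    lab <- label_corpus(reports, gazetteer, config$labeler, gt = gt)
    weak_labels <- lab$labels
    write_label_csv(weak_labels, file.path(run_dir, "labels.csv"))
    if (nrow(lab$trace) > 0) {
      writeLines(map_chr(seq_len(nrow(lab$trace)), function(i) {
        jsonlite::toJSON(as.list(lab$trace[i, ]), auto_unbox = TRUE)
      }), file.path(run_dir, "trace.jsonl"))
    }
    if (!is.null(lab$metrics)) {
      summary$labeler <- as.list(lab$metrics)
    }
    logs$label_reports <- stage_log(run_dir, "label_reports", config$seed,
                                    file.path(run_dir, "labels.csv"))
    out$labeler <- lab
  }

  cv <- NULL
  backbone <- NULL
  if ("train" %in% config$stages) {
    if (is.null(corpus)) {
      abort("train needs the simulate stage's bags; enable 'simulate'",
            class = "pathmil_validation_error")
    }
    bags <- map(corpus$cases, "bag")
    # weak supervision: use extracted labels when the labeler ran, else noisy
    if (!is.null(weak_labels)) {
      wl <- label_matrix(weak_labels)
      bags <- map(bags, function(bag) {
        bag$label <- setNames(wl[bag$slide_id, ], class_names())
        bag
      })
    }
    backbone <- backbone_spec(config$backbone_arch, seed = derive_seed(config$seed, 7L))
    cv <- cross_validate(bags, backbone, config$train, k = config$k,
                         seed = config$seed)
    saveRDS(list(fits = map(cv$fits, "head"), backbone_arch = config$backbone_arch,
                 config = config$train, classes = class_names(),
                 version = config$version),
            file.path(run_dir, "checkpoints.rds"))
    readr::write_csv(cv$fold_metrics, file.path(run_dir, "fold_metrics.csv"))
    summary$wsi <- as.list(setNames(
      paste0(sprintf("%.3f", cv$summary$mean), " ± ", sprintf("%.3f", cv$summary$sd)),
      cv$summary$metric))
    logs$train <- stage_log(run_dir, "train", config$seed,
                            file.path(run_dir, c("checkpoints.rds", "fold_metrics.csv")))
    out$cv <- cv
  }

  if ("evaluate" %in% config$stages) {
    if (!is.null(cv)) {
      bags <- map(corpus$cases, "bag")
      pe <- patch_eval_table(bags, backbone, cv$fits[[1]]$head)
      if (nrow(pe) > 0) summary$patch_kappa <- cohen_kappa(pe)
      tab <- predict_bags(bags, backbone, cv$fits[[1]]$head,
                          config$train$decision_threshold)
      readr::write_csv(tab, file.path(run_dir, "predictions.csv"))
    }
    jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    logs$evaluate <- stage_log(run_dir, "evaluate", config$seed,
                               file.path(run_dir, "summary.json"))
  }
  readr::write_csv(bind_rows(logs), file.path(run_dir, "stages.csv"))
  out$summary <- summary
  invisible(out)
}
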