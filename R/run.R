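#' Run configuration for the command-line workflow
#'
#' A single structured document (YAML on disk) capturing every parameter of
#' a run — binning, QC, normalization, model, classification, validation,
#' seeds and IO paths — so that any numeric result is traceable to a config
#' hash and seed set.
#'
#' @param path Path to a YAML config file, or `NULL` for the documented
#'   defaults.
#' @return List of class `run_config` with a `hash` attribute.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    scenario = "distinct_classes",
    binning = list(mz_min = 600, mz_max = 620, bin_width = 0.1),
    qc = list(min_scans = 3, min_total_intensity = 1e3),
    normalization = "tic",
    model = list(n_pc = NULL, ridge = 1e-6),
    classification = list(threshold = 0.95, outlier_quantile = 0.999),
    validation = list(p = 0.2, repeats = 25,
                      usage_fractions = seq(0.1, 1, by = 0.1),
                      cv_threshold = 0),
    sparse = list(n_top = 100, keep = "all_unflagged"),
    seeds = list(simulate = 1, validate = 1),
    io = list(dir = "tissueprint_run"))
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (nm in names(user)) {
      if (is.list(user[[nm]]) && is.list(cfg[[nm]])) {
        for (sub in names(user[[nm]])) cfg[[nm]][[sub]] <- user[[nm]][[sub]]
      } else {
        cfg[[nm]] <- user[[nm]]
      }
    }
  }
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Fingerprint of a run configuration
#'
#' @param config A `run_config` (or any serializable list).
#' @return 8-hex-digit hash of the canonical JSON form.
#' @export
config_hash <- function(config) {
  attributes(config) <- attributes(config)["names"]
  fnv1a(as.character(jsonlite::toJSON(config, digits = NA, auto_unbox = TRUE,
                                      null = "null")))
}

write_run_log <- function(dir, command, config, extra = list()) {
  log <- c(list(command = command,
                package_version = as.character(utils::packageVersion("tissueprint")),
                config_hash = attr(config, "hash") %||% config_hash(config),
                seeds = config$seeds),
           extra)
  jsonlite::write_json(log, file.path(dir, paste0(command, "_log.json")),
                       digits = NA, auto_unbox = TRUE, null = "null")
}

report_json <- function(obj, path, config) {
  payload <- list(schema = "tissueprint/report/1",
                  config_hash = attr(config, "hash") %||% config_hash(config),
                  report = obj)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Execute one workflow command
#'
#' The programmatic core behind the `tissueprint` command-line script. Each
#' command writes its artifacts into `config$io$dir` together with a run log
#' (config hash, seeds, package version, event counts in/out and QC
#' exclusions), so reruns with identical config and seeds reproduce
#' artifacts bit-identically.
#'
#' Commands: `simulate` (write a synthetic dataset), `preprocess` (QC +
#' normalize to a binned matrix), `fit` (train and serialize a model),
#' `predict` (classify a binned matrix with a stored model),
#' `crossvalidate`, `permute-control`, `pseudo-control`, `learning-curve`,
#' `sparse` (top features, annotation filter, sparse refit + side-by-side
#' CV), `report` (merge full and sparse reports into one comparison
#' document).
#'
#' @param name Command name.
#' @param config A `run_config` from [read_run_config()].
#' @return Invisible list of artifact paths.
#' @export
run_command <- function(name = c("simulate", "preprocess", "fit", "predict",
                                 "crossvalidate", "permute-control",
                                 "pseudo-control", "learning-curve",
                                 "sparse", "report"),
                        config = read_run_config()) {
  name <- match.arg(name)
  dir <- config$io$dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  load_fp <- function() {
    ds <- read_dataset(file.path(dir, "dataset"))
    qc <- qc_criteria(min_scans = config$qc$min_scans,
                      min_total_intensity = config$qc$min_total_intensity)
    preprocess_dataset(ds, qc = qc, normalization = config$normalization)
  }
  cv_call <- function(fp, labels, n_pc = config$model$n_pc, seed_off = 0) {
    crossvalidate(fp$x, labels, fp$manifest$specimen_id,
                  p = config$validation$p,
                  repeats = config$validation$repeats,
                  n_pc = n_pc,
                  threshold = config$validation$cv_threshold,
                  ridge = config$model$ridge,
                  seed = derive_seed(config$seeds$validate, seed_off))
  }
  report_from <- function(rep) {
    list(accuracy = rep$accuracy, kappa = rep$kappa,
         duty_cycle = rep$duty_cycle,
         sensitivity = as.list(rep$per_class_sensitivity),
         specificity = as.list(rep$per_class_specificity),
         auroc = as.list(rep$auroc_ovr),
         concordance = rep$concordance,
         unclassified_count = rep$unclassified_count,
         confusion_matrix = unclass(rep$confusion_matrix))
  }
  write_cm <- function(rep, path) {
    utils::write.csv(as.data.frame.matrix(rep$confusion_matrix), path)
  }

  if (name == "simulate") {
    ds <- if (identical(config$scenario, "custom")) {
      generate_dataset(do.call(synthetic_config,
                               c(config$generator,
                                 list(seed = config$seeds$simulate))))
    } else {
      generate_dataset(scenario_preset(config$scenario,
                                       seed = config$seeds$simulate))
    }
    write_dataset(ds, file.path(dir, "dataset"))
    out$dataset <- file.path(dir, "dataset")
    write_run_log(dir, name, config,
                  list(n_events = nrow(ds$manifest)))
  } else if (name == "preprocess") {
    fp <- load_fp()
    utils::write.csv(cbind(event_id = fp$manifest$event_id,
                           as.data.frame(fp$x)),
                     file.path(dir, "binned_matrix.csv"), row.names = FALSE)
    utils::write.csv(fp$qc_log, file.path(dir, "qc_log.csv"),
                     row.names = FALSE)
    out$matrix <- file.path(dir, "binned_matrix.csv")
    write_run_log(dir, name, config,
                  list(n_in = nrow(fp$qc_log), n_out = nrow(fp$x),
                       qc_excluded = sum(fp$qc_log$status == "fail")))
  } else if (name == "fit") {
    fp <- load_fp()
    model <- pcalda(fp$x, fp$manifest$class_label,
                    n_pc = config$model$n_pc, ridge = config$model$ridge)
    write_pcalda(model, file.path(dir, "model.json"))
    ld <- project_ld(model, fp$x)
    utils::write.csv(data.frame(event_id = fp$manifest$event_id, ld,
                                label = fp$manifest$class_label),
                     file.path(dir, "scores.csv"), row.names = FALSE)
    out$model <- file.path(dir, "model.json")
    write_run_log(dir, name, config,
                  list(n_events = nrow(fp$x), n_pc = model$n_pc))
  } else if (name == "predict") {
    fp <- load_fp()
    model <- read_pcalda(file.path(dir, "model.json"))
    pred <- predict(model, fp$x,
                    threshold = config$classification$threshold,
                    outlier_quantile = config$classification$outlier_quantile,
                    event_id = fp$manifest$event_id)
    utils::write.csv(pred, file.path(dir, "predictions.csv"),
                     row.names = FALSE)
    out$predictions <- file.path(dir, "predictions.csv")
    stats <- classification_statistics(pred, fp$manifest$class_label)
    write_run_log(dir, name, config,
                  list(duty_cycle = stats$duty_cycle,
                       accuracy = stats$accuracy))
  } else if (name == "crossvalidate") {
    fp <- load_fp()
    rep <- cv_call(fp, fp$manifest$class_label)
    report_json(report_from(rep), file.path(dir, "cv_report.json"), config)
    write_cm(rep, file.path(dir, "cv_confusion.csv"))
    out$report <- file.path(dir, "cv_report.json")
    write_run_log(dir, name, config, list(accuracy = rep$accuracy))
  } else if (name == "permute-control") {
    fp <- load_fp()
    perm <- permute_labels_mixed(fp$manifest$class_label,
                                 seed = derive_seed(config$seeds$validate, 77))
    rep <- cv_call(fp, perm, seed_off = 77)
    report_json(report_from(rep), file.path(dir, "permute_report.json"), config)
    write_cm(rep, file.path(dir, "permute_confusion.csv"))
    out$report <- file.path(dir, "permute_report.json")
    write_run_log(dir, name, config, list(accuracy = rep$accuracy))
  } else if (name == "pseudo-control") {
    fp <- load_fp()
    k <- max(2, length(unique(fp$manifest$class_label)))
    pseudo <- pseudo_classes(nrow(fp$x), k = k,
                             seed = derive_seed(config$seeds$validate, 88))
    rep <- cv_call(fp, pseudo, seed_off = 88)
    report_json(report_from(rep), file.path(dir, "pseudo_report.json"), config)
    out$report <- file.path(dir, "pseudo_report.json")
    write_run_log(dir, name, config, list(accuracy = rep$accuracy))
  } else if (name == "learning-curve") {
    fp <- load_fp()
    lc <- learning_curve(fp$x, fp$manifest$class_label,
                         fp$manifest$specimen_id,
                         usage_fractions = config$validation$usage_fractions,
                         p = config$validation$p,
                         threshold = config$validation$cv_threshold,
                         seed = config$seeds$validate)
    utils::write.csv(lc, file.path(dir, "learning_curve.csv"),
                     row.names = FALSE)
    out$curve <- file.path(dir, "learning_curve.csv")
    write_run_log(dir, name, config,
                  list(final_accuracy = lc$accuracy[nrow(lc)]))
  } else if (name == "sparse") {
    fp <- load_fp()
    model <- pcalda(fp$x, fp$manifest$class_label,
                    n_pc = config$model$n_pc, ridge = config$model$ridge)
    feats <- select_top_features(model, n = min(config$sparse$n_top,
                                                ncol(fp$x)))
    ann_path <- file.path(dir, "annotations.csv")
    retained <- if (file.exists(ann_path)) {
      ann <- utils::read.csv(ann_path, stringsAsFactors = FALSE)
      apply_annotations(feats, ann, keep = config$sparse$keep,
                        n_bins = ncol(fp$x))
    } else feats
    utils::write.csv(feats, file.path(dir, "top_features.csv"),
                     row.names = FALSE)
    sparse_model <- fit_sparse(fp$x, fp$manifest$class_label, retained$bin,
                               ridge = config$model$ridge)
    write_pcalda(sparse_model, file.path(dir, "sparse_model.json"))
    rep <- crossvalidate(fp$x[, sparse_model$bins, drop = FALSE],
                         fp$manifest$class_label, fp$manifest$specimen_id,
                         p = config$validation$p,
                         repeats = config$validation$repeats,
                         threshold = config$validation$cv_threshold,
                         ridge = config$model$ridge,
                         seed = config$seeds$validate)
    report_json(c(report_from(rep),
                  list(feature_set = retained$bin)),
                file.path(dir, "sparse_report.json"), config)
    out$report <- file.path(dir, "sparse_report.json")
    write_run_log(dir, name, config,
                  list(n_features = length(retained$bin),
                       accuracy = rep$accuracy))
  } else if (name == "report") {
    paths <- c(full = file.path(dir, "cv_report.json"),
               sparse = file.path(dir, "sparse_report.json"),
               permuted = file.path(dir, "permute_report.json"),
               pseudo = file.path(dir, "pseudo_report.json"))
    have <- paths[file.exists(paths)]
    if (!length(have)) stop("no reports found to merge", call. = FALSE)
    merged <- lapply(have, jsonlite::read_json)
    report_json(merged, file.path(dir, "combined_report.json"), config)
    out$report <- file.path(dir, "combined_report.json")
    write_run_log(dir, name, config, list(merged = names(have)))
  }
  invisible(out)
}
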