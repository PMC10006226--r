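#' Whole-pipeline configuration
#'
#' Bundles the per-stage settings. A `run_config` round-trips through YAML
#' ([write_run_config()] / [read_run_config()]) to an equivalent run.
#'
#' @param synthetic A [synthetic_config()] (used by the simulate stage; set
#'   `manifest` instead to run on existing data).
#' @param quantization A [quantization_config()].
#' @param glcm A [glcm_config()].
#' @param wavelet A [wavelet_config()].
#' @param classifier A [classifier_config()].
#' @param seed Seed for the classifier split (the synthetic stage uses the
#'   seed inside `synthetic`).
#' @param manifest Optional path to an existing manifest CSV; when given,
#'   the simulate stage is skipped and features are extracted from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       quantization = quantization_config(),
                       glcm = glcm_config(),
                       wavelet = wavelet_config(),
                       classifier = classifier_config(),
                       seed = 1L,
                       manifest = NULL) {
  structure(list(synthetic = synthetic, quantization = quantization,
                 glcm = glcm, wavelet = wavelet, classifier = classifier,
                 seed = as.integer(seed), manifest = manifest),
            class = "run_config")
}

#' Serialize / restore a run configuration (YAML)
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `path` (write); the restored `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  plain <- lapply(unclass(config), function(x) {
    if (is.list(x)) unclass(x) else x
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config(
    synthetic = do.call(synthetic_config, y$synthetic %||% list()),
    quantization = do.call(quantization_config, y$quantization %||% list()),
    glcm = do.call(glcm_config, y$glcm %||% list()),
    wavelet = do.call(wavelet_config, y$wavelet %||% list()),
    classifier = do.call(classifier_config, y$classifier %||% list()),
    seed = y$seed %||% 1L,
    manifest = y$manifest
  )
  cfg
}

#' Short hash identifying a run configuration
#'
#' MD5 of the YAML serialization, truncated to 8 hex digits; stamped into
#' every output the pipeline writes.
#'
#' @param config A [run_config()].
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  substr(unname(tools::md5sum(tmp)), 1, 8)
}

stage <- function(name, roi = NULL, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed",
         if (!is.null(roi)) paste0(" (ROI ", roi, ")"), ": ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the full texture-analysis pipeline
#'
#' simulate (or ingest an existing manifest) -> extract per-ROI features ->
#' compare groups -> train/evaluate classifiers. All stage outputs are
#' written under `out_dir`:
#' `manifest.csv` (+ `images/`, `masks/` when simulating), `features.csv`,
#' `group_summary.csv`, `classifier_report.csv`, `roc_points.csv` and
#' `run_log.txt`. Stages communicate via these files only, so real
#' micrographs can enter at the features stage by pointing `manifest` at
#' them. The whole run is reproducible from (config, seed).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest`, `features`, `summary`,
#'   `reports`, `hash` and the output paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir = "chromtex_run") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "run_log.txt")
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  cat("", file = log_path)
  logline("chromtex ", as.character(utils::packageVersion("chromtex")),
          " | R ", getRversion(), " | config ", hash,
          " | seed ", config$seed)

  if (is.null(config$manifest)) {
    manifest <- stage("simulate", expr = {
      logline("simulate: ", 2L * config$synthetic$n_per_class,
              " synthetic ROIs (seed ", config$synthetic$seed, ")")
      generate_dataset(config$synthetic, out_dir)
    })
  } else {
    manifest <- stage("ingest", expr = read_manifest(config$manifest))
    logline("ingest: ", nrow(manifest), " ROIs from ", config$manifest)
  }

  features <- stage("features", expr = {
    extract_features(manifest, config$quantization, config$glcm,
                     config$wavelet)
  })
  features_path <- file.path(out_dir, "features.csv")
  write_feature_table(features, features_path)
  logline("features: ", nrow(features), " x ", length(FEATURE_NAMES),
          " -> ", features_path, " [config ", hash, "]")

  summary <- stage("compare", expr = summarize_groups(features))
  summary_path <- file.path(out_dir, "group_summary.csv")
  write_group_summary(summary, summary_path)
  logline("compare: ", nrow(summary), " features -> ", summary_path)

  reports <- stage("classify", expr = {
    train_and_evaluate(features, seed = config$seed,
                       config = config$classifier)
  })
  report_df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(model = r$model, accuracy = r$accuracy, auc = r$auc,
               n_train = r$n_train, n_test = r$n_test, seed = r$seed,
               config = hash, stringsAsFactors = FALSE)
  }))
  report_path <- file.path(out_dir, "classifier_report.csv")
  utils::write.csv(report_df, report_path, row.names = FALSE, quote = FALSE)
  roc_df <- do.call(rbind, lapply(reports, function(r) {
    cbind(model = r$model, r$roc)
  }))
  roc_path <- file.path(out_dir, "roc_points.csv")
  utils::write.csv(roc_df, roc_path, row.names = FALSE, quote = FALSE)
  logline("classify: ", paste(sprintf("%s acc %.3f auc %.3f",
                                      report_df$model, report_df$accuracy,
                                      report_df$auc), collapse = "; "))

  invisible(list(manifest = manifest, features = features,
                 summary = summary, reports = reports, hash = hash,
                 paths = list(features = features_path,
                              summary = summary_path,
                              classifier = report_path, roc = roc_path,
                              log = log_path)))
}
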