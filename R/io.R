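# Feature-table I/O and the end-to-end experiment runner.

#' Read a labeled feature table
#'
#' Reads a comma-separated table (header required, "." decimal) with
#' numeric sensor-feature columns, a class-label column and an optional
#' batch column, into an [enose_dataset()].  Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param label_col Name of the label column; default `"label"`.
#' @param batch_col Name of the optional batch column; default `"batch"`.
#' @return An [enose_dataset()].
#' @export
read_feature_table <- function(path, label_col = "label",
                               batch_col = "batch") {
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop2("cannot read '", path, "': ",
                                           conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) == 0) stop2("empty feature table: ", path)
  if (!label_col %in% names(df))
    stop2("missing label column '", label_col, "' in ", path)
  batch <- if (batch_col %in% names(df)) df[[batch_col]] else NULL
  feat_cols <- setdiff(names(df), c(label_col, batch_col))
  if (length(feat_cols) == 0) stop2("no feature columns in ", path)
  for (cn in feat_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop2("non-numeric feature cell at row ", bad, ", column '", cn, "'")
    }
    if (anyNA(v))
      stop2("missing value at row ", which(is.na(v))[1],
            ", column '", cn, "'")
  }
  X <- as.matrix(df[, feat_cols, drop = FALSE])
  enose_dataset(X, df[[label_col]], batch = batch,
                meta = list(source = path))
}

#' Write a labeled feature table
#'
#' Writes the dataset as CSV with one column per sensor feature, a
#' `label` column and (if present) a `batch` column; round-trips through
#' [read_feature_table()].
#'
#' @param data An [enose_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  if (!inherits(data, "enose_dataset")) stop2("`data` must be an enose_dataset")
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Run a configured end-to-end experiment
#'
#' Executes simulate/load -> feature extraction -> evaluation protocol and
#' (optionally) writes the report tables, confusion matrices and a
#' reproducibility manifest to an output directory.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{data}{Path to a feature table, \emph{or}}
#'     \item{simulate}{List `list(type = "wound"|"drift", config = ...)`.}
#'     \item{method}{One of none/pca/lpp/fda/kfda/qwkfda.}
#'     \item{method_args}{Optional list of extractor hyperparameters.}
#'     \item{protocol}{List `list(type = "holdout", repeats, fraction)` or
#'       `list(type = "batch", train_batch)`.}
#'     \item{classifier}{Optional [classifier_spec()].}
#'     \item{seed}{Integer seed for the whole run.}
#'   }
#' @param out_dir Optional output directory (created if needed).
#' @return The `eval_report`, invisibly.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  seed <- config$seed %||% 1L
  data <- if (!is.null(config$data)) {
    read_feature_table(config$data)
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    switch(sim$type %||% "wound",
      wound = simulate_wound_dataset(sim$config %||% wound_sensor_config(),
                                     seed = seed),
      drift = simulate_drift_dataset(sim$config %||% drift_sensor_config(),
                                     seed = seed),
      stop2("unknown simulate type '", sim$type, "'"))
  } else stop2("config needs exactly one data source (`data` or `simulate`)")

  extractor <- do.call(extractor_spec,
                       c(list(method = config$method %||% "none"),
                         config$method_args %||% list()))
  classifier <- config$classifier %||% classifier_spec()
  proto <- config$protocol %||% list(type = "holdout")
  report <- switch(proto$type %||% "holdout",
    holdout = repeated_holdout_evaluate(
      data, extractor, classifier = classifier,
      repeats = proto$repeats %||% 10,
      fraction = proto$fraction %||% 0.5, seed = seed + 1L),
    batch = batch_transfer_evaluate(
      data, extractor, classifier = classifier,
      train_batch = proto$train_batch, seed = seed + 1L),
    stop2("unknown protocol type '", proto$type, "'"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      data.frame(run = seq_along(report$per_split_accuracy),
                 accuracy = report$per_split_accuracy),
      file.path(out_dir, "per_run_accuracy.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(mean_accuracy = report$mean_accuracy,
                 sd_accuracy = report$sd_accuracy),
      file.path(out_dir, "summary.csv"), row.names = FALSE)
    for (i in seq_along(report$confusions)) {
      nm <- names(report$confusions)[i] %||% as.character(i)
      if (is.null(names(report$confusions)) || nm == "") nm <- i
      utils::write.csv(as.data.frame.matrix(report$confusions[[i]]),
                       file.path(out_dir, paste0("confusion_", nm, ".csv")))
    }
    manifest <- list(
      method = extractor$method,
      method_args = config$method_args %||% list(),
      protocol = proto,
      seed = seed,
      data_source = config$data %||% paste0("simulate:",
                                            config$simulate$type %||% "wound"),
      r_version = R.version.string,
      package_version = as.character(utils::packageVersion("wkfda")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}

#' Reference confusion matrices from the e-nose literature
#'
#' Best-case 4-class wound-headspace confusion matrices reported for a
#' weighted-kernel discriminant with gaussian (n = 10), polynomial
#' (n = 7) and sigmoid (n = 10) base-kernel banks, shipped as a
#' plain-text fixture.  Rows follow the published orientation (class by
#' class with row totals `n`); [accuracy_from_confusion()] is
#' orientation-invariant.
#'
#' @return Named list of 4 x 4 count matrices
#'   (`gaussian`, `polynomial`, `sigmoid`).
#' @export
reference_confusion_matrices <- function() {
  path <- system.file("extdata", "reference_confusions.csv",
                      package = "wkfda", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (k in unique(df$kernel)) {
    sub <- df[df$kernel == k, ]
    sub <- sub[order(sub$class), ]
    m <- as.matrix(sub[, paste0("class_", 1:4)])
    dimnames(m) <- list(predicted = sub$class, truth = 1:4)
    out[[k]] <- m
  }
  out
}

#' Reference per-batch accuracy tables from the e-nose literature
#'
#' Published per-batch test accuracies (batches 2-5, batch 1 fixed for
#' training) for weighted-kernel discriminants with 2-10 gaussian /
#' polynomial / sigmoid base kernels, and for the control methods, on a
#' 4-gas drift benchmark; includes the published column averages
#' (`batch == "average"`).
#'
#' @return Data frame with columns `table` (gaussian / polynomial /
#'   sigmoid / controls), `setting` (number of base kernels, or control
#'   method name), `batch` (`"2"`..`"5"` or `"average"`), `accuracy` (%).
#' @export
reference_batch_accuracies <- function() {
  path <- system.file("extdata", "reference_batch_accuracies.csv",
                      package = "wkfda", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(table = "character",
                                 setting = "character",
                                 batch = "character",
                                 accuracy = "numeric"))
}
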