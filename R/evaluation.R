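# Evaluation protocols: stratified repeated hold-out with mean +/- SD,
# fixed-batch transfer across drifting sensor batches, confusion matrices
# and accuracy, with a pluggable feature extractor and classifier.

#' Specify the downstream classifier
#'
#' The evaluation protocols score feature extractors by the test accuracy
#' of a classifier trained on the extracted features.  The default is a
#' radial-basis support-vector machine (the usual choice for e-nose
#' pattern recognition), fitted via \pkg{e1071}; features are
#' standardized internally using training statistics.
#'
#' @param type Currently `"svm_radial"` or `"svm_linear"`.
#' @param cost Soft-margin cost parameter; default 10.
#' @param gamma RBF bandwidth; `NULL` uses 1/(number of features).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(type = c("svm_radial", "svm_linear"),
                            cost = 10, gamma = NULL) {
  type <- match.arg(type)
  if (cost <= 0) stop2("`cost` must be positive")
  structure(list(type = type, cost = cost, gamma = gamma),
            class = "classifier_spec")
}

.fit_classifier <- function(spec, X, y) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  kern <- if (spec$type == "svm_linear") "linear" else "radial"
  gamma <- spec$gamma %||% (1 / ncol(Xs))
  fit <- e1071::svm(x = Xs, y = y, kernel = kern, cost = spec$cost,
                    gamma = gamma, scale = FALSE)
  list(fit = fit, center = ctr, scale = scl, levels = levels(y))
}

.predict_classifier <- function(model, Z) {
  Z <- as.matrix(Z)
  Zs <- sweep(sweep(Z, 2, model$center), 2, model$scale, `/`)
  as.character(stats::predict(model$fit, Zs))
}

#' Specify a feature extractor
#'
#' A lightweight description of which dimensionality-reduction method to
#' fit on a training partition, dispatched internally by the evaluation
#' protocols.  `"none"` passes the raw features through (the no-extraction
#' control arm).
#'
#' @param method One of `"none"`, `"pca"`, `"lpp"`, `"fda"`, `"kfda"`,
#'   `"qwkfda"`.
#' @param ... Method hyperparameters: `n_components` (all methods;
#'   defaults to 3, capped at C - 1 for the discriminant methods),
#'   `k_neighbors` / `heat_t` (lpp), `kernel` (kfda), `config` (qwkfda, a
#'   [qwkfda_config()]).
#' @return An object of class `extractor_spec`.
#' @export
extractor_spec <- function(method = c("none", "pca", "lpp", "fda", "kfda",
                                      "qwkfda"), ...) {
  method <- match.arg(method)
  structure(list(method = method, args = list(...)),
            class = "extractor_spec")
}

.fit_extractor <- function(spec, X, labels) {
  a <- spec$args
  C <- nlevels(droplevels(as.factor(labels)))
  ncmp_lin <- a$n_components %||% 3L
  ncmp_dis <- min(a$n_components %||% 3L, C - 1L)
  model <- switch(spec$method,
    none = structure(list(), class = "identity_extractor"),
    pca  = fit_pca(X, n_components = ncmp_lin),
    lpp  = fit_lpp(X, n_components = ncmp_lin,
                   k_neighbors = a$k_neighbors %||% 5,
                   heat_t = a$heat_t),
    fda  = fit_fda(X, labels, n_components = ncmp_dis),
    kfda = fit_kfda(X, labels, kernel = a$kernel,
                    n_components = ncmp_dis),
    qwkfda = fit_qwkfda(X, labels, config = a$config %||% qwkfda_config()))
  model
}

.transform_extractor <- function(model, Z) {
  if (inherits(model, "identity_extractor")) return(as.matrix(Z))
  stats::predict(model, Z)
}

#' Stratified random hold-out split
#'
#' Splits sample indices into disjoint train/test sets, stratified by
#' class: per class, `round(fraction * N_c)` samples (at least 1, at most
#' N_c - 1) go to training.
#'
#' @param labels Class labels.
#' @param fraction Training fraction in (0, 1); default 0.5.
#' @param seed Optional seed for a reproducible split.
#' @return List with integer index vectors `train` and `test`.
#' @export
holdout_split <- function(labels, fraction = 0.5, seed = NULL) {
  labels <- droplevels(as.factor(labels))
  if (fraction <= 0 || fraction >= 1) stop2("`fraction` must be in (0, 1)")
  with_seed(seed, {
    train <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 2)
        stop2("class '", cl, "' has fewer than 2 samples; cannot split")
      n_tr <- min(max(round(fraction * length(idx)), 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

# stratified fold assignment for cross-validation
.stratified_folds <- function(labels, k) {
  labels <- droplevels(as.factor(labels))
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Confusion matrix of predictions
#'
#' Cross-tabulates predictions against truth with rows = predicted class
#' and columns = true class, over the union of observed labels (or an
#' explicit level set).
#'
#' @param predicted,truth Vectors of class labels.
#' @param labels Optional explicit level ordering.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(predicted, truth, labels = NULL) {
  labels <- labels %||% sort(unique(c(as.character(predicted),
                                      as.character(truth))))
  cm <- table(factor(as.character(predicted), levels = labels),
              factor(as.character(truth), levels = labels))
  out <- matrix(as.integer(cm), nrow = length(labels),
                dimnames = list(predicted = labels, truth = labels))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Overall accuracy from a confusion matrix
#'
#' Sum of the diagonal over the total count, as a percentage.  The result
#' is invariant to transposing the matrix, so either axis convention for
#' predicted vs. true gives the same accuracy.
#'
#' @param cm Square count matrix.
#' @return Accuracy in percent.
#' @export
accuracy_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop2("confusion matrix must be square")
  if (any(cm < 0)) stop2("confusion counts must be nonnegative")
  total <- sum(cm)
  if (total == 0) stop2("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Mean and standard deviation of a set of accuracies
#'
#' Arithmetic mean with the sample (n - 1 denominator) standard
#' deviation; a single value has SD 0.
#'
#' @param values Numeric vector, length >= 1.
#' @return List with `mean` and `sd`.
#' @examples
#' mean_sd(c(93.75, 96.875, 100, 75))  # mean 91.40625
#' @export
mean_sd <- function(values) {
  if (length(values) < 1) stop2("`values` must be non-empty")
  list(mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else 0)
}

.new_eval_report <- function(per_split_accuracy, confusions, method,
                             per_batch_accuracy = NULL) {
  ms <- mean_sd(per_split_accuracy)
  structure(list(per_split_accuracy = per_split_accuracy,
                 mean_accuracy = ms$mean,
                 sd_accuracy = ms$sd,
                 per_batch_accuracy = per_batch_accuracy,
                 confusions = confusions,
                 method = method),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s>\n", x$method))
  cat(sprintf("  accuracy %s +/- %s%% over %d run(s)\n",
              format(round_half_up(x$mean_accuracy, 2), nsmall = 2),
              format(round_half_up(x$sd_accuracy, 2), nsmall = 2),
              length(x$per_split_accuracy)))
  if (!is.null(x$per_batch_accuracy)) {
    cat("  per-batch accuracy (%):\n")
    print(round_half_up(x$per_batch_accuracy, 2))
  }
  invisible(x)
}

#' Repeated stratified hold-out evaluation
#'
#' The protocol for single-batch data: repeat `repeats` times a
#' stratified `fraction`/(1 - `fraction`) split, fit the extractor on the
#' training partition only, train the classifier on the extracted
#' training features, predict the test partition, and record accuracy and
#' the confusion matrix; report the per-split accuracies with their mean
#' and SD.  The extractor never sees test samples.
#'
#' @param data An [enose_dataset()], or a list with elements `X` and
#'   `labels`.
#' @param extractor An [extractor_spec()].
#' @param classifier A [classifier_spec()]; default RBF SVM.
#' @param repeats Number of random splits; default 10.
#' @param fraction Training fraction; default 0.5.
#' @param seed Seed making the whole protocol (splits and any stochastic
#'   extractor fitting) reproducible.
#' @return An `eval_report`.
#' @export
repeated_holdout_evaluate <- function(data, extractor,
                                      classifier = classifier_spec(),
                                      repeats = 10, fraction = 0.5,
                                      seed = NULL) {
  X <- .as_sample_matrix(data$X)
  labels <- droplevels(as.factor(data$labels))
  if (repeats < 1) stop2("`repeats` must be >= 1")
  with_seed(seed, {
    acc <- numeric(repeats)
    confusions <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      sp <- holdout_split(labels, fraction)
      Xtr <- X[sp$train, , drop = FALSE]
      ytr <- labels[sp$train]
      Xte <- X[sp$test, , drop = FALSE]
      yte <- labels[sp$test]
      ext <- .fit_extractor(extractor, Xtr, ytr)
      Ftr <- .transform_extractor(ext, Xtr)
      Fte <- .transform_extractor(ext, Xte)
      clf <- .fit_classifier(classifier, Ftr, ytr)
      pred <- .predict_classifier(clf, Fte)
      cm <- confusion_matrix(pred, yte, labels = levels(labels))
      confusions[[r]] <- cm
      acc[r] <- accuracy_from_confusion(cm)
    }
    .new_eval_report(acc, confusions, extractor$method)
  })
}

#' Fixed-batch transfer evaluation
#'
#' The protocol for multi-batch (drifting) data: fit the extractor and
#' classifier once on the designated training batch, then report one test
#' accuracy per remaining batch plus their arithmetic mean.  Degradation
#' on later batches measures sensitivity to sensor drift.
#'
#' @param data An [enose_dataset()] with a `batch` field, or a list with
#'   `X`, `labels`, `batch`.
#' @param extractor An [extractor_spec()].
#' @param classifier A [classifier_spec()].
#' @param train_batch Batch id used for training; default the first batch.
#' @param seed Optional seed (stochastic extractors).
#' @return An `eval_report` whose `per_batch_accuracy` is a named vector
#'   of test accuracies and whose mean is their average.
#' @export
batch_transfer_evaluate <- function(data, extractor,
                                    classifier = classifier_spec(),
                                    train_batch = NULL, seed = NULL) {
  X <- .as_sample_matrix(data$X)
  labels <- droplevels(as.factor(data$labels))
  batch <- data$batch
  if (is.null(batch)) stop2("`data` has no batch labels")
  batch <- as.character(batch)
  ids <- unique(batch)
  if (length(ids) < 2) stop2("need at least two batches")
  train_batch <- as.character(train_batch %||% ids[1])
  if (!train_batch %in% ids)
    stop2("unknown training batch id '", train_batch, "'")
  with_seed(seed, {
    tr <- batch == train_batch
    ext <- .fit_extractor(extractor, X[tr, , drop = FALSE], labels[tr])
    Ftr <- .transform_extractor(ext, X[tr, , drop = FALSE])
    clf <- .fit_classifier(classifier, Ftr, labels[tr])
    test_ids <- setdiff(ids, train_batch)
    acc <- numeric(length(test_ids))
    confusions <- vector("list", length(test_ids))
    for (i in seq_along(test_ids)) {
      te <- batch == test_ids[i]
      Fte <- .transform_extractor(ext, X[te, , drop = FALSE])
      pred <- .predict_classifier(clf, Fte)
      cm <- confusion_matrix(pred, labels[te], labels = levels(labels))
      confusions[[i]] <- cm
      acc[i] <- accuracy_from_confusion(cm)
    }
    names(acc) <- test_ids
    names(confusions) <- test_ids
    .new_eval_report(acc, confusions, extractor$method,
                     per_batch_accuracy = acc)
  })
}

#' Compare feature-extraction methods under repeated hold-out
#'
#' Convenience harness running [repeated_holdout_evaluate()] for several
#' extraction methods on the same dataset and seed, so the per-method
#' mean accuracies are directly comparable (the typical bar-chart
#' comparison of PCA / LPP / FDA / KFDA / weighted-kernel FDA).
#'
#' @param data An [enose_dataset()].
#' @param extractors Named list of [extractor_spec()] objects; default
#'   covers none/pca/lpp/fda/kfda/qwkfda with a desk-scale QWKFDA search
#'   ([qwkfda_config()] with a small swarm; see the methods vignette).
#' @param classifier A [classifier_spec()].
#' @param repeats,fraction,seed As in [repeated_holdout_evaluate()].
#' @return List with `mean_accuracy` (named vector, %), `sd_accuracy`,
#'   and the full `reports`.
#' @export
compare_extraction_methods <- function(data, extractors = NULL,
                                       classifier = classifier_spec(),
                                       repeats = 10, fraction = 0.5,
                                       seed = NULL) {
  extractors <- extractors %||% default_method_suite()
  if (is.null(names(extractors)) || any(names(extractors) == ""))
    stop2("`extractors` must be a named list")
  reports <- vector("list", length(extractors))
  names(reports) <- names(extractors)
  for (i in seq_along(extractors)) {
    reports[[i]] <- repeated_holdout_evaluate(
      data, extractors[[i]], classifier = classifier,
      repeats = repeats, fraction = fraction,
      seed = if (is.null(seed)) NULL else seed + 1000L * i)
  }
  list(mean_accuracy = vapply(reports, `[[`, numeric(1), "mean_accuracy"),
       sd_accuracy = vapply(reports, `[[`, numeric(1), "sd_accuracy"),
       reports = reports)
}

#' Default suite of extractors for method comparison
#'
#' PCA, LPP, FDA, plain gaussian-kernel KFDA, and QPSO-tuned weighted
#' kernel FDA with a desk-scale search budget (3 gaussian bases, swarm 8,
#' 12 iterations).
#'
#' @return Named list of [extractor_spec()] objects.
#' @export
default_method_suite <- function() {
  list(
    pca  = extractor_spec("pca"),
    lpp  = extractor_spec("lpp"),
    fda  = extractor_spec("fda"),
    kfda = extractor_spec("kfda"),
    qwkfda = extractor_spec("qwkfda", config = qwkfda_config(
      kernel_family = "gaussian", n_bases = 3,
      qpso = list(swarm_size = 10, max_iters = 15, patience = 8),
      cv_folds = 5)))
}
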