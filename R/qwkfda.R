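# QPSO-tuned weighted-kernel Fisher discriminant analysis: a swarm search
# over the mixing weights (and optionally the base-kernel parameters) of a
# composite kernel, scored by stratified cross-validated classification
# accuracy of the KFDA -> SVM pipeline on the training partition.

#' Configuration of the weighted-kernel search
#'
#' @param kernel_family Family of the base-kernel bank: `"gaussian"`,
#'   `"polynomial"` or `"sigmoid"`.
#' @param n_bases Number of base kernels n (>= 1); the composite kernel is
#'   \eqn{\sum_m p_m k_m}.
#' @param optimize_kernel_params If `TRUE` (default) the search vector
#'   also carries one kernel parameter per base (gaussian: log2 sigma2;
#'   polynomial: the offset c1, degrees stay fixed at 1..n; sigmoid: log10
#'   beta0); if `FALSE` only the weights are searched and the bank keeps
#'   its grid parameters ([default_kernel_bank()]).
#' @param param_bounds Length-2 bounds for the per-base parameter on its
#'   search scale; defaults: gaussian `c(-4, 4)` (log2 sigma2),
#'   polynomial `c(0, 3)` (c1), sigmoid `c(-3, 1)` (log10 beta0).
#' @param cv_folds Stratified folds for the fitness; default 5.
#' @param cv_repeats Number of independent fold assignments averaged in
#'   the fitness (repeated cross-validation); default 1.  More repeats
#'   reduce selection noise at proportional cost.
#' @param n_components Discriminants extracted inside the fitness and by
#'   the final fit; default `min(3, C - 1)` at fit time.
#' @param classifier [classifier_spec()] scoring the folds.
#' @param qpso Either a [qpso_config()] (its bounds are replaced by the
#'   search-vector bounds) or a list of overrides for the defaults
#'   (swarm 20, 100 iterations, beta 1.0 -> 0.5, patience 20).
#' @return An object of class `qwkfda_config`.
#' @export
qwkfda_config <- function(kernel_family = c("gaussian", "polynomial",
                                            "sigmoid"),
                          n_bases = 4, optimize_kernel_params = TRUE,
                          param_bounds = NULL, cv_folds = 5,
                          cv_repeats = 1,
                          n_components = NULL,
                          classifier = classifier_spec(),
                          qpso = list()) {
  kernel_family <- match.arg(kernel_family)
  if (n_bases < 1) stop2("`n_bases` must be >= 1")
  if (cv_folds < 2) stop2("`cv_folds` must be >= 2")
  if (cv_repeats < 1) stop2("`cv_repeats` must be >= 1")
  param_bounds <- param_bounds %||% switch(kernel_family,
    gaussian = c(-4, 4), polynomial = c(0, 3), sigmoid = c(-3, 1))
  if (length(param_bounds) != 2 || param_bounds[1] >= param_bounds[2])
    stop2("`param_bounds` must be an increasing length-2 vector")
  if (inherits(qpso, "qpso_config")) qpso <- unclass(qpso)["bounds" != names(unclass(qpso))]
  qpso_defaults <- list(swarm_size = 20, max_iters = 100,
                        beta_start = 1.0, beta_end = 0.5, seed = NULL,
                        patience = 20)
  qpso <- utils::modifyList(qpso_defaults, qpso[names(qpso) %in%
                                                  names(qpso_defaults)])
  structure(list(kernel_family = kernel_family,
                 n_bases = as.integer(n_bases),
                 optimize_kernel_params = isTRUE(optimize_kernel_params),
                 param_bounds = as.numeric(param_bounds),
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 n_components = n_components,
                 classifier = classifier,
                 qpso = qpso),
            class = "qwkfda_config")
}

#' Default bank of base kernels
#'
#' The grid used when base-kernel parameters are not searched and as the
#' reference initialization of the parameter search: gaussian length
#' scales on the geometric grid \eqn{\sigma^2 \in 2^{-3} \dots 2^{3}}
#' spread over n points; polynomial degrees 1..n with c0 = c1 = 1;
#' sigmoid slopes \eqn{\beta_0 \in 10^{-2} \dots 10^{0}} with
#' \eqn{\beta_1 = -1}.
#'
#' @param family Kernel family.
#' @param n_bases Number of base kernels.
#' @return A list of [kernel_spec()] objects.
#' @export
default_kernel_bank <- function(family = c("gaussian", "polynomial",
                                           "sigmoid"), n_bases) {
  family <- match.arg(family)
  n <- as.integer(n_bases)
  if (n < 1) stop2("`n_bases` must be >= 1")
  switch(family,
    gaussian = {
      s2 <- if (n == 1) 1 else 2^seq(-3, 3, length.out = n)
      lapply(s2, function(s) kernel_spec("gaussian", sigma2 = s))
    },
    polynomial = lapply(seq_len(n), function(d)
      kernel_spec("polynomial", c0 = 1, c1 = 1, degree = d)),
    sigmoid = {
      b0 <- if (n == 1) 0.1 else 10^seq(-2, 0, length.out = n)
      lapply(b0, function(b) kernel_spec("sigmoid", beta0 = b, beta1 = -1))
    })
}

# bounds of the QPSO search vector: n weights in [0,1], optionally n
# kernel parameters on their search scale
.search_bounds <- function(config) {
  n <- config$n_bases
  b <- cbind(rep(0, n), rep(1, n))
  if (config$optimize_kernel_params)
    b <- rbind(b, cbind(rep(config$param_bounds[1], n),
                        rep(config$param_bounds[2], n)))
  b
}

#' Decode a search vector into a composite kernel
#'
#' The first `n_bases` entries are the (nonnegative, normalized on
#' construction) mixing weights; when kernel parameters are searched the
#' next `n_bases` entries set the per-base parameter on its search scale.
#' Out-of-bounds entries are clipped.  An all-zero weight block is a
#' degenerate composite kernel and raises an error.
#'
#' @param vec Numeric search vector of length `n_bases` or `2 * n_bases`.
#' @param config A [qwkfda_config()].
#' @return A [composite_kernel()] specification.
#' @export
decode_search_vector <- function(vec, config) {
  n <- config$n_bases
  expected <- if (config$optimize_kernel_params) 2L * n else n
  if (length(vec) != expected)
    stop2("search vector must have length ", expected)
  b <- .search_bounds(config)
  vec <- pmin(pmax(vec, b[, 1]), b[, 2])
  w <- vec[seq_len(n)]
  if (config$optimize_kernel_params) {
    pars <- vec[n + seq_len(n)]
    bases <- switch(config$kernel_family,
      gaussian = lapply(pars, function(p)
        kernel_spec("gaussian", sigma2 = 2^p)),
      polynomial = lapply(seq_len(n), function(m)
        kernel_spec("polynomial", c0 = 1, c1 = pars[m], degree = m)),
      sigmoid = lapply(pars, function(p)
        kernel_spec("sigmoid", beta0 = 10^p, beta1 = -1)))
  } else {
    bases <- default_kernel_bank(config$kernel_family, n)
  }
  composite_kernel(bases, w)
}

#' Encode a composite kernel as a search vector
#'
#' Inverse of [decode_search_vector()] for kernels representable within
#' the configured family and bounds; `decode(encode(k))` reproduces the
#' normalized weights and parameters.
#'
#' @param ck A [composite_kernel()] of the configured family and size.
#' @param config A [qwkfda_config()].
#' @return Numeric search vector.
#' @export
encode_search_vector <- function(ck, config) {
  n <- config$n_bases
  if (length(ck$bases) != n) stop2("kernel bank size mismatch")
  if (!all(vapply(ck$bases, function(b) b$family, character(1)) ==
             config$kernel_family))
    stop2("kernel family mismatch")
  v <- ck$weights
  if (config$optimize_kernel_params) {
    pars <- switch(config$kernel_family,
      gaussian = vapply(ck$bases, function(b) log2(b$params$sigma2),
                        numeric(1)),
      polynomial = vapply(ck$bases, function(b) b$params$c1, numeric(1)),
      sigmoid = vapply(ck$bases, function(b) log10(b$params$beta0),
                       numeric(1)))
    v <- c(v, pars)
  }
  v
}

# Warm starts seeded into the swarm: the equally weighted default grid
# bank, and (gaussian family) a single base at the median-squared-distance
# length scale -- the plain-KFDA heuristic -- so the search always
# considers its own sensible initialization.
.warm_starts <- function(X, config) {
  n <- config$n_bases
  grid <- composite_kernel(default_kernel_bank(config$kernel_family, n),
                           rep(1, n))
  starts <- matrix(encode_search_vector(grid, config), nrow = 1)
  if (config$kernel_family == "gaussian" && config$optimize_kernel_params) {
    s2 <- stats::median(stats::dist(X)^2)
    if (is.finite(s2) && s2 > 0) {
      v <- c(c(1, rep(0, n - 1)), rep(log2(s2), n))
      starts <- rbind(starts, v)
    }
  }
  starts[, ] <- pmin(pmax(starts, rep(.search_bounds(config)[, 1],
                                      each = nrow(starts))),
                     rep(.search_bounds(config)[, 2], each = nrow(starts)))
  starts
}

# Cross-validated fitness of a candidate kernel: 1 - mean stratified CV
# accuracy of [KFDA projection -> SVM] on the training data only,
# averaged over one or more fixed fold assignments (`folds` is a matrix
# with one assignment per column).  Any failure (degenerate kernel,
# eigen-solver breakdown in a fold) scores the worst possible fitness so
# the swarm moves on.
qwkfda_fitness <- function(vec, X, labels, config, folds) {
  tryCatch({
    kernel <- decode_search_vector(vec, config)
    C <- nlevels(labels)
    ncmp <- min(config$n_components %||% 3L, C - 1L)
    folds <- as.matrix(folds)
    accs <- numeric(0)
    for (r in seq_len(ncol(folds))) {
      fr <- folds[, r]
      for (f in seq_len(max(fr))) {
        tr <- fr != f
        fit <- fit_kfda(X[tr, , drop = FALSE], labels[tr], kernel = kernel,
                        n_components = ncmp)
        Ftr <- project_training(fit)
        Fte <- stats::predict(fit, X[!tr, , drop = FALSE])
        clf <- .fit_classifier(config$classifier, Ftr, labels[tr])
        pred <- .predict_classifier(clf, Fte)
        accs <- c(accs, mean(pred == as.character(labels[!tr])))
      }
    }
    1 - mean(accs)
  }, error = function(e) 1)
}

#' Fit a QPSO-tuned weighted-kernel Fisher discriminant
#'
#' Runs the QPSO search over the composite-kernel mixing weights (and,
#' by default, the base-kernel parameters), scoring each candidate by
#' stratified `cv_folds`-fold cross-validated accuracy of the
#' KFDA-projection-plus-SVM pipeline on the training data, then refits
#' KFDA on the full training set with the best kernel found.  No test
#' data is consumed: model selection is internal to the training
#' partition.
#'
#' @param X Training sample matrix.
#' @param labels Class labels.
#' @param config A [qwkfda_config()].
#' @param seed Optional seed covering the fold assignment and the swarm;
#'   a fixed seed makes the fit fully reproducible.
#' @return Object of class `qwkfda` with elements `kfda` (the final
#'   [fit_kfda()] model), `kernel` (best composite kernel),
#'   `optimization` (the [qpso_optimize()] result, whose `history` is the
#'   fitness trace), `cv_accuracy` (best cross-validated accuracy, %),
#'   and `config`.
#' @export
fit_qwkfda <- function(X, labels, config = qwkfda_config(), seed = NULL) {
  if (!inherits(config, "qwkfda_config"))
    stop2("`config` must be a qwkfda_config")
  X <- .as_sample_matrix(X)
  labels <- droplevels(as.factor(labels))
  with_seed(seed, {
    folds <- vapply(seq_len(config$cv_repeats), function(i)
      .stratified_folds(labels, config$cv_folds),
      integer(length(labels)))
    bounds <- .search_bounds(config)
    qcfg <- do.call(qpso_config,
                    c(list(bounds = bounds,
                           init_positions = .warm_starts(X, config)),
                      config$qpso))
    objective <- function(v) qwkfda_fitness(v, X, labels, config, folds)
    opt <- qpso_optimize(objective, qcfg)
    kernel <- decode_search_vector(opt$best_position, config)
    C <- nlevels(labels)
    ncmp <- min(config$n_components %||% 3L, C - 1L)
    final <- fit_kfda(X, labels, kernel = kernel, n_components = ncmp)
    structure(list(kfda = final, kernel = kernel, optimization = opt,
                   cv_accuracy = 100 * (1 - opt$best_fitness),
                   config = config),
              class = "qwkfda")
  })
}

#' @export
print.qwkfda <- function(x, ...) {
  cat(sprintf("<qwkfda: %s family, %d base kernel(s), CV accuracy %.2f%%>\n",
              x$config$kernel_family, x$config$n_bases, x$cv_accuracy))
  print(x$kernel)
  invisible(x)
}

#' Project samples with a fitted weighted-kernel discriminant
#'
#' @param object A [fit_qwkfda()] model.
#' @param newdata Sample matrix.
#' @param ... Unused.
#' @return Score matrix (rows = samples).
#' @export
predict.qwkfda <- function(object, newdata, ...) {
  stats::predict(object$kfda, newdata)
}

#' Sweep the number and family of base kernels
#'
#' Reproduces the experimental design that varies the base-kernel family
#' and the number of base kernels n, evaluating each configuration with
#' either the repeated hold-out protocol (mean +/- SD accuracy) or the
#' fixed-batch transfer protocol (per-batch accuracies and their mean).
#'
#' @param data An [enose_dataset()].
#' @param families Character vector of kernel families to sweep.
#' @param n_bases Integer vector of bank sizes (e.g. `2:10`).
#' @param protocol `"holdout"` or `"batch"`.
#' @param config_template A [qwkfda_config()] supplying everything except
#'   family and n_bases.
#' @param repeats,fraction Hold-out protocol settings.
#' @param train_batch Batch-transfer training batch.
#' @param classifier A [classifier_spec()].
#' @param seed Base seed.
#' @return A data frame with one row per (family, n) and columns
#'   `mean_accuracy`, `sd_accuracy` (hold-out) or per-batch accuracy
#'   columns plus `mean_accuracy` (batch transfer).
#' @export
sweep_base_kernels <- function(data, families = c("gaussian", "polynomial",
                                                  "sigmoid"),
                               n_bases = 2:10,
                               protocol = c("holdout", "batch"),
                               config_template = NULL,
                               repeats = 10, fraction = 0.5,
                               train_batch = NULL,
                               classifier = classifier_spec(),
                               seed = 1) {
  protocol <- match.arg(protocol)
  tmpl <- config_template %||% qwkfda_config(
    qpso = list(swarm_size = 8, max_iters = 12, patience = 6),
    cv_folds = 3)
  rows <- list()
  for (fam in families) {
    for (n in n_bases) {
      cfg <- tmpl
      cfg$kernel_family <- fam
      cfg$n_bases <- as.integer(n)
      ex <- extractor_spec("qwkfda", config = cfg)
      rep_seed <- seed + 17L * n + 1000L * match(fam, families)
      if (protocol == "holdout") {
        r <- repeated_holdout_evaluate(data, ex, classifier = classifier,
                                       repeats = repeats,
                                       fraction = fraction,
                                       seed = rep_seed)
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, n_bases = n,
          mean_accuracy = r$mean_accuracy, sd_accuracy = r$sd_accuracy)
      } else {
        r <- batch_transfer_evaluate(data, ex, classifier = classifier,
                                     train_batch = train_batch,
                                     seed = rep_seed)
        row <- data.frame(family = fam, n_bases = n,
                          mean_accuracy = r$mean_accuracy)
        for (b in names(r$per_batch_accuracy))
          row[[paste0("batch_", b)]] <- unname(r$per_batch_accuracy[b])
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}
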