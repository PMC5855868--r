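# Base kernels, weighted composite kernels, Gram matrices, centering and
# positive-semidefiniteness checks.  Everything downstream (KFDA, the
# QPSO-tuned weighted kernel) flows through the Gram matrices built here;
# the feature map is never materialized.

#' Specify a base kernel
#'
#' Constructs a validated specification of one of the three kernel families
#' commonly used for chemosensor data:
#' \describe{
#'   \item{gaussian}{\eqn{k(x,z) = \exp(-\|x-z\|^2 / \sigma^2)} with squared
#'     length-scale `sigma2` > 0.}
#'   \item{polynomial}{\eqn{k(x,z) = (c_0 \langle x,z\rangle + c_1)^d} with
#'     integer degree `degree` >= 1.}
#'   \item{sigmoid}{\eqn{k(x,z) = \tanh(\beta_0 \langle x,z\rangle + \beta_1)}.
#'     Not positive semidefinite for all parameter values; accepted anyway
#'     (see [check_psd()]).}
#' }
#'
#' @param family One of `"gaussian"`, `"polynomial"`, `"sigmoid"`.
#' @param ... Family parameters: `sigma2` (gaussian); `c0`, `c1`, `degree`
#'   (polynomial); `beta0`, `beta1` (sigmoid).  Unspecified parameters take
#'   the defaults `sigma2 = 1`, `c0 = 1`, `c1 = 1`, `degree = 2`,
#'   `beta0 = 0.1`, `beta1 = -1`.
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("gaussian", sigma2 = 2)
#' kernel_spec("polynomial", c0 = 1, c1 = 0, degree = 1)  # linear kernel
#' @export
kernel_spec <- function(family = c("gaussian", "polynomial", "sigmoid"), ...) {
  family <- match.arg(family)
  supplied <- list(...)
  defaults <- switch(family,
    gaussian   = list(sigma2 = 1),
    polynomial = list(c0 = 1, c1 = 1, degree = 2),
    sigmoid    = list(beta0 = 0.1, beta1 = -1))
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown) > 0 || (length(supplied) > 0 && is.null(names(supplied))))
    stop2("unknown parameter(s) for ", family, " kernel: ",
          paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, supplied)
  if (!all(vapply(params, function(p) is.numeric(p) && length(p) == 1 &&
                    is.finite(p), logical(1))))
    stop2("kernel parameters must be finite scalars")
  if (family == "gaussian" && params$sigma2 <= 0)
    stop2("gaussian kernel requires sigma2 > 0")
  if (family == "polynomial") {
    if (params$degree < 1 || params$degree != round(params$degree))
      stop2("polynomial kernel requires integer degree >= 1")
    params$degree <- as.integer(params$degree)
  }
  structure(list(family = family, params = params), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec: %s (%s)>\n", x$family,
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Specify a weighted composite kernel
#'
#' A composite kernel is the weighted sum \eqn{k(x,z) = \sum_m p_m k_m(x,z)}
#' of a bank of base kernels.  Nonnegative combinations of Mercer kernels
#' are again Mercer kernels, so the composite inherits validity from its
#' bases.  Weights are clipped to be nonnegative and rescaled to sum to one
#' on construction: the Fisher criterion is invariant to positive rescaling
#' of the kernel, so the overall scale of `weights` is a spurious degree of
#' freedom.
#'
#' @param bases A list of [kernel_spec()] objects (a single `kernel_spec`
#'   is promoted to a one-element bank).
#' @param weights Numeric vector of mixing weights, one per base; at least
#'   one must be positive.
#' @return An object of class `composite_kernel_spec` with normalized
#'   `weights`.
#' @examples
#' composite_kernel(list(kernel_spec("gaussian", sigma2 = 0.5),
#'                       kernel_spec("gaussian", sigma2 = 2)), c(1, 3))
#' @export
composite_kernel <- function(bases, weights = NULL) {
  if (inherits(bases, "kernel_spec")) bases <- list(bases)
  if (!is.list(bases) || length(bases) < 1 ||
      !all(vapply(bases, inherits, logical(1), "kernel_spec")))
    stop2("`bases` must be a non-empty list of kernel_spec objects")
  n <- length(bases)
  if (is.null(weights)) weights <- rep(1, n)
  if (!is.numeric(weights) || length(weights) != n || anyNA(weights))
    stop2("`weights` must be a numeric vector with one entry per base")
  w <- pmax(weights, 0)
  if (sum(w) <= 0)
    stop2("degenerate composite kernel: all weights are zero")
  structure(list(bases = bases, weights = w / sum(w)),
            class = "composite_kernel_spec")
}

#' @export
print.composite_kernel_spec <- function(x, ...) {
  cat(sprintf("<composite_kernel_spec: %d base(s)>\n", length(x$bases)))
  for (i in seq_along(x$bases))
    cat(sprintf("  p=%.4f  %s (%s)\n", x$weights[i], x$bases[[i]]$family,
                paste(names(x$bases[[i]]$params),
                      unlist(x$bases[[i]]$params), sep = "=",
                      collapse = ", ")))
  invisible(x)
}

as_composite_kernel <- function(kernel) {
  if (inherits(kernel, "composite_kernel_spec")) return(kernel)
  if (inherits(kernel, "kernel_spec")) return(composite_kernel(kernel, 1))
  stop2("`kernel` must be a kernel_spec or composite_kernel_spec")
}

#' Evaluate a base kernel at a pair of points
#'
#' @param spec A [kernel_spec()].
#' @param x,z Numeric vectors of equal length.
#' @return The scalar kernel value \eqn{k(x, z)}.
#' @examples
#' kernel_eval(kernel_spec("gaussian", sigma2 = 2), c(0, 0), c(1, 1))
#' @export
kernel_eval <- function(spec, x, z) {
  if (!inherits(spec, "kernel_spec")) stop2("`spec` must be a kernel_spec")
  if (!is.numeric(x) || !is.numeric(z)) stop2("inputs must be numeric")
  if (length(x) != length(z))
    stop2("dimension mismatch: length(x) = ", length(x),
          ", length(z) = ", length(z))
  if (!all(is.finite(x)) || !all(is.finite(z)))
    stop2("non-finite values in kernel inputs")
  p <- spec$params
  switch(spec$family,
    gaussian   = exp(-sum((x - z)^2) / p$sigma2),
    polynomial = (p$c0 * sum(x * z) + p$c1)^p$degree,
    sigmoid    = tanh(p$beta0 * sum(x * z) + p$beta1))
}

# Gram matrix of a single base kernel; exact symmetry by mirroring the
# upper triangle.
.base_gram <- function(spec, X) {
  p <- spec$params
  K <- switch(spec$family,
    gaussian = {
      D2 <- as.matrix(stats::dist(X))^2
      exp(-D2 / p$sigma2)
    },
    polynomial = (p$c0 * tcrossprod(X) + p$c1)^p$degree,
    sigmoid    = tanh(p$beta0 * tcrossprod(X) + p$beta1))
  K[lower.tri(K)] <- t(K)[lower.tri(K)]
  dimnames(K) <- NULL
  K
}

.as_sample_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (!is.matrix(X) || !is.numeric(X)) stop2("`X` must be a numeric matrix")
  if (anyNA(X) || !all(is.finite(X))) stop2("non-finite values in `X`")
  X
}

#' Compute a (composite) kernel Gram matrix
#'
#' Builds the N x N matrix of kernel evaluations over the rows of `X`.  For
#' a composite kernel the result is the weighted sum of the base Gram
#' matrices, with the normalized weights stored in the spec.
#'
#' @param kernel A [kernel_spec()] or [composite_kernel()] object.
#' @param X Sample matrix with N >= 2 rows (observations) and features in
#'   columns.
#' @return A symmetric N x N matrix with attribute `centered = FALSE`.
#' @export
kernel_matrix <- function(kernel, X) {
  X <- .as_sample_matrix(X)
  if (nrow(X) < 2) stop2("`X` must have at least 2 rows")
  ck <- as_composite_kernel(kernel)
  K <- matrix(0, nrow(X), nrow(X))
  for (m in seq_along(ck$bases))
    K <- K + ck$weights[m] * .base_gram(ck$bases[[m]], X)
  attr(K, "centered") <- FALSE
  K
}

#' Cross-kernel matrix between training and new points
#'
#' Evaluates \eqn{k(x_i, z_j)} for every training row \eqn{x_i} of `X` and
#' every row \eqn{z_j} of `Z` under the given (possibly composite) kernel.
#' These are the vectors through which a fitted kernel discriminant
#' projects unseen samples.
#'
#' @param kernel A [kernel_spec()] or [composite_kernel()] object.
#' @param X Training sample matrix (N x p).
#' @param Z New sample matrix (M x p) or a single length-p vector.
#' @return An N x M matrix.
#' @export
cross_kernel <- function(kernel, X, Z) {
  X <- .as_sample_matrix(X)
  if (is.vector(Z) && is.numeric(Z)) Z <- matrix(Z, nrow = 1)
  Z <- .as_sample_matrix(Z)
  if (ncol(Z) != ncol(X))
    stop2("dimension mismatch: training has ", ncol(X),
          " features, new data has ", ncol(Z))
  ck <- as_composite_kernel(kernel)
  G <- X %*% t(Z)                       # shared inner products
  out <- matrix(0, nrow(X), nrow(Z))
  for (m in seq_along(ck$bases)) {
    sp <- ck$bases[[m]]
    p <- sp$params
    Km <- switch(sp$family,
      gaussian = {
        D2 <- outer(rowSums(X^2), rep(1, nrow(Z))) +
              outer(rep(1, nrow(X)), rowSums(Z^2)) - 2 * G
        exp(-pmax(D2, 0) / p$sigma2)
      },
      polynomial = (p$c0 * G + p$c1)^p$degree,
      sigmoid    = tanh(p$beta0 * G + p$beta1))
    out <- out + ck$weights[m] * Km
  }
  out
}

#' Double-center a kernel matrix
#'
#' Applies the centering map \eqn{\tilde K = H K H} with
#' \eqn{H = I - J/N} (J the all-ones matrix), which realizes mean-centering
#' of the implicit feature-space points.  Row and column sums of the result
#' are zero; the map is idempotent.
#'
#' @param K Symmetric kernel matrix.
#' @return The centered matrix, with attribute `centered = TRUE`.
#' @export
center_kernel_matrix <- function(K) {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop2("`K` must be a square matrix")
  rm_ <- rowMeans(K)
  gm <- mean(K)
  Kc <- K - outer(rm_, rep(1, ncol(K))) - outer(rep(1, nrow(K)), rm_) + gm
  attr(Kc, "centered") <- TRUE
  Kc
}

#' Center cross-kernel columns consistently with the training centering
#'
#' A test point's kernel vector must live in the same centered feature
#' space as the training Gram matrix.  Given the training row means and
#' grand mean of the uncentered training Gram matrix, each column
#' \eqn{k_z} of `Kz` is mapped to
#' \eqn{\tilde k_z = k_z - \bar k_z \mathbf{1} - r + g} where \eqn{r} is
#' the training row-mean vector and \eqn{g} the training grand mean.
#' Feeding the training Gram matrix itself through this map reproduces
#' [center_kernel_matrix()].
#'
#' @param Kz N x M cross-kernel matrix ([cross_kernel()]).
#' @param train_row_means Row means of the uncentered training Gram matrix.
#' @param train_mean Grand mean of the uncentered training Gram matrix.
#' @return The centered N x M matrix.
#' @export
center_cross_kernel <- function(Kz, train_row_means, train_mean) {
  if (!is.matrix(Kz)) Kz <- as.matrix(Kz)
  if (length(train_row_means) != nrow(Kz))
    stop2("`train_row_means` must have one entry per training sample")
  cm <- colMeans(Kz)
  Kz - outer(rep(1, nrow(Kz)), cm) -
    outer(train_row_means, rep(1, ncol(Kz))) + train_mean
}

#' Check positive semidefiniteness of a kernel matrix
#'
#' A symmetric kernel function is a Mercer kernel iff every finite Gram
#' matrix it generates is positive semidefinite.  This verifies the finite
#' condition: the minimum eigenvalue must be no smaller than
#' `-tol * max(1, max eigenvalue)`.  Gaussian and polynomial kernels (and
#' their nonnegative combinations) always pass; sigmoid kernels may not,
#' and this function reports rather than rejects.
#'
#' @param K Symmetric matrix.
#' @param tol Relative tolerance (default `1e-8`, the double-precision
#'   eigensolver noise floor).
#' @return A list with `psd` (logical), `min_eigenvalue`, `max_eigenvalue`.
#' @examples
#' check_psd(diag(3))$psd             # TRUE
#' check_psd(matrix(c(1, 2, 2, 1), 2))$psd  # FALSE: eigenvalues 3, -1
#' @export
check_psd <- function(K, tol = 1e-8) {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop2("`K` must be a square matrix")
  scale_ <- max(1, max(abs(K)))
  if (max(abs(K - t(K))) > 1e-8 * scale_)
    stop2("`K` is not symmetric")
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(psd = min(ev) >= -tol * max(1, max(ev)),
       min_eigenvalue = min(ev),
       max_eigenvalue = max(ev))
}
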