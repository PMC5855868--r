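# Kernel Fisher discriminant analysis on the Gram matrix.  The Fisher
# criterion in the implicit feature space reduces to the generalized
# eigenproblem  (K B K) alpha = lambda (K K) alpha  on the centered Gram
# matrix K, where B is the block-diagonal class-membership matrix; the
# discriminant directions are never formed explicitly.

#' Block-diagonal class membership matrix B
#'
#' For class-contiguously ordered samples, B is block diagonal with the
#' i-th block the \eqn{N_i \times N_i} constant matrix \eqn{1/N_i}.  B is
#' symmetric and idempotent with trace equal to the number of classes; its
#' rows each sum to one.
#'
#' @param class_sizes Integer vector of per-class sample counts (all >= 1).
#' @return The N x N block matrix, N = sum(class_sizes).
#' @examples
#' build_block_b(c(2, 2))
#' @export
build_block_b <- function(class_sizes) {
  if (length(class_sizes) < 1 || any(class_sizes < 1) ||
      any(class_sizes != round(class_sizes)))
    stop2("`class_sizes` must be positive integers (no empty class)")
  N <- sum(class_sizes)
  B <- matrix(0, N, N)
  off <- 0L
  for (Ni in class_sizes) {
    idx <- off + seq_len(Ni)
    B[idx, idx] <- 1 / Ni
    off <- off + Ni
  }
  B
}

#' Fit a kernel Fisher discriminant
#'
#' Computes the centered Gram matrix \eqn{\tilde K} of the training
#' samples under a single or weighted-composite kernel, internally
#' reorders samples class-contiguously to realize the block structure of
#' B, and solves
#' \deqn{(\tilde K B \tilde K)\,\alpha = \lambda (\tilde K \tilde K + \mu I)\,\alpha,}
#' a symmetric definite pencil after the ridge
#' \eqn{\mu = 10^{-8}\,\mathrm{tr}(\tilde K \tilde K)/N} (the squared Gram
#' matrix is rank deficient).  Coefficient columns are normalized so
#' \eqn{\alpha^T \tilde K \alpha = 1}, i.e. unit-norm discriminants in
#' feature space, and the reported eigenvalues are the achieved Fisher
#' quotients \eqn{\alpha^T \tilde K B \tilde K \alpha / \alpha^T \tilde K
#' \tilde K \alpha} recomputed from the unregularized matrices.
#'
#' @param X Training sample matrix (N x p, N >= C + 1).
#' @param labels Class labels, one per row.
#' @param kernel A [kernel_spec()] or [composite_kernel()]; default is a
#'   gaussian kernel with `sigma2` set to the median squared pairwise
#'   distance of `X` (a standard length-scale heuristic).
#' @param n_components Number of discriminants, at most C - 1; default
#'   `min(3, C - 1)`.
#' @return An object of class `kfda` holding the kernel, the stored
#'   (reordered) training features and coefficient matrix `A`, the
#'   centering statistics needed to project new samples, `eigenvalues`,
#'   and the training `scores` in the original row order.
#' @seealso [project_training()], [predict.kfda()]
#' @export
fit_kfda <- function(X, labels, kernel = NULL, n_components = NULL) {
  X <- .as_sample_matrix(X)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != nrow(X)) stop2("one label per row required")
  C <- nlevels(labels)
  N <- nrow(X)
  if (C < 2) stop2("at least two classes are required")
  if (N < C + 1) stop2("need at least C + 1 samples")
  n_components <- n_components %||% min(3L, C - 1L)
  if (n_components > C - 1)
    stop2("KFDA admits at most C - 1 = ", C - 1, " components")
  if (is.null(kernel)) {
    d2 <- stats::dist(X)^2
    s2 <- stats::median(d2)
    if (!is.finite(s2) || s2 <= 0) s2 <- 1
    kernel <- kernel_spec("gaussian", sigma2 = s2)
  }
  kernel <- as_composite_kernel(kernel)

  ord <- order(labels)                 # class-contiguous ordering
  Xo <- X[ord, , drop = FALSE]
  lo <- labels[ord]
  class_sizes <- as.integer(table(lo))

  K <- kernel_matrix(kernel, Xo)
  row_means <- rowMeans(K)
  grand_mean <- mean(K)
  Kc <- center_kernel_matrix(K)
  B <- build_block_b(class_sizes)

  M <- Kc %*% B %*% Kc
  M <- (M + t(M)) / 2
  KK <- Kc %*% Kc
  KK <- (KK + t(KK)) / 2
  mu <- 1e-8 * sum(diag(KK)) / N
  if (mu <= 0) mu <- 1e-12
  ge <- .sym_geneig(M, KK + mu * diag(N))
  A <- ge$vectors[, seq_len(n_components), drop = FALSE]

  # normalize alpha so  alpha' Kc alpha = 1  (unit-norm w in feature space)
  for (j in seq_len(n_components)) {
    s <- drop(crossprod(A[, j], Kc %*% A[, j]))
    if (s <= 0) s <- sum(A[, j]^2)     # degenerate direction: fall back
    A[, j] <- A[, j] / sqrt(s)
  }
  A <- .fix_signs(A)

  # achieved Fisher quotients, from the unregularized pencil
  eigenvalues <- vapply(seq_len(n_components), function(j) {
    num <- drop(crossprod(A[, j], M %*% A[, j]))
    den <- drop(crossprod(A[, j], KK %*% A[, j]))
    num / den
  }, numeric(1))

  scores_ord <- Kc %*% A
  scores <- matrix(0, N, n_components)
  scores[ord, ] <- scores_ord
  colnames(scores) <- paste0("KFD", seq_len(n_components))

  structure(list(kernel = kernel,
                 X_train = Xo,
                 labels = lo,
                 A = A,
                 eigenvalues = eigenvalues,
                 K_row_means = row_means,
                 K_grand_mean = grand_mean,
                 class_order = levels(lo),
                 class_sizes = class_sizes,
                 n_components = n_components,
                 scores = scores,
                 perm = ord),
            class = "kfda")
}

#' @export
print.kfda <- function(x, ...) {
  cat(sprintf("<kfda: %d samples, %d classes, %d component(s)>\n",
              nrow(x$X_train), length(x$class_sizes), x$n_components))
  cat("  Fisher quotients:",
      paste(signif(x$eigenvalues, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Training-set discriminant scores
#'
#' Returns the projections \eqn{Y = \tilde K A} of the training samples
#' onto the fitted discriminants, in the original input row order.
#'
#' @param model A fitted [fit_kfda()] model.
#' @return N x n_components score matrix.
#' @export
project_training <- function(model) {
  if (!inherits(model, "kfda")) stop2("`model` must be a kfda fit")
  model$scores
}

#' Project new samples through a fitted kernel discriminant
#'
#' For each new row z the cross-kernel vector
#' \eqn{k_z = (k(x_1,z),\dots,k(x_N,z))^T} is computed with the training
#' kernel, centered consistently with the training Gram matrix
#' ([center_cross_kernel()]), and projected as \eqn{g = A^T \tilde k_z}.
#' Feeding the training set through this path reproduces
#' [project_training()] up to numerical noise.
#'
#' @param object A fitted `kfda` model.
#' @param newdata Sample matrix (M x p); an M = 0 matrix yields a 0-row
#'   score matrix.
#' @param ... Unused.
#' @return M x n_components score matrix.
#' @export
predict.kfda <- function(object, newdata, ...) {
  if (is.vector(newdata) && is.numeric(newdata))
    newdata <- matrix(newdata, nrow = 1)
  Z <- as.matrix(newdata)
  if (ncol(Z) != ncol(object$X_train))
    stop2("dimension mismatch: model expects ", ncol(object$X_train),
          " features, got ", ncol(Z))
  if (nrow(Z) == 0)
    return(matrix(0, 0, object$n_components,
                  dimnames = list(NULL, colnames(object$scores))))
  Kz <- cross_kernel(object$kernel, object$X_train, Z)
  Kzc <- center_cross_kernel(Kz, object$K_row_means, object$K_grand_mean)
  out <- t(Kzc) %*% object$A
  colnames(out) <- colnames(object$scores)
  out
}
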