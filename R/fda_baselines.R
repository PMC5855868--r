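# Explicit-space linear reducers used as controls around the kernel
# discriminant: Fisher discriminant analysis on input-space scatter
# matrices, principal component analysis, and locality preserving
# projections (graph-Laplacian embedding).

#' Between- and within-class scatter matrices
#'
#' Computes, on globally centered data, the between-class scatter
#' \eqn{S_B = (1/N) \sum_i N_i m_i m_i^T} and the within-class scatter
#' \eqn{S_W = (1/N) \sum_i \sum_j (x_j^i - m_i)(x_j^i - m_i)^T}, where
#' \eqn{m_i} is the class-i mean of the centered features.  With these
#' normalizations \eqn{S_B + S_W} equals the total scatter.
#'
#' @param X Sample matrix (rows = observations).
#' @param labels Class labels, one per row; at least two classes.
#' @return List with `S_B`, `S_W`, `class_means` (C x p matrix of centered
#'   class means), `global_mean` (the centering shift), `class_sizes`.
#' @export
scatter_matrices <- function(X, labels) {
  X <- .as_sample_matrix(X)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (length(labels) != nrow(X)) stop2("one label per row required")
  if (nlevels(labels) < 2) stop2("at least two classes are required")
  N <- nrow(X)
  global_mean <- colMeans(X)
  Xc <- sweep(X, 2, global_mean)
  p <- ncol(X)
  S_B <- matrix(0, p, p)
  S_W <- matrix(0, p, p)
  cls <- levels(labels)
  class_means <- matrix(0, length(cls), p,
                        dimnames = list(cls, colnames(X)))
  class_sizes <- integer(length(cls))
  for (i in seq_along(cls)) {
    Xi <- Xc[labels == cls[i], , drop = FALSE]
    Ni <- nrow(Xi)
    mi <- colMeans(Xi)
    class_means[i, ] <- mi
    class_sizes[i] <- Ni
    S_B <- S_B + Ni * tcrossprod(mi)
    Di <- sweep(Xi, 2, mi)
    S_W <- S_W + crossprod(Di)
  }
  list(S_B = S_B / N, S_W = S_W / N, class_means = class_means,
       global_mean = global_mean, class_sizes = class_sizes)
}

# Fix eigenvector signs so the largest-magnitude entry of each column is
# positive; makes reducer outputs reproducible across solvers.
.fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# Solve the symmetric generalized eigenproblem  A v = lambda B v  with B
# symmetric positive definite, via Cholesky reduction.  Returns eigenpairs
# in decreasing eigenvalue order.
.sym_geneig <- function(A, B) {
  R <- tryCatch(chol(B), error = function(e)
    stop2("generalized eigenproblem: right-hand matrix not positive ",
          "definite after regularization (", conditionMessage(e), ")"))
  Ri <- backsolve(R, diag(nrow(B)))
  Cs <- crossprod(Ri, A) %*% Ri
  Cs <- (Cs + t(Cs)) / 2
  e <- eigen(Cs, symmetric = TRUE)
  list(values = e$values, vectors = Ri %*% e$vectors)
}

.new_projection_model <- function(method, directions, eigenvalues, center,
                                  scores = NULL, extra = list()) {
  structure(c(list(method = method, directions = directions,
                   eigenvalues = eigenvalues, center = center,
                   n_components = ncol(directions), scores = scores),
              extra),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model: %s, %d component(s), %d feature(s)>\n",
              x$method, x$n_components, nrow(x$directions)))
  invisible(x)
}

#' Fisher discriminant analysis in input space
#'
#' Maximizes the Fisher criterion \eqn{w^T S_B w / w^T S_W w} by solving
#' the generalized eigenproblem \eqn{S_B w = \lambda S_W w}, with the
#' within-class scatter ridge-regularized as
#' \eqn{S_W + \mu I, \mu = 10^{-8}\,\mathrm{tr}(S_W)/p} (needed when
#' N < p, as happens for 15-sensor data at 50/50 split size).  At most
#' C - 1 informative directions exist.
#'
#' @param X Sample matrix.
#' @param labels Class labels (>= 2 classes).
#' @param n_components Number of directions to keep; defaults to
#'   `min(3, C - 1)` and must not exceed C - 1.
#' @return A `projection_model` with unit-norm `directions` (columns),
#'   `eigenvalues` (the Fisher quotients, decreasing) and the training
#'   `scores`.
#' @export
fit_fda <- function(X, labels, n_components = NULL) {
  X <- .as_sample_matrix(X)
  labels <- droplevels(as.factor(labels))
  C <- nlevels(labels)
  sc <- scatter_matrices(X, labels)
  n_components <- n_components %||% min(3L, C - 1L)
  if (n_components > C - 1)
    stop2("FDA admits at most C - 1 = ", C - 1, " components")
  p <- ncol(X)
  mu <- 1e-8 * sum(diag(sc$S_W)) / p
  if (mu <= 0) mu <- 1e-12
  ge <- .sym_geneig(sc$S_B, sc$S_W + mu * diag(p))
  W <- ge$vectors[, seq_len(n_components), drop = FALSE]
  W <- apply(W, 2, function(v) v / sqrt(sum(v^2)))
  W <- .fix_signs(matrix(W, nrow = p))
  scores <- sweep(X, 2, sc$global_mean) %*% W
  .new_projection_model("fda", W, ge$values[seq_len(n_components)],
                        sc$global_mean, scores)
}

#' Principal component analysis
#'
#' Eigendecomposition of the covariance of the centered features;
#' directions ordered by decreasing explained variance, signs fixed so the
#' largest-magnitude loading is positive.
#'
#' @param X Sample matrix.
#' @param n_components Number of components (<= number of features);
#'   default 3.
#' @return A `projection_model`.
#' @export
fit_pca <- function(X, n_components = 3) {
  X <- .as_sample_matrix(X)
  if (n_components > ncol(X))
    stop2("n_components exceeds the number of features")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  W <- .fix_signs(pc$rotation[, seq_len(n_components), drop = FALSE])
  scores <- sweep(X, 2, pc$center) %*% W
  .new_projection_model("pca", W, pc$sdev[seq_len(n_components)]^2,
                        pc$center, scores,
                        extra = list(all_eigenvalues = pc$sdev^2))
}

# breadth-first connectivity check on an adjacency matrix
.graph_connected <- function(Adj) {
  n <- nrow(Adj)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0) {
    i <- queue[1L]
    queue <- queue[-1L]
    nb <- which(Adj[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Locality preserving projections
#'
#' Linear embedding that preserves local neighborhood structure: a
#' symmetric k-nearest-neighbor graph with heat-kernel edge weights
#' \eqn{\exp(-\|x_i-x_j\|^2/t)} defines a graph Laplacian
#' \eqn{L = D - W}; directions solve
#' \eqn{X^T L X\, a = \lambda X^T D X\, a} and the smallest-eigenvalue
#' solutions are kept.
#'
#' @param X Sample matrix.
#' @param n_components Number of directions; default 3.
#' @param k_neighbors Neighborhood size (default 5; must be < N).
#' @param heat_t Heat-kernel bandwidth; defaults to the mean squared
#'   pairwise distance.
#' @return A `projection_model`; `eigenvalues` are the kept (smallest)
#'   generalized eigenvalues in increasing order.
#' @export
fit_lpp <- function(X, n_components = 3, k_neighbors = 5, heat_t = NULL) {
  X <- .as_sample_matrix(X)
  N <- nrow(X)
  if (k_neighbors >= N) stop2("`k_neighbors` must be smaller than N")
  if (n_components > ncol(X))
    stop2("n_components exceeds the number of features")
  D2 <- as.matrix(stats::dist(X))^2
  heat_t <- heat_t %||% mean(D2[upper.tri(D2)])
  if (!is.finite(heat_t) || heat_t <= 0) heat_t <- 1
  W <- matrix(0, N, N)
  for (i in seq_len(N)) {
    nb <- order(D2[i, ])[-1][seq_len(k_neighbors)]
    W[i, nb] <- exp(-D2[i, nb] / heat_t)
  }
  W <- pmax(W, t(W))                   # symmetric kNN graph
  diag(W) <- 0
  if (!.graph_connected(W))
    warning("LPP neighborhood graph is disconnected; proceeding anyway",
            call. = FALSE)
  Dg <- diag(rowSums(W))
  L <- Dg - W
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  M1 <- crossprod(Xc, L) %*% Xc
  M2 <- crossprod(Xc, Dg) %*% Xc
  mu <- 1e-8 * sum(diag(M2)) / ncol(X)
  if (mu <= 0) mu <- 1e-12
  ge <- .sym_geneig(M1, M2 + mu * diag(ncol(X)))
  idx <- rev(seq_len(length(ge$values)))[seq_len(n_components)]  # smallest
  A <- ge$vectors[, idx, drop = FALSE]
  A <- apply(A, 2, function(v) v / sqrt(sum(v^2)))
  A <- .fix_signs(matrix(A, nrow = ncol(X)))
  scores <- Xc %*% A
  .new_projection_model("lpp", A, ge$values[idx], center, scores,
                        extra = list(k_neighbors = k_neighbors,
                                     heat_t = heat_t, affinity = W))
}

#' Project new samples with a fitted linear reducer
#'
#' @param object A `projection_model` from [fit_fda()], [fit_pca()] or
#'   [fit_lpp()].
#' @param newdata Sample matrix with the training feature dimension.
#' @param ... Unused.
#' @return The reduced score matrix (rows = samples).
#' @export
predict.projection_model <- function(object, newdata, ...) {
  Z <- .as_sample_matrix(newdata)
  if (ncol(Z) != nrow(object$directions))
    stop2("dimension mismatch: model expects ", nrow(object$directions),
          " features, got ", ncol(Z))
  sweep(Z, 2, object$center) %*% object$directions
}
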