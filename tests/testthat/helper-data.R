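# Small in-code fixtures shared across test files.

# isotropic gaussian blobs, one per row of `centers`
make_blobs <- function(n_per_class, centers, sd = 0.5, seed = NULL) {
  wkfda:::with_seed(seed, {
    C <- nrow(centers)
    p <- ncol(centers)
    X <- do.call(rbind, lapply(seq_len(C), function(i)
      matrix(rnorm(n_per_class * p, 0, sd), n_per_class, p) +
        matrix(centers[i, ], n_per_class, p, byrow = TRUE)))
    list(X = X, labels = factor(rep(paste0("c", seq_len(C)),
                                    each = n_per_class)))
  })
}

# two concentric rings in 2-D: not linearly separable
make_rings <- function(n_per_class = 30, r = c(1, 3), noise = 0.15,
                       seed = NULL) {
  wkfda:::with_seed(seed, {
    th <- runif(2 * n_per_class, 0, 2 * pi)
    rad <- rep(r, each = n_per_class) + rnorm(2 * n_per_class, 0, noise)
    list(X = cbind(rad * cos(th), rad * sin(th)),
         labels = factor(rep(c("inner", "outer"), each = n_per_class)))
  })
}

# leave-one-out 1-nearest-neighbour accuracy
loo_1nn_accuracy <- function(X, labels) {
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  mean(labels[apply(D, 1, which.min)] == labels)
}
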