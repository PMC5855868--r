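test_that("block membership matrix has the stated structure", {
  B <- build_block_b(c(2, 2))
  expect_equal(B, rbind(c(.5, .5, 0, 0), c(.5, .5, 0, 0),
                        c(0, 0, .5, .5), c(0, 0, .5, .5)))
  B2 <- build_block_b(c(3, 1, 4))
  expect_equal(sum(diag(B2)), 3)                 # trace = C
  expect_equal(rowSums(B2), rep(1, 8))           # rows sum to one
  expect_equal(B2 %*% B2, B2, tolerance = 1e-10) # idempotent
  expect_error(build_block_b(c(2, 0)), "positive integers")
})

test_that("linear-kernel KFDA matches explicit FDA scores", {
  lin <- kernel_spec("polynomial", c0 = 1, c1 = 0, degree = 1)
  set.seed(31)
  for (i in 1:6) {
    C <- sample(2:4, 1)
    d <- make_blobs(sample(6:15, 1),
                    matrix(rnorm(C * 4, sd = 2), C, 4), sd = 0.7)
    f <- fit_fda(d$X, d$labels, 1)
    k <- fit_kfda(d$X, d$labels, kernel = lin, n_components = 1)
    expect_gte(abs(cor(f$scores[, 1], project_training(k)[, 1])), 0.999)
  }
})

test_that("component count is capped at C - 1", {
  d <- make_blobs(8, matrix(rnorm(16, sd = 3), 4, 4), sd = 0.5, seed = 1)
  expect_error(fit_kfda(d$X, d$labels, n_components = 4), "at most")
  k <- fit_kfda(d$X, d$labels)
  expect_equal(k$n_components, 3)
})

test_that("Fisher quotient is invariant to positive kernel scaling", {
  d <- make_blobs(10, rbind(c(0, 0), c(2, 2)), sd = 0.6, seed = 5)
  k1 <- fit_kfda(d$X, d$labels,
                 kernel_spec("polynomial", c0 = 1, c1 = 0, degree = 1), 1)
  k5 <- fit_kfda(d$X, d$labels,
                 kernel_spec("polynomial", c0 = 5, c1 = 0, degree = 1), 1)
  expect_equal(k1$eigenvalues, k5$eigenvalues, tolerance = 1e-6)
})

test_that("training projections and out-of-sample projections agree", {
  d <- make_blobs(12, rbind(c(0, 0, 0), c(3, 0, 1), c(0, 3, -1)),
                  sd = 0.8, seed = 17)
  k <- fit_kfda(d$X, d$labels, kernel_spec("gaussian", sigma2 = 4), 2)
  expect_equal(predict(k, d$X), project_training(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  # duplicated test point projects identically
  Z <- rbind(d$X[1, ], d$X[1, ])
  g <- predict(k, Z)
  expect_equal(g[1, ], g[2, ])
  expect_false(anyNA(project_training(k)))
})

test_that("projection is linear in the kernel vector for linear kernels", {
  lin <- kernel_spec("polynomial", c0 = 1, c1 = 0, degree = 1)
  d <- make_blobs(10, rbind(c(0, 0), c(4, 1)), sd = 0.5, seed = 23)
  k <- fit_kfda(d$X, d$labels, lin, 1)
  mid <- (d$X[2, ] + d$X[12, ]) / 2
  g <- predict(k, rbind(d$X[2, ], d$X[12, ], mid))
  expect_equal(g[3, ], (g[1, ] + g[2, ]) / 2, tolerance = 1e-8)
})

test_that("score intervals of separable classes do not overlap", {
  d <- make_blobs(15, rbind(c(0, 0), c(6, 0)), sd = 0.5, seed = 29)
  k <- fit_kfda(d$X, d$labels, kernel_spec("gaussian", sigma2 = 8), 1)
  s <- project_training(k)[, 1]
  a <- s[d$labels == "c1"]; b <- s[d$labels == "c2"]
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("eigenvalues equal the Rayleigh quotient recomputed from K, B", {
  d <- make_blobs(9, matrix(rnorm(12, sd = 2), 3, 4), sd = 0.6, seed = 41)
  k <- fit_kfda(d$X, d$labels, kernel_spec("gaussian", sigma2 = 3), 2)
  K <- kernel_matrix(k$kernel, k$X_train)
  Kc <- center_kernel_matrix(K)
  B <- build_block_b(k$class_sizes)
  for (j in seq_len(k$n_components)) {
    a <- k$A[, j]
    q <- drop(crossprod(a, Kc %*% B %*% Kc %*% a)) /
      drop(crossprod(a, Kc %*% Kc %*% a))
    expect_equal(q, k$eigenvalues[j], tolerance = 1e-6)
  }
  # unit feature-space norm: alpha' Kc alpha = 1
  expect_equal(diag(crossprod(k$A, Kc %*% k$A)),
               rep(1, k$n_components), tolerance = 1e-8)
})

test_that("sample order does not change the spectrum", {
  d <- make_blobs(8, matrix(rnorm(12, sd = 2), 3, 4), sd = 0.6, seed = 43)
  k1 <- fit_kfda(d$X, d$labels, kernel_spec("gaussian", sigma2 = 2), 2)
  perm <- sample(nrow(d$X))
  k2 <- fit_kfda(d$X[perm, ], d$labels[perm],
                 kernel_spec("gaussian", sigma2 = 2), 2)
  expect_equal(k1$eigenvalues, k2$eigenvalues, tolerance = 1e-8)
})

test_that("gaussian KFDA beats FDA on concentric classes", {
  wins <- 0
  for (s in 1:5) {
    d <- make_rings(30, seed = s)
    sp <- holdout_split(d$labels, 0.5, seed = 100 + s)
    acc <- function(scores_tr, scores_te) {
      D <- as.matrix(dist(rbind(scores_tr, scores_te)))
      ntr <- nrow(scores_tr)
      nn <- apply(D[(ntr + 1):nrow(D), 1:ntr, drop = FALSE], 1, which.min)
      mean(d$labels[sp$train][nn] == d$labels[sp$test])
    }
    f <- fit_fda(d$X[sp$train, ], d$labels[sp$train], 1)
    k <- fit_kfda(d$X[sp$train, ], d$labels[sp$train],
                  kernel_spec("gaussian", sigma2 = 1), 1)
    a_f <- acc(f$scores, predict(f, d$X[sp$test, ]))
    a_k <- acc(project_training(k), predict(k, d$X[sp$test, ]))
    wins <- wins + (a_k > a_f)
  }
  expect_gte(wins, 3)
})

test_that("empty projection input yields an empty score matrix", {
  d <- make_blobs(6, rbind(c(0, 0), c(3, 3)), sd = 0.4, seed = 2)
  k <- fit_kfda(d$X, d$labels, n_components = 1)
  out <- predict(k, matrix(0, 0, 2))
  expect_equal(dim(out), c(0, 1))
  expect_error(predict(k, matrix(0, 2, 5)), "dimension mismatch")
})
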