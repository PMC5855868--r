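test_that("base kernels evaluate their closed forms", {
  g <- kernel_spec("gaussian", sigma2 = 2)
  expect_equal(kernel_eval(g, c(0, 0), c(1, 1)), exp(-1))
  # zero distance gives 1 for any length-scale
  for (s2 in c(0.01, 1, 50))
    expect_equal(kernel_eval(kernel_spec("gaussian", sigma2 = s2),
                             c(3, -2), c(3, -2)), 1)
  # linear kernel reduces to the inner product
  lin <- kernel_spec("polynomial", c0 = 1, c1 = 0, degree = 1)
  x <- c(1, 2, -3); z <- c(0.5, -1, 2)
  expect_equal(kernel_eval(lin, x, z), sum(x * z))
  sig <- kernel_spec("sigmoid", beta0 = 0.3, beta1 = -1)
  expect_equal(kernel_eval(sig, x, z), tanh(0.3 * sum(x * z) - 1))
  # symmetric in its arguments
  expect_equal(kernel_eval(g, x, z), kernel_eval(g, z, x))
})

test_that("kernel evaluation rejects bad inputs", {
  g <- kernel_spec("gaussian")
  expect_error(kernel_eval(g, c(1, 2), c(1, 2, 3)), "dimension mismatch")
  expect_error(kernel_eval(g, c(1, NA), c(1, 2)), "non-finite")
  expect_error(kernel_spec("gaussian", sigma2 = -1), "sigma2 > 0")
  expect_error(kernel_spec("polynomial", degree = 0.5), "integer degree")
  expect_error(kernel_spec("gaussian", nonsense = 2), "unknown parameter")
})

test_that("Gram matrices match entrywise evaluation and are symmetric", {
  X <- matrix(c(0, 1), ncol = 1)
  K <- kernel_matrix(kernel_spec("gaussian", sigma2 = 1), X)
  expect_equal(unclass(K)[1:2, 1:2],
               matrix(c(1, exp(-1), exp(-1), 1), 2),
               ignore_attr = TRUE)
  set.seed(7)
  X <- matrix(rnorm(30), 10, 3)
  lin <- kernel_spec("polynomial", c0 = 1, c1 = 0, degree = 1)
  expect_equal(kernel_matrix(lin, X), tcrossprod(X), ignore_attr = TRUE)
  Kg <- kernel_matrix(kernel_spec("gaussian", sigma2 = 3), X)
  expect_equal(diag(Kg), rep(1, 10))
  expect_equal(max(abs(Kg - t(Kg))), 0)
  expect_error(kernel_matrix(lin, X[1, , drop = FALSE]), "at least 2 rows")
})

test_that("composite kernels are normalized weighted sums of their bases", {
  set.seed(11)
  X <- matrix(rnorm(40), 10, 4)
  b1 <- kernel_spec("gaussian", sigma2 = 0.5)
  b2 <- kernel_spec("polynomial", degree = 2)
  # weights are rescaled to sum to one
  ck <- composite_kernel(list(b1, b2), c(0.2, 0.2))
  expect_equal(ck$weights, c(0.5, 0.5))
  # weight (1, 0) collapses to the first base exactly
  K1 <- kernel_matrix(composite_kernel(list(b1, b2), c(1, 0)), X)
  expect_equal(K1, kernel_matrix(b1, X), tolerance = 0)
  # linearity against separately computed base Grams
  K <- kernel_matrix(composite_kernel(list(b1, b2), c(0.3, 0.7)), X)
  expect_equal(unclass(K),
               unclass(0.3 * kernel_matrix(b1, X) +
                         0.7 * kernel_matrix(b2, X)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # convex combination of unit diagonals stays 1
  Kgg <- kernel_matrix(composite_kernel(
    list(b1, kernel_spec("gaussian", sigma2 = 4)), c(0.5, 0.5)), X)
  expect_equal(diag(Kgg), rep(1, 10))
  expect_true(check_psd(Kgg)$min_eigenvalue >= -1e-8)
  expect_error(composite_kernel(list(b1, b2), c(0, 0)), "degenerate")
})

test_that("double centering zeroes row sums and is idempotent", {
  expect_equal(unclass(center_kernel_matrix(diag(2))),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2), ignore_attr = TRUE)
  expect_equal(unclass(center_kernel_matrix(matrix(1, 3, 3))),
               matrix(0, 3, 3), ignore_attr = TRUE)
  set.seed(3)
  K <- kernel_matrix(kernel_spec("gaussian"), matrix(rnorm(24), 8, 3))
  Kc <- center_kernel_matrix(K)
  expect_lt(max(abs(rowSums(Kc))), 1e-8)
  expect_lt(max(abs(colSums(Kc))), 1e-8)
  expect_equal(unclass(center_kernel_matrix(Kc)), unclass(Kc),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("cross-kernel vectors agree with Gram columns and are linear", {
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3)
  b1 <- kernel_spec("gaussian", sigma2 = 2)
  b2 <- kernel_spec("polynomial", degree = 3)
  K <- kernel_matrix(b1, X)
  v <- cross_kernel(b1, X, X[4, ])
  expect_equal(drop(v), unname(K[, 4]), tolerance = 1e-12)
  # composite cross vector = weighted sum of per-base vectors
  z <- rnorm(3)
  vc <- cross_kernel(composite_kernel(list(b1, b2), c(0.3, 0.7)), X, z)
  expect_equal(vc, 0.3 * cross_kernel(b1, X, z) +
                 0.7 * cross_kernel(b2, X, z), tolerance = 1e-12)
  expect_error(cross_kernel(b1, X, c(1, 2)), "dimension mismatch")
  # feeding the training Gram through the test-centering map reproduces
  # the double-centered Gram matrix
  Kc <- center_cross_kernel(K, rowMeans(K), mean(K))
  expect_equal(unclass(Kc), unclass(center_kernel_matrix(K)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PSD check accepts Mercer Grams and flags indefinite matrices", {
  r <- check_psd(diag(3))
  expect_true(r$psd)
  expect_equal(r$min_eigenvalue, 1)
  r2 <- check_psd(matrix(c(1, 2, 2, 1), 2))
  expect_false(r2$psd)
  expect_equal(sort(c(r2$min_eigenvalue, r2$max_eigenvalue)), c(-1, 3))
  set.seed(9)
  Kg <- kernel_matrix(kernel_spec("gaussian", sigma2 = 1.5),
                      matrix(rnorm(100), 20, 5))
  expect_true(check_psd(Kg)$psd)
  expect_error(check_psd(matrix(c(1, 5, 0, 1), 2)), "not symmetric")
})

test_that("nonnegative combinations of Mercer kernels stay PSD", {
  # closure property on randomized instances
  set.seed(21)
  for (i in 1:15) {
    n <- sample(5:30, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    K1 <- kernel_matrix(kernel_spec("gaussian", sigma2 = runif(1, 0.2, 5)), X)
    K2 <- kernel_matrix(kernel_spec("polynomial",
                                    degree = sample(1:3, 1),
                                    c1 = runif(1, 0, 2)), X)
    a <- runif(1, 0, 3); b <- runif(1, 0, 3)
    expect_true(check_psd(a * K1 + b * K2)$psd)
  }
})
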