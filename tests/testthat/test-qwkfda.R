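tiny_qpso <- list(swarm_size = 6, max_iters = 6, patience = 4)

test_that("search vectors round-trip through encode/decode", {
  cfg <- qwkfda_config("gaussian", n_bases = 3)
  set.seed(2)
  for (i in 1:5) {
    v <- c(runif(3), runif(3, -4, 4))
    ck <- decode_search_vector(v, cfg)
    v2 <- encode_search_vector(ck, cfg)
    # weights come back normalized, parameters exactly
    expect_equal(v2[1:3], pmax(v[1:3], 0) / sum(pmax(v[1:3], 0)),
                 tolerance = 1e-12)
    expect_equal(v2[4:6], v[4:6], tolerance = 1e-12)
    expect_equal(encode_search_vector(decode_search_vector(v2, cfg), cfg),
                 v2, tolerance = 1e-12)
  }
  # equal raw weights decode to the uniform simplex point
  cfgw <- qwkfda_config("gaussian", n_bases = 2,
                        optimize_kernel_params = FALSE)
  expect_equal(decode_search_vector(c(0.2, 0.2), cfgw)$weights, c(0.5, 0.5))
  expect_error(decode_search_vector(c(0, 0), cfgw), "degenerate")
  expect_error(decode_search_vector(c(0.5, 0.5, 0.5), cfgw), "length")
})

test_that("polynomial and sigmoid banks decode to their families", {
  cfgp <- qwkfda_config("polynomial", n_bases = 3)
  ck <- decode_search_vector(c(1, 1, 1, 0.5, 1.5, 2.5), cfgp)
  expect_equal(vapply(ck$bases, function(b) b$params$degree, integer(1)),
               1:3)
  expect_equal(vapply(ck$bases, function(b) b$params$c1, numeric(1)),
               c(0.5, 1.5, 2.5))
  cfgs <- qwkfda_config("sigmoid", n_bases = 2)
  ck2 <- decode_search_vector(c(1, 1, -1, 0), cfgs)
  expect_equal(vapply(ck2$bases, function(b) b$params$beta0, numeric(1)),
               c(0.1, 1))
})

test_that("fitness is low on separable data and near chance under the null", {
  d <- make_blobs(12, rbind(c(0, 0), c(6, 6)), sd = 0.4, seed = 10)
  cfg <- qwkfda_config("gaussian", n_bases = 2, cv_folds = 3)
  folds <- matrix(wkfda:::with_seed(1, wkfda:::.stratified_folds(d$labels, 3)))
  v <- c(0.5, 0.5, 0, 1)
  f_easy <- wkfda:::qwkfda_fitness(v, d$X, d$labels, cfg, folds)
  expect_lte(f_easy, 0.05)
  # permuted labels: accuracy near 1/C
  yperm <- wkfda:::with_seed(42, sample(d$labels))
  foldsp <- matrix(wkfda:::with_seed(2, wkfda:::.stratified_folds(yperm, 3)))
  f_null <- wkfda:::qwkfda_fitness(v, d$X, yperm, cfg, foldsp)
  expect_lt(abs(f_null - 0.5), 0.15)
  # deterministic given the same folds
  expect_identical(f_easy,
                   wkfda:::qwkfda_fitness(v, d$X, d$labels, cfg, folds))
})

test_that("a single fixed base kernel reproduces plain KFDA exactly", {
  d <- make_blobs(10, rbind(c(0, 0, 0), c(2, 1, 0), c(0, 2, 2)), sd = 0.6,
                  seed = 20)
  cfg <- qwkfda_config("gaussian", n_bases = 1,
                       optimize_kernel_params = FALSE,
                       cv_folds = 3, qpso = c(tiny_qpso, list(seed = 1)))
  m <- fit_qwkfda(d$X, d$labels, cfg, seed = 1)
  plain <- fit_kfda(d$X, d$labels,
                    kernel = default_kernel_bank("gaussian", 1)[[1]],
                    n_components = 2)
  expect_equal(project_training(m$kfda), project_training(plain),
               tolerance = 1e-8)
  Z <- matrix(rnorm(9), 3)
  expect_equal(predict(m, Z), predict(plain, Z), tolerance = 1e-8)
})

test_that("fitted searches stay in bounds and transform consistently", {
  d <- make_blobs(10, rbind(c(0, 0), c(3, 3), c(-3, 3)), sd = 0.7,
                  seed = 30)
  cfg <- qwkfda_config("gaussian", n_bases = 2, cv_folds = 3,
                       qpso = tiny_qpso)
  m <- fit_qwkfda(d$X, d$labels, cfg, seed = 3)
  b <- wkfda:::.search_bounds(cfg)
  expect_true(all(m$optimization$best_position >= b[, 1] &
                    m$optimization$best_position <= b[, 2]))
  # transform of the training set equals stored scores
  expect_equal(predict(m, d$X), project_training(m$kfda),
               tolerance = 1e-8, ignore_attr = TRUE)
  # batch of one equals the matching row of a batch of many
  Z <- matrix(rnorm(8), 4)
  expect_equal(predict(m, Z[2, , drop = FALSE]), predict(m, Z)[2, , drop = FALSE],
               tolerance = 1e-12)
  # empty input, empty output
  expect_equal(nrow(predict(m, matrix(0, 0, 2))), 0)
  # end-to-end reproducibility under a fixed seed
  m2 <- fit_qwkfda(d$X, d$labels, cfg, seed = 3)
  expect_identical(m$optimization$best_position,
                   m2$optimization$best_position)
  expect_equal(project_training(m$kfda), project_training(m2$kfda))
})

test_that("the search is no worse than its own grid initialization", {
  d <- simulate_wound_dataset(
    wound_sensor_config(samples_per_class = 10), seed = 8)
  cfg <- qwkfda_config("gaussian", n_bases = 3, cv_folds = 3,
                       qpso = list(swarm_size = 8, max_iters = 10,
                                   patience = 6))
  m <- wkfda:::with_seed(5, fit_qwkfda(d$X, d$labels, cfg))
  # fitness of the equally weighted default grid bank, on the same folds
  # the fit used is unavailable here; recompute with a fresh assignment
  # and allow the 2-point slack
  folds <- matrix(wkfda:::with_seed(5, wkfda:::.stratified_folds(d$labels,
                                                                 3)))
  grid <- composite_kernel(default_kernel_bank("gaussian", 3), rep(1, 3))
  f_grid <- wkfda:::qwkfda_fitness(encode_search_vector(grid, cfg),
                                   d$X, d$labels, cfg, folds)
  expect_lte(m$optimization$best_fitness, f_grid + 0.02)
})

test_that("the sweep harness emits one row per family and bank size", {
  d <- simulate_wound_dataset(
    wound_sensor_config(samples_per_class = 8), seed = 4)
  tmpl <- qwkfda_config(cv_folds = 2,
                        qpso = list(swarm_size = 4, max_iters = 3,
                                    patience = 2))
  tab <- suppressWarnings(sweep_base_kernels(
    d, families = "gaussian", n_bases = 2:3, protocol = "holdout",
    config_template = tmpl, repeats = 2, seed = 1))
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("family", "n_bases", "mean_accuracy", "sd_accuracy"))
  expect_true(all(tab$mean_accuracy >= 0 & tab$mean_accuracy <= 100))
})
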