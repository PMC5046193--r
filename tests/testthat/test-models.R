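# MLR::Vina grid search, the forest protocol, the fixed Vina scorer.

test_that("fixed Vina model converts weighted inter energy to pKd", {
  X <- matrix(0, 2, 11, dimnames = list(NULL, vina_term_names()))
  w <- vina_weights()
  # arrange e_inter = -8 kcal/mol via the repulsion slot, nrot = 0
  X[1, "repulsion_inter"] <- -8 / w[["w3"]]
  # same energy but nrot = 5 engages the rotor penalty
  X[2, "repulsion_inter"] <- -8 / w[["w3"]]; X[2, "nrot"] <- 5
  m <- vina_model()
  p <- predict(m, X)
  expect_equal(p[1], 5.86795844072)
  expect_equal(p[2], 5.86795844072 / (1 + w[["w6"]] * 5))
  expect_error(predict(m, X[, 1:4]), "needs columns")
})

test_that("MLR grid stages enumerate 101 and 31 candidates", {
  set.seed(2)
  n <- 40
  X <- cbind(matrix(rnorm(10 * n), n, 10,
                    dimnames = list(NULL, vina_term_names()[1:10])),
             nrot = sample(0:8, n, TRUE))
  y <- rnorm(n, 5)
  m <- fit_mlr_vina(X, y, selection = "train")
  expect_equal(nrow(m$grid$stage1), 101)
  expect_equal(m$grid$stage1$w6[c(1, 101)], c(0, 1))
  expect_equal(nrow(m$grid$stage2), 31)
  expect_equal(m$grid$stage2$w6[c(1, 31)], c(0, 0.030))
})

test_that("noise-free generator parameters are recovered exactly", {
  ds <- make_dataset(fixture_config(n_complexes = 60, noise_sd = 0),
                     seed = 5)
  expect_equal(ds$truth$w6, 0.02)
  tab <- featurize_complexes(ds$complexes, 1, "vina11")
  fm <- feature_matrix(tab)
  m <- fit_mlr_vina(fm$X, fm$y)
  expect_equal(m$w6, 0.02)
  est <- m$coefficients
  expect_lt(abs(est[["(Intercept)"]] - ds$truth$intercept), 1e-6)
  expect_lt(max(abs(est[2:11] - ds$truth$coefficients)), 1e-6)
  expect_lt(abs(est[["nrot"]]), 1e-6)
  # residuals vanish: predictions reproduce the affinities
  expect_lt(rmse(predict(m, fm$X), fm$y), 1e-8)
})

test_that("MLR with w6 = 0 equals plain OLS on untransformed features", {
  set.seed(9)
  n <- 50
  X <- cbind(matrix(rnorm(5 * n), n, 5,
                    dimnames = list(NULL, vina_term_names()[1:5])),
             nrot = sample(0:6, n, TRUE))
  y <- rnorm(n, 5)
  Xt <- X  # hand-force w6 = 0 by refitting at that grid point
  m <- fit_mlr_vina(X, y, selection = "train")
  beta0 <- coef(lm(y ~ Xt))
  pred0 <- cbind(1, Xt) %*% beta0
  # the w6 = 0 grid entry's criterion equals the OLS in-sample RMSE
  expect_equal(m$grid$stage2$criterion[1], rmse(as.vector(pred0), y),
               tolerance = 1e-10)
})

test_that("forest predictions are the mean of tree predictions", {
  set.seed(4)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- X[, 1] * 2 + rnorm(40, sd = 0.1)
  f <- fit_forest(X, y, n_trees = 25, mtry_grid = 2, seeds = 1)
  pred <- predict(f, X)
  by_tree <- vapply(f$trees, function(tr) {
    walk <- function(i, node = 1) {
      while (tr$var[node] >= 0) {
        node <- if (X[i, tr$var[node] + 1] <= tr$split[node])
          tr$left[node] + 1 else tr$right[node] + 1
      }
      tr$pred[node]
    }
    vapply(seq_len(nrow(X)), walk, numeric(1))
  }, numeric(nrow(X)))
  expect_equal(pred, rowMeans(by_tree), tolerance = 1e-12)
})

test_that("degenerate targets and protocol bookkeeping behave", {
  set.seed(6)
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(6.2, 30)
  f <- fit_forest(X, y, n_trees = 20, seeds = 1)
  expect_equal(unique(predict(f, X)), 6.2)
  expect_equal(f$oob_rmse, 0)

  # mtry search over P features -> P candidate models per seed
  X11 <- matrix(rnorm(40 * 11), 40, 11,
                dimnames = list(NULL, vina_term_names()))
  y11 <- rnorm(40, 5)
  f11 <- fit_forest(X11, y11, n_trees = 10, seeds = 1:2)
  expect_equal(dim(f11$search), c(2, 11))
  expect_true(all(is.finite(f11$search)))

  expect_error(predict(f11, X11[, 1:5]), "feature")
  expect_error(fit_forest(X[1:5, ], y[1:5], n_trees = 5), "at least 10")
})

test_that("forests are deterministic given a seed and learn a monotone signal", {
  set.seed(12)
  n <- 300
  X <- matrix(rnorm(n * 11), n, 11, dimnames = list(NULL, vina_term_names()))
  y <- 5 + 2 * tanh(X[, 1]) + rnorm(n, sd = 0.2)
  trn <- 1:200; tst <- 201:300
  f1 <- fit_forest(X[trn, ], y[trn], n_trees = 150, mtry_grid = c(3, 6),
                   seeds = 1:3)
  f2 <- fit_forest(X[trn, ], y[trn], n_trees = 150, mtry_grid = c(3, 6),
                   seeds = 1:3)
  expect_identical(predict(f1, X[tst, ]), predict(f2, X[tst, ]))
  expect_gt(rp(predict(f1, X[tst, ]), y[tst]), 0.9)
})

test_that("test-RMSE (replication) selection is honoured and flagged", {
  set.seed(21)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- X[, 2] + rnorm(60, sd = 0.3)
  f <- fit_forest(X[1:40, ], y[1:40], n_trees = 30, mtry_grid = 2,
                  seeds = 1:4, selection = "test",
                  test_X = X[41:60, ], test_y = y[41:60])
  expect_equal(f$selection, "test")
  test_rmses <- vapply(1:4, function(s) {
    g <- fit_forest(X[1:40, ], y[1:40], n_trees = 30, mtry_grid = 2,
                    seeds = s)
    rmse(predict(g, X[41:60, ]), y[41:60])
  }, numeric(1))
  expect_equal(f$seed, which.min(test_rmses))
  expect_error(fit_forest(X, y, n_trees = 5, selection = "test"), "test_X")
})

test_that("model persistence round-trips with provenance", {
  set.seed(3)
  X <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rnorm(20, 5)
  f <- fit_forest(X, y, n_trees = 10, mtry_grid = 2, seeds = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(f, path, scheme_id = 2, feature_set = "vina11", d_cutoff = 12)
  back <- load_model(path)
  expect_equal(back$scheme_id, 2)
  expect_identical(predict(back$model, X), predict(f, X))
})
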