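toy_features <- function(n = 60, seed = 3) {
  enfusion:::with_seed(seed, {
    y <- rep_len(c(0L, 1L), n)
    X <- cbind(x1 = y * 2 + stats::rnorm(n, sd = 0.3),
               x2 = -y + stats::rnorm(n, sd = 0.3))
    rownames(X) <- sprintf("s%03d", seq_len(n))
    list(X = X, y = y)
  })
}

test_that("fuse_features concatenates blocks and standardizes with stored stats", {
  a <- matrix(stats::rnorm(5 * 3), 5, 3,
              dimnames = list(paste0("s", 1:5), paste0("ms", 1:3)))
  b <- matrix(stats::rnorm(5 * 2), 5, 2,
              dimnames = list(paste0("s", 1:5), paste0("dyn", 1:2)))
  f <- fuse_features(a, b)
  expect_identical(dim(f), c(5L, 5L))
  expect_identical(colnames(f), c(colnames(a), colnames(b)))
  expect_equal(unname(colMeans(f)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(f, 2, stats::sd)), rep(1, 5), tolerance = 1e-9)

  # constant column maps to zero, not NaN
  a2 <- a; a2[, 2] <- 7
  f2 <- fuse_features(a2, b)
  expect_true(all(f2[, 2] == 0))

  # stored scaling reproduces the training transform on new data
  sc <- attr(f, "scaling")
  f3 <- fuse_features(a, b, scaling = sc)
  expect_equal(unclass(f3), unclass(f), ignore_attr = TRUE)

  bb <- b; rownames(bb) <- rev(rownames(b))
  expect_error(fuse_features(a, bb), "ids")
})

test_that("hard vote is the mean label with a strict 0.5 threshold", {
  # all 8 three-classifier label triples against a majority oracle
  for (a in 0:1) for (b in 0:1) for (c in 0:1) {
    v <- hard_vote(c(a, b, c))
    expect_equal(v$vote, mean(c(a, b, c)))
    expect_identical(v$class, as.integer(sum(c(a, b, c)) >= 2))
  }
  expect_identical(hard_vote(c(1, 1, 0))$class, 1L)
  expect_identical(hard_vote(c(0, 0, 0))$class, 0L)
  # even split: vote 0.5 is NOT an enhancer (strict inequality)
  expect_identical(hard_vote(c(1, 0))$class, 0L)
  expect_error(hard_vote(integer(0)), "no base labels")
  expect_error(hard_vote(c(1, 2)), "binary")
})

test_that("the cascade forest fits separable data within few layers", {
  tf <- toy_features(100, seed = 3)
  cfg <- list(n_forests = 2L, n_trees = 25L, max_layers = 3L, n_folds = 3L,
              predictor = "none")
  cf <- train_cascade_forest(tf$X, tf$y, cfg, seed = 3)
  expect_lte(cf$depth, 3L)
  p <- predict(cf, tf$X)
  expect_gte(mean((p > 0.5) == (tf$y == 1L)), 0.99)

  cf1 <- train_cascade_forest(tf$X, tf$y,
                              utils::modifyList(cfg, list(max_layers = 1L)),
                              seed = 3)
  expect_identical(cf1$depth, 1L)
  expect_identical(length(cf1$layers), 1L)
  expect_error(train_cascade_forest(tf$X, rep(1L, 100), cfg), "both classes")
})

test_that("cascade depth and layer feature growth follow the contract", {
  # weakly informative data keeps the cascade growing for several layers
  enfusion:::with_seed(5, {
    n <- 120
    y <- rep_len(c(0L, 1L), n)
    X <- matrix(stats::rnorm(n * 6), n, 6)
    X[, 1] <- X[, 1] + 0.8 * y
  })
  cfg <- list(n_forests = 2L, n_trees = 15L, max_layers = 4L, n_folds = 3L,
              predictor = "none")
  cf <- train_cascade_forest(X, y, cfg, seed = 9)
  expect_lte(cf$depth, 4L)
  # layer l consumes the original features plus (n_forests x 2) appended
  # probability columns per preceding layer
  for (l in seq_along(cf$layers)) {
    forest_fit <- cf$layers[[l]][[1]]$models[[1]]
    expect_identical(length(forest_fit$forest$ncat),
                     ncol(X) + (l - 1L) * cfg$n_forests * 2L)
  }
})

test_that("the gradient-boosted final predictor stacks on the cascade features", {
  tf <- toy_features(80, seed = 7)
  cfg <- list(n_forests = 2L, n_trees = 15L, max_layers = 2L, n_folds = 3L,
              predictor = "xgboost")
  cf <- train_cascade_forest(tf$X, tf$y, cfg, seed = 2)
  expect_false(is.null(cf$predictor))
  p <- predict(cf, tf$X)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(mean((p > 0.5) == (tf$y == 1L)), 0.95)
})

test_that("label-shuffled data gives chance-level held-out cascade accuracy", {
  cfg <- list(n_forests = 2L, n_trees = 10L, max_layers = 1L, n_folds = 3L,
              predictor = "none")
  accs <- enfusion:::with_seed(17, {
    vapply(1:20, function(rep_i) {
      n <- 60
      X <- matrix(stats::rnorm(n * 5), n, 5)
      y <- sample(rep_len(c(0L, 1L), n))
      tr <- sample(n, 40)
      cf <- train_cascade_forest(X[tr, ], y[tr], cfg, seed = rep_i)
      mean((predict(cf, X[-tr, ]) > 0.5) == (y[-tr] == 1L))
    }, 1)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("the three-member ensemble trains, votes and is deterministic", {
  tf <- toy_features(80, seed = 21)
  f <- fuse_features(tf$X[, 1, drop = FALSE], tf$X[, 2, drop = FALSE])
  cfg <- ensemble_config(cascade_forest = list(n_forests = 2L, n_trees = 10L,
                                               max_layers = 1L), seed = 4)
  m <- train_ensemble(f, tf$y, cfg)
  pred <- predict(m, f)
  expect_identical(nrow(pred), 80L)
  expect_true(all(pred$vote %in% c(0, 1/3, 2/3, 1)))
  expect_identical(pred$class, as.integer(pred$vote > 0.5))
  expect_gte(mean(pred$class == tf$y), 0.9)
  for (base in c("svm", "random_forest", "cascade")) {
    expect_gte(mean(pred[[base]] == tf$y), 0.8)
  }

  m2 <- train_ensemble(f, tf$y, cfg)
  expect_identical(predict(m2, f), pred)

  # per-sample independence: permuting rows permutes predictions
  # (rebuild the fused matrix so the stored scaling is applied once)
  perm <- enfusion:::with_seed(2, sample(80))
  f_perm <- fuse_features(tf$X[perm, 1, drop = FALSE],
                          tf$X[perm, 2, drop = FALSE],
                          scaling = attr(f, "scaling"))
  pred_perm <- predict(m, f_perm)
  expect_identical(pred_perm$class, pred$class[perm])
  expect_identical(pred_perm$vote, pred$vote[perm])

  expect_error(predict(m, f[, c(2, 1)]), "fusion feature-name")
})

test_that("a minimum viable input of two samples per class trains", {
  X <- matrix(c(0, 0, 1, 1, 5, 6, 7, 8), 4, 2,
              dimnames = list(paste0("s", 1:4), c("a", "b")))
  y <- c(0L, 0L, 1L, 1L)
  f <- fuse_features(X[, 1, drop = FALSE], X[, 2, drop = FALSE])
  cfg <- ensemble_config(cascade_forest = list(n_forests = 2L, n_trees = 5L,
                                               max_layers = 1L), seed = 1)
  m <- train_ensemble(f, y, cfg)
  pred <- predict(m, f)
  expect_identical(nrow(pred), 4L)
  expect_identical(ncol(pred), 6L)  # id, 3 base labels, vote, class
})
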