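# Base learners and the stacking ensemble.

make_blobs <- function(n_per = 100, sep = 3, seed = 41) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, mean = sep), ncol = 2))
  colnames(X) <- c("f1", "f2")
  list(X = scale(X), y = rep(c(0L, 1L), each = n_per))
}

test_that("the ELM solves the ridge normal equations and interpolates small data", {
  # 20 well-separated points with arbitrary labels
  u <- seq(-2, 2, length.out = 20)
  X <- cbind(a = u, b = u^2 - 1)
  y <- rep(c(0L, 1L), 10)
  m <- train_elm(X, y, n_hidden = 200, ridge = 1e-3, seed = 7)
  # analytic solution: residual of (H'H + rI) beta = H'y is ~zero
  H <- plogis(X %*% m$W + matrix(m$b, nrow(X), m$n_hidden, byrow = TRUE))
  lhs <- (crossprod(H) + diag(m$ridge, m$n_hidden)) %*% m$beta
  rhs <- crossprod(H, y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)
  # an over-complete random basis at near-zero ridge interpolates arbitrary
  # labels of 20 distinct points (at the pipeline's ~20-feature dimension)
  set.seed(43)
  X10 <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("f", 1:10)))
  m0 <- train_elm(X10, y, n_hidden = 200, ridge = 1e-8, seed = 7)
  expect_lt(max(abs(predict_proba(m0, X10) - y)), 0.05)
})

test_that("learners are deterministic under a fixed seed and separate clean blobs", {
  blobs <- make_blobs()
  m1 <- train_elm(blobs$X, blobs$y, seed = 5)
  m2 <- train_elm(blobs$X, blobs$y, seed = 5)
  expect_identical(m1$beta, m2$beta)
  test <- make_blobs(seed = 99)
  for (fit in list(train_logreg(blobs$X, blobs$y),
                   train_elm(blobs$X, blobs$y, seed = 5),
                   train_boost(blobs$X, blobs$y, seed = 5))) {
    p <- predict_proba(fit, test$X)
    expect_true(all(p >= 0 & p <= 1))
    expect_gte(mean((p > 0.5) == test$y), 0.95)
  }
})

test_that("probability predictions respect the feature-name contract", {
  blobs <- make_blobs(n_per = 30)
  m <- train_logreg(blobs$X, blobs$y)
  bad <- blobs$X
  colnames(bad) <- c("x1", "x2")
  expect_error(predict_proba(m, bad), "Missing feature")
  # extra columns are fine; order does not matter
  extra <- cbind(blobs$X[, 2:1, drop = FALSE], junk = rnorm(nrow(blobs$X)))
  expect_equal(predict_proba(m, extra), predict_proba(m, blobs$X))
})

test_that("stacking produces in-range out-of-fold meta-features and is reproducible", {
  blobs <- make_blobs(n_per = 60, sep = 1.5)
  m <- train_stack(blobs$X, blobs$y, seed = 11)
  expect_equal(dim(m$oof), c(120, 3))
  expect_true(all(m$oof >= 0 & m$oof <= 1))
  expect_false(anyNA(m$oof))
  m2 <- train_stack(blobs$X, blobs$y, seed = 11)
  expect_equal(predict_stack(m, blobs$X), predict_stack(m2, blobs$X))
  m3 <- train_stack(blobs$X, blobs$y, seed = 12)
  expect_false(identical(m$oof, m3$oof)) # folds move with the seed
})

test_that("stack prediction equals the manual base-to-meta composition", {
  blobs <- make_blobs(n_per = 50, sep = 2)
  test <- make_blobs(n_per = 20, sep = 2, seed = 77)
  m <- train_stack(blobs$X, blobs$y, seed = 3)
  base <- sapply(m$base_models, function(b) predict_proba(b, test$X))
  colnames(base) <- c("lr", "elm", "boost")
  manual <- predict_proba(m$meta_model, base)
  expect_equal(predict_stack(m, test$X), manual, tolerance = 1e-12)
  # permuting rows permutes scores identically
  perm <- sample(nrow(test$X))
  expect_equal(predict_stack(m, test$X[perm, ]), predict_stack(m, test$X)[perm])
})

test_that("mean fusion averages the base probabilities", {
  blobs <- make_blobs(n_per = 40, sep = 2)
  m <- train_stack(blobs$X, blobs$y, fusion = "mean", seed = 4)
  test <- make_blobs(n_per = 10, sep = 2, seed = 78)
  base <- sapply(m$base_models, function(b) predict_proba(b, test$X))
  expect_equal(predict_stack(m, test$X), rowMeans(base), tolerance = 1e-12)
  expect_null(m$meta_model)
})

test_that("out-of-fold meta-features leak nothing across rows", {
  # deleting a row and refitting must not change any other row's
  # out-of-fold meta-feature, provided the fold assignment of the
  # remaining rows is held fixed
  blobs <- make_blobs(n_per = 25, sep = 1)
  y <- blobs$y
  fold <- eegfatigue:::.stratified_folds(y, 5, 123)
  oof_for <- function(keep) {
    X <- blobs$X[keep, , drop = FALSE]
    yk <- y[keep]
    fk <- fold[keep]
    oof <- matrix(NA_real_, sum(keep), 3)
    for (f in unique(fk)) {
      tr <- fk != f
      ms <- list(train_logreg(X[tr, ], yk[tr]),
                 train_elm(X[tr, ], yk[tr], seed = 9),
                 train_boost(X[tr, ], yk[tr], seed = 9))
      oof[!tr, ] <- sapply(ms, function(m) predict_proba(m, X[!tr, , drop = FALSE]))
    }
    oof
  }
  keep_all <- rep(TRUE, length(y))
  drop_one <- keep_all; drop_one[10] <- FALSE
  oof_full <- oof_for(keep_all)
  oof_drop <- oof_for(drop_one)
  # held-out rows sharing row 10's fold keep identical meta-features:
  # their training split never saw row 10
  same <- setdiff(which(fold == fold[10]), 10)
  same_d <- match(same, which(drop_one))
  expect_equal(oof_full[same, ], oof_drop[same_d, ], tolerance = 1e-9)
})

test_that("stacking degenerates gracefully when base learners agree", {
  blobs <- make_blobs(n_per = 60, sep = 2.5)
  test <- make_blobs(n_per = 40, sep = 2.5, seed = 55)
  m <- train_stack(blobs$X, blobs$y, seed = 6)
  acc_stack <- mean((predict_stack(m, test$X) > 0.5) == test$y)
  acc_lr <- mean((predict_proba(m$base_models$lr, test$X) > 0.5) == test$y)
  expect_gte(acc_stack, acc_lr - 0.01)
  # agreeing confident base learners yield a confident fused score
  strong <- matrix(0.9, 1, 3, dimnames = list(NULL, c("lr", "elm", "boost")))
  expect_gt(predict_proba(m$meta_model, strong), 0.5)
})

test_that("tidy and glance summarise a fitted stack", {
  blobs <- make_blobs(n_per = 30)
  m <- train_stack(blobs$X, blobs$y, seed = 2)
  td <- tidy(m)
  expect_equal(td$term, c("(Intercept)", "lr", "elm", "boost"))
  gl <- glance(m)
  expect_equal(gl$fusion, "stack")
  expect_equal(gl$n_features, 2L)
})
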