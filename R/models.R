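# Base learners (ridge-penalised logistic regression, extreme learning
# machine, gradient-boosted trees) and the stacking ensemble that fuses
# their probabilities through a logistic meta-combiner fitted on
# out-of-fold predictions.

.as_feature_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

.check_features <- function(model, X) {
  X <- .as_feature_matrix(X)
  want <- model$feature_names
  if (!all(want %in% colnames(X))) {
    abort(sprintf("Missing feature column(s): %s",
                  paste(setdiff(want, colnames(X)), collapse = ", ")))
  }
  X[, want, drop = FALSE]
}

# Per-feature z-scoring fitted on training rows only.
fit_zscore <- function(X) {
  X <- .as_feature_matrix(X)
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[sigma == 0] <- 1
  list(mu = mu, sigma = sigma, feature_names = colnames(X))
}

apply_zscore <- function(scaler, X) {
  X <- .as_feature_matrix(X)[, scaler$feature_names, drop = FALSE]
  sweep(sweep(X, 2, scaler$mu), 2, scaler$sigma, "/")
}

#' Ridge-penalised logistic regression learner
#'
#' L2-regularised logistic regression (via glmnet at a single fixed
#' lambda); the small default penalty keeps coefficients finite under
#' quasi-separation without materially shrinking them.
#'
#' @param X Feature matrix (rows = epochs), already standardised by the
#'   caller.
#' @param y Binary 0/1 labels.
#' @param lambda Ridge penalty (default `1 / nrow(X)`).
#' @return An object of class `fatigue_logreg`.
#' @export
train_logreg <- function(X, y, lambda = NULL) {
  X <- .as_feature_matrix(X)
  lambda <- lambda %||% (1 / nrow(X))
  fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = 0, lambda = lambda, standardize = FALSE)
  structure(list(fit = fit, lambda = lambda, feature_names = colnames(X)),
            class = "fatigue_logreg")
}

#' Extreme learning machine learner
#'
#' A single-hidden-layer feed-forward network whose input weights and
#' hidden biases are drawn once from uniform(-1, 1) and never trained; the
#' output weights are the closed-form ridge-regularised least-squares
#' solution mapping the sigmoid hidden activations to the 0/1 labels.
#'
#' @param X Standardised feature matrix.
#' @param y Binary 0/1 labels.
#' @param n_hidden Hidden units (default 200).
#' @param ridge Ridge regularisation on the output weights (default 1e-3).
#' @param seed Seed for the random hidden layer.
#' @return An object of class `fatigue_elm`.
#' @export
train_elm <- function(X, y, n_hidden = 200L, ridge = 1e-3, seed = 1L) {
  if (n_hidden < 1) abort("`n_hidden` must be >= 1.")
  X <- .as_feature_matrix(X)
  p <- ncol(X)
  wb <- with_local_seed(seed, {
    list(W = matrix(runif(p * n_hidden, -1, 1), p, n_hidden),
         b = runif(n_hidden, -1, 1))
  })
  H <- plogis(X %*% wb$W + matrix(wb$b, nrow(X), n_hidden, byrow = TRUE))
  # Primal and dual forms of the same ridge solution; the dual (kernel)
  # form is better conditioned when rows < hidden units.
  beta <- if (nrow(H) < n_hidden) {
    crossprod(H, solve(tcrossprod(H) + diag(ridge, nrow(H)), y))
  } else {
    solve(crossprod(H) + diag(ridge, n_hidden), crossprod(H, y))
  }
  structure(list(W = wb$W, b = wb$b, beta = beta, n_hidden = n_hidden,
                 ridge = ridge, seed = seed, feature_names = colnames(X)),
            class = "fatigue_elm")
}

#' Gradient-boosted tree learner
#'
#' Gradient-boosted decision trees (xgboost backend) with logistic loss:
#' 200 trees, maximum depth 6, learning rate 0.1 by default.
#'
#' @param X Feature matrix.
#' @param y Binary 0/1 labels.
#' @param nrounds,max_depth,eta Boosting hyperparameters.
#' @param seed Seed (single-threaded boosting is deterministic; the seed is
#'   kept for interface symmetry).
#' @return An object of class `fatigue_boost`.
#' @export
train_boost <- function(X, y, nrounds = 200L, max_depth = 6L, eta = 0.1,
                        seed = 1L) {
  X <- .as_feature_matrix(X)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
  fit <- with_local_seed(seed, {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1L),
      data = dtrain, nrounds = nrounds, verbose = 0
    )
  })
  structure(list(fit = fit, feature_names = colnames(X)),
            class = "fatigue_boost")
}

#' Probability predictions of a fitted learner
#'
#' Scores in `[0, 1]` per row; thresholding at 0.5 gives class labels.
#'
#' @param model A fitted learner or stacking model.
#' @param X Feature matrix whose columns include the training features.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict_proba <- function(model, X, ...) UseMethod("predict_proba")

#' @export
predict_proba.fatigue_logreg <- function(model, X, ...) {
  X <- .check_features(model, X)
  as.numeric(predict(model$fit, newx = X, type = "response"))
}

#' @export
predict_proba.fatigue_elm <- function(model, X, ...) {
  X <- .check_features(model, X)
  H <- plogis(X %*% model$W + matrix(model$b, nrow(X), model$n_hidden,
                                     byrow = TRUE))
  pmin(pmax(as.numeric(H %*% model$beta), 0), 1)
}

#' @export
predict_proba.fatigue_boost <- function(model, X, ...) {
  X <- .check_features(model, X)
  as.numeric(predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1L)))
}

# Stratified fold assignment, deterministic under `seed`.
.stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  fold
}

#' Train the stacking ensemble
#'
#' Fits the three base learners (logistic regression, ELM, gradient-boosted
#' trees) in `n_inner_folds` stratified inner folds, collects their
#' held-out probabilities into a 3-column out-of-fold meta-feature matrix,
#' fits a logistic meta-combiner on that matrix, and finally refits the
#' base learners on all rows for deployment. With `fusion = "mean"` the
#' learned combiner is replaced by the plain average of the three base
#' probabilities.
#'
#' @param X Standardised feature matrix.
#' @param y Binary 0/1 labels (both classes present).
#' @param n_inner_folds Inner folds for the meta-features (default 5).
#' @param fusion `"stack"` (learned logistic combiner, default) or
#'   `"mean"` (average of base probabilities).
#' @param seed Pipeline seed; per-learner substreams are derived from it.
#' @param elm_hidden,elm_ridge ELM hyperparameters.
#' @param boost_nrounds,boost_depth,boost_eta Boosting hyperparameters.
#' @return An object of class `fatigue_stack`.
#' @export
train_stack <- function(X, y, n_inner_folds = 5L,
                        fusion = c("stack", "mean"), seed = 1L,
                        elm_hidden = 200L, elm_ridge = 1e-3,
                        boost_nrounds = 200L, boost_depth = 6L,
                        boost_eta = 0.1) {
  fusion <- match.arg(fusion)
  X <- .as_feature_matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("Both classes must be present.")
  k <- n_inner_folds
  min_class <- min(table(y))
  if (k > min_class) {
    k <- max(2L, as.integer(min_class))
    warn(sprintf("Refolding with k = %d: a class is too small for %d inner folds.",
                 k, n_inner_folds))
  }
  fit_base <- function(Xtr, ytr, sd_elm, sd_boost) {
    list(
      lr = train_logreg(Xtr, ytr),
      elm = train_elm(Xtr, ytr, n_hidden = elm_hidden, ridge = elm_ridge,
                      seed = sd_elm),
      boost = train_boost(Xtr, ytr, nrounds = boost_nrounds,
                          max_depth = boost_depth, eta = boost_eta,
                          seed = sd_boost)
    )
  }
  meta_model <- NULL
  oof <- NULL
  if (fusion == "stack") {
    fold <- .stratified_folds(y, k, derive_seed(seed, "folds"))
    oof <- matrix(NA_real_, nrow(X), 3,
                  dimnames = list(NULL, c("lr", "elm", "boost")))
    for (f in seq_len(k)) {
      tr <- fold != f
      base_f <- fit_base(X[tr, , drop = FALSE], y[tr],
                         derive_seed(seed, "elm", f),
                         derive_seed(seed, "boost", f))
      Xte <- X[!tr, , drop = FALSE]
      oof[!tr, ] <- vapply(base_f, function(mod) predict_proba(mod, Xte),
                           numeric(sum(!tr)))
    }
    meta_model <- train_logreg(oof, y, lambda = 1 / nrow(oof))
  }
  base_models <- fit_base(X, y, derive_seed(seed, "elm", 0L),
                          derive_seed(seed, "boost", 0L))
  structure(
    list(base_models = base_models, meta_model = meta_model, fusion = fusion,
         n_inner_folds = k, oof = oof, seed = seed,
         feature_names = colnames(X)),
    class = "fatigue_stack"
  )
}

#' Predict with a stacking ensemble
#'
#' Applies the three deployed base learners and fuses their probabilities
#' with the meta-combiner (or their mean, for `fusion = "mean"`).
#'
#' @param model A [train_stack()] model.
#' @param X Feature matrix.
#' @return Scores in `[0, 1]`.
#' @export
predict_stack <- function(model, X) {
  X <- .check_features(model, X)
  base <- vapply(model$base_models, function(mod) predict_proba(mod, X),
                 numeric(nrow(X)))
  if (nrow(X) == 1L) base <- matrix(base, nrow = 1,
                                    dimnames = list(NULL, names(model$base_models)))
  colnames(base) <- c("lr", "elm", "boost")
  if (model$fusion == "mean") {
    rowMeans(base)
  } else {
    predict_proba(model$meta_model, base)
  }
}

#' @export
predict_proba.fatigue_stack <- function(model, X, ...) predict_stack(model, X)

#' @export
tidy.fatigue_stack <- function(x, ...) {
  cf <- if (!is.null(x$meta_model)) {
    as.numeric(stats::coef(x$meta_model$fit))
  } else {
    c(NA_real_, rep(1 / 3, 3))
  }
  tibble::tibble(term = c("(Intercept)", "lr", "elm", "boost"),
                 estimate = cf)
}

#' @export
glance.fatigue_stack <- function(x, ...) {
  tibble::tibble(fusion = x$fusion, n_inner_folds = x$n_inner_folds,
                 n_features = length(x$feature_names), seed = x$seed)
}
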