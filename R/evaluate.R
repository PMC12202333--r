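# Leave-one-subject-out cross-validation, metrics, ROC/AUC and the
# end-to-end pipeline runner.

#' Confusion matrix from labels and predictions
#'
#' Positive class = fatigue (label 1) throughout.
#'
#' @param truth Binary 0/1 true labels.
#' @param predicted Binary 0/1 predicted labels.
#' @return A `confusion_matrix` object (named list `tn`, `fp`, `fn`, `tp`).
#' @export
confusion_matrix <- function(truth, predicted) {
  structure(list(tn = sum(truth == 0 & predicted == 0),
                 fp = sum(truth == 0 & predicted == 1),
                 fn = sum(truth == 1 & predicted == 0),
                 tp = sum(truth == 1 & predicted == 1)),
            class = "confusion_matrix")
}

.add_cm <- function(a, b) {
  structure(list(tn = a$tn + b$tn, fp = a$fp + b$fp,
                 fn = a$fn + b$fn, tp = a$tp + b$tp),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity (= recall, on the fatigue class), specificity,
#' precision and F1. Ratios with a zero denominator are reported as `NA`
#' rather than 0.
#'
#' @param cm A [confusion_matrix()] (or list with `tn`, `fp`, `fn`, `tp`).
#' @return A one-row tibble with columns `ACC`, `SN`, `SP`, `precision`,
#'   `recall`, `F1`.
#' @export
compute_metrics <- function(cm) {
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  if (total == 0) abort("Empty confusion matrix.")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sn <- ratio(cm$tp, cm$tp + cm$fn)
  sp <- ratio(cm$tn, cm$tn + cm$fp)
  prec <- ratio(cm$tp, cm$tp + cm$fp)
  f1 <- if (!is.na(prec) && !is.na(sn) && (prec + sn) > 0) {
    2 * prec * sn / (prec + sn)
  } else {
    NA_real_
  }
  tibble::tibble(ACC = (cm$tp + cm$tn) / total, SN = sn, SP = sp,
                 precision = prec, recall = sn, F1 = f1)
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: the test set is all of that subject's epochs, the
#' training set is everyone else's. All fold-level transforms (pruning,
#' scaling, model fitting) must be fitted inside the fold on training rows
#' only.
#'
#' @param table Feature table with a `subject_id` column.
#' @return A tibble with columns `subject`, `train` and `test`
#'   (list-columns of row indices).
#' @export
loso_split <- function(table) {
  subjects <- unique(table$subject_id)
  if (length(subjects) < 2) abort("Need at least 2 subjects for LOSO.")
  purrr::map_dfr(subjects, function(s) {
    test <- which(table$subject_id == s)
    if (length(unique(table$label[test])) < 2) {
      warn(sprintf("Subject %s has a single class; some metrics will be NA.", s))
    }
    tibble::tibble(subject = s, train = list(which(table$subject_id != s)),
                   test = list(test))
  })
}

#' ROC curve
#'
#' Threshold sweep over the unique scores (ties grouped), positive class =
#' label 1. The first row is the (0, 0) corner.
#'
#' @param labels Binary 0/1 labels (both classes present).
#' @param scores Numeric scores, higher = more positive.
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(labels, scores) {
  if (length(unique(labels)) < 2) abort("Both classes must be present.")
  if (any(!is.finite(scores))) abort("Scores must be finite.")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  np <- sum(lab == 1)
  nn <- sum(lab == 0)
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  last <- !duplicated(sc, fromLast = TRUE) # last index of each tied block
  tibble::tibble(threshold = c(Inf, sc[last]),
                 fpr = c(0, fp[last] / nn),
                 tpr = c(0, tp[last] / np))
}

#' Area under the ROC curve
#'
#' Trapezoidal rule over [roc_curve()]; with tied scores grouped this
#' equals the normalised Mann-Whitney U statistic
#' `P(score+ > score-) + 0.5 P(tie)`.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  rc <- roc_curve(labels, scores)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}

#' Mean and standard deviation of per-subject metrics
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of each metric across
#' subjects; subjects with an undefined (NA) metric are excluded from that
#' metric's n.
#'
#' @param per_subject Tibble of per-subject metric rows (one row per
#'   subject) containing numeric metric columns.
#' @return A tibble with columns `metric`, `mean`, `sd`, `n`.
#' @export
summarize_metrics <- function(per_subject) {
  if (nrow(per_subject) < 2) abort("Need at least 2 subjects to summarise.")
  num <- per_subject[vapply(per_subject, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("subject", "subject_id"))]
  tidyr::pivot_longer(num, dplyr::everything(),
                      names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop") |>
    dplyr::arrange(match(.data$metric, names(num)))
}

#' Leave-one-subject-out evaluation of a feature table
#'
#' For every LOSO fold: prunes correlated features on the training rows
#' ([correlation_prune()]), z-scores on the training rows, trains the
#' requested classifier, and scores the held-out subject. Decision
#' threshold for the confusion matrices is 0.5; ROC/AUC are computed on
#' the pooled scores.
#'
#' @param features Feature table from [extract_feature_table()] (or the
#'   RBP baseline); must contain `subject_id` and `label`.
#' @param classifier `"stack"` (default), `"lr"`, `"elm"` or `"boost"`.
#' @param fusion Fusion rule for the stacking model.
#' @param prune_threshold Correlation-pruning threshold (default 0.98).
#' @param seed Pipeline seed.
#' @param ... Passed to [train_stack()].
#' @return A `cv_result` object: list with `per_subject` (tibble of
#'   per-subject metrics), `pooled` (summed confusion matrix), `summary`
#'   (mean +/- SD), `scores` (pooled labels and scores), `auc`.
#' @export
run_loso <- function(features, classifier = c("stack", "lr", "elm", "boost"),
                     fusion = c("stack", "mean"), prune_threshold = 0.98,
                     seed = 1L, ...) {
  classifier <- match.arg(classifier)
  fusion <- match.arg(fusion)
  folds <- loso_split(features)
  feats <- feature_columns(features)
  per_subject <- vector("list", nrow(folds))
  all_scores <- vector("list", nrow(folds))
  pooled <- structure(list(tn = 0, fp = 0, fn = 0, tp = 0),
                      class = "confusion_matrix")
  for (i in seq_len(nrow(folds))) {
    tr_idx <- folds$train[[i]]
    te_idx <- folds$test[[i]]
    train_tbl <- features[tr_idx, , drop = FALSE]
    pruned <- correlation_prune(train_tbl, threshold = prune_threshold)
    kept <- attr(pruned$report, "kept")
    scaler <- fit_zscore(as.matrix(train_tbl[kept]))
    Xtr <- apply_zscore(scaler, as.matrix(train_tbl[kept]))
    Xte <- apply_zscore(scaler, as.matrix(features[te_idx, kept, drop = FALSE]))
    ytr <- features$label[tr_idx]
    fold_seed <- derive_seed(seed, "fold", i)
    model <- switch(
      classifier,
      stack = train_stack(Xtr, ytr, fusion = fusion, seed = fold_seed, ...),
      lr = train_logreg(Xtr, ytr),
      elm = train_elm(Xtr, ytr, seed = fold_seed),
      boost = train_boost(Xtr, ytr, seed = fold_seed)
    )
    scores <- predict_proba(model, Xte)
    truth <- features$label[te_idx]
    cm <- confusion_matrix(truth, as.integer(scores >= 0.5))
    pooled <- .add_cm(pooled, cm)
    met <- compute_metrics(cm)
    met$AUC <- if (length(unique(truth)) == 2) roc_auc(truth, scores) else NA_real_
    per_subject[[i]] <- dplyr::bind_cols(
      tibble::tibble(subject = folds$subject[i]), met,
      tibble::tibble(cm = list(cm), n_kept = length(kept))
    )
    all_scores[[i]] <- tibble::tibble(subject = folds$subject[i],
                                      label = truth, score = scores)
  }
  per_subject <- dplyr::bind_rows(per_subject)
  scores_tbl <- dplyr::bind_rows(all_scores)
  metric_cols <- per_subject[c("subject", "ACC", "SN", "SP", "precision",
                               "recall", "F1", "AUC")]
  structure(
    list(per_subject = per_subject,
         pooled = pooled,
         summary = summarize_metrics(metric_cols),
         scores = scores_tbl,
         auc = roc_auc(scores_tbl$label, scores_tbl$score),
         classifier = classifier, fusion = fusion, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out CV (%s classifier, %d subjects)\n",
              x$classifier, nrow(x$per_subject)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  cat(sprintf("  pooled ACC %.4f, pooled AUC %.4f\n",
              compute_metrics(x$pooled)$ACC, x$auc))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) {
  x$per_subject[c("subject", "ACC", "SN", "SP", "precision", "recall",
                  "F1", "AUC")]
}

#' @export
glance.cv_result <- function(x, ...) {
  s <- x$summary
  out <- tibble::as_tibble(as.list(setNames(s$mean, paste0("mean_", s$metric))))
  out$pooled_ACC <- compute_metrics(x$pooled)$ACC
  out$pooled_AUC <- x$auc
  out$n_subjects <- nrow(x$per_subject)
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.cv_result <- function(object, ...) {
  rc <- roc_curve(object$scores$label, object$scores$score)
  ggplot2::ggplot(rc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("Pooled ROC (%s), AUC = %.3f",
                                  object$classifier, object$auc)) +
    ggplot2::theme_minimal()
}

# Select the feature columns belonging to a channel set.
.channel_subset <- function(features, channels) {
  feats <- feature_columns(features)
  keep <- switch(channels,
                 FP1 = grepl("_FP1$", feats),
                 FP2 = grepl("_FP2$", feats),
                 both = rep(TRUE, length(feats)),
                 abort(sprintf("Unknown channel set '%s'.", channels)))
  features[c("subject_id", "state", "label", feats[keep])]
}

#' Run the full detection pipeline on a set of recordings
#'
#' Preprocesses the recordings, extracts the entropy feature table (one
#' shared table reused across channel sets), and runs leave-one-subject-out
#' evaluation for each requested channel set (`FP1`, `FP2`, `both`), with
#' per-fold pruning and scaling. `feature_set = "rbp"` swaps the entropy
#' features for the FFT relative-band-power baseline under the identical
#' protocol.
#'
#' @param recordings Recording tibble ([generate_cohort()] format).
#' @param config An [entropy_config()].
#' @param channels Channel sets to evaluate (default all three).
#' @param feature_set `"entropy"` (default) or `"rbp"`.
#' @param classifier,fusion,seed Passed to [run_loso()].
#' @param verbose Print progress.
#' @param ... Passed to [run_loso()].
#' @return A tibble with one row per channel set: `channels`, `n_epochs`,
#'   `mean_ACC`, `sd_ACC`, `pooled_ACC`, `AUC` and a `result` list-column
#'   of `cv_result` objects.
#' @export
run_pipeline <- function(recordings, config = entropy_config(),
                         channels = c("FP1", "FP2", "both"),
                         feature_set = c("entropy", "rbp"),
                         classifier = "stack", fusion = "stack", seed = 1L,
                         verbose = FALSE, ...) {
  feature_set <- match.arg(feature_set)
  epochs <- preprocess_pipeline(recordings, verbose = verbose)
  features <- if (feature_set == "entropy") {
    extract_feature_table(epochs, config)
  } else {
    extract_rbp_table(epochs)
  }
  purrr::map_dfr(channels, function(ch) {
    if (verbose) message("Evaluating channel set: ", ch)
    sub <- .channel_subset(features, ch)
    res <- run_loso(sub, classifier = classifier, fusion = fusion,
                    seed = seed, ...)
    acc <- res$summary[res$summary$metric == "ACC", ]
    tibble::tibble(channels = ch, n_epochs = nrow(sub),
                   mean_ACC = acc$mean, sd_ACC = acc$sd,
                   pooled_ACC = compute_metrics(res$pooled)$ACC,
                   AUC = res$auc, result = list(res))
  })
}
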