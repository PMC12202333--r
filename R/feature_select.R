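# Correlation-based feature pruning.

#' Drop highly correlated features
#'
#' Computes the Pearson correlation matrix of the feature columns (the
#' caller supplies the training slice only - pruning must never see test
#' rows) and greedily scans features in table order, dropping any feature
#' whose absolute correlation with an earlier kept feature exceeds
#' `threshold`. Zero-variance features are dropped with reason
#' `"constant"`. Greedy keep-first order makes the result deterministic.
#'
#' @param table Feature table (tibble); columns other than `subject_id`,
#'   `state`, `epoch`, `label` are treated as features.
#' @param threshold Absolute-correlation threshold in `(0, 1]`
#'   (default 0.98).
#' @return A list with `table` (pruned tibble) and `report` (a
#'   `prune_report`: tibble of dropped features with partner and
#'   correlation, plus the kept names and threshold as attributes).
#' @export
correlation_prune <- function(table, threshold = 0.98) {
  if (nrow(table) < 2) abort("Need at least 2 rows to estimate correlations.")
  if (!(threshold > 0 && threshold <= 1)) abort("`threshold` must be in (0, 1].")
  feats <- feature_columns(table)
  X <- as.matrix(table[feats])
  sds <- apply(X, 2, sd)
  dropped <- tibble::tibble(dropped = character(), partner = character(),
                            correlation = numeric(), reason = character())
  kept <- character()
  const <- feats[sds == 0]
  for (f in const) {
    dropped <- dplyr::add_row(dropped, dropped = f, partner = NA_character_,
                              correlation = NA_real_, reason = "constant")
  }
  varying <- setdiff(feats, const)
  if (length(varying) > 0) {
    cm <- stats::cor(X[, varying, drop = FALSE])
    for (f in varying) {
      r_prev <- if (length(kept)) abs(cm[f, kept]) else numeric()
      if (length(r_prev) && max(r_prev) > threshold) {
        partner <- kept[which.max(r_prev)]
        dropped <- dplyr::add_row(dropped, dropped = f, partner = partner,
                                  correlation = cm[f, partner],
                                  reason = "correlated")
      } else {
        kept <- c(kept, f)
      }
    }
  }
  pruned <- table[c(setdiff(names(table), feats), kept)]
  report <- structure(dropped, kept = kept, threshold = threshold,
                      class = c("prune_report", class(dropped)))
  list(table = pruned, report = report)
}

#' Pearson correlation matrix of a feature table
#'
#' Symmetric, unit diagonal. Constant columns get zero off-diagonal entries
#' and are flagged in the `constant` attribute.
#'
#' @inheritParams correlation_prune
#' @return A correlation matrix with feature names as dimnames.
#' @export
correlation_heatmap <- function(table) {
  if (nrow(table) < 2) abort("Need at least 2 rows.")
  feats <- feature_columns(table)
  X <- as.matrix(table[feats])
  sds <- apply(X, 2, sd)
  cm <- suppressWarnings(stats::cor(X))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  attr(cm, "constant") <- feats[sds == 0]
  cm
}

#' Plot a feature correlation heatmap
#'
#' @inheritParams correlation_prune
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(table) {
  cm <- correlation_heatmap(table)
  df <- tibble::as_tibble(as.table(cm), .name_repair = ~ c("x", "y", "r"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
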