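# Assemble per-epoch feature vectors and feature tables.

# Feature names for one channel, in stable order.
.channel_feature_names <- function(ch, config) {
  c(paste0(c("AE", "FE", "KE", "PE", "SE", "SPE", "WPE"), "_", ch),
    paste0("WLE_", seq_len(config$wle_levels + 1), "_", ch),
    paste0("STE_", ch))
}

#' Names of the entropy features at a given configuration
#'
#' @param config An [entropy_config()].
#' @return Character vector (22 names at defaults), FP1 block then FP2.
#' @export
entropy_feature_names <- function(config = entropy_config()) {
  c(.channel_feature_names("FP1", config), .channel_feature_names("FP2", config))
}

# All scalar features of one channel; `other` is the opposite channel
# (needed for the transfer-entropy feature, which measures information
# flowing INTO this channel).
.channel_features <- function(x, other, fs, config) {
  vals <- c(
    approximate_entropy(x, config$m_aef, config$r_factor),
    fuzzy_entropy(x, config$m_aef, config$r_factor, config$fe_gradient),
    kolmogorov_entropy(x, config$m_ke),
    permutation_entropy(x, config$pe_m, config$pe_tau, config$pe_scale),
    as.numeric(sample_entropy(x, config$m_aef, config$r_factor)),
    spectral_entropy(x, fs, config$spe_band),
    wavelet_packet_energy_entropy(x, config$wavelet, config$wpe_depth),
    wavelet_log_energy(x, config$wavelet, config$wle_levels),
    symbolic_transfer_entropy(other, x, config$ste_k)
  )
  unname(vals)
}

#' Extract the entropy feature vector of one epoch
#'
#' Computes, per channel: approximate, fuzzy, Kolmogorov, permutation,
#' sample, spectral and wavelet-packet energy entropy, the wavelet
#' log-energy leaves, and the symbolic transfer entropy flowing into the
#' channel from the other channel - 22 named values at the default
#' configuration, named to match the `<MEASURE>_<CHANNEL>` convention
#' (e.g. `WLE_2_FP1`, `STE_FP2`).
#'
#' @param fp1,fp2 Numeric vectors: one preprocessed 1-s epoch per channel.
#' @param fs Sampling rate in Hz.
#' @param config An [entropy_config()].
#' @return A named numeric vector of length 22 (at defaults).
#' @export
extract_features <- function(fp1, fp2, fs, config = entropy_config()) {
  vals <- c(.channel_features(fp1, fp2, fs, config),
            .channel_features(fp2, fp1, fs, config))
  if (any(!is.finite(vals))) {
    bad <- entropy_feature_names(config)[!is.finite(vals)]
    abort(sprintf("Non-finite feature value(s): %s", paste(bad, collapse = ", ")))
  }
  setNames(vals, entropy_feature_names(config))
}

#' Build the epochs-by-features entropy table
#'
#' Applies [extract_features()] to every epoch and returns the classifier
#' input: one row per epoch with the named entropy features plus
#' `subject_id`, `state` and `label` (normal = 0, fatigue = 1).
#'
#' @param epochs Epoch tibble from [preprocess_pipeline()].
#' @param config An [entropy_config()].
#' @return A tibble: metadata columns then 22 feature columns.
#' @export
extract_feature_table <- function(epochs, config = entropy_config()) {
  feats <- purrr::pmap(
    list(epochs$FP1, epochs$FP2, epochs$fs),
    function(fp1, fp2, fs) extract_features(fp1, fp2, fs, config)
  )
  mat <- do.call(rbind, feats)
  dplyr::bind_cols(
    tibble::tibble(subject_id = epochs$subject_id, state = epochs$state,
                   label = state_to_label(epochs$state)),
    tibble::as_tibble(mat)
  )
}

#' Build the relative-band-power baseline table
#'
#' The FFT baseline feature set: per channel, the delta/theta/alpha/beta
#' fractions of 1-50 Hz power (8 features), with the same metadata columns
#' as [extract_feature_table()].
#'
#' @param epochs Epoch tibble from [preprocess_pipeline()].
#' @return A tibble with columns `RBP_<band>_<channel>`.
#' @export
extract_rbp_table <- function(epochs) {
  feats <- purrr::pmap(
    list(epochs$FP1, epochs$FP2, epochs$fs),
    function(fp1, fp2, fs) {
      v1 <- relative_band_power(fp1, fs)
      v2 <- relative_band_power(fp2, fs)
      setNames(c(v1, v2),
               c(paste0("RBP_", names(v1), "_FP1"),
                 paste0("RBP_", names(v2), "_FP2")))
    }
  )
  mat <- do.call(rbind, feats)
  dplyr::bind_cols(
    tibble::tibble(subject_id = epochs$subject_id, state = epochs$state,
                   label = state_to_label(epochs$state)),
    tibble::as_tibble(mat)
  )
}
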