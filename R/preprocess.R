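# Preprocessing: raw two-channel recordings -> quality-screened, normalised
# 1-s epochs. Stage order: notch -> band-pass -> wavelet denoise -> epoch ->
# variance gate -> per-epoch min-max normalisation. The variance gate runs
# on physical units (uV^2) before normalisation destroys them.

# Zero-phase filtering with odd-reflection padding at both ends, which
# suppresses the start-up transients of the forward-backward pass.
.filtfilt_padded <- function(filt, x, n_pad) {
  n <- length(x)
  n_pad <- min(n - 1, n_pad)
  if (n_pad < 1) return(as.numeric(signal::filtfilt(filt, x)))
  left <- 2 * x[1] - x[(n_pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - n_pad)]
  y <- as.numeric(signal::filtfilt(filt, c(left, x, right)))
  y[(n_pad + 1):(n_pad + n)]
}

#' Notch filter at the mains frequency
#'
#' Fourth-order IIR band-stop (Butterworth design, Q = 30) applied
#' forward-backward for zero phase.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz; must exceed `2 * notch_hz`.
#' @param notch_hz Centre frequency to remove (default 50 Hz mains).
#' @param q Quality factor; bandwidth is `notch_hz / q`.
#' @return Filtered signal, same length as `x`.
#' @export
notch_filter <- function(x, fs, notch_hz = 50, q = 30) {
  if (fs <= 2 * notch_hz) {
    abort("`fs` must exceed twice the notch frequency.")
  }
  bw <- notch_hz / q
  w <- c(notch_hz - bw / 2, notch_hz + bw / 2) / (fs / 2)
  filt <- signal::butter(2, w, type = "stop")
  .filtfilt_padded(filt, x, n_pad = round(3 * fs / bw))
}

#' Band-pass filter
#'
#' Butterworth band-pass applied forward-backward (zero phase), so epoch
#' timing is not shifted.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz, `0 < lo < hi <= fs/2`.
#' @param order Butterworth design order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, lo = 1, hi = 50, order = 4) {
  if (!(lo > 0 && lo < hi && hi <= fs / 2)) {
    abort("Invalid band: need 0 < lo < hi <= fs/2.")
  }
  # High-pass then low-pass cascade: numerically better conditioned than a
  # single band-pass prototype when lo/fs is very small. Removing the mean
  # first avoids a DC step transient at the edges.
  mu <- mean(x)
  hp <- signal::butter(order, lo / (fs / 2), type = "high")
  y <- .filtfilt_padded(hp, x - mu, n_pad = round(3 * fs / lo))
  if (hi < fs / 2) {
    lp <- signal::butter(order, hi / (fs / 2), type = "low")
    y <- .filtfilt_padded(lp, y, n_pad = round(3 * fs / hi))
  }
  y
}

#' Wavelet soft-threshold denoising
#'
#' Decomposes with [wavedec()] and soft-thresholds the detail coefficients
#' with the universal threshold `sigma * sqrt(2 log n)`, where `sigma` is
#' the robust noise estimate `MAD / 0.6745` of the finest detail level and
#' `n` the signal length, then reconstructs. Shrinks transient/spiky
#' artifacts such as muscle bursts while passing smooth oscillatory
#' content.
#'
#' @param x Numeric signal of length >= `2^levels`.
#' @param wavelet Wavelet basis (default `"db4"`).
#' @param levels Decomposition levels (default 4).
#' @param threshold Optional fixed threshold applied at every level;
#'   `NULL` (default) uses the universal threshold. `0` gives plain
#'   perfect reconstruction.
#' @return Denoised signal, same length as `x`.
#' @export
wavelet_denoise <- function(x, wavelet = "db4", levels = 4, threshold = NULL) {
  dec <- wavedec(x, wavelet = wavelet, levels = levels)
  if (is.null(threshold)) {
    sigma <- median(abs(dec$d[[1]])) / 0.6745
    threshold <- sigma * sqrt(2 * log(max(length(x), 2)))
  }
  soft <- function(d, t) sign(d) * pmax(abs(d) - t, 0)
  dec$d <- lapply(dec$d, soft, t = threshold)
  waverec(dec)
}

#' Epoch amplitude-variance quality gate
#'
#' An epoch passes only if the sample variance of every channel is below
#' `max_var` (in uV^2, so the gate must run before normalisation).
#'
#' @param epoch Numeric vector (one channel) or list/data frame of channels.
#' @param max_var Variance threshold in uV^2 (default 50).
#' @return `TRUE` if every channel's variance is strictly below `max_var`.
#' @export
quality_check <- function(epoch, max_var = 50) {
  chans <- if (is.numeric(epoch)) list(epoch) else as.list(epoch)
  if (length(chans) == 0L || any(lengths(chans) == 0L)) {
    abort("Empty epoch.")
  }
  all(vapply(chans, var, numeric(1)) < max_var)
}

#' Min-max normalisation to [0, 1]
#'
#' Order-preserving affine map of a signal onto `[0, 1]`. A constant signal
#' is degenerate: it is mapped to all 0.5 with a warning.
#'
#' @param x Numeric signal.
#' @return Normalised signal.
#' @export
minmax_normalize <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) {
    warn("Constant signal: min-max normalisation returns all 0.5.")
    return(rep(0.5, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Cut a recording into non-overlapping 1-second epochs
#'
#' Contiguous windows of exactly `fs` samples; a trailing partial second is
#' dropped. A 5-minute recording therefore yields 300 epochs.
#'
#' @param recording A one-row (or multi-row) recording tibble with columns
#'   `subject_id`, `state`, `fs` and list-columns `FP1`, `FP2`.
#' @return A tibble with one row per epoch: `subject_id`, `state`, `epoch`
#'   (1-based index), `fs`, list-columns `FP1`, `FP2`.
#' @export
epoch_recording <- function(recording) {
  purrr::pmap_dfr(recording, function(subject_id, state, fs, FP1, FP2, ...) {
    n_ep <- floor(length(FP1) / fs)
    if (n_ep < 1) {
      warn(sprintf("Recording (subject %s, %s) shorter than 1 s; no epochs.",
                   subject_id, state))
      return(tibble::tibble(subject_id = integer(), state = character(),
                            epoch = integer(), fs = numeric(),
                            FP1 = list(), FP2 = list()))
    }
    cut_one <- function(x) {
      lapply(seq_len(n_ep), function(i) x[((i - 1) * fs + 1):(i * fs)])
    }
    tibble::tibble(subject_id = subject_id, state = state,
                   epoch = seq_len(n_ep), fs = fs,
                   FP1 = cut_one(FP1), FP2 = cut_one(FP2))
  })
}

#' Full preprocessing pipeline
#'
#' Applies, per recording: notch filter, band-pass filter, wavelet
#' soft-threshold denoising, 1-s epoching, the variance quality gate
#' (rejecting an epoch if any channel's variance is >= `max_var` uV^2), and
#' per-epoch min-max normalisation of the surviving epochs. Normalising per
#' epoch keeps all scaling local to the classification unit, so no
#' information crosses the later train/test boundary.
#'
#' @param recordings Recording tibble (one or more rows) as produced by
#'   [generate_cohort()] or [read_cohort_csv()].
#' @param notch_hz Notch frequency (default 50 Hz); `NA` skips the stage.
#' @param band Band-pass edges in Hz (default `c(1, 50)`).
#' @param max_var Variance gate threshold in uV^2 (default 50).
#' @param wavelet,denoise_levels Wavelet denoising settings.
#' @param verbose Print the count of rejected epochs (default TRUE).
#' @return An epoch tibble as from [epoch_recording()], quality-screened and
#'   normalised to `[0, 1]`, with attribute `n_rejected`.
#' @export
preprocess_pipeline <- function(recordings, notch_hz = 50, band = c(1, 50),
                                max_var = 50, wavelet = "db4",
                                denoise_levels = 4, verbose = TRUE) {
  clean <- purrr::pmap_dfr(recordings, function(subject_id, state, fs, FP1, FP2, ...) {
    run <- function(x) {
      if (!is.na(notch_hz) && fs > 2 * notch_hz) x <- notch_filter(x, fs, notch_hz)
      x <- bandpass_filter(x, fs, band[1], band[2])
      wavelet_denoise(x, wavelet = wavelet, levels = denoise_levels)
    }
    tibble::tibble(subject_id = subject_id, state = state, fs = fs,
                   FP1 = list(run(FP1)), FP2 = list(run(FP2)))
  })
  epochs <- epoch_recording(clean)
  keep <- purrr::map2_lgl(epochs$FP1, epochs$FP2,
                          ~ quality_check(list(.x, .y), max_var = max_var))
  n_rejected <- sum(!keep)
  if (verbose) {
    message(sprintf("Rejected %d of %d epochs (variance gate at %g uV^2).",
                    n_rejected, length(keep), max_var))
  }
  epochs <- epochs[keep, , drop = FALSE]
  epochs$FP1 <- lapply(epochs$FP1, minmax_normalize)
  epochs$FP2 <- lapply(epochs$FP2, minmax_normalize)
  attr(epochs, "n_rejected") <- n_rejected
  epochs
}
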