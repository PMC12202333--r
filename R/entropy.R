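# The nine entropy estimators plus the FFT relative-band-power baseline.
# Template-matching measures (AE/SE/FE/K2) use the Chebyshev norm and are
# backed by C++ kernels; the remainder are vectorised R.

#' Entropy estimator configuration
#'
#' All estimator parameters in one place. The defaults are the operating
#' point the pipeline is designed around: embedding dimension 2 with
#' tolerance 0.7 standard deviations for approximate/sample/fuzzy entropy,
#' fuzzy membership exponent 2, Kolmogorov embedding dimension 6,
#' permutation order 5 with delay 4 at coarse-graining scale 2, spectral
#' band 1-50 Hz, symbol history 1 for transfer entropy, and a db3 wavelet
#' with 2 decomposition levels (hence 3 wavelet log-energy leaves) and
#' packet depth 2.
#'
#' @param m_aef Embedding dimension for approximate/sample/fuzzy entropy.
#' @param r_factor Tolerance as a multiple of the signal's SD.
#' @param fe_gradient Fuzzy membership exponent n.
#' @param m_ke Embedding dimension for Kolmogorov entropy.
#' @param pe_m,pe_tau,pe_scale Permutation entropy order, delay and
#'   coarse-graining scale.
#' @param spe_band Spectral-entropy band in Hz.
#' @param ste_k Symbol history length for symbolic transfer entropy.
#' @param wavelet Wavelet basis for the wavelet entropies.
#' @param wle_levels Wavelet log-energy decomposition levels (leaves =
#'   `wle_levels + 1`).
#' @param wpe_depth Wavelet-packet tree depth (leaves = `2^depth`).
#' @return An object of class `entropy_config`.
#' @export
entropy_config <- function(m_aef = 2L, r_factor = 0.7, fe_gradient = 2,
                           m_ke = 6L, pe_m = 5L, pe_tau = 4L, pe_scale = 2L,
                           spe_band = c(1, 50), ste_k = 1L, wavelet = "db3",
                           wle_levels = 2L, wpe_depth = 2L) {
  stopifnot(m_aef >= 1, r_factor > 0, m_ke >= 1, pe_m >= 2, pe_tau >= 1,
            pe_scale >= 1, ste_k >= 1, wle_levels >= 1, wpe_depth >= 1,
            length(spe_band) == 2, spe_band[1] > 0, spe_band[1] < spe_band[2])
  structure(
    list(m_aef = as.integer(m_aef), r_factor = r_factor,
         fe_gradient = fe_gradient, m_ke = as.integer(m_ke),
         pe_m = as.integer(pe_m), pe_tau = as.integer(pe_tau),
         pe_scale = as.integer(pe_scale), spe_band = spe_band,
         ste_k = as.integer(ste_k), wavelet = wavelet,
         wle_levels = as.integer(wle_levels),
         wpe_depth = as.integer(wpe_depth)),
    class = "entropy_config"
  )
}

#' Approximate entropy
#'
#' Pincus' regularity statistic `Phi(m) - Phi(m+1)` with self-matches
#' included, Chebyshev distances, and tolerance `r = r_factor * sd(x)`.
#'
#' @param x Numeric series.
#' @param m Embedding dimension.
#' @param r_factor Tolerance multiplier on `sd(x)`.
#' @return Approximate entropy in nats.
#' @export
approximate_entropy <- function(x, m = 2L, r_factor = 0.7) {
  if (length(x) <= m + 1) abort("Series too short for the embedding dimension.")
  s <- sd(x)
  if (s == 0) return(0)
  cpp_apen(as.numeric(x), as.integer(m), r_factor * s)
}

#' Sample entropy
#'
#' `-log(A/B)` where B (A) counts template pairs within tolerance at length
#' `m` (`m + 1`); self-matches excluded. When no length-(m+1) pair matches
#' (`A = 0`), the guarded upper bound `log(B + 1e-10)` is returned with
#' attribute `flagged = TRUE`.
#'
#' @inheritParams approximate_entropy
#' @return Sample entropy in nats.
#' @export
sample_entropy <- function(x, m = 2L, r_factor = 0.7) {
  if (length(x) <= m + 1) abort("Series too short for the embedding dimension.")
  s <- sd(x)
  if (s == 0) return(0)
  ab <- cpp_sampen_counts(as.numeric(x), as.integer(m), r_factor * s)
  if (ab[2] == 0) abort("No template matches at length m; series too short or irregular.")
  if (ab[1] == 0) {
    return(structure(log(ab[2] + 1e-10), flagged = TRUE))
  }
  -log(ab[1] / ab[2])
}

#' Fuzzy entropy
#'
#' Sample-entropy variant with mean-centred templates and smooth membership
#' `exp(-(d/r)^n)` in place of the hard tolerance, which makes the estimate
#' continuous in the data.
#'
#' @inheritParams approximate_entropy
#' @param n Membership exponent (gradient of the fuzzy boundary).
#' @return Fuzzy entropy in nats.
#' @export
fuzzy_entropy <- function(x, m = 2L, r_factor = 0.7, n = 2) {
  if (length(x) <= m + 1) abort("Series too short for the embedding dimension.")
  s <- sd(x)
  if (s == 0) return(0)
  cpp_fuzzyen(as.numeric(x), as.integer(m), r_factor * s, n)
}

#' Distance scale for Kolmogorov entropy
#'
#' The mean absolute deviation `sum(|s_i - mean|) / N` used as the
#' neighbourhood radius of the second-order Kolmogorov entropy estimator.
#'
#' @param x Numeric series.
#' @return The radius r0.
#' @export
ke_radius <- function(x) {
  mean(abs(x - mean(x)))
}

#' Second-order Kolmogorov entropy (maximum-likelihood estimate)
#'
#' Embeds the series at dimension `m` (delay 1) and, for every pair of
#' embedded points initially within the radius [ke_radius()], records the
#' number of consecutive steps b the pair stays within that radius. The
#' maximum-likelihood entropy rate per sample step is
#' `K2 = -log(1 - 1/mean(b))`, which is near zero for periodic signals and
#' positive for chaotic or stochastic ones.
#'
#' @param x Numeric series.
#' @param m Embedding dimension (default 6).
#' @return K2 in nats per sample step.
#' @export
kolmogorov_entropy <- function(x, m = 6L) {
  if (length(x) <= m + 1) abort("Series too short for the embedding dimension.")
  r0 <- ke_radius(x)
  res <- cpp_k2_escape(as.numeric(x), as.integer(m), r0)
  if (res[1] == 0) {
    abort("Kolmogorov entropy estimator failure: no embedded pairs within r0.")
  }
  bbar <- res[2]
  if (bbar <= 1) {
    abort("Kolmogorov entropy estimator failure: every pair escapes immediately.")
  }
  -log(1 - 1 / bbar)
}

# Lehmer code of each row of an embedding matrix -> ordinal pattern ids.
.ordinal_codes <- function(E) {
  m <- ncol(E)
  code <- integer(nrow(E))
  fact <- factorial((m - 1):0)
  for (k in seq_len(m - 1)) {
    smaller <- rep(0L, nrow(E))
    for (j in (k + 1):m) {
      smaller <- smaller + (E[, j] < E[, k])
    }
    code <- code + smaller * fact[k]
  }
  code
}

#' Permutation entropy (coarse-grained)
#'
#' Coarse-grains the series by non-overlapping window means of width
#' `scale`, counts ordinal patterns of order `m` at delay `tau`, and
#' returns the Shannon entropy of the pattern distribution normalised by
#' `log(m!)` so the value lies in `[0, 1]`. Ties are broken by position
#' (first occurrence ranks lower).
#'
#' @param x Numeric series.
#' @param m Pattern order (embedding dimension).
#' @param tau Delay in (coarse-grained) samples.
#' @param scale Coarse-graining scale (1 = none).
#' @return Normalised permutation entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(x, m = 5L, tau = 4L, scale = 2L) {
  if (scale > 1) {
    n_win <- floor(length(x) / scale)
    if (n_win < 1) abort("Series too short for the coarse-graining scale.")
    x <- colMeans(matrix(x[seq_len(n_win * scale)], nrow = scale))
  }
  n_pat <- length(x) - (m - 1) * tau
  if (n_pat < 1) {
    abort(sprintf("Series too short: need at least %d coarse-grained samples.",
                  (m - 1) * tau + 1))
  }
  E <- sapply(seq_len(m), function(k) x[seq_len(n_pat) + (k - 1) * tau])
  if (n_pat == 1) E <- matrix(E, nrow = 1)
  counts <- table(.ordinal_codes(E))
  p <- as.numeric(counts) / n_pat
  -sum(p * log(p)) / log(factorial(m))
}

# One-sided periodogram (DC dropped): power per frequency bin.
.periodogram <- function(x, fs) {
  n <- length(x)
  half <- floor(n / 2)
  p <- (Mod(fft(x))^2 / n)[2:(half + 1)]
  tibble::tibble(freq = (1:half) * fs / n, power = p)
}

#' Spectral entropy
#'
#' Shannon entropy of the normalised periodogram restricted to `band`,
#' divided by `log` of the number of bins, so a flat spectrum scores 1 and
#' a single line scores near 0.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param band Frequency band in Hz (default 1-50).
#' @return Spectral entropy in `[0, 1]`.
#' @export
spectral_entropy <- function(x, fs, band = c(1, 50)) {
  pg <- .periodogram(x, fs)
  pg <- pg[pg$freq >= band[1] & pg$freq <= band[2], ]
  tot <- sum(pg$power)
  if (nrow(pg) < 2 || tot <= 0) abort("No spectral power in the requested band.")
  p <- pg$power / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(nrow(pg))
}

# First-difference binarisation: increments -> 1, everything else -> 0.
binarize_diff <- function(x) {
  as.integer(diff(x) > 0)
}

#' Symbolic transfer entropy
#'
#' Both series are symbolised by the first-difference rule (an amplitude
#' increment is "1", anything else "0") and the transfer entropy
#' `TE(source -> target) = I(target_future; source_past | target_past)` is
#' estimated from plug-in joint frequencies with history length `k`.
#' Non-negative, in bits.
#'
#' @param source,target Numeric series of equal length.
#' @param k Symbol history length (default 1).
#' @return Transfer entropy in bits.
#' @export
symbolic_transfer_entropy <- function(source, target, k = 1L) {
  if (length(source) != length(target)) abort("Sequences must have equal length.")
  xs <- binarize_diff(source)
  ys <- binarize_diff(target)
  n <- length(ys)
  if (n < k + 1) abort("Sequences too short for the history length.")
  idx <- seq_len(n - k)
  hist_code <- function(s) {
    code <- 0
    for (j in seq_len(k)) code <- code * 2 + s[idx + j - 1]
    code
  }
  yf <- factor(ys[idx + k], levels = 0:1)          # target future symbol
  yh <- factor(hist_code(ys), levels = 0:(2^k - 1)) # target history
  xh <- factor(hist_code(xs), levels = 0:(2^k - 1)) # source history
  joint <- table(yf, yh, xh)
  pj <- joint / sum(joint)
  # conditional tables
  p_yh_xh <- apply(pj, c(2, 3), sum)
  p_yh <- apply(pj, 2, sum)
  p_yf_yh <- apply(pj, c(1, 2), sum)
  te <- 0
  dn <- dimnames(pj)
  for (a in seq_along(dn[[1]])) for (b in seq_along(dn[[2]])) for (cc in seq_along(dn[[3]])) {
    pabc <- pj[a, b, cc]
    if (pabc > 0) {
      cond_full <- pabc / p_yh_xh[b, cc]
      cond_marg <- p_yf_yh[a, b] / p_yh[b]
      te <- te + pabc * log2(cond_full / cond_marg)
    }
  }
  max(te, 0)
}

#' Wavelet log-energy per leaf band
#'
#' Discrete wavelet decomposition to `levels`; the leaves are the deepest
#' approximation plus every detail band (`levels + 1` leaves, ordered
#' approximation first, then details deepest to shallowest). Each leaf
#' contributes `sum_j log(c_j^2)`; coefficients exactly zero are floored at
#' 1e-12 inside the log.
#'
#' @param x Numeric series.
#' @param wavelet Wavelet basis (default `"db3"`).
#' @param levels Decomposition levels (default 2).
#' @return Named numeric vector `WLE_1 .. WLE_(levels+1)`.
#' @export
wavelet_log_energy <- function(x, wavelet = "db3", levels = 2L) {
  dec <- wavedec(x, wavelet = wavelet, levels = levels)
  leaves <- c(list(dec$a), rev(dec$d)) # approximation, then deepest detail first
  vals <- vapply(leaves, function(cf) sum(log(pmax(cf^2, 1e-12))), numeric(1))
  setNames(vals, paste0("WLE_", seq_along(vals)))
}

#' Wavelet-packet energies per leaf
#'
#' Full wavelet-packet tree to `depth`; returns the `2^depth` leaf energies
#' (sums of squared coefficients) in natural filter-bank order.
#'
#' @inheritParams wavelet_log_energy
#' @param depth Packet tree depth.
#' @return Numeric vector of `2^depth` energies.
#' @export
wavelet_packet_energies <- function(x, wavelet = "db3", depth = 2L) {
  vapply(wavelet_packet_leaves(x, wavelet = wavelet, depth = depth),
         function(cf) sum(cf^2), numeric(1))
}

#' Wavelet-packet energy entropy
#'
#' Shannon entropy (base 2) of the fraction of total energy in each leaf of
#' the depth-`depth` wavelet-packet tree: `-sum p_i log2 p_i`, in
#' `[0, depth]` bits.
#'
#' @inheritParams wavelet_packet_energies
#' @return Entropy in bits.
#' @export
wavelet_packet_energy_entropy <- function(x, wavelet = "db3", depth = 2L) {
  e <- wavelet_packet_energies(x, wavelet = wavelet, depth = depth)
  tot <- sum(e)
  if (tot <= 0) abort("Zero total energy in the wavelet-packet tree.")
  p <- e / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Relative band power (FFT baseline)
#'
#' Fraction of 1-50 Hz periodogram power in the delta (1-4), theta (4-8),
#' alpha (8-13) and beta (13-30 Hz) bands. The fractions need not sum to 1
#' (the 30-50 Hz residual is excluded from the numerators).
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @return Named vector `c(delta, theta, alpha, beta)` of fractions.
#' @export
relative_band_power <- function(x, fs) {
  pg <- .periodogram(x, fs)
  total_band <- c(1, 50)
  pg <- pg[pg$freq >= total_band[1] & pg$freq <= total_band[2], ]
  tot <- sum(pg$power)
  if (tot <= 0) abort("No spectral power in 1-50 Hz.")
  bands <- list(delta = c(1, 4), theta = c(4, 8),
                alpha = c(8, 13), beta = c(13, 30))
  vapply(bands, function(b) {
    sum(pg$power[pg$freq >= b[1] & pg$freq < b[2]]) / tot
  }, numeric(1))
}
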