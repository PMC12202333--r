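# Orthogonal Daubechies wavelet machinery used by the denoiser and the
# wavelet-based entropy features. The transform is the standard pyramid
# algorithm with circular (periodised) convolution; signals whose length is
# not a multiple of 2^levels are zero-padded to the next dyadic multiple and
# truncated back after reconstruction, which keeps the analysis/synthesis
# pair exactly invertible at every length.

# Daubechies scaling (low-pass) filters, sum = sqrt(2).
.db_filters <- list(
  db2 = c(0.48296291314469025, 0.83651630373746899,
          0.22414386804185735, -0.12940952255092145),
  db3 = c(0.33267055295095688, 0.80689150931333875, 0.45987750211933132,
          -0.13501102001039084, -0.08544127388224149, 0.03522629188210562),
  db4 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
          -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
          0.03288301166698295, -0.01059740178499728)
)

wavelet_filter <- function(wavelet) {
  h <- .db_filters[[wavelet]]
  if (is.null(h)) {
    abort(sprintf("Unknown wavelet '%s'; available: %s.",
                  wavelet, paste(names(.db_filters), collapse = ", ")))
  }
  g <- rev(h) * c(1, -1) # quadrature mirror: g[n] = (-1)^n h[L-1-n]
  list(lo = h, hi = g)
}

# One analysis step on an even-length vector: circular convolution with the
# low/high-pass filters, downsampled by 2.
dwt_step <- function(x, filt) {
  n <- length(x)
  L <- length(filt$lo)
  idx <- outer(seq(0L, n - 2L, by = 2L), seq_len(L) - 1L, `+`) %% n + 1L
  xm <- matrix(x[idx], nrow = n %/% 2L, ncol = L)
  list(a = drop(xm %*% filt$lo), d = drop(xm %*% filt$hi))
}

# Inverse of dwt_step (transpose of the orthonormal analysis operator).
idwt_step <- function(a, d, filt) {
  n <- 2L * length(a)
  L <- length(filt$lo)
  x <- numeric(n)
  for (k in seq_along(a)) {
    pos <- (2L * (k - 1L) + seq_len(L) - 1L) %% n + 1L
    x[pos] <- x[pos] + a[k] * filt$lo + d[k] * filt$hi
  }
  x
}

pad_dyadic <- function(x, levels) {
  mult <- 2L^levels
  n <- length(x)
  m <- as.integer(ceiling(n / mult) * mult)
  if (m > n) x <- c(x, numeric(m - n))
  x
}

#' Multilevel discrete wavelet decomposition
#'
#' Decomposes a signal into `levels` detail bands plus a final approximation
#' using an orthonormal Daubechies filter bank with periodised convolution.
#' Inputs whose length is not a multiple of `2^levels` are zero-padded to the
#' next dyadic multiple (recorded in the result so [waverec()] can truncate).
#'
#' @param x Numeric vector.
#' @param wavelet Wavelet name (`"db2"`, `"db3"`, `"db4"`).
#' @param levels Number of decomposition levels (>= 1).
#' @return A list with `a` (deepest approximation), `d` (list of detail
#'   coefficient vectors, element 1 = finest level), `wavelet`, `levels`,
#'   and `n` (original length).
#' @export
wavedec <- function(x, wavelet = "db4", levels = 4L) {
  levels <- as.integer(levels)
  if (levels < 1L) abort("`levels` must be >= 1.")
  if (length(x) < 2L^levels) {
    abort(sprintf("Signal too short: need at least %d samples for %d levels.",
                  2L^levels, levels))
  }
  filt <- wavelet_filter(wavelet)
  n <- length(x)
  a <- pad_dyadic(x, levels)
  d <- vector("list", levels)
  for (j in seq_len(levels)) {
    s <- dwt_step(a, filt)
    a <- s$a
    d[[j]] <- s$d
  }
  list(a = a, d = d, wavelet = wavelet, levels = levels, n = n)
}

#' Reconstruct a signal from a wavelet decomposition
#'
#' Exact inverse of [wavedec()] (perfect reconstruction up to floating-point
#' round-off).
#'
#' @param dec A decomposition as returned by [wavedec()].
#' @return Numeric vector of the original length.
#' @export
waverec <- function(dec) {
  filt <- wavelet_filter(dec$wavelet)
  a <- dec$a
  for (j in rev(seq_len(dec$levels))) {
    a <- idwt_step(a, dec$d[[j]], filt)
  }
  a[seq_len(dec$n)]
}

# Full wavelet-packet analysis to `depth`: both filters are applied
# recursively to every node, yielding 2^depth leaf coefficient vectors in
# natural (filter-bank) order.
wavelet_packet_leaves <- function(x, wavelet = "db3", depth = 2L) {
  depth <- as.integer(depth)
  if (depth < 1L) abort("`depth` must be >= 1.")
  if (length(x) < 2L^depth) abort("Signal too short for the requested packet depth.")
  filt <- wavelet_filter(wavelet)
  nodes <- list(pad_dyadic(x, depth))
  for (j in seq_len(depth)) {
    nodes <- unlist(lapply(nodes, function(v) {
      s <- dwt_step(v, filt)
      list(s$a, s$d)
    }), recursive = FALSE)
  }
  nodes
}

# Rebuild a signal from 2^depth leaf coefficient vectors (inverse packet
# transform); used in tests to construct signals with prescribed leaf
# energies.
wavelet_packet_reconstruct <- function(leaves, wavelet = "db3") {
  filt <- wavelet_filter(wavelet)
  while (length(leaves) > 1L) {
    leaves <- lapply(seq_len(length(leaves) / 2L), function(i) {
      idwt_step(leaves[[2L * i - 1L]], leaves[[2L * i]], filt)
    })
  }
  leaves[[1L]]
}
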