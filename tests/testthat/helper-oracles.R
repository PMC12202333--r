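# Naive, independent reference implementations used to validate the package
# estimators. These favour clarity over speed: explicit double loops and
# literal textbook formulas.

chebyshev <- function(a, b) max(abs(a - b))

oracle_apen <- function(x, m, r_factor) {
  r <- r_factor * sd(x)
  phi <- function(mm) {
    M <- length(x) - mm + 1
    templ <- lapply(seq_len(M), function(i) x[i:(i + mm - 1)])
    mean(sapply(seq_len(M), function(i) {
      cnt <- sum(sapply(seq_len(M), function(j) chebyshev(templ[[i]], templ[[j]]) <= r))
      log(cnt / M)
    }))
  }
  phi(m) - phi(m + 1)
}

oracle_sampen <- function(x, m, r_factor) {
  r <- r_factor * sd(x)
  M <- length(x) - m
  A <- 0; B <- 0
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      if (chebyshev(x[i:(i + m - 1)], x[j:(j + m - 1)]) <= r) {
        B <- B + 1
        if (chebyshev(x[i:(i + m)], x[j:(j + m)]) <= r) A <- A + 1
      }
    }
  }
  -log(A / B)
}

oracle_fuzzyen <- function(x, m, r_factor, n) {
  r <- r_factor * sd(x)
  phi <- function(mm) {
    M <- length(x) - mm
    templ <- lapply(seq_len(M), function(i) {
      v <- x[i:(i + mm - 1)]
      v - mean(v)
    })
    tot <- 0; cnt <- 0
    for (i in seq_len(M - 1)) {
      for (j in (i + 1):M) {
        d <- chebyshev(templ[[i]], templ[[j]])
        tot <- tot + exp(-(d / r)^n)
        cnt <- cnt + 1
      }
    }
    tot / cnt
  }
  -log(phi(m + 1) / phi(m))
}

oracle_perm_entropy <- function(x, m, tau, scale) {
  if (scale > 1) {
    nw <- floor(length(x) / scale)
    x <- sapply(seq_len(nw), function(i) mean(x[((i - 1) * scale + 1):(i * scale)]))
  }
  np <- length(x) - (m - 1) * tau
  pats <- sapply(seq_len(np), function(i) {
    paste(order(x[i + (0:(m - 1)) * tau]), collapse = "-")
  })
  p <- table(pats) / np
  -sum(p * log(p)) / log(factorial(m))
}

# Plug-in symbolic transfer entropy by explicit enumeration of all
# (future, target-history, source-history) symbol combinations, k = 1.
oracle_ste_k1 <- function(source, target) {
  xs <- as.integer(diff(source) > 0)
  ys <- as.integer(diff(target) > 0)
  n <- length(ys)
  yf <- ys[2:n]; yh <- ys[1:(n - 1)]; xh <- xs[1:(n - 1)]
  N <- length(yf)
  te <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    p_abc <- sum(yf == a & yh == b & xh == cc) / N
    if (p_abc > 0) {
      p_bc <- sum(yh == b & xh == cc) / N
      p_ab <- sum(yf == a & yh == b) / N
      p_b <- sum(yh == b) / N
      te <- te + p_abc * log2((p_abc / p_bc) / (p_ab / p_b))
    }
  }
  te
}

# AUC as the all-pairs Mann-Whitney probability P(s+ > s-) + 0.5 P(tie).
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Orthonormal periodised DWT analysis step as an explicit matrix product:
# an independent path to the subband coefficients.
oracle_dwt_matrix <- function(x, h) {
  n <- length(x)
  g <- rev(h) * c(1, -1)
  rows <- n / 2
  A <- matrix(0, rows, n); D <- matrix(0, rows, n)
  for (k in seq_len(rows)) {
    pos <- (2 * (k - 1) + seq_along(h) - 1) %% n + 1
    for (i in seq_along(h)) {
      A[k, pos[i]] <- A[k, pos[i]] + h[i]
      D[k, pos[i]] <- D[k, pos[i]] + g[i]
    }
  }
  list(a = as.numeric(A %*% x), d = as.numeric(D %*% x))
}
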