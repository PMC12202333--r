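# The nine entropy estimators and the band-power baseline: brute-force
# oracle equivalence, analytic limit behaviour, and the feature assembly.

test_that("approximate/sample/fuzzy entropy match naive double-loop oracles", {
  set.seed(11)
  x <- runif(200)
  expect_equal(approximate_entropy(x, 2, 0.7), oracle_apen(x, 2, 0.7),
               tolerance = 1e-10)
  expect_equal(sample_entropy(x, 2, 0.7), oracle_sampen(x, 2, 0.7),
               tolerance = 1e-10)
  expect_equal(fuzzy_entropy(x, 2, 0.7, 2), oracle_fuzzyen(x, 2, 0.7, 2),
               tolerance = 1e-10)
  # a second parameterisation
  y <- rnorm(150)
  expect_equal(approximate_entropy(y, 3, 0.5), oracle_apen(y, 3, 0.5),
               tolerance = 1e-10)
  expect_equal(sample_entropy(y, 3, 0.5), oracle_sampen(y, 3, 0.5),
               tolerance = 1e-10)
  expect_equal(fuzzy_entropy(y, 2, 0.5, 3), oracle_fuzzyen(y, 2, 0.5, 3),
               tolerance = 1e-10)
})

test_that("regularity statistics vanish on constant input and rank noise above sine", {
  const <- rep(3.2, 100)
  expect_equal(approximate_entropy(const), 0)
  expect_equal(sample_entropy(const), 0)
  expect_equal(fuzzy_entropy(const), 0)
  set.seed(12)
  noise <- runif(200)
  sine <- sin(2 * pi * 6 * seq_len(200) / 200)
  expect_gt(approximate_entropy(noise), approximate_entropy(sine))
  expect_gt(sample_entropy(noise), sample_entropy(sine))
  expect_gt(fuzzy_entropy(noise), fuzzy_entropy(sine))
})

test_that("fuzzy entropy is continuous under tiny perturbations", {
  set.seed(13)
  x <- runif(150)
  fe <- fuzzy_entropy(x)
  fe_eps <- fuzzy_entropy(x + 1e-6 * rnorm(150))
  expect_lt(abs(fe - fe_eps), 1e-3)
})

test_that("Kolmogorov entropy: radius formula, periodic limit, and noise ordering", {
  expect_equal(ke_radius(c(1, 2, 3, 4)), 1.0) # mean |x - 2.5|
  sine <- sin(2 * pi * 6 * seq_len(1000) / 1000)
  k2_sine <- kolmogorov_entropy(sine, 6)
  expect_lt(k2_sine, 0.05) # near zero for a non-chaotic signal
  expect_gte(k2_sine, 0)
  set.seed(14)
  expect_gt(kolmogorov_entropy(runif(500), 6), k2_sine)
})

test_that("permutation entropy: monotone limit, noise limit, histogram oracle", {
  expect_equal(permutation_entropy(seq_len(100)), 0) # single ordinal pattern
  set.seed(15)
  expect_gt(permutation_entropy(runif(10000)), 0.97) # approaches 1 for iid noise
  x <- runif(500)
  expect_equal(permutation_entropy(x, 5, 4, 2), oracle_perm_entropy(x, 5, 4, 2))
  expect_equal(permutation_entropy(x, 4, 2, 1), oracle_perm_entropy(x, 4, 2, 1))
  expect_error(permutation_entropy(runif(10), 5, 4, 2), "short")
})

test_that("spectral entropy: concentration and flatness limits, bounded in [0, 1]", {
  sine <- sin(2 * pi * 6 * seq_len(200) / 200)
  expect_lt(spectral_entropy(sine, 200), 0.2)
  set.seed(16)
  vals <- replicate(5, spectral_entropy(rnorm(1000), 1000))
  expect_gt(mean(vals), 0.85) # flatness limit (~0.89 expected at 50 bins)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(spectral_entropy(rep(0, 100), 100), "power")
})

test_that("symbolic transfer entropy: directionality, independence limit, exact oracle", {
  set.seed(17)
  a <- rnorm(3000)
  b <- c(0, a[-3000]) + 0.05 * rnorm(3000) # b is a lagged copy of a
  expect_gt(symbolic_transfer_entropy(a, b),
            10 * symbolic_transfer_entropy(b, a))
  u <- rnorm(10000); v <- rnorm(10000)
  expect_lt(symbolic_transfer_entropy(u, v), 0.01)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(symbolic_transfer_entropy(x, y), oracle_ste_k1(x, y),
               tolerance = 1e-12)
  expect_gte(symbolic_transfer_entropy(x, y), 0)
  expect_error(symbolic_transfer_entropy(rnorm(5), rnorm(6)), "equal length")
})

test_that("wavelet log-energy: leaf count, scaling identity, independent coefficient oracle", {
  set.seed(18)
  x <- rnorm(200)
  wle <- wavelet_log_energy(x, "db3", 2)
  expect_named(wle, c("WLE_1", "WLE_2", "WLE_3"))
  # scaling by 10 adds (#coeffs in leaf) * log(100) to each leaf
  wle10 <- wavelet_log_energy(10 * x, "db3", 2)
  dec <- wavedec(x, "db3", 2)
  n_leaf <- c(length(dec$a), length(dec$d[[2]]), length(dec$d[[1]]))
  expect_equal(wle10 - wle, setNames(n_leaf * log(100), names(wle)),
               tolerance = 1e-9)
  # leaves recomputed through the independent matrix-operator transform
  filt <- eegfatigue:::wavelet_filter("db3")
  s1 <- oracle_dwt_matrix(x, filt$lo)
  s2 <- oracle_dwt_matrix(s1$a, filt$lo)
  ref <- c(sum(log(s2$a^2)), sum(log(s2$d^2)), sum(log(s1$d^2)))
  expect_equal(unname(wle), ref, tolerance = 1e-9)
})

test_that("wavelet-packet energy entropy: concentration, uniform 2-bit limit, energy oracle", {
  # equal energy in all four depth-2 leaves -> exactly 2 bits
  set.seed(19)
  leaves <- lapply(1:4, function(i) {
    v <- rnorm(32)
    v / sqrt(sum(v^2)) # unit energy each
  })
  x_uniform <- eegfatigue:::wavelet_packet_reconstruct(leaves, "db3")
  expect_equal(wavelet_packet_energy_entropy(x_uniform, "db3", 2), 2,
               tolerance = 1e-9)
  # all energy in one leaf -> zero bits
  one <- lapply(1:4, function(i) if (i == 1) rnorm(32) else numeric(32))
  x_conc <- eegfatigue:::wavelet_packet_reconstruct(one, "db3")
  expect_lt(wavelet_packet_energy_entropy(x_conc, "db3", 2), 1e-9)
  # entropy agrees with independently computed leaf energies
  y <- rnorm(128)
  e <- vapply(eegfatigue:::wavelet_packet_leaves(y, "db3", 2),
              function(cf) sum(cf^2), numeric(1))
  p <- e / sum(e)
  expect_equal(wavelet_packet_energy_entropy(y, "db3", 2), -sum(p * log2(p)),
               tolerance = 1e-9)
})

test_that("relative band power concentrates on the stimulus band and stays in [0, 1]", {
  sine <- sin(2 * pi * 6 * seq_len(400) / 200)
  rbp <- relative_band_power(sine, 200)
  expect_named(rbp, c("delta", "theta", "alpha", "beta"))
  expect_gte(rbp[["theta"]], 0.9)
  set.seed(20)
  rbp2 <- relative_band_power(rnorm(200), 200)
  expect_true(all(rbp2 >= 0 & rbp2 <= 1))
  expect_lte(sum(rbp2), 1)
})

test_that("feature extraction emits 22 stably named finite features per epoch", {
  ep <- small_epochs()
  fv <- extract_features(ep$FP1[[1]], ep$FP2[[1]], ep$fs[1])
  expect_length(fv, 22)
  expect_named(fv, entropy_feature_names())
  expect_true(all(is.finite(fv)))
  # swapping channels swaps suffixes, not values
  fv_sw <- extract_features(ep$FP2[[1]], ep$FP1[[1]], ep$fs[1])
  expect_equal(unname(fv_sw["AE_FP1"]), unname(fv["AE_FP2"]))
  expect_equal(unname(fv_sw["STE_FP2"]), unname(fv["STE_FP1"]))
})

test_that("the feature table is rectangular with finite values and binary labels", {
  ft <- small_features()
  expect_equal(nrow(ft), 4 * 2 * 20)
  expect_equal(ncol(ft), 22 + 3)
  expect_true(all(is.finite(as.matrix(ft[entropy_feature_names()]))))
  expect_setequal(unique(ft$label), c(0L, 1L))
  expect_equal(ft$label, as.integer(ft$state == "fatigue"))
})
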