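# Synthetic two-state forehead-EEG cohort generator.
#
# The signal model is the minimal construction that moves every feature
# family the downstream pipeline uses: four band-limited oscillators
# (randomised carrier frequency and phase, slow sinusoidal amplitude
# modulation) summed with 1/f background noise, a per-subject multiplicative
# baseline factor shared by both states, and a lagged cross-channel coupling
# from FP1 into FP2. Fatigue recordings get enriched theta/delta amplitudes,
# reduced broadband noise (higher regularity, hence lower sample/fuzzy
# entropy) and a stronger FP1->FP2 coupling gain.

.band_ranges <- list(delta = c(1, 4), theta = c(4, 8),
                     alpha = c(8, 13), beta = c(13, 30))

.base_band_amps <- c(delta = 1.5, theta = 1.2, alpha = 1.5, beta = 0.8)
.base_noise_amp <- 1.2
.base_coupling <- list(lag = 2L, gain = 0.3)

# Fatigue-state multipliers per effect-size preset. "none" is the null
# configuration (both states statistically identical) used to check that the
# pipeline cannot fabricate discrimination.
.effect_presets <- list(
  weak = list(band = c(delta = 1.15, theta = 1.3, alpha = 0.95, beta = 0.9),
              noise = 0.8, gain = 1.5),
  moderate = list(band = c(delta = 1.3, theta = 1.8, alpha = 0.9, beta = 0.8),
                  noise = 0.6, gain = 2.0),
  strong = list(band = c(delta = 1.5, theta = 2.6, alpha = 0.8, beta = 0.7),
                noise = 0.4, gain = 3.0),
  none = list(band = c(delta = 1, theta = 1, alpha = 1, beta = 1),
              noise = 1, gain = 1.0)
)

#' Parameters of the synthetic EEG signal model
#'
#' Bundles every knob of the two-state cohort generator: sampling rate,
#' recording duration, per-state oscillator amplitudes for the four
#' canonical EEG bands, per-state 1/f noise amplitude, per-state FP1->FP2
#' coupling (lag in samples, gain), the spread of the per-subject baseline
#' factor, and the master seed.
#'
#' @param fs Sampling rate in Hz (default 200; must exceed twice the highest
#'   oscillator frequency, 30 Hz).
#' @param duration_s Seconds per recording (default 300, i.e. the 5-minute
#'   recordings the pipeline is designed around).
#' @param effect_size One of `"weak"`, `"moderate"`, `"strong"`, `"none"`;
#'   selects the fatigue-state multipliers applied to `band_amps`,
#'   `noise_amp` and the coupling gain. `"none"` makes both states
#'   identical (null model).
#' @param band_amps Named list with elements `normal` and `fatigue`, each a
#'   named vector of oscillator amplitudes in microvolts for delta
#'   (1-4 Hz), theta (4-8 Hz), alpha (8-13 Hz) and beta (13-30 Hz).
#'   Defaults are derived from `effect_size`.
#' @param noise_amp Named list (`normal`, `fatigue`) of 1/f background noise
#'   amplitudes (standard deviation, microvolts).
#' @param coupling Named list (`normal`, `fatigue`) of lists with `lag`
#'   (samples) and `gain` in `[0, 1)` for the FP1->FP2 shared component.
#' @param subject_sd Standard deviation (log scale) of the per-subject
#'   multiplicative baseline factor.
#' @param seed Master seed; all per-(subject, state) streams derive from it.
#' @return An object of class `signal_model_params`.
#' @export
signal_model_params <- function(fs = 200, duration_s = 300,
                                effect_size = c("moderate", "weak", "strong", "none"),
                                band_amps = NULL, noise_amp = NULL,
                                coupling = NULL, subject_sd = 0.15,
                                seed = 42L) {
  effect_size <- match.arg(effect_size)
  assert_scalar_number(fs, "fs", lower = 2 * max(.band_ranges$beta) + 1e-9)
  assert_scalar_number(duration_s, "duration_s", lower = 1e-9)
  assert_scalar_number(subject_sd, "subject_sd", lower = 0)
  preset <- .effect_presets[[effect_size]]
  if (is.null(band_amps)) {
    band_amps <- list(normal = .base_band_amps,
                      fatigue = .base_band_amps * preset$band)
  }
  if (is.null(noise_amp)) {
    noise_amp <- list(normal = .base_noise_amp,
                      fatigue = .base_noise_amp * preset$noise)
  }
  if (is.null(coupling)) {
    coupling <- list(
      normal = .base_coupling,
      fatigue = list(lag = .base_coupling$lag,
                     gain = min(.base_coupling$gain * preset$gain, 0.95))
    )
  }
  for (st in c("normal", "fatigue")) {
    if (any(band_amps[[st]] < 0) || noise_amp[[st]] < 0) {
      abort("All amplitudes must be non-negative.")
    }
  }
  share <- function(a) sum(a[c("delta", "theta")]) / sum(a)
  identical_states <- identical(band_amps$normal, band_amps$fatigue) &&
    identical(noise_amp$normal, noise_amp$fatigue)
  if (!identical_states && share(band_amps$fatigue) <= share(band_amps$normal)) {
    abort("Fatigue band amplitudes must give a strictly higher theta+delta share than normal.")
  }
  structure(
    list(fs = fs, duration_s = duration_s, effect_size = effect_size,
         band_amps = band_amps, noise_amp = noise_amp, coupling = coupling,
         subject_sd = subject_sd, seed = as.integer(seed)),
    class = "signal_model_params"
  )
}

# 1/f-amplitude background noise, unit standard deviation.
pink_noise <- function(n) {
  w <- rnorm(n)
  f <- fft(w)
  freq <- c(1, seq_len(n - 1))
  freq <- pmin(freq, n - freq + 1) # symmetric spectral weight
  f <- f / sqrt(freq)
  x <- Re(fft(f, inverse = TRUE)) / n
  x / sd(x)
}

# Random structural parameters of one channel's oscillators: each band is
# a superposition of `n_carriers` amplitude-modulated sinusoids spread over
# the band, which stabilises the band's relative power across recordings.
.draw_osc_structure <- function(n_carriers = 3L) {
  lapply(.band_ranges, function(rng) {
    list(f0 = runif(n_carriers, rng[1], rng[2]),
         ph = runif(n_carriers, 0, 2 * pi),
         fm = runif(n_carriers, 0.05, 0.3),
         phm = runif(n_carriers, 0, 2 * pi))
  })
}

# Render the oscillatory signal from a structure and per-band amplitudes.
.oscillators <- function(t, structure, amps) {
  x <- numeric(length(t))
  for (band in names(.band_ranges)) {
    s <- structure[[band]]
    nc <- length(s$f0)
    for (i in seq_len(nc)) {
      env <- 1 + 0.5 * sin(2 * pi * s$fm[i] * t + s$phm[i])
      x <- x + amps[[band]] / sqrt(nc) * env * sin(2 * pi * s$f0[i] * t + s$ph[i])
    }
  }
  x
}

circular_lag <- function(x, lag) {
  n <- length(x)
  lag <- lag %% n
  if (lag == 0) return(x)
  c(x[(n - lag + 1):n], x[seq_len(n - lag)])
}

#' Generate one synthetic two-channel EEG recording
#'
#' Draws a deterministic pseudo-EEG recording for one subject in one state.
#' FP2 is built as `sqrt(1 - gain^2)` times its own oscillators plus `gain`
#' times a lag-delayed copy of FP1's oscillatory component, so information
#' flows FP1 -> FP2 by construction (symbolic transfer entropy FP1->FP2
#' exceeds the reverse direction). The per-subject baseline factor is drawn
#' from a substream keyed on the subject only, so both states of a subject
#' share it.
#'
#' @param subject_id Integer subject identifier.
#' @param state `"normal"` or `"fatigue"`.
#' @param params A [signal_model_params()] object.
#' @return A one-row tibble with columns `subject_id`, `state`, `fs`, and
#'   list-columns `FP1`, `FP2` holding the sampled signals in microvolts.
#' @export
generate_recording <- function(subject_id, state, params = signal_model_params()) {
  if (!state %in% c("normal", "fatigue")) {
    abort(sprintf("Unknown state label '%s'; expected 'normal' or 'fatigue'.", state))
  }
  fs <- params$fs
  n <- round(params$duration_s * fs)
  t <- seq_len(n) / fs
  amps <- params$band_amps[[state]]
  namp <- params$noise_amp[[state]]
  cpl <- params$coupling[[state]]
  # Oscillator structure (carrier frequencies, phases, modulation) is drawn
  # from a per-subject stream shared by both states, so the state contrast
  # is carried by the amplitude/noise/coupling parameters alone; the noise
  # realisation is per-(subject, state).
  sub_stream <- with_local_seed(derive_seed(params$seed, subject_id, "subject"), {
    list(sf = exp(rnorm(1, 0, params$subject_sd)),
         struct1 = .draw_osc_structure(),
         struct2 = .draw_osc_structure())
  })
  sf <- sub_stream$sf
  sig <- with_local_seed(derive_seed(params$seed, subject_id, state), {
    osc1 <- .oscillators(t, sub_stream$struct1, amps)
    osc2 <- .oscillators(t, sub_stream$struct2, amps)
    n1 <- namp * pink_noise(n)
    n2 <- namp * pink_noise(n)
    fp1 <- osc1 + n1
    fp2 <- sqrt(max(0, 1 - cpl$gain^2)) * osc2 +
      cpl$gain * circular_lag(osc1, cpl$lag) + n2
    list(FP1 = sf * fp1, FP2 = sf * fp2)
  })
  tibble::tibble(subject_id = as.integer(subject_id), state = state,
                 fs = fs, FP1 = list(sig$FP1), FP2 = list(sig$FP2))
}

#' Generate a labelled multi-subject cohort
#'
#' One normal and one fatigue recording per subject, reproducible from the
#' seed in `params` (per-(subject, state) substreams are derived by hashing,
#' so generation order does not matter).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param params A [signal_model_params()] object.
#' @return A tibble of `2 * n_subjects` rows in [generate_recording()]
#'   format.
#' @export
generate_cohort <- function(n_subjects, params = signal_model_params()) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort("`n_subjects` must be >= 1.")
  }
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    dplyr::bind_rows(generate_recording(s, "normal", params),
                     generate_recording(s, "fatigue", params))
  })
}

#' Write a cohort to per-recording CSV files plus a manifest
#'
#' Each recording becomes `subject<ID>_<state>.csv` with columns `FP1`,
#' `FP2` (microvolts); `manifest.csv` lists path, subject id, state and
#' sampling rate.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- purrr::pmap_dfr(cohort, function(subject_id, state, fs, FP1, FP2) {
    path <- file.path(dir, sprintf("subject%03d_%s.csv", subject_id, state))
    readr::write_csv(tibble::tibble(FP1 = FP1, FP2 = FP2), path)
    tibble::tibble(path = basename(path), subject_id = subject_id,
                   state = state, fs = fs)
  })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir Directory containing `manifest.csv` and the recording CSVs.
#' @return A cohort tibble in [generate_recording()] format.
#' @export
read_cohort_csv <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  purrr::pmap_dfr(manifest, function(path, subject_id, state, fs) {
    sig <- readr::read_csv(file.path(dir, path), show_col_types = FALSE)
    tibble::tibble(subject_id = as.integer(subject_id), state = state,
                   fs = fs, FP1 = list(sig$FP1), FP2 = list(sig$FP2))
  })
}
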