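# Multi-subject synthetic EEG with planted subject-specific beta-band
# structure: a subset of "informative" channels carries a subject-specific
# oscillation (individual frequency, per-channel amplitude signature and
# phase lags, shared-source mixing controlling phase locking), all other
# channels draw from one population distribution, on top of 1/f^alpha
# background and white sensor noise.

#' Simulation configuration
#'
#' Defaults mirror the acquisition geometry of a 13-subject study with a
#' 14-channel consumer headset: 80 s per subject at 128 Hz, so 2-s
#' epoching yields 40 epochs per subject (520 rows over 13 subjects).
#'
#' @param n_subjects Number of subjects (default 13).
#' @param montage Montage name or [montage] object (default "emotiv14").
#' @param duration_s Recording length per subject in seconds (default 80).
#' @param fs Sampling rate in Hz (default 128); \code{duration_s * fs}
#'   must be integral.
#' @param informative_channels Channels carrying subject-identifying
#'   structure (default \code{c("T8", "F8", "FC6", "FC5")}).
#' @param amplitude_contrast Ratio of the subject-specific amplitude range
#'   to the common beta amplitude (default 1): informative-channel
#'   amplitudes are \code{beta_amplitude * (1 + contrast * U(0,1))},
#'   drawn once per subject.
#' @param kappa Shared-source mixing weight in [0, 1] (default 0.8); the
#'   planted phase-locking level among informative channels. At 1 the
#'   informative channels of a subject are phase-locked copies of one
#'   source; at 0 every channel oscillates independently.
#' @param noise_sd White sensor-noise standard deviation in microvolts
#'   (default 2).
#' @param pink_sd Amplitude of the 1/f^alpha background in microvolts
#'   (default 4).
#' @param pink_exponent Spectral exponent alpha of the background
#'   (default 1).
#' @param beta_amplitude Common beta oscillation amplitude in microvolts
#'   (default 6).
#' @param lag_spread Half-width (radians) of the uniform per-subject
#'   phase lags on informative channels (default pi; 0 makes informative
#'   channels exact scaled copies when \code{kappa = 1}).
#' @param block_s Length in seconds of the independent oscillation blocks
#'   (default 2, matching the downstream epoch length so epochs are
#'   exchangeable within subject).
#' @param seed Integer seed; recordings are bit-identical given the seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_subjects = 13, montage = "emotiv14",
                       duration_s = 80, fs = 128,
                       informative_channels = c("T8", "F8", "FC6", "FC5"),
                       amplitude_contrast = 1, kappa = 0.8,
                       noise_sd = 2, pink_sd = 4, pink_exponent = 1,
                       beta_amplitude = 6, lag_spread = pi,
                       block_s = 2, seed = 1) {
  if (is.character(montage)) montage <- load_montage(montage)
  stopifnot(inherits(montage, "montage"), n_subjects >= 1,
            kappa >= 0, kappa <= 1, noise_sd >= 0, pink_sd >= 0,
            amplitude_contrast >= 0, beta_amplitude > 0,
            abs(duration_s * fs - round(duration_s * fs)) < 1e-9)
  unknown <- setdiff(informative_channels, montage$channels)
  if (length(unknown) > 0L)
    stop("informative channels not in montage: ",
         paste(unknown, collapse = ", "))
  structure(list(n_subjects = n_subjects, montage = montage,
                 duration_s = duration_s, fs = fs,
                 informative_channels = informative_channels,
                 amplitude_contrast = amplitude_contrast, kappa = kappa,
                 noise_sd = noise_sd, pink_sd = pink_sd,
                 pink_exponent = pink_exponent,
                 beta_amplitude = beta_amplitude,
                 lag_spread = lag_spread, block_s = block_s, seed = seed),
            class = "sim_config")
}

# 1/f^alpha noise by spectral shaping of white noise, unit variance.
pink_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  idx <- 0:(n - 1)
  f <- pmin(idx, n - idx)
  shape <- c(0, 1 / f[-1]^(alpha / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Simulate multi-subject EEG recordings
#'
#' Each subject gets an individual beta frequency in 15-28 Hz and, on the
#' informative channels, an amplitude signature and phase lags drawn once
#' per subject. Within every \code{block_s}-second block, channel c of
#' subject s is
#' \code{A_sc * (kappa * cos(2 pi f_s t + phi_sc) +
#' (1 - kappa) * cos(2 pi nu t + psi))}
#' with \code{(nu, psi)} independent per channel and block, plus
#' 1/f^alpha background and white noise. Non-informative channels carry
#' only the independent oscillation at the common amplitude, so their
#' epochs are exchangeable across subjects.
#'
#' @param config A [sim_config()].
#' @return List with \code{recordings} (one [eeg_recording] per subject,
#'   ids \code{"S01"}, \code{"S02"}, ...) and \code{ground_truth}
#'   (informative channels and the per-subject frequencies, amplitudes
#'   and lags).
#' @export
simulate_eeg <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mont <- config$montage
  ch <- mont$channels
  n_ch <- length(ch)
  n_t <- round(config$duration_s * config$fs)
  t_glob <- (0:(n_t - 1)) / config$fs
  spb <- round(config$block_s * config$fs)
  n_blocks <- ceiling(n_t / spb)
  inf_ix <- match(config$informative_channels, ch)
  ids <- sprintf("S%02d", seq_len(config$n_subjects))
  recordings <- vector("list", config$n_subjects)
  truth <- vector("list", config$n_subjects)
  with_seed(config$seed, {
    for (s in seq_len(config$n_subjects)) {
      f_s <- stats::runif(1, 15, 28)
      g <- stats::runif(length(inf_ix))
      A <- rep(config$beta_amplitude, n_ch)
      A[inf_ix] <- config$beta_amplitude *
        (1 + config$amplitude_contrast * g)
      lags <- stats::runif(length(inf_ix),
                           -config$lag_spread, config$lag_spread)
      nu <- matrix(stats::runif(n_ch * n_blocks, 15, 28), n_ch)
      psi <- matrix(stats::runif(n_ch * n_blocks, -pi, pi), n_ch)
      x <- matrix(0, n_ch, n_t)
      for (c_i in seq_len(n_ch)) {
        indep <- numeric(n_t)
        for (b in seq_len(n_blocks)) {
          ix <- ((b - 1L) * spb + 1L):min(b * spb, n_t)
          tb <- t_glob[ix] - t_glob[ix[1]]
          indep[ix] <- cos(2 * pi * nu[c_i, b] * tb + psi[c_i, b])
        }
        k_pos <- match(c_i, inf_ix)
        osc <- if (!is.na(k_pos))
          config$kappa * cos(2 * pi * f_s * t_glob + lags[k_pos]) +
            (1 - config$kappa) * indep
        else indep
        x[c_i, ] <- A[c_i] * osc
      }
      if (config$pink_sd > 0)
        for (c_i in seq_len(n_ch))
          x[c_i, ] <- x[c_i, ] +
            config$pink_sd * pink_noise(n_t, config$pink_exponent)
      if (config$noise_sd > 0)
        x <- x + matrix(stats::rnorm(n_ch * n_t, sd = config$noise_sd),
                        n_ch)
      recordings[[s]] <- eeg_recording(ids[s], mont, x, config$fs)
      truth[[s]] <- list(subject = ids[s], frequency = f_s,
                         amplitudes = stats::setNames(A, ch),
                         lags = stats::setNames(lags,
                                                config$informative_channels))
    }
  })
  list(recordings = recordings,
       ground_truth = list(informative_channels =
                             config$informative_channels,
                           subjects = truth))
}

#' Simulate and write EDF files plus ground truth
#'
#' Writes one EDF per subject (\code{S01.edf}, ...) and a
#' \code{ground_truth.json} with the planted parameters.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
simulate_to_edf <- function(config, dir) {
  sim <- simulate_eeg(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in sim$recordings)
    write_edf(rec, file.path(dir, paste0(rec$subject_id, ".edf")))
  jsonlite::write_json(sim$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
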