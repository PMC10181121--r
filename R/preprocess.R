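# Preprocessing pipeline: baseline correction, zero-phase FIR band-pass
# (broadband 5-40 Hz, then the analysis band, beta 13-30 Hz by default),
# segmentation into fixed-length epochs.

#' Remove the mean voltage from every channel
#'
#' Baseline correction by per-channel whole-recording mean subtraction.
#'
#' @param rec An [eeg_recording].
#' @return The recording with zero-mean channels.
#' @export
baseline_correct <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"), ncol(rec$samples) > 0L)
  rec$samples <- rec$samples - rowMeans(rec$samples)
  rec
}

# Hamming-window FIR band-pass of the given transition width, applied
# forward-backward for zero phase. The Hamming window's transition width is
# about 3.3/N in normalized frequency, so N = ceiling(3.3 fs / width),
# rounded up to even (odd tap count, symmetric type-I filter).
design_fir <- function(low, high, fs, transition = 2) {
  n <- ceiling(3.3 * fs / transition)
  if (n %% 2L == 1L) n <- n + 1L
  as.numeric(signal::fir1(n, c(low, high) / (fs / 2), type = "pass"))
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) FIR filter applied forward and backward
#' (\code{signal::filtfilt}), giving zero phase distortion and doubling the
#' stopband attenuation. The default 2 Hz transition width gives well over
#' 30 dB attenuation one transition width outside the band.
#'
#' @param rec An [eeg_recording].
#' @param low,high Band edges in Hz; \code{0 < low < high < fs/2}.
#' @param transition Transition width in Hz (default 2).
#' @return The filtered recording, with attribute \code{band} set.
#' @export
bandpass <- function(rec, low, high, transition = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  b <- design_fir(low, high, rec$fs, transition)
  if (ncol(rec$samples) <= 3L * length(b))
    stop("recording too short for the designed filter (need > ",
         3L * length(b), " samples)")
  rec$samples <- t(apply(rec$samples, 1L, fir_filtfilt, b = b))
  attr(rec, "band") <- c(low, high)
  rec
}

# Zero-phase FIR application. Forward-backward filtering with an FIR b is
# convolution with conv(b, rev(b)) followed by removal of the group delay;
# done here in the frequency domain with reflected end padding (as in the
# classic filtfilt) to suppress start/end transients.
fir_filtfilt <- function(x, b) {
  nb <- length(b)
  L <- 3L * nb
  n <- length(x)
  if (n <= L) stop("signal too short for zero-phase filtering")
  pre <- 2 * x[1] - x[(L + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - L)]
  xe <- c(pre, x, post)
  c2 <- stats::convolve(b, rev(b), type = "open")   # length 2*nb - 1
  m <- length(xe) + length(c2) - 1L
  N <- stats::nextn(m, 2)
  y <- Re(stats::fft(stats::fft(c(xe, numeric(N - length(xe)))) *
                       stats::fft(c(c2, numeric(N - length(c2)))),
                     inverse = TRUE)) / N
  # linear-convolution output; the filtered sample aligned with xe[i] is
  # y[i + nb - 1] (zero-phase: delay (length(c2)-1)/2 = nb - 1)
  y[(L + nb):(L + nb + n - 1L)]
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts the recording into non-overlapping consecutive epochs; a trailing
#' partial epoch is discarded. Optionally rejects epochs containing any
#' sample beyond an absolute amplitude threshold.
#'
#' @param rec An [eeg_recording].
#' @param epoch_length Epoch duration in seconds (default 2).
#' @param reject_threshold Absolute amplitude threshold in microvolts, or
#'   \code{NULL} (default) to keep every epoch.
#' @return An [eeg_epochs] object; its \code{band} is taken from the
#'   recording if it has been band-pass filtered.
#' @export
segment_epochs <- function(rec, epoch_length = 2, reject_threshold = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- round(epoch_length * rec$fs)
  if (spe < 1L || ncol(rec$samples) < spe)
    stop("recording shorter than one epoch")
  n_ep <- floor(ncol(rec$samples) / spe)
  n_ch <- nrow(rec$samples)
  ep <- array(0, c(n_ep, n_ch, spe))
  for (e in seq_len(n_ep))
    ep[e, , ] <- rec$samples[, ((e - 1L) * spe + 1L):(e * spe)]
  if (!is.null(reject_threshold)) {
    keep <- apply(ep, 1L, function(m) all(abs(m) <= reject_threshold))
    if (!any(keep)) stop("all epochs rejected by amplitude threshold")
    ep <- ep[keep, , , drop = FALSE]
  }
  eeg_epochs(rec$subject_id, rec$montage, ep, rec$fs,
             band = attr(rec, "band"))
}

#' Full preprocessing pipeline
#'
#' Baseline correction, broadband FIR band-pass (default 5-40 Hz), band
#' filtering to the analysis band (default beta, 13-30 Hz), and epoching.
#'
#' @param rec An [eeg_recording].
#' @param broadband Length-2 numeric, the noise-reduction band in Hz.
#' @param band Length-2 numeric, the analysis band in Hz.
#' @param epoch_length Epoch duration in seconds.
#' @param reject_threshold Optional epoch rejection threshold in microvolts.
#' @return An [eeg_epochs] in the analysis band.
#' @export
preprocess <- function(rec, broadband = c(5, 40), band = c(13, 30),
                       epoch_length = 2, reject_threshold = NULL) {
  rec <- baseline_correct(rec)
  rec <- bandpass(rec, broadband[1], broadband[2])
  rec <- bandpass(rec, band[1], band[2])
  segment_epochs(rec, epoch_length, reject_threshold)
}
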