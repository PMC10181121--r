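# Containers for continuous and epoched multi-channel EEG.

#' Construct a continuous EEG recording
#'
#' @param subject_id Subject label.
#' @param montage A [montage]; rows of \code{samples} must follow its
#'   channel order.
#' @param samples Numeric channels x time matrix, in microvolts.
#' @param fs Sampling rate in Hz.
#' @return An object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(subject_id, montage, samples, fs) {
  stopifnot(inherits(montage, "montage"), is.matrix(samples), fs > 0)
  if (nrow(samples) != length(montage$channels))
    stop("samples must have one row per montage channel")
  rownames(samples) <- montage$channels
  structure(list(subject_id = as.character(subject_id), montage = montage,
                 samples = samples, fs = fs),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording: subject '", x$subject_id, "', ",
      nrow(x$samples), " channels (", x$montage$name, "), ",
      ncol(x$samples), " samples at ", x$fs, " Hz (",
      round(ncol(x$samples) / x$fs, 2), " s)\n", sep = "")
  invisible(x)
}

#' Construct an epoched EEG recording
#'
#' @param subject_id Subject label.
#' @param montage A [montage].
#' @param epochs Numeric array n_epochs x channels x samples_per_epoch,
#'   in microvolts.
#' @param fs Sampling rate in Hz.
#' @param band Length-2 numeric, the (low, high) Hz band the signal was
#'   filtered to, or \code{NULL} for broadband.
#' @return An object of class \code{eeg_epochs}.
#' @export
eeg_epochs <- function(subject_id, montage, epochs, fs, band = NULL) {
  stopifnot(inherits(montage, "montage"), length(dim(epochs)) == 3L, fs > 0)
  if (dim(epochs)[2] != length(montage$channels))
    stop("epochs must have one slice per montage channel")
  structure(list(subject_id = as.character(subject_id), montage = montage,
                 epochs = epochs, fs = fs, band = band),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("Epoched EEG: subject '", x$subject_id, "', ",
      dim(x$epochs)[1], " epochs x ", dim(x$epochs)[2], " channels x ",
      dim(x$epochs)[3], " samples at ", x$fs, " Hz",
      if (!is.null(x$band))
        paste0(", band ", x$band[1], "-", x$band[2], " Hz"),
      "\n", sep = "")
  invisible(x)
}
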