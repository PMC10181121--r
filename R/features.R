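# Per-epoch features: multitaper beta-band power (PS), hemispheric asymmetry
# index (AI), and phase-locking value (PLV) between channel pairs.

# --- Slepian tapers -------------------------------------------------------

# Discrete prolate spheroidal sequences via the symmetric tridiagonal
# eigenproblem (Percival & Walden 1993, ch. 8): diagonal
# ((N-1-2t)/2)^2 cos(2*pi*W), off-diagonal t(N-t)/2. The top-k eigenvectors
# are the tapers, unit energy, ordered by decreasing in-band concentration.
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' @param n Taper length in samples.
#' @param nw Time-half-bandwidth product (default 2).
#' @param k Number of tapers (default 3, i.e. 2*nw - 1).
#' @return An n x k matrix of orthonormal tapers. Sign convention: each
#'   taper has a positive sum, or a positive leading lobe when the sum
#'   vanishes (antisymmetric tapers).
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  stopifnot(n >= 2L, nw > 0, k >= 1L, k <= n)
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t_idx <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  off_v <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  A <- diag(diag_v)
  A[cbind(1:(n - 1), 2:n)] <- off_v
  A[cbind(2:n, 1:(n - 1))] <- off_v
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    if (abs(s) > 1e-9) {
      if (s < 0) tapers[, j] <- -tapers[, j]
    } else if (tapers[which.max(abs(tapers[, j]) > 1e-6), j] < 0) {
      tapers[, j] <- -tapers[, j]
    }
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

# --- spectral power -------------------------------------------------------

# One-sided multitaper PSD of the columns of a samples x channels matrix,
# averaged over tapers, returned as a (positive frequencies) x channels
# matrix together with the frequency grid.
multitaper_psd <- function(x, fs, nw = 2, k = 3) {
  n <- nrow(x)
  tapers <- dpss_tapers(n, nw, k)
  acc <- 0
  for (j in seq_len(k)) {
    X <- stats::mvfft(x * tapers[, j])
    acc <- acc + Mod(X)^2
  }
  psd <- 2 * acc / (k * fs)          # unit-energy tapers: no extra norm
  freqs <- (0:(n - 1)) * fs / n
  keep <- freqs <= fs / 2
  list(freq = freqs[keep], psd = psd[keep, , drop = FALSE])
}

#' Multitaper band-averaged spectral power
#'
#' Power spectral density of one epoch of one channel, estimated with
#' Slepian multitapers (default time-half-bandwidth 2, 3 tapers), averaged
#' across the frequency bins inside \code{band} (inclusive). This is the PS
#' feature: one scalar per channel per epoch, in microvolt^2/Hz.
#'
#' @param x Numeric vector, one epoch of one channel.
#' @param fs Sampling rate in Hz.
#' @param band Length-2 numeric, band edges in Hz (within Nyquist).
#' @param nw,k Multitaper parameters, see [dpss_tapers()].
#' @return Band-averaged PSD (scalar, >= 0; strictly positive for nonzero
#'   input).
#' @export
band_power <- function(x, fs, band = c(13, 30), nw = 2, k = 3) {
  if (length(x) < 2L) stop("zero-length or degenerate input")
  if (band[2] > fs / 2) stop("band exceeds the Nyquist frequency")
  mt <- multitaper_psd(matrix(x, ncol = 1L), fs, nw, k)
  sel <- mt$freq >= band[1] & mt$freq <= band[2]
  if (!any(sel)) stop("no frequency bins inside the band")
  mean(mt$psd[sel, 1L])
}

#' Hemispheric asymmetry index
#'
#' Natural logarithm of the ratio of left- to right-hemisphere band power
#' for a mirror electrode pair: \code{log(ps_left / ps_right)}.
#' Antisymmetric under swapping the arguments and invariant to a common
#' gain applied to both channels.
#'
#' @param ps_left,ps_right Strictly positive band powers.
#' @return The asymmetry index (dimensionless).
#' @export
asymmetry_index <- function(ps_left, ps_right) {
  if (any(ps_left <= 0) || any(ps_right <= 0))
    stop("band powers must be strictly positive (degenerate input upstream)")
  log(ps_left / ps_right)
}

# --- phase ----------------------------------------------------------------

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited epoch
#'
#' Phase of the analytic signal (frequency-domain Hilbert transform).
#' The leading and trailing 5% of samples are flagged invalid (attribute
#' \code{"valid"}) so PLV averaging can exclude transform edge artifacts.
#'
#' @param x Numeric vector, one beta-filtered epoch of one channel.
#' @return Numeric vector of phases in (-pi, pi], with logical attribute
#'   \code{"valid"}.
#' @export
instantaneous_phase <- function(x) {
  if (stats::sd(x) == 0) stop("constant input: phase undefined")
  ph <- Arg(analytic_signal(x))
  n <- length(x)
  edge <- ceiling(0.05 * n)
  valid <- rep(TRUE, n)
  valid[seq_len(edge)] <- FALSE
  valid[(n - edge + 1L):n] <- FALSE
  attr(ph, "valid") <- valid
  ph
}

#' Phase-locking value between two phase series
#'
#' Modulus of the time average of the unit phasor of the phase difference,
#' \code{|mean(exp(i (theta_a - theta_b)))|}, over the samples both series
#' flag as valid. 1 means perfect locking (constant phase difference,
#' independent of amplitude), 0 means no locking.
#'
#' @param phase_a,phase_b Phase series from [instantaneous_phase()] (plain
#'   numeric vectors are accepted; all samples are then used).
#' @return PLV in [0, 1].
#' @export
plv <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) stop("phase series length mismatch")
  va <- attr(phase_a, "valid"); vb <- attr(phase_b, "valid")
  valid <- rep(TRUE, length(phase_a))
  if (!is.null(va)) valid <- valid & va
  if (!is.null(vb)) valid <- valid & vb
  d <- phase_a[valid] - phase_b[valid]
  Mod(mean(exp(1i * d)))
}

# --- feature table --------------------------------------------------------

#' Build the epochs-by-features table
#'
#' For every epoch of every recording: PS = multitaper band power per
#' channel; AI = log left/right PS ratio per mirror pair (from the same
#' per-epoch PS values); PLV per unordered channel pair from the analytic
#' phases of the epoch. Columns follow the catalog's canonical order.
#'
#' @param recordings A list of [eeg_epochs], all over the catalog's
#'   montage with one common band and sampling rate.
#' @param catalog A [feature_catalog]; its montage fixes the expected
#'   channels.
#' @param nw,k Multitaper parameters for the PS features.
#' @return An object of class \code{feature_table}: list with fields
#'   \code{values} (rows x features numeric matrix), \code{subject}
#'   (character, one per row), \code{epoch} (integer index within
#'   subject), \code{catalog}, \code{band}, \code{fs}.
#' @export
build_feature_table <- function(recordings, catalog, nw = 2, k = 3) {
  stopifnot(inherits(catalog, "feature_catalog"), length(recordings) > 0L)
  if (inherits(recordings, "eeg_epochs")) recordings <- list(recordings)
  mont <- attr(catalog, "montage")
  fs <- recordings[[1]]$fs
  band <- recordings[[1]]$band
  if (is.null(band)) band <- c(13, 30)
  for (r in recordings) {
    if (!identical(r$montage$channels, mont$channels))
      stop("montage mismatch between recording and catalog")
    if (r$fs != fs) stop("recordings have differing sampling rates")
  }
  ch <- mont$channels
  is_ps <- catalog$group == "PS"
  is_ai <- catalog$group == "AI"
  is_plv <- catalog$group == "PLV"
  ps_ix <- match(catalog$ch1[is_ps], ch)
  ai_l <- match(catalog$ch1[is_ai], ch)
  ai_r <- match(catalog$ch2[is_ai], ch)
  plv_i <- match(catalog$ch1[is_plv], ch)
  plv_j <- match(catalog$ch2[is_plv], ch)

  rows <- list(); subj <- character(0); epid <- integer(0)
  for (r in recordings) {
    n_ep <- dim(r$epochs)[1]
    spe <- dim(r$epochs)[3]
    sel_band <- {
      freqs <- (0:(spe - 1)) * fs / spe
      freqs <= fs / 2 & freqs >= band[1] & freqs <= band[2]
    }
    freqs <- (0:(spe - 1)) * fs / spe
    keep_pos <- freqs <= fs / 2
    edge <- ceiling(0.05 * spe)
    valid <- rep(TRUE, spe)
    valid[c(seq_len(edge), (spe - edge + 1L):spe)] <- FALSE
    tapers <- dpss_tapers(spe, nw, k)
    h <- { # analytic-signal frequency weights
      hh <- numeric(spe)
      if (spe %% 2L == 0L) { hh[c(1L, spe / 2 + 1L)] <- 1; hh[2:(spe / 2)] <- 2 }
      else { hh[1L] <- 1; hh[2:((spe + 1L) / 2)] <- 2 }
      hh
    }
    for (e in seq_len(n_ep)) {
      E <- t(r$epochs[e, , ])                 # samples x channels
      acc <- 0
      for (j in seq_len(k))
        acc <- acc + Mod(stats::mvfft(E * tapers[, j]))^2
      psd <- 2 * acc / (k * fs)
      ps <- colMeans(psd[keep_pos & sel_band, , drop = FALSE])
      row <- numeric(nrow(catalog))
      row[is_ps] <- ps[ps_ix]
      if (any(is_ai)) {
        if (any(ps <= 0))
          stop("non-positive band power; degenerate epoch for subject ",
               r$subject_id)
        row[is_ai] <- log(ps[ai_l] / ps[ai_r])
      }
      if (any(is_plv)) {
        Z <- stats::mvfft(stats::mvfft(E) * h, inverse = TRUE) / spe
        U <- exp(1i * Arg(Z[valid, , drop = FALSE]))
        G <- crossprod(Conj(U), U) / sum(valid)   # G[a,b] = mean phasor
        row[is_plv] <- Mod(G[cbind(plv_i, plv_j)])
      }
      rows[[length(rows) + 1L]] <- row
      subj <- c(subj, r$subject_id)
      epid <- c(epid, e)
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- catalog$name
  structure(list(values = values, subject = subj, epoch = epid,
                 catalog = catalog, band = band, fs = fs),
            class = "feature_table")
}

#' Restrict a feature table to a channel subset
#'
#' @param table A \code{feature_table}.
#' @param subset Character vector of channel labels.
#' @return A \code{feature_table} over [supported_features()] of the subset.
#' @export
subset_feature_table <- function(table, subset) {
  stopifnot(inherits(table, "feature_table"))
  cat2 <- supported_features(table$catalog, subset)
  out <- table
  out$values <- table$values[, cat2$name, drop = FALSE]
  out$catalog <- cat2
  out
}

#' @export
print.feature_table <- function(x, ...) {
  gs <- attr(x$catalog, "group_sizes")
  cat("Feature table: ", nrow(x$values), " epochs x ", ncol(x$values),
      " features (", gs[["PS"]], " PS, ", gs[["AI"]], " AI, ", gs[["PLV"]],
      " PLV), ", length(unique(x$subject)), " subjects, band ",
      x$band[1], "-", x$band[2], " Hz\n", sep = "")
  invisible(x)
}

#' Write a feature table to CSV
#'
#' Columns \code{subject}, \code{epoch}, then the canonical feature names;
#' values printed with 12 significant digits so the round-trip through
#' [read_feature_table()] is lossless at that precision.
#'
#' @param table A \code{feature_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(subject = table$subject, epoch = table$epoch,
                   signif(table$values, 12), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @param catalog The [feature_catalog] the columns refer to.
#' @param band,fs Band edges and sampling rate to record on the table.
#' @return A \code{feature_table}.
#' @export
read_feature_table <- function(path, catalog, band = c(13, 30), fs = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(catalog$name %in% colnames(df)))
    stop("CSV columns do not cover the catalog features")
  structure(list(values = as.matrix(df[, catalog$name, drop = FALSE]),
                 subject = as.character(df$subject),
                 epoch = as.integer(df$epoch),
                 catalog = catalog, band = band, fs = fs),
            class = "feature_table")
}
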