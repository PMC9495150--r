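## Feature extraction: STFT magnitude -> 128-band Mel spectrogram (dB) ->
## 20-order MFCCs; the two blocks are normalized independently and stacked
## into the fused 148 x 801 matrix that feeds the classifier.

N_FFT <- 400L      # 25 ms window at 16 kHz
HOP <- 200L        # 12.5 ms hop
N_MELS <- 128L
N_MFCC <- 20L
DB_FLOOR <- -80    # dynamic-range floor for dB conversion

#' Hertz to Mel
#'
#' The Mel scale maps physical frequency to perceived pitch:
#' `mel = 2595 * log10(1 + f/700)`.
#'
#' @param f Frequency in Hz (>= 0); vectorized.
#' @return Mel value(s).
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("hz_to_mel: frequency must be non-negative")
  2595 * log10(1 + f / 700)
}

#' Mel to Hertz (inverse of [hz_to_mel()])
#' @param m Mel value(s) (>= 0).
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Short-time Fourier transform magnitude
#'
#' Centered framing (the signal is zero-padded by `n_fft/2` on both sides),
#' periodic Hann window of 400 samples, hop 200 samples; magnitudes of the
#' non-negative-frequency DFT bins.  A 10 s clip at 16 kHz yields a
#' 201 x 801 matrix (rows = frequency bins 0..200, columns = time frames).
#'
#' @param clip An [audio_clip()] (any length > 0).
#' @param n_fft Window size in samples (default 400).
#' @param hop Hop length in samples (default 200).
#' @return A `spectrogram` matrix (bins x frames) with attributes
#'   `sample_rate`, `n_fft`, `hop`.
#' @export
stft_magnitude <- function(clip, n_fft = N_FFT, hop = HOP) {
  stopifnot_clip(clip)
  x <- clip$samples
  if (!length(x)) stop("stft_magnitude: empty clip")
  half <- n_fft %/% 2
  xp <- c(numeric(half), x, numeric(half))
  n_frames <- length(x) %/% hop + 1L
  idx <- outer(seq_len(n_fft), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(xp[idx], nrow = n_fft)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_fft) - 1) / n_fft)  # periodic Hann
  S <- abs(stats::mvfft(frames * w))[seq_len(half + 1L), , drop = FALSE]
  structure(S, class = c("spectrogram", "matrix"),
            sample_rate = clip$sample_rate, n_fft = n_fft, hop = hop)
}

#' Triangular Mel filterbank
#'
#' `n_mels` triangular filters with peaks spaced uniformly on the Mel scale
#' between `f_min` and `f_max`, evaluated at the FFT bin center frequencies
#' and area-normalized (each filter scaled by `2 / bandwidth`) so filter
#' output is comparable across bands.
#'
#' @param n_mels Number of filters (default 128).
#' @param n_fft FFT size (default 400).
#' @param sample_rate Sampling rate in Hz.
#' @param f_min,f_max Frequency span of the bank.
#' @return `n_mels x (n_fft/2 + 1)` non-negative matrix.
#' @export
mel_filterbank <- function(n_mels = N_MELS, n_fft = N_FFT,
                           sample_rate = 16000, f_min = 0,
                           f_max = sample_rate / 2) {
  mel_pts <- seq(hz_to_mel(f_min), hz_to_mel(f_max), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bin_hz <- (0:(n_fft %/% 2)) * sample_rate / n_fft
  fb <- matrix(0, n_mels, length(bin_hz))
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ctr <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (bin_hz - lo) / (ctr - lo)
    down <- (hi - bin_hz) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)
  }
  fb
}

#' Mel spectrogram
#'
#' Applies the 128-band triangular Mel filterbank to the power spectrogram
#' (squared STFT magnitudes).
#'
#' @param spec A `spectrogram` from [stft_magnitude()].
#' @param n_mels Number of Mel bands (default 128).
#' @return A `mel_spectrogram` matrix (`n_mels` x frames) with attribute
#'   `in_decibels = FALSE`.
#' @export
mel_spectrogram <- function(spec, n_mels = N_MELS) {
  if (!inherits(spec, "spectrogram")) stop("mel_spectrogram: expected a spectrogram")
  fb <- mel_filterbank(n_mels, attr(spec, "n_fft"), attr(spec, "sample_rate"))
  M <- fb %*% (unclass(spec)^2)
  structure(M, class = c("mel_spectrogram", "matrix"), in_decibels = FALSE)
}

#' Power to decibels
#'
#' `10 * log10(power / max(power))`, floored at `floor_db` (default -80), so
#' 0 dB is the strongest time-frequency cell.  An all-zero matrix maps to the
#' floor everywhere.
#'
#' @param m A `mel_spectrogram` (power) or non-negative matrix.
#' @param floor_db Dynamic-range floor in dB.
#' @return Same shape, in dB; for `mel_spectrogram` input the
#'   `in_decibels` attribute is set.
#' @export
power_to_db <- function(m, floor_db = DB_FLOOR) {
  was_mel <- inherits(m, "mel_spectrogram")
  v <- unclass(m)
  ref <- max(v)
  out <- if (ref <= 0) {
    matrix(floor_db, nrow(v), ncol(v))
  } else {
    pmax(10 * log10(pmax(v, .Machine$double.xmin) / ref), floor_db)
  }
  if (was_mel) {
    structure(out, class = c("mel_spectrogram", "matrix"), in_decibels = TRUE)
  } else out
}

# Orthonormal DCT-II matrix (k x n): row 0 scaled by sqrt(1/n), rest sqrt(2/n).
dct_matrix <- function(k, n) {
  D <- matrix(0, k, n)
  for (i in 0:(k - 1)) {
    D[i + 1, ] <- cos(pi * (2 * (0:(n - 1)) + 1) * i / (2 * n)) *
      if (i == 0) sqrt(1 / n) else sqrt(2 / n)
  }
  D
}

#' Mel-frequency cepstral coefficients
#'
#' Orthonormal type-II DCT along the frequency axis of the decibel-scaled
#' Mel spectrogram; the first `n_mfcc` coefficients (orders 0..19) are kept.
#'
#' @param mel_db A `mel_spectrogram` in decibels (see [power_to_db()]).
#' @param n_mfcc Number of cepstral orders (default 20).
#' @return `n_mfcc x frames` matrix of class `mfcc_matrix`.
#' @export
mfcc <- function(mel_db, n_mfcc = N_MFCC) {
  if (!inherits(mel_db, "mel_spectrogram") || !isTRUE(attr(mel_db, "in_decibels"))) {
    stop("mfcc: input must be a decibel-scaled mel_spectrogram")
  }
  D <- dct_matrix(n_mfcc, nrow(mel_db))
  structure(D %*% unclass(mel_db), class = c("mfcc_matrix", "matrix"))
}

#' Whole-matrix standardization
#'
#' `(m - mean(m)) / sd(m)` with the mean and population standard deviation
#' taken over every element of the matrix, so the output has mean 0 and
#' standard deviation 1.
#'
#' @param m Numeric matrix with at least two distinct values.
#' @return Standardized matrix.
#' @export
normalize_feature <- function(m) {
  v <- unclass(m)
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  if (sd_pop == 0) stop("normalize_feature: constant matrix (zero std)")
  (v - mu) / sd_pop
}

#' Fuse Mel-spectrogram and MFCC blocks
#'
#' Stacks the 128-row Mel block on top of the 20-row MFCC block.  With
#' `normalize = TRUE` (the default) each block is standardized independently
#' via [normalize_feature()] *before* concatenation, so neither block's
#' dynamic range dominates the other.
#'
#' @param mel_db Decibel-scaled `mel_spectrogram`.
#' @param mf An `mfcc_matrix` with the same number of columns.
#' @param normalize Standardize each block first? Default `TRUE`.
#' @return A `feature_matrix` of `nrow(mel_db) + nrow(mf)` rows, with
#'   attributes `mel_rows`, `mfcc_rows`, `normalized`.
#' @export
fuse <- function(mel_db, mf, normalize = TRUE) {
  if (ncol(mel_db) != ncol(mf)) {
    stop("fuse: column (frame) counts differ: ", ncol(mel_db), " vs ", ncol(mf))
  }
  a <- unclass(mel_db); b <- unclass(mf)
  if (normalize) { a <- normalize_feature(a); b <- normalize_feature(b) }
  structure(rbind(a, b), class = c("feature_matrix", "matrix"),
            mel_rows = nrow(a), mfcc_rows = nrow(b), normalized = normalize)
}

#' Featurize a standardized clip
#'
#' Full feature chain: STFT magnitude -> Mel power spectrogram -> dB ->
#' MFCC; Mel(dB) and MFCC blocks fused (each standardized by default) into
#' the 148 x 801 model input.
#'
#' @param clip A standardized 10 s [audio_clip()] (see [standardize()]).
#' @param normalize Standardize each block before fusion? Default `TRUE`.
#' @param n_mels,n_mfcc Band/order counts (defaults 128 and 20).
#' @return A `feature_matrix` (`n_mels + n_mfcc` rows x 801 columns).
#' @export
featurize <- function(clip, normalize = TRUE, n_mels = N_MELS, n_mfcc = N_MFCC) {
  S <- stft_magnitude(clip)
  mel_db <- power_to_db(mel_spectrogram(S, n_mels))
  fuse(mel_db, mfcc(mel_db, n_mfcc), normalize = normalize)
}

#' Waveform features for the raw-input baseline
#'
#' Reshapes a standardized 160,000-sample clip into non-overlapping
#' 200-sample frames (a 200 x 800 matrix) so the same sequence classifier
#' can consume raw audio: each column is one 12.5 ms step.
#'
#' @param clip A standardized [audio_clip()].
#' @param frame Samples per step (default 200).
#' @return A `feature_matrix` of `frame` rows.
#' @export
waveform_features <- function(clip, frame = 200L) {
  stopifnot_clip(clip)
  x <- clip$samples
  n <- (length(x) %/% frame) * frame
  structure(matrix(x[seq_len(n)], nrow = frame),
            class = c("feature_matrix", "matrix"),
            mel_rows = 0L, mfcc_rows = 0L, normalized = FALSE)
}
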