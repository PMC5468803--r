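#' Feature extraction configuration
#'
#' Frame geometry and filterbank settings for the cepstral front end.
#' Defaults: 16 ms frames with 8 ms hop (so a 576 ms event spans exactly
#' 71 frames at 8 kHz), Hamming window, 26 triangular mel filters over
#' 0-4000 Hz, 256-point FFT (frames zero-padded from 128 samples),
#' log floor 1e-10, 13 cepstra including c0, delta regression over
#' +/-2 frames. Preemphasis is off by default: floor-coupled fall
#' signals concentrate their energy below 1 kHz and a preemphasis
#' high-pass would suppress exactly the discriminative band.
#'
#' @param frame_ms,hop_ms Frame length and hop in milliseconds.
#' @param n_mels Number of triangular mel filters.
#' @param n_fft FFT size (frames are zero-padded up to it).
#' @param n_cepstra Number of cepstral coefficients kept (from c0 up).
#' @param delta_width Half-width of the delta regression window (frames).
#' @param log_floor Floor applied to filterbank energies before the log.
#' @param preemphasis First-order preemphasis coefficient; 0 disables.
#' @param use_c0 Keep the 0th cepstral coefficient as the first feature
#'   (`TRUE`, default) or replace it with the frame log-energy.
#' @param fmin,fmax Filterbank edge frequencies in Hz; `fmax = NULL`
#'   means Nyquist.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(frame_ms = 16, hop_ms = 8, n_mels = 26,
                           n_fft = 256, n_cepstra = 13, delta_width = 2,
                           log_floor = 1e-10, preemphasis = 0,
                           use_c0 = TRUE, fmin = 0, fmax = NULL) {
  stopifnot(frame_ms > 0, hop_ms > 0, n_mels >= n_cepstra, n_fft >= 2,
            delta_width >= 1, log_floor > 0)
  structure(list(frame_ms = frame_ms, hop_ms = hop_ms, n_mels = n_mels,
                 n_fft = n_fft, n_cepstra = n_cepstra,
                 delta_width = delta_width, log_floor = log_floor,
                 preemphasis = preemphasis, use_c0 = use_c0,
                 fmin = fmin, fmax = fmax),
            class = "feature_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank matrix
#'
#' @param n_mels Number of filters.
#' @param n_fft FFT size.
#' @param sample_rate Sampling rate in Hz.
#' @param fmin,fmax Band edges in Hz (`fmax = NULL` means Nyquist).
#' @return An `n_mels x (n_fft/2 + 1)` weight matrix acting on the
#'   one-sided power spectrum.
#' @export
mel_filterbank <- function(n_mels, n_fft, sample_rate, fmin = 0, fmax = NULL) {
  if (is.null(fmax)) fmax <- sample_rate / 2
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * sample_rate / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

# orthonormal DCT-II basis, rows = coefficients 0..(n_ceps-1)
dct_matrix <- function(n_ceps, n_mels) {
  k <- seq_len(n_ceps) - 1L
  n <- seq_len(n_mels) - 1L
  B <- sqrt(2 / n_mels) * cos(outer(k, n + 0.5) * pi / n_mels)
  B[1, ] <- B[1, ] / sqrt(2)
  B
}

#' Extract static MFCCs from an audio segment
#'
#' Per frame: (optional preemphasis) -> Hamming window -> zero-padded
#' FFT magnitude-squared -> triangular mel filterbank -> floored log ->
#' orthonormal DCT-II -> first `n_cepstra` coefficients. The tail of the
#' signal that does not fill a whole frame is dropped.
#'
#' @param seg An [audio_segment] (8 kHz by convention; any rate accepted
#'   and read from the segment).
#' @param cfg A [feature_config].
#' @return An `L x n_cepstra` matrix of class `mfcc_matrix` with
#'   attributes `frame_ms`, `hop_ms`, `sample_rate`.
#' @export
extract_mfcc <- function(seg, cfg = feature_config()) {
  stopifnot(inherits(seg, "audio_segment"), inherits(cfg, "feature_config"))
  x <- seg$samples
  if (cfg$preemphasis > 0) x <- c(x[1], x[-1] - cfg$preemphasis * x[-length(x)])
  flen <- round(cfg$frame_ms * seg$sample_rate / 1000)
  hop  <- round(cfg$hop_ms * seg$sample_rate / 1000)
  if (length(x) < flen) {
    stop("extract_mfcc: segment shorter than one frame (", length(x), " < ",
         flen, " samples)")
  }
  if (flen > cfg$n_fft) stop("extract_mfcc: frame longer than n_fft")
  n_frames <- (length(x) - flen) %/% hop + 1L
  idx <- outer(seq_len(flen), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(x[idx], nrow = flen) * hamming_window(flen)
  padded <- matrix(0, cfg$n_fft, n_frames)
  padded[seq_len(flen), ] <- frames
  spec <- stats::mvfft(padded)
  n_bins <- cfg$n_fft %/% 2L + 1L
  power <- abs(spec[seq_len(n_bins), , drop = FALSE])^2
  fb <- mel_filterbank(cfg$n_mels, cfg$n_fft, seg$sample_rate, cfg$fmin, cfg$fmax)
  logE <- log(pmax(fb %*% power, cfg$log_floor))
  cep <- dct_matrix(cfg$n_cepstra, cfg$n_mels) %*% logE
  if (!cfg$use_c0) {
    cep[1, ] <- log(pmax(colSums(frames^2), cfg$log_floor))
  }
  out <- t(cep)
  structure(out, class = c("mfcc_matrix", class(out)),
            frame_ms = cfg$frame_ms, hop_ms = cfg$hop_ms,
            sample_rate = seg$sample_rate)
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

#' Append delta and delta-delta coefficients
#'
#' First derivatives by symmetric regression over `+/-width` frames with
#' the standard weights `sum_n n (c[t+n] - c[t-n]) / (2 sum_n n^2)`;
#' edge frames are replicated. Second derivatives are deltas of the
#' deltas. A 13-column static matrix becomes 39 columns.
#'
#' @param mfcc An `mfcc_matrix` (or plain matrix), frames in rows.
#' @param width Regression half-width in frames.
#' @return Matrix with `3 x ncol(mfcc)` columns, same class/attributes.
#' @export
append_deltas <- function(mfcc, width = 2L) {
  m <- unclass(mfcc)
  d1 <- delta_regression(m, width)
  d2 <- delta_regression(d1, width)
  out <- cbind(m, d1, d2)
  structure(out, class = class(mfcc),
            frame_ms = attr(mfcc, "frame_ms"), hop_ms = attr(mfcc, "hop_ms"),
            sample_rate = attr(mfcc, "sample_rate"))
}

delta_regression <- function(m, width = 2L) {
  L <- nrow(m)
  denom <- 2 * sum(seq_len(width)^2)
  out <- matrix(0, L, ncol(m))
  for (n in seq_len(width)) {
    fwd <- pmin(L, seq_len(L) + n)   # replicate edge frames
    bwd <- pmax(1L, seq_len(L) - n)
    out <- out + n * (m[fwd, , drop = FALSE] - m[bwd, , drop = FALSE])
  }
  out / denom
}
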