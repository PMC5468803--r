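#' Labelled mono audio segment
#'
#' The basic container moved through the pipeline: a mono waveform in
#' `[-1, 1]` with its sample rate, an event class label, and an acoustic
#' condition tag. Event classes follow the corpus taxonomy: `human_fall`,
#' `object_fall:<subclass>` (e.g. `object_fall:book`), `human_activity`
#' and `music`.
#'
#' @param samples Numeric vector of samples; must be finite and within
#'   `[-1, 1]` (a tolerance of 1e-9 absorbs round-off).
#' @param sample_rate Sampling rate in Hz, positive scalar.
#' @param label Event class label string.
#' @param condition `"clean"` or `"noisy"`.
#' @param id Opaque identifier string.
#' @return An object of class `audio_segment`.
#' @export
audio_segment <- function(samples, sample_rate, label = "human_activity",
                          condition = c("clean", "noisy"), id = "seg") {
  condition <- match.arg(condition)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio_segment: empty sample vector")
  if (!all(is.finite(samples))) stop("audio_segment: non-finite samples")
  if (max(abs(samples)) > 1 + 1e-9) {
    stop("audio_segment: samples exceed full scale [-1, 1]")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("audio_segment: sample_rate must be a positive scalar")
  }
  structure(
    list(samples = pmin(1, pmax(-1, samples)), sample_rate = sample_rate,
         label = as.character(label), condition = condition,
         id = as.character(id)),
    class = "audio_segment"
  )
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment '%s'> %s/%s: %d samples @ %g Hz (%.3f s), peak %.3f\n",
              x$id, x$label, x$condition, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, max(abs(x$samples))))
  invisible(x)
}

#' @export
length.audio_segment <- function(x) length(x$samples)

is_fall_label <- function(label) label == "human_fall"

## ---- RIFF/PCM WAV I/O -------------------------------------------------
## Minimal canonical-form reader/writer for PCM WAV (8/16/24/32-bit int
## and 32-bit float). Chunk-walks the RIFF structure so files with extra
## chunks (LIST, fact, ...) still load.

#' Read a PCM WAV file
#'
#' Multichannel input is averaged to mono; integer samples are scaled to
#' `[-1, 1]` by the full-scale value of their bit depth.
#'
#' @param path Path to a RIFF/PCM WAV file.
#' @param label,condition,id Metadata attached to the returned segment;
#'   `id` defaults to the file name without extension.
#' @return An [audio_segment].
#' @export
load_wav <- function(path, label = "human_activity", condition = "clean",
                     id = NULL) {
  if (!file.exists(path)) stop("load_wav: file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("load_wav: not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("load_wav: not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    tag <- readChar(con, 4, useBytes = TRUE)
    if (length(tag) == 0L || nchar(tag) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(tag, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(body[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        rate     = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1, 2, endian = "little", signed = FALSE)
      )
    } else if (identical(tag, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L)) # chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw) || length(data_raw) == 0L) {
    stop("load_wav: missing fmt/data chunk or empty data: ", path)
  }
  if (!fmt$format %in% c(1L, 3L)) {
    stop("load_wav: unsupported WAV format code ", fmt$format)
  }

  x <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", length(data_raw), 1,
                               signed = FALSE)) - 128) / 128,
    "16" = as.numeric(readBin(data_raw, "integer", length(data_raw) %/% 2L, 2,
                              signed = TRUE, endian = "little")) / 32768,
    "24" = read_int24(data_raw) / 8388608,
    "32" = if (fmt$format == 3L) {
      as.numeric(readBin(data_raw, "double", length(data_raw) %/% 4L, 4,
                         endian = "little"))
    } else {
      as.numeric(readBin(data_raw, "integer", length(data_raw) %/% 4L, 4,
                         endian = "little")) / 2147483648
    },
    stop("load_wav: unsupported bit depth ", fmt$bits)
  )
  if (fmt$channels > 1L) {
    n <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n * fmt$channels)], nrow = fmt$channels))
  }
  if (length(x) == 0L) stop("load_wav: decoded zero samples: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  audio_segment(pmin(1, pmax(-1, x)), fmt$rate, label = label,
                condition = condition, id = id)
}

read_int24 <- function(raw) {
  n <- length(raw) %/% 3L
  m <- matrix(as.integer(raw[seq_len(n * 3L)]), nrow = 3L)
  v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
  ifelse(v >= 8388608, v - 16777216, v)
}

#' Write an audio segment as 16-bit PCM WAV
#'
#' @param seg An [audio_segment].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_wav <- function(seg, path) {
  stopifnot(inherits(seg, "audio_segment"))
  pcm <- as.integer(pmin(32767, pmax(-32768, round(seg$samples * 32768))))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(seg$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(seg$sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

## ---- standardisation --------------------------------------------------

#' Standardise a segment to the pipeline's sampling convention
#'
#' Resamples to `target_rate` (polyphase FIR with anti-aliasing via
#' [signal::resample]) and quantises to `bit_depth` bits
#' (round-to-nearest, clipped at full scale, no dither), then
#' renormalises to `[-1, 1]`. Idempotent on already-conforming input.
#' Upsampling is refused unless `allow_upsample = TRUE`, since raising
#' the rate fabricates no information and usually signals a mislabelled
#' input.
#'
#' @param seg An [audio_segment].
#' @param target_rate Target sampling rate in Hz (default 8000).
#' @param bit_depth Quantisation depth in bits (default 16).
#' @param allow_upsample Permit `target_rate` above the input rate.
#' @return An [audio_segment] at `target_rate`.
#' @export
standardize <- function(seg, target_rate = 8000, bit_depth = 16,
                        allow_upsample = FALSE) {
  stopifnot(inherits(seg, "audio_segment"))
  x <- seg$samples
  if (seg$sample_rate != target_rate) {
    if (target_rate > seg$sample_rate && !allow_upsample) {
      stop("standardize: refusing to upsample ", seg$sample_rate, " -> ",
           target_rate, " Hz (set allow_upsample = TRUE to override)")
    }
    fr <- rational_ratio(target_rate / seg$sample_rate)
    x <- signal::resample(x, fr[1], fr[2])
    n_expect <- round(length(seg$samples) * target_rate / seg$sample_rate)
    if (length(x) > n_expect) x <- x[seq_len(n_expect)]
    if (length(x) < n_expect) x <- c(x, rep(0, n_expect - length(x)))
  }
  full <- 2^(bit_depth - 1)
  q <- pmin(full - 1, pmax(-full, round(x * full)))
  audio_segment(q / full, target_rate, label = seg$label,
                condition = seg$condition, id = seg$id)
}

# small-denominator rational approximation of a rate ratio
rational_ratio <- function(r, max_den = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(p), q) }
    if (err < 1e-12) break
  }
  best
}

## ---- SNR mixing -------------------------------------------------------

#' Mix background into an event at a prescribed SNR
#'
#' The noise is looped or cropped to the event length and scaled so that
#' `10*log10(P_event / P_noise_scaled) == snr_db`; the mix is then peak
#' normalised if it exceeds full scale. `snr_db = Inf` returns the event
#' unchanged (clean condition preserved).
#'
#' @param event,noise [audio_segment]s at equal sample rates.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @return An [audio_segment] tagged `condition = "noisy"` (unless
#'   `snr_db = Inf`).
#' @export
mix_at_snr <- function(event, noise, snr_db = 0) {
  stopifnot(inherits(event, "audio_segment"), inherits(noise, "audio_segment"))
  if (is.infinite(snr_db) && snr_db > 0) return(event)
  if (event$sample_rate != noise$sample_rate) {
    stop("mix_at_snr: sample rates differ")
  }
  n <- length(event$samples)
  nz <- noise$samples
  if (length(nz) < n) nz <- rep_len(nz, n) else nz <- nz[seq_len(n)]
  p_e <- mean(event$samples^2)
  p_n <- mean(nz^2)
  if (p_e <= 0 || p_n <= 0) stop("mix_at_snr: silent event or noise, SNR undefined")
  scale <- sqrt(p_e / (p_n * 10^(snr_db / 10)))
  y <- event$samples + scale * nz
  peak <- max(abs(y))
  if (peak > 1) y <- y / peak
  audio_segment(y, event$sample_rate, label = event$label,
                condition = "noisy", id = paste0(event$id, "_n"))
}
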