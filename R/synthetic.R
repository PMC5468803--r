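## Parametric synthetic acoustic scenes. All classes are synthesised by
## DSP primitives (filtered impulses, pulse trains, harmonic stacks), so
## a seed fully determines every byte and no recordings are needed.
##
## The emulated corpus structure: human falls are impulsive events whose
## energy sits below 1 kHz (a floor-coupled sensor strongly low-passes
## structure-borne impacts); object falls are shorter, brighter impulses
## with a per-subclass resonance; background sounds are sustained
## footstep trains with speech-band noise, or harmonic music; noisy
## variants mix a background draw into an event at a configured SNR.

#' Synthetic scene configuration
#'
#' Defaults mirror the reference corpus layout at reduced training
#' scale: evaluation sets of 44 falls + 44 nonfalls (set 1: activity and
#' music; set 2: object falls; set 3: both), a normal-sound training
#' pool, an object-fall candidate pool and a background pool for
#' template construction. Event lengths are lognormal (median 0.8 s,
#' sigma 0.4 on the log scale); `duration_preset = "long"` switches to a
#' 1.7 s mean matching the corpus-level mean fall length.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param snr_db SNR (dB) at which backgrounds are mixed into events for
#'   the noisy condition; 0 dB (equal power) by default.
#' @param object_similarity In `[0, 1]`: how far object-fall resonances
#'   are pulled toward the human-fall band (1 = maximally confusable).
#' @param duration_preset `"short"` (median 0.8 s) or `"long"` (mean
#'   1.7 s).
#' @param train_counts Named counts of training-pool classes.
#' @param object_pool_n,background_pool_n Template candidate pool sizes.
#' @param scale Multiplier applied to all set/pool counts (folds need at
#'   least 4 falls and 4 nonfalls per set).
#' @param seed Integer seed; the corpus is bit-reproducible given it.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(sample_rate = 8000, snr_db = 0,
                         object_similarity = 0.5,
                         duration_preset = c("short", "long"),
                         train_counts = c(human_activity = 32, music = 63),
                         object_pool_n = 37, background_pool_n = 47,
                         scale = 1, seed = 1L) {
  duration_preset <- match.arg(duration_preset)
  stopifnot(sample_rate > 0, object_similarity >= 0, object_similarity <= 1,
            scale > 0, all(train_counts >= 0))
  dur <- if (duration_preset == "short") {
    c(meanlog = log(0.8), sdlog = 0.4)
  } else {
    c(meanlog = log(1.7) - 0.4^2 / 2, sdlog = 0.4)
  }
  structure(list(sample_rate = sample_rate, snr_db = snr_db,
                 object_similarity = object_similarity,
                 duration_meanlog = unname(dur["meanlog"]),
                 duration_sdlog = unname(dur["sdlog"]),
                 train_counts = train_counts,
                 object_pool_n = object_pool_n,
                 background_pool_n = background_pool_n,
                 scale = scale, seed = as.integer(seed)),
            class = "scene_config")
}

object_subclasses <- c("basket", "fork", "ball", "book", "bag", "chair")

# per-subclass resonance (Hz) and decay (s) of the clean object profiles
object_profiles <- data.frame(
  subclass = object_subclasses,
  freq = c(850, 2200, 420, 700, 550, 1050),
  decay = c(0.05, 0.12, 0.08, 0.03, 0.025, 0.06)
)

rand_duration <- function(cfg, min_s = 0.3, max_s = 3) {
  min(max_s, max(min_s, stats::rlnorm(1, cfg$duration_meanlog, cfg$duration_sdlog)))
}

# one decaying-resonance impact: excitation burst through exponentially
# damped sinusoids plus a low-passed noise thump
impact <- function(n, fs, freqs, decays, noise_lp = 600, amp = 1) {
  t <- seq_len(n) / fs
  x <- numeric(n)
  for (k in seq_along(freqs)) {
    x <- x + stats::runif(1, 0.5, 1) * sin(2 * pi * freqs[k] * t + stats::runif(1, 0, 2 * pi)) *
      exp(-t / decays[k])
  }
  burst_n <- max(8L, round(0.01 * fs))
  burst <- stats::rnorm(n) * exp(-t / (decays[1] / 2))
  bf <- signal::butter(4, min(0.99, noise_lp / (fs / 2)), type = "low")
  burst <- signal::filter(bf, burst)
  amp * (x + 0.4 * as.numeric(burst) / max(abs(burst), 1e-12))
}

peak_normalize <- function(x, peak) {
  m <- max(abs(x))
  if (m < 1e-12) return(x)
  x / m * peak
}

#' Generate one synthetic acoustic event
#'
#' Classes: `"human_fall"`, `"object_fall:<subclass>"` with subclasses
#' basket, fork, ball, book, bag, chair, `"human_activity"`, `"music"`.
#' Human falls are built so that at least 80% of their spectral energy
#' lies below 1 kHz — the defining property of floor-coupled fall
#' signatures that the generator contracts to reproduce.
#'
#' @param class Event class label.
#' @param cfg A [scene_config].
#' @param id Identifier for the resulting segment.
#' @param seed Optional seed; when NULL the current RNG stream is used
#'   (so [gen_corpus] draws a reproducible sequence).
#' @return An [audio_segment] at `cfg$sample_rate`, condition `"clean"`.
#' @export
gen_event <- function(class, cfg = scene_config(), id = class, seed = NULL) {
  gen <- function() {
    fs <- cfg$sample_rate
    dur <- rand_duration(cfg)
    n <- round(dur * fs)
    cls <- sub(":.*$", "", class)
    x <- switch(cls,
      human_fall = {
        # primary body impact + optional secondary (limb) impact
        f1 <- stats::runif(1, 70, 180); f2 <- stats::runif(1, 180, 340)
        x <- impact(n, fs, c(f1, f2), c(stats::runif(1, 0.06, 0.14),
                                        stats::runif(1, 0.03, 0.08)))
        if (stats::runif(1) < 0.7) {
          lag <- round(stats::runif(1, 0.08, 0.2) * fs)
          if (lag < n - 16) {
            sec <- impact(n - lag, fs, stats::runif(1, 90, 300),
                          stats::runif(1, 0.03, 0.08), amp = stats::runif(1, 0.3, 0.7))
            x[(lag + 1):n] <- x[(lag + 1):n] + sec
          }
        }
        x
      },
      object_fall = {
        sub <- sub("^object_fall:?", "", class)
        if (!sub %in% object_profiles$subclass) sub <- "book"
        p <- object_profiles[object_profiles$subclass == sub, ]
        # similarity dial drags the resonance toward the human-fall band
        f <- p$freq * (220 / p$freq)^cfg$object_similarity
        n <- max(round(n * 0.5), round(0.2 * fs))  # objects ring shorter
        x <- impact(n, fs, c(f, f * stats::runif(1, 1.4, 1.9)),
                    c(p$decay, p$decay / 2),
                    noise_lp = min(3500, 2 * f))
        if (stats::runif(1) < 0.5) {  # bounce
          lag <- round(stats::runif(1, 0.05, 0.12) * fs)
          if (lag < n - 16) {
            x[(lag + 1):n] <- x[(lag + 1):n] +
              impact(n - lag, fs, f * stats::runif(1, 0.9, 1.1), p$decay / 2,
                     noise_lp = min(3500, 2 * f), amp = 0.5)
          }
        }
        x
      },
      human_activity = {
        t <- seq_len(n) / fs
        # footsteps: low thumps at walking rate
        steps <- numeric(n)
        period <- stats::runif(1, 0.4, 0.7)
        t0 <- stats::runif(1, 0, period / 2)
        while (t0 < dur) {
          i0 <- round(t0 * fs) + 1L
          len <- min(n - i0 + 1L, round(0.12 * fs))
          if (len > 16) {
            steps[i0:(i0 + len - 1L)] <- steps[i0:(i0 + len - 1L)] +
              impact(len, fs, stats::runif(1, 60, 140), 0.03,
                     amp = stats::runif(1, 0.2, 0.45))
          }
          t0 <- t0 + period * stats::runif(1, 0.85, 1.15)
        }
        # speech-band modulated noise
        bf <- signal::butter(4, c(300, 2500) / (fs / 2), type = "pass")
        sp <- as.numeric(signal::filter(bf, stats::rnorm(n)))
        sp <- sp / max(abs(sp), 1e-12)
        envl <- 0.55 + 0.45 * sin(2 * pi * stats::runif(1, 3, 7) * t +
                                  stats::runif(1, 0, 2 * pi))
        steps + 0.5 * sp * envl
      },
      music = {
        t <- seq_len(n) / fs
        x <- numeric(n)
        root <- stats::runif(1, 110, 330)
        change <- n %/% 2L
        for (half in 1:2) {
          idx <- if (half == 1) seq_len(change) else (change + 1L):n
          if (length(idx) < 8L) next
          f0 <- root * if (half == 1) 1 else stats::runif(1, 0.8, 1.3)
          for (h in 1:5) {
            vib <- 1 + 0.002 * sin(2 * pi * 5 * t[idx])
            x[idx] <- x[idx] + (1 / h) * sin(2 * pi * h * f0 * vib * t[idx] +
                                             stats::runif(1, 0, 2 * pi))
          }
        }
        x * (0.8 + 0.2 * sin(2 * pi * stats::runif(1, 0.5, 2) * t))
      },
      stop("gen_event: unknown class ", class)
    )
    x <- x + 1e-4 * stats::rnorm(length(x))   # sensor noise floor
    audio_segment(peak_normalize(x, stats::runif(1, 0.35, 0.6)), fs,
                  label = class, condition = "clean", id = id)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# composition tables of the three evaluation-set analogues
set_composition <- function(scale) {
  ct <- function(x) pmax(ifelse(x > 0, 1, 0), round(x * scale))
  list(
    set1 = c(human_fall = ct(44), human_activity = ct(15), music = ct(29)),
    set2 = c(human_fall = ct(44),
             stats::setNames(ct(c(7, 7, 8, 7, 8, 7)),
                             paste0("object_fall:", object_subclasses))),
    set3 = c(human_fall = ct(44),
             stats::setNames(ct(c(3, 4, 4, 3, 4, 4)),
                             paste0("object_fall:", object_subclasses)),
             human_activity = ct(8), music = ct(14))
  )
}

expand_counts <- function(counts) rep(names(counts), counts)

#' Generate a full synthetic corpus
#'
#' Produces the training pool (background sounds only), the three
#' evaluation-set analogues in clean and noisy variants, and the
#' template candidate pools (object falls; background sounds). Noisy
#' variants mix each event with a freshly drawn background at
#' `cfg$snr_db`.
#'
#' @param cfg A [scene_config].
#' @param out_dir Optional directory; when given, WAV files and a
#'   `manifest.csv` (columns id, path, label, condition, part) are
#'   written there.
#' @return A list with elements `train` (list of segments), `sets`
#'   (each with `clean`, `noisy`, `manifest`), `object_pool`,
#'   `background_pool` (each with `clean`, `noisy`), and `config`.
#' @export
gen_corpus <- function(cfg = scene_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, {
    mk_events <- function(labels, prefix) {
      lapply(seq_along(labels), function(i) {
        gen_event(labels[i], cfg, id = sprintf("%s_%03d_%s", prefix, i,
                                               sub(":.*$", "", labels[i])))
      })
    }
    background_draw <- function(id) {
      gen_event(sample(c("human_activity", "music"), 1L), cfg, id = id)
    }
    noisy_of <- function(segs, prefix) {
      lapply(seq_along(segs), function(i) {
        mix_at_snr(segs[[i]], background_draw(sprintf("%s_bg_%03d", prefix, i)),
                   cfg$snr_db)
      })
    }

    train_scale <- round(cfg$train_counts * cfg$scale)
    train_scale[train_scale < 1] <- 1
    train <- mk_events(expand_counts(train_scale), "train")

    comp <- set_composition(cfg$scale)
    sets <- lapply(names(comp), function(sname) {
      labels <- expand_counts(comp[[sname]])
      clean <- mk_events(labels, sname)
      noisy <- noisy_of(clean, sname)
      manifest <- data.frame(
        id = vapply(clean, `[[`, "", "id"),
        label = labels,
        is_fall = is_fall_label(labels),
        stringsAsFactors = FALSE)
      list(clean = clean, noisy = noisy, manifest = manifest)
    })
    names(sets) <- names(comp)

    n_obj <- max(1, round(cfg$object_pool_n * cfg$scale))
    obj_labels <- paste0("object_fall:",
                         rep_len(object_subclasses, n_obj))
    object_clean <- mk_events(obj_labels, "objpool")
    n_bg <- max(1, round(cfg$background_pool_n * cfg$scale))
    bg_labels <- rep_len(c("human_activity", "music", "music"), n_bg)
    background_clean <- mk_events(bg_labels, "bgpool")

    corpus <- list(
      train = train, sets = sets,
      object_pool = list(clean = object_clean,
                         noisy = noisy_of(object_clean, "objpool")),
      background_pool = list(clean = background_clean,
                             noisy = noisy_of(background_clean, "bgpool")),
      config = cfg)

    if (!is.null(out_dir)) write_corpus(corpus, out_dir)
    corpus
  })
}

# write all corpus WAVs plus a manifest CSV
write_corpus <- function(corpus, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  emit <- function(segs, part) {
    for (s in segs) {
      fn <- file.path(out_dir, paste0(s$id, "_", s$condition, ".wav"))
      save_wav(s, fn)
      rows[[length(rows) + 1L]] <<- data.frame(
        id = s$id, path = basename(fn), label = s$label,
        condition = s$condition, part = part, stringsAsFactors = FALSE)
    }
  }
  emit(corpus$train, "train")
  for (sname in names(corpus$sets)) {
    emit(corpus$sets[[sname]]$clean, sname)
    emit(corpus$sets[[sname]]$noisy, sname)
  }
  emit(corpus$object_pool$clean, "object_pool")
  emit(corpus$object_pool$noisy, "object_pool")
  emit(corpus$background_pool$clean, "background_pool")
  emit(corpus$background_pool$noisy, "background_pool")
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Fraction of spectral energy below a cutoff frequency
#'
#' @param seg An [audio_segment].
#' @param cutoff_hz Cutoff in Hz (default 1000).
#' @return Scalar in `[0, 1]`.
#' @export
spectral_energy_below <- function(seg, cutoff_hz = 1000) {
  x <- seg$samples - mean(seg$samples)
  p <- abs(stats::fft(x))^2
  n <- length(x)
  half <- p[seq_len(n %/% 2L + 1L)]
  freqs <- (seq_along(half) - 1L) * seg$sample_rate / n
  sum(half[freqs <= cutoff_hz]) / sum(half)
}
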