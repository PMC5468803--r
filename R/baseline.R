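## Windowed frame-level comparison method: the event's 39-D feature
## sequence is cut into 71-frame windows with 50% overlap, each window
## is screened by a one-class SVM trained directly on window statistics
## (no supervectors), and the event is a fall iff at least two
## consecutive windows are flagged as novelty.

#' Windowed baseline configuration
#'
#' @param window_frames Window length in frames (default 71, i.e.
#'   576 ms at 16 ms frames / 8 ms hop).
#' @param overlap_fraction Fractional window overlap in `[0, 1)`.
#' @param min_consecutive_novel Consecutive novel windows required to
#'   call a fall.
#' @return A list of class `baseline_config`.
#' @export
baseline_config <- function(window_frames = 71L, overlap_fraction = 0.5,
                            min_consecutive_novel = 2L) {
  stopifnot(window_frames >= 1L, overlap_fraction >= 0, overlap_fraction < 1,
            min_consecutive_novel >= 1L)
  structure(list(window_frames = as.integer(window_frames),
                 overlap_fraction = overlap_fraction,
                 min_consecutive_novel = as.integer(min_consecutive_novel)),
            class = "baseline_config")
}

# start indices of sliding windows; events shorter than one window get a
# single truncated window
baseline_window_starts <- function(L, cfg) {
  hop <- max(1L, as.integer(floor(cfg$window_frames * (1 - cfg$overlap_fraction))))
  if (L < cfg$window_frames) {
    return(list(starts = 1L, length = as.integer(L), hop = hop))
  }
  n <- (L - cfg$window_frames) %/% hop + 1L
  list(starts = (seq_len(n) - 1L) * hop + 1L, length = cfg$window_frames, hop = hop)
}

# per-window summary fed to the OCSVM: the mean frame vector
window_stat <- function(m, start, len) {
  colMeans(m[start:(start + len - 1L), , drop = FALSE])
}

#' Train the baseline window-level novelty model
#'
#' @param normal List of [audio_segment]s of normal sounds.
#' @param features A [feature_config]; 13 static + deltas are used.
#' @param nu,gamma One-class SVM hyperparameters.
#' @param cfg A [baseline_config].
#' @param seed Unused (the solver is deterministic); kept for interface
#'   symmetry.
#' @return An `ocsvm_model` over window-mean vectors, with the
#'   configurations attached as attributes.
#' @export
train_baseline <- function(normal, features = feature_config(),
                           nu = 0.3, gamma = 2^-7, cfg = baseline_config(),
                           seed = 1L) {
  stats_list <- lapply(normal, function(s) {
    m <- unclass(append_deltas(extract_mfcc(s, features), features$delta_width))
    w <- baseline_window_starts(nrow(m), cfg)
    t(vapply(w$starts, function(st) window_stat(m, st, w$length),
             numeric(ncol(m))))
  })
  X <- do.call(rbind, stats_list)
  model <- train_ocsvm(X, nu = nu, gamma = gamma, seed = seed)
  attr(model, "baseline_config") <- cfg
  attr(model, "feature_config") <- features
  model
}

#' Run-length decision over a novelty pattern
#'
#' @param novel Logical vector: is each window novel?
#' @param min_consecutive Required run length.
#' @return TRUE iff some run of novel windows reaches `min_consecutive`.
#' @export
consecutive_novelty <- function(novel, min_consecutive = 2L) {
  if (length(novel) == 0L) return(FALSE)
  r <- rle(as.logical(novel))
  any(r$values & r$lengths >= min_consecutive)
}

#' Windowed baseline fall decision for one event
#'
#' @param mfcc 39-column feature matrix of the event (frames in rows).
#' @param ocsvm_frames `ocsvm_model` trained on window-mean vectors.
#' @param cfg A [baseline_config].
#' @return A list with `label` (`"fall"`/`"nonfall"`), the per-window
#'   logical `novel` vector and the window `starts`.
#' @export
windowed_detect <- function(mfcc, ocsvm_frames, cfg = baseline_config()) {
  m <- unclass(mfcc)
  if (is.null(dim(m)) || nrow(m) == 0L) stop("windowed_detect: empty feature matrix")
  w <- baseline_window_starts(nrow(m), cfg)
  X <- t(vapply(w$starts, function(st) window_stat(m, st, w$length),
                numeric(ncol(m))))
  novel <- ocsvm_decision(ocsvm_frames, X)$sign == -1L
  fall <- consecutive_novelty(novel, cfg$min_consecutive_novel)
  list(label = if (fall) "fall" else "nonfall", novel = novel,
       starts = w$starts)
}
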