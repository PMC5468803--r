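## Template-matching refinement stage: a set of supervector templates
## representing known false-positive sounds. An abnormal event is kept
## as a fall only if its minimum Euclidean distance to the template set
## exceeds the threshold beta; otherwise the templates veto the alarm.

#' Construct a template set
#'
#' @param templates Numeric matrix of template supervectors (rows), or
#'   NULL for an empty set.
#' @param labels Per-template class labels.
#' @param origin Per-template provenance, `"a-priori"` or `"user-marked"`.
#' @param beta Nonnegative decision threshold (may be set later by
#'   [select_threshold]).
#' @param config_hash Hash binding the set to the feature/UBM
#'   configuration it was built against.
#' @return Object of class `template_set`.
#' @export
template_set <- function(templates = NULL, labels = character(0),
                         origin = character(0), beta = 0,
                         config_hash = NA_character_) {
  if (is.null(templates)) {
    templates <- matrix(numeric(0), nrow = 0, ncol = 0)
  } else {
    templates <- as.matrix(templates)
  }
  n <- nrow(templates)
  if (length(labels) == 0L) labels <- rep(NA_character_, n)
  if (length(origin) == 0L) origin <- rep("a-priori", n)
  stopifnot(length(labels) == n, length(origin) == n, beta >= 0)
  structure(list(templates = templates, labels = as.character(labels),
                 origin = as.character(origin), beta = beta,
                 config_hash = config_hash),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> N = %d templates, beta = %.6g\n",
              nrow(x$templates), x$beta))
  if (nrow(x$templates) > 0) {
    tab <- table(x$labels, x$origin)
    print(tab)
  }
  invisible(x)
}

#' Minimum Euclidean distance from a query to the template set
#'
#' Ties resolve to the lowest template index.
#'
#' @param x Query supervector.
#' @param ts A `template_set` with at least one template.
#' @return List with `d_min` and `index` of the nearest template.
#' @export
min_distance <- function(x, ts) {
  stopifnot(inherits(ts, "template_set"))
  if (nrow(ts$templates) == 0L) stop("min_distance: empty template set")
  x <- as.numeric(x)
  if (length(x) != ncol(ts$templates)) stop("min_distance: dimension mismatch")
  d2 <- rowSums(sweep(ts$templates, 2, x)^2)
  i <- which.min(d2)   # which.min returns the first (lowest-index) minimum
  list(d_min = sqrt(d2[i]), index = i)
}

#' Template-matching decision rule
#'
#' Strict inequality: `fall` iff `d_min > beta`; `d_min == beta` is a
#' nonfall (the templates win the tie).
#'
#' @param d_min Minimum distance from [min_distance].
#' @param beta Decision threshold.
#' @return `"fall"` or `"nonfall"`.
#' @export
template_decision <- function(d_min, beta) {
  if (d_min > beta) "fall" else "nonfall"
}

#' Select the decision threshold at the density intersection
#'
#' Estimates Gaussian kernel densities (Scott's-rule bandwidth) of the
#' fall and nonfall minimum-distance samples on a common 512-point grid
#' spanning the pooled range plus three bandwidths, and returns the grid
#' point where the nonfall density crosses below the fall density. With
#' several crossings, the one closest to the midpoint of the two sample
#' medians is taken; with none, the midpoint of the sample means is
#' returned with a warning.
#'
#' @param fall_dists,nonfall_dists Minimum distances of validation fall
#'   and nonfall events to the template set.
#' @param n_grid Grid resolution.
#' @return Scalar threshold beta.
#' @export
select_threshold <- function(fall_dists, nonfall_dists, n_grid = 512L) {
  fall_dists <- as.numeric(fall_dists); nonfall_dists <- as.numeric(nonfall_dists)
  if (length(fall_dists) == 0L || length(nonfall_dists) == 0L) {
    stop("select_threshold: both distance samples must be non-empty")
  }
  if (length(fall_dists) == length(nonfall_dists) &&
      isTRUE(all.equal(sort(fall_dists), sort(nonfall_dists)))) {
    stop("select_threshold: fall and nonfall samples are identical")
  }
  if (stats::median(fall_dists) <= stats::median(nonfall_dists)) {
    warning("select_threshold: fall distances are not stochastically larger than nonfall distances")
  }
  bw_f <- scott_bw(fall_dists)
  bw_n <- scott_bw(nonfall_dists)
  pad <- 3 * max(bw_f, bw_n)
  lo <- min(fall_dists, nonfall_dists) - pad
  hi <- max(fall_dists, nonfall_dists) + pad
  df <- stats::density(fall_dists, bw = bw_f, from = lo, to = hi, n = n_grid)
  dn <- stats::density(nonfall_dists, bw = bw_n, from = lo, to = hi, n = n_grid)
  grid <- df$x
  diff_sign <- sign(dn$y - df$y)       # + where nonfall density dominates
  cross <- which(diff_sign[-length(diff_sign)] > 0 & diff_sign[-1] <= 0)
  if (length(cross) == 0L) {
    warning("select_threshold: densities do not cross on the grid; using mean midpoint")
    return((mean(fall_dists) + mean(nonfall_dists)) / 2)
  }
  beta_cands <- grid[cross + 1L]
  mid <- (stats::median(fall_dists) + stats::median(nonfall_dists)) / 2
  beta_cands[which.min(abs(beta_cands - mid))]
}

# Scott's rule bandwidth; falls back to a small positive width for
# degenerate (near-constant) samples
scott_bw <- function(x) {
  bw <- tryCatch(stats::bw.nrd(x), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- max(1e-3, 1e-3 * abs(mean(x)))
  bw
}

#' Build object-fall templates from stage-1 false alarms
#'
#' Runs the trained novelty detector over a pool of labelled nonfall
#' candidates and keeps exactly those flagged abnormal — the events the
#' first stage would misclassify as falls.
#'
#' @param candidates Matrix of candidate supervectors (rows).
#' @param labels Per-candidate subclass labels.
#' @param stage1 Trained `ocsvm_model`.
#' @param beta Threshold stored on the resulting set.
#' @param config_hash Configuration hash to stamp on the set.
#' @return A `template_set` (possibly empty).
#' @export
build_object_templates <- function(candidates, labels, stage1, beta = 0,
                                   config_hash = NA_character_) {
  candidates <- as.matrix(candidates)
  if (length(labels) != nrow(candidates)) stop("build_object_templates: label length mismatch")
  keep <- ocsvm_decision(stage1, candidates)$sign == -1L
  template_set(candidates[keep, , drop = FALSE], labels = labels[keep],
               origin = rep("a-priori", sum(keep)), beta = beta,
               config_hash = config_hash)
}

#' Build background templates by nearest-pool selection
#'
#' For each development event the closest item of a background pool
#' (Euclidean distance on supervectors) is added to the set; duplicate
#' selections (exact vector equality) are kept once.
#'
#' @param dev_events Matrix of development-set supervectors (rows).
#' @param background_pool Matrix of background supervectors (rows).
#' @param pool_labels Labels of the pool items.
#' @param beta,config_hash As in [build_object_templates].
#' @return A `template_set`.
#' @export
build_background_templates <- function(dev_events, background_pool,
                                       pool_labels = NULL, beta = 0,
                                       config_hash = NA_character_) {
  dev_events <- as.matrix(dev_events)
  background_pool <- as.matrix(background_pool)
  if (nrow(dev_events) == 0L || nrow(background_pool) == 0L) {
    stop("build_background_templates: empty input set")
  }
  if (is.null(pool_labels)) pool_labels <- rep("background", nrow(background_pool))
  sel <- integer(nrow(dev_events))
  for (i in seq_len(nrow(dev_events))) {
    d2 <- rowSums(sweep(background_pool, 2, dev_events[i, ])^2)
    sel[i] <- which.min(d2)
  }
  sel <- unique(sel)
  tpl <- background_pool[sel, , drop = FALSE]
  dup <- duplicated(apply(tpl, 1, paste, collapse = "\r"))
  template_set(tpl[!dup, , drop = FALSE], labels = pool_labels[sel][!dup],
               origin = rep("a-priori", sum(!dup)), beta = beta,
               config_hash = config_hash)
}

#' Add one template to a set
#'
#' The threshold beta is deliberately left unchanged; re-selection is an
#' explicit separate step.
#'
#' @param ts A `template_set`.
#' @param x Supervector to add.
#' @param label Class label of the new template.
#' @param origin Provenance tag, default `"user-marked"`.
#' @return The grown `template_set`.
#' @export
add_template <- function(ts, x, label = NA_character_, origin = "user-marked") {
  stopifnot(inherits(ts, "template_set"))
  x <- as.numeric(x)
  if (nrow(ts$templates) > 0L) {
    if (length(x) != ncol(ts$templates)) stop("add_template: dimension mismatch")
    if (any(apply(ts$templates, 1, function(r) isTRUE(all.equal(r, x, check.attributes = FALSE))))) {
      stop("add_template: duplicate template rejected")
    }
    tpl <- rbind(ts$templates, x)
  } else {
    tpl <- matrix(x, nrow = 1)
  }
  rownames(tpl) <- NULL
  template_set(tpl, labels = c(ts$labels, label),
               origin = c(ts$origin, origin), beta = ts$beta,
               config_hash = ts$config_hash)
}
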