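## Two-stage cascade: OCSVM novelty screening over supervectors,
## followed by template-matching veto of known false-positive sounds.
## Stage 1 can only raise alarms; the template stage can only veto them.

# md5 of a canonical deparse; binds features <-> UBM <-> OCSVM <-> templates
config_hash <- function(...) {
  obj <- lapply(list(...), function(x) {
    if (is.numeric(x)) signif(x, 12) else x
  })
  txt <- paste(deparse(obj, control = "exact"), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

feature_hash <- function(cfg, J, relevance) {
  config_hash(unclass(cfg), J = J, relevance = relevance)
}

segment_supervector <- function(seg, ubm, cfg, relevance) {
  compute_gms(ubm, append_deltas(extract_mfcc(seg, cfg), cfg$delta_width),
              relevance)
}

#' Fit the two-stage acoustic fall detector
#'
#' Trains the full cascade from labelled audio segments:
#' \enumerate{
#'   \item MFCC + delta features are extracted from the normal-sound
#'     pool and pooled to train the diagonal-GMM background model by EM;
#'   \item each normal event is embedded as a Gaussian Mean Supervector
#'     and a one-class SVM is fitted to them;
#'   \item object-fall templates are the candidate events the stage-1
#'     model misclassifies as abnormal; background templates are the
#'     pool items nearest to the validation events;
#'   \item the veto threshold beta is selected at the intersection of
#'     the fall / nonfall minimum-distance densities of the validation
#'     events (skipped if no validation data, in which case `beta` must
#'     be given).
#' }
#'
#' @param normal List of [audio_segment]s of normal sounds (activity,
#'   music) for UBM and OCSVM training.
#' @param object_candidates Optional list of nonfall candidate segments
#'   for a-priori object templates.
#' @param background_pool Optional list of background segments for
#'   nearest-pool templates (requires `validation`).
#' @param validation Optional list of labelled segments used for
#'   background-template selection and threshold selection.
#' @param J Number of UBM components.
#' @param nu,gamma One-class SVM hyperparameters.
#' @param relevance MAP relevance factor.
#' @param beta Veto threshold used if no validation data is supplied.
#' @param features A [feature_config].
#' @param seed Integer seed for the EM initialisation.
#' @return An object of class `fall_detector` containing `ubm`, `ocsvm`,
#'   `templates`, the feature configuration and the binding hash.
#' @export
fall_detector <- function(normal, object_candidates = NULL,
                          background_pool = NULL, validation = NULL,
                          J = 8, nu = 0.3, gamma = 2^-7, relevance = 16,
                          beta = 0, features = feature_config(), seed = 1L) {
  stopifnot(length(normal) >= 2L)
  feats <- lapply(normal, function(s) append_deltas(extract_mfcc(s, features),
                                                    features$delta_width))
  pool <- do.call(rbind, lapply(feats, unclass))
  ubm <- train_ubm(pool, J = J, seed = seed)
  hash <- feature_hash(features, J, relevance)
  sv_train <- t(vapply(feats, function(f) compute_gms(ubm, f, relevance),
                       numeric(ubm$D * ubm$J)))
  ocsvm <- train_ocsvm(sv_train, nu = nu, gamma = gamma, seed = seed)

  tpl <- template_set(beta = beta, config_hash = hash)
  if (!is.null(object_candidates) && length(object_candidates) > 0L) {
    cand <- t(vapply(object_candidates,
                     function(s) segment_supervector(s, ubm, features, relevance),
                     numeric(ubm$D * ubm$J)))
    obj_tpl <- build_object_templates(cand,
                                      labels = vapply(object_candidates, `[[`, "", "label"),
                                      stage1 = ocsvm, beta = beta,
                                      config_hash = hash)
    for (i in seq_len(nrow(obj_tpl$templates))) {
      tpl <- add_template(tpl, obj_tpl$templates[i, ],
                          label = obj_tpl$labels[i], origin = "a-priori")
    }
  }
  val_sv <- NULL
  if (!is.null(validation) && length(validation) > 0L) {
    val_sv <- t(vapply(validation,
                       function(s) segment_supervector(s, ubm, features, relevance),
                       numeric(ubm$D * ubm$J)))
  }
  if (!is.null(background_pool) && length(background_pool) > 0L &&
      !is.null(val_sv)) {
    bg <- t(vapply(background_pool,
                   function(s) segment_supervector(s, ubm, features, relevance),
                   numeric(ubm$D * ubm$J)))
    bg_tpl <- build_background_templates(val_sv, bg,
                                         pool_labels = vapply(background_pool, `[[`, "", "label"),
                                         beta = beta, config_hash = hash)
    for (i in seq_len(nrow(bg_tpl$templates))) {
      tpl <- tryCatch(add_template(tpl, bg_tpl$templates[i, ],
                                   label = bg_tpl$labels[i], origin = "a-priori"),
                      error = function(e) tpl)  # skip exact duplicates
    }
  }
  if (!is.null(val_sv) && nrow(tpl$templates) > 0L) {
    lab <- vapply(validation, `[[`, "", "label")
    dmin <- apply(val_sv, 1, function(v) min_distance(v, tpl)$d_min)
    is_fall <- is_fall_label(lab)
    if (any(is_fall) && any(!is_fall)) {
      tpl$beta <- select_threshold(dmin[is_fall], dmin[!is_fall])
    }
  }

  structure(list(ubm = ubm, ocsvm = ocsvm, templates = tpl,
                 features = features, relevance = relevance,
                 J = J, nu = nu, gamma = gamma,
                 config_hash = hash, seed = seed),
            class = "fall_detector")
}

#' Run the cascade on one audio segment
#'
#' Features -> supervector -> stage-1 novelty decision; only if the
#' event is abnormal is the template distance evaluated. Stage 1 saying
#' "normal" is final (templates veto alarms, never promote them).
#'
#' @param seg An [audio_segment].
#' @param detector A fitted [fall_detector], or NULL if `ubm`, `ocsvm`
#'   and `ts` are given separately.
#' @param ubm,ocsvm,ts,cfg,relevance Individual stage models (used when
#'   `detector` is NULL); `ts` must carry a matching `config_hash`.
#' @return A one-row `data.frame` (class `detection`) with columns
#'   `id`, `stage1_sign`, `stage1_margin`, `d_min` (NA when stage 1 says
#'   normal) and `final_label`.
#' @export
detect <- function(seg, detector = NULL, ubm = NULL, ocsvm = NULL, ts = NULL,
                   cfg = NULL, relevance = 16) {
  if (!is.null(detector)) {
    stopifnot(inherits(detector, "fall_detector"))
    ubm <- detector$ubm; ocsvm <- detector$ocsvm; ts <- detector$templates
    cfg <- detector$features; relevance <- detector$relevance
    expected <- detector$config_hash
  } else {
    expected <- feature_hash(cfg, ubm$J, relevance)
  }
  if (!is.na(ts$config_hash) && !identical(ts$config_hash, expected)) {
    stop("detect: template set was built against a different feature/UBM configuration")
  }
  sv <- segment_supervector(seg, ubm, cfg, relevance)
  s1 <- ocsvm_decision(ocsvm, sv)
  d_min <- NA_real_
  if (s1$sign == -1L && nrow(ts$templates) > 0L) {
    d_min <- min_distance(sv, ts)$d_min
    final <- template_decision(d_min, ts$beta)
  } else if (s1$sign == -1L) {
    final <- "fall"   # no templates: every stage-1 alarm passes through
  } else {
    final <- "nonfall"
  }
  out <- data.frame(id = seg$id, stage1_sign = s1$sign,
                    stage1_margin = s1$margin, d_min = d_min,
                    final_label = final, stringsAsFactors = FALSE)
  attr(out, "supervector") <- sv
  class(out) <- c("detection", class(out))
  out
}

#' User feedback on a raised alarm
#'
#' Closes the user-aided loop: when the user marks a detected fall as a
#' false positive, the event's supervector becomes a new user-marked
#' template, so replays of the same sound are vetoed. True positives
#' leave the set untouched; calling this on a nonfall detection is a
#' warned no-op.
#'
#' @param det A `detection` row from [detect].
#' @param truth Ground truth from the user: `"fall"` or `"nonfall"`.
#' @param ts The current `template_set`.
#' @return The (possibly grown) `template_set`.
#' @export
user_feedback <- function(det, truth = c("fall", "nonfall"), ts) {
  truth <- match.arg(truth)
  if (!identical(det$final_label, "fall")) {
    warning("user_feedback: detection was not a fall; template set unchanged")
    return(ts)
  }
  if (truth == "fall") return(ts)
  sv <- attr(det, "supervector")
  if (is.null(sv)) stop("user_feedback: detection carries no supervector")
  add_template(ts, sv, label = "user", origin = "user-marked")
}

#' @export
print.fall_detector <- function(x, ...) {
  cat("Two-stage acoustic fall detector\n")
  cat(sprintf("  features : %d MFCC + deltas (D = %d), frame %g ms / hop %g ms\n",
              x$features$n_cepstra, 3 * x$features$n_cepstra,
              x$features$frame_ms, x$features$hop_ms))
  cat(sprintf("  UBM      : J = %d components (relevance r = %g)\n",
              x$J, x$relevance))
  cat(sprintf("  OCSVM    : nu = %g, gamma = %g, %d SVs\n",
              x$nu, x$gamma, nrow(x$ocsvm$sv)))
  cat(sprintf("  templates: N = %d, beta = %.6g\n",
              nrow(x$templates$templates), x$templates$beta))
  invisible(x)
}

#' @export
summary.fall_detector <- function(object, ...) {
  out <- list(
    J = object$J, nu = object$nu, gamma = object$gamma,
    relevance = object$relevance,
    supervector_dim = object$ubm$D * object$ubm$J,
    n_support_vectors = nrow(object$ocsvm$sv),
    n_templates = nrow(object$templates$templates),
    template_classes = table(object$templates$labels),
    beta = object$templates$beta,
    em_iterations = length(object$ubm$loglik_trace),
    config_hash = object$config_hash
  )
  class(out) <- "summary.fall_detector"
  out
}

#' @export
print.summary.fall_detector <- function(x, ...) {
  cat(sprintf("fall_detector: supervector dim %d (J = %d), OCSVM nu = %g gamma = %g\n",
              x$supervector_dim, x$J, x$nu, x$gamma))
  cat(sprintf("  %d support vectors, %d templates, beta = %.6g, EM iterations %d\n",
              x$n_support_vectors, x$n_templates, x$beta, x$em_iterations))
  if (length(x$template_classes)) {
    cat("  templates by class:\n")
    print(x$template_classes)
  }
  invisible(x)
}

#' Classify audio segments with a fitted detector
#'
#' @param object A [fall_detector].
#' @param newdata A single [audio_segment] or a list of them.
#' @param ... Unused.
#' @return A `data.frame` with one `detection` row per segment.
#' @export
predict.fall_detector <- function(object, newdata, ...) {
  if (inherits(newdata, "audio_segment")) newdata <- list(newdata)
  rows <- lapply(newdata, detect, detector = object)
  out <- do.call(rbind, lapply(rows, function(r) { attr(r, "supervector") <- NULL; r }))
  rownames(out) <- NULL
  out
}
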