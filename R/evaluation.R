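## Evaluation protocol: stratified fold construction, lattice grid
## search with fixed tie-breaking, and cumulative-count F1 reporting
## over fold rotations (one fold tunes the hyperparameters, the
## remaining folds are scored; counts are pooled across rotations).

#' Stratified fold plan for an evaluation set
#'
#' Falls and nonfalls are shuffled (seeded) and dealt round-robin into
#' `n_folds` disjoint folds, so a 44+44 corpus yields four folds of
#' 11 falls + 11 nonfalls. The rotation schedule uses each fold once as
#' the validation fold, with the remaining folds as test material.
#'
#' @param manifest `data.frame` with at least columns `id` and `label`
#'   (fall events are those labelled `"human_fall"`).
#' @param n_folds Number of folds.
#' @param seed Integer seed; the plan is deterministic given it.
#' @return Object of class `fold_plan`: a list of row-index vectors
#'   `folds` plus the `rotation` order.
#' @export
make_folds <- function(manifest, n_folds = 4L, seed = 1L) {
  stopifnot(is.data.frame(manifest), all(c("id", "label") %in% names(manifest)))
  is_fall <- is_fall_label(manifest$label)
  if (sum(is_fall) < n_folds || sum(!is_fall) < n_folds) {
    stop("make_folds: need at least ", n_folds, " falls and ", n_folds, " nonfalls")
  }
  deal <- function(idx) {
    idx <- with_seed(seed + length(idx), sample(idx))
    split(idx, rep_len(seq_len(n_folds), length(idx)))
  }
  f_fall <- deal(which(is_fall))
  f_non <- deal(which(!is_fall))
  folds <- lapply(seq_len(n_folds), function(k) sort(c(f_fall[[k]], f_non[[k]])))
  structure(list(folds = folds, rotation = seq_len(n_folds), seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, length, 1L)
  cat(sprintf("<fold_plan> %d folds of sizes %s\n", length(x$folds),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' F1 measure from cumulative counts
#'
#' `2 tp / (2 tp + fn + fp)`, the harmonic mean of precision and recall
#' computed from pooled true positives, false negatives and false
#' positives.
#'
#' @param tp,fp,fn Nonnegative counts; all zero is an error (the measure
#'   is undefined with no falls and no alarms).
#' @return Scalar in `[0, 1]`.
#' @export
f1_measure <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) stop("f1_measure: undefined for tp = fp = fn = 0")
  2 * tp / (2 * tp + fn + fp)
}

#' Hyperparameter lattice
#'
#' Defaults are the full validation lattice: UBM sizes
#' `J = 1, 2, 4, ..., 64`, `nu = 0.1, ..., 1.0` and
#' `gamma = 2^-15, 2^-13, ..., 2^3`; the template threshold beta is not
#' part of the lattice (it is selected by [select_threshold]).
#'
#' @param J,nu,gamma Candidate values.
#' @return Object of class `grid_space`.
#' @export
grid_space <- function(J = 2^(0:6), nu = seq(0.1, 1.0, by = 0.1),
                       gamma = 2^seq(-15, 3, by = 2)) {
  stopifnot(all(J >= 1), all(nu > 0 & nu <= 1), all(gamma > 0))
  structure(list(J = J, nu = nu, gamma = gamma), class = "grid_space")
}

# full lattice as a data.frame in a fixed enumeration order
enumerate_grid <- function(grid) {
  expand.grid(gamma = grid$gamma, nu = grid$nu, J = grid$J,
              KEEP.OUT.ATTRS = FALSE)[, c("J", "nu", "gamma")]
}

# tie-break: max F1, then smallest J, then smallest nu, then largest gamma
pick_best <- function(scores) {
  o <- order(-scores$f1, scores$J, scores$nu, -scores$gamma)
  scores[o[1L], , drop = FALSE]
}

#' Grid search over the hyperparameter lattice
#'
#' Evaluates `scorer` at every lattice point for every rotation of the
#' fold plan and returns the best point per rotation (ties broken by
#' smallest `J`, then smallest `nu`, then largest `gamma`).
#'
#' @param plan A `fold_plan`.
#' @param grid A `grid_space`.
#' @param scorer `function(J, nu, gamma, rotation)` returning a
#'   validation F1 (or any score to maximise).
#' @return `data.frame` with one row per rotation: `rotation`, `J`,
#'   `nu`, `gamma`, `f1`.
#' @export
grid_search <- function(plan, grid, scorer) {
  lattice <- enumerate_grid(grid)
  out <- lapply(plan$rotation, function(r) {
    sc <- lattice
    sc$f1 <- vapply(seq_len(nrow(lattice)), function(i) {
      scorer(lattice$J[i], lattice$nu[i], lattice$gamma[i], r)
    }, numeric(1))
    best <- pick_best(sc)
    cbind(rotation = r, best)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# counts from predicted/true fall indicators
count_outcomes <- function(pred_fall, true_fall) {
  c(tp = sum(pred_fall & true_fall), fp = sum(pred_fall & !true_fall),
    fn = sum(!pred_fall & true_fall), tn = sum(!pred_fall & !true_fall))
}

## ---- experiment front end --------------------------------------------

#' Precompute features, UBM and supervectors for a synthetic corpus
#'
#' The expensive, method-independent part of an experiment: MFCC+delta
#' matrices for every segment, the EM-trained UBM on the pooled training
#' frames, supervectors for all corpus parts, and window statistics for
#' the baseline. Reused across methods/sets/conditions by [evaluate].
#'
#' @param corpus A corpus from [gen_corpus].
#' @param J UBM component count.
#' @param features A [feature_config].
#' @param relevance MAP relevance factor.
#' @param seed EM seed.
#' @return Object of class `experiment_frontend`.
#' @export
prepare_frontend <- function(corpus, J = 8, features = feature_config(),
                             relevance = 16, seed = 1L) {
  feats_of <- function(segs) {
    lapply(segs, function(s) unclass(append_deltas(extract_mfcc(s, features),
                                                   features$delta_width)))
  }
  train_feats <- feats_of(corpus$train)
  ubm <- train_ubm(do.call(rbind, train_feats), J = J, seed = seed)
  sv_of <- function(featlist) {
    if (length(featlist) == 0L) return(NULL)
    t(vapply(featlist, function(f) compute_gms(ubm, f, relevance),
             numeric(ubm$D * ubm$J)))
  }
  wstats_of <- function(featlist, bcfg) {
    lapply(featlist, function(m) {
      w <- baseline_window_starts(nrow(m), bcfg)
      t(vapply(w$starts, function(st) window_stat(m, st, w$length),
               numeric(ncol(m))))
    })
  }
  bcfg <- baseline_config()
  parts <- list()
  for (set in names(corpus$sets)) {
    for (cond in c("clean", "noisy")) {
      segs <- corpus$sets[[set]][[cond]]
      if (is.null(segs)) next
      f <- feats_of(segs)
      parts[[paste(set, cond, sep = ".")]] <- list(
        sv = sv_of(f), wstats = wstats_of(f, bcfg),
        manifest = corpus$sets[[set]]$manifest)
    }
  }
  pools <- list()
  for (pool in c("object_pool", "background_pool")) {
    for (cond in c("clean", "noisy")) {
      segs <- corpus[[pool]][[cond]]
      if (is.null(segs)) next
      pools[[paste(pool, cond, sep = ".")]] <- list(
        sv = sv_of(feats_of(segs)),
        labels = vapply(segs, `[[`, "", "label"))
    }
  }
  structure(list(ubm = ubm, J = J, features = features,
                 relevance = relevance, seed = seed,
                 train_sv = sv_of(train_feats),
                 train_wstats = wstats_of(train_feats, bcfg),
                 baseline_cfg = bcfg, parts = parts, pools = pools,
                 hash = feature_hash(features, J, relevance)),
            class = "experiment_frontend")
}

## ---- cascade / baseline scoring on precomputed embeddings ------------

# templates + beta from a validation split, given a trained stage-1 model
cascade_stage2 <- function(fe, ocsvm, set_key, val_idx, condition) {
  part <- fe$parts[[set_key]]
  man <- part$manifest
  classes <- sub(":.*$", "", man$label)
  tpl <- NULL
  if (any(classes == "object_fall")) {
    pool <- fe$pools[[paste("object_pool", condition, sep = ".")]]
    if (!is.null(pool)) {
      tpl <- build_object_templates(pool$sv, pool$labels, ocsvm,
                                    config_hash = fe$hash)
    }
  }
  if (any(classes %in% c("human_activity", "music"))) {
    pool <- fe$pools[[paste("background_pool", condition, sep = ".")]]
    if (!is.null(pool)) {
      bg <- build_background_templates(part$sv[val_idx, , drop = FALSE],
                                       pool$sv, pool$labels,
                                       config_hash = fe$hash)
      if (is.null(tpl) || nrow(tpl$templates) == 0L) {
        tpl <- bg
      } else if (nrow(bg$templates) > 0L) {
        for (i in seq_len(nrow(bg$templates))) {
          tpl <- tryCatch(add_template(tpl, bg$templates[i, ],
                                       label = bg$labels[i], origin = "a-priori"),
                          error = function(e) tpl)
        }
      }
    }
  }
  if (is.null(tpl) || nrow(tpl$templates) == 0L) return(NULL)
  dmin <- apply(part$sv[val_idx, , drop = FALSE], 1,
                function(v) min_distance(v, tpl)$d_min)
  fall <- is_fall_label(man$label[val_idx])
  if (any(fall) && any(!fall) &&
      !isTRUE(all.equal(sort(dmin[fall]), sort(dmin[!fall])))) {
    tpl$beta <- suppressWarnings(select_threshold(dmin[fall], dmin[!fall]))
  }
  tpl
}

# fall/nonfall labels for the rows `idx` of one set part
score_events <- function(fe, method, set_key, idx, ocsvm, tpl) {
  part <- fe$parts[[set_key]]
  if (method == "baseline") {
    vapply(part$wstats[idx], function(X) {
      novel <- ocsvm_decision(ocsvm, X)$sign == -1L
      consecutive_novelty(novel, fe$baseline_cfg$min_consecutive_novel)
    }, logical(1))
  } else {
    s1 <- ocsvm_decision(ocsvm, part$sv[idx, , drop = FALSE])$sign == -1L
    if (method == "ocsvm_only" || is.null(tpl) || nrow(tpl$templates) == 0L) {
      s1
    } else {
      out <- s1
      for (k in which(s1)) {
        d <- min_distance(part$sv[idx[k], ], tpl)$d_min
        out[k] <- template_decision(d, tpl$beta) == "fall"
      }
      out
    }
  }
}

#' Run the fold-rotation evaluation protocol
#'
#' For every rotation of the fold plan, hyperparameters are tuned on the
#' validation fold by exhaustive grid search (validation F1, fixed
#' tie-breaking) and the remaining folds are scored; true/false
#' positives and false negatives are cumulated over rotations into one
#' F1 per `(method, set, condition)`.
#'
#' Methods: `"cascade"` (OCSVM + template veto with beta selected on the
#' validation fold), `"ocsvm_only"` (stage 1 alone) and `"baseline"`
#' (windowed frame-level method).
#'
#' @param frontend An `experiment_frontend` from [prepare_frontend], or
#'   a corpus from [gen_corpus] (then the front end is built first).
#' @param set Which evaluation set analogue: `"set1"`, `"set2"`, `"set3"`.
#' @param method `"cascade"`, `"ocsvm_only"` or `"baseline"`.
#' @param condition `"clean"` or `"noisy"`.
#' @param grid `grid_space` over `nu`/`gamma` (the front end fixes `J`).
#' @param n_folds,seed Fold-plan geometry and seed.
#' @return Object of class `eval_report` with cumulative counts, the F1,
#'   per-rotation chosen hyperparameters, and the per-event decisions.
#' @export
evaluate <- function(frontend, set = c("set1", "set2", "set3"),
                     method = c("cascade", "ocsvm_only", "baseline"),
                     condition = c("clean", "noisy"),
                     grid = grid_space(J = NULL, nu = c(0.1, 0.2, 0.3),
                                       gamma = 2^c(-15, -11, -7, -3)),
                     n_folds = 4L, seed = 1L) {
  set <- match.arg(set); method <- match.arg(method)
  condition <- match.arg(condition)
  if (!inherits(frontend, "experiment_frontend")) {
    frontend <- prepare_frontend(frontend, seed = seed)
  }
  fe <- frontend
  set_key <- paste(set, condition, sep = ".")
  if (is.null(fe$parts[[set_key]])) stop("evaluate: no such set/condition: ", set_key)
  man <- fe$parts[[set_key]]$manifest
  plan <- make_folds(man, n_folds = n_folds, seed = seed)

  fit_stage1 <- function(nu, gamma) {
    if (method == "baseline") {
      train_ocsvm(do.call(rbind, fe$train_wstats), nu = nu, gamma = gamma)
    } else {
      train_ocsvm(fe$train_sv, nu = nu, gamma = gamma)
    }
  }

  lattice <- enumerate_grid(grid_space(J = fe$J, nu = grid$nu, gamma = grid$gamma))
  counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  chosen <- NULL
  decisions <- NULL
  models <- new.env(parent = emptyenv())  # cache stage-1 fits across rotations

  for (r in plan$rotation) {
    val_idx <- plan$folds[[r]]
    test_idx <- sort(unlist(plan$folds[-r]))
    sc <- lattice
    sc$f1 <- vapply(seq_len(nrow(lattice)), function(i) {
      key <- paste(lattice$nu[i], lattice$gamma[i])
      if (is.null(models[[key]])) {
        models[[key]] <- tryCatch(fit_stage1(lattice$nu[i], lattice$gamma[i]),
                                  error = function(e) NULL)
      }
      m <- models[[key]]
      if (is.null(m)) return(NA_real_)
      tpl <- if (method == "cascade") {
        cascade_stage2(fe, m, set_key, val_idx, condition)
      } else NULL
      pred <- score_events(fe, method, set_key, val_idx, m, tpl)
      cts <- count_outcomes(pred, is_fall_label(man$label[val_idx]))
      if (sum(cts[c("tp", "fp", "fn")]) == 0) return(0)
      f1_measure(cts["tp"], cts["fp"], cts["fn"])
    }, numeric(1))
    sc <- sc[!is.na(sc$f1), , drop = FALSE]
    if (nrow(sc) == 0L) stop("evaluate: no lattice point trainable in rotation ", r)
    best <- pick_best(sc)
    m <- models[[paste(best$nu, best$gamma)]]
    tpl <- if (method == "cascade") {
      cascade_stage2(fe, m, set_key, val_idx, condition)
    } else NULL
    pred <- score_events(fe, method, set_key, test_idx, m, tpl)
    truth <- is_fall_label(man$label[test_idx])
    counts <- counts + count_outcomes(pred, truth)
    chosen <- rbind(chosen, data.frame(rotation = r, J = fe$J, nu = best$nu,
                                       gamma = best$gamma,
                                       beta = if (!is.null(tpl)) tpl$beta else NA_real_,
                                       val_f1 = best$f1))
    decisions <- rbind(decisions,
                       data.frame(rotation = r, id = man$id[test_idx],
                                  label = man$label[test_idx],
                                  predicted = ifelse(pred, "fall", "nonfall"),
                                  stringsAsFactors = FALSE))
  }
  f1 <- f1_measure(counts["tp"], counts["fp"], counts["fn"])
  structure(list(method = method, set = set, condition = condition,
                 counts = counts, f1 = unname(f1), params = chosen,
                 decisions = decisions),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s on %s (%s): F1 = %.4f  [tp %d, fp %d, fn %d, tn %d]\n",
              x$method, x$set, x$condition, x$f1,
              x$counts["tp"], x$counts["fp"], x$counts["fn"], x$counts["tn"]))
  invisible(x)
}
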