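## Threshold-selection protocol: stratified 10-fold cross-validation, a
## random search of 10 threshold sets per fold evaluated on the training
## recordings, ROC-distance selection, and a cumulative confusion matrix
## over the test folds.

#' Threshold search ranges
#'
#' The shipped defaults reproduce the search ranges under which each
#' algorithm's thresholds were originally tuned on the MobiAct corpus
#' (acceleration in g, angular velocity in rad/s, timers in ms):
#'
#' * `alg1`: `smv_ff` (0.7, 0.9), `smv_ip` (1.5, 1.7), `av_ff` (0.3, 0.7],
#'   `av_ip` (0.7, 1.1).
#' * `alg2`: `sv` (1.7, 2.3) g, `av` (21, 23) deg, `ca` (42, 46) deg,
#'   `sv_g` (2, 2.4) rad/s, `sv_ga` (36, 40) rad/s^2.
#' * `alg3`: `th_ca` (0.4, 0.8), `th_g` (0.3, 0.7) rad/s,
#'   `th_cg` (0.2, 0.6).
#' * `alg4`: `smv_peak` (1.8, 2.2) g, `at_low` (1000, 2000) ms,
#'   `at_high` (2500, 3000) ms, `fs_low` (-2500, -1500) ms,
#'   `fs_high` (500, 1500) ms, `k` 1..9 (odd).
#'
#' Ranges for the other corpora were never published; the MobiAct ranges
#' are reused as defaults.
#'
#' @param algorithm `"alg1"`, `"alg2"`, `"alg3"` or `"alg4"`.
#' @return data.frame with columns `name`, `low`, `high`, `integer`,
#'   `odd`.
#' @export
default_ranges <- function(algorithm = c("alg1", "alg2", "alg3", "alg4")) {
  algorithm <- match.arg(algorithm)
  rng <- function(name, low, high, integer = FALSE, odd = FALSE)
    data.frame(name = name, low = low, high = high, integer = integer,
               odd = odd)
  switch(algorithm,
    alg1 = rbind(rng("smv_ff", 0.7, 0.9), rng("smv_ip", 1.5, 1.7),
                 rng("av_ff", 0.3, 0.7), rng("av_ip", 0.7, 1.1)),
    alg2 = rbind(rng("sv", 1.7, 2.3), rng("av", 21, 23), rng("ca", 42, 46),
                 rng("sv_g", 2, 2.4), rng("sv_ga", 36, 40)),
    alg3 = rbind(rng("th_ca", 0.4, 0.8), rng("th_g", 0.3, 0.7),
                 rng("th_cg", 0.2, 0.6)),
    alg4 = rbind(rng("smv_peak", 1.8, 2.2),
                 rng("at_low", 1000, 2000, integer = TRUE),
                 rng("at_high", 2500, 3000, integer = TRUE),
                 rng("fs_low", -2500, -1500, integer = TRUE),
                 rng("fs_high", 500, 1500, integer = TRUE),
                 rng("k", 1, 9, integer = TRUE, odd = TRUE)))
}

#' Reference operating points
#'
#' The threshold values originally selected on the MobiAct corpus by the
#' random-search/ROC procedure; convenient defaults for single-recording
#' detection and for tests.
#'
#' @param algorithm algorithm name.
#' @return the matching threshold/parameter object.
#' @export
default_thresholds <- function(algorithm = c("alg1", "alg2", "alg3", "alg4")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    alg1 = alg1_thresholds(smv_ff = 0.8362, smv_ip = 1.5731,
                           av_ff = 0.5633, av_ip = 0.7387),
    alg2 = alg2_thresholds(sv = 2.0422, av = 21.4522, ca = 42.6328,
                           sv_g = 2.3986, sv_ga = 39.6284),
    alg3 = alg3_thresholds(th_ca = 0.7684, th_g = 0.3331, th_cg = 0.3216),
    alg4 = alg4_params(smv_peak = 1.8618, at_low = 1423, at_high = 2702,
                       fs_low = -2170, fs_high = 1155, k = 7))
}

## Wrap a named list of sampled values into the algorithm's threshold
## object.
as_thresholds <- function(algorithm, values) {
  switch(algorithm,
    alg1 = do.call(alg1_thresholds, values),
    alg2 = do.call(alg2_thresholds, values),
    alg3 = do.call(alg3_thresholds, values),
    alg4 = do.call(alg4_params, values),
    ff_config_error(paste0("unknown algorithm '", algorithm,
                           "'; choose one of alg1, alg2, alg3, alg4")))
}

#' Randomly sample threshold sets
#'
#' Each value is drawn uniformly and independently from its range;
#' integer-valued parameters (timers, k) are drawn as integers, and
#' odd-constrained ones from the odd integers of the range.
#'
#' @param ranges a [default_ranges()]-style data.frame.
#' @param n_sets number of sets (>= 1).
#' @param seed integer seed for reproducibility.
#' @return list of `n_sets` named lists of threshold values.
#' @export
sample_thresholds <- function(ranges, n_sets, seed = NULL) {
  if (!nrow(ranges)) ff_config_error("empty search ranges")
  if (n_sets < 1) ff_contract_error("n_sets must be >= 1")
  draw <- function() {
    vals <- lapply(seq_len(nrow(ranges)), function(i) {
      lo <- ranges$low[i]; hi <- ranges$high[i]
      if (isTRUE(ranges$odd[i])) {
        cand <- seq(ceiling(lo), floor(hi))
        cand <- cand[cand %% 2 == 1]
        cand[sample.int(length(cand), 1)]
      } else if (isTRUE(ranges$integer[i])) {
        as.integer(floor(stats::runif(1, lo, hi + 1)))
      } else {
        stats::runif(1, lo, hi)
      }
    })
    stats::setNames(vals, ranges$name)
  }
  body <- function() lapply(seq_len(n_sets), function(i) draw())
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' ROC-distance selection
#'
#' Picks the candidate whose training (sensitivity, specificity) point
#' lies closest to the ideal (0, 1) corner of the sensitivity vs.
#' (1 - specificity) plane, i.e. minimizes
#' `sqrt((1 - specificity)^2 + (1 - sensitivity)^2)`; ties go to the
#' lower candidate index.  Undefined metrics count as 0.
#'
#' @param sensitivity,specificity numeric vectors over candidates.
#' @return index of the selected candidate.
#' @export
roc_select <- function(sensitivity, specificity) {
  if (!length(sensitivity) || length(sensitivity) != length(specificity))
    ff_contract_error("need matching nonempty metric vectors")
  sens <- ifelse(is.na(sensitivity), 0, sensitivity)
  spec <- ifelse(is.na(specificity), 0, specificity)
  which.min(sqrt((1 - spec)^2 + (1 - sens)^2))
}

#' Stratified fold assignment
#'
#' Partitions recordings into `n_folds` folds preserving the fall/ADL
#' proportion per fold to within one recording.
#'
#' @param is_fall logical vector of class labels.
#' @param n_folds fold count.
#' @param seed integer seed.
#' @return integer vector of fold indices (1-based).
#' @export
stratified_folds <- function(is_fall, n_folds = 10, seed = NULL) {
  n <- length(is_fall)
  for (cls in unique(is_fall)) {
    if (sum(is_fall == cls) < n_folds)
      ff_data_error(sprintf(
        "class with %d member(s) cannot fill %d folds; use fewer folds",
        sum(is_fall == cls), n_folds))
  }
  assign_cls <- function(idx) {
    perm <- idx[sample.int(length(idx))]
    stats::setNames(rep_len(seq_len(n_folds), length(perm)), perm)
  }
  body <- function() {
    folds <- integer(n)
    for (cls in unique(is_fall)) {
      a <- assign_cls(which(is_fall == cls))
      folds[as.integer(names(a))] <- a
    }
    folds
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

## ---------------------------------------------------------------------
## Detector registry.  Each detector exposes:
##   fold_setup(train)          threshold-independent per-fold context
##                              (e.g. the fall pattern built from the
##                              training falls)
##   featurize(rec, ctx)        threshold-independent per-recording cache
##   fit(train_feats, th, ctx)  threshold-dependent model (alg4's kNN)
##   decide(feat, th, model, ctx)  detection times for one recording
get_detector <- function(algorithm) {
  switch(algorithm,
    alg1 = list(
      ctx_free = TRUE,
      fold_setup = function(train) NULL,
      featurize = function(rec, ctx) alg1_featurize(rec),
      fit = function(train_feats, train_recs, th, ctx) NULL,
      decide = function(feat, th, model, ctx) alg1_decide(feat, th)),
    alg2 = list(
      ctx_free = TRUE,
      fold_setup = function(train) NULL,
      featurize = function(rec, ctx) alg2_featurize(rec),
      fit = function(train_feats, train_recs, th, ctx) NULL,
      decide = function(feat, th, model, ctx) alg2_decide(feat, th)),
    alg3 = list(
      ctx_free = FALSE,
      fold_setup = function(train) {
        falls <- Filter(function(r) r$is_fall, train)
        if (!length(falls)) ff_data_error("no fall recordings to build a pattern")
        build_pattern(falls)
      },
      featurize = function(rec, ctx) alg3_featurize(rec, ctx),
      fit = function(train_feats, train_recs, th, ctx) NULL,
      decide = function(feat, th, model, ctx) alg3_decide(feat, th)),
    alg4 = list(
      ctx_free = TRUE,
      fold_setup = function(train) train,   # kNN refits need the recordings
      featurize = function(rec, ctx)
        list(smv = magnitude(rec$A), fs = rec$fs),
      fit = function(train_feats, train_recs, th, ctx) {
        labels <- vapply(train_recs, function(r) r$is_fall, logical(1))
        rows <- lapply(train_feats, function(f)
          alg4_peak_features(f$smv, f$fs, th))
        ok <- !vapply(rows, is.null, logical(1))
        if (sum(ok) < th$k) ff_data_error("not enough usable training recordings")
        knn_fit(do.call(rbind, rows[ok]), labels[ok], k = th$k)
      },
      decide = function(feat, th, model, ctx) {
        cand <- fsm_candidates(feat$smv, feat$fs, th)
        if (!nrow(cand)) return(numeric(0))
        X <- t(vapply(seq_len(nrow(cand)), function(i) {
          idx <- window_slice(cand$seg_start[i], cand$seg_end[i])
          extract_features(feat$smv[idx], feat$fs, th$smv_peak)
        }, numeric(11)))
        cand$peak_time[knn_classify(model, X,
                                    k = min(model$k, nrow(model$Z)))]
      }),
    ff_config_error(paste0("unknown algorithm '", algorithm,
                           "'; choose one of alg1, alg2, alg3, alg4")))
}

## Recording-level confusion matrix: >= 1 detection flags the recording.
## Detector errors on a recording count as "no detection" and are logged.
eval_confusion <- function(feats, labels, decide_one) {
  flagged <- vapply(feats, function(f) {
    times <- tryCatch(decide_one(f), error = function(e) {
      warning("detector error treated as no detection: ",
              conditionMessage(e))
      numeric(0)
    })
    length(times) > 0
  }, logical(1))
  confusion_matrix(tp = sum(flagged & labels), tn = sum(!flagged & !labels),
                   fp = sum(flagged & !labels), fn = sum(!flagged & labels))
}

#' Cross-validated random threshold search
#'
#' The standard protocol: stratified `n_folds`-fold cross-validation; in
#' every fold, `n_sets` random threshold sets are drawn from the search
#' ranges and evaluated on the fold's *training* recordings
#' (recording-level decisions); the set whose training
#' (sensitivity, specificity) lies closest to the ROC ideal corner is
#' selected and evaluated once on the fold's test recordings.  The fold
#' matrices are summed into a cumulative confusion matrix, and the overall
#' best threshold set is the ROC-selected winner among the per-fold
#' winners (by their training ROC points).  All randomness (fold
#' assignment, candidate draws) derives deterministically from `seed`.
#'
#' @param recordings list of labelled, preprocessed [imu_recording]s.
#' @param algorithm `"alg1"`, `"alg2"`, `"alg3"` or `"alg4"`.
#' @param ranges search ranges (default: [default_ranges()]).
#' @param n_sets candidate threshold sets per fold (default 10).
#' @param n_folds folds (default 10).
#' @param seed master seed.
#' @return object of class `cv_result`: list with `algorithm`,
#'   `fold_results` (data.frame: fold, train_sensitivity,
#'   train_specificity, tp, tn, fp, fn, and the selected threshold
#'   values), `fold_thresholds` (list), `cumulative` (confusion matrix),
#'   `best_thresholds`, `fold_metrics` (per-fold [metrics()]), `seed`.
#' @export
cross_validate <- function(recordings, algorithm,
                           ranges = default_ranges(algorithm),
                           n_sets = 10, n_folds = 10, seed = 1) {
  det <- get_detector(algorithm)
  labels <- vapply(recordings, function(r) r$is_fall, logical(1))
  folds <- stratified_folds(labels, n_folds, seed = seed)
  fold_seeds <- with_seed(seed + 1L, sample.int(.Machine$integer.max - 1,
                                                n_folds))
  fold_rows <- list(); fold_ths <- list(); fold_cms <- list()
  ## per-recording features are fold-independent for detectors without a
  ## fold context; compute them once for the whole corpus
  all_feats <- if (isTRUE(det$ctx_free))
    lapply(recordings, det$featurize, ctx = NULL)
  for (f in seq_len(n_folds)) {
    tr_idx <- which(folds != f); te_idx <- which(folds == f)
    train <- recordings[tr_idx]; test <- recordings[te_idx]
    ctx <- det$fold_setup(train)
    if (isTRUE(det$ctx_free)) {
      tr_feats <- all_feats[tr_idx]; te_feats <- all_feats[te_idx]
    } else {
      tr_feats <- lapply(train, det$featurize, ctx = ctx)
      te_feats <- lapply(test, det$featurize, ctx = ctx)
    }
    cands <- sample_thresholds(ranges, n_sets, seed = fold_seeds[f])
    sens <- spec <- numeric(n_sets); models <- vector("list", n_sets)
    ths <- lapply(cands, function(v) as_thresholds(algorithm, v))
    for (ci in seq_len(n_sets)) {
      th <- ths[[ci]]
      models[ci] <- list(tryCatch(det$fit(tr_feats, train, th, ctx),
                                  error = function(e) e))
      if (inherits(models[[ci]], "error")) { sens[ci] <- NA; spec[ci] <- NA; next }
      cm <- eval_confusion(tr_feats, labels[tr_idx], function(ft)
        det$decide(ft, th, models[[ci]], ctx))
      m <- metrics(cm)
      sens[ci] <- m$sensitivity; spec[ci] <- m$specificity
    }
    best <- roc_select(sens, spec)
    th <- ths[[best]]
    cm_test <- eval_confusion(te_feats, labels[te_idx], function(ft)
      det$decide(ft, th, models[[best]], ctx))
    fold_ths[[f]] <- cands[[best]]
    fold_cms[[f]] <- cm_test
    fold_rows[[f]] <- data.frame(
      fold = f, train_sensitivity = sens[best], train_specificity = spec[best],
      tp = cm_test$tp, tn = cm_test$tn, fp = cm_test$fp, fn = cm_test$fn)
  }
  fold_results <- do.call(rbind, fold_rows)
  cumulative <- Reduce(`+`, fold_cms)
  overall <- roc_select(fold_results$train_sensitivity,
                        fold_results$train_specificity)
  structure(list(
    algorithm = algorithm,
    fold_results = fold_results,
    fold_thresholds = fold_ths,
    cumulative = cumulative,
    best_thresholds = fold_ths[[overall]],
    best_fold = overall,
    fold_metrics = lapply(fold_cms, metrics),
    n_sets = n_sets, n_folds = n_folds, seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: %d-fold CV, %d candidate sets/fold, seed %d\n",
              x$algorithm, x$n_folds, x$n_sets, x$seed))
  print(x$cumulative)
  m <- metrics(x$cumulative)
  cat(sprintf("cumulative sensitivity %.4f, specificity %.4f\n",
              m$sensitivity, m$specificity))
  invisible(x)
}
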