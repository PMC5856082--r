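## Performance metrics and the Friedman + Nemenyi comparison chain.

#' Confusion matrix
#'
#' @param tp,tn,fp,fn nonnegative counts.  A fall recording with at least
#'   one detection is a TP; an ADL recording with at least one detection
#'   is an FP.
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp = 0, tn = 0, fp = 0, fn = 0) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0)) ff_contract_error("confusion counts must be nonnegative")
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d  FN %d  FP %d  TN %d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

## Elementwise sum, used for the cumulative matrix.
#' @export
`+.confusion_matrix` <- function(e1, e2) {
  confusion_matrix(e1$tp + e2$tp, e1$tn + e2$tn, e1$fp + e2$fp, e1$fn + e2$fn)
}

#' Detection performance metrics
#'
#' Sensitivity (= recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' precision `TP/(TP+FP)` and `F1 = 2 * precision * recall /
#' (precision + recall)`.  Any metric whose denominator is zero is
#' returned as `NA` (undefined propagates as missing, never silently 0).
#'
#' @param cm a [confusion_matrix].
#' @return named list of class `metric_set` with `sensitivity`,
#'   `specificity`, `precision`, `f1`.
#' @export
metrics <- function(cm) {
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rat(cm$tp, cm$tp + cm$fn)
  spec <- rat(cm$tn, cm$tn + cm$fp)
  prec <- rat(cm$tp, cm$tp + cm$fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  structure(list(sensitivity = sens, specificity = spec, precision = prec,
                 f1 = f1), class = "metric_set")
}

#' Friedman rank test (two-way layout with replication)
#'
#' Nonparametric counterpart of ANOVA for comparing `k` algorithms whose
#' scores come in `n_groups` groups (e.g. datasets) of `n_reps` replicate
#' rows (e.g. cross-validation folds).  All `n_reps * k` entries of a
#' group are ranked jointly (average ranks for ties), and the ranks are
#' decomposed ANOVA-style into Groups / Columns / Interaction / Error
#' sums of squares.  The chi-square statistic is the Columns sum of
#' squares scaled by the total rank variance,
#' `chi^2 = SS_Columns / (S_total / (n_groups * (n_reps * k - 1)))`,
#' which reduces to the textbook tie-corrected Friedman statistic when
#' `n_reps = 1`; `p` comes from the chi-square distribution with `k - 1`
#' degrees of freedom.  Ranking within a group forces every group mean to
#' the grand mean, so the Groups row always carries zero sum of squares
#' (its `n_groups - 1` degrees of freedom are what make the Error row
#' `n_groups * k * (n_reps - 1)`).
#'
#' @param scores numeric matrix, `n_groups * n_reps` rows by `k` columns
#'   (column = algorithm); rows of a group are contiguous.
#' @param n_groups number of groups `d`.
#' @param n_reps replicates per group `r` (`nrow = d * r`).
#' @return an object of class `friedman_table`: a data.frame with rows
#'   Groups / Columns / Interaction / Error / Total and columns `SS`,
#'   `df`, `MS`, plus attributes `chisq`, `p_value`, `ranks` (the rank
#'   matrix) and `avg_ranks`.
#' @export
friedman_test <- function(scores, n_groups = nrow(scores), n_reps = 1) {
  scores <- as.matrix(scores)
  k <- ncol(scores); d <- n_groups; r <- n_reps
  if (k < 2) ff_contract_error("need at least two algorithms")
  if (nrow(scores) != d * r)
    ff_contract_error("nrow(scores) must equal n_groups * n_reps")
  if (anyNA(scores)) ff_contract_error("scores must not contain NA")

  R <- matrix(0, d * r, k)
  for (g in seq_len(d)) {
    rows <- ((g - 1) * r + 1):(g * r)
    R[rows, ] <- matrix(rank(scores[rows, ]), r, k)
  }
  mu <- (r * k + 1) / 2               # grand mean of joint ranks
  col_mean <- colMeans(R)
  grp_mean <- vapply(seq_len(d), function(g)
    mean(R[((g - 1) * r + 1):(g * r), ]), numeric(1))
  ss_col <- d * r * sum((col_mean - mu)^2)
  ss_grp <- r * k * sum((grp_mean - mu)^2)      # identically 0
  cell <- matrix(0, d, k)
  for (g in seq_len(d))
    cell[g, ] <- colMeans(R[((g - 1) * r + 1):(g * r), , drop = FALSE])
  dev <- sweep(sweep(cell, 2, col_mean, "-"), 1, grp_mean, "-") + mu
  ss_int <- r * sum(dev^2)
  s_total <- sum((R - mu)^2)
  ss_err <- s_total - ss_grp - ss_col - ss_int

  df <- c(d - 1, k - 1, (k - 1) * (d - 1), d * k * (r - 1), d * r * k - 1)
  ss <- c(ss_grp, ss_col, ss_int, ss_err, s_total)
  ms <- ifelse(df > 0, ss / df, NA_real_)
  chisq <- if (s_total <= 1e-12) 0 else
    ss_col / (s_total / (d * (r * k - 1)))
  p <- stats::pchisq(chisq, df = k - 1, lower.tail = FALSE)

  tab <- data.frame(Source = c("Groups", "Columns", "Interaction", "Error",
                               "Total"),
                    SS = ss, df = df, MS = ms)
  structure(tab, class = c("friedman_table", "data.frame"),
            chisq = chisq, p_value = p, ranks = R,
            avg_ranks = col_mean, k = k, n_groups = d, n_reps = r)
}

#' @export
print.friedman_table <- function(x, ...) {
  cat("Friedman test (two-way layout on joint within-group ranks)\n")
  print.data.frame(cbind(x, `Chi-sq` = c(NA, attr(x, "chisq"), NA, NA, NA),
                         `Prob>Chi-sq` = c(NA, attr(x, "p_value"),
                                           NA, NA, NA)),
                   row.names = FALSE, digits = 6)
  invisible(x)
}

## Critical values q_alpha of the Nemenyi test (studentized range / sqrt 2)
## for k = 2..10 algorithms, embedded so no statistical-table dependency
## is needed.
NEMENYI_Q <- list(
  "0.05" = c(`2` = 1.959964, `3` = 2.343701, `4` = 2.569032,
             `5` = 2.727774, `6` = 2.849705, `7` = 2.948320,
             `8` = 3.030879, `9` = 3.101730, `10` = 3.163684),
  "0.1" = c(`2` = 1.644854, `3` = 2.052293, `4` = 2.291341,
            `5` = 2.459516, `6` = 2.588521, `7` = 2.692732,
            `8` = 2.779884, `9` = 2.854606, `10` = 2.920063))

#' Nemenyi post-hoc test
#'
#' Pairwise comparison of average ranks after a rejected Friedman test.
#' Two algorithms differ significantly when their average ranks differ by
#' at least the critical distance
#' `CD = q_alpha(k) * sqrt(k * (k + 1) / (6 * n_blocks))`.
#'
#' @param avg_ranks named numeric vector of per-algorithm average ranks
#'   (rank 1 = best).
#' @param n_blocks number of rank blocks the averages come from.
#' @param alpha significance level; 0.05 or 0.10 (embedded q table).
#' @return an object of class `nemenyi_result`: list with `avg_ranks`,
#'   `cd`, `alpha`, and a logical `significant` matrix.
#' @export
nemenyi <- function(avg_ranks, n_blocks, alpha = 0.05) {
  k <- length(avg_ranks)
  key <- as.character(alpha)
  if (!key %in% names(NEMENYI_Q))
    ff_config_error(paste("unsupported alpha; supported:",
                          paste(names(NEMENYI_Q), collapse = ", ")))
  qtab <- NEMENYI_Q[[key]]
  if (!as.character(k) %in% names(qtab))
    ff_config_error("q values embedded for k = 2..10 only")
  q <- qtab[[as.character(k)]]
  cd <- q * sqrt(k * (k + 1) / (6 * n_blocks))
  dif <- abs(outer(avg_ranks, avg_ranks, "-"))
  sig <- dif >= cd
  diag(sig) <- FALSE
  structure(list(avg_ranks = avg_ranks, cd = cd, alpha = alpha, q = q,
                 n_blocks = n_blocks, significant = sig),
            class = "nemenyi_result")
}

#' @export
print.nemenyi_result <- function(x, ...) {
  cat(sprintf("Nemenyi post-hoc: CD = %.4f (alpha = %g, N = %d)\n",
              x$cd, x$alpha, x$n_blocks))
  print(round(x$avg_ranks, 3))
  invisible(x)
}

format_mean_sd <- function(x) sprintf("%.4f (%.4f)", mean(x), stats::sd(x))

#' Compare algorithms across datasets
#'
#' Builds the per-fold metric matrix (`n_datasets * n_folds` rows by
#' `n_algorithms` columns) from cross-validation results, runs
#' [friedman_test()] with the datasets as groups and folds as replicates,
#' and -- when the null is rejected at `alpha` -- the [nemenyi()]
#' post-hoc on the per-fold average ranks (rank 1 = best = highest
#' metric).  Folds in which any algorithm's metric is undefined are
#' excluded; if that leaves the groups unbalanced, each remaining fold is
#' treated as its own block.
#'
#' @param cv_results nested list: `cv_results[[dataset]][[algorithm]]`,
#'   each a [cross_validate()] result with identical fold counts.
#' @param metric `"sensitivity"`, `"specificity"`, `"precision"` or
#'   `"f1"`.
#' @param alpha significance level.
#' @return list of class `algorithm_comparison`: `metric`, `table`
#'   (mean (sd) strings per dataset x algorithm), `friedman`,
#'   `avg_ranks`, `nemenyi` (or `NULL`), `scores`.
#' @export
compare_algorithms <- function(cv_results, metric = "f1", alpha = 0.05) {
  datasets <- names(cv_results) %||% paste0("dataset", seq_along(cv_results))
  algs <- names(cv_results[[1]]) %||% paste0("alg", seq_along(cv_results[[1]]))
  n_folds <- vapply(cv_results, function(d)
    vapply(d, function(cv) nrow(cv$fold_results), integer(1)), integer(length(algs)))
  if (length(unique(as.vector(n_folds))) != 1)
    ff_contract_error("all cross-validations must use the same fold count")
  r <- n_folds[1]

  per_fold <- function(cv) vapply(seq_len(r), function(f)
    metrics(confusion_matrix(cv$fold_results$tp[f], cv$fold_results$tn[f],
                             cv$fold_results$fp[f],
                             cv$fold_results$fn[f]))[[metric]],
    numeric(1))
  scores <- do.call(rbind, lapply(cv_results, function(d)
    do.call(cbind, lapply(d, per_fold))))
  colnames(scores) <- algs

  keep <- stats::complete.cases(scores)
  if (!all(keep)) {
    warning(sum(!keep), " fold(s) dropped: undefined ", metric)
    grp_sizes <- tapply(keep, rep(seq_along(datasets), each = r), sum)
    scores_used <- scores[keep, , drop = FALSE]
    if (length(unique(grp_sizes)) == 1 && grp_sizes[1] > 0) {
      fr <- friedman_test(scores_used, n_groups = length(datasets),
                          n_reps = grp_sizes[1])
    } else {
      fr <- friedman_test(scores_used, n_groups = nrow(scores_used),
                          n_reps = 1)
    }
  } else {
    scores_used <- scores
    fr <- friedman_test(scores, n_groups = length(datasets), n_reps = r)
  }

  ## per-fold ranks (one block per row, rank 1 = best) for the post-hoc
  rank_rows <- t(apply(-scores_used, 1, rank))
  avg_ranks <- stats::setNames(colMeans(rank_rows), algs)
  nem <- if (attr(fr, "p_value") < alpha)
    nemenyi(avg_ranks, n_blocks = nrow(scores_used), alpha = alpha)
  tab <- do.call(rbind, lapply(seq_along(datasets), function(gi) {
    rows <- ((gi - 1) * r + 1):(gi * r)
    vapply(seq_along(algs), function(j)
      format_mean_sd(scores[rows, j][is.finite(scores[rows, j])]),
      character(1))
  }))
  dimnames(tab) <- list(datasets, algs)
  structure(list(metric = metric, table = tab, friedman = fr,
                 avg_ranks = avg_ranks, nemenyi = nem, scores = scores,
                 alpha = alpha),
            class = "algorithm_comparison")
}

#' @export
print.algorithm_comparison <- function(x, ...) {
  cat(sprintf("Algorithm comparison on %s\n", x$metric))
  print(x$table, quote = FALSE)
  cat(sprintf("\nFriedman chi-sq = %.2f, p = %.3g\n",
              attr(x$friedman, "chisq"), attr(x$friedman, "p_value")))
  if (!is.null(x$nemenyi)) print(x$nemenyi)
  invisible(x)
}
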