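## End-to-end pipeline: simulate corpora, run the threshold-search
## cross-validation per (dataset, algorithm), compare algorithms per
## metric, serialize everything as JSON.

#' Run configuration
#'
#' @param datasets list of dataset specs, each a list with `name`,
#'   `n_falls`, `n_adls`, and optionally `fs`, `seed`.
#' @param algorithms character vector of detector names.
#' @param n_folds,n_sets cross-validation protocol sizes.
#' @param metric_alpha significance level for the comparison.
#' @param seed master seed; per-dataset seeds default to `seed + index`.
#' @param out output directory (`NULL` = nothing written).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(datasets, algorithms = c("alg1", "alg2", "alg3", "alg4"),
                       n_folds = 10, n_sets = 10, metric_alpha = 0.05,
                       seed = 1, out = NULL) {
  known <- c("alg1", "alg2", "alg3", "alg4")
  bad <- setdiff(algorithms, known)
  if (length(bad))
    ff_config_error(paste0("unknown algorithm(s) ", paste(bad, collapse = ", "),
                           "; choose among ", paste(known, collapse = ", ")))
  for (d in datasets)
    if (is.null(d$n_falls) || is.null(d$n_adls))
      ff_config_error("every dataset spec needs n_falls and n_adls")
  structure(list(datasets = datasets, algorithms = algorithms,
                 n_folds = n_folds, n_sets = n_sets,
                 metric_alpha = metric_alpha, seed = seed, out = out),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON config file.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg$algorithms <- unlist(cfg$algorithms %||% c("alg1", "alg2", "alg3", "alg4"))
  do.call(run_config, cfg[!vapply(cfg, is.null, logical(1))])
}

cv_result_to_list <- function(cv) {
  list(algorithm = cv$algorithm, seed = cv$seed,
       fold_results = cv$fold_results,
       fold_thresholds = cv$fold_thresholds,
       cumulative = unclass(cv$cumulative),
       best_thresholds = cv$best_thresholds,
       cumulative_metrics = unclass(metrics(cv$cumulative)))
}

#' Run the full comparison pipeline
#'
#' Generates each configured synthetic dataset, preprocesses it, runs the
#' cross-validated threshold search for every configured algorithm, and
#' -- when more than one dataset and algorithm are present -- the
#' Friedman/Nemenyi comparison for each of the four metrics.  Fully
#' deterministic under the config seed.
#'
#' @param cfg a [run_config()] (or path to a JSON config).
#' @return list of class `pipeline_result` with `cv` (nested
#'   dataset x algorithm list of `cv_result`), `comparisons` (per
#'   metric), and `config`.  If `cfg$out` is set, writes
#'   `results.json` there.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cv <- list()
  for (di in seq_along(cfg$datasets)) {
    ds <- cfg$datasets[[di]]
    name <- ds$name %||% paste0("dataset", di)
    corpus <- generate_dataset(ds$n_falls, ds$n_adls,
                               fs = ds$fs %||% 50,
                               seed = ds$seed %||% (cfg$seed + di))
    recs <- lapply(corpus$recordings, preprocess)
    cv[[name]] <- list()
    for (alg in cfg$algorithms) {
      cv[[name]][[alg]] <- cross_validate(
        recs, alg, n_sets = cfg$n_sets, n_folds = cfg$n_folds,
        seed = cfg$seed)
    }
  }
  comparisons <- NULL
  if (length(cv) >= 2 && length(cfg$algorithms) >= 2) {
    comparisons <- lapply(
      stats::setNames(nm = c("sensitivity", "specificity", "precision", "f1")),
      function(m) compare_algorithms(cv, metric = m,
                                     alpha = cfg$metric_alpha))
  }
  res <- structure(list(cv = cv, comparisons = comparisons, config = cfg),
                   class = "pipeline_result")
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    ser <- list(
      config = unclass(cfg[c("algorithms", "n_folds", "n_sets", "seed")]),
      cv = lapply(cv, function(d) lapply(d, cv_result_to_list)),
      comparisons = lapply(comparisons, function(cp) list(
        metric = cp$metric, table = cp$table,
        chisq = attr(cp$friedman, "chisq"),
        p_value = attr(cp$friedman, "p_value"),
        avg_ranks = cp$avg_ranks,
        nemenyi_cd = if (!is.null(cp$nemenyi)) cp$nemenyi$cd)))
    jsonlite::write_json(ser, file.path(cfg$out, "results.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  res
}
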