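# Experiment runners: repeated external cross-validation and nested
# tuning, plus the JSON-configured command-line front end.

#' Repeated external cross-validation
#'
#' For each repeat, draws a fresh fold assignment (band-aware when the
#' dataset carries band identifiers with at least `nFolds` distinct
#' bands, stratified otherwise), trains a hyper-ensemble on each
#' training split and scores the held-out fold, so every sample is
#' scored exactly once per repeat. Fold structure is re-drawn per
#' repeat from a seed offset.
#'
#' @param dataset a [smurf_dataset()].
#' @param h a [hyperparams()] object.
#' @param nFolds external fold count (default 10).
#' @param n_repeats number of CV repetitions (default 1).
#' @param seed integer master seed.
#' @param n_workers parallel workers.
#' @return Object of class `smurf_cv_result`: `scores`
#'   (`n_samples x n_repeats` out-of-fold score matrix), `fold_of`
#'   (matching fold-index matrix), `metrics` (data.frame with one row
#'   per repeat x fold: `repeat_`, `fold`, `auroc`, `auprc`), and
#'   `summary` (mean and sd of each metric over all folds and repeats).
#' @export
run_cv <- function(dataset, h, nFolds = 10L, n_repeats = 1L, seed = 1L,
                   n_workers = 1L) {
  stopifnot(inherits(dataset, "smurf_dataset"))
  h <- as_hyperparams(h)
  n <- nrow(dataset$features)
  scores <- matrix(NA_real_, n, n_repeats)
  fold_of <- matrix(NA_integer_, n, n_repeats)
  metrics <- list()
  for (r in seq_len(n_repeats)) {
    rep_seed <- derive_seed(seed, r - 1L)
    folds <- make_folds(dataset, nFolds, rep_seed)
    fold_of[, r] <- folds$fold_of
    for (f in seq_len(nFolds) - 1L) {
      test_idx <- which(folds$fold_of == f)
      train_idx <- which(folds$fold_of != f)
      model <- smurf_train(subset_dataset(dataset, train_idx), h,
                           n_workers = n_workers,
                           master_seed = derive_seed(rep_seed, f + 1L))
      sc <- predict(model, dataset$features[test_idx, , drop = FALSE],
                    n_workers = n_workers)
      scores[test_idx, r] <- sc
      metrics[[length(metrics) + 1L]] <- data.frame(
        repeat_ = r, fold = f,
        auroc = auroc(sc, dataset$labels[test_idx]),
        auprc = auprc(sc, dataset$labels[test_idx])
      )
    }
  }
  metrics <- do.call(rbind, metrics)
  structure(
    list(
      scores = scores,
      fold_of = fold_of,
      metrics = metrics,
      summary = data.frame(
        metric = c("auroc", "auprc"),
        mean = c(mean(metrics$auroc), mean(metrics$auprc)),
        sd = c(stats::sd(metrics$auroc), stats::sd(metrics$auprc))
      )
    ),
    class = "smurf_cv_result"
  )
}

#' @export
print.smurf_cv_result <- function(x, ...) {
  cat("external CV: ", ncol(x$scores), " repeat(s) x ",
      max(x$metrics$fold) + 1L, " folds\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.4f (sd %.4f)\n", toupper(s$metric[i]),
                s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Nested cross-validation with per-fold hyper-parameter tuning
#'
#' For each external fold, hyper-parameters are selected by searching
#' `space` on the fold's training portion only (internal CV inside that
#' portion); the winning combination is then retrained on the full
#' training portion and scores the external test fold. No test-fold
#' sample ever participates in tuning — the returned `audit` records
#' the tuning indices so this can be checked.
#'
#' @param dataset a [smurf_dataset()].
#' @param space a `param_grid()` or `param_intervals()` space; grid
#'   spaces are searched exhaustively, interval spaces by Bayesian
#'   optimization.
#' @param nFolds_external,nFolds_internal external and internal fold
#'   counts (defaults 10 and 9).
#' @param seed integer master seed.
#' @param n_workers parallel workers.
#' @param ... passed on to [grid_search()] or [bayes_search()]
#'   (e.g. `max_iter`, `n_init`).
#' @return Object of class `smurf_nested_result`: `best_h` (list of
#'   per-external-fold [hyperparams()]), `metrics` (per-fold `auroc`
#'   and `auprc`), `scores` (out-of-fold score vector), `fold_of`,
#'   `tune_results`, and `audit` (per-fold list with `tune_idx` and
#'   `test_idx` sample indices).
#' @export
run_nested_tune <- function(dataset, space, nFolds_external = 10L,
                            nFolds_internal = 9L, seed = 1L,
                            n_workers = 1L, ...) {
  stopifnot(inherits(dataset, "smurf_dataset"),
            inherits(space, "smurf_param_space"))
  folds <- make_folds(dataset, nFolds_external, derive_seed(seed, 0L))
  n <- nrow(dataset$features)
  scores <- rep(NA_real_, n)
  best_h <- vector("list", nFolds_external)
  tune_results <- vector("list", nFolds_external)
  audit <- vector("list", nFolds_external)
  metrics <- list()
  for (f in seq_len(nFolds_external) - 1L) {
    test_idx <- which(folds$fold_of == f)
    train_idx <- which(folds$fold_of != f)
    sub <- subset_dataset(dataset, train_idx)
    fold_seed <- derive_seed(seed, f + 1L)
    tr <- if (space$type == "grid") {
      grid_search(space, sub, nFolds = nFolds_internal, seed = fold_seed,
                  n_workers = n_workers, ...)
    } else {
      bayes_search(space, sub, nFolds = nFolds_internal, seed = fold_seed,
                   n_workers = n_workers, ...)
    }
    tune_results[[f + 1L]] <- tr
    best_h[[f + 1L]] <- tr$best
    model <- smurf_train(sub, tr$best, n_workers = n_workers,
                         master_seed = derive_seed(fold_seed, 7L))
    sc <- predict(model, dataset$features[test_idx, , drop = FALSE],
                  n_workers = n_workers)
    scores[test_idx] <- sc
    audit[[f + 1L]] <- list(tune_idx = train_idx, test_idx = test_idx)
    metrics[[length(metrics) + 1L]] <- data.frame(
      fold = f,
      auroc = auroc(sc, dataset$labels[test_idx]),
      auprc = auprc(sc, dataset$labels[test_idx])
    )
  }
  structure(
    list(
      best_h = best_h,
      metrics = do.call(rbind, metrics),
      scores = scores,
      fold_of = folds$fold_of,
      tune_results = tune_results,
      audit = audit
    ),
    class = "smurf_nested_result"
  )
}

#' @export
print.smurf_nested_result <- function(x, ...) {
  cat("nested tuning over ", nrow(x$metrics), " external folds\n", sep = "")
  cat(sprintf("  mean AUROC %.4f, mean AUPRC %.4f\n",
              mean(x$metrics$auroc), mean(x$metrics$auprc)))
  invisible(x)
}

# ---- JSON-configured front end -------------------------------------------

KNOWN_CONFIG_KEYS <- c(
  "mode", "matrix_path", "labels_path", "band_path", "fold_path",
  "tsv_path", "h", "space", "nFolds_external", "nFolds_internal",
  "n_repeats", "seed", "n_workers", "out_dir", "band_aware", "synth",
  "model_path", "max_iter", "n_init", "quiet"
)

RUN_MODES <- c("train", "predict", "cv", "tune-grid", "tune-bayes",
               "generate")

#' Read and validate a JSON run configuration
#'
#' Unknown keys produce a warning, not an error; validation failures
#' are reported all at once.
#'
#' @param path path to a JSON file.
#' @return The validated configuration as a list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), KNOWN_CONFIG_KEYS)
  if (length(unknown) > 0L) {
    warning("ignoring unknown config keys: ",
            paste(unknown, collapse = ", "))
  }
  problems <- character(0)
  if (is.null(cfg$mode) || !cfg$mode %in% RUN_MODES) {
    problems <- c(problems, paste0("mode must be one of: ",
                                   paste(RUN_MODES, collapse = ", ")))
  }
  needs_data <- !identical(cfg$mode, "generate")
  if (needs_data && is.null(cfg$tsv_path) &&
      (is.null(cfg$matrix_path) || is.null(cfg$labels_path))) {
    problems <- c(problems,
                  "data required: either tsv_path or matrix_path + labels_path")
  }
  if (is.null(cfg$seed)) {
    problems <- c(problems, "seed is required")
  }
  if (identical(cfg$mode, "generate") && is.null(cfg$synth)) {
    problems <- c(problems, "generate mode requires a 'synth' block")
  }
  if (identical(cfg$mode, "predict") && is.null(cfg$model_path)) {
    problems <- c(problems, "predict mode requires model_path")
  }
  if (!is.null(cfg$mode) && cfg$mode %in% c("tune-grid", "tune-bayes") &&
      is.null(cfg$space)) {
    problems <- c(problems, "tuning modes require a 'space' block")
  }
  if (length(problems) > 0L) {
    stop_config("invalid configuration:\n  - ",
                paste(problems, collapse = "\n  - "))
  }
  cfg
}

load_config_dataset <- function(cfg) {
  if (!is.null(cfg$tsv_path)) {
    read_dataset_tsv(cfg$tsv_path)
  } else {
    read_dataset(cfg$matrix_path, cfg$labels_path,
                 band_path = cfg$band_path, fold_path = cfg$fold_path)
  }
}

config_space <- function(cfg) {
  sp <- lapply(cfg$space, as.integer)
  if (identical(cfg$mode, "tune-grid")) do.call(param_grid, sp)
  else do.call(param_intervals, sp)
}

log_msg <- function(quiet, ...) {
  if (!isTRUE(quiet)) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  }
}

write_provenance <- function(cfg, out_dir) {
  prov <- list(
    config = cfg,
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("smurfens"))
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Execute a validated run configuration
#'
#' Dispatches on `mode` and writes score files, metric tables (TSV),
#' a JSON summary and a provenance record under `out_dir`.
#'
#' @param cfg configuration list from [read_run_config()].
#' @return Invisibly, the mode-specific result object.
#' @export
run_config <- function(cfg) {
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  quiet <- isTRUE(cfg$quiet)
  write_provenance(cfg, out_dir)
  seed <- as.integer(cfg$seed)
  n_workers <- as.integer(cfg$n_workers %||% 1L)
  h <- if (!is.null(cfg$h)) do.call(hyperparams, lapply(cfg$h, as.integer))
       else hyperparams()

  result <- switch(
    cfg$mode,
    "generate" = {
      spec <- do.call(synth_spec, c(cfg$synth, list(seed = seed)))
      d <- generate_synth(spec)
      log_msg(quiet, "generated ", nrow(d$features), " samples (",
              n_positives(d), " positives)")
      write_dataset(d, file.path(out_dir, "matrix.txt"),
                    file.path(out_dir, "labels.txt"),
                    band_path = if (!is.null(d$band_ids))
                      file.path(out_dir, "bands.txt"))
      d
    },
    "train" = {
      d <- load_config_dataset(cfg)
      model <- smurf_train(d, h, n_workers = n_workers, master_seed = seed)
      save_model(model, file.path(out_dir, "model.rds"))
      log_msg(quiet, "trained ", h$nParts, "-part ensemble")
      model
    },
    "predict" = {
      d <- load_config_dataset(cfg)
      model <- load_model(cfg$model_path)
      sc <- predict(model, d, n_workers = n_workers)
      write_scores(sc, file.path(out_dir, "scores.txt"), d$sample_ids)
      sc
    },
    "cv" = {
      d <- load_config_dataset(cfg)
      res <- run_cv(d, h, nFolds = as.integer(cfg$nFolds_external %||% 10L),
                    n_repeats = as.integer(cfg$n_repeats %||% 1L),
                    seed = seed, n_workers = n_workers)
      for (r in seq_len(ncol(res$scores))) {
        write_scores(res$scores[, r],
                     file.path(out_dir, sprintf("scores_rep%d.txt", r)),
                     d$sample_ids)
      }
      utils::write.table(res$metrics, file.path(out_dir, "metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(summary = res$summary),
        file.path(out_dir, "summary.json"),
        auto_unbox = TRUE, pretty = TRUE, dataframe = "rows"
      )
      log_msg(quiet, sprintf("CV done: mean AUPRC %.4f",
                             res$summary$mean[res$summary$metric == "auprc"]))
      res
    },
    "tune-grid" = ,
    "tune-bayes" = {
      d <- load_config_dataset(cfg)
      space <- config_space(cfg)
      extra <- if (identical(cfg$mode, "tune-bayes")) {
        list(max_iter = as.integer(cfg$max_iter %||% 60L),
             n_init = as.integer(cfg$n_init %||% 10L))
      } else {
        list()
      }
      res <- do.call(run_nested_tune, c(
        list(d, space,
             nFolds_external = as.integer(cfg$nFolds_external %||% 10L),
             nFolds_internal = as.integer(cfg$nFolds_internal %||% 9L),
             seed = seed, n_workers = n_workers),
        extra
      ))
      write_scores(res$scores, file.path(out_dir, "scores.txt"),
                   d$sample_ids)
      utils::write.table(res$metrics, file.path(out_dir, "metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(best_per_fold = lapply(res$best_h, unclass),
             mean_auprc = mean(res$metrics$auprc),
             mean_auroc = mean(res$metrics$auroc)),
        file.path(out_dir, "summary.json"),
        auto_unbox = TRUE, pretty = TRUE
      )
      log_msg(quiet, sprintf("nested tuning done: mean AUPRC %.4f",
                             mean(res$metrics$auprc)))
      res
    }
  )
  invisible(result)
}

#' Command-line entry point
#'
#' Usage: `smurf <mode> --config cfg.json [--seed N] [--workers N]
#' [--out DIR] [--quiet]`. Command-line options override the
#' corresponding config keys. Exit codes: 0 success, 2 configuration
#' error, 3 data error, 4 runtime failure.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return The exit code, invisibly. A wrapper script should pass it to
#'   `quit(status = )`.
#' @export
smurf_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: smurf <", paste(RUN_MODES, collapse = "|"),
    "> --config cfg.json [--seed N] [--workers N] [--out DIR] [--quiet]"
  )
  code <- tryCatch({
    if (length(args) < 1L || !args[1L] %in% RUN_MODES) {
      message(usage)
      return(invisible(2L))
    }
    opt <- list(mode = args[1L])
    i <- 2L
    while (i <= length(args)) {
      a <- args[i]
      take <- function() {
        if (i + 1L > length(args)) stop_config("missing value for ", a)
        args[i + 1L]
      }
      switch(a,
        "--config" = { opt$config <- take(); i <- i + 2L },
        "--seed" = { opt$seed <- as.integer(take()); i <- i + 2L },
        "--workers" = { opt$workers <- as.integer(take()); i <- i + 2L },
        "--out" = { opt$out <- take(); i <- i + 2L },
        "--quiet" = { opt$quiet <- TRUE; i <- i + 1L },
        stop_config("unknown option: ", a)
      )
    }
    if (is.null(opt$config)) stop_config("--config is required")
    cfg <- jsonlite::fromJSON(opt$config, simplifyVector = TRUE)
    cfg$mode <- opt$mode
    if (!is.null(opt$seed)) cfg$seed <- opt$seed
    if (!is.null(opt$workers)) cfg$n_workers <- opt$workers
    if (!is.null(opt$out)) cfg$out_dir <- opt$out
    if (isTRUE(opt$quiet)) cfg$quiet <- TRUE
    # full validation happens on the merged configuration
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(cfg, tmp, auto_unbox = TRUE)
    cfg <- read_run_config(tmp)
    run_config(cfg)
    0L
  },
  smurfens_config_error = function(e) { message("config error: ",
                                                conditionMessage(e)); 2L },
  smurfens_data_error = function(e) { message("data error: ",
                                              conditionMessage(e)); 3L },
  error = function(e) { message("error: ", conditionMessage(e)); 4L })
  invisible(code)
}
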