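# Hyper-ensemble training and prediction: one probability forest per
# part of the negative partition, consensus by averaging.

MODEL_FORMAT_VERSION <- "smurf_ensemble/1"

#' Plan the assignment of partition parts to parallel workers
#'
#' Parts are grouped into `q` contiguous chunks whose sizes differ by at
#' most one; each chunk is processed by one worker. When `q > nParts`
#' the surplus chunks are empty. The chunking only affects scheduling,
#' never results.
#'
#' @param nParts positive integer, number of parts.
#' @param q positive integer, number of workers/chunks.
#' @return Object of class `smurf_chunkplan`: list of `q` integer vectors
#'   of 0-based part indices.
#' @examples
#' plan_chunks(10, 4) # sizes 3, 3, 2, 2
#' @export
plan_chunks <- function(nParts, q) {
  nParts <- as.integer(nParts)
  q <- as.integer(q)
  if (nParts < 1L) stop_config("nParts must be >= 1")
  if (q < 1L) stop_config("q must be >= 1")
  sizes <- rep(nParts %/% q, q)
  extra <- nParts %% q
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  chunks <- lapply(seq_len(q), function(i) {
    if (sizes[i] == 0L) integer(0) else (starts[i]:ends[i]) - 1L
  })
  structure(chunks, class = "smurf_chunkplan")
}

# Train the forest for one already-assembled part. The ranger seed is
# derived from the part seed so that refitting is reproducible and
# independent of which worker runs it.
train_part_forest <- function(part, h, master_seed) {
  part_seed <- derive_seed(master_seed, part$part_index)
  ranger::ranger(
    x = part$X,
    y = factor(part$y, levels = c(0L, 1L)),
    num.trees = h$nTrees,
    mtry = h$mTry,
    probability = TRUE,
    seed = derive_seed(part_seed, 2L),
    num.threads = 1L
  )
}

#' Train a hyper-ensemble of random forests
#'
#' Implements the four-step scheme for extreme class imbalance:
#' (1) partition the negatives into `h$nParts` disjoint parts; (2) build
#' each part's balanced training set — all positives, `fp` SMOTE
#' synthetics per positive, and `ratio * (1 + fp) * n_pos` undersampled
#' negatives; (3) fit one probability forest (`nTrees` trees, `mTry`
#' split features) per part; (4) at prediction time, average the
#' per-forest positive-class probabilities.
#'
#' Every per-part random draw is seeded by a value derived
#' deterministically from `(master_seed, part_index)`, so the fitted
#' model — and therefore every downstream score — is identical for any
#' `n_workers`.
#'
#' @param dataset a [smurf_dataset()] with at least one positive and at
#'   least `h$nParts` negatives.
#' @param h a [hyperparams()] object (or list coercible to one).
#' @param n_workers positive integer, parallel workers (forked
#'   processes; falls back to sequential where forking is unavailable).
#' @param master_seed integer master seed.
#' @return Object of class `smurf_ensemble`: list with `forests`,
#'   `h`, `master_seed`, `n_features`, `training_meta` (per-part class
#'   counts).
#' @seealso [predict.smurf_ensemble()], [save_model()]
#' @export
smurf_train <- function(dataset, h, n_workers = 1L, master_seed = 1L) {
  stopifnot(inherits(dataset, "smurf_dataset"))
  h <- as_hyperparams(h)
  n_workers <- as.integer(n_workers)
  if (n_workers < 1L) stop_config("n_workers must be >= 1")
  check_feasible(dataset, h)

  parts_idx <- partition_negatives(dataset, h$nParts,
                                   derive_seed(master_seed, 0L))
  plan <- plan_chunks(h$nParts, n_workers)

  fit_chunk <- function(chunk) {
    lapply(chunk, function(i) {
      part <- assemble_part(dataset, parts_idx[[i + 1L]], h,
                            seed = master_seed, part_index = i)
      list(
        forest = train_part_forest(part, h, master_seed),
        meta = c(part = i, table(part$provenance))
      )
    })
  }

  fitted <- if (n_workers == 1L || .Platform$OS.type == "windows") {
    lapply(plan, fit_chunk)
  } else {
    parallel::mclapply(plan, fit_chunk, mc.cores = n_workers,
                       mc.preschedule = FALSE)
  }
  fitted <- unlist(fitted, recursive = FALSE)
  # chunks are contiguous blocks of 0..nParts-1, so flattening restores
  # part order
  meta <- do.call(rbind, lapply(fitted, `[[`, "meta"))
  structure(
    list(
      forests = lapply(fitted, `[[`, "forest"),
      h = h,
      master_seed = as.integer(master_seed),
      n_features = ncol(dataset$features),
      feature_names = colnames(dataset$features),
      training_meta = meta
    ),
    class = "smurf_ensemble"
  )
}

#' @export
print.smurf_ensemble <- function(x, ...) {
  cat("smurf_ensemble: ", length(x$forests), " forests x ", x$h$nTrees,
      " trees (mTry = ", x$h$mTry, "), ", x$n_features, " features\n",
      sep = "")
  invisible(x)
}

#' Consensus prediction of a hyper-ensemble
#'
#' The score of a sample is the arithmetic mean over the `nParts`
#' forests of that forest's positive-class probability (itself the mean
#' over trees of the terminal-node positive-class proportion). Scores
#' lie in `[0, 1]`.
#'
#' @param object a fitted `smurf_ensemble`.
#' @param newdata numeric matrix (or [smurf_dataset()]) with
#'   `n_features` columns.
#' @param n_workers positive integer, parallel workers; results are
#'   identical for any value.
#' @param ... unused.
#' @return Numeric vector of scores, one per row of `newdata`.
#' @export
predict.smurf_ensemble <- function(object, newdata, n_workers = 1L, ...) {
  X <- if (inherits(newdata, "smurf_dataset")) newdata$features else
    as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop_data("newdata has ", ncol(X), " features; model expects ",
              object$n_features)
  }
  colnames(X) <- object$feature_names
  forest_score <- function(f) {
    p <- stats::predict(f, data = X, num.threads = 1L)$predictions
    p[, "1"]
  }
  n_workers <- as.integer(n_workers)
  scores <- if (n_workers > 1L && .Platform$OS.type != "windows") {
    plan <- plan_chunks(length(object$forests), n_workers)
    out <- parallel::mclapply(plan, function(chunk) {
      lapply(chunk, function(i) forest_score(object$forests[[i + 1L]]))
    }, mc.cores = n_workers, mc.preschedule = FALSE)
    unlist(out, recursive = FALSE)
  } else {
    lapply(object$forests, forest_score)
  }
  Reduce(`+`, scores) / length(scores)
}

#' Save and restore a fitted hyper-ensemble
#'
#' The archive embeds a format-version string; loading a file written by
#' an incompatible version (or not by [save_model()] at all) fails.
#'
#' @param model a `smurf_ensemble`.
#' @param path file path.
#' @return `load_model` returns the restored `smurf_ensemble`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "smurf_ensemble"))
  saveRDS(list(format = MODEL_FORMAT_VERSION, model = model), path)
  invisible(NULL)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_data("model file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop_data("corrupt model file: ", path))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT_VERSION)) {
    stop_data("not a compatible model file (expected format ",
              MODEL_FORMAT_VERSION, "): ", path)
  }
  obj$model
}
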