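# Hyper-parameter auto-tuning over the discrete 6-dimensional space
# (nParts, fp, ratio, k, nTrees, mTry). Each candidate is scored by
# internal cross-validation, maximizing AUPRC. Two strategies:
# exhaustive grid search, and Bayesian optimization with a Gaussian
# process surrogate and expected-improvement acquisition.

PARAM_NAMES <- c("nParts", "fp", "ratio", "k", "nTrees", "mTry")

#' Hyper-parameter search spaces
#'
#' `param_grid()` takes an explicit value list per parameter and defines
#' an exhaustive grid; `param_intervals()` takes inclusive integer
#' bounds `c(lower, upper)` per parameter and defines the integer
#' lattice searched by Bayesian optimization. A scalar fixes the
#' parameter in either form.
#'
#' @param nParts,fp,ratio,k,nTrees,mTry value vector (`param_grid`) or
#'   `c(lower, upper)` bounds (`param_intervals`).
#' @return Object of class `smurf_param_space` with `type` `"grid"` or
#'   `"intervals"`.
#' @examples
#' param_grid(nParts = c(10, 50), fp = c(1, 2), ratio = c(1, 2, 5))
#' param_intervals(nParts = c(10, 300), fp = c(1, 10))
#' @export
param_grid <- function(nParts = 100, fp = 2, ratio = 3, k = 5,
                       nTrees = 10, mTry = 5) {
  axes <- list(nParts = nParts, fp = fp, ratio = ratio, k = k,
               nTrees = nTrees, mTry = mTry)
  for (nm in PARAM_NAMES) {
    v <- axes[[nm]]
    if (length(v) < 1L || anyNA(v) || any(v != round(v))) {
      stop_config(nm, ": grid axis must be a non-empty integer vector")
    }
    axes[[nm]] <- as.integer(sort(unique(v)))
  }
  structure(list(type = "grid", axes = axes), class = "smurf_param_space")
}

#' @rdname param_grid
#' @export
param_intervals <- function(nParts = c(10, 300), fp = c(1, 10),
                            ratio = c(1, 10), k = 5, nTrees = c(10, 100),
                            mTry = c(2, 10)) {
  axes <- list(nParts = nParts, fp = fp, ratio = ratio, k = k,
               nTrees = nTrees, mTry = mTry)
  for (nm in PARAM_NAMES) {
    v <- axes[[nm]]
    if (length(v) == 1L) v <- c(v, v)
    if (length(v) != 2L || anyNA(v) || any(v != round(v)) || v[1L] > v[2L]) {
      stop_config(nm, ": interval must be c(lower, upper) with ",
                  "lower <= upper")
    }
    axes[[nm]] <- as.integer(v)
  }
  structure(list(type = "intervals", axes = axes),
            class = "smurf_param_space")
}

#' @export
print.smurf_param_space <- function(x, ...) {
  cat("parameter space (", x$type, "):\n", sep = "")
  for (nm in PARAM_NAMES) {
    v <- x$axes[[nm]]
    cat("  ", nm, ": ",
        if (x$type == "grid") paste0("{", paste(v, collapse = ", "), "}")
        else paste0("[", v[1L], ", ", v[2L], "]"),
        "\n", sep = "")
  }
  invisible(x)
}

#' Enumerate every combination of a grid space
#'
#' Cartesian product in the fixed axis order nParts, fp, ratio, k,
#' nTrees, mTry (the first axis varying fastest).
#'
#' @param space a `param_grid()` space.
#' @return List of [hyperparams()] objects of length equal to the
#'   product of the axis sizes.
#' @export
enumerate_grid <- function(space) {
  stopifnot(inherits(space, "smurf_param_space"))
  if (space$type != "grid") {
    stop_config("enumerate_grid requires explicit value lists, not ",
                "intervals; use param_grid()")
  }
  combos <- expand.grid(space$axes, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) do.call(hyperparams, combos[i, ]))
}

#' Internal cross-validation AUPRC of one hyper-parameter combination
#'
#' Builds `nFolds` internal folds (band-aware when the dataset carries
#' band identifiers and has enough distinct bands, stratified
#' otherwise), trains a hyper-ensemble on each training split and
#' scores the held-out fold; returns the mean AUPRC across folds.
#' An infeasible combination (e.g. `nParts` exceeding a split's
#' negatives) yields `-Inf` with attribute `failed = TRUE`, never an
#' exception, so a search can record it and move on.
#'
#' @param dataset a [smurf_dataset()].
#' @param h a [hyperparams()] object.
#' @param nFolds internal fold count (>= 2).
#' @param seed integer seed; folds and per-fold training are derived
#'   from it.
#' @param n_workers parallel workers for ensemble training.
#' @return Mean AUPRC, with attributes `per_fold` (numeric vector) and
#'   `failed` (logical).
#' @export
internal_cv_auprc <- function(dataset, h, nFolds, seed, n_workers = 1L) {
  stopifnot(inherits(dataset, "smurf_dataset"))
  h <- as_hyperparams(h)
  folds <- make_folds(dataset, nFolds, seed)
  per_fold <- rep(NA_real_, nFolds)
  for (f in seq_len(nFolds) - 1L) {
    test_idx <- which(folds$fold_of == f)
    train_idx <- which(folds$fold_of != f)
    res <- tryCatch({
      sub <- subset_dataset(dataset, train_idx)
      model <- smurf_train(sub, h, n_workers = n_workers,
                           master_seed = derive_seed(seed, f + 1L))
      scores <- predict(model, dataset$features[test_idx, , drop = FALSE],
                        n_workers = n_workers)
      auprc(scores, dataset$labels[test_idx])
    }, smurfens_config_error = function(e) NA_real_,
       smurfens_data_error = function(e) NA_real_)
    per_fold[f + 1L] <- res
  }
  failed <- anyNA(per_fold)
  out <- if (failed) -Inf else mean(per_fold)
  attr(out, "per_fold") <- per_fold
  attr(out, "failed") <- failed
  out
}

# Band-aware folds when possible, stratified otherwise.
make_folds <- function(dataset, nFolds, seed) {
  if (!is.null(dataset$band_ids) &&
      length(unique(dataset$band_ids)) >= nFolds) {
    band_aware_kfold(dataset$band_ids, dataset$labels, nFolds, seed)
  } else {
    stratified_kfold(dataset$labels, nFolds, seed)
  }
}

#' Subset a dataset by sample index
#'
#' Keeps features, labels and any annotations aligned.
#'
#' @param dataset a [smurf_dataset()].
#' @param idx integer vector of row indices to keep.
#' @return A [smurf_dataset()] restricted to `idx`.
#' @export
subset_dataset <- function(dataset, idx) {
  smurf_dataset(
    dataset$features[idx, , drop = FALSE],
    dataset$labels[idx],
    band_ids = dataset$band_ids[idx],
    category_ids = dataset$category_ids[idx],
    sample_ids = dataset$sample_ids[idx]
  )
}

new_tune_result <- function(evaluations, per_fold, strategy) {
  best_i <- which.max(evaluations$mean_auprc)[1L]
  structure(
    list(
      evaluations = evaluations,
      per_fold = per_fold,
      best = do.call(hyperparams,
                     as.list(evaluations[best_i, PARAM_NAMES])),
      best_auprc = evaluations$mean_auprc[best_i],
      n_evaluations = nrow(evaluations),
      strategy = strategy
    ),
    class = "smurf_tune_result"
  )
}

#' @export
print.smurf_tune_result <- function(x, ...) {
  cat("tuning (", x$strategy, "): ", x$n_evaluations,
      " evaluations, best mean AUPRC = ", signif(x$best_auprc, 4), "\n",
      sep = "")
  print(x$best)
  invisible(x)
}

#' Exhaustive grid search
#'
#' Evaluates every combination of the grid by internal-CV AUPRC and
#' returns the argmax (ties: first encountered in enumeration order).
#'
#' @param space a `param_grid()` space.
#' @param dataset a [smurf_dataset()].
#' @param nFolds internal fold count.
#' @param seed integer seed shared by every evaluation, so all
#'   combinations face identical folds.
#' @param n_workers parallel workers for ensemble training.
#' @param objective optional replacement objective
#'   `function(h) -> numeric`, used in place of internal CV (for
#'   deterministic search diagnostics).
#' @return Object of class `smurf_tune_result` with one row per
#'   combination in `evaluations` (columns: the six parameters,
#'   `mean_auprc`, `failed`), `per_fold` (list of per-fold AUPRC
#'   vectors), `best`, `n_evaluations`, `strategy`.
#' @export
grid_search <- function(space, dataset, nFolds = 9L, seed = 1L,
                        n_workers = 1L, objective = NULL) {
  grid <- enumerate_grid(space)
  obj <- objective %||% function(h) {
    internal_cv_auprc(dataset, h, nFolds, seed, n_workers)
  }
  vals <- lapply(grid, obj)
  evaluations <- cbind(
    do.call(rbind.data.frame, lapply(grid, function(h) as.list(unclass(h)))),
    mean_auprc = vapply(vals, as.numeric, 0),
    failed = vapply(vals, function(v) isTRUE(attr(v, "failed")), FALSE)
  )
  per_fold <- lapply(vals, function(v) attr(v, "per_fold"))
  new_tune_result(evaluations, per_fold, "grid")
}

# ---- Bayesian optimization ------------------------------------------------

lattice_size <- function(axes) {
  prod(vapply(axes, function(b) b[2L] - b[1L] + 1, 0))
}

# Enumerate a small lattice exhaustively, as a matrix of rows.
enumerate_lattice <- function(axes) {
  as.matrix(expand.grid(lapply(axes, function(b) b[1L]:b[2L]),
                        KEEP.OUT.ATTRS = FALSE))
}

sample_lattice <- function(axes, n) {
  m <- vapply(axes, function(b) {
    if (b[1L] == b[2L]) rep(b[1L], n)
    else sample(b[1L]:b[2L], n, replace = TRUE)
  }, numeric(n))
  matrix(m, nrow = n, dimnames = list(NULL, names(axes)))
}

point_key <- function(m) apply(m, 1L, paste, collapse = "/")

# Normalize lattice coordinates to [0,1] per axis (constant axes drop
# to 0) for the GP kernel.
normalize_points <- function(m, axes) {
  for (j in seq_along(axes)) {
    b <- axes[[j]]
    w <- b[2L] - b[1L]
    m[, j] <- if (w == 0) 0 else (m[, j] - b[1L]) / w
  }
  m
}

# Gaussian-process posterior with a squared-exponential kernel on
# normalized coordinates; fixed length-scale, small nugget. Returns
# predictive mean and standard deviation at `Xnew`.
gp_posterior <- function(X, y, Xnew, lengthscale = 0.3, nugget = 1e-6) {
  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y < 1e-12) sd_y <- 1
  z <- (y - mu_y) / sd_y
  sqdist <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  }
  K <- exp(-pmax(sqdist(X, X), 0) / (2 * lengthscale^2))
  diag(K) <- diag(K) + nugget
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, z, transpose = TRUE))
  Ks <- exp(-pmax(sqdist(Xnew, X), 0) / (2 * lengthscale^2))
  mu <- Ks %*% alpha
  v <- backsolve(L, t(Ks), transpose = TRUE)
  var <- pmax(1 - colSums(v^2), 0)
  list(mean = as.numeric(mu) * sd_y + mu_y, sd = sqrt(var) * sd_y)
}

expected_improvement <- function(mu, sd, best) {
  ei <- numeric(length(mu))
  pos <- sd > 1e-12
  d <- mu[pos] - best
  zz <- d / sd[pos]
  ei[pos] <- d * stats::pnorm(zz) + sd[pos] * stats::dnorm(zz)
  ei
}

#' Bayesian optimization over the hyper-parameter lattice
#'
#' Starts from `n_init` random lattice points, then repeatedly fits a
#' Gaussian-process surrogate (squared-exponential kernel on
#' unit-normalized coordinates) to the evaluation history and evaluates
#' the candidate maximizing expected improvement over a random lattice
#' pool (exhaustive when the lattice is small). Stops at `max_iter`
#' total evaluations, or earlier when the best value has not improved
#' by more than `tol` for `patience` consecutive proposals, or when the
#' lattice is exhausted. Duplicate proposals are never evaluated.
#' Failed evaluations are kept in the history but excluded from
#' surrogate fitting; a surrogate failure falls back to a random
#' proposal.
#'
#' @param space a `param_intervals()` space.
#' @param dataset a [smurf_dataset()].
#' @param nFolds internal fold count.
#' @param max_iter maximum total evaluations (default 60).
#' @param n_init initial random evaluations (default 10).
#' @param seed integer seed for the whole search.
#' @param n_workers parallel workers for ensemble training.
#' @param tol,patience early-stopping rule: stop after `patience`
#'   consecutive proposals improving the best by no more than `tol`.
#' @param pool_size candidate pool per acquisition step.
#' @param objective optional replacement objective
#'   `function(h) -> numeric` (see [grid_search()]).
#' @return A `smurf_tune_result` with `strategy = "bayes"`.
#' @export
bayes_search <- function(space, dataset = NULL, nFolds = 9L, max_iter = 60L,
                         n_init = 10L, seed = 1L, n_workers = 1L,
                         tol = 1e-4, patience = 10L, pool_size = 2048L,
                         objective = NULL) {
  stopifnot(inherits(space, "smurf_param_space"))
  if (space$type != "intervals") {
    stop_config("bayes_search requires interval axes; use param_intervals()")
  }
  if (max_iter < 1L) stop_config("max_iter must be >= 1")
  n_init <- min(n_init, max_iter)
  axes <- space$axes
  total <- lattice_size(axes)
  obj <- objective %||% function(h) {
    internal_cv_auprc(dataset, h, nFolds, seed, n_workers)
  }

  small <- total <= pool_size
  full <- if (small) enumerate_lattice(axes)
  history <- matrix(numeric(0), ncol = 6L,
                    dimnames = list(NULL, PARAM_NAMES))
  vals <- list()

  evaluate <- function(pt) {
    h <- do.call(hyperparams, as.list(pt))
    obj(h)
  }

  with_seed(seed, {
    # initial design: distinct random lattice points
    n_init_eff <- min(n_init, total)
    init <- if (small) {
      full[sample.int(nrow(full), n_init_eff), , drop = FALSE]
    } else {
      pts <- sample_lattice(axes, n_init_eff * 4L)
      pts <- pts[!duplicated(point_key(pts)), , drop = FALSE]
      pts[seq_len(min(n_init_eff, nrow(pts))), , drop = FALSE]
    }
    for (i in seq_len(nrow(init))) {
      history <- rbind(history, init[i, ])
      vals[[length(vals) + 1L]] <- evaluate(init[i, ])
    }

    best_val <- max(c(-Inf, vapply(vals, as.numeric, 0)))
    stall <- 0L
    while (nrow(history) < max_iter && nrow(history) < total &&
           stall < patience) {
      cand <- if (small) full else sample_lattice(axes, pool_size)
      cand <- cand[!point_key(cand) %in% point_key(history), , drop = FALSE]
      if (nrow(cand) == 0L) break
      finite <- is.finite(vapply(vals, as.numeric, 0))
      proposal <- NULL
      if (sum(finite) >= 2L) {
        proposal <- tryCatch({
          gp <- gp_posterior(
            normalize_points(history[finite, , drop = FALSE], axes),
            vapply(vals[finite], as.numeric, 0),
            normalize_points(cand, axes)
          )
          ei <- expected_improvement(gp$mean, gp$sd, best_val)
          cand[which.max(ei), ]
        }, error = function(e) NULL)
      }
      if (is.null(proposal)) {
        proposal <- cand[sample.int(nrow(cand), 1L), ]
      }
      history <- rbind(history, proposal)
      v <- evaluate(proposal)
      vals[[length(vals) + 1L]] <- v
      if (as.numeric(v) > best_val + tol) {
        best_val <- as.numeric(v)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
    }
  })

  evaluations <- cbind(
    as.data.frame(history),
    mean_auprc = vapply(vals, as.numeric, 0),
    failed = vapply(vals, function(v) isTRUE(attr(v, "failed")), FALSE)
  )
  per_fold <- lapply(vals, function(v) attr(v, "per_fold"))
  new_tune_result(evaluations, per_fold, "bayes")
}

#' Write a tuning log as TSV
#'
#' One row per evaluation: the six parameters, the mean AUPRC and the
#' failure flag.
#'
#' @param result a `smurf_tune_result`.
#' @param path output path.
#' @return Invisibly, `NULL`.
#' @export
write_tuning_log <- function(result, path) {
  stopifnot(inherits(result, "smurf_tune_result"))
  utils::write.table(result$evaluations, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
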