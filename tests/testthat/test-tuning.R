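test_that("grid enumeration is the Cartesian product in fixed order", {
  sp <- param_grid(nParts = c(2, 4), fp = c(0, 1), ratio = 1, k = 3,
                   nTrees = 5, mTry = 2)
  grid <- enumerate_grid(sp)
  expect_length(grid, 4L)
  expect_equal(vapply(grid, `[[`, 0L, "nParts"), c(2L, 4L, 2L, 4L))
  expect_equal(vapply(grid, `[[`, 0L, "fp"), c(0L, 0L, 1L, 1L))

  single <- enumerate_grid(param_grid(nParts = 3, fp = 1, ratio = 1, k = 3,
                                      nTrees = 5, mTry = 2))
  expect_length(single, 1L)

  expect_error(enumerate_grid(param_intervals(nParts = c(1, 5))),
               "param_grid")
})

test_that("internal CV scores a combination and flags infeasible ones", {
  d <- tiny_dataset(n = 240, n_pos = 20, effect = 10, seed = 71)
  h <- hyperparams(nParts = 3, fp = 1, ratio = 2, k = 3, nTrees = 10,
                   mTry = 2)
  v <- internal_cv_auprc(d, h, nFolds = 2L, seed = 5)
  expect_length(attr(v, "per_fold"), 2L)
  expect_false(attr(v, "failed"))
  expect_gt(as.numeric(v), 0.95) # effect size 10 separates almost perfectly
  # determinism
  expect_equal(as.numeric(internal_cv_auprc(d, h, nFolds = 2L, seed = 5)),
               as.numeric(v))

  # nParts larger than any split's negatives: failed, not an exception
  bad <- hyperparams(nParts = 500, fp = 1, ratio = 1, k = 3, nTrees = 5,
                     mTry = 2)
  vb <- internal_cv_auprc(d, bad, nFolds = 2L, seed = 5)
  expect_identical(as.numeric(vb), -Inf)
  expect_true(attr(vb, "failed"))
})

test_that("grid search returns the exact argmax of its evaluations", {
  # deterministic mock objective: brute-force argmax is known
  sp <- param_grid(nParts = c(2, 4, 6), fp = c(0, 1, 2), ratio = 1, k = 3,
                   nTrees = 5, mTry = 2)
  f <- function(h) -abs(h$nParts - 4) - abs(h$fp - 1)
  res <- grid_search(sp, objective = f)
  expect_equal(res$n_evaluations, 9L)
  expect_equal(res$best$nParts, 4L)
  expect_equal(res$best$fp, 1L)
  expect_true(all(res$best_auprc >= res$evaluations$mean_auprc))

  # on data: best recorded evaluation is the returned best
  d <- tiny_dataset(n = 200, n_pos = 15, effect = 3, seed = 81)
  sp2 <- param_grid(nParts = 2, fp = c(0, 2), ratio = 2, k = 3, nTrees = 8,
                    mTry = 2)
  res2 <- grid_search(sp2, d, nFolds = 2L, seed = 7)
  expect_equal(res2$n_evaluations, 2L)
  expect_equal(res2$best_auprc, max(res2$evaluations$mean_auprc))
})

test_that("Bayesian search respects lattice, budget and no-duplicate rules", {
  sp <- param_intervals(nParts = c(1, 6), fp = c(0, 4), ratio = c(1, 3),
                        k = 5, nTrees = 10, mTry = 2)
  f <- function(h) -((h$nParts - 3)^2 + (h$fp - 2)^2 + (h$ratio - 2)^2) / 10
  res <- bayes_search(sp, max_iter = 20L, n_init = 6L, seed = 3,
                      objective = f)
  expect_lte(res$n_evaluations, 20L)
  ev <- res$evaluations
  # all points on the lattice
  expect_true(all(ev$nParts %in% 1:6 & ev$fp %in% 0:4 & ev$ratio %in% 1:3))
  expect_true(all(ev$k == 5L & ev$nTrees == 10L & ev$mTry == 2L))
  # no duplicate evaluations
  keys <- apply(ev[, c("nParts", "fp", "ratio")], 1L, paste, collapse = "/")
  expect_equal(anyDuplicated(keys), 0L)

  # all-singleton intervals: exactly one evaluation
  sp1 <- param_intervals(nParts = 3, fp = 1, ratio = 1, k = 3, nTrees = 5,
                         mTry = 2)
  res1 <- bayes_search(sp1, max_iter = 10L, n_init = 5L, seed = 1,
                       objective = f)
  expect_equal(res1$n_evaluations, 1L)
  expect_equal(res1$best$nParts, 3L)
})

test_that("Bayesian search locates a known optimum on a small lattice", {
  sp <- param_intervals(nParts = c(1, 5), fp = c(0, 4), ratio = 1, k = 5,
                        nTrees = 10, mTry = 1)
  f <- function(h) 1 - 0.1 * ((h$nParts - 4)^2 + (h$fp - 3)^2) +
    0.01 * sin(h$nParts + h$fp)
  hits <- 0L
  for (s in 1:5) {
    r <- bayes_search(sp, max_iter = 15L, n_init = 6L, seed = s,
                      objective = f)
    hits <- hits + (r$best$nParts == 4L && r$best$fp == 3L)
  }
  expect_gte(hits, 4L)
})

test_that("tuning logs write one TSV row per evaluation", {
  sp <- param_grid(nParts = c(2, 3), fp = 0, ratio = 1, k = 3, nTrees = 5,
                   mTry = 2)
  res <- grid_search(sp, objective = function(h) h$nParts / 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tuning_log(res, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("nParts", "mean_auprc", "failed") %in% names(tab)))
})
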