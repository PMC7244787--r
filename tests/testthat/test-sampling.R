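test_that("negative partition is disjoint, covering, and near-equal sized", {
  d <- tiny_dataset(n = 110, n_pos = 10, seed = 3)
  neg <- which(d$labels == 0L) # 100 negatives

  p1 <- partition_negatives(d, 1L, seed = 9)
  expect_length(p1, 1L)
  expect_setequal(p1[[1]], neg)

  for (nParts in c(3L, 7L, 100L)) {
    parts <- partition_negatives(d, nParts, seed = 9)
    sizes <- lengths(parts)
    expect_lte(max(sizes) - min(sizes), 1L)
    all_idx <- unlist(parts)
    expect_equal(length(all_idx), length(unique(all_idx))) # disjoint
    expect_setequal(all_idx, neg)                          # covering
  }

  expect_error(partition_negatives(d, 101L, seed = 1), "negatives")
  # determinism
  expect_identical(partition_negatives(d, 5L, seed = 4),
                   partition_negatives(d, 5L, seed = 4))
})

test_that("SMOTE synthesizes fp rows per positive on k-NN segments", {
  # fp = 2 with 5 positives: two novel examples per positive
  set.seed(1)
  P <- matrix(rnorm(5 * 3), 5, 3)
  out <- smote_oversample(P, fp = 2, k = 2, seed = 7)
  expect_equal(nrow(out), 10L)

  expect_equal(nrow(smote_oversample(P, fp = 0, k = 2, seed = 7)), 0L)
  expect_error(smote_oversample(P[1, , drop = FALSE], fp = 1, k = 1, seed = 1),
               ">=2 positives")

  # collinear pair: all synthetics stay on the segment, second coord 0
  P2 <- rbind(c(0, 0), c(1, 0))
  s2 <- smote_oversample(P2, fp = 3, k = 1, seed = 5)
  expect_equal(nrow(s2), 6L)
  expect_true(all(s2[, 2] == 0))
  expect_true(all(s2[, 1] >= 0 & s2[, 1] <= 1))

  # geometric oracle: every synthetic row lies on some p -> kNN(p) segment
  set.seed(2)
  P3 <- matrix(rnorm(12 * 4), 12, 4)
  s3 <- smote_oversample(P3, fp = 3, k = 4, seed = 11)
  expect_true(all(apply(s3, 1L, on_some_segment, P = P3, k = 4)))

  # k clamps to n_pos - 1
  s4 <- smote_oversample(P2, fp = 2, k = 10, seed = 3)
  expect_equal(nrow(s4), 4L)
})

test_that("undersampling takes min(target, available) uniformly", {
  idx <- 101:200
  expect_length(undersample_negatives(idx, 0L, seed = 1), 0L)
  expect_setequal(undersample_negatives(11:15, 50L, seed = 1), 11:15)
  s <- undersample_negatives(idx, 60L, seed = 2)
  expect_length(s, 60L)
  expect_true(all(s %in% idx))
  expect_equal(length(unique(s)), 60L)
  expect_identical(undersample_negatives(idx, 60L, seed = 2), s)
})

test_that("part assembly obeys the fp/ratio balance laws", {
  d <- tiny_dataset(n = 1000, n_pos = 100, seed = 5)
  parts <- partition_negatives(d, 2L, seed = 1)

  # fp=1, ratio=1: 100 original + 100 synthetic positives + 200 negatives
  h <- hyperparams(nParts = 2, fp = 1, ratio = 1, k = 5, nTrees = 5, mTry = 2)
  ps <- assemble_part(d, parts[[1]], h, seed = 9, part_index = 0L)
  tab <- table(ps$provenance)
  expect_equal(unname(tab[["original_positive"]]), 100L)
  expect_equal(unname(tab[["synthetic_positive"]]), 100L)
  expect_equal(unname(tab[["sampled_negative"]]), 200L)
  expect_equal(nrow(ps$X), 400L)
  expect_equal(sum(ps$y == 1L), 200L)
  # exact ratio when negatives suffice
  expect_equal(sum(ps$y == 0L) / sum(ps$y == 1L), h$ratio)

  # fp=0 disables SMOTE
  h0 <- hyperparams(nParts = 2, fp = 0, ratio = 1, nTrees = 5, mTry = 2)
  ps0 <- assemble_part(d, parts[[1]], h0, seed = 9)
  expect_equal(sum(ps0$provenance == "synthetic_positive"), 0L)
  expect_equal(sum(ps0$y == 0L), 100L)

  # shortfall: part smaller than target keeps all part negatives
  d3 <- tiny_dataset(n = 13, n_pos = 3, seed = 8)
  h3 <- hyperparams(nParts = 5, fp = 1, ratio = 1, k = 2, nTrees = 5,
                    mTry = 2)
  parts3 <- partition_negatives(d3, 5L, seed = 1)
  ps3 <- assemble_part(d3, parts3[[1]], h3, seed = 2)
  expect_equal(sum(ps3$y == 1L), 6L)               # 3 original + 3 synthetic
  expect_equal(sum(ps3$y == 0L), length(parts3[[1]])) # all 2 available

  # determinism in (seed, part_index)
  expect_identical(assemble_part(d, parts[[2]], h, seed = 9, part_index = 1L),
                   assemble_part(d, parts[[2]], h, seed = 9, part_index = 1L))
  ps_a <- assemble_part(d, parts[[1]], h, seed = 9, part_index = 0L)
  ps_b <- assemble_part(d, parts[[1]], h, seed = 9, part_index = 1L)
  expect_false(identical(ps_a$X, ps_b$X))
})
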