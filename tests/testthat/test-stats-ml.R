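test_that("rank-sum p-values match exact enumeration", {
  # complete separation of two groups of 8: the two most extreme of the
  # C(16, 8) equally likely rank configurations
  a <- 1:8; b <- 101:108
  res <- compare_group_scores(a, b, test = "rank_sum")
  expect_equal(res$p_value, 2 / choose(16, 8), tolerance = 1e-12)

  res_id <- compare_group_scores(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res_id$p_value, 1)

  # random small configurations against enumeration over rank assignments
  set.seed(5)
  for (rep in 1:5) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    x <- sample(100, n1); y <- sample(100, n2)
    while (any(x %in% y)) y <- sample(100, n2)
    got <- compare_group_scores(x, y, test = "rank_sum")$p_value
    # enumerate all rank splits: two-sided p of the rank-sum statistic
    all_ranks <- rank(c(x, y))
    w_obs <- sum(all_ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
    splits <- utils::combn(n1 + n2, n1, simplify = FALSE)
    ws <- vapply(splits, function(s) sum(seq_len(n1 + n2)[s]) -
                   n1 * (n1 + 1) / 2, numeric(1))
    mu <- n1 * n2 / 2
    want <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("paired signed-rank detects a uniform shift over 22 functions", {
  set.seed(9)
  base <- runif(22)
  res <- compare_group_scores(base, base - 0.1, test = "signed_rank")
  expect_lt(res$p_value, 0.05)
  expect_error(compare_group_scores(1:5, 1:4, test = "signed_rank"),
               "equal-length")
})

test_that("missing scores are dropped and reported", {
  res <- compare_group_scores(c(1, 2, NA, 4), c(5, NA, 7, 8, 9))
  expect_equal(res$n_a, 3)
  expect_equal(res$n_b, 4)
  expect_equal(res$n_dropped, 2)
  expect_error(compare_group_scores(c(NA, NA), c(1, 2)), "at least 2")
})

test_that("rank-based AUC behaves like the Mann-Whitney statistic", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  set.seed(3)
  sc <- rnorm(20); lab <- rep(c(0, 1), 10)
  expect_equal(compute_auc(-sc, lab), 1 - compute_auc(sc, lab))
  # invariant under strictly monotone transforms
  expect_equal(compute_auc(exp(sc), lab), compute_auc(sc, lab))
  expect_equal(compute_auc(rank(sc), lab), compute_auc(sc, lab))
  # against an independent implementation
  proc_auc <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                             direction = "<")))
  expect_equal(compute_auc(sc, lab), proc_auc, tolerance = 1e-12)
  expect_error(compute_auc(sc, rep(1, 20)), "both classes")
})

test_that("the SVM classifier separates a separable functionality table", {
  set.seed(31)
  n <- 16
  X <- cbind(f1 = c(rnorm(8, 3), rnorm(8, -3)),
             f2 = c(rnorm(8, -2), rnorm(8, 2)),
             noise = rnorm(n))
  rownames(X) <- sprintf("s%d", 1:n)
  y <- stats::setNames(rep(c("high", "low"), each = 8), rownames(X))
  res <- svm_classify(X, y, n_splits = 30, n_perm = 0, seed = 3)
  expect_equal(res$mean_auc, 1.0)
  # shuffled labels hover around chance
  y_shuf <- stats::setNames(sample(y), names(y))
  res_s <- svm_classify(X, y_shuf, n_splits = 30, n_perm = 0, seed = 3)
  expect_gt(res_s$mean_auc, 0.30)
  expect_lt(res_s$mean_auc, 0.70)
})

test_that("svm_classify is reproducible and validates its inputs", {
  set.seed(8)
  X <- matrix(rnorm(16 * 4), 16, 4,
              dimnames = list(sprintf("s%d", 1:16), paste0("f", 1:4)))
  y <- rep(c("a", "b"), each = 8)
  r1 <- svm_classify(X, y, n_splits = 10, n_perm = 20, seed = 99)
  r2 <- svm_classify(X, y, n_splits = 10, n_perm = 20, seed = 99)
  expect_identical(r1$split_aucs, r2$split_aucs)
  expect_identical(r1$p_empirical, r2$p_empirical)
  expect_gte(r1$p_empirical, 1 / 21)
  expect_error(svm_classify(X, rep("a", 16)), "binary")
  expect_error(svm_classify(X[1:5, ], c("a", "a", "a", "b", "b")),
               "at least 3")
})

test_that("gluconeogenesis partitioning arithmetic is exact", {
  g <- gng_partition(0.55, 0.30)
  expect_equal(c(g$gng_tot, g$gng_pyr, g$gng_gly), c(55, 30, 25))
  expect_false(g$flagged_negative)

  g2 <- gng_partition(0.40, 0.40)
  expect_equal(g2$gng_gly, 0)

  expect_warning(g3 <- gng_partition(0.40, 0.50), "negative")
  expect_equal(g3$gng_gly, -10)
  expect_true(g3$flagged_negative)

  # identity holds to machine precision for arbitrary inputs
  set.seed(2)
  for (i in 1:50) {
    a <- runif(1); b <- runif(1)
    g4 <- suppressWarnings(gng_partition(a, b))
    expect_identical(g4$gng_gly, g4$gng_tot - g4$gng_pyr)
  }
  expect_error(gng_partition(-0.1, 0.2), "non-negative")
  expect_error(gng_partition(Inf, 0.2), "finite")
})
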