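#' Compare functionality scores between groups
#'
#' Group comparison of per-sample scores. The default for two unpaired
#' patient groups is the Wilcoxon rank-sum test (exact p for combined
#' n <= 20, normal approximation above); the paired signed-rank variant is
#' used when comparing paired score vectors (e.g. the 22 function medians of
#' two groups), and a two-sided t-test is available for concentrations.
#' Missing scores are dropped (pairwise for the paired test); the number of
#' dropped values is reported in the result.
#'
#' @param scores_a,scores_b numeric vectors.
#' @param test `"rank_sum"`, `"signed_rank"`, or `"t_two_sided"`.
#' @return List of class `group_comparison`: `statistic`, `p_value`, `test`,
#'   `n_a`, `n_b`, `n_dropped`.
#' @export
compare_group_scores <- function(scores_a, scores_b,
                                 test = c("rank_sum", "signed_rank",
                                          "t_two_sided")) {
  test <- match.arg(test)
  if (test == "signed_rank") {
    if (length(scores_a) != length(scores_b)) {
      stop("signed_rank requires equal-length (paired) score vectors")
    }
    keep <- is.finite(scores_a) & is.finite(scores_b)
    n_dropped <- sum(!keep)
    a <- scores_a[keep]; b <- scores_b[keep]
    if (length(a) < 2) stop("too few complete pairs")
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  } else {
    a <- scores_a[is.finite(scores_a)]
    b <- scores_b[is.finite(scores_b)]
    n_dropped <- (length(scores_a) - length(a)) +
      (length(scores_b) - length(b))
    if (length(a) < 2 || length(b) < 2) {
      stop("need at least 2 finite scores per group")
    }
    ht <- if (test == "rank_sum") {
      suppressWarnings(
        stats::wilcox.test(a, b, exact = (length(a) + length(b)) <= 20))
    } else {
      stats::t.test(a, b)
    }
  }
  structure(list(statistic = unname(ht$statistic),
                 p_value = min(1, ht$p.value), test = test,
                 n_a = length(a), n_b = length(b), n_dropped = n_dropped),
            class = "group_comparison")
}

#' Per-function group comparison table
#'
#' Applies [compare_group_scores()] to every function of a functionality
#' profile table, separately for the activity and the adaptability score.
#'
#' @param profiles long data.frame from [profile_functionality()].
#' @param groups named character/factor vector (sample id -> group label,
#'   exactly two levels).
#' @param test test passed on to [compare_group_scores()].
#' @return data.frame: `function_id`, `score_type`, `statistic`, `p_value`,
#'   `test`.
#' @export
compare_functionality_groups <- function(profiles, groups,
                                         test = "rank_sum") {
  lv <- unique(as.character(groups))
  if (length(lv) != 2) stop("groups must have exactly two levels")
  rows <- list()
  for (fid in unique(profiles$function_id)) {
    sub <- profiles[profiles$function_id == fid, ]
    g <- as.character(groups[sub$sample_id])
    for (sc in c("activity", "adaptability")) {
      x <- sub[[sc]][g == lv[1]]
      y <- sub[[sc]][g == lv[2]]
      res <- tryCatch(compare_group_scores(x, y, test = test),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        function_id = fid, score_type = sc,
        statistic = if (is.null(res)) NA_real_ else res$statistic,
        p_value = if (is.null(res)) NA_real_ else res$p_value,
        test = test, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from ranks (the Mann-Whitney
#' statistic), with ties counted half.
#'
#' @param scores numeric decision values.
#' @param labels binary labels (logical, 0/1 or two-level factor); the
#'   second factor level / `TRUE` / `1` is the positive class.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  if (is.factor(labels)) {
    pos <- labels == levels(labels)[2]
  } else {
    pos <- as.logical(labels)
  }
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties (counted half)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' SVM classification of liver-fat groups with permutation testing
#'
#' Repeated random-split evaluation of a maximum-margin classifier on a
#' samples x features table (typically functionality scores). Splits are
#' stratified by class, two thirds training by default; features are
#' standardized on the training fold. Performance is the mean test-fold AUC
#' over splits, and significance is assessed by re-running the whole
#' procedure on label permutations:
#' `p = (#{mean AUC permuted >= observed} + 1) / (n_perm + 1)`.
#'
#' @param features numeric matrix, samples in rows (rownames = sample ids).
#' @param labels binary labels, named by sample or aligned with rows.
#' @param n_splits number of random train/test splits.
#' @param train_fraction fraction of each class used for training.
#' @param n_perm number of label permutations (0 disables the test).
#' @param seed RNG seed.
#' @param kernel SVM kernel (`"linear"` default, `"radial"` available).
#' @param cost SVM cost parameter.
#' @return List of class `classification_result`: `mean_auc`, `split_aucs`,
#'   `p_empirical`, `n_splits`, `n_perm`, `seed`.
#' @export
svm_classify <- function(features, labels, n_splits = 100,
                         train_fraction = 2 / 3, n_perm = 1000, seed = 1,
                         kernel = "linear", cost = 1) {
  features <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must be binary")
  if (min(table(y)) < 3) stop("need at least 3 samples per class")
  keep_cols <- apply(features, 2, function(col) all(is.finite(col)))
  features <- features[, keep_cols, drop = FALSE]
  if (ncol(features) == 0) stop("no complete feature columns")

  split_eval <- function(yy) {
    aucs <- numeric(n_splits)
    for (s in seq_len(n_splits)) {
      repeat {
        tr <- unlist(lapply(levels(yy), function(lv) {
          idx <- which(yy == lv)
          sample(idx, max(1, round(train_fraction * length(idx))))
        }))
        te <- setdiff(seq_along(yy), tr)
        if (length(unique(yy[te])) == 2) break
        # degenerate split (a class missing from the test fold): resample
      }
      mu <- colMeans(features[tr, , drop = FALSE])
      sd_ <- apply(features[tr, , drop = FALSE], 2, stats::sd)
      sd_[sd_ == 0 | is.na(sd_)] <- 1
      Xtr <- scale(features[tr, , drop = FALSE], center = mu, scale = sd_)
      Xte <- scale(features[te, , drop = FALSE], center = mu, scale = sd_)
      fit <- e1071::svm(Xtr, yy[tr], kernel = kernel, cost = cost,
                        scale = FALSE)
      dvm <- attr(stats::predict(fit, Xte, decision.values = TRUE),
                  "decision.values")
      dv <- dvm[, 1]
      # positive decision values point at the first class named in the
      # "A/B" column label; orient the score towards the second factor level
      oriented_pos <- strsplit(colnames(dvm)[1], "/", fixed = TRUE)[[1]][1]
      if (oriented_pos != levels(yy)[2]) dv <- -dv
      aucs[s] <- compute_auc(dv, yy[te])
    }
    aucs
  }

  set.seed(seed)
  split_aucs <- split_eval(y)
  mean_auc <- mean(split_aucs)
  p_emp <- NA_real_
  if (n_perm > 0) {
    perm_means <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      perm_means[b] <- mean(split_eval(sample(y)))
    }
    p_emp <- (sum(perm_means >= mean_auc) + 1) / (n_perm + 1)
  }
  structure(list(mean_auc = mean_auc, split_aucs = split_aucs,
                 p_empirical = p_emp, n_splits = n_splits, n_perm = n_perm,
                 seed = seed, kernel = kernel),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("classification_result: mean AUC",
      format(x$mean_auc, digits = 4), "over", x$n_splits, "splits")
  if (!is.na(x$p_empirical)) {
    cat(", empirical p =", format(x$p_empirical, digits = 4),
        paste0("(", x$n_perm, " permutations)"))
  }
  cat("\n")
  invisible(x)
}

#' Partition gluconeogenesis by substrate from deuterium enrichments
#'
#' In deuterated-water tracer studies the fractional contribution of
#' gluconeogenesis to endogenous glucose production (GNGtot, %) is the
#' ratio of deuterium enrichment at carbon 5 versus carbon 2 of glucose;
#' the lactate/pyruvate contribution (GNGpyr, %) is the carbon 6 / carbon 2
#' ratio; and the glycerol contribution (GNGgly, %) is their difference.
#'
#' @param c5_c2 C5/C2 enrichment ratio (>= 0).
#' @param c6_c2 C6/C2 enrichment ratio (>= 0).
#' @return List of class `gng_partition`: `gng_tot`, `gng_pyr`, `gng_gly`
#'   (all in % of endogenous glucose production) and `flagged_negative`
#'   (`TRUE` when `gng_gly < 0`, which is physiologically impossible and
#'   indicates measurement error; the value is returned as-is).
#' @examples
#' gng_partition(0.55, 0.30)  # 55% total, 30% from pyruvate, 25% glycerol
#' @export
gng_partition <- function(c5_c2, c6_c2) {
  if (!is.finite(c5_c2) || !is.finite(c6_c2) || c5_c2 < 0 || c6_c2 < 0) {
    stop("enrichment ratios must be finite and non-negative")
  }
  gng_tot <- 100 * c5_c2
  gng_pyr <- 100 * c6_c2
  gng_gly <- gng_tot - gng_pyr
  flagged <- gng_gly < 0
  if (flagged) {
    warning("negative glycerol contribution (GNGpyr > GNGtot)")
  }
  structure(list(gng_tot = gng_tot, gng_pyr = gng_pyr, gng_gly = gng_gly,
                 flagged_negative = flagged),
            class = "gng_partition")
}
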