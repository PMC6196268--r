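#' Monte-Carlo cross-validation accuracy of a ridge classifier
#'
#' Repeats `R` stratified random learning/test splits; on each, a
#' regularized-least-squares classifier ([rls()]) is fit on the learning
#' samples and its accuracy (fraction of correctly predicted labels)
#' measured on the test samples.
#'
#' @param mat log2-scale [expr_matrix()] (typically restricted to a
#'   signature with [subset_matrix()]).
#' @param metadata two-group metadata.
#' @param mu ridge penalty (default 0.1).
#' @param R number of random splits (default 100).
#' @param test_fraction held-out fraction per group (default 0.25).
#' @param seed integer seed.
#' @param permute draw a fresh random permutation of the group labels for
#'   every split (the permutation null arm): each accuracy sample is then
#'   an independent draw from the chance distribution, centred at 0.5.
#' @return numeric vector of R accuracies in `[0, 1]`.
#' @export
montecarlo_cv_accuracy <- function(mat, metadata, mu = 0.1, R = 100L,
                                   test_fraction = 0.25, seed = 1L,
                                   permute = FALSE) {
  .assert_log2(mat, "montecarlo_cv_accuracy()")
  if (R < 1L) stop("'R' must be >= 1")
  md <- check_metadata(mat, metadata)
  y <- factor(as.character(md$group))
  if (nlevels(y) != 2L) stop("exactly two groups required")
  X <- t(unclass(mat))
  set.seed(seed)
  idx0 <- split(seq_along(y), y)
  n_test <- lapply(idx0, function(g)
    max(1L, round(test_fraction * length(g))))
  if (any(vapply(idx0, length, 0L) - unlist(n_test) < 1L))
    stop("test fraction leaves a class empty in the learning set")
  vapply(seq_len(R), function(r) {
    yr <- if (permute) sample(y) else y
    idx <- split(seq_along(yr), yr)
    test <- unlist(mapply(function(g, k) sample(g, k), idx, n_test,
                          SIMPLIFY = FALSE))
    keep <- apply(X[-test, , drop = FALSE], 2, stats::sd) > 0
    fit <- rls(X[-test, keep, drop = FALSE], yr[-test], mu = mu)
    mean(predict(fit, X[test, keep, drop = FALSE]) ==
           as.character(yr[test]))
  }, 0)
}

#' Two-sample Kolmogorov-Smirnov comparison of accuracy distributions
#'
#' Tests whether the accuracies obtained under the true labels and under
#' permuted labels come from the same distribution; a small p-value means
#' the classifier's performance is not explained by chance. Two-sided
#' [stats::ks.test()]; the exact p-value is used when both samples are
#' small and tie-free, the asymptotic approximation otherwise.
#'
#' @param acc_true,acc_perm non-empty numeric accuracy samples.
#' @return list with `D` (the KS statistic, the maximum distance between
#'   the two empirical CDFs) and `p`.
#' @export
ks_significance <- function(acc_true, acc_perm) {
  if (!length(acc_true) || !length(acc_perm))
    stop("both accuracy samples must be non-empty")
  ht <- suppressWarnings(stats::ks.test(acc_true, acc_perm,
                                        alternative = "two.sided"))
  list(D = unname(ht$statistic), p = ht$p.value)
}

#' Full validation report for a signature
#'
#' Runs [montecarlo_cv_accuracy()] under the true labels (`R_true` splits)
#' and under permuted labels (`R_perm` splits, labels re-permuted each
#' repetition block), and compares the two accuracy distributions with
#' [ks_significance()].
#'
#' @inheritParams montecarlo_cv_accuracy
#' @param R_true,R_perm repetitions per arm (defaults 100).
#' @return object of class `validation_report`: `acc_true`, `acc_perm`,
#'   `mean_accuracy`, `D`, `p`, `seed`, `mu`.
#' @export
validate_signature <- function(mat, metadata, mu = 0.1, R_true = 100L,
                               R_perm = 100L, test_fraction = 0.25,
                               seed = 1L) {
  acc_true <- montecarlo_cv_accuracy(mat, metadata, mu = mu, R = R_true,
                                     test_fraction = test_fraction,
                                     seed = seed)
  acc_perm <- montecarlo_cv_accuracy(mat, metadata, mu = mu, R = R_perm,
                                     test_fraction = test_fraction,
                                     seed = seed + 1L, permute = TRUE)
  ks <- ks_significance(acc_true, acc_perm)
  structure(list(acc_true = acc_true, acc_perm = acc_perm,
                 mean_accuracy = mean(acc_true), D = ks$D, p = ks$p,
                 seed = seed, mu = mu,
                 harmonization = "per-platform z-score"),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Monte-Carlo CV validation (%d true / %d permuted splits)\n",
              length(x$acc_true), length(x$acc_perm)))
  cat(sprintf("  mean accuracy (true labels): %.3f\n", x$mean_accuracy))
  cat(sprintf("  mean accuracy (permuted):    %.3f\n", mean(x$acc_perm)))
  cat(sprintf("  KS D = %.3f, p = %.3g\n", x$D, x$p))
  invisible(x)
}

#' Classify samples measured on a different platform
#'
#' Applies a microarray-trained linear model to a new cohort measured with
#' qPCR. The qPCR values are expected on a log2-like scale (per-feature
#' -dCt, i.e. reference-normalized negative Ct differences); each feature
#' is z-scored across the new cohort to remove platform location and scale
#' before the model's sign rule is applied on its standardized weights.
#' Features with zero variance in the new cohort are dropped with a
#' warning and the rule applied over the remaining weights.
#'
#' @param model a fitted [l1l2()]/[rls()] model.
#' @param new_expr matrix, features x samples (rownames = feature ids
#'   covering the model's features; colnames = sample ids), log2-like
#'   relative expression (e.g. -dCt).
#' @return named character/numeric vector of predicted labels.
#' @export
cross_technology_predict <- function(model, new_expr) {
  feats <- names(model$beta)
  missing <- setdiff(feats, rownames(new_expr))
  if (length(missing))
    stop("new cohort is missing model features: ",
         paste(missing, collapse = ", "))
  X <- t(new_expr[feats, , drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance features dropped in new cohort: ",
            paste(feats[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(X)
  beta <- model$beta[colnames(Z)]
  score <- drop(Z %*% beta) + model$intercept
  pos <- score >= 0
  cls <- model$classes
  out <- if (identical(unname(cls), c("-1", "1"))) ifelse(pos, 1, -1)
         else ifelse(pos, cls[["pos"]], cls[["neg"]])
  stats::setNames(out, rownames(X))
}
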