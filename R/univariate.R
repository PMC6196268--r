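#' Two-group differential expression on log2 intensities
#'
#' Per feature: a two-sample test on log2 values (Welch t by default,
#' Mann-Whitney by flag), multiplicity adjustment across all tested
#' features, and classification into induced / repressed / unchanged in the
#' dim group. A feature is induced when its adjusted p-value is at most
#' `alpha` and the difference of group medians delta = median(dim) -
#' median(bright) is at least log2(fc_min) (i.e. at least `fc_min`-fold up
#' in dim), repressed with delta at most -log2(fc_min), unchanged otherwise.
#' Features not detected above `detect_theta` in at least half the samples
#' of either group are excluded before testing.
#'
#' @param mat log2-scale [expr_matrix()].
#' @param metadata two-group metadata; each group needs >= 2 samples.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param fc_min minimum fold change (default 2: |delta| >= 1 log2).
#' @param test `"welch_t"` or `"mann_whitney"`.
#' @param adjust `"BH"` or `"bonferroni"`.
#' @param detect_theta detection threshold applied before testing, same
#'   scale as the matrix; `NULL` disables the filter.
#' @return data frame of class `diff_result` with columns feature,
#'   median_log2_bright, median_log2_dim, delta_log2, fold_change, p, p_adj,
#'   status; fold_change is the signed linear fold, sign(delta) * 2^|delta|.
#' @export
differential_expression <- function(mat, metadata, alpha = 0.05,
                                    fc_min = 2.0,
                                    test = c("welch_t", "mann_whitney"),
                                    adjust = c("BH", "bonferroni"),
                                    detect_theta = 1.0) {
  test <- match.arg(test); adjust <- match.arg(adjust)
  .assert_log2(mat, "differential_expression()")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  if (fc_min < 1) stop("'fc_min' must be >= 1")
  idx <- .two_groups(mat, metadata)
  if (any(lengths(idx) < 2L)) stop("each group needs at least 2 samples")
  if (!all(c("bright", "dim") %in% names(idx)))
    stop("differential_expression() contrasts groups 'bright' and 'dim'")
  keep <- rownames(mat)
  if (!is.null(detect_theta)) {
    det <- detection_call(mat, metadata, theta = detect_theta, f = 0.5)
    keep <- union(det$groups[[1]]$at_least, det$groups[[2]]$at_least)
  }
  sub <- unclass(mat)[rownames(mat) %in% keep, , drop = FALSE]
  a <- sub[, idx$bright, drop = FALSE]
  b <- sub[, idx$dim, drop = FALSE]
  med_a <- apply(a, 1, stats::median)
  med_b <- apply(b, 1, stats::median)
  delta <- med_b - med_a
  p <- vapply(seq_len(nrow(sub)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (stats::sd(c(x, y)) == 0) return(1)
    if (test == "welch_t")
      stats::t.test(y, x)$p.value
    else
      suppressWarnings(stats::wilcox.test(y, x)$p.value)
  }, 0)
  p_adj <- adjust_pvalues(p, method = adjust)
  thr <- log2(fc_min)
  status <- rep("unchanged", nrow(sub))
  status[p_adj <= alpha & delta >= thr] <- "induced"
  status[p_adj <= alpha & delta <= -thr] <- "repressed"
  out <- data.frame(feature = rownames(sub),
                    median_log2_bright = med_a,
                    median_log2_dim = med_b,
                    delta_log2 = delta,
                    fold_change = sign(delta) * 2^abs(delta),
                    p = p, p_adj = p_adj, status = status,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up or Bonferroni, via [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Hierarchical bi-clustering of features and samples
#'
#' Agglomerative clustering of each axis independently, the analysis behind
#' two-way heat-map dendrograms. Default distance is 1 - Pearson
#' correlation with average linkage; Euclidean and other
#' [stats::hclust()] linkages are selectable. Items are ordered
#' lexicographically before clustering so ties resolve deterministically.
#'
#' @param mat centered log2-scale [expr_matrix()], >= 2 rows and columns.
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage an [stats::hclust()] method (default `"average"`).
#' @return list with `features` and `samples`, each an `hclust` tree.
#' @export
hierarchical_bicluster <- function(mat, distance = c("correlation",
                                                     "euclidean"),
                                   linkage = "average") {
  distance <- match.arg(distance)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need at least 2 features and 2 samples")
  one_axis <- function(m) {
    m <- m[order(rownames(m)), , drop = FALSE]
    if (distance == "correlation") {
      if (any(apply(m, 1, stats::sd) == 0))
        stop("constant rows have undefined correlation distance; ",
             "use distance = 'euclidean'")
      d <- stats::as.dist(1 - stats::cor(t(m)))
    } else {
      d <- stats::dist(m)
    }
    stats::hclust(d, method = linkage)
  }
  list(features = one_axis(unclass(mat)),
       samples = one_axis(t(unclass(mat))))
}

#' Group-comparison tests
#'
#' Welch t, exact-where-possible Mann-Whitney, or one-way ANOVA followed by
#' Bonferroni-adjusted pairwise t post-tests (the three-subset comparison
#' design).
#'
#' @param values numeric vector of measurements.
#' @param group factor/character of group labels, same length.
#' @param kind `"welch_t"`, `"mann_whitney"`, or `"anova_bonferroni"`.
#' @return for the two-sample kinds, a list with `statistic` and `p`; for
#'   ANOVA, a list with `statistic` (F), `p` (overall), and `pairwise`
#'   (named vector of Bonferroni-adjusted pairwise p-values, clipped at 1).
#' @export
group_mean_test <- function(values, group,
                            kind = c("welch_t", "mann_whitney",
                                     "anova_bonferroni")) {
  kind <- match.arg(kind)
  group <- factor(group)
  if (any(table(group) == 0) || anyNA(values)) stop("empty group or NAs")
  k <- nlevels(group)
  if (kind %in% c("welch_t", "mann_whitney")) {
    if (k != 2L) stop(kind, " requires exactly 2 groups")
    sp <- split(values, group)
    if (kind == "welch_t") {
      ht <- stats::t.test(sp[[1]], sp[[2]])
    } else {
      n <- min(lengths(sp))
      ht <- suppressWarnings(
        stats::wilcox.test(sp[[1]], sp[[2]], exact = n <= 8 &&
                             !any(duplicated(values))))
    }
    list(statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    if (k < 3L) stop("anova_bonferroni requires >= 3 groups")
    fit <- stats::aov(values ~ group)
    sm <- summary(fit)[[1]]
    pw <- stats::pairwise.t.test(values, group, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)$p.value
    pairs <- stats::na.omit(data.frame(
      a = rep(rownames(pw), ncol(pw)), b = rep(colnames(pw),
                                               each = nrow(pw)),
      p = as.vector(pw)))
    list(statistic = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
         pairwise = stats::setNames(pmin(pairs$p, 1),
                                    paste(pairs$a, pairs$b, sep = " vs ")))
  }
}
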