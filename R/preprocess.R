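#' Detection floor on linear-scale intensities
#'
#' Replaces every intensity below `floor` light units (LU) by `floor`, the
#' standard microarray thresholding step that precedes the log2 transform
#' (values at or above the floor are untouched).
#'
#' @param mat linear-scale [expr_matrix()].
#' @param floor positive detection floor, LU (default 1).
#' @return floored linear-scale matrix.
#' @export
floor_threshold <- function(mat, floor = 1.0) {
  if (!identical(expr_scale(mat), "linear"))
    stop("floor_threshold() expects a linear-scale matrix")
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
    stop("'floor' must be a single positive number")
  out <- unclass(mat)
  out[out < floor] <- floor
  expr_matrix(out, scale = "linear")
}

#' Log2 transform of linear intensities
#'
#' @param mat linear-scale [expr_matrix()] with strictly positive values
#'   (guaranteed after [floor_threshold()]).
#' @return log2-scale matrix.
#' @export
log2_transform <- function(mat) {
  if (!identical(expr_scale(mat), "linear"))
    stop("log2_transform() expects a linear-scale matrix")
  if (any(unclass(mat) <= 0))
    stop("non-positive intensities; apply floor_threshold() first")
  expr_matrix(log2(unclass(mat)), scale = "log2")
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) onto the common distribution given by the
#' across-sample mean of order statistics; tied values within a column
#' receive the mean of the reference distribution over the tied rank span.
#' Delegates to \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param mat [expr_matrix()] with at least 2 samples.
#' @return normalized matrix on the same scale.
#' @export
quantile_normalize <- function(mat) {
  if (ncol(mat) < 2L) {
    warning("single sample: quantile normalization is a no-op")
    return(mat)
  }
  out <- limma::normalizeQuantiles(unclass(mat), ties = TRUE)
  dimnames(out) <- dimnames(mat)
  expr_matrix(out, scale = expr_scale(mat))
}

#' Location-only batch adjustment
#'
#' Per feature, each batch's values are shifted so every batch mean equals
#' the feature's grand mean. This removes an additive batch offset while
#' preserving within-batch group contrasts exactly. Requires every batch to
#' contain both groups, otherwise the shift would absorb the group effect
#' (confounded design).
#'
#' @param mat log2-scale [expr_matrix()].
#' @param metadata sample metadata with `batch_id` (and `group`, used for
#'   the confounding check).
#' @return adjusted matrix.
#' @export
batch_adjust <- function(mat, metadata) {
  .assert_log2(mat, "batch_adjust()")
  md <- check_metadata(mat, metadata, require_batch = TRUE)
  if (anyNA(md$batch_id)) stop("every sample needs a batch id")
  batches <- split(seq_len(ncol(mat)), as.character(md$batch_id))
  if (length(batches) > 1L && !is.null(md$group)) {
    ngroups <- length(unique(as.character(md$group)))
    for (b in names(batches)) {
      gb <- unique(as.character(md$group[batches[[b]]]))
      if (length(gb) < ngroups)
        stop("batch '", b, "' does not contain all groups: ",
             "batch and group are confounded, refusing to adjust")
    }
  }
  vals <- unclass(mat)
  grand <- rowMeans(vals)
  for (idx in batches) {
    bm <- rowMeans(vals[, idx, drop = FALSE])
    vals[, idx] <- vals[, idx, drop = FALSE] - (bm - grand)
  }
  expr_matrix(vals, scale = "log2")
}

#' Median-center each feature
#'
#' Subtracts each feature's across-sample median, the centering used for
#' heat-map display of log2 intensities; idempotent.
#'
#' @param mat log2-scale [expr_matrix()].
#' @return centered matrix.
#' @export
median_center <- function(mat) {
  .assert_log2(mat, "median_center()")
  vals <- unclass(mat)
  med <- apply(vals, 1, stats::median)
  expr_matrix(vals - med, scale = "log2")
}

#' Detection calls per phenotype group
#'
#' A feature is called detected in a sample when its value exceeds the
#' threshold `theta`; per group the summary reports the features detected in
#' at least `ceiling(f * n)` of the group's n samples ("half or more" for
#' the default f = 0.5) and in all samples, plus the features shared by both
#' groups and exclusive to each (based on the half-or-more sets).
#'
#' @param mat [expr_matrix()]; `theta` must be on the same scale (the
#'   default 1 light unit applies to the normalized log2 table, i.e. values
#'   strictly above 1 log2 LU; use `scale = "linear"` with a linear matrix).
#' @param metadata two-group sample metadata.
#' @param theta detection threshold (default 1.0).
#' @param f fraction of the group's samples required (default 0.5).
#' @return object of class `detection_summary`: per-group sets/counts and
#'   shared/exclusive partitions.
#' @export
detection_call <- function(mat, metadata, theta = 1.0, f = 0.5) {
  idx <- .two_groups(mat, metadata)
  vals <- unclass(mat)
  per_group <- lapply(idx, function(cols) {
    if (!length(cols)) stop("empty group")
    sub <- vals[, cols, drop = FALSE]
    n <- ncol(sub)
    hits <- rowSums(sub > theta)
    list(at_least = rownames(mat)[hits >= ceiling(f * n)],
         all = rownames(mat)[hits == n])
  })
  g <- names(per_group)
  shared <- intersect(per_group[[1]]$at_least, per_group[[2]]$at_least)
  excl <- list(setdiff(per_group[[1]]$at_least, per_group[[2]]$at_least),
               setdiff(per_group[[2]]$at_least, per_group[[1]]$at_least))
  names(excl) <- g
  structure(list(theta = theta, f = f, groups = per_group, shared = shared,
                 exclusive = excl,
                 counts = c(stats::setNames(
                   unlist(lapply(per_group, function(p)
                     c(length(p$at_least), length(p$all)))),
                   as.vector(outer(c("at_least", "all"), g,
                                   function(a, b) paste(b, a, sep = "_")))),
                   shared = length(shared),
                   exclusive_total = length(excl[[1]]) + length(excl[[2]]))),
            class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat(sprintf("Detection at theta = %g (>= %d%% of group samples):\n",
              x$theta, round(100 * x$f)))
  for (g in names(x$groups))
    cat(sprintf("  %s: %d detected (>= fraction), %d in all samples\n",
                g, length(x$groups[[g]]$at_least), length(x$groups[[g]]$all)))
  cat(sprintf("  shared: %d; exclusive: %s\n", length(x$shared),
              paste(sprintf("%s=%d", names(x$exclusive),
                            lengths(x$exclusive)), collapse = ", ")))
  invisible(x)
}

#' Run the full preprocessing chain
#'
#' Floor at `floor` LU, log2 transform, quantile normalization, optional
#' batch adjustment, optional median centering — in that order.
#'
#' @param mat linear-scale [expr_matrix()].
#' @param metadata sample metadata (needed when `batch = TRUE`).
#' @param floor detection floor, LU.
#' @param batch apply [batch_adjust()].
#' @param center apply [median_center()].
#' @return log2-scale preprocessed matrix.
#' @export
preprocess_chain <- function(mat, metadata = NULL, floor = 1.0,
                             batch = TRUE, center = FALSE) {
  out <- quantile_normalize(log2_transform(floor_threshold(mat, floor)))
  if (batch) {
    if (is.null(metadata)) stop("metadata required for batch adjustment")
    out <- batch_adjust(out, metadata)
  }
  if (center) out <- median_center(out)
  out
}
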