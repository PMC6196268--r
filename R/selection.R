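#' Stability selection over nested cross-validation
#'
#' The signature-discovery engine: the data are split `B` times into
#' stratified learning/test pairs (outer loop); on each learning set an
#' inner stratified cross-validation picks the penalty pair (tau, mu) of
#' the [l1l2()] classifier that minimizes mean inner misclassification
#' error (ties broken toward the smallest tau — the densest,
#' correlation-retaining model, as in the reference sparse-selection
#' frameworks — then the sparser fit, then the smaller mu); the model
#' is refit on the whole learning set, its nonzero-weight features recorded
#' as that split's list, and its error measured on the held-out test set.
#' Features are then ranked by the fraction of the B lists that contain
#' them, and the aggregated signature keeps those at frequency >= `phi`.
#'
#' @param mat log2-scale [expr_matrix()] (features x samples).
#' @param metadata two-group metadata; each group needs more than B... at
#'   least `ceiling(1/(1-test_fraction))` samples and >= 2 per fold; an
#'   error suggests a smaller `B` when a group is smaller than `B`.
#' @param B number of outer splits (default 5).
#' @param test_fraction fraction of each group held out per split
#'   (default 0.25).
#' @param inner_folds folds of the inner model-selection loop (default 4).
#' @param tau_ratios descending fractions of the learning-set [tau_max()]
#'   forming the tau grid (default 20 geometric points from 1 to 0.01).
#' @param mu_ratios multipliers of the spectral scale (largest eigenvalue
#'   of the standardized learning Gram matrix / n) forming the mu grid
#'   (default `c(1e-3, 1e-2, 1e-1)`).
#' @param phi frequency threshold for the aggregated signature
#'   (default 0.5).
#' @param seed integer seed; identical seeds give identical splits, lists
#'   and signature.
#' @param pair_by_donor keep each donor's paired samples in the same side
#'   of every outer split (requires `donor_id` metadata).
#' @param tol,max_iter solver controls passed to [l1l2()].
#' @return object of class `selection_run`: per-split results (`splits`),
#'   `frequency` table (feature, count, frequency, mean_abs_beta),
#'   aggregated `signature`, `mean_accuracy`, and the call parameters.
#' @export
nested_cv_select <- function(mat, metadata, B = 5L, test_fraction = 0.25,
                             inner_folds = 4L,
                             tau_ratios = 0.01^seq(0, 1, length.out = 20),
                             mu_ratios = c(1e-3, 1e-2, 1e-1),
                             phi = 0.5, seed = 1L,
                             pair_by_donor = FALSE,
                             tol = 1e-6, max_iter = 10000L) {
  .assert_log2(mat, "nested_cv_select()")
  idx <- .two_groups(mat, metadata)
  md <- check_metadata(mat, metadata)
  if (any(lengths(idx) < B))
    stop("a group has fewer samples than B = ", B,
         "; use a smaller B")
  X_all <- t(unclass(mat))
  y_all <- factor(as.character(md$group))
  const <- apply(X_all, 2, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant features dropped before standardization")
    X_all <- X_all[, !const, drop = FALSE]
  }
  set.seed(seed)
  split_seeds <- sample.int(.Machine$integer.max - 1L, B)

  splits <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(split_seeds[b])
    test_idx <- if (pair_by_donor) {
      if (is.null(md$donor_id)) stop("pair_by_donor needs donor_id metadata")
      donors <- unique(as.character(md$donor_id))
      td <- sample(donors, max(1L, round(test_fraction * length(donors))))
      which(as.character(md$donor_id) %in% td)
    } else {
      unlist(lapply(idx, function(g)
        sample(g, max(1L, round(test_fraction * length(g))))))
    }
    learn_idx <- setdiff(seq_len(ncol(mat)), test_idx)
    if (length(unique(y_all[test_idx])) < 2L ||
        length(unique(y_all[learn_idx])) < 2L)
      stop("a split left a class empty; adjust test_fraction")
    sel <- .select_on_learning(X_all[learn_idx, , drop = FALSE],
                               y_all[learn_idx], inner_folds,
                               tau_ratios, mu_ratios, tol, max_iter)
    pred <- predict(sel$model, X_all[test_idx, , drop = FALSE])
    test_error <- mean(pred != as.character(y_all[test_idx]))
    splits[[b]] <- list(
      learn = rownames(X_all)[learn_idx], test = rownames(X_all)[test_idx],
      tau = sel$tau, mu = sel$mu, inner_error = sel$inner_error,
      selected = sel$model$selected,
      beta = sel$model$beta[sel$model$selected],
      test_error = test_error)
  }

  all_sel <- unlist(lapply(splits, `[[`, "selected"))
  counts <- table(all_sel)
  feats <- names(counts)
  mean_abs_beta <- vapply(feats, function(f) {
    v <- unlist(lapply(splits, function(s) abs(s$beta[f])))
    mean(v, na.rm = TRUE)
  }, 0)
  freq <- data.frame(feature = feats, count = as.integer(counts),
                     frequency = as.integer(counts) / B,
                     mean_abs_beta = mean_abs_beta,
                     row.names = NULL, stringsAsFactors = FALSE)
  freq <- freq[order(-freq$frequency, -freq$mean_abs_beta, freq$feature), ]
  run <- structure(list(B = B, test_fraction = test_fraction,
                        inner_folds = inner_folds, phi = phi, seed = seed,
                        splits = splits, frequency = freq,
                        mean_accuracy = 1 - mean(vapply(splits, `[[`,
                                                        0, "test_error")),
                        dropped_constant = sum(const)),
                   class = "selection_run")
  run$signature <- aggregate_by_frequency(run, phi)
  run
}

# inner model selection on one learning set: grid over (tau, mu) scored by
# inner-CV misclassification; ties -> smaller tau, then sparser, smaller mu
.select_on_learning <- function(X, y, inner_folds, tau_ratios, mu_ratios,
                                tol, max_iter) {
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  n <- nrow(X)
  tm <- tau_max(X, y)
  tau_grid <- sort(tm * tau_ratios, decreasing = TRUE)
  xs <- scale(X)
  spec <- max(eigen(tcrossprod(xs), symmetric = TRUE,
                    only.values = TRUE)$values) / n
  mu_grid <- mu_ratios * spec

  folds <- .stratified_folds(y, inner_folds)
  err <- array(0, c(length(tau_grid), length(mu_grid)))
  size <- array(0, c(length(tau_grid), length(mu_grid)))
  for (fold in seq_along(folds)) {
    hold <- folds[[fold]]
    Xtr <- X[-hold, , drop = FALSE]; ytr <- y[-hold]
    ktr <- apply(Xtr, 2, stats::sd) > 0
    Xtr <- Xtr[, ktr, drop = FALSE]
    for (m in seq_along(mu_grid)) {
      b0 <- NULL
      for (t in seq_along(tau_grid)) {
        fit <- l1l2(Xtr, ytr, tau = tau_grid[t], mu = mu_grid[m],
                    tol = tol, max_iter = max_iter, beta0 = b0)
        b0 <- fit$beta
        pred <- predict(fit, X[hold, colnames(Xtr), drop = FALSE])
        err[t, m] <- err[t, m] + mean(pred != as.character(y[hold]))
        size[t, m] <- size[t, m] + length(fit$selected)
      }
    }
  }
  err <- err / length(folds); size <- size / length(folds)
  cand <- which(err == min(err), arr.ind = TRUE)
  # error ties are broken toward the smallest tau (the densest,
  # correlation-retaining model, as in the reference l1l2 frameworks),
  # then toward the sparser fit, then the smaller mu
  cand <- cand[order(tau_grid[cand[, 1]], size[cand],
                     mu_grid[cand[, 2]]), , drop = FALSE]
  t_best <- cand[1, 1]; m_best <- cand[1, 2]
  model <- l1l2(X, y, tau = tau_grid[t_best], mu = mu_grid[m_best],
                tol = tol, max_iter = max_iter)
  list(model = model, tau = tau_grid[t_best], mu = mu_grid[m_best],
       inner_error = min(err))
}

.stratified_folds <- function(y, k) {
  folds <- vector("list", k)
  for (g in levels(factor(y))) {
    gi <- sample(which(y == g))
    part <- split(gi, rep_len(seq_len(k), length(gi)))
    for (j in seq_along(part))
      folds[[j]] <- c(folds[[j]], part[[j]])
  }
  folds
}

#' Frequency-threshold aggregation of selection lists
#'
#' Keeps the features selected in at least a fraction `phi` of the outer
#' splits, ordered by frequency, then mean absolute standardized weight,
#' then name. `phi = 1` returns the intersection of all lists. The full
#' count-vs-frequency table stays available in `run$frequency` as the
#' slope diagnostic.
#'
#' @param run a [nested_cv_select()] result.
#' @param phi frequency cutoff in (0, 1] (default 0.5).
#' @return character vector of stable signature features.
#' @export
aggregate_by_frequency <- function(run, phi = 0.5) {
  if (!inherits(run, "selection_run")) stop("'run' must be a selection_run")
  if (!is.numeric(phi) || phi <= 0 || phi > 1)
    stop("'phi' must lie in (0, 1]")
  if (!length(run$splits)) stop("selection run has no splits")
  f <- run$frequency
  f$feature[f$frequency >= phi]
}

#' Restrict an expression matrix to a signature
#'
#' @param mat [expr_matrix()].
#' @param signature non-empty character vector of feature ids, all present
#'   in `mat`; rows are returned in signature order.
#' @return the subsetted [expr_matrix()].
#' @export
subset_matrix <- function(mat, signature) {
  if (!length(signature)) stop("empty signature")
  missing <- setdiff(signature, rownames(mat))
  if (length(missing))
    stop("features not in matrix: ", paste(missing, collapse = ", "))
  mat[signature, , drop = FALSE]
}

#' @export
print.selection_run <- function(x, ...) {
  cat(sprintf(
    "Nested-CV selection: B = %d splits, test fraction %.2f, phi = %.2f\n",
    x$B, x$test_fraction, x$phi))
  cat(sprintf("  mean test accuracy: %.3f\n", x$mean_accuracy))
  cat(sprintf("  aggregated signature: %d features\n", length(x$signature)))
  sizes <- vapply(x$splits, function(s) length(s$selected), 0L)
  cat("  per-split list sizes: ", paste(sizes, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.selection_run <- function(object, ...) {
  print(object)
  cat("\nSelection frequency (top 20):\n")
  print(utils::head(object$frequency, 20), row.names = FALSE)
  invisible(object)
}

#' Serialize a selection run to JSON
#'
#' @param run a [nested_cv_select()] result.
#' @param path output path.
#' @export
write_selection_json <- function(run, path) {
  doc <- unclass(run)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
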