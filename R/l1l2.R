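#' Sparse linear classifier with combined l1 + l2 penalties
#'
#' Fits the penalized regression
#' \deqn{\min_\beta \frac{1}{n}\|y - X\beta - b\|_2^2
#'       + \tau\|\beta\|_1 + \mu\|\beta\|_2^2}
#' on class labels coded -1/+1, by accelerated proximal gradient (FISTA
#' with soft-thresholding and a monotone restart). The l1 weight `tau`
#' induces exact sparsity — the selected variables are those with nonzero
#' weight — while the l2 weight `mu` stabilizes the fit and lets groups of
#' correlated variables enter together rather than picking one
#' representative. The sign of the fitted linear score classifies new
#' samples.
#'
#' Features are standardized internally to zero mean and unit variance
#' using the training data only; the intercept is unpenalized and equals
#' the label mean under this centering.
#'
#' @param x numeric matrix, n samples x d features, with column names.
#' @param y labels: numeric -1/+1, or a factor/character with two levels.
#'   For factors, level `"dim"` (if present) is the positive class,
#'   otherwise the second level.
#' @param tau l1 penalty weight, >= 0.
#' @param mu l2 penalty weight, >= 0.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence yields a warning and the
#'   best iterate, flagged in the result.
#' @param beta0 optional warm-start coefficient vector.
#' @return an object of class `l1l2` with components `beta` (named weight
#'   vector on standardized inputs), `intercept`, `center`/`scale`
#'   (training standardization), `tau`, `mu`, `classes`, `selected`
#'   (names of nonzero-weight features), `objective`, `iterations`,
#'   `converged`.
#' @seealso [predict.l1l2()], [rls()], [regularization_path()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
#' y <- rep(c(-1, 1), each = 5)
#' x[, 1] <- x[, 1] + y          # informative feature
#' fit <- l1l2(x, y, tau = 0.5, mu = 0.01)
#' coef(fit)
#' predict(fit, x)
#' @export
l1l2 <- function(x, y, tau, mu, tol = 1e-6, max_iter = 10000L,
                 beta0 = NULL) {
  if (tau < 0 || mu < 0) stop("'tau' and 'mu' must be >= 0")
  prep <- .prep_xy(x, y)
  xs <- prep$xs; yc <- prep$y - prep$intercept
  n <- nrow(xs); d <- ncol(xs)

  # Lipschitz constant of the smooth part (1/n)||yc - X b||^2 + mu||b||^2
  s1 <- if (n <= d) sqrt(max(eigen(tcrossprod(xs), symmetric = TRUE,
                                   only.values = TRUE)$values, 0))
        else norm(xs, "2")
  L <- 2 * s1^2 / n + 2 * mu
  if (L <= 0) L <- 1

  obj <- function(b) {
    r <- yc - drop(xs %*% b)
    sum(r^2) / n + tau * sum(abs(b)) + mu * sum(b^2)
  }
  soft <- function(v, lam) sign(v) * pmax(abs(v) - lam, 0)

  beta <- if (is.null(beta0)) numeric(d) else as.numeric(beta0)
  z <- beta; t_k <- 1
  J_prev <- obj(beta)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    grad <- drop(crossprod(xs, drop(xs %*% z) - yc)) * (2 / n) + 2 * mu * z
    beta_new <- soft(z - grad / L, tau / L)
    J_new <- obj(beta_new)
    if (J_new > J_prev) {           # monotone restart: drop momentum
      z <- beta; t_k <- 1
      grad <- drop(crossprod(xs, drop(xs %*% z) - yc)) * (2 / n) +
        2 * mu * z
      beta_new <- soft(z - grad / L, tau / L)
      J_new <- obj(beta_new)
    }
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- beta_new + ((t_k - 1) / t_next) * (beta_new - beta)
    beta <- beta_new; t_k <- t_next
    if (abs(J_prev - J_new) < tol * max(1, abs(J_prev))) {
      J_prev <- J_new; converged <- TRUE; break
    }
    J_prev <- J_new
  }
  if (!converged)
    warning("l1l2 did not converge in ", max_iter,
            " iterations; returning best iterate")
  names(beta) <- colnames(xs)
  structure(list(beta = beta, intercept = prep$intercept,
                 center = prep$center, scale = prep$scale,
                 tau = tau, mu = mu, classes = prep$classes,
                 selected = names(beta)[beta != 0],
                 objective = J_prev, iterations = it,
                 converged = converged, loss = "square", n = n),
            class = "l1l2")
}

#' Regularized least squares (ridge) classifier
#'
#' The exact closed-form solution of the [l1l2()] objective with no l1
#' term (`tau = 0`): \eqn{\beta = (X^T X + n\mu I)^{-1} X^T (y - \bar y)}
#' on standardized features, solved in the dual when d > n.
#'
#' @inheritParams l1l2
#' @param mu l2 penalty weight, > 0.
#' @return object of class `c("rls", "l1l2")`; all `l1l2` methods apply.
#' @export
rls <- function(x, y, mu) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("'mu' must be a single positive number")
  prep <- .prep_xy(x, y)
  xs <- prep$xs; yc <- prep$y - prep$intercept
  n <- nrow(xs); d <- ncol(xs)
  beta <- if (d > n) {
    drop(crossprod(xs, solve(tcrossprod(xs) + n * mu * diag(n), yc)))
  } else {
    drop(solve(crossprod(xs) + n * mu * diag(d), crossprod(xs, yc)))
  }
  names(beta) <- colnames(xs)
  structure(list(beta = beta, intercept = prep$intercept,
                 center = prep$center, scale = prep$scale,
                 tau = 0, mu = mu, classes = prep$classes,
                 selected = names(beta)[beta != 0],
                 objective = sum((yc - drop(xs %*% beta))^2) / n +
                   mu * sum(beta^2),
                 iterations = 0L, converged = TRUE, loss = "square", n = n),
            class = c("rls", "l1l2"))
}

# standardize x, encode y; shared by l1l2() and rls()
.prep_xy <- function(x, y) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  enc <- .encode_labels(y)
  if (nrow(x) != length(enc$y)) stop("nrow(x) must equal length(y)")
  if (nrow(x) < 2L) stop("need at least 2 samples")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- scl == 0
  if (any(zero))
    stop("zero-variance features: ",
         paste(colnames(x)[zero], collapse = ", "))
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  list(xs = xs, y = enc$y, intercept = mean(enc$y),
       center = ctr, scale = scl, classes = enc$classes)
}

.encode_labels <- function(y) {
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (!identical(u, c(-1, 1)))
      stop("numeric labels must be -1/+1 with both classes present")
    return(list(y = as.numeric(y), classes = c(neg = "-1", pos = "1")))
  }
  f <- factor(y)
  if (nlevels(f) != 2L)
    stop("labels must have exactly 2 classes, found ", nlevels(f))
  lev <- levels(f)
  if ("dim" %in% lev) lev <- c(setdiff(lev, "dim"), "dim")
  list(y = ifelse(as.character(f) == lev[2], 1, -1),
       classes = c(neg = lev[1], pos = lev[2]))
}

#' Classify new samples with a fitted l1l2 / RLS model
#'
#' New samples are standardized with the model's training parameters and
#' classified by the sign of the linear score; a score of exactly zero maps
#' to the positive class.
#'
#' @param object a fitted [l1l2()] or [rls()] model.
#' @param newdata matrix of samples x features; must contain all model
#'   features by name (extra columns ignored). An unnamed matrix with the
#'   same number of columns is taken in training order.
#' @param type `"class"` for labels, `"score"` for the linear score.
#' @param ... unused.
#' @return labels (in the training label coding) or numeric scores.
#' @export
predict.l1l2 <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  feats <- names(object$beta)
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(feats, colnames(newdata))
    if (length(missing))
      stop("newdata is missing model features: ",
           paste(missing, collapse = ", "))
    newdata <- newdata[, feats, drop = FALSE]
  } else if (ncol(newdata) != length(feats)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(feats))
  }
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  score <- drop(xs %*% object$beta) + object$intercept
  if (type == "score") return(score)
  pos <- score >= 0                     # tie rule: sign(0) -> positive class
  cls <- object$classes
  if (identical(unname(cls), c("-1", "1"))) ifelse(pos, 1, -1)
  else ifelse(pos, cls[["pos"]], cls[["neg"]])
}

#' @export
coef.l1l2 <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$beta)
}

#' @export
print.l1l2 <- function(x, ...) {
  kind <- if (inherits(x, "rls")) "Regularized least squares"
          else "l1l2 sparse linear"
  cat(sprintf("%s classifier (tau = %g, mu = %g)\n", kind, x$tau, x$mu))
  cat(sprintf("  %d/%d features selected; classes %s (-) / %s (+)\n",
              length(x$selected), length(x$beta),
              x$classes[["neg"]], x$classes[["pos"]]))
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}

#' @export
summary.l1l2 <- function(object, ...) {
  sel <- object$beta[object$beta != 0]
  structure(list(model = object,
                 selected = sel[order(-abs(sel))]),
            class = "summary.l1l2")
}

#' @export
print.summary.l1l2 <- function(x, ...) {
  print(x$model)
  cat(sprintf("  objective %.6g after %d iterations\n",
              x$model$objective, x$model$iterations))
  if (length(x$selected)) {
    cat("  nonzero weights (standardized scale):\n")
    print(round(x$selected, 4))
  }
  invisible(x)
}

#' Warm-started l1l2 solutions along a tau grid
#'
#' Fits the model at every value of a descending l1-penalty grid, warm
#' starting each fit from the previous solution, and reports the selected
#' set size per `tau` — the "tuning dial" that trades signature size
#' against fit.
#'
#' @inheritParams l1l2
#' @param tau_grid descending vector of l1 weights; `NULL` builds a
#'   geometric grid of `grid_length` values from `tau_max(x, y)` (where the
#'   solution is empty) down to `tau_max * grid_ratio`.
#' @param grid_length,grid_ratio auto-grid shape (defaults 20 and 0.01).
#' @return object of class `l1l2_path`: list with `models` (one [l1l2()]
#'   fit per grid point) and `path` (data frame: tau, n_selected).
#' @export
regularization_path <- function(x, y, tau_grid = NULL, mu = 0.01,
                                grid_length = 20L, grid_ratio = 0.01,
                                tol = 1e-6, max_iter = 10000L) {
  if (is.null(tau_grid)) {
    # tiny headroom over the critical value so the first fit is exactly
    # empty despite floating-point rounding
    tm <- tau_max(x, y) * (1 + 1e-6)
    tau_grid <- tm * grid_ratio^(seq(0, 1, length.out = grid_length))
  }
  if (!length(tau_grid)) stop("empty tau grid")
  if (is.unsorted(rev(tau_grid), strictly = FALSE))
    stop("tau_grid must be descending")
  models <- vector("list", length(tau_grid))
  b0 <- NULL
  for (i in seq_along(tau_grid)) {
    models[[i]] <- l1l2(x, y, tau = tau_grid[i], mu = mu, tol = tol,
                        max_iter = max_iter, beta0 = b0)
    b0 <- models[[i]]$beta
  }
  structure(list(models = models,
                 path = data.frame(tau = tau_grid,
                                   n_selected = vapply(models, function(m)
                                     length(m$selected), 0L))),
            class = "l1l2_path")
}

#' @export
print.l1l2_path <- function(x, ...) {
  cat("l1l2 regularization path:\n")
  print(x$path, row.names = FALSE)
  invisible(x)
}

#' Smallest l1 weight with an all-zero solution
#'
#' On standardized features, the l1l2 solution is identically zero exactly
#' when `tau >= 2 max_j |<x_j, y - mean(y)>| / n`.
#'
#' @inheritParams l1l2
#' @return the critical tau value.
#' @export
tau_max <- function(x, y) {
  prep <- .prep_xy(x, y)
  yc <- prep$y - prep$intercept
  2 * max(abs(drop(crossprod(prep$xs, yc)))) / nrow(prep$xs)
}

#' Serialize a fitted model to JSON
#'
#' @param model an [l1l2()]/[rls()] fit.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the path (invisibly) or the JSON string.
#' @export
write_model_json <- function(model, path = NULL) {
  doc <- list(class = class(model), features = names(model$beta),
              beta = unname(model$beta), intercept = model$intercept,
              center = unname(model$center), scale = unname(model$scale),
              tau = model$tau, mu = model$mu, loss = model$loss,
              classes = as.list(model$classes), n = model$n,
              iterations = model$iterations, converged = model$converged,
              objective = model$objective)
  if (is.null(path))
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a model written by [write_model_json()]
#'
#' @param path JSON file path (or a JSON string).
#' @return an `l1l2` model object.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  feats <- doc$features
  structure(list(beta = stats::setNames(doc$beta, feats),
                 intercept = doc$intercept,
                 center = stats::setNames(doc$center, feats),
                 scale = stats::setNames(doc$scale, feats),
                 tau = doc$tau, mu = doc$mu,
                 classes = unlist(doc$classes),
                 selected = feats[doc$beta != 0],
                 objective = doc$objective,
                 iterations = doc$iterations, converged = doc$converged,
                 loss = doc$loss, n = doc$n),
            class = doc$class)
}
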