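# shared in-code fixtures

# raw numeric values of an expr_matrix, attributes beyond dim/dimnames gone
mat_values <- function(m) {
  out <- unclass(m)
  attr(out, "scale") <- NULL
  out
}

tiny_expr <- function(vals = matrix(c(1, 2, 3, 4, 5, 6), 3, 2),
                      scale = "log2",
                      features = paste0("hsa-miR-", seq_len(nrow(vals))),
                      samples = paste0("s", seq_len(ncol(vals)))) {
  dimnames(vals) <- list(features, samples)
  expr_matrix(vals, scale = scale)
}

two_group_meta <- function(samples, groups, batch = NULL, donor = NULL) {
  data.frame(sample_id = samples, group = groups,
             donor_id = donor %||% paste0("d", seq_along(samples)),
             batch_id = batch %||% "batch1",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# well-separated two-class design matrix: k informative of d features
separable_xy <- function(n_per = 5, d = 6, k = 2, shift = 4, sd = 0.3,
                         seed = 42) {
  set.seed(seed)
  y <- rep(c(-1, 1), each = n_per)
  x <- matrix(rnorm(2 * n_per * d, sd = 1), 2 * n_per, d,
              dimnames = list(NULL, paste0("f", seq_len(d))))
  for (j in seq_len(k)) x[, j] <- shift * y + rnorm(2 * n_per, sd = sd)
  list(x = x, y = y)
}

# exhaustive-search oracle for the l1l2 objective: cyclic coordinate
# descent on standardized inputs, independent of the FISTA path
l1l2_coord_oracle <- function(x, y, tau, mu, sweeps = 20000) {
  xs <- scale(x); yc <- y - mean(y); n <- nrow(xs)
  d <- ncol(xs)
  beta <- numeric(d)
  for (s in seq_len(sweeps)) {
    old <- beta
    for (j in seq_len(d)) {
      r <- yc - xs[, -j, drop = FALSE] %*% beta[-j]
      rho <- sum(xs[, j] * r) / n
      denom <- sum(xs[, j]^2) / n + mu
      beta[j] <- sign(rho) * max(abs(rho) - tau / 2, 0) / denom
    }
    if (max(abs(beta - old)) < 1e-13) break
  }
  beta
}

l1l2_objective <- function(x, y, beta, tau, mu) {
  xs <- scale(x); yc <- y - mean(y); n <- nrow(xs)
  sum((yc - xs %*% beta)^2) / n + tau * sum(abs(beta)) + mu * sum(beta^2)
}

# KS two-sample D by direct comparison of the empirical CDFs
ks_D_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(t) mean(a <= t), 0)
  Fb <- vapply(grid, function(t) mean(b <= t), 0)
  max(abs(Fa - Fb))
}

# upper hypergeometric tail by explicit combinatorial sum
hyper_tail_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
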