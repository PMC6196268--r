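test_that("a dominating l1 penalty empties the model", {
  fx <- separable_xy()
  tm <- tau_max(fx$x, fx$y)
  fit <- l1l2(fx$x, fx$y, tau = tm * 1.01, mu = 0.01)
  expect_equal(unname(fit$beta), rep(0, ncol(fx$x)))
  expect_equal(fit$intercept, mean(fx$y))
  expect_length(fit$selected, 0)
  # just below tau_max something enters
  fit2 <- l1l2(fx$x, fx$y, tau = tm * 0.95, mu = 0.01)
  expect_gt(length(fit2$selected), 0)
})

test_that("tau = 0 reproduces the ridge closed form to 1e-8", {
  set.seed(1)
  x <- matrix(rnorm(18), 6, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- c(-1, -1, -1, 1, 1, 1)
  fista <- suppressWarnings(l1l2(x, y, tau = 0, mu = 0.05, tol = 0,
                                 max_iter = 5e4))
  xs <- scale(x); yc <- y - mean(y)
  closed <- drop(solve(crossprod(xs) + 6 * 0.05 * diag(3),
                       crossprod(xs, yc)))
  expect_lt(max(abs(fista$beta - closed)), 1e-8)
  expect_lt(max(abs(rls(x, y, mu = 0.05)$beta - closed)), 1e-12)
})

test_that("one-dimensional fit matches the soft-threshold closed form", {
  set.seed(2)
  x <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "a"))
  y <- rep(c(-1, 1), 5)
  for (tau in c(0.05, 0.3, 1)) {
    fit <- suppressWarnings(l1l2(x, y, tau = tau, mu = 0.02, tol = 0,
                                 max_iter = 2e4))
    xs <- scale(x); yc <- y - mean(y); n <- 10
    rho <- sum(xs * yc) / n
    closed <- sign(rho) * max(abs(rho) - tau / 2, 0) /
      (sum(xs^2) / n + 0.02)
    expect_lt(abs(unname(fit$beta) - closed), 1e-10)
  }
})

test_that("solution matches a coordinate-descent oracle on small cases", {
  set.seed(3)
  for (case in 1:4) {
    x <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- c(-1, -1, 1, 1, sample(c(-1, 1), 1))
    if (length(unique(y)) < 2) y[5] <- -y[4]
    tau <- runif(1, 0.05, 0.5); mu <- runif(1, 0.01, 0.2)
    fit <- suppressWarnings(l1l2(x, y, tau = tau, mu = mu, tol = 0,
                                 max_iter = 3e4))
    oracle <- l1l2_coord_oracle(x, y, tau, mu)
    expect_lt(abs(l1l2_objective(x, y, fit$beta, tau, mu) -
                    l1l2_objective(x, y, oracle, tau, mu)), 1e-9)
    expect_lt(max(abs(fit$beta - oracle)), 1e-5)
  }
})

test_that("sparsity is exact and selected set shrinks along the path", {
  fx <- separable_xy(d = 10, k = 3)
  fit <- l1l2(fx$x, fx$y, tau = 0.8, mu = 0.01)
  expect_true(any(fit$beta == 0))          # hard zeros, not small values
  path <- regularization_path(fx$x, fx$y, mu = 0.01)
  expect_equal(path$path$n_selected[1], 0L)  # auto grid starts at tau_max
  expect_equal(nrow(path$path), 20L)
  # endpoint approaches the ridge solution as tau -> 0
  tiny <- suppressWarnings(
    l1l2(fx$x, fx$y, tau = 1e-10, mu = 0.05, tol = 0, max_iter = 5e4))
  expect_lt(max(abs(tiny$beta - rls(fx$x, fx$y, mu = 0.05)$beta)), 1e-6)
  expect_error(regularization_path(fx$x, fx$y, tau_grid = numeric()),
               "empty")
  expect_error(regularization_path(fx$x, fx$y, tau_grid = c(0.1, 0.5)),
               "descending")
})

test_that("prediction: sign rule, tie to positive class, name matching", {
  fx <- separable_xy()
  fit <- l1l2(fx$x, fx$y, tau = 0.1, mu = 0.01)
  expect_equal(predict(fit, fx$x), fx$y)   # separable: 0 training errors
  # exact-zero score maps to +1 by the documented tie rule
  zfit <- fit
  zfit$beta[] <- 0; zfit$intercept <- 0
  expect_true(all(predict(zfit, fx$x) == 1))
  expect_error(predict(fit, fx$x[, 1:3]), "missing model features")
  # factor labels come back as labels, dim being the positive class
  yf <- factor(ifelse(fx$y > 0, "dim", "bright"))
  ffit <- l1l2(fx$x, yf, tau = 0.1, mu = 0.01)
  expect_equal(unname(predict(ffit, fx$x)),
               ifelse(fx$y > 0, "dim", "bright"))
  expect_identical(ffit$classes[["pos"]], "dim")
})

test_that("permuting feature order permutes the weights identically", {
  fx <- separable_xy(d = 8, k = 2)
  fit <- l1l2(fx$x, fx$y, tau = 0.2, mu = 0.05)
  perm <- sample(ncol(fx$x))
  fit_p <- l1l2(fx$x[, perm], fx$y, tau = 0.2, mu = 0.05)
  expect_equal(fit_p$beta[names(fit$beta)], fit$beta, tolerance = 1e-7)
})

test_that("ridge contract: mu > 0 required, beta -> 0 as mu grows,
           orthonormal-design closed form", {
  fx <- separable_xy()
  expect_error(rls(fx$x, fx$y, mu = 0), "positive")
  big <- rls(fx$x, fx$y, mu = 1e6)
  expect_lt(max(abs(big$beta)), 1e-3)
  # exactly orthogonal centered design: the normal equations decouple and
  # beta_j = <x_j, y - mean(y)> / (x_j'x_j + n mu) per coordinate
  n <- 8
  x <- cbind(f1 = rep(c(-1, 1), 4),
             f2 = rep(c(-1, -1, 1, 1), 2),
             f3 = rep(c(-1, 1), each = 4))
  y <- c(-1, 1, 1, -1, 1, -1, -1, 1)
  fit <- rls(x, y, mu = 0.3)
  xs <- scale(x)                     # same standardization as the fitter
  yc <- y - mean(y)
  expect_equal(unname(fit$beta),
               unname(drop(crossprod(xs, yc)) /
                        (colSums(xs^2) + n * 0.3)),
               tolerance = 1e-12)
  # and the primal/dual solvers agree when d > n
  set.seed(9)
  xw <- matrix(rnorm(5 * 12), 5, 12,
               dimnames = list(NULL, paste0("g", 1:12)))
  yw <- c(-1, -1, 1, 1, 1)
  dual <- rls(xw, yw, mu = 0.2)$beta
  xsw <- scale(xw); ycw <- yw - mean(yw)
  primal <- drop(solve(crossprod(xsw) + 5 * 0.2 * diag(12),
                       crossprod(xsw, ycw)))
  expect_equal(unname(dual), unname(primal), tolerance = 1e-10)
})

test_that("degenerate inputs are rejected with clear errors", {
  fx <- separable_xy()
  expect_error(l1l2(fx$x, rep(1, 10), tau = 0.1, mu = 0.1), "both classes")
  xz <- fx$x; xz[, 2] <- 7
  expect_error(l1l2(xz, fx$y, tau = 0.1, mu = 0.1), "zero-variance")
  expect_error(l1l2(fx$x, fx$y, tau = -1, mu = 0.1), ">= 0")
})

test_that("models serialize to JSON and back without loss", {
  fx <- separable_xy()
  fit <- l1l2(fx$x, fx$y, tau = 0.3, mu = 0.02)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$center, fit$center)
  expect_equal(back$tau, fit$tau)
  expect_equal(predict(back, fx$x), predict(fit, fx$x))
  expect_s3_class(back, "l1l2")
})
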